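test_that("log-ratio variances match a direct computation", {
  f <- matrix(c(
    0.10, 0.20, 0.30, 0.40,
    0.15, 0.25, 0.25, 0.35,
    0.05, 0.30, 0.40, 0.25,
    0.20, 0.20, 0.30, 0.30
  ), 4, 4, byrow = TRUE)
  T_mat <- log_ratio_variances(f)
  # direct spreadsheet-style oracle for a couple of entries
  expect_equal(T_mat[1, 2], stats::var(log(f[, 1] / f[, 2])))
  expect_equal(T_mat[3, 4], stats::var(log(f[, 3] / f[, 4])))
  expect_equal(T_mat, t(T_mat))
  expect_true(all(diag(T_mat) == 0))

  # identical columns give zero log-ratio variance
  f2 <- cbind(f[, 1], f[, 1], f[, 2], f[, 3])
  f2 <- f2 / rowSums(f2)
  expect_equal(log_ratio_variances(f2)[1, 2], 0)

  expect_error(log_ratio_variances(cbind(f[, 1:3], 0)), "positive")
  expect_error(log_ratio_variances(f[, 1:3]), "4 OTUs")
})

test_that("the basis solve recovers near-zero correlations on a null basis", {
  p <- 50; n <- 200
  z <- otudyn:::with_seed(31, matrix(rnorm(n * p, sd = 0.5), n, p))
  f <- exp(z) / rowSums(exp(z))
  est <- basis_correlations_once(log_ratio_variances(f))
  r <- est$rho; diag(r) <- 0
  expect_lt(max(abs(r)), 0.3)
  expect_true(all(diag(est$rho) == 1))
  expect_true(all(est$rho >= -1 & est$rho <= 1))
  expect_true(all(est$omega > 0))
})

test_that("a planted correlated pair is estimated close to its latent value", {
  p <- 30; n <- 200
  z <- otudyn:::with_seed(32, {
    base <- matrix(rnorm(n * p, sd = 0.6), n, p)
    shared <- rnorm(n, sd = 0.6)
    base[, 1] <- sqrt(0.8) * shared + sqrt(0.2) * base[, 1]
    base[, 2] <- sqrt(0.8) * shared + sqrt(0.2) * base[, 2]
    base
  })
  f <- exp(z) / rowSums(exp(z))
  est <- basis_correlations_once(log_ratio_variances(f))
  truth <- cor(z[, 1], z[, 2])
  expect_lt(abs(est$rho[1, 2] - truth), 0.15)
})

test_that("the full estimate is deterministic and compositionally invariant", {
  sim <- blocky_table(n = 60, n_otus = 20, seed = 33)
  r1 <- sparcc_estimate(sim$table$counts, seed = 5)
  r2 <- sparcc_estimate(sim$table$counts, seed = 5)
  expect_identical(r1$rho, r2$rho)

  # exact fractions are unchanged by per-sample scaling, hence so is rho
  cnt <- sim$table$counts + 1   # strictly positive
  f <- cnt / rowSums(cnt)
  scaled <- cnt * rep(c(1, 3, 7), length.out = nrow(cnt))
  f_scaled <- scaled / rowSums(scaled)
  expect_equal(f, f_scaled)
  e1 <- basis_correlations_once(log_ratio_variances(f))
  e2 <- basis_correlations_once(log_ratio_variances(f_scaled))
  expect_identical(e1$rho, e2$rho)
})

test_that("block correlation structure is recovered from counts", {
  sim <- blocky_table(n = 100, n_otus = 50, rho = 0.8, seed = 34)
  sp <- sparcc_estimate(sim$table$counts, seed = 35)
  b <- sim$truth$block_assignments
  within <- sp$rho[b == 1, b == 1]
  between <- sp$rho[b == 1, b == 2]
  expect_gt(mean(within[upper.tri(within)]), mean(between) + 0.3)
})

test_that("permutation null p-values respect their floor and symmetry", {
  # one small correlated block among mostly independent OTUs, so the
  # sparsity assumption holds and the planted pairs are detectable
  d <- study_design("G1", 0, matrix(60, 1, 1), n_otus = 16)
  eff <- effect_spec(d, n_blocks = 1, block_size = 4, rho_block = 0.8)
  sim <- simulate_otu_table(d, eff, seed = 36)
  sp <- sparcc_estimate(sim$table$counts, n_est_iter = 5, seed = 37)
  pv <- suppressWarnings(
    sparcc_null_pvalues(sim$table$counts, sp$rho, n_null = 20, seed = 38,
                        n_est_iter = 5)
  )
  expect_gte(min(pv), 1 / 21)
  expect_equal(pv, t(pv))
  expect_true(all(diag(pv) == 1))
  # strongly correlated within-block pairs sit at or near the floor
  b <- sim$truth$block_assignments
  wb <- pv[b == 1, b == 1]
  expect_lt(median(wb[upper.tri(wb)]), 0.2)
  expect_error(sparcc_null_pvalues(sim$table$counts, sp$rho, n_null = 0), ">= 1")
})

test_that("network construction thresholds edges correctly", {
  rho <- diag(4)
  rho[1, 2] <- rho[2, 1] <- 0.8
  rho[3, 4] <- rho[4, 3] <- -0.6
  rho[1, 3] <- rho[3, 1] <- 0.3
  colnames(rho) <- rownames(rho) <- sprintf("OTU%d", 1:4)
  net <- build_network(list(rho = rho), edge_threshold = 0.5)
  expect_equal(nrow(net$edges), 2L)
  expect_setequal(net$edges$sign, c("positive", "negative"))

  none <- build_network(list(rho = diag(4) * 1), edge_threshold = 0.5)
  expect_equal(nrow(none$edges), 0L)

  full <- build_network(list(rho = rho), edge_threshold = 0)
  # brute-force count of super-threshold upper-triangle entries
  expect_equal(nrow(full$edges), sum(abs(rho[upper.tri(rho)]) > 0))

  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".graphml")
  write_network(net, f1, f2)
  expect_true(file.exists(f1) && file.exists(f2))
})

test_that("exclusion iteration flags non-positive variances instead of failing", {
  # pathological T matrix: one OTU identical to another drives omega negative
  sim <- blocky_table(n = 30, n_otus = 8, rho = 0, seed = 40)
  cnt <- sim$table$counts
  cnt[, 2] <- cnt[, 1]
  f <- (cnt + 1) / rowSums(cnt + 1)
  expect_no_error(suppressWarnings(basis_correlations_once(log_ratio_variances(f))))
})
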