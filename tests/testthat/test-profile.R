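make_table <- function(counts, groups = NULL, days = NULL) {
  n <- nrow(counts)
  otu_table(counts, data.frame(
    sample_id = rownames(counts) %||% sprintf("S%03d", seq_len(n)),
    group = groups %||% rep("G", n),
    day = days %||% rep(0L, n),
    subject = sprintf("M%02d", seq_len(n))
  ))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("rarefaction excludes shallow samples and hits the target depth", {
  counts <- rbind(
    S1 = c(5000, 3000, 999),   # 8999 reads: excluded
    S2 = c(6000, 3000, 1000),  # 10000 reads
    S3 = c(9000, 0, 0)         # exactly at depth: returned unchanged
  )
  tab <- make_table(counts)
  rar <- rarefy(tab, depth = 9000, n_rep = 3, seed = 1)
  expect_equal(rar$excluded_samples, "S1")
  expect_true(all(rowSums(rar$counts) == 9000))
  expect_equal(unname(rar$counts["S3", ]), c(9000, 0, 0))

  shallow <- make_table(rbind(S1 = c(10, 10)))
  expect_error(rarefy(shallow, depth = 9000), "below")

  # deterministic under a fixed seed
  rar2 <- rarefy(tab, depth = 9000, n_rep = 3, seed = 1)
  expect_identical(rar$counts, rar2$counts)
  expect_identical(rar$alpha, rar2$alpha)
})

test_that("richness and Shannon follow their closed forms", {
  expect_equal(observed_otus(c(5, 0, 3)), 2)
  expect_equal(observed_otus(c(0, 0)), 0)
  expect_equal(shannon(c(1, 1, 1, 1)), 2)
  expect_equal(shannon(c(9000, 0, 0)), 0)
  expect_equal(shannon(c(2, 1, 1)), 1.5)
  expect_error(shannon(c(0, 0)), "positive")
  # natural-log option
  expect_equal(shannon(c(1, 1), base = exp(1)), log(2))
})

test_that("rarefied richness never exceeds raw richness", {
  for (s in 1:5) {
    counts <- with_seed(s, matrix(rpois(5 * 40, 60), 5, 40))
    rownames(counts) <- sprintf("S%d", 1:5)
    tab <- make_table(counts)
    rar <- rarefy(tab, depth = min(rowSums(counts)), n_rep = 1, seed = s)
    expect_true(all(rowSums(rar$counts > 0) <= rowSums(counts > 0)))
  }
})
with_seed <- otudyn:::with_seed

test_that("mean Shannon over 1000 repetitions is tightly estimated", {
  counts <- matrix(with_seed(9, rpois(100, 150)), 1, 100,
                   dimnames = list("S1", NULL))
  tab <- make_table(counts)
  rar <- rarefy(tab, depth = 9000, n_rep = 1000, seed = 2)
  expect_lt(rar$alpha$shannon_se, 0.01)
})

test_that("Bray-Curtis matches its definition", {
  m <- rbind(a = c(5, 5, 0), b = c(0, 5, 5), c = c(5, 5, 0), d = c(1, 0, 0))
  D <- bray_curtis(m)
  expect_equal(D["a", "c"], 0)
  expect_equal(D["a", "b"], 0.5)
  disj <- bray_curtis(rbind(x = c(3, 0), y = c(0, 7)))
  expect_equal(disj["x", "y"], 1)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0 & D <= 1))
})

test_that("PCoA reconstructs Euclidean configurations", {
  pts <- with_seed(3, matrix(rnorm(20), 10, 2))
  D <- as.matrix(dist(pts))
  ord <- pcoa(D)
  Dhat <- as.matrix(dist(ord$coordinates))
  expect_lt(max(abs(Dhat - D)), 1e-8)
  expect_true(all(diff(ord$eigenvalues) <= 1e-12))
  expect_lte(sum(ord$proportion_explained), 1 + 1e-12)

  # eigenvalue sum equals the trace of the Gower-centered matrix
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D^2 %*% J
  all_eig <- c(ord$eigenvalues, ord$negative_eigenvalues)
  expect_lt(abs(sum(all_eig) - sum(diag(B))) / max(1, abs(sum(diag(B)))), 1e-6)

  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")

  ident <- pcoa(matrix(0, 4, 4))
  expect_true(ncol(ident$coordinates) == 0 || max(abs(ident$coordinates)) < 1e-10)
})

test_that("PCA via PCoA on Euclidean distances matches prcomp scores", {
  ab <- with_seed(8, matrix(runif(60), 6, 10))
  ab <- ab / rowSums(ab)
  ord <- pca_ordination(ab)
  pc <- prcomp(ab, center = TRUE, scale. = FALSE)
  k <- min(3, ncol(ord$coordinates))
  for (j in seq_len(k)) {
    expect_lt(min(max(abs(ord$coordinates[, j] - pc$x[, j])),
                  max(abs(ord$coordinates[, j] + pc$x[, j]))), 1e-8)
  }
})

test_that("baseline-distance trajectories are computable per group-day", {
  sim <- simulate_otu_table(build_default_design(n_otus = 30),
                            effect_spec(build_default_design(n_otus = 30),
                                        n_blocks = 2, block_size = 5),
                            seed = 17)
  rar <- rarefy(sim$table, depth = 9000, n_rep = 1, seed = 1)
  D <- bray_curtis(rar)
  traj <- distance_from_baseline(D, rar$metadata)
  expect_setequal(unique(traj$group), c("PBS", "DSS", "DSS_BPB5"))
  expect_true(all(traj$mean_dist >= 0 & traj$mean_dist <= 1))
  # treated groups drift further from baseline than the control by day 7
  d7 <- function(g) traj$mean_dist[traj$group == g & traj$day == 7]
  expect_gt(d7("DSS"), d7("PBS"))
})
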