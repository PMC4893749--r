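block_rho <- function(sizes, within = 0.9, between = -0.2, noise = 0, seed = 1) {
  p <- sum(sizes)
  blk <- rep(seq_along(sizes), sizes)
  rho <- matrix(between, p, p)
  for (b in seq_along(sizes)) rho[blk == b, blk == b] <- within
  if (noise > 0) {
    e <- otudyn:::with_seed(seed, matrix(rnorm(p * p, sd = noise), p, p))
    rho <- rho + (e + t(e)) / 2
  }
  diag(rho) <- 1
  colnames(rho) <- rownames(rho) <- sprintf("OTU%02d", seq_len(p))
  rho
}

test_that("correlation distance is the mirrored correlation", {
  rho <- block_rho(c(2, 2))
  d <- correlation_distance(rho)
  expect_equal(d[1, 2], 1 - 0.9)
  expect_equal(d[1, 3], 1.2)
  expect_true(all(diag(d) == 0))
  expect_equal(correlation_distance(matrix(c(1, -1, -1, 1), 2))[1, 2], 2)
})

test_that("Ward tree separates two tight distant clusters at the top split", {
  pts <- rbind(matrix(rnorm(10, 0, 0.05), 5, 2), matrix(rnorm(10, 10, 0.05), 5, 2))
  D <- as.matrix(dist(pts))
  rownames(D) <- colnames(D) <- sprintf("P%02d", 1:10)
  h <- ward_dendrogram(D)
  top <- stats::cutree(h, 2)
  expect_equal(length(unique(top[1:5])), 1L)
  expect_equal(length(unique(top[6:10])), 1L)
  expect_false(top[1] == top[6])
  expect_setequal(h$order, 1:10)

  h2 <- ward_dendrogram(as.matrix(dist(c(0, 1))))
  expect_equal(nrow(h2$merge), 1L)
})

test_that("two clean correlation blocks give exactly two CAGs", {
  rho <- block_rho(c(6, 6), within = 0.9, between = -0.2, noise = 0.03)
  D <- correlation_distance(rho)
  cut <- permanova_cut(ward_dendrogram(D), D, n_perm = 999, seed = 2)
  expect_equal(cut$n_cags, 2L)
  truth <- rep(1:2, each = 6)
  expect_equal(mclust::adjustedRandIndex(cut$assignment, truth), 1)
})

test_that("a structureless correlation matrix stays a single CAG", {
  rho <- block_rho(12, within = 0, between = 0, noise = 0.08, seed = 5)
  diag(rho) <- 1
  D <- correlation_distance(rho)
  cut <- permanova_cut(ward_dendrogram(D), D, n_perm = 999, seed = 3)
  expect_equal(cut$n_cags, 1L)
})

test_that("the CAG partition is disjoint and exhaustive, and alpha is monotone", {
  rho <- block_rho(c(5, 5, 5), within = 0.85, between = -0.1, noise = 0.05)
  D <- correlation_distance(rho)
  tree <- ward_dendrogram(D)
  cut <- permanova_cut(tree, D, n_perm = 999, seed = 4)
  expect_setequal(names(cut$assignment), colnames(rho))
  expect_true(all(cut$assignment >= 1 & cut$assignment <= cut$n_cags))
  expect_equal(length(cut$assignment), ncol(rho))

  loose <- permanova_cut(tree, D, alpha = 0.2, n_perm = 999, seed = 4)
  expect_gte(loose$n_cags, cut$n_cags)

  single <- permanova_cut(NULL, matrix(0, 1, 1))
  expect_equal(single$n_cags, 1L)
})

test_that("CAG abundance profiles conserve the key-OTU total", {
  ab <- rbind(S1 = c(0.2, 0.3, 0.5), S2 = c(0.1, 0.1, 0.8))
  colnames(ab) <- c("OTU1", "OTU2", "OTU3")
  asg <- c(OTU1 = 1L, OTU2 = 1L, OTU3 = 2L)
  prof <- cag_abundance_profiles(ab, asg)
  expect_equal(unname(prof[, "CAG1"]), c(0.5, 0.2))
  expect_equal(unname(prof[, "CAG2"]), c(0.5, 0.8))
  expect_equal(rowSums(prof), rowSums(ab))

  singleton <- cag_abundance_profiles(ab, c(OTU2 = 1L))
  expect_equal(unname(singleton[, 1]), unname(ab[, "OTU2"]))

  expect_error(cag_abundance_profiles(ab, c(OTUX = 1L)), "absent")
})

test_that("CAG dynamics flag a planted fold change against the reference", {
  d <- study_design(c("CTRL", "TRT"), c(0, 1), matrix(12, 2, 2), n_otus = 40)
  eff <- effect_spec(d, n_blocks = 2, block_size = 5, rho_block = 0,
                     effect_size = log(4), depleted_blocks = 1,
                     enriched_blocks = integer(), treated_groups = "TRT",
                     invader_group = NA)
  # make the depletion active at both days
  eff$shift[1:5, "TRT", ] <- -log(4)
  sim <- simulate_otu_table(d, eff, seed = 6)
  ab <- relative_abundances(sim$table)
  asg <- stats::setNames(rep(1:2, each = 5), sprintf("OTU%03d", 1:10))
  prof <- cag_abundance_profiles(ab, asg)
  dyn <- cag_group_dynamics(prof, sim$table$metadata, reference_group = "CTRL")
  hit <- dyn[dyn$cag == "CAG1", ]
  expect_true(all(hit$adjusted_p < 0.05))
  expect_true(all(dyn$adjusted_p >= dyn$raw_p))

  one_group <- sim$table$metadata[sim$table$metadata$group == "TRT", ]
  expect_error(
    cag_group_dynamics(prof[one_group$sample_id, , drop = FALSE], one_group, "TRT"),
    "2 groups"
  )
})

test_that("invader correlates split by sign at the threshold", {
  rho <- block_rho(c(3, 3), within = 0.9, between = -0.7)
  out <- invader_correlates(list(rho = rho), "OTU01", threshold = 0.5)
  expect_setequal(out$positive, c("OTU02", "OTU03"))
  expect_setequal(out$negative, c("OTU04", "OTU05", "OTU06"))

  zero <- diag(5); colnames(zero) <- rownames(zero) <- sprintf("Z%d", 1:5)
  none <- invader_correlates(list(rho = zero), "Z1")
  expect_length(none$positive, 0)
  expect_length(none$negative, 0)

  capped <- invader_correlates(list(rho = rho), "OTU01", threshold = 1)
  expect_length(capped$positive, 0)
  expect_length(capped$negative, 0)
  expect_error(invader_correlates(list(rho = rho), "missing"), "not present")
})

test_that("CAG assignment exports TSV and Newick", {
  rho <- block_rho(c(4, 4), noise = 0.02)
  D <- correlation_distance(rho)
  cut <- permanova_cut(ward_dendrogram(D), D, n_perm = 199, seed = 9)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".nwk")
  write_cag_assignment(cut, f1, f2)
  tab <- utils::read.delim(f1)
  expect_equal(nrow(tab), 8L)
  phy <- ape::read.tree(f2)
  expect_equal(length(phy$tip.label), 8L)
})
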