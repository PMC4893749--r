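test_that("quality truncation cuts at the first low-quality base", {
  r <- fastq_read("a", "ACGT", c(30L, 30L, 2L, 30L))
  tr <- truncate_at_quality(r)
  expect_equal(tr$bases, "AC")
  expect_equal(tr$quals, c(30L, 30L))

  r2 <- fastq_read("b", "ACGT", rep(40L, 4))
  expect_identical(truncate_at_quality(r2), r2)

  r3 <- fastq_read("c", "ACG", c(2L, 30L, 30L))
  expect_equal(nchar(truncate_at_quality(r3)$bases), 0L)
})

test_that("expected error follows the Phred sum", {
  expect_equal(expected_error(rep(20L, 400)), 4.0)
  expect_equal(expected_error(rep(30L, 50)), 0.05)
  expect_equal(expected_error(integer(0)), 0.0)
  expect_error(expected_error(c(10L, -1L)), ">= 0")
})

test_that("pair merging finds the true overlap and applies the thresholds", {
  tpl <- random_templates(1, 500, seed = 2)[[1]]
  # 300-base reads sharing an exact 100-base overlap
  p <- make_pair(tpl, 300, 300, rep(40L, 300), rep(40L, 300))
  m <- merge_pair(p$fwd, p$rev)
  expect_equal(nchar(m$bases), 500L)
  expect_equal(attr(m, "overlap_len"), 100L)
  expect_equal(m$bases, tpl)

  # 49-base overlap falls below the minimum
  p49 <- make_pair(tpl, 300, 249, rep(40L, 300), rep(40L, 249))
  expect_null(merge_pair(p49$fwd, p49$rev))

  # 20 mismatches in a 100-base overlap exceed the 10% tolerance
  rb <- strsplit(p$rev$bases, "")[[1]]
  flip <- function(b) c(A = "C", C = "G", G = "T", T = "A")[[b]]
  mism_pos <- 250:269   # lies inside the overlap region of the reverse read
  rb[mism_pos] <- vapply(rb[mism_pos], flip, "")
  bad_rev <- fastq_read("p1", paste(rb, collapse = ""), p$rev$quals)
  expect_null(merge_pair(p$fwd, bad_rev))

  # higher quality wins inside the overlap
  rb2 <- strsplit(p$rev$bases, "")[[1]]
  rb2[260] <- flip(rb2[260])
  qr <- rep(40L, 300); qr[260] <- 10L
  m2 <- merge_pair(p$fwd, fastq_read("p1", paste(rb2, collapse = ""), qr))
  expect_equal(m2$bases, tpl)   # forward base (Q40) kept over the Q10 error
})

test_that("length/EE filter keeps only long, low-error reads and is idempotent", {
  mk <- function(len, q) fastq_read("x", paste(rep("A", len), collapse = ""),
                                    rep(as.integer(q), len))
  r399 <- mk(399, 40)                       # EE ~ 0.04 but too short
  r450 <- mk(450, 40)                       # EE 0.045 <= 0.5
  r450ee <- mk(450, 29)                     # EE = 450 * 10^-2.9 = 0.566 > 0.5
  kept <- qc_filter_reads(list(r399, r450, r450ee))
  expect_length(kept, 1)
  expect_equal(nchar(kept[[1]]$bases), 450L)
  expect_identical(qc_filter_reads(kept), kept)

  # inclusive boundary: EE exactly 0.5 is kept
  r_half <- fastq_read("y", paste(rep("A", 400), collapse = ""),
                       c(rep(40L, 399), 0L))   # EE = 399e-4 + 1 > 0.5? no: Q0 = 1
  expect_length(qc_filter_reads(list(r_half)), 0)
  quals <- rep(30L, 400); quals[1:100] <- 24L  # EE = 300*.001 + 100*10^-2.4
  ee <- expected_error(quals)
  expect_lt(abs(ee - (300 * 1e-3 + 100 * 10^-2.4)), 1e-12)
})

test_that("simulated fixtures exercise every QC branch with known verdicts", {
  tpl <- random_templates(2, 500, seed = 9)

  all_q <- function(q) function(rl_f, rl_r) list(fwd = rep(as.integer(q), rl_f),
                                                 rev = rep(as.integer(q), rl_r))
  # all Q=40: every pair merges to the template length and passes
  rr <- simulate_paired_reads(tpl, c(tpl1 = 5, tpl2 = 5), all_q(40), seed = 1)
  expect_true(all(rr$expected_pass))
  qc <- qc_process_pairs(rr$fwd, rr$rev)
  expect_true(all(qc$pass))
  expect_true(all(vapply(qc$merged, function(r) nchar(r$bases), 0L) == 500L))

  # all Q=2: truncated to nothing, every pair fails
  rr2 <- simulate_paired_reads(tpl, c(tpl1 = 3), all_q(2), seed = 1)
  expect_false(any(rr2$expected_pass))
  expect_false(any(qc_process_pairs(rr2$fwd, rr2$rev)$pass))

  # all Q=20: merges but EE = 500 * 0.01 >> 0.5
  rr3 <- simulate_paired_reads(tpl, c(tpl1 = 3), all_q(20), seed = 1)
  expect_false(any(rr3$expected_pass))
  expect_false(any(qc_process_pairs(rr3$fwd, rr3$rev)$pass))

  expect_error(simulate_paired_reads(tpl, c(tpl1 = 1), overlap = 0), ">= 1")
})

test_that("QC decisions match the planted verdicts on mixed fixtures", {
  tpl <- random_templates(4, 500, seed = 11)
  counts <- c(tpl1 = 50, tpl2 = 50, tpl3 = 50, tpl4 = 50)
  rr <- simulate_paired_reads(tpl, counts, default_quality_model(), seed = 13)
  qc <- qc_process_pairs(rr$fwd, rr$rev)
  expect_equal(unname(qc$pass), unname(rr$expected_pass))
  # both verdict classes must actually occur for this to be a real check
  expect_gt(mean(rr$expected_pass), 0.3)
  expect_lt(mean(rr$expected_pass), 0.95)
})

test_that("FASTQ records round-trip through Phred+33 files", {
  reads <- list(
    fastq_read("r1", "ACGTN", c(2L, 10L, 20L, 30L, 40L)),
    fastq_read("r2", "GGGG", rep(35L, 4))
  )
  f <- tempfile(fileext = ".fastq")
  write_fastq(reads, f)
  back <- read_fastq(f)
  expect_equal(back[[1]]$bases, "ACGTN")
  expect_equal(back[[1]]$quals, c(2L, 10L, 20L, 30L, 40L))
  expect_equal(back[[2]]$id, "r2")
})
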