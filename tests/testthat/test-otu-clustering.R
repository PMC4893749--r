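test_that("dereplication groups exact duplicates and drops singletons", {
  out <- dereplicate(c("AAA", "AAA", "CCC"))
  expect_equal(out$sequence, "AAA")
  expect_equal(out$size, 2L)

  expect_equal(nrow(dereplicate(character(0))), 0L)

  seqs <- c(rep("ATAT", 3), rep("CGCG", 3), rep("GGGG", 2))
  out3 <- dereplicate(sample(seqs))
  expect_equal(out3$size, c(3L, 3L, 2L))
  # ties broken lexicographically, so the order is fully deterministic
  expect_equal(out3$sequence, c("ATAT", "CGCG", "GGGG"))
})

test_that("alignment identity counts matches over non-terminal columns", {
  base <- strsplit(random_templates(1, 100, seed = 4)[[1]], "")[[1]]
  flip <- function(b) c(A = "C", C = "G", G = "T", T = "A")[[b]]
  two <- base; two[c(10, 50)] <- vapply(two[c(10, 50)], flip, "")
  five <- base; five[c(10, 30, 50, 70, 90)] <- vapply(five[c(10, 30, 50, 70, 90)], flip, "")
  expect_equal(seq_identity(paste(base, collapse = ""), paste(two, collapse = "")), 0.98)
  expect_equal(seq_identity(paste(base, collapse = ""), paste(five, collapse = "")), 0.95)
  expect_equal(seq_identity("ACGTACGT", "ACGTACGT"), 1)
})

test_that("greedy clustering honours the 97% identity rule", {
  base <- strsplit(random_templates(1, 100, seed = 5)[[1]], "")[[1]]
  flip <- function(b) c(A = "C", C = "G", G = "T", T = "A")[[b]]
  two <- base; two[c(3, 60)] <- vapply(two[c(3, 60)], flip, "")
  five <- base; five[seq(5, 85, by = 20)] <- vapply(five[seq(5, 85, by = 20)], flip, "")

  u1 <- data.frame(sequence = c(paste(base, collapse = ""), paste(two, collapse = "")),
                   size = c(5L, 3L))
  expect_equal(nrow(cluster_otus(u1)), 1L)     # 98% identity joins
  expect_equal(cluster_otus(u1)$size, 8L)

  u2 <- data.frame(sequence = c(paste(base, collapse = ""), paste(five, collapse = "")),
                   size = c(5L, 3L))
  expect_equal(nrow(cluster_otus(u2)), 2L)     # 95% identity founds a new centroid

  u3 <- data.frame(sequence = "ACGTACGTAC", size = 2L)
  expect_equal(cluster_otus(u3)$sequence, "ACGTACGTAC")

  # at identity 1.0 every unique sequence is its own centroid
  u4 <- dereplicate(c(rep("AAAA", 2), rep("AAAT", 2), rep("AATT", 2)))
  expect_equal(nrow(cluster_otus(u4, identity = 1)), 3L)
})

test_that("read mapping assigns by best identity with abundance tie-break", {
  base <- strsplit(random_templates(1, 100, seed = 6)[[1]], "")[[1]]
  flip <- function(b) c(A = "C", C = "G", G = "T", T = "A")[[b]]
  c1 <- base
  c2 <- base; c2[seq(2, 30, by = 4)] <- vapply(c2[seq(2, 30, by = 4)], flip, "")
  centroids <- data.frame(
    otu_id = c("OTU1", "OTU2"),
    sequence = c(paste(c1, collapse = ""), paste(c2, collapse = "")),
    size = c(10L, 20L)
  )
  # identical to centroid 1
  expect_equal(unname(map_reads(paste(c1, collapse = ""), centroids)), c(1L, 0L))

  # below the cutoff everywhere: dropped (5 mismatches to c1, and c2 differs more)
  far <- base; far[c(11, 31, 51, 71, 91)] <- vapply(far[c(11, 31, 51, 71, 91)], flip, "")
  expect_equal(sum(map_reads(paste(far, collapse = ""), centroids)), 0L)

  # equidistant read goes to the larger centroid
  eq1 <- base; eq1[c(40, 80)] <- vapply(eq1[c(40, 80)], flip, "")
  big <- data.frame(
    otu_id = c("OTU1", "OTU2"),
    sequence = c(paste(base, collapse = ""), paste(eq1, collapse = "")),
    size = c(3L, 9L)
  )
  mid <- base; mid[40] <- flip(base[40])   # 1 mismatch to each -> 99% to both
  counts <- map_reads(paste(mid, collapse = ""), big)
  expect_equal(unname(counts), c(0L, 1L))
  expect_error(map_reads("ACGT", centroids[0, ]), "non-empty")
})

test_that("mapped counts never exceed the QC-passing read count", {
  tpl <- random_templates(2, 500, seed = 21)
  rr <- simulate_paired_reads(tpl, c(tpl1 = 30, tpl2 = 30), seed = 22)
  qc <- qc_process_pairs(rr$fwd, rr$rev)
  uniq <- dereplicate(qc$merged, min_size = 1)
  cents <- cluster_otus(uniq)
  counts <- map_reads(qc$merged, cents)
  expect_lte(sum(counts), length(qc$merged))
  expect_equal(nrow(cents), 2L)   # two templates, two OTUs
})

test_that("chimera hook and centroid FASTA export behave", {
  u <- dereplicate(c(rep("ACGT", 3), rep("TTTT", 2)))
  expect_identical(chimera_filter(u), u)
  cents <- cluster_otus(u, identity = 1)
  f <- tempfile(fileext = ".fasta")
  write_centroids_fasta(cents, f)
  back <- Biostrings::readDNAStringSet(f)
  expect_equal(length(back), nrow(cents))
})
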