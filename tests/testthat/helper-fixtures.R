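# Shared fixture builders; everything is generated in code at test time.

# two groups sampled at day 7 (full treatment effect), one enriched block of
# 10 OTUs among 100, no latent correlation
two_group_table <- function(effect = log(4), n = 12, seed = 1, n_otus = 100) {
  d <- study_design(c("A", "B"), 7, matrix(c(n, n), 2, 1), n_otus = n_otus)
  eff <- effect_spec(d,
    n_blocks = 1, block_size = 10, rho_block = 0,
    effect_size = effect, depleted_blocks = integer(), enriched_blocks = 1,
    treated_groups = "B", invader_group = NA
  )
  simulate_otu_table(d, eff, seed)
}

# single-group cross-sectional community of correlated blocks (5 blocks of
# 10 at the default size; fewer/smaller blocks for small test tables)
blocky_table <- function(n = 100, n_otus = 50, rho = 0.8, seed = 1) {
  d <- study_design("G1", 0, matrix(n, 1, 1), n_otus = n_otus)
  n_blocks <- max(2, min(5, n_otus %/% 10))
  eff <- effect_spec(d, n_blocks = n_blocks, block_size = n_otus %/% n_blocks,
                     rho_block = rho)
  simulate_otu_table(d, eff, seed = seed)
}

planted_ids <- function(k = 10) sprintf("OTU%03d", seq_len(k))

# a read pair covering a fixed template with given quality vectors
make_pair <- function(template, rl_f, rl_r, qf, qr, id = "p1") {
  L <- nchar(template)
  fwd <- fastq_read(id, substr(template, 1, rl_f), qf)
  rev <- fastq_read(id, reverse_complement(substr(template, L - rl_r + 1, L)), qr)
  list(fwd = fwd, rev = rev)
}
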