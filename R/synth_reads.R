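#' Random template sequences for read simulation
#'
#' @param n number of sequences.
#' @param length template length in bases (>= 430 for the default QC rules
#'   to be satisfiable).
#' @param seed integer seed.
#' @return named character vector of templates (`tpl1`, `tpl2`, ...).
#' @export
random_templates <- function(n, length = 500, seed = 1) {
  with_seed(seed, {
    out <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
    }, "")
    names(out) <- sprintf("tpl%d", seq_len(n))
    out
  })
}

#' Default per-pair quality model
#'
#' A mixture of scenarios that exercise every branch of the QC rules:
#' `good` pairs (Q 35-40 throughout, pass), `early_crash` pairs (a Q=2 base
#' planted early in one read, so truncation destroys the overlap),
#' `low_tail` pairs (a long Q=13 tail on both reads, so the merged expected
#' error exceeds 0.5) and `dead` pairs (Q=2 at the first base of one read).
#'
#' @param p_good,p_crash,p_low,p_dead mixture weights (normalized
#'   internally).
#' @return a function `(rl_f, rl_r) -> list(fwd, rev)` of Phred vectors,
#'   drawing one scenario per call from the current RNG stream.
#' @export
default_quality_model <- function(p_good = 0.70, p_crash = 0.12,
                                  p_low = 0.13, p_dead = 0.05) {
  w <- c(good = p_good, early_crash = p_crash, low_tail = p_low, dead = p_dead)
  w <- w / sum(w)
  function(rl_f, rl_r) {
    scen <- sample(names(w), 1, prob = w)
    base <- function(n) sample(35:40, n, replace = TRUE)
    qf <- base(rl_f); qr <- base(rl_r)
    if (scen == "early_crash") {
      which_read <- sample(1:2, 1)
      pos <- sample(30:min(150, rl_f - 1, rl_r - 1), 1)
      if (which_read == 1) qf[pos] <- 2L else qr[pos] <- 2L
    } else if (scen == "low_tail") {
      tl <- min(150L, rl_f - 1L, rl_r - 1L)
      qf[(rl_f - tl + 1):rl_f] <- 13L
      qr[(rl_r - tl + 1):rl_r] <- 13L
    } else if (scen == "dead") {
      if (sample(1:2, 1) == 1) qf[1] <- 2L else qr[1] <- 2L
    }
    list(fwd = as.integer(qf), rev = as.integer(qr))
  }
}

# QC verdict computed from the planted layout alone (truncation points, true
# overlap offset, realized mismatches, merged qualities) -- independent of
# the merge search in merge_pair().
.expected_pass_oracle <- function(fwd_b, fwd_q, rev_b, rev_q, tpl_len,
                                  qmax, min_overlap, max_mismatch_frac,
                                  min_len, max_ee) {
  lf <- {h <- which(fwd_q <= qmax); if (length(h)) h[1] - 1L else length(fwd_q)}
  lr <- {h <- which(rev_q <= qmax); if (length(h)) h[1] - 1L else length(rev_q)}
  if (lf == 0L || lr == 0L) return(FALSE)
  o <- lf + lr - tpl_len
  if (o < min_overlap) return(FALSE)
  rc_b <- .revcomp_ints(rev_b[seq_len(lr)])   # covers template tail positions
  rc_q <- rev(rev_q[seq_len(lr)])
  s <- tpl_len - lr + 1L
  ov_f <- fwd_b[s:lf]
  ov_r <- rc_b[seq_len(o)]
  if ((o - sum(ov_f == ov_r)) / o > max_mismatch_frac) return(FALSE)
  tail_idx <- if (lr > o) (o + 1L):lr else integer(0)
  mq <- c(fwd_q[seq_len(s - 1L)], pmax(fwd_q[s:lf], rc_q[seq_len(o)]),
          rc_q[tail_idx])
  tpl_len >= min_len && expected_error(mq) <= max_ee
}

#' Simulate paired-end reads with planted qualities and known QC verdicts
#'
#' Forward reads cover the 5' end of each template and reverse reads the 3'
#' end (reverse-complemented), overlapping by `overlap` bases before any
#' truncation. Per-base substitution errors are drawn at the Phred-implied
#' rate `10^(-Q/10)`. For every pair the expected QC verdict is computed
#' from the planted layout (truncation points, true offset, realized
#' mismatches, merged qualities) using the same rule set as the QC module,
#' but without running its overlap search — it is the independent oracle for
#' QC testing.
#'
#' @param otu_sequences named character vector of template sequences, each
#'   at least 430 bases.
#' @param sample_counts named integer vector: read pairs per template
#'   (names must index `otu_sequences`).
#' @param quality_model a function `(rl_f, rl_r) -> list(fwd, rev)` of Phred
#'   vectors; see [default_quality_model()].
#' @param seed integer seed.
#' @param overlap intended pre-truncation overlap length (>= 1; default 100).
#' @param qmax,min_overlap,max_mismatch_frac,min_len,max_ee QC rule
#'   parameters used for the planted verdicts (defaults match the QC
#'   module's defaults).
#' @return list with `fwd`, `rev` (lists of [fastq_read]) and
#'   `expected_pass` (named logical, one per pair).
#' @export
simulate_paired_reads <- function(otu_sequences, sample_counts,
                                  quality_model = default_quality_model(),
                                  seed = 1, overlap = 100,
                                  qmax = 2, min_overlap = 50,
                                  max_mismatch_frac = 0.1,
                                  min_len = 400, max_ee = 0.5) {
  if (overlap < 1) stop("overlap must be >= 1", call. = FALSE)
  if (any(nchar(otu_sequences) < 430)) {
    stop("all templates must be at least 430 bases", call. = FALSE)
  }
  tpl_of_pair <- rep(names(sample_counts), sample_counts)
  n <- length(tpl_of_pair)
  fwd <- vector("list", n); rv <- vector("list", n)
  pass <- logical(n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      tpl <- otu_sequences[[tpl_of_pair[i]]]
      L <- nchar(tpl)
      rl_f <- as.integer(ceiling((L + overlap) / 2))
      rl_r <- L + as.integer(overlap) - rl_f
      if (rl_f > L || rl_r > L) stop("read length exceeds template length", call. = FALSE)
      q <- quality_model(rl_f, rl_r)
      t_int <- .base_ints(tpl)
      fb <- .add_errors(t_int[seq_len(rl_f)], q$fwd)
      rb <- .add_errors(.revcomp_ints(t_int[(L - rl_r + 1L):L]), q$rev)
      id <- sprintf("read%05d_%s", i, tpl_of_pair[i])
      fwd[[i]] <- fastq_read(id, intToUtf8(fb), q$fwd)
      rv[[i]] <- fastq_read(id, intToUtf8(rb), q$rev)
      pass[i] <- .expected_pass_oracle(
        fb, q$fwd, rb, q$rev, L,
        qmax, min_overlap, max_mismatch_frac, min_len, max_ee
      )
    }
  })
  names(pass) <- vapply(fwd, `[[`, "", "id")
  list(fwd = fwd, rev = rv, expected_pass = pass)
}

# substitute bases at the Phred-implied error rate (uniform over the other 3)
.add_errors <- function(b_int, quals) {
  pe <- 10^(-quals / 10)
  err <- stats::runif(length(b_int)) < pe
  if (any(err)) {
    acgt <- c(65L, 67L, 71L, 84L)
    for (j in which(err)) {
      b_int[j] <- sample(setdiff(acgt, b_int[j]), 1)
    }
  }
  b_int
}
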