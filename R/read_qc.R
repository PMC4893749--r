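#' Truncate a read at the first low-quality base
#'
#' Returns the prefix ending just before the first position whose Phred
#' score is `<= qmax`; the whole read when no such position exists. The
#' result may be empty.
#'
#' @param read a [fastq_read].
#' @param qmax quality ceiling that triggers truncation (default 2).
#' @return a (possibly empty) `fastq_read`.
#' @export
truncate_at_quality <- function(read, qmax = 2) {
  stopifnot(inherits(read, "fastq_read"))
  hit <- which(read$quals <= qmax)
  if (!length(hit)) return(read)
  k <- hit[1] - 1L
  fastq_read(read$id, substr(read$bases, 1L, k), read$quals[seq_len(k)])
}

#' Expected number of sequencing errors implied by Phred scores
#'
#' `EE = sum_b 10^(-Q_b / 10)`.
#'
#' @param quals integer vector of Phred scores (possibly empty).
#' @return the expected error, a non-negative number.
#' @export
expected_error <- function(quals) {
  if (length(quals) && any(quals < 0)) stop("Phred scores must be >= 0", call. = FALSE)
  sum(10^(-as.numeric(quals) / 10))
}

#' Merge a forward/reverse read pair by ungapped overlap
#'
#' The reverse read is reverse-complemented, then slid along the forward
#' read; the offset maximizing the number of matching overlap positions is
#' chosen (ties: smallest offset, i.e. longest overlap). The merge succeeds
#' only if the overlap is at least `min_overlap` bases and its mismatch
#' fraction is at most `max_mismatch_frac`. Within the overlap the base with
#' the higher quality is kept and its quality assigned; ties keep the
#' forward base.
#'
#' @param fwd,rev [fastq_read] records (reverse read in raw orientation).
#' @param min_overlap minimum acceptable overlap length (default 50).
#' @param max_mismatch_frac maximum tolerated overlap mismatch fraction
#'   (default 0.1).
#' @return a merged `fastq_read` with attribute `overlap_len`, or `NULL`
#'   when the pair cannot be merged.
#' @export
merge_pair <- function(fwd, rev, min_overlap = 50, max_mismatch_frac = 0.1) {
  stopifnot(inherits(fwd, "fastq_read"), inherits(rev, "fastq_read"))
  if (min_overlap < 1) stop("min_overlap must be >= 1", call. = FALSE)
  lf <- nchar(fwd$bases); lr <- nchar(rev$bases)
  if (lf == 0L || lr == 0L) return(NULL)
  f <- .base_ints(fwd$bases); fq <- fwd$quals
  r <- .revcomp_ints(.base_ints(rev$bases)); rq <- rev(rev$quals)

  best_s <- NA_integer_; best_m <- -1L; best_o <- 0L
  for (s in seq_len(lf)) {
    o <- min(lf - s + 1L, lr)
    m <- sum(f[s:(s + o - 1L)] == r[seq_len(o)])
    if (m > best_m) { best_m <- m; best_s <- s; best_o <- o }
  }
  if (best_o < min_overlap) return(NULL)
  if ((best_o - best_m) / best_o > max_mismatch_frac) return(NULL)

  s <- best_s
  len <- max(lf, s + lr - 1L)
  mb <- integer(len); mq <- integer(len)
  mb[seq_len(lf)] <- f; mq[seq_len(lf)] <- fq
  pos <- s + seq_len(lr) - 1L        # template positions covered by the reverse read
  inside <- pos <= lf
  take_rev <- inside & (rq > fq[pmin(pos, lf)])
  mb[pos[take_rev]] <- r[which(take_rev)]
  mq[pos[inside]] <- pmax(mq[pos[inside]], rq[inside])
  mb[pos[!inside]] <- r[which(!inside)]
  mq[pos[!inside]] <- rq[!inside]

  out <- fastq_read(fwd$id, intToUtf8(mb), mq)
  attr(out, "overlap_len") <- best_o
  out
}

#' Length and expected-error filter for merged reads
#'
#' Keeps reads at least `min_len` bases long with expected error at most
#' `max_ee`; order is preserved and the filter is idempotent.
#'
#' @param merged list of merged [fastq_read]s.
#' @param min_len minimum merged length kept (default 400, i.e. "longer than
#'   399").
#' @param max_ee maximum expected error kept, inclusive (default 0.5).
#' @return the retained sublist.
#' @export
qc_filter_reads <- function(merged, min_len = 400, max_ee = 0.5) {
  keep <- vapply(merged, function(r) {
    nchar(r$bases) >= min_len && expected_error(r$quals) <= max_ee
  }, logical(1))
  merged[keep]
}

#' Run the full per-pair QC chain: truncate, merge, filter
#'
#' @param fwd,rev equal-length lists of [fastq_read]s (paired by position).
#' @param qmax truncation quality ceiling.
#' @inheritParams merge_pair
#' @inheritParams qc_filter_reads
#' @return list with `merged` (the passing merged reads) and `pass`
#'   (a logical per input pair).
#' @export
qc_process_pairs <- function(fwd, rev, qmax = 2, min_overlap = 50,
                             max_mismatch_frac = 0.1, min_len = 400,
                             max_ee = 0.5) {
  stopifnot(length(fwd) == length(rev))
  merged <- vector("list", length(fwd))
  pass <- logical(length(fwd))
  for (i in seq_along(fwd)) {
    tf <- truncate_at_quality(fwd[[i]], qmax)
    tr <- truncate_at_quality(rev[[i]], qmax)
    m <- merge_pair(tf, tr, min_overlap, max_mismatch_frac)
    if (is.null(m)) next
    ok <- nchar(m$bases) >= min_len && expected_error(m$quals) <= max_ee
    if (ok) { merged[[i]] <- m; pass[i] <- TRUE }
  }
  list(merged = merged[pass], pass = pass)
}
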