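#' Dereplicate reads into unique sequences, discarding singletons
#'
#' Groups exact duplicate sequences, sorts by decreasing abundance (ties:
#' lexicographic sequence order) and removes sequences seen fewer than
#' `min_size` times.
#'
#' @param seqs character vector of sequences (or a list of [fastq_read]s).
#' @param min_size minimum copy number retained (default 2: singletons
#'   discarded).
#' @return data.frame with columns `sequence` and `size`, sorted by
#'   decreasing `size`.
#' @export
dereplicate <- function(seqs, min_size = 2) {
  if (is.list(seqs)) seqs <- vapply(seqs, `[[`, "", "bases")
  if (!length(seqs)) return(data.frame(sequence = character(0), size = integer(0)))
  tab <- table(seqs)
  out <- data.frame(sequence = names(tab), size = as.integer(tab))
  out <- out[out$size >= min_size, , drop = FALSE]
  out <- out[order(-out$size, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise global-alignment identity
#'
#' Needleman-Wunsch global alignment (match 1, mismatch -1, gap open 4, gap
#' extend 1); identity is matches divided by alignment columns with terminal
#' gap columns excluded.
#'
#' @param a,b character strings.
#' @return identity in `[0, 1]`.
#' @export
seq_identity <- function(a, b) {
  if (identical(a, b)) return(1)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 4, gapExtension = 1
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  gap <- pa == "-" | sa == "-"
  # terminal gap columns: leading/trailing runs of gap in either sequence
  lead <- max(.gap_run(pa, TRUE), .gap_run(sa, TRUE))
  trail <- max(.gap_run(pa, FALSE), .gap_run(sa, FALSE))
  keep <- seq_along(pa)
  if (lead > 0) keep <- keep[keep > lead]
  if (trail > 0) keep <- keep[keep <= length(pa) - trail]
  if (!length(keep)) return(0)
  sum(pa[keep] == sa[keep] & !gap[keep]) / length(keep)
}

.gap_run <- function(chars, leading) {
  v <- if (leading) chars else rev(chars)
  r <- rle(v == "-")
  if (r$values[1]) r$lengths[1] else 0L
}

#' Greedy centroid OTU clustering at a fixed identity
#'
#' Scans unique sequences in decreasing-abundance order; each joins the
#' first existing centroid with global-alignment identity at least
#' `identity`, otherwise it founds a new centroid.
#'
#' @param uniques data.frame from [dereplicate()] (columns `sequence`,
#'   `size`), already sorted by decreasing size.
#' @param identity clustering identity threshold (default 0.97).
#' @return data.frame with `otu_id`, `sequence` (centroid) and `size`
#'   (total member abundance).
#' @export
cluster_otus <- function(uniques, identity = 0.97) {
  cent <- character(0); size <- integer(0)
  for (i in seq_len(nrow(uniques))) {
    s <- uniques$sequence[i]; n <- uniques$size[i]
    placed <- FALSE
    for (j in seq_along(cent)) {
      if (seq_identity(s, cent[j]) >= identity) {
        size[j] <- size[j] + n
        placed <- TRUE
        break
      }
    }
    if (!placed) { cent <- c(cent, s); size <- c(size, n) }
  }
  data.frame(otu_id = sprintf("OTU%d", seq_along(cent)),
             sequence = cent, size = size)
}

#' Chimera-filter hook
#'
#' Reference-based chimera detection is outside this package's scope (it is
#' performed by external tools against a reference database); this hook
#' keeps the pipeline stage explicit. `method = "none"` passes all unique
#' sequences through unchanged.
#'
#' @param uniques data.frame from [dereplicate()].
#' @param method only `"none"` is implemented.
#' @return the (unchanged) unique-sequence table.
#' @export
chimera_filter <- function(uniques, method = c("none")) {
  match.arg(method)
  uniques
}

#' Write OTU centroid sequences as FASTA
#'
#' @param centroids data.frame from [cluster_otus()].
#' @param path output FASTA path.
#' @return invisibly, the path.
#' @export
write_centroids_fasta <- function(centroids, path) {
  x <- Biostrings::DNAStringSet(centroids$sequence)
  names(x) <- centroids$otu_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Map quality-filtered reads onto OTU centroids
#'
#' Each read is assigned to the centroid of highest identity when that
#' identity reaches the cutoff (ties: the more abundant centroid); reads
#' below the cutoff everywhere are dropped.
#'
#' @param reads character vector of read sequences (or list of
#'   [fastq_read]s).
#' @param centroids data.frame from [cluster_otus()].
#' @param identity mapping identity cutoff (default 0.97).
#' @return named integer vector of per-centroid read counts (single-sample
#'   OTU counts).
#' @export
map_reads <- function(reads, centroids, identity = 0.97) {
  if (!nrow(centroids)) stop("centroids must be non-empty", call. = FALSE)
  if (is.list(reads)) reads <- vapply(reads, `[[`, "", "bases")
  counts <- stats::setNames(integer(nrow(centroids)), centroids$otu_id)
  for (r in reads) {
    ids <- vapply(centroids$sequence, function(cs) seq_identity(r, cs), 0)
    best <- max(ids)
    if (best < identity) next
    cand <- which(ids == best)
    if (length(cand) > 1) cand <- cand[which.max(centroids$size[cand])]
    counts[cand] <- counts[cand] + 1L
  }
  counts
}
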