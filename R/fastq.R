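# Lightweight FASTQ record representation used by the QC stage: a list with
# `id`, `bases` (character string over ACGTN) and `quals` (integer Phred
# scores, one per base). File IO goes through Biostrings (Phred+33).

#' Create a FASTQ read record
#'
#' @param id read identifier.
#' @param bases character string of bases.
#' @param quals integer vector of Phred quality scores, same length as
#'   `bases`.
#' @return a `fastq_read` list.
#' @export
fastq_read <- function(id, bases, quals) {
  quals <- as.integer(quals)
  if (nchar(bases) != length(quals)) {
    stop("bases and quals must have equal length", call. = FALSE)
  }
  if (length(quals) && any(quals < 0)) stop("Phred scores must be >= 0", call. = FALSE)
  structure(list(id = id, bases = bases, quals = quals), class = "fastq_read")
}

#' Write / read lists of reads as Phred+33 FASTQ
#'
#' @param reads list of [fastq_read] records.
#' @param path file path.
#' @return `read_fastq` returns a list of `fastq_read`s; `write_fastq`
#'   returns the path invisibly.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(vapply(reads, `[[`, "", "bases"))
  names(seqs) <- vapply(reads, `[[`, "", "id")
  quals <- Biostrings::PhredQuality(vapply(
    reads, function(r) intToUtf8(r$quals + 33L), ""
  ))
  # Biostrings warns that per-sequence metadata columns are dropped on write
  suppressWarnings({
    x <- Biostrings::QualityScaledDNAStringSet(seqs, quals)
    Biostrings::writeQualityScaledXStringSet(x, path)
  })
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readQualityScaledDNAStringSet(path)
  q <- as.character(Biostrings::quality(x))
  lapply(seq_along(x), function(i) {
    fastq_read(
      id = names(x)[i],
      bases = as.character(x[[i]]),
      quals = utf8ToInt(q[i]) - 33L
    )
  })
}

# integer-code helpers for fast ungapped comparison
.base_ints <- function(s) utf8ToInt(s)

.revcomp_ints <- function(v) {
  # A<->T, C<->G, N fixed (utf8 codes: A65 C67 G71 T84 N78)
  out <- integer(length(v))
  out[v == 65L] <- 84L; out[v == 84L] <- 65L
  out[v == 67L] <- 71L; out[v == 71L] <- 67L
  out[v == 78L] <- 78L
  rev(out)
}

#' Reverse-complement a base string
#' @param s character string over ACGTN.
#' @return the reverse complement string.
#' @export
reverse_complement <- function(s) {
  if (nchar(s) == 0) return(s)
  intToUtf8(.revcomp_ints(.base_ints(s)))
}
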