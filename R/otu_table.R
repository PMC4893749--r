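#' Construct a sample x OTU count table with sample metadata
#'
#' The central container of the pipeline: an integer count matrix with one
#' row per sample and one column per OTU, carrying the longitudinal design
#' (group, day, subject) as sample metadata and optional taxonomy strings as
#' OTU metadata.
#'
#' @param counts numeric matrix, samples in rows, OTUs in columns; entries
#'   must be non-negative and finite. Row names are sample ids, column names
#'   OTU ids (generated when absent).
#' @param metadata data.frame with columns `sample_id`, `group`, `day`,
#'   `subject`, one row per sample, in the same order as `counts` rows.
#' @param taxonomy optional character vector of taxonomy strings, one per OTU.
#' @return an object of class `otu_table`: a list with elements `counts`,
#'   `metadata`, `otu_ids`, `taxonomy`.
#' @export
otu_table <- function(counts, metadata, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be non-negative and finite", call. = FALSE)
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("S%03d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("OTU%d", seq_len(ncol(counts)))
  }
  if (anyDuplicated(rownames(counts))) stop("sample ids must be unique", call. = FALSE)
  if (anyDuplicated(colnames(counts))) stop("OTU ids must be unique", call. = FALSE)
  metadata <- as.data.frame(metadata)
  req <- c("sample_id", "group", "day", "subject")
  if (!all(req %in% names(metadata))) {
    stop("metadata must have columns sample_id, group, day, subject", call. = FALSE)
  }
  if (nrow(metadata) != nrow(counts)) {
    stop("metadata rows must match count matrix rows", call. = FALSE)
  }
  if (!identical(as.character(metadata$sample_id), rownames(counts))) {
    stop("metadata$sample_id must match count row names in order", call. = FALSE)
  }
  if (!is.null(taxonomy) && length(taxonomy) != ncol(counts)) {
    stop("taxonomy must have one entry per OTU", call. = FALSE)
  }
  structure(
    list(
      counts = counts,
      metadata = metadata,
      otu_ids = colnames(counts),
      taxonomy = taxonomy
    ),
    class = "otu_table"
  )
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf(
    "otu_table: %d samples x %d OTUs; groups: %s; days: %s\n",
    nrow(x$counts), ncol(x$counts),
    paste(unique(x$metadata$group), collapse = ", "),
    paste(sort(unique(x$metadata$day)), collapse = ", ")
  ))
  invisible(x)
}

#' Per-sample relative abundances
#'
#' @param x an `otu_table` or a count matrix (samples x OTUs).
#' @return matrix of the same shape whose rows sum to 1.
#' @export
relative_abundances <- function(x) {
  m <- if (inherits(x, "otu_table")) x$counts else as.matrix(x)
  tot <- rowSums(m)
  if (any(tot <= 0)) stop("every sample needs a positive total count", call. = FALSE)
  sweep(m, 1, tot, "/")
}

#' Subset an OTU table by samples and/or OTUs
#'
#' @param x an `otu_table`.
#' @param samples logical/integer/character index of samples to keep.
#' @param otus logical/integer/character index of OTUs to keep.
#' @return an `otu_table`.
#' @export
subset_otu_table <- function(x, samples = NULL, otus = NULL) {
  stopifnot(inherits(x, "otu_table"))
  counts <- x$counts
  meta <- x$metadata
  tax <- x$taxonomy
  if (!is.null(samples)) {
    counts <- counts[samples, , drop = FALSE]
    meta <- meta[match(rownames(counts), meta$sample_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  if (!is.null(otus)) {
    keep <- if (is.character(otus)) match(otus, colnames(counts)) else otus
    counts <- counts[, keep, drop = FALSE]
    if (!is.null(tax)) tax <- tax[keep]
  }
  otu_table(counts, meta, tax)
}

#' Write / read an OTU table as plain TSV
#'
#' The count file has OTUs in rows and samples in columns (the conventional
#' orientation of shared OTU tables); the metadata file has columns
#' sample_id, group, day, subject.
#'
#' @param x an `otu_table`.
#' @param counts_file,metadata_file output paths.
#' @return invisibly, the paths written.
#' @export
write_otu_table <- function(x, counts_file, metadata_file) {
  stopifnot(inherits(x, "otu_table"))
  tab <- data.frame(otu_id = x$otu_ids, t(x$counts), check.names = FALSE)
  utils::write.table(tab, counts_file, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$metadata, metadata_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(counts_file, metadata_file))
}

#' Write an OTU table in BIOM format (JSON, version 1.0)
#'
#' @param x an [otu_table].
#' @param file output path.
#' @return invisibly, the path.
#' @export
write_otu_table_biom <- function(x, file) {
  stopifnot(inherits(x, "otu_table"))
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop("the biomformat package is required for BIOM output", call. = FALSE)
  }
  b <- biomformat::make_biom(t(x$counts))
  biomformat::write_biom(b, file)
  invisible(file)
}

#' @rdname write_otu_table
#' @export
read_otu_table <- function(counts_file, metadata_file) {
  tab <- utils::read.delim(counts_file, check.names = FALSE)
  meta <- utils::read.delim(metadata_file)
  counts <- t(as.matrix(tab[, -1, drop = FALSE]))
  colnames(counts) <- tab[[1]]
  meta <- meta[match(rownames(counts), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  otu_table(counts, meta)
}
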