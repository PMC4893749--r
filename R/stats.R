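#' Mann-Whitney U test
#'
#' Rank-sum test with midrank ties. The p-value is exact (enumeration) when
#' the combined sample size is at most `exact_max_n` and there are no ties,
#' otherwise the normal approximation with tie and continuity corrections is
#' used — the study's group sizes (6-12 per cell) straddle the regime where
#' the approximation degrades, hence the low switch point.
#'
#' @param x,y non-empty numeric vectors.
#' @param exact_max_n combined-size ceiling for the exact p (default 12).
#' @return list with `U` (statistic for `x`) and `p_value` (two-sided).
#' @export
mann_whitney_u <- function(x, y, exact_max_n = 12) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y)) <= exact_max_n && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)
  )
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Kruskal-Wallis rank test across groups
#'
#' @param groups list of numeric vectors (>= 2 groups, total n >= 3).
#' @return list with `H` (tie-corrected statistic) and `p_value`
#'   (chi-square, g-1 df).
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (sum(lengths(groups)) < 3) stop("need total n >= 3", call. = FALSE)
  if (length(unique(unlist(groups))) == 1L) {
    # all observations identical: no rank variation, H is 0 by convention
    return(list(H = 0, p_value = 1))
  }
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), p_value = kt$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `adj_(i) = min_{j >= i}(p_(j) * m / j)`, capped at 1, returned in the
#' input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Differential-abundance testing for one contrast
#'
#' Per-OTU Mann-Whitney tests on relative abundances between two sample
#' sets, Benjamini-Hochberg adjusted across OTUs; enrichment direction is
#' the sign of the median difference relative to the reference (second)
#' side.
#'
#' @param table an [otu_table] (counts are converted to relative
#'   abundances) or a relative-abundance matrix.
#' @param metadata data.frame with `sample_id`, `group`, `day` (required
#'   when `table` is a matrix without accompanying metadata).
#' @param contrast list with sides `a` and `b`, each a list with `group`
#'   and optionally `day` (see [pairwise_screen()]); side `b` is the
#'   reference.
#' @param alpha_fdr FDR significance level (default 0.05).
#' @return data.frame with one row per OTU: `otu_id`, `statistic`, `raw_p`,
#'   `adjusted_p`, `direction` (`"enriched"`/`"depleted"`/`"none"` vs the
#'   reference), `significant`.
#' @export
differential_otus <- function(table, metadata = NULL, contrast,
                              alpha_fdr = 0.05) {
  if (inherits(table, "otu_table")) {
    abund <- relative_abundances(table)
    metadata <- metadata %||% table$metadata
  } else {
    abund <- as.matrix(table)
    if (is.null(metadata)) stop("metadata required for matrix input", call. = FALSE)
  }
  meta <- metadata[match(rownames(abund), metadata$sample_id), ]
  sel <- function(side) {
    i <- meta$group %in% side$group
    if (!is.null(side$day)) i <- i & meta$day %in% side$day
    which(i)
  }
  ia <- sel(contrast$a); ib <- sel(contrast$b)
  if (length(ia) < 1 || length(ib) < 1) stop("empty contrast side", call. = FALSE)
  res <- lapply(colnames(abund), function(o) {
    xa <- abund[ia, o]; xb <- abund[ib, o]
    if (length(unique(c(xa, xb))) == 1L) {
      return(data.frame(otu_id = o, statistic = length(xa) * length(xb) / 2,
                        raw_p = 1, med_diff = 0))
    }
    mw <- mann_whitney_u(xa, xb)
    data.frame(otu_id = o, statistic = mw$U, raw_p = mw$p_value,
               med_diff = stats::median(xa) - stats::median(xb))
  })
  out <- do.call(rbind, res)
  out$adjusted_p <- benjamini_hochberg(out$raw_p)
  out$direction <- ifelse(out$med_diff > 0, "enriched",
                          ifelse(out$med_diff < 0, "depleted", "none"))
  out$significant <- out$adjusted_p < alpha_fdr
  out$med_diff <- NULL
  out
}
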