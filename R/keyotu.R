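#' Random-forest discrimination model for one group pair
#'
#' Trains a classification forest on relative abundances and records the
#' out-of-bag class error and the unscaled mean decrease in accuracy (MDA)
#' of every OTU: the average over trees of the drop in out-of-bag accuracy
#' when that OTU's values are permuted.
#'
#' @param abund samples x OTUs matrix of relative abundances.
#' @param pair_labels factor/character with exactly 2 levels, one per
#'   sample, each represented at least twice.
#' @param n_trees number of trees (default 1000).
#' @param seed integer seed.
#' @param pair_id optional label for the model.
#' @return a `pair_model`: list with `pair`, `oob_class_error`, `importance`
#'   (named MDA vector over all input OTUs), `n_trees`, `seed`.
#' @export
fit_pair_model <- function(abund, pair_labels, n_trees = 1000, seed = 1,
                           pair_id = NULL) {
  abund <- as.matrix(abund)
  y <- factor(as.character(pair_labels))
  if (nlevels(y) != 2) stop("exactly 2 classes required", call. = FALSE)
  if (any(table(y) < 2)) stop("each class needs at least 2 samples", call. = FALSE)
  rf <- with_seed(seed, {
    randomForest::randomForest(x = abund, y = y, ntree = n_trees,
                               importance = TRUE)
  })
  mda <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  oob <- mean(rf$predicted != y)
  structure(
    list(pair = pair_id %||% paste(levels(y), collapse = "_vs_"),
         oob_class_error = oob,
         importance = stats::setNames(as.numeric(mda), colnames(abund)),
         n_trees = n_trees, seed = seed),
    class = "pair_model"
  )
}

#' Union key OTUs across successful pair models
#'
#' Discards models whose out-of-bag class error exceeds `max_class_error`
#' (default 0: only perfectly discriminating models count) and unions the
#' OTUs whose MDA strictly exceeds `mda_threshold` across the survivors,
#' recording which models contributed each OTU.
#'
#' @param models list of `pair_model`s.
#' @param mda_threshold importance cutoff (default 0.003).
#' @param max_class_error maximum OOB error of a "successful" model
#'   (default 0).
#' @return a `key_otu_set`: list with `otu_ids` (non-redundant), `provenance`
#'   (named list OTU -> contributing pair ids), `n_models_used`.
#' @export
select_key_otus <- function(models, mda_threshold = 0.003, max_class_error = 0) {
  ok <- Filter(function(m) m$oob_class_error <= max_class_error, models)
  prov <- list()
  for (m in ok) {
    hits <- names(m$importance)[m$importance > mda_threshold]
    for (h in hits) prov[[h]] <- c(prov[[h]], m$pair)
  }
  structure(
    list(otu_ids = names(prov), provenance = prov, n_models_used = length(ok)),
    class = "key_otu_set"
  )
}

#' @export
print.key_otu_set <- function(x, ...) {
  cat(sprintf("key_otu_set: %d OTUs from %d successful model(s)\n",
              length(x$otu_ids), x$n_models_used))
  invisible(x)
}
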