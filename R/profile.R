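#' Rarefy an OTU table to even depth
#'
#' Samples with fewer than `depth` reads are excluded (and recorded). Each
#' retained sample is subsampled without replacement; alpha diversity is
#' averaged over `n_rep` independent repetitions, while the table kept for
#' beta diversity is the first repetition under the given seed.
#'
#' @param x an [otu_table].
#' @param depth target depth (default 9000).
#' @param n_rep repetitions for the alpha-diversity average (default 1000).
#' @param seed integer seed.
#' @param shannon_base logarithm base for the Shannon index (default 2).
#' @return a `rarefied_table`: list with `counts` (repetition-0 table, rows
#'   summing to `depth`), `metadata`, `depth`, `n_rep`, `excluded_samples`,
#'   and `alpha` (per-sample mean observed OTUs and Shannon over the
#'   repetitions, with Monte-Carlo standard errors).
#' @export
rarefy <- function(x, depth = 9000, n_rep = 1000, seed = 1, shannon_base = 2) {
  stopifnot(inherits(x, "otu_table"))
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  tot <- rowSums(x$counts)
  excluded <- rownames(x$counts)[tot < depth]
  keep <- tot >= depth
  if (!any(keep)) stop("all samples fall below the rarefaction depth", call. = FALSE)
  m <- x$counts[keep, , drop = FALSE]
  meta <- x$metadata[keep, , drop = FALSE]
  rownames(meta) <- NULL

  rep0 <- NULL
  obs_sum <- sh_sum <- obs_sq <- sh_sq <- numeric(nrow(m))
  with_seed(seed, {
    for (r in seq_len(n_rep)) {
      # silence vegan's "are these really counts?" nag: inputs here are
      # validated integer counts whose smallest nonzero entry may be > 1
      sub <- withCallingHandlers(
        vegan::rrarefy(m, depth),
        warning = function(w) {
          if (grepl("observed counts", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        }
      )
      if (r == 1L) rep0 <- sub
      ob <- rowSums(sub > 0)
      sh <- apply(sub, 1, shannon, base = shannon_base)
      obs_sum <- obs_sum + ob; obs_sq <- obs_sq + ob^2
      sh_sum <- sh_sum + sh; sh_sq <- sh_sq + sh^2
    }
  })
  alpha <- data.frame(
    sample_id = rownames(m),
    observed_otus = obs_sum / n_rep,
    shannon = sh_sum / n_rep,
    observed_se = if (n_rep > 1) sqrt(pmax(obs_sq / n_rep - (obs_sum / n_rep)^2, 0) / n_rep) else NA_real_,
    shannon_se = if (n_rep > 1) sqrt(pmax(sh_sq / n_rep - (sh_sum / n_rep)^2, 0) / n_rep) else NA_real_
  )
  structure(
    list(counts = rep0, metadata = meta, depth = depth, n_rep = n_rep,
         excluded_samples = excluded, alpha = alpha,
         shannon_base = shannon_base),
    class = "rarefied_table"
  )
}

#' Number of OTUs present in a sample
#'
#' @param sample_counts numeric vector of counts.
#' @return the count of entries greater than zero.
#' @export
observed_otus <- function(sample_counts) sum(sample_counts > 0)

#' Shannon diversity index
#'
#' `H = -sum p_i log_base(p_i)` over the OTUs present in the sample.
#'
#' @param sample_counts numeric vector of counts (total must be positive).
#' @param base logarithm base (default 2: H in bits).
#' @return the Shannon index.
#' @export
shannon <- function(sample_counts, base = 2) {
  tot <- sum(sample_counts)
  if (tot <= 0) stop("sample total must be positive", call. = FALSE)
  p <- sample_counts[sample_counts > 0] / tot
  -sum(p * log(p, base = base))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum |x_k - y_k| / sum (x_k + y_k)`; intended for equal-depth
#' (rarefied) counts.
#'
#' @param counts samples x OTUs matrix, a `rarefied_table`, or an
#'   [otu_table].
#' @return a symmetric `dist_matrix` (plain labeled matrix, zero diagonal,
#'   entries in `[0, 1]`).
#' @export
bray_curtis <- function(counts) {
  m <- if (inherits(counts, "rarefied_table")) counts$counts
       else if (inherits(counts, "otu_table")) counts$counts
       else as.matrix(counts)
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  diag(d) <- 0
  d
}

.check_distance_matrix <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || !isTRUE(all.equal(D, t(D), tolerance = 1e-10))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix must have zero diagonal", call. = FALSE)
  D
}

#' Principal coordinates analysis (classical MDS)
#'
#' Gower-centers the squared-distance matrix and eigendecomposes it;
#' coordinates are eigenvectors scaled by the square root of their (positive)
#' eigenvalues. Negative eigenvalues are dropped and reported.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @return list with `coordinates` (samples x axes), `eigenvalues`
#'   (descending, positive only), `negative_eigenvalues`, and
#'   `proportion_explained` (over the positive eigenvalues).
#' @export
pcoa <- function(D) {
  D <- .check_distance_matrix(D)
  n <- nrow(D)
  # cmdscale warns when fewer than k eigenvalues are positive; the positive
  # subset is extracted explicitly below
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > sqrt(.Machine$double.eps) * max(abs(eig), 1))
  coords <- fit$points[, seq_along(pos), drop = FALSE]
  colnames(coords) <- sprintf("PC%d", seq_along(pos))
  rownames(coords) <- rownames(D)
  list(
    coordinates = coords,
    eigenvalues = eig[pos],
    negative_eigenvalues = eig[eig < 0],
    proportion_explained = eig[pos] / sum(eig[pos])
  )
}

#' Principal components of relative abundances, via PCoA
#'
#' Classical PCA scores are recovered by applying [pcoa()] to the Euclidean
#' distance matrix of the relative abundances (the two are mathematically
#' equivalent), avoiding a second ordination code path.
#'
#' @param abund samples x OTUs relative-abundance matrix (or an
#'   [otu_table]).
#' @return as [pcoa()].
#' @export
pca_ordination <- function(abund) {
  if (inherits(abund, "otu_table")) abund <- relative_abundances(abund)
  pcoa(as.matrix(stats::dist(abund)))
}

#' Mean community distance of each group-day from its own baseline
#'
#' For every (group, day) cell, averages the distances between that cell's
#' samples and the same group's baseline-day samples — the
#' "variation from baseline" trajectory statistic.
#'
#' @param D labeled distance matrix over samples.
#' @param metadata data.frame with `sample_id`, `group`, `day` covering the
#'   labels of `D`.
#' @param baseline_day the reference day (default -1).
#' @return data.frame with `group`, `day`, `mean_dist`, `se`, `n_pairs`.
#' @export
distance_from_baseline <- function(D, metadata, baseline_day = -1) {
  D <- .check_distance_matrix(D)
  meta <- metadata[match(rownames(D), metadata$sample_id), ]
  out <- list()
  for (g in unique(meta$group)) {
    base_idx <- which(meta$group == g & meta$day == baseline_day)
    if (!length(base_idx)) next
    for (d in sort(unique(meta$day))) {
      idx <- which(meta$group == g & meta$day == d)
      if (!length(idx)) next
      vals <- as.vector(D[idx, base_idx, drop = FALSE])
      if (d == baseline_day) {
        sub <- D[idx, idx, drop = FALSE]
        vals <- sub[upper.tri(sub)]
        if (!length(vals)) next
      }
      out[[length(out) + 1L]] <- data.frame(
        group = g, day = d, mean_dist = mean(vals),
        se = stats::sd(vals) / sqrt(length(vals)), n_pairs = length(vals)
      )
    }
  }
  do.call(rbind, out)
}
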