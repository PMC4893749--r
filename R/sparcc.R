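#' Log-ratio variance matrix
#'
#' `t_ij = var(log(x_i) - log(x_j))` over samples (unbiased, n-1
#' denominator); the raw material of compositional basis-correlation
#' estimation.
#'
#' @param fractions samples x OTUs matrix of strictly positive fractions.
#' @return symmetric OTU x OTU matrix with zero diagonal.
#' @export
log_ratio_variances <- function(fractions) {
  f <- as.matrix(fractions)
  if (any(f <= 0)) stop("all fractions must be strictly positive", call. = FALSE)
  if (ncol(f) < 4) stop("need at least 4 OTUs", call. = FALSE)
  if (nrow(f) < 4) stop("need at least 4 samples", call. = FALSE)
  lg <- log(f)
  cv <- stats::cov(lg)           # n-1 denominator
  v <- diag(cv)
  T_mat <- outer(v, v, "+") - 2 * cv
  T_mat <- (T_mat + t(T_mat)) / 2
  diag(T_mat) <- 0
  T_mat[T_mat < 0] <- 0          # numerical guard
  dimnames(T_mat) <- dimnames(cv)
  T_mat
}

#' One pass of the sparse basis-correlation approximation
#'
#' Under the sparsity assumption (correlations approximately sum to zero),
#' the per-OTU basis variances omega solve the linear system `M omega = t+`
#' where `t+` are the row sums of the log-ratio variance matrix restricted
#' to non-excluded pairs, `M` has `1` for each non-excluded pair and the
#' count of non-excluded partners on the diagonal. Basis correlations are
#' then `rho_ij = (omega_i + omega_j - t_ij) / (2 sqrt(omega_i omega_j))`,
#' clipped to `[-1, 1]`.
#'
#' @param T_mat log-ratio variance matrix from [log_ratio_variances()].
#' @param excluded optional 2-column matrix of excluded pair indices.
#' @return list with `rho` (clipped correlation matrix, unit diagonal) and
#'   `omega` (basis variances). OTUs whose solved variance is non-positive
#'   are flagged: their correlations are set to 0 (diagonal kept at 1) with
#'   a warning.
#' @export
basis_correlations_once <- function(T_mat, excluded = NULL) {
  p <- ncol(T_mat)
  if (p < 4) stop("need at least 4 non-excluded OTUs", call. = FALSE)
  A <- matrix(1, p, p)
  Tx <- T_mat
  if (!is.null(excluded) && nrow(excluded)) {
    for (r in seq_len(nrow(excluded))) {
      i <- excluded[r, 1]; j <- excluded[r, 2]
      A[i, j] <- A[j, i] <- 0
      Tx[i, j] <- Tx[j, i] <- 0
    }
  }
  diag(A) <- 0
  M <- A
  diag(M) <- rowSums(A)
  t_plus <- rowSums(Tx)
  omega <- solve(M, t_plus)
  bad <- omega <= 0
  omega_safe <- ifelse(bad, NA_real_, omega)
  denom <- 2 * sqrt(outer(omega_safe, omega_safe))
  rho <- (outer(omega_safe, omega_safe, "+") - T_mat) / denom
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  if (any(bad)) {
    warning(sprintf("%d OTU(s) with non-positive basis variance; correlations zeroed",
                    sum(bad)))
    rho[bad, ] <- 0
    rho[, bad] <- 0
  }
  diag(rho) <- 1
  dimnames(rho) <- dimnames(T_mat)
  list(rho = rho, omega = omega)
}

# iterative strong-pair exclusion: repeatedly drop the most extreme
# remaining |rho| off-diagonal pair while it exceeds the threshold
.basis_with_exclusions <- function(T_mat, exclusion_threshold, max_exclusions) {
  excluded <- matrix(integer(0), ncol = 2)
  est <- basis_correlations_once(T_mat, excluded)
  for (round in seq_len(max_exclusions)) {
    r <- abs(est$rho)
    diag(r) <- 0
    if (nrow(excluded)) {
      r[excluded] <- 0
      r[excluded[, c(2, 1), drop = FALSE]] <- 0
    }
    top <- which.max(r)
    if (r[top] <= exclusion_threshold) break
    ij <- arrayInd(top, dim(r))
    excluded <- rbind(excluded, ij)
    est <- basis_correlations_once(T_mat, excluded)
  }
  est$excluded <- excluded
  est
}

#' SparCC basis-correlation estimate from an OTU count table
#'
#' Per iteration, fractions are drawn from the add-one (Dirichlet-posterior)
#' resampling of the counts, log-ratio variances computed, and the sparse
#' basis approximation solved with iterative strong-pair exclusion; the
#' final correlation matrix is the element-wise median (optionally mean)
#' over iterations.
#'
#' @param counts an [otu_table] or samples x OTUs count matrix (>= 4 OTUs).
#' @param n_est_iter resampling iterations (default 20).
#' @param exclusion_threshold |rho| above which the most extreme pair is
#'   excluded from the sparsity system (default 0.1).
#' @param max_exclusions maximum exclusion rounds per iteration (default 10).
#' @param seed integer seed.
#' @param aggregate `"median"` (default) or `"mean"` across iterations.
#' @param resample draw Dirichlet-posterior fractions per iteration
#'   (default). With `FALSE` a single pass on `(x + 1) / sum(x + 1)`
#'   fractions is used and the result is deterministic given the counts.
#' @return a `sparcc_result`: list with `rho`, `omega`, `excluded_pairs`
#'   (last iteration's), `n_est_iter`.
#' @export
sparcc_estimate <- function(counts, n_est_iter = 20, exclusion_threshold = 0.1,
                            max_exclusions = 10, seed = 1,
                            aggregate = c("median", "mean"), resample = TRUE) {
  aggregate <- match.arg(aggregate)
  m <- if (inherits(counts, "otu_table")) counts$counts else as.matrix(counts)
  if (ncol(m) < 4) stop("need at least 4 OTUs", call. = FALSE)
  p <- ncol(m)
  if (!resample) {
    f <- (m + 1) / rowSums(m + 1)
    est <- .basis_with_exclusions(log_ratio_variances(f),
                                  exclusion_threshold, max_exclusions)
    return(structure(list(rho = est$rho, omega = est$omega,
                          excluded_pairs = est$excluded, n_est_iter = 1L),
                     class = "sparcc_result"))
  }
  rhos <- array(NA_real_, c(p, p, n_est_iter))
  omegas <- matrix(NA_real_, p, n_est_iter)
  last_excl <- NULL
  with_seed(seed, {
    for (it in seq_len(n_est_iter)) {
      f <- .rdirichlet_rows(m + 1)
      est <- .basis_with_exclusions(log_ratio_variances(f),
                                    exclusion_threshold, max_exclusions)
      rhos[, , it] <- est$rho
      omegas[, it] <- est$omega
      last_excl <- est$excluded
    }
  })
  agg <- if (aggregate == "median") function(x) apply(x, c(1, 2), stats::median)
         else function(x) apply(x, c(1, 2), mean)
  rho <- agg(rhos)
  rho[rho > 1] <- 1; rho[rho < -1] <- -1
  diag(rho) <- 1
  dimnames(rho) <- list(colnames(m), colnames(m))
  structure(
    list(rho = rho, omega = rowMeans(omegas),
         excluded_pairs = last_excl, n_est_iter = n_est_iter),
    class = "sparcc_result"
  )
}

# one Dirichlet draw per row with the rows of `alpha` as parameters
.rdirichlet_rows <- function(alpha) {
  g <- matrix(stats::rgamma(length(alpha), shape = as.vector(alpha)),
              nrow(alpha), ncol(alpha))
  g / rowSums(g)
}

#' Permutation null p-values for SparCC correlations
#'
#' Builds `n_null` datasets by independently permuting each OTU's counts
#' across samples (destroying all correlation while preserving marginals),
#' re-estimates the correlation matrix on each, and reports two-sided
#' pseudo-p-values `p_ij = (1 + #{|rho_null| >= |rho_obs,ij|}) / (n_null + 1)`.
#'
#' @param counts as in [sparcc_estimate()].
#' @param rho_obs observed correlation matrix.
#' @param n_null number of null datasets (default 100).
#' @param seed integer seed.
#' @param ... passed to [sparcc_estimate()] for the null re-estimates.
#' @return symmetric matrix of pseudo-p-values (diagonal 1).
#' @export
sparcc_null_pvalues <- function(counts, rho_obs, n_null = 100, seed = 1, ...) {
  if (n_null < 1) stop("n_null must be >= 1", call. = FALSE)
  m <- if (inherits(counts, "otu_table")) counts$counts else as.matrix(counts)
  hits <- matrix(0, ncol(m), ncol(m))
  a_obs <- abs(rho_obs)
  with_seed(seed, {
    for (b in seq_len(n_null)) {
      perm <- apply(m, 2, sample)
      r_null <- sparcc_estimate(perm, seed = child_seed(seed, b), ...)$rho
      hits <- hits + (abs(r_null) >= a_obs)
    }
  })
  p <- (1 + hits) / (n_null + 1)
  p <- (p + t(p)) / 2
  diag(p) <- 1
  dimnames(p) <- dimnames(rho_obs)
  p
}

#' Correlation network above a magnitude threshold
#'
#' @param result a `sparcc_result` (or any list with a `rho` matrix).
#' @param edge_threshold draw edges with `|rho|` strictly greater than this
#'   (default 0.5).
#' @param abundance optional named mean-abundance vector for the nodes.
#' @return list with `nodes` (data.frame: `otu_id`, `mean_abundance`) and
#'   `edges` (data.frame: `from`, `to`, `rho`, `sign`).
#' @export
build_network <- function(result, edge_threshold = 0.5, abundance = NULL) {
  rho <- result$rho
  ids <- colnames(rho) %||% sprintf("OTU%d", seq_len(ncol(rho)))
  ut <- which(upper.tri(rho) & abs(rho) > edge_threshold, arr.ind = TRUE)
  edges <- data.frame(
    from = ids[ut[, 1]], to = ids[ut[, 2]],
    rho = rho[ut],
    sign = ifelse(rho[ut] > 0, "positive", "negative")
  )
  nodes <- data.frame(
    otu_id = ids,
    mean_abundance = if (is.null(abundance)) NA_real_ else as.numeric(abundance[ids])
  )
  list(nodes = nodes, edges = edges)
}

#' Export a correlation network as edge-list TSV and GraphML
#'
#' @param network from [build_network()].
#' @param edge_file path for the edge-list TSV.
#' @param graphml_file optional path for a GraphML export.
#' @return invisibly, the paths written.
#' @export
write_network <- function(network, edge_file, graphml_file = NULL) {
  utils::write.table(network$edges, edge_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_file)) {
    g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                       vertices = network$nodes)
    igraph::write_graph(g, graphml_file, format = "graphml")
  }
  invisible(c(edge_file, graphml_file))
}
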