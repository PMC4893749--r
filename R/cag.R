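#' Correlation-derived distance between OTUs
#'
#' `d_ij = 1 - rho_ij`, in `[0, 2]`: anticorrelated OTUs are maximally far
#' apart, so they fall into opposing co-abundance groups.
#'
#' @param rho symmetric correlation matrix (unit diagonal).
#' @return distance matrix with zero diagonal.
#' @export
correlation_distance <- function(rho) {
  d <- 1 - as.matrix(rho)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

#' Ward dendrogram over a distance matrix
#'
#' Agglomerative Ward linkage via the Lance-Williams update on the supplied
#' dissimilarities.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @return an `hclust` tree.
#' @export
ward_dendrogram <- function(D) {
  D <- .check_distance_matrix(D)
  stats::hclust(stats::as.dist(D), method = "ward.D")
}

#' Cut a dendrogram into co-abundance groups by per-split PERMANOVA
#'
#' Top-down recursion over the Ward tree. At each node the pseudo-F of the
#' two child OTU sets is computed from the distance matrix with the one-way
#' PERMANOVA partition (see [permanova_test()]). Because the tree itself
#' chose the split that maximizes separation, comparing that pseudo-F
#' against plain relabelings of the same OTUs is anti-conservative and
#' splits pure noise; the null therefore has to account for the selection.
#' The null model of "this node is one co-abundance group" is an
#' exchangeable correlation matrix at the node's median off-diagonal level
#' plus correlation-estimation (Wishart-type) noise whose magnitude matches
#' the MAD of the node's off-diagonal entries. Each null draw is
#' re-clustered with Ward and the pseudo-F of its best two-way split forms
#' the null distribution; the reported p-value is
#' `(1 + #{F_null >= F_obs}) / (n_used + 1)`. Draws stop early once
#' enough exceedances have accumulated that `p < alpha` is impossible.
#' An accepted split (`p < alpha`) recurses into both children (a
#' one-member child becomes a singleton CAG); a rejected or untestable node
#' becomes a single CAG.
#'
#' @param tree `hclust` tree built from `D` (see [ward_dendrogram()]).
#' @param D the distance matrix the tree was built from.
#' @param alpha split acceptance level (default 0.005).
#' @param n_perm maximum permutations per split test (default 9999).
#' @param seed integer seed.
#' @return a `cag_assignment`: list with `assignment` (named integer OTU ->
#'   CAG id), `n_cags`, `tree`, `split_pvalues` (data.frame over tested
#'   nodes).
#' @export
permanova_cut <- function(tree, D, alpha = 0.005, n_perm = 9999, seed = 1) {
  D <- .check_distance_matrix(D)
  n <- nrow(D)
  labels <- rownames(D) %||% tree$labels %||% sprintf("OTU%d", seq_len(n))

  members <- function(node) {
    if (node < 0) return(-node)
    c(members(tree$merge[node, 1]), members(tree$merge[node, 2]))
  }

  assignment <- integer(n)
  splits <- list()
  next_cag <- 0L
  counter <- 0L

  assign_cag <- function(idx) {
    next_cag <<- next_cag + 1L
    assignment[idx] <<- next_cag
  }

  recurse <- function(node) {
    if (node < 0) { assign_cag(-node); return(invisible()) }
    left <- members(tree$merge[node, 1])
    right <- members(tree$merge[node, 2])
    idx <- c(left, right)
    counter <<- counter + 1L
    res <- .split_test(D[idx, idx, drop = FALSE], length(left),
                       alpha = alpha, n_perm = n_perm,
                       seed = child_seed(seed, counter))
    splits[[length(splits) + 1L]] <<- data.frame(
      node = node, n_left = length(left), n_right = length(right),
      pseudo_F = res$F_obs, p_value = res$p_value,
      n_perm_used = res$n_used, accepted = res$p_value < alpha
    )
    if (res$p_value < alpha) {
      recurse(tree$merge[node, 1])
      recurse(tree$merge[node, 2])
    } else {
      assign_cag(idx)
    }
  }

  if (n == 1L) {
    assignment <- 1L
    next_cag <- 1L
  } else {
    recurse(nrow(tree$merge))
  }
  names(assignment) <- labels
  structure(
    list(assignment = assignment, n_cags = next_cag, tree = tree,
         split_pvalues = if (length(splits)) do.call(rbind, splits) else NULL),
    class = "cag_assignment"
  )
}

# PERMANOVA pseudo-F of a 2-group partition from a squared-distance matrix
.split_f <- function(D2, grp) {
  m <- nrow(D2)
  ss_total <- sum(D2[upper.tri(D2)]) / m
  ssw <- 0
  for (k in 1:2) {
    idx <- which(grp == k)
    if (length(idx) > 1) ssw <- ssw + sum(D2[idx, idx]) / (2 * length(idx))
  }
  if (ssw <= 0) return(Inf)
  ((ss_total - ssw) / 1) / (ssw / (m - 2))
}

# Selection-aware significance of one dendrogram split.
#
# Null model of "this node is one co-abundance group": an exchangeable
# (compound-symmetric) correlation at the node's median level plus
# correlation-estimation noise of matched magnitude (MAD of the off-diagonal
# entries; Wishart-type noise drawn at the implied effective sample size).
# Each null draw is re-clustered with Ward and the pseudo-F of its best
# two-way split is the null statistic, so the comparison accounts for the
# fact that the tree itself selected the most separated split.
.split_test <- function(Dsub, n_left, alpha, n_perm, seed) {
  m <- nrow(Dsub)
  grp_obs <- c(rep(1L, n_left), rep(2L, m - n_left))
  F_obs <- .split_f(Dsub^2, grp_obs)
  if (m < 3) {
    return(list(F_obs = F_obs, p_value = 1, n_used = 0L))
  }
  S <- 1 - Dsub
  off <- S[lower.tri(S)]
  mu <- stats::median(off)
  s <- stats::mad(off)
  if (!is.finite(s) || s < 1e-8) {
    return(list(F_obs = F_obs, p_value = 1, n_used = 0L))
  }
  n_eff <- max(5, min(1e7, round(1 / s^2)))
  k_stop <- ceiling(alpha * (n_perm + 1))   # once reached, p < alpha is impossible
  k <- 0L; i <- 0L
  with_seed(seed, {
    while (i < n_perm && k < k_stop) {
      i <- i + 1L
      if (n_eff > m) {
        W <- stats::rWishart(1, df = n_eff, Sigma = diag(m) / n_eff)[, , 1]
        R <- stats::cov2cor(W)
      } else {
        R <- suppressWarnings(stats::cor(matrix(stats::rnorm(n_eff * m), n_eff, m)))
        R[!is.finite(R)] <- 0
        diag(R) <- 1
      }
      dn <- 1 - mu - R    # off-diagonal: 1 - (mu + R_ij); diagonal reset below
      diag(dn) <- 0
      dn[dn < 0] <- 0
      dn[dn > 2] <- 2
      h <- stats::hclust(stats::as.dist(dn), method = "ward.D")
      g <- stats::cutree(h, k = 2)
      if (.split_f(dn^2, g) >= F_obs - 1e-12) k <- k + 1L
    }
  })
  list(F_obs = F_obs, p_value = (1 + k) / (i + 1), n_used = i)
}

#' @export
print.cag_assignment <- function(x, ...) {
  cat(sprintf("cag_assignment: %d OTUs in %d CAG(s)\n",
              length(x$assignment), x$n_cags))
  invisible(x)
}

#' Per-sample CAG abundance profiles
#'
#' Sums the relative abundances of each CAG's member OTUs per sample; CAG
#' totals per sample conserve the summed key-OTU abundance.
#'
#' @param abund samples x OTUs relative-abundance matrix (or an
#'   [otu_table], converted internally).
#' @param assignment a `cag_assignment` (or named OTU -> CAG integer
#'   vector); its OTUs must be a subset of the table's.
#' @return matrix samples x CAGs (columns `CAG1`, `CAG2`, ...).
#' @export
cag_abundance_profiles <- function(abund, assignment) {
  if (inherits(abund, "otu_table")) abund <- relative_abundances(abund)
  a <- if (inherits(assignment, "cag_assignment")) assignment$assignment else assignment
  missing_otus <- setdiff(names(a), colnames(abund))
  if (length(missing_otus)) {
    stop("assignment OTUs absent from table: ", paste(missing_otus, collapse = ", "),
         call. = FALSE)
  }
  cags <- sort(unique(a))
  prof <- vapply(cags, function(k) {
    rowSums(abund[, names(a)[a == k], drop = FALSE])
  }, numeric(nrow(abund)))
  colnames(prof) <- sprintf("CAG%d", cags)
  rownames(prof) <- rownames(abund)
  prof
}

#' Group-vs-reference tests of CAG trajectories
#'
#' For every CAG, day and non-reference group, a Kruskal-Wallis test of that
#' group against the reference group at the same day;
#' Benjamini-Hochberg adjustment is applied across the whole CAG x day x
#' group family. Significance stars: `*` FDR < 0.05, `**` < 0.01,
#' `***` < 0.005.
#'
#' @param profile samples x CAGs matrix from [cag_abundance_profiles()].
#' @param metadata data.frame with `sample_id`, `group`, `day` covering the
#'   profile rows.
#' @param reference_group the comparison baseline (e.g. the plain-disease
#'   group).
#' @return data.frame with `cag`, `day`, `group`, `H`, `raw_p`,
#'   `adjusted_p`, `stars`.
#' @export
cag_group_dynamics <- function(profile, metadata, reference_group) {
  meta <- metadata[match(rownames(profile), metadata$sample_id), ]
  if (length(unique(meta$group)) < 2) {
    stop("need at least 2 groups", call. = FALSE)
  }
  if (!reference_group %in% meta$group) {
    stop("reference_group not present in metadata", call. = FALSE)
  }
  rows <- list()
  for (cg in colnames(profile)) {
    for (d in sort(unique(meta$day))) {
      ref <- profile[meta$group == reference_group & meta$day == d, cg]
      for (g in setdiff(unique(meta$group), reference_group)) {
        val <- profile[meta$group == g & meta$day == d, cg]
        if (length(ref) < 2 || length(val) < 2) next
        kt <- kruskal_wallis(list(val, ref))
        rows[[length(rows) + 1L]] <- data.frame(
          cag = cg, day = d, group = g, H = kt$H, raw_p = kt$p_value
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  out$adjusted_p <- benjamini_hochberg(out$raw_p)
  out$stars <- ifelse(out$adjusted_p < 0.005, "***",
                      ifelse(out$adjusted_p < 0.01, "**",
                             ifelse(out$adjusted_p < 0.05, "*", "")))
  out
}

#' OTUs strongly correlated with the invading taxon
#'
#' @param result a `sparcc_result` (or list with `rho`).
#' @param invader_otu column name of the invader in `rho`.
#' @param threshold correlation magnitude cutoff (default 0.5).
#' @return list with `positive` and `negative` OTU id vectors.
#' @export
invader_correlates <- function(result, invader_otu, threshold = 0.5) {
  rho <- result$rho
  if (!invader_otu %in% colnames(rho)) {
    stop("invader OTU not present in the correlation matrix", call. = FALSE)
  }
  r <- rho[invader_otu, ]
  r <- r[names(r) != invader_otu]
  list(positive = names(r)[r > threshold],
       negative = names(r)[r < -threshold])
}

#' Export a CAG assignment and dendrogram
#'
#' @param assignment a `cag_assignment`.
#' @param assignment_file TSV path (`otu_id`, `cag`).
#' @param newick_file optional Newick path for the dendrogram (with merge
#'   heights).
#' @return invisibly, the paths written.
#' @export
write_cag_assignment <- function(assignment, assignment_file, newick_file = NULL) {
  utils::write.table(
    data.frame(otu_id = names(assignment$assignment),
               cag = sprintf("CAG%d", assignment$assignment)),
    assignment_file, sep = "\t", quote = FALSE, row.names = FALSE
  )
  if (!is.null(newick_file)) {
    phy <- ape::as.phylo(assignment$tree)
    ape::write.tree(phy, newick_file)
  }
  invisible(c(assignment_file, newick_file))
}
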