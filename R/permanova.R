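#' One-way PERMANOVA on a distance matrix
#'
#' Partitions the sum of squared dissimilarities between and within groups:
#' `SS_total = (1/n) sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2`,
#' `F = (SS_between / (g - 1)) / (SS_within / (n - g))`,
#' with significance from uniform permutations of the sample labels:
#' `p = (1 + #{F_perm >= F_obs}) / (n_perm + 1)`. With `exact = TRUE` all
#' distinct label assignments are enumerated instead and
#' `p = #{F >= F_obs} / #assignments` (the observed assignment included).
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param labels group label per sample (row order of `D`).
#' @param n_perm number of random permutations (default 9999).
#' @param seed integer seed for the permutations.
#' @param exact enumerate all distinct assignments (feasible for small n).
#' @param allow_singletons permit groups of size 1 (used by the dendrogram
#'   cut; singleton groups contribute zero within-group sum).
#' @return a `permanova_result`: list with `pseudo_F`, `p_value`,
#'   `n_permutations`, `group_sizes`, `ss_between`, `ss_within`,
#'   `ss_total`.
#' @export
permanova_test <- function(D, labels, n_perm = 9999, seed = 1,
                           exact = FALSE, allow_singletons = FALSE) {
  D <- .check_distance_matrix(D)
  labels <- as.character(labels)
  n <- nrow(D)
  stopifnot(length(labels) == n)
  sizes <- table(labels)
  g <- length(sizes)
  if (g < 2) stop("need at least 2 groups", call. = FALSE)
  if (!allow_singletons && any(sizes < 2)) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  D2 <- D^2
  ss_total <- sum(D2[upper.tri(D2)]) / n

  f_stat <- function(lab_idx_list) {
    ssw <- 0
    for (idx in lab_idx_list) {
      ng <- length(idx)
      if (ng > 1) ssw <- ssw + sum(D2[idx, idx]) / (2 * ng)
    }
    ssb <- ss_total - ssw
    if (ssw <= 0) return(Inf)
    (ssb / (g - 1)) / (ssw / (n - g))
  }
  obs_idx <- split(seq_len(n), labels)
  F_obs <- f_stat(obs_idx)

  if (exact) {
    asg <- .enumerate_assignments(as.integer(sizes))
    Fs <- vapply(asg, function(a) f_stat(split(seq_len(n), a)), 0)
    p <- mean(Fs >= F_obs - 1e-12)
    n_used <- length(asg)
  } else {
    # vectorized permutation null: for each group, quadratic forms
    # u' D2 u over all permuted indicator vectors at once
    perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
    })
    ssw_perm <- numeric(n_perm)
    lab_int <- match(labels, names(sizes))
    for (k in seq_len(g)) {
      U <- matrix(0, n, n_perm)
      sel <- which(lab_int == k)
      U[cbind(as.vector(perm[sel, , drop = FALSE]),
              rep(seq_len(n_perm), each = length(sel)))] <- 1
      ng <- length(sel)
      if (ng > 1) {
        qf <- colSums(U * (D2 %*% U)) / 2
        ssw_perm <- ssw_perm + qf / ng
      }
    }
    F_perm <- ifelse(ssw_perm <= 0, Inf,
                     ((ss_total - ssw_perm) / (g - 1)) / (ssw_perm / (n - g)))
    p <- (1 + sum(F_perm >= F_obs - 1e-12)) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(
    list(pseudo_F = F_obs, p_value = p, n_permutations = n_used,
         group_sizes = as.integer(sizes), groups = names(sizes),
         ss_between = ss_total - sum(vapply(obs_idx, function(idx) {
           if (length(idx) > 1) sum(D2[idx, idx]) / (2 * length(idx)) else 0
         }, 0)),
         ss_within = sum(vapply(obs_idx, function(idx) {
           if (length(idx) > 1) sum(D2[idx, idx]) / (2 * length(idx)) else 0
         }, 0)),
         ss_total = ss_total),
    class = "permanova_result"
  )
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g, p = %.4g (%d permutations; groups %s)\n",
              x$pseudo_F, x$p_value, x$n_permutations,
              paste(sprintf("%s n=%d", x$groups, x$group_sizes), collapse = ", ")))
  invisible(x)
}

# all distinct assignments of n items to groups with fixed sizes
.enumerate_assignments <- function(sizes) {
  n <- sum(sizes)
  out <- list()
  recurse <- function(remaining, assignment, k) {
    if (k == length(sizes)) {
      assignment[remaining] <- k
      out[[length(out) + 1L]] <<- assignment
      return(invisible())
    }
    picks <- utils::combn(remaining, sizes[k], simplify = FALSE)
    for (p in picks) {
      a <- assignment; a[p] <- k
      recurse(setdiff(remaining, p), a, k + 1L)
    }
  }
  recurse(seq_len(n), integer(n), 1L)
  out
}

#' Screen group-pair contrasts by PERMANOVA
#'
#' Runs [permanova_test()] on the sample subset of each contrast and flags
#' significance at raw `alpha` (unadjusted screening that gates the
#' random-forest models).
#'
#' @param D distance matrix over samples.
#' @param metadata data.frame with `sample_id`, `group`, `day` matching the
#'   labels of `D`.
#' @param contrasts list of contrasts, each a list with elements `a` and
#'   `b`, themselves lists with `group` and optionally `day` (a vector of
#'   days, `NULL` = all days).
#' @param alpha screening level (default 0.05).
#' @param n_perm,seed passed to [permanova_test()].
#' @return data.frame with one row per contrast: `contrast`, `n_a`, `n_b`,
#'   `pseudo_F`, `p_value`, `significant` (skipped contrasts carry `NA` and
#'   a warning).
#' @export
pairwise_screen <- function(D, metadata, contrasts, alpha = 0.05,
                            n_perm = 9999, seed = 1) {
  D <- .check_distance_matrix(D)
  meta <- metadata[match(rownames(D), metadata$sample_id), ]
  sel <- function(side) {
    i <- meta$group %in% side$group
    if (!is.null(side$day)) i <- i & meta$day %in% side$day
    which(i)
  }
  rows <- list()
  for (ci in seq_along(contrasts)) {
    ct <- contrasts[[ci]]
    ia <- sel(ct$a); ib <- sel(ct$b)
    nm <- ct$name %||% sprintf(
      "%s_d%s_vs_%s_d%s",
      paste(ct$a$group, collapse = "+"), paste(ct$a$day %||% "all", collapse = "+"),
      paste(ct$b$group, collapse = "+"), paste(ct$b$day %||% "all", collapse = "+")
    )
    if (length(ia) < 2 || length(ib) < 2) {
      warning(sprintf("contrast '%s' skipped: fewer than 2 samples on one side", nm))
      rows[[ci]] <- data.frame(contrast = nm, n_a = length(ia), n_b = length(ib),
                               pseudo_F = NA_real_, p_value = NA_real_,
                               significant = NA)
      next
    }
    idx <- c(ia, ib)
    res <- permanova_test(
      D[idx, idx, drop = FALSE],
      c(rep("a", length(ia)), rep("b", length(ib))),
      n_perm = n_perm, seed = child_seed(seed, ci)
    )
    rows[[ci]] <- data.frame(contrast = nm, n_a = length(ia), n_b = length(ib),
                             pseudo_F = res$pseudo_F, p_value = res$p_value,
                             significant = res$p_value < alpha)
  }
  do.call(rbind, rows)
}

#' All group-vs-group contrasts at each sampling day
#'
#' @param design a `study_design` (or any object with `groups` and `days`).
#' @return a contrast list consumable by [pairwise_screen()].
#' @export
default_contrasts <- function(design) {
  out <- list()
  gs <- design$groups
  for (d in design$days) {
    for (i in seq_along(gs)) for (j in seq_along(gs)) {
      if (i >= j) next
      out[[length(out) + 1L]] <- list(
        a = list(group = gs[i], day = d), b = list(group = gs[j], day = d),
        name = sprintf("%s_vs_%s_day%d", gs[i], gs[j], d)
      )
    }
  }
  out
}
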