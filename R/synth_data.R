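#' Define a longitudinal multi-group study design
#'
#' @param groups character vector of group labels.
#' @param days integer timepoints, strictly increasing. Negative days are
#'   pre-treatment baselines.
#' @param n_samples integer matrix of per-(group, day) sample counts with
#'   `length(groups)` rows and `length(days)` columns.
#' @param n_otus number of resident OTUs simulated (an invading taxon, if
#'   any, is added on top).
#' @param depth_range length-2 integer vector; per-sample sequencing depths
#'   are drawn uniformly from this range.
#' @return a `study_design` object.
#' @export
study_design <- function(groups, days, n_samples, n_otus = 100,
                         depth_range = c(9000L, 30000L)) {
  groups <- as.character(groups)
  days <- as.integer(days)
  n_samples <- as.matrix(n_samples)
  if (any(diff(days) <= 0)) stop("days must be strictly increasing", call. = FALSE)
  if (!identical(dim(n_samples), c(length(groups), length(days)))) {
    stop("n_samples must be groups x days", call. = FALSE)
  }
  if (any(n_samples < 1)) stop("all per-cell sample counts must be >= 1", call. = FALSE)
  if (n_otus < 4) stop("n_otus must be >= 4 (compositional correlation needs >= 4 taxa)",
                       call. = FALSE)
  if (length(depth_range) != 2 || depth_range[1] > depth_range[2] || depth_range[1] < 1) {
    stop("depth_range must be an increasing positive pair", call. = FALSE)
  }
  dimnames(n_samples) <- list(groups, as.character(days))
  structure(
    list(groups = groups, days = days, n_samples = n_samples,
         n_otus = as.integer(n_otus), depth_range = as.integer(depth_range)),
    class = "study_design"
  )
}

#' The default three-group, four-day colitis study design
#'
#' Three groups (vehicle control `PBS`, colitis induction `DSS`, colitis plus
#' gavage of a butyrate-producing invader `DSS_BPB5`) sampled at days
#' -1 (baseline), 2, 4 and 7, with the per-cell sample sizes of the study
#' this pipeline emulates: DSS+BPB5 (12, 11, 12, 6), DSS (12, 12, 12, 6),
#' PBS (12, 10, 12, 6); 123 samples in total.
#'
#' @param n_otus resident OTU count (default 100).
#' @param depth_range per-sample depth range (default 9000-30000 reads).
#' @return a `study_design`.
#' @export
build_default_design <- function(n_otus = 100, depth_range = c(9000L, 30000L)) {
  study_design(
    groups = c("PBS", "DSS", "DSS_BPB5"),
    days = c(-1L, 2L, 4L, 7L),
    n_samples = rbind(
      PBS      = c(12L, 10L, 12L, 6L),
      DSS      = c(12L, 12L, 12L, 6L),
      DSS_BPB5 = c(12L, 11L, 12L, 6L)
    ),
    n_otus = n_otus,
    depth_range = depth_range
  )
}

# piecewise-linear treatment ramp: 0 until the block's onset day, full
# effect from day 7 on
.effect_ramp <- function(day, onset = 0) {
  span <- max(7 - onset, 1)
  pmin(pmax(day - onset, 0) / span, 1)
}

#' Planted effect structure for the synthetic community
#'
#' Describes the latent (log-scale) model of the generator: OTUs are grouped
#' into correlated blocks; selected blocks are depleted or enriched along a
#' treatment ramp in the diseased groups; the invader group experiences the
#' same effects `shift_lead_days` days early; an invading taxon is present
#' only in the inoculated group from its first post-gavage day, co-varying
#' with one resident block (its planted correlates).
#'
#' @param design a `study_design`.
#' @param n_blocks number of correlated blocks (default 5).
#' @param block_size OTUs per block (default 10); remaining OTUs are
#'   uncorrelated background.
#' @param rho_block within-block latent correlation in `[0, 1)`.
#' @param sigma latent log-abundance standard deviation per OTU.
#' @param effect_size maximum latent log-fold effect of treatment (full ramp).
#' @param depleted_blocks,enriched_blocks block indices shifted down/up under
#'   treatment.
#' @param block_onsets per-block onset day of the treatment effect in the
#'   plain-treatment group (recycled/truncated to `n_blocks`). The default
#'   makes the second block a late-onset guild (onset day 4): its shift is
#'   only detectable by day 7 under plain treatment but, with the invader
#'   group's lead, already by day 2-4 — the observable signature of an
#'   accelerated community shift on this sampling grid.
#' @param treated_groups groups receiving the treatment effect; by default
#'   every group except the first (the vehicle control).
#' @param invader_group group inoculated with the invader; by default
#'   `"DSS_BPB5"` when that group exists, otherwise none. `NA` disables the
#'   invader entirely.
#' @param invader_block resident block the invader co-varies with.
#' @param invader_log_abundance latent log-abundance of the invader relative
#'   to the resident mean (0 = typical resident OTU).
#' @param invader_first_day first day the invader is detectable.
#' @param shift_lead_days days by which the invader group's treatment effects
#'   precede the plain-treatment group's.
#' @param base_log_mean optional length-`n_otus` vector of baseline latent
#'   log-means (default: mild even spread on `[-1, 1]`).
#' @return an `effect_spec` object, including the per-(group, day) latent
#'   shift array `shift` and, when enabled, the invader description.
#' @export
effect_spec <- function(design,
                        n_blocks = 5, block_size = 10,
                        rho_block = 0.8, sigma = 0.5,
                        effect_size = 2,
                        depleted_blocks = c(1, 2),
                        enriched_blocks = 3,
                        block_onsets = c(0, 4, 0, 0, 0),
                        treated_groups = NULL,
                        invader_group = NULL,
                        invader_block = 3,
                        invader_log_abundance = 1.5,
                        invader_first_day = 2,
                        shift_lead_days = 3,
                        base_log_mean = NULL) {
  stopifnot(inherits(design, "study_design"))
  p <- design$n_otus
  if (n_blocks * block_size > p) stop("blocks exceed n_otus", call. = FALSE)
  if (rho_block < 0 || rho_block >= 1) stop("rho_block must lie in [0, 1)", call. = FALSE)
  blocks <- rep(0L, p)
  for (b in seq_len(n_blocks)) {
    blocks[((b - 1) * block_size + 1):(b * block_size)] <- b
  }
  if (is.null(base_log_mean)) {
    base_log_mean <- if (p > 1) seq(-1, 1, length.out = p) else 0
  }
  stopifnot(length(base_log_mean) == p)
  if (is.null(treated_groups)) {
    # every non-control group (the first group is the vehicle control)
    treated_groups <- setdiff(design$groups, design$groups[1])
  }
  if (is.null(invader_group)) {
    invader_group <- if ("DSS_BPB5" %in% design$groups) "DSS_BPB5" else NA
  }
  has_invader <- !is.na(invader_group)
  if (has_invader && !invader_group %in% design$groups) {
    stop("invader_group must be one of the design's groups", call. = FALSE)
  }
  bad <- setdiff(treated_groups, design$groups)
  if (length(bad)) stop("unknown treated group(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)

  # latent log shift per OTU x group x day; covers every (group, day) cell
  shift <- array(
    0, dim = c(p, length(design$groups), length(design$days)),
    dimnames = list(NULL, design$groups, as.character(design$days))
  )
  onsets <- rep_len(block_onsets, max(n_blocks, 1L))
  for (g in design$groups) {
    if (!g %in% treated_groups) next
    lead <- if (has_invader && identical(g, invader_group)) shift_lead_days else 0
    for (di in seq_along(design$days)) {
      d <- design$days[di]
      for (b in unique(c(depleted_blocks, enriched_blocks))) {
        r <- if (d < 0) 0 else .effect_ramp(d + lead, onsets[b])
        sgn <- if (b %in% depleted_blocks) -1 else 1
        shift[blocks == b, g, di] <- sgn * effect_size * r
      }
    }
  }

  invader <- NULL
  if (has_invader) {
    invader <- list(
      group = invader_group, block = invader_block,
      log_abundance = invader_log_abundance,
      first_day = invader_first_day, otu_id = "OTU_invader"
    )
  }
  structure(
    list(block_assignments = blocks, rho_block = rho_block, sigma = sigma,
         effect_size = effect_size, base_log_mean = base_log_mean,
         shift = shift, invader = invader, shift_lead_days = shift_lead_days,
         depleted_blocks = depleted_blocks, enriched_blocks = enriched_blocks),
    class = "effect_spec"
  )
}

#' A no-structure effect specification (global null)
#'
#' All treatment effects zero, no latent correlation, no invader; used for
#' calibration of downstream tests.
#'
#' @inheritParams effect_spec
#' @export
null_effect_spec <- function(design, sigma = 0.5) {
  effect_spec(design,
    n_blocks = 0, block_size = 0,
    rho_block = 0, sigma = sigma, effect_size = 0,
    depleted_blocks = integer(), enriched_blocks = integer(),
    invader_group = NA, base_log_mean = rep(0, design$n_otus)
  )
}

#' Simulate a longitudinal compositional OTU count table
#'
#' Latent per-sample log-abundances are multivariate normal with
#' block-structured correlation (`rho_block` within a block, 0 between),
#' shifted by the planted group-by-day effects; a softmax maps them to
#' fractions; counts are multinomial at a depth drawn uniformly from the
#' design's depth range. The invading taxon, when present, is an extra
#' column that is exactly zero in non-inoculated groups and before its first
#' day, and co-varies with its host block in inoculated samples.
#'
#' @param design a `study_design`.
#' @param effects an `effect_spec` built from the same design.
#' @param seed integer seed; identical inputs and seed give identical output.
#' @return a list with `table` (an [otu_table]) and `truth` (the planted
#'   structure: block assignments, latent fractions, per-group-pair
#'   discriminatory OTU sets, invader id and correlates).
#' @export
simulate_otu_table <- function(design, effects, seed) {
  stopifnot(inherits(design, "study_design"), inherits(effects, "effect_spec"))
  p <- design$n_otus
  if (p < 4) stop("need at least 4 OTUs", call. = FALSE)
  blocks <- effects$block_assignments
  rho <- effects$rho_block
  sigma <- effects$sigma
  inv <- effects$invader
  otu_ids <- sprintf("OTU%03d", seq_len(p))
  all_ids <- c(otu_ids, if (!is.null(inv)) inv$otu_id)
  n_cols <- length(all_ids)

  rows <- list(); meta <- list(); lat <- list()
  with_seed(seed, {
    ri <- 0L
    for (gi in seq_along(design$groups)) {
      g <- design$groups[gi]
      for (di in seq_along(design$days)) {
        d <- design$days[di]
        n_k <- design$n_samples[gi, di]
        for (k in seq_len(n_k)) {
          ri <- ri + 1L
          # shared block factors + idiosyncratic noise on the latent log scale
          n_b <- max(blocks)
          fb <- if (n_b > 0) stats::rnorm(n_b) else numeric(0)
          eps <- stats::rnorm(p)
          z <- effects$base_log_mean + effects$shift[, gi, di]
          in_block <- blocks > 0
          z[in_block] <- z[in_block] +
            sigma * (sqrt(rho) * fb[blocks[in_block]] + sqrt(1 - rho) * eps[in_block])
          z[!in_block] <- z[!in_block] + sigma * eps[!in_block]

          ez <- exp(z)
          if (!is.null(inv)) {
            present <- identical(g, inv$group) && d >= inv$first_day
            if (present) {
              e_inv <- stats::rnorm(1)
              f_shared <- if (inv$block >= 1 && inv$block <= n_b) fb[inv$block] else 0
              z_inv <- inv$log_abundance +
                sigma * (sqrt(rho) * f_shared + sqrt(1 - rho) * e_inv)
              ez <- c(ez, exp(z_inv))
            } else {
              ez <- c(ez, 0)
            }
          }
          frac <- ez / sum(ez)
          depth <- floor(stats::runif(1, design$depth_range[1], design$depth_range[2] + 1))
          cnt <- stats::rmultinom(1, depth, frac)[, 1]
          rows[[ri]] <- cnt
          lat[[ri]] <- frac
          meta[[ri]] <- data.frame(
            sample_id = sprintf("%s_D%d_M%02d", g, d, k),
            group = g, day = d, subject = sprintf("%s_M%02d", g, k),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  })
  counts <- do.call(rbind, rows)
  latent <- do.call(rbind, lat)
  metadata <- do.call(rbind, meta)
  colnames(counts) <- colnames(latent) <- all_ids
  rownames(counts) <- rownames(latent) <- metadata$sample_id

  truth <- list(
    block_assignments = stats::setNames(blocks, otu_ids),
    latent_fractions = latent,
    discriminatory = .discriminatory_sets(design, effects, otu_ids),
    invader_otu = if (!is.null(inv)) inv$otu_id else NA_character_,
    invader_correlates = if (!is.null(inv)) otu_ids[blocks == inv$block] else character(0)
  )
  list(table = otu_table(counts, metadata), truth = truth)
}

# OTUs whose planted latent shift differs between two groups at any day
.discriminatory_sets <- function(design, effects, otu_ids) {
  out <- list()
  gs <- design$groups
  for (i in seq_along(gs)) {
    for (j in seq_along(gs)) {
      if (i >= j) next
      dif <- apply(abs(effects$shift[, gs[i], , drop = FALSE] -
                         effects$shift[, gs[j], , drop = FALSE]), 1, max)
      set <- otu_ids[dif > 0]
      inv <- effects$invader
      if (!is.null(inv) && xor(identical(gs[i], inv$group), identical(gs[j], inv$group))) {
        set <- c(set, inv$otu_id)
      }
      out[[paste(gs[i], gs[j], sep = "_vs_")]] <- set
    }
  }
  out
}
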