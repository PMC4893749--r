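#' Build and validate a pipeline configuration
#'
#' A declarative description of one end-to-end run: rarefaction, the
#' PERMANOVA screen, random-forest key-OTU selection, SparCC, CAG
#' clustering, trajectory dynamics and differential testing. Every
#' stochastic stage takes its seed from `seeds`; unknown keys are rejected
#' so typos cannot silently fall back to defaults.
#'
#' @param out_dir run directory (created if needed).
#' @param rarefy_depth,rarefy_n_rep rarefaction depth and alpha repetitions.
#' @param screen_alpha,screen_n_perm PERMANOVA screen level/permutations.
#' @param rf_n_trees,mda_threshold,max_class_error key-OTU stage settings.
#' @param sparcc_n_iter,sparcc_n_null SparCC iterations / null datasets.
#' @param edge_threshold network edge |rho| cutoff.
#' @param cag_alpha,cag_n_perm CAG split test settings.
#' @param reference_group reference for CAG dynamics and differential tests.
#' @param fdr_alpha FDR level for differential OTUs.
#' @param contrasts contrast list for the screen (NULL: all group pairs per
#'   day).
#' @param seeds named list of integer seeds; must contain `rarefy`,
#'   `screen`, `rf`, `sparcc`, `cag`.
#' @param ... rejected: any unknown key raises an error.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            rarefy_depth = 9000, rarefy_n_rep = 1000,
                            screen_alpha = 0.05, screen_n_perm = 9999,
                            rf_n_trees = 1000, mda_threshold = 0.003,
                            max_class_error = 0,
                            sparcc_n_iter = 20, sparcc_n_null = 100,
                            edge_threshold = 0.5,
                            cag_alpha = 0.005, cag_n_perm = 9999,
                            reference_group = "DSS", fdr_alpha = 0.05,
                            contrasts = NULL,
                            seeds = list(), ...) {
  extra <- list(...)
  if (length(extra)) {
    stop("unknown config key(s): ", paste(names(extra), collapse = ", "),
         call. = FALSE)
  }
  need <- c("rarefy", "screen", "rf", "sparcc", "cag")
  miss <- setdiff(need, names(seeds))
  if (length(miss)) {
    stop("missing seed(s) for stage(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (s in need) stop_if_not_scalar_number(seeds[[s]], paste0("seeds$", s))
  structure(
    list(out_dir = out_dir, rarefy_depth = rarefy_depth,
         rarefy_n_rep = rarefy_n_rep, screen_alpha = screen_alpha,
         screen_n_perm = screen_n_perm, rf_n_trees = rf_n_trees,
         mda_threshold = mda_threshold, max_class_error = max_class_error,
         sparcc_n_iter = sparcc_n_iter, sparcc_n_null = sparcc_n_null,
         edge_threshold = edge_threshold, cag_alpha = cag_alpha,
         cag_n_perm = cag_n_perm, reference_group = reference_group,
         fdr_alpha = fdr_alpha, contrasts = contrasts, seeds = seeds),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline on an OTU table
#'
#' Stages, in order: rarefaction (alpha diversity over repetitions, beta on
#' repetition 0) -> Bray-Curtis PCoA -> PERMANOVA screen of group-pair
#' contrasts -> random-forest models on significant pairs -> key-OTU union
#' -> SparCC on the key OTUs (plus permutation p-values) -> correlation
#' network -> Ward/PERMANOVA CAGs -> CAG group dynamics -> differential
#' OTU tables -> baseline-distance trajectories. Every intermediate is
#' written under `config$out_dir` as plain text, along with a log of the
#' parameters and seeds actually used and a machine-readable JSON summary.
#'
#' @param table an [otu_table].
#' @param config a [pipeline_config()].
#' @param invader_otu optional id of the invading taxon for correlate
#'   extraction.
#' @param resume reuse cached per-stage results found in `out_dir` from an
#'   earlier run with the same config (stage results are cached as `.cache_*`
#'   files); the final results are identical either way.
#' @return the summary list (invisibly also written as `summary.json`).
#' @export
run_pipeline <- function(table, config, invader_otu = NULL, resume = FALSE) {
  stopifnot(inherits(table, "otu_table"), inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cached <- function(name, compute) {
    f <- file.path(config$out_dir, sprintf(".cache_%s.rds", name))
    if (resume && file.exists(f)) return(readRDS(f))
    v <- compute()
    saveRDS(v, f)
    v
  }
  logf <- file.path(config$out_dir, "pipeline.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = logf, append = TRUE)
  cat("", file = logf)
  log_line("otudyn pipeline, package version %s", as.character(utils::packageVersion("otudyn")))
  for (k in setdiff(names(config), c("contrasts", "seeds"))) {
    log_line("param %s = %s", k, paste(format(config[[k]]), collapse = ","))
  }
  for (k in names(config$seeds)) log_line("seed %s = %d", k, as.integer(config$seeds[[k]]))

  # --- rarefaction -----------------------------------------------------
  rar <- cached("rarefy", function() {
    rarefy(table, depth = config$rarefy_depth, n_rep = config$rarefy_n_rep,
           seed = config$seeds$rarefy)
  })
  utils::write.table(rar$alpha, file.path(config$out_dir, "alpha_diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_line("stage rarefy: depth=%d, kept %d samples, excluded %d",
           config$rarefy_depth, nrow(rar$counts), length(rar$excluded_samples))
  meta <- rar$metadata
  abund <- rar$counts / config$rarefy_depth

  # --- beta diversity / ordination ------------------------------------
  D <- bray_curtis(rar)
  utils::write.table(D, file.path(config$out_dir, "bray_curtis.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  ord <- pcoa(D)
  ord_out <- data.frame(sample_id = rownames(ord$coordinates),
                        ord$coordinates[, seq_len(min(5, ncol(ord$coordinates))),
                                        drop = FALSE])
  utils::write.table(ord_out, file.path(config$out_dir, "pcoa.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  traj <- distance_from_baseline(D, meta)
  utils::write.table(traj, file.path(config$out_dir, "baseline_distance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_line("stage ordination: %d positive eigenvalues", length(ord$eigenvalues))

  # --- PERMANOVA screen ------------------------------------------------
  contrasts <- config$contrasts %||% default_contrasts(
    list(groups = unique(meta$group), days = sort(unique(meta$day)))
  )
  screen <- cached("screen", function() {
    pairwise_screen(D, meta, contrasts, alpha = config$screen_alpha,
                    n_perm = config$screen_n_perm, seed = config$seeds$screen)
  })
  utils::write.table(screen, file.path(config$out_dir, "permanova_screen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_line("stage screen: %d of %d contrasts significant at %.3g",
           sum(screen$significant, na.rm = TRUE), nrow(screen), config$screen_alpha)

  # --- random-forest key OTUs -----------------------------------------
  sig <- which(!is.na(screen$significant) & screen$significant)
  models <- cached("rf", function() {
    out <- list()
    for (ci in sig) {
      ct <- contrasts[[ci]]
      selside <- function(side) {
        i <- meta$group %in% side$group
        if (!is.null(side$day)) i <- i & meta$day %in% side$day
        which(i)
      }
      ia <- selside(ct$a); ib <- selside(ct$b)
      idx <- c(ia, ib)
      out[[screen$contrast[ci]]] <- fit_pair_model(
        abund[idx, , drop = FALSE],
        c(rep("a", length(ia)), rep("b", length(ib))),
        n_trees = config$rf_n_trees,
        seed = child_seed(config$seeds$rf, ci),
        pair_id = screen$contrast[ci]
      )
    }
    out
  })
  model_tab <- do.call(rbind, lapply(models, function(m) {
    data.frame(pair = m$pair, oob_error = m$oob_class_error)
  }))
  if (!is.null(model_tab)) {
    utils::write.table(model_tab, file.path(config$out_dir, "rf_models.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  keys <- select_key_otus(models, mda_threshold = config$mda_threshold,
                          max_class_error = config$max_class_error)
  utils::write.table(
    data.frame(otu_id = keys$otu_ids,
               provenance = vapply(keys$provenance, paste, "", collapse = ";")),
    file.path(config$out_dir, "key_otus.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  log_line("stage keyotu: %d key OTUs from %d successful models",
           length(keys$otu_ids), keys$n_models_used)

  summary <- list(
    n_samples = nrow(rar$counts),
    excluded_samples = rar$excluded_samples,
    n_significant_contrasts = sum(screen$significant, na.rm = TRUE),
    contrast_pvalues = stats::setNames(screen$p_value, screen$contrast),
    n_key_otus = length(keys$otu_ids)
  )

  if (length(keys$otu_ids) >= 4) {
    # --- SparCC + network ---------------------------------------------
    key_counts <- rar$counts[, keys$otu_ids, drop = FALSE]
    sp <- cached("sparcc", function() {
      sparcc_estimate(key_counts, n_est_iter = config$sparcc_n_iter,
                      seed = config$seeds$sparcc)
    })
    pv <- cached("sparcc_null", function() {
      sparcc_null_pvalues(key_counts, sp$rho, n_null = config$sparcc_n_null,
                          seed = child_seed(config$seeds$sparcc, 1),
                          n_est_iter = config$sparcc_n_iter)
    })
    utils::write.table(sp$rho, file.path(config$out_dir, "sparcc_rho.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    utils::write.table(pv, file.path(config$out_dir, "sparcc_pvalues.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    net <- build_network(sp, edge_threshold = config$edge_threshold,
                         abundance = colMeans(abund[, keys$otu_ids, drop = FALSE]))
    write_network(net, file.path(config$out_dir, "network_edges.tsv"),
                  file.path(config$out_dir, "network.graphml"))
    log_line("stage sparcc: %d network edges above |rho| > %.2f",
             nrow(net$edges), config$edge_threshold)

    # --- CAGs ----------------------------------------------------------
    Dc <- correlation_distance(sp$rho)
    cags <- cached("cag", function() {
      permanova_cut(ward_dendrogram(Dc), Dc, alpha = config$cag_alpha,
                    n_perm = config$cag_n_perm, seed = config$seeds$cag)
    })
    write_cag_assignment(cags, file.path(config$out_dir, "cag_assignment.tsv"),
                         file.path(config$out_dir, "cag_dendrogram.nwk"))
    prof <- cag_abundance_profiles(abund, cags)
    utils::write.table(data.frame(sample_id = rownames(prof), prof),
                       file.path(config$out_dir, "cag_profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dyn <- cag_group_dynamics(prof, meta, config$reference_group)
    utils::write.table(dyn, file.path(config$out_dir, "cag_dynamics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_line("stage cag: %d CAGs", cags$n_cags)
    summary$n_cags <- cags$n_cags
    summary$n_network_edges <- nrow(net$edges)

    if (!is.null(invader_otu) && invader_otu %in% colnames(sp$rho)) {
      corr <- invader_correlates(sp, invader_otu, threshold = config$edge_threshold)
      summary$invader_positive <- corr$positive
      summary$invader_negative <- corr$negative
      log_line("stage invader: %d positive, %d negative correlates",
               length(corr$positive), length(corr$negative))
    }
  } else {
    log_line("stage sparcc/cag skipped: fewer than 4 key OTUs")
    summary$n_cags <- 0L
  }

  # --- differential tables --------------------------------------------
  ref <- config$reference_group
  diff_list <- list()
  for (g in setdiff(unique(meta$group), ref)) {
    for (d in sort(unique(meta$day))) {
      if (sum(meta$group == g & meta$day == d) < 2 ||
          sum(meta$group == ref & meta$day == d) < 2) next
      ct <- list(a = list(group = g, day = d), b = list(group = ref, day = d))
      dt <- differential_otus(abund, meta, ct, alpha_fdr = config$fdr_alpha)
      dt$contrast <- sprintf("%s_vs_%s_day%d", g, ref, d)
      diff_list[[dt$contrast[1]]] <- dt
    }
  }
  if (length(diff_list)) {
    difftab <- do.call(rbind, diff_list)
    utils::write.table(difftab, file.path(config$out_dir, "differential_otus.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$n_differential <- sum(difftab$significant)
  }
  log_line("pipeline complete")

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
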