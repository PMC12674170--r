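#' Build an analysis configuration
#'
#' Collects every stage parameter of the end-to-end pipeline with its
#' default. Inputs can be given as in-memory objects (`cohort`, `atlas`),
#' as file paths (`cohort_stem` for [read_cohort()], `atlas_path` for
#' [read_atlas()]), or as simulation parameter sets (`simulate`, a list of
#' `twin_sim_params` whose cohorts are generated and combined).
#'
#' @param ... named overrides of the defaults listed below.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  defaults <- list(
    cohort = NULL, cohort_stem = NULL, simulate = NULL,
    atlas = NULL, atlas_path = NULL,
    stages = c("gscore", "cross_twin", "consensus", "fingerprint",
               "diff_predict", "comparisons"),
    zygosities = c("MZ", "DZ"),
    B = 1000L, perms_per_model = 100L, alpha_screen = 0.05,
    max_components = 100L, inner_folds = 5L,
    consensus_fraction = 0.5, top_k = 5L,
    diff_k = 10L, top_m = 400L, n_perm = 5000L,
    networks = character(0),
    conf = 0.95, alpha = 0.05,
    seed = 1L, output_dir = NULL)
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  structure(utils::modifyList(defaults, over), class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Keys mirror [analysis_config()] arguments; unspecified keys keep their
#' defaults.
#'
#' @param path YAML file path.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(analysis_config, vals)
}

resolve_inputs <- function(config) {
  cohort <- config$cohort
  if (is.null(cohort) && !is.null(config$cohort_stem))
    cohort <- read_cohort(config$cohort_stem)
  if (is.null(cohort) && !is.null(config$simulate)) {
    parts <- lapply(config$simulate, function(p) {
      if (!inherits(p, "twin_sim_params")) p <- do.call(twin_sim_params, p)
      generate_cohort(p)
    })
    cohort <- if (length(parts) == 1L) parts[[1L]]
              else do.call(combine_cohorts, parts)
  }
  if (is.null(cohort))
    stop("config must supply one of: cohort, cohort_stem, simulate")
  atlas <- config$atlas
  if (is.null(atlas) && !is.null(config$atlas_path))
    atlas <- read_atlas(config$atlas_path)
  if (is.null(atlas)) atlas <- scaled_atlas(cohort$n_nodes)
  if (atlas$node_count != cohort$n_nodes)
    stop("atlas node count (", atlas$node_count,
         ") disagrees with cohort (", cohort$n_nodes, ")")
  list(cohort = cohort, atlas = atlas)
}

#' Run the full twin-connectome analysis
#'
#' Executes the enabled stages in dependency order — G-score adjustment and
#' twin statistics, cross-twin LOGOCV prediction per zygosity, consensus
#' edges and node strengths, co-twin fingerprinting (whole-brain and
#' intelligence-related masks), within-pair difference prediction
#' (whole-brain and per network) and correlation comparisons — and
#' collects one report block per stage. Deterministic given the config
#' seed. When `output_dir` is set, the report is written as JSON plus a
#' human-readable summary, and partial results are flushed if a later
#' stage fails.
#'
#' @param config an `analysis_config`.
#' @return list of class `analysis_report`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  stages <- config$stages
  known <- c("gscore", "cross_twin", "consensus", "fingerprint",
             "diff_predict", "comparisons")
  if (length(setdiff(stages, known)))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  if ("consensus" %in% stages && !"cross_twin" %in% stages)
    stop("stage 'consensus' requires stage 'cross_twin' ",
         "(edge selections come from the bootstrap models)")
  inputs <- resolve_inputs(config)
  cohort <- adjust_cohort_gscore(inputs$cohort)
  atlas <- inputs$atlas
  zygos <- intersect(config$zygosities, unique(cohort$roster$zygosity))
  report <- list(provenance = list(
    package_version = as.character(utils::packageVersion("twincpm")),
    seed = config$seed,
    config = config[!vapply(config, is.object, TRUE) &
                      !names(config) %in% c("cohort", "atlas", "simulate")],
    n_subjects = nrow(cohort$roster),
    n_nodes = cohort$n_nodes,
    zygosities = zygos))
  flush <- function() {
    if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  }
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      flush()
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if ("gscore" %in% stages) {
    report$gscore <- run_stage("gscore", function() {
      tc <- lapply(stats::setNames(zygos, zygos), function(zy)
        twin_pair_correlation(cohort, zy))
      de <- lapply(stats::setNames(zygos, zygos), function(zy)
        twin_pair_correlation(cohort, zy, method = "double_entry")$r)
      h2 <- if (all(c("MZ", "DZ") %in% zygos))
        unclass(falconer_h2(tc$MZ$r, tc$DZ$r)) else NULL
      list(twin_correlations = tc, double_entry_r = de, falconer = h2)
    })
  }

  predictions <- NULL
  if ("cross_twin" %in% stages) {
    report$cross_twin <- run_stage("cross_twin", function() {
      predictions <<- lapply(stats::setNames(zygos, zygos), function(zy)
        run_logocv_bootstrap(cohort, zy, B = config$B,
                             perms_per_model = config$perms_per_model,
                             alpha_screen = config$alpha_screen,
                             max_components = config$max_components,
                             inner_folds = config$inner_folds,
                             seed = config$seed))
      lapply(predictions, function(pr)
        list(mean_r = pr$mean_r, p_perm = pr$p_perm,
             iteration_r = pr$iteration_r,
             null_mean = mean(pr$null_draws)))
    })
  }

  masks <- list()
  if ("consensus" %in% stages) {
    report$consensus <- run_stage("consensus", function() {
      out <- lapply(stats::setNames(zygos, zygos), function(zy) {
        cons <- tally_edge_selection(predictions[[zy]])
        keep <- threshold_consensus(cons, config$consensus_fraction)
        masks[[zy]] <<- keep
        strength <- node_strength(keep, cohort$n_nodes)
        list(n_edges = length(keep),
             edges = consensus_edge_table(keep, cons, atlas),
             top_nodes = top_k_nodes(strength, config$top_k, atlas),
             network_tally = network_tally(keep, atlas))
      })
      out
    })
  }

  if ("fingerprint" %in% stages) {
    report$fingerprint <- run_stage("fingerprint", function() {
      lapply(stats::setNames(zygos, zygos), function(zy) {
        whole <- identification_accuracy(cohort, zy)
        block <- list(whole_brain = list(accuracy = whole$accuracy,
                                         n = whole$n_attempted))
        mask <- masks[[zy]]
        if (!is.null(mask) && length(mask) >= 2L) {
          rel <- identification_accuracy(cohort, zy, edge_mask = mask)
          block$intelligence_related <-
            list(accuracy = rel$accuracy, n = rel$n_attempted,
                 n_edges = length(mask))
        }
        block
      })
    })
  }

  diff_results <- NULL
  if ("diff_predict" %in% stages) {
    report$diff_predict <- run_stage("diff_predict", function() {
      diff_results <<- lapply(stats::setNames(zygos, zygos), function(zy) {
        diffs <- pair_differences(cohort, zy)
        whole <- run_kfold_diff_prediction(
          diffs, k = config$diff_k, top_m = config$top_m,
          n_perm = config$n_perm,
          max_components = config$max_components,
          inner_folds = config$inner_folds, seed = config$seed)
        nets <- lapply(stats::setNames(config$networks, config$networks),
                       function(nw)
          network_specific_prediction(
            diffs, atlas, nw, k = config$diff_k, top_m = config$top_m,
            n_perm = config$n_perm,
            max_components = config$max_components,
            inner_folds = config$inner_folds, seed = config$seed))
        list(whole = whole, networks = nets)
      })
      lapply(diff_results, function(dz)
        c(list(whole_brain = list(r = dz$whole$r, p_perm = dz$whole$p_perm)),
          list(networks = lapply(dz$networks, function(nr)
            list(r = nr$r, p_perm = nr$p_perm)))))
    })
  }

  if ("comparisons" %in% stages) {
    report$comparisons <- run_stage("comparisons", function() {
      out <- list()
      if (!is.null(predictions) && all(c("MZ", "DZ") %in% names(predictions))) {
        n_ind <- vapply(c("MZ", "DZ"), function(zy)
          sum(cohort$roster$zygosity == zy), numeric(1))
        out$cross_twin_mz_vs_dz <- unclass(correlation_comparison(
          predictions$MZ$mean_r, n_ind["MZ"],
          predictions$DZ$mean_r, n_ind["DZ"],
          conf = config$conf, alpha = config$alpha))
      }
      if (!is.null(diff_results) &&
          all(c("MZ", "DZ") %in% names(diff_results))) {
        n_pair <- vapply(c("MZ", "DZ"), function(zy)
          sum(cohort$roster$zygosity == zy) / 2, numeric(1))
        out$diff_mz_vs_dz <- unclass(correlation_comparison(
          diff_results$MZ$whole$r, n_pair["MZ"],
          diff_results$DZ$whole$r, n_pair["DZ"],
          conf = config$conf, alpha = config$alpha))
        for (nw in config$networks) {
          out[[paste0("diff_", nw, "_mz_vs_dz")]] <-
            unclass(correlation_comparison(
              diff_results$MZ$networks[[nw]]$r, n_pair["MZ"],
              diff_results$DZ$networks[[nw]]$r, n_pair["DZ"],
              conf = config$conf, alpha = config$alpha))
        }
      }
      out
    })
  }

  class(report) <- "analysis_report"
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  con <- file(file.path(dir, "summary.txt"), "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("twincpm analysis report (package %s, seed %s)",
    report$provenance$package_version, report$provenance$seed)
  if (!is.null(report$gscore)) {
    for (zy in names(report$gscore$twin_correlations)) {
      tc <- report$gscore$twin_correlations[[zy]]
      w("%s twin G correlation: r = %.3f (p = %.3g, %d pairs)",
        zy, tc$r, tc$p, tc$n_pairs)
    }
    if (!is.null(report$gscore$falconer))
      w("Falconer h2 = %.3f", report$gscore$falconer$h2)
  }
  if (!is.null(report$cross_twin))
    for (zy in names(report$cross_twin))
      w("%s cross-twin prediction: mean r = %.3f, p_perm = %.3g",
        zy, report$cross_twin[[zy]]$mean_r, report$cross_twin[[zy]]$p_perm)
  if (!is.null(report$consensus))
    for (zy in names(report$consensus))
      w("%s consensus edges (> fraction threshold): %d",
        zy, report$consensus[[zy]]$n_edges)
  if (!is.null(report$fingerprint))
    for (zy in names(report$fingerprint)) {
      fp <- report$fingerprint[[zy]]
      w("%s identification: whole-brain %.1f%%%s", zy,
        fp$whole_brain$accuracy,
        if (!is.null(fp$intelligence_related))
          sprintf(", intelligence-related %.1f%%",
                  fp$intelligence_related$accuracy) else "")
    }
  if (!is.null(report$diff_predict))
    for (zy in names(report$diff_predict))
      w("%s difference model: r = %.3f, p_perm = %.3g", zy,
        report$diff_predict[[zy]]$whole_brain$r,
        report$diff_predict[[zy]]$whole_brain$p_perm)
  invisible(NULL)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("analysis_report with blocks:",
      paste(setdiff(names(x), "provenance"), collapse = ", "), "\n")
  invisible(x)
}
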