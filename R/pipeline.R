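# End-to-end orchestration: simulate/ingest -> preprocess -> latent models ->
# screening -> consensus -> ROC -> enrichment -> network.

#' Pipeline configuration
#'
#' All stage parameters with defaults matching the reference analysis: 0.02
#' ppm buckets over 0.52-9.30 ppm excluding 4.32-6.10 ppm, minimum-positive/5
#' imputation, geometric-mean normalization + glog, unit-variance scaling,
#' 100-permutation validation, |loading| > 0.2 and VIP > 1 selection,
#' Wilcoxon screening at adjusted p < 0.05 with the consensus gate at
#' p < 0.01, enrichment min_hits 2, and network degree cutoff 2.
#'
#' @param input `"simulate"`, or a path to a feature-table CSV
#' @param design a [cohort_design()] used when `input = "simulate"`
#'   (`NULL` = default design re-seeded from `seed`)
#' @param via_spectra simulate full spectra and re-quantify them instead of
#'   using the concentration table directly
#' @param bin_width,bin_range,exclusions spectral binning scheme
#' @param glog_lambda glog parameter (`NULL` = table minimum positive)
#' @param scaling feature scaling mode
#' @param pca_components,plsda_components,oplsda_orthogonal model sizes
#' @param k_folds cross-validation folds for Q2
#' @param n_perm label permutations for model validation (0 = skip)
#' @param top_k PCA contribution count entering the consensus
#' @param loading_thresh,vip_thresh,consensus_p,screening_alpha selection
#'   thresholds
#' @param panel_size number of prominent markers combined into the ROC panel
#' @param panel_method `"linear"` or `"logistic"` panel score
#' @param min_hits,degree_cutoff enrichment/network filters
#' @param seed master seed; all stage seeds derive from it
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(input = "simulate", design = NULL,
                            via_spectra = FALSE,
                            bin_width = 0.02, bin_range = c(0.52, 9.30),
                            exclusions = list(c(4.32, 6.10)),
                            glog_lambda = NULL,
                            scaling = "unit_variance",
                            pca_components = 2, plsda_components = 2,
                            oplsda_orthogonal = 1, k_folds = 7,
                            n_perm = 100, top_k = 7,
                            loading_thresh = 0.2, vip_thresh = 1,
                            consensus_p = 0.01, screening_alpha = 0.05,
                            panel_size = 3, panel_method = "linear",
                            min_hits = 2, degree_cutoff = 2, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  stop_if_not(requireNamespace("yaml", quietly = TRUE),
              "reading YAML configs requires the 'yaml' package")
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  stop_if_not(length(unknown) == 0L,
              "unknown config key(s): %s", paste(unknown, collapse = ", "))
  if (!is.null(raw$exclusions)) raw$exclusions <- lapply(raw$exclusions, unlist)
  if (!is.null(raw$bin_range)) raw$bin_range <- unlist(raw$bin_range)
  do.call(pipeline_config, raw)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s': %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full biomarker-discovery pipeline
#'
#' Executes all stages in order under a single seed and returns a
#' machine-readable report. Quality gates (PCA R2X > 0.4; PLS/OPLS R2Y and
#' Q2 > 0.5) are recorded as flags, never as errors.
#'
#' @param config a [pipeline_config()]
#' @return an object of class `pipeline_report`
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stop_if_not(inherits(config, "pipeline_config"),
              "config must be a pipeline_config")
  truth <- NULL
  tab <- with_stage("input", {
    if (identical(config$input, "simulate")) {
      design <- config$design
      if (is.null(design)) design <- cohort_design(seed = config$seed)
      cohort <- generate_cohort(design)
      truth <- cohort$truth
      if (isTRUE(config$via_spectra)) {
        spectra <- generate_cohort_spectra(cohort, noise_sd = 0)
        spectra <- lapply(spectra, reference_to_tsp)
        suppressWarnings(integrate_cohort(spectra))
      } else {
        cohort$table
      }
    } else {
      read_feature_table(config$input)
    }
  })
  processed <- with_stage("preprocess", {
    glog <- glog_transform(normalize_geometric_mean(impute_missing(tab)),
                           config$glog_lambda)
    list(glog = glog, scaled = autoscale(glog, config$scaling))
  })
  X <- processed$scaled$values
  y <- tab$group
  models <- with_stage("models", {
    pca <- fit_pca(X, n_components = config$pca_components, center = TRUE)
    plsda <- fit_plsda(X, y, n_components = config$plsda_components)
    oplsda <- fit_oplsda(X, y, n_orthogonal = config$oplsda_orthogonal)
    q2_plsda <- as.numeric(cross_validate_q2(
      X, y, model_spec("plsda", n_components = config$plsda_components),
      config$k_folds, seed = config$seed))
    q2_oplsda <- as.numeric(cross_validate_q2(
      X, y, model_spec("oplsda", n_orthogonal = config$oplsda_orthogonal),
      config$k_folds, seed = config$seed))
    list(pca = pca, plsda = plsda, oplsda = oplsda,
         q2_plsda = q2_plsda, q2_oplsda = q2_oplsda)
  })
  permutation <- if (config$n_perm > 0) with_stage("permutation", {
    list(
      plsda = permutation_test(
        X, y, model_spec("plsda", n_components = config$plsda_components),
        n_perm = config$n_perm, k_folds = config$k_folds,
        seed = config$seed + 1L),
      oplsda = permutation_test(
        X, y, model_spec("oplsda", n_orthogonal = config$oplsda_orthogonal),
        n_perm = config$n_perm, k_folds = config$k_folds,
        seed = config$seed + 2L)
    )
  }) else NULL
  screening <- with_stage("screening", {
    t_glog <- processed$glog
    screen_wilcoxon(t_glog, alpha = config$screening_alpha)
  })
  consensus <- with_stage("consensus", {
    select_consensus(
      model_selections = list(
        pca = model_feature_set(models$pca, top_k = config$top_k),
        plsda = model_feature_set(models$plsda,
                                  loading_thresh = config$loading_thresh),
        oplsda = model_feature_set(models$oplsda,
                                   loading_thresh = config$loading_thresh)),
      wilcoxon_results = screening,
      vip_values = vip(models$oplsda),
      universe = colnames(X),
      p_thresh = config$consensus_p,
      vip_thresh = config$vip_thresh)
  })
  roc <- with_stage("roc", {
    t_glog <- processed$glog
    single <- lapply(consensus$prominent, function(m) {
      roc_curve(t_glog$values[, m], y)
    })
    names(single) <- consensus$prominent
    panel <- NULL
    if (length(consensus$prominent) >= 2L) {
      v <- vip(models$oplsda)[consensus$prominent]
      markers <- names(sort(v, decreasing = TRUE))
      markers <- markers[seq_len(min(config$panel_size, length(markers)))]
      panel <- fit_panel(t_glog, markers, method = config$panel_method)
    }
    list(single = single, panel = panel)
  })
  enrichment <- with_stage("enrichment", {
    if (length(consensus$prominent) >= 1L) {
      kegg <- try(enrich_hypergeometric(consensus$prominent,
                                        load_pathway_library("kegg"),
                                        min_hits = config$min_hits),
                  silent = TRUE)
      smpdb <- try(enrich_hypergeometric(consensus$prominent,
                                         load_pathway_library("smpdb"),
                                         min_hits = config$min_hits),
                   silent = TRUE)
      list(kegg = if (inherits(kegg, "try-error")) NULL else kegg,
           smpdb = if (inherits(smpdb, "try-error")) NULL else smpdb)
    } else NULL
  })
  network <- with_stage("network", {
    filter_network_by_degree(load_interaction_network(),
                             cutoff = config$degree_cutoff,
                             protect = consensus$prominent)
  })
  gates <- list(
    pca_r2x_gt_0.4 = sum(models$pca$r2x) > 0.4,
    plsda_r2y_gt_0.5 = models$plsda$r2y > 0.5,
    plsda_q2_gt_0.5 = models$q2_plsda > 0.5,
    oplsda_r2y_gt_0.5 = models$oplsda$r2y > 0.5,
    oplsda_q2_gt_0.5 = models$q2_oplsda > 0.5
  )
  structure(
    list(config = config, table = tab, truth = truth, processed = processed,
         models = models, permutation = permutation, screening = screening,
         consensus = consensus, roc = roc, enrichment = enrichment,
         network = network, quality_gates = gates,
         provenance = list(package = "nmrbiomark",
                           version = as.character(utils::packageVersion("nmrbiomark")),
                           seed = config$seed)),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("nmrbiomark pipeline report\n")
  cat(sprintf("  cohort: %d samples x %d features (seed %d)\n",
              nrow(x$table$values), ncol(x$table$values), x$config$seed))
  cat(sprintf("  PCA R2X = %.3f | PLS-DA R2Y = %.3f, Q2 = %.3f | OPLS-DA R2Y = %.3f, Q2 = %.3f\n",
              sum(x$models$pca$r2x), x$models$plsda$r2y, x$models$q2_plsda,
              x$models$oplsda$r2y, x$models$q2_oplsda))
  if (!is.null(x$permutation))
    cat(sprintf("  permutation p (Q2): PLS-DA %.4f, OPLS-DA %.4f\n",
                x$permutation$plsda$p_q2, x$permutation$oplsda$p_q2))
  cat(sprintf("  prominent metabolites: %s\n",
              paste(x$consensus$prominent, collapse = ", ")))
  if (!is.null(x$roc$panel))
    cat(sprintf("  panel (%s): AUC = %.3f, sens = %.0f%%, spec = %.0f%%\n",
                paste(x$roc$panel$markers, collapse = " + "),
                x$roc$panel$roc$auc, 100 * x$roc$panel$roc$sens_at_youden,
                100 * x$roc$panel$roc$spec_at_youden))
  failed <- names(x$quality_gates)[!unlist(x$quality_gates)]
  if (length(failed) > 0L)
    cat("  quality gates not met:", paste(failed, collapse = ", "), "\n")
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Writes the input and processed tables (CSV), screening results (CSV),
#' enrichment tables (CSV) and a JSON summary of models, consensus, ROC and
#' provenance.
#'
#' @param report a `pipeline_report`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_pipeline_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(report$table, file.path(dir, "input_table.csv"))
  write_feature_table(report$processed$scaled,
                      file.path(dir, "processed_table.csv"))
  utils::write.csv(report$screening, file.path(dir, "univariate.csv"),
                   row.names = FALSE)
  if (!is.null(report$enrichment$kegg))
    utils::write.csv(report$enrichment$kegg,
                     file.path(dir, "enrichment_kegg.csv"), row.names = FALSE)
  if (!is.null(report$enrichment$smpdb))
    utils::write.csv(report$enrichment$smpdb,
                     file.path(dir, "enrichment_smpdb.csv"), row.names = FALSE)
  summary <- list(
    provenance = report$provenance,
    quality_gates = report$quality_gates,
    models = list(
      pca = list(r2x = report$models$pca$r2x),
      plsda = list(r2y = report$models$plsda$r2y, q2 = report$models$q2_plsda),
      oplsda = list(r2y = report$models$oplsda$r2y,
                    q2 = report$models$q2_oplsda,
                    vip = as.list(vip(report$models$oplsda)))
    ),
    permutation = if (!is.null(report$permutation)) list(
      plsda = list(p_r2y = report$permutation$plsda$p_r2y,
                   p_q2 = report$permutation$plsda$p_q2),
      oplsda = list(p_r2y = report$permutation$oplsda$p_r2y,
                    p_q2 = report$permutation$oplsda$p_q2)
    ),
    consensus = list(
      per_model = report$consensus$per_model_sets,
      two_model = report$consensus$two_model_set,
      wilcoxon = report$consensus$wilcoxon_set,
      vip = report$consensus$vip_set,
      prominent = report$consensus$prominent
    ),
    roc = list(
      single = lapply(report$roc$single, function(r) {
        list(auc = r$auc, sensitivity = r$sens_at_youden,
             specificity = r$spec_at_youden)
      }),
      panel = if (!is.null(report$roc$panel)) list(
        markers = report$roc$panel$markers,
        auc = report$roc$panel$roc$auc,
        sensitivity = report$roc$panel$roc$sens_at_youden,
        specificity = report$roc$panel$roc$spec_at_youden
      )
    )
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
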