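# Consensus ("prominent metabolite") selection across models, Wilcoxon
# screening and VIP.

#' Consensus biomarker selection
#'
#' Combines three criteria: (i) the feature is recommended by at least two of
#' the latent-variable models (PCA top-k contribution; PLS-DA and OPLS-DA by
#' absolute normalized loading), (ii) Bonferroni-adjusted Wilcoxon p below
#' `p_thresh`, and (iii) OPLS-DA VIP above `vip_thresh`. The prominent set is
#' the intersection of the three criterion sets.
#'
#' @param model_selections named list of character vectors: the feature set
#'   each model recommends (use [model_feature_set()] on fitted models)
#' @param wilcoxon_results data.frame from [screen_wilcoxon()] (or any with
#'   `feature` and `p_adj` columns)
#' @param vip_values named numeric vector of VIP values
#' @param universe the feature universe; defaults to the union of the inputs'
#'   features
#' @param p_thresh Wilcoxon adjusted-p threshold (default 0.01)
#' @param vip_thresh VIP threshold (default 1)
#' @return an object of class `consensus_result` with per-model sets, the
#'   two-model set, Wilcoxon and VIP sets, the prominent set, and Venn counts
#' @export
select_consensus <- function(model_selections, wilcoxon_results, vip_values,
                             universe = NULL, p_thresh = 0.01, vip_thresh = 1) {
  stop_if_not(is.list(model_selections) && length(model_selections) >= 2L,
              "model_selections must list at least two model feature sets")
  wil_features <- wilcoxon_results$feature
  if (is.null(universe))
    universe <- unique(c(unlist(model_selections), wil_features,
                         names(vip_values)))
  for (nm in names(model_selections)) {
    unknown <- setdiff(model_selections[[nm]], universe)
    stop_if_not(length(unknown) == 0L, "unknown feature(s) in %s selection: %s",
                nm, paste(unknown, collapse = ", "))
  }
  stop_if_not(all(wil_features %in% universe),
              "unknown feature(s) in Wilcoxon results")
  stop_if_not(all(names(vip_values) %in% universe),
              "unknown feature(s) in VIP values")
  counts <- table(unlist(lapply(model_selections, unique)))
  two_model <- universe[universe %in% names(counts)[counts >= 2L]]
  wilcoxon_set <- wil_features[wilcoxon_results$p_adj < p_thresh]
  vip_set <- names(vip_values)[vip_values > vip_thresh]
  prominent <- intersect(intersect(two_model, wilcoxon_set), vip_set)
  structure(
    list(per_model_sets = model_selections,
         two_model_set = two_model,
         wilcoxon_set = wilcoxon_set,
         vip_set = vip_set,
         prominent = prominent,
         universe = universe,
         params = list(p_thresh = p_thresh, vip_thresh = vip_thresh),
         venn_models = venn_counts(model_selections),
         venn_criteria = venn_counts(list(two_model = two_model,
                                          wilcoxon = wilcoxon_set,
                                          vip = vip_set))),
    class = "consensus_result"
  )
}

# Region counts of the Venn diagram over up to three sets.
venn_counts <- function(sets) {
  members <- unique(unlist(sets))
  pattern <- vapply(members, function(m) {
    paste(ifelse(vapply(sets, function(s) m %in% s, TRUE), "1", "0"),
          collapse = "")
  }, "")
  as.list(table(pattern))
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus biomarker selection\n")
  for (nm in names(x$per_model_sets))
    cat(sprintf("  %-8s: %d features\n", nm, length(x$per_model_sets[[nm]])))
  cat(sprintf("  >=2 models          : %d\n", length(x$two_model_set)))
  cat(sprintf("  Wilcoxon p_adj < %-4s: %d\n", format(x$params$p_thresh),
              length(x$wilcoxon_set)))
  cat(sprintf("  VIP > %-13s: %d\n", format(x$params$vip_thresh),
              length(x$vip_set)))
  cat(sprintf("  prominent           : %s\n",
              paste(x$prominent, collapse = ", ")))
  invisible(x)
}
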