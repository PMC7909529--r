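# Univariate screening: Wilcoxon rank-sum with Bonferroni adjustment,
# Pearson correlation matrices, and one-way subgroup ANOVA.

#' Two-sample Wilcoxon rank-sum test
#'
#' Thin wrapper around [stats::wilcox.test()] exposing the screening
#' pipeline's policy: exact p by enumeration when both samples are small
#' (`min(n, m) <= exact_cutoff`) and tie-free, otherwise the normal
#' approximation with tie and continuity correction. The reported statistic
#' is the rank-sum W of the first sample (midranks for ties).
#'
#' @param a,b numeric samples (both non-empty)
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`
#' @param exact_cutoff small-sample cutoff for the exact test in auto mode
#' @return list with `statistic` (rank-sum of `a`), `p_value`, `method`
#' @export
wilcoxon_rank_sum <- function(a, b, mode = c("auto", "exact", "normal_approx"),
                              exact_cutoff = 12) {
  mode <- match.arg(mode)
  stop_if_not(length(a) > 0 && length(b) > 0, "both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- switch(mode,
                  exact = TRUE,
                  normal_approx = FALSE,
                  auto = min(length(a), length(b)) <= exact_cutoff && !ties)
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  ranks <- rank(c(a, b))
  list(statistic = sum(ranks[seq_along(a)]),
       p_value = ht$p.value,
       method = if (exact && !ties) "exact" else "normal approximation")
}

#' Bonferroni adjustment
#'
#' `p -> min(1, m * p)` with `m = length(p)`.
#'
#' @param p vector of p-values in `[0, 1]`
#' @return adjusted p-values
#' @export
adjust_bonferroni <- function(p) {
  stop_if_not(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "bonferroni")
}

#' Wilcoxon screening of all features
#'
#' Tests every feature for a case-vs-control location difference
#' (two-sided), adjusts with Bonferroni across features, and labels the
#' direction by the sign of the case-minus-control median difference.
#'
#' @param t a [feature_table()]
#' @param mode test mode, see [wilcoxon_rank_sum()]
#' @param alpha significance level on the adjusted p
#' @return data.frame with columns `feature`, `statistic`, `p_raw`, `p_adj`,
#'   `direction`, `significant`
#' @export
screen_wilcoxon <- function(t, mode = "auto", alpha = 0.05) {
  stop_if_not(inherits(t, "feature_table"), "t must be a feature_table")
  x <- t$values
  is_case <- t$group == levels(t$group)[2L]
  res <- lapply(seq_len(ncol(x)), function(j) {
    w <- wilcoxon_rank_sum(x[is_case, j], x[!is_case, j], mode = mode)
    delta <- stats::median(x[is_case, j]) - stats::median(x[!is_case, j])
    data.frame(feature = colnames(x)[j], statistic = w$statistic,
               p_raw = w$p_value,
               direction = if (delta >= 0) "up" else "down",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- adjust_bonferroni(out$p_raw)
  out$significant <- out$p_adj < alpha
  out[, c("feature", "statistic", "p_raw", "p_adj", "direction", "significant")]
}

#' Pearson correlation matrix with p-values
#'
#' Pairwise Pearson r between the selected features with p-values from the
#' t-distribution transform `t = r sqrt((n - 2) / (1 - r^2))`. Constant
#' features are flagged and their pairs set to `NA`.
#'
#' @param t a [feature_table()] or numeric matrix (>= 3 samples)
#' @param features feature subset (default: all)
#' @return list with matrices `r` and `p` and a character vector
#'   `constant_features`
#' @export
pearson_correlation_matrix <- function(t, features = NULL) {
  x <- ft_values(t)
  if (!is.null(features)) {
    missing <- setdiff(features, colnames(x))
    stop_if_not(length(missing) == 0L,
                "unknown feature(s): %s", paste(missing, collapse = ", "))
    x <- x[, features, drop = FALSE]
  }
  n <- nrow(x)
  stop_if_not(n >= 3L, "need at least 3 samples")
  sds <- apply(x, 2L, stats::sd)
  constant <- colnames(x)[sds == 0]
  r <- suppressWarnings(stats::cor(x))
  r[constant, ] <- NA; r[, constant] <- NA
  diag(r) <- ifelse(colnames(x) %in% constant, NA, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- NA
  list(r = r, p = p, constant_features = constant)
}

#' One-way ANOVA across subgroup levels
#'
#' Classical (equal-variance) one-way ANOVA F-test per feature across the
#' levels of a subgroup annotation, with Bonferroni adjustment across
#' features. Samples with missing subgroup labels are dropped.
#'
#' @param t a [feature_table()] with subgroup annotations
#' @param subgroup name of the subgroup column
#' @param features feature subset (default: all)
#' @return data.frame with columns `feature`, `statistic` (F), `p_raw`,
#'   `p_adj`
#' @export
anova_subgroups <- function(t, subgroup, features = NULL) {
  stop_if_not(inherits(t, "feature_table"), "t must be a feature_table")
  stop_if_not(!is.null(t$subgroups) && subgroup %in% names(t$subgroups),
              "unknown subgroup annotation '%s'", subgroup)
  g <- t$subgroups[[subgroup]]
  keep <- !is.na(g)
  g <- droplevels(as.factor(g[keep]))
  stop_if_not(nlevels(g) >= 2L, "need at least 2 subgroup levels")
  stop_if_not(all(tabulate(g) >= 2L), "every subgroup level needs >= 2 members")
  x <- t$values[keep, , drop = FALSE]
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  res <- lapply(seq_len(ncol(x)), function(j) {
    ft <- stats::oneway.test(x[, j] ~ g, var.equal = TRUE)
    data.frame(feature = colnames(x)[j],
               statistic = unname(ft$statistic),
               p_raw = ft$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- adjust_bonferroni(out$p_raw)
  out
}
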