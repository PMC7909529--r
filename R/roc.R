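# ROC analysis of single markers and marker panels, and a paired
# sensitivity comparison.

#' Receiver operating characteristic curve
#'
#' Sweeps thresholds over the unique score values (a sample is called case
#' when its score is >= the threshold; higher scores are treated as more
#' case-like, with no automatic flipping). AUC is the trapezoidal area under
#' the (1 - specificity, sensitivity) curve, which credits tied scores with
#' 1/2 and therefore equals the Mann-Whitney concordance U / (n1 n2). The
#' operating point maximizes the Youden index (sens + spec - 1), ties going
#' to the lowest threshold.
#'
#' @param scores numeric marker scores
#' @param labels binary class labels (second factor level / "case" = positive)
#' @return an object of class `roc_result` with `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `youden_threshold`, `sens_at_youden`,
#'   `spec_at_youden`
#' @export
roc_curve <- function(scores, labels) {
  f <- droplevels(as.factor(labels))
  stop_if_not(nlevels(f) == 2L, "labels must contain both classes")
  is_case <- f == levels(f)[2L]
  n1 <- sum(is_case); n0 <- sum(!is_case)
  thr <- c(sort(unique(scores)), Inf)
  sens <- vapply(thr, function(t) mean(scores[is_case] >= t), 0)
  spec <- vapply(thr, function(t) mean(scores[!is_case] < t), 0)
  # trapezoid over the curve from (FPR, TPR) = (1, 1) down to (0, 0)
  fpr <- c(1, 1 - spec)
  tpr <- c(1, sens)
  auc <- -trapz(fpr, tpr)   # fpr is decreasing along the sweep
  youden <- sens + spec - 1
  best <- which.max(youden)   # which.max takes the first (lowest threshold)
  structure(
    list(thresholds = thr, sensitivity = sens, specificity = spec,
         auc = auc, youden_threshold = thr[best],
         sens_at_youden = sens[best], spec_at_youden = spec[best],
         n_case = n1, n_control = n0),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (%d cases vs %d controls)\n",
              x$auc, x$n_case, x$n_control))
  cat(sprintf("  Youden threshold %.4g: sensitivity = %.0f%%, specificity = %.0f%%\n",
              x$youden_threshold, 100 * x$sens_at_youden,
              100 * x$spec_at_youden))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(1 - x$specificity, x$sensitivity, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("AUC = %.3f", x$auc), xlim = c(0, 1),
                 ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Fit a marker panel classifier
#'
#' Combines markers into a single panel score: `method = "linear"` is least
#' squares of the 0/1 label on the marker values, `"logistic"` is binomial
#' maximum likelihood (IRLS via [stats::glm()], up to 100 iterations); in
#' both cases the per-sample score is the linear predictor and the ROC is
#' computed by resubstitution on the training samples. Complete separation
#' under the logistic fit is detected and flagged, not fatal.
#'
#' @param t a [feature_table()]
#' @param markers feature names to combine
#' @param method `"linear"` or `"logistic"`
#' @return an object of class `panel_model` with `coefficients`, `score`,
#'   `roc`, and flags
#' @export
fit_panel <- function(t, markers, method = c("linear", "logistic")) {
  method <- match.arg(method)
  stop_if_not(inherits(t, "feature_table"), "t must be a feature_table")
  missing <- setdiff(markers, colnames(t$values))
  stop_if_not(length(missing) == 0L,
              "unknown marker(s): %s", paste(missing, collapse = ", "))
  X <- t$values[, markers, drop = FALSE]
  Xd <- cbind("(Intercept)" = 1, X)
  qr_x <- qr(Xd)
  if (qr_x$rank < ncol(Xd)) {
    dropped <- colnames(Xd)[qr_x$pivot[(qr_x$rank + 1L):ncol(Xd)]]
    stop(sprintf("collinear markers: %s linearly dependent on the rest",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  y01 <- as.numeric(t$group == levels(t$group)[2L])
  separation <- FALSE
  nonconv <- FALSE
  if (method == "linear") {
    fit <- stats::lm.fit(Xd, y01)
    coefs <- fit$coefficients
    score <- as.numeric(Xd %*% coefs)
  } else {
    fit <- withCallingHandlers(
      stats::glm.fit(Xd, y01, family = stats::binomial(),
                     control = stats::glm.control(maxit = 100, epsilon = 1e-8)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          separation <<- TRUE
        invokeRestart("muffleWarning")
      })
    nonconv <- !fit$converged
    coefs <- fit$coefficients
    score <- as.numeric(Xd %*% coefs)   # linear predictor
  }
  structure(
    list(markers = markers, method = method, coefficients = coefs,
         score = score, labels = t$group,
         roc = roc_curve(score, t$group),
         separation = separation, non_convergence = nonconv),
    class = "panel_model"
  )
}

#' @export
print.panel_model <- function(x, ...) {
  cat(sprintf("%s marker panel (%s): AUC = %.3f\n",
              paste(x$markers, collapse = " + "), x$method, x$roc$auc))
  if (x$separation) cat("  note: complete separation detected\n")
  if (x$non_convergence) cat("  note: IRLS did not converge\n")
  invisible(x)
}

#' @export
predict.panel_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_table")) newdata$values else as.matrix(newdata)
  Xd <- cbind(1, X[, object$markers, drop = FALSE])
  as.numeric(Xd %*% object$coefficients)
}

#' Compare the sensitivity of two panels
#'
#' Classifies the case samples with each panel at its own Youden threshold
#' and applies the exact McNemar (paired binomial) test to the discordant
#' classifications: `p = 2 P(X <= min(b, c) | Bin(b + c, 1/2))`, capped at 1.
#' With no discordant cases the test is undefined and p = 1 is returned with
#' a flag.
#'
#' @param panel_a,panel_b `panel_model`s fitted on the same samples
#' @return list with `p_value`, discordant counts `b` (only A correct) and
#'   `c` (only B correct), and `no_discordant` flag
#' @export
compare_sensitivity <- function(panel_a, panel_b) {
  stop_if_not(length(panel_a$score) == length(panel_b$score),
              "panels must be scored on the same samples")
  stop_if_not(identical(as.character(panel_a$labels),
                        as.character(panel_b$labels)),
              "panels must share the same sample labels")
  is_case <- panel_a$labels == levels(panel_a$labels)[2L]
  correct_a <- panel_a$score[is_case] >= panel_a$roc$youden_threshold
  correct_b <- panel_b$score[is_case] >= panel_b$roc$youden_threshold
  b <- sum(correct_a & !correct_b)
  cc <- sum(!correct_a & correct_b)
  if (b + cc == 0L)
    return(list(p_value = 1, b = b, c = cc, no_discordant = TRUE))
  p <- stats::binom.test(b, b + cc, p = 0.5)$p.value
  list(p_value = p, b = b, c = cc, no_discordant = FALSE)
}
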