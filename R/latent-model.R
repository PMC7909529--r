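# Shared infrastructure for the NIPALS latent-variable models.

# Binary class encoding: centered 0/1 dummy. All reported quantities (R2Y,
# Q2, VIP, unit-normalized loadings, scores up to scale) are invariant to the
# affine coding choice.
encode_y <- function(y) {
  f <- as.factor(y)
  f <- droplevels(f)
  stop_if_not(nlevels(f) == 2L, "y must contain exactly two classes")
  y01 <- as.numeric(f) - 1
  list(yc = y01 - mean(y01), y01 = y01, mean01 = mean(y01), levels = levels(f))
}

prepare_x <- function(X, center = TRUE, scale = FALSE) {
  X <- as.matrix(X)
  stop_if_not(is.numeric(X), "X must be numeric")
  stop_if_not(nrow(X) >= 2L, "need at least 2 samples")
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  ctr <- if (center) colMeans(X) else rep(0, ncol(X))
  scl <- if (scale) {
    s <- apply(X, 2L, stats::sd)
    ifelse(s > 0, s, 1)
  } else rep(1, ncol(X))
  list(Xs = sweep(sweep(X, 2L, ctr), 2L, scl, "/"), center = ctr, scale = scl)
}

# Flip a weight/loading vector so its largest-magnitude entry is positive;
# returns +1 or -1.
sign_fix <- function(v) {
  s <- sign(v[which.max(abs(v))])
  if (s == 0) 1 else s
}

apply_x_transform <- function(m, newdata) {
  X <- as.matrix(newdata)
  stop_if_not(ncol(X) == length(m$x_center),
              "newdata has %d features, model expects %d",
              ncol(X), length(m$x_center))
  sweep(sweep(X, 2L, m$x_center), 2L, m$x_scale, "/")
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt(p * sum_a[SSY_a (w_ja/||w_a||)^2] / sum_a SSY_a)` over the
#' predictive components, where `SSY_a = q_a^2 t_a' t_a` and `p` is the
#' number of features; the mean squared VIP is always 1.
#'
#' @param m a fitted PLS-DA or OPLS-DA model
#' @param ... unused
#' @return named numeric vector of VIP values
#' @export
vip <- function(m, ...) UseMethod("vip")

#' @export
vip.default <- function(m, ...) {
  stop("VIP is defined for PLS-DA and OPLS-DA models only", call. = FALSE)
}

vip_from_parts <- function(W, SSY, feature_names) {
  p <- nrow(W)
  wn <- sweep(W, 2L, sqrt(colSums(W^2)), "/")
  v <- sqrt(p * as.numeric(wn^2 %*% SSY) / sum(SSY))
  names(v) <- feature_names
  v
}

#' @export
vip.nmr_plsda <- function(m, ...) vip_from_parts(m$weights, m$ssy, m$features)

#' @export
vip.nmr_oplsda <- function(m, ...) {
  vip_from_parts(m$weights, m$ssy, m$features)
}

#' @export
vip.nmr_pca <- function(m, ...) {
  stop("VIP is defined for PLS-DA and OPLS-DA models only", call. = FALSE)
}

#' @export
coef.nmr_plsda <- function(object, ...) object$loadings

#' @export
coef.nmr_oplsda <- function(object, ...) object$loadings

#' @export
coef.nmr_pca <- function(object, ...) object$loadings

#' Score plot of a latent-variable model
#'
#' Plots the first two score dimensions (for OPLS-DA: predictive vs first
#' orthogonal), colored by class where available.
#'
#' @param x a fitted latent model
#' @param ... forwarded to [graphics::plot()]
#' @export
plot.latent_model <- function(x, ...) {
  sc <- x$scores
  if (!is.null(x$scores_orth) && ncol(x$scores) == 1L)
    sc <- cbind(x$scores, x$scores_orth[, 1L, drop = FALSE])
  if (ncol(sc) == 1L) sc <- cbind(sc, 0)
  col <- if (!is.null(x$y_levels)) as.integer(factor(x$y_class)) + 1L else 1L
  graphics::plot(sc[, 1L], sc[, 2L], col = col, pch = 19,
                 xlab = "component 1", ylab = "component 2",
                 main = toupper(x$kind), ...)
  invisible(x)
}

#' @export
print.latent_model <- function(x, ...) {
  cat(sprintf("%s model: %d samples x %d features\n",
              toupper(x$kind), nrow(x$scores), length(x$features)))
  if (!is.null(x$r2x)) cat(sprintf("  cumulative R2X = %.3f\n", sum(x$r2x)))
  if (!is.null(x$r2y)) cat(sprintf("  R2Y = %.3f\n", x$r2y))
  invisible(x)
}

#' @export
summary.latent_model <- function(object, ...) {
  print(object)
  if (!is.null(object$r2x)) {
    cat("  R2X per component:",
        paste(sprintf("%.3f", object$r2x), collapse = ", "), "\n")
  }
  if (!is.null(object$ssy)) {
    v <- vip(object)
    cat("  top VIP:", paste(sprintf("%s=%.2f", names(sort(v, decreasing = TRUE))[1:5],
                                    sort(v, decreasing = TRUE)[1:5]),
                            collapse = ", "), "\n")
  }
  invisible(object)
}

#' Per-model feature selection
#'
#' Extracts the feature set a fitted model recommends: the top `top_k`
#' features by first-component contribution for PCA, or the features whose
#' unit-normalized first predictive-component loading exceeds
#' `loading_thresh` in absolute value for PLS-DA/OPLS-DA.
#'
#' @param m a fitted latent model
#' @param top_k PCA contribution cut (count)
#' @param loading_thresh absolute normalized-loading threshold
#' @return character vector of feature names
#' @export
model_feature_set <- function(m, top_k = 7, loading_thresh = 0.2) {
  if (inherits(m, "nmr_pca")) {
    pca_contributions(m, component = 1L, top_k = top_k)$feature
  } else {
    p1 <- m$loadings[, 1L]
    p1 <- p1 / sqrt(sum(p1^2))
    m$features[abs(p1) > loading_thresh]
  }
}
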