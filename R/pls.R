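# Two-class PLS-DA by NIPALS.

#' Fit a two-class PLS-DA model (NIPALS)
#'
#' The class label is encoded as a centered 0/1 column. Per component:
#' `w = X'y / ||X'y||`, `t = Xw`, `p = X't / t't`, `q = y't / t't`, then X
#' and y are deflated by the component. `R2Y = 1 - ||y - yhat||^2 / ||y||^2`
#' on the centered label; `R2X` per component is the fraction of the initial
#' X sum of squares carried by `t p'`. Weight signs follow the
#' largest-magnitude-entry-positive convention.
#'
#' @param X numeric matrix, samples in rows
#' @param y binary class labels (factor/character/0-1); first level = control
#' @param n_components number of latent components
#' @param center,scale column transform applied to X before fitting
#' @return an object of classes `nmr_plsda`, `latent_model`
#' @export
fit_plsda <- function(X, y, n_components = 2, center = TRUE, scale = FALSE) {
  prep <- prepare_x(X, center, scale)
  Xc <- prep$Xs
  enc <- encode_y(y)
  stop_if_not(length(enc$yc) == nrow(Xc), "length(y) must equal nrow(X)")
  n <- nrow(Xc); p <- ncol(Xc)
  A <- n_components
  stop_if_not(A >= 1L, "n_components must be >= 1")
  ssx0 <- sum(Xc^2)
  ssy0 <- sum(enc$yc^2)
  E <- Xc; f <- enc$yc
  W <- matrix(0, p, A); P <- matrix(0, p, A); Tm <- matrix(0, n, A)
  q <- numeric(A); r2x <- numeric(A); ssy <- numeric(A)
  for (a in seq_len(A)) {
    w <- as.numeric(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * sqrt(ssx0) * max(abs(f), 1e-300))
      stop("n_components exceeds the predictive rank of (X, y)", call. = FALSE)
    w <- w / nw
    t <- as.numeric(E %*% w)
    tt <- sum(t^2)
    if (tt < 1e-14 * ssx0)
      stop("n_components exceeds the rank of X", call. = FALSE)
    pv <- as.numeric(crossprod(E, t)) / tt
    qa <- sum(f * t) / tt
    s <- sign_fix(w)
    w <- s * w; t <- s * t; pv <- s * pv; qa <- s * qa
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- t; q[a] <- qa
    r2x[a] <- tt * sum(pv^2) / ssx0
    ssy[a] <- qa^2 * tt
    E <- E - tcrossprod(t, pv)
    f <- f - t * qa
  }
  yhat <- as.numeric(Tm %*% q)
  r2y <- 1 - sum((enc$yc - yhat)^2) / ssy0
  dimnames(W) <- dimnames(P) <- list(colnames(Xc), sprintf("comp%d", seq_len(A)))
  dimnames(Tm) <- list(rownames(Xc), sprintf("comp%d", seq_len(A)))
  structure(
    list(kind = "plsda", n_components = A,
         scores = Tm, loadings = P, weights = W, y_loadings = q,
         r2x = r2x, r2y = r2y, ssy = ssy, fitted_yc = yhat,
         features = colnames(Xc),
         y_levels = enc$levels, y_class = as.character(y),
         y_mean01 = enc$mean01, y01 = enc$y01,
         x_center = prep$center, x_scale = prep$scale),
    class = c("nmr_plsda", "latent_model")
  )
}

#' @export
print.nmr_plsda <- function(x, ...) {
  cat(sprintf("PLS-DA model: %d components, %d samples x %d features\n",
              x$n_components, nrow(x$scores), length(x$features)))
  cat(sprintf("  R2X = %.3f (cumulative), R2Y = %.3f\n", sum(x$r2x), x$r2y))
  invisible(x)
}

#' @export
predict.nmr_plsda <- function(object, newdata, ...) {
  E <- apply_x_transform(object, newdata)
  A <- object$n_components
  Tm <- matrix(0, nrow(E), A)
  for (a in seq_len(A)) {
    Tm[, a] <- E %*% object$weights[, a]
    E <- E - tcrossprod(Tm[, a], object$loadings[, a])
  }
  y_score <- as.numeric(Tm %*% object$y_loadings) + object$y_mean01
  list(scores = Tm, y_score = y_score,
       class = object$y_levels[(y_score > 0.5) + 1L])
}

#' @export
fitted.nmr_plsda <- function(object, ...) object$fitted_yc + object$y_mean01

#' @export
residuals.nmr_plsda <- function(object, ...) {
  object$y01 - fitted(object)
}
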