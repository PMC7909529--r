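# OPLS-DA: orthogonal signal correction (Trygg-Wold) followed by one
# predictive PLS component.

#' Fit a two-class OPLS-DA model
#'
#' Splits X-variation into components orthogonal to the class response and a
#' single predictive component. With `w = X'y / ||X'y||`, each orthogonal
#' round computes `t = Xw`, `p = X't/t't`, `w_orth = p - (w'p)w` normalized,
#' `t_orth = X w_orth`, `p_orth = X't_orth / t_orth't_orth` and deflates
#' `X <- X - t_orth p_orth'`. The predictive component is one NIPALS PLS
#' component on the filtered X; its score is orthogonal to every `t_orth` by
#' construction. R2Y and VIP use the predictive component only.
#'
#' @param X numeric matrix, samples in rows
#' @param y binary class labels
#' @param n_orthogonal number of orthogonal components (default 1)
#' @param center,scale column transform applied to X before fitting
#' @return an object of classes `nmr_oplsda`, `latent_model` with predictive
#'   `scores`/`loadings`/`weights` and orthogonal `scores_orth`,
#'   `loadings_orth`, `weights_orth`
#' @export
fit_oplsda <- function(X, y, n_orthogonal = 1, center = TRUE, scale = FALSE) {
  prep <- prepare_x(X, center, scale)
  Xc <- prep$Xs
  enc <- encode_y(y)
  stop_if_not(length(enc$yc) == nrow(Xc), "length(y) must equal nrow(X)")
  n <- nrow(Xc); p <- ncol(Xc)
  H <- n_orthogonal
  stop_if_not(H >= 0L, "n_orthogonal must be >= 0")
  stop_if_not(H < min(n - 1L, p), "n_orthogonal must be below the rank of X")
  ssx0 <- sum(Xc^2)
  ssy0 <- sum(enc$yc^2)
  w <- as.numeric(crossprod(Xc, enc$yc))
  nw <- sqrt(sum(w^2))
  stop_if_not(nw > 0, "X carries no covariance with the class label")
  w <- w / nw
  E <- Xc
  W_o <- matrix(0, p, max(H, 1L)); P_o <- matrix(0, p, max(H, 1L))
  T_o <- matrix(0, n, max(H, 1L)); r2x_orth <- numeric(H)
  for (h in seq_len(H)) {
    t <- as.numeric(E %*% w)
    tt <- sum(t^2)
    stop_if_not(tt > 1e-14 * ssx0, "orthogonal filtering exhausted the rank of X")
    pv <- as.numeric(crossprod(E, t)) / tt
    wo <- pv - sum(w * pv) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-10 * sqrt(sum(pv^2) + 1e-300)) {
      # no y-orthogonal structure left: record a zero component
      next
    }
    wo <- wo / nwo
    s <- sign_fix(wo)
    wo <- s * wo
    to <- as.numeric(E %*% wo)
    tto <- sum(to^2)
    if (tto < 1e-14 * ssx0) next
    po <- as.numeric(crossprod(E, to)) / tto
    W_o[, h] <- wo; T_o[, h] <- to; P_o[, h] <- po
    r2x_orth[h] <- tto * sum(po^2) / ssx0
    E <- E - tcrossprod(to, po)
  }
  # predictive PLS component on the filtered matrix
  wp <- as.numeric(crossprod(E, enc$yc))
  nwp <- sqrt(sum(wp^2))
  stop_if_not(nwp > 0, "filtered X carries no covariance with the class label")
  wp <- wp / nwp
  t <- as.numeric(E %*% wp)
  tt <- sum(t^2)
  stop_if_not(tt > 1e-14 * ssx0, "no predictive variation left after filtering")
  pv <- as.numeric(crossprod(E, t)) / tt
  qa <- sum(enc$yc * t) / tt
  s <- sign_fix(wp)
  wp <- s * wp; t <- s * t; pv <- s * pv; qa <- s * qa
  yhat <- t * qa
  r2y <- 1 - sum((enc$yc - yhat)^2) / ssy0
  W <- matrix(wp, p, 1L); P <- matrix(pv, p, 1L); Tm <- matrix(t, n, 1L)
  dimnames(W) <- dimnames(P) <- list(colnames(Xc), "pred")
  dimnames(Tm) <- list(rownames(Xc), "pred")
  orth_names <- sprintf("orth%d", seq_len(max(H, 1L)))
  dimnames(W_o) <- dimnames(P_o) <- list(colnames(Xc), orth_names)
  dimnames(T_o) <- list(rownames(Xc), orth_names)
  if (H == 0L) { W_o <- W_o[, 0L, drop = FALSE]; P_o <- P_o[, 0L, drop = FALSE]
                 T_o <- T_o[, 0L, drop = FALSE] }
  structure(
    list(kind = "oplsda", n_components = 1L, n_orthogonal = H,
         scores = Tm, loadings = P, weights = W, y_loadings = qa,
         scores_orth = T_o, loadings_orth = P_o, weights_orth = W_o,
         r2x = tt * sum(pv^2) / ssx0, r2x_orth = r2x_orth,
         r2y = r2y, ssy = qa^2 * tt, fitted_yc = yhat,
         features = colnames(Xc),
         y_levels = enc$levels, y_class = as.character(y),
         y_mean01 = enc$mean01, y01 = enc$y01,
         x_center = prep$center, x_scale = prep$scale),
    class = c("nmr_oplsda", "latent_model")
  )
}

#' @export
print.nmr_oplsda <- function(x, ...) {
  cat(sprintf("OPLS-DA model: 1 predictive + %d orthogonal component(s), %d samples x %d features\n",
              x$n_orthogonal, nrow(x$scores), length(x$features)))
  cat(sprintf("  R2X(pred) = %.3f, R2X(orth) = %.3f, R2Y = %.3f\n",
              x$r2x, sum(x$r2x_orth), x$r2y))
  invisible(x)
}

#' @export
predict.nmr_oplsda <- function(object, newdata, ...) {
  E <- apply_x_transform(object, newdata)
  H <- object$n_orthogonal
  T_o <- matrix(0, nrow(E), H)
  for (h in seq_len(H)) {
    T_o[, h] <- E %*% object$weights_orth[, h]
    E <- E - tcrossprod(T_o[, h], object$loadings_orth[, h])
  }
  t <- as.numeric(E %*% object$weights[, 1L])
  y_score <- t * object$y_loadings + object$y_mean01
  list(scores = matrix(t, ncol = 1L), scores_orth = T_o, y_score = y_score,
       class = object$y_levels[(y_score > 0.5) + 1L])
}

#' @export
fitted.nmr_oplsda <- function(object, ...) object$fitted_yc + object$y_mean01

#' @export
residuals.nmr_oplsda <- function(object, ...) {
  object$y01 - fitted(object)
}
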