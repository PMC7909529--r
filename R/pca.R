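# Principal component analysis by NIPALS with Gram-Schmidt
# re-orthogonalization.

#' Fit a PCA model (NIPALS)
#'
#' Components are extracted one at a time by the NIPALS power iteration and
#' ordered by decreasing explained variance. Loadings are orthonormal; each
#' component's sign is fixed so its largest-magnitude loading entry is
#' positive, making results reproducible across platforms.
#'
#' @param X numeric matrix, samples in rows (already scaled as desired)
#' @param n_components number of components, at most `min(n_samples - 1,
#'   n_features)`
#' @param center,scale column centering/unit-variance scaling applied before
#'   fitting (centering defaults on; pass pre-scaled data with `scale = FALSE`)
#' @return an object of classes `nmr_pca`, `latent_model` with scores,
#'   loadings, per-component explained-variance fractions (`r2x`)
#' @export
fit_pca <- function(X, n_components = 2, center = TRUE, scale = FALSE) {
  prep <- prepare_x(X, center, scale)
  Xc <- prep$Xs
  n <- nrow(Xc); p <- ncol(Xc)
  stop_if_not(n_components >= 1 && n_components <= min(n - 1L, p),
              "n_components must be in [1, min(n_samples - 1, n_features)]")
  tss <- sum(Xc^2)
  stop_if_not(tss > 0, "X has no variance")
  A <- n_components
  P <- matrix(0, p, A); Tm <- matrix(0, n, A); expl <- numeric(A)
  E <- Xc
  for (a in seq_len(A)) {
    t <- E[, which.max(colSums(E^2))]
    if (sum(t^2) < 1e-14 * tss)
      stop("n_components exceeds the rank of X", call. = FALSE)
    for (iter in seq_len(1000L)) {
      pv <- as.numeric(crossprod(E, t)) / sum(t^2)
      if (a > 1L) {   # guard orthogonality against previous loadings
        prev <- P[, seq_len(a - 1L), drop = FALSE]
        pv <- pv - prev %*% crossprod(prev, pv)
      }
      pv <- pv / sqrt(sum(pv^2))
      t_new <- as.numeric(E %*% pv)
      if (sum((t_new - t)^2) < 1e-24 * sum(t_new^2)) { t <- t_new; break }
      t <- t_new
    }
    s <- sign_fix(pv)
    pv <- s * pv; t <- s * t
    P[, a] <- pv; Tm[, a] <- t
    expl[a] <- sum(t^2) / tss
    E <- E - tcrossprod(t, pv)
  }
  dimnames(P) <- list(colnames(Xc), sprintf("PC%d", seq_len(A)))
  dimnames(Tm) <- list(rownames(Xc), sprintf("PC%d", seq_len(A)))
  structure(
    list(kind = "pca", n_components = A, scores = Tm, loadings = P,
         r2x = expl, features = colnames(Xc),
         x_center = prep$center, x_scale = prep$scale, tss = tss),
    class = c("nmr_pca", "latent_model")
  )
}

#' Per-feature contributions on a PCA component
#'
#' The contribution of feature j on component a is `p_ja^2 / sum_j p_ja^2`
#' (loadings are unit vectors, so contributions sum to 1). Ties are broken by
#' feature order.
#'
#' @param m a fitted [fit_pca()] model
#' @param component component index
#' @param top_k how many features to return (`NULL` = all)
#' @return data.frame with columns `feature`, `contribution`, sorted
#'   decreasing
#' @export
pca_contributions <- function(m, component = 1L, top_k = NULL) {
  stop_if_not(inherits(m, "nmr_pca"), "contributions are defined for PCA models")
  stop_if_not(component >= 1L && component <= m$n_components,
              "invalid component index")
  contrib <- m$loadings[, component]^2
  contrib <- contrib / sum(contrib)
  ord <- order(-contrib)
  out <- data.frame(feature = m$features[ord], contribution = contrib[ord],
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(top_k)) out <- out[seq_len(min(top_k, nrow(out))), , drop = FALSE]
  out
}

#' @export
predict.nmr_pca <- function(object, newdata, ...) {
  apply_x_transform(object, newdata) %*% object$loadings
}
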