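# Feature-table preprocessing: minimum-positive imputation, per-sample
# geometric-mean normalization, generalized log transform, and scaling.

#' Replace missing, zero and negative values
#'
#' Per feature (column), every missing, zero or negative entry is replaced by
#' one fifth of the column's minimum positive value; positive entries are
#' untouched. Idempotent. A feature with no positive value at all cannot be
#' recovered and raises an error naming it.
#'
#' @param t a [feature_table()] or numeric matrix
#' @return same type as the input, all values positive
#' @export
impute_missing <- function(t) {
  x <- ft_values(t)
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    pos <- col[!is.na(col) & col > 0]
    bad <- is.na(col) | col <= 0
    if (any(bad)) {
      stop_if_not(length(pos) > 0L,
                  "feature '%s' has no positive value to impute from",
                  colnames(x)[j])
      col[bad] <- min(pos) / 5
      x[, j] <- col
    }
  }
  ft_rewrap(t, x)
}

#' Normalize each sample by its geometric mean
#'
#' Divides every sample row by the geometric mean of its own values — the
#' standard dilution correction for urine. Requires strictly positive values
#' (run [impute_missing()] first). Afterwards every row's geometric mean is 1.
#'
#' @param t a [feature_table()] or numeric matrix with positive entries
#' @return normalized table of the same type
#' @export
normalize_geometric_mean <- function(t) {
  x <- ft_values(t)
  stop_if_not(all(is.finite(x)) && all(x > 0),
              "geometric-mean normalization requires strictly positive values")
  gm <- exp(rowMeans(log(x)))
  ft_rewrap(t, x / gm)
}

#' Generalized log transform
#'
#' Elementwise `g(x) = ln((x + sqrt(x^2 + lambda^2)) / 2)`, a
#' variance-stabilizing transform that is defined for non-positive values and
#' reduces to `ln(x)` at `lambda = 0`. The default `lambda` is the table's
#' global minimum positive value.
#'
#' @param t a [feature_table()] or numeric matrix
#' @param lambda transform parameter, `>= 0`; `NULL` for the default
#' @return transformed table; the `lambda` used is attached as attribute
#'   `"lambda"` of the value matrix
#' @export
glog_transform <- function(t, lambda = NULL) {
  x <- ft_values(t)
  stop_if_not(all(is.finite(x)), "values must be finite")
  if (is.null(lambda)) {
    pos <- x[x > 0]
    stop_if_not(length(pos) > 0L, "cannot derive lambda: no positive values")
    lambda <- min(pos)
  }
  stop_if_not(lambda >= 0, "lambda must be non-negative")
  g <- log((x + sqrt(x^2 + lambda^2)) / 2)
  attr(g, "lambda") <- lambda
  ft_rewrap(t, g)
}

#' Inverse of the generalized log transform
#'
#' @param g glog-transformed values
#' @param lambda the lambda used in the forward transform
#' @return the original values
#' @export
glog_inverse <- function(g, lambda) {
  x <- ft_values(g)
  y <- exp(x)
  ft_rewrap(g, y - lambda^2 / (4 * y))
}

#' Column scaling for latent-variable modelling
#'
#' Centers every feature; `unit_variance` additionally divides by the
#' feature's standard deviation (n-1 denominator), `pareto` by its square
#' root. Constant features are centered only and flagged in the
#' `"degenerate_features"` attribute.
#'
#' @param t a [feature_table()] or numeric matrix with at least 2 samples
#' @param mode `"unit_variance"` (default), `"center"` or `"pareto"`
#' @return scaled table; value matrix carries attributes `"center"`,
#'   `"scale"` and `"degenerate_features"`
#' @export
autoscale <- function(t, mode = c("unit_variance", "center", "pareto")) {
  mode <- match.arg(mode)
  x <- ft_values(t)
  stop_if_not(nrow(x) >= 2L, "autoscale needs at least 2 samples")
  ctr <- colMeans(x)
  sds <- apply(x, 2L, stats::sd)
  degenerate <- colnames(x)[sds == 0]
  scl <- switch(mode,
                center = rep(1, ncol(x)),
                unit_variance = ifelse(sds > 0, sds, 1),
                pareto = ifelse(sds > 0, sqrt(sds), 1))
  out <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  attr(out, "degenerate_features") <- degenerate
  ft_rewrap(t, out)
}

#' Run the full preprocessing chain
#'
#' Imputation, geometric-mean normalization, glog transform, then scaling —
#' the order the downstream latent-variable models expect.
#'
#' @param t a [feature_table()] or numeric matrix
#' @param lambda glog parameter (`NULL` = table minimum positive value)
#' @param scaling scaling mode passed to [autoscale()], or `"none"`
#' @return preprocessed table of the same type
#' @export
preprocess_table <- function(t, lambda = NULL,
                             scaling = c("unit_variance", "center", "pareto", "none")) {
  scaling <- match.arg(scaling)
  out <- glog_transform(normalize_geometric_mean(impute_missing(t)), lambda)
  if (scaling != "none") out <- autoscale(out, scaling)
  out
}
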