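# Cross-validated Q2 and permutation validation of the supervised models.

#' Describe a supervised model for validation
#'
#' @param kind `"plsda"` or `"oplsda"`
#' @param n_components PLS-DA component count
#' @param n_orthogonal OPLS-DA orthogonal component count
#' @return a `model_spec` list
#' @export
model_spec <- function(kind = c("plsda", "oplsda"), n_components = 2,
                       n_orthogonal = 1) {
  kind <- match.arg(kind)
  structure(list(kind = kind, n_components = n_components,
                 n_orthogonal = n_orthogonal), class = "model_spec")
}

fit_spec_model <- function(X, y, spec) {
  switch(spec$kind,
         plsda = fit_plsda(X, y, n_components = spec$n_components),
         oplsda = fit_oplsda(X, y, n_orthogonal = spec$n_orthogonal),
         stop("unknown model kind: ", spec$kind))
}

# Stratified fold assignment: class members are shuffled and dealt round-robin
# so every fold (and hence every training split) keeps both classes.
make_stratified_folds <- function(y, k_folds, seed) {
  f <- droplevels(as.factor(y))
  stop_if_not(k_folds >= 2L, "k_folds must be >= 2")
  stop_if_not(nlevels(f) == 2L, "y must contain exactly two classes")
  stop_if_not(all(tabulate(f) >= 2L),
              "each class needs at least 2 members for stratified folds")
  set.seed(seed)
  fold <- integer(length(f))
  for (lev in levels(f)) {
    idx <- sample(which(f == lev))
    fold[idx] <- rep_len(seq_len(k_folds), length(idx))
  }
  fold
}

#' Cross-validated predictive ability Q2
#'
#' Stratified k-fold cross-validation of the class label:
#' `Q2 = 1 - PRESS / SSY`, where PRESS accumulates the squared errors of
#' out-of-fold label predictions and SSY is the total sum of squares of the
#' centered label. Deterministic under `seed`.
#'
#' @param X numeric matrix, samples in rows
#' @param y binary class labels
#' @param spec a [model_spec()]
#' @param k_folds number of folds (default 7)
#' @param seed RNG seed for fold assignment
#' @return Q2 (numeric scalar) with attributes `press` and `ssy`
#' @export
cross_validate_q2 <- function(X, y, spec = model_spec(), k_folds = 7, seed = 1L) {
  X <- as.matrix(X)
  f <- droplevels(as.factor(y))
  y01 <- as.numeric(f) - 1
  fold <- make_stratified_folds(f, k_folds, seed)
  press <- 0
  for (k in sort(unique(fold))) {
    train <- fold != k
    m <- fit_spec_model(X[train, , drop = FALSE], f[train], spec)
    pr <- predict(m, X[!train, , drop = FALSE])
    # predict() decodes on the 0/1 scale of the training labels; the factor
    # level order is shared, so scores are comparable across folds
    press <- press + sum((y01[!train] - pr$y_score)^2)
  }
  ssy <- sum((y01 - mean(y01))^2)
  q2 <- 1 - press / ssy
  attr(q2, "press") <- press
  attr(q2, "ssy") <- ssy
  q2
}

#' Permutation validation of R2Y and Q2
#'
#' Refits the model and recomputes Q2 under `n_perm` uniformly random
#' permutations of the class labels. P-values follow the add-one rule
#' `p = (1 + #{permuted >= observed}) / (1 + n_perm)`, so with 100
#' permutations the smallest attainable p is 1/101.
#'
#' @param X numeric matrix, samples in rows
#' @param y binary class labels
#' @param spec a [model_spec()]
#' @param n_perm number of permutations (default 100)
#' @param k_folds folds for the Q2 computation
#' @param seed RNG seed (controls permutations and fold assignments)
#' @return an object of class `permutation_result`: observed and permuted
#'   (R2Y, Q2) and p-values `p_r2y`, `p_q2`
#' @export
permutation_test <- function(X, y, spec = model_spec(), n_perm = 100,
                             k_folds = 7, seed = 1L) {
  stop_if_not(n_perm >= 1, "n_perm must be >= 1")
  X <- as.matrix(X)
  f <- droplevels(as.factor(y))
  obs_r2y <- fit_spec_model(X, f, spec)$r2y
  obs_q2 <- as.numeric(cross_validate_q2(X, f, spec, k_folds, seed = seed))
  perm_r2y <- numeric(n_perm)
  perm_q2 <- numeric(n_perm)
  set.seed(seed)
  perms <- lapply(seq_len(n_perm), function(b) sample(seq_along(f)))
  for (b in seq_len(n_perm)) {
    yp <- f[perms[[b]]]
    perm_r2y[b] <- fit_spec_model(X, yp, spec)$r2y
    perm_q2[b] <- as.numeric(cross_validate_q2(X, yp, spec, k_folds,
                                               seed = seed + b))
  }
  structure(
    list(n_perm = n_perm,
         observed = c(r2y = obs_r2y, q2 = obs_q2),
         permuted = data.frame(r2y = perm_r2y, q2 = perm_q2),
         p_r2y = (1 + sum(perm_r2y >= obs_r2y)) / (1 + n_perm),
         p_q2 = (1 + sum(perm_q2 >= obs_q2)) / (1 + n_perm),
         spec = spec, seed = seed),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation validation (%d permutations, %s)\n",
              x$n_perm, x$spec$kind))
  cat(sprintf("  observed R2Y = %.3f (p = %.4f), Q2 = %.3f (p = %.4f)\n",
              x$observed["r2y"], x$p_r2y, x$observed["q2"], x$p_q2))
  invisible(x)
}

#' @export
plot.permutation_result <- function(x, ...) {
  graphics::hist(x$permuted$q2, breaks = 20,
                 main = "Permutation null of Q2", xlab = "Q2", ...)
  graphics::abline(v = x$observed["q2"], col = 2, lwd = 2)
  invisible(x)
}
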