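# Consensus selection, ROC curves, marker panels, sensitivity comparison.

test_that("consensus on the published selection lists recovers the reference sets", {
  sel <- reference_model_selections()
  vips <- reference_vip()
  wil <- data.frame(feature = names(vips),
                    p_adj = ifelse(names(vips) %in% sel$wilcoxon_p01,
                                   0.001, 0.5))
  cons <- select_consensus(sel[c("pca", "plsda", "oplsda")], wil, vips,
                           universe = names(vips))
  expect_length(cons$two_model_set, 8L)
  expect_setequal(cons$vip_set,
                  c("guanidinoacetate", "L-alanine", "phenylacetylglycine",
                    "acetate", "L-lactate", "glycine", "dimethylglycine"))
  expect_setequal(cons$prominent,
                  c("guanidinoacetate", "phenylacetylglycine", "glycine",
                    "L-lactate", "L-alanine"))
})

test_that("disjoint model selections give an empty consensus without error", {
  sets <- list(m1 = c("a", "b"), m2 = c("c", "d"), m3 = c("e"))
  wil <- data.frame(feature = letters[1:6], p_adj = rep(0.001, 6))
  vips <- setNames(rep(2, 6), letters[1:6])
  cons <- select_consensus(sets, wil, vips, universe = letters[1:6])
  expect_length(cons$two_model_set, 0L)
  expect_length(cons$prominent, 0L)
})

test_that("consensus rejects features outside the universe", {
  sets <- list(m1 = c("a", "zz"), m2 = "a")
  wil <- data.frame(feature = "a", p_adj = 0.001)
  expect_error(select_consensus(sets, wil, c(a = 2), universe = c("a", "b")),
               "unknown feature")
})

test_that("consensus is monotone in its thresholds", {
  set.seed(14)
  feats <- sprintf("m%02d", 1:12)
  sets <- list(m1 = sample(feats, 6), m2 = sample(feats, 6),
               m3 = sample(feats, 6))
  wil <- data.frame(feature = feats, p_adj = runif(12))
  vips <- setNames(runif(12, 0, 2), feats)
  tight <- select_consensus(sets, wil, vips, universe = feats,
                            p_thresh = 0.05, vip_thresh = 1.2)
  loose <- select_consensus(sets, wil, vips, universe = feats,
                            p_thresh = 0.5, vip_thresh = 0.8)
  expect_true(all(tight$wilcoxon_set %in% loose$wilcoxon_set))
  expect_true(all(tight$vip_set %in% loose$vip_set))
  expect_true(all(tight$prominent %in% loose$prominent))
})

test_that("ROC handles perfect separation, partial overlap and total ties", {
  lvl <- function(x) factor(x, levels = c("control", "case"))
  r1 <- roc_curve(c(1, 2, 3, 4, 5, 6),
                  lvl(rep(c("control", "case"), each = 3)))
  expect_equal(r1$auc, 1.0)
  expect_equal(r1$sens_at_youden, 1)
  expect_equal(r1$spec_at_youden, 1)

  r2 <- roc_curve(c(1, 3, 2, 4), lvl(c("control", "control", "case", "case")))
  expect_equal(r2$auc, 0.75)   # 3 of 4 pairs concordant

  r3 <- roc_curve(rep(2, 8), lvl(rep(c("control", "case"), 4)))
  expect_equal(r3$auc, 0.5)
  expect_error(roc_curve(1:4, rep("case", 4)), "both classes")
})

test_that("AUC equals the Mann-Whitney concordance on random instances", {
  for (seed in 1:100) {
    set.seed(seed)
    n1 <- sample(3:10, 1); n0 <- sample(3:10, 1)
    scores <- sample(1:6, n0 + n1, replace = TRUE) + # ties on purpose
      round(rnorm(n0 + n1), 1)
    labels <- factor(rep(c("control", "case"), c(n0, n1)),
                     levels = c("control", "case"))
    r <- roc_curve(scores, labels)
    case <- scores[labels == "case"]; ctrl <- scores[labels == "control"]
    u <- sum(outer(case, ctrl, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(r$auc, u / (n0 * n1), tolerance = 1e-10)
  }
})

test_that("AUC of negated tie-free scores is the complement", {
  set.seed(23)
  scores <- rnorm(30)
  labels <- factor(rep(c("control", "case"), 15),
                   levels = c("control", "case"))
  expect_equal(roc_curve(scores, labels)$auc +
                 roc_curve(-scores, labels)$auc, 1, tolerance = 1e-12)
})

test_that("a single-marker panel inherits the marker's AUC", {
  set.seed(16)
  x <- cbind(m1 = rnorm(40) + rep(c(0, 1.5), 20), m2 = rnorm(40))
  tab <- toy_feature_table(x, group = rep(c("control", "case"), 20))
  p1 <- fit_panel(tab, "m1", method = "linear")
  expect_equal(p1$roc$auc, roc_curve(x[, "m1"], tab$group)$auc,
               tolerance = 1e-12)
  # logistic score is a monotone transform: same resubstitution AUC
  p1l <- fit_panel(tab, "m1", method = "logistic")
  expect_equal(p1l$roc$auc, p1$roc$auc, tolerance = 1e-12)
})

test_that("adding a marker never increases the linear panel's RSS", {
  set.seed(18)
  x <- matrix(rnorm(120), 40, 3)
  colnames(x) <- c("a", "b", "c")
  tab <- toy_feature_table(x, group = rep(c("control", "case"), 20))
  y01 <- as.numeric(tab$group == "case")
  rss <- function(p) sum((y01 - p$score)^2)
  expect_lte(rss(fit_panel(tab, c("a", "b"))), rss(fit_panel(tab, "a")))
  expect_lte(rss(fit_panel(tab, c("a", "b", "c"))),
             rss(fit_panel(tab, c("a", "b"))))
})

test_that("collinear markers raise a rank-deficiency error", {
  x <- cbind(a = rnorm(20), b = 0)
  x <- cbind(x, c = 2 * x[, "a"])
  tab <- toy_feature_table(x, group = rep(c("control", "case"), 10))
  expect_error(fit_panel(tab, c("a", "c")), "collinear")
})

test_that("complete separation is flagged under the logistic fit", {
  x <- cbind(m = c(rnorm(10, -3), rnorm(10, 3)))
  tab <- toy_feature_table(x, group = rep(c("control", "case"), each = 10))
  p <- fit_panel(tab, "m", method = "logistic")
  expect_true(p$separation)
})

test_that("the paired sensitivity comparison is an exact binomial test", {
  fake_panel <- function(correct_cases) {
    # cases scored at/above threshold 0 when correct, below when not
    score <- c(rep(-1, 10), ifelse(correct_cases, 1, -1))
    structure(list(score = score,
                   labels = factor(rep(c("control", "case"), each = 10),
                                   levels = c("control", "case")),
                   roc = list(youden_threshold = 0)),
              class = "panel_model")
  }
  a <- fake_panel(rep(TRUE, 10))
  expect_equal(compare_sensitivity(a, a)$p_value, 1.0)
  # discordant b = 1 (only A correct), c = 9 (only B correct)
  pa <- fake_panel(c(TRUE, rep(FALSE, 9)))
  pb <- fake_panel(c(FALSE, rep(TRUE, 9)))
  cmp <- compare_sensitivity(pa, pb)
  expect_identical(c(cmp$b, cmp$c), c(1L, 9L))
  expect_equal(cmp$p_value, 2 * pbinom(1, 10, 0.5), tolerance = 1e-12)
  # no discordant cases -> flagged p = 1
  none <- compare_sensitivity(fake_panel(rep(FALSE, 10)),
                              fake_panel(rep(FALSE, 10)))
  expect_true(none$no_discordant)
  expect_equal(none$p_value, 1)
})
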