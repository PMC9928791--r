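# brute-force AUC oracle: pairwise win/tie counting
auc_pairs <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

trapezoid_area <- function(roc) {
  fpr <- 1 - roc$specificity
  sum(diff(fpr) * (roc$sensitivity[-1] +
                     roc$sensitivity[-length(roc$sensitivity)]) / 2)
}

test_that("AUC matches enumeration on canonical cases", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(roc_auc(rep(5, 8), rep(c(0, 1), 4))$auc, 0.5)
  expect_equal(roc_auc(c(1, 3, 2, 4), c(0, 0, 1, 1))$auc, 0.75)
  expect_error(roc_auc(1:4, rep(1, 4)), "both")
})

test_that("ROC curve is monotone and AUC equals the trapezoid area", {
  set.seed(19)
  for (trial in 1:50) {
    n <- sample(6:80, 1)
    scores <- round(rnorm(n), sample(0:2, 1))  # induce ties
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
    roc <- roc_auc(scores, labels)
    expect_true(all(diff(roc$sensitivity) >= 0))
    expect_true(all(diff(1 - roc$specificity) >= 0))
    expect_equal(roc$auc, trapezoid_area(roc), tolerance = 1e-12)
    if (n <= 20)
      expect_equal(roc$auc, auc_pairs(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC is invariant to monotone transforms and flips with sign", {
  set.seed(29)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.5)
  labels[1:2] <- c(0, 1)
  a <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(exp(scores), labels)$auc, a, tolerance = 1e-12)
  expect_equal(roc_auc(rank(scores), labels)$auc, a, tolerance = 1e-12)
  # tie-free: AUC(s) + AUC(-s) = 1
  expect_equal(roc_auc(-scores, labels)$auc, 1 - a, tolerance = 1e-12)
})

test_that("AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(37)
  scores <- round(rnorm(100), 1)
  labels <- rbinom(100, 1, 0.5)
  labels[1:2] <- c(0, 1)
  expect_equal(roc_auc(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE, direction = "<"))),
               tolerance = 1e-12)
})

test_that("stratified bootstrap is deterministic with degenerate limits", {
  scores <- c(1, 2, 3, 10, 11, 12)
  labels <- c(0, 0, 0, 1, 1, 1)
  b <- bootstrap_auc(scores, labels, n_iter = 200, seed = 5)
  expect_true(all(b$replicate_aucs == 1))
  expect_equal(c(b$ci_low, b$ci_high), c(1, 1))
  b2 <- bootstrap_auc(scores, labels, n_iter = 200, seed = 5)
  expect_identical(b$replicate_aucs, b2$replicate_aucs)
  expect_true(b$ci_low <= b$mean_auc && b$mean_auc <= b$ci_high)
  # seeds matter when the data leave room for resampling variation
  set.seed(8)
  sc <- rnorm(40); lb <- rep(c(0, 1), 20)
  expect_false(identical(bootstrap_auc(sc, lb, 100, 5)$replicate_aucs,
                         bootstrap_auc(sc, lb, 100, 6)$replicate_aucs))
})

test_that("bootstrap mean recovers the closed-form binormal AUC", {
  set.seed(41)
  scores <- c(rnorm(200, 0), rnorm(200, 2))
  labels <- rep(c(0, 1), each = 200)
  b <- bootstrap_auc(scores, labels, n_iter = 1000, seed = 17)
  expect_equal(b$mean_auc, pnorm(2 / sqrt(2)), tolerance = 0.03 / 0.92)
})

test_that("paired bootstrap AUC comparison obeys its symmetries", {
  set.seed(43)
  scores <- rnorm(80); labels <- rep(c(0, 1), 40)
  same <- compare_auc_bootstrap(scores, scores, labels, n_iter = 500,
                                seed = 2)
  expect_equal(same$delta_auc, 0)
  expect_equal(same$p_value, 1)
  # perfectly separating vs pure-noise score: p at the 1/n_iter floor
  sep <- c(rnorm(100, 0, 0.1), rnorm(100, 10, 0.1))
  noise <- rnorm(200)
  lab <- rep(c(0, 1), each = 100)
  strong <- compare_auc_bootstrap(sep, noise, lab, n_iter = 500, seed = 3)
  expect_equal(strong$p_value, 1 / 500)
  # swapping the scores negates delta, p unchanged
  a <- rnorm(80); b2 <- a + rnorm(80, 0, 0.5)
  ab <- compare_auc_bootstrap(a, b2, labels, n_iter = 400, seed = 9)
  ba <- compare_auc_bootstrap(b2, a, labels, n_iter = 400, seed = 9)
  expect_equal(ab$delta_auc, -ba$delta_auc, tolerance = 1e-12)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
})

test_that("threshold selection maximizes sensitivity at the spec floor", {
  # enumerated example: candidates are midpoints plus infinities
  op <- select_threshold(c(1, 2, 3, 2.5, 4, 5),
                         c(0, 0, 0, 1, 1, 1), min_specificity = 1.0)
  expect_true(op$threshold > 3 && op$threshold <= 4)
  expect_equal(op$sensitivity, 2 / 3)
  expect_equal(op$specificity, 1.0)
  # perfect separation: both rates 1 at any constraint
  op2 <- select_threshold(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1), 0.5)
  expect_equal(op2$sensitivity, 1.0)
  expect_equal(op2$specificity, 1.0)
  # tightening the constraint never raises achievable sensitivity, and the
  # chosen point always lies on the roc_auc curve
  set.seed(47)
  scores <- round(rnorm(60), 1)
  labels <- rbinom(60, 1, 0.5); labels[1:2] <- c(0, 1)
  roc <- roc_auc(scores, labels)
  prev <- 1
  for (ms in c(0.5, 0.7, 0.9, 0.98, 1.0)) {
    op <- select_threshold(scores, labels, ms)
    expect_lte(op$sensitivity, prev)
    expect_gte(op$specificity, ms)
    prev <- op$sensitivity
    onc <- any(abs(roc$sensitivity - op$sensitivity) < 1e-12 &
                 abs(roc$specificity - op$specificity) < 1e-12)
    expect_true(onc)
  }
})

# hypergeometric enumeration oracle for the two-sided Fisher test
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(xs, c1, n - c1, r1)
  p_obs <- dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

test_that("Fisher's exact test matches exhaustive enumeration", {
  # LDH elevation: 8/75 low-grade vs 28/47 post-transformation
  tab <- matrix(c(8, 67, 28, 19), 2, byrow = TRUE)
  p <- fishers_exact(tab)
  expect_lt(p, 0.001)
  expect_equal(p, fisher_oracle(tab), tolerance = 1e-10)
  expect_equal(fishers_exact(matrix(5, 2, 2)), 1.0)
  set.seed(53)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 8), 2)
    expect_equal(fishers_exact(tab), fisher_oracle(tab), tolerance = 1e-10)
  }
})

test_that("two-sample t-test matches hand computation and permutation", {
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # pooled formula by hand: means 2 and 5, s2 = 1, se = sqrt(2/3), df = 4
  st <- two_sample_t(c(1, 2, 3), c(4, 5, 6), "student")
  expect_equal(st$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(st$t, -3.674, tolerance = 1e-3)
  expect_equal(st$p, 2 * pt(-3 / sqrt(2 / 3), df = 4), tolerance = 1e-12)
  expect_equal(st$p, 0.0214, tolerance = 1e-2)
  # degenerate zero-variance limits
  expect_equal(two_sample_t(c(2, 2), c(2, 2))$p, 1)
  expect_equal(two_sample_t(c(2, 2), c(3, 3))$p, 0)
  # permutation oracle at small n
  set.seed(59)
  x <- rnorm(5); y <- rnorm(6, 1)
  obs <- abs(two_sample_t(x, y, "student")$t)
  pooled <- c(x, y)
  perm <- replicate(20000, {
    idx <- sample(11, 5)
    abs(two_sample_t(pooled[idx], pooled[-idx], "student")$t)
  })
  expect_equal(two_sample_t(x, y, "student")$p, mean(perm >= obs - 1e-12),
               tolerance = 0.15)
})
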