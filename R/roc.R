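# ROC / AUC machinery.  The AUC is the tie-corrected Mann-Whitney statistic
# (probability a random positive outscores a random negative, ties
# half-credited); the trapezoid area over the empirical ROC curve is equal
# to it, which the test suite asserts to 1e-12.

# fast rank-based AUC used throughout (including bootstrap loops)
.auc <- function(scores, labels) {
  r <- rank(scores)
  n_pos <- sum(labels)
  n_neg <- length(labels) - n_pos
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

.check_labels <- function(labels) {
  labels <- as.logical(labels)
  if (anyNA(labels)) stop("labels must be binary without NA")
  if (all(labels) || !any(labels))
    stop("both outcome classes must be present")
  labels
}

#' ROC curve and AUC
#'
#' Operating points are generated by the rule "predict positive when
#' score >= threshold" at every unique observed score (plus `Inf`, the
#' all-negative corner).  The AUC is the Mann-Whitney statistic with
#' half-credit for ties, identical to the trapezoid area under the curve.
#'
#' @param scores Numeric scores (higher = more suspicious for the positive
#'   class).
#' @param labels Binary labels, `TRUE`/1 = positive (transformed).
#' @return An object of class `roc_result`: list with descending
#'   `thresholds`, `sensitivity`, `specificity`, `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- .check_labels(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!labels] < t), numeric(1))
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = .auc(scores, labels),
                 n_pos = sum(labels), n_neg = sum(!labels)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.4f (%d positives, %d negatives, %d thresholds)\n",
              x$auc, x$n_pos, x$n_neg, length(x$thresholds)))
  invisible(x)
}

# stratified resample indices preserving class sizes
.strat_indices <- function(labels) {
  pos <- which(labels); neg <- which(!labels)
  c(pos[sample.int(length(pos), replace = TRUE)],
    neg[sample.int(length(neg), replace = TRUE)])
}

#' Class-stratified bootstrap of the AUC
#'
#' Each replicate resamples patients with replacement within class (class
#' sizes preserved, so every replicate has both classes); the 95% CI is the
#' percentile interval of the replicate AUCs.
#'
#' @inheritParams roc_auc
#' @param n_iter Number of bootstrap replicates.
#' @param seed Integer seed; fixed seed gives identical replicate lists.
#' @return A `bootstrap_auc` object: `point_auc`, `replicate_aucs`,
#'   `mean_auc`, `ci_low`, `ci_high`, `n_iter`, `seed`.
#' @export
bootstrap_auc <- function(scores, labels, n_iter = 1000, seed = 1L) {
  labels <- .check_labels(labels)
  stopifnot(n_iter >= 1)
  set.seed(as.integer(seed))
  reps <- vapply(seq_len(n_iter), function(b) {
    idx <- .strat_indices(labels)
    .auc(scores[idx], labels[idx])
  }, numeric(1))
  ci <- unname(stats::quantile(reps, c(0.025, 0.975)))
  structure(list(point_auc = .auc(scores, labels), replicate_aucs = reps,
                 mean_auc = mean(reps), ci_low = ci[1], ci_high = ci[2],
                 n_iter = n_iter, seed = as.integer(seed)),
            class = "bootstrap_auc")
}

#' @export
print.bootstrap_auc <- function(x, ...) {
  cat(sprintf("Bootstrap AUC: point %.4f | mean %.4f (95%% CI %.4f-%.4f, %d reps)\n",
              x$point_auc, x$mean_auc, x$ci_low, x$ci_high, x$n_iter))
  invisible(x)
}

#' Paired bootstrap comparison of two scores' AUCs
#'
#' Both score vectors are evaluated on the same stratified resamples, so the
#' replicate AUC difference is a paired statistic.  The two-sided p-value is
#' `2 * min(P(delta <= 0), P(delta >= 0))`, floored at `1 / n_iter` (an
#' empirical p of exactly 0 is not reportable) and capped at 1.
#'
#' @param scores_a,scores_b Two scores for the same patients.
#' @inheritParams bootstrap_auc
#' @return List with `auc_a`, `auc_b`, `delta_auc` (a minus b, point
#'   estimate), `replicate_deltas`, `p_value`.
#' @export
compare_auc_bootstrap <- function(scores_a, scores_b, labels,
                                  n_iter = 1000, seed = 1L) {
  labels <- .check_labels(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  set.seed(as.integer(seed))
  deltas <- vapply(seq_len(n_iter), function(b) {
    idx <- .strat_indices(labels)
    .auc(scores_a[idx], labels[idx]) - .auc(scores_b[idx], labels[idx])
  }, numeric(1))
  p <- 2 * min(mean(deltas <= 0), mean(deltas >= 0))
  p <- min(1, max(p, 1 / n_iter))
  list(auc_a = .auc(scores_a, labels), auc_b = .auc(scores_b, labels),
       delta_auc = .auc(scores_a, labels) - .auc(scores_b, labels),
       replicate_deltas = deltas, p_value = p, n_iter = n_iter)
}

#' Specificity-constrained operating-point selection
#'
#' Candidate thresholds are the midpoints between adjacent distinct observed
#' scores plus the two infinities (decision rule: score >= threshold =>
#' predict transformed).  Among candidates meeting
#' `specificity >= min_specificity`, the one maximizing sensitivity is
#' returned; ties are broken toward higher specificity, then lower
#' threshold.
#'
#' @inheritParams roc_auc
#' @param min_specificity Required specificity, in (0, 1].
#' @return List of class `operating_point`: `threshold`, `sensitivity`,
#'   `specificity`.
#' @export
select_threshold <- function(scores, labels, min_specificity) {
  labels <- .check_labels(labels)
  stopifnot(min_specificity > 0, min_specificity <= 1)
  s <- sort(unique(scores))
  cand <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  sens <- vapply(cand, function(t) mean(scores[labels] >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(scores[!labels] < t), numeric(1))
  ok <- spec >= min_specificity
  # max sensitivity, then max specificity, then lowest threshold
  best <- order(!ok, -sens, -spec, cand)[1]
  structure(list(threshold = cand[best], sensitivity = sens[best],
                 specificity = spec[best]), class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf("Operating point: threshold %.4g | sensitivity %.3f | specificity %.3f\n",
              x$threshold, x$sensitivity, x$specificity))
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact p-value obtained by summing hypergeometric probabilities
#' at most that of the observed table (delegates to [stats::fisher.test()]).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fishers_exact <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L), all(table >= 0),
            all(table == round(table)))
  stats::fisher.test(table, alternative = "two.sided")$p.value
}

#' Unpaired two-sample t-test
#'
#' Student (pooled-variance) or Welch variant, two-sided.  The degenerate
#' zero-variance case is resolved by the documented limit: equal means give
#' p = 1, unequal means give p = 0.
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @param variant `"student"` or `"welch"`.
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_t <- function(x, y, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2, p = 0))
  }
  fit <- stats::t.test(x, y, var.equal = (variant == "student"))
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}
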