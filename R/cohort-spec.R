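#' Calibrate a log-normal distribution from a published mean and range
#'
#' Turns a summary of the form "mean m (range: lo--hi)" over `n` observations
#' into log-normal parameters.  The log-range is equated to the expected
#' range of `n` normal draws using the Blom approximation for the expected
#' maximum order statistic, `z_n = qnorm((n - 0.375) / (n + 0.25))`, so that
#' `sigma_log = (log(hi) - log(lo)) / (2 * z_n)`.  The log-mean is then set
#' so the distribution's arithmetic mean equals `target_mean` exactly:
#' `mu_log = log(target_mean) - sigma_log^2 / 2`.
#'
#' @param target_mean Published arithmetic mean (must lie inside the range).
#' @param observed_range Length-2 numeric, `c(lo, hi)` with `0 < lo < hi`.
#' @param n Number of observations the range was taken over (>= 2).
#' @return A list with components `mu_log` and `sigma_log`.
#' @examples
#' calibrate_lognormal(8.71, c(1.70, 22.57), 53)
#' @export
calibrate_lognormal <- function(target_mean, observed_range, n) {
  lo <- observed_range[[1]]
  hi <- observed_range[[2]]
  if (!is.finite(lo) || !is.finite(hi) || lo <= 0 || hi <= lo)
    stop("invalid range: need 0 < lo < hi, got [", lo, ", ", hi, "]")
  if (!is.finite(target_mean) || target_mean <= lo || target_mean >= hi)
    stop("target_mean must lie strictly inside the observed range")
  if (n < 2) stop("n must be >= 2")
  z_n <- stats::qnorm((n - 0.375) / (n + 0.25))
  sigma_log <- (log(hi) - log(lo)) / (2 * z_n)
  list(mu_log = log(target_mean) - sigma_log^2 / 2, sigma_log = sigma_log)
}

#' Per-group generative specification for a synthetic cohort
#'
#' Bundles the parameters that define one patient group: log-normal marginals
#' for SUV-max and TLG coupled by a Gaussian copula, a Bernoulli LDH-elevation
#' probability, the follicular-histology fraction, a log-normal follow-up /
#' time-to-transformation distribution, and the lesion-count range.
#'
#' @param group_label One of `"control"`, `"pre_transformation"`,
#'   `"post_transformation"`.
#' @param n Number of patients (>= 1).
#' @param suvmax_dist,tlg_dist,time_dist Lists with `mu_log` and `sigma_log`
#'   (as returned by [calibrate_lognormal()]); `tlg_dist` is in cc-scaled
#'   SUV x cc units, `time_dist` in months.
#' @param copula_rho Correlation in `[-1, 1]` between the latent Gaussian
#'   scores of SUV-max and TLG.
#' @param p_ldh_elevated Probability that serum LDH is elevated.
#' @param p_ldh_missing Probability that the LDH flag is unavailable (`NA`);
#'   0 by default.
#' @param histology_fl_fraction Probability of follicular histology.
#' @param roi_range Integer range `c(min, max)` the per-patient ROI count is
#'   drawn uniformly from.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_label, n, suvmax_dist, tlg_dist,
                        copula_rho = 0.5, p_ldh_elevated = 0,
                        p_ldh_missing = 0, histology_fl_fraction = 0.8,
                        time_dist = list(mu_log = log(100), sigma_log = 0.8),
                        roi_range = c(1L, 12L)) {
  spec <- structure(list(
    group_label = group_label, n = as.integer(n),
    suvmax_dist = suvmax_dist, tlg_dist = tlg_dist,
    copula_rho = copula_rho, p_ldh_elevated = p_ldh_elevated,
    p_ldh_missing = p_ldh_missing,
    histology_fl_fraction = histology_fl_fraction,
    time_dist = time_dist,
    roi_range = as.integer(roi_range)), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

valid_groups <- c("control", "pre_transformation", "post_transformation")

validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!spec$group_label %in% valid_groups)
    stop("group_label must be one of: ", paste(valid_groups, collapse = ", "))
  if (is.na(spec$n) || spec$n < 1L) stop("n must be >= 1")
  for (p in c("p_ldh_elevated", "p_ldh_missing", "histology_fl_fraction"))
    if (spec[[p]] < 0 || spec[[p]] > 1) stop(p, " must lie in [0, 1]")
  if (abs(spec$copula_rho) > 1) stop("copula_rho must lie in [-1, 1]")
  for (d in c("suvmax_dist", "tlg_dist", "time_dist")) {
    dist <- spec[[d]]
    if (!is.finite(dist$mu_log) || !is.finite(dist$sigma_log) ||
        dist$sigma_log <= 0)
      stop(d, ": sigma_log must be finite and > 0")
    if (!is.finite(exp(dist$mu_log + dist$sigma_log^2 / 2)))
      stop(d, ": implied log-normal mean is not finite")
  }
  if (length(spec$roi_range) != 2L || spec$roi_range[1] < 1L ||
      spec$roi_range[2] < spec$roi_range[1])
    stop("roi_range must be c(min, max) with 1 <= min <= max")
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  mean_of <- function(d) exp(d$mu_log + d$sigma_log^2 / 2)
  cat("Cohort spec:", x$group_label, " (n =", x$n, ")\n")
  cat(sprintf("  SUV-max ~ logN(%.3f, %.3f)  mean %.2f\n",
              x$suvmax_dist$mu_log, x$suvmax_dist$sigma_log,
              mean_of(x$suvmax_dist)))
  cat(sprintf("  TLG     ~ logN(%.3f, %.3f)  mean %.2f cc\n",
              x$tlg_dist$mu_log, x$tlg_dist$sigma_log, mean_of(x$tlg_dist)))
  cat(sprintf("  copula rho %.2f | P(LDH elevated) %.3f | FL fraction %.2f\n",
              x$copula_rho, x$p_ldh_elevated, x$histology_fl_fraction))
  invisible(x)
}

#' Serialize / deserialize cohort specifications as JSON
#'
#' @param spec A `cohort_spec`, or a named list of them.
#' @param path File path to write to / read from.
#' @return `read_cohort_spec()` returns a `cohort_spec` (or named list of
#'   them); `write_cohort_spec()` returns `path` invisibly.
#' @export
write_cohort_spec <- function(spec, path) {
  payload <- if (inherits(spec, "cohort_spec")) unclass(spec) else
    lapply(spec, unclass)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  rebuild <- function(x) {
    x$roi_range <- as.integer(x$roi_range)
    x$n <- as.integer(x$n)
    validate_cohort_spec(structure(x, class = "cohort_spec"))
  }
  if (!is.null(raw$group_label)) rebuild(raw) else lapply(raw, rebuild)
}
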