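# All cohort-level randomness flows through set.seed(seed) here; callers that
# need several independent streams derive sub-seeds with substream_seed().

#' Generate a synthetic patient cohort
#'
#' Draws `spec$n` patient records.  SUV-max and TLG come from the two
#' log-normal marginals coupled by a Gaussian copula with correlation
#' `spec$copula_rho`; LDH elevation, histology and (optional) LDH missingness
#' are Bernoulli; follow-up / time-to-transformation is log-normal; the ROI
#' count is uniform over `spec$roi_range`.  MTV is back-filled for schema
#' completeness as TLG divided by an SUV-mean proxy of `0.5 * suvmax` (it is
#' never used by the transformation score).
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; identical `(spec, seed)` gives identical output.
#' @return A data.frame with columns `patient_id`, `group`, `histology`
#'   (`"FL"`/`"non_FL"`), `suvmax`, `tlg_cc`, `mtv_cc`, `n_roi`,
#'   `ldh_elevated` (logical, `NA` = unavailable) and `time_months`.
#' @export
generate_cohort <- function(spec, seed) {
  validate_cohort_spec(spec)
  set.seed(as.integer(seed))
  n <- spec$n
  rho <- spec$copula_rho
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  suvmax <- exp(spec$suvmax_dist$mu_log + spec$suvmax_dist$sigma_log * z1)
  tlg <- exp(spec$tlg_dist$mu_log + spec$tlg_dist$sigma_log * z2)
  ldh <- stats::runif(n) < spec$p_ldh_elevated
  if (spec$p_ldh_missing > 0)
    ldh[stats::runif(n) < spec$p_ldh_missing] <- NA
  histology <- ifelse(stats::runif(n) < spec$histology_fl_fraction,
                      "FL", "non_FL")
  time_months <- exp(spec$time_dist$mu_log +
                       spec$time_dist$sigma_log * stats::rnorm(n))
  n_roi <- sample(seq.int(spec$roi_range[1], spec$roi_range[2]), n,
                  replace = TRUE)
  prefix <- c(control = "ctl", pre_transformation = "pre",
              post_transformation = "post")[[spec$group_label]]
  data.frame(
    patient_id = sprintf("%s_%04d", prefix, seq_len(n)),
    group = spec$group_label,
    histology = histology,
    suvmax = suvmax,
    tlg_cc = tlg,
    mtv_cc = tlg / (0.5 * suvmax),
    n_roi = n_roi,
    ldh_elevated = ldh,
    time_months = time_months,
    stringsAsFactors = FALSE)
}

#' Derive a reproducible sub-seed from a root seed and a stream name
#'
#' Keeps all pipeline randomness traceable to one root seed while giving
#' each stage (cohort generation, bootstrap, ...) an independent stream.
#' Result is a positive integer below 2^31 - 1.
#'
#' @param root Integer root seed.
#' @param name Character stream name.
#' @param index Optional replicate index folded into the stream.
#' @export
substream_seed <- function(root, name, index = 0L) {
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 131 + code) %% 2147483647
  as.integer((abs(as.numeric(root)) * 48271 + h * 16807 + index) %%
               2147483646 + 1)
}

# Published group summaries the presets are calibrated to: arithmetic mean,
# observed range and group size for SUV-max, TLG (cc) and times (months),
# plus LDH-elevated fractions among patients with LDH available.
.discovery_summaries <- list(
  control = list(n = 53L,
                 suv = list(8.71, c(1.70, 22.57)),
                 tlg = list(368.58, c(2.48, 3367.24)),
                 time = list(96.0, c(3.9, 305.3)),
                 p_ldh = 6 / 44, fl = 41 / 53, roi = c(1L, 9L)),
  pre_transformation = list(n = 28L,
                 suv = list(11.61, c(2.40, 20.71)),
                 tlg = list(995.33, c(6.16, 3883.23)),
                 time = list(100.9, c(4.9, 306.4)),
                 p_ldh = 2 / 31, fl = 42 / 53, roi = c(1L, 15L)),
  post_transformation = list(n = 53L,
                 suv = list(22.03, c(4.54, 57.26)),
                 tlg = list(3256.18, c(13.37, 16530.56)),
                 time = list(100.9, c(4.9, 306.4)),
                 p_ldh = 28 / 47, fl = 42 / 53, roi = c(1L, 14L)))

.validation_summaries <- list(
  control = list(n = 8L,
                 suv = list(8.12, c(2.50, 17.09)),
                 tlg = list(1664, c(18, 12062)),
                 time = list(96.0, c(3.9, 305.3)),
                 p_ldh = 6 / 44, fl = 7 / 8, roi = c(1L, 9L)),
  post_transformation = list(n = 15L,
                 suv = list(21.15, c(5.57, 44.14)),
                 tlg = list(2766, c(13, 11880)),
                 time = list(100.9, c(4.9, 306.4)),
                 p_ldh = 28 / 47, fl = 13 / 15, roi = c(1L, 14L)))

.spec_from_summary <- function(group, s, copula_rho) {
  cohort_spec(
    group_label = group, n = s$n,
    suvmax_dist = calibrate_lognormal(s$suv[[1]], s$suv[[2]], s$n),
    tlg_dist = calibrate_lognormal(s$tlg[[1]], s$tlg[[2]], s$n),
    copula_rho = copula_rho,
    p_ldh_elevated = s$p_ldh,
    histology_fl_fraction = s$fl,
    time_dist = calibrate_lognormal(s$time[[1]], s$time[[2]], s$n),
    roi_range = s$roi)
}

#' Preset cohort specifications for the discovery and validation studies
#'
#' `discovery_preset()` returns specs for the matched case-control discovery
#' study: 53 controls, 53 post-transformation cases, and the 28-patient
#' pre-transformation scan subset.  `validation_preset()` returns the
#' independent 8-control / 15-transformed validation study.  Each group's
#' log-normal marginals are calibrated from its published mean and range via
#' [calibrate_lognormal()]; LDH-elevation probabilities are the published
#' elevated/available fractions.  The copula correlation defaults to the
#' committed package constant 0.5 (moderate positive SUV-max/TLG dependence;
#' each marginal's own discriminative ability is unaffected by it).
#'
#' @param copula_rho Latent correlation between SUV-max and TLG.
#' @return Named list of [cohort_spec()] objects.
#' @export
discovery_preset <- function(copula_rho = 0.5) {
  specs <- lapply(names(.discovery_summaries), function(g)
    .spec_from_summary(g, .discovery_summaries[[g]], copula_rho))
  names(specs) <- names(.discovery_summaries)
  specs
}

#' @rdname discovery_preset
#' @export
validation_preset <- function(copula_rho = 0.5) {
  specs <- lapply(names(.validation_summaries), function(g)
    .spec_from_summary(g, .validation_summaries[[g]], copula_rho))
  names(specs) <- names(.validation_summaries)
  specs
}
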