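#' LDH scaling factor
#'
#' Returns 2 when serum LDH is elevated above the laboratory reference and 1
#' otherwise.  An unknown (`NA`) LDH status maps to 1, the conservative
#' non-inflating default; callers can count how often this default fired via
#' the `n_defaulted` attribute.
#'
#' @param ldh_elevated Logical vector; `NA` = unknown.
#' @return Integer vector of 1s and 2s with attribute `n_defaulted`.
#' @export
ldh_factor <- function(ldh_elevated) {
  k <- ifelse(is.na(ldh_elevated), 1L, ifelse(ldh_elevated, 2L, 1L))
  attr(k, "n_defaulted") <- sum(is.na(ldh_elevated))
  k
}

#' Multiplicative PET transformation score
#'
#' `score = suvmax * log10(1 + tlg) * K_LDH`, where `K_LDH` is 2 for
#' elevated serum LDH and 1 otherwise ([ldh_factor()]).  SUV-max captures
#' lesion avidity, the damped `log10(1 + TLG)` term captures disease burden
#' on the same order of magnitude, and their product lets either low-burden
#' high-avidity or high-burden low-avidity disease raise the score.
#'
#' @param suvmax Non-negative SUV (vectorized).
#' @param tlg Non-negative total lesion glycolysis, cc-scaled SUV x cc.
#' @param ldh_elevated Logical (or `NA` = unknown).
#' @return Numeric score(s), dimensionless, >= 0.
#' @examples
#' transformation_score(10, 9, FALSE)   # 10 * log10(10) * 1 = 10
#' @export
transformation_score <- function(suvmax, tlg, ldh_elevated = FALSE) {
  if (any(suvmax < 0, na.rm = TRUE) || any(tlg < 0, na.rm = TRUE))
    stop("suvmax and tlg must be >= 0")
  as.numeric(suvmax * log10(1 + tlg) * ldh_factor(ldh_elevated))
}

#' Append the transformation score to a cohort table
#'
#' @param records Cohort data.frame with columns `suvmax`, `tlg_cc`,
#'   `ldh_elevated`.
#' @return The data.frame with a `score` column appended and an attribute
#'   `n_ldh_defaulted` counting records whose unknown LDH defaulted to
#'   factor 1.
#' @export
score_cohort <- function(records) {
  stopifnot(all(c("suvmax", "tlg_cc", "ldh_elevated") %in% names(records)))
  records$score <- transformation_score(records$suvmax, records$tlg_cc,
                                        records$ldh_elevated)
  attr(records, "n_ldh_defaulted") <- sum(is.na(records$ldh_elevated))
  records
}
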