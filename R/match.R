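#' 1:1 case-control matching on histology and follow-up time
#'
#' Matching proceeds in two stages, mirroring a matched case-control design:
#' first the control pool is partitioned by histology and each case is
#' constrained to a control of the same histology, which equalizes the FL
#' fraction of the two groups exactly; then, within each histology stratum,
#' cases are matched greedily without replacement to the control whose
#' follow-up time is nearest the case's time-to-transformation (cases
#' processed in decreasing order of time so the hardest-to-match extremes
#' are paired first).  The returned balance check is the unpaired Student
#' t-test between matched control follow-up times and case times.
#'
#' @param cases data.frame of case records (cohort schema; `time_months` is
#'   time-to-transformation).
#' @param pool data.frame of candidate control records (all
#'   `group == "control"`; `time_months` is follow-up time).
#' @return A `match_result`: `matched_pairs` (data.frame `case_id`,
#'   `control_id`), `histology_fl_fraction_cases` / `_controls`,
#'   `time_mean_cases` / `_controls`, `time_p_value`.
#' @export
match_controls <- function(cases, pool) {
  need <- c("patient_id", "histology", "time_months")
  stopifnot(all(need %in% names(cases)), all(need %in% names(pool)))
  if ("group" %in% names(pool) && any(pool$group != "control"))
    stop("the matching pool must contain only control records")
  if (nrow(pool) < nrow(cases))
    stop("control pool (", nrow(pool), ") smaller than case list (",
         nrow(cases), ")")
  deficits <- character()
  pairs <- NULL
  for (h in unique(cases$histology)) {
    cs <- cases[cases$histology == h, ]
    ps <- pool[pool$histology == h, ]
    if (nrow(ps) < nrow(cs)) {
      deficits <- c(deficits, sprintf(
        "histology %s: %d cases but only %d controls (deficit %d)",
        h, nrow(cs), nrow(ps), nrow(cs) - nrow(ps)))
      next
    }
    cs <- cs[order(cs$time_months, decreasing = TRUE), ]
    avail <- seq_len(nrow(ps))
    for (r in seq_len(nrow(cs))) {
      j <- avail[which.min(abs(ps$time_months[avail] - cs$time_months[r]))]
      pairs <- rbind(pairs, data.frame(
        case_id = cs$patient_id[r], control_id = ps$patient_id[j],
        stringsAsFactors = FALSE))
      avail <- setdiff(avail, j)
    }
  }
  if (length(deficits) > 0)
    stop("infeasible histology matching:\n  ",
         paste(deficits, collapse = "\n  "))
  ctl <- pool[match(pairs$control_id, pool$patient_id), ]
  tt <- two_sample_t(ctl$time_months, cases$time_months, "student")
  structure(list(
    matched_pairs = pairs,
    histology_fl_fraction_cases = mean(cases$histology == "FL"),
    histology_fl_fraction_controls = mean(ctl$histology == "FL"),
    time_mean_cases = mean(cases$time_months),
    time_mean_controls = mean(ctl$time_months),
    time_p_value = tt$p), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("Matched %d case-control pairs\n", nrow(x$matched_pairs)))
  cat(sprintf("  FL fraction: cases %.3f vs controls %.3f\n",
              x$histology_fl_fraction_cases, x$histology_fl_fraction_controls))
  cat(sprintf("  time (months): cases %.1f vs controls %.1f (t-test p = %.3f)\n",
              x$time_mean_cases, x$time_mean_controls, x$time_p_value))
  invisible(x)
}
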