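#' Cohort attrition bookkeeping
#'
#' Accounts for a longitudinal cohort's attrition from recruitment to the
#' analysis sample: subjects lost after a single assessment (with reasons)
#' and, of the remainder, how many have multiple imaging follow-ups. The
#' published design this package emulates recruited 121 patients, of whom
#' 18 attended only one assessment (death 7, withdrawal 6, moved 1, lost to
#' follow-up 2, partial testing 2), leaving 103 with repeat cognition of
#' whom 99 had repeat MRI.
#'
#' @param recruited number recruited at baseline.
#' @param single_visit_reasons named integer vector of reasons for
#'   attending only one assessment.
#' @param with_multiple_mri number of the multi-assessment subjects with
#'   repeat MRI.
#' @return list: `n_single_visit`, `n_multiple_assessment`,
#'   `n_analysis_sample`.
#' @export
attrition_summary <- function(recruited, single_visit_reasons,
                              with_multiple_mri) {
  n_single <- sum(single_visit_reasons)
  n_multi <- recruited - n_single
  if (with_multiple_mri > n_multi) {
    stop("analysis sample cannot exceed the multi-assessment sample")
  }
  list(n_single_visit = n_single,
       n_multiple_assessment = n_multi,
       n_analysis_sample = with_multiple_mri)
}

#' Conversion fraction as a printed percentage
#'
#' @param n_converted converters.
#' @param n_total cohort size.
#' @param digits decimal places for the printed percentage (default 1).
#' @return percentage, rounded as printed.
#' @export
conversion_rate <- function(n_converted, n_total, digits = 1) {
  round(100 * n_converted / n_total, digits)
}
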