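# Published summary counts from the national internal validation of the
# NHS England AKI algorithm against UK Renal Registry submissions
# (December 2014 - September 2020). These printed aggregates are the only
# patient-free surface of that audit and serve as reference inputs for the
# agreement machinery; row-level registry data are not redistributable.

#' Published local-vs-central alert cross-tabulation
#'
#' The 4x4 matrix of raw frequencies of local laboratory alert stages
#' (rows, 0--3; stage 0 inferred from alert absence after each laboratory's
#' live date) against centrally recomputed stages (columns, 0--3), pooled
#' over 9,096,667 creatinine results from English laboratories submitting
#' to the UK Renal Registry.
#'
#' @return `aki_confusion` counts matrix
#' @export
#' @examples
#' gwet_ac1(ukrr_alert_matrix())$coefficient
ukrr_alert_matrix <- function() {
  m <- matrix(c(
    7260258, 165802,  46541,  44433,
     167922, 788731,  21288,  10343,
      30252,  23711, 229065,   7970,
      30522,  63430,  45053, 161346),
    nrow = 4, byrow = TRUE,
    dimnames = list(local = 0:3, central = 0:3))
  as_confusion(m)
}

#' Published alert descriptives
#'
#' Stage counts of nonzero alerts in the same national audit: local
#' laboratory alerts as received by the registry, and the corresponding
#' centrally recomputed alerts.
#'
#' @return list with `local` and `central` (named stage-count vectors for
#'   stages 1--3), `local_total`, `central_total`, `n_patients`
#' @export
ukrr_alert_summary <- function() {
  list(
    local = c(`1` = 988284, `2` = 290998, `3` = 300351),
    central = c(`1` = 1067239, `2` = 349405, `3` = 230206),
    local_total = 1579633,   # sum of the published stage counts
    central_total = 1646850,
    n_patients = 475634
  )
}
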