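#' Pipeline configuration
#'
#' Every numeric threshold of the detection algorithm and every behavioural
#' toggle of the pipeline lives in one nested list so that "variant local
#' algorithm" experiments can override any of them. Values not supplied keep
#' their defaults.
#'
#' The `engine` block holds the staging rules:
#' \describe{
#'   \item{ratio_stage1/2/3}{C1:reference-value ratio cut-offs (1.5, 2, 3);
#'     the 1.5 and 3 boundaries are inclusive.}
#'   \item{delta48_umol}{absolute 48-hour rise threshold, strict
#'     (> 26 umol/L).}
#'   \item{high_c1_umol, high_c1_enabled}{escalation to stage 3 when the
#'     ratio criterion for stage 1 is met and the index creatinine is at
#'     least 354 umol/L; on by default, gated because it comes from the
#'     published flowchart rather than the KDIGO core rules.}
#'   \item{rv1_days, rv2_days, delta_hours}{look-back windows: RV1 is the
#'     lowest result in the open interval (t-7d, t), RV2 the median over
#'     [t-365d, t-7d], the 48-h comparator the lowest over (t-48h, t).}
#'   \item{ratio_mode}{"both" evaluates C1/RV1 and C1/RV2 and stages on the
#'     larger ratio; "prefer_rv1" uses RV1 when available.}
#'   \item{match_tolerance_hours}{window for linking a received alert to the
#'     creatinine result that fired it (same patient and laboratory).}
#' }
#'
#' The `io` block: physiologic creatinine bounds, the adult age window
#' (inclusive 18--99 completed years), the fatal reject-rate threshold, and
#' whether kidney-replacement-therapy censoring also drops creatinine rows.
#'
#' @param ... named overrides, merged recursively (e.g.
#'   `akival_config(engine = list(high_c1_enabled = FALSE))`).
#' @return nested configuration list of class `akival_config`
#' @export
#' @examples
#' cfg <- akival_config(engine = list(ratio_mode = "prefer_rv1"))
#' cfg$engine$ratio_mode
akival_config <- function(...) {
  base <- list(
    engine = list(
      ratio_stage1 = 1.5,
      ratio_stage2 = 2,
      ratio_stage3 = 3,
      delta48_umol = 26,
      high_c1_umol = 354,
      high_c1_enabled = TRUE,
      rv1_days = 7,
      rv2_days = 365,
      delta_hours = 48,
      ratio_mode = "both",
      match_tolerance_hours = 24
    ),
    io = list(
      scr_max = 4000,
      reject_threshold = 0.05,
      age_min = 18,
      age_max = 99,
      krt_drop_scr = FALSE
    ),
    agreement = list(
      weights = "ordinal",
      conf_level = 0.95
    )
  )
  cfg <- merge_config(base, list(...))
  structure(cfg, class = c("akival_config", "list"))
}

merge_config <- function(base, override) {
  if (length(override) == 0) return(base)
  stopifnot(!is.null(names(override)), all(nzchar(names(override))))
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a YAML configuration file
#'
#' Settings found in the file override `akival_config()` defaults; every
#' effective toggle is echoed to the log when `verbose = TRUE` so that a run
#' is self-describing.
#'
#' @param path YAML file
#' @param verbose echo the merged configuration via [message()]
#' @return `akival_config` list
#' @export
read_config <- function(path, verbose = FALSE) {
  stopifnot(file.exists(path))
  raw <- yaml::read_yaml(path)
  cfg <- do.call(akival_config, raw[intersect(names(raw), c("engine", "io", "agreement"))])
  extra <- raw[setdiff(names(raw), c("engine", "io", "agreement"))]
  cfg[names(extra)] <- extra
  if (verbose) echo_config(cfg)
  cfg
}

echo_config <- function(cfg, prefix = "config") {
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    key <- paste0(prefix, ".", nm)
    if (is.list(v)) echo_config(v, key)
    else message(key, " = ", paste(v, collapse = ","))
  }
  invisible(cfg)
}
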