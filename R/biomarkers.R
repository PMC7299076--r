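#' Ejection fraction
#'
#' `EF = 100 (EDV - ESV)/EDV` (%). An end-systolic volume exceeding the
#' end-diastolic volume yields a negative EF with a warning rather than an
#' error, so sweeps over degenerate parameter sets are not interrupted.
#'
#' @param edv end-diastolic volume (ml, > 0).
#' @param esv end-systolic volume (ml, >= 0).
#' @return percentage.
#' @examples
#' ejection_fraction(160, 80)  # 50
#' @export
ejection_fraction <- function(edv, esv) {
  if (any(edv <= 0)) abort("EDV must be positive.")
  if (any(esv < 0)) abort("ESV must be non-negative.")
  if (any(esv > edv)) warn("ESV exceeds EDV: negative ejection fraction.")
  100 * (edv - esv) / edv
}

#' End-systolic pressure
#'
#' The maximum ventricular pressure over a heartbeat.
#'
#' @param p_endo_trace numeric vector of cavity pressures (mmHg).
#' @return mmHg.
#' @export
end_systolic_pressure <- function(p_endo_trace) {
  if (length(p_endo_trace) == 0L) abort("empty pressure trace.")
  max(p_endo_trace)
}

#' Longitudinal fractional shortening
#'
#' `LFS = 100 (L0 - L)/L0` (%), with `L` the apico-basal cavity length at
#' the end of the ejection phase. Lengthening gives a negative value.
#'
#' @param l0 reference length (> 0).
#' @param l length at end of ejection.
#' @return percentage.
#' @export
longitudinal_fractional_shortening <- function(l0, l) {
  if (any(l0 <= 0)) abort("L0 must be positive.")
  100 * (l0 - l) / l0
}

#' Wall thickening
#'
#' `WT = 100 (T - T0)/T0` (%), with thickness evaluated between paired
#' endocardial/epicardial points at fixed reference height; thinning gives
#' a negative value. Pairing at the reference height is known to bias WT
#' (the pairing height changes during contraction); it is kept as the
#' framework's definition, with the bias documented.
#'
#' @param t0 reference wall thickness (> 0).
#' @param t thickness at end of ejection.
#' @return percentage.
#' @export
wall_thickening <- function(t0, t) {
  if (any(t0 <= 0)) abort("T0 must be positive.")
  100 * (t - t0) / t0
}

#' Classify biomarkers against healthy ranges
#'
#' Labels each biomarker as below / in / above its clinical healthy range
#' and adds the ejection-fraction-based binary classification: `healthy`
#' when EF >= 40%, `diseased` below; plus an indicator for EF < 35%, the
#' implantable-cardioverter-defibrillator guideline threshold.
#'
#' @param bm one-row data frame (or named list) with `EF`, `ESP`, `LFS`,
#'   `WT`.
#' @param ranges tibble of ranges as from [healthy_ranges()].
#' @param ef_threshold healthy/diseased EF split (default 40).
#' @param icd_threshold device-guideline EF threshold (default 35).
#' @return tibble with columns `biomarker`, `value`, `lower`, `upper`,
#'   `status`, plus attributes `ef_class` and `below_icd_threshold`.
#' @export
classify_health <- function(bm, ranges = healthy_ranges(),
                            ef_threshold = 40, icd_threshold = 35) {
  bm <- as.list(bm)
  need <- c("EF", "ESP", "LFS", "WT")
  miss <- setdiff(need, names(bm))
  if (length(miss)) abort(paste("missing biomarkers:", paste(miss, collapse = ", ")))
  out <- dplyr::mutate(
    dplyr::left_join(
      tibble::tibble(biomarker = need,
                     value = vapply(bm[need], as.numeric, numeric(1))),
      ranges, by = "biomarker"
    ),
    status = dplyr::case_when(
      .data$value < .data$lower ~ "below",
      .data$value > .data$upper ~ "above",
      TRUE ~ "in"
    )
  )
  attr(out, "ef_class") <- if (bm$EF >= ef_threshold) "healthy" else "diseased"
  attr(out, "below_icd_threshold") <- bm$EF < icd_threshold
  out
}
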