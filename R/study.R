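#' Map a sensitivity design onto lumped-cycle biomarkers
#'
#' Runs one lumped-ventricle cardiac cycle per design row and collects the
#' four mechanical biomarkers. Design columns are the shipped sensitivity
#' parameters: `P0`, `P_ej`, `C`, `R` (circulation), `kort2`
#' (orthotropic activation), `T_ref` (kPa), `K` (kPa) and `a_s` (Pa)
#' (constitutive), while `k_epi` and `phi` have no lumped spherical
#' analogue and are accepted as inert pass-throughs (recorded in the
#' `inert_parameters` attribute). The relaxation-to-filling threshold
#' tracks the swept `P0`.
#'
#' Rows whose cycle fails (no ejection, or a numerical failure) yield
#' biomarker values of 0/NA and `completed = FALSE`; they are reported,
#' not dropped, so the sensitivity layer can apply its own mask.
#'
#' @param design a [oat_design()] or [lhs_design()] tibble.
#' @param geom a [lumped_geometry()].
#' @param cell a [cell_system()]; `T_ref` is overridden per row.
#' @param dt time step (ms).
#' @param n_quad wall quadrature points.
#' @param progress print a dot per run.
#' @return tibble with one row per design row: `EF`, `ESP`, `LFS`, `WT`,
#'   `EDV`, `ESV`, `stroke_volume`, `completed`.
#' @export
run_biomarker_study <- function(design, geom = lumped_geometry(),
                                cell = cell_system(), dt = 1,
                                n_quad = 1L, progress = FALSE) {
  X <- dplyr::select(tibble::as_tibble(design),
                     -dplyr::any_of(c(".param", ".level")))
  rows <- purrr::map(seq_len(nrow(X)), function(i) {
    pr <- as.list(X[i, ])
    bm <- tryCatch(
      cycle_biomarkers(run_design_cycle(pr, geom, cell, dt, n_quad)),
      error = function(e) {
        tibble::tibble(EF = NA_real_, ESP = NA_real_, LFS = NA_real_,
                       WT = NA_real_, EDV = geom$edv, ESV = NA_real_,
                       stroke_volume = NA_real_, completed = FALSE)
      }
    )
    if (progress) cat(".")
    bm
  })
  if (progress) cat("\n")
  out <- dplyr::bind_rows(rows)
  attr(out, "inert_parameters") <- intersect(c("k_epi", "phi"), names(X))
  out
}

# build per-row parameter objects and run one cycle
run_design_cycle <- function(pr, geom, cell, dt, n_quad) {
  land <- cell$land
  if (!is.null(pr[["T_ref"]])) land <- land_params(t_ref = pr[["T_ref"]] * 1000)  # kPa -> Pa
  passive <- ho_params()
  pov <- list()
  if (!is.null(pr[["K"]])) pov$K <- pr[["K"]] * 1000                              # kPa -> Pa
  if (!is.null(pr[["a_s"]])) pov$as <- pr[["a_s"]]                                # Pa
  if (length(pov)) passive <- do.call(ho_params, pov)
  cov <- list()
  if (!is.null(pr[["P0"]])) { cov$p0 <- pr[["P0"]]; cov$p_fill_threshold <- pr[["P0"]] }
  if (!is.null(pr[["P_ej"]])) cov$p_ej <- pr[["P_ej"]]
  if (!is.null(pr[["C"]])) cov$compliance <- pr[["C"]]
  if (!is.null(pr[["R"]])) cov$resistance <- pr[["R"]]
  circ <- do.call(circulation_params, cov)
  cell2 <- cell_system(land = land, coupling = cell$coupling, driver = cell$driver)
  run_cardiac_cycle(geom = geom, cell = cell2, circ = circ, passive = passive,
                    kort2 = if (is.null(pr[["kort2"]])) 0 else pr[["kort2"]],
                    dt = dt, n_quad = n_quad)
}

#' One-at-a-time sweep of a single parameter
#'
#' Convenience wrapper building a reduced design that varies one shipped
#' parameter over `n_val` grid levels (others at baseline) and returning
#' its biomarkers joined to the swept values.
#'
#' @param name parameter name from [sensitivity_param_table()].
#' @param n_val number of levels.
#' @param specs parameter table.
#' @inheritParams run_biomarker_study
#' @return tibble: swept `value` plus the biomarker columns.
#' @export
sweep_parameter <- function(name, n_val = 5, specs = sensitivity_param_table(),
                            geom = lumped_geometry(), cell = cell_system(),
                            dt = 1, n_quad = 1L) {
  spec <- specs[specs$name == name, ]
  if (nrow(spec) != 1L) abort(paste0("unknown parameter: ", name))
  design <- oat_design(spec, n_val = n_val)
  bm <- run_biomarker_study(design, geom, cell, dt, n_quad)
  dplyr::bind_cols(tibble::tibble(value = design[[name]]), bm)
}
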