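# broom-style tidiers for the package's result objects

#' Tidy a simulated cardiac cycle
#'
#' Returns the full time-resolved trace as a tibble (`t`, `phase`,
#' `p_endo`, `p_art`, `v_endo`, `sigma_0`, `lambda`, `wall_thickness`,
#' `cavity_length`, `t_act`, `ca_i`).
#'
#' @param x a `cardiac_cycle` from [run_cardiac_cycle()].
#' @param ... ignored.
#' @return tibble.
#' @export
tidy.cardiac_cycle <- function(x, ...) x$trace

#' One-row summary of a cardiac cycle
#'
#' The four clinical biomarkers plus volumes and completion status.
#'
#' @inheritParams tidy.cardiac_cycle
#' @return one-row tibble.
#' @export
glance.cardiac_cycle <- function(x, ...) cycle_biomarkers(x)

#' Tidy a PRCC sensitivity report
#'
#' @param x a `prcc_report`.
#' @param ... ignored.
#' @return tibble with `parameter`, `biomarker`, `prcc`, `p_value`,
#'   `significant`, `sign`.
#' @export
tidy.prcc_report <- function(x, ...) tibble::as_tibble(x)

#' One-row summary of a PRCC report
#'
#' @inheritParams tidy.prcc_report
#' @return tibble with run counts, the significance level and the number of
#'   significant cells.
#' @export
glance.prcc_report <- function(x, ...) {
  tibble::tibble(
    n_used = attr(x, "n_used"),
    n_failed = attr(x, "n_failed"),
    alpha = attr(x, "alpha"),
    n_significant = sum(x$significant)
  )
}

#' Tidy a paced-cell result
#'
#' The beat-by-beat convergence trace.
#'
#' @param x a `paced_cell` from [pace_to_steady_state()].
#' @param ... ignored.
#' @return tibble with `beat`, `max_change`.
#' @export
tidy.paced_cell <- function(x, ...) x$trace

#' One-row summary of a paced cell
#'
#' @inheritParams tidy.paced_cell
#' @return tibble with the final state and convergence measure.
#' @export
glance.paced_cell <- function(x, ...) {
  dplyr::bind_cols(
    tibble::as_tibble(as.list(x$state)),
    tibble::tibble(final_change = tail(x$trace$max_change, 1),
                   n_beats = nrow(x$trace), bpm = x$bpm)
  )
}

#' @export
print.cardiac_cycle <- function(x, ...) {
  bm <- cycle_biomarkers(x)
  cat("<cardiac_cycle> phases:", paste(x$phases_reached, collapse = " -> "),
      if (!x$completed) "(incomplete)" else "", "\n")
  cat(sprintf("  EF %.1f%%  ESP %.1f mmHg  LFS %.1f%%  WT %.1f%%  (EDV %.1f ml, ESV %.1f ml)\n",
              bm$EF, bm$ESP, bm$LFS, bm$WT, bm$EDV, bm$ESV))
  invisible(x)
}

#' @export
print.prcc_report <- function(x, ...) {
  cat("<prcc_report> n =", attr(x, "n_used"), "runs (", attr(x, "n_failed"),
      "failed ), alpha =", attr(x, "alpha"), "\n")
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Write / read a cycle trace as CSV
#'
#' Pressure-volume trace CSV with a provenance comment line (package
#' version) and columns `t, phase, p_endo, p_art, v_endo, sigma_0,
#' wall_thickness, lambda, ...`.
#'
#' @param cycle a `cardiac_cycle`.
#' @param path output path.
#' @return `path` invisibly (writer); tibble (reader).
#' @export
write_trace_csv <- function(cycle, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- tryCatch(as.character(utils::packageVersion("cardioem")),
                  error = function(e) "dev")
  writeLines(paste0("# cardioem ", ver, " cardiac-cycle trace"), con)
  utils::write.csv(cycle$trace, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
}
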