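# ggplot2 visualisations

#' Pressure-volume loop of a simulated cycle
#'
#' The PV trajectory in the (volume, pressure) plane, coloured by phase;
#' a healthy loop is traversed clockwise (net positive stroke work).
#'
#' @param object a `cardiac_cycle`.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.cardiac_cycle <- function(object, ...) {
  tr <- object$trace
  ggplot(tr, aes(x = .data$v_endo, y = .data$p_endo, colour = .data$phase)) +
    geom_path(linewidth = 0.7) +
    labs(x = "cavity volume (ml)", y = "cavity pressure (mmHg)",
         colour = "phase", title = "Pressure-volume loop") +
    theme_minimal()
}

#' Time courses of a simulated cycle
#'
#' Pressure, volume, active tension and calcium against time.
#'
#' @param cycle a `cardiac_cycle`.
#' @return a ggplot object.
#' @export
plot_cycle_timecourse <- function(cycle) {
  tr <- tidyr::pivot_longer(
    dplyr::select(cycle$trace, "t", "p_endo", "v_endo", "t_act", "ca_i"),
    -"t", names_to = "quantity", values_to = "value"
  )
  ggplot(tr, aes(x = .data$t, y = .data$value)) +
    geom_line() +
    facet_wrap(~ .data$quantity, scales = "free_y", ncol = 1) +
    labs(x = "time (ms)", y = NULL) +
    theme_minimal()
}

#' PRCC heat map
#'
#' Parameter-by-biomarker PRCC values with `+`/`-` marks on the
#' statistically significant cells.
#'
#' @param object a `prcc_report`.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.prcc_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot(df, aes(x = .data$biomarker, y = .data$parameter, fill = .data$prcc)) +
    geom_tile() +
    geom_text(aes(label = .data$sign)) +
    scale_fill_gradient2(limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "PRCC") +
    theme_minimal()
}

#' Pacing convergence plot
#'
#' Beat-to-beat maximal state change on a log scale.
#'
#' @param object a `paced_cell`.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.paced_cell <- function(object, ...) {
  ggplot(object$trace, aes(x = .data$beat, y = .data$max_change)) +
    geom_line() +
    ggplot2::scale_y_log10() +
    labs(x = "beat", y = "max |state change| per beat") +
    theme_minimal()
}
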