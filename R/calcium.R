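#' Calcium-coupling parameters
#'
#' Buffering and scaling constants for the intracellular calcium balance:
#' calmodulin buffer concentration `cmdn_bar` and dissociation constant
#' `k_cmdn`, and the maximal troponin concentration `trpn_max` that scales
#' the contraction-to-calcium feedback. All in uM.
#'
#' @param ... named overrides.
#' @return list of class `ca_coupling_params`.
#' @export
ca_coupling_params <- function(...) {
  p <- default_params()$calcium
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown)) abort(paste("unknown calcium parameter(s):", paste(unknown, collapse = ", ")))
  p[names(ov)] <- ov
  if (any(unlist(p) < 0)) abort("calcium coupling parameters must be non-negative.")
  structure(p, class = "ca_coupling_params")
}

#' Buffered intracellular calcium balance
#'
#' The free-calcium rate with instantaneous calmodulin buffering and the
#' troponin feedback from the contraction model:
#' \deqn{\frac{d[Ca]_i}{dt} = \beta_{buf}([Ca]_i)\,
#'   \left[\Sigma_{flux} - TRPN_{max}\frac{dCaTRPN}{dt}\right],\qquad
#'   \beta_{buf} = \left[1 + \frac{\overline{CMDN}\,K_{CMDN}}{([Ca]_i+K_{CMDN})^2}\right]^{-1}.}
#' `flux_sum` aggregates all membrane and sarcoplasmic-reticulum fluxes; it
#' is an opaque input supplied by whichever driver or ionic adapter is
#' attached, so this function is agnostic to the grouping of individual
#' currents.
#'
#' @param ca_i free calcium (uM, > 0).
#' @param flux_sum net non-troponin calcium flux (uM/ms).
#' @param dCaTRPN_dt troponin binding rate (1/ms).
#' @param p a [ca_coupling_params()].
#' @return calcium rate (uM/ms).
#' @export
buffered_ca_rhs <- function(ca_i, flux_sum, dCaTRPN_dt, p = ca_coupling_params()) {
  if (any(ca_i <= 0)) abort("ca_i must be positive.")
  beta_buf <- 1 / (1 + p$cmdn_bar * p$k_cmdn / (ca_i + p$k_cmdn)^2)
  beta_buf * (flux_sum - p$trpn_max * dCaTRPN_dt)
}

#' Synthetic calcium transient specification
#'
#' Parameters of the periodic synthetic calcium driver standing in for a
#' full ionic model: diastolic level, amplitude, time to peak, decay time
#' constant and beat period. Defaults emulate a healthy human ventricular
#' transient at 70 bpm.
#'
#' @param ... named overrides (`diastolic`, `amplitude`, `time_to_peak`,
#'   `tau_decay`, `period`).
#' @return list of class `ca_driver_spec`.
#' @export
ca_driver_spec <- function(...) {
  p <- default_params()$driver
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown)) abort(paste("unknown driver parameter(s):", paste(unknown, collapse = ", ")))
  p[names(ov)] <- ov
  if (p$amplitude <= 0 || p$period <= 0) abort("amplitude and period must be positive.")
  # shape: double-exponential rise/decay, pinned to zero at both beat ends so
  # the transient is continuous across the wrap, then normalised to unit peak
  tau1 <- p$tau_decay
  tau2 <- p$time_to_peak / 3
  raw <- function(s) exp(-s / tau1) - exp(-s / tau2)
  gP <- raw(p$period)
  shape <- function(s) raw(s) - gP * s / p$period
  smax <- max(shape(seq(0, p$period, length.out = 4096)))
  p$shape <- function(s) shape(s) / smax
  structure(p, class = "ca_driver_spec")
}

#' Synthetic periodic calcium transient
#'
#' Evaluates the driver at time `t` (ms): diastolic level plus amplitude
#' times a rise-decay shape, exactly periodic in the beat period.
#'
#' @param t time (ms, >= 0), vectorised.
#' @param spec a [ca_driver_spec()].
#' @return calcium concentration (uM).
#' @export
synthetic_transient <- function(t, spec = ca_driver_spec()) {
  if (any(t < 0)) abort("t must be non-negative.")
  s <- t %% spec$period
  spec$diastolic + spec$amplitude * spec$shape(s)
}

#' Coupled contraction-calcium cell system
#'
#' Bundles the Land contraction model with the buffered calcium balance and
#' a flux driver. In the default synthetic mode the driver supplies the
#' non-troponin flux that would, in the absence of troponin feedback,
#' reproduce the synthetic transient; the troponin term then perturbs the
#' free calcium, giving genuine bidirectional coupling.
#'
#' @param land a [land_params()].
#' @param coupling a [ca_coupling_params()].
#' @param driver a [ca_driver_spec()].
#' @return list of class `cell_system`.
#' @export
cell_system <- function(land = land_params(), coupling = ca_coupling_params(),
                        driver = ca_driver_spec()) {
  structure(list(land = land, coupling = coupling, driver = driver),
            class = "cell_system")
}

# full cell RHS: 6 Land states + free calcium; lam clamped or prescribed
cell_rhs <- function(t, y, parms, cell, lam_fn, dlam_fn) {
  q <- y[1:6]
  names(q) <- c("S", "W", "CaTRPN", "B", "zeta_s", "zeta_w")
  ca <- max(y[[7]], 1e-6)
  lam <- lam_fn(t); dlam <- dlam_fn(t)
  dq <- land_rhs(q, ca, lam, dlam, cell$land)
  # target-transient flux: what the synthetic transient alone would require
  eps <- 1e-3
  ca_tgt <- synthetic_transient(t, cell$driver)
  dca_tgt <- (synthetic_transient(t + eps, cell$driver) -
                synthetic_transient(max(t - eps, 0), cell$driver)) / (2 * eps)
  beta_tgt <- 1 / (1 + cell$coupling$cmdn_bar * cell$coupling$k_cmdn /
                     (ca_tgt + cell$coupling$k_cmdn)^2)
  flux <- dca_tgt / beta_tgt + 0.1 * (ca_tgt - ca)  # weak relaxation to target
  dca <- buffered_ca_rhs(ca, flux, dq[["CaTRPN"]], cell$coupling)
  list(c(dq, dca))
}

#' Pace a coupled cell to periodic steady state
#'
#' Integrates the coupled contraction-calcium cell at fixed stretch
#' (`lambda = 1`, `lambda_dot = 0`) for `n_beats` beats at `bpm`, recording
#' the end-of-beat state after every beat. The convergence trace is the
#' maximum absolute state change between consecutive end-of-beat snapshots.
#' The framework default is 70 bpm for 1000 beats; the synthetic driver
#' reaches beat-to-beat changes below 1e-6 far sooner, so tests and desk
#' runs may use fewer beats.
#'
#' @param cell a [cell_system()].
#' @param bpm pacing rate (beats per minute).
#' @param n_beats number of beats to integrate.
#' @param q0 initial Land state.
#' @param ca0 initial free calcium (uM; default, the driver's diastolic).
#' @return object of class `paced_cell`: list with `state` (named end state
#'   vector incl. `ca_i`), `trace` (tibble beat/max_change), `bpm`, `period`.
#' @export
pace_to_steady_state <- function(cell = cell_system(), bpm = 70, n_beats = 1000,
                                 q0 = land_state(), ca0 = NULL) {
  period <- 60000 / bpm
  if (is.null(ca0)) ca0 <- cell$driver$diastolic
  y <- c(unclass(q0), ca_i = ca0)
  lam_fn <- function(t) 1; dlam_fn <- function(t) 0
  prev <- y
  changes <- numeric(n_beats)
  for (b in seq_len(n_beats)) {
    out <- deSolve::lsoda(y, c(0, period), cell_rhs, parms = NULL,
                          cell = cell, lam_fn = lam_fn, dlam_fn = dlam_fn,
                          rtol = 1e-8, atol = 1e-10)
    y <- out[nrow(out), -1]
    if (any(!is.finite(y))) {
      abort(paste0("cell state diverged during pacing at beat ", b, "."))
    }
    changes[b] <- max(abs(y - prev))
    prev <- y
  }
  names(y) <- c("S", "W", "CaTRPN", "B", "zeta_s", "zeta_w", "ca_i")
  structure(
    list(
      state = y,
      trace = tibble::tibble(beat = seq_len(n_beats), max_change = changes),
      bpm = bpm, period = period
    ),
    class = "paced_cell"
  )
}

#' Write a cell state snapshot
#'
#' Columnar text snapshot, one row per state variable (`variable value`),
#' machine-parsable and round-trippable with [read_cell_snapshot()].
#'
#' @param state named numeric vector (e.g. `paced_cell$state`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cell_snapshot <- function(state, path) {
  df <- data.frame(variable = names(state), value = as.numeric(state))
  utils::write.table(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cell_snapshot
#' @export
read_cell_snapshot <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  setNames(df$value, df$variable)
}
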