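#' Unit conversions for pressures and stresses
#'
#' The package works in SI pascals for stresses internally, while the
#' circulation layer exposes clinical mmHg, and some published parameter
#' tables use barye (Ba, CGS: 1 Ba = 0.1 Pa). These helpers centralise the
#' conversion constants so no magic numbers appear in model code.
#'
#' @param x numeric vector of values to convert.
#' @return numeric vector in the target unit.
#' @examples
#' mmhg_to_pa(1)   # 133.322...
#' pa_to_mmhg(mmhg_to_pa(20))
#' @name units
NULL

PA_PER_MMHG <- 133.322387415
PA_PER_BA <- 0.1

#' @rdname units
#' @export
mmhg_to_pa <- function(x) x * PA_PER_MMHG

#' @rdname units
#' @export
pa_to_mmhg <- function(x) x / PA_PER_MMHG

#' @rdname units
#' @export
ba_to_pa <- function(x) x * PA_PER_BA

#' @rdname units
#' @export
pa_to_ba <- function(x) x / PA_PER_BA

#' @rdname units
#' @export
kpa_to_mmhg <- function(x) pa_to_mmhg(x * 1000)

#' @rdname units
#' @export
mmhg_to_kpa <- function(x) mmhg_to_pa(x) / 1000
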