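# Parameter file handling: the shipped defaults plus user configuration
# overlays. A config is a plain nested list mirroring the YAML structure.

the <- new.env(parent = emptyenv())

#' Default model parameters
#'
#' Reads (and caches) the shipped parameter file, which holds all module
#' parameter blocks with their units and provenance comments.
#'
#' @return nested named list of parameter blocks.
#' @export
default_params <- function() {
  if (is.null(the$defaults)) {
    path <- system.file("extdata", "default_params.yaml", package = "cardioem")
    if (path == "") {
      # during development (package loaded but not installed)
      path <- file.path("inst", "extdata", "default_params.yaml")
    }
    the$defaults <- yaml::read_yaml(path)
  }
  the$defaults
}

#' Sensitivity-analysis parameter table
#'
#' The ten mechanical parameters of the sensitivity study with their ranges,
#' baselines and units, as a tibble. The baseline of `R` (750) sits at the
#' top of its range (75-750); this is preserved as shipped, with a warning
#' attribute rather than a rejection.
#'
#' @return tibble with columns `name`, `lower`, `upper`, `baseline`,
#'   `units`, `submodel`.
#' @export
sensitivity_param_table <- function() {
  path <- system.file("extdata", "sensitivity_params.csv", package = "cardioem")
  if (path == "") path <- file.path("inst", "extdata", "sensitivity_params.csv")
  tb <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  validate_param_specs(tb)
  tb
}

#' Healthy biomarker ranges
#'
#' Clinical healthy ranges for the four mechanical biomarkers.
#'
#' @return tibble with columns `biomarker`, `lower`, `upper`, `units`.
#' @export
healthy_ranges <- function() {
  path <- system.file("extdata", "healthy_ranges.csv", package = "cardioem")
  if (path == "") path <- file.path("inst", "extdata", "healthy_ranges.csv")
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

validate_param_specs <- function(specs) {
  stopifnot(is.data.frame(specs))
  need <- c("name", "lower", "upper", "baseline")
  miss <- setdiff(need, names(specs))
  if (length(miss)) abort(paste("parameter table lacks columns:", paste(miss, collapse = ", ")))
  if (any(specs$upper <= specs$lower)) abort("parameter ranges must have upper > lower.")
  off <- specs$baseline < specs$lower | specs$baseline > specs$upper
  if (any(off)) {
    warn(paste(
      "baseline outside its range for:",
      paste(specs$name[off], collapse = ", "),
      "(kept as shipped)"
    ))
  }
  invisible(specs)
}

# deep-merge override list `ov` into defaults `base`; unknown keys are errors
merge_config <- function(base, ov, path = character()) {
  for (nm in names(ov)) {
    here <- c(path, nm)
    if (!nm %in% names(base)) {
      abort(paste0("unknown configuration key: ", paste(here, collapse = "$")))
    }
    if (is.list(base[[nm]]) && is.list(ov[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], ov[[nm]], here)
    } else {
      base[[nm]] <- ov[[nm]]
    }
  }
  base
}

#' Load a run configuration
#'
#' Reads a YAML configuration file, overlays it on the shipped defaults and
#' validates cross-field invariants. Unknown keys are a hard error so typos
#' cannot silently fall back to defaults. An empty (or missing-content) file
#' yields the pure baseline configuration.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @return validated nested list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_params()
  if (!is.null(path)) {
    ov <- yaml::read_yaml(path)
    if (!is.null(ov)) cfg <- merge_config(cfg, ov)
  }
  validate_config(cfg)
  structure(cfg, class = c("run_config", "list"))
}

#' Save a run configuration
#'
#' Writes the resolved configuration as YAML next to a run's outputs so that
#' every run is reproducible from its emitted configuration plus seed.
#'
#' @param cfg a configuration list.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

validate_config <- function(cfg) {
  cc <- cfg$circulation
  if (cc$p0 <= 0) abort("circulation$p0 must be positive.")
  if (cc$p_ej <= cc$p0) abort("circulation$p_ej must exceed circulation$p0.")
  if (cc$compliance <= 0 || cc$resistance <= 0 || cc$gamma <= 0) {
    abort("circulation compliance, resistance and gamma must be positive.")
  }
  pr <- cfg$propagation
  if (!(pr$sigma_f >= pr$sigma_s && pr$sigma_s >= pr$sigma_n && pr$sigma_n > 0)) {
    abort("diffusivities must satisfy sigma_f >= sigma_s >= sigma_n > 0.")
  }
  if (cfg$geometry$edv <= 0 || cfg$geometry$wall_thickness <= 0) {
    abort("geometry edv and wall_thickness must be positive.")
  }
  if (any(unlist(cfg$passive) <= 0)) abort("passive parameters must all be positive.")
  invisible(cfg)
}
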