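# Run configuration: a single nested list describing scenario, acquisition,
# inversion settings and outputs, round-tripping losslessly through YAML.

.config_defaults <- function() {
  list(
    scenario = list(
      frequency = 1e9,
      extent = c(0.14, 0.14, 0.14),
      coupling = list(eps_r = 20, sigma = 0),
      layers = list(
        list(shape = "sphere", center = c(0, 0, 0), semi_axes = 0.05,
             eps_r = 45.37, sigma = 0.77)
      ),
      stroke = list(enabled = TRUE, center = c(0.018, 0.018, 0),
                    semi_axes = c(0.015, 0.012, 0.012),
                    eps_r = 64.41, sigma = 1.58)
    ),
    acquisition = list(
      n_antennas = 8L, radius = 0.06, source = "dipole",
      polarization = c(0, 0, 1), ra = 0.65e-3, rb = 2.1e-3,
      h_data = 0.004, h_inv = 0.005
    ),
    inversion = list(
      variant = "novel", eval_mode = "linear", n_iter = 100L,
      doi = "all", solver_tol = 1e-12
    ),
    noise = list(snr_db = NULL, seed = 1L),
    output = list(dir = "csifem-out")
  )
}

#' Build a run configuration
#'
#' Starts from the package defaults (a 50 mm homogeneous head sphere in a
#' 140 mm box of coupling medium, 8 dipole antennas on a 60 mm equatorial
#' ring at 1 GHz, 4 mm data mesh and 5 mm inversion mesh) and overrides
#' them with the named values supplied; unknown keys are rejected.
#'
#' @param ... nested overrides, e.g.
#'   `run_config(inversion = list(variant = "standard"))`.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- .merge_config(.config_defaults(), list(...))
  validate_config(cfg)
}

.merge_config <- function(base, override, path = "") {
  for (nm in names(override)) {
    if (!nm %in% names(base)) {
      stop("unknown configuration key: ", sub("^\\.", "", paste0(path, ".",
                                                                 nm)))
    }
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]])) && nm != "layers") {
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]],
                                  paste0(path, ".", nm))
    } else {
      # base[nm] <- list(...) keeps explicit NULLs instead of deleting
      base[nm] <- list(override[[nm]])
    }
  }
  base
}

#' Validate a run configuration
#' @param cfg a configuration list.
#' @return the validated `run_config` (invisibly classed).
#' @export
validate_config <- function(cfg) {
  known <- names(.config_defaults())
  extra <- setdiff(names(cfg), known)
  if (length(extra)) stop("unknown configuration key: ", extra[1L])
  stopifnot(cfg$scenario$frequency > 0,
            length(cfg$scenario$extent) == 3L,
            cfg$acquisition$n_antennas >= 2L,
            cfg$inversion$variant %in% c("novel", "standard"),
            cfg$inversion$eval_mode %in% c("linear", "barycenter"),
            cfg$inversion$n_iter >= 1L,
            cfg$inversion$doi %in% c("all", "half"))
  structure(cfg, class = "run_config")
}

#' Read / write a configuration file
#'
#' YAML round trip; [read_config()] validates and rejects unknown keys.
#'
#' @param cfg a `run_config`.
#' @param path file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 17L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # re-merge over defaults so types/keys are checked
  cfg <- .merge_config(.config_defaults(), raw)
  validate_config(cfg)
}

# helpers turning a config into package objects -----------------------------

config_phantom <- function(cfg) {
  phantom_spec(layers = cfg$scenario$layers,
               coupling = cfg$scenario$coupling,
               frequency = cfg$scenario$frequency)
}

config_stroke <- function(cfg) {
  s <- cfg$scenario$stroke
  if (is.null(s) || !isTRUE(s$enabled)) return(NULL)
  stroke_spec(center = s$center, semi_axes = s$semi_axes,
              eps_r = s$eps_r, sigma = s$sigma)
}

config_acquisition <- function(cfg) {
  a <- cfg$acquisition
  acquisition_spec(n_antennas = a$n_antennas, radius = a$radius,
                   source = a$source, polarization = a$polarization,
                   ra = a$ra, rb = a$rb, h_data = a$h_data,
                   h_inv = a$h_inv)
}

# geometric DoI restriction: "half" keeps the half-space y >= 0 within the
# outermost phantom layer (the half-back part of the head)
config_doi_mask <- function(cfg, mesh) {
  I <- nrow(mesh$tets)
  outer_layer <- cfg$scenario$layers[[1L]]
  inside <- .inside_shape(mesh$barycenters, .normalize_shape(outer_layer))
  if (cfg$inversion$doi == "half") {
    inside & mesh$barycenters[, 2L] >= 0
  } else {
    inside
  }
}
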