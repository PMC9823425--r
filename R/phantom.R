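# Synthetic layered head phantoms and per-cell material maps.
#
# Complex relative permittivity follows the exp(+j omega t) convention,
#   eps = eps_r - j sigma / (omega eps0),
# so passive media have a non-positive imaginary part.

#' Complex relative permittivity of a lossy medium
#'
#' @param eps_r real relative permittivity (>= 1 for physical media).
#' @param sigma conductivity in S/m.
#' @param frequency frequency in Hz.
#' @return complex relative permittivity `eps_r - 1i * sigma/(omega eps0)`.
#' @export
complex_permittivity <- function(eps_r, sigma, frequency) {
  complex(real = eps_r, imaginary = -sigma / (2 * pi * frequency * .EPS0))
}

#' Squared wavenumber of a medium
#' @param eps complex relative permittivity.
#' @param frequency frequency in Hz.
#' @return complex `omega^2 mu0 eps0 eps`.
#' @export
wavenumber2 <- function(eps, frequency) {
  (2 * pi * frequency)^2 * .MU0 * .EPS0 * eps
}

#' Specify a layered phantom
#'
#' Layers are listed outermost to innermost; each later layer overrides the
#' earlier ones cell-wise.  Everything outside all layers is coupling medium.
#'
#' @param layers list of layers, each a list with `shape` ("sphere" or
#'   "ellipsoid"), `center` (length-3, metres), `semi_axes` (length-3 for an
#'   ellipsoid, scalar radius accepted for a sphere), `eps_r` and `sigma`.
#' @param coupling list with `eps_r` and `sigma` of the coupling medium.
#' @param frequency working frequency in Hz.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(layers, coupling, frequency = 1e9) {
  layers <- lapply(layers, .normalize_shape)
  for (ly in layers) {
    if (ly$eps_r < 1 || ly$sigma < 0) {
      stop("layers need eps_r >= 1 and sigma >= 0")
    }
  }
  if (coupling$eps_r < 1 || coupling$sigma < 0) {
    stop("coupling medium needs eps_r >= 1 and sigma >= 0")
  }
  structure(list(layers = layers, coupling = coupling,
                 frequency = frequency),
            class = "phantom_spec")
}

#' Specify a stroke-like inclusion
#'
#' Defaults to the dielectric properties of blood at 1 GHz
#' (`eps_r = 64.41`, `sigma = 1.58` S/m).
#'
#' @param center length-3 centre (metres).
#' @param semi_axes length-3 ellipsoid semi-axes (metres); a scalar gives a
#'   sphere.
#' @param eps_r,sigma dielectric properties of the inclusion.
#' @return a `stroke_spec` object.
#' @export
stroke_spec <- function(center, semi_axes, eps_r = 64.41, sigma = 1.58) {
  s <- .normalize_shape(list(shape = "ellipsoid", center = center,
                             semi_axes = semi_axes, eps_r = eps_r,
                             sigma = sigma))
  structure(s, class = "stroke_spec")
}

.normalize_shape <- function(ly) {
  if (length(ly$semi_axes) == 1L) ly$semi_axes <- rep(ly$semi_axes, 3L)
  stopifnot(length(ly$center) == 3L, length(ly$semi_axes) == 3L,
            all(ly$semi_axes >= 0))
  if (is.null(ly$shape)) ly$shape <- "ellipsoid"
  ly
}

.inside_shape <- function(points, shape) {
  d <- sweep(points, 2L, shape$center)
  if (any(shape$semi_axes == 0)) return(rep(FALSE, nrow(points)))
  rowSums(sweep(d, 2L, shape$semi_axes, "/")^2) <= 1
}

#' Build the per-cell material map of a phantom
#'
#' Assigns the complex relative permittivity of each tetrahedron by testing
#' its barycenter against the phantom layers (later layers override earlier
#' ones); cells outside all layers take the coupling medium.  The background
#' scenario of the map is the pure coupling medium.
#'
#' @param mesh a `tet_mesh`.
#' @param spec a [phantom_spec()].
#' @return a `material_map` with per-cell `eps_b` (background), `eps_target`
#'   and the squared wavenumbers `kb2` (background) and `k2` (target).
#' @export
build_phantom_materials <- function(mesh, spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  bb_lo <- apply(mesh$nodes, 2L, min)
  bb_hi <- apply(mesh$nodes, 2L, max)
  for (ly in spec$layers) {
    if (any(ly$center - ly$semi_axes < bb_lo) ||
        any(ly$center + ly$semi_axes > bb_hi)) {
      stop("phantom layer extends outside the mesh bounds")
    }
  }
  I <- nrow(mesh$tets)
  eps_c <- complex_permittivity(spec$coupling$eps_r, spec$coupling$sigma,
                                spec$frequency)
  eps_t <- rep(eps_c, I)
  for (ly in spec$layers) {
    inside <- .inside_shape(mesh$barycenters, ly)
    eps_t[inside] <- complex_permittivity(ly$eps_r, ly$sigma, spec$frequency)
  }
  .material_map(mesh, spec$frequency, eps_b = rep(eps_c, I),
                eps_target = eps_t)
}

.material_map <- function(mesh, frequency, eps_b, eps_target) {
  if (any(Im(eps_b) > 1e-12) || any(Im(eps_target) > 1e-12)) {
    stop("passive media require Im(eps) <= 0 under the exp(+j omega t) ",
         "convention")
  }
  structure(list(frequency = frequency,
                 eps_b = eps_b, eps_target = eps_target,
                 kb2 = wavenumber2(eps_b, frequency),
                 k2 = wavenumber2(eps_target, frequency)),
            class = "material_map")
}

#' Add a stroke-like inclusion to a material map
#'
#' Cells whose barycenter lies inside the inclusion take the inclusion's
#' permittivity in the target scenario; all other cells (and the background
#' scenario) are unchanged.
#'
#' @param materials a `material_map`.
#' @param mesh the `tet_mesh` the map was built on.
#' @param stroke a [stroke_spec()].
#' @param within optional shape (e.g. the innermost phantom layer) that must
#'   fully contain the inclusion; violation is an error.
#' @return the updated `material_map`.
#' @export
add_inclusion <- function(materials, mesh, stroke, within = NULL) {
  stopifnot(inherits(materials, "material_map"))
  if (!is.null(within)) {
    within <- .normalize_shape(within)
    # inclusion bounding box must sit inside the containing ellipsoid
    corners <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
    pts <- sweep(corners %*% diag(stroke$semi_axes), 2L, stroke$center, "+")
    if (!all(.inside_shape(pts, within))) {
      stop("inclusion is not fully inside the containing layer")
    }
  }
  inside <- .inside_shape(mesh$barycenters, stroke)
  eps_t <- materials$eps_target
  eps_t[inside] <- complex_permittivity(stroke$eps_r, stroke$sigma,
                                        materials$frequency)
  .material_map(mesh, materials$frequency, materials$eps_b, eps_t)
}

#' @export
print.material_map <- function(x, ...) {
  cat("material_map:", length(x$eps_b), "cells at",
      x$frequency / 1e9, "GHz\n")
  cat("  background eps range:", paste(signif(range(Re(x$eps_b)), 5),
                                       collapse = " .. "), "\n")
  cat("  target eps_r range:", paste(signif(range(Re(x$eps_target)), 5),
                                     collapse = " .. "), "\n")
  invisible(x)
}
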