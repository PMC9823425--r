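# TEM coaxial-port model: the modal field on the annular port surface,
# projection of fields onto the mode, S-parameter conversion, and the
# scattered-data representation used by the inversion.

#' Define a coaxial port
#'
#' The port is the annulus between radii `ra` and `rb` centred at `center`
#' and lying in the plane with unit normal `normal`.
#'
#' @param center length-3 centre (metres).
#' @param normal length-3 plane normal (normalized internally).
#' @param ra,rb inner and outer radii (metres), `0 < ra < rb`.
#' @return a `coax_port` object carrying a deterministic in-plane frame
#'   `(u, v)`.
#' @export
coax_port <- function(center, normal, ra, rb) {
  stopifnot(ra > 0, rb > ra)
  n <- normal / sqrt(sum(normal^2))
  ref <- if (abs(n[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- .cross3(ref, n)
  u <- u / sqrt(sum(u^2))
  v <- .cross3(n, u)
  structure(list(center = center, normal = n, ra = ra, rb = rb,
                 u = u, v = v),
            class = "coax_port")
}

.cross3 <- function(x, y) {
  c(x[2L] * y[3L] - x[3L] * y[2L],
    x[3L] * y[1L] - x[1L] * y[3L],
    x[1L] * y[2L] - x[2L] * y[1L])
}

#' Evaluate the coaxial TEM modal field
#'
#' The normalized TEM mode of a coaxial aperture,
#' `e_TEM = rho_hat / (rho * sqrt(2 pi ln(rb/ra)))`, radial in the port plane
#' and normalized so that the surface integral of its squared magnitude over
#' the annulus is 1.
#'
#' @param port a [coax_port()].
#' @param point length-3 position on the annulus.
#' @param tol tolerance (metres) for the on-annulus check.
#' @return length-3 mode vector (1/m units).
#' @export
etem_eval <- function(port, point, tol = 1e-9) {
  d <- point - port$center
  if (abs(sum(d * port$normal)) > tol) {
    stop("point is not on the port plane")
  }
  x <- sum(d * port$u); y <- sum(d * port$v)
  rho <- sqrt(x^2 + y^2)
  if (rho < port$ra - tol || rho > port$rb + tol) {
    stop("point is outside the port annulus")
  }
  rho_hat <- (x * port$u + y * port$v) / rho
  rho_hat / (rho * sqrt(2 * pi * log(port$rb / port$ra)))
}

#' Quadrature points and weights on a port annulus
#'
#' Tensor-product rule: Gauss-Legendre in the radial coordinate and the
#' (exponentially accurate, periodic) trapezoid rule in the angle.  The
#' default orders integrate the `1/rho^2` mode-power integrand to better
#' than 1e-10.
#'
#' @param port a [coax_port()].
#' @param n_rho,n_phi quadrature orders.
#' @return list with `points` (n x 3) and `weights` (surface measure).
#' @export
port_quadrature <- function(port, n_rho = 16L, n_phi = 32L) {
  gl <- pracma::gaussLegendre(n_rho, port$ra, port$rb)
  phi <- 2 * pi * (seq_len(n_phi) - 1L) / n_phi
  wphi <- rep(2 * pi / n_phi, n_phi)
  rho <- rep(gl$x, times = n_phi)
  wr <- rep(gl$w, times = n_phi)
  ph <- rep(phi, each = n_rho)
  wp <- rep(wphi, each = n_rho)
  pts <- matrix(port$center, nrow = length(rho), ncol = 3L, byrow = TRUE) +
    outer(rho * cos(ph), port$u) + outer(rho * sin(ph), port$v)
  list(points = pts, weights = wr * wp * rho)
}

#' Project a field onto the port TEM mode
#'
#' Computes the annulus inner product `<E, e_TEM>` by quadrature, given a
#' function `field_fun(points)` returning an n x 3 (complex) matrix of field
#' values.
#'
#' @param port a [coax_port()].
#' @param field_fun vectorized field evaluator.
#' @param quad optional precomputed [port_quadrature()].
#' @return complex scalar.
#' @export
port_project <- function(port, field_fun, quad = port_quadrature(port)) {
  ev <- field_fun(quad$points)
  em <- t(apply(quad$points, 1L, function(p) etem_eval(port, p)))
  sum(quad$weights * (ev[, 1L] * em[, 1L] + ev[, 2L] * em[, 2L] +
                      ev[, 3L] * em[, 3L]))
}

#' S-parameter from port fields
#'
#' With a unit-amplitude TEM impressed field at the transmitting port, the
#' scattering parameter is the TEM projection of the received port field;
#' at the transmitting port itself the impressed field is subtracted first.
#'
#' @param Em_proj complex TEM projection `<E_m, e_TEM>` of the total field at
#'   the receiving port.
#' @param Et_plus_amplitude amplitude of the impressed TEM wave at the
#'   transmitter (must be nonzero; the normalized convention uses 1).
#' @param m_equals_t is the receiving port the transmitting one?
#' @return the complex S-parameter `S_mt`.
#' @export
sparam_from_port_fields <- function(Em_proj, Et_plus_amplitude = 1,
                                    m_equals_t = FALSE) {
  if (Et_plus_amplitude == 0) stop("impressed amplitude must be nonzero")
  if (m_equals_t) {
    (Em_proj - Et_plus_amplitude) / Et_plus_amplitude
  } else {
    Em_proj / Et_plus_amplitude
  }
}

#' Scattered data from total and background S-parameters
#'
#' The scattered field at port `m` due to transmitter `t` is represented by
#' the S-parameter difference between the scenario under test and the
#' background scenario; the resulting T x T complex matrix is the data the
#' inversion fits.
#'
#' @param s_tot,s_inc T x T complex S-parameter matrices (receiver in rows,
#'   transmitter in columns) for the target and background scenarios.
#' @return T x T complex matrix of scattered data.
#' @export
scattered_data_from_sparams <- function(s_tot, s_inc) {
  if (!all(dim(s_tot) == dim(s_inc))) {
    stop("S-parameter sets have mismatched shapes")
  }
  s_tot - s_inc
}

#' Reciprocity defect of an S-parameter matrix
#' @param s T x T complex matrix.
#' @return `norm(S - t(S)) / norm(S)` (Frobenius).
#' @export
sparam_reciprocity <- function(s) {
  sqrt(sum(Mod(s - t(s))^2)) / sqrt(sum(Mod(s)^2))
}
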