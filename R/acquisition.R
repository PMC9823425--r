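# Acquisition models: antenna layout on a ring, excitation right-hand sides
# and the measurement operator that samples a field solution at the
# receivers (elementary dipoles or TEM coaxial ports).

#' Specify the acquisition setup
#'
#' `n_antennas` antennas on an equatorial ring of radius `radius` in the
#' z = 0 plane, each acting as transmitter and receiver.  With the
#' `"dipole"` source model each antenna is an elementary electric dipole
#' with moment along `polarization`; with `"coax_port"` each antenna is an
#' annular coaxial aperture facing the centre, excited by (and projected
#' onto) its TEM mode.
#'
#' @param n_antennas number of antennas T.
#' @param radius ring radius in metres.
#' @param source `"dipole"` or `"coax_port"`.
#' @param polarization dipole moment direction (dipole model).
#' @param ra,rb coaxial radii in metres (port model).
#' @param h_data,h_inv target edge lengths of the data-generation and
#'   inversion meshes; they must differ unless an inverse-crime run is
#'   explicitly requested.
#' @return an `acquisition_spec` object with antenna positions filled in.
#' @export
acquisition_spec <- function(n_antennas = 8L, radius = 0.06,
                             source = c("dipole", "coax_port"),
                             polarization = c(0, 0, 1),
                             ra = 0.65e-3, rb = 2.1e-3,
                             h_data = 0.004, h_inv = 0.005) {
  source <- match.arg(source)
  ang <- 2 * pi * (seq_len(n_antennas) - 1L) / n_antennas
  pos <- cbind(radius * cos(ang), radius * sin(ang), 0)
  polarization <- polarization / sqrt(sum(polarization^2))
  ports <- NULL
  if (source == "coax_port") {
    ports <- lapply(seq_len(n_antennas), function(t) {
      coax_port(center = pos[t, ], normal = -pos[t, ] / radius,
                ra = ra, rb = rb)
    })
  }
  structure(list(n_antennas = as.integer(n_antennas), radius = radius,
                 source = source, positions = pos,
                 polarization = polarization, ports = ports,
                 h_data = h_data, h_inv = h_inv),
            class = "acquisition_spec")
}

# sparse accumulation of  sum_k w_k f(r_k) . N_e(r_k)  over edges
.accumulate_edge_samples <- function(mesh, points, vectors, weights = NULL) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  if (is.null(dim(vectors))) {
    vectors <- matrix(vectors, nrow = nrow(points), ncol = 3L, byrow = TRUE)
  }
  if (is.null(weights)) weights <- rep(1, nrow(points))
  idx <- integer(0); val <- complex(0)
  for (k in seq_len(nrow(points))) {
    ti <- locate_point(mesh, points[k, ])
    lam <- barycentric_coords(mesh, ti, points[k, ])
    g <- .single_tet_gradients(mesh, ti)
    for (le in 1:6) {
      lp <- .local_edge_pairs[le, ]
      if (mesh$tet_edge_sign[ti, le] > 0L) {
        a <- lp[1L]; b <- lp[2L]
      } else {
        a <- lp[2L]; b <- lp[1L]
      }
      w <- lam[a] * g[b, ] - lam[b] * g[a, ]
      idx <- c(idx, mesh$tet_edges[ti, le])
      val <- c(val, weights[k] * sum(vectors[k, ] * w))
    }
  }
  list(idx = idx, val = val)
}

#' Excitation right-hand side for one transmitter
#'
#' Weak-form source term `-1i omega mu0 <J, N_e>`: a point electric dipole
#' (unit current moment, A m) for the dipole model, or the TEM modal field
#' impressed as an electric surface current on the port annulus for the
#' coax model.
#'
#' @param mesh a `tet_mesh`.
#' @param acq an [acquisition_spec()].
#' @param t transmitter index.
#' @param frequency frequency in Hz.
#' @return complex vector of length E.
#' @export
excitation_rhs <- function(mesh, acq, t, frequency) {
  om <- 2 * pi * frequency
  b <- rep(0 + 0i, nrow(mesh$edges))
  if (acq$source == "dipole") {
    s <- .accumulate_edge_samples(mesh, acq$positions[t, ],
                                  acq$polarization)
  } else {
    port <- acq$ports[[t]]
    quad <- port_quadrature(port)
    em <- t(apply(quad$points, 1L, function(p) etem_eval(port, p)))
    s <- .accumulate_edge_samples(mesh, quad$points, em, quad$weights)
  }
  add <- rowsum(data.frame(re = Re(s$val), im = Im(s$val)), s$idx)
  ids <- as.integer(rownames(add))
  b[ids] <- complex(real = add$re, imaginary = add$im)
  (-1i * om * .MU0) * b
}

#' Measurement operator over all receivers
#'
#' Builds the sparse T x E matrix whose row `m` maps edge coefficients to
#' the receiver-m sample: the polarization component of the field at the
#' receiver dipole, or the TEM projection `<E, e_TEM>` over the port
#' annulus.
#'
#' @param mesh a `tet_mesh`.
#' @param acq an [acquisition_spec()].
#' @return a `zspmat` of dimension T x E.
#' @export
measurement_matrix <- function(mesh, acq) {
  Tn <- acq$n_antennas
  ii <- integer(0); jj <- integer(0); xx <- complex(0)
  for (mrec in seq_len(Tn)) {
    if (acq$source == "dipole") {
      s <- .accumulate_edge_samples(mesh, acq$positions[mrec, ],
                                    acq$polarization)
    } else {
      port <- acq$ports[[mrec]]
      quad <- port_quadrature(port)
      em <- t(apply(quad$points, 1L, function(p) etem_eval(port, p)))
      s <- .accumulate_edge_samples(mesh, quad$points, em, quad$weights)
    }
    ii <- c(ii, rep.int(mrec, length(s$idx)))
    jj <- c(jj, s$idx)
    xx <- c(xx, s$val)
  }
  zsp_matrix(ii, jj, xx, dims = c(Tn, nrow(mesh$edges)))
}
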