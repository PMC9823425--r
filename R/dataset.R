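# Synthetic data generation: forward-solve the background and target
# scenarios on a data mesh, sample the scattered field at the receivers,
# and prepare the incident field and operators on a (different) inversion
# mesh.

#' Generate a synthetic scattering dataset
#'
#' Forward-solves the background and target scenarios on the data mesh to
#' produce the T x T scattered data, and the background scenario on the
#' inversion mesh to produce the incident field and the factorized
#' background operators the inversion uses.  Using the same mesh for both
#' is the "inverse crime" and is refused unless explicitly requested.
#'
#' @param phantom a [phantom_spec()].
#' @param stroke optional [stroke_spec()] inclusion (NULL for the
#'   background-only scenario).
#' @param acq an [acquisition_spec()]; `acq$h_data` and `acq$h_inv` set the
#'   two mesh resolutions.
#' @param extent length-3 domain box size in metres.
#' @param noise_snr_db optional signal-to-noise ratio in dB; complex
#'   circular Gaussian noise is added per data entry, scaled to the
#'   per-transmitter scattered-data norm.  Default: noiseless.
#' @param seed integer seed for the noise generator (required when noise is
#'   requested).
#' @param allow_inverse_crime proceed without warning when the two meshes
#'   coincide.
#' @param solver_tol forward-solve relative residual tolerance.
#' @return a `csi_dataset` list with elements `data` (T x T complex,
#'   receivers in rows), `einc` (E x T incident coefficients on the
#'   inversion mesh), `sys` (factorized background system, inversion mesh),
#'   `mesh` (inversion mesh), `materials` (inversion-mesh material map,
#'   including the true target for reference), `meas`, `acq`, `phantom`,
#'   `stroke`, `extent` and a `provenance` block.
#' @export
generate_dataset <- function(phantom, stroke, acq, extent = rep(0.14, 3L),
                             noise_snr_db = NULL, seed = NULL,
                             allow_inverse_crime = FALSE,
                             solver_tol = 1e-12) {
  stopifnot(inherits(phantom, "phantom_spec"),
            inherits(acq, "acquisition_spec"))
  if (isTRUE(all.equal(acq$h_data, acq$h_inv)) && !allow_inverse_crime) {
    warning("data and inversion meshes coincide (inverse crime); ",
            "set allow_inverse_crime = TRUE to silence this")
  }
  if (!is.null(noise_snr_db) && is.null(seed)) {
    stop("noise requested without a seed")
  }
  f <- phantom$frequency
  kb_bnd <- sqrt(wavenumber2(
    complex_permittivity(phantom$coupling$eps_r, phantom$coupling$sigma, f),
    f))

  # --- data mesh: background and target forward solves
  mesh_d <- build_box_mesh(extent, acq$h_data)
  .check_antennas(acq, phantom, extent)
  mat_d <- build_phantom_materials(mesh_d, phantom)
  if (!is.null(stroke)) mat_d <- add_inclusion(mat_d, mesh_d, stroke)
  Tn <- acq$n_antennas
  B_d <- vapply(seq_len(Tn),
                function(t) excitation_rhs(mesh_d, acq, t, f),
                complex(nrow(mesh_d$edges)))
  # scope each data-mesh factorization so at most one is held at a time
  etot_d <- local({
    sys_t_d <- assemble_system(mesh_d, mat_d$k2, kb_bnd)
    solve_forward(sys_t_d, B_d, tol = solver_tol)
  })
  .release_memory()
  sys_b_d <- assemble_system(mesh_d, mat_d$kb2, kb_bnd)
  einc_d <- solve_forward(sys_b_d, B_d, tol = solver_tol)
  meas_d <- measurement_matrix(mesh_d, acq)
  sdata <- zsp_mult(meas_d, etot_d - einc_d)

  if (!is.null(noise_snr_db)) {
    set.seed(as.integer(seed))
    for (t in seq_len(Tn)) {
      s <- sqrt(mean(Mod(sdata[, t])^2)) * 10^(-noise_snr_db / 20)
      sdata[, t] <- sdata[, t] +
        complex(real = stats::rnorm(Tn, sd = s / sqrt(2)),
                imaginary = stats::rnorm(Tn, sd = s / sqrt(2)))
    }
  }

  # --- inversion mesh: incident field and background operators
  if (isTRUE(all.equal(acq$h_data, acq$h_inv))) {
    mesh_i <- mesh_d
    sys_b_i <- sys_b_d
    einc_i <- einc_d
    meas_i <- meas_d
    mat_i <- mat_d
  } else {
    sys_b_d$fac <- NULL   # the inversion uses its own mesh's operators
    gc(FALSE)
    mesh_i <- build_box_mesh(extent, acq$h_inv)
    mat_i <- build_phantom_materials(mesh_i, phantom)
    if (!is.null(stroke)) mat_i <- add_inclusion(mat_i, mesh_i, stroke)
    sys_b_i <- assemble_system(mesh_i, mat_i$kb2, kb_bnd)
    B_i <- vapply(seq_len(Tn),
                  function(t) excitation_rhs(mesh_i, acq, t, f),
                  complex(nrow(mesh_i$edges)))
    einc_i <- solve_forward(sys_b_i, B_i, tol = solver_tol)
    meas_i <- measurement_matrix(mesh_i, acq)
  }

  structure(list(
    data = sdata, einc = einc_i, sys = sys_b_i, mesh = mesh_i,
    materials = mat_i, meas = meas_i, acq = acq, phantom = phantom,
    stroke = stroke, extent = extent, frequency = f,
    kb_boundary = kb_bnd, solver_tol = solver_tol,
    provenance = list(
      seed = seed, noise_snr_db = noise_snr_db,
      mesh_data_hash = mesh_hash(mesh_d),
      mesh_inv_hash = mesh_hash(mesh_i),
      generated = "csifem generate_dataset")
  ), class = "csi_dataset")
}

.check_antennas <- function(acq, phantom, extent) {
  half <- extent / 2
  if (any(abs(acq$positions) > matrix(half, nrow(acq$positions), 3L,
                                      byrow = TRUE))) {
    stop("antennas fall outside the domain box")
  }
  for (ly in phantom$layers) {
    if (any(.inside_shape(acq$positions, ly))) {
      stop("antennas fall inside a phantom layer")
    }
  }
  invisible(TRUE)
}

#' Deterministic content hash of a mesh
#'
#' A cheap, dependency-free fingerprint (counts plus full-precision
#' checksums of coordinates and connectivity) used in dataset provenance.
#'
#' @param mesh a `tet_mesh`.
#' @return character scalar.
#' @export
mesh_hash <- function(mesh) {
  fmt <- function(x) sprintf("%.17g", x)
  paste(nrow(mesh$nodes), nrow(mesh$tets), nrow(mesh$edges),
        fmt(sum(mesh$nodes)), fmt(sum(mesh$nodes^2)),
        fmt(sum(as.numeric(mesh$tets) * seq_along(mesh$tets))),
        sep = ":")
}

#' Write / read a dataset bundle
#'
#' Serializes the dataset to a single binary container (R's native
#' serialization).  The operator factorization is dropped on write and
#' rebuilt on read.
#'
#' @param dataset a `csi_dataset`.
#' @param path file path (conventionally `.rds`).
#' @export
write_dataset <- function(dataset, path) {
  dataset$sys$fac <- NULL
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname write_dataset
#' @param refactorize rebuild the background factorization after reading.
#' @export
read_dataset <- function(path, refactorize = TRUE) {
  d <- readRDS(path)
  if (refactorize && is.null(d$sys$fac)) {
    d$sys$fac <- wave_solver(d$sys$A)
  }
  d
}
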