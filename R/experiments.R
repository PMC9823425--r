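# High-level experiment drivers: the discretization-accuracy consistency
# study (same-mesh residual, scattered-field recovery and exact-point cost
# functional, for both contrast-source discretizations) and the end-to-end
# imaging pipeline driven by a run_config.

#' Same-mesh consistency study of the contrast-source discretizations
#'
#' Builds (or accepts) a scenario, FEM-solves the background and target
#' scenarios on a single mesh, forms the exact contrast and contrast
#' sources, and evaluates, for each requested discretization: the
#' wave-equation residual norms, the scattered-field recovery error and the
#' cost-functional terms at the exact solution.
#'
#' @param phantom a [phantom_spec()]; the default is the homogeneous head:
#'   a 50 mm sphere with the head-average dielectric properties
#'   (`eps_r = 45.37`, `sigma = 0.77` S/m) in coupling medium
#'   (`eps_r = 20`) at 1 GHz.
#' @param stroke optional [stroke_spec()] inclusion.
#' @param acq an [acquisition_spec()]; only `h_inv` is used (single mesh).
#' @param extent domain box (metres).
#' @param h mesh edge length (metres).
#' @param variants list of `c(variant, eval_mode)` pairs to evaluate.
#' @param solver_tol forward-solve tolerance.
#' @return a `consistency_study` list: per-variant results plus the shared
#'   scenario objects.
#' @export
consistency_study <- function(phantom = NULL, stroke = NULL,
                              acq = acquisition_spec(n_antennas = 4L),
                              extent = rep(0.14, 3L), h = 0.005,
                              variants = list(c("novel", "linear"),
                                              c("novel", "barycenter"),
                                              c("standard", "barycenter")),
                              solver_tol = 1e-12) {
  if (is.null(phantom)) {
    phantom <- phantom_spec(
      layers = list(list(shape = "sphere", center = c(0, 0, 0),
                         semi_axes = 0.05, eps_r = 45.37, sigma = 0.77)),
      coupling = list(eps_r = 20, sigma = 0), frequency = 1e9)
  }
  f <- phantom$frequency
  mesh <- build_box_mesh(extent, h)
  materials <- build_phantom_materials(mesh, phantom)
  if (!is.null(stroke)) materials <- add_inclusion(materials, mesh, stroke)
  kb_bnd <- sqrt(wavenumber2(
    complex_permittivity(phantom$coupling$eps_r, phantom$coupling$sigma, f),
    f))
  Tn <- acq$n_antennas
  B <- vapply(seq_len(Tn), function(t) excitation_rhs(mesh, acq, t, f),
              complex(nrow(mesh$edges)))
  # the target-scenario factorization lives only inside this call, so at
  # most one factorization is held at any time
  etot <- local({
    sys_t <- assemble_system(mesh, materials$k2, kb_bnd)
    solve_forward(sys_t, B, tol = solver_tol)
  })
  .release_memory()
  sys_b <- assemble_system(mesh, materials$kb2, kb_bnd)
  einc <- solve_forward(sys_b, B, tol = solver_tol)
  meas <- measurement_matrix(mesh, acq)
  sdata <- zsp_mult(meas, etot - einc)
  chi <- contrast_from_materials(materials)

  results <- list()
  for (v in variants) {
    ops <- csi_operators(mesh, materials$kb2, sys_b, meas,
                         variant = v[1L], eval_mode = v[2L],
                         tol = solver_tol)
    key <- paste(v, collapse = "_")
    results[[key]] <- list(
      residual = wave_equation_residual(ops, chi, etot, einc),
      esct_error = esct_recovery_error(ops, chi, etot, einc),
      exact_cost = exact_cost_eval(ops, chi, etot, einc, sdata)
    )
  }
  structure(list(results = results, mesh = mesh, materials = materials,
                 chi = chi, einc = einc, etot = etot, data = sdata,
                 sys_background = sys_b, meas = meas, acq = acq,
                 phantom = phantom, solver_tol = solver_tol),
            class = "consistency_study")
}

#' Tabulate a consistency study
#'
#' One row per discretization with the aggregated residual norms, the
#' scattered-field recovery error and the exact-point cost terms.
#'
#' @param study a [consistency_study()].
#' @return data.frame.
#' @export
consistency_table <- function(study) {
  rows <- lapply(names(study$results), function(k) {
    r <- study$results[[k]]
    data.frame(discretization = k,
               eta = r$residual$eta, eta_r = r$residual$eta_r,
               esct_eta = r$esct_error$eta, esct_eta_r = r$esct_error$eta_r,
               FS = r$exact_cost$FS, FD = r$exact_cost$FD)
  })
  do.call(rbind, rows)
}

#' @export
print.consistency_study <- function(x, ...) {
  cat("consistency study on", nrow(x$mesh$tets), "cells /",
      nrow(x$mesh$edges), "edges,", x$acq$n_antennas, "antennas\n")
  print(consistency_table(x), digits = 4)
  invisible(x)
}

#' Run the full imaging pipeline from a configuration
#'
#' Generates the dataset (different data/inversion meshes), builds the
#' inversion operators for the configured discretization and domain of
#' interest, and runs the CSI iterations.
#'
#' @param cfg a [run_config()].
#' @param dataset optionally a pre-generated `csi_dataset` (e.g. from
#'   [generate_dataset()] or [read_dataset()]).
#' @param verbose print progress.
#' @return list with `dataset`, `ops`, `result` (a `csi_result`) and the
#'   true contrast on the inversion mesh for reference.
#' @export
run_pipeline <- function(cfg, dataset = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(dataset)) {
    dataset <- generate_dataset(
      phantom = config_phantom(cfg), stroke = config_stroke(cfg),
      acq = config_acquisition(cfg), extent = cfg$scenario$extent,
      noise_snr_db = cfg$noise$snr_db, seed = cfg$noise$seed,
      solver_tol = cfg$inversion$solver_tol)
  }
  doi <- config_doi_mask(cfg, dataset$mesh)
  ops <- csi_operators(dataset$mesh, dataset$materials$kb2, dataset$sys,
                       dataset$meas, variant = cfg$inversion$variant,
                       eval_mode = cfg$inversion$eval_mode,
                       doi_mask = doi, tol = cfg$inversion$solver_tol)
  chi_true <- contrast_from_materials(dataset$materials, doi)
  result <- run_csi(ops, dataset$data, dataset$einc,
                    n_iter = cfg$inversion$n_iter,
                    chi_ref = chi_true$chi, verbose = verbose)
  list(dataset = dataset, ops = ops, result = result,
       chi_true = chi_true, doi_mask = doi)
}
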