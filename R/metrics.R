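# Accuracy diagnostics for the contrast-source discretizations: residuals
# of the discretized wave equation, scattered-field recovery errors,
# exact-point cost functional values, stroke-region statistics and
# convergence reporting.

#' Euclidean and relative residual norms
#'
#' `eta = sqrt(sum(|lhs - rhs|^2))` and `eta_r = eta / sqrt(sum(|lhs|^2))`,
#' with complex moduli inside the sums.  A zero left-hand side with a
#' nonzero residual reports `eta_r = Inf` with a warning.
#'
#' @param lhs,rhs complex vectors of equal length.
#' @return list with `eta` and `eta_r`.
#' @export
residual_norms <- function(lhs, rhs) {
  if (length(lhs) != length(rhs)) stop("lhs/rhs length mismatch")
  eta <- sqrt(sum(Mod(lhs - rhs)^2))
  ln <- sqrt(sum(Mod(lhs)^2))
  if (ln == 0) {
    if (eta > 0) {
      warning("zero LHS with nonzero residual: eta_r is infinite")
      return(list(eta = eta, eta_r = Inf))
    }
    return(list(eta = 0, eta_r = 0))
  }
  list(eta = eta, eta_r = eta / ln)
}

#' Wave-equation residual of a contrast-source discretization
#'
#' Forms the left-hand side `(U - V - A_abc) e_sct` from the FEM-solved
#' fields and the right-hand side `R omega` from the exact contrast and
#' total field, and reports the residual norms per transmitter and
#' aggregated over all transmitters.
#'
#' @param ops a [csi_operators()] bundle (its variant/eval_mode selects the
#'   discretization under test).
#' @param chi per-cell exact contrast (vector or `contrast`).
#' @param etot,einc E x T matrices of total/incident field coefficients on
#'   the same mesh.
#' @return list with `per_transmitter` (data.frame of eta, eta_r) and
#'   aggregated `eta`, `eta_r`.
#' @export
wave_equation_residual <- function(ops, chi, etot, einc) {
  if (inherits(chi, "contrast")) chi <- chi$chi
  Tn <- ncol(etot)
  lhs_all <- rhs_all <- NULL
  rows <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    esct <- etot[, t] - einc[, t]
    lhs <- zsp_mult(ops$sys$A, esct)
    rhs <- apply_coupling(ops$R, apply_X(ops, chi, etot[, t]))
    rn <- residual_norms(lhs, rhs)
    rows[[t]] <- data.frame(transmitter = t, eta = rn$eta,
                            eta_r = rn$eta_r)
    lhs_all <- c(lhs_all, lhs)
    rhs_all <- c(rhs_all, rhs)
  }
  agg <- residual_norms(lhs_all, rhs_all)
  list(per_transmitter = do.call(rbind, rows),
       eta = agg$eta, eta_r = agg$eta_r,
       variant = ops$variant, eval_mode = ops$eval_mode)
}

#' Scattered-field recovery error
#'
#' Solves the discretized wave equation for the scattered field from the
#' exact contrast sources and compares the result with the FEM reference
#' `e_tot - e_inc`.
#'
#' @inheritParams wave_equation_residual
#' @return same structure as [wave_equation_residual()].
#' @export
esct_recovery_error <- function(ops, chi, etot, einc) {
  if (inherits(chi, "contrast")) chi <- chi$chi
  Tn <- ncol(etot)
  lhs_all <- rhs_all <- NULL
  rows <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    esct_ref <- etot[, t] - einc[, t]
    esct_rec <- apply_GD(ops, apply_X(ops, chi, etot[, t]))
    rn <- residual_norms(esct_ref, esct_rec)
    rows[[t]] <- data.frame(transmitter = t, eta = rn$eta,
                            eta_r = rn$eta_r)
    lhs_all <- c(lhs_all, esct_ref)
    rhs_all <- c(rhs_all, esct_rec)
  }
  agg <- residual_norms(lhs_all, rhs_all)
  list(per_transmitter = do.call(rbind, rows),
       eta = agg$eta, eta_r = agg$eta_r,
       variant = ops$variant, eval_mode = ops$eval_mode)
}

#' Cost functional evaluated at the exact solution
#'
#' Substitutes the exact contrast and exact contrast sources into the data
#' and object cost terms; for an exactly consistent discretization both
#' vanish up to the forward-solver floor.
#'
#' @inheritParams wave_equation_residual
#' @param data T x T scattered-data matrix generated on the same mesh.
#' @return list with `FS` and `FD`.
#' @export
exact_cost_eval <- function(ops, chi, etot, einc, data) {
  if (inherits(chi, "contrast")) chi <- chi$chi
  omegas <- lapply(seq_len(ncol(etot)), function(t) {
    apply_X(ops, chi, etot[, t])
  })
  list(FS = cost_FS(ops, omegas, data),
       FD = cost_FD(ops, chi, omegas, einc),
       variant = ops$variant, eval_mode = ops$eval_mode)
}

#' Reconstructed dielectric properties from a contrast map
#'
#' Inverts the contrast definition: `eps = eps_b (1 + chi)`, then
#' `eps_r = Re(eps)` and `sigma = -Im(eps) omega eps0`.
#'
#' @param chi per-cell complex contrast.
#' @param eps_b per-cell complex background permittivity.
#' @param frequency frequency in Hz.
#' @return data.frame with per-cell `eps_r` and `sigma`.
#' @export
dielectric_from_contrast <- function(chi, eps_b, frequency) {
  eps <- eps_b * (1 + chi)
  data.frame(eps_r = Re(eps),
             sigma = -Im(eps) * 2 * pi * frequency * .EPS0)
}

#' Region statistics of a reconstruction
#'
#' Mean, standard deviation and maximum of the reconstructed permittivity
#' and conductivity over a cell region, plus the percentage of region cells
#' above detection thresholds.
#'
#' @param chi_rec per-cell reconstructed contrast.
#' @param eps_b per-cell complex background permittivity.
#' @param frequency frequency in Hz.
#' @param region integer or logical cell index set.
#' @param eps_threshold,sigma_threshold detection thresholds (relative
#'   permittivity and S/m).
#' @return a `region_stats` list.
#' @export
stroke_stats <- function(chi_rec, eps_b, frequency, region,
                         eps_threshold = 53, sigma_threshold = 1) {
  if (is.logical(region)) region <- which(region)
  if (length(region) == 0L) stop("empty region")
  d <- dielectric_from_contrast(chi_rec, eps_b, frequency)
  er <- d$eps_r[region]; sg <- d$sigma[region]
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  structure(list(
    n_cells = length(region),
    eps_r = list(mean = mean(er), sd = sd0(er), max = max(er)),
    sigma = list(mean = mean(sg), sd = sd0(sg), max = max(sg)),
    pct_eps_above = 100 * mean(er > eps_threshold),
    pct_sigma_above = 100 * mean(sg > sigma_threshold),
    eps_threshold = eps_threshold, sigma_threshold = sigma_threshold
  ), class = "region_stats")
}

#' @export
print.region_stats <- function(x, ...) {
  cat(sprintf("region of %d cells\n", x$n_cells))
  cat(sprintf("  eps_r: %.2f +/- %.2f (max %.2f); %.2f%% above %.2f\n",
              x$eps_r$mean, x$eps_r$sd, x$eps_r$max, x$pct_eps_above,
              x$eps_threshold))
  cat(sprintf("  sigma: %.3f +/- %.3f (max %.3f) S/m; %.2f%% above %.3f\n",
              x$sigma$mean, x$sigma$sd, x$sigma$max, x$pct_sigma_above,
              x$sigma_threshold))
  invisible(x)
}

#' Convergence log of one or more CSI runs
#'
#' Binds per-iteration cost histories into one long table ready for
#' log-scale plotting, with a `run` label for overlaying variants.
#'
#' @param ... named `csi_result` objects (or data.frame histories).
#' @return data.frame with columns run, n, FS, FD, FCSI.
#' @export
convergence_report <- function(...) {
  runs <- list(...)
  nm <- names(runs)
  if (is.null(nm)) nm <- paste0("run", seq_along(runs))
  out <- vector("list", length(runs))
  for (k in seq_along(runs)) {
    h <- runs[[k]]
    if (inherits(h, "csi_result")) h <- h$history
    if (is.null(h) || nrow(h) == 0L) stop("empty history in run ", nm[k])
    h <- h[, intersect(c("n", "FS", "FD", "FCSI"), names(h))]
    h$run <- nm[k]
    out[[k]] <- h
  }
  res <- do.call(rbind, out)
  res[, c("run", "n", "FS", "FD", "FCSI")]
}
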