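test_that("GD and GS are linear, vanish at zero, and satisfy the adjoint identity", {
  pair <- tiny_forward_pair()
  ops <- csi_operators(pair$mesh, pair$materials$kb2, pair$sys_b,
                       pair$meas, variant = "novel", eval_mode = "linear")
  nI <- 6L * nrow(pair$mesh$tets)
  expect_true(all(apply_GD(ops, rep(0 + 0i, nI)) == 0))
  expect_true(all(apply_GS(ops, rep(0 + 0i, nI)) == 0))
  set.seed(1)
  w1 <- complex(real = rnorm(nI), imaginary = rnorm(nI))
  w2 <- complex(real = rnorm(nI), imaginary = rnorm(nI))
  g1 <- apply_GD(ops, w1); g2 <- apply_GD(ops, w2)
  g12 <- apply_GD(ops, (2 - 1i) * w1 + 0.5 * w2)
  expect_lt(max(Mod(g12 - (2 - 1i) * g1 - 0.5 * g2)),
            1e-8 * max(Mod(g1)))
  # adjoint inner-product identity <GS w, d> = <w, GS^H d>
  Tn <- ops$meas$dim[1L]
  d <- complex(real = rnorm(Tn), imaginary = rnorm(Tn))
  lhs <- sum(Conj(apply_GS(ops, w1)) * d)
  rhs <- sum(Conj(w1) * apply_GS_adjoint(ops, d))
  expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-10)
  # the same for the per-cell vector discretization
  ops_s <- csi_operators(pair$mesh, pair$materials$kb2, pair$sys_b,
                         pair$meas, variant = "standard")
  ws <- matrix(complex(real = rnorm(3 * nrow(pair$mesh$tets)),
                       imaginary = rnorm(3 * nrow(pair$mesh$tets))),
               ncol = 3)
  lhs <- sum(Conj(apply_GS(ops_s, ws)) * d)
  rhs <- sum(Conj(ws) * apply_GS_adjoint(ops_s, d))
  expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-10)
})

test_that("cost functionals behave as defined: FS(0) = 1, floors at the exact point", {
  pair <- tiny_forward_pair()
  ops <- csi_operators(pair$mesh, pair$materials$kb2, pair$sys_b,
                       pair$meas, variant = "novel", eval_mode = "linear")
  chi <- contrast_from_materials(pair$materials)
  Tn <- ncol(pair$data)
  zero <- lapply(seq_len(Tn), function(t) {
    rep(0 + 0i, 6L * nrow(pair$mesh$tets))
  })
  expect_equal(cost_FS(ops, zero, pair$data), 1)
  # exact (chi, omega) from the same-mesh forward pair: both terms at floor
  omegas <- omega_from_exact(ops, chi, pair$etot)
  FS <- cost_FS(ops, omegas, pair$data)
  FD <- cost_FD(ops, chi, omegas, pair$einc)
  expect_lt(FS, 1e-18)
  expect_lt(FD, 1e-18)
  # FD = 0 when the object equation holds exactly
  expect_error(cost_FD(ops, rep(0 + 0i, nrow(pair$mesh$tets)), omegas,
                       pair$einc), "backpropagation")
  # perturbing chi by +10% lifts FD off the floor
  FD2 <- cost_FD(ops, 1.1 * chi$chi, omegas, pair$einc)
  expect_gt(FD2, 1e3 * max(FD, 1e-30))
})

test_that("backpropagation produces the one-parameter minimizer of the data error", {
  pair <- tiny_forward_pair()
  ops <- csi_operators(pair$mesh, pair$materials$kb2, pair$sys_b,
                       pair$meas, variant = "novel", eval_mode = "linear")
  om0 <- backprop_init(ops, pair$data)
  derr <- function(gamma, t) {
    g <- apply_GS_adjoint(ops, pair$data[, t])
    sqrt(sum(Mod(pair$data[, t] - gamma * apply_GS(ops, g))^2))
  }
  for (t in c(1L, 3L)) {
    g <- apply_GS_adjoint(ops, pair$data[, t])
    gamma <- sum(Mod(g)^2) / sum(Mod(apply_GS(ops, g))^2)
    expect_equal(om0[[t]], gamma * g, tolerance = 1e-10)
    e0 <- derr(gamma, t)
    expect_gt(derr(1.1 * gamma, t), e0)
    expect_gt(derr(0.9 * gamma, t), e0)
  }
  # a transmitter with zero data gets a zero guess and a warning
  d2 <- pair$data; d2[, 2] <- 0
  expect_warning(om2 <- backprop_init(ops, d2), "zero data")
  expect_true(all(om2[[2]] == 0))
  expect_error(backprop_init(ops, 0 * pair$data), "all-zero")
})

test_that("the contrast update is the cell-wise least-squares solution", {
  pair <- tiny_forward_pair()
  ops <- csi_operators(pair$mesh, pair$materials$kb2, pair$sys_b,
                       pair$meas, variant = "novel", eval_mode = "linear")
  # with one transmitter and the field frozen at E_inc, the update must be
  # chi_i = sum_e conj(E_inc_e) omega_e / sum_e |E_inc_e|^2
  set.seed(4)
  nI <- 6L * nrow(pair$mesh$tets)
  w <- complex(real = rnorm(nI), imaginary = rnorm(nI))
  upd <- csifem:::.chi_update(ops, list(w), list(pair$einc[, 1]))
  s <- pair$einc[as.vector(t(pair$mesh$tet_edges)), 1]
  num <- colSums(matrix(Conj(s) * w, nrow = 6L))
  den <- colSums(matrix(Mod(s)^2, nrow = 6L))
  expect_equal(upd$num, num, tolerance = 1e-12)
  expect_equal(upd$den, den, tolerance = 1e-12)
})

test_that("CSI iterations decrease the cost and recover a low-contrast inclusion", {
  setup <- recovery_setup()
  ds <- setup$ds
  ops <- csi_operators(ds$mesh, ds$materials$kb2, ds$sys, ds$meas,
                       variant = "novel", eval_mode = "linear",
                       doi_mask = setup$doi)
  chi_true <- contrast_from_materials(ds$materials, setup$doi)
  expect_lt(max(Mod(chi_true$chi)), 0.8)
  res <- run_csi(ops, ds$data, ds$einc, n_iter = 25,
                 chi_ref = chi_true$chi)
  h <- res$history
  expect_equal(h$FCSI, h$FS + h$FD, tolerance = 1e-12)
  expect_true(all(diff(h$FCSI) <= 1e-10 * h$FCSI[1]))
  expect_lt(h$chi_err[25], h$chi_err[1])
  # reconstructed permittivity is higher inside the true inclusion
  d <- dielectric_from_contrast(res$chi, ds$materials$eps_b, 1e9)
  ins <- csifem:::.inside_shape(ds$mesh$barycenters, setup$stroke)
  expect_gt(mean(d$eps_r[ins & setup$doi]),
            mean(d$eps_r[!ins & setup$doi]))
})

test_that("restricting the domain of interest shrinks the unknown count proportionally", {
  setup <- recovery_setup()
  ds <- setup$ds
  doi_full <- setup$doi
  doi_half <- doi_full & ds$mesh$barycenters[, 2] >= 0
  ops_full <- csi_operators(ds$mesh, ds$materials$kb2, ds$sys, ds$meas,
                            doi_mask = doi_full)
  ops_half <- csi_operators(ds$mesh, ds$materials$kb2, ds$sys, ds$meas,
                            doi_mask = doi_half)
  expect_equal(ops_full$n_unknowns, 6L * sum(doi_full))
  expect_equal(ops_half$n_unknowns, 6L * sum(doi_half))
  expect_equal(ops_half$n_unknowns / ops_full$n_unknowns,
               sum(doi_half) / sum(doi_full))
})
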