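# Independent numerical-quadrature oracles used to check the closed-form
# element integrals, plus small scenario builders shared across tests.

# degree-3 Keast rule on a tetrahedron (exact for cubic polynomials,
# hence for all products of two Whitney edge functions)
tet_quadrature <- function(mesh, tet_index) {
  vid <- mesh$tets[tet_index, ]
  vx <- mesh$nodes[vid, , drop = FALSE]
  lam <- rbind(c(0.25, 0.25, 0.25, 0.25),
               c(0.5, 1/6, 1/6, 1/6), c(1/6, 0.5, 1/6, 1/6),
               c(1/6, 1/6, 0.5, 1/6), c(1/6, 1/6, 1/6, 0.5))
  w <- c(-4/5, 9/20, 9/20, 9/20, 9/20) * mesh$volumes[tet_index]
  list(points = lam %*% vx, weights = w)
}

# degree-3 rule on a triangle (for the boundary-term oracle)
tri_quadrature <- function(p1, p2, p3) {
  area <- sqrt(sum(pracma::cross(p2 - p1, p3 - p1)^2)) / 2
  lam <- rbind(c(1/3, 1/3, 1/3),
               c(0.6, 0.2, 0.2), c(0.2, 0.6, 0.2), c(0.2, 0.2, 0.6))
  w <- c(-27/48, 25/48, 25/48, 25/48) * area
  list(points = lam %*% rbind(p1, p2, p3), weights = w)
}

# barycentric gradients computed the "slow" way, independent of the
# cross-product formulas used in the assembly code
oracle_lambda_gradients <- function(mesh, tet_index) {
  vid <- mesh$tets[tet_index, ]
  A <- rbind(1, t(mesh$nodes[vid, , drop = FALSE]))
  Ainv <- solve(A)          # row p of Ainv: (a_p, b_p) with lambda = a + b.r
  Ainv[, 2:4, drop = FALSE]
}

# Whitney function of local edge `le` evaluated via the oracle gradients
oracle_whitney <- function(mesh, tet_index, le, point) {
  g <- oracle_lambda_gradients(mesh, tet_index)
  lam <- barycentric_coords(mesh, tet_index, point)
  lp <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))[le, ]
  if (mesh$tet_edge_sign[tet_index, le] < 0) lp <- rev(lp)
  lam[lp[1]] * g[lp[2], ] - lam[lp[2]] * g[lp[1], ]
}

# numerical curl of a Whitney function by central differences
oracle_whitney_curl <- function(mesh, tet_index, le, point, h = 1e-6) {
  f <- function(p) oracle_whitney(mesh, tet_index, le, p)
  d <- function(comp, dir) {
    e <- c(0, 0, 0); e[dir] <- h
    (f(point + e)[comp] - f(point - e)[comp]) / (2 * h)
  }
  c(d(3, 2) - d(2, 3), d(1, 3) - d(3, 1), d(2, 1) - d(1, 2))
}

# a deterministic "random" tetrahedron mesh: one tet with perturbed corners
random_single_tet <- function(seed) {
  set.seed(seed)
  repeat {
    nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)) +
      matrix(stats::runif(12, -0.25, 0.25), 4, 3)
    mesh <- structure(list(nodes = nodes, tets = matrix(1:4, 1),
                           grid = NULL), class = "tet_mesh")
    v <- abs(det(cbind(nodes[2, ] - nodes[1, ], nodes[3, ] - nodes[1, ],
                       nodes[4, ] - nodes[1, ])) / 6)
    if (v > 1e-3) break
  }
  mesh <- csifem:::.orient_tets(mesh)
  mesh <- enumerate_edges(mesh)
  csifem:::.find_boundary_faces(mesh)
}

# small head-in-box scenario used by the forward / CSI tests: coarse enough
# to keep direct solves instant
tiny_scenario <- function(h = 0.02, extent = rep(0.12, 3),
                          head_radius = 0.04, eps_head = 45.37,
                          sigma_head = 0.77, n_antennas = 4L,
                          ring_radius = 0.05, frequency = 1e9) {
  phantom <- phantom_spec(
    layers = list(list(shape = "sphere", center = c(0, 0, 0),
                       semi_axes = head_radius, eps_r = eps_head,
                       sigma = sigma_head)),
    coupling = list(eps_r = 20, sigma = 0), frequency = frequency)
  acq <- acquisition_spec(n_antennas = n_antennas, radius = ring_radius,
                          h_data = h, h_inv = h)
  list(phantom = phantom, acq = acq, extent = extent, h = h,
       frequency = frequency)
}

# assembled forward pair (background/target) on one mesh for a scenario
tiny_forward_pair <- function(sc = tiny_scenario(), stroke = NULL) {
  mesh <- build_box_mesh(sc$extent, sc$h)
  materials <- build_phantom_materials(mesh, sc$phantom)
  if (!is.null(stroke)) materials <- add_inclusion(materials, mesh, stroke)
  kb_bnd <- sqrt(wavenumber2(
    complex_permittivity(sc$phantom$coupling$eps_r,
                         sc$phantom$coupling$sigma, sc$frequency),
    sc$frequency))
  sys_b <- assemble_system(mesh, materials$kb2, kb_bnd)
  sys_t <- assemble_system(mesh, materials$k2, kb_bnd)
  B <- vapply(seq_len(sc$acq$n_antennas),
              function(t) excitation_rhs(mesh, sc$acq, t, sc$frequency),
              complex(nrow(mesh$edges)))
  einc <- solve_forward(sys_b, B)
  etot <- solve_forward(sys_t, B)
  meas <- measurement_matrix(mesh, sc$acq)
  list(mesh = mesh, materials = materials, sys_b = sys_b, sys_t = sys_t,
       einc = einc, etot = etot, meas = meas,
       data = zsp_mult(meas, etot - einc), sc = sc, kb_bnd = kb_bnd)
}

# low-contrast stroke-recovery scenario on distinct data/inversion meshes,
# shared by the CSI behavior tests
recovery_setup <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    phantom <- phantom_spec(
      layers = list(list(shape = "sphere", center = c(0, 0, 0),
                         semi_axes = 0.035, eps_r = 30, sigma = 0.2)),
      coupling = list(eps_r = 20, sigma = 0), frequency = 1e9)
    stroke <- stroke_spec(center = c(0.012, 0.008, 0), semi_axes = 0.012,
                          eps_r = 34.5, sigma = 0.3)
    acq <- acquisition_spec(n_antennas = 8L, radius = 0.045,
                            h_data = 0.012, h_inv = 0.015)
    ds <- generate_dataset(phantom, stroke, acq, extent = rep(0.12, 3))
    doi <- rowSums(ds$mesh$barycenters^2) <= 0.035^2
    cache <<- list(ds = ds, doi = doi, stroke = stroke, phantom = phantom)
    cache
  }
})
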