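test_that("closed-form element matrices match quadrature oracles on random tets", {
  skip_if_not_installed("pracma")
  for (seed in 1:12) {
    m <- random_single_tet(seed)
    q <- tet_quadrature(m, 1)
    U <- assemble_stiffness(m)
    V <- assemble_mass(m, 2.5 - 0.7i)
    eid <- m$tet_edges[1, ]
    for (k in 1:6) for (l in k:6) {
      # stiffness: constant integrand (curl x curl), any rule integrates it
      ck <- oracle_whitney_curl(m, 1, k, drop(q$points[1, ]))
      cl <- oracle_whitney_curl(m, 1, l, drop(q$points[1, ]))
      u_o <- m$volumes[1] * sum(ck * cl)
      u_c <- Re(U$re[eid[k], eid[l]])
      expect_equal(u_c, u_o, tolerance = 1e-6)  # fd-curl limited accuracy
      # mass: quadratic integrand, degree-3 rule is exact
      s <- 0
      for (p in seq_along(q$weights)) {
        s <- s + q$weights[p] *
          sum(oracle_whitney(m, 1, k, drop(q$points[p, ])) *
              oracle_whitney(m, 1, l, drop(q$points[p, ])))
      }
      v_c <- V$re[eid[k], eid[l]] + 1i * V$im[eid[k], eid[l]]
      expect_equal(v_c, (2.5 - 0.7i) * s, tolerance = 1e-12)
    }
  }
})

test_that("stiffness matrix has the gradient-field null space and rank 3 per tet", {
  m <- random_single_tet(42)
  U <- as.matrix(U0 <- assemble_stiffness(m)$re)
  expect_equal(U, t(U), tolerance = 1e-12)
  expect_equal(Matrix::rankMatrix(U, tol = 1e-9)[1], 3)
  # discrete gradient of any nodal function is in ker(U)
  set.seed(1)
  phi <- stats::rnorm(4)
  gcoef <- phi[m$edges[, 2]] - phi[m$edges[, 1]]
  expect_lt(max(abs(U %*% gcoef)), 1e-12 * max(abs(U)))

  # the same on a multi-tet mesh
  mm <- build_box_mesh(c(0.1, 0.1, 0.1), 0.05)
  UU <- assemble_stiffness(mm)
  phi <- stats::rnorm(nrow(mm$nodes))
  gcoef <- complex(real = phi[mm$edges[, 2]] - phi[mm$edges[, 1]])
  r <- zsp_mult(UU, gcoef)
  expect_lt(max(Mod(r)), 1e-10 * zsp_norm(UU))
})

test_that("mass assembly is linear in kb2 and vanishes for kb2 = 0", {
  m <- build_box_mesh(c(0.06, 0.06, 0.06), 0.03)
  I <- nrow(m$tets)
  V0 <- assemble_mass(m, rep(0 + 0i, I))
  expect_equal(zsp_norm(V0), 0)
  V1 <- assemble_mass(m, rep(1 + 0i, I))
  Vc <- assemble_mass(m, rep(3 - 2i, I))
  expect_lt(zsp_norm(Vc - zsp_scale(V1, 3 - 2i)), 1e-12 * zsp_norm(Vc))
  expect_error(assemble_mass(m, rep(1 + 0i, I - 1)), "per tetrahedron")
})

test_that("assembly is invariant under tet reordering", {
  m <- build_box_mesh(c(0.06, 0.06, 0.06), 0.03)
  set.seed(5)
  perm <- sample(nrow(m$tets))
  m2 <- structure(list(nodes = m$nodes, tets = m$tets[perm, ],
                       grid = NULL), class = "tet_mesh")
  m2 <- csifem:::.orient_tets(m2)
  m2 <- enumerate_edges(m2)
  m2 <- csifem:::.find_boundary_faces(m2)
  # same node pairs get the same edge numbering (keys are sorted), so the
  # assembled operators must agree entry-wise
  expect_equal(m2$edges, m$edges)
  kb2 <- complex(real = stats::runif(nrow(m$tets), 1, 2),
                 imaginary = -stats::runif(nrow(m$tets)))
  U1 <- assemble_stiffness(m); U2 <- assemble_stiffness(m2)
  expect_lt(zsp_norm(U1 - U2), 1e-12 * zsp_norm(U1))
  V1 <- assemble_mass(m, kb2); V2 <- assemble_mass(m2, kb2[perm])
  expect_lt(zsp_norm(V1 - V2), 1e-12 * zsp_norm(V1))
})

test_that("element matrices scale dimensionally under mesh dilation", {
  # curls scale as 1/s^2 and volumes as s^3, so U entries scale as 1/s;
  # edge functions scale as 1/s, so the unit mass matrix scales as s
  m <- random_single_tet(9)
  ms <- m
  ms$nodes <- 2 * m$nodes
  ms <- csifem:::.orient_tets(ms)
  ms <- enumerate_edges(ms)
  U1 <- as.matrix(assemble_stiffness(m)$re)
  U2 <- as.matrix(assemble_stiffness(ms)$re)
  expect_equal(U2, U1 / 2, tolerance = 1e-12)
  V1 <- as.matrix(assemble_mass(m, 1 + 0i)$re)
  V2 <- as.matrix(assemble_mass(ms, 1 + 0i)$re)
  expect_equal(V2, 2 * V1, tolerance = 1e-12)
})

test_that("boundary term matches a surface-quadrature oracle and is surface-supported", {
  skip_if_not_installed("pracma")
  m <- build_box_mesh(c(0.06, 0.06, 0.06), 0.03)
  kb <- 120 - 15i
  A <- assemble_abc(m, kb)
  expect_equal(zsp_norm(assemble_abc(m, 0)), 0)
  # interior edges have empty rows
  on_bnd <- rep(FALSE, nrow(m$edges))
  f <- m$boundary_faces
  for (k in 1:3) for (l in (k):3) if (k != l) {
    on_bnd[csifem:::.edge_lookup(m, f[, k], f[, l])] <- TRUE
  }
  interior <- which(!on_bnd)
  Aabs <- abs(A$re) + abs(A$im)
  expect_equal(sum(Aabs[interior, ]), 0)
  expect_equal(sum(Aabs[, interior]), 0)
  # oracle: quadrature of the tangential-component product per face
  for (fi in c(1L, 5L, nrow(f))) {
    tri <- f[fi, ]
    ti <- m$boundary_face_tet[fi]
    p <- m$nodes[tri, , drop = FALSE]
    nrm <- pracma::cross(p[2, ] - p[1, ], p[3, ] - p[1, ])
    nrm <- nrm / sqrt(sum(nrm^2))
    q <- tri_quadrature(p[1, ], p[2, ], p[3, ])
    le_of <- function(a, b) {
      le <- which(apply(m$tet_edges[ti, , drop = FALSE], 2, function(e) {
        all(sort(m$edges[e, ]) == sort(c(a, b)))
      }))
      le[1]
    }
    pairs <- rbind(c(tri[1], tri[2]), c(tri[1], tri[3]), c(tri[2], tri[3]))
    for (ke in 1:3) for (leid in 1:3) {
      lek <- le_of(pairs[ke, 1], pairs[ke, 2])
      lel <- le_of(pairs[leid, 1], pairs[leid, 2])
      s <- 0
      for (qq in seq_along(q$weights)) {
        wk <- oracle_whitney(m, ti, lek, drop(q$points[qq, ]))
        wl <- oracle_whitney(m, ti, lel, drop(q$points[qq, ]))
        wk_t <- wk - sum(wk * nrm) * nrm
        wl_t <- wl - sum(wl * nrm) * nrm
        s <- s + q$weights[qq] * sum(wk_t * wl_t)
      }
      ek <- m$tet_edges[ti, lek]; el <- m$tet_edges[ti, lel]
      got <- A$re[ek, el] + 1i * A$im[ek, el]
      # the face contributes additively; compare against the sum of oracle
      # contributions from all boundary faces sharing the edge pair
      faces_sharing <- which(apply(f, 1, function(tr) {
        all(m$edges[ek, ] %in% tr) && all(m$edges[el, ] %in% tr)
      }))
      s_all <- 0
      for (fj in faces_sharing) {
        trj <- f[fj, ]; tj <- m$boundary_face_tet[fj]
        pj <- m$nodes[trj, , drop = FALSE]
        nj <- pracma::cross(pj[2, ] - pj[1, ], pj[3, ] - pj[1, ])
        nj <- nj / sqrt(sum(nj^2))
        qj <- tri_quadrature(pj[1, ], pj[2, ], pj[3, ])
        lekj <- which(apply(m$tet_edges[tj, , drop = FALSE], 2,
                            function(e) e == ek))
        lelj <- which(apply(m$tet_edges[tj, , drop = FALSE], 2,
                            function(e) e == el))
        if (!length(lekj) || !length(lelj)) next
        for (qq in seq_along(qj$weights)) {
          wk <- oracle_whitney(m, tj, lekj[1], drop(qj$points[qq, ]))
          wl <- oracle_whitney(m, tj, lelj[1], drop(qj$points[qq, ]))
          wk_t <- wk - sum(wk * nj) * nj
          wl_t <- wl - sum(wl * nj) * nj
          s_all <- s_all + qj$weights[qq] * sum(wk_t * wl_t)
        }
      }
      expect_equal(got, 1i * kb * s_all, tolerance = 1e-10)
    }
  }
})
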