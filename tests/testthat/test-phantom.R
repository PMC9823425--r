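test_that("complex permittivity follows the passive-medium convention", {
  eps0 <- 8.8541878128e-12
  e <- complex_permittivity(45.37, 0.77, 1e9)
  expect_equal(Re(e), 45.37)
  expect_equal(Im(e), -0.77 / (2 * pi * 1e9 * eps0))
  expect_lt(Im(e), 0)
  expect_equal(Im(complex_permittivity(20, 0, 1e9)), 0)
})

test_that("phantom material maps assign layers by barycenter with override", {
  m <- build_box_mesh(c(0.12, 0.12, 0.12), 0.01)
  ph <- phantom_spec(
    layers = list(
      list(shape = "sphere", center = c(0, 0, 0), semi_axes = 0.04,
           eps_r = 45.37, sigma = 0.77),
      list(shape = "ellipsoid", center = c(0.01, 0, 0),
           semi_axes = c(0.015, 0.01, 0.01), eps_r = 52, sigma = 1)),
    coupling = list(eps_r = 20, sigma = 0))
  mat <- build_phantom_materials(m, ph)
  # background scenario is pure coupling medium
  expect_true(all(mat$eps_b == complex_permittivity(20, 0, 1e9)))
  # target: head value where inside sphere but outside inner ellipsoid
  pin <- which(rowSums(m$barycenters^2) < 0.03^2 &
                 rowSums(sweep(sweep(m$barycenters, 2, c(0.01, 0, 0)), 2,
                               c(0.015, 0.01, 0.01), "/")^2) > 1.2)
  expect_true(all(mat$eps_target[pin] ==
                    complex_permittivity(45.37, 0.77, 1e9)))
  # inner layer overrides the outer one
  pinner <- which(rowSums(sweep(sweep(m$barycenters, 2, c(0.01, 0, 0)), 2,
                                c(0.015, 0.01, 0.01), "/")^2) < 0.8)
  expect_true(all(mat$eps_target[pinner] ==
                    complex_permittivity(52, 1, 1e9)))
  # a single layer covering the box would poke out: rejected
  expect_error(build_phantom_materials(m, phantom_spec(
    layers = list(list(shape = "sphere", center = c(0, 0, 0),
                       semi_axes = 0.2, eps_r = 10, sigma = 0)),
    coupling = list(eps_r = 20, sigma = 0))), "outside")
})

test_that("layer volume fractions match a Monte-Carlo hit-count oracle", {
  m <- build_box_mesh(c(0.12, 0.12, 0.12), 0.006)
  ph <- phantom_spec(
    layers = list(list(shape = "sphere", center = c(0, 0, 0),
                       semi_axes = 0.04, eps_r = 45.37, sigma = 0.77)),
    coupling = list(eps_r = 20, sigma = 0))
  mat <- build_phantom_materials(m, ph)
  head_cells <- mat$eps_target != mat$eps_b[1]
  vol_frac <- sum(m$volumes[head_cells]) / sum(m$volumes)
  set.seed(99)
  pts <- matrix(stats::runif(3e5, -0.06, 0.06), ncol = 3)
  hits <- mean(rowSums(pts^2) <= 0.04^2)
  se <- sqrt(hits * (1 - hits) / nrow(pts))
  expect_lt(abs(vol_frac - hits), 3 * se + 0.01)
})

test_that("inclusions modify only their interior and respect containment", {
  m <- build_box_mesh(c(0.12, 0.12, 0.12), 0.01)
  ph <- phantom_spec(
    layers = list(list(shape = "sphere", center = c(0, 0, 0),
                       semi_axes = 0.045, eps_r = 45.37, sigma = 0.77)),
    coupling = list(eps_r = 20, sigma = 0))
  mat <- build_phantom_materials(m, ph)
  st <- stroke_spec(center = c(0.01, 0.01, 0), semi_axes = 0.012)
  mat2 <- add_inclusion(mat, m, st,
                        within = list(shape = "sphere",
                                      center = c(0, 0, 0),
                                      semi_axes = 0.045))
  inside <- rowSums(sweep(sweep(m$barycenters, 2, st$center), 2,
                          st$semi_axes, "/")^2) <= 1
  expect_true(all(mat2$eps_target[inside] ==
                    complex_permittivity(64.41, 1.58, 1e9)))
  expect_equal(mat2$eps_target[!inside], mat$eps_target[!inside])
  expect_equal(mat2$eps_b, mat$eps_b)
  # zero-volume inclusion changes nothing
  mat3 <- add_inclusion(mat, m, stroke_spec(c(0, 0, 0), 0))
  expect_equal(mat3$eps_target, mat$eps_target)
  # inclusion poking out of the containing layer is rejected
  expect_error(
    add_inclusion(mat, m, stroke_spec(c(0.04, 0, 0), 0.02),
                  within = list(shape = "sphere", center = c(0, 0, 0),
                                semi_axes = 0.045)),
    "not fully inside")
})

test_that("contrast is the normalized permittivity difference", {
  m <- build_box_mesh(c(0.06, 0.06, 0.06), 0.03)
  ph <- phantom_spec(layers = list(), coupling = list(eps_r = 20, sigma = 0))
  mat <- build_phantom_materials(m, ph)
  chi0 <- contrast_from_materials(mat)
  expect_true(all(chi0$chi == 0))
  # blood over homogeneous head background, complex division oracle
  eb <- complex_permittivity(45.37, 0.77, 1e9)
  et <- complex_permittivity(64.41, 1.58, 1e9)
  mat$eps_b <- rep(eb, length(mat$eps_b))
  mat$eps_target <- rep(et, length(mat$eps_target))
  chi <- contrast_from_materials(mat)
  expect_equal(chi$chi[1], (et - eb) / eb, tolerance = 1e-15)
  # eps_target = 2 eps_b  =>  chi = 1
  mat$eps_target <- 2 * mat$eps_b
  expect_true(all(abs(contrast_from_materials(mat)$chi - 1) < 1e-15))
  # doi mask zeroes the outside
  mask <- rep(FALSE, length(mat$eps_b)); mask[1:3] <- TRUE
  chi_m <- contrast_from_materials(mat, mask)
  expect_true(all(chi_m$chi[-(1:3)] == 0))
  expect_true(all(chi_m$chi[1:3] == 1))
})
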