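test_that("dataset generation is deterministic and records provenance", {
  setup <- recovery_setup()
  d1 <- generate_dataset(setup$phantom, setup$stroke, setup$ds$acq,
                         extent = rep(0.12, 3))
  expect_identical(d1$data, setup$ds$data)
  expect_identical(d1$einc, setup$ds$einc)
  expect_identical(d1$provenance$mesh_inv_hash,
                   mesh_hash(setup$ds$mesh))
  # with noise: same seed bit-identical, different seed different
  dn1 <- generate_dataset(setup$phantom, setup$stroke, setup$ds$acq,
                          extent = rep(0.12, 3), noise_snr_db = 30,
                          seed = 11)
  dn2 <- generate_dataset(setup$phantom, setup$stroke, setup$ds$acq,
                          extent = rep(0.12, 3), noise_snr_db = 30,
                          seed = 11)
  dn3 <- generate_dataset(setup$phantom, setup$stroke, setup$ds$acq,
                          extent = rep(0.12, 3), noise_snr_db = 30,
                          seed = 12)
  expect_identical(dn1$data, dn2$data)
  expect_false(identical(dn1$data, dn3$data))
  # noise level roughly matches the requested SNR
  snr_emp <- 20 * log10(sqrt(sum(Mod(setup$ds$data)^2)) /
                          sqrt(sum(Mod(dn1$data - setup$ds$data)^2)))
  expect_lt(abs(snr_emp - 30), 6)
  expect_error(generate_dataset(setup$phantom, setup$stroke, setup$ds$acq,
                                extent = rep(0.12, 3), noise_snr_db = 30),
               "seed")
})

test_that("no target means scattered data at the numerical floor", {
  sc <- tiny_scenario(h = 0.02)
  # a phantom whose target equals the background: no layers at all
  phantom0 <- phantom_spec(layers = list(),
                           coupling = list(eps_r = 20, sigma = 0))
  acq <- acquisition_spec(n_antennas = 4L, radius = 0.05,
                          h_data = 0.02, h_inv = 0.02)
  ds <- suppressWarnings(generate_dataset(phantom0, NULL, acq,
                                          extent = rep(0.12, 3)))
  # compare with the scale of data from an actual target
  ds1 <- suppressWarnings(generate_dataset(sc$phantom, NULL, acq,
                                           extent = rep(0.12, 3)))
  expect_lt(sqrt(sum(Mod(ds$data)^2)),
            1e-8 * sqrt(sum(Mod(ds1$data)^2)))
})

test_that("requesting identical meshes warns about the inverse crime", {
  sc <- tiny_scenario(h = 0.02)
  acq <- acquisition_spec(n_antennas = 4L, radius = 0.05,
                          h_data = 0.02, h_inv = 0.02)
  expect_warning(generate_dataset(sc$phantom, NULL, acq,
                                  extent = rep(0.12, 3)),
                 "inverse crime")
  expect_silent(generate_dataset(sc$phantom, NULL, acq,
                                 extent = rep(0.12, 3),
                                 allow_inverse_crime = TRUE))
})

test_that("simulated data are reciprocal and grow with inclusion contrast", {
  setup <- recovery_setup()
  expect_lt(sparam_reciprocity(setup$ds$data), 1e-6)
  norms <- c()
  for (de in c(2, 4.5, 8)) {
    st <- stroke_spec(center = c(0.012, 0.008, 0), semi_axes = 0.012,
                      eps_r = 30 + de, sigma = 0.2)
    ds <- generate_dataset(setup$phantom, st, setup$ds$acq,
                           extent = rep(0.12, 3))
    norms <- c(norms, sqrt(sum(Mod(ds$data)^2)))
  }
  expect_true(all(diff(norms) > 0))
})

test_that("dataset bundles round-trip through disk with refactorization", {
  setup <- recovery_setup()
  path <- tempfile(fileext = ".rds")
  write_dataset(setup$ds, path)
  ds2 <- read_dataset(path)
  expect_identical(ds2$data, setup$ds$data)
  expect_identical(ds2$einc, setup$ds$einc)
  # the rebuilt factorization solves the same system
  set.seed(9)
  b <- complex(real = rnorm(nrow(ds2$mesh$edges)),
               imaginary = rnorm(nrow(ds2$mesh$edges)))
  x <- solve_forward(ds2$sys, b)
  r <- b - zsp_mult(setup$ds$sys$A, x)
  expect_lt(sqrt(sum(Mod(r)^2)) / sqrt(sum(Mod(b)^2)), 1e-10)
  unlink(path)
})

test_that("antenna placement is validated against the phantom and the box", {
  setup <- recovery_setup()
  acq_bad <- acquisition_spec(n_antennas = 4L, radius = 0.02,
                              h_data = 0.012, h_inv = 0.015)
  expect_error(generate_dataset(setup$phantom, NULL, acq_bad,
                                extent = rep(0.12, 3)), "inside")
  acq_out <- acquisition_spec(n_antennas = 4L, radius = 0.08,
                              h_data = 0.012, h_inv = 0.015)
  expect_error(generate_dataset(setup$phantom, NULL, acq_out,
                                extent = rep(0.12, 3)), "outside")
})
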