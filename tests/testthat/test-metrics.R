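test_that("residual norms are the Euclidean and relative errors", {
  expect_equal(residual_norms(c(3 + 0i, 4 + 0i), c(0i, 0i)),
               list(eta = 5, eta_r = 1))
  z <- c(1 + 2i, -3 + 1i, 0.5i)
  expect_equal(residual_norms(z, z), list(eta = 0, eta_r = 0))
  r1 <- residual_norms(z, z * 1.01)
  r2 <- residual_norms((2 - 5i) * z, (2 - 5i) * z * 1.01)
  expect_equal(r2$eta, Mod(2 - 5i) * r1$eta, tolerance = 1e-12)
  expect_equal(r2$eta_r, r1$eta_r, tolerance = 1e-12)
  expect_warning(r3 <- residual_norms(c(0i, 0i), c(1 + 0i, 0i)),
                 "infinite")
  expect_equal(r3$eta_r, Inf)
  expect_error(residual_norms(z, z[1:2]), "mismatch")
})

test_that("discretization diagnostics order novel below standard on a head scenario", {
  study <- consistency_study(acq = acquisition_spec(n_antennas = 4L,
                                                    radius = 0.05),
                             extent = rep(0.12, 3), h = 0.015)
  tab <- consistency_table(study)
  novel <- tab[tab$discretization == "novel_linear", ]
  std <- tab[tab$discretization == "standard_barycenter", ]
  bary <- tab[tab$discretization == "novel_barycenter", ]
  # the exactly consistent discretization sits at the solver floor
  expect_lt(novel$eta_r, 1e-8)
  expect_lt(novel$FS, 1e-15)
  expect_lt(novel$FD, 1e-15)
  # the per-cell discretizations carry a real discretization error
  expect_gt(std$eta_r, 10 * novel$eta_r)
  expect_gt(std$FS, 10 * novel$FS)
  expect_gt(std$FD, 10 * novel$FD)
  expect_gt(std$esct_eta_r, novel$esct_eta_r)
  # barycenter mode of the scalar machinery reproduces the standard numbers
  expect_equal(bary$eta_r, std$eta_r, tolerance = 1e-8)
  # zero contrast: both residuals vanish
  chi0 <- rep(0 + 0i, nrow(study$mesh$tets))
  ops <- csi_operators(study$mesh, study$materials$kb2,
                       study$sys_background, study$meas)
  wr <- wave_equation_residual(ops, chi0, study$einc, study$einc)
  expect_equal(wr$eta, 0)
})

test_that("scattered-field recovery error tracks the solver floor", {
  study <- consistency_study(acq = acquisition_spec(n_antennas = 2L,
                                                    radius = 0.05),
                             extent = rep(0.12, 3), h = 0.02,
                             variants = list(c("novel", "linear")))
  r <- study$results$novel_linear$esct_error
  expect_lt(r$eta_r, 1e-8)
  expect_true(all(r$per_transmitter$eta_r < 1e-8))
})

test_that("stroke-region statistics count thresholds and moments correctly", {
  # 4-cell toy region
  chi <- c(52, 54, 55, 50) / 40 - 1   # over a background of eps_r = 40
  stats <- stroke_stats(complex(real = chi), rep(40 + 0i, 4), 1e9,
                        region = 1:4, eps_threshold = 53,
                        sigma_threshold = 1)
  expect_equal(stats$pct_eps_above, 50)
  expect_equal(stats$eps_r$mean, mean(c(52, 54, 55, 50)))
  expect_equal(stats$eps_r$max, 55)
  # uniform blood-valued reconstruction
  eb <- complex_permittivity(45.37, 0.77, 1e9)
  bl <- complex_permittivity(64.41, 1.58, 1e9)
  chi_b <- rep((bl - eb) / eb, 10)
  sb <- stroke_stats(chi_b, rep(eb, 10), 1e9, region = 1:10)
  expect_equal(sb$eps_r$mean, 64.41, tolerance = 1e-10)
  expect_equal(sb$eps_r$sd, 0, tolerance = 1e-8)
  expect_equal(sb$pct_eps_above, 100)
  expect_equal(sb$sigma$mean, 1.58, tolerance = 1e-10)
  # standard deviation matches a two-pass oracle on random data
  set.seed(21)
  chi_r <- complex(real = runif(50, -0.1, 0.4),
                   imaginary = -runif(50, 0, 0.2))
  sr <- stroke_stats(chi_r, rep(eb, 50), 1e9, region = 1:50)
  d <- dielectric_from_contrast(chi_r, rep(eb, 50), 1e9)
  mu <- sum(d$eps_r) / 50
  expect_equal(sr$eps_r$sd, sqrt(sum((d$eps_r - mu)^2) / 49),
               tolerance = 1e-12)
  expect_error(stroke_stats(chi_r, rep(eb, 50), 1e9, region = integer(0)),
               "empty")
})

test_that("convergence reports bind runs and satisfy the cost identity", {
  h1 <- data.frame(n = 1:3, FS = c(1, 0.5, 0.2), FD = c(0.3, 0.2, 0.1))
  h1$FCSI <- h1$FS + h1$FD
  h2 <- data.frame(n = 1:3, FS = c(2, 1, 0.5), FD = c(0.5, 0.4, 0.2))
  h2$FCSI <- h2$FS + h2$FD
  rep_ <- convergence_report(novel = h1, standard = h2)
  expect_equal(nrow(rep_), 6)
  expect_equal(rep_$FCSI, rep_$FS + rep_$FD)
  expect_true(all(rep_$run[1:3] == "novel"))
  # log writer round-trips through text
  path <- tempfile(fileext = ".tsv")
  write_convergence_log(h1, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(back$FCSI, h1$FCSI, tolerance = 1e-12)
  unlink(path)
})
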