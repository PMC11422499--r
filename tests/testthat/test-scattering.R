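simple_cal <- function(angle = 124, wl = 500, sf = 1e-5, dark = 50,
                       path = 0.05, chi = NA_real_) {
  tibble::tibble(angle_deg = angle, wavelength = wl, scale_factor = sf,
                 dark_offset = dark, path_length_m = path, chi = chi)
}

counts_series <- function(counts, angle = 124, wl = 500, n_t = 5) {
  tidyr::expand_grid(time_s = seq_len(n_t) - 1, angle_deg = angle,
                     wavelength = wl) %>%
    dplyr::mutate(counts = counts)
}

test_that("count calibration is exact channel arithmetic with QC on negatives", {
  cal <- simple_cal()
  expect_equal(counts_to_beta(counts_series(100), cal)$beta, 5e-4)
  expect_equal(counts_to_beta(counts_series(50), cal)$beta, 0)
  neg <- counts_to_beta(counts_series(40), cal)
  expect_equal(neg$beta, -1e-4)
  expect_true(neg$qc_negative)
  expect_error(counts_to_beta(counts_series(100, wl = 600), cal),
               "no calibration")
})

test_that("along-path absorption compensation is the exponential factor", {
  vsf <- tibble::tibble(angle_deg = 124, wavelength = 500, beta = 1e-3,
                        fraction = "total")
  a <- spectrum(c(400, 500, 700), c(0.4, 0.4, 0.4))
  out <- path_absorption_correct(vsf, a, path_length_m = 0.05)
  expect_equal(out$beta, 1e-3 * exp(0.02), tolerance = 1e-12)  # 1.0202e-3

  a0 <- spectrum(c(400, 500, 700), c(0, 0, 0))
  expect_equal(path_absorption_correct(vsf, a0, path_length_m = 0.05)$beta,
               1e-3)
  # strictly increasing in absorption for positive path length
  b1 <- path_absorption_correct(vsf, spectrum(c(400, 500, 700), rep(0.1, 3)),
                                path_length_m = 0.05)$beta
  b2 <- path_absorption_correct(vsf, spectrum(c(400, 500, 700), rep(0.2, 3)),
                                path_length_m = 0.05)$beta
  expect_gt(b2, b1)
  expect_error(path_absorption_correct(vsf, a, path_length_m = -1),
               "negative")
})

test_that("dissolved subtraction is channelwise with mismatch detection", {
  u <- tibble::tibble(angle_deg = 124, wavelength = 500, beta = 5e-4,
                      fraction = "total")
  f <- u; f$beta <- 1e-4; f$fraction <- "dissolved"
  out <- subtract_dissolved(u, f)
  expect_equal(out$beta, 4e-4)
  expect_equal(out$fraction, "particulate")
  expect_equal(subtract_dissolved(u, u)$beta, 0)
  zero <- f; zero$beta <- 0
  expect_equal(subtract_dissolved(u, zero)$beta, u$beta)
  mism <- f; mism$wavelength <- 501
  expect_error(subtract_dissolved(u, mism), "channels")
})

test_that("chi conversion is the single-angle backscatter formula, linear in both factors", {
  vsf <- tibble::tibble(angle_deg = 124, wavelength = 441, beta = 1e-4,
                        fraction = "particulate")
  out <- chi_bbp(vsf, chi = 1.1)
  expect_equal(out$bbp, 2 * pi * 1.1 * 1e-4, tolerance = 1e-12)  # 6.9115e-4
  expect_equal(chi_bbp(dplyr::mutate(vsf, beta = 0), chi = 1.1)$bbp, 0)
  expect_equal(chi_bbp(dplyr::mutate(vsf, beta = 3e-4), chi = 1.1)$bbp,
               3 * out$bbp, tolerance = 1e-12)
  expect_equal(chi_bbp(vsf, chi = 2.2)$bbp, 2 * out$bbp, tolerance = 1e-12)
  expect_error(chi_bbp(vsf, cal = simple_cal(chi = NA_real_)), "chi")
})

test_that("chi conversion commutes with dissolved subtraction (linearity)", {
  u <- tibble::tibble(angle_deg = 141, wavelength = 550, beta = 6e-4,
                      fraction = "total")
  f <- dplyr::mutate(u, beta = 2e-4, fraction = "dissolved")
  direct <- chi_bbp(subtract_dissolved(u, f), chi = 0.9)$bbp
  split <- chi_bbp(u, chi = 0.9)$bbp - chi_bbp(f, chi = 0.9)$bbp
  expect_equal(direct, split, tolerance = 1e-15)
})

test_that("three-angle integration is exact for cubic integrands and accurate for smooth VSFs", {
  angles <- c(104, 130, 151)
  th <- angles * pi / 180

  # integrand constructed to be a cubic vanishing at pi: interpolation exact
  w_cubic <- function(t) (pi - t) * (t - 1)^2
  beta_vals <- w_cubic(th) / (2 * pi * sin(th))
  vsf <- tibble::tibble(angle_deg = angles, wavelength = 650,
                        beta = beta_vals, fraction = "particulate")
  analytic <- integrate(w_cubic, pi / 2, pi, rel.tol = 1e-13)$value
  expect_equal(integrate_vsf(vsf)$bbp, analytic, tolerance = 1e-12)

  # isotropic VSF: truth is 2*pi*beta (dense quadrature oracle)
  iso <- tibble::tibble(angle_deg = angles, wavelength = 650, beta = 1e-3,
                        fraction = "particulate")
  oracle <- integrate(function(t) 2 * pi * sin(t) * 1e-3, pi / 2, pi,
                      rel.tol = 1e-12)$value
  expect_equal(oracle, 2 * pi * 1e-3, tolerance = 1e-9)
  expect_lt(abs(integrate_vsf(iso)$bbp - oracle) / oracle, 0.02)

  # zero VSF integrates to zero
  z <- dplyr::mutate(iso, beta = 0)
  expect_equal(integrate_vsf(z)$bbp, 0)
})

test_that("three-angle integration is deterministic interpolation: angle order does not matter", {
  withr::with_seed(9, {
    angles <- c(104, 130, 151)
    vsf <- tibble::tibble(angle_deg = angles, wavelength = 532,
                          beta = abs(rnorm(3, 1e-3, 3e-4)),
                          fraction = "particulate")
    ref <- integrate_vsf(vsf)$bbp
    for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
      expect_equal(integrate_vsf(vsf[perm, ])$bbp, ref, tolerance = 1e-14)
    }
  })
  dup <- tibble::tibble(angle_deg = c(104, 104, 151), wavelength = 532,
                        beta = 1e-3, fraction = "particulate")
  expect_error(integrate_vsf(dup), "distinct")
  outside <- tibble::tibble(angle_deg = c(80, 130, 151), wavelength = 532,
                            beta = 1e-3, fraction = "particulate")
  expect_error(integrate_vsf(outside), "90")
})

test_that("both backscatter routes recover the generator's true b_bp", {
  truth <- fix_truth()
  runs <- fix_runs_clean()
  ab <- truth_absorption_pair(truth)

  # chi route at 124 degrees, chi derived from the phase function by quadrature
  raw_phase <- function(th) {
    exp(-truth$phase$decay * (th - pi / 2)) + truth$phase$floor
  }
  norm <- integrate(function(t) 2 * pi * raw_phase(t) * sin(t), pi / 2, pi,
                    rel.tol = 1e-12)$value
  chi_124 <- norm / (2 * pi * raw_phase(124 * pi / 180))
  expect_equal(chi_124, chi_from_phase(truth, 124), tolerance = 1e-10)

  s <- runs$scatter$bb9
  bbp_chi <- process_scatter_run(s$unfiltered, s$filtered, s$cal,
                                 ab$a_sc, ab$a_g, route = "chi")
  expect_lt(max(abs(bbp_chi$bbp / truth_bbp(truth, bbp_chi$wavelength) - 1)),
            1e-6)

  # integration route: cubic interpolation of a smooth phase function
  v <- runs$scatter$vsf3
  bbp_int <- process_scatter_run(v$unfiltered, v$filtered, v$cal,
                                 ab$a_sc, ab$a_g, route = "integrate")
  expect_lt(max(abs(bbp_int$bbp / truth_bbp(truth, bbp_int$wavelength) - 1)),
            0.02)
})
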