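# minimal coefficient table with flat coefficients for hand arithmetic
flat_coeffs <- function(psi_t = 0.004, psi_sa = -1.8e-4, psi_sc = -1.0e-4,
                        t_r = 15) {
  tab <- tibble::tibble(wavelength = c(400, 550, 750),
                        psi_t = psi_t, psi_sa = psi_sa, psi_sc = psi_sc)
  attr(tab, "t_r") <- t_r
  tab
}

test_that("baseline subtraction is exact elementwise arithmetic", {
  wl <- c(440, 550)
  s <- spectrum(wl, c(0.10, 0.10))
  cal <- spectrum(wl, c(0.01, 0.01))
  expect_equal(subtract_baseline(s, cal)$value, c(0.09, 0.09))
  expect_equal(subtract_baseline(s, s)$value, c(0, 0))
  expect_error(subtract_baseline(s, spectrum(c(440, 551), c(0, 0))), "axes")
})

test_that("a pure-water run processed against its own calibration stays within the instrument noise floor", {
  runs <- fix_runs_noisy()
  water_med <- median_reduce(runs$acs$pure_water$a)
  # second pure-water rendering with different noise draws, same instrument
  runs2 <- render_runs(generate_truth(43, "exponential"), noise_scale = 1)
  resid <- median_reduce(subtract_baseline(runs2$acs$pure_water$a, water_med))
  expect_lt(max(abs(resid$value)), 0.003)
})

test_that("temperature/salinity correction matches hand arithmetic in both sign conventions", {
  co <- flat_coeffs()
  s <- spectrum(c(440, 550), c(0.5, 0.5))
  # T_m - T_r = 5, S_m = 32
  as_printed <- ts_correct(s, co, t_m = 20, s_m = 32, channel = "a",
                           sign_convention = "as_printed")
  expect_equal(as_printed$value, rep(0.5 - 0.02 + 32 * (-1.8e-4), 2),
               tolerance = 1e-12)                        # 0.47424
  flipped <- ts_correct(s, co, t_m = 20, s_m = 32, channel = "a",
                        sign_convention = "subtract_salinity")
  expect_equal(flipped$value, rep(0.5 - 0.02 - 32 * (-1.8e-4), 2),
               tolerance = 1e-12)                        # 0.48576
  # attenuation channel uses psi_sc
  c_corr <- ts_correct(s, co, t_m = 20, s_m = 32, channel = "c")
  expect_equal(c_corr$value, rep(0.5 - 0.02 + 32 * (-1.0e-4), 2),
               tolerance = 1e-12)

  ident <- ts_correct(s, co, t_m = 15, s_m = 0, channel = "a")
  expect_equal(ident$value, s$value)
})

test_that("temperature/salinity correction is affine in the measurement", {
  co <- flat_coeffs()
  s <- spectrum(c(440, 550), c(0.5, 0.3))
  shifted <- s; shifted$value <- s$value + 0.123
  expect_equal(
    ts_correct(shifted, co, t_m = 22, s_m = 30, channel = "a")$value,
    ts_correct(s, co, t_m = 22, s_m = 30, channel = "a")$value + 0.123)
})

test_that("scatter correction matches hand arithmetic and nulls the reference wavelength", {
  wl <- c(440, 715)
  a_t <- spectrum(wl, c(0.5, 0.01))
  c_t <- spectrum(wl, c(1.0, 0.5), kind = "attenuation")
  out <- scatter_correct(a_t, c_t)
  expect_equal(out$value[1], 0.5 - (0.01 / 0.49) * (1.0 - 0.5),
               tolerance = 1e-12)                        # 0.489796
  expect_equal(out$value[2], 0)

  # a_t(lambda_ref) = 0 means no correction at all
  a_t0 <- spectrum(wl, c(0.5, 0))
  expect_equal(scatter_correct(a_t0, c_t)$value, a_t0$value)

  # the printed variant does not null the reference wavelength
  printed <- scatter_correct(a_t, c_t, method = "as_printed")
  expect_equal(printed$value[1], (0.5 / 0.49) * 0.5, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(printed$value[2], 0)))

  expect_error(scatter_correct(spectrum(wl, c(0.5, 0.6)), c_t), "degenerate")
})

test_that("scatter correction nulls 715 nm for arbitrary synthetic spectra", {
  withr::with_seed(5, {
    wl <- seq(400, 730, 5)
    for (i in 1:10) {
      a_t <- spectrum(wl, abs(rnorm(length(wl), 0.2, 0.05)))
      c_t <- spectrum(wl, a_t$value + abs(rnorm(length(wl), 0.8, 0.1)),
                      kind = "attenuation")
      out <- scatter_correct(a_t, c_t, lambda_ref = 715)
      expect_equal(interp_spectrum(out, 715)$value, 0, tolerance = 1e-12)
    }
  })
})

test_that("particulate/dissolved partition is conservative arithmetic", {
  wl <- c(440, 550)
  part <- partition_particulate(
    spectrum(wl, c(0.3, 0.3)), spectrum(wl, c(1.0, 1.0), "attenuation"),
    spectrum(wl, c(0.1, 0.1)), spectrum(wl, c(0.2, 0.2), "attenuation"))
  expect_equal(part$a_p, c(0.2, 0.2))
  expect_equal(part$c_p, c(0.8, 0.8))
  expect_equal(part$b_p, c(0.6, 0.6))

  # zero dissolved fraction passes totals through
  z <- spectrum(wl, c(0, 0))
  part0 <- partition_particulate(spectrum(wl, c(0.3, 0.2)),
                                 spectrum(wl, c(1, 0.9), "attenuation"), z,
                                 spectrum(wl, c(0, 0), "attenuation"))
  expect_equal(part0$a_p, c(0.3, 0.2))
  # fully dissolved sample leaves nothing particulate
  s <- spectrum(wl, c(0.3, 0.2))
  cc <- spectrum(wl, c(1, 0.9), "attenuation")
  part1 <- partition_particulate(s, cc, s, cc)
  expect_equal(part1$b_p, c(0, 0))
})

test_that("full pipeline recovers a zero-noise synthetic run exactly at instrument wavelengths", {
  truth <- fix_truth()
  res <- fix_acs_clean()
  nat <- res$native
  expect_lt(max(abs(nat$a_p - truth_a_p(truth, nat$wavelength))), 1e-9)
  expect_lt(max(abs(nat$c_p - truth_c_p(truth, nat$wavelength))), 1e-9)
  expect_lt(max(abs(nat$a_g - truth_a_g(truth, nat$wavelength))), 1e-9)
  expect_lt(max(abs(nat$b_p - truth_b_p(truth, nat$wavelength))), 1e-9)
  # conservation identities survive the pipeline
  expect_equal(nat$b_p, nat$c_p - nat$a_p, tolerance = 1e-12)
})

test_that("products come out on the uniform 2.5 nm grid with a QC report", {
  res <- fix_acs_clean()
  steps <- diff(res$products$wavelength)
  expect_equal(unique(round(steps, 9)), 2.5)
  expect_equal(range(res$products$wavelength), c(400, 730))
  expect_named(res$products, c("wavelength", "a_p", "c_p", "b_p", "a_g", "c_g"))
  expect_true(all(c("product", "n_negative") %in% names(res$qc)))
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(nrow(glance(res)), 1)
})

test_that("a missing stream is reported by name", {
  runs <- fix_runs_clean()
  broken <- runs$acs
  broken$filtered <- NULL
  expect_error(process_acs_run(broken, runs$coeffs), "filtered")
  broken2 <- runs$acs
  broken2$unfiltered$c <- NULL
  expect_error(process_acs_run(broken2, runs$coeffs), "`c` channel")
})

test_that("recovery error scales proportionally with injected noise", {
  truth <- fix_truth()
  err_at <- function(scale) {
    runs <- render_runs(truth, noise_scale = scale)
    nat <- process_acs_run(runs$acs, runs$coeffs)$native
    median(abs(nat$a_p - truth_a_p(truth, nat$wavelength)))
  }
  e0 <- err_at(0); e1 <- err_at(1); e2 <- err_at(2)
  expect_lt(e0, 1e-9)
  expect_gt(e1, 1e-5)
  expect_gt(e2 / e1, 1.5)
  expect_lt(e2 / e1, 2.5)
})
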