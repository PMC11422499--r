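test_that("the pathlength-amplification transform matches its defining constants", {
  expect_equal(odfp_to_ods(1.0), 0.323)
  expect_equal(odfp_to_ods(0), 0)
  expect_equal(odfp_to_ods(0.5), 0.323 * 0.5^2.0867, tolerance = 1e-12)
  expect_equal(odfp_to_ods(0.5), 0.0760, tolerance = 1e-3)
  # negatives are clamped before the non-integer power
  expect_equal(odfp_to_ods(-0.2), 0)
  # monotone nondecreasing
  x <- seq(-0.1, 1.5, 0.01)
  expect_true(all(diff(odfp_to_ods(x)) >= 0))
  # spectrum form preserved
  s <- spectrum(c(400, 500), c(1, 1), kind = "optical_density")
  expect_equal(odfp_to_ods(s)$value, c(0.323, 0.323))
})

test_that("log-log regression on the transform recovers the amplification exponent", {
  od <- seq(0.05, 1.2, 0.01)
  fit <- lm(log(odfp_to_ods(od)) ~ log(od))
  expect_equal(unname(coef(fit)[2]), 2.0867, tolerance = 1e-9)
  expect_equal(exp(unname(coef(fit)[1])), 0.323, tolerance = 1e-9)
})

test_that("geometric conversion to absorption follows V/A proportionality", {
  expect_equal(ods_to_absorption(0.1, volume_m3 = 0.02, area_m2 = 1),
               log(10) * 0.1 / 0.02, tolerance = 1e-12)   # 11.5129
  expect_equal(ods_to_absorption(0, 0.02, 1), 0)
  expect_equal(ods_to_absorption(0.1, 0.04, 1),
               ods_to_absorption(0.1, 0.02, 1) / 2)
  expect_error(ods_to_absorption(0.1, 0, 1), "volume")
  expect_error(ods_to_absorption(0.1, 0.02, -1), "area")
  expect_equal(spot_area(20), pi * 0.01^2)
  expect_error(spot_area(0), "diameter")
})

test_that("phytoplankton absorption is the particulate/detrital difference", {
  wl <- c(440, 676)
  a_p <- spectrum(wl, c(0.05, 0.03))
  a_d <- spectrum(wl, c(0.01, 0.002))
  expect_equal(phytoplankton_absorption(a_p, a_d)$value, c(0.04, 0.028))
  expect_equal(phytoplankton_absorption(a_p, a_p)$value, c(0, 0))
  z <- spectrum(wl, c(0, 0))
  expect_equal(phytoplankton_absorption(a_p, z)$value, a_p$value)
  # a_ph + a_d = a_p by construction
  a_ph <- phytoplankton_absorption(a_p, a_d)
  expect_equal(a_ph$value + a_d$value, a_p$value)
})

test_that("replicate aggregation matches a two-pass mean/sd oracle", {
  withr::with_seed(31, {
    scans <- tidyr::expand_grid(replicate = 1:3, wavelength = c(400, 500, 600))
    scans$value <- rnorm(nrow(scans))
    agg <- aggregate_replicates(scans)
    for (w in c(400, 500, 600)) {
      v <- scans$value[scans$wavelength == w]
      mu <- sum(v) / length(v)
      s2 <- sum((v - mu)^2) / (length(v) - 1)
      expect_equal(agg$mean[agg$wavelength == w], mu)
      expect_equal(agg$sd[agg$wavelength == w], sqrt(s2))
    }
    expect_equal(agg$n, rep(3L, 3))
    single <- aggregate_replicates(dplyr::filter(scans, replicate == 1))
    expect_true(all(is.na(single$sd)))
  })
})

test_that("detrital fitting recovers a clean exponential and fixes k at the tail mean", {
  wl <- as.numeric(seq(290, 850, 2))
  clean <- spectrum(wl, 0.03 * exp(-0.011 * (wl - 400)))
  fit <- fit_detrital(clean)
  expect_equal(fit$model, "exp_simple")
  expect_equal(fit$s, 0.011, tolerance = 1e-4 / 0.011)
  expect_lt(abs(fit$s - 0.011), 1e-4)
  expect_equal(fit$a0, 0.03, tolerance = 1e-6)

  # a steep exponential is gone by 700 nm, so the 700-850 tail is flat at k
  withk <- spectrum(wl, 0.03 * exp(-0.025 * (wl - 400)) + 0.002)
  fitk <- fit_detrital(withk)
  tail_mean <- mean(withk$value[wl >= 700 & wl <= 850])
  kc <- dplyr::filter(fitk$candidates, model == "exp_offset")
  expect_equal(unique(kc$k), tail_mean)
  expect_lt(abs(unique(kc$k) - 0.002), 1e-5)
  expect_equal(fitk$model, "exp_offset")
  expect_equal(fitk$s, 0.025, tolerance = 1e-3)

  # both fit windows are reported, plus the per-model window average
  expect_equal(sort(unique(fit$candidates$window_nm)),
               c("380-530", "380-600"))
  expect_true("s_mean_windows" %in% names(fit$s_by_model))
  expect_error(fit_detrital(spectrum(seq(400, 700, 2),
                                     rep(0.01, 151))), "380-850")
})

test_that("model selection under a residual pigment peak matches a grid-search oracle", {
  wl <- as.numeric(seq(290, 850, 2))
  base <- 0.03 * exp(-0.0115 * (wl - 400))
  peak <- 0.004 * exp(-(wl - 675)^2 / (2 * 12^2))   # incomplete depigmentation
  contaminated <- spectrum(wl, base + peak)
  fit <- fit_detrital(contaminated)

  # fitted curve lies below the residual peak at its center
  at675 <- which.min(abs(wl - 675))
  expect_lt(fit$fitted$value[at675], contaminated$value[at675])

  # brute-force oracle: profile a0 over a dense S grid per model and window,
  # minimising RMSE on the original scale
  oracle_rmse <- function(model, window) {
    sel <- wl >= window[1] & wl <= window[2]
    x <- wl[sel]; y <- contaminated$value[sel]
    k <- if (model == "exp_offset") {
      mean(contaminated$value[wl >= 700 & wl <= 850])
    } else 0
    best <- Inf
    for (s in seq(0.004, 0.03, 5e-5)) {
      f <- if (model == "power_law") (x / 400)^(-s) else exp(-s * (x - 400))
      a0 <- sum(f * (y - k)) / sum(f^2)
      rmse <- sqrt(mean((y - a0 * f - k)^2))
      best <- min(best, rmse)
    }
    best
  }
  oracle <- expand.grid(model = c("exp_simple", "power_law", "exp_offset"),
                        win = 1:2, stringsAsFactors = FALSE)
  oracle$rmse <- mapply(function(m, w) {
    oracle_rmse(m, list(c(380, 530), c(380, 600))[[w]])
  }, oracle$model, oracle$win)
  oracle_winner <- oracle$model[which.min(oracle$rmse)]
  expect_equal(fit$model, oracle_winner)
})

test_that("linearised and refined estimators agree on clean data", {
  wl <- as.numeric(seq(290, 850, 2))
  clean <- spectrum(wl, 0.025 * exp(-0.013 * (wl - 400)))
  lin <- fit_detrital(clean, refine = FALSE)
  ref <- fit_detrital(clean, refine = TRUE)
  expect_equal(lin$s, ref$s, tolerance = 1e-6)
  expect_equal(lin$a0, ref$a0, tolerance = 1e-6)
})

test_that("the filter-pad pipeline inverts rendered pads and recovers pigment ratios", {
  truth <- fix_truth()
  runs <- fix_runs_clean()
  fp <- runs$filterpad
  res <- process_filterpad(fp$sample_scans, fp$blank, fp$volume_m3,
                           fp$spot_diameter_mm, fp$depigmented_scans)
  s <- res$spectra
  # zero-noise render/process round trip is exact
  expect_lt(max(abs(s$a_p - truth_a_p(truth, s$wavelength, null_715 = FALSE))),
            1e-9)
  expect_lt(max(abs(s$a_d - truth_a_d(truth, s$wavelength, null_715 = FALSE))),
            1e-9)
  # blue-to-red phytoplankton absorption ratio at the noisy level stays in
  # the generator's documented envelope (5%)
  runs_n <- fix_runs_noisy()
  fpn <- runs_n$filterpad
  resn <- process_filterpad(fpn$sample_scans, fpn$blank, fpn$volume_m3,
                            fpn$spot_diameter_mm, fpn$depigmented_scans)
  gn <- glance(resn)
  ratio <- gn$a_ph_440 / gn$a_ph_676
  ratio_true <- truth_a_ph(truth, 440, null_715 = FALSE) /
    truth_a_ph(truth, 676, null_715 = FALSE)
  expect_lt(abs(ratio / ratio_true - 1), 0.05)
})
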