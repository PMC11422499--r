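#' Pathlength-amplification transform of filter-pad optical density
#'
#' Particles concentrated on a glass-fiber filter sit in a highly
#' scattering medium that lengthens the effective optical path, inflating
#' measured optical density relative to the same particles in suspension.
#' The empirical power-law transform
#' \deqn{OD_s = 0.323\,(OD_{fp})^{2.0867}}
#' converts blank-corrected filter-pad OD to suspension-equivalent OD.
#' Negative blank-corrected values (pure noise around zero loading) are
#' clamped to zero before the non-integer power, which is undefined for
#' negatives.
#'
#' @param od_fp Blank-corrected filter-pad OD spectrum (tibble), or a bare
#'   numeric vector of OD values.
#' @return Suspension-equivalent OD in the same form as the input.
#' @examples
#' odfp_to_ods(c(0, 0.5, 1.0))
#' @export
odfp_to_ods <- function(od_fp) {
  f <- function(x) 0.323 * pmax(x, 0)^2.0867
  if (is.data.frame(od_fp)) {
    validate_spectrum(od_fp)
    out <- od_fp
    out$value <- f(od_fp$value)
    return(out)
  }
  f(od_fp)
}

#' Convert suspension-equivalent OD to an absorption coefficient
#'
#' Geometric conversion from optical density to an absorption coefficient
#' using the filtration pathlength V/A:
#' \deqn{a(\lambda) = \ln(10)\, OD_s(\lambda)\, / \,(V/A)}
#' where V is the filtration volume (m^3) and A the area of the particle
#' spot on the filter (m^2).
#'
#' @param od_s Suspension-equivalent OD spectrum (tibble or numeric).
#' @param volume_m3 Filtration volume, m^3 (> 0).
#' @param area_m2 Particle-spot area, m^2 (> 0); see [spot_area()].
#' @return Absorption spectrum (m^-1) in the same form as the input.
#' @export
ods_to_absorption <- function(od_s, volume_m3, area_m2) {
  if (!is.finite(volume_m3) || volume_m3 <= 0) abort("filtration volume must be > 0")
  if (!is.finite(area_m2) || area_m2 <= 0) abort("spot area must be > 0")
  f <- function(x) log(10) * x / (volume_m3 / area_m2)
  if (is.data.frame(od_s)) {
    validate_spectrum(od_s)
    out <- od_s
    out$value <- f(od_s$value)
    out$kind <- "absorption"
    return(out)
  }
  f(od_s)
}

#' Particle-spot area from its measured diameter
#'
#' @param diameter_mm Spot diameter in millimeters, as measured with
#'   calipers on the filter.
#' @return Spot area in m^2.
#' @export
spot_area <- function(diameter_mm) {
  if (!is.finite(diameter_mm) || diameter_mm <= 0) {
    abort("spot diameter must be a positive number (mm)")
  }
  pi * (diameter_mm / 2 / 1000)^2
}

#' Phytoplankton absorption by difference
#'
#' `a_ph = a_p - a_d`: total particle absorption minus depigmented
#' (detrital) absorption, wavelength by wavelength on a shared axis.
#'
#' @param a_p Total particle absorption spectrum.
#' @param a_d Depigmented (detrital) absorption spectrum.
#' @return Phytoplankton absorption spectrum.
#' @export
phytoplankton_absorption <- function(a_p, a_d) {
  out <- spectral_difference(a_p, a_d)
  out$source <- "a_ph = a_p - a_d"
  out
}

#' Aggregate replicate spectra
#'
#' Per-wavelength mean, sample standard deviation (n-1 denominator) and
#' count across replicate scans of the same sample.
#'
#' @param scans Long tibble with columns `replicate`, `wavelength`,
#'   `value`.
#' @return Tibble `wavelength`, `mean`, `sd`, `n` (`sd` is `NA` for a
#'   single replicate).
#' @export
aggregate_replicates <- function(scans) {
  if (!all(c("replicate", "wavelength", "value") %in% names(scans))) {
    abort("`scans` needs columns replicate, wavelength, value")
  }
  scans %>%
    dplyr::group_by(.data$wavelength) %>%
    dplyr::summarise(mean = mean(.data$value),
                     sd = sd(.data$value),
                     n = dplyr::n(), .groups = "drop") %>%
    dplyr::arrange(.data$wavelength)
}

detrital_models <- c("exp_simple", "power_law", "exp_offset")
detrital_windows <- list(c(380, 530), c(380, 600))

# fit one (model, window) candidate by linearised least squares; returns NULL
# when the log transform is infeasible on that window
fit_detrital_candidate <- function(wl, a, model, window, k_tail,
                                   refine = FALSE, init_s = c(0.012, 0.014)) {
  in_win <- wl >= window[1] & wl <= window[2]
  x <- wl[in_win]; y <- a[in_win]
  offset <- if (model == "exp_offset") k_tail else 0
  ypos <- y - offset
  if (any(ypos <= 0)) return(NULL)
  if (model == "power_law") {
    ft <- lm(log(ypos) ~ I(log(x / 400)))
    s_x <- -coef(ft)[[2]]
    a0 <- exp(coef(ft)[[1]])
    fitted_fun <- function(l) a0 * (l / 400)^(-s_x)
  } else {
    ft <- lm(log(ypos) ~ I(x - 400))
    s_x <- -coef(ft)[[2]]
    a0 <- exp(coef(ft)[[1]])
    fitted_fun <- function(l) a0 * exp(-s_x * (l - 400)) + offset
    if (model == "exp_simple") fitted_fun <- function(l) a0 * exp(-s_x * (l - 400))
  }
  if (refine) {
    # iterative refinement on the original scale, seeded at the two
    # conventional starting slopes; keep whichever start converges lower
    best <- NULL
    for (s0 in init_s) {
      fit_try <- tryCatch({
        if (model == "power_law") {
          minpack.lm::nlsLM(y ~ A * (x / 400)^(-S), start = list(A = a0, S = s0),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
        } else {
          minpack.lm::nlsLM(y ~ A * exp(-S * (x - 400)) + offset,
                            start = list(A = a0, S = s0),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
        }
      }, error = function(e) NULL)
      if (!is.null(fit_try)) {
        rss <- sum(stats::residuals(fit_try)^2)
        if (is.null(best) || rss < best$rss) best <- list(fit = fit_try, rss = rss)
      }
    }
    if (!is.null(best)) {
      a0 <- coef(best$fit)[["A"]]
      s_x <- coef(best$fit)[["S"]]
      fitted_fun <- if (model == "power_law") {
        function(l) a0 * (l / 400)^(-s_x)
      } else if (model == "exp_offset") {
        function(l) a0 * exp(-s_x * (l - 400)) + offset
      } else {
        function(l) a0 * exp(-s_x * (l - 400))
      }
    }
  }
  yhat <- fitted_fun(x)
  rmse <- sqrt(mean((y - yhat)^2))
  r <- if (sd(yhat) > 0 && sd(y) > 0) stats::cor(y, yhat) else NA_real_
  list(model = model, window = window, s = s_x, a0 = a0,
       k = if (model == "exp_offset") k_tail else NA_real_,
       rmse = rmse, r = r, fitted_fun = fitted_fun)
}

#' Fit a smooth detrital absorption spectrum
#'
#' When chemical depigmentation leaves residual pigment peaks in a
#' measured detrital spectrum, a smooth model is fitted instead.  Three
#' model families are tried over two fit windows (380-530 nm and
#' 380-600 nm):
#' \itemize{
#'   \item `exp_simple`: \eqn{a_d(\lambda) = a_d(400)\,e^{-S(\lambda-400)}}
#'   \item `power_law`: \eqn{a_d(\lambda) = a_d(400)\,(\lambda/400)^{-S}}
#'   \item `exp_offset`: exponential plus a constant null offset k, fixed
#'     (not fitted) at the mean of the spectrum over 700-850 nm
#' }
#' The spectral slope S of each candidate is estimated by linear least
#' squares on the log-transformed (offset-subtracted, for `exp_offset`)
#' values; candidates whose transform window contains nonpositive values
#' are dropped.  Among surviving candidates the one with the lowest RMSE
#' over its own fit window is retained, ties broken by the higher
#' correlation coefficient.  Setting `refine = TRUE` additionally runs
#' Levenberg-Marquardt refinement on the original scale, seeded at the
#' conventional starting slopes 0.012 and 0.014 nm^-1.
#'
#' @param a_d Measured (possibly pigment-contaminated) detrital absorption
#'   spectrum covering 380-850 nm.
#' @param refine Run nonlinear refinement after the linearised fit.
#' @param windows List of fit windows (nm); default the two standard ones.
#' @return An object of class `detrital_fit`: the selected model with
#'   fields `model`, `window`, `s` (nm^-1, or dimensionless for the power
#'   law), `a0` (m^-1 at 400 nm), `k`, `rmse`, `r`, the full candidate
#'   table, the per-model mean of S across the two windows, and the
#'   fitted spectrum on the input axis.  Supports `tidy()` (candidate
#'   table), `glance()` (selected fit) and `autoplot()`.
#' @export
fit_detrital <- function(a_d, refine = FALSE, windows = detrital_windows) {
  validate_spectrum(a_d)
  wl <- a_d$wavelength; a <- a_d$value
  if (min(wl) > 380 || max(wl) < 850) {
    abort("detrital fitting needs coverage of 380-850 nm (fit windows plus the 700-850 nm null-offset tail)")
  }
  tail_sel <- wl >= 700 & wl <= 850
  k_tail <- mean(a[tail_sel])

  cands <- list()
  for (model in detrital_models) {
    for (window in windows) {
      cand <- fit_detrital_candidate(wl, a, model, window, k_tail,
                                     refine = refine)
      if (!is.null(cand)) cands[[length(cands) + 1L]] <- cand
    }
  }
  if (!length(cands)) {
    abort("all detrital model candidates were infeasible (nonpositive values in every log-transform window)")
  }
  tab <- purrr::map_dfr(cands, function(cd) {
    tibble::tibble(model = cd$model,
                   window_nm = sprintf("%g-%g", cd$window[1], cd$window[2]),
                   s = cd$s, a0 = cd$a0, k = cd$k, rmse = cd$rmse, r = cd$r)
  })
  # selection: lowest RMSE, ties to the higher correlation coefficient
  ord <- order(tab$rmse, -tab$r)
  best <- cands[[ord[1]]]
  s_by_model <- tab %>%
    dplyr::group_by(.data$model) %>%
    dplyr::summarise(s_mean_windows = mean(.data$s), .groups = "drop")
  fitted <- tibble::tibble(wavelength = wl, value = best$fitted_fun(wl),
                           kind = "absorption", source = "detrital fit")
  structure(list(model = best$model, window = best$window, s = best$s,
                 a0 = best$a0, k = best$k, rmse = best$rmse, r = best$r,
                 candidates = tab, s_by_model = s_by_model,
                 fitted = fitted, observed = a_d, refined = refine),
            class = "detrital_fit")
}

#' @export
print.detrital_fit <- function(x, ...) {
  cat(sprintf("<detrital_fit> %s over %g-%g nm: S = %.5f, a_d(400) = %.5f",
              x$model, x$window[1], x$window[2], x$s, x$a0))
  if (!is.na(x$k)) cat(sprintf(", k = %.5f", x$k))
  cat(sprintf("\n  rmse = %.3g m^-1, r = %.4f (%d candidates)\n",
              x$rmse, x$r, nrow(x$candidates)))
  invisible(x)
}

#' @rdname fit_detrital
#' @param x A `detrital_fit` object.
#' @param ... Unused.
#' @export
tidy.detrital_fit <- function(x, ...) x$candidates

#' @rdname fit_detrital
#' @export
glance.detrital_fit <- function(x, ...) {
  tibble::tibble(model = x$model,
                 window_nm = sprintf("%g-%g", x$window[1], x$window[2]),
                 s = x$s, a0 = x$a0, k = x$k, rmse = x$rmse, r = x$r,
                 refined = x$refined)
}

#' Process a set of filter-pad scans for one sample
#'
#' End-to-end filter-pad pipeline: subtract the blank scan from each
#' replicate, average replicates, clamp negatives, apply the
#' pathlength-amplification transform and the V/A geometric conversion to
#' obtain total particle absorption `a_p`; the same route applied to the
#' depigmented scans yields detrital absorption `a_d`, and `a_ph` follows
#' by difference.  When `fit_detrital = TRUE` (or when no depigmented scan
#' exists) a smooth model fit replaces/supplies `a_d`.
#'
#' @param sample_scans Long tibble of sample scans (`replicate`,
#'   `wavelength`, `value` = OD_fp).
#' @param blank Blank filter spectrum on the same axis.
#' @param volume_m3 Filtration volume, m^3.
#' @param spot_diameter_mm Measured particle-spot diameter, mm.
#' @param depigmented_scans Optional long tibble of depigmented scans.
#' @param fit_smooth_detrital Replace the measured detrital spectrum by its
#'   smooth model fit (used when depigmentation left residual peaks).
#' @return An object of class `filterpad_result` with `spectra` (tibble
#'   `wavelength`, `a_p`, `a_d`, `a_ph`, `a_p_sd`), the detrital fit (if
#'   any), and the geometry used.  Supports `tidy()`, `glance()` and
#'   `autoplot()`.
#' @export
process_filterpad <- function(sample_scans, blank, volume_m3,
                              spot_diameter_mm, depigmented_scans = NULL,
                              fit_smooth_detrital = FALSE) {
  area <- spot_area(spot_diameter_mm)
  od_to_a <- function(scans) {
    agg <- scans %>%
      dplyr::group_by(.data$replicate) %>%
      dplyr::group_modify(function(d, key) {
        s <- tibble::tibble(wavelength = d$wavelength, value = d$value)
        s <- spectral_difference(s, blank)
        s$value <- pmax(s$value, 0)
        odfp_to_ods(s) %>% ods_to_absorption(volume_m3, area)
      }) %>%
      dplyr::ungroup()
    aggregate_replicates(agg)
  }
  ap_agg <- od_to_a(sample_scans)
  a_p <- tibble::tibble(wavelength = ap_agg$wavelength, value = ap_agg$mean,
                        kind = "absorption", source = "filter pad a_p")
  fit <- NULL
  if (!is.null(depigmented_scans)) {
    ad_agg <- od_to_a(depigmented_scans)
    a_d <- tibble::tibble(wavelength = ad_agg$wavelength, value = ad_agg$mean,
                          kind = "absorption", source = "filter pad a_d")
    if (fit_smooth_detrital) {
      fit <- fit_detrital(a_d)
      a_d <- fit$fitted
    }
  } else {
    fit <- fit_detrital(a_p)
    a_d <- fit$fitted
  }
  a_ph <- phytoplankton_absorption(a_p, a_d)
  spectra <- tibble::tibble(wavelength = a_p$wavelength,
                            a_p = a_p$value, a_d = a_d$value,
                            a_ph = a_ph$value, a_p_sd = ap_agg$sd)
  structure(list(spectra = spectra, detrital_fit = fit,
                 geometry = list(volume_m3 = volume_m3,
                                 spot_diameter_mm = spot_diameter_mm,
                                 area_m2 = area),
                 n_replicates = max(ap_agg$n)),
            class = "filterpad_result")
}

#' @export
print.filterpad_result <- function(x, ...) {
  cat(sprintf("<filterpad_result> %d wavelengths (%g-%g nm), %d replicate(s)\n",
              nrow(x$spectra), min(x$spectra$wavelength),
              max(x$spectra$wavelength), x$n_replicates))
  cat(sprintf("  pathlength V/A = %.3f m\n",
              x$geometry$volume_m3 / x$geometry$area_m2))
  if (!is.null(x$detrital_fit)) {
    cat("  detrital spectrum from model fit:\n  ")
    print(x$detrital_fit)
  }
  invisible(x)
}

#' @rdname process_filterpad
#' @param x A `filterpad_result`.
#' @param ... Unused.
#' @export
tidy.filterpad_result <- function(x, ...) {
  x$spectra %>%
    dplyr::select(-dplyr::all_of("a_p_sd")) %>%
    tidyr::pivot_longer(-dplyr::all_of("wavelength"),
                        names_to = "product", values_to = "value")
}

#' @rdname process_filterpad
#' @export
glance.filterpad_result <- function(x, ...) {
  s <- x$spectra
  tibble::tibble(
    n_wavelengths = nrow(s),
    n_replicates = x$n_replicates,
    pathlength_m = x$geometry$volume_m3 / x$geometry$area_m2,
    a_ph_440 = interp_spectrum_values(s$wavelength, s$a_ph, 440),
    a_ph_676 = interp_spectrum_values(s$wavelength, s$a_ph, 676),
    detrital_model = if (is.null(x$detrital_fit)) NA_character_ else x$detrital_fit$model)
}
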