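#' Built-in backscatter sensor family configurations
#'
#' Channel layouts for the four sensor families the flow-through system
#' supports: two single-angle sensors converted to b_bp with a chi factor
#' (`bb9`: nine wavelengths at 124 degrees; `hs6`: six wavelengths at
#' 141 degrees) and two three-angle sensors whose volume scattering
#' function is integrated over the backward hemisphere (`vsf3`: three
#' wavelengths; `vsfr`: 650 nm only; both at 104/130/151 degrees).
#'
#' @param family One of `"bb9"`, `"hs6"`, `"vsf3"`, `"vsfr"`.
#' @return A tibble with columns `family`, `angle_deg`, `wavelength`,
#'   `route` (`"chi"` or `"integrate"`).
#' @examples
#' sensor_config("vsf3")
#' @export
sensor_config <- function(family = c("bb9", "hs6", "vsf3", "vsfr")) {
  family <- match.arg(family)
  cfg <- switch(family,
    bb9 = tidyr::expand_grid(
      angle_deg = 124,
      wavelength = c(409, 441, 488, 508, 526, 594, 652, 679, 717)) %>%
      dplyr::mutate(route = "chi"),
    hs6 = tidyr::expand_grid(
      angle_deg = 141,
      wavelength = c(375, 440, 488, 550, 620, 700)) %>%
      dplyr::mutate(route = "chi"),
    vsf3 = tidyr::expand_grid(
      angle_deg = c(104, 130, 151),
      wavelength = c(440, 532, 660)) %>%
      dplyr::mutate(route = "integrate"),
    vsfr = tidyr::expand_grid(
      angle_deg = c(104, 130, 151),
      wavelength = 650) %>%
      dplyr::mutate(route = "integrate"))
  dplyr::bind_cols(tibble::tibble(family = family), cfg)
}

validate_calibration <- function(cal) {
  need <- c("angle_deg", "wavelength", "scale_factor", "dark_offset")
  if (!is.data.frame(cal) || !all(need %in% names(cal))) {
    abort(sprintf("calibration needs columns %s", paste(need, collapse = ", ")))
  }
  if (any(cal$scale_factor <= 0)) abort("scale factors must be positive")
  if ("path_length_m" %in% names(cal) && any(cal$path_length_m < 0)) {
    abort("path lengths must be nonnegative")
  }
  invisible(cal)
}

#' Convert raw scattering counts to the volume scattering function
#'
#' Applies the per-channel factory calibration, beta_t = SF(theta,lambda) *
#' (V - DO(theta,lambda)), then reduces the time series by the median.
#' Negative values (counts below the dark offset, possible in very clear
#' water) are retained and flagged in the `qc_negative` column rather than
#' clamped.
#'
#' @param series Long tibble of raw counts with columns `time_s`,
#'   `angle_deg`, `wavelength`, `counts`.
#' @param cal Calibration tibble with columns `angle_deg`, `wavelength`,
#'   `scale_factor` (m^-1 sr^-1 per count), `dark_offset` (counts), and
#'   optionally `path_length_m` and `chi`.
#' @param fraction Label for the resulting VSF: `"total"`, `"dissolved"` or
#'   `"particulate"`.
#' @return A tibble `angle_deg`, `wavelength`, `beta` (m^-1 sr^-1),
#'   `fraction`, `qc_negative`.
#' @export
counts_to_beta <- function(series, cal,
                           fraction = c("total", "dissolved", "particulate")) {
  fraction <- match.arg(fraction)
  validate_calibration(cal)
  need <- c("time_s", "angle_deg", "wavelength", "counts")
  if (!all(need %in% names(series))) {
    abort(sprintf("count series needs columns %s", paste(need, collapse = ", ")))
  }
  chans <- dplyr::distinct(series, .data$angle_deg, .data$wavelength)
  missing <- dplyr::anti_join(chans, cal, by = c("angle_deg", "wavelength"))
  if (nrow(missing) > 0) {
    abort(sprintf("no calibration for channel(s): %s",
                  paste(sprintf("(%g deg, %g nm)", missing$angle_deg,
                                missing$wavelength), collapse = ", ")))
  }
  series %>%
    dplyr::left_join(cal, by = c("angle_deg", "wavelength")) %>%
    dplyr::mutate(beta = .data$scale_factor * (.data$counts - .data$dark_offset)) %>%
    dplyr::group_by(.data$angle_deg, .data$wavelength) %>%
    dplyr::summarise(beta = median(.data$beta), .groups = "drop") %>%
    dplyr::mutate(fraction = fraction, qc_negative = .data$beta < 0) %>%
    dplyr::arrange(.data$angle_deg, .data$wavelength)
}

#' Compensate the VSF for absorption along the optical path
#'
#' Light travelling from source to detector inside a scattering sensor is
#' attenuated by absorption over the instrument's effective optical path
#' length L (meters, a per-channel calibration property):
#' `beta = beta_t * exp(L * a(lambda))`, where `a` is the
#' scatter-corrected absorption spectrum of the water being measured
#' (total absorption for unfiltered runs, dissolved absorption for
#' filtered runs), interpolated onto each channel wavelength.
#'
#' @param vsf VSF tibble from [counts_to_beta()].
#' @param a_sc Absorption spectrum covering the channel wavelengths.
#' @param cal Calibration tibble carrying `path_length_m` per channel (or
#'   supply `path_length_m` directly).
#' @param path_length_m Optional scalar override of the path length, m.
#' @return The VSF tibble with compensated `beta`.
#' @export
path_absorption_correct <- function(vsf, a_sc, cal = NULL,
                                    path_length_m = NULL) {
  validate_spectrum(a_sc)
  if (is.null(path_length_m)) {
    if (is.null(cal) || !"path_length_m" %in% names(cal)) {
      abort("supply `path_length_m` directly or a calibration with a path_length_m column")
    }
    vsf <- dplyr::left_join(
      vsf, dplyr::select(cal, dplyr::all_of(c("angle_deg", "wavelength",
                                              "path_length_m"))),
      by = c("angle_deg", "wavelength"))
  } else {
    vsf$path_length_m <- path_length_m
  }
  if (any(is.na(vsf$path_length_m)) || any(vsf$path_length_m < 0)) {
    abort("path length missing or negative for some channels")
  }
  a_here <- interp_spectrum_values(a_sc$wavelength, a_sc$value, vsf$wavelength)
  vsf %>%
    dplyr::mutate(beta = .data$beta * exp(.data$path_length_m * a_here)) %>%
    dplyr::select(-dplyr::all_of("path_length_m"))
}

#' Subtract the dissolved VSF from the unfiltered VSF
#'
#' The particle-field volume scattering function is obtained by measured
#' subtraction of the 0.2-micron-filtered run from the unfiltered run,
#' channel by channel, in place of a computational pure-seawater
#' correction.
#'
#' @param unfiltered,filtered VSF tibbles with identical channels.
#' @return Particulate VSF tibble (`fraction = "particulate"`).
#' @export
subtract_dissolved <- function(unfiltered, filtered) {
  joined <- dplyr::full_join(
    dplyr::select(unfiltered, dplyr::all_of(c("angle_deg", "wavelength", "beta"))),
    dplyr::select(filtered, dplyr::all_of(c("angle_deg", "wavelength", "beta"))),
    by = c("angle_deg", "wavelength"), suffix = c("_u", "_f"))
  if (anyNA(joined$beta_u) || anyNA(joined$beta_f)) {
    abort("unfiltered and filtered VSFs do not share the same channels")
  }
  joined %>%
    dplyr::transmute(.data$angle_deg, .data$wavelength,
                     beta = .data$beta_u - .data$beta_f,
                     fraction = "particulate") %>%
    dplyr::arrange(.data$angle_deg, .data$wavelength)
}

#' Particulate backscattering from a single-angle VSF (chi factor)
#'
#' Converts a single-angle particulate VSF measurement to the backward
#' hemisphere integral via the dimensionless chi factor:
#' `b_bp(lambda) = 2 * pi * chi * beta_p(theta, lambda)`.  Chi depends on
#' the sensor's centroid angle and the particle phase function; no default
#' is provided because no universal value exists.
#'
#' @param beta_p Particulate VSF tibble (single angle per wavelength).
#' @param cal Calibration tibble with a `chi` column, or `chi` directly.
#' @param chi Optional scalar chi override.
#' @return Tibble `wavelength`, `angle_deg`, `bbp` (m^-1).
#' @examples
#' vsf <- tibble::tibble(angle_deg = 124, wavelength = 441,
#'                       beta = 1e-4, fraction = "particulate")
#' chi_bbp(vsf, chi = 1.1)
#' @export
chi_bbp <- function(beta_p, cal = NULL, chi = NULL) {
  if (is.null(chi)) {
    if (is.null(cal) || !"chi" %in% names(cal)) {
      abort(paste("no chi factor configured: supply `chi` or a calibration",
                  "with a chi column (chi is sensor- and angle-specific and",
                  "has no defensible default)"))
    }
    beta_p <- dplyr::left_join(
      beta_p, dplyr::select(cal, dplyr::all_of(c("angle_deg", "wavelength", "chi"))),
      by = c("angle_deg", "wavelength"))
  } else {
    beta_p$chi <- chi
  }
  if (anyNA(beta_p$chi) || any(beta_p$chi <= 0)) {
    abort("chi factor missing or nonpositive for some channels")
  }
  beta_p %>%
    dplyr::transmute(.data$wavelength, .data$angle_deg,
                     bbp = 2 * pi * .data$chi * .data$beta) %>%
    dplyr::arrange(.data$wavelength)
}

# coefficients of the unique cubic through 4 points, lowest degree first
cubic_through <- function(x, y) {
  solve(outer(x, 0:3, `^`), y)
}

# analytic integral of a cubic (coeffs lowest degree first) over [lo, hi]
integrate_cubic <- function(coefs, lo, hi) {
  k <- seq_along(coefs)
  sum(coefs * (hi^k - lo^k) / k)
}

#' Particulate backscattering by three-angle VSF integration
#'
#' For sensors that resolve the VSF at three backward angles, the
#' backscattering coefficient is obtained per wavelength by (1) forming
#' the polar integrand `w(theta) = 2 * pi * sin(theta) * beta_p(theta)`
#' at the three measurement angles (in radians), (2) appending the exact
#' endpoint `w(pi) = 0` (since sin(pi) = 0), (3) passing the unique third
#' order polynomial through the four points, and (4) integrating it
#' analytically from pi/2 to pi.  This is deterministic interpolation, not
#' regression: the result is independent of the order of the input angles,
#' and exact whenever the integrand is itself a cubic vanishing at pi.
#' The stretch between 90 degrees and the smallest measured angle is
#' covered only by polynomial extrapolation, a documented property of the
#' procedure.
#'
#' @param beta_p Particulate VSF tibble with exactly three distinct angles
#'   per wavelength, all strictly inside (90, 180) degrees.
#' @return Tibble `wavelength`, `bbp` (m^-1).
#' @examples
#' vsf <- tidyr::expand_grid(angle_deg = c(104, 130, 151), wavelength = 532)
#' vsf$beta <- 1e-3   # isotropic: b_bp is close to 2*pi*beta
#' integrate_vsf(vsf)
#' @export
integrate_vsf <- function(beta_p) {
  if (!all(c("angle_deg", "wavelength", "beta") %in% names(beta_p))) {
    abort("`beta_p` needs columns angle_deg, wavelength, beta")
  }
  beta_p %>%
    dplyr::group_by(.data$wavelength) %>%
    dplyr::group_modify(function(d, key) {
      ang <- d$angle_deg
      if (length(ang) != 3L || anyDuplicated(ang)) {
        abort(sprintf(
          "three distinct measurement angles required per wavelength (got %s at %g nm)",
          paste(ang, collapse = "/"), key$wavelength[[1]]))
      }
      if (any(ang <= 90) || any(ang >= 180)) {
        abort("measurement angles must lie strictly inside (90, 180) degrees")
      }
      th <- ang * pi / 180
      w <- 2 * pi * sin(th) * d$beta
      coefs <- cubic_through(c(th, pi), c(w, 0))
      tibble::tibble(bbp = integrate_cubic(coefs, pi / 2, pi))
    }) %>%
    dplyr::ungroup()
}

#' Process a complete backscatter run
#'
#' Orchestrates one sensor's unfiltered and filtered count records through
#' calibration ([counts_to_beta()]), along-path absorption compensation
#' ([path_absorption_correct()], using total absorption for the unfiltered
#' stream and dissolved absorption for the filtered stream), dissolved
#' subtraction ([subtract_dissolved()]) and the appropriate b_bp route
#' (chi conversion for single-angle sensors, cubic VSF integration for
#' three-angle sensors).
#'
#' @param unfiltered,filtered Raw count series (`time_s`, `angle_deg`,
#'   `wavelength`, `counts`).
#' @param cal Calibration tibble (see [counts_to_beta()]); must carry
#'   `path_length_m`, and `chi` when `route = "chi"`.
#' @param a_sc Scatter-corrected total absorption spectrum.
#' @param a_g Dissolved absorption spectrum.
#' @param route `"chi"` or `"integrate"`.
#' @return Tibble `wavelength`, `bbp` (m^-1), with the particulate VSF
#'   attached as attribute `"beta_p"`.
#' @export
process_scatter_run <- function(unfiltered, filtered, cal, a_sc, a_g,
                                route = c("chi", "integrate")) {
  route <- match.arg(route)
  beta_u <- counts_to_beta(unfiltered, cal, fraction = "total") %>%
    path_absorption_correct(a_sc, cal)
  beta_f <- counts_to_beta(filtered, cal, fraction = "dissolved") %>%
    path_absorption_correct(a_g, cal)
  beta_p <- subtract_dissolved(beta_u, beta_f)
  out <- if (route == "chi") {
    chi_bbp(beta_p, cal) %>% dplyr::select(dplyr::all_of(c("wavelength", "bbp")))
  } else {
    integrate_vsf(beta_p)
  }
  attr(out, "beta_p") <- beta_p
  out
}
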