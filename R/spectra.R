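#' Spectral data model
#'
#' A spectrum is an ordinary tibble with a `wavelength` column (nm, strictly
#' increasing) and a `value` column, optionally tagged with a `kind`
#' (`"absorption"`, `"attenuation"`, `"scattering"` or `"optical_density"`)
#' and a free-text `source` label.  All pipeline functions take and return
#' these tibbles so results chain with the pipe.
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly increasing.
#' @param value Numeric vector, same length as `wavelength`.  Units are
#'   m^-1 for absorption/attenuation/scattering and dimensionless for
#'   optical density.
#' @param kind One of `"absorption"`, `"attenuation"`, `"scattering"`,
#'   `"optical_density"`.
#' @param source Free-text instrument or processing-stage label.
#' @return A tibble with columns `wavelength`, `value`, `kind`, `source`.
#' @examples
#' spectrum(c(440, 550, 676), c(0.05, 0.01, 0.03), kind = "absorption")
#' @export
spectrum <- function(wavelength, value,
                     kind = c("absorption", "attenuation", "scattering",
                              "optical_density"),
                     source = NA_character_) {
  kind <- match.arg(kind)
  s <- tibble::tibble(wavelength = as.numeric(wavelength),
                      value = as.numeric(value),
                      kind = kind, source = source)
  validate_spectrum(s)
  s
}

#' Validate a spectrum tibble
#'
#' Checks the invariants every spectral function relies on: the two required
#' columns exist, are the same length (guaranteed by the data frame), and the
#' wavelength axis is strictly increasing and finite.
#'
#' @param s A data frame with columns `wavelength` and `value`.
#' @return `s`, invisibly, if valid; otherwise an error.
#' @export
validate_spectrum <- function(s) {
  if (!is.data.frame(s) || !all(c("wavelength", "value") %in% names(s))) {
    abort("a spectrum needs `wavelength` and `value` columns")
  }
  if (nrow(s) == 0L) abort("spectrum is empty")
  wl <- s$wavelength
  if (anyNA(wl) || any(!is.finite(wl))) abort("wavelengths must be finite")
  if (any(diff(wl) <= 0)) abort("wavelengths must be strictly increasing")
  invisible(s)
}

#' Units label for a spectral kind
#' @param kind Spectral kind string.
#' @return Unit label used on plot axes: `"m^-1"` or `""` (optical density).
#' @export
spectral_units <- function(kind) {
  if (identical(kind, "optical_density")) "" else "m^-1"
}

#' Median time reduction of a spectral time series
#'
#' Collapses a spectral time series to one spectrum by taking the
#' per-wavelength median over all time steps.  The median is the default
#' (and sole) reduction because it is insensitive to the bubble spikes and
#' burst noise that contaminate flow-through records: replacing any strict
#' minority of time steps with arbitrary outliers leaves it unchanged.
#' With an even number of records the median is the mean of the two central
#' order statistics.
#'
#' @param series A tibble in long form with columns `time_s`, `wavelength`,
#'   `value` (plus optional `kind`/`source`, which are carried through).
#' @return A spectrum tibble (one row per wavelength).
#' @examples
#' ts <- tidyr::expand_grid(time_s = 0:9, wavelength = c(440, 550))
#' ts$value <- 0.5
#' median_reduce(ts)
#' @export
median_reduce <- function(series) {
  if (!is.data.frame(series) ||
      !all(c("time_s", "wavelength", "value") %in% names(series))) {
    abort("`series` needs columns time_s, wavelength, value")
  }
  if (nrow(series) == 0L) abort("cannot reduce an empty time series")
  keep <- intersect(c("kind", "source"), names(series))
  out <- series %>%
    dplyr::group_by(.data$wavelength) %>%
    dplyr::summarise(value = median(.data$value, na.rm = TRUE),
                     dplyr::across(dplyr::all_of(keep), dplyr::first),
                     .groups = "drop") %>%
    dplyr::arrange(.data$wavelength)
  out
}

#' Optional rolling-median despiker for spectral time series
#'
#' Flags, per wavelength channel, time steps whose deviation from a rolling
#' median exceeds `n_mad` robust standard deviations (MAD), and drops them.
#' Off by default throughout the pipelines: the plain median reduction
#' already rejects minority spikes, so this is only useful when more than
#' a small fraction of a record is contaminated.
#'
#' @param series Long spectral time series (`time_s`, `wavelength`, `value`).
#' @param window Odd integer width of the rolling median, in time steps.
#' @param n_mad Rejection threshold in MAD units.
#' @return The series with flagged rows removed.
#' @export
despike_timeseries <- function(series, window = 11L, n_mad = 5) {
  if (window %% 2L == 0L) window <- window + 1L
  series %>%
    dplyr::group_by(.data$wavelength) %>%
    dplyr::arrange(.data$time_s, .by_group = TRUE) %>%
    dplyr::mutate(
      .rm = if (dplyr::n() >= window) {
        stats::runmed(.data$value, window, endrule = "median")
      } else {
        rep(median(.data$value), dplyr::n())
      },
      .mad = stats::mad(.data$value - .rm) + .Machine$double.eps,
      .keep_row = abs(.data$value - .rm) <= n_mad * .mad
    ) %>%
    dplyr::ungroup() %>%
    dplyr::filter(.data$.keep_row) %>%
    dplyr::select(-dplyr::all_of(c(".rm", ".mad", ".keep_row")))
}

# shape-preserving cubic Hermite interpolation with a hard no-extrapolation
# contract; every spectral interpolation in the package funnels through here
interp_spectrum_values <- function(wavelength, value, at) {
  rng <- range(wavelength)
  if (any(at < rng[1] - 1e-9) || any(at > rng[2] + 1e-9)) {
    abort(sprintf(
      "requested wavelengths [%g, %g] outside measured support [%g, %g]; extrapolation is not performed",
      min(at), max(at), rng[1], rng[2]))
  }
  if (length(wavelength) < 3L) {
    return(stats::approx(wavelength, value, xout = at, rule = 1)$y)
  }
  pracma::pchip(wavelength, value, pmin(pmax(at, rng[1]), rng[2]))
}

#' Interpolate a spectrum onto arbitrary wavelengths
#'
#' Monotonicity-preserving piecewise cubic Hermite interpolation (PCHIP)
#' of a spectrum onto the requested wavelengths.  Values at input nodes are
#' reproduced exactly and interpolated values never overshoot the local
#' range of the bracketing nodes.  Extrapolation beyond the measured
#' support is an error.
#'
#' @param s Spectrum tibble.
#' @param at Numeric vector of target wavelengths (nm), within the
#'   measured range.
#' @return A spectrum tibble on `at`.
#' @export
interp_spectrum <- function(s, at) {
  validate_spectrum(s)
  at <- sort(as.numeric(at))
  v <- interp_spectrum_values(s$wavelength, s$value, at)
  out <- tibble::tibble(wavelength = at, value = v)
  for (col in intersect(c("kind", "source"), names(s))) out[[col]] <- s[[col]][1]
  out
}

#' Regrid a spectrum to a uniform wavelength grid
#'
#' Evaluates the shape-preserving PCHIP interpolant of `s` on the uniform
#' grid `seq(grid_start, grid_stop, grid_step)`.  The default grid,
#' 400-730 nm at 2.5 nm, is the common reporting grid for hyperspectral
#' absorption/attenuation products.  The grid must lie inside the measured
#' wavelength range (no extrapolation).
#'
#' @param s Spectrum tibble.
#' @param grid_start,grid_stop,grid_step Grid definition in nm.
#' @return A spectrum tibble on the uniform grid.
#' @examples
#' s <- spectrum(seq(400, 730, 5), exp(-((seq(400, 730, 5) - 440) / 30)^2))
#' regrid_spectrum(s)
#' @export
regrid_spectrum <- function(s, grid_start = 400, grid_stop = 730,
                            grid_step = 2.5) {
  grid <- seq(grid_start, grid_stop, by = grid_step)
  interp_spectrum(s, grid)
}

#' Elementwise spectral arithmetic with axis checking
#'
#' Subtracts one spectrum from another after verifying that the two share a
#' wavelength axis.  Used for baseline subtraction, dissolved-fraction
#' partitions and phytoplankton/detrital differencing.
#'
#' @param a,b Spectrum tibbles on the same wavelength axis.
#' @return Spectrum tibble of `a$value - b$value`, carrying `a`'s labels.
#' @export
spectral_difference <- function(a, b) {
  validate_spectrum(a); validate_spectrum(b)
  check_shared_axis(a, b)
  out <- a
  out$value <- a$value - b$value
  out
}

check_shared_axis <- function(a, b, tol = 1e-6) {
  if (nrow(a) != nrow(b) || max(abs(a$wavelength - b$wavelength)) > tol) {
    abort("wavelength axes differ; interpolate onto a shared axis first")
  }
  invisible(TRUE)
}
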