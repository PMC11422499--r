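#' Temperature/salinity correction coefficient tables
#'
#' The hyperspectral absorption/attenuation meter responds to water
#' temperature and salinity as well as to the dissolved and particulate
#' material of interest; per-wavelength correction coefficients Psi_T
#' (m^-1 per degree C), Psi_Sa and Psi_Sc (m^-1 per practical-salinity
#' unit, for the absorption and attenuation channels respectively) remove
#' those responses.  Tables are supplied by the user as three-coefficient
#' delimited files; the package ships a clearly-labelled synthetic fixture
#' (`phytoptics_extdata("synthetic_ts_coefficients.tsv")`) for examples and
#' tests, which does not reproduce any published coefficient set.
#'
#' @param path Path to a delimited file with columns `wavelength`, `psi_t`,
#'   `psi_sa`, `psi_sc` and an optional `# t_r:` comment header giving the
#'   reference temperature of the table (degrees C).
#' @return A tibble with those columns; the reference temperature is
#'   attached as attribute `t_r`.
#' @export
read_ts_coefficients <- function(path) {
  header <- readLines(path, n = 10L)
  t_r <- NA_real_
  tr_line <- grep("^#\\s*t_r:", header, value = TRUE)
  if (length(tr_line)) t_r <- as.numeric(sub("^#\\s*t_r:\\s*", "", tr_line[1]))
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  need <- c("wavelength", "psi_t", "psi_sa", "psi_sc")
  if (!all(need %in% names(tab))) {
    abort(sprintf("coefficient table %s must have columns %s",
                  path, paste(need, collapse = ", ")))
  }
  if (any(diff(tab$wavelength) <= 0)) {
    abort("coefficient wavelengths must be strictly increasing")
  }
  attr(tab, "t_r") <- t_r
  tab
}

# interpolate one psi column onto target wavelengths
psi_at <- function(coeffs, column, at) {
  interp_spectrum_values(coeffs$wavelength, coeffs[[column]], at)
}

#' Subtract a pure-water baseline
#'
#' Removes the same-day ultrapure-water calibration spectrum from a sample
#' measurement, channel by channel.  Works on a single spectrum or, when
#' `sample` has a `time_s` column, on every time step of a series (joined
#' by wavelength).
#'
#' @param sample Spectrum or long spectral time series.
#' @param water_cal Pure-water calibration spectrum (typically the median
#'   of the daily pure-water record) on the same wavelength axis.
#' @return `sample` with the baseline removed.
#' @examples
#' s <- spectrum(c(440, 550), c(0.10, 0.10))
#' w <- spectrum(c(440, 550), c(0.01, 0.01))
#' subtract_baseline(s, w)
#' @export
subtract_baseline <- function(sample, water_cal) {
  validate_spectrum(water_cal)
  if ("time_s" %in% names(sample)) {
    wl <- sort(unique(sample$wavelength))
    if (length(wl) != nrow(water_cal) ||
        max(abs(wl - water_cal$wavelength)) > 1e-6) {
      abort("wavelength axes differ between sample series and water calibration")
    }
    cal <- tibble::tibble(wavelength = water_cal$wavelength,
                          .cal = water_cal$value)
    out <- sample %>%
      dplyr::left_join(cal, by = "wavelength") %>%
      dplyr::mutate(value = .data$value - .data$.cal) %>%
      dplyr::select(-dplyr::all_of(".cal"))
    return(out)
  }
  spectral_difference(sample, water_cal)
}

#' Temperature and salinity correction
#'
#' Removes the instrument's water temperature and salinity response from a
#' measured absorption or attenuation spectrum:
#'
#' \deqn{a_t(\lambda) = a_m(\lambda) - (T_m - T_r)\,\Psi_T(\lambda) \pm S_m\,\Psi_{Sa}(\lambda)}
#'
#' and analogously for attenuation with \eqn{\Psi_{Sc}}.  The sign of the
#' salinity term is governed by `sign_convention`: `"as_printed"` adds
#' `S_m * Psi_S` (so a negative tabulated coefficient subtracts), while
#' `"subtract_salinity"` subtracts both terms, matching coefficient tables
#' published with the opposite sign convention.  The correction is affine
#' in the measurement, so it commutes with median time reduction; it may be
#' applied to a spectrum or to a full time series.
#'
#' @param measured Spectrum or long time series (absorption or attenuation).
#' @param coeffs Coefficient tibble from [read_ts_coefficients()]; values
#'   are interpolated onto the measurement wavelengths.
#' @param t_m,s_m Measured temperature (deg C) and practical salinity.
#' @param t_r Reference temperature of the coefficient table; defaults to
#'   the table's `t_r` attribute.
#' @param channel `"a"` (uses `psi_sa`) or `"c"` (uses `psi_sc`).
#' @param sign_convention `"as_printed"` or `"subtract_salinity"`.
#' @return The corrected spectrum/series.
#' @export
ts_correct <- function(measured, coeffs, t_m, s_m,
                       t_r = attr(coeffs, "t_r"),
                       channel = c("a", "c"),
                       sign_convention = c("as_printed", "subtract_salinity")) {
  channel <- match.arg(channel)
  sign_convention <- match.arg(sign_convention)
  if (is.null(t_r) || is.na(t_r)) {
    abort("reference temperature t_r is not available; supply it or use a coefficient table with a `# t_r:` header")
  }
  psi_s_col <- if (channel == "a") "psi_sa" else "psi_sc"
  s_sign <- if (sign_convention == "as_printed") +1 else -1
  wl <- sort(unique(measured$wavelength))
  corr <- tibble::tibble(
    wavelength = wl,
    .corr = (t_m - t_r) * psi_at(coeffs, "psi_t", wl) -
      s_sign * s_m * psi_at(coeffs, psi_s_col, wl))
  out <- measured %>%
    dplyr::left_join(corr, by = "wavelength") %>%
    dplyr::mutate(value = .data$value - .data$.corr) %>%
    dplyr::select(-dplyr::all_of(".corr"))
  out
}

#' Residual-scatter correction of the absorption tube
#'
#' A reflecting-tube absorption meter fails to collect a fraction of the
#' light scattered by particles, inflating measured absorption.  The
#' proportional correction assumes true absorption is negligible at a red
#' reference wavelength (default 715 nm) and that the scattering error is
#' proportional to the scattering coefficient \eqn{c_t - a_t}:
#'
#' \deqn{a_{sc}(\lambda) = a_t(\lambda) -
#'   \frac{a_t(\lambda_{ref})}{c_t(\lambda_{ref}) - a_t(\lambda_{ref})}
#'   \left(c_t(\lambda) - a_t(\lambda)\right)}
#'
#' which forces \eqn{a_{sc}(\lambda_{ref}) = 0} exactly.  `method =
#' "as_printed"` reproduces a variant sometimes encountered in print that
#' omits the leading \eqn{a_t(\lambda)} term and so does not null the
#' reference wavelength; it is retained for auditability only.
#'
#' @param a_t,c_t Temperature/salinity-corrected absorption and attenuation
#'   spectra on a shared axis containing (or bracketing) `lambda_ref`.
#' @param lambda_ref Reference wavelength in nm (default 715).
#' @param method `"proportional"` (default) or `"as_printed"`.
#' @return Scatter-corrected absorption spectrum.
#' @export
scatter_correct <- function(a_t, c_t, lambda_ref = 715,
                            method = c("proportional", "as_printed")) {
  method <- match.arg(method)
  validate_spectrum(a_t); validate_spectrum(c_t)
  check_shared_axis(a_t, c_t)
  a_ref <- interp_spectrum_values(a_t$wavelength, a_t$value, lambda_ref)
  c_ref <- interp_spectrum_values(c_t$wavelength, c_t$value, lambda_ref)
  denom <- c_ref - a_ref
  if (denom <= 0) {
    abort(sprintf(
      "degenerate scatter correction: c_t(%g) = %.4g <= a_t(%g) = %.4g",
      lambda_ref, c_ref, lambda_ref, a_ref))
  }
  ratio <- a_ref / denom
  out <- a_t
  b_t <- c_t$value - a_t$value
  out$value <- if (method == "proportional") {
    a_t$value - ratio * b_t
  } else {
    (a_t$value / denom) * b_t
  }
  out$source <- paste0("scatter-corrected (lambda_ref = ", lambda_ref, " nm)")
  out
}

#' Particulate/dissolved partition of absorption and attenuation
#'
#' Splits total (unfiltered) optical properties into particulate and
#' dissolved fractions using the 0.2-micron-filtered stream:
#' `a_p = a_sc - a_g`, `c_p = c_t - c_g`, and particulate total scattering
#' `b_p = c_p - a_p`.  The identities `a_p + a_g = a_sc` and
#' `c_p + c_g = c_t` hold at every wavelength by construction; negative
#' values are retained (clamping would destroy conservation) and should be
#' screened through the QC report of [process_acs_run()].
#'
#' @param a_sc Scatter-corrected total absorption spectrum.
#' @param c_t Temperature/salinity-corrected total attenuation spectrum.
#' @param a_g,c_g Dissolved (filtered) absorption and attenuation spectra.
#' @return A tibble with columns `wavelength`, `a_p`, `c_p`, `b_p` (m^-1).
#' @examples
#' wl <- c(440, 550)
#' partition_particulate(
#'   spectrum(wl, c(0.3, 0.2)), spectrum(wl, c(1.0, 0.9), "attenuation"),
#'   spectrum(wl, c(0.1, 0.05)), spectrum(wl, c(0.2, 0.15), "attenuation"))
#' @export
partition_particulate <- function(a_sc, c_t, a_g, c_g) {
  for (s in list(a_sc, c_t, a_g, c_g)) validate_spectrum(s)
  check_shared_axis(a_sc, c_t); check_shared_axis(a_sc, a_g)
  check_shared_axis(a_sc, c_g)
  a_p <- a_sc$value - a_g$value
  c_p <- c_t$value - c_g$value
  tibble::tibble(wavelength = a_sc$wavelength,
                 a_p = a_p, c_p = c_p, b_p = c_p - a_p)
}

#' Process a complete absorption/attenuation run
#'
#' Full pipeline for one flow-through run of a hyperspectral
#' absorption/attenuation meter: same-day pure-water baseline subtraction,
#' temperature/salinity correction of every time step, median time
#' reduction, proportional residual-scatter correction of the unfiltered
#' absorption channel, particulate/dissolved partition against the
#' 0.2-micron-filtered stream, and regridding of all products to a uniform
#' 2.5 nm wavelength grid.  The filtered absorption stream is used directly
#' as `a_g` (a particle-free stream has near-zero scattering, which makes
#' the proportional correction degenerate there and unnecessary).
#'
#' @param run A run bundle: a list with elements `pure_water`, `unfiltered`
#'   and `filtered`, each a list holding long time-series tibbles `a` and
#'   `c`; `unfiltered` and `filtered` also carry `hydro = list(t_m, s_m)`.
#'   See [read_run_directory()] and [render_runs()].
#' @param coeffs Temperature/salinity coefficient table
#'   ([read_ts_coefficients()]).
#' @param t_r Reference temperature; defaults to the coefficient table's.
#' @param lambda_ref Scatter-correction reference wavelength, nm.
#' @param grid_start,grid_stop,grid_step Output grid (nm); default
#'   400-730 at 2.5.
#' @param sign_convention Salinity-term convention, see [ts_correct()].
#' @param scatter_method See [scatter_correct()].
#' @return An object of class `acs_products`: a list with `products` (wide
#'   tibble `wavelength`, `a_p`, `c_p`, `b_p`, `a_g`, `c_g` on the uniform
#'   grid), `native` (same products on the instrument wavelength axis),
#'   `qc` (per-product negative-value counts) and the configuration used.
#'   `tidy()` returns the products in long form; `glance()` a one-row
#'   summary; `autoplot()` an overview figure.
#' @export
process_acs_run <- function(run, coeffs, t_r = attr(coeffs, "t_r"),
                            lambda_ref = 715,
                            grid_start = 400, grid_stop = 730, grid_step = 2.5,
                            sign_convention = c("as_printed",
                                                "subtract_salinity"),
                            scatter_method = c("proportional", "as_printed")) {
  sign_convention <- match.arg(sign_convention)
  scatter_method <- match.arg(scatter_method)
  for (stream in c("pure_water", "unfiltered", "filtered")) {
    if (is.null(run[[stream]])) abort(sprintf("run is missing the `%s` stream", stream))
    for (ch in c("a", "c")) {
      if (is.null(run[[stream]][[ch]])) {
        abort(sprintf("run is missing the `%s` channel of the `%s` stream", ch, stream))
      }
    }
  }

  water <- list(a = median_reduce(run$pure_water$a),
                c = median_reduce(run$pure_water$c))

  reduce_stream <- function(stream) {
    hy <- run[[stream]]$hydro
    if (is.null(hy)) abort(sprintf("`%s` stream has no hydro (t_m, s_m) record", stream))
    lapply(setNames(c("a", "c"), c("a", "c")), function(ch) {
      run[[stream]][[ch]] %>%
        subtract_baseline(water[[ch]]) %>%
        ts_correct(coeffs, t_m = hy$t_m, s_m = hy$s_m, t_r = t_r,
                   channel = ch, sign_convention = sign_convention) %>%
        median_reduce()
    })
  }

  unf <- reduce_stream("unfiltered")
  fil <- reduce_stream("filtered")

  a_sc <- scatter_correct(unf$a, unf$c, lambda_ref = lambda_ref,
                          method = scatter_method)
  part <- partition_particulate(a_sc, unf$c, fil$a, fil$c)

  native <- part %>%
    dplyr::mutate(a_g = fil$a$value, c_g = fil$c$value)

  regrid_col <- function(col) {
    interp_spectrum_values(native$wavelength, native[[col]],
                           seq(grid_start, grid_stop, by = grid_step))
  }
  grid <- seq(grid_start, grid_stop, by = grid_step)
  products <- tibble::tibble(wavelength = grid)
  for (col in c("a_p", "c_p", "b_p", "a_g", "c_g")) {
    products[[col]] <- regrid_col(col)
  }

  qc <- products %>%
    tidyr::pivot_longer(-dplyr::all_of("wavelength"),
                        names_to = "product", values_to = "value") %>%
    dplyr::group_by(.data$product) %>%
    dplyr::summarise(n_negative = sum(.data$value < 0),
                     min_value = min(.data$value), .groups = "drop")

  structure(list(products = products, native = native, qc = qc,
                 config = list(lambda_ref = lambda_ref,
                               sign_convention = sign_convention,
                               scatter_method = scatter_method,
                               t_r = t_r,
                               grid = c(grid_start, grid_stop, grid_step))),
            class = "acs_products")
}

#' @export
print.acs_products <- function(x, ...) {
  g <- x$config$grid
  cat(sprintf("<acs_products> %d wavelengths (%g-%g nm @ %g nm)\n",
              nrow(x$products), g[1], g[2], g[3]))
  cat(sprintf("  scatter correction: %s at %g nm; salinity convention: %s\n",
              x$config$scatter_method, x$config$lambda_ref,
              x$config$sign_convention))
  neg <- sum(x$qc$n_negative)
  if (neg > 0) cat(sprintf("  QC: %d negative product values flagged\n", neg))
  invisible(x)
}

#' @rdname process_acs_run
#' @param x An `acs_products` object.
#' @param ... Unused.
#' @export
tidy.acs_products <- function(x, ...) {
  x$products %>%
    tidyr::pivot_longer(-dplyr::all_of("wavelength"),
                        names_to = "product", values_to = "value")
}

#' @rdname process_acs_run
#' @export
glance.acs_products <- function(x, ...) {
  tibble::tibble(
    n_wavelengths = nrow(x$products),
    grid_step = x$config$grid[3],
    lambda_ref = x$config$lambda_ref,
    n_negative = sum(x$qc$n_negative),
    a_p_440 = interp_spectrum_values(x$products$wavelength, x$products$a_p, 440),
    b_p_532 = interp_spectrum_values(x$products$wavelength, x$products$b_p, 532))
}
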