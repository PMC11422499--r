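#' Generate a ground-truth record for a synthetic culture run
#'
#' Builds the full set of ground-truth inherent optical properties for one
#' simulated flow-through experiment from a named scenario preset:
#' phytoplankton absorption as a sum of Gaussian pigment bands, detrital
#' and dissolved (CDOM) absorption as spectral exponentials, particulate
#' attenuation as a power law, a two-parameter backward-hemisphere phase
#' function (exponential decay in angle plus an isotropic floor) with the
#' particulate backscattering coefficient tied to it by quadrature, a
#' log-normal particle volume distribution, instrument noise levels,
#' hydrographic state and discrete analyte concentrations.  Scenario
#' presets live as YAML data files under
#' `phytoptics_extdata("scenarios")`; `"mixture"` blends the two
#' single-phase presets linearly by dilution weight, so its additive
#' optical components are exactly the weighted sums of the components'.
#'
#' The record is fully deterministic given `(seed, scenario)`; the seed is
#' stored and consumed only by [render_runs()].
#'
#' @param seed Integer seed for the downstream renderer.
#' @param scenario `"exponential"`, `"stationary"` or `"mixture"` (or the
#'   path of a user-written scenario YAML file).
#' @return An object of class `iop_truth` (a list of generation
#'   parameters plus the phase-function normalisation constant).
#' @examples
#' truth <- generate_truth(1, "exponential")
#' truth_a_ph(truth, c(440, 676))
#' @export
generate_truth <- function(seed, scenario = "exponential") {
  params <- load_scenario(scenario)
  truth <- c(list(seed = as.integer(seed), scenario = scenario), params)
  # normalise the backward phase function so that
  # 2*pi * int_{pi/2}^{pi} p(theta) sin(theta) dtheta = 1
  raw <- function(th) exp(-truth$phase$decay * (th - pi / 2)) + truth$phase$floor
  z <- integrate(function(th) 2 * pi * raw(th) * sin(th), pi / 2, pi,
                 rel.tol = 1e-12)$value
  truth$phase$norm <- z
  structure(truth, class = "iop_truth")
}

load_scenario <- function(scenario) {
  path <- if (file.exists(scenario)) scenario else {
    p <- system.file("extdata", "scenarios", paste0(scenario, ".yaml"),
                     package = "phytoptics")
    if (!nzchar(p)) {
      avail <- sub("\\.yaml$", "",
                   list.files(system.file("extdata", "scenarios",
                                          package = "phytoptics")))
      abort(sprintf("unknown scenario '%s'; available: %s", scenario,
                    paste(avail, collapse = ", ")))
    }
    p
  }
  params <- yaml::read_yaml(path)
  if (!is.null(params$components)) {
    parts <- lapply(params$components, load_scenario)
    w <- as.numeric(params$weights)
    if (length(w) != length(parts)) abort("mixture weights must match components")
    params <- blend_scenarios(parts, w)
  }
  params
}

# dilution-weighted blend: additive optical amplitudes and concentrations
# scale linearly; shape parameters (slopes, phase, noise, hydro) are taken
# as concentration-weighted means
blend_scenarios <- function(parts, w) {
  w <- w / sum(w)
  out <- parts[[1]]
  out$pigment_bands <- purrr::flatten(purrr::map2(parts, w, function(p, wi) {
    purrr::map(p$pigment_bands, function(b) {
      b$amplitude <- b$amplitude * wi; b
    })
  }))
  wmean <- function(field) sum(purrr::map_dbl(parts, field) * w)
  for (f in c("a_d400", "a_g400", "c_p532", "b_g_flat", "tchla",
              "poc_umol_l")) {
    out[[f]] <- wmean(f)
  }
  for (f in c("s_d", "s_g", "gamma", "bb_ratio", "bb_ratio_dissolved",
              "scatter_frac", "tchla_cv", "poc_cv")) {
    out[[f]] <- wmean(f)
  }
  out$psd$total_pvc_ul_l <- sum(purrr::map_dbl(parts, ~ .x$psd$total_pvc_ul_l) * w)
  out$psd$median_um <- sum(purrr::map_dbl(parts, ~ .x$psd$median_um) * w)
  out$psd$gsd <- sum(purrr::map_dbl(parts, ~ .x$psd$gsd) * w)
  out
}

#' @export
print.iop_truth <- function(x, ...) {
  cat(sprintf("<iop_truth> scenario '%s', seed %d\n", x$scenario, x$seed))
  cat(sprintf("  %d pigment bands; a_d(400) = %g (S_d = %g), a_g(400) = %g (S_g = %g)\n",
              length(x$pigment_bands), x$a_d400, x$s_d, x$a_g400, x$s_g))
  cat(sprintf("  c_p(532) = %g (gamma = %g); b_bp/b_p = %g\n",
              x$c_p532, x$gamma, x$bb_ratio))
  invisible(x)
}

#' Evaluate ground-truth spectra
#'
#' Analytic evaluation of the truth record's component spectra at
#' arbitrary wavelengths.  By default the absorption components are
#' returned in the "null-at-715-nm" convention (each component minus its
#' own 715 nm value): the proportional residual-scatter correction can
#' only recover absorption relative to its reference-wavelength value, so
#' truths in this convention are what a perfect pipeline recovers exactly.
#' `null_715 = FALSE` returns the physical spectra, which is what the
#' filter-pad renderer uses (a spectrophotometer with an integrating
#' sphere has no such identifiability limit).
#'
#' @param truth An `iop_truth` record.
#' @param wl Wavelengths, nm.
#' @param null_715 Return absorption relative to its 715 nm value.
#' @return Numeric vector of the quantity at `wl`.
#' @name truth-spectra
NULL

#' @rdname truth-spectra
#' @export
truth_a_ph <- function(truth, wl, null_715 = TRUE) {
  f <- function(l) {
    Reduce(`+`, purrr::map(truth$pigment_bands, function(b) {
      b$amplitude * exp(-(l - b$center)^2 / (2 * b$sigma^2))
    }))
  }
  if (null_715) f(wl) - f(715) else f(wl)
}

#' @rdname truth-spectra
#' @export
truth_a_d <- function(truth, wl, null_715 = TRUE) {
  f <- function(l) truth$a_d400 * exp(-truth$s_d * (l - 400))
  if (null_715) f(wl) - f(715) else f(wl)
}

#' @rdname truth-spectra
#' @export
truth_a_g <- function(truth, wl, null_715 = TRUE) {
  f <- function(l) truth$a_g400 * exp(-truth$s_g * (l - 400))
  if (null_715) f(wl) - f(715) else f(wl)
}

#' @rdname truth-spectra
#' @export
truth_a_p <- function(truth, wl, null_715 = TRUE) {
  truth_a_ph(truth, wl, null_715) + truth_a_d(truth, wl, null_715)
}

#' @rdname truth-spectra
#' @export
truth_c_p <- function(truth, wl) truth$c_p532 * (wl / 532)^(-truth$gamma)

#' @rdname truth-spectra
#' @export
truth_c_g <- function(truth, wl) truth_a_g(truth, wl) + truth$b_g_flat

#' @rdname truth-spectra
#' @export
truth_b_p <- function(truth, wl) truth_c_p(truth, wl) - truth_a_p(truth, wl)

#' @rdname truth-spectra
#' @export
truth_bbp <- function(truth, wl) truth$bb_ratio * truth_b_p(truth, wl)

#' Ground-truth backward phase function and chi factors
#'
#' `truth_phase()` evaluates the normalised backward phase function
#' p(theta) (sr^-1-like weight; `2*pi*integral(p*sin)` over the backward
#' hemisphere is 1 by construction), so the true particulate VSF is
#' `beta_p(theta, lambda) = b_bp(lambda) * p(theta)`.  `chi_from_phase()`
#' derives the exact single-angle conversion factor for this phase
#' function, `chi(theta) = 1 / (2 * pi * p(theta))`, the value that makes
#' `2 * pi * chi * beta_p(theta)` reproduce b_bp.
#'
#' @param truth An `iop_truth` record.
#' @param angle_deg Scattering angle(s), degrees.
#' @return Numeric vector.
#' @export
truth_phase <- function(truth, angle_deg) {
  th <- angle_deg * pi / 180
  (exp(-truth$phase$decay * (th - pi / 2)) + truth$phase$floor) /
    truth$phase$norm
}

#' @rdname truth_phase
#' @export
chi_from_phase <- function(truth, angle_deg) {
  1 / (2 * pi * truth_phase(truth, angle_deg))
}

#' Ground-truth per-bin particle volume concentration
#'
#' Integrates the scenario's log-normal particle volume density over each
#' bin of the 32-bin logarithmic grid and scales to the scenario's total
#' volume concentration.
#'
#' @param truth An `iop_truth` record.
#' @param grid Size grid from [make_bin_grid()].
#' @return Numeric vector of per-bin PVC, uL/L.
#' @export
truth_pvc <- function(truth, grid = make_bin_grid()) {
  mlog <- log(truth$psd$median_um)
  slog <- log(truth$psd$gsd)
  cdf <- function(d) stats::plnorm(d, mlog, slog)
  mass <- cdf(grid$upper_um) - cdf(grid$lower_um)
  truth$psd$total_pvc_ul_l * mass / (cdf(max(grid$upper_um)) - cdf(min(grid$lower_um)))
}

# --- rendering ------------------------------------------------------------

acs_wavelengths <- function() seq(400, 730, by = 5)
pad_wavelengths <- function() seq(290, 850, by = 2)
n_time_steps <- 150L

# additive gaussian noise plus sparse multiplicative bubble bursts; both
# scale linearly with noise_scale so recovery error is proportional to it
perturb <- function(values, sd, spike_prob, spike_mag, noise_scale) {
  n <- length(values)
  z <- rnorm(n)
  spikes <- runif(n) < spike_prob
  out <- values + noise_scale * sd * z
  out[spikes] <- out[spikes] * (1 + noise_scale * spike_mag)
  out
}

render_acs_stream <- function(truth, base_fun, baseline_fun, corr, wl,
                              noise_scale) {
  n_t <- n_time_steps
  grid <- tidyr::expand_grid(time_s = seq_len(n_t) - 1, wavelength = wl)
  base <- base_fun(grid$wavelength) + baseline_fun(grid$wavelength) +
    corr(grid$wavelength)
  grid$value <- perturb(base, truth$noise$acs_sd, truth$noise$spike_prob,
                        truth$noise$spike_mag, noise_scale)
  grid
}

#' Render synthetic instrument streams from a truth record
#'
#' The inverse of every processing stage: takes a ground-truth record and
#' renders the raw streams each pipeline consumes — matched pure-water,
#' unfiltered and 0.2-micron-filtered absorption/attenuation time series
#' (with temperature/salinity terms, an a-tube uncollected-scattering
#' contamination proportional to total scattering, a smooth instrument
#' baseline, Gaussian noise and sparse multiplicative bubble spikes), raw
#' scattering counts per sensor family (dark offsets and scale factors
#' applied in reverse, along-path absorption attenuation included),
#' per-bin particle volume concentration series, filter-pad optical
#' density scans (pathlength amplification inverted, blank added) and a
#' discrete analyte table.  At `noise_scale = 0` the processing pipelines
#' recover the truth record exactly (to numerical round-off) at the
#' instrument wavelengths; noise and spikes scale linearly with
#' `noise_scale`.
#'
#' @param truth An `iop_truth` record from [generate_truth()].
#' @param noise_scale Multiplier on all noise standard deviations and
#'   spike amplitudes (0 = noise-free).
#' @param families Scatter sensor families to render.
#' @return A list with elements `acs` (run bundle for
#'   [process_acs_run()]), `coeffs` (the packaged synthetic T/S
#'   coefficient table used in rendering), `scatter` (per family:
#'   `unfiltered`, `filtered`, `cal`, `route`), `lisst`, `filterpad`,
#'   `discrete` and `truth`.
#' @export
render_runs <- function(truth, noise_scale = 1,
                        families = c("bb9", "vsf3")) {
  stopifnot(inherits(truth, "iop_truth"))
  coeffs <- read_ts_coefficients(
    phytoptics_extdata("synthetic_ts_coefficients.tsv"))
  t_r <- attr(coeffs, "t_r")
  hy <- truth$hydro
  wl <- acs_wavelengths()
  eps <- truth$scatter_frac

  a_tot <- function(l) truth_a_p(truth, l) + truth_a_g(truth, l)
  c_tot <- function(l) truth_c_p(truth, l) + truth_c_g(truth, l)
  # a-tube reading contaminated by a fraction eps of the scattering it
  # fails to collect: a_t = (a_true + eps * c_true) / (1 + eps), so that
  # the proportional correction with a_true(715) = 0 inverts it exactly
  a_tube_unf <- function(l) (a_tot(l) + eps * c_tot(l)) / (1 + eps)
  base_a <- function(l) 0.020 * exp(-(l - 400) / 300)
  base_c <- function(l) 0.040 * exp(-(l - 400) / 250)
  corr_a <- function(l) {
    (hy$t_m - t_r) * psi_at(coeffs, "psi_t", l) - hy$s_m * psi_at(coeffs, "psi_sa", l)
  }
  corr_c <- function(l) {
    (hy$t_m - t_r) * psi_at(coeffs, "psi_t", l) - hy$s_m * psi_at(coeffs, "psi_sc", l)
  }
  zero <- function(l) rep(0, length(l))

  withr::with_seed(truth$seed, {
    acs <- list(
      pure_water = list(
        a = render_acs_stream(truth, zero, base_a, zero, wl, noise_scale),
        c = render_acs_stream(truth, zero, base_c, zero, wl, noise_scale)),
      unfiltered = list(
        a = render_acs_stream(truth, a_tube_unf, base_a, corr_a, wl, noise_scale),
        c = render_acs_stream(truth, c_tot, base_c, corr_c, wl, noise_scale),
        hydro = hy),
      filtered = list(
        a = render_acs_stream(truth, function(l) truth_a_g(truth, l),
                              base_a, corr_a, wl, noise_scale),
        c = render_acs_stream(truth, function(l) truth_c_g(truth, l),
                              base_c, corr_c, wl, noise_scale),
        hydro = hy))

    scatter <- lapply(setNames(families, families), function(fam) {
      cfg <- sensor_config(fam)
      cal <- cfg %>%
        dplyr::mutate(
          scale_factor = 1e-6,
          dark_offset = 50,
          path_length_m = 0.05,
          chi = ifelse(.data$route == "chi",
                       chi_from_phase(truth, .data$angle_deg), NA_real_))
      render_counts <- function(beta_fun, absorb_fun) {
        grid <- tidyr::expand_grid(time_s = seq_len(n_time_steps) - 1,
                                   channel = seq_len(nrow(cfg)))
        ang <- cfg$angle_deg[grid$channel]
        lam <- cfg$wavelength[grid$channel]
        beta_meas <- beta_fun(ang, lam) * exp(-0.05 * absorb_fun(lam))
        counts <- 50 + beta_meas / 1e-6
        grid %>%
          dplyr::transmute(.data$time_s, angle_deg = ang, wavelength = lam,
                           counts = perturb(counts, truth$noise$counts_sd,
                                            truth$noise$spike_prob,
                                            truth$noise$spike_mag,
                                            noise_scale))
      }
      b_bg <- truth$bb_ratio_dissolved * truth$b_g_flat
      beta_dis <- function(ang, lam) b_bg * truth_phase(truth, ang)
      beta_unf <- function(ang, lam) {
        truth_bbp(truth, lam) * truth_phase(truth, ang) + beta_dis(ang, lam)
      }
      list(
        unfiltered = render_counts(beta_unf, function(l) a_tot(l)),
        filtered = render_counts(beta_dis, function(l) truth_a_g(truth, l)),
        cal = cal, route = cfg$route[1])
    })

    grid <- make_bin_grid()
    pvc0 <- truth_pvc(truth, grid)
    lisst <- tidyr::expand_grid(time_s = seq_len(n_time_steps) - 1,
                                bin = grid$bin) %>%
      dplyr::mutate(pvc_ul_per_l = pmax(0, perturb(
        pvc0[.data$bin], truth$noise$lisst_rel_sd * pvc0[.data$bin],
        truth$noise$spike_prob, truth$noise$spike_mag, noise_scale)))

    wl_pad <- pad_wavelengths()
    pad_geom <- truth$pad
    va <- pad_geom$volume_m3 / spot_area(pad_geom$spot_diameter_mm)
    blank_fun <- function(l) 0.04 + 0.02 * exp(-(l - 290) / 200)
    render_pads <- function(a_fun) {
      purrr::map_dfr(seq_len(pad_geom$n_replicates), function(rep_i) {
        od_s <- a_fun(wl_pad) * va / log(10)
        od_fp <- (pmax(od_s, 0) / 0.323)^(1 / 2.0867)
        tibble::tibble(
          replicate = rep_i, wavelength = wl_pad,
          value = od_fp + blank_fun(wl_pad) +
            noise_scale * truth$noise$pad_od_sd * rnorm(length(wl_pad)))
      })
    }
    filterpad <- list(
      sample_scans = render_pads(function(l) truth_a_p(truth, l, null_715 = FALSE)),
      depigmented_scans = render_pads(function(l) truth_a_d(truth, l, null_715 = FALSE)),
      blank = tibble::tibble(wavelength = wl_pad, value = blank_fun(wl_pad),
                             kind = "optical_density", source = "blank filter"),
      volume_m3 = pad_geom$volume_m3,
      spot_diameter_mm = pad_geom$spot_diameter_mm)

    n_rep <- 3L
    discrete <- purrr::map_dfr(
      list(c("tchla", truth$tchla, truth$tchla_cv),
           c("poc", truth$poc_umol_l, truth$poc_cv)),
      function(row) {
        mu <- as.numeric(row[2]); cv <- as.numeric(row[3])
        tibble::tibble(sample_id = "run", analyte = row[1],
                       replicate = seq_len(n_rep),
                       value = mu * (1 + noise_scale * cv * rnorm(n_rep)))
      })

    list(acs = acs, coeffs = coeffs, scatter = scatter, lisst = lisst,
         filterpad = filterpad, discrete = discrete, truth = truth)
  })
}
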