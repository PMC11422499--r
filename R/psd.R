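#' The 32-bin logarithmic particle size grid
#'
#' Builds the laser-diffraction sizer's standard size-class grid: 33
#' strictly increasing bin edges spanning 2.5-500 micrometers with a
#' constant geometric edge ratio of (500/2.5)^(1/32), giving 32 bins.
#' Bin centers are the geometric means of adjacent edges, the natural
#' representative diameter on a logarithmic grid.
#'
#' @param d_min,d_max Grid limits in micrometers.
#' @param n_bins Number of bins.
#' @return A tibble with columns `bin`, `lower_um`, `upper_um`, `d_um`
#'   (geometric-mean center).
#' @examples
#' make_bin_grid()
#' @export
make_bin_grid <- function(d_min = 2.5, d_max = 500, n_bins = 32L) {
  edges <- d_min * (d_max / d_min)^(seq(0, n_bins) / n_bins)
  tibble::tibble(bin = seq_len(n_bins),
                 lower_um = edges[-(n_bins + 1)],
                 upper_um = edges[-1],
                 d_um = sqrt(edges[-(n_bins + 1)] * edges[-1]))
}

#' Convert per-bin particle volume to number concentration
#'
#' Inverts the spherical volume relation per size bin:
#' `N(D) = PVC / ((4/3) * pi * (d/2)^3)`, with the instrument's particle
#' volume concentration (microliters per liter) converted internally to
#' cubic micrometers per milliliter (1 uL/L = 1e6 um^3/mL) so that `N(D)`
#' comes out in particles per milliliter.  The representative diameter `d`
#' is the geometric-mean bin center by default; the lower edge and the
#' arithmetic edge midpoint are available for sensitivity checks.
#'
#' @param pvc Numeric vector of per-bin particle volume concentration,
#'   uL/L, length matching `grid`, or a data frame with columns `bin` and
#'   `pvc_ul_per_l`.
#' @param grid Size grid from [make_bin_grid()].
#' @param d_choice Which representative diameter to use: `"center"`
#'   (geometric mean, default), `"lower"`, or `"midpoint"`.
#' @return The grid tibble with columns `pvc_ul_per_l` and `n_per_ml`
#'   appended.
#' @examples
#' grid <- make_bin_grid()
#' pvc_to_number(rep(1, 32), grid)
#' @export
pvc_to_number <- function(pvc, grid = make_bin_grid(),
                          d_choice = c("center", "lower", "midpoint")) {
  d_choice <- match.arg(d_choice)
  if (is.data.frame(pvc)) {
    if (!all(c("bin", "pvc_ul_per_l") %in% names(pvc))) {
      abort("data-frame `pvc` needs columns bin, pvc_ul_per_l")
    }
    pvc <- pvc$pvc_ul_per_l[order(pvc$bin)]
  }
  if (length(pvc) != nrow(grid)) {
    abort(sprintf("expected %d per-bin PVC values, got %d", nrow(grid),
                  length(pvc)))
  }
  if (any(pvc < 0)) abort("PVC must be nonnegative")
  d <- switch(d_choice,
              center = grid$d_um,
              lower = grid$lower_um,
              midpoint = (grid$lower_um + grid$upper_um) / 2)
  pvc_um3_ml <- pvc * 1e6                       # uL/L -> um^3/mL
  sphere_vol <- (4 / 3) * pi * (d / 2)^3        # um^3
  out <- grid
  out$pvc_ul_per_l <- pvc
  out$n_per_ml <- pvc_um3_ml / sphere_vol
  out
}

#' Append the cross-sectional area size distribution
#'
#' Multiplies the per-bin number concentration by the cross-sectional area
#' of the representative particle, `A(D) = N(D) * (pi/4) * (d * 1e-6)^2`,
#' with `d` in micrometers converted to meters, so the area distribution
#' is in m^2 per mL.
#'
#' @param psd Tibble from [pvc_to_number()] (must carry `n_per_ml` and
#'   `d_um`).
#' @return `psd` with column `a_m2_per_ml` appended.
#' @export
number_to_area <- function(psd) {
  if (!all(c("n_per_ml", "d_um") %in% names(psd))) {
    abort("`psd` needs columns n_per_ml and d_um (see pvc_to_number())")
  }
  psd$a_m2_per_ml <- psd$n_per_ml * (pi / 4) * (psd$d_um * 1e-6)^2
  psd
}

#' Process a laser-diffraction PSD time series
#'
#' Median-reduces a per-bin particle volume concentration time series over
#' time, then derives the number and area size distributions.  Reduction
#' happens before conversion: the volume-to-number conversion is linear in
#' PVC within a bin, so the ordering only matters across bins and the
#' median of the raw instrument quantity is the better-defined statistic.
#'
#' @param series Long tibble with columns `time_s`, `bin`, `pvc_ul_per_l`.
#' @param grid Size grid from [make_bin_grid()].
#' @param d_choice See [pvc_to_number()].
#' @return Per-bin tibble with `d_um`, `pvc_ul_per_l`, `n_per_ml`,
#'   `a_m2_per_ml`.
#' @export
process_lisst_run <- function(series, grid = make_bin_grid(),
                              d_choice = "center") {
  if (!all(c("time_s", "bin", "pvc_ul_per_l") %in% names(series))) {
    abort("`series` needs columns time_s, bin, pvc_ul_per_l")
  }
  med <- series %>%
    dplyr::group_by(.data$bin) %>%
    dplyr::summarise(pvc_ul_per_l = median(.data$pvc_ul_per_l),
                     .groups = "drop") %>%
    dplyr::arrange(.data$bin)
  if (nrow(med) != nrow(grid)) {
    abort(sprintf("series has %d bins; grid has %d", nrow(med), nrow(grid)))
  }
  pvc_to_number(med$pvc_ul_per_l, grid, d_choice = d_choice) %>%
    number_to_area()
}

#' Total particle volume implied by a number distribution
#'
#' The algebraic inverse of [pvc_to_number()]: summing
#' `N(D) * (4/3) * pi * (d/2)^3` over bins and converting back to uL/L
#' recovers total PVC exactly, a conservation identity used in QC.
#'
#' @param psd Tibble with `n_per_ml` and `d_um`.
#' @return Total particle volume concentration, uL/L.
#' @export
total_pvc <- function(psd) {
  sum(psd$n_per_ml * (4 / 3) * pi * (psd$d_um / 2)^3) / 1e6
}
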