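#' Path to a packaged data file
#' @param ... Path components under the package's `extdata` directory;
#'   empty to list the directory.
#' @return File path.
#' @export
phytoptics_extdata <- function(...) {
  system.file("extdata", ..., package = "phytoptics", mustWork = TRUE)
}

#' The phytoplankton pigment reference table
#'
#' Chromatographic and optical reference properties of the HPLC-resolved
#' phytoplankton pigments, in order of retention time: pigment name,
#' abbreviation, retention time (minutes) and absorption maxima (nm, with
#' shoulders marked by parentheses in the packaged file).  One pigment
#' (chlorophyll c1) carries no abbreviation of its own; the two carotenes
#' share the abbreviation "Caro".
#'
#' @return A tibble with columns `name`, `abbreviation`,
#'   `retention_time_min`, `absorption_maxima_nm` (the raw maxima string),
#'   `maxima` (list column of numeric maxima) and `shoulder` (list column
#'   of logical shoulder flags, parallel to `maxima`).
#' @examples
#' pigment_table()
#' @export
pigment_table <- function() {
  tab <- readr::read_tsv(phytoptics_extdata("pigment_table.tsv"),
                         show_col_types = FALSE, progress = FALSE)
  parsed <- purrr::map(tab$absorption_maxima_nm, function(s) {
    toks <- trimws(strsplit(s, ",")[[1]])
    list(maxima = as.numeric(gsub("[()]", "", toks)),
         shoulder = grepl("^\\(", toks))
  })
  tab$maxima <- purrr::map(parsed, "maxima")
  tab$shoulder <- purrr::map(parsed, "shoulder")
  tab
}

#' Look up a pigment by abbreviation or name
#'
#' Case-insensitive match on the abbreviation first, then on the full
#' name.  An unknown key is an error that lists the valid abbreviations.
#' Ambiguous abbreviations (the carotenes both abbreviate to "Caro")
#' return every matching row.
#'
#' @param key Pigment abbreviation (e.g. `"Fuco"`) or full name.
#' @return One or more rows of [pigment_table()].
#' @examples
#' pigment_lookup("Fuco")$maxima
#' @export
pigment_lookup <- function(key) {
  tab <- pigment_table()
  k <- tolower(trimws(key))
  hit <- tab[!is.na(tab$abbreviation) & tolower(tab$abbreviation) == k, ]
  if (nrow(hit) == 0L) hit <- tab[tolower(tab$name) == k, ]
  if (nrow(hit) == 0L) {
    abort(sprintf("unknown pigment '%s'; valid abbreviations: %s", key,
                  paste(unique(stats::na.omit(tab$abbreviation)),
                        collapse = ", ")))
  }
  hit
}

#' Ratio of two measured means with propagated uncertainty
#'
#' Computes the ratio R = mu_x / mu_y of two batch means (e.g. a pigment
#' concentration over the carbon concentration) and approximates the
#' standard deviation of the ratio from the coefficients of variation of
#' the two measurements:
#' \deqn{\sigma_R \cong \frac{\mu_X}{\mu_Y}\sqrt{CV_X^2 + CV_Y^2 +
#'   3\,CV_Y^2 CV_X^2 + 8\,CV_Y^4}}
#' The higher-order terms account for the bias and variance inflation of
#' a ratio of noisy quantities beyond the familiar first-order
#' \eqn{\sqrt{CV_X^2 + CV_Y^2}} propagation; the approximation is accurate
#' to a few percent for CVs up to about 0.15.
#'
#' @param mu_x,mu_y Means of numerator and denominator (`mu_y` nonzero).
#' @param cv_x,cv_y Coefficients of variation (sd/mean, >= 0).
#' @return A one-row tibble `value`, `sigma_r`, `mu_x`, `mu_y`, `cv_x`,
#'   `cv_y`.
#' @examples
#' ratio_with_error(10, 0.1, 2, 0.05)
#' @export
ratio_with_error <- function(mu_x, cv_x, mu_y, cv_y) {
  if (mu_y == 0) abort("denominator mean must be nonzero")
  if (cv_x < 0 || cv_y < 0) abort("coefficients of variation must be >= 0")
  sigma_r <- abs(mu_x / mu_y) *
    sqrt(cv_x^2 + cv_y^2 + 3 * cv_y^2 * cv_x^2 + 8 * cv_y^4)
  tibble::tibble(value = mu_x / mu_y, sigma_r = sigma_r,
                 mu_x = mu_x, mu_y = mu_y, cv_x = cv_x, cv_y = cv_y)
}

#' Pigment and carbon ratios for a tidy analyte table
#'
#' Applies [ratio_with_error()] over a tidy table of batch analyte means,
#' dividing every requested analyte by a denominator analyte (total
#' chlorophyll a by default), per sample.
#'
#' @param analytes Tidy tibble with columns `sample_id`, `analyte`,
#'   `mean`, `sd`, `n`.
#' @param denominator Analyte name used as the denominator.
#' @return Tibble `sample_id`, `analyte`, `value`, `sigma_r`.
#' @export
analyte_ratios <- function(analytes, denominator = "tchla") {
  need <- c("sample_id", "analyte", "mean", "sd")
  if (!all(need %in% names(analytes))) {
    abort(sprintf("`analytes` needs columns %s", paste(need, collapse = ", ")))
  }
  den <- analytes %>% dplyr::filter(.data$analyte == denominator)
  if (nrow(den) == 0L) {
    abort(sprintf("denominator analyte '%s' not present", denominator))
  }
  num <- analytes %>% dplyr::filter(.data$analyte != denominator)
  num %>%
    dplyr::inner_join(den, by = "sample_id", suffix = c("", "_den")) %>%
    dplyr::rowwise() %>%
    dplyr::mutate(ratio_tbl = list(ratio_with_error(
      .data$mean, .data$sd / .data$mean,
      .data$mean_den, .data$sd_den / .data$mean_den))) %>%
    dplyr::ungroup() %>%
    tidyr::unnest_wider("ratio_tbl", names_sep = ".") %>%
    dplyr::transmute(.data$sample_id, .data$analyte,
                     denominator = denominator,
                     value = .data$ratio_tbl.value,
                     sigma_r = .data$ratio_tbl.sigma_r)
}

#' Chlorophyll-specific normalization
#'
#' Divides an absorption or backscattering quantity by the total
#' chlorophyll-a concentration, yielding chlorophyll-specific
#' coefficients (m^2 per mg chl-a).  Total chlorophyll a is defined as
#' monovinyl plus divinyl chlorophyll a; chlorophyllide a is excluded by
#' default but can be folded in via [total_chla()].
#'
#' @param x Spectrum tibble (a `value` column) or bare numeric vector.
#' @param tchla Total chlorophyll-a concentration, mg m^-3 (> 0).
#' @return `x` divided elementwise by `tchla`.
#' @examples
#' normalize_to_chla(0.06, tchla = 2)   # 0.03 m^2 / mg
#' @export
normalize_to_chla <- function(x, tchla) {
  if (!is.finite(tchla) || tchla <= 0) abort("tchla must be > 0")
  if (is.data.frame(x)) {
    out <- x
    out$value <- x$value / tchla
    return(out)
  }
  x / tchla
}

#' Total chlorophyll a from component concentrations
#'
#' @param chla Monovinyl chlorophyll a, mg m^-3.
#' @param dvchla Divinyl chlorophyll a, mg m^-3.
#' @param chlide Chlorophyllide a, mg m^-3; excluded unless
#'   `include_chlide = TRUE`.
#' @param include_chlide Include chlorophyllide a in the total.
#' @return Total chlorophyll a, mg m^-3.
#' @export
total_chla <- function(chla, dvchla = 0, chlide = 0, include_chlide = FALSE) {
  chla + dvchla + if (include_chlide) chlide else 0
}

#' Cell biovolume from microscopy dimensions
#'
#' Geometric biovolume rules for microscopy-measured cells: diatoms are
#' treated as cylinders, with the unmeasured dimension filled in by the
#' viewing convention (in girdle view the height is taken equal to the
#' measured diameter; in valve view the diameter is taken equal to the
#' measured height); other cells are ovoids (prolate spheroid,
#' `(pi/6) * major * minor^2`) when the axes differ, or spheres
#' (`(pi/6) * d^3`) when they are equal.
#'
#' @param shape One of `"cylinder_girdle"`, `"cylinder_valve"`, `"ovoid"`,
#'   `"sphere"`.
#' @param axes Named or positional numeric axes in micrometers:
#'   `cylinder_girdle` takes `diameter` (height assumed equal),
#'   `cylinder_valve` takes `height` (diameter assumed equal), `ovoid`
#'   takes `c(major, minor)`, `sphere` takes `diameter`.
#' @return Biovolume in cubic micrometers.
#' @examples
#' biovolume("sphere", 10)
#' biovolume("cylinder_girdle", 10)
#' @export
biovolume <- function(shape = c("cylinder_girdle", "cylinder_valve", "ovoid",
                                "sphere"),
                      axes) {
  shape <- match.arg(shape)
  axes <- as.numeric(axes)
  if (any(!is.finite(axes)) || any(axes <= 0)) abort("axes must be positive")
  n_need <- switch(shape, ovoid = 2L, 1L)
  if (length(axes) != n_need) {
    abort(sprintf("shape '%s' needs %d axis value(s), got %d", shape, n_need,
                  length(axes)))
  }
  switch(shape,
    cylinder_girdle = pi * (axes[1] / 2)^2 * axes[1],
    cylinder_valve = pi * (axes[1] / 2)^2 * axes[1],
    ovoid = {
      major <- max(axes); minor <- min(axes)
      if (axes[1] == axes[2]) (pi / 6) * axes[1]^3
      else (pi / 6) * major * minor^2
    },
    sphere = (pi / 6) * axes[1]^3)
}

#' Per-taxon, per-wavelength summary statistics
#'
#' Mean and sample standard deviation (n-1 denominator) of a
#' chlorophyll-specific (or any) spectral quantity across all records in
#' each taxonomic group, wavelength by wavelength, with the group size
#' reported.  Each input record counts as one observation; a group with a
#' single record reports an undefined (NA) standard deviation.
#'
#' @param records Tidy tibble with columns `taxon`, `wavelength`, `value`
#'   (one row per record and wavelength).
#' @return Tibble `taxon`, `wavelength`, `mean`, `sd`, `n`.
#' @export
taxon_summary <- function(records) {
  need <- c("taxon", "wavelength", "value")
  if (!all(need %in% names(records))) {
    abort(sprintf("`records` needs columns %s", paste(need, collapse = ", ")))
  }
  empty <- records %>%
    dplyr::group_by(.data$taxon) %>%
    dplyr::summarise(n = sum(!is.na(.data$value)), .groups = "drop") %>%
    dplyr::filter(.data$n == 0)
  if (nrow(empty) > 0) {
    warn(sprintf("omitting empty group(s): %s",
                 paste(empty$taxon, collapse = ", ")))
    records <- records %>% dplyr::filter(!.data$taxon %in% empty$taxon)
  }
  records %>%
    dplyr::group_by(.data$taxon, .data$wavelength) %>%
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
}
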