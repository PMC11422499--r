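#' Read and write spectra as two-column delimited text
#'
#' The on-disk dialect for a single spectrum is tab-separated
#' `wavelength_nm` / `value` with `# kind:` and `# source:` comment
#' headers.
#'
#' @param s Spectrum tibble.
#' @param path File path.
#' @return `read_spectrum_tsv()` returns a spectrum tibble;
#'   `write_spectrum_tsv()` returns `path` invisibly.
#' @export
write_spectrum_tsv <- function(s, path) {
  validate_spectrum(s)
  kind <- if ("kind" %in% names(s)) s$kind[1] else "absorption"
  source <- if ("source" %in% names(s)) s$source[1] else NA_character_
  lines <- c(sprintf("# kind: %s", kind),
             if (!is.na(source)) sprintf("# source: %s", source),
             "wavelength_nm\tvalue",
             sprintf("%.10g\t%.10g", s$wavelength, s$value))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_spectrum_tsv
#' @export
read_spectrum_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such spectrum file: %s", path))
  header <- readLines(path, n = 5L)
  get_tag <- function(tag) {
    ln <- grep(sprintf("^#\\s*%s:", tag), header, value = TRUE)
    if (length(ln)) trimws(sub(sprintf("^#\\s*%s:", tag), "", ln[1])) else NA_character_
  }
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  out <- tibble::tibble(wavelength = tab$wavelength_nm, value = tab$value,
                        kind = get_tag("kind") %||% "absorption",
                        source = get_tag("source"))
  validate_spectrum(out)
  out
}

#' Read and write spectral time series as wide delimited text
#'
#' One row per time step: first column `time_s`, remaining columns one
#' per wavelength (named `wl_<nm>`).
#'
#' @param series Long time-series tibble (`time_s`, `wavelength`, `value`).
#' @param path File path.
#' @return `read_timeseries_tsv()` returns the long tibble;
#'   `write_timeseries_tsv()` returns `path` invisibly.
#' @export
write_timeseries_tsv <- function(series, path) {
  wide <- series %>%
    dplyr::mutate(wavelength = sprintf("wl_%g", .data$wavelength)) %>%
    tidyr::pivot_wider(id_cols = "time_s", names_from = "wavelength",
                       values_from = "value")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_timeseries_tsv
#' @export
read_timeseries_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such time-series file: %s", path))
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  known <- c("time_s", grep("^wl_", names(wide), value = TRUE))
  extra <- setdiff(names(wide), known)
  if (length(extra)) {
    warn(sprintf("%s: ignoring unknown column(s) %s", basename(path),
                 paste(extra, collapse = ", ")))
    wide <- wide[known]
  }
  wide %>%
    tidyr::pivot_longer(-dplyr::all_of("time_s"), names_to = "wavelength",
                        values_to = "value") %>%
    dplyr::mutate(wavelength = as.numeric(sub("^wl_", "", .data$wavelength))) %>%
    dplyr::arrange(.data$time_s, .data$wavelength)
}

#' Write a rendered run bundle to a directory
#'
#' Serialises the output of [render_runs()] into the directory layout the
#' processing side of the package (and its command line) consumes:
#' wide time-series files and a hydro sidecar for the
#' absorption/attenuation meter, long count files plus a calibration
#' table per scattering sensor, a per-bin volume concentration table for
#' the particle sizer, filter-pad scans with a manifest, a discrete
#' analyte table, and the ground truth as JSON for test harnesses.
#'
#' @param runs Bundle from [render_runs()].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_run_directory <- function(runs, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  acs_dir <- file.path(path, "acs")
  dir.create(acs_dir, showWarnings = FALSE)
  for (stream in c("pure_water", "unfiltered", "filtered")) {
    for (ch in c("a", "c")) {
      write_timeseries_tsv(runs$acs[[stream]][[ch]],
                           file.path(acs_dir, sprintf("%s_%s.tsv", stream, ch)))
    }
  }
  hy <- runs$acs$unfiltered$hydro
  yaml::write_yaml(list(t_r = attr(runs$coeffs, "t_r"),
                        unfiltered = runs$acs$unfiltered$hydro,
                        filtered = runs$acs$filtered$hydro),
                   file.path(acs_dir, "hydro.yml"))
  coef_path <- file.path(acs_dir, "ts_coefficients.tsv")
  writeLines(c(sprintf("# t_r: %g", attr(runs$coeffs, "t_r")),
               paste(names(runs$coeffs), collapse = "\t"),
               do.call(sprintf, c(list(paste(rep("%.10g", ncol(runs$coeffs)),
                                             collapse = "\t")),
                                  unname(as.list(runs$coeffs))))),
             coef_path)

  sc_dir <- file.path(path, "scatter")
  dir.create(sc_dir, showWarnings = FALSE)
  for (fam in names(runs$scatter)) {
    s <- runs$scatter[[fam]]
    readr::write_tsv(s$unfiltered,
                     file.path(sc_dir, sprintf("%s_unfiltered.tsv", fam)),
                     progress = FALSE)
    readr::write_tsv(s$filtered,
                     file.path(sc_dir, sprintf("%s_filtered.tsv", fam)),
                     progress = FALSE)
    readr::write_tsv(s$cal,
                     file.path(sc_dir, sprintf("%s_calibration.tsv", fam)),
                     progress = FALSE)
  }

  lisst_dir <- file.path(path, "lisst")
  dir.create(lisst_dir, showWarnings = FALSE)
  readr::write_tsv(runs$lisst, file.path(lisst_dir, "pvc.tsv"),
                   progress = FALSE)

  fp_dir <- file.path(path, "filterpad")
  dir.create(file.path(fp_dir, "scans"), recursive = TRUE,
             showWarnings = FALSE)
  fp <- runs$filterpad
  manifest <- list()
  write_scan <- function(df, role, rep_i) {
    fname <- sprintf("scans/%s_rep%d.tsv", role, rep_i)
    s <- tibble::tibble(wavelength = df$wavelength, value = df$value,
                        kind = "optical_density", source = role)
    write_spectrum_tsv(s, file.path(fp_dir, fname))
    tibble::tibble(sample_id = "run", role = role, replicate = rep_i,
                   file = fname, volume_liters = fp$volume_m3 * 1000,
                   spot_diameter_mm = fp$spot_diameter_mm)
  }
  for (rep_i in unique(fp$sample_scans$replicate)) {
    manifest <- c(manifest, list(write_scan(
      dplyr::filter(fp$sample_scans, .data$replicate == rep_i), "sample", rep_i)))
  }
  for (rep_i in unique(fp$depigmented_scans$replicate)) {
    manifest <- c(manifest, list(write_scan(
      dplyr::filter(fp$depigmented_scans, .data$replicate == rep_i),
      "depigmented", rep_i)))
  }
  manifest <- c(manifest, list(write_scan(
    dplyr::mutate(fp$blank, replicate = 1L), "blank", 1L)))
  readr::write_tsv(dplyr::bind_rows(manifest),
                   file.path(fp_dir, "manifest.tsv"), progress = FALSE)

  readr::write_tsv(runs$discrete, file.path(path, "discrete_analytes.tsv"),
                   progress = FALSE)

  truth <- runs$truth
  truth_ser <- unclass(truth)
  jsonlite::write_json(truth_ser, file.path(path, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a run directory into typed bundles
#'
#' Inverse of [write_run_directory()]: validates the directory layout and
#' returns the same structure [render_runs()] produces (minus the truth
#' record, returned separately under `truth` when `truth.json` is
#' present).  A missing stream is an error naming the missing file.
#'
#' @param path Run directory.
#' @return A run bundle list.
#' @export
read_run_directory <- function(path) {
  if (!dir.exists(path)) abort(sprintf("no such run directory: %s", path))
  need_ts <- function(f) {
    p <- file.path(path, "acs", f)
    if (!file.exists(p)) abort(sprintf("run directory is missing %s", p))
    read_timeseries_tsv(p)
  }
  hydro_path <- file.path(path, "acs", "hydro.yml")
  if (!file.exists(hydro_path)) {
    abort(sprintf("run directory is missing %s", hydro_path))
  }
  hy <- yaml::read_yaml(hydro_path)
  acs <- list(
    pure_water = list(a = need_ts("pure_water_a.tsv"),
                      c = need_ts("pure_water_c.tsv")),
    unfiltered = list(a = need_ts("unfiltered_a.tsv"),
                      c = need_ts("unfiltered_c.tsv"), hydro = hy$unfiltered),
    filtered = list(a = need_ts("filtered_a.tsv"),
                    c = need_ts("filtered_c.tsv"), hydro = hy$filtered))
  coeffs <- read_ts_coefficients(file.path(path, "acs", "ts_coefficients.tsv"))

  sc_dir <- file.path(path, "scatter")
  scatter <- list()
  if (dir.exists(sc_dir)) {
    fams <- unique(sub("_(unfiltered|filtered|calibration)\\.tsv$", "",
                       list.files(sc_dir, pattern = "\\.tsv$")))
    for (fam in fams) {
      rd <- function(stub) {
        p <- file.path(sc_dir, sprintf("%s_%s.tsv", fam, stub))
        if (!file.exists(p)) abort(sprintf("run directory is missing %s", p))
        readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
      }
      cal <- rd("calibration")
      scatter[[fam]] <- list(unfiltered = rd("unfiltered"),
                             filtered = rd("filtered"), cal = cal,
                             route = cal$route[1])
    }
  }

  lisst <- NULL
  lisst_path <- file.path(path, "lisst", "pvc.tsv")
  if (file.exists(lisst_path)) {
    lisst <- readr::read_tsv(lisst_path, show_col_types = FALSE,
                             progress = FALSE)
  }

  filterpad <- NULL
  man_path <- file.path(path, "filterpad", "manifest.tsv")
  if (file.exists(man_path)) {
    man <- readr::read_tsv(man_path, show_col_types = FALSE, progress = FALSE)
    need_meta <- c("role", "replicate", "file", "volume_liters",
                   "spot_diameter_mm")
    if (!all(need_meta %in% names(man))) {
      abort(sprintf("filter-pad manifest must have columns %s",
                    paste(need_meta, collapse = ", ")))
    }
    read_role <- function(role) {
      rows <- dplyr::filter(man, .data$role == !!role)
      if (nrow(rows) == 0L) return(NULL)
      purrr::map_dfr(seq_len(nrow(rows)), function(i) {
        s <- read_spectrum_tsv(file.path(path, "filterpad", rows$file[i]))
        tibble::tibble(replicate = rows$replicate[i],
                       wavelength = s$wavelength, value = s$value)
      })
    }
    blank_rows <- read_role("blank")
    if (is.null(blank_rows)) abort("filter-pad manifest has no blank scan")
    filterpad <- list(
      sample_scans = read_role("sample"),
      depigmented_scans = read_role("depigmented"),
      blank = tibble::tibble(wavelength = blank_rows$wavelength,
                             value = blank_rows$value,
                             kind = "optical_density", source = "blank filter"),
      volume_m3 = man$volume_liters[1] / 1000,
      spot_diameter_mm = man$spot_diameter_mm[1])
    if (is.null(filterpad$sample_scans)) {
      abort("filter-pad manifest has no sample scans")
    }
  }

  discrete <- NULL
  disc_path <- file.path(path, "discrete_analytes.tsv")
  if (file.exists(disc_path)) {
    discrete <- readr::read_tsv(disc_path, show_col_types = FALSE,
                                progress = FALSE)
  }

  truth <- NULL
  truth_path <- file.path(path, "truth.json")
  if (file.exists(truth_path)) {
    truth <- structure(jsonlite::read_json(truth_path, simplifyVector = TRUE,
                                           simplifyDataFrame = FALSE),
                       class = "iop_truth")
  }

  list(acs = acs, coeffs = coeffs, scatter = scatter, lisst = lisst,
       filterpad = filterpad, discrete = discrete, truth = truth)
}

#' Export processed products as a multi-sheet library workbook
#'
#' Writes one sheet per product, with the strain metadata block repeated
#' on every sheet and missing values written as the literal `"NA"`.  The
#' default backend writes a directory of TSV sheets (one file per sheet,
#' stable names); `format = "xlsx"` produces a single spreadsheet
#' workbook through the system `python` and openpyxl when available.
#'
#' @param products Named list of data frames, one per sheet.
#' @param metadata One-row data frame of strain metadata repeated on every
#'   sheet.
#' @param path Output directory (tsv) or `.xlsx` file path.
#' @param format `"tsv"` or `"xlsx"`.
#' @return `path`, invisibly.
#' @export
write_library_workbook <- function(products, metadata, path,
                                   format = c("tsv", "xlsx")) {
  format <- match.arg(format)
  if (!length(products)) abort("no products to write")
  if (is.null(names(products)) || any(!nzchar(names(products)))) {
    abort("every product sheet needs a name")
  }
  if (!is.data.frame(metadata) || nrow(metadata) != 1L) {
    abort("metadata must be a one-row data frame")
  }
  sheets <- purrr::map(products, function(p) {
    dplyr::bind_cols(metadata[rep(1L, nrow(p)), , drop = FALSE],
                     tibble::as_tibble(p))
  })
  if (format == "tsv") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(sheets)) {
      readr::write_tsv(sheets[[nm]], file.path(path, paste0(nm, ".tsv")),
                       na = "NA", progress = FALSE)
    }
    return(invisible(path))
  }
  python <- Sys.which("python")
  if (!nzchar(python)) {
    abort("xlsx export needs a `python` with openpyxl on the PATH; use format = 'tsv' otherwise")
  }
  tmp <- tempfile("workbook_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  for (nm in names(sheets)) {
    readr::write_tsv(sheets[[nm]], file.path(tmp, paste0(nm, ".tsv")),
                     na = "NA", progress = FALSE)
  }
  script <- file.path(tmp, "make_xlsx.py")
  writeLines(c(
    "import csv, sys, glob, os",
    "from openpyxl import Workbook",
    "src, dst = sys.argv[1], sys.argv[2]",
    "wb = Workbook(); wb.remove(wb.active)",
    "for f in sorted(glob.glob(os.path.join(src, '*.tsv'))):",
    "    name = os.path.splitext(os.path.basename(f))[0][:31]",
    "    ws = wb.create_sheet(title=name)",
    "    with open(f) as fh:",
    "        for row in csv.reader(fh, delimiter='\\t'):",
    "            out = []",
    "            for cell in row:",
    "                try:",
    "                    out.append(float(cell))",
    "                except ValueError:",
    "                    out.append(cell)",
    "            ws.append(out)",
    "wb.save(dst)"), script)
  status <- system2(python, c(script, tmp, path), stdout = TRUE,
                    stderr = TRUE)
  if (!file.exists(path)) {
    abort(sprintf("xlsx export failed: %s", paste(status, collapse = "; ")))
  }
  invisible(path)
}

#' @rdname write_library_workbook
#' @export
read_library_workbook <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tsv$", full.names = TRUE)
    if (!length(files)) abort(sprintf("no sheets found in %s", path))
    out <- purrr::map(files, readr::read_tsv, show_col_types = FALSE,
                      progress = FALSE, na = "NA")
    names(out) <- sub("\\.tsv$", "", basename(files))
    return(out)
  }
  if (!requireNamespace("readxl", quietly = TRUE)) {
    abort("reading xlsx workbooks needs the readxl package")
  }
  sheets <- readxl::excel_sheets(path)
  out <- purrr::map(sheets, function(sh) {
    tibble::as_tibble(readxl::read_excel(path, sheet = sh, na = "NA"))
  })
  names(out) <- sheets
  out
}

#' Provenance record for a processing run
#'
#' Captures everything needed to reproduce a processing output
#' bit-for-bit: MD5 hashes of the input files, the configuration in
#' force (reference wavelength, sign conventions, chi factors, fit
#' selections), and the package version.
#'
#' @param input_paths Character vector of input files/directories.
#' @param config Named list of stage parameters.
#' @return A list suitable for [jsonlite::write_json()].
#' @export
provenance_record <- function(input_paths, config = list()) {
  files <- unlist(purrr::map(input_paths, function(p) {
    if (dir.exists(p)) list.files(p, recursive = TRUE, full.names = TRUE) else p
  }))
  files <- files[file.exists(files)]
  list(package = "phytoptics",
       version = as.character(utils::packageVersion("phytoptics")),
       inputs = as.list(tools::md5sum(files)),
       config = config)
}
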