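#' Path to a packaged example/fixture file
#'
#' @param file File name under `inst/extdata`; with no argument, lists the
#'   available files.
#' @return A file path (or a character vector of file names).
#' @export
spectrocal_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "spectrocal")))
  }
  path <- system.file("extdata", file, package = "spectrocal")
  if (!nzchar(path)) abort(paste0("no packaged file '", file, "'"))
  path
}

parse_column_label <- function(label) {
  # "<sample>_<replicate>" with an optional "r" prefix on the replicate,
  # e.g. "A_r1" or "A_1"; sample labels may themselves contain underscores.
  m <- regmatches(label, regexec("^(.*)_r?([0-9]+)$", label))[[1]]
  if (length(m) != 3) {
    abort(paste0("cannot parse spectrum column label '", label,
                 "' as <sample>_<replicate>"))
  }
  list(sample = m[2], replicate = as.integer(m[3]))
}

#' Read reflectance spectra from disk
#'
#' Three dialects are supported:
#' \describe{
#'   \item{`csv-wide`}{first column `wavelength_nm`, one column per spectrum
#'     labelled `<sample>_<replicate>` (e.g. `A_r1`).}
#'   \item{`csv-long`}{columns `sample, replicate, wavelength_nm, value`.}
#'   \item{`jcampdx-min`}{a minimal JCAMP-DX-like dialect: one block per
#'     spectrum delimited by `##TITLE=<sample>_<replicate>` and `##END=`,
#'     with `##FIRSTX=`, `##DELTAX=`, `##NPOINTS=` records and a fixed-step
#'     `##XYDATA=(X++(Y..Y))` table whose lines hold an abscissa followed by
#'     ordinates.}
#' }
#'
#' @param path Input file.
#' @param dialect One of `"csv-wide"`, `"csv-long"`, `"jcampdx-min"`.
#' @return A validated, grid-harmonized spectra tibble (see [as_spectra()]).
#' @export
read_spectra <- function(path, dialect = c("csv-wide", "csv-long", "jcampdx-min")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  out <- switch(dialect,
    "csv-wide" = read_spectra_wide(path),
    "csv-long" = {
      x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
      x
    },
    "jcampdx-min" = read_spectra_jcamp(path)
  )
  as_spectra(out, harmonized = TRUE)
}

read_spectra_wide <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (names(x)[1] != "wavelength_nm") {
    # tolerate a generic first column name such as "wavelength"
    names(x)[1] <- "wavelength_nm"
  }
  if (is.unsorted(x$wavelength_nm, strictly = TRUE)) {
    abort("non-monotone grid")
  }
  long <- tidyr::pivot_longer(x, -"wavelength_nm",
                              names_to = "label", values_to = "value")
  ids <- lapply(unique(long$label), function(l) {
    c(list(label = l), parse_column_label(l))
  })
  ids <- dplyr::bind_rows(lapply(ids, tibble::as_tibble))
  long |>
    dplyr::left_join(ids, by = "label") |>
    dplyr::select("sample", "replicate", "wavelength_nm", "value")
}

read_spectra_jcamp <- function(path) {
  lines <- readLines(path)
  starts <- grep("^##TITLE=", lines)
  if (length(starts) == 0) abort("no ##TITLE= records found")
  ends <- grep("^##END=", lines)
  if (length(ends) != length(starts)) abort("unbalanced ##TITLE=/##END= blocks")
  blocks <- Map(function(s, e) lines[s:e], starts, ends)
  out <- lapply(blocks, function(b) {
    get_field <- function(key) {
      hit <- grep(paste0("^##", key, "="), b, value = TRUE)
      if (length(hit) == 0) abort(paste0("missing ##", key, "= record"))
      sub(paste0("^##", key, "="), "", hit[1])
    }
    title <- get_field("TITLE")
    firstx <- as.numeric(get_field("FIRSTX"))
    deltax <- as.numeric(get_field("DELTAX"))
    npoints <- as.integer(get_field("NPOINTS"))
    if (!is.finite(deltax) || deltax <= 0) abort("non-monotone grid")
    data_at <- grep("^##XYDATA=", b)
    if (length(data_at) == 0) abort("missing ##XYDATA= record")
    data_lines <- b[(data_at[1] + 1):(length(b) - 1)]
    data_lines <- data_lines[!grepl("^##", data_lines)]
    vals <- lapply(strsplit(trimws(data_lines), "[[:space:]]+"), as.numeric)
    y <- unlist(lapply(vals, function(v) v[-1]))
    x_check <- vapply(vals, function(v) v[1], numeric(1))
    n_per <- vapply(vals, function(v) length(v) - 1L, integer(1))
    expect_x <- firstx + deltax * c(0, cumsum(n_per[-length(n_per)]))
    if (any(abs(x_check - expect_x) > 1e-6 * max(1, abs(deltax)))) {
      abort("XYDATA abscissae inconsistent with FIRSTX/DELTAX")
    }
    if (length(y) != npoints) {
      abort(paste0("NPOINTS=", npoints, " but ", length(y), " ordinates read"))
    }
    id <- parse_column_label(title)
    tibble::tibble(sample = id$sample, replicate = id$replicate,
                   wavelength_nm = firstx + deltax * (seq_len(npoints) - 1),
                   value = y)
  })
  dplyr::bind_rows(out)
}

#' Write reflectance spectra to disk
#'
#' Values are written at full double precision so that a read/write round
#' trip is lossless. See [read_spectra()] for the dialects.
#'
#' @param spectra A spectra table.
#' @param path Output file.
#' @param dialect One of `"csv-wide"`, `"csv-long"`, `"jcampdx-min"`.
#'   `csv-wide` and `jcampdx-min` require a common grid across spectra.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path,
                          dialect = c("csv-wide", "csv-long", "jcampdx-min")) {
  dialect <- match.arg(dialect)
  spectra <- as_spectra(spectra, harmonized = dialect != "csv-long")
  if (dialect == "csv-long") {
    readr::write_csv(spectra, path, progress = FALSE)
    return(invisible(path))
  }
  if (dialect == "csv-wide") {
    wide <- spectra |>
      dplyr::mutate(label = paste0(.data$sample, "_r", .data$replicate)) |>
      tidyr::pivot_wider(id_cols = "wavelength_nm",
                         names_from = "label", values_from = "value")
    readr::write_csv(wide, path, progress = FALSE)
    return(invisible(path))
  }
  # jcampdx-min
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(v) format(v, digits = 17, scientific = FALSE, trim = TRUE)
  spectra |>
    dplyr::group_by(.data$sample, .data$replicate) |>
    dplyr::group_walk(function(g, key) {
      wl <- g$wavelength_nm
      step <- unique(round(diff(wl), 9))
      if (length(step) != 1) {
        abort("jcampdx-min requires a fixed wavelength step")
      }
      writeLines(c(
        paste0("##TITLE=", key$sample, "_r", key$replicate),
        "##XUNITS=NANOMETERS",
        "##YUNITS=REFLECTANCE",
        paste0("##FIRSTX=", fmt(wl[1])),
        paste0("##DELTAX=", fmt(step)),
        paste0("##NPOINTS=", length(wl)),
        "##XYDATA=(X++(Y..Y))"
      ), con)
      idx <- split(seq_along(wl), ceiling(seq_along(wl) / 5))
      for (ii in idx) {
        writeLines(paste(fmt(wl[ii[1]]),
                         paste(fmt(g$value[ii]), collapse = " ")), con)
      }
      writeLines("##END=", con)
    })
  invisible(path)
}

#' Read a component-by-sample reference concentration table
#'
#' The file is a long CSV with columns `component_index, component_name,
#' sample, concentration_mg_g, sd`; empty fields denote values not determined
#' by the reference method (missing). Missing concentrations exclude that
#' sample from the affected component's calibration; the `sd` column is
#' carried along but not used in modeling.
#'
#' @param path CSV file; defaults to the packaged reference table of HPLC-UV
#'   concentrations (mg/g) for 14 components in ten Arnicae flos samples.
#' @return A tibble with one row per component-sample pair.
#' @export
read_concentration_table <- function(path = spectrocal_example("arnica_concentrations.csv")) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         component_index = readr::col_integer(),
                         component_name = readr::col_character(),
                         sample = readr::col_character(),
                         concentration_mg_g = readr::col_double(),
                         sd = readr::col_double()
                       ))
  required <- c("component_index", "component_name", "sample",
                "concentration_mg_g", "sd")
  if (!all(required %in% names(x))) {
    abort("concentration table lacks required columns")
  }
  bad <- which(is.na(x$component_index) | is.na(x$sample) | !nzchar(x$sample))
  if (length(bad) > 0) {
    abort(paste0("malformed concentration row at component index ",
                 x$component_index[bad[1]] %||% "<NA>"))
  }
  if (any(x$concentration_mg_g < 0, na.rm = TRUE)) {
    abort(paste0("negative concentration for component ",
                 x$component_index[which(x$concentration_mg_g < 0)[1]]))
  }
  idx <- x |>
    dplyr::distinct(.data$component_index, .data$component_name)
  if (anyDuplicated(idx$component_index) > 0) {
    abort("component indices are not unique")
  }
  x
}

#' Packaged reference concentrations for the Arnicae flos study
#'
#' HPLC-UV reference concentrations (mg/g of dried flower material) of 14
#' phytochemical components - phenolic acids, sesquiterpene lactones and
#' flavonoids - in ten Arnicae flos samples labelled `A` to `J`. Entries the
#' reference method did not determine are `NA`.
#'
#' @return A tibble in the layout of [read_concentration_table()].
#' @export
arnica_concentrations <- function() {
  read_concentration_table()
}

#' Packaged calibration summary of the three preprocessing variants
#'
#' The reported calibration statistics (RMSECV in mg/g, R-squared, and number
#' of latent variables) for each of the 14 components under the three
#' preprocessing variants (`none`, `gs`, `sbsf`), as a comparison-report
#' tibble suitable for [count_best_by_method()]. Component numbering follows
#' the summary table itself (which differs from the concentration table for
#' components 7-12; e.g. quercetin is 12 here but 11 there).
#'
#' @return A comparison-report tibble.
#' @export
arnica_model_summary <- function() {
  x <- readr::read_csv(spectrocal_example("arnica_model_summary.csv"),
                       show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         component_index = readr::col_integer(),
                         component_name = readr::col_character(),
                         method = readr::col_character(),
                         rmsecv = readr::col_double(),
                         r2 = readr::col_double(),
                         n_pc = readr::col_integer()
                       ))
  new_comparison_report(x, metadata = list(source = "published summary table"))
}
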