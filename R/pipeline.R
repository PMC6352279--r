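new_comparison_report <- function(cells, metadata = list()) {
  cells <- tibble::as_tibble(cells)
  class(cells) <- c("comparison_report", class(cells))
  attr(cells, "metadata") <- metadata
  cells
}

#' Run the full three-way calibration comparison
#'
#' Orchestrates the whole workflow for every component and every requested
#' preprocessing method: trim the raw spectra to the artifact-free regions,
#' average replicates, differentiate (for `gs`/`sbsf`), trim to the
#' method-specific retained regions, assemble the data matrix, screen the
#' component's concentrations for outliers, then run leave-one-out
#' cross-validation with fold-wise mean centering and select the
#' latent-variable count by minimum RMSECV. A failure in one
#' component-method cell is recorded in that cell's `note`; the remaining
#' cells are still computed. The result is deterministic given its inputs.
#'
#' @param spectra Replicated spectra table (measured or from
#'   [generate_study()]).
#' @param conc Concentration tibble (see [read_concentration_table()]).
#' @param methods Preprocessing methods to compare, subset of
#'   `c("none", "gs", "sbsf")`.
#' @param filter_specs Named list of [filter_spec()]s for `"gs"` and
#'   `"sbsf"`; defaults to the study settings (GS half-window 10 / degree 2,
#'   SBSF window 2 / degree 3).
#' @param raw_regions Regions applied to the raw spectra before
#'   differentiation (default `270-850` and `907-2000` nm).
#' @param regions Named list of post-processing retained regions per method;
#'   defaults to [default_regions()].
#' @param algorithm `"pls1"` or `"pcr"`.
#' @param max_pc Largest latent-variable count offered to selection (clipped
#'   per component to `n - 2`).
#' @param outlier_threshold Robust z-score cutoff for [detect_outliers()].
#' @param components Component indices to model; default all in `conc`.
#' @return A `comparison_report`: one row per component-method cell with
#'   `n_pc`, `rmsecv`, `r2`, `slope`, `offset`, `n` (samples used),
#'   `excluded` (list-column of labels like `"H (outlier)"`) and `note`. Run
#'   settings are stored in the `"metadata"` attribute.
#' @export
run_pipeline <- function(spectra, conc,
                         methods = c("none", "gs", "sbsf"),
                         filter_specs = list(gs = filter_spec("gs"),
                                             sbsf = filter_spec("sbsf")),
                         raw_regions = default_regions("none"),
                         regions = list(none = default_regions("none"),
                                        gs = default_regions("gs"),
                                        sbsf = default_regions("sbsf")),
                         algorithm = c("pls1", "pcr"),
                         max_pc = 8L,
                         outlier_threshold = 5,
                         components = NULL) {
  algorithm <- match.arg(algorithm)
  methods <- match.arg(methods, several.ok = TRUE)
  spectra <- as_spectra(spectra)
  components <- components %||% sort(unique(conc$component_index))
  comp_names <- conc |>
    dplyr::distinct(.data$component_index, .data$component_name)

  base <- spectra |>
    trim_regions(raw_regions) |>
    average_replicates()

  matrices <- list()
  for (m in methods) {
    prepped <- if (m == "none") base else
      derive_spectra(base, filter_specs[[m]])
    matrices[[m]] <- spectra_matrix(trim_regions(prepped, regions[[m]]))
  }

  cells <- purrr::map_dfr(components, function(ci) {
    cname <- comp_names$component_name[comp_names$component_index == ci][1]
    flagged <- tryCatch(
      {
        rep <- detect_outliers(conc, ci, threshold = outlier_threshold)
        rep$sample[rep$flagged]
      },
      error = function(e) character(0)
    )
    purrr::map_dfr(methods, function(m) {
      X <- matrices[[m]]
      yv <- conc$concentration_mg_g[conc$component_index == ci]
      names(yv) <- conc$sample[conc$component_index == ci]
      y <- yv[rownames(X)]
      excluded <- c(
        paste0(rownames(X)[is.na(y)], " (missing reference)"),
        paste0(intersect(flagged, rownames(X)[!is.na(y)]), " (outlier)")
      )
      y[names(y) %in% flagged] <- NA
      res <- tryCatch(
        {
          keep_n <- sum(!is.na(y))
          cv <- withCallingHandlers(
            loocv_calibration(X, y, max_pc = min(max_pc, keep_n - 2L),
                              algorithm = algorithm),
            warning = function(w) invokeRestart("muffleWarning")
          )
          sel <- select_pcs(cv)
          tibble::tibble(n_pc = sel$n_pc, rmsecv = sel$rmsecv, r2 = sel$r2,
                         slope = sel$slope, offset = sel$offset,
                         n = keep_n, note = NA_character_)
        },
        error = function(e) {
          tibble::tibble(n_pc = NA_integer_, rmsecv = NA_real_,
                         r2 = NA_real_, slope = NA_real_, offset = NA_real_,
                         n = sum(!is.na(y)),
                         note = paste0("component ", ci, " / ", m, ": ",
                                       conditionMessage(e)))
        }
      )
      dplyr::bind_cols(
        tibble::tibble(component_index = as.integer(ci),
                       component_name = cname, method = m),
        res,
        tibble::tibble(excluded = list(excluded))
      )
    })
  })

  new_comparison_report(cells, metadata = list(
    algorithm = algorithm,
    max_pc = as.integer(max_pc),
    outlier_threshold = outlier_threshold,
    methods = methods,
    filter_specs = lapply(filter_specs, unclass),
    raw_regions = as.data.frame(raw_regions),
    regions = lapply(regions, as.data.frame),
    package_version = as.character(utils::packageVersion("spectrocal"))
  ))
}

#' Best preprocessing method per component
#'
#' The method with strictly the lowest RMSECV wins a component; when two or
#' more methods tie for the minimum the component is credited to no method
#' (`best_method = NA`).
#'
#' @param report A `comparison_report`.
#' @return A tibble with one row per component: `component_index`,
#'   `component_name`, `best_method`, `best_rmsecv`.
#' @export
best_methods <- function(report) {
  report |>
    tibble::as_tibble() |>
    dplyr::filter(!is.na(.data$rmsecv)) |>
    dplyr::group_by(.data$component_index, .data$component_name) |>
    dplyr::summarise(
      best_method = {
        lo <- min(.data$rmsecv)
        winners <- .data$method[.data$rmsecv == lo]
        if (length(winners) == 1) winners else NA_character_
      },
      best_rmsecv = min(.data$rmsecv),
      .groups = "drop"
    )
}

#' Tally how many components each method wins
#'
#' Counts, over a chosen component subset, how many components each
#' preprocessing method wins by strict minimum RMSECV; ties are credited to
#' no method. The default subset 1-13 covers the actively monitored
#' components and leaves out component 14.
#'
#' @param report A `comparison_report`.
#' @param components Component indices to tally over.
#' @return A tibble with `method`, `n_best`, and a `components` list-column
#'   of the winning component indices.
#' @export
count_best_by_method <- function(report, components = 1:13) {
  bm <- best_methods(report) |>
    dplyr::filter(.data$component_index %in% components)
  all_methods <- unique(tibble::as_tibble(report)$method)
  purrr::map_dfr(all_methods, function(m) {
    won <- bm$component_index[!is.na(bm$best_method) & bm$best_method == m]
    tibble::tibble(method = m, n_best = length(won),
                   components = list(sort(won)))
  })
}

report_cells <- function(report) {
  report |>
    tibble::as_tibble() |>
    dplyr::select(dplyr::any_of(c("component_index", "component_name",
                                  "method", "n_pc", "rmsecv", "r2",
                                  "slope", "offset", "n", "note")))
}

#' Export a comparison report
#'
#' `json` writes the cells plus run metadata and round-trips losslessly
#' through [import_report()]. `csv` writes the long cell table (one row per
#' component-method pair, the shape used for RMSECV comparison plots).
#' `markdown` writes a grid with one row per component and one column group
#' (RMSECV, R-squared, latent variables) per method.
#'
#' @param report A `comparison_report`.
#' @param path Output file.
#' @param format One of `"json"`, `"csv"`, `"markdown"`.
#' @return `path`, invisibly.
#' @export
export_report <- function(report, path, format = c("json", "csv", "markdown")) {
  format <- match.arg(format)
  cells <- report_cells(report)
  if (format == "json") {
    payload <- list(cells = cells,
                    metadata = attr(report, "metadata") %||% list())
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  } else if (format == "csv") {
    readr::write_csv(cells, path, progress = FALSE)
  } else {
    methods <- unique(cells$method)
    wide <- cells |>
      tidyr::pivot_wider(id_cols = c("component_index", "component_name"),
                         names_from = "method",
                         values_from = c("rmsecv", "r2", "n_pc"))
    header <- c("No", "Component",
                unlist(lapply(methods, function(m)
                  paste0(c("RMSECV ", "R2 ", "PCs "), m))))
    lines <- c(paste0("| ", paste(header, collapse = " | "), " |"),
               paste0("|", paste(rep("---", length(header)), collapse = "|"),
                      "|"))
    for (i in seq_len(nrow(wide))) {
      vals <- unlist(lapply(methods, function(m) {
        c(format(wide[[paste0("rmsecv_", m)]][i], digits = 4),
          format(wide[[paste0("r2_", m)]][i], digits = 4),
          as.character(wide[[paste0("n_pc_", m)]][i]))
      }))
      lines <- c(lines, paste0("| ", wide$component_index[i], " | ",
                               wide$component_name[i], " | ",
                               paste(vals, collapse = " | "), " |"))
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a comparison report back from disk
#'
#' @param path File written by [export_report()].
#' @param format `"json"` or `"csv"`.
#' @return A `comparison_report`.
#' @export
import_report <- function(path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- jsonlite::read_json(path, simplifyVector = TRUE)
    cells <- tibble::as_tibble(payload$cells)
    cells$component_index <- as.integer(cells$component_index)
    cells$n_pc <- as.integer(cells$n_pc)
    if (!"note" %in% names(cells)) cells$note <- NA_character_
    new_comparison_report(cells, metadata = payload$metadata)
  } else {
    cells <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    cells$component_index <- as.integer(cells$component_index)
    cells$n_pc <- as.integer(cells$n_pc)
    new_comparison_report(cells, metadata = list(source = path))
  }
}
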