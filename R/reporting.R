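#' Enumerate a cross-validation smoothing-parameter grid
#'
#' Penalized-likelihood dating selects its smoothing parameter lambda by
#' cross-validation over a multiplicative grid: starting at `cv_start`, each
#' candidate is the previous one divided by `factor`, down to the last value
#' not below `cv_stop` (a value exactly equal to `cv_stop` within a relative
#' `1e-9` is included).
#'
#' @param cv_start First (largest) smoothing value, `>= cv_stop`.
#' @param cv_stop Smallest admissible smoothing value, `> 0`.
#' @param factor Multiplicative step, `> 1` (default 10).
#' @return An object of class `smoothing_grid` with the descending `values`.
#' @examples
#' length(smoothing_grid(100, 0.01)$values)  # 5: 100, 10, 1, 0.1, 0.01
#' @export
smoothing_grid <- function(cv_start, cv_stop, factor = 10) {
  if (!(cv_stop > 0)) stop("cv_stop must be > 0", call. = FALSE)
  if (cv_start < cv_stop) stop("cv_start must be >= cv_stop", call. = FALSE)
  if (!(factor > 1)) stop("factor must be > 1", call. = FALSE)
  n_steps <- floor(log(cv_start / cv_stop) / log(factor) + 1e-9)
  values <- cv_start / factor^(0:n_steps)
  structure(list(cv_start = cv_start, cv_stop = cv_stop, factor = factor,
                 values = values),
            class = "smoothing_grid")
}

#' @export
print.smoothing_grid <- function(x, ...) {
  cat(sprintf("<smoothing_grid> %d values from %g down to %g (factor %g)\n",
              length(x$values), x$cv_start, utils::tail(x$values, 1), x$factor))
  invisible(x)
}

#' @export
length.smoothing_grid <- function(x) length(x$values)

#' Aggregate per-dataset comparison metrics across a study collection
#'
#' Given a table of per-dataset metrics (one [glance()] row per
#' dataset-method comparison), computes the across-dataset mean and median
#' of the slope, the mean normalized difference, the coverage, and the
#' median normalized uncertainty width of the estimating method, per method
#' label.
#'
#' @param results A tibble with columns `method_est`, `beta`, `d_bar`,
#'   `coverage`, `median_u_width_est` (e.g. bound [glance()] rows).
#' @return A tibble, one row per method, with `n_datasets` and
#'   `mean_`/`median_` columns for each statistic.
#' @export
aggregate_summary <- function(results) {
  stopifnot(is.data.frame(results))
  results |>
    dplyr::group_by(method = .data$method_est) |>
    dplyr::summarise(
      n_datasets = dplyr::n(),
      mean_beta = mean(.data$beta), median_beta = stats::median(.data$beta),
      mean_d_bar = mean(.data$d_bar), median_d_bar = stats::median(.data$d_bar),
      mean_coverage = mean(.data$coverage, na.rm = TRUE),
      median_coverage = stats::median(.data$coverage, na.rm = TRUE),
      mean_u_width = mean(.data$median_u_width_est, na.rm = TRUE),
      median_u_width = stats::median(.data$median_u_width_est, na.rm = TRUE),
      .groups = "drop")
}

read_tree_auto <- function(path, method = NA_character_) {
  if (inherits(path, "timetree")) return(path)
  if (grepl("\\.(nex|nexus|tre[e]?)$", path, ignore.case = TRUE) &&
      any(grepl("#NEXUS", readLines(path, n = 1), ignore.case = TRUE))) {
    read_chronogram_nexus(path, method = method)
  } else {
    read_chronogram_newick(path, method = method)
  }
}

#' Run the full comparison pipeline over a dataset configuration
#'
#' Each configuration entry describes one dataset: a reference chronogram,
#' one or more estimate chronograms, and optionally an outgroup to prune,
#' a calibration file/list, and a feature row. Trees may be given as file
#' paths (Newick or annotated NEXUS, auto-detected) or as in-memory
#' `timetree` objects. Failures in individual datasets are recorded and the
#' run continues.
#'
#' @param config A list of dataset entries, or a path to a YAML/JSON file
#'   holding one. Entry fields: `label`, `reference`, `estimate` (scalar or
#'   list, optionally named by method), `outgroup` (character vector),
#'   `calibrations` (path or list of [calibration_spec()]).
#' @param out_dir Optional output directory: per-node TSVs, per-dataset
#'   metric JSONs, and the aggregate summary are written there.
#' @param mode,age_floor,drop_root Passed to [compare_dataset()].
#' @return A list with `results` (per dataset-method [glance()] rows),
#'   `summary` ([aggregate_summary()] output), `comparisons` (the
#'   `chrono_comparison` objects) and `failures` (tibble of label + error).
#' @export
run_compare <- function(config, out_dir = NULL, mode = "strict",
                        age_floor = 1e-10, drop_root = FALSE) {
  config <- load_config(config)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list(); comparisons <- list(); failures <- list()
  for (entry in config) {
    label <- entry$label %||% "dataset"
    res <- tryCatch({
      ref <- read_tree_auto(entry$reference, method = "reference")
      calibs <- entry$calibrations
      if (is.character(calibs) && length(calibs) == 1 && file.exists(calibs)) {
        calibs <- read_calibrations(calibs)
      }
      outgroup <- entry$outgroup %||% character()
      ref <- prune_outgroup(ref, outgroup)
      ests <- entry$estimate
      if (inherits(ests, "timetree") || is.character(ests) && length(ests) == 1) {
        ests <- list(ests)
      }
      nm <- names(ests) %||% paste0("estimate", seq_along(ests))
      nm[!nzchar(nm)] <- paste0("estimate", which(!nzchar(nm)))
      purrr::map2(ests, nm, function(est, est_name) {
        est <- read_tree_auto(est, method = est_name)
        est <- prune_outgroup(est, outgroup)
        cmp <- compare_dataset(ref, est, mode = mode, calibrations = calibs,
                               drop_root = drop_root, age_floor = age_floor,
                               label = label)
        if (!is.null(out_dir)) {
          base <- file.path(out_dir, paste0(label, "_", est_name))
          readr::write_tsv(cmp$nodes, paste0(base, "_nodes.tsv"), na = "")
          jsonlite::write_json(cmp$metrics, paste0(base, "_metrics.json"),
                               auto_unbox = TRUE, digits = NA)
        }
        cmp
      })
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        tibble::tibble(label = label, error = conditionMessage(res))
      next
    }
    comparisons <- c(comparisons, res)
    results <- c(results, purrr::map(res, glance))
  }
  results <- dplyr::bind_rows(results)
  summary <- if (nrow(results)) aggregate_summary(results) else tibble::tibble()
  failures <- if (length(failures)) dplyr::bind_rows(failures) else
    tibble::tibble(label = character(), error = character())
  if (!is.null(out_dir)) {
    if (nrow(results)) {
      readr::write_tsv(results, file.path(out_dir, "per_dataset_metrics.tsv"), na = "")
      jsonlite::write_json(summary, file.path(out_dir, "aggregate_summary.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }
    if (nrow(failures)) {
      readr::write_tsv(failures, file.path(out_dir, "failures.tsv"))
    }
  }
  list(results = results, summary = summary, comparisons = comparisons,
       failures = failures)
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1 && file.exists(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    } else {
      yaml::read_yaml(config)
    }
    if (!is.null(config$datasets)) config <- config$datasets
  }
  stopifnot(is.list(config))
  config
}

#' Simulate a study collection and write it to disk
#'
#' Runs [generate_study_collection()] and writes, per dataset, the reference
#' and estimate trees as annotated NEXUS (intervals preserved), a features
#' TSV, and a manifest JSON recording every generator parameter and the
#' seed, so a run can be reproduced exactly.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param ... Passed to [generate_study_collection()].
#' @return The collection, invisibly; `$manifest` holds the manifest path.
#' @export
run_simulate <- function(out_dir, seed, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  args <- list(...)
  coll <- generate_study_collection(seed = seed, ...)
  cfg <- list()
  for (d in coll$datasets) {
    ddir <- file.path(out_dir, d$label)
    dir.create(ddir, showWarnings = FALSE)
    write_chronogram_nexus(d$reference, file.path(ddir, "reference.nex"))
    write_chronogram_nexus(d$estimate, file.path(ddir, "estimate.nex"))
    cfg[[length(cfg) + 1L]] <- list(
      label = d$label,
      reference = file.path(ddir, "reference.nex"),
      estimate = file.path(ddir, "estimate.nex"))
  }
  readr::write_tsv(coll$features, file.path(out_dir, "features.tsv"))
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(seed = seed, parameters = args,
         n_datasets = length(coll$datasets),
         datasets = cfg),
    manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  coll$manifest <- manifest
  coll$config <- cfg
  invisible(coll)
}
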