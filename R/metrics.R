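#' Mean normalized node-age difference between two methods
#'
#' For each matched node, the signed normalized difference is
#' `delta_i = (t_est_i - t_ref_i) / t_ref_i`; the summary statistic is
#' `D-bar = mean(|delta_i|) * 100`, in percent. Normalizing by the reference
#' (Bayesian) age makes datasets spanning very different depths of the Tree
#' of Life comparable. Nodes whose reference age falls below `age_floor` are
#' excluded from both the per-node deltas and the mean (division by
#' near-zero ages), and the exclusion count is reported.
#'
#' @param table A `matched_nodes` tibble (see [match_nodes()]).
#' @param age_floor Minimum reference age for inclusion (default `1e-10`).
#' @return A list with `d_bar` (percent), `per_node_delta` (signed, `NA` for
#'   excluded rows, aligned with `table`), `n_used`, `n_excluded`.
#' @export
mean_normalized_difference <- function(table, age_floor = 1e-10) {
  stopifnot(is.data.frame(table), nrow(table) >= 1)
  keep <- table$t_ref >= age_floor
  if (!any(keep)) {
    stop("all rows excluded: every reference age is below age_floor",
         call. = FALSE)
  }
  delta <- rep(NA_real_, nrow(table))
  delta[keep] <- (table$t_est[keep] - table$t_ref[keep]) / table$t_ref[keep]
  list(d_bar = mean(abs(delta[keep])) * 100,
       per_node_delta = delta,
       n_used = sum(keep),
       n_excluded = sum(!keep))
}

#' Linear regression through the origin of estimate on reference ages
#'
#' Fits `t_est = beta * t_ref` by least squares:
#' `beta = sum(t_ref * t_est) / sum(t_ref^2)`. The coefficient of
#' determination is the uncentered form standard for through-origin fits,
#' `r2 = 1 - RSS / sum(t_est^2)`; the centered variant (which can be
#' negative without an intercept) is also returned. `mse = RSS / n`.
#'
#' @param table A `matched_nodes` tibble with at least 2 rows.
#' @return A list with `beta`, `r2`, `r2_centered`, `mse`, `n`.
#' @export
regression_through_origin <- function(table) {
  stopifnot(is.data.frame(table))
  x <- table$t_ref; y <- table$t_est
  if (length(x) < 2) stop("need at least 2 matched nodes", call. = FALSE)
  sxx <- sum(x^2)
  if (sxx == 0) stop("all reference ages are zero", call. = FALSE)
  beta <- sum(x * y) / sxx
  rss <- sum((y - beta * x)^2)
  tss_u <- sum(y^2)
  tss_c <- sum((y - mean(y))^2)
  list(beta = beta,
       r2 = if (tss_u > 0) 1 - rss / tss_u else NA_real_,
       r2_centered = if (tss_c > 0) 1 - rss / tss_c else NA_real_,
       mse = rss / length(x),
       n = length(x))
}

#' Coverage of point estimates by the other method's intervals
#'
#' The frequency (percent) with which one method's node ages fall inside the
#' other method's uncertainty intervals, with inclusive bounds (HPD
#' endpoints are conventionally closed). The default direction asks how
#' often the fast method's estimates sit inside the reference (Bayesian)
#' credibility intervals. Rows lacking the needed interval are excluded and
#' counted.
#'
#' @param table A `matched_nodes` tibble.
#' @param direction `"est_in_ref"` (default) or `"ref_in_est"`.
#' @return A list with `coverage` (percent), `covered` (logical, `NA` for
#'   rows without an interval), `n_used`, `n_excluded`.
#' @export
coverage_fraction <- function(table, direction = c("est_in_ref", "ref_in_est")) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(table), nrow(table) >= 1)
  if (direction == "est_in_ref") {
    lo <- table$ref_lo; hi <- table$ref_hi; t <- table$t_est
  } else {
    lo <- table$est_lo; hi <- table$est_hi; t <- table$t_ref
  }
  has <- !is.na(lo) & !is.na(hi)
  if (!any(has)) stop("no rows carry the required interval", call. = FALSE)
  covered <- rep(NA, nrow(table))
  covered[has] <- t[has] >= lo[has] & t[has] <= hi[has]
  list(coverage = mean(covered[has]) * 100,
       covered = covered,
       n_used = sum(has),
       n_excluded = sum(!has))
}

#' Normalized uncertainty widths
#'
#' For each node with an interval, `width_i = (upper_i - lower_i) / t_i`,
#' the interval width as a fraction of the node's own age estimate. Nodes
#' with ages below `age_floor` are excluded (division by values near zero)
#' and counted. The median uses the mean of the two central order statistics
#' for an even count.
#'
#' @param x A `timetree`, or a `matched_nodes` tibble together with `side`.
#' @param side When `x` is a matched table: `"ref"` or `"est"` picks which
#'   method's ages and intervals are used.
#' @param age_floor Minimum age for inclusion (default `1e-10`).
#' @return A list with `median_width`, `per_node_width` (aligned, `NA` for
#'   excluded or interval-less rows), `n_used`, `n_excluded` (age-floor
#'   exclusions among interval-carrying nodes).
#' @export
uncertainty_widths <- function(x, side = c("ref", "est"), age_floor = 1e-10) {
  side <- match.arg(side)
  if (inherits(x, "timetree")) {
    tab <- clade_table(x)
    t <- tab$age; lo <- tab$lower; hi <- tab$upper
  } else {
    stopifnot(is.data.frame(x))
    if (side == "ref") {
      t <- x$t_ref; lo <- x$ref_lo; hi <- x$ref_hi
    } else {
      t <- x$t_est; lo <- x$est_lo; hi <- x$est_hi
    }
  }
  has <- !is.na(lo) & !is.na(hi)
  keep <- has & t >= age_floor
  if (!any(keep)) stop("no interval-carrying nodes above age_floor", call. = FALSE)
  width <- rep(NA_real_, length(t))
  width[keep] <- (hi[keep] - lo[keep]) / t[keep]
  list(median_width = stats::median(width[keep]),
       per_node_width = width,
       n_used = sum(keep),
       n_excluded = sum(has & !keep))
}

#' Compare two timetrees over the same taxa
#'
#' Matches nodes between a reference chronogram (typically Bayesian, with
#' credibility intervals) and an estimate chronogram (a fast dating method)
#' and computes the full per-dataset statistics bundle: through-origin
#' regression slope `beta`, uncentered `r2`, `mse`, the mean normalized
#' difference `d_bar` (percent), coverage of estimate ages by reference
#' intervals (percent), and the median normalized uncertainty width of each
#' method. The same `age_floor` is applied to every statistic that divides
#' by a node age, with exclusion counts reported per statistic.
#'
#' @param reference,estimate `timetree` objects over identical leaf sets.
#' @param mode,calibrations,drop_root Passed to [match_nodes()].
#' @param age_floor Minimum reference age for normalized statistics.
#' @param label Optional dataset label.
#' @return An object of class `chrono_comparison`: a list with `nodes` (the
#'   per-node tibble), `metrics` (named list), `label`, and method labels.
#'   Use [tidy()][generics::tidy] for per-node rows and
#'   [glance()][generics::glance] for the one-row summary.
#' @export
compare_dataset <- function(reference, estimate, mode = c("strict", "intersect"),
                            calibrations = NULL, drop_root = FALSE,
                            age_floor = 1e-10, label = NA_character_) {
  mode <- match.arg(mode)
  tab <- match_nodes(reference, estimate, mode = mode,
                     calibrations = calibrations, drop_root = drop_root)
  comparison_from_table(tab, age_floor = age_floor, label = label)
}

#' Compute the comparison statistics from an existing matched-node table
#'
#' @param table A `matched_nodes` tibble.
#' @inheritParams compare_dataset
#' @return A `chrono_comparison`.
#' @export
comparison_from_table <- function(table, age_floor = 1e-10,
                                  label = NA_character_) {
  nd <- mean_normalized_difference(table, age_floor = age_floor)
  reg <- regression_through_origin(table)
  cov <- tryCatch(coverage_fraction(table, "est_in_ref"), error = function(e) NULL)
  w_ref <- tryCatch(uncertainty_widths(table, "ref", age_floor), error = function(e) NULL)
  w_est <- tryCatch(uncertainty_widths(table, "est", age_floor), error = function(e) NULL)
  nodes <- tibble::as_tibble(table) |>
    dplyr::mutate(
      delta_signed = nd$per_node_delta,
      covered = if (is.null(cov)) NA else cov$covered,
      u_width_ref = if (is.null(w_ref)) NA_real_ else w_ref$per_node_width,
      u_width_est = if (is.null(w_est)) NA_real_ else w_est$per_node_width,
      excluded_flag = .data$t_ref < age_floor
    )
  metrics <- list(
    beta = reg$beta, r2 = reg$r2, r2_centered = reg$r2_centered,
    mse = reg$mse,
    d_bar = nd$d_bar,
    coverage = if (is.null(cov)) NA_real_ else cov$coverage,
    median_u_width_ref = if (is.null(w_ref)) NA_real_ else w_ref$median_width,
    median_u_width_est = if (is.null(w_est)) NA_real_ else w_est$median_width,
    n_nodes = nrow(table),
    n_used_delta = nd$n_used, n_excluded_delta = nd$n_excluded,
    n_used_coverage = if (is.null(cov)) 0L else cov$n_used,
    n_excluded_coverage = if (is.null(cov)) nrow(table) else cov$n_excluded,
    n_excluded_width_ref = if (is.null(w_ref)) NA_integer_ else w_ref$n_excluded,
    n_excluded_width_est = if (is.null(w_est)) NA_integer_ else w_est$n_excluded
  )
  structure(list(nodes = nodes, metrics = metrics, label = label,
                 method_ref = attr(table, "method_ref"),
                 method_est = attr(table, "method_est"),
                 age_floor = age_floor),
            class = "chrono_comparison")
}

#' @export
print.chrono_comparison <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<chrono_comparison> %s vs %s%s\n",
              ifelse(is.na(x$method_est), "estimate", x$method_est),
              ifelse(is.na(x$method_ref), "reference", x$method_ref),
              ifelse(is.na(x$label), "", paste0(" [", x$label, "]"))))
  cat(sprintf("  n nodes: %d (age-floor exclusions: %d)\n",
              m$n_nodes, m$n_excluded_delta))
  cat(sprintf("  beta = %.4f, R2 = %.4f, MSE = %.4g\n", m$beta, m$r2, m$mse))
  cat(sprintf("  D-bar = %.2f%%, coverage = %s\n", m$d_bar,
              ifelse(is.na(m$coverage), "NA", sprintf("%.1f%%", m$coverage))))
  cat(sprintf("  median U width: ref %s, est %s\n",
              format(m$median_u_width_ref, digits = 4),
              format(m$median_u_width_est, digits = 4)))
  invisible(x)
}
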