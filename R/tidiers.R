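#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-node rows of a comparison
#'
#' @param x A `chrono_comparison`.
#' @param ... Unused.
#' @return The per-node tibble: clade, paired ages, intervals, signed
#'   normalized difference, coverage flag, per-node normalized widths,
#'   calibration and exclusion flags.
#' @export
tidy.chrono_comparison <- function(x, ...) {
  x$nodes
}

#' One-row summary of a comparison
#'
#' @param x A `chrono_comparison`.
#' @param ... Unused.
#' @return A one-row tibble with the dataset label, method labels, and all
#'   comparison metrics (beta, r2, mse, d_bar, coverage, median widths and
#'   the per-statistic usage/exclusion counts).
#' @export
glance.chrono_comparison <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(label = x$label,
                   method_ref = x$method_ref %||% NA_character_,
                   method_est = x$method_est %||% NA_character_),
    tibble::as_tibble(x$metrics)
  )
}
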