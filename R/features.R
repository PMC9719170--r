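#' Absolute deviation of regression slopes from 1
#'
#' `|beta - 1|` per dataset: the response used to model how far a fast
#' method's timescale departs from proportionality with the Bayesian one.
#'
#' @param betas Numeric vector of through-origin slopes.
#' @return `abs(betas - 1)`.
#' @export
abs_beta_deviation <- function(betas) {
  stopifnot(is.numeric(betas), all(is.finite(betas)))
  abs(betas - 1)
}

#' Assemble a dataset-feature table
#'
#' One row per dataset: taxa count, alignment site count, calibration count
#' and calibration density (calibrations / internal nodes of the pruned
#' ingroup tree; supplied directly or computed from `calib_count` and
#' `n_nodes`).
#'
#' @param label Dataset labels.
#' @param taxa_count,site_count,calib_count Non-negative counts.
#' @param calib_density Optional fraction in `[0, 1]`; computed as
#'   `calib_count / n_nodes` when `n_nodes` is given instead.
#' @param n_nodes Optional denominator for the calibration density.
#' @return A tibble with class `dataset_features`.
#' @export
dataset_features <- function(label, taxa_count, site_count, calib_count,
                             calib_density = NULL, n_nodes = NULL) {
  if (is.null(calib_density)) {
    if (is.null(n_nodes)) n_nodes <- taxa_count - 1L
    calib_density <- calibration_density(calib_count, n_nodes)
  }
  stopifnot(all(taxa_count >= 0), all(site_count >= 0), all(calib_count >= 0),
            all(calib_density >= 0 & calib_density <= 1))
  out <- tibble::tibble(label = as.character(label),
                        taxa_count = taxa_count, site_count = site_count,
                        calib_count = calib_count,
                        calib_density = calib_density)
  class(out) <- c("dataset_features", class(out))
  out
}

#' Linear feature model for method disagreement
#'
#' Ordinary least squares (with intercept) relating dataset features to a
#' disagreement response — either `|beta - 1|` ([abs_beta_deviation()]) or
#' the regression MSE. Count-valued predictors (`taxa_count`, `site_count`)
#' enter on the log10 scale by default since they span orders of magnitude
#' across phylogenomic studies; all predictors are then standardized
#' (mean 0, SD 1) so the fit does not depend on units. Feature importance
#' is the share of the summed absolute t statistics over the non-intercept
#' terms, in percent (raw `|t|` is also reported); the model-level p value
#' is the F test of the full model against the intercept-only model.
#'
#' @param features A data frame with columns `taxa_count`, `site_count`,
#'   `calib_density` (see [dataset_features()]).
#' @param responses Numeric response vector, one per dataset row.
#' @param response_kind `"abs_beta_dev"` or `"mse"` (annotation only).
#' @param log_features Character vector of predictors entered as log10.
#' @param predictors Feature columns to use (default the three dataset
#'   features).
#' @return An object of class `feature_model_fit` with [tidy()] and
#'   [glance()] methods.
#' @export
fit_feature_model <- function(features, responses,
                              response_kind = c("abs_beta_dev", "mse"),
                              log_features = c("taxa_count", "site_count"),
                              predictors = c("taxa_count", "site_count",
                                             "calib_density")) {
  response_kind <- match.arg(response_kind)
  stopifnot(is.data.frame(features), length(predictors) >= 1)
  miss <- setdiff(predictors, names(features))
  if (length(miss)) {
    stop("features lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(features) != length(responses)) {
    stop("features and responses have different lengths", call. = FALSE)
  }
  if (!all(is.finite(responses))) stop("responses must be finite", call. = FALSE)
  n <- nrow(features)
  if (n < max(5, length(predictors) + 2)) {
    stop("too few datasets for the number of predictors", call. = FALSE)
  }
  X <- purrr::map_dfc(predictors, function(p) {
    v <- as.numeric(features[[p]])
    if (p %in% log_features) {
      if (any(v <= 0)) stop("cannot log-transform non-positive ", p, call. = FALSE)
      v <- log10(v)
    }
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      stop(sprintf("predictor '%s' is constant", p), call. = FALSE)
    }
    tibble::tibble(!!p := (v - mean(v)) / s)
  })
  if (qr(as.matrix(X))$rank < ncol(X)) {
    stop("predictors are collinear after standardization", call. = FALSE)
  }
  dat <- dplyr::mutate(X, .response = responses)
  fit <- stats::lm(.response ~ ., data = dat)
  sm <- summary(fit)
  coefs <- sm$coefficients
  terms <- setdiff(rownames(coefs), "(Intercept)")
  abs_t <- abs(coefs[terms, "t value"])
  importance <- if (sum(abs_t) > 0) abs_t / sum(abs_t) * 100 else
    rep(NA_real_, length(abs_t))
  fstat <- sm$fstatistic
  p_overall <- if (is.null(fstat)) NA_real_ else
    unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  structure(list(
    fit = fit,
    response_kind = response_kind,
    log_features = log_features,
    terms = tibble::tibble(
      term = terms,
      estimate = coefs[terms, "Estimate"],
      std_error = coefs[terms, "Std. Error"],
      t_statistic = coefs[terms, "t value"],
      p_value = coefs[terms, "Pr(>|t|)"],
      abs_t = abs_t,
      importance_percent = unname(importance)),
    r2 = sm$r.squared,
    p_value = p_overall,
    n = n
  ), class = "feature_model_fit")
}

#' @export
print.feature_model_fit <- function(x, ...) {
  cat(sprintf("<feature_model_fit> response = %s, n = %d, R2 = %.3f, p = %.3g\n",
              x$response_kind, x$n, x$r2, x$p_value))
  print(x$terms)
  invisible(x)
}

#' @rdname fit_feature_model
#' @param x A `feature_model_fit`.
#' @param ... Unused.
#' @export
tidy.feature_model_fit <- function(x, ...) x$terms

#' @rdname fit_feature_model
#' @export
glance.feature_model_fit <- function(x, ...) {
  tibble::tibble(response_kind = x$response_kind, r.squared = x$r2,
                 p.value = x$p_value, nobs = x$n,
                 top_feature = x$terms$term[which.max(x$terms$importance_percent)])
}
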