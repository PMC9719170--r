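#' Node-age calibration specifications
#'
#' A calibration attaches prior information on a node's age to a clade,
#' either as hard bounds or as a probability density. Supported forms:
#' `bounds(min?, max?)` (either side may be absent), `uniform(min, max)`,
#' `normal(mean, sd)`, `lognormal(meanlog, sdlog, offset)`,
#' `exponential(mean, offset)` and `skew_t(location, scale, slant, df)`.
#' Offsets shift the exponential/lognormal support away from zero, as dating
#' priors are typically anchored on a fossil minimum.
#'
#' @param clade Clade key (sorted leaf labels joined by `";"`) or character
#'   vector of leaf labels (joined for you).
#' @param form One of `"bounds"`, `"uniform"`, `"normal"`, `"lognormal"`,
#'   `"exponential"`, `"skew_t"`.
#' @param ... Named numeric parameters of the form (see above). All age
#'   parameters are in the tree's time units.
#' @return An object of class `calibration_spec`.
#' @export
calibration_spec <- function(clade, form, ...) {
  form <- match.arg(form, c("bounds", "uniform", "normal", "lognormal",
                            "exponential", "skew_t"))
  if (length(clade) > 1) clade <- paste(sort(clade, method = "radix"), collapse = ";")
  par <- list(...)
  need <- switch(form,
    bounds = character(),
    uniform = c("min", "max"),
    normal = c("mean", "sd"),
    lognormal = c("meanlog", "sdlog"),
    exponential = c("mean"),
    skew_t = c("location", "scale", "slant", "df"))
  miss <- setdiff(need, names(par))
  if (length(miss)) {
    stop(sprintf("calibration form '%s' requires parameter(s): %s",
                 form, paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (form %in% c("lognormal", "exponential") && is.null(par$offset)) par$offset <- 0
  check_pos <- function(nm) {
    if (!is.null(par[[nm]]) && par[[nm]] <= 0) {
      stop(sprintf("parameter '%s' must be > 0", nm), call. = FALSE)
    }
  }
  if (form == "normal") check_pos("sd")
  if (form == "lognormal") check_pos("sdlog")
  if (form == "exponential") check_pos("mean")
  if (form == "skew_t") { check_pos("scale"); check_pos("df") }
  if (!is.null(par$offset) && par$offset < 0) {
    stop("offset must be >= 0", call. = FALSE)
  }
  if (form %in% c("bounds", "uniform") &&
      !is.null(par$min) && !is.null(par$max) && par$min > par$max) {
    stop("min must be <= max", call. = FALSE)
  }
  structure(list(clade = clade, form = form, par = par),
            class = "calibration_spec")
}

#' @export
print.calibration_spec <- function(x, ...) {
  cat(sprintf("<calibration> %s(%s) on {%s}\n", x$form,
              paste(names(x$par), unlist(x$par), sep = "=", collapse = ", "),
              x$clade))
  invisible(x)
}

#' Convert a calibration density to hard min/max bounds
#'
#' Density calibrations are converted to the hard bounds that penalized
#' likelihood dating requires by taking the lower 2.5% and upper 97.5%
#' quantiles of the density (quantile levels configurable). Uniform and
#' bounds forms pass through unchanged: a uniform prior's bounds are already
#' the hard minimum and maximum. Skew-t densities are first approximated by
#' a normal via [approximate_normal()].
#'
#' @param spec A `calibration_spec`.
#' @param q_low,q_high Quantile levels, `0 <= q_low < q_high <= 1`.
#' @param seed Seed for the skew-t normal approximation.
#' @return A `calibration_spec` of form `bounds`.
#' @export
density_to_bounds <- function(spec, q_low = 0.025, q_high = 0.975, seed = 1L) {
  stopifnot(inherits(spec, "calibration_spec"))
  if (!(q_low >= 0 && q_low < q_high && q_high <= 1)) {
    stop("need 0 <= q_low < q_high <= 1", call. = FALSE)
  }
  p <- spec$par
  if (spec$form %in% c("bounds", "uniform")) {
    if (spec$form == "bounds" && !missing(q_low)) {
      warning("bounds calibration passes through unchanged; quantiles ignored",
              call. = FALSE)
    }
    return(calibration_spec(spec$clade, "bounds", min = p$min, max = p$max))
  }
  if (spec$form == "skew_t") {
    spec <- approximate_normal(spec, seed = seed)
    p <- spec$par
  }
  qfun <- switch(spec$form,
    normal = function(q) stats::qnorm(q, p$mean, p$sd),
    lognormal = function(q) p$offset + stats::qlnorm(q, p$meanlog, p$sdlog),
    exponential = function(q) p$offset + stats::qexp(q, rate = 1 / p$mean))
  lo <- qfun(q_low); hi <- qfun(q_high)
  calibration_spec(spec$clade, "bounds", min = max(lo, 0), max = hi)
}

#' Approximate a skew-t calibration by a normal density
#'
#' Draws `n_samples` variates from the skew-t (Azzalini parameterization:
#' a skew-normal divided by the square root of an independent scaled
#' chi-squared with `df` degrees of freedom) and fits a normal by maximum
#' likelihood, i.e. the sample mean and (ML) standard deviation. The
#' sampling approach generalizes to any density and mirrors how skew-t
#' priors are ported to software that lacks them. Deterministic given
#' `seed`.
#'
#' @param spec A `calibration_spec` of form `skew_t`.
#' @param n_samples Number of Monte Carlo draws (default `1e6`).
#' @param seed Integer seed.
#' @return A `calibration_spec` of form `normal` on the same clade.
#' @export
approximate_normal <- function(spec, n_samples = 1e6, seed = 1L) {
  stopifnot(inherits(spec, "calibration_spec"))
  if (spec$form != "skew_t") {
    stop("approximate_normal expects a skew_t calibration", call. = FALSE)
  }
  p <- spec$par
  if (p$scale <= 0) stop("degenerate scale <= 0", call. = FALSE)
  if (n_samples < 2) stop("n_samples must be >= 2", call. = FALSE)
  draws <- withr::with_seed(seed,
    rskew_t(n_samples, p$location, p$scale, p$slant, p$df))
  m <- mean(draws)
  s <- sqrt(mean((draws - m)^2))
  calibration_spec(spec$clade, "normal", mean = m, sd = s)
}

#' Skew-t random variates
#'
#' Azzalini-style skew-t: `location + scale * Z / sqrt(W/df)` with `Z`
#' skew-normal with slant `alpha` (generated as
#' `delta*|U0| + sqrt(1-delta^2)*U1`, `delta = alpha/sqrt(1+alpha^2)`)
#' and `W ~ chi-squared(df)` independent.
#'
#' @param n Number of draws.
#' @param location,scale,slant,df Skew-t parameters (`scale > 0`, `df > 0`).
#' @return Numeric vector of length `n`.
#' @export
rskew_t <- function(n, location = 0, scale = 1, slant = 0, df = Inf) {
  stopifnot(scale > 0, df > 0)
  delta <- slant / sqrt(1 + slant^2)
  u0 <- stats::rnorm(n)
  u1 <- stats::rnorm(n)
  z <- delta * abs(u0) + sqrt(1 - delta^2) * u1
  w <- if (is.finite(df)) sqrt(stats::rchisq(n, df) / df) else 1
  location + scale * z / w
}

#' Fraction of calibrated nodes
#'
#' The calibration density of a dataset: number of calibrations divided by
#' the number of tree nodes. The denominator defaults to the internal-node
#' count of the pruned ingroup tree.
#'
#' @param n_calibrations Number of calibrations, `0 <= n_calibrations <= n_nodes`.
#' @param n_nodes Number of tree nodes, `> 0`.
#' @return A fraction in `[0, 1]`.
#' @export
calibration_density <- function(n_calibrations, n_nodes) {
  if (any(n_nodes <= 0)) stop("n_nodes must be > 0", call. = FALSE)
  if (any(n_calibrations < 0) || any(n_calibrations > n_nodes)) {
    stop("need 0 <= n_calibrations <= n_nodes", call. = FALSE)
  }
  n_calibrations / n_nodes
}

#' Read and write calibration tables
#'
#' TSV with columns `clade` (semicolon-joined taxa), `form`, and
#' `parameters` (comma-separated `key=value` list). One-sided bounds leave
#' the absent side out of the parameter list.
#'
#' @param specs List of `calibration_spec` objects.
#' @param path File path.
#' @return For the reader, a list of `calibration_spec`; the writer returns
#'   `specs` invisibly.
#' @export
write_calibrations <- function(specs, path) {
  if (inherits(specs, "calibration_spec")) specs <- list(specs)
  tab <- tibble::tibble(
    clade = vapply(specs, function(s) s$clade, character(1)),
    form = vapply(specs, function(s) s$form, character(1)),
    parameters = vapply(specs, function(s) {
      p <- s$par[!vapply(s$par, is.null, logical(1))]
      paste(names(p), vapply(p, function(v) sprintf("%.17g", v), character(1)),
            sep = "=", collapse = ",")
    }, character(1))
  )
  readr::write_tsv(tab, path, na = "")
  invisible(specs)
}

#' @rdname write_calibrations
#' @export
read_calibrations <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = "", progress = FALSE)
  purrr::pmap(tab, function(clade, form, parameters, ...) {
    par <- list()
    if (!is.na(parameters) && nzchar(parameters)) {
      kv <- strsplit(strsplit(parameters, ",")[[1]], "=")
      par <- stats::setNames(
        lapply(kv, function(x) as.numeric(x[2])),
        vapply(kv, `[`, character(1), 1))
    }
    do.call(calibration_spec, c(list(clade = clade, form = form), par))
  })
}
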