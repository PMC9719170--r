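#' Simulate a Yule (pure-birth) timetree
#'
#' Lineages split at exponential waiting times with total rate
#' `birth_rate * (current lineage count)`, the splitting lineage chosen
#' uniformly, until `n_taxa` lineages exist; one further waiting time sets
#' the present. Node ages are then rescaled linearly so the root age equals
#' `root_age` exactly. Deterministic given `seed`.
#'
#' @param n_taxa Number of leaves (`>= 2`).
#' @param birth_rate Speciation rate, events per time unit (`> 0`).
#' @param root_age Target root age in time units (`> 0`).
#' @param seed Optional integer seed.
#' @return An ultrametric binary `timetree` with leaf labels `t1..tn`.
#' @export
simulate_yule_timetree <- function(n_taxa, birth_rate = 1, root_age = 100,
                                   seed = NULL) {
  stopifnot(n_taxa >= 2, birth_rate > 0, root_age > 0)
  run <- function() {
    # node bookkeeping: internal nodes created in chronological (preorder)
    # order; active lineages are pending tips
    parent <- integer(0); time <- numeric(0); is_int <- logical(0)
    new_node <- function(p, t, internal) {
      parent[length(parent) + 1L] <<- p
      time[length(time) + 1L] <<- t
      is_int[length(is_int) + 1L] <<- internal
      length(parent)
    }
    t_now <- 0
    root <- new_node(0L, 0, TRUE)
    active <- c(new_node(root, NA, FALSE), new_node(root, NA, FALSE))
    while (length(active) < n_taxa) {
      k <- length(active)
      t_now <- t_now + stats::rexp(1, rate = birth_rate * k)
      i <- sample.int(k, 1)
      nd <- active[i]
      parent[nd] <- parent[nd]  # keep
      time[nd] <- t_now
      is_int[nd] <- TRUE
      active <- c(active[-i], new_node(nd, NA, FALSE), new_node(nd, NA, FALSE))
    }
    present <- t_now + stats::rexp(1, rate = birth_rate * n_taxa)
    time[is.na(time)] <- present
    list(parent = parent, time = time, is_int = is_int, present = present)
  }
  sim <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  is_int <- sim$is_int
  n_int <- sum(is_int)
  map <- integer(length(sim$parent))
  map[!is_int] <- seq_len(n_taxa)
  # creation order puts every internal parent before its internal children
  map[is_int] <- n_taxa + seq_len(n_int)
  has_parent <- sim$parent > 0L
  edge <- cbind(map[sim$parent[has_parent]], map[has_parent])
  ages_raw <- sim$present - sim$time
  scale <- root_age / ages_raw[which(is_int)[1]]
  ages <- numeric(n_taxa + n_int)
  ages[map] <- ages_raw * scale
  ages[seq_len(n_taxa)] <- 0
  phy <- structure(list(edge = edge,
                        edge.length = ages[edge[, 1]] - ages[edge[, 2]],
                        tip.label = paste0("t", seq_len(n_taxa)),
                        Nnode = n_int),
                   class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  timetree(phy, ages, method = "yule_simulation", dialect = "simulated")
}

#' Distort a timetree with multiplicative bias and node-age noise
#'
#' Models a dating method that is systematically biased and noisy: the root
#' age becomes `k * age * exp(e0 - sigma^2/2)` with `e0 ~ N(0, sigma^2)`
#' (the `-sigma^2/2` correction makes the root distortion mean-one, so the
#' expected regression slope against the original tree is close to `k`);
#' every other internal node, processed root-down, keeps its relative
#' position via `age' = parent_age' * r^g` where `r = age / parent_age` and
#' `g = exp(delta)`, `delta ~ N(0, sigma^2)`. Because `r` is in `[0, 1)` and
#' `g > 0`, parent-child age ordering is preserved for any `sigma` without
#' clipping. Leaves stay at age 0, topology is untouched, intervals are
#' dropped (attach fresh ones with [attach_intervals()]). Deterministic
#' given `seed`; with `sigma = 0` the output ages are exactly `k` times the
#' input ages.
#'
#' @param tree A `timetree`.
#' @param k Multiplicative age bias (`> 0`).
#' @param sigma Node-age noise SD on the log scale (`>= 0`).
#' @param seed Optional integer seed.
#' @return A `timetree` with method label recording `k` and `sigma`.
#' @export
perturb_timetree <- function(tree, k = 1, sigma = 0, seed = NULL) {
  stopifnot(k > 0, sigma >= 0)
  validate_timetree(tree)
  phy <- tree$phylo
  n_tip <- length(phy$tip.label)
  root <- n_tip + 1L
  ages <- tree$ages
  new_ages <- numeric(length(ages))
  if (sigma == 0) {
    new_ages <- k * ages
    new_ages[seq_len(n_tip)] <- 0
  } else {
    edge <- ape::reorder.phylo(phy, "cladewise")$edge  # parents before children
    draw <- function() {
      e0 <- stats::rnorm(1, 0, sigma)
      internal_children <- edge[edge[, 2] > n_tip, 2]
      deltas <- stats::rnorm(length(internal_children), 0, sigma)
      list(e0 = e0, deltas = stats::setNames(deltas, internal_children))
    }
    z <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    new_ages[root] <- k * ages[root] * exp(z$e0 - sigma^2 / 2)
    for (e in seq_len(nrow(edge))) {
      ch <- edge[e, 2]
      if (ch <= n_tip) next
      p <- edge[e, 1]
      r <- if (ages[p] > 0) ages[ch] / ages[p] else 0
      g <- exp(z$deltas[[as.character(ch)]])
      new_ages[ch] <- new_ages[p] * r^g
    }
  }
  out <- new_timetree(phy, new_ages,
                      method = sprintf("perturbed(k=%g,sigma=%g)", k, sigma),
                      dialect = "simulated")
  out$phylo <- edge_lengths_from_ages(out)
  validate_timetree(out)
}

#' Attach symmetric relative-width intervals to every internal node
#'
#' Each internal node with age `t` gets the interval
#' `(t * (1 - w), t * (1 + w))`, floored at 0; leaves get none. By the
#' normalized-width definition this makes every per-node U width exactly
#' `2w`.
#'
#' @param tree A `timetree`.
#' @param w Relative half-width per side (`>= 0`).
#' @param kind Interval kind tag.
#' @return The `timetree` with intervals replaced.
#' @export
attach_intervals <- function(tree, w, kind = "unspecified") {
  stopifnot(w >= 0, kind %in% interval_kinds())
  n_tip <- length(tree$phylo$tip.label)
  internal <- (n_tip + 1L):(n_tip + tree$phylo$Nnode)
  t <- tree$ages[internal]
  tree$intervals <- tibble::tibble(
    node = internal,
    lower = pmax(t * (1 - w), 0),
    upper = t * (1 + w),
    kind = kind
  )
  tree
}

#' Generate a collection of synthetic comparison studies
#'
#' Emulates a multi-study evaluation design: each dataset gets features
#' (taxa count, alignment length, calibration count) drawn from ranges
#' mirroring published phylogenomic studies, a reference "Bayesian"
#' timetree with credibility-style intervals, and a distorted "fast-method"
#' estimate tree with confidence-style intervals. The method bias of
#' dataset `d` is `k_d = k * exp(gamma * z_d)` where `z_d` is the
#' standardized target feature (log10 scale for the count features), so a
#' non-zero `gamma` plants a linear feature signal that the feature models
#' should recover. All randomness flows from `seed`: per-dataset sub-seeds
#' are drawn up front, so the collection is reproducible as a whole.
#'
#' @param n_datasets Number of studies (default 23).
#' @param taxa_range,site_range Ranges sampled log-uniformly
#'   (defaults 16–615 taxa, 5e3–4.25e6 sites).
#' @param calib_range Range of calibration counts, sampled uniformly and
#'   capped at the internal-node count.
#' @param birth_rate,root_age Yule simulation parameters.
#' @param k Baseline multiplicative bias of the fast method.
#' @param sigma Node-age noise SD.
#' @param w_ref,w_est Relative interval half-widths for the reference and
#'   estimate trees (defaults 0.32 and 0.10, giving normalized widths of
#'   0.64 and 0.20 — typical of Bayesian credibility intervals and of
#'   narrow bootstrap confidence intervals respectively).
#' @param feature_effect List `(target, gamma)`: which feature drives the
#'   bias and how strongly (default `gamma = 0`, no planted signal).
#' @param seed Optional integer seed.
#' @return A list with `datasets` (each `label`, `reference`, `estimate`,
#'   `k_true`) and `features` (a [dataset_features()] tibble with `k_true`).
#' @export
generate_study_collection <- function(n_datasets = 23,
                                      taxa_range = c(16, 615),
                                      site_range = c(5e3, 4.25e6),
                                      calib_range = c(1, 31),
                                      birth_rate = 1, root_age = 100,
                                      k = 1, sigma = 0.05,
                                      w_ref = 0.32, w_est = 0.10,
                                      feature_effect = list(target = "site_count",
                                                            gamma = 0),
                                      seed = NULL) {
  stopifnot(n_datasets >= 1, all(taxa_range >= 3), all(site_range > 0),
            all(calib_range >= 0), k > 0, sigma >= 0, w_ref >= 0, w_est >= 0)
  target <- match.arg(feature_effect$target,
                      c("site_count", "taxa_count", "calib_density"))
  gamma <- feature_effect$gamma %||% 0
  draw_setup <- function() {
    list(
      taxa = round(exp(stats::runif(n_datasets, log(taxa_range[1]),
                                    log(taxa_range[2])))),
      sites = round(exp(stats::runif(n_datasets, log(site_range[1]),
                                     log(site_range[2])))),
      calib = round(stats::runif(n_datasets, calib_range[1], calib_range[2])),
      sub_seeds = sample.int(.Machine$integer.max - 1L, 2L * n_datasets)
    )
  }
  su <- if (is.null(seed)) draw_setup() else withr::with_seed(seed, draw_setup())
  taxa <- pmax(su$taxa, 3)
  calib <- pmin(pmax(su$calib, 0), taxa - 1)
  feats <- dataset_features(
    label = sprintf("synth%02d", seq_len(n_datasets)),
    taxa_count = taxa, site_count = su$sites, calib_count = calib,
    n_nodes = taxa - 1)
  raw <- switch(target,
    site_count = log10(feats$site_count),
    taxa_count = log10(feats$taxa_count),
    calib_density = feats$calib_density)
  z <- if (stats::sd(raw) > 0) (raw - mean(raw)) / stats::sd(raw) else raw * 0
  k_d <- k * exp(gamma * z)
  datasets <- purrr::map(seq_len(n_datasets), function(d) {
    ref <- simulate_yule_timetree(taxa[d], birth_rate, root_age,
                                  seed = su$sub_seeds[2 * d - 1])
    ref$method <- "bayesian_reference"
    ref <- attach_intervals(ref, w_ref, "CrI")
    est <- perturb_timetree(ref, k = k_d[d], sigma = sigma,
                            seed = su$sub_seeds[2 * d])
    est$method <- "fast_estimate"
    est <- attach_intervals(est, w_est, "CI_analytic")
    list(label = feats$label[d], reference = ref, estimate = est,
         k_true = k_d[d])
  })
  feats$k_true <- k_d
  list(datasets = datasets, features = feats)
}
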