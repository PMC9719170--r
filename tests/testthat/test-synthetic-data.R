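test_that("Yule simulation satisfies structure and rescaling contracts", {
  two <- simulate_yule_timetree(2, seed = 1, root_age = 42)
  expect_equal(two$phylo$Nnode, 1)
  expect_equal(root_age(two), 42)

  big <- simulate_yule_timetree(50, seed = 2, root_age = 100)
  expect_equal(big$phylo$Nnode, 49)
  expect_true(all(big$ages[1:50] == 0))
  expect_equal(root_age(big), 100)
  expect_true(ape::is.binary.phylo(big$phylo))
  expect_error(simulate_yule_timetree(1), "n_taxa")
})

test_that("Yule node-age distribution matches an independent split-time oracle", {
  n <- 6; lambda <- 1; root_age <- 10; reps <- 2000
  pkg <- withr::with_seed(71, {
    t(vapply(seq_len(reps), function(i) {
      tt <- simulate_yule_timetree(n, lambda, root_age)
      sort(node_table(tt)$age)
    }, double(n - 1)))
  })
  orc <- withr::with_seed(72, {
    t(vapply(seq_len(reps), function(i) {
      sort(yule_ages_oracle(n, lambda, root_age))
    }, double(n - 1)))
  })
  se <- sqrt(apply(pkg, 2, stats::var) / reps + apply(orc, 2, stats::var) / reps)
  expect_true(all(abs(colMeans(pkg) - colMeans(orc)) < 2.5 * se))
})

test_that("perturbation identity, exact scaling, and topology preservation", {
  tt <- simulate_yule_timetree(20, seed = 3)
  expect_identical(perturb_timetree(tt, k = 1, sigma = 0)$ages, tt$ages)

  doubled <- perturb_timetree(tt, k = 2, sigma = 0)
  expect_identical(doubled$ages[21:39], 2 * tt$ages[21:39])
  cmp <- compare_dataset(tt, doubled)
  expect_equal(cmp$metrics$beta, 2)
  expect_equal(cmp$metrics$r2, 1)
  expect_equal(cmp$metrics$d_bar, 100)

  noisy <- perturb_timetree(tt, k = 1.5, sigma = 0.6, seed = 4)
  expect_identical(clade_index(noisy)$clade, clade_index(tt)$clade)
})

test_that("perturbation preserves parent-child ordering even at large sigma", {
  for (s in 1:20) {
    tt <- simulate_yule_timetree(12, seed = 100 + s)
    pt <- perturb_timetree(tt, k = exp(stats::runif(1, -1, 1)), sigma = 2,
                           seed = 200 + s)
    edge <- pt$phylo$edge
    expect_true(all(pt$ages[edge[, 1]] >= pt$ages[edge[, 2]]))
    expect_true(all(pt$ages[1:12] == 0))
  }
})

test_that("perturbation is deterministic per seed and varies across seeds", {
  tt <- simulate_yule_timetree(15, seed = 5)
  a <- perturb_timetree(tt, 1.2, 0.1, seed = 6)
  b <- perturb_timetree(tt, 1.2, 0.1, seed = 6)
  c <- perturb_timetree(tt, 1.2, 0.1, seed = 7)
  expect_identical(a$ages, b$ages)
  expect_false(identical(a$ages, c$ages))
  expect_identical(simulate_yule_timetree(15, seed = 5)$ages, tt$ages)
})

test_that("interval attachment gives exact widths and boundary coverage", {
  tt <- simulate_yule_timetree(10, seed = 8)
  w0 <- attach_intervals(tt, 0)
  expect_equal(w0$intervals$lower, w0$intervals$upper)
  expect_equal(compare_dataset(w0, tt)$metrics$coverage, 100)

  w2 <- attach_intervals(tt, 0.2, "HPD")
  expect_equal(uncertainty_widths(w2)$median_width, 0.4)
  expect_equal(unique(w2$intervals$kind), "HPD")
})

test_that("empirical coverage under perturbation matches a direct Monte-Carlo oracle", {
  # single-node view: the root of a 2-taxon tree isolates the root
  # distortion law k*exp(e0 - s^2/2); containment in (t(1-w), t(1+w)) has a
  # closed probability under the lognormal law
  w <- 0.2; sigma <- 0.05; reps <- 500
  cov_pipeline <- withr::with_seed(81, mean(vapply(seq_len(reps), function(i) {
    tt <- attach_intervals(simulate_yule_timetree(2, root_age = 50), w, "CrI")
    pt <- perturb_timetree(tt, k = 1, sigma = sigma)
    coverage_fraction(match_nodes(tt, pt))$coverage / 100
  }, double(1))))
  p_oracle <- stats::pnorm((log(1 + w) + sigma^2 / 2) / sigma) -
    stats::pnorm((log(1 - w) + sigma^2 / 2) / sigma)
  se <- sqrt(p_oracle * (1 - p_oracle) / reps)
  expect_lt(abs(cov_pipeline - p_oracle), max(2 * se, 0.01))
})

test_that("generated collections obey the timetree invariants", {
  specs <- withr::with_seed(91, data.frame(
    n = sample(3:15, 60, replace = TRUE),
    k = exp(stats::runif(60, -0.7, 0.7)),
    sigma = stats::runif(60, 0, 0.5),
    w = stats::runif(60, 0, 0.5)))
  for (i in seq_len(nrow(specs))) {
    tt <- simulate_yule_timetree(specs$n[i], seed = 1000 + i)
    pt <- attach_intervals(perturb_timetree(tt, specs$k[i], specs$sigma[i],
                                            seed = 2000 + i),
                           specs$w[i], "CI_analytic")
    expect_no_error(validate_timetree(tt))
    expect_no_error(validate_timetree(pt))
  }
})

test_that("study collections have the requested cardinality and planted biases", {
  coll <- generate_study_collection(n_datasets = 23, sigma = 0, seed = 10)
  expect_length(coll$datasets, 23)
  expect_equal(nrow(coll$features), 23)
  expect_true(all(coll$features$k_true == 1))   # gamma = 0: all biases equal k
  expect_true(all(coll$features$taxa_count >= 16 &
                    coll$features$taxa_count <= 615))
  expect_true(all(coll$features$calib_count <= coll$features$taxa_count - 1))
  expect_true(all(coll$features$calib_density >= 0 &
                    coll$features$calib_density <= 1))

  gam <- generate_study_collection(n_datasets = 8, k = 1.2, sigma = 0,
                                   feature_effect = list(target = "site_count",
                                                         gamma = 0.3),
                                   seed = 11)
  z <- scale(log10(gam$features$site_count))[, 1]
  expect_equal(gam$features$k_true, 1.2 * exp(0.3 * z), tolerance = 1e-12)
  # sigma = 0: the pipeline recovers each planted bias exactly
  betas <- vapply(gam$datasets, function(d) {
    compare_dataset(d$reference, d$estimate)$metrics$beta
  }, double(1))
  expect_equal(betas, gam$features$k_true, tolerance = 1e-12)
})

test_that("collections are reproducible from one seed", {
  a <- generate_study_collection(n_datasets = 3, seed = 12)
  b <- generate_study_collection(n_datasets = 3, seed = 12)
  expect_identical(a$features, b$features)
  expect_identical(a$datasets[[2]]$estimate$ages, b$datasets[[2]]$estimate$ages)
  c <- generate_study_collection(n_datasets = 3, seed = 13)
  expect_false(identical(a$features$site_count, c$features$site_count))
})
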