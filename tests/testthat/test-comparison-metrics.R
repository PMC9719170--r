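test_that("mean normalized difference matches hand evaluation", {
  expect_equal(mean_normalized_difference(make_matched(c(10, 20), c(10, 20)))$d_bar, 0)
  expect_equal(mean_normalized_difference(make_matched(c(10, 20), c(12, 18)))$d_bar, 15)
  tref <- c(3, 7, 11, 40)
  nd <- mean_normalized_difference(make_matched(tref, 1.5 * tref))
  expect_equal(nd$d_bar, 50)
  expect_equal(nd$per_node_delta, rep(0.5, 4))
})

test_that("age-floor exclusions apply to the normalized difference", {
  tab <- make_matched(c(1e-12, 10), c(5, 20))
  nd <- mean_normalized_difference(tab)
  expect_equal(nd$n_excluded, 1)
  expect_true(is.na(nd$per_node_delta[1]))
  expect_equal(nd$d_bar, 100)
  expect_error(mean_normalized_difference(make_matched(1e-20, 1)), "age_floor")
})

test_that("through-origin regression matches exact cases and the grid-search oracle", {
  r <- regression_through_origin(make_matched(c(1, 2, 3), c(2, 4, 6)))
  expect_equal(r$beta, 2)
  expect_equal(r$r2, 1)
  expect_equal(r$mse, 0)

  r2 <- regression_through_origin(make_matched(c(1, 2), c(2, 3)))
  expect_equal(r2$beta, 1.6)
  expect_equal(r2$mse, 0.1)
  expect_equal(r2$beta, grid_search_beta(c(1, 2), c(2, 3)), tolerance = 1e-6)

  expect_error(regression_through_origin(make_matched(1, 2)), "at least 2")
  expect_error(regression_through_origin(make_matched(c(0, 0), c(1, 2))),
               "zero")
})

test_that("coverage uses inclusive bounds and counts interval-less rows", {
  tab <- make_matched(c(12, 28), c(15, 25),
                      ref_lo = c(10, 26), ref_hi = c(20, 30))
  expect_equal(coverage_fraction(tab)$coverage, 50)

  exact <- make_matched(5, 5, ref_lo = 5, ref_hi = 5)
  exact <- dplyr::bind_rows(exact, exact)
  class(exact) <- c("matched_nodes", class(exact))
  expect_equal(coverage_fraction(exact)$coverage, 100)

  mixed <- make_matched(c(10, 20), c(10, 50),
                        ref_lo = c(9, NA), ref_hi = c(11, NA))
  cv <- coverage_fraction(mixed)
  expect_equal(cv$n_excluded, 1)
  expect_equal(cv$coverage, 100)
  expect_error(coverage_fraction(make_matched(1, 1)), "interval")
  # reverse direction reads the estimate's intervals
  rev <- make_matched(10, 12, est_lo = 9, est_hi = 11)
  expect_equal(coverage_fraction(rev, "ref_in_est")$coverage, 100)
})

test_that("normalized uncertainty widths follow the width formula", {
  tab <- make_matched(10, 10, ref_lo = 8, ref_hi = 12)
  expect_equal(uncertainty_widths(tab, "ref")$median_width, 0.4)

  t <- c(2, 5, 9, 40)
  tab2 <- make_matched(t, t, ref_lo = t * 0.8, ref_hi = t * 1.2)
  expect_equal(uncertainty_widths(tab2, "ref")$median_width, 0.4)

  tab3 <- make_matched(c(1e-12, 10), c(1e-12, 10),
                       ref_lo = c(0, 8), ref_hi = c(1, 12))
  w <- uncertainty_widths(tab3, "ref")
  expect_equal(w$n_excluded, 1)
  expect_equal(w$n_used, 1)
  # even count: mean of the two central order statistics
  tab4 <- make_matched(c(10, 10), c(10, 10),
                       ref_lo = c(9, 8), ref_hi = c(11, 12))
  expect_equal(uncertainty_widths(tab4, "ref")$median_width, 0.3)
})

test_that("compare_dataset composes the statistics deterministically", {
  tt <- simulate_yule_timetree(20, seed = 5) |> attach_intervals(0.2, "CrI")
  cmp <- compare_dataset(tt, tt)
  expect_equal(cmp$metrics$beta, 1)
  expect_equal(cmp$metrics$d_bar, 0)
  expect_equal(cmp$metrics$coverage, 100)
  expect_equal(cmp$metrics$mse, 0)

  est <- tt
  est$ages <- 2 * est$ages
  est$phylo <- chronocomp:::edge_lengths_from_ages(est)
  est <- attach_intervals(est, 0.2, "CI_analytic")
  cmp2 <- compare_dataset(tt, est)
  expect_equal(cmp2$metrics$beta, 2)
  expect_equal(cmp2$metrics$d_bar, 100)
})

test_that("a mixed 4-leaf fixture equals brute-force per-row recomputation", {
  ref <- read_chronogram_newick("(((A:2,B:2):3,C:5):5,D:10);") |>
    attach_intervals(0.3, "CrI")
  est <- read_chronogram_newick("(((A:2.6,B:2.6):2.8,C:5.4):6.6,D:12);") |>
    attach_intervals(0.12, "CI_analytic")
  cmp <- compare_dataset(ref, est)
  oracle <- brute_force_metrics(tidy(cmp))
  for (m in names(oracle)) {
    expect_equal(cmp$metrics[[m]], oracle[[m]], tolerance = 1e-12, label = m)
  }
})

test_that("scale equivariance and unit invariance hold", {
  ref <- simulate_yule_timetree(25, seed = 8) |> attach_intervals(0.25, "CrI")
  est <- perturb_timetree(ref, k = 1.2, sigma = 0.08, seed = 9) |>
    attach_intervals(0.1, "CI_analytic")
  base <- compare_dataset(ref, est)

  # multiply estimate ages by c: beta scales by c
  est2 <- est; est2$ages <- 3 * est2$ages
  est2$phylo <- chronocomp:::edge_lengths_from_ages(est2)
  est2 <- attach_intervals(est2, 0.1, "CI_analytic")
  expect_equal(compare_dataset(ref, est2)$metrics$beta,
               3 * base$metrics$beta, tolerance = 1e-12)

  # multiply ALL ages and intervals by c: everything but mse unchanged
  rescale <- function(tt, c) {
    tt$ages <- c * tt$ages
    tt$intervals$lower <- c * tt$intervals$lower
    tt$intervals$upper <- c * tt$intervals$upper
    tt$phylo <- chronocomp:::edge_lengths_from_ages(tt)
    tt
  }
  both <- compare_dataset(rescale(ref, 7), rescale(est, 7))
  expect_equal(both$metrics$beta, base$metrics$beta, tolerance = 1e-12)
  expect_equal(both$metrics$r2, base$metrics$r2, tolerance = 1e-12)
  expect_equal(both$metrics$d_bar, base$metrics$d_bar, tolerance = 1e-12)
  expect_equal(both$metrics$coverage, base$metrics$coverage)
  expect_equal(both$metrics$median_u_width_ref, base$metrics$median_u_width_ref,
               tolerance = 1e-12)
  expect_equal(both$metrics$mse, 49 * base$metrics$mse, tolerance = 1e-10)
})

test_that("coverage is monotone under interval widening and deltas are self-consistent", {
  ref <- simulate_yule_timetree(30, seed = 21)
  est <- perturb_timetree(ref, k = 1.1, sigma = 0.1, seed = 22)
  widths <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  cov <- vapply(widths, function(w) {
    compare_dataset(attach_intervals(ref, w, "CrI"), est)$metrics$coverage
  }, double(1))
  expect_true(all(diff(cov) >= 0))

  cmp <- compare_dataset(attach_intervals(ref, 0.2, "CrI"), est)
  nodes <- tidy(cmp)
  expect_equal(cmp$metrics$d_bar,
               mean(abs(nodes$delta_signed[!nodes$excluded_flag])) * 100)
})

test_that("glance returns one consistent row", {
  ref <- simulate_yule_timetree(10, seed = 2) |> attach_intervals(0.3, "CrI")
  cmp <- compare_dataset(ref, perturb_timetree(ref, 1.4, 0.02, seed = 3),
                         label = "ds1")
  g <- glance(cmp)
  expect_equal(nrow(g), 1)
  expect_equal(g$label, "ds1")
  expect_equal(g$n_used_delta + g$n_excluded_delta, g$n_nodes)
  expect_equal(g$n_used_coverage + g$n_excluded_coverage, g$n_nodes)
  expect_true(g$d_bar >= 0)
  expect_true(g$coverage >= 0 && g$coverage <= 100)
})
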