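test_that("smoothing grid enumeration matches direct expansion", {
  g <- smoothing_grid(100, 0.01, 10)
  expect_equal(g$values, c(100, 10, 1, 0.1, 0.01))
  expect_equal(length(smoothing_grid(1, 1, 10)), 1)
  expect_equal(length(smoothing_grid(1e17, 1e-19, 10)), 37)
  # strictly descending, first = cv_start, last >= cv_stop
  expect_true(all(diff(g$values) < 0))
  expect_equal(g$values[1], 100)
  expect_gte(utils::tail(g$values, 1), g$cv_stop * (1 - 1e-9))
  expect_error(smoothing_grid(1, 10), "cv_start")
  expect_error(smoothing_grid(1, 0.1, factor = 1), "factor")
  expect_error(smoothing_grid(1, -1), "cv_stop")
})

test_that("simulate run writes reproducible files and a usable manifest", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  c1 <- run_simulate(d1, seed = 5, n_datasets = 2, taxa_range = c(5, 12))
  c2 <- run_simulate(d2, seed = 5, n_datasets = 2, taxa_range = c(5, 12))
  f1 <- file.path(d1, "synth01", "reference.nex")
  f2 <- file.path(d2, "synth01", "reference.nex")
  expect_identical(readLines(f1), readLines(f2))   # byte-identical per seed
  expect_length(list.dirs(d1, recursive = FALSE), 2)
  manifest <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(manifest$seed, 5)
  expect_equal(manifest$n_datasets, 2)
  # trees on disk reload to the in-memory collection
  back <- read_chronogram_nexus(f1)
  expect_equal(node_table(back)$age,
               node_table(c1$datasets[[1]]$reference)$age)
})

test_that("simulate then compare round-trips exact scaling through files", {
  dir <- withr::local_tempdir()
  coll <- run_simulate(dir, seed = 9, n_datasets = 3, taxa_range = c(6, 15),
                       k = 1.2, sigma = 0)
  out <- run_compare(coll$config, out_dir = file.path(dir, "out"))
  expect_equal(nrow(out$results), 3)
  expect_equal(out$results$beta, rep(1.2, 3), tolerance = 1e-10)
  expect_equal(out$summary$mean_d_bar, 20, tolerance = 1e-8)
  expect_true(file.exists(file.path(dir, "out", "aggregate_summary.json")))
})

test_that("aggregate summary equals brute-force recomputation from emitted files", {
  dir <- withr::local_tempdir()
  coll <- run_simulate(dir, seed = 21, n_datasets = 5, taxa_range = c(6, 20),
                       k = 1.3, sigma = 0.05)
  out <- run_compare(coll$config, out_dir = file.path(dir, "out"))
  json_files <- list.files(file.path(dir, "out"), pattern = "_metrics\\.json$",
                           full.names = TRUE)
  expect_length(json_files, 5)
  per <- lapply(json_files, jsonlite::read_json)
  betas <- vapply(per, function(p) p$beta, double(1))
  dbars <- vapply(per, function(p) p$d_bar, double(1))
  expect_equal(out$summary$mean_beta, mean(betas), tolerance = 1e-12)
  expect_equal(out$summary$median_beta, stats::median(betas), tolerance = 1e-12)
  expect_equal(out$summary$mean_d_bar, mean(dbars), tolerance = 1e-12)
  # exclusion logs reconcile with per-node TSV flags
  tsvs <- list.files(file.path(dir, "out"), pattern = "_nodes\\.tsv$",
                     full.names = TRUE)
  flags <- vapply(tsvs, function(f) {
    sum(readr::read_tsv(f, show_col_types = FALSE)$excluded_flag)
  }, double(1))
  expect_equal(unname(flags),
               vapply(per, function(p) as.numeric(p$n_excluded_delta), double(1)))
})

test_that("median beta over known distortions follows order statistics", {
  ref <- simulate_yule_timetree(12, seed = 31) |> attach_intervals(0.3, "CrI")
  rows <- lapply(c(1, 1.5, 2), function(k) {
    est <- perturb_timetree(ref, k, 0)
    est$method <- "fast"   # one method across datasets
    glance(compare_dataset(ref, est, label = sprintf("k%g", k)))
  })
  summ <- aggregate_summary(dplyr::bind_rows(rows))
  expect_equal(summ$median_beta, 1.5)
  expect_equal(summ$mean_beta, 1.5)
})

test_that("dataset failures are recorded while the run continues", {
  ref <- simulate_yule_timetree(8, seed = 41) |> attach_intervals(0.2, "CrI")
  est <- perturb_timetree(ref, 1.1, 0, seed = 42)
  bad <- simulate_yule_timetree(8, seed = 43)   # different tip labels? same; force leaf mismatch
  bad$phylo$tip.label[1] <- "zzz"
  cfg <- list(
    list(label = "ok", reference = ref, estimate = est),
    list(label = "broken", reference = ref, estimate = bad))
  out <- run_compare(cfg)
  expect_equal(nrow(out$results), 1)
  expect_equal(out$failures$label, "broken")
  expect_match(out$failures$error, "leaf sets differ")
})

test_that("config files (YAML) drive the pipeline end to end with outgroups", {
  dir <- withr::local_tempdir()
  # 6-leaf trees with a 2-taxon outgroup grafted on
  ref <- read_chronogram_newick(
    "((((A:2,B:2):3,C:5):5,D:10):5,(O1:6,O2:6):9);")
  est <- read_chronogram_newick(
    "((((A:3,B:3):3,C:6):6,D:12):6,(O1:8,O2:8):10);")
  rp <- file.path(dir, "ref.nwk"); ep <- file.path(dir, "est.nwk")
  write_chronogram_newick(ref, rp); write_chronogram_newick(est, ep)
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(list(datasets = list(list(
    label = "ds1", reference = rp, estimate = ep,
    outgroup = c("O1", "O2")))), cfg_path)
  out <- run_compare(cfg_path)
  expect_equal(nrow(out$results), 1)
  expect_equal(out$results$n_nodes, 3)   # ingroup internal nodes only
  expect_equal(out$results$beta,
               regression_through_origin(
                 match_nodes(prune_outgroup(ref, c("O1", "O2")),
                             prune_outgroup(est, c("O1", "O2"))))$beta)
})

test_that("plot builders return ggplot objects", {
  ref <- simulate_yule_timetree(10, seed = 51) |> attach_intervals(0.2, "CrI")
  cmp <- compare_dataset(ref, perturb_timetree(ref, 1.2, 0.05, seed = 52),
                         calibrations = clade_index(ref)$clade[1])
  expect_s3_class(ggplot2::autoplot(cmp), "ggplot")
  rows <- dplyr::bind_rows(glance(cmp), glance(cmp))
  expect_s3_class(plot_metric_distribution(rows, "d_bar"), "ggplot")
})
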