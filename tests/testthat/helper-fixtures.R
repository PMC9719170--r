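# Shared fixtures and independent oracles for the test suite.

# matched-node table built directly (bypasses tree matching) for metric tests
make_matched <- function(t_ref, t_est,
                         ref_lo = NA_real_, ref_hi = NA_real_,
                         est_lo = NA_real_, est_hi = NA_real_,
                         calibrated = FALSE) {
  n <- length(t_ref)
  tab <- tibble::tibble(
    clade = sprintf("c%02d", seq_len(n)),
    t_ref = t_ref, ref_lo = rep_len(ref_lo, n), ref_hi = rep_len(ref_hi, n),
    ref_kind = NA_character_,
    t_est = t_est, est_lo = rep_len(est_lo, n), est_hi = rep_len(est_hi, n),
    est_kind = NA_character_,
    calibrated = rep_len(calibrated, n))
  class(tab) <- c("matched_nodes", class(tab))
  tab
}

# independent Yule age oracle: split times only, no tree construction.
# j lineages wait Exp(lambda * j); present set one waiting time after the
# (n-1)-th split; ages rescaled so the root sits at root_age.
yule_ages_oracle <- function(n_taxa, lambda, root_age) {
  s <- numeric(n_taxa - 1)
  s[1] <- 0
  t <- 0
  for (j in 2:(n_taxa - 1)) {
    t <- t + stats::rexp(1, lambda * j)
    s[j] <- t
  }
  present <- t + stats::rexp(1, lambda * n_taxa)
  root_age * (present - s) / present
}

# brute-force per-row recomputation of every comparison statistic
brute_force_metrics <- function(tab, age_floor = 1e-10) {
  n <- nrow(tab)
  deltas <- c(); covered <- c(); w_ref <- c(); w_est <- c()
  sxy <- 0; sxx <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + tab$t_ref[i] * tab$t_est[i]
    sxx <- sxx + tab$t_ref[i]^2
    if (tab$t_ref[i] >= age_floor) {
      deltas <- c(deltas, (tab$t_est[i] - tab$t_ref[i]) / tab$t_ref[i])
    }
    if (!is.na(tab$ref_lo[i]) && !is.na(tab$ref_hi[i])) {
      covered <- c(covered, tab$t_est[i] >= tab$ref_lo[i] &&
                             tab$t_est[i] <= tab$ref_hi[i])
      if (tab$t_ref[i] >= age_floor) {
        w_ref <- c(w_ref, (tab$ref_hi[i] - tab$ref_lo[i]) / tab$t_ref[i])
      }
    }
    if (!is.na(tab$est_lo[i]) && !is.na(tab$est_hi[i]) &&
        tab$t_est[i] >= age_floor) {
      w_est <- c(w_est, (tab$est_hi[i] - tab$est_lo[i]) / tab$t_est[i])
    }
  }
  beta <- sxy / sxx
  rss <- 0
  for (i in seq_len(n)) rss <- rss + (tab$t_est[i] - beta * tab$t_ref[i])^2
  list(beta = beta,
       r2 = 1 - rss / sum(tab$t_est^2),
       mse = rss / n,
       d_bar = mean(abs(deltas)) * 100,
       coverage = if (length(covered)) mean(covered) * 100 else NA_real_,
       median_u_width_ref = if (length(w_ref)) stats::median(w_ref) else NA_real_,
       median_u_width_est = if (length(w_est)) stats::median(w_est) else NA_real_)
}

# grid-search SSE minimizer over beta in [0, 5] at a fixed step
grid_search_beta <- function(x, y, step = 1e-6, upper = 5) {
  grid <- seq(0, upper, by = step)
  sse <- sum(y^2) - 2 * grid * sum(x * y) + grid^2 * sum(x^2)
  grid[which.min(sse)]
}

# 5-leaf ultrametric newick with distinct node ages (MRCA(A,B)=2,
# MRCA(A,B,C)=5, MRCA(D,E)=3, root=10)
nwk5 <- "(((A:2,B:2):3,C:5):5,(D:3,E:3):7);"

# annotated NEXUS fixture (BEAST MCC dialect): same topology as a 3-leaf
# tree with heights and one HPD annotation
nexus3 <- paste(
  "#NEXUS",
  "Begin taxa;",
  "\tDimensions ntax=3;",
  "\tTaxlabels A B C;",
  "End;",
  "Begin trees;",
  "\tTranslate",
  "\t\t1 A,",
  "\t\t2 B,",
  "\t\t3 C",
  "\t\t;",
  paste0("tree TREE1 = [&R] ((1[&height=0]:1.2,2[&height=0]:1.2)",
         "[&height=1.2,height_95%_HPD={0.9,1.6}]:1.8,3[&height=0]:3.0)",
         "[&height=3.0,height_95%_HPD={2.5,3.5}];"),
  "End;", sep = "\n")
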