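#' Index the clades of a timetree
#'
#' Every internal node is identified by its clade key: the sorted set of leaf
#' labels it subtends, joined by `";"`. Two nodes of one tree never share a
#' key; the root's key is the full leaf set. Polytomies are indexed as-is
#' (one entry per internal node actually present).
#'
#' @param tree A `timetree` or an [ape::phylo].
#' @return A tibble with columns `clade`, `node` (ape node number) and
#'   `n_leaves`, one row per internal node.
#' @export
clade_index <- function(tree) {
  phy <- if (inherits(tree, "timetree")) tree$phylo else tree
  labs <- phy$tip.label
  if (anyDuplicated(labs)) {
    stop("duplicate leaf labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "), call. = FALSE)
  }
  n_tip <- length(labs)
  n_all <- n_tip + phy$Nnode
  # postorder accumulation of sorted leaf-index sets
  ord <- sort(labs, method = "radix", index.return = TRUE)
  rank <- integer(n_tip); rank[ord$ix] <- seq_len(n_tip)
  sorted_labs <- ord$x
  sets <- vector("list", n_all)
  for (i in seq_len(n_tip)) sets[[i]] <- rank[i]
  edge <- ape::reorder.phylo(phy, "postorder")$edge
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  internal <- (n_tip + 1L):n_all
  keys <- vapply(internal, function(nd) {
    paste(sorted_labs[sort.int(sets[[nd]])], collapse = ";")
  }, character(1))
  tibble::tibble(clade = keys, node = internal,
                 n_leaves = lengths(sets[internal]))
}

# join a tree's ages/intervals onto its clade index
clade_table <- function(tree) {
  clade_index(tree) |>
    dplyr::mutate(age = tree$ages[.data$node]) |>
    dplyr::left_join(tree$intervals, by = "node")
}

#' Match homologous nodes between two timetrees
#'
#' Pairs internal nodes of a reference tree (typically the Bayesian
#' chronogram) and an estimate tree (a fast dating method) by clade key and
#' assembles the table every comparison statistic consumes. Both trees must
#' cover the identical leaf set.
#'
#' In `"strict"` mode (default; appropriate when both methods dated the same
#' fixed topology) any topological mismatch is an error naming the unmatched
#' clades. In `"intersect"` mode only shared clades are returned and the
#' number of unmatched clades per tree is recorded in attributes
#' `n_unmatched_ref` / `n_unmatched_est`.
#'
#' @param reference,estimate `timetree` objects over the same taxa.
#' @param mode `"strict"` or `"intersect"`.
#' @param calibrations Optional list of calibration specs (see
#'   [calibration_spec()]) or character vector of clade keys; matched rows
#'   whose clade is calibrated get `calibrated = TRUE`. Purely annotational:
#'   no statistic depends on it.
#' @param drop_root Drop the root row (the full-leaf-set clade)? Default
#'   `FALSE`: the ingroup root usually carries a calibration and the study
#'   design includes it.
#' @return A tibble of class `matched_nodes` with columns `clade`, `t_ref`,
#'   `ref_lo`, `ref_hi`, `ref_kind`, `t_est`, `est_lo`, `est_hi`, `est_kind`,
#'   `calibrated`, plus attributes `method_ref` and `method_est`.
#' @export
match_nodes <- function(reference, estimate, mode = c("strict", "intersect"),
                        calibrations = NULL, drop_root = FALSE) {
  mode <- match.arg(mode)
  ref_labs <- reference$phylo$tip.label
  est_labs <- estimate$phylo$tip.label
  only_ref <- setdiff(ref_labs, est_labs)
  only_est <- setdiff(est_labs, ref_labs)
  if (length(only_ref) || length(only_est)) {
    stop("leaf sets differ; only in reference: {",
         paste(only_ref, collapse = ", "), "}; only in estimate: {",
         paste(only_est, collapse = ", "), "}", call. = FALSE)
  }
  ref <- clade_table(reference)
  est <- clade_table(estimate)
  unmatched_ref <- setdiff(ref$clade, est$clade)
  unmatched_est <- setdiff(est$clade, ref$clade)
  if (mode == "strict" && (length(unmatched_ref) || length(unmatched_est))) {
    stop("topologies differ in strict mode; clades only in reference: {",
         paste(unmatched_ref, collapse = " | "), "}; only in estimate: {",
         paste(unmatched_est, collapse = " | "), "}", call. = FALSE)
  }
  tab <- dplyr::inner_join(
    ref |> dplyr::select("clade", t_ref = "age", ref_lo = "lower",
                         ref_hi = "upper", ref_kind = "kind"),
    est |> dplyr::select("clade", t_est = "age", est_lo = "lower",
                         est_hi = "upper", est_kind = "kind"),
    by = "clade") |>
    dplyr::arrange(.data$clade)
  calib_keys <- calibration_clades(calibrations)
  tab$calibrated <- tab$clade %in% calib_keys
  if (drop_root) {
    root_key <- paste(sort(ref_labs, method = "radix"), collapse = ";")
    tab <- tab[tab$clade != root_key, , drop = FALSE]
  }
  attr(tab, "method_ref") <- reference$method
  attr(tab, "method_est") <- estimate$method
  attr(tab, "n_unmatched_ref") <- length(unmatched_ref)
  attr(tab, "n_unmatched_est") <- length(unmatched_est)
  class(tab) <- c("matched_nodes", class(tab))
  tab
}

calibration_clades <- function(calibrations) {
  if (is.null(calibrations)) return(character())
  if (is.character(calibrations)) return(calibrations)
  vapply(calibrations, function(cs) {
    if (inherits(cs, "calibration_spec")) cs$clade else as.character(cs)
  }, character(1))
}

#' Serialize a matched-node table to TSV
#' @param table A `matched_nodes` tibble.
#' @param path Output path.
#' @return The table, invisibly.
#' @export
write_matched_nodes <- function(table, path) {
  readr::write_tsv(tibble::as_tibble(table), path, na = "")
  invisible(table)
}
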