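#' Time-calibrated phylogeny with node ages and uncertainty intervals
#'
#' A `timetree` wraps an [ape::phylo] tree together with node ages measured
#' backward from the present (extant leaves sit at age 0, in the time units of
#' the source chronogram, typically Ma) and optional per-node uncertainty
#' intervals (HPD/credibility/confidence intervals on node ages).
#'
#' @param phylo A rooted [ape::phylo] object.
#' @param ages Numeric vector of node ages indexed by ape node number
#'   (tips `1..n`, internals `n+1..n+Nnode`). Leaves must be at age 0 and
#'   every parent at least as old as its children.
#' @param intervals Optional tibble with columns `node`, `lower`, `upper`,
#'   `kind` giving an uncertainty interval per (internal) node. The point age
#'   may lie outside its interval: bootstrap confidence intervals observed in
#'   practice do not always contain the point estimate.
#' @param method Free-text label of the dating method that produced the tree.
#' @param dialect Source format tag (e.g. `"newick"`, `"nexus"`).
#'
#' @return An object of class `timetree`.
#' @export
timetree <- function(phylo, ages, intervals = NULL,
                     method = NA_character_, dialect = NA_character_) {
  x <- new_timetree(phylo, ages, intervals, method, dialect)
  validate_timetree(x)
}

new_timetree <- function(phylo, ages, intervals = NULL,
                         method = NA_character_, dialect = NA_character_) {
  if (is.null(intervals)) {
    intervals <- tibble::tibble(node = integer(), lower = double(),
                                upper = double(), kind = character())
  }
  structure(
    list(phylo = phylo, ages = as.numeric(ages),
         intervals = tibble::as_tibble(intervals),
         method = method, dialect = dialect),
    class = "timetree"
  )
}

interval_kinds <- function() {
  c("HPD", "CrI", "CI_analytic", "CI_bootstrap", "unspecified")
}

#' Validate timetree invariants
#'
#' Checks that leaf labels are unique, every leaf has age 0, every parent is
#' at least as old as its children, and all intervals satisfy
#' `lower <= upper` with finite non-negative endpoints.
#'
#' @param x A `timetree`.
#' @param eps_ultra Relative tolerance on the leaf-age-zero check.
#' @return `x`, invisibly unchanged, or an error.
#' @export
validate_timetree <- function(x, eps_ultra = 1e-6) {
  phy <- x$phylo
  if (!inherits(phy, "phylo")) stop("`phylo` must be an ape phylo object", call. = FALSE)
  n_tip <- length(phy$tip.label)
  # a chronogram is rooted by construction: exactly one node without a parent
  # (ape::is.rooted would reject a basal polytomy, which is legal input here)
  basal <- setdiff(phy$edge[, 1], phy$edge[, 2])
  if (length(basal) != 1) stop("timetree must have a single root", call. = FALSE)
  n_all <- n_tip + phy$Nnode
  if (length(x$ages) != n_all) {
    stop(sprintf("ages has length %d, expected %d (tips + internal nodes)",
                 length(x$ages), n_all), call. = FALSE)
  }
  if (anyDuplicated(phy$tip.label)) {
    dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
    stop("duplicate leaf labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  scale <- max(x$ages, 0)
  tip_ages <- x$ages[seq_len(n_tip)]
  if (any(abs(tip_ages) > eps_ultra * max(scale, 1e-300))) {
    stop("leaf ages must be 0 (tree not ultrametric in age space)", call. = FALSE)
  }
  parent <- phy$edge[, 1]; child <- phy$edge[, 2]
  bad <- which(x$ages[parent] < x$ages[child] - eps_ultra * max(scale, 1e-300))
  if (length(bad)) {
    stop(sprintf("age(parent) < age(child) on %d edge(s); first offending child node %d",
                 length(bad), child[bad[1]]), call. = FALSE)
  }
  iv <- x$intervals
  if (nrow(iv)) {
    if (any(!is.finite(iv$lower)) || any(!is.finite(iv$upper)) ||
        any(iv$lower < 0) || any(iv$upper < 0)) {
      stop("interval bounds must be finite and non-negative", call. = FALSE)
    }
    if (any(iv$lower > iv$upper)) {
      stop("interval lower > upper for node(s): ",
           paste(iv$node[iv$lower > iv$upper], collapse = ", "), call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.timetree <- function(x, ...) {
  n_tip <- length(x$phylo$tip.label)
  cat(sprintf("<timetree> %d leaves, %d internal nodes, root age %.6g\n",
              n_tip, x$phylo$Nnode, root_age(x)))
  if (!is.na(x$method)) cat("  method: ", x$method, "\n", sep = "")
  if (nrow(x$intervals)) {
    cat(sprintf("  intervals on %d node(s) (%s)\n", nrow(x$intervals),
                paste(unique(x$intervals$kind), collapse = ", ")))
  }
  invisible(x)
}

#' Root age of a timetree
#' @param x A `timetree`.
#' @return The age of the root node.
#' @export
root_age <- function(x) {
  x$ages[length(x$phylo$tip.label) + 1L]
}

#' Derive node ages from branch durations
#'
#' Given a rooted tree whose edge lengths are time durations, computes
#' `age(node) = root_age - depth(node)` where depth is the summed duration
#' from the root and the root age equals the (common) tip depth. The tree
#' must be ultrametric: the spread of tip depths relative to the maximum tip
#' depth may not exceed `eps_ultra`. Ages of leaves are set exactly to 0.
#'
#' @param phylo A rooted [ape::phylo] with complete non-negative edge lengths.
#' @param eps_ultra Relative ultrametricity tolerance (spread / max tip
#'   depth). The default `1e-6` absorbs the rounding noise that MCMC summary
#'   trees typically carry.
#' @param method,dialect Passed through to [timetree()].
#' @return A `timetree`.
#' @export
ages_from_branch_lengths <- function(phylo, eps_ultra = 1e-6,
                                     method = NA_character_,
                                     dialect = NA_character_) {
  if (is.null(phylo$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (anyNA(phylo$edge.length)) {
    bad <- which(is.na(phylo$edge.length))[1]
    stop(sprintf("missing branch length on edge %d (%d -> %d)",
                 bad, phylo$edge[bad, 1], phylo$edge[bad, 2]), call. = FALSE)
  }
  if (any(phylo$edge.length < 0)) {
    stop("negative branch length(s): durations must be >= 0", call. = FALSE)
  }
  depth <- ape::node.depth.edgelength(phylo)
  n_tip <- length(phylo$tip.label)
  tip_depth <- depth[seq_len(n_tip)]
  dmax <- max(tip_depth)
  spread <- if (dmax > 0) (dmax - min(tip_depth)) / dmax else 0
  if (spread > eps_ultra) {
    stop(sprintf(paste0("tree is not ultrametric: relative tip-depth spread ",
                        "%.3g exceeds eps_ultra = %.3g"), spread, eps_ultra),
         call. = FALSE)
  }
  ages <- dmax - depth
  ages[ages < 0] <- 0
  ages[seq_len(n_tip)] <- 0
  timetree(phylo, ages, method = method, dialect = dialect)
}

# Rewrite edge lengths of the wrapped phylo from the stored ages.
edge_lengths_from_ages <- function(x) {
  phy <- x$phylo
  len <- x$ages[phy$edge[, 1]] - x$ages[phy$edge[, 2]]
  len[len < 0] <- 0
  phy$edge.length <- len
  phy
}

#' Tabulate internal nodes of a timetree
#'
#' One row per internal node with its clade key (sorted leaf labels joined by
#' `";"`), age, and interval bounds (NA where absent), in deterministic order
#' (sorted clade keys).
#'
#' @param tree A `timetree`.
#' @return A tibble with columns `clade`, `age`, `lower`, `upper`, `kind`.
#' @export
node_table <- function(tree) {
  idx <- clade_index(tree)
  n_tip <- length(tree$phylo$tip.label)
  out <- idx |>
    dplyr::mutate(age = tree$ages[.data$node]) |>
    dplyr::left_join(tree$intervals, by = "node") |>
    dplyr::arrange(.data$clade) |>
    dplyr::select("clade", "age", "lower", "upper", "kind")
  out
}

#' @export
#' @method as_tibble timetree
as_tibble.timetree <- function(x, ...) node_table(x)

#' Write and read internal-node tables as TSV
#'
#' `write_node_table()` serializes [node_table()] output (tab-delimited,
#' UTF-8, `.` decimal separator, header row); `read_node_table()` reads it
#' back. Absent interval bounds are empty fields.
#'
#' @param tree A `timetree` (or a node-table tibble).
#' @param path File path; `write_node_table(NULL)` returns the tibble.
#' @return The node-table tibble, invisibly for the writer.
#' @export
write_node_table <- function(tree, path = NULL) {
  tab <- if (inherits(tree, "timetree")) node_table(tree) else tibble::as_tibble(tree)
  if (!is.null(path)) readr::write_tsv(tab, path, na = "")
  invisible(tab)
}

#' @rdname write_node_table
#' @export
read_node_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    clade = readr::col_character(), age = readr::col_double(),
    lower = readr::col_double(), upper = readr::col_double(),
    kind = readr::col_character()), na = "", progress = FALSE)
}
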