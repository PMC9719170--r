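#' Remove a monophyletic outgroup from a timetree
#'
#' Drops the outgroup taxa and re-roots the tree at the ingroup's most recent
#' common ancestor. Ages and uncertainty intervals of all retained nodes are
#' unchanged: ages are measured backward from the present, so removing taxa
#' does not move any remaining divergence. This mirrors the usual protocol in
#' dating studies where the outgroup is used only to root the ingroup and is
#' stripped from the estimated timetrees before comparison.
#'
#' @param tree A `timetree`.
#' @param outgroup_taxa Character vector of leaf labels. Must be a proper,
#'   monophyletic subset of the leaves. An empty set returns the tree
#'   unchanged.
#' @return A `timetree` over the ingroup leaves only.
#' @export
prune_outgroup <- function(tree, outgroup_taxa) {
  outgroup_taxa <- normalize_taxon(as.character(outgroup_taxa))
  outgroup_taxa <- outgroup_taxa[nzchar(outgroup_taxa)]
  if (!length(outgroup_taxa)) return(tree)
  labs <- tree$phylo$tip.label
  missing <- setdiff(outgroup_taxa, labs)
  if (length(missing)) {
    stop("outgroup taxa not in tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(outgroup_taxa) >= length(labs) - 1) {
    stop("outgroup must leave at least two ingroup taxa", call. = FALSE)
  }
  if (length(outgroup_taxa) > 1 &&
      !ape::is.monophyletic(tree$phylo, outgroup_taxa)) {
    stop("outgroup is not monophyletic: {",
         paste(sort(outgroup_taxa), collapse = ", "), "}", call. = FALSE)
  }
  old <- clade_table(tree)
  phy2 <- ape::drop.tip(tree$phylo, outgroup_taxa, collapse.singles = TRUE)
  idx2 <- clade_index(phy2)
  hit <- match(idx2$clade, old$clade)
  if (anyNA(hit)) {
    stop("internal error: pruned clade missing from original tree", call. = FALSE)
  }
  n_tip2 <- length(phy2$tip.label)
  ages2 <- numeric(n_tip2 + phy2$Nnode)
  ages2[idx2$node] <- old$age[hit]
  iv_rows <- which(!is.na(old$lower[hit]))
  intervals2 <- tibble::tibble(
    node = idx2$node[iv_rows],
    lower = old$lower[hit][iv_rows],
    upper = old$upper[hit][iv_rows],
    kind = old$kind[hit][iv_rows]
  )
  out <- new_timetree(phy2, ages2, intervals2,
                      method = tree$method, dialect = tree$dialect)
  out$phylo <- edge_lengths_from_ages(out)
  validate_timetree(out)
}
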