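#' Read a chronogram from Newick text
#'
#' Parses a Newick tree whose branch lengths are time durations and converts
#' it to a `timetree` (node ages backward from the present). The tree must be
#' ultrametric within `eps_ultra`.
#'
#' @param x A file path or a literal Newick string.
#' @param eps_ultra Relative ultrametricity tolerance, see
#'   [ages_from_branch_lengths()].
#' @param method Method label to attach.
#' @return A `timetree` with dialect `"newick"`.
#' @export
read_chronogram_newick <- function(x, eps_ultra = 1e-6, method = NA_character_) {
  text <- slurp_text(x)
  check_newick_syntax(text)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop("malformed Newick input", call. = FALSE)
  if (inherits(phy, "multiPhylo")) phy <- phy[[1]]
  ages_from_branch_lengths(phy, eps_ultra = eps_ultra,
                           method = method, dialect = "newick")
}

#' Write a chronogram as Newick
#'
#' Branch lengths are emitted as age differences at `digits` significant
#' digits (default 17, which round-trips doubles exactly).
#'
#' @param tree A `timetree`.
#' @param path Output path, or `NULL` to return the Newick string.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_chronogram_newick <- function(tree, path = NULL, digits = 17) {
  phy <- edge_lengths_from_ages(tree)
  txt <- ape::write.tree(phy, digits = digits)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

slurp_text <- function(x) {
  stopifnot(is.character(x), length(x) >= 1)
  if (length(x) == 1 && !grepl("[(;\n]", x) && file.exists(x)) {
    return(paste(readLines(x, warn = FALSE), collapse = "\n"))
  }
  paste(x, collapse = "\n")
}

# cheap structural check so malformed input fails with a position
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("malformed Newick: unbalanced ')' at position %d", i),
             call. = FALSE)
      }
    }
  }
  if (depth != 0L) {
    stop(sprintf("malformed Newick: %d unclosed '(' at end of input", depth),
         call. = FALSE)
  }
  if (!grepl(";", text, fixed = TRUE)) {
    stop(sprintf("malformed Newick: missing ';' terminator at position %d",
                 nchar(text)), call. = FALSE)
  }
  invisible(TRUE)
}
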