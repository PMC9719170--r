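#' Read a chronogram from NEXUS with node annotations
#'
#' Parses a NEXUS TREES block whose tree carries BEAST/FigTree-style
#' bracketed node metacomments, e.g. `[&height=1.2,height_95%_HPD={0.9,1.6}]`
#' (BEAST MCC trees) or `[&95%={10.1, 12.3}]` (MCMCTree output opened in
#' FigTree). The first annotation key from `interval_keys` found on a node
#' populates its uncertainty interval; nodes without any listed key simply
#' get no interval. Translate tables are honored and taxon names are
#' compared after quote/whitespace normalization.
#'
#' @param x A file path or literal NEXUS text.
#' @param interval_keys Named character vector in priority order: values are
#'   annotation keys, names the interval kind recorded for each
#'   (`HPD`, `CrI`, `CI_analytic`, `CI_bootstrap`, `unspecified`).
#' @param age_source `"height"` (default): node ages are taken from the
#'   `height` annotation where present, falling back to branch-length depth;
#'   `"depth"`: ages always derived from branch lengths. When both are
#'   available and disagree by more than `eps_ultra` (relative to the root
#'   age) a warning reports the largest discrepancy.
#' @param eps_ultra Relative ultrametricity / discrepancy tolerance.
#' @param method Method label to attach.
#' @return A `timetree` with dialect `"nexus"`.
#' @export
read_chronogram_nexus <- function(x,
                                  interval_keys = default_interval_keys(),
                                  age_source = c("height", "depth"),
                                  eps_ultra = 1e-6,
                                  method = NA_character_) {
  age_source <- match.arg(age_source)
  text <- slurp_text(x)
  if (is.null(names(interval_keys))) {
    names(interval_keys) <- rep("unspecified", length(interval_keys))
  }
  trees_block <- extract_trees_block(text)
  translate <- parse_translate_table(trees_block)
  newick <- extract_first_tree(trees_block)
  parsed <- parse_annotated_newick(newick)
  phy <- parsed$phylo
  phy$tip.label <- normalize_taxon(phy$tip.label)
  if (length(translate)) {
    hit <- match(phy$tip.label, names(translate))
    phy$tip.label <- ifelse(is.na(hit), phy$tip.label, unname(translate)[hit])
  }
  base <- ages_from_branch_lengths(phy, eps_ultra = eps_ultra,
                                   method = method, dialect = "nexus")
  ann <- lapply(parsed$comments, parse_annotations)
  ages <- base$ages
  if (age_source == "height") {
    heights <- vapply(ann, function(a) {
      h <- a[["height"]]
      if (is.null(h)) NA_real_ else h[1]
    }, double(1))
    has_h <- !is.na(heights)
    if (any(has_h)) {
      diff <- abs(heights[has_h] - ages[has_h])
      scale <- max(ages, 1e-300)
      if (max(diff) / scale > eps_ultra) {
        warning(sprintf(paste0("height annotations disagree with branch-length ",
                               "depths (max relative discrepancy %.3g)"),
                        max(diff) / scale), call. = FALSE)
      }
      ages[has_h] <- heights[has_h]
    }
    n_tip <- length(phy$tip.label)
    ages[seq_len(n_tip)] <- 0
  }
  iv <- extract_intervals(ann, interval_keys, phy, ages)
  timetree(phy, ages, intervals = iv, method = method, dialect = "nexus")
}

#' @rdname read_chronogram_nexus
#' @export
default_interval_keys <- function() {
  c(HPD = "height_95%_HPD", CrI = "95%", CI_analytic = "CI")
}

extract_trees_block <- function(text) {
  m <- regexpr("(?is)begin\\s+trees\\s*;.*?\\bend\\s*;", text, perl = TRUE)
  if (m == -1) stop("no TREES block found in NEXUS input", call. = FALSE)
  regmatches(text, m)
}

parse_translate_table <- function(block) {
  m <- regexpr("(?is)\\btranslate\\b(.*?);", block, perl = TRUE)
  if (m == -1) return(character())
  body <- sub("(?is)\\btranslate\\b", "", regmatches(block, m), perl = TRUE)
  body <- sub(";\\s*$", "", body)
  entries <- strsplit(body, ",")[[1]]
  entries <- trimws(entries)
  entries <- entries[nzchar(entries)]
  out <- character(0)
  for (e in entries) {
    parts <- regmatches(e, regexec("^(\\S+)\\s+(.+)$", e))[[1]]
    if (length(parts) == 3) out[parts[2]] <- normalize_taxon(parts[3])
  }
  out
}

extract_first_tree <- function(block) {
  m <- regexpr("(?is)\\btree\\b[^=]*=(.*?);", block, perl = TRUE)
  if (m == -1) stop("no tree statement found in TREES block", call. = FALSE)
  newick <- sub("(?is)^\\btree\\b[^=]*=", "", regmatches(block, m), perl = TRUE)
  newick <- sub("^\\s*\\[&[RU]\\]\\s*", "", newick)
  paste0(trimws(newick))
}

normalize_taxon <- function(x) {
  x <- trimws(x)
  gsub("^['\"]|['\"]$", "", x)
}

# --- comment-aware Newick parsing ---------------------------------------

# Returns list(phylo, comments): `comments` holds the concatenated [&...]
# metacomment bodies per ape node number ("" when absent).
parse_annotated_newick <- function(text) {
  text <- trimws(text)
  s <- strsplit(text, "", fixed = TRUE)[[1]]
  st <- new.env(parent = emptyenv())
  st$pos <- 1L
  st$n <- length(s)
  st$parent <- integer(0)
  st$label <- character(0)
  st$length <- numeric(0)
  st$comment <- character(0)
  st$children <- integer(0)   # child count per node

  peek <- function() if (st$pos <= st$n) s[st$pos] else ""
  adv <- function() st$pos <- st$pos + 1L
  skip_ws <- function() while (st$pos <= st$n && grepl("^\\s$", s[st$pos])) adv()
  err <- function(msg) stop(sprintf("malformed tree string at position %d: %s",
                                    st$pos, msg), call. = FALSE)

  read_comments <- function() {
    out <- character(0)
    skip_ws()
    while (peek() == "[") {
      start <- st$pos
      depth <- 0L
      repeat {
        if (st$pos > st$n) err("unterminated comment")
        if (s[st$pos] == "[") depth <- depth + 1L
        if (s[st$pos] == "]") {
          depth <- depth - 1L
          if (depth == 0L) break
        }
        adv()
      }
      body <- paste(s[(start + 1L):(st$pos - 1L)], collapse = "")
      adv()
      if (startsWith(body, "&")) out <- c(out, substring(body, 2))
      skip_ws()
    }
    paste(out, collapse = ",")
  }

  read_name <- function() {
    skip_ws()
    if (peek() %in% c("'", '"')) {
      q <- peek(); adv()
      start <- st$pos
      while (st$pos <= st$n && s[st$pos] != q) adv()
      if (st$pos > st$n) err("unterminated quoted label")
      nm <- paste(s[start:(st$pos - 1L)], collapse = "")
      adv()
      return(nm)
    }
    start <- st$pos
    while (st$pos <= st$n && !(s[st$pos] %in% c("(", ")", ",", ":", ";", "[")) &&
           !grepl("^\\s$", s[st$pos])) adv()
    if (st$pos == start) return("")
    paste(s[start:(st$pos - 1L)], collapse = "")
  }

  read_number <- function() {
    skip_ws()
    start <- st$pos
    while (st$pos <= st$n && grepl("^[-+0-9.eE]$", s[st$pos])) adv()
    if (st$pos == start) err("expected a branch length")
    val <- suppressWarnings(as.numeric(paste(s[start:(st$pos - 1L)], collapse = "")))
    if (is.na(val)) err("unreadable branch length")
    val
  }

  new_node <- function(parent) {
    id <- length(st$parent) + 1L
    st$parent[id] <- parent
    st$label[id] <- ""
    st$length[id] <- NA_real_
    st$comment[id] <- ""
    st$children[id] <- 0L
    if (parent > 0L) st$children[parent] <- st$children[parent] + 1L
    id
  }

  parse_clade <- function(parent) {
    skip_ws()
    id <- new_node(parent)
    if (peek() == "(") {
      adv()
      repeat {
        parse_clade(id)
        skip_ws()
        if (peek() == ",") { adv(); next }
        if (peek() == ")") { adv(); break }
        err("expected ',' or ')'")
      }
      st$label[id] <- read_name()
    } else {
      st$label[id] <- read_name()
      if (!nzchar(st$label[id])) err("expected a taxon label")
    }
    cm <- read_comments()
    skip_ws()
    if (peek() == ":") {
      adv()
      cm2 <- read_comments()
      st$length[id] <- read_number()
      cm3 <- read_comments()
      cm <- paste(c(cm, cm2, cm3)[nzchar(c(cm, cm2, cm3))], collapse = ",")
    }
    st$comment[id] <- cm
    id
  }

  parse_clade(0L)
  skip_ws()
  if (peek() != ";" && peek() != "") err("expected ';' terminator")

  is_tip <- st$children == 0L
  n_tip <- sum(is_tip)
  n_int <- sum(!is_tip)
  if (n_tip < 2) err("fewer than two leaves")
  map <- integer(length(st$parent))
  map[is_tip] <- seq_len(n_tip)
  map[!is_tip] <- n_tip + seq_len(n_int)   # creation order is preorder
  has_parent <- st$parent > 0L
  edge <- cbind(map[st$parent[has_parent]], map[has_parent])
  edge.length <- st$length[has_parent]
  if (anyNA(edge.length)) {
    bad <- which(is.na(edge.length))[1]
    stop(sprintf("missing branch length on edge to node %d", edge[bad, 2]),
         call. = FALSE)
  }
  phy <- structure(list(edge = edge, edge.length = edge.length,
                        tip.label = st$label[is_tip], Nnode = n_int),
                   class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  comments <- character(n_tip + n_int)
  comments[map] <- st$comment
  list(phylo = phy, comments = comments)
}

# "height=1.2,height_95%_HPD={0.9,1.6}" -> named list of numeric vectors /
# character scalars
parse_annotations <- function(comment) {
  if (!nzchar(comment)) return(list())
  chars <- strsplit(comment, "", fixed = TRUE)[[1]]
  parts <- character(0)
  depth <- 0L; start <- 1L
  for (i in seq_along(chars)) {
    if (chars[i] %in% c("{", "[")) depth <- depth + 1L
    if (chars[i] %in% c("}", "]")) depth <- depth - 1L
    if (chars[i] == "," && depth == 0L) {
      parts <- c(parts, paste(chars[start:(i - 1L)], collapse = ""))
      start <- i + 1L
    }
  }
  parts <- c(parts, paste(chars[start:length(chars)], collapse = ""))
  out <- list()
  for (p in parts) {
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq == -1) next
    key <- trimws(substr(p, 1, eq - 1))
    val <- trimws(substr(p, eq + 1, nchar(p)))
    if (startsWith(val, "{")) {
      inner <- sub("^\\{", "", sub("\\}$", "", val))
      num <- suppressWarnings(as.numeric(trimws(strsplit(inner, ",")[[1]])))
      out[[key]] <- num
    } else {
      num <- suppressWarnings(as.numeric(val))
      out[[key]] <- if (is.na(num)) gsub("^\"|\"$", "", val) else num
    }
  }
  out
}

extract_intervals <- function(ann, interval_keys, phy, ages) {
  rows <- list()
  for (nd in seq_along(ann)) {
    a <- ann[[nd]]
    if (!length(a)) next
    for (j in seq_along(interval_keys)) {
      key <- interval_keys[[j]]
      if (!is.null(a[[key]]) && length(a[[key]]) >= 2 &&
          all(is.finite(a[[key]][1:2]))) {
        lo <- a[[key]][1]; hi <- a[[key]][2]
        kind <- names(interval_keys)[j]
        if (!is.null(a[["interval_kind"]]) &&
            a[["interval_kind"]] %in% interval_kinds()) {
          kind <- a[["interval_kind"]]
        }
        if (lo > hi) {
          key_str <- clade_of_node(phy, nd)
          stop(sprintf("interval lower > upper on clade {%s}", key_str),
               call. = FALSE)
        }
        rows[[length(rows) + 1L]] <-
          tibble::tibble(node = nd, lower = lo, upper = hi, kind = kind)
        break
      }
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(node = integer(), lower = double(),
                          upper = double(), kind = character()))
  }
  dplyr::bind_rows(rows)
}

clade_of_node <- function(phy, nd) {
  n_tip <- length(phy$tip.label)
  if (nd <= n_tip) return(phy$tip.label[nd])
  tips <- ape::extract.clade(phy, nd)$tip.label
  paste(sort(tips, method = "radix"), collapse = ";")
}

#' Write a chronogram as annotated NEXUS
#'
#' Emits a taxa block, a translate table, and one tree whose nodes carry
#' `height` annotations plus uncertainty intervals under the annotation key
#' conventional for their kind (`height_95%_HPD` for HPD, `95%` for CrI,
#' `CI` otherwise, with an explicit `interval_kind` tag so round-trips
#' preserve the kind).
#'
#' @param tree A `timetree`.
#' @param path Output path, or `NULL` to return the NEXUS text.
#' @param digits Significant digits for ages and branch lengths (default 17,
#'   which round-trips doubles exactly).
#' @return The NEXUS text (invisibly when written to a file).
#' @export
write_chronogram_nexus <- function(tree, path = NULL, digits = 17) {
  phy <- tree$phylo
  n_tip <- length(phy$tip.label)
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  iv <- tree$intervals
  iv_key <- c(HPD = "height_95%_HPD", CrI = "95%", CI_analytic = "CI",
              CI_bootstrap = "CI", unspecified = "CI")
  node_ann <- function(nd) {
    parts <- c(sprintf("height=%s", fmt(tree$ages[nd])))
    hit <- which(iv$node == nd)
    if (length(hit)) {
      k <- iv$kind[hit[1]]
      if (is.na(k) || !k %in% names(iv_key)) k <- "unspecified"
      parts <- c(parts,
                 sprintf("%s={%s,%s}", iv_key[[k]],
                         fmt(iv$lower[hit[1]]), fmt(iv$upper[hit[1]])),
                 sprintf("interval_kind=%s", k))
    }
    sprintf("[&%s]", paste(parts, collapse = ","))
  }
  children <- split(phy$edge[, 2], phy$edge[, 1])
  build <- function(nd) {
    kids <- children[[as.character(nd)]]
    body <- if (is.null(kids)) {
      as.character(match(nd, seq_len(n_tip)))
    } else {
      sprintf("(%s)", paste(vapply(kids, build, character(1)), collapse = ","))
    }
    ann <- node_ann(nd)
    parent <- phy$edge[phy$edge[, 2] == nd, 1]
    if (length(parent)) {
      len <- tree$ages[parent] - tree$ages[nd]
      sprintf("%s%s:%s", body, ann, fmt(max(len, 0)))
    } else {
      sprintf("%s%s", body, ann)
    }
  }
  root <- n_tip + 1L
  lines <- c(
    "#NEXUS",
    "Begin taxa;",
    sprintf("\tDimensions ntax=%d;", n_tip),
    "\tTaxlabels",
    sprintf("\t\t%s", phy$tip.label),
    "\t\t;",
    "End;",
    "Begin trees;",
    "\tTranslate",
    sprintf("\t\t%d %s%s", seq_len(n_tip), phy$tip.label,
            c(rep(",", n_tip - 1), "")),
    "\t\t;",
    sprintf("tree TREE1 = [&R] %s;", build(root)),
    "End;"
  )
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
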