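#' Time-calibrated trees (chronograms)
#'
#' A chronogram is a rooted ultrametric phylogeny whose node heights are
#' absolute ages in millions of years (Ma). Node ages, not branch lengths, are
#' the primary representation here: every tip sits at age 0, every internal
#' node is strictly older than its children, and the branch subtending a node
#' has length `age(parent) - age(node)` in Myr. Objects are `ape::phylo` trees
#' with class `chronogram` and a `node_age` attribute, so the whole `ape`
#' toolbox keeps working on them.
#'
#' @name chronogram
NULL

.ULTRA_RTOL <- 1e-9

#' Construct and validate a chronogram from a phylo object
#'
#' Derives node ages from the branch lengths of a rooted `phylo` tree and
#' checks the chronogram invariants: strictly positive branch lengths and
#' root-to-tip path sums equal for every tip (ultrametricity) within
#' `1e-9` relative to the root age.
#'
#' @param phy A rooted `ape::phylo` with branch lengths, or a newick string.
#' @param age_source Optional character vector (one per internal node, in
#'   node-number order) recording where each age came from, e.g. `"reported"`
#'   or `"interpolated_synthetic"`. Kept as an attribute and surfaced by
#'   [node_ages()].
#' @return A `chronogram` object (also of class `phylo`).
#' @examples
#' as_chronogram(ape::read.tree(text = "((A:5,B:5):5,C:10);"))
#' @export
as_chronogram <- function(phy, age_source = NULL) {
  if (is.character(phy)) phy <- ape::read.tree(text = phy)
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length)) {
    stop("tree has no branch lengths; use build_chronogram() to supply ages",
         call. = FALSE)
  }
  if (!ape::is.rooted(phy)) stop("chronograms must be rooted", call. = FALSE)
  n_tip <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)
  root_age <- max(depth)
  age <- root_age - depth
  tol <- .ULTRA_RTOL * max(root_age, 1)
  bad <- which(abs(age[seq_len(n_tip)]) > tol)
  if (length(bad) > 0) {
    stop(sprintf("tree is not ultrametric: tip '%s' ends %.3g Myr from the present",
                 phy$tip.label[bad[1]], age[bad[1]]), call. = FALSE)
  }
  age[seq_len(n_tip)] <- 0
  if (any(phy$edge.length <= 0)) {
    e <- which(phy$edge.length <= 0)[1]
    stop(sprintf("non-positive branch length on the edge above node %d",
                 phy$edge[e, 2]), call. = FALSE)
  }
  phy$edge.length <- age[phy$edge[, 1]] - age[phy$edge[, 2]]
  attr(phy, "node_age") <- age
  if (!is.null(age_source)) attr(phy, "age_source") <- age_source
  class(phy) <- c("chronogram", "phylo")
  phy
}

#' Read a chronogram from newick text
#'
#' @param file Path to a newick file (one tree).
#' @param text Newick string, used instead of `file` when given.
#' @param age_mode `"branch-lengths"` (standard newick; ages derived from the
#'   branch lengths) or `"node-ages"` (internal node labels carry the node age
#'   in Ma and branch lengths are ignored/absent).
#' @return A [chronogram].
#' @examples
#' read_chronogram(text = "((A:5,B:5):5,C:10);")
#' read_chronogram(text = "((A,B)5,C)10;", age_mode = "node-ages")
#' @export
read_chronogram <- function(file = NULL, text = NULL,
                            age_mode = c("branch-lengths", "node-ages")) {
  age_mode <- match.arg(age_mode)
  phy <- withCallingHandlers(
    tryCatch(
      if (is.null(text)) ape::read.tree(file) else ape::read.tree(text = text),
      error = function(e) stop(sprintf("malformed newick: %s", conditionMessage(e)),
                               call. = FALSE)),
    warning = function(w) invokeRestart("muffleWarning"))
  if (is.null(phy)) stop("malformed newick: no tree could be parsed", call. = FALSE)
  if (age_mode == "branch-lengths") return(as_chronogram(phy))
  lab <- phy$node.label
  if (is.null(lab)) stop("age_mode = 'node-ages' needs internal node labels", call. = FALSE)
  ages <- suppressWarnings(as.numeric(lab))
  if (anyNA(ages)) {
    stop(sprintf("internal node label '%s' is not a numeric age",
                 lab[which(is.na(ages))[1]]), call. = FALSE)
  }
  n_tip <- length(phy$tip.label)
  age <- c(rep(0, n_tip), ages)
  phy$edge.length <- age[phy$edge[, 1]] - age[phy$edge[, 2]]
  phy$node.label <- NULL
  as_chronogram(phy)
}

#' Write a chronogram as newick
#'
#' Branch lengths (Myr) are written with enough digits that
#' reading the file back reproduces topology, labels and node ages to 1e-9.
#'
#' @param x A [chronogram].
#' @param file Output path; when `NULL` the newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The newick string, invisibly when written to a file.
#' @export
write_chronogram <- function(x, file = NULL, digits = 12) {
  stopifnot(inherits(x, "phylo"))
  txt <- ape::write.tree(x, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Node ages of a chronogram as a tibble
#'
#' @param x A [chronogram].
#' @return A tibble with columns `node` (ape node number), `label` (tip label
#'   or `NA`), `age_ma`, `is_tip`, and `source` when age provenance was
#'   recorded on the fixture.
#' @export
node_ages <- function(x) {
  stopifnot(inherits(x, "chronogram"))
  age <- attr(x, "node_age")
  n_tip <- length(x$tip.label)
  out <- tibble::tibble(
    node = seq_along(age),
    label = c(x$tip.label, rep(NA_character_, length(age) - n_tip)),
    age_ma = age,
    is_tip = seq_along(age) <= n_tip)
  src <- attr(x, "age_source")
  if (!is.null(src)) out$source <- c(rep("tip", n_tip), src)
  out
}

#' Age of the most recent common ancestor of a set of tips
#'
#' @param x A [chronogram].
#' @param tips Character vector of two or more tip labels.
#' @return The MRCA age in Ma.
#' @export
mrca_age <- function(x, tips) {
  stopifnot(inherits(x, "chronogram"))
  missing_tips <- setdiff(tips, x$tip.label)
  if (length(missing_tips) > 0) {
    stop(sprintf("tip '%s' is not in the tree", missing_tips[1]), call. = FALSE)
  }
  node <- if (length(tips) == 1) match(tips, x$tip.label) else ape::getMRCA(x, tips)
  attr(x, "node_age")[node]
}

#' Build a chronogram from a topology and a clade-age table
#'
#' Every internal node of the topology must be dated by exactly one entry of
#' the table; each entry names a clade by a set of tip labels whose MRCA is
#' the node, plus its age in Ma. Tips are implicitly at age 0. The resulting
#' tree is ultrametric by construction and its MRCA ages equal the table
#' entries exactly.
#'
#' @param topology A `phylo` (or newick string) without branch lengths.
#' @param ages A data frame with columns `clade_tips` (tip labels separated by
#'   `";"`) and `age_ma`; an optional `source` column is carried through to
#'   [node_ages()].
#' @return A [chronogram].
#' @examples
#' build_chronogram("((A,B),C);",
#'   tibble::tibble(clade_tips = c("A;B;C", "A;B"), age_ma = c(10, 4)))
#' @export
build_chronogram <- function(topology, ages) {
  if (is.character(topology)) topology <- ape::read.tree(text = topology)
  stopifnot(inherits(topology, "phylo"), is.data.frame(ages))
  if (!all(c("clade_tips", "age_ma") %in% names(ages))) {
    stop("`ages` needs columns clade_tips and age_ma", call. = FALSE)
  }
  n_tip <- length(topology$tip.label)
  n_node <- topology$Nnode
  age <- rep(NA_real_, n_tip + n_node)
  age[seq_len(n_tip)] <- 0
  src <- rep(NA_character_, n_node)
  has_src <- "source" %in% names(ages)
  for (i in seq_len(nrow(ages))) {
    tips <- strsplit(ages$clade_tips[i], ";", fixed = TRUE)[[1]]
    tips <- trimws(tips)
    missing_tips <- setdiff(tips, topology$tip.label)
    if (length(missing_tips) > 0) {
      stop(sprintf("clade-age entry %d names unknown tip '%s'", i, missing_tips[1]),
           call. = FALSE)
    }
    node <- ape::getMRCA(topology, tips)
    if (!is.na(age[node])) {
      stop(sprintf("internal node (MRCA of %s) is dated twice", ages$clade_tips[i]),
           call. = FALSE)
    }
    age[node] <- ages$age_ma[i]
    if (has_src) src[node - n_tip] <- ages$source[i]
  }
  if (anyNA(age)) {
    node <- which(is.na(age))[1]
    tips <- topology$tip.label[.descendant_tips(topology, node)]
    stop(sprintf("no age supplied for the internal node spanning {%s}",
                 paste(tips, collapse = ", ")), call. = FALSE)
  }
  bad <- which(age[topology$edge[, 2]] >= age[topology$edge[, 1]])
  if (length(bad) > 0) {
    ch <- topology$edge[bad[1], 2]
    stop(sprintf("age of node %d (%.4g Ma) is not younger than its parent (%.4g Ma)",
                 ch, age[ch], age[topology$edge[bad[1], 1]]), call. = FALSE)
  }
  topology$edge.length <- age[topology$edge[, 1]] - age[topology$edge[, 2]]
  as_chronogram(topology, age_source = if (has_src) src else NULL)
}

# tip numbers below a node (including the node itself when it is a tip)
.descendant_tips <- function(phy, node) {
  n_tip <- length(phy$tip.label)
  if (node <= n_tip) return(node)
  todo <- node
  tips <- integer(0)
  while (length(todo) > 0) {
    ch <- phy$edge[phy$edge[, 1] %in% todo, 2]
    tips <- c(tips, ch[ch <= n_tip])
    todo <- ch[ch > n_tip]
  }
  tips
}

#' Collapse a species-level chronogram to one representative tip per group
#'
#' Used to move from a species tree to a family-level tree: each group (e.g.
#' family) must be monophyletic; it is replaced by a single tip at age 0
#' attached at the group's stem, and the tip is renamed to the group label.
#' Ages of all surviving internal nodes are unchanged.
#'
#' @param x A [chronogram].
#' @param mapping A data frame with columns `tip` and `group` covering every
#'   tip, or a named character vector (names = tips, values = groups).
#' @return A [chronogram] with one tip per group.
#' @export
collapse_to_representatives <- function(x, mapping) {
  stopifnot(inherits(x, "chronogram"))
  if (!is.data.frame(mapping)) {
    mapping <- tibble::tibble(tip = names(mapping), group = unname(mapping))
  }
  stopifnot(all(c("tip", "group") %in% names(mapping)))
  uncovered <- setdiff(x$tip.label, mapping$tip)
  if (length(uncovered) > 0) {
    stop(sprintf("mapping does not cover tip '%s'", uncovered[1]), call. = FALSE)
  }
  grp <- split(mapping$tip, mapping$group)
  for (g in names(grp)) {
    tips <- intersect(grp[[g]], x$tip.label)
    if (length(tips) < 2) next
    node <- ape::getMRCA(x, tips)
    below <- x$tip.label[.descendant_tips(x, node)]
    intruders <- setdiff(below, tips)
    if (length(intruders) > 0) {
      stop(sprintf("group '%s' is not monophyletic: tip '%s' intrudes",
                   g, intruders[1]), call. = FALSE)
    }
  }
  keep <- vapply(grp, function(tips) intersect(tips, x$tip.label)[1], character(1))
  pruned <- ape::drop.tip(x, setdiff(x$tip.label, unname(keep)))
  pruned$tip.label <- names(keep)[match(pruned$tip.label, unname(keep))]
  as_chronogram(pruned)
}

#' Read or write a clade-age table
#'
#' The on-disk format is CSV with columns `clade_tips` (tip labels separated
#' by `";"`), `age_ma`, and optionally `source`.
#'
#' @param path CSV path.
#' @return `read_clade_ages()`: a tibble; `write_clade_ages()`: `path`,
#'   invisibly.
#' @export
read_clade_ages <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(age_ma = readr::col_double()))
  stopifnot(all(c("clade_tips", "age_ma") %in% names(out)))
  out
}

#' @rdname read_clade_ages
#' @param ages A clade-age data frame.
#' @export
write_clade_ages <- function(ages, path) {
  readr::write_csv(ages, path)
  invisible(path)
}

#' @export
print.chronogram <- function(x, ...) {
  age <- attr(x, "node_age")
  cat(sprintf("Chronogram: %d tips, root age %.4g Ma\n",
              length(x$tip.label), max(age)))
  NextMethod()
}
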