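#' Read a Newick tree, optionally midpoint rooting it
#'
#' Parses a Newick file (or literal string) into an `ape::phylo` tree. Missing
#' branch lengths are set to 0. Because downstream phylogenetic distances
#' require a rooted tree, trees that carry no usable root — an unrooted
#' representation, i.e. a basal multifurcation — are midpoint rooted: the root
#' is placed halfway along the longest leaf-to-leaf path. `midpoint = "always"`
#' re-roots any input at its midpoint (as done when consuming trees from
#' programs that emit arbitrary rootings); `"never"` leaves the parsed tree
#' untouched.
#'
#' @param path file path, or a Newick string ending in ";".
#' @param midpoint one of `"auto"` (default: midpoint root only when the parsed
#'   tree is unrooted or its root multifurcates), `"always"`, `"never"`.
#' @return a rooted `phylo` object with a `$rooted` attribute-free standard
#'   structure; branch lengths are non-negative.
#' @export
read_newick_tree <- function(path, midpoint = c("auto", "always", "never")) {
  midpoint <- match.arg(midpoint)
  txt <- if (grepl(";", path, fixed = TRUE)) path else {
    paste(readLines(path, warn = FALSE), collapse = "")
  }
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close) {
    offs <- unbalanced_paren_offset(txt)
    stop(sprintf("unbalanced parentheses in Newick string near character %d", offs))
  }
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("could not parse Newick string")
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  tree$edge.length[is.na(tree$edge.length)] <- 0
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels in tree")
  needs_root <- !ape::is.rooted(tree) ||
    sum(tree$edge[, 1] == ape::Ntip(tree) + 1L) > 2L
  if (midpoint == "always" || (midpoint == "auto" && needs_root)) {
    tree <- phangorn::midpoint(tree)
  }
  tree
}

# First character position at which the parenthesis balance breaks.
unbalanced_paren_offset <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) return(i)
  }
  length(chars)
}

#' Total branch length of a tree
#' @param tree a `phylo` object.
#' @return sum of all branch lengths.
#' @export
tree_total_length <- function(tree) sum(tree$edge.length)

#' Generate a random rooted binary tree
#'
#' Random binary topology with independent exponential(1) branch lengths,
#' midpoint rooted; used as a fixture generator for phylogenetic distance
#' tests.
#'
#' @param n_leaves number of leaves (>= 2).
#' @param seed integer seed; the same seed reproduces the same tree.
#' @return a rooted binary `phylo` with `n_leaves` tips and `2 * n_leaves - 2`
#'   branches.
#' @export
random_tree <- function(n_leaves, seed = 1L) {
  stopifnot(n_leaves >= 2)
  set.seed(substream_seed(seed, 977L))
  tree <- ape::rtree(n_leaves, rooted = TRUE, br = function(n) stats::rexp(n, 1))
  if (n_leaves > 2) tree <- phangorn::midpoint(tree)
  tree
}
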