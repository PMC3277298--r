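#' Parse a rooted Newick tree
#'
#' Reads a single rooted Newick statement into an \code{ape} \code{"phylo"}
#' object, with strict validation: parentheses must balance, tip labels must
#' be unique and non-empty, and branch lengths (when present) must be
#' non-negative. Child order is preserved as written; node identifiers are
#' assigned deterministically (cladewise/preorder), so downstream
#' tie-breaking rules are reproducible.
#'
#' @param text A Newick string terminated by \code{";"}.
#' @return A rooted \code{"phylo"} tree.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty Newick string")
  if (!endsWith(text, ";")) stop("Newick statement must end with ';'")
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced parentheses: unexpected ')' at position ", i)
    }
  }
  if (depth != 0L) stop("unbalanced parentheses: ", depth, " '(' left open")
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick string")
  validate_tree(tree)
  ape::reorder.phylo(tree, order = "cladewise")
}

#' Serialize a tree to Newick
#'
#' Round-trip property: \code{parse_newick(write_newick(t))} is isomorphic to
#' \code{t}, with identical labels and branch lengths.
#'
#' @param tree A \code{"phylo"} tree.
#' @return A single Newick string ending in \code{";"}.
#' @export
write_newick <- function(tree) {
  validate_tree(tree)
  ape::write.tree(tree)
}

#' Validate a phylo tree against the package's invariants
#'
#' @param tree A \code{"phylo"} object.
#' @return The tree, invisibly.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' tree")
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stop("empty tip label")
  dup <- labs[duplicated(labs)]
  if (length(dup)) stop("duplicate tip label: ", dup[[1L]])
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0, na.rm = TRUE)) {
    bad <- which(tree$edge.length < 0)[[1L]]
    stop("negative branch length on edge ", bad)
  }
  # exactly one root: nodes never appearing as a child
  parents <- unique(tree$edge[, 1L])
  children <- tree$edge[, 2L]
  roots <- setdiff(parents, children)
  if (length(roots) != 1L) stop("tree must have exactly one root")
  if (anyDuplicated(children)) stop("a node has more than one parent")
  invisible(tree)
}

root_node <- function(tree) {
  setdiff(unique(tree$edge[, 1L]), tree$edge[, 2L])
}

#' Children of each node, in stored (written) order
#' @keywords internal
children_list <- function(tree) {
  n_node <- max(tree$edge)
  out <- vector("list", n_node)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    out[[p]] <- c(out[[p]], tree$edge[i, 2L])
  }
  out
}

#' Preorder sequence of node ids
#'
#' Deterministic root-first traversal following stored child order. The
#' position of a node in this sequence is its preorder rank, used for all
#' documented tie-breaking.
#'
#' @param tree A \code{"phylo"} tree.
#' @return Integer vector of node ids in preorder.
#' @export
node_preorder <- function(tree) {
  kids <- children_list(tree)
  out <- integer(0)
  stack <- root_node(tree)
  while (length(stack)) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    out <- c(out, v)
    stack <- c(kids[[v]], stack)
  }
  out
}

postorder_edges <- function(tree) {
  tr <- ape::reorder.phylo(tree, order = "postorder")
  tr$edge
}

tip_id <- function(tree, label) {
  i <- match(label, tree$tip.label)
  if (anyNA(i)) stop("unknown taxon: ", paste(label[is.na(i)], collapse = ", "))
  i
}

#' Most recent common ancestor of a set of tips
#'
#' @param tree A \code{"phylo"} tree.
#' @param taxa Character vector of tip labels (non-empty).
#' @return Node id of the deepest node ancestral to all named tips; for a
#'   single taxon, the tip itself.
#' @export
mrca_node <- function(tree, taxa) {
  if (!length(taxa)) stop("empty taxon set")
  ids <- tip_id(tree, unique(taxa))
  if (length(ids) == 1L) return(ids)
  ape::getMRCA(tree, ids)
}

ancestors_of <- function(tree, node) {
  # node ids from root down to (and including) `node`
  par <- integer(max(tree$edge))
  par[tree$edge[, 2L]] <- tree$edge[, 1L]
  path <- node
  r <- root_node(tree)
  while (node != r) {
    node <- par[node]
    path <- c(node, path)
  }
  path
}

#' Patristic distance between two tips
#'
#' Sum of branch lengths on the path connecting two tips of a phylogram.
#'
#' @param tree A \code{"phylo"} tree with branch lengths.
#' @param a,b Tip labels.
#' @return Non-negative numeric distance (same units as the branch lengths).
#' @export
patristic_distance <- function(tree, a, b) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  ia <- tip_id(tree, a)
  ib <- tip_id(tree, b)
  if (ia == ib) return(0)
  pa <- ancestors_of(tree, ia)
  pb <- ancestors_of(tree, ib)
  common <- max(which(pa[seq_len(min(length(pa), length(pb)))] ==
                        pb[seq_len(min(length(pa), length(pb)))]))
  nodes <- c(pa[-seq_len(common)], pb[-seq_len(common)])
  if (anyNA(tree$edge.length[match(nodes, tree$edge[, 2L])])) {
    stop("missing branch length on path")
  }
  sum(tree$edge.length[match(nodes, tree$edge[, 2L])])
}

#' Load a packaged Caenorhabditis fixture tree
#'
#' The 26-species topology transcribed from the genus-wide maximum-likelihood
#' analysis. The \code{"caenorhabditis26+outgroup"} variant adds a
#' \emph{Protorhabditis} outgroup tip used to root character reconstructions.
#'
#' @param name One of \code{"caenorhabditis26"} or
#'   \code{"caenorhabditis26+outgroup"}.
#' @return A rooted \code{"phylo"} tree without branch lengths.
#' @export
load_fixture_tree <- function(name = c("caenorhabditis26",
                                       "caenorhabditis26+outgroup")) {
  name <- match.arg(name)
  file <- if (name == "caenorhabditis26") "caenorhabditis26.nwk" else
    "caenorhabditis26_outgroup.nwk"
  path <- system.file("extdata", file, package = "caenophylo", mustWork = TRUE)
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Load the packaged phenotypic character matrix
#'
#' Discrete phenotypic characters (reproductive mode, spicule and male-tail
#' morphology, mating position, RNAi competence) for the 26 cultured
#' Caenorhabditis species plus the Protorhabditis outgroup, re-encoded from
#' the study's figures and running text. \code{"?"} marks states the source
#' does not report.
#'
#' @return A \code{CharacterMatrix} (see \code{\link{read_character_matrix}}).
#' @export
load_fixture_characters <- function() {
  path <- system.file("extdata", "caenorhabditis_characters.tsv",
                      package = "caenophylo", mustWork = TRUE)
  read_character_matrix(path)
}

#' Manifest of fixture taxa
#' @return Data frame with columns \code{label}, \code{display_name},
#'   \code{clade}.
#' @export
fixture_taxa <- function() {
  path <- system.file("extdata", "caenorhabditis_taxa.tsv",
                      package = "caenophylo", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
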