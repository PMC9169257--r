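## Rooted-tree input and indexing.
##
## Trees are held as ape "phylo" objects (the field's standard container).
## All model code works through the index built by tree_index(): internal
## nodes visited in postorder, each with its ordered children (Newick order),
## so parameter vectors align reproducibly across fits and simulations.

#' Read a rooted phylogenetic tree from a Newick file
#'
#' Parses a single Newick tree, validates it for use as a model scaffold
#' (rooted, unique non-empty leaf labels), and collapses unary internal
#' nodes ("singleton chains"), summing branch lengths along collapsed
#' edges.  Multifurcations are allowed.
#'
#' @param path Path to a file containing one Newick string, or a
#'   literal Newick string (must end in ";").
#' @return An object of class \code{"phylo"} (see \pkg{ape}).
#' @examples
#' tr <- read_newick(text = "((A,B),C);")
#' tr$tip.label
#' @export
read_newick <- function(path, text = NULL) {
  if (is.null(text)) {
    stop_if(!file.exists(path), "tree file not found: ", path)
    phy <- tryCatch(ape::read.tree(path),
                    error = function(e) stop("malformed Newick in ", path, ": ",
                                             conditionMessage(e), call. = FALSE))
  } else {
    phy <- tryCatch(suppressWarnings(ape::read.tree(text = text)),
                    error = function(e) stop("malformed Newick: ",
                                             conditionMessage(e), call. = FALSE))
  }
  stop_if(is.null(phy), "malformed or empty Newick input")
  if (inherits(phy, "multiPhylo")) {
    stop_if(length(phy) != 1L, "expected exactly one tree, found ", length(phy))
    phy <- phy[[1L]]
  }
  validate_tree(phy)
}

#' @noRd
validate_tree <- function(phy) {
  stop_if(!inherits(phy, "phylo"), "not a phylogenetic tree")
  stop_if(ape::Ntip(phy) < 2L, "tree must have at least 2 leaves")
  phy <- ape::collapse.singles(phy)
  labs <- phy$tip.label
  stop_if(any(is.na(labs) | labs == ""), "tree has empty leaf labels")
  dup <- unique(labs[duplicated(labs)])
  stop_if(length(dup) > 0L,
          "duplicate leaf labels: ", paste(dup, collapse = ", "))
  if (!is.rooted_safe(phy))
    stop("tree must be rooted", call. = FALSE)
  phy
}

#' @noRd
is.rooted_safe <- function(phy) {
  ## ape considers a basal trifurcation unrooted; for count factorization a
  ## multifurcating root is a perfectly good node, so only reject trees with
  ## no identifiable root at all.
  tab <- tabulate(phy$edge[, 2L], nbins = ape::Ntip(phy) + phy$Nnode)
  root <- which(tab == 0L)
  length(root) == 1L
}

#' Build the postorder index of a rooted tree
#'
#' Internal scaffolding used by every model: internal nodes in postorder
#' (children before parents), the ordered children of each internal node
#' (Newick order), and the set of leaves descending from every node.
#'
#' @param phy A \code{"phylo"} object.
#' @return A list with components \code{n_leaf}, \code{n_node} (internal
#'   nodes), \code{root}, \code{int_nodes} (ape node ids, postorder),
#'   \code{children} (list over internal nodes, ordered child ids),
#'   \code{parent} (vector over all nodes), \code{leaves} (list over all
#'   nodes: descending tip indices), \code{node_name} (display name per
#'   node: tip label or N<id>).
#' @keywords internal
#' @export
tree_index <- function(phy) {
  phy <- validate_tree(phy)
  n <- ape::Ntip(phy); m <- phy$Nnode; M <- n + m
  parent <- integer(M); parent[] <- NA_integer_
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  root <- which(is.na(parent) & seq_len(M) > n)
  stop_if(length(root) != 1L, "tree must have exactly one root")

  ## children in edge (Newick) order
  children <- vector("list", M)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1L]
    children[[p]] <- c(children[[p]], phy$edge[e, 2L])
  }

  ## postorder over internal nodes: repeatedly emit nodes whose internal
  ## children have all been emitted
  depth <- integer(M); depth[root] <- 0L
  ord <- root
  i <- 1L
  while (i <= length(ord)) {
    v <- ord[i]
    kids <- children[[v]]
    if (!is.null(kids)) {
      depth[kids] <- depth[v] + 1L
      ord <- c(ord, kids[kids > n])
    }
    i <- i + 1L
  }
  int_post <- rev(ord)  # children before parents

  leaves <- vector("list", M)
  for (t in seq_len(n)) leaves[[t]] <- t
  for (v in int_post) {
    leaves[[v]] <- unlist(leaves[children[[v]]], use.names = FALSE)
  }

  node_name <- character(M)
  node_name[seq_len(n)] <- phy$tip.label
  if (!is.null(phy$node.label) && length(phy$node.label) == m &&
      !anyNA(phy$node.label) && all(nzchar(phy$node.label)) &&
      !anyDuplicated(c(phy$tip.label, phy$node.label))) {
    node_name[n + seq_len(m)] <- phy$node.label
  } else {
    node_name[n + seq_len(m)] <- paste0("N", n + seq_len(m))
  }

  list(phy = phy, n_leaf = n, n_node = m, root = root,
       int_nodes = int_post, children = children, parent = parent,
       leaves = leaves, depth = depth, node_name = node_name)
}
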