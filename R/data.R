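## Dataset container and readers.
##
## A microbiome_data object is the aligned triplet (counts, tree, metadata):
## count columns are reordered to the tree's leaf order and metadata rows to
## the count rows, so every downstream routine can index by position.

#' Construct a microbiome dataset
#'
#' Validates and aligns a sample-by-taxon count matrix, a rooted
#' phylogenetic tree over the taxa, and an optional per-sample metadata
#' table.  Count columns are put in the tree's leaf order; metadata rows
#' are matched to count rows by name.
#'
#' @param counts Numeric matrix (or data frame) of non-negative integer
#'   counts; rows are samples, columns are taxa named by tree leaf labels.
#' @param tree A \code{"phylo"} tree whose leaf labels are exactly the
#'   count column names (as a set).
#' @param metadata Optional data frame of per-sample covariates/responses;
#'   row names (or a first column of sample ids) must match the count rows.
#' @return An object of class \code{"microbiome_data"}: a list with
#'   elements \code{counts}, \code{tree}, \code{metadata}, \code{index}.
#' @examples
#' tr <- read_newick(text = "((A,B),C);")
#' y <- matrix(c(2, 0, 2, 5, 1, 3), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("A", "B", "C")))
#' md <- microbiome_data(y, tr)
#' @export
microbiome_data <- function(counts, tree, metadata = NULL) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  stop_if(!is.matrix(counts) || !is.numeric(counts),
          "'counts' must be a numeric matrix")
  stop_if(is.null(colnames(counts)), "'counts' must have taxon column names")
  stop_if(!is_count_matrix(counts),
          "'counts' must contain finite non-negative integers")
  counts <- round(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("sample", seq_len(nrow(counts)))

  idx <- tree_index(tree)
  tree <- idx$phy
  taxa <- colnames(counts)
  extra   <- setdiff(taxa, tree$tip.label)
  missing <- setdiff(tree$tip.label, taxa)
  if (length(extra) || length(missing)) {
    stop("count columns and tree leaves differ",
         if (length(extra)) paste0("; in counts only: {",
                                   paste(extra, collapse = ", "), "}"),
         if (length(missing)) paste0("; in tree only: {",
                                     paste(missing, collapse = ", "), "}"),
         call. = FALSE)
  }
  counts <- counts[, tree$tip.label, drop = FALSE]

  if (!is.null(metadata)) {
    stop_if(!is.data.frame(metadata), "'metadata' must be a data frame")
    ids <- rownames(counts)
    if (!all(ids %in% rownames(metadata)))
      stop("metadata rows and count rows differ; missing samples: ",
           paste(setdiff(ids, rownames(metadata)), collapse = ", "),
           call. = FALSE)
    metadata <- metadata[ids, , drop = FALSE]
  }

  structure(list(counts = counts, tree = tree, metadata = metadata,
                 index = idx),
            class = "microbiome_data")
}

#' @export
print.microbiome_data <- function(x, ...) {
  cat("microbiome_data:", nrow(x$counts), "samples x",
      ncol(x$counts), "taxa;",
      x$index$n_node, "internal tree nodes\n")
  if (!is.null(x$metadata))
    cat("metadata:", ncol(x$metadata), "variables (",
        paste(utils::head(colnames(x$metadata), 5L), collapse = ", "), ")\n")
  invisible(x)
}

#' @noRd
read_table_generic <- function(path) {
  stop_if(!file.exists(path), "file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "")
}

#' Read a count table
#'
#' TSV/CSV with a header row of taxon names and a first column of sample
#' ids.  A BIOM file (JSON or HDF5) is accepted when the \pkg{biomformat}
#' package is installed; BIOM stores taxa as rows, so the matrix is
#' transposed to samples-by-taxa.
#'
#' @param path Path to the count file.
#' @return A numeric matrix, samples in rows.
#' @export
read_counts <- function(path) {
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    stop_if(!requireNamespace("biomformat", quietly = TRUE),
            "reading BIOM files requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    mat <- t(as.matrix(biomformat::biom_data(b)))
    return(mat)
  }
  df <- read_table_generic(path)
  as.matrix(df)
}

#' Read an aligned counts + tree + metadata dataset
#'
#' The three input files of a typical phylogeny-aware analysis: a count
#' matrix, a rooted Newick tree over its taxa, and a sample metadata
#' table.  See \code{\link{microbiome_data}} for the alignment rules.
#'
#' @param counts_path Count table (TSV/CSV/BIOM); see \code{\link{read_counts}}.
#' @param tree_path Newick file.
#' @param metadata_path Optional metadata table (TSV/CSV, first column =
#'   sample id).
#' @return A \code{"microbiome_data"} object.
#' @export
read_dataset <- function(counts_path, tree_path, metadata_path = NULL) {
  counts <- read_counts(counts_path)
  tree <- read_newick(tree_path)
  metadata <- if (!is.null(metadata_path)) read_table_generic(metadata_path)
  microbiome_data(counts, tree, metadata)
}

#' Aggregate leaf counts to internal-node child counts
#'
#' For every internal node v of the tree, forms the n-by-k_v matrix whose
#' j-th column is the sum of counts over the leaves descending through
#' v's j-th child.  These subtree sums are the sufficient statistics of
#' the Dirichlet-tree multinomial, whose likelihood factorizes into one
#' Dirichlet-multinomial per internal node.
#'
#' @param data A \code{"microbiome_data"} object.
#' @return An object of class \code{"node_counts"}: a list with \code{Y}
#'   (named list of per-node count matrices, internal nodes in postorder),
#'   \code{index} (the tree index) and \code{tree}.
#' @examples
#' tr <- read_newick(text = "((A,B),C);")
#' y <- matrix(c(2, 0, 2), 1, dimnames = list("s1", c("A", "B", "C")))
#' nc <- aggregate_node_counts(microbiome_data(y, tr))
#' nc$Y
#' @export
aggregate_node_counts <- function(data) {
  stop_if(!inherits(data, "microbiome_data"),
          "'data' must be a microbiome_data object")
  idx <- data$index
  counts <- data$counts
  n <- nrow(counts)
  ## subtree totals per node, one postorder pass
  tot <- matrix(0, n, idx$n_leaf + idx$n_node)
  tot[, seq_len(idx$n_leaf)] <- counts
  Y <- vector("list", length(idx$int_nodes))
  names(Y) <- idx$node_name[idx$int_nodes]
  for (i in seq_along(idx$int_nodes)) {
    v <- idx$int_nodes[i]
    kids <- idx$children[[v]]
    yv <- tot[, kids, drop = FALSE]
    colnames(yv) <- idx$node_name[kids]
    rownames(yv) <- rownames(counts)
    tot[, v] <- rowSums(yv)
    Y[[i]] <- yv
  }
  structure(list(Y = Y, index = idx, tree = data$tree), class = "node_counts")
}

#' @export
print.node_counts <- function(x, ...) {
  cat("node_counts:", length(x$Y), "internal nodes,",
      nrow(x$Y[[1L]]), "samples\n")
  invisible(x)
}
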