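## Fixture builders shared across the test files.  Everything is built
## in code; no fixture is read from disk except where a test targets the
## file readers themselves.

tiny_tree <- function() read_newick(text = "((A,B),C);")

tiny_counts <- function() {
  matrix(c(2, 0, 2,
           5, 1, 3), nrow = 2, byrow = TRUE,
         dimnames = list(c("s1", "s2"), c("A", "B", "C")))
}

tiny_dataset <- function(metadata = NULL) {
  md <- metadata %||% data.frame(bmi = c(22.5, 31.0),
                                 row.names = c("s1", "s2"))
  microbiome_data(tiny_counts(), tiny_tree(), md)
}

## write a counts/metadata TSV in the package's interchange layout
write_counts_tsv <- function(counts, path) {
  df <- data.frame(sample = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_metadata_tsv <- function(md, path) {
  df <- data.frame(sample = rownames(md), md, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

## a fabricated penalized-regression fit, for testing the component
## extraction in isolation
fake_tasso_fit <- function(tree, gamma) {
  A <- build_ancestor_matrix(tree)
  g <- setNames(rep(0, ncol(A)), colnames(A))
  g[names(gamma)] <- gamma
  structure(list(gamma = g, beta = drop(A %*% g), intercept = 0,
                 lambda = 0.1, A = A, tree = tree, n = 0L,
                 y = numeric(0), fitted = numeric(0)),
            class = c("tasso_fit", "treelasso_fit"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
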