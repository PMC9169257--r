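test_that("read_newick parses, validates and collapses singleton chains", {
  tr <- read_newick(text = "((A,B),C);")
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 3L)
  expect_equal(tr$Nnode, 2L)

  poly <- read_newick(text = "(A,B,C);")
  expect_equal(poly$Nnode, 1L)
  idx <- tree_index(poly)
  expect_length(idx$children[[idx$root]], 3L)

  expect_error(read_newick(text = "((A,A),C);"), "duplicate")
  expect_error(read_newick(text = "this is not newick"))
  expect_error(read_newick(tempfile("nope")), "not found")

  ## unary chain collapsed on read
  chain <- read_newick(text = "(((A,B)),C);")
  expect_equal(chain$Nnode, 2L)
})

test_that("newick round trip preserves topology, labels and child order", {
  for (s in 1:5) {
    tr <- random_tree(7, seed = s, shape = "random-multifurcating")
    tr2 <- read_newick(text = ape::write.tree(tr))
    i1 <- tree_index(tr); i2 <- tree_index(tr2)
    expect_identical(i2$phy$tip.label, i1$phy$tip.label)
    expect_identical(lengths(i2$children[i2$int_nodes]),
                     lengths(i1$children[i1$int_nodes]))
    ## same leaf partition at every internal node, in the same child order
    part <- function(ix) lapply(ix$int_nodes, function(v)
      lapply(ix$children[[v]], function(ch) ix$phy$tip.label[ix$leaves[[ch]]]))
    expect_identical(part(i2), part(i1))
  }
})

test_that("read_dataset aligns counts, tree and metadata", {
  td <- withr::local_tempdir()
  counts <- tiny_counts()[, c("C", "A", "B")]   # scrambled column order
  cp <- write_counts_tsv(counts, file.path(td, "counts.tsv"))
  tp <- file.path(td, "tree.nwk")
  writeLines("((A,B),C);", tp)
  mp <- write_metadata_tsv(data.frame(bmi = c(22.5, 31), row.names = c("s1", "s2")),
                           file.path(td, "meta.tsv"))

  d <- read_dataset(cp, tp, mp)
  expect_identical(colnames(d$counts), c("A", "B", "C"))
  expect_identical(rownames(d$metadata), rownames(d$counts))
  expect_equal(d$counts["s1", ], c(A = 2, B = 0, C = 2))

  ## mismatched taxon sets are reported with the offending labels
  bad <- cbind(counts, D = c(1, 1))
  cpb <- write_counts_tsv(bad, file.path(td, "bad.tsv"))
  expect_error(read_dataset(cpb, tp, mp), "D")

  ## all-zero counts are legal input
  zero <- tiny_counts() * 0
  cpz <- write_counts_tsv(zero, file.path(td, "zero.tsv"))
  expect_silent(d0 <- read_dataset(cpz, tp, mp))
  expect_true(all(d0$counts == 0))
})

test_that("non-integer or negative counts are rejected", {
  tr <- tiny_tree()
  x <- tiny_counts(); x[1, 1] <- 1.5
  expect_error(microbiome_data(x, tr), "integer")
  x <- tiny_counts(); x[1, 1] <- -1
  expect_error(microbiome_data(x, tr), "negative")
})

test_that("node count aggregation computes subtree sums with conservation", {
  nc <- aggregate_node_counts(tiny_dataset())
  ## sample s1: A=2, B=0, C=2
  expect_equal(nc$Y[["N4"]]["s1", ], c(N5 = 2, C = 2))
  expect_equal(nc$Y[["N5"]]["s1", ], c(A = 2, B = 0))

  ## star tree: single node table equals the raw counts
  star <- read_newick(text = "(A,B,C);")
  ncs <- aggregate_node_counts(microbiome_data(tiny_counts(), star))
  expect_equal(unname(ncs$Y[[1L]]), unname(tiny_counts()))

  ## conservation on random data: child sums equal the parent allocation
  tr <- random_tree(9, seed = 4, shape = "random-multifurcating")
  cnt <- matrix(rpois(9 * 6, 30), 6, 9, dimnames = list(NULL, tr$tip.label))
  d <- microbiome_data(cnt, tr)
  nc <- aggregate_node_counts(d)
  idx <- d$index
  for (v in idx$int_nodes) {
    yv <- nc$Y[[idx$node_name[v]]]
    par <- idx$parent[v]
    entering <- if (is.na(par)) rowSums(d$counts) else {
      nc$Y[[idx$node_name[par]]][, idx$node_name[v]]
    }
    expect_equal(unname(rowSums(yv)), unname(entering))
  }
})

test_that("aggregation is invariant to input column permutation", {
  tr <- random_tree(8, seed = 2)
  cnt <- matrix(rpois(8 * 5, 20), 5, 8, dimnames = list(NULL, tr$tip.label))
  nc1 <- aggregate_node_counts(microbiome_data(cnt, tr))
  perm <- sample(8)
  nc2 <- aggregate_node_counts(microbiome_data(cnt[, perm], tr))
  expect_equal(nc1$Y, nc2$Y)
})
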