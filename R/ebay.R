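## Empirical-Bayes relative abundances.
##
## A Dirichlet-tree prior on the composition, with hyper-parameters fitted
## by evidence maximization (exactly a DTM fit, by conjugacy), yields
## closed-form posterior-mean branch probabilities at every internal node;
## the leaf abundance is the product of branch probabilities along the
## root-to-leaf path.  The zero-inflated prior splits the mass of a
## zero-count branch between "structurally absent" (abundance exactly 0)
## and "present but unobserved" (the conjugate mean), weighted by the
## EM posterior of the absence indicators.

#' Empirical-Bayes estimates of relative abundances
#'
#' Estimates per-sample compositions as posterior means under a
#' (zero-inflated) Dirichlet-tree prior whose hyper-parameters are fitted
#' to the data by evidence maximization.
#'
#' @param data A \code{"microbiome_data"} object.
#' @param prior \code{"dtm"} (Dirichlet-tree) or \code{"zidtm"}
#'   (zero-inflated Dirichlet-tree).
#' @param penalty Ridge on \eqn{\log\alpha} for the evidence fit.
#' @param fit Optional pre-computed \code{"dtm_fit"} (skips refitting;
#'   its type must match \code{prior}).
#' @return A matrix of class \code{"ebay"} (samples x leaves, rows
#'   summing to 1) with the fitted model in attribute \code{"fit"}.
#'   Under the plain Dirichlet-tree prior every entry is strictly
#'   positive (zero-count taxa are shrunk toward the prior mean, not to
#'   zero).
#' @examples
#' tr <- read_newick(text = "((A,B),C);")
#' y <- matrix(c(2, 0, 2, 5, 1, 3), 2, 3, byrow = TRUE,
#'             dimnames = list(NULL, c("A", "B", "C")))
#' ebay_compositions(microbiome_data(y, tr))
#' @export
ebay_compositions <- function(data, prior = c("dtm", "zidtm"),
                              penalty = 0, fit = NULL) {
  prior <- match.arg(prior)
  stop_if(!inherits(data, "microbiome_data"), "'data' must be microbiome_data")
  table <- aggregate_node_counts(data)
  if (is.null(fit)) {
    fit <- fit_dtm(table, zero_inflated = prior == "zidtm",
                   penalty = if (prior == "dtm") penalty else 0)
  }
  bp <- branch_posterior_means(table, fit)
  comp <- posterior_leaf_abundance(data$tree, bp)
  rownames(comp) <- rownames(data$counts)
  ## renormalize only to absorb float error
  comp <- comp / rowSums(comp)
  structure(comp, class = c("ebay", "matrix"), fit = fit)
}

#' @export
print.ebay <- function(x, ...) {
  cat("empirical-Bayes compositions:", nrow(x), "samples x", ncol(x), "taxa\n")
  print(utils::head(unclass(x)[, seq_len(min(6L, ncol(x))), drop = FALSE], 4L))
  invisible(x)
}

## posterior-mean branch probabilities per internal node (list of n x k)
#' @noRd
branch_posterior_means <- function(table, fit) {
  nodes <- names(table$Y)
  zi <- !is.null(fit$pi)
  bp <- lapply(nodes, function(v) {
    Y <- table$Y[[v]]
    a <- fit$alpha[[v]]
    if (!zi) {
      B <- sweep(Y, 2L, a, "+")
      return(B / rowSums(B))
    }
    zidm_branch_means(Y, a, fit$pi[[v]])
  })
  names(bp) <- nodes
  bp
}

## ZI posterior mean: average the conditional Dirichlet mean over the
## posterior of the present set (absent children get exactly 0)
#' @noRd
zidm_branch_means <- function(Y, alpha, pi) {
  n <- nrow(Y); k <- ncol(Y)
  B <- matrix(0, n, k, dimnames = dimnames(Y))
  lp <- log(pmax(pi, 1e-300)); l1p <- log1p(-pi)
  for (i in seq_len(n)) {
    y <- Y[i, ]
    pos <- which(y > 0); z <- which(y == 0)
    if (length(pos) == 0L) {
      ## no reads entered this node: prior mean over present sets
      pos <- integer(0)
    }
    Ts <- if (length(z) == 0L) list(integer(0)) else {
      unlist(lapply(0:(2^length(z) - 1L), function(m)
        list(z[bitwAnd(m, bitwShiftL(1L, seq_along(z) - 1L)) > 0L])),
        recursive = FALSE)
    }
    lw <- numeric(length(Ts)); means <- vector("list", length(Ts))
    for (s in seq_along(Ts)) {
      S <- sort(c(pos, Ts[[s]]))
      if (length(S) == 0L) { lw[s] <- -Inf; means[[s]] <- rep(0, k); next }
      absent <- setdiff(z, Ts[[s]])
      lw[s] <- sum(l1p[S]) + sum(lp[absent]) +
        logdm_subset(y, alpha, S)
      m <- rep(0, k)
      m[S] <- (alpha[S] + y[S]) / sum(alpha[S] + y[S])
      means[[s]] <- m
    }
    w <- exp(lw - max(lw)); w <- w / sum(w)
    B[i, ] <- Reduce(`+`, Map(`*`, means, w))
  }
  B
}

#' Leaf abundances from branch probabilities
#'
#' Multiplies branch probabilities along every root-to-leaf path: leaf
#' j's abundance is the product over the edges on its path of the
#' probability assigned to the child taken.  Rows sum to one exactly
#' when every per-node branch vector does.
#'
#' @param tree A \code{"phylo"} tree.
#' @param branch_probs Named list over internal nodes (names as in
#'   \code{\link{aggregate_node_counts}}): n x k_v matrices of branch
#'   probabilities.
#' @return An n x n_leaf composition matrix (columns in tree leaf order).
#' @export
posterior_leaf_abundance <- function(tree, branch_probs) {
  idx <- tree_index(tree)
  nodes <- idx$node_name[idx$int_nodes]
  stop_if(!all(nodes %in% names(branch_probs)),
          "branch_probs missing nodes: ",
          paste(setdiff(nodes, names(branch_probs)), collapse = ", "))
  n <- nrow(branch_probs[[nodes[1L]]])
  M <- idx$n_leaf + idx$n_node
  prob <- matrix(0, n, M)
  prob[, idx$root] <- 1
  ## parents before children
  for (v in rev(idx$int_nodes)) {
    b <- branch_probs[[idx$node_name[v]]]
    kids <- idx$children[[v]]
    for (j in seq_along(kids))
      prob[, kids[j]] <- prob[, v] * b[, j]
  }
  comp <- prob[, seq_len(idx$n_leaf), drop = FALSE]
  colnames(comp) <- idx$phy$tip.label
  comp
}
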