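## Synthetic data: random trees, (zero-inflated) DTM counts, and sparse
## (log-)linear responses.  These generators define the package's test
## bed; every routine is a pure function of its arguments and seed.

#' Generate a random rooted tree
#'
#' @param n_leaves Number of leaves (>= 2); labels T1..Tn.
#' @param seed Integer seed (required; generation is deterministic).
#' @param shape \code{"balanced"} (recursive halving),
#'   \code{"random-binary"} (uniform branching via \pkg{ape}), or
#'   \code{"random-multifurcating"} (random binary with short internal
#'   edges collapsed).
#' @return A \code{"phylo"} tree.
#' @examples
#' ape::write.tree(random_tree(4, seed = 1, shape = "balanced"))
#' @export
random_tree <- function(n_leaves, seed,
                        shape = c("random-binary", "balanced",
                                  "random-multifurcating")) {
  shape <- match.arg(shape)
  stop_if(n_leaves < 2L, "'n_leaves' must be at least 2")
  labs <- paste0("T", seq_len(n_leaves))
  if (shape == "balanced") {
    build <- function(v) {
      if (length(v) == 1L) return(v)
      h <- ceiling(length(v) / 2)
      paste0("(", build(v[seq_len(h)]), ",", build(v[-seq_len(h)]), ")")
    }
    return(read_newick(text = paste0(build(labs), ";")))
  }
  phy <- with_seed(seed, ape::rtree(n_leaves, rooted = TRUE))
  phy$tip.label <- labs
  if (shape == "random-multifurcating" && n_leaves > 3L) {
    ## collapse the shortest third of internal edges into polytomies
    internal <- phy$edge[, 2L] > ape::Ntip(phy)
    if (any(internal)) {
      thr <- stats::quantile(phy$edge.length[internal], 1 / 3)
      phy$edge.length[internal & phy$edge.length <= thr] <- 0
      phy <- ape::di2multi(phy, tol = 1e-12)
    }
  }
  validate_tree(phy)
}

## expand a scalar/per-node alpha (or pi) spec into the per-node list form
#' @noRd
expand_node_param <- function(spec, idx, default, what) {
  nodes <- idx$node_name[idx$int_nodes]
  if (is.list(spec)) {
    stop_if(!all(nodes %in% names(spec)), "missing ", what, " for some nodes")
    return(spec[nodes])
  }
  out <- lapply(idx$int_nodes, function(v) {
    k <- length(idx$children[[v]])
    val <- rep_len(spec %||% default, k)
    names(val) <- idx$node_name[idx$children[[v]]]
    val
  })
  names(out) <- nodes
  out
}

#' Sample counts from a (zero-inflated) Dirichlet-tree multinomial
#'
#' Top-down generative pass: at each internal node a branch-probability
#' vector is drawn from Dirichlet(alpha) (after masking each child as
#' structurally absent with its probability pi; an all-absent draw is
#' rejected and redrawn), and the count entering the node is split
#' multinomially among the children.  Row sums equal the requested
#' depths exactly.
#'
#' @param tree A \code{"phylo"} tree.
#' @param params List with \code{alpha}: either a single positive number
#'   (symmetric Dirichlet at every node) or a named per-node list of
#'   child-parameter vectors; optionally \code{pi}, same shapes, for
#'   structural-zero probabilities.
#' @param depths Vector of per-sample total counts (>= 0); one sample
#'   per entry.
#' @param seed Integer seed.
#' @return A \code{"microbiome_data"} whose metadata records the depth;
#'   attribute \code{"true_compositions"} holds the drawn per-sample
#'   leaf probabilities (strictly positive only where present).
#' @export
sample_dtm <- function(tree, params, depths, seed) {
  idx <- tree_index(tree)
  stop_if(any(depths < 0), "'depths' must be non-negative")
  alpha <- expand_node_param(params$alpha, idx, 1, "alpha")
  pi <- expand_node_param(params$pi %||% 0, idx, 0, "pi")
  stop_if(any(unlist(alpha) <= 0), "alpha must be positive")
  stop_if(any(unlist(pi) < 0) || any(unlist(pi) >= 1), "pi must lie in [0, 1)")
  n <- length(depths)
  M <- idx$n_leaf + idx$n_node

  with_seed(seed, {
    counts <- matrix(0, n, idx$n_leaf,
                     dimnames = list(paste0("sample", seq_len(n)),
                                     idx$phy$tip.label))
    truecomp <- matrix(0, n, idx$n_leaf, dimnames = dimnames(counts))
    for (i in seq_len(n)) {
      node_count <- numeric(M); node_count[idx$root] <- depths[i]
      node_prob <- numeric(M); node_prob[idx$root] <- 1
      for (v in rev(idx$int_nodes)) {            # parents before children
        kids <- idx$children[[v]]
        vn <- idx$node_name[v]
        a <- alpha[[vn]]; pv <- pi[[vn]]
        present <- rep(TRUE, length(kids))
        if (any(pv > 0)) {
          for (try in seq_len(100L)) {
            present <- stats::runif(length(kids)) >= pv
            if (any(present)) break
          }
          stop_if(!any(present), "all children structurally absent at node ", vn)
        }
        b <- numeric(length(kids))
        g <- stats::rgamma(sum(present), shape = a[present], rate = 1)
        if (all(g == 0)) g[1L] <- 1          # guard against underflow
        b[present] <- g / sum(g)
        node_prob[kids] <- node_prob[v] * b
        if (node_count[v] > 0) {
          split <- stats::rmultinom(1L, node_count[v], b)[, 1L]
          node_count[kids] <- split
        }
      }
      counts[i, ] <- node_count[seq_len(idx$n_leaf)]
      truecomp[i, ] <- node_prob[seq_len(idx$n_leaf)]
    }
    md <- data.frame(depth = depths, row.names = rownames(counts))
    out <- microbiome_data(counts, idx$phy, md)
    attr(out, "true_compositions") <- truecomp
    out
  })
}

#' Generate responses from a sparse (log-)linear model on compositions
#'
#' \code{y = sum_u effect_u * f(p_u) + N(0, noise_sd^2)}, where p_u is
#' the abundance of leaf u (or the aggregated subtree abundance when u
#' names an internal node, which requires \code{tree}) and f is log for
#' the log-contrast model or identity for the linear model.  Log-contrast
#' effects must sum to zero (closure invariance) and require strictly
#' positive abundances.
#'
#' @param compositions Composition matrix (samples x leaves).
#' @param effects Named numeric vector: names are leaf labels or
#'   internal-node names, values are coefficients.
#' @param noise_sd Non-negative noise standard deviation.
#' @param model \code{"log-contrast"} or \code{"linear"}.
#' @param seed Integer seed.
#' @param tree Required when \code{effects} names internal nodes.
#' @return Numeric response vector.
#' @export
sample_response <- function(compositions, effects, noise_sd,
                            model = c("log-contrast", "linear"), seed,
                            tree = NULL) {
  model <- match.arg(model)
  if (inherits(compositions, "ebay")) compositions <- unclass(compositions)
  stop_if(is.null(names(effects)) || any(!nzchar(names(effects))),
          "'effects' must be a named vector")
  leafnames <- colnames(compositions)
  X <- matrix(NA_real_, nrow(compositions), length(effects))
  for (u in seq_along(effects)) {
    nm <- names(effects)[u]
    if (nm %in% leafnames) {
      X[, u] <- compositions[, nm]
    } else {
      stop_if(is.null(tree), "effect on node '", nm, "' requires 'tree'")
      idx <- tree_index(tree)
      v <- match(nm, idx$node_name)
      stop_if(is.na(v), "unknown effect name: ", nm)
      X[, u] <- rowSums(compositions[, idx$phy$tip.label[idx$leaves[[v]]],
                                     drop = FALSE])
    }
  }
  if (model == "log-contrast") {
    stop_if(abs(sum(effects)) > 1e-8, "log-contrast effects must sum to zero")
    stop_if(any(X <= 0), "log-contrast model requires positive abundances")
    X <- log(X)
  }
  mu <- drop(X %*% effects)
  with_seed(seed, mu + stats::rnorm(length(mu), 0, noise_sd))
}

#' Default benchmark scene
#'
#' One call producing the package's standard synthetic study: a random
#' binary tree, DTM counts with symmetric Dirichlet parameters at
#' negative-binomial sequencing depths, and a response from a sparse
#' two-leaf log-contrast effect on the true compositions.  Defaults: 16
#' leaves, 100 samples, depth ~ NegBin(mean 10000, size 5), alpha = 1,
#' no zero inflation, effect +/-1.5 on leaves T1 and T2, noise sd 0.5 —
#' the scale of a typical small 16S cohort.
#'
#' @param seed Integer seed.
#' @param n_samples,n_leaves,depth_mean,depth_size,alpha,pi,effect_size,noise_sd
#'   Scene parameters; \code{pi} may be a per-node list for structural
#'   zeros.
#' @param effect_leaves Character pair of leaf labels carrying effects
#'   \code{+effect_size} and \code{-effect_size}.
#' @return List with \code{data} (a \code{"microbiome_data"} whose
#'   metadata includes the response \code{y} and \code{depth}) and
#'   \code{truth} (tree, alpha, pi, effects, noise_sd, true
#'   compositions).
#' @export
simulate_benchmark <- function(seed, n_samples = 100L, n_leaves = 16L,
                               depth_mean = 10000, depth_size = 5,
                               alpha = 1, pi = 0, effect_size = 1.5,
                               noise_sd = 0.5,
                               effect_leaves = c("T1", "T2")) {
  seeds <- with_seed(seed, sample.int(2^31 - 1L, 4L))
  tree <- random_tree(n_leaves, seed = seeds[1L])
  depths <- with_seed(seeds[2L],
                      stats::rnbinom(n_samples, size = depth_size,
                                     mu = depth_mean))
  depths <- pmax(depths, 1L)
  data <- sample_dtm(tree, list(alpha = alpha, pi = pi), depths,
                     seed = seeds[3L])
  comp <- attr(data, "true_compositions")
  effects <- stats::setNames(c(effect_size, -effect_size), effect_leaves)
  y <- sample_response(comp, effects, noise_sd, model = "log-contrast",
                       seed = seeds[4L])
  data$metadata$y <- y
  list(data = data,
       truth = list(tree = tree, alpha = alpha, pi = pi,
                    effects = effects, noise_sd = noise_sd,
                    compositions = comp, depths = depths))
}
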