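## Tree-guided multiscale penalized regression.
##
## Both methods reparameterize the leaf coefficient vector beta through
## the tree: beta = A gamma, where A is the binary leaf x node ancestor
## matrix (root excluded).  An l1 penalty on gamma then selects whole
## subtrees: a single nonzero gamma_u gives all leaves under u a common
## coefficient.
##
## TASSO: linear log-contrast model.  Predictors are log relative
## abundances, and beta is constrained to sum to zero so the fit is
## invariant to closure (scale of each composition).  Requires strictly
## positive compositions (use the eBay output).
##
## Tree-guided fused lasso: standard linear model on raw relative
## abundances (zeros allowed); a nonzero gamma_u uses the aggregated
## subtree abundance of u as a predictor.
##
## Solver: cyclic coordinate descent on gamma; the zero-sum constraint is
## enforced by an augmented-Lagrangian outer loop (see src/cd_lasso.cpp).

#' Leaf-by-node ancestor matrix
#'
#' Binary matrix A with one row per leaf and one column per non-root
#' node (full postorder); A[j, u] = 1 iff u lies on the path from the
#' root to leaf j (the leaf itself included, the root excluded).  The
#' leaf columns form an identity block and each column sums to the
#' number of leaves under its node.
#'
#' @param tree A \code{"phylo"} tree.
#' @return The ancestor matrix with row names = leaf labels and column
#'   names = node names.
#' @examples
#' build_ancestor_matrix(read_newick(text = "((A,B),C);"))
#' @export
build_ancestor_matrix <- function(tree) {
  idx <- tree_index(tree)
  ## full postorder of all nodes (children before parents, child order kept)
  post <- integer(0)
  stack <- list(list(v = idx$root, i = 0L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    kids <- idx$children[[top$v]]
    if (is.null(kids) || top$i >= length(kids)) {
      post <- c(post, top$v)
      stack[[length(stack)]] <- NULL
    } else {
      stack[[length(stack)]]$i <- top$i + 1L
      stack[[length(stack) + 1L]] <- list(v = kids[top$i + 1L], i = 0L)
    }
  }
  cols <- setdiff(post, idx$root)
  A <- matrix(0, idx$n_leaf, length(cols),
              dimnames = list(idx$phy$tip.label, idx$node_name[cols]))
  for (j in seq_along(cols)) A[idx$leaves[[cols[j]]], j] <- 1
  attr(A, "node_ids") <- cols
  attr(A, "depth") <- idx$depth[cols]
  A
}

## validate a composition/response pair against the tree; returns pieces
#' @noRd
penreg_inputs <- function(x, y, tree, log_transform) {
  if (inherits(x, "ebay")) x <- unclass(x)
  stop_if(!is.matrix(x) || !is.numeric(x), "'x' must be a numeric matrix")
  idx <- tree_index(tree)
  stop_if(is.null(colnames(x)) ||
            !setequal(colnames(x), idx$phy$tip.label),
          "composition columns must match tree leaf labels")
  x <- x[, idx$phy$tip.label, drop = FALSE]
  stop_if(any(x < 0), "compositions must be non-negative")
  if (log_transform)
    stop_if(any(x <= 0),
            "log-contrast model requires strictly positive compositions ",
            "(use ebay_compositions() output)")
  y <- as.numeric(y)
  stop_if(length(y) != nrow(x), "length(y) must equal nrow(x)")
  stop_if(anyNA(y) || anyNA(x), "missing values are not supported")
  stop_if(stats::sd(y) == 0, "response has zero variance")
  A <- build_ancestor_matrix(idx$phy)
  Z <- if (log_transform) log(x) else x
  list(x = x, y = y, Z = Z, A = A, idx = idx, M = Z %*% A)
}

## smallest lambda at which gamma = 0 is optimal
#' @noRd
lambda_max_value <- function(cvec, s, w, constrained) {
  cw <- cvec / w
  if (!constrained) return(max(abs(cw)))
  ## gamma = 0 is optimal iff exists nu with |c_u - nu s_u| <= lambda w_u
  f <- function(nu) max(abs((cvec - nu * s) / w))
  rng <- range(cvec / s)
  if (diff(rng) == 0) return(f(rng[1L]))
  stats::optimize(f, lower = rng[1L] - 1e-9, upper = rng[2L] + 1e-9,
                  tol = 1e-12)$objective
}

## solve a descending-lambda path with warm starts on a fixed design
#' @noRd
penreg_path <- function(M, y, s, w, lambdas, constrained, tol = 1e-7) {
  n <- nrow(M)
  mbar <- colMeans(M); Mc <- sweep(M, 2L, mbar)
  ybar <- mean(y); yc <- y - ybar
  G <- crossprod(Mc) / n
  cvec <- drop(crossprod(Mc, yc)) / n
  q <- length(cvec)
  gam <- rep(0, q)
  out <- matrix(0, q, length(lambdas),
                dimnames = list(colnames(M), NULL))
  for (l in seq_along(lambdas)) {
    gam <- cd_lasso_al(G, cvec, s, lambdas[l], w, gam,
                       constrained, tol, 2000L, 1.0)
    out[, l] <- gam
  }
  list(gamma = out, mbar = mbar, ybar = ybar)
}

#' @noRd
default_lambda_grid <- function(lmax, n_lambda = 100L, ratio = 1e-3) {
  exp(seq(log(lmax), log(lmax * ratio), length.out = n_lambda))
}

#' K-fold cross-validation for the tree-guided penalized regressions
#'
#' Deterministic fold assignment from the seed; returns the
#' mean-squared-error curve over the lambda grid together with the
#' minimizer and the one-standard-error choice.
#'
#' @param x Composition matrix (leaves as columns).
#' @param y Numeric response.
#' @param tree A \code{"phylo"} tree over the composition columns.
#' @param method \code{"tasso"} or \code{"fused"}.
#' @param lambda_grid Optional descending lambda grid (default: 100
#'   log-spaced values from the data-derived lambda_max down by 1e-3).
#' @param k_folds Number of folds (2..n; n gives leave-one-out).
#' @param seed Integer seed for the fold assignment (required).
#' @param weights Optional per-node penalty weights.
#' @return List with \code{lambda_min}, \code{lambda_1se} and
#'   \code{cv_curve} (data frame: lambda, mean, se).
#' @export
cross_validate <- function(x, y, tree, method = c("tasso", "fused"),
                           lambda_grid = NULL, k_folds = 10L, seed,
                           weights = NULL) {
  method <- match.arg(method)
  constrained <- method == "tasso"
  pin <- penreg_inputs(x, y, tree, log_transform = constrained)
  n <- nrow(pin$M)
  k_folds <- as.integer(k_folds)
  stop_if(k_folds < 2L || k_folds > n, "'k_folds' must be in 2..n")
  s <- if (constrained) colSums(pin$A) else rep(0, ncol(pin$A))
  w <- weights %||% rep(1, ncol(pin$A))
  if (is.null(lambda_grid)) {
    mbar <- colMeans(pin$M)
    cvec <- drop(crossprod(sweep(pin$M, 2L, mbar), pin$y - mean(pin$y))) / n
    lambda_grid <- default_lambda_grid(lambda_max_value(cvec, s, w, constrained))
  }
  stop_if(length(lambda_grid) == 0L, "empty lambda grid")
  folds <- with_seed(seed, sample(rep_len(seq_len(k_folds), n)))
  errs <- matrix(NA_real_, n, length(lambda_grid))
  for (f in seq_len(k_folds)) {
    te <- folds == f
    path <- penreg_path(pin$M[!te, , drop = FALSE], pin$y[!te],
                        s, w, lambda_grid, constrained)
    Mte <- sweep(pin$M[te, , drop = FALSE], 2L, path$mbar)
    pred <- path$ybar + Mte %*% path$gamma
    errs[te, ] <- (pin$y[te] - pred)^2
  }
  mean_err <- colMeans(errs)
  ## standard error of the mean CV error across folds
  fold_err <- t(vapply(seq_len(k_folds), function(f)
    colMeans(errs[folds == f, , drop = FALSE]), numeric(length(lambda_grid))))
  se_err <- apply(fold_err, 2L, stats::sd) / sqrt(k_folds)
  i_min <- which.min(mean_err)
  thresh <- mean_err[i_min] + se_err[i_min]
  i_1se <- which(mean_err <= thresh)[1L]  # grid descends: first = sparsest
  list(lambda_min = lambda_grid[i_min],
       lambda_1se = lambda_grid[i_1se],
       cv_curve = data.frame(lambda = lambda_grid, mean = mean_err,
                             se = se_err))
}

## shared fitting engine behind tasso() and tree_fused_lasso()
#' @noRd
penreg_fit <- function(x, y, tree, lambda, k_folds, seed, weights,
                       cv_rule, constrained, cls) {
  pin <- penreg_inputs(x, y, tree, log_transform = constrained)
  n <- nrow(pin$M)
  s_con <- if (constrained) colSums(pin$A) else rep(0, ncol(pin$A))
  w <- weights %||% rep(1, ncol(pin$A))
  mbar <- colMeans(pin$M)
  cvec <- drop(crossprod(sweep(pin$M, 2L, mbar), pin$y - mean(pin$y))) / n
  lmax <- lambda_max_value(cvec, s_con, w, constrained)
  grid <- default_lambda_grid(max(lmax, .Machine$double.eps))

  cv <- NULL
  if (identical(lambda, "cv")) {
    stop_if(missing(seed) || is.null(seed),
            "cross-validation requires an explicit 'seed'")
    cv <- cross_validate(x, y, tree,
                         method = if (constrained) "tasso" else "fused",
                         lambda_grid = grid, k_folds = k_folds, seed = seed,
                         weights = weights)
    lambda <- if (cv_rule == "lambda.1se") cv$lambda_1se else cv$lambda_min
  }
  stop_if(!is.numeric(lambda) || lambda < 0, "invalid lambda")

  ## solve down the grid to the requested lambda for warm starts
  lams <- c(grid[grid > lambda], lambda)
  path <- penreg_path(pin$M, pin$y, s_con, w, lams, constrained)
  gamma <- path$gamma[, length(lams)]
  gamma <- canonicalize_gamma(gamma, pin$A)
  beta <- drop(pin$A %*% gamma)
  intercept <- path$ybar - sum(path$mbar * gamma)

  fit <- structure(list(
    gamma = gamma, beta = beta, intercept = intercept,
    lambda = lambda, lambda_path = grid, cv = cv,
    tree = pin$idx$phy, A = pin$A, weights = w,
    fitted = intercept + drop(pin$M %*% gamma),
    y = pin$y, n = n, call = sys.call(-1)),
    class = c(cls, "treelasso_fit"))
  fit
}

#' Tree-guided sparse log-contrast regression (TASSO)
#'
#' Regresses a univariate response on log relative abundances under the
#' linear log-contrast model (leaf coefficients sum to zero), with an l1
#' penalty on tree-node coefficients so that selection happens at
#' subtree level: the method picks subcompositions rather than
#' individual taxa.  Solves
#' \deqn{\min_{\beta_0,\gamma} \frac{1}{2n}\|y - \beta_0 - Z A \gamma\|^2
#'   + \lambda \|\gamma\|_1 \quad \mathrm{s.t.}\ 1^\top A\gamma = 0,}
#' with \eqn{Z = \log(x)} and A the ancestor matrix.
#'
#' @param x Strictly positive composition matrix (samples x leaves),
#'   e.g. the output of \code{\link{ebay_compositions}}.
#' @param y Numeric response (e.g. BMI).
#' @param tree Rooted tree over the composition columns.
#' @param lambda Non-negative penalty, or \code{"cv"} to tune by k-fold
#'   cross-validation.
#' @param k_folds,seed Cross-validation settings (seed is required for
#'   \code{lambda = "cv"}).
#' @param weights Optional per-node penalty weights (default 1).
#' @param cv_rule \code{"lambda.1se"} (default, parsimonious) or
#'   \code{"lambda.min"}.
#' @return An object of class \code{c("tasso_fit", "treelasso_fit")}
#'   with node coefficients \code{gamma}, leaf coefficients
#'   \code{beta = A gamma} (summing to zero), \code{intercept},
#'   \code{lambda}, \code{lambda_path}, \code{cv}, and the selected
#'   subcompositions via \code{\link{extract_subcompositions}}.
#' @examples
#' sim <- simulate_benchmark(seed = 1, n_samples = 40, n_leaves = 8)
#' comp <- ebay_compositions(sim$data)
#' fit <- tasso(comp, sim$data$metadata$y, sim$data$tree, lambda = "cv", seed = 1)
#' coef(fit)
#' @export
tasso <- function(x, y, tree, lambda = "cv", k_folds = 10L, seed = NULL,
                  weights = NULL, cv_rule = c("lambda.1se", "lambda.min")) {
  cv_rule <- match.arg(cv_rule)
  penreg_fit(x, y, tree, lambda, k_folds, seed, weights, cv_rule,
             constrained = TRUE, cls = "tasso_fit")
}

#' Tree-guided fused lasso on relative abundances
#'
#' Penalized linear regression of a response on raw relative abundances
#' (zeros allowed; no log transform) with an l1 penalty on tree-node
#' coefficients.  A nonzero coefficient at an internal node uses the
#' aggregated subtree abundance as one predictor, fusing the node's
#' leaves into a taxon at a higher taxonomic level.
#'
#' @inheritParams tasso
#' @param x Composition matrix with rows summing to 1; zeros permitted.
#' @return An object of class \code{c("tfl_fit", "treelasso_fit")}; see
#'   \code{\link{tasso}}.  \code{selected_taxa(fit)} lists the tree
#'   nodes with nonzero coefficients.
#' @export
tree_fused_lasso <- function(x, y, tree, lambda = "cv", k_folds = 10L,
                             seed = NULL, weights = NULL,
                             cv_rule = c("lambda.1se", "lambda.min")) {
  cv_rule <- match.arg(cv_rule)
  penreg_fit(x, y, tree, lambda, k_folds, seed, weights, cv_rule,
             constrained = FALSE, cls = "tfl_fit")
}

## Collinearity between a node column and its children (col_u = sum of
## child cols) means gamma is not unique.  Canonical form: whenever all
## children of a node carry a common additive component, move it up to
## the node — fewest nonzero nodes, preferring shallower ones.
#' @noRd
canonicalize_gamma <- function(gamma, A, tol = 1e-8) {
  ## recover child relationships from the column structure: node u's
  ## children are the maximal columns strictly contained in u's leaf set
  nm <- colnames(A)
  leafsets <- lapply(seq_len(ncol(A)), function(j) which(A[, j] > 0))
  sizes <- lengths(leafsets)
  ord <- order(sizes)                      # children before parents
  g <- gamma
  for (j in ord) {
    if (sizes[j] == 1L) next
    inside <- which(vapply(seq_len(ncol(A)), function(l)
      l != j && sizes[l] < sizes[j] && all(leafsets[[l]] %in% leafsets[[j]]),
      logical(1)))
    if (!length(inside)) next
    ## maximal contained columns = direct children
    kids <- inside[vapply(inside, function(l)
      !any(vapply(inside, function(l2)
        l2 != l && sizes[l2] > sizes[l] &&
          all(leafsets[[l]] %in% leafsets[[l2]]), logical(1))),
      logical(1))]
    if (length(kids) < 2L) next
    if (sum(sizes[kids]) != sizes[j]) next  # children must tile the node
    shift <- g[kids][1L]
    if (abs(shift) > tol && all(abs(g[kids] - shift) < tol)) {
      g[j] <- g[j] + shift
      g[kids] <- g[kids] - shift
    }
  }
  g[abs(g) < tol] <- 0
  names(g) <- nm
  g
}

#' Selected subcompositions of a TASSO fit
#'
#' Groups leaves with equal nonzero coefficients into maximal
#' node-aligned components and pairs opposite-signed components into
#' subcompositions by sign balance: the zero-sum constraint means real
#' selection comes in (approximately) cancelling pairs.  Because the
#' constraint must hold exactly, the solution also carries small
#' "slack" components that absorb the imbalance of the dominant pair;
#' these do not balance against anything of comparable size and are
#' returned as a final subcomposition flagged \code{balanced = FALSE}.
#' The detected subcompositions are the balanced ones.
#'
#' @param fit A \code{"tasso_fit"} (or any \code{"treelasso_fit"}).
#' @param tree Optional tree (defaults to the fit's own).
#' @param tol Coefficients below this are treated as zero.
#' @param balance_tol Relative tolerance for pairing: components with
#'   coefficients c1 > 0 > c2 pair when |c1 + c2| <= balance_tol *
#'   max(|c1|, |c2|).
#' @return List of subcompositions; each is a list of components with
#'   \code{node}, \code{leaves} and \code{coefficient}, and carries
#'   attribute \code{"balanced"}.  Empty list for the null fit.
#' @export
extract_subcompositions <- function(fit, tree = NULL, tol = 1e-8,
                                    balance_tol = 0.25) {
  stop_if(!inherits(fit, "treelasso_fit"), "'fit' must be a treelasso_fit")
  tree <- tree %||% fit$tree
  A <- fit$A
  beta <- fit$beta
  nz <- which(abs(beta) > tol)
  if (!length(nz)) return(list())
  leafsets <- lapply(seq_len(ncol(A)), function(j) which(A[, j] > 0))
  sizes <- lengths(leafsets)

  ## group leaves by coefficient value, then tile each group with
  ## maximal node leaf-sets (largest, i.e. shallowest, first)
  vals <- beta[nz]
  grp <- cutree_by_value(vals, tol)
  components <- list()
  for (gid in unique(grp)) {
    leaves_g <- nz[grp == gid]
    coefficient <- mean(beta[leaves_g])
    remaining <- leaves_g
    for (j in order(-sizes)) {
      if (!length(remaining)) break
      ls <- leafsets[[j]]
      if (length(ls) <= length(remaining) && all(ls %in% remaining)) {
        components[[length(components) + 1L]] <- list(
          node = colnames(A)[j],
          leaves = rownames(A)[ls],
          coefficient = coefficient)
        remaining <- setdiff(remaining, ls)
      }
    }
  }

  ## Scale separation: the zero-sum slack lives orders of magnitude
  ## below the genuinely selected components.  Split at the largest
  ## gap in log-magnitude (if it exceeds one order); below-gap
  ## components are constraint slack and are never paired.
  coefs <- vapply(components, function(cp) cp$coefficient, numeric(1))
  slack <- rep(FALSE, length(coefs))
  if (length(coefs) > 1L) {
    o <- order(-abs(coefs))
    lg <- log10(abs(coefs[o]))
    gaps <- lg[-length(lg)] - lg[-1L]
    gi <- which.max(gaps)
    if (gaps[gi] > 1) slack[o[(gi + 1L):length(o)]] <- TRUE
  }

  ## pair opposite-signed components by sign balance, largest first
  paired <- slack          # slack never pairs
  subcomps <- list()
  for (i in order(-abs(coefs))) {
    if (paired[i]) next
    cand <- which(!paired & seq_along(coefs) != i &
                    sign(coefs) == -sign(coefs[i]))
    if (length(cand)) {
      mis <- abs(coefs[cand] + coefs[i]) /
        pmax(abs(coefs[cand]), abs(coefs[i]))
      j <- cand[which.min(mis)]
      if (min(mis) <= balance_tol) {
        paired[c(i, j)] <- TRUE
        subcomps[[length(subcomps) + 1L]] <-
          structure(components[c(i, j)], balanced = TRUE)
      }
    }
  }
  rest <- which(slack | !paired)
  if (length(rest))
    subcomps[[length(subcomps) + 1L]] <-
      structure(components[rest], balanced = FALSE)
  subcomps
}

#' Tree nodes selected by a tree-guided fused lasso fit
#'
#' @param fit A \code{"tfl_fit"}.
#' @param tol Zero threshold on node coefficients.
#' @return Data frame of selected nodes (taxa at their taxonomic level)
#'   with leaf counts and coefficients.
#' @export
selected_taxa <- function(fit, tol = 1e-8) {
  stop_if(!inherits(fit, "treelasso_fit"), "'fit' must be a treelasso_fit")
  nz <- which(abs(fit$gamma) > tol)
  data.frame(node = names(fit$gamma)[nz],
             n_leaves = colSums(fit$A)[nz],
             gamma = unname(fit$gamma[nz]),
             row.names = NULL, stringsAsFactors = FALSE)
}

## group numeric values into equality classes at tolerance tol
#' @noRd
cutree_by_value <- function(v, tol) {
  o <- order(v)
  g <- integer(length(v)); gid <- 1L
  g[o[1L]] <- gid
  if (length(v) > 1L) for (i in 2L:length(v)) {
    if (v[o[i]] - v[o[i - 1L]] > tol) gid <- gid + 1L
    g[o[i]] <- gid
  }
  g
}

#' @export
print.treelasso_fit <- function(x, ...) {
  kind <- if (inherits(x, "tasso_fit")) "TASSO (sparse log-contrast)"
          else "tree-guided fused lasso"
  cat(kind, "fit\n")
  cat(sprintf("  n = %d, lambda = %.5g, nonzero nodes = %d\n",
              x$n, x$lambda, sum(abs(x$gamma) > 1e-8)))
  if (inherits(x, "tasso_fit")) {
    sc <- extract_subcompositions(x)
    nbal <- sum(vapply(sc, function(s) isTRUE(attr(s, "balanced")), logical(1)))
    cat("  detected subcompositions:", nbal, "\n")
  } else {
    cat("  selected taxa:", nrow(selected_taxa(x)), "\n")
  }
  invisible(x)
}

#' @export
coef.treelasso_fit <- function(object, level = c("leaf", "node"), ...) {
  level <- match.arg(level)
  if (level == "leaf") c(`(Intercept)` = object$intercept, object$beta)
  else c(`(Intercept)` = object$intercept, object$gamma)
}

#' @export
predict.treelasso_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  if (inherits(newdata, "ebay")) newdata <- unclass(newdata)
  stop_if(is.null(colnames(newdata)) ||
            !setequal(colnames(newdata), rownames(object$A)),
          "newdata columns must match the training leaf labels")
  newdata <- newdata[, rownames(object$A), drop = FALSE]
  Z <- if (inherits(object, "tasso_fit")) log(newdata) else newdata
  drop(object$intercept + Z %*% object$beta)
}

#' @export
fitted.treelasso_fit <- function(object, ...) object$fitted

#' @export
residuals.treelasso_fit <- function(object, ...) object$y - object$fitted

#' Plot the cross-validation curve or coefficient profile
#'
#' With a CV-tuned fit, plots mean CV error +/- one standard error over
#' the lambda grid, marking lambda_min and lambda_1se; otherwise plots
#' the leaf coefficients.
#' @param x A \code{"treelasso_fit"}.
#' @param ... Passed to the underlying plot call.
#' @export
plot.treelasso_fit <- function(x, ...) {
  if (!is.null(x$cv)) {
    cc <- x$cv$cv_curve
    plot(log(cc$lambda), cc$mean, type = "l", xlab = "log(lambda)",
         ylab = "mean CV error", ...)
    graphics::arrows(log(cc$lambda), cc$mean - cc$se,
                     log(cc$lambda), cc$mean + cc$se,
                     angle = 90, code = 3, length = 0.02, col = "grey")
    graphics::abline(v = log(c(x$cv$lambda_min, x$cv$lambda_1se)),
                     lty = c(2, 3))
  } else {
    graphics::barplot(x$beta, las = 2, ylab = "leaf coefficient", ...)
  }
  invisible(x)
}
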