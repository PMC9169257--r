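## shared small instance: 6-leaf tree, strictly positive compositions
make_instance <- function(seed, n = 30, n_leaves = 6) {
  sim <- simulate_benchmark(seed = seed, n_samples = n, n_leaves = n_leaves,
                            depth_mean = 2000, depth_size = 5)
  comp <- ebay_compositions(sim$data)
  list(x = unclass(comp), y = sim$data$metadata$y, tree = sim$data$tree)
}

test_that("the ancestor matrix realizes root-to-leaf paths", {
  A <- build_ancestor_matrix(tiny_tree())
  expect_equal(unname(A[, "N5"]), c(1, 1, 0))
  expect_true(all(A[cbind(1:3, match(c("A", "B", "C"), colnames(A)))] == 1))

  ## star tree: identity (no internal non-root nodes)
  As <- build_ancestor_matrix(read_newick(text = "(A,B,C);"))
  expect_equal(unname(As), diag(3), ignore_attr = TRUE)

  ## column sums are subtree leaf counts on a random multifurcating tree
  tr <- random_tree(11, seed = 6, shape = "random-multifurcating")
  At <- build_ancestor_matrix(tr)
  idx <- tree_index(tr)
  ids <- attr(At, "node_ids")
  expect_equal(unname(colSums(At)), lengths(idx$leaves[ids]))
})

test_that("a large enough lambda yields the null model", {
  inst <- make_instance(41)
  for (fitter in list(tasso, tree_fused_lasso)) {
    fit <- fitter(inst$x, inst$y, inst$tree, lambda = 1e4)
    expect_equal(unname(fit$gamma), rep(0, length(fit$gamma)))
    expect_equal(fit$intercept, mean(inst$y), tolerance = 1e-10)
    ## and just above the computed lambda_max the fit is already null
    fit2 <- fitter(inst$x, inst$y, inst$tree,
                   lambda = max(fit$lambda_path) * 1.0001)
    expect_equal(unname(fit2$gamma), rep(0, length(fit2$gamma)))
  }
})

test_that("unpenalized TASSO solves constrained least squares", {
  inst <- make_instance(42)
  fit <- tasso(inst$x, inst$y, inst$tree, lambda = 0)
  ## KKT closed form for min ||yc - Zc b||^2 s.t. 1'b = 0
  Z <- log(inst$x); Zc <- scale(Z, scale = FALSE)
  yc <- inst$y - mean(inst$y)
  p <- ncol(Z)
  K <- rbind(cbind(crossprod(Zc), rep(1, p)), c(rep(1, p), 0))
  sol <- solve(K, c(crossprod(Zc, yc), 0))
  expect_equal(unname(fit$beta), unname(sol[1:p]), tolerance = 1e-4)
  expect_equal(sum(fit$beta), 0, tolerance = 1e-8)
})

test_that("unpenalized fused lasso matches least squares on the node design", {
  inst <- make_instance(43)
  fit <- tree_fused_lasso(inst$x, inst$y, inst$tree, lambda = 0)
  oracle <- oracle_penreg(inst$x %*% fit$A, inst$y, 0)
  M <- inst$x %*% fit$A
  expect_equal(oracle_objective(M, inst$y, fit$gamma, fit$intercept, 0),
               oracle$objective, tolerance = 1e-6)
  ## the node design is collinear, so compare fitted values, not gamma
  expect_equal(unname(fit$intercept + drop(M %*% fit$gamma)),
               unname(oracle$intercept + drop(M %*% oracle$gamma)),
               tolerance = 1e-4)
})

test_that("both fitters agree with the proximal-gradient oracle", {
  for (seed in c(51, 52)) {
    inst <- make_instance(seed, n = 50, n_leaves = 8)
    A <- build_ancestor_matrix(inst$tree)
    s <- colSums(A)
    for (constrained in c(TRUE, FALSE)) {
      M <- (if (constrained) log(inst$x) else inst$x) %*% A
      fitter <- if (constrained) tasso else tree_fused_lasso
      fit0 <- fitter(inst$x, inst$y, inst$tree, lambda = 1e4)
      for (frac in c(0.5, 0.1, 0.01)) {
        lam <- max(fit0$lambda_path) * frac
        fit <- fitter(inst$x, inst$y, inst$tree, lambda = lam)
        orc <- oracle_penreg(M, inst$y, lam, s = if (constrained) s else NULL)
        obj_fit <- oracle_objective(M, inst$y, fit$gamma, fit$intercept, lam)
        obj_orc <- oracle_objective(M, inst$y, orc$gamma, orc$intercept, lam)
        expect_equal(obj_fit, obj_orc, tolerance = 1e-6)
        if (constrained) {
          ## the zero-sum constraint identifies beta
          expect_equal(unname(drop(A %*% fit$gamma)),
                       unname(drop(A %*% orc$gamma)), tolerance = 1e-4)
        } else {
          ## compositional X sums to 1, so beta is identified only up to
          ## a constant shift absorbed by the intercept: compare the
          ## identified predictions instead
          expect_equal(unname(fit$intercept + drop(M %*% fit$gamma)),
                       unname(orc$intercept + drop(M %*% orc$gamma)),
                       tolerance = 1e-4)
        }
      }
    }
  }
})

test_that("TASSO is invariant to per-sample rescaling of the composition", {
  inst <- make_instance(44)
  lam <- 0.1
  f1 <- tasso(inst$x, inst$y, inst$tree, lambda = lam)
  x2 <- inst$x
  x2[3, ] <- x2[3, ] * 50          # unclosed rescaling of one sample
  x2[7, ] <- x2[7, ] * 0.01
  f2 <- tasso(x2, inst$y, inst$tree, lambda = lam)
  expect_equal(f2$gamma, f1$gamma, tolerance = 1e-6)
})

test_that("the fused lasso accepts exact zeros", {
  inst <- make_instance(45)
  x <- inst$x
  x[x < stats::quantile(x, 0.2)] <- 0
  x <- x / rowSums(x)
  fit <- tree_fused_lasso(x, inst$y, inst$tree, lambda = 0.01)
  expect_true(all(is.finite(fit$beta)))
  expect_true(all(is.finite(fit$fitted)))
  expect_error(tasso(x, inst$y, inst$tree, lambda = 0.01), "positive")
})

test_that("leave-one-out cross-validation matches a brute-force loop", {
  inst <- make_instance(46, n = 10)
  grid <- exp(seq(log(2), log(0.02), length.out = 8))
  cv <- cross_validate(inst$x, inst$y, inst$tree, method = "tasso",
                       lambda_grid = grid, k_folds = 10, seed = 3)
  brute <- matrix(NA_real_, 10, length(grid))
  for (i in 1:10) {
    for (l in seq_along(grid)) {
      fit <- tasso(inst$x[-i, ], inst$y[-i], inst$tree, lambda = grid[l])
      brute[i, l] <- (inst$y[i] - predict(fit, inst$x[i, , drop = FALSE]))^2
    }
  }
  expect_equal(cv$cv_curve$mean, colMeans(brute), tolerance = 1e-6)
  expect_equal(cv$lambda_min, grid[which.min(colMeans(brute))])
})

test_that("cross-validation output is well-formed", {
  inst <- make_instance(47, n = 24)
  cv <- cross_validate(inst$x, inst$y, inst$tree, method = "fused",
                       k_folds = 4, seed = 5)
  expect_equal(nrow(cv$cv_curve), 100L)
  expect_true(all(cv$cv_curve$se >= 0))
  expect_gte(cv$lambda_1se, cv$lambda_min)
  expect_error(cross_validate(inst$x, inst$y, inst$tree, k_folds = 1, seed = 1),
               "k_folds")
  expect_error(cross_validate(inst$x, inst$y, inst$tree,
                              lambda_grid = numeric(0), k_folds = 4, seed = 1),
               "empty")
})

test_that("the active set shrinks along the regularization path", {
  inst <- make_instance(48, n = 40, n_leaves = 8)
  pin <- mbtree:::penreg_inputs(inst$x, inst$y, inst$tree, log_transform = TRUE)
  s <- colSums(pin$A); w <- rep(1, ncol(pin$A))
  mbar <- colMeans(pin$M)
  cvec <- drop(crossprod(sweep(pin$M, 2, mbar), inst$y - mean(inst$y))) / nrow(pin$M)
  grid <- mbtree:::default_lambda_grid(
    mbtree:::lambda_max_value(cvec, s, w, TRUE))
  path <- mbtree:::penreg_path(pin$M, inst$y, s, w, grid, TRUE)
  nnz <- colSums(abs(path$gamma) > 1e-8)
  expect_equal(nnz[1L], 0L, ignore_attr = TRUE)   # null at lambda_max
  ## statistically monotone along the descending grid: growth dominates,
  ## occasional local swaps of collinear nodes are tolerated
  expect_lte(mean(diff(nnz) < 0), 0.1)
  expect_gt(nnz[length(nnz)], nnz[1L])
})

test_that("subcomposition extraction maps coefficients to tree nodes", {
  tr <- read_newick(text = "(((A,B),(C,D)),(E,F));")
  ## a two-leaf contrast
  f1 <- fake_tasso_fit(tr, c(A = 2, B = -2))
  sc1 <- extract_subcompositions(f1)
  expect_length(sc1, 1L)
  expect_true(isTRUE(attr(sc1[[1L]], "balanced")))
  expect_setequal(vapply(sc1[[1L]], `[[`, "", "node"), c("A", "B"))

  ## the null fit selects nothing
  expect_length(extract_subcompositions(fake_tasso_fit(tr, c(A = 0))), 0L)

  ## internal nodes with opposite gamma form a subtree-level subcomposition
  idx <- tree_index(tr)
  nodeAB <- idx$node_name[idx$parent[match("A", tr$tip.label)]]
  nodeEF <- idx$node_name[idx$parent[match("E", tr$tip.label)]]
  g <- setNames(c(1.2, -1.2), c(nodeAB, nodeEF))
  sc2 <- extract_subcompositions(fake_tasso_fit(tr, g))
  expect_length(sc2, 1L)
  comps <- sc2[[1L]]
  leaves <- lapply(comps, `[[`, "leaves")
  expect_setequal(vapply(comps, `[[`, "", "node"), c(nodeAB, nodeEF))
  expect_true(setequal(leaves[[1L]], c("A", "B")) ||
                setequal(leaves[[1L]], c("E", "F")))
})

test_that("fused-lasso selection reports taxa at internal levels", {
  tr <- read_newick(text = "(((A,B),(C,D)),(E,F));")
  idx <- tree_index(tr)
  nodeAB <- idx$node_name[idx$parent[match("A", tr$tip.label)]]
  f <- fake_tasso_fit(tr, setNames(3, nodeAB))
  class(f) <- c("tfl_fit", "treelasso_fit")
  sel <- selected_taxa(f)
  expect_equal(sel$node, nodeAB)
  expect_equal(sel$n_leaves, 2)
  ## beta is fused (constant) on the node's leaves
  expect_equal(unname(f$beta[c("A", "B")]), c(3, 3))
})

test_that("fit accessors and the CV plot are well-behaved", {
  inst <- make_instance(49, n = 24)
  fit <- tasso(inst$x, inst$y, inst$tree, lambda = "cv", k_folds = 4, seed = 2)
  expect_equal(fitted(fit), predict(fit))
  expect_equal(residuals(fit), inst$y - fitted(fit))
  expect_equal(unname(coef(fit, "leaf")[-1L]),
               unname(drop(fit$A %*% coef(fit, "node")[-1L])))
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(fit))
})
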