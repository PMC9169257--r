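## a fit object with fixed hyper-parameters, bypassing evidence maximization
fixed_fit <- function(alpha, pi = NULL) {
  structure(list(alpha = alpha, pi = pi, type = "mle"), class = "dtm_fit")
}

test_that("posterior means follow Dirichlet-multinomial conjugacy", {
  ## single node, alpha = (1,1), counts (3,1): posterior mean (2/3, 1/3)
  star <- read_newick(text = "(A,B);")
  d <- microbiome_data(matrix(c(3, 1), 1, dimnames = list("s", c("A", "B"))), star)
  comp <- ebay_compositions(d, fit = fixed_fit(list(N3 = c(A = 1, B = 1))))
  expect_equal(unname(comp[1, ]), c(2 / 3, 1 / 3), tolerance = 1e-12)

  ## worked 3-leaf example with unit alpha everywhere
  d3 <- microbiome_data(matrix(c(2, 0, 2), 1, dimnames = list("s", c("A", "B", "C"))),
                        tiny_tree())
  comp3 <- ebay_compositions(
    d3, fit = fixed_fit(list(N4 = c(N5 = 1, C = 1), N5 = c(A = 1, B = 1))))
  expect_equal(unname(comp3[1, ]), c(0.375, 0.125, 0.5), tolerance = 1e-12)
})

test_that("conjugate branch mean matches numerical integration", {
  ## Beta posterior: E[p | y] via quadrature against the closed form
  a <- c(1.7, 0.6); y <- c(4, 2)
  num <- integrate(function(p) p * p^(a[1] + y[1] - 1) * (1 - p)^(a[2] + y[2] - 1),
                   0, 1, rel.tol = 1e-12)$value
  den <- integrate(function(p) p^(a[1] + y[1] - 1) * (1 - p)^(a[2] + y[2] - 1),
                   0, 1, rel.tol = 1e-12)$value
  expect_equal((a[1] + y[1]) / sum(a + y), num / den, tolerance = 1e-8)
})

test_that("compositions are closed, positive, and shrink toward the prior", {
  sim <- simulate_benchmark(seed = 31, n_samples = 30, n_leaves = 8,
                            depth_mean = 300, depth_size = 2)
  d <- sim$data
  comp <- ebay_compositions(d)
  expect_equal(unname(rowSums(comp)), rep(1, nrow(comp)), tolerance = 1e-10)
  ## zero-count taxa still get positive posterior abundance
  expect_true(all(comp > 0))

  ## shrinkage direction at every node: posterior branch probability lies
  ## between the empirical proportion and the prior mean
  fit <- attr(comp, "fit")
  nc <- aggregate_node_counts(d)
  bp <- mbtree:::branch_posterior_means(nc, fit)
  for (v in names(nc$Y)) {
    Y <- nc$Y[[v]]; a <- fit$alpha[[v]]
    prior <- a / sum(a)
    for (i in which(rowSums(Y) > 0)) {
      emp <- Y[i, ] / sum(Y[i, ])
      lo <- pmin(emp, prior) - 1e-12; hi <- pmax(emp, prior) + 1e-12
      expect_true(all(bp[[v]][i, ] >= lo & bp[[v]][i, ] <= hi))
    }
  }
})

test_that("depth limits recover the empirical and prior proportions", {
  tr <- tiny_tree()
  alpha <- list(N4 = c(N5 = 2, C = 1), N5 = c(A = 1, B = 3))
  ## deep sample: empirical proportions dominate the prior
  p_emp <- c(0.5, 0.3, 0.2)
  deep <- microbiome_data(
    matrix(1e7 * p_emp, 1, dimnames = list("s", c("A", "B", "C"))), tr)
  comp <- ebay_compositions(deep, fit = fixed_fit(alpha))
  expect_equal(unname(comp[1, ]), p_emp, tolerance = 1e-5)

  ## empty sample: the prior mean flows down the tree
  empty <- microbiome_data(
    matrix(0, 1, 3, dimnames = list("s", c("A", "B", "C"))), tr)
  comp0 <- ebay_compositions(empty, fit = fixed_fit(alpha))
  expect_equal(unname(comp0[1, ]), c(2 / 3 * 1 / 4, 2 / 3 * 3 / 4, 1 / 3),
               tolerance = 1e-12)
})

test_that("leaf abundances are path products of branch probabilities", {
  tr <- tiny_tree()
  bp <- list(N4 = matrix(c(0.6, 0.4), 1, dimnames = list(NULL, c("N5", "C"))),
             N5 = matrix(c(0.5, 0.5), 1, dimnames = list(NULL, c("A", "B"))))
  expect_equal(unname(posterior_leaf_abundance(tr, bp)[1, ]), c(0.3, 0.3, 0.4))

  ## uniform branch probabilities are uniform leaves only on balanced trees
  bal <- read_newick(text = "((A,B),(C,D));")
  bpu <- list(N5 = matrix(0.5, 1, 2), N6 = matrix(0.5, 1, 2),
              N7 = matrix(0.5, 1, 2))
  names(bpu) <- names(aggregate_node_counts(
    microbiome_data(matrix(1, 1, 4, dimnames = list(NULL, bal$tip.label)), bal))$Y)
  expect_equal(unname(posterior_leaf_abundance(bal, bpu)[1, ]), rep(0.25, 4))
  bp3 <- list(N4 = matrix(0.5, 1, 2), N5 = matrix(0.5, 1, 2))
  expect_equal(unname(posterior_leaf_abundance(tr, bp3)[1, ]), c(0.25, 0.25, 0.5))

  ## star tree: identity
  star <- read_newick(text = "(A,B,C);")
  bps <- list(N4 = matrix(c(0.2, 0.3, 0.5), 1))
  expect_equal(unname(posterior_leaf_abundance(star, bps)[1, ]), c(0.2, 0.3, 0.5))
})

test_that("zero-inflated eBay splits mass between absence and shrinkage", {
  set.seed(13)
  star <- read_newick(text = "(A,B);")
  n <- 80
  absent <- runif(n) < 0.5
  y1 <- ifelse(absent, 0, rbinom(n, 50, 0.4))
  cnt <- cbind(A = y1, B = 50 - y1)
  d <- microbiome_data(cnt, star)
  compz <- ebay_compositions(d, prior = "zidtm")
  expect_equal(unname(rowSums(compz)), rep(1, n), tolerance = 1e-10)
  ## zero-count samples sit well below the plain conjugate mean
  comp <- ebay_compositions(d, prior = "dtm")
  zi_zero_mean <- mean(compz[y1 == 0, "A"])
  plain_zero_mean <- mean(comp[y1 == 0, "A"])
  expect_lt(zi_zero_mean, 0.5 * plain_zero_mean)
  ## positive-count samples: present set is forced, so the estimate is
  ## the plain conjugate mean under the ZI fit's own hyper-parameters
  zfit <- attr(compz, "fit")
  a <- zfit$alpha[[1L]]
  i <- which(y1 > 0)
  expect_equal(unname(compz[i, "A"]),
               unname((a[1] + y1[i]) / (sum(a) + 50)), tolerance = 1e-10)
})
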