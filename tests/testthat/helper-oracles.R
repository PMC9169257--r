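## Independent solvers and reference computations used only as test
## oracles.  They deliberately share no code path with the package:
## direct gamma-function DM evaluation, grid searches, enumeration, and
## a proximal-gradient (FISTA) solver for the penalized regressions.

## --- Dirichlet-multinomial pmf via plain gamma functions -------------
oracle_dm_pmf <- function(y, alpha) {
  n <- sum(y)
  exp(lgamma(n + 1) - sum(lgamma(y + 1))) *
    gamma(sum(alpha)) / gamma(sum(alpha) + n) *
    prod(gamma(alpha + y) / gamma(alpha))
}

## all count vectors of length k with sum n
oracle_enumerate_counts <- function(n, k) {
  if (k == 1L) return(matrix(n, 1, 1))
  out <- NULL
  for (i in 0:n) {
    rest <- oracle_enumerate_counts(n - i, k - 1L)
    out <- rbind(out, cbind(i, rest))
  }
  unname(out)
}

## overflow-safe DM log pmf for the fit oracle
oracle_dm_logpmf <- function(y, alpha) {
  n <- sum(y)
  lgamma(n + 1) - sum(lgamma(y + 1)) +
    lgamma(sum(alpha)) - lgamma(sum(alpha) + n) +
    sum(lgamma(alpha + y)) - sum(lgamma(alpha))
}

## grid + polish maximizer of the DM likelihood over (0, 50]^2
oracle_fit_dm2 <- function(Y, grid_max = 50, step = 0.5) {
  ll <- function(a) sum(apply(Y, 1L, oracle_dm_logpmf, alpha = a))
  g <- as.matrix(expand.grid(a1 = seq(step, grid_max, by = step),
                             a2 = seq(step, grid_max, by = step)))
  vals <- apply(g, 1L, ll)
  best <- g[which.max(vals), ]
  ## polish with a quasi-Newton ascent on log alpha using numerical
  ## derivatives (the optimum may sit far outside the grid, e.g. on the
  ## multinomial boundary alpha -> infinity)
  polish <- optim(log(best), function(th) -ll(exp(th)), method = "L-BFGS-B",
                  lower = -20, upper = 20,
                  control = list(maxit = 2000, factr = 1e1))
  list(alpha = exp(polish$par), loglik = ll(exp(polish$par)))
}

## --- proximal-gradient (FISTA) oracle for the penalized fits ---------
## prox of lambda*||g||_1 restricted to {s'g = 0}: soft-threshold after
## shifting by nu*s, with nu found by bisection on the monotone map
## nu -> s' soft(z - nu*s, lambda)
oracle_prox_constrained <- function(z, s, lambda) {
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
  f <- function(nu) sum(s * soft(z - nu * s, lambda))
  lo <- min((z - lambda) / s) - 1; hi <- max((z + lambda) / s) + 1
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  soft(z - (lo + hi) / 2 * s, lambda)
}

## minimize (1/2n)||yc - Mc g||^2 + lambda||g||_1  (+ s'g = 0 if constrained)
oracle_penreg <- function(M, y, lambda, s = NULL, maxit = 50000, tol = 1e-12) {
  n <- nrow(M)
  mbar <- colMeans(M); Mc <- sweep(M, 2, mbar)
  ybar <- mean(y); yc <- y - ybar
  L <- max(eigen(crossprod(Mc) / n, symmetric = TRUE, only.values = TRUE)$values)
  q <- ncol(M)
  g <- rep(0, q); v <- g; t_k <- 1
  obj <- function(g) sum((yc - Mc %*% g)^2) / (2 * n) + lambda * sum(abs(g))
  last <- Inf
  for (it in seq_len(maxit)) {
    grad <- -crossprod(Mc, yc - Mc %*% v) / n
    z <- v - grad / L
    gn <- if (is.null(s)) sign(z) * pmax(abs(z) - lambda / L, 0)
          else oracle_prox_constrained(drop(z), s, lambda / L)
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    v <- gn + ((t_k - 1) / t_new) * (gn - g)
    g <- gn; t_k <- t_new
    if (it %% 100 == 0) {
      o <- obj(g)
      if (abs(last - o) < tol * (1 + abs(o))) break
      last <- o
    }
  }
  list(gamma = drop(g), beta = NULL, intercept = ybar - sum(mbar * g),
       objective = obj(g))
}

## objective of the package's fits, computed independently
oracle_objective <- function(M, y, gamma, intercept, lambda) {
  sum((y - intercept - M %*% gamma)^2) / (2 * nrow(M)) + lambda * sum(abs(gamma))
}
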