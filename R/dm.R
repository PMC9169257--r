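## Dirichlet-multinomial (DM) building blocks.
##
## The DM is the compound distribution of multinomial counts whose
## probability vector is Dirichlet(alpha):
##   P(y | alpha) = C(n; y) * Gamma(A)/Gamma(A+n) * prod_j Gamma(a_j+y_j)/Gamma(a_j),
## with n = sum(y), A = sum(alpha).  Every model in the package reduces to
## sums of DM log-likelihoods over the internal nodes of the tree.

#' Dirichlet-multinomial log probability
#'
#' @param y Non-negative integer count vector (length >= 2), or a matrix
#'   with one count vector per row.
#' @param alpha Strictly positive Dirichlet parameter vector, recycled
#'   across rows when \code{y} is a matrix.
#' @return The log pmf; a vector with one entry per row when \code{y} is
#'   a matrix.  A row of all zeros has probability 1 (log 0\eqn{=}0).
#' @examples
#' dm_logpmf(c(3, 2), c(1, 1))   # log(1/6): unit-alpha DM is uniform
#' @export
dm_logpmf <- function(y, alpha) {
  if (!is.matrix(y)) y <- matrix(y, nrow = 1L)
  stop_if(ncol(y) < 2L, "need at least 2 categories")
  stop_if(length(alpha) != ncol(y), "length(alpha) must match ncol(y)")
  stop_if(any(!is.finite(alpha)) || any(alpha <= 0), "alpha must be positive and finite")
  stop_if(any(y < 0) || any(abs(y - round(y)) > 1e-8), "y must be non-negative integers")
  dm_logpmf_mat(y, alpha)
}

## vectorized core, no validation
#' @noRd
dm_logpmf_mat <- function(Y, alpha) {
  n <- rowSums(Y)
  A <- sum(alpha)
  lgamma(n + 1) - rowSums(lgamma(Y + 1)) +
    lgamma(A) - lgamma(A + n) +
    rowSums(lgamma(sweep(Y, 2L, alpha, "+"))) - sum(lgamma(alpha))
}

## gradient of sum_i log DM(y_i | alpha) wrt alpha
#' @noRd
dm_grad <- function(Y, alpha) {
  n <- rowSums(Y)
  A <- sum(alpha)
  common <- sum(digamma(A) - digamma(A + n))
  colSums(digamma(sweep(Y, 2L, alpha, "+"))) - nrow(Y) * digamma(alpha) + common
}

## method-of-moments initializer: match mean proportions and, through the
## precision A = sum(alpha), the overdispersion of observed proportions
#' @noRd
dm_moment_init <- function(Y) {
  n <- rowSums(Y)
  keep <- n > 0
  Yp <- Y[keep, , drop = FALSE]
  np <- n[keep]
  P <- Yp / np
  p <- colMeans(P)
  p <- pmax(p, 1e-6); p <- p / sum(p)
  A0 <- 1
  if (nrow(Yp) >= 3L) {
    nbar <- mean(np)
    v <- apply(P, 2L, stats::var)
    ev <- p * (1 - p)
    ok <- ev > 1e-10 & v > 0
    if (any(ok)) {
      cc <- v[ok] / ev[ok]                       # ~ (nbar + A)/(nbar (1 + A))
      a0 <- nbar * (1 - cc) / (cc * nbar - 1)
      a0 <- a0[is.finite(a0) & a0 > 0]
      if (length(a0)) A0 <- stats::median(a0)
    }
  }
  A0 <- min(max(A0, 1e-2), 1e4)
  pmax(A0 * p, 1e-4)
}

#' Fit a Dirichlet-multinomial by (penalized) maximum likelihood
#'
#' Maximizes \eqn{\sum_i \log DM(y_i \mid \alpha) - \lambda \|\log\alpha\|^2}
#' over \eqn{\alpha > 0} by quasi-Newton ascent on \eqn{\log\alpha}
#' (unconstrained), started from a method-of-moments estimate.  The ridge
#' on \eqn{\log\alpha} shrinks toward the uniform prior \eqn{\alpha = 1}
#' and keeps estimates off the boundary; the default is no penalty.
#'
#' @param y Count matrix, one sample per row (rows whose total is zero
#'   contribute nothing and are dropped).
#' @param penalty Non-negative ridge weight on \eqn{\log\alpha}.
#' @param weights Optional non-negative per-row case weights.
#' @param init Optional starting \eqn{\alpha}.
#' @param control List: \code{maxit} (default 500).
#' @return List with \code{alpha}, \code{loglik} (unpenalized, at the
#'   optimum), \code{objective}, \code{converged}, \code{iterations}.
#' @examples
#' fit_dm(rbind(c(3, 1), c(2, 2), c(4, 0)))$alpha
#' @export
fit_dm <- function(y, penalty = 0, weights = NULL, init = NULL,
                   control = list()) {
  if (!is.matrix(y)) y <- matrix(y, nrow = 1L)
  stop_if(ncol(y) < 2L, "need at least 2 categories")
  stop_if(penalty < 0, "'penalty' must be non-negative")
  w <- weights %||% rep(1, nrow(y))
  stop_if(length(w) != nrow(y) || any(w < 0), "invalid weights")
  keep <- rowSums(y) > 0 & w > 0
  stop_if(!any(keep), "all rows have zero total count")
  Y <- y[keep, , drop = FALSE]
  w <- w[keep]
  k <- ncol(Y)
  maxit <- control$maxit %||% 500L

  wl <- function(alpha) sum(w * dm_logpmf_mat(Y, alpha))
  wg <- function(alpha) {
    n <- rowSums(Y); A <- sum(alpha)
    common <- sum(w * (digamma(A) - digamma(A + n)))
    colSums(w * digamma(sweep(Y, 2L, alpha, "+"))) -
      sum(w) * digamma(alpha) + common
  }
  negobj <- function(theta) {
    a <- exp(theta)
    -(wl(a) - penalty * sum(theta^2))
  }
  neggrad <- function(theta) {
    a <- exp(theta)
    -(a * wg(a) - 2 * penalty * theta)
  }

  ## |log alpha| is boxed at 20: far beyond any plausible precision, and
  ## it keeps lgamma(A) - lgamma(A + n) away from catastrophic
  ## cancellation (which would otherwise fake a perfect likelihood)
  bnd <- 20
  a0 <- init %||% dm_moment_init(Y)
  a0 <- pmax(pmin(a0, exp(bnd - 1)), exp(-bnd + 1))
  opt <- stats::optim(log(a0), negobj, neggrad, method = "L-BFGS-B",
                      lower = -bnd, upper = bnd,
                      control = list(maxit = maxit, factr = 1e4))
  ## fall back to the uniform start if the moment start landed badly
  opt2 <- stats::optim(rep(0, k), negobj, neggrad, method = "L-BFGS-B",
                       lower = -bnd, upper = bnd,
                       control = list(maxit = maxit, factr = 1e4))
  if (opt2$value < opt$value) opt <- opt2
  alpha <- exp(opt$par)
  names(alpha) <- colnames(y)
  list(alpha = alpha,
       loglik = wl(alpha),
       objective = -opt$value,
       converged = opt$convergence == 0L,
       iterations = opt$counts[["function"]])
}
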