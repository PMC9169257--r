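## Dirichlet-tree multinomial (DTM) fitting.
##
## The DTM factorizes over the internal nodes of the phylogeny: counts
## entering a node are split among its children by an independent DM.
## Fitting therefore decomposes into independent per-node DM problems;
## a log link attaches sample covariates to the node-level Dirichlet
## parameters, and a zero-inflated variant (see zidtm.R) adds per-branch
## structural-zero probabilities.

#' Dirichlet-tree multinomial log-likelihood
#'
#' Sum over samples and internal nodes of the per-node DM log pmf.
#' Samples whose count entering a node is zero contribute nothing to
#' that node's factor.
#'
#' @param table A \code{"node_counts"} object (see
#'   \code{\link{aggregate_node_counts}}).
#' @param params Named list of positive Dirichlet parameter vectors, one
#'   per internal node of the table, with matching child counts.
#' @return The total log-likelihood, with per-node contributions in
#'   attribute \code{"by_node"}.
#' @export
dtm_loglik <- function(table, params) {
  stop_if(!inherits(table, "node_counts"), "'table' must be node_counts")
  nm <- names(table$Y)
  stop_if(!all(nm %in% names(params)),
          "params missing nodes: ",
          paste(setdiff(nm, names(params)), collapse = ", "))
  by_node <- vapply(nm, function(v) {
    a <- params[[v]]
    stop_if(length(a) != ncol(table$Y[[v]]),
            "alpha length mismatch at node ", v)
    sum(dm_logpmf_mat(table$Y[[v]], a))
  }, numeric(1))
  structure(sum(by_node), by_node = by_node)
}

#' Fit a (zero-inflated) Dirichlet-tree multinomial model
#'
#' Fits one DM factor per internal node of the phylogeny.  Three model
#' forms are available:
#' \itemize{
#'   \item \code{formula = NULL, zero_inflated = FALSE}: per-node
#'     (penalized) maximum likelihood for the Dirichlet parameters.
#'   \item \code{formula} given: per-node DM regression through a log
#'     link, \eqn{\alpha_v(x) = \exp(\beta_v^\top [1, x])}, with per-node
#'     Wald standard errors and a likelihood-ratio test against the
#'     intercept-only model (raw and BH-adjusted p-values).
#'   \item \code{zero_inflated = TRUE}: per-node zero-inflated DM fitted
#'     by EM, with a structural-absence probability per child branch.
#' }
#'
#' @param data A \code{"microbiome_data"} or \code{"node_counts"} object.
#' @param formula Optional one-sided formula over metadata columns,
#'   e.g. \code{~ bmi}; requires metadata.
#' @param zero_inflated Fit the zero-inflated variant (not combinable
#'   with \code{formula}).
#' @param penalty Non-negative ridge on \eqn{\log\alpha} (see
#'   \code{\link{fit_dm}}).
#' @param control Optimizer/EM settings passed down (\code{maxit},
#'   \code{reltol}, \code{em_maxit}, \code{em_tol}).
#' @return An object of class \code{"dtm_fit"} with components
#'   \code{alpha} (list per node), and depending on the form \code{pi},
#'   \code{beta}, \code{se}, \code{tests}; plus \code{report}
#'   (log-likelihood, per-node contributions, convergence), \code{tree},
#'   \code{node_names}.
#' @examples
#' tr <- read_newick(text = "((A,B),C);")
#' y <- matrix(rpois(30, 20), 10, 3, dimnames = list(NULL, c("A", "B", "C")))
#' fit <- fit_dtm(microbiome_data(y, tr))
#' coef(fit)
#' @export
fit_dtm <- function(data, formula = NULL, zero_inflated = FALSE,
                    penalty = 0, control = list()) {
  if (inherits(data, "microbiome_data")) {
    table <- aggregate_node_counts(data)
    metadata <- data$metadata
  } else if (inherits(data, "node_counts")) {
    table <- data
    metadata <- NULL
  } else stop("'data' must be microbiome_data or node_counts", call. = FALSE)
  stop_if(!is.null(formula) && zero_inflated,
          "zero-inflated DTM regression is not supported")

  nodes <- names(table$Y)
  if (!is.null(formula)) {
    if (inherits(data, "microbiome_data")) {
      stop_if(is.null(metadata), "formula fitting requires metadata")
      X <- stats::model.matrix(formula, metadata)
    } else stop("formula fitting requires a microbiome_data object", call. = FALSE)
    stop_if(qr(X)$rank < ncol(X), "design matrix is rank deficient")
    fits <- lapply(nodes, function(v)
      fit_dm_reg_node(table$Y[[v]], X, control = control))
    names(fits) <- nodes
    tests <- do.call(rbind, lapply(nodes, function(v) {
      f <- fits[[v]]
      data.frame(node = v, lrt = f$lrt, df = f$df,
                 p_value = f$p_value, stringsAsFactors = FALSE)
    }))
    tests$p_adj <- stats::p.adjust(tests$p_value, "BH")
    out <- list(type = "regression",
                alpha = lapply(fits, function(f) f$alpha0),
                beta = lapply(fits, function(f) f$beta),
                se = lapply(fits, function(f) f$se),
                tests = tests,
                formula = formula,
                design_names = colnames(X))
    ll <- vapply(fits, function(f) f$loglik, numeric(1))
    iters <- max(vapply(fits, function(f) f$iterations, numeric(1)))
    conv <- all(vapply(fits, function(f) f$converged, logical(1)))
  } else if (zero_inflated) {
    fits <- lapply(nodes, function(v) fit_zidm_node(table$Y[[v]], control))
    names(fits) <- nodes
    out <- list(type = "zidtm",
                alpha = lapply(fits, function(f) f$alpha),
                pi = lapply(fits, function(f) f$pi),
                em_trace = lapply(fits, function(f) f$trace))
    ll <- vapply(fits, function(f) f$loglik, numeric(1))
    iters <- max(vapply(fits, function(f) length(f$trace), numeric(1)))
    conv <- all(vapply(fits, function(f) f$converged, logical(1)))
  } else {
    fits <- lapply(nodes, function(v)
      fit_dm(table$Y[[v]], penalty = penalty, control = control))
    names(fits) <- nodes
    out <- list(type = "mle",
                alpha = lapply(fits, function(f) f$alpha),
                penalty = penalty)
    ll <- vapply(fits, function(f) f$loglik, numeric(1))
    iters <- max(vapply(fits, function(f) f$iterations, numeric(1)))
    conv <- all(vapply(fits, function(f) f$converged, logical(1)))
  }

  names(ll) <- nodes
  out$report <- list(log_likelihood = sum(ll), by_node = ll,
                     n_iterations = iters, converged = conv)
  out$tree <- table$tree
  out$index <- table$index
  out$node_names <- nodes
  out$call <- match.call()
  class(out) <- "dtm_fit"
  out
}

## per-node DM regression with log link alpha(x) = exp(B' [1, x])
#' @noRd
fit_dm_reg_node <- function(Y, X, control = list()) {
  keep <- rowSums(Y) > 0
  Yk <- Y[keep, , drop = FALSE]
  Xk <- X[keep, , drop = FALSE]
  k <- ncol(Y); q <- ncol(X)
  maxit <- control$maxit %||% 500L

  ## the linear predictor is clamped: beyond |eta| = 20 the likelihood
  ## is flat to numerical precision and lgamma differences cancel badly
  ll_fun <- function(B) {        # B is q x k
    A <- exp(pmin(pmax(Xk %*% B, -20), 20))   # n x k per-sample alpha
    n <- rowSums(Yk); As <- rowSums(A)
    sum(lgamma(n + 1) - rowSums(lgamma(Yk + 1)) +
        lgamma(As) - lgamma(As + n) +
        rowSums(lgamma(A + Yk) - lgamma(A)))
  }
  grad_fun <- function(B) {
    A <- exp(pmin(pmax(Xk %*% B, -20), 20))
    n <- rowSums(Yk); As <- rowSums(A)
    G <- (digamma(As) - digamma(As + n)) + digamma(A + Yk) - digamma(A)
    crossprod(Xk, A * G)         # q x k
  }
  fit_with_ridge <- function(r) {
    neg <- function(b) {
      B <- matrix(b, q, k)
      v <- -(ll_fun(B) - r * sum(b[-seq_len(k)]^2))
      if (!is.finite(v)) 1e10 else v
    }
    ngr <- function(b) {
      B <- matrix(b, q, k)
      g <- -grad_fun(B)
      g[-1L, ] <- g[-1L, ] + 2 * r * B[-1L, , drop = FALSE]
      as.vector(g)
    }
    a0 <- fit_dm(Yk)$alpha
    b0 <- rbind(log(a0), matrix(0, q - 1L, k))
    stats::optim(as.vector(b0), neg, ngr, method = "BFGS",
                 control = list(maxit = maxit, reltol = 1e-12))
  }
  opt <- fit_with_ridge(0)
  ridged <- FALSE
  if (opt$convergence != 0 || !is.finite(opt$value) ||
      any(abs(opt$par) > 30)) {
    opt <- fit_with_ridge(1e-3)          # separation-like divergence fallback
    ridged <- TRUE
  }
  B <- matrix(opt$par, q, k,
              dimnames = list(colnames(X), colnames(Y)))
  ## observed information (numerical Hessian of the negative log-likelihood)
  H <- stats::optimHess(opt$par, function(b) -ll_fun(matrix(b, q, k)))
  se <- tryCatch({
    V <- solve(H)
    matrix(sqrt(pmax(diag(V), 0)), q, k,
           dimnames = dimnames(B))
  }, error = function(e) matrix(NA_real_, q, k, dimnames = dimnames(B)))

  ll_full <- ll_fun(B)
  null_fit <- fit_dm(Yk)
  ll0 <- null_fit$loglik
  df <- (q - 1L) * k
  lrt <- max(0, 2 * (ll_full - ll0))
  list(beta = B, se = se, alpha0 = null_fit$alpha,
       loglik = ll_full, lrt = lrt, df = df,
       p_value = stats::pchisq(lrt, df, lower.tail = FALSE),
       converged = opt$convergence == 0L, ridged = ridged,
       iterations = opt$counts[["function"]])
}

#' @export
print.dtm_fit <- function(x, ...) {
  lab <- switch(x$type, mle = "Dirichlet-tree multinomial (ML)",
                regression = "Dirichlet-tree multinomial regression",
                zidtm = "zero-inflated Dirichlet-tree multinomial (EM)")
  cat(lab, "\n")
  cat(sprintf("  %d internal nodes; log-likelihood %.4f; %s\n",
              length(x$node_names), x$report$log_likelihood,
              if (x$report$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
summary.dtm_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.dtm_fit")
}

#' @export
print.summary.dtm_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  if (f$type == "regression") {
    cat("\nPer-node likelihood-ratio tests vs intercept-only:\n")
    print(f$tests, row.names = FALSE, digits = 4)
  } else {
    cat("\nPer-node Dirichlet parameters:\n")
    for (v in f$node_names) {
      cat(" ", v, ":", paste(sprintf("%s=%.3g", names(f$alpha[[v]]),
                                     f$alpha[[v]]), collapse = ", "))
      if (!is.null(f$pi))
        cat("  pi:", paste(sprintf("%.3g", f$pi[[v]]), collapse = ", "))
      cat("\n")
    }
  }
  invisible(x)
}

#' @export
coef.dtm_fit <- function(object, ...) {
  if (object$type == "regression") object$beta else object$alpha
}

#' @export
logLik.dtm_fit <- function(object, ...) {
  npar <- switch(object$type,
    mle = sum(lengths(object$alpha)),
    regression = sum(vapply(object$beta, length, integer(1))),
    zidtm = sum(lengths(object$alpha)) +
      sum(vapply(object$pi, function(p) sum(p > 0), numeric(1))))
  structure(object$report$log_likelihood, df = npar,
            nobs = NA_integer_, class = "logLik")
}

#' Simulate count datasets from a fitted DTM model
#'
#' Draws new count matrices from the fitted (zero-inflated) DTM at given
#' sequencing depths, using the model's own tree.
#'
#' @param object A \code{"dtm_fit"} (type \code{mle} or \code{zidtm}).
#' @param nsim Number of datasets.
#' @param seed Integer seed (required for reproducibility).
#' @param depths Vector of per-sample total counts.
#' @param ... Unused.
#' @return A list of \code{"microbiome_data"} objects (length \code{nsim}).
#' @export
simulate.dtm_fit <- function(object, nsim = 1, seed = 1,
                             depths = NULL, ...) {
  stop_if(object$type == "regression",
          "simulate() supports the mle and zidtm forms")
  depths <- depths %||% rep(1000L, 10L)
  params <- if (object$type == "zidtm")
    list(alpha = object$alpha, pi = object$pi) else list(alpha = object$alpha)
  with_seed(seed, lapply(seq_len(nsim), function(i)
    sample_dtm(object$tree, params, depths,
               seed = sample.int(.Machine$integer.max, 1L))))
}
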