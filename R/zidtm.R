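## Zero-inflated Dirichlet-multinomial EM, one internal node at a time.
##
## Model: each child branch j of a node is structurally absent with
## probability pi_j, independently across branches; conditional on the
## present set S (the all-absent configuration is excluded by
## conditioning), the counts entering the node are split among S by a DM
## with parameters alpha restricted to S.  A present set that omits a
## child with a positive count has likelihood zero, so only the
## zero-count children are uncertain, and the E-step enumerates subsets
## of them.  With a one-element present set the split is degenerate (all
## counts to that child, probability one).  Samples without any
## zero-count child have a deterministic E-step and are handled in bulk.

## log DM over the present set S (columns of Y), handling |S| == 1
#' @noRd
logdm_subset <- function(yrow, alpha, S) {
  if (length(S) == 1L) return(0)
  dm_logpmf_mat(matrix(yrow[S], nrow = 1L), alpha[S])[1L]
}

#' @noRd
fit_zidm_node <- function(Y, control = list()) {
  keep <- rowSums(Y) > 0
  Yk <- Y[keep, , drop = FALSE]
  n <- nrow(Yk); k <- ncol(Y)
  em_maxit <- control$em_maxit %||% 200L
  em_tol <- control$em_tol %||% 1e-8

  zero_children <- which(colSums(Yk == 0) > 0)        # only these can have pi > 0
  alpha <- fit_dm(Yk)$alpha
  pi <- rep(0, k)
  pi[zero_children] <- pmin(0.5, colMeans(Yk[, zero_children, drop = FALSE] == 0) / 2)
  names(pi) <- colnames(Y)

  if (length(zero_children) == 0L) {
    f <- fit_dm(Yk)
    return(list(alpha = f$alpha, pi = pi, loglik = f$loglik,
                trace = f$loglik, converged = TRUE))
  }

  clean <- rowSums(Yk == 0) == 0L          # no uncertain children
  dirty <- which(!clean)
  pos <- lapply(dirty, function(i) which(Yk[i, ] > 0))
  zer <- lapply(dirty, function(i) which(Yk[i, ] == 0))
  stop_if(length(zer) && max(lengths(zer)) > 16L,
          "too many zero-count children at one node for exact EM enumeration")
  subsets_of <- function(z) {
    if (length(z) == 0L) return(list(integer(0)))
    unlist(lapply(0:(2^length(z) - 1L), function(m)
      list(z[bitwAnd(m, bitwShiftL(1L, seq_along(z) - 1L)) > 0L])),
      recursive = FALSE)
  }
  Tsets <- lapply(zer, subsets_of)

  ## log-weights of every admissible present set for dirty sample d
  dirty_logw <- function(d, alpha, lp, l1p) {
    vapply(Tsets[[d]], function(Tset) {
      S <- c(pos[[d]], Tset)
      absent <- setdiff(zer[[d]], Tset)
      sum(l1p[S]) + sum(lp[absent]) + logdm_subset(Yk[dirty[d], ], alpha, S)
    }, numeric(1))
  }

  obs_ll <- function(alpha, pi) {
    lp <- log(pmax(pi, 1e-300)); l1p <- log1p(-pi)
    ll <- sum(dm_logpmf_mat(Yk[clean, , drop = FALSE], alpha)) +
      sum(clean) * sum(l1p)
    ll + sum(vapply(seq_along(dirty), function(d) {
      lw <- dirty_logw(d, alpha, lp, l1p)
      mx <- max(lw); mx + log(sum(exp(lw - mx)))
    }, numeric(1)))
  }

  trace <- obs_ll(alpha, pi)
  converged <- FALSE
  for (it in seq_len(em_maxit)) {
    ## E-step: posterior over present sets for the dirty samples
    lp <- log(pmax(pi, 1e-300)); l1p <- log1p(-pi)
    absent_sum <- rep(0, k)
    resp <- vector("list", length(dirty))
    for (d in seq_along(dirty)) {
      lw <- dirty_logw(d, alpha, lp, l1p)
      w <- exp(lw - max(lw)); w <- w / sum(w)
      for (s in seq_along(Tsets[[d]])) {
        absent <- setdiff(zer[[d]], Tsets[[d]][[s]])
        absent_sum[absent] <- absent_sum[absent] + w[s]
      }
      resp[[d]] <- w
    }

    ## M-step: pi = posterior-weighted absence frequency
    pi_new <- absent_sum / n
    pi_new[-zero_children] <- 0
    pi_new <- pmin(pi_new, 1 - 1e-8)
    names(pi_new) <- colnames(Y)

    ## M-step for alpha: weighted DM fit over present sets.  Group the
    ## (sample, present-set) pairs by pattern; the clean samples form
    ## one unweighted full-set group.
    pat_key <- character(0); pat_rows <- list(); pat_w <- list(); pat_S <- list()
    for (d in seq_along(dirty)) {
      ws <- resp[[d]]
      for (s in seq_along(Tsets[[d]])) {
        S <- c(pos[[d]], Tsets[[d]][[s]])
        if (length(S) < 2L || ws[s] < 1e-12) next
        key <- paste(sort(S), collapse = ",")
        j <- match(key, pat_key)
        if (is.na(j)) {
          pat_key <- c(pat_key, key); j <- length(pat_key)
          pat_rows[[j]] <- integer(0); pat_w[[j]] <- numeric(0)
          pat_S[[j]] <- sort(S)
        }
        pat_rows[[j]] <- c(pat_rows[[j]], dirty[d])
        pat_w[[j]] <- c(pat_w[[j]], ws[s])
      }
    }
    Yclean <- Yk[clean, , drop = FALSE]
    Qfun <- function(a) {
      tot <- if (nrow(Yclean)) sum(dm_logpmf_mat(Yclean, a)) else 0
      for (j in seq_along(pat_key)) {
        S <- pat_S[[j]]
        tot <- tot + sum(pat_w[[j]] *
          dm_logpmf_mat(Yk[pat_rows[[j]], S, drop = FALSE], a[S]))
      }
      tot
    }
    opt <- stats::optim(pmin(pmax(log(alpha), -20), 20),
                        function(th) -Qfun(exp(th)),
                        method = "L-BFGS-B", lower = -20, upper = 20,
                        control = list(maxit = 200, factr = 1e4))
    alpha_new <- exp(opt$par)
    ## generalized EM: keep the current alpha if the optimizer failed to
    ## improve the expected complete-data objective
    if (Qfun(alpha_new) < Qfun(alpha)) alpha_new <- alpha
    names(alpha_new) <- colnames(Y)

    ll_new <- obs_ll(alpha_new, pi_new)
    stop_if(ll_new < trace[length(trace)] - 1e-8,
            "EM log-likelihood decreased; this indicates a bug")
    delta <- ll_new - trace[length(trace)]
    alpha <- alpha_new; pi <- pi_new
    trace <- c(trace, ll_new)
    if (abs(delta) < em_tol * (abs(ll_new) + 1)) { converged <- TRUE; break }
  }

  list(alpha = alpha, pi = pi, loglik = trace[length(trace)],
       trace = trace, converged = converged)
}
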