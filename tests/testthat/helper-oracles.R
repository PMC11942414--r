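# Independent brute-force oracles the test-suite checks the implementation
# against. These deliberately use different algorithms (generic optimizers,
# sequential Gram-Schmidt, exhaustive enumeration, pair counting) than the
# code under test.

# Generic-optimizer logistic regression: minimize the negative (optionally
# penalized) log-likelihood with Nelder-Mead + BFGS polish.
oracle_logistic <- function(x, y, w = rep(1, length(y)), lambda = 0,
                            bound = NULL) {
  s2 <- sum(w * (x - sum(w * x) / sum(w))^2) / sum(w)
  nll <- function(th) {
    eta <- th[1] + th[2] * x
    -(sum(w * (y * eta - log(1 + exp(eta)))) - lambda * s2 * th[2]^2)
  }
  if (is.null(bound)) {
    f <- stats::optim(c(0, 0), nll, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  } else {
    f <- stats::optim(c(0, 0), nll, method = "L-BFGS-B",
                      lower = c(-Inf, -bound / sqrt(s2)),
                      upper = c(Inf, bound / sqrt(s2)),
                      control = list(maxit = 1000, factr = 1e1))
  }
  list(intercept = f$par[1], coef = f$par[2],
       loglik = -nll(f$par) - lambda * s2 * f$par[2]^2)
}

# Sequential Gram-Schmidt deflation: orthogonalize X against the selected
# columns one at a time.
oracle_gram_schmidt <- function(X, selected) {
  R <- X
  basis <- list()
  for (j in seq_len(ncol(selected))) {
    v <- selected[, j]
    for (u in basis) v <- v - sum(u * v) * u
    nv <- sqrt(sum(v * v))
    if (nv > 1e-10) basis[[length(basis) + 1]] <- v / nv
  }
  for (u in basis) R <- R - u %*% crossprod(u, R)
  R
}

# Greedy forward selection by ordinary least squares on the residual
# outcome (for gaussian problems with lambda = 0 this is the classical
# stagewise-path oracle for FS-PLS's gaussian limit).
oracle_forward_ols <- function(X, y, k) {
  sel <- integer(0)
  for (i in seq_len(k)) {
    rss <- vapply(seq_len(ncol(X)), function(j) {
      if (j %in% sel) return(Inf)
      fit <- stats::lm.fit(cbind(1, X[, c(sel, j)]), y)
      sum(fit$residuals^2)
    }, numeric(1))
    sel <- c(sel, which.min(rss))
  }
  sel
}

# AUC by exhaustive pair counting.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Wasserstein-1 for equal-size samples: mean absolute difference of sorted
# values (the closed form on matched quantiles).
oracle_wasserstein_equal <- function(a, b) mean(abs(sort(a) - sort(b)))

# Brute-force trimmed mean: drop floor(trim * n) smallest and largest.
oracle_trimmed_mean <- function(x, trim) {
  n <- length(x)
  k <- floor(trim * n)
  xs <- sort(x)
  mean(xs[(k + 1):(n - k)])
}

# Exhaustive univariate argmax over columns (ties to lowest index) using
# reference fitters: lm / glm / nnet::multinom.
oracle_argmax_loglik <- function(X, y, family) {
  lls <- vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    if (stats::var(x) < 1e-12) return(-Inf)
    if (family == "gaussian") {
      fit <- stats::lm(y ~ x)
      n <- length(y)
      rss <- sum(fit$residuals^2)
      -n / 2 * (log(2 * pi * rss / n) + 1)
    } else if (family == "binomial") {
      fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial))
      as.numeric(stats::logLik(fit))
    } else {
      fit <- nnet::multinom(factor(y) ~ x, trace = FALSE, reltol = 1e-13)
      -fit$value
    }
  }, numeric(1))
  which.max(lls)
}
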