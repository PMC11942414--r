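# Core numerical layer: weighted log-likelihoods, univariate maximum-
# likelihood and L2-shrunken fits for the gaussian / binomial / multinomial
# families, and the chi-squared likelihood-ratio test. Everything here is
# exact-likelihood; the gaussian family uses the profile (MLE) variance so
# that likelihood-ratio statistics are self-contained.

# Numerically stable log(1 + exp(x)).
log1pexp <- function(x) {
  out <- x
  small <- x <= 33
  out[small] <- log1p(exp(x[small]))
  out
}

# Weighted column variance (MLE denominator).
weighted_colvar <- function(X, w) {
  W <- sum(w)
  mu <- colSums(X * w) / W
  colSums(X * X * w) / W - mu^2
}

#' Log-likelihood of the intercept-only model
#'
#' Closed-form maximum log-likelihood of the null (intercept-only) model for
#' the outcome's family: gaussian uses the weighted mean and profile (MLE)
#' variance; binomial the weighted class proportion; multinomial the weighted
#' class proportions. Sample weights multiply each sample's contribution.
#'
#' @param y an [outcome()] object (or a plain vector, coerced with family
#'   inference).
#' @return the null log-likelihood (a single number).
#' @examples
#' null_loglik(outcome(c(0, 1), "binomial")) # 2 * log(0.5)
#' @export
null_loglik <- function(y) {
  y <- as_outcome(y)
  w <- outcome_weights(y)
  v <- y$values
  W <- sum(w)
  switch(y$family,
    gaussian = {
      mu <- sum(w * v) / W
      s2 <- sum(w * (v - mu)^2) / W
      if (s2 <= 0) stop("degenerate outcome: zero variance")
      -W / 2 * (log(2 * pi * s2) + 1)
    },
    binomial = {
      p <- sum(w * v) / W
      if (p <= 0 || p >= 1) stop("degenerate outcome: single class present")
      sum(w * (v * log(p) + (1 - v) * log(1 - p)))
    },
    multinomial = {
      cls <- sort(unique(v))
      if (length(cls) < 2L) stop("degenerate outcome: single class present")
      Wc <- vapply(cls, function(c) sum(w[v == c]), numeric(1))
      if (any(Wc <= 0)) stop("degenerate outcome: class with zero total weight")
      sum(Wc * log(Wc / W))
    }
  )
}

# Null intercept(s): gaussian mean, binomial logit proportion, multinomial
# log-odds of each non-reference class against class 0.
null_intercept <- function(y) {
  w <- outcome_weights(y)
  v <- y$values
  W <- sum(w)
  switch(y$family,
    gaussian = sum(w * v) / W,
    binomial = stats::qlogis(sum(w * v) / W),
    multinomial = {
      C <- length(unique(v))
      pc <- vapply(0:(C - 1), function(c) sum(w[v == c]) / W, numeric(1))
      log(pc[-1] / pc[1])
    }
  )
}

# Gaussian weighted profile log-likelihood given fitted values (RSS floored
# so exact fits stay finite).
gaussian_loglik <- function(v, w, mu) {
  W <- sum(w)
  rss <- max(sum(w * (v - mu)^2), 1e-300)
  -W / 2 * (log(2 * pi * rss / W) + 1)
}

# Intercept-only fit on top of a fixed linear-predictor offset: the "null"
# each selection step is tested against. With a zero offset this is the
# ordinary intercept-only null model.
fit_offset_null <- function(y, off = NULL) {
  w <- outcome_weights(y)
  v <- y$values
  W <- sum(w)
  K <- outcome_df(y)
  if (is.null(off)) {
    return(list(intercept = null_intercept(y), loglik = null_loglik(y)))
  }
  switch(y$family,
    gaussian = {
      r <- v - as.numeric(off)
      a <- sum(w * r) / W
      list(intercept = a, loglik = gaussian_loglik(v, w, as.numeric(off) + a))
    },
    binomial = {
      off <- as.numeric(off)
      a <- 0
      ll <- sum(w * (v * off - log1pexp(off)))
      for (i in 1:100) {
        eta <- off + a
        mu <- stats::plogis(eta)
        g <- sum(w * (v - mu))
        h <- sum(w * mu * (1 - mu))
        step <- g / max(h, 1e-12)
        repeat {
          a_new <- a + step
          ll_new <- sum(w * (v * (off + a_new) - log1pexp(off + a_new)))
          if (ll_new >= ll - 1e-12 || abs(step) < 1e-14) break
          step <- step / 2
        }
        done <- abs(ll_new - ll) <= 1e-10 * (abs(ll_new) + 1)
        a <- a_new
        ll <- ll_new
        if (done) break
      }
      list(intercept = a, loglik = ll)
    },
    multinomial = {
      off <- as.matrix(off)
      Yind <- outer(v, seq_len(K), function(vv, k) as.numeric(vv == k))
      negobj <- function(a) {
        ETA <- off + matrix(a, length(v), K, byrow = TRUE)
        M <- pmax(0, apply(ETA, 1L, max))
        logden <- M + log(exp(-M) + rowSums(exp(ETA - M)))
        -sum(w * (rowSums(Yind * ETA) - logden))
      }
      neggrad <- function(a) {
        ETA <- off + matrix(a, length(v), K, byrow = TRUE)
        M <- pmax(0, apply(ETA, 1L, max))
        logden <- M + log(exp(-M) + rowSums(exp(ETA - M)))
        P <- exp(ETA - logden)
        -colSums(w * (Yind - P))
      }
      fit <- stats::optim(rep(0, K), negobj, neggrad, method = "L-BFGS-B",
                          control = list(maxit = 200, factr = 1e3))
      list(intercept = fit$par, loglik = -fit$value)
    }
  )
}

# ---- gaussian univariate (closed form / 1-d penalized optimum) -------------

fit_gaussian_one <- function(x, v, w, lambda, off = NULL) {
  if (!is.null(off)) v <- v - as.numeric(off)
  W <- sum(w)
  xm <- sum(w * x) / W
  ym <- sum(w * v) / W
  xc <- x - xm
  yc <- v - ym
  sxx <- sum(w * xc * xc)
  sxy <- sum(w * xc * yc)
  syy <- sum(w * yc * yc)
  s2 <- sxx / W # MLE variance of x, for the standardized penalty
  if (syy <= 0) {
    if (is.null(off)) stop("degenerate outcome: zero variance")
    syy <- 1e-300 # offset already fits exactly; nothing left to explain
  }
  b_ols <- sxy / sxx
  ll_of <- function(b) {
    # floor the RSS so an exact fit yields a large finite loglik
    rss <- max(syy - 2 * b * sxy + b * b * sxx, 1e-300)
    -W / 2 * (log(2 * pi * rss / W) + 1)
  }
  if (lambda <= 0) {
    b <- b_ols
  } else if (abs(b_ols) < 1e-14) {
    b <- 0
  } else {
    # penalized profile loglik is unimodal between 0 and the OLS slope
    opt <- stats::optimize(function(b) ll_of(b) - lambda * s2 * b * b,
                           interval = sort(c(0, b_ols)) + c(-1e-9, 1e-9),
                           maximum = TRUE, tol = 1e-12)
    b <- opt$maximum
  }
  list(coef = b, intercept = ym - b * xm, loglik = ll_of(b), converged = TRUE)
}

# ---- binomial univariate (vectorized damped Newton over columns) -----------

# Fits intercept + slope logistic regressions of y on every column of X
# simultaneously. Penalty lambda * (slope * sd_x)^2 on the slope only.
# Slopes are box-constrained to |b * sd_x| <= cap; fits that end on the
# boundary (separation) or fail to converge are flagged converged = FALSE.
screen_binomial <- function(X, v, w, lambda = 0, cap = 30,
                            maxit = 100L, tol = 1e-8, off = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  s2 <- weighted_colvar(X, w)
  s <- sqrt(pmax(s2, 0))
  bmax <- ifelse(s > 0, cap / s, Inf)
  if (is.null(off)) off <- 0 else off <- as.numeric(off)
  a <- if (identical(off, 0))
    rep(null_intercept(outcome(v, "binomial", w)), p) else rep(0, p)
  b <- rep(0, p)
  pen <- 2 * lambda * s2

  obj <- function(a, b) {
    ETA <- off + sweep(sweep(X, 2L, b, "*"), 2L, a, "+")
    colSums(w * (v * ETA - log1pexp(ETA))) - lambda * s2 * b * b
  }
  ll_pen <- obj(a, b)
  converged <- rep(FALSE, p)
  for (it in seq_len(maxit)) {
    ETA <- off + sweep(sweep(X, 2L, b, "*"), 2L, a, "+")
    MU <- stats::plogis(ETA)
    R <- w * (v - MU)
    ga <- colSums(R)
    gb <- colSums(R * X) - pen * b
    V <- w * MU * (1 - MU)
    haa <- colSums(V)
    hab <- colSums(V * X)
    hbb <- colSums(V * X * X) + pen
    det <- haa * hbb - hab * hab
    bad <- !is.finite(det) | det < 1e-300
    da <- ifelse(bad, ga / pmax(haa, 1e-10), (hbb * ga - hab * gb) / det)
    db <- ifelse(bad, gb / pmax(hbb, 1e-10), (haa * gb - hab * ga) / det)
    step <- rep(1, p)
    for (h in 1:30) {
      a_new <- a + step * da
      b_new <- pmin(pmax(b + step * db, -bmax), bmax)
      ll_new <- obj(a_new, b_new)
      worse <- ll_new < ll_pen - 1e-12
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
    }
    delta <- abs(ll_new - ll_pen)
    a <- a_new
    b <- b_new
    done <- delta <= tol * (abs(ll_new) + 1)
    ll_pen <- ll_new
    if (all(done)) {
      converged <- rep(TRUE, p)
      break
    }
  }
  if (!all(converged)) converged <- done
  at_bound <- is.finite(bmax) & (abs(b) >= bmax - 1e-9)
  converged[at_bound] <- FALSE
  list(intercept = a, coef = b, loglik = ll_pen + lambda * s2 * b * b,
       converged = converged)
}

# ---- multinomial univariate (L-BFGS-B on the exact likelihood) -------------

fit_multinom_one <- function(x, y, lambda = 0, cap = 30, maxit = 200L,
                             off = NULL) {
  v <- y$values
  w <- outcome_weights(y)
  C <- length(unique(v))
  K <- C - 1L
  W <- sum(w)
  xm <- sum(w * x) / W
  s2 <- sum(w * (x - xm)^2) / W
  s <- sqrt(s2)
  OFF <- if (is.null(off)) matrix(0, length(x), K) else as.matrix(off)
  Yind <- outer(v, seq_len(K), function(vv, k) as.numeric(vv == k)) # m x K
  negobj <- function(theta) {
    a <- theta[seq_len(K)]
    b <- theta[K + seq_len(K)]
    ETA <- OFF + outer(x, b) + matrix(a, length(x), K, byrow = TRUE)
    M <- pmax(0, apply(ETA, 1L, max))
    logden <- M + log(exp(-M) + rowSums(exp(ETA - M)))
    ll <- sum(w * (rowSums(Yind * ETA) - logden))
    -(ll - lambda * s2 * sum(b * b))
  }
  neggrad <- function(theta) {
    a <- theta[seq_len(K)]
    b <- theta[K + seq_len(K)]
    ETA <- OFF + outer(x, b) + matrix(a, length(x), K, byrow = TRUE)
    M <- pmax(0, apply(ETA, 1L, max))
    logden <- M + log(exp(-M) + rowSums(exp(ETA - M)))
    P <- exp(ETA - logden)
    D <- w * (Yind - P)
    c(-colSums(D), -(colSums(D * x) - 2 * lambda * s2 * b))
  }
  a0 <- if (is.null(off)) null_intercept(y) else rep(0, K)
  bmax <- if (s > 0) cap / s else Inf
  fit <- stats::optim(c(a0, rep(0, K)), negobj, neggrad, method = "L-BFGS-B",
                      lower = c(rep(-Inf, K), rep(-bmax, K)),
                      upper = c(rep(Inf, K), rep(bmax, K)),
                      control = list(maxit = maxit, factr = 1e3))
  a <- fit$par[seq_len(K)]
  b <- fit$par[K + seq_len(K)]
  at_bound <- is.finite(bmax) & (abs(b) >= bmax - 1e-9)
  list(coef = b, intercept = a,
       loglik = -(fit$value) - lambda * s2 * sum(b * b),
       converged = fit$convergence == 0 && !any(at_bound))
}

#' Univariate maximum-likelihood fit of one feature against the outcome
#'
#' Fits an intercept-plus-slope model of the outcome on a single feature:
#' weighted least squares for gaussian outcomes, logistic regression for
#' binomial, and multinomial logistic regression (first class as reference,
#' exact likelihood) for multinomial. An optional ridge penalty
#' `lambda * (slope_on_standardized_scale)^2` shrinks the slope only (the
#' intercept is never penalized); the feature is standardized to unit
#' variance internally and the coefficient reported on the original scale.
#'
#' A zero-variance feature returns the null model (slope 0). On (quasi-)
#' separable binomial or multinomial data the standardized slope is capped at
#' 30 and the fit is flagged `converged = FALSE` instead of diverging.
#'
#' @param x numeric feature vector.
#' @param y an [outcome()] (or vector coercible to one).
#' @param lambda non-negative ridge penalty on the slope (default 0 =
#'   maximum likelihood).
#' @param offset optional fixed linear-predictor offset (vector, or n-by-
#'   `C-1` matrix for multinomial) added to the model; the reported
#'   intercept is then the update on top of the offset. Used by the
#'   forward-selection loop, which carries the accumulated model as an
#'   offset at every step.
#' @return list with `coef` (slope; length `C-1` for multinomial),
#'   `intercept` (same shape), `loglik` (unpenalized log-likelihood attained
#'   at the returned coefficients) and `converged`.
#' @seealso [ridge_refit()], [null_loglik()], [lrt_pvalue()]
#' @export
fit_univariate <- function(x, y, lambda = 0, offset = NULL) {
  y <- as_outcome(y)
  x <- as.numeric(x)
  if (length(x) != length(y$values))
    stop("feature length does not match outcome length")
  if (any(!is.finite(x))) stop("feature contains non-finite values")
  if (lambda < 0) stop("lambda must be non-negative")
  w <- outcome_weights(y)
  W <- sum(w)
  s2 <- sum(w * (x - sum(w * x) / W)^2) / W
  if (s2 < 1e-12) {
    # zero-variance predictor: identical to the (offset-)null model
    K <- outcome_df(y)
    nf <- fit_offset_null(y, offset)
    return(list(coef = if (K > 1L) rep(0, K) else 0, intercept = nf$intercept,
                loglik = nf$loglik, converged = TRUE))
  }
  switch(y$family,
    gaussian = fit_gaussian_one(x, y$values, w, lambda, off = offset),
    binomial = {
      f <- screen_binomial(matrix(x, ncol = 1), y$values, w, lambda,
                           off = offset)
      list(coef = f$coef[1], intercept = f$intercept[1],
           loglik = f$loglik[1], converged = f$converged[1])
    },
    multinomial = fit_multinom_one(x, y, lambda, off = offset)
  )
}

#' Re-fit a selected feature's coefficient with L2 shrinkage
#'
#' Ridge-penalized version of [fit_univariate()]: maximizes
#' `loglik - lambda * beta_std^2` where `beta_std` is the slope after
#' standardizing the feature to unit variance (the reported coefficient is
#' rescaled back to the original feature scale). `lambda = 0` reproduces the
#' maximum-likelihood fit exactly.
#'
#' @inheritParams fit_univariate
#' @param lambda non-negative shrinkage strength (default 0.01).
#' @return as [fit_univariate()].
#' @export
ridge_refit <- function(x, y, lambda = 0.01, offset = NULL) {
  fit_univariate(x, y, lambda = lambda, offset = offset)
}

#' Chi-squared likelihood-ratio p-value
#'
#' Upper-tail chi-squared probability of the likelihood-ratio statistic
#' `2 * (loglik_model - loglik_null)` at `df` degrees of freedom. Used as
#' the stopping rule of the forward-selection loop (`df = 1` for gaussian
#' and binomial steps, `C - 1` for multinomial).
#'
#' @param loglik_model log-likelihood of the fitted model.
#' @param loglik_null log-likelihood of the null model on the same data.
#' @param df positive integer degrees of freedom.
#' @return p-value in `[0, 1]`.
#' @examples
#' lrt_pvalue(-1, -2.9207295, df = 1) # ~0.05
#' @export
lrt_pvalue <- function(loglik_model, loglik_null, df) {
  if (length(df) != 1L || !is.finite(df) || df < 1 || df != round(df))
    stop("df must be a positive integer")
  stat <- 2 * (loglik_model - loglik_null)
  if (stat < -1e-6)
    stop("model log-likelihood is below the null log-likelihood")
  stats::pchisq(max(stat, 0), df = df, lower.tail = FALSE)
}
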