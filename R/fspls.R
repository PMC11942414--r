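# FS-PLS proper: forward selection where the data matrix is deflated after
# every step by projecting out the subspace spanned by all selected columns
# (via a thin SVD), so each new feature is chosen for the outcome variation
# it explains orthogonally to the signature so far. Coefficients are fitted
# once, in the deflated space, and never revisited.

#' Center a feature matrix and record per-feature means
#'
#' Subtracts each column's mean and records the means, which are needed to
#' center unseen samples at prediction time.
#'
#' @param x numeric sample-by-feature matrix (samples in rows). Column names
#'   are used as feature identifiers; unnamed columns get `V1..Vp`.
#' @return an object of class `feature_matrix`: list with `data` (centered
#'   matrix), `feature_ids`, `feature_means`, `centered = TRUE`.
#' @export
center <- function(x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (anyDuplicated(colnames(x))) stop("feature ids must be unique")
  bad <- which(!apply(is.finite(x), 2L, all))
  if (length(bad))
    stop(sprintf("non-finite values in feature(s): %s",
                 paste(colnames(x)[utils::head(bad, 5)], collapse = ", ")))
  mu <- colMeans(x)
  structure(
    list(data = sweep(x, 2L, mu, "-"), feature_ids = colnames(x),
         feature_means = stats::setNames(mu, colnames(x)), centered = TRUE),
    class = "feature_matrix"
  )
}

#' Deflate a matrix against the span of selected columns
#'
#' Computes `R = X - U U' X` where `U` is an orthonormal basis (thin SVD) of
#' the column space of `selected`; singular directions with singular value
#' below `1e-10` times the largest are discarded, guarding against collinear
#' selections. With zero selected columns, `X` is returned unchanged. Every
#' column of the result is orthogonal to every selected column.
#'
#' @param x centered m-by-p matrix (or a [center()]ed `feature_matrix`).
#' @param selected m-by-k matrix of previously selected (centered) columns;
#'   `k = 0` is allowed.
#' @return the deflated m-by-p matrix.
#' @export
deflate <- function(x, selected) {
  if (inherits(x, "feature_matrix")) x <- x$data
  x <- as.matrix(x)
  if (is.null(selected) || NCOL(selected) == 0L) return(x)
  selected <- as.matrix(selected)
  if (nrow(selected) != nrow(x)) stop("dimension mismatch between x and selected")
  sv <- svd(selected)
  keep <- sv$d > 1e-10 * sv$d[1]
  if (!any(keep)) return(x)
  U <- sv$u[, keep, drop = FALSE]
  x - U %*% crossprod(U, x)
}

# Univariate screen of every candidate column on top of a fixed linear-
# predictor offset: returns per-column loglik (and fit pieces), vectorized
# for gaussian/binomial, looped for multinomial.
screen_columns <- function(X, y, lambda = 0, offset = NULL) {
  w <- outcome_weights(y)
  if (y$family == "gaussian") {
    v <- y$values
    if (!is.null(offset)) v <- v - as.numeric(offset)
    W <- sum(w)
    xm <- colSums(X * w) / W
    ym <- sum(w * v) / W
    Xc <- sweep(X, 2L, xm, "-")
    vc <- v - ym
    sxx <- colSums(Xc * Xc * w)
    sxy <- colSums(Xc * vc * w)
    syy <- sum(w * vc * vc)
    b <- ifelse(sxx > 0, sxy / sxx, 0)
    rss <- pmax(syy - ifelse(sxx > 0, sxy^2 / sxx, 0), 1e-300)
    list(coef = b, intercept = ym - b * xm,
         loglik = -W / 2 * (log(2 * pi * rss / W) + 1),
         converged = rep(TRUE, ncol(X)))
  } else if (y$family == "binomial") {
    screen_binomial(X, y$values, w, lambda, off = offset)
  } else {
    fits <- lapply(seq_len(ncol(X)), function(j)
      fit_multinom_one(X[, j], y, lambda, off = offset))
    list(coef = lapply(fits, `[[`, "coef"),
         intercept = lapply(fits, `[[`, "intercept"),
         loglik = vapply(fits, `[[`, numeric(1), "loglik"),
         converged = vapply(fits, `[[`, logical(1), "converged"))
  }
}

#' Select the next feature by maximum univariate likelihood
#'
#' Fits a univariate model of the outcome on every non-excluded,
#' non-degenerate column of the (deflated) matrix and returns the column
#' attaining the maximum log-likelihood; ties break to the lowest column
#' index. Columns whose variance falls below `1e-12` after deflation (which
#' includes all previously selected features) are not candidates.
#'
#' @param rk (deflated) m-by-p matrix.
#' @param y an [outcome()].
#' @param excluded integer indices never to consider.
#' @param offset optional fixed linear-predictor offset (the accumulated
#'   model), carried into every candidate fit.
#' @return list with `index`, and `fit` (as [fit_univariate()]).
#' @export
select_next <- function(rk, y, excluded = integer(0), offset = NULL) {
  y <- as_outcome(y)
  rk <- as.matrix(rk)
  w <- outcome_weights(y)
  vars <- weighted_colvar(rk, w)
  cand <- setdiff(which(vars >= 1e-12), excluded)
  if (length(cand) == 0L)
    stop(structure(class = c("fspls_degenerate", "error", "condition"),
                   list(message = "all candidate columns are degenerate after deflation",
                        call = sys.call())))
  sc <- screen_columns(rk[, cand, drop = FALSE], y, offset = offset)
  best <- which.max(sc$loglik) # first max: ties break to lowest index
  j <- cand[best]
  pick <- function(f) if (is.list(f)) f[[best]] else f[best]
  list(index = j,
       fit = list(coef = pick(sc$coef), intercept = pick(sc$intercept),
                  loglik = sc$loglik[best], converged = sc$converged[best]))
}

#' Fit an FS-PLS model
#'
#' Runs the forward-selection loop: center the matrix, deflate it against
#' the selected columns, pick the feature with maximum univariate
#' log-likelihood in the deflated space — every candidate fit carries the
#' accumulated model as a fixed linear-predictor offset — re-fit its
#' coefficient with L2 shrinkage, and test the new feature against the
#' offset-only null (at step one, the intercept-only null) with a
#' chi-squared likelihood-ratio test. Selection stops when the p-value
#' reaches `pvalue_threshold` (unless `force_to_max`), when `max_features`
#' have been selected, or when no informative candidate remains. Each
#' step's coefficient is fixed in its deflated space and never revisited;
#' the model's linear predictor is the null intercept plus the accumulated
#' per-step contributions.
#'
#' @param x numeric sample-by-feature matrix (samples in rows), or a
#'   [center()]ed `feature_matrix`.
#' @param y an [outcome()], or a vector (family inferred or given via
#'   `family`).
#' @param family optional family override when `y` is a plain vector.
#' @param weights optional per-sample weights (see [outcome()]).
#' @param pvalue_threshold stop once the step p-value reaches this value
#'   (default 0.05).
#' @param max_features cap on the number of selected features (default
#'   `Inf`).
#' @param ridge_lambda L2 shrinkage used for the per-step coefficient refit
#'   (default 0.01; the selection itself uses the unpenalized likelihood).
#' @param force_to_max continue past the p-value threshold until
#'   `max_features` features are selected (default `FALSE`).
#' @return an object of class `fspls_model`; see Details. Supports
#'   [predict()][predict.fspls_model] with optional truncation to a prefix
#'   of steps, and JSON round-tripping via [write_fspls_model()].
#' @details The returned model records, per step: the feature, its
#'   deflated-space coefficient and intercept update, the step's univariate
#'   log-likelihood and likelihood-ratio p-value, the new orthonormal basis
#'   direction of the selected subspace, and the projection coefficients of
#'   the chosen column on the previously selected columns (the
#'   orthogonalization data needed to replay deflation on unseen single
#'   samples). `loss_path` holds the cumulative training loss (gaussian:
#'   MSE; binomial/multinomial: mean deviance) and its standard error at
#'   every model size, for use with [select_model_size()].
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(300), 50, 6, dimnames = list(NULL, paste0("g", 1:6)))
#' y <- x[, 2] * 2 + rnorm(50, sd = 0.1)
#' m <- fspls(x, y, family = "gaussian")
#' m$steps[[1]]$feature_id
#' @export
fspls <- function(x, y, family = NULL, weights = NULL,
                  pvalue_threshold = 0.05, max_features = Inf,
                  ridge_lambda = 0.01, force_to_max = FALSE) {
  if (pvalue_threshold <= 0 || pvalue_threshold > 1)
    stop("pvalue_threshold must be in (0, 1]")
  if (max_features < 1) stop("max_features must be >= 1")
  fm <- if (inherits(x, "feature_matrix")) x else center(x)
  Xc <- fm$data
  m <- nrow(Xc)
  if (m < 3L) stop("need at least 3 samples")
  y <- as_outcome(y, family, weights)
  if (length(y$values) != m) stop("outcome length does not match sample count")
  w <- outcome_weights(y)
  K <- outcome_df(y)
  ll0 <- null_loglik(y)
  a0 <- null_intercept(y)
  df <- K

  sel <- integer(0)
  steps <- list()
  # lp: accumulated linear predictor (null intercept + fixed per-step
  # contributions); carried as the offset of every subsequent step's fits
  lp <- matrix(rep(as.numeric(a0), each = m), m, K)
  loss <- numeric(0)
  loss_se <- numeric(0)
  stop_reason <- NULL

  repeat {
    if (length(sel) >= max_features) {
      stop_reason <- "max_features"
      break
    }
    if (y$family == "gaussian" && length(sel)) {
      # nothing left to explain: residual variance at numerical zero
      res <- y$values - lp[, 1]
      if (sum(w * res^2) <= 1e-10 * sum(w * (y$values - sum(w * y$values) / sum(w))^2)) {
        stop_reason <- "loglik_degenerate"
        break
      }
    }
    R <- deflate(Xc, Xc[, sel, drop = FALSE])
    off <- if (K == 1L) lp[, 1] else lp
    sn <- tryCatch(select_next(R, y, excluded = sel, offset = off),
                   fspls_degenerate = function(e) NULL)
    if (is.null(sn)) {
      stop_reason <- "loglik_degenerate"
      break
    }
    ll_null_k <- if (length(sel) == 0L) ll0 else fit_offset_null(y, off)$loglik
    pval <- lrt_pvalue(sn$fit$loglik, ll_null_k, df)
    if (!force_to_max && pval >= pvalue_threshold) {
      stop_reason <- "pvalue_threshold"
      break
    }
    j <- sn$index
    r <- R[, j]
    refit <- fit_univariate(r, y, lambda = ridge_lambda, offset = off)
    gamma <- if (length(sel)) {
      g <- qr.coef(qr(Xc[, sel, drop = FALSE]), Xc[, j])
      g[!is.finite(g)] <- 0
      stats::setNames(as.numeric(g), fm$feature_ids[sel])
    } else {
      stats::setNames(numeric(0), character(0))
    }
    beta <- refit$coef
    iu <- refit$intercept # intercept update on top of the offset
    lp <- lp + outer(r, as.numeric(beta)) +
      matrix(rep(as.numeric(iu), each = m), m, K)
    tl <- training_loss(y, lp, w)
    loss <- c(loss, tl$loss)
    loss_se <- c(loss_se, tl$se)
    steps[[length(steps) + 1L]] <- list(
      feature_index = j,
      feature_id = fm$feature_ids[j],
      beta = as.numeric(beta),
      intercept_update = as.numeric(iu),
      loglik = sn$fit$loglik,
      pvalue = pval,
      converged = refit$converged,
      basis_vector = r / sqrt(sum(r * r)),
      loadings = gamma
    )
    sel <- c(sel, j)
  }

  sel_ids <- fm$feature_ids[sel]
  structure(
    list(
      family = y$family,
      levels = y$levels,
      steps = steps,
      feature_means = fm$feature_means[sel_ids],
      null_intercept = as.numeric(a0),
      null_loglik = ll0,
      stop_reason = stop_reason,
      options = list(pvalue_threshold = pvalue_threshold,
                     max_features = max_features,
                     ridge_lambda = ridge_lambda,
                     force_to_max = force_to_max),
      loss_path = data.frame(size = seq_along(loss), loss = loss, se = loss_se),
      training_linpred = if (K == 1L) lp[, 1] else lp,
      n_train = m
    ),
    class = "fspls_model"
  )
}

# Cumulative training loss at the current model size, with a standard error
# from per-sample loss contributions: gaussian weighted MSE, binomial /
# multinomial mean deviance (-2 loglik per unit weight).
training_loss <- function(y, lp, w) {
  v <- y$values
  W <- sum(w)
  per <- switch(y$family,
    gaussian = (v - lp[, 1])^2,
    binomial = -2 * (v * lp[, 1] - log1pexp(lp[, 1])),
    multinomial = {
      K <- ncol(lp)
      M <- pmax(0, apply(lp, 1L, max))
      logden <- M + log(exp(-M) + rowSums(exp(lp - M)))
      etay <- ifelse(v == 0, 0, lp[cbind(seq_along(v), pmax(v, 1))])
      -2 * (etay - logden)
    }
  )
  mu <- sum(w * per) / W
  list(loss = mu,
       se = sqrt(sum(w * (per - mu)^2) / W) / sqrt(length(v)))
}

#' @export
print.fspls_model <- function(x, ...) {
  cat(sprintf("<fspls_model> family=%s, %d step(s), stop=%s\n",
              x$family, length(x$steps), x$stop_reason))
  if (length(x$steps)) {
    tab <- data.frame(
      feature = vapply(x$steps, `[[`, character(1), "feature_id"),
      pvalue = signif(vapply(x$steps, `[[`, numeric(1), "pvalue"), 3),
      loglik = signif(vapply(x$steps, `[[`, numeric(1), "loglik"), 6)
    )
    print(tab, row.names = FALSE)
  }
  invisible(x)
}

#' Features a fitted model needs at prediction time
#'
#' @param model an `fspls_model`.
#' @param through_step optionally truncate to the first `through_step` steps.
#' @return character vector of feature ids.
#' @export
required_features <- function(model, through_step = NULL) {
  ks <- n_steps_used(model, through_step)
  if (ks == 0L) return(character(0))
  ids <- vapply(model$steps[seq_len(ks)], `[[`, character(1), "feature_id")
  unique(c(ids, unlist(lapply(model$steps[seq_len(ks)],
                              function(s) names(s$loadings)))))
}

n_steps_used <- function(model, through_step) {
  k <- length(model$steps)
  if (is.null(through_step)) return(k)
  if (through_step < 0) stop("through_step must be >= 0")
  min(as.integer(through_step), k)
}

#' Predict from a fitted FS-PLS model
#'
#' Centers new samples with the training feature means, replays each step's
#' deflation using the stored projection coefficients, accumulates the fixed
#' per-step contributions to the linear predictor, and applies the family's
#' inverse link. No batch statistics are used, so a single sample predicts
#' identically on its own or within a batch.
#'
#' @param object an `fspls_model`.
#' @param newdata matrix or data frame with named columns covering
#'   `required_features(object)` (extra columns are ignored). A single
#'   sample may be given as a named vector.
#' @param through_step truncate the model to its first `through_step` steps
#'   (e.g. the output of [select_model_size()]).
#' @param type `"response"` (default: gaussian mean / binomial probability /
#'   multinomial class-probability matrix) or `"link"` (linear predictor).
#' @param ... unused.
#' @return numeric vector (gaussian/binomial) or n-by-C matrix of class
#'   probabilities (multinomial, columns named by class).
#' @export
predict.fspls_model <- function(object, newdata, through_step = NULL,
                                type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
  newdata <- as.matrix(newdata)
  ks <- n_steps_used(object, through_step)
  req <- required_features(object, ks)
  missing_ids <- setdiff(req, colnames(newdata))
  if (length(missing_ids))
    stop(sprintf("newdata is missing required feature(s): %s",
                 paste(missing_ids, collapse = ", ")))
  n <- nrow(newdata)
  K <- if (object$family == "multinomial") length(object$levels) - 1L else 1L
  acc_int <- object$null_intercept
  eta <- matrix(0, n, K)
  if (ks > 0L) {
    Z <- sweep(newdata[, req, drop = FALSE], 2L,
               object$feature_means[req], "-")
    for (k in seq_len(ks)) {
      st <- object$steps[[k]]
      d <- Z[, st$feature_id]
      if (length(st$loadings))
        d <- d - as.numeric(Z[, names(st$loadings), drop = FALSE] %*% st$loadings)
      eta <- eta + outer(d, st$beta)
      acc_int <- acc_int + st$intercept_update
    }
  }
  eta <- sweep(eta, 2L, as.numeric(acc_int), "+")
  if (type == "link")
    return(if (K == 1L) as.numeric(eta) else eta)
  switch(object$family,
    gaussian = as.numeric(eta),
    binomial = as.numeric(stats::plogis(eta)),
    multinomial = {
      M <- pmax(0, apply(eta, 1L, max))
      logden <- M + log(exp(-M) + rowSums(exp(eta - M)))
      P <- cbind(exp(-logden), exp(eta - logden))
      colnames(P) <- object$levels
      rownames(P) <- rownames(newdata)
      P
    }
  )
}

#' Choose a model size from a loss path (min / one-standard-error rule)
#'
#' @param losses training or cross-validated loss at each model size
#'   (position `k` = model truncated to `k` features).
#' @param rule `"min"` (smallest loss, ties to the smaller size) or
#'   `"one_se"` (smallest size whose loss is within one standard error of
#'   the minimum, using the standard error at the minimizing size).
#' @param se standard errors, same length as `losses` (required for
#'   `"one_se"`).
#' @return the chosen size (integer).
#' @examples
#' select_model_size(c(5, 3, 2, 2.1), "min") # 3
#' select_model_size(c(5, 3, 2), "one_se", se = c(1, 1, 1)) # 2
#' @export
select_model_size <- function(losses, rule = c("min", "one_se"), se = NULL) {
  rule <- match.arg(rule)
  if (length(losses) == 0L) stop("empty loss vector")
  kmin <- which.min(losses)
  if (rule == "min") return(kmin)
  if (is.null(se) || length(se) != length(losses))
    stop("one_se rule needs standard errors of the same length as losses")
  which(losses <= losses[kmin] + se[kmin])[1L]
}
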