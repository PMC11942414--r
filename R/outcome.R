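#' Construct an outcome vector with family and optional sample weights
#'
#' Wraps the response of a signature-discovery problem together with its
#' distributional family and optional non-negative per-sample weights.
#' Continuous outcomes use the `gaussian` family, two-class outcomes the
#' `binomial` family (coded 0/1), and outcomes with three or more classes
#' the `multinomial` family (class labels are kept and the first level is
#' used as the reference class).
#'
#' @param values numeric vector (gaussian), 0/1 vector, logical or two-level
#'   factor (binomial), or factor / character / integer labels (multinomial).
#' @param family one of `"gaussian"`, `"binomial"`, `"multinomial"`.
#' @param weights optional non-negative numeric vector, one entry per sample,
#'   applied multiplicatively to each sample's log-likelihood contribution.
#'   At least one weight must be strictly positive.
#' @return an object of class `fspls_outcome` with elements `values`
#'   (numeric; for multinomial, integer class codes `0..C-1`), `family`,
#'   `weights` (`NULL` if unweighted), and for multinomial `levels`.
#' @examples
#' outcome(c(0, 1, 1, 0), "binomial")
#' outcome(c("a", "b", "c", "a"), "multinomial")
#' @export
outcome <- function(values, family = c("gaussian", "binomial", "multinomial"),
                    weights = NULL) {
  family <- match.arg(family)
  if (length(values) < 1L) stop("outcome values must be non-empty")
  levels_ <- NULL
  if (family == "gaussian") {
    values <- as.numeric(values)
    if (any(!is.finite(values))) stop("gaussian outcome contains non-finite values")
  } else if (family == "binomial") {
    if (is.factor(values)) {
      if (nlevels(values) > 2L) stop("binomial outcome has more than 2 levels")
      values <- as.numeric(values) - 1
    } else if (is.logical(values)) {
      values <- as.numeric(values)
    } else {
      values <- as.numeric(values)
    }
    if (any(!is.finite(values)) || !all(values %in% c(0, 1)))
      stop("binomial outcome values must be 0 or 1")
  } else {
    f <- factor(values)
    levels_ <- levels(f)
    if (nlevels(f) < 2L)
      stop("multinomial outcome needs at least 2 distinct classes")
    values <- as.numeric(f) - 1
  }
  if (!is.null(weights)) {
    weights <- as.numeric(weights)
    if (length(weights) != length(values))
      stop("weights length does not match outcome length")
    if (any(!is.finite(weights)) || any(weights < 0))
      stop("weights must be finite and non-negative")
    if (!any(weights > 0)) stop("at least one weight must be positive")
  }
  structure(
    list(values = values, family = family, weights = weights, levels = levels_),
    class = "fspls_outcome"
  )
}

#' @export
print.fspls_outcome <- function(x, ...) {
  cat(sprintf("<fspls_outcome> family=%s, n=%d%s%s\n", x$family,
              length(x$values),
              if (!is.null(x$weights)) ", weighted" else "",
              if (!is.null(x$levels))
                sprintf(", classes=%s", paste(x$levels, collapse = ",")) else ""))
  invisible(x)
}

# Coerce y (+ family/weights) into an fspls_outcome, inferring family when
# unstated: numeric 0/1 -> binomial, other numeric -> gaussian,
# factor/character -> binomial or multinomial by number of levels.
as_outcome <- function(y, family = NULL, weights = NULL) {
  if (inherits(y, "fspls_outcome")) {
    if (!is.null(weights)) y$weights <- outcome(y$values, y$family, weights)$weights
    return(y)
  }
  if (is.null(family)) {
    if (is.factor(y) || is.character(y)) {
      family <- if (length(unique(as.character(y))) > 2L) "multinomial" else "binomial"
    } else if (is.logical(y) || all(y %in% c(0, 1))) {
      family <- "binomial"
    } else {
      family <- "gaussian"
    }
  }
  outcome(y, family, weights)
}

# Effective weights (all-ones when unweighted).
outcome_weights <- function(y) {
  if (is.null(y$weights)) rep(1, length(y$values)) else y$weights
}

# Number of linear predictors per feature: 1, or C-1 for multinomial.
outcome_df <- function(y) {
  if (y$family == "multinomial") length(unique(y$values)) - 1L else 1L
}
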