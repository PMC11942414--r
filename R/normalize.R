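# Library-size surrogate normalisation. A sparse gaussian FS-PLS model of
# log library size on a handful of highly expressed features ("surrogates",
# typically housekeeping-like genes) replaces the full-assay total, so a
# signature can be applied to a single unseen sample in which only the
# signature and surrogate features were measured. Two constructions use the
# fitted model: "faux" normalisation subtracts the *predicted* log library
# size from every log count, and "ratio" normalisation recasts the feature
# space as log-ratios against each surrogate feature (a per-sample-scaling
# invariant representation).

#' Per-sample log library sizes
#'
#' Natural log of each sample's total count, computed on the unfiltered
#' count matrix (filtering must happen after, not before).
#'
#' @param counts non-negative sample-by-feature count matrix.
#' @return numeric vector of log library sizes, named by sample.
#' @export
library_sizes <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- rowSums(counts)
  if (any(tot <= 0)) {
    who <- rownames(counts)[tot <= 0]
    if (is.null(who)) who <- which(tot <= 0)
    stop(sprintf("sample(s) with zero total counts: %s",
                 paste(utils::head(who, 5), collapse = ", ")))
  }
  stats::setNames(log(tot), rownames(counts))
}

#' Log-transform a count matrix
#'
#' `log(count + pseudocount)`, natural base. The pseudocount guards zeros;
#' downstream log-ratio constructions are base-invariant.
#'
#' @param counts non-negative count matrix.
#' @param pseudocount positive value added before the log (default 1).
#' @export
log_transform <- function(counts, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be positive")
  log(as.matrix(counts) + pseudocount)
}

#' Fit a library-size surrogate model
#'
#' Fits a gaussian FS-PLS model of log library size on log-transformed,
#' otherwise un-normalised counts, capped at `max_features` surrogates, then
#' truncates the selection path with the one-standard-error rule on the
#' training mean-squared error. Candidate features should be pre-filtered to
#' stably, highly expressed ones (see [filter_top_expressed()] and
#' [intersect_features()]).
#'
#' @param log_counts log-transformed un-normalised sample-by-feature matrix
#'   (candidate features only).
#' @param log_lib per-sample log library sizes from [library_sizes()],
#'   computed on the unfiltered counts.
#' @param max_features cap on the number of normalizing features (default 2).
#' @param pvalue_threshold,ridge_lambda passed to [fspls()].
#' @param pseudocount recorded so prediction-time transforms match training.
#' @return an `fspls_normalization`: list with `inner` (the gaussian
#'   `fspls_model`), `normalizing_features`, `pseudocount`.
#' @export
fit_normalization <- function(log_counts, log_lib, max_features = 2,
                              pvalue_threshold = 0.05, ridge_lambda = 0.01,
                              pseudocount = 1) {
  fit <- fspls(log_counts, outcome(log_lib, "gaussian"),
               pvalue_threshold = pvalue_threshold,
               max_features = max_features, ridge_lambda = ridge_lambda)
  if (length(fit$steps) == 0L)
    stop("no feature predicts library size at the stated threshold")
  k <- select_model_size(fit$loss_path$loss, "one_se", fit$loss_path$se)
  fit$steps <- fit$steps[seq_len(k)]
  fit$loss_path <- fit$loss_path[seq_len(k), , drop = FALSE]
  ids <- vapply(fit$steps, `[[`, character(1), "feature_id")
  fit$feature_means <- fit$feature_means[required_features(fit)]
  structure(list(inner = fit, normalizing_features = ids,
                 pseudocount = pseudocount),
            class = "fspls_normalization")
}

#' @export
print.fspls_normalization <- function(x, ...) {
  cat(sprintf("<fspls_normalization> %d surrogate feature(s): %s\n",
              length(x$normalizing_features),
              paste(x$normalizing_features, collapse = ", ")))
  invisible(x)
}

#' Predict log library sizes from a surrogate model
#'
#' @param object an `fspls_normalization`.
#' @param log_counts log-transformed counts containing (at least) the
#'   normalizing features; a single sample may be a named vector.
#' @param ... unused.
#' @return predicted log library size per sample.
#' @export
predict.fspls_normalization <- function(object, log_counts, ...) {
  predict(object$inner, log_counts)
}

new_normalized_matrix <- function(data, mode, model = NULL) {
  structure(list(data = data, mode = mode, provenance = model,
                 feature_ids = colnames(data)),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("<normalized_matrix> mode=%s, %d sample(s) x %d feature(s)\n",
              x$mode, nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Ordinary library-size normalisation
#'
#' The baseline arm: each sample's true log library size is subtracted from
#' every log count (the log-scale analogue of dividing counts by the total).
#'
#' @param log_counts log-transformed count matrix.
#' @param log_lib per-sample log library sizes.
#' @return a `normalized_matrix` with mode `"ordinary"`.
#' @export
ordinary_normalize <- function(log_counts, log_lib) {
  log_counts <- as.matrix(log_counts)
  if (length(log_lib) != nrow(log_counts))
    stop("log_lib length does not match sample count")
  new_normalized_matrix(sweep(log_counts, 1L, as.numeric(log_lib), "-"),
                        "ordinary")
}

check_norm_features <- function(log_counts, model) {
  missing_ids <- setdiff(model$normalizing_features, colnames(log_counts))
  if (length(missing_ids))
    stop(sprintf("missing normalizing feature(s): %s",
                 paste(missing_ids, collapse = ", ")))
}

#' Faux normalisation by predicted library size
#'
#' Subtracts each sample's *predicted* log library size (from the surrogate
#' model) from every log-count entry. Only the normalizing features need to
#' be measured, so a single sample can be normalised in isolation.
#'
#' @param log_counts log-transformed count matrix (single samples may be
#'   named vectors).
#' @param model an `fspls_normalization` from [fit_normalization()].
#' @return a `normalized_matrix` with mode `"faux"`.
#' @export
faux_normalize <- function(log_counts, model) {
  if (is.null(dim(log_counts))) log_counts <- t(as.matrix(log_counts))
  log_counts <- as.matrix(log_counts)
  check_norm_features(log_counts, model)
  pred <- predict(model, log_counts)
  new_normalized_matrix(sweep(log_counts, 1L, pred, "-"), "faux", model)
}

#' Ratio normalisation against each surrogate feature
#'
#' Recasts the feature space as log-ratios: output column `(j, g)` is
#' `log_counts[, j] - log_counts[, g]` for every feature `j` and every
#' normalizing feature `g`, yielding `p * q` columns with composite ids
#' `"feature/normfeature"`. The representation is invariant to any
#' per-sample scaling (library-size shift on the log scale), and a single
#' sample can be transformed in isolation. Self-ratio columns (`g` against
#' itself) are retained as constant zeros so the dimension statement holds
#' exactly; selection ignores zero-variance columns anyway.
#'
#' @inheritParams faux_normalize
#' @return a `normalized_matrix` with mode `"ratio"` and `p * q` columns.
#' @export
ratio_normalize <- function(log_counts, model) {
  if (is.null(dim(log_counts))) log_counts <- t(as.matrix(log_counts))
  log_counts <- as.matrix(log_counts)
  check_norm_features(log_counts, model)
  q <- length(model$normalizing_features)
  blocks <- lapply(model$normalizing_features, function(g) {
    b <- log_counts - log_counts[, g]
    colnames(b) <- paste0(colnames(log_counts), "/", g)
    b
  })
  new_normalized_matrix(do.call(cbind, blocks), "ratio", model)
}

#' Parse a ratio-normalised model's raw feature requirements
#'
#' Maps composite ratio ids `"a/b"` back to the raw features `a` and `b`.
#' For faux / ordinary ids the id itself is returned.
#'
#' @param ids character feature ids (possibly composite).
#' @return character vector of raw feature ids.
#' @export
raw_feature_ids <- function(ids) {
  unique(unlist(strsplit(ids, "/", fixed = TRUE)))
}

#' Keep the most variable features
#'
#' @param x sample-by-feature matrix.
#' @param k number of features to keep (default 10000; all if `p <= k`).
#' @return character vector of the selected feature ids, by decreasing
#'   variance.
#' @export
filter_top_variable <- function(x, k = 10000) {
  if (k < 1) stop("k must be >= 1")
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  v <- apply(x, 2L, stats::var)
  colnames(x)[order(-v)][seq_len(min(k, ncol(x)))]
}

#' Keep the most expressed features by trimmed mean
#'
#' Ranks features by the mean of their values after discarding the lowest
#' and highest `floor(trim * m)` samples, then keeps the top `k`. The trim
#' makes the ranking robust to single extreme samples.
#'
#' @param x sample-by-feature matrix.
#' @param k number of features to keep (default 10000).
#' @param trim trimming fraction per tail, in `[0, 0.5)` (default 0.05).
#' @return character vector of the selected feature ids, by decreasing
#'   trimmed mean.
#' @export
filter_top_expressed <- function(x, k = 10000, trim = 0.05) {
  if (k < 1) stop("k must be >= 1")
  if (trim < 0 || trim >= 0.5) stop("trim must be in [0, 0.5)")
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  tm <- apply(x, 2L, mean, trim = trim)
  colnames(x)[order(-tm)][seq_len(min(k, ncol(x)))]
}

#' Intersect feature-id collections, preserving the first one's order
#'
#' Used to restrict normalisation candidates to features stably expressed in
#' every dataset under consideration.
#'
#' @param ... two or more character vectors of feature ids.
#' @return ids present in every collection, in the order of the first.
#' @export
intersect_features <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]])) sets <- sets[[1]]
  if (length(sets) < 2L) stop("need at least two feature-id collections")
  out <- Reduce(function(a, b) a[a %in% b], sets)
  if (length(out) == 0L) stop("no features are common to all collections")
  out
}
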