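# Cross-validation harness and performance metrics. Fold plans are
# deterministic given a seed and are reused across the normalisation and
# discrimination tasks so held-out samples are unseen by both models. All
# training-side statistics (filters, surrogate models, signatures) are
# computed from training folds only.

#' Build a (stratified) cross-validation fold plan
#'
#' Deterministic given `seed`. Stratified plans preserve class proportions
#' within one sample per fold.
#'
#' @param labels outcome vector (class labels for stratification; any vector
#'   when `stratified = FALSE`).
#' @param n_folds number of folds (default 5).
#' @param seed integer seed.
#' @param stratified stratify by `labels` (default `TRUE`).
#' @return a `fold_plan`: list with `assignments` (fold index per sample),
#'   `n_folds`, `seed`, `stratified`.
#' @export
make_folds <- function(labels, n_folds = 5, seed = 1, stratified = TRUE) {
  n <- length(labels)
  if (n_folds < 2L || n_folds > n) stop("n_folds must be in [2, n]")
  assignments <- integer(n)
  withr::with_seed(as.integer(seed), {
    if (stratified) {
      f <- factor(labels)
      if (min(table(f)) < n_folds)
        stop("smallest class has fewer samples than folds; cannot stratify")
      for (lev in levels(f)) {
        idx <- which(f == lev)
        assignments[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
      }
    } else {
      assignments <- sample(rep_len(seq_len(n_folds), n))
    }
  })
  structure(list(assignments = assignments, n_folds = as.integer(n_folds),
                 seed = as.integer(seed), stratified = stratified),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d folds, %d samples, seed=%d%s\n", x$n_folds,
              length(x$assignments), x$seed,
              if (x$stratified) ", stratified" else ""))
  invisible(x)
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Probability that a random positive outscores a random negative, counting
#' ties as one half; invariant under strictly monotone transforms of the
#' scores.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1, logical, or two-level factor).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as_outcome(labels, "binomial")$values
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-class one-vs-rest metrics from a probability matrix
#'
#' One-vs-rest AUC per class; hard class assignments by row argmax (ties
#' broken to the lowest class index); sensitivity is the recall of the class
#' and specificity its true-negative rate. A class absent from `labels` gets
#' `NA` metrics and is flagged in `undefined`.
#'
#' @param prob_matrix n-by-C matrix of class probabilities, columns named by
#'   class; rows must sum to 1 within `1e-6`.
#' @param labels true class labels.
#' @return data frame with one row per class: `class`, `auc`, `sensitivity`,
#'   `specificity`, `undefined`; plus attribute `macro_auc` (unweighted mean
#'   of the defined per-class AUCs).
#' @export
per_class_metrics <- function(prob_matrix, labels) {
  prob_matrix <- as.matrix(prob_matrix)
  if (is.null(colnames(prob_matrix))) stop("prob_matrix must have class names")
  if (any(abs(rowSums(prob_matrix) - 1) > 1e-6))
    stop("probability rows must sum to 1")
  labels <- as.character(labels)
  classes <- colnames(prob_matrix)
  hard <- classes[max.col(prob_matrix, ties.method = "first")]
  rows <- lapply(classes, function(cl) {
    present <- any(labels == cl)
    if (!present)
      return(data.frame(class = cl, auc = NA_real_, sensitivity = NA_real_,
                        specificity = NA_real_, undefined = TRUE))
    is_cl <- labels == cl
    data.frame(
      class = cl,
      auc = auc(prob_matrix[, cl], is_cl),
      sensitivity = mean(hard[is_cl] == cl),
      specificity = mean(hard[!is_cl] != cl),
      undefined = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "macro_auc") <- mean(out$auc, na.rm = TRUE)
  out
}

#' Wasserstein-1 separation of predicted probabilities
#'
#' One-dimensional Wasserstein-1 distance between the empirical
#' distributions of predicted class probability among cases and among
#' controls — the area between the two empirical CDFs. Larger values mean
#' the model separates the groups with more confidence than AUC alone can
#' show. Symmetric in the two groups.
#'
#' @param probs predicted probabilities (values in `[0, 1]`).
#' @param is_case binary indicator of case status, same length.
#' @return non-negative distance.
#' @export
wasserstein_separation <- function(probs, is_case) {
  is_case <- as_outcome(is_case, "binomial")$values
  if (length(probs) != length(is_case)) stop("length mismatch")
  a <- sort(probs[is_case == 1])
  b <- sort(probs[is_case == 0])
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  grid <- sort(unique(c(a, b)))
  if (length(grid) == 1L) return(0)
  mids <- grid[-length(grid)]
  dx <- diff(grid)
  Fa <- stats::ecdf(a)(mids)
  Fb <- stats::ecdf(b)(mids)
  sum(abs(Fa - Fb) * dx)
}

#' Inverse-class-proportion sample weights
#'
#' Weight of a sample in class `c` is `n / (C * n_c)`; the mean weight is 1
#' and the weighted class proportions become uniform.
#'
#' @param labels class labels (all classes present).
#' @return numeric weights, one per sample.
#' @export
class_weights <- function(labels) {
  f <- factor(labels)
  n <- length(f)
  C <- nlevels(f)
  nc <- table(f)
  as.numeric(n / (C * nc[f]))
}

#' Adjusted R-squared of held-out predictions
#'
#' Treats the fitted model as a single predictor of truth:
#' `1 - (1 - R2) * (n - 1) / (n - 2)`.
#'
#' @param truth,pred numeric vectors.
#' @export
adjusted_r2 <- function(truth, pred) {
  n <- length(truth)
  r2 <- 1 - sum((truth - pred)^2) / sum((truth - mean(truth))^2)
  1 - (1 - r2) * (n - 1) / (n - 2)
}

# t-based 95% CI of a fold-mean.
fold_ci <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  m <- mean(x)
  if (n < 2L) return(c(mean = m, lo = NA_real_, hi = NA_real_))
  half <- stats::qt(0.975, df = n - 1) * stats::sd(x) / sqrt(n)
  c(mean = m, lo = m - half, hi = m + half)
}

#' Cross-validated benchmark of normalisation + signature discovery
#'
#' For each fold: computes the training-side filters, (for `faux` / `ratio`
#' modes) fits the library-size surrogate model on the training folds,
#' normalises training and held-out samples with the training-side solution,
#' fits the FS-PLS discrimination model on the training folds, and predicts
#' the held-out fold. No statistic is ever computed from test samples during
#' training (ordinary normalisation uses each sample's own total count,
#' which is a per-sample quantity). Held-out predictions are concatenated
#' across folds for pooled per-class metrics.
#'
#' @param x sample-by-feature matrix: raw counts for modes
#'   `"ordinary"`, `"faux"`, `"ratio"`; any numeric matrix for `"none"`
#'   (no normalisation, e.g. microarray intensities).
#' @param y outcome vector or [outcome()].
#' @param plan a [make_folds()] plan.
#' @param mode normalisation mode.
#' @param family optional family override.
#' @param weighting `"none"` or `"inverse_class"` (per-fold
#'   [class_weights()] on the training samples).
#' @param k_variable,k_expressed,trim filter settings (see
#'   [filter_top_variable()], [filter_top_expressed()]).
#' @param pseudocount log-transform pseudocount for count modes.
#' @param norm_max_features surrogate-model feature cap (default 2).
#' @param pvalue_threshold,max_features,ridge_lambda,force_to_max passed to
#'   [fspls()].
#' @param autoscale standardize features to unit train-fold variance
#'   (microarray-style; applied separately to train and test partitions;
#'   only for mode `"none"`).
#' @return an `fspls_benchmark`: list with `folds` (per-fold metric table),
#'   `pooled` (per-class metrics incl. Wasserstein separation on pooled
#'   predictions), `summary` (fold-mean and 95% t-CI per metric),
#'   `n_features` per fold, `predictions`, `models`, plus the run settings.
#' @export
run_benchmark <- function(x, y, plan, mode = c("ordinary", "faux", "ratio", "none"),
                          family = NULL, weighting = c("none", "inverse_class"),
                          k_variable = 10000, k_expressed = 10000, trim = 0.05,
                          pseudocount = 1, norm_max_features = 2,
                          pvalue_threshold = 0.05, max_features = Inf,
                          ridge_lambda = 0.01, force_to_max = FALSE,
                          autoscale = FALSE) {
  mode <- match.arg(mode)
  weighting <- match.arg(weighting)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (is.null(rownames(x))) rownames(x) <- paste0("sample_", seq_len(nrow(x)))
  yout <- as_outcome(y, family)
  if (length(yout$values) != nrow(x)) stop("outcome length does not match x")
  stopifnot(length(plan$assignments) == nrow(x))
  is_count_mode <- mode %in% c("ordinary", "faux", "ratio")
  if (is_count_mode && any(x < 0))
    stop(sprintf("mode '%s' requires a non-negative count matrix", mode))

  fold_rows <- list()
  pred_rows <- list()
  models <- list()
  norm_models <- list()
  n_features <- integer(plan$n_folds)

  lib_all <- if (is_count_mode) library_sizes(x) else NULL
  logx_all <- if (is_count_mode) log_transform(x, pseudocount) else NULL

  for (f in seq_len(plan$n_folds)) {
    tr <- plan$assignments != f
    te <- !tr
    nm <- NULL
    if (mode == "none") {
      xtr <- x[tr, , drop = FALSE]
      xte <- x[te, , drop = FALSE]
      if (autoscale) {
        sc <- function(z) {
          s <- apply(z, 2L, stats::sd)
          sweep(z, 2L, ifelse(s > 0, s, 1), "/")
        }
        xtr <- sc(xtr)
        xte <- sc(xte) # scaled within partition: no train/test leakage
      }
    } else if (mode == "ordinary") {
      xtr <- ordinary_normalize(logx_all[tr, , drop = FALSE], lib_all[tr])$data
      xte <- ordinary_normalize(logx_all[te, , drop = FALSE], lib_all[te])$data
    } else {
      cand_norm <- filter_top_expressed(x[tr, , drop = FALSE], k_expressed, trim)
      nm <- fit_normalization(logx_all[tr, cand_norm, drop = FALSE],
                              lib_all[tr], max_features = norm_max_features,
                              pvalue_threshold = pvalue_threshold,
                              ridge_lambda = ridge_lambda,
                              pseudocount = pseudocount)
      normalize_with <- if (mode == "faux") faux_normalize else ratio_normalize
      xtr <- normalize_with(logx_all[tr, , drop = FALSE], nm)$data
      xte <- normalize_with(logx_all[te, , drop = FALSE], nm)$data
    }
    cand <- filter_top_variable(xtr, k_variable)
    wts <- if (weighting == "inverse_class") class_weights(yout$values[tr]) else NULL
    ytr <- outcome(if (yout$family == "multinomial")
                     factor(yout$levels[yout$values[tr] + 1], levels = yout$levels)
                   else yout$values[tr],
                   yout$family, wts)
    fit <- fspls(xtr[, cand, drop = FALSE], ytr,
                 pvalue_threshold = pvalue_threshold,
                 max_features = max_features, ridge_lambda = ridge_lambda,
                 force_to_max = force_to_max)
    models[[f]] <- fit
    norm_models[[f]] <- nm
    n_features[f] <- length(fit$steps)
    pred <- predict(fit, xte)
    truth <- yout$values[te]
    if (yout$family == "gaussian") {
      fold_rows[[f]] <- data.frame(fold = f, class = NA_character_,
        metric = c("mse", "adj_r2"),
        value = c(mean((truth - pred)^2), adjusted_r2(truth, pred)))
      pred_rows[[f]] <- data.frame(sample = rownames(x)[te], fold = f,
                                   truth = truth, score = pred)
    } else if (yout$family == "binomial") {
      fold_rows[[f]] <- data.frame(fold = f, class = NA_character_,
        metric = "auc", value = auc(pred, truth))
      pred_rows[[f]] <- data.frame(sample = rownames(x)[te], fold = f,
                                   truth = truth, score = pred)
    } else {
      pcm <- per_class_metrics(pred, yout$levels[truth + 1])
      fold_rows[[f]] <- data.frame(
        fold = f,
        class = c(pcm$class, NA_character_),
        metric = c(rep("auc", nrow(pcm)), "macro_auc"),
        value = c(pcm$auc, attr(pcm, "macro_auc")))
      pr <- data.frame(sample = rownames(x)[te], fold = f,
                       truth = yout$levels[truth + 1])
      pred_rows[[f]] <- cbind(pr, as.data.frame(pred))
    }
  }

  folds <- do.call(rbind, fold_rows)
  predictions <- do.call(rbind, pred_rows)
  pooled <- NULL
  if (yout$family == "binomial") {
    pooled <- list(auc = auc(predictions$score, predictions$truth),
                   wasserstein = wasserstein_separation(
                     predictions$score, predictions$truth))
  } else if (yout$family == "multinomial") {
    P <- as.matrix(predictions[, yout$levels, drop = FALSE])
    pcm <- per_class_metrics(P, predictions$truth)
    pcm$wasserstein <- vapply(yout$levels, function(cl)
      wasserstein_separation(P[, cl], predictions$truth == cl), numeric(1))
    pooled <- list(per_class = pcm, macro_auc = attr(pcm, "macro_auc"))
  } else {
    pooled <- list(mse = mean((predictions$truth - predictions$score)^2),
                   adj_r2 = adjusted_r2(predictions$truth, predictions$score))
  }
  summary_tab <- do.call(rbind, lapply(split(folds, folds$metric), function(d) {
    ci <- fold_ci(d$value)
    data.frame(metric = d$metric[1], mean = ci["mean"], lo = ci["lo"],
               hi = ci["hi"], row.names = NULL)
  }))
  structure(list(folds = folds, pooled = pooled, summary = summary_tab,
                 n_features = n_features, predictions = predictions,
                 models = models, norm_models = norm_models,
                 mode = mode, family = yout$family, weighting = weighting,
                 plan = plan),
            class = "fspls_benchmark")
}

#' @export
print.fspls_benchmark <- function(x, ...) {
  cat(sprintf("<fspls_benchmark> mode=%s, family=%s, %d folds\n",
              x$mode, x$family, x$plan$n_folds))
  print(x$summary, row.names = FALSE)
  cat(sprintf("features per fold: %s\n", paste(x$n_features, collapse = ", ")))
  invisible(x)
}

#' Write a benchmark report to JSON and TSV
#'
#' Writes `report.json` (full report: per-fold metrics, pooled metrics,
#' feature counts, settings) and `report.tsv` (one row per fold, class and
#' metric) into `dir`, plus `folds.tsv` (sample_id, fold).
#'
#' @param report an `fspls_benchmark`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  doc <- list(mode = report$mode, family = report$family,
              weighting = report$weighting,
              n_features = report$n_features,
              folds = report$folds,
              summary = report$summary,
              pooled = report$pooled)
  jsonlite::write_json(doc, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  data.table::fwrite(report$folds, file.path(dir, "report.tsv"), sep = "\t")
  data.table::fwrite(
    data.frame(sample_id = report$predictions$sample,
               fold = report$predictions$fold),
    file.path(dir, "folds.tsv"), sep = "\t")
  invisible(dir)
}
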