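# JSON round-tripping of fitted models. The document is versioned; readers
# reject unknown versions rather than guessing.

FSPLS_MODEL_VERSION <- "1.0"

model_to_list <- function(model) {
  list(
    version = FSPLS_MODEL_VERSION,
    type = "fspls_model",
    family = model$family,
    levels = model$levels,
    options = model$options,
    null_intercept = model$null_intercept,
    null_loglik = model$null_loglik,
    stop_reason = model$stop_reason,
    feature_means = as.list(model$feature_means),
    n_train = model$n_train,
    loss_path = as.list(model$loss_path),
    steps = lapply(model$steps, function(s) {
      list(feature_id = s$feature_id, beta = s$beta,
           intercept_update = s$intercept_update,
           loglik = s$loglik, pvalue = s$pvalue, converged = s$converged,
           basis_vector = s$basis_vector,
           loadings = as.list(s$loadings))
    })
  )
}

num <- function(x) as.numeric(unlist(x, use.names = FALSE))

list_to_model <- function(l) {
  structure(
    list(
      family = l$family,
      levels = if (length(l$levels)) as.character(unlist(l$levels)) else NULL,
      steps = lapply(l$steps, function(s) {
        list(feature_index = NA_integer_,
             feature_id = s$feature_id,
             beta = num(s$beta),
             intercept_update = num(s$intercept_update),
             loglik = num(s$loglik), pvalue = num(s$pvalue),
             converged = isTRUE(unlist(s$converged)),
             basis_vector = num(s$basis_vector),
             loadings = stats::setNames(num(s$loadings), names(s$loadings)))
      }),
      feature_means = stats::setNames(num(l$feature_means),
                                      names(l$feature_means)),
      null_intercept = num(l$null_intercept),
      null_loglik = num(l$null_loglik),
      stop_reason = l$stop_reason,
      options = lapply(l$options, unlist),
      loss_path = data.frame(size = num(l$loss_path$size),
                             loss = num(l$loss_path$loss),
                             se = num(l$loss_path$se)),
      n_train = num(l$n_train)
    ),
    class = "fspls_model"
  )
}

#' Write a fitted model to JSON
#'
#' Serializes an `fspls_model` or `fspls_normalization` (see
#' [fit_normalization()]) to a versioned JSON document that
#' [read_fspls_model()] can restore exactly enough to reproduce predictions.
#'
#' @param model a fitted `fspls_model` or `fspls_normalization`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fspls_model <- function(model, path) {
  if (inherits(model, "fspls_normalization")) {
    doc <- model_to_list(model$inner)
    doc$type <- "fspls_normalization"
    doc$pseudocount <- model$pseudocount
    doc$normalizing_features <- model$normalizing_features
  } else if (inherits(model, "fspls_model")) {
    doc <- model_to_list(model)
  } else {
    stop("model must be an fspls_model or fspls_normalization")
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' @param path a file written by [write_fspls_model()].
#' @return an `fspls_model` or `fspls_normalization`.
#' @export
read_fspls_model <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(l$version) || !identical(as.character(l$version), FSPLS_MODEL_VERSION))
    stop(sprintf("unsupported model version: %s",
                 if (is.null(l$version)) "<missing>" else as.character(l$version)))
  inner <- list_to_model(l)
  if (identical(l$type, "fspls_normalization")) {
    structure(list(inner = inner,
                   normalizing_features = as.character(unlist(l$normalizing_features)),
                   pseudocount = as.numeric(l$pseudocount)),
              class = "fspls_normalization")
  } else {
    inner
  }
}
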