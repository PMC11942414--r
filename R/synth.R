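# Synthetic data with the statistical structure the method assumes:
# over-dispersed (negative binomial) counts with sample-specific library
# sizes, a small set of truly outcome-associated features, housekeeping
# features whose abundance scales strictly with library size, and optional
# blocks of correlated nuisance features driven by a shared latent factor.
# All randomness flows through one explicit seed; the same seed reproduces
# the same data bit for bit.

#' Simulate an omics-like count matrix with planted structure
#'
#' Counts are drawn negative-binomially with mean
#' `s_i * base_g * effect(class_i, g) * block_factor`, where the size
#' factors `s_i` are log-normal. Signal features carry a class-dependent
#' log-fold-change (for multinomial outcomes each signal feature is
#' up-regulated in one class, assigned round-robin; for gaussian outcomes
#' the log-mean shifts linearly with the standardized outcome).
#' Housekeeping features have effect identically 1, high baseline
#' expression, and Poisson noise around `s_i * base_g * exp(N(0,
#' hk_noise_sd))`, making them ideal library-size surrogates. Correlated
#' blocks share a latent log-normal factor; the first member of a block may
#' itself carry the class effect.
#'
#' @param m,p samples and features.
#' @param family outcome family: `"binomial"`, `"multinomial"` or
#'   `"gaussian"`.
#' @param n_signal number of outcome-associated features.
#' @param effect_size log-fold-change of signal features (recycled).
#' @param n_housekeeping number of library-size-tracking features.
#' @param hk_noise_sd log-scale noise of housekeeping expression around the
#'   library size (default 0.02).
#' @param size_factor_sd sd of the log-normal library size factors (default
#'   0.5).
#' @param correlation_blocks list of `list(size =, rho =, signal = FALSE)`
#'   entries; each block consumes `size` features whose log counts correlate
#'   at about `rho` within the block.
#' @param nb_dispersion negative-binomial dispersion (`1/size`; default
#'   0.4).
#' @param class_proportions class proportions (length C; default balanced
#'   two-class).
#' @param base_mean_range,hk_mean_range log-uniform baseline expression
#'   ranges for ordinary and housekeeping features.
#' @param seed integer seed.
#' @return list with `counts` (m-by-p, dimnames `sample_i` / `gene_j`), `y`
#'   (outcome vector: 0/1, factor, or numeric), and `truth` (signal /
#'   housekeeping / block feature ids, true size factors, effects).
#' @export
simulate_counts <- function(m = 200, p = 500, family = c("binomial", "multinomial", "gaussian"),
                            n_signal = 4, effect_size = 1,
                            n_housekeeping = 5, hk_noise_sd = 0.02,
                            size_factor_sd = 0.5,
                            correlation_blocks = list(),
                            nb_dispersion = 0.4,
                            class_proportions = c(0.5, 0.5),
                            base_mean_range = c(2, 200),
                            hk_mean_range = c(200, 2000),
                            seed = 1) {
  family <- match.arg(family)
  blocks_n <- sum(vapply(correlation_blocks, function(b) b$size, numeric(1)))
  if (n_signal + n_housekeeping + blocks_n > p)
    stop("infeasible: n_signal + n_housekeeping + block features exceed p")
  if (abs(sum(class_proportions) - 1) > 1e-8)
    stop("class_proportions must sum to 1")
  withr::with_seed(as.integer(seed), {
    C <- length(class_proportions)
    y <- switch(family,
      gaussian = stats::rnorm(m),
      binomial = {
        if (C != 2) stop("binomial family needs 2 class proportions")
        as.numeric(stats::runif(m) < class_proportions[2])
      },
      multinomial = {
        lab <- sample(seq_len(C) - 1L, m, replace = TRUE, prob = class_proportions)
        factor(paste0("class", lab))
      }
    )
    z <- switch(family, gaussian = y, binomial = y,
                multinomial = as.numeric(factor(y)) - 1)
    s <- exp(stats::rnorm(m, 0, size_factor_sd))
    ids <- paste0("gene_", seq_len(p))
    sig_idx <- seq_len(n_signal)
    hk_idx <- n_signal + seq_len(n_housekeeping)
    blk_idx <- list()
    nxt <- n_signal + n_housekeeping
    for (b in seq_along(correlation_blocks)) {
      blk_idx[[b]] <- nxt + seq_len(correlation_blocks[[b]]$size)
      nxt <- nxt + correlation_blocks[[b]]$size
    }
    base <- exp(stats::runif(p, log(base_mean_range[1]), log(base_mean_range[2])))
    base[hk_idx] <- exp(stats::runif(n_housekeeping, log(hk_mean_range[1]),
                                     log(hk_mean_range[2])))
    ef <- rep_len(effect_size, max(n_signal, 1L))
    # class effect on the log-mean scale
    E <- matrix(0, m, p)
    if (n_signal > 0) {
      if (family == "multinomial") {
        up_class <- rep_len(seq_len(C) - 1L, n_signal) # round-robin target class
        for (k in seq_len(n_signal))
          E[, sig_idx[k]] <- ef[k] * (z == up_class[k])
      } else if (family == "binomial") {
        for (k in seq_len(n_signal)) E[, sig_idx[k]] <- ef[k] * z
      } else {
        zs <- (z - mean(z)) / stats::sd(z)
        for (k in seq_len(n_signal)) E[, sig_idx[k]] <- ef[k] * zs
      }
    }
    # block latent structure on the log-mean scale; block features are
    # highly expressed and tightly measured (low dispersion) so the latent
    # split is calibrated against the total log-count variance and the
    # realized within-block correlation lands on the requested rho
    sigma_blk <- 0.8
    disp <- rep(nb_dispersion, p)
    for (b in seq_along(correlation_blocks)) {
      bl <- correlation_blocks[[b]]
      f <- stats::rnorm(m)
      idx <- blk_idx[[b]]
      disp[idx] <- 0.005
      base[idx] <- exp(stats::runif(length(idx), log(hk_mean_range[1]),
                                    log(hk_mean_range[2])))
      v_nb <- 0.005 + 1 / exp(mean(log(hk_mean_range))) # count-noise var of log
      v_tot <- sigma_blk^2 + v_nb
      shared <- sqrt(bl$rho * v_tot)
      own <- sqrt(max((1 - bl$rho) * v_tot - v_nb, 0))
      for (j in seq_along(idx)) {
        E[, idx[j]] <- E[, idx[j]] + shared * f +
          stats::rnorm(m, 0, own)
      }
      if (isTRUE(bl$signal)) {
        # the whole co-regulated module is differentially expressed: the
        # class effect rides on the shared factor, so members are mutually
        # redundant given any one of them
        efb <- ef[1]
        shift <- switch(family,
                        binomial = efb * z,
                        multinomial = efb * (z == 0),
                        gaussian = efb * (z - mean(z)) / stats::sd(z))
        E[, idx] <- E[, idx] + shift
      }
    }
    MU <- s * sweep(exp(E), 2L, base, "*")
    counts <- matrix(stats::rnbinom(m * p, mu = MU, size = rep(1 / disp, each = m)),
                     m, p)
    # housekeeping: strictly library-size-proportional; hk_noise_sd is the
    # surrogate's entire log-scale noise (rounding to integer counts is the
    # only other distortion)
    for (j in hk_idx) {
      counts[, j] <- round(s * base[j] * exp(stats::rnorm(m, 0, hk_noise_sd)))
    }
    dimnames(counts) <- list(paste0("sample_", seq_len(m)), ids)
    list(
      counts = counts,
      y = y,
      truth = list(signal = ids[sig_idx], housekeeping = ids[hk_idx],
                   blocks = lapply(blk_idx, function(i) ids[i]),
                   size_factors = s, effect_size = ef,
                   base_means = stats::setNames(base, ids))
    )
  })
}

#' Simulate a gaussian-feature matrix with class-shifted markers
#'
#' Microarray-style analogue of [simulate_counts()]: features are standard
#' normal and each signal feature's mean is shifted by `delta` in the
#' positive class (binomial) or linearly with the outcome (gaussian, where
#' `y ~ N(0,1)` and signal features get slope `delta`). A per-feature shift
#' of `delta` gives a single-feature ROC AUC of `pnorm(delta / sqrt(2))`.
#'
#' @param m,p samples and features.
#' @param family `"binomial"` or `"gaussian"`.
#' @param n_signal number of shifted features.
#' @param delta class shift (binomial) or outcome slope (gaussian).
#' @param class_proportions binomial class proportions.
#' @param seed integer seed.
#' @return list with `x` (m-by-p matrix, features `gene_j`), `y`, `truth`.
#' @export
simulate_gaussian <- function(m = 100, p = 50, family = c("binomial", "gaussian"),
                              n_signal = 0, delta = 1,
                              class_proportions = c(0.5, 0.5), seed = 1) {
  family <- match.arg(family)
  if (n_signal > p) stop("infeasible: n_signal > p")
  withr::with_seed(as.integer(seed), {
    x <- matrix(stats::rnorm(m * p), m, p,
                dimnames = list(paste0("sample_", seq_len(m)),
                                paste0("gene_", seq_len(p))))
    if (family == "binomial") {
      y <- as.numeric(stats::runif(m) < class_proportions[2])
      if (n_signal > 0)
        x[, seq_len(n_signal)] <- x[, seq_len(n_signal)] + delta * y
    } else {
      y <- stats::rnorm(m)
      if (n_signal > 0)
        x[, seq_len(n_signal)] <- x[, seq_len(n_signal)] + delta * y
    }
    list(x = x, y = y,
         truth = list(signal = colnames(x)[seq_len(n_signal)], delta = delta))
  })
}

#' Small fixed datasets with hand-checkable answers
#'
#' Three deterministic fixtures used throughout the test-suite:
#' \describe{
#'   \item{`a`}{a 12-by-6 gaussian problem (`y` driven by features 3 and 5
#'     plus small noise) whose selection path is verifiable against a
#'     greedy forward ordinary-least-squares oracle;}
#'   \item{`b`}{a 40-by-20 binomial problem with two strongly shifted
#'     markers (features 1 and 2, opposite directions) that are exactly
#'     recoverable and give perfect training separation;}
#'   \item{`c`}{a 30-by-15 count matrix with log-normal library sizes and
#'     two near-noiseless housekeeping genes (features 1 and 2) tracking
#'     them.}
#' }
#'
#' @return named list of fixtures, each a list with the data and outcome
#'   (fixture `c` has `counts` and `log_lib`).
#' @export
golden_fixtures <- function() {
  a <- withr::with_seed(101L, {
    x <- matrix(stats::rnorm(12 * 6), 12, 6,
                dimnames = list(NULL, paste0("g", 1:6)))
    y <- 3 * x[, 3] - 2 * x[, 5] + 0.05 * stats::rnorm(12)
    list(x = x, y = y, true_features = c("g3", "g5"))
  })
  b <- withr::with_seed(102L, {
    cls <- rep(c(0, 1), each = 20)
    x <- matrix(stats::rnorm(40 * 20), 40, 20,
                dimnames = list(NULL, paste0("g", 1:20)))
    x[, 1] <- x[, 1] + 3 * cls
    x[, 2] <- x[, 2] - 3 * cls
    list(x = x, y = cls, true_features = c("g1", "g2"))
  })
  cc <- withr::with_seed(103L, {
    m <- 30; p <- 15
    s <- exp(stats::rnorm(m, 0, 0.5))
    counts <- matrix(0, m, p, dimnames = list(paste0("s", seq_len(m)),
                                              paste0("g", seq_len(p))))
    # the two surrogates dominate the library total, so the total tracks
    # them (plus their small log-noise) rather than per-gene count noise
    counts[, 1] <- round(s * 4000 * exp(stats::rnorm(m, 0, 0.015)))
    counts[, 2] <- round(s * 2000 * exp(stats::rnorm(m, 0, 0.015)))
    base <- exp(stats::runif(p - 2, log(2), log(30)))
    counts[, 3:p] <- matrix(
      stats::rnbinom(m * (p - 2), mu = rep(s, p - 2) *
                       rep(base, each = m), size = 1 / 0.2), m, p - 2)
    list(counts = counts, log_lib = log(rowSums(counts)),
         housekeeping = c("g1", "g2"), size_factors = s)
  })
  list(a = a, b = b, c = cc)
}
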