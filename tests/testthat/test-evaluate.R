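# Fold plans, metrics and the cross-validated benchmark harness.

test_that("fold plans are balanced, stratified and deterministic", {
  p1 <- make_folds(rep(0:1, each = 5), 5, seed = 3)
  expect_equal(as.vector(table(p1$assignments)), rep(2L, 5))
  p2 <- make_folds(rep(0:1, each = 5), 5, seed = 3)
  expect_identical(p1$assignments, p2$assignments)
  expect_false(identical(p1$assignments,
                         make_folds(rep(0:1, each = 5), 5, seed = 4)$assignments))
  # 60/40 labels: every fold within one sample of the class split
  y <- rep(c(0, 1), c(60, 40))
  p3 <- make_folds(y, 5, seed = 9)
  tab <- table(p3$assignments, y)
  expect_true(all(tab[, "0"] == 12) && all(tab[, "1"] == 8))
  expect_error(make_folds(rep(c(0, 1), c(97, 3)), 5, seed = 1), "stratify")
})

test_that("auc matches exhaustive pair counting and its invariances", {
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  set.seed(61)
  for (i in 1:5) {
    s <- rnorm(40)
    l <- rbinom(40, 1, 0.5)
    if (length(unique(l)) < 2) next
    expect_equal(auc(s, l), oracle_auc(s, l))
    # invariant under strictly monotone transforms
    expect_equal(auc(exp(2 * s) + 1, l), auc(s, l))
  }
  # ties counted one half
  expect_equal(auc(c(1, 1, 1, 1), c(0, 1, 0, 1)), 0.5)
  # perfect separation
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("per-class metrics reduce to one-vs-rest auc and document the tie rule", {
  P <- diag(3)
  colnames(P) <- c("a", "b", "c")
  m <- per_class_metrics(P, c("a", "b", "c"))
  expect_equal(m$sensitivity, rep(1, 3))
  expect_equal(m$specificity, rep(1, 3))
  # uniform rows: argmax ties break to the lowest class index
  U <- matrix(1 / 3, 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  mu <- per_class_metrics(U, c("a", "a", "b", "c"))
  expect_equal(mu$sensitivity, c(1, 0, 0))
  # random probabilities: per-class AUC equals auc() on the reduction
  set.seed(62)
  P2 <- matrix(rexp(200 * 3), 200, 3)
  P2 <- P2 / rowSums(P2)
  colnames(P2) <- c("a", "b", "c")
  lab <- sample(c("a", "b", "c"), 200, replace = TRUE)
  m2 <- per_class_metrics(P2, lab)
  for (cl in c("a", "b", "c"))
    expect_equal(m2$auc[m2$class == cl], auc(P2[, cl], lab == cl))
  expect_equal(attr(m2, "macro_auc"), mean(m2$auc))
  # a class absent from the labels is flagged, not silently zero
  m3 <- per_class_metrics(P2, sample(c("a", "b"), 200, replace = TRUE))
  expect_true(m3$undefined[m3$class == "c"])
  expect_true(is.na(m3$auc[m3$class == "c"]))
})

test_that("wasserstein separation matches the sorted-sample closed form", {
  expect_equal(wasserstein_separation(c(0.2, 0.5, 0.8, 0.2, 0.5, 0.8),
                                      c(1, 1, 1, 0, 0, 0)), 0)
  expect_equal(wasserstein_separation(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(wasserstein_separation(c(0.8, 0.9, 0.1, 0.2), c(1, 1, 0, 0)), 0.7)
  set.seed(63)
  for (i in 1:5) {
    a <- runif(20)
    b <- runif(20)
    w <- wasserstein_separation(c(a, b), rep(c(1, 0), each = 20))
    expect_equal(w, oracle_wasserstein_equal(a, b))
    # symmetric in the two groups
    expect_equal(w, wasserstein_separation(c(b, a), rep(c(1, 0), each = 20)))
  }
  expect_error(wasserstein_separation(runif(3), c(1, 1, 1)), "non-empty")
})

test_that("inverse-class-proportion weights balance the classes", {
  expect_equal(class_weights(c(0, 0, 1, 1)), rep(1, 4))
  expect_equal(class_weights(c(0, 0, 0, 1)), c(2 / 3, 2 / 3, 2 / 3, 2))
  w <- class_weights(c("a", "a", "a", "b", "b", "c"))
  expect_equal(mean(w), 1)
  # weighted class proportions become uniform
  f <- factor(c("a", "a", "a", "b", "b", "c"))
  expect_equal(as.vector(tapply(w, f, sum) / sum(w)), rep(1 / 3, 3))
})

test_that("the benchmark reports per-fold metrics and is reproducible", {
  sim <- simulate_counts(m = 100, p = 80, family = "binomial", n_signal = 3,
                         effect_size = 1.5, n_housekeeping = 3, seed = 64)
  plan <- make_folds(sim$y, 5, seed = 65)
  b <- run_benchmark(sim$counts, sim$y, plan, mode = "ordinary",
                     family = "binomial", k_variable = 60, k_expressed = 40)
  expect_equal(sum(b$folds$metric == "auc"), 5)
  expect_length(b$n_features, 5)
  expect_true(all(b$summary$metric == "auc"))
  b2 <- run_benchmark(sim$counts, sim$y, plan, mode = "ordinary",
                      family = "binomial", k_variable = 60, k_expressed = 40)
  expect_identical(b$predictions, b2$predictions)
  # report files
  d <- tempfile()
  write_report(b, d)
  expect_true(file.exists(file.path(d, "report.json")))
  tsv <- data.table::fread(file.path(d, "report.tsv"))
  expect_equal(nrow(tsv), nrow(b$folds))
})

test_that("shuffled labels give chance-level pooled AUC", {
  aucs <- vapply(1:5, function(s) {
    sim <- simulate_counts(m = 120, p = 60, family = "binomial", n_signal = 4,
                           effect_size = 1.5, seed = 600 + s)
    y <- withr::with_seed(700 + s, sample(sim$y))
    plan <- make_folds(y, 5, seed = s)
    run_benchmark(sim$counts, y, plan, mode = "ordinary", family = "binomial",
                  k_variable = 60, k_expressed = 40)$pooled$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("faux-mode prediction needs only signature plus surrogate features", {
  sim <- simulate_counts(m = 100, p = 80, family = "binomial", n_signal = 3,
                         effect_size = 1.8, n_housekeeping = 3, seed = 66)
  plan <- make_folds(sim$y, 5, seed = 67)
  b <- run_benchmark(sim$counts, sim$y, plan, mode = "faux",
                     family = "binomial", k_variable = 60, k_expressed = 40)
  f <- 1
  fit <- b$models[[f]]
  nm <- b$norm_models[[f]]
  te <- plan$assignments == f
  need <- union(required_features(fit), nm$normalizing_features)
  expect_lt(length(need), ncol(sim$counts)) # genuinely a reduced panel
  # predictions from the reduced panel alone match the full-assay pipeline
  panel <- log_transform(sim$counts[te, need, drop = FALSE])
  pred_panel <- predict(fit, faux_normalize(panel, nm)$data)
  full <- faux_normalize(log_transform(sim$counts[te, , drop = FALSE]), nm)$data
  expect_equal(pred_panel, predict(fit, full), tolerance = 1e-12)
})

test_that("multinomial benchmarks pool per-class metrics across folds", {
  sim <- simulate_counts(m = 150, p = 60, family = "multinomial", n_signal = 6,
                         effect_size = 2.5, class_proportions = c(0.4, 0.3, 0.3),
                         seed = 68)
  plan <- make_folds(sim$y, 5, seed = 69)
  b <- run_benchmark(sim$counts, sim$y, plan, mode = "ordinary",
                     family = "multinomial", k_variable = 60, k_expressed = 40,
                     max_features = 4)
  pc <- b$pooled$per_class
  expect_equal(nrow(pc), 3)
  expect_true(all(pc$auc >= 0 & pc$auc <= 1))
  expect_true(all(pc$wasserstein >= 0))
  expect_equal(b$pooled$macro_auc, mean(pc$auc))
  # weighted variant runs and balances training weights
  bw <- run_benchmark(sim$counts, sim$y, plan, mode = "ordinary",
                      family = "multinomial", weighting = "inverse_class",
                      k_variable = 60, k_expressed = 40, max_features = 4)
  expect_s3_class(bw, "fspls_benchmark")
})
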