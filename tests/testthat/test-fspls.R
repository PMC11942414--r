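# Forward selection with projection deflation: centering, deflation,
# selection, the fit loop, prediction replay, model-size rule and
# serialization.

test_that("center records means and is idempotent", {
  x <- cbind(a = c(1, 2, 3), b = c(0, 0, 0), c = c(-1, 1, 0))
  fm <- center(x)
  expect_equal(fm$data[, "a"], c(-1, 0, 1))
  expect_equal(unname(fm$feature_means), c(2, 0, 0))
  fm2 <- center(fm$data)
  expect_lt(max(abs(fm2$data - fm$data)), 1e-12)
  x[2, 2] <- NA
  expect_error(center(x), "b")
})

test_that("deflation removes exactly the selected span", {
  set.seed(21)
  X <- matrix(rnorm(20 * 8), 20, 8)
  X <- sweep(X, 2, colMeans(X))
  expect_identical(deflate(X, X[, integer(0)]), X)
  # deflating by a column annihilates that column
  R1 <- deflate(X, X[, 3, drop = FALSE])
  expect_lt(sqrt(sum(R1[, 3]^2)), 1e-10)
  # three selected columns: orthogonality and Gram-Schmidt agreement
  sel <- X[, c(2, 5, 7)]
  R <- deflate(X, sel)
  expect_lt(max(abs(crossprod(sel, R))), 1e-8)
  expect_lt(max(abs(R - oracle_gram_schmidt(X, sel))), 1e-8)
  expect_error(deflate(X, matrix(0, 5, 2)), "dimension")
})

test_that("select_next finds a planted signal and breaks ties low", {
  hits <- 0
  for (s in 1:20) {
    sim <- simulate_gaussian(100, 15, "gaussian", n_signal = 0, seed = 100 + s)
    y <- 3 * sim$x[, 9] + rnorm(100, sd = 0.1)
    sn <- select_next(scale(sim$x, scale = FALSE), outcome(y, "gaussian"))
    hits <- hits + (sn$index == 9)
  }
  expect_gte(hits, 19)
  # identical optimal columns: lowest index wins
  x <- cbind(rnorm(30), 0, 0)
  x[, 3] <- x[, 2] <- x[, 1]
  y <- outcome(x[, 1] + rnorm(30, sd = 0.2), "gaussian")
  expect_equal(select_next(scale(x, scale = FALSE), y)$index, 1)
  expect_equal(select_next(scale(x, scale = FALSE), y, excluded = 1)$index, 2)
  expect_error(select_next(matrix(0, 10, 3), outcome(rnorm(10), "gaussian")),
               class = "fspls_degenerate")
})

test_that("exact linear outcomes recover exactly the generating features", {
  sim <- simulate_gaussian(60, 20, "gaussian", n_signal = 0, seed = 3)
  y <- 3 * sim$x[, 3] - 2 * sim$x[, 7]
  m <- fspls(sim$x, y, family = "gaussian", ridge_lambda = 0)
  expect_equal(sort(vapply(m$steps, `[[`, character(1), "feature_id")),
               c("gene_3", "gene_7"))
  expect_lt(mean((predict(m, sim$x) - y)^2), 1e-16)
  expect_equal(m$stop_reason, "loglik_degenerate")
})

test_that("gaussian FS-PLS on an orthonormal design equals OLS on the selected set", {
  set.seed(22)
  X <- qr.Q(qr(matrix(rnorm(40 * 8), 40, 8)))
  X <- sweep(X, 2, colMeans(X))
  colnames(X) <- paste0("g", 1:8)
  y <- X[, 2] * 5 + X[, 6] * 3 + rnorm(40, sd = 0.5)
  m <- fspls(X, y, family = "gaussian", ridge_lambda = 0)
  sel <- vapply(m$steps, `[[`, character(1), "feature_id")
  ols <- lm(y ~ X[, sel])
  expect_lt(max(abs(predict(m, X) - fitted(ols))), 1e-8)
})

test_that("the fit loop never reselects and step logliks are non-decreasing", {
  set.seed(23)
  for (i in 1:10) {
    fam <- c("gaussian", "binomial")[(i %% 2) + 1]
    sim <- simulate_gaussian(60, 15, fam, n_signal = 4, delta = 1.2,
                             seed = 400 + i)
    y <- if (fam == "gaussian") rowSums(sim$x[, 1:4]) + rnorm(60) else sim$y
    m <- fspls(sim$x, y, family = fam, ridge_lambda = 0, max_features = 6)
    ids <- vapply(m$steps, `[[`, character(1), "feature_id")
    expect_equal(anyDuplicated(ids), 0L)
    lls <- vapply(m$steps, `[[`, numeric(1), "loglik")
    if (length(lls) > 1) expect_true(all(diff(lls) >= -1e-6))
    # basis vectors are unit-norm and mutually orthogonal
    B <- vapply(m$steps, `[[`, numeric(60), "basis_vector")
    G <- crossprod(B)
    expect_lt(max(abs(G - diag(ncol(B)))), 1e-8)
  }
})

test_that("correlated blocks contribute at most one selected feature", {
  sim <- simulate_counts(m = 200, p = 60, family = "binomial", n_signal = 0,
                         n_housekeeping = 0, size_factor_sd = 0,
                         correlation_blocks = list(list(size = 5, rho = 0.96,
                                                        signal = TRUE)),
                         seed = 31)
  logx <- log_transform(sim$counts)
  m <- fspls(logx, sim$y, family = "binomial", max_features = 5)
  block <- sim$truth$blocks[[1]]
  sel <- vapply(m$steps, `[[`, character(1), "feature_id")
  expect_lte(sum(sel %in% block), 1)
})

test_that("max_features and force_to_max control the path length", {
  sim <- simulate_gaussian(80, 20, "binomial", n_signal = 3, delta = 1.5, seed = 24)
  m <- fspls(sim$x, sim$y, family = "binomial", max_features = 2)
  expect_length(m$steps, 2)
  expect_equal(m$stop_reason, "max_features")
  mf <- fspls(sim$x, sim$y, family = "binomial", max_features = 6,
              force_to_max = TRUE)
  expect_length(mf$steps, 6)
})

test_that("prediction replays training exactly, one sample at a time", {
  g <- golden_fixtures()
  mb <- fspls(g$b$x, g$b$y, family = "binomial")
  # training replay of the linear predictor
  expect_lt(max(abs(predict(mb, g$b$x, type = "link") - mb$training_linpred)),
            1e-10)
  # single-sample equals batch
  p <- predict(mb, g$b$x)
  ones <- vapply(1:nrow(g$b$x), function(i)
    predict(mb, g$b$x[i, , drop = FALSE]), numeric(1))
  expect_lt(max(abs(p - ones)), 1e-12)
  # a named vector works as a single sample
  expect_equal(unname(predict(mb, g$b$x[3, ])), unname(p[3]))
  # missing features are reported by name
  expect_error(predict(mb, g$b$x[, -1]), "g1")
})

test_that("zero-step models predict the null model", {
  sim <- simulate_gaussian(50, 10, "binomial", n_signal = 0, seed = 25)
  m <- fspls(sim$x, sim$y, family = "binomial", pvalue_threshold = 1e-12)
  expect_length(m$steps, 0)
  expect_equal(unname(predict(m, sim$x)), rep(mean(sim$y), 50))
})

test_that("through_step truncation matches a refit prefix's predictions", {
  sim <- simulate_gaussian(80, 20, "binomial", n_signal = 3, delta = 1.5, seed = 26)
  m <- fspls(sim$x, sim$y, family = "binomial", max_features = 3)
  m1 <- fspls(sim$x, sim$y, family = "binomial", max_features = 1)
  expect_equal(predict(m, sim$x, through_step = 1), predict(m1, sim$x),
               tolerance = 1e-10)
  expect_equal(predict(m, sim$x, through_step = 0),
               rep(mean(sim$y), 80), ignore_attr = TRUE)
})

test_that("model-size selection follows the min and one-SE rules", {
  expect_equal(select_model_size(c(5, 3, 2, 2.1), "min"), 3)
  expect_equal(select_model_size(c(5, 3, 2, 2), "min"), 3) # ties to smaller
  expect_equal(select_model_size(c(5, 3, 2), "one_se", se = c(1, 1, 1)), 2)
  expect_equal(select_model_size(c(5, 3, 2), "one_se", se = c(0, 0, 0)), 3)
  expect_error(select_model_size(numeric(0), "min"), "empty")
  expect_error(select_model_size(c(1, 2), "one_se"), "standard errors")
})

test_that("models survive a JSON round trip and reject unknown versions", {
  sim <- simulate_gaussian(60, 12, "binomial", n_signal = 2, delta = 2, seed = 27)
  m <- fspls(sim$x, sim$y, family = "binomial")
  tf <- tempfile(fileext = ".json")
  write_fspls_model(m, tf)
  m2 <- read_fspls_model(tf)
  expect_equal(predict(m2, sim$x), predict(m, sim$x), tolerance = 1e-12)
  expect_equal(m2$stop_reason, m$stop_reason)
  # multinomial round trip keeps class names
  simm <- simulate_counts(m = 90, p = 30, family = "multinomial", n_signal = 3,
                          effect_size = 2, class_proportions = rep(1 / 3, 3),
                          seed = 28)
  logm <- log_transform(simm$counts)
  mm <- fspls(logm, simm$y, family = "multinomial", max_features = 3)
  write_fspls_model(mm, tf)
  mm2 <- read_fspls_model(tf)
  expect_equal(predict(mm2, logm), predict(mm, logm), tolerance = 1e-12)
  # version guard
  doc <- jsonlite::read_json(tf)
  doc$version <- "99.0"
  jsonlite::write_json(doc, tf, auto_unbox = TRUE, null = "null")
  expect_error(read_fspls_model(tf), "version")
})
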