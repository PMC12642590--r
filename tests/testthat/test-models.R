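# Model construction, training, prediction and evaluation metrics.

test_that("architectures have the documented shapes and parameter counts", {
  # LR on a 56 x 40 input: one weight per feature plus intercept
  lr <- build_model(model_config("LR"), c(56, 40))
  expect_equal(n_parameters(lr), 56L * 40L + 1L)

  # valid-padding convolution: output length 56 - 5 + 1 = 52
  cnn <- build_model(model_config("CNN", filters = 16, kernel = 5),
                     c(56, 49))
  conv1 <- Filter(function(l) l$kind == "conv", cnn$layers)[[1]]
  expect_equal(conv1$Tout, 52L)
  expect_equal(dim(conv1$W), c(5L * 49L, 16L))

  # GCN needs a matching graph
  expect_error(build_model(model_config("GCN"), c(10, 40)), "requires")
  g <- build_contact_graph(matrix(rnorm(30), 10), 5)
  expect_error(build_model(model_config("GCN"), c(12, 40), g), "nodes")
})

test_that("LR training equals closed-form least squares on small instances", {
  set.seed(21)
  n <- 60; L <- 4; D <- 5
  x <- matrix(rnorm(n * L * D), n)
  beta <- rnorm(L * D + 1)
  y <- drop(cbind(1, x) %*% beta) + rnorm(n, sd = 0.1)
  m <- build_model(model_config("LR"), c(L, D))
  m <- train_model(m, x, y)
  oracle <- lm.fit(cbind(1, x), y)$coefficients
  expect_equal(unname(coef(m)), unname(oracle), tolerance = 1e-6)
  expect_equal(predict(m, x), drop(cbind(1, x) %*% oracle), tolerance = 1e-6)
})

test_that("LR recovers a noiseless linear fitness exactly", {
  w <- tiny_world()
  ds <- tiny_dataset(w, n = 150)
  res <- world_resources(w)
  x <- encode_dataset(ds, res, TRUE)
  set.seed(2)
  beta <- rnorm(ncol(x) + 1, sd = 0.3)
  y_lin <- drop(cbind(1, x) %*% beta)
  m <- train_model(build_model(model_config("LR"), c(attr(x, "L"), 49)),
                   x, y_lin)
  expect_gte(cor(predict(m, x), y_lin), 0.999)
})

test_that("training is deterministic under the config seed", {
  set.seed(5)
  n <- 120; L <- 6; D <- 8
  x <- matrix(rnorm(n * L * D), n)
  y <- rnorm(n)
  cfg <- model_config("NN", hidden = 8, epochs = 5, seed = 7)
  tr <- function() {
    m <- build_model(cfg, c(L, D))
    train_model(m, x[1:90, ], y[1:90], x[91:120, ], y[91:120])
  }
  a <- tr(); b <- tr()
  expect_identical(a$history, b$history)
  expect_identical(predict(a, x), predict(b, x))
})

test_that("prediction validates feature width and ignores row order", {
  set.seed(6)
  n <- 80; L <- 5; D <- 6
  x <- matrix(rnorm(n * L * D), n)
  y <- rnorm(n)
  m <- train_model(build_model(model_config("NN", hidden = 4, epochs = 3,
                                            seed = 1), c(L, D)),
                   x[1:60, ], y[1:60], x[61:80, ], y[61:80])
  expect_error(predict(m, x[, 1:10]), "columns")
  perm <- sample(n)
  expect_equal(predict(m, x)[perm], predict(m, x[perm, ]))
})

test_that("evaluation metrics match hand computations", {
  m <- structure(list(family = "LR", trained = TRUE, L = 2, D = 2,
                      coef = c(0, 1, 0, 0, 0)), class = "vep_model")
  ev0 <- eval_metrics(c(1, 2, 3, 4), c(1.5, 1.5, 3.5, 3.5))
  expect_equal(ev0$mae, 0.5)
  ev1 <- eval_metrics(1:10, 1:10)
  expect_equal(ev1$pearson, 1)
  expect_equal(ev1$spearman, 1)
  expect_equal(ev1$mae, 0)
  ev2 <- eval_metrics(1:10, -(1:10))
  expect_equal(ev2$pearson, -1)
  # constant predictions: correlations undefined, MAE still reported
  ev3 <- eval_metrics(1:4, rep(2.5, 4))
  expect_true(ev3$constant)
  expect_true(is.na(ev3$pearson))
  expect_equal(ev3$mae, mean(abs(1:4 - 2.5)))
  # MAE stratified by mutation count
  ev4 <- eval_metrics(c(0, 0, 0), c(1, 2, 3), n_mut = c(1, 1, 2))
  expect_equal(unname(ev4$mae_by_n_mut["1"]), 1.5)
  expect_equal(unname(ev4$mae_by_n_mut["2"]), 3)
})

test_that("a one-layer GCN on an edgeless graph is per-residue local", {
  L <- 8; D <- 5
  g <- structure(list(adjacency = matrix(0, L, L)), class = "contact_graph")
  cfg <- model_config("GCN", gcn_channels = 3, hidden = 4, seed = 2)
  m <- build_model(cfg, c(L, D), g)
  # propagation matrix of the edgeless graph is the identity
  gcn_layer <- Filter(function(l) l$kind == "gcn", m$layers)[[1]]
  expect_equal(gcn_layer$Ahat, diag(L))
  # node outputs after the graph convolution depend only on their own input
  x1 <- matrix(rnorm(L * D), 1)
  x2 <- x1
  x2[1, (3 * D + 1):(4 * D)] <- rnorm(D)   # perturb node 4 only
  fw1 <- biovep:::net_forward(m$layers[1:2], x1)
  fw2 <- biovep:::net_forward(m$layers[1:2], x2)
  H1 <- matrix(fw1$out, L)  # (n*L) x channels with n = 1: rows are nodes
  H2 <- matrix(fw2$out, L)
  changed <- which(rowSums(H1 != H2) > 0)
  expect_equal(changed, 4L)
})

test_that("vep_fit returns a fitted model with working methods", {
  w <- tiny_world()
  ds <- tiny_dataset(w, n = 200)
  res <- world_resources(w)
  fit <- vep_fit(ds, res, model_config("LR"), scheme = "random")
  expect_s3_class(fit, "vep_model")
  expect_true(fit$trained)
  expect_equal(fit$split$scheme, "random")
  expect_length(residuals(fit), length(fit$split$test))
  expect_equal(fitted(fit) + residuals(fit), fit$test$truth)
  expect_output(print(fit), "LR variant effect predictor")
  # predict on a dms_dataset goes through the stored resources
  p <- predict(fit, ds)
  expect_length(p, nrow(ds$variants))
  # degenerate: constant scores still train and flag undefined correlations
  ds2 <- ds
  ds2$variants$score <- rep(1, nrow(ds2$variants))
  fit2 <- vep_fit(ds2, res, model_config("LR"), scheme = "random")
  expect_true(fit2$eval$constant || fit2$eval$mae < 1e-8)
})

test_that("run_experiment produces a tidy table with median summaries", {
  w <- tiny_world()
  ds <- tiny_dataset(w, n = 250)
  res <- world_resources(w)
  out <- run_experiment(ds, res, schemes = "random", families = "LR",
                        with_biophysics = c(TRUE, FALSE), n_repeats = 2)
  expect_equal(nrow(out), 4L)
  expect_setequal(names(out)[1:4], c("scheme", "family", "biophysics", "seed"))
  s <- experiment_summary(out)
  expect_equal(nrow(s), 2L)
  # single repeat gives a single-row report
  out1 <- run_experiment(ds, res, schemes = "random", families = "LR",
                         with_biophysics = TRUE, n_repeats = 1)
  expect_equal(nrow(out1), 1L)
})

test_that("grid search selects a candidate by validation loss", {
  w <- tiny_world()
  ds <- tiny_dataset(w, n = 200)
  res <- world_resources(w)
  grid <- list(LR = list(model_config("LR", ridge = 0),
                         model_config("LR", ridge = 1e3)))
  out <- run_experiment(ds, res, schemes = "random", families = "LR",
                        with_biophysics = TRUE, n_repeats = 1, grid = grid)
  expect_equal(nrow(out), 1L)
  expect_false(is.na(out$pearson))
})
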