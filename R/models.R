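# Model families (LR / NN / CNN / GCN), training, evaluation and the
# multi-scheme experiment harness.

#' Model configuration
#'
#' Collects every tunable of the four regressor families. Nothing here is
#' hard-coded elsewhere: the experiment harness accepts lists of
#' configurations for validation-based grid search.
#'
#' @param family One of `"LR"`, `"NN"`, `"CNN"`, `"GCN"`.
#' @param hidden Dense hidden-layer widths (after flatten for CNN/GCN).
#' @param filters Convolution channel widths, one per conv layer (CNN).
#' @param kernel Convolution kernel width in residues (CNN).
#' @param gcn_channels Graph-convolution channel widths, one per layer (GCN).
#' @param dropout Dropout rate after the hidden dense layer; default 0.2.
#' @param group_dropout Feature-bagging rate: probability of dropping each
#'   whole encoding block (one-hot / AAIndex / energy / RMSF, all positions
#'   at once) per training sample, with inverse scaling of survivors. Forces
#'   every block to carry predictive weight on its own, which is what lets
#'   the position-transferable energy block be learned in the presence of
#'   the more easily memorized sequence blocks. 0 disables.
#' @param lrelu_slope Negative-side slope of the leaky ReLU.
#' @param learning_rate Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param min_epochs Burn-in epochs: epochs before this are never selected as
#'   best weights or snapshots and the early-stopping clock does not run.
#'   Useful under extrapolation splits, where the validation criterion is
#'   noisy before the transferable signal has developed.
#' @param lr_decay Per-epoch multiplicative learning-rate decay (1 = constant
#'   rate).
#' @param early_stop Validation criterion for early stopping and best-weight
#'   selection: `"loss"` (validation MSE) or `"spearman"` (validation rank
#'   correlation, calibration-insensitive — the more stable choice under
#'   extrapolation splits, where a model can rank unseen-position variants
#'   well before its output scale is calibrated).
#' @param snapshots Number of best-validation weight snapshots kept during
#'   training; predictions average over them (iterate ensembling). 1 keeps
#'   only the single best epoch.
#' @param restart_every Warm-restart period in epochs: reload the
#'   best-validation weights and reset the optimizer moments every this many
#'   epochs (0 disables). Counters memorization drift on extrapolation
#'   splits.
#' @param weight_decay Decoupled (AdamW-style) weight-decay rate applied to
#'   the dense head layers only; the shared convolution / graph-convolution
#'   filters are never decayed. Penalizing the position-indexed readout while
#'   leaving the weight-shared filters free pushes the fit toward
#'   position-balanced solutions, which is what lets the energy channel
#'   transfer to unseen positions.
#' @param seed Seed controlling initialization, data order and dropout.
#' @param ridge Ridge penalty for the LR family (0 = ridgeless).
#' @return Object of class `vep_config`.
#' @export
model_config <- function(family = c("LR", "NN", "CNN", "GCN"),
                         hidden = 64L, filters = c(16L, 16L), kernel = 5L,
                         gcn_channels = c(16L, 16L), dropout = 0.2,
                         group_dropout = 0,
                         lrelu_slope = 0.01, learning_rate = 1e-3,
                         batch_size = 64L, epochs = 100L, patience = 10L,
                         min_epochs = 0L, weight_decay = NULL, lr_decay = 1,
                         early_stop = c("loss", "spearman"), snapshots = 1L,
                         restart_every = 0L, seed = 1L, ridge = 0) {
  family <- match.arg(family)
  early_stop <- match.arg(early_stop)
  # shared-filter families default to a strongly decayed head (see vignette);
  # decaying a pure dense network would penalize every layer, so NN/LR do not
  if (is.null(weight_decay))
    weight_decay <- if (family %in% c("CNN", "GCN")) 10 else 0
  stopifnot(dropout >= 0, dropout < 1, group_dropout >= 0, group_dropout < 1,
            all(hidden >= 1), kernel >= 1,
            all(filters >= 1), all(gcn_channels >= 1), learning_rate > 0,
            batch_size >= 1, epochs >= 1, patience >= 0, weight_decay >= 0,
            lr_decay > 0, lr_decay <= 1, ridge >= 0)
  structure(list(family = family, hidden = as.integer(hidden),
                 filters = as.integer(filters), kernel = as.integer(kernel),
                 gcn_channels = as.integer(gcn_channels), dropout = dropout,
                 group_dropout = group_dropout,
                 lrelu_slope = lrelu_slope, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 min_epochs = as.integer(min_epochs),
                 weight_decay = weight_decay, lr_decay = lr_decay,
                 early_stop = early_stop, snapshots = as.integer(snapshots),
                 restart_every = as.integer(restart_every),
                 seed = as.integer(seed), ridge = ridge),
            class = "vep_config")
}

#' @export
print.vep_config <- function(x, ...) {
  cat(sprintf("%s config: ", x$family))
  extra <- switch(x$family,
                  LR = sprintf("ridge %.3g", x$ridge),
                  NN = paste("hidden", paste(x$hidden, collapse = "-")),
                  CNN = sprintf("filters %s kernel %d hidden %s",
                                paste(x$filters, collapse = "-"), x$kernel,
                                paste(x$hidden, collapse = "-")),
                  GCN = sprintf("channels %s hidden %s",
                                paste(x$gcn_channels, collapse = "-"),
                                paste(x$hidden, collapse = "-")))
  cat(extra, sprintf("| dropout %.2f lr %.3g batch %d epochs %d seed %d\n",
                     x$dropout, x$learning_rate, x$batch_size, x$epochs, x$seed))
  invisible(x)
}

#' Build an untrained model
#'
#' Constructs the architecture for a given input shape: LR is an affine map
#' on the flattened `N_res x D` matrix; NN stacks dense layers with leaky
#' ReLU; CNN applies stride-1, valid-padding 1-D convolutions across residue
#' positions (features as channels) before a dense head; GCN applies graph
#' convolutions over the symmetric-normalized contact-graph propagation
#' matrix. All nonlinear families end with leaky ReLU, dropout after the
#' hidden dense layer, and a scalar linear output.
#'
#' @param config A [model_config()].
#' @param input_shape Integer pair `c(N_res, D)`.
#' @param graph A [build_contact_graph()] result; required for GCN, whose
#'   node count must equal `N_res`.
#' @param feature_blocks Flattened column indices of the encoding blocks (the
#'   `blocks` attribute of [encode_dataset()] output); required when
#'   `config$group_dropout > 0`.
#' @return An untrained `vep_model`.
#' @export
build_model <- function(config, input_shape, graph = NULL,
                        feature_blocks = NULL) {
  stopifnot(inherits(config, "vep_config"), length(input_shape) == 2L)
  L <- as.integer(input_shape[1]); D <- as.integer(input_shape[2])
  layers <- NULL
  if (config$family == "GCN") {
    if (is.null(graph)) stop("GCN requires a contact graph")
    A <- if (inherits(graph, "contact_graph")) graph$adjacency else as.matrix(graph)
    if (nrow(A) != L)
      stop("graph has ", nrow(A), " nodes but the input has ", L, " residues")
  }
  if (config$group_dropout > 0 && config$family != "LR" &&
      is.null(feature_blocks))
    stop("group_dropout > 0 requires feature_blocks (see encode_dataset)")
  if (config$family != "LR") {
    layers <- with_seed(config$seed, build_layers(config, L, D, graph))
    if (config$group_dropout > 0)
      layers <- c(list(layer_group_dropout(feature_blocks,
                                           config$group_dropout)), layers)
  }
  structure(list(family = config$family, config = config, L = L, D = D,
                 layers = layers, coef = NULL, trained = FALSE,
                 history = NULL),
            class = "vep_model")
}

build_layers <- function(config, L, D, graph) {
  slope <- config$lrelu_slope
  layers <- list()
  if (config$family == "NN") {
    nin <- L * D
    for (h in config$hidden) {
      layers <- c(layers, list(layer_dense(nin, h), layer_lrelu(slope)))
      nin <- h
    }
    layers <- c(layers, list(layer_dropout(config$dropout),
                             layer_dense(nin, 1L)))
  } else if (config$family == "CNN") {
    len <- L; ch <- D
    layers <- list(layer_to_seq(L, D))
    for (nf in config$filters) {
      if (len < config$kernel)
        stop("sequence length ", len, " shorter than kernel ", config$kernel)
      layers <- c(layers, list(layer_conv(len, ch, config$kernel, nf),
                               layer_lrelu(slope)))
      len <- len - config$kernel + 1L; ch <- nf
    }
    layers <- c(layers, list(layer_flatten(len, ch)))
    nin <- len * ch
    for (h in config$hidden) {
      layers <- c(layers, list(layer_dense(nin, h), layer_lrelu(slope)))
      nin <- h
    }
    layers <- c(layers, list(layer_dropout(config$dropout),
                             layer_dense(nin, 1L)))
  } else if (config$family == "GCN") {
    Ahat <- normalize_adjacency(graph)
    ch <- D
    layers <- list(layer_to_seq(L, D))
    for (nf in config$gcn_channels) {
      layers <- c(layers, list(layer_gcn(L, ch, nf, Ahat), layer_lrelu(slope)))
      ch <- nf
    }
    layers <- c(layers, list(layer_flatten(L, ch)))
    nin <- L * ch
    for (h in config$hidden) {
      layers <- c(layers, list(layer_dense(nin, h), layer_lrelu(slope)))
      nin <- h
    }
    layers <- c(layers, list(layer_dropout(config$dropout),
                             layer_dense(nin, 1L)))
  }
  layers
}

#' Count of trainable parameters
#' @param model A `vep_model`.
#' @return Integer.
#' @export
n_parameters <- function(model) {
  if (model$family == "LR") return(model$L * model$D + 1L)
  sum(vapply(model$layers, function(l)
    if (is.null(l$W)) 0L else length(l$W) + length(l$b), 0L))
}

check_input <- function(model, x) {
  if (ncol(x) != model$L * model$D)
    stop("feature matrix has ", ncol(x), " columns; model was trained on ",
         "N_res x D = ", model$L, " x ", model$D, " = ", model$L * model$D)
}

#' Train a model on encoded data
#'
#' Minimizes mean-squared error on the functional scores. LR is solved by
#' exact least squares; the other families run seeded mini-batch Adam with
#' early stopping on the validation loss, restoring the best weights. The
#' whole procedure (initialization, batch order, dropout) is a deterministic
#' function of `config$seed`.
#'
#' @param model An untrained [build_model()] result.
#' @param x,y Training feature matrix (`n x (N_res*D)`) and score vector.
#' @param x_val,y_val Validation set (required for NN/CNN/GCN early stopping).
#' @return The trained `vep_model` with a `$history` data frame
#'   (epoch, train_loss, val_loss).
#' @export
train_model <- function(model, x, y, x_val = NULL, y_val = NULL) {
  stopifnot(inherits(model, "vep_model"))
  check_input(model, x)
  if (any(!is.finite(y))) stop("training scores must be finite")
  cfg <- model$config
  if (model$family == "LR") {
    model$coef <- lstsq_fit(x, y, ridge = cfg$ridge)
    tl <- mean((lstsq_predict(model$coef, x) - y)^2)
    vl <- if (is.null(x_val)) NA_real_
          else mean((lstsq_predict(model$coef, x_val) - y_val)^2)
    model$history <- data.frame(epoch = 1L, train_loss = tl, val_loss = vl)
  } else {
    if (is.null(x_val))
      stop(model$family, " training requires a validation set for early stopping")
    check_input(model, x_val)
    # standardize targets so the default learning rate is scale-free
    ctr <- mean(y)
    scl <- stats::sd(y)
    if (!is.finite(scl) || scl == 0) scl <- 1
    fit <- with_seed(cfg$seed, net_train(
      model$layers, x, (y - ctr) / scl, x_val, (y_val - ctr) / scl,
      lr = cfg$learning_rate, batch_size = cfg$batch_size,
      epochs = cfg$epochs, patience = cfg$patience,
      weight_decay = cfg$weight_decay, lr_decay = cfg$lr_decay,
      select = cfg$early_stop, min_epochs = cfg$min_epochs,
      snapshots = cfg$snapshots, restart_every = cfg$restart_every))
    model$layers <- fit$layers
    model$snapshot_layers <- fit$snapshot_layers
    model$y_center <- ctr
    model$y_scale <- scl
    model$history <- fit$history
    model$best_epoch <- fit$best_epoch
  }
  model$trained <- TRUE
  model
}

#' Predict scores for new variants
#'
#' @param object A trained `vep_model`.
#' @param newdata An encoded feature matrix (`n x (N_res*D)`), a single
#'   `N_res x D` matrix, or a [dms_dataset()] (possible when the model was
#'   fitted through [vep_fit()], which stores its feature resources).
#' @param ... Unused.
#' @return Numeric vector of predicted scores.
#' @export
predict.vep_model <- function(object, newdata, ...) {
  if (!object$trained) stop("model is not trained")
  if (inherits(newdata, "dms_dataset")) {
    if (is.null(object$resources))
      stop("model carries no feature resources; encode the dataset first")
    newdata <- encode_dataset(newdata, object$resources,
                              object$with_biophysics)
  }
  if (is.matrix(newdata) && nrow(newdata) == object$L &&
      ncol(newdata) == object$D)
    newdata <- matrix(as.vector(t(newdata)), nrow = 1L)
  check_input(object, newdata)
  if (object$family == "LR") return(lstsq_predict(object$coef, newdata))
  raw <- if (is.null(object$snapshot_layers)) {
    net_predict(object$layers, newdata)
  } else {
    preds <- vapply(object$snapshot_layers,
                    function(ly) net_predict(ly, newdata),
                    numeric(nrow(newdata)))
    if (is.matrix(preds)) rowMeans(preds) else mean(preds)
  }
  raw * (object$y_scale %||% 1) + (object$y_center %||% 0)
}

#' Evaluate predictions against true scores
#'
#' Computes Pearson r, Spearman rho and MAE between true and predicted
#' scores, plus an MAE breakdown by mutations-per-variant when available.
#' Correlations are undefined (reported `NA` with `constant = TRUE`) when
#' either vector is constant.
#'
#' @param model A trained `vep_model`.
#' @param x Encoded test features (may carry an `n_mut` attribute, as
#'   [encode_dataset()] output does).
#' @param y True scores.
#' @param n_mut Optional mutations-per-variant vector for the MAE breakdown.
#' @return Object of class `vep_eval`: list with `pearson`, `spearman`,
#'   `mae`, `mae_by_n_mut`, `n`, `constant`.
#' @export
evaluate_model <- function(model, x, y, n_mut = NULL) {
  if (length(y) == 0L) stop("empty test set")
  pred <- predict(model, x)
  if (is.null(n_mut)) n_mut <- attr(x, "n_mut", exact = TRUE)
  eval_metrics(y, pred, n_mut)
}

eval_metrics <- function(y, pred, n_mut = NULL) {
  constant <- stats::sd(pred) == 0 || stats::sd(y) == 0
  pearson <- if (constant) NA_real_ else stats::cor(y, pred)
  spearman <- if (constant) NA_real_
              else stats::cor(y, pred, method = "spearman")
  mae <- mean(abs(y - pred))
  mae_by <- if (is.null(n_mut)) NULL
            else tapply(abs(y - pred), n_mut, mean)
  structure(list(pearson = pearson, spearman = spearman, mae = mae,
                 mae_by_n_mut = mae_by, n = length(y), constant = constant),
            class = "vep_eval")
}

#' @export
print.vep_eval <- function(x, ...) {
  cat(sprintf("n = %d: Pearson %s, Spearman %s, MAE %.4g%s\n", x$n,
              format(round(x$pearson, 3)), format(round(x$spearman, 3)),
              x$mae,
              if (x$constant) " (constant predictions: correlations undefined)" else ""))
  if (!is.null(x$mae_by_n_mut)) {
    cat("  MAE by mutation count: ",
        paste(sprintf("%s:%.3g", names(x$mae_by_n_mut), x$mae_by_n_mut),
              collapse = "  "), "\n", sep = "")
  }
  invisible(x)
}

#' Fit a variant effect predictor
#'
#' The central fitting function: splits the dataset under the chosen scheme,
#' encodes variants with or without the biophysics blocks, trains the model
#' family given by `config`, and evaluates on the held-out test set. The
#' returned object supports `print`, `summary`, `coef`, `predict`,
#' `residuals` and `plot`.
#'
#' @param dataset A [dms_dataset()] with scores.
#' @param resources A [feature_resources()] bundle for the same reference.
#' @param config A [model_config()]; its seed drives the split and training.
#' @param scheme Split scheme (ignored when `split` is given).
#' @param with_biophysics Include energy + RMSF feature blocks.
#' @param graph Contact graph (required for GCN).
#' @param split An existing `data_split` to reuse.
#' @param fractions Split fractions.
#' @return A trained `vep_model` carrying `$split`, `$eval` (test metrics),
#'   `$test` (indices, truth, predictions), `$resources` and
#'   `$with_biophysics`.
#' @examples
#' \donttest{
#' w <- generate_world(L = 30, seed = 1)
#' ds <- generate_dms(w, n_variants = 400, seed = 1)
#' res <- world_resources(w)
#' fit <- vep_fit(ds, res, model_config("LR"), scheme = "random")
#' fit
#' }
#' @export
vep_fit <- function(dataset, resources, config = model_config("CNN"),
                    scheme = c("random", "mutational", "positional"),
                    with_biophysics = TRUE, graph = NULL, split = NULL,
                    fractions = c(0.70, 0.15, 0.15)) {
  scheme <- match.arg(scheme)
  if (is.null(split))
    split <- make_split(dataset, scheme, fractions, seed = config$seed)
  x <- encode_dataset(dataset, resources, with_biophysics)
  y <- dataset$variants$score
  used <- c(split$train, split$validation, split$test)
  if (any(is.na(y[used]))) stop("dataset has missing scores in the split")
  model <- build_model(config, c(attr(x, "L"), attr(x, "D")), graph,
                       feature_blocks = attr(x, "blocks"))
  model <- train_model(model,
                       x[split$train, , drop = FALSE], y[split$train],
                       x[split$validation, , drop = FALSE], y[split$validation])
  model$split <- split
  model$resources <- resources
  model$with_biophysics <- with_biophysics
  model$dataset_name <- dataset$name
  if (length(split$test)) {
    xt <- x[split$test, , drop = FALSE]
    pred <- predict(model, xt)
    model$eval <- eval_metrics(y[split$test], pred,
                               attr(x, "n_mut")[split$test])
    model$test <- list(index = split$test, truth = y[split$test],
                       predicted = pred)
  }
  model
}

#' @export
print.vep_model <- function(x, ...) {
  cat(sprintf("%s variant effect predictor (%s)\n", x$family,
              if (x$trained) "trained" else "untrained"))
  cat(sprintf("  input: %d residues x %d features; %d parameters\n",
              x$L, x$D, n_parameters(x)))
  if (!is.null(x$split))
    cat(sprintf("  %s split, biophysics %s\n", x$split$scheme,
                if (isTRUE(x$with_biophysics)) "on" else "off"))
  if (!is.null(x$eval)) { cat("  test "); print(x$eval) }
  invisible(x)
}

#' @export
summary.vep_model <- function(object, ...) {
  print(object)
  if (!is.null(object$history) && nrow(object$history) > 1) {
    cat(sprintf("  trained %d epochs (best at %d), final val loss %.4g\n",
                max(object$history$epoch),
                object$best_epoch %||% max(object$history$epoch),
                object$history$val_loss[nrow(object$history)]))
  }
  invisible(object)
}

#' @export
coef.vep_model <- function(object, ...) {
  if (!object$trained) stop("model is not trained")
  if (object$family == "LR") {
    cf <- object$coef
    names(cf) <- c("(Intercept)", paste0("x", seq_len(length(cf) - 1L)))
    return(cf)
  }
  params <- Filter(Negate(is.null),
                   lapply(object$layers,
                          function(l) if (is.null(l$W)) NULL else list(W = l$W, b = l$b)))
  params
}

#' @export
residuals.vep_model <- function(object, ...) {
  if (is.null(object$test)) stop("model has no stored test set")
  object$test$truth - object$test$predicted
}

#' @export
fitted.vep_model <- function(object, ...) {
  if (is.null(object$test)) stop("model has no stored test set")
  object$test$predicted
}

#' Diagnostic plot: test predictions vs truth and training history
#' @param x A fitted `vep_model` from [vep_fit()].
#' @param ... Passed to `plot`.
#' @export
plot.vep_model <- function(x, ...) {
  if (is.null(x$test)) stop("model has no stored test set")
  op <- graphics::par(mfrow = c(1, if (is.null(x$history) ||
                                       nrow(x$history) < 2) 1 else 2))
  on.exit(graphics::par(op))
  graphics::plot(x$test$truth, x$test$predicted,
                 xlab = "observed score", ylab = "predicted score",
                 main = sprintf("%s test set (r = %s)", x$family,
                                format(round(x$eval$pearson, 2))), ...)
  graphics::abline(0, 1, lty = 2)
  if (!is.null(x$history) && nrow(x$history) >= 2) {
    graphics::matplot(x$history$epoch,
                      cbind(x$history$train_loss, x$history$val_loss),
                      type = "l", lty = 1, xlab = "epoch", ylab = "MSE",
                      main = "training history")
    graphics::legend("topright", c("train", "validation"), lty = 1,
                     col = 1:2, bty = "n")
  }
  invisible(x)
}

#' Run the full with/without-biophysics experiment
#'
#' For every combination of split scheme, model family, biophysics flag and
#' repeat seed: split, encode, train, evaluate. Optionally grid-searches a
#' list of candidate configurations per family, selecting by validation MSE.
#'
#' @param dataset A scored [dms_dataset()].
#' @param resources A [feature_resources()] bundle.
#' @param graph Contact graph (needed when `"GCN"` is among the families).
#' @param schemes Subset of `c("random", "mutational", "positional")`.
#' @param families Subset of `c("LR", "NN", "CNN", "GCN")`.
#' @param with_biophysics Logical vector of feature regimes to run.
#' @param n_repeats Seeded repeats per cell; default 5.
#' @param seeds Explicit seeds (default `1:n_repeats`); each seed drives both
#'   the split and the training.
#' @param configs Named list of [model_config()] templates per family
#'   (defaults used otherwise).
#' @param grid Named list (per family) of *lists* of configs to grid-search.
#' @param fractions Split fractions.
#' @return Data frame with one row per run (scheme, family, biophysics, seed,
#'   pearson, spearman, mae, n_train, n_test) and a `summary` attribute of
#'   medians over repeats; see [experiment_summary()].
#' @export
run_experiment <- function(dataset, resources, graph = NULL,
                           schemes = c("random", "mutational", "positional"),
                           families = c("LR", "NN", "CNN", "GCN"),
                           with_biophysics = c(TRUE, FALSE),
                           n_repeats = 5L, seeds = NULL, configs = NULL,
                           grid = NULL, fractions = c(0.70, 0.15, 0.15)) {
  if (is.null(seeds)) seeds <- seq_len(n_repeats)
  y <- dataset$variants$score
  if (any(is.na(y))) stop("dataset has missing scores")
  encodings <- lapply(stats::setNames(unique(with_biophysics),
                                      unique(with_biophysics)),
                      function(bp) encode_dataset(dataset, resources, bp))
  rows <- list()
  for (scheme in schemes) for (seed in seeds) {
    split <- make_split(dataset, scheme, fractions, seed = seed)
    for (bp in unique(with_biophysics)) {
      x <- encodings[[as.character(bp)]]
      for (family in families) {
        base_cfg <- if (!is.null(configs[[family]])) configs[[family]]
                    else model_config(family)
        candidates <- if (!is.null(grid[[family]])) grid[[family]]
                      else list(base_cfg)
        best <- NULL; best_val <- Inf
        for (cand in candidates) {
          cand$seed <- as.integer(seed)
          m <- build_model(cand, c(attr(x, "L"), attr(x, "D")), graph,
                           feature_blocks = attr(x, "blocks"))
          m <- train_model(m, x[split$train, , drop = FALSE], y[split$train],
                           x[split$validation, , drop = FALSE],
                           y[split$validation])
          val <- if (!is.null(m$history$val_crit))
            min(m$history$val_crit, na.rm = TRUE)
          else min(m$history$val_loss, na.rm = TRUE)
          if (val < best_val) { best <- m; best_val <- val }
        }
        ev <- evaluate_model(best, x[split$test, , drop = FALSE],
                             y[split$test],
                             attr(x, "n_mut")[split$test])
        rows[[length(rows) + 1L]] <- data.frame(
          scheme = scheme, family = family, biophysics = bp,
          seed = seed, pearson = ev$pearson, spearman = ev$spearman,
          mae = ev$mae, n_train = length(split$train),
          n_test = length(split$test))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- experiment_summary(out)
  out
}

#' Median-over-repeats summary of an experiment table
#' @param results The data frame returned by [run_experiment()].
#' @return Data frame of medians of pearson/spearman/mae per
#'   (scheme, family, biophysics) cell.
#' @export
experiment_summary <- function(results) {
  agg <- stats::aggregate(results[c("pearson", "spearman", "mae")],
                          by = results[c("scheme", "family", "biophysics")],
                          FUN = function(v) stats::median(v, na.rm = TRUE))
  agg[order(agg$scheme, agg$family, agg$biophysics), , drop = FALSE]
}
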