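# Library-size x read-depth resampling benchmark: how DMS dataset quality
# (number of variants, sequencing depth) limits VEP accuracy.

#' Design of a resampling experiment
#'
#' @param library_sizes Integer grid of training-library sizes (variants).
#' @param read_budgets Numeric grid of total sequencing-read budgets
#'   (input + selected pools combined).
#' @param test_size Held-out test-set size; default 10000, truncated to the
#'   dataset size.
#' @param replicates Resampled libraries per grid cell; default 5.
#' @param seed Master seed for the whole experiment.
#' @return Object of class `resample_design`.
#' @export
resample_design <- function(library_sizes, read_budgets, test_size = 10000L,
                            replicates = 5L, seed = 1L) {
  stopifnot(all(library_sizes >= 1), all(read_budgets >= 1),
            test_size >= 1, replicates >= 1)
  structure(list(library_sizes = as.integer(library_sizes),
                 read_budgets = as.numeric(read_budgets),
                 test_size = as.integer(test_size),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "resample_design")
}

# Fast row subset of a dms_dataset (skips re-parsing).
subset_dataset <- function(dataset, idx, name = dataset$name) {
  out <- dataset
  out$variants <- dataset$variants[idx, , drop = FALSE]
  rownames(out$variants) <- NULL
  out$mutations <- dataset$mutations[idx]
  out$name <- name
  out
}

#' Split a counted dataset into a fixed test set and a resampling pool
#'
#' Draws the test set uniformly at random (seeded by the design) and leaves
#' the remainder as the base pool from which training libraries are
#' resampled; the two never overlap.
#'
#' @param dataset A [dms_dataset()] with read counts.
#' @param design A [resample_design()].
#' @return List with `test` and `pool` (both `dms_dataset`s) and the
#'   corresponding index vectors `test_idx`, `pool_idx`.
#' @export
make_base <- function(dataset, design) {
  v <- dataset$variants
  if (all(is.na(v$count_input)) || all(is.na(v$count_selected)))
    stop("dataset has no read counts")
  n <- nrow(v)
  size <- min(design$test_size, n)
  test_idx <- with_seed(design$seed, sort(sample.int(n, size)))
  pool_idx <- setdiff(seq_len(n), test_idx)
  if (length(pool_idx) == 0L)
    stop("test set consumes the whole dataset; nothing left to resample")
  list(test = subset_dataset(dataset, test_idx, "test"),
       pool = subset_dataset(dataset, pool_idx, "pool"),
       test_idx = test_idx, pool_idx = pool_idx)
}

#' Resample a training library from the base pool
#'
#' Draws a uniform variant subset of size `library_size`, renormalizes its
#' input and selected read counts into two multinomial distributions, splits
#' `read_budget` between the input and selected pools in proportion to the
#' base pool's total input:selected read fraction, and draws new counts from
#' the two multinomials. The drawn reads always sum exactly to `read_budget`.
#'
#' @param pool Base-pool `dms_dataset` (from [make_base()]).
#' @param library_size Number of variants to sample (without replacement).
#' @param read_budget Total reads to distribute.
#' @param seed Seed for this library.
#' @return A `dms_dataset` of `library_size` variants with fresh
#'   `count_input` / `count_selected` columns (scores cleared; rescore with
#'   [score_from_counts()]).
#' @export
resample_library <- function(pool, library_size, read_budget, seed = 1L) {
  v <- pool$variants
  n <- nrow(v)
  if (library_size > n)
    stop("library_size ", library_size, " exceeds pool size ", n)
  tot_in <- sum(v$count_input); tot_sel <- sum(v$count_selected)
  if (tot_in <= 0 || tot_sel <= 0)
    stop("pool has zero total reads in one condition")
  with_seed(seed, {
    idx <- sort(sample.int(n, library_size))
    sub <- subset_dataset(pool, idx, "library")
    p_in <- sub$variants$count_input
    p_sel <- sub$variants$count_selected
    if (sum(p_in) <= 0 || sum(p_sel) <= 0)
      stop("sampled library has zero total reads in one condition")
    frac_in <- tot_in / (tot_in + tot_sel)
    budget_in <- round(read_budget * frac_in)
    budget_sel <- read_budget - budget_in
    sub$variants$count_input <- as.numeric(
      stats::rmultinom(1L, budget_in, p_in / sum(p_in)))
    sub$variants$count_selected <- as.numeric(
      stats::rmultinom(1L, budget_sel, p_sel / sum(p_sel)))
    sub$variants$score <- NA_real_
    attr(sub, "pool_index") <- idx
    sub
  })
}

#' Run the resampling grid
#'
#' For every (library size, read budget) cell and replicate: resample a
#' library, recompute enrichment scores from the fresh counts, train the
#' specified model on the library, and measure test-set Pearson r against the
#' base scores of the fixed held-out test set. Cells whose library size
#' exceeds the pool are reported empty.
#'
#' Scores of resampled libraries are centered on the base dataset's wild-type
#' counts (the wild-type record need not survive subsampling; the centering
#' term is a constant offset and does not affect correlations).
#'
#' @param dataset A counted [dms_dataset()]; scores are computed from counts
#'   if absent.
#' @param design A [resample_design()].
#' @param resources A [feature_resources()] bundle.
#' @param config Model configuration; default exact linear regression, which
#'   keeps the grid fast.
#' @param with_biophysics Feature regime for the trained models.
#' @param graph Contact graph (only for a GCN `config`).
#' @param val_fraction Fraction of each library held out for validation /
#'   early stopping.
#' @return Data frame (class `resample_grid`): `library_size`, `read_budget`,
#'   `replicate`, `pearson`, `spearman`, `n_train`, `empty`.
#' @export
score_and_grid <- function(dataset, design, resources,
                           config = model_config("LR"),
                           with_biophysics = TRUE, graph = NULL,
                           val_fraction = 0.15) {
  if (all(is.na(dataset$variants$score)))
    dataset <- score_from_counts(dataset)
  base <- make_base(dataset, design)
  iwt <- which(n_mutations(dataset) == 0L)
  wt_counts <- if (length(iwt))
    c(dataset$variants$count_input[iwt[1]], dataset$variants$count_selected[iwt[1]])
  else c(0, 0)
  x_all <- encode_dataset(dataset, resources, with_biophysics)
  x_test <- x_all[base$test_idx, , drop = FALSE]
  y_test <- dataset$variants$score[base$test_idx]
  rows <- list()
  cell <- 0L
  for (ls in design$library_sizes) for (rb in design$read_budgets) {
    for (rep in seq_len(design$replicates)) {
      cell <- cell + 1L
      if (ls > nrow(base$pool$variants)) {
        rows[[cell]] <- data.frame(library_size = ls, read_budget = rb,
                                   replicate = rep, pearson = NA_real_,
                                   spearman = NA_real_, n_train = NA_integer_,
                                   empty = TRUE)
        next
      }
      seed_r <- (design$seed + 7919L * cell) %% .Machine$integer.max
      lib <- resample_library(base$pool, ls, rb, seed = seed_r)
      lib <- score_from_counts(lib, wt_counts = wt_counts)
      lib_rows <- base$pool_idx[attr(lib, "pool_index")]
      x_lib <- x_all[lib_rows, , drop = FALSE]
      y_lib <- lib$variants$score
      n_lib <- length(y_lib)
      n_val <- max(1L, floor(val_fraction * n_lib))
      val <- with_seed(seed_r + 1L, sample.int(n_lib, n_val))
      tr <- setdiff(seq_len(n_lib), val)
      cfg <- config; cfg$seed <- as.integer(seed_r)
      m <- build_model(cfg, c(attr(x_all, "L"), attr(x_all, "D")), graph,
                       feature_blocks = attr(x_all, "blocks"))
      m <- train_model(m, x_lib[tr, , drop = FALSE], y_lib[tr],
                       x_lib[val, , drop = FALSE], y_lib[val])
      ev <- evaluate_model(m, x_test, y_test)
      rows[[cell]] <- data.frame(library_size = ls, read_budget = rb,
                                 replicate = rep, pearson = ev$pearson,
                                 spearman = ev$spearman, n_train = n_lib,
                                 empty = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("resample_grid", "data.frame")
  attr(out, "design") <- design
  out
}

#' Directional trend check for a resampling grid
#'
#' Tests that the median test correlation is non-decreasing along read
#' budgets (within each library size) and along library sizes (within each
#' budget), allowing dips within sampling noise: a decrease is tolerated up
#' to `z` standard errors of the difference of cell medians, with the
#' standard errors estimated from the replicate spread of the two cells.
#'
#' @param results A [score_and_grid()] result.
#' @param metric Column to test.
#' @param z Noise allowance in standard errors; default 2.
#' @return Logical vector, one entry per directional comparison, `TRUE` where
#'   the trend holds within noise.
#' @export
resample_trends <- function(results, metric = "pearson", z = 2) {
  results <- results[!results$empty, , drop = FALSE]
  budgets <- sort(unique(results$read_budget))
  sizes <- sort(unique(results$library_size))
  cell <- function(b, s) results[[metric]][results$read_budget == b &
                                             results$library_size == s]
  ok <- logical(0)
  cmp <- function(lo, hi) {
    # median difference with replicate-spread noise allowance (1.2533 is the
    # large-sample efficiency factor of the median vs the mean)
    se <- sqrt(stats::var(lo) / length(lo) + stats::var(hi) / length(hi)) *
      1.2533
    stats::median(hi) - stats::median(lo) >= -z * se
  }
  for (s in sizes) for (i in seq_len(length(budgets) - 1L))
    ok <- c(ok, cmp(cell(budgets[i], s), cell(budgets[i + 1L], s)))
  for (b in budgets) for (j in seq_len(length(sizes) - 1L))
    ok <- c(ok, cmp(cell(b, sizes[j]), cell(b, sizes[j + 1L])))
  ok
}

#' Median heat-map table of a resampling grid
#'
#' @param results A [score_and_grid()] result.
#' @param metric `"pearson"` or `"spearman"`.
#' @return Matrix of medians over replicates, read budgets in rows
#'   (ascending) and library sizes in columns; empty cells are `NA`.
#' @export
resample_heatmap <- function(results, metric = "pearson") {
  budgets <- sort(unique(results$read_budget))
  sizes <- sort(unique(results$library_size))
  out <- matrix(NA_real_, length(budgets), length(sizes),
                dimnames = list(format(budgets, scientific = TRUE),
                                sizes))
  for (i in seq_along(budgets)) for (j in seq_along(sizes)) {
    v <- results[[metric]][results$read_budget == budgets[i] &
                             results$library_size == sizes[j] & !results$empty]
    if (length(v)) out[i, j] <- stats::median(v, na.rm = TRUE)
  }
  out
}
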