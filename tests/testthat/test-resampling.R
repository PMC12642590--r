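# Read-count resampling experiment.

make_counted <- function(n = 120, seed = 4) {
  w <- tiny_world()
  generate_dms(w, n_variants = n, read_depth = 2e5, seed = seed)
}

test_that("base construction yields disjoint test set and pool, seeded", {
  ds <- make_counted(n = 29)             # + wild type = 30 records
  design <- resample_design(library_sizes = 10, read_budgets = 1e4,
                            test_size = 10, seed = 2)
  base <- make_base(ds, design)
  expect_length(base$test_idx, 10L)
  expect_length(base$pool_idx, 20L)
  expect_length(intersect(base$test_idx, base$pool_idx), 0)
  base2 <- make_base(ds, design)
  expect_identical(base$test_idx, base2$test_idx)

  # a test size beyond the dataset leaves nothing to resample
  huge <- resample_design(10, 1e4, test_size = 1000, seed = 2)
  expect_error(make_base(ds, huge), "nothing left")
  noc <- dms_dataset(tiny_world()$reference, ds$variants$variant[1:5])
  expect_error(make_base(noc, design), "no read counts")
})

test_that("read budgets are split proportionally and drawn exactly", {
  ds <- make_counted()
  design <- resample_design(50, 1000, test_size = 20, seed = 3)
  base <- make_base(ds, design)
  tot_in <- sum(base$pool$variants$count_input)
  tot_sel <- sum(base$pool$variants$count_selected)
  lib <- resample_library(base$pool, 50, 1000, seed = 9)
  drawn_in <- sum(lib$variants$count_input)
  drawn_sel <- sum(lib$variants$count_selected)
  expect_equal(drawn_in + drawn_sel, 1000)
  expect_equal(drawn_in, round(1000 * tot_in / (tot_in + tot_sel)))
  expect_equal(nrow(lib$variants), 50L)
  expect_error(resample_library(base$pool, 1e5, 1000), "exceeds pool")
})

test_that("a 3:1 base read ratio sends 750 of 1000 reads to the input pool", {
  ref <- "MAELKQ"
  ds <- dms_dataset(ref, c("_wt", "E3K", "A2C", "K5R"),
                    count_input = c(300, 150, 100, 50),
                    count_selected = c(100, 50, 30, 20))
  design <- resample_design(2, 1000, test_size = 1, seed = 5)
  base <- make_base(ds, design)
  ratio <- sum(base$pool$variants$count_input) /
    sum(base$pool$variants$count_input + base$pool$variants$count_selected)
  lib <- resample_library(base$pool, 2, 1000, seed = 1)
  expect_equal(sum(lib$variants$count_input), round(1000 * ratio))
})

test_that("multinomial resampling reproduces expected per-variant counts", {
  ref <- "MAELKQ"
  ds <- dms_dataset(ref, c("_wt", "E3K", "A2C", "K5R", "L4P"),
                    count_input = c(400, 200, 200, 100, 100),
                    count_selected = c(400, 200, 200, 100, 100))
  design <- resample_design(4, 2000, test_size = 1, seed = 6)
  base <- make_base(ds, design)
  # keep the whole pool as the library so probabilities are known exactly
  nrep <- 200
  pool_n <- nrow(base$pool$variants)
  draws <- sapply(seq_len(nrep), function(r)
    resample_library(base$pool, pool_n, 2000, seed = r)$variants$count_input)
  p <- base$pool$variants$count_input / sum(base$pool$variants$count_input)
  budget_in <- sum(draws[, 1])
  expected <- budget_in * p
  se <- sqrt(budget_in * p * (1 - p) / nrep)
  expect_true(all(abs(rowMeans(draws) - expected) <= 3 * se + 1e-9))
})

test_that("a single-variant library receives every read", {
  ds <- make_counted()
  design <- resample_design(1, 500, test_size = 20, seed = 3)
  base <- make_base(ds, design)
  lib <- resample_library(base$pool, 1, 500, seed = 2)
  expect_equal(sum(lib$variants$count_input) +
                 sum(lib$variants$count_selected), 500)
  expect_equal(nrow(lib$variants), 1L)
})

test_that("resampled scores converge to base scores at high depth", {
  w <- tiny_world()
  ds <- generate_dms(w, n_variants = 300, read_depth = 1e6, seed = 12)
  design <- resample_design(250, 1e6, test_size = 30, seed = 7)
  base <- make_base(ds, design)
  iwt <- which(n_mutations(ds) == 0L)
  wt_counts <- c(ds$variants$count_input[iwt],
                 ds$variants$count_selected[iwt])
  lib <- resample_library(base$pool, 250, 1e6, seed = 4)
  lib <- score_from_counts(lib, wt_counts = wt_counts)
  base_scores <- base$pool$variants$score[attr(lib, "pool_index")]
  expect_gte(cor(lib$variants$score, base_scores), 0.99)
})

test_that("the grid runs, marks undersized cells empty and degrades with
           read budget", {
  w <- tiny_world()
  ds <- generate_dms(w, n_variants = 250, read_depth = 5e5, seed = 15)
  res <- world_resources(w)
  design <- resample_design(library_sizes = c(150, 1000),
                            read_budgets = c(200, 5e5),
                            test_size = 60, replicates = 2, seed = 1)
  grid <- score_and_grid(ds, design, res)
  expect_equal(nrow(grid), 8L)
  expect_true(all(grid$empty[grid$library_size == 1000]))
  ok <- grid[!grid$empty, ]
  hm <- resample_heatmap(grid)
  expect_equal(dim(hm), c(2L, 2L))
  # large-budget cell beats the starved 200-read cell
  expect_gt(hm["5e+05", "150"], hm["2e+02", "150"])
  # the fixed test set never enters any library
  base <- make_base(ds, design)
  lib <- resample_library(base$pool, 150, 200, seed = 99)
  expect_length(intersect(base$test$variants$variant,
                          lib$variants$variant), 0)
})
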