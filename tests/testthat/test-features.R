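# Energy squashing, term selection, normalization, AAIndex PCA and the
# per-variant feature encoding.

test_that("squash_energy is identity below threshold and saturates above", {
  expect_equal(squash_energy(10), 10)
  expect_equal(squash_energy(50), 50)
  expect_equal(squash_energy(100), 50 + 50 * tanh(1))
  expect_equal(squash_energy(100), 88.079, tolerance = 1e-4)
  expect_equal(squash_energy(-120), -120)   # negative energies untouched
  expect_error(squash_energy(Inf), "finite")
})

test_that("squash_energy is monotone and bounded by twice the threshold", {
  set.seed(5)
  x <- sort(runif(500, -200, 500))
  y <- squash_energy(x)
  expect_true(all(diff(y) >= 0))
  expect_true(all(y < 100))
  # continuity at the threshold
  expect_equal(squash_energy(50 + 1e-9), 50, tolerance = 1e-6)
})

test_that("select_energy_terms ranks components by variance with ddG first", {
  set.seed(42)
  L <- 10L
  terms <- paste0("term_", letters[1:10])
  vals <- array(0, c(L, 20, 11),
                dimnames = list(as.character(1:L), aa_canonical(),
                                c(terms, "ddg_total")))
  sds <- 10:1
  for (t in 1:10) vals[, , t] <- rnorm(L * 20, sd = sds[t])
  vals[, , 11] <- apply(vals[, , 1:10], c(1, 2), sum)
  et <- energy_table(vals)
  sel <- select_energy_terms(et, k = 8)
  expect_equal(sel[1], "ddg_total")
  # brute-force oracle: sample variances of each component, sorted descending
  oracle <- names(sort(vapply(terms, function(tm)
    var(as.vector(vals[, , tm])), 0), decreasing = TRUE))
  expect_equal(sel[-1], oracle[1:7])

  expect_equal(select_energy_terms(et, k = 0), character(0))
  expect_error(select_energy_terms(et, k = 12), "exceeds")

  # zero-variance components are never selected ahead of varying ones
  vals2 <- vals
  vals2[, , "term_a"] <- 3      # constant
  et2 <- energy_table(vals2)
  sel2 <- select_energy_terms(et2, k = 8)
  expect_false("term_a" %in% sel2)
})

test_that("min-max normalization maps the training range onto [0,1] and clips", {
  nm <- fit_minmax(c(2, 4, 6))
  expect_equal(apply_minmax(nm, 4), 0.5)
  expect_equal(apply_minmax(nm, 2), 0)
  expect_equal(apply_minmax(nm, 6), 1)
  expect_equal(apply_minmax(nm, 8), 1)      # clipped above
  expect_equal(apply_minmax(nm, -1), 0)     # clipped below
  expect_error(fit_minmax(rep(3, 5)), "constant")

  set.seed(1)
  v <- rnorm(50)
  out <- apply_minmax(fit_minmax(v), v)
  expect_equal(min(out), 0)
  expect_equal(max(out), 1)
})

test_that("AAIndex PCA yields exactly 19 informative components from 20 rows", {
  set.seed(9)
  m <- matrix(rnorm(20 * 566), 20, dimnames = list(aa_canonical(), NULL))
  pcs <- compute_aaindex_pcs(m, K = 19)
  expect_equal(dim(pcs$scores), c(20L, 19L))
  # 20 centered points span at most 19 dimensions: 19 PCs carry 100% variance
  expect_equal(sum(pcs$variance_explained[1:19]), 1, tolerance = 1e-10)
  # each normalized component spans [0, 1] exactly
  expect_equal(unname(apply(pcs$scores, 2, min)), rep(0, 19))
  expect_equal(unname(apply(pcs$scores, 2, max)), rep(1, 19))

  # identical rows: rank 0 after centering
  flat <- matrix(rep(rnorm(25), each = 20), 20,
                 dimnames = list(aa_canonical(), NULL))
  expect_error(compute_aaindex_pcs(flat), "rank")

  # a known two-factor structure concentrates variance in two components
  u <- matrix(rnorm(20 * 2), 20)
  v <- matrix(rnorm(2 * 25), 2)
  m2 <- u %*% v + matrix(rnorm(20 * 25, sd = 1e-3), 20)
  rownames(m2) <- aa_canonical()
  pcs2 <- compute_aaindex_pcs(m2, K = 19)
  expect_gt(sum(pcs2$variance_explained[1:2]), 0.99)
})

test_that("feature widths are 49 with biophysics and 40 without", {
  world <- tiny_world()
  res <- world_resources(world)
  L <- world$L
  wt <- parse_variant("_wt", world$reference)
  M <- encode_variant(wt, res, with_biophysics = TRUE)
  expect_equal(dim(M), c(L, 49L))
  M0 <- encode_variant(wt, res, with_biophysics = FALSE)
  expect_equal(dim(M0), c(L, 40L))
  # block widths: one-hot 21, AAIndex 19, energy 8, RMSF 1
  expect_equal(sum(grepl("^onehot_", colnames(M))), 21L)
  expect_equal(sum(grepl("^aaindex_", colnames(M))), 19L)
  expect_equal(sum(grepl("^energy_", colnames(M))), 8L)
  expect_equal(sum(colnames(M) == "rmsf"), 1L)
})

test_that("one-hot rows sum to one with a single nonzero entry", {
  world <- tiny_world()
  res <- world_resources(world)
  set.seed(3)
  for (i in 1:10) {
    s <- random_variant_string(world$reference)
    M <- encode_variant(s, res, with_biophysics = TRUE)
    oh <- M[, grepl("^onehot_", colnames(M))]
    expect_equal(unname(rowSums(oh)), rep(1, world$L))
    expect_equal(unname(rowSums(oh != 0)), rep(1, world$L))
    # all feature blocks normalized to [0, 1]
    expect_true(all(M >= 0 & M <= 1))
  }
})

test_that("encoding is local, permutation-invariant and biophysics-off is
           independent of energy resources", {
  world <- tiny_world()
  res <- world_resources(world)
  wtM <- encode_variant("_wt", res, with_biophysics = TRUE)
  m3 <- setdiff(aa_canonical(), world$ref_chars[3])[1]
  m10 <- setdiff(aa_canonical(), world$ref_chars[10])[1]
  a <- sprintf("%s3%s,%s10%s", world$ref_chars[3], m3, world$ref_chars[10], m10)
  v <- encode_variant(a, res, with_biophysics = TRUE)
  differs <- which(rowSums(v != wtM) > 0)
  expect_equal(differs, c(3L, 10L))

  b <- sprintf("%s10%s,%s3%s", world$ref_chars[10], m10, world$ref_chars[3], m3)
  expect_equal(encode_variant(a, res, TRUE), encode_variant(b, res, TRUE))

  res_plain <- feature_resources(world$reference, world$aaindex)
  expect_equal(encode_variant(a, res, FALSE),
               encode_variant(a, res_plain, FALSE))
  expect_error(encode_variant(a, res_plain, TRUE), "requires")
})

test_that("stop-symbol rows use the maximally destabilizing energy fallback", {
  world <- tiny_world()
  res <- world_resources(world)
  s <- sprintf("%s5*", world$ref_chars[5])
  M <- encode_variant(s, res, with_biophysics = TRUE)
  en <- M[5, grepl("^energy_", colnames(M))]
  expect_equal(unname(en), rep(1, 8))   # squash ceiling normalizes to 1
  expect_equal(unname(M[5, "onehot_*"]), 1)
})

test_that("energy tables round-trip through TSV with protocol metadata", {
  world <- tiny_world()
  path <- tempfile(fileext = ".tsv")
  write_energy_table(world$energy, path, reference = world$reference)
  back <- read_energy_table(path)
  expect_equal(back$values, world$energy$values, tolerance = 1e-12)
  expect_equal(back$protocol$repack_radius, 12)
  expect_equal(back$protocol$nloop, 1)
})

test_that("encode_dataset flattens position-major and matches encode_variant", {
  world <- tiny_world()
  res <- world_resources(world)
  ds <- tiny_dataset(world, n = 20)
  x <- encode_dataset(ds, res, TRUE)
  expect_equal(dim(x), c(21L, world$L * 49L))
  i <- 7L
  M <- encode_variant(ds$variants$variant[i], res, TRUE)
  expect_equal(unname(x[i, ]), as.vector(t(M)))
})
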