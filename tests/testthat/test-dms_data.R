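# Variant parsing, enrichment scoring and dataset IO.

test_that("parse_variant handles well-formed, wild-type and offset inputs", {
  ref <- "MAELKQ"
  v <- parse_variant("E3K", ref)
  expect_equal(v$position, 3L)
  expect_equal(v$wt, "E")
  expect_equal(v$mut, "K")

  wt <- parse_variant("", ref)
  expect_equal(nrow(wt), 0L)
  expect_equal(nrow(parse_variant("_wt", ref)), 0L)

  # multi-mutant, order-normalized
  v2 <- parse_variant("K5R,A2C", ref)
  expect_equal(v2$position, c(2L, 5L))

  # published numbering offset by +10
  v3 <- parse_variant("E13K", ref, offset = 10L)
  expect_equal(v3$position, 3L)

  # stop symbol allowed as mutant
  v4 <- parse_variant("Q6*", ref)
  expect_equal(v4$mut, "*")
})

test_that("parse_variant rejects invalid tokens with informative errors", {
  ref <- "MAELKQ"
  expect_error(parse_variant("A3K", ref), "mismatch.*position.*3")
  expect_error(parse_variant("E3K,E3R", ref), "duplicate")
  expect_error(parse_variant("E3E", ref), "equals wild type")
  expect_error(parse_variant("E9K", ref), "out of range")
  expect_error(parse_variant("E3B", ref), "unknown mutant")
  expect_error(parse_variant("*3K", ref), "unknown wild-type")
  expect_error(parse_variant("E3", ref), "malformed")
  expect_error(parse_variant("E3-", ref), "deletion")
})

test_that("parse and format are mutually inverse on random variants", {
  set.seed(101)
  world <- tiny_world()
  for (i in 1:50) {
    s <- random_variant_string(world$reference)
    v <- parse_variant(s, world$reference)
    expect_identical(format_variant(v), s)
    expect_identical(parse_variant(format_variant(v), world$reference), v)
  }
  expect_identical(format_variant(parse_variant("_wt", world$reference)), "_wt")
})

test_that("enrichment score matches hand computation and handles edge cases", {
  # log2(31.5 / 3.5) with equal wild-type ratios
  expect_equal(enrichment_score(3, 31, 7, 7), log2(31.5 / 3.5))
  expect_equal(round(enrichment_score(3, 31, 7, 7), 4), 3.1699)
  expect_equal(enrichment_score(7, 7, 7, 7), 0)
  # zero counts fall back to the pseudocount ratio of 1 on both sides
  expect_equal(enrichment_score(0, 0, 10, 10), 0)
  expect_error(enrichment_score(-1, 3, 7, 7), "non-negative")
})

test_that("enrichment score is antisymmetric and strictly monotone", {
  set.seed(7)
  for (i in 1:25) {
    cv <- sample(0:50, 2)
    cw <- sample(0:50, 2)
    expect_equal(enrichment_score(cv[1], cv[2], cw[1], cw[2]),
                 -enrichment_score(cw[1], cw[2], cv[1], cv[2]))
  }
  s <- enrichment_score(10, 0:40, 7, 7)
  expect_true(all(diff(s) > 0))          # increasing in selected reads
  s2 <- enrichment_score(0:40, 10, 7, 7)
  expect_true(all(diff(s2) < 0))         # decreasing in input reads
})

test_that("DMS tables round-trip through TSV and drop indels with a count", {
  ref <- "MAELKQ"
  ds <- dms_dataset(ref, c("_wt", "E3K", "A2C,K5R"),
                    score = c(0, -1.25, 0.5),
                    count_input = c(100, 40, 25),
                    count_selected = c(100, 10, 30))
  path <- tempfile(fileext = ".tsv")
  write_dms_table(ds, path)
  back <- read_dms_table(path, ref)
  expect_equal(back$variants$variant, ds$variants$variant)
  expect_equal(back$variants$score, ds$variants$score)
  expect_equal(back$variants$count_input, ds$variants$count_input)

  # a deletion row is excluded with a counted warning
  lines <- readLines(path)
  writeLines(c(lines, "E3del\t0.1\t5\t5"), path)
  expect_warning(bad <- read_dms_table(path, ref), "1 deletion/indel")
  expect_equal(nrow(bad$variants), 3L)

  # malformed rows are reported with their line number
  writeLines(c(lines, "EK3\t0.1\t5\t5"), path)
  expect_error(read_dms_table(path, ref), "line 5")
})

test_that("scores are computed from counts when the score column is absent", {
  ref <- "MAELKQ"
  path <- tempfile(fileext = ".tsv")
  writeLines(c("variant\tcount_input\tcount_selected",
               "_wt\t7\t7", "E3K\t3\t31", "A2C\t10\t0"), path)
  ds <- read_dms_table(path, ref)
  expect_equal(ds$variants$score,
               enrichment_score(c(7, 3, 10), c(7, 31, 0), 7, 7))
})

test_that("dataset summary computes missense coverage by definition", {
  ref <- paste(rep("ACDEFGHKLMNPQRSTVWYI", 3), collapse = "")  # L = 60
  L <- nchar(ref)
  ds1 <- dms_dataset(substr(ref, 1, 56), "C2K")
  s1 <- dataset_summary(ds1)
  expect_equal(s1$coverage, 1 / (56 * 19))
  expect_equal(s1$n_unique_mutations, 1L)

  # empty dataset
  s0 <- dataset_summary(dms_dataset(ref, character(0)))
  expect_equal(s0$coverage, 0)
  expect_equal(s0$n_variants, 0L)

  # full saturation: all 19 substitutions at every site
  refc <- strsplit(ref, "")[[1]]
  all_singles <- unlist(lapply(seq_len(L), function(p)
    paste0(refc[p], p, setdiff(aa_canonical(), refc[p]))))
  sfull <- dataset_summary(dms_dataset(ref, all_singles))
  expect_equal(sfull$coverage, 1)

  # stop variants count as unique mutations but not missense coverage
  sstop <- dataset_summary(dms_dataset(ref, c("C2K", "C2*")))
  expect_equal(sstop$n_unique_mutations, 2L)
  expect_equal(sstop$coverage, 1 / (L * 19))
})
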