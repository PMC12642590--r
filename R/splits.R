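# Reproducible train/validation/test splits: random, mutational-extrapolation
# and positional-extrapolation schemes.

new_data_split <- function(train, validation, test, scheme, seed, fractions,
                           dropped = data.frame(index = integer(0),
                                                reason = character(0))) {
  structure(list(train = sort(train), validation = sort(validation),
                 test = sort(test), scheme = scheme, seed = seed,
                 fractions = fractions, dropped = dropped),
            class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("%s split (seed %s): train %d / validation %d / test %d",
              x$scheme, format(x$seed), length(x$train),
              length(x$validation), length(x$test)))
  if (nrow(x$dropped)) cat(sprintf(" (%d dropped)", nrow(x$dropped)))
  cat("\n")
  invisible(x)
}

check_fractions <- function(fractions) {
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three positive numbers summing to 1")
}

# Partition n items into train/validation/test index sets: the validation and
# test sets get floor(f * n) items, the remainder goes to training.
partition_indices <- function(n, fractions) {
  n_val <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  perm <- sample.int(n)
  list(train = perm[seq_len(n - n_val - n_test)],
       validation = perm[n - n_val - n_test + seq_len(n_val)],
       test = perm[n - n_test + seq_len(n_test)])
}

#' Random 70/15/15 split of a DMS dataset
#'
#' Variants are permuted deterministically from `seed` and assigned so the
#' validation and test sets hold `floor(f * N)` variants each, with the
#' remainder in training.
#'
#' @param dataset A [dms_dataset()].
#' @param fractions Train/validation/test fractions; default
#'   `c(0.70, 0.15, 0.15)`.
#' @param seed Integer seed; the split is a pure function of
#'   `(dataset, fractions, seed)`.
#' @return A `data_split` with disjoint, exhaustive index sets.
#' @export
random_split <- function(dataset, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  check_fractions(fractions)
  n <- nrow(dataset$variants)
  if (n < 3L) stop("dataset has fewer than 3 variants")
  parts <- with_seed(seed, partition_indices(n, fractions))
  new_data_split(parts$train, parts$validation, parts$test,
                 "random", seed, fractions)
}

# Shared machinery for the two extrapolation schemes: partition the given
# per-variant key sets (unique mutations or positions) and keep a variant only
# if all its keys land in one partition.
extrapolation_split <- function(dataset, keys_per_variant, fractions, seed,
                                scheme) {
  check_fractions(fractions)
  all_keys <- unique(unlist(keys_per_variant))
  if (length(all_keys) < 3L)
    stop("dataset must cover at least 3 unique ",
         if (scheme == "mutational") "mutations" else "positions")
  parts <- with_seed(seed, partition_indices(length(all_keys), fractions))
  assignment <- integer(length(all_keys))  # 1 train, 2 val, 3 test
  assignment[parts$train] <- 1L
  assignment[parts$validation] <- 2L
  assignment[parts$test] <- 3L
  names(assignment) <- all_keys
  sets <- list(integer(0), integer(0), integer(0))
  dropped_idx <- integer(0); dropped_why <- character(0)
  for (i in seq_along(keys_per_variant)) {
    k <- keys_per_variant[[i]]
    if (length(k) == 0L) {      # wild-type record: no keys constrain it
      sets[[1L]] <- c(sets[[1L]], i)
      next
    }
    a <- unique(assignment[k])
    if (length(a) == 1L) {
      sets[[a]] <- c(sets[[a]], i)
    } else {
      dropped_idx <- c(dropped_idx, i)
      dropped_why <- c(dropped_why, paste0(scheme, " keys span partitions"))
    }
  }
  new_data_split(sets[[1]], sets[[2]], sets[[3]], scheme, seed, fractions,
                 dropped = data.frame(index = dropped_idx, reason = dropped_why,
                                      stringsAsFactors = FALSE))
}

#' Mutational-extrapolation split
#'
#' The unique point mutations (position, mutant amino acid pairs) of the
#' dataset are partitioned 70/15/15; a variant is assigned to a partition only
#' if every one of its mutations belongs to that partition. Variants whose
#' mutations span partitions are dropped (and recorded), so no mutation type
#' is shared between training and test.
#'
#' @inheritParams random_split
#' @return A `data_split`; `$dropped` lists the discarded variants.
#' @export
mutational_split <- function(dataset, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  keys <- lapply(dataset$mutations, function(m)
    if (nrow(m)) paste0(m$position, ">", m$mut) else character(0))
  extrapolation_split(dataset, keys, fractions, seed, "mutational")
}

#' Positional-extrapolation split
#'
#' Like [mutational_split()] but partitioning mutated residue positions, so
#' the test set contains only mutations at positions entirely unseen during
#' training — the hardest generalization task for sequence-only models.
#'
#' @inheritParams random_split
#' @return A `data_split`.
#' @export
positional_split <- function(dataset, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  keys <- lapply(dataset$mutations, function(m)
    if (nrow(m)) as.character(m$position) else character(0))
  extrapolation_split(dataset, keys, fractions, seed, "positional")
}

#' Dispatch on a split-scheme name
#'
#' @param dataset A [dms_dataset()].
#' @param scheme One of `"random"`, `"mutational"`, `"positional"`.
#' @param fractions,seed Passed through.
#' @return A `data_split`.
#' @export
make_split <- function(dataset, scheme = c("random", "mutational", "positional"),
                       fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  scheme <- match.arg(scheme)
  switch(scheme,
         random = random_split(dataset, fractions, seed),
         mutational = mutational_split(dataset, fractions, seed),
         positional = positional_split(dataset, fractions, seed))
}

#' Persist / load a split as JSON
#'
#' @param split A `data_split`.
#' @param path JSON file.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(
    list(scheme = split$scheme, seed = split$seed, fractions = split$fractions,
         train = split$train, validation = split$validation, test = split$test,
         dropped = split$dropped),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  dropped <- if (length(x$dropped)) as.data.frame(x$dropped)
             else data.frame(index = integer(0), reason = character(0))
  new_data_split(as.integer(x$train), as.integer(x$validation),
                 as.integer(x$test), x$scheme, x$seed,
                 as.numeric(x$fractions), dropped)
}
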