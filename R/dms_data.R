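# DMS variant datasets: parsing, validation, enrichment scoring, TSV IO.

#' Parse a variant string against a reference sequence
#'
#' A variant is a comma-separated list of point-mutation tokens of the form
#' `<wt><position><mut>`, e.g. `"E3K,L10P"`. Positions are 1-based into
#' `reference` (after subtracting `offset`, for datasets numbered against a
#' different coordinate system). The empty string or the sentinel `"_wt"`
#' denotes the wild type. The mutant symbol may be any of the 21-letter
#' alphabet (20 canonical amino acids plus the stop symbol `*`); the wild-type
#' symbol must be canonical and must match `reference` at that position.
#'
#' @param text Variant string.
#' @param reference Reference amino-acid sequence (single string).
#' @param offset Integer subtracted from published positions to obtain 1-based
#'   indices into `reference`. Default 0.
#' @return An object of class `vep_variant`: a data frame with columns
#'   `position`, `wt`, `mut`, ordered by position. Zero rows for wild type.
#' @examples
#' parse_variant("E3K", "MAEL")
#' parse_variant("", "MAEL")        # wild type
#' @export
parse_variant <- function(text, reference, offset = 0L) {
  stopifnot(is.character(reference), length(reference) == 1L)
  ref <- strsplit(reference, "")[[1]]
  L <- length(ref)
  text <- trimws(text)
  if (is.na(text) || text == "" || text == "_wt")
    return(new_variant(integer(0), character(0), character(0)))
  tokens <- strsplit(text, ",", fixed = TRUE)[[1]]
  tokens <- trimws(tokens)
  m <- regmatches(tokens, regexec("^([A-Za-z*])([0-9]+)([A-Za-z*-])$", tokens))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad))
    stop("malformed mutation token(s): ", paste(tokens[bad], collapse = ", "))
  wt  <- toupper(vapply(m, `[`, "", 2L))
  pos <- as.integer(vapply(m, `[`, "", 3L)) - as.integer(offset)
  mut <- toupper(vapply(m, `[`, "", 4L))
  if (any(mut == "-"))
    stop("deletion token(s) not allowed: ", paste(tokens[mut == "-"], collapse = ", "))
  if (any(!wt %in% .AA20))
    stop("unknown wild-type symbol(s): ", paste(unique(wt[!wt %in% .AA20]), collapse = ", "))
  if (any(!mut %in% .AA21))
    stop("unknown mutant symbol(s): ", paste(unique(mut[!mut %in% .AA21]), collapse = ", "))
  if (any(pos < 1L | pos > L))
    stop("position(s) out of range 1..", L, ": ",
         paste(pos[pos < 1L | pos > L] + offset, collapse = ", "))
  mismatch <- ref[pos] != wt
  if (any(mismatch))
    stop("wild-type mismatch at position(s) ",
         paste(sprintf("%d (reference has %s, token says %s)",
                       pos[mismatch] + as.integer(offset), ref[pos[mismatch]], wt[mismatch]),
               collapse = "; "))
  if (anyDuplicated(pos))
    stop("duplicate mutated position(s): ", paste(unique(pos[duplicated(pos)]), collapse = ", "))
  if (any(mut == wt))
    stop("mutant equals wild type at position(s) ", paste(pos[mut == wt], collapse = ", "))
  o <- order(pos)
  new_variant(pos[o], wt[o], mut[o])
}

new_variant <- function(position, wt, mut) {
  structure(data.frame(position = as.integer(position), wt = wt, mut = mut,
                       stringsAsFactors = FALSE),
            class = c("vep_variant", "data.frame"))
}

#' Format a parsed variant back to its string form
#'
#' Inverse of [parse_variant()]: mutations are written `<wt><position><mut>`
#' joined by commas, with `"_wt"` for the wild type.
#'
#' @param variant A `vep_variant` (or a data frame with columns
#'   `position`, `wt`, `mut`).
#' @param offset Added back to positions (see [parse_variant()]).
#' @return A single character string.
#' @export
format_variant <- function(variant, offset = 0L) {
  if (nrow(variant) == 0L) return("_wt")
  paste0(variant$wt, variant$position + as.integer(offset), variant$mut,
         collapse = ",")
}

#' Construct a DMS dataset
#'
#' Bundles a reference sequence with a table of variants, functional scores
#' and optional sequencing read counts. Every variant string is parsed and
#' validated against the reference at construction time.
#'
#' @param reference Reference amino-acid sequence.
#' @param variants Character vector of variant strings (see [parse_variant()]).
#' @param score Numeric functional scores, or `NULL`.
#' @param count_input,count_selected Non-negative integer read counts for the
#'   input and post-selection pools, or `NULL`.
#' @param name Dataset label.
#' @param offset Position offset passed to [parse_variant()].
#' @return An object of class `dms_dataset` with elements `reference`, `name`,
#'   `variants` (data frame: `variant`, `score`, `count_input`,
#'   `count_selected`) and `mutations` (list of parsed `vep_variant`s).
#' @export
dms_dataset <- function(reference, variants, score = NULL,
                        count_input = NULL, count_selected = NULL,
                        name = "dms", offset = 0L) {
  stopifnot(is.character(reference), length(reference) == 1L, nchar(reference) >= 1L)
  n <- length(variants)
  chk_counts <- function(x, what) {
    if (is.null(x)) return(rep(NA_real_, n))
    x <- as.numeric(x)
    if (length(x) != n) stop(what, " must have one value per variant")
    if (any(!is.na(x) & (x < 0 | x != floor(x))))
      stop(what, " must be non-negative integers")
    x
  }
  score <- if (is.null(score)) rep(NA_real_, n) else as.numeric(score)
  if (length(score) != n) stop("score must have one value per variant")
  tab <- data.frame(variant = as.character(variants), score = score,
                    count_input = chk_counts(count_input, "count_input"),
                    count_selected = chk_counts(count_selected, "count_selected"),
                    stringsAsFactors = FALSE)
  muts <- lapply(tab$variant, parse_variant, reference = reference, offset = offset)
  # canonical string form so that parse/format round-trips exactly
  tab$variant <- vapply(muts, format_variant, "", offset = offset)
  structure(list(reference = toupper(reference), name = name,
                 variants = tab, mutations = muts, offset = as.integer(offset)),
            class = "dms_dataset")
}

#' @export
print.dms_dataset <- function(x, ...) {
  cat(sprintf("DMS dataset '%s': %d variants, reference length %d\n",
              x$name, nrow(x$variants), nchar(x$reference)))
  nm <- n_mutations(x)
  cat("  mutations per variant: ",
      paste(sprintf("%d:%d", as.integer(names(table(nm))), as.integer(table(nm))),
            collapse = "  "), "\n", sep = "")
  if (any(!is.na(x$variants$score)))
    cat(sprintf("  score range: [%.3g, %.3g]\n",
                min(x$variants$score, na.rm = TRUE), max(x$variants$score, na.rm = TRUE)))
  invisible(x)
}

#' Number of mutations per variant
#' @param dataset A `dms_dataset`.
#' @return Integer vector, one entry per variant.
#' @export
n_mutations <- function(dataset) {
  vapply(dataset$mutations, nrow, 1L)
}

#' Enrichment score from input / selected read counts
#'
#' Two-condition log-ratio score with pseudocounts, centered on the wild type:
#' \deqn{s = \log_2\frac{c_{sel}+p}{c_{inp}+p} -
#'           \log_2\frac{wt_{sel}+p}{wt_{inp}+p}}
#' This is the standard two-timepoint ratio form used for selection assays;
#' it is deterministic and vectorized over variants.
#'
#' @param count_input,count_selected Variant read counts (vectors allowed).
#' @param wt_input,wt_selected Wild-type read counts (scalars).
#' @param pseudocount Added to every count; default 0.5.
#' @return Numeric vector of scores.
#' @examples
#' enrichment_score(3, 31, 7, 7)  # log2(31.5/3.5) = 3.1699
#' @export
enrichment_score <- function(count_input, count_selected,
                             wt_input, wt_selected, pseudocount = 0.5) {
  counts <- c(count_input, count_selected, wt_input, wt_selected)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("read counts must be finite and non-negative")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  log2((count_selected + pseudocount) / (count_input + pseudocount)) -
    log2((wt_selected + pseudocount) / (wt_input + pseudocount))
}

# Identify indel records (deletion '-'/'del'/'ins' tokens) that the reader drops.
is_indel_string <- function(text) {
  grepl("(^|,)\\s*[A-Za-z*][0-9]+-\\s*(,|$)", text) |
    grepl("del|ins", text, ignore.case = TRUE)
}

#' Read a DMS variant table
#'
#' Reads a tab-separated table with a header containing at least a `variant`
#' column, plus optional `score`, `count_input` and `count_selected` columns.
#' Rows describing deletions or indels are excluded with a warning reporting
#' how many were dropped (the modelling pipeline handles missense
#' substitutions only). If the table has read counts but no scores, scores are
#' computed with [enrichment_score()] against the wild-type record (`"_wt"`),
#' which must then be present.
#'
#' @param path TSV file.
#' @param reference Reference sequence string, or path to a FASTA file.
#' @param name Dataset label (defaults to the file name).
#' @param offset Position offset (see [parse_variant()]).
#' @return A [dms_dataset()].
#' @export
read_dms_table <- function(path, reference, name = NULL, offset = 0L) {
  if (file.exists(reference) && grepl("\\.(fa|fasta|faa)$", reference, ignore.case = TRUE))
    reference <- read_fasta_sequence(reference)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  if (!"variant" %in% names(tab))
    stop("'", path, "' lacks the required 'variant' column")
  tab$variant[is.na(tab$variant)] <- ""
  drop <- is_indel_string(tab$variant)
  if (any(drop)) {
    warning(sum(drop), " deletion/indel record(s) removed from '", path, "'")
    tab <- tab[!drop, , drop = FALSE]
  }
  parsed <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    parsed[[i]] <- tryCatch(
      parse_variant(tab$variant[i], reference, offset = offset),
      error = function(e) stop("line ", i + 1L, " of '", path, "': ",
                               conditionMessage(e), call. = FALSE))
  }
  score <- if ("score" %in% names(tab)) as.numeric(tab$score) else NULL
  ci <- if ("count_input" %in% names(tab)) tab$count_input else NULL
  cs <- if ("count_selected" %in% names(tab)) tab$count_selected else NULL
  ds <- dms_dataset(reference, tab$variant, score = score,
                    count_input = ci, count_selected = cs,
                    name = if (is.null(name)) basename(path) else name,
                    offset = offset)
  if (all(is.na(ds$variants$score)) && !is.null(ci) && !is.null(cs))
    ds <- score_from_counts(ds)
  ds
}

#' Compute enrichment scores for every variant of a counted dataset
#'
#' Replaces (or fills) the `score` column from the read counts using
#' [enrichment_score()], centered on the dataset's wild-type record.
#'
#' @param dataset A `dms_dataset` with read counts.
#' @param pseudocount Passed to [enrichment_score()].
#' @param wt_counts Optional length-2 numeric `(input, selected)` overriding
#'   the wild-type record's counts (used when scoring resampled libraries
#'   against a base wild type).
#' @return The dataset with its `score` column populated.
#' @export
score_from_counts <- function(dataset, pseudocount = 0.5, wt_counts = NULL) {
  v <- dataset$variants
  if (all(is.na(v$count_input)) || all(is.na(v$count_selected)))
    stop("dataset has no read counts to score")
  if (is.null(wt_counts)) {
    iwt <- which(n_mutations(dataset) == 0L)
    if (length(iwt) == 0L)
      stop("no wild-type record to center enrichment scores on; supply wt_counts")
    wt_counts <- c(v$count_input[iwt[1]], v$count_selected[iwt[1]])
  }
  dataset$variants$score <- enrichment_score(v$count_input, v$count_selected,
                                             wt_counts[1], wt_counts[2],
                                             pseudocount = pseudocount)
  dataset
}

#' Write a DMS dataset as a tab-separated table
#'
#' @param dataset A `dms_dataset`.
#' @param path Output TSV file.
#' @return `path`, invisibly. Round-trips losslessly through
#'   [read_dms_table()] up to float formatting.
#' @export
write_dms_table <- function(dataset, path) {
  tab <- dataset$variants
  keep <- c(TRUE, any(!is.na(tab$score)),
            any(!is.na(tab$count_input)), any(!is.na(tab$count_selected)))
  utils::write.table(tab[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarize a DMS dataset
#'
#' Reports dataset size, the number of distinct point mutations observed, the
#' fraction of the possible missense space covered (out of `L x 19` canonical
#' substitutions), and the mutations-per-variant histogram.
#'
#' @param dataset A `dms_dataset`.
#' @return A list of class `dms_summary` with elements `n_variants`,
#'   `n_unique_mutations`, `coverage`, `mutations_per_variant` (named table)
#'   and `n_positions_covered`.
#' @export
dataset_summary <- function(dataset) {
  L <- nchar(dataset$reference)
  muts <- do.call(rbind, dataset$mutations)
  if (is.null(muts) || nrow(muts) == 0L) {
    keys <- character(0); canon <- character(0); posc <- integer(0)
  } else {
    keys <- unique(paste0(muts$position, ">", muts$mut))
    canon <- unique(paste0(muts$position, ">", muts$mut)[muts$mut %in% .AA20])
    posc <- unique(muts$position)
  }
  histo <- table(n_mutations(dataset), dnn = NULL)
  structure(list(
    name = dataset$name,
    n_variants = nrow(dataset$variants),
    n_unique_mutations = length(keys),
    coverage = length(canon) / (L * 19),
    n_positions_covered = length(posc),
    mutations_per_variant = histo), class = "dms_summary")
}

#' @export
print.dms_summary <- function(x, ...) {
  cat(sprintf("'%s': %d variants, %d unique mutations, coverage %.1f%% of L x 19, %d positions touched\n",
              x$name, x$n_variants, x$n_unique_mutations, 100 * x$coverage,
              x$n_positions_covered))
  cat("  mutations per variant:\n")
  print(x$mutations_per_variant)
  invisible(x)
}
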