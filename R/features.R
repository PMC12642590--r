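# Biophysics feature resources (energy table, AAIndex PCs, RMSF) and the
# per-variant N_res x D feature encoding.

#' Construct a per-site mutational energy table
#'
#' Holds, for every (position, substitution) pair over the 20 canonical amino
#' acids — including the wild-type self-substitution — a vector of energy-term
#' values in Rosetta energy units (REU): the total ddG (folding free-energy
#' change, wild type minus mutant) plus its per-term components.
#'
#' @param values Numeric array `L x 20 x n_terms` with `dimnames` position
#'   (1..L as character), amino acid (canonical one-letter codes) and term
#'   label. One term must be `"ddg_total"`.
#' @param protocol List of protocol metadata, typically
#'   `list(repack_radius = 12, nloop = 1)` (side-chain repacking radius in
#'   Angstrom and repacking iterations used by the external ddG adapter).
#' @return An object of class `energy_table`.
#' @export
energy_table <- function(values, protocol = list(repack_radius = 12, nloop = 1)) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  d <- dimnames(values)
  if (is.null(d) || length(d) != 3L)
    stop("values needs dimnames: position, amino acid, term")
  if (!setequal(d[[2]], .AA20))
    stop("second dimension must cover the 20 canonical amino acids")
  if (!"ddg_total" %in% d[[3]])
    stop("terms must include 'ddg_total'")
  values <- values[, .AA20, , drop = FALSE]
  if (any(!is.finite(values))) stop("energy values must be finite")
  structure(list(L = dim(values)[1], terms = d[[3]],
                 values = values, protocol = protocol),
            class = "energy_table")
}

#' @export
print.energy_table <- function(x, ...) {
  cat(sprintf("Energy table: %d positions x 20 substitutions x %d terms (REU)\n",
              x$L, length(x$terms)))
  cat("  protocol:", paste(names(x$protocol), unlist(x$protocol),
                           sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Read / write an energy table as TSV
#'
#' The file has columns `position`, `wt_aa`, `mut_aa`, `ddg_total` and one
#' column per component term; protocol metadata lives in a leading comment
#' line of the form `# repack_radius=12 nloop=1`.
#'
#' @param path TSV file.
#' @return For `read_energy_table`, an [energy_table()].
#' @export
read_energy_table <- function(path) {
  first <- readLines(path, n = 1L)
  protocol <- list()
  if (startsWith(first, "#")) {
    kv <- strsplit(trimws(sub("^#", "", first)), "[[:space:]]+")[[1]]
    kv <- strsplit(kv, "=", fixed = TRUE)
    protocol <- stats::setNames(lapply(kv, function(p) as.numeric(p[2])),
                                vapply(kv, `[`, "", 1L))
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("position", "wt_aa", "mut_aa", "ddg_total")
  if (!all(need %in% names(tab)))
    stop("energy table must have columns ", paste(need, collapse = ", "))
  terms <- setdiff(names(tab), c("position", "wt_aa", "mut_aa"))
  L <- max(tab$position)
  vals <- array(NA_real_, dim = c(L, 20L, length(terms)),
                dimnames = list(as.character(seq_len(L)), .AA20, terms))
  for (tm in terms)
    vals[cbind(tab$position, match(tab$mut_aa, .AA20), match(tm, terms))] <- tab[[tm]]
  if (any(is.na(vals)))
    stop("energy table incomplete: every (position, amino acid) pair must be present")
  energy_table(vals, protocol = protocol)
}

#' @rdname read_energy_table
#' @param table An [energy_table()].
#' @param reference Optional reference sequence used to fill the `wt_aa`
#'   column; `"X"` is written when unknown.
#' @export
write_energy_table <- function(table, path, reference = NULL) {
  L <- table$L
  grid <- expand.grid(mut_aa = .AA20, position = seq_len(L),
                      stringsAsFactors = FALSE)[, c("position", "mut_aa")]
  wt <- if (is.null(reference)) rep("X", nrow(grid))
        else strsplit(toupper(reference), "")[[1]][grid$position]
  out <- data.frame(position = grid$position, wt_aa = wt, mut_aa = grid$mut_aa)
  for (tm in table$terms)
    out[[tm]] <- table$values[cbind(grid$position, match(grid$mut_aa, .AA20),
                                    match(tm, table$terms))]
  con <- file(path, "w")
  on.exit(close(con))
  if (length(table$protocol))
    writeLines(paste0("# ", paste(names(table$protocol), unlist(table$protocol),
                                  sep = "=", collapse = " ")), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Squash large energy values
#'
#' Exceedingly large positive energies (typically steric clashes) are not
#' quantitatively meaningful; values above `threshold` REU are squashed with a
#' saturating tanh while values at or below it pass through unchanged:
#' identity for `x <= t`, and `t + t*tanh((x - t)/t)` above. The map is
#' continuous with unit slope at the threshold and bounded above by `2*t`.
#'
#' @param value Numeric vector (REU).
#' @param threshold Squash threshold in REU; default 50.
#' @return Squashed values, same length.
#' @examples
#' squash_energy(c(10, 50, 100))  # 10, 50, 50 + 50*tanh(1)
#' @export
squash_energy <- function(value, threshold = 50) {
  if (any(!is.finite(value))) stop("energy values must be finite")
  stopifnot(threshold > 0)
  ifelse(value <= threshold, value,
         threshold + threshold * tanh((value - threshold) / threshold))
}

#' Select high-variance energy terms
#'
#' The energy block of the feature encoding keeps the total ddG plus the
#' component terms of largest variance across all (position, substitution)
#' entries; low-variance components carry little signal and are discarded.
#' Ties are broken by term-label lexicographic order.
#'
#' @param table An [energy_table()].
#' @param k Total number of energy features to keep, including `ddg_total`;
#'   default 8 (i.e. the 7 highest-variance components plus the total).
#' @return Character vector of `k` term labels, `"ddg_total"` first.
#' @export
select_energy_terms <- function(table, k = 8) {
  stopifnot(inherits(table, "energy_table"), k >= 0, k == floor(k))
  if (k == 0) return(character(0))
  comps <- setdiff(table$terms, "ddg_total")
  if (k - 1 > length(comps))
    stop("k = ", k, " exceeds available terms (", length(comps),
         " components + ddg_total)")
  vars <- vapply(comps, function(tm) stats::var(as.vector(table$values[, , tm])), 0)
  ord <- order(-vars, comps)  # variance descending, label ascending on ties
  c("ddg_total", comps[ord][seq_len(k - 1)])
}

#' Fit and apply min-max normalization
#'
#' `fit_minmax` records the training minimum and maximum of each feature;
#' `apply_minmax` rescales to `[0, 1]`, clipping values outside the training
#' range (so unseen test values never leave the unit interval).
#'
#' @param values Numeric vector (one feature) or matrix (features in columns).
#' @return For `fit_minmax`, an object of class `minmax` with fields `min` and
#'   `max` per feature.
#' @examples
#' nm <- fit_minmax(c(2, 4, 6))
#' apply_minmax(nm, c(4, 8))  # 0.5, 1 (clipped)
#' @export
fit_minmax <- function(values) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  lo <- apply(values, 2L, min)
  hi <- apply(values, 2L, max)
  if (any(!is.finite(lo)) || any(!is.finite(hi)))
    stop("values must be finite")
  if (any(hi <= lo))
    stop("constant feature(s) at column(s) ",
         paste(which(hi <= lo), collapse = ", "),
         ": exclude constant features before normalization")
  structure(list(min = lo, max = hi), class = "minmax")
}

#' @rdname fit_minmax
#' @param normalizer A fitted `minmax` object.
#' @export
apply_minmax <- function(normalizer, values) {
  stopifnot(inherits(normalizer, "minmax"))
  if (is.null(dim(values))) {
    out <- (values - normalizer$min[1]) / (normalizer$max[1] - normalizer$min[1])
  } else {
    out <- sweep(values, 2L, normalizer$min, "-")
    out <- sweep(out, 2L, normalizer$max - normalizer$min, "/")
  }
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Principal components of an amino-acid property matrix
#'
#' Column-centers a `20 x P` AAIndex-style property matrix (one row per
#' canonical amino acid) and extracts principal-component scores. Twenty
#' centered points span at most 19 dimensions, so 19 components carry 100% of
#' the variance; the first `K` score columns are returned, each min-max
#' normalized to `[0, 1]`.
#'
#' @param property_matrix Numeric `20 x P` matrix, rownames the canonical
#'   amino acids (assumed in [aa_canonical()] order when absent).
#' @param K Number of components to keep; default 19.
#' @return Object of class `aaindex_pcs`: list with `scores` (`20 x K`,
#'   rownames amino acids), `variance_explained` (per component, full
#'   spectrum) and `K`.
#' @export
compute_aaindex_pcs <- function(property_matrix, K = 19) {
  stopifnot(is.matrix(property_matrix), nrow(property_matrix) == 20L)
  if (any(!is.finite(property_matrix))) stop("property matrix has missing entries")
  if (ncol(property_matrix) < K)
    stop("need at least K = ", K, " properties, got ", ncol(property_matrix))
  rn <- rownames(property_matrix) %||% .AA20
  if (!setequal(rn, .AA20)) stop("rownames must be the 20 canonical amino acids")
  centered <- scale(property_matrix, center = TRUE, scale = FALSE)
  rank <- qr(centered)$rank
  if (rank < K)
    stop("property matrix rank is ", rank, " after centering; cannot extract ",
         K, " components")
  pc <- stats::prcomp(property_matrix, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(K), drop = FALSE]
  scores <- apply_minmax(fit_minmax(scores), scores)
  rownames(scores) <- rn
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores[.AA20, , drop = FALSE],
                 variance_explained = ve, K = K),
            class = "aaindex_pcs")
}

#' Read tabular feature resources
#'
#' `read_rmsf_profile` reads a TSV with columns `position`, `rmsf` (Angstrom)
#' and returns the per-residue vector; `read_aaindex_matrix` reads a TSV of 20
#' rows (first column the amino acid) by P property columns.
#'
#' @param path TSV file.
#' @export
read_rmsf_profile <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t")
  stopifnot(all(c("position", "rmsf") %in% names(tab)))
  out <- numeric(max(tab$position))
  out[tab$position] <- tab$rmsf
  if (any(out < 0)) stop("RMSF values must be non-negative")
  out
}

#' @rdname read_rmsf_profile
#' @export
read_aaindex_matrix <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1L)
  as.matrix(tab)
}

#' Assemble the feature resources for a protein
#'
#' Bundles everything [encode_variant()] needs: the AAIndex principal
#' components, the energy table with its selected high-variance terms
#' (squashed at `squash_threshold` REU and min-max normalized over the table),
#' and the min-max-normalized RMSF profile. The energy table and RMSF profile
#' may be omitted, in which case only biophysics-free encodings (D = 40) are
#' possible.
#'
#' Stop-symbol substitutions have no energy-table entry; their energy features
#' fall back to the squash ceiling (`2 * squash_threshold`, maximally
#' destabilizing — a stop codon truncates the protein), which normalizes to 1.
#' Wild-type rows carry the table's self-substitution entry.
#'
#' @param reference Reference amino-acid sequence.
#' @param aaindex A `20 x P` property matrix or a precomputed
#'   [compute_aaindex_pcs()] result.
#' @param energy An [energy_table()] with `L == nchar(reference)`, or `NULL`.
#' @param rmsf Numeric per-residue RMSF vector (length L), or `NULL`.
#' @param n_energy_terms Width of the energy block (total ddG + components);
#'   default 8.
#' @param squash_threshold REU threshold for [squash_energy()]; default 50.
#' @param K Number of AAIndex components; default 19.
#' @return Object of class `vep_resources`.
#' @export
feature_resources <- function(reference, aaindex, energy = NULL, rmsf = NULL,
                              n_energy_terms = 8, squash_threshold = 50, K = 19) {
  reference <- toupper(reference)
  L <- nchar(reference)
  ref <- strsplit(reference, "")[[1]]
  if (!all(ref %in% .AA20)) stop("reference contains non-canonical symbols")
  pcs <- if (inherits(aaindex, "aaindex_pcs")) aaindex
         else compute_aaindex_pcs(aaindex, K = K)
  # 21-row lookup: canonical rows from the PCs, stop-symbol row all zero
  aa_block <- rbind(pcs$scores, matrix(0, 1L, pcs$K, dimnames = list("*")))
  sel <- NULL; enc_energy <- NULL; energy_norm <- NULL
  if (!is.null(energy)) {
    stopifnot(inherits(energy, "energy_table"))
    if (energy$L != L) stop("energy table length ", energy$L,
                            " does not match reference length ", L)
    sel <- select_energy_terms(energy, k = n_energy_terms)
    sq <- array(NA_real_, dim = c(L, 20L, length(sel)),
                dimnames = list(NULL, .AA20, sel))
    for (tm in sel)
      sq[, , tm] <- squash_energy(energy$values[, , tm], squash_threshold)
    flat <- matrix(sq, nrow = L * 20L, ncol = length(sel),
                   dimnames = list(NULL, sel))
    energy_norm <- fit_minmax(flat)
    flatn <- apply_minmax(energy_norm, flat)
    # L x 21 x k: canonical substitutions plus the stop-symbol fallback column
    enc_energy <- array(NA_real_, dim = c(L, 21L, length(sel)),
                        dimnames = list(NULL, .AA21, sel))
    enc_energy[, .AA20, ] <- array(flatn, dim = c(L, 20L, length(sel)))
    stop_row <- apply_minmax(energy_norm,
                             matrix(2 * squash_threshold, 1L, length(sel),
                                    dimnames = list(NULL, sel)))
    enc_energy[, "*", ] <- matrix(rep(stop_row, each = L), nrow = L)
  }
  rmsf_norm <- NULL
  if (!is.null(rmsf)) {
    if (length(rmsf) != L) stop("RMSF profile length must equal reference length")
    if (any(rmsf < 0)) stop("RMSF values must be non-negative")
    rmsf_norm <- apply_minmax(fit_minmax(rmsf), rmsf)
  }
  structure(list(reference = reference, L = L, ref_chars = ref,
                 aaindex = pcs, aa_block = aa_block,
                 energy = energy, selected_terms = sel,
                 energy_normalizer = energy_norm, enc_energy = enc_energy,
                 rmsf = rmsf, rmsf_norm = rmsf_norm,
                 squash_threshold = squash_threshold),
            class = "vep_resources")
}

#' @export
print.vep_resources <- function(x, ...) {
  cat(sprintf("Feature resources for %d-residue protein\n", x$L))
  cat(sprintf("  AAIndex: %d components\n", x$aaindex$K))
  if (!is.null(x$energy))
    cat("  energy terms:", paste(x$selected_terms, collapse = ", "), "\n")
  cat("  RMSF profile:", if (is.null(x$rmsf)) "absent" else "present", "\n")
  cat(sprintf("  per-residue feature width: %d (biophysics) / %d (sequence only)\n",
              feature_width(x, TRUE), feature_width(x, FALSE)))
  invisible(x)
}

#' Per-residue feature width
#' @param resources A [feature_resources()] bundle.
#' @param with_biophysics Logical.
#' @return Integer D: 21 (one-hot) + K AAIndex components, plus the energy
#'   block and RMSF column when biophysics is enabled.
#' @export
feature_width <- function(resources, with_biophysics = TRUE) {
  d <- 21L + resources$aaindex$K
  if (with_biophysics) {
    if (is.null(resources$enc_energy) || is.null(resources$rmsf_norm))
      stop("biophysics encoding requires both an energy table and an RMSF profile")
    d <- d + length(resources$selected_terms) + 1L
  }
  as.integer(d)
}

# Row of per-residue features for amino acid `aa` at position `pos`.
# Layout: one-hot(21) | AAIndex(K) | [energy(k) | rmsf(1)].
encode_row <- function(resources, pos, aa, with_biophysics) {
  onehot <- numeric(21L)
  onehot[match(aa, .AA21)] <- 1
  row <- c(onehot, resources$aa_block[aa, ])
  if (with_biophysics)
    row <- c(row, resources$enc_energy[pos, aa, ], resources$rmsf_norm[pos])
  row
}

# Full wild-type encoding as an L x D matrix, cached on the resources object.
wildtype_encoding <- function(resources, with_biophysics) {
  D <- feature_width(resources, with_biophysics)
  M <- matrix(0, resources$L, D)
  for (p in seq_len(resources$L))
    M[p, ] <- encode_row(resources, p, resources$ref_chars[p], with_biophysics)
  kterms <- if (with_biophysics) resources$selected_terms else character(0)
  colnames(M) <- c(paste0("onehot_", .AA21),
                   paste0("aaindex_PC", seq_len(resources$aaindex$K)),
                   if (with_biophysics) c(paste0("energy_", kterms), "rmsf"))
  M
}

#' Encode a variant as an `N_res x D` feature matrix
#'
#' Row `i` holds the features of the amino acid present at position `i` in the
#' variant sequence: its one-hot indicator over the 21-symbol alphabet, its
#' AAIndex principal components, and — when biophysics is enabled — the
#' squashed, min-max-normalized energy terms of the substitution at `i`
#' (wild-type rows use the self-substitution entry; stop rows the ceiling
#' fallback) plus the normalized RMSF of residue `i`. Multi-mutant variants
#' place each mutation's single-mutation energy row at its own position;
#' additivity across sites is left to the downstream model.
#'
#' @param variant A variant string or parsed `vep_variant`.
#' @param resources A [feature_resources()] bundle.
#' @param with_biophysics Include the energy + RMSF blocks (D = 49 with the
#'   defaults) or not (D = 40).
#' @return Numeric `L x D` matrix.
#' @export
encode_variant <- function(variant, resources, with_biophysics = TRUE) {
  if (is.character(variant))
    variant <- parse_variant(variant, resources$reference)
  M <- wildtype_encoding(resources, with_biophysics)
  for (j in seq_len(nrow(variant)))
    M[variant$position[j], ] <- encode_row(resources, variant$position[j],
                                           variant$mut[j], with_biophysics)
  M
}

#' Encode every variant of a dataset (flattened)
#'
#' Encodes the whole dataset into an `n x (L*D)` matrix, each row a variant's
#' feature matrix flattened position-major (residue 1's D features, then
#' residue 2's, ...). This is the layout the model engine consumes.
#'
#' @param dataset A [dms_dataset()] whose reference matches the resources.
#' @param resources A [feature_resources()] bundle.
#' @param with_biophysics Logical; see [encode_variant()].
#' @return Numeric matrix with attributes `L`, `D` and `n_mut` (mutations per
#'   variant).
#' @export
encode_dataset <- function(dataset, resources, with_biophysics = TRUE) {
  if (dataset$reference != resources$reference)
    stop("dataset reference does not match the feature resources")
  L <- resources$L
  D <- feature_width(resources, with_biophysics)
  wt <- wildtype_encoding(resources, with_biophysics)
  wt_flat <- as.vector(t(wt))
  n <- nrow(dataset$variants)
  X <- matrix(rep(wt_flat, times = n), nrow = n, byrow = TRUE)
  for (i in seq_len(n)) {
    mv <- dataset$mutations[[i]]
    for (j in seq_len(nrow(mv))) {
      p <- mv$position[j]
      X[i, ((p - 1L) * D + 1L):(p * D)] <-
        encode_row(resources, p, mv$mut[j], with_biophysics)
    }
  }
  structure(X, L = L, D = D, n_mut = n_mutations(dataset),
            blocks = feature_blocks(colnames(wt), L, D))
}

# Flattened column indices of each encoding block (one-hot / AAIndex /
# energy / RMSF), used for feature-group dropout.
feature_blocks <- function(cn, L, D) {
  pats <- c(onehot = "^onehot_", aaindex = "^aaindex_", energy = "^energy_",
            rmsf = "^rmsf$")
  blocks <- lapply(pats, function(p) {
    cset <- grep(p, cn)
    if (!length(cset)) return(NULL)
    as.vector(outer(cset, (seq_len(L) - 1L) * D, "+"))
  })
  Filter(Negate(is.null), blocks)
}
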