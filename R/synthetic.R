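# Synthetic fixtures: a self-consistent protein "world" (sequence, structure,
# energy table, RMSF, amino-acid properties) whose ground-truth fitness is an
# explicit logistic function of the total mutational energy, plus a DMS
# simulator that turns that fitness into sequencing read counts.

# REF2015-style component term labels (19 components; ddg_total is the sum).
.SYN_TERMS <- c("fa_atr", "fa_rep", "fa_intra_rep", "fa_sol", "lk_ball_wtd",
                "fa_intra_sol_xover4", "fa_elec", "pro_close", "hbond_sr_bb",
                "hbond_lr_bb", "hbond_bb_sc", "hbond_sc", "dslf_fa13",
                "omega", "fa_dun", "p_aa_pp", "yhh_planarity", "ref",
                "rama_prepro")

#' Generate a synthetic protein world
#'
#' Produces a complete set of mutually consistent fixtures: a random
#' reference sequence, idealized alpha-helical coordinates (whose
#' representative-atom contact graph is connected at 7 Angstrom), a per-site
#' x per-substitution energy table with heterogeneous per-term variances
#' (total ddG = sum of components; self-substitutions all zero; a small
#' fraction of entries pushed above the 50 REU squash threshold to mimic
#' steric clashes), a non-negative RMSF profile, and an AAIndex-style 20 x P
#' property matrix. Regenerating with the same seed reproduces every artifact
#' exactly.
#'
#' The ground-truth fitness is a logistic function of the summed total ddG of
#' a variant's mutations (see [true_fitness()]): a stability-threshold model
#' in which function is lost once cumulative destabilization crosses the
#' midpoint. Fitness thus depends on sequence *only through the energy
#' table*, which is what makes the biophysics features sufficient statistics
#' for extrapolation experiments.
#'
#' @param L Protein length (>= 10).
#' @param n_terms Number of component energy terms; default 19.
#' @param seed Integer seed.
#' @param n_properties Columns of the synthetic property matrix; default 30.
#' @param midpoint,softness Logistic stability midpoint and softness (REU).
#' @param max_score Fitness of a fully stable protein.
#' @param noise_sd Gaussian observation noise added when simulating datasets.
#' @param alpha Selection strength coupling fitness to enrichment.
#' @param clash_prob Fraction of substitutions given a large clash penalty.
#' @param clash_size Size of the clash penalty (REU), added to `fa_rep`.
#' @return Object of class `synthetic_world`.
#' @export
generate_world <- function(L = 50L, n_terms = 19L, seed = 1L,
                           n_properties = 30L, midpoint = 5, softness = 2,
                           max_score = 1, noise_sd = 0.02, alpha = 3,
                           clash_prob = 0.02, clash_size = 70) {
  stopifnot(L >= 10L, n_terms >= 2L, n_terms <= length(.SYN_TERMS),
            softness > 0, max_score > 0, noise_sd >= 0)
  with_seed(seed, {
    ref_chars <- sample(.AA20, L, replace = TRUE)
    reference <- paste(ref_chars, collapse = "")
    # idealized alpha helix: 1.5 A rise, 100 deg twist, 2.3 A radius;
    # C-beta sits 1.53 A radially outward from the C-alpha
    ang <- (seq_len(L) - 1L) * 100 * pi / 180
    ca <- cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * (seq_len(L) - 1L))
    cb <- ca + 1.53 * cbind(cos(ang), sin(ang), 0)
    rep_xyz <- ifelse(matrix(ref_chars == "G", L, 3L), ca, cb)
    terms <- .SYN_TERMS[seq_len(n_terms)]
    sds <- 2.5 * 0.8^(seq_len(n_terms) - 1L)   # heterogeneous term variances
    vals <- array(0, dim = c(L, 20L, n_terms + 1L),
                  dimnames = list(as.character(seq_len(L)), .AA20,
                                  c(terms, "ddg_total")))
    for (t in seq_len(n_terms))
      vals[, , t] <- matrix(stats::rnorm(L * 20L, mean = 0.2, sd = sds[t]),
                            L, 20L)
    clash <- matrix(stats::runif(L * 20L) < clash_prob, L, 20L)
    vals[, , "fa_rep"] <- vals[, , "fa_rep"] + clash * clash_size
    # wild-type self-substitutions are exactly zero in every term
    for (p in seq_len(L)) vals[p, ref_chars[p], ] <- 0
    vals[, , "ddg_total"] <- apply(vals[, , seq_len(n_terms), drop = FALSE],
                                   c(1, 2), sum)
    et <- energy_table(vals, protocol = list(repack_radius = 12, nloop = 1))
    rmsf <- 0.5 + 0.6 * sin(pi * (seq_len(L) - 1L) / (L - 1L))^2 +
      abs(stats::rnorm(L, 0, 0.08))
    props <- matrix(stats::rnorm(20L * n_properties), 20L, n_properties,
                    dimnames = list(.AA20, paste0("prop_", seq_len(n_properties))))
    props <- sweep(props, 2L, stats::runif(n_properties, 0.5, 3), "*")
    structure(list(reference = reference, ref_chars = ref_chars, L = L,
                   coords = rep_xyz, coords_ca = ca, coords_cb = cb,
                   energy = et, rmsf = rmsf, aaindex = props,
                   fitness = list(midpoint = midpoint, softness = softness,
                                  max_score = max_score, noise_sd = noise_sd),
                   alpha = alpha, seed = as.integer(seed)),
              class = "synthetic_world")
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("Synthetic world (seed %d): %d residues, %d energy terms + total\n",
              x$seed, x$L, length(x$energy$terms) - 1L))
  cat(sprintf("  fitness: logistic, midpoint %.3g REU, softness %.3g, max %.3g, noise sd %.3g; selection alpha %.3g\n",
              x$fitness$midpoint, x$fitness$softness, x$fitness$max_score,
              x$fitness$noise_sd, x$alpha))
  invisible(x)
}

# Summed total ddG of a variant's mutations; stop substitutions (no table
# entry) count as 100 REU, i.e. effectively complete destabilization.
variant_ddg <- function(world, variant) {
  if (is.character(variant)) variant <- parse_variant(variant, world$reference)
  if (nrow(variant) == 0L) return(0)
  dd <- numeric(nrow(variant))
  for (j in seq_len(nrow(variant))) {
    if (variant$mut[j] == "*") dd[j] <- 100
    else dd[j] <- world$energy$values[variant$position[j], variant$mut[j],
                                      "ddg_total"]
  }
  sum(dd)
}

#' Ground-truth fitness of a variant
#'
#' A logistic stability-threshold model:
#' \deqn{F = \frac{F_{max}}{1 + \exp((\Delta\Delta G_{tot} - \mu)/\sigma_f)}}
#' where the total ddG sums the energy-table entries of the variant's
#' mutations (additivity). The wild type has ddG 0 and noiseless fitness
#' `max_score / (1 + exp(-midpoint/softness))`; a variant whose total ddG
#' equals the midpoint scores exactly `max_score / 2`. Optional Gaussian
#' observation noise (`noise_sd > 0`) models assay error; the deterministic
#' value is returned by default.
#'
#' @param world A [generate_world()] result.
#' @param variant Variant string, parsed `vep_variant`, list of either, or a
#'   [dms_dataset()] (vectorized over its variants).
#' @param noise_sd Gaussian noise s.d.; default 0 (deterministic).
#' @return Numeric fitness value(s).
#' @export
true_fitness <- function(world, variant, noise_sd = 0) {
  stopifnot(inherits(world, "synthetic_world"))
  variants <- if (inherits(variant, "dms_dataset")) variant$mutations
              else if (is.character(variant)) as.list(variant)
              else if (is.list(variant) && !is.data.frame(variant)) variant
              else list(variant)
  dd <- vapply(variants, function(v) variant_ddg(world, v), 0)
  f <- world$fitness$max_score /
    (1 + exp((dd - world$fitness$midpoint) / world$fitness$softness))
  if (noise_sd > 0) f <- f + stats::rnorm(length(f), 0, noise_sd)
  f
}

#' Simulate a DMS dataset from a synthetic world
#'
#' Draws variants with a configurable mutations-per-variant distribution
#' (positions uniform, substitutions uniform over the 19 non-wild-type
#' canonical amino acids, duplicate variants removed), assigns each a
#' ground-truth fitness with observation noise, and simulates sequencing:
#' input counts are multinomial over variant abundances (Gamma-distributed
#' library skew, wild type enriched 10x), selected counts are multinomial
#' with probabilities proportional to `abundance * exp(alpha * fitness)`.
#' Enrichment scores are attached via [score_from_counts()].
#'
#' @param world A [generate_world()] result.
#' @param n_variants Number of distinct mutant variants.
#' @param mutations_per_variant Named probability vector over mutation
#'   counts; default 45% singles, 45% doubles, 10% triples — the single/double
#'   dominated shape typical of DMS libraries.
#' @param read_depth Reads per pool (input and selected each); default 2e6.
#' @param alpha Selection strength; defaults to the world's.
#' @param include_wt Include a `"_wt"` record (needed for score centering).
#' @param seed Integer seed.
#' @return A [dms_dataset()] with counts and scores; the extra column
#'   `true_fitness` holds the noiseless ground truth.
#' @export
generate_dms <- function(world, n_variants = 5000L,
                         mutations_per_variant = c("1" = 0.45, "2" = 0.45,
                                                   "3" = 0.10),
                         read_depth = 2e6, alpha = world$alpha,
                         include_wt = TRUE, seed = 1L) {
  stopifnot(n_variants >= 1L, read_depth >= 1)
  ks <- as.integer(names(mutations_per_variant))
  stopifnot(all(ks >= 1), all(mutations_per_variant >= 0))
  with_seed(seed, {
    draw_one <- function() {
      k <- sample(ks, 1L, prob = mutations_per_variant)
      pos <- sort(sample.int(world$L, k))
      mut <- vapply(pos, function(p)
        sample(setdiff(.AA20, world$ref_chars[p]), 1L), "")
      paste0(world$ref_chars[pos], pos, mut, collapse = ",")
    }
    strings <- character(0)
    while (length(strings) < n_variants) {
      need <- n_variants - length(strings)
      strings <- unique(c(strings, replicate(ceiling(need * 1.2), draw_one())))
    }
    strings <- strings[seq_len(n_variants)]
    if (include_wt) strings <- c("_wt", strings)
    n <- length(strings)
    muts <- lapply(strings, parse_variant, reference = world$reference)
    f_det <- true_fitness(world, muts)
    f_obs <- f_det + stats::rnorm(n, 0, world$fitness$noise_sd)
    f_obs[strings == "_wt"] <- f_det[strings == "_wt"]  # wt is the reference
    abundance <- stats::rgamma(n, shape = 1, rate = 1) + 1e-6
    abundance[strings == "_wt"] <- 10 * mean(abundance)
    p_in <- abundance / sum(abundance)
    c_in <- as.numeric(stats::rmultinom(1L, read_depth, p_in))
    w_sel <- p_in * exp(alpha * f_obs)
    c_sel <- as.numeric(stats::rmultinom(1L, read_depth, w_sel / sum(w_sel)))
    ds <- dms_dataset(world$reference, strings, count_input = c_in,
                      count_selected = c_sel,
                      name = sprintf("synthetic_L%d_seed%d", world$L, seed))
    if (include_wt) ds <- score_from_counts(ds)
    ds$variants$true_fitness <- f_det
    ds
  })
}

#' Feature resources derived from a synthetic world
#'
#' Convenience wrapper: [feature_resources()] built from the world's own
#' property matrix, energy table and RMSF profile.
#'
#' @param world A [generate_world()] result.
#' @param ... Passed to [feature_resources()].
#' @return A `vep_resources` bundle.
#' @export
world_resources <- function(world, ...) {
  feature_resources(world$reference, world$aaindex, energy = world$energy,
                    rmsf = world$rmsf, ...)
}

#' Write a synthetic world's fixture files
#'
#' Emits the standard plain-text formats the rest of the package consumes:
#' `reference.fasta`, `energy.tsv` (with the protocol header comment),
#' `rmsf.tsv`, `aaindex.tsv` and `structure.pdb` (N/CA/CB-less minimal PDB:
#' C-alpha for every residue plus C-beta for non-glycines).
#'
#' @param world A [generate_world()] result.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "reference.fasta"),
             energy = file.path(dir, "energy.tsv"),
             rmsf = file.path(dir, "rmsf.tsv"),
             aaindex = file.path(dir, "aaindex.tsv"),
             pdb = file.path(dir, "structure.pdb"))
  write_fasta_sequence(world$reference, paths["fasta"], name = "synthetic")
  write_energy_table(world$energy, paths["energy"], reference = world$reference)
  utils::write.table(data.frame(position = seq_len(world$L), rmsf = world$rmsf),
                     paths["rmsf"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(aa = rownames(world$aaindex), world$aaindex),
                     paths["aaindex"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_world_pdb(world, paths["pdb"])
  paths
}

write_world_pdb <- function(world, path) {
  xyz <- NULL; elety <- character(0); resno <- integer(0); resid <- character(0)
  for (i in seq_len(world$L)) {
    xyz <- rbind(xyz, world$coords_ca[i, ])
    elety <- c(elety, "CA"); resno <- c(resno, i)
    resid <- c(resid, bio3d::aa123(world$ref_chars[i]))
    if (world$ref_chars[i] != "G") {
      xyz <- rbind(xyz, world$coords_cb[i, ])
      elety <- c(elety, "CB"); resno <- c(resno, i)
      resid <- c(resid, bio3d::aa123(world$ref_chars[i]))
    }
  }
  bio3d::write.pdb(pdb = NULL, file = path, xyz = as.vector(t(xyz)),
                   resno = resno, resid = resid, elety = elety,
                   chain = rep("A", length(resno)))
  invisible(path)
}
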