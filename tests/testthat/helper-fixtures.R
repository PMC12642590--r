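# Shared small fixtures, built in code.

# A tiny deterministic world reused across tests (L = 25 keeps everything fast).
tiny_world <- function(seed = 11) generate_world(L = 25L, seed = seed)

tiny_dataset <- function(world = tiny_world(), n = 200L, seed = 3L, ...) {
  generate_dms(world, n_variants = n, seed = seed, ...)
}

# A random valid variant string against a reference, for round-trip checks.
random_variant_string <- function(reference, max_mut = 3L) {
  ref <- strsplit(reference, "")[[1]]
  k <- sample.int(max_mut, 1L)
  pos <- sort(sample.int(length(ref), k))
  mut <- vapply(pos, function(p)
    sample(setdiff(aa_alphabet(), ref[p]), 1L), "")
  paste0(ref[pos], pos, mut, collapse = ",")
}
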