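# Residue contact graphs from structure coordinates (GCN topology).

#' Extract representative atom coordinates from a PDB structure
#'
#' For the contact graph each residue is represented by one atom: the C-alpha
#' for glycine and the C-beta for every other residue type. The first model
#' and (by default) the first chain of the structure are used; residues with
#' insertion codes are rejected, and the chain sequence must match the
#' reference exactly.
#'
#' @param pdb Path to a PDB file or a `bio3d` `pdb` object.
#' @param reference Reference amino-acid sequence the chain must match.
#' @param chain Chain identifier; default the first chain in the file.
#' @return Object of class `residue_coords`: list with `xyz` (`L x 3` matrix,
#'   Angstrom), `residues` (one-letter codes) and `chain`.
#' @export
extract_representative_atoms <- function(pdb, reference, chain = NULL) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb, verbose = FALSE)
  atoms <- pdb$atom
  atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- atoms$chain[1]
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no ATOM records for chain '", chain, "'")
  if (any(!is.na(atoms$insert) & atoms$insert != ""))
    stop("insertion codes are not supported (chain '", chain, "')")
  ref <- strsplit(toupper(reference), "")[[1]]
  L <- length(ref)
  resno <- unique(atoms$resno)
  if (length(resno) != L)
    stop("chain '", chain, "' resolves ", length(resno),
         " residues but the reference has ", L)
  xyz <- matrix(NA_real_, L, 3L)
  res1 <- character(L)
  missing <- character(0)
  for (i in seq_len(L)) {
    ra <- atoms[atoms$resno == resno[i], , drop = FALSE]
    res1[i] <- bio3d::aa321(ra$resid[1])
    want <- if (res1[i] == "G") "CA" else "CB"
    hit <- which(ra$elety == want)
    if (length(hit) == 0L) {
      missing <- c(missing, sprintf("%d (%s, no %s)", i, ra$resid[1], want))
    } else {
      xyz[i, ] <- as.numeric(ra[hit[1], c("x", "y", "z")])
    }
  }
  if (length(missing))
    stop("missing representative atom at position(s): ",
         paste(missing, collapse = "; "))
  if (!all(res1 == ref)) {
    bad <- which(res1 != ref)
    stop("chain sequence mismatch vs reference at position(s) ",
         paste(sprintf("%d (%s vs %s)", bad, res1[bad], ref[bad]), collapse = ", "))
  }
  if (any(!is.finite(xyz))) stop("non-finite coordinates")
  structure(list(xyz = xyz, residues = res1, chain = chain),
            class = "residue_coords")
}

#' Build a residue contact graph
#'
#' Residues are nodes; an undirected edge joins residues `i != j` whose
#' representative atoms lie within `threshold` Angstrom (Euclidean distance).
#'
#' @param coords A `residue_coords` object or a plain `L x 3` coordinate
#'   matrix.
#' @param threshold Contact cutoff in Angstrom (6 is typical for large
#'   beta-rich proteins, 7 otherwise).
#' @return Object of class `contact_graph`: list with `adjacency` (`L x L`
#'   binary, symmetric, zero diagonal), `distances` and `threshold`.
#' @export
build_contact_graph <- function(coords, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  xyz <- if (inherits(coords, "residue_coords")) coords$xyz else as.matrix(coords)
  stopifnot(ncol(xyz) == 3L, all(is.finite(xyz)))
  dm <- as.matrix(stats::dist(xyz))
  A <- (dm <= threshold) * 1
  diag(A) <- 0
  dimnames(A) <- NULL
  structure(list(adjacency = A, distances = dm, threshold = threshold),
            class = "contact_graph")
}

#' @export
print.contact_graph <- function(x, ...) {
  L <- nrow(x$adjacency)
  cat(sprintf("Contact graph: %d residues, %d edges, threshold %.1f A\n",
              L, sum(x$adjacency) / 2, x$threshold))
  invisible(x)
}

#' Symmetric-normalized propagation matrix for graph convolution
#'
#' Adds self-loops and symmetrically normalizes:
#' \eqn{\hat A = D^{-1/2}(A + I)D^{-1/2}} with \eqn{D} the degree matrix of
#' \eqn{A + I}. This is the standard spectral graph-convolution propagation
#' rule; an edgeless graph yields the identity.
#'
#' @param graph A [build_contact_graph()] result (or a bare adjacency matrix).
#' @return Dense `L x L` propagation matrix.
#' @export
normalize_adjacency <- function(graph) {
  A <- if (inherits(graph, "contact_graph")) graph$adjacency else as.matrix(graph)
  stopifnot(nrow(A) == ncol(A), isTRUE(all.equal(A, t(A))), all(diag(A) == 0))
  AI <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(AI))
  AI * outer(dinv, dinv)
}

#' Write a contact graph as an edge-list TSV
#'
#' @param graph A `contact_graph`.
#' @param path Output TSV with columns `i`, `j`, `distance` (upper triangle).
#' @export
write_edge_list <- function(graph, path) {
  idx <- which(upper.tri(graph$adjacency) & graph$adjacency == 1, arr.ind = TRUE)
  out <- data.frame(i = idx[, 1], j = idx[, 2],
                    distance = graph$distances[idx])
  out <- out[order(out$i, out$j), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
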