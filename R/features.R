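# The 5-dimensional feature vector: structural position (x, y, z), pLDDT,
# and the BLOSUM62 substitution penalty.

MOVA_FEATURES <- c("x", "y", "z", "plddt", "delta_blosum62")

#' Compute feature vectors for variants against a structure profile
#'
#' For each variant, copies the mean x/y/z coordinates and pLDDT of the
#' variant residue from the structure profile and appends
#' `delta_blosum62(ref, alt)`. The variant's reference amino acid must match
#' the structure's residue at that position — a mismatch (typically a
#' transcript/isoform mix-up) is a hard error, not a warning.
#'
#' @param variants data.frame of variant records (see [read_variant_table()]).
#' @param profile `StructureProfile` for the same protein.
#' @return data.frame with columns `x`, `y`, `z`, `plddt`, `delta_blosum62`,
#'   one row per variant, in input order.
#' @export
featurize_variants <- function(variants, profile) {
  stopifnot(inherits(profile, "StructureProfile"))
  res <- profile$residues
  idx <- match(variants$position, res$position)
  if (anyNA(idx)) {
    bad <- unique(variants$position[is.na(idx)])
    stop(sprintf("position(s) absent from structure '%s': %s",
                 profile$gene_id, paste(bad, collapse = ", ")), call. = FALSE)
  }
  mism <- which(res$aa[idx] != variants$ref)
  if (length(mism) > 0L) {
    i <- mism[1L]
    stop(sprintf(
      "reference mismatch at position %d: variant table says %s, structure '%s' has %s (%d mismatch(es) total; check transcript/isoform)",
      variants$position[i], variants$ref[i], profile$gene_id, res$aa[idx[i]],
      length(mism)), call. = FALSE)
  }
  data.frame(
    x = res$x[idx], y = res$y[idx], z = res$z[idx],
    plddt = res$plddt[idx],
    delta_blosum62 = delta_blosum62(variants$ref, variants$alt)
  )
}

#' Feature vector for a single substitution
#'
#' @param position 1-based residue index.
#' @param ref_aa,alt_aa One-letter amino-acid codes.
#' @param profile `StructureProfile`.
#' @return Named numeric vector `(x, y, z, plddt, delta_blosum62)`.
#' @export
featurize <- function(position, ref_aa, alt_aa, profile) {
  v <- data.frame(gene = profile$gene_id, position = position,
                  ref = ref_aa, alt = alt_aa, label = "unlabeled",
                  stringsAsFactors = FALSE)
  unlist(featurize_variants(v, profile)[1L, ])
}
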