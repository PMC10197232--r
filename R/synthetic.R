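# Self-contained synthetic fixtures: AlphaFold-like single-chain structures,
# hotspot-clustered labeled variants, and a tunably informative external
# score. These emulate the study conditions end to end (a protein whose
# pathogenic variants cluster in a 3D hotspot, scored against uniform
# neutral variants) without any download.

#' Specification of a synthetic gene dataset
#'
#' Defaults describe the reference simulation: a 400-residue compact
#' self-avoiding chain with 3.8 Angstrom steps (Calpha-Calpha), a pathogenic
#' hotspot of radius 12 Angstrom centred at residue `round(0.8 * length)`
#' (C-terminal region, where real hotspots such as the TDP-43 one sit), 50
#' pathogenic variants of which 90% fall inside the hotspot, 150 neutral
#' variants uniform over the chain, pLDDT 90 in the core and 40 in the final
#' 10% of residues (a disordered tail), and an external score that mixes the
#' label with uniform noise at weight `external_informativeness`.
#'
#' @param length Number of residues.
#' @param step Calpha-Calpha step length, Angstrom.
#' @param hotspot_center Residue index of the hotspot centre.
#' @param hotspot_radius Hotspot radius, Angstrom.
#' @param n_pos,n_neg Number of pathogenic / neutral variants.
#' @param p_pos_in_hotspot Fraction of pathogenic variants placed inside the
#'   hotspot.
#' @param plddt_core,plddt_tail pLDDT values (0-100) for the structured core
#'   and the disordered tail.
#' @param tail_fraction Fraction of C-terminal residues forming the
#'   low-pLDDT tail.
#' @param external_informativeness Weight in \[0, 1\] of the label in the
#'   external score column; 0 = pure noise, 1 = the label itself.
#' @param seed Integer RNG seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(length = 400L, step = 3.8,
                           hotspot_center = round(0.8 * length),
                           hotspot_radius = 12,
                           n_pos = 50L, n_neg = 150L,
                           p_pos_in_hotspot = 0.9,
                           plddt_core = 90, plddt_tail = 40,
                           tail_fraction = 0.1,
                           external_informativeness = 0.5,
                           seed = 1L) {
  stopifnot(length >= 2L, step > 0, hotspot_center >= 1L,
            hotspot_center <= length, hotspot_radius > 0,
            n_pos >= 5L, n_neg >= 5L,  # k = 5 stratification by construction
            p_pos_in_hotspot >= 0, p_pos_in_hotspot <= 1,
            plddt_core >= 0, plddt_core <= 100,
            plddt_tail >= 0, plddt_tail <= 100,
            tail_fraction >= 0, tail_fraction < 1,
            external_informativeness >= 0, external_informativeness <= 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate a synthetic AlphaFold-like structure
#'
#' Grows a self-avoiding chain with fixed step length inside a confinement
#' sphere of radius `step * sqrt(length)`: each new residue is placed `step`
#' Angstrom from the previous one in a uniformly random direction, rejecting
#' candidates closer than 3.5 Angstrom to any earlier residue (excluded
#' volume) or outside the sphere (compactness). One pseudo-Calpha atom per
#' residue; residue identities uniform over the 20 canonical amino acids;
#' pLDDT from the spec's core/tail profile.
#'
#' @param spec [synthetic_spec()].
#' @param path Optional path; when given, the structure is also written as a
#'   PDB file via [write_structure()] and re-read, so the returned profile
#'   carries the file's formatting precision.
#' @param gene_id Identifier for the profile.
#' @return A `StructureProfile`.
#' @export
generate_structure <- function(spec = synthetic_spec(), path = NULL,
                               gene_id = "SYNTH1") {
  set.seed(spec$seed)
  min_sep <- 3.5
  confine <- spec$step * sqrt(spec$length)
  max_restarts <- 50L
  max_tries <- 200L
  for (attempt in seq_len(max_restarts)) {
    xyz <- matrix(NA_real_, spec$length, 3L)
    xyz[1L, ] <- 0
    ok <- TRUE
    for (i in seq_len(spec$length - 1L) + 1L) {
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        u <- stats::rnorm(3)
        cand <- xyz[i - 1L, ] + spec$step * u / sqrt(sum(u^2))
        if (sqrt(sum(cand^2)) > confine) next
        prev <- xyz[seq_len(i - 2L), , drop = FALSE]
        if (nrow(prev) > 0L) {
          d2 <- (prev[, 1L] - cand[1L])^2 + (prev[, 2L] - cand[2L])^2 +
                (prev[, 3L] - cand[3L])^2
          if (min(d2) < min_sep^2) next
        }
        xyz[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) break
  }
  if (!ok) {
    stop("chain generation failed after bounded retries; increase the confinement radius (shorter chain or larger step)",
         call. = FALSE)
  }
  n_tail <- floor(spec$tail_fraction * spec$length)
  plddt <- rep(spec$plddt_core, spec$length)
  if (n_tail > 0L) {
    plddt[(spec$length - n_tail + 1L):spec$length] <- spec$plddt_tail
  }
  atoms <- data.frame(
    position = seq_len(spec$length),
    aa = sample(AA_CODES, spec$length, replace = TRUE),
    atom = "CA",
    x = round(xyz[, 1L], 3), y = round(xyz[, 2L], 3), z = round(xyz[, 3L], 3),
    plddt = plddt,
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    write_structure(atoms, path)
    return(read_structure(path, gene_id = gene_id))
  }
  new_structure_profile(
    gene_id,
    data.frame(position = atoms$position, aa = atoms$aa, x = atoms$x,
               y = atoms$y, z = atoms$z, plddt = atoms$plddt,
               n_atoms = 1L, stringsAsFactors = FALSE)
  )
}

#' Generate hotspot-clustered labeled variants for a synthetic structure
#'
#' Pathogenic ("positive") variants are placed at residues within
#' `hotspot_radius` Angstrom of the hotspot centre's coordinates with
#' probability `p_pos_in_hotspot` (per variant), and uniformly over the chain
#' otherwise; neutral ("negative") variants are uniform over the chain.
#' Reference amino acids are read from the structure; alternates are drawn
#' uniformly from the 19 non-reference residues, independent of the label, so
#' the substitution penalty carries no signal by construction. An `external`
#' score column is attached:
#' `informativeness * label + (1 - informativeness) * Uniform(0, 1)`.
#'
#' @param spec [synthetic_spec()].
#' @param profile `StructureProfile` from [generate_structure()] under the
#'   same spec.
#' @return Variant data.frame (see [read_variant_table()]) with an `external`
#'   score column.
#' @export
generate_variants <- function(spec, profile) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(profile, "StructureProfile"))
  set.seed(spec$seed + 1L)
  res <- profile$residues
  centre <- unlist(res[res$position == spec$hotspot_center, c("x", "y", "z")])
  if (length(centre) != 3L) {
    stop("hotspot centre residue absent from the structure", call. = FALSE)
  }
  d_centre <- sqrt((res$x - centre[1L])^2 + (res$y - centre[2L])^2 +
                   (res$z - centre[3L])^2)
  hot <- which(d_centre <= spec$hotspot_radius)
  if (length(hot) == 0L) {
    stop("hotspot contains no residues; increase hotspot_radius", call. = FALSE)
  }
  in_hot <- stats::runif(spec$n_pos) < spec$p_pos_in_hotspot
  pos_idx <- ifelse(in_hot,
                    hot[sample.int(length(hot), spec$n_pos, replace = TRUE)],
                    sample.int(nrow(res), spec$n_pos, replace = TRUE))
  neg_idx <- sample.int(nrow(res), spec$n_neg, replace = TRUE)
  idx <- c(pos_idx, neg_idx)
  label <- rep(c("positive", "negative"), c(spec$n_pos, spec$n_neg))
  ref <- res$aa[idx]
  alt <- vapply(ref, function(a) sample(setdiff(AA_CODES, a), 1L), "")
  y <- as.integer(label == "positive")
  external <- spec$external_informativeness * y +
    (1 - spec$external_informativeness) * stats::runif(length(y))
  out <- data.frame(gene = profile$gene_id, position = res$position[idx],
                    ref = ref, alt = unname(alt), label = label,
                    external = external, stringsAsFactors = FALSE)
  validate_variants(out)
}

#' Generate a complete synthetic dataset (structure + variants)
#'
#' @param spec [synthetic_spec()].
#' @param dir Optional output directory; when given, writes `structure.pdb`,
#'   `variants.tsv` and `spec.json` there.
#' @param gene_id Identifier for the gene.
#' @return List with `spec`, `profile` and `variants`.
#' @export
simulate_dataset <- function(spec = synthetic_spec(), dir = NULL,
                             gene_id = "SYNTH1") {
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    profile <- generate_structure(spec, path = file.path(dir, "structure.pdb"),
                                  gene_id = gene_id)
  } else {
    profile <- generate_structure(spec, gene_id = gene_id)
  }
  variants <- generate_variants(spec, profile)
  if (!is.null(dir)) {
    write_variant_table(variants, file.path(dir, "variants.tsv"))
    jsonlite::write_json(unclass(spec), file.path(dir, "spec.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(spec = spec, profile = profile, variants = variants)
}
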