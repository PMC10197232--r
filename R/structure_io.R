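# Reading and writing AlphaFold-dialect PDB files.
#
# AlphaFold DB models are single-chain PDB v3.3 files numbered 1..L in
# UniProt coordinates, with the per-residue pLDDT confidence stored in the
# B-factor column of every atom. Parsing is strictly fixed-column (the files
# are column-conformant); whitespace splitting would mis-read negative
# coordinates that abut the previous field.

#' Read an AlphaFold-style PDB file into a per-residue structure profile
#'
#' Parses the ATOM records of a single-chain PDB v3.3 file and reduces them
#' to one row per residue: the one-letter amino acid, the arithmetic mean of
#' the atomic x/y/z coordinates (Angstrom), and the mean B-factor, which in
#' AlphaFold models carries the pLDDT confidence (0-100).
#'
#' @param path Path to the PDB file.
#' @param gene_id Gene/protein identifier attached to the profile.
#' @return A `StructureProfile`: a list with elements `gene_id`, `residues`
#'   (data.frame with columns `position`, `aa`, `x`, `y`, `z`, `plddt`,
#'   `n_atoms`, ordered by strictly increasing `position`) and `source_path`.
#' @details HETATM, TER and END records are ignored. Files with more than one
#'   chain, with insertion codes, with unknown residue names, or with no ATOM
#'   records are rejected with an explicit error (AlphaFold models have a
#'   single chain A and no insertion codes).
#' @seealso [write_structure()]
#' @export
read_structure <- function(path, gene_id = sub("\\.pdb$", "", basename(path))) {
  if (!file.exists(path)) {
    stop(sprintf("structure file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  atom <- lines[startsWith(lines, "ATOM  ")]
  if (length(atom) == 0L) {
    stop(sprintf("no ATOM records in %s", path), call. = FALSE)
  }
  # PDB v3.3 fixed columns (1-based): resName 18-20, chain 22, resSeq 23-26,
  # iCode 27, x 31-38, y 39-46, z 47-54, B-factor 61-66.
  chain <- substr(atom, 22, 22)
  chains <- unique(chain)
  if (length(chains) > 1L) {
    stop(sprintf("expected a single chain, found %d chains: %s",
                 length(chains), paste(chains, collapse = ", ")),
         call. = FALSE)
  }
  icode <- trimws(substr(atom, 27, 27))
  if (any(icode != "")) {
    stop("insertion codes are not supported (found at residue(s) ",
         paste(unique(trimws(substr(atom, 23, 27))[icode != ""]), collapse = ", "),
         ")", call. = FALSE)
  }
  resname <- trimws(substr(atom, 18, 20))
  unknown <- setdiff(unique(resname), names(AA_THREE_TO_ONE))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown residue name(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  resseq <- as.integer(substr(atom, 23, 26))
  x <- as.numeric(substr(atom, 31, 38))
  y <- as.numeric(substr(atom, 39, 46))
  z <- as.numeric(substr(atom, 47, 54))
  b <- as.numeric(substr(atom, 61, 66))
  if (anyNA(resseq) || anyNA(x) || anyNA(y) || anyNA(z) || anyNA(b)) {
    stop(sprintf("malformed ATOM record(s) in %s", path), call. = FALSE)
  }

  pos <- sort(unique(resseq))
  grp <- match(resseq, pos)
  agg <- function(v) as.numeric(tapply(v, grp, mean))
  aa3 <- tapply(resname, grp, function(r) {
    u <- unique(r)
    if (length(u) > 1L) {
      stop(sprintf("conflicting residue names within one residue number: %s",
                   paste(u, collapse = ", ")), call. = FALSE)
    }
    u
  })
  residues <- data.frame(
    position = pos,
    aa = unname(AA_THREE_TO_ONE[as.character(aa3)]),
    x = agg(x), y = agg(y), z = agg(z),
    plddt = agg(b),
    n_atoms = as.integer(tabulate(grp)),
    stringsAsFactors = FALSE
  )
  if (any(residues$plddt < 0 | residues$plddt > 100)) {
    stop("pLDDT (B-factor) values outside [0, 100]", call. = FALSE)
  }
  new_structure_profile(gene_id, residues, source_path = path)
}

new_structure_profile <- function(gene_id, residues, source_path = NA_character_) {
  stopifnot(is.data.frame(residues),
            all(c("position", "aa", "x", "y", "z", "plddt") %in% names(residues)))
  if (is.unsorted(residues$position, strictly = TRUE)) {
    stop("residue positions must be strictly increasing", call. = FALSE)
  }
  structure(
    list(gene_id = gene_id, residues = residues, source_path = source_path),
    class = "StructureProfile"
  )
}

#' @export
print.StructureProfile <- function(x, ...) {
  cat(sprintf("StructureProfile '%s': %d residues (%d-%d), mean pLDDT %.1f\n",
              x$gene_id, nrow(x$residues), min(x$residues$position),
              max(x$residues$position), mean(x$residues$plddt)))
  invisible(x)
}

#' Write atoms as an AlphaFold-style PDB file
#'
#' Emits PDB v3.3 ATOM records (single chain A, pLDDT in the B-factor field,
#' coordinates to 3 decimals, B-factor to 2) that [read_structure()] parses
#' back to an equal profile within that formatting precision.
#'
#' @param atoms data.frame with one row per atom: columns `position`
#'   (1-based residue number), `aa` (one-letter code), `x`, `y`, `z`
#'   (Angstrom), `plddt` (0-100) and optionally `atom` (PDB atom name,
#'   default `"CA"`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(atoms, path) {
  if (!is.data.frame(atoms) || nrow(atoms) == 0L) {
    stop("'atoms' must be a non-empty data.frame", call. = FALSE)
  }
  req <- c("position", "aa", "x", "y", "z", "plddt")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0L) {
    stop(sprintf("'atoms' is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  check_aa(atoms$aa, "residue")
  if (is.null(atoms$atom)) atoms$atom <- "CA"
  name4 <- sprintf(" %-3s", atoms$atom)  # standard left-justified-at-col-14 names
  rec <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(atoms)), name4, AA_ONE_TO_THREE[atoms$aa], "A",
    as.integer(atoms$position), atoms$x, atoms$y, atoms$z, 1.00, atoms$plddt,
    substr(trimws(atoms$atom), 1, 1)
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(rec, "TER", "END"), con)
  invisible(path)
}

#' Convert a structure profile to a one-atom-per-residue atom table
#'
#' Convenience for writing a profile back to disk when only residue-level
#' coordinates are available (one pseudo-Calpha per residue).
#'
#' @param profile A `StructureProfile`.
#' @return data.frame suitable for [write_structure()].
#' @export
profile_atoms <- function(profile) {
  stopifnot(inherits(profile, "StructureProfile"))
  r <- profile$residues
  data.frame(position = r$position, aa = r$aa, atom = "CA",
             x = r$x, y = r$y, z = r$z, plddt = r$plddt,
             stringsAsFactors = FALSE)
}
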