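# Labeled variant tables.
#
# Tab-separated, UTF-8, header `gene position ref alt label`, positions
# 1-based residue indices on the UniProt-canonical (AlphaFold DB) sequence.
# Any additional numeric columns are carried along as external scores
# (e.g. REVEL, CADD) for evaluation and fusion.

VARIANT_LABELS <- c("positive", "negative", "unlabeled")
VARIANT_CORE_COLS <- c("gene", "position", "ref", "alt", "label")

#' Read a labeled variant table
#'
#' @param path Path to a TSV with header columns `gene`, `position`, `ref`,
#'   `alt`, `label` (values `positive`, `negative` or `unlabeled`) plus any
#'   number of external score columns (numeric; `NA` allowed).
#' @return data.frame of validated variant records; external score columns
#'   are listed in `attr(, "score_columns")`.
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("variant table not found: %s", path), call. = FALSE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(VARIANT_CORE_COLS, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("variant table %s is missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  validate_variants(df, path = path)
}

#' Validate a variant record table
#'
#' Checks column types, canonical amino-acid codes, positive 1-based
#' positions and known labels; errors name the offending data line
#' (header = line 1).
#'
#' @param variants data.frame with the core variant columns.
#' @param path Optional source path used in error messages.
#' @return The validated data.frame with `attr(, "score_columns")` set.
#' @export
validate_variants <- function(variants, path = "<in-memory>") {
  line_of <- function(i) i + 1L  # +1 for the header line
  bad_msg <- function(rows, what) {
    stop(sprintf("%s: %s at line(s) %s", path, what,
                 paste(line_of(rows), collapse = ", ")), call. = FALSE)
  }
  pos <- suppressWarnings(as.integer(variants$position))
  bad <- which(is.na(pos) | pos < 1L)
  if (length(bad) > 0L) bad_msg(bad, "position is not a positive integer")
  variants$position <- pos
  bad <- which(!(variants$ref %in% AA_CODES))
  if (length(bad) > 0L) bad_msg(bad, "non-canonical ref amino acid")
  bad <- which(!(variants$alt %in% AA_CODES))
  if (length(bad) > 0L) bad_msg(bad, "non-canonical alt amino acid")
  bad <- which(!(variants$label %in% VARIANT_LABELS))
  if (length(bad) > 0L) {
    bad_msg(bad, sprintf("unknown label %s (expected %s)",
                         paste(unique(variants$label[bad]), collapse = "/"),
                         paste(VARIANT_LABELS, collapse = "/")))
  }
  score_cols <- setdiff(names(variants), VARIANT_CORE_COLS)
  for (sc in score_cols) {
    v <- suppressWarnings(as.numeric(variants[[sc]]))
    bad <- which(is.na(v) & !is.na(variants[[sc]]) & variants[[sc]] != "")
    if (length(bad) > 0L) bad_msg(bad, sprintf("non-numeric value in score column '%s'", sc))
    variants[[sc]] <- v
  }
  attr(variants, "score_columns") <- score_cols
  variants
}

#' Write a variant table as TSV
#'
#' @param variants data.frame of variant records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# 0/1 label vector for modelling; 'unlabeled' records are rejected.
variant_labels01 <- function(variants) {
  if (any(variants$label == "unlabeled")) {
    stop("dataset contains unlabeled variants; label them or drop them first",
         call. = FALSE)
  }
  as.integer(variants$label == "positive")
}
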