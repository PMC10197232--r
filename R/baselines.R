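# Distance-to-known-pathogenic-variant baseline and per-feature ablation.

#' Minimum Euclidean distance to a set of pathogenic residues
#'
#' Distances are between residue mean coordinates (the same per-residue
#' reduction as the model features), in Angstrom.
#'
#' @param coord Numeric length-3 vector (x, y, z) of the query residue.
#' @param pathogenic_coords Numeric matrix with 3 columns, one row per known
#'   pathogenic residue.
#' @return Minimum distance in Angstrom (0 when the query coincides with a
#'   pathogenic residue).
#' @export
min_distance <- function(coord, pathogenic_coords) {
  pathogenic_coords <- rbind(pathogenic_coords)
  if (nrow(pathogenic_coords) == 0L) {
    stop("empty pathogenic set: at least one known pathogenic residue required",
         call. = FALSE)
  }
  stopifnot(length(coord) == 3L, ncol(pathogenic_coords) == 3L)
  d2 <- (pathogenic_coords[, 1L] - coord[1L])^2 +
        (pathogenic_coords[, 2L] - coord[2L])^2 +
        (pathogenic_coords[, 3L] - coord[3L])^2
  sqrt(min(d2))
}

# Residue mean coordinates for each variant, as an n x 3 matrix.
variant_coords <- function(variants, profile) {
  f <- featurize_variants(variants, profile)
  as.matrix(f[, c("x", "y", "z")])
}

# Held-out distance scores for one fold: the pathogenic reference set is
# built from TRAINING-split positives only. Returns -min_distance (higher =
# more pathogenic) for the test indices. Split out so leakage can be tested
# directly against index sets.
fold_distance_scores <- function(train, test, labels01, coords) {
  ref <- coords[train[labels01[train] == 1L], , drop = FALSE]
  if (nrow(ref) == 0L) {
    stop("training split contains no pathogenic variants; cannot form the distance reference set",
         call. = FALSE)
  }
  -vapply(test, function(i) min_distance(coords[i, ], ref), numeric(1))
}

#' Cross-validated distance-to-known-pathogenic-variant baseline
#'
#' Within each fold of the repeated stratified CV, the set of known
#' pathogenic residues is taken from the training split only; each held-out
#' variant is scored by the negated minimum Euclidean distance from its
#' residue to that set (smaller distance = more pathogenic), and the usual
#' AUC/ROC machinery is applied. No model is fitted.
#'
#' @inheritParams mova_cv
#' @return A `mova_cv_result`.
#' @export
distance_cv <- function(variants, profile, cv = cv_config()) {
  y <- variant_labels01(variants)
  coords <- variant_coords(variants, profile)
  scorer <- function(train, test, seed) {
    fold_distance_scores(train, test, y, coords)
  }
  run_cv(y, scorer, cv)
}

#' Per-feature ablation experiment
#'
#' Runs the cross-validated classifier restricted to each feature subset and
#' tabulates the mean AUC per subset, under one shared CV seed so subsets see
#' identical fold assignments.
#'
#' @inheritParams mova_cv
#' @param subsets Named list of character vectors of feature names, e.g.
#'   `list(xyz = c("x","y","z"), plddt = "plddt")`.
#' @return List with `table` (data.frame subset/mean_auc) and `results`
#'   (named list of `mova_cv_result`).
#' @export
feature_ablation <- function(variants, profile,
                             subsets = list(
                               xyz = c("x", "y", "z"),
                               plddt = "plddt",
                               blosum = "delta_blosum62",
                               plddt_blosum = c("plddt", "delta_blosum62"),
                               full = MOVA_FEATURES),
                             model_config = mova_config(), cv = cv_config()) {
  if (length(subsets) == 0L) stop("'subsets' must be non-empty", call. = FALSE)
  if (is.null(names(subsets))) {
    names(subsets) <- vapply(subsets, paste, "", collapse = "+")
  }
  results <- lapply(subsets, function(fs) {
    mova_cv(variants, profile, features = fs,
            model_config = model_config, cv = cv)
  })
  list(
    table = data.frame(
      subset = names(subsets),
      features = vapply(subsets, paste, "", collapse = "+"),
      mean_auc = vapply(results, function(r) r$mean_auc, numeric(1)),
      row.names = NULL
    ),
    results = results
  )
}

# Fold-internal distance feature: for every example, the minimum distance to
# the TRAINING-split pathogenic residues; pathogenic training examples use
# leave-self-out distances so the column is not degenerately zero on the
# class that defines it.
fold_distance_feature <- function(train, test, labels01, coords) {
  pos_train <- train[labels01[train] == 1L]
  if (length(pos_train) < 2L) {
    stop("need at least 2 pathogenic variants in the training split for leave-self-out distances",
         call. = FALSE)
  }
  ref <- coords[pos_train, , drop = FALSE]
  dist_for <- function(i) {
    keep <- pos_train != i
    if (all(keep)) min_distance(coords[i, ], ref)
    else min_distance(coords[i, ], ref[keep, , drop = FALSE])
  }
  list(train = vapply(train, dist_for, numeric(1)),
       test = vapply(test, function(i) min_distance(coords[i, ], ref), numeric(1)))
}

#' Cross-validation with the distance baseline added as a sixth feature
#'
#' Augments the 5 structural features with the fold-internal minimum distance
#' to training-split pathogenic residues (leave-self-out for the pathogenic
#' training examples themselves) and runs the standard repeated stratified CV.
#'
#' @inheritParams mova_cv
#' @return A `mova_cv_result`.
#' @export
distance_as_feature_cv <- function(variants, profile,
                                   model_config = mova_config(),
                                   cv = cv_config()) {
  y <- variant_labels01(variants)
  feats <- featurize_variants(variants, profile)
  coords <- as.matrix(feats[, c("x", "y", "z")])
  scorer <- function(train, test, seed) {
    d <- fold_distance_feature(train, test, y, coords)
    xtr <- cbind(feats[train, , drop = FALSE], pathogenic_distance = d$train)
    xte <- cbind(feats[test, , drop = FALSE], pathogenic_distance = d$test)
    m <- fit_backend(xtr, y[train], model_config, seed)
    m(xte)
  }
  run_cv(y, scorer, cv)
}
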