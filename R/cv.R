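# Repeated stratified k-fold cross-validation, rank-based ROC/AUC,
# Youden-index cutoffs, and evaluation of precomputed score columns.

#' Cross-validation configuration
#'
#' @param k Number of folds (default 5).
#' @param repeats Number of independent repetitions of the whole k-fold split
#'   (default 5, i.e. 25 folds in total).
#' @param seed Master RNG seed; repeat `r` draws its fold assignment from
#'   `seed + r - 1`, and the fold model for repeat `r`, fold `f` is fitted
#'   with seed `seed + 1000 + (r - 1) * k + (f - 1)`.
#' @return A `cv_config` list.
#' @export
cv_config <- function(k = 5L, repeats = 5L, seed = 1L) {
  stopifnot(k >= 2L, repeats >= 1L)
  structure(list(k = as.integer(k), repeats = as.integer(repeats),
                 seed = as.integer(seed)), class = "cv_config")
}

#' Stratified fold assignment
#'
#' Partitions indices into `k` disjoint folds such that each class's members
#' are spread as evenly as possible: per-fold counts of each class differ by
#' at most 1, and per-fold total sizes differ by at most 1 (the remainder of
#' the larger class is assigned to the currently smallest folds).
#'
#' @param labels01 Integer 0/1 label vector.
#' @param k Number of folds.
#' @param seed RNG seed for the (random) assignment.
#' @return List of `k` integer index vectors covering `seq_along(labels01)`
#'   exactly once.
#' @export
stratified_folds <- function(labels01, k = 5L, seed = 1L) {
  n <- length(labels01)
  if (k < 2L || k > n) {
    stop(sprintf("k = %d must be between 2 and the number of records (%d)", k, n),
         call. = FALSE)
  }
  set.seed(seed)
  fold <- integer(n)
  # Majority class first, cyclically over a shuffled fold order; then the
  # other class cyclically over folds ordered by current load (ascending),
  # so overall fold sizes stay within 1 of each other.
  shuffle <- function(v) v[sample.int(length(v))]  # never the 1:n pitfall
  classes <- names(sort(table(labels01), decreasing = TRUE))
  order1 <- sample.int(k)
  idx1 <- shuffle(which(labels01 == as.integer(classes[1L])))
  fold[idx1] <- rep_len(order1, length(idx1))
  if (length(classes) > 1L) {
    load <- tabulate(fold, nbins = k)
    order2 <- order(load, sample.int(k))  # random tie-break among equal loads
    idx2 <- shuffle(which(labels01 == as.integer(classes[2L])))
    fold[idx2] <- rep_len(order2, length(idx2))
  }
  lapply(seq_len(k), function(f) which(fold == f))
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Rank statistic: the probability that a random positive outscores a random
#' negative, counting ties as 1/2 —
#' `(#\{score_pos > score_neg\} + 0.5 * #ties) / (n_pos * n_neg)`.
#'
#' @param scores Numeric scores, higher = more pathogenic.
#' @param labels01 Integer 0/1 labels.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels01) {
  stopifnot(length(scores) == length(labels01))
  npos <- sum(labels01 == 1L)
  nneg <- sum(labels01 == 0L)
  if (npos == 0L || nneg == 0L) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)  # average ranks handle ties as 1/2
  (sum(r[labels01 == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Youden-index cutoff
#'
#' Scans the observed scores as candidate thresholds under the classification
#' rule `score >= t` and returns the threshold maximising
#' J = sensitivity + specificity - 1; ties are broken toward the smallest
#' threshold.
#'
#' @inheritParams auc
#' @return The selected threshold.
#' @export
youden_cutoff <- function(scores, labels01) {
  stopifnot(length(scores) == length(labels01))
  pos <- scores[labels01 == 1L]
  neg <- scores[labels01 == 0L]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("Youden cutoff undefined: both classes must be present", call. = FALSE)
  }
  cand <- sort(unique(scores))
  # J = TP/n_pos + TN/n_neg - 1 is maximised exactly where the integer
  # TP * n_neg + TN * n_pos is, which keeps ties exact (no float noise)
  j_scaled <- vapply(cand, function(t) {
    sum(pos >= t) * length(neg) + sum(neg < t) * length(pos)
  }, numeric(1))
  cand[which.max(j_scaled)]  # first (= smallest) maximiser
}

# ROC step curve as (fpr, tpr) points at each distinct threshold, descending,
# starting at (0, 0) and ending at (1, 1).
roc_points <- function(scores, labels01) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels01[o]
  keep <- c(s[-length(s)] != s[-1L], TRUE)  # last index of each tied block
  tp <- cumsum(y)[keep]
  fp <- cumsum(1L - y)[keep]
  data.frame(fpr = c(0, fp / sum(labels01 == 0L)),
             tpr = c(0, tp / sum(labels01 == 1L)))
}

# Vertical averaging of per-fold ROC curves on a common FPR grid.
average_roc <- function(roc_list, grid = seq(0, 1, by = 0.01)) {
  tprs <- vapply(roc_list, function(rc) {
    stats::approx(rc$fpr, rc$tpr, xout = grid, method = "linear",
                  ties = max, rule = 2)$y
  }, numeric(length(grid)))
  data.frame(fpr = grid, tpr = rowMeans(tprs))
}

# Core engine shared by model CV, the distance baseline and score fusion.
# scorer(train_idx, test_idx, seed) returns held-out scores for test_idx
# (higher = more pathogenic); optionally carries attr "extra" collected
# per fold (e.g. fitted coefficients).
run_cv <- function(labels01, scorer, cv = cv_config()) {
  n <- length(labels01)
  npos <- sum(labels01 == 1L)
  nneg <- sum(labels01 == 0L)
  if (npos < cv$k || nneg < cv$k) {
    stop(sprintf(
      "stratified %d-fold CV needs at least %d members of each class (have %d positive, %d negative)",
      cv$k, cv$k, npos, nneg), call. = FALSE)
  }
  fold_auc <- matrix(NA_real_, cv$repeats, cv$k,
                     dimnames = list(paste0("repeat", seq_len(cv$repeats)),
                                     paste0("fold", seq_len(cv$k))))
  fold_cut <- fold_auc
  heldout <- matrix(NA_real_, cv$repeats, n)
  rocs <- vector("list", cv$repeats * cv$k)
  extras <- vector("list", cv$repeats * cv$k)
  for (r in seq_len(cv$repeats)) {
    folds <- stratified_folds(labels01, cv$k, seed = cv$seed + r - 1L)
    for (f in seq_len(cv$k)) {
      test <- folds[[f]]
      train <- setdiff(seq_len(n), test)
      s <- scorer(train, test,
                  seed = cv$seed + 1000L + (r - 1L) * cv$k + (f - 1L))
      i <- (r - 1L) * cv$k + f
      fold_auc[r, f] <- auc(s, labels01[test])
      fold_cut[r, f] <- youden_cutoff(s, labels01[test])
      rocs[[i]] <- roc_points(s, labels01[test])
      extras[[i]] <- attr(s, "extra")
      heldout[r, test] <- s
    }
  }
  structure(list(
    fold_auc = fold_auc,
    mean_auc = mean(fold_auc),
    mean_roc = average_roc(rocs),
    fivefold_mv = colMeans(heldout),
    cutoff = mean(fold_cut),
    fold_cutoffs = fold_cut,
    fold_extras = extras,
    cv = cv
  ), class = "mova_cv_result")
}

#' @export
print.mova_cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV x %d repeats: mean AUC %.3f (fold range %.3f-%.3f), Youden cutoff %.3f\n",
              x$cv$k, x$cv$repeats, x$mean_auc, min(x$fold_auc),
              max(x$fold_auc), x$cutoff))
  invisible(x)
}

#' Repeated stratified cross-validation of the structural classifier
#'
#' For each repeat, splits the labeled variants into `k` stratified folds;
#' for each fold, trains the classifier on the remaining folds and scores the
#' held-out fold. Reports per-fold AUCs, their arithmetic mean, the
#' vertically averaged ROC curve (101-point FPR grid), the mean Youden cutoff
#' over all folds, and each variant's mean held-out prediction across repeats
#' (the fivefold model value, "5F-MV").
#'
#' @param variants Labeled variant data.frame.
#' @param profile `StructureProfile`.
#' @param features Feature subset to train on (default all 5).
#' @param model_config [mova_config()].
#' @param cv [cv_config()].
#' @return A `mova_cv_result` list; see [run_cv()] fields.
#' @export
mova_cv <- function(variants, profile, features = MOVA_FEATURES,
                    model_config = mova_config(), cv = cv_config()) {
  bad <- setdiff(features, MOVA_FEATURES)
  if (length(bad) > 0L) {
    stop(sprintf("unknown feature name(s): %s (available: %s)",
                 paste(bad, collapse = ", "),
                 paste(MOVA_FEATURES, collapse = ", ")), call. = FALSE)
  }
  y <- variant_labels01(variants)
  feats <- featurize_variants(variants, profile)[, features, drop = FALSE]
  scorer <- function(train, test, seed) {
    m <- fit_backend(feats[train, , drop = FALSE], y[train], model_config, seed)
    m(feats[test, , drop = FALSE])
  }
  run_cv(y, scorer, cv)
}

#' ROC/AUC of a precomputed score column
#'
#' Evaluates an external score (e.g. REVEL, CADD) against the labels with no
#' training. Records missing the score are dropped with a message stating the
#' count; they are never imputed.
#'
#' @param variants Labeled variant data.frame carrying the score column.
#' @param column Name of the score column.
#' @return List with `auc`, `roc` (step-curve points), `cutoff` (Youden) and
#'   `n_used` / `n_dropped`.
#' @export
evaluate_score_column <- function(variants, column) {
  if (!column %in% names(variants)) {
    stop(sprintf("score column '%s' not present in the variant table", column),
         call. = FALSE)
  }
  s <- as.numeric(variants[[column]])
  keep <- !is.na(s)
  if (!any(keep)) {
    stop(sprintf("score column '%s' is missing on every record", column),
         call. = FALSE)
  }
  if (any(!keep)) {
    message(sprintf("evaluate_score_column: dropped %d record(s) missing '%s'",
                    sum(!keep), column))
  }
  y <- variant_labels01(variants[keep, , drop = FALSE])
  list(auc = auc(s[keep], y), roc = roc_points(s[keep], y),
       cutoff = youden_cutoff(s[keep], y),
       n_used = sum(keep), n_dropped = sum(!keep))
}

#' Spearman's rank correlation
#'
#' Pearson correlation of tie-averaged ranks, with explicit preconditions
#' (equal lengths of at least 3; no constant vector, for which rho is
#' undefined).
#'
#' @param xs,ys Numeric vectors.
#' @return Spearman's rho.
#' @export
spearman_rho <- function(xs, ys) {
  if (length(xs) != length(ys)) stop("length mismatch", call. = FALSE)
  if (length(xs) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    stop("rho undefined for a constant vector", call. = FALSE)
  }
  stats::cor(xs, ys, method = "spearman")
}
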