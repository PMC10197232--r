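# Per-gene random-forest classifier and the 30-run final ensemble.

#' Model configuration
#'
#' Pins the "default" random-forest settings explicitly so runs are
#' reproducible: 500 trees, `floor(sqrt(p))` candidate features per split
#' (p = 5 features gives 2), unlimited depth, no class weighting. The
#' positive-class score is the fraction of trees voting positive.
#'
#' @param n_trees Number of trees per forest.
#' @param n_final_runs Number of independently seeded full-data forests whose
#'   mean prediction is the final pathogenicity value.
#' @param backend `"rf"` (randomForest), or a fitting function
#'   `function(x, y01, seed)` returning a scorer `function(newx) -> prob`
#'   (used for stub backends in tests and for plugging in alternatives).
#' @return A `mova_config` list.
#' @export
mova_config <- function(n_trees = 500L, n_final_runs = 30L, backend = "rf") {
  stopifnot(n_trees >= 1L, n_final_runs >= 1L)
  if (!is.function(backend) && !identical(backend, "rf")) {
    stop(sprintf("unknown backend '%s' (available: \"rf\", or a fitting function)",
                 backend), call. = FALSE)
  }
  structure(list(n_trees = as.integer(n_trees),
                 n_final_runs = as.integer(n_final_runs),
                 backend = backend),
            class = "mova_config")
}

# Fit one classifier; returns function(newx) -> positive-class probability.
fit_backend <- function(x, y01, config, seed) {
  if (is.function(config$backend)) {
    return(config$backend(x, y01, seed))
  }
  if (all(vapply(x, function(col) length(unique(col)) == 1L, logical(1)))) {
    # no split is possible anywhere: every tree is a root node voting the
    # bootstrap class proportions, whose mean is the training class ratio
    ratio <- mean(y01)
    scorer <- function(newx) rep(ratio, nrow(newx))
    attr(scorer, "oob_prob") <- rep(ratio, nrow(x))
    return(scorer)
  }
  set.seed(seed)
  rf <- randomForest::randomForest(
    x = x, y = factor(y01, levels = c(0L, 1L)),
    ntree = config$n_trees, mtry = max(1L, floor(sqrt(ncol(x))))
  )
  scorer <- function(newx) {
    unname(stats::predict(rf, newx, type = "prob")[, "1"])
  }
  attr(scorer, "oob_prob") <- unname(rf$votes[, "1"])
  attr(scorer, "model") <- rf
  scorer
}

check_trainable <- function(features, labels01) {
  if (!is.data.frame(features) && !is.matrix(features)) {
    stop("'features' must be a data.frame or matrix", call. = FALSE)
  }
  if (nrow(features) == 0L) stop("empty training set", call. = FALSE)
  if (length(labels01) != nrow(features)) {
    stop("length(labels) must equal nrow(features)", call. = FALSE)
  }
  if (length(unique(labels01)) < 2L) {
    stop("training set contains a single class; need both positive and negative examples",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Train a pathogenicity classifier on feature vectors
#'
#' @param features data.frame of feature columns (rows = variants).
#' @param labels01 Integer 0/1 labels (1 = pathogenic).
#' @param config [mova_config()].
#' @param seed Integer RNG seed for the fit.
#' @return An object of class `mova_model` with `$predict_prob(newx)`
#'   returning the positive-class probability in \[0, 1\].
#' @export
mova_train <- function(features, labels01, config = mova_config(), seed = 1L) {
  check_trainable(features, labels01)
  scorer <- fit_backend(as.data.frame(features), as.integer(labels01), config, seed)
  structure(list(predict_prob = scorer, config = config, seed = seed,
                 features = colnames(features)),
            class = "mova_model")
}

# Every possible single-residue substitution of the profile: length x 20 rows.
all_substitutions <- function(profile) {
  r <- profile$residues
  data.frame(
    gene = profile$gene_id,
    position = rep(r$position, each = length(AA_CODES)),
    ref = rep(r$aa, each = length(AA_CODES)),
    alt = rep(AA_CODES, times = nrow(r)),
    label = "unlabeled",
    stringsAsFactors = FALSE
  )
}

#' Final ensemble score table for every possible substitution
#'
#' Fits `n_final_runs` independently seeded forests on the full labeled
#' dataset (seeds `seed, seed + 1, ...`), predicts the pathogenicity
#' probability of every (residue, alternate amino acid) pair of the protein,
#' and reports the mean prediction per substitution. Rows whose alternate
#' equals the reference residue are set to 0.
#'
#' @param variants Labeled variant data.frame (both classes required).
#' @param profile `StructureProfile` of the protein.
#' @param config [mova_config()]; `n_final_runs` controls the ensemble size.
#' @param seed Base RNG seed.
#' @return data.frame of class `mova_score_table` with columns `gene`,
#'   `position`, `ref`, `alt`, `mova_value` and exactly
#'   `nrow(profile$residues) * 20` rows, values in \[0, 1\].
#' @export
mova_score_table <- function(variants, profile, config = mova_config(),
                             seed = 1L) {
  y <- variant_labels01(variants)
  feats <- featurize_variants(variants, profile)
  check_trainable(feats, y)
  grid <- all_substitutions(profile)
  grid_feats <- featurize_variants(grid, profile)
  preds <- vapply(seq_len(config$n_final_runs) - 1L, function(i) {
    m <- fit_backend(feats, y, config, seed = seed + i)
    m(grid_feats)
  }, numeric(nrow(grid)))
  out <- data.frame(gene = grid$gene, position = grid$position,
                    ref = grid$ref, alt = grid$alt,
                    mova_value = rowMeans(preds),
                    stringsAsFactors = FALSE)
  out$mova_value[out$ref == out$alt] <- 0
  class(out) <- c("mova_score_table", "data.frame")
  out
}
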