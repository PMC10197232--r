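# Logistic-regression fusion of the structural classifier with an external
# missense score (REVEL/CADD style), evaluated under the same repeated
# stratified CV.

# One fold of the fusion: fit the forest on the training split, use its
# out-of-bag probabilities as the training-side classifier input (avoids
# optimistic resubstitution inputs to the logistic model), fit
# label ~ prob + external by maximum-likelihood logistic regression, and
# score the test split. On (quasi-)separation the ML fit is replaced by a
# ridge-stabilised logistic fit, with a message. Split out so that fitted
# coefficients can be examined independently of the CV loop.
fold_combine_fit <- function(train, test, labels01, feats, ext, model_config,
                             seed) {
  m <- fit_backend(feats[train, , drop = FALSE], labels01[train], model_config,
                   seed)
  prob_train <- attr(m, "oob_prob")
  if (is.null(prob_train)) prob_train <- m(feats[train, , drop = FALSE])
  dtr <- data.frame(y = labels01[train], prob = prob_train, ext = ext[train])
  dte <- data.frame(prob = m(feats[test, , drop = FALSE]), ext = ext[test])

  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ prob + ext, family = stats::binomial(), data = dtr),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (separated) {
    message("combine_cv: (quasi-)separation in the logistic fit; using a ridge-stabilised fit for this fold")
    xm <- as.matrix(dtr[, c("prob", "ext")])
    rf <- glmnet::glmnet(xm, dtr$y, family = "binomial", alpha = 0,
                         lambda = 1e-3, standardize = TRUE)
    coefs <- as.numeric(stats::coef(rf))
    scores <- as.numeric(stats::predict(rf, as.matrix(dte), type = "response"))
  } else {
    coefs <- unname(stats::coef(fit))
    scores <- unname(stats::predict(fit, dte, type = "response"))
  }
  names(coefs) <- c("intercept", "beta_prob", "beta_external")
  list(scores = scores, coefficients = coefs, ridge = separated)
}

#' Cross-validated fusion of the classifier with an external score
#'
#' Per fold: the random forest is fitted on the training split; a logistic
#' regression of the label on (out-of-bag forest probability, external score)
#' is fitted on the same training split; the held-out fold is scored by
#' passing its forest probabilities and external scores through the fitted
#' logistic model. AUC/ROC/cutoff machinery is shared with [mova_cv()].
#' Records missing the external score are dropped with a message.
#'
#' @inheritParams mova_cv
#' @param external Name of the external score column (e.g. `"REVEL"`).
#' @return A `mova_cv_result` with an extra `coefficients` matrix (one row
#'   per fold: intercept, beta_prob, beta_external) and `n_dropped`.
#' @export
combine_cv <- function(variants, profile, external,
                       model_config = mova_config(), cv = cv_config()) {
  if (!external %in% names(variants)) {
    stop(sprintf("external score column '%s' not present in the variant table",
                 external), call. = FALSE)
  }
  s <- as.numeric(variants[[external]])
  keep <- !is.na(s)
  if (!any(keep)) {
    stop(sprintf("external score column '%s' is missing on every record", external),
         call. = FALSE)
  }
  if (any(!keep)) {
    message(sprintf("combine_cv: dropped %d record(s) missing '%s'",
                    sum(!keep), external))
  }
  variants <- variants[keep, , drop = FALSE]
  ext <- s[keep]
  y <- variant_labels01(variants)
  feats <- featurize_variants(variants, profile)
  scorer <- function(train, test, seed) {
    fold <- fold_combine_fit(train, test, y, feats, ext, model_config, seed)
    structure(fold$scores,
              extra = list(coefficients = fold$coefficients, ridge = fold$ridge))
  }
  res <- run_cv(y, scorer, cv)
  res$coefficients <- do.call(rbind, lapply(res$fold_extras, `[[`, "coefficients"))
  res$n_dropped <- sum(!keep)
  res
}
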