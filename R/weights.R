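#' Pool cross-validation fold weights into one absolute weight per feature
#'
#' For each of the 48 features, averages the absolute value of its ridge
#' coefficients over all cross-validation folds and all time lags, yielding
#' a single non-negative contribution score per feature. Absolute values are
#' used so a feature counts equally whether it maps to an HFB increase or
#' decrease; `collapse = "max"` keeps the strongest lag instead of the mean.
#'
#' @param result an `encoding_result` with per-fold weights.
#' @param collapse how to collapse across lags: `"mean"` (default) or
#'   `"max"` of the fold-averaged absolute lag weights.
#' @return Named numeric vector of 48 pooled absolute weights.
#' @export
pool_fold_weights <- function(result, collapse = c("mean", "max")) {
  collapse <- match.arg(collapse)
  W <- result$fold_weights
  if (is.null(W)) stop_invalid("encoding result carries no fold weights")
  labels <- result$column_labels
  if (is.null(labels)) stop_invalid("encoding result carries no column labels")
  absw <- colMeans(abs(W))          # over folds
  feats <- unique(labels$feature)
  pooled <- vapply(feats, function(f) {
    v <- absw[labels$feature == f]
    if (collapse == "mean") mean(v) else max(v)
  }, numeric(1))
  names(pooled) <- feats
  pooled
}

#' Average pooled weights over the complex and basic emotion sets
#'
#' @param profile named pooled-weight vector from [pool_fold_weights()].
#' @param feature_set an [emotion_feature_set()].
#' @return List: `complex_mean` (guilt, embarrassment, pride, envy),
#'   `basic_mean` (joy, sadness, fear, anger, disgust, surprise).
#' @export
aggregate_emotion_classes <- function(profile, feature_set = emotion_feature_set()) {
  missing <- setdiff(c(feature_set$complex_set, feature_set$basic_set),
                     names(profile))
  if (length(missing))
    stop_invalid("profile is missing features: ", paste(missing, collapse = ", "))
  list(complex_mean = mean(profile[feature_set$complex_set]),
       basic_mean = mean(profile[feature_set$basic_set]))
}

#' Keep only participants whose encoding accuracy is significant
#'
#' The weight-age analysis includes a participant if and only if the
#' permutation p-value of their prediction accuracy is below `alpha`.
#'
#' @param profiles list of per-participant profiles (each a list with at
#'   least `weights` and `age`).
#' @param p_values numeric, matched to `profiles`.
#' @param alpha inclusion threshold (default 0.05).
#' @return The included subset of `profiles`.
#' @export
filter_significant_profiles <- function(profiles, p_values, alpha = 0.05) {
  if (length(profiles) != length(p_values))
    stop_invalid("one p-value per profile is required")
  profiles[p_values < alpha]
}

#' Correlate encoding weights with age across participants
#'
#' For each feature, the Pearson correlation between participants' pooled
#' absolute weight and their age, with two-sided p-values (uncorrected for
#' the 48 tests); features are ranked by r from largest to smallest. The
#' complex and basic aggregates are correlated with age on the aggregated
#' weights (not by averaging per-feature correlations).
#'
#' @param profiles list of participant profiles, each a list with `weights`
#'   (named 48-vector), `age`, and optionally `id`.
#' @param feature_set an [emotion_feature_set()].
#' @return List of class `weight_age_result`: `table` (`data.frame` with
#'   `feature`, `r`, `p`, `class`, ranked by `r` descending; zero-variance
#'   features are dropped from the ranking with a warning), `complex_r`,
#'   `complex_p`, `basic_r`, `basic_p`, `n`.
#' @export
weight_age_correlation <- function(profiles, feature_set = emotion_feature_set()) {
  if (length(profiles) < 3L)
    stop_invalid("need at least three participants")
  ages <- vapply(profiles, function(p) p$age, numeric(1))
  if (length(unique(ages)) < 2L)
    stop_invalid("degenerate input: ages are constant")
  W <- do.call(rbind, lapply(profiles, function(p)
    p$weights[feature_set$names]))
  agg <- t(vapply(profiles, function(p) {
    a <- aggregate_emotion_classes(p$weights, feature_set)
    c(a$complex_mean, a$basic_mean)
  }, numeric(2)))
  per_feature <- lapply(feature_set$names, function(f) {
    w <- W[, f]
    if (stats::sd(w) == 0) return(NULL)
    ct <- stats::cor.test(w, ages)
    data.frame(feature = f, r = unname(ct$estimate), p = ct$p.value)
  })
  dropped <- vapply(per_feature, is.null, logical(1))
  if (any(dropped))
    warning(sum(dropped), " zero-variance feature(s) excluded from ranking")
  tab <- do.call(rbind, per_feature[!dropped])
  if (is.null(tab) || nrow(tab) == 0L)
    stop_invalid("no feature has weight variance across participants")
  tab$class <- ifelse(tab$feature %in% feature_set$complex_set, "complex",
                      ifelse(tab$feature %in% feature_set$basic_set, "basic",
                             "other"))
  tab <- tab[order(-tab$r), ]
  rownames(tab) <- NULL
  cx <- stats::cor.test(agg[, 1L], ages)
  bs <- stats::cor.test(agg[, 2L], ages)
  out <- list(table = tab,
              complex_r = unname(cx$estimate), complex_p = cx$p.value,
              basic_r = unname(bs$estimate), basic_p = bs$p.value,
              n = length(profiles))
  class(out) <- "weight_age_result"
  out
}
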