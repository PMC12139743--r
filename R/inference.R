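t_result <- function(ht) {
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

check_variance <- function(x, what) {
  if (length(x) < 2L) stop_invalid(what, " needs at least two values")
  if (stats::sd(x) == 0)
    stop_invalid("degenerate input: ", what, " has zero variance")
}

#' One-sample t test of prediction accuracies against zero
#'
#' Tests whether a group's encoding-model accuracies (one r per participant)
#' are significantly greater than zero, reported two-sided with `df = n - 1`.
#'
#' @param x numeric vector of per-participant accuracies.
#' @param mu null value (default 0).
#' @return List: `t`, `df`, `p` (two-sided).
#' @export
one_sample_t <- function(x, mu = 0) {
  check_variance(x, "sample")
  t_result(stats::t.test(x, mu = mu))
}

#' Paired t test between conditions
#'
#' Two-sided paired t test of per-participant accuracy differences (e.g.
#' speech vs music), `df = n - 1`.
#'
#' @param x,y matched numeric vectors.
#' @return List: `t`, `df`, `p`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("paired samples must match in length")
  check_variance(x - y, "paired differences")
  t_result(stats::t.test(x, y, paired = TRUE))
}

#' Unpaired two-sample t test between groups
#'
#' Student (equal-variance) two-sample t test, two-sided.
#'
#' @param a,b numeric vectors (childhood / post-childhood accuracies).
#' @return List: `t`, `df`, `p`.
#' @export
unpaired_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop_invalid("both groups need at least two values")
  if (stats::sd(c(a - mean(a), b - mean(b))) == 0)
    stop_invalid("degenerate input: zero pooled variance")
  t_result(stats::t.test(a, b, var.equal = TRUE))
}

#' Voice effect on encoding accuracy
#'
#' The voice effect is each participant's accuracy difference between the
#' speech and music conditions; groups are compared on these differences
#' with an unpaired t test.
#'
#' @param r_speech,r_music per-participant accuracies, matched order.
#' @param group factor/character of group labels (two levels) — optional; if
#'   omitted only the differences are returned.
#' @return List: `difference` (per participant), and, when `group` is given,
#'   `contrast` (the unpaired test) plus `group_means`.
#' @export
voice_effect <- function(r_speech, r_music, group = NULL) {
  if (length(r_speech) != length(r_music))
    stop_invalid("conditions must be matched per participant")
  d <- r_speech - r_music
  out <- list(difference = d)
  if (!is.null(group)) {
    lev <- unique(group)
    if (length(lev) != 2L) stop_invalid("group must have exactly two levels")
    out$contrast <- unpaired_t(d[group == lev[1L]], d[group == lev[2L]])
    out$group_means <- stats::setNames(
      c(mean(d[group == lev[1L]]), mean(d[group == lev[2L]])), lev)
  }
  out
}

# Permute feature time bins jointly across the 48 features. unit = "bin":
# uniform permutation of all bins (within each condition group); unit =
# "circular": independent circular shift within each block — a stricter
# null under temporal autocorrelation.
shuffle_features <- function(features, unit = c("bin", "circular"),
                             condition_of_block = NULL) {
  unit <- match.arg(unit)
  if (unit == "circular") {
    return(lapply(features, function(x) {
      s <- sample.int(nrow(x), 1L) - 1L
      if (s == 0L) x else x[c((s + 1L):nrow(x), 1L:s), , drop = FALSE]
    }))
  }
  n_per <- vapply(features, nrow, integer(1))
  grp <- if (is.null(condition_of_block)) rep("all", length(features))
         else condition_of_block
  stacked <- do.call(rbind, features)
  row_grp <- rep(grp, n_per)
  perm <- seq_len(nrow(stacked))
  for (g in unique(row_grp)) {
    idx <- which(row_grp == g)
    perm[idx] <- idx[sample.int(length(idx))]
  }
  stacked <- stacked[perm, , drop = FALSE]
  ends <- cumsum(n_per)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out <- Map(function(s, e) stacked[s:e, , drop = FALSE], starts, ends)
  names(out) <- names(features)
  out
}

#' Temporal-shuffle permutation test of encoding accuracy
#'
#' Builds a null distribution for the cross-validated prediction accuracy by
#' shuffling the feature time bins (jointly across all 48 features,
#' preserving their cross-feature structure) and re-running the full design
#' + cross-validation analysis for each shuffle. The two-tailed p-value is
#' `(#\{|null| >= |observed|\} + 1) / (n_perm + 1)`; the +1 guards the
#' small-sample floor so p is never exactly 0.
#'
#' @param features named list of per-block feature matrices.
#' @param binned `[n_bins x n_contacts]` binned HFB response matrix aligned
#'   with the stacked feature rows.
#' @param lambda ridge penalty (e.g. the globally selected one).
#' @param lags lags in seconds.
#' @param fs_feat feature rate in Hz.
#' @param n_perm number of shuffles (default 5000).
#' @param k_folds folds (default 5).
#' @param unit `"bin"` (uniform bin shuffle, default) or `"circular"`
#'   (per-block circular shifts).
#' @param condition_of_block optional condition label per block; bins are
#'   then only permuted within condition.
#' @param seed integer seed.
#' @return List of class `permutation_result`: `observed_r`, `null_r`
#'   (length `n_perm`), `p_two_tailed`, `n_perm`.
#' @export
permutation_test <- function(features, binned, lambda, lags = c(0, 0.5, 1),
                             fs_feat = 2, n_perm = 5000, k_folds = 5,
                             unit = c("bin", "circular"),
                             condition_of_block = NULL, seed = 1) {
  unit <- match.arg(unit)
  if (n_perm < 1) stop_invalid("n_perm must be >= 1")
  eval_one <- function(feats) {
    X <- build_lagged_design(feats, lags, fs_feat)
    cc <- concatenate_contacts(binned, X)
    suppressWarnings(
      cv_evaluate(cc$X, cc$y, lambda, block_of_row = cc$block_of_row,
                  k_folds = k_folds, keep_weights = FALSE)$mean_r)
  }
  observed <- eval_one(features)
  null_r <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    eval_one(shuffle_features(features, unit, condition_of_block)),
    numeric(1)))
  p <- (sum(abs(null_r) >= abs(observed)) + 1) / (n_perm + 1)
  out <- list(observed_r = observed, null_r = null_r, p_two_tailed = p,
              n_perm = n_perm)
  class(out) <- "permutation_result"
  out
}

#' Group-level permutation test
#'
#' Same temporal shuffle, applied simultaneously to every participant's
#' dataset; each iteration's null statistic is the across-participant mean
#' accuracy, testing whether a group's mean accuracy exceeds chance.
#'
#' @param datasets list of per-participant lists with elements `features`
#'   and `binned` (as in [permutation_test()]).
#' @inheritParams permutation_test
#' @return A `permutation_result` for the group-mean accuracy.
#' @export
group_permutation_test <- function(datasets, lambda, lags = c(0, 0.5, 1),
                                   fs_feat = 2, n_perm = 5000, k_folds = 5,
                                   unit = c("bin", "circular"),
                                   condition_of_block = NULL, seed = 1) {
  unit <- match.arg(unit)
  if (n_perm < 1) stop_invalid("n_perm must be >= 1")
  eval_mean <- function(shuffle) {
    mean(vapply(datasets, function(d) {
      feats <- if (shuffle) shuffle_features(d$features, unit,
                                             condition_of_block)
               else d$features
      X <- build_lagged_design(feats, lags, fs_feat)
      cc <- concatenate_contacts(d$binned, X)
      suppressWarnings(
        cv_evaluate(cc$X, cc$y, lambda, block_of_row = cc$block_of_row,
                    k_folds = k_folds, keep_weights = FALSE)$mean_r)
    }, numeric(1)))
  }
  observed <- eval_mean(FALSE)
  null_r <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    eval_mean(TRUE), numeric(1)))
  p <- (sum(abs(null_r) >= abs(observed)) + 1) / (n_perm + 1)
  out <- list(observed_r = observed, null_r = null_r, p_two_tailed = p,
              n_perm = n_perm)
  class(out) <- "permutation_result"
  out
}
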