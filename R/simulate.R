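#' Generate a movie-like block schedule
#'
#' Builds an ordered schedule of contiguous stimulus blocks alternating
#' between speech and music, emulating the structure of a naturalistic short
#' film cut into 30 s segments. Under the default movie layout (13 or more
#' blocks starting with music) the fifth music block is flagged
#' feature-absent: it contains no faces, so no facial-emotion features exist
#' for it and it contributes no rows to any design matrix.
#'
#' @param n_blocks number of blocks (>= 2).
#' @param block_dur block duration in seconds (> 0).
#' @param seed integer seed; controls the starting condition when
#'   `movie_layout = FALSE`.
#' @param movie_layout if `TRUE` (default when `n_blocks >= 13`) the schedule
#'   starts with music — giving 7 music + 6 speech blocks at 13 — and flags
#'   the fifth music block feature-absent. If `FALSE`, the starting condition
#'   is drawn from the seed and no block is flagged.
#' @param first_onset onset of the first block in seconds (default 10, leaving
#'   pre-stimulus room for baseline windows).
#' @return A `data.frame` with columns `onset`, `duration`, `trial_type`
#'   (`"speech"`/`"music"`), `block_index`, `features_present`.
#' @export
generate_block_schedule <- function(n_blocks = 13, block_dur = 30, seed = 1,
                                    movie_layout = n_blocks >= 13,
                                    first_onset = 10) {
  if (n_blocks < 2) stop_invalid("n_blocks must be >= 2")
  if (block_dur <= 0) stop_invalid("block duration must be positive")
  start <- if (movie_layout) "music" else
    with_seed(seed, sample(c("music", "speech"), 1L))
  conds <- rep(c(start, setdiff(c("music", "speech"), start)),
               length.out = n_blocks)
  onsets <- first_onset + (seq_len(n_blocks) - 1L) * block_dur
  sched <- data.frame(
    onset = onsets,
    duration = rep(block_dur, n_blocks),
    trial_type = conds,
    block_index = seq_len(n_blocks),
    features_present = TRUE,
    stringsAsFactors = FALSE
  )
  if (movie_layout) {
    music_idx <- which(sched$trial_type == "music")
    if (length(music_idx) >= 5L)
      sched$features_present[music_idx[5L]] <- FALSE
  }
  sched
}

#' Generate smooth bounded facial-emotion feature timecourses
#'
#' For every feature-present block, draws 48 smooth timecourses bounded in
#' (0, 1) on the feature sampling grid, emulating per-frame facial-expression
#' scores after aggregation and 2 Hz resampling. Each trace is Gaussian noise
#' smoothed with a kernel of width `smoothness` seconds, standardized, and
#' mapped through the normal CDF — smooth, exactly bounded, and with
#' autocorrelation length set by `smoothness`.
#'
#' @param schedule block schedule from [generate_block_schedule()].
#' @param fs_feat feature sampling rate in Hz (default 2).
#' @param smoothness autocorrelation length in seconds (default 2).
#' @param seed integer seed.
#' @param feature_set an [emotion_feature_set()].
#' @return Named list (one element per feature-present block, named by block
#'   index) of `[n_samples x 48]` matrices with feature-name columns.
#' @export
generate_feature_timecourses <- function(schedule, fs_feat = 2, smoothness = 2,
                                         seed = 1,
                                         feature_set = emotion_feature_set()) {
  if (fs_feat <= 0) stop_invalid("fs_feat must be positive")
  validate_feature_set(feature_set)
  blocks <- schedule[schedule$features_present, , drop = FALSE]
  sd_samp <- smoothness * fs_feat
  with_seed(seed, {
    out <- lapply(seq_len(nrow(blocks)), function(i) {
      n <- round(blocks$duration[i] * fs_feat)
      m <- vapply(seq_len(48L), function(f) {
        z <- gauss_smooth(stats::rnorm(n), sd_samp)
        s <- stats::sd(z)
        if (s == 0) z[] <- 0 else z <- (z - mean(z)) / s
        stats::pnorm(z)
      }, numeric(n))
      colnames(m) <- feature_set$names
      m
    })
    names(out) <- as.character(blocks$block_index)
    out
  })
}

#' Ground-truth encoding weights for simulation
#'
#' Draws a `[48 x n_lags]` weight matrix used as the generative truth of the
#' forward model. Complex-emotion rows are drawn non-negative so that an
#' age-dependent increment added to them grows their absolute weight
#' monotonically across a cohort.
#'
#' Two truth structures are available. The default draws every coefficient
#' independently (`lag_coherent = FALSE`). With `lag_coherent = TRUE` each
#' feature gets one overall effect size (exponentially distributed across
#' features, so a few features dominate — sparse tuning) and one sign shared
#' by all its lags, modulated by a smooth positive lag profile. That is the
#' more physiological structure: a feature that raises broadband amplitude at
#' lag 0 does not flip to suppressing it half a second later, and its
#' response decays smoothly over the lag window rather than jumping sign to
#' sign.
#'
#' @param feature_set an [emotion_feature_set()].
#' @param n_lags number of lag columns (default 3).
#' @param weight_sd scale of the weight draws: the per-coefficient standard
#'   deviation when `lag_coherent = FALSE`, the mean per-feature effect size
#'   when `lag_coherent = TRUE`.
#' @param noise_sd standard deviation of additive Gaussian noise on the
#'   binned response, in z-units (>= 0).
#' @param seed integer seed.
#' @param lag_coherent if `TRUE`, draw sign-coherent per-feature lag profiles
#'   with heterogeneous effect sizes instead of independent coefficients.
#' @return List of class `ground_truth`: `weights` (rownames = features),
#'   `noise_sd`, `seed`.
#' @export
generate_ground_truth <- function(feature_set = emotion_feature_set(),
                                  n_lags = 3, weight_sd = 1, noise_sd = 1,
                                  seed = 1, lag_coherent = FALSE) {
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  validate_feature_set(feature_set)
  w <- with_seed(seed, {
    if (lag_coherent) {
      scale_f <- stats::rexp(48L, rate = 1 / weight_sd)
      sign_f <- sample(c(-1, 1), 48L, replace = TRUE)
      profile <- matrix(stats::runif(48L * n_lags, 0.5, 1), 48L, n_lags)
      scale_f * sign_f * profile
    } else {
      matrix(stats::rnorm(48L * n_lags, sd = weight_sd),
             nrow = 48L, ncol = n_lags)
    }
  })
  rownames(w) <- feature_set$names
  cx <- rownames(w) %in% feature_set$complex_set
  w[cx, ] <- abs(w[cx, ])
  out <- list(weights = w, noise_sd = noise_sd, seed = seed)
  class(out) <- "ground_truth"
  out
}

#' Forward model: binned HFB response from features and true weights
#'
#' Computes `y(t) = sum_f sum_l w[f, l] * x_f(t - lag_l) + eps` on the feature
#' grid, per block. Lagged samples falling before a block's start are zero —
#' blocks are separate epochs and are never convolved across their
#' boundaries.
#'
#' @param features named list of `[n x 48]` feature matrices per block.
#' @param truth a `ground_truth` object (or any list with `weights`,
#'   `noise_sd`).
#' @param lags lag values in seconds; length must match `ncol(truth$weights)`.
#' @param fs_feat feature sampling rate in Hz.
#' @param seed seed for the noise draw (`NULL` = use current RNG stream).
#' @return Named list of numeric response vectors, one per block.
#' @export
synthesize_binned_hfb <- function(features, truth, lags = c(0, 0.5, 1),
                                  fs_feat = 2, seed = NULL) {
  if (length(lags) != ncol(truth$weights))
    stop_invalid("length(lags) must equal ncol(truth$weights)")
  if (!all(is.finite(truth$weights)))
    stop_invalid("ground-truth weights must be finite")
  gen <- function() {
    lapply(features, function(x) {
      X <- lag_stack(x, lags, fs_feat)
      y <- as.numeric(X %*% matrix(lag_major_weights(truth$weights), ncol = 1L))
      if (truth$noise_sd > 0)
        y <- y + stats::rnorm(length(y), sd = truth$noise_sd)
      y
    })
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# weights stored [feature x lag]; design columns are lag-major
# (lag0 f1..f48, lag1 f1..f48, ...), so flatten lag by lag.
lag_major_weights <- function(w) as.numeric(w)
# as.numeric of a matrix is column-major = all features for lag 1, then lag 2:
# exactly the lag-major design order.

# Zero-padded within-block lagging of a [n x 48] feature block.
lag_stack <- function(x, lags, fs_feat) {
  n <- nrow(x)
  do.call(cbind, lapply(lags, function(l) {
    s <- round(l * fs_feat)
    if (s == 0) return(x)
    rbind(matrix(0, s, ncol(x)), x[seq_len(n - s), , drop = FALSE])
  }))
}

#' Synthesize a raw multichannel recording carrying a known HFB envelope
#'
#' Inverts the preprocessing chain for testing: each contact's trace is
#' band-limited noise in `carrier_band` whose amplitude is modulated by the
#' squared target envelope (the chain square-root-transforms the extracted
#' amplitude, so squaring here makes the chain recover the target up to an
#' affine map). The target is the per-block binned series, linearly
#' interpolated to the raw grid on top of a constant resting level; outside
#' blocks the resting level alone drives the carrier, providing baseline
#' samples for the -0.2 to 0 s windows.
#'
#' @param binned_hfb list of per-block target series (one element per
#'   feature-present block of `schedule`), or a list of such lists — one per
#'   contact.
#' @param schedule block schedule; targets map onto its feature-present
#'   blocks in order.
#' @param fs_raw raw sampling rate in Hz (default 1000; must exceed twice the
#'   carrier band's upper edge).
#' @param carrier_band band of the noise carrier in Hz (default 110-140).
#' @param gain scaling from target units to envelope units.
#' @param base_level resting envelope level (> 0 keeps baseline variance
#'   positive).
#' @param line_amp amplitude of an additive 50 Hz line component (default 0).
#' @param pink_sd standard deviation of additive broadband 1/f noise
#'   (default 0).
#' @param fs_target sampling rate of the binned targets in Hz (default 2).
#' @param seed integer seed.
#' @return A [recording_session()] covering all blocks plus padding.
#' @export
synthesize_raw_signal <- function(binned_hfb, schedule, fs_raw = 1000,
                                  carrier_band = c(110, 140), gain = 0.2,
                                  base_level = 1, line_amp = 0, pink_sd = 0,
                                  fs_target = 2, seed = 1) {
  if (fs_raw < 2 * max(carrier_band))
    stop_invalid("fs_raw violates the Nyquist limit for the carrier band")
  per_contact <- is.list(binned_hfb[[1L]])
  contacts <- if (per_contact) binned_hfb else list(binned_hfb)
  fp <- schedule[schedule$features_present, , drop = FALSE]
  if (length(contacts[[1L]]) != nrow(fp))
    stop_invalid("binned_hfb must have one series per feature-present block")
  total_dur <- max(schedule$onset + schedule$duration) + 2
  n <- round(total_dur * fs_raw)
  t_raw <- (seq_len(n) - 1L) / fs_raw
  bf <- signal::butter(4, carrier_band / (fs_raw / 2), type = "pass")
  with_seed(seed, {
    sig <- vapply(contacts, function(targets) {
      env <- rep(0, n)
      for (i in seq_len(nrow(fp))) {
        y <- targets[[i]]
        tt <- fp$onset[i] + (seq_along(y) - 0.5) / fs_target
        idx <- which(t_raw >= fp$onset[i] & t_raw < fp$onset[i] + fp$duration[i])
        env[idx] <- stats::approx(tt, y, xout = t_raw[idx], rule = 2)$y
      }
      amp <- (base_level + gain * env)^2
      carrier <- signal::filtfilt(bf, stats::rnorm(n))
      carrier <- carrier / stats::sd(carrier)
      x <- carrier * amp
      if (line_amp > 0) x <- x + line_amp * sin(2 * pi * 50 * t_raw)
      if (pink_sd > 0) x <- x + pink_noise(n, pink_sd)
      x
    }, numeric(n))
    recording_session(t(sig), fs = fs_raw,
                      channel_names = paste0("ch", seq_along(contacts)))
  })
}

# Approximate 1/f noise via cumulative-sum-filtered white noise, rescaled.
pink_noise <- function(n, sd) {
  w <- stats::rnorm(n)
  sp <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)
  sp <- sp / sqrt(f)
  x <- Re(stats::fft(sp, inverse = TRUE)) / n
  sd * x / stats::sd(x)
}

#' Cohort specification for the synthetic study
#'
#' @param participants `data.frame` with columns `id`, `age` (years), `group`
#'   (`"childhood"` ages 5-10, `"post_childhood"` ages 13-55), `dlpfc`,
#'   `pstc` (logical area coverage), `n_contacts` (per covered area, >= 4).
#' @param complex_age_slope weight increment per year of age added to
#'   complex-emotion features (all lags).
#' @param music_weight_scale named numeric of per-group multipliers applied
#'   to the generative weights in the music condition (default 1 for both
#'   groups) — a knob for voice-modulated encoding.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(participants, complex_age_slope = 0,
                        music_weight_scale = c(childhood = 1,
                                               post_childhood = 1)) {
  req <- c("id", "age", "group", "dlpfc", "pstc", "n_contacts")
  if (!all(req %in% names(participants)))
    stop_invalid("participants must have columns: ", paste(req, collapse = ", "))
  if (nrow(participants) == 0L) stop_invalid("cohort must be non-empty")
  ch <- participants$group == "childhood"
  if (any(participants$age[ch] < 5 | participants$age[ch] > 10))
    stop_invalid("childhood ages must lie in [5, 10]")
  if (any(participants$age[!ch] < 13 | participants$age[!ch] > 55))
    stop_invalid("post-childhood ages must lie in [13, 55]")
  if (any(participants$n_contacts < 4))
    stop_invalid("each covered area needs at least four contacts")
  out <- list(participants = participants,
              complex_age_slope = complex_age_slope,
              music_weight_scale = music_weight_scale)
  class(out) <- "cohort_spec"
  out
}

#' Default synthetic cohort layout
#'
#' Eleven children (ages 5-10) and thirty-one post-childhood individuals
#' (ages 13-55). Area coverage mirrors the study's distribution: 8 childhood
#' DLPFC and 4 childhood pSTC (one child carrying both), 13 post-childhood
#' DLPFC and 25 post-childhood pSTC (seven carrying both).
#'
#' @param n_contacts contacts per covered area (default 4).
#' @param complex_age_slope passed to [cohort_spec()].
#' @param music_weight_scale passed to [cohort_spec()].
#' @param seed seed for the age draws.
#' @return A `cohort_spec`.
#' @export
default_cohort_spec <- function(n_contacts = 4, complex_age_slope = 0.05,
                                music_weight_scale = c(childhood = 1,
                                                       post_childhood = 1),
                                seed = 1) {
  with_seed(seed, {
    age_ch <- round(stats::runif(11, 5, 10), 1)
    age_po <- round(stats::runif(31, 13, 55), 1)
  })
  participants <- data.frame(
    id = sprintf("S%02d", 1:42),
    age = c(age_ch, age_po),
    group = rep(c("childhood", "post_childhood"), c(11, 31)),
    dlpfc = c(rep(c(TRUE, FALSE), c(8, 3)), rep(c(TRUE, FALSE), c(13, 18))),
    pstc = c(rep(c(FALSE, TRUE), c(7, 4)), rep(c(FALSE, TRUE), c(6, 25))),
    n_contacts = n_contacts,
    stringsAsFactors = FALSE
  )
  cohort_spec(participants, complex_age_slope = complex_age_slope,
              music_weight_scale = music_weight_scale)
}

#' Generate a synthetic cohort of binned HFB datasets with known truth
#'
#' Every participant watches the same simulated movie (shared schedule and
#' feature timecourses). Per covered area, each contact's binned HFB response
#' follows the linear forward model under participant-specific true weights
#' plus independent Gaussian noise:
#' * complex-emotion weights grow linearly with age:
#'   `w_complex(age) = w_base + complex_age_slope * (age - min cohort age)`;
#' * childhood DLPFC weights are zero (facial-emotion features are not
#'   encoded there), giving the group-difference machinery a known null;
#' * in the music condition weights are scaled by the group's
#'   `music_weight_scale`.
#'
#' @param spec a [cohort_spec()].
#' @param base_truth a `ground_truth` (default drawn from `seed`).
#' @param seed integer master seed.
#' @param lags lags in seconds.
#' @param fs_feat feature rate in Hz.
#' @param feature_set an [emotion_feature_set()].
#' @param smoothness feature smoothness in seconds.
#' @return List of class `synthetic_cohort`: `metadata` (one row per
#'   participant: id, age, group, areas, contact counts), `schedule`,
#'   `features` (per-block matrices), `data` (per participant, per area:
#'   `[n_bins_total x n_contacts]` binned response matrix over all
#'   feature-present blocks), `truth` (per participant per area true weight
#'   matrices), `bins` (block index and condition of each response row),
#'   `spec`, `lags`.
#' @export
generate_cohort <- function(spec, base_truth = NULL, seed = 1,
                            lags = c(0, 0.5, 1), fs_feat = 2,
                            feature_set = emotion_feature_set(),
                            smoothness = 2) {
  if (!inherits(spec, "cohort_spec")) stop_invalid("spec must be a cohort_spec")
  if (is.null(base_truth))
    base_truth <- generate_ground_truth(feature_set, n_lags = length(lags),
                                        weight_sd = 0.15, noise_sd = 1,
                                        seed = seed)
  schedule <- generate_block_schedule(13, 30, seed = seed)
  features <- generate_feature_timecourses(schedule, fs_feat, smoothness,
                                           seed = seed,
                                           feature_set = feature_set)
  fp <- schedule[schedule$features_present, , drop = FALSE]
  bins <- data.frame(
    block_index = rep(fp$block_index, vapply(features, nrow, 1L)),
    condition = rep(fp$trial_type, vapply(features, nrow, 1L)),
    stringsAsFactors = FALSE
  )
  pp <- spec$participants
  min_age <- min(pp$age)
  cx <- rownames(base_truth$weights) %in% feature_set$complex_set
  with_seed(seed, {
    data <- list(); truth <- list()
    for (i in seq_len(nrow(pp))) {
      pid <- pp$id[i]
      w_p <- base_truth$weights
      w_p[cx, ] <- w_p[cx, ] + spec$complex_age_slope * (pp$age[i] - min_age)
      areas <- c("DLPFC", "pSTC")[c(pp$dlpfc[i], pp$pstc[i])]
      data[[pid]] <- list(); truth[[pid]] <- list()
      for (area in areas) {
        w <- w_p
        if (area == "DLPFC" && pp$group[i] == "childhood") w[] <- 0
        mscale <- spec$music_weight_scale[[pp$group[i]]]
        truth_area <- w
        y_mat <- vapply(seq_len(pp$n_contacts[i]), function(k) {
          unlist(lapply(seq_len(nrow(fp)), function(b) {
            wb <- if (fp$trial_type[b] == "music") w * mscale else w
            X <- lag_stack(features[[b]], lags, fs_feat)
            as.numeric(X %*% lag_major_weights(wb)) +
              stats::rnorm(nrow(X), sd = base_truth$noise_sd)
          }), use.names = FALSE)
        }, numeric(nrow(bins)))
        colnames(y_mat) <- sprintf("%s_%s_c%d", pid, area,
                                   seq_len(pp$n_contacts[i]))
        data[[pid]][[area]] <- y_mat
        truth[[pid]][[area]] <- truth_area
      }
    }
    metadata <- data.frame(
      id = pp$id, age = pp$age, group = pp$group,
      n_contacts_dlpfc = ifelse(pp$dlpfc, pp$n_contacts, 0L),
      n_contacts_pstc = ifelse(pp$pstc, pp$n_contacts, 0L),
      stringsAsFactors = FALSE
    )
    out <- list(metadata = metadata, schedule = schedule, features = features,
                data = data, truth = truth, bins = bins, spec = spec,
                lags = lags, base_truth = base_truth)
    class(out) <- "synthetic_cohort"
    out
  })
}
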