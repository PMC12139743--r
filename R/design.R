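#' Collapse per-face scores to per-frame features by maximum
#'
#' Naturalistic frames can contain several faces; each frame's feature value
#' is the maximum score over all faces detected in it. Frames listed with no
#' face rows score 0 on every feature (no facial emotion present).
#'
#' @param face_table `data.frame` with columns `time_s`, `face_id`, and one
#'   column per feature; `face_id = NA` marks a faceless frame.
#' @param feature_names the 48 feature labels expected as columns.
#' @return List: `times` (sorted unique frame times), `features`
#'   `[n_frames x 48]` matrix.
#' @export
max_over_faces <- function(face_table, feature_names = emotion_feature_set()$names) {
  missing <- setdiff(feature_names, names(face_table))
  if (length(missing))
    stop_invalid("face table is missing feature columns: ",
                 paste(utils::head(missing, 3), collapse = ", "))
  scores <- as.matrix(face_table[, feature_names, drop = FALSE])
  faceless <- is.na(face_table$face_id)
  if (any(!faceless & (scores < 0 | scores > 1), na.rm = TRUE))
    stop_invalid("feature scores must lie in [0, 1]")
  times <- sort(unique(face_table$time_s))
  out <- matrix(0, length(times), length(feature_names),
                dimnames = list(NULL, feature_names))
  for (i in seq_along(times)) {
    rows <- which(face_table$time_s == times[i] & !faceless)
    if (length(rows))
      out[i, ] <- apply(scores[rows, , drop = FALSE], 2L, max)
  }
  list(times = times, features = out)
}

#' Resample per-frame features onto the 2 Hz analysis grid
#'
#' Averages all frames falling in each half-open 0.5 s bin
#' `[t0 + k/fs, t0 + (k+1)/fs)` of a block. Bins with no frames (face-
#' detection gaps) score 0, consistent with the faceless-frame convention.
#'
#' @param features `[n_frames x 48]` per-frame matrix.
#' @param frame_times frame timestamps in seconds (increasing).
#' @param t_start block onset in seconds.
#' @param duration block duration in seconds.
#' @param fs_feat output rate in Hz (default 2).
#' @return `[duration * fs_feat x 48]` matrix of bin means in `[0, 1]`.
#' @export
resample_to_2hz <- function(features, frame_times, t_start, duration,
                            fs_feat = 2) {
  if (is.unsorted(frame_times))
    stop_invalid("frame_times must be increasing")
  if (length(frame_times) == 0L)
    stop_invalid("block contains no frames")
  n_bins <- round(duration * fs_feat)
  bin <- floor((frame_times - t_start) * fs_feat) + 1L
  keep <- bin >= 1L & bin <= n_bins
  out <- matrix(0, n_bins, ncol(features),
                dimnames = list(NULL, colnames(features)))
  counts <- tabulate(bin[keep], n_bins)
  sums <- rowsum(features[keep, , drop = FALSE], bin[keep])
  idx <- as.integer(rownames(sums))
  out[idx, ] <- sums / counts[idx]
  out
}

#' Build the time-lagged design matrix
#'
#' Stacks, per feature-present block, the feature matrix and its time-shifted
#' copies at the given lags (default 0, 0.5, 1 s). Lagged samples preceding a
#' block's start are zero: blocks are separate epochs, never lag-convolved
#' across boundaries. Columns are ordered lag-major:
#' `lag0 x feature 1..48, lag0.5 x feature 1..48, ...`.
#'
#' @param features named list of `[n x 48]` per-block feature matrices
#'   (feature-present blocks only).
#' @param lags lags in seconds; each must be a multiple of the feature grid
#'   step `1 / fs_feat`.
#' @param fs_feat feature rate in Hz.
#' @return Matrix `[n_bins_total x 48 * n_lags]` with attributes
#'   `column_labels` (`data.frame(feature, lag)`), `block_of_row`, `lags`.
#' @export
build_lagged_design <- function(features, lags = c(0, 0.5, 1), fs_feat = 2) {
  shifts <- lags * fs_feat
  if (any(abs(shifts - round(shifts)) > 1e-9))
    stop_invalid("lags must be multiples of the ", 1 / fs_feat, " s grid")
  X <- do.call(rbind, lapply(features, lag_stack, lags = lags,
                             fs_feat = fs_feat))
  feat_names <- colnames(features[[1L]])
  labels <- data.frame(
    feature = rep(feat_names, times = length(lags)),
    lag = rep(lags, each = length(feat_names))
  )
  colnames(X) <- paste0(labels$feature, "@", labels$lag)
  block_ids <- names(features)
  if (is.null(block_ids)) block_ids <- as.character(seq_along(features))
  attr(X, "column_labels") <- labels
  attr(X, "block_of_row") <- rep(block_ids, vapply(features, nrow, integer(1)))
  attr(X, "lags") <- lags
  X
}

#' Bin an HFB response into 500 ms windows
#'
#' Each bin is the mean of its samples (200 samples at 400 Hz per 0.5 s bin),
#' matching the temporal resolution of the feature timecourses.
#'
#' @param x numeric vector (one contact's epoch) or an `hfb_epochs` object.
#' @param fs sampling rate of `x` in Hz (taken from the object if given one).
#' @param bin bin duration in seconds (default 0.5).
#' @param blocks for `hfb_epochs` input, which blocks to keep (default the
#'   feature-present blocks).
#' @return For a vector: a vector of bin means. For `hfb_epochs`: a
#'   `[n_bins_total x n_channels]` matrix over the kept blocks (stacked in
#'   schedule order) with attribute `block_of_row`.
#' @export
bin_response <- function(x, fs = NULL, bin = 0.5, blocks = NULL) {
  if (inherits(x, "hfb_epochs")) {
    sched <- x$schedule
    if (is.null(blocks)) blocks <- sched$block_index[sched$features_present]
    b_rows <- match(blocks, sched$block_index)
    per_block <- lapply(b_rows, function(b) {
      m <- x$amplitude[, b, , drop = FALSE]
      m <- array(m, dim = dim(m)[c(1L, 3L)])
      apply(m, 1L, bin_vector, fs = x$fs, bin = bin)
    })
    out <- do.call(rbind, per_block)
    colnames(out) <- x$channel_names
    attr(out, "block_of_row") <-
      rep(as.character(blocks), vapply(per_block, nrow, integer(1)))
    return(out)
  }
  bin_vector(x, fs, bin)
}

bin_vector <- function(x, fs, bin) {
  k <- fs * bin
  if (abs(k - round(k)) > 1e-9)
    stop_invalid("bin duration must hold an integer number of samples")
  k <- as.integer(round(k))
  if (length(x) %% k != 0L)
    stop_invalid("signal length is not a whole number of bins")
  colMeans(matrix(x, nrow = k))
}

#' Concatenate contacts of an area into one regression problem
#'
#' All contacts within an area share one weight vector: the response vectors
#' are stacked vertically and the design matrix is replicated once per
#' contact, so a single ridge fit pools every contact's data.
#'
#' @param binned `[n_bins x n_contacts]` matrix of binned responses.
#' @param X lagged design matrix for the same bins.
#' @return List: `X` (stacked design), `y`, `contact_of_row`, `block_of_row`.
#' @export
concatenate_contacts <- function(binned, X) {
  binned <- as.matrix(binned)
  if (nrow(binned) != nrow(X))
    stop_invalid("binned response rows (", nrow(binned),
                 ") do not match design rows (", nrow(X), ")")
  if (ncol(binned) < 1L) stop_invalid("need at least one contact")
  m <- ncol(binned)
  block <- attr(X, "block_of_row")
  Xs <- X[rep(seq_len(nrow(X)), m), , drop = FALSE]
  attr(Xs, "column_labels") <- attr(X, "column_labels")
  attr(Xs, "lags") <- attr(X, "lags")
  list(
    X = Xs,
    y = as.numeric(binned),
    contact_of_row = rep(seq_len(m), each = nrow(X)),
    block_of_row = rep(block, m)
  )
}
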