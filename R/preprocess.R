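#' Construct a recording session
#'
#' Container for a raw (or amplitude) multichannel intracranial recording.
#'
#' @param signal `[n_channels x n_samples]` numeric matrix, microvolts.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_names character vector, one per channel.
#' @param channel_regions optional region labels (`"DLPFC"`, `"pSTC"`,
#'   `"other"`).
#' @param bad_channels character vector of channels to exclude from analysis
#'   (e.g. artifact-contaminated contacts listed in a channels TSV `status`
#'   column).
#' @return List of class `recording_session`.
#' @export
recording_session <- function(signal, fs, channel_names = NULL,
                              channel_regions = NULL, bad_channels = character()) {
  signal <- as.matrix(signal)
  if (fs <= 0) stop_invalid("fs must be positive")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(signal)))
  if (length(channel_names) != nrow(signal))
    stop_invalid("channel_names length must match channel count")
  if (is.null(channel_regions))
    channel_regions <- rep("other", nrow(signal))
  rownames(signal) <- channel_names
  good <- !(channel_names %in% bad_channels)
  if (anyNA(signal[good, , drop = FALSE]))
    stop_invalid("good channels must contain no NA")
  out <- list(signal = signal, fs = fs, channel_names = channel_names,
              channel_regions = channel_regions, bad_channels = bad_channels)
  class(out) <- "recording_session"
  out
}

good_channels <- function(session)
  !(session$channel_names %in% session$bad_channels)

#' Line-noise notch filter at 50 Hz
#'
#' Zero-phase narrow band-stop (2nd-order Butterworth, ~1.7 Hz wide, the
#' bandwidth of a Q = 30 notch) applied forwards and backwards to every
#' channel, removing the mains component without touching the passband.
#'
#' @param session a [recording_session()].
#' @param freq notch frequency in Hz (default 50).
#' @param q quality factor setting the stop-band width `freq / q`.
#' @return The session with filtered signal.
#' @export
notch_50 <- function(session, freq = 50, q = 30) {
  if (session$fs <= 2 * freq)
    stop_invalid("sampling rate too low for a ", freq, " Hz notch")
  bw <- freq / q
  bf <- signal::butter(2, c(freq - bw / 2, freq + bw / 2) / (session$fs / 2),
                       type = "stop")
  session$signal <- t(apply(session$signal, 1L,
                            function(x) signal::filtfilt(bf, x)))
  rownames(session$signal) <- session$channel_names
  session
}

#' Common average reference
#'
#' Subtracts, at every sample, the mean across all good channels. Bad
#' channels are excluded from the average but still re-referenced by it.
#'
#' @param session a [recording_session()].
#' @return The re-referenced session.
#' @export
common_average_reference <- function(session) {
  good <- good_channels(session)
  if (sum(good) < 2L)
    stop_invalid("common average reference needs at least two good channels")
  avg <- colMeans(session$signal[good, , drop = FALSE])
  session$signal <- sweep(session$signal, 2L, avg)
  session
}

# One-sided spectrum doubling; the magnitude of the analytic signal is the
# instantaneous envelope of a band-limited trace.
analytic_amplitude <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' High-frequency broadband amplitude extraction
#'
#' Band-pass filters each channel 110-140 Hz (4th-order Butterworth, applied
#' zero-phase) and takes the magnitude of the Hilbert analytic signal,
#' yielding the instantaneous HFB amplitude.
#'
#' @param session a [recording_session()].
#' @param band band edges in Hz (default `c(110, 140)`).
#' @return The session with its signal replaced by the non-negative
#'   amplitude trace.
#' @export
extract_hfb_amplitude <- function(session, band = c(110, 140)) {
  if (session$fs < 2 * max(band))
    stop_invalid("sampling rate violates the Nyquist limit for the band")
  bf <- signal::butter(4, band / (session$fs / 2), type = "pass")
  session$signal <- t(apply(session$signal, 1L, function(x)
    analytic_amplitude(signal::filtfilt(bf, x))))
  rownames(session$signal) <- session$channel_names
  session
}

#' Epoch, downsample, square-root transform and baseline-z-score
#'
#' Cuts each block's `[-0.2, duration]` s window from the amplitude trace,
#' resamples it to `target_fs` (polyphase, anti-aliased), square-root
#' transforms the amplitude, and z-scores every contact/block against the
#' mean and SD of its own -0.2 to 0 s pre-stimulus baseline (computed after
#' the same downsampling and square-root, so baseline and epoch live on the
#' same scale). The returned epochs span `[0, duration]` s.
#'
#' @param session amplitude-domain [recording_session()] (output of
#'   [extract_hfb_amplitude()]).
#' @param schedule block schedule.
#' @param target_fs output rate in Hz (default 400).
#' @param baseline baseline window in seconds relative to onset
#'   (default `c(-0.2, 0)`).
#' @return List of class `hfb_epochs`: `amplitude`
#'   `[n_channels x n_blocks x n_samples_per_block]` (z-units), `fs`,
#'   `schedule`, `channel_names`, `channel_regions`, `bad_channels`.
#' @export
epoch_and_normalize <- function(session, schedule, target_fs = 400,
                                baseline = c(-0.2, 0)) {
  fs <- session$fs
  if (target_fs > fs)
    stop_invalid("target_fs must not exceed the session sampling rate")
  n_base <- round((baseline[2] - baseline[1]) * target_fs)
  n_ep <- round(schedule$duration[1] * target_fs)
  n_samples <- ncol(session$signal)
  for (b in seq_len(nrow(schedule))) {
    i0 <- round((schedule$onset[b] + baseline[1]) * fs) + 1L
    i1 <- round((schedule$onset[b] + schedule$duration[b]) * fs)
    if (i0 < 1L || i1 > n_samples)
      stop_invalid("block ", schedule$block_index[b],
                   " exceeds the recording extent")
  }
  n_ch <- nrow(session$signal)
  amp <- array(NA_real_, dim = c(n_ch, nrow(schedule), n_ep))
  for (b in seq_len(nrow(schedule))) {
    i0 <- round((schedule$onset[b] + baseline[1]) * fs) + 1L
    i1 <- round((schedule$onset[b] + schedule$duration[b]) * fs)
    for (ch in seq_len(n_ch)) {
      seg <- session$signal[ch, i0:i1]
      seg <- resample_padded(seg, fs, target_fs)
      seg <- sqrt(pmax(seg, 0))
      base <- seg[seq_len(n_base)]
      mu <- mean(base); sdv <- stats::sd(base)
      if (!is.finite(sdv) || sdv == 0)
        stop_invalid("degenerate baseline (zero variance) in block ",
                     schedule$block_index[b], ", channel ",
                     session$channel_names[ch])
      z <- (seg - mu) / sdv
      amp[ch, b, ] <- z[(n_base + 1L):(n_base + n_ep)]
    }
  }
  out <- list(amplitude = amp, fs = target_fs, schedule = schedule,
              channel_names = session$channel_names,
              channel_regions = session$channel_regions,
              bad_channels = session$bad_channels)
  class(out) <- "hfb_epochs"
  out
}

# Anti-aliased downsampling with unit DC gain: zero-phase 4th-order
# Butterworth low-pass at 0.9 x the target Nyquist, then evaluation on the
# target grid by linear interpolation. The segment is reflect-padded first so
# the filter's edge transient never reaches it — the baseline window sits at
# the segment start and would otherwise be contaminated.
resample_padded <- function(seg, fs, target_fs) {
  if (target_fs == fs) return(seg)
  n <- length(seg)
  npad <- min(round(0.5 * fs), n - 1L)
  left <- seg[(npad + 1L):2L]
  right <- seg[(n - 1L):(n - npad)]
  padded <- c(left, seg, right)
  bf <- signal::butter(4, 0.9 * target_fs / fs, type = "low")
  padded <- signal::filtfilt(bf, padded)
  t_in <- (seq_along(padded) - 1L - npad) / fs
  n_out <- round(n * target_fs / fs)
  t_out <- (seq_len(n_out) - 1L) / target_fs
  stats::approx(t_in, padded, xout = t_out, rule = 2)$y
}

#' Full preprocessing chain
#'
#' notch -> common average reference -> band-pass + Hilbert envelope ->
#' epoch -> downsample -> square-root -> baseline z-score, in that fixed
#' order.
#'
#' @inheritParams epoch_and_normalize
#' @inheritParams extract_hfb_amplitude
#' @param notch_freq mains frequency in Hz.
#' @return An `hfb_epochs` object.
#' @export
preprocess_session <- function(session, schedule, band = c(110, 140),
                               notch_freq = 50, target_fs = 400,
                               baseline = c(-0.2, 0)) {
  session <- notch_50(session, freq = notch_freq)
  session <- common_average_reference(session)
  session <- extract_hfb_amplitude(session, band = band)
  epoch_and_normalize(session, schedule, target_fs = target_fs,
                      baseline = baseline)
}
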