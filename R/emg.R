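#' Construct a raw facial-EMG recording
#'
#' Two-channel (corrugator supercilii, levator labii) surface EMG with an
#' event list marking stimulus onsets.  Events must leave at least 2 s of
#' signal before onset (the baseline window) and 6 s after (the picture
#' window); the sampling rate must exceed twice the 300 Hz low-pass cutoff.
#'
#' @param corrugator,levator Numeric vectors of equal length, in mV.
#' @param sampling_rate Hz (default 1000).
#' @param events Data frame with columns `onset_sample` (1-based) and
#'   `condition`.
#' @return An `emg_recording` object.
#' @export
emg_recording <- function(corrugator, levator, sampling_rate = 1000, events) {
  stopifnot(length(corrugator) == length(levator),
            is.data.frame(events),
            all(c("onset_sample", "condition") %in% names(events)))
  if (sampling_rate <= 2 * 300) {
    stop("sampling rate must exceed twice the 300 Hz low-pass cutoff",
         call. = FALSE)
  }
  n <- length(corrugator)
  pre <- 2 * sampling_rate
  post <- 6 * sampling_rate
  bad <- events$onset_sample - pre < 1 | events$onset_sample + post - 1 > n
  if (any(bad)) {
    warning(sum(bad), " event(s) without a full 2 s baseline / 6 s picture ",
            "window dropped", call. = FALSE)
    events <- events[!bad, , drop = FALSE]
  }
  structure(list(corrugator = corrugator, levator = levator,
                 sampling_rate = sampling_rate, events = events),
            class = "emg_recording")
}

# zero-phase second-order IIR notch (quality factor q) at freq Hz
notch_filter <- function(x, freq, fs, q = 30) {
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  signal::filtfilt(signal::Arma(b = b, a = a), x)
}

# filter -> rectify -> moving-average smooth, all at the native rate
condition_signal <- function(x, fs, smooth_window) {
  hp <- signal::butter(8, 20 / (fs / 2), type = "high")
  lp <- signal::butter(8, 300 / (fs / 2), type = "low")
  y <- signal::filtfilt(hp, x)
  y <- signal::filtfilt(lp, y)
  y <- notch_filter(y, 50, fs)
  y <- abs(y)
  w <- max(1L, round(smooth_window * fs))
  as.numeric(stats::filter(y, rep(1 / w, w), sides = 2, circular = FALSE))
}

#' Preprocess a facial-EMG recording into per-trial activity
#'
#' The chain of the block design's EMG analysis: 20 Hz high-pass and 300 Hz
#' low-pass Butterworth filters (order 8, applied forward-backward for zero
#' phase), a 50 Hz notch (second-order IIR, quality factor 30), full-wave
#' rectification, integration by moving-average smoothing, decimation of
#' the smoothed trace to `downsample_rate`, then per-trial averaging over
#' the 6 s picture window with subtraction of the mean over the 2 s
#' pre-onset baseline.  The baseline-corrected pre-onset mean of every
#' trial is zero by construction.
#'
#' Already-processed inputs are rejected: the function only accepts raw
#' `emg_recording` objects.
#'
#' @param recording An [emg_recording()].
#' @param smooth_window Moving-average integration window in seconds
#'   (default 0.1).
#' @param downsample_rate Rate (Hz) of the decimated smoothed trace used
#'   for the window averages (default 100).
#' @return An `emg_trials` data frame: `channel`, `condition`, `trial`,
#'   `onset_sample`, `baseline`, `activity` (mV, baseline-corrected
#'   picture-window mean), with the condition-by-channel averages in
#'   `attr(, "condition_means")`.
#' @export
preprocess_emg <- function(recording, smooth_window = 0.1,
                           downsample_rate = 100) {
  if (!inherits(recording, "emg_recording")) {
    stop("preprocess_emg() expects a raw emg_recording; ",
         "processed traces cannot be re-processed", call. = FALSE)
  }
  fs <- recording$sampling_rate
  dec <- max(1L, round(fs / downsample_rate))
  ev <- recording$events
  out <- list()
  for (ch in c("corrugator", "levator")) {
    smooth <- condition_signal(recording[[ch]], fs, smooth_window)
    idx <- seq(1L, length(smooth), by = dec)  # 100 Hz bookkeeping
    trace <- smooth[idx]
    for (i in seq_len(nrow(ev))) {
      on <- ev$onset_sample[i]
      on_d <- ceiling(on / dec)
      pre <- trace[(on_d - 2 * downsample_rate):(on_d - 1)]
      win <- trace[on_d:(on_d + 6 * downsample_rate - 1)]
      base <- mean(pre, na.rm = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        channel = ch, condition = ev$condition[i], trial = i,
        onset_sample = on, baseline = base,
        activity = mean(win, na.rm = TRUE) - base,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  cm <- stats::aggregate(activity ~ channel + condition, data = res, FUN = mean)
  structure(res, condition_means = cm, class = c("emg_trials", "data.frame"))
}

#' Synthesize a facial-EMG recording with known condition amplitudes
#'
#' Gaussian noise carrier band-limited to `carrier_band`, normalized to
#' unit standard deviation and scaled by a per-sample amplitude envelope:
#' `baseline_sd` mV outside stimulus windows and a condition-dependent
#' amplitude inside them.  The event schedule follows the block design: per
#' condition block, `trials` trials of a 3-5 s uniform fixation gap
#' followed by a 6 s picture.  The expected rectified-smoothed activity of
#' a window with amplitude `a` is `a * sqrt(2/pi)` mV, so condition deltas
#' default to the published corrugator/levator condition means scaled by
#' `sqrt(pi/2)`.
#'
#' @param conditions Character vector of block conditions.
#' @param deltas Named list per channel (`corrugator`, `levator`) of named
#'   per-condition target activity shifts in mV (baseline-corrected
#'   rectified-mean scale).
#' @param trials Trials per condition block.
#' @param baseline_sd Carrier amplitude outside stimulus windows (mV).
#' @param sampling_rate Hz.
#' @param carrier_band Length-2 numeric band (Hz) of the noise carrier.
#' @param seed Integer seed; the recording is identical on replay.
#' @return An [emg_recording()].
#' @export
synthesize_emg <- function(conditions = c("view_neu", "view_neg",
                                          "distraction", "distancing",
                                          "suppression"),
                           deltas = list(
                             corrugator = c(view_neu = 0.04, view_neg = 1.03,
                                            distraction = 0, distancing = 0.25,
                                            suppression = 0.07),
                             levator = c(view_neu = 0.09, view_neg = 0.58,
                                         distraction = -0.05, distancing = 0.01,
                                         suppression = -0.03)),
                           trials = 20, baseline_sd = 2,
                           sampling_rate = 1000, carrier_band = c(20, 300),
                           seed = 1) {
  fs <- sampling_rate
  withr::with_seed(as.integer(seed), {
    # event schedule
    onsets <- integer(0); cond <- character(0)
    t_cur <- fs * 3L  # lead-in
    for (cd in conditions) {
      for (tr in seq_len(trials)) {
        gap <- stats::runif(1, 3, 5)
        on <- t_cur + round(gap * fs)
        onsets <- c(onsets, on)
        cond <- c(cond, cd)
        t_cur <- on + 6L * fs
      }
    }
    n <- t_cur + 3L * fs  # tail padding
    bp <- signal::butter(8, carrier_band / (fs / 2), type = "pass")
    make_channel <- function(ch) {
      carrier <- signal::filtfilt(bp, stats::rnorm(n))
      carrier <- carrier / stats::sd(carrier)
      env <- rep(baseline_sd, n)
      amp <- baseline_sd + deltas[[ch]][cond] * sqrt(pi / 2)
      for (i in seq_along(onsets)) {
        env[onsets[i]:(onsets[i] + 6L * fs - 1L)] <- amp[i]
      }
      carrier * env
    }
    corr <- make_channel("corrugator")
    lev <- make_channel("levator")
  })
  emg_recording(corr, lev, sampling_rate = fs,
                events = data.frame(onset_sample = onsets, condition = cond,
                                    stringsAsFactors = FALSE))
}
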