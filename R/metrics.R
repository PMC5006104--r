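#' Bundle single-trial response traces with their stimulus reference
#'
#' Container for the input-output analyses: equal-length single-trial
#' traces (model `S_mean` or LFP), the stimulus reference waveform on the
#' same sample grid, and the stimulus event onsets.
#'
#' @param trials Matrix (samples x trials) or list of equal-length
#'   numeric vectors.
#' @param fs Sampling rate (samples per second).
#' @param stimulus Stimulus reference waveform on the same grid (may be
#'   `NULL` if only trial-to-trial analyses are needed).
#' @param event_times Stimulus onsets (ms from trace start).
#' @return An object of class `response_set`.
#' @export
response_set <- function(trials, fs, stimulus = NULL,
                         event_times = numeric(0)) {
  if (is.list(trials)) trials <- do.call(cbind, trials)
  trials <- as.matrix(trials)
  stopifnot(is.numeric(trials), fs > 0)
  if (!is.null(stimulus) && length(stimulus) != nrow(trials))
    stop("response_set: stimulus waveform must match the trial grid")
  structure(list(trials = trials, fs = fs, stimulus = stimulus,
                 event_times = as.numeric(event_times)),
            class = "response_set")
}

#' Bundle spike-time trials with stimulus onsets
#'
#' @param trials List of numeric vectors of spike times (ms) per trial.
#' @param event_times Stimulus onsets (ms).
#' @param duration Trial duration (ms); spike times must not exceed it.
#' @return An object of class `spike_set`.
#' @export
spike_set <- function(trials, event_times, duration = NULL) {
  stopifnot(is.list(trials))
  trials <- lapply(trials, function(x) {
    x <- as.numeric(x)
    if (is.unsorted(x)) stop("spike_set: spike times must be sorted")
    if (!is.null(duration) && length(x) && (min(x) < 0 || max(x) > duration))
      stop("spike_set: spike times outside trial duration")
    x
  })
  structure(list(trials = trials, event_times = as.numeric(event_times),
                 duration = duration),
            class = "spike_set")
}

#' Trial-by-trial response reliability
#'
#' Mean zero-lag Pearson correlation over all unordered pairs of
#' single-trial traces.  Pairs involving a constant (zero-variance)
#' trial are excluded with a warning; if no valid pair remains the
#' metric is undefined and an error is raised.
#'
#' @param rs A [response_set()] with at least 2 trials.
#' @return Mean pairwise correlation, in `[-1, 1]`.
#' @export
tbt_reliability <- function(rs) {
  stopifnot(inherits(rs, "response_set"))
  x <- rs$trials
  if (ncol(x) < 2) stop("tbt_reliability: need >= 2 trials")
  sds <- apply(x, 2, sd)
  ok <- sds > 0
  if (any(!ok))
    warning("tbt_reliability: excluding ", sum(!ok),
            " constant trial(s) from pairwise correlations")
  if (sum(ok) < 2)
    stop("tbt_reliability: undefined, all trial pairs excluded")
  cm <- cor(x[, ok, drop = FALSE])
  mean(cm[upper.tri(cm)])
}

# Pearson cross-correlation of stimulus vs response at response lags
# 0..max_lag samples (response lagging the stimulus).
xcorr_lags <- function(stim, resp, max_lag_samples) {
  n <- length(stim)
  vapply(0:max_lag_samples, function(l) {
    if (n - l < 3) return(NA_real_)
    a <- stim[seq_len(n - l)]
    b <- resp[seq_len(n - l) + l]
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  }, numeric(1))
}

#' Stimulus-response cross-correlation amplitude and decay
#'
#' Per trial, the Pearson-normalized cross-correlation between the
#' stimulus reference waveform and the single-trial response over
#' response lags `0..max_lag` ms.  `io_amp` is the mean over trials of
#' the per-trial correlogram peak; `io_tau` is the decay constant of a
#' single-exponential least-squares fit to the trial-averaged
#' correlogram, from its peak to the `max_lag` lag.
#'
#' @param rs A [response_set()] with a non-constant stimulus waveform.
#' @param max_lag Maximum response lag (ms). Default 100.
#' @return List with `io_amp` (correlation), `io_tau` (ms),
#'   `correlogram` (trial-averaged, one value per lag sample), and
#'   `lags` (ms).
#' @export
io_correlation <- function(rs, max_lag = 100) {
  stopifnot(inherits(rs, "response_set"))
  if (is.null(rs$stimulus) || sd(rs$stimulus) == 0)
    stop("io_correlation: need a non-constant stimulus waveform")
  L <- min(round(max_lag * rs$fs / 1000), nrow(rs$trials) - 3)
  cc <- apply(rs$trials, 2, function(tr)
    xcorr_lags(rs$stimulus, tr, L))
  cc <- matrix(cc, nrow = L + 1)
  peaks <- apply(cc, 2, max, na.rm = TRUE)
  avg <- rowMeans(cc)
  lags_ms <- (0:L) * 1000 / rs$fs
  tau <- fit_correlogram_tau(avg, lags_ms)
  list(io_amp = mean(peaks), io_tau = tau, correlogram = avg,
       lags = lags_ms)
}

# Exponential decay fit A*exp(-(lag - lag_peak)/tau) from the
# correlogram peak to the last lag; Levenberg-Marquardt NLS with a
# log-linear fallback when all points are positive.  Non-positive or
# failed fits raise an undefined-metric error.
fit_correlogram_tau <- function(avg, lags_ms) {
  p <- which.max(avg)
  if (p >= length(avg))
    stop("io_correlation: correlogram peak at the last lag, no decay to fit")
  y <- avg[p:length(avg)]
  l <- lags_ms[p:length(avg)] - lags_ms[p]
  tau <- tryCatch({
    fit <- minpack.lm::nlsLM(y ~ A * exp(-l / tau),
                             start = list(A = max(y), tau = 20),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    unname(coef(fit)[["tau"]])
  }, error = function(e) NA_real_)
  if (!is.na(tau) && tau > 0) return(tau)
  if (all(y > 0)) {
    sl <- unname(coef(lm(log(y) ~ l))[2])
    if (sl < 0) return(-1 / sl)
  }
  stop("io_correlation: exponential fit failed or non-positive tau ",
       "(peak lag ", lags_ms[p], " ms, peak value ",
       signif(avg[p], 3), ")")
}

# Event-aligned, baseline-subtracted average response profile pooled
# over events and trials; window and baseline in ms relative to onset.
event_aligned_profile <- function(rs, window = c(0, 100), baseline = 50) {
  stopifnot(length(rs$event_times) >= 1)
  fs <- rs$fs
  w0 <- round(window[1] * fs / 1000)
  w1 <- round(window[2] * fs / 1000)
  nb <- round(baseline * fs / 1000)
  acc <- numeric(w1 - w0 + 1)
  count <- 0L
  for (tr in seq_len(ncol(rs$trials))) {
    x <- rs$trials[, tr]
    for (ev in rs$event_times) {
      i0 <- round(ev * fs / 1000) + 1
      if (i0 - nb < 1 || i0 + w1 > length(x)) next
      base <- if (nb > 0) mean(x[(i0 - nb):(i0 - 1)]) else 0
      acc <- acc + (x[(i0 + w0):(i0 + w1)] - base)
      count <- count + 1L
    }
  }
  if (count == 0L) stop("event_aligned_profile: no usable events")
  list(profile = acc / count,
       t = (w0:w1) * 1000 / fs)
}

# Interpolated time at which a normalized cumulative profile reaches 0.5.
cumulative_t50 <- function(profile, t) {
  total <- sum(profile)
  if (total <= 0)
    stop("t50: cumulative response profile is non-positive")
  cum <- cumsum(profile) / total
  if (min(diff(cum)) < -0.05)
    stop("t50: cumulative response profile is non-monotone")
  k <- which(cum >= 0.5)[1]
  if (is.na(k)) stop("t50: cumulative profile never reaches 0.5")
  if (k == 1) return(t[1])
  t[k - 1] + (0.5 - cum[k - 1]) / (cum[k] - cum[k - 1]) * (t[k] - t[k - 1])
}

#' Time to half-maximal cumulative response (continuous traces)
#'
#' Averages the event-aligned, baseline-subtracted response across all
#' events and trials, forms the normalized cumulative profile over the
#' analysis window, and returns the linearly interpolated time at which
#' it reaches 0.5.
#'
#' @param rs A [response_set()] with at least one event.
#' @param window Post-stimulus window (ms). Default `c(0, 100)`.
#' @param baseline Pre-event baseline duration (ms). Default 50.
#' @return T50 (ms post-stimulus).
#' @export
t50_model <- function(rs, window = c(0, 100), baseline = 50) {
  stopifnot(inherits(rs, "response_set"))
  pr <- event_aligned_profile(rs, window = window, baseline = baseline)
  cumulative_t50(pr$profile, pr$t)
}

#' Time to half-maximal cumulative response (spike trains)
#'
#' Pools spikes across events and trials into a peristimulus histogram
#' within the analysis window (default 10-80 ms post-stimulus, skipping
#' the initial conduction delay), normalizes the cumulative count, and
#' interpolates the time at 0.5.
#'
#' @param ss A [spike_set()].
#' @param window Post-stimulus window (ms). Default `c(10, 80)`.
#' @param bin Histogram bin width (ms). Default 1.
#' @return T50 (ms post-stimulus).
#' @export
t50_spikes <- function(ss, window = c(10, 80), bin = 1) {
  stopifnot(inherits(ss, "spike_set"))
  rel <- unlist(lapply(ss$trials, function(sp)
    unlist(lapply(ss$event_times, function(ev) sp - ev))))
  rel <- rel[rel >= window[1] & rel <= window[2]]
  if (!length(rel)) stop("t50_spikes: no spikes in the analysis window")
  breaks <- seq(window[1], window[2], by = bin)
  if (breaks[length(breaks)] < window[2])
    breaks <- c(breaks, window[2])
  h <- graphics::hist(rel, breaks = breaks, plot = FALSE)
  cumulative_t50(h$counts, h$mids)
}

#' Mean evoked response amplitude
#'
#' Mean over events and trials of the baseline-subtracted peak response
#' within the post-event window.
#'
#' @param rs A [response_set()] with at least one event.
#' @param window Post-stimulus window (ms). Default `c(0, 100)`.
#' @param baseline Pre-event baseline duration (ms). Default 50.
#' @return Mean peak amplitude (trace units).
#' @export
response_amplitude <- function(rs, window = c(0, 100), baseline = 50) {
  stopifnot(inherits(rs, "response_set"), length(rs$event_times) >= 1)
  fs <- rs$fs
  w0 <- round(window[1] * fs / 1000)
  w1 <- round(window[2] * fs / 1000)
  nb <- round(baseline * fs / 1000)
  peaks <- c()
  for (tr in seq_len(ncol(rs$trials))) {
    x <- rs$trials[, tr]
    for (ev in rs$event_times) {
      i0 <- round(ev * fs / 1000) + 1
      if (i0 - nb < 1 || i0 + w1 > length(x)) next
      base <- if (nb > 0) mean(x[(i0 - nb):(i0 - 1)]) else 0
      peaks <- c(peaks, max(x[(i0 + w0):(i0 + w1)]) - base)
    }
  }
  if (!length(peaks)) stop("response_amplitude: no usable events")
  mean(peaks)
}

#' Low-pass filter and downsample an LFP-like trace to 200 Hz
#'
#' Zero-phase (forward-backward) 4th-order Butterworth low-pass at
#' 100 Hz, then decimation to 200 samples per second.
#'
#' @param x Raw trace.
#' @param fs_in Input sampling rate; must be `>= 400` and an integer
#'   multiple of 200.
#' @return List with `trace` (filtered, decimated) and `fs` (200).
#' @export
preprocess_lfp <- function(x, fs_in) {
  if (fs_in < 400)
    stop("preprocess_lfp: fs_in must be >= 400 to honor the 100 Hz cutoff")
  if (fs_in %% 200 != 0)
    stop("preprocess_lfp: fs_in must be an integer multiple of 200")
  bf <- signal::butter(4, 100 / (fs_in / 2), type = "low")
  y <- signal::filtfilt(bf, x)
  r <- fs_in / 200
  list(trace = y[seq(1, length(y), by = r)], fs = 200)
}

#' Two-tailed paired t test between conditions
#'
#' @param control,modulated Equal-length paired samples (`n >= 2`).
#' @return List with `t`, `p`, `df`.  Identical samples return `t = 0`,
#'   `p = 1` by convention; any other zero-variance difference is an
#'   error.
#' @export
paired_comparison <- function(control, modulated) {
  stopifnot(length(control) == length(modulated), length(control) >= 2)
  d <- modulated - control
  if (sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, p = 1, df = length(d) - 1L))
    stop("paired_comparison: zero variance of paired differences")
  }
  tt <- t.test(modulated, control, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}
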