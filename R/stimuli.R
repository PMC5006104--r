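#' Rectangular pulse trains for both ensembles
#'
#' Builds paired raw (unfiltered) waveforms of rectangular current pulses.
#' Each event delivers simultaneous pulses of possibly different
#' amplitudes to the two ensembles; a pulse is active on
#' `[onset, onset + width)`.
#'
#' @param events A data.frame with columns `onset` (ms), `amp1`, `amp2`
#'   (nA). Zero rows give all-zero waveforms.
#' @param width Pulse duration (ms). Default 10.
#' @param dt Sample step (ms).
#' @param duration Waveform duration (ms); samples cover `[0, duration]`.
#' @return A list with `raw1`, `raw2` (nA per sample) and `t` (ms).
#' @export
pulse_train <- function(events, width = 10, dt, duration) {
  events <- as.data.frame(events)
  stopifnot(dt > 0, duration > 0, width > 0)
  n <- round(duration / dt) + 1
  t <- seq(0, by = dt, length.out = n)
  raw1 <- numeric(n)
  raw2 <- numeric(n)
  if (nrow(events)) {
    stopifnot(all(c("onset", "amp1", "amp2") %in% names(events)))
    ord <- order(events$onset)
    events <- events[ord, ]
    if (any(events$onset < 0) || any(events$onset + width > duration))
      stop("pulse_train: pulses must lie within [0, duration]")
    if (nrow(events) > 1 &&
        any(diff(events$onset) < width))
      stop("pulse_train: overlapping pulses")
    for (i in seq_len(nrow(events))) {
      idx <- which(t >= events$onset[i] & t < events$onset[i] + width)
      raw1[idx] <- raw1[idx] + events$amp1[i]
      raw2[idx] <- raw2[idx] + events$amp2[i]
    }
  }
  list(raw1 = raw1, raw2 = raw2, t = t)
}

#' First-order low-pass filter with unit DC gain
#'
#' Exponential smoothing `y[k] = y[k-1] + (dt/tau) * (x[k] - y[k-1])`,
#' the same explicit discretization used for the background-noise
#' process; a step input converges to the step amplitude.
#'
#' @param raw Input waveform (numeric vector).
#' @param tau Filter time constant (ms). Default 10.
#' @param dt Sample step (ms).
#' @return Filtered waveform of the same length.
#' @export
filter_waveform <- function(raw, tau = 10, dt) {
  stopifnot(tau > 0, dt > 0)
  as.numeric(stats::filter(raw * (dt / tau), 1 - dt / tau,
                           method = "recursive"))
}

#' Sinusoidal input waveform
#'
#' `amp * sin(2*pi*freq*t + phase)`; when attached to a stimulus program
#' the identical sinusoid drives both ensembles (a common slow-oscillation
#' input).
#'
#' @param freq Frequency (Hz). Default 2.
#' @param amp Amplitude (nA). Default 0.05.
#' @param phase Phase (radians).
#' @param dt Sample step (ms).
#' @param duration Duration (ms).
#' @return Waveform (nA per sample) on `[0, duration]`.
#' @export
sinusoid <- function(freq = 2, amp = 0.05, phase = 0, dt, duration) {
  stopifnot(freq > 0, dt > 0, duration > 0)
  t <- seq(0, by = dt, length.out = round(duration / dt) + 1)
  amp * sin(2 * pi * freq * t / 1000 + phase)
}

#' Assemble a stimulus program
#'
#' A stimulus program holds the paired external input waveforms for the
#' two ensembles: a low-pass-filtered pulse train (per-ensemble
#' amplitudes) plus an optional common sinusoid.  Waveforms are fully
#' reconstructible from the stored events, filter constant, and sinusoid
#' parameters.
#'
#' @param events data.frame with `onset` (ms), `amp1`, `amp2` (nA).
#' @param duration Program duration (ms).
#' @param dt Sample step (ms). Default 0.1.
#' @param width Pulse width (ms). Default 10.
#' @param pulse_tau Pulse low-pass filter time constant (ms). Default 10.
#' @param sine `NULL`, or a list with `freq` (Hz), `amp` (nA), `phase`
#'   (radians) describing a common sinusoidal input to both ensembles.
#' @return An object of class `stimulus_program` with fields `dt`,
#'   `duration`, `events`, `width`, `pulse_tau`, `sine`, `pulse1`,
#'   `pulse2` (filtered pulse waveforms), and `waveform1`, `waveform2`
#'   (pulse + sinusoid, the actual model inputs on `[0, duration]`).
#' @export
stimulus_program <- function(events, duration, dt = 0.1, width = 10,
                             pulse_tau = 10, sine = NULL) {
  events <- as.data.frame(events)
  raw <- pulse_train(events, width = width, dt = dt, duration = duration)
  pulse1 <- filter_waveform(raw$raw1, tau = pulse_tau, dt = dt)
  pulse2 <- filter_waveform(raw$raw2, tau = pulse_tau, dt = dt)
  s <- numeric(length(pulse1))
  if (!is.null(sine)) {
    stopifnot(is.list(sine), all(c("freq", "amp", "phase") %in% names(sine)))
    s <- sinusoid(sine$freq, sine$amp, sine$phase, dt = dt,
                  duration = duration)
  }
  structure(list(dt = dt, duration = duration, events = events,
                 width = width, pulse_tau = pulse_tau, sine = sine,
                 pulse1 = pulse1, pulse2 = pulse2,
                 waveform1 = pulse1 + s, waveform2 = pulse2 + s),
            class = "stimulus_program")
}

# Per-step external input including burn-in: step k (0-based,
# k = 0 .. n_burn + n_steps - 1) uses the input at t_k = (k - n_burn)*dt.
# Pulses are zero before t = 0; the sinusoid is evaluated continuously.
program_input <- function(program, n_burn) {
  dt <- program$dt
  n_steps <- round(program$duration / dt)
  i1 <- c(numeric(n_burn), program$pulse1[seq_len(n_steps)])
  i2 <- c(numeric(n_burn), program$pulse2[seq_len(n_steps)])
  if (!is.null(program$sine)) {
    tk <- (seq_len(n_burn + n_steps) - 1 - n_burn) * dt
    s <- program$sine$amp *
      sin(2 * pi * program$sine$freq * tk / 1000 + program$sine$phase)
    i1 <- i1 + s
    i2 <- i2 + s
  }
  list(istim1 = i1, istim2 = i2)
}

#' Coincident-stimulus series (fixed I1, ratio-scaled I2)
#'
#' A series of simultaneous pulse pairs: ensemble 1 receives a fixed
#' amplitude on every event while ensemble 2 receives `ratio * I1_amp`,
#' with ratios spanning 0 to 4.  With the default 13 linearly spaced
#' ratios the `I1 = I2` condition falls exactly at stimulus index 4
#' (1-based, ratio 1).
#'
#' @param I1_amp Ensemble-1 pulse amplitude (nA). Default 0.5.
#' @param ratios Nondecreasing amplitude ratios, first 0, last 4.
#' @param isi Inter-stimulus interval (ms). Default 1000.
#' @param lead Time before the first pulse (ms). Default 500.
#' @param width,dt,pulse_tau,sine Passed to [stimulus_program()].
#' @return A `stimulus_program`.
#' @export
coincident_series <- function(I1_amp = 0.5,
                              ratios = seq(0, 4, length.out = 13),
                              isi = 1000, lead = 500, width = 10,
                              dt = 0.1, pulse_tau = 10, sine = NULL) {
  stopifnot(length(ratios) >= 2, all(diff(ratios) >= 0))
  if (abs(ratios[1]) > 1e-12 || abs(ratios[length(ratios)] - 4) > 1e-12)
    stop("coincident_series: ratios must start at 0 and end at 4")
  n <- length(ratios)
  events <- data.frame(onset = lead + (seq_len(n) - 1) * isi,
                       amp1 = rep(I1_amp, n),
                       amp2 = ratios * I1_amp)
  stimulus_program(events, duration = lead + n * isi, dt = dt,
                   width = width, pulse_tau = pulse_tau, sine = sine)
}

#' Proportional-stimulus series (Istim2 = ratio * Istim1)
#'
#' Sensory-like transient inputs exciting one ensemble more strongly
#' than the other at a fixed proportion across all amplitudes.
#'
#' @param amps Ensemble-1 pulse amplitudes (nA), within `[0.06, 0.6]`.
#'   Default 10 linearly spaced values.
#' @param ratio Amplitude proportion for ensemble 2. Default 0.6.
#' @param isi Inter-stimulus interval (ms). Default 400.
#' @param lead Time before the first pulse (ms). Default 200.
#' @param duration Program duration (ms); default `lead + isi*length(amps)`.
#' @param width,dt,pulse_tau,sine Passed to [stimulus_program()].
#' @return A `stimulus_program`.
#' @export
proportional_series <- function(amps = seq(0.06, 0.6, length.out = 10),
                                ratio = 0.6, isi = 400, lead = 200,
                                duration = NULL, width = 10, dt = 0.1,
                                pulse_tau = 10, sine = NULL) {
  stopifnot(length(amps) >= 1)
  if (any(amps < 0.06 - 1e-9 | amps > 0.6 + 1e-9))
    stop("proportional_series: amplitudes must lie within [0.06, 0.6] nA")
  n <- length(amps)
  if (is.null(duration)) duration <- lead + isi * n
  events <- data.frame(onset = lead + (seq_len(n) - 1) * isi,
                       amp1 = amps, amp2 = ratio * amps)
  stimulus_program(events, duration = duration, dt = dt, width = width,
                   pulse_tau = pulse_tau, sine = sine)
}

#' Serialize a stimulus program to a plain list
#'
#' Only generative fields are stored (events, grid, filter constant,
#' sinusoid parameters); [program_from_list()] rebuilds the waveforms
#' bit-exactly.
#'
#' @param program A `stimulus_program`.
#' @return A plain list safe to write as JSON.
#' @export
program_to_list <- function(program) {
  stopifnot(inherits(program, "stimulus_program"))
  list(dt = program$dt, duration = program$duration,
       events = program$events, width = program$width,
       pulse_tau = program$pulse_tau, sine = program$sine)
}

#' Rebuild a stimulus program from its serialized form
#' @param x A list as produced by [program_to_list()].
#' @return A `stimulus_program`.
#' @export
program_from_list <- function(x) {
  stimulus_program(as.data.frame(x$events), duration = x$duration,
                   dt = x$dt, width = x$width, pulse_tau = x$pulse_tau,
                   sine = x$sine)
}
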