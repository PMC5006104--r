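#' Build a response set from simulated trial traces
#'
#' Collects the `S_mean` traces of a list of trials into a
#' [response_set()], using the filtered transient (pulse) waveform of
#' ensemble 1 as the stimulus reference, decimated onto the recorded
#' trace grid.  The pulse waveform is identical across trials of a
#' protocol (only the sinusoid phase varies), so the reference is taken
#' from the first program.
#'
#' @param traces List of `trial_trace` objects (equal grids).
#' @param program The `stimulus_program` of (any) one trial.
#' @return A [response_set()].
#' @export
traces_to_response_set <- function(traces, program) {
  stopifnot(length(traces) >= 1)
  fs <- trace_fs(traces[[1]])
  re <- traces[[1]]$record_every
  n <- length(traces[[1]]$t)
  stim <- program$pulse1[seq(1, by = re, length.out = n)]
  response_set(lapply(traces, `[[`, "S_mean"), fs = fs,
               stimulus = stim, event_times = program$events$onset)
}

# Per-trial sinusoid phase stream, decoupled from the noise stream.
phase_from_seed <- function(trial_seed) {
  set.seed(as.integer((trial_seed + 1367130551) %% 2147483647))
  runif(1, 0, 2 * pi)
}

#' Per-cell sensory-fidelity metrics
#'
#' Computes the full input-output metric set from one cell's trial
#' traces: trial-to-trial reliability, stimulus-response
#' cross-correlation peak (`io_amp`) and decay (`io_tau_ms`), time to
#' half-maximal cumulative response (`t50_ms`), and mean evoked response
#' amplitude.  A failed correlogram fit yields `NA` for `io_tau_ms`.
#'
#' @param traces List of `trial_trace`.
#' @param programs List of the per-trial `stimulus_program`s.
#' @param spec The cell's `model_spec` (unused, part of the sweep
#'   metric-function contract).
#' @return Named numeric vector.
#' @export
sensory_fidelity_metrics <- function(traces, programs, spec = NULL) {
  rs <- traces_to_response_set(traces, programs[[1]])
  tbt <- if (ncol(rs$trials) >= 2) tbt_reliability(rs) else NA_real_
  io <- tryCatch(io_correlation(rs), error = function(e) NULL)
  tau <- if (is.null(io)) NA_real_ else io$io_tau
  amp <- if (is.null(io)) NA_real_ else io$io_amp
  t50 <- tryCatch(t50_model(rs), error = function(e) NA_real_)
  ra <- tryCatch(response_amplitude(rs), error = function(e) NA_real_)
  c(tbt_r = tbt, io_amp = amp, io_tau_ms = tau, t50_ms = t50,
    resp_amp = ra)
}

#' Sensory-fidelity sweep (proportional transients, optional sinusoid)
#'
#' Runs the proportional-transient protocol over a (Js, Jo) grid:
#' 10 ms pulses with `Istim2 = 0.6 * Istim1`, amplitudes spanning
#' 0.06-0.6 nA, OU background noise, and (optionally) a 2 Hz sinusoidal
#' background with a fresh uniform-random phase per trial.  Per cell the
#' full input-output metric set is computed on the average ensemble
#' activity `(S1 + S2)/2`.
#'
#' @param grid A [sweep_grid()]; default [transient_grid()].
#' @param n_trials Trials per cell. Default 20.
#' @param seed Master seed.
#' @param with_sine Include the 2 Hz sinusoidal background.
#' @param amps Transient amplitudes (nA).
#' @param isi Inter-stimulus interval (ms). Default 400.
#' @param Io Background mean current (nA). Default 0.32.
#' @param sigma_noise Noise amplitude (nA). Default 0.02.
#' @param sine_amp,sine_freq Sinusoid amplitude (nA) and frequency (Hz).
#' @param dt,record_every Integration step and trace decimation.
#' @return A `sweep_result` whose table has columns `Js`, `Jo`,
#'   `tbt_r`, `io_amp`, `io_tau_ms`, `t50_ms`, `resp_amp`.
#' @export
run_sensory_fidelity_sweep <- function(grid = transient_grid(),
                                       n_trials = 20, seed = 1,
                                       with_sine = TRUE,
                                       amps = seq(0.06, 0.6,
                                                  length.out = 10),
                                       isi = 400, Io = 0.32,
                                       sigma_noise = 0.02,
                                       sine_amp = 0.05, sine_freq = 2,
                                       dt = 0.1, record_every = 10) {
  template <- model_spec(couplings(0.2, 0.2),
                         noise_spec(Io, sigma_noise))
  base <- proportional_series(amps = amps, isi = isi, dt = dt)
  factory <- function(trial_seed) {
    if (!with_sine) return(base)
    p <- base
    phase <- phase_from_seed(trial_seed)
    p$sine <- list(freq = sine_freq, amp = sine_amp, phase = phase)
    s <- sinusoid(sine_freq, sine_amp, phase, dt = dt,
                  duration = p$duration)
    p$waveform1 <- p$pulse1 + s
    p$waveform2 <- p$pulse2 + s
    p
  }
  run_sweep(grid, template, factory, n_trials = n_trials, seed = seed,
            metrics_fun = sensory_fidelity_metrics, dt = dt,
            record_every = record_every)
}

#' Coincident-stimulus protocol for one model
#'
#' Runs the 13-stimulus coincident series (fixed `I1`, `I2` ratio 0-4)
#' for a single (Js, Jo) model, extracts per-stimulus peak responses
#' (averaged across trials), and summarizes cross-suppression.
#'
#' @param Js,Jo Coupling values (nA).
#' @param n_trials Number of trials. Default 4.
#' @param seed Master seed.
#' @param I1_amp Ensemble-1 pulse amplitude (nA). Default 0.5.
#' @param isi Inter-stimulus interval (ms). Default 1000.
#' @param Io,sigma_noise Noise parameters. Defaults 0.32 and 0.001 nA.
#' @param crossing_tol Tolerance for the peak-crossing comparison
#'   (gating units). Default 0.02.
#' @param dt,record_every Integration step and trace decimation.
#' @return List with `peaks` (trial-averaged per-stimulus peaks),
#'   `delta_s1`, `crossing` (stimulus index or `NA`), `regime`
#'   (majority over trials), and `traces`.
#' @export
run_coincident_protocol <- function(Js, Jo, n_trials = 4, seed = 1,
                                    I1_amp = 0.5, isi = 1000,
                                    Io = 0.32, sigma_noise = 0.001,
                                    crossing_tol = 0.02, dt = 0.1,
                                    record_every = 10) {
  spec <- model_spec(couplings(Js, Jo), noise_spec(Io, sigma_noise))
  prog <- coincident_series(I1_amp = I1_amp, isi = isi, dt = dt)
  traces <- lapply(seq_len(n_trials), function(k)
    integrate_trial(spec, prog, seed = derive_trial_seed(seed, 1, 1, k),
                    dt = dt, record_every = record_every))
  pk <- lapply(traces, peak_trajectories, events = prog$events)
  p1 <- rowMeans(vapply(pk, `[[`, numeric(nrow(pk[[1]])), "S1_peak"))
  p2 <- rowMeans(vapply(pk, `[[`, numeric(nrow(pk[[1]])), "S2_peak"))
  regimes <- vapply(traces, classify_regime, character(1),
                    events = prog$events)
  list(peaks = data.frame(stimulus = seq_along(p1),
                          S1_peak = p1, S2_peak = p2),
       delta_s1 = delta_s1(p1),
       crossing = crossing_index(p1, p2, tol = crossing_tol),
       regime = names(sort(table(regimes), decreasing = TRUE))[1],
       traces = traces)
}

#' Slow-oscillation (2 Hz) response power for one model
#'
#' Drives both ensembles with an identical 2 Hz sinusoid (fresh random
#' phase per trial) on top of OU background noise and returns the mean
#' 2 Hz power of the demeaned average ensemble activity across trials.
#'
#' @param Js,Jo Coupling values (nA).
#' @param Io Background mean current (nA). Default 0.33.
#' @param sigma_noise Noise amplitude (nA). Default 0.001.
#' @param sine_amp Sinusoid amplitude (nA). Default 0.05.
#' @param sine_freq Sinusoid frequency (Hz). Default 2.
#' @param n_trials Number of trials. Default 4.
#' @param duration Trial duration (ms). Default 5000.
#' @param seed Master seed.
#' @param dt,record_every Integration step and trace decimation.
#' @return Mean 2 Hz power (gating-units^2/Hz) across trials.
#' @export
run_slow_osc_protocol <- function(Js, Jo, Io = 0.33, sigma_noise = 0.001,
                                  sine_amp = 0.05, sine_freq = 2,
                                  n_trials = 4, duration = 5000,
                                  seed = 1, dt = 0.1, record_every = 10) {
  spec <- model_spec(couplings(Js, Jo), noise_spec(Io, sigma_noise))
  no_events <- data.frame(onset = numeric(0), amp1 = numeric(0),
                          amp2 = numeric(0))
  pows <- vapply(seq_len(n_trials), function(k) {
    ts <- derive_trial_seed(seed, 1, 1, k)
    prog <- stimulus_program(no_events, duration = duration, dt = dt,
                             sine = list(freq = sine_freq, amp = sine_amp,
                                         phase = phase_from_seed(ts)))
    tr <- integrate_trial(spec, prog, seed = ts, dt = dt,
                          record_every = record_every)
    band_power(tr$S_mean - mean(tr$S_mean), fs = trace_fs(tr),
               freq = sine_freq)
  }, numeric(1))
  mean(pows)
}

#' 2 Hz power map over a (Js, Jo) grid
#'
#' @param grid A [sweep_grid()]; default [transient_grid()].
#' @param seed Master seed.
#' @param ... Passed to [run_slow_osc_protocol()].
#' @return data.frame with `Js`, `Jo`, `power_2hz`.
#' @export
run_slow_osc_sweep <- function(grid = transient_grid(), seed = 1, ...) {
  cells <- expand.grid(i = seq_along(grid$Js_values),
                       j = seq_along(grid$Jo_values))
  pow <- mapply(function(i, j)
    run_slow_osc_protocol(grid$Js_values[i], grid$Jo_values[j],
                          seed = derive_trial_seed(seed, i, j, 1), ...),
    cells$i, cells$j)
  data.frame(Js = grid$Js_values[cells$i], Jo = grid$Jo_values[cells$j],
             power_2hz = pow)
}
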