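#' Parameter grid over self-excitation and cross-inhibition
#'
#' @param Js_values,Jo_values Ascending coupling values (nA).
#' @param range_tag `"transient"` (Js and Jo both 0.01-0.37 nA) or
#'   `"full"` (Js 0.01-0.74, Jo 0.01-0.37).
#' @return An object of class `sweep_grid`.
#' @export
sweep_grid <- function(Js_values, Jo_values,
                       range_tag = c("transient", "full")) {
  range_tag <- match.arg(range_tag)
  stopifnot(is.numeric(Js_values), is.numeric(Jo_values),
            !is.unsorted(Js_values), !is.unsorted(Jo_values))
  js_max <- if (range_tag == "full") 0.74 else 0.37
  eps <- 1e-9
  if (any(Js_values < 0.01 - eps | Js_values > js_max + eps))
    stop("sweep_grid: Js values outside the ", range_tag, " range")
  if (any(Jo_values < 0.01 - eps | Jo_values > 0.37 + eps))
    stop("sweep_grid: Jo values outside the ", range_tag, " range")
  structure(list(Js_values = Js_values, Jo_values = Jo_values,
                 range_tag = range_tag),
            class = "sweep_grid")
}

#' Default transient-range grid (Js, Jo in 0.01-0.37 nA)
#' @param n Points per axis. Default 10.
#' @return A `sweep_grid`.
#' @export
transient_grid <- function(n = 10) {
  sweep_grid(seq(0.01, 0.37, length.out = n),
             seq(0.01, 0.37, length.out = n), "transient")
}

#' Default full-range grid (Js 0.01-0.74, Jo 0.01-0.37 nA)
#' @param n Points per axis. Default 10.
#' @return A `sweep_grid`.
#' @export
full_grid <- function(n = 10) {
  sweep_grid(seq(0.01, 0.74, length.out = n),
             seq(0.01, 0.37, length.out = n), "full")
}

#' Counter-based per-trial seed derivation
#'
#' Derives an RNG seed from (master seed, Js index, Jo index, trial
#' index) so that grid cells are independent and results do not depend
#' on execution order.  Distinct within `i, j <= 30` and `trial <= 100`;
#' always below 2^31.
#'
#' @param master Master seed (integer).
#' @param i,j 1-based grid indices (Js, Jo).
#' @param trial 1-based trial index.
#' @return An integer seed.
#' @export
derive_trial_seed <- function(master, i, j, trial) {
  stopifnot(i >= 1, i <= 30, j >= 1, j <= 30, trial >= 1, trial <= 100)
  as.integer((master %% 20000) * 100000 + i * 3163 + j * 101 + trial)
}

#' Run a (Js, Jo) parameter sweep
#'
#' For each grid cell, integrates `n_trials` independent trials (fresh
#' noise, and a fresh stimulus program per trial so that e.g. a random
#' sinusoid phase can differ across trials) and summarizes them with a
#' metric function.  Deterministic given the master seed; cells are
#' seeded independently so execution order is irrelevant.  A diverged
#' trial is recorded as a per-cell failure and the sweep continues.
#'
#' @param grid A [sweep_grid()].
#' @param template A [model_spec()] whose couplings are replaced cell by
#'   cell.
#' @param program_factory `function(trial_seed)` returning a
#'   [stimulus_program()] for one trial.
#' @param n_trials Trials per cell.
#' @param seed Master seed.
#' @param metrics_fun `function(traces, programs, spec)` returning a
#'   named numeric vector of per-cell metrics.
#' @param dt Integration step (ms). Default 0.1.
#' @param record_every Trace decimation factor. Default 10 (1 ms grid).
#' @param burn_in Burn-in before `t = 0` (ms). Default 500.
#' @param keep_traces Retain all trial traces in the result (memory
#'   heavy; default `FALSE`).
#' @return A `sweep_result` with a per-cell `table` (data.frame with
#'   `Js`, `Jo`, `n_failed`, and one column per metric) plus the grid,
#'   seeds and (optionally) traces.
#' @export
run_sweep <- function(grid, template, program_factory, n_trials, seed,
                      metrics_fun, dt = 0.1, record_every = 10,
                      burn_in = 500, keep_traces = FALSE) {
  stopifnot(inherits(grid, "sweep_grid"), inherits(template, "model_spec"),
            is.function(program_factory), is.function(metrics_fun),
            n_trials >= 1)
  cells <- expand.grid(i = seq_along(grid$Js_values),
                       j = seq_along(grid$Jo_values))
  rows <- vector("list", nrow(cells))
  traces_all <- if (keep_traces) vector("list", nrow(cells)) else NULL
  for (ci in seq_len(nrow(cells))) {
    i <- cells$i[ci]; j <- cells$j[ci]
    spec <- template
    spec$couplings <- couplings(grid$Js_values[i], grid$Jo_values[j])
    traces <- vector("list", n_trials)
    programs <- vector("list", n_trials)
    failed <- 0L
    for (k in seq_len(n_trials)) {
      ts <- derive_trial_seed(seed, i, j, k)
      prog <- program_factory(ts)
      tr <- tryCatch(
        integrate_trial(spec, prog, seed = ts, dt = dt,
                        burn_in = burn_in, record_every = record_every),
        error = function(e) e)
      if (inherits(tr, "error")) {
        failed <- failed + 1L
      } else {
        traces[[k]] <- tr
        programs[[k]] <- prog
      }
    }
    ok <- !vapply(traces, is.null, logical(1))
    m <- if (any(ok)) metrics_fun(traces[ok], programs[ok], spec) else NULL
    rows[[ci]] <- list(Js = grid$Js_values[i], Jo = grid$Jo_values[j],
                       i = i, j = j, n_failed = failed, metrics = m)
    if (keep_traces) traces_all[[ci]] <- traces
  }
  metric_names <- unique(unlist(lapply(rows, function(r) names(r$metrics))))
  tab <- do.call(rbind, lapply(rows, function(r) {
    base <- data.frame(Js = r$Js, Jo = r$Jo, i = r$i, j = r$j,
                       n_failed = r$n_failed)
    if (!length(metric_names)) return(base)
    m <- stats::setNames(rep(NA_real_, length(metric_names)), metric_names)
    m[names(r$metrics)] <- r$metrics
    cbind(base, as.data.frame(as.list(m), check.names = FALSE))
  }))
  structure(list(grid = grid, table = tab, seed = seed,
                 n_trials = n_trials, traces = traces_all),
            class = "sweep_result")
}

#' Per-stimulus peak responses of both ensembles
#'
#' For each stimulus event, the maximum of `S1` and of `S2` in the
#' response window from the pulse onset to the next onset (or the end of
#' the trace for the last event).
#'
#' @param trace A `trial_trace`.
#' @param events data.frame with an `onset` column (ms) or a numeric
#'   vector of onsets.
#' @return data.frame with `stimulus`, `onset`, `S1_peak`, `S2_peak`.
#' @export
peak_trajectories <- function(trace, events) {
  stopifnot(inherits(trace, "trial_trace"))
  onsets <- if (is.data.frame(events)) events$onset else as.numeric(events)
  stopifnot(length(onsets) >= 1, !is.unsorted(onsets))
  ends <- c(onsets[-1], max(trace$t))
  p1 <- numeric(length(onsets)); p2 <- numeric(length(onsets))
  for (k in seq_along(onsets)) {
    idx <- which(trace$t >= onsets[k] & trace$t < ends[k])
    if (!length(idx)) stop("peak_trajectories: empty response window")
    p1[k] <- max(trace$S1[idx])
    p2[k] <- max(trace$S2[idx])
  }
  data.frame(stimulus = seq_along(onsets), onset = onsets,
             S1_peak = p1, S2_peak = p2)
}

#' Cross-suppression index from a peak trajectory
#'
#' Difference between the ensemble-1 peak to the first stimulus (no
#' competing input) and to the last stimulus (strongest competing
#' input); positive when cross-suppression reduces `S1`.
#'
#' @param peaks1 Per-stimulus `S1` peaks (numeric, length >= 2).
#' @return The scalar difference.
#' @export
delta_s1 <- function(peaks1) {
  stopifnot(is.numeric(peaks1), length(peaks1) >= 2)
  peaks1[1] - peaks1[length(peaks1)]
}

#' First stimulus at which ensemble 2 overtakes ensemble 1
#'
#' Smallest stimulus index at which `S2_peak >= S1_peak - tol`;
#' `NA` when the trajectories never cross.  A small positive `tol`
#' makes the comparison robust at the symmetric `I1 = I2` stimulus,
#' where the two peaks are equal up to noise.
#'
#' @param peaks1,peaks2 Equal-length per-stimulus peak vectors.
#' @param tol Comparison tolerance (gating units). Default 0.
#' @return Integer index, or `NA_integer_` if absent.
#' @export
crossing_index <- function(peaks1, peaks2, tol = 0) {
  stopifnot(length(peaks1) == length(peaks2))
  hit <- which(peaks2 >= peaks1 - tol)
  if (!length(hit)) NA_integer_ else as.integer(hit[1])
}

#' Classify a trial as transient or sustained
#'
#' A trial is `"sustained"` if, after at least one stimulus, the larger
#' of the two gating variables stays above `threshold` for at least
#' `dwell` of the interval up to the next stimulus onset (or trace end);
#' otherwise `"transient"`.
#'
#' @param trace A `trial_trace`.
#' @param events Event onsets (data.frame with `onset` or numeric, ms).
#' @param threshold Persistence threshold on `max(S1, S2)`. Default 0.3.
#' @param dwell Minimum fraction of the interval above threshold.
#'   Default 0.8.
#' @return `"transient"` or `"sustained"`.
#' @export
classify_regime <- function(trace, events, threshold = 0.3, dwell = 0.8) {
  stopifnot(inherits(trace, "trial_trace"))
  onsets <- if (is.data.frame(events)) events$onset else as.numeric(events)
  ends <- c(onsets[-1], max(trace$t))
  smax <- pmax(trace$S1, trace$S2)
  for (k in seq_along(onsets)) {
    idx <- which(trace$t > onsets[k] & trace$t <= ends[k])
    if (!length(idx)) next
    if (mean(smax[idx] > threshold) >= dwell) return("sustained")
  }
  "transient"
}
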