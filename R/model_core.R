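#' Input-current to firing-rate transfer function
#'
#' Effective transfer function of a mean-field ensemble,
#' `r = (a*I - b) / (1 - exp(-d*(a*I - b)))`.  The removable singularity
#' at `a*I = b` is handled by the two-term Taylor expansion
#' `r ~ 1/d + (a*I - b)/2` when `|a*I - b| < 1e-6`.
#'
#' @param I Total synaptic input current (nA); vectorized.
#' @param p A [transfer_params()] object.
#' @return Firing rate (Hz), strictly positive and increasing in `I`.
#' @examples
#' firing_rate(0.4, transfer_params())  # at the singularity: 1/d
#' @export
firing_rate <- function(I, p = transfer_params()) {
  stopifnot(inherits(p, "transfer_params"))
  if (!is.numeric(I) || any(!is.finite(I)))
    stop("firing_rate: I must be finite numeric")
  x <- p$a * I - p$b
  r <- ifelse(abs(x) < 1e-6, 1 / p$d + 0.5 * x, x / (1 - exp(-p$d * x)))
  as.numeric(r)
}

#' Total synaptic input currents for both ensembles
#'
#' `I1 = Js*S1 - Jo*S2 + Istim1 + Inoise1` and symmetrically for `I2`:
#' self-coupling is excitatory, cross-coupling inhibitory.
#'
#' @param S1,S2 Gating variables, in `[0, 1]`; vectorized.
#' @param c A [couplings()] object.
#' @param Istim1,Istim2 External stimulus currents (nA).
#' @param Inoise1,Inoise2 Background noise currents (nA).
#' @return A list with components `I1` and `I2` (nA).
#' @export
total_inputs <- function(S1, S2, c, Istim1 = 0, Istim2 = 0,
                         Inoise1 = 0, Inoise2 = 0) {
  stopifnot(inherits(c, "couplings"))
  if (any(S1 < 0 | S1 > 1) || any(S2 < 0 | S2 > 1))
    stop("total_inputs: S1, S2 must lie in [0, 1]")
  list(I1 = c$Js * S1 - c$Jo * S2 + Istim1 + Inoise1,
       I2 = c$Js * S2 - c$Jo * S1 + Istim2 + Inoise2)
}

#' One Euler-Maruyama update of the background noise current
#'
#' Ornstein-Uhlenbeck process with mean `Io` and correlation time
#' `tau_noise`; the stochastic increment is scaled as
#' `sigma_noise * sqrt(2*dt/tau_noise) * z` so that the stationary
#' standard deviation of the process equals `sigma_noise`.
#'
#' @param x Current value of the noise current (nA).
#' @param spec A [noise_spec()] object.
#' @param dt Time step (ms); should be well below `tau_noise`.
#' @param z A standard-normal draw.
#' @return Updated noise current (nA).
#' @export
step_ou_noise <- function(x, spec, dt, z) {
  stopifnot(inherits(spec, "noise_spec"), dt > 0)
  if (dt >= spec$tau_noise)
    warning("step_ou_noise: dt >= tau_noise, discretization is inaccurate")
  x + (dt / spec$tau_noise) * (spec$Io - x) +
    spec$sigma_noise * sqrt(2 * dt / spec$tau_noise) * z
}

#' Time derivative of the synaptic gating variable
#'
#' `dS/dt = -S/tau_s + (1 - S) * gamma * r`, with `tau_s` converted to
#' seconds so the result is in 1/s for `r` in Hz.
#'
#' @param S Gating variable, in `[0, 1]`.
#' @param r Ensemble firing rate (Hz), `>= 0`.
#' @param g A [gating_params()] object.
#' @return Rate of change of `S` (1/s).
#' @export
gating_derivative <- function(S, r, g = gating_params()) {
  stopifnot(inherits(g, "gating_params"))
  if (any(S < 0 | S > 1)) stop("gating_derivative: S must lie in [0, 1]")
  if (any(r < 0)) stop("gating_derivative: r must be >= 0")
  -S / (g$tau_s / 1000) + (1 - S) * g$gamma * r
}

#' Fixed point of the gating dynamics at constant rate
#'
#' Closed-form steady state `gamma*r*tau_s / (1 + gamma*r*tau_s)`
#' (with `tau_s` in seconds); used for initial conditions.
#'
#' @param r Firing rate (Hz), `>= 0`; vectorized.
#' @param g A [gating_params()] object.
#' @return Steady-state gating value in `[0, 1)`.
#' @export
steady_state_gating <- function(r, g = gating_params()) {
  stopifnot(inherits(g, "gating_params"))
  if (any(r < 0)) stop("steady_state_gating: r must be >= 0")
  grt <- g$gamma * r * (g$tau_s / 1000)
  grt / (1 + grt)
}

#' Integrate one stochastic trial of the two-ensemble circuit
#'
#' Explicit Euler-Maruyama integration of the coupled gating and noise
#' dynamics under a stimulus program.  A burn-in period precedes `t = 0`
#' of the program: pulses are absent during burn-in, but any sinusoidal
#' component of the program is evaluated continuously at negative times
#' and the noise process runs throughout.  Identical `seed` and inputs
#' give bit-identical output.
#'
#' @param spec A [model_spec()].
#' @param program A [stimulus_program()].
#' @param seed Integer RNG seed for the noise increments.
#' @param dt Integration step (ms); must equal the program grid step.
#' @param S_init Length-2 initial gating values; default is the gating
#'   fixed point at the firing rate produced by the mean background
#'   current `Io` alone.
#' @param burn_in Burn-in duration (ms) before `t = 0`. Default 500.
#' @param record_every Record every this-many integration steps
#'   (1 = full resolution; 10 gives a 1 ms grid at `dt = 0.1`).
#' @return A `trial_trace` list: `dt`, `record_every`, `t` (ms, from 0),
#'   `S1`, `S2`, `Inoise1`, `Inoise2`, `S_mean = (S1 + S2)/2`, `seed`.
#' @examples
#' prog <- proportional_series(amps = 0.3, duration = 600, lead = 200,
#'                             dt = 0.1)
#' spec <- model_spec(couplings(0.2, 0.1), noise_spec(0.32, 0.001))
#' tr <- integrate_trial(spec, prog, seed = 1, record_every = 10)
#' @export
integrate_trial <- function(spec, program, seed, dt = program$dt,
                            S_init = NULL, burn_in = 500,
                            record_every = 1) {
  stopifnot(inherits(spec, "model_spec"),
            inherits(program, "stimulus_program"))
  if (abs(dt - program$dt) > 1e-12)
    stop("integrate_trial: dt must match the program grid step")
  if (dt <= 0) stop("integrate_trial: dt must be > 0")

  n_burn <- round(burn_in / dt)
  n_steps <- round(program$duration / dt)
  n_total <- n_burn + n_steps

  if (is.null(S_init)) {
    r0 <- firing_rate(spec$noise$Io, spec$transfer)
    S_init <- rep(steady_state_gating(r0, spec$gating), 2)
  }
  stopifnot(length(S_init) == 2, all(S_init >= 0 & S_init <= 1))

  # external input per integration step, burn-in included
  stim <- program_input(program, n_burn = n_burn)

  set.seed(seed)
  z1 <- rnorm(n_total)
  z2 <- rnorm(n_total)

  out <- .integrate_core(dt, n_burn,
                         stim$istim1, stim$istim2, z1, z2,
                         spec$transfer$a, spec$transfer$b, spec$transfer$d,
                         spec$couplings$Js * spec$coupling_scale,
                         spec$couplings$Jo * spec$coupling_scale,
                         spec$noise$Io, spec$noise$sigma_noise,
                         spec$noise$tau_noise,
                         spec$gating$gamma, spec$gating$tau_s,
                         S_init[1], S_init[2], as.integer(record_every))

  t_rec <- seq(0, by = dt * record_every, length.out = length(out$S1))
  structure(list(dt = dt, record_every = record_every, t = t_rec,
                 S1 = out$S1, S2 = out$S2,
                 Inoise1 = out$Inoise1, Inoise2 = out$Inoise2,
                 S_mean = (out$S1 + out$S2) / 2, seed = seed),
            class = "trial_trace")
}

#' Sampling rate of a recorded trial trace
#' @param trace A `trial_trace`.
#' @return Samples per second of the recorded (possibly decimated) grid.
#' @export
trace_fs <- function(trace) {
  stopifnot(inherits(trace, "trial_trace"))
  1000 / (trace$dt * trace$record_every)
}
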