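# Independent reference implementations used as test oracles.  These are
# deliberately naive (plain R loops, direct formulas) and never share code
# with the package internals they check.

# Plain-R Euler-Maruyama integration of the two-ensemble system, mirroring
# the integrator's RNG usage (set.seed(seed); z1 then z2).
r_reference_integrate <- function(spec, program, seed, dt, burn_in = 500) {
  f <- function(I) {
    x <- spec$transfer$a * I - spec$transfer$b
    if (abs(x) < 1e-6) 1 / spec$transfer$d + x / 2
    else x / (1 - exp(-spec$transfer$d * x))
  }
  n_burn <- round(burn_in / dt)
  n_steps <- round(program$duration / dt)
  n_total <- n_burn + n_steps
  stim <- mfcircuit:::program_input(program, n_burn = n_burn)
  set.seed(seed)
  z1 <- rnorm(n_total); z2 <- rnorm(n_total)

  r0 <- firing_rate(spec$noise$Io, spec$transfer)
  S1 <- S2 <- steady_state_gating(r0, spec$gating)
  In1 <- In2 <- spec$noise$Io
  Js <- spec$couplings$Js * spec$coupling_scale
  Jo <- spec$couplings$Jo * spec$coupling_scale
  g <- spec$gating; ns <- spec$noise
  kick <- ns$sigma_noise * sqrt(2 * dt / ns$tau_noise)

  oS1 <- numeric(n_steps + 1); oS2 <- numeric(n_steps + 1)
  oI1 <- numeric(n_steps + 1); oI2 <- numeric(n_steps + 1)
  irec <- 1
  for (k in seq_len(n_total + 1) - 1) {
    if (k >= n_burn) {
      oS1[irec] <- S1; oS2[irec] <- S2
      oI1[irec] <- In1; oI2[irec] <- In2
      irec <- irec + 1
    }
    if (k == n_total) break
    I1 <- Js * S1 - Jo * S2 + stim$istim1[k + 1] + In1
    I2 <- Js * S2 - Jo * S1 + stim$istim2[k + 1] + In2
    S1 <- S1 + dt / 1000 * (-S1 / (g$tau_s / 1000) + (1 - S1) * g$gamma * f(I1))
    S2 <- S2 + dt / 1000 * (-S2 / (g$tau_s / 1000) + (1 - S2) * g$gamma * f(I2))
    S1 <- min(max(S1, 0), 1); S2 <- min(max(S2, 0), 1)
    In1 <- In1 + dt / ns$tau_noise * (ns$Io - In1) + kick * z1[k + 1]
    In2 <- In2 + dt / ns$tau_noise * (ns$Io - In2) + kick * z2[k + 1]
  }
  list(S1 = oS1, S2 = oS2, Inoise1 = oI1, Inoise2 = oI2)
}

# Brute-force mean pairwise Pearson correlation.
brute_pairwise_cor <- function(mat) {
  n <- ncol(mat)
  vals <- c()
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      vals <- c(vals, cor(mat[, i], mat[, j]))
  mean(vals)
}

# Textbook paired t statistic.
textbook_paired_t <- function(x, y) {
  d <- y - x
  n <- length(d)
  tval <- mean(d) / (sd(d) / sqrt(n))
  list(t = tval, p = 2 * pt(-abs(tval), df = n - 1), df = n - 1)
}

# Tiny default model used across tests (transient-range cell).
tiny_spec <- function(Js = 0.2, Jo = 0.1, Io = 0.32, sigma = 0.001, ...) {
  model_spec(couplings(Js, Jo), noise_spec(Io, sigma), ...)
}
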