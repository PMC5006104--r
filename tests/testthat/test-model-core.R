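test_that("transfer function matches direct evaluation and handles the singularity", {
  p <- transfer_params()
  # removable singularity at a*I = b: limit is 1/d
  expect_equal(firing_rate(p$b / p$a, p), 1 / p$d, tolerance = 1e-9)
  # direct high-precision evaluation at I = 0 and I = 1 nA
  expect_equal(firing_rate(0, p), -108 / (1 - exp(0.154 * 108)),
               tolerance = 1e-12)
  expect_equal(firing_rate(0, p), 6.512e-6, tolerance = 1e-3)
  expect_equal(firing_rate(1, p), 162 / (1 - exp(-0.154 * 162)),
               tolerance = 1e-12)
  expect_equal(firing_rate(1, p), 162.0, tolerance = 1e-8)
  # continuity across the singularity
  eps <- 1e-9
  expect_equal(firing_rate((p$b - eps) / p$a, p),
               firing_rate((p$b + eps) / p$a, p), tolerance = 1e-6)
  expect_error(firing_rate(NaN, p), "finite")
})

test_that("transfer function is strictly increasing and positive on a fine grid", {
  I <- seq(-1, 2, length.out = 1000)
  r <- firing_rate(I)
  expect_true(all(r > 0))
  expect_true(all(diff(r) > 0))
})

test_that("total synaptic inputs follow the coupling equation and its symmetry", {
  expect_equal(total_inputs(0, 0, couplings(0.3, 0.1)), list(I1 = 0, I2 = 0))
  # self and cross terms cancel exactly when Js = Jo and S1 = S2
  ti <- total_inputs(0.5, 0.5, couplings(0.35, 0.35),
                     Inoise1 = 0.32, Inoise2 = 0.32)
  expect_equal(ti$I1, 0.32)
  expect_equal(ti$I2, 0.32)
  # hand arithmetic
  ti <- total_inputs(1, 0, couplings(0.33, 0.01))
  expect_equal(ti$I1, 0.33)
  expect_equal(ti$I2, -0.01)
  # exchanging ensemble labels exchanges outputs
  a <- total_inputs(0.2, 0.7, couplings(0.4, 0.2), 0.1, 0.3, 0.05, 0.02)
  b <- total_inputs(0.7, 0.2, couplings(0.4, 0.2), 0.3, 0.1, 0.02, 0.05)
  expect_identical(a$I1, b$I2)
  expect_identical(a$I2, b$I1)
})

test_that("OU noise update has the stated fixed point, decay, and stationary SD", {
  spec <- noise_spec(Io = 0.3, sigma_noise = 0)
  expect_equal(step_ou_noise(0.3, spec, dt = 1, z = 0.7), 0.3)
  # closed-form one-step decay under explicit Euler
  expect_equal(step_ou_noise(1.3, spec, dt = 1, z = 0), 0.3 + 0.9)
  expect_warning(step_ou_noise(0.3, spec, dt = 20, z = 0), "dt")

  # long-run stationary SD equals sigma_noise (AR(1) recursion; verified
  # below to be the identical update rule as step_ou_noise)
  sigma <- 0.02; dt <- 0.25; tau <- 10
  sp <- noise_spec(Io = 0, sigma_noise = sigma, tau_noise = tau)
  set.seed(11)
  n <- 1e6
  z <- rnorm(n)
  kick <- sigma * sqrt(2 * dt / tau) * z
  x <- as.numeric(stats::filter(kick, 1 - dt / tau, method = "recursive"))
  xi <- 0
  for (k in 1:50) {
    xi <- step_ou_noise(xi, sp, dt, z[k])
    expect_equal(xi, x[k], tolerance = 1e-12)
  }
  # allowance: Monte-Carlo error (3 SE with ~n*dt/(2*tau) effective
  # samples) plus the O(dt/tau) Euler discretization bias
  n_eff <- n * dt / (2 * tau)
  se_sd <- sigma / sqrt(2 * n_eff)
  bias <- sigma * (sqrt(2 / (2 - dt / tau)) - 1)
  expect_lt(abs(sd(x[1000:n]) - sigma), 3 * se_sd + bias)
  # stationary mean ~ Io and autocorrelation time ~ tau_noise (20%)
  expect_lt(abs(mean(x[1000:n])), 4 * sigma / sqrt(n_eff))
  lags <- seq(4, 80, by = 4)  # 1..20 ms in steps of dt = 0.25 ms
  ac <- acf(x[1000:n], lag.max = 80, plot = FALSE)$acf[, 1, 1]
  tau_hat <- -1 / coef(lm(log(ac[lags + 1]) ~ I(lags * dt)))[2]
  expect_lt(abs(tau_hat - tau) / tau, 0.2)
})

test_that("gating derivative and its closed-form fixed point agree", {
  g <- gating_params()
  expect_equal(gating_derivative(0, 0, g), 0)
  expect_equal(gating_derivative(1, 55, g), -10)  # saturation: -1/tau_s
  expect_equal(gating_derivative(0.5, 10, g), -5 + 0.5 * 0.641 * 10)
  expect_equal(steady_state_gating(0, g), 0)
  expect_equal(steady_state_gating(10, g), 0.641 / 1.641, tolerance = 1e-9)
  expect_gt(steady_state_gating(1e6, g), 0.9999)
  # derivative vanishes at the fixed point
  for (r in c(0.5, 3, 20, 120))
    expect_equal(gating_derivative(steady_state_gating(r, g), r, g), 0,
                 tolerance = 1e-10)
})

test_that("integrator reproduces a plain-R reference implementation", {
  spec <- tiny_spec(sigma = 0.01)
  prog <- proportional_series(amps = c(0.2, 0.5), isi = 150, lead = 50,
                              dt = 0.5)
  tr <- integrate_trial(spec, prog, seed = 9, dt = 0.5, burn_in = 100)
  ref <- r_reference_integrate(spec, prog, seed = 9, dt = 0.5,
                               burn_in = 100)
  expect_equal(tr$S1, ref$S1, tolerance = 1e-12)
  expect_equal(tr$S2, ref$S2, tolerance = 1e-12)
  expect_equal(tr$Inoise1, ref$Inoise1, tolerance = 1e-12)
})

test_that("integration is deterministic, bounded, and label-symmetric", {
  spec <- tiny_spec(sigma = 0.02)
  prog <- proportional_series(amps = c(0.3, 0.6), isi = 200, lead = 100)
  t1 <- integrate_trial(spec, prog, seed = 5, record_every = 10)
  t2 <- integrate_trial(spec, prog, seed = 5, record_every = 10)
  expect_identical(t1, t2)
  expect_true(all(t1$S1 >= 0 & t1$S1 <= 1))
  expect_true(all(t1$S2 >= 0 & t1$S2 <= 1))
  expect_equal(t1$S_mean, (t1$S1 + t1$S2) / 2)

  # identical deterministic inputs to both ensembles -> identical traces
  spec0 <- tiny_spec(Js = 0.3, Jo = 0.2, sigma = 0)
  ev <- data.frame(onset = c(100, 400), amp1 = c(0.4, 0.4),
                   amp2 = c(0.4, 0.4))
  progsym <- stimulus_program(ev, duration = 700)
  ts <- integrate_trial(spec0, progsym, seed = 3)
  expect_identical(ts$S1, ts$S2)
})

test_that("near-zero background keeps gating near zero", {
  spec <- model_spec(couplings(0.2, 0.1), noise_spec(Io = 0, sigma_noise = 0))
  prog <- stimulus_program(data.frame(onset = numeric(0),
                                      amp1 = numeric(0), amp2 = numeric(0)),
                           duration = 2000)
  tr <- integrate_trial(spec, prog, seed = 1, S_init = c(0, 0),
                        record_every = 10)
  expect_lt(max(tr$S1, tr$S2), 1e-3)
})

test_that("halving the integration step changes the trajectory negligibly", {
  spec <- tiny_spec(Js = 0.3, Jo = 0.2, sigma = 0)
  ev <- data.frame(onset = c(300, 1100), amp1 = c(0.3, 0.2),
                   amp2 = c(0.2, 0.3))
  tr1 <- integrate_trial(spec, stimulus_program(ev, duration = 2000,
                                                dt = 0.1),
                         seed = 1, record_every = 10)
  tr2 <- integrate_trial(spec, stimulus_program(ev, duration = 2000,
                                                dt = 0.05),
                         seed = 1, dt = 0.05, record_every = 20)
  expect_lt(max(abs(tr1$S1 - tr2$S1)), 1e-3)
  expect_lt(max(abs(tr1$S2 - tr2$S2)), 1e-3)
})

test_that("persistent activity appears only in the high-coupling regime", {
  # high self-excitation + high cross-inhibition: a single pulse drives
  # winner-take-all activity that persists >= 1 s after stimulus offset
  ev <- data.frame(onset = 200, amp1 = 0.5, amp2 = 0)
  prog <- stimulus_program(ev, duration = 2200)
  hi <- integrate_trial(model_spec(couplings(0.65, 0.33),
                                   noise_spec(0.32, 0.001)),
                        prog, seed = 2, record_every = 10)
  late <- hi$t > 1210  # >= 1 s after pulse offset
  expect_true(all(hi$S1[late] > 0.5))
  expect_true(all(hi$S2[late] < 0.1))
  # low couplings: the response decays back within 1 s
  lo <- integrate_trial(model_spec(couplings(0.17, 0.01),
                                   noise_spec(0.32, 0.001)),
                        prog, seed = 2, record_every = 10)
  base <- mean(lo$S1[lo$t < 200])
  expect_lt(max(lo$S1[late]), base + 0.05)
})

test_that("integration surfaces divergence instead of clipping", {
  # a coarse step with a strong input overshoots S past 1 + 1e-6
  spec <- model_spec(couplings(0.7, 0.01), noise_spec(0.5, 0))
  ev <- data.frame(onset = 10, amp1 = 3, amp2 = 0)
  prog <- stimulus_program(ev, duration = 200, dt = 5)
  expect_error(integrate_trial(spec, prog, seed = 1, dt = 5, burn_in = 0),
               "overshoot")
})
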