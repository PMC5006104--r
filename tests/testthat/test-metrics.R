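test_that("trial-by-trial reliability matches a brute-force pairwise oracle", {
  x <- sin(seq(0, 4 * pi, length.out = 50))
  rs_same <- response_set(cbind(x, x, x), fs = 1000)
  expect_equal(tbt_reliability(rs_same), 1.0)
  rs_neg <- response_set(cbind(x, -x), fs = 1000)
  expect_equal(tbt_reliability(rs_neg), -1.0)

  m <- cbind(c(1, 3, 2, 5, 4), c(2, 2, 3, 6, 3),
             c(0, 4, 1, 5, 5), c(1, 1, 4, 4, 2))
  expect_equal(tbt_reliability(response_set(m, fs = 1000)),
               brute_pairwise_cor(m), tolerance = 1e-12)

  # constant trials are excluded with a warning; all-excluded errors
  mc <- cbind(x, x, rep(0.3, 50))
  expect_warning(r <- tbt_reliability(response_set(mc, fs = 1000)),
                 "constant")
  expect_equal(r, 1.0)
  expect_error(suppressWarnings(
    tbt_reliability(response_set(cbind(rep(1, 10), rep(2, 10)), fs = 1000))),
    "undefined")
  expect_error(tbt_reliability(response_set(cbind(x), fs = 1000)), ">= 2")
})

test_that("reliability and I-O amplitude are invariant to affine rescaling", {
  set.seed(2)
  stim <- filter_waveform(c(rep(0, 20), rep(1, 10), rep(0, 170)), dt = 1)
  trials <- sapply(1:4, function(k) stim + 0.1 * rnorm(200))
  rs <- response_set(trials, fs = 1000, stimulus = stim)
  rs2 <- response_set(5.5 * trials + 2, fs = 1000, stimulus = stim)
  expect_equal(tbt_reliability(rs), tbt_reliability(rs2),
               tolerance = 1e-10)
  expect_equal(io_correlation(rs)$io_amp, io_correlation(rs2)$io_amp,
               tolerance = 1e-10)
})

test_that("I-O correlation recovers self-correlation and a known kernel decay", {
  dt <- 1
  raw <- numeric(600)
  for (on in c(50, 250, 450)) raw[on:(on + 9)] <- 0.5
  stim <- filter_waveform(raw, tau = 10, dt = dt)
  # response identical to the stimulus: peak correlation 1 at zero lag,
  # and the fitted decay equals the stimulus autocorrelogram decay
  rs_self <- response_set(cbind(stim, stim), fs = 1000, stimulus = stim)
  io_self <- io_correlation(rs_self)
  expect_equal(io_self$io_amp, 1.0, tolerance = 1e-10)
  expect_equal(which.max(io_self$correlogram), 1L)

  # response = stimulus convolved with exp(-t/20 ms): fitted decay close
  # to the decay of the correlogram of the known kernel
  ker <- exp(-(0:150) / 20)
  resp <- as.numeric(stats::filter(c(stim, numeric(150)), ker,
                                   method = "convolution", sides = 1))
  resp <- resp[seq_along(stim)]
  resp[is.na(resp)] <- 0
  rs_k <- response_set(cbind(resp, resp), fs = 1000, stimulus = stim)
  io_k <- io_correlation(rs_k)
  # oracle: least-squares exponential decay of the averaged correlogram
  # recovered by brute grid search over tau
  cc <- io_k$correlogram
  p <- which.max(cc)
  y <- cc[p:101]; l <- 0:(101 - p)
  sse <- vapply(seq(1, 100, by = 0.05), function(tau) {
    basis <- exp(-l / tau)
    A <- sum(y * basis) / sum(basis^2)
    sum((y - A * basis)^2)
  }, numeric(1))
  tau_oracle <- seq(1, 100, by = 0.05)[which.min(sse)]
  expect_equal(io_k$io_tau, tau_oracle, tolerance = 0.02)
  # and the fitted decay tracks the known 20 ms kernel timescale
  expect_lt(abs(io_k$io_tau - 20) / 20, 0.35)

  # white-noise response uncorrelated with the stimulus
  set.seed(33)
  wn <- matrix(rnorm(600 * 8), 600, 8)
  io_w <- io_correlation(response_set(wn, fs = 1000, stimulus = stim))
  se <- 1 / sqrt(600 - 101)
  expect_lt(abs(io_w$io_amp), 5 * se)
  expect_error(io_correlation(response_set(wn, fs = 1000,
                                           stimulus = rep(1, 600))),
               "non-constant")
})

test_that("T50 of continuous traces matches closed-form and quadrature oracles", {
  fs <- 1000
  n <- 400
  ev <- 100
  # instantaneous sustained step at the event: uniform accumulation -> 50 ms
  step <- c(rep(0, ev), rep(1, n - ev))
  rs <- response_set(cbind(step, step), fs = fs, event_times = ev)
  expect_equal(t50_model(rs), 50, tolerance = 0.5)
  # impulse concentrated at +20 ms
  imp <- numeric(n); imp[ev + 20 + 1] <- 1
  rs_i <- response_set(cbind(imp), fs = fs, event_times = ev)
  expect_equal(t50_model(rs_i), 20, tolerance = 1)
  # exponential decay exp(-t/tau): t50 solves the cumulative equation,
  # checked against numerical quadrature
  tau <- 30
  expdec <- c(rep(0, ev), exp(-(0:(n - ev - 1)) / tau))
  rs_e <- response_set(cbind(expdec), fs = fs, event_times = ev)
  tt <- seq(0, 100, by = 0.01)
  cumq <- cumsum(exp(-tt / tau)); cumq <- cumq / cumq[length(cumq)]
  t50_oracle <- tt[which(cumq >= 0.5)[1]]
  expect_equal(t50_model(rs_e), t50_oracle, tolerance = 1)
  # degenerate profiles are surfaced
  rs_z <- response_set(cbind(rep(0, n)), fs = fs, event_times = ev)
  expect_error(t50_model(rs_z), "non-positive")
})

test_that("T50 of spike trains matches analytic profiles", {
  ev <- c(500, 1500)
  # all spikes exactly 30 ms post-event
  ss <- spike_set(list(sort(ev + 30), sort(ev + 30)), event_times = ev)
  expect_equal(t50_spikes(ss), 30, tolerance = 1)
  # uniform spikes on [10, 80] ms -> midpoint 45 ms
  set.seed(4)
  sp <- sort(unlist(lapply(ev, function(e) e + runif(4000, 10, 80))))
  expect_equal(t50_spikes(spike_set(list(sp), event_times = ev)), 45,
               tolerance = 1.5)
  # inhomogeneous-Poisson spikes from an exponential rate profile:
  # t50 matches the profile's analytic half-mass point within 2 ms
  tau <- 25
  lam <- function(u) exp(-(u - 10) / tau) * (u >= 10)
  tt <- seq(10, 80, by = 0.01)
  cum <- cumsum(lam(tt)); cum <- cum / cum[length(cum)]
  t50_true <- tt[which(cum >= 0.5)[1]]
  set.seed(5)
  events <- seq(200, by = 200, length.out = 50)
  spikes <- sort(unlist(lapply(events, function(e) {
    u <- seq(10, 80, by = 1)
    counts <- rpois(length(u), 4 * lam(u))
    rep(e + u, counts) + runif(sum(counts))
  })))
  expect_equal(t50_spikes(spike_set(list(spikes), event_times = events)),
               t50_true, tolerance = 2)
  expect_error(t50_spikes(spike_set(list(ev + 200), event_times = ev)),
               "no spikes")
})

test_that("band power scales quadratically and separates frequencies", {
  fs <- 200
  t <- seq(0, 10, by = 1 / fs)
  s2 <- sin(2 * pi * 2 * t)
  p1 <- band_power(0.3 * s2, fs, freq = 2)
  p2 <- band_power(0.6 * s2, fs, freq = 2)
  expect_equal(p2 / p1, 4, tolerance = 0.05)
  s5 <- sin(2 * pi * 5 * t)
  expect_lt(band_power(s5, fs, freq = 2) / band_power(s5, fs, freq = 5),
            0.01)
  expect_error(band_power(s2[1:150], fs, freq = 2), "two cycles")
})

test_that("response amplitude recovers known baseline-subtracted peaks", {
  n <- 1000; fs <- 1000
  ev <- c(200, 600)
  x <- rep(0.2, n)
  x[(ev[1] + 1):(ev[1] + 50)] <- 0.2 + 0.5 * sin(seq(0, pi, length.out = 50))
  x[(ev[2] + 1):(ev[2] + 50)] <- 0.2 + 0.3 * sin(seq(0, pi, length.out = 50))
  rs <- response_set(cbind(x), fs = fs, event_times = ev)
  expect_equal(response_amplitude(rs), 0.4, tolerance = 1e-3)
  zero <- response_set(cbind(rep(0, n)), fs = fs, event_times = ev)
  expect_equal(response_amplitude(zero), 0)
})

test_that("LFP preprocessing preserves the passband and removes the stopband", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  dc <- rep(1.5, length(t))
  out <- preprocess_lfp(dc, fs)
  expect_equal(out$fs, 200)
  # interior samples (filtfilt has edge transients)
  expect_equal(mean(out$trace[50:350]), 1.5, tolerance = 1e-3)
  s10 <- sin(2 * pi * 10 * t)
  out10 <- preprocess_lfp(s10, fs)
  mid <- out10$trace[50:350]
  expect_equal(max(abs(mid)), 1, tolerance = 0.02)
  s150 <- sin(2 * pi * 150 * t)
  out150 <- preprocess_lfp(s150, fs)
  expect_lt(max(abs(out150$trace[50:350])), 0.05)
  expect_error(preprocess_lfp(dc, 300), ">= 400")
  expect_error(preprocess_lfp(dc, 500), "multiple")
})

test_that("paired comparison matches the textbook formula and handles degeneracy", {
  ctl <- c(10.2, 11.5, 9.8, 12.0, 10.9, 11.1, 10.4)
  mod <- c(11.0, 12.1, 10.5, 12.2, 11.8, 11.0, 11.5)
  res <- paired_comparison(ctl, mod)
  oracle <- textbook_paired_t(ctl, mod)
  expect_equal(res$t, oracle$t, tolerance = 1e-10)
  expect_equal(res$p, oracle$p, tolerance = 1e-10)
  expect_equal(res$df, 6)
  same <- paired_comparison(ctl, ctl)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(paired_comparison(ctl, ctl + 2), "zero variance")
})
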