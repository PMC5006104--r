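#' Transfer-function parameters
#'
#' Parameters of the effective input-current to firing-rate transfer
#' function `r = (a*I - b) / (1 - exp(-d*(a*I - b)))` used for each
#' mean-field ensemble.
#'
#' @param a Gain (Hz/nA). Default 270.
#' @param b Threshold (Hz). Default 108.
#' @param d Curvature (s). Default 0.154.
#' @return An object of class `transfer_params`.
#' @export
transfer_params <- function(a = 270, b = 108, d = 0.154) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(d),
            length(a) == 1, length(b) == 1, length(d) == 1)
  if (!all(is.finite(c(a, b, d))) || a <= 0 || b <= 0 || d <= 0)
    stop("transfer_params: a, b, d must be finite and > 0")
  structure(list(a = a, b = b, d = d), class = "transfer_params")
}

#' Synaptic coupling parameters
#'
#' Effective self-coupling `Js` (net self-excitation) and cross-coupling
#' magnitude `Jo` (net cross-inhibition; enters the input equations with a
#' negative sign and is stored as a magnitude `|Jo| >= 0`).  The model is
#' symmetric: one `Js` and one `Jo` apply to both ensembles.
#'
#' @param Js Self-coupling (nA), `>= 0`.
#' @param Jo Cross-coupling magnitude (nA), `>= 0`.
#' @return An object of class `couplings`.
#' @export
couplings <- function(Js, Jo) {
  stopifnot(is.numeric(Js), is.numeric(Jo), length(Js) == 1, length(Jo) == 1)
  if (!all(is.finite(c(Js, Jo))) || Js < 0 || Jo < 0)
    stop("couplings: Js and Jo must be finite and >= 0 (Jo is a magnitude)")
  structure(list(Js = Js, Jo = Jo), class = "couplings")
}

#' Background-noise specification
#'
#' Ornstein-Uhlenbeck background current with mean `Io`, stationary
#' standard deviation `sigma_noise`, and correlation time `tau_noise`.
#' The two ensembles receive statistically independent realizations.
#'
#' @param Io Background mean current (nA).
#' @param sigma_noise Noise amplitude (nA), stationary SD of the process.
#' @param tau_noise Correlation time (ms). Default 10.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(Io, sigma_noise, tau_noise = 10) {
  stopifnot(is.numeric(Io), is.numeric(sigma_noise), is.numeric(tau_noise))
  if (!all(is.finite(c(Io, sigma_noise, tau_noise))) ||
      sigma_noise < 0 || tau_noise <= 0)
    stop("noise_spec: need finite Io, sigma_noise >= 0, tau_noise > 0")
  structure(list(Io = Io, sigma_noise = sigma_noise, tau_noise = tau_noise),
            class = "noise_spec")
}

#' Synaptic gating dynamics parameters
#'
#' @param gamma Saturation factor, in (0, 1]. Default 0.641.
#' @param tau_s Network (gating) time constant (ms). Default 100.
#' @return An object of class `gating_params`.
#' @export
gating_params <- function(gamma = 0.641, tau_s = 100) {
  stopifnot(is.numeric(gamma), is.numeric(tau_s))
  if (!all(is.finite(c(gamma, tau_s))) || gamma <= 0 || gamma > 1 ||
      tau_s <= 0)
    stop("gating_params: need gamma in (0,1] and tau_s > 0")
  structure(list(gamma = gamma, tau_s = tau_s), class = "gating_params")
}

#' Full model specification for one circuit instance
#'
#' Bundles transfer-function, coupling, noise, and gating parameters.
#'
#' @param couplings A [couplings()] object (required: `Js`, `Jo` are the
#'   swept parameters and have no universal default).
#' @param noise A [noise_spec()] object.
#' @param transfer A [transfer_params()] object.
#' @param gating A [gating_params()] object.
#' @param coupling_scale Factor by which the couplings weight the gating
#'   variables in the recurrent currents, i.e.
#'   `I1 = Js*scale*S1 - Jo*scale*S2 + Istim1 + Inoise1`.  The default
#'   (`NULL`) uses `gating$gamma`, so the couplings weight the saturating
#'   synaptic drive `gamma*S`: under this convention the transient
#'   operating range (`Js` up to 0.37 nA at `Io = 0.32` nA) is genuinely
#'   transient and the winner-take-all regime begins only in the upper
#'   half of the full coupling range.  Setting `coupling_scale = 1`
#'   weights `S` directly, which makes every model with
#'   `Js` above roughly 0.29 nA bistable at that background level (see
#'   the methods vignette for the fixed-point analysis).
#' @return An object of class `model_spec`.
#' @examples
#' spec <- model_spec(couplings(0.35, 0.01), noise_spec(0.32, 0.02))
#' @export
model_spec <- function(couplings, noise,
                       transfer = transfer_params(),
                       gating = gating_params(),
                       coupling_scale = NULL) {
  stopifnot(inherits(couplings, "couplings"),
            inherits(noise, "noise_spec"),
            inherits(transfer, "transfer_params"),
            inherits(gating, "gating_params"))
  if (is.null(coupling_scale)) coupling_scale <- gating$gamma
  stopifnot(is.numeric(coupling_scale), coupling_scale > 0)
  structure(list(transfer = transfer, couplings = couplings,
                 noise = noise, gating = gating,
                 coupling_scale = coupling_scale),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>\n")
  cat(sprintf("  couplings: Js = %g nA, Jo = %g nA (drive scale %g)\n",
              x$couplings$Js, x$couplings$Jo, x$coupling_scale))
  cat(sprintf("  noise:     Io = %g nA, sigma = %g nA, tau = %g ms\n",
              x$noise$Io, x$noise$sigma_noise, x$noise$tau_noise))
  cat(sprintf("  transfer:  a = %g Hz/nA, b = %g Hz, d = %g s\n",
              x$transfer$a, x$transfer$b, x$transfer$d))
  cat(sprintf("  gating:    gamma = %g, tau_s = %g ms\n",
              x$gating$gamma, x$gating$tau_s))
  invisible(x)
}
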