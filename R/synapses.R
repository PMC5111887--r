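#' Synapse parameters
#'
#' Kinetic parameters for one synapse type. AMPA, NMDA and GABA-A follow a
#' first-order transmitter-gated activation scheme (open fraction `[O]`
#' driven by a brief transmitter pulse on each presynaptic spike); GABA-B
#' uses a second-order G-protein cascade with a quartic activation
#' nonlinearity acting on a K+ channel.
#'
#' @param type `"AMPA"`, `"NMDA"`, `"GABA_A"` or `"GABA_B"`.
#' @param g_syn Maximal conductance (uS).
#' @param tau_scale GABA-A decay-time scale factor (>= 1 only in propofol
#'   mode; divides the closing rate).
#' @param constants Constants list.
#' @return List of class `synapse_params`.
#' @export
synapse_params <- function(type = c("AMPA", "NMDA", "GABA_A", "GABA_B"),
                           g_syn = 1, tau_scale = 1,
                           constants = somnet_constants()) {
  type <- match.arg(type)
  stopifnot(g_syn >= 0, tau_scale > 0)
  k <- constants$synapse
  rev <- constants$reversals
  p <- switch(type,
    AMPA = list(alpha = k$ampa$alpha, beta = k$ampa$beta, e_rev = rev$e_ampa),
    NMDA = list(
      alpha = k$nmda$alpha, beta = k$nmda$beta, e_rev = rev$e_ampa,
      mg_vhalf = k$nmda$mg_vhalf, mg_slope = k$nmda$mg_slope
    ),
    GABA_A = list(alpha = k$gabaa$alpha, beta = k$gabaa$beta / tau_scale, e_rev = rev$e_gaba),
    GABA_B = list(
      k1 = k$gabab$k1, k2 = k$gabab$k2, k3 = k$gabab$k3, k4 = k$gabab$k4,
      kd = k$gabab$kd, n = k$gabab$hill, e_rev = rev$e_k
    )
  )
  p$type <- type
  p$g_syn <- g_syn
  p$tau_scale <- tau_scale
  p$t_pulse_mM <- k$t_pulse_mM
  p$t_pulse_ms <- k$t_pulse_ms
  structure(p, class = "synapse_params")
}

#' Instantaneous synaptic current
#'
#' `I = L * g_syn * efficacy * [O] * (V_post - E_rev)` (nA when `g_syn` is in
#' uS and voltages in mV). `L` is the neuromodulator scaling factor (LACh for
#' AMPA on the scaled projections, LGABA for GABA-A). For NMDA the sigmoidal
#' magnesium-block factor multiplies the conductance. Positive values are
#' outward currents (the membrane equations subtract synaptic currents).
#'
#' @param open Open fraction `[O]` in `[0,1]` (for GABA-B: the activated
#'   K-channel fraction).
#' @param params [synapse_params()].
#' @param v_post Postsynaptic voltage (mV).
#' @param l_scale Neuromodulator scale factor (> 0).
#' @param efficacy Short-term depression efficacy in (0,1].
#' @return Current in nA.
#' @export
synaptic_current <- function(open, params, v_post, l_scale = 1, efficacy = 1) {
  stopifnot(l_scale > 0, open >= 0, open <= 1)
  g <- l_scale * params$g_syn * efficacy * open
  if (params$type == "NMDA") {
    g <- g / (1 + exp(-(v_post - params$mg_vhalf) / params$mg_slope))
  }
  g * (v_post - params$e_rev)
}

#' Advance a first-order synapse open fraction
#'
#' Exact piecewise-exponential update of `d[O]/dt = alpha T (1-[O]) - beta [O]`
#' where the transmitter `T` is `t_pulse_mM` during a pulse and 0 otherwise.
#'
#' @param open Current open fraction.
#' @param params [synapse_params()] (AMPA, NMDA or GABA-A).
#' @param dt Step (ms).
#' @param transmitter_on Is a transmitter pulse active during this step?
#' @return Updated open fraction.
#' @export
synapse_open_step <- function(open, params, dt, transmitter_on = FALSE) {
  if (transmitter_on) {
    at <- params$alpha * params$t_pulse_mM
    o_inf <- at / (at + params$beta)
    o_inf + (open - o_inf) * exp(-(at + params$beta) * dt)
  } else {
    open * exp(-params$beta * dt)
  }
}

#' Miniature-PSP release hazard
#'
#' Instantaneous release rate (per ms) of the miniature-PSP point process as
#' a function of the time since the last presynaptic spike:
#' `(2/(1 + exp(-dt/20)) - 1)/250`. The rate is zero immediately after a
#' spike and saturates at 1/250 per ms.
#'
#' @param delta_t Time since last presynaptic spike (ms), non-negative.
#' @param constants Constants list.
#' @return Rate per ms, vectorized.
#' @examples
#' mini_rate(0)      # 0
#' mini_rate(1e6)    # ~ 1/250
#' @export
mini_rate <- function(delta_t, constants = somnet_constants()) {
  if (any(delta_t < 0)) stop("delta_t must be non-negative")
  m <- constants$synapse$mini
  (2 / (1 + exp(-delta_t / m$rate_tau)) - 1) / m$rate_cap
}

# integrated hazard H(delta) with closed form (see mini_rate)
mini_hazard_integral <- function(delta_t, constants = somnet_constants()) {
  m <- constants$synapse$mini
  tau <- m$rate_tau
  (2 * tau * log((1 + exp(delta_t / tau)) / 2) - delta_t) / m$rate_cap
}

#' Sample the next miniature release time
#'
#' Draws the waiting time from the inhomogeneous Poisson process whose hazard
#' is [mini_rate()], by inverting the integrated hazard (Newton iteration on
#' the closed form). The process is reset at each presynaptic spike.
#'
#' @param u Uniform(0,1) random draw (supply for reproducibility; default
#'   draws from the session RNG).
#' @param constants Constants list.
#' @return Waiting time (ms) since the last presynaptic spike.
#' @export
mini_next_release <- function(u = runif(1), constants = somnet_constants()) {
  m <- constants$synapse$mini
  target <- -log(u)
  # initial guess from the asymptotic linear branch of H
  d <- max(10, m$rate_cap * target + 2 * m$rate_tau * log(2))
  for (i in 1:60) {
    f <- mini_hazard_integral(d, constants) - target
    fp <- mini_rate(d, constants)
    step <- f / max(fp, 1e-12)
    d <- max(d - step, d / 2)
    if (abs(step) < 1e-9) break
  }
  d
}

#' Advance a GABA-B synapse
#'
#' Second-order scheme: transmitter binds receptor `R` which catalyzes
#' G-protein `G` production; the K+ channel activation is
#' `G^n / (G^n + Kd)` with `n = 4`. The response has a characteristically
#' slower onset than GABA-A and saturates below 1 under sustained input.
#'
#' @param state Named vector/list with `r` (bound receptor) and `g`
#'   (G-protein concentration).
#' @param params [synapse_params]`("GABA_B")`.
#' @param dt Step (ms), positive.
#' @param transmitter_on Is a transmitter pulse active?
#' @return Named vector with updated `r`, `g`, and `act` (channel activation).
#' @export
gabab_step <- function(state, params = synapse_params("GABA_B"), dt = 0.02,
                       transmitter_on = FALSE) {
  if (dt <= 0) stop("dt must be positive")
  s <- as.list(state)
  tconc <- if (transmitter_on) params$t_pulse_mM else 0
  nsub <- max(1L, ceiling(dt / 0.1))
  h <- dt / nsub
  r <- s$r
  g <- s$g
  for (i in seq_len(nsub)) {
    dr <- params$k1 * tconc * (1 - r) - params$k2 * r
    dg <- params$k3 * r - params$k4 * g
    r <- min(max(r + h * dr, 0), 1)
    g <- max(g + h * dg, 0)
  }
  gn <- g^params$n
  c(r = r, g = g, act = gn / (gn + params$kd))
}

#' Short-term synaptic depression step
#'
#' Multiplicative use-dependent depression with exponential recovery:
#' on a presynaptic spike the efficacy drops to `efficacy * (1 - use)`;
#' otherwise it recovers toward 1 with time constant `tau_rec`.
#'
#' @param efficacy Current efficacy in (0, 1].
#' @param spike Did the presynaptic cell spike at this step?
#' @param dt Step (ms).
#' @param use Use fraction per spike.
#' @param tau_rec Recovery time constant (ms).
#' @return Updated efficacy.
#' @export
depression_step <- function(efficacy, spike = FALSE, dt = 0.02,
                            use = somnet_constants()$synapse$depression$use,
                            tau_rec = somnet_constants()$synapse$depression$tau_rec) {
  stopifnot(efficacy > 0, efficacy <= 1)
  e <- 1 + (efficacy - 1) * exp(-dt / tau_rec)
  if (spike) e <- e * (1 - use)
  e
}
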