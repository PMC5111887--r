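#' h-current steady-state activation
#'
#' Voltage activation curve of the hyperpolarization-activated cation current
#' in thalamocortical relay cells, `1 / (1 + exp((V + 75 + shift) / 5.5))`.
#' The histamine level acts on the h-current through `shift` (mV): higher
#' histamine corresponds to a more positive (less negative) shift, moving the
#' activation curve rightward and increasing activation at a fixed voltage.
#'
#' @param v Membrane voltage (mV), vectorized.
#' @param shift Activation-curve shift (mV), e.g. `-8` awake, `-3` N2,
#'   `-2` N3, `0` REM.
#' @return Activation fraction in (0, 1).
#' @examples
#' h_inf(-75, 0)    # exactly 0.5
#' h_inf(-67, -8)   # exactly 0.5
#' @export
h_inf <- function(v, shift = 0) {
  stopifnot(is.finite(v), is.finite(shift))
  k <- somnet_constants()$ih
  1 / (1 + exp((v + k$vhalf + shift) / k$slope))
}

#' Cell parameters for one of the four cell types
#'
#' Assembles the full parameter set (conductance densities, reversal
#' potentials, compartment areas, kinetic constants) for a pyramidal (PY),
#' interneuron (IN), thalamocortical relay (TC) or reticular (RE) cell from
#' the constants file.
#'
#' @param kind One of `"PY"`, `"IN"`, `"TC"`, `"RE"`.
#' @param constants Constants list (see [somnet_constants()]).
#' @return A list of class `cell_params`.
#' @export
cell_params <- function(kind = c("PY", "IN", "TC", "RE"), constants = somnet_constants()) {
  kind <- match.arg(kind)
  k <- constants
  p <- switch(kind,
    PY = c(k$cortex$py, list(
      cm = k$cortex$cm, rho = k$areas$rho_py,
      area_soma = k$areas$soma_cm2, area_dend = k$areas$soma_cm2 * k$areas$rho_py
    )),
    IN = c(k$cortex$`in`, list(
      cm = k$cortex$cm, rho = k$areas$rho_in,
      area_soma = k$areas$soma_cm2, area_dend = k$areas$soma_cm2 * k$areas$rho_in
    )),
    TC = c(k$thalamus$tc, list(cm = k$thalamus$cm, area = k$areas$tc_cm2, ih = k$ih)),
    RE = c(k$thalamus$re, list(cm = k$thalamus$cm, area = k$areas$re_cm2))
  )
  if (kind %in% c("PY", "IN")) {
    # axial coupling conductance expressed per unit area of each compartment
    g_total <- 1 / (k$cortex$kappa_Mohm * 1e6) * 1e3            # mS (absolute)
    p$g_cs_soma <- g_total / p$area_soma                        # mS/cm^2
    p$g_cs_dend <- g_total / p$area_dend
  }
  p$kind <- kind
  p$constants <- k
  structure(p, class = "cell_params")
}

#' Initial state vector for a single cell
#'
#' @param kind Cell type.
#' @param v Initial voltage (mV) for all compartments.
#' @param constants Constants list.
#' @return Named numeric vector: compartment voltages, gating fractions,
#'   intracellular calcium (mM) and, for TC, the h-current state fractions.
#' @export
cell_state <- function(kind = c("PY", "IN", "TC", "RE"), v = -68, constants = somnet_constants()) {
  kind <- match.arg(kind)
  k <- constants
  tadj <- cx_tadj(k)
  switch(kind,
    PY = ,
    IN = {
      na <- cx_na_rates(v, tadj, k$cortex$kinetics$na_shift)
      kk <- cx_k_rates(v, tadj)
      km <- cx_km_rates(v, tadj, k$cortex$kinetics$km_rate)
      ca <- cx_ca_rates(v, tadj)
      c(
        vd = v, vs = v,
        m_nad = na$minf, h_nad = na$hinf, m_nap = cx_nap_minf(v, 1),
        m_ca = ca$minf, h_ca = ca$hinf, m_km = km$minf, m_kca = 0,
        m_nas = na$minf, h_nas = na$hinf, n_ks = kk$ninf,
        ca_i = k$cortex$calcium$floor_mM
      )
    },
    TC = {
      na <- th_na_rates(v, k$thalamus$kinetics$vtr)
      kk <- th_k_rates(v, k$thalamus$kinetics$vtr_k)
      it <- tc_it_rates(v)
      c(
        v = v, m_na = na$minf, h_na = na$hinf, n_k = kk$ninf,
        m_it = it$minf, h_it = it$hinf,
        o_h = h_inf(v, -8), p1_h = 0, ol_h = 0,
        ca_i = k$thalamus$calcium$floor_mM
      )
    },
    RE = {
      na <- th_na_rates(v, k$thalamus$kinetics$vtr)
      kk <- th_k_rates(v, k$thalamus$kinetics$vtr_k)
      it <- re_it_rates(v)
      c(
        v = v, m_na = na$minf, h_na = na$hinf, n_k = kk$ninf,
        m_it = it$minf, h_it = it$hinf,
        ca_i = k$thalamus$calcium$floor_mM
      )
    }
  )
}

check_state <- function(state) {
  bad <- names(state)[!is.finite(state)]
  if (length(bad) > 0) {
    stop("non-finite state variable(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Time derivatives of a single cell's state
#'
#' Evaluates the membrane and gating equations of one cell. For cortical
#' cells (PY, IN) the axo-somatic compartment carries no capacitance; its
#' voltage is obtained by solving the algebraic current balance
#' `g_cs (Vd - Vs) = I_Na,s + I_K,s + I_Nap,s` by damped fixed-point
#' iteration, and the returned list contains the solved somatic voltage.
#' The potassium leak conductance is multiplied by the cell-type-specific
#' acetylcholine scalar (`ach_scale`); for TC cells the h-current activation
#' curve is shifted by `shift_ha` (mV).
#'
#' @param kind Cell type, `"PY"|"IN"|"TC"|"RE"`.
#' @param state Named state vector from [cell_state()].
#' @param params Parameters from [cell_params()].
#' @param ach_scale K-leak multiplier (AChPY for PY/IN, AChTC for TC,
#'   AChRE for RE). Must be positive.
#' @param shift_ha h-current activation shift, mV (TC only).
#' @param i_syn Total synaptic current (nA); positive = outward.
#' @param i_inj Injected current (nA); positive = depolarizing.
#' @return List with `derivs` (named vector, per-ms), `vs` (solved somatic
#'   voltage for cortical kinds, else `NA`), and `currents` (named vector of
#'   membrane current densities, uA/cm^2).
#' @export
cell_derivatives <- function(kind, state, params = cell_params(kind),
                             ach_scale = 1, shift_ha = -8,
                             i_syn = 0, i_inj = 0) {
  stopifnot(ach_scale > 0)
  check_state(state)
  k <- params$constants
  s <- as.list(state)
  rev <- k$reversals
  if (kind %in% c("PY", "IN")) {
    tadj <- cx_tadj(k)
    kin <- k$cortex$kinetics
    vd <- s$vd
    # dendritic currents (uA/cm^2)
    i_kl <- ach_scale * params$g_kleak * (vd - rev$e_k)
    i_cl <- params$g_clleak * (vd - rev$e_cl_cortex)
    i_na <- params$g_na_dend * s$m_nad^3 * s$h_nad * (vd - rev$e_na)
    i_nap <- params$g_nap_dend * kin$nap_act_max * s$m_nap * (vd - rev$e_na)
    i_ca <- params$g_ca_dend * s$m_ca^2 * s$h_ca * (vd - rev$e_ca_cortex)
    i_kca <- tadj * params$g_kca_dend * s$m_kca * (vd - rev$e_k)
    i_km <- tadj * params$g_km_dend * s$m_km * (vd - rev$e_k)
    # algebraic somatic voltage: damped fixed-point on the current balance
    vs <- s$vs
    gna <- params$g_na_soma
    gk <- params$g_k_soma
    gnap <- params$g_nap_soma
    for (i in seq_len(k$engine$soma_max_iter)) {
      g1 <- gna * s$m_nas^3 * s$h_nas
      g2 <- gk * s$n_ks
      g3 <- gnap * cx_nap_minf(vs, kin$nap_act_max)
      vs_new <- (params$g_cs_soma * vd + g1 * rev$e_na + g2 * rev$e_k + g3 * rev$e_na) /
        (params$g_cs_soma + g1 + g2 + g3)
      vs_new <- vs + 0.7 * (vs_new - vs)
      if (abs(vs_new - vs) < k$engine$soma_tol_mV) {
        vs <- vs_new
        break
      }
      vs <- vs_new
    }
    i_syn_dens <- i_syn * 1e-3 / params$area_dend # nA -> uA/cm^2 (1e-3 mA/uA... nA/cm^2 -> uA/cm^2)
    i_inj_dens <- i_inj * 1e-3 / params$area_dend
    dvd <- (-(i_kl + i_cl + i_na + i_nap + i_ca + i_kca + i_km) -
      params$g_cs_dend * (vd - vs) - i_syn_dens + i_inj_dens) / params$cm
    na <- cx_na_rates(vd, tadj, kin$na_shift)
    nas <- cx_na_rates(vs, tadj, kin$na_shift)
    ks <- cx_k_rates(vs, tadj)
    km <- cx_km_rates(vd, tadj, kin$km_rate)
    kca <- cx_kca_rates(s$ca_i, tadj, kin$kca_alpha_per_mM, kin$kca_beta)
    cac <- cx_ca_rates(vd, tadj)
    cal <- k$cortex$calcium
    derivs <- c(
      vd = dvd, vs = 0,
      m_nad = (na$minf - s$m_nad) / na$taum,
      h_nad = (na$hinf - s$h_nad) / na$tauh,
      m_nap = (cx_nap_minf(vd, 1) - s$m_nap) / kin$nap_tau,
      m_ca = (cac$minf - s$m_ca) / cac$taum,
      h_ca = (cac$hinf - s$h_ca) / cac$tauh,
      m_km = (km$minf - s$m_km) / km$taum,
      m_kca = (kca$minf - s$m_kca) / kca$taum,
      m_nas = (nas$minf - s$m_nas) / nas$taum,
      h_nas = (nas$hinf - s$h_nas) / nas$tauh,
      n_ks = (ks$ninf - s$n_ks) / ks$taun,
      ca_i = -cal$drive * min(i_ca, 0) + (cal$floor_mM - s$ca_i) / cal$tau_ms
    )
    list(
      derivs = derivs, vs = vs,
      currents = c(
        i_kleak = i_kl, i_clleak = i_cl, i_na = i_na, i_nap = i_nap,
        i_ca = i_ca, i_kca = i_kca, i_km = i_km
      )
    )
  } else if (kind == "TC") {
    kin <- k$thalamus$kinetics
    v <- s$v
    eca <- eca_nernst(s$ca_i, rev$ca_o_mM, k$temperature_C)
    i_kl <- ach_scale * params$g_kleak * (v - rev$e_k)
    i_l <- params$g_leak * (v - rev$e_leak_tc)
    i_na <- params$g_na * s$m_na^3 * s$h_na * (v - rev$e_na)
    i_k <- params$g_k * s$n_k^4 * (v - rev$e_k)
    i_t <- params$g_lca * s$m_it^2 * s$h_it * (v - eca)
    i_h <- params$g_h * (s$o_h + k$ih$k_locked * s$ol_h) * (v - rev$e_h)
    i_syn_dens <- i_syn * 1e-3 / params$area
    i_inj_dens <- i_inj * 1e-3 / params$area
    dv <- (-(i_kl + i_l + i_na + i_k + i_t + i_h) - i_syn_dens + i_inj_dens) / params$cm
    na <- th_na_rates(v, kin$vtr)
    kk <- th_k_rates(v, kin$vtr_k)
    it <- tc_it_rates(v, kin$it_tc_mshift, kin$it_tc_hshift,
      kin$q10_it_m^((k$temperature_C - kin$base_temp_it) / 10),
      kin$q10_it_h^((k$temperature_C - kin$base_temp_it) / 10)
    )
    hh <- ih_derivs(s$o_h, s$p1_h, s$ol_h, s$ca_i, v, shift_ha, k$ih)
    cal <- k$thalamus$calcium
    derivs <- c(
      v = dv,
      m_na = (na$minf - s$m_na) / na$taum, h_na = (na$hinf - s$h_na) / na$tauh,
      n_k = (kk$ninf - s$n_k) / kk$taun,
      m_it = (it$minf - s$m_it) / it$taum, h_it = (it$hinf - s$h_it) / it$tauh,
      o_h = hh$do, p1_h = hh$dp1, ol_h = hh$dol,
      ca_i = -cal$drive * min(i_t, 0) + (cal$floor_mM - s$ca_i) / cal$tau_ms
    )
    list(derivs = derivs, vs = NA_real_, currents = c(
      i_kleak = i_kl, i_leak = i_l, i_na = i_na, i_k = i_k, i_t = i_t, i_h = i_h
    ))
  } else { # RE
    kin <- k$thalamus$kinetics
    v <- s$v
    eca <- eca_nernst(s$ca_i, rev$ca_o_mM, k$temperature_C)
    i_kl <- ach_scale * params$g_kleak * (v - rev$e_k)
    i_l <- params$g_leak * (v - rev$e_leak_re)
    i_na <- params$g_na * s$m_na^3 * s$h_na * (v - rev$e_na)
    i_k <- params$g_k * s$n_k^4 * (v - rev$e_k)
    i_t <- params$g_lca * s$m_it^2 * s$h_it * (v - eca)
    i_syn_dens <- i_syn * 1e-3 / params$area
    i_inj_dens <- i_inj * 1e-3 / params$area
    dv <- (-(i_kl + i_l + i_na + i_k + i_t) - i_syn_dens + i_inj_dens) / params$cm
    na <- th_na_rates(v, kin$vtr)
    kk <- th_k_rates(v, kin$vtr_k)
    it <- re_it_rates(v, kin$it_re_mshift, kin$it_re_hshift)
    cal <- k$thalamus$calcium
    derivs <- c(
      v = dv,
      m_na = (na$minf - s$m_na) / na$taum, h_na = (na$hinf - s$h_na) / na$tauh,
      n_k = (kk$ninf - s$n_k) / kk$taun,
      m_it = (it$minf - s$m_it) / it$taum, h_it = (it$hinf - s$h_it) / it$tauh,
      ca_i = -cal$drive * min(i_t, 0) + (cal$floor_mM - s$ca_i) / cal$tau_ms
    )
    list(derivs = derivs, vs = NA_real_, currents = c(
      i_kleak = i_kl, i_leak = i_l, i_na = i_na, i_k = i_k, i_t = i_t
    ))
  }
}

# derivatives of the calcium-gated h-current state
# scheme: C <-> O (voltage), P0 + 4 Ca <-> P1, O + P1 <-> OL
ih_derivs <- function(o, p1, ol, ca, v, shift, ihk) {
  hi <- 1 / (1 + exp((v + ihk$vhalf + shift) / ihk$slope))
  taus <- ih_tau_s(v, ihk$tau_floor)
  alpha <- hi / taus
  beta <- (1 - hi) / taus
  cfrac <- 1 - o - ol
  list(
    do = alpha * cfrac - beta * o - ihk$k3 * o * p1 + ihk$k4 * ol,
    dp1 = ihk$k1 * ca^4 * (1 - p1) - ihk$k2 * p1,
    dol = ihk$k3 * o * p1 - ihk$k4 * ol
  )
}

#' Step the calcium-gated h-current state scheme
#'
#' Advances the h-current state (open fraction `o`, calcium-bound regulatory
#' fraction `p1`, calcium-locked open fraction `ol`) by `dt` at a fixed
#' voltage and calcium level, using sub-stepped Euler integration. With zero
#' calcium the locked state decays away and the open fraction relaxes to
#' [h_inf()]; the effective conductance factor is `o + k_locked * ol`.
#'
#' @param state Named vector or list with `o`, `p1`, `ol` in `[0,1]`.
#' @param ca Intracellular calcium (mM).
#' @param v Membrane voltage (mV).
#' @param shift_ha Activation shift (mV).
#' @param dt Time step (ms), must be positive.
#' @param constants Constants list.
#' @return Named vector with updated `o`, `p1`, `ol`.
#' @export
ih_kinetics_step <- function(state, ca, v, shift_ha = 0, dt = 0.02,
                             constants = somnet_constants()) {
  if (dt <= 0) stop("dt must be positive")
  s <- as.list(state)
  stopifnot(all(unlist(s[c("o", "p1", "ol")]) >= 0), all(unlist(s[c("o", "p1", "ol")]) <= 1))
  ihk <- constants$ih
  nsub <- max(1L, ceiling(dt / 0.25))
  h <- dt / nsub
  o <- s$o
  p1 <- s$p1
  ol <- s$ol
  for (i in seq_len(nsub)) {
    d <- ih_derivs(o, p1, ol, ca, v, shift_ha, ihk)
    o <- min(max(o + h * d$do, 0), 1)
    p1 <- min(max(p1 + h * d$dp1, 0), 1)
    ol <- min(max(ol + h * d$dol, 0), 1)
    if (o + ol > 1) { # keep C = 1 - O - OL a valid fraction
      sc <- 1 / (o + ol)
      o <- o * sc
      ol <- ol * sc
    }
  }
  c(o = o, p1 = p1, ol = ol)
}

#' Step the intracellular calcium pool
#'
#' First-order pool: inward Ca-current influx plus exponential relaxation to
#' the resting floor, `dCa/dt = -drive * min(I_Ca, 0) + (floor - Ca)/tau`.
#' Uses the exact exponential update for the time step.
#'
#' @param ca Calcium concentration (mM), non-negative.
#' @param i_ca Calcium current density (uA/cm^2); only the inward (negative)
#'   part drives influx.
#' @param dt Time step (ms).
#' @param pool Calcium pool parameters (`drive`, `floor_mM`, `tau_ms`);
#'   default: cortical pool.
#' @return Updated calcium (mM), non-negative.
#' @export
calcium_step <- function(ca, i_ca, dt, pool = somnet_constants()$cortex$calcium) {
  stopifnot(ca >= 0)
  influx <- -pool$drive * min(i_ca, 0)
  target <- pool$floor_mM + influx * pool$tau_ms
  max(target + (ca - target) * exp(-dt / pool$tau_ms), 0)
}

#' Simulate one isolated cell
#'
#' Integrates a single cell of the given type with the compiled engine, with
#' an optional DC current injection window. Useful for characterizing
#' intrinsic dynamics (e.g. the post-hyperpolarization rebound burst of TC
#' cells) and for integrator convergence checks.
#'
#' @param kind Cell type.
#' @param duration_ms Total simulated time (ms).
#' @param dt Integration step (ms).
#' @param v0 Initial voltage (mV).
#' @param ach_scale,shift_ha Neuromodulator scalars (see [cell_derivatives()]).
#' @param i_inj_nA DC amplitude (nA) applied between `inj_from_ms` and `inj_to_ms`.
#' @param inj_from_ms,inj_to_ms Injection window (ms).
#' @param record_every_ms Sampling interval of the returned trace.
#' @param constants Constants list.
#' @return A tibble with columns `time_ms`, `v` (somatic voltage for
#'   cortical cells), plus `vd`, `ca_i` and h-current/gating extrema
#'   attributes; spike times (0 mV upward crossings) in attribute `spikes`.
#' @export
simulate_cell <- function(kind = c("PY", "IN", "TC", "RE"), duration_ms = 1000,
                          dt = NULL, v0 = -68, ach_scale = 1, shift_ha = -8,
                          i_inj_nA = 0, inj_from_ms = 0, inj_to_ms = 0,
                          record_every_ms = NULL, constants = somnet_constants()) {
  kind <- match.arg(kind)
  if (is.null(dt)) dt <- constants$engine$dt_ms
  if (is.null(record_every_ms)) record_every_ms <- max(dt, 0.1)
  res <- sim_single_cell_cpp(
    kind, flatten_constants(constants), duration_ms, dt, v0,
    ach_scale, shift_ha, i_inj_nA, inj_from_ms, inj_to_ms, record_every_ms
  )
  out <- tibble::tibble(
    time_ms = res$time, v = res$v, vd = res$vd, ca_i = res$ca
  )
  attr(out, "spikes") <- res$spikes
  attr(out, "gate_range") <- res$gate_range
  attr(out, "kind") <- kind
  out
}
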