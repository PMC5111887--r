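# Voltage-dependent rate functions for every intrinsic current.
# These are the R-side reference forms; the compiled engine tabulates the
# same expressions (see src/engine.cpp). All rates are per ms, voltages mV.

# guard against 0/0 in Traub/Mainen-style linoid expressions
vtrap <- function(x, y) ifelse(abs(x / y) < 1e-6, y * (1 - x / y / 2), x / (exp(x / y) - 1))

# ---- cortical fast Na (soma and dendrite) ----
cx_na_rates <- function(v, tadj, shift = 0) {
  v <- v - shift
  am <- 0.182 * vtrap(-(v + 35), 9)        # = 0.182 (v+35)/(1-exp(-(v+35)/9))
  bm <- 0.124 * vtrap(v + 35, 9)
  ah <- 0.024 * vtrap(-(v + 50), 5)
  bh <- 0.0091 * vtrap(v + 75, 5)
  hinf <- 1 / (1 + exp((v + 65) / 6.2))
  list(
    minf = am / (am + bm), taum = 1 / ((am + bm) * tadj),
    hinf = hinf, tauh = 1 / ((ah + bh) * tadj)
  )
}

# ---- cortical delayed rectifier (soma) ----
cx_k_rates <- function(v, tadj) {
  aa <- 0.02 * vtrap(-(v - 25), 9)
  bb <- 0.002 * vtrap(v - 25, 9)
  list(ninf = aa / (aa + bb), taun = 1 / ((aa + bb) * tadj))
}

# ---- persistent Na (activation capped, instantaneous-like) ----
cx_nap_minf <- function(v, cap) cap / (1 + exp(-(v + 42) / 5))

# ---- slow non-inactivating K (M-current) ----
cx_km_rates <- function(v, tadj, r = 1e-4) {
  a <- r * vtrap(-(v + 30), 9)
  b <- r * vtrap(v + 30, 9)
  list(minf = a / (a + b), taum = 1 / ((a + b) * tadj))
}

# ---- Ca-dependent K ----
cx_kca_rates <- function(ca, tadj, a_per_mM = 10, beta = 0.02) {
  a <- a_per_mM * ca
  list(minf = a / (a + beta), taum = 1 / ((a + beta) * tadj))
}

# ---- high-voltage-activated Ca (dendrite) ----
cx_ca_rates <- function(v, tadj) {
  am <- 0.055 * vtrap(-27 - v, 3.8)
  bm <- 0.94 * exp((-75 - v) / 17)
  ah <- 0.000457 * exp((-13 - v) / 50)
  bh <- 0.0065 / (exp((-15 - v) / 28) + 1)
  list(
    minf = am / (am + bm), taum = 1 / ((am + bm) * tadj),
    hinf = ah / (ah + bh), tauh = 1 / ((ah + bh) * tadj)
  )
}

# ---- thalamic fast Na / K (Traub-style, threshold-shifted) ----
th_na_rates <- function(v, vtr = -50) {
  v2 <- v - vtr
  am <- 0.32 * vtrap(13 - v2, 4)
  bm <- 0.28 * vtrap(v2 - 40, 5)
  ah <- 0.128 * exp((17 - v2) / 18)
  bh <- 4 / (1 + exp((40 - v2) / 5))
  list(
    minf = am / (am + bm), taum = 1 / (am + bm),
    hinf = ah / (ah + bh), tauh = 1 / (ah + bh)
  )
}

th_k_rates <- function(v, vtr = -50) {
  v2 <- v - vtr
  an <- 0.032 * vtrap(15 - v2, 5)
  bn <- 0.5 * exp((10 - v2) / 40)
  list(ninf = an / (an + bn), taun = 1 / (an + bn))
}

# ---- low-threshold Ca, TC type (Huguenard/McCormick) ----
tc_it_rates <- function(v, mshift = 57, hshift = 81, phim = 3.55^1.2, phih = 3^1.2) {
  minf <- 1 / (1 + exp(-(v + mshift) / 6.2))
  hinf <- 1 / (1 + exp((v + hshift) / 4))
  taum <- (0.612 + 1 / (exp(-(v + 132) / 16.7) + exp((v + 16.8) / 18.2))) / phim
  tauh <- ifelse(v < -80, exp((v + 467) / 66.6), 28 + exp(-(v + 22) / 10.5)) / phih
  list(minf = minf, taum = taum, hinf = hinf, tauh = tauh)
}

# ---- low-threshold Ca, RE type (Huguenard/Prince) ----
re_it_rates <- function(v, mshift = 52, hshift = 80, phim = 5^1.2, phih = 3^1.2) {
  minf <- 1 / (1 + exp(-(v + mshift) / 7.4))
  hinf <- 1 / (1 + exp((v + hshift) / 5))
  taum <- (3 + 1 / (exp((v + 27) / 10) + exp(-(v + 102) / 15))) / phim
  tauh <- (85 + 1 / (exp((v + 48) / 4) + exp(-(v + 407) / 50))) / phih
  list(minf = minf, taum = taum, hinf = hinf, tauh = tauh)
}

# thalamic Ca reversal via Nernst (Ca in mM)
eca_nernst <- function(ca_i, ca_o = 2, temp_C = 36) {
  1000 * 8.31441 * (273.15 + temp_C) / (2 * 96485.3) * log(ca_o / pmax(ca_i, 1e-9))
}

# h-current slow time constant (no HA shift; the shift acts on h_inf only)
ih_tau_s <- function(v, tau_floor = 20) {
  tau_floor + 1000 / (exp((v + 71.5) / 14.2) + exp(-(v + 89) / 11.6))
}

cx_tadj <- function(k) k$cortex$kinetics$q10_na^((k$temperature_C - k$cortex$kinetics$base_temp_cortex) / 10)
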