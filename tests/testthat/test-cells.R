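test_that("h-current activation curve hits its closed-form anchors and limits", {
  expect_equal(h_inf(-75, 0), 0.5)
  expect_equal(h_inf(-67, -8), 0.5)
  expect_equal(h_inf(-1e4, 0), 1, tolerance = 1e-12)
  expect_lt(h_inf(60, 0), 1e-10)
  # strictly decreasing in voltage
  v <- seq(-120, 60, by = 0.5)
  expect_true(all(diff(h_inf(v, -8)) < 0))
  # the printed form is decreasing in the shift parameter: a more negative
  # ShiftHA moves the half-activation voltage rightward (more current)
  for (vv in c(-90, -75, -60)) {
    expect_true(all(diff(h_inf(vv, c(-8, -3, -2, 0))) < 0))
  }
})

test_that("cell parameters reproduce the printed conductance table", {
  py <- cell_params("PY")
  expect_equal(py$g_kleak, 0.007)
  expect_equal(py$g_clleak, 0.023)
  expect_equal(py$g_nap_dend, 2.0)
  expect_equal(py$g_na_dend, 0.8)
  expect_equal(py$g_na_soma, 3000)
  expect_equal(py$g_k_soma, 200)
  expect_equal(py$cm, 0.075)
  inn <- cell_params("IN")
  expect_equal(inn$g_kleak, 0.034)
  expect_equal(inn$g_clleak, 0.006)
  expect_equal(inn$g_na_soma, 2500)
  expect_equal(inn$g_nap_dend, 0)
  tc <- cell_params("TC")
  expect_equal(tc$g_leak, 0.01)
  expect_equal(tc$g_kleak, 0.007)
  expect_equal(tc$g_na, 90)
  expect_equal(tc$g_lca, 2.5)
  expect_equal(tc$g_h, 0.015)
  re <- cell_params("RE")
  expect_equal(re$g_leak, 0.05)
  expect_equal(re$g_kleak, 0.016)
  expect_equal(re$g_na, 100)
  expect_equal(re$g_lca, 2.2)
})

test_that("cell derivatives satisfy the stated contracts", {
  # zero all conductances except the Cl leak: Vd relaxes to E_Cl and the
  # Cl reversal is the fixed point
  k <- somnet_constants()
  p <- cell_params("PY")
  for (nm in c(
    "g_kleak", "g_na_dend", "g_nap_dend", "g_ca_dend", "g_kca_dend",
    "g_km_dend", "g_na_soma", "g_k_soma", "g_nap_soma"
  )) {
    p[[nm]] <- 0 # axial coupling kept: with a passive soma Vs tracks Vd
  }
  # above E_Cl the voltage must move down, below it up
  expect_lt(cell_derivatives("PY", cell_state("PY", v = -50), p)$derivs[["vd"]], 0)
  expect_gt(cell_derivatives("PY", cell_state("PY", v = -80), p)$derivs[["vd"]], 0)
  st0 <- cell_state("PY", v = k$reversals$e_cl_cortex)
  expect_equal(cell_derivatives("PY", st0, p)$derivs[["vd"]], 0, tolerance = 1e-10)

  # somatic algebraic balance holds at the returned voltage
  st <- cell_state("PY", v = -65)
  full <- cell_params("PY")
  r <- cell_derivatives("PY", st, full)
  vs <- r$vs
  s <- as.list(st)
  g1 <- full$g_na_soma * s$m_nas^3 * s$h_nas
  g2 <- full$g_k_soma * s$n_ks
  g3 <- full$g_nap_soma * 0.02 / (1 + exp(-(vs + 42) / 5))
  resid <- full$g_cs_soma * (s$vd - vs) -
    (g1 * (vs - k$reversals$e_na) + g2 * (vs - k$reversals$e_k) + g3 * (vs - k$reversals$e_na))
  expect_lt(abs(resid), 1e-3)

  # non-finite state rejected with the offending name
  bad <- cell_state("TC")
  bad["m_it"] <- NaN
  expect_error(cell_derivatives("TC", bad), "m_it")
  expect_error(cell_derivatives("PY", cell_state("PY"), ach_scale = -1))
})

test_that("resting voltage is monotone non-increasing in the K-leak scale", {
  for (kind in c("PY", "TC", "RE")) {
    v_rest <- vapply(c(0.8, 1.0, 1.25, 1.8, 2.0), function(sc) {
      s <- simulate_cell(kind, duration_ms = 1500, v0 = -70, ach_scale = sc, shift_ha = -3)
      mean(s$v[s$time_ms > 1200])
    }, numeric(1))
    expect_true(all(diff(v_rest) < 0.2), info = kind)
    expect_lt(v_rest[5], v_rest[1])
  }
})

test_that("TC cells fire a rebound burst after release from hyperpolarization", {
  s <- simulate_cell("TC",
    duration_ms = 1500, v0 = -70, shift_ha = -8,
    i_inj_nA = -0.3, inj_from_ms = 200, inj_to_ms = 700
  )
  spikes <- attr(s, "spikes")
  expect_gte(sum(spikes > 700 & spikes < 850), 2)
  # gating fractions stayed in [0, 1] along the whole trajectory
  gr <- attr(s, "gate_range")
  expect_gte(gr[["min"]], 0)
  expect_lte(gr[["max"]], 1)
})

test_that("h-current kinetics relax to the detailed-balance limit", {
  k <- somnet_constants()
  # Ca = 0, fixed V: O -> h_inf(V), OL -> 0 (the locked state drains
  # through the slow k2/k4 rates, so the horizon must cover tens of seconds)
  st <- c(o = 0.1, p1 = 0.02, ol = 0.05)
  v <- -80
  for (i in 1:12500) st <- ih_kinetics_step(st, ca = 0, v = v, shift_ha = -3, dt = 2)
  expect_equal(unname(st["o"]), h_inf(v, -3), tolerance = 2e-2)
  expect_lt(st[["ol"]], 5e-3)
  expect_lt(st[["p1"]], 1e-4)

  # sustained calcium: locked fraction rises monotonically from rest
  st <- c(o = h_inf(-70, -3), p1 = 0, ol = 0)
  ols <- numeric(30)
  for (i in 1:30) {
    for (j in 1:20) st <- ih_kinetics_step(st, ca = 0.005, v = -70, shift_ha = -3, dt = 1)
    ols[i] <- st[["ol"]]
  }
  expect_true(all(diff(ols) > -1e-9))
  expect_gt(ols[30], 0.2)
  expect_error(ih_kinetics_step(st, 0, -70, 0, dt = -1))
})

test_that("calcium pool follows its first-order closed form", {
  pool <- somnet_constants()$cortex$calcium
  expect_equal(calcium_step(pool$floor_mM, 0, 1, pool), pool$floor_mM)
  # decay limit
  ca <- 2 * pool$floor_mM
  for (i in 1:5000) ca <- calcium_step(ca, 0, 1, pool)
  expect_equal(ca, pool$floor_mM, tolerance = 1e-9)
  # constant influx settles at floor + tau * rate (closed form of the pool)
  influx_i <- -2 # uA/cm^2 inward
  ca <- pool$floor_mM
  for (i in 1:8000) ca <- calcium_step(ca, influx_i, 1, pool)
  expect_equal(ca, pool$floor_mM + pool$tau_ms * pool$drive * 2, tolerance = 1e-6)
})
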