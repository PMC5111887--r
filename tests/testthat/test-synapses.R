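test_that("synaptic current follows I = L g E [O] (V - E_rev)", {
  ampa <- synapse_params("AMPA", g_syn = 0.024)
  expect_equal(synaptic_current(0.5, ampa, v_post = 0), 0)
  gaba <- synapse_params("GABA_A", g_syn = 0.05)
  expect_equal(synaptic_current(0, gaba, v_post = -70), 0)
  # direct evaluation, uS * mV = nA
  expect_equal(
    synaptic_current(0.5, ampa, v_post = -70, l_scale = 2),
    2 * 0.024 * 0.5 * (-70 - 0)
  )
  # doubling the neuromodulator scale exactly doubles the current
  for (o in c(0.1, 0.5, 0.9)) {
    i1 <- synaptic_current(o, ampa, v_post = -55, l_scale = 1.3)
    i2 <- synaptic_current(o, ampa, v_post = -55, l_scale = 2.6)
    expect_equal(i2, 2 * i1)
  }
  expect_error(synaptic_current(0.5, ampa, -70, l_scale = 0))
})

test_that("open fractions stay in [0,1] under pulsed transmitter", {
  for (type in c("AMPA", "NMDA", "GABA_A")) {
    p <- synapse_params(type)
    o <- 0
    track <- numeric(0)
    for (i in 1:4000) {
      on <- (i %% 500) < 15 # 0.3 ms pulse every 10 ms at dt 0.02
      o <- synapse_open_step(o, p, dt = 0.02, transmitter_on = on)
      track <- c(track, o)
    }
    expect_true(all(track >= 0 & track <= 1), info = type)
    expect_gt(max(track), 0.05)
  }
})

test_that("miniature release hazard matches its printed form and limits", {
  expect_equal(mini_rate(0), 0)
  expect_equal(mini_rate(1e7), 1 / 250, tolerance = 1e-10)
  expect_equal(mini_rate(20), (2 / (1 + exp(-1)) - 1) / 250)
  dts <- seq(0, 500, by = 1)
  expect_true(all(diff(mini_rate(dts)) > 0))
  expect_true(all(mini_rate(dts) <= 1 / 250))
  expect_error(mini_rate(-1))
})

test_that("sampled mini waiting times reproduce the inhomogeneous hazard", {
  # empirical CDF of sampled waits vs the closed-form survival
  # S(t) = exp(-H(t)) with H the integrated hazard
  set.seed(7)
  n <- 20000
  waits <- vapply(runif(n), mini_next_release, numeric(1))
  for (q in c(100, 250, 500, 1000)) {
    emp <- mean(waits <= q)
    theor <- 1 - exp(-somnet:::mini_hazard_integral(q))
    se <- sqrt(theor * (1 - theor) / n)
    expect_lt(abs(emp - theor), 3 * se + 1e-3)
  }
})

test_that("GABA-B cascade is slow, saturating and decays without input", {
  pB <- synapse_params("GABA_B")
  pA <- synapse_params("GABA_A")
  dt <- 0.1
  # single brief pulse: GABA-B activation peaks later than GABA-A
  stB <- c(r = 0, g = 0)
  oA <- 0
  actB <- numeric(3000)
  actA <- numeric(3000)
  for (i in 1:3000) {
    on <- i <= 3 # 0.3 ms pulse
    stB <- gabab_step(stB[c("r", "g")], pB, dt, on)
    oA <- synapse_open_step(oA, pA, dt, on)
    actB[i] <- stB[["act"]]
    actA[i] <- oA
  }
  expect_gt(which.max(actB), which.max(actA))
  # no further input: activation decays toward 0
  expect_lt(actB[3000], max(actB) / 2)
  # sustained input saturates below 1
  stB <- c(r = 0, g = 0)
  for (i in 1:20000) stB <- gabab_step(stB[c("r", "g")], pB, dt, TRUE)
  expect_lt(stB[["act"]], 1)
  expect_gt(stB[["act"]], 0.2)
  expect_error(gabab_step(c(r = 0, g = 0), pB, dt = 0))
})

test_that("short-term depression has the analytic periodic fixed point", {
  u <- somnet_constants()$synapse$depression$use
  tau <- somnet_constants()$synapse$depression$tau_rec
  # no spikes: recovery to 1
  e <- 0.2
  for (i in 1:100) e <- depression_step(e, FALSE, dt = 100)
  expect_equal(e, 1, tolerance = 1e-6)
  # single spike: multiplicative drop
  expect_equal(depression_step(1, TRUE, dt = 1e-9), 1 - u, tolerance = 1e-6)
  # 10 Hz train: iterated map must converge to the closed-form fixed point
  period <- 100
  decay <- exp(-period / tau)
  e_star <- (1 - decay) / (1 - (1 - u) * decay) # pre-spike efficacy
  e <- 1
  for (i in 1:300) e <- depression_step(e, TRUE, dt = period)
  # e is the post-spike value; one recovery interval gives the pre-spike one
  e_pre <- 1 + (e - 1) * decay
  expect_equal(e_pre, e_star, tolerance = 1e-4)
})
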