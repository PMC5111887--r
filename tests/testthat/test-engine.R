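test_that("identical seeds give bit-identical simulations", {
  net <- tiny_net()
  cfg <- sim_config(stage_schedule("n2", durations_s = 3), seed = 11)
  s1 <- simulate_network(net, cfg)
  s2 <- simulate_network(net, cfg)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$py_vd, s2$py_vd)
  s3 <- simulate_network(net, sim_config(stage_schedule("n2", durations_s = 3), seed = 12))
  expect_false(identical(s1$py_vd, s3$py_vd))
})

test_that("gating fractions stay in [0,1] on every recorded frame", {
  net <- reduced_net()
  sim <- simulate_network(net, sim_config(stage_schedule("n2", durations_s = 4), seed = 2))
  expect_gte(sim$gate_range[["min"]], 0)
  expect_lte(sim$gate_range[["max"]], 1)
  expect_true(all(abs(sim$py_vd) < 150))
})

test_that("a zero-amplitude pulse leaves the seeded run unchanged", {
  net <- tiny_net()
  cfg <- sim_config(stage_schedule("awake", durations_s = 2), seed = 5)
  cfg0 <- apply_dc_pulse(cfg, "TC", 0, 100, 500)
  s1 <- simulate_network(net, cfg)
  s2 <- simulate_network(net, cfg0)
  expect_identical(s1$spikes, s2$spikes)
  expect_error(apply_dc_pulse(cfg, "TC", 1.5, 100, 5000), "outside")
})

test_that("a DC pulse to TC drives transient thalamic and cortical firing", {
  net <- reduced_net()
  cfg <- sim_config(stage_schedule("awake", durations_s = 6), seed = 1)
  cfg <- apply_dc_pulse(cfg, "TC", 1.5, 100, 2000)
  sim <- simulate_network(net, cfg)
  sp <- sim$spikes
  rate_during <- sum(sp$t_ms >= 2000 & sp$t_ms < 2300) / 0.3
  rate_before <- sum(sp$t_ms >= 1000 & sp$t_ms < 1900) / 0.9
  rate_late <- sum(sp$t_ms >= 4500 & sp$t_ms < 5900) / 1.4
  expect_gt(rate_during, rate_before + 20) # transient increase
  # the network returns toward baseline afterwards
  expect_lt(rate_late, (rate_during - rate_before) / 2 + rate_before)
})

test_that("stage-labeled firing rates and tidiers work end to end", {
  net <- tiny_net()
  sim <- simulate_network(
    net,
    sim_config(stage_schedule("awake", "n3", durations_s = 2), seed = 3)
  )
  fr <- firing_rates(sim, by_stage = TRUE)
  expect_setequal(unique(fr$stage), c("awake", "n3"))
  expect_equal(nrow(fr), 8)
  g <- glance(sim)
  expect_equal(g$duration_s, 4)
  td <- tidy(sim)
  expect_true(all(td$rate_hz >= 0))
  path <- tempfile(fileext = ".tsv")
  export_spikes(sim, path)
  expect_true(file.exists(path))
})

test_that("halving dt barely moves stimulus-locked burst spikes", {
  # rebound burst is time-locked to the release from hyperpolarization, so
  # spike times converge with dt (tonic trains accumulate phase drift and
  # are held only to the <5% rate-change contract)
  run <- function(dt) {
    simulate_cell("TC",
      duration_ms = 1100, dt = dt, v0 = -70,
      i_inj_nA = -0.3, inj_from_ms = 200, inj_to_ms = 700
    )
  }
  sp1 <- attr(run(0.02), "spikes")
  sp2 <- attr(run(0.01), "spikes")
  expect_gt(min(length(sp1), length(sp2)), 1)
  # burst-onset latency converges; intra-burst intervals accumulate drift
  expect_lt(abs(sp1[1] - sp2[1]), 1)
  # tonic-rate convergence: halving dt changes the spike count by < 5%
  tonic <- function(dt) {
    length(attr(simulate_cell("TC",
      duration_ms = 1200, dt = dt, v0 = -70,
      i_inj_nA = 0.1, inj_from_ms = 200, inj_to_ms = 1100
    ), "spikes"))
  }
  n1 <- tonic(0.02)
  n2 <- tonic(0.01)
  expect_lt(abs(n1 - n2) / n2, 0.05)
})
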