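test_that("sweep bookkeeping: one feature row per grid point, resumable", {
  grid <- tidyr::expand_grid(ach = c(60, 100), gaba = c(100, 150), ha = c(50, 100))
  manifest <- tempfile(fileext = ".csv")
  ft <- run_sweep(grid,
    seed = 3, scale = "reduced", trial_s = 6, discard_s = 3,
    manifest_csv = manifest
  )
  expect_equal(nrow(ft), 8)
  expect_true(all(c("ach", "ha", "gaba", "delta_power", "spindle_power", "plv") %in% names(ft)))
  expect_true(all(ft$delta_power >= 0))
  # resume: completed points are skipped, result is unchanged
  t0 <- Sys.time()
  ft2 <- run_sweep(grid,
    seed = 3, scale = "reduced", trial_s = 6, discard_s = 3,
    manifest_csv = manifest
  )
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 5)
  expect_equal(nrow(ft2), 8)
  expect_equal(sort(ft2$delta_power), sort(ft$delta_power), tolerance = 1e-8)
})

test_that("a sweep point at 100% levels equals a standalone awake-level run", {
  grid <- tibble::tibble(ach = 100, gaba = 100, ha = 100)
  ft <- run_sweep(grid, seed = 7, scale = "reduced", trial_s = 6, discard_s = 3)
  net <- reduced_net()
  st <- continuous_scalars(100, 100, 100)
  cfg <- sim_config(stage_schedule(st, durations_s = 6), seed = 8, discard_s = 3)
  sim <- simulate_network(net, cfg)
  ref <- feature_table(sim, window_s = 3)
  expect_equal(ft$delta_power, ref$delta_power, tolerance = 1e-10)
  expect_equal(ft$spindle_power, ref$spindle_power, tolerance = 1e-10)
})

test_that("presets run end to end and emit machine-readable verdicts", {
  expect_gt(length(experiment_presets()), 10)
  r <- run_preset("fig5_g", seed = 1, scale = "reduced", stage_s = 6)
  expect_s3_class(r$verdicts, "tbl_df")
  expect_setequal(names(r$verdicts), c("check", "value", "pass"))
  expect_true("activated_in_seg2" %in% r$verdicts$check)
  expect_output(print(r), "fig5_g")
  expect_error(run_preset("fig99"), "unknown preset")
})
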