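test_that("named-stage scalars reproduce the printed tables exactly", {
  aw <- stage_scalars("awake")
  expect_equal(aw$ach_py, 1)
  expect_equal(aw$ach_re, 1)
  expect_equal(aw$lach, 1)
  expect_equal(aw$lgaba, 1)
  expect_equal(aw$shift_ha, -8)
  n2 <- stage_scalars("n2")
  expect_equal(n2$ach_py, 1.25)
  expect_equal(n2$ach_tc, 1.25)
  expect_equal(n2$ach_re, 0.8)
  expect_equal(n2$lach, 1.25)
  expect_equal(n2$lgaba, 1.15)
  expect_equal(n2$shift_ha, -3)
  n3 <- stage_scalars("n3")
  expect_equal(n3$ach_py, 1.8)
  expect_equal(n3$ach_tc, 2.0) # documented gap: not printed for N3
  expect_equal(n3$ach_re, 0.5)
  expect_equal(n3$lach, 2.0)
  expect_equal(n3$lgaba, 1.3)
  expect_equal(n3$shift_ha, -2)
  rem <- stage_scalars("rem")
  expect_equal(rem$ach_py, 0.85)
  expect_equal(rem$ach_re, 1.15)
  expect_equal(rem$lach, 0.8)
  expect_equal(rem$lgaba, 0.75)
  expect_equal(rem$shift_ha, 0)
  expect_error(stage_scalars("n4"), "unknown stage")
})

test_that("continuous scalars interpolate the stage anchors exactly", {
  # round trip through all four stages' printed levels
  tab <- stage_table <- somnet:::stage_table()
  for (i in seq_len(nrow(tab))) {
    st <- continuous_scalars(tab$ach[i], tab$ha[i], tab$gaba[i])
    named <- stage_scalars(tab$stage[i])
    for (f in c("ach_py", "ach_tc", "ach_re", "lach", "lgaba", "shift_ha")) {
      expect_equal(st[[f]], named[[f]], info = paste(tab$stage[i], f))
    }
  }
  # intermediate ACh lies strictly between the N2 and N3 values
  mid <- continuous_scalars(75, 30, 130)
  n2 <- stage_scalars("n2")
  n3 <- stage_scalars("n3")
  for (f in c("ach_py", "ach_tc", "lach")) {
    expect_gt(mid[[f]], n2[[f]])
    expect_lt(mid[[f]], n3[[f]])
  }
  expect_lt(mid$ach_re, n2$ach_re)
  expect_gt(mid$ach_re, n3$ach_re)
  # monotone: lower ACh -> larger AChPY, smaller AChRE
  achs <- seq(10, 120, by = 5)
  apy <- vapply(achs, function(a) continuous_scalars(a, 50, 100)$ach_py, numeric(1))
  are <- vapply(achs, function(a) continuous_scalars(a, 50, 100)$ach_re, numeric(1))
  expect_true(all(diff(apy) < 1e-12))
  expect_true(all(diff(are) > -1e-12))
  expect_error(continuous_scalars(-5, 100, 100), "ACH|ACh")
  expect_error(continuous_scalars(100, 100, 400), "GABA")
})

test_that("applying modulators rescales effective parameters idempotently", {
  net <- tiny_net()
  n3 <- apply_modulators(net, stage_scalars("n3"))
  eff <- n3$effective$edges
  base <- net$edges
  # PY K-leak x1.8, RE x0.5 via the state itself
  expect_equal(n3$effective$ach_py, 1.8)
  expect_equal(n3$effective$ach_re, 0.5)
  # N2: IN-PY GABA-A scaled by 1.15
  n2 <- apply_modulators(net, stage_scalars("n2"))
  i <- n2$effective$edges$projection == "in_py_gabaa"
  expect_equal(
    n2$effective$edges$weight_eff_uS[i],
    1.15 * base$weight_uS[i]
  )
  # LACh applies to PY-PY, TC-PY, TC-IN AMPA but not PY-IN
  j <- eff$projection == "py_py_ampa"
  expect_equal(eff$weight_eff_uS[j], 2 * base$weight_uS[j])
  jj <- eff$projection == "py_in_ampa"
  expect_equal(eff$weight_eff_uS[jj], base$weight_uS[jj])
  # awake = identity; base never mutated; reapplication idempotent
  aw <- apply_modulators(net, stage_scalars("awake"))
  expect_equal(aw$effective$edges$weight_eff_uS, base$weight_uS)
  expect_identical(aw$edges, net$edges)
  aw2 <- apply_modulators(aw, stage_scalars("awake"))
  expect_identical(aw2$effective$edges, aw$effective$edges)
})

test_that("propofol modes set the decay scale and neuromodulator levels", {
  tau_only <- propofol_mode("tau_only")
  aw <- stage_scalars("awake")
  for (f in c("ach_py", "ach_tc", "ach_re", "lach", "lgaba", "shift_ha")) {
    expect_equal(tau_only[[f]], aw[[f]])
  }
  expect_equal(tau_only$tau_scale, 2.5) # "increased by 150%"
  expect_equal(propofol_mode("tau_only", interpretation = "factor")$tau_scale, 1.5)
  comb <- propofol_mode("combined")
  expect_equal(comb$ach, 75)
  expect_equal(comb$ha, 30)
  expect_equal(comb$tau_scale, 2.5)
  ident <- propofol_mode("tau_only", tau_increase_pct = 0)
  expect_equal(ident$tau_scale, 1)
})

test_that("tonic GABA variants follow their per-stage tables", {
  for (st in c("awake", "n2", "n3", "rem")) expect_equal(tonic_gaba_variant("A", st), 1)
  expect_equal(tonic_gaba_variant("B", "n2"), 1.15)
  expect_equal(tonic_gaba_variant("B", "n3"), 1.30)
  expect_equal(tonic_gaba_variant("B", "rem"), 0.75)
  expect_equal(tonic_gaba_variant("C", "n2"), 0.85)
  expect_equal(tonic_gaba_variant("C", "n3"), 0.70)
  expect_equal(tonic_gaba_variant("C", "rem"), 1.25)
})

test_that("schedules expand to continuous or stepwise scalar time courses", {
  sch <- stage_schedule("awake", "n3", durations_s = 10, ramp_s = 1)
  sc <- schedule_scalars(sch)
  # ramp: value at 10 s start differs from value at 11 s (end of ramp)
  expect_equal(sc$ach_py[sc$time_ms == 10000], 1)
  expect_equal(sc$ach_py[sc$time_ms == 11000], 1.8)
  sch0 <- stage_schedule("awake", "n3", durations_s = 10, ramp_s = 0)
  sc0 <- schedule_scalars(sch0)
  expect_equal(sort(unique(sc0$ach_py)), c(1, 1.8))
  expect_error(stage_schedule("awake", durations_s = -1))
  expect_equal(
    schedule_stage_at(sch, c(1, 9.9, 10.5, 19)),
    c("awake", "awake", "n3", "n3")
  )
  # tonic variant fixes phasic GABA at awake and scales minis
  schB <- stage_schedule("awake", "n3", durations_s = 5, tonic_variant = "B")
  expect_equal(schB$states[[2]]$lgaba_th, 1)
  expect_equal(schB$states[[2]]$mini_scale, 1.30)
})
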