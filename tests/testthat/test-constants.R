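test_that("constants load from the versioned file and accept overrides", {
  k <- somnet_constants()
  expect_equal(k$version, 1)
  expect_equal(k$cortex$py$g_kleak, 0.007)
  k2 <- somnet_constants(list(cortex = list(py = list(g_kleak = 0.01))))
  expect_equal(k2$cortex$py$g_kleak, 0.01)
  expect_equal(k2$cortex$py$g_clleak, 0.023) # untouched siblings survive
  expect_equal(k2$thalamus$tc$g_h, k$thalamus$tc$g_h)
  # flattened view used by the engine has dotted names
  fl <- somnet:::flatten_constants(k)
  expect_equal(unname(fl["synapse.ampa.alpha"]), 1.1)
  expect_equal(unname(fl["network.gsyn_uS.re_tc_gabab"]), 0.02)
  # round trip through yaml
  path <- tempfile(fileext = ".yaml")
  write_constants(path, k)
  k3 <- yaml::read_yaml(path)
  expect_equal(k3$synapse$gabab$hill, 4)
  expect_equal(k3$network$radii$tc_py, 10)
})
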