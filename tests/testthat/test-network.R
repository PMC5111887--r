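test_that("cross-layer center mapping is proportional with endpoint anchors", {
  expect_equal(map_center(0, 100, 500), 0)
  expect_equal(map_center(99, 100, 500), 499)
  expect_equal(map_center(50, 100, 500), 252) # round(50 * 499/99)
  expect_equal(map_center(0:4, 5, 5), 0:4)
  expect_error(map_center(0, 0, 10))
  expect_error(map_center(10, 10, 50))
})

test_that("fan-in counts match the topographic wiring rules", {
  net <- full_net()
  e <- net$edges
  fanin <- function(proj, tgt) sum(e$projection == proj & e$tgt == tgt)
  # interior PY receives from 10 PY (r = 5, self excluded)
  expect_equal(fanin("py_py_ampa", 250), 10)
  # boundary truncation: first PY has 5 partners
  expect_equal(fanin("py_py_ampa", 1), 5)
  # interior IN receives from 5 TC (r = 2, cross-layer)
  expect_equal(fanin("tc_in_ampa", 50), 5)
  # interior PY receives from 21 TC (r = 10, cross-layer)
  expect_equal(fanin("tc_py_ampa", 250), 21)
  # no self-edges anywhere in same-population projections
  same <- e[e$projection %in% c("py_py_ampa", "py_py_nmda", "re_re_gabaa"), ]
  expect_true(all(same$src != same$tgt))
})

test_that("per-target conductance normalization keeps the printed total", {
  net <- full_net()
  e <- net$edges
  tot <- e |>
    dplyr::filter(.data$projection == "py_py_ampa") |>
    dplyr::group_by(.data$tgt) |>
    dplyr::summarise(g = sum(.data$weight_uS))
  expect_true(all(abs(tot$g - 0.024) < 1e-12))
})

test_that("connectivity is mirror-symmetric for interior cells", {
  spec <- network_spec(n_py = 60, n_in = 12, n_tc = 12, n_re = 12)
  e <- build_connectivity(spec)
  pp <- e[e$projection == "py_py_ampa", ]
  n <- 60
  mirrored <- data.frame(src = n + 1 - pp$src, tgt = n + 1 - pp$tgt)
  key <- function(d) sort(paste(d$src, d$tgt))
  expect_identical(key(pp), key(mirrored))
})

test_that("edge counts scale linearly with layer size at fixed radius", {
  count_pp <- function(n) {
    spec <- network_spec(n_py = n, n_in = 10, n_tc = 10, n_re = 10)
    # small thalamic layers trigger the intended full-connectivity warning
    sum(suppressWarnings(build_connectivity(spec))$projection == "py_py_ampa")
  }
  c1 <- count_pp(100)
  c2 <- count_pp(200)
  # interior edges 2r per cell; boundary corrections identical, so the
  # difference is exactly 100 * 2r
  expect_equal(c2 - c1, 100 * 10)
})

test_that("oversized radius warns and yields full connectivity", {
  spec <- network_spec(
    n_py = 10, n_in = 4, n_tc = 4, n_re = 4,
    radii = list(py_py = 50)
  )
  w <- testthat::capture_warnings(e <- build_connectivity(spec))
  expect_true(any(grepl("full connectivity", w)))
  expect_equal(sum(e$projection == "py_py_ampa"), 10 * 9)
})

test_that("assembly is deterministic and reports per-projection counts", {
  n1 <- suppressWarnings(assemble_network(network_spec(n_py = 50, n_in = 10, n_tc = 10, n_re = 10)))
  n2 <- suppressWarnings(assemble_network(network_spec(n_py = 50, n_in = 10, n_tc = 10, n_re = 10)))
  expect_identical(n1$summary, n2$summary)
  expect_identical(n1$edges, n2$edges)
  expect_setequal(
    n1$summary$projection,
    somnet:::projection_defs()$projection
  )
  path <- tempfile(fileext = ".tsv")
  network_summary(n1, path)
  expect_true(file.exists(path))
  tab <- read.delim(path)
  expect_equal(nrow(tab), nrow(n1$summary))
})
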