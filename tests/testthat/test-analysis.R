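test_that("LFP construction averages groups and respects linearity", {
  # constant voltages give a constant LFP
  m <- matrix(-65, nrow = 500, ncol = 20)
  lfp <- compute_lfp(m, "all", sample_rate_hz = 100)
  expect_true(all(lfp$ch1 == -65))
  # groups of 100 over 500 cells yield 5 channels
  m2 <- matrix(rnorm(200 * 500), nrow = 200, ncol = 500)
  g5 <- compute_lfp(m2, groups_of(100), sample_rate_hz = 100)
  expect_length(somnet:::lfp_channels(g5), 5)
  expect_equal(g5$ch1, rowMeans(m2[, 1:100]))
  # antisymmetric groups cancel in the global average
  v <- rnorm(100)
  m3 <- cbind(v, -v)
  all3 <- compute_lfp(m3, "all", sample_rate_hz = 100)
  expect_true(all(abs(all3$ch1) < 1e-12))
  byg <- compute_lfp(m3, groups_of(1), sample_rate_hz = 100)
  expect_equal(byg$ch1, v)
  expect_equal(byg$ch2, -v)
  # remainder rule: last group smaller
  g3 <- compute_lfp(m2[, 1:250], groups_of(100), sample_rate_hz = 100)
  expect_length(somnet:::lfp_channels(g3), 3)
})

test_that("band power concentrates on spectral content and satisfies Parseval", {
  fs <- 200
  t <- seq_len(2000) / fs
  x10 <- sin(2 * pi * 10 * t)
  lfp <- as_lfp(matrix(x10), fs)
  sp <- band_power(lfp, c(7, 15), window_s = 5)
  dl <- band_power(lfp, c(0.5, 4), window_s = 5)
  expect_gt(mean(sp$power) / max(mean(dl$power), 1e-15), 100)
  # DC-only signal: zero spindle-band power
  lfp_dc <- as_lfp(matrix(rep(3, 1000)), fs)
  expect_lt(max(band_power(lfp_dc, c(7, 15), window_s = 2)$power), 1e-20)
  # Parseval with the rectangular window: band powers over a partition of
  # (0, Nyquist] sum to the variance
  set.seed(3)
  x <- rnorm(1024)
  lfpx <- as_lfp(matrix(x), fs)
  edges <- seq(0, fs / 2, length.out = 9)
  tot <- 0
  for (i in 1:8) {
    tot <- tot + band_power(lfpx, c(edges[i], edges[i + 1]),
      window_s = 1024 / fs, window_fn = "rect"
    )$power
  }
  seg <- x - mean(x)
  expect_equal(tot, mean(seg^2), tolerance = 1e-8)
  # white noise: two disjoint equal-width bands carry equal power on average
  set.seed(4)
  p1 <- p2 <- numeric(40)
  for (i in 1:40) {
    w <- as_lfp(matrix(rnorm(800)), fs)
    p1[i] <- band_power(w, c(10, 20), window_s = 4, window_fn = "rect")$power
    p2[i] <- band_power(w, c(60, 70), window_s = 4, window_fn = "rect")$power
  }
  expect_lt(abs(mean(p1) - mean(p2)) / mean(p2), 0.15)
  expect_error(band_power(lfpx, c(15, 7)), "increasing")
  expect_error(band_power(lfpx, c(10, 500)), "Nyquist")
})

test_that("band power and PLV are invariant to constant offsets", {
  fs <- 200
  set.seed(9)
  x <- rnorm(1000) + sin(2 * pi * 9 * seq_len(1000) / fs)
  y <- rnorm(1000) + sin(2 * pi * 9 * seq_len(1000) / fs + 1)
  p0 <- band_power(as_lfp(matrix(x), fs), c(7, 15), window_s = 5)$power
  p1 <- band_power(as_lfp(matrix(x + 40), fs), c(7, 15), window_s = 5)$power
  expect_equal(p0, p1, tolerance = 1e-10)
  expect_equal(
    plv(x, y, sample_rate_hz = fs),
    plv(x + 25, y - 10, sample_rate_hz = fs),
    tolerance = 1e-10
  )
})

test_that("phase-locking value hits its closed-form anchors", {
  fs <- 200
  set.seed(5)
  x <- rnorm(4000) + 2 * sin(2 * pi * 8 * seq_len(4000) / fs)
  expect_equal(plv(x, x, sample_rate_hz = fs), 1, tolerance = 1e-9)
  # constant phase shift of a narrowband signal still gives PLV 1
  t <- seq_len(8000) / fs
  a <- sin(2 * pi * 10 * t)
  b <- sin(2 * pi * 10 * t + 1.2)
  expect_equal(plv(a, b, band = c(5, 15), sample_rate_hz = fs), 1, tolerance = 1e-3)
  # long independent noise: PLV near zero
  set.seed(6)
  n1 <- rnorm(1e5)
  n2 <- rnorm(1e5)
  expect_lt(plv(n1, n2, sample_rate_hz = 1000), 0.1)
  expect_error(plv(rep(1, 100), rnorm(100), sample_rate_hz = fs), "zero-variance")
  expect_error(plv(rnorm(50), rnorm(60), sample_rate_hz = fs), "equal length")
})

test_that("event detection recovers constructed spindle and SO fixtures", {
  bs <- burst_signal(fs = 200, dur_s = 12, f = 10, burst_from = 5, burst_len = 1.5)
  lfp <- as_lfp(matrix(bs$x), bs$fs)
  ev <- detect_events(lfp, "spindle")
  expect_equal(nrow(ev), 1)
  # the zero-phase filter and envelope smoothing widen edges by ~0.1 s each
  expect_lt(abs(ev$duration_s - 1.5), 0.35)
  expect_lt(abs(ev$onset_s - 5), 0.3)
  expect_lt(abs(ev$peak_freq_hz - 10), 1)
  # amplitude rescaling leaves the episode count unchanged (relative mode)
  ev2 <- detect_events(as_lfp(matrix(5 * bs$x), bs$fs), "spindle")
  expect_equal(nrow(ev2), nrow(ev))
  # spectrogram method: the longest episode covers the burst
  ev3 <- detect_events(lfp, "spindle", method = "spectrogram")
  expect_gte(nrow(ev3), 1)
  main <- ev3[which.max(ev3$duration_s), ]
  expect_lt(main$onset_s, 5.5)
  expect_gt(main$offset_s, 6.0)
  # SO fixture: 0.8 Hz alternation
  fs <- 200
  t <- seq_len(fs * 20) / fs
  so <- sign(sin(2 * pi * 0.8 * t)) + 0.05 * rnorm(length(t))
  evso <- detect_events(as_lfp(matrix(so), fs), "slow_oscillation")
  rate <- nrow(evso) / 20
  expect_lt(abs(rate - 0.8), 0.2)
  expect_lt(abs(median(evso$peak_freq_hz) - 0.8), 0.3)
  # flat signal: no events of either kind
  flat <- as_lfp(matrix(rep(0, 2000)), fs)
  expect_equal(nrow(detect_events(flat, "spindle")), 0)
  expect_equal(nrow(detect_events(flat, "slow_oscillation")), 0)
})

test_that("spindle-delta correlation matches exact and sampled cases", {
  d <- tibble::tibble(spindle_power = (1:50) / 10, delta_power = (1:50) / 10)
  expect_equal(spindle_delta_correlation(d)$r, 1)
  d2 <- tibble::tibble(spindle_power = 1:50, delta_power = 100 - (1:50))
  expect_equal(spindle_delta_correlation(d2, log_transform = FALSE)$r, -1)
  # seeded bivariate normal with rho = 0.4: r in the sampling interval
  set.seed(42)
  n <- 500
  z1 <- rnorm(n)
  z2 <- 0.4 * z1 + sqrt(1 - 0.16) * rnorm(n)
  r <- spindle_delta_correlation(
    tibble::tibble(spindle_power = z1, delta_power = z2),
    log_transform = FALSE
  )$r
  expect_gt(r, 0.32)
  expect_lt(r, 0.47)
  expect_error(spindle_delta_correlation(d[1:2, ]), "at least 3")
})

test_that("mixture clustering recovers constructed component counts", {
  set.seed(10)
  blob <- function(mu, n = 300) {
    cbind(rnorm(n, mu[1], 0.1), rnorm(n, mu[2], 0.1), rnorm(n, mu[3], 0.05))
  }
  x <- rbind(blob(c(0, 0, 0.2)), blob(c(3, 0, 0.5)), blob(c(0, 3, 0.8)))
  f <- tibble::tibble(
    delta_power = 10^x[, 1], spindle_power = 10^x[, 2],
    plv = pmin(pmax(x[, 3], 0), 1)
  )
  m3 <- cluster_states(f, max_components = 6, seed = 1)
  expect_equal(m3$k, 3)
  expect_equal(sum(m3$weights), 1, tolerance = 1e-6)
  # single Gaussian: one component
  set.seed(11)
  g1 <- tibble::tibble(
    delta_power = 10^rnorm(600), spindle_power = 10^rnorm(600),
    plv = pmin(pmax(rnorm(600, 0.5, 0.1), 0), 1)
  )
  m1 <- cluster_states(g1, max_components = 5, seed = 1)
  expect_equal(m1$k, 1)
  # determinism under identical seed
  m3b <- cluster_states(f, max_components = 6, seed = 1)
  expect_equal(m3$assignment, m3b$assignment)
  expect_equal(m3$aic, m3b$aic)
  # tidy/glance accessors
  td <- tidy(m3)
  expect_equal(nrow(td), 3)
  expect_equal(glance(m3)$k, 3)
})

test_that("cluster projection to neuromodulator space is moment-exact", {
  set.seed(12)
  f <- tibble::tibble(
    delta_power = 10^c(rnorm(150, 0), rnorm(150, 4)),
    spindle_power = 10^c(rnorm(150, 4), rnorm(150, 0)),
    plv = runif(300, 0.2, 0.8)
  )
  m <- cluster_states(f, max_components = 4, seed = 2)
  # axis-aligned grid of members: center at the centroid, axis-aligned cov
  coords <- tibble::tibble(
    ach = rep(c(20, 40), length.out = 300),
    ha = rep(c(30, 60), each = 150),
    gaba = runif(300, 90, 110)
  )
  pr <- project_clusters(m, coords)
  expect_equal(nrow(pr), m$k)
  for (i in seq_len(nrow(pr))) {
    idx <- which(m$assignment == pr$cluster[i])
    if (!pr$degenerate[i]) {
      expect_equal(pr$ach[i], mean(coords$ach[idx]))
      expect_equal(pr$axis1[i], sqrt(max(eigen(cov(coords[idx, ]))$values)))
    }
  }
  # all members at one point: zero-volume ellipsoid at that point
  one <- coords
  one$ach <- 50
  one$ha <- 50
  one$gaba <- 100
  pr1 <- project_clusters(m, one)
  expect_true(all(pr1$axis1[!pr1$degenerate] < 1e-9))
  expect_true(all(pr1$ach == 50))
  # degenerate flag for tiny clusters
  m_small <- m
  m_small$assignment[m_small$assignment == 1][-(1:2)] <- 2
  pr2 <- project_clusters(m_small, coords)
  expect_true(pr2$degenerate[1])
})
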