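#' Frequency-band presets
#'
#' Band conventions used in different recording contexts: the model preset
#' uses delta 0.5-4 Hz and spindle 7-15 Hz; the animal (cat/mouse LFP)
#' preset 0.2-4 and 8-15 Hz; the human (ECoG) preset 0.01-2 and 9-17 Hz.
#'
#' @param context `"model"`, `"animal"` or `"human"`.
#' @return List with `delta` and `spindle` (Hz ranges) and the PLV band.
#' @export
band_presets <- function(context = c("model", "animal", "human")) {
  context <- match.arg(context)
  switch(context,
    model = list(delta = c(0.5, 4), spindle = c(7, 15), plv = c(0.5, 20)),
    animal = list(delta = c(0.2, 4), spindle = c(8, 15), plv = c(0.5, 20)),
    human = list(delta = c(0.01, 2), spindle = c(9, 17), plv = c(0.5, 20))
  )
}

#' Grouping descriptor for LFP construction
#'
#' @param n Cells per group.
#' @return Grouping object for [compute_lfp()].
#' @export
groups_of <- function(n) {
  stopifnot(n >= 1)
  structure(list(n = as.integer(n)), class = "lfp_grouping")
}

#' Simulated local field potential
#'
#' The model LFP is the arithmetic mean of PY dendritic membrane voltages
#' over a group of cells: either all cells (one global channel) or
#' consecutive groups of `n` (e.g. `groups_of(100)` on 500 PY gives 5
#' channels). If the group size does not divide the population, the last
#' group is smaller.
#'
#' @param x A `tc_sim` (uses the recorded PY voltages, dropping the
#'   configured transient) or a numeric matrix (time x cells).
#' @param grouping `"all"` or [groups_of()].
#' @param sample_rate_hz Sample rate; inferred from a `tc_sim`.
#' @param discard_s Transient to drop; defaults to the sim's configured value.
#' @return An `lfp_series`: tibble with `time_s` and channel columns
#'   `ch1..chN`; attributes `sample_rate_hz` and `grouping`.
#' @export
compute_lfp <- function(x, grouping = "all", sample_rate_hz = NULL, discard_s = NULL) {
  if (inherits(x, "tc_sim")) {
    if (ncol(x$py_vd) == 0) stop("this simulation did not record PY voltages")
    sample_rate_hz <- 1000 / x$config$record_dt_ms
    if (is.null(discard_s)) discard_s <- x$config$discard_s
    keep <- x$time_s > discard_s
    v <- x$py_vd[keep, , drop = FALSE]
    tt <- x$time_s[keep]
  } else {
    v <- as.matrix(x)
    if (is.null(sample_rate_hz)) stop("sample_rate_hz required for matrix input")
    tt <- seq_len(nrow(v)) / sample_rate_hz
    if (is.null(discard_s)) discard_s <- 0
    keep <- tt > discard_s
    v <- v[keep, , drop = FALSE]
    tt <- tt[keep]
  }
  stopifnot(all(is.finite(v)))
  ncells <- ncol(v)
  if (identical(grouping, "all")) {
    groups <- list(seq_len(ncells))
  } else if (inherits(grouping, "lfp_grouping")) {
    n <- grouping$n
    if (n > ncells) stop("group size exceeds the number of cells")
    starts <- seq(1, ncells, by = n)
    groups <- lapply(starts, function(s) s:min(s + n - 1, ncells))
  } else {
    stop("grouping must be \"all\" or groups_of(n)")
  }
  ch <- vapply(groups, function(g) rowMeans(v[, g, drop = FALSE]), numeric(nrow(v)))
  ch <- matrix(ch, nrow = nrow(v))
  out <- tibble::as_tibble(as.data.frame(ch), .name_repair = "minimal")
  names(out) <- paste0("ch", seq_along(groups))
  out <- dplyr::mutate(out, time_s = tt, .before = 1)
  attr(out, "sample_rate_hz") <- sample_rate_hz
  attr(out, "grouping") <- if (identical(grouping, "all")) "all" else paste0("groups_of_", grouping$n)
  class(out) <- c("lfp_series", class(out))
  out
}

lfp_channels <- function(lfp) setdiff(names(lfp), "time_s")

lfp_rate <- function(lfp, sample_rate_hz = NULL) {
  r <- attr(lfp, "sample_rate_hz")
  if (is.null(r)) r <- sample_rate_hz
  if (is.null(r)) stop("sample rate unknown; pass sample_rate_hz")
  r
}

# one-sided periodogram power in [lo, hi] Hz; `power` is integrated spectral
# density so that, with the rectangular window, band powers over a partition
# of [0, Nyquist] sum to the signal variance (Parseval).
periodogram_band <- function(x, fs, lo, hi, window_fn = c("hann", "rect")) {
  window_fn <- match.arg(window_fn)
  n <- length(x)
  x <- x - mean(x)
  w <- if (window_fn == "hann") 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1))) else rep(1, n)
  xw <- x * w
  sp <- Mod(fft(xw))^2 / (sum(w^2) * n)
  freq <- (seq_len(n) - 1) * fs / n
  half <- 2:(floor(n / 2) + 1) # positive frequencies (fold in negatives)
  dens <- sp[half]
  neg <- n - (half - 1) + 1
  neg_ok <- neg >= 1 & neg <= n & neg != half
  dens[neg_ok] <- dens[neg_ok] + sp[neg[neg_ok]]
  f <- freq[half]
  sum(dens[f > lo & f <= hi])
}

#' Band-integrated spectral power per sliding window
#'
#' FFT periodogram (Hann window by default; rectangular for exact Parseval
#' partitioning) of each window of each channel, integrated over the band.
#'
#' @param lfp An `lfp_series` (or data frame with `time_s` + channels).
#' @param band Two-element Hz range.
#' @param window_s Window length (s).
#' @param slide_s Window step (s); default `window_s` (non-overlapping).
#' @param window_fn `"hann"` or `"rect"`.
#' @param sample_rate_hz Required when `lfp` lacks the attribute.
#' @return Tibble: `channel`, `window_start_s`, `window_end_s`, `power`.
#' @export
band_power <- function(lfp, band, window_s = 2, slide_s = NULL,
                       window_fn = "hann", sample_rate_hz = NULL) {
  fs <- lfp_rate(lfp, sample_rate_hz)
  if (band[1] >= band[2]) stop("band must be increasing (lo < hi)")
  if (band[2] > fs / 2) stop("band exceeds the Nyquist frequency")
  if (is.null(slide_s)) slide_s <- window_s
  chans <- lfp_channels(lfp)
  nwin <- floor(window_s * fs)
  if (nwin > nrow(lfp)) stop("window longer than the series")
  step <- max(1, floor(slide_s * fs))
  starts <- seq(1, nrow(lfp) - nwin + 1, by = step)
  t0 <- lfp$time_s[1]
  purrr::map_dfr(chans, function(ch) {
    x <- lfp[[ch]]
    tibble::tibble(
      channel = ch,
      window_start_s = t0 + (starts - 1) / fs,
      window_end_s = t0 + (starts - 1 + nwin) / fs,
      power = vapply(
        starts,
        function(s) periodogram_band(x[s:(s + nwin - 1)], fs, band[1], band[2], window_fn),
        numeric(1)
      )
    )
  })
}

# zero-phase FFT band-pass with raised-cosine transitions
fft_bandpass <- function(x, fs, lo, hi) {
  n <- length(x)
  x0 <- x - mean(x)
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq) # two-sided
  tw <- max(0.05, 0.1 * (hi - lo))
  lo_edge <- max(lo, 0)
  mask <- rep(1, n)
  ramp_up <- freq < lo_edge
  mask[ramp_up] <- 0.5 * (1 + cos(pi * pmin((lo_edge - freq[ramp_up]) / tw, 1)))
  ramp_dn <- freq > hi
  mask[ramp_dn] <- 0.5 * (1 + cos(pi * pmin((freq[ramp_dn] - hi) / tw, 1)))
  Re(fft(fft(x0) * mask, inverse = TRUE)) / n
}

# analytic signal via FFT
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Phase-locking value between two channels
#'
#' Both signals are band-pass filtered (default 0.5-20 Hz), instantaneous
#' phases are extracted from the analytic signal, and the PLV is the modulus
#' of the mean unit phasor of the phase difference. 1 means perfect phase
#' locking; independent signals approach 0 with increasing length.
#'
#' @param a,b Equal-length numeric vectors.
#' @param band Hz range for the band-pass filter.
#' @param sample_rate_hz Sample rate.
#' @return PLV in `[0, 1]`.
#' @export
plv <- function(a, b, band = c(0.5, 20), sample_rate_hz) {
  if (length(a) != length(b)) stop("channels must have equal length")
  if (var(a) == 0 || var(b) == 0) stop("zero-variance channel")
  fa <- fft_bandpass(a, sample_rate_hz, band[1], band[2])
  fb <- fft_bandpass(b, sample_rate_hz, band[1], band[2])
  pa <- Arg(hilbert_analytic(fa))
  pb <- Arg(hilbert_analytic(fb))
  Mod(mean(exp(1i * (pa - pb))))
}

#' Mean pairwise PLV across the channels of an LFP series
#'
#' @param lfp An `lfp_series` with >= 2 channels.
#' @inheritParams plv
#' @return Tibble of channel pairs and their PLV, with the mean as attribute
#'   `mean_plv`.
#' @export
plv_pairs <- function(lfp, band = c(0.5, 20), sample_rate_hz = NULL) {
  fs <- lfp_rate(lfp, sample_rate_hz)
  chans <- lfp_channels(lfp)
  if (length(chans) < 2) stop("need at least two channels")
  pairs <- utils::combn(chans, 2)
  out <- tibble::tibble(
    ch_a = pairs[1, ], ch_b = pairs[2, ],
    plv = apply(pairs, 2, function(p) plv(lfp[[p[1]]], lfp[[p[2]]], band, fs))
  )
  attr(out, "mean_plv") <- mean(out$plv)
  out
}

#' Detect spindle or slow-oscillation episodes
#'
#' Spindles: the envelope (analytic-signal modulus) of the 7-15 Hz filtered
#' signal must exceed `threshold` times the epoch median envelope for at
#' least `min_duration_s`; episodes separated by less than `merge_gap_s` are
#' merged. Thresholding is relative to the epoch's own envelope
#' distribution, so detection is invariant to amplitude rescaling.
#' Slow oscillations: half-waves of the delta-filtered signal qualify when
#' their peak magnitude exceeds `amp_frac` times the 90th-percentile
#' half-wave peak (a robust fraction-of-maximum rule); each qualifying
#' negative half-wave with its successor forms one cycle event.
#'
#' @param lfp `lfp_series`, or numeric vector with `sample_rate_hz`.
#' @param kind `"spindle"` or `"slow_oscillation"`.
#' @param band Hz band (defaults per kind: 7-15 or 0.5-4).
#' @param threshold Envelope threshold in multiples of the median (spindle).
#' @param min_duration_s Minimum episode duration (spindle).
#' @param merge_gap_s Merge gap (spindle).
#' @param amp_frac Half-wave amplitude threshold as a fraction of the
#'   90th-percentile peak (slow oscillation).
#' @param sample_rate_hz Sample rate when `lfp` is a plain vector.
#' @param channel Channel to analyze (default first).
#' @param method Spindle detection method: `"envelope"` (Hilbert envelope at
#'   full time resolution, default) or `"spectrogram"` (band power in 1 s
#'   windows sliding by 0.25 s; episodes are maximal runs of windows with
#'   power above `threshold` times the median window power, so bursts closer
#'   than the window length merge — this mirrors reading episode durations
#'   off a spectrogram).
#' @return Tibble: `onset_s`, `offset_s`, `duration_s`, `peak_freq_hz`.
#' @export
detect_events <- function(lfp, kind = c("spindle", "slow_oscillation"),
                          band = NULL, threshold = 2, min_duration_s = 0.4,
                          merge_gap_s = 0.3, amp_frac = 0.4,
                          sample_rate_hz = NULL, channel = NULL,
                          method = c("envelope", "spectrogram")) {
  kind <- match.arg(kind)
  method <- match.arg(method)
  if (is.numeric(lfp)) {
    fs <- sample_rate_hz
    if (is.null(fs)) stop("sample_rate_hz required for vector input")
    x <- lfp
    t0 <- 0
  } else {
    fs <- lfp_rate(lfp, sample_rate_hz)
    if (is.null(channel)) channel <- lfp_channels(lfp)[1]
    x <- lfp[[channel]]
    t0 <- lfp$time_s[1]
  }
  if (fs < 100) stop("sample rate must be >= 100 Hz")
  empty <- tibble::tibble(
    onset_s = numeric(0), offset_s = numeric(0),
    duration_s = numeric(0), peak_freq_hz = numeric(0)
  )
  if (sd(x) == 0) {
    return(empty)
  }
  if (kind == "spindle" && method == "spectrogram") {
    if (is.null(band)) band <- c(7, 15)
    win_s <- 1
    slide_s <- 0.25
    lf <- tibble::tibble(time_s = t0 + seq_along(x) / fs, x = x)
    names(lf)[2] <- "ch1"
    attr(lf, "sample_rate_hz") <- fs
    class(lf) <- c("lfp_series", class(lf))
    bp <- band_power(lf, band, window_s = win_s, slide_s = slide_s)
    above <- bp$power > threshold * median(bp$power)
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    seg <- tibble::tibble(
      onset_s = bp$window_start_s[starts[r$values]],
      offset_s = bp$window_end_s[ends[r$values]]
    )
    if (nrow(seg) == 0) {
      return(empty)
    }
    # successive window spans can overlap; merge overlapping episodes
    merged <- list()
    cur <- seg[1, ]
    if (nrow(seg) > 1) {
      for (i in 2:nrow(seg)) {
        if (seg$onset_s[i] <= cur$offset_s) {
          cur$offset_s <- max(cur$offset_s, seg$offset_s[i])
        } else {
          merged[[length(merged) + 1]] <- cur
          cur <- seg[i, ]
        }
      }
    }
    merged[[length(merged) + 1]] <- cur
    seg <- dplyr::bind_rows(merged)
    seg$duration_s <- seg$offset_s - seg$onset_s
    seg <- seg[seg$duration_s >= min_duration_s, ]
    if (nrow(seg) == 0) {
      return(empty)
    }
    filt <- fft_bandpass(x, fs, band[1], band[2])
    seg$peak_freq_hz <- vapply(seq_len(nrow(seg)), function(i) {
      i0 <- max(1, round((seg$onset_s[i] - t0) * fs))
      i1 <- min(length(filt), round((seg$offset_s[i] - t0) * fs))
      xs <- filt[i0:i1]
      n <- length(xs)
      spec <- Mod(fft(xs - mean(xs)))^2
      f <- (seq_len(n) - 1) * fs / n
      inb <- which(f >= band[1] & f <= band[2])
      if (length(inb) == 0) {
        return(NA_real_)
      }
      f[inb[which.max(spec[inb])]]
    }, numeric(1))
    return(seg[, c("onset_s", "offset_s", "duration_s", "peak_freq_hz")])
  }
  if (kind == "spindle") {
    if (is.null(band)) band <- c(7, 15)
    filt <- fft_bandpass(x, fs, band[1], band[2])
    env <- Mod(hilbert_analytic(filt))
    thr <- threshold * median(env)
    above <- env > thr
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    seg <- tibble::tibble(start = starts[r$values], end = ends[r$values])
    if (nrow(seg) == 0) {
      return(empty)
    }
    # merge short gaps
    merged <- list()
    cur <- seg[1, ]
    if (nrow(seg) > 1) {
      for (i in 2:nrow(seg)) {
        if ((seg$start[i] - cur$end) / fs < merge_gap_s) {
          cur$end <- seg$end[i]
        } else {
          merged[[length(merged) + 1]] <- cur
          cur <- seg[i, ]
        }
      }
    }
    merged[[length(merged) + 1]] <- cur
    seg <- dplyr::bind_rows(merged)
    seg <- seg[(seg$end - seg$start + 1) / fs >= min_duration_s, ]
    if (nrow(seg) == 0) {
      return(empty)
    }
    pk <- vapply(seq_len(nrow(seg)), function(i) {
      xs <- filt[seg$start[i]:seg$end[i]]
      n <- length(xs)
      spec <- Mod(fft(xs - mean(xs)))^2
      f <- (seq_len(n) - 1) * fs / n
      inb <- which(f >= band[1] & f <= band[2])
      if (length(inb) == 0) {
        return(NA_real_)
      }
      f[inb[which.max(spec[inb])]]
    }, numeric(1))
    tibble::tibble(
      onset_s = t0 + (seg$start - 1) / fs,
      offset_s = t0 + seg$end / fs,
      duration_s = (seg$end - seg$start + 1) / fs,
      peak_freq_hz = pk
    )
  } else {
    if (is.null(band)) band <- c(0.5, 4)
    filt <- fft_bandpass(x, fs, band[1], band[2])
    sgn <- sign(filt)
    sgn[sgn == 0] <- 1
    chg <- which(diff(sgn) != 0)
    if (length(chg) < 2) {
      return(empty)
    }
    bounds <- c(1, chg, length(filt))
    hw <- tibble::tibble(
      start = utils::head(bounds, -1) + c(0, rep(1, length(bounds) - 2)),
      end = utils::tail(bounds, -1)
    )
    hw$peak <- vapply(seq_len(nrow(hw)), function(i) {
      max(abs(filt[hw$start[i]:hw$end[i]]))
    }, numeric(1))
    hw$neg <- vapply(seq_len(nrow(hw)), function(i) {
      mean(filt[hw$start[i]:hw$end[i]]) < 0
    }, logical(1))
    thr <- amp_frac * quantile(hw$peak, 0.9)
    hw$ok <- hw$peak >= thr
    ev <- list()
    i <- 1
    while (i < nrow(hw)) {
      if (hw$neg[i] && hw$ok[i] && !hw$neg[i + 1] && hw$ok[i + 1]) {
        ev[[length(ev) + 1]] <- tibble::tibble(start = hw$start[i], end = hw$end[i + 1])
        i <- i + 2
      } else {
        i <- i + 1
      }
    }
    if (length(ev) == 0) {
      return(empty)
    }
    ev <- dplyr::bind_rows(ev)
    dur <- (ev$end - ev$start + 1) / fs
    tibble::tibble(
      onset_s = t0 + (ev$start - 1) / fs,
      offset_s = t0 + ev$end / fs,
      duration_s = dur,
      peak_freq_hz = 1 / dur
    )
  }
}

#' Spindle-band episode detection on the spectrogram scale
#'
#' Convenience wrapper: detects 7-15 Hz episodes on the global LFP of a
#' simulation segment and summarizes counts, median duration and
#' inter-onset intervals.
#'
#' @param lfp An `lfp_series`.
#' @param ... Passed to [detect_events()].
#' @return List with `events` (tibble), `n`, `median_duration_s`,
#'   `mean_onset_interval_s` (NA with < 2 events).
#' @export
spindle_stats <- function(lfp, ...) {
  ev <- detect_events(lfp, "spindle", ...)
  ev <- ev[order(ev$onset_s), ]
  list(
    events = ev,
    n = nrow(ev),
    median_duration_s = if (nrow(ev)) median(ev$duration_s) else NA_real_,
    mean_onset_interval_s = if (nrow(ev) > 1) mean(diff(ev$onset_s)) else NA_real_
  )
}

#' Dominant spectral peak of a channel
#'
#' @param lfp `lfp_series`.
#' @param fmin,fmax Search range (Hz).
#' @param channel Channel (default first).
#' @return Peak frequency (Hz) of the Hann periodogram of the whole segment.
#' @export
dominant_frequency <- function(lfp, fmin = 0.1, fmax = 30, channel = NULL) {
  fs <- lfp_rate(lfp)
  if (is.null(channel)) channel <- lfp_channels(lfp)[1]
  x <- lfp[[channel]]
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
  spec <- Mod(fft((x - mean(x)) * w))^2
  f <- (seq_len(n) - 1) * fs / n
  inb <- which(f >= fmin & f <= fmax)
  f[inb[which.max(spec[inb])]]
}

#' Per-window spectral feature table
#'
#' Computes, for consecutive windows of a simulation: delta power and
#' spindle power of the global LFP, the mean pairwise PLV across group
#' LFPs, and the stage label. This is the input to
#' [spindle_delta_correlation()] and [cluster_states()].
#'
#' @param sim A `tc_sim`.
#' @param window_s Window length (s), non-overlapping.
#' @param bands A [band_presets()] list.
#' @param group_size Cells per LFP group for the PLV channels (default:
#'   population size / 5).
#' @param discard_s Transient override.
#' @return Tibble: `window_start_s`, `window_end_s`, `delta_power`,
#'   `spindle_power`, `plv`, `stage`.
#' @export
feature_table <- function(sim, window_s = 2, bands = band_presets("model"),
                          group_size = NULL, discard_s = NULL) {
  stopifnot(inherits(sim, "tc_sim"))
  lfp_all <- compute_lfp(sim, "all", discard_s = discard_s)
  n_py <- ncol(sim$py_vd)
  if (is.null(group_size)) group_size <- max(1, floor(n_py / 5))
  lfp_g <- compute_lfp(sim, groups_of(group_size), discard_s = discard_s)
  fs <- lfp_rate(lfp_all)
  d <- band_power(lfp_all, bands$delta, window_s = window_s)
  s <- band_power(lfp_all, bands$spindle, window_s = window_s)
  nwin <- floor(window_s * fs)
  starts <- seq(1, nrow(lfp_g) - nwin + 1, by = nwin)
  pl <- vapply(starts, function(st) {
    sub <- lfp_g[st:(st + nwin - 1), ]
    vars <- vapply(lfp_channels(sub), function(c2) var(sub[[c2]]), numeric(1))
    if (any(vars == 0)) {
      return(NA_real_)
    }
    attr(plv_pairs(sub, bands$plv, fs), "mean_plv")
  }, numeric(1))
  nw <- min(nrow(d), length(pl))
  out <- tibble::tibble(
    window_start_s = d$window_start_s[seq_len(nw)],
    window_end_s = d$window_end_s[seq_len(nw)],
    delta_power = d$power[seq_len(nw)],
    spindle_power = s$power[seq_len(nw)],
    plv = pl[seq_len(nw)]
  )
  out$stage <- schedule_stage_at(sim$config$schedule, out$window_start_s)
  out
}

#' Correlation between spindle and delta power across windows
#'
#' Pearson correlation with the standard t-based two-sided test.
#'
#' @param features Data frame with `spindle_power` and `delta_power` (e.g.
#'   from [feature_table()]), or any two-column numeric data frame.
#' @param log_transform Correlate log10 powers (default TRUE; powers span
#'   orders of magnitude)?
#' @return Tibble with `r`, `p_value`, `n`.
#' @export
spindle_delta_correlation <- function(features, log_transform = TRUE) {
  x <- features$spindle_power
  y <- features$delta_power
  if (is.null(x) || is.null(y)) {
    x <- features[[1]]
    y <- features[[2]]
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) stop("need at least 3 windows")
  if (log_transform) {
    eps <- 1e-12
    x <- log10(x + eps)
    y <- log10(y + eps)
  }
  ct <- suppressWarnings(cor.test(x, y))
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Gaussian-mixture clustering of network regimes
#'
#' Fits full-covariance Gaussian mixtures with 1..`max_components`
#' components to the feature space (log10 delta power, log10 spindle power,
#' PLV by default), by EM (up to `em_iter` iterations), computes the AIC
#' curve, and selects the component count at which the AIC saturates: the
#' smallest k with `AIC(k+1) - AIC(k) > -q` (plain argmin with
#' `rule = "argmin"`).
#'
#' @param features Data frame of feature columns (see `feature_cols`).
#' @param max_components Largest component count fitted.
#' @param feature_cols Columns used (default delta, spindle, PLV).
#' @param log_power Apply log10 to the power columns?
#' @param em_iter Maximum EM iterations.
#' @param seed RNG seed (initialization and any restarts).
#' @param q Saturation tolerance on the AIC difference.
#' @param rule `"saturation"` or `"argmin"`.
#' @return Object of class `state_cluster_model`: mixture parameters,
#'   AIC curve, selected `k`, per-row assignments.
#' @export
cluster_states <- function(features, max_components = 12,
                           feature_cols = c("delta_power", "spindle_power", "plv"),
                           log_power = TRUE, em_iter = 500, seed = 1,
                           q = 2, rule = c("saturation", "argmin")) {
  rule <- match.arg(rule)
  stopifnot(all(feature_cols %in% names(features)))
  X <- as.data.frame(features)[, feature_cols]
  if (log_power) {
    for (cc in grep("power", feature_cols, value = TRUE)) {
      X[[cc]] <- log10(X[[cc]] + 1e-12)
    }
  }
  ok <- stats::complete.cases(X)
  X <- as.matrix(X[ok, ])
  if (nrow(X) < 3) stop("need at least 3 complete feature rows")
  max_components <- min(max_components, nrow(X) - 1)
  ctrl <- emControl(itmax = c(em_iter, em_iter))
  fits <- vector("list", max_components)
  aic <- rep(NA_real_, max_components)
  set.seed(seed)
  for (g in seq_len(max_components)) {
    fit <- tryCatch(
      suppressWarnings(Mclust(X,
        G = g, modelNames = "VVV",
        control = ctrl, verbose = FALSE
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    df <- nMclustParams("VVV", d = ncol(X), G = g)
    fits[[g]] <- fit
    aic[g] <- -2 * fit$loglik + 2 * df
  }
  if (all(is.na(aic))) stop("no mixture could be fitted")
  k <- if (rule == "argmin") {
    which.min(aic)
  } else {
    sel <- NA_integer_
    for (g in seq_len(max_components - 1)) {
      if (!is.na(aic[g]) && !is.na(aic[g + 1]) && (aic[g + 1] - aic[g]) > -q) {
        sel <- g
        break
      }
    }
    if (is.na(sel)) which.min(aic) else sel
  }
  fit <- fits[[k]]
  structure(
    list(
      k = k, aic = aic, loglik = fit$loglik,
      means = fit$parameters$mean,
      covariances = fit$parameters$variance$sigma,
      weights = fit$parameters$pro,
      assignment = {
        a <- rep(NA_integer_, length(ok))
        a[ok] <- fit$classification
        a
      },
      feature_cols = feature_cols, log_power = log_power,
      data = X, rule = rule, q = q, seed = seed
    ),
    class = "state_cluster_model"
  )
}

#' @export
print.state_cluster_model <- function(x, ...) {
  cat(sprintf(
    "<state_cluster_model> %d components (of %d tried), loglik %.1f\n",
    x$k, length(x$aic), x$loglik
  ))
  cat("AIC: ", paste(round(x$aic, 1), collapse = " "), "\n")
  invisible(x)
}

#' Project clusters into neuromodulator space
#'
#' For each cluster, the member trials' (ACh, HA, GABA) coordinates give an
#' ellipsoid: center at the member mean, axes from the eigendecomposition
#' of the member covariance. Clusters with fewer than 4 members are flagged
#' degenerate and get no ellipsoid.
#'
#' @param model A `state_cluster_model`.
#' @param coords Data frame with columns `ach`, `ha`, `gaba`, one row per
#'   feature row used in the clustering.
#' @return Tibble: `cluster`, `n`, `degenerate`, center columns, axis
#'   lengths `axis1..3` (sqrt eigenvalues) and list-column `cov`.
#' @export
project_clusters <- function(model, coords) {
  stopifnot(inherits(model, "state_cluster_model"))
  cols <- c("ach", "ha", "gaba")
  if (!all(cols %in% names(coords))) stop("coords needs columns ach, ha, gaba")
  if (nrow(coords) != length(model$assignment)) {
    stop("coords must have one row per clustered trial")
  }
  purrr::map_dfr(seq_len(model$k), function(cl) {
    idx <- which(model$assignment == cl)
    m <- coords[idx, cols, drop = FALSE]
    if (length(idx) < 4) {
      return(tibble::tibble(
        cluster = cl, n = length(idx), degenerate = TRUE,
        ach = if (length(idx)) mean(m$ach) else NA_real_,
        ha = if (length(idx)) mean(m$ha) else NA_real_,
        gaba = if (length(idx)) mean(m$gaba) else NA_real_,
        axis1 = NA_real_, axis2 = NA_real_, axis3 = NA_real_,
        cov = list(NULL)
      ))
    }
    cv <- stats::cov(m)
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
    ev[ev < 0] <- 0
    tibble::tibble(
      cluster = cl, n = length(idx), degenerate = FALSE,
      ach = mean(m$ach), ha = mean(m$ha), gaba = mean(m$gaba),
      axis1 = sqrt(ev[1]), axis2 = sqrt(ev[2]), axis3 = sqrt(ev[3]),
      cov = list(cv)
    )
  })
}
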