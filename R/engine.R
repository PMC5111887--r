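flatten_constants <- function(constants = somnet_constants()) {
  v <- unlist(constants)
  storage.mode(v) <- "double"
  v
}

pop_ids <- c(PY = 0L, IN = 1L, TC = 2L, RE = 3L)
type_ids <- c(AMPA = 0L, NMDA = 1L, GABA_A = 2L, GABA_B = 3L)
lclass_ids <- c(none = 0L, lach = 1L, lgaba_cx = 2L, lgaba_th = 3L)

#' Simulation configuration
#'
#' @param schedule A [stage_schedule()] defining the stage sequence; total
#'   run duration is the sum of stage durations.
#' @param dt_ms Integration step (ms).
#' @param seed Integer seed; a fixed seed gives a bit-reproducible run.
#' @param discard_s Initial transient (s) that analysis-facing accessors drop
#'   (the raw recordings keep it).
#' @param record_py_v Record all PY dendritic voltages (needed for LFPs)?
#' @param record_dt_ms Sampling interval of stored voltages (default 1 ms,
#'   i.e. 1 kHz).
#' @param v_jitter_mV Uniform jitter of initial voltages (seeded).
#' @param stim List of stimulation events (see [apply_dc_pulse()]).
#' @param extended Extended-model mode: dendritic KCa, Km and persistent-Na
#'   conductances are additionally scaled by AChPY (default off).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(schedule, dt_ms = NULL, seed = 1, discard_s = 0,
                       record_py_v = TRUE, record_dt_ms = 1,
                       v_jitter_mV = 2, stim = list(), extended = FALSE) {
  stopifnot(inherits(schedule, "stage_schedule"))
  if (is.null(dt_ms)) dt_ms <- somnet_constants()$engine$dt_ms
  stopifnot(dt_ms > 0)
  duration_s <- sum(schedule$durations_s)
  if (duration_s <= discard_s) stop("duration must exceed the discarded transient")
  structure(
    list(
      schedule = schedule, dt_ms = dt_ms, seed = as.integer(seed),
      discard_s = discard_s, record_py_v = record_py_v,
      record_dt_ms = record_dt_ms, v_jitter_mV = v_jitter_mV,
      stim = stim, extended = extended, duration_s = duration_s
    ),
    class = "sim_config"
  )
}

#' Add a DC current pulse to a configuration
#'
#' The standard stability probe is a 100 ms, 1.5 nA DC pulse to the TC
#' population.
#'
#' @param config A [sim_config()].
#' @param pop Target population (`"PY"|"IN"|"TC"|"RE"`).
#' @param amplitude_nA Pulse amplitude (nA), finite.
#' @param duration_ms Pulse duration (ms).
#' @param onset_ms Pulse onset (ms from run start).
#' @return The updated config.
#' @export
apply_dc_pulse <- function(config, pop = "TC", amplitude_nA = 1.5,
                           duration_ms = 100, onset_ms = 1000) {
  stopifnot(inherits(config, "sim_config"), is.finite(amplitude_nA))
  if (onset_ms < 0 || (onset_ms + duration_ms) > config$duration_s * 1000) {
    stop("stimulation window lies outside the run duration")
  }
  config$stim <- c(config$stim, list(list(
    pop = unname(pop_ids[[pop]]), amp = amplitude_nA,
    from = onset_ms, to = onset_ms + duration_ms
  )))
  config
}

# compact per-target fan-in ranges for the compiled engine
compact_projections <- function(network) {
  edges <- network$edges
  sizes <- network$spec$sizes
  split_edges <- split(edges, edges$projection)
  lapply(split_edges, function(ed) {
    src_pop <- pop_ids[[projection_defs(network$spec$constants)$src[
      projection_defs(network$spec$constants)$projection == ed$projection[1]
    ]]]
    d <- projection_defs(network$spec$constants)
    d <- d[d$projection == ed$projection[1], ]
    n_tgt <- sizes[[d$tgt]]
    lo <- rep(1L, n_tgt)
    hi <- rep(0L, n_tgt)
    w <- rep(0, n_tgt)
    self_ex <- rep(0L, n_tgt)
    by_tgt <- split(ed$src - 1L, ed$tgt)
    for (tg in names(by_tgt)) {
      j <- as.integer(tg)
      srcs <- sort(by_tgt[[tg]])
      rng <- range(srcs)
      expected <- rng[1]:rng[2]
      hole <- setdiff(expected, srcs)
      if (length(hole) == 0) {
        self_ex[j] <- 0L
      } else if (identical(hole, j - 1L) || identical(hole, as.integer(j - 1L))) {
        self_ex[j] <- 1L
      } else {
        stop("non-contiguous fan-in range for ", ed$projection[1], " target ", j)
      }
      lo[j] <- rng[1]
      hi[j] <- rng[2]
      w[j] <- ed$weight_uS[ed$tgt == j][1]
    }
    list(
      type = unname(type_ids[[d$type]]),
      src_pop = unname(pop_ids[[d$src]]),
      tgt_pop = unname(pop_ids[[d$tgt]]),
      l_class = unname(lclass_ids[[d$l_class]]),
      depression = d$depression,
      lo = lo, hi = hi, self_ex = self_ex, w = w
    )
  })
}

mini_edge_table <- function(network) {
  edges <- dplyr::filter(network$edges, .data$g_mini_uS > 0)
  if (nrow(edges) == 0) {
    return(data.frame(
      src_pop = integer(0), src = integer(0), tgt_pop = integer(0),
      tgt = integer(0), cls = integer(0), g = numeric(0)
    ))
  }
  d <- projection_defs(network$spec$constants)
  meta <- setNames(split(d, seq_len(nrow(d))), d$projection)
  src_pop <- vapply(edges$projection, function(p) unname(pop_ids[[meta[[p]]$src]]), integer(1))
  tgt_pop <- vapply(edges$projection, function(p) unname(pop_ids[[meta[[p]]$tgt]]), integer(1))
  cls <- ifelse(edges$type == "GABA_A", 2L, ifelse(edges$l_class == "lach", 0L, 1L))
  data.frame(
    src_pop = src_pop, src = edges$src - 1L, tgt_pop = tgt_pop,
    tgt = edges$tgt - 1L, cls = cls, g = edges$g_mini_uS
  )
}

#' Run a network simulation
#'
#' Integrates the assembled network under a stage schedule with the compiled
#' engine. Identical seeds give bit-identical results. Miniature PSPs are
#' the only noise source.
#'
#' @param network A `tc_network` from [assemble_network()].
#' @param config A [sim_config()].
#' @return Object of class `tc_sim` with elements:
#'   `time_s` (recording times), `py_vd` (matrix, PY dendritic voltages at
#'   the recording rate), `pop_mean` (tibble of population-mean voltages),
#'   `exemplar` (tibble, one representative cell per population), `spikes`
#'   (tibble: `pop`, `cell`, `t_ms`), `scalars` (applied neuromodulator
#'   scalar time courses), `gate_range`, `config`, `network_summary`.
#' @export
simulate_network <- function(network, config) {
  stopifnot(inherits(network, "tc_network"), inherits(config, "sim_config"))
  if (network$spec$boundary != "truncate") {
    stop("the compiled engine supports the flat ('truncate') boundary rule")
  }
  consts <- network$spec$constants
  scal <- schedule_scalars(config$schedule)
  scal_mat <- as.matrix(scal[, c("time_ms", scalar_names)])
  res <- run_network_cpp(
    flatten_constants(consts),
    list(
      n_py = unname(network$spec$sizes[["PY"]]), n_in = unname(network$spec$sizes[["IN"]]),
      n_tc = unname(network$spec$sizes[["TC"]]), n_re = unname(network$spec$sizes[["RE"]])
    ),
    unname(compact_projections(network)),
    mini_edge_table(network),
    scal_mat,
    list(
      dt = config$dt_ms, seed = as.double(config$seed),
      duration_ms = config$duration_s * 1000,
      record_dt_ms = config$record_dt_ms, record_py_v = config$record_py_v,
      v_jitter = config$v_jitter_mV, stim = config$stim,
      extended = config$extended
    )
  )
  pops <- c("PY", "IN", "TC", "RE")
  spikes <- dplyr::bind_rows(lapply(seq_along(pops), function(i) {
    df <- res[[paste0("spikes_", tolower(pops[i]))]]
    tibble::tibble(pop = pops[i], cell = df$cell + 1L, t_ms = df$t_ms)
  }))
  pop_mean <- tibble::as_tibble(as.data.frame(res$pop_mean))
  names(pop_mean) <- pops
  pop_mean$time_s <- res$time_s
  exemplar <- tibble::as_tibble(as.data.frame(res$exemplar))
  names(exemplar) <- pops
  exemplar$time_s <- res$time_s
  scalars <- tibble::as_tibble(as.data.frame(res$scalars))
  names(scalars) <- scalar_names
  scalars$time_s <- res$time_s
  structure(
    list(
      time_s = res$time_s, py_vd = res$py_vd, pop_mean = pop_mean,
      exemplar = exemplar, spikes = spikes, scalars = scalars,
      gate_range = c(min = res$gate_min, max = res$gate_max),
      config = config, network_summary = network$summary,
      sizes = network$spec$sizes
    ),
    class = "tc_sim"
  )
}

#' @export
print.tc_sim <- function(x, ...) {
  cat(sprintf(
    "<tc_sim> %.1f s, %d PY cells recorded at %.0f Hz, %d spikes, seed %d\n",
    max(x$time_s), ncol(x$py_vd), 1000 / x$config$record_dt_ms,
    nrow(x$spikes), x$config$seed
  ))
  print(firing_rates(x))
  invisible(x)
}

#' Mean firing rates per population (and optionally per stage)
#'
#' Rates are computed over the analysis window (after the configured
#' transient).
#'
#' @param sim A `tc_sim`.
#' @param by_stage Split by schedule stage?
#' @return Tibble with `pop`, optional `stage`, `rate_hz`.
#' @export
firing_rates <- function(sim, by_stage = FALSE) {
  stopifnot(inherits(sim, "tc_sim"))
  t0 <- sim$config$discard_s
  t_end <- sim$config$duration_s
  n_cells <- c(
    PY = unname(sim$sizes[["PY"]]), IN = unname(sim$sizes[["IN"]]),
    TC = unname(sim$sizes[["TC"]]), RE = unname(sim$sizes[["RE"]])
  )
  sp <- dplyr::filter(sim$spikes, .data$t_ms >= t0 * 1000)
  if (by_stage) {
    sp$stage <- schedule_stage_at(sim$config$schedule, sp$t_ms / 1000)
    stages <- tibble::tibble(
      stage = sim$config$schedule$labels,
      dur = sim$config$schedule$durations_s
    )
    grid <- tidyr::expand_grid(pop = names(n_cells), stages)
    counts <- dplyr::count(sp, .data$pop, .data$stage)
    out <- dplyr::left_join(grid, counts, by = c("pop", "stage"))
    out$n[is.na(out$n)] <- 0L
    # note: the transient is not subtracted per stage; rates in the first
    # stage include only post-transient spikes over the full stage length
    out$rate_hz <- out$n / (n_cells[out$pop] * out$dur)
    return(dplyr::select(out, "pop", "stage", "rate_hz"))
  }
  counts <- dplyr::count(sp, .data$pop)
  out <- tibble::tibble(pop = names(n_cells))
  out <- dplyr::left_join(out, counts, by = "pop")
  out$n[is.na(out$n)] <- 0L
  out$rate_hz <- out$n / (n_cells[out$pop] * (t_end - t0))
  dplyr::select(out, "pop", "rate_hz")
}

#' Export a spike raster as columnar text
#'
#' @param sim A `tc_sim`.
#' @param path Output path (tab-separated: pop, cell_id, t_ms).
#' @return `path`, invisibly.
#' @export
export_spikes <- function(sim, path) {
  utils::write.table(sim$spikes, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
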