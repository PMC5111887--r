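# Printed per-stage tables: neuromodulator levels (% of awake) and the
# derived parameter scalars. AChTC for N3 is not printed; 2.0 is shipped as
# the default (the thalamus-only N3 minimal-model preset uses 2.0), see the
# methods vignette.
stage_table <- function() {
  tibble::tibble(
    stage = c("awake", "n2", "n3", "rem"),
    ach = c(100, 80, 50, 115),
    ha = c(100, 40, 30, 10),
    gaba = c(100, 115, 130, 75),
    ach_py = c(1, 1.25, 1.8, 0.85),
    ach_tc = c(1, 1.25, 2.0, 0.85),
    ach_re = c(1, 0.8, 0.5, 1.15),
    lach = c(1, 1.25, 2.0, 0.8),
    lgaba = c(1, 1.15, 1.3, 0.75),
    shift_ha = c(-8, -3, -2, 0)
  )
}

new_neuromod_state <- function(levels, scalars, mini_scale = 1, tau_scale = 1) {
  s <- c(as.list(levels), as.list(scalars),
    list(mini_scale = mini_scale, tau_scale = tau_scale)
  )
  # LGABA acts on cortical (IN-PY) and thalamic (RE-RE, RE-TC) GABA-A
  # conductances; the two components can be overridden independently
  # (minimal-model experiments restrict changes to one region).
  if (is.null(s$lgaba_cx)) s$lgaba_cx <- s$lgaba
  if (is.null(s$lgaba_th)) s$lgaba_th <- s$lgaba
  structure(s, class = "neuromod_state")
}

#' Override individual neuromodulator scalars
#'
#' Builds a modified copy of a `neuromod_state` with named scalars replaced,
#' e.g. restricting stage changes to the thalamus or cortex for
#' minimal-model experiments. Settable fields: `ach_py`, `ach_tc`,
#' `ach_re`, `lach`, `lgaba_cx` (IN-PY), `lgaba_th` (RE-RE, RE-TC),
#' `shift_ha`, `mini_scale`, `tau_scale`.
#'
#' @param state Base `neuromod_state`.
#' @param ... Named scalar replacements.
#' @return A `neuromod_state`.
#' @export
modulator_override <- function(state, ...) {
  stopifnot(inherits(state, "neuromod_state"))
  repl <- list(...)
  allowed <- c(scalar_names, "lgaba")
  bad <- setdiff(names(repl), allowed)
  if (length(bad)) stop("unknown scalar(s): ", paste(bad, collapse = ", "))
  for (nm in names(repl)) {
    state[[nm]] <- repl[[nm]]
    if (nm == "lgaba") {
      state$lgaba_cx <- repl[[nm]]
      state$lgaba_th <- repl[[nm]]
    }
  }
  state
}

#' @export
print.neuromod_state <- function(x, ...) {
  cat(sprintf(
    "<neuromod_state> ACh %.0f%%, HA %.0f%%, GABA %.0f%%\n", x$ach, x$ha, x$gaba
  ))
  cat(sprintf(
    "  AChPY %.3g  AChTC %.3g  AChRE %.3g  LACh %.3g  LGABA %.3g  ShiftHA %.3g mV\n",
    x$ach_py, x$ach_tc, x$ach_re, x$lach, x$lgaba, x$shift_ha
  ))
  if (x$mini_scale != 1 || x$tau_scale != 1) {
    cat(sprintf("  mini-IPSP scale %.3g  GABA-A tau scale %.3g\n", x$mini_scale, x$tau_scale))
  }
  invisible(x)
}

#' Neuromodulator scalars for a named vigilance stage
#'
#' Returns the full per-stage parameter table: the K-leak multipliers
#' (AChPY for cortex, AChTC and AChRE for thalamus), the AMPA multiplier
#' LACh, the GABA-A multiplier LGABA, and the h-current activation shift
#' ShiftHA, together with the stage's nominal ACh/HA/GABA levels.
#'
#' @param stage `"awake"`, `"n2"`, `"n3"` or `"rem"` (case-insensitive).
#' @return A `neuromod_state`.
#' @examples
#' stage_scalars("n3")
#' @export
stage_scalars <- function(stage) {
  stage <- tolower(stage)
  tab <- stage_table()
  if (!stage %in% tab$stage) {
    stop("unknown stage '", stage, "'; expected one of ", paste(tab$stage, collapse = ", "))
  }
  row <- tab[tab$stage == stage, ]
  new_neuromod_state(
    levels = list(ach = row$ach, ha = row$ha, gaba = row$gaba),
    scalars = list(
      ach_py = row$ach_py, ach_tc = row$ach_tc, ach_re = row$ach_re,
      lach = row$lach, lgaba = row$lgaba, shift_ha = row$shift_ha
    )
  )
}

# piecewise-linear interpolation through anchor points with linear
# end-segment extrapolation
interp_extrap <- function(x, y, xout) {
  o <- order(x)
  x <- x[o]
  y <- y[o]
  n <- length(x)
  ifelse(
    xout < x[1], y[1] + (xout - x[1]) * (y[2] - y[1]) / (x[2] - x[1]),
    ifelse(
      xout > x[n], y[n] + (xout - x[n]) * (y[n] - y[n - 1]) / (x[n] - x[n - 1]),
      approx(x, y, xout)$y
    )
  )
}

neuromod_bounds <- list(ach = c(0, 150), ha = c(0, 150), gaba = c(0, 250))

#' Neuromodulator scalars for arbitrary ACh/HA/GABA levels
#'
#' Maps continuous neuromodulator levels (percent of the awake level) to the
#' parameter scalars by component-wise piecewise-linear interpolation through
#' the four named-stage anchors, with linear end-segment extrapolation. The
#' mapping is monotone: lower ACh gives larger AChPY/AChTC/LACh and smaller
#' AChRE; lower HA gives a more negative ShiftHA; LGABA equals GABA/100.
#'
#' @param ach,ha,gaba Levels in percent of awake. Allowed ranges: ACh 0-150,
#'   HA 0-150, GABA 0-250.
#' @return A `neuromod_state`.
#' @examples
#' continuous_scalars(100, 100, 100) # awake scalars
#' continuous_scalars(50, 30, 130)   # N3 scalars
#' @export
continuous_scalars <- function(ach, ha, gaba) {
  for (nm in c("ach", "ha", "gaba")) {
    v <- get(nm)
    b <- neuromod_bounds[[nm]]
    if (!is.finite(v) || v < b[1] || v > b[2]) {
      stop(sprintf("%s level %.3g outside allowed range [%g, %g]", toupper(nm), v, b[1], b[2]))
    }
  }
  tab <- stage_table()
  new_neuromod_state(
    levels = list(ach = ach, ha = ha, gaba = gaba),
    scalars = list(
      ach_py = interp_extrap(tab$ach, tab$ach_py, ach),
      ach_tc = interp_extrap(tab$ach, tab$ach_tc, ach),
      ach_re = interp_extrap(tab$ach, tab$ach_re, ach),
      lach = interp_extrap(tab$ach, tab$lach, ach),
      lgaba = interp_extrap(tab$gaba, tab$lgaba, gaba),
      shift_ha = interp_extrap(tab$ha, tab$shift_ha, ha)
    )
  )
}

#' Apply a neuromodulator state to an assembled network
#'
#' Computes the effective parameters: AMPA conductances on the
#' LACh-sensitive projections (PY-PY, TC-PY, TC-IN) are multiplied by LACh,
#' GABA-A conductances on IN-PY, RE-RE and RE-TC by LGABA, potassium-leak
#' conductances by the cell-type scalar, and the h-current activation curve
#' is shifted by ShiftHA. Base parameters are never mutated; re-applying the
#' same state is idempotent.
#'
#' @param network A `tc_network`.
#' @param state A `neuromod_state`.
#' @return The network with an `effective` element (edge weights and cell
#'   scalars under the given state).
#' @export
apply_modulators <- function(network, state) {
  stopifnot(inherits(network, "tc_network"), inherits(state, "neuromod_state"))
  e <- network$edges
  scale <- dplyr::case_when(
    e$l_class == "lach" ~ state$lach,
    e$l_class == "lgaba_cx" ~ state$lgaba_cx,
    e$l_class == "lgaba_th" ~ state$lgaba_th,
    TRUE ~ 1
  )
  network$effective <- list(
    state = state,
    edges = dplyr::mutate(e,
      weight_eff_uS = .data$weight_uS * scale,
      g_mini_eff_uS = .data$g_mini_uS *
        ifelse(.data$type == "GABA_A", state$mini_scale,
          ifelse(e$l_class == "lach", state$lach, 1)
        )
    ),
    ach_py = state$ach_py, ach_tc = state$ach_tc, ach_re = state$ach_re,
    shift_ha = state$shift_ha, tau_scale = state$tau_scale
  )
  network
}

#' Propofol anesthesia mode
#'
#' Lengthens the GABA-A IPSP decay and (in the combined mode) reduces ACh
#' and HA to the levels used for natural slow-wave sleep in the cat version
#' of the model (ACh 75%, HA 30%, GABA 130%). "Increased by 150%" is read as
#' multiplying the decay time constant by 2.5 by default
#' (`interpretation = "increase_by"`); `"factor"` reads it as a multiplier of
#' 1.5.
#'
#' @param mode `"combined"` (tau increase + ACh/HA reduction) or
#'   `"tau_only"` (awake scalars, only the decay lengthened).
#' @param tau_increase_pct Percent increase of the GABA-A decay constant.
#' @param interpretation `"increase_by"` (scale = 1 + pct/100) or
#'   `"factor"` (scale = pct/100).
#' @return A `neuromod_state` with `tau_scale` set.
#' @export
propofol_mode <- function(mode = c("combined", "tau_only"),
                          tau_increase_pct = 150,
                          interpretation = c("increase_by", "factor")) {
  mode <- match.arg(mode)
  interpretation <- match.arg(interpretation)
  stopifnot(tau_increase_pct >= 0)
  tau_scale <- if (interpretation == "increase_by") {
    1 + tau_increase_pct / 100
  } else {
    max(tau_increase_pct / 100, 1)
  }
  base <- if (mode == "combined") continuous_scalars(75, 30, 130) else stage_scalars("awake")
  base$tau_scale <- tau_scale
  base
}

#' Tonic-GABA (miniature IPSP) experiment variants
#'
#' Variant A keeps both phasic and tonic GABA fixed at the awake level for
#' the whole simulation; variant B varies the miniature-IPSP conductance
#' following microdialysis GABA measurements (115% N2, 130% N3, 75% REM);
#' variant C assumes co-release of GABA with ACh/HA (85% N2, 70% N3,
#' 125% REM). In all three variants the phasic (spike-evoked) GABA
#' conductance stays at the awake value.
#'
#' @param variant `"A"`, `"B"` or `"C"`.
#' @param stage Stage name.
#' @return Miniature-IPSP scale factor (1 for awake in all variants).
#' @export
tonic_gaba_variant <- function(variant = c("A", "B", "C"), stage) {
  variant <- match.arg(variant)
  stage <- tolower(stage)
  stopifnot(stage %in% stage_table()$stage)
  tab <- list(
    A = c(awake = 1, n2 = 1, n3 = 1, rem = 1),
    B = c(awake = 1, n2 = 1.15, n3 = 1.30, rem = 0.75),
    C = c(awake = 1, n2 = 0.85, n3 = 0.70, rem = 1.25)
  )
  unname(tab[[variant]][stage])
}

#' Stage schedule
#'
#' Ordered sequence of vigilance stages (or raw neuromodulator states) with
#' durations and linear transition ramps.
#'
#' @param ... Schedule entries: either stage names (`"awake"`, `"n2"`, ...)
#'   or `neuromod_state` objects.
#' @param durations_s Numeric vector of durations (s), recycled.
#' @param ramp_s Transition ramp (s) applied at each stage change (default
#'   1 s linear; 0 gives stepwise changes).
#' @param tonic_variant Optional tonic-GABA variant (`"A"|"B"|"C"`): forces
#'   phasic LGABA to the awake value and sets the mini-IPSP scale per stage.
#' @return Object of class `stage_schedule`.
#' @examples
#' stage_schedule("awake", "n2", "n3", "rem", durations_s = 20)
#' @export
stage_schedule <- function(..., durations_s, ramp_s = 1, tonic_variant = NULL) {
  entries <- list(...)
  if (length(entries) == 0) stop("schedule needs at least one entry")
  if (any(durations_s <= 0)) stop("durations must be positive")
  if (any(ramp_s < 0)) stop("ramps must be non-negative")
  durations_s <- rep_len(durations_s, length(entries))
  ramp_s <- rep_len(ramp_s, length(entries))
  states <- lapply(entries, function(e) {
    if (inherits(e, "neuromod_state")) {
      return(e)
    }
    st <- stage_scalars(e)
    if (!is.null(tonic_variant)) {
      st$mini_scale <- tonic_gaba_variant(tonic_variant, e)
      # phasic GABA fixed at the awake level in the tonic variants
      st$lgaba <- 1
      st$lgaba_cx <- 1
      st$lgaba_th <- 1
    }
    st
  })
  labels <- vapply(seq_along(entries), function(i) {
    if (is.character(entries[[i]])) tolower(entries[[i]]) else sprintf("state%d", i)
  }, character(1))
  structure(
    list(states = states, labels = labels, durations_s = durations_s, ramp_s = ramp_s),
    class = "stage_schedule"
  )
}

# scalar names passed to the engine, in column order
scalar_names <- c(
  "ach_py", "ach_tc", "ach_re", "lach", "lgaba_cx", "lgaba_th",
  "shift_ha", "mini_scale", "tau_scale"
)

#' Scalar time courses of a schedule
#'
#' Expands a [stage_schedule()] into piecewise-linear breakpoints of all
#' engine scalars. With a positive ramp the time courses are continuous;
#' with ramp 0 they are stepwise.
#'
#' @param schedule A `stage_schedule`.
#' @return Tibble with `time_ms`, one column per scalar, and `stage`.
#' @export
schedule_scalars <- function(schedule) {
  stopifnot(inherits(schedule, "stage_schedule"))
  rows <- list()
  t <- 0
  for (i in seq_along(schedule$states)) {
    s <- schedule$states[[i]]
    vals <- unlist(s[scalar_names])
    dur <- schedule$durations_s[i] * 1000
    ramp <- if (i == 1) 0 else schedule$ramp_s[i] * 1000
    ramp <- min(ramp, dur)
    if (i == 1) {
      rows[[length(rows) + 1]] <- c(time_ms = t, vals)
    } else {
      rows[[length(rows) + 1]] <- c(time_ms = t + ramp, vals)
    }
    rows[[length(rows) + 1]] <- c(time_ms = t + dur, vals)
    t <- t + dur
  }
  out <- tibble::as_tibble(as.data.frame(do.call(rbind, rows)))
  out$stage <- rep(schedule$labels, each = 2)
  out
}

#' Stage label at a given time
#'
#' @param schedule A `stage_schedule`.
#' @param time_s Times (s) from the start of the run.
#' @return Character vector of stage labels.
#' @export
schedule_stage_at <- function(schedule, time_s) {
  ends <- cumsum(schedule$durations_s)
  idx <- findInterval(time_s, c(0, utils::head(ends, -1)), rightmost.closed = FALSE)
  idx[idx < 1] <- 1
  idx[idx > length(schedule$labels)] <- length(schedule$labels)
  schedule$labels[idx]
}
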