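#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted regime-cluster model
#'
#' One row per mixture component with its weight and feature-space mean.
#'
#' @param x A `state_cluster_model`.
#' @param ... Unused.
#' @return Tibble.
#' @export
tidy.state_cluster_model <- function(x, ...) {
  mu <- t(x$means)
  colnames(mu) <- x$feature_cols
  out <- tibble::as_tibble(as.data.frame(mu))
  out <- dplyr::mutate(out,
    component = dplyr::row_number(), weight = x$weights,
    n = as.integer(table(factor(x$assignment, levels = seq_len(x$k)))),
    .before = 1
  )
  out
}

#' Model-level summary of a regime-cluster model
#'
#' @param x A `state_cluster_model`.
#' @param ... Unused.
#' @return One-row tibble with `k`, `loglik`, `aic`, `n`.
#' @export
glance.state_cluster_model <- function(x, ...) {
  tibble::tibble(
    k = x$k, loglik = x$loglik, aic = x$aic[x$k],
    n = sum(!is.na(x$assignment))
  )
}

#' Tidy a simulation: per-population, per-stage firing rates
#'
#' @param x A `tc_sim`.
#' @param ... Unused.
#' @return Tibble from [firing_rates()] split by stage.
#' @export
tidy.tc_sim <- function(x, ...) {
  firing_rates(x, by_stage = TRUE)
}

#' One-row summary of a simulation
#'
#' @param x A `tc_sim`.
#' @param ... Unused.
#' @return Tibble with duration, spike count, seed and gate-range check.
#' @export
glance.tc_sim <- function(x, ...) {
  tibble::tibble(
    duration_s = x$config$duration_s,
    dt_ms = x$config$dt_ms,
    n_spikes = nrow(x$spikes),
    seed = x$config$seed,
    gate_min = unname(x$gate_range["min"]),
    gate_max = unname(x$gate_range["max"])
  )
}
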