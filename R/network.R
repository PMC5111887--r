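# Projection table: who connects to whom, with which receptor, scaled by
# which neuromodulator factor. Radii come from the constants file. The
# printed maximal conductance is treated as the total input to a target cell
# and divided by its realized fan-in (boundary-robust); `normalization =
# "per_synapse"` uses the printed value per edge instead.
projection_defs <- function(constants = somnet_constants()) {
  g <- constants$network$gsyn_uS
  m <- constants$synapse$mini
  tibble::tribble(
    ~projection, ~src, ~tgt, ~type, ~g_total, ~l_class, ~depression, ~g_mini,
    "py_py_ampa", "PY", "PY", "AMPA", g$py_py_ampa, "lach", TRUE, m$g_py_py,
    "py_py_nmda", "PY", "PY", "NMDA", g$py_py_nmda, "none", TRUE, 0,
    "py_in_ampa", "PY", "IN", "AMPA", g$py_in_ampa, "none", TRUE, m$g_py_in,
    "py_in_nmda", "PY", "IN", "NMDA", g$py_in_nmda, "none", TRUE, 0,
    "in_py_gabaa", "IN", "PY", "GABA_A", g$in_py_gabaa, "lgaba_cx", FALSE, m$g_in_py,
    "py_tc_ampa", "PY", "TC", "AMPA", g$py_tc_ampa, "none", FALSE, 0,
    "py_re_ampa", "PY", "RE", "AMPA", g$py_re_ampa, "none", FALSE, 0,
    "tc_py_ampa", "TC", "PY", "AMPA", g$tc_py_ampa, "lach", FALSE, 0,
    "tc_in_ampa", "TC", "IN", "AMPA", g$tc_in_ampa, "lach", FALSE, 0,
    "tc_re_ampa", "TC", "RE", "AMPA", g$tc_re_ampa, "none", FALSE, 0,
    "re_tc_gabaa", "RE", "TC", "GABA_A", g$re_tc_gabaa, "lgaba_th", FALSE, 0,
    "re_tc_gabab", "RE", "TC", "GABA_B", g$re_tc_gabab, "none", FALSE, 0,
    "re_re_gabaa", "RE", "RE", "GABA_A", g$re_re_gabaa, "lgaba_th", FALSE, 0
  )
}

radius_key <- c(
  py_py_ampa = "py_py", py_py_nmda = "py_py", py_in_ampa = "py_in",
  py_in_nmda = "py_in", in_py_gabaa = "in_py", py_tc_ampa = "py_tc",
  py_re_ampa = "py_re", tc_py_ampa = "tc_py", tc_in_ampa = "tc_in",
  tc_re_ampa = "tc_re", re_tc_gabaa = "re_tc", re_tc_gabab = "re_tc",
  re_re_gabaa = "re_re"
)

#' Network specification
#'
#' Population sizes, per-projection connection radii and wiring rules for
#' the one-dimensional topographic thalamocortical network (default: 500 PY,
#' 100 IN, 100 TC, 100 RE).
#'
#' @param n_py,n_in,n_tc,n_re Population sizes (>= 1).
#' @param radii Named list overriding connection radii (names as in the
#'   constants file, e.g. `py_py`, `tc_py`).
#' @param boundary `"truncate"` (flat, default) or `"periodic"`.
#' @param normalization `"total"` (printed conductance divided by realized
#'   fan-in, default) or `"per_synapse"`.
#' @param constants Constants list.
#' @return Object of class `network_spec`.
#' @export
network_spec <- function(n_py = NULL, n_in = NULL, n_tc = NULL, n_re = NULL,
                         radii = NULL, boundary = c("truncate", "periodic"),
                         normalization = c("total", "per_synapse"),
                         constants = somnet_constants()) {
  boundary <- match.arg(boundary)
  normalization <- match.arg(normalization)
  net <- constants$network
  sizes <- c(
    PY = if (is.null(n_py)) net$n_py else n_py,
    IN = if (is.null(n_in)) net$n_in else n_in,
    TC = if (is.null(n_tc)) net$n_tc else n_tc,
    RE = if (is.null(n_re)) net$n_re else n_re
  )
  if (any(sizes < 1)) stop("population sizes must be >= 1")
  r <- net$radii
  if (!is.null(radii)) r <- modify_deep(r, radii)
  if (any(unlist(r) < 0)) stop("radii must be non-negative")
  structure(
    list(
      sizes = sizes, radii = r, boundary = boundary,
      normalization = normalization, constants = constants
    ),
    class = "network_spec"
  )
}

#' Reduced-scale network specification
#'
#' Desk-scale surrogate of the full network: 100 PY / 20 IN / 20 TC / 20 RE
#' with all connection radii divided by 5 (rounded up, minimum 1).
#'
#' @param constants Constants list.
#' @inheritParams network_spec
#' @return `network_spec` object.
#' @export
reduced_network_spec <- function(boundary = "truncate", constants = somnet_constants()) {
  r <- lapply(constants$network$radii, function(x) max(1L, ceiling(x / 5)))
  network_spec(
    n_py = 100, n_in = 20, n_tc = 20, n_re = 20, radii = r,
    boundary = boundary, constants = constants
  )
}

#' Map a cell index across layers of different sizes
#'
#' Proportional index mapping between two one-dimensional layers (0-based
#' indices): endpoints map to endpoints and interior cells map to
#' `round(i * (target_size - 1) / (source_size - 1))`.
#'
#' @param source_index 0-based index in the source layer.
#' @param source_size,target_size Layer sizes (>= 1).
#' @return 0-based center index in the target layer.
#' @examples
#' map_center(0, 100, 500)   # 0
#' map_center(99, 100, 500)  # 499
#' @export
map_center <- function(source_index, source_size, target_size) {
  if (source_size < 1 || target_size < 1) stop("empty layer")
  stopifnot(all(source_index >= 0), all(source_index < source_size))
  if (source_size == 1) {
    return(rep(floor((target_size - 1) / 2), length(source_index)))
  }
  round(source_index * (target_size - 1) / (source_size - 1))
}

#' Build the network edge list
#'
#' Deterministic local wiring: for each projection, each *target* cell's
#' index is mapped into the source layer ([map_center()]) and every source
#' cell within the projection radius (source-layer units) connects to it.
#' For same-population projections self-connections are excluded, giving an
#' interior fan-in of `2r`; cross-layer fan-in is `2r + 1`. Under the default
#' flat boundary, edge cells have truncated fan-in. A radius covering the
#' whole source layer yields full connectivity (with a warning).
#'
#' @param spec A [network_spec()].
#' @return Tibble with columns `projection`, `type`, `src`, `tgt` (1-based
#'   within population), `weight_uS` (per-edge maximal conductance after
#'   normalization), `g_mini_uS`, `l_class`, `depression`.
#' @export
build_connectivity <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  defs <- projection_defs(spec$constants)
  out <- vector("list", nrow(defs))
  for (i in seq_len(nrow(defs))) {
    d <- defs[i, ]
    n_src <- spec$sizes[[d$src]]
    n_tgt <- spec$sizes[[d$tgt]]
    r <- spec$radii[[radius_key[[d$projection]]]]
    if (r >= n_src) {
      warning("radius ", r, " covers the whole ", d$src, " layer for ", d$projection,
        "; using full connectivity",
        call. = FALSE
      )
    }
    tgt_idx <- seq_len(n_tgt) - 1L
    centers <- map_center(tgt_idx, n_tgt, n_src)
    edges <- lapply(seq_len(n_tgt), function(j) {
      ctr <- centers[j]
      src0 <- (ctr - r):(ctr + r)
      if (spec$boundary == "periodic") {
        src0 <- src0 %% n_src
      } else {
        src0 <- src0[src0 >= 0 & src0 < n_src]
      }
      src0 <- unique(src0)
      if (d$src == d$tgt) src0 <- src0[src0 != (j - 1L)]
      if (length(src0) == 0) {
        return(NULL)
      }
      w <- if (spec$normalization == "total") d$g_total / length(src0) else d$g_total
      tibble::tibble(src = src0 + 1L, tgt = j, weight_uS = w)
    })
    edges <- dplyr::bind_rows(edges)
    if (nrow(edges) > 0) {
      mini_w <- if (d$g_mini > 0) {
        # the miniature quantum is a property of the synapse: the printed
        # value divided by the canonical (default-network) interior fan-in,
        # independent of the simulated network's scale
        r_def <- spec$constants$network$radii[[radius_key[[d$projection]]]]
        fan_def <- if (d$src == d$tgt) 2 * r_def else 2 * r_def + 1
        if (spec$normalization == "total") d$g_mini / fan_def else d$g_mini
      } else {
        0
      }
      out[[i]] <- tibble::tibble(
        projection = d$projection, type = d$type,
        src = edges$src, tgt = edges$tgt, weight_uS = edges$weight_uS,
        g_mini_uS = mini_w, l_class = d$l_class, depression = d$depression
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Assemble a runnable network
#'
#' Binds the edge list, cell parameters and synapse kinetics into an object
#' the engine can run. The assembly is deterministic given the spec.
#'
#' @param spec [network_spec()].
#' @return Object of class `tc_network` with elements `spec`, `edges`,
#'   `summary` (per-projection edge counts).
#' @export
assemble_network <- function(spec = network_spec()) {
  edges <- build_connectivity(spec)
  summ <- edges |>
    dplyr::count(.data$projection, .data$type, name = "n_edges") |>
    dplyr::arrange(.data$projection)
  structure(list(spec = spec, edges = edges, summary = summ), class = "tc_network")
}

#' @export
print.tc_network <- function(x, ...) {
  s <- x$spec$sizes
  cat(sprintf(
    "<tc_network> %d PY, %d IN, %d TC, %d RE; %d edges\n",
    s[["PY"]], s[["IN"]], s[["TC"]], s[["RE"]], nrow(x$edges)
  ))
  print(x$summary, n = Inf)
  invisible(x)
}

#' Export the per-projection edge-count summary
#'
#' @param network A `tc_network`.
#' @param path Optional path to write a tab-separated table.
#' @return The summary tibble (invisibly if written).
#' @export
network_summary <- function(network, path = NULL) {
  stopifnot(inherits(network, "tc_network"))
  if (!is.null(path)) {
    utils::write.table(network$summary, path,
      sep = "\t", row.names = FALSE, quote = FALSE
    )
    return(invisible(network$summary))
  }
  network$summary
}
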