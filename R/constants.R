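#' @useDynLib somnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom mclust Mclust mclustBIC emControl nMclustParams
#' @importFrom rlang .data
#' @importFrom stats fft cor cor.test quantile setNames rnorm runif approx var sd median aggregate
#' @importFrom utils head tail read.csv write.csv modifyList
NULL

.somnet_env <- new.env(parent = emptyenv())

#' Model constants
#'
#' Loads the versioned constants file shipped with the package
#' (`inst/extdata/constants.yaml`), which holds every numeric parameter of the
#' cell, synapse and network models: conductances, reversal potentials,
#' kinetic rate parameters, compartment areas, connectivity radii and engine
#' defaults. Values can be overridden with a (nested) list, e.g. from a run
#' configuration.
#'
#' @param overrides Optional named (nested) list merged over the defaults.
#' @return Nested list of constants.
#' @examples
#' k <- somnet_constants()
#' k$cortex$py$g_kleak
#' k2 <- somnet_constants(list(cortex = list(py = list(g_kleak = 0.01))))
#' @export
somnet_constants <- function(overrides = NULL) {
  if (is.null(.somnet_env$constants)) {
    path <- system.file("extdata", "constants.yaml", package = "somnet")
    .somnet_env$constants <- yaml::read_yaml(path)
  }
  k <- .somnet_env$constants
  if (!is.null(overrides)) k <- modify_deep(k, overrides)
  k
}

modify_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_deep(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

#' Write the current constants to a YAML file
#'
#' Useful for archiving the exact parameterization of a run alongside its
#' outputs.
#'
#' @param path Output file path.
#' @param constants Constants list (default: package defaults).
#' @return `path`, invisibly.
#' @export
write_constants <- function(path, constants = somnet_constants()) {
  yaml::write_yaml(constants, path)
  invisible(path)
}
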