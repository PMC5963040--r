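#' Run configuration for the TEforge pipeline
#'
#' A validated container for every tunable threshold used downstream.
#' Fractions must lie in (0, 1]; lengths must be positive integers.
#'
#' @slot params named list of parameter values
#' @export
setClass("TEConfig", representation(params = "list"))

.TE_CONFIG_DEFAULTS <- list(
  ## step-1 curation
  min_detected_len = 500L,     # similarity/read-based length filter (bp)
  ## benchmark thresholds
  partial_cov = 0.40,
  complete_cov = 0.70,
  ## annotation
  flc_cov = 0.95,
  chain_gap = 500L,
  anno_min_len = 80L,
  ## family building (80-80-80)
  family_identity = 0.80,
  family_coverage = 0.80,
  family_min_len = 80L,
  mcl_inflation = 1.5,
  ## activity crossing
  expressed_cov = 0.90,
  ## classification
  trim_lard_boundary = 4000L,
  mite_max_len = 800L,
  orf_min_len = 300L,
  terminal_arm_min = 20L,
  terminal_identity = 0.80,
  domain_min_score = 100,
  ## similarity detection
  min_identity = 0.80,
  min_hit_len = 100L,
  ## structural detectors
  ltr_min = 100L, ltr_max = 1000L,
  ltr_elem_min = 1000L, ltr_elem_max = 15000L,
  ltr_identity = 0.85, ltr_tsd = c(4L, 6L),
  tir_min = 10L, tir_tsd = c(2L, 10L), tir_identity = 0.80,
  sine_len_range = c(80L, 600L), sine_min_tail = 8L, sine_tsd = c(7L, 10L),
  ## repetitiveness / read-based detectors
  repeat_k = 16L, repeat_min_copies = 3L,
  reads_k = 21L, abundance_factor = 5,
  ## global
  seed = 1L
)

.FRACTION_PARAMS <- c("partial_cov", "complete_cov", "flc_cov",
                      "family_identity", "family_coverage", "expressed_cov",
                      "min_identity", "ltr_identity", "tir_identity",
                      "terminal_identity")
.LENGTH_PARAMS <- c("min_detected_len", "chain_gap", "anno_min_len",
                    "family_min_len", "trim_lard_boundary", "mite_max_len",
                    "orf_min_len", "terminal_arm_min", "min_hit_len",
                    "ltr_min", "ltr_max", "ltr_elem_min", "ltr_elem_max",
                    "tir_min", "sine_min_tail", "repeat_k", "reads_k")

setValidity("TEConfig", function(object) {
  p <- object@params
  miss <- setdiff(names(.TE_CONFIG_DEFAULTS), names(p))
  if (length(miss)) return(paste("missing parameters:", paste(miss, collapse = ", ")))
  for (nm in .FRACTION_PARAMS) {
    v <- p[[nm]]
    if (!is.numeric(v) || any(v <= 0) || any(v > 1))
      return(sprintf("parameter '%s' must be a fraction in (0, 1]", nm))
  }
  for (nm in .LENGTH_PARAMS) {
    v <- p[[nm]]
    if (!is.numeric(v) || any(v < 1) || any(v != as.integer(v)))
      return(sprintf("parameter '%s' must be a positive integer", nm))
  }
  TRUE
})

#' Build a run configuration
#'
#' @param ... named parameter overrides of the documented defaults
#' @return a validated \linkS4class{TEConfig}
#' @examples
#' cfg <- teConfig(min_detected_len = 400L)
#' cfg[["min_detected_len"]]
#' @export
teConfig <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(.TE_CONFIG_DEFAULTS))
  if (length(unknown))
    .stopf("unknown configuration parameter(s): %s", paste(unknown, collapse = ", "))
  p <- modifyList(.TE_CONFIG_DEFAULTS, over)
  new("TEConfig", params = p)
}

#' @describeIn teConfig parameter access by name
#' @param x a TEConfig
#' @param i parameter name
#' @export
setMethod("[[", "TEConfig", function(x, i) {
  if (!i %in% names(x@params)) .stopf("no such configuration parameter: %s", i)
  x@params[[i]]
})

setMethod("show", "TEConfig", function(object) {
  cat("TEConfig with", length(object@params), "parameters\n")
  p <- object@params
  for (nm in names(p))
    cat(sprintf("  %-20s %s\n", nm, paste(p[[nm]], collapse = "-")))
})

#' Read / write a configuration as YAML
#'
#' @param path file path
#' @return \code{readConfigYAML} returns a TEConfig
#' @export
readConfigYAML <- function(path) {
  p <- yaml::read_yaml(path)
  for (nm in intersect(names(p), .LENGTH_PARAMS)) p[[nm]] <- as.integer(p[[nm]])
  for (nm in c("ltr_tsd", "tir_tsd", "sine_tsd", "sine_len_range",
               "ltr_elem_min", "ltr_elem_max"))
    if (nm %in% names(p)) p[[nm]] <- as.integer(p[[nm]])
  do.call(teConfig, p)
}

#' @rdname readConfigYAML
#' @param config a TEConfig
#' @export
writeConfigYAML <- function(config, path) {
  yaml::write_yaml(config@params, path)
  invisible(path)
}
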