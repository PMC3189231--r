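# Run configuration: thresholds, matching mode, QC gates, ancestry mapping.

#' Pipeline run configuration
#'
#' Assembles (and validates) the configuration list consumed by every
#' pipeline stage. Defaults are the analysis conditions of the study design
#' this package implements:
#' \itemize{
#'   \item \code{frequency_threshold} 0.015 -- candidates whose
#'     ancestry-matched control carrier frequency reaches 1.5\% are
#'     rejected;
#'   \item \code{overlap_fraction} 0.5 with \code{overlap_mode}
#'     \code{"reciprocal"} -- two records are the same CNV when they overlap
#'     by at least half of both their lengths;
#'   \item sample QC: \code{sdlrr_max} 0.4, \code{max_cnvs} 300,
#'     \code{min_call_rate} 0.95, review zone 0.3 < SDLRR < 0.4 with
#'     100-300 CNVs; call QC: \code{min_snps} 3, autosomes only;
#'   \item \code{strict_qc} FALSE -- review-zone samples are kept with a
#'     flag; \code{require_single_introducer} TRUE -- carriers not
#'     explainable by descent from one introducing ancestor are rejected.
#' }
#'
#' @param frequency_threshold Control-frequency rejection threshold.
#' @param overlap_fraction Required overlap fraction for CNV identity.
#' @param overlap_mode \code{"reciprocal"} or \code{"either"}.
#' @param sdlrr_max,max_cnvs,min_call_rate,min_snps Sample/call QC gates.
#' @param review_sdlrr,review_cnvs Bounds of the manual-review zone.
#' @param strict_qc Exclude review-zone samples entirely.
#' @param require_single_introducer Reject candidates without a
#'   single-origin explanation.
#' @param ancestry_by_family Named character vector mapping family id to
#'   ancestry label (used to pick the matched control column).
#' @param default_ancestry Ancestry assumed for unmapped families.
#' @param cohort_sizes Named numeric vector: control cohort sizes by
#'   ancestry, passed to [readPopulationTable()] when reading the control
#'   table.
#' @param cohort_order Order of recruiting cohorts in bracketed carrier
#'   count annotations.
#' @param seed RNG seed recorded with the run.
#' @return A validated configuration list of class \code{"pedcnvseg_config"}.
#' @export
runConfig <- function(frequency_threshold = 0.015,
                      overlap_fraction = 0.5,
                      overlap_mode = c("reciprocal", "either"),
                      sdlrr_max = 0.4,
                      max_cnvs = 300,
                      min_call_rate = 0.95,
                      min_snps = 3,
                      review_sdlrr = c(0.3, 0.4),
                      review_cnvs = c(100, 300),
                      strict_qc = FALSE,
                      require_single_introducer = TRUE,
                      ancestry_by_family = character(),
                      default_ancestry = "EUR",
                      cohort_sizes = c(EUR = 727, AA = 111),
                      cohort_order = c("HIHG", "NBC"),
                      seed = NULL) {
  overlap_mode <- match.arg(overlap_mode)
  cfg <- list(frequency_threshold = frequency_threshold,
              overlap_fraction = overlap_fraction,
              overlap_mode = overlap_mode,
              sdlrr_max = sdlrr_max, max_cnvs = max_cnvs,
              min_call_rate = min_call_rate, min_snps = min_snps,
              review_sdlrr = review_sdlrr, review_cnvs = review_cnvs,
              strict_qc = isTRUE(strict_qc),
              require_single_introducer = isTRUE(require_single_introducer),
              ancestry_by_family = ancestry_by_family,
              default_ancestry = default_ancestry,
              cohort_sizes = cohort_sizes,
              cohort_order = cohort_order,
              seed = seed)
  fr <- c(cfg$frequency_threshold, cfg$overlap_fraction, cfg$min_call_rate)
  if (any(fr < 0 | fr > 1))
    stop("fractions must lie in [0, 1]")
  if (cfg$sdlrr_max <= 0 || cfg$max_cnvs <= 0 || cfg$min_snps <= 0)
    stop("QC thresholds must be positive")
  class(cfg) <- "pedcnvseg_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Reads a YAML file whose keys match the arguments of [runConfig()];
#' unspecified keys keep their defaults, unknown keys are an error.
#'
#' @param path Path to a YAML configuration file.
#' @return A configuration list, as from [runConfig()].
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(runConfig))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (key in c("ancestry_by_family", "cohort_sizes"))
    if (!is.null(raw[[key]])) raw[[key]] <- unlist(raw[[key]])
  do.call(runConfig, raw)
}

#' Write a run configuration to YAML
#'
#' @param config A configuration list from [runConfig()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeRunConfig <- function(config, path) {
  x <- unclass(config)
  x <- x[!vapply(x, is.null, logical(1L))]
  for (key in c("ancestry_by_family", "cohort_sizes")) {
    if (length(x[[key]])) x[[key]] <- as.list(x[[key]])
    else x[[key]] <- NULL
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

familyAncestry <- function(config, family_id) {
  anc <- config$ancestry_by_family
  if (length(anc) && family_id %in% names(anc)) unname(anc[[family_id]])
  else config$default_ancestry
}
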