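# Sample- and call-level quality control gates.

#' Sample-level quality control
#'
#' Applies the array QC gates to per-sample metrics: samples fail when the
#' standard deviation of the normalized intensity (SDLRR) reaches 0.4, when
#' more than 300 CNVs were detected, or when the genotyping call rate falls
#' below 95\%. Samples in the manual-review zone (0.3 < SDLRR < 0.4 and
#' 100-300 detected CNVs, inclusive) are flagged \code{"review"}; boundary
#' values SDLRR = 0.3 and 100 CNVs lie outside the zone. Review samples are
#' retained by default and excluded only under strict QC
#' (\code{config$strict_qc}).
#'
#' @param metrics data.frame with columns \code{sample_id}, \code{sdlrr},
#'   \code{n_cnvs}, \code{call_rate}; any missing metric is an error, never
#'   a silent pass.
#' @param config A [runConfig()] list supplying the thresholds.
#' @return The metrics data.frame with added \code{verdict}
#'   (\code{pass}/\code{review}/\code{fail}) and \code{reasons}
#'   (comma-separated codes) columns.
#' @export
sampleQC <- function(metrics, config = runConfig()) {
  req <- c("sample_id", "sdlrr", "n_cnvs", "call_rate")
  if (!all(req %in% names(metrics)))
    stop("QC metrics must have columns: ", paste(req, collapse = ", "))
  if (any(is.na(metrics$sdlrr) | is.na(metrics$n_cnvs) |
          is.na(metrics$call_rate)))
    stop("missing QC metric for sample(s): ",
         paste(metrics$sample_id[is.na(metrics$sdlrr) |
                                 is.na(metrics$n_cnvs) |
                                 is.na(metrics$call_rate)], collapse = ", "))
  out <- as.data.frame(metrics, stringsAsFactors = FALSE)
  reasons <- vector("list", nrow(out))
  for (i in seq_len(nrow(out))) {
    r <- character()
    if (out$sdlrr[i] >= config$sdlrr_max) r <- c(r, "SDLRR")
    if (out$n_cnvs[i] > config$max_cnvs) r <- c(r, "MAX_CNVS")
    if (out$call_rate[i] < config$min_call_rate) r <- c(r, "CALL_RATE")
    reasons[[i]] <- r
  }
  fail <- lengths(reasons) > 0L
  review <- !fail &
    out$sdlrr > config$review_sdlrr[1L] & out$sdlrr < config$review_sdlrr[2L] &
    out$n_cnvs >= config$review_cnvs[1L] & out$n_cnvs <= config$review_cnvs[2L]
  out$verdict <- ifelse(fail, "fail", ifelse(review, "review", "pass"))
  out$reasons <- vapply(seq_along(reasons), function(i) {
    if (fail[i]) paste(reasons[[i]], collapse = ",")
    else if (review[i]) "REVIEW_ZONE" else ""
  }, character(1L))
  out
}

#' Call-level quality control
#'
#' Drops calls supported by fewer than \code{config$min_snps} probes
#' (default 3) and calls on non-autosomes (X, Y, XY, MT); hemizygosity in
#' males and X inactivation in females make sex-chromosome copy number
#' uninterpretable with autosomal thresholds. Conservation holds: retained
#' plus excluded counts equal the input count.
#'
#' @param callset A \linkS4class{CNVCallSet}.
#' @param config A [runConfig()] list.
#' @return List with \code{retained} (a \linkS4class{CNVCallSet}),
#'   \code{excluded} (data.frame with an \code{exclusion_reason} column) and
#'   \code{counts} (named integer vector of per-reason exclusion counts).
#' @export
callQC <- function(callset, config = runConfig()) {
  x <- cnvCalls(callset)
  reason <- rep(NA_character_, nrow(x))
  reason[x$num_snps < config$min_snps] <- "min_snps"
  reason[is.na(reason) & !isAutosome(x$chrom)] <- "autosome"
  keep <- is.na(reason)
  excluded <- x[!keep, , drop = FALSE]
  excluded$exclusion_reason <- reason[!keep]
  counts <- c(min_snps = sum(reason == "min_snps", na.rm = TRUE),
              autosome = sum(reason == "autosome", na.rm = TRUE),
              retained = sum(keep))
  list(retained = CNVCallSet(x[keep, , drop = FALSE]),
       excluded = excluded, counts = counts)
}
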