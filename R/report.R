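# Candidate report writer/reader (TSV mirroring the reference table layout,
# or JSON).

reportOrder <- function(x) {
  order(match(x$cnv_type, c("del", "dup")), chromRank(x$chrom), x$start)
}

#' Write the candidate CNV report
#'
#' Writes the retained candidates as a deterministic report: deletions
#' before duplications, then by chromosome and start. The TSV carries the
#' boundaries ("chr<k>:<start>-<end>"), the recomputed length, the family,
#' genes and gene context, the per-ancestry control frequency with
#' bracketed per-cohort carrier counts ("0.012 [8/1]"), the database event
#' count, priority tier, transmission label and carrier lists. The JSON
#' format serializes the same rows.
#'
#' @param x A \linkS4class{CandidateSet} or a candidate data.frame.
#' @param path Output path.
#' @param format \code{"tsv"} (default) or \code{"json"}.
#' @param retainedOnly Write only retained candidates (default TRUE).
#' @return The path, invisibly.
#' @export
writeCandidateReport <- function(x, path, format = c("tsv", "json"),
                                 retainedOnly = TRUE) {
  format <- match.arg(format)
  cand <- if (is(x, "CandidateSet")) candidates(x) else as.data.frame(x)
  if (retainedOnly && nrow(cand))
    cand <- cand[cand$verdict == "retained", , drop = FALSE]
  if (nrow(cand)) cand <- cand[reportOrder(cand), , drop = FALSE]
  out <- data.frame(
    cnv_type = cand$cnv_type,
    boundaries = if (nrow(cand))
      sprintf("chr%s:%d-%d", cand$chrom, as.integer(cand$start),
              as.integer(cand$end)) else character(),
    length_bp = cand$length_bp,
    family_id = cand$family_id,
    genes = cand$genes,
    gene_context = cand$gene_context,
    control_freq = cand$control_freq,
    dgv_count = cand$dgv_count,
    priority_tier = cand$priority_tier,
    transmission = cand$transmission,
    literature_overlap = cand$literature_overlap,
    affected_carriers = cand$affected_carriers,
    unaffected_blood_carriers = cand$unaffected_blood_carriers,
    married_in_carriers = cand$married_in_carriers,
    verdict = cand$verdict,
    stringsAsFactors = FALSE)
  if (format == "tsv") {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a candidate CNV report
#'
#' Parses a TSV report written by [writeCandidateReport()] back into a
#' candidate data.frame (boundaries split into chrom/start/end, length
#' recomputed).
#'
#' @param path Path to the TSV report.
#' @return data.frame of candidates.
#' @export
readCandidateReport <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = "character", quote = "",
                         comment.char = "")
  if (nrow(x) == 0L) return(x)
  mm <- regmatches(x$boundaries,
                   regexec("^chr([0-9XYMT]+):([0-9]+)-([0-9]+)$",
                           x$boundaries))
  if (any(lengths(mm) != 4L)) stop("malformed boundaries column")
  x$chrom <- vapply(mm, `[`, "", 2L)
  x$start <- as.numeric(vapply(mm, `[`, "", 3L))
  x$end <- as.numeric(vapply(mm, `[`, "", 4L))
  x$length_bp <- x$end - x$start
  x$dgv_count <- as.numeric(x$dgv_count)
  x$priority_tier <- as.integer(x$priority_tier)
  x
}
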