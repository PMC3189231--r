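# Tabular inputs: population CNV tables, QC metric sidecars, BED regions,
# gene models, clinical sidecars.

#' Read a population CNV table
#'
#' TSV with header columns \code{chrom}, \code{start}, \code{end},
#' \code{type} and optionally \code{cohort}, \code{ancestry},
#' \code{sample_id}. Used both for control cohorts (which have per-ancestry
#' cohort sizes and per-individual carrier records) and for DGV-style
#' population databases (event records, no usable cohort size).
#'
#' @param path Path to the TSV.
#' @param cohortSizes Named numeric vector of cohort sizes by ancestry;
#'   empty for database tables.
#' @return A \linkS4class{PopulationCNVTable}.
#' @export
readPopulationTable <- function(path, cohortSizes = numeric()) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = "character", comment.char = "",
                         quote = "")
  if (nrow(x) == 0L) return(PopulationCNVTable(NULL, cohortSizes))
  PopulationCNVTable(x, cohortSizes)
}

#' Write a population CNV table
#'
#' @param table A \linkS4class{PopulationCNVTable}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writePopulationTable <- function(table, path) {
  x <- popRecords(table)
  x$start <- formatC(x$start, format = "d")
  x$end <- formatC(x$end, format = "d")
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a sample QC metrics sidecar
#'
#' TSV with header columns \code{sample_id}, \code{sdlrr}, \code{n_cnvs},
#' \code{call_rate}.
#'
#' @param path Path to the TSV.
#' @return data.frame of per-sample metrics.
#' @export
readQCMetrics <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  req <- c("sample_id", "sdlrr", "n_cnvs", "call_rate")
  if (!all(req %in% names(x)))
    stop("QC metrics file must have columns: ", paste(req, collapse = ", "))
  x$sample_id <- as.character(x$sample_id)
  x
}

#' Read a BED3+ region table
#'
#' BED is 0-based half-open; under the package's boundary convention
#' (length = end - start, intervals as half-open position sets) BED
#' coordinates map onto internal boundaries without a shift, so start/end
#' are ingested as-is. Lines starting with "track" or "browser" and comment
#' lines are skipped.
#'
#' @param path Path to the BED file.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{name} (name defaults to "region_<i>").
#' @export
readBedRegions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) &
                 !grepl("^(track|browser|#)", trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) stop("BED line with fewer than 3 fields")
  data.frame(
    chrom = normalizeChrom(vapply(parts, `[`, "", 1L)),
    start = as.numeric(vapply(parts, `[`, "", 2L)),
    end = as.numeric(vapply(parts, `[`, "", 3L)),
    name = vapply(seq_along(parts), function(i)
      if (length(parts[[i]]) >= 4L) parts[[i]][4L]
      else paste0("region_", i), ""),
    stringsAsFactors = FALSE)
}

#' Read gene models from a BED12-style file
#'
#' Columns 1-6 give the transcript span, name and strand; columns 10-12
#' (blockCount, blockSizes, blockStarts) give the exon structure. Files
#' with fewer than 12 columns are accepted, in which case the whole span is
#' treated as a single exon. Coordinates are ingested as for
#' [readBedRegions()].
#'
#' @param path Path to the BED file.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{name}, \code{strand} and a list-column \code{exons} of
#'   data.frames (\code{start}, \code{end}).
#' @export
readGeneModels <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) &
                 !grepl("^(track|browser|#)", trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (length(parts) && any(lengths(parts) < 4L))
    stop("gene model BED needs at least 4 fields (chrom, start, end, name)")
  genes <- data.frame(
    chrom = normalizeChrom(vapply(parts, `[`, "", 1L)),
    start = as.numeric(vapply(parts, `[`, "", 2L)),
    end = as.numeric(vapply(parts, `[`, "", 3L)),
    name = vapply(parts, `[`, "", 4L),
    strand = vapply(parts, function(p)
      if (length(p) >= 6L && p[6L] %in% c("+", "-")) p[6L] else "+", ""),
    stringsAsFactors = FALSE)
  genes$exons <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) >= 12L) {
      sizes <- as.numeric(strsplit(p[11L], ",")[[1L]])
      offs <- as.numeric(strsplit(p[12L], ",")[[1L]])
      data.frame(start = genes$start[i] + offs,
                 end = genes$start[i] + offs + sizes)
    } else {
      data.frame(start = genes$start[i], end = genes$end[i])
    }
  })
  genes
}

#' Read a clinical-diagnosis sidecar
#'
#' TSV with columns \code{id} and \code{diagnoses} (semicolon- or
#' comma-separated labels; an empty field means no recorded diagnosis).
#' Carries the non-ASD clinical phenotypes that the PED affection column
#' cannot, for the carrier-versus-spouse comparison.
#'
#' @param path Path to the TSV.
#' @return data.frame with columns \code{id}, \code{diagnoses}.
#' @export
readClinicalSidecar <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = "character", quote = "",
                         comment.char = "")
  if (!all(c("id", "diagnoses") %in% names(x)))
    stop("clinical sidecar must have columns: id, diagnoses")
  x
}
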