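#' Pedigree of one extended family
#'
#' Holds the member table of a single family. Each row describes one
#' individual: \code{id}, \code{father}/\code{mother} (\code{NA} for
#' founders; both present or both absent), \code{sex} (\code{"M"},
#' \code{"F"}, \code{"U"}), \code{affection} (\code{"affected"},
#' \code{"unaffected"}, \code{"unknown"}) and \code{dna} (logical: DNA
#' available for genotyping). Parent links must be acyclic and refer to
#' members of the same pedigree.
#'
#' @slot familyId Family identifier.
#' @slot members data.frame as described above.
#' @exportClass Pedigree
setClass("Pedigree",
         representation(familyId = "character", members = "data.frame"))

.PED_COLS <- c("id", "father", "mother", "sex", "affection", "dna")

setValidity("Pedigree", function(object) {
  m <- object@members
  msgs <- character()
  if (!all(.PED_COLS %in% names(m)))
    return(paste("members must have columns:", paste(.PED_COLS, collapse = ", ")))
  if (anyDuplicated(m$id))
    msgs <- c(msgs, paste("duplicate individual id:",
                          paste(unique(m$id[duplicated(m$id)]), collapse = ", ")))
  known <- m$id
  bad_f <- !is.na(m$father) & !(m$father %in% known)
  bad_m <- !is.na(m$mother) & !(m$mother %in% known)
  if (any(bad_f | bad_m))
    msgs <- c(msgs, paste("unknown parent id for individual(s):",
                          paste(m$id[bad_f | bad_m], collapse = ", ")))
  if (any(is.na(m$father) != is.na(m$mother)))
    msgs <- c(msgs, "individuals must have both parents known or both unknown")
  if (!all(m$affection %in% c("affected", "unaffected", "unknown")))
    msgs <- c(msgs, "affection must be affected/unaffected/unknown")
  if (length(msgs) == 0L) {
    d <- tryCatch(pedigreeDepths(m), error = function(e) conditionMessage(e))
    if (is.character(d)) msgs <- c(msgs, d)
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a Pedigree
#'
#' Builds and validates a \linkS4class{Pedigree}. Individuals listed with a
#' single known parent are completed with a synthetic placeholder founder
#' (logged with a message). A warning (not an error) is raised when the
#' family does not contain at least two affected members related no closer
#' than avuncular, the defining property of an extended multiplex family.
#'
#' @param familyId Family identifier.
#' @param members data.frame with columns \code{id}, \code{father},
#'   \code{mother}, \code{sex}, \code{affection}, \code{dna} (missing
#'   \code{sex}/\code{affection}/\code{dna} columns are filled with
#'   \code{"U"}/\code{"unknown"}/\code{FALSE}).
#' @param checkExtended Warn when the family lacks an affected avuncular or
#'   more distant pair. Default TRUE.
#' @return A \linkS4class{Pedigree}.
#' @export
Pedigree <- function(familyId, members, checkExtended = TRUE) {
  m <- as.data.frame(members, stringsAsFactors = FALSE)
  if (!"sex" %in% names(m)) m$sex <- "U"
  if (!"affection" %in% names(m)) m$affection <- "unknown"
  if (!"dna" %in% names(m)) m$dna <- FALSE
  for (col in c("id", "father", "mother", "sex", "affection"))
    m[[col]] <- as.character(m[[col]])
  m$father[m$father %in% c("0", "")] <- NA_character_
  m$mother[m$mother %in% c("0", "")] <- NA_character_
  m$dna <- as.logical(m$dna)

  # Complete single-known-parent records with placeholder founders.
  single <- which(is.na(m$father) != is.na(m$mother))
  for (i in single) {
    side <- if (is.na(m$father[i])) "father" else "mother"
    ph <- paste0(m$id[i], "_ph", side)
    message("Pedigree ", familyId, ": adding placeholder ", side,
            " '", ph, "' for individual ", m$id[i])
    m[[side]][i] <- ph
    m <- rbind(m, data.frame(id = ph, father = NA_character_,
                             mother = NA_character_,
                             sex = if (side == "father") "M" else "F",
                             affection = "unknown", dna = FALSE,
                             stringsAsFactors = FALSE))
  }
  rownames(m) <- NULL
  obj <- new("Pedigree", familyId = as.character(familyId), members = m)
  if (checkExtended) .warnIfNotExtended(obj)
  obj
}

.warnIfNotExtended <- function(ped) {
  aff <- members(ped)$id[members(ped)$affection == "affected"]
  if (length(aff) < 2L) {
    warning("Pedigree ", familyId(ped),
            ": fewer than two affected members; not an extended multiplex family",
            call. = FALSE)
    return(invisible(FALSE))
  }
  pairs <- utils::combn(aff, 2L)
  sh <- apply(pairs, 2L, function(p)
    tryCatch(expectedSharing(ped, p[1L], p[2L]), error = function(e) NA_real_))
  # avuncular expected sharing is 0.25; anything <= 0.25 counts as distant
  if (!any(!is.na(sh) & sh <= 0.25 & sh > 0)) {
    warning("Pedigree ", familyId(ped),
            ": no affected avuncular-or-more-distant pair found",
            call. = FALSE)
    return(invisible(FALSE))
  }
  invisible(TRUE)
}

#' @rdname accessors
#' @export
setMethod("familyId", "Pedigree", function(x) x@familyId)

#' @rdname accessors
#' @export
setMethod("members", "Pedigree", function(x) x@members)

setMethod("show", "Pedigree", function(object) {
  m <- object@members
  cat("Pedigree ", object@familyId, ": ", nrow(m), " members (",
      sum(m$affection == "affected"), " affected, ",
      sum(is.na(m$father)), " founders, ",
      sum(m$dna), " with DNA)\n", sep = "")
})

#' A set of CNV calls
#'
#' Container for per-sample CNV calls. The call table has columns
#' \code{sample_id}, \code{chrom}, \code{start}, \code{end},
#' \code{copy_number} (0, 1, 3 or 4; the diploid state 2 is not a call),
#' \code{num_snps} (supporting probe count), \code{source} (free-text
#' provenance) and the derived \code{cnv_type} (\code{"del"} for copy number
#' below 2, \code{"dup"} above 2).
#'
#' @slot calls data.frame as described.
#' @exportClass CNVCallSet
setClass("CNVCallSet", representation(calls = "data.frame"))

.CALL_COLS <- c("sample_id", "chrom", "start", "end", "copy_number",
                "num_snps", "source", "cnv_type")

setValidity("CNVCallSet", function(object) {
  x <- object@calls
  if (!all(.CALL_COLS %in% names(x)))
    return(paste("calls must have columns:", paste(.CALL_COLS, collapse = ", ")))
  if (nrow(x) == 0L) return(TRUE)
  if (!all(x$copy_number %in% c(0L, 1L, 3L, 4L)))
    return("copy_number must be 0, 1, 3 or 4 (2 = diploid, not a call)")
  if (any(x$end < x$start)) return("interval end < start")
  if (any(x$num_snps < 1L)) return("num_snps must be positive")
  if (!identical(x$cnv_type, cnvTypeFromCN(x$copy_number)))
    return("cnv_type inconsistent with copy_number")
  TRUE
})

#' Construct a CNVCallSet
#'
#' @param calls data.frame with columns \code{sample_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{copy_number}, \code{num_snps} and
#'   optionally \code{source}; \code{cnv_type} is derived.
#' @return A \linkS4class{CNVCallSet}.
#' @export
CNVCallSet <- function(calls = NULL) {
  if (is.null(calls) || nrow(as.data.frame(calls)) == 0L) {
    calls <- data.frame(sample_id = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        copy_number = integer(), num_snps = integer(),
                        source = character(), cnv_type = character(),
                        stringsAsFactors = FALSE)
    return(new("CNVCallSet", calls = calls))
  }
  x <- as.data.frame(calls, stringsAsFactors = FALSE)
  if (!"source" %in% names(x)) x$source <- NA_character_
  x$sample_id <- as.character(x$sample_id)
  x$chrom <- normalizeChrom(x$chrom)
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  x$copy_number <- as.integer(x$copy_number)
  x$num_snps <- as.integer(x$num_snps)
  x$cnv_type <- cnvTypeFromCN(x$copy_number)
  x <- x[, .CALL_COLS]
  rownames(x) <- NULL
  new("CNVCallSet", calls = x)
}

#' @rdname accessors
#' @export
setMethod("cnvCalls", "CNVCallSet", function(x) x@calls)

setMethod("show", "CNVCallSet", function(object) {
  x <- object@calls
  cat("CNVCallSet: ", nrow(x), " calls in ",
      length(unique(x$sample_id)), " samples (",
      sum(x$cnv_type == "del"), " del / ",
      sum(x$cnv_type == "dup"), " dup)\n", sep = "")
})

setMethod("length", "CNVCallSet", function(x) nrow(x@calls))

#' Population CNV table
#'
#' Indexed store of control-cohort or population-database (DGV-style) CNV
#' records, supporting per-ancestry carrier counting under the same-CNV
#' predicate. Records carry \code{chrom}, \code{start}, \code{end},
#' \code{type} (\code{del}/\code{dup}), \code{cohort} (e.g. recruiting
#' center, or \code{"DGV"}), \code{ancestry} and \code{sample_id} (may be
#' \code{NA} for databases that report events, not carriers).
#'
#' @slot records data.frame as described.
#' @slot cohortSizes Named numeric vector: number of individuals per
#'   ancestry (NA when the source has no usable cohort size, as for DGV).
#' @exportClass PopulationCNVTable
setClass("PopulationCNVTable",
         representation(records = "data.frame", cohortSizes = "numeric"))

.POP_COLS <- c("chrom", "start", "end", "type", "cohort", "ancestry", "sample_id")

setValidity("PopulationCNVTable", function(object) {
  x <- object@records
  if (!all(.POP_COLS %in% names(x)))
    return(paste("records must have columns:", paste(.POP_COLS, collapse = ", ")))
  if (nrow(x) > 0L && !all(x$type %in% c("del", "dup")))
    return(paste("unknown CNV type token:",
                 paste(setdiff(unique(x$type), c("del", "dup")), collapse = ", ")))
  if (nrow(x) > 0L && any(x$end < x$start)) return("interval end < start")
  TRUE
})

#' Construct a PopulationCNVTable
#'
#' @param records data.frame of population CNV records (see class docs);
#'   missing \code{cohort}/\code{ancestry}/\code{sample_id} columns are
#'   filled with NA.
#' @param cohortSizes Named numeric vector of cohort sizes by ancestry.
#' @return A \linkS4class{PopulationCNVTable}.
#' @export
PopulationCNVTable <- function(records = NULL, cohortSizes = numeric()) {
  if (is.null(records) || nrow(as.data.frame(records)) == 0L) {
    records <- data.frame(chrom = character(), start = numeric(),
                          end = numeric(), type = character(),
                          cohort = character(), ancestry = character(),
                          sample_id = character(), stringsAsFactors = FALSE)
  } else {
    records <- as.data.frame(records, stringsAsFactors = FALSE)
    for (col in c("cohort", "ancestry", "sample_id"))
      if (!col %in% names(records)) records[[col]] <- NA_character_
    records$chrom <- normalizeChrom(records$chrom)
    records$start <- as.numeric(records$start)
    records$end <- as.numeric(records$end)
    records$type <- as.character(records$type)
    records <- records[, .POP_COLS]
    rownames(records) <- NULL
  }
  new("PopulationCNVTable", records = records,
      cohortSizes = if (length(cohortSizes)) unlist(cohortSizes) else numeric())
}

#' @rdname accessors
#' @export
setMethod("popRecords", "PopulationCNVTable", function(x) x@records)

#' @rdname accessors
#' @export
setMethod("cohortSizes", "PopulationCNVTable", function(x) x@cohortSizes)

setMethod("show", "PopulationCNVTable", function(object) {
  cat("PopulationCNVTable: ", nrow(object@records), " records",
      if (length(object@cohortSizes))
        paste0("; cohort sizes: ",
               paste(names(object@cohortSizes), object@cohortSizes,
                     sep = "=", collapse = ", ")) else "",
      "\n", sep = "")
})

#' Candidate co-segregating CNVs with their filter trace
#'
#' Result container of the segregation pipeline. \code{candidates()} returns
#' one row per family-level candidate CNV with its interval, type, carrier
#' lists (comma-separated id strings), per-ancestry control frequencies,
#' DGV-style event count, literature-overlap class, priority tier,
#' transmission label and verdict (\code{retained} or \code{rejected} plus a
#' reason code). \code{filterTrace()} returns the per-stage audit table:
#' every candidate appears once per stage it entered, with a verdict.
#'
#' @slot candidates data.frame, one row per candidate.
#' @slot trace data.frame with columns \code{family_id},
#'   \code{candidate_id}, \code{stage}, \code{verdict}, \code{reason}.
#' @exportClass CandidateSet
setClass("CandidateSet",
         representation(candidates = "data.frame", trace = "data.frame"))

#' Construct a CandidateSet
#'
#' @param candidates Candidate table (see class docs).
#' @param trace Filter trace table.
#' @return A \linkS4class{CandidateSet}.
#' @export
CandidateSet <- function(candidates = NULL, trace = NULL) {
  if (is.null(candidates)) candidates <- emptyCandidates()
  if (is.null(trace))
    trace <- data.frame(family_id = character(), candidate_id = character(),
                        stage = character(), verdict = character(),
                        reason = character(), stringsAsFactors = FALSE)
  new("CandidateSet", candidates = as.data.frame(candidates),
      trace = as.data.frame(trace))
}

.CAND_COLS <- c("candidate_id", "family_id", "chrom", "start", "end",
                "length_bp", "cnv_type", "affected_carriers",
                "unaffected_blood_carriers", "married_in_carriers",
                "transmission", "introducers", "matched_ancestry",
                "matched_control_freq", "total_control_carriers",
                "control_freq", "dgv_count", "literature_overlap",
                "priority_tier", "genes", "gene_context",
                "verdict", "reason")

emptyCandidates <- function() {
  df <- data.frame(candidate_id = character(), family_id = character(),
                   chrom = character(), start = numeric(), end = numeric(),
                   length_bp = numeric(), cnv_type = character(),
                   affected_carriers = character(),
                   unaffected_blood_carriers = character(),
                   married_in_carriers = character(),
                   transmission = character(), introducers = character(),
                   matched_ancestry = character(),
                   matched_control_freq = numeric(),
                   total_control_carriers = numeric(),
                   control_freq = character(), dgv_count = numeric(),
                   literature_overlap = character(),
                   priority_tier = integer(),
                   genes = character(), gene_context = character(),
                   verdict = character(), reason = character(),
                   stringsAsFactors = FALSE)
  df[, .CAND_COLS]
}

#' @rdname accessors
#' @export
setMethod("candidates", "CandidateSet", function(x) x@candidates)

#' @rdname accessors
#' @export
setMethod("filterTrace", "CandidateSet", function(x) x@trace)

setMethod("show", "CandidateSet", function(object) {
  x <- object@candidates
  ret <- x[x$verdict == "retained", , drop = FALSE]
  cat("CandidateSet: ", nrow(x), " candidates, ", nrow(ret), " retained (",
      sum(ret$cnv_type == "del"), " del / ", sum(ret$cnv_type == "dup"),
      " dup) in ", length(unique(ret$family_id)), " families\n", sep = "")
})
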