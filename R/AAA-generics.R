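#' @import methods
NULL

#' Accessor generics
#'
#' Accessors for the package's S4 containers. \code{members()} returns the
#' member table of a \linkS4class{Pedigree}; \code{cnvCalls()} the call table
#' of a \linkS4class{CNVCallSet}; \code{popRecords()} and \code{cohortSizes()}
#' the record table and per-ancestry cohort sizes of a
#' \linkS4class{PopulationCNVTable}; \code{candidates()} and
#' \code{filterTrace()} the candidate table and per-stage trace of a
#' \linkS4class{CandidateSet}; \code{familyId()} the family identifier.
#'
#' @param x An object.
#' @return A \code{data.frame} (or character/numeric vector for
#'   \code{familyId}/\code{cohortSizes}).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("familyId", function(x) standardGeneric("familyId"))

#' @rdname accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname accessors
#' @export
setGeneric("cnvCalls", function(x) standardGeneric("cnvCalls"))

#' @rdname accessors
#' @export
setGeneric("popRecords", function(x) standardGeneric("popRecords"))

#' @rdname accessors
#' @export
setGeneric("cohortSizes", function(x) standardGeneric("cohortSizes"))

#' @rdname accessors
#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))

#' @rdname accessors
#' @export
setGeneric("filterTrace", function(x) standardGeneric("filterTrace"))
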