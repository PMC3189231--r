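#' Genomic interval arithmetic under the probe-boundary length convention
#'
#' Throughout the package a genomic interval is a chromosome label plus two
#' integer boundary positions: the positions of the first and last supporting
#' array probe of a CNV call. The length of an interval is defined as
#' \code{end - start}, i.e. the span between its boundary probes. Every
#' overlap computation, including the 50\% reciprocal-overlap rule used to
#' decide whether two records describe "the same CNV", uses this convention.
#'
#' Equivalently, an interval can be thought of as the half-open position set
#' \code{[start, end)}: \code{overlapBp()} agrees with counting the positions
#' two such sets share. BED input (0-based, half-open) therefore maps onto the
#' internal convention without coordinate shifts.
#'
#' @param start,end Integer boundary positions, \code{end >= start}.
#' @return \code{intervalLength()}: integer vector of lengths in bp.
#' @examples
#' intervalLength(45408389, 45411073)  # 2684
#' @export
intervalLength <- function(start, end) {
  if (length(start) != length(end))
    stop("start and end must have equal length")
  if (any(is.na(start) | is.na(end)))
    stop("interval boundaries must not be NA")
  if (any(end < start))
    stop("invalid interval: end < start")
  as.numeric(end) - as.numeric(start)
}

#' Normalize a chromosome label
#'
#' Strips any "chr" prefix (case-insensitively) and upper-cases the rest, so
#' "chr1", "Chr1" and "1" compare equal.
#'
#' @param chrom Character vector of chromosome labels.
#' @return Normalized character vector.
#' @export
normalizeChrom <- function(chrom) {
  toupper(sub("^chr", "", as.character(chrom), ignore.case = TRUE))
}

#' Is a chromosome an autosome?
#'
#' @param chrom Character vector of chromosome labels (any "chr" prefix is
#'   ignored).
#' @return Logical vector; TRUE for chromosomes "1".."22".
#' @export
isAutosome <- function(chrom) {
  normalizeChrom(chrom) %in% as.character(1:22)
}

# Sort key for chromosome labels: 1..22, then X, Y, XY, MT/M, then others.
chromRank <- function(chrom) {
  n <- normalizeChrom(chrom)
  r <- suppressWarnings(as.integer(n))
  extra <- match(n, c("X", "Y", "XY", "MT", "M"))
  r[is.na(r)] <- 22L + extra[is.na(r)]
  r[is.na(r)] <- 99L
  r
}

#' Overlap in base pairs between two intervals
#'
#' Vectorized. Returns 0 for intervals on different chromosomes or disjoint
#' intervals; otherwise \code{min(endA, endB) - max(startA, startB)}. The
#' result is symmetric in its two operands.
#'
#' @param chromA,startA,endA First interval(s).
#' @param chromB,startB,endB Second interval(s).
#' @return Numeric vector of non-negative overlap widths in bp.
#' @export
overlapBp <- function(chromA, startA, endA, chromB, startB, endB) {
  same <- normalizeChrom(chromA) == normalizeChrom(chromB)
  ov <- pmin(as.numeric(endA), as.numeric(endB)) -
    pmax(as.numeric(startA), as.numeric(startB))
  ov[!same] <- 0
  pmax(ov, 0)
}

#' Do two CNV records describe the same CNV?
#'
#' Two records are the same CNV when their types match (deletion with
#' deletion, duplication with duplication) and they overlap by at least
#' \code{fraction} of their lengths. Under the default \code{"reciprocal"}
#' mode the overlap must cover at least \code{fraction} of \emph{both}
#' records; under \code{"either"} one side suffices.
#'
#' @param chromA,startA,endA,typeA First record; type is \code{"del"} or
#'   \code{"dup"}.
#' @param chromB,startB,endB,typeB Second record.
#' @param fraction Required overlap fraction, default 0.5.
#' @param mode \code{"reciprocal"} (default) or \code{"either"}.
#' @return Logical vector.
#' @export
isSameCNV <- function(chromA, startA, endA, typeA,
                      chromB, startB, endB, typeB,
                      fraction = 0.5, mode = c("reciprocal", "either")) {
  mode <- match.arg(mode)
  lenA <- as.numeric(endA) - as.numeric(startA)
  lenB <- as.numeric(endB) - as.numeric(startB)
  if (any(lenA <= 0) || any(lenB <= 0))
    stop("zero-length operand in CNV comparison")
  ov <- overlapBp(chromA, startA, endA, chromB, startB, endB)
  fa <- ov / lenA
  fb <- ov / lenB
  covered <- if (mode == "reciprocal") fa >= fraction & fb >= fraction
             else fa >= fraction | fb >= fraction
  as.character(typeA) == as.character(typeB) & covered
}

#' Intersection of a set of intervals on one chromosome
#'
#' @param chrom,start,end Parallel vectors describing the intervals; all on
#'   the same chromosome.
#' @return A list with elements \code{chrom}, \code{start}, \code{end} when
#'   the common intersection has positive length, otherwise \code{NULL}.
#' @export
intersectAll <- function(chrom, start, end) {
  if (length(chrom) == 0L) stop("intersectAll: empty interval set")
  if (length(unique(normalizeChrom(chrom))) > 1L)
    stop("intersectAll: intervals on mixed chromosomes")
  s <- max(as.numeric(start))
  e <- min(as.numeric(end))
  if (e - s <= 0) return(NULL)
  list(chrom = as.character(chrom[1L]), start = s, end = e)
}

# Derived CNV type from an integer copy number (2 is not a call).
cnvTypeFromCN <- function(copy_number) {
  if (any(copy_number == 2L))
    stop("copy number 2 is the diploid state, not a CNV call")
  ifelse(copy_number < 2L, "del", "dup")
}
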