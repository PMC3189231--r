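# Supporting statistics: exact 2x2 association, rank-based group comparison,
# carrier-frequency arithmetic.

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.0125 -> 0.013 at 3 digits), the
#' convention used for all displayed frequencies. Base R's round() ties to
#' even, which would print 9/727 and 5/727 differently from the reference
#' tables.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 3L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.check2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (length(cells) != 4L || any(is.na(cells)))
    stop("a 2x2 table needs four non-missing cell counts")
  if (any(cells < 0)) stop("negative cell count in 2x2 table")
  if (any(cells != round(cells))) stop("cell counts must be integers")
  if (sum(cells) == 0) stop("empty 2x2 table")
  matrix(as.integer(cells), nrow = 2L, byrow = TRUE)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value with margins fixed: the sum of hypergeometric
#' point probabilities of all tables at least as extreme as (i.e. with point
#' probability no greater than) the observed one. When any margin is zero
#' only one table is possible and p = 1.
#'
#' @param a,b,c,d Cell counts, row-wise: \code{[[a, b], [c, d]]}. \code{a}
#'   may also be a 2x2 matrix, in which case the other arguments are
#'   ignored.
#' @return The two-sided p-value in (0, 1].
#' @examples
#' fisherExactTwoSided(12, 8, 6, 14)  # 0.111 at 3 decimals
#' @export
fisherExactTwoSided <- function(a, b = NULL, c = NULL, d = NULL) {
  tab <- if (is.matrix(a)) .check2x2(a[1, 1], a[1, 2], a[2, 1], a[2, 2])
         else .check2x2(a, b, c, d)
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) return(1)
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Kruskal-Wallis rank-sum comparison of per-sample CNV counts
#'
#' Compares two or more groups of per-sample counts with the Kruskal-Wallis
#' test on mid-ranks, tie-corrected, with the p-value from the chi-square
#' approximation on k - 1 degrees of freedom. For small problems
#' (\code{exact = TRUE}, total N <= 10) an exact permutation p-value is
#' computed by enumerating every assignment of the observations to groups
#' of the observed sizes.
#'
#' @param groups A list of two or more non-empty numeric vectors.
#' @param exact Compute the exact permutation p-value (total N <= 10 only).
#' @return List with \code{H} (tie-corrected statistic), \code{df},
#'   \code{p.value} and \code{method}.
#' @export
kruskalWallis <- function(groups, exact = FALSE) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least two groups")
  if (any(lengths(groups) == 0L)) stop("empty group")
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(values) < 3L) stop("need at least three observations in total")
  if (length(unique(values)) == 1L) {
    # complete ties: the tie correction degenerates to 0/0; by convention
    # there is no evidence of any group difference
    return(list(H = 0, df = length(groups) - 1L, p.value = 1,
                method = "complete ties"))
  }
  kt <- stats::kruskal.test(values, g)
  out <- list(H = unname(kt$statistic), df = unname(kt$parameter),
              p.value = kt$p.value, method = "chi-square approximation")
  if (exact) {
    n <- length(values)
    if (n > 10L) stop("exact permutation p-value supported for N <= 10 only")
    sizes <- lengths(groups)
    stat <- function(assign)
      unname(stats::kruskal.test(values, factor(assign))$statistic)
    hobs <- out$H
    idx <- seq_len(n)
    count <- 0L
    total <- 0L
    recurse <- function(remaining, gi, assign) {
      if (gi == length(sizes)) {
        assign[remaining] <- gi
        total <<- total + 1L
        if (stat(assign) >= hobs - 1e-12) count <<- count + 1L
        return(invisible())
      }
      picks <- utils::combn(remaining, sizes[gi], simplify = FALSE)
      for (p in picks) {
        assign[p] <- gi
        recurse(setdiff(remaining, p), gi + 1L, assign)
      }
    }
    recurse(idx, 1L, integer(n))
    out$p.value <- count / total
    out$method <- "exact permutation"
  }
  out
}

#' Carrier frequency in a control cohort
#'
#' Returns the exact fraction (used for all threshold comparisons) together
#' with the 3-decimal display value rounded half-up, the convention of the
#' reported control-frequency columns (9/727 displays as 0.012, 5/727 as
#' 0.007).
#'
#' @param carriers Number of distinct carrier individuals.
#' @param n Cohort size (> 0).
#' @return List with \code{fraction} and \code{display}.
#' @export
carrierFrequency <- function(carriers, n) {
  if (length(n) != 1L || is.na(n) || n <= 0) stop("cohort size must be positive")
  if (any(carriers < 0 | carriers > n))
    stop("carriers must lie in [0, cohort size]")
  list(fraction = carriers / n, display = roundHalfUp(carriers / n, 3L))
}

#' Compare clinical diagnoses of CNV carriers and their non-carrier spouses
#'
#' Builds the 2x2 table (carrier vs non-carrier spouse) x (any non-ASD
#' clinical diagnosis vs none) over carrier-spouse pairs and applies the
#' two-sided Fisher's exact test. Eligible carriers are carriers without a
#' formal ASD diagnosis whose reproductive partner is genotyped and does not
#' carry the variant; pairs whose spouse is also a carrier are excluded and
#' logged. Each individual is counted once even when carrying several
#' candidate CNVs.
#'
#' @param peds Named list of \linkS4class{Pedigree} objects.
#' @param candidateTable Candidate data.frame (retained rows of a
#'   \linkS4class{CandidateSet}), with \code{family_id} and the carrier
#'   list columns.
#' @param clinical data.frame with columns \code{id} and \code{diagnoses}
#'   (free-text label list; empty or NA = no diagnosis).
#' @return List with \code{table} (2x2 matrix), \code{p.value},
#'   \code{pairs} (data.frame of carrier/spouse ids) and
#'   \code{excluded_pairs}.
#' @export
carrierSpouseComparison <- function(peds, candidateTable, clinical) {
  diagnosed <- clinical$id[!is.na(clinical$diagnoses) &
                           nzchar(trimws(clinical$diagnoses))]
  pairs <- list()
  excluded <- list()
  for (fid in unique(candidateTable$family_id)) {
    ped <- peds[[fid]]
    if (is.null(ped)) stop("no pedigree for family ", fid)
    rows <- candidateTable[candidateTable$family_id == fid, , drop = FALSE]
    carrierIds <- unique(unlist(lapply(
      c(rows$affected_carriers, rows$unaffected_blood_carriers,
        rows$married_in_carriers), splitIds)))
    m <- members(ped)
    genotyped <- m$id[m$dna]
    eligible <- setdiff(carrierIds, m$id[m$affection == "affected"])
    for (cid in eligible) {
      for (sp in spousesOf(ped, cid)) {
        if (sp %in% carrierIds) {
          excluded[[length(excluded) + 1L]] <-
            data.frame(family_id = fid, carrier = cid, spouse = sp,
                       reason = "spouse_is_carrier", stringsAsFactors = FALSE)
          next
        }
        if (!(sp %in% genotyped)) next   # carrier status unknown
        pairs[[length(pairs) + 1L]] <-
          data.frame(family_id = fid, carrier = cid, spouse = sp,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(pairs) == 0L) stop("no comparable carrier-spouse pairs")
  pairs <- do.call(rbind, pairs)
  pairs <- pairs[!duplicated(pairs$carrier), , drop = FALSE]
  carrierDx <- pairs$carrier %in% diagnosed
  spouseDx <- pairs$spouse %in% diagnosed
  tab <- matrix(c(sum(carrierDx), sum(!carrierDx),
                  sum(spouseDx), sum(!spouseDx)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("carrier", "spouse"),
                                c("diagnosis", "none")))
  list(table = tab, p.value = fisherExactTwoSided(tab),
       pairs = pairs,
       excluded_pairs = if (length(excluded)) do.call(rbind, excluded)
                        else NULL)
}

splitIds <- function(x) {
  if (length(x) == 0L || is.na(x) || !nzchar(x)) return(character())
  trimws(strsplit(x, ",", fixed = TRUE)[[1L]])
}
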