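# Pedigree machinery: relatedness, member classification, transmission paths.

# Generation depth of every member (founders = 0). Errors on parent cycles.
pedigreeDepths <- function(m) {
  depth <- stats::setNames(rep(NA_integer_, nrow(m)), m$id)
  depth[is.na(m$father)] <- 0L
  for (iter in seq_len(nrow(m) + 1L)) {
    todo <- is.na(depth)
    if (!any(todo)) return(depth)
    for (i in which(todo[m$id])) {
      df <- depth[m$father[i]]
      dm <- depth[m$mother[i]]
      if (!is.na(df) && !is.na(dm)) depth[m$id[i]] <- max(df, dm) + 1L
    }
    if (identical(todo, is.na(depth)))
      stop("pedigree parent links contain a cycle")
  }
  stop("pedigree parent links contain a cycle")
}

.memberRow <- function(ped, id) {
  m <- members(ped)
  i <- match(id, m$id)
  if (any(is.na(i))) stop("unknown individual: ",
                          paste(id[is.na(i)], collapse = ", "))
  i
}

# All ancestors of id (excluding id).
pedigreeAncestors <- function(ped, id) {
  m <- members(ped)
  .memberRow(ped, id)
  out <- character()
  frontier <- id
  while (length(frontier)) {
    i <- match(frontier, m$id)
    parents <- unique(stats::na.omit(c(m$father[i], m$mother[i])))
    parents <- setdiff(parents, out)
    out <- c(out, parents)
    frontier <- parents
  }
  out
}

# All descendants of id (excluding id).
pedigreeDescendants <- function(ped, id) {
  m <- members(ped)
  out <- character()
  frontier <- id
  while (length(frontier)) {
    kids <- m$id[(!is.na(m$father) & m$father %in% frontier) |
                 (!is.na(m$mother) & m$mother %in% frontier)]
    kids <- setdiff(unique(kids), out)
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

# Co-parents (spouses in the reproductive sense) of id.
spousesOf <- function(ped, id) {
  m <- members(ped)
  kids <- !is.na(m$father) & (m$father == id | m$mother == id)
  other <- ifelse(m$father[kids] == id, m$mother[kids], m$father[kids])
  unique(other)
}

#' Kinship coefficient between two pedigree members
#'
#' Recursive kinship: founders are unrelated and non-inbred;
#' \eqn{\phi(i,i) = (1 + \phi(f_i, m_i)) / 2} and, recursing on the
#' individual of greater generation depth,
#' \eqn{\phi(i,j) = (\phi(f_i, j) + \phi(m_i, j)) / 2}.
#'
#' @param ped A \linkS4class{Pedigree}.
#' @param i,j Member ids.
#' @return The kinship coefficient \eqn{\phi} (e.g. 0.25 for parent-child,
#'   1/16 for first cousins).
#' @seealso [expectedSharing()]
#' @export
kinship <- function(ped, i, j) {
  m <- members(ped)
  .memberRow(ped, c(i, j))
  depth <- pedigreeDepths(m)
  father <- stats::setNames(m$father, m$id)
  mother <- stats::setNames(m$mother, m$id)
  memo <- new.env(parent = emptyenv())
  phi <- function(a, b) {
    if (is.na(a) || is.na(b)) return(0)
    key <- if (a <= b) paste(a, b, sep = "\r") else paste(b, a, sep = "\r")
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- if (a == b) {
      (1 + phi(father[[a]], mother[[a]])) / 2
    } else {
      # recurse on the deeper individual; ties broken arbitrarily (valid
      # because the deeper-or-equal one cannot be an ancestor of the other)
      if (depth[[a]] < depth[[b]]) { tmp <- a; a <- b; b <- tmp }
      (phi(father[[a]], b) + phi(mother[[a]], b)) / 2
    }
    memo[[key]] <- val
    val
  }
  phi(i, j)
}

#' Expected autosomal genome sharing of a relative pair
#'
#' For a non-inbred pair the expected fraction of the autosomal genome
#' shared identical-by-descent is twice the kinship coefficient: 0.5 for
#' full siblings, 0.25 for an avuncular pair, 0.125 for first cousins and
#' 0.03125 for second cousins.
#'
#' @param ped A \linkS4class{Pedigree}.
#' @param i,j Distinct member ids.
#' @return Expected shared fraction in [0, 1].
#' @export
expectedSharing <- function(ped, i, j) {
  if (identical(i, j))
    stop("expectedSharing is defined for distinct individuals only")
  2 * kinship(ped, i, j)
}

#' Partition pedigree members by lineage role
#'
#' Splits members into \code{affected}, \code{unaffected_blood} and
#' \code{married_in}. Married-in individuals are founders (no parent links)
#' whose reproductive partner is a non-founder blood-line member; the
#' founding couple(s) at the top of the pedigree -- founders partnered with
#' other founders -- are blood by definition. Affected individuals go to the
#' \code{affected} partition regardless of lineage. Deterministic.
#'
#' @param ped A \linkS4class{Pedigree}.
#' @return List of character vectors \code{affected},
#'   \code{unaffected_blood}, \code{married_in}.
#' @export
classifyMembers <- function(ped) {
  m <- members(ped)
  founder <- is.na(m$father)
  married_in <- logical(nrow(m))
  for (i in which(founder)) {
    sp <- spousesOf(ped, m$id[i])
    if (length(sp) == 0L) next                      # isolated founder: blood
    sp_founder <- founder[match(sp, m$id)]
    # partnered with at least one non-founder and no founder: married-in
    if (!any(sp_founder)) married_in[i] <- TRUE
  }
  affected <- m$affection == "affected"
  list(affected = m$id[affected],
       unaffected_blood = m$id[!affected & !married_in],
       married_in = m$id[!affected & married_in])
}

#' Infer the transmission path of a variant through a family
#'
#' Searches for a single introducing ancestor (a member, typically a founder
#' or married-in individual, possibly genotype-unknown) such that every
#' known carrier is the introducer or one of its descendants, and each
#' carrier's ancestral path to the introducer passes only through carriers
#' or genotype-unknown individuals. Genotyped non-carriers block paths;
#' untyped members are permissive.
#'
#' The transmission label is evaluated from each affected carrier's
#' perspective: the parent through which the variant arrives. All-maternal
#' routes give \code{"maternal"}, all-paternal \code{"paternal"}, mixed
#' routes \code{"both"}, and ambiguous routes (both parents feasible for
#' some affected) \code{"undetermined"}. When no single-origin explanation
#' exists, \code{consistent} is \code{FALSE} and the label is
#' \code{"undetermined"}.
#'
#' Ties among feasible introducers are broken toward the most recent
#' (deepest) one, then lexicographically; alternatives are reported in
#' \code{alternatives}.
#'
#' @param ped A \linkS4class{Pedigree}.
#' @param carriers Character vector of known carrier ids.
#' @param genotyped Character vector of ids with known carrier status
#'   (default: members with DNA available). Members outside this set are
#'   treated as genotype-unknown.
#' @return List with \code{label}, \code{introducer}, \code{alternatives},
#'   \code{consistent} and \code{arrivals} (named vector, per affected
#'   carrier: \code{"maternal"}, \code{"paternal"} or \code{"ambiguous"}).
#' @export
inferTransmission <- function(ped, carriers,
                              genotyped = members(ped)$id[members(ped)$dna]) {
  m <- members(ped)
  .memberRow(ped, carriers)
  carriers <- unique(carriers)
  depth <- pedigreeDepths(m)
  father <- stats::setNames(m$father, m$id)
  mother <- stats::setNames(m$mother, m$id)

  # permissive = carrier or genotype-unknown
  allowed <- stats::setNames(!(m$id %in% genotyped) | (m$id %in% carriers),
                             m$id)

  if (length(carriers) == 0L)
    return(list(label = "undetermined", introducer = NA_character_,
                alternatives = character(), consistent = FALSE,
                arrivals = character()))

  # reach(v, c): v can pass the variant up to c through allowed individuals
  reachesFrom <- function(cand) {
    memo <- new.env(parent = emptyenv())
    reach <- function(v) {
      if (is.na(v)) return(FALSE)
      if (v == cand) return(TRUE)
      got <- memo[[v]]
      if (!is.null(got)) return(got)
      memo[[v]] <- FALSE   # cycle guard (parent links are acyclic anyway)
      ok <- FALSE
      for (p in c(father[[v]], mother[[v]]))
        if (!is.na(p) && allowed[[p]] && reach(p)) { ok <- TRUE; break }
      memo[[v]] <- ok
      ok
    }
    reach
  }

  feasible <- character()
  for (cand in m$id) {
    if (!allowed[[cand]]) next
    reach <- reachesFrom(cand)
    if (all(vapply(carriers, reach, logical(1L)))) feasible <- c(feasible, cand)
  }

  if (length(feasible) == 0L)
    return(list(label = "undetermined", introducer = NA_character_,
                alternatives = character(), consistent = FALSE,
                arrivals = character()))

  ord <- order(-depth[feasible], feasible)
  introducer <- feasible[ord][1L]
  alternatives <- feasible[ord][-1L]

  reach <- reachesFrom(introducer)
  affectedCarriers <- intersect(carriers, m$id[m$affection == "affected"])
  arrivals <- character()
  for (a in setdiff(affectedCarriers, introducer)) {
    viaF <- !is.na(father[[a]]) && allowed[[father[[a]]]] && reach(father[[a]])
    viaM <- !is.na(mother[[a]]) && allowed[[mother[[a]]]] && reach(mother[[a]])
    arrivals[a] <- if (viaF && viaM) "ambiguous"
                   else if (viaM) "maternal"
                   else if (viaF) "paternal"
                   else "ambiguous"   # introducer is the affected's ancestorless self-case
  }

  label <- if (length(arrivals) == 0L) "undetermined"
           else if (any(arrivals == "ambiguous")) "undetermined"
           else if (all(arrivals == "maternal")) "maternal"
           else if (all(arrivals == "paternal")) "paternal"
           else "both"

  list(label = label, introducer = introducer, alternatives = alternatives,
       consistent = TRUE, arrivals = arrivals)
}

#' Drop family branches with no informative individual
#'
#' A branch is the descendant subtree of one child of the founding couple,
#' together with the married-in partners of its members. Branches containing
#' none of \code{informative} (typically the genotyped affected members) are
#' removed; the founding couple itself is kept.
#'
#' @param ped A \linkS4class{Pedigree}.
#' @param informative Character vector of ids that make a branch worth
#'   keeping.
#' @return List with the pruned \code{ped} and the \code{dropped} ids.
#' @export
pruneUninformativeBranches <- function(ped, informative) {
  m <- members(ped)
  parts <- classifyMembers(ped)
  founders <- m$id[is.na(m$father)]
  topCouple <- setdiff(founders, parts$married_in)
  if (length(topCouple) == 0L)
    return(list(ped = ped, dropped = character()))
  kids <- m$id[!is.na(m$father) &
               (m$father %in% topCouple | m$mother %in% topCouple)]
  dropped <- character()
  for (k in kids) {
    branch <- c(k, pedigreeDescendants(ped, k))
    partners <- unlist(lapply(branch, spousesOf, ped = ped))
    branchAll <- setdiff(unique(c(branch, partners)), topCouple)
    if (!any(branchAll %in% informative))
      dropped <- c(dropped, branchAll)
  }
  dropped <- setdiff(unique(dropped), informative)
  if (length(dropped) == 0L) return(list(ped = ped, dropped = character()))
  keep <- !(m$id %in% dropped)
  m2 <- m[keep, , drop = FALSE]
  # sever parent links pointing at dropped members
  m2$father[!is.na(m2$father) & !(m2$father %in% m2$id)] <- NA_character_
  m2$mother[!is.na(m2$mother) & !(m2$mother %in% m2$id)] <- NA_character_
  bad <- is.na(m2$father) != is.na(m2$mother)
  m2$father[bad] <- NA_character_
  m2$mother[bad] <- NA_character_
  list(ped = Pedigree(familyId(ped), m2, checkExtended = FALSE),
       dropped = dropped)
}
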