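# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# Exhaustive two-sided Fisher p: sum of hypergeometric point probabilities
# over the whole support, keeping tables whose point probability does not
# exceed the observed one (within relative tolerance 1e-7).
fisherEnumOracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  pr <- stats::dhyper(xs, r1, r2, c1)
  pobs <- stats::dhyper(a, r1, r2, c1)
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

# Path-counting kinship for non-inbred pedigrees: sum over common ancestors
# and path pairs that meet only at the ancestor of (1/2)^(len_i + len_j + 1).
pathsToAncestors <- function(m, id) {
  father <- stats::setNames(m$father, m$id)
  mother <- stats::setNames(m$mother, m$id)
  out <- list()
  walk <- function(node, path) {
    out[[length(out) + 1L]] <<- list(anc = node, path = path)
    for (p in c(father[[node]], mother[[node]]))
      if (!is.na(p)) walk(p, c(path, p))
  }
  walk(id, id)
  out
}

kinshipPathOracle <- function(ped, i, j) {
  m <- members(ped)
  pi <- pathsToAncestors(m, i)
  pj <- pathsToAncestors(m, j)
  tot <- 0
  for (x in pi) for (y in pj) {
    if (x$anc != y$anc) next
    if (length(intersect(x$path, y$path)) != 1L) next
    tot <- tot + 0.5^((length(x$path) - 1L) + (length(y$path) - 1L) + 1L)
  }
  tot
}

# Position-counting overlap: intervals as half-open position sets.
overlapBruteForce <- function(s1, e1, s2, e2) {
  length(intersect(seq_len(e1 - s1) + s1 - 1L, seq_len(e2 - s2) + s2 - 1L))
}

# Random non-inbred pedigree: a founding couple, random branching, spouses
# always new founders. Returns a Pedigree of <= maxDepth + 1 generations.
randomPedigree <- function(fid, maxDepth = 4L) {
  counter <- 0L
  nid <- function() {
    counter <<- counter + 1L
    paste0(fid, "_", counter)
  }
  rows <- list()
  add <- function(id, father, mother, sex) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, father = father, mother = mother, sex = sex,
      affection = "unknown", dna = FALSE, stringsAsFactors = FALSE)
  }
  grow <- function(father, mother, depth) {
    for (k in seq_len(sample(1:3, 1L))) {
      kid <- nid()
      sex <- sample(c("M", "F"), 1L)
      add(kid, father, mother, sex)
      if (depth < maxDepth && stats::runif(1) < 0.6) {
        sp <- nid()
        add(sp, NA_character_, NA_character_, if (sex == "M") "F" else "M")
        fa <- if (sex == "M") kid else sp
        mo <- if (sex == "M") sp else kid
        grow(fa, mo, depth + 1L)
      }
    }
  }
  f1 <- nid(); f2 <- nid()
  add(f1, NA_character_, NA_character_, "M")
  add(f2, NA_character_, NA_character_, "F")
  grow(f1, f2, 1L)
  Pedigree(fid, do.call(rbind, rows), checkExtended = FALSE)
}

affectedIdsOf <- function(ped) {
  m <- members(ped)
  m$id[m$affection == "affected"]
}

# Calls data.frame builder for constructed test families.
mkCalls <- function(sample_id, chrom, start, end, cn = 1L, num_snps = 10L) {
  data.frame(sample_id = sample_id, chrom = chrom, start = start, end = end,
             copy_number = cn, num_snps = num_snps, source = "test",
             stringsAsFactors = FALSE)
}

passQC <- function(sample_ids) {
  data.frame(sample_id = sample_ids, sdlrr = 0.2, n_cnvs = 10L,
             call_rate = 0.99, stringsAsFactors = FALSE)
}
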