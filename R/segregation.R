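# The multi-step co-segregation filter: family-wise shared-CNV detection,
# married-in/segregation exclusion, population-frequency evaluation,
# prioritization, gene-context annotation, and end-to-end orchestration.

newCandidateRow <- function(family_id, chrom, start, end, cnv_type) {
  data.frame(
    candidate_id = paste0(family_id, ":", cnv_type, ":chr", chrom, ":",
                          format(start, scientific = FALSE), "-",
                          format(end, scientific = FALSE)),
    family_id = family_id, chrom = chrom, start = start, end = end,
    length_bp = end - start, cnv_type = cnv_type,
    affected_carriers = "", unaffected_blood_carriers = "",
    married_in_carriers = "", transmission = NA_character_,
    introducers = NA_character_, matched_ancestry = NA_character_,
    matched_control_freq = NA_real_, total_control_carriers = NA_real_,
    control_freq = NA_character_, dgv_count = NA_real_,
    literature_overlap = NA_character_, priority_tier = NA_integer_,
    genes = NA_character_, gene_context = NA_character_,
    verdict = "candidate", reason = "",
    stringsAsFactors = FALSE)[, .CAND_COLS]
}

#' Detect CNV regions shared by every genotyped affected family member
#'
#' For each chromosome and CNV type, finds groups of calls -- all pairwise
#' the same CNV under the reciprocal-overlap rule -- to which every
#' genotyped affected member contributes at least one call, and emits a
#' candidate whose interval is the intersection of the group. Groups are
#' maximal cliques of the same-CNV graph; when several maximal groups at
#' one locus (one connected component) qualify, the one with the longest
#' intersection is kept. If any affected member lacks a matching call at a
#' locus, no candidate is emitted there.
#'
#' Carriers of any affection status whose calls match the candidate are
#' recorded, partitioned by [classifyMembers()] into affected, unaffected
#' blood-relative and married-in carriers.
#'
#' @param ped A \linkS4class{Pedigree}.
#' @param callset A \linkS4class{CNVCallSet} (QC-passed calls; calls from
#'   samples outside the pedigree are ignored).
#' @param config A [runConfig()] list.
#' @param affectedIds Ids of the affected members available for testing
#'   (default: affected members with DNA). Fewer than two is a skip with a
#'   warning.
#' @return data.frame of pre-filter candidate rows (may be empty).
#' @export
familySharedCandidates <- function(ped, callset, config = runConfig(),
                                   affectedIds = NULL) {
  m <- members(ped)
  if (is.null(affectedIds))
    affectedIds <- m$id[m$affection == "affected" & m$dna]
  if (length(affectedIds) < 2L) {
    warning("family ", familyId(ped),
            ": fewer than two genotyped affected members; skipped",
            call. = FALSE)
    return(emptyCandidates())
  }
  calls <- cnvCalls(callset)
  calls <- calls[calls$sample_id %in% m$id, , drop = FALSE]
  affCalls <- calls[calls$sample_id %in% affectedIds, , drop = FALSE]
  out <- emptyCandidates()
  if (nrow(affCalls) == 0L) return(out)

  parts <- classifyMembers(ped)
  for (chrom in unique(affCalls$chrom)) {
    for (type in unique(affCalls$cnv_type[affCalls$chrom == chrom])) {
      grp <- affCalls[affCalls$chrom == chrom & affCalls$cnv_type == type, ,
                      drop = FALSE]
      if (!all(affectedIds %in% grp$sample_id)) next
      n <- nrow(grp)
      adj <- matrix(FALSE, n, n)
      for (i in seq_len(n)) for (j in seq_len(n)) if (i < j)
        adj[i, j] <- adj[j, i] <- isSameCNV(
          grp$chrom[i], grp$start[i], grp$end[i], grp$cnv_type[i],
          grp$chrom[j], grp$start[j], grp$end[j], grp$cnv_type[j],
          fraction = config$overlap_fraction, mode = config$overlap_mode)
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      comp <- igraph::components(g)$membership
      cliques <- igraph::max_cliques(g)
      for (cid in unique(comp)) {
        compCliques <- Filter(function(cl) all(comp[as.integer(cl)] == cid),
                              cliques)
        best <- NULL
        for (cl in compCliques) {
          idx <- as.integer(cl)
          if (!all(affectedIds %in% grp$sample_id[idx])) next
          iv <- intersectAll(grp$chrom[idx], grp$start[idx], grp$end[idx])
          if (is.null(iv)) next
          if (is.null(best) || (iv$end - iv$start) >
                (best$end - best$start)) best <- iv
        }
        if (is.null(best)) next
        row <- newCandidateRow(familyId(ped), chrom, best$start, best$end,
                               type)
        hit <- isSameCNV(calls$chrom, calls$start, calls$end, calls$cnv_type,
                         chrom, best$start, best$end, type,
                         fraction = config$overlap_fraction,
                         mode = config$overlap_mode)
        carriers <- unique(calls$sample_id[hit])
        row$affected_carriers <-
          paste(intersect(carriers, parts$affected), collapse = ",")
        row$unaffected_blood_carriers <-
          paste(intersect(carriers, parts$unaffected_blood), collapse = ",")
        row$married_in_carriers <-
          paste(intersect(carriers, parts$married_in), collapse = ",")
        out <- rbind(out, row)
      }
    }
  }
  out <- out[!duplicated(out$candidate_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Married-in and segregation exclusion filter
#'
#' Rejects a candidate carried by more than one married-in unaffected
#' individual (two unrelated entries into the family cannot be identical by
#' descent from one source), and candidates whose carriers admit no
#' single-introducer explanation under [inferTransmission()] (the
#' operational reading of "no clear segregation with affection status").
#' Unaffected blood-relative carriers are permitted -- the model is
#' dominant inheritance with incomplete penetrance -- and the transmission
#' label is attached to retained candidates.
#'
#' @param candidate One candidate row from [familySharedCandidates()].
#' @param ped The family's \linkS4class{Pedigree}.
#' @param config A [runConfig()] list.
#' @param genotyped Ids with known carrier status (default: members with
#'   DNA).
#' @return The updated candidate row with verdict
#'   \code{"retained"}/\code{"rejected"}, reason code, transmission label
#'   and introducer.
#' @export
segregationFilter <- function(candidate, ped, config = runConfig(),
                              genotyped = members(ped)$id[members(ped)$dna]) {
  mi <- splitIds(candidate$married_in_carriers)
  if (length(mi) > 1L) {
    candidate$verdict <- "rejected"
    candidate$reason <- "married_in>1"
    return(candidate)
  }
  carriers <- c(splitIds(candidate$affected_carriers),
                splitIds(candidate$unaffected_blood_carriers), mi)
  tr <- inferTransmission(ped, carriers, genotyped)
  candidate$transmission <- tr$label
  candidate$introducers <- paste(c(tr$introducer, tr$alternatives),
                                 collapse = ",")
  if (!tr$consistent && config$require_single_introducer) {
    candidate$verdict <- "rejected"
    candidate$reason <- "no_segregation"
    return(candidate)
  }
  candidate$verdict <- "retained"
  candidate
}

#' Count distinct population carriers matching a CNV
#'
#' Queries a \linkS4class{PopulationCNVTable} with the same-CNV predicate
#' and counts distinct carrier individuals: an individual with several
#' matching records counts once; records without a sample id (event
#' databases) each count as one.
#'
#' @param popTable A \linkS4class{PopulationCNVTable}.
#' @param chrom,start,end,type The query CNV.
#' @param config A [runConfig()] list (overlap rule).
#' @return List with \code{total} (distinct carriers), \code{byAncestry}
#'   (per-ancestry carrier and per-cohort counts) and \code{events}
#'   (matching records before deduplication).
#' @export
countPopulationCarriers <- function(popTable, chrom, start, end, type,
                                    config = runConfig()) {
  rec <- popRecords(popTable)
  if (nrow(rec) == 0L)
    return(list(total = 0, byAncestry = list(), events = 0))
  hit <- isSameCNV(rec$chrom, rec$start, rec$end, rec$type,
                   chrom, start, end, type,
                   fraction = config$overlap_fraction,
                   mode = config$overlap_mode)
  rec <- rec[hit, , drop = FALSE]
  if (nrow(rec) == 0L)
    return(list(total = 0, byAncestry = list(), events = 0))
  ids <- ifelse(is.na(rec$sample_id),
                paste0(".row", seq_len(nrow(rec))), rec$sample_id)
  dedup <- !duplicated(ids)
  rec <- rec[dedup, , drop = FALSE]
  byAnc <- list()
  for (anc in unique(rec$ancestry[!is.na(rec$ancestry)])) {
    sub <- rec[!is.na(rec$ancestry) & rec$ancestry == anc, , drop = FALSE]
    byAnc[[anc]] <- list(carriers = nrow(sub),
                         byCohort = table(factor(sub$cohort,
                                                 levels = config$cohort_order)))
  }
  list(total = nrow(rec), byAncestry = byAnc, events = sum(hit))
}

formatFreqAnnotation <- function(freqDisplay, cohortCounts) {
  num <- if (freqDisplay == 0) "0" else sprintf("%.3f", freqDisplay)
  if (is.null(cohortCounts) || sum(cohortCounts) == 0) return(num)
  paste0(num, " [", paste(as.integer(cohortCounts), collapse = "/"), "]")
}

#' Population-frequency evaluation of a candidate
#'
#' Computes the control carrier frequency per ancestry (distinct control
#' individuals matching the candidate under the same-CNV rule, divided by
#' the ancestry's cohort size) and the DGV-style event count. A candidate
#' is rejected when its ancestry-matched control frequency reaches
#' \code{config$frequency_threshold} (default 1.5\%); frequencies in
#' non-matched ancestries are reported but never ground rejection, and the
#' database event count is annotation only (common-in-DGV candidates with
#' zero control carriers survive).
#'
#' @param candidate One candidate row.
#' @param controlTable Control-cohort \linkS4class{PopulationCNVTable}
#'   (must carry cohort sizes).
#' @param dgvTable Database \linkS4class{PopulationCNVTable} (may be
#'   empty).
#' @param ancestry The family's ancestry label; must be present among the
#'   control cohort sizes.
#' @param config A [runConfig()] list.
#' @return The updated candidate row (verdict, frequencies, annotation).
#' @export
populationFilter <- function(candidate, controlTable, dgvTable = NULL,
                             ancestry, config = runConfig()) {
  sizes <- cohortSizes(controlTable)
  if (!(ancestry %in% names(sizes)))
    stop("ancestry '", ancestry, "' missing from control cohort sizes")
  cnt <- countPopulationCarriers(controlTable, candidate$chrom,
                                 candidate$start, candidate$end,
                                 candidate$cnv_type, config)
  annot <- character()
  for (anc in names(sizes)) {
    carriers <- if (!is.null(cnt$byAncestry[[anc]]))
      cnt$byAncestry[[anc]]$carriers else 0
    fr <- carrierFrequency(carriers, sizes[[anc]])
    annot[anc] <- formatFreqAnnotation(
      fr$display,
      if (!is.null(cnt$byAncestry[[anc]])) cnt$byAncestry[[anc]]$byCohort
      else NULL)
  }
  matched <- if (!is.null(cnt$byAncestry[[ancestry]]))
    cnt$byAncestry[[ancestry]]$carriers else 0
  matchedFreq <- matched / sizes[[ancestry]]

  candidate$matched_ancestry <- ancestry
  candidate$matched_control_freq <- matchedFreq
  candidate$total_control_carriers <- cnt$total
  candidate$control_freq <- paste(names(annot), annot, sep = "=",
                                  collapse = ";")
  dgv <- if (is.null(dgvTable)) 0 else
    countPopulationCarriers(dgvTable, candidate$chrom, candidate$start,
                            candidate$end, candidate$cnv_type, config)$total
  candidate$dgv_count <- dgv
  if (matchedFreq >= config$frequency_threshold) {
    candidate$verdict <- "rejected"
    candidate$reason <- "frequency"
  } else {
    candidate$verdict <- "retained"
  }
  candidate
}

#' Priority tier of a retained candidate
#'
#' Tier 1: absent in controls and the population database, and overlapping
#' a literature region (similar breakpoints, or contained within a larger
#' reported region). Tier 2: absent in both but novel (no literature
#' overlap). Tier 3: present at low (sub-threshold) frequency in controls
#' or present in the database. Deterministic.
#'
#' @param candidate One retained candidate row with population annotations.
#' @param literatureRegions data.frame from [readBedRegions()] of reported
#'   regions, or NULL.
#' @param config A [runConfig()] list.
#' @return The candidate row with \code{priority_tier} and
#'   \code{literature_overlap}
#'   (\code{none}/\code{partial-of-larger-region}/\code{similar-breakpoints})
#'   filled.
#' @export
prioritizeCandidate <- function(candidate, literatureRegions = NULL,
                                config = runConfig()) {
  lit <- "none"
  if (!is.null(literatureRegions) && nrow(literatureRegions)) {
    r <- literatureRegions
    ov <- overlapBp(r$chrom, r$start, r$end,
                    candidate$chrom, candidate$start, candidate$end)
    lenC <- candidate$end - candidate$start
    lenR <- r$end - r$start
    similar <- ov >= config$overlap_fraction * lenC &
               ov >= config$overlap_fraction * lenR
    within <- ov > 0 & candidate$start >= r$start & candidate$end <= r$end
    if (any(similar)) lit <- "similar-breakpoints"
    else if (any(within)) lit <- "partial-of-larger-region"
  }
  candidate$literature_overlap <- lit
  absent <- candidate$total_control_carriers == 0 && candidate$dgv_count == 0
  candidate$priority_tier <-
    if (absent && lit != "none") 1L else if (absent) 2L else 3L
  candidate
}

formatKb <- function(bp) {
  paste0(formatC(bp / 1000, format = "f", digits = 1, big.mark = ""), " kb")
}

#' Gene-context annotation of a candidate
#'
#' Classifies each gene overlapping the candidate: \code{whole-gene} when
#' the gene span lies entirely within the candidate, \code{exonic-portion}
#' when the candidate overlaps at least one exon without containing the
#' whole gene, \code{intronic} when the candidate lies inside the gene
#' without touching an exon, and \code{non-coding-overlap} for a partial
#' overlap that meets no exon. With no overlapping gene, the nearest gene
#' on the chromosome is reported with its distance and orientation
#' (upstream/downstream relative to the gene's strand).
#'
#' @param candidate One candidate row.
#' @param geneModels data.frame from [readGeneModels()], or NULL.
#' @return The candidate row with \code{genes} and \code{gene_context}
#'   filled.
#' @export
annotateGenes <- function(candidate, geneModels = NULL) {
  if (is.null(geneModels) || nrow(geneModels) == 0L) {
    candidate$genes <- ""
    candidate$gene_context <- "no annotation"
    return(candidate)
  }
  g <- geneModels[geneModels$chrom == normalizeChrom(candidate$chrom), ,
                  drop = FALSE]
  if (nrow(g) == 0L) {
    candidate$genes <- ""
    candidate$gene_context <- "no annotation"
    return(candidate)
  }
  ov <- overlapBp(g$chrom, g$start, g$end,
                  candidate$chrom, candidate$start, candidate$end)
  hit <- which(ov > 0)
  if (length(hit)) {
    ctx <- character()
    for (i in hit) {
      whole <- g$start[i] >= candidate$start && g$end[i] <= candidate$end
      exons <- g$exons[[i]]
      exOv <- any(overlapBp(rep(candidate$chrom, nrow(exons)),
                            exons$start, exons$end,
                            candidate$chrom, candidate$start,
                            candidate$end) > 0)
      inside <- candidate$start >= g$start[i] && candidate$end <= g$end[i]
      cls <- if (whole) "whole-gene"
             else if (exOv) "exonic-portion"
             else if (inside) "intronic"
             else "non-coding-overlap"
      ctx[g$name[i]] <- cls
    }
    candidate$genes <- paste(names(ctx), collapse = ",")
    candidate$gene_context <- paste(names(ctx), ctx, sep = ":",
                                    collapse = ";")
    return(candidate)
  }
  # nearest gene with signed distance; orientation by gene strand
  before <- candidate$end <= g$start
  after <- candidate$start >= g$end
  dist <- ifelse(before, g$start - candidate$end,
                 ifelse(after, candidate$start - g$end, 0))
  i <- which.min(dist)
  side <- if (before[i]) {
    if (g$strand[i] == "+") "upstream" else "downstream"
  } else {
    if (g$strand[i] == "+") "downstream" else "upstream"
  }
  candidate$genes <- g$name[i]
  candidate$gene_context <- paste0(g$name[i], ":nearest(",
                                   formatKb(dist[i]), " ", side, ")")
  candidate
}

traceRow <- function(candidate, stage) {
  data.frame(family_id = candidate$family_id,
             candidate_id = candidate$candidate_id, stage = stage,
             verdict = candidate$verdict, reason = candidate$reason,
             stringsAsFactors = FALSE)
}

#' Run the full co-segregation pipeline
#'
#' Orchestrates the stages: sample QC, call QC, family-wise shared-CNV
#' detection, married-in/segregation exclusion, population-frequency
#' evaluation, prioritization and gene-context annotation. Fully
#' deterministic given its inputs. Families with fewer than two genotyped
#' affected members (after QC) are skipped with a warning; pedigree
#' branches containing no genotyped affected member are pruned before
#' classification.
#'
#' @param callset A \linkS4class{CNVCallSet} of all samples.
#' @param peds Named list of \linkS4class{Pedigree} objects.
#' @param qcMetrics data.frame of per-sample QC metrics (see [sampleQC()]).
#' @param controlTable Control \linkS4class{PopulationCNVTable} with cohort
#'   sizes.
#' @param dgvTable Database \linkS4class{PopulationCNVTable}, or NULL.
#' @param literatureRegions data.frame of reported regions, or NULL.
#' @param geneModels data.frame of gene models, or NULL.
#' @param config A [runConfig()] list.
#' @return A \linkS4class{CandidateSet} with the per-stage filter trace.
#' @export
runPipeline <- function(callset, peds, qcMetrics, controlTable,
                        dgvTable = NULL, literatureRegions = NULL,
                        geneModels = NULL, config = runConfig()) {
  qc <- sampleQC(qcMetrics, config)
  ok <- qc$verdict == "pass" | (!config$strict_qc & qc$verdict == "review")
  passSamples <- qc$sample_id[ok]
  calls <- cnvCalls(callset)
  calls <- calls[calls$sample_id %in% passSamples, , drop = FALSE]
  cq <- callQC(CNVCallSet(calls), config)
  callsetQ <- cq$retained

  allCand <- emptyCandidates()
  trace <- data.frame(family_id = character(), candidate_id = character(),
                      stage = character(), verdict = character(),
                      reason = character(), stringsAsFactors = FALSE)
  for (fid in names(peds)) {
    ped <- peds[[fid]]
    m <- members(ped)
    genotypedPass <- m$id[m$dna & m$id %in% passSamples]
    affectedDNA <- intersect(genotypedPass,
                             m$id[m$affection == "affected"])
    if (length(affectedDNA) < 2L) {
      warning("family ", fid,
              ": fewer than two genotyped affected members after QC; skipped",
              call. = FALSE)
      next
    }
    pruned <- pruneUninformativeBranches(ped, affectedDNA)
    pedA <- pruned$ped
    cand <- familySharedCandidates(pedA, callsetQ, config,
                                   affectedIds = affectedDNA)
    if (nrow(cand) == 0L) next
    for (k in seq_len(nrow(cand))) {
      row <- cand[k, , drop = FALSE]
      trace <- rbind(trace, traceRow(row, "shared"))
      row <- segregationFilter(row, pedA, config,
                               genotyped = genotypedPass)
      trace <- rbind(trace, traceRow(row, "segregation"))
      if (row$verdict == "retained") {
        row <- populationFilter(row, controlTable, dgvTable,
                                familyAncestry(config, fid), config)
        trace <- rbind(trace, traceRow(row, "population"))
      }
      if (row$verdict == "retained") {
        row <- prioritizeCandidate(row, literatureRegions, config)
        trace <- rbind(trace, traceRow(row, "prioritize"))
        row <- annotateGenes(row, geneModels)
        trace <- rbind(trace, traceRow(row, "annotate"))
      }
      allCand <- rbind(allCand, row)
    }
  }
  rownames(allCand) <- NULL
  CandidateSet(allCand, trace)
}
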