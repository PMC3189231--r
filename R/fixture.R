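# Deterministic reference fixture: eleven extended families carrying twelve
# validated co-segregating CNVs, with control/DGV tables realizing the
# reported carrier counts, literature regions, synthetic gene models and a
# clinical sidecar. No randomness.

# The twelve validated loci: boundaries, type, family, reported control
# carrier counts per ancestry and cohort, DGV event count (">300" realized
# as 301 -- the pipeline thresholds on presence, not magnitude), and
# transmission class of the fixture family (deletions maternal,
# duplications both maternal and paternal).
fixtureLoci <- function() {
  utils::read.table(header = TRUE, stringsAsFactors = FALSE, text = "
type cytoband chrom start end family eur_hihg eur_nbc aa_hihg aa_nbc dgv route
del 1p34.1 1 45408389 45411073 17545 8 1 3 0 4 maternal
del 2p24.2-p24.1 2 19065745 19100096 7745 0 0 0 0 5 maternal
del 6q11.1 6 62507037 62519883 17342 0 0 0 0 2 maternal
del 12q24.32 12 125875006 125881162 17678 1 4 0 0 18 maternal
del 13q31.1 13 77912491 77917728 17142 0 0 0 0 0 maternal
dup 3p26.3 3 57010 103697 37994 2 0 0 0 5 both
dup 4p16.3 4 2704290 2747426 7663 0 0 0 0 0 both
dup 7p21.3 7 8144894 8497305 17122 0 0 0 0 0 both
dup 10p12.31 10 21727129 21818381 37232 0 0 0 0 0 both
dup 10q23.32 10 93621936 93730409 37425 0 0 0 0 0 both
dup 15q11.2 15 18411624 18472812 17668 0 0 0 0 0 both
dup 15q24.1 15 72538187 72549215 17122 0 0 0 0 0 both
")
}

# 15q11.2 control counts are non-zero; patch after the compact table above
# to keep the table readable.
fixtureLociFull <- function() {
  x <- fixtureLoci()
  i <- x$cytoband == "15q11.2"
  x$eur_hihg[i] <- 3; x$aa_nbc[i] <- 1; x$dgv[i] <- 301
  x
}

# One fixture family: founding couple, two branches, one affected cousin
# per branch, one (or for the doubly-affected family, two) typed carrier
# transmitting parents. In "maternal" families both blood parents are
# female, so the variant arrives through the mother in both branches; in
# "both" families one blood parent is male and one female. Only affected
# cousins, the typed transmitting parent(s) and the married-in spouses of
# typed parents have DNA available, mirroring sparse genotyping of upper
# generations.
fixtureFamily <- function(familyId, route, bothParentsTyped = FALSE) {
  p <- function(code) paste0(familyId, "_", code)
  maternal <- route == "maternal"
  blood1Sex <- if (maternal) "F" else "M"
  m <- data.frame(
    id = p(c("1", "2", "11", "13", "12", "14", "111", "121")),
    father = c(NA, NA, p("1"), NA, p("1"), NA,
               if (maternal) p("13") else p("11"),
               p("14")),
    mother = c(NA, NA, p("2"), NA, p("2"), NA,
               if (maternal) p("11") else p("13"),
               p("12")),
    sex = c("M", "F", blood1Sex, if (maternal) "M" else "F", "F", "M",
            "M", "M"),
    affection = c("unknown", "unknown", "unaffected", "unaffected",
                  "unknown", "unknown", "affected", "affected"),
    dna = c(FALSE, FALSE, TRUE, TRUE, bothParentsTyped, bothParentsTyped,
            TRUE, TRUE),
    stringsAsFactors = FALSE)
  if (bothParentsTyped)
    m$affection[m$id %in% p(c("12", "14"))] <- "unaffected"
  Pedigree(familyId, m, checkExtended = FALSE)
}

# Carriers of a family's CNV: the two affected cousins plus the typed
# transmitting blood parent(s).
fixtureCarriers <- function(familyId, bothParentsTyped = FALSE) {
  p <- function(code) paste0(familyId, "_", code)
  c(p("111"), p("121"), p("11"), if (bothParentsTyped) p("12"))
}

fixtureGeneBed <- function() {
  # BED12; exon blocks place the two small deletions inside introns, the
  # indicated genes wholly inside their duplications, and exonic portions
  # inside the larger duplications. Synthetic placements consistent with
  # the described gene relationships, not real transcript coordinates.
  bed12 <- function(chrom, start, end, name, strand, exonStarts, exonSizes)
    paste(paste0("chr", chrom), start, end, name, 0, strand, start, end, 0,
          length(exonStarts),
          paste0(paste(exonSizes, collapse = ","), ","),
          paste0(paste(exonStarts - start, collapse = ","), ","),
          sep = "\t")
  c(
    bed12(1, 45350000, 45500000, "ZSWIM5", "+",
          c(45350000, 45430000, 45499000), c(1000, 1000, 1000)),
    bed12(2, 19180000, 19200000, "OSR1", "-", 19180000, 20000),
    bed12(3, 212697, 425000, "CHL1", "+", c(212697, 424000), c(1000, 1000)),
    bed12(4, 2710000, 2740000, "TNIP2", "-", c(2710000, 2739000),
          c(1000, 1000)),
    bed12(6, 62400000, 62700000, "KHDRBS2", "+",
          c(62400000, 62600000, 62699000), c(1000, 1000, 1000)),
    bed12(7, 7890000, 8190000, "NXPH1", "+", c(7890000, 8150000),
          c(1000, 1000)),
    bed12(7, 8300000, 8650000, "ICA1", "-", c(8400000, 8649000),
          c(1000, 1000)),
    bed12(10, 21880000, 21900000, "C10orf114", "+", 21880000, 20000),
    bed12(10, 93670000, 93672000, "FGFBP3", "-", 93670000, 2000),
    bed12(10, 93700000, 93790000, "BTAF1", "+", c(93710000, 93789000),
          c(1000, 1000)),
    bed12(12, 125920000, 125930000, "LOC100128554", "+", 125920000, 10000),
    bed12(13, 78071228, 78076228, "POU4F1", "+", 78071228, 5000),
    bed12(15, 18550000, 18560000, "GOLGA6L6", "+", 18550000, 10000),
    bed12(15, 72520000, 72555000, "UBL7", "+", c(72540000, 72554000),
          c(1000, 1000)))
}

#' Write the deterministic reference fixture
#'
#' Builds, with no randomness, a complete input set for the pipeline:
#' eleven extended families of European ancestry carrying twelve validated
#' co-segregating CNVs (five deletions, seven duplications; one family
#' carries two duplications in the same four individuals), PennCNV-style
#' calls placing each CNV in the family's affected cousins plus the typed
#' transmitting parent(s), control tables realizing the reported
#' per-ancestry/per-cohort carrier counts over cohort sizes 727 (EUR) and
#' 111 (AA), a DGV-style table realizing the reported event counts (">300"
#' as 301), literature regions for the two previously reported loci,
#' synthetic gene models reproducing the described gene contexts, a
#' clinical-diagnosis sidecar, QC metrics, and the run configuration.
#'
#' Pedigree topologies are documented canonical simplifications: each
#' family is a founding couple with two branches and one affected cousin
#' per branch, preserving the affected-relationship class, the carrier
#' counts and the transmission routes (deletions maternal, duplications
#' both maternal and paternal).
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list of the written paths and the in-memory
#'   objects (\code{callset}, \code{peds}, \code{qcMetrics},
#'   \code{controls}, \code{dgv}, \code{literature}, \code{genes},
#'   \code{clinical}, \code{runConfig}).
#' @export
paperFixture <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  loci <- fixtureLociFull()
  famIds <- unique(loci$family)

  peds <- list()
  for (fid in famIds) {
    route <- loci$route[match(fid, loci$family)]
    peds[[as.character(fid)]] <-
      fixtureFamily(as.character(fid), route,
                    bothParentsTyped = fid == "17122")
  }

  callRows <- list()
  for (k in seq_len(nrow(loci))) {
    fid <- as.character(loci$family[k])
    carriers <- fixtureCarriers(fid, bothParentsTyped = fid == "17122")
    len <- loci$end[k] - loci$start[k]
    for (id in carriers) {
      callRows[[length(callRows) + 1L]] <- data.frame(
        sample_id = id, chrom = as.character(loci$chrom[k]),
        start = loci$start[k], end = loci$end[k],
        copy_number = if (loci$type[k] == "del") 1L else 3L,
        num_snps = max(3L, as.integer(len / 2000)),
        source = "fixture", stringsAsFactors = FALSE)
    }
  }
  callset <- CNVCallSet(do.call(rbind, callRows))

  typed <- unlist(lapply(peds, function(p) members(p)$id[members(p)$dna]),
                  use.names = FALSE)
  nPerSample <- table(factor(cnvCalls(callset)$sample_id, levels = typed))
  qcMetrics <- data.frame(sample_id = typed, sdlrr = 0.18,
                          n_cnvs = as.integer(nPerSample),
                          call_rate = 0.99, stringsAsFactors = FALSE)

  ctrlRows <- list()
  addCtrl <- function(k, n, cohort, ancestry) {
    if (n == 0) return(invisible())
    for (i in seq_len(n)) {
      ctrlRows[[length(ctrlRows) + 1L]] <<- data.frame(
        chrom = as.character(loci$chrom[k]),
        start = loci$start[k], end = loci$end[k],
        type = loci$type[k], cohort = cohort,
        ancestry = ancestry,
        sample_id = sprintf("CTRL_%s_%s_L%02d_%02d", ancestry, cohort, k, i),
        stringsAsFactors = FALSE)
    }
  }
  for (k in seq_len(nrow(loci))) {
    addCtrl(k, loci$eur_hihg[k], "HIHG", "EUR")
    addCtrl(k, loci$eur_nbc[k], "NBC", "EUR")
    addCtrl(k, loci$aa_hihg[k], "HIHG", "AA")
    addCtrl(k, loci$aa_nbc[k], "NBC", "AA")
  }
  controls <- PopulationCNVTable(
    if (length(ctrlRows)) do.call(rbind, ctrlRows) else NULL,
    cohortSizes = c(EUR = 727, AA = 111))

  dgvRows <- list()
  for (k in seq_len(nrow(loci))) {
    n <- loci$dgv[k]
    if (n == 0) next
    dgvRows[[length(dgvRows) + 1L]] <- data.frame(
      chrom = as.character(loci$chrom[k]), start = loci$start[k],
      end = loci$end[k], type = loci$type[k], cohort = "DGV",
      ancestry = NA_character_,
      sample_id = sprintf("DGV_L%02d_%04d", k, seq_len(n)),
      stringsAsFactors = FALSE)
  }
  dgv <- PopulationCNVTable(do.call(rbind, dgvRows))

  litLines <- c(
    "chr7\t8144894\t8497305\tASD_7p21.3_reported",
    "chr15\t72538187\t72549215\tASD_15q24.1_reported",
    "chr15\t71800000\t73130000\tASD_15q24_critical_region")

  # Clinical sidecar: a subset of the unaffected carrier parents and of
  # their non-carrier spouses have a recorded neuropsychiatric or
  # developmental diagnosis.
  clinical <- data.frame(
    id = c("17545_11", "7745_11", "17342_11", "17678_11", "37994_11",
           "17122_11", "17122_12", "17545_13", "37232_13"),
    diagnoses = c("ADHD", "anxiety disorder", "depression",
                  "speech disorder", "OCD", "ASD symptoms", "ODD",
                  "alcoholism", "speech disorder"),
    stringsAsFactors = FALSE)

  cfg <- runConfig(
    ancestry_by_family = stats::setNames(rep("EUR", length(famIds)),
                                         as.character(famIds)))

  paths <- list(
    calls = file.path(dir, "calls.rawcnv"),
    ped = file.path(dir, "families.ped"),
    qc = file.path(dir, "qc_metrics.tsv"),
    controls = file.path(dir, "controls.tsv"),
    dgv = file.path(dir, "dgv.tsv"),
    literature = file.path(dir, "literature.bed"),
    genes = file.path(dir, "genes.bed"),
    clinical = file.path(dir, "clinical.tsv"),
    config = file.path(dir, "config.yaml"))
  writePennCNV(callset, paths$calls)
  writePed(peds, paths$ped)
  utils::write.table(qcMetrics, paths$qc, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writePopulationTable(controls, paths$controls)
  writePopulationTable(dgv, paths$dgv)
  writeLines(litLines, paths$literature)
  writeLines(fixtureGeneBed(), paths$genes)
  utils::write.table(clinical, paths$clinical, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeRunConfig(cfg, paths$config)

  invisible(c(list(paths = paths), list(
    callset = callset, peds = peds, qcMetrics = qcMetrics,
    controls = controls, dgv = dgv,
    literature = readBedRegions(paths$literature),
    genes = readGeneModels(paths$genes),
    clinical = clinical, runConfig = cfg)))
}
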