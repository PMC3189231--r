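fixtureOnce <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- paperFixture(file.path(tempdir(), "segfix"))
      res <- runPipeline(fx$callset, fx$peds, fx$qcMetrics, fx$controls,
                         fx$dgv, fx$literature, fx$genes,
                         config = fx$runConfig)
      cache <<- list(fx = fx, res = res)
    }
    cache
  }
})

test_that("shared candidates require every genotyped affected member", {
  ped <- generatePedigree("first_cousin_pair", "FS")
  cfg <- runConfig()
  # identical deletion in both affected cousins -> one candidate
  both <- CNVCallSet(mkCalls(c("FS_111", "FS_131"), "9",
                             c(1e6, 1e6), c(1.05e6, 1.05e6)))
  cand <- familySharedCandidates(ped, both, cfg)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$start, 1e6)
  expect_equal(cand$cnv_type, "del")
  expect_setequal(strsplit(cand$affected_carriers, ",")[[1]],
                  c("FS_111", "FS_131"))

  # only one cousin carries it -> no candidate
  one <- CNVCallSet(mkCalls("FS_111", "9", 1e6, 1.05e6))
  expect_equal(nrow(familySharedCandidates(ped, one, cfg)), 0L)

  # overlapping but non-identical boundaries -> intersection is reported
  two <- CNVCallSet(mkCalls(c("FS_111", "FS_131"), "7",
                            c(8144894, 8150000), c(8497305, 8500000),
                            cn = 3L))
  cand2 <- familySharedCandidates(ped, two, cfg)
  expect_equal(nrow(cand2), 1L)
  expect_equal(cand2$start, 8150000)
  expect_equal(cand2$end, 8497305)

  # a single genotyped affected member is a skip with warning
  solo <- Pedigree("S1", data.frame(
    id = c("f", "m", "k"), father = c(NA, NA, "f"),
    mother = c(NA, NA, "m"), sex = c("M", "F", "M"),
    affection = c("unknown", "unknown", "affected"),
    dna = c(FALSE, FALSE, TRUE), stringsAsFactors = FALSE),
    checkExtended = FALSE)
  expect_warning(out <- familySharedCandidates(solo, both, cfg),
                 "fewer than two")
  expect_equal(nrow(out), 0L)
})

test_that("lower overlap fractions never lose shared candidates", {
  ped <- generatePedigree("first_cousin_pair", "MN")
  set.seed(51)
  rows <- list()
  for (i in 1:12) {
    s <- i * 1e6
    len <- sample(2e4:1e5, 1)
    rows[[length(rows) + 1L]] <- mkCalls(
      "MN_111", "8", s, s + len)
    rows[[length(rows) + 1L]] <- mkCalls(
      "MN_131", "8", s + sample(0:3e4, 1), s + len + sample(0:3e4, 1))
  }
  cs <- CNVCallSet(do.call(rbind, rows))
  strict <- familySharedCandidates(ped, cs, runConfig(overlap_fraction = 0.5))
  loose <- familySharedCandidates(ped, cs, runConfig(overlap_fraction = 0.3))
  expect_true(all(strict$candidate_id %in% loose$candidate_id))
  expect_gte(nrow(loose), nrow(strict))
})

test_that("segregation filter rejects multiple married-in carriers", {
  ped <- generatePedigree("first_cousin_pair", "MI")
  cand <- pedcnvseg:::newCandidateRow("MI", "5", 1e6, 1.1e6, "del")
  cand$affected_carriers <- "MI_111,MI_131"
  cand$married_in_carriers <- "MI_12,MI_14"   # spouses in both branches
  out <- segregationFilter(cand, ped)
  expect_equal(out$verdict, "rejected")
  expect_equal(out$reason, "married_in>1")
})

test_that("segregation filter accepts unaffected transmitting parents", {
  ped <- generatePedigree("first_cousin_pair", "TP")
  cand <- pedcnvseg:::newCandidateRow("TP", "5", 1e6, 1.1e6, "del")
  cand$affected_carriers <- "TP_111,TP_131"
  cand$unaffected_blood_carriers <- "TP_11,TP_13"
  out <- segregationFilter(cand, ped)
  expect_equal(out$verdict, "retained")
  expect_equal(out$transmission, "both")
})

test_that("segregation filter rejects carriers without a common introducer", {
  ped <- generatePedigree("first_cousin_pair", "NC")
  cand <- pedcnvseg:::newCandidateRow("NC", "5", 1e6, 1.1e6, "del")
  # cousins carry, but their genotyped blood parents do not
  cand$affected_carriers <- "NC_111,NC_131"
  out <- segregationFilter(cand, ped)
  expect_equal(out$verdict, "rejected")
  expect_equal(out$reason, "no_segregation")
})

test_that("population filter thresholds on the matched ancestry only", {
  cfg <- runConfig()
  mkTab <- function(nEur, nAa) {
    rows <- list()
    if (nEur) rows[[1]] <- data.frame(
      chrom = "1", start = 1e6, end = 1.1e6, type = "del", cohort = "HIHG",
      ancestry = "EUR", sample_id = paste0("E", 1:nEur),
      stringsAsFactors = FALSE)
    if (nAa) rows[[length(rows) + 1]] <- data.frame(
      chrom = "1", start = 1e6, end = 1.1e6, type = "del", cohort = "HIHG",
      ancestry = "AA", sample_id = paste0("A", 1:nAa),
      stringsAsFactors = FALSE)
    PopulationCNVTable(if (length(rows)) do.call(rbind, rows) else NULL,
                       c(EUR = 727, AA = 111))
  }
  cand <- pedcnvseg:::newCandidateRow("F", "1", 1e6, 1.1e6, "del")

  zero <- populationFilter(cand, mkTab(0, 0), NULL, "EUR", cfg)
  expect_equal(zero$verdict, "retained")
  expect_equal(zero$matched_control_freq, 0)

  nine <- populationFilter(cand, mkTab(9, 0), NULL, "EUR", cfg)
  expect_equal(nine$verdict, "retained")   # 9/727 = 0.012 < 0.015
  expect_match(nine$control_freq, "EUR=0.012 \\[9/0\\]")

  # 0.027 in the matched ancestry -> rejected ...
  aa <- populationFilter(cand, mkTab(0, 3), NULL, "AA", cfg)
  expect_equal(aa$verdict, "rejected")
  expect_equal(aa$reason, "frequency")
  # ... but the same table matched to EUR retains (3/111 is unmatched)
  eur <- populationFilter(cand, mkTab(0, 3), NULL, "EUR", cfg)
  expect_equal(eur$verdict, "retained")

  expect_error(populationFilter(cand, mkTab(0, 0), NULL, "AMR", cfg),
               "missing from control cohort sizes")
})

test_that("a higher frequency threshold never removes retained candidates", {
  fx <- fixtureOnce()$fx
  run <- function(thr) {
    cfg <- runConfig(frequency_threshold = thr,
                     ancestry_by_family = fx$runConfig$ancestry_by_family)
    res <- runPipeline(fx$callset, fx$peds, fx$qcMetrics, fx$controls,
                       fx$dgv, fx$literature, fx$genes, config = cfg)
    cand <- candidates(res)
    cand$candidate_id[cand$verdict == "retained"]
  }
  low <- run(0.005)
  mid <- run(0.015)
  high <- run(0.5)
  expect_true(all(low %in% mid))
  expect_true(all(mid %in% high))
})

test_that("database presence annotates but never rejects", {
  cfg <- runConfig()
  cand <- pedcnvseg:::newCandidateRow("F", "15", 18411624, 18472812, "dup")
  dgv <- PopulationCNVTable(data.frame(
    chrom = "15", start = 18411624, end = 18472812, type = "dup",
    cohort = "DGV", ancestry = NA_character_,
    sample_id = sprintf("D%03d", 1:301), stringsAsFactors = FALSE))
  empty <- PopulationCNVTable(NULL, c(EUR = 727))
  out <- populationFilter(cand, empty, dgv, "EUR", cfg)
  expect_equal(out$verdict, "retained")
  expect_equal(out$dgv_count, 301)
})

test_that("priority tiers follow population absence and literature overlap", {
  cfg <- runConfig()
  lit <- data.frame(chrom = "7", start = 8144894, end = 8497305,
                    name = "reported", stringsAsFactors = FALSE)
  base <- pedcnvseg:::newCandidateRow("F", "7", 8144894, 8497305, "dup")
  base$total_control_carriers <- 0
  base$dgv_count <- 0
  t1 <- prioritizeCandidate(base, lit, cfg)
  expect_equal(t1$priority_tier, 1L)
  expect_equal(t1$literature_overlap, "similar-breakpoints")

  t2 <- prioritizeCandidate(base, NULL, cfg)
  expect_equal(t2$priority_tier, 2L)
  expect_equal(t2$literature_overlap, "none")

  low <- base
  low$total_control_carriers <- 3
  low$dgv_count <- 301
  t3 <- prioritizeCandidate(low, lit, cfg)
  expect_equal(t3$priority_tier, 3L)

  # small candidate inside a much larger reported region
  big <- data.frame(chrom = "15", start = 71800000, end = 73130000,
                    name = "critical", stringsAsFactors = FALSE)
  small <- pedcnvseg:::newCandidateRow("F", "15", 72538187, 72549215, "dup")
  small$total_control_carriers <- 0
  small$dgv_count <- 0
  tw <- prioritizeCandidate(small, big, cfg)
  expect_equal(tw$literature_overlap, "partial-of-larger-region")
  expect_equal(tw$priority_tier, 1L)
})

test_that("gene context classes cover intronic, whole-gene and nearest", {
  g <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(
    paste("chr1", 1000, 101000, "INTRO", 0, "+", 1000, 101000, 0, 2,
          "100,100,", "0,99900,", sep = "\t"),
    paste("chr2", 5000, 6000, "WHOLE", 0, "+", 5000, 6000, 0, 1,
          "1000,", "0,", sep = "\t"),
    paste("chr3", 500000, 600000, "NEAR", 0, "+", 500000, 600000, 0, 1,
          "100000,", "0,", sep = "\t"),
    paste("chr3", 900000, 950000, "FAR", 0, "-", 900000, 950000, 0, 1,
          "50000,", "0,", sep = "\t")), g)
  gm <- readGeneModels(g)

  intro <- annotateGenes(
    pedcnvseg:::newCandidateRow("F", "1", 20000, 30000, "del"), gm)
  expect_equal(intro$gene_context, "INTRO:intronic")

  whole <- annotateGenes(
    pedcnvseg:::newCandidateRow("F", "2", 4000, 7000, "dup"), gm)
  expect_equal(whole$gene_context, "WHOLE:whole-gene")

  near <- annotateGenes(
    pedcnvseg:::newCandidateRow("F", "3", 300000, 346500, "del"), gm)
  expect_equal(near$gene_context, "NEAR:nearest(153.5 kb upstream)")

  none <- annotateGenes(
    pedcnvseg:::newCandidateRow("F", "9", 1000, 2000, "del"), gm)
  expect_equal(none$gene_context, "no annotation")
})

test_that("the reference fixture yields the twelve expected candidates", {
  res <- fixtureOnce()$res
  cand <- candidates(res)
  ret <- cand[cand$verdict == "retained", ]
  expect_equal(nrow(ret), 12L)
  expect_equal(sum(ret$cnv_type == "del"), 5L)
  expect_equal(sum(ret$cnv_type == "dup"), 7L)
  expect_equal(length(unique(ret$family_id)), 11L)
  two <- ret[ret$family_id == "17122", ]
  expect_equal(nrow(two), 2L)
  expect_equal(two$transmission[1], two$transmission[2])
  expect_setequal(strsplit(two$affected_carriers[1], ",")[[1]],
                  strsplit(two$affected_carriers[2], ",")[[1]])
  # every genotyped affected member appears among the affected carriers
  fx <- fixtureOnce()$fx
  for (k in seq_len(nrow(ret))) {
    ped <- fx$peds[[ret$family_id[k]]]
    m <- members(ped)
    affDna <- m$id[m$affection == "affected" & m$dna]
    expect_true(all(affDna %in% strsplit(ret$affected_carriers[k], ",")[[1]]))
  }
})

test_that("the filter trace conserves candidates stage to stage", {
  res <- fixtureOnce()$res
  tr <- filterTrace(res)
  expect_false(any(duplicated(tr[, c("candidate_id", "stage")])))
  entered <- tr$candidate_id[tr$stage == "shared"]
  seg <- tr[tr$stage == "segregation", ]
  expect_setequal(seg$candidate_id, entered)
  pop <- tr[tr$stage == "population", ]
  expect_setequal(pop$candidate_id,
                  seg$candidate_id[seg$verdict == "retained"])
  pri <- tr[tr$stage == "prioritize", ]
  expect_setequal(pri$candidate_id,
                  pop$candidate_id[pop$verdict == "retained"])
})

test_that("a cohort with no CNV calls yields an empty result", {
  fx <- fixtureOnce()$fx
  res <- runPipeline(CNVCallSet(), fx$peds, fx$qcMetrics, fx$controls,
                     fx$dgv, config = fx$runConfig)
  expect_equal(nrow(candidates(res)), 0L)
  expect_equal(nrow(filterTrace(res)), 0L)
})
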