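test_that("pedigree templates realize the intended relationships", {
  fc <- generatePedigree("first_cousin_pair", "A")
  expect_equal(expectedSharing(fc, "A_111", "A_131"), 0.125)
  sc <- generatePedigree("second_cousin_pair", "B")
  expect_equal(expectedSharing(sc, "B_1111", "B_1311"), 0.03125)
  for (s in c("first_cousin_pair", "avuncular_pair", "second_cousin_pair",
              "three_affected", "four_affected")) {
    ped <- generatePedigree(s, "V")
    expect_s4_class(ped, "Pedigree")
    expect_true(validObject(ped))
    m <- members(ped)
    expect_gte(sum(m$affection == "affected" & m$dna), 2L)
  }
  expect_error(generatePedigree("no_such_template", "X"), "unknown")
})

test_that("gene dropping is Mendelian and respects designations", {
  set.seed(61)
  ped <- generatePedigree("four_affected", "GD")
  m <- members(ped)
  for (r in 1:50) {
    copies <- geneDrop(ped, introducer = "GD_1")
    # every non-founder carrier has a carrier parent
    for (id in m$id[!is.na(m$father)]) {
      if (copies[[id]] > 0L)
        expect_true(copies[[m$father[m$id == id]]] > 0L ||
                    copies[[m$mother[m$id == id]]] > 0L)
    }
  }
  none <- geneDrop(ped, freq = 0)
  expect_true(all(none == 0L))
  expect_error(geneDrop(ped, freq = 1.5), "frequency")
  expect_error(geneDrop(ped), "exactly one")
})

test_that("founder carrier fraction is binomially calibrated", {
  set.seed(62)
  founders <- data.frame(
    id = paste0("P_", 1:1000), father = NA_character_,
    mother = NA_character_, sex = rep(c("M", "F"), 500),
    affection = "unknown", dna = FALSE, stringsAsFactors = FALSE)
  ped <- Pedigree("P", founders, checkExtended = FALSE)
  copies <- geneDrop(ped, freq = 0.2)
  carriers <- sum(copies > 0L)
  expect_gte(carriers, qbinom(0.005, 1000, 0.2))
  expect_lte(carriers, qbinom(0.995, 1000, 0.2))
})

test_that("full-penetrance planted variants make every affected a carrier", {
  set.seed(63)
  cfg <- simulationConfig(penetrance = 1, phenocopy = 0)
  for (r in 1:20) {
    fam <- pedcnvseg:::simulateFamily("first_cousin_pair", paste0("S", r),
                                      planted = TRUE, config = cfg)
    m <- members(fam$ped)
    affected <- m$id[m$affection == "affected"]
    expect_true(all(fam$carriers[affected] > 0L))
  }
})

test_that("cohort emission is deterministic and jitter-controlled", {
  cfg <- simulationConfig(n_two = 2, n_three = 1, n_four = 0,
                          background = defaultBackgroundPool(6),
                          planted = data.frame(
                            chrom = "5", start = 5e6, end = 5.1e6,
                            type = "del", family_index = 1))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  emitCohort(cfg, d1, seed = 99)
  emitCohort(cfg, d2, seed = 99)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the cohort
  d3 <- withr::local_tempdir()
  emitCohort(cfg, d3, seed = 100)
  expect_false(identical(readLines(file.path(d1, "calls.rawcnv")),
                         readLines(file.path(d3, "calls.rawcnv"))))

  # jitter 0: all calls at a planted locus share exact coordinates
  cfg0 <- simulationConfig(n_two = 1, n_three = 0, n_four = 0,
                           background = NULL, jitter = 0,
                           penetrance = 1, phenocopy = 0,
                           planted = data.frame(
                             chrom = "5", start = 5e6, end = 5.1e6,
                             type = "del", family_index = 1))
  sim <- simulateCohort(cfg0, seed = 7)
  calls <- cnvCalls(sim$callset)
  expect_true(all(calls$start == 5e6 & calls$end == 5.1e6))
})

test_that("control carrier frequencies match the configured background", {
  cfg <- simulationConfig(n_two = 1, n_three = 0, n_four = 0,
                          background = data.frame(
                            chrom = c("3", "11"), start = c(3e7, 4e7),
                            end = c(3.01e7, 4.02e7),
                            type = c("del", "dup"), freq = c(0.05, 0.08),
                            stringsAsFactors = FALSE))
  sim <- simulateCohort(cfg, seed = 17)
  n <- sum(cfg$control_sizes)   # 838 controls
  rec <- popRecords(sim$controls)
  for (k in 1:2) {
    bg <- cfg$background[k, ]
    hit <- isSameCNV(rec$chrom, rec$start, rec$end, rec$type,
                     bg$chrom, bg$start, bg$end, bg$type)
    carriers <- length(unique(rec$sample_id[hit]))
    expect_gte(carriers, qbinom(0.0005, n, bg$freq))
    expect_lte(carriers, qbinom(0.9995, n, bg$freq))
  }
})

test_that("the pipeline retains exactly the planted variants of a cohort", {
  planted <- data.frame(
    chrom = as.character(c(1, 2, 3, 4, 5, 6, 7, 7, 8, 9, 10, 11)),
    start = 1e7 + (0:11) * 5e5,
    end = 1e7 + (0:11) * 5e5 + c(3e4, 5e4, 2e4, 8e4, 1e5, 4e4, 3.5e5,
                                 1.1e4, 6e4, 9e4, 1e5, 5e4),
    type = c("del", "del", "del", "del", "del", "dup", "dup", "dup",
             "dup", "dup", "dup", "dup"),
    family_index = c(1, 2, 3, 4, 5, 6, 7, 7, 8, 9, 10, 11),
    stringsAsFactors = FALSE)
  cfg <- simulationConfig(n_two = 8, n_three = 2, n_four = 1,
                          penetrance = 1, phenocopy = 0,
                          background = defaultBackgroundPool(10),
                          planted = planted)
  sim <- simulateCohort(cfg, seed = 23)
  res <- suppressWarnings(
    runPipeline(sim$callset, sim$peds, sim$qcMetrics, sim$controls,
                sim$dgv, config = sim$runConfig))
  cand <- candidates(res)
  ret <- cand[cand$verdict == "retained", ]
  truth <- sim$truth
  matchTruth <- function(row) {
    any(truth$family_id == row$family_id &
          isSameCNV(truth$chrom, truth$start, truth$end, truth$type,
                    row$chrom, row$start, row$end, row$cnv_type))
  }
  # every retained candidate is a planted variant and vice versa
  expect_equal(nrow(ret), nrow(truth))
  for (k in seq_len(nrow(ret)))
    expect_true(matchTruth(ret[k, , drop = FALSE]))
})

test_that("ascertained penetrance-0.6 retention brackets the analytic rate", {
  pen <- 0.6; phe <- 0.001
  # exact retention-given-ascertainment for the first-cousin template:
  # enumerate transmissions (introducer "x_1" het) and affection outcomes
  pRA <- 0; pA <- 0
  q <- function(c) if (c > 0) pen else phe
  for (c11 in 0:1) for (c13 in 0:1) for (c111 in 0:1) for (c131 in 0:1) {
    p <- dbinom(c11, 1, 0.5) * dbinom(c13, 1, 0.5) *
      dbinom(c111, 1, c11 / 2) * dbinom(c131, 1, c13 / 2)
    if (p == 0) next
    pA <- pA + p * q(c111) * q(c131)
    if (c111 == 1 && c131 == 1) {
      nNonCarrierTyped <- 2 + (c11 == 0) + (c13 == 0)  # spouses + parents
      pRA <- pRA + p * pen^2 * (1 - phe)^nNonCarrierTyped
    }
  }
  analytic <- pRA / pA

  set.seed(64)
  cfg <- simulationConfig(n_two = 1, n_three = 0, n_four = 0,
                          penetrance = pen, phenocopy = phe,
                          background = NULL,
                          planted = data.frame(
                            chrom = "5", start = 5e6, end = 5.1e6,
                            type = "del", family_index = 1))
  retained <- 0L
  reps <- 50L
  for (r in seq_len(reps)) {
    sim <- simulateCohort(cfg, seed = 1000 + r)
    res <- tryCatch(
      suppressWarnings(
        runPipeline(sim$callset, sim$peds, sim$qcMetrics, sim$controls,
                    sim$dgv, config = sim$runConfig)),
      error = function(e) NULL)
    if (is.null(res)) next
    cand <- candidates(res)
    ret <- cand[cand$verdict == "retained", , drop = FALSE]
    hit <- nrow(ret) > 0 && any(
      isSameCNV(ret$chrom, ret$start, ret$end, ret$cnv_type,
                "5", 5e6, 5.1e6, "del"))
    if (hit) retained <- retained + 1L
  }
  expect_gte(retained, qbinom(0.005, reps, analytic))
  expect_lte(retained, qbinom(0.995, reps, analytic))
})
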