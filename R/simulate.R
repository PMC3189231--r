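# Seeded generator of extended-family cohorts: pedigree templates, gene
# dropping with incomplete penetrance, background CNV polymorphisms, control
# cohorts and truth logs.

#' Simulation configuration
#'
#' Conditions of a simulated cohort. Defaults emulate the study design the
#' package targets: 42 extended families -- 28 with two, 8 with three and 6
#' with four affected cousin-or-more-distant relatives -- genotyped
#' alongside a pediatric control cohort of 727 European-ancestry and 111
#' African-American individuals (the post-QC analysis sizes), under a
#' dominant risk-CNV model with incomplete penetrance.
#'
#' @param n_two,n_three,n_four Family counts by number of affected distant
#'   relatives.
#' @param penetrance Probability that a risk-CNV carrier is affected. The
#'   source study reports no estimate; 0.6 is the package default, stated
#'   as configuration rather than an empirical claim.
#' @param phenocopy Probability that a non-carrier is affected.
#' @param control_sizes Named vector of control cohort sizes by ancestry.
#' @param hihg_fraction Fraction of controls recruited by the first center
#'   (cohort label "HIHG"); the remainder are "NBC".
#' @param background data.frame of background CNV polymorphism loci
#'   (\code{chrom}, \code{start}, \code{end}, \code{type}, \code{freq} --
#'   population carrier frequency).
#' @param planted data.frame of planted risk CNVs (\code{chrom},
#'   \code{start}, \code{end}, \code{type}, \code{family_index} -- which
#'   families, by position, receive the variant), or NULL for none.
#' @param jitter Per-sample boundary jitter in bp (uniform within +/-
#'   jitter, capped so reciprocal overlap with the locus definition is
#'   preserved).
#' @param max_resample Resampling cap for the ascertainment condition.
#' @return A list of class \code{"pedcnvseg_simconfig"}.
#' @export
simulationConfig <- function(n_two = 28, n_three = 8, n_four = 6,
                             penetrance = 0.6, phenocopy = 0.001,
                             control_sizes = c(EUR = 727, AA = 111),
                             hihg_fraction = 0.6,
                             background = defaultBackgroundPool(),
                             planted = NULL,
                             jitter = 500,
                             max_resample = 10000) {
  probs <- c(penetrance, phenocopy)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!is.null(background) && nrow(background) &&
      any(background$freq < 0 | background$freq > 1))
    stop("background frequencies must lie in [0, 1]")
  cfg <- list(n_two = n_two, n_three = n_three, n_four = n_four,
              penetrance = penetrance, phenocopy = phenocopy,
              control_sizes = control_sizes,
              hihg_fraction = hihg_fraction,
              background = background, planted = planted,
              jitter = jitter, max_resample = max_resample)
  class(cfg) <- "pedcnvseg_simconfig"
  cfg
}

#' Default background CNV polymorphism pool
#'
#' A deterministic pool of common CNV polymorphism loci spread over the
#' autosomes, with carrier frequencies of 3-10\% -- common enough that the
#' control-frequency filter is their expected fate, matching their role as
#' benign polymorphisms.
#'
#' @param n Number of loci.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{type}, \code{freq}.
#' @export
defaultBackgroundPool <- function(n = 30) {
  i <- seq_len(n)
  sizes <- c(10e3, 25e3, 50e3, 100e3, 200e3)[(i - 1L) %% 5L + 1L]
  start <- 20e6 + ((i - 1L) %/% 22L) * 7e6 + (i - 1L) %% 22L * 1e6
  data.frame(chrom = as.character((i - 1L) %% 22L + 1L),
             start = start, end = start + sizes,
             type = c("del", "dup")[(i - 1L) %% 2L + 1L],
             freq = seq(0.03, 0.10, length.out = 8L)[(i - 1L) %% 8L + 1L],
             stringsAsFactors = FALSE)
}

# Pedigree template: member table plus the ids of the cousin-generation
# slots (used for ascertainment), the default introducing founder, and the
# template-designated affected members.
pedigreeTemplate <- function(structure, familyId) {
  p <- function(code) paste0(familyId, "_", code)
  row <- function(code, father = NA, mother = NA, sex, dna = FALSE)
    data.frame(id = p(code),
               father = if (is.na(father)) NA_character_ else p(father),
               mother = if (is.na(mother)) NA_character_ else p(mother),
               sex = sex, affection = "unknown", dna = dna,
               stringsAsFactors = FALSE)
  branches <- function(k) {
    # k branches from the founding couple, one child per branch
    out <- list(row("1", sex = "M"), row("2", sex = "F"))
    cousins <- character()
    for (b in seq_len(k)) {
      blood <- as.character(10 + 2 * (b - 1) + 1)         # 11, 13, 15, ...
      spouse <- as.character(10 + 2 * (b - 1) + 2)        # 12, 14, 16, ...
      bloodSex <- if (b %% 2L == 1L) "M" else "F"
      out <- c(out, list(
        row(blood, "1", "2", sex = bloodSex, dna = TRUE),
        row(spouse, sex = if (bloodSex == "M") "F" else "M", dna = TRUE)))
      kid <- paste0(blood, "1")
      fa <- if (bloodSex == "M") blood else spouse
      mo <- if (bloodSex == "M") spouse else blood
      out <- c(out, list(row(kid, fa, mo, sex = "M", dna = TRUE)))
      cousins <- c(cousins, p(kid))
    }
    list(members = do.call(rbind, out), cousins = cousins)
  }
  tmpl <- switch(structure,
    first_cousin_pair = {
      b <- branches(2L)
      list(members = b$members, cousins = b$cousins, affected = b$cousins)
    },
    three_affected = {
      b <- branches(3L)
      list(members = b$members, cousins = b$cousins, affected = b$cousins)
    },
    four_affected = {
      b <- branches(4L)
      list(members = b$members, cousins = b$cousins, affected = b$cousins)
    },
    avuncular_pair = {
      m <- rbind(row("1", sex = "M"), row("2", sex = "F"),
                 row("11", "1", "2", sex = "M", dna = TRUE),
                 row("13", "1", "2", sex = "F", dna = TRUE),
                 row("14", sex = "M", dna = TRUE),
                 row("131", "14", "13", sex = "M", dna = TRUE))
      list(members = m, cousins = c(p("11"), p("131")),
           affected = c(p("11"), p("131")))
    },
    second_cousin_pair = {
      m <- rbind(row("1", sex = "M"), row("2", sex = "F"),
                 row("11", "1", "2", sex = "M"),
                 row("12", sex = "F"),
                 row("13", "1", "2", sex = "F"),
                 row("14", sex = "M"),
                 row("111", "11", "12", sex = "M", dna = TRUE),
                 row("112", sex = "F", dna = TRUE),
                 row("131", "14", "13", sex = "F", dna = TRUE),
                 row("132", sex = "M", dna = TRUE),
                 row("1111", "111", "112", sex = "M", dna = TRUE),
                 row("1311", "132", "131", sex = "M", dna = TRUE))
      list(members = m, cousins = c(p("1111"), p("1311")),
           affected = c(p("1111"), p("1311")))
    },
    stop("unknown pedigree template: ", structure))
  tmpl$introducer <- p("1")
  tmpl$structure <- structure
  tmpl
}

#' Generate a template extended-family pedigree
#'
#' Builds a 3-4 generation pedigree from a named template
#' (\code{"first_cousin_pair"}, \code{"avuncular_pair"},
#' \code{"second_cousin_pair"}, \code{"three_affected"},
#' \code{"four_affected"}), with married-in spouses, template-designated
#' affected members, and DNA availability flags (descendant generations and
#' their parents typed; founders untyped).
#'
#' @param structure Template name.
#' @param familyId Family identifier; member ids are prefixed with it.
#' @return A \linkS4class{Pedigree}.
#' @export
generatePedigree <- function(structure, familyId) {
  tmpl <- pedigreeTemplate(structure, familyId)
  m <- tmpl$members
  m$affection[m$id %in% tmpl$affected] <- "affected"
  m$affection[!(m$id %in% tmpl$affected) & m$dna] <- "unaffected"
  Pedigree(familyId, m, checkExtended = FALSE)
}

#' Drop a variant through a pedigree
#'
#' Standard gene dropping with diploid bookkeeping. Founders receive copies
#' either by designation (\code{introducer} starts with one copy) or by
#' population carrier frequency \code{freq} (per-allele frequency
#' \eqn{1 - \sqrt{1 - freq}}, so the founder carrier fraction matches
#' \code{freq}). Each child inherits one allele per parent, present with
#' probability copies/2.
#'
#' @param ped A \linkS4class{Pedigree}.
#' @param freq Population carrier frequency for founder assignment
#'   (background mode), or NULL.
#' @param introducer Id of the designated introducing founder (planted
#'   mode), or NULL.
#' @return Named integer vector of copy counts (0, 1, 2) per member.
#' @export
geneDrop <- function(ped, freq = NULL, introducer = NULL) {
  m <- members(ped)
  if (is.null(freq) == is.null(introducer))
    stop("give exactly one of freq or introducer")
  if (!is.null(freq) && (freq < 0 || freq > 1))
    stop("frequency must lie in [0, 1]")
  copies <- stats::setNames(integer(nrow(m)), m$id)
  founders <- m$id[is.na(m$father)]
  if (!is.null(introducer)) {
    .memberRow(ped, introducer)
    copies[introducer] <- 1L
  } else {
    a <- 1 - sqrt(1 - freq)
    copies[founders] <- stats::rbinom(length(founders), 2L, a)
  }
  depth <- pedigreeDepths(m)
  for (id in m$id[order(depth[m$id])]) {
    i <- match(id, m$id)
    if (is.na(m$father[i])) next
    copies[id] <- stats::rbinom(1L, 1L, copies[m$father[i]] / 2) +
                  stats::rbinom(1L, 1L, copies[m$mother[i]] / 2)
  }
  copies
}

# Ascertained planted-variant family: redrop variant and affection until the
# required number of cousin-generation members is affected.
simulateFamily <- function(structure, familyId, planted = FALSE,
                           config = simulationConfig()) {
  tmpl <- pedigreeTemplate(structure, familyId)
  ped0 <- Pedigree(familyId, tmpl$members, checkExtended = FALSE)
  required <- length(tmpl$affected)
  if (!planted) {
    m <- members(ped0)
    m$affection[m$id %in% tmpl$affected] <- "affected"
    m$affection[!(m$id %in% tmpl$affected) & m$dna] <- "unaffected"
    return(list(ped = Pedigree(familyId, m, checkExtended = FALSE),
                carriers = stats::setNames(integer(nrow(m)), m$id),
                introducer = NA_character_, resamples = 0L))
  }
  for (it in seq_len(config$max_resample)) {
    copies <- geneDrop(ped0, introducer = tmpl$introducer)
    m <- members(ped0)
    pAff <- ifelse(copies[m$id] > 0L, config$penetrance, config$phenocopy)
    affected <- stats::runif(nrow(m)) < pAff
    if (sum(affected[m$id %in% tmpl$cousins]) >= required) {
      m$affection <- ifelse(affected, "affected", "unaffected")
      m$affection[is.na(m$father) & !m$dna & !affected] <- "unknown"
      return(list(ped = Pedigree(familyId, m, checkExtended = FALSE),
                  carriers = copies, introducer = tmpl$introducer,
                  resamples = it))
    }
  }
  stop("family ", familyId, ": ascertainment condition not met within ",
       config$max_resample, " resamples")
}

jitterInterval <- function(start, end, jitter) {
  len <- end - start
  j <- min(jitter, floor(len / 8))
  if (j <= 0) return(c(start, end))
  c(start + sample.int(2L * j + 1L, 1L) - j - 1L,
    end + sample.int(2L * j + 1L, 1L) - j - 1L)
}

callsForCarriers <- function(copies, ped, locus, config) {
  m <- members(ped)
  typedCarriers <- m$id[m$dna & copies[m$id] > 0L]
  if (length(typedCarriers) == 0L) return(NULL)
  rows <- lapply(typedCarriers, function(id) {
    iv <- jitterInterval(locus$start, locus$end, config$jitter)
    cn <- if (locus$type == "del") 2L - min(copies[[id]], 2L)
          else 2L + min(copies[[id]], 2L)
    data.frame(sample_id = id, chrom = locus$chrom,
               start = iv[1L], end = iv[2L], copy_number = cn,
               num_snps = max(3L, as.integer((iv[2L] - iv[1L]) / 2000)),
               source = "simulated", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a full extended-family cohort
#'
#' Generates the cohort in memory: family pedigrees (ascertainment by
#' resampling for planted-variant families, template affection otherwise),
#' planted and background CNV calls for typed members with per-sample
#' boundary jitter, passing sample-QC metrics, an ancestry-stratified
#' control cohort carrying the background polymorphisms, a DGV-style event
#' table, and the truth log of every planted variant. Deterministic given
#' the seed.
#'
#' @param config A [simulationConfig()].
#' @param seed Integer RNG seed.
#' @return List with \code{callset}, \code{peds}, \code{qcMetrics},
#'   \code{controls}, \code{dgv}, \code{truth}, \code{runConfig}.
#' @export
simulateCohort <- function(config = simulationConfig(), seed = 1L) {
  set.seed(seed)
  twoMix <- c("first_cousin_pair", "first_cousin_pair",
              "avuncular_pair", "second_cousin_pair")
  structures <- c(rep(twoMix, length.out = config$n_two),
                  rep("three_affected", config$n_three),
                  rep("four_affected", config$n_four))
  nFam <- length(structures)
  familyIds <- sprintf("F%03d", seq_len(nFam))

  planted <- config$planted
  plantedByFam <- vector("list", nFam)
  if (!is.null(planted) && nrow(planted)) {
    for (k in seq_len(nrow(planted))) {
      fi <- planted$family_index[k]
      if (fi > nFam) stop("planted family_index beyond cohort size")
      plantedByFam[[fi]] <- rbind(plantedByFam[[fi]], planted[k, ])
    }
  }

  peds <- list()
  callRows <- list()
  truthRows <- list()
  for (i in seq_len(nFam)) {
    fid <- familyIds[i]
    hasPlanted <- !is.null(plantedByFam[[i]])
    fam <- simulateFamily(structures[i], fid, planted = hasPlanted,
                          config = config)
    peds[[fid]] <- fam$ped
    if (hasPlanted) {
      for (k in seq_len(nrow(plantedByFam[[i]]))) {
        locus <- plantedByFam[[i]][k, ]
        callRows[[length(callRows) + 1L]] <-
          callsForCarriers(fam$carriers, fam$ped, locus, config)
        truthRows[[length(truthRows) + 1L]] <- data.frame(
          family_id = fid, chrom = locus$chrom, start = locus$start,
          end = locus$end, type = locus$type,
          introducer = fam$introducer,
          carriers = paste(names(fam$carriers)[fam$carriers > 0L],
                           collapse = ","),
          resamples = fam$resamples, stringsAsFactors = FALSE)
      }
    }
    bg <- config$background
    if (!is.null(bg) && nrow(bg)) {
      for (k in seq_len(nrow(bg))) {
        copies <- geneDrop(fam$ped, freq = bg$freq[k])
        callRows[[length(callRows) + 1L]] <-
          callsForCarriers(copies, fam$ped, bg[k, ], config)
      }
    }
  }
  calls <- do.call(rbind, Filter(Negate(is.null), callRows))
  callset <- CNVCallSet(calls)

  typed <- unlist(lapply(peds, function(p) members(p)$id[members(p)$dna]),
                  use.names = FALSE)
  nPerSample <- table(factor(cnvCalls(callset)$sample_id, levels = typed))
  qcMetrics <- data.frame(
    sample_id = typed,
    sdlrr = round(stats::runif(length(typed), 0.12, 0.28), 3),
    n_cnvs = as.integer(nPerSample),
    call_rate = round(stats::runif(length(typed), 0.96, 0.999), 4),
    stringsAsFactors = FALSE)

  # control cohort: background polymorphisms at their configured frequency
  ctrlRows <- list()
  for (anc in names(config$control_sizes)) {
    n <- config$control_sizes[[anc]]
    ids <- sprintf("CTRL_%s_%04d", anc, seq_len(n))
    cohort <- ifelse(seq_len(n) <= round(config$hihg_fraction * n),
                     "HIHG", "NBC")
    bg <- config$background
    if (is.null(bg) || nrow(bg) == 0L) next
    for (k in seq_len(nrow(bg))) {
      carrier <- stats::runif(n) < bg$freq[k]
      if (!any(carrier)) next
      for (j in which(carrier)) {
        iv <- jitterInterval(bg$start[k], bg$end[k], config$jitter)
        ctrlRows[[length(ctrlRows) + 1L]] <- data.frame(
          chrom = bg$chrom[k], start = iv[1L], end = iv[2L],
          type = bg$type[k], cohort = cohort[j], ancestry = anc,
          sample_id = ids[j], stringsAsFactors = FALSE)
      }
    }
  }
  controls <- PopulationCNVTable(
    if (length(ctrlRows)) do.call(rbind, ctrlRows) else NULL,
    cohortSizes = config$control_sizes)

  dgvRows <- list()
  bg <- config$background
  if (!is.null(bg) && nrow(bg)) {
    for (k in seq_len(nrow(bg))) {
      nEvents <- stats::rbinom(1L, 500L, bg$freq[k])
      if (nEvents == 0L) next
      dgvRows[[length(dgvRows) + 1L]] <- data.frame(
        chrom = bg$chrom[k], start = bg$start[k], end = bg$end[k],
        type = bg$type[k], cohort = "DGV", ancestry = NA_character_,
        sample_id = sprintf("DGV_L%02d_%04d", k, seq_len(nEvents)),
        stringsAsFactors = FALSE)
    }
  }
  dgv <- PopulationCNVTable(
    if (length(dgvRows)) do.call(rbind, dgvRows) else NULL)

  truth <- if (length(truthRows)) do.call(rbind, truthRows) else
    data.frame(family_id = character(), chrom = character(),
               start = numeric(), end = numeric(), type = character(),
               introducer = character(), carriers = character(),
               resamples = integer(), stringsAsFactors = FALSE)

  rc <- runConfig(
    ancestry_by_family = stats::setNames(
      rep(names(config$control_sizes)[1L], nFam), familyIds),
    seed = seed)

  list(callset = callset, peds = peds, qcMetrics = qcMetrics,
       controls = controls, dgv = dgv, truth = truth, runConfig = rc)
}

#' Write a simulated cohort to files
#'
#' Runs [simulateCohort()] and writes its outputs: PennCNV-style calls
#' (\code{calls.rawcnv}), pedigrees (\code{families.ped}), QC metrics
#' (\code{qc_metrics.tsv}), control and DGV-style tables
#' (\code{controls.tsv}, \code{dgv.tsv}), the planted-variant truth log
#' (\code{truth.tsv}) and the run configuration (\code{config.yaml}).
#' Byte-identical across runs with the same seed and configuration.
#'
#' @param config A [simulationConfig()].
#' @param dir Output directory (created if needed).
#' @param seed Integer RNG seed.
#' @return Invisibly, the list of written paths plus the in-memory cohort.
#' @export
emitCohort <- function(config = simulationConfig(), dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulateCohort(config, seed)
  paths <- list(
    calls = file.path(dir, "calls.rawcnv"),
    ped = file.path(dir, "families.ped"),
    qc = file.path(dir, "qc_metrics.tsv"),
    controls = file.path(dir, "controls.tsv"),
    dgv = file.path(dir, "dgv.tsv"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "config.yaml"))
  writePennCNV(sim$callset, paths$calls)
  writePed(sim$peds, paths$ped)
  utils::write.table(sim$qcMetrics, paths$qc, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writePopulationTable(sim$controls, paths$controls)
  writePopulationTable(sim$dgv, paths$dgv)
  utils::write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeRunConfig(sim$runConfig, paths$config)
  invisible(c(paths, list(cohort = sim)))
}
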