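# PED pedigree file reader/writer (pre-makeped 6-column dialect, with an
# optional 7th column for DNA availability).

#' Read a PED pedigree file
#'
#' Whitespace-delimited, one individual per line: family id, individual id,
#' father id, mother id, sex (1 = male, 2 = female, 0 = unknown), phenotype
#' (2 = affected, 1 = unaffected, 0 or -9 = unknown). A 7th column, when
#' present, carries DNA availability (1/0). Parent identifier "0" marks a
#' founder. A parent id absent from the file is a structural error, as is a
#' duplicated individual.
#'
#' @param path Path to the PED file.
#' @return A named list of \linkS4class{Pedigree} objects, one per family.
#' @export
readPed <- function(path) {
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           comment.char = "#")
  if (ncol(raw) < 6L) stop("PED file needs at least 6 columns")
  names(raw)[1:6] <- c("family", "id", "father", "mother", "sex", "phen")
  dna <- if (ncol(raw) >= 7L) raw[[7L]] == "1" else rep(FALSE, nrow(raw))
  sex <- c(`1` = "M", `2` = "F")[raw$sex]
  sex[is.na(sex)] <- "U"
  aff <- rep("unknown", nrow(raw))
  aff[raw$phen == "2"] <- "affected"
  aff[raw$phen == "1"] <- "unaffected"
  out <- list()
  for (fid in unique(raw$family)) {
    sel <- raw$family == fid
    m <- data.frame(id = raw$id[sel], father = raw$father[sel],
                    mother = raw$mother[sel], sex = sex[sel],
                    affection = aff[sel], dna = dna[sel],
                    stringsAsFactors = FALSE)
    if (anyDuplicated(m$id))
      stop("family ", fid, ": individual listed twice: ",
           paste(unique(m$id[duplicated(m$id)]), collapse = ", "))
    known <- c(m$id, "0", "")
    badp <- (!(m$father %in% known)) | (!(m$mother %in% known))
    if (any(badp))
      stop("family ", fid, ": parent id not present in file for individual(s): ",
           paste(m$id[badp], collapse = ", "))
    out[[fid]] <- Pedigree(fid, m, checkExtended = FALSE)
  }
  out
}

#' Write pedigrees to a PED file
#'
#' Inverse of [readPed()]; emits the 6 standard columns plus the DNA
#' availability column.
#'
#' @param peds A \linkS4class{Pedigree} or a list of them.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writePed <- function(peds, path) {
  if (is(peds, "Pedigree")) peds <- list(peds)
  rows <- lapply(peds, function(ped) {
    m <- members(ped)
    data.frame(family = familyId(ped), id = m$id,
               father = ifelse(is.na(m$father), "0", m$father),
               mother = ifelse(is.na(m$mother), "0", m$mother),
               sex = c(M = "1", F = "2", U = "0")[m$sex],
               phen = c(affected = "2", unaffected = "1",
                        unknown = "0")[m$affection],
               dna = ifelse(m$dna, "1", "0"), stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
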