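# Reader/writer for PennCNV-style one-call-per-line text output.

#' Read PennCNV-style CNV calls
#'
#' Parses the tool's standard text output: one call per line with a region
#' token \code{chr<k>:<start>-<end>}, a \code{numsnp=<n>} token, a
#' \code{state<s>,cn=<c>} token and a sample identifier token. Parsing is
#' token-based, so column order differences between tool versions are
#' tolerated; unrecognized \code{key=value} tokens (\code{startsnp=},
#' \code{endsnp=}, \code{conf=}, ...) are ignored. The first bare token that
#' is neither the region nor \code{key=value}-shaped is taken as the sample
#' identifier.
#'
#' Any \code{length=} token is recomputed from the boundaries, never
#' trusted; thousands separators are ignored and a discrepancy greater than
#' 1 bp raises a warning. A malformed region token or a missing required
#' token is a parse error reporting the line number; \code{cn=2} (the
#' diploid state) is a rejected-record error.
#'
#' @param path Path to the call file.
#' @return A \linkS4class{CNVCallSet} (empty for an empty file).
#' @export
readPennCNV <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(CNVCallSet())
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    region <- grep("^(chr)?[0-9XYMTxymt]+:[0-9]+-[0-9]+$", tok, value = TRUE)
    if (length(region) != 1L)
      stop("line ", i, ": malformed or missing region token")
    mm <- regmatches(region,
                     regexec("^(chr)?([0-9XYMTxymt]+):([0-9]+)-([0-9]+)$",
                             region))[[1L]]
    chrom <- mm[3L]; start <- as.numeric(mm[4L]); end <- as.numeric(mm[5L])
    kv <- tok[grepl("=", tok, fixed = TRUE)]
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    getv <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
    numsnp <- getv("numsnp")
    if (is.na(numsnp))
      stop("line ", i, ": missing numsnp token")
    statecn <- grep("^state[0-9]+,cn=[0-9]+$", tok, value = TRUE)
    if (length(statecn) == 1L) {
      cn <- as.integer(sub("^state[0-9]+,cn=", "", statecn))
    } else if (!is.na(getv("cn"))) {
      cn <- as.integer(getv("cn"))
    } else stop("line ", i, ": missing state/cn token")
    if (is.na(cn)) stop("line ", i, ": unparseable copy number")
    if (cn == 2L)
      stop("line ", i, ": rejected record with cn=2 (diploid state)")
    sample <- tok[!grepl("=", tok, fixed = TRUE) & tok != region]
    if (length(sample) < 1L)
      stop("line ", i, ": missing sample identifier token")
    lenTok <- getv("length")
    if (!is.na(lenTok)) {
      given <- as.numeric(gsub(",", "", lenTok, fixed = TRUE))
      if (is.finite(given) && abs(given - (end - start)) > 1)
        warning("line ", i, ": length token ", lenTok,
                " disagrees with boundaries (", end - start, " bp)")
    }
    rows[[i]] <- data.frame(sample_id = sample[1L], chrom = chrom,
                            start = start, end = end, copy_number = cn,
                            num_snps = as.integer(numsnp),
                            source = NA_character_, stringsAsFactors = FALSE)
  }
  CNVCallSet(do.call(rbind, rows))
}

#' Write CNV calls in PennCNV-style text format
#'
#' Inverse of [readPennCNV()]: emits the region, \code{numsnp=},
#' \code{length=} (with thousands separators), \code{state<s>,cn=} and
#' sample identifier tokens. The state number follows the caller's
#' convention for the four non-diploid copy numbers (0, 1, 3, 4 map to
#' states 1, 2, 5, 6).
#'
#' @param callset A \linkS4class{CNVCallSet}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writePennCNV <- function(callset, path) {
  x <- cnvCalls(callset)
  stateOf <- c(`0` = 1L, `1` = 2L, `3` = 5L, `4` = 6L)
  lines <- sprintf("chr%s:%d-%d numsnp=%d length=%s state%d,cn=%d %s",
                   x$chrom, as.integer(x$start), as.integer(x$end),
                   x$num_snps,
                   formatC(x$end - x$start, format = "d", big.mark = ","),
                   stateOf[as.character(x$copy_number)], x$copy_number,
                   x$sample_id)
  writeLines(lines, path)
  invisible(path)
}
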