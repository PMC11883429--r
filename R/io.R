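## FASTQ I/O thin wrappers (Biostrings does the format work).

#' Write a simulated read-pair set as FASTQ
#'
#' @param sim result of [simulateAmpliconReadPairs()] or
#'   [simulateBisulfiteReads()], or any list with `r1`/`r2`
#'   [Biostrings::QualityScaledDNAStringSet] elements.
#' @param r1Path,r2Path output FASTQ paths (`.gz` for compressed output).
#' @return invisibly, the two paths.
#' @export
writeFastqPair <- function(sim, r1Path, r2Path) {
  Biostrings::writeQualityScaledXStringSet(
    sim$r1, r1Path, compress = grepl("\\.gz$", r1Path))
  Biostrings::writeQualityScaledXStringSet(
    sim$r2, r2Path, compress = grepl("\\.gz$", r2Path))
  invisible(c(r1Path, r2Path))
}

#' Read a FASTQ read pair into quality-scaled string sets
#'
#' @param r1Path,r2Path FASTQ paths (optionally gzipped).
#' @return list with `r1`, `r2` [Biostrings::QualityScaledDNAStringSet].
#' @export
readFastqPair <- function(r1Path, r2Path) {
  ## Biostrings warns that FASTQ metadata columns are dropped; none exist
  rd <- function(p) suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(p))
  list(r1 = rd(r1Path), r2 = rd(r2Path))
}

#' Write a simulation truth table as TSV
#'
#' @param sim a simulation result with a `truth` data.frame.
#' @param path output TSV path.
#' @export
writeTruthTable <- function(sim, path) {
  write.table(sim$truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
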