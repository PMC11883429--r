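## Shared fixtures, built once per test run.

refAmplicon <- syntheticAmplicon()

## a small genome (10 x 2100 bp windows) for fast methylome unit tests
testGenome <- function(copyFactor = 1, cpgMethRate = 0.8,
                       conversionFailureRate = 0.02, seed = 3L) {
  syntheticGenome(nWindows = 10L, windowWidth = 2100L, targetIndex = 5L,
                  copyFactor = copyFactor, cpgMethRate = cpgMethRate,
                  conversionFailureRate = conversionFailureRate,
                  cpgSpacing = 150L, seed = seed)
}

## quality-scaled read set from plain strings at a constant phred
qsReads <- function(seqs, phred = 35L) {
  q <- Biostrings::PhredQuality(
    vapply(nchar(seqs), function(w) strrep(intToUtf8(phred + 33L), w),
           character(1)))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs), q)
  names(x) <- sprintf("pair%06d", seq_along(seqs))
  x
}

revcompChr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
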