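## Central S4 containers. Coordinates on the amplicon are 0-based half-open
## throughout ([start, end)); cut sites are between-base indices. Methylome
## containers use 1-based GRanges as usual for Bioconductor.

#' Amplicon reference with guide geometry
#'
#' Coordinate model of a PCR amplicon: the primer-delimited sequence plus,
#' for each guide, the located protospacer/PAM, the strand, the blunt cut
#' site (a between-base index 3 bp 5' of the PAM on the protospacer strand)
#' and the +/-5 bp indel-detection window around it.
#'
#' @slot name amplicon label.
#' @slot sequence [Biostrings::DNAString] of the primer-delimited amplicon.
#' @slot primerFwd,primerRev primer sequences (reverse primer as given,
#'   i.e. reverse-complement of the amplicon 3' end).
#' @slot guideSites `data.frame` with one row per guide, sorted by cut site:
#'   `name`, `strand`, `protoStart`, `protoEnd`, `pamStart`, `pamEnd`,
#'   `cut`, `winStart`, `winEnd` (all 0-based half-open; `cut` between-base).
#'
#' @seealso [buildReference()], [locateGuide()], [syntheticAmplicon()]
#' @export
setClass("AmpliconReference",
  representation(
    name = "character",
    sequence = "DNAString",
    primerFwd = "character",
    primerRev = "character",
    guideSites = "data.frame"
  )
)

setValidity("AmpliconReference", function(object) {
  gs <- object@guideSites
  msg <- character()
  need <- c("name", "strand", "protoStart", "protoEnd", "pamStart",
            "pamEnd", "cut", "winStart", "winEnd")
  if (!all(need %in% names(gs)))
    msg <- c(msg, "guideSites lacks required columns")
  else {
    L <- length(object@sequence)
    if (nrow(gs) && any(gs$winStart < 0 | gs$winEnd > L))
      msg <- c(msg, "guide window outside amplicon bounds")
    if (nrow(gs) && is.unsorted(gs$cut))
      msg <- c(msg, "guideSites must be sorted by cut site")
    if (nrow(gs) && any(gs$winEnd - gs$winStart != 10L))
      msg <- c(msg, "guide windows must span 10 between-base positions")
  }
  if (length(msg)) msg else TRUE
})

#' Multi-window genome model for bisulfite simulation and mapping
#'
#' A small synthetic genome organised as fixed-width windows, one of which
#' (the target) is sampled with `copyFactor`-fold density to emulate
#' extrachromosomal amplification of a locus.
#'
#' @slot contigs [Biostrings::DNAStringSet] of contig sequences.
#' @slot windowWidth tiling width in bp (default 21000).
#' @slot targetWindow [GenomicRanges::GRanges] of length 1, grid-aligned.
#' @slot copyFactor read-sampling density multiplier for the target
#'   window (>= 1; 1 = uniform genome).
#' @slot cpgMethRate per-CpG methylation probability.
#' @slot conversionFailureRate probability that an unmethylated cytosine
#'   escapes bisulfite conversion.
#' @slot name model label.
#'
#' @seealso [syntheticGenome()], [simulateBisulfiteReads()]
#' @export
setClass("GenomeModel",
  representation(
    contigs = "DNAStringSet",
    windowWidth = "integer",
    targetWindow = "GRanges",
    copyFactor = "numeric",
    cpgMethRate = "numeric",
    conversionFailureRate = "numeric",
    name = "character"
  )
)

setValidity("GenomeModel", function(object) {
  msg <- character()
  if (object@copyFactor < 1)
    msg <- c(msg, "copyFactor must be >= 1")
  if (object@cpgMethRate < 0 || object@cpgMethRate > 1)
    msg <- c(msg, "cpgMethRate must be in [0,1]")
  if (object@conversionFailureRate < 0 || object@conversionFailureRate >= 0.5)
    msg <- c(msg, "conversionFailureRate must be in [0, 0.5)")
  if (length(object@targetWindow) != 1L)
    msg <- c(msg, "targetWindow must be a single range")
  else {
    st <- GenomicRanges::start(object@targetWindow)
    if ((st - 1L) %% object@windowWidth != 0L)
      msg <- c(msg, "targetWindow must be aligned to the window grid")
  }
  if (length(msg)) msg else TRUE
})

#' Per-sample variant-category profile
#'
#' Summary of one sample's classified read pairs: category proportions,
#' reference conformity (proportion of category I), the binomial margin of
#' error at the sample's read depth, the Shannon entropy of the category
#' spectrum, and the inclusion QC gates (>150 on-target pairs, margin of
#' error < 5%).
#'
#' @seealso [summarizeSample()], [conformity()], [entropyBits()]
#' @export
setClass("SampleVariantProfile",
  representation(
    label = "character",
    nPairsTotal = "integer",
    nPairsOnTarget = "integer",
    proportions = "numeric",
    conformity = "numeric",
    epsilon = "numeric",
    entropyBits = "numeric",
    z = "numeric",
    qcPass = "logical",
    qcReasons = "character"
  )
)

#' Per-sample methylome window summary
#'
#' Totals and QC for one bisulfite sample: CpG-call count, conversion
#' efficiency (converted fraction of non-CpG cytosine calls), duplicate
#' read-pair fraction, the target-window CpG-call proportion (and the
#' read-level fraction), window call counts, QC gates (conversion > 97%,
#' > 10,000 CG calls, <= 1% duplicates) and, once [callAmplification()] has
#' been applied, the amplified/baseline call.
#'
#' @seealso [summarizeMethylome()], [callAmplification()]
#' @export
setClass("MethylomeSummary",
  representation(
    label = "character",
    nPairs = "integer",
    nPairsMapped = "integer",
    totalCgCalls = "integer",
    totalNonCpgCalls = "integer",
    conversionEfficiency = "numeric",
    duplicateFraction = "numeric",
    targetProportion = "numeric",
    targetReadFraction = "numeric",
    windowCounts = "integer",
    qcPass = "logical",
    qcReasons = "character",
    amplificationCall = "character"
  )
)

#' Cohort-level report
#'
#' Aggregation of per-sample profiles from one pipeline arm, with group
#' labels, rank-sum group comparisons, the excluded samples and their QC
#' reasons, and run provenance (config hash, seed).
#'
#' @seealso [runAmpliconArm()], [runMethylomeArm()], [writeCohortReport()]
#' @export
setClass("CohortReport",
  representation(
    arm = "character",
    samples = "data.frame",
    profiles = "list",
    comparisons = "data.frame",
    excluded = "data.frame",
    provenance = "list"
  )
)
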