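## Bisulfite arm: synthetic multi-window genome, PBAT-style read simulation,
## three-letter mapping, CpG methylation calling, fixed-width window tiling
## and the target-window call-proportion statistic with QC gates.

#' Construct a synthetic multi-window genome model
#'
#' One contig of `nWindows * windowWidth` bp in which CpG dinucleotides are
#' placed on a regular grid (equal CpG count per window, so that CpG-call
#' proportions track read-sampling density), all other accidental CpGs
#' having been removed. One grid-aligned window is designated the target
#' and is sampled with `copyFactor`-fold density by
#' [simulateBisulfiteReads()].
#'
#' @param nWindows number of windows (default 10).
#' @param windowWidth window width in bp (default 21000).
#' @param targetIndex 1-based index of the target window.
#' @param copyFactor sampling-density multiplier for the target (>= 1).
#' @param cpgMethRate per-CpG methylation probability.
#' @param conversionFailureRate probability an unmethylated cytosine is
#'   read as unconverted.
#' @param cpgSpacing CpG grid spacing in bp (default 150).
#' @param seed integer seed for the background sequence.
#' @return a [GenomeModel-class].
#' @export
syntheticGenome <- function(nWindows = 10L, windowWidth = 21000L,
                            targetIndex = 5L, copyFactor = 1,
                            cpgMethRate = 0.8,
                            conversionFailureRate = 0.02,
                            cpgSpacing = 150L, seed = 1L) {
  stopifnot(nWindows >= 2L, targetIndex >= 1L, targetIndex <= nWindows)
  L <- nWindows * windowWidth
  s <- withr::with_seed(seed,
    sample(c("A", "C", "G", "T"), L, replace = TRUE),
    .rng_kind = "Mersenne-Twister", .rng_normal_kind = "Inversion",
    .rng_sample_kind = "Rejection")
  ## strip accidental CpGs (G after C -> A; one pass suffices)
  bad <- which(s[-L] == "C" & s[-1L] == "G")
  if (length(bad)) s[bad + 1L] <- "A"
  ## regular CpG grid, identical count per window
  nPer <- (windowWidth - cpgSpacing) %/% cpgSpacing + 1L
  for (w in seq_len(nWindows) - 1L) {
    pos <- w * windowWidth + (cpgSpacing %/% 2L) +
      (seq_len(nPer) - 1L) * cpgSpacing + 1L          # 1-based C position
    s[pos] <- "C"
    s[pos + 1L] <- "G"
  }
  contigs <- Biostrings::DNAStringSet(paste(s, collapse = ""))
  names(contigs) <- "chr_sim"
  tw <- GenomicRanges::GRanges(
    "chr_sim",
    IRanges::IRanges(start = (targetIndex - 1L) * windowWidth + 1L,
                     width = windowWidth),
    seqlengths = c(chr_sim = L))
  new("GenomeModel", contigs = contigs, windowWidth = as.integer(windowWidth),
      targetWindow = tw, copyFactor = copyFactor,
      cpgMethRate = cpgMethRate,
      conversionFailureRate = conversionFailureRate,
      name = sprintf("synthetic_%dx%dbp", nWindows, windowWidth))
}

#' Tile a genome model into fixed-width windows
#'
#' Windows tile each contig left to right at the model's window width; the
#' last window of a contig may be short.
#'
#' @param genome a [GenomeModel-class].
#' @return [GenomicRanges::GRanges] of windows, in genome order.
#' @export
tileWindows <- function(genome) {
  sl <- setNames(Biostrings::width(genome@contigs), names(genome@contigs))
  GenomicRanges::tileGenome(sl, tilewidth = genome@windowWidth,
                            cut.last.tile.in.chrom = TRUE)
}

#' Simulate PBAT-style bisulfite read pairs
#'
#' Fragments are sampled window-weighted (the target window with
#' `copyFactor`-fold weight, all others uniformly) and entirely within one
#' window; each fragment is bisulfite-converted on the original top strand
#' (CpG cytosines stay C with probability
#' `cpgMethRate + (1 - cpgMethRate) * conversionFailureRate`, other
#' cytosines with probability `conversionFailureRate`, else C becomes T).
#' R1 is the fragment's first `readLen` bases; R2 the reverse complement of
#' its last `readLen` bases. Optionally a fraction of pairs is replaced by
#' exact duplicates of other pairs. Deterministic given `seed`.
#'
#' @param genome a [GenomeModel-class].
#' @param nPairs number of read pairs.
#' @param readLen read length (default 151).
#' @param fragLen mean fragment length (default 320; must be >= `readLen`
#'   and <= the window width).
#' @param fragJitter half-range of the uniform fragment-length variation
#'   (default 30 bp; clamped so fragments stay in
#'   `[readLen, windowWidth]`).
#' @param duplicateRate fraction of pairs replaced by exact duplicates.
#' @param seed integer seed.
#' @return list with `r1`, `r2` ([Biostrings::QualityScaledDNAStringSet]),
#'   `truth` (`pairId`, `window`, `start`, `inTarget`, `duplicateOf`),
#'   `seed`.
#' @export
simulateBisulfiteReads <- function(genome, nPairs, readLen = 151L,
                                   fragLen = 320L, fragJitter = 30L,
                                   duplicateRate = 0, seed = 1L) {
  stopifnot(nPairs >= 1L, fragLen >= readLen,
            fragLen <= genome@windowWidth, fragJitter >= 0L)
  if (genome@copyFactor < 1) stop("copyFactor must be >= 1")
  win <- tileWindows(genome)
  win <- win[GenomicRanges::width(win) >= fragLen]
  wts <- rep(1, length(win))
  hit <- IRanges::overlapsAny(win, genome@targetWindow, type = "equal")
  wts[hit] <- genome@copyFactor
  contig <- genome@contigs[[1L]]
  chars <- strsplit(as.character(contig), "", fixed = TRUE)[[1L]]
  L <- length(chars)
  isC <- chars == "C"
  isCpG <- isC & c(chars[-1L] == "G", FALSE)
  m <- genome@cpgMethRate
  f <- genome@conversionFailureRate
  loJ <- max(readLen, fragLen - fragJitter)
  hiJ <- min(genome@windowWidth, fragLen + fragJitter)
  withr::with_seed(seed, {
    wIdx <- sample.int(length(win), nPairs, replace = TRUE, prob = wts)
    flen <- loJ + floor(runif(nPairs) * (hiJ - loJ + 1L))
    starts <- GenomicRanges::start(win)[wIdx] +
      floor(runif(nPairs) *
              (GenomicRanges::width(win)[wIdx] - flen + 1L))
    r1 <- character(nPairs); r2 <- character(nPairs)
    for (i in seq_len(nPairs)) {
      p <- starts[i]
      pos <- p:(p + flen[i] - 1L)
      frag <- chars[pos]
      cOff <- which(isC[pos])
      if (length(cOff)) {
        ctx <- isCpG[pos[cOff]]
        u <- runif(length(cOff))
        keep <- ifelse(ctx, u < m + (1 - m) * f, u < f)
        frag[cOff[!keep]] <- "T"
      }
      r1[i] <- paste(frag[seq_len(readLen)], collapse = "")
      r2[i] <- paste(rev(c(A = "T", C = "G", G = "C", T = "A")[
        frag[(flen[i] - readLen + 1L):flen[i]]]), collapse = "")
    }
    duplicateOf <- rep(NA_integer_, nPairs)
    if (duplicateRate > 0 && nPairs > 1L) {
      nd <- round(duplicateRate * nPairs)
      if (nd > 0L) {
        tgt <- sample(2:nPairs, min(nd, nPairs - 1L))
        for (i in tgt) {
          src <- sample.int(i - 1L, 1L)
          r1[i] <- r1[src]; r2[i] <- r2[src]
          starts[i] <- starts[src]; wIdx[i] <- wIdx[src]
          duplicateOf[i] <- src
        }
      }
    }
  }, .rng_kind = "Mersenne-Twister", .rng_normal_kind = "Inversion",
     .rng_sample_kind = "Rejection")
  ids <- sprintf("frag%06d", seq_len(nPairs))
  mk <- function(s) {
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(s),
      Biostrings::PhredQuality(.qualString(nchar(s), "constant", 35L)))
    names(x) <- ids
    x
  }
  list(r1 = mk(r1), r2 = mk(r2),
       truth = data.frame(pairId = ids, window = wIdx, start = starts,
                          inTarget = hit[wIdx], duplicateOf = duplicateOf,
                          stringsAsFactors = FALSE),
       seed = seed)
}

.collapseCT <- function(x) chartr("C", "T", x)

#' Map bisulfite reads in three-letter space
#'
#' Each read is C-to-T collapsed in both its as-is and reverse-complement
#' orientation and matched exactly against the C-to-T-collapsed genome
#' (both strands). Exactly one hit over all orientation/strand
#' combinations is required; anything else is unmapped.
#'
#' @param reads character vector, [Biostrings::DNAStringSet] or
#'   [Biostrings::QualityScaledDNAStringSet].
#' @param genome a [GenomeModel-class].
#' @return `data.frame` with one row per read: `mapped`, `contig`,
#'   `strand` (`+` = top, `-` = bottom genomic strand), `orientation`
#'   (`"as-is"` or `"revcomp"`: which orientation of the read aligns to
#'   that strand), `strandStart0` (0-based start in strand space) and
#'   `fwdStart0` (0-based start on the forward contig).
#' @export
bisulfiteMap <- function(reads, genome) {
  seqs <- as.character(reads)
  n <- length(seqs)
  contigNames <- names(genome@contigs)
  lens <- Biostrings::width(genome@contigs)
  fwd <- .collapseCT(as.character(genome@contigs))
  rev <- .collapseCT(as.character(
    Biostrings::reverseComplement(genome@contigs)))
  subjects <- Biostrings::DNAStringSet(c(fwd, rev))
  subStrand <- rep(c("+", "-"), each = length(contigNames))
  subContig <- rep(contigNames, 2L)
  subLen <- rep(lens, 2L)
  collA <- .collapseCT(seqs)
  collB <- .collapseCT(as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs))))
  out <- data.frame(mapped = logical(n), contig = NA_character_,
                    strand = NA_character_, orientation = NA_character_,
                    strandStart0 = NA_integer_, fwdStart0 = NA_integer_,
                    stringsAsFactors = FALSE)
  widths <- nchar(seqs)
  for (w in unique(widths)) {
    sel <- which(widths == w)
    if (w < 1L) next
    hits <- matrix(0L, nrow = length(sel), ncol = 0)
    firsts <- matrix(NA_integer_, nrow = length(sel), ncol = 0)
    combo <- list()
    for (orient in c("as-is", "revcomp")) {
      pats <- if (orient == "as-is") collA[sel] else collB[sel]
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(pats))
      for (sj in seq_along(subjects)) {
        mi <- Biostrings::matchPDict(pd, subjects[[sj]])
        sidx <- Biostrings::startIndex(mi)
        cnt <- S4Vectors::elementNROWS(sidx)
        first <- rep(NA_integer_, length(sel))
        has <- cnt > 0L
        if (any(has))
          first[has] <- vapply(sidx[has], `[`, integer(1), 1L)
        hits <- cbind(hits, cnt)
        firsts <- cbind(firsts, first)
        combo[[length(combo) + 1L]] <- list(orient = orient, sj = sj)
      }
    }
    uniq <- which(rowSums(hits) == 1L)
    if (!length(uniq)) next
    col <- max.col(hits[uniq, , drop = FALSE] > 0L, ties.method = "first")
    sj <- vapply(combo, `[[`, integer(1), "sj")[col]
    st0 <- firsts[cbind(uniq, col)] - 1L
    ridx <- sel[uniq]
    out$mapped[ridx] <- TRUE
    out$contig[ridx] <- subContig[sj]
    out$strand[ridx] <- subStrand[sj]
    out$orientation[ridx] <-
      vapply(combo, `[[`, character(1), "orient")[col]
    out$strandStart0[ridx] <- st0
    out$fwdStart0[ridx] <- ifelse(subStrand[sj] == "+", st0,
                                  subLen[sj] - st0 - w)
  }
  out
}

#' Call CpG and non-CpG methylation states under mapped reads
#'
#' For every reference cytosine (on the mapped strand) covered by a read:
#' a read base C is called methylated, T unmethylated, anything else is
#' skipped. Context (CpG vs non-CpG) comes from the reference dinucleotide
#' on the mapped strand.
#'
#' @param reads the reads passed to [bisulfiteMap()].
#' @param mapping the `data.frame` returned by [bisulfiteMap()].
#' @param genome a [GenomeModel-class].
#' @return [GenomicRanges::GRanges] of single-base calls (position of the
#'   cytosine on the forward contig, 1-based) with metadata `context`
#'   (`"CpG"`/`"nonCpG"`) and `state` (`"methylated"`/`"unmethylated"`).
#' @export
callMethylation <- function(reads, mapping, genome) {
  seqs <- as.character(reads)
  contigNames <- names(genome@contigs)
  lens <- setNames(Biostrings::width(genome@contigs), contigNames)
  ## sorted C positions (1-based) and their CpG context, per contig/strand
  cinfo <- list()
  for (cn in contigNames) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") as.character(genome@contigs[[cn]])
      else as.character(Biostrings::reverseComplement(genome@contigs[[cn]]))
      ch <- strsplit(s, "", fixed = TRUE)[[1L]]
      cpos <- which(ch == "C")
      isCpG <- cpos < length(ch) & ch[pmin(cpos + 1L, length(ch))] == "G"
      cinfo[[paste0(cn, strand)]] <- list(cpos = cpos, isCpG = isCpG)
    }
  }
  mappedIdx <- which(mapping$mapped)
  aligned <- seqs[mappedIdx]
  needRc <- mapping$orientation[mappedIdx] == "revcomp"
  if (any(needRc))
    aligned[needRc] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(aligned[needRc])))
  posV <- integer(); ctxV <- logical(); baseV <- character()
  cgV <- character(); strV <- character()
  key <- paste0(mapping$contig[mappedIdx], mapping$strand[mappedIdx])
  for (grp in unique(key)) {
    gi <- which(key == grp)
    ci <- cinfo[[grp]]
    p0 <- mapping$strandStart0[mappedIdx[gi]]
    w <- nchar(aligned[gi])
    lo <- findInterval(p0, ci$cpos) + 1L      # first C with pos > p0
    hi <- findInterval(p0 + w, ci$cpos)       # last C with pos <= p0 + w
    k <- pmax(hi - lo + 1L, 0L)
    if (!sum(k)) next
    cIdx <- sequence(k) + rep(lo - 1L, k)
    rrep <- rep(gi, k)
    sPos <- ci$cpos[cIdx]
    off <- sPos - rep(p0, k)                  # 1-based offset in read
    base <- substring(aligned[rrep], off, off)
    use <- base %in% c("C", "T")
    if (!any(use)) next
    cn <- mapping$contig[mappedIdx[gi[1L]]]
    strand <- mapping$strand[mappedIdx[gi[1L]]]
    L <- lens[[cn]]
    sP <- sPos[use]
    posV <- c(posV, if (strand == "+") sP else L - sP + 1L)
    ctxV <- c(ctxV, ci$isCpG[cIdx[use]])
    baseV <- c(baseV, base[use])
    cgV <- c(cgV, rep(cn, sum(use)))
    strV <- c(strV, rep(strand, sum(use)))
  }
  if (!length(posV)) {
    gr <- GenomicRanges::GRanges(seqlengths = lens)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(context = character(),
                                                 state = character())
    return(gr)
  }
  GenomicRanges::GRanges(
    cgV, IRanges::IRanges(start = posV, width = 1L), strand = strV,
    context = ifelse(ctxV, "CpG", "nonCpG"),
    state = ifelse(baseV == "C", "methylated", "unmethylated"),
    seqlengths = lens)
}

#' CpG-call counts per window
#'
#' @param calls [GenomicRanges::GRanges] from [callMethylation()].
#' @param windows [GenomicRanges::GRanges] from [tileWindows()].
#' @param context which context to count (default `"CpG"`).
#' @return integer vector, one count per window; sums to the number of
#'   calls in that context.
#' @export
windowCounts <- function(calls, windows, context = "CpG") {
  keep <- calls[S4Vectors::mcols(calls)$context == context]
  GenomicRanges::countOverlaps(windows, keep, ignore.strand = TRUE)
}

#' Target-window CpG-call proportion
#'
#' CpG calls (methylated and unmethylated both count) falling in the
#' target window divided by all CpG calls.
#'
#' @param calls [GenomicRanges::GRanges] from [callMethylation()].
#' @param target the target window ([GenomicRanges::GRanges] of length 1).
#' @return fraction in `[0, 1]`.
#' @export
windowProportion <- function(calls, target) {
  cg <- calls[S4Vectors::mcols(calls)$context == "CpG"]
  if (!length(cg)) stop("zero CpG calls: proportion undefined")
  sum(IRanges::overlapsAny(cg, target, ignore.strand = TRUE)) / length(cg)
}

#' Summarize a bisulfite sample
#'
#' Maps both mates, calls methylation, computes the conversion efficiency
#' (converted fraction of non-CpG cytosine calls), the duplicate read-pair
#' fraction (identical R1+R2 pairs), window call counts and the
#' target-window CpG-call proportion, and applies the QC gates: conversion
#' efficiency > 97%, more than 10,000 CG calls, and at most 1% duplicate
#' pairs (all strict, as printed).
#'
#' @param sim a list with `r1`/`r2` reads (e.g. from
#'   [simulateBisulfiteReads()]), or FASTQ paths via [readFastqPair()].
#' @param genome a [GenomeModel-class].
#' @param label sample label.
#' @param minConversion,minCgCalls,maxDuplicates QC gates.
#' @return a [MethylomeSummary-class].
#' @export
summarizeMethylome <- function(sim, genome, label = "sample",
                               minConversion = 0.97, minCgCalls = 10000L,
                               maxDuplicates = 0.01) {
  r1 <- as.character(sim$r1); r2 <- as.character(sim$r2)
  n <- length(r1)
  stopifnot(length(r2) == n)
  dupFrac <- if (n) 1 - length(unique(paste(r1, r2))) / n else 0
  reads <- c(r1, r2)
  mapping <- bisulfiteMap(reads, genome)
  calls <- callMethylation(reads, mapping, genome)
  ctx <- S4Vectors::mcols(calls)$context
  st <- S4Vectors::mcols(calls)$state
  nCg <- sum(ctx == "CpG")
  nNon <- sum(ctx == "nonCpG")
  conv <- if (nNon) sum(ctx == "nonCpG" & st == "unmethylated") / nNon
          else NA_real_
  win <- tileWindows(genome)
  wc <- windowCounts(calls, win)
  tgtProp <- if (nCg) windowProportion(calls, genome@targetWindow)
             else NA_real_
  mappedPair <- mapping$mapped[seq_len(n)] | mapping$mapped[n + seq_len(n)]
  mIdx <- which(mapping$mapped)
  tgtRead <- if (length(mIdx)) {
    gr <- GenomicRanges::GRanges(
      mapping$contig[mIdx],
      IRanges::IRanges(start = mapping$fwdStart0[mIdx] + 1L,
                       width = nchar(reads[mIdx])))
    mean(IRanges::overlapsAny(gr, genome@targetWindow,
                              ignore.strand = TRUE))
  } else NA_real_
  reasons <- methylomeQc(conv, nCg, dupFrac, minConversion, minCgCalls,
                         maxDuplicates)
  new("MethylomeSummary", label = label, nPairs = as.integer(n),
      nPairsMapped = as.integer(sum(mappedPair)),
      totalCgCalls = as.integer(nCg),
      totalNonCpgCalls = as.integer(nNon),
      conversionEfficiency = conv, duplicateFraction = dupFrac,
      targetProportion = tgtProp, targetReadFraction = tgtRead,
      windowCounts = as.integer(wc),
      qcPass = length(reasons) == 0L,
      qcReasons = if (length(reasons)) reasons else character(),
      amplificationCall = NA_character_)
}

#' Methylome sample inclusion gates
#'
#' The three inclusion gates, strict inequalities exactly as printed:
#' conversion efficiency must exceed `minConversion` (97%), the CG-call
#' count must exceed `minCgCalls` (10,000), and samples with a duplicate
#' fraction above `maxDuplicates` (1%) are rejected. A sample sitting
#' exactly on the 97% or 10,000 boundary is excluded; one with exactly 1%
#' duplicates is kept.
#'
#' @param conversionEfficiency converted fraction of non-CpG calls.
#' @param totalCgCalls number of CpG-context calls.
#' @param duplicateFraction fraction of identical read pairs.
#' @param minConversion,minCgCalls,maxDuplicates gate values.
#' @return character vector of failure reasons (empty = pass).
#' @export
methylomeQc <- function(conversionEfficiency, totalCgCalls,
                        duplicateFraction, minConversion = 0.97,
                        minCgCalls = 10000L, maxDuplicates = 0.01) {
  reasons <- character()
  if (is.na(conversionEfficiency) || conversionEfficiency <= minConversion)
    reasons <- c(reasons, sprintf("conversion efficiency <= %g",
                                  minConversion))
  if (totalCgCalls <= minCgCalls)
    reasons <- c(reasons, sprintf("CG calls <= %d", minCgCalls))
  if (duplicateFraction > maxDuplicates)
    reasons <- c(reasons, sprintf("duplicate pairs > %g", maxDuplicates))
  reasons
}

#' @describeIn callAmplification call from a target proportion directly.
#' @export
setMethod("callAmplification", "numeric",
  function(x, baseline, foldThreshold = 3.0) {
    stopifnot(baseline > 0, foldThreshold > 0)
    if (x > foldThreshold * baseline) "amplified" else "baseline"
  })

#' @describeIn callAmplification call a QC-passing summary; a QC-failing
#'   summary gets an `NA` call (no call) with a warning.
#' @export
setMethod("callAmplification", "MethylomeSummary",
  function(x, baseline, foldThreshold = 3.0) {
    if (!x@qcPass) {
      warning("QC fail for '", x@label, "': no amplification call")
      x@amplificationCall <- NA_character_
      return(x)
    }
    x@amplificationCall <- callAmplification(x@targetProportion, baseline,
                                             foldThreshold)
    x
  })
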