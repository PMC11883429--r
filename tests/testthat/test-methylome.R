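test_that("fixed-width tiling yields the expected window grid", {
  g <- testGenome()
  win <- tileWindows(g)
  expect_equal(length(win), 10L)
  expect_equal(unique(GenomicRanges::width(win)), 2100L)
  ## a 210,000-bp contig at 21-kb width gives exactly 10 windows
  gBig <- syntheticGenome(nWindows = 10L, windowWidth = 21000L)
  expect_equal(length(tileWindows(gBig)), 10L)
  ## a trailing short window is kept
  g2 <- g
  g2@contigs <- Biostrings::DNAStringSet(
    paste0(as.character(g@contigs[[1]]), strrep("A", 500)))
  names(g2@contigs) <- "chr_sim"
  expect_equal(GenomicRanges::width(tileWindows(g2))[11], 500L)
})

test_that("every CpG-grid window carries the same CpG count", {
  g <- testGenome()
  ch <- strsplit(as.character(g@contigs[[1]]), "")[[1]]
  cpg <- which(ch == "C" & c(ch[-1], "") == "G")
  counts <- table(cut(cpg, breaks = seq(0, 21000, by = 2100)))
  expect_equal(length(unique(as.integer(counts))), 1L)
})

test_that("converted reads map back to their origin", {
  g <- testGenome(seed = 8)
  sim <- simulateBisulfiteReads(g, 40, seed = 2)
  mp <- bisulfiteMap(sim$r1, g)
  expect_true(all(mp$mapped))
  expect_equal(mp$fwdStart0, sim$truth$start - 1L)
  expect_true(all(mp$strand == "+" & mp$orientation == "as-is"))
  ## R2 mates map through their reverse complement
  mp2 <- bisulfiteMap(sim$r2, g)
  expect_true(all(mp2$mapped))
  expect_true(all(mp2$orientation == "revcomp"))
})

test_that("methylated CpGs do not break three-letter mapping", {
  g <- testGenome(cpgMethRate = 1, conversionFailureRate = 0, seed = 8)
  sim <- simulateBisulfiteReads(g, 30, seed = 4)
  expect_true(all(bisulfiteMap(sim$r1, g)$mapped))
})

test_that("reads matching a duplicated contig are ambiguous", {
  g <- testGenome(seed = 8)
  sim <- simulateBisulfiteReads(g, 20, seed = 6)
  dup <- g
  dup@contigs <- Biostrings::DNAStringSet(rep(as.character(g@contigs), 2))
  names(dup@contigs) <- c("chrA", "chrB")
  dup@targetWindow <- GenomicRanges::GRanges(
    "chrA", IRanges::IRanges(GenomicRanges::start(g@targetWindow),
                             width = g@windowWidth),
    seqlengths = setNames(rep(Biostrings::width(g@contigs), 2),
                          c("chrA", "chrB")))
  mp <- bisulfiteMap(sim$r1, dup)
  expect_false(any(mp$mapped))
})

test_that("methylation states follow the simulation parameters", {
  ## no methylation, no failures: reads carry no original-strand C and all
  ## calls are unmethylated
  g0 <- testGenome(cpgMethRate = 0, conversionFailureRate = 0, seed = 8)
  sim0 <- simulateBisulfiteReads(g0, 30, seed = 5)
  expect_false(any(grepl("C", as.character(sim0$r1))))
  calls0 <- callMethylation(sim0$r1, bisulfiteMap(sim0$r1, g0), g0)
  expect_true(all(S4Vectors::mcols(calls0)$state == "unmethylated"))
  ## full methylation, no failures: every CpG call methylated, every
  ## non-CpG call converted
  g1 <- testGenome(cpgMethRate = 1, conversionFailureRate = 0, seed = 8)
  sim1 <- simulateBisulfiteReads(g1, 30, seed = 5)
  calls1 <- callMethylation(sim1$r1, bisulfiteMap(sim1$r1, g1), g1)
  ctx <- S4Vectors::mcols(calls1)$context
  st <- S4Vectors::mcols(calls1)$state
  expect_true(all(st[ctx == "CpG"] == "methylated"))
  expect_true(all(st[ctx == "nonCpG"] == "unmethylated"))
})

test_that("bottom-strand bisulfite reads are called on the minus strand", {
  g <- testGenome(cpgMethRate = 1, conversionFailureRate = 0, seed = 8)
  seg <- as.character(Biostrings::subseq(g@contigs[[1]], 501, 651))
  ## bottom-strand original: reverse complement, then C->T convert
  ## everything except CpG cytosines (methylation keeps them)
  bot <- revcompChr(seg)
  ch <- strsplit(bot, "")[[1]]
  isC <- ch == "C"
  isCpG <- isC & c(ch[-1] == "G", FALSE)
  ch[isC & !isCpG] <- "T"
  read <- paste(ch, collapse = "")
  mp <- bisulfiteMap(read, g)
  expect_true(mp$mapped)
  expect_equal(mp$strand, "-")
  calls <- callMethylation(read, mp, g)
  expect_true(all(as.character(GenomicRanges::strand(calls)) == "-"))
  ctx <- S4Vectors::mcols(calls)$context
  expect_true(all(S4Vectors::mcols(calls)$state[ctx == "CpG"] ==
                    "methylated"))
})

test_that("window counts conserve the CpG-call total", {
  g <- testGenome(seed = 8)
  sim <- simulateBisulfiteReads(g, 200, seed = 9)
  reads <- c(as.character(sim$r1), as.character(sim$r2))
  calls <- callMethylation(reads, bisulfiteMap(reads, g), g)
  wc <- windowCounts(calls, tileWindows(g))
  expect_equal(sum(wc), sum(S4Vectors::mcols(calls)$context == "CpG"))
})

test_that("the target-window proportion tracks the sampling density", {
  ## uniform genome: ~1/10
  g1 <- testGenome(copyFactor = 1, seed = 8)
  s1 <- summarizeMethylome(simulateBisulfiteReads(g1, 2000, seed = 10), g1)
  expect_lt(abs(targetProportion(s1) - 0.1), 3 * sqrt(0.1 * 0.9 / 2000))
  ## amplified target: 50 / 59
  g50 <- testGenome(copyFactor = 50, seed = 8)
  s50 <- summarizeMethylome(simulateBisulfiteReads(g50, 2000, seed = 10),
                            g50)
  p <- 50 / 59
  expect_lt(abs(targetProportion(s50) - p), 3 * sqrt(p * (1 - p) / 2000))
})

test_that("target proportions recover the closed form across copy factors", {
  for (cf in c(1, 5, 20)) {
    g <- testGenome(copyFactor = cf, seed = 8)
    s <- summarizeMethylome(simulateBisulfiteReads(g, 1500, seed = cf), g)
    p <- cf / (cf + 9)
    expect_lt(abs(targetProportion(s) - p),
              3 * sqrt(p * (1 - p) / 1500) + 1e-9,
              label = sprintf("copyFactor %d deviation", cf))
  }
})

test_that("conversion efficiency estimates one minus the failure rate", {
  g <- testGenome(conversionFailureRate = 0.02, seed = 8)
  s <- summarizeMethylome(simulateBisulfiteReads(g, 1500, seed = 14), g)
  n <- s@totalNonCpgCalls
  expect_gt(n, 1000)
  expect_lt(abs(s@conversionEfficiency - 0.98),
            3 * sqrt(0.98 * 0.02 / n))
})

test_that("injected exact duplicates are detected", {
  g <- testGenome(seed = 8)
  sim <- simulateBisulfiteReads(g, 500, duplicateRate = 0.04, seed = 15)
  s <- summarizeMethylome(sim, g)
  expect_gte(s@duplicateFraction, 0.03)
  expect_false(s@qcPass)
  expect_match(paste(s@qcReasons, collapse = ";"), "duplicate")
})

test_that("windowProportion handles the degenerate cases", {
  g <- testGenome()
  tw <- g@targetWindow
  inT <- GenomicRanges::GRanges("chr_sim",
    IRanges::IRanges(GenomicRanges::start(tw) + c(5, 10, 20), width = 1),
    context = "CpG", state = "methylated")
  expect_equal(windowProportion(inT, tw), 1)
  noCg <- GenomicRanges::GRanges("chr_sim", IRanges::IRanges(1, width = 1),
                                 context = "nonCpG", state = "unmethylated")
  expect_error(windowProportion(noCg, tw), "zero CpG calls")
})

test_that("the QC gates are strict exactly as printed", {
  expect_length(methylomeQc(0.98, 20000L, 0), 0L)
  ## conversion efficiency of exactly 97% is excluded
  expect_match(methylomeQc(0.97, 20000L, 0), "conversion")
  expect_length(methylomeQc(0.97 + 1e-9, 20000L, 0), 0L)
  ## exactly 10,000 CG calls is excluded
  expect_match(methylomeQc(0.98, 10000L, 0), "CG calls")
  expect_length(methylomeQc(0.98, 10001L, 0), 0L)
  ## exactly 1% duplicates is kept; anything above is rejected
  expect_length(methylomeQc(0.98, 20000L, 0.01), 0L)
  expect_match(methylomeQc(0.98, 20000L, 0.0100001), "duplicate")
})

test_that("amplification calls compare against a fold threshold", {
  expect_equal(callAmplification(0.00214, 0.00214), "baseline")
  expect_equal(callAmplification(0.013, 0.00214), "amplified")   # 6.1-fold
  expect_equal(callAmplification(0.003, 0.00214), "baseline")    # 1.4-fold
  expect_equal(callAmplification(0.0065, 0.00214), "amplified")
  g <- testGenome(copyFactor = 50, seed = 8)
  s <- summarizeMethylome(simulateBisulfiteReads(g, 1500, seed = 10), g)
  s@qcPass <- TRUE; s@qcReasons <- character()
  called <- callAmplification(s, baseline = 0.1)
  expect_equal(amplificationCall(called), "amplified")
  s@qcPass <- FALSE; s@qcReasons <- "CG calls <= 10000"
  expect_warning(noCall <- callAmplification(s, baseline = 0.1), "no amplification")
  expect_true(is.na(amplificationCall(noCall)))
})
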