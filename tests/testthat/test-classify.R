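## independent oracle for the 3'-trim rule: argmax over kept lengths of the
## running sum of (threshold - q) accumulated from the 3' end
trimOracle <- function(q, threshold = 20L) {
  n <- length(q)
  s <- vapply(0:n, function(x)
    if (x == n) 0 else sum(threshold - q[(x + 1):n]), numeric(1))
  if (max(s) <= 0) return(n)
  max(which(s == max(s))) - 1L
}

qsFromInts <- function(seq, q) {
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seq),
    Biostrings::PhredQuality(intToUtf8(q + 33L, multiple = FALSE)))
}

test_that("quality trimming follows the running-sum rule", {
  ## high-quality read untouched
  r <- qsFromInts(strrep("ACGT", 10), rep(35L, 40))
  expect_equal(Biostrings::width(qualityTrim(r)), 40L)
  ## a q2 tail is removed entirely
  q <- c(rep(35L, 30), rep(2L, 10))
  r <- qsFromInts(strrep("ACGT", 10), q)
  tr <- qualityTrim(r)
  expect_equal(Biostrings::width(tr), 30L)
  expect_equal(Biostrings::width(Biostrings::quality(tr)), 30L)
  ## an all-q2 read becomes empty
  r <- qsFromInts(strrep("AC", 10), rep(2L, 20))
  expect_equal(Biostrings::width(qualityTrim(r)), 0L)
})

test_that("quality trimming matches the independent oracle on random reads", {
  withr::with_seed(11, {
    for (i in 1:40) {
      n <- sample(10:60, 1)
      q <- sample(2:40, n, replace = TRUE)
      seq <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                   collapse = "")
      got <- Biostrings::width(qualityTrim(qsFromInts(seq, q)))
      expect_equal(got, trimOracle(q), info = paste("case", i))
    }
  })
})

test_that("a perfect R1 aligns cleanly from the amplicon start", {
  refStr <- as.character(refSequence(refAmplicon))
  a <- alignRead(substr(refStr, 1, 151), refAmplicon)
  expect_true(a$mapped)
  expect_equal(a$strand, "+")
  expect_equal(c(a$refStart, a$refEnd), c(0L, 151L))
  expect_equal(a$nMismatch, 0L)
  expect_equal(nrow(a$ops), 0L)
})

test_that("a localized deletion is recovered and agrees with a full NW oracle", {
  ref <- refAmplicon
  refStr <- as.character(refSequence(ref))
  mol <- applyVariant(ref, variantSpec(list(list(type = "del", site = 1,
                                                 len = 3))))
  read <- substr(mol, 1, 151)
  a <- alignRead(read, ref)
  del <- a$ops[a$ops$op == "del", ]
  expect_equal(nrow(del), 1L)
  expect_equal(del$len, 3L)
  gs <- guideSites(ref)
  expect_true(del$refStart < gs$winEnd[1] &&
                del$refStart + del$len > gs$winStart[1])
  ## oracle: Needleman-Wunsch global alignment of the read against the
  ## reference prefix it spans
  pw <- Biostrings::pairwiseAlignment(
    read, substr(refStr, 1, a$refEnd), type = "global",
    gapOpening = 6, gapExtension = 1)
  expect_equal(unname(Biostrings::nindel(pw)@deletion[, "WidthSum"]), 3L)
  orc <- Biostrings::deletion(pw)[[1]]
  expect_equal(BiocGenerics::start(orc), del$refStart + 1L)
})

test_that("an inter-site deletion displaces the read 3' match", {
  refStr <- as.character(refSequence(refAmplicon))
  ## 120-bp deletion starting at position 60 (0-based)
  mol <- paste0(substr(refStr, 1, 60), substr(refStr, 181, 317))
  a <- alignRead(substr(mol, 1, 151), refAmplicon)
  expect_equal(a$refEnd - a$refStart, 271L)
})

test_that("off-target reads are reported as unmapped", {
  a <- alignRead(strrep("ACGT", 38), refAmplicon)
  expect_false(a$mapped)
  expect_match(a$reason, "anchor")
})

test_that("minus-strand reads map through the reverse complement", {
  refStr <- as.character(refSequence(refAmplicon))
  r2 <- revcompChr(substr(refStr, 167, 317))
  a <- alignRead(r2, refAmplicon)
  expect_true(a$mapped)
  expect_equal(a$strand, "-")
  expect_equal(c(a$refStart, a$refEnd), c(166L, 317L))
})

test_that("event detection applies the window and displacement rules", {
  ref <- refAmplicon
  refStr <- as.character(refSequence(ref))
  ## clean alignment: no events
  a <- alignRead(substr(refStr, 1, 151), ref)
  expect_equal(nrow(detectEvents(a, ref)), 0L)
  ## displacement > 151 fires the large-deletion rule
  mol <- applyVariant(ref, variantSpec(list(list(type = "span",
                                                 from = 1, to = 2))))
  a <- alignRead(substr(mol, 1, 151), ref)
  ev <- detectEvents(a, ref)
  lg <- ev[ev$kind == "large_deletion", ]
  expect_equal(nrow(lg), 1L)
  expect_false(lg$ambiguous)
  expect_setequal(lg$sites[[1]], c(1L, 2L))
  ## a 2-bp insertion 30 bp away from every window is not localized
  mol <- paste0(substr(refStr, 1, 100), "AT", substr(refStr, 101, 317))
  a <- alignRead(substr(mol, 1, 151), ref)
  expect_equal(nrow(detectEvents(a, ref)), 0L)
})

test_that("the displacement rule fires exactly when the span exceeds the read length", {
  ref <- refAmplicon
  refStr <- as.character(refSequence(ref))
  ## grid up to the widest inter-site span (190 bp); beyond that the
  ## post-junction read tail becomes too short to anchor the deletion
  for (d in seq(2L, 190L, by = 27L)) {
    mol <- paste0(substr(refStr, 1, 57), substr(refStr, 58 + d, 317))
    read <- substr(mol, 1, 151)
    a <- alignRead(read, ref)
    span <- min(nchar(read), nchar(mol)) + d    # oracle arithmetic
    ev <- detectEvents(a, ref)
    expect_equal(any(ev$kind == "large_deletion"), span > 151,
                 info = paste("d =", d))
  }
})

## event-table constructors for classifyPair tests
localEv <- function(site, net = -3) {
  out <- data.frame(kind = "local_indel", net = net, ambiguous = FALSE)
  out$sites <- list(site)
  out
}
spanEv <- function(sites, net) {
  out <- data.frame(kind = "large_deletion", net = net,
                    ambiguous = length(sites) < 2)
  out$sites <- list(sites)
  out
}

test_that("pair classification follows the precedence order", {
  ref <- refAmplicon
  ## no events on either mate -> reference
  expect_equal(classifyPair(NULL, NULL, ref)$category, "I")
  ## single local indel
  expect_equal(classifyPair(localEv(1), NULL, ref)$category, "II")
  expect_equal(classifyPair(NULL, localEv(3), ref)$category, "III")
  ## local indels on the two mates combine into the multi-site class
  expect_equal(classifyPair(localEv(1), localEv(3), ref)$category, "IV")
  ## a large deletion takes precedence over a local indel
  cl <- classifyPair(localEv(1), spanEv(c(1, 2), -99), ref)
  expect_equal(cl$category, "V")
  expect_false(cl$discordant)
  ## spans map by their outermost sites
  expect_equal(classifyPair(spanEv(c(1, 2, 3), -190), NULL, ref)$category,
               "VI")
  expect_equal(classifyPair(NULL, spanEv(c(2, 3), -91), ref)$category,
               "VII")
  ## indels at the untested middle guide do not make a category
  expect_equal(classifyPair(localEv(2), NULL, ref)$category, "I")
  ## an ambiguous span never maps to a deletion class
  expect_equal(classifyPair(spanEv(1, -8), NULL, ref)$category, "I")
})

test_that("conflicting spans are discordant and resolve to the larger lesion", {
  cl <- classifyPair(spanEv(c(1, 2), -99), spanEv(c(2, 3), -91), refAmplicon)
  expect_true(cl$discordant)
  expect_equal(cl$category, "V")
  cl <- classifyPair(spanEv(c(1, 2), -91), spanEv(c(1, 3), -190), refAmplicon)
  expect_equal(cl$category, "VI")
})

test_that("a configurable precedence order is honoured", {
  cl <- classifyPair(localEv(1), spanEv(c(1, 2), -99), refAmplicon,
                     precedence = c("multi_site", "single_site",
                                    "large_deletion"))
  expect_equal(cl$category, "II")
})

test_that("pairs survive the loss of one mate", {
  refStr <- as.character(refSequence(refAmplicon))
  mol <- applyVariant(refAmplicon, variantSpec(list(
    list(type = "del", site = 3, len = 4))))
  r1 <- qsReads(c(strrep("ACGT", 38)))                     # off-target
  r2 <- qsReads(revcompChr(substr(mol, nchar(mol) - 150, nchar(mol))))
  calls <- classifyReadPairs(r1, r2, refAmplicon)
  expect_true(calls$onTarget)
  expect_equal(calls$category, "III")
  ## both mates off-target -> excluded
  calls <- classifyReadPairs(r1, r1, refAmplicon)
  expect_false(calls$onTarget)
  expect_true(is.na(calls$category))
})

test_that("substitutions never create indel events, within tolerance", {
  refStr <- as.character(refSequence(refAmplicon))
  r1 <- substr(refStr, 1, 151)
  mutate <- function(s, pos) {
    for (p in pos) substr(s, p, p) <- c(A = "C", C = "A", G = "T",
                                        T = "G")[substr(s, p, p)]
    s
  }
  two <- mutate(r1, c(60, 90))
  four <- mutate(r1, c(60, 90, 110, 130))
  r2 <- revcompChr(substr(refStr, 167, 317))
  calls <- classifyReadPairs(qsReads(c(two, four)), qsReads(c(r2, r2)),
                             refAmplicon)
  expect_equal(calls$category[1], "I")          # within tolerance
  expect_false(calls$onTarget[2])               # > 2 mismatches, no events
})

test_that("sample summaries report conformity, margin and entropy", {
  refStr <- as.character(refSequence(refAmplicon))
  wt1 <- substr(refStr, 1, 151)
  wt2 <- revcompChr(substr(refStr, 167, 317))
  calls <- classifyReadPairs(qsReads(rep(wt1, 200)), qsReads(rep(wt2, 200)),
                             refAmplicon)
  prof <- summarizeSample(calls, refAmplicon)
  expect_equal(prof@nPairsOnTarget, 200L)
  expect_equal(conformity(prof), 1)
  expect_equal(epsilonOf(prof), 0)
  expect_equal(entropyBits(prof), 0)
  expect_true(qcPass(prof))
  expect_equal(sum(categoryProportions(prof)), 1)
})

test_that("the >150-pair gate is strict", {
  refStr <- as.character(refSequence(refAmplicon))
  wt1 <- substr(refStr, 1, 151)
  wt2 <- revcompChr(substr(refStr, 167, 317))
  at150 <- summarizeSample(
    classifyReadPairs(qsReads(rep(wt1, 150)), qsReads(rep(wt2, 150)),
                      refAmplicon), refAmplicon)
  expect_false(qcPass(at150))
  expect_match(qcReasons(at150), "150")
  at151 <- summarizeSample(
    classifyReadPairs(qsReads(rep(wt1, 151)), qsReads(rep(wt2, 151)),
                      refAmplicon), refAmplicon)
  expect_true(qcPass(at151))
})

test_that("an all-off-target sample fails QC with a reason", {
  bad <- qsReads(rep(strrep("ACGT", 38), 3))
  prof <- summarizeSample(classifyReadPairs(bad, bad, refAmplicon),
                          refAmplicon)
  expect_false(qcPass(prof))
  expect_equal(qcReasons(prof), "no on-target pairs")
})

test_that("conformity decreases as the edited fraction grows", {
  confs <- vapply(c(0, 0.3, 0.6, 1), function(edited) {
    sim <- simulateAmpliconReadPairs(
      refAmplicon, conformityMixture(refAmplicon, 1 - edited),
      nPairs = 600, seed = 21)
    conformity(summarizeSample(
      classifyReadPairs(sim$r1, sim$r2, refAmplicon), refAmplicon))
  }, numeric(1))
  expect_true(all(diff(confs) <= 0))
  expect_equal(confs[1], 1)
  expect_equal(confs[4], 0)
})
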