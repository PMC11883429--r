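## Cohort orchestration: simulate -> classify / methylome -> stats, with
## QC-based exclusion, group comparisons and JSON/TSV reports.

.cohortProvenance <- function(config, seed) {
  list(configHash = rlang::hash(config), seed = seed,
       package = as.character(utils::packageVersion("rdnaedit")))
}

#' Run the amplicon (editing-outcome) arm on a synthetic cohort
#'
#' Each sample spec is simulated (or read from FASTQ), classified and
#' summarized; samples failing the inclusion gates (>150 on-target pairs,
#' margin of error < 5%) are excluded with reasons. When at least two
#' groups have two or more passing samples, the first two groups are
#' compared by rank-sum test on conformity and on entropy.
#'
#' @param reference an [AmpliconReference-class].
#' @param samples list of sample specs: each a list with `label`, `group`
#'   and either `mixture` (+ `nPairs`) for simulation or `r1`/`r2` FASTQ
#'   paths.
#' @param nPairs default pair count for simulated samples.
#' @param subErrorRate per-base substitution error rate for simulation.
#' @param z,minPairs,maxEpsilon see [summarizeSample()].
#' @param localSites,precedence see [classifyPair()].
#' @param seed master seed; sample `i` uses `seed + i`.
#' @return a [CohortReport-class].
#' @export
runAmpliconArm <- function(reference, samples, nPairs = 1000L,
                           subErrorRate = 0, z = 2.326348,
                           minPairs = 150L, maxEpsilon = 0.05,
                           localSites = NULL,
                           precedence = .defaultPrecedence, seed = 1L) {
  profiles <- list()
  rows <- list()
  for (i in seq_along(samples)) {
    sp <- samples[[i]]
    label <- if (!is.null(sp$label)) sp$label else sprintf("sample%02d", i)
    if (!is.null(sp$mixture)) {
      np <- if (!is.null(sp$nPairs)) sp$nPairs else nPairs
      sim <- simulateAmpliconReadPairs(reference, sp$mixture, np,
                                       subErrorRate = subErrorRate,
                                       seed = seed + i,
                                       localSites = localSites)
      reads <- list(r1 = sim$r1, r2 = sim$r2)
    } else {
      reads <- readFastqPair(sp$r1, sp$r2)
    }
    calls <- classifyReadPairs(reads$r1, reads$r2, reference,
                               localSites = localSites,
                               precedence = precedence)
    prof <- summarizeSample(calls, reference, label = label, z = z,
                            minPairs = minPairs, maxEpsilon = maxEpsilon,
                            localSites = localSites)
    profiles[[label]] <- prof
    rows[[i]] <- data.frame(
      label = label, group = if (!is.null(sp$group)) sp$group else NA,
      nPairsOnTarget = prof@nPairsOnTarget,
      conformity = prof@conformity, epsilon = prof@epsilon,
      entropyBits = prof@entropyBits, qcPass = prof@qcPass,
      qcReasons = paste(prof@qcReasons, collapse = "; "),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  included <- tab[tab$qcPass, , drop = FALSE]
  excluded <- tab[!tab$qcPass, c("label", "group", "qcReasons"),
                  drop = FALSE]
  comparisons <- .groupComparisons(included,
                                   metrics = c("conformity", "entropyBits"))
  new("CohortReport", arm = "amplicon", samples = tab,
      profiles = profiles, comparisons = comparisons, excluded = excluded,
      provenance = .cohortProvenance(
        list(samples = lapply(samples, function(s)
          s[setdiff(names(s), c("r1", "r2"))]),
          nPairs = nPairs, subErrorRate = subErrorRate, z = z), seed))
}

.groupComparisons <- function(tab, metrics) {
  out <- data.frame(metric = character(), groupA = character(),
                    groupB = character(), statistic = numeric(),
                    p = numeric(), stars = character(),
                    stringsAsFactors = FALSE)
  grps <- unique(stats::na.omit(tab$group))
  if (length(grps) < 2L) return(out)
  a <- grps[1L]; b <- grps[2L]
  for (mtr in metrics) {
    xa <- tab[[mtr]][tab$group == a]
    xb <- tab[[mtr]][tab$group == b]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    if (length(xa) < 2L || length(xb) < 2L) next
    wt <- wilcoxonRankSum(xa, xb)
    out <- rbind(out, data.frame(
      metric = mtr, groupA = a, groupB = b, statistic = wt$statistic,
      p = wt$p, stars = significanceStars(wt$p), stringsAsFactors = FALSE))
  }
  out
}

#' Run the methylome (amplification-call) arm on a synthetic cohort
#'
#' Each sample spec gets its own genome model (same geometry, its own
#' `copyFactor`), reads are simulated (or read from FASTQ), summarized and
#' QC-gated, and passing samples receive an amplified/baseline call
#' against `baseline`. Calls are cross-tabulated against group labels.
#'
#' @param samples list of specs: each a list with `label`, `group` and
#'   `copyFactor` (simulation) or `r1`/`r2` FASTQ paths.
#' @param nPairs read pairs per sample (default 6000, comfortably above
#'   the >10,000 CG-call inclusion gate at the default genome geometry).
#' @param baseline unamplified target-window proportion used for the call
#'   (default: the uniform expectation of the genome geometry).
#' @param foldThreshold see [callAmplification()].
#' @param nWindows,windowWidth,targetIndex,cpgMethRate,conversionFailureRate
#'   genome geometry passed to [syntheticGenome()].
#' @param duplicateRate exact-duplicate injection rate for simulation.
#' @param seed master seed; sample `i` uses `seed + i`.
#' @return a [CohortReport-class]; `comparisons` holds the call-by-group
#'   cross-tabulation in long form.
#' @export
runMethylomeArm <- function(samples, nPairs = 6000L, baseline = NULL,
                            foldThreshold = 3.0, nWindows = 10L,
                            windowWidth = 21000L, targetIndex = 5L,
                            cpgMethRate = 0.8,
                            conversionFailureRate = 0.02,
                            duplicateRate = 0, seed = 1L) {
  win <- NULL
  profiles <- list()
  rows <- list()
  for (i in seq_along(samples)) {
    sp <- samples[[i]]
    label <- if (!is.null(sp$label)) sp$label else sprintf("sample%02d", i)
    cf <- if (!is.null(sp$copyFactor)) sp$copyFactor else 1
    genome <- syntheticGenome(nWindows = nWindows,
                              windowWidth = windowWidth,
                              targetIndex = targetIndex, copyFactor = cf,
                              cpgMethRate = cpgMethRate,
                              conversionFailureRate = conversionFailureRate,
                              seed = seed)
    if (is.null(win)) {
      win <- tileWindows(genome)
      if (is.null(baseline)) baseline <- 1 / length(win)
    }
    if (!is.null(sp$r1)) {
      sim <- readFastqPair(sp$r1, sp$r2)
    } else {
      np <- if (!is.null(sp$nPairs)) sp$nPairs else nPairs
      sim <- simulateBisulfiteReads(genome, np,
                                    duplicateRate = duplicateRate,
                                    seed = seed + i)
    }
    prof <- summarizeMethylome(sim, genome, label = label)
    if (prof@qcPass)
      prof <- callAmplification(prof, baseline, foldThreshold)
    profiles[[label]] <- prof
    rows[[i]] <- data.frame(
      label = label, group = if (!is.null(sp$group)) sp$group else NA,
      copyFactor = cf, nPairs = prof@nPairs,
      totalCgCalls = prof@totalCgCalls,
      conversionEfficiency = prof@conversionEfficiency,
      duplicateFraction = prof@duplicateFraction,
      targetProportion = prof@targetProportion,
      amplificationCall = prof@amplificationCall,
      qcPass = prof@qcPass,
      qcReasons = paste(prof@qcReasons, collapse = "; "),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  excluded <- tab[!tab$qcPass, c("label", "group", "qcReasons"),
                  drop = FALSE]
  called <- tab[tab$qcPass & !is.na(tab$amplificationCall), , drop = FALSE]
  xt <- if (nrow(called) && any(!is.na(called$group))) {
    as.data.frame(table(group = called$group,
                        call = called$amplificationCall),
                  stringsAsFactors = FALSE)
  } else data.frame(group = character(), call = character(),
                    Freq = integer(), stringsAsFactors = FALSE)
  new("CohortReport", arm = "methylome", samples = tab,
      profiles = profiles, comparisons = xt, excluded = excluded,
      provenance = .cohortProvenance(
        list(samples = lapply(samples, function(s)
          s[setdiff(names(s), c("r1", "r2"))]),
          nPairs = nPairs, baseline = baseline,
          foldThreshold = foldThreshold, nWindows = nWindows,
          windowWidth = windowWidth), seed))
}

#' Write a cohort report to disk
#'
#' Emits `<arm>_samples.tsv`, `<arm>_comparisons.tsv` and a full
#' `<arm>_report.json` (samples, comparisons, exclusions with reasons,
#' provenance).
#'
#' @param report a [CohortReport-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the JSON path.
#' @export
writeCohortReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stub <- file.path(dir, report@arm)
  write.table(report@samples, paste0(stub, "_samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(report@comparisons, paste0(stub, "_comparisons.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  json <- paste0(stub, "_report.json")
  jsonlite::write_json(
    list(arm = report@arm, samples = report@samples,
         comparisons = report@comparisons, excluded = report@excluded,
         provenance = report@provenance),
    json, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(json)
}
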