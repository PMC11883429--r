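## The indel-variant identification pipeline: trim, align, detect events,
## resolve a per-pair category by precedence, summarize a sample.

.defaultPrecedence <- c("large_deletion", "multi_site", "single_site")

## BWA-style 3' running-sum trim: keep length maximizing
## S(x) = sum_{i > x} (threshold - q_i); keep everything if max(S) <= 0.
## Largest keep wins ties (least trimming).
.trimKeepLength <- function(q, threshold) {
  n <- length(q)
  if (n == 0L) return(0L)
  s <- rev(cumsum(rev(threshold - q)))      # S(x) for x = 0..n-1
  s <- c(s, 0)                              # S(n) = 0
  best <- max(s)
  if (best <= 0) return(n)
  max(which(s == best)) - 1L
}

#' Quality-trim reads from the 3' end
#'
#' BWA-style running-sum trimming at a phred threshold (default 20): the
#' kept prefix maximizes the running sum of `threshold - q` accumulated
#' from the 3' end; reads may become empty.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param threshold phred threshold.
#' @return a trimmed [Biostrings::QualityScaledDNAStringSet].
#' @export
qualityTrim <- function(reads, threshold = 20L) {
  if (!is(reads, "QualityScaledDNAStringSet"))
    stop("reads must be a QualityScaledDNAStringSet")
  qm <- as(Biostrings::quality(reads), "IntegerList")
  keep <- vapply(qm, .trimKeepLength, integer(1), threshold = threshold)
  out <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::subseq(as(reads, "DNAStringSet"), 1L, keep),
    Biostrings::PhredQuality(Biostrings::subseq(
      as(Biostrings::quality(reads), "BStringSet"), 1L, keep)))
  names(out) <- names(reads)
  out
}

.alnFromCpp <- function(x) {
  if (!isTRUE(x$mapped)) {
    return(structure(list(mapped = FALSE, reason = x$reason),
                     class = "AmpliconAlignment"))
  }
  ops <- x$ops
  df <- data.frame(
    op = c("ins", "del")[ops[, "code"]],
    refStart = ops[, "refStart"],
    len = ops[, "len"],
    seq = as.character(x$insSeq),
    stringsAsFactors = FALSE)
  structure(list(mapped = TRUE, strand = x$strand, refStart = x$refStart,
                 refEnd = x$refEnd, nMismatch = x$nMismatch, ops = df),
            class = "AmpliconAlignment")
}

#' Align one read to the amplicon reference
#'
#' Anchored gapped alignment: the read's 5' `anchorLen`-mer is located on
#' either strand of the reference (unique best hit, at most
#' `anchorMaxMismatch` mismatches), then the full read is aligned by
#' semi-global unit-cost edit distance with a free reference suffix.
#' Substitutions are always preferred over indels on equal cost, and indels
#' are left-aligned. `refStart`/`refEnd` delimit the half-open reference
#' span of the read on the forward strand (0-based).
#'
#' @param read character scalar or [Biostrings::DNAString].
#' @param reference an [AmpliconReference-class].
#' @param anchorLen anchor k-mer length (default 20, the primer length).
#' @param anchorMaxMismatch mismatches tolerated in the anchor.
#' @return an `"AmpliconAlignment"` list: `mapped`, `strand`, `refStart`,
#'   `refEnd`, `nMismatch`, `ops` (`data.frame` of `ins`/`del` operations
#'   with `refStart`, `len`, inserted `seq`), or `mapped = FALSE` with a
#'   `reason` for off-target reads.
#' @export
alignRead <- function(read, reference, anchorLen = 20L,
                      anchorMaxMismatch = 1L) {
  res <- alignReadSet(as.character(read), reference, anchorLen,
                      anchorMaxMismatch)
  res[[1L]]
}

#' Align a set of reads to the amplicon reference
#'
#' Vectorized form of [alignRead()].
#'
#' @param reads character vector or [Biostrings::DNAStringSet].
#' @inheritParams alignRead
#' @return list of `"AmpliconAlignment"` objects.
#' @export
alignReadSet <- function(reads, reference, anchorLen = 20L,
                         anchorMaxMismatch = 1L) {
  raw <- .alignReadsCpp(as.character(reads),
                        as.character(refSequence(reference)),
                        anchor_len = anchorLen,
                        anchor_max_mm = anchorMaxMismatch)
  lapply(raw, .alnFromCpp)
}

#' Detect indel events in an alignment
#'
#' Two event kinds: a `local_indel` for every indel operation whose
#' reference footprint intersects a guide's +/-5 bp cut-site window, and a
#' `large_deletion` when the read's reference span exceeds `readLen` (the
#' split-read displacement rule: the read 3' end matches more than
#' `readLen` bp from where its start matched). The large-deletion `sites`
#' are the guides whose cut sites fall within the deleted interval
#' (endpoints included); fewer than two sites flags the span as ambiguous,
#' and such events do not map to an inter-site deletion category.
#'
#' @param aln an `"AmpliconAlignment"` from [alignRead()].
#' @param reference an [AmpliconReference-class].
#' @param readLen displacement threshold in bp (default 151).
#' @return `data.frame` with columns `kind`, `sites` (list column of guide
#'   indices), `net` (signed net length change in bp), `ambiguous`.
#' @export
detectEvents <- function(aln, reference, readLen = 151L) {
  empty <- data.frame(kind = character(), net = integer(),
                      ambiguous = logical())
  empty$sites <- list()
  if (!isTRUE(aln$mapped)) return(empty)
  gs <- guideSites(reference)
  ops <- aln$ops
  rows <- list()
  if (nrow(ops)) {
    for (i in seq_len(nrow(ops))) {
      s <- ops$refStart[i]
      e <- s + ifelse(ops$op[i] == "del", ops$len[i], 0L)
      hit <- if (ops$op[i] == "del")
        which(s < gs$winEnd & e > gs$winStart)
      else
        which(s >= gs$winStart & s <= gs$winEnd)
      if (length(hit)) {
        net <- ifelse(ops$op[i] == "ins", ops$len[i], -ops$len[i])
        rows[[length(rows) + 1L]] <- list(kind = "local_indel",
                                          sites = hit, net = net)
      }
    }
  }
  span <- aln$refEnd - aln$refStart
  if (span > readLen && any(ops$op == "del")) {
    del <- ops[ops$op == "del", , drop = FALSE]
    lo <- min(del$refStart)
    hi <- max(del$refStart + del$len)
    ## +/-5 bp tolerance (the cut-site window radius) absorbs left-aligned
    ## placement of junction-homologous deletions
    sites <- which(gs$cut >= lo - 5L & gs$cut <= hi + 5L)
    net <- sum(ifelse(ops$op == "ins", ops$len, -ops$len))
    rows[[length(rows) + 1L]] <- list(kind = "large_deletion", sites = sites,
                                      net = net)
  }
  if (!length(rows)) return(empty)
  out <- data.frame(kind = vapply(rows, `[[`, character(1), "kind"),
                    net = vapply(rows, `[[`, numeric(1), "net"),
                    stringsAsFactors = FALSE)
  out$sites <- lapply(rows, `[[`, "sites")
  out$ambiguous <- out$kind == "large_deletion" &
    vapply(out$sites, length, integer(1)) < 2L
  out
}

#' Resolve the final category of a read pair
#'
#' Events from both mates are pooled. Unambiguous large deletions map to
#' their inter-site deletion span (min and max spanned site); localized
#' indel sites restricted to the tested `localSites` map to a single-site
#' or multi-site indel class. When several classes are supported the
#' highest-precedence tier wins (default: large deletion > multi-site >
#' single-site > reference). Mates supporting different deletion spans are
#' flagged discordant and resolved toward the larger net length change.
#'
#' @param eventsR1,eventsR2 event tables from [detectEvents()] (either may
#'   be `NULL` for a dropped mate).
#' @param reference an [AmpliconReference-class].
#' @param localSites tested local-indel sites (see [variantCategories()]).
#' @param precedence character vector ordering the tiers
#'   `"large_deletion"`, `"multi_site"`, `"single_site"`.
#' @return list with `category` (roman id), `discordant` (logical).
#' @export
classifyPair <- function(eventsR1, eventsR2, reference, localSites = NULL,
                         precedence = .defaultPrecedence) {
  cats <- variantCategories(reference, localSites)
  ls <- resolveLocalSites(reference, localSites)
  lut <- .categoryLookup(cats)
  ev <- rbind(eventsR1, eventsR2)
  spans <- list()
  locals <- integer()
  if (!is.null(ev) && nrow(ev)) {
    lg <- ev[ev$kind == "large_deletion" & !ev$ambiguous, , drop = FALSE]
    if (nrow(lg))
      spans <- lapply(seq_len(nrow(lg)), function(i)
        list(sites = lg$sites[[i]], net = lg$net[i]))
    loc <- ev[ev$kind == "local_indel", , drop = FALSE]
    if (nrow(loc))
      locals <- intersect(sort(unique(unlist(loc$sites))), ls)
  }
  .resolveCategory(spans, locals, lut, precedence)
}

## fast-path internals shared by classifyPair and classifyReadPairs --------

.categoryLookup <- function(cats) {
  sg <- cats[cats$type == "single", , drop = FALSE]
  sp <- cats[cats$type == "span", , drop = FALSE]
  list(refId = cats$id[cats$type == "reference"],
       singleId = setNames(sg$id, as.character(sg$site)),
       multiId = if (any(cats$type == "multi"))
         cats$id[cats$type == "multi"] else character(),
       spanId = setNames(sp$id, paste(sp$from, sp$to, sep = "-")))
}

## events of one mate from the raw aligner result: tested-window local hits
## and (if the displacement rule fires with >= 2 spanned sites) the deletion
## span
.mateEvents <- function(a, gs, readLen) {
  ops <- a$ops
  k <- nrow(ops)
  locals <- integer()
  span <- NULL
  if (k) {
    code <- ops[, 1L]; st <- ops[, 2L]; len <- ops[, 3L]
    isDel <- code == 2L
    en <- st + ifelse(isDel, len, 0L)
    for (s in seq_len(nrow(gs))) {
      hit <- any(ifelse(isDel,
                        st < gs$winEnd[s] & en > gs$winStart[s],
                        st >= gs$winStart[s] & st <= gs$winEnd[s]))
      if (hit) locals <- c(locals, s)
    }
    if ((a$refEnd - a$refStart) > readLen && any(isDel)) {
      lo <- min(st[isDel]); hi <- max(en[isDel])
      sites <- which(gs$cut >= lo - 5L & gs$cut <= hi + 5L)
      if (length(sites) >= 2L)
        span <- list(sites = sites,
                     net = sum(ifelse(code == 1L, len, -len)))
    }
  }
  list(locals = locals, span = span)
}

.resolveCategory <- function(spans, locals, lut, precedence) {
  discordant <- FALSE
  spanId <- character()
  if (length(spans)) {
    keys <- vapply(spans, function(s)
      paste(min(s$sites), max(s$sites), sep = "-"), character(1))
    if (length(unique(keys)) > 1L) {
      discordant <- TRUE
      pick <- which.max(vapply(spans, function(s) abs(s$net), numeric(1)))
    } else pick <- 1L
    spanId <- unname(lut$spanId[keys[pick]])
  }
  for (tier in precedence) {
    if (tier == "large_deletion" && length(spanId) && !is.na(spanId))
      return(list(category = spanId, discordant = discordant))
    if (tier == "multi_site" && length(locals) >= 2L && length(lut$multiId))
      return(list(category = lut$multiId, discordant = discordant))
    if (tier == "single_site" && length(locals) == 1L) {
      id <- unname(lut$singleId[as.character(locals)])
      if (!is.na(id)) return(list(category = id, discordant = discordant))
    }
  }
  list(category = lut$refId, discordant = discordant)
}

#' Classify every read pair of a sample
#'
#' End-to-end per-sample driver: quality trimming, anchored alignment of
#' both mates, event detection and precedence-based category resolution.
#' A pair with one off-target or empty mate is classified from the
#' surviving mate; a pair with both mates off-target, or supported only by
#' mates with more than `maxMismatch` substitutions and no events, is
#' excluded from the on-target count.
#'
#' @param r1,r2 [Biostrings::QualityScaledDNAStringSet] (or
#'   [Biostrings::DNAStringSet]/character, skipping trimming), or FASTQ
#'   file paths.
#' @param reference an [AmpliconReference-class].
#' @param localSites,precedence see [classifyPair()].
#' @param readLen displacement threshold for the large-deletion rule.
#' @param trimThreshold phred threshold for [qualityTrim()]; `NA` disables.
#' @param maxMismatch per-mate substitution tolerance for category I.
#' @param anchorLen,anchorMaxMismatch see [alignRead()].
#' @return `data.frame` with one row per pair: `pairId`, `category` (`NA`
#'   for excluded pairs), `onTarget`, `discordant`, per-mate `mapped` and
#'   mismatch counts.
#' @export
classifyReadPairs <- function(r1, r2, reference, localSites = NULL,
                              precedence = .defaultPrecedence,
                              readLen = 151L, trimThreshold = 20L,
                              maxMismatch = 2L, anchorLen = 20L,
                              anchorMaxMismatch = 1L) {
  if (is.character(r1) && length(r1) == 1L && file.exists(r1)) {
    fq <- readFastqPair(r1, r2)
    r1 <- fq$r1; r2 <- fq$r2
  }
  if (is(r1, "QualityScaledDNAStringSet") && !is.na(trimThreshold)) {
    r1 <- qualityTrim(r1, trimThreshold)
    r2 <- qualityTrim(r2, trimThreshold)
  }
  ids <- names(r1)
  if (is.null(ids)) ids <- sprintf("pair%06d", seq_along(r1))
  n <- length(r1)
  stopifnot(length(r2) == n)
  s1 <- as.character(r1); s2 <- as.character(r2)
  refStr <- as.character(refSequence(reference))
  a1 <- .alignReadsCpp(s1, refStr, anchor_len = anchorLen,
                       anchor_max_mm = anchorMaxMismatch)
  a2 <- .alignReadsCpp(s2, refStr, anchor_len = anchorLen,
                       anchor_max_mm = anchorMaxMismatch)
  cats <- variantCategories(reference, localSites)
  ls <- resolveLocalSites(reference, localSites)
  gs <- guideSites(reference)
  lut <- .categoryLookup(cats)
  refId <- lut$refId
  category <- character(n); onTarget <- logical(n); disc <- logical(n)
  m1 <- vapply(a1, function(a) isTRUE(a$mapped), logical(1))
  m2 <- vapply(a2, function(a) isTRUE(a$mapped), logical(1))
  mm1 <- vapply(a1, function(a) if (isTRUE(a$mapped)) a$nMismatch else NA_integer_,
                integer(1))
  mm2 <- vapply(a2, function(a) if (isTRUE(a$mapped)) a$nMismatch else NA_integer_,
                integer(1))
  for (i in seq_len(n)) {
    if (!m1[i] && !m2[i]) {
      category[i] <- NA_character_; onTarget[i] <- FALSE
      next
    }
    e1 <- if (m1[i]) .mateEvents(a1[[i]], gs, readLen) else NULL
    e2 <- if (m2[i]) .mateEvents(a2[[i]], gs, readLen) else NULL
    spans <- c(if (!is.null(e1$span)) list(e1$span),
               if (!is.null(e2$span)) list(e2$span))
    locals <- intersect(sort(unique(c(e1$locals, e2$locals))), ls)
    cl <- .resolveCategory(spans, locals, lut, precedence)
    if (cl$category == refId) {
      worst <- max(c(mm1[i], mm2[i]), na.rm = TRUE)
      if (worst > maxMismatch) {
        category[i] <- NA_character_; onTarget[i] <- FALSE
        next
      }
    }
    category[i] <- cl$category
    onTarget[i] <- TRUE
    disc[i] <- cl$discordant
  }
  data.frame(pairId = ids, category = category, onTarget = onTarget,
             discordant = disc, r1Mapped = m1, r2Mapped = m2,
             nMismatchR1 = mm1, nMismatchR2 = mm2,
             stringsAsFactors = FALSE)
}

#' Summarize a sample's variant calls
#'
#' Category proportions over classified (on-target) pairs, reference
#' conformity (the proportion of category I), the binomial margin of error
#' at the sample depth, Shannon entropy of the category spectrum, and the
#' inclusion QC gates: strictly more than `minPairs` on-target pairs and a
#' margin of error strictly below `maxEpsilon`.
#'
#' @param calls `data.frame` from [classifyReadPairs()].
#' @param reference an [AmpliconReference-class].
#' @param label sample label.
#' @param z margin-of-error multiplier (default the 99%-labelled constant
#'   2.326348; see [marginOfError()]).
#' @param minPairs,maxEpsilon QC gates (defaults 150 pairs, 5%).
#' @param localSites see [variantCategories()].
#' @return a [SampleVariantProfile-class].
#' @export
summarizeSample <- function(calls, reference, label = "sample",
                            z = 2.326348, minPairs = 150L,
                            maxEpsilon = 0.05, localSites = NULL) {
  cats <- variantCategories(reference, localSites)
  onT <- calls[calls$onTarget & !is.na(calls$category), , drop = FALSE]
  nTot <- nrow(calls)
  nOn <- nrow(onT)
  if (nOn == 0L) {
    return(new("SampleVariantProfile", label = label,
               nPairsTotal = as.integer(nTot), nPairsOnTarget = 0L,
               proportions = setNames(rep(NA_real_, nrow(cats)), cats$id),
               conformity = NA_real_, epsilon = NA_real_,
               entropyBits = NA_real_, z = z, qcPass = FALSE,
               qcReasons = "no on-target pairs"))
  }
  counts <- table(factor(onT$category, levels = cats$id))
  props <- as.numeric(counts) / nOn
  names(props) <- cats$id
  conf <- props[[cats$id[cats$type == "reference"]]]
  eps <- marginOfError(conf, nOn, z)$epsilon
  ent <- shannonEntropy(props)$bits
  reasons <- character()
  if (nOn <= minPairs)
    reasons <- c(reasons, sprintf("<=%d read pairs", minPairs))
  if (eps >= maxEpsilon)
    reasons <- c(reasons, sprintf("margin of error >= %g", maxEpsilon))
  new("SampleVariantProfile", label = label,
      nPairsTotal = as.integer(nTot), nPairsOnTarget = as.integer(nOn),
      proportions = props, conformity = conf, epsilon = eps,
      entropyBits = ent, z = z, qcPass = length(reasons) == 0L,
      qcReasons = if (length(reasons)) reasons else character())
}
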