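## Synthetic amplicon read-pair generator with ground truth.

#' Describe one molecular species in a simulated mixture
#'
#' Edits are given against an [AmpliconReference-class]: localized deletions
#' and insertions are placed at a guide cut site (so their footprint
#' intersects that site's window), and a large deletion removes everything
#' between two cut sites.
#'
#' @param edits list of edits, each one of
#'   `list(type = "del", site = i, len = L)` (deletion of `L` bp centred on
#'   the cut, optional `offset` shifting its start),
#'   `list(type = "ins", site = i, seq = "ACGT")` (insertion at the cut), or
#'   `list(type = "span", from = i, to = j)` (deletion from cut `i` to cut
#'   `j`). An empty list is the unedited reference species.
#' @param weight fraction of molecules of this species in the mixture.
#' @param name optional species label.
#' @return list with class `"VariantSpec"`.
#' @export
variantSpec <- function(edits = list(), weight = 1, name = NULL) {
  stopifnot(is.list(edits), is.numeric(weight), weight >= 0)
  if (sum(vapply(edits, function(e) identical(e$type, "span"), logical(1))) > 1L)
    stop("at most one large-deletion span per species")
  structure(list(edits = edits, weight = weight, name = name),
            class = "VariantSpec")
}

## resolve an edit to its reference footprint [start, end) (ins: start==end)
.editFootprint <- function(reference, e) {
  gs <- guideSites(reference)
  if (e$type == "del") {
    len <- as.integer(e$len)
    if (len < 1L) stop("deletion length must be >= 1")
    off <- if (is.null(e$offset)) -(len %/% 2L) else as.integer(e$offset)
    st <- gs$cut[e$site] + off
    c(st, st + len)
  } else if (e$type == "ins") {
    q <- gs$cut[e$site]
    c(q, q)
  } else if (e$type == "span") {
    if (e$from >= e$to) stop("span requires from < to")
    c(gs$cut[e$from], gs$cut[e$to])
  } else stop("unknown edit type: ", e$type)
}

#' Apply a variant spec to the reference, producing the molecule sequence
#'
#' @param reference an [AmpliconReference-class].
#' @param spec a [variantSpec()].
#' @return character scalar: the mutated molecule sequence.
#' @examples
#' ref <- syntheticAmplicon()
#' nchar(applyVariant(ref, variantSpec()))               # 317
#' nchar(applyVariant(ref, variantSpec(list(list(type = "del", site = 1,
#'                                               len = 3)))))  # 314
#' @export
applyVariant <- function(reference, spec) {
  stopifnot(inherits(spec, "VariantSpec"))
  seq <- as.character(refSequence(reference))
  L <- nchar(seq)
  gs <- guideSites(reference)
  edits <- spec$edits
  if (!length(edits)) return(seq)
  fps <- t(vapply(edits, function(e) .editFootprint(reference, e),
                  numeric(2)))
  if (any(fps[, 1] < 0) || any(fps[, 2] > L))
    stop("edit outside amplicon bounds")
  ## overlap check (insertions are points; two edits may not share ground)
  ord <- order(fps[, 1], fps[, 2])
  fps <- fps[ord, , drop = FALSE]
  edits <- edits[ord]
  if (nrow(fps) > 1L) {
    for (i in 2:nrow(fps)) {
      prevEnd <- fps[i - 1L, 2]
      if (fps[i, 1] < prevEnd ||
          (fps[i, 1] == prevEnd && fps[i - 1L, 1] == fps[i, 1]))
        stop("overlapping edits")
    }
  }
  ## localized edits must intersect their site's window
  for (i in seq_along(edits)) {
    e <- edits[[i]]
    if (e$type %in% c("del", "ins")) {
      w <- c(gs$winStart[e$site], gs$winEnd[e$site])
      ok <- if (e$type == "del") fps[i, 1] < w[2] && fps[i, 2] > w[1]
            else fps[i, 1] >= w[1] && fps[i, 1] <= w[2]
      if (!ok) stop("edit does not intersect site window")
    }
  }
  ## apply right-to-left (0-based half-open -> R substr is 1-based)
  for (i in rev(seq_along(edits))) {
    e <- edits[[i]]
    st <- fps[i, 1]; en <- fps[i, 2]
    left <- substr(seq, 1L, st)
    right <- substr(seq, en + 1L, nchar(seq))
    mid <- if (e$type == "ins") toupper(e$seq) else ""
    seq <- paste0(left, mid, right)
  }
  seq
}

#' Expected variant category of a molecular species
#'
#' The category that a fully covered, error-free read pair from this
#' species is classified as, under the taxonomy of [variantCategories()].
#'
#' @inheritParams applyVariant
#' @param localSites as in [variantCategories()].
#' @return the roman-numeral category id.
#' @export
expectedCategory <- function(reference, spec, localSites = NULL) {
  cats <- variantCategories(reference, localSites)
  ls <- resolveLocalSites(reference, localSites)
  spans <- Filter(function(e) e$type == "span", spec$edits)
  if (length(spans)) {
    e <- spans[[1L]]
    return(cats$id[cats$type == "span" & cats$from == e$from &
                     cats$to == e$to])
  }
  sites <- unique(vapply(Filter(function(e) e$type %in% c("del", "ins"),
                                spec$edits),
                         function(e) as.integer(e$site), integer(1)))
  sites <- intersect(sites, ls)
  if (length(sites) >= 2L) cats$id[cats$type == "multi"]
  else if (length(sites) == 1L) cats$id[cats$type == "single" &
                                          cats$site == sites]
  else cats$id[cats$type == "reference"]
}

#' Canonical mixture containing every constructible lesion type
#'
#' One species per category of the default taxonomy: the unedited
#' reference, a localized deletion at each tested site (an insertion at the
#' last one), indels at both tested sites, and each inter-site deletion
#' span.
#'
#' @inheritParams expectedCategory
#' @param weights numeric weights, one per species (default uniform).
#' @return list of [variantSpec()]s whose `name`s are the category ids.
#' @export
fullMixture <- function(reference, weights = NULL, localSites = NULL) {
  ls <- resolveLocalSites(reference, localSites)
  k <- nrow(guideSites(reference))
  specs <- list(variantSpec())
  for (i in seq_along(ls)) {
    e <- if (i == length(ls) && length(ls) > 1L)
      list(type = "ins", site = ls[i], seq = "TCGA")
    else list(type = "del", site = ls[i], len = 3L)
    specs[[length(specs) + 1L]] <- variantSpec(list(e))
  }
  if (length(ls) >= 2L)
    specs[[length(specs) + 1L]] <- variantSpec(list(
      list(type = "del", site = ls[1L], len = 3L),
      list(type = "del", site = ls[length(ls)], len = 2L)))
  if (k >= 2L) {
    prs <- utils::combn(k, 2L)
    for (j in seq_len(ncol(prs)))
      specs[[length(specs) + 1L]] <- variantSpec(list(
        list(type = "span", from = prs[1L, j], to = prs[2L, j])))
  }
  if (is.null(weights)) weights <- rep(1 / length(specs), length(specs))
  if (length(weights) != length(specs)) stop("one weight per species")
  for (i in seq_along(specs)) {
    specs[[i]]$weight <- weights[i]
    specs[[i]]$name <- expectedCategory(reference, specs[[i]], localSites)
  }
  specs
}

#' Mixture with a prescribed reference conformity
#'
#' The unedited species gets weight `conformity`; the remaining mass is
#' split equally over the edited species of [fullMixture()].
#'
#' @inheritParams fullMixture
#' @param conformity true fraction of unedited molecules.
#' @export
conformityMixture <- function(reference, conformity, localSites = NULL) {
  specs <- fullMixture(reference, localSites = localSites)
  stopifnot(conformity >= 0, conformity <= 1)
  w <- c(conformity, rep((1 - conformity) / (length(specs) - 1L),
                         length(specs) - 1L))
  for (i in seq_along(specs)) specs[[i]]$weight <- w[i]
  specs
}

.qualString <- function(width, model = c("constant", "ramp"), phred = 35L) {
  model <- match.arg(model)
  if (model == "constant") {
    strrep(intToUtf8(phred + 33L), width)
  } else {
    vapply(width, function(w) {
      rampLen <- min(20L, w)
      q <- c(rep(phred, w - rampLen),
             round(seq(phred, 2L, length.out = rampLen)))
      intToUtf8(q + 33L, multiple = FALSE)
    }, character(1))
  }
}

.addSubErrors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  w <- nchar(seqs)
  nerr <- rbinom(length(seqs), w, rate)
  idx <- which(nerr > 0L)
  for (i in idx) {
    pos <- sample.int(w[i], nerr[i])
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    for (p in pos) {
      ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate paired-end amplicon reads from a variant mixture
#'
#' Each read pair is drawn i.i.d. from the mixture; R1 is the first
#' `readLen` bases of the molecule and R2 the reverse complement of the
#' last `readLen` bases (both truncated to the molecule length when the
#' molecule is shorter, flagged in the truth table). Substitution errors
#' are applied per base at `subErrorRate`; output is deterministic given
#' `seed`.
#'
#' @param reference an [AmpliconReference-class].
#' @param mixture list of [variantSpec()]s; weights must sum to 1.
#' @param nPairs number of read pairs.
#' @param readLen read length in bp (default 151).
#' @param subErrorRate per-base substitution error probability.
#' @param qualityModel `"constant"` (all `phred`) or `"ramp"` (linear 3'
#'   decline over the last 20 bases, to exercise trimming).
#' @param phred phred score for the quality model.
#' @param seed integer seed; the generator is Mersenne-Twister and the run
#'   is byte-reproducible.
#' @param localSites taxonomy option passed to [expectedCategory()].
#' @return list with elements `r1`, `r2`
#'   ([Biostrings::QualityScaledDNAStringSet]), `truth` (`data.frame` with
#'   `pairId`, `component`, `category`, `molLen`, `truncated`), `weights`,
#'   `seed`.
#' @export
simulateAmpliconReadPairs <- function(reference, mixture, nPairs,
                                      readLen = 151L, subErrorRate = 0,
                                      qualityModel = "constant",
                                      phred = 35L, seed = 1L,
                                      localSites = NULL) {
  stopifnot(nPairs >= 1L, readLen >= 1L, subErrorRate >= 0,
            subErrorRate < 0.5)
  w <- vapply(mixture, function(s) s$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-9) stop("mixture weights must sum to 1")
  mols <- vapply(mixture, function(s) applyVariant(reference, s),
                 character(1))
  cats <- vapply(seq_along(mixture), function(i)
    expectedCategory(reference, mixture[[i]], localSites), character(1))
  molLen <- nchar(mols)
  r1t <- substr(mols, 1L, pmin(readLen, molLen))
  r2t <- vapply(seq_along(mols), function(i) {
    tail <- substr(mols[i], max(1L, molLen[i] - readLen + 1L), molLen[i])
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(tail)))
  }, character(1))
  withr::with_seed(seed, {
    comp <- sample.int(length(mixture), nPairs, replace = TRUE, prob = w)
    r1 <- .addSubErrors(r1t[comp], subErrorRate)
    r2 <- .addSubErrors(r2t[comp], subErrorRate)
  }, .rng_kind = "Mersenne-Twister", .rng_normal_kind = "Inversion",
     .rng_sample_kind = "Rejection")
  ids <- sprintf("pair%06d", seq_len(nPairs))
  q1 <- Biostrings::PhredQuality(.qualString(nchar(r1), qualityModel, phred))
  q2 <- Biostrings::PhredQuality(.qualString(nchar(r2), qualityModel, phred))
  mk <- function(s, q) {
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(s), q)
    names(x) <- ids
    x
  }
  list(
    r1 = mk(r1, q1), r2 = mk(r2, q2),
    truth = data.frame(pairId = ids, component = comp,
                       category = cats[comp], molLen = molLen[comp],
                       truncated = molLen[comp] < readLen,
                       stringsAsFactors = FALSE),
    weights = setNames(w, cats), seed = seed)
}
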