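## Amplicon coordinate model: locate guides, build the reference object.
## All coordinates 0-based half-open; cut sites are between-base indices.

#' Define a guide
#'
#' @param name guide label.
#' @param protospacer 20-nt protospacer sequence (on the guide strand).
#' @param pam 3-nt NGG-class PAM; `N` in the first position is a wildcard.
#' @return a `list` with class `"GuideDef"`.
#' @export
guideDef <- function(name, protospacer, pam = "NGG") {
  protospacer <- toupper(protospacer)
  pam <- toupper(pam)
  if (nchar(protospacer) != 20L)
    stop("protospacer must be 20 nt, got ", nchar(protospacer))
  if (nchar(pam) != 3L)
    stop("pam must be 3 nt")
  if (!grepl("^[ACGT]+$", protospacer))
    stop("protospacer alphabet must be A/C/G/T")
  if (!grepl("^[ACGTN][ACGT][ACGT]$", pam))
    stop("pam must be [ACGTN][ACGT][ACGT]")
  structure(list(name = as.character(name), protospacer = protospacer,
                 pam = pam), class = "GuideDef")
}

#' Read guide definitions from a TSV file
#'
#' Expects columns `name`, `protospacer`, `pam`.
#'
#' @param path TSV file path.
#' @return list of [guideDef()] objects.
#' @export
readGuideTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "protospacer", "pam")
  if (!all(need %in% names(tab)))
    stop("guide table must have columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i)
    guideDef(tab$name[i], tab$protospacer[i], tab$pam[i]))
}

## between-base cut site for a forward-strand hit with protospacer at
## [s, s+20) and PAM at [s+20, s+23): blunt cut 3 bp 5' of the PAM.
.cutFromForwardHit <- function(protoStart) protoStart + 17L

#' Locate a guide on a reference sequence
#'
#' Searches both strands for the unique protospacer+PAM match and derives
#' the blunt cut site (3 bp 5' of the PAM on the protospacer strand) and
#' the +/-5 bp indel-detection window `[cut - 5, cut + 5)`.
#'
#' @param referenceSequence a [Biostrings::DNAString] or character scalar.
#' @param guide a [guideDef()].
#' @return one-row `data.frame` with the `guideSites` columns of
#'   [AmpliconReference-class].
#' @examples
#' ref <- syntheticAmplicon()
#' locateGuide(refSequence(ref), guideDef("sg1", "CCGTTTCTAGCATTAGTCCG", "GGG"))
#' @export
locateGuide <- function(referenceSequence, guide) {
  if (!inherits(guide, "GuideDef")) stop("guide must be a GuideDef")
  seq <- if (is(referenceSequence, "DNAString")) referenceSequence
         else Biostrings::DNAString(as.character(referenceSequence))
  if (length(seq) == 0L) stop("reference sequence is empty")
  pat <- Biostrings::DNAString(paste0(guide$protospacer, guide$pam))
  fwd <- Biostrings::matchPattern(pat, seq, fixed = FALSE)
  rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat), seq,
                                  fixed = FALSE)
  nHits <- length(fwd) + length(rev)
  if (nHits == 0L) stop("guide not found: ", guide$name)
  if (nHits > 1L) stop("ambiguous guide placement: ", guide$name)
  L <- length(seq)
  if (length(fwd) == 1L) {
    protoStart <- BiocGenerics::start(fwd)[1L] - 1L     # to 0-based
    cut <- .cutFromForwardHit(protoStart)
    out <- data.frame(
      name = guide$name, strand = "+",
      protoStart = protoStart, protoEnd = protoStart + 20L,
      pamStart = protoStart + 20L, pamEnd = protoStart + 23L,
      cut = cut, winStart = cut - 5L, winEnd = cut + 5L,
      stringsAsFactors = FALSE)
  } else {
    ## reverse-complement hit occupies [s, s+23) on the forward strand with
    ## PAM' first: PAM at [s, s+3), protospacer at [s+3, s+23). On the
    ## protospacer (minus) strand the cut is 3 bp 5' of the PAM, i.e. at
    ## forward between-base index s+3+3 ... mirror of the forward rule.
    s <- BiocGenerics::start(rev)[1L] - 1L
    protoStartMinus <- L - (s + 23L)                     # minus-strand coords
    cutMinus <- .cutFromForwardHit(protoStartMinus)
    cut <- L - cutMinus
    out <- data.frame(
      name = guide$name, strand = "-",
      protoStart = s + 3L, protoEnd = s + 23L,
      pamStart = s, pamEnd = s + 3L,
      cut = cut, winStart = cut - 5L, winEnd = cut + 5L,
      stringsAsFactors = FALSE)
  }
  out
}

#' Build an amplicon reference from sequence, primers and guides
#'
#' Trims the input sequence to the primer-delimited extent (forward primer
#' matched as given, reverse primer as its reverse complement), locates all
#' guides within the amplicon and returns the assembled coordinate model
#' with guide sites sorted by cut position (ties broken by guide name).
#'
#' @param sequence a [Biostrings::DNAString] or character scalar.
#' @param primerFwd,primerRev primer sequences; each must match exactly once.
#' @param guides list of [guideDef()] objects.
#' @param name amplicon label.
#' @return an [AmpliconReference-class].
#' @export
buildReference <- function(sequence, primerFwd, primerRev, guides,
                           name = "amplicon") {
  seq <- if (is(sequence, "DNAString")) sequence
         else Biostrings::DNAString(toupper(as.character(sequence)))
  primerFwd <- toupper(as.character(primerFwd))
  primerRev <- toupper(as.character(primerRev))
  if (length(seq) < max(nchar(primerFwd), nchar(primerRev)))
    stop("sequence shorter than a primer")
  fhits <- Biostrings::matchPattern(Biostrings::DNAString(primerFwd), seq)
  rpat <- Biostrings::reverseComplement(Biostrings::DNAString(primerRev))
  rhits <- Biostrings::matchPattern(rpat, seq)
  if (length(fhits) == 0L) stop("forward primer not found")
  if (length(fhits) > 1L) stop("forward primer matches multiple times")
  if (length(rhits) == 0L) stop("reverse primer not found")
  if (length(rhits) > 1L) stop("reverse primer matches multiple times")
  from <- BiocGenerics::start(fhits)[1L]
  to <- BiocGenerics::end(rhits)[1L]
  if (from >= to) stop("primers are inverted on this sequence")
  amplicon <- Biostrings::subseq(seq, from, to)
  sites <- do.call(rbind, lapply(guides, function(g) locateGuide(amplicon, g)))
  if (is.null(sites)) sites <- data.frame(
    name = character(), strand = character(), protoStart = integer(),
    protoEnd = integer(), pamStart = integer(), pamEnd = integer(),
    cut = integer(), winStart = integer(), winEnd = integer(),
    stringsAsFactors = FALSE)
  sites <- sites[order(sites$cut, sites$name), , drop = FALSE]
  rownames(sites) <- NULL
  L <- length(amplicon)
  if (nrow(sites) && any(sites$winStart < 0L | sites$winEnd > L))
    stop("guide window outside amplicon bounds")
  new("AmpliconReference", name = name, sequence = amplicon,
      primerFwd = primerFwd, primerRev = primerRev, guideSites = sites)
}

#' Built-in synthetic 317-bp amplicon with three guides
#'
#' Loads the package's synthetic amplicon fixture (a 317-bp sequence that is
#' not a genomic sequence, shipped as FASTA + guide TSV under `extdata`)
#' and assembles it with [buildReference()]. The three guides sit at
#' realistic spacing (cut sites 57, 156, 247) with the middle guide on the
#' minus strand; primers are the terminal 20 bp.
#'
#' @return an [AmpliconReference-class].
#' @export
syntheticAmplicon <- function() {
  fa <- system.file("extdata", "synthetic_amplicon.fa", package = "rdnaedit",
                    mustWork = TRUE)
  gt <- system.file("extdata", "synthetic_guides.tsv", package = "rdnaedit",
                    mustWork = TRUE)
  seq <- Biostrings::readDNAStringSet(fa)[[1L]]
  guides <- readGuideTable(gt)
  primerFwd <- as.character(Biostrings::subseq(seq, 1L, 20L))
  primerRev <- as.character(Biostrings::reverseComplement(
    Biostrings::subseq(seq, length(seq) - 19L, length(seq))))
  buildReference(seq, primerFwd, primerRev, guides,
                 name = "synthetic_45SM_promoter_amplicon")
}

#' Variant-category taxonomy for an amplicon
#'
#' Instantiates the read-pair category taxonomy from the guide set:
#' category I is the unedited reference; one single-site indel class per
#' *tested* local site; one multi-site indel class (indels at two or more
#' tested sites); and one inter-site large-deletion class per pair of cut
#' sites. By default local indels are tested at the two outer guides (first
#' and last by cut coordinate), which for a three-guide amplicon yields the
#' seven-category taxonomy (reference + 2 singles + 1 multi + 3 deletion
#' spans).
#'
#' @param reference an [AmpliconReference-class].
#' @param localSites integer indices (by cut-site order) of the guides whose
#'   windows are tested for localized indels; `NULL` (default) = the outer
#'   guides; `"all"` = every guide.
#' @return `data.frame` with columns `id` (roman numeral), `type`
#'   (`reference`/`single`/`multi`/`span`), `site`, `from`, `to`, `label`.
#' @export
variantCategories <- function(reference, localSites = NULL) {
  gs <- guideSites(reference)
  k <- nrow(gs)
  if (k < 1L) stop("reference has no guide sites")
  localSites <- resolveLocalSites(reference, localSites)
  rows <- list(data.frame(id = NA, type = "reference", site = NA_integer_,
                          from = NA_integer_, to = NA_integer_,
                          label = "reference", stringsAsFactors = FALSE))
  for (s in localSites)
    rows[[length(rows) + 1L]] <- data.frame(
      id = NA, type = "single", site = s, from = NA_integer_,
      to = NA_integer_, label = paste0("indel@", gs$name[s]),
      stringsAsFactors = FALSE)
  if (length(localSites) >= 2L)
    rows[[length(rows) + 1L]] <- data.frame(
      id = NA, type = "multi", site = NA_integer_, from = NA_integer_,
      to = NA_integer_, label = "multi-site indel", stringsAsFactors = FALSE)
  if (k >= 2L) {
    prs <- utils::combn(k, 2L)
    for (j in seq_len(ncol(prs)))
      rows[[length(rows) + 1L]] <- data.frame(
        id = NA, type = "span", site = NA_integer_,
        from = prs[1L, j], to = prs[2L, j],
        label = paste0("deletion ", gs$name[prs[1L, j]], "-",
                       gs$name[prs[2L, j]]),
        stringsAsFactors = FALSE)
  }
  cats <- do.call(rbind, rows)
  cats$id <- as.character(utils::as.roman(seq_len(nrow(cats))))
  cats
}

## localSites spec -> sorted integer indices
resolveLocalSites <- function(reference, localSites) {
  k <- nrow(guideSites(reference))
  if (is.null(localSites)) {
    if (k == 1L) 1L else sort(unique(c(1L, k)))
  } else if (identical(localSites, "all")) {
    seq_len(k)
  } else {
    ls <- sort(unique(as.integer(localSites)))
    if (any(ls < 1L | ls > k)) stop("localSites out of range")
    ls
  }
}
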