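#' @importClassesFrom Biostrings DNAString DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
NULL

#' Accessors for rdnaedit containers
#'
#' Small accessor generics in place of direct slot access.
#'
#' @param x an rdnaedit S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("refSequence", function(x) standardGeneric("refSequence"))

#' @rdname accessors
#' @export
setGeneric("guideSites", function(x) standardGeneric("guideSites"))

#' @rdname accessors
#' @export
setGeneric("cutSites", function(x) standardGeneric("cutSites"))

#' @rdname accessors
#' @export
setGeneric("conformity", function(x) standardGeneric("conformity"))

#' @rdname accessors
#' @export
setGeneric("epsilonOf", function(x) standardGeneric("epsilonOf"))

#' @rdname accessors
#' @export
setGeneric("entropyBits", function(x) standardGeneric("entropyBits"))

#' @rdname accessors
#' @export
setGeneric("categoryProportions", function(x) standardGeneric("categoryProportions"))

#' @rdname accessors
#' @export
setGeneric("qcPass", function(x) standardGeneric("qcPass"))

#' @rdname accessors
#' @export
setGeneric("qcReasons", function(x) standardGeneric("qcReasons"))

#' @rdname accessors
#' @export
setGeneric("targetProportion", function(x) standardGeneric("targetProportion"))

#' @rdname accessors
#' @export
setGeneric("amplificationCall", function(x) standardGeneric("amplificationCall"))

#' @rdname accessors
#' @export
setGeneric("sampleTable", function(x) standardGeneric("sampleTable"))

#' @rdname accessors
#' @export
setGeneric("comparisons", function(x) standardGeneric("comparisons"))

#' Call a sample amplified or baseline
#'
#' @param x a [MethylomeSummary-class] (or the target proportion itself in
#'   the numeric method).
#' @param baseline baseline (unamplified) target-window proportion.
#' @param foldThreshold call "amplified" when the target proportion exceeds
#'   `foldThreshold * baseline` (default 3).
#' @return `"amplified"`, `"baseline"`, or for a QC-failing summary `NA`.
#' @export
setGeneric("callAmplification",
  function(x, baseline, foldThreshold = 3.0) standardGeneric("callAmplification"))

## ---- accessor methods -----------------------------------------------------

#' @rdname accessors
#' @export
setMethod("refSequence", "AmpliconReference", function(x) x@sequence)

#' @rdname accessors
#' @export
setMethod("guideSites", "AmpliconReference", function(x) x@guideSites)

#' @rdname accessors
#' @export
setMethod("cutSites", "AmpliconReference", function(x)
  setNames(x@guideSites$cut, x@guideSites$name))

#' @rdname accessors
#' @export
setMethod("conformity", "SampleVariantProfile", function(x) x@conformity)

#' @rdname accessors
#' @export
setMethod("epsilonOf", "SampleVariantProfile", function(x) x@epsilon)

#' @rdname accessors
#' @export
setMethod("entropyBits", "SampleVariantProfile", function(x) x@entropyBits)

#' @rdname accessors
#' @export
setMethod("categoryProportions", "SampleVariantProfile", function(x) x@proportions)

#' @rdname accessors
#' @export
setMethod("qcPass", "SampleVariantProfile", function(x) x@qcPass)

#' @rdname accessors
#' @export
setMethod("qcReasons", "SampleVariantProfile", function(x) x@qcReasons)

#' @rdname accessors
#' @export
setMethod("qcPass", "MethylomeSummary", function(x) x@qcPass)

#' @rdname accessors
#' @export
setMethod("qcReasons", "MethylomeSummary", function(x) x@qcReasons)

#' @rdname accessors
#' @export
setMethod("targetProportion", "MethylomeSummary", function(x) x@targetProportion)

#' @rdname accessors
#' @export
setMethod("amplificationCall", "MethylomeSummary", function(x) x@amplificationCall)

#' @rdname accessors
#' @export
setMethod("sampleTable", "CohortReport", function(x) x@samples)

#' @rdname accessors
#' @export
setMethod("comparisons", "CohortReport", function(x) x@comparisons)

## ---- show methods ---------------------------------------------------------

setMethod("show", "AmpliconReference", function(object) {
  gs <- object@guideSites
  cat("AmpliconReference '", object@name, "': ",
      length(object@sequence), " bp, ", nrow(gs), " guide site(s)\n", sep = "")
  if (nrow(gs)) {
    for (i in seq_len(nrow(gs)))
      cat(sprintf("  %s (%s) cut=%d window=[%d,%d)\n",
                  gs$name[i], gs$strand[i], gs$cut[i],
                  gs$winStart[i], gs$winEnd[i]))
  }
})

setMethod("show", "GenomeModel", function(object) {
  tw <- object@targetWindow
  cat("GenomeModel '", object@name, "': ",
      length(object@contigs), " contig(s), total ",
      sum(Biostrings::width(object@contigs)), " bp; window width ",
      object@windowWidth, " bp\n", sep = "")
  cat(sprintf("  target %s:%d-%d, copyFactor %g, CpG meth %.3f, conv. failure %.4f\n",
              as.character(GenomeInfoDb::seqnames(tw)),
              GenomicRanges::start(tw), GenomicRanges::end(tw),
              object@copyFactor, object@cpgMethRate,
              object@conversionFailureRate))
})

setMethod("show", "SampleVariantProfile", function(object) {
  cat("SampleVariantProfile '", object@label, "'\n", sep = "")
  cat(sprintf("  pairs: %d total, %d on-target\n",
              object@nPairsTotal, object@nPairsOnTarget))
  cat(sprintf("  conformity %.4f (eps %.4f, z %.6f), entropy %.3f bits\n",
              object@conformity, object@epsilon, object@z,
              object@entropyBits))
  cat("  QC:", if (object@qcPass) "pass" else
    paste("fail -", paste(object@qcReasons, collapse = "; ")), "\n")
})

setMethod("show", "MethylomeSummary", function(object) {
  cat("MethylomeSummary '", object@label, "'\n", sep = "")
  cat(sprintf("  pairs: %d (%d mapped), CG calls %d\n",
              object@nPairs, object@nPairsMapped, object@totalCgCalls))
  cat(sprintf("  conversion %.4f, duplicates %.4f, target proportion %.5f\n",
              object@conversionEfficiency, object@duplicateFraction,
              object@targetProportion))
  cat("  QC:", if (object@qcPass) "pass" else
    paste("fail -", paste(object@qcReasons, collapse = "; ")), "\n")
  if (!is.na(object@amplificationCall))
    cat("  call:", object@amplificationCall, "\n")
})

setMethod("show", "CohortReport", function(object) {
  cat("CohortReport (", object@arm, " arm): ",
      nrow(object@samples), " sample(s), ",
      nrow(object@excluded), " excluded\n", sep = "")
  if (nrow(object@samples)) print(head(object@samples, 10))
  if (nrow(object@comparisons)) {
    cat("group comparisons:\n")
    print(object@comparisons)
  }
})
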