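## Accessors and show methods. Slot access from user code should go through
## these rather than `@`.

#' @rdname AccuracyBound-class
#' @param object,x An `AccuracyBound`.
#' @param digits Number of decimal places kept in the truncated percent.
#' @details `accuracyPercent()` and `basesPerError()` truncate (rather than
#'   round) at the reported precision: the estimate is a lower bound on
#'   accuracy, so truncation keeps the reported figure conservative.
#' @export
accuracyPercent <- function(x, digits = 5) {
  stopifnot(is(x, "AccuracyBound"))
  floor(100 * (1 - x@aComplement) * 10^digits) / 10^digits
}

#' @rdname AccuracyBound-class
#' @export
phredScore <- function(x) {
  stopifnot(is(x, "AccuracyBound"))
  x@phred
}

#' @rdname AccuracyBound-class
#' @export
basesPerError <- function(x) {
  stopifnot(is(x, "AccuracyBound"))
  if (x@aComplement <= 0) return(Inf)
  floor(1 / x@aComplement)
}

#' @rdname AccuracyBound-class
#' @export
accuracyValue <- function(x) {
  stopifnot(is(x, "AccuracyBound"))
  x@aBound
}

#' @rdname AccuracyBound-class
#' @export
stopProbBound <- function(x) {
  stopifnot(is(x, "AccuracyBound"))
  x@tBound
}

setMethod("show", "AccuracyBound", function(object) {
  cat("AccuracyBound from", format(object@nCodons, big.mark = ","),
      "codons with", object@nStops, "internal stop(s)\n")
  cat(sprintf("  T bound:            %.6g per codon\n", object@tBound))
  cat(sprintf("  per-base accuracy:  >= %.5f%%\n", accuracyPercent(object)))
  cat(sprintf("  Phred score:        >= %.4f\n", round(object@phred, 4)))
  cat(sprintf("  < 1 error in:       %s bases\n",
              format(basesPerError(object), big.mark = ",")))
})

#' @rdname OrfCatalog-class
#' @param x An `OrfCatalog`.
#' @export
totalCodons <- function(x) {
  stopifnot(is(x, "OrfCatalog"))
  x@totalCodons
}

#' @rdname OrfCatalog-class
#' @export
internalStops <- function(x) {
  stopifnot(is(x, "OrfCatalog"))
  x@internalStops
}

#' @rdname OrfCatalog-class
#' @export
orfGenes <- function(x) {
  stopifnot(is(x, "OrfCatalog"))
  x@genes
}

setMethod("show", "OrfCatalog", function(object) {
  cat("OrfCatalog:", nrow(object@genes), "genes (",
      sum(object@genes$included), "included )\n")
  cat("  total codons:  ", format(object@totalCodons, big.mark = ","), "\n")
  cat("  internal stops:", object@internalStops, "\n")
})

#' @rdname GeneVerification-class
#' @param x A `GeneVerification`.
#' @export
geneStatus <- function(x) {
  stopifnot(is(x, "GeneVerification"))
  x@status
}

#' @rdname GeneVerification-class
#' @export
proteinIdentity <- function(x) {
  stopifnot(is(x, "GeneVerification"))
  x@identity
}

#' @rdname GeneVerification-class
#' @export
exonHits <- function(x) {
  stopifnot(is(x, "GeneVerification"))
  x@hits
}

setMethod("show", "GeneVerification", function(object) {
  cat(sprintf("GeneVerification %s: %s (%d exon hits, identity %.3f)\n",
              object@geneId, object@status, nrow(object@hits),
              object@identity))
  if (object@status != "complete" && nzchar(object@reason))
    cat("  reason:", object@reason, "\n")
})

#' @rdname KaryotypeStats-class
#' @param x A `KaryotypeStats`.
#' @export
nFusions <- function(x) {
  stopifnot(is(x, "KaryotypeStats"))
  x@nFusions
}

#' @rdname KaryotypeStats-class
#' @export
nFissions <- function(x) {
  stopifnot(is(x, "KaryotypeStats"))
  x@nFissions
}

setMethod("show", "KaryotypeStats", function(object) {
  cat("KaryotypeStats:\n")
  cat("  fusions:           ", object@nFusions, "\n")
  cat("  fissions:          ", object@nFissions, "\n")
  cat("  fundamental number:", object@fundamentalNumber, "\n")
  cat("  diploid number 2n: ", object@diploidNumber, "\n")
})

#' @rdname KaryotypeCorrespondence-class
#' @param x A `KaryotypeCorrespondence`.
#' @export
chromosomeSegments <- function(x) {
  stopifnot(is(x, "KaryotypeCorrespondence"))
  x@segments
}

#' @rdname KaryotypeCorrespondence-class
#' @export
chromosomeMorphology <- function(x) {
  stopifnot(is(x, "KaryotypeCorrespondence"))
  x@morphology
}

#' @rdname KaryotypeCorrespondence-class
#' @details `segmentChromosomes()` is the inverse map: for every ancestral
#'   segment, the chromosomes carrying it.
#' @export
segmentChromosomes <- function(x) {
  stopifnot(is(x, "KaryotypeCorrespondence"))
  segs <- unique(unlist(x@segments, use.names = FALSE))
  setNames(lapply(segs, function(s) {
    names(x@segments)[vapply(x@segments, function(v) s %in% v, logical(1))]
  }), segs)
}

setMethod("show", "KaryotypeCorrespondence", function(object) {
  cat("KaryotypeCorrespondence:", length(object@segments), "chromosomes,",
      length(unique(unlist(object@segments))), "ancestral segments\n")
})

#' @rdname HetSpectrum-class
#' @param x A `HetSpectrum`.
#' @export
spectrumCounts <- function(x) {
  stopifnot(is(x, "HetSpectrum"))
  x@counts
}

#' @rdname HetSpectrum-class
#' @details `ratePerMb()` returns `counts * 1e6 / referenceLength`.
#' @export
ratePerMb <- function(x) {
  stopifnot(is(x, "HetSpectrum"))
  x@counts * 1e6 / x@referenceLength
}

setMethod("show", "HetSpectrum", function(object) {
  cat("HetSpectrum over", format(object@referenceLength, big.mark = ","),
      "bp (size classes", -object@maxSize, "..", object@maxSize, ")\n")
  print(round(ratePerMb(object), 4))
})

#' @rdname TilingReport-class
#' @param x A `TilingReport`.
#' @export
tilingPass <- function(x) {
  stopifnot(is(x, "TilingReport"))
  x@pass
}

#' @rdname TilingReport-class
#' @export
minWindowDepth <- function(x) {
  stopifnot(is(x, "TilingReport"))
  x@minDepth
}

#' @rdname TilingReport-class
#' @export
uncoveredWindows <- function(x) {
  stopifnot(is(x, "TilingReport"))
  x@uncoveredWindows
}

setMethod("show", "TilingReport", function(object) {
  cat(sprintf(
    "TilingReport: %d-bp windows, step %d%s\n  min depth %.0f (threshold %.0f), %d uncovered window(s) -> %s\n",
    object@window, object@step,
    if (object@circular) ", circular" else "",
    object@minDepth, object@depthThreshold, object@uncoveredWindows,
    if (object@pass) "PASS" else "FAIL"))
})

#' @rdname TruthSet-class
#' @param x A `TruthSet`.
#' @export
geneModels <- function(x) {
  stopifnot(is(x, "TruthSet"))
  x@geneModels
}

#' @rdname TruthSet-class
#' @export
truthProteins <- function(x) {
  stopifnot(is(x, "TruthSet"))
  x@proteins
}

#' @rdname TruthSet-class
#' @export
contigOrigin <- function(x) {
  stopifnot(is(x, "TruthSet"))
  x@contigOrigin
}

#' @rdname TruthSet-class
#' @export
numtLoci <- function(x) {
  stopifnot(is(x, "TruthSet"))
  x@numts
}

#' @rdname TruthSet-class
#' @export
contaminantIds <- function(x) {
  stopifnot(is(x, "TruthSet"))
  x@contaminants
}

#' @rdname TruthSet-class
#' @export
variantTruth <- function(x) {
  stopifnot(is(x, "TruthSet"))
  x@variantTruth
}

#' @rdname TruthSet-class
#' @export
truthKaryotype <- function(x) {
  stopifnot(is(x, "TruthSet"))
  x@karyotype
}

setMethod("show", "TruthSet", function(object) {
  cat("TruthSet:",
      length(unique(object@geneModels$gene_id)), "genes,",
      length(object@numts), "NUMTs,",
      length(object@contaminants), "contaminant contig(s),",
      nrow(object@variantTruth), "variants\n")
})

setMethod("show", "SynthConfig", function(object) {
  cat("SynthConfig:", format(object@genomeLength, big.mark = ","), "bp,",
      object@nChromosomes, "ancestral segments,", object@nGenes, "genes,",
      object@nNumts, "NUMTs\n")
})

#' @rdname ExonQuerySet-class
#' @param x An `ExonQuerySet`.
#' @param gene A gene id.
#' @export
queryGenes <- function(x) {
  stopifnot(is(x, "ExonQuerySet"))
  unique(x@geneId)
}

#' @rdname ExonQuerySet-class
#' @export
queryProtein <- function(x, gene) {
  stopifnot(is(x, "ExonQuerySet"))
  unname(x@protein[gene])
}

#' @rdname ExonQuerySet-class
#' @export
geneExons <- function(x, gene) {
  stopifnot(is(x, "ExonQuerySet"))
  sel <- x@geneId == gene
  ord <- order(x@exonIndex[sel])
  x@seq[sel][ord]
}

setMethod("show", "ExonQuerySet", function(object) {
  cat("ExonQuerySet:", length(unique(object@geneId)), "genes,",
      length(object@seq), "exon probes\n")
})
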