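## Karyotype reconciliation: derive fusion/fission counts and the
## fundamental number from a chromosome <-> ancestral-segment correspondence.

#' Construct a karyotype correspondence
#'
#' @param segments Named list: chromosome -> ordered character vector of
#'   ancestral segment labels carried by that chromosome.
#' @param morphology Named character vector over the same chromosomes
#'   (`"submetacentric"`, `"acrocentric"` or `"metacentric"`); defaults to
#'   acrocentric for single-segment chromosomes and submetacentric for
#'   multi-segment (fused) chromosomes.
#' @return A [KaryotypeCorrespondence-class].
#' @export
karyotypeCorrespondence <- function(segments, morphology = NULL) {
  if (is.null(morphology)) {
    morphology <- vapply(segments, function(s)
      if (length(s) > 1L) "submetacentric" else "acrocentric", character(1))
  }
  new("KaryotypeCorrespondence", segments = segments, morphology = morphology)
}

#' Read a correspondence table from TSV
#'
#' Expected columns: `chromosome`, `segments` (comma-separated ordered
#' labels), and optionally `morphology`.
#'
#' @param path TSV file path.
#' @return A [KaryotypeCorrespondence-class].
#' @export
readCorrespondence <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chromosome", "segments") %in% names(df)))
  segs <- setNames(strsplit(df$segments, ","), df$chromosome)
  segs <- lapply(segs, trimws)
  morph <- if ("morphology" %in% names(df))
    setNames(df$morphology, df$chromosome) else NULL
  karyotypeCorrespondence(segs, morph)
}

#' The muskox autosome correspondence to the pecoran ancestral karyotype
#'
#' The established segment correspondence for the muskox (2n = 48): 23
#' autosome types, of which six submetacentric chromosomes each carry two
#' ancestral segments (the fusions N1+A2, R+B2, T+C2, V+C1, W+S and U+Q) and
#' segment U additionally occurs alone on an acrocentric chromosome (the one
#' fission), with the remaining 17 autosomes acrocentric and in one-to-one
#' correspondence with ancestral segments.
#'
#' @return A [KaryotypeCorrespondence-class] over the 23 muskox autosome
#'   types.
#' @export
muskoxKaryotype <- function() {
  fused <- list(
    chr1 = c("N1", "A2"),
    chr2 = c("R", "B2"),
    chr3 = c("T", "C2"),
    chr4 = c("V", "C1"),
    chr5 = c("W", "S"),
    chr6 = c("U", "Q"))
  singles <- c("A1", "B1", "C3", "D", "E", "F", "G", "H", "I", "J", "K",
               "L", "M", "N2", "O", "P", "U")
  segments <- c(fused, setNames(as.list(singles),
                                sprintf("chr%d", 6L + seq_along(singles))))
  morphology <- setNames(c(rep("submetacentric", length(fused)),
                           rep("acrocentric", length(singles))),
                         names(segments))
  karyotypeCorrespondence(segments, morphology)
}

#' Reconcile a karyotype against its ancestral segment set
#'
#' Fusions are chromosomes carrying more than one ancestral segment (each
#' extra segment on a chromosome is one fusion); fissions are ancestral
#' segments spread over more than one chromosome (each extra chromosome is
#' one fission). The counts satisfy the balance
#' `n_segments - n_chromosomes = n_fusions - n_fissions`. The fundamental
#' number and diploid number are derived from the morphology annotation
#' (inversions are not representable in a correspondence table and are not
#' counted).
#'
#' @param correspondence A [KaryotypeCorrespondence-class].
#' @return A [KaryotypeStats-class].
#' @export
reconcileKaryotype <- function(correspondence) {
  stopifnot(is(correspondence, "KaryotypeCorrespondence"))
  validObject(correspondence)
  segs <- chromosomeSegments(correspondence)
  if (!length(segs)) {
    return(new("KaryotypeStats", nFusions = 0L, nFissions = 0L,
               fundamentalNumber = 0L, diploidNumber = 0L))
  }
  fusions <- sum(vapply(segs, function(s) max(0L, length(s) - 1L), integer(1)))
  inv <- segmentChromosomes(correspondence)
  fissions <- sum(vapply(inv, function(ch) max(0L, length(ch) - 1L),
                         integer(1)))
  morph <- chromosomeMorphology(correspondence)
  nBiarmed <- sum(morph %in% c("submetacentric", "metacentric"))
  nAcro <- sum(morph == "acrocentric")
  new("KaryotypeStats",
      nFusions = as.integer(fusions), nFissions = as.integer(fissions),
      fundamentalNumber = as.integer(fundamentalNumber(nBiarmed, nAcro)),
      diploidNumber = as.integer(2L * (length(segs) + 1L)))
}

#' Diploid autosomal fundamental number
#'
#' The autosomal arm count of a diploid karyotype: biarmed chromosomes
#' (submetacentric or metacentric) contribute two arms per copy and
#' acrocentric chromosomes one, so `FN = 2 * (2 * nBiarmed + nAcrocentric)`
#' with counts given per haploid autosome type.
#'
#' @param nBiarmed Number of biarmed autosome types (haploid count).
#' @param nAcrocentric Number of acrocentric autosome types (haploid count).
#' @return The diploid autosomal arm count.
#' @examples
#' fundamentalNumber(6, 17)  # 58
#' @export
fundamentalNumber <- function(nBiarmed, nAcrocentric) {
  if (nBiarmed < 0 || nAcrocentric < 0) stop("counts must be non-negative")
  2 * (2 * nBiarmed + nAcrocentric)
}
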