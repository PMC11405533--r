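## S4 classes for the central result and configuration objects.

#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Biostrings DNAStringSet
NULL

#' Synthetic genome configuration
#'
#' Parameters controlling [makeGenome()] and its companions. Construct with
#' [synthConfig()]; all downstream generator behaviour is determined by the
#' configuration plus a single integer seed, so identical inputs give
#' byte-identical outputs.
#'
#' @slot genomeLength Total nuclear genome length in bp (across ancestral
#'   segments).
#' @slot nChromosomes Number of ancestral chromosome segments.
#' @slot nGenes Number of multi-exon genes planted into the derived assembly.
#' @slot exonsPerGene Inclusive integer range `c(lo, hi)` of exons per gene.
#' @slot exonLength Inclusive range of coding exon lengths (bp).
#' @slot intronLength Inclusive range of intron lengths (bp).
#' @slot spliceDonor,spliceAcceptor Consensus splice dinucleotides written at
#'   every intron boundary (defaults `"GT"`/`"AG"`).
#' @slot perBaseAccuracy Probability of a correct base call used when
#'   corrupting sequences.
#' @slot hetSnvPerMb Heterozygous SNV rate per megabase.
#' @slot hetIndelPerMb Named numeric vector of heterozygous indel rates per
#'   megabase, one entry per size class (names like `"-2"`, `"1"`).
#' @slot nNumts Number of nuclear-mitochondrial (NUMT) insertions.
#' @slot numtLength Inclusive range of NUMT lengths (bp).
#' @slot numtDivergence Per-base substitution probability applied to NUMT
#'   copies of the mitochondrion.
#' @slot mitoLength Length of the synthetic circular mitochondrion (bp).
#' @slot contaminantLength Length of the contaminant contig (bp; 0 disables).
#' @slot contigsPerChromosome Number of contigs each derived chromosome is
#'   split into.
#' @slot rearrangements List of rearrangement operations applied to the
#'   ancestral segment set; each element is a list with a `type` field of
#'   `"fusion"`, `"fission"` or `"inversion"` (see [makeGenome()]).
#' @slot depthMean Mean read depth used by coverage simulations.
#' @export
setClass("SynthConfig", representation(
  genomeLength = "numeric",
  nChromosomes = "integer",
  nGenes = "integer",
  exonsPerGene = "integer",
  exonLength = "integer",
  intronLength = "integer",
  spliceDonor = "character",
  spliceAcceptor = "character",
  perBaseAccuracy = "numeric",
  hetSnvPerMb = "numeric",
  hetIndelPerMb = "numeric",
  nNumts = "integer",
  numtLength = "integer",
  numtDivergence = "numeric",
  mitoLength = "integer",
  contaminantLength = "integer",
  contigsPerChromosome = "integer",
  rearrangements = "list",
  depthMean = "numeric"
))

setValidity("SynthConfig", function(object) {
  msg <- character(0)
  rates <- c(object@perBaseAccuracy, object@hetSnvPerMb, object@hetIndelPerMb,
             object@numtDivergence, object@depthMean)
  if (any(rates < 0)) msg <- c(msg, "all rates must be >= 0")
  if (object@perBaseAccuracy > 1) msg <- c(msg, "perBaseAccuracy must be <= 1")
  for (nm in c("exonsPerGene", "exonLength", "intronLength", "numtLength")) {
    r <- slot(object, nm)
    if (length(r) != 2L || r[2L] < r[1L] || r[1L] < 1L)
      msg <- c(msg, sprintf("%s must be a non-empty positive range", nm))
  }
  if (object@nChromosomes < 1L) msg <- c(msg, "need at least one chromosome")
  if (nchar(object@spliceDonor) != 2L || nchar(object@spliceAcceptor) != 2L)
    msg <- c(msg, "splice signals must be dinucleotides")
  ## every gene needs to fit: worst-case footprint must not exceed the genome
  worst <- object@nGenes * (object@exonsPerGene[2L] * object@exonLength[2L] +
    (object@exonsPerGene[2L] - 1L) * object@intronLength[2L])
  if (worst > object@genomeLength)
    msg <- c(msg, sprintf(
      "configuration infeasible: %d genes with worst-case footprint %d bp do not fit in %d bp",
      object@nGenes, worst, as.integer(object@genomeLength)))
  if (length(msg)) msg else TRUE
})

#' Truth bookkeeping for a synthetic genome
#'
#' Returned by [makeGenome()] inside its result list. Records everything the
#' generator planted so downstream stages can be scored against known truth.
#'
#' @slot geneModels A [GenomicRanges::GRanges] of planted exons with metadata
#'   columns `gene_id` and `exon_rank` (0-based half-open coordinates are used
#'   internally; the GRanges itself is 1-based closed as usual for Bioconductor).
#' @slot proteins Named character vector of the translated CDS per gene
#'   (terminal stop removed).
#' @slot contigOrigin data.frame mapping each contig interval to its derived
#'   chromosome and ancestral segment interval.
#' @slot numts [GenomicRanges::GRanges] of implanted NUMT loci.
#' @slot contaminants Character vector of contaminant contig ids.
#' @slot karyotype Named list: derived chromosome -> ordered ancestral segment
#'   labels.
#' @slot variantTruth data.frame of planted variants (filled by
#'   [makeVariants()]).
#' @export
setClass("TruthSet", representation(
  geneModels = "GRanges",
  proteins = "character",
  contigOrigin = "data.frame",
  numts = "GRanges",
  contaminants = "character",
  karyotype = "list",
  variantTruth = "data.frame"
))

#' Accuracy bound inferred from stop-free ORFs
#'
#' Result of [accuracyBound()]. Full precision is retained in the slots;
#' [accuracyPercent()] and [basesPerError()] report at the conventional
#' printed precision, truncated toward the conservative side (the bound is a
#' lower bound on accuracy).
#'
#' @slot tBound Upper bound on the per-codon spurious-stop probability.
#' @slot aBound Lower bound on per-base accuracy (probability).
#' @slot aComplement `1 - aBound` kept at full *relative* precision (a
#'   double near 1 cannot represent its own complement accurately; this slot
#'   is what Phred and bases-per-error are derived from).
#' @slot phred Phred-scaled accuracy, `-10*log10(aComplement)`.
#' @slot nCodons,nStops Inputs the bound was computed from.
#' @export
setClass("AccuracyBound", representation(
  tBound = "numeric",
  aBound = "numeric",
  aComplement = "numeric",
  phred = "numeric",
  nCodons = "numeric",
  nStops = "numeric"
))

setValidity("AccuracyBound", function(object) {
  msg <- character(0)
  if (object@aBound < 0 || object@aBound > 1)
    msg <- c(msg, "aBound must be in [0, 1]")
  if (abs((1 - object@aComplement) - object@aBound) > 1e-9)
    msg <- c(msg, "aComplement inconsistent with aBound")
  if (object@aComplement > 0 &&
      abs(object@phred - (-10 * log10(object@aComplement))) > 1e-8)
    msg <- c(msg, "phred inconsistent with aComplement")
  if (length(msg)) msg else TRUE
})

#' Catalogue of ORF codon counts
#'
#' Result of [countOrfCodons()]: per-gene codon and internal-stop counts, with
#' totals over the genes that passed structural checks.
#'
#' @slot genes data.frame with one row per gene: `gene_id`, `n_codons`,
#'   `internal_stops`, `has_start`, `has_stop`, `in_frame`, `included`,
#'   `reason`.
#' @slot totalCodons Total codons across included genes.
#' @slot internalStops Total internal (non-terminal) stop codons across
#'   included genes.
#' @export
setClass("OrfCatalog", representation(
  genes = "data.frame",
  totalCodons = "numeric",
  internalStops = "numeric"
))

setValidity("OrfCatalog", function(object) {
  g <- object@genes[object@genes$included, , drop = FALSE]
  if (!isTRUE(all.equal(object@totalCodons, sum(g$n_codons))))
    return("totalCodons must equal the sum over included genes")
  if (!isTRUE(all.equal(object@internalStops, sum(g$internal_stops))))
    return("internalStops must equal the sum over included genes")
  TRUE
})

#' Exon queries for homology-based gene verification
#'
#' Ordered exon probes for one or more genes, with the full-length query
#' protein per gene. Build with [exonQuerySet()] or derive from a synthetic
#' truth set with [exonQueriesFromTruth()].
#'
#' @slot geneId Character vector, one entry per exon.
#' @slot exonIndex Integer ordinal of each exon within its gene (1-based).
#' @slot seq [Biostrings::DNAStringSet] of exon nucleotide sequences.
#' @slot protein Named character vector of full-length query proteins, one per
#'   gene.
#' @export
setClass("ExonQuerySet", representation(
  geneId = "character",
  exonIndex = "integer",
  seq = "DNAStringSet",
  protein = "character"
))

setValidity("ExonQuerySet", function(object) {
  msg <- character(0)
  n <- length(object@geneId)
  if (length(object@exonIndex) != n || length(object@seq) != n)
    msg <- c(msg, "geneId, exonIndex and seq must have equal length")
  if (!all(unique(object@geneId) %in% names(object@protein)))
    msg <- c(msg, "every gene needs a query protein")
  for (g in unique(object@geneId)) {
    idx <- sort(object@exonIndex[object@geneId == g])
    if (!identical(idx, seq_along(idx)))
      msg <- c(msg, sprintf("exon indices of gene %s must be 1..k", g))
  }
  if (length(msg)) msg else TRUE
})

#' Exon-walking verification result for one gene
#'
#' Produced by [classifyGene()] / [verifyGenes()]. `status` is `"complete"`
#' only when the assembled CDS starts with an initiation codon, ends with a
#' termination codon, has no internal stop, every exon was found with
#' conserved reading frame and consensus splice signals, and the translated
#' protein is at least `minIdentity` identical to the full-length query.
#'
#' @slot geneId Gene identifier.
#' @slot hits data.frame of accepted exon hits (0-based half-open
#'   coordinates), one row per found exon.
#' @slot cds Assembled coding sequence (character).
#' @slot protein Translation of the assembled CDS (terminal stop stripped).
#' @slot identity Global protein identity to the full-length query.
#' @slot hasStart,hasStop Logical ORF-structure flags.
#' @slot status One of `"complete"`, `"fragmented"`, `"missing"`.
#' @slot reason Short machine-readable reason when not complete.
#' @export
setClass("GeneVerification", representation(
  geneId = "character",
  hits = "data.frame",
  cds = "character",
  protein = "character",
  identity = "numeric",
  hasStart = "logical",
  hasStop = "logical",
  status = "character",
  reason = "character"
))

setValidity("GeneVerification", function(object) {
  if (!object@status %in% c("complete", "fragmented", "missing"))
    return("status must be complete, fragmented or missing")
  if (object@status == "complete" &&
      !(object@hasStart && object@hasStop && object@identity >= 0))
    return("complete requires start and stop codons")
  if (object@status == "missing" && nrow(object@hits) > 0)
    return("missing means no exon hit at all")
  TRUE
})

#' Chromosome-to-ancestral-segment correspondence
#'
#' Maps each derived chromosome to its ordered list of conserved ancestral
#' segments, with per-chromosome morphology. Fusion and fission counts and the
#' fundamental number are derived with [reconcileKaryotype()].
#'
#' @slot segments Named list: chromosome -> character vector of ancestral
#'   segment labels carried by that chromosome (ordered from the centromere).
#' @slot morphology Named character vector over the same chromosomes with
#'   values `"submetacentric"`, `"acrocentric"` or `"metacentric"`.
#' @export
setClass("KaryotypeCorrespondence", representation(
  segments = "list",
  morphology = "character"
))

setValidity("KaryotypeCorrespondence", function(object) {
  msg <- character(0)
  if (length(object@segments) &&
      !identical(sort(names(object@segments)), sort(names(object@morphology))))
    msg <- c(msg, "segments and morphology must cover the same chromosomes")
  dup <- vapply(object@segments, function(s) anyDuplicated(s) > 0, logical(1))
  if (any(dup))
    msg <- c(msg, "segment labels must be unique within a chromosome")
  bad <- setdiff(object@morphology,
                 c("submetacentric", "acrocentric", "metacentric"))
  if (length(bad)) msg <- c(msg, "unknown morphology value")
  if (length(msg)) msg else TRUE
})

#' Karyotype reconciliation statistics
#'
#' @slot nFusions Number of fusion events implied by the correspondence.
#' @slot nFissions Number of fission events.
#' @slot fundamentalNumber Diploid autosomal arm count.
#' @slot diploidNumber 2n, counting one sex-chromosome pair.
#' @export
setClass("KaryotypeStats", representation(
  nFusions = "integer",
  nFissions = "integer",
  fundamentalNumber = "integer",
  diploidNumber = "integer"
))

#' Heterozygosity spectrum by variant size
#'
#' Counts of heterozygous variants binned by size class (negative sizes are
#' deletions, 0 is an SNV, positive sizes insertions), with rates per megabase
#' of reference sequence.
#'
#' @slot counts Named integer vector over size classes `-k .. k`.
#' @slot referenceLength Reference length in bp used for normalisation.
#' @slot maxSize Clipping bound k.
#' @export
setClass("HetSpectrum", representation(
  counts = "integer",
  referenceLength = "numeric",
  maxSize = "integer"
))

setValidity("HetSpectrum", function(object) {
  k <- object@maxSize
  if (!identical(names(object@counts), as.character(seq(-k, k))))
    return("counts must be named -k..k")
  if (any(object@counts < 0)) return("counts must be >= 0")
  if (object@referenceLength <= 0) return("referenceLength must be > 0")
  TRUE
})

#' Coverage tiling validation report
#'
#' @slot window Moving-window width (bp).
#' @slot step Window step (bp).
#' @slot minDepth Minimum over per-window depths (reads fully covering the
#'   window).
#' @slot uncoveredWindows Number of windows with zero depth.
#' @slot depthThreshold Depth the minimum is compared against.
#' @slot circular Whether windows wrap across the origin.
#' @slot pass TRUE iff no window is uncovered and the minimum depth exceeds
#'   the threshold.
#' @export
setClass("TilingReport", representation(
  window = "integer",
  step = "integer",
  minDepth = "numeric",
  uncoveredWindows = "integer",
  depthThreshold = "numeric",
  circular = "logical",
  pass = "logical"
))

setValidity("TilingReport", function(object) {
  expected <- object@uncoveredWindows == 0L && object@minDepth > object@depthThreshold
  if (!identical(object@pass, expected))
    return("pass must equal (uncovered == 0 and min depth > threshold)")
  TRUE
})
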