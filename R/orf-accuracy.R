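## Residual sequencing-error estimation from stop-free open reading frames.
##
## The model: a codon is correct only if all three base calls are correct
## (probability A^3). Of the 63 possible wrong codons at a position, 3 are
## termination codons, so the probability that sequencing error turns an
## in-frame non-stop codon into a spurious stop is
##
##     T = (1 - A^3) * 3/63.
##
## Observing zero internal stops across N annotated codons therefore bounds
## T below 1/N, and inverting the formula gives a lower bound on A.

STOP_FRACTION <- 3 / 63

#' Probability of a spurious in-frame termination codon
#'
#' `T = (1 - A^3) * 3/63`, where `A` is the per-base accuracy. `T` is 0 at
#' `A = 1` and `3/63` at `A = 0`, and is monotone non-increasing in `A`.
#'
#' @param A Per-base accuracy (vectorised), each value in `[0, 1]`, or an
#'   [AccuracyBound-class] (whose full-precision accuracy complement is then
#'   used, so composing with [accuracyBound()] round-trips the stop
#'   probability to better than 1e-12 relative error).
#' @return The spurious-stop probability per codon.
#' @export
spuriousStopProb <- function(A) {
  if (is(A, "AccuracyBound")) {
    ## 1 - A^3 = 3d - 3d^2 + d^3 with d = 1 - A, exact for small d
    d <- A@aComplement
    return((3 * d - 3 * d^2 + d^3) * STOP_FRACTION)
  }
  if (!is.numeric(A) || any(is.na(A)) || any(A < 0) || any(A > 1))
    stop("A must be a probability in [0, 1]")
  ## -expm1(3 log A) = 1 - A^3, computed without cancellation near A = 1
  out <- ifelse(A > 0, -expm1(3 * log(A)), 1) * STOP_FRACTION
  unname(out)
}

#' Accuracy lower bound from stop-free codon counts
#'
#' With `nStops = 0` internal stops over `nCodons` codons, the spurious-stop
#' probability is bounded by `T < 1/nCodons`; substituting into
#' `T = (1 - A^3) * 3/63` and solving gives
#' `A = (1 - 21 * T)^(1/3)`. For `nStops > 0` the point estimate
#' `T = nStops/nCodons` is used instead (an extension of the zero-stop
#' bound). When `21 * T > 1` (fewer than 21 codons) the bound is vacuous and
#' `A` is clamped to 0 with a warning.
#'
#' @param nCodons Number of annotated codons observed (must be > 0).
#' @param nStops Number of internal stop codons observed (default 0).
#' @return An [AccuracyBound-class]; report with [accuracyPercent()],
#'   [phredScore()] and [basesPerError()].
#' @examples
#' b <- accuracyBound(782521)
#' accuracyPercent(b)   # 99.99910
#' round(phredScore(b), 4)  # 50.4839
#' basesPerError(b)     # 111787
#' @export
accuracyBound <- function(nCodons, nStops = 0) {
  stopifnot(length(nCodons) == 1L, length(nStops) == 1L)
  if (nCodons <= 0) stop("nCodons must be > 0")
  if (nStops >= nCodons) stop("nStops must be < nCodons")
  tBound <- max(nStops, 1) / nCodons
  if (tBound / STOP_FRACTION > 1) {
    warning("fewer than 21 codons: accuracy bound clamped to 0")
    aBound <- 0
    aComplement <- 1
  } else {
    ## (1 - 21 T)^(1/3) via log1p/expm1, stable for small T; the complement
    ## 1 - A is kept at full relative precision
    logA <- log1p(-tBound / STOP_FRACTION) / 3
    aBound <- exp(logA)
    aComplement <- -expm1(logA)
  }
  phred <- if (aComplement <= 0) Inf else -10 * log10(aComplement)
  new("AccuracyBound", tBound = tBound, aBound = aBound,
      aComplement = aComplement, phred = phred,
      nCodons = as.numeric(nCodons), nStops = as.numeric(nStops))
}

## Extract the spliced CDS of one gene from the assembly (exons in rank
## order; strand-aware).
extractCds <- function(assembly, exons) {
  ord <- order(exons$exon_rank)
  exons <- exons[ord, , drop = FALSE]
  pieces <- vapply(seq_len(nrow(exons)), function(i) {
    s <- as.character(Biostrings::subseq(assembly[[exons$contig[i]]],
                                         start = exons$start[i],
                                         end = exons$end[i]))
    if (exons$strand[i] == "-") revcompChar(s) else s
  }, character(1))
  if (any(exons$strand == "-")) pieces <- rev(pieces)
  paste(pieces, collapse = "")
}

#' Tabulate codons and internal stops over annotated CDS models
#'
#' Splices each gene's CDS out of the assembly, translates it, and counts
#' codons and internal (non-terminal) stop codons. Genes whose CDS length is
#' not divisible by 3 are excluded from the totals with a per-gene reason;
#' genes lacking an initiation or terminal termination codon are flagged but
#' still counted.
#'
#' @param assembly A [Biostrings::DNAStringSet].
#' @param cds CDS coordinates: a [GenomicRanges::GRanges] with metadata
#'   columns `gene_id` and `exon_rank` (as produced by the synthetic truth
#'   set), or a data.frame with columns `contig`, `start`, `end` (1-based
#'   closed), `strand`, `gene_id`, `exon_rank`.
#' @return An [OrfCatalog-class].
#' @export
countOrfCodons <- function(assembly, cds) {
  if (is(cds, "GRanges")) {
    cds <- data.frame(contig = as.character(GenomicRanges::seqnames(cds)),
                      start = GenomicRanges::start(cds),
                      end = GenomicRanges::end(cds),
                      strand = as.character(GenomicRanges::strand(cds)),
                      gene_id = cds$gene_id, exon_rank = cds$exon_rank,
                      stringsAsFactors = FALSE)
  }
  cds$strand[cds$strand == "*"] <- "+"
  geneIds <- unique(cds$gene_id)
  rows <- lapply(geneIds, function(gid) {
    exons <- cds[cds$gene_id == gid, , drop = FALSE]
    seq <- extractCds(assembly, exons)
    n <- nchar(seq)
    if (n %% 3L != 0L) {
      return(data.frame(gene_id = gid, n_codons = 0L, internal_stops = 0L,
                        has_start = NA, has_stop = NA, in_frame = FALSE,
                        included = FALSE, reason = "length not divisible by 3",
                        stringsAsFactors = FALSE))
    }
    codons <- splitCodons(seq)
    nCod <- length(codons)
    hasStart <- nCod > 0L && codons[1L] == "ATG"
    hasStop <- nCod > 0L && codons[nCod] %in% STOP_CODONS
    internal <- if (nCod > 1L) sum(codons[-nCod] %in% STOP_CODONS) else 0L
    reason <- if (!hasStart || !hasStop) "ORF structure violation" else ""
    data.frame(gene_id = gid, n_codons = nCod, internal_stops = internal,
               has_start = hasStart, has_stop = hasStop, in_frame = TRUE,
               included = TRUE, reason = reason, stringsAsFactors = FALSE)
  })
  genes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), n_codons = integer(0),
               internal_stops = integer(0), has_start = logical(0),
               has_stop = logical(0), in_frame = logical(0),
               included = logical(0), reason = character(0))
  inc <- genes[genes$included, , drop = FALSE]
  new("OrfCatalog", genes = genes,
      totalCodons = sum(inc$n_codons),
      internalStops = sum(inc$internal_stops))
}

#' Monte-Carlo validation of the spurious-stop model
#'
#' Simulates sequencing error over a set of non-stop codons: each codon is
#' independently incorrect with probability `1 - A^3`, and an incorrect
#' codon is replaced by one of its 63 alternatives uniformly. Premature
#' (non-terminal) stop counts per replicate are compared with the analytic
#' expectation `nCodons * spuriousStopProb(A)`.
#'
#' @param catalog An [OrfCatalog-class], or a plain codon count.
#' @param A Per-base accuracy.
#' @param replicates Number of replicates.
#' @param seed Integer seed.
#' @return A list with `observed` (integer vector of premature-stop counts
#'   per replicate), `expected` (analytic mean count), and `sigma` (binomial
#'   standard deviation of a single replicate).
#' @export
simulateStopInjection <- function(catalog, A, replicates = 10L, seed = 1L) {
  n <- if (is(catalog, "OrfCatalog")) totalCodons(catalog) else catalog
  stopifnot(n > 0)
  if (A < 0 || A > 1) stop("A must be in [0, 1]")
  set.seed(as.integer(seed))
  tAnalytic <- spuriousStopProb(A)
  ## sample original codons uniformly from the non-stop alphabet once per
  ## replicate; only incorrect codons need their replacement drawn
  stopIdx <- match(STOP_CODONS, ALL_CODONS)
  observed <- vapply(seq_len(replicates), function(r) {
    nBad <- rbinom(1L, n, 1 - A^3)
    if (nBad == 0L) return(0L)
    orig <- sample(match(NONSTOP_CODONS, ALL_CODONS), nBad, replace = TRUE)
    repl <- ((orig - 1L + sample.int(63L, nBad, replace = TRUE)) %% 64L) + 1L
    sum(repl %in% stopIdx)
  }, integer(1))
  list(observed = observed, expected = n * tAnalytic,
       sigma = sqrt(n * tAnalytic * (1 - tAnalytic)))
}
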