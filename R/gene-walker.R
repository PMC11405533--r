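## Exon-level gene verification: find the best-scoring seed exon, walk
## outward in incremental windows for the adjacent exons, check splice
## signals and reading frame at every junction, and classify the gene as
## complete / fragmented / missing.
##
## The search engine is anchored local alignment: short exact probe k-mers
## locate candidate regions (the seed-and-extend idea behind BLAST-style
## searches), and an affine-gap Smith-Waterman (Biostrings::pairwiseAlignment)
## scores the full exon against each candidate region.

nucMatrix <- local({
  mat <- NULL
  function() {
    if (is.null(mat))
      mat <<- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                       mismatch = -1,
                                                       baseOnly = TRUE)
    mat
  }
})

alignLocal <- function(query, subject) {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(query),
    subject = subject,
    type = "local", substitutionMatrix = nucMatrix(),
    gapOpening = 2, gapExtension = 0.5)
}

## Candidate windows (1-based closed IRanges) on `contig` where `query` may
## align, from exact matches of evenly spaced probe k-mers.
anchorWindows <- function(contig, query, k = 16L, nProbes = 5L, pad = 40L) {
  qlen <- nchar(query)
  if (qlen < k) return(IRanges::IRanges())
  offs <- unique(floor(seq(1L, qlen - k + 1L, length.out = min(nProbes, qlen - k + 1L))))
  hits <- lapply(offs, function(o) {
    m <- Biostrings::matchPattern(substr(query, o, o + k - 1L), contig)
    s <- Biostrings::start(m) - (o - 1L)
    s[s >= 1L - pad]
  })
  starts <- unlist(hits, use.names = FALSE)
  if (!length(starts)) return(IRanges::IRanges())
  iv <- IRanges::IRanges(start = pmax(1L, starts - pad),
                         end = pmin(length(contig), starts + qlen - 1L + pad))
  IRanges::reduce(iv)
}

## Best local hit of `query` (already oriented) inside region [from, to]
## (1-based closed) of `contig`. Uses direct DP when the region is small and
## anchored DP otherwise. Returns NULL or list(start, end (0-based half-open),
## score, identity, length).
bestHitInRegion <- function(contig, query, from, to, directLimit = 60000L) {
  from <- max(1L, as.integer(from)); to <- min(length(contig), as.integer(to))
  if (to - from + 1L < 10L) return(NULL)
  region <- Biostrings::subseq(contig, start = from, end = to)
  windows <- if (length(region) <= directLimit) {
    IRanges::IRanges(1L, length(region))
  } else {
    anchorWindows(region, query)
  }
  best <- NULL
  for (i in seq_along(windows)) {
    ws <- IRanges::start(windows)[i]; we <- IRanges::end(windows)[i]
    aln <- alignLocal(query, Biostrings::subseq(region, ws, we))
    sc <- Biostrings::score(aln)
    if (is.null(best) || sc > best$score) {
      sstart <- from + ws - 1L + Biostrings::start(Biostrings::subject(aln)) - 1L
      send <- from + ws - 1L + Biostrings::end(Biostrings::subject(aln))
      best <- list(start = sstart - 1L, end = send - 1L,  # 0-based half-open
                   score = sc,
                   identity = Biostrings::pid(aln, type = "PID1") / 100,
                   length = send - sstart)
    }
  }
  best
}

#' Locate the seed exon of a gene
#'
#' Scores every exon probe of the gene against both strands of every contig
#' and returns the highest-scoring local hit. Ties are broken
#' deterministically: longer alignment, then leftmost coordinate, then the
#' `+` strand.
#'
#' @param assembly A [Biostrings::DNAStringSet].
#' @param queries An [ExonQuerySet-class].
#' @param gene Gene id to search for.
#' @param minScoreFrac Minimum hit score as a fraction of the exon length
#'   (match = +1 scoring); below this the gene has no seed and is a
#'   candidate for "missing".
#' @return A one-row data.frame (`gene_id`, `exon_index`, `contig`, `start`,
#'   `end` 0-based half-open, `strand`, `score`, `identity`, `frame_offset`,
#'   `extension`), or `NULL` when nothing scores above threshold.
#' @export
#' @rdname findSeedExon
#' @details `seedIndex()` pre-computes the probe dictionary and its anchor
#'   positions over the whole assembly for *all* genes in the query set;
#'   pass the result to repeated [findSeedExon()] calls (as [verifyGenes()]
#'   does) so every contig is scanned once.
#' @export
seedIndex <- function(assembly, queries, k = 16L, nProbes = 4L) {
  stopifnot(is(queries, "ExonQuerySet"))
  probes <- character(0)
  probeExon <- integer(0); probeStrand <- character(0); probeOff <- integer(0)
  oriented <- list()
  for (i in seq_along(queries@geneId)) {
    q <- as.character(queries@seq[[i]])
    qlen <- nchar(q)
    if (qlen < k) next
    for (strand in c("+", "-")) {
      o <- if (strand == "+") q else revcompChar(q)
      oriented[[paste0(i, strand)]] <- o
      offs <- unique(floor(seq(1L, qlen - k + 1L,
                               length.out = min(nProbes, qlen - k + 1L))))
      probes <- c(probes, substring(o, offs, offs + k - 1L))
      probeExon <- c(probeExon, rep(i, length(offs)))
      probeStrand <- c(probeStrand, rep(strand, length(offs)))
      probeOff <- c(probeOff, offs)
    }
  }
  anchors <- list()
  if (length(probes)) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(probes))
    for (ctg in names(assembly)) {
      anchors[[ctg]] <- Biostrings::startIndex(
        Biostrings::matchPDict(pd, assembly[[ctg]]))
    }
  }
  list(probeExon = probeExon, probeStrand = probeStrand,
       probeOff = probeOff, oriented = oriented, anchors = anchors, k = k)
}

findSeedExon <- function(assembly, queries, gene, minScoreFrac = 0.5,
                         index = NULL) {
  stopifnot(is(queries, "ExonQuerySet"))
  sel <- which(queries@geneId == gene)
  if (!length(sel)) stop("gene has no exon queries: ", gene)
  if (is.null(index)) index <- seedIndex(assembly, queries)
  pad <- 40L
  mine <- index$probeExon %in% sel
  cand <- list()
  for (ctg in names(assembly)) {
    starts <- index$anchors[[ctg]]
    if (is.null(starts)) next
    contig <- assembly[[ctg]]
    hitPat <- which(mine & lengths(starts) > 0L)
    if (!length(hitPat)) next
    for (key in unique(paste0(index$probeExon[hitPat],
                              index$probeStrand[hitPat]))) {
      pats <- hitPat[paste0(index$probeExon[hitPat],
                            index$probeStrand[hitPat]) == key]
      i <- index$probeExon[pats[1L]]
      strand <- index$probeStrand[pats[1L]]
      q <- index$oriented[[key]]
      qlen <- nchar(q)
      anchorStarts <- unlist(lapply(pats, function(p)
        starts[[p]] - (index$probeOff[p] - 1L)), use.names = FALSE)
      wins <- IRanges::reduce(IRanges::IRanges(
        start = pmax(1L, anchorStarts - pad),
        end = pmin(length(contig), anchorStarts + qlen - 1L + pad)))
      for (w in seq_along(wins)) {
        hit <- bestHitInRegion(contig, q,
                               IRanges::start(wins)[w],
                               IRanges::end(wins)[w])
        if (is.null(hit) || hit$score < minScoreFrac * qlen) next
        cand[[length(cand) + 1L]] <- data.frame(
          gene_id = gene, exon_index = queries@exonIndex[i], contig = ctg,
          start = hit$start, end = hit$end, strand = strand,
          score = hit$score, identity = hit$identity,
          frame_offset = (hit$length - qlen) %% 3L, extension = 0L,
          splice_ok = NA, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cand)) return(NULL)
  all <- do.call(rbind, cand)
  ord <- order(-all$score, -(all$end - all$start), all$start,
               match(all$strand, c("+", "-")))
  all[ord[1L], , drop = FALSE]
}

## Observed donor/acceptor dinucleotides at the junction between the hit of
## transcript-order exon a and the next exon b (both 0-based half-open, same
## contig, same strand).
junctionDinucs <- function(contig, a, b, strand) {
  L <- length(contig)
  getseq <- function(from, to) {
    if (from < 1L || to > L) return("")
    as.character(Biostrings::subseq(contig, from, to))
  }
  if (strand == "+") {
    donor <- getseq(a$end + 1L, a$end + 2L)
    acceptor <- getseq(b$start - 1L, b$start)
  } else {
    donor <- revcompChar(getseq(a$start - 1L, a$start))
    acceptor <- revcompChar(getseq(b$end + 1L, b$end + 2L))
  }
  list(donor = donor, acceptor = acceptor)
}

#' Walk outward from a seed exon to recover the full exon chain
#'
#' From the seed hit, searches for each adjacent exon in an incremental
#' window: the search region starts one `window` wide and grows by one
#' window per failed attempt, up to `maxExtension` or the contig end. A hit
#' is accepted only when its score clears `minScoreFrac`, its length
#' preserves the reading frame of the query exon (length difference
#' divisible by 3), and the intron boundaries it implies carry the consensus
#' donor/acceptor dinucleotides. Walking proceeds in both directions until
#' all exons are identified or a direction is exhausted (partial chains are
#' candidates for "fragmented").
#'
#' @param assembly A [Biostrings::DNAStringSet].
#' @param seed Seed hit from [findSeedExon()].
#' @param queries An [ExonQuerySet-class].
#' @param window Incremental search window (bp), default 10000.
#' @param maxExtension Maximum total extension per intron (bp).
#' @param minScoreFrac Minimum acceptable score as a fraction of exon length.
#' @param spliceDonor,spliceAcceptor Consensus splice dinucleotides.
#' @return data.frame of accepted hits ordered by exon index, with the
#'   per-exon `extension` counter (number of window increments used).
#' @export
walkExons <- function(assembly, seed, queries, window = 10000L,
                      maxExtension = 1e6, minScoreFrac = 0.5,
                      spliceDonor = "GT", spliceAcceptor = "AG") {
  stopifnot(window > 0, !is.null(seed))
  gene <- seed$gene_id
  nExons <- max(queries@exonIndex[queries@geneId == gene])
  contig <- assembly[[seed$contig]]
  strand <- seed$strand
  chain <- vector("list", nExons)
  chain[[seed$exon_index]] <- seed

  walkOne <- function(prev, idx, transcriptDir) {
    qi <- which(queries@geneId == gene & queries@exonIndex == idx)
    q <- as.character(queries@seq[[qi]])
    qlen <- nchar(q)
    oriented <- if (strand == "+") q else revcompChar(q)
    ## transcript-downstream is genomic-right on '+', genomic-left on '-'
    genomicRight <- (transcriptDir > 0) == (strand == "+")
    n <- 0L
    repeat {
      n <- n + 1L
      span <- n * window
      if (span - window >= maxExtension) return(NULL)
      if (genomicRight) {
        from <- prev$end + 1L
        to <- prev$end + min(span, maxExtension)
        exhausted <- from > length(contig)
      } else {
        from <- prev$start - min(span, maxExtension) + 1L
        to <- prev$start
        exhausted <- to < 1L
      }
      if (exhausted) return(NULL)
      hit <- bestHitInRegion(contig, oriented, from, to)
      if (!is.null(hit) && hit$score >= minScoreFrac * qlen) {
        cand <- data.frame(
          gene_id = gene, exon_index = idx, contig = seed$contig,
          start = hit$start, end = hit$end, strand = strand,
          score = hit$score, identity = hit$identity,
          frame_offset = (hit$length - qlen) %% 3L, extension = n,
          splice_ok = NA, stringsAsFactors = FALSE)
        a <- if (transcriptDir > 0) prev else cand
        b <- if (transcriptDir > 0) cand else prev
        dn <- junctionDinucs(contig, a, b, strand)
        cand$splice_ok <- identical(dn$donor, spliceDonor) &&
          identical(dn$acceptor, spliceAcceptor)
        if (cand$frame_offset == 0L && cand$splice_ok) return(cand)
        ## an off-frame or non-canonical candidate: keep extending in case
        ## the true exon lies further out
      }
      atEnd <- if (genomicRight) to >= length(contig) else from <= 1L
      if (atEnd) return(NULL)
    }
  }

  for (idx in seq(seed$exon_index + 1L, length.out = nExons - seed$exon_index)) {
    nxt <- walkOne(chain[[idx - 1L]], idx, +1L)
    if (is.null(nxt)) break
    chain[[idx]] <- nxt
  }
  for (idx in rev(seq_len(seed$exon_index - 1L))) {
    nxt <- walkOne(chain[[idx + 1L]], idx, -1L)
    if (is.null(nxt)) break
    chain[[idx]] <- nxt
  }
  found <- !vapply(chain, is.null, logical(1))
  if (!any(found)) return(seed[0, , drop = FALSE])
  do.call(rbind, chain[found])
}

## Global protein identity of `prot` against the full-length query protein:
## matches / query length (end gaps against the query are penalised by
## construction of the denominator).
proteinIdentityTo <- function(prot, queryProt) {
  if (!nzchar(prot) || !nzchar(queryProt)) return(0)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(prot),
    subject = Biostrings::AAString(queryProt),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  Biostrings::nmatch(aln) / nchar(queryProt)
}

#' Classify a gene from its recovered exon chain
#'
#' Assembles the CDS from the accepted exon hits in order, translates it,
#' computes global protein identity against the full-length query, and
#' applies the completeness rule: `complete` requires an initiation codon, a
#' terminal termination codon, no internal stop, every exon found with
#' conserved frame and canonical splice signals, and protein identity of at
#' least `minIdentity` (default 70%). A gene with no seed is `missing`;
#' anything else is `fragmented` with a reason code (frameshifts never raise
#' an error).
#'
#' @param assembly A [Biostrings::DNAStringSet].
#' @param chain Hits from [walkExons()] (possibly empty or `NULL`).
#' @param queries An [ExonQuerySet-class].
#' @param gene Gene id.
#' @param minIdentity Minimum protein identity for completeness.
#' @return A [GeneVerification-class].
#' @export
classifyGene <- function(assembly, chain, queries, gene, minIdentity = 0.70) {
  queryProt <- queryProtein(queries, gene)
  nExons <- max(queries@exonIndex[queries@geneId == gene])
  if (is.null(chain) || nrow(chain) == 0L) {
    return(new("GeneVerification", geneId = gene,
               hits = data.frame(), cds = "", protein = "",
               identity = 0, hasStart = FALSE, hasStop = FALSE,
               status = "missing", reason = "no seed exon"))
  }
  chain <- chain[order(chain$exon_index), , drop = FALSE]
  pieces <- vapply(seq_len(nrow(chain)), function(i) {
    s <- as.character(Biostrings::subseq(assembly[[chain$contig[i]]],
                                         start = chain$start[i] + 1L,
                                         end = chain$end[i]))
    if (chain$strand[i] == "-") revcompChar(s) else s
  }, character(1))
  cds <- paste(pieces, collapse = "")

  fragment <- function(reason, protein = "", identity = 0,
                       hasStart = FALSE, hasStop = FALSE) {
    new("GeneVerification", geneId = gene, hits = chain, cds = cds,
        protein = protein, identity = identity, hasStart = hasStart,
        hasStop = hasStop, status = "fragmented", reason = reason)
  }

  if (nchar(cds) %% 3L != 0L) return(fragment("frameshift in assembled CDS"))
  codons <- splitCodons(cds)
  hasStart <- length(codons) > 0L && codons[1L] == "ATG"
  hasStop <- length(codons) > 0L && codons[length(codons)] %in% STOP_CODONS
  internal <- length(codons) > 1L && any(codons[-length(codons)] %in% STOP_CODONS)
  protein <- sub("\\*$", "",
                 as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                                    if.fuzzy.codon = "solve")))
  identity <- proteinIdentityTo(protein, queryProt)

  allFound <- nrow(chain) == nExons
  framesOk <- all(chain$frame_offset == 0L)
  ## every evaluated junction must be canonical (the seed row carries NA)
  spliceOk <- all(stats::na.omit(chain$splice_ok))

  status <- "complete"; reason <- ""
  if (!allFound) { status <- "fragmented"; reason <- "exon chain incomplete" }
  else if (internal) { status <- "fragmented"; reason <- "internal stop codon" }
  else if (!hasStart) { status <- "fragmented"; reason <- "no initiation codon" }
  else if (!hasStop) { status <- "fragmented"; reason <- "no termination codon" }
  else if (!framesOk) { status <- "fragmented"; reason <- "reading frame not conserved" }
  else if (!spliceOk) { status <- "fragmented"; reason <- "non-canonical splice signal" }
  else if (identity < minIdentity) {
    status <- "fragmented"
    reason <- sprintf("protein identity %.3f below %.2f", identity, minIdentity)
  }
  new("GeneVerification", geneId = gene, hits = chain, cds = cds,
      protein = protein, identity = identity, hasStart = hasStart,
      hasStop = hasStop, status = status, reason = reason)
}

#' Verify a set of genes at exon resolution
#'
#' Runs [findSeedExon()], [walkExons()] and [classifyGene()] for every gene
#' in the query set.
#'
#' @inheritParams walkExons
#' @inheritParams classifyGene
#' @return Named list of [GeneVerification-class], one per gene; summarise
#'   with [verificationTable()].
#' @export
verifyGenes <- function(assembly, queries, window = 10000L,
                        maxExtension = 1e6, minIdentity = 0.70,
                        minScoreFrac = 0.5,
                        spliceDonor = "GT", spliceAcceptor = "AG") {
  genes <- queryGenes(queries)
  index <- seedIndex(assembly, queries)
  out <- lapply(genes, function(g) {
    seed <- findSeedExon(assembly, queries, g, minScoreFrac = minScoreFrac,
                         index = index)
    chain <- if (is.null(seed)) NULL else
      walkExons(assembly, seed, queries, window = window,
                maxExtension = maxExtension, minScoreFrac = minScoreFrac,
                spliceDonor = spliceDonor, spliceAcceptor = spliceAcceptor)
    classifyGene(assembly, chain, queries, g, minIdentity = minIdentity)
  })
  setNames(out, genes)
}

#' Tabulate verification results
#'
#' @param verifications List of [GeneVerification-class] from [verifyGenes()].
#' @return data.frame with one row per gene.
#' @export
verificationTable <- function(verifications) {
  do.call(rbind, lapply(verifications, function(v) {
    data.frame(gene_id = v@geneId, status = v@status,
               identity = v@identity, n_exons_found = nrow(v@hits),
               has_start = v@hasStart, has_stop = v@hasStop,
               reason = v@reason, stringsAsFactors = FALSE)
  }))
}

#' Summarise a completeness rescue pass
#'
#' Given verification results for the genes an initial marker screen scored
#' as fragmented or missing, tabulates counts per status and the revised
#' completeness percentage over the full marker set.
#'
#' @param verifications List of [GeneVerification-class] (may be empty).
#' @param markerSetSize Size of the full marker gene set.
#' @param nCompleteBefore Genes scored complete before the rescue pass.
#' @return List with `statusCounts`, `preCompleteness` and
#'   `revisedCompleteness` (both percentages of `markerSetSize`), and
#'   `nRescued`.
#' @export
rescueReport <- function(verifications, markerSetSize, nCompleteBefore) {
  stopifnot(markerSetSize > 0, nCompleteBefore >= 0,
            nCompleteBefore <= markerSetSize)
  statuses <- vapply(verifications, geneStatus, character(1))
  counts <- setNames(
    vapply(c("complete", "fragmented", "missing"),
           function(s) sum(statuses == s), integer(1)),
    c("complete", "fragmented", "missing"))
  nRescued <- counts[["complete"]]
  list(statusCounts = counts,
       preCompleteness = 100 * nCompleteBefore / markerSetSize,
       nRescued = nRescued,
       revisedCompleteness = 100 * (nCompleteBefore + nRescued) / markerSetSize)
}
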