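## Synthetic genomes, gene models, alignments and variant sets with known
## truth. The generator overwrites windows of the derived chromosomes in
## place (it never inserts), so ancestral/derived coordinate bookkeeping
## stays exact.

#' Build a synthetic-genome configuration
#'
#' Defaults describe a desk-scale caricature of a long-read mammalian
#' assembly project: a low-heterozygosity diploid (0.5 het SNVs/Mb), a 16,431
#' bp circular mitochondrion, NUMT insertions of 200-2000 bp at 10%
#' divergence, and a 26 kb contaminant contig. See the package vignette for
#' the reasoning behind each default.
#'
#' @param genomeLength Total nuclear genome length (bp).
#' @param nChromosomes Number of ancestral chromosome segments.
#' @param nGenes Number of planted multi-exon genes.
#' @param exonsPerGene,exonLength,intronLength Inclusive integer ranges
#'   `c(lo, hi)`.
#' @param spliceDonor,spliceAcceptor Consensus splice dinucleotides.
#' @param perBaseAccuracy Per-base accuracy used by corruption helpers.
#' @param hetSnvPerMb Heterozygous SNV rate per Mb.
#' @param hetIndelPerMb Named rates per Mb per indel size class (names are
#'   signed sizes, e.g. `c("-2" = 0.05, "1" = 0.05)`).
#' @param nNumts,numtLength,numtDivergence NUMT count, length range and
#'   per-base divergence.
#' @param mitoLength Length of the synthetic circular mitochondrion.
#' @param contaminantLength Length of the contaminant contig (0 disables).
#' @param contigsPerChromosome Contigs each derived chromosome is cut into.
#' @param rearrangements List of rearrangement ops applied to the ancestral
#'   segments; see [makeGenome()].
#' @param depthMean Mean simulated read depth.
#' @return A validated [SynthConfig-class] object.
#' @export
synthConfig <- function(genomeLength = 1e6,
                        nChromosomes = 4L,
                        nGenes = 20L,
                        exonsPerGene = c(2L, 5L),
                        exonLength = c(90L, 240L),
                        intronLength = c(200L, 800L),
                        spliceDonor = "GT",
                        spliceAcceptor = "AG",
                        perBaseAccuracy = 0.999991,
                        hetSnvPerMb = 0.5,
                        hetIndelPerMb = c("-3" = 0.05, "-2" = 0.05, "-1" = 0.1,
                                          "1" = 0.1, "2" = 0.05, "3" = 0.05),
                        nNumts = 10L,
                        numtLength = c(200L, 2000L),
                        numtDivergence = 0.10,
                        mitoLength = 16431L,
                        contaminantLength = 26000L,
                        contigsPerChromosome = 2L,
                        rearrangements = list(),
                        depthMean = 90) {
  new("SynthConfig",
      genomeLength = genomeLength,
      nChromosomes = as.integer(nChromosomes),
      nGenes = as.integer(nGenes),
      exonsPerGene = as.integer(exonsPerGene),
      exonLength = as.integer(exonLength),
      intronLength = as.integer(intronLength),
      spliceDonor = spliceDonor,
      spliceAcceptor = spliceAcceptor,
      perBaseAccuracy = perBaseAccuracy,
      hetSnvPerMb = hetSnvPerMb,
      hetIndelPerMb = hetIndelPerMb,
      nNumts = as.integer(nNumts),
      numtLength = as.integer(numtLength),
      numtDivergence = numtDivergence,
      mitoLength = as.integer(mitoLength),
      contaminantLength = as.integer(contaminantLength),
      contigsPerChromosome = as.integer(contigsPerChromosome),
      rearrangements = rearrangements,
      depthMean = depthMean)
}

## Apply rearrangement ops to the identity karyotype. A karyotype is a list
## of chromosomes, each a data.frame(segment, anc_start, anc_end, strand).
applyRearrangements <- function(karyo, ops) {
  findChromWith <- function(karyo, segment) {
    hit <- which(vapply(karyo, function(p) segment %in% p$segment, logical(1)))
    if (length(hit) == 0L)
      stop("rearrangement refers to unknown segment: ", segment)
    hit[1L]
  }
  for (op in ops) {
    type <- op$type %||% stop("rearrangement op needs a 'type'")
    if (type == "fusion") {
      idx <- vapply(op$segments, function(s) findChromWith(karyo, s), integer(1))
      idx <- unique(idx)
      if (length(idx) < 2L)
        stop("fusion needs segments on two distinct chromosomes")
      fused <- do.call(rbind, karyo[idx])
      karyo <- c(karyo[-idx], list(fused))
    } else if (type == "fission") {
      i <- findChromWith(karyo, op$segment)
      parts <- karyo[[i]]
      if (nrow(parts) != 1L)
        stop("fission currently splits single-segment chromosomes only")
      at <- op$at %||% 0.5
      brk <- parts$anc_start + round(at * (parts$anc_end - parts$anc_start))
      left <- data.frame(segment = parts$segment, anc_start = parts$anc_start,
                         anc_end = brk, strand = parts$strand)
      right <- data.frame(segment = parts$segment, anc_start = brk,
                          anc_end = parts$anc_end, strand = parts$strand)
      karyo <- c(karyo[-i], list(left, right))
    } else if (type == "inversion") {
      i <- findChromWith(karyo, op$segment)
      j <- which(karyo[[i]]$segment == op$segment)[1L]
      karyo[[i]]$strand[j] <- if (karyo[[i]]$strand[j] == "+") "-" else "+"
    } else {
      stop("unknown rearrangement type: ", type)
    }
  }
  names(karyo) <- sprintf("chr%d", seq_along(karyo))
  karyo
}

## Find a free placement window on one of the contigs; returns
## list(contig, start) with 0-based start, or errors if nothing fits.
reserveWindow <- function(occupied, contigLengths, len, buffer = 100L,
                          what = "feature") {
  ord <- sample(names(contigLengths), length(contigLengths),
                prob = contigLengths / sum(contigLengths))
  for (ctg in unique(ord)) {
    L <- contigLengths[[ctg]]
    if (L < len + 2L * buffer) next
    for (try in seq_len(60L)) {
      start <- sample.int(L - len - 2L * buffer, 1L) + buffer
      iv <- c(start, start + len)
      occ <- occupied[[ctg]]
      clash <- !is.null(occ) && any(iv[1L] < occ[, 2L] + buffer &
                                    occ[, 1L] - buffer < iv[2L])
      if (!clash) return(list(contig = ctg, start = start))
    }
  }
  stop("configuration infeasible: could not place ", what,
       " of length ", len, " without overlap")
}

## Build one gene: returns list(seq, exon_offsets (0-based within gene),
## exon_lengths, cds, protein).
buildGene <- function(config) {
  nEx <- sampleRange(config@exonsPerGene)
  exLens <- sampleRange(config@exonLength, nEx)
  rem <- sum(exLens) %% 3L
  exLens[nEx] <- exLens[nEx] - rem
  nCod <- sum(exLens) %/% 3L
  codons <- c("ATG",
              if (nCod > 2L) sample(NONSTOP_CODONS, nCod - 2L, replace = TRUE),
              sample(STOP_CODONS, 1L))
  cds <- paste(codons, collapse = "")
  ends <- cumsum(exLens)
  starts <- c(0L, head(ends, -1L))
  exSeqs <- substring(cds, starts + 1L, ends)
  inLens <- if (nEx > 1L) sampleRange(config@intronLength, nEx - 1L) else integer(0)
  pieces <- character(0)
  offsets <- integer(nEx)
  at <- 0L
  for (i in seq_len(nEx)) {
    offsets[i] <- at
    pieces <- c(pieces, exSeqs[i])
    at <- at + exLens[i]
    if (i < nEx) {
      intron <- paste0(config@spliceDonor, randomDna(inLens[i] - 4L),
                       config@spliceAcceptor)
      pieces <- c(pieces, intron)
      at <- at + inLens[i]
    }
  }
  protein <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  list(seq = paste(pieces, collapse = ""), exon_offsets = offsets,
       exon_lengths = exLens, cds = cds,
       protein = sub("\\*$", "", protein))
}

## Per-base substitution at a fixed rate (used for NUMT divergence).
mutateBases <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(ch)) < rate)
  if (length(hit)) {
    ch[hit] <- vapply(ch[hit],
                      function(b) sample(setdiff(BASES, b), 1L), character(1))
  }
  paste(ch, collapse = "")
}

#' Generate a synthetic assembly with known truth
#'
#' Builds an ancestral segment set, derives chromosomes by applying the
#' configured fusions/fissions/inversions, cuts the chromosomes into contigs,
#' then plants intact multi-exon genes (ATG start, single terminal stop, no
#' internal stops, consensus splice signals at every intron boundary), NUMT
#' copies of a synthetic circular mitochondrion at the configured divergence,
#' and an unrelated contaminant contig. All planting overwrites sequence
#' windows, so recorded coordinates are exact.
#'
#' @param config A [SynthConfig-class] from [synthConfig()].
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return A list with elements `assembly` (a
#'   [Biostrings::DNAStringSet] of contigs, plus the contaminant contig and
#'   the mitochondrion as `"MT"`), `ancestral` (DNAStringSet of ancestral
#'   segments), `mito` (the mitochondrion as character), and `truth`
#'   (a [TruthSet-class]).
#' @export
makeGenome <- function(config, seed = 1L) {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  set.seed(as.integer(seed))

  mito <- randomDna(config@mitoLength)

  segLen <- as.integer(floor(config@genomeLength / config@nChromosomes))
  segNames <- sprintf("S%d", seq_len(config@nChromosomes))
  segments <- setNames(vapply(segNames, function(s) randomDna(segLen),
                              character(1)), segNames)

  karyo0 <- setNames(lapply(segNames, function(s)
    data.frame(segment = s, anc_start = 0L, anc_end = segLen,
               strand = "+", stringsAsFactors = FALSE)),
    sprintf("chr%d", seq_along(segNames)))
  karyo <- applyRearrangements(karyo0, config@rearrangements)

  chromSeqs <- vapply(karyo, function(parts) {
    paste(vapply(seq_len(nrow(parts)), function(i) {
      p <- parts[i, ]
      s <- substr(segments[[p$segment]], p$anc_start + 1L, p$anc_end)
      if (p$strand == "-") revcompChar(s) else s
    }, character(1)), collapse = "")
  }, character(1))

  ## cut chromosomes into contigs
  contigSeqs <- character(0)
  originRows <- list()
  ctgIdx <- 0L
  for (chrom in names(karyo)) {
    L <- nchar(chromSeqs[[chrom]])
    ncut <- config@contigsPerChromosome
    cuts <- if (ncut > 1L) {
      sort(sample(seq.int(floor(L / (2L * ncut)), L - floor(L / (2L * ncut))),
                  ncut - 1L))
    } else integer(0)
    bounds <- c(0L, cuts, L)
    parts <- karyo[[chrom]]
    partEnds <- cumsum(parts$anc_end - parts$anc_start)
    partStarts <- c(0L, head(partEnds, -1L))
    for (i in seq_len(length(bounds) - 1L)) {
      ctgIdx <- ctgIdx + 1L
      name <- sprintf("ctg%04d", ctgIdx)
      cStart <- bounds[i]; cEnd <- bounds[i + 1L]
      contigSeqs[[name]] <- substr(chromSeqs[[chrom]], cStart + 1L, cEnd)
      for (j in seq_len(nrow(parts))) {
        a <- max(cStart, partStarts[j]); b <- min(cEnd, partEnds[j])
        if (a >= b) next
        p <- parts[j, ]
        if (p$strand == "+") {
          tstart <- p$anc_start + (a - partStarts[j])
          tend <- p$anc_start + (b - partStarts[j])
        } else {
          tend <- p$anc_end - (a - partStarts[j])
          tstart <- p$anc_end - (b - partStarts[j])
        }
        originRows[[length(originRows) + 1L]] <- data.frame(
          contig = name, contig_length = cEnd - cStart,
          qstart = a - cStart, qend = b - cStart,
          chromosome = chrom, chrom_start = a, chrom_end = b,
          segment = p$segment, seg_length = segLen,
          tstart = tstart, tend = tend, strand = p$strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  origin <- do.call(rbind, originRows)
  contigLengths <- vapply(contigSeqs, nchar, integer(1))

  ## plant genes and NUMTs by overwriting free windows
  occupied <- list()
  geneRows <- list()
  proteins <- character(0)
  for (g in seq_len(config@nGenes)) {
    gene <- buildGene(config)
    glen <- nchar(gene$seq)
    slot <- reserveWindow(occupied, contigLengths, glen, what = "gene")
    ctg <- slot$contig; at <- slot$start
    substr(contigSeqs[[ctg]], at + 1L, at + glen) <- gene$seq
    occupied[[ctg]] <- rbind(occupied[[ctg]], c(at, at + glen))
    gid <- sprintf("gene%04d", g)
    proteins[[gid]] <- gene$protein
    geneRows[[g]] <- data.frame(
      contig = ctg,
      start = at + gene$exon_offsets,                 # 0-based
      end = at + gene$exon_offsets + gene$exon_lengths,
      gene_id = gid, exon_rank = seq_along(gene$exon_offsets),
      stringsAsFactors = FALSE)
  }
  geneDf <- if (length(geneRows)) do.call(rbind, geneRows) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               gene_id = character(0), exon_rank = integer(0))
  geneModels <- GenomicRanges::GRanges(
    seqnames = geneDf$contig,
    ranges = IRanges::IRanges(start = geneDf$start + 1L, end = geneDf$end),
    strand = rep("+", nrow(geneDf)),
    gene_id = geneDf$gene_id, exon_rank = geneDf$exon_rank)

  numtRows <- list()
  for (i in seq_len(config@nNumts)) {
    len <- sampleRange(config@numtLength)
    mStart <- sample.int(config@mitoLength - len, 1L) - 1L
    copy <- mutateBases(substr(mito, mStart + 1L, mStart + len),
                        config@numtDivergence)
    slot <- reserveWindow(occupied, contigLengths, len, what = "NUMT")
    substr(contigSeqs[[slot$contig]], slot$start + 1L, slot$start + len) <- copy
    occupied[[slot$contig]] <- rbind(occupied[[slot$contig]],
                                     c(slot$start, slot$start + len))
    numtRows[[i]] <- data.frame(
      contig = slot$contig, start = slot$start, end = slot$start + len,
      mito_start = mStart, mito_end = mStart + len,
      divergence = config@numtDivergence, stringsAsFactors = FALSE)
  }
  numtDf <- if (length(numtRows)) do.call(rbind, numtRows) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               mito_start = integer(0), mito_end = integer(0),
               divergence = numeric(0))
  numts <- GenomicRanges::GRanges(
    seqnames = numtDf$contig,
    ranges = IRanges::IRanges(start = numtDf$start + 1L, end = numtDf$end),
    strand = rep("*", nrow(numtDf)),
    mito_start = numtDf$mito_start, mito_end = numtDf$mito_end,
    divergence = numtDf$divergence)

  contaminants <- character(0)
  if (config@contaminantLength > 0L) {
    contigSeqs[["contam1"]] <- randomDna(config@contaminantLength)
    contaminants <- "contam1"
  }
  contigSeqs[["MT"]] <- mito

  assembly <- Biostrings::DNAStringSet(contigSeqs)
  truth <- new("TruthSet",
               geneModels = geneModels,
               proteins = proteins,
               contigOrigin = origin,
               numts = numts,
               contaminants = contaminants,
               karyotype = lapply(karyo, function(p) p$segment),
               variantTruth = data.frame())
  list(assembly = assembly,
       ancestral = Biostrings::DNAStringSet(segments),
       mito = mito,
       truth = truth)
}

#' Corrupt a sequence under a fixed per-base accuracy
#'
#' Two modes. `"codon"` implements the spurious-stop error model exactly:
#' each codon is independently correct with probability `accuracy^3`, and an
#' incorrect codon is replaced uniformly by one of its 63 alternatives.
#' `"base"` flips each base independently with probability `1 - accuracy`
#' to one of the three other bases. The two modes are *not* equivalent: the
#' codon model conditions on at least one base error per altered codon and
#' redistributes uniformly over all 63 wrong codons, whereas per-base errors
#' concentrate on single-mismatch codons.
#'
#' @param seq Character scalar or [Biostrings::DNAString]; `"codon"` mode
#'   requires the length to be divisible by 3.
#' @param accuracy Per-base accuracy in `[0, 1]`.
#' @param seed Integer seed.
#' @param mode `"codon"` or `"base"`.
#' @return The corrupted sequence as a character scalar.
#' @export
corruptSequence <- function(seq, accuracy, seed = 1L,
                            mode = c("codon", "base")) {
  mode <- match.arg(mode)
  if (!is.numeric(accuracy) || accuracy < 0 || accuracy > 1)
    stop("accuracy must be in [0, 1]")
  seq <- as.character(seq)
  set.seed(as.integer(seed))
  if (mode == "codon") {
    codons <- splitCodons(seq)
    if (!length(codons)) return(seq)
    bad <- which(runif(length(codons)) > accuracy^3)
    if (length(bad)) {
      idx <- match(codons[bad], ALL_CODONS)
      offs <- sample.int(63L, length(bad), replace = TRUE)
      codons[bad] <- ALL_CODONS[((idx - 1L + offs) %% 64L) + 1L]
    }
    paste(codons, collapse = "")
  } else {
    ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
    bad <- which(runif(length(ch)) > accuracy)
    if (length(bad)) {
      idx <- match(ch[bad], BASES)
      offs <- sample.int(3L, length(bad), replace = TRUE)
      ch[bad] <- BASES[((idx - 1L + offs) %% 4L) + 1L]
    }
    paste(ch, collapse = "")
  }
}

## Annotation draws for pass records and for each failing rule. The mixture
## components deliberately straddle the hard-filter thresholds so truth
## labels are unambiguous.
passAnnotations <- function(n) {
  data.frame(QD = runif(n, 10, 30), MQ = runif(n, 55, 60),
             SOR = runif(n, 0.3, 2.5), FS = runif(n, 0, 10),
             MQRankSum = runif(n, -2, 2), ReadPosRankSum = runif(n, -2, 2))
}

FAIL_DRAWS <- list(
  snv = list(
    QD = function() runif(1, 0, 1.9), MQ = function() runif(1, 10, 39),
    SOR = function() runif(1, 3.5, 9), FS = function() runif(1, 70, 200),
    MQRankSum = function() runif(1, -20, -13),
    ReadPosRankSum = function() runif(1, -15, -8.5)),
  indel = list(
    QD = function() runif(1, 0, 1.9), SOR = function() runif(1, 10.5, 20),
    FS = function() runif(1, 210, 400),
    ReadPosRankSum = function() runif(1, -30, -20.5)))

#' Generate heterozygous variant records with truth labels
#'
#' Plants heterozygous SNVs and indels on the nuclear contigs at the
#' configured per-Mb rates (counts are Poisson in contig length). Each record
#' carries GATK-style INFO annotations drawn from a two-component mixture:
#' with probability `failFraction` the record violates exactly one randomly
#' chosen hard-filter rule for its variant type, otherwise every annotation
#' is drawn comfortably inside the passing region. The truth label is stored
#' in `truth_pass`.
#'
#' @param genome Result of [makeGenome()], or a [Biostrings::DNAStringSet].
#' @param config A [SynthConfig-class].
#' @param seed Integer seed.
#' @param failFraction Fraction of records that violate one hard-filter rule.
#' @param failAnnotation Optional annotation name; when given, every failing
#'   record violates this rule (when applicable to its variant type) instead
#'   of a randomly chosen one.
#' @param excludeContigs Contigs to leave variant-free; defaults to the
#'   contaminant contigs and `"MT"` when `genome` carries a truth set.
#' @return data.frame of variant records (`chrom`, `pos` 1-based, `ref`,
#'   `alt`, `gt`, `size`, `truth_pass`, and the six INFO annotations).
#' @export
makeVariants <- function(genome, config, seed = 1L, failFraction = 0,
                         failAnnotation = NULL, excludeContigs = NULL) {
  stopifnot(is(config, "SynthConfig"))
  if (is.list(genome)) {
    assembly <- genome$assembly
    if (is.null(excludeContigs))
      excludeContigs <- c(contaminantIds(genome$truth), "MT")
  } else {
    assembly <- genome
    excludeContigs <- excludeContigs %||% character(0)
  }
  set.seed(as.integer(seed))
  sizes <- c(0, as.integer(names(config@hetIndelPerMb)))
  rates <- c(config@hetSnvPerMb, unname(config@hetIndelPerMb))
  contigs <- setdiff(names(assembly), excludeContigs)
  rows <- list()
  for (ctg in contigs) {
    L <- Biostrings::width(assembly[ctg])
    seqc <- as.character(assembly[[ctg]])
    maxDel <- max(c(1L, -sizes))
    for (k in seq_along(sizes)) {
      size <- sizes[k]
      n <- rpois(1L, L * rates[k] / 1e6)
      if (n == 0L) next
      pos <- sample.int(L - maxDel - 1L, min(n, L - maxDel - 1L))
      for (p in pos) {
        refBase <- substr(seqc, p, p)
        if (size == 0) {
          ref <- refBase
          alt <- sample(setdiff(BASES, refBase), 1L)
        } else if (size > 0) {
          ref <- refBase
          alt <- paste0(refBase, randomDna(size))
        } else {
          ref <- substr(seqc, p, p - size)
          alt <- refBase
        }
        fails <- failFraction > 0 && runif(1) < failFraction
        ann <- passAnnotations(1L)
        if (fails) {
          draws <- if (size == 0) FAIL_DRAWS$snv else FAIL_DRAWS$indel
          rule <- if (!is.null(failAnnotation) &&
                      failAnnotation %in% names(draws)) failAnnotation
            else sample(names(draws), 1L)
          ann[[rule]] <- draws[[rule]]()
        }
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(chrom = ctg, pos = p, ref = ref, alt = alt, gt = "0/1",
                     size = size, truth_pass = !fails,
                     stringsAsFactors = FALSE),
          ann)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gt = character(0), size = integer(0),
                      truth_pass = logical(0), QD = numeric(0), MQ = numeric(0),
                      SOR = numeric(0), FS = numeric(0),
                      MQRankSum = numeric(0), ReadPosRankSum = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Emit truth-driven contig-to-reference alignment records
#'
#' Constructs PAF-semantics alignment records from the provenance the
#' generator recorded: each contig gets one record per ancestral segment
#' interval it derives from, at the stated divergence (matching bases are
#' `block * (1 - divergence)` rounded down). Optional decoy records send
#' random contigs to wrong segments at a higher divergence, emulating the
#' spurious alignments a divergence filter should remove.
#'
#' @param truth A [TruthSet-class] (or the list from [makeGenome()]).
#' @param divergence Divergence of the true records.
#' @param nDecoys Number of decoy records.
#' @param decoyDivergence Divergence assigned to decoys.
#' @param seed Integer seed.
#' @return data.frame in the layout of [readPaf()] with an extra logical
#'   column `decoy`.
#' @export
makeAlignments <- function(truth, divergence = 0.05, nDecoys = 0L,
                           decoyDivergence = 0.30, seed = 1L) {
  if (is.list(truth)) truth <- truth$truth
  stopifnot(is(truth, "TruthSet"))
  set.seed(as.integer(seed))
  o <- contigOrigin(truth)
  block <- o$qend - o$qstart
  rec <- data.frame(
    qname = o$contig, qlen = o$contig_length,
    qstart = o$qstart, qend = o$qend, strand = o$strand,
    tname = o$segment, tlen = o$seg_length,
    tstart = o$tstart, tend = o$tend,
    nmatch = floor(block * (1 - divergence)), blocklen = block,
    mapq = 60L, decoy = FALSE, stringsAsFactors = FALSE)
  if (nDecoys > 0L) {
    segs <- unique(o$segment)
    ctgs <- unique(o$contig)
    dec <- lapply(seq_len(nDecoys), function(i) {
      ctg <- sample(ctgs, 1L)
      qlen <- o$contig_length[match(ctg, o$contig)]
      trueSegs <- o$segment[o$contig == ctg]
      wrong <- setdiff(segs, trueSegs)
      if (!length(wrong)) wrong <- segs
      blk <- max(100L, floor(qlen / 4L))
      data.frame(qname = ctg, qlen = qlen, qstart = 0L, qend = blk,
                 strand = sample(c("+", "-"), 1L),
                 tname = sample(wrong, 1L),
                 tlen = o$seg_length[1L], tstart = 0L, tend = blk,
                 nmatch = floor(blk * (1 - decoyDivergence)), blocklen = blk,
                 mapq = 0L, decoy = TRUE, stringsAsFactors = FALSE)
    })
    rec <- rbind(rec, do.call(rbind, dec))
  }
  rec$divergence <- 1 - rec$nmatch / rec$blocklen
  rownames(rec) <- NULL
  rec
}

#' Construct an exon query set
#'
#' @param geneId Character vector, one per exon.
#' @param exonIndex Integer exon ordinals (1-based within gene).
#' @param seq Exon sequences (character or DNAStringSet).
#' @param protein Named character vector of full-length query proteins.
#' @return An [ExonQuerySet-class].
#' @export
exonQuerySet <- function(geneId, exonIndex, seq, protein) {
  new("ExonQuerySet", geneId = as.character(geneId),
      exonIndex = as.integer(exonIndex),
      seq = Biostrings::DNAStringSet(seq),
      protein = protein)
}

#' Derive exon queries from a synthetic truth set
#'
#' Extracts every planted exon from the assembly in truth coordinates and
#' pairs it with the stored query protein, producing the probe set the gene
#' walker is evaluated against.
#'
#' @param genome Result of [makeGenome()].
#' @return An [ExonQuerySet-class].
#' @export
exonQueriesFromTruth <- function(genome) {
  truth <- genome$truth
  gm <- geneModels(truth)
  if (!length(gm))
    return(exonQuerySet(character(0), integer(0), Biostrings::DNAStringSet(),
                        character(0)))
  seqs <- Biostrings::DNAStringSet(vapply(seq_along(gm), function(i) {
    as.character(Biostrings::subseq(
      genome$assembly[[as.character(GenomicRanges::seqnames(gm)[i])]],
      start = GenomicRanges::start(gm)[i], end = GenomicRanges::end(gm)[i]))
  }, character(1)))
  exonQuerySet(gm$gene_id, gm$exon_rank, seqs, truthProteins(truth))
}
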