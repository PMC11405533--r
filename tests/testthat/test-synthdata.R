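test_that("generator handles the empty case and is byte-deterministic", {
  cfg <- tinyConfig(nGenes = 0L)
  g <- makeGenome(cfg, seed = 1)
  expect_length(geneModels(g$truth), 0)

  g2 <- makeGenome(cfg, seed = 1)
  f1 <- tempfile(); f2 <- tempfile()
  writeFasta(g$assembly, f1); writeFasta(g2$assembly, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(contigOrigin(g$truth), contigOrigin(g2$truth))

  g3 <- makeGenome(cfg, seed = 2)
  expect_false(identical(as.character(g$assembly), as.character(g3$assembly)))
})

test_that("planted genes re-translate to stop-free proteins (independent oracle)", {
  cfg <- synthConfig(genomeLength = 5e5, nGenes = 10L,
                     exonsPerGene = c(3L, 3L), nNumts = 0L,
                     contaminantLength = 0L)
  g <- makeGenome(cfg, seed = 42)
  gm <- geneModels(g$truth)
  for (gid in unique(gm$gene_id)) {
    ex <- gm[gm$gene_id == gid]
    ex <- ex[order(ex$exon_rank)]
    cds <- paste(vapply(seq_along(ex), function(i) {
      as.character(Biostrings::subseq(
        g$assembly[[as.character(GenomicRanges::seqnames(ex)[i])]],
        GenomicRanges::start(ex)[i], GenomicRanges::end(ex)[i]))
    }, character(1)), collapse = "")
    prot <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_match(prot, "^M[^*]*\\*$")  # intact ORF, no internal stop
    expect_identical(sub("\\*$", "", prot),
                     unname(truthProteins(g$truth)[gid]))
  }
  # canonical splice signals at every intron boundary
  for (gid in unique(gm$gene_id)) {
    ex <- gm[gm$gene_id == gid]
    ex <- ex[order(ex$exon_rank)]
    ctg <- g$assembly[[as.character(GenomicRanges::seqnames(ex)[1])]]
    for (i in seq_len(length(ex) - 1)) {
      donor <- as.character(Biostrings::subseq(
        ctg, GenomicRanges::end(ex)[i] + 1, GenomicRanges::end(ex)[i] + 2))
      acceptor <- as.character(Biostrings::subseq(
        ctg, GenomicRanges::start(ex)[i + 1] - 2,
        GenomicRanges::start(ex)[i + 1] - 1))
      expect_identical(donor, "GT")
      expect_identical(acceptor, "AG")
    }
  }
})

test_that("infeasible gene configurations error instead of truncating", {
  expect_error(synthConfig(genomeLength = 10000, nGenes = 100L),
               "infeasible")
})

test_that("codon corruption matches its model at the boundaries and in rate", {
  s <- strrep("ATGAAACCC", 10)
  expect_identical(corruptSequence(s, 1.0, seed = 1), s)

  worst <- corruptSequence(s, 0.0, seed = 1)
  orig <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  new <- substring(worst, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  expect_true(all(orig != new))  # every codon replaced by an alternative

  # binomial check: altered-codon fraction within 5 sigma of 1 - A^3
  nCod <- 1e5
  set.seed(3)
  big <- paste(sample(c("ATG", "AAA", "CCC", "GGG"), nCod, TRUE),
               collapse = "")
  A <- 0.99
  cor <- corruptSequence(big, A, seed = 5)
  o <- substring(big, seq(1, nchar(big), 3), seq(3, nchar(big), 3))
  n <- substring(cor, seq(1, nchar(big), 3), seq(3, nchar(big), 3))
  p <- 1 - A^3
  expect_lt(abs(sum(o != n) - nCod * p), 5 * sqrt(nCod * p * (1 - p)))

  expect_error(corruptSequence(s, 1.2), "accuracy")
})

test_that("variant generation recovers configured rates and mixtures", {
  cfg0 <- synthConfig(genomeLength = 1e6, nChromosomes = 1L,
                      contigsPerChromosome = 1L, nGenes = 0L, nNumts = 0L,
                      contaminantLength = 0L, hetSnvPerMb = 0,
                      hetIndelPerMb = c("1" = 0))
  g <- makeGenome(cfg0, seed = 1)
  expect_identical(nrow(makeVariants(g, cfg0, seed = 1)), 0L)

  cfg <- synthConfig(genomeLength = 1e6, nChromosomes = 1L,
                     contigsPerChromosome = 1L, nGenes = 0L, nNumts = 0L,
                     contaminantLength = 0L, hetSnvPerMb = 100,
                     hetIndelPerMb = c("-1" = 0))
  g <- makeGenome(cfg, seed = 1)
  calls <- makeVariants(g, cfg, seed = 2)
  snv <- calls[calls$size == 0, ]
  expect_lt(abs(nrow(snv) - 100), 5 * sqrt(100))  # Poisson check

  # fail mixture straddles the QD threshold
  callsF <- makeVariants(g, cfg, seed = 3, failFraction = 0.5,
                         failAnnotation = "QD")
  fracLow <- mean(callsF$QD < 2.0)
  expect_lt(abs(fracLow - 0.5), 5 * sqrt(0.25 / nrow(callsF)))
  expect_identical(callsF$QD < 2.0, !callsF$truth_pass)

  # ref alleles match the genome
  seqc <- as.character(g$assembly[[1]])
  expect_true(all(substring(seqc, calls$pos, calls$pos) ==
                    substring(calls$ref, 1, 1)))
})

test_that("alignment records follow truth origins, fusions, and decoys", {
  cfg <- synthConfig(genomeLength = 4e5, nChromosomes = 4L, nGenes = 0L,
                     nNumts = 0L, contaminantLength = 0L,
                     rearrangements = list(
                       list(type = "fusion", segments = c("S1", "S2"))))
  g <- makeGenome(cfg, seed = 3)
  paf <- makeAlignments(g$truth, seed = 3)
  # every contig's best target is its origin segment
  o <- contigOrigin(g$truth)
  for (ctg in unique(paf$qname)) {
    best <- paf$tname[paf$qname == ctg][
      which.max(paf$blocklen[paf$qname == ctg])]
    expect_true(best %in% o$segment[o$contig == ctg])
  }
  # exactly one derived chromosome maps to two ancestral segments
  perChrom <- lapply(truthKaryotype(g$truth), unique)
  expect_identical(sum(lengths(perChrom) == 2), 1L)

  # decoys at 0.30 divergence are exactly what the 20% filter removes
  pafD <- makeAlignments(g$truth, nDecoys = 6, decoyDivergence = 0.30,
                         seed = 4)
  kept <- filterAlignments(pafD, maxDivergence = 0.20)
  expect_identical(attr(kept, "n_dropped"), 6L)
  expect_false(any(kept$decoy))
})

test_that("emitted GFF3 and VCF re-parse to the recorded truth", {
  cfg <- tinyConfig(hetSnvPerMb = 50)
  g <- makeGenome(cfg, seed = 6)
  gff <- tempfile(fileext = ".gff3")
  writeGff3(geneModels(g$truth), gff)
  back <- readGff3(gff)
  ord <- order(back$gene_id, back$exon_rank)
  gm <- geneModels(g$truth)
  expect_identical(GenomicRanges::start(back)[ord], GenomicRanges::start(gm))
  expect_identical(GenomicRanges::end(back)[ord], GenomicRanges::end(gm))
  expect_identical(back$gene_id[ord], gm$gene_id)

  calls <- makeVariants(g, cfg, seed = 6)
  vcf <- tempfile(fileext = ".vcf")
  writeVcfRecords(calls, vcf)
  reread <- readVariantCalls(vcf)
  expect_identical(nrow(reread), nrow(calls))
  expect_identical(reread$pos, as.integer(calls$pos))
  expect_identical(reread$ref, calls$ref)
  expect_identical(reread$alt, calls$alt)
})

test_that("truth coordinates always lie within their sequences", {
  g <- makeGenome(tinyConfig(), seed = 8)
  widths <- setNames(Biostrings::width(g$assembly), names(g$assembly))
  gm <- geneModels(g$truth)
  expect_true(all(GenomicRanges::end(gm) <=
                    widths[as.character(GenomicRanges::seqnames(gm))]))
  nu <- numtLoci(g$truth)
  expect_true(all(GenomicRanges::end(nu) <=
                    widths[as.character(GenomicRanges::seqnames(nu))]))
  o <- contigOrigin(g$truth)
  expect_true(all(o$qend <= o$contig_length & o$qstart >= 0))
  expect_true(all(o$tend <= o$seg_length & o$tstart >= 0))
})
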