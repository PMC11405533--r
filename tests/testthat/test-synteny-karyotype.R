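mkRecord <- function(qname, tname, nmatch, blocklen, strand = "+",
                     tstart = 0, qlen = blocklen, tlen = 1e6) {
  data.frame(qname = qname, qlen = qlen, qstart = 0, qend = blocklen,
             strand = strand, tname = tname, tlen = tlen, tstart = tstart,
             tend = tstart + blocklen, nmatch = nmatch, blocklen = blocklen,
             mapq = 60, divergence = 1 - nmatch / blocklen,
             stringsAsFactors = FALSE)
}

test_that("the divergence filter keeps 0.19 and drops 0.21", {
  recs <- rbind(mkRecord("a", "t", 810, 1000), mkRecord("b", "t", 790, 1000))
  kept <- filterAlignments(recs, maxDivergence = 0.20)
  expect_identical(kept$qname, "a")
  expect_identical(attr(kept, "n_dropped"), 1L)
})

test_that("assignment picks the majority label and flags near ties", {
  one <- assignChromosomes(mkRecord("ctg", "chr5", 950, 1000))
  expect_identical(one$chromosome, "chr5")
  expect_equal(one$support_fraction, 1.0)
  expect_false(one$conflict)

  split7030 <- rbind(mkRecord("ctg", "chrA", 690, 700),
                     mkRecord("ctg", "chrB", 295, 300))
  a <- assignChromosomes(split7030)
  expect_identical(a$chromosome, "chrA")
  expect_equal(a$support_fraction, 0.7)
  expect_false(a$conflict)        # margin 0.4 > 0.1

  split5248 <- rbind(mkRecord("ctg", "chrA", 510, 520),
                     mkRecord("ctg", "chrB", 470, 480))
  b <- assignChromosomes(split5248)
  expect_identical(b$chromosome, "chrA")
  expect_true(b$conflict)         # margin 0.04 is inside the 0.1 band
})

test_that("assignment recovers truth origins on a rearranged synthetic genome", {
  cfg <- synthConfig(genomeLength = 4e5, nChromosomes = 4L, nGenes = 0L,
                     nNumts = 0L, contaminantLength = 0L,
                     contigsPerChromosome = 3L,
                     rearrangements = list(
                       list(type = "fusion", segments = c("S1", "S2")),
                       list(type = "fission", segment = "S3"),
                       list(type = "inversion", segment = "S4")))
  g <- makeGenome(cfg, seed = 131)
  paf <- makeAlignments(g$truth, nDecoys = 8, seed = 131)
  kept <- filterAlignments(paf)
  asg <- assignChromosomes(kept)
  o <- contigOrigin(g$truth)
  # every non-chimeric contig must be assigned its origin segment
  for (i in seq_len(nrow(asg))) {
    segs <- unique(o$segment[o$contig == asg$contig[i]])
    if (length(segs) == 1L)
      expect_identical(asg$chromosome[i], segs)
  }
  # assignment is invariant under reverse-complementing a contig: flipping
  # the strand column must not change any label
  flipped <- kept
  flipped$strand <- ifelse(flipped$strand == "+", "-", "+")
  expect_identical(assignChromosomes(flipped)$chromosome, asg$chromosome)
})

test_that("ordering and orientation follow target coordinates and strand", {
  recs <- rbind(mkRecord("c2", "chr1", 900, 1000, tstart = 1e6),
                mkRecord("c1", "chr1", 900, 1000, tstart = 0),
                mkRecord("c3", "chr1", 900, 1000, strand = "-", tstart = 2e6))
  asg <- assignChromosomes(recs)
  lay <- orderAndOrient(asg, recs)
  expect_identical(lay$layout$contig, c("c1", "c2", "c3"))
  expect_identical(lay$layout$orientation, c("+", "+", "-"))
  # AGP conservation: component rows cover exactly the contig lengths
  comp <- lay$agp[lay$agp$component_type == "W", ]
  expect_equal(sum(comp$object_end - comp$object_beg + 1),
               sum(recs$qlen))
  # coordinates are contiguous and 1-based per object
  for (obj in unique(lay$agp$object)) {
    sub <- lay$agp[lay$agp$object == obj, ]
    expect_equal(sub$object_beg[1], 1)
    expect_true(all(sub$object_beg[-1] == head(sub$object_end, -1) + 1))
  }

  # shuffled contigs from one chromosome recover the truth order
  set.seed(132)
  truthOrder <- sprintf("t%02d", 1:8)
  recs2 <- do.call(rbind, lapply(sample(8), function(i)
    mkRecord(truthOrder[i], "chrX", 950, 1000, tstart = (i - 1) * 1000)))
  lay2 <- orderAndOrient(assignChromosomes(recs2), recs2)
  expect_identical(lay2$layout$contig, truthOrder)
})

test_that("adjacency constraints are vacuous when empty, strict otherwise", {
  recs <- rbind(mkRecord("A", "chr1", 900, 1000, tstart = 0),
                mkRecord("B", "chr1", 900, 1000, tstart = 2000))
  lay <- orderAndOrient(assignChromosomes(recs), recs)$layout
  expect_identical(nrow(consistencyCheck(lay, NULL)), 0L)
  expect_identical(nrow(consistencyCheck(lay, data.frame(a = character(0),
                                                         b = character(0)))),
                   0L)
  viol <- consistencyCheck(lay, data.frame(a = "A", b = "C"))
  expect_identical(nrow(viol), 1L)
  expect_identical(viol$a, "A")
  ok <- consistencyCheck(lay, data.frame(a = "A", b = "B"))
  expect_identical(nrow(ok), 0L)
})

test_that("karyotype reconciliation matches the established correspondence", {
  stats <- reconcileKaryotype(muskoxKaryotype())
  expect_identical(nFusions(stats), 6L)
  expect_identical(nFissions(stats), 1L)
  expect_identical(stats@fundamentalNumber, 58L)
  expect_identical(stats@diploidNumber, 48L)

  # identity mapping: nothing to reconcile
  ident <- karyotypeCorrespondence(setNames(as.list(LETTERS[1:5]),
                                            paste0("chr", 1:5)))
  s0 <- reconcileKaryotype(ident)
  expect_identical(nFusions(s0), 0L)
  expect_identical(nFissions(s0), 0L)

  # empty correspondence
  sEmpty <- reconcileKaryotype(karyotypeCorrespondence(list()))
  expect_identical(nFusions(sEmpty), 0L)
})

test_that("random fusion/fission histories are recovered exactly", {
  set.seed(141)
  for (rep in 1:10) {
    nSeg <- sample(6:12, 1)
    segs <- sprintf("S%d", seq_len(nSeg))
    karyo <- as.list(segs)
    f <- sample(0:3, 1)
    # fusions join whole chromosomes that each carry one distinct segment
    for (i in seq_len(f)) {
      pick <- sample(length(karyo), 2)
      karyo <- c(karyo[-pick], list(c(karyo[[pick[1]]], karyo[[pick[2]]])))
    }
    # fissions split single-segment chromosomes not already involved
    singles <- which(lengths(karyo) == 1)
    gmax <- min(2, length(singles) - 1)
    g <- if (gmax > 0) sample(0:gmax, 1) else 0
    for (i in seq_len(g)) {
      singles <- which(lengths(karyo) == 1)
      tgt <- sample(singles, 1)
      karyo <- c(karyo, karyo[tgt])  # same segment now on two chromosomes
    }
    names(karyo) <- sprintf("chr%d", seq_along(karyo))
    stats <- reconcileKaryotype(karyotypeCorrespondence(karyo))
    expect_identical(nFusions(stats), as.integer(f))
    expect_identical(nFissions(stats), as.integer(g))
    # Euler-style balance on every instance
    nSegU <- length(unique(unlist(karyo)))
    expect_identical(nSegU - length(karyo),
                     as.integer(nFusions(stats) - nFissions(stats)))
  }
})

test_that("fundamental number arithmetic", {
  expect_equal(fundamentalNumber(6, 17), 58)
  expect_equal(fundamentalNumber(0, 0), 0)
  expect_equal(fundamentalNumber(1, 0), 4)
  expect_error(fundamentalNumber(-1, 0), "non-negative")
})

test_that("assembly metrics match hand enumeration and are order-invariant", {
  m1 <- assemblyMetrics(10)
  expect_equal(m1$n50, 10)
  expect_equal(m1$l50, 1)
  m2 <- assemblyMetrics(c(5, 4, 3, 2))
  expect_equal(m2$n50, 4)
  expect_equal(m2$l50, 2)
  set.seed(151)
  lens <- sample.int(1e6, 50)
  expect_identical(assemblyMetrics(lens), assemblyMetrics(sample(lens)))
  expect_error(assemblyMetrics(numeric(0)), "empty")
  expect_error(assemblyMetrics(c(5, 0)), "positive")
})
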