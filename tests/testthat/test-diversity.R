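mkCall <- function(size = 0, gt = "0/1", QD = 20, MQ = 60, SOR = 1, FS = 0,
                   MQRankSum = 0, ReadPosRankSum = 0, pos = 100,
                   chrom = "chr1") {
  ref <- if (size < 0) strrep("A", 1 - size) else "A"
  alt <- if (size > 0) paste0("A", strrep("C", size)) else
    if (size < 0) "A" else "C"
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gt = gt,
             size = size, QD = QD, MQ = MQ, SOR = SOR, FS = FS,
             MQRankSum = MQRankSum, ReadPosRankSum = ReadPosRankSum,
             stringsAsFactors = FALSE)
}

test_that("hard-filter thresholds fire exactly as specified", {
  expect_identical(applyHardFilters(mkCall(QD = 1.9))$filter, "FAIL")
  expect_identical(applyHardFilters(mkCall(QD = 2.1))$filter, "PASS")
  ok <- applyHardFilters(mkCall(QD = 20, MQ = 60, SOR = 1, FS = 0))
  expect_identical(ok$filter, "PASS")

  # SNV-only rules do not apply to indels
  expect_identical(applyHardFilters(mkCall(size = 2, MQ = 10))$filter, "PASS")
  # indel SOR threshold is 10, not 3
  expect_identical(applyHardFilters(mkCall(size = -1, SOR = 5))$filter, "PASS")
  expect_identical(applyHardFilters(mkCall(size = -1, SOR = 11))$filter, "FAIL")

  # missing annotations never fire
  na <- mkCall(); na$MQ <- NA_real_
  expect_identical(applyHardFilters(na)$filter, "PASS")

  # rule provenance is recorded
  f <- applyHardFilters(mkCall(QD = 1, FS = 70))
  expect_match(f$failed_rules, "QD")
  expect_match(f$failed_rules, "FS")

  # SQR accepted as an alias for SOR
  alias <- mkCall(); names(alias)[names(alias) == "SOR"] <- "SQR"
  alias$SQR <- 5
  expect_identical(applyHardFilters(alias)$filter, "FAIL")
})

test_that("filtering is idempotent and reproduces generator truth labels", {
  cfg <- synthConfig(genomeLength = 1e6, nChromosomes = 1L,
                     contigsPerChromosome = 1L, nGenes = 0L, nNumts = 0L,
                     contaminantLength = 0L, hetSnvPerMb = 150,
                     hetIndelPerMb = c("-2" = 30, "-1" = 30,
                                       "1" = 30, "2" = 30))
  g <- makeGenome(cfg, seed = 161)
  calls <- makeVariants(g, cfg, seed = 162, failFraction = 0.4)
  f1 <- applyHardFilters(calls)
  # confusion matrix is diagonal
  expect_identical(f1$filter == "PASS", f1$truth_pass)
  # idempotence
  f2 <- applyHardFilters(f1)
  expect_identical(f1$filter, f2$filter)
})

test_that("heterozygosity spectrum bins, excludes and normalises correctly", {
  empty <- hetSpectrum(mkCall()[0, ], 1e6, maxSize = 3)
  expect_true(all(spectrumCounts(empty) == 0))

  calls <- do.call(rbind, c(replicate(100, mkCall(), simplify = FALSE)))
  spec <- hetSpectrum(calls, 1e6, maxSize = 3)
  expect_equal(unname(ratePerMb(spec)["0"]), 100)

  # homozygous-alt calls are excluded
  hom <- rbind(mkCall(), mkCall(gt = "1/1"), mkCall(gt = "1|1"))
  expect_equal(sum(spectrumCounts(hetSpectrum(hom, 1e6))), 1)

  # phased heterozygotes count
  expect_equal(sum(spectrumCounts(hetSpectrum(mkCall(gt = "0|1"), 1e6))), 1)

  # spectrum conservation with clipping at the bin edges
  mix <- rbind(mkCall(size = 0), mkCall(size = 2), mkCall(size = -5),
               mkCall(size = 12))
  spec2 <- hetSpectrum(mix, 1e6, maxSize = 3)
  expect_equal(sum(spectrumCounts(spec2)), nrow(mix))
  expect_equal(unname(spectrumCounts(spec2)[c("-3", "3")]), c(1L, 1L))

  # failed calls are excluded
  f <- applyHardFilters(rbind(mkCall(), mkCall(QD = 1)))
  expect_equal(sum(spectrumCounts(hetSpectrum(f, 1e6))), 1)
})

test_that("configured heterozygosity rates are recovered across seeds", {
  cfg <- synthConfig(genomeLength = 1e6, nChromosomes = 1L,
                     contigsPerChromosome = 1L, nGenes = 0L, nNumts = 0L,
                     contaminantLength = 0L, hetSnvPerMb = 10,
                     hetIndelPerMb = c("1" = 0))
  g <- makeGenome(cfg, seed = 171)
  total <- 0
  nSeeds <- 10
  for (s in seq_len(nSeeds)) {
    calls <- makeVariants(g, cfg, seed = 1000 + s)
    total <- total + sum(spectrumCounts(hetSpectrum(calls, 1e6)))
  }
  expected <- 10 * nSeeds
  expect_lt(abs(total - expected), 5 * sqrt(expected))
})

test_that("gene-region tabulation respects interval boundaries exactly", {
  exons <- data.frame(gene_id = "g1", chrom = "chr1",
                      start = 100, end = 200)  # 0-based half-open
  inside <- geneRegionVariants(mkCall(pos = 101), exons)   # first base
  expect_equal(inside$n_variants, 1)
  lastBase <- geneRegionVariants(mkCall(pos = 200), exons)
  expect_equal(lastBase$n_variants, 1)
  before <- geneRegionVariants(mkCall(pos = 100), exons)
  expect_equal(before$n_variants, 0)
  after <- geneRegionVariants(mkCall(pos = 201), exons)
  expect_equal(after$n_variants, 0)

  # indels are excluded from profiles
  indel <- geneRegionVariants(mkCall(size = 2, pos = 150), exons)
  expect_equal(indel$n_variants, 0)

  expect_error(geneRegionVariants(mkCall(), exons[0, ]), "interval")
})

test_that("profiles match a brute-force membership oracle", {
  set.seed(181)
  exons <- data.frame(gene_id = rep(c("g1", "g2"), each = 2),
                      chrom = "chr1",
                      start = c(100, 400, 1000, 1500),
                      end = c(200, 500, 1200, 1600))
  calls <- do.call(rbind, lapply(sample.int(2000, 120), function(p)
    mkCall(pos = p)))
  calls$specimen <- sample(c("s1", "s2"), nrow(calls), TRUE)
  prof <- geneRegionVariants(calls, exons)
  for (i in seq_len(nrow(prof))) {
    iv <- exons[exons$gene_id == prof$gene_id[i], ]
    want <- 0L
    sub <- calls[calls$specimen == prof$specimen[i], ]
    for (j in seq_len(nrow(sub))) {
      p <- sub$pos[j]
      if (any(p > iv$start & p <= iv$end)) want <- want + 1L
    }
    expect_equal(prof$n_variants[i], want)
  }
})

test_that("unique profile counting uses set identity", {
  prof <- data.frame(
    specimen = c("s1", "s2", "s3"),
    gene_id = "g1",
    n_variants = c(1, 1, 1),
    profile = c("chr1:5:A", "chr1:5:A", "chr1:9:T"),
    stringsAsFactors = FALSE)
  expect_identical(unname(countUniqueProfiles(prof)), 2L)

  same <- prof; same$profile <- "chr1:5:A"
  expect_identical(unname(countUniqueProfiles(same)), 1L)

  # empty profiles are excluded by default, countable on request
  withEmpty <- prof; withEmpty$profile[3] <- ""
  expect_identical(unname(countUniqueProfiles(withEmpty)), 1L)
  expect_identical(unname(countUniqueProfiles(withEmpty,
                                              includeEmpty = TRUE)), 2L)

  # invariant under specimen reordering; reference specimen excludable
  shuffled <- prof[c(3, 1, 2), ]
  expect_identical(countUniqueProfiles(shuffled), countUniqueProfiles(prof))
  expect_identical(unname(countUniqueProfiles(prof,
                                              excludeSpecimens = "s3")), 1L)
})

test_that("random profile matrices match a brute-force set cardinality", {
  set.seed(191)
  for (rep in 1:5) {
    nSpec <- sample(3:8, 1)
    sites <- sprintf("chr1:%d:A", sample.int(50, 6))
    profs <- vapply(seq_len(nSpec), function(i) {
      chosen <- sites[runif(length(sites)) < 0.5]
      paste(sort(chosen), collapse = ",")
    }, character(1))
    df <- data.frame(specimen = sprintf("s%d", seq_len(nSpec)),
                     gene_id = "g", n_variants = 1, profile = profs,
                     stringsAsFactors = FALSE)
    brute <- length(unique(profs[nzchar(profs)]))
    expect_identical(unname(countUniqueProfiles(df)), brute)
  }
})
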