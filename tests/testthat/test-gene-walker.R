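test_that("seed finding recovers planted copies on either strand", {
  exon <- randomSeq(150, seed = 31)
  host <- plantIn(20000, exon, 5000, seed = 32)
  asm <- Biostrings::DNAStringSet(c(ctgA = host))
  q <- exonQuerySet("g1", 1L, exon, c(g1 = "MFAKE"))

  hit <- findSeedExon(asm, q, "g1")
  expect_equal(hit$start, 5000)
  expect_equal(hit$end, 5150)
  expect_identical(hit$strand, "+")
  expect_equal(hit$identity, 1.0)

  # reverse-strand planting: same score, strand '-'
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(exon)))
  hostRc <- plantIn(20000, rc, 5000, seed = 32)
  hitRc <- findSeedExon(Biostrings::DNAStringSet(c(ctgA = hostRc)), q, "g1")
  expect_identical(hitRc$strand, "-")
  expect_equal(hitRc$score, hit$score)
  expect_equal(hitRc$start, 5000)
})

test_that("the seed is the highest-identity copy when two are planted", {
  exon <- randomSeq(150, seed = 41)
  degraded <- mutateN(exon, 15, seed = 42)   # 90% identity copy
  host <- randomSeq(30000, seed = 43)
  substr(host, 2001, 2150) <- degraded
  substr(host, 20001, 20150) <- exon
  asm <- Biostrings::DNAStringSet(c(ctg = host))
  q <- exonQuerySet("g1", 1L, exon, c(g1 = "MFAKE"))
  hit <- findSeedExon(asm, q, "g1")
  expect_equal(hit$start, 20000)
  expect_equal(hit$identity, 1.0)
})

test_that("walking recovers a three-exon gene at truth coordinates", {
  cfg <- synthConfig(genomeLength = 1.5e5, nChromosomes = 1L,
                     contigsPerChromosome = 1L, nGenes = 1L,
                     exonsPerGene = c(3L, 3L), intronLength = c(400L, 600L),
                     nNumts = 0L, contaminantLength = 0L)
  g <- makeGenome(cfg, seed = 51)
  q <- exonQueriesFromTruth(g)
  seed <- findSeedExon(g$assembly, q, "gene0001")
  chain <- walkExons(g$assembly, seed, q)
  gm <- geneModels(g$truth)
  expect_equal(nrow(chain), 3)
  expect_equal(chain$start + 1, GenomicRanges::start(gm)[order(gm$exon_rank)])
  expect_equal(chain$end, GenomicRanges::end(gm)[order(gm$exon_rank)])
  v <- classifyGene(g$assembly, chain, q, "gene0001")
  expect_identical(geneStatus(v), "complete")
  expect_equal(proteinIdentity(v), 1.0)
})

test_that("a deleted middle exon leaves the gene fragmented", {
  cfg <- synthConfig(genomeLength = 1.5e5, nChromosomes = 1L,
                     contigsPerChromosome = 1L, nGenes = 1L,
                     exonsPerGene = c(3L, 3L), intronLength = c(400L, 600L),
                     nNumts = 0L, contaminantLength = 0L)
  g <- makeGenome(cfg, seed = 52)
  q <- exonQueriesFromTruth(g)
  gm <- geneModels(g$truth)
  gm <- gm[order(gm$exon_rank)]
  # overwrite the middle exon with unrelated sequence
  ctg <- names(g$assembly)[1]
  s <- as.character(g$assembly[[ctg]])
  mid <- 2L
  repl <- randomSeq(GenomicRanges::width(gm)[mid], seed = 53)
  substr(s, GenomicRanges::start(gm)[mid], GenomicRanges::end(gm)[mid]) <- repl
  asm <- Biostrings::DNAStringSet(setNames(s, ctg))
  v <- verifyGenes(asm, q)[["gene0001"]]
  expect_identical(geneStatus(v), "fragmented")
})

test_that("a missing gene classifies as missing", {
  asm <- Biostrings::DNAStringSet(c(ctg = randomSeq(30000, seed = 61)))
  q <- exonQuerySet("g1", 1L, randomSeq(150, seed = 62), c(g1 = "MFAKE"))
  v <- verifyGenes(asm, q)[["g1"]]
  expect_identical(geneStatus(v), "missing")
  expect_identical(nrow(exonHits(v)), 0L)
})

test_that("a 25-kb intron is crossed on the third window extension", {
  cds <- paste0("ATG", strrep("GCT", 80), "TGGCCA", strrep("AAC", 80), "TAG")
  brk <- 246  # split keeps both exons > 200 bp
  exons <- c(substr(cds, 1, brk), substr(cds, brk + 1, nchar(cds)))
  gene <- handGene(exons, 25000L, seed = 63)
  host <- plantIn(60000, gene$seq, 10000, seed = 64)
  asm <- Biostrings::DNAStringSet(c(ctg = host))
  prot <- sub("\\*$", "", as.character(
    Biostrings::translate(Biostrings::DNAString(cds))))
  q <- exonQuerySet(c("g1", "g1"), 1:2, exons, c(g1 = prot))
  seed <- findSeedExon(asm, q, "g1")
  chain <- walkExons(asm, seed, q, window = 10000)
  expect_equal(nrow(chain), 2)
  other <- chain[chain$exon_index != seed$exon_index, ]
  expect_identical(other$extension, 3L)
  v <- classifyGene(asm, chain, q, "g1")
  expect_identical(geneStatus(v), "complete")
})

test_that("the identity threshold separates complete from fragmented", {
  cfg <- synthConfig(genomeLength = 1.5e5, nChromosomes = 1L,
                     contigsPerChromosome = 1L, nGenes = 1L,
                     exonsPerGene = c(2L, 2L), nNumts = 0L,
                     contaminantLength = 0L)
  g <- makeGenome(cfg, seed = 71)
  q <- exonQueriesFromTruth(g)
  prot <- queryProtein(q, "gene0001")
  # degrade the query protein so identity drops below 0.70
  aa <- strsplit(prot, "")[[1]]
  set.seed(72)
  swap <- sample(seq_along(aa), ceiling(0.35 * length(aa)))
  aa[swap] <- vapply(aa[swap], function(x)
    sample(setdiff(c("A", "G", "V", "L", "S", "T", "P"), x), 1), character(1))
  qBad <- exonQuerySet(q@geneId, q@exonIndex, q@seq,
                       setNames(paste(aa, collapse = ""), "gene0001"))
  vGood <- verifyGenes(g$assembly, q)[["gene0001"]]
  vBad <- verifyGenes(g$assembly, qBad)[["gene0001"]]
  expect_identical(geneStatus(vGood), "complete")
  expect_identical(geneStatus(vBad), "fragmented")
  expect_lt(proteinIdentity(vBad), 0.70)
  expect_match(vBad@reason, "identity")
})

test_that("reverse-complementing a contig leaves gene status unchanged", {
  cfg <- synthConfig(genomeLength = 2e5, nChromosomes = 1L,
                     contigsPerChromosome = 1L, nGenes = 3L,
                     nNumts = 0L, contaminantLength = 0L)
  g <- makeGenome(cfg, seed = 81)
  q <- exonQueriesFromTruth(g)
  fwd <- verificationTable(verifyGenes(g$assembly, q))
  rcAsm <- Biostrings::reverseComplement(g$assembly)
  names(rcAsm) <- names(g$assembly)
  rev <- verificationTable(verifyGenes(rcAsm, q))
  expect_identical(fwd$status, rev$status)
  expect_equal(fwd$identity, rev$identity)
})

test_that("rescue accounting reproduces the marker-set arithmetic", {
  # 8852 of 9226 complete before rescue
  empty <- rescueReport(list(), 9226, 8852)
  expect_equal(round(empty$preCompleteness, 1), 95.9)
  expect_equal(round(100 - empty$preCompleteness, 1), 4.1)
  expect_identical(unname(empty$statusCounts), c(0L, 0L, 0L))

  # all 374 fragmented/missing genes rescued -> 100%
  fake <- replicate(374, new("GeneVerification", geneId = "g",
                             hits = data.frame(x = 1), cds = "ATGTAG",
                             protein = "M", identity = 1, hasStart = TRUE,
                             hasStop = TRUE, status = "complete",
                             reason = ""), simplify = FALSE)
  full <- rescueReport(fake, 9226, 8852)
  expect_equal(full$revisedCompleteness, 100)
})
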