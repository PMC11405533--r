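# Shared fixture builders. Everything is generated in code; seeds are fixed
# so every run sees identical data.

tinyConfig <- function(nGenes = 5L, nNumts = 3L, contaminantLength = 8000L,
                       ...) {
  synthConfig(genomeLength = 2e5, nChromosomes = 2L, nGenes = nGenes,
              nNumts = nNumts, contaminantLength = contaminantLength,
              contigsPerChromosome = 2L, ...)
}

# A gene hand-built base by base: exon sequences, intron lengths and the
# expected protein are all known independently of the generator.
handGene <- function(exonSeqs, intronLens, donor = "GT", acceptor = "AG",
                     seed = 99L) {
  set.seed(seed)
  introns <- vapply(intronLens, function(l)
    paste0(donor, paste(sample(c("A", "C", "G", "T"), l - 4L, TRUE),
                        collapse = ""), acceptor), character(1))
  pieces <- character(0)
  offsets <- integer(length(exonSeqs))
  at <- 0L
  for (i in seq_along(exonSeqs)) {
    offsets[i] <- at
    pieces <- c(pieces, exonSeqs[i])
    at <- at + nchar(exonSeqs[i])
    if (i <= length(introns)) {
      pieces <- c(pieces, introns[i])
      at <- at + nchar(introns[i])
    }
  }
  list(seq = paste(pieces, collapse = ""), offsets = offsets,
       cds = paste(exonSeqs, collapse = ""))
}

randomSeq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

# Plant `insert` inside a random host sequence at 0-based `at`.
plantIn <- function(hostLen, insert, at, seed = 1L) {
  host <- randomSeq(hostLen, seed = seed)
  stopifnot(at + nchar(insert) <= hostLen)
  substr(host, at + 1L, at + nchar(insert)) <- insert
  host
}

# Mutate exactly `n` positions of a sequence (substitutions only).
mutateN <- function(seq, n, seed = 1L) {
  set.seed(seed)
  ch <- strsplit(seq, "")[[1L]]
  pos <- sample(length(ch), n)
  ch[pos] <- vapply(ch[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  paste(ch, collapse = "")
}
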