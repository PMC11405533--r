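## Readers and writers for the standard formats the toolkit exchanges:
## FASTA (Biostrings), GFF3 (rtracklayer), PAF, VCF 4.2, AGP 2.1, TSV.

#' Read and write FASTA
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()]; sequence content round-trips
#' byte-stably (case is normalised to upper on read).
#'
#' @param path File path.
#' @return `readFasta` returns a [Biostrings::DNAStringSet].
#' @export
readFasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ## keep only the id token of each header, as alignment tools do
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  Biostrings::DNAStringSet(toupper(seqs))
}

#' @rdname readFasta
#' @param seqs A [Biostrings::DNAStringSet] (or named character vector).
#' @export
writeFasta <- function(seqs, path) {
  if (!is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, filepath = path, width = 70L)
  invisible(path)
}

#' Read PAF alignment records
#'
#' Parses the 12 mandatory PAF columns (optional SAM-style tags are
#' ignored) and computes `divergence = 1 - nmatch / blocklen`.
#'
#' @param path PAF file path.
#' @return data.frame with columns `qname`, `qlen`, `qstart`, `qend`,
#'   `strand`, `tname`, `tlen`, `tstart`, `tend`, `nmatch`, `blocklen`,
#'   `mapq`, `divergence`.
#' @export
readPaf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  cols <- c("qname", "qlen", "qstart", "qend", "strand", "tname", "tlen",
            "tstart", "tend", "nmatch", "blocklen", "mapq")
  if (!length(lines)) {
    out <- as.data.frame(setNames(rep(list(character(0)), 12L), cols))
    out$divergence <- numeric(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 12L
  if (any(short))
    stop("PAF parse error: line ", which(short)[1L], " has fewer than 12 columns")
  mat <- t(vapply(fields, function(f) f[1:12], character(12L)))
  out <- data.frame(mat, stringsAsFactors = FALSE)
  names(out) <- cols
  numCols <- c("qlen", "qstart", "qend", "tlen", "tstart", "tend", "nmatch",
               "blocklen", "mapq")
  for (cc in numCols) out[[cc]] <- as.numeric(out[[cc]])
  if (any(out$strand != "+" & out$strand != "-"))
    stop("PAF parse error: invalid strand")
  if (any(out$qstart >= out$qend | out$qend > out$qlen |
          out$tstart >= out$tend | out$tend > out$tlen))
    stop("PAF parse error: coordinates out of range")
  out$divergence <- 1 - out$nmatch / out$blocklen
  out
}

#' @rdname readPaf
#' @param records Alignment data.frame in `readPaf` layout.
#' @export
writePaf <- function(records, path) {
  cols <- c("qname", "qlen", "qstart", "qend", "strand", "tname", "tlen",
            "tstart", "tend", "nmatch", "blocklen", "mapq")
  lines <- do.call(paste, c(lapply(cols, function(cc) {
    v <- records[[cc]]
    if (is.numeric(v)) format(v, scientific = FALSE, trim = TRUE) else v
  }), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write AGP 2.1 rows
#'
#' @param agp AGP data.frame from [orderAndOrient()].
#' @param path Output path.
#' @export
writeAgp <- function(agp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  utils::write.table(agp, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' Emits the truth exon coordinates (1-based on output, per the standard).
#'
#' @param geneModels A [GenomicRanges::GRanges] with `gene_id` and
#'   `exon_rank` metadata columns.
#' @param path Output path.
#' @export
writeGff3 <- function(geneModels, path) {
  gr <- geneModels
  gr$type <- "exon"
  gr$ID <- paste0(gr$gene_id, ".exon", gr$exon_rank)
  gr$Parent <- gr$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read exon models from GFF3
#'
#' @param path GFF3 path.
#' @return A [GenomicRanges::GRanges] with `gene_id` and `exon_rank`.
#' @export
readGff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "exon"]
  GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(gr),
    ranges = IRanges::ranges(gr),
    strand = GenomicRanges::strand(gr),
    gene_id = as.character(gr$gene_id),
    exon_rank = as.integer(gr$exon_rank))
}

#' Write variant records as VCF 4.2
#'
#' @param records Variant data.frame from [makeVariants()] (columns `chrom`,
#'   `pos`, `ref`, `alt`, `gt` and the INFO annotations).
#' @param path Output path.
#' @param contigLengths Optional named vector for `##contig` headers.
#' @export
writeVcfRecords <- function(records, path, contigLengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=oxqc",
               if (!is.null(contigLengths))
                 sprintf("##contig=<ID=%s,length=%d>", names(contigLengths),
                         as.integer(contigLengths)),
               sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
                       c("QD", "MQ", "SOR", "FS", "MQRankSum", "ReadPosRankSum"),
                       "Annotation"),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "sample1"), collapse = "\t")), con)
  if (nrow(records)) {
    anns <- c("QD", "MQ", "SOR", "FS", "MQRankSum", "ReadPosRankSum")
    info <- apply(records[, anns, drop = FALSE], 1L, function(v)
      paste(sprintf("%s=%.4f", anns, as.numeric(v)), collapse = ";"))
    lines <- paste(records$chrom, records$pos, ".", records$ref, records$alt,
                   "30", ".", info, "GT", records$gt, sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read variant calls from a VCF file
#'
#' Parses a VCF 4.2 file into the flat call layout the diversity module
#' consumes, splitting multi-allelic records into biallelic calls first.
#' INFO keys `QD`, `MQ`, `SOR` (or `SQR`), `FS`, `MQRankSum` and
#' `ReadPosRankSum` are extracted when present (absent keys become NA).
#'
#' @param path VCF path.
#' @param specimen Specimen id attached to the calls (defaults to the
#'   sample name in the VCF, or `"specimen1"`).
#' @return data.frame of calls (`chrom`, `pos`, `ref`, `alt`, `gt`, `size`,
#'   annotations, `specimen`).
#' @export
readVariantCalls <- function(path, specimen = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fm <- vcfR::getFIX(v)
  if (is.null(dim(fm))) fm <- t(fm)   # single-record VCFs drop to a vector
  fix <- as.data.frame(fm, stringsAsFactors = FALSE)
  anns <- c("QD", "MQ", "SOR", "FS", "MQRankSum", "ReadPosRankSum")
  getInfo <- function(key) {
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = key)))
  }
  infoVals <- lapply(anns, getInfo)
  names(infoVals) <- anns
  sqr <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = "SQR")))
  if (all(is.na(infoVals$SOR)) && any(!is.na(sqr))) infoVals$SOR <- sqr
  gtMat <- tryCatch(vcfR::extract.gt(v, element = "GT"),
                    error = function(e) NULL)
  gt <- if (is.null(gtMat)) rep("0/1", nrow(fix)) else unname(gtMat[, 1L])
  if (is.null(specimen))
    specimen <- if (!is.null(gtMat)) colnames(gtMat)[1L] else "specimen1"
  base <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT, gt = gt,
                     stringsAsFactors = FALSE)
  for (a in anns) base[[a]] <- infoVals[[a]]
  ## split multi-allelic records into biallelic calls
  multi <- grepl(",", base$alt, fixed = TRUE)
  if (any(multi)) {
    pieces <- lapply(which(multi), function(i) {
      alts <- strsplit(base$alt[i], ",", fixed = TRUE)[[1L]]
      row <- base[rep(i, length(alts)), , drop = FALSE]
      row$alt <- alts
      row
    })
    base <- rbind(base[!multi, , drop = FALSE], do.call(rbind, pieces))
    base <- base[order(base$chrom, base$pos), , drop = FALSE]
  }
  base$size <- nchar(base$alt) - nchar(base$ref)
  base$specimen <- specimen
  rownames(base) <- NULL
  base
}
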