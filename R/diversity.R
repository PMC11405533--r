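## GATK-style hard filtering, heterozygosity spectra, and per-gene variant
## profile tabulation.

#' Hard-filter criteria for SNVs and indels
#'
#' The conventional germline hard-filter thresholds: an SNV fails when
#' `QD < 2.0`, `MQ < 40.0`, `SOR > 3.0`, `FS > 60.0`, `MQRankSum < -12.5` or
#' `ReadPosRankSum < -8.0`; an indel fails when `QD < 2.0`, `SOR > 10.0`,
#' `FS > 200.0` or `ReadPosRankSum < -20.0`. A missing annotation never
#' fires a rule. `SQR` is accepted as an input alias for `SOR`.
#'
#' @param snv,indel Optional named lists overriding individual thresholds.
#' @return A list of class `filter_criteria` with `snv` and `indel`
#'   threshold sets.
#' @export
hardFilterCriteria <- function(snv = list(), indel = list()) {
  defSnv <- list(QD = c("<", 2.0), MQ = c("<", 40.0), SOR = c(">", 3.0),
                 FS = c(">", 60.0), MQRankSum = c("<", -12.5),
                 ReadPosRankSum = c("<", -8.0))
  defIndel <- list(QD = c("<", 2.0), SOR = c(">", 10.0), FS = c(">", 200.0),
                   ReadPosRankSum = c("<", -20.0))
  structure(list(snv = utils::modifyList(defSnv, snv),
                 indel = utils::modifyList(defIndel, indel)),
            class = "filter_criteria")
}

#' Apply hard filters to variant calls
#'
#' Calls are typed SNV/indel by their size class (`size == 0` for SNVs,
#' inferred from `nchar(alt) - nchar(ref)` when absent). A call passes when
#' no applicable rule fires; failed calls record which rules fired. Missing
#' (NA) annotations never fire. Columns named `SQR` are treated as `SOR`.
#'
#' @param calls data.frame of variant calls with annotation columns among
#'   `QD`, `MQ`, `SOR`, `FS`, `MQRankSum`, `ReadPosRankSum`.
#' @param criteria From [hardFilterCriteria()].
#' @return `calls` with columns `filter` (`"PASS"` or `"FAIL"`) and
#'   `failed_rules` (semicolon-separated rule provenance).
#' @export
applyHardFilters <- function(calls, criteria = hardFilterCriteria()) {
  stopifnot(is.data.frame(calls), inherits(criteria, "filter_criteria"))
  if (!nrow(calls)) {
    calls$filter <- character(0)
    calls$failed_rules <- character(0)
    return(calls)
  }
  if (is.null(calls$size))
    calls$size <- nchar(calls$alt) - nchar(calls$ref)
  if (!is.null(calls$SQR) && is.null(calls$SOR)) calls$SOR <- calls$SQR
  isSnv <- calls$size == 0
  failed <- rep("", nrow(calls))
  for (type in c("snv", "indel")) {
    sel <- if (type == "snv") isSnv else !isSnv
    for (ann in names(criteria[[type]])) {
      if (is.null(calls[[ann]])) next
      rule <- criteria[[type]][[ann]]
      thr <- as.numeric(rule[2L])
      val <- calls[[ann]]
      fires <- sel & !is.na(val) &
        (if (rule[1L] == "<") val < thr else val > thr)
      tag <- sprintf("%s%s%g", ann, rule[1L], thr)
      failed[fires] <- ifelse(nzchar(failed[fires]),
                              paste(failed[fires], tag, sep = ";"), tag)
    }
  }
  calls$filter <- ifelse(nzchar(failed), "FAIL", "PASS")
  calls$failed_rules <- failed
  calls
}

isHetGenotype <- function(gt) {
  parts <- strsplit(gsub("\\|", "/", gt), "/", fixed = FALSE)
  vapply(parts, function(p) length(unique(p)) > 1L, logical(1))
}

#' Heterozygosity spectrum per megabase by variant size
#'
#' Bins heterozygous passing calls by size class (`nchar(alt) - nchar(ref)`:
#' negative for deletions, 0 for SNVs, positive for insertions), clipping
#' at `+/- maxSize`, and normalises to rates per megabase of reference
#' sequence. Homozygous-alt calls and calls failing filters are excluded.
#'
#' @param calls data.frame of calls; if a `filter` column exists only
#'   `"PASS"` calls are used.
#' @param referenceLength Reference length in bp (> 0).
#' @param maxSize Clipping bound k (default 10).
#' @return A [HetSpectrum-class].
#' @export
hetSpectrum <- function(calls, referenceLength, maxSize = 10L) {
  stopifnot(referenceLength > 0)
  maxSize <- as.integer(maxSize)
  if (!is.null(calls$filter)) calls <- calls[calls$filter == "PASS", , drop = FALSE]
  if (is.null(calls$size) && nrow(calls))
    calls$size <- nchar(calls$alt) - nchar(calls$ref)
  if (nrow(calls)) calls <- calls[isHetGenotype(calls$gt), , drop = FALSE]
  bins <- seq.int(-maxSize, maxSize)
  counts <- setNames(integer(length(bins)), as.character(bins))
  if (nrow(calls)) {
    clipped <- pmax(-maxSize, pmin(maxSize, calls$size))
    tab <- table(factor(clipped, levels = bins))
    counts[] <- as.integer(tab)
  }
  new("HetSpectrum", counts = counts,
      referenceLength = as.numeric(referenceLength), maxSize = maxSize)
}

#' Tabulate single-base variants within gene exon regions
#'
#' For each specimen and gene, collects the set of single-base substitution
#' calls whose positions fall inside the gene's exon intervals (1-based
#' closed membership; interval input is 0-based half-open). Indels are
#' excluded. The resulting position/alt sets are the variant profiles whose
#' distinct combinations measure allelic diversity.
#'
#' @param calls data.frame with at least `chrom`, `pos` (1-based), `ref`,
#'   `alt` and optionally `specimen` (a single anonymous specimen is assumed
#'   when absent). Only `"PASS"` calls are used when a `filter` column
#'   exists.
#' @param exons Exon intervals per gene: data.frame with `gene_id`, `chrom`,
#'   `start`, `end` (0-based half-open), or a [GenomicRanges::GRanges] with
#'   a `gene_id` column (1-based closed, as usual).
#' @return data.frame with one row per (specimen, gene): `specimen`,
#'   `gene_id`, `n_variants`, `profile` (canonical `pos:alt` string, empty
#'   when no variants).
#' @export
geneRegionVariants <- function(calls, exons) {
  if (is(exons, "GRanges")) {
    exons <- data.frame(gene_id = exons$gene_id,
                        chrom = as.character(GenomicRanges::seqnames(exons)),
                        start = GenomicRanges::start(exons) - 1L,
                        end = GenomicRanges::end(exons),
                        stringsAsFactors = FALSE)
  }
  genes <- unique(exons$gene_id)
  if (!length(genes)) stop("no exon intervals supplied")
  bad <- vapply(genes, function(g) !any(exons$gene_id == g), logical(1))
  if (any(bad)) stop("gene without intervals")
  if (!is.null(calls$filter)) calls <- calls[calls$filter == "PASS", , drop = FALSE]
  if (is.null(calls$specimen)) calls$specimen <- "specimen1"
  snv <- calls[nchar(calls$ref) == 1L & nchar(calls$alt) == 1L, , drop = FALSE]
  specimens <- unique(calls$specimen)
  rows <- list()
  for (sp in specimens) {
    sub <- snv[snv$specimen == sp, , drop = FALSE]
    for (g in genes) {
      iv <- exons[exons$gene_id == g, , drop = FALSE]
      inGene <- logical(nrow(sub))
      for (i in seq_len(nrow(iv))) {
        ## 0-based half-open [start, end) contains 1-based pos iff
        ## start < pos <= end
        inGene <- inGene | (sub$chrom == iv$chrom[i] &
                            sub$pos > iv$start[i] & sub$pos <= iv$end[i])
      }
      hits <- sub[inGene, , drop = FALSE]
      prof <- if (nrow(hits))
        paste(sort(paste0(hits$chrom, ":", hits$pos, ":", hits$alt)),
              collapse = ",") else ""
      rows[[length(rows) + 1L]] <- data.frame(
        specimen = sp, gene_id = g, n_variants = nrow(hits),
        profile = prof, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count unique variant profiles per gene across specimens
#'
#' A variant profile is the set of single-base variants a specimen carries
#' within a gene's exons; the count is the number of distinct non-empty
#' profiles across specimens (set identity, invariant under specimen
#' order). Empty profiles denote "no variants" and are excluded by default;
#' set `includeEmpty = TRUE` to count them as one shared profile.
#'
#' @param profiles data.frame from [geneRegionVariants()].
#' @param includeEmpty Whether the empty profile counts as a profile.
#' @param excludeSpecimens Specimens to drop before counting (e.g. the
#'   reference-derived specimen).
#' @return Named integer vector of unique-profile counts per gene.
#' @export
countUniqueProfiles <- function(profiles, includeEmpty = FALSE,
                                excludeSpecimens = character(0)) {
  stopifnot(is.data.frame(profiles))
  profiles <- profiles[!profiles$specimen %in% excludeSpecimens, , drop = FALSE]
  vapply(split(profiles$profile, profiles$gene_id), function(p) {
    if (!includeEmpty) p <- p[nzchar(p)]
    length(unique(p))
  }, integer(1))
}
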