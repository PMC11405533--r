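## End-to-end pipeline over the synthetic generator and every analysis
## stage, with a JSON-able summary. The command-line entry point in
## inst/exec/oxqc is a thin wrapper over these functions.

#' Default pipeline configuration
#'
#' Stage toggles and per-stage parameters. Defaults mirror the conventional
#' analysis values: 5 kb contamination windows, 10 kb gene-walking windows,
#' 50 bp coverage tiling windows, a 20% alignment divergence cap, a 70%
#' protein-identity completeness threshold, and the standard hard-filter
#' thresholds. Unknown keys are rejected when merging.
#'
#' @param ... Named overrides, e.g. `pipelineConfig(screens = list(window =
#'   2000))`.
#' @return Nested list of class `pipeline_config`.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    stages = list(simulate = TRUE, orf_accuracy = TRUE, gene_walker = FALSE,
                  screens = TRUE, synteny = TRUE, karyotype = TRUE,
                  diversity = TRUE),
    synth = list(),                      # overrides for synthConfig()
    orf_accuracy = list(),
    gene_walker = list(window = 10000, min_identity = 0.70,
                       max_genes = 10),
    screens = list(window = 5000, min_identity = 0.95,
                   tiling_window = 50, tiling_depth = 7500),
    synteny = list(max_divergence = 0.20, n_decoys = 5),
    diversity = list(max_size = 10, fail_fraction = 0.2)
  )
  mergeConfig(cfg, list(...))
}

mergeConfig <- function(base, override, path = "") {
  for (key in names(override)) {
    if (!key %in% names(base))
      stop("unknown configuration key: ", paste0(path, key))
    if (is.list(base[[key]]) && is.list(override[[key]]) &&
        !is.null(names(base[[key]]))) {
      base[[key]] <- mergeConfig(base[[key]], override[[key]],
                                 paste0(path, key, "."))
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Configuration file; keys override [pipelineConfig()]
#'   defaults, unknown keys are rejected.
#' @return A `pipeline_config` list.
#' @export
readPipelineConfig <- function(path) {
  override <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(pipelineConfig, override %||% list())
}

#' Run the full synthetic-data pipeline
#'
#' Simulates a genome under the configuration, then runs each enabled stage
#' and aggregates the key numbers into one summary list: the inferred
#' accuracy bound, gene-verification completeness, contamination calls,
#' NUMT recall, karyotype statistics and the heterozygosity spectrum. Two
#' runs with the same configuration and seed give identical summaries.
#'
#' @param config From [pipelineConfig()] / [readPipelineConfig()].
#' @param seed Integer seed for every stochastic stage.
#' @param outdir Optional directory; when given, per-stage artifacts
#'   (FASTA/GFF3/VCF/PAF/AGP/JSON) are written there.
#' @return Nested summary list (also written as `summary.json` under
#'   `outdir`).
#' @export
runPipeline <- function(config = pipelineConfig(), seed = 1L, outdir = NULL) {
  summary <- list(seed = seed)
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  st <- config$stages
  if (!isTRUE(st$simulate)) {
    if (!is.null(outdir))
      jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                           auto_unbox = TRUE, digits = NA)
    return(summary)
  }

  synthArgs <- config$synth
  scfg <- do.call(synthConfig, synthArgs)
  genome <- makeGenome(scfg, seed = seed)
  truth <- genome$truth
  nuclear <- setdiff(names(genome$assembly),
                     c(contaminantIds(truth), "MT"))
  summary$simulate <- list(
    n_contigs = length(genome$assembly),
    n_genes = length(unique(geneModels(truth)$gene_id)),
    n_numts = length(numtLoci(truth)))
  if (!is.null(outdir)) {
    writeFasta(genome$assembly, file.path(outdir, "assembly.fa"))
    if (length(geneModels(truth)))
      writeGff3(geneModels(truth), file.path(outdir, "genes.gff3"))
  }

  if (isTRUE(st$orf_accuracy) && length(geneModels(truth))) {
    catalog <- countOrfCodons(genome$assembly, geneModels(truth))
    bound <- accuracyBound(totalCodons(catalog),
                           nStops = internalStops(catalog))
    summary$orf_accuracy <- list(
      total_codons = totalCodons(catalog),
      internal_stops = internalStops(catalog),
      accuracy_percent = accuracyPercent(bound),
      phred = round(phredScore(bound), 4),
      bases_per_error = basesPerError(bound))
  }

  if (isTRUE(st$gene_walker) && length(geneModels(truth))) {
    queries <- exonQueriesFromTruth(genome)
    keep <- head(queryGenes(queries), config$gene_walker$max_genes)
    sel <- queries@geneId %in% keep
    sub <- exonQuerySet(queries@geneId[sel], queries@exonIndex[sel],
                        queries@seq[sel], queries@protein[keep])
    ver <- verifyGenes(genome$assembly, sub,
                       window = config$gene_walker$window,
                       minIdentity = config$gene_walker$min_identity)
    tab <- verificationTable(ver)
    summary$gene_walker <- list(
      n_verified = nrow(tab),
      n_complete = sum(tab$status == "complete"),
      completeness_percent = 100 * mean(tab$status == "complete"))
  }

  if (isTRUE(st$screens)) {
    contam <- genome$assembly[contaminantIds(truth)]
    if (length(contam)) {
      scr <- windowScreen(genome$assembly[c(nuclear, contaminantIds(truth))],
                          contam,
                          window = config$screens$window,
                          minIdentity = config$screens$min_identity)
      summary$screens$contamination <- list(
        n_positive_windows = nrow(scr$windows),
        n_remove = sum(scr$calls$action == "remove"))
    }
    loci <- numtScan(genome$assembly[c(nuclear, "MT")], genome$mito)
    hits <- GenomicRanges::countOverlaps(numtLoci(truth), loci)
    summary$screens$numt <- list(
      n_truth = length(numtLoci(truth)),
      n_found = length(loci),
      recall = if (length(numtLoci(truth))) mean(hits > 0) else NA)
  }

  if (isTRUE(st$synteny)) {
    paf <- makeAlignments(truth, nDecoys = config$synteny$n_decoys,
                          seed = seed)
    kept <- filterAlignments(paf,
                             maxDivergence = config$synteny$max_divergence)
    asg <- assignChromosomes(kept)
    metrics <- assemblyMetrics(
      Biostrings::width(genome$assembly[nuclear]))
    summary$synteny <- list(
      n_alignments = nrow(paf), n_kept = nrow(kept),
      n_assigned = nrow(asg), n50 = metrics$n50, l50 = metrics$l50)
    if (!is.null(outdir)) {
      writePaf(paf, file.path(outdir, "alignments.paf"))
      layout <- orderAndOrient(asg, kept)
      writeAgp(layout$agp, file.path(outdir, "scaffolds.agp"))
    }
  }

  if (isTRUE(st$karyotype)) {
    stats <- reconcileKaryotype(muskoxKaryotype())
    summary$karyotype <- list(
      n_fusions = nFusions(stats), n_fissions = nFissions(stats),
      fundamental_number = stats@fundamentalNumber,
      diploid_number = stats@diploidNumber)
  }

  if (isTRUE(st$diversity)) {
    calls <- makeVariants(genome, scfg, seed = seed,
                          failFraction = config$diversity$fail_fraction)
    filtered <- applyHardFilters(calls)
    refLen <- sum(Biostrings::width(genome$assembly[nuclear]))
    spec <- hetSpectrum(filtered, refLen,
                        maxSize = config$diversity$max_size)
    summary$diversity <- list(
      n_calls = nrow(calls),
      n_pass = sum(filtered$filter == "PASS"),
      het_snv_per_mb = unname(ratePerMb(spec)["0"]))
    if (!is.null(outdir))
      writeVcfRecords(calls, file.path(outdir, "variants.vcf"),
                      contigLengths = setNames(
                        Biostrings::width(genome$assembly),
                        names(genome$assembly)))
  }

  if (!is.null(outdir))
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  summary
}
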