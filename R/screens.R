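## Windowed contamination screening, marker screening, NUMT scanning, and
## mitochondrial circularization / coverage-tiling validation.
##
## Alignment-based screens share one strategy: exact k-mers of the subject
## locate candidate regions in the assembly (seed), and affine-gap local
## alignment scores the candidate (extend). E-value-style thresholds are
## approximated by a Karlin-Altschul minimum score for the +1/-1 scoring
## scheme (lambda = ln 3 for equifrequent bases); identity and length
## thresholds are exposed directly.

## Anchor pairs between `contig` and `subject`: 1-based start positions of
## every shared exact k-mer, found with a constant-width dictionary
## (Aho-Corasick via matchPDict). Returns data.frame(qpos, tpos).
kmerAnchors <- function(contig, subject, k = 13L, maxPerKmer = 8L) {
  subjChar <- toupper(as.character(subject))
  n <- nchar(subjChar)
  empty <- data.frame(qpos = integer(0), tpos = integer(0))
  if (n < k) return(empty)
  tstarts <- seq_len(n - k + 1L)
  kmers <- substring(subjChar, tstarts, tstarts + k - 1L)
  byKmer <- split(tstarts, kmers)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(names(byKmer)))
  m <- Biostrings::startIndex(Biostrings::matchPDict(pd, contig))
  hit <- which(lengths(m) > 0L)
  if (!length(hit)) return(empty)
  rows <- lapply(hit, function(p) {
    ts <- head(byKmer[[p]], maxPerKmer)
    qs <- head(m[[p]], maxPerKmer)
    expand.grid(qpos = qs, tpos = ts, KEEP.OUT.ATTRS = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$qpos), , drop = FALSE]
}

## Cluster anchor pairs by assembly position into candidate intervals,
## keeping the subject interval spanned by each cluster's anchors.
clusterAnchors <- function(pairs, k, gap = 300L) {
  empty <- data.frame(qstart = integer(0), qend = integer(0),
                      tmin = integer(0), tmax = integer(0),
                      n_anchors = integer(0))
  if (!nrow(pairs)) return(empty)
  red <- IRanges::reduce(IRanges::IRanges(start = pairs$qpos, width = k),
                         min.gapwidth = gap, with.revmap = TRUE)
  rv <- S4Vectors::mcols(red)$revmap
  data.frame(
    qstart = IRanges::start(red), qend = IRanges::end(red),
    tmin = vapply(rv, function(i) min(pairs$tpos[i]), integer(1)),
    tmax = vapply(rv, function(i) max(pairs$tpos[i]), integer(1)),
    n_anchors = lengths(rv))
}

## Karlin-Altschul minimum score for an E-value threshold under +1/-1
## scoring with equifrequent bases: lambda = ln 3, K ~ 0.35 (ungapped
## approximation).
minScoreForEvalue <- function(evalue, m, n, lambda = log(3), K = 0.35) {
  if (evalue <= 0) stop("evalue must be > 0")
  log(K * m * n / evalue) / lambda
}

## Locally align `query` against the subject region around its matched
## interval; returns list(identity, score, qstart, qend, tstart, tend) in
## 0-based half-open coordinates of query/subject, or NULL.
alignCandidate <- function(query, subject, pad = 200L) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = query, subject = subject, type = "local",
    substitutionMatrix = nucMatrix(), gapOpening = 2, gapExtension = 0.5)
  list(score = Biostrings::score(aln),
       identity = Biostrings::pid(aln, type = "PID1") / 100,
       qstart = Biostrings::start(Biostrings::pattern(aln)) - 1L,
       qend = Biostrings::end(Biostrings::pattern(aln)),
       tstart = Biostrings::start(Biostrings::subject(aln)) - 1L,
       tend = Biostrings::end(Biostrings::subject(aln)))
}

#' Windowed contamination screen
#'
#' Tiles every contig into non-overlapping fixed-width windows (the last
#' window of a contig may be truncated; a contig shorter than one window is a
#' single truncated window) and aligns each window against the subject
#' database. A window is positive when its best alignment reaches
#' `minIdentity` over at least `minHitLength` aligned bases. Per-contig
#' calls: `remove` when at least `minAdjacent` positive windows are adjacent
#' or at least `shortContigFraction` of the contig's windows are positive,
#' `flag` when any window is positive, else `keep`.
#'
#' @param assembly A [Biostrings::DNAStringSet].
#' @param subjects A [Biostrings::DNAStringSet] of potential contaminant
#'   sequences (must be non-empty).
#' @param window Window width in bp (default 5000).
#' @param minIdentity Identity needed for a positive window (default 0.95).
#' @param minHitLength Minimum aligned length for a positive window.
#' @param minAdjacent Adjacent positive windows needed for removal.
#' @param shortContigFraction Fraction of positive windows that also
#'   triggers removal.
#' @return List with `windows` (data.frame of positive windows: contig,
#'   window ordinal, 0-based window start, best subject, identity, score)
#'   and `calls` (data.frame per contig: n windows, n positive, max adjacent
#'   run, action).
#' @export
windowScreen <- function(assembly, subjects, window = 5000L,
                         minIdentity = 0.95, minHitLength = 100L,
                         minAdjacent = 2L, shortContigFraction = 0.5) {
  stopifnot(length(subjects) > 0)
  k <- 21L
  hitRows <- list()
  callRows <- list()
  for (ctg in names(assembly)) {
    contig <- assembly[[ctg]]
    L <- length(contig)
    starts <- seq.int(1L, max(1L, L), by = window)
    nWin <- length(starts)
    positive <- logical(nWin)
    bestSubj <- character(nWin); bestId <- numeric(nWin); bestSc <- numeric(nWin)
    for (s in seq_along(subjects)) {
      anchors <- kmerAnchors(contig, subjects[[s]], k = k)
      if (!nrow(anchors)) next
      candWin <- unique((anchors$qpos - 1L) %/% window + 1L)
      for (w in candWin) {
        wFrom <- starts[w]; wTo <- min(L, starts[w] + window - 1L)
        inWin <- anchors$qpos >= wFrom & anchors$qpos <= wTo
        tFrom <- max(1L, min(anchors$tpos[inWin]) - 500L)
        tTo <- min(length(subjects[[s]]),
                   max(anchors$tpos[inWin]) + k + 500L)
        hit <- alignCandidate(Biostrings::subseq(contig, wFrom, wTo),
                              Biostrings::subseq(subjects[[s]], tFrom, tTo))
        if (hit$identity >= minIdentity &&
            (hit$qend - hit$qstart) >= min(minHitLength, wTo - wFrom + 1L) &&
            hit$score > bestSc[w]) {
          positive[w] <- TRUE
          bestSubj[w] <- names(subjects)[s] %||% as.character(s)
          bestId[w] <- hit$identity
          bestSc[w] <- hit$score
        }
      }
    }
    if (any(positive)) {
      idx <- which(positive)
      hitRows[[ctg]] <- data.frame(
        contig = ctg, window_ordinal = idx, window_start = starts[idx] - 1L,
        subject = bestSubj[idx], identity = bestId[idx], score = bestSc[idx],
        stringsAsFactors = FALSE)
    }
    runs <- rle(positive)
    maxRun <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
    action <- if (maxRun >= minAdjacent ||
                  sum(positive) / nWin >= shortContigFraction) "remove"
      else if (any(positive)) "flag" else "keep"
    callRows[[ctg]] <- data.frame(
      contig = ctg, n_windows = nWin, n_positive = sum(positive),
      max_adjacent_run = maxRun, action = action, stringsAsFactors = FALSE)
  }
  list(windows = if (length(hitRows)) do.call(rbind, c(hitRows, make.row.names = FALSE))
         else data.frame(contig = character(0), window_ordinal = integer(0),
                         window_start = integer(0), subject = character(0),
                         identity = numeric(0), score = numeric(0)),
       calls = do.call(rbind, c(callRows, make.row.names = FALSE)))
}

#' Marker presence screen
#'
#' Locates copies of short marker sequences (e.g. a lineage-specific SINE) in
#' the assembly. Candidate regions are anchored by exact marker k-mers,
#' verified by local alignment, and loci closer than `mergeDistance` are
#' merged. An empty result means the assembly is clean for those markers.
#'
#' @param assembly A [Biostrings::DNAStringSet].
#' @param markers A [Biostrings::DNAStringSet] of marker sequences.
#' @param minIdentity Minimum alignment identity for a locus.
#' @param minLength Minimum locus length in bp (default half the marker).
#' @param mergeDistance Loci within this many bp are merged (default 50).
#' @return A [GenomicRanges::GRanges] of marker loci with metadata columns
#'   `marker`, `identity` and `score`.
#' @export
markerScreen <- function(assembly, markers, minIdentity = 0.8,
                         minLength = NULL, mergeDistance = 50L) {
  k <- 13L
  out <- list()
  for (mi in seq_along(markers)) {
    marker <- markers[[mi]]
    mname <- names(markers)[mi] %||% sprintf("marker%d", mi)
    minLen <- minLength %||% floor(length(marker) / 2)
    for (ctg in names(assembly)) {
      contig <- assembly[[ctg]]
      anchors <- kmerAnchors(contig, marker, k = k)
      clusters <- clusterAnchors(anchors, k, gap = max(2L * k, mergeDistance))
      for (ci in seq_len(nrow(clusters))) {
        from <- max(1L, clusters$qstart[ci] - 100L)
        to <- min(length(contig), clusters$qend[ci] + 100L)
        hit <- alignCandidate(Biostrings::DNAString(as.character(marker)),
                              Biostrings::subseq(contig, from, to))
        if (hit$identity >= minIdentity && (hit$tend - hit$tstart) >= minLen) {
          out[[length(out) + 1L]] <- GenomicRanges::GRanges(
            seqnames = ctg,
            ranges = IRanges::IRanges(start = from + hit$tstart,
                                      end = from + hit$tend - 1L),
            marker = mname, identity = hit$identity, score = hit$score)
        }
      }
    }
  }
  if (!length(out))
    return(GenomicRanges::GRanges(marker = character(0),
                                  identity = numeric(0), score = numeric(0)))
  loci <- sort(suppressWarnings(do.call(c, out)))
  merged <- GenomicRanges::reduce(loci, min.gapwidth = mergeDistance,
                                  with.revmap = TRUE)
  merged$marker <- vapply(merged$revmap, function(i)
    loci$marker[i[1L]], character(1))
  merged$identity <- vapply(merged$revmap, function(i)
    max(loci$identity[i]), numeric(1))
  merged$score <- vapply(merged$revmap, function(i)
    max(loci$score[i]), numeric(1))
  merged$revmap <- NULL
  merged
}

#' Scan an assembly for nuclear-mitochondrial insertions (NUMTs)
#'
#' Aligns the mitochondrial genome against the nuclear assembly and reports
#' merged loci passing the score threshold implied by `maxEvalue` (the
#' threshold is selectable on either side of 1 since the conventional
#' notation is ambiguous; the default reads it as an E-value cutoff of
#' 1e-4). The contig carrying the mitochondrion itself is excluded by id.
#'
#' @param assembly A [Biostrings::DNAStringSet].
#' @param mito The mitochondrial sequence (character or DNAString).
#' @param maxEvalue E-value threshold translated into a minimum alignment
#'   score; default `1e-4`.
#' @param minLength Minimum locus length (default 50 bp).
#' @param mergeDistance Raw hits within this many bp merge into one locus.
#' @param excludeContigs Contig ids to skip (default `"MT"`).
#' @param k Anchor k-mer size.
#' @return A [GenomicRanges::GRanges] of NUMT loci with metadata columns
#'   `identity`, `score`, `mito_start`, `mito_end` (0-based half-open on the
#'   mitochondrion).
#' @export
numtScan <- function(assembly, mito, maxEvalue = 1e-4, minLength = 50L,
                     mergeDistance = 50L, excludeContigs = "MT", k = 13L) {
  mito <- Biostrings::DNAString(as.character(mito))
  contigs <- setdiff(names(assembly), excludeContigs)
  out <- list()
  for (ctg in contigs) {
    contig <- assembly[[ctg]]
    minScore <- minScoreForEvalue(maxEvalue, length(mito), length(contig))
    anchors <- kmerAnchors(contig, mito, k = k)
    clusters <- clusterAnchors(anchors, k, gap = 300L)
    for (ci in seq_len(nrow(clusters))) {
      from <- max(1L, clusters$qstart[ci] - 200L)
      to <- min(length(contig), clusters$qend[ci] + 200L)
      tFrom <- max(1L, clusters$tmin[ci] - 300L)
      tTo <- min(length(mito), clusters$tmax[ci] + k + 300L)
      hit <- alignCandidate(Biostrings::subseq(contig, from, to),
                            Biostrings::subseq(mito, tFrom, tTo))
      if (hit$score >= minScore && (hit$qend - hit$qstart) >= minLength) {
        out[[length(out) + 1L]] <- GenomicRanges::GRanges(
          seqnames = ctg,
          ranges = IRanges::IRanges(start = from + hit$qstart,
                                    end = from + hit$qend - 1L),
          identity = hit$identity, score = hit$score,
          mito_start = tFrom - 1L + hit$tstart,
          mito_end = tFrom - 1L + hit$tend)
      }
    }
  }
  if (!length(out))
    return(GenomicRanges::GRanges(identity = numeric(0), score = numeric(0),
                                  mito_start = integer(0),
                                  mito_end = integer(0)))
  loci <- sort(suppressWarnings(do.call(c, out)))
  merged <- GenomicRanges::reduce(loci, min.gapwidth = mergeDistance,
                                  with.revmap = TRUE)
  merged$identity <- vapply(merged$revmap, function(i)
    max(loci$identity[i]), numeric(1))
  merged$score <- vapply(merged$revmap, function(i)
    max(loci$score[i]), numeric(1))
  merged$mito_start <- vapply(merged$revmap, function(i)
    min(loci$mito_start[i]), numeric(1))
  merged$mito_end <- vapply(merged$revmap, function(i)
    max(loci$mito_end[i]), numeric(1))
  merged$revmap <- NULL
  merged
}

#' Circularize a contig with a terminal direct repeat
#'
#' Looks for the longest suffix of the contig that matches its prefix with
#' at most `tolerance` mismatches (ungapped). One copy of the overlap is
#' trimmed, so the circular length equals the linear length minus the
#' overlap. When no terminal overlap of at least `minOverlap` bp exists the
#' contig is not circularizable and an error is raised; in particular,
#' circularizing an already-trimmed sequence errors rather than trimming
#' twice.
#'
#' @param contig Character or [Biostrings::DNAString].
#' @param minOverlap Minimum acceptable overlap (bp, default 50).
#' @param maxOverlap Longest overlap considered (default 5000).
#' @param tolerance Maximum mismatches tolerated in the overlap.
#' @return List with `sequence` (the circular sequence, character),
#'   `overlap` (trimmed overlap length), `mismatches`, and `junction`
#'   (0-based position on the circle where the trimmed copy began, i.e. the
#'   circular length).
#' @export
circularize <- function(contig, minOverlap = 50L, maxOverlap = 5000L,
                        tolerance = 0L) {
  seq <- as.character(contig)
  n <- nchar(seq)
  if (n <= minOverlap) stop("not circularizable: sequence shorter than minOverlap")
  x <- charToRaw(seq)
  upper <- min(maxOverlap, n - 1L)
  for (L in seq.int(upper, minOverlap)) {
    mm <- rawMismatches(x[seq_len(L)], x[seq.int(n - L + 1L, n)])
    if (mm <= tolerance) {
      return(list(sequence = substr(seq, 1L, n - L),
                  overlap = L, mismatches = mm, junction = n - L))
    }
  }
  stop("not circularizable: no terminal overlap of >= ", minOverlap,
       " bp within ", tolerance, " mismatch(es)")
}

#' Validate coverage by moving-window tiling
#'
#' Computes, for every `window`-bp moving window (advanced by `step`), the
#' number of read placements that fully cover the window, wrapping across
#' the origin when `circular`. The validation passes when no window is
#' uncovered and the minimum depth exceeds `minDepth`.
#'
#' @param placements Read placements: a data.frame with `start`/`end`
#'   (1-based closed; `end` may exceed `seqLength` to denote wrapping) or an
#'   [IRanges::IRanges].
#' @param seqLength Length of the (optionally circular) sequence.
#' @param window Window width (default 50).
#' @param step Window step (default 1).
#' @param minDepth Depth threshold the minimum is compared against.
#' @param circular Whether the sequence is circular (default TRUE).
#' @return A [TilingReport-class].
#' @export
tilingValidation <- function(placements, seqLength, window = 50L, step = 1L,
                             minDepth = 0, circular = TRUE) {
  window <- as.integer(window); step <- as.integer(step)
  seqLength <- as.integer(seqLength)
  if (window > seqLength) stop("window exceeds sequence length")
  if (is(placements, "IRanges")) {
    placements <- data.frame(start = IRanges::start(placements),
                             end = IRanges::end(placements))
  }
  ## a read [a, b] fully covers windows starting in [a, b - window + 1];
  ## accumulate with a difference array over window-start positions
  nStarts <- if (circular) seqLength else seqLength - window + 1L
  diffArr <- numeric(nStarts + 1L)
  for (i in seq_len(nrow(placements))) {
    a <- placements$start[i]; b <- placements$end[i]
    l <- b - a + 1L
    if (l < window) next
    if (!circular) {
      from <- max(1L, a); to <- min(nStarts, b - window + 1L)
      if (from > to) next
      diffArr[from] <- diffArr[from] + 1
      diffArr[to + 1L] <- diffArr[to + 1L] - 1
    } else {
      ## an arc covering the whole circle covers every window; a shorter
      ## arc of length l covers the l - window + 1 starts from its own
      ## start (mod L)
      span <- if (l >= seqLength) nStarts else l - window + 1L
      from <- ((a - 1L) %% seqLength) + 1L
      to <- from + span - 1L
      if (to <= nStarts) {
        diffArr[from] <- diffArr[from] + 1
        diffArr[to + 1L] <- diffArr[to + 1L] - 1
      } else {
        diffArr[from] <- diffArr[from] + 1
        diffArr[nStarts + 1L] <- diffArr[nStarts + 1L] - 1
        diffArr[1L] <- diffArr[1L] + 1
        diffArr[to - nStarts + 1L] <- diffArr[to - nStarts + 1L] - 1
      }
    }
  }
  depth <- cumsum(diffArr[seq_len(nStarts)])
  depth <- depth[seq.int(1L, nStarts, by = step)]
  minObs <- if (length(depth)) min(depth) else 0
  uncovered <- sum(depth == 0)
  new("TilingReport", window = window, step = step,
      minDepth = minObs, uncoveredWindows = as.integer(uncovered),
      depthThreshold = as.numeric(minDepth), circular = circular,
      pass = uncovered == 0L && minObs > minDepth)
}
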