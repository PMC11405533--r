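## Synteny-based chromosome assignment from PAF-semantics alignments, AGP
## scaffold layout, repeat-graph consistency checking, and assembly metrics.

#' Filter alignment records by divergence and block length
#'
#' Retains records with divergence at or below `maxDivergence` (the asm20
#' convention: up to 20% divergence) and aligned block length of at least
#' `minBlock`.
#'
#' @param records Alignment data.frame from [readPaf()] or
#'   [makeAlignments()].
#' @param maxDivergence Maximum divergence retained (default 0.20).
#' @param minBlock Minimum block length retained (default 0).
#' @return The retained records, with attributes `n_input` and `n_dropped`.
#' @export
filterAlignments <- function(records, maxDivergence = 0.20, minBlock = 0L) {
  stopifnot(is.data.frame(records))
  keep <- records$divergence <= maxDivergence & records$blocklen >= minBlock
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_input") <- nrow(records)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Assign contigs to chromosomes by aligned-base support
#'
#' For each contig, support per target chromosome (or arm) label is the sum
#' of aligned block lengths; the label with the most support on the
#' top-ranked reference with at least one alignment wins. When records carry
#' a `reference` column, `ranking` gives the precedence order between
#' references. A conflict is flagged when the runner-up label's support
#' fraction comes within `conflictMargin` of the winner's.
#'
#' @param records Filtered alignment records; target labels are taken from
#'   `tname` (optionally remapped via `labelMap`).
#' @param ranking Character vector of reference names in precedence order
#'   (only used when `records$reference` exists).
#' @param conflictMargin Support-fraction margin under which the runner-up
#'   flags a conflict (default 0.1).
#' @param labelMap Optional named character vector remapping target names to
#'   chromosome labels (the hook for painting-map style label refinement).
#' @return data.frame with one row per contig: `contig`, `chromosome`,
#'   `support` (aligned bases), `support_fraction`, `runner_up`,
#'   `runner_up_fraction`, `conflict`. Contigs without alignments are absent
#'   (listed in attribute `unassigned` when the records carry `qname` levels).
#' @export
assignChromosomes <- function(records, ranking = NULL, conflictMargin = 0.1,
                              labelMap = NULL) {
  stopifnot(is.data.frame(records))
  if (!nrow(records)) {
    return(data.frame(contig = character(0), chromosome = character(0),
                      support = numeric(0), support_fraction = numeric(0),
                      runner_up = character(0), runner_up_fraction = numeric(0),
                      conflict = logical(0)))
  }
  labels <- records$tname
  if (!is.null(labelMap)) {
    hit <- labels %in% names(labelMap)
    labels[hit] <- unname(labelMap[labels[hit]])
  }
  records$label <- labels
  rows <- lapply(split(records, records$qname), function(r) {
    if (!is.null(r$reference) && !is.null(ranking)) {
      for (ref in ranking) {
        if (any(r$reference == ref)) {
          r <- r[r$reference == ref, , drop = FALSE]
          break
        }
      }
    }
    sup <- tapply(r$blocklen, r$label, sum)
    sup <- sort(sup, decreasing = TRUE)
    total <- sum(sup)
    frac <- sup / total
    runnerUp <- if (length(sup) > 1L) names(sup)[2L] else NA_character_
    runnerFrac <- if (length(sup) > 1L) unname(frac[2L]) else 0
    data.frame(contig = r$qname[1L], chromosome = names(sup)[1L],
               support = unname(sup[1L]), support_fraction = unname(frac[1L]),
               runner_up = runnerUp, runner_up_fraction = runnerFrac,
               conflict = unname(frac[1L]) - runnerFrac < conflictMargin &&
                 length(sup) > 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Order and orient contigs within assigned chromosomes
#'
#' Within each chromosome, contigs are ordered by the block-length-weighted
#' median of their target coordinates and oriented by the strand carrying
#' the majority of aligned bases (ties resolve to `+` with a warning).
#' Input contigs are never split or edited; fixed-length gaps are placed
#' between consecutive contigs.
#'
#' @param assignments From [assignChromosomes()].
#' @param records The alignment records the assignments were computed from.
#' @param gapLength Gap placed between consecutive contigs (default 100 bp,
#'   emitted as AGP "U" rows).
#' @return List with `layout` (data.frame: chromosome, ordinal, contig,
#'   orientation, contig_length, gap_after) and `agp` (data.frame of AGP
#'   2.1 rows; write with [writeAgp()]).
#' @export
orderAndOrient <- function(assignments, records, gapLength = 100L) {
  stopifnot(is.data.frame(assignments), is.data.frame(records))
  layoutRows <- list()
  for (chrom in unique(assignments$chromosome)) {
    ctgs <- assignments$contig[assignments$chromosome == chrom]
    info <- lapply(ctgs, function(ctg) {
      r <- records[records$qname == ctg & records$tname == chrom, , drop = FALSE]
      if (!nrow(r))
        r <- records[records$qname == ctg, , drop = FALSE]
      mid <- (r$tstart + r$tend) / 2
      pos <- median(rep(mid, pmax(1L, r$blocklen %/% 1000L)))
      plus <- sum(r$blocklen[r$strand == "+"])
      minus <- sum(r$blocklen[r$strand == "-"])
      if (plus == minus && minus > 0)
        warning("orientation tie for contig ", ctg, "; using '+'")
      list(contig = ctg, pos = pos,
           orientation = if (minus > plus) "-" else "+",
           length = r$qlen[1L])
    })
    info <- info[order(vapply(info, `[[`, numeric(1), "pos"))]
    for (i in seq_along(info)) {
      layoutRows[[length(layoutRows) + 1L]] <- data.frame(
        chromosome = chrom, ordinal = i, contig = info[[i]]$contig,
        orientation = info[[i]]$orientation,
        contig_length = info[[i]]$length,
        gap_after = if (i < length(info)) gapLength else 0L,
        stringsAsFactors = FALSE)
    }
  }
  layout <- do.call(rbind, layoutRows)
  if (anyDuplicated(layout$contig))
    stop("a contig was assigned to more than one chromosome")

  agpRows <- list()
  for (chrom in unique(layout$chromosome)) {
    sub <- layout[layout$chromosome == chrom, , drop = FALSE]
    at <- 0L; part <- 0L
    for (i in seq_len(nrow(sub))) {
      part <- part + 1L
      len <- sub$contig_length[i]
      agpRows[[length(agpRows) + 1L]] <- data.frame(
        object = chrom, object_beg = at + 1L, object_end = at + len,
        part_number = part, component_type = "W",
        component_id = sub$contig[i], component_beg = 1L,
        component_end = len, orientation = sub$orientation[i],
        stringsAsFactors = FALSE)
      at <- at + len
      if (sub$gap_after[i] > 0L) {
        part <- part + 1L
        agpRows[[length(agpRows) + 1L]] <- data.frame(
          object = chrom, object_beg = at + 1L,
          object_end = at + sub$gap_after[i], part_number = part,
          component_type = "U", component_id = as.character(sub$gap_after[i]),
          component_beg = "scaffold", component_end = "yes",
          orientation = "align_genus", stringsAsFactors = FALSE)
        at <- at + sub$gap_after[i]
      }
    }
  }
  list(layout = layout, agp = do.call(rbind, agpRows))
}

#' Check a layout against allowed contig adjacencies
#'
#' Abstracts an assembler's repeat-graph consistency review: every adjacent
#' contig pair in the layout must appear in the allowed adjacency set
#' (order-insensitive). An empty constraint set means no constraints and
#' yields zero violations.
#'
#' @param layout Layout data.frame from [orderAndOrient()].
#' @param allowed data.frame with columns `a` and `b` of allowed adjacent
#'   contig pairs, or an empty data.frame / NULL for no constraints.
#' @return data.frame of violating pairs (`chromosome`, `a`, `b`).
#' @export
consistencyCheck <- function(layout, allowed = NULL) {
  empty <- data.frame(chromosome = character(0), a = character(0),
                      b = character(0), stringsAsFactors = FALSE)
  if (is.null(allowed) || nrow(allowed) == 0L) return(empty)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  allowedKeys <- key(allowed$a, allowed$b)
  rows <- list()
  for (chrom in unique(layout$chromosome)) {
    ctgs <- layout$contig[layout$chromosome == chrom][
      order(layout$ordinal[layout$chromosome == chrom])]
    if (length(ctgs) < 2L) next
    a <- head(ctgs, -1L); b <- tail(ctgs, -1L)
    bad <- !(key(a, b) %in% allowedKeys)
    if (any(bad))
      rows[[chrom]] <- data.frame(chromosome = chrom, a = a[bad], b = b[bad],
                                  stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assembly contiguity metrics
#'
#' N50 is the smallest length in the minimal descending-sorted prefix of
#' lengths whose sum reaches half the total; L50 is the size of that prefix.
#'
#' @param lengths Positive contig or scaffold lengths.
#' @return List with `n50`, `l50`, `total` and `count`.
#' @export
assemblyMetrics <- function(lengths) {
  if (!length(lengths)) stop("empty length list")
  if (any(lengths <= 0)) stop("lengths must be positive")
  sorted <- sort(as.numeric(lengths), decreasing = TRUE)
  csum <- cumsum(sorted)
  l50 <- which(csum >= sum(sorted) / 2)[1L]
  list(n50 = sorted[l50], l50 = l50, total = sum(sorted),
       count = length(lengths))
}
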