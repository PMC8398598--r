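#' Fit the fragment-size model from concordant pairs
#'
#' Robustly estimates the fragment-size distribution from proper
#' same-contig inward-facing pairs (median and MAD-scaled sd of the
#' outer distance) and derives the discordance cutoff
#' `mean + 3 * sd`: a pair whose mates map farther apart than this
#' "expected fragment size" is discordant.
#'
#' @param reads alignment table from `read_alignments()`.
#' @param min_pairs minimum usable pairs (default 100).
#' @return An `nb_fragment_model`: list with `fragment_mean`,
#'   `fragment_sd`, `cutoff`.
#' @export
fit_fragment_model <- function(reads, min_pairs = 100) {
  use <- reads$paired & reads$first_of_pair & reads$chrom == reads$mchrom &
    reads$tlen > 0 & !reads$reverse
  d <- reads$tlen[use]
  if (length(d) < min_pairs) {
    stop("too few proper pairs to fit a fragment model (", length(d),
         " < ", min_pairs, ")")
  }
  m <- stats::median(d)
  s <- stats::mad(d)
  structure(list(fragment_mean = m, fragment_sd = s, cutoff = m + 3 * s),
            class = "nb_fragment_model")
}

#' @export
print.nb_fragment_model <- function(x, ...) {
  cat(sprintf("nb_fragment_model: mean %.0f, sd %.1f, discordance cutoff %.0f\n",
              x$fragment_mean, x$fragment_sd, x$cutoff))
  invisible(x)
}

# junction-proximal coordinate of a mate: rightmost aligned base for a
# forward read, leftmost for a reverse read
anchor_pos <- function(pos, end, reverse) ifelse(reverse, pos, end)

#' Extract discordant read pairs
#'
#' A pair is discordant when its mates map to different contigs, or map
#' farther apart than the fragment-model cutoff, or are not in the
#' expected inward (forward/reverse) orientation. Pairs are oriented so
#' side A sorts before side B by (contig, position); each side carries
#' the junction-proximal coordinate of its mate.
#'
#' @param reads alignment table.
#' @param model `nb_fragment_model`.
#' @param min_mapq minimum mapping quality for both mates (default 20).
#' @return data.frame: `qname`, `chrom_a`, `pos_a`, `strand_a`,
#'   `chrom_b`, `pos_b`, `strand_b`, `orientation` (one of
#'   `translocation`, `del_like`, `dup_like`, `inv_like`).
#' @export
extract_discordant <- function(reads, model, min_mapq = 20) {
  reads <- reads[reads$paired & reads$mapq >= min_mapq &
                   bitwAnd(reads$flag, 8L) == 0L, , drop = FALSE]
  r1 <- reads[reads$first_of_pair, , drop = FALSE]
  r2 <- reads[!reads$first_of_pair, , drop = FALSE]
  m <- match(r1$qname, r2$qname)
  ok <- !is.na(m)
  r1 <- r1[ok, , drop = FALSE]
  r2 <- r2[m[ok], , drop = FALSE]
  if (nrow(r1) == 0) return(empty_discordant())

  diff_contig <- r1$chrom != r2$chrom
  lo <- pmin(r1$pos, r2$pos)
  hi <- pmax(r1$end, r2$end)
  dist <- hi - lo + 1L
  # inward-facing: the forward mate starts before the reverse mate
  fwd_first <- ifelse(r1$reverse == r2$reverse, NA,
                      ifelse(r1$reverse, r2$pos <= r1$pos, r1$pos <= r2$pos))
  inward <- !diff_contig & !is.na(fwd_first) & fwd_first
  disc <- diff_contig | (!diff_contig & dist > model$cutoff) | !inward
  r1 <- r1[disc, , drop = FALSE]
  r2 <- r2[disc, , drop = FALSE]
  if (nrow(r1) == 0) return(empty_discordant())

  orientation <- ifelse(r1$chrom != r2$chrom, "translocation",
    ifelse(r1$reverse == r2$reverse, "inv_like",
      ifelse(ifelse(r1$reverse, r2$pos <= r1$pos, r1$pos <= r2$pos),
             "del_like", "dup_like")))
  a1 <- anchor_pos(r1$pos, r1$end, r1$reverse)
  a2 <- anchor_pos(r2$pos, r2$end, r2$reverse)
  swap <- (r1$chrom > r2$chrom) | (r1$chrom == r2$chrom & a1 > a2)
  out <- data.frame(
    qname = r1$qname,
    chrom_a = ifelse(swap, r2$chrom, r1$chrom),
    pos_a = ifelse(swap, a2, a1),
    strand_a = ifelse(swap, ifelse(r2$reverse, "-", "+"), ifelse(r1$reverse, "-", "+")),
    chrom_b = ifelse(swap, r1$chrom, r2$chrom),
    pos_b = ifelse(swap, a1, a2),
    strand_b = ifelse(swap, ifelse(r1$reverse, "-", "+"), ifelse(r2$reverse, "-", "+")),
    orientation = orientation,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

empty_discordant <- function() {
  data.frame(qname = character(), chrom_a = character(), pos_a = integer(),
             strand_a = character(), chrom_b = character(), pos_b = integer(),
             strand_b = character(), orientation = character(),
             stringsAsFactors = FALSE)
}

# union-find over n items given an edge list
components_from_edges <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      ri <- find(edges[e, 1]); rj <- find(edges[e, 2])
      if (ri != rj) parent[rj] <- ri
    }
  }
  vapply(seq_len(n), find, 1L)
}

#' Cluster discordant pairs into candidate rearrangements
#'
#' Single-linkage clustering within groups of identical orientation and
#' contig pair: two pairs are linked when both their A-side and B-side
#' positions are within `window` bp. Clusters with fewer than
#' `min_support` pairs are dropped.
#'
#' @param pairs data.frame from `extract_discordant()`.
#' @param window linkage window in bp (default 500).
#' @param min_support minimum pairs per cluster (default 3).
#' @return data.frame, one row per cluster: contigs, A/B interval
#'   bounds, `orientation`, `n_pairs`, and `members` (list column of
#'   pair row indices).
#' @export
cluster_discordant <- function(pairs, window = 500, min_support = 3) {
  if (nrow(pairs) == 0) return(empty_clusters())
  grp <- paste(pairs$chrom_a, pairs$chrom_b, pairs$orientation, sep = "\r")
  out <- list()
  for (g in unique(grp)) {
    idx <- which(grp == g)
    sub <- pairs[idx, , drop = FALSE]
    n <- nrow(sub)
    edges <- which(outer(sub$pos_a, sub$pos_a, function(x, y) abs(x - y) <= window) &
                     outer(sub$pos_b, sub$pos_b, function(x, y) abs(x - y) <= window),
                   arr.ind = TRUE)
    edges <- edges[edges[, 1] < edges[, 2], , drop = FALSE]
    comp <- components_from_edges(n, edges)
    for (cc in unique(comp)) {
      mem <- idx[comp == cc]
      if (length(mem) < min_support) next
      out[[length(out) + 1L]] <- data.frame(
        chrom_a = sub$chrom_a[1],
        start_a = min(pairs$pos_a[mem]), end_a = max(pairs$pos_a[mem]),
        chrom_b = sub$chrom_b[1],
        start_b = min(pairs$pos_b[mem]), end_b = max(pairs$pos_b[mem]),
        orientation = sub$orientation[1],
        n_pairs = length(mem),
        stringsAsFactors = FALSE
      )
      out[[length(out)]]$members <- I(list(mem))
    }
  }
  if (length(out) == 0) return(empty_clusters())
  res <- do.call(rbind, out)
  res[order(res$chrom_a, res$start_a, res$chrom_b, res$start_b), , drop = FALSE]
}

empty_clusters <- function() {
  data.frame(chrom_a = character(), start_a = integer(), end_a = integer(),
             chrom_b = character(), start_b = integer(), end_b = integer(),
             orientation = character(), n_pairs = integer(),
             members = I(list()), stringsAsFactors = FALSE)
}

# clip coordinates of soft-clipped reads: trailing S -> last aligned base,
# leading S -> first aligned base
clip_positions <- function(reads) {
  lead <- grepl("^[0-9]+S", reads$cigar)
  trail <- grepl("[0-9]+S$", reads$cigar)
  data.frame(
    chrom = c(reads$chrom[lead], reads$chrom[trail]),
    pos = c(reads$pos[lead], reads$end[trail]),
    stringsAsFactors = FALSE
  )
}

#' Refine a cluster's breakpoints with clipped reads
#'
#' Soft-clipped reads whose clip coordinate falls inside (or within
#' `pad` bp of) the cluster interval vote for the junction position;
#' when any are present, the plurality clip coordinate is reported at
#' base-pair resolution, otherwise the cluster interval midpoints are
#' reported at interval resolution.
#'
#' @param cluster one row of `cluster_discordant()` output.
#' @param reads alignment table (for clip evidence).
#' @param pad search padding around the cluster interval (default 300).
#' @return one-row data.frame: `chrom_a`, `pos_a`, `chrom_b`, `pos_b`,
#'   `orientation`, `n_discordant_pairs`, `n_clipped_reads`,
#'   `resolution` ("base_pair" or "interval").
#' @export
refine_breakpoint <- function(cluster, reads, pad = 300) {
  clips <- clip_positions(reads)
  side <- function(chrom, lo, hi) {
    v <- clips$pos[clips$chrom == chrom & clips$pos >= lo - pad & clips$pos <= hi + pad]
    if (length(v) == 0) return(NULL)
    tab <- sort(table(v), decreasing = TRUE)
    list(pos = as.integer(names(tab)[1]), n = as.integer(tab[1]))
  }
  a <- side(cluster$chrom_a, cluster$start_a, cluster$end_a)
  b <- side(cluster$chrom_b, cluster$start_b, cluster$end_b)
  data.frame(
    chrom_a = cluster$chrom_a,
    pos_a = if (!is.null(a)) a$pos else as.integer(round((cluster$start_a + cluster$end_a) / 2)),
    chrom_b = cluster$chrom_b,
    pos_b = if (!is.null(b)) b$pos else as.integer(round((cluster$start_b + cluster$end_b) / 2)),
    orientation = cluster$orientation,
    n_discordant_pairs = cluster$n_pairs,
    n_clipped_reads = (if (!is.null(a)) a$n else 0L) + (if (!is.null(b)) b$n else 0L),
    resolution = if (!is.null(a) || !is.null(b)) "base_pair" else "interval",
    stringsAsFactors = FALSE
  )
}

#' Classify a breakpoint relative to the TERT locus
#'
#' Rearrangements near TERT drive telomerase activation by two distinct
#' routes: breakpoints upstream of the transcription start site relocate
#' regulatory elements, while breakpoints inside the gene body disrupt
#' or fuse the gene itself. The two classes are never conflated: a
#' breakpoint inside the gene is `tert_intragenic`, one within
#' `upstream_window` bp 5' of the TSS is `tert_upstream`, anything else
#' is `other`.
#'
#' @param bp one-row breakpoint data.frame (`chrom_a`, `pos_a`,
#'   `chrom_b`, `pos_b`).
#' @param tert_interval `GRanges` of the TERT gene body.
#' @param tert_strand "+" or "-" (TSS at start or end respectively).
#' @param upstream_window upstream extent in bp (default 25000).
#' @return one of "tert_intragenic", "tert_upstream", "other".
#' @export
classify_tert_rearrangement <- function(bp, tert_interval, tert_strand = "+",
                                        upstream_window = 25000) {
  ch <- as.character(GenomicRanges::seqnames(tert_interval))[1]
  g_lo <- min(GenomicRanges::start(tert_interval))
  g_hi <- max(GenomicRanges::end(tert_interval))
  ends <- data.frame(chrom = c(bp$chrom_a, bp$chrom_b), pos = c(bp$pos_a, bp$pos_b))
  inside <- ends$chrom == ch & ends$pos >= g_lo & ends$pos <= g_hi
  if (any(inside)) return("tert_intragenic")
  if (tert_strand == "+") {
    up <- ends$chrom == ch & ends$pos >= g_lo - upstream_window & ends$pos < g_lo
  } else {
    up <- ends$chrom == ch & ends$pos > g_hi & ends$pos <= g_hi + upstream_window
  }
  if (any(up)) return("tert_upstream")
  "other"
}

#' Detect an intragenic partial deletion from bin ratios and breakpoints
#'
#' A partial deletion is called when a contiguous internal run of at
#' least `min_run` loss-significant bins (z < -`z_cut`) is flanked on
#' both sides by non-significant intra-gene bins. A breakpoint within
#' `window` bp of either run edge upgrades confidence
#' (`breakpoint_supported`); a breakpoint inside the gene without any
#' depth signature yields a `breakpoint_only` record, since low tumor
#' content can erase the depth signal while junction fragments survive.
#'
#' @param gene gene symbol (for the output record).
#' @param ratios `bin_ratios()` rows for this gene, in bin order.
#' @param breakpoints optional breakpoint data.frame (`chrom_a`,
#'   `pos_a`, `chrom_b`, `pos_b`).
#' @param z_cut significance threshold (default 3).
#' @param min_run minimum run length in bins (default 3).
#' @param window breakpoint co-location window in bp (default 500).
#' @return one-row data.frame (`gene`, `type`, `start`, `end`,
#'   `n_bins_lost`, `confidence`) or NULL when nothing is detected.
#' @export
detect_partial_deletion <- function(gene, ratios, breakpoints = NULL,
                                    z_cut = 3, min_run = 3, window = 500) {
  if (nrow(ratios) < 6) stop("partial-deletion detection needs at least 6 bins")
  loss <- ratios$z < -z_cut
  gene_lo <- min(ratios$start)
  gene_hi <- max(ratios$end)
  bp_in_gene <- function() {
    if (is.null(breakpoints) || nrow(breakpoints) == 0) return(FALSE)
    ends <- data.frame(chrom = c(breakpoints$chrom_a, breakpoints$chrom_b),
                       pos = c(breakpoints$pos_a, breakpoints$pos_b))
    any(ends$chrom == ratios$chrom[1] & ends$pos >= gene_lo & ends$pos <= gene_hi)
  }
  r <- rle(loss)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  runs <- which(r$values & r$lengths >= min_run)
  internal <- runs[starts_idx[runs] > 1 & ends_idx[runs] < nrow(ratios)]
  if (length(internal) == 0) {
    if (all(loss)) return(NULL)  # whole-gene loss: handled by the CNV caller
    if (bp_in_gene()) {
      return(data.frame(gene = gene, type = "breakpoint_only",
                        start = NA_integer_, end = NA_integer_,
                        n_bins_lost = 0L, confidence = "breakpoint_only",
                        stringsAsFactors = FALSE))
    }
    return(NULL)
  }
  best <- internal[which.max(r$lengths[internal])]
  i1 <- starts_idx[best]; i2 <- ends_idx[best]
  run_lo <- ratios$start[i1]
  run_hi <- ratios$end[i2]
  supported <- FALSE
  if (!is.null(breakpoints) && nrow(breakpoints) > 0) {
    ends <- data.frame(chrom = c(breakpoints$chrom_a, breakpoints$chrom_b),
                       pos = c(breakpoints$pos_a, breakpoints$pos_b))
    supported <- any(ends$chrom == ratios$chrom[1] &
                       (abs(ends$pos - run_lo) <= window |
                          abs(ends$pos - run_hi) <= window))
  }
  data.frame(gene = gene, type = "partial_deletion",
             start = run_lo, end = run_hi, n_bins_lost = i2 - i1 + 1L,
             confidence = if (supported) "breakpoint_supported" else "depth_only",
             stringsAsFactors = FALSE)
}

#' Call structural variants from an alignment table
#'
#' End-to-end discordant-pair pipeline: fit the fragment model, extract
#' discordant pairs, cluster them, refine each cluster's breakpoints
#' with clipped reads, and annotate affected panel genes (including TERT
#' rearrangement classes when TERT is on the panel).
#'
#' @param reads alignment table (or SAM/BAM path).
#' @param panel an `nb_panel`.
#' @param model optional prefit `nb_fragment_model`.
#' @param window clustering window in bp (default 500).
#' @param min_support minimum discordant pairs per call (default 3).
#' @param min_mapq minimum mapping quality (default 20).
#' @param tert_strand strand of TERT on the synthetic/panel reference.
#' @param upstream_window TERT upstream window (default 25000).
#' @param min_event_span minimum span (`pos_b - pos_a`) for same-contig
#'   del/dup-like calls; smaller spans are indistinguishable from
#'   fragment-length tail outliers (the discordance cutoff itself admits
#'   the extreme tail of concordant pairs) and are dropped. Defaults to
#'   `cutoff + window`; this is the caller's deletion size detection
#'   limit.
#' @return data.frame of calls: breakpoints, orientation, support
#'   counts, `resolution`, `genes` (comma-joined), `annotation`.
#' @export
call_svs <- function(reads, panel, model = NULL, window = 500, min_support = 3,
                     min_mapq = 20, tert_strand = "+", upstream_window = 25000,
                     min_event_span = NULL) {
  if (is.character(reads)) reads <- read_alignments(reads)
  if (is.null(model)) model <- fit_fragment_model(reads)
  if (is.null(min_event_span)) min_event_span <- model$cutoff + window
  pairs <- extract_discordant(reads, model, min_mapq = min_mapq)
  clusters <- cluster_discordant(pairs, window = window, min_support = min_support)
  if (nrow(clusters) == 0) {
    return(data.frame(chrom_a = character(), pos_a = integer(),
                      chrom_b = character(), pos_b = integer(),
                      orientation = character(), n_discordant_pairs = integer(),
                      n_clipped_reads = integer(), resolution = character(),
                      genes = character(), annotation = character(),
                      stringsAsFactors = FALSE))
  }
  calls <- do.call(rbind, lapply(seq_len(nrow(clusters)), function(i) {
    refine_breakpoint(clusters[i, , drop = FALSE], reads)
  }))
  noise_like <- calls$chrom_a == calls$chrom_b &
    calls$orientation %in% c("del_like", "dup_like") &
    (calls$pos_b - calls$pos_a) < min_event_span
  calls <- calls[!noise_like, , drop = FALSE]
  if (nrow(calls) == 0) {
    return(data.frame(chrom_a = character(), pos_a = integer(),
                      chrom_b = character(), pos_b = integer(),
                      orientation = character(), n_discordant_pairs = integer(),
                      n_clipped_reads = integer(), resolution = character(),
                      genes = character(), annotation = character(),
                      stringsAsFactors = FALSE))
  }
  mc <- S4Vectors::mcols(panel$regions)
  gene_gr <- panel$regions[!is.na(mc$gene) & mc$region_class == "gene_target"]
  calls$genes <- vapply(seq_len(nrow(calls)), function(i) {
    ends <- GenomicRanges::GRanges(c(calls$chrom_a[i], calls$chrom_b[i]),
                                   IRanges::IRanges(c(calls$pos_a[i], calls$pos_b[i]), width = 1))
    hits <- unique(S4Vectors::mcols(gene_gr)$gene[
      S4Vectors::queryHits(GenomicRanges::findOverlaps(gene_gr, ends))])
    if (length(hits) == 0) "" else paste(sort(hits), collapse = ",")
  }, "")
  calls$annotation <- "other"
  if ("TERT" %in% panel$genes) {
    tert <- gene_interval(panel, "TERT")
    for (i in seq_len(nrow(calls))) {
      calls$annotation[i] <- classify_tert_rearrangement(
        calls[i, , drop = FALSE], tert, tert_strand = tert_strand,
        upstream_window = upstream_window)
    }
  }
  rownames(calls) <- NULL
  calls
}
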