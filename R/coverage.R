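#' Fraction of uniquely aligned reads on target
#'
#' Counts primary aligned reads with mapping quality at or above
#' `min_mapq`; the numerator is those overlapping any panel region by at
#' least one base. This is the enrichment-efficiency metric reported for
#' hybrid-capture assays.
#'
#' @param reads alignment table from `read_alignments()` (or a
#'   SAM/BAM path).
#' @param panel an `nb_panel`.
#' @param min_mapq minimum mapping quality defining "uniquely aligned"
#'   (default 20).
#' @return fraction in [0, 1].
#' @export
on_target_fraction <- function(reads, panel, min_mapq = 20) {
  if (is.character(reads)) reads <- read_alignments(reads)
  reads <- reads[reads$mapq >= min_mapq, , drop = FALSE]
  if (nrow(reads) == 0) stop("no reads pass the mapping-quality filter; fraction undefined")
  gr <- GenomicRanges::GRanges(reads$chrom, IRanges::IRanges(reads$pos, reads$end))
  targets <- GenomicRanges::reduce(panel$regions, ignore.strand = TRUE)
  sum(IRanges::overlapsAny(gr, targets)) / nrow(reads)
}

#' Per-base depth over the panel target territory
#'
#' Depth counts aligned read bases (CIGAR M/=/X operations) from primary
#' reads passing the mapping-quality filter; soft-clipped bases do not
#' contribute. Reads on contigs absent from the panel are skipped with a
#' warning.
#'
#' @param reads alignment table from `read_alignments()` (or a
#'   SAM/BAM path).
#' @param panel an `nb_panel`.
#' @param min_mapq minimum mapping quality (default 20).
#' @return An `nb_depth_profile`: list with `regions` (panel `GRanges`),
#'   `depth` (list of integer per-base depth vectors, one per region),
#'   `region_mean` (numeric), `n_unique_reads`, `n_on_target_reads`.
#' @export
depth_profile <- function(reads, panel, min_mapq = 20) {
  if (is.character(reads)) reads <- read_alignments(reads)
  reads <- reads[reads$mapq >= min_mapq, , drop = FALSE]
  regions <- panel$regions
  panel_chroms <- unique(as.character(GenomicRanges::seqnames(regions)))
  off_contig <- !reads$chrom %in% panel_chroms
  if (any(off_contig)) {
    warning(sum(off_contig), " reads on contigs absent from the panel were skipped")
    reads <- reads[!off_contig, , drop = FALSE]
  }
  targets <- GenomicRanges::reduce(regions, ignore.strand = TRUE)
  read_gr <- GenomicRanges::GRanges(reads$chrom, IRanges::IRanges(reads$pos, reads$end))
  n_on <- sum(IRanges::overlapsAny(read_gr, targets))

  segs <- aligned_segments(reads)
  cov <- GenomicRanges::coverage(segs)
  depth <- vector("list", length(regions))
  for (i in seq_along(regions)) {
    ch <- as.character(GenomicRanges::seqnames(regions))[i]
    st <- GenomicRanges::start(regions)[i]
    en <- GenomicRanges::end(regions)[i]
    depth[[i]] <- if (ch %in% names(cov)) {
      rle <- cov[[ch]]
      # pad so regions beyond the last covered base read as zero depth
      if (length(rle) < en) {
        rle <- c(rle, S4Vectors::Rle(0L, en - length(rle)))
      }
      as.integer(S4Vectors::window(rle, st, en))
    } else {
      integer(en - st + 1L)
    }
  }
  structure(list(
    regions = regions,
    depth = depth,
    region_mean = vapply(depth, mean, 0),
    n_unique_reads = nrow(reads),
    n_on_target_reads = n_on
  ), class = "nb_depth_profile")
}

#' @export
print.nb_depth_profile <- function(x, ...) {
  cat(sprintf("nb_depth_profile: %d regions, mean depth %.1f, %d unique reads (%d on target)\n",
              length(x$regions), mean(unlist(x$depth)), x$n_unique_reads,
              x$n_on_target_reads))
  invisible(x)
}

#' Depth attained by a fraction of target bases
#'
#' Returns the largest depth `v` such that at least a fraction `q` of
#' all target bases are covered at depth `v` or more — e.g. `q = 0.95`
#' gives the "coverage of 95% of target" statistic used to summarize
#' capture uniformity. Non-increasing in `q`; `q = 1` gives the minimum
#' depth.
#'
#' @param profile an `nb_depth_profile`.
#' @param q fraction of target bases, in (0, 1] (default 0.95).
#' @return integer depth.
#' @export
coverage_at_fraction <- function(profile, q = 0.95) {
  d <- unlist(profile$depth)
  if (length(d) == 0) stop("empty depth profile")
  if (q <= 0 || q > 1) stop("q must lie in (0, 1]")
  d <- sort(d)
  n <- length(d)
  d[n - ceiling(q * n) + 1L]
}

#' Mean depth per analysis bin
#'
#' @param profile an `nb_depth_profile` computed on the same panel the
#'   bins were derived from.
#' @param bins `GRanges` from `make_bins()`.
#' @return data.frame with one row per bin: `chrom`, `start` (0-based),
#'   `end`, `region_idx`, `bin_idx`, `gene`, `region_class`, `depth`
#'   (mean per-base depth in the bin).
#' @export
bin_depths <- function(profile, bins) {
  mc <- S4Vectors::mcols(bins)
  depth <- numeric(length(bins))
  for (i in seq_along(bins)) {
    ri <- mc$region_idx[i]
    off1 <- GenomicRanges::start(bins)[i] - GenomicRanges::start(profile$regions)[ri] + 1L
    off2 <- GenomicRanges::end(bins)[i] - GenomicRanges::start(profile$regions)[ri] + 1L
    depth[i] <- mean(profile$depth[[ri]][off1:off2])
  }
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(bins)),
    start = GenomicRanges::start(bins) - 1L,
    end = GenomicRanges::end(bins),
    region_idx = mc$region_idx, bin_idx = mc$bin_idx,
    gene = mc$gene, region_class = mc$region_class,
    depth = depth, stringsAsFactors = FALSE
  )
}

#' Alignment QC summary
#'
#' @param reads alignment table or SAM/BAM path.
#' @param panel an `nb_panel`.
#' @param min_mapq minimum mapping quality (default 20).
#' @param q coverage fraction for the depth statistic (default 0.95).
#' @return list with `n_unique_reads`, `on_target_fraction`,
#'   `mean_target_depth`, `coverage_at_q`.
#' @export
qc_summary <- function(reads, panel, min_mapq = 20, q = 0.95) {
  if (is.character(reads)) reads <- read_alignments(reads)
  prof <- depth_profile(reads, panel, min_mapq = min_mapq)
  list(
    n_unique_reads = prof$n_unique_reads,
    on_target_fraction = on_target_fraction(reads, panel, min_mapq = min_mapq),
    mean_target_depth = mean(unlist(prof$depth)),
    coverage_at_q = coverage_at_fraction(prof, q)
  )
}
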