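#' SNV calling parameters
#'
#' Defaults are tuned for high-depth panel data: a site needs at least
#' `min_depth` coverage, `min_alt` supporting reads and a variant
#' allele fraction of `min_vaf` to be reported. Calls below
#' `subclonal_vaf` are flagged subclonal. In tumor-only mode a VAF
#' inside `germline_band` (heterozygous) or at or above `germline_hom`
#' (homozygous) raises a germline-suspicion flag — a flag, never a hard
#' filter, because rigorous filtering would silently drop rare but
#' relevant somatic events.
#'
#' @param min_depth minimum site depth (default 100).
#' @param min_alt minimum alt-supporting reads (default 10).
#' @param min_vaf minimum variant allele fraction (default 0.05).
#' @param base_quality_floor minimum base quality counted (default 20).
#' @param min_mapq minimum mapping quality (default 20).
#' @param subclonal_vaf subclonality threshold (default 0.20).
#' @param germline_band heterozygous germline VAF band (default
#'   c(0.40, 0.60)).
#' @param germline_hom homozygous germline VAF threshold (default 0.90).
#' @return list of parameters.
#' @export
snv_params <- function(min_depth = 100, min_alt = 10, min_vaf = 0.05,
                       base_quality_floor = 20, min_mapq = 20,
                       subclonal_vaf = 0.20,
                       germline_band = c(0.40, 0.60), germline_hom = 0.90) {
  if (min_vaf <= 0 || min_vaf >= 1) stop("min_vaf must lie in (0, 1)")
  if (min_alt < 1) stop("min_alt must be at least 1")
  list(min_depth = min_depth, min_alt = min_alt, min_vaf = min_vaf,
       base_quality_floor = base_quality_floor, min_mapq = min_mapq,
       subclonal_vaf = subclonal_vaf, germline_band = germline_band,
       germline_hom = germline_hom)
}

#' Base-level pileup over the panel
#'
#' Counts A/C/G/T from aligned (CIGAR M/=/X) read bases meeting the
#' mapping- and base-quality floors at every panel base. A file path is
#' piled up with `Rsamtools::pileup()`; an in-memory alignment table
#' (e.g. straight from `simulate_reads()`) is counted directly from the
#' aligned segments, which lets simulation replicates skip disk I/O.
#'
#' @param x SAM/BAM path or alignment table from `read_alignments()`.
#' @param reference `DNAStringSet` or FASTA path (for the ref base).
#' @param panel an `nb_panel`.
#' @param params `snv_params()`.
#' @return data.frame: `chrom`, `pos` (1-based), `ref`, `A`, `C`, `G`,
#'   `T`, `depth`.
#' @export
pileup_table <- function(x, reference, panel, params = snv_params()) {
  if (is.character(reference) && length(reference) == 1 && file.exists(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  targets <- GenomicRanges::reduce(panel$regions, ignore.strand = TRUE)
  miss <- setdiff(unique(as.character(GenomicRanges::seqnames(targets))), names(reference))
  if (length(miss)) stop("panel contigs absent from the reference: ",
                         paste(miss, collapse = ", "))
  if (is.character(x)) {
    counts <- pileup_from_file(x, targets, params)
  } else {
    counts <- pileup_from_table(x, targets, params)
  }
  if (nrow(counts) == 0) return(counts)
  counts$ref <- NA_character_
  for (ch in unique(counts$chrom)) {
    sel <- counts$chrom == ch
    refstr <- as.character(reference[[ch]])
    counts$ref[sel] <- substring(refstr, counts$pos[sel], counts$pos[sel])
  }
  counts[, c("chrom", "pos", "ref", "A", "C", "G", "T", "depth")]
}

pileup_from_file <- function(path, targets, params) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^@", first) || grepl("\\.sam$", path, ignore.case = TRUE)) {
    # asBam sorts by coordinate and indexes
    sorted <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE)
  } else {
    sorted <- Rsamtools::sortBam(path, destination = tempfile())
    Rsamtools::indexBam(sorted)
  }
  p <- Rsamtools::pileup(
    sorted,
    scanBamParam = Rsamtools::ScanBamParam(which = targets),
    pileupParam = Rsamtools::PileupParam(
      max_depth = 1e6, min_base_quality = params$base_quality_floor,
      min_mapq = params$min_mapq, distinguish_strands = FALSE,
      include_deletions = FALSE, include_insertions = FALSE
    )
  )
  if (nrow(p) == 0) {
    return(data.frame(chrom = character(), pos = integer(), A = integer(),
                      C = integer(), G = integer(), T = integer(),
                      depth = integer(), stringsAsFactors = FALSE))
  }
  p <- p[p$nucleotide %in% c("A", "C", "G", "T"), , drop = FALSE]
  wide <- stats::reshape(
    p[, c("seqnames", "pos", "nucleotide", "count")],
    idvar = c("seqnames", "pos"), timevar = "nucleotide", direction = "wide"
  )
  for (b in c("A", "C", "G", "T")) {
    col <- paste0("count.", b)
    if (!col %in% names(wide)) wide[[col]] <- 0L
    wide[[col]][is.na(wide[[col]])] <- 0L
  }
  out <- data.frame(chrom = as.character(wide$seqnames), pos = wide$pos,
                    A = wide$count.A, C = wide$count.C,
                    G = wide$count.G, T = wide$count.T,
                    stringsAsFactors = FALSE)
  out$depth <- out$A + out$C + out$G + out$T
  out[order(out$chrom, out$pos), , drop = FALSE]
}

pileup_from_table <- function(reads, targets, params) {
  reads <- reads[reads$mapq >= params$min_mapq, , drop = FALSE]
  if (!"end" %in% names(reads)) {
    reads$end <- reads$pos +
      GenomicAlignments::cigarWidthAlongReferenceSpace(reads$cigar) - 1L
  }
  bases4 <- c("A", "C", "G", "T")
  # reference/query coordinates of every aligned (M/=/X) segment
  rsegs <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    reads$cigar, pos = reads$pos, ops = c("M", "=", "X"))
  qsegs <- GenomicAlignments::cigarRangesAlongQuerySpace(
    reads$cigar, ops = c("M", "=", "X"))
  nseg <- lengths(rsegs)
  seg <- data.frame(
    read = rep(seq_len(nrow(reads)), nseg),
    rs = IRanges::start(unlist(rsegs, use.names = FALSE)),
    re = IRanges::end(unlist(rsegs, use.names = FALSE)),
    qs = IRanges::start(unlist(qsegs, use.names = FALSE))
  )
  seg$chrom <- reads$chrom[seg$read]
  res <- list()
  for (i in seq_along(targets)) {
    ch <- as.character(GenomicRanges::seqnames(targets))[i]
    lo <- GenomicRanges::start(targets)[i]
    hi <- GenomicRanges::end(targets)[i]
    L <- hi - lo + 1L
    sub <- seg[seg$chrom == ch & seg$rs <= hi & seg$re >= lo, , drop = FALSE]
    if (nrow(sub) == 0) next
    s <- pmax(sub$rs, lo)
    e <- pmin(sub$re, hi)
    qoff <- sub$qs + (s - sub$rs)
    chunk <- substring(reads$seq[sub$read], qoff, qoff + (e - s))
    lens <- e - s + 1L
    all_bases <- strsplit(paste(chunk, collapse = ""), "")[[1]]
    cols <- sequence(lens) - 1L + rep(s - lo + 1L, lens)
    bidx <- match(all_bases, bases4)
    ok <- !is.na(bidx)
    counts <- tabulate((cols[ok] - 1L) * 4L + bidx[ok], nbins = 4L * L)
    mat <- matrix(counts, nrow = 4L)
    depth <- colSums(mat)
    nz <- which(depth > 0)
    if (length(nz) == 0) next
    res[[length(res) + 1L]] <- data.frame(
      chrom = ch, pos = lo + nz - 1L,
      A = mat[1, nz], C = mat[2, nz], G = mat[3, nz], T = mat[4, nz],
      depth = depth[nz], stringsAsFactors = FALSE
    )
  }
  if (length(res) == 0) {
    return(data.frame(chrom = character(), pos = integer(), A = integer(),
                      C = integer(), G = integer(), T = integer(),
                      depth = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Call single-nucleotide variants from a pileup
#'
#' A site is reported when its depth, alternate read count and VAF all
#' clear the configured thresholds; the most frequent non-reference
#' base is the alternate allele. Calls with VAF below the subclonality
#' threshold are flagged `subclonal`.
#'
#' @param pileups data.frame from `pileup_table()`.
#' @param params `snv_params()`.
#' @return data.frame: `chrom`, `pos`, `ref`, `alt`, `alt_count`,
#'   `depth`, `vaf`, `subclonal`.
#' @export
call_snvs <- function(pileups, params = snv_params()) {
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), alt_count = integer(), depth = integer(),
                      vaf = numeric(), subclonal = logical(), stringsAsFactors = FALSE)
  if (nrow(pileups) == 0) return(empty)
  bases <- c("A", "C", "G", "T")
  cnt <- as.matrix(pileups[, bases])
  ref_idx <- match(pileups$ref, bases)
  cnt_alt <- cnt
  cnt_alt[cbind(seq_len(nrow(cnt)), ref_idx)] <- -1L
  alt_idx <- max.col(cnt_alt, ties.method = "first")
  alt_count <- cnt[cbind(seq_len(nrow(cnt)), alt_idx)]
  vaf <- ifelse(pileups$depth > 0, alt_count / pileups$depth, 0)
  keep <- pileups$depth >= params$min_depth &
    alt_count >= params$min_alt & vaf >= params$min_vaf
  if (!any(keep)) return(empty)
  out <- data.frame(
    chrom = pileups$chrom[keep], pos = pileups$pos[keep],
    ref = pileups$ref[keep], alt = bases[alt_idx[keep]],
    alt_count = alt_count[keep], depth = pileups$depth[keep],
    vaf = vaf[keep], subclonal = vaf[keep] < params$subclonal_vaf,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Annotate calls against a hotspot table
#'
#' Matches calls by (chrom, pos, alt) against a hotspot table with
#' columns `gene`, `chrom`, `pos`, `alt`, `protein_change`, `tier`;
#' matched calls get `hotspot_tier1 = TRUE` (tier 1) and the protein
#' change attached. Unmatched calls pass through unchanged.
#'
#' @param calls data.frame from `call_snvs()`.
#' @param hotspots hotspot table (data.frame or TSV path). The bundled
#'   synthetic table for the example panel is used when omitted.
#' @return calls with `gene`, `protein_change`, `hotspot_tier1` added.
#' @export
annotate_hotspots <- function(calls, hotspots = NULL) {
  if (is.null(hotspots)) {
    hotspots <- system.file("extdata", "hotspots_synthetic.tsv", package = "nbpanel")
  }
  if (is.character(hotspots)) hotspots <- utils::read.delim(hotspots, stringsAsFactors = FALSE)
  key <- paste(calls$chrom, calls$pos, calls$alt)
  hkey <- paste(hotspots$chrom, hotspots$pos, hotspots$alt)
  m <- match(key, hkey)
  calls$gene <- ifelse(!is.na(m), hotspots$gene[m],
                       if ("gene" %in% names(calls)) calls$gene else NA_character_)
  calls$protein_change <- ifelse(!is.na(m), hotspots$protein_change[m], NA_character_)
  calls$hotspot_tier1 <- !is.na(m) & hotspots$tier[m] == 1
  calls
}

#' Flag calls with a germline-like allele fraction
#'
#' Tumor-only mode cannot prove somatic origin; calls whose VAF sits in
#' the heterozygous band or at homozygous levels are flagged as
#' possibly germline. Calls matching an optional population-variant
#' site list are flagged regardless of VAF. The flag never removes a
#' call.
#'
#' @param calls data.frame from `call_snvs()`.
#' @param params `snv_params()`.
#' @param population_sites optional data.frame (`chrom`, `pos`, `alt`)
#'   of known population variants.
#' @return calls with a `possible_germline` logical column.
#' @export
flag_possible_germline <- function(calls, params = snv_params(),
                                   population_sites = NULL) {
  band <- params$germline_band
  flag <- (calls$vaf >= band[1] & calls$vaf <= band[2]) |
    calls$vaf >= params$germline_hom
  if (!is.null(population_sites) && nrow(calls)) {
    key <- paste(calls$chrom, calls$pos, calls$alt)
    pkey <- paste(population_sites$chrom, population_sites$pos, population_sites$alt)
    flag <- flag | key %in% pkey
  }
  calls$possible_germline <- flag
  calls
}

#' Probability of detecting a variant at given depth
#'
#' The chance that at least `min_alt` of `depth` reads carry the
#' variant allele when each does so independently with probability
#' `vaf`: the upper tail of Binomial(depth, vaf). This quantifies why a
#' subclonal variant comfortably called at panel depth (~1000x) is
#' frequently missed at exome depth (~45x).
#'
#' @param vaf allele fraction in [0, 1].
#' @param depth site coverage (>= 1).
#' @param min_alt minimum supporting reads (>= 1).
#' @return detection probability in [0, 1]; vectorized.
#' @export
detection_probability <- function(vaf, depth, min_alt) {
  if (any(vaf < 0 | vaf > 1)) stop("vaf must lie in [0, 1]")
  if (any(depth < 1)) stop("depth must be at least 1")
  if (any(min_alt < 1)) stop("min_alt must be at least 1")
  stats::pbinom(min_alt - 1, size = depth, prob = vaf, lower.tail = FALSE)
}

#' Attach panel gene symbols to calls by position
#'
#' @param calls data.frame with `chrom` and `pos` columns.
#' @param panel an `nb_panel`.
#' @return calls with a `gene` column (NA outside gene targets);
#'   existing gene assignments (e.g. from hotspot annotation) are kept.
#' @export
assign_snv_genes <- function(calls, panel) {
  if (nrow(calls) == 0) {
    calls$gene <- character(0)
    return(calls)
  }
  mc <- S4Vectors::mcols(panel$regions)
  gene_gr <- panel$regions[!is.na(mc$gene) & mc$region_class == "gene_target"]
  q <- GenomicRanges::GRanges(calls$chrom, IRanges::IRanges(calls$pos, width = 1))
  hit <- GenomicRanges::findOverlaps(q, gene_gr, select = "first")
  found <- S4Vectors::mcols(gene_gr)$gene[hit]
  if ("gene" %in% names(calls)) {
    calls$gene <- ifelse(is.na(calls$gene), found, calls$gene)
  } else {
    calls$gene <- found
  }
  calls
}
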