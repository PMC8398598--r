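#' Simulation configuration for hybrid-capture alignments
#'
#' Defines the generative model for a synthetic targeted-capture dataset:
#' reference contigs, the panel, depth and enrichment behavior, the
#' fragment-size distribution, tumor purity, and the ground-truth copy
#' number / SNV / structural-variant events. The generator emits reads
#' pre-aligned (positions and CIGARs are computed analytically), so no
#' aligner is involved; breakpoint-spanning reads carry soft clips and
#' their mates land on the partner locus, reproducing the discordant-pair
#' and clipped-read signal the callers consume.
#'
#' @param contigs data.frame with columns `name` and `length` (bp).
#' @param panel an `nb_panel`; fragments are enriched over its regions.
#' @param mean_depth target fold-coverage over panel bases.
#' @param on_target_fraction expected fraction of emitted reads that
#'   overlap a panel region (the enrichment efficiency), in [0, 1].
#' @param fragment_mean,fragment_sd fragment-size distribution (bp);
#'   lengths are normal, truncated at twice the read length.
#' @param read_length read length in bp.
#' @param purity tumor-cell fraction in (0, 1]. Depth over a copy-number
#'   interval scales by `(purity * CN + (1 - purity) * 2) / 2`; SNV alt
#'   probability scales by `purity`.
#' @param cnv_truth data.frame(chrom, start, end, cn): 0-based half-open
#'   intervals with integer total copy number (diploid background = 2).
#' @param snv_truth data.frame(chrom, pos, alt, vaf): 1-based positions;
#'   `vaf` is the tumor-cell variant allele fraction in (0, 1]. Optional
#'   column `ref` pins the reference base at the site.
#' @param sv_truth data.frame(chrom_a, pos_a, chrom_b, pos_b, type, af):
#'   junctions joining the plus strand of A (ending at `pos_a`, 1-based)
#'   to the plus strand of B (starting at `pos_b`); `type` is
#'   `"translocation"` (different contigs) or `"deletion"` (same contig,
#'   pos_a < pos_b); `af` (default 0.5) is the junction allele fraction.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param flank bp around each target inside which a read still counts as
#'   enrichment spill; off-target reads are placed outside target+flank.
#' @param base_error_rate per-base substitution error rate (default 0).
#' @param mapq0_fraction fraction of reads downgraded to MAPQ 0 to
#'   exercise unique-alignment filters.
#' @return A `sim_config` list.
#' @export
sim_config <- function(contigs, panel,
                       mean_depth = 500,
                       on_target_fraction = 0.45,
                       fragment_mean = 250, fragment_sd = 50,
                       read_length = 100,
                       purity = 1,
                       cnv_truth = NULL, snv_truth = NULL, sv_truth = NULL,
                       seed = 1L,
                       flank = 500,
                       base_error_rate = 0,
                       mapq0_fraction = 0) {
  stopifnot(is.data.frame(contigs), all(c("name", "length") %in% names(contigs)))
  if (on_target_fraction < 0 || on_target_fraction > 1) {
    stop("on_target_fraction must lie in [0, 1]")
  }
  if (purity <= 0 || purity > 1) stop("purity must lie in (0, 1]")
  if (fragment_mean < 2 * read_length) {
    stop("fragment_mean must be at least twice the read length")
  }
  if (!is.null(cnv_truth)) {
    stopifnot(all(c("chrom", "start", "end", "cn") %in% names(cnv_truth)))
    if (any(cnv_truth$cn < 0 | cnv_truth$cn != round(cnv_truth$cn))) {
      stop("copy numbers must be non-negative integers")
    }
  }
  if (!is.null(snv_truth)) {
    stopifnot(all(c("chrom", "pos", "alt", "vaf") %in% names(snv_truth)))
    if (any(snv_truth$vaf <= 0 | snv_truth$vaf > 1)) stop("vaf must lie in (0, 1]")
  }
  if (!is.null(sv_truth)) {
    stopifnot(all(c("chrom_a", "pos_a", "chrom_b", "pos_b", "type") %in% names(sv_truth)))
    if (is.null(sv_truth$af)) sv_truth$af <- 0.5
    for (i in seq_len(nrow(sv_truth))) {
      for (side in c("a", "b")) {
        ch <- sv_truth[[paste0("chrom_", side)]][i]
        po <- sv_truth[[paste0("pos_", side)]][i]
        len <- contigs$length[match(ch, contigs$name)]
        if (is.na(len) || po < 1 || po > len) {
          stop("SV breakpoint outside contigs: ", ch, ":", po)
        }
      }
    }
  }
  structure(list(
    contigs = contigs, panel = panel, mean_depth = mean_depth,
    on_target_fraction = on_target_fraction,
    fragment_mean = fragment_mean, fragment_sd = fragment_sd,
    read_length = read_length, purity = purity,
    cnv_truth = cnv_truth, snv_truth = snv_truth, sv_truth = sv_truth,
    seed = as.integer(seed), flank = flank,
    base_error_rate = base_error_rate, mapq0_fraction = mapq0_fraction
  ), class = "sim_config")
}

#' Generative alt-allele probability at a site
#'
#' Returns the probability with which the simulator emits the alternate
#' base in a read (fragment) covering the site: the configured tumor VAF
#' diluted by purity under a copy-neutral model, i.e. `purity * vaf`.
#' Sites with no configured SNV return 0.
#'
#' @param config a `sim_config`.
#' @param chrom,pos site (1-based).
#' @return expected alt fraction in [0, 1].
#' @export
expected_vaf <- function(config, chrom, pos) {
  if (!chrom %in% config$contigs$name) stop("site not on a simulated contig: ", chrom)
  if (pos < 1 || pos > config$contigs$length[match(chrom, config$contigs$name)]) {
    stop("site not covered by the configuration: ", chrom, ":", pos)
  }
  st <- config$snv_truth
  if (is.null(st)) return(0)
  hit <- st$chrom == chrom & st$pos == pos
  if (!any(hit)) return(0)
  config$purity * st$vaf[which(hit)[1]]
}

#' Simulate the reference sequence
#'
#' Random uniform-base contigs; at configured SNV sites the reference
#' base is pinned (to the `ref` column when given, otherwise to a base
#' different from the alt allele) so truth alt alleles are always
#' non-reference.
#'
#' @param config a `sim_config`.
#' @return named `DNAStringSet`.
#' @export
simulate_reference <- function(config) {
  set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  seqs <- lapply(seq_len(nrow(config$contigs)), function(i) {
    paste(sample(bases, config$contigs$length[i], replace = TRUE), collapse = "")
  })
  names(seqs) <- config$contigs$name
  if (!is.null(config$snv_truth)) {
    st <- config$snv_truth
    for (i in seq_len(nrow(st))) {
      s <- seqs[[st$chrom[i]]]
      cur <- substring(s, st$pos[i], st$pos[i])
      want <- if (!is.null(st$ref)) st$ref[i] else if (cur != st$alt[i]) cur else setdiff(bases, st$alt[i])[1]
      substring(s, st$pos[i], st$pos[i]) <- want
      seqs[[st$chrom[i]]] <- s
    }
  }
  Biostrings::DNAStringSet(unlist(seqs))
}

cn_multiplier <- function(chrom, pos, cnv_truth, purity) {
  mult <- rep(1, length(pos))
  if (is.null(cnv_truth)) return(mult)
  for (i in seq_len(nrow(cnv_truth))) {
    hit <- chrom == cnv_truth$chrom[i] &
      pos > cnv_truth$start[i] & pos <= cnv_truth$end[i]
    mult[hit] <- (purity * cnv_truth$cn[i] + (1 - purity) * 2) / 2
  }
  mult
}

trunc_frag_lengths <- function(n, config) {
  fl <- round(stats::rnorm(n, config$fragment_mean, config$fragment_sd))
  pmax(fl, 2 * config$read_length)
}

# one read-pair block: all vectors aligned; coordinates 1-based
empty_reads <- function() {
  data.frame(qname = character(), mate = integer(), chrom = character(),
             pos = integer(), end = integer(), strand = character(),
             cigar = character(), seq = character(), mchrom = character(),
             mpos = integer(), proper = logical(), stringsAsFactors = FALSE)
}

#' Simulate aligned reads in memory
#'
#' Draws fragments over the panel (enriched, copy-number weighted),
#' junction-spanning fragments for each structural variant, and
#' off-target background, and returns the alignment records as a
#' data.frame without touching disk. `simulate_dataset()` wraps this and
#' serializes to SAM.
#'
#' @param config a `sim_config`.
#' @param reference optional `DNAStringSet` from `simulate_reference()`;
#'   generated on the fly when omitted.
#' @return list with `reads` (data.frame: qname, flag, chrom, pos, mapq,
#'   cigar, mchrom, mpos, tlen, seq), and `truth` (realized event
#'   bookkeeping: per-SV junction fragment and clipped-read counts,
#'   per-SNV generative VAF, the configured CNV intervals).
#' @export
simulate_reads <- function(config, reference = NULL) {
  if (is.null(reference)) reference <- simulate_reference(config)
  set.seed(config$seed + 1L)
  rl <- config$read_length
  refc <- as.character(reference)

  targets <- GenomicRanges::reduce(config$panel$regions, ignore.strand = TRUE)
  lambda <- config$mean_depth / (2 * rl)  # fragment starts per bp

  blocks <- list()
  frag_counter <- 0L

  ## --- on-target fragments, copy-number weighted ---
  for (i in seq_along(targets)) {
    ch <- as.character(GenomicRanges::seqnames(targets))[i]
    st <- GenomicRanges::start(targets)[i]
    en <- GenomicRanges::end(targets)[i]
    clen <- config$contigs$length[match(ch, config$contigs$name)]
    grid <- max(1L, st - config$fragment_mean + 1L):en
    w <- cn_multiplier(ch, grid + round(config$fragment_mean / 2), config$cnv_truth, config$purity)
    n <- stats::rpois(1, lambda * sum(w))
    if (n == 0) next
    s <- sample(grid, n, replace = TRUE, prob = w)
    fl <- trunc_frag_lengths(n, config)
    fl <- pmin(fl, clen - s + 1L)  # stay on the contig
    keep <- fl >= 2 * rl
    s <- s[keep]; fl <- fl[keep]; n <- sum(keep)
    if (n == 0) next
    ids <- sprintf("frag%08d", frag_counter + seq_len(n))
    frag_counter <- frag_counter + n
    r1 <- data.frame(qname = ids, mate = 1L, chrom = ch, pos = s,
                     end = s + rl - 1L, strand = "+",
                     cigar = paste0(rl, "M"),
                     seq = substring(refc[[ch]], s, s + rl - 1L),
                     mchrom = ch, mpos = s + fl - rl, proper = TRUE,
                     stringsAsFactors = FALSE)
    r2 <- data.frame(qname = ids, mate = 2L, chrom = ch, pos = s + fl - rl,
                     end = s + fl - 1L, strand = "-",
                     cigar = paste0(rl, "M"),
                     seq = substring(refc[[ch]], s + fl - rl, s + fl - 1L),
                     mchrom = ch, mpos = s, proper = TRUE,
                     stringsAsFactors = FALSE)
    blocks[[length(blocks) + 1L]] <- rbind(r1, r2)
  }
  reads <- if (length(blocks)) do.call(rbind, blocks) else empty_reads()

  ## --- SNV alleles, decided per fragment so mates agree ---
  snv_real <- NULL
  if (!is.null(config$snv_truth) && nrow(reads) > 0) {
    st <- config$snv_truth
    snv_real <- st
    snv_real$p_alt <- config$purity * st$vaf
    snv_real$n_alt_reads <- 0L
    for (i in seq_len(nrow(st))) {
      cov <- which(reads$chrom == st$chrom[i] & reads$pos <= st$pos[i] &
                     reads$end >= st$pos[i] & reads$cigar == paste0(rl, "M"))
      if (length(cov) == 0) next
      frags <- unique(reads$qname[cov])
      alt_frag <- frags[stats::runif(length(frags)) < snv_real$p_alt[i]]
      alt_reads <- cov[reads$qname[cov] %in% alt_frag]
      if (length(alt_reads)) {
        off <- st$pos[i] - reads$pos[alt_reads] + 1L
        seqs <- reads$seq[alt_reads]
        substring(seqs, off, off) <- st$alt[i]
        reads$seq[alt_reads] <- seqs
        snv_real$n_alt_reads[i] <- length(alt_reads)
      }
    }
  }

  ## --- junction-spanning fragments for each structural variant ---
  sv_real <- NULL
  if (!is.null(config$sv_truth)) {
    sv <- config$sv_truth
    sv_real <- sv
    sv_real$n_fragments <- 0L
    sv_real$n_clipped <- 0L
    for (j in seq_len(nrow(sv))) {
      # physical (fragment) coverage of the junction on the variant allele
      n <- stats::rpois(1, lambda * config$fragment_mean * sv$af[j] * config$purity)
      if (n == 0) next
      fl <- trunc_frag_lengths(n, config)
      # junction offset within the fragment; >= 20 aligned bases per side
      u <- vapply(fl, function(l) sample(seq(20L, l - 20L), 1L), 1L)
      ids <- sprintf("svfrag%02d_%06d", j, seq_len(n))
      a_ch <- sv$chrom_a[j]; a_pos <- sv$pos_a[j]
      b_ch <- sv$chrom_b[j]; b_pos <- sv$pos_b[j]
      # read1: last `u` fragment bases before the junction come from A
      m1 <- pmin(u, rl)                      # aligned A bases in read1
      clip1 <- rl - m1                       # B bases soft-clipped
      # read1 covers fragment offsets [1, rl]; A part is offsets [1, u]
      p1 <- a_pos - u + 1L
      a_left <- p1
      seq1 <- ifelse(clip1 > 0,
                     paste0(substring(refc[[a_ch]], a_left, a_pos),
                            substring(refc[[b_ch]], b_pos, b_pos + clip1 - 1L)),
                     substring(refc[[a_ch]], a_left, a_left + rl - 1L))
      cig1 <- ifelse(clip1 > 0, paste0(m1, "M", clip1, "S"), paste0(rl, "M"))
      # read2 (reverse) covers fragment offsets [fl-rl+1, fl]; B part is (fl-u) bases
      bb <- fl - u                           # B bases in the fragment
      m2 <- pmin(bb, rl)                     # aligned B bases in read2
      clip2 <- rl - m2                       # A bases soft-clipped (5' of B)
      p2 <- b_pos + pmax(bb - rl, 0L)
      seq2 <- ifelse(clip2 > 0,
                     paste0(substring(refc[[a_ch]], a_pos - clip2 + 1L, a_pos),
                            substring(refc[[b_ch]], b_pos, b_pos + m2 - 1L)),
                     substring(refc[[b_ch]], p2, p2 + rl - 1L))
      cig2 <- ifelse(clip2 > 0, paste0(clip2, "S", m2, "M"), paste0(rl, "M"))
      r1 <- data.frame(qname = ids, mate = 1L, chrom = a_ch, pos = p1,
                       end = p1 + m1 - 1L, strand = "+", cigar = cig1,
                       seq = seq1, mchrom = b_ch, mpos = p2, proper = FALSE,
                       stringsAsFactors = FALSE)
      r2 <- data.frame(qname = ids, mate = 2L, chrom = b_ch, pos = p2,
                       end = p2 + m2 - 1L, strand = "-", cigar = cig2,
                       seq = seq2, mchrom = a_ch, mpos = p1, proper = FALSE,
                       stringsAsFactors = FALSE)
      blk <- rbind(r1, r2)
      reads <- rbind(reads, blk)
      sv_real$n_fragments[j] <- n
      sv_real$n_clipped[j] <- sum(clip1 > 0) + sum(clip2 > 0)
    }
  }

  ## --- off-target background to hit the configured on-target fraction ---
  tgt_gr <- targets
  read_gr <- GenomicRanges::GRanges(reads$chrom, IRanges::IRanges(reads$pos, reads$end))
  n_hit <- sum(IRanges::overlapsAny(read_gr, tgt_gr))
  p <- config$on_target_fraction
  n_off <- if (p >= 1 || n_hit == 0) 0L else max(0L, round(n_hit / p) - nrow(reads))
  if (n_off > 0) {
    avoid <- GenomicRanges::resize(tgt_gr, GenomicRanges::width(tgt_gr) + 2 * config$flank, fix = "center")
    open <- list()
    for (i in seq_len(nrow(config$contigs))) {
      ch <- config$contigs$name[i]
      whole <- GenomicRanges::GRanges(ch, IRanges::IRanges(1, config$contigs$length[i] - config$fragment_mean - 3 * config$fragment_sd))
      open[[i]] <- GenomicRanges::setdiff(whole, avoid, ignore.strand = TRUE)
    }
    open <- do.call(c, open)
    n_pairs <- ceiling(n_off / 2)
    pick <- sample(length(open), n_pairs, replace = TRUE,
                   prob = GenomicRanges::width(open))
    s <- GenomicRanges::start(open)[pick] +
      floor(stats::runif(n_pairs) * GenomicRanges::width(open)[pick])
    ch <- as.character(GenomicRanges::seqnames(open))[pick]
    fl <- trunc_frag_lengths(n_pairs, config)
    ids <- sprintf("offfrag%08d", seq_len(n_pairs))
    r1 <- data.frame(qname = ids, mate = 1L, chrom = ch, pos = s,
                     end = s + rl - 1L, strand = "+", cigar = paste0(rl, "M"),
                     seq = substring(refc[ch], s, s + rl - 1L),
                     mchrom = ch, mpos = s + fl - rl, proper = TRUE,
                     stringsAsFactors = FALSE)
    r2 <- data.frame(qname = ids, mate = 2L, chrom = ch, pos = s + fl - rl,
                     end = s + fl - 1L, strand = "-", cigar = paste0(rl, "M"),
                     seq = substring(refc[ch], s + fl - rl, s + fl - 1L),
                     mchrom = ch, mpos = s, proper = TRUE,
                     stringsAsFactors = FALSE)
    reads <- rbind(reads, r1, r2)
  }

  ## --- sequencing errors and MAPQ assignment ---
  if (config$base_error_rate > 0 && nrow(reads) > 0) {
    n_err <- stats::rbinom(nrow(reads), rl, config$base_error_rate)
    for (i in which(n_err > 0)) {
      off <- sample.int(rl, n_err[i])
      s <- reads$seq[i]
      for (o in off) {
        substring(s, o, o) <- sample(setdiff(c("A", "C", "G", "T"), substring(s, o, o)), 1)
      }
      reads$seq[i] <- s
    }
  }
  mapq <- rep(60L, nrow(reads))
  if (config$mapq0_fraction > 0 && nrow(reads) > 0) {
    mapq[stats::runif(nrow(reads)) < config$mapq0_fraction] <- 0L
  }

  ## --- assemble SAM-like fields ---
  # mate strand bit: read1's mate (read2) is reverse, read2's mate forward
  flag <- 1L + ifelse(reads$proper, 2L, 0L) +
    ifelse(reads$strand == "-", 16L, 0L) +
    ifelse(reads$mate == 1L, 32L, 0L) +
    ifelse(reads$mate == 1L, 64L, 128L)
  same <- reads$chrom == reads$mchrom
  span <- ifelse(same, abs(reads$mpos - reads$pos) + rl, 0L)
  tlen <- ifelse(same, ifelse(reads$pos <= reads$mpos, span, -span), 0L)
  out <- data.frame(
    qname = reads$qname, flag = as.integer(flag), chrom = reads$chrom,
    pos = as.integer(reads$pos), mapq = mapq, cigar = reads$cigar,
    mchrom = reads$mchrom, mpos = as.integer(reads$mpos),
    tlen = as.integer(tlen), seq = reads$seq,
    stringsAsFactors = FALSE
  )
  ord <- order(match(out$chrom, config$contigs$name), out$pos, out$qname, out$flag)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL

  truth <- list(
    cnv = config$cnv_truth, snv = snv_real, sv = sv_real,
    n_reads = nrow(out),
    n_on_target = n_hit,
    config = list(mean_depth = config$mean_depth,
                  on_target_fraction = config$on_target_fraction,
                  fragment_mean = config$fragment_mean,
                  fragment_sd = config$fragment_sd,
                  read_length = rl, purity = config$purity,
                  seed = config$seed)
  )
  list(reads = out, truth = truth)
}

#' Simulate a full dataset on disk
#'
#' Writes the reference FASTA, a coordinate-sorted SAM with `@HD`/`@SQ`
#' headers, and a JSON truth file. Running twice with the same config and
#' seed produces byte-identical files.
#'
#' @param config a `sim_config`.
#' @param out_dir output directory (created if missing).
#' @param prefix file-name prefix (default "sim").
#' @return list with paths `fasta`, `sam`, `truth_json`, plus the `truth`
#'   list itself.
#' @export
simulate_dataset <- function(config, out_dir, prefix = "sim") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  reference <- simulate_reference(config)
  sim <- simulate_reads(config, reference)
  fasta <- file.path(out_dir, paste0(prefix, "_ref.fa"))
  Biostrings::writeXStringSet(reference, fasta)
  sam <- file.path(out_dir, paste0(prefix, ".sam"))
  write_sam(sim$reads, config$contigs, sam)
  truth_json <- file.path(out_dir, paste0(prefix, "_truth.json"))
  jsonlite::write_json(sim$truth, truth_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  list(fasta = fasta, sam = sam, truth_json = truth_json, truth = sim$truth)
}

#' Write alignment records as SAM
#'
#' @param reads data.frame as returned by `simulate_reads()`.
#' @param contigs data.frame(name, length) for the `@SQ` header lines.
#' @param path output path.
#' @export
write_sam <- function(reads, contigs, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", contigs$name, contigs$length))
  rnext <- ifelse(reads$mchrom == reads$chrom, "=", reads$mchrom)
  qual <- strrep("I", nchar(reads$seq))
  body <- paste(reads$qname, reads$flag, reads$chrom, reads$pos, reads$mapq,
                reads$cigar, rnext, reads$mpos, reads$tlen, reads$seq, qual,
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Convert simulator read records to the alignment-table schema
#'
#' `simulate_reads()` emits SAM-field records; this adds the derived
#' columns (`end`, flag decompositions) that `read_alignments()` would
#' produce, so simulated reads can feed the callers without a SAM/BAM
#' round-trip. Round-tripping through `write_sam()` and
#' `read_alignments()` yields the same table.
#'
#' @param reads data.frame from `simulate_reads()$reads`.
#' @return alignment table as from `read_alignments()`.
#' @export
as_alignment_table <- function(reads) {
  reads$end <- reads$pos +
    GenomicAlignments::cigarWidthAlongReferenceSpace(reads$cigar) - 1L
  reads$reverse <- bitwAnd(reads$flag, 16L) > 0L
  reads$first_of_pair <- bitwAnd(reads$flag, 64L) > 0L
  reads$paired <- bitwAnd(reads$flag, 1L) > 0L
  reads$proper <- bitwAnd(reads$flag, 2L) > 0L
  reads[, c("qname", "flag", "chrom", "pos", "end", "mapq", "cigar",
            "mchrom", "mpos", "tlen", "seq", "reverse", "first_of_pair",
            "paired", "proper")]
}
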