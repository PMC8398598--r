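# Shared fixtures: small panels and simulation configs sized so the whole
# suite runs in minutes, plus brute-force oracles used by several tests.

# panel of 7 equal gene regions (600 bp) on one contig plus 12 reference
# probes on another; used for copy-number simulations
cnv_fixture <- function() {
  bed <- c(
    sprintf("cA\t%d\t%d\tG%d", seq(5000, 41000, by = 6000),
            seq(5600, 41600, by = 6000), 1:7),
    sprintf("cB\t%d\t%d\tREF_%02d", seq(2000, 24000, by = 2000),
            seq(2120, 24120, by = 2000), 1:12)
  )
  panel <- load_panel(bed)
  list(panel = panel,
       contigs = data.frame(name = c("cA", "cB"), length = c(60000L, 30000L),
                            stringsAsFactors = FALSE),
       bins = make_bins(panel, 100))
}

# panel with named marker genes for SV / risk simulations
sv_fixture <- function() {
  bed <- c(
    "sA\t10000\t13000\tALK",
    "sA\t20000\t24000\tATRX",
    "sB\t10000\t13000\tTERT",
    sprintf("sB\t%d\t%d\tREF_%02d", seq(25000, 35000, by = 2000),
            seq(25120, 35120, by = 2000), 1:6)
  )
  panel <- load_panel(bed)
  list(panel = panel,
       contigs = data.frame(name = c("sA", "sB"), length = c(40000L, 40000L),
                            stringsAsFactors = FALSE))
}

# depth profile from an in-memory simulation
sim_profile <- function(fx, seed, mean_depth = 1000, cnv = NULL, purity = 1, ...) {
  cfg <- sim_config(fx$contigs, fx$panel, mean_depth = mean_depth, seed = seed,
                    cnv_truth = cnv, purity = purity, ...)
  depth_profile(as_alignment_table(simulate_reads(cfg)$reads), fx$panel)
}

# 0-based half-open interval of a named gene/region label
region_interval <- function(panel, label) {
  mc <- S4Vectors::mcols(panel$regions)
  i <- which(!is.na(mc$gene) & mc$gene == label)
  c(start = GenomicRanges::start(panel$regions)[i[1]] - 1L,
    end = max(GenomicRanges::end(panel$regions)[i]))
}

# hand-built depth profile: depths is a list of per-region depth vectors
# matching panel regions
fake_profile <- function(panel, depths) {
  structure(list(
    regions = panel$regions,
    depth = depths,
    region_mean = vapply(depths, mean, 0),
    n_unique_reads = sum(lengths(depths)),
    n_on_target_reads = sum(lengths(depths))
  ), class = "nb_depth_profile")
}

# minimal alignment-table row constructor for hand-built read sets
mk_read <- function(qname, chrom, pos, cigar = "100M", mapq = 60L, flag = 99L,
                    mchrom = chrom, mpos = pos, tlen = 0L,
                    seq = strrep("A", 100L)) {
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  data.frame(qname = qname, flag = flag, chrom = chrom, pos = pos,
             end = pos + width - 1L, mapq = mapq, cigar = cigar,
             mchrom = mchrom, mpos = mpos, tlen = tlen, seq = seq,
             reverse = bitwAnd(flag, 16L) > 0L,
             first_of_pair = bitwAnd(flag, 64L) > 0L,
             paired = bitwAnd(flag, 1L) > 0L,
             proper = bitwAnd(flag, 2L) > 0L,
             stringsAsFactors = FALSE)
}

# an inward-facing read pair with a given outer distance (both 100M)
mk_pair <- function(qname, chrom, pos1, outer, chrom2 = chrom,
                    pos2 = NULL, mapq = 60L) {
  if (is.null(pos2)) pos2 <- pos1 + outer - 100L
  rbind(
    mk_read(qname, chrom, pos1, flag = 97L, mchrom = chrom2, mpos = pos2,
            tlen = if (chrom == chrom2) outer else 0L, mapq = mapq),
    mk_read(qname, chrom2, pos2, flag = 145L, mchrom = chrom, mpos = pos1,
            tlen = if (chrom == chrom2) -outer else 0L, mapq = mapq)
  )
}

# brute-force single-linkage consensus oracle for SV merging: O(n^2)
# adjacency + transitive closure, median positions, caller-count filter
merge_oracle <- function(calls, window, min_callers) {
  n <- nrow(calls)
  if (n == 0) return(NULL)
  swap <- (calls$chrom_a > calls$chrom_b) |
    (calls$chrom_a == calls$chrom_b & calls$pos_a > calls$pos_b)
  ca <- ifelse(swap, calls$chrom_b, calls$chrom_a)
  pa <- ifelse(swap, calls$pos_b, calls$pos_a)
  cb <- ifelse(swap, calls$chrom_a, calls$chrom_b)
  pb <- ifelse(swap, calls$pos_a, calls$pos_b)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- ca[i] == ca[j] && cb[i] == cb[j] &&
      calls$type[i] == calls$type[j] &&
      abs(pa[i] - pa[j]) <= window && abs(pb[i] - pb[j]) <= window
  }
  reach <- adj
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (reach[i, k] && reach[k, j]) reach[i, j] <- TRUE
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1L
      comp[reach[i, ]] <- cid
    }
  }
  rows <- lapply(unique(comp), function(cc) {
    mem <- comp == cc
    callers <- sort(unique(calls$caller[mem]))
    if (length(callers) < min_callers) return(NULL)
    data.frame(chrom_a = ca[mem][1],
               pos_a = as.integer(round(stats::median(pa[mem]))),
               chrom_b = cb[mem][1],
               pos_b = as.integer(round(stats::median(pb[mem]))),
               type = calls$type[mem][1],
               n_callers = length(callers),
               callers = paste(callers, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out <- out[order(out$chrom_a, out$pos_a, out$chrom_b, out$pos_b, out$type), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# random multi-caller call sets over a couple of contigs
random_callsets <- function(seed, n_max = 50) {
  set.seed(seed)
  n <- sample.int(n_max, 1)
  data.frame(
    chrom_a = sample(c("c1", "c2"), n, replace = TRUE),
    pos_a = sample.int(5000, n, replace = TRUE),
    chrom_b = sample(c("c1", "c2"), n, replace = TRUE),
    pos_b = sample.int(5000, n, replace = TRUE),
    type = sample(c("DEL", "TRA"), n, replace = TRUE),
    caller = sample(paste0("caller", 1:4), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}
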