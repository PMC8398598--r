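test_that("fragment model is the robust location/scale of outer distances", {
  pairs <- do.call(rbind, lapply(1:120, function(i)
    mk_pair(paste0("p", i), "c1", 1000L + i * 10L, 250L)))
  fm <- fit_fragment_model(pairs)
  expect_equal(fm$fragment_mean, 250)
  expect_equal(fm$fragment_sd, 0)
  expect_equal(fm$cutoff, 250)

  set.seed(2)
  d <- as.integer(round(rnorm(2000, 250, 25)))
  pairs2 <- do.call(rbind, lapply(seq_along(d), function(i)
    mk_pair(paste0("q", i), "c1", 1000L + i, d[i])))
  fm2 <- fit_fragment_model(pairs2)
  expect_lt(abs(fm2$cutoff - 325), 10)

  expect_error(fit_fragment_model(pairs[1:20, ]), "too few")
})

test_that("discordance follows the contig/distance/orientation definition", {
  fm <- structure(list(fragment_mean = 250, fragment_sd = 25, cutoff = 325),
                  class = "nb_fragment_model")
  # different contigs
  d1 <- extract_discordant(mk_pair("a", "c2", 100L, 0L, chrom2 = "c5", pos2 = 200L), fm)
  expect_equal(nrow(d1), 1)
  expect_equal(d1$orientation, "translocation")
  # same contig below cutoff: concordant
  expect_equal(nrow(extract_discordant(mk_pair("b", "c1", 100L, 300L), fm)), 0)
  # same contig far above cutoff
  d3 <- extract_discordant(mk_pair("c", "c1", 100L, 10000L), fm)
  expect_equal(nrow(d3), 1)
  expect_equal(d3$orientation, "del_like")
  # MAPQ filter removes the pair
  expect_equal(nrow(extract_discordant(
    mk_pair("d", "c1", 100L, 10000L, mapq = 5L), fm)), 0)
})

test_that("single-linkage clustering honors window and support", {
  mk_disc <- function(qname, pa, pb) data.frame(
    qname = qname, chrom_a = "c1", pos_a = pa, strand_a = "+",
    chrom_b = "c2", pos_b = pb, strand_b = "-",
    orientation = "translocation", stringsAsFactors = FALSE)
  tight <- do.call(rbind, lapply(1:5, function(i)
    mk_disc(paste0("t", i), 1000L + i * 10L, 5000L + i * 10L)))
  cl <- cluster_discordant(tight, window = 500, min_support = 3)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_pairs, 5)

  sparse <- rbind(mk_disc("s1", 1000L, 5000L), mk_disc("s2", 11000L, 15000L))
  expect_equal(nrow(cluster_discordant(sparse, min_support = 3)), 0)

  # chain at 400 bp steps joins under single-linkage even though the
  # extremes are > window apart; brute-force all-pairs linkage agrees
  chain <- do.call(rbind, lapply(0:5, function(i)
    mk_disc(paste0("ch", i), 1000L + i * 400L, 5000L + i * 400L)))
  cl2 <- cluster_discordant(chain, window = 500, min_support = 3)
  expect_equal(nrow(cl2), 1)
  expect_equal(cl2$n_pairs, 6)
  adj <- outer(chain$pos_a, chain$pos_a, function(x, y) abs(x - y) <= 500) &
    outer(chain$pos_b, chain$pos_b, function(x, y) abs(x - y) <= 500)
  reach <- adj
  for (k in 1:6) reach <- reach | (reach %*% adj > 0)
  expect_true(all(reach))  # oracle: one connected component
})

test_that("clipped reads refine breakpoints to base pairs", {
  cluster <- data.frame(chrom_a = "c1", start_a = 14800L, end_a = 15100L,
                        chrom_b = "c2", start_b = 5000L, end_b = 5200L,
                        orientation = "translocation", n_pairs = 10L,
                        stringsAsFactors = FALSE)
  clipped <- do.call(rbind, lapply(1:10, function(i)
    mk_read(paste0("cl", i), "c1", 14931L, cigar = "70M30S")))  # ends at 15000
  bp <- refine_breakpoint(cluster, clipped)
  expect_equal(bp$resolution, "base_pair")
  expect_equal(bp$pos_a, 15000)
  expect_equal(bp$n_clipped_reads, 10)

  none <- mk_read("x", "c1", 14000L)
  bp2 <- refine_breakpoint(cluster, none)
  expect_equal(bp2$resolution, "interval")
  expect_equal(bp2$pos_a, round((14800 + 15100) / 2))
})

test_that("TERT breakpoints classify as intragenic, upstream, or other", {
  tert <- GenomicRanges::GRanges("chr5", IRanges::IRanges(50001, 53000))
  bp <- function(ch, pos) data.frame(chrom_a = ch, pos_a = pos,
                                     chrom_b = "chr9", pos_b = 1e6)
  expect_equal(classify_tert_rearrangement(bp("chr5", 51500), tert), "tert_intragenic")
  expect_equal(classify_tert_rearrangement(bp("chr5", 40001), tert), "tert_upstream")
  expect_equal(classify_tert_rearrangement(bp("chr5", 20000), tert), "other")
  expect_equal(classify_tert_rearrangement(bp("chr1", 51500), tert), "other")
  # on the minus strand the upstream window flips 3'-ward in coordinates
  expect_equal(classify_tert_rearrangement(bp("chr5", 60000), tert,
                                           tert_strand = "-"), "tert_upstream")
  expect_equal(classify_tert_rearrangement(bp("chr5", 40001), tert,
                                           tert_strand = "-"), "other")
})

test_that("partial deletions need an internal loss run with neutral flanks", {
  mk_ratios <- function(ratio) data.frame(
    chrom = "cX", start = 20000 + 100 * (seq_along(ratio) - 1),
    end = 20000 + 100 * seq_along(ratio), region_idx = 1,
    bin_idx = seq_along(ratio), gene = "ATRX", region_class = "gene_target",
    d_obs = 1000 * ratio, d_exp = 1000, ratio = ratio,
    z = (1000 * ratio - 1000) / 32)
  partial <- detect_partial_deletion("ATRX", mk_ratios(c(1, 1, .5, .5, .5, 1, 1)))
  expect_equal(partial$type, "partial_deletion")
  expect_equal(partial$n_bins_lost, 3)
  expect_equal(partial$confidence, "depth_only")

  whole <- detect_partial_deletion("ATRX", mk_ratios(rep(.5, 7)))
  expect_null(whole)  # whole-gene loss belongs to the CNV caller

  clean <- detect_partial_deletion("ATRX", mk_ratios(rep(1, 7)))
  expect_null(clean)

  # breakpoint at a run edge upgrades confidence
  bp <- data.frame(chrom_a = "cX", pos_a = 20200, chrom_b = "cX", pos_b = 20500)
  conf <- detect_partial_deletion("ATRX", mk_ratios(c(1, 1, .5, .5, .5, 1, 1)),
                                  breakpoints = bp)
  expect_equal(conf$confidence, "breakpoint_supported")

  # breakpoint without any depth run: breakpoint_only record
  only <- detect_partial_deletion("ATRX", mk_ratios(rep(1, 7)), breakpoints = bp)
  expect_equal(only$type, "breakpoint_only")

  expect_error(detect_partial_deletion("ATRX", mk_ratios(c(1, 1, 1))), "6 bins")
})

test_that("simulated rearrangements are recovered end to end", {
  fx <- sv_fixture()
  alk <- region_interval(fx$panel, "ALK")
  atrx <- region_interval(fx$panel, "ATRX")
  del_lo <- atrx[["start"]] + 1200L
  del_hi <- del_lo + 1500L
  sv <- data.frame(chrom_a = c("sA", "sA"),
                   pos_a = c(alk[["start"]] + 1500L, del_lo),
                   chrom_b = c("sB", "sA"),
                   pos_b = c(11500L, del_hi),
                   type = c("translocation", "deletion"), af = 0.5)
  cnv <- data.frame(chrom = "sA", start = del_lo, end = del_hi - 1L, cn = 1)
  cfg <- sim_config(fx$contigs, fx$panel, mean_depth = 400, seed = 77,
                    sv_truth = sv, cnv_truth = cnv)
  reads <- as_alignment_table(simulate_reads(cfg)$reads)
  calls <- call_svs(reads, fx$panel)

  tra <- calls[calls$orientation == "translocation", ]
  expect_equal(nrow(tra), 1)
  expect_equal(tra$resolution, "base_pair")
  expect_lte(abs(tra$pos_a - sv$pos_a[1]), 5)
  expect_lte(abs(tra$pos_b - sv$pos_b[1]), 5)
  expect_equal(tra$annotation, "tert_intragenic")
  expect_match(tra$genes, "ALK")

  del <- calls[calls$orientation == "del_like", ]
  expect_equal(nrow(del), 1)
  expect_lte(abs(del$pos_a - del_lo), 10)
  expect_lte(abs(del$pos_b - del_hi), 10)
  expect_match(del$genes, "ATRX")
})
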