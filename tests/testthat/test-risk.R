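# helpers to assemble profiles from minimal marker descriptions
mk_cnv_row <- function(region, category) {
  data.frame(region = region, call = TRUE, reason = "called",
             direction = if (category %in% c("loss", "deep_loss")) "loss" else "gain",
             category = category, mean_ratio = 1, cn_estimate = 1,
             frac_significant = 1, n_bins = 10, stringsAsFactors = FALSE)
}
mk_sv_row <- function(annotation) {
  data.frame(chrom_a = "c", pos_a = 1L, chrom_b = "c", pos_b = 2L,
             orientation = "translocation", n_discordant_pairs = 10L,
             n_clipped_reads = 5L, resolution = "base_pair", genes = "TERT",
             annotation = annotation, stringsAsFactors = FALSE)
}
mk_snv_row <- function(gene, vaf = 0.3, germline = FALSE) {
  data.frame(chrom = "c", pos = 1L, ref = "A", alt = "G", alt_count = 100L,
             depth = 1000L, vaf = vaf, subclonal = vaf < 0.2, gene = gene,
             possible_germline = germline, stringsAsFactors = FALSE)
}
mk_profile <- function(id = "s1", cnv = NULL, sv = NULL, snv = NULL, atrx = NULL) {
  tumor_profile(id, cnv_calls = cnv, sv_calls = sv, snv_calls = snv,
                atrx_events = atrx)
}

test_that("telomere-maintenance status aggregates the three marker classes", {
  expect_equal(telomere_maintenance_status(
    mk_profile(cnv = mk_cnv_row("MYCN", "amplification"))), "mycn_amplification")
  expect_equal(telomere_maintenance_status(
    mk_profile(sv = mk_sv_row("tert_upstream"))), "tert_rearrangement")
  expect_equal(telomere_maintenance_status(
    mk_profile(sv = mk_sv_row("tert_intragenic"))), "tert_rearrangement")
  expect_equal(telomere_maintenance_status(
    mk_profile(snv = mk_snv_row("ATRX"))), "atrx_alteration")
  expect_equal(telomere_maintenance_status(
    mk_profile(atrx = data.frame(type = "partial_deletion"))), "atrx_alteration")
  # co-occurring MYCN amplification and TERT rearrangement
  expect_equal(telomere_maintenance_status(
    mk_profile(cnv = mk_cnv_row("MYCN", "amplification"),
               sv = mk_sv_row("tert_upstream"))), "multiple")
  expect_equal(telomere_maintenance_status(mk_profile()), "none")
  # upstream and intragenic TERT classes are reported distinctly
  mk <- tmm_markers(mk_profile(sv = rbind(mk_sv_row("tert_upstream"),
                                          mk_sv_row("tert_intragenic"))))
  expect_setequal(mk, c("tert_rearrangement_upstream",
                        "tert_rearrangement_intragenic"))
})

test_that("risk classification is exhaustive over TMM and pathway combinations", {
  tmm_opts <- list(
    none = list(),
    mycn = list(cnv = mk_cnv_row("MYCN", "amplification")),
    tert = list(sv = mk_sv_row("tert_upstream")),
    atrx = list(snv = mk_snv_row("ATRX")),
    mycn_tert = list(cnv = mk_cnv_row("MYCN", "amplification"),
                     sv = mk_sv_row("tert_upstream")),
    all = list(cnv = mk_cnv_row("MYCN", "amplification"),
               sv = mk_sv_row("tert_intragenic"),
               atrx = data.frame(type = "partial_deletion"))
  )
  pathway_opts <- list(
    none = NULL,
    ras = mk_snv_row("ALK"),
    p53 = mk_snv_row("TP53"),
    both = rbind(mk_snv_row("ALK"), mk_snv_row("TP53"))
  )
  for (tn in names(tmm_opts)) {
    for (pn in names(pathway_opts)) {
      args <- tmm_opts[[tn]]
      extra_snv <- pathway_opts[[pn]]
      snv <- rbind(args$snv, extra_snv)
      prof <- tumor_profile("x", cnv_calls = args$cnv, sv_calls = args$sv,
                            snv_calls = snv, atrx_events = args$atrx)
      rc <- classify_risk(prof)
      tmm_pos <- tn != "none"
      path_pos <- pn != "none"
      want <- if (tmm_pos && path_pos) "ultra_high_risk"
              else if (tmm_pos) "high_risk_tmm" else "tmm_negative"
      expect_equal(rc$risk_class, want, info = paste(tn, pn))
      if (pn == "ras") expect_equal(rc$pathway_hits, "RAS_MAPK")
      if (pn == "both") expect_setequal(rc$pathway_hits, c("RAS_MAPK", "p53_MDM2"))
      if (!tmm_pos) expect_match(rc$caveat, "ALT")
    }
  }
})

test_that("germline-flagged SNVs do not count as pathway hits by default", {
  prof <- mk_profile(cnv = mk_cnv_row("MYCN", "amplification"),
                     snv = mk_snv_row("ALK", vaf = 0.5, germline = TRUE))
  expect_equal(classify_risk(prof)$risk_class, "high_risk_tmm")
  expect_equal(classify_risk(prof, include_germline = TRUE)$risk_class,
               "ultra_high_risk")
  # amplification of a pathway gene is a hit even without SNVs
  amp <- mk_profile(cnv = rbind(mk_cnv_row("MYCN", "amplification"),
                                mk_cnv_row("ALK", "amplification")))
  expect_equal(classify_risk(amp)$risk_class, "ultra_high_risk")
  expect_error(classify_risk(mk_profile(), pathway_gene_sets = list()), "empty")
})

test_that("pathway gene sets load from TSV", {
  sets <- read_pathway_gene_sets(
    system.file("extdata", "pathway_gene_sets_default.tsv", package = "nbpanel"))
  expect_setequal(names(sets), c("RAS_MAPK", "p53_MDM2"))
  expect_true("ALK" %in% sets$RAS_MAPK)
  expect_true("TP53" %in% sets$p53_MDM2)
})

test_that("FISH subclonal fractions aggregate by summation", {
  expect_equal(aggregate_fish_fraction(c(14, 10, 2)), 26)
  expect_equal(aggregate_fish_fraction(100), 100)
  expect_equal(aggregate_fish_fraction(numeric(0)), 0)
  expect_equal(aggregate_fish_fraction(
    data.frame(ratio = c("2:1", "3:1"), percent = c(14, 10))), 24)
  expect_error(aggregate_fish_fraction(c(60, 50)), "100")
  expect_error(aggregate_fish_fraction(c(-1, 5)), "non-negative")
})

test_that("concordance counts and lists planted discordances", {
  ids <- sprintf("P%02d", 1:20)
  ref <- data.frame(sample_id = rep(ids, 2),
                    marker = rep(c("MYCN", "1p36"), each = 20),
                    call = rep(c(TRUE, FALSE), 20), stringsAsFactors = FALSE)
  same <- concordance(ref, ref)
  expect_equal(nrow(same$discordant), 0)
  expect_true(all(rowSums(same$per_marker[, -1]) == 20))

  panel <- ref
  flip <- panel$sample_id == "P07" & panel$marker == "1p36"
  panel$call[flip] <- FALSE
  ref$call[flip] <- TRUE
  rep_ <- concordance(panel, ref)
  expect_equal(nrow(rep_$discordant), 1)
  expect_equal(rep_$discordant$sample_id, "P07")
  expect_equal(rep_$discordant$reason, "reference_only")
  m <- rep_$per_marker[rep_$per_marker$marker == "1p36", ]
  expect_equal(m$reference_only, 1)
  expect_true(all(rowSums(rep_$per_marker[, -1]) == 20))

  expect_error(concordance(panel[-1, ], ref), "absent")
})

test_that("oncoplot matrix reflects profiles and is order invariant", {
  one <- mk_profile("s1", snv = mk_snv_row("ALK"))
  op1 <- build_oncoplot_matrix(list(one))
  expect_equal(sum(op1$matrix != "none"), 1)
  expect_equal(op1$matrix["ALK", "s1"], "SNV")

  empty <- build_oncoplot_matrix(list())
  expect_equal(ncol(empty$matrix), 0)

  profs <- list(
    mk_profile("a", cnv = mk_cnv_row("MYCN", "amplification"),
               snv = mk_snv_row("ALK")),
    mk_profile("b", sv = mk_sv_row("tert_upstream")),
    mk_profile("c", cnv = mk_cnv_row("1p36", "loss")),
    mk_profile("d")
  )
  op <- build_oncoplot_matrix(profs)
  # cell counts equal planted event counts
  expect_equal(sum(op$matrix != "none"), 4)
  expect_equal(op$matrix["MYCN", "a"], "amplification")
  expect_equal(op$matrix["TERT", "b"], "rearrangement")
  expect_equal(op$matrix["1p36", "c"], "loss")
  # ultra-high-risk sample sorts first
  expect_equal(colnames(op$matrix)[1], "a")
  expect_equal(op$covariates$risk_class[1], "ultra_high_risk")
  # input order does not change the result
  op_rev <- build_oncoplot_matrix(rev(profs))
  expect_equal(op$matrix, op_rev$matrix)

  tsv <- tempfile(fileext = ".tsv")
  write_oncoplot_tsv(op, tsv)
  lines <- readLines(tsv)
  expect_equal(sum(grepl("^#", lines)), 3)
  expect_equal(length(lines), 3 + 1 + nrow(op$matrix))
})
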