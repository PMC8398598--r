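# hand-built bin scaffolding: one panel whose regions are exact multiples
# of the bin size, so bin depths can be set directly
ratio_panel <- function() {
  load_panel(c("c1\t0\t1000\tG1",        # 10 bins
               "c1\t2000\t3000\tG2",     # 10 bins
               sprintf("c2\t%d\t%d\tREF_%02d", seq(0, 1800, 200),
                       seq(100, 1900, 200), 1:10)))
}

profile_with_bin_depths <- function(panel, per_bin) {
  # expand per-bin depths into constant per-base depths
  depths <- lapply(seq_along(panel$regions), function(i) {
    w <- GenomicRanges::width(panel$regions)[i]
    nb <- ceiling(w / 100)
    rep(as.integer(per_bin[[i]]), each = 100)[seq_len(w)]
  })
  fake_profile(panel, depths)
}

test_that("control model aggregates by median with a Poisson dispersion floor", {
  p <- ratio_panel()
  bins <- make_bins(p, 100)
  flat <- function(v) c(list(rep(v, 10)), list(rep(v, 10)), as.list(rep(v, 10)))
  c1 <- profile_with_bin_depths(p, flat(100))
  c2 <- profile_with_bin_depths(p, flat(120))
  model <- build_control_model(list(c1, c2), bins)
  # both controls are flat, so library scaling maps both onto the pooled
  # median and the per-bin expectation is their common scaled value
  expect_true(all(abs(model$d_exp - 110) < 1e-9))
  # identical controls: dispersion sits exactly at the prediction-error
  # floor (counting noise + median estimation error), never zero
  model2 <- build_control_model(list(c1, c1, c1), bins)
  expect_equal(model2$dispersion, sqrt(model2$d_exp * (1 + pi / 6)))
  expect_true(all(model2$dispersion >= sqrt(model2$d_exp)))
  expect_gt(min(model2$dispersion), 0)
})

test_that("bin ratios recover per-bin fold changes and z-scores", {
  p <- ratio_panel()
  bins <- make_bins(p, 100)
  flat <- function(v) c(list(rep(v, 10)), list(rep(v, 10)), as.list(rep(v, 10)))
  model <- build_control_model(list(profile_with_bin_depths(p, flat(1000)),
                                    profile_with_bin_depths(p, flat(1000)),
                                    profile_with_bin_depths(p, flat(1000))), bins)
  # identical sample: all ratios 1, all z 0
  r0 <- bin_ratios(profile_with_bin_depths(p, flat(1000)), model, bins)
  expect_true(all(abs(r0$ratio - 1) < 1e-9))
  expect_true(all(abs(r0$z) < 1e-9))
  # doubled G1 bins: ratio 2 there, 1 elsewhere (probes anchor scaling)
  doubled <- c(list(rep(2000, 10)), list(rep(1000, 10)), as.list(rep(1000, 10)))
  r2 <- bin_ratios(profile_with_bin_depths(p, doubled), model, bins)
  expect_true(all(abs(r2$ratio[r2$gene %in% "G1"] - 2) < 1e-9))
  expect_true(all(abs(r2$ratio[is.na(r2$gene)] - 1) < 1e-9))
})

test_that("bin ratios are invariant under a common depth rescaling", {
  p <- ratio_panel()
  bins <- make_bins(p, 100)
  set.seed(3)
  base <- lapply(GenomicRanges::width(p$regions), function(w)
    rpois(ceiling(w / 100), 900))
  scale_profiles <- function(k) {
    ctrl <- lapply(1:3, function(i) profile_with_bin_depths(
      p, lapply(base, function(b) k * (b + i))))
    samp <- profile_with_bin_depths(p, lapply(base, function(b) k * (b + 50)))
    bin_ratios(samp, build_control_model(ctrl, bins), bins)
  }
  r1 <- scale_profiles(1)
  r4 <- scale_profiles(4)
  expect_equal(r1$ratio, r4$ratio, tolerance = 1e-9)
})

test_that("the majority-of-bins rule gates region calls", {
  mk_ratios <- function(z) data.frame(chrom = "c1", start = seq_along(z),
                                      end = seq_along(z) + 1, region_idx = 1,
                                      bin_idx = seq_along(z), gene = "G",
                                      region_class = "gene_target",
                                      d_obs = 1000, d_exp = 1000,
                                      ratio = 1 + z / 10, z = z)
  up8 <- call_region_cnv(mk_ratios(c(rep(5, 8), 0, 0)), "G")
  expect_true(up8$call)
  expect_equal(up8$direction, "gain")
  expect_equal(up8$frac_significant, 0.8)

  half <- call_region_cnv(mk_ratios(c(rep(5, 5), rep(0, 5))), "G")
  expect_false(half$call)  # exactly 50% is not a majority
  expect_equal(half$reason, "no_significant_majority")

  mixed <- call_region_cnv(mk_ratios(c(rep(5, 4), rep(-5, 4), 0, 0)), "G")
  expect_false(mixed$call)
  expect_equal(mixed$reason, "mixed_direction")

  few <- call_region_cnv(mk_ratios(c(5, 5)), "G")
  expect_false(few$call)
  expect_equal(few$reason, "insufficient_bins")
})

test_that("copy-number estimation inverts the purity mixture", {
  expect_equal(estimate_copy_number(2.0, 1.0), 4.0)
  expect_equal(estimate_copy_number(2.0, 0.5), 6.0)
  expect_equal(estimate_copy_number(1.0, 0.7), 2.0)
  expect_equal(estimate_copy_number(0.01, 0.5), 0)  # clipped at zero
  expect_error(estimate_copy_number(2.0, 0), "purity")
})

test_that("copy-number categories follow the diagnostic thresholds", {
  expect_equal(classify_cnv(40), "amplification")
  expect_equal(classify_cnv(8), "amplification")
  expect_equal(classify_cnv(4), "gain")
  expect_equal(classify_cnv(2.5), "gain")
  expect_equal(classify_cnv(2.0), "neutral")
  expect_equal(classify_cnv(1.0), "loss")
  expect_equal(classify_cnv(1.5), "loss")
  expect_equal(classify_cnv(0.3), "deep_loss")
})

test_that("a held-out diploid sample stays quiet against simulated controls", {
  fx <- cnv_fixture()
  model <- build_control_model(lapply(101:103, function(s)
    sim_profile(fx, s, mean_depth = 500)), fx$bins)
  r <- bin_ratios(sim_profile(fx, 199, mean_depth = 500), model, fx$bins)
  expect_gt(mean(abs(r$z) < 3), 0.99)
  expect_equal(sum(call_cnvs(r)$call), 0)
})

test_that("simulated amplification is recovered through the full stack", {
  fx <- cnv_fixture()
  model <- build_control_model(lapply(111:113, function(s)
    sim_profile(fx, s, mean_depth = 500)), fx$bins)
  iv <- region_interval(fx$panel, "G3")
  cnv <- data.frame(chrom = "cA", start = iv["start"] - 2000,
                    end = iv["end"] + 2000, cn = 8)
  r <- bin_ratios(sim_profile(fx, 221, mean_depth = 500, cnv = cnv), model, fx$bins)
  calls <- call_cnvs(r)
  g3 <- calls[calls$region == "G3", ]
  expect_true(g3$call)
  expect_equal(g3$category, "amplification")
  expect_lt(abs(g3$cn_estimate - 8) / 8, 0.2)
  expect_equal(sum(calls$call), 1)
})
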