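#' Build a copy-number control model from diploid control samples
#'
#' Controls are assumed diploid over the whole panel, so they capture
#' only the technical (capture + sequencing) variation. Each control's
#' bin depths are library-size normalized to the pooled median before
#' aggregation; the expected depth per bin is the median across controls
#' and the dispersion is the MAD-derived standard deviation, floored at
#' the Poisson prediction-error bound
#' `sqrt(d_exp * (1 + pi / (2 * n_controls)))`: counting noise in the
#' future sample plus the sampling error of a median estimated from
#' `n_controls` noisy control profiles (a median is pi/2 times less
#' efficient than a mean). The floor keeps z-scores finite and
#' calibrated even when controls happen to agree exactly. Bins with no
#' depth in any control, or expected depth below `min_expected`, are
#' masked.
#'
#' @param control_profiles list of `nb_depth_profile`s, all computed on
#'   the same panel.
#' @param bins `GRanges` from `make_bins()` on that panel.
#' @param min_expected bins with expected depth below this are masked
#'   (default 10).
#' @return An `nb_control_model`.
#' @export
build_control_model <- function(control_profiles, bins, min_expected = 10) {
  if (length(control_profiles) < 1) stop("need at least one control profile")
  mats <- lapply(control_profiles, bin_depths, bins = bins)
  nb <- nrow(mats[[1]])
  if (!all(vapply(mats, nrow, 0L) == nb)) stop("control profiles have mismatched bin sets")
  depth <- do.call(cbind, lapply(mats, `[[`, "depth"))
  med_per_control <- apply(depth, 2, stats::median)
  pooled <- stats::median(med_per_control)
  if (pooled <= 0) stop("controls have no usable depth")
  scaled <- sweep(depth, 2, pooled / med_per_control, `*`)
  d_exp <- apply(scaled, 1, stats::median)
  disp <- apply(scaled, 1, stats::mad)  # already scaled to sd for normal data
  floor_sd <- sqrt(pmax(d_exp, 0) * (1 + pi / (2 * length(control_profiles))))
  disp <- pmax(disp, floor_sd)
  masked <- d_exp < min_expected | apply(depth, 1, function(x) all(x == 0))
  bt <- mats[[1]][, c("chrom", "start", "end", "region_idx", "bin_idx",
                      "gene", "region_class")]
  structure(list(
    bins = bt, d_exp = d_exp, dispersion = disp, masked = masked,
    n_controls = length(control_profiles)
  ), class = "nb_control_model")
}

#' @export
print.nb_control_model <- function(x, ...) {
  cat(sprintf("nb_control_model: %d bins (%d masked), %d controls\n",
              nrow(x$bins), sum(x$masked), x$n_controls))
  invisible(x)
}

# median-of-ratios library-size factor; reference probes anchor the
# normalization when present (they sit in copy-neutral territory by design)
library_size_factor <- function(d_obs, model) {
  use <- !model$masked & model$d_exp > 0
  ref <- use & model$bins$region_class == "reference_probe"
  if (sum(ref) >= 5) use <- ref
  stats::median(d_obs[use] / model$d_exp[use])
}

#' Per-bin depth ratios of a sample against the control model
#'
#' The sample's bin depths are library-size normalized onto the model's
#' scale (median of per-bin observed/expected ratios over reference-probe
#' bins when at least five are usable, otherwise over all unmasked bins),
#' then each unmasked bin gets the ratio `r = d_obs / d_exp` and the
#' z-score `(d_obs - d_exp) / dispersion`.
#'
#' @param sample an `nb_depth_profile` (or a `bin_depths()` data.frame).
#' @param model an `nb_control_model`.
#' @param bins the `GRanges` bins used for the model; required when
#'   `sample` is a profile.
#' @return data.frame with the model's bin columns plus `d_obs`
#'   (normalized), `d_exp`, `ratio`, `z`; masked bins are excluded.
#' @export
bin_ratios <- function(sample, model, bins = NULL) {
  if (inherits(sample, "nb_depth_profile")) {
    if (is.null(bins)) stop("bins are required when passing a depth profile")
    sample <- bin_depths(sample, bins)
  }
  if (nrow(sample) != nrow(model$bins)) stop("sample bin set does not match the model")
  if (all(model$masked)) stop("no unmasked bins in the control model")
  f <- library_size_factor(sample$depth, model)
  if (!is.finite(f) || f <= 0) stop("library-size factor is not positive; sample unusable")
  d_obs <- sample$depth / f
  out <- model$bins
  out$d_obs <- d_obs
  out$d_exp <- model$d_exp
  out$ratio <- ifelse(model$d_exp > 0, d_obs / model$d_exp, NA_real_)
  out$z <- (d_obs - model$d_exp) / model$dispersion
  out[!model$masked, , drop = FALSE]
}

#' Call a copy-number alteration for one gene or region
#'
#' Implements the majority-of-bins rule: a call is emitted only when
#' strictly more than `majority` of the region's unmasked bins deviate
#' significantly (|z| > `z_cut`) from the control expectation *in the
#' same direction*. Significant bins split across both directions yield
#' a no-call (`mixed_direction`); fewer than `min_bins` bins yield a
#' no-call (`insufficient_bins`).
#'
#' @param ratios `bin_ratios()` rows belonging to one gene/region.
#' @param region label for the output row.
#' @param z_cut z threshold for a significant bin (default 3).
#' @param majority required fraction of significant same-sign bins,
#'   exclusive (default 0.5).
#' @param min_bins minimum unmasked bins (default 3).
#' @param purity tumor purity for copy-number estimation (default 1).
#' @param ploidy background ploidy (default 2).
#' @return one-row data.frame: `region`, `call` (logical), `reason`,
#'   `direction`, `category`, `mean_ratio`, `cn_estimate`,
#'   `frac_significant`, `n_bins`.
#' @export
call_region_cnv <- function(ratios, region = NA_character_, z_cut = 3,
                            majority = 0.5, min_bins = 3,
                            purity = 1, ploidy = 2) {
  n <- nrow(ratios)
  no_call <- function(reason) {
    data.frame(region = region, call = FALSE, reason = reason,
               direction = NA_character_, category = "neutral",
               mean_ratio = if (n) mean(ratios$ratio) else NA_real_,
               cn_estimate = NA_real_,
               frac_significant = NA_real_, n_bins = n,
               stringsAsFactors = FALSE)
  }
  if (n < min_bins) return(no_call("insufficient_bins"))
  up <- ratios$z > z_cut
  dn <- ratios$z < -z_cut
  frac_up <- sum(up) / n
  frac_dn <- sum(dn) / n
  if (frac_up <= majority && frac_dn <= majority) {
    out <- no_call(if (sum(up) + sum(dn) > majority * n) "mixed_direction"
                   else "no_significant_majority")
    return(out)
  }
  dir <- if (frac_up > majority) "gain" else "loss"
  sig <- if (dir == "gain") up else dn
  mean_ratio <- mean(ratios$ratio[sig])
  cn <- estimate_copy_number(mean_ratio, purity = purity, ploidy = ploidy)
  data.frame(region = region, call = TRUE, reason = "called",
             direction = dir, category = classify_cnv(cn),
             mean_ratio = mean_ratio, cn_estimate = cn,
             frac_significant = max(frac_up, frac_dn), n_bins = n,
             stringsAsFactors = FALSE)
}

#' Absolute copy number from a depth ratio
#'
#' Inverts the purity-mixture model: an observed ratio `r` over a region
#' of tumor copy number CN in a sample of purity `p` satisfies
#' `r = (p * CN + (1 - p) * ploidy) / ploidy`, so
#' `CN = (ploidy * r - ploidy * (1 - p)) / p`, clipped at zero.
#'
#' @param mean_ratio depth ratio against the diploid expectation.
#' @param purity tumor-cell fraction in (0, 1].
#' @param ploidy background ploidy (default 2).
#' @return copy-number estimate (non-negative).
#' @export
estimate_copy_number <- function(mean_ratio, purity = 1, ploidy = 2) {
  if (purity <= 0 || purity > 1) stop("purity must lie in (0, 1]")
  pmax(0, (ploidy * mean_ratio - ploidy * (1 - purity)) / purity)
}

#' Categorize a copy-number estimate
#'
#' Thresholds follow diagnostic convention for high-level amplification
#' (at least 4-fold over diploid): `amplification` at CN >= 8, `gain` at
#' CN >= 2.5, `deep_loss` at CN <= 0.5, `loss` at CN <= 1.5, otherwise
#' `neutral`.
#'
#' @param cn copy-number estimate, non-negative.
#' @param amp_cn amplification threshold (default 8).
#' @return one of "amplification", "gain", "neutral", "loss", "deep_loss".
#' @export
classify_cnv <- function(cn, amp_cn = 8) {
  ifelse(cn >= amp_cn, "amplification",
         ifelse(cn >= 2.5, "gain",
                ifelse(cn <= 0.5, "deep_loss",
                       ifelse(cn <= 1.5, "loss", "neutral"))))
}

#' Call copy-number alterations for every gene and chromosomal region
#'
#' Groups the sample's bin ratios by gene symbol (gene targets) or
#' region label (1p36/11q/17q tiles; tiles sharing a label are assessed
#' jointly), applies the majority-of-bins rule to each group, and
#' estimates absolute copy number for emitted calls. Reference probes
#' are normalization anchors and are never called.
#'
#' @param ratios output of `bin_ratios()`.
#' @inheritParams call_region_cnv
#' @return data.frame with one row per gene/region (see
#'   `call_region_cnv()`).
#' @export
call_cnvs <- function(ratios, z_cut = 3, majority = 0.5, min_bins = 3,
                      purity = 1, ploidy = 2) {
  callable <- ratios[ratios$region_class != "reference_probe", , drop = FALSE]
  key <- ifelse(!is.na(callable$gene), callable$gene,
                paste0("region_", callable$region_idx))
  rows <- lapply(split(callable, key), function(grp) {
    call_region_cnv(grp, region = unique(ifelse(is.na(grp$gene),
                                                paste0("region_", grp$region_idx),
                                                grp$gene))[1],
                    z_cut = z_cut, majority = majority, min_bins = min_bins,
                    purity = purity, ploidy = ploidy)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$region), , drop = FALSE]
}
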