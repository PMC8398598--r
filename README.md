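# nbpanel

Downstream analysis toolkit for high-depth hybrid-capture panel sequencing
of neuroblastoma, for molecular diagnostics developers and bioinformaticians
validating targeted assays. From aligned reads (SAM/BAM) plus a panel
definition (BED + gene table), it produces the complete marker set used for
neuroblastoma risk stratification — copy-number state of *MYCN*, 1p36, 11q
and 17q, *TERT* rearrangements, *ATRX* alterations, pathway SNVs — and the
derived risk class, including the ultra-high-risk category.

## Methods at a glance

* **Copy number.** The target territory is tiled into bins (default
  100 bp). Diploid technical controls give a per-bin expected depth
  (median across library-size-normalized controls) and dispersion (MAD,
  floored at the Poisson prediction-error bound
  `sqrt(d_exp (1 + π/2n))`). A sample's bin ratios `r = d_obs/d_exp` are
  normalized by median-of-ratios over genome-wide reference probes; a
  gene/region is called only when a strict majority of its bins deviates
  at |z| > 3 in one direction. Absolute copy number inverts the purity
  mixture `r = (p·CN + (1−p)·2)/2`; amplification is CN ≥ 8.
* **Rearrangements.** Discordant pairs (different contigs, distance above
  the robustly fit `mean + 3sd` fragment-size cutoff, or wrong
  orientation) are clustered by single linkage (500 bp windows, ≥ 3
  pairs); soft-clip voting refines breakpoints to base-pair resolution.
  *TERT* breakpoints are classified upstream (≤ 25 kb 5′ of the TSS)
  versus intragenic; *ATRX* partial deletions need an internal run of
  loss bins with neutral flanks, optionally breakpoint-supported.
* **Multi-caller consensus.** Call sets (BND VCF or breakpoint TSV) merge
  when both breakpoints fall within a 500 bp window; consensus calls
  supported by fewer than two distinct callers are discarded.
* **SNVs.** Tumor-only pileup calling (depth ≥ 100, alt reads ≥ 10,
  VAF ≥ 0.05), subclonal flag below 20% VAF, germline-suspicion flag in
  the 40–60% / ≥ 90% VAF bands (never a hard filter), positional hotspot
  annotation. `detection_probability(f, c, k) = P(X ≥ k), X ~ Bin(c, f)`
  quantifies why a 10.5% VAF variant callable at 1000× is missed at 45×
  with probability ≈ 0.135.
* **Risk.** Telomere maintenance (TMM) = *MYCN* amplification, *TERT*
  rearrangement, or *ATRX* alteration. TMM + a RAS/MAPK or p53/MDM2
  pathway hit → `ultra_high_risk`; TMM alone → `high_risk_tmm`; no TMM →
  `tmm_negative` (with an explicit caveat that ALT/telomerase expression
  are unassessed).
* **Simulator.** A generator emits reference FASTA, coordinate-sorted SAM
  and a JSON truth set with configurable depth, on-target fraction,
  fragment-size distribution, purity, CNV/SNV/SV truth — every caller is
  validated end to end against known ground truth.

See `vignettes/nbpanel-methods.Rmd` for the full model description and
design rationale.

## Worked example

Simulate a 300× tumor (purity 0.8) carrying a *MYCN* amplification
(CN 40), an *ALK* F1174L SNV (VAF 0.32) and a translocation 10 kb
upstream of *TERT*, then run the full pipeline:

```r
library(nbpanel)
panel <- example_panel()      # synthetic mini-panel: 4 genes, 30 tiles, 65 probes
contigs <- example_contigs()

cfg_tumor <- sim_config(
  contigs, panel, mean_depth = 300, seed = 42, purity = 0.8,
  cnv_truth = data.frame(chrom = "chr2s", start = 28000, end = 35000, cn = 40),
  snv_truth = data.frame(chrom = "chr2s", pos = 61174, ref = "C", alt = "A", vaf = 0.32),
  sv_truth  = data.frame(chrom_a = "chr5s", pos_a = 40000, chrom_b = "chr17s",
                         pos_b = 5000, type = "translocation", af = 0.4))
sim <- simulate_dataset(cfg_tumor, "sim_out")
reads <- read_alignments(sim$sam)

str(qc_summary(reads, panel))
#> List of 4
#>  $ n_unique_reads    : int 726422
#>  $ on_target_fraction: num 0.45
#>  $ mean_target_depth : num 565       # diploid 300x + the amplicon
#>  $ coverage_at_q     : int 267

bins <- make_bins(panel, 100)
controls <- lapply(1:3, function(s) {
  ctrl <- simulate_reads(sim_config(contigs, panel, mean_depth = 300, seed = s))
  depth_profile(as_alignment_table(ctrl$reads), panel)
})
model <- build_control_model(controls, bins)
ratios <- bin_ratios(depth_profile(reads, panel), model, bins)
cnv <- call_cnvs(ratios, purity = 0.8)
cnv[cnv$call, c("region", "direction", "category", "mean_ratio", "cn_estimate")]
#>   region direction      category mean_ratio cn_estimate
#> 6   MYCN      gain amplification   16.59557    40.98894

svs <- call_svs(reads, panel)
svs[, c("chrom_a", "pos_a", "chrom_b", "pos_b", "orientation",
        "n_discordant_pairs", "n_clipped_reads", "resolution", "annotation")]
#>   chrom_a pos_a chrom_b pos_b   orientation n_discordant_pairs n_clipped_reads
#> 1  chr17s  5000   chr5s 40000 translocation                138             106
#>   resolution    annotation
#> 1  base_pair tert_upstream

pileup <- pileup_table(sim$sam, sim$fasta, panel)
snvs <- flag_possible_germline(assign_snv_genes(annotate_hotspots(call_snvs(pileup)), panel))
snvs[, c("chrom", "pos", "alt", "depth", "vaf", "gene", "protein_change",
         "hotspot_tier1", "subclonal", "possible_germline")]
#>   chrom   pos alt depth       vaf gene protein_change hotspot_tier1
#> 1 chr2s 61174   A   305 0.2032787  ALK         F1174L          TRUE
#>   subclonal possible_germline
#> 1     FALSE             FALSE

profile <- tumor_profile("example_tumor", cnv_calls = cnv, sv_calls = svs,
                         snv_calls = snvs, purity = 0.8)
classify_risk(profile)
#> nb_risk_call [example_tumor]: ultra_high_risk (TMM: multiple; pathways: RAS_MAPK)
```

The planted CN-40 amplification is recovered as CN 40.99, the
translocation breakpoints exactly (base-pair resolution from 106 clipped
reads) and annotated as a *TERT*-upstream rearrangement, and the *ALK*
hotspot SNV at the purity-diluted VAF. Amplified *MYCN* plus the upstream
*TERT* rearrangement give two telomere-maintenance mechanisms; with the
*ALK* (RAS/MAPK pathway) mutation the sample classifies as
ultra-high-risk.

A thin CLI wraps the same functions (installed under `exec/`):
`nbpanel panel --bed panel.bed`, `nbpanel qc --bam s.bam --bed panel.bed`,
`nbpanel cnv --bam s.bam --controls c1.bam,c2.bam --bed panel.bed`,
`nbpanel sv-merge --window 500 --min-callers 2 a.vcf b.tsv`, etc.

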