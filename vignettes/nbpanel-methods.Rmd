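---
title: "Methods: targeted panel analysis for neuroblastoma risk stratification"
author: "nbpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted panel analysis for neuroblastoma risk stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbpanel)
```

# Scope and model

`nbpanel` implements the downstream analysis of a high-depth hybrid-capture
panel assay for neuroblastoma: copy-number calling from binned depth ratios
against diploid technical controls, rearrangement detection from discordant
read pairs with clipped-read breakpoint refinement, multi-caller
structural-variant consensus merging, tumor-only SNV calling with variant
allele fractions, and aggregation of marker calls into telomere-maintenance
status and an ultra-high-risk classification. The toolkit starts from
aligned reads (SAM/BAM); alignment itself is out of scope. A paired-end
alignment simulator generates reference, reads and machine-readable truth so
every caller is validated end to end without any external data.

The clinically interpreted markers are the canonical neuroblastoma set:
*MYCN* amplification, 1p36 and 11q loss, 17q gain, *TERT* rearrangement,
*ATRX* alteration (SNV or intragenic deletion), *ALK* and other pathway
mutations.

# Panel representation

A panel is a set of target regions with three classes: `gene_target`
(exon/gene capture footprints), `chromosomal_region` (tiles over 1p36, 11q,
17q used for arm-level copy-number assessment) and `reference_probe`
(probes spread over copy-neutral territory that anchor library-size
normalization). Coordinates are BED-convention 0-based half-open at every
I/O boundary and 1-based closed internally (the `IRanges` convention).
Overlapping records of the same class are merged on load; records that
merely touch stay separate. Each region is tiled into fixed-size analysis
bins (default 100 bp; the last bin of a region may be short). The default
bin size balances breakpoint resolution against per-bin counting noise at
the assay's working depth (~1000x: roughly 100,000 sequenced bases per bin).

The bundled `example_panel()` is a synthetic stand-in (4 marker genes,
30 chromosomal-region tiles, 65 reference probes on named synthetic
contigs); real assays supply their own BED and gene table.

# The synthetic-data generator

The simulator emits *pre-aligned* reads: positions and CIGAR strings are
computed analytically from the generative model, so no aligner is involved
and the truth is exact. It emulates:

* **Enrichment.** Fragment start positions are drawn uniformly over each
  target extended by one fragment length, at a rate of
  `mean_depth / (2 * read_length)` starts per base; this yields uniform
  expected depth `mean_depth` across the whole region, with the enrichment
  ramp falling in the flanks. Off-target read pairs are placed uniformly
  outside target+flank territory in exactly the number needed to realize
  the configured on-target fraction (default 0.45, the working range of
  hybrid-capture assays).
* **Fragment sizes.** Normal with mean 250 bp and sd 50 bp (read length
  100 bp), truncated at twice the read length. These are fixture choices
  representative of sheared FFPE/frozen libraries, not measured values.
* **Copy number.** Sampling over a truth interval of total copy number CN
  in a sample of purity p scales by `(p * CN + (1 - p) * 2) / 2` — the
  depth-ratio mixture the caller later inverts.
* **SNVs.** Alleles are decided per fragment (so mates agree) with alt
  probability `purity * vaf` under a copy-neutral model; `expected_vaf()`
  exposes this generative probability for parameter-recovery tests.
* **Rearrangements.** Each truth junction emits chimeric fragments at a
  rate proportional to physical junction coverage times the junction
  allele fraction. Reads falling across the junction get soft-clipped
  CIGARs (e.g. `70M30S`) whose clip coordinate is exactly the junction
  base; mates land on the partner locus, producing the discordant-pair
  signal. At least 20 aligned bases are required on each side of a
  junction read, mirroring aligner placement limits.
* **Nuisance parameters.** Optional uniform base-error rate (default 0,
  0.001 for specificity stress tests) and a configurable MAPQ-0 fraction
  to exercise the "uniquely aligned" filters. Base qualities are uniform
  (Q40): quality-dependent error structure is not modeled.

A fixed seed gives byte-identical FASTA/SAM/JSON output. What passing
tests on this generator do *not* show: robustness to GC-dependent coverage
waves, FFPE deamination artifacts, duplicate structure, repeat-induced
multi-mapping, or indel noise — all absent from the generative model by
design.

# Coverage QC

"Uniquely aligned" is operationalized as MAPQ >= 20 (configurable); the
on-target fraction counts reads (not pairs) overlapping any target by at
least one base. Depth counts aligned M/=/X bases only. The uniformity
statistic `coverage_at_fraction(profile, q)` returns the largest depth v
such that at least a fraction q of *target bases* reach v; the base-level
reading is the stricter of the two plausible interpretations (per-base vs
per-region) and is the one implemented.

# Copy-number calling

Each control profile is library-size normalized to the pooled median and
the per-bin expected depth is the across-control median — robust to a
stray contaminated control. The per-bin dispersion is the MAD-derived sd
floored at the Poisson prediction-error bound

$$\sigma_b = \sqrt{d_{exp}\left(1 + \frac{\pi}{2\,n_{controls}}\right)},$$

which accounts for counting noise in the future sample *plus* the sampling
error of a median estimated from `n_controls` noisy profiles (a median is
π/2 less efficient than a mean). With a bare `sqrt(d_exp)` floor the null
|z|>3 rate is ~1.5% per bin at typical control-cohort sizes; with the
prediction-error floor it is ~0.3%, which keeps the region-level false-call
rate at the documented <=1%.

A sample's bins are normalized onto the model scale by median-of-ratios
over the reference probes (when at least five are usable; otherwise all
unmasked bins), then `r = d_obs / d_exp` and `z = (d_obs - d_exp) / sigma`.
A gene or region is called only when *strictly more than half* of its bins
deviate at |z| > 3 in a common direction — the majority-of-bins rule;
significant bins split across both directions yield an explicit
`mixed_direction` no-call, and regions with fewer than 3 bins an
`insufficient_bins` no-call. Absolute copy number inverts the purity
mixture, `CN = (2r - 2(1 - p)) / p` (clipped at 0), with purity
user-supplied (default 1; purity inference is out of scope). Categories
follow diagnostic convention: amplification at CN >= 8 (>= 4-fold over
diploid, the *MYCN* convention), gain at CN >= 2.5, loss at CN <= 1.5,
deep loss at CN <= 0.5. Allele-specific copy number and copy-neutral LOH
are out of scope (they require SNP-level allele fractions the panel does
not provide).

# Rearrangement calling

The fragment-size model is fit robustly (median, MAD-scaled sd) from
proper inward-facing pairs; the discordance cutoff is `mean + 3 sd` — the
multiplier is a design choice, as only "larger than the expected fragment
size" is specified by the underlying method. A pair is discordant when its
mates map to different contigs, farther apart than the cutoff, or not
inward-facing. Discordant pairs cluster by single linkage (both ends
within 500 bp, orientations matching); clusters below 3 supporting pairs
are dropped. Breakpoints are refined by soft-clip voting: the plurality
clip coordinate within the cluster interval gives base-pair resolution;
without clips the cluster midpoints are reported at interval resolution.

Because a `mean + 3 sd` cutoff necessarily admits the extreme tail of
concordant fragments (~0.1–0.2% of pairs), small same-contig del/dup-like
clusters are indistinguishable from fragment-length noise. The caller
therefore drops same-contig del/dup-like calls whose refined span is below
`cutoff + window` (~0.9 kb at default settings); this is the deletion-size
detection limit, and it is the package's resolution of the open question
whether discordant pairs alone suffice for reporting. Translocations are
unaffected.

*TERT* rearrangements are classified by breakpoint position and never
conflated: inside the gene body (`tert_intragenic`, the fusion-type event)
versus within 25 kb 5' of the TSS (`tert_upstream`, the
regulatory-hijacking type). The window is configurable; 25 kb covers the
reported upstream rearrangement territory. *ATRX* partial deletions
require a contiguous internal run of >= 3 loss-significant bins flanked by
neutral bins; a co-located breakpoint upgrades confidence, and a
breakpoint without the depth signature yields a `breakpoint_only` record
(low tumor content can erase the depth signal while junction fragments
survive).

# Multi-caller consensus

`merge_sv_callsets()` implements the windowed collapse rule used for
whole-genome SV integration: calls whose two breakpoints both lie within
500 bp (single linkage, type-compatible) merge into one consensus call at
the per-side median position with the union of caller names; consensus
calls from fewer than 2 distinct callers are discarded. `window = 0` and
`min_callers = 1` reproduce the obvious limit behaviors. The merge is
invariant to caller and row order; tests verify equality against a
brute-force transitive-closure oracle on random call sets.

# SNV calling

The pileup counts M/=/X-aligned bases meeting MAPQ and base-quality
floors. File input goes through `Rsamtools::pileup()`; in-memory
simulated reads are counted directly from the alignment table (the two
paths are asserted identical in the tests). A site is reported when depth
>= 100, alt reads >= 10 and VAF >= 0.05 — thresholds chosen so a 10.5%
subclonal variant is comfortably callable at panel depth (~1000x) while
the same variant at exome depth (45x) is frequently missed; all are
configurable. Calls under 20% VAF are flagged subclonal. Tumor-only mode
is primary: VAFs in the 40–60% band or >= 90% raise a *possible germline*
flag, which never removes a call — hard germline filtering risks
discarding rare but relevant somatic events. `detection_probability()`
returns the upper binomial tail P(X >= k), X ~ Bin(c, f): the quantitative
argument for why high coverage matters for subclonal detection. Indels are
out of scope.

# Risk stratification

Telomere-maintenance mechanisms (TMM) are *MYCN* amplification, *TERT*
rearrangement (either breakpoint class, reported distinctly) and *ATRX*
alteration; one positive marker gives that status, several give
`multiple`, none gives `none`. Risk follows a pure truth table: TMM plus
at least one RAS/MAPK- or p53/MDM2-pathway hit (SNV or amplification of a
pathway gene) is `ultra_high_risk`; TMM alone is `high_risk_tmm`; no TMM
is `tmm_negative` — deliberately *not* asserted to be low-risk, because
alternative telomere lengthening and telomerase expression are not
assessable from panel DNA, and the report carries that caveat explicitly.
Germline-flagged SNVs are excluded from pathway counting by default
(overridable). The bundled pathway gene sets are documented working
stand-ins and user-overridable via TSV. FISH comparison utilities
aggregate subclonal per-ratio-class cell fractions by summation (e.g.
14% + 10% + 2% = 26% aberrant cells — below the detection limit of a bulk
depth ratio at moderate purity, which is why such cases appear
reference-only in concordance reports). Clinical covariates (stage, age,
histology) and survival modeling are out of scope.

# Numerical and design choices

* Ties in soft-clip voting break toward the smallest coordinate;
  cluster/consensus ordering is lexicographic, making every output
  deterministic.
* Region calls group bins by gene symbol or chromosomal-region label, so
  scattered tiles of 1p36/11q/17q are assessed jointly.
* `estimate_copy_number` is the exact inverse of the simulator's mixture
  model; parameter-recovery tests close that loop at CN 1–40 and purity
  0.5–1.
* Degenerate inputs fail loudly: empty BED, zero usable depth, mismatched
  bin sets, undefined on-target denominators and out-of-contig truth
  events all raise errors naming the problem.
* Problem sizes in the tests (5–10 kb panels at 500–1000x, 3–5 controls,
  300–500 SNV replicates) are chosen as the smallest sizes at which the
  binomial/Poisson expectations used by the assertions are sharp.

# Known limitations

* Purity is an input, not an estimate; at low purity the loss categories
  compress toward neutral (the caveat applies equally to the original
  assay design).
* The deletion-size detection limit (~0.9 kb at default fragment sizes)
  means small intragenic deletions rely on clipped-read evidence.
* The simulator's clean error model means specificity results are upper
  bounds for real FFPE libraries.
* Hotspot annotation is a positional lookup table, not a consequence
  predictor.
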