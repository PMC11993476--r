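---
title: "Nominating ADC targets and payloads from paired tumor/NAT proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nominating ADC targets and payloads from paired tumor/NAT proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adcscreen)
```

## The problem

Antibody–drug conjugates (ADCs) deliver a cytotoxic payload to tumor cells
through an antibody against a cell-surface antigen. A usable ADC target must
satisfy three criteria at once: it is strongly overexpressed in tumor
relative to matched normal tissue, it sits on the plasma membrane where an
antibody can reach it, and it is near-absent across the body's normal
tissues so the payload is not delivered systemically. `adcscreen`
operationalizes this screen as a reproducible pipeline over paired
tumor/normal-adjacent-tissue (NAT) protein abundance data, and adds the
downstream quantifications a preclinical ADC program needs: a
druggable-payload screen, antibody internalization kinetics, spatial
proximity statistics on multiplexed immunofluorescence (mIF) cell maps,
immune-deconvolution associations, and small clinical metrics.

## The nomination funnel

### Paired differential proteomics

For patient $i$ and protein $j$ with linear-scale abundances $T_{ij}$
(tumor) and $N_{ij}$ (NAT), the per-patient log fold change is

$$\mathrm{FC}_{ij} = \log_2 \frac{T_{ij} + \varepsilon}{N_{ij} + \varepsilon},$$

with pseudocount $\varepsilon$ (default 1 on the linear intensity scale —
negligible against label-free MS intensities of order $2^{20}$, but it keeps
zeros finite). Differential expression per protein is a two-sided paired
t-test on $\log_2(\cdot + \varepsilon)$ abundances; intensity-scale
proteomics is approximately log-normal, which makes the paired t on logs
the standard choice. Multiplicity is controlled by Benjamini–Hochberg
step-up q-values over all tested proteins. A pair is dropped protein-wise
when either member is missing; proteins with fewer than 3 complete pairs
are flagged untested and excluded from the BH family, so they neither gain
nor grant FDR. The reported summary `log2fc` is the across-patient *median*
of $\mathrm{FC}_{ij}$: robust, and aligned with the per-patient framing
used for specificity below. Proteins are ranked by q ascending with ties
broken by $|\mathrm{log2fc}|$ descending, then identifier — a total,
reproducible order.

The t-statistics are computed column-wise in closed form rather than in a
loop over `t.test()` calls; the unit tests verify the two agree to
`1e-12`, and a literal step-up implementation of BH (a double loop over
the sorted p-values) serves as the independent oracle for the q-values.

### Membrane filter and normal-tissue expression index

The top-$k$ upregulated proteins (default $k = 20$) are intersected with a
surfaceome catalog — one gene symbol per line, with optional alias
resolution, matched case-insensitively. Unknown aliases simply fail to
match; unknown *ordinal levels* in the tissue table, by contrast, are hard
errors, because silently scoring them 0 would deflate the index in the
candidate's favor.

Each surviving candidate is scored by its **normal-tissue expression
index**: over the table of (default) 41 normal tissues annotated at ordinal
levels, the sum of scores high = 3, medium = 2, low = 1, not detected = 0.
The index ranges from 0 (undetected everywhere — the ideal ADC target) to
$3 \times 41 = 123$ (high everywhere). It is invariant to tissue order and
is deliberately a plain sum: an interpretable, assumption-free summary of
how body-wide the antigen is.

### Specificity and the composite ranking

From the per-patient log2FC matrix, a candidate's tumor specificity is
summarized as its median log2FC across patients, plus — against each
established reference target (e.g. HER2, TROP2, CLDN18) — the fraction of
patients in which the candidate's log2FC *strictly* exceeds the
reference's. Ties do not credit the candidate.

Candidates are ranked by normal-tissue index ascending, ties broken by
specificity median descending, then identifier. The source study ranks
informally (the chosen target simply had the lowest index and the highest
specificity); making the composite order explicit — safety first, then
specificity — was an open design choice, and it is configurable in the
sense that all component scores are retained in the report for re-sorting.

### Payload screen

Upregulated DEPs (q below threshold, log2fc > 0) are intersected with a
drug–target catalog (union of sources such as GDSC, CTRP, and the Broad
Repurposing collection; provenance retained per record). Only targets with
at least one **approved or clinical-trial** drug qualify; preclinical-only
records are excluded. Because "how many druggable DEPs" can be counted as
proteins or as protein–drug pairs, the report carries both counts. The
top-10 ranking is by q ascending, ties by log2fc descending, then id.

## Downstream quantifications

### Internalization kinetics

An ADC only works if the antibody–antigen complex is endocytosed. From a
flow-cytometry time series of surface MFI, the internalization efficiency
at time $t$ is

$$E(t) = \left(1 - \frac{\mathrm{MFI}(t)}{\mathrm{MFI}(0)}\right) \times 100\%.$$

The empirical plateau is the final-time efficiency (the standard "after
4 h" reading with the default 0/30/60/120/240 min design); optionally a
monoexponential model $E(t) = 100\,p\,(1 - e^{-kt})$ is fitted by bounded
Levenberg–Marquardt least squares ($p \in [0,1]$, $k \ge 0$), with the
start value for $p$ taken from the empirical plateau. Negative
efficiencies are possible under noise and are *retained* (with a warning
below −5%) rather than clipped — clipping hides assay problems. Replicates
are averaged per time point before curve construction.

### Spatial proximity in mIF cell maps

Given per-cell coordinates and phenotype labels, the package counts
target-phenotype cells (e.g. CD138+ plasma cells) by distance band from
the nearest source-phenotype cell (e.g. CD66c+ tumor cells), with
half-open bands $[0,50), [50,100), [100,150), [150,200)$ µm. Design
choices, each of which some other convention could reasonably replace:

* **Nearest-source binning** — each target counted once, at its minimum
  distance to any source; avoids multi-counting near dense source regions.
* **Half-open bands** — a cell at exactly 50 µm falls in 50–100;
  deterministic and consistent with disjoint printed ranges.
* **No edge correction** — raw counts are reported, as in routine mIF
  practice; comparisons are between groups measured on equal fields, so
  edge bias largely cancels.
* **Conservation** — bin counts + beyond-range targets + co-labeled
  exclusions always equal the total target count; this is asserted in the
  tests, and counts are invariant under rigid motions of the coordinates.

Samples are dichotomized at the median of a per-sample variable (default:
the proportion of source-phenotype cells; an external H-score column can
be used instead): strictly above the median is "high", at or below is
"low". Group comparisons are two-sided Welch t or Mann–Whitney, with group
means reported.

### Immune associations and clinical metrics

Immune-cell fractions and scores are consumed from any deconvolution tool,
never computed: the module validates that fraction columns lie in [0, 1],
records the tool label, and associates each column with target expression
via the same median-split rule (shared code path with the spatial module)
plus Pearson *and* Spearman correlations — both reported, since the
appropriate type for this kind of data is genuinely ambiguous. Raw
two-sided p-values by default; BH adjustment behind a flag.

The clinical metrics are deliberately tiny, exact functions: the IHC
H-score $\sum_i i \cdot \mathrm{pct}_i$ over intensities 1–3 (0–300; the
standard histoscore, adopted because it is the field's default);
caliper tumor volume $0.5\,w^2 \ell$ with the squared term forced to the
smaller dimension by swapping; CIN classification as MSS **and** FGA ≥ 5%
(inclusive), with percent-scale FGA auto-detected (values > 1 divided by
100, with a warning) to avoid the 5-vs-0.05 trap; and mutation-prevalence
2×2 contingency with Haldane–Anscombe-corrected odds ratios and two-sided
Fisher exact p (cross-checked against an explicit hypergeometric tail
enumeration).

## The synthetic-data generators

Every input has a generator with planted ground truth, so each stage can
be tested for *recovery*, not just for running:

* **Proteomics** — per-protein baseline $\log_2$ intensity
  $\sim N(20, 2)$; tumor and NAT log2 abundances $\sim N(\text{baseline},
  0.5)$; 10 of 200 proteins get +2 log2 added to tumor samples of all 100
  pairs. Abundances are exponentiated to the linear scale. The planted
  best target is a DEP forced into the membrane set (sampled at fraction
  0.4), and the tissue generator forces it to a strictly minimal
  normal-tissue index.
* **mIF fields** — sources are a homogeneous Poisson process on a square
  field (1000 µm default, intensity 5×10⁻⁵/µm² ≈ 50 cells); targets are a
  Poisson process (4×10⁻⁴/µm² ≈ 400 candidates) thinned with retention
  $1 - a e^{-d_\min/\tau}$, the one-parameter smooth depletion law chosen
  for the "fewer plasma cells near tumor cells" phenotype ($a = 0.8$,
  $\tau = 50$ µm for the "high" group; $a = 0$, i.e. complete spatial
  randomness, for "low").
* **MFI series** — $\mathrm{MFI}(t) = \mathrm{MFI}_0 (1 - p(1 -
  e^{-kt}))(1 + \epsilon)$, $\epsilon \sim N(0, \mathrm{cv})$, noise-free
  at $t=0$; defaults $p = 0.4$, $k = 0.02/\mathrm{min}$, cv = 0.02.
* **Fraction tables** — a latent Gaussian correlated with expression at
  $r = -0.5$ is mapped through the normal CDF onto a plasma-cell fraction
  in [0, 0.2]; the monotone map attenuates the Pearson correlation only
  slightly (to ≈ −0.49 in expectation), well inside the ±0.15 recovery
  tolerance used in the tests.

Fixed seed and configuration give byte-identical output; each generator
draws from its own seeded stream (a fixed per-operation offset of the one
user seed), so adding a stage never perturbs another stage's data.

The parameter values above were chosen once as realistic for the field
(cohort-scale paired designs of ~100 patients, 2-fold-and-up effects on
MS intensities, ~40–50% internalization plateaus over 4 h, depletion
ranges on the order of one radial band) and are *not* tuned: the
statistical tests assert recovery under exactly these conditions.

**What the generators do not emulate:** missing-value structure of real MS
data (missingness is supported by the pipeline but not planted by
default), correlated proteins, batch effects, tissue-level correlation in
the ordinal table, cell-shape and segmentation error in mIF, and
saturation or compensation artifacts in flow cytometry. Passing tests
therefore demonstrate the *computational* correctness and calibration of
the pipeline under a clean generative model, not robustness to every
pathology of real data.

## Numerical choices and degenerate inputs

* Paired t with zero variance: all-zero differences give statistic 0,
  p = 1; nonzero mean with zero variance gives p = 0 (perfect separation).
* BH q-values are computed only over tested proteins; untested proteins
  carry NA and no rank.
* The internalization fit is bounded ($p \in [0,1]$, $k \ge 0$) and falls
  back to `fit = NULL` if the optimizer fails; the empirical plateau never
  depends on the fit.
* `compare_groups` with two constant groups reports the exact mean
  difference with `p_value = NA` and a degenerate flag rather than erroring.
* All composite sorts specify complete tie-break chains ending in the
  identifier, so every ranking is a deterministic total order.
* Median dichotomization sends values equal to the median to "low"; an
  all-constant vector labels everything "low" with a warning.

## Problem sizes in the test suite

The suite runs the oracle-equivalence checks at 1000 random p-vectors
(n ≤ 50) for BH, 50 seeds of 500-cell maps for radial binning, the FDR
calibration at 500 simulations of 30 pairs × 200 proteins, the CSR
annulus-area calibration at 200 fields against a uniform-sampling area
oracle, and the depletion power study at 100 repetitions of 30 fields per
group — sizes chosen to make Monte-Carlo error small relative to the
asserted tolerances while keeping a full run in a few minutes on one core.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(seed = 1, out_dir = "adcscreen_run")
res <- run_pipeline(cfg)
head(res$nomination)
res$payloads
```

The nomination report ranks the planted best target first (lowest
normal-tissue index, highest specificity median among membrane DEPs), the
payload table lists the planted druggable DEPs with their drugs and
phases, and `provenance.json` records the configuration, seed, versions,
and MD5 checksum of every artifact; rerunning with the same seed
reproduces all artifacts bit-identically.

## Known limitations

* The pipeline consumes abundance tables as given; normalization and batch
  correction of raw MS intensities are upstream concerns.
* The differential test is a paired t on logs; count-based or
  limma-moderated alternatives are not provided.
* Spatial statistics are 2-D, single-field, without edge correction or
  per-cell weighting.
* The tissue list of the normal-tissue index is user-supplied; the package
  imposes only the level vocabulary and the count (default 41).
* External-cohort validation (TCGA-style expression panels, single-cell
  atlases) is out of scope.
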