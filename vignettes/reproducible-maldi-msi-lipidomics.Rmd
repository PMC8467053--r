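---
title: "Reproducibility-filtered MALDI-MSI lipidomics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reproducibility-filtered MALDI-MSI lipidomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

MALDI mass spectrometry imaging (MSI) of formalin-fixed paraffin-embedded
(FFPE) tissue acquires one mass spectrum per ~50 µm pixel of a tissue
section. FFPE archives are the material with long-term clinical follow-up,
but lipid analysis in them is hard: formalin cross-links amine-bearing
lipids (phosphatidylethanolamines, phosphatidylserines), and sample
preparation — deparaffinization, antigen retrieval, matrix spraying — makes
the measurement sensitive to day-to-day variation. Before any biology can be
read off such data, two questions must be answered per m/z feature: *is it
reproducible across technical replicates?* and *is it tissue-derived rather
than MALDI-matrix-derived?*

`lipidmsi` implements an analysis workflow for a treated-versus-control
xenograft design: 8 biological samples (4 dosed with a glutaminase
inhibitor, 4 control) × 3 technical replicate sections, each replicate
measured on a different day, positive-mode spectra on m/z 500–1300. Because
no raw data of this kind are publicly deposited, the package ships a
ground-truthed synthetic study generator, so every stage is exercised end to
end and scored against a known truth.

## Pipeline model, stage by stage

**TIC normalization.** Each pixel spectrum is scaled by (dataset-mean TIC /
pixel TIC). The target is the dataset-mean TIC rather than 1, so normalized
intensities stay on a count-like scale; this makes the master-list gate
"mean intensity > 1" meaningful. Zero-TIC pixels are left untouched and
flagged. Note a structural property of TIC normalization: if a large share
of total signal changes between two regions, the normalization compresses
the measured fold change. In real MALDI-TOF data the TIC is dominated by
matrix-derived chemical background, so the compression is small; the
generator reproduces that regime (see below).

**Peak picking.** ROI mean spectra (tumor, necrosis per section) are
baseline-corrected (rolling minimum over 5 Da, smoothed by a rolling mean of
the same width, clipped at 0), optionally Savitzky–Golay smoothed (0.5 Da
window, order 2), and local maxima are kept when S/N ≥ 10, absolute
intensity ≥ 0.14, and relative intensity ≥ 0 × base peak. Noise is the
median absolute deviation in a sliding 10 Da window × 1.4826 — robust to the
peaks themselves. The centroid is the intensity-weighted mean over the
apex's FWHM support ("picking height 100" is read as centroiding at the
apex; the original tool's exact semantics are not recoverable). Shoulder
maxima inside the FWHM support of a larger accepted peak are removed.

**Mass merging.** m/z values within 220 ppm are treated as one mass.
Implementation: pool and sort all values, break between neighbours whose gap
exceeds 220 ppm of the smaller value. This single-linkage gap rule is
deterministic, order-free, and provably equal to the transitive closure of
all pairwise within-window relations (tested against a union-find oracle).
A cluster can chain beyond 220 ppm end to end; the realized span is
recorded.

**Reproducibility gates.** Per biological sample: a mass must appear in the
tumor (or necrosis) mean spectrum of *all three* technical replicates; its
per-replicate intensity CV (100·SD/mean, n−1 denominator) must be < 45%
(strict). A third list keeps masses present in both regions in all
replicates whose per-replicate log2(tumor/necrosis) has CV < 60%. The three
lists are unioned with ppm dedup.

**Matrix, isotope and detectability filters.** A candidate is
matrix-derived if the ROC AUC of its pixel intensities, with off-tissue as
positive class (Mann–Whitney rank formulation, ties ½), exceeds 0.9 *and*
its off-tissue mean exceeds its on-tissue mean. +1 isotopes (Δ = 1.00335 Da
within 220 ppm, smaller intensity than a retained lower mass, ascending
scan) are removed. The original workflow's visual "low-quality signal"
screen is automated as a detection-frequency rule: a mass detectable
(intensity > 1) in fewer than 1% of tissue pixels is dropped. One shared
filter configuration is used for the per-sample pass and the final
master-list re-check, since nothing suggests different thresholds were used.

**Master list.** Masses surviving per-sample filtering in ≥ 2 biological
samples (inclusive) with overall mean TIC-normalized intensity > 1 (strict),
after a final isotope re-check; ordered by m/z and invariant to input
permutation.

**Reproducibility metrics.** Whole-dataset CV: per mass, sections measured
on one day are averaged into a day-level dataset mean; the CV across the
three day-level means is reported as mean ± SD over masses. The
prose description of this aggregation is ambiguous in the source workflow;
the implementation follows the reading that yields exactly one CV per mass,
which is how the reference master list tabulates it. Intraday/interday CVs
use three replicate sections of one biological sample measured on the
same/different days.

**Tumor vs necrosis.** MSI pixels are spatially autocorrelated, so a naive
per-pixel test overstates n. The workflow's counter: per technical
replicate, draw 1% of tumor/necrosis pixels (stratified per section ×
region, minimum 1), fit intensity ~ region with a random intercept per
biological sample by REML (`nlme`, as in the original analysis), repeat 100
times, BH-adjust within each iteration across masses, and report the
mean and range of log2FC and adjusted p. log2FC is computed from the drawn
pixels' region means, not from the regression coefficient — the two
quantities are deliberately separate. Singular fits fall back to OLS with a
flag. A mass is significant with |mean log2FC| > 0.5 and mean adjusted
p < 0.05 in ≥ 2 of 3 replicates with consistent sign.

**Treated vs control.** Three parallel views: (i) Wilcoxon rank-sum on
section tumor mean intensities, 4 vs 4 per technical replicate (exact for
n ≤ 10 without ties), significant at p < 0.05 in ≥ 2 of 3 replicates;
(ii) pixel-level ROC on equally sized subsets of up to 15,000 tumor spectra
per arm — the "per biological replicate" AUC construction is
under-specified in the source, and is implemented as: each sample's tumor
pixels scored against *all* opposite-arm tumor pixels, per technical
replicate, with the criterion AUC ≥ 0.7 in ≥ 2/3 of the sample's replicates
for ≥ 3/4 samples of an arm (denominators scale proportionally when
sections are missing); (iii) PCA of section tumor mean spectra
(mean-centered, SVD, sign fixed so the largest-magnitude loading is
positive). A mass is a marker if either the Wilcoxon or the AUC criterion
holds — the two criteria are parallel significance routes, which matches a
reported borderline case (Wilcoxon p = 0.06 but AUC 0.87) being retained.

**Lipid annotation.** Putative identification by accurate mass only:
monoisotopic masses from IUPAC most-abundant-isotope values, cation adducts
[M+H]+, [M+Na]+, [M+H−H2O]+ with the electron mass subtracted (0.55 mDa ≈
0.7 ppm at m/z 800 — without it the sub-ppm tier is unreachable), candidates
ranked by |ppm| within a 10 ppm tolerance, tiers: sub_ppm (< 1), loose
(8–10), within_10. The bundled table holds the species the reference master
list reports plus ~250 even-chain glycerophospholipid/sphingomyelin decoys;
no live database queries, so results are reproducible offline. One table
entry ("PI 20:1") matches its reported accurate mass only under the
lyso-species formula; the table uses that formula under the reported name
and says so in its `note` column.

## The synthetic study generator

Each section renders every planted peak as a Gaussian (FWHM 0.3 Da) on the
0.1 Da axis. The apex amplitude of peak *l* in pixel *p* is

    base_l · 2^(tn_l·[tumor]) · 2^(arm_l·[treated]) · day_(l,d) · jitter_(l,s) · eps_(l,p)

with lognormal day effects (CV 0.25) shared by all sections measured the
same day, lognormal per-section jitter (CV 0.15), and lognormal pixel noise
(CV 0.4) whose log is a Gaussian random field with correlation length 2
pixels (Gaussian-filtered white noise — cheap, and it creates exactly the
spatial autocorrelation the subsampled LMM is designed to blunt). All
lognormals have mean 1, so planted fold changes are unbiased. Regions are
contiguous: an elliptical tissue mask (≈ 55% of the 40 × 40 grid), a
necrosis disc (≈ 35% of tissue) at a random interior position, and excluded
boundary pixels between the two, mirroring the exclusion of mixed areas at
annotation. Matrix peaks are amplified 10× off-tissue; lipids are absent
off-tissue. +1 isotopes (ratio 0.35) co-vary *perfectly* with their parent
pixel for pixel — isotope intensities are physically proportional to the
parent, and modeling them with independent noise would break the premise of
the isotope filter. Per-section calibration shifts are uniform in ±75 ppm,
so the spread across sections stays within the 220 ppm merge window.
Half-normal background noise (SD 1.5 per bin) makes total background
dominate total lipid signal, as matrix chemical noise does in positive-mode
MALDI-TOF.

Defaults: 26 true lipids (6 tumor-up at log2FC +1.0, 2 necrosis-up at −0.6;
3 treated-up at +0.5, 1 control-up at −0.8), 5 matrix peaks, base
intensities lognormal(log 30, 0.8). The differential structure mirrors the
reference study's master-list scale; the noise scales were chosen once so
the resulting whole-dataset (~23%), interday (~25–30%) and intraday (~15%)
CVs land in the regime the reference workflow reports, and were not revisited.

What the generator does *not* emulate: ionization suppression, isotope fine
structure, peak-shape tailing, spatial drift of calibration within a
section, and biological within-region heterogeneity beyond the stationary
noise field. Passing tests therefore demonstrate that the pipeline's logic
and statistics behave as specified under a realistic noise budget — not that
the pipeline is robust to every artifact of real instruments.

## Numerical choices and degenerate inputs

- Windowed ion intensities (pixel tables, mean-spectrum lookups) integrate
  ±0.4 Da around a mass and subtract a local baseline estimated as the
  median of sideband bins at ±(0.45–0.75) Da, scaled to the window width.
  The sidebands sit inside ±0.75 Da so the +1 isotope never contaminates
  them. Without this subtraction, additive background inside the window
  compresses measured fold changes toward zero.
- Boundary semantics are literal: CV gates strict `<`, matrix AUC strict
  `>`, "at least two biological replicates" inclusive `>=`, mean intensity
  strict `>`, marker AUC inclusive `>=`.
- A noiseless-generator identity check (planted log2FC recovered exactly)
  is run on the raw extraction path: with a single planted lipid, TIC
  normalization cancels the region effect *by construction*, so the
  normalized path cannot reproduce it exactly; this is a property of TIC
  normalization, not a defect of the generator.
- Zero necrosis intensity in any replicate excludes a mass from the log2FC
  gate (logged); zero region means inside an LMM iteration skip that
  iteration's fold change (counted); a zero mean makes a CV undefined
  (`NA` with a warning); empty spectra yield empty peak lists; an ROI label
  outside the closed set is an error naming the offending row.
- Randomness: one master seed fans out per (stage, replicate, iteration)
  through a counter-based multiplicative scheme (`derive_seed`), so results
  are reproducible and independent of execution order, and derived seeds
  stay below 2^31.
- LMM uses REML (the estimator of the named implementation's default);
  fits are on TIC-normalized intensities untransformed; log2FC inside an
  iteration uses the drawn pixels' region means.

## Problem sizes

The analysis scripts and the acceptance checks run the full default study:
24 sections of 40 × 40 pixels, 8001-bin spectra, 100 LMM iterations × 3
replicates × master masses. Sections are streamed — regenerated from the
seed on demand and reduced to mean spectra and pixel tables — rather than
held in memory as 24 dense matrices. Unit tests use reduced studies (16 × 16
grids, 8 lipids) chosen to exercise every code path at interactive speed;
the multi-seed checks use 5 seeds (fold-change recovery), 10 seeds
(interday vs intraday ordering, sign test) and 1000 simulations (LMM type-I
error).

## Known limitations

- Peak centroids on the 0.1 Da axis carry ~0.02 Da quantization error
  (~25 ppm at m/z 800) — harmless under a 220 ppm merge window, but this
  implementation is not a recalibration tool.
- The chained single-linkage merge can, in principle, fuse two distinct
  lipids closer than ~0.16 Da at m/z 700; the generator plants lipids ≥ 5 Da
  apart, and real TOF master lists at this resolution face the same limit.
- Annotation is by accurate mass alone: isobaric species within tolerance
  are returned as ranked candidates, never resolved (no MS/MS scoring).
- The AUC marker criterion's per-sample construction is one defensible
  reading of an under-specified rule; alternatives (e.g. sample-vs-sample
  AUCs) would change borderline calls.
- Batch-effect correction is out of scope: day effects are measured (CV
  reports), not removed.
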