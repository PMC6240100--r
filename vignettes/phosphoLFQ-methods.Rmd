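---
title: "Methods: XIC-based label-free phosphopeptide quantification and differential regulation"
author: "phosphoLFQ"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: XIC-based label-free quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphoLFQ)
```

# Overview

phosphoLFQ quantifies identified phosphopeptides across label-free LC-MS
runs from their MS1 signal and tests their regulation between condition
groups. The pipeline has four stages, run in this fixed order:

1. **XIC quantification** (`quantifyAll()`): for every peptide species and
   every run, sum centroid intensities per MS1 scan inside a ±7 ppm
   window around the peptide m/z, restricted to scans within ±2 min of
   the peptide's reference retention time, and integrate the resulting
   trace by the trapezoidal rule. Every peptide gets a value in every
   run; absence of signal is intensity 0 (match-between-runs zero-fill),
   so the peptide × run matrix is complete.
2. **Technical-replicate averaging** (`averageTechnicalReplicates()`):
   arithmetic mean of each sample's replicate runs.
3. **Total-intensity normalization** (`normalizeTotalIntensity()`): each
   sample column divided by its own total, rescaled by the mean of the
   original column totals.
4. **Differential statistics** (`diffPhos()`): per-peptide pooled-variance
   two-sided Student's t test between a control and a comparison group,
   log2 fold changes with a matrix-wide pseudo-intensity, and the
   two-tier volcano classification (P < 0.05 / P < 0.01 with a
   |log2 FC| > 0.8 gate), plus Venn partitioning of up/down calls and
   fold-change heatmaps across comparisons.

A synthetic study generator (`generateStudy()`) produces runs with known
ground truth so the full chain is verifiable; phosphosite-assignment
confidence is annotated as delta scores over positional isoforms
(`deltaScore()`, `enumerateSiteIsoforms()`).

# The quantification model and its assumptions

The XIC model assumes centroided MS1 spectra, a mass accuracy well
inside the ppm window, and chromatographic peaks that elute within the
retention-time window of a per-peptide reference time. Three choices in
the extraction were genuinely open and are fixed as follows:

* **Sum, not apex, per scan.** The per-scan window intensity is the sum
  of all matching centroids. Summing is robust to centroid splitting and
  makes the trace — and therefore the area — exactly linear in the
  underlying signal, a property the test suite exercises directly.
* **Reference retention time = median of observed identification RTs.**
  Cross-run quantification needs an RT anchor for runs where the peptide
  was not identified. The median over the runs where it *was* identified
  is robust to a single aberrant identification and reduces to the
  observed RT when there is only one.
* **Peptide species are (sequence, phosphosite set, charge).** Charge
  states have distinct m/z targets and are quantified as distinct rows;
  no charge-state merging is attempted.

Numerical rules: integration is trapezoidal on retention time in
minutes; a trace with fewer than two points has zero width and
integrates to 0; no intensity floor is applied before integration, so
zeros arise only from genuinely absent signal. Window lookups use
`findInterval()` on the per-run m/z-sorted centroid list — a binary
search whose results are identical to a linear scan, which is what the
linearity and monotonicity property tests would expose if it were not.

# Normalization and the replicate mean

Zero-filled (undetected) values participate in the technical-replicate
mean as true zeros: the zero is a measurement under the zero-fill rule,
and no exclusion rule is part of the method. Averaging precedes
normalization, and the package enforces that order through the `level`
state of the quantification object (`run` → `sample` → `normalized`).

"Normalized to total sample intensity" fixes only the ratio structure of
each column; the absolute scale is a free choice. The package rescales
by the mean of the original column totals so intensities stay on a
familiar scale. Consequently, scaling one sample's column changes the
global rescale constant but not the normalized ratio structure — the
invariant that matters for every downstream fold change and t test, and
the one the tests assert. After normalization all column sums are equal
(to within 1e-10 relative).

# Differential statistics

The test is the classical pooled-variance two-sided Student's t test
(not Welch), on n_A + n_B − 2 degrees of freedom; the package applies it
as stated, without multiple-testing correction, because the significance
call is the joint volcano rule — a raw-P tier *and* a fold-change
gate — rather than a P-value cutoff alone. Degenerate inputs are
resolved deterministically: two constant equal groups give t = 0,
p = 1; two constant unequal groups give an infinite statistic and the
smallest representable positive p, flagged in a `degenerate` column
rather than erroring, so one pathological peptide cannot abort a
screen-wide analysis.

Fold changes use a matrix-wide pseudo-intensity ε = half the smallest
positive value in the matrix: `log2(mean_B + ε) − log2(mean_A + ε)`.
This keeps zero-filled peptides finite, is deterministic, and scales
with the data. A peptide that is zero in both groups has fold change 0
and is flagged. The fold-change threshold of 0.8 is interpreted on the
log2 axis (|log₂ FC| > 0.8, i.e. a ≈1.74-fold change); the convention is
exposed as the `fcThreshold` argument, so a user preferring a linear
1.8-ratio gate can pass `log2(1.8)` explicitly.

Venn partitions are computed separately for up- and downregulated calls
across the 2–3 group comparisons, with region counts that always sum to
the union; the heatmap view reports, per peptide, the mean fold change
of the mutant group over control in each comparison.

# The synthetic study generator

`generateStudy()` emulates the structure of a two-genotype endothelial
phosphoproteomics screen: 2 genotypes × 3 treatment arms (vehicle 24 h,
4-OHT 24 h, 4-OHT 96 h) × 4 biological replicates = 24 samples, each
acquired as 2 technical runs (48 runs), MS1 scans every 2.1 s over
m/z 375–1500, and chromatographic peaks of 30 s at base — which at that
duty cycle guarantees at least 10 data points per peak. The elution
profile is Gaussian with the base interpreted as 4σ (σ = 7.5 s for a
30 s base), chosen because its closed-form area (amplitude · σ · √2π)
provides an independent oracle for the trapezoidal integrator. Each
peptide is a single monoisotopic centroid: the extraction operates on
one target m/z, so isotope envelopes would add realism without adding
testable behaviour.

Tunable truth parameters (all exposed via `truthParams()`):

| parameter | default | meaning |
|---|---|---|
| `nPeptides` | 500 | population size; 500 keeps a full-spectra study in seconds at the 20 min default gradient |
| `fracRegulated` | 0.1 | fraction with a true genotype effect |
| `effectLog2fc` | 2 | injected \|log2 FC\|, sign drawn per peptide |
| `biologicalCV` | 0.2 | log-normal CV across biological replicates |
| `technicalCV` | 0.05 | log-normal CV across technical runs |
| `dropoutProb` | 0.05 | per-(peptide, run) Bernoulli absence |
| `peakBaseWidthS` | 30 s | peak width at base (4σ) |
| `mzErrorPpmSd` | 1.5 ppm | per-(peptide, run) mass error; ±7 ppm ≈ 4.7σ, so windows rarely clip true signal |
| `rtJitterMinSd` | 0.15 min | per-(peptide, run) RT error, well inside ±2 min |
| `backgroundPeaksPerScan` | 5 | uniform background centroids per scan, intensities ≤ 1e4 against peptide apexes of ~1e7 |

The biological and technical CVs and the dropout rate are
implementer-chosen (no published per-condition variance exists for this
design); 20% biological and 5% technical multiplicative variation with
5% missingness are typical of replicated label-free phosphoproteomics
at this depth, and all three are configuration-exposed rather than
baked in. Base abundances are log-normal (meanlog = log 1e6,
sdlog = 1), giving the 2–3 orders of magnitude of dynamic range the
zero-fill and ε rules must survive.

Determinism: a master stream seeded by the user draws the peptide
population, the truth, and one sub-seed per run; each run's noise comes
from its own sub-stream. Identical seeds therefore give bit-identical
studies, and per-run noise does not shift when the number of peptides
upstream changes the master stream's consumption pattern within a run.

**What the generator does not emulate** — and what passing tests
therefore do not show about real data: isotope and charge-state
envelopes, MS/MS acquisition, retention-time nonlinearity or drift
between runs (so no RT alignment is needed or implemented),
intensity-dependent missingness (dropout is uniform Bernoulli, whereas
real missingness is censoring-like and biased toward low abundance),
interference from co-eluting near-isobaric peptides, and search-engine
identification errors (identifications are taken as given, as the
pipeline consumes them). Results on synthetic data validate the
*arithmetic* of the pipeline, not the biological fidelity of any one
real acquisition.

# Validation design and problem sizes

The package validates itself at three levels, with sizes chosen to keep
the whole suite in tens of seconds:

* **Oracle tests**: trapezoidal XIC areas against the closed-form
  Gaussian integral (within 2%, dominated by the 4σ truncation of the
  simulated peak, which carries 99.994% of the mass); the pooled t
  against `stats::t.test(var.equal = TRUE)` and against a brute-force
  sums-based implementation of the formula (1e-10 in t).
* **Recovery**: a noiseless study must reproduce ground-truth areas with
  R² > 0.999 and zeros exactly where presence is false; a default-noise
  500-peptide study pushed through the full pipeline must recover the
  injected |log2 FC| = 2 effects with ≥ 90% sensitivity, < 2% false
  positives, and a mean recovered effect within ±0.15.
* **Calibration**: on a 2000-peptide null study (no regulated peptides,
  4 vs 4 samples) the fraction of P < 0.05 must fall in the exact
  binomial 99% interval around 0.05. This calibration study is simulated
  at the abundance level (`spectra = FALSE`), which yields exactly the
  run-level areas an ideal extractor would recover; the spectra path is
  already covered by the recovery study, and 2000 peptides × 48 runs of
  raw scans would add minutes without adding information.

# Known limitations

* No retention-time alignment: runs are assumed co-registered to within
  the ±2 min window, which holds for the simulated jitter but not for
  long multi-batch acquisitions.
* The ε rule makes fold changes of fully-absent peptides finite but
  compresses them toward 0 when intensities are near the matrix minimum;
  such peptides carry a `degenerate`/zero flag and deserve inspection.
* Delta scores are computed from search-engine isoform scores supplied
  in the identification table; the package enumerates isoforms and
  differences scores but does not re-score spectra. A peptide whose only
  isoform is unambiguous reports its own score as delta by convention
  (configurable to `NA`).
* The pooled t test assumes approximately equal group variances;
  with the default generator both groups share the same CV, so this is
  exact in simulation and an approximation on real data.
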