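---
title: "Methods and design of the seedcycle analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the seedcycle analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedcycle)
```

# Scope

`seedcycle` implements the desk-side computations of a seed-priming
multi-omics study design: seeds go through a rehydration–dehydration cycle
(hydropriming, dry-back, post-priming imbibition, with unprimed imbibition
as control), and each physiological state is profiled by label-free
quantitative (LFQ) proteomics, germination tests, the alkaline comet
assay, and qRT-PCR. The package starts from the search engine's
protein-group intensity table and from count/curve tables; it does not
touch spectra, images, or primer design.

A synthetic-data module generates every input with the statistical
structure the analysis assumes, so the whole pipeline is testable without
any external download. The generators define the study conditions the
tests exercise; they are not tuning knobs.

# Differential protein abundance

## Filtering

For a pairwise comparison of two conditions with five replicates each, a
protein group is retained when it is supported by at least two peptides
and has at most four missing values across the ten samples. A protein
completely absent from one condition but fully quantified in the other is
*also* retained: these are the "detected only in one condition" proteins,
which are biologically the most drastic changes and receive a pseudo fold
change below. (Without this clause the missing-value cap would silently
discard exactly the proteins the condition-unique tally is meant to
count; a condition-absent protein with a complete other condition has
five missing values, which is the per-protein cap the comparison tables
use.)

## Normalization: modified robust z-score

Present intensities are log2-transformed. Per sample, values are
standardized robustly, \((x - \mathrm{median}) / (1.4826\,\mathrm{MAD})\),
with the 1.4826 factor making the MAD a consistent estimator of a normal
standard deviation. The "modified" step rescales every sample's z-scores
by the grand median and grand robust scale of the pooled log2 data, so
values remain interpretable as log2 intensities and every sample's median
equals the grand median. A sample with zero MAD (possible with heavy
ties) falls back to an IQR-based scale; if that is also zero the sample
is centered only and a warning is emitted. Missing values stay missing —
no imputation is performed at the intensity level.

Robust location/scale estimation assumes a mostly-null proteome: if a
large fraction of proteins (tens of percent) shifts in one condition,
that condition's scale estimate inflates and effect sizes compress. Power
simulations in the test suite therefore use a 10% differential fraction,
which is already generous for real experiments.

## Testing, fold changes, pseudo fold changes

Each retained protein with at least two quantified replicates per
condition is tested with the classical two-sample *t*-test with pooled
variance (df \(= n_1 + n_2 - 2\)) on normalized log2 values; the
statistic is oriented second-condition-minus-first so its sign agrees
with the fold change. Fold changes are computed on the raw-intensity
scale as the difference of mean log2 intensities, following the
convention that the *second* condition of a pairwise comparison is
divided by the *first*.

When a protein is completely unquantified in one condition, its missing
group average is replaced by the log2 of the mean of the 10% smallest
per-protein condition-mean intensities among proteins quantified in that
condition (at least one protein; `ceiling(0.1 m)` of `m` quantified
proteins). This *pseudo fold change* is a detection-limit-style surrogate:
it says "at least this much", grows with the abundance of the detected
condition, and is flagged so downstream consumers never confuse it with a
measured ratio. Pseudo-fold-change proteins are not *t*-tested (one group
has no data).

P-values are adjusted by Benjamini–Hochberg step-up (the adjustment
procedure is configurable in principle but BH is the proteome-wide
default). Significance classes at adjusted *p* < 0.05 and |log2 FC| ≥ 1:
`accumulated` (up in the second condition), `depleted` (up in the first),
`only_in_second` / `only_in_first` (pseudo fold change of sufficient
magnitude), otherwise `not_significant`; proteins with insufficient data
are reported unclassified (`NA`).

Two choices here are deliberately conservative defaults rather than the
only defensible ones: testing on normalized values with fold changes on
raw log2 means (the scales are not forced to agree), and `max_missing = 4`
(the per-comparison wording) with the condition-absent clause reproducing
the per-protein cap of 5. Both are parameters.

# Preranked gene-set enrichment

Proteins are ranked by their comparison *t*-statistic and a gene set's
enrichment score (ES) is the classic weighted Kolmogorov–Smirnov
running-sum extremum: members increment the sum by
\(|s|^w / \sum_{hits} |s|^w\) (weight exponent \(w = 1\) by default),
non-members decrement by \(1/(N - n_{hits})\); ES ∈ [−1, 1]. Ties in the
ranking keep stable input order. When the positive and negative extrema
tie exactly in magnitude the reported sign follows the first extremum of
maximal magnitude.

The null distribution is built from `n_perm` random member sets of equal
size. NES divides the observed ES by the mean |ES| of same-sign null
scores; the permutation p-value is one-tailed within the same-sign null,
\(p = (1 + \#\{|ES_{null}| \ge |ES|, \text{same sign}\}) /
(1 + \#\{\text{same sign}\})\). Conditioning the denominator on the
same-sign count (the standard convention) is what makes null p-values
uniform, a property the test suite checks by Kolmogorov–Smirnov;
normalizing by `n_perm` instead would bound p at ~0.5. p ≥ 1/(n_perm+1)
always; a degenerate null yields NES `NA`, p = 1. Simple set-permutation
is implemented (not the adaptive multilevel variant); with the default
1000 permutations the smallest attainable p is about 0.001, which is
adequate for the heatmap-style summaries the pipeline produces. Gene-set
size bounds default to 5–500 members present in the ranking.

A discrete-selection counterpart (hypergeometric over-representation of
significant proteins against the quantified background, BH-adjusted) is
provided for gene-ontology-style term enrichment of the
significant-protein lists.

# Germination indices

From per-replicate counts of newly germinated seeds \(n_i\) at times
\(t_i\) (interval endpoints; \(\Sigma n_i \le\) seeds sown):

* germinability \(G = 100\,\Sigma n_i / n_{seeds}\);
* mean germination time \(MGT = \Sigma n_i t_i / \Sigma n_i\);
* mean germination rate \(MGR = 1/MGT\) and coefficient of velocity
  \(CVG = 100/MGT\);
* uncertainty \(U = -\Sigma f_i \log_2 f_i\) (bits; entropy of the
  germination-time distribution);
* synchrony \(Z = \Sigma \binom{n_i}{2} / \binom{\Sigma n_i}{2}\)
  (probability two random germinated seeds share an interval);
* \(T_{50}\): the time the cumulative curve reaches half its *final*
  value, linearly interpolated between bracketing observations (boundary
  flagged if half is already reached at the first observation).

Indices are computed per replicate and then averaged. This is not
cosmetic: group \(CVG \ne 100 / \overline{MGT}\) because of the Jensen
gap, and published index tables are only internally consistent under
replicate-level averaging. Group comparisons use the two-tailed
heteroscedastic (Welch) *t*-test with significance stars at
0.05/0.01/0.001, and treatment effects are summarized as signed percent
change versus the reference group, \(100\,(x - x_{ref})/x_{ref}\).

# Comet assay

Nucleoids are visually classified upstream into damage classes 0–4; the
slide score in arbitrary units is
\(\mathrm{a.u.} = 100\,\Sigma (N_c \cdot c) / N_{tot} \in [0, 400]\).
The per-slide score is the replicate unit (100 nucleoids per slide is the
scoring convention of the emulated protocol, not enforced); groups are
compared by Welch's *t*-test. The score is linear in class proportions,
so the expected score of a multinomial slide is \(100\,\Sigma p_c c\), a
closed form the simulation tests verify.

# qPCR quantification

## Efficiency and Ct from raw curves

Per reaction, the exponential phase is found on the background-subtracted
curve as a *window of linearity*: cycles with fluorescence between a
noise floor (1% of the curve maximum) and the plateau band (90% of
maximum — at realistic noise levels that bound keeps many noise standard
deviations away from saturation) are candidates; starting from the
longest contiguous window and shrinking only if linearity fails, the
algorithm fits log2 fluorescence against cycle by least squares weighted
with \(F^2\) — the inverse variance of \(\log F\) when instrument noise
is additive — and accepts the longest window whose weighted r² reaches
0.99 (otherwise the best-fitting window is used and the result flagged
low-quality). The slope \(b\) gives the per-cycle efficiency
\(E = 2^{b}\); the threshold cycle is the fractional cycle where the
fitted line crosses 20% of the curve maximum. Flat curves are rejected.

Noiseless synthetic curves are recovered exactly. With additive noise at
1% of the plateau the eligible log-linear window of a single curve is
only ~5–7 cycles, and recovery within ~5% is what a single curve supports;
at the package's default noise level (0.2% of plateau) recovery is within
2%. Efficiencies entering quantification are per-assay means across a
gene's reactions (per-reaction values are available in the QC table).

## Relative expression

The efficiency-corrected expression ratio follows the Pfaffl model,
\(E_t^{\Delta Ct_t} / E_{ref}^{\Delta Ct_{ref}}\) with
\(\Delta Ct = Ct_{control} - Ct_{sample}\) (induction ⇒ ratio > 1); with
both efficiencies 2 this reduces to \(2^{-\Delta\Delta Ct}\). Multiple
reference genes are combined by geometric mean, the standard
multi-reference convention. Per transition, per-replicate ratios of the
second condition against the first condition's mean Ct are combined
geometrically, so the reported log2 fold change is exactly antisymmetric
under transition reversal; replicate log-ratios of the two conditions are
compared by Welch's *t*-test.

# Cross-layer integration

Transcript and protein log2 fold changes are joined per gene × transition;
pairs with an absent value on either layer (e.g. a protein without
quantification in a transition) are excluded pairwise and the exclusion
count reported. Agreement is summarized by the sample Pearson correlation
with a two-sided *t*-based p-value, and — because published practice for
such comparisons sometimes uses a median-based procedure instead — by the
Mann–Whitney U comparison of the two layers' fold-change distributions.
Both are reported side by side. The Mann–Whitney p is exact (full
enumeration of group assignments, ties included) for samples up to 8 per
group and uses the tie-corrected normal approximation above that.

# The synthetic-data generators

* **Proteome**: intensities \(2^{baseline + effect + N(0, sd)}\) with
  baseline log2 = 20 (≈10⁶, a typical LFQ magnitude) and replicate sd 0.5;
  sporadic missingness is missing-completely-at-random at a configurable
  rate, plus explicit condition-wise absence for selected proteins.
  Real LFQ missingness is partly intensity-dependent; MCAR is the minimal
  assumption under which the filtering and pseudo-fold-change rules are
  testable, so passing tests demonstrate correctness of the chain, not
  robustness to informative missingness. Peptide counts are 1 + Poisson(4).
* **Germination**: discrete-time survival — each still-ungerminated seed
  germinates in interval *i* with hazard \(h_i\); 3 replicates × 20 seeds
  by default. The pipeline's default hazards give expected indices close
  to the unprimed/hydroprimed contrast the package emulates (UP: G ≈ 85%,
  MGT ≈ 1.66 d; P: MGT ≈ 1.25 d).
* **qPCR**: \(F = \min(F_0 E^c, plateau) + N(0, \sigma)\), floored at 0 —
  a sharp saturation, adequate for testing the exponential-phase window
  fit but without the soft sigmoidal shoulder of real chemistry.
* **Comet**: one multinomial draw over the five classes per slide.

Every generator draws from its own explicitly seeded stream and restores
the caller's RNG state; identical seeds give byte-identical outputs.

# Pipeline and reproducibility

`run_pipeline()` wires the stages over the declared design — eight seed
states and the ten pairwise transitions between them — and writes
per-stage CSVs, a per-comparison count summary (quantified / accumulated
/ depleted / only-in-one-condition), a JSON summary and a run log. All
stage seeds derive from the single config seed; the test suite asserts
that a rerun reproduces every output file byte for byte and the bundled
simulated intensity table round-trips through the on-disk
protein-groups dialect. Desk-scale defaults (600 proteins, 200
permutations) keep a full run in seconds; the statistical acceptance
checks use larger sizes (2000-protein null calibration, 500 spiked
proteins in a 5000-protein table, 999 permutations) chosen so Monte-Carlo
error is small relative to the properties asserted.

# Known limitations

* The robust-z normalization assumes a mostly-null proteome (see above).
* Pseudo fold changes are surrogates with detection-limit semantics; they
  should never enter averaging with measured fold changes.
* Simple GSEA permutation bounds p at 1/(n_perm+1); very small p-values
  require raising `n_perm`.
* The qPCR generator's sharp plateau and additive noise are idealized;
  per-reaction efficiency scatter of real chemistries is not modelled.
* Germination hazards are interval-constant; censoring beyond the last
  observation day is treated as non-germination.
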