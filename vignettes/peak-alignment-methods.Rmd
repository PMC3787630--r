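---
title: "Peak matching alignment for GCxGC-MS: models, measures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peak matching alignment for GCxGC-MS: models, measures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcxgcalign)
```

## The problem

Comprehensive two-dimensional gas chromatography coupled to mass
spectrometry (GCxGC-MS) characterizes every detected compound peak by a
pair of retention times $(r_1, r_2)$ — primary and secondary column —
and a fragment-ion mass spectrum, an intensity vector
$X = (x_1, \dots, x_g)$ over $g$ nominal-mass m/z channels. In a
biomarker study many runs must be compared, so the peaks that belong to
the same metabolite in different runs have to be recognized: *peak
matching alignment*. Under homogeneous acquisition conditions the
retention times of corresponding peaks differ only by run-to-run jitter,
and their spectra differ only by measurement noise, so both coordinates
carry matching information.

`gcxgcalign` implements the peak-matching toolbox around two
ingredients:

* **Spectral similarity** $S(t, r)$ between the target peak's spectrum
  and a reference peak's spectrum: cosine (dot product), Pearson,
  Spearman, partial correlation and part (semipartial) correlation,
  the last two optionally in a *two-step* rank-restricted form.
* **Retention time distance** $D_d(t, r)$ between the two peaks'
  retention-time pairs: Euclidean, Maximum (Chebyshev), Manhattan and
  Canberra.

Five alignment procedures combine them:

| method | rule |
|--------|------|
| PAD    | nearest reference by $D_d$ alone |
| PAS    | most similar reference by $S$ alone |
| DW-PAS | $S$-argmax within the $k$ nearest references by $D_d$ |
| SW-PAD | $D_d$-argmin within references with $S \ge \rho$ |
| PAM    | argmax of the mixture score $M_d = \dfrac{w}{1 + D_d} + (1 - w)\,S$ |

Matching is per target peak; a reference peak may be claimed by several
targets (no bijection is enforced — the evaluation counts matched pairs,
and a pair is only correct if it is a true correspondence). A greedy
one-to-one mode (`one_to_one = TRUE`) is available as a diagnostic; it
is greedy rather than an optimal assignment, which keeps it dependency-
free and is sufficient for its exploratory purpose.

## Partial and part correlation, and the two-step device

Treat each peak as a random variable observed across the $g$ m/z
channels. The partial correlation of the target spectrum $X$ with
reference spectrum $Y_i$ given the other reference spectra
$Y^{(i)}$ is the Pearson correlation of the residuals of $X$ and $Y_i$
after least-squares regression (with intercept) on $Y^{(i)}$; the part
(semipartial) correlation regresses only $Y_i$. Conditioning removes the
spectral structure shared across the reference list — common fragment
backbones, near-duplicate compounds — and retains what is specific to
peak $i$; this is why conditioning-based measures shine exactly when
many peaks share spectral information.

When peaks outnumber channels ($m > g$) the full conditioning design is
singular. The two-step form conditions only on the $q$ reference spectra
most Pearson-correlated with $X$: rank all reference peaks except $i$ by
$r_{XY_j}$ in descending order and keep ranks $\le q$. Three
conventions had to be fixed where the construction is silent:

* peak $i$ is removed *before* ranking, so it never consumes a rank
  slot;
* ranking ties break by lower reference index (determinism);
* an undefined Pearson score (constant spectrum) ranks below all
  defined scores.

Rank-deficient conditioning designs (duplicate spectra) are handled by
pivoted least squares, equivalent to dropping redundant columns. A
residual whose spread collapses below $10^{-10}$ of its column's
original spread carries no signal; the score is then reported as
missing (`NA`) rather than as a spurious $\pm 1$. Inside
`similarity_matrix()` missing scores stay missing and the aligners
simply never select them; a target whose whole row is missing is left
unmatched.

Two useful identities are tested rather than assumed: with an empty
conditioning set both partial and part reduce *exactly* to Pearson; and
when the conditioning spectra are sample-orthogonal to both $X$ and
$Y_i$, Pearson, partial and part coincide to $10^{-10}$.

One property of the semipartial correlation matters operationally: the
part correlation of a peak with an identical copy of itself given a
conditioning set $Z$ is $\sqrt{1 - R^2_{X|Z}} < 1$, not 1. A similarity
window (SW-PAD) thresholding part scores therefore excludes even
perfect replicates once $\rho$ exceeds that floor; in the dense regime
the floor reaches $\approx 0.05$. This is a property of the measure,
not an implementation artifact, and it is why part correlation pairs
badly with similarity windows.

## Retention time distances

Distances operate on raw seconds in both dimensions; no standardization
is applied because the Canberra distance,
$|\Delta_1|/(|a_1|+|b_1|) + |\Delta_2|/(|a_2|+|b_2|)$, is
self-normalizing per dimension (a zero-denominator term contributes 0)
and is the recommended choice when the two dimensions live on very
different scales (minutes-scale $r_1$ versus seconds-scale $r_2$). An
exploratory per-dimension z-scaling would be a pre-processing step on
the peak lists, not a distance option. Window ties at the boundary
break by lower reference index.

## Evaluation

With $s$ true pairs, $u$ matched pairs, and an $m \times n$ comparison:
$\mathrm{TP}$ = matched true pairs, $\mathrm{FP} = u - \mathrm{TP}$,
$\mathrm{FN} = s - \mathrm{TP}$,
$\mathrm{TN} = mn - s - \mathrm{FP}$, and

$$\mathrm{TPR} = \mathrm{TP}/s, \quad
\mathrm{FPR} = (u-\mathrm{TP})/(mn-s), \quad
\mathrm{PPV} = \mathrm{TP}/u, \quad
F_1 = 2\,\mathrm{TP}/(s+u).$$

With $u = 0$, PPV and $F_1$ are undefined (reported `NA`) while TPR and
FPR are still 0. ROC curves come in two forms. The generic
`roc_curve()` takes scores with truth labels, thresholds at the
descending unique scores, anchors the curve at (0,0) and (1,1), and
integrates by trapezoid — on ties-free scores this AUC equals the
Mann-Whitney statistic exactly, which the tests exploit as an
independent oracle. `alignment_roc()` instead re-thresholds an
alignment's own match scores and recomputes TPR/FPR from the confusion
formulas above (TPR = FPR = 0 when no match survives a cut-off); the
thresholded quantity is each method's selection score (similarity for
PAS/DW-PAS, negated distance for PAD/SW-PAD, mixture score for PAM).
`score_distributions()` splits the full similarity matrix into
same-peak and different-peak scores; `overlap_coefficient()` summarizes
their separation as the overlapping area of two kernel density
estimates.

## The synthetic data generator

No public GCxGC-MS set with certified peak correspondences can ship
inside a package, so the generator is a first-class module: it emulates
two regimes — a sparse mixture-of-standards run (`data1_like`, 75
compounds) and a dense biological run (`data2_like`, 450 compounds) —
with known ground truth, and every quantitative claim in the tests is
computed on its output.

A compound library draws, per compound:

* **backbone fragments** from a small shared pool (default 8 of a
  12-channel pool) following one global intensity profile modulated per
  compound — the common low-mass and derivatization fragments that make
  *all* real EI spectra correlated. The backbone carries
  `shared_intensity_frac` of the total ion intensity (0.4 sparse / 0.55
  dense);
* **compound-specific fragments** (6 channels) drawn without
  replacement from the still-unused part of the m/z grid while any
  remains, then with replacement — so a crowded grid (450 compounds on
  201 channels) reuses channels and distinct compounds overlap more, the
  structural difficulty of dense data;
* **a flat low-intensity background** ("grass") on essentially all
  remaining channels (15% of total intensity), near-identical across
  compounds;
* with probability `family_rate` (0.05 sparse / 0.25 dense) the
  compound is instead a perturbed copy of an earlier compound's spectrum
  — isomers and related metabolites that are spectrally confusable but
  elute elsewhere.

An observation of a compound adds Gaussian retention-time jitter
(default sd 5 s / 0.05 s per dimension), multiplicative log-normal
spectral noise whose relative magnitude grows as channel intensity
falls (shot-noise-like, capped at 5 times the base-peak level;
`spectral_noise_cv` 0.3 sparse / 0.4 dense), an optional detection
floor and channel dropout (both 0 by default), and a log-normal area
factor. Retention times are uniform over the run by default with a
bimodal option. Both lists are sorted by first-dimension retention time
and harmonized onto one m/z grid; truth records the shared compounds.

Two generator design points deserve their reasoning spelled out:

* **Why the flat shared background exists.** Rank correlation turned
  out to be remarkably robust in every "sparse spectrum" configuration:
  with only informative channels present, the zero/nonzero support
  pattern alone identifies a spectrum, and multiplicative noise almost
  never demotes a large fragment below the background, so Spearman beat
  every other measure — the opposite of what is observed on real
  ChromaTOF peak lists, where spectra are dense with small, poorly
  reproducible values. Giving every spectrum a *flat* (informationless)
  background on most channels, re-shuffled in rank by heteroscedastic
  noise on every observation, dilutes the rank vector with noise while
  adding almost no energy: intensity-weighted measures (cosine,
  Pearson, and the conditioning measures built on them) are unaffected,
  and Spearman degrades — reproducing its observed weakness for the
  mechanistically right reason.
* **Why target-only extras default to zero.** The presets treat the
  reference run as the more complete one: every target peak has a true
  partner. PAD and PAS match every target unconditionally, so
  target-only decoys would make $u > s$ and put $F_1 = 1$ out of reach
  even for a perfect, noise-free aligner; reference-side extras (3
  sparse / 22 dense, giving Table-1-like peak counts) still provide
  decoys. `extra_target` remains available for false-positive studies.

Preset noise magnitudes are a calibration: the instrument papers give
no quantitative jitter or noise levels, so the values were chosen once
so that the sparse regime aligns in the mid-90s of percent F1 and the
scaled dense regime in the 60s–70s, the qualitative ranges reported for
standards mixtures versus biological samples; they are documented here
as calibration, not as ground truth, and the tests assert directions
and orderings, not those absolute levels.

What passing tests on this generator shows — and what it does not: the
generator reproduces spectral crowding, shared-fragment correlation,
rank-fragile backgrounds and confusable families, but not
deconvolution artifacts with structured (non-independent) errors,
retention-time drift that varies along the run, or class-structured
metabolite families; conclusions about method *orderings* transfer to
the degree those mechanisms dominate real data.

## Benchmarking harness

`sweep_grid()` defaults to the canonical grids — $k \in \{3,5,10,15,
20\}$, 13 equally spaced $\rho \in [0.1, 0.99]$, 13 equally spaced
$w \in [0.01, 0.99]$, $q \in \{3,5,7,10,15,20,30,50,70,100\}$ (the
interval grids are stated by endpoints and count only; equal spacing is
this package's realization). `run_sweep()` evaluates every combination
on every supplied run pair, reports all confusion metrics plus AUC per
row, flags infeasible rows ($q \ge m$) as skipped, and appends
per-combination means and standard errors across pairs. Similarity
matrices are cached per (pair, measure, q), which is what makes dense
sweeps affordable; the cache is exactly equivalent to recomputation and
the tests verify single-run rows against direct calls. For multi-run
studies the intended convention is: first run is the reference, all
others are targets, metrics averaged across target runs.

Problem sizes in the shipped tests are chosen to keep the full suite
around two minutes on one core: oracle suites use $g \le 50$,
$m \le 10$ for the similarity measures and $n, m \le 30$ for the
aligners; the directional comparisons use 10 replicate pairs of a
150-compound dense regime and the 75-compound sparse preset; the
noise-free recovery check runs both presets including the full
450-compound dense list.

## Numerical choices and degenerate inputs

* Unit-mass binning at spectrum construction; harmonization takes the
  union grid, zero-fills, and conserves each spectrum's total ion
  intensity exactly.
* Undefined scores (zero-norm or constant spectra, collapsed residuals)
  are errors in the scalar API and missing values in the matrix API.
* Score ties in every aligner break by smaller retention-time distance
  (the method's own distance; Euclidean where the method has none),
  then lower reference index; merge ties break by earliest position.
* `mixture_score` special-cases $w = 1$ so that missing similarities
  cannot contaminate the pure-distance limit.
* All generator randomness flows from one integer seed; the caller's
  RNG state is saved and restored.

## Limitations

* The partial/part implementation targets $q \lesssim 100$ conditioning
  spectra; it is dense linear algebra, not a sparse or shrinkage
  estimator.
* The greedy one-to-one mode is not an optimal assignment.
* The CLI's evaluate subcommand trusts the truth file's indexing into
  the merged lists; no label-based reconciliation is attempted.
* Heterogeneous acquisition conditions (different temperature programs
  between runs) are out of scope; all distances assume directly
  comparable retention times.
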