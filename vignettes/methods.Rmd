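---
title: "Models and methods behind sersev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sersev}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sersev)
```

This vignette explains the scientific model the package implements, the
tunable parameters and their defaults, what the synthetic-data generator
does and does not emulate, and the numerical design choices — in the spirit
of how a model-based analysis package should document itself.

## The measurement and its model

A SERS substrate with vesicle-sized hotspots yields one Raman spectrum per
small extracellular vesicle, recorded here on a fixed axis of 1117 Raman
shifts from 564 to 1681 cm⁻¹ (`wavenumber_grid()`, spacing ≈ 1.0009 cm⁻¹).
Proteins dominate the vesicle cargo signal, and a protein's SERS fingerprint
is approximately additive over its residues. The package therefore models a
vesicle spectrum as a non-negative linear combination of the 20 amino-acid
reference spectra:

$$S(\nu) \;=\; \sum_{a=1}^{20} c_a\, B_a(\nu) + \text{baseline} + \text{noise},
\qquad c_a = \frac{f_a\,\mathrm{act}_a}{\sum_b f_b\,\mathrm{act}_b},$$

where $f_a$ is the molar fraction of amino acid $a$ in the vesicle proteome
and $\mathrm{act}_a$ its SERS activity. Two facts motivate the two factors:
MS quantification gives molar composition, but Raman cross-sections differ
by roughly an order of magnitude between substances, so composition alone
does not predict spectral weight. Activity is proxied by the reference
spectrum's signal-to-noise ratio (`estimate_snr()`), a robust ratio
$\max(y)/\hat\sigma$ with $\hat\sigma = \mathrm{median}|\Delta y| /
(0.6745\sqrt2)$ — a first-difference estimator that needs no user-chosen
signal-free window and is invariant under rescaling. An exactly noiseless
spectrum returns a flagged `Inf` rather than a silent division by zero.

**Assumptions and known limitations.** Additivity over amino acids ignores
secondary structure, residue context, lipids and nucleic acids; on real
vesicles those produce peaks the simulation cannot have, which caps
achievable matching rates and inflates coefficient deviations. The model is
also scale-free: hotspot-to-hotspot enhancement varies wildly, so all
comparisons run on ℓ2-normalized spectra and on coefficient vectors
normalized to sum 1.

## MS → amino-acid composition

`amino_acid_frequencies()` computes
$f_a = \sum_p w_p n_{pa} \big/ \sum_p w_p L_p$ with $w_p$ the protein's
relative abundance, $n_{pa}$ its count of residue $a$ and $L_p$ its count of
standard residues. This is molar-fraction semantics: duplicating a protein
row while halving its abundance, or rescaling all abundances, changes
nothing. Non-standard letters (B, J, O, U, X, Z) are excluded from numerator
and denominator and counted per protein, because the basis has exactly 20
members. Sequences come from a local FASTA rather than any online lookup, so
an analysis is reproducible from files alone. The abundance column (iBAQ,
LFQ, spectral counts, …) is taken as given weights; no re-quantification is
attempted.

## Preprocessing

Raw spectra carry a broad background (substrate, residual PBS). The package
subtracts an asymmetric-least-squares baseline: iteratively reweighted
penalized least squares where points above the current baseline get weight
$p$ and points below $1-p$, with a second-difference smoothness penalty
$\lambda$. Defaults $\lambda = 10^5$, $p = 0.01$ suit a slowly varying
background under lines of 6–20 cm⁻¹ width at ≈1 cm⁻¹ sampling; both are
settable in `preprocess_config()`. Two consequences matter downstream:

* **Dictionary consistency.** Overlapping Lorentzian tails form a smooth
  pedestal that ALS partially removes. If targets are corrected but basis
  spectra are not, unmixing inherits a large systematic error; the pipeline
  therefore corrects the dictionary with the same configuration (this is
  also why basis spectra are stored baseline-corrected and max-normalized,
  with activities carrying the intensity scale).
* **No clipping.** Negative residual intensities after correction are left
  in place; clipping would bias small coefficients upward.

Spectra failing an optional SNR gate are flagged in metadata, never dropped.

## Unmixing

The reference solver is non-negative least squares (active-set, via
`pracma::lsqnonneg`): the convex program $\min_w \|y - Bw\|_2,\ w \ge 0$ has
a unique solution for any basis with linearly independent spectra, and the
reported coefficients are $w/\sum w$. A deterministic boosted alternative
(`method = "boosted"`: stagewise forward fitting, single-basis-spectrum weak
learners, shrinkage 0.5, 200 rounds) is provided for users who prefer an
ensemble-of-weak-regressors formulation; it approximates the convex optimum
and is bit-reproducible, but NNLS is the default and the method against
which deviation statistics should be read. A near-duplicate basis (pairwise
cosine similarity at 1 within tolerance) triggers a warning because weights
are then not identifiable.

Fitted-vs-reference agreement is summarized by `mean_deviation()` in two
modes, because "mean deviation" between coefficient vectors is ambiguous:
*relative* (mean of $|c^{fit}_a - c^{ref}_a| / c^{ref}_a$ over reference
entries > 0) is harsh on near-zero coefficients; *absolute* (mean
$|c^{fit}_a - c^{ref}_a|$, in percentage points against a mean coefficient
of 5 points) is scale-stable. Both are always reported.

## Peak matching

`detect_peaks()` finds local maxima with topographic prominence at least
5% of the spectrum maximum and pairwise separation at least 10 cm⁻¹ (more
prominent peak wins). `matching_rate()` then matches two position lists
greedily by ascending distance, one-to-one, within a half-width of 8 cm⁻¹
(≈8 grid steps); one broad reference band can therefore not absorb several
query peaks, and enlarging the tolerance can only increase the rate. The
default direction is "fraction of predicted (simulated/fitted) peaks found
in the measurement"; both directions and their mean are available since a
published matching rate may be either. All three parameters are plain
configuration (`match_config()`) and are echoed into outputs.

## LDA and overlap rates

Groups of vesicle spectra (SEC fractions, cell lines) are discriminated by
Fisher LDA on the full 1117-point spectra, reduced to
$\min(\text{groups} - 1, 2)$ axes. With tens-to-hundreds of spectra and 1117
features, the within-class scatter is far from full rank; the solver
works in the SVD span of the data and inverts the scatter through a
tolerance-based pseudo-inverse. One further choice is essential: when
$p \gg n$, the *unregularized* Fisher direction can separate any labeling of
the training data perfectly by exploiting noise dimensions, which makes
every training-score overlap rate degenerately zero. `fit_lda()` therefore
shrinks the within-class scatter toward a spherical target,
$(1-\gamma)S_W + \gamma\,\bar\lambda I$ with $\gamma = 0.1$ by default —
the smallest level, among the decades examined on planted-overlap synthetic
data, that keeps the discriminant anchored to reproducible spectral
structure (planted common-vesicle rates of 5/10/15% are recovered in order
rather than collapsing to 0%). $\gamma = 0$ recovers the textbook
pseudo-inverse estimator, which is also the setting used when cross-checking
against an independent LDA implementation. Axes are ordered by eigenvalue
and signs fixed (first non-negligible loading positive), so scores are
bit-reproducible.

"Common vesicle" rates come in three rules, because the counting rule for a
2-D map is a genuine design choice: `range1d` (percent of A's scores inside
B's score range — the natural rule for a binary, 1-D map), `hull2d`
(inside the convex hull of the other group, boundary inclusive; degenerate
hulls fall back to segment/point membership), and `classify` (nearest group
centroid in score space, whose per-group rates sum to ≤ 100%). When a 2-D
overlap is reported, both `hull2d` and `classify` are computed side by side,
since they answer slightly different questions (occupancy of a region vs
attribution to a group). The pooled two-cell-type analysis
(`pooled_fraction_overlap()`) fits a binary LDA on cell type and reports the
range-rule overlap of each query fraction against all reference scores.

## The synthetic generator

`synthetic_spec()` fixes everything behind one seed; every generator is a
pure function of its spec, and written bundles are byte-identical across
reruns.

* **Basis**: per amino acid, 4–8 Lorentzian lines (the natural Raman line
  profile), centers uniform in the interior of the grid, FWHM 6–20 cm⁻¹,
  max-normalized; pairs with cosine similarity ≥ 0.95 are regenerated so the
  dictionary stays identifiable. Activities are uniform on [1, 10] — about
  the order-of-magnitude spread seen between substances' SERS responses.
* **Vesicles**: per-spectrum compositions from
  $\mathrm{Dirichlet}(\kappa \cdot \text{mean})$ — variability that respects
  the simplex; default $\kappa = 300$ gives a few percent relative spread
  (moderate vesicle-to-vesicle heterogeneity), and test studies use
  $\kappa$ down to 80 for visibly spread clouds. The clean signal is the
  coefficient-weighted basis mixture; a random order-2 polynomial background
  (amplitude 0.2 of the signal maximum — a prominent but not dominating
  PBS-like pedestal) and Gaussian noise (default 2% of the maximum) are
  added.
* **MS fixture**: sequences of length 100–600 sampled from the target
  composition, plus one homopolymer "adjustment" protein per represented
  residue whose abundance is solved in closed form so the implied
  frequencies equal the target exactly (machine precision), not merely in
  expectation. A single adjustment protein cannot close 19 degrees of
  freedom with integer residue counts, hence one per residue; exactness
  requires at least as many proteins as represented residues, below which
  the generator warns and falls back to integer rounding.

What the generator deliberately does **not** emulate: lipid/nucleic-acid
bands, hotspot enhancement physics, cosmic-ray spikes, wavelength
miscalibration, and non-additive residue effects. Consequently, passing
tests demonstrate that the algorithms are correct and calibrated under the
stated statistical model — not that real instrument data will reach the same
matching rates or deviations; on fully model-consistent synthetic data the
matching rate is 100% by construction.

## Numerical choices and degenerate inputs

* Axes are canonicalized to ascending wavenumber on read; duplicate
  wavenumbers, ragged map sweeps and non-numeric cells are hard errors with
  the offending position or line named.
* Resampling is linear interpolation and refuses extrapolation.
* The all-zero spectrum cannot be normalized or unmixed (errors), a flat
  spectrum has no peaks (empty list, not an error), and an empty reference
  peak list makes the matching rate undefined (error naming the direction).
* Pearson correlation between two compositions is `NA` when either is
  constant (e.g. uniform vs uniform), not a warning.
* Dirichlet draws handle zero mean entries exactly (those amino acids stay
  at zero).
* All pipeline randomness flows from the spec/config seed; reports exclude
  wall-clock timing (written separately) so reruns are byte-identical.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated data:
recovery studies use 3 groups × 60 spectra on the full 1117-point grid; the
two-cell-type study uses 59/115/47 + 65/68/31 spectra; property checks use
reduced grids (201–601 points) where the full axis adds nothing. These sizes
keep a complete run in the tens of seconds on a single core while leaving
every statistic estimable.
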