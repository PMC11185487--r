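# sersev

Single-vesicle SERS spectral analysis of extracellular vesicles.

Small extracellular vesicles (sEVs, "exosomes", 30–150 nm) are heterogeneous,
and bulk assays such as Western blot average that heterogeneity away.
Surface-enhanced Raman spectroscopy (SERS) substrates whose hotspots are
comparable in size to one vesicle make it possible to record one Raman
fingerprint per vesicle, and those fingerprints track the vesicle's
biomolecular — chiefly protein — content. `sersev` implements the analysis
side of such an experiment for researchers working with SEC-fractionated
vesicle preparations and mass-spectrometry (MS) proteomics:

1. **MS → composition.** Protein relative abundances plus local FASTA
   sequences are translated into the molar fractions *f(a)* of the 20 amino
   acids: *f(a) = Σₚ wₚ·nₚₐ / Σₚ wₚ·Lₚ*.
2. **Forward model.** Each amino acid contributes in proportion to both its
   abundance and its SERS activity (proxied by the signal-to-noise ratio of
   its reference spectrum): mixing coefficients
   *c(a) = f(a)·act(a) / Σ_b f(b)·act(b)*, and the simulated vesicle spectrum
   is the linear combination *S(ν) = Σₐ c(a)·Bₐ(ν)* of the 20 reference
   spectra.
3. **Unmixing.** A measured spectrum is inverted into coefficients by
   non-negative least squares, `min‖y − Bw‖₂ s.t. w ≥ 0` (a deterministic
   boosted stagewise fit is available as an alternative), after asymmetric
   least-squares baseline correction and normalization.
4. **Agreement statistics.** Peak-location matching rate (greedy one-to-one
   matching within a wavenumber tolerance, default 8 cm⁻¹) and mean deviation
   between fitted and MS-derived coefficients (relative and absolute modes).
5. **Subpopulation discrimination.** Shrinkage-regularized Fisher LDA on the
   1117-point spectra (1 axis for two groups, 2 axes for three or more), with
   overlap rates: 1-D score-range rule, 2-D convex-hull and
   nearest-centroid rules, and the pooled two-cell-type per-fraction
   analysis.
6. **Synthetic ground truth.** A fully seeded generator produces amino-acid
   basis spectra (Lorentzian line sets), vesicle populations with Dirichlet
   within-group compositional variability, and MS tables + FASTA whose
   implied frequencies match a requested composition to machine precision —
   so every stage is testable without instrument data.

## Worked example

```r
library(sersev)

spec <- synthetic_spec(
  seed = 42,
  groups = list(
    synthetic_group("F7", 20, human_aa_frequencies(), concentration = 120),
    synthetic_group("F8", 20, composition_vector(
      setNames(as.numeric(human_aa_frequencies()) *
               exp(sin(1:20) * 0.4), amino_acids())), concentration = 120)))
basis <- generate_basis(spec)             # 20 reference spectra + activities
ves   <- generate_vesicle_set(spec, basis)  # 40 vesicle spectra + truth
pre   <- preprocess_set(ves$set, preprocess_config())

# unmix the first vesicle
fit <- fit_composition(pre[[1]], basis)
fit
#> <sers_fit> method=nnls, residual norm 0.2301
#> top coefficients: P=0.185, A=0.176, K=0.105, F=0.094, L=0.081
mean(abs(fit$coefficients - ves$coefficients[1, ]))
#> [1] 0.0149

# MS fixture round trip: implied frequencies match the human background
ms   <- generate_ms_fixture(human_aa_frequencies(), n_proteins = 90, seed = 7)
freq <- amino_acid_frequencies(ms$table)
compare_to_reference(freq, human_aa_frequencies())
#> <composition_comparison> r = 1.0000, mean relative deviation = 0.00%

# discriminate the two fractions
emb <- fit_lda(pre, set_meta(pre, "fraction", NA_character_))
emb
#> <sers_lda> 40 spectra, 2 groups -> 1 dim(s)
overlap_rate_groups(emb, rule = "range1d")
#> <overlap_report> rule = range1d
#>    F7 F8
#> F7 NA  0
#> F8  0 NA
```

The fitted coefficients recover the generating mixture to ~0.015 mean
absolute error at 2% noise, the MS translation is exact by construction, and
the two fractions — whose mean compositions differ by a ±40% modulation —
separate with zero score-range overlap.

For a file-based run, `write_synthetic_bundle()` materializes a bundle
(vesicle map TSV + manifest, basis CSVs, MS CSV + FASTA) and
`run_pipeline(pipeline_config("<dir>/manifest.yaml"))` executes every stage
and writes `report.json`.

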