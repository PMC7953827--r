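---
title: "Methods: similarity-matrix QC of reduced mass-spectra representations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: similarity-matrix QC of reduced mass-spectra representations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Ambient-ionization profiling of tissue produces a handful of spectra per
sample and thousands of m/z features per spectrum. With far more features
than samples, most statistical and machine-learning tools need a reduced
representation first. Two families of reductions compete: *top-N
thresholding* (keep only the N most intense bins of each spectrum — a naive
projection onto the high-intensity subspace) and *dimensionality-reduction
(DR) algorithms* (PCA, PLS-DA, NNMF, Isomap, UMAP, diffusion maps). `ssmdr`
provides both behind one contract and a quantitative way to judge what each
representation preserves: class structure (e.g. astrocytoma vs.
glioblastoma) and acquisition-date batch structure.

Only reductions that can project *new* spectra through an already-fitted
mapping are included, because downstream classifiers need out-of-sample
projection; that criterion excludes methods such as t-SNE.

## The similarity matrix and the block-contrast statistic

For spectra $x_1, \dots, x_n$ (raw, thresholded, or embedded), the spectra
similarity matrix (SSM) is

$$S_{ij} = \frac{\langle x_i, x_j\rangle}{\lVert x_i\rVert\,\lVert x_j\rVert},$$

the cosine similarity, which is invariant to per-spectrum rescaling (so no
intensity normalization is required upstream). Displayed with rows ordered
by acquisition date, batch effects appear as diagonal blocks; ordered by
diagnosis (then date within diagnosis), class structure appears as diagonal
blocks separated by boundary lines.

Visual block structure is quantified by the **block contrast**

$$C = \overline{S}_{\text{within}} - \overline{S}_{\text{between}},$$

the mean similarity over same-group pairs minus the mean over
different-group pairs, diagonal excluded. $C$ depends only on the group
labels, never on the display permutation. Significance uses a label
permutation test with the $(b+1)/(n+1)$ estimator (999 shuffles by default),
which never reports an exact zero. Groups with fewer than two members
cannot contribute within-group pairs and are excluded from the within mean
with a warning.

Zero-norm spectra — possible after aggressive thresholding when a spectrum
shares no bins with the retained support — get similarity 0 to everything
rather than erroring, with a warning.

## Preprocessing

* **Binning.** Peaks are accumulated onto half-open bins
  $[100 + 0.25i,\ 100 + 0.25(i+1))$ Th; the default range 100–2000 Th at
  0.25 Th gives 7600 bins. Co-binned peaks are *summed* (a max-rule is the
  obvious alternative; summation is the package's choice and is documented
  rather than asserted as universal). Peaks outside the range, including a
  peak exactly at the upper limit, are dropped with a logged count.
* **Moving median filter** (window 51 bins). With `step == window` — the
  default — the spectrum is partitioned into consecutive 51-bin blocks and
  every bin is replaced by its block median, broadcast back to full length
  so the 7600-bin grid survives downstream. With `step = 1` a classic
  centered sliding median is used. The filter axis is m/z: a width-51
  window along the scan axis would be impossible with only ~5 scans per
  measurement. The block median suits dense, profile-like low-resolution
  spectra; on sparse centroided data it annihilates isolated peaks, so the
  synthetic-data analyses in this package run with `median_filter = FALSE`.
* **Baseline subtraction.** A rolling minimum over `window` bins (default
  400 bins = 100 Th) followed by a centered moving average of the same
  window — a morphological-opening analogue — estimates the baseline, which
  is subtracted with clipping at zero. On any flat region at least a window
  wide, adding a constant offset leaves the output unchanged. The window is
  configurable; 400 bins is wide enough to pass under isolated peaks and
  narrow enough to track the slow exponential decay typical of
  electrospray baselines.
* **Order.** Binning, then median filter, then baseline subtraction.
  Every step preserves nonnegativity, and the applied parameters are
  recorded in the result's `provenance` attribute.

## Thresholding as dimensionality reduction

`top_n_threshold()` keeps the N most intense bins per spectrum (ties at the
cutoff break toward the lower bin index, making results order-independent);
spectra with at most N non-zero bins pass through unchanged. The *effective
dimensionality* of a thresholded dataset is the number of non-zero bins in
the arithmetic mean spectrum — for nonnegative data, exactly the union of
the per-spectrum supports. `occupancy_curve()` tabulates it over the
standard levels 5, 10, 25, 75, 200 plus the unthresholded value. The
average is unnormalized: for nonnegative data the non-zero set is invariant
to any per-spectrum scaling anyway.

## The DR harness

All six methods run behind `fit_reduce()` / `predict()` with target
dimensions typically 3, 5, 7 and `n_neighbors = 5` for the neighbor-graph
methods; parameters not set explicitly keep the backend defaults and are
recorded in the fitted object's provenance.

* **PCA** — `stats::prcomp`, mean-centered, no scaling. Transform applies
  the linear map.
* **PLS-DA** — PLS regression against one-hot class indicators
  (`mixOmics::plsda`), coordinates = X-scores; the only supervised method.
  Constant (zero-variance) bins are dropped before the fit and the kept
  set is stored for transform. `scale = FALSE`, because whole-spectrum
  columns of zeros (common after thresholding) make per-column
  standardization degenerate.
* **NNMF** — multiplicative-update (Lee–Seung) factorization
  $M \approx WH$, $W, H \ge 0$, Frobenius objective, implemented in the
  package; the objective trace is recorded and is non-increasing. After
  the alternating updates, $W$ is polished to the *exact* nonnegative
  least-squares solution given the final $H$ (exhaustive active-set
  enumeration, exact for small $k$), so projecting a training spectrum
  reproduces its coordinates. No centering, to preserve nonnegativity.
* **Isomap** — k-nearest-neighbor graph on Euclidean distances
  (symmetrized), geodesics by graph shortest paths (`igraph`), classical
  MDS of the geodesic matrix. If the kNN graph is disconnected, components
  are joined by their shortest bridging edge (count recorded in
  provenance). Out-of-sample points extend geodesics through their k
  nearest training points and use the standard landmark-MDS formula; a
  duplicated training point reproduces its coordinates exactly.
* **UMAP** — `uwot::umap` with `ret_model = TRUE`; both a Euclidean and a
  cosine variant are exposed via `metric`. Seeded, with single-threaded
  SGD for bit-reproducibility. Transform via `uwot::umap_transform`;
  because the transform includes stochastic refinement, a duplicated
  training point lands *near* (not on) its original — the tests bound the
  displacement by a fraction of the embedding diameter.
* **Diffusion map** — Gaussian kernel with bandwidth $\sigma$ = median
  pairwise distance, $\alpha = 1$ density normalization, spectral
  decomposition of the symmetrized transition operator; coordinates are
  $\lambda_\ell \psi_\ell$, skipping the trivial stationary eigenvector.
  Out-of-sample points use a Nyström extension, which is exact for
  duplicated training points.

Eigenvector signs are fixed deterministically (largest-magnitude entry
positive), so spectral methods are reproducible across runs.

## The synthetic study generator

No clinical profiling dataset ships with the package, so
`generate_spectra()` builds one with the statistical structure such data
exhibits, and `default_study_config()` fixes the desk-scale study used by
all simulation-based tests: 2 diagnosis classes × 8 patients × 1 sample ×
3 fragments × 5 scans = 240 spectra per polarity on the 7600-bin grid.

Each spectrum is

$$\text{intensity} = \text{template} \times \text{patient effect} \times
\text{fragment effect} \times \text{batch fold} \times \text{scan noise}
\;+\; \text{baseline} \;+\; \text{counting noise}.$$

Design choices that matter:

* **Template.** ~340 peaks on the bin grid (positions drawn on the grid,
  not in continuous m/z, so tests never hinge on bin-edge rounding). The
  top decile are *major ions*: shared, measurement-dominated, arranged on
  a geometric intensity ladder (ratio 1.25 in positive mode, 1.12 in
  negative mode — negative-mode spectra have a flatter major-ion top, so
  rank churn reaches deeper). The bulk is lognormal
  (meanlog $\log 2000$, sdlog 1.2). Class markers (40 per class) sit ×8
  above the bulk and are boosted by $1 + \text{class\_separation}$
  (default 2) in their own class; separation 0 makes the class templates
  identical.
* **Polarity.** The scan noise CV is the polarity's `top_peak_cv` on the
  major ions (0.1 positive, 0.8 negative) and $0.3\,\text{CV} + 0.05$ on
  the rest. A CV difference confined strictly to the top decile cannot
  reproduce the observed occupancy separation at deep thresholds (75,
  200), where growth is driven by rank churn *below* the top decile, so
  the reduced share extends the polarity difference down the list.
  Additionally, patient/fragment variability on major ions is attenuated
  ×0.3 only when the polarity has stable majors (positive mode): positive
  spectra describe the measurement, negative spectra the sample.
* **Batch effect.** Batches are contiguous acquisition-date intervals
  (default 3). Each batch multiplies a random 10% of bins by `magnitude`
  (default 2) and adds a few batch-specific contaminant peaks — the
  signature of solvent or maintenance changes. Folds act damped (exponent
  0.3) on major ions, so the raw positive-mode SSM stays homogeneous while
  reduced representations still expose the correlated bulk shift — batch
  structure becomes *more* visible after DR, not less.
* **Nesting and schedule.** Patient effects are lognormal per
  (patient, peak) — a single scalar per patient would be invisible to
  cosine similarity; ground truth stores the full matrix plus per-patient
  geometric means. One acquisition date per measured sample, classes
  interleaved along the calendar so diagnosis is never confounded with
  batch.
* **Noise.** Exponentially decaying additive baseline (50 counts at
  100 Th, decay 1/500 per Th) and Poisson counting noise.

These magnitudes were fixed once, by simulating the generator's stated
qualitative targets (stable positive-mode top-5, unstable negative-mode
top-5, occupancy growing slower in positive mode, batch contrast rising
with fold magnitude) *before* the test expectations were frozen; they are
package choices describing plausible instrument behavior, not estimates of
any particular instrument.

What the generator does **not** emulate: chemically realistic lipid
envelopes, isotope patterns, m/z calibration drift, profile-mode peak
shapes, or missing scans. Passing tests therefore demonstrate that the
pipeline's operations behave as specified on data with the right
*statistical* structure — they are not evidence about any particular
clinical dataset.

## The comparison grid

`run_comparison()` crosses {raw baseline, 5 thresholding levels, 6 DR
methods × dims 3/5/7} with both polarities and both orderings: 96 rows
under the defaults. Thresholding cells compute the SSM in the thresholded
*spectrum* space (thresholding is a reduction of the spectrum, not an
embedding). Date-ordered rows are scored against batch labels (explicit
`batch_id` when present, else the year-month of the acquisition date as a
proxy); diagnosis-ordered rows against the diagnosis. Every stochastic
stage derives its seed from the plan seed through one splitting scheme, so
a run is reproducible row-for-row; the per-cell permutation count defaults
to 199 across the grid (the standalone `block_contrast()` uses 999). A
failing cell (e.g. a degenerate neighbor graph) is recorded as a failed row
and the grid continues — partial grids are informative. With an output
directory, per-cell SSM CSVs (and optionally PNGs with explicit color
limits in JSON sidecars — panels with different limits are not comparable)
are written together with a manifest of MD5 content hashes; artifact paths
inside `result.csv` are relative, so hashes do not depend on where the run
directory lives.

`rank_methods()` sorts rows by contrast within (polarity, grouping, dim),
breaking ties by permutation p-value and then by name, and never drops
rows.

## Numerical and interface choices

* Native matrix file: plain text, header + embedded metadata TSV + dense
  rows or sparse triplets (chosen automatically above 90% zeros); values
  serialized with 17 significant digits so round trips are bit-exact.
* Dates are ISO-8601; every ordering uses `(date, spectrum_id)`
  tie-breaks; class blocks order lexicographically. All deterministic.
* The loaders accept centroided input only; mzML is read through
  Bioconductor's `mzR`, with polarity taken per spectrum and an explicit
  override when the file does not record it.
* Cosine is the only similarity measure shipped; the `ssm` object carries
  a `measure` tag so a correlation measure could be added without a format
  change.
* Problem sizes used by the shipped tests and the acceptance script — the
  240 × 7600 desk-scale study per polarity, 5–20 simulation seeds per
  property, 199–999 permutations — were chosen as the smallest sizes at
  which the studied effects are comfortably resolved.

## Known limitations

* The baseline estimator is a generic morphological stand-in; it is not a
  reimplementation of any instrument vendor's algorithm.
* PLS-DA with two classes uses one-hot indicators; for many unbalanced
  classes other codings may behave better.
* UMAP is evaluated at library defaults (plus the metric choice); its
  performance is known to be strongly parameter-dependent, and no
  hyperparameter optimization is attempted for any method.
* The block contrast compares group means; it does not model nested
  (patient-within-class) correlation. The tests account for nesting by
  permuting labels at the patient level where that is the right null.
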