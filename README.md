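# ssmdr

Similarity-matrix quality control for dimensionality-reduced
ambient-ionization mass spectra.

## The problem

Mass-spectrometric profiling of tissue — e.g. comparing astrocytoma and
glioblastoma resections during neurosurgery — produces spectra with
thousands of m/z features but only tens of samples. Before any statistics
or machine learning can run, the representation has to be reduced, either
by **top-N peak thresholding** (keep the N most intense bins per spectrum)
or by a **dimensionality-reduction (DR) algorithm**. `ssmdr` is for
analysts who need to decide *which* reduction preserves the structure they
care about: diagnosis classes, and acquisition-date batch effects caused by
device maintenance or solvent changes.

The package provides, end to end:

- binning of centroided spectra onto a fixed grid (100–2000 Th at 0.25 Th
  → 7600 bins), a width-51 moving-median filter, and rolling-minimum
  baseline subtraction;
- top-N thresholding with its occupancy accounting (non-zero bins in the
  average spectrum vs. N);
- six DR methods — PCA, PLS-DA, NNMF, Isomap, UMAP, diffusion map — behind
  one `fit_reduce()` / `predict()` contract with out-of-sample projection
  (the inclusion criterion: methods that cannot project new spectra, such
  as t-SNE, are out);
- the **spectra similarity matrix** (SSM): for spectra $x_i$,
  $S_{ij} = \langle x_i, x_j\rangle / (\lVert x_i\rVert \lVert x_j\rVert)$,
  displayed ordered by acquisition date (batch blocks) or by diagnosis
  (class blocks), and summarized by the **block contrast**
  $C = \bar S_{\text{within}} - \bar S_{\text{between}}$ with a
  label-permutation p-value;
- a seeded synthetic-spectra generator reproducing the statistical
  structure of clinical profiling data (two tumor-like classes, patients /
  samples / fragments / scans nesting, polarity-dependent major-peak
  stability, date-linked batch effects), so the whole pipeline is testable
  without clinical data;
- `run_comparison()`, the full evaluation grid {raw, 5 threshold levels,
  6 methods × dims 3/5/7} × 2 orderings × 2 polarities, with ranked
  results and hashed artifacts.

## Worked example

Simulate the packaged desk-scale study (240 negative-mode spectra), remove
the baseline, and ask whether raw cosine similarities or a 7-component
Isomap embedding separate the two diagnoses better:

```r
library(ssmdr)

cfg <- default_study_config(seed = 42)
neg <- generate_spectra(cfg, "negative")
ds  <- preprocess_spectra(neg$dataset, median_filter = FALSE)
ds
#> <spectra_dataset> 240 spectra x 7600 features
#>   grid: [100, 2000) Th @ 0.25 Th
#>   polarity: negative | diagnoses: astrocytoma, glioblastoma
#>   dates: 2019-01-01 .. 2019-01-16

occupancy_curve(ds, levels = c(5, 25, 200))
#>   n_peaks polarity effective_dim
#> 1       5 negative            27
#> 2      25 negative            74
#> 3     200 negative           296
#> 4    7600 negative          7600

emb <- fit_reduce(ds, "isomap", n_components = 7, seed = 42)

ssm_raw <- compute_ssm(ds, order = "by_class_then_date")
ssm_iso <- compute_ssm(embedding_to_dataset(emb), order = "by_class_then_date")
dplyr::bind_rows(
  raw    = block_contrast(ssm_raw, "diagnosis", seed = 42),
  isomap = block_contrast(ssm_iso, "diagnosis", seed = 42),
  .id = "representation")
#>   representation within_mean between_mean  contrast p_value
#> 1            raw  0.64584839   0.61641029 0.0294381   0.001
#> 2         isomap  0.07476611  -0.05169335 0.1264595   0.001
```

Reading the numbers: keeping only the top 5 peaks of each of the 240
spectra still occupies 27 distinct bins — negative-mode major peaks churn
from scan to scan (the positive-mode curve sits lower at every level). On
raw spectra the two diagnoses differ by a cosine contrast of only 0.029;
after Isomap the same 240 spectra show a contrast of 0.126 at the same
permutation significance — the embedding sharpens the class block structure
more than fourfold. `autoplot(ssm_iso)` draws the SSM heatmap with the
diagnosis boundary; `run_comparison()` repeats this for every reduction in
the grid and `rank_methods()` sorts the winners.

A thin CLI over the same functions ships in `inst/cli/ssmdr`
(`simulate`, `threshold`, `reduce`, `ssm`, `compare` subcommands).

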