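#' Derive a child seed from a base seed
#'
#' All stochastic stages are seeded from one base integer via this splitting
#' scheme, so an entire run is reproducible from a single seed.
#' @noRd
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) %% 1e6) * 2011 + offset * 10007) %% 2147483647L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic spectra generator
#'
#' Defines a two-class (astrocytoma-like vs. glioblastoma-like) profiling
#' study with nested structure — patients, tissue samples, ~3 measured
#' fragments per sample, several consecutive scans per fragment — plus an
#' acquisition-date batch effect and polarity-dependent stability of the
#' major peaks (positive mode: stable; negative mode: strongly varying
#' relative intensities).
#'
#' @param n_patients_per_class Patients per diagnosis class (total spectra
#'   per polarity = `2 * n_patients_per_class * samples_per_patient *
#'   fragments_per_sample * scans_per_fragment`).
#' @param samples_per_patient,fragments_per_sample,scans_per_fragment
#'   Nesting counts; defaults 1, 3 and 5.
#' @param n_shared_peaks,n_class_peaks Template peaks common to both classes
#'   and specific intensity markers per class.
#' @param class_separation Nonnegative scalar: class markers have intensity
#'   `base * (1 + class_separation)` in their own class and `base` in the
#'   other; 0 makes the two class templates identical.
#' @param marker_intensity_boost Multiplier lifting class-marker base
#'   intensities above the lognormal bulk (default 8), placing them in the
#'   mid-intensity range where they carry weight in negative-mode
#'   similarities without disturbing the major-ion top.
#' @param patient_cv,fragment_cv Coefficients of variation of the lognormal
#'   per-(patient, peak) and per-(fragment, peak) multiplicative effects —
#'   the inter-patient and intra-sample biological variability.
#' @param polarity_profile Per-polarity scan-noise profile; each entry is a
#'   list with `top_peak_cv` (CV of the lognormal scan noise on the
#'   top-decile template peaks) and `rank_stability` (`"high"`/`"low"`,
#'   descriptive). Non-top peaks receive `0.3 * top_peak_cv + 0.05`.
#' @param batch_effect List with `n_batches` (contiguous acquisition-date
#'   blocks), `magnitude` (multiplicative fold applied to template peaks in
#'   a random `affected_fraction` of bins; 1 = no batch effect),
#'   `affected_fraction`, and `contaminant_peaks` (extra peaks present only
#'   within one batch, emulating solvent/maintenance changes).
#' @param noise List with `baseline_amplitude` (counts at the low-m/z end),
#'   `baseline_decay_per_Th` (exponential decay rate of the baseline), and
#'   `counting_noise_dispersion` (>= 0; Poisson counting noise scale, 0
#'   disables it).
#' @param template_meanlog,template_sdlog Lognormal parameters of the base
#'   template peak intensities.
#' @param grid The [bin_grid()] peaks are placed on (positions are drawn on
#'   the bin grid, not in continuous m/z).
#' @param seed Base seed; generation is bit-reproducible given the config.
#' @return A validated `synth_config` object.
#' @seealso [generate_spectra()], [default_study_config()]
#' @export
synth_config <- function(n_patients_per_class = 8L,
                         samples_per_patient = 1L,
                         fragments_per_sample = 3L,
                         scans_per_fragment = 5L,
                         n_shared_peaks = 260L,
                         n_class_peaks = 40L,
                         class_separation = 2,
                         marker_intensity_boost = 8,
                         patient_cv = 0.3,
                         fragment_cv = 0.15,
                         polarity_profile = list(
                           positive = list(top_peak_cv = 0.1, rank_stability = "high"),
                           negative = list(top_peak_cv = 0.8, rank_stability = "low")),
                         batch_effect = list(n_batches = 3L, magnitude = 2,
                                             affected_fraction = 0.1,
                                             contaminant_peaks = 5L),
                         noise = list(baseline_amplitude = 50,
                                      baseline_decay_per_Th = 1 / 500,
                                      counting_noise_dispersion = 1),
                         template_meanlog = log(2000),
                         template_sdlog = 1.2,
                         grid = bin_grid(),
                         seed = 1L) {
  cfg <- structure(as.list(environment()), class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  counts <- c(cfg$n_patients_per_class, cfg$samples_per_patient,
              cfg$fragments_per_sample, cfg$scans_per_fragment,
              cfg$n_shared_peaks, cfg$n_class_peaks,
              cfg$batch_effect$n_batches, cfg$batch_effect$contaminant_peaks)
  if (any(counts < 0)) {
    abort("all counts in a synth_config must be >= 0.",
          class = "ssmdr_validation_error")
  }
  if (cfg$class_separation < 0) {
    abort("`class_separation` must be >= 0.", class = "ssmdr_validation_error")
  }
  for (p in c("positive", "negative")) {
    if (is.null(cfg$polarity_profile[[p]]) || cfg$polarity_profile[[p]]$top_peak_cv <= 0) {
      abort(sprintf("polarity_profile$%s$top_peak_cv must be > 0.", p),
            class = "ssmdr_validation_error")
    }
  }
  invisible(cfg)
}

#' The packaged desk-scale study-like configuration
#'
#' Eight patients per class with one sample each, three fragments per sample
#' and five scans per fragment: 240 spectra per polarity on the default
#' 7600-bin grid.  This is the fixture behind all simulation-based package
#' properties (polarity-dependent occupancy growth, batch-contrast recovery,
#' comparison grid).
#'
#' @param ... Overrides forwarded to [synth_config()].
#' @return A `synth_config`.
#' @export
default_study_config <- function(...) {
  synth_config(...)
}

#' Number of spectra a config generates per polarity
#' @noRd
config_n_spectra <- function(cfg) {
  2L * cfg$n_patients_per_class * cfg$samples_per_patient *
    cfg$fragments_per_sample * cfg$scans_per_fragment
}

#' Generate a synthetic spectra dataset with known ground truth
#'
#' Draws a two-class peak template on the bin grid, then builds every
#' spectrum as `template x patient effect x fragment effect x batch profile
#' x lognormal scan noise`, adds an exponentially decaying baseline and
#' Poisson counting noise, and assembles row-aligned metadata with monotone
#' acquisition dates (one date per measured sample, classes interleaved so
#' diagnosis is not confounded with batch).  Batches are contiguous in
#' acquisition date, emulating changes of measurement conditions at device
#' maintenance.
#'
#' @param config A [synth_config()].
#' @param polarity `"positive"` or `"negative"`; selects the scan-noise
#'   profile (positive mode has stable major peaks, negative mode strongly
#'   varying relative intensities of the major peaks).
#' @param seed Optional override of `config$seed`.
#' @return A list with elements
#'   * `dataset`: a [spectra_dataset()] of raw (baseline-containing) spectra;
#'   * `truth`: ground truth — template positions and intensities per class,
#'     `class_peak_positions`, per-spectrum `batch_assignment`, per-batch
#'     affected bins and contaminant positions, and the per-(patient, peak)
#'     multiplicative `patient_effects` (with per-patient geometric means).
#' @examples
#' \donttest{
#' sim <- generate_spectra(synth_config(n_patients_per_class = 2), "positive")
#' dim(sim$dataset)
#' }
#' @export
generate_spectra <- function(config, polarity = c("positive", "negative"),
                             seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  polarity <- match.arg(polarity)
  n_total <- config_n_spectra(config)
  if (n_total == 0) {
    abort("config generates zero spectra.", class = "ssmdr_validation_error")
  }
  base_seed <- if (is.null(seed)) config$seed else seed
  with_seed(derive_seed(base_seed, if (polarity == "positive") 1L else 2L),
            generate_spectra_impl(config, polarity))
}

generate_spectra_impl <- function(cfg, polarity) {
  grid <- cfg$grid
  classes <- c("astrocytoma", "glioblastoma")
  n_tpl <- cfg$n_shared_peaks + 2L * cfg$n_class_peaks
  n_contam <- cfg$batch_effect$n_batches * cfg$batch_effect$contaminant_peaks
  pos_all <- sample.int(grid$n_bins, n_tpl + n_contam)
  positions <- sort(pos_all[seq_len(n_tpl)])
  contam_pool <- pos_all[-seq_len(n_tpl)]
  role <- sample(rep(c("shared", "astrocytoma", "glioblastoma"),
                     c(cfg$n_shared_peaks, cfg$n_class_peaks, cfg$n_class_peaks)))
  base_int <- rlnorm(n_tpl, cfg$template_meanlog, cfg$template_sdlog)

  # Major-ion ladder: the top decile of template peaks are shared
  # measurement-dominated ions on a geometric intensity ladder (ratio 1.25,
  # ~3 decades of dynamic range), sitting above the lognormal bulk.  Their
  # clear rank gaps make the top peaks stable under the positive-mode scan
  # CV and unstable under the negative-mode one.
  n_major <- max(2L, round(0.1 * n_tpl))
  shared_idx <- which(role == "shared")
  if (length(shared_idx) < n_major) {
    abort("n_shared_peaks too small: the top decile of template peaks must be shared.",
          class = "ssmdr_validation_error")
  }
  major <- sample(shared_idx, n_major)
  prof <- cfg$polarity_profile[[polarity]]
  # negative-mode spectra have a flatter major-ion top (smaller rank gaps),
  # so rank churn reaches deeper into the list than in positive mode
  ladder_ratio <- if (identical(prof$rank_stability, "high")) 1.25 else 1.12
  ladder_base <- exp(cfg$template_meanlog + 2.5 * cfg$template_sdlog)
  base_int[major] <- ladder_base * ladder_ratio^(seq_len(n_major)) *
    rlnorm(n_major, 0, 0.05)
  is_major <- seq_len(n_tpl) %in% major

  # class markers sit above the bulk; own-class markers additionally
  # boosted by (1 + class_separation)
  base_int[role != "shared"] <- base_int[role != "shared"] *
    cfg$marker_intensity_boost
  template <- sapply(classes, function(cl) {
    base_int * ifelse(role == cl, 1 + cfg$class_separation, 1)
  })

  # scan-noise CV per peak: full polarity CV on the major (top-decile) ions,
  # a reduced share elsewhere (rank churn below the top decile)
  cv_rest <- 0.3 * prof$top_peak_cv + 0.05
  cv_mat <- sapply(classes, function(cl) {
    ifelse(is_major, prof$top_peak_cv, cv_rest)
  })

  # patients and measurement schedule (one date per measured sample,
  # classes interleaved so diagnosis is not confounded with acquisition date)
  patients <- tibble(
    patient_id = sprintf("P%02d", seq_len(2L * cfg$n_patients_per_class)),
    diagnosis = rep(classes, cfg$n_patients_per_class)
  )
  units <- tidyr::expand_grid(patients, sample_rep = seq_len(cfg$samples_per_patient))
  units <- mutate(units,
                  sample_id = sprintf("%s_S%d", .data$patient_id, .data$sample_rep),
                  acquisition_date = as.Date("2019-01-01") + row_number() - 1L)
  nb <- max(1L, cfg$batch_effect$n_batches)
  units$batch_id <- sprintf("batch%d", ceiling(seq_len(nrow(units)) / nrow(units) * nb))

  # per-(patient, peak) and per-batch multiplicative structures
  # Biological (patient / fragment) variability acts on the bulk peaks at
  # full strength; on the major ions it is attenuated only when the polarity
  # has stable major peaks (positive mode: major ions reflect the
  # measurement; negative mode: major peaks are sample-specific).
  cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))
  peak_atten <- ifelse(is_major & identical(prof$rank_stability, "high"), 0.3, 1)
  sd_p <- cv_to_sdlog(cfg$patient_cv) * peak_atten
  patient_fx <- matrix(rlnorm(nrow(patients) * n_tpl,
                              rep(-sd_p^2 / 2, each = nrow(patients)),
                              rep(sd_p, each = nrow(patients))),
                       nrow(patients), n_tpl,
                       dimnames = list(patients$patient_id, NULL))

  batches <- unique(units$batch_id)
  n_aff <- round(cfg$batch_effect$affected_fraction * grid$n_bins)
  batch_profile <- lapply(setNames(batches, batches), function(b) {
    mult <- rep(1, grid$n_bins)
    aff <- sample.int(grid$n_bins, n_aff)
    mult[aff] <- cfg$batch_effect$magnitude
    k <- cfg$batch_effect$contaminant_peaks
    contam <- if (k > 0) sample(contam_pool, k) else integer(0)
    list(mult = mult, affected = aff, contaminant = contam,
         contaminant_int = rlnorm(length(contam), cfg$template_meanlog,
                                  cfg$template_sdlog))
  })

  # expand to one row per scan
  meta <- tidyr::expand_grid(units,
                             fragment = seq_len(cfg$fragments_per_sample),
                             scan_index = seq_len(cfg$scans_per_fragment) - 1L)
  meta <- mutate(meta,
                 spectrum_id = sprintf("%s_f%d_sc%d", .data$sample_id,
                                       .data$fragment, .data$scan_index),
                 polarity = polarity)

  sd_f <- cv_to_sdlog(cfg$fragment_cv) * peak_atten
  frag_key <- paste(meta$sample_id, meta$fragment)
  frag_levels <- unique(frag_key)
  frag_fx <- matrix(rlnorm(length(frag_levels) * n_tpl,
                           rep(-sd_f^2 / 2, each = length(frag_levels)),
                           rep(sd_f, each = length(frag_levels))),
                    length(frag_levels), n_tpl,
                    dimnames = list(frag_levels, NULL))

  values <- matrix(0, nrow(meta), grid$n_bins)
  for (i in seq_len(nrow(meta))) {
    cl <- meta$diagnosis[i]
    bp <- batch_profile[[meta$batch_id[i]]]
    sdlog <- cv_to_sdlog(cv_mat[, cl])
    scan_noise <- rlnorm(n_tpl, -sdlog^2 / 2, sdlog)
    # maintenance folds hit the bulk chemistry fully; major ions respond
    # with damped folds, so the raw SSM stays homogeneous while reduced
    # representations can still pick the correlated bulk shift up
    fold <- bp$mult[positions]^ifelse(is_major, 0.3, 1)
    peak <- template[, cl] * patient_fx[meta$patient_id[i], ] *
      frag_fx[frag_key[i], ] * fold * scan_noise
    values[i, positions] <- peak
    if (length(bp$contaminant)) {
      values[i, bp$contaminant] <- values[i, bp$contaminant] +
        bp$contaminant_int * rlnorm(length(bp$contaminant), -sdlog[1]^2 / 2, sdlog[1])
    }
  }

  centers <- grid$start + (seq_len(grid$n_bins) - 0.5) * grid$width
  baseline <- cfg$noise$baseline_amplitude *
    exp(-(centers - grid$start) * cfg$noise$baseline_decay_per_Th)
  values <- sweep(values, 2, baseline, "+")
  d <- cfg$noise$counting_noise_dispersion
  if (d > 0) {
    values[] <- rpois(length(values), values / d) * d
  }

  meta_out <- select(meta, all_of(c(meta_required_cols, "batch_id", "scan_index", "fragment")))
  dataset <- spectra_dataset(values, meta_out, grid)

  truth <- list(
    template = tibble(position = positions, mz = centers[positions],
                      role = role, major = is_major,
                      astrocytoma = template[, "astrocytoma"],
                      glioblastoma = template[, "glioblastoma"]),
    class_peak_positions = lapply(setNames(classes, classes),
                                  function(cl) positions[role == cl]),
    batch_assignment = setNames(meta_out$batch_id, meta_out$spectrum_id),
    batch_profile = lapply(batch_profile, function(b) b[c("affected", "contaminant")]),
    patient_effects = patient_fx,
    patient_effect_gmean = exp(rowMeans(log(patient_fx))),
    polarity = polarity,
    config = cfg
  )
  list(dataset = dataset, truth = truth)
}
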