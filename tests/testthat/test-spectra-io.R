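test_that("peak-list CSV reading validates and sorts", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("spectrum_id,mz,intensity",
               "s1,150.20,2.0",
               "s1,150.05,1.0"), f)
  out <- read_peaklist_csv(f)
  expect_equal(nrow(out$peaks), 2)
  expect_equal(out$peaks$mz, c(150.05, 150.20)) # sorted by m/z
  expect_null(out$meta)

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("spectrum_id,mz,intensity", empty)
  expect_equal(nrow(read_peaklist_csv(empty)$peaks), 0)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("spectrum_id,mz,intensity", "s1,150.0,-1"), bad)
  expect_error(read_peaklist_csv(bad), class = "ssmdr_validation_error")

  nocol <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("spectrum_id,mz", "s1,150.0"), nocol)
  expect_error(read_peaklist_csv(nocol), regexp = "intensity",
               class = "ssmdr_format_error")
})

test_that("inline metadata columns are picked up from the peak table", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(paste("spectrum_id,mz,intensity,sample_id,patient_id,",
                     "diagnosis,polarity,acquisition_date", sep = ""),
               "s1,150.05,1.0,smp1,p1,astrocytoma,positive,2020-03-01",
               "s1,150.20,2.0,smp1,p1,astrocytoma,positive,2020-03-01"), f)
  out <- read_peaklist_csv(f)
  expect_s3_class(out$meta, "tbl_df")
  expect_equal(nrow(out$meta), 1)
  expect_equal(out$meta$acquisition_date, as.Date("2020-03-01"))
})

test_that("native matrix format round-trips bit-for-bit, dense and sparse", {
  # dense: random values with full precision
  ds <- random_dataset(4, 60, seed = 11)
  ds$values[1, 3] <- pi * 1e-7
  ds <- spectra_dataset(ds$values, ds$meta, ds$grid)
  f <- withr::local_tempfile(fileext = ".txt")
  write_spectra(ds, f)
  back <- read_spectra(f)
  expect_identical(back$values, ds$values)
  expect_equal(back$meta$spectrum_id, ds$meta$spectrum_id)
  expect_equal(back$meta$acquisition_date, ds$meta$acquisition_date)
  expect_true(any(grepl("#storage dense", readLines(f))))

  # sparse: thresholded data (> 90% zeros) switches storage automatically
  sp <- threshold_dataset(random_dataset(5, 200, seed = 2), 4)
  f2 <- withr::local_tempfile(fileext = ".txt")
  write_spectra(sp, f2)
  expect_true(any(grepl("#storage sparse", readLines(f2))))
  back2 <- read_spectra(f2)
  expect_identical(back2$values, sp$values)

  # empty dataset round-trips
  e <- spectra_dataset(matrix(0, 0, 100), make_meta(0), tiny_grid())
  f3 <- withr::local_tempfile(fileext = ".txt")
  write_spectra(e, f3)
  back3 <- read_spectra(f3)
  expect_equal(dim(back3$values), c(0L, 100L))
})

test_that("dataset construction rejects metadata/matrix mismatches", {
  expect_error(spectra_dataset(matrix(1, 3, 100), make_meta(2), tiny_grid()),
               class = "ssmdr_validation_error")
  expect_error(spectra_dataset(matrix(-1, 2, 100), make_meta(2), tiny_grid()),
               class = "ssmdr_validation_error")
  meta_dup <- make_meta(2, ids = c("a", "a"))
  expect_error(spectra_dataset(matrix(1, 2, 100), meta_dup, tiny_grid()),
               class = "ssmdr_validation_error")
})

test_that("mzML and CSV loaders agree on a fixture exported both ways", {
  skip_if_not_installed("mzR")
  grid <- bin_grid()
  set.seed(5)
  mzs <- lapply(1:3, function(i) sort(runif(20, 120, 1900)))
  ints <- lapply(1:3, function(i) rexp(20) * 1000)
  # write mzML via mzR
  hdr <- data.frame(
    seqNum = 1:3, acquisitionNum = 1:3, msLevel = 1L, polarity = 1L,
    peaksCount = 20L, totIonCurrent = vapply(ints, sum, 1),
    retentionTime = c(1, 2, 3), basePeakMZ = 0, basePeakIntensity = 0,
    collisionEnergy = 0, ionisationEnergy = 0, lowMZ = 100, highMZ = 2000,
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = "", spectrumId = sprintf("scan=%d", 1:3),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = 100,
    scanWindowUpperLimit = 2000)
  fmz <- withr::local_tempfile(fileext = ".mzML")
  mzR::writeMSData(lapply(1:3, function(i) cbind(mz = mzs[[i]], intensity = ints[[i]])),
                   file = fmz, header = hdr, outformat = "mzml")
  mz_out <- read_mzml(fmz, sample_id = "fx", patient_id = "p1")
  expect_equal(unique(mz_out$meta$polarity), "positive")
  expect_equal(mz_out$meta$scan_index, 0:2)

  # same peaks through the CSV path
  fcsv <- withr::local_tempfile(fileext = ".csv")
  long <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(spectrum_id = sprintf("fx_sc%d", i - 1), mz = mzs[[i]],
               intensity = ints[[i]])
  }))
  write.csv(long, fcsv, row.names = FALSE)
  csv_out <- read_peaklist_csv(fcsv)
  expect_equal(csv_out$peaks$mz, mz_out$peaks$mz, tolerance = 1e-6)
  expect_equal(csv_out$peaks$intensity, mz_out$peaks$intensity, tolerance = 1e-6)

  # out-of-range peaks are clipped with a message
  mzs2 <- list(c(150, 2500))
  hdr2 <- hdr[1, ]
  hdr2$peaksCount <- 2L
  fmz2 <- withr::local_tempfile(fileext = ".mzML")
  mzR::writeMSData(list(cbind(mz = mzs2[[1]], intensity = c(1, 2))),
                   file = fmz2, header = hdr2, outformat = "mzml")
  expect_message(out2 <- read_mzml(fmz2), regexp = "retained 1 of 2")
  expect_equal(out2$peaks$mz, 150)

  # corrupt XML errors
  fbad <- withr::local_tempfile(fileext = ".mzML")
  writeLines("<mzML><run>", fbad)
  expect_error(suppressWarnings(read_mzml(fbad)))
})

test_that("as_peaklist and bin_peaklist are mutually inverse on grid-aligned data", {
  ds <- threshold_dataset(random_dataset(3, 80, seed = 4), 10)
  peaks <- as_peaklist(ds)
  back <- bin_peaklist(peaks, ds$meta, ds$grid)
  expect_equal(back$values, ds$values)
})
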