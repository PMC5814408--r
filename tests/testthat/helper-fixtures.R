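# Fixtures built in code.

# Minimal MS1 map: Gaussian elution of given isotope ladders.
make_gaussian_map <- function(mz_ladders, amplitudes, rt0 = 10, sigma = 0.05,
                              rt_span = c(9.4, 10.6), step = 0.02) {
  scan_rt <- seq(rt_span[1], rt_span[2], by = step)
  rows <- list()
  for (k in seq_along(mz_ladders)) {
    for (s in seq_along(scan_rt)) {
      g <- exp(-(scan_rt[s] - rt0[min(k, length(rt0))])^2 / (2 * sigma^2))
      int <- amplitudes[[k]] * g
      keep <- int > 0
      if (any(keep)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          scan = s, rt = scan_rt[s],
          mz = mz_ladders[[k]][keep], intensity = int[keep]
        )
      }
    }
  }
  dplyr::arrange(dplyr::bind_rows(rows), scan, mz)
}

# Header scaffold for writing a small mzML file through mzR.
write_test_mzml <- function(ms1, path) {
  scans <- split(seq_len(nrow(ms1)), ms1$scan)
  pks <- lapply(scans, function(i) cbind(mz = ms1$mz[i], intensity = ms1$intensity[i]))
  n <- length(scans)
  rts <- ms1$rt[!duplicated(ms1$scan)]
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L, peaksCount = lengths(scans),
    totIonCurrent = vapply(pks, function(p) sum(p[, 2]), numeric(1)),
    retentionTime = rts * 60, basePeakMZ = 0, basePeakIntensity = 0,
    collisionEnergy = NA_real_, ionisationEnergy = 0, lowMZ = 0, highMZ = 0,
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_, isolationWindowTargetMZ = NA_real_,
    isolationWindowLowerOffset = NA_real_, isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_
  )
  mzR::writeMSData(pks, path, header = hdr)
  invisible(path)
}
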