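## Shared fixtures, built in code at test time.

aaDays <- c(0, 1, 2, 3, 4, 6, 9, 12, 17, 22, 30)
hwDays <- c(0, 1, 2, 3, 6, 7, 9, 13, 16, 21, 24, 31)

## write a small Percolator-style PSM table and return its path
writeToyPsmTable <- function(rows, path = tempfile(fileext = ".tsv")) {
  write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

toyPsmRows <- function() {
  data.frame(
    PSMId = paste0("run_", 1:3, "_2_1"),
    sequence = c("LVNELTEFAK", "PEPTIK[+6.0201]R", "ELVISM[+15.9949]K"),
    charge = c(2L, 2L, 2L),
    scan = c(100L, 200L, 300L),
    retention_time = c(10, 12, 14),
    `q-value` = c(0.005, 0.02, 0.009),
    proteinIds = c("P001", "P002", "P003"),
    check.names = FALSE, stringsAsFactors = FALSE)
}

## noise-free AA RIA series on the standard schedule
makeAaSeries <- function(k, kp = NULL, plateau = 0.45, days = aaDays) {
  A <- if (is.null(kp)) oneCompartmentA(days, k, 0, plateau)
  else twoCompartmentA(days, k, kp, 0, plateau)
  riaTimeSeries(days, A, 0, plateau, chemistry = "AA")
}

## hand-built in-memory MS1 spectra (same shape as readMs1 output)
makeMs1 <- function(rt, peaks, scan = seq_along(rt)) {
  structure(list(rt = rt, scan = scan, peaks = peaks), class = "Ms1Spectra")
}
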