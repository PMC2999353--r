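# Reading, writing and validating centroided LC/MS maps.

#' Construct an LC/MS map of centroided scans
#'
#' An `lcms_map` is the in-memory representation of a centroided LC/MS run:
#' a sequence of scans, each holding a retention time (seconds) and a peak
#' matrix of (m/z, intensity) pairs sorted strictly ascending by m/z.
#' Scan indices are 0-based throughout the package and its file formats.
#'
#' @param rt Numeric vector of retention times (seconds), strictly increasing.
#' @param peaks List (same length as `rt`) of two-column matrices with columns
#'   `mz` and `intensity`; m/z strictly ascending, intensities non-negative.
#'   Duplicate m/z values within a scan are summed.
#' @param scan_interval Nominal time between scans (seconds). Defaults to the
#'   median retention-time difference.
#' @return Object of class `lcms_map` with elements `rt`, `peaks`,
#'   `scan_interval`.
#' @export
#' @examples
#' m <- lcms_map(rt = c(0, 1), peaks = list(
#'   cbind(mz = c(500.1, 500.6), intensity = c(10, 5)),
#'   cbind(mz = 500.1, intensity = 8)))
#' n_scans(m)
lcms_map <- function(rt, peaks, scan_interval = NULL) {
  if (length(rt) != length(peaks))
    icpd_stop("rt and peaks must have the same length")
  if (length(rt) > 0) {
    if (any(!is.finite(rt)) || any(rt < 0))
      icpd_stop("retention times must be finite and >= 0")
    if (length(rt) > 1 && any(diff(rt) <= 0))
      icpd_stop("scans must be sorted strictly ascending by retention time")
  }
  peaks <- lapply(seq_along(peaks), function(i) {
    p <- peaks[[i]]
    if (is.null(p) || length(p) == 0)
      return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("mz", "intensity"))))
    p <- matrix(as.numeric(p), ncol = 2, dimnames = list(NULL, c("mz", "intensity")))
    if (any(!is.finite(p)))
      icpd_stop("non-finite peak value in scan ", i - 1L)
    if (any(p[, 1] <= 0))
      icpd_stop("non-positive m/z in scan ", i - 1L)
    if (any(p[, 2] < 0))
      icpd_stop("negative intensity in scan ", i - 1L)
    o <- order(p[, 1])
    p <- p[o, , drop = FALSE]
    if (anyDuplicated(p[, 1])) {     # merge coincident centroids
      inten <- rowsum(p[, 2], group = p[, 1], reorder = TRUE)
      p <- cbind(mz = as.numeric(rownames(inten)), intensity = as.numeric(inten))
    }
    p
  })
  if (is.null(scan_interval))
    scan_interval <- if (length(rt) > 1) stats::median(diff(rt)) else 1
  structure(list(rt = as.numeric(rt), peaks = peaks,
                 scan_interval = as.numeric(scan_interval)),
            class = "lcms_map")
}

#' Number of scans in an LC/MS map
#' @param map An `lcms_map`.
#' @return Integer scan count.
#' @export
n_scans <- function(map) length(map$rt)

#' @export
print.lcms_map <- function(x, ...) {
  np <- sum(vapply(x$peaks, nrow, integer(1)))
  cat(sprintf("<lcms_map> %d MS1 scans, %d centroid peaks\n", n_scans(x), np))
  if (n_scans(x) > 0) {
    cat(sprintf("  rt: %.1f .. %.1f s (interval %.3g s)\n",
                x$rt[1], x$rt[n_scans(x)], x$scan_interval))
    allmz <- unlist(lapply(x$peaks, function(p) range(p[, 1])[is.finite(range(p[, 1]))]))
    if (length(allmz)) cat(sprintf("  m/z: %.4f .. %.4f\n", min(allmz), max(allmz)))
  }
  invisible(x)
}

#' Read an LC/MS map from disk
#'
#' Supports a simple tab-separated dialect (columns `scan rt mz intensity`,
#' 0-based scan index, one row per centroid peak; a scan without peaks is a
#' single row with `NA` m/z and intensity) and mzML (MS1 scans, via the mzR
#' package). Profile-mode
#' mzML is rejected unless `centroided = FALSE`, in which case
#' [centroid_scan()] is applied to each scan.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"` or `"mzml"`.
#' @param centroided For mzML input: assert the data are centroided (default).
#'   If `FALSE`, profile scans are centroided with [centroid_scan()].
#' @return An [lcms_map()].
#' @export
read_map <- function(path, format = c("auto", "tsv", "mzml"), centroided = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "tsv"
  if (format == "mzml") return(.read_mzml(path, centroided))
  .read_tsv_map(path)
}

.read_tsv_map <- function(path) {
  if (file.size(path) == 0) icpd_stop("empty map file: ", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = "numeric", check.names = FALSE)
  need <- c("scan", "rt", "mz", "intensity")
  if (!all(need %in% names(d)))
    icpd_stop("map tsv must have columns: ", paste(need, collapse = " "))
  if (nrow(d) == 0) return(lcms_map(numeric(0), list()))
  sc <- sort(unique(d$scan))
  if (any(sc != round(sc)) || any(sc < 0))
    icpd_stop("scan indices must be non-negative integers")
  rt <- vapply(sc, function(s) {
    r <- unique(d$rt[d$scan == s])
    if (length(r) != 1) icpd_stop("inconsistent rt in scan ", s)
    r
  }, numeric(1))
  if (length(rt) > 1 && any(diff(rt) <= 0))
    icpd_stop("retention time must increase strictly with scan index")
  peaks <- lapply(sc, function(s) {
    rows <- d[d$scan == s & !is.na(d$mz), , drop = FALSE]
    cbind(mz = rows$mz, intensity = rows$intensity)
  })
  lcms_map(rt, peaks)
}

.read_mzml <- function(path, centroided = TRUE) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the mzR package")
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hd <- mzR::header(fh)
  ms1 <- which(hd$msLevel == 1L)
  if (length(ms1) == 0) return(lcms_map(numeric(0), list()))
  cent_flag <- hd$centroided[ms1]
  if (centroided && any(!is.na(cent_flag) & !cent_flag))
    icpd_stop("profile-mode mzML scans found; re-run with centroided = FALSE")
  pk <- mzR::peaks(fh, ms1)
  if (is.matrix(pk)) pk <- list(pk)
  peaks <- lapply(seq_along(ms1), function(i) {
    p <- pk[[i]]
    if (!centroided && !is.na(cent_flag[i]) && !cent_flag[i])
      p <- centroid_scan(p[, 1], p[, 2])
    p[p[, 2] > 0, , drop = FALSE]    # drop the writer's empty-scan placeholder
  })
  lcms_map(hd$retentionTime[ms1], peaks)
}

#' Write an LC/MS map to disk
#'
#' Inverse of [read_map()]; `read_map(write_map(m, f), f)` reproduces the map
#' up to floating-point round-trip.
#'
#' @param map An [lcms_map()].
#' @param path Output path.
#' @param format `"auto"`, `"tsv"` or `"mzml"`.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, format = c("auto", "tsv", "mzml")) {
  format <- match.arg(format)
  if (!inherits(map, "lcms_map")) icpd_stop("map must be an lcms_map")
  if (format == "auto")
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "tsv"
  if (format == "mzml") return(.write_mzml(map, path))
  rows <- lapply(seq_len(n_scans(map)), function(i) {
    p <- map$peaks[[i]]
    if (nrow(p) == 0)   # marker row: the scan exists but holds no peaks
      return(data.frame(scan = i - 1L, rt = map$rt[i], mz = NA_real_,
                        intensity = NA_real_))
    data.frame(scan = i - 1L, rt = map$rt[i], mz = p[, 1], intensity = p[, 2])
  })
  d <- do.call(rbind, rows)
  if (is.null(d)) d <- data.frame(scan = integer(0), rt = numeric(0),
                                  mz = numeric(0), intensity = numeric(0))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("scan\trt\tmz\tintensity", con)
  if (nrow(d) > 0)
    writeLines(sprintf("%d\t%.15g\t%.15g\t%.15g", d$scan, d$rt, d$mz, d$intensity), con)
  invisible(path)
}

.write_mzml <- function(map, path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("writing mzML requires the mzR package")
  ns <- n_scans(map)
  if (ns == 0) icpd_stop("mzR cannot write an empty mzML file; use tsv")
  pks <- lapply(map$peaks, function(p) {
    if (nrow(p) == 0) p <- cbind(mz = 1.0, intensity = 0.0)  # placeholder peak
    unname(p)
  })
  nr <- vapply(pks, nrow, integer(1))
  basei <- vapply(pks, function(p) if (nrow(p)) which.max(p[, 2]) else 1L, integer(1))
  hdr <- data.frame(
    seqNum = seq_len(ns), acquisitionNum = seq_len(ns), msLevel = 1L,
    polarity = 1L, peaksCount = nr,
    totIonCurrent = vapply(pks, function(p) sum(p[, 2]), numeric(1)),
    retentionTime = map$rt,
    basePeakMZ = mapply(function(p, i) p[i, 1], pks, basei),
    basePeakIntensity = mapply(function(p, i) p[i, 2], pks, basei),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(pks, function(p) min(p[, 1]), numeric(1)),
    highMZ = vapply(pks, function(p) max(p[, 1]), numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = sprintf("scan=%d", seq_len(ns)),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_)
  mzR::writeMSData(pks, path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Centroid one profile-mode spectrum by local-maximum picking
#'
#' Picks strict local maxima of the intensity profile above `floor`; each
#' centroid m/z is the intensity-weighted mean over the maximum and its
#' immediate neighbours, and the reported intensity is the apex intensity.
#'
#' @param mz_grid Strictly ascending m/z grid.
#' @param intensities Matching non-negative intensities.
#' @param floor Intensity floor; maxima with apex `<= floor` are dropped.
#'   Default 0 keeps every positive maximum (candidate filtering belongs to
#'   the downstream detector, not the centroider).
#' @return Two-column matrix (`mz`, `intensity`).
#' @export
#' @examples
#' centroid_scan(seq(100, 100.04, by = 0.01), c(0, 1, 2, 1, 0))
centroid_scan <- function(mz_grid, intensities, floor = 0) {
  if (length(mz_grid) != length(intensities))
    icpd_stop("mz_grid and intensities must have equal length")
  n <- length(mz_grid)
  empty <- matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("mz", "intensity")))
  if (n < 3) return(empty)
  if (any(diff(mz_grid) <= 0)) icpd_stop("mz_grid must be strictly ascending")
  x <- as.numeric(intensities)
  i <- 2:(n - 1)
  apex <- i[x[i] > x[i - 1] & x[i] > x[i + 1] & x[i] > floor & x[i] > 0]
  if (length(apex) == 0) return(empty)
  mz <- vapply(apex, function(j) {
    k <- (j - 1):(j + 1)
    sum(mz_grid[k] * x[k]) / sum(x[k])
  }, numeric(1))
  cbind(mz = mz, intensity = x[apex])
}
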