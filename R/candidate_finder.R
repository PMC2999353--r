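# Candidate generation: centroid collection, ppm binning, elution
# segmentation, duplicate merging and charge-state expansion.

#' Flatten an LC/MS map into one centroid table
#'
#' @param map An [lcms_map()].
#' @return Data frame with one row per centroid peak: `scan` (0-based), `mz`,
#'   `intensity`.
#' @export
collect_centroids <- function(map) {
  if (!inherits(map, "lcms_map")) icpd_stop("map must be an lcms_map")
  ns <- n_scans(map)
  if (ns == 0)
    return(data.frame(scan = integer(0), mz = numeric(0), intensity = numeric(0)))
  nr <- vapply(map$peaks, nrow, integer(1))
  data.frame(
    scan = rep(0:(ns - 1L), nr),
    mz = unlist(lapply(map$peaks, function(p) p[, 1]), use.names = FALSE),
    intensity = unlist(lapply(map$peaks, function(p) p[, 2]), use.names = FALSE))
}

#' Group centroid m/z values into ppm-width bins
#'
#' Centroids are sorted by m/z and partitioned greedily: a new bin starts when
#' the next m/z exceeds the current bin's anchor (its first member) by more
#' than `2 * dmz` ppm. Each bin's upper edge is then extended by `dmz` ppm
#' into the following bin, so a centroid near a bin boundary may belong to
#' two bins; the duplicate candidates this creates are removed later by the
#' merging step of [make_mzlist()].
#'
#' @param centroids Data frame from [collect_centroids()].
#' @param dmz ppm tolerance (half-width of the instrument mass accuracy).
#' @return Object of class `mz_bins`: list with `centroids` (sorted by m/z)
#'   and `bins`, a list of integer index vectors into `centroids`.
#' @export
bin_mz <- function(centroids, dmz) {
  if (!is.finite(dmz) || dmz <= 0) icpd_stop("dmz must be > 0")
  n <- nrow(centroids)
  if (n == 0)
    return(structure(list(centroids = centroids, bins = list()), class = "mz_bins"))
  cent <- centroids[order(centroids$mz, centroids$scan), , drop = FALSE]
  rownames(cent) <- NULL
  mz <- cent$mz
  bin_id <- integer(n)
  anchor <- mz[1]; b <- 1L; bin_id[1] <- 1L
  if (n > 1) for (i in 2:n) {
    if (mz[i] > anchor * (1 + 2e-6 * dmz)) { b <- b + 1L; anchor <- mz[i] }
    bin_id[i] <- b
  }
  base <- split(seq_len(n), bin_id)
  bins <- lapply(seq_along(base), function(k) {
    idx <- base[[k]]
    if (k < length(base)) {
      edge <- mz[idx[length(idx)]] * (1 + 1e-6 * dmz)
      nxt <- base[[k + 1]]
      idx <- c(idx, nxt[mz[nxt] <= edge])
    }
    idx
  })
  structure(list(centroids = cent, bins = bins), class = "mz_bins")
}

#' @export
print.mz_bins <- function(x, ...) {
  cat(sprintf("<mz_bins> %d centroids in %d bins\n", nrow(x$centroids), length(x$bins)))
  invisible(x)
}

#' Extracted ion chromatogram of one m/z bin
#'
#' @param bins An `mz_bins` object from [bin_mz()].
#' @param which Bin number.
#' @param map The [lcms_map()] the centroids came from (supplies the scan
#'   count).
#' @return Numeric intensity trace indexed by scan (position `t + 1` holds
#'   scan `t`); member centroid intensities falling in the same scan are
#'   summed, scans without members are 0.
#' @export
bin_xic <- function(bins, which, map) {
  if (!inherits(bins, "mz_bins")) icpd_stop("bins must come from bin_mz()")
  if (which < 1 || which > length(bins$bins)) icpd_stop("no such bin: ", which)
  idx <- bins$bins[[which]]
  trace <- numeric(n_scans(map))
  if (length(idx)) {
    m <- bins$centroids[idx, ]
    agg <- rowsum(m$intensity, group = m$scan)
    trace[as.integer(rownames(agg)) + 1L] <- agg[, 1]
  }
  trace
}

#' Segment an elution trace into candidate elution windows
#'
#' Maximal runs of non-zero values are located; runs separated by at most `g`
#' consecutive zero scans are merged (interior zeros are kept inside the
#' window); merged runs containing fewer than `s` non-zero values are
#' discarded.
#'
#' @param trace Numeric intensity trace (position `t + 1` = scan `t`).
#' @param s Minimum number of non-zero scans in a segment (lower bound on LC
#'   peak width; small values such as 2-3 avoid missing narrow peptides).
#' @param g Maximum gap (zero scans) bridged when merging runs, e.g. scans
#'   lost to interleaved fragmentation duty cycles.
#' @return Data frame with columns `rt_start`, `rt_end`: inclusive 0-based
#'   scan indices, one row per segment.
#' @export
#' @examples
#' extract_segments(c(0, 5, 7, 0, 0, 3, 4, 0), s = 2, g = 1)
extract_segments <- function(trace, s, g) {
  if (!is.finite(s) || s < 1) icpd_stop("s must be >= 1")
  if (!is.finite(g) || g < 0) icpd_stop("g must be >= 0")
  nz <- trace != 0
  if (!any(nz)) return(data.frame(rt_start = integer(0), rt_end = integer(0)))
  r <- rle(nz)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
    gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
    if (gap <= g) merged$end[nrow(merged)] <- runs$end[i]
    else merged <- rbind(merged, runs[i, ])
  }
  nz_count <- vapply(seq_len(nrow(merged)),
                     function(i) sum(nz[merged$start[i]:merged$end[i]]), integer(1))
  merged <- merged[nz_count >= s, , drop = FALSE]
  data.frame(rt_start = merged$start - 1L, rt_end = merged$end - 1L)
}

#' Build the m/z candidate list of an LC/MS map
#'
#' Runs ppm binning ([bin_mz()]), per-bin elution extraction and segmentation
#' ([extract_segments()]) and emits one candidate per bin segment with an
#' intensity-weighted mean m/z recalculated from the member centroids inside
#' the segment. Candidates whose m/z values agree within `dmz` ppm and whose
#' elution windows share at least one scan are then merged (union window,
#' intensity-weighted mean m/z), repeatedly until a fixpoint, which removes
#' the duplicates created by bin overlap while keeping same-m/z peptides that
#' elute at different times separate.
#'
#' @param map An [lcms_map()].
#' @param dmz ppm tolerance.
#' @param s,g Segmentation parameters, see [extract_segments()].
#' @return Data frame (`mzlist`) with columns `mz`, `rt_start`, `rt_end`,
#'   `intensity` (summed segment intensity), sorted by (`mz`, `rt_start`).
#' @export
make_mzlist <- function(map, dmz = 10, s = 3, g = 2) {
  cent <- collect_centroids(map)
  bins <- bin_mz(cent, dmz)
  ns <- n_scans(map)
  out <- vector("list", length(bins$bins))
  for (k in seq_along(bins$bins)) {
    idx <- bins$bins[[k]]
    m <- bins$centroids[idx, ]
    trace <- numeric(ns)
    agg <- rowsum(m$intensity, group = m$scan)
    trace[as.integer(rownames(agg)) + 1L] <- agg[, 1]
    seg <- extract_segments(trace, s, g)
    if (nrow(seg) == 0) next
    out[[k]] <- do.call(rbind, lapply(seq_len(nrow(seg)), function(i) {
      inseg <- m$scan >= seg$rt_start[i] & m$scan <= seg$rt_end[i]
      w <- m$intensity[inseg]
      data.frame(mz = sum(m$mz[inseg] * w) / sum(w),
                 rt_start = seg$rt_start[i], rt_end = seg$rt_end[i],
                 intensity = sum(w))
    }))
  }
  cand <- do.call(rbind, out)
  if (is.null(cand))
    return(data.frame(mz = numeric(0), rt_start = integer(0),
                      rt_end = integer(0), intensity = numeric(0)))
  merge_mz_candidates(cand, dmz)
}

#' Merge duplicate m/z candidates
#'
#' One pass of the [make_mzlist()] merging rule applied to fixpoint:
#' candidates within `dmz` ppm in m/z whose windows overlap by >= 1 scan are
#' combined. Idempotent: applying it to its own output changes nothing.
#'
#' @param mzlist Data frame with columns `mz`, `rt_start`, `rt_end`,
#'   `intensity`.
#' @param dmz ppm tolerance.
#' @return Merged data frame, sorted by (`mz`, `rt_start`).
#' @export
merge_mz_candidates <- function(mzlist, dmz) {
  repeat {
    o <- order(mzlist$mz, mzlist$rt_start)
    mzlist <- mzlist[o, , drop = FALSE]
    rownames(mzlist) <- NULL
    n <- nrow(mzlist)
    if (n < 2) break
    keep <- rep(TRUE, n)
    changed <- FALSE
    for (i in seq_len(n - 1)) {
      if (!keep[i]) next
      j <- i + 1L
      while (j <= n && mzlist$mz[j] <= mzlist$mz[i] * (1 + 1e-6 * dmz)) {
        if (keep[j] &&
            max(mzlist$rt_start[i], mzlist$rt_start[j]) <=
            min(mzlist$rt_end[i], mzlist$rt_end[j])) {
          wi <- mzlist$intensity[i]; wj <- mzlist$intensity[j]
          mzlist$mz[i] <- (mzlist$mz[i] * wi + mzlist$mz[j] * wj) / (wi + wj)
          mzlist$rt_start[i] <- min(mzlist$rt_start[i], mzlist$rt_start[j])
          mzlist$rt_end[i] <- max(mzlist$rt_end[i], mzlist$rt_end[j])
          mzlist$intensity[i] <- wi + wj
          keep[j] <- FALSE
          changed <- TRUE
        }
        j <- j + 1L
      }
    }
    mzlist <- mzlist[keep, , drop = FALSE]
    if (!changed) break
  }
  rownames(mzlist) <- NULL
  mzlist
}

#' Expand m/z candidates over charge-state hypotheses
#'
#' Every m/z candidate is assumed in turn to be the monoisotopic peak of a
#' peptide at each charge state 1..CS; the neutral mass under hypothesis `cs`
#' is `mz * cs - cs * w_p`.
#'
#' @param mzlist Data frame from [make_mzlist()].
#' @param CS Maximum charge state considered (default 4).
#' @return Data frame (`masslist`) with `CS * nrow(mzlist)` rows and columns
#'   `mass`, `cs`, `rt_start`, `rt_end`, `source_mz`.
#' @export
expand_charge_states <- function(mzlist, CS = 4) {
  if (!is.finite(CS) || CS < 1) icpd_stop("CS must be >= 1")
  CS <- as.integer(CS)
  n <- nrow(mzlist)
  if (n == 0)
    return(data.frame(mass = numeric(0), cs = integer(0), rt_start = integer(0),
                      rt_end = integer(0), source_mz = numeric(0)))
  cs <- rep(seq_len(CS), each = n)
  data.frame(mass = rep(mzlist$mz, CS) * cs - cs * .icpd$proton_mass,
             cs = cs,
             rt_start = rep(mzlist$rt_start, CS),
             rt_end = rep(mzlist$rt_end, CS),
             source_mz = rep(mzlist$mz, CS))
}

#' Write a charge-expanded candidate list to tsv
#' @param masslist Data frame from [expand_charge_states()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_masslist <- function(masslist, path) {
  utils::write.table(
    masslist[, c("mass", "cs", "rt_start", "rt_end", "source_mz")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
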