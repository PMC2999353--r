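# Core detector: trace-grid extraction, information combining across scans
# and charge states, likelihood-based isotope matching, and the full
# detection pipeline.

#' Extract the charge-by-isotope trace grid of one peptide candidate
#'
#' For a candidate (neutral mass hypothesis + elution window), sums centroid
#' intensities falling inside the half-open ppm window around
#' `mz_of(mass, cs, iso)` for every scan of the window, charge state 1..CS
#' and isotope position 0..n_iso-1.
#'
#' @param map An [lcms_map()].
#' @param candidate One-row data frame (or list) with `mass`, `rt_start`,
#'   `rt_end` (inclusive 0-based scan indices).
#' @param dmz ppm tolerance.
#' @param CS Maximum charge state.
#' @param n_iso Number of isotope positions.
#' @return Object of class `trace_grid`: list with `y` (array of dimension
#'   time x CS x n_iso), `candidate`, `dmz`.
#' @export
extract_trace_grid <- function(map, candidate, dmz = 10, CS = 4, n_iso = 5) {
  rs <- candidate$rt_start; re <- candidate$rt_end
  if (rs < 0 || re > n_scans(map) - 1 || rs > re)
    icpd_stop("candidate window [", rs, ", ", re, "] outside map scan range")
  mzmat <- outer(seq_len(CS), 0:(n_iso - 1),
                 function(cs, iso) mz_of(candidate$mass, cs, iso))
  lo <- as.vector(mzmat) * (1 - dmz * 1e-6)
  hi <- as.vector(mzmat) * (1 + dmz * 1e-6)
  nt <- re - rs + 1L
  y <- array(0, dim = c(nt, CS, n_iso))
  for (t in rs:re) {
    p <- map$peaks[[t + 1L]]
    if (nrow(p) == 0) next
    csum <- c(0, cumsum(p[, 2]))
    a <- findInterval(lo, p[, 1], left.open = TRUE)  # peaks strictly below lo
    b <- findInterval(hi, p[, 1], left.open = TRUE)  # peaks strictly below hi
    y[t - rs + 1L, , ] <- csum[b + 1L] - csum[a + 1L]
  }
  structure(list(y = y, candidate = candidate, dmz = dmz), class = "trace_grid")
}

# Bulk trace-grid extraction for many candidates at once.  All (scan, window)
# queries are encoded on a single sorted key axis (scan * KEY + mz) so two
# findInterval calls against the flattened map answer every window sum.
# Equivalent to calling extract_trace_grid() per candidate, but vastly faster.
.extract_grids_bulk <- function(map, masslist, dmz = 10, CS = 4, n_iso = 5,
                                chunk = 2000L) {
  nC <- nrow(masslist)
  if (nC == 0) return(list())
  cent <- collect_centroids(map)
  KEY <- 1e5  # > any m/z in practice; keeps the combined key strictly ordered
  if (nrow(cent) > 0 && max(cent$mz) >= KEY) icpd_stop("m/z exceeds key range")
  keys <- cent$scan * KEY + cent$mz         # already sorted (scan asc, mz asc)
  csum <- c(0, cumsum(cent$intensity))
  grids <- vector("list", nC)
  for (c0 in seq(1L, nC, by = chunk)) {
    c1 <- min(c0 + chunk - 1L, nC)
    ids <- c0:c1
    nt <- masslist$rt_end[ids] - masslist$rt_start[ids] + 1L
    ncell <- nt * CS * n_iso
    # per candidate, linear cell order is (t fastest, then cs, then iso),
    # matching array(dim = c(nt, CS, n_iso))
    win_per_cand <- lapply(ids, function(i) {
      as.vector(outer(seq_len(CS), 0:(n_iso - 1),
                      function(cs, iso) mz_of(masslist$mass[i], cs, iso)))
    })
    mzq <- unlist(lapply(seq_along(ids), function(k)
      rep(win_per_cand[[k]], each = nt[k])), use.names = FALSE)
    scq <- unlist(lapply(seq_along(ids), function(k)
      rep.int(masslist$rt_start[ids[k]]:masslist$rt_end[ids[k]], CS * n_iso)),
      use.names = FALSE)
    qlo <- scq * KEY + mzq * (1 - dmz * 1e-6)
    qhi <- scq * KEY + mzq * (1 + dmz * 1e-6)
    a <- findInterval(qlo, keys, left.open = TRUE)
    b <- findInterval(qhi, keys, left.open = TRUE)
    sums <- csum[b + 1L] - csum[a + 1L]
    off <- cumsum(c(0, ncell))
    for (k in seq_along(ids)) {
      grids[[ids[k]]] <- structure(
        list(y = array(sums[(off[k] + 1L):off[k + 1L]],
                       dim = c(nt[k], CS, n_iso)),
             candidate = masslist[ids[k], , drop = FALSE], dmz = dmz),
        class = "trace_grid")
    }
  }
  grids
}

#' Estimate the elution profile of a candidate from its trace grid
#'
#' The profile is the scan-wise total of the grid (summed over charge states
#' and isotope positions), normalised to sum 1. An all-zero grid yields a
#' flagged empty profile.
#'
#' @param grid A `trace_grid`.
#' @return Object of class `elution_profile`: list with `C` (non-negative,
#'   sums to 1, or all zeros) and `empty` flag.
#' @export
estimate_elution_profile <- function(grid) {
  m <- matrix(grid$y, nrow = dim(grid$y)[1])
  tot <- rowSums(m)
  s <- sum(tot)
  if (s <= 0)
    return(structure(list(C = tot, empty = TRUE), class = "elution_profile"))
  structure(list(C = tot / s, empty = FALSE), class = "elution_profile")
}

#' Combine grid observations into one isotope-pattern estimate
#'
#' Implements the information-combining step: the grid is summed over charge
#' states (the charge-state distribution sums to one, so it cancels) and
#' combined over scans with matched-filter weights `w(t) = C(t) / sum(C^2)`.
#' Under the signal model the result `y_hat[iso]` has mean `A * f(iso)` with
#' coefficient exactly 1 -- a noise-corrupted copy of the isotope pattern --
#' and the matched filter is the minimum-variance linear combination under
#' i.i.d. per-cell noise. The abundance estimate is `A_hat = sum(y_hat)`.
#'
#' @param grid A `trace_grid`.
#' @param profile An `elution_profile` (typically from
#'   [estimate_elution_profile()]; pass the true profile for estimator
#'   contract checks).
#' @return Object of class `combined_pattern`: list with `y_hat` (length
#'   n_iso), `A_hat`, `n_obs` (grid cells), `w2sum` (`sum(w^2)`, the
#'   per-charge noise-variance gain of the filter) and `empty` flag.
#' @export
combine_observations <- function(grid, profile) {
  niso <- dim(grid$y)[3]
  if (profile$empty)
    return(structure(list(y_hat = numeric(niso), A_hat = 0,
                          n_obs = length(grid$y), w2sum = 0, empty = TRUE),
                     class = "combined_pattern"))
  w <- profile$C / sum(profile$C^2)
  cs_summed <- apply(grid$y, c(1, 3), sum)       # time x iso
  y_hat <- as.numeric(crossprod(cs_summed, w))
  structure(list(y_hat = y_hat, A_hat = sum(y_hat),
                 n_obs = length(grid$y), w2sum = sum(w^2), empty = FALSE),
            class = "combined_pattern")
}

#' Single-scan isotope-pattern estimate (baseline)
#'
#' The baseline used by scan-at-a-time detectors: pick the single
#' (scan, charge) row of the grid with the largest summed intensity, use its
#' isotope vector directly as the pattern estimate, and take the highest
#' single peak intensity of that row as the abundance estimate.
#'
#' @param grid A `trace_grid`.
#' @return A `combined_pattern` (with `n_obs = n_iso`, `w2sum = 1`).
#' @export
single_scan_pattern <- function(grid) {
  d <- dim(grid$y)
  m <- matrix(grid$y, nrow = d[1] * d[2])        # (t, cs) rows x iso cols
  tot <- rowSums(m)
  niso <- d[3]
  if (max(tot) <= 0)
    return(structure(list(y_hat = numeric(niso), A_hat = 0, n_obs = niso,
                          w2sum = 1, empty = TRUE), class = "combined_pattern"))
  y_hat <- m[which.max(tot), ]
  structure(list(y_hat = y_hat, A_hat = max(y_hat), n_obs = niso,
                 w2sum = 1, empty = FALSE), class = "combined_pattern")
}

#' Calibrate the power-law noise-variance constant
#'
#' The per-candidate noise variance is modelled as `sigma'^2 = c * A_hat^p`.
#' The constant `c` is estimated robustly as the median over candidates of
#' the mean squared isotope residual divided by `A_hat^p`.
#'
#' @param patterns List of `combined_pattern` objects.
#' @param f_theo List of matching theoretical patterns ([theoretical_pattern()]
#'   objects or plain `f_iso` vectors).
#' @param p Noise exponent (1, 2 or 3).
#' @return Strictly positive scalar `c`.
#' @export
calibrate_noise_constant <- function(patterns, f_theo, p) {
  if (!p %in% c(1, 2, 3)) icpd_stop("p must be 1, 2 or 3")
  A <- vapply(patterns, function(x) x$A_hat, numeric(1))
  ok <- which(A > 0)
  if (length(ok) < 10)
    icpd_stop("need >= 10 candidates with positive abundance to calibrate c; ",
              "supply c manually")
  ratio <- vapply(ok, function(i) {
    f <- f_theo[[i]]
    if (inherits(f, "theoretical_pattern")) f <- f$f_iso
    mean((patterns[[i]]$y_hat - patterns[[i]]$A_hat * f)^2) / patterns[[i]]$A_hat^p
  }, numeric(1))
  c_hat <- stats::median(ratio)
  if (c_hat <= 0) {
    c_hat <- 1e-12 * max(A)^p     # degenerate (e.g. noise-free) input: floor
    if (c_hat <= 0) icpd_stop("all abundances zero; cannot calibrate c")
    warning("all median residuals are zero; noise constant floored at ",
            format(c_hat), call. = FALSE)
  }
  c_hat
}

#' Noise model for the matching score
#' @param p Noise exponent, one of 1, 2, 3 (variance `sigma'^2 = c * A^p`).
#' @param c Proportionality constant, > 0.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(p = 3, c) {
  if (!p %in% c(1, 2, 3)) icpd_stop("p must be 1, 2 or 3")
  if (!is.finite(c) || c <= 0) icpd_stop("c must be > 0")
  structure(list(p = p, c = c), class = "noise_model")
}

#' Isotope-pattern matching score
#'
#' Gaussian log-likelihood that the combined observation `y_hat` arose from a
#' peptide with theoretical pattern `f` and abundance `A_hat`, under per-iso
#' noise variance `sigma'^2 = c * max(A_hat, A_floor)^p`. By default only the
#' standardized mismatch (the exponent) is returned,
#' `-(1/2) sum((y_hat - A_hat f)^2) / sigma'^2`, whose maximum over `y_hat`
#' is 0 for every candidate; this makes one threshold comparable across
#' candidates of different abundance. `normalized = TRUE` adds the Gaussian
#' normalisation term `-(n_iso/2) log(2 pi sigma'^2)` giving the full
#' log-density (monotone-equivalent per candidate, but it adds a
#' `-(n_iso p / 2) log A_hat` offset across candidates).
#'
#' @param pattern A `combined_pattern`.
#' @param f_theo A [theoretical_pattern()] or plain `f_iso` vector.
#' @param noise A [noise_model()].
#' @param A_floor Abundance floor used inside the variance (prevents a zero
#'   variance for empty candidates); typically the smallest positive
#'   intensity of the map.
#' @param normalized Include the log-normalisation term (default `FALSE`).
#' @return Scalar score (higher = more peptide-like); `-Inf` for an empty
#'   pattern (`A_hat = 0`).
#' @export
matching_score <- function(pattern, f_theo, noise, A_floor = .Machine$double.eps,
                           normalized = FALSE) {
  if (pattern$A_hat <= 0 || isTRUE(pattern$empty)) return(-Inf)
  f <- if (inherits(f_theo, "theoretical_pattern")) f_theo$f_iso else f_theo
  if (length(f) != length(pattern$y_hat))
    icpd_stop("theoretical pattern length does not match y_hat")
  sigma2 <- noise$c * max(pattern$A_hat, A_floor)^noise$p
  score <- -sum((pattern$y_hat - pattern$A_hat * f)^2) / (2 * sigma2)
  if (normalized) score <- score - length(f) / 2 * log(2 * pi * sigma2)
  score
}

#' Single-scan baseline matching score
#'
#' Scores the [single_scan_pattern()] of the grid with [matching_score()]:
#' the isotope pattern is estimated from the one (scan, charge) with the
#' highest summed intensity and the abundance from its highest single peak,
#' without combining information across scans or charge states.
#'
#' @inheritParams matching_score
#' @param grid A `trace_grid`.
#' @return Scalar score; `-Inf` for an all-zero grid.
#' @export
single_scan_score <- function(grid, f_theo, noise, A_floor = .Machine$double.eps,
                              normalized = FALSE) {
  matching_score(single_scan_pattern(grid), f_theo, noise,
                 A_floor = A_floor, normalized = normalized)
}

#' Detect peptide features in an LC/MS map
#'
#' The full detection pipeline: build the m/z candidate list
#' ([make_mzlist()]), expand charge-state hypotheses
#' ([expand_charge_states()]), extract each candidate's charge-by-isotope
#' trace grid, combine the observations across scans and charge states
#' ([combine_observations()]), calibrate the power-law noise constant
#' (unless `c` is given) and score every candidate against its theoretical
#' averagine pattern. The single-scan baseline score is computed alongside
#' with its own noise calibration. Thresholding is left to the caller: the
#' returned table carries all candidates sorted by descending score.
#'
#' @param map An [lcms_map()].
#' @param dmz Mass accuracy window, ppm (default 10).
#' @param s Minimum non-zero scans per elution segment (default 3).
#' @param g Maximum bridged gap in scans (default 2).
#' @param CS Maximum charge state (default 4).
#' @param n_iso Isotope positions modelled (default 5).
#' @param p Noise exponent in `sigma'^2 = c * A_hat^p` (default 3).
#' @param c Optional fixed noise constant; calibrated from the data when
#'   `NULL`.
#' @param normalized Use the full Gaussian log-density instead of the
#'   standardized mismatch (see [matching_score()]).
#' @return Object of class `icpd`: list with `outlist` (data frame `mass`,
#'   `cs`, `rt_start`, `rt_end`, `source_mz`, `score`, `single_scan_score`,
#'   `volume`, `max_intensity`, `A_hat`, sorted by descending `score`),
#'   `params`, `noise` (calibrated constants), and the per-candidate
#'   combined patterns needed to re-score under other `p` values.
#' @seealso [score_sweep()], [sweep_curves()], [simulate_map()]
#' @export
#' @examples
#' bm <- make_benchmark("noise_free")
#' fit <- icpd(bm$map)
#' fit
icpd <- function(map, dmz = 10, s = 3, g = 2, CS = 4, n_iso = 5, p = 3,
                 c = NULL, normalized = FALSE) {
  if (!inherits(map, "lcms_map")) icpd_stop("map must be an lcms_map")
  params <- list(dmz = dmz, s = s, g = g, CS = CS, n_iso = n_iso, p = p,
                 normalized = normalized)
  mzlist <- make_mzlist(map, dmz = dmz, s = s, g = g)
  masslist <- expand_charge_states(mzlist, CS = CS)
  n <- nrow(masslist)
  cent <- collect_centroids(map)
  A_floor <- if (any(cent$intensity > 0)) min(cent$intensity[cent$intensity > 0])
             else .Machine$double.eps
  if (n == 0) {
    out <- cbind(masslist, score = numeric(0), single_scan_score = numeric(0),
                 volume = numeric(0), max_intensity = numeric(0),
                 A_hat = numeric(0))
    return(structure(list(outlist = out, params = params,
                          noise = list(p = p, c = NA_real_, c_single = NA_real_),
                          A_floor = A_floor, Y = NULL, F = NULL, n_candidates = 0L),
                     class = "icpd"))
  }
  grids <- .extract_grids_bulk(map, masslist, dmz = dmz, CS = CS, n_iso = n_iso)
  Y <- matrix(0, n, n_iso)      # combined patterns
  Yss <- matrix(0, n, n_iso)    # single-scan patterns
  A <- numeric(n); Ass <- numeric(n)
  volume <- numeric(n); max_int <- numeric(n)
  F <- matrix(0, n, n_iso)
  for (i in seq_len(n)) {
    g_i <- grids[[i]]
    volume[i] <- sum(g_i$y)
    max_int[i] <- if (length(g_i$y)) max(g_i$y) else 0
    pat <- combine_observations(g_i, estimate_elution_profile(g_i))
    Y[i, ] <- pat$y_hat; A[i] <- pat$A_hat
    ss <- single_scan_pattern(g_i)
    Yss[i, ] <- ss$y_hat; Ass[i] <- ss$A_hat
    F[i, ] <- theoretical_pattern(masslist$mass[i], n_iso)$f_iso
  }
  cal <- .calibrate_matrix(Y, A, F, p, given = c)
  cal_ss <- .calibrate_matrix(Yss, Ass, F, p, given = NULL)
  score <- .score_matrix(Y, A, F, p, cal, A_floor, n_iso, normalized)
  score_ss <- .score_matrix(Yss, Ass, F, p, cal_ss, A_floor, n_iso, normalized)
  out <- cbind(masslist,
               score = score, single_scan_score = score_ss,
               volume = volume, max_intensity = max_int, A_hat = A)
  o <- order(-out$score, out$mass)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  structure(list(outlist = out, params = params,
                 noise = list(p = p, c = cal, c_single = cal_ss),
                 A_floor = A_floor,
                 Y = Y[o, , drop = FALSE], F = F[o, , drop = FALSE],
                 A = A[o], Yss = Yss[o, , drop = FALSE], Ass = Ass[o],
                 n_candidates = n),
            class = "icpd")
}

# Vectorised calibration / scoring over pattern matrices.
.calibrate_matrix <- function(Y, A, F, p, given = NULL) {
  if (!is.null(given)) {
    if (!is.finite(given) || given <= 0) icpd_stop("c must be > 0")
    return(given)
  }
  ok <- A > 0
  if (sum(ok) < 10)
    icpd_stop("need >= 10 candidates with positive abundance to calibrate c; ",
              "supply c manually")
  resid <- rowMeans((Y[ok, , drop = FALSE] - A[ok] * F[ok, , drop = FALSE])^2)
  c_hat <- stats::median(resid / A[ok]^p)
  if (c_hat <= 0) {
    c_hat <- 1e-12 * max(A)^p
    warning("median residual is zero; noise constant floored at ",
            format(c_hat), call. = FALSE)
  }
  c_hat
}

.score_matrix <- function(Y, A, F, p, c_hat, A_floor, n_iso, normalized) {
  sigma2 <- c_hat * pmax(A, A_floor)^p
  sc <- -rowSums((Y - A * F)^2) / (2 * sigma2)
  if (normalized) sc <- sc - n_iso / 2 * log(2 * pi * sigma2)
  sc[A <= 0] <- -Inf
  sc
}

#' Re-score a detection under other noise exponents
#'
#' Uses the combined patterns stored in the fit to recompute the matching
#' score (with a fresh calibration of `c`) for each requested exponent,
#' without re-extracting the map.
#'
#' @param fit An [icpd()] object.
#' @param p_values Noise exponents to score under (subset of 1:3).
#' @return Matrix with one column per exponent (named `p1`, `p2`, ...), rows
#'   aligned with `fit$outlist`.
#' @export
score_sweep <- function(fit, p_values = c(1, 2, 3)) {
  if (!inherits(fit, "icpd")) icpd_stop("fit must be an icpd object")
  if (fit$n_candidates == 0) icpd_stop("fit has no candidates")
  out <- sapply(p_values, function(p) {
    c_p <- .calibrate_matrix(fit$Y, fit$A, fit$F, p)
    .score_matrix(fit$Y, fit$A, fit$F, p, c_p, fit$A_floor,
                  ncol(fit$Y), fit$params$normalized)
  })
  colnames(out) <- paste0("p", p_values)
  out
}

#' @export
print.icpd <- function(x, ...) {
  cat(sprintf("<icpd> %d scored candidates (dmz %g ppm, CS %d, n_iso %d, p %d)\n",
              x$n_candidates, x$params$dmz, x$params$CS, x$params$n_iso,
              x$noise$p))
  if (x$n_candidates > 0) {
    cat(sprintf("  noise constant c = %.4g (single-scan %.4g)\n",
                x$noise$c, x$noise$c_single))
    cat("  top candidates:\n")
    print(utils::head(x$outlist[, c("mass", "cs", "rt_start", "rt_end",
                                    "score", "volume")], 5), digits = 6)
  }
  invisible(x)
}

#' @export
summary.icpd <- function(object, ...) {
  s <- object$outlist$score
  structure(list(n = object$n_candidates, params = object$params,
                 noise = object$noise,
                 score_quantiles = if (length(s))
                   stats::quantile(s[is.finite(s)],
                                   c(0, .25, .5, .75, .9, .99, 1)) else NULL),
            class = "summary.icpd")
}

#' @export
print.summary.icpd <- function(x, ...) {
  cat(sprintf("ICPD detection summary: %d candidates, p = %d, c = %.4g\n",
              x$n, x$noise$p, x$noise$c))
  if (!is.null(x$score_quantiles)) {
    cat("score quantiles:\n")
    print(signif(x$score_quantiles, 4))
  }
  invisible(x)
}

#' @export
as.data.frame.icpd <- function(x, ...) x$outlist

#' Plot a detection result
#'
#' Score against peak volume (log10) for every candidate; a threshold on the
#' matching score is a horizontal cut.
#'
#' @param x An [icpd()] object.
#' @param threshold Optional score threshold drawn as a horizontal line.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.icpd <- function(x, threshold = NULL, ...) {
  ol <- x$outlist
  keep <- is.finite(ol$score) & ol$volume > 0
  graphics::plot(log10(ol$volume[keep]), ol$score[keep],
                 xlab = "log10 peak volume", ylab = "isotope matching score",
                 pch = 20, col = grDevices::grey(0.3, 0.5), ...)
  if (!is.null(threshold)) graphics::abline(h = threshold, col = 2, lty = 2)
  invisible(x)
}

#' Write a scored candidate list to tsv
#'
#' Columns `mass cs rt_start rt_end score volume max_intensity` (plus
#' `single_scan_score`, `source_mz`, `A_hat`), sorted by descending score.
#'
#' @param x An [icpd()] object or its `outlist` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_outlist <- function(x, path) {
  ol <- if (inherits(x, "icpd")) x$outlist else x
  utils::write.table(ol, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a scored candidate list written by [write_outlist()]
#' @param path File path.
#' @return Data frame.
#' @export
read_outlist <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("mass", "cs", "rt_start", "rt_end", "score")
  miss <- setdiff(need, names(d))
  if (length(miss)) icpd_stop("outlist missing column(s): ",
                              paste(miss, collapse = ", "))
  d
}
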