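# Ground-truth LC/MS simulator implementing the generative signal model:
# each peptide elutes according to an elution distribution, disperses over
# charge states and isotope positions, and every emitted cell is corrupted by
# additive noise whose variance follows a power law of abundance.

.elution_shapes <- c("gaussian", "exp_mod_gaussian", "asymmetric_triangle", "plateau")

#' Sample a chromatographic elution profile
#'
#' Produces a non-negative profile over scans summing to 1. Non-Gaussian
#' shapes matter because a large share of real LC peaks (tailing, plateauing,
#' narrow spikes) do not conform to a Gaussian, and the detector makes no
#' shape assumption.
#'
#' @param shape One of `"gaussian"` (FWHM = `width`), `"exp_mod_gaussian"`
#'   (Gaussian rise with exponential tail), `"asymmetric_triangle"` (fast
#'   rise, slow fall) or `"plateau"` (flat top of `width` scans). Hyphens may
#'   be used instead of underscores.
#' @param apex Apex scan (0-based, may be fractional), within the scan range.
#' @param width Characteristic width in scans, >= used as FWHM/plateau/ramp
#'   scale; >= 1 except for the delta-like Gaussian limit.
#' @param n_scans Number of scans.
#' @return Numeric vector of length `n_scans`, entries >= 0, summing to 1.
#' @export
#' @examples
#' sample_elution("plateau", apex = 10, width = 4, n_scans = 20)
sample_elution <- function(shape, apex, width, n_scans) {
  shape <- gsub("-", "_", as.character(shape))
  if (!shape %in% .elution_shapes)
    icpd_stop("unknown elution shape: ", shape,
              " (use one of ", paste(.elution_shapes, collapse = ", "), ")")
  if (!is.finite(apex) || apex < 0 || apex > n_scans - 1)
    icpd_stop("apex must lie within the scan range")
  if (!is.finite(width) || width < 0) icpd_stop("width must be >= 0")
  t <- 0:(n_scans - 1)
  v <- switch(shape,
    gaussian = {
      sd <- width / (2 * sqrt(2 * log(2)))
      if (sd < 1e-8) { d <- numeric(n_scans); d[round(apex) + 1] <- 1; d }
      else exp(-(t - apex)^2 / (2 * sd^2))
    },
    exp_mod_gaussian = {
      sd <- max(width / 4, 1e-8); tau <- max(width / 2, 1e-8)
      z <- (t - apex) / sd - sd / tau
      d <- exp(sd^2 / (2 * tau^2) - (t - apex) / tau) * stats::pnorm(z)
      d[!is.finite(d)] <- 0
      d
    },
    asymmetric_triangle = {
      rise <- max(0.3 * width, 0.5); fall <- max(0.7 * width, 0.5)
      pmax(0, ifelse(t <= apex, 1 - (apex - t) / rise, 1 - (t - apex) / fall))
    },
    plateau = {
      w <- max(1L, as.integer(round(width)))
      start <- round(apex) - (w %/% 2)
      as.numeric(t >= start & t < start + w)
    })
  v[v < 1e-3 * max(v)] <- 0   # peak bounds: support is the region >= 0.1% of apex
  if (sum(v) <= 0) { v <- numeric(n_scans); v[round(apex) + 1] <- 1 }
  v / sum(v)
}

#' Simulation configuration
#'
#' Collects everything [simulate_map()] needs. Peptides and contaminants may
#' be given as explicit tables or sampled; sampled values are drawn
#' deterministically from `seed`.
#'
#' @param n_scans Number of MS1 scans.
#' @param scan_interval Seconds between scans (default 1).
#' @param peptides Optional data frame with columns `mass`, `abundance`,
#'   `cs` (primary charge), `cs2_frac` (fraction dispersed to charge
#'   `cs + 1`), `shape`, `apex`, `width`, and optionally `tier`. Sampled when
#'   `NULL`.
#' @param n_peptides,mass_range,abundance_range Sampler settings used when
#'   `peptides` is `NULL` (abundances drawn log-uniformly).
#' @param contaminants Optional data frame with columns `kind` (one of
#'   `"single_spike"`, `"doublet"`, `"flat_multiplet"`), `mz`, `spacing_cs`,
#'   `abundance`, `shape`, `apex`, `width`. Sampled when `NULL` and
#'   `n_contaminants > 0`.
#' @param n_contaminants,contaminant_mz_range,contaminant_abundance_range
#'   Contaminant sampler settings.
#' @param noise List with `c`, `p` (per-cell variance `c * A^p` with `A` the
#'   feature's total abundance) and `baseline` (additive variance floor).
#' @param mz_jitter_ppm Gaussian ppm error applied to each emitted centroid's
#'   m/z (default `10/3`: one third of the default mass-accuracy window, so
#'   ~99.7% of centroids fall inside +-dmz).
#' @param drop_threshold Intensities at or below this value are not emitted
#'   (centroided data carry no explicit zeros).
#' @param CS,n_iso Charge-state / isotope-position ranges emulated.
#' @param seed Integer seed; a fixed seed yields a byte-identical map.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_scans = 60, scan_interval = 1, peptides = NULL,
                       n_peptides = 20, mass_range = c(700, 2500),
                       abundance_range = c(1e5, 1e6),
                       contaminants = NULL, n_contaminants = 0,
                       contaminant_mz_range = c(300, 1400),
                       contaminant_abundance_range = NULL,
                       noise = list(c = 0, p = 2, baseline = 0),
                       mz_jitter_ppm = 10 / 3, drop_threshold = 0,
                       CS = 4, n_iso = 5, seed = 1) {
  if (n_scans < 1) icpd_stop("n_scans must be >= 1")
  for (nm in c("c", "p", "baseline"))
    if (is.null(noise[[nm]])) icpd_stop("noise must supply c, p and baseline")
  if (is.null(contaminant_abundance_range))
    contaminant_abundance_range <- abundance_range
  structure(as.list(environment()), class = "sim_config")
}

# Run fn with a private, restored RNG stream.
.with_seed <- function(seed, fn) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else on.exit(if (exists(".Random.seed", globalenv(), inherits = FALSE))
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  fn()
}

.sample_peptides <- function(cfg) {
  n <- cfg$n_peptides
  if (n == 0)
    return(data.frame(mass = numeric(0), abundance = numeric(0),
                      cs = integer(0), cs2_frac = numeric(0),
                      shape = character(0), apex = numeric(0),
                      width = numeric(0)))
  data.frame(
    mass = stats::runif(n, cfg$mass_range[1], cfg$mass_range[2]),
    abundance = 10^stats::runif(n, log10(cfg$abundance_range[1]),
                                log10(cfg$abundance_range[2])),
    cs = pmin(sample(1:3, n, replace = TRUE, prob = c(0.3, 0.5, 0.2)), cfg$CS),
    cs2_frac = 0.3,
    shape = sample(.elution_shapes, n, replace = TRUE),
    apex = stats::runif(n, 0.1 * cfg$n_scans, 0.9 * cfg$n_scans - 1),
    width = stats::rlnorm(n, log(8), 0.25))
}

.sample_contaminants <- function(cfg) {
  n <- cfg$n_contaminants
  data.frame(
    kind = sample(c("single_spike", "doublet", "flat_multiplet"), n, replace = TRUE),
    mz = stats::runif(n, cfg$contaminant_mz_range[1], cfg$contaminant_mz_range[2]),
    spacing_cs = sample(1:2, n, replace = TRUE),
    abundance = 10^stats::runif(n, log10(cfg$contaminant_abundance_range[1]),
                                log10(cfg$contaminant_abundance_range[2])),
    shape = sample(.elution_shapes, n, replace = TRUE),
    apex = stats::runif(n, 0.1 * cfg$n_scans, 0.9 * cfg$n_scans - 1),
    width = stats::rlnorm(n, log(8), 0.25))
}

# m/z positions and weights of one contaminant feature.  None of the kinds
# carries an averagine-like envelope: a lone spike, a doublet at half the
# isotope spacing, or a flat four-peak multiplet.
.contaminant_positions <- function(kind, mz, spacing_cs) {
  wn <- .icpd$neutron_shift
  switch(as.character(kind),
    single_spike = list(pos = mz, w = 1),
    doublet = list(pos = c(mz, mz + 0.5 * wn / spacing_cs), w = c(0.6, 0.4)),
    flat_multiplet = list(pos = mz + (0:3) * wn / spacing_cs, w = rep(0.25, 4)),
    icpd_stop("unknown contaminant kind: ", kind))
}

#' Simulate a centroided LC/MS map with known ground truth
#'
#' For every peptide, centroid peaks are placed at
#' `mz_of(mass, cs, iso)` for each charge state and isotope position, with
#' intensity `A * C(t) * f(cs) * f(iso)` plus zero-mean Gaussian noise of
#' variance `c * A^p + baseline`; negative results are clamped to zero and
#' intensities at or below `drop_threshold` are omitted. Each emitted
#' centroid's m/z is jittered by a Gaussian ppm error. Contaminant features
#' without averagine-like isotope structure are added the same way. m/z
#' collisions between features are allowed (they happen in real maps) and
#' coincident centroids are summed.
#'
#' @param config A [sim_config()].
#' @return List with `map` (an [lcms_map()]) and `truth` (a `ground_truth`
#'   data frame: `mass`, `rt_start`, `rt_end`, `abundance`, `cs_dist`, plus
#'   `tier` when present; contaminant locations in
#'   `attr(truth, "contaminants")`).
#' @export
#' @examples
#' sim <- simulate_map(sim_config(n_peptides = 3, seed = 7))
#' sim$truth
simulate_map <- function(config) {
  if (!inherits(config, "sim_config")) icpd_stop("config must be a sim_config")
  .with_seed(config$seed, function() .simulate_map_impl(config))
}

.simulate_map_impl <- function(cfg) {
  pep <- if (is.null(cfg$peptides)) .sample_peptides(cfg) else cfg$peptides
  con <- if (!is.null(cfg$contaminants)) cfg$contaminants
         else if (cfg$n_contaminants > 0) .sample_contaminants(cfg) else NULL
  rows <- list()
  emit <- function(scan0, pos, expected, sd) {
    # expected: matrix scans x positions of model intensities
    nz <- expected > 0
    if (sd > 0) expected <- pmax(expected + stats::rnorm(length(expected), 0, sd), 0)
    expected[!nz] <- 0
    keep <- which(expected > cfg$drop_threshold & expected > 0, arr.ind = TRUE)
    if (nrow(keep) == 0) return(NULL)
    mz0 <- pos[keep[, 2]]
    data.frame(
      scan = scan0 + keep[, 1] - 1L,
      mz = mz0 * (1 + stats::rnorm(nrow(keep), 0, cfg$mz_jitter_ppm) * 1e-6),
      intensity = expected[keep])
  }
  truth <- NULL
  if (nrow(pep) > 0) {
    truth <- do.call(rbind, lapply(seq_len(nrow(pep)), function(i) {
      P <- pep[i, ]
      C <- sample_elution(P$shape, P$apex, P$width, cfg$n_scans)
      sup <- which(C > 0)
      f <- theoretical_pattern(P$mass, cfg$n_iso)$f_iso
      cs2 <- if (P$cs + 1 <= cfg$CS) P$cs2_frac else 0
      csw <- stats::setNames(c(1 - cs2, if (cs2 > 0) cs2),
                             c(P$cs, if (cs2 > 0) P$cs + 1))
      sd_i <- if (!is.null(P$noise_sd) && is.finite(P$noise_sd)) P$noise_sd
              else sqrt(cfg$noise$c * P$abundance^cfg$noise$p + cfg$noise$baseline)
      for (k in seq_along(csw)) {
        cs <- as.integer(names(csw)[k])
        pos <- mz_of(P$mass, cs, 0:(cfg$n_iso - 1))
        expected <- outer(P$abundance * C[sup] * csw[k], f)
        rows[[length(rows) + 1]] <<- emit(min(sup) - 1L, pos, expected, sd_i)
      }
      tr <- data.frame(mass = P$mass, rt_start = min(sup) - 1L,
                       rt_end = max(sup) - 1L, abundance = P$abundance,
                       cs_dist = paste(sprintf("%s:%.2f", names(csw), csw),
                                       collapse = "|"))
      if ("tier" %in% names(P)) tr$tier <- P$tier
      tr
    }))
  }
  if (!is.null(con) && nrow(con) > 0) {
    con$rt_start <- NA_integer_; con$rt_end <- NA_integer_
    for (i in seq_len(nrow(con))) {
      K <- con[i, ]
      C <- sample_elution(K$shape, K$apex, K$width, cfg$n_scans)
      sup <- which(C > 0)
      pw <- .contaminant_positions(K$kind, K$mz, K$spacing_cs)
      sd_i <- if (!is.null(K$noise_sd) && is.finite(K$noise_sd)) K$noise_sd
              else sqrt(cfg$noise$c * K$abundance^cfg$noise$p + cfg$noise$baseline)
      expected <- outer(K$abundance * C[sup], pw$w)
      rows[[length(rows) + 1]] <- emit(min(sup) - 1L, pw$pos, expected, sd_i)
      con$rt_start[i] <- min(sup) - 1L; con$rt_end[i] <- max(sup) - 1L
    }
  }
  d <- do.call(rbind, rows)
  peaks <- rep(list(matrix(numeric(0), ncol = 2)), cfg$n_scans)
  if (!is.null(d) && nrow(d) > 0) {
    byscan <- split(d[, c("mz", "intensity")], d$scan)
    for (nm in names(byscan))
      peaks[[as.integer(nm) + 1L]] <- as.matrix(byscan[[nm]])
  }
  map <- lcms_map(rt = (0:(cfg$n_scans - 1)) * cfg$scan_interval, peaks,
                  scan_interval = cfg$scan_interval)
  if (is.null(truth))
    truth <- data.frame(mass = numeric(0), rt_start = integer(0),
                        rt_end = integer(0), abundance = numeric(0),
                        cs_dist = character(0))
  attr(truth, "contaminants") <- con
  class(truth) <- c("ground_truth", "data.frame")
  list(map = map, truth = truth)
}

# Peptide table targeting a given per-cell signal-to-noise ratio: abundance
# is set so that the apex monoisotopic cell of the dominant charge equals
# snr * sigma0, where sigma0 is the per-cell noise standard deviation.
.snr_peptides <- function(n, snr, sigma0, n_scans, mass_range, cs2_frac = 0.3,
                          CS = 4, n_iso = 5) {
  pep <- data.frame(
    mass = stats::runif(n, mass_range[1], mass_range[2]),
    cs = pmin(sample(1:3, n, replace = TRUE, prob = c(0.3, 0.5, 0.2)), CS),
    cs2_frac = cs2_frac,
    shape = sample(.elution_shapes, n, replace = TRUE),
    apex = stats::runif(n, 0.1 * n_scans, 0.9 * n_scans - 1),
    width = stats::rlnorm(n, log(8), 0.25),
    snr = snr)
  pep$abundance <- vapply(seq_len(n), function(i) {
    c_apex <- max(sample_elution(pep$shape[i], pep$apex[i], pep$width[i], n_scans))
    f0 <- theoretical_pattern(pep$mass[i], n_iso)$f_iso[1]
    w1 <- if (pep$cs[i] + 1 <= CS) 1 - cs2_frac else 1
    pep$snr[i] * sigma0 / (c_apex * w1 * f0)
  }, numeric(1))
  pep
}

.snr_contaminants <- function(n, snr_range, sigma0, n_scans, mz_range) {
  con <- data.frame(
    kind = sample(c("single_spike", "doublet", "flat_multiplet"), n, replace = TRUE),
    mz = stats::runif(n, mz_range[1], mz_range[2]),
    spacing_cs = sample(1:2, n, replace = TRUE),
    shape = sample(.elution_shapes, n, replace = TRUE),
    apex = stats::runif(n, 0.1 * n_scans, 0.9 * n_scans - 1),
    width = stats::rlnorm(n, log(8), 0.25),
    snr = stats::runif(n, snr_range[1], snr_range[2]))
  con$abundance <- vapply(seq_len(n), function(i) {
    c_apex <- max(sample_elution(con$shape[i], con$apex[i], con$width[i], n_scans))
    wmax <- max(.contaminant_positions(con$kind[i], con$mz[i], con$spacing_cs[i])$w)
    con$snr[i] * sigma0 / (c_apex * wmax)
  }, numeric(1))
  con
}

#' Deterministic benchmark maps
#'
#' Seeded study conditions used throughout the package's tests and scripts:
#' \describe{
#'   \item{`noise_free`}{20 equal-abundance peptides, no noise, no
#'     contaminants: every candidate step is exact up to m/z jitter.}
#'   \item{`low_snr_sweep`}{60 peptides in four per-cell SNR tiers
#'     (2, 5, 10, 20; 15 peptides each, `tier` column in the truth) plus 40
#'     contaminants, under a homoscedastic baseline noise floor.}
#'   \item{`dynamic_range`}{40 peptides with abundances log-spaced over four
#'     orders of magnitude (decade `tier`s, emulating a dynamic-range
#'     standard at desk scale) plus 30 contaminants, noise variance
#'     `c * A^2 + baseline`.}
#'   \item{`info_combining`}{300 low-abundance peptides at per-cell SNR 3
#'     plus 300 contaminants of comparable apex intensity: the stress test
#'     for combining evidence across scans vs single-scan scoring.}
#'   \item{`abundance_recovery`}{200 peptides at per-cell SNR 20, no
#'     contaminants: abundance-estimator check.}
#' }
#'
#' @param preset Preset name.
#' @param seed Optional seed override (each preset has a fixed default).
#' @return List with `map`, `truth`, `config`.
#' @export
make_benchmark <- function(preset = c("noise_free", "low_snr_sweep",
                                      "dynamic_range", "info_combining",
                                      "abundance_recovery"),
                           seed = NULL) {
  preset <- tryCatch(match.arg(preset),
                     error = function(e) icpd_stop("unknown preset: ", preset[1]))
  cfg <- switch(preset,
    noise_free = {
      pep <- .with_seed(if (is.null(seed)) 101 else seed, function()
        data.frame(mass = seq(800, 2400, length.out = 20) +
                     stats::runif(20, -5, 5),
                   abundance = 1e6,
                   cs = rep(c(1L, 2L, 2L, 3L), 5), cs2_frac = 0.3,
                   shape = rep(.elution_shapes, 5),
                   apex = stats::runif(20, 8, 50), width = stats::rlnorm(20, log(8), 0.25)))
      sim_config(n_scans = 60, peptides = pep,
                 noise = list(c = 0, p = 3, baseline = 0),
                 seed = if (is.null(seed)) 102 else seed + 1)
    },
    low_snr_sweep = {
      sigma0 <- 50
      pep <- .with_seed(if (is.null(seed)) 201 else seed, function() {
        p <- do.call(rbind, lapply(c(2, 5, 10, 20), function(snr)
          .snr_peptides(15, snr, sigma0, 100, c(700, 2500))))
        p$tier <- paste0("snr", p$snr)
        p
      })
      con <- .with_seed(if (is.null(seed)) 202 else seed + 1, function()
        .snr_contaminants(40, c(2, 20), sigma0, 100, c(300, 1400)))
      sim_config(n_scans = 100, peptides = pep, contaminants = con,
                 noise = list(c = 0, p = 3, baseline = sigma0^2),
                 seed = if (is.null(seed)) 203 else seed + 2)
    },
    dynamic_range = {
      pep <- .with_seed(if (is.null(seed)) 301 else seed, function() {
        p <- .sample_peptides(sim_config(n_scans = 100, n_peptides = 40))
        p$abundance <- 10^seq(3, 7, length.out = 40)
        p$tier <- paste0("decade", rep(1:4, each = 10))
        p
      })
      con <- .with_seed(if (is.null(seed)) 302 else seed + 1, function() {
        cc <- .sample_contaminants(sim_config(
          n_scans = 100, n_contaminants = 30,
          contaminant_abundance_range = c(1e3, 1e6)))
        cc
      })
      sim_config(n_scans = 100, peptides = pep, contaminants = con,
                 noise = list(c = 1e-4, p = 2, baseline = 50^2),
                 seed = if (is.null(seed)) 303 else seed + 2)
    },
    info_combining = {
      sigma0 <- 50
      pep <- .with_seed(if (is.null(seed)) 401 else seed, function()
        .snr_peptides(300, 3, sigma0, 140, c(700, 2500)))
      con <- .with_seed(if (is.null(seed)) 402 else seed + 1, function()
        .snr_contaminants(300, c(2, 8), sigma0, 140, c(300, 1400)))
      sim_config(n_scans = 140, peptides = pep, contaminants = con,
                 noise = list(c = 0, p = 3, baseline = sigma0^2),
                 seed = if (is.null(seed)) 403 else seed + 2)
    },
    abundance_recovery = {
      sigma0 <- 50
      pep <- .with_seed(if (is.null(seed)) 501 else seed, function()
        .snr_peptides(200, 20, sigma0, 120, c(700, 2500)))
      sim_config(n_scans = 120, peptides = pep,
                 noise = list(c = 0, p = 3, baseline = sigma0^2),
                 seed = if (is.null(seed)) 502 else seed + 1)
    })
  sim <- simulate_map(cfg)
  list(map = sim$map, truth = sim$truth, config = cfg)
}

#' Write / read a ground-truth peptide table
#'
#' Tab-separated with columns `mass rt_start rt_end abundance cs_dist`
#' (plus `tier` when present). Contaminant locations, if any, go to
#' `<path>.contaminants.tsv`.
#'
#' @param truth A `ground_truth` data frame from [simulate_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(as.data.frame(truth), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  con <- attr(truth, "contaminants")
  if (!is.null(con) && nrow(con) > 0)
    utils::write.table(con, paste0(path, ".contaminants.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("mass", "rt_start", "rt_end", "abundance")
  miss <- setdiff(need, names(d))
  if (length(miss)) icpd_stop("truth missing column(s): ",
                              paste(miss, collapse = ", "))
  cpath <- paste0(path, ".contaminants.tsv")
  if (file.exists(cpath))
    attr(d, "contaminants") <- utils::read.table(cpath, header = TRUE, sep = "\t")
  class(d) <- c("ground_truth", "data.frame")
  d
}
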