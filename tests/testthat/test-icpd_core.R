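test_that("trace grids reproduce the noise-free signal model", {
  mass <- 1200; A <- 1e5
  pep <- data.frame(mass = mass, abundance = A, cs = 2L, cs2_frac = 0,
                    shape = "gaussian", apex = 10, width = 5)
  sim <- simulate_map(sim_config(n_scans = 24, peptides = pep,
                                 noise = list(c = 0, p = 3, baseline = 0),
                                 mz_jitter_ppm = 0, seed = 3))
  tr <- sim$truth
  cand <- data.frame(mass = mass, rt_start = tr$rt_start, rt_end = tr$rt_end)
  g <- extract_trace_grid(sim$map, cand, dmz = 10, CS = 4, n_iso = 5)
  f <- theoretical_pattern(mass, 5)$f_iso
  C <- sample_elution("gaussian", 10, 5, 24)
  Csup <- C[C > 0]
  # only the true charge column is populated, proportional to C(t) * f(iso)
  expect_equal(g$y[, 2, ], outer(A * Csup, f), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(sum(g$y[, c(1, 3, 4), ]), 0)

  # empty region
  g0 <- extract_trace_grid(lcms_map(0:3, rep(list(NULL), 4)),
                           data.frame(mass = 800, rt_start = 0L, rt_end = 3L))
  expect_true(all(g0$y == 0))
  expect_error(extract_trace_grid(sim$map,
                                  data.frame(mass = 800, rt_start = 0L, rt_end = 99L)),
               class = "icpd_validation_error")
})

test_that("two centroids inside one window cell are summed", {
  mz0 <- mz_of(1000, 1, 0)
  m <- lcms_map(0, list(cbind(mz = c(mz0 * (1 - 2e-6), mz0 * (1 + 2e-6)),
                              intensity = c(3, 4))))
  g <- extract_trace_grid(m, data.frame(mass = 1000, rt_start = 0L, rt_end = 0L),
                          dmz = 10, CS = 2, n_iso = 2)
  expect_equal(g$y[1, 1, 1], 7)
})

test_that("bulk grid extraction matches the per-candidate path", {
  sim <- simulate_map(sim_config(n_peptides = 6, n_scans = 40, seed = 21,
                                 noise = list(c = 0, p = 3, baseline = 100)))
  ml <- expand_charge_states(make_mzlist(sim$map), CS = 3)
  ml <- ml[seq_len(min(25, nrow(ml))), ]
  bulk <- icpd:::.extract_grids_bulk(sim$map, ml, dmz = 10, CS = 3, n_iso = 4,
                                     chunk = 7L)
  for (i in seq_len(nrow(ml))) {
    single <- extract_trace_grid(sim$map, ml[i, ], dmz = 10, CS = 3, n_iso = 4)
    expect_equal(bulk[[i]]$y, single$y)
  }
})

test_that("elution profile estimation recovers the true profile noise-free", {
  C <- sample_elution("asymmetric_triangle", 5, 6, 15)
  g <- model_grid(1e4, C[C > 0], c(0, 0.7, 0.3, 0), theoretical_pattern(900)$f_iso)
  prof <- estimate_elution_profile(g)
  expect_false(prof$empty)
  expect_equal(prof$C, C[C > 0] / sum(C[C > 0]), tolerance = 1e-12)

  z <- estimate_elution_profile(model_grid(0, c(1, 1), c(1, 0), c(1, 0)))
  expect_true(z$empty)
  expect_equal(sum(z$C), 0)
})

test_that("combining is exact on noise-free grids and flags empty evidence", {
  A <- 5e4
  f <- theoretical_pattern(1600)$f_iso
  C <- sample_elution("exp_mod_gaussian", 4, 5, 20)
  g <- model_grid(A, C[C > 0], c(0.2, 0.5, 0.3), f)
  pat <- combine_observations(g, estimate_elution_profile(g))
  expect_equal(pat$y_hat, A * f, tolerance = 1e-9)
  expect_equal(pat$A_hat, A, tolerance = 1e-9)

  zg <- model_grid(0, c(1, 1, 1), c(1, 0), c(1, 0, 0))
  zp <- combine_observations(zg, estimate_elution_profile(zg))
  expect_true(zp$empty)
  expect_equal(zp$A_hat, 0)
  expect_equal(matching_score(zp, c(1, 0, 0), noise_model(3, 1)), -Inf)
})

test_that("combined estimator is unbiased with the matched-filter variance", {
  set.seed(7)
  A <- 1e5; f <- theoretical_pattern(1500)$f_iso
  C <- sample_elution("gaussian", 5, 6, 12)
  fcs <- c(0, 0.7, 0.3, 0)
  mu <- model_grid(A, C, fcs, f)$y
  sigma <- A * max(C) * 0.7 * f[1] / 10          # per-cell SNR 10 at the apex
  prof <- true_profile(C)
  n_rep <- 1000
  Y <- matrix(0, n_rep, length(f))
  for (r in seq_len(n_rep)) {
    g <- structure(list(y = mu + stats::rnorm(length(mu), 0, sigma), dmz = 10),
                   class = "trace_grid")
    Y[r, ] <- combine_observations(g, prof)$y_hat
  }
  se <- apply(Y, 2, stats::sd) / sqrt(n_rep)
  expect_true(all(abs(colMeans(Y) - A * f) <= 2 * se))
  w <- prof$C / sum(prof$C^2)
  v_analytic <- sigma^2 * length(fcs) * sum(w^2)
  expect_true(all(abs(apply(Y, 2, stats::var) / v_analytic - 1) < 0.1))
})

test_that("noise-constant calibration recovers the generating constant", {
  set.seed(13)
  c0 <- 1e-4; p <- 2
  f <- theoretical_pattern(1100)$f_iso
  patterns <- lapply(1:200, function(i) {
    A <- stats::runif(1, 1e4, 1e6)
    y <- A * f + stats::rnorm(5, 0, sqrt(c0 * A^p))
    structure(list(y_hat = y, A_hat = sum(y), n_obs = 5, w2sum = 1,
                   empty = FALSE), class = "combined_pattern")
  })
  c_hat <- calibrate_noise_constant(patterns, rep(list(f), 200), p)
  expect_gt(c_hat, c0 / 2)
  expect_lt(c_hat, c0 * 2)

  # homogeneity: doubling intensities leaves c invariant at p = 2
  pat2 <- lapply(patterns, function(x) {
    x$y_hat <- 2 * x$y_hat; x$A_hat <- 2 * x$A_hat; x
  })
  c2 <- calibrate_noise_constant(pat2, rep(list(f), 200), 2)
  expect_equal(c2, calibrate_noise_constant(patterns, rep(list(f), 200), 2),
               tolerance = 1e-9)

  # degenerate: zero residuals floor the constant with a warning
  perfect <- lapply(1:20, function(i)
    structure(list(y_hat = 100 * f, A_hat = 100, n_obs = 5, w2sum = 1,
                   empty = FALSE), class = "combined_pattern"))
  expect_warning(cf <- calibrate_noise_constant(perfect, rep(list(f), 20), 3),
                 "floored")
  expect_gt(cf, 0)
  expect_error(calibrate_noise_constant(perfect[1:5], rep(list(f), 5), 3),
               class = "icpd_validation_error")
})

test_that("matching score is maximal at the perfect match and concave", {
  f <- theoretical_pattern(1500)$f_iso
  nm <- noise_model(3, 1e-6)
  A <- 1e4
  perfect <- structure(list(y_hat = A * f, A_hat = A, empty = FALSE),
                       class = "combined_pattern")
  expect_equal(matching_score(perfect, f, nm), 0)
  sigma2 <- nm$c * A^nm$p
  expect_equal(matching_score(perfect, f, nm, normalized = TRUE),
               -length(f) / 2 * log(2 * pi * sigma2))

  # strictly decreasing along any perturbation direction
  set.seed(4)
  for (i in 1:10) {
    dir <- stats::rnorm(5)
    s1 <- matching_score(structure(list(y_hat = A * f + 0.5 * dir, A_hat = A,
                                        empty = FALSE), class = "combined_pattern"),
                         f, nm)
    s2 <- matching_score(structure(list(y_hat = A * f + 1.5 * dir, A_hat = A,
                                        empty = FALSE), class = "combined_pattern"),
                         f, nm)
    expect_lt(s1, 0); expect_lt(s2, s1)
  }

  # averagine-shaped pattern beats a flat one at equal abundance
  flat <- structure(list(y_hat = rep(A / 5, 5), A_hat = A, empty = FALSE),
                    class = "combined_pattern")
  expect_gt(matching_score(perfect, f, nm), matching_score(flat, f, nm))
})

test_that("single-scan pattern picks the strongest (scan, charge) row", {
  f <- theoretical_pattern(1000)$f_iso
  C <- c(0.2, 0.5, 0.3)
  g <- model_grid(1e4, C, c(0.3, 0.7), f)
  ss <- single_scan_pattern(g)
  expect_equal(ss$y_hat, 1e4 * 0.5 * 0.7 * f, tolerance = 1e-12)
  expect_equal(ss$A_hat, max(ss$y_hat))

  # degenerate single-scan elution: combined and single-scan see the same rows
  g1 <- model_grid(1e4, 1, c(0, 1), f)
  comb <- combine_observations(g1, true_profile(1))
  expect_equal(single_scan_pattern(g1)$y_hat, comb$y_hat)

  expect_equal(single_scan_score(model_grid(0, c(1, 1), c(1, 0), f), f,
                                 noise_model(3, 1)), -Inf)
})

test_that("the pipeline recovers clean peptides and satisfies its invariants", {
  pep <- data.frame(mass = c(900.17, 1400.52, 2100.9),
                    abundance = 2e5, cs = c(1L, 2L, 3L), cs2_frac = 0.3,
                    shape = "gaussian", apex = c(8, 15, 22), width = 6)
  sim <- simulate_map(sim_config(n_scans = 32, peptides = pep,
                                 noise = list(c = 0, p = 3, baseline = 0),
                                 seed = 9))
  fit <- icpd(sim$map)
  expect_s3_class(fit, "icpd")
  ol <- fit$outlist
  expect_true(all(ol$volume >= ol$max_intensity))
  expect_true(all(ol$max_intensity >= 0))
  expect_true(!is.unsorted(rev(ol$score)))
  md <- match_detections(ol, sim$truth)
  expect_true(all(attr(md, "truth_hit")))
  # best-scoring hypothesis of each truth peptide carries one of its real
  # charges (the peptide disperses over cs and cs + 1)
  hits <- md[md$label == "hit", ]
  hit_cs <- hits$cs[order(hits$truth_row)]
  expect_true(all(hit_cs == pep$cs | hit_cs == pep$cs + 1L))

  # determinism
  fit2 <- icpd(sim$map)
  expect_equal(fit2$outlist, fit$outlist)

  # empty map
  fe <- icpd(lcms_map(0:5, rep(list(NULL), 6)))
  expect_equal(nrow(fe$outlist), 0L)
})

test_that("score ranking is invariant to global intensity rescaling", {
  sim <- simulate_map(sim_config(n_peptides = 8, n_scans = 40, seed = 17,
                                 noise = list(c = 1e-5, p = 2, baseline = 400)))
  fit1 <- icpd(sim$map)
  scaled <- sim$map
  scaled$peaks <- lapply(scaled$peaks, function(p) { p[, 2] <- p[, 2] * 50; p })
  fit2 <- icpd(scaled)
  key <- function(f) paste(round(f$outlist$mass, 4), f$outlist$cs,
                           f$outlist$rt_start)
  expect_equal(key(fit2), key(fit1))
  expect_equal(fit2$outlist$score, fit1$outlist$score, tolerance = 1e-8)
})

test_that("score_sweep re-scores stored patterns across exponents", {
  sim <- simulate_map(sim_config(n_peptides = 6, n_scans = 40, seed = 23,
                                 noise = list(c = 1e-5, p = 2, baseline = 400)))
  fit <- icpd(sim$map)
  sw <- score_sweep(fit, c(1, 2, 3))
  expect_equal(colnames(sw), c("p1", "p2", "p3"))
  expect_equal(nrow(sw), fit$n_candidates)
  # p = 3 column reproduces the fit's own scores (same calibration rule)
  expect_equal(sw[, "p3"], fit$outlist$score, tolerance = 1e-12,
               ignore_attr = TRUE)
})
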