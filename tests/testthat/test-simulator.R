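test_that("elution shapes are normalised distributions on the scan range", {
  for (shape in c("gaussian", "exp-mod-gaussian", "asymmetric-triangle",
                  "plateau")) {
    C <- sample_elution(shape, apex = 12, width = 6, n_scans = 40)
    expect_length(C, 40)
    expect_true(all(C >= 0))
    expect_equal(sum(C), 1, tolerance = 1e-9)
  }
  # plateau of width 4: four equal quarters
  expect_equal(sort(unique(sample_elution("plateau", 10, 4, 20))), c(0, 0.25))
  expect_equal(sum(sample_elution("plateau", 10, 4, 20) > 0), 4L)
  # delta limit of the gaussian
  C0 <- sample_elution("gaussian", 7, 0, 20)
  expect_equal(C0[8], 1)
  expect_error(sample_elution("boxcar", 5, 3, 10),
               class = "icpd_validation_error")
  expect_error(sample_elution("gaussian", 50, 3, 10),
               class = "icpd_validation_error")
})

test_that("noise-free emission follows the signal model exactly", {
  mass <- 1234.5; A <- 4e4
  pep <- data.frame(mass = mass, abundance = A, cs = 2L, cs2_frac = 0,
                    shape = "gaussian", apex = 9, width = 4)
  sim <- simulate_map(sim_config(n_scans = 20, peptides = pep,
                                 noise = list(c = 0, p = 1, baseline = 0),
                                 mz_jitter_ppm = 0, seed = 2))
  f <- theoretical_pattern(mass, 5)$f_iso
  C <- sample_elution("gaussian", 9, 4, 20)
  cc <- collect_centroids(sim$map)
  for (k in 0:4) {
    at_k <- cc[abs(cc$mz - mz_of(mass, 2, k)) < 1e-9, ]
    expect_equal(at_k$intensity, A * C[C > 0] * f[k + 1], tolerance = 1e-9)
  }
  # conservation: with no noise, drop or clamp the map integrates to A
  expect_equal(sum(cc$intensity), A, tolerance = 1e-9)
})

test_that("simulation is deterministic in the seed", {
  cfg <- sim_config(n_peptides = 5, n_contaminants = 5, n_scans = 25,
                    noise = list(c = 1e-5, p = 2, baseline = 100), seed = 77)
  s1 <- simulate_map(cfg)
  s2 <- simulate_map(cfg)
  expect_identical(s1$map, s2$map)
  expect_identical(as.data.frame(s1$truth), as.data.frame(s2$truth))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_map(s1$map, f1, format = "tsv"); write_map(s2$map, f2, format = "tsv")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("per-cell noise variance follows the configured power law", {
  A <- 1e5; c0 <- 2.5e-7; p <- 2
  pep <- data.frame(mass = 1000, abundance = A, cs = 1L, cs2_frac = 0,
                    shape = "plateau", apex = 50, width = 90)
  sd_cell <- sqrt(c0 * A^p)
  f <- theoretical_pattern(1000, 5)$f_iso
  C <- sample_elution("plateau", 50, 90, 100)
  resid <- unlist(lapply(1:12, function(s) {
    sim <- simulate_map(sim_config(n_scans = 100, peptides = pep,
                                   noise = list(c = c0, p = p, baseline = 0),
                                   mz_jitter_ppm = 0, seed = 1000 + s))
    cc <- collect_centroids(sim$map)
    unlist(lapply(0:4, function(k) {
      mu <- A * C[C > 0] * f[k + 1]
      if (mu[1] / sd_cell < 5) return(NULL)   # keep cells where clamping is nil
      at_k <- cc[abs(cc$mz - mz_of(1000, 1, k)) < 1e-6, ]
      at_k$intensity - mu
    }))
  }))
  expect_gt(length(resid), 2000)
  expect_lt(abs(stats::var(resid) / (c0 * A^p) - 1), 0.1)
})

test_that("contaminant kinds produce the advertised peak groups", {
  wn <- icpd_constants()$neutron_shift
  con <- data.frame(kind = c("single_spike", "doublet", "flat_multiplet"),
                    mz = c(400, 500, 600), spacing_cs = 1L, abundance = 1e4,
                    shape = "plateau", apex = 5, width = 3)
  sim <- simulate_map(sim_config(n_scans = 12, peptides = NULL, n_peptides = 0,
                                 contaminants = con,
                                 noise = list(c = 0, p = 1, baseline = 0),
                                 mz_jitter_ppm = 0, seed = 4))
  cc <- collect_centroids(sim$map)
  mz_at <- sort(unique(round(cc$mz, 4)))
  expect_true(400 %in% mz_at)
  expect_true(all(round(c(500, 500 + 0.5 * wn), 4) %in% mz_at))
  expect_true(all(round(600 + (0:3) * wn, 4) %in% mz_at))
  # flat multiplet really is flat
  flat <- cc[cc$scan == 5 & cc$mz > 599, ]
  expect_equal(length(unique(round(flat$intensity, 6))), 1L)
})

test_that("benchmark presets encode their stated study conditions", {
  nf <- make_benchmark("noise_free")
  expect_equal(nrow(nf$truth), 20L)
  expect_null(attr(nf$truth, "contaminants"))

  dr <- make_benchmark("dynamic_range")
  span <- log10(max(dr$truth$abundance) / min(dr$truth$abundance))
  expect_equal(span, 4, tolerance = 1e-9)
  expect_equal(sort(unique(dr$truth$tier)), paste0("decade", 1:4))

  ls <- make_benchmark("low_snr_sweep")
  expect_equal(as.vector(table(ls$truth$tier)[paste0("snr", c(2, 5, 10, 20))]),
               rep(15L, 4))
  expect_equal(nrow(attr(ls$truth, "contaminants")), 40L)

  expect_error(make_benchmark("nope"), class = "icpd_validation_error")
})

test_that("truth tables round-trip to tsv including contaminants", {
  sim <- simulate_map(sim_config(n_peptides = 3, n_contaminants = 2,
                                 n_scans = 20, seed = 8))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_equal(back$mass, sim$truth$mass)
  expect_equal(back$abundance, sim$truth$abundance)
  expect_equal(nrow(attr(back, "contaminants")), 2L)
})
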