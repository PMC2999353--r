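# Independent elemental-convolution oracle for isotope envelopes, and small
# fixture builders used across the test files.

# Averagine composition and per-atom heavy-isotope abundances, written out
# independently of the package internals.
.oracle_unit <- c(C = 4.9384, H = 7.7583, N = 1.3577, O = 1.4773, S = 0.0417)
.oracle_iso <- list(                      # nominal shift -> probability, per atom
  C = c("1" = 0.0107),
  H = c("1" = 0.000115),
  N = c("1" = 0.00364),
  O = c("1" = 0.00038, "2" = 0.00205),
  S = c("1" = 0.0075, "2" = 0.0425, "4" = 0.0001))

# Brute-force isotope envelope: convolve the exact per-atom shift
# distributions of the rounded averagine formula for the given mass.
elemental_pattern_oracle <- function(mass, n_iso = 5, n_keep = 12) {
  counts <- round(.oracle_unit * mass / 111.1254)
  dist <- c(1, rep(0, n_keep))
  for (el in names(counts)) {
    sp <- .oracle_iso[[el]]
    atom <- c(1 - sum(sp), rep(0, n_keep))
    for (s in names(sp)) atom[as.integer(s) + 1] <- sp[[s]]
    n <- counts[[el]]
    if (n > 0) for (i in seq_len(n)) {     # polynomial multiplication
      new <- numeric(n_keep + 1)
      for (k in seq_along(atom)) if (atom[k] > 0)
        new[k:(n_keep + 1)] <- new[k:(n_keep + 1)] +
          atom[k] * dist[1:(n_keep + 2 - k)]
      dist <- new
    }
  }
  f <- dist[1:n_iso]
  f / sum(f)
}

total_variation <- function(a, b) 0.5 * sum(abs(a - b))

# A trace grid built directly from the signal model (no map extraction).
model_grid <- function(A, C, f_cs, f_iso, noise_sd = 0) {
  nt <- length(C); CS <- length(f_cs); n_iso <- length(f_iso)
  y <- array(0, dim = c(nt, CS, n_iso))
  for (cs in seq_len(CS)) for (k in seq_len(n_iso))
    y[, cs, k] <- A * C * f_cs[cs] * f_iso[k]
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  structure(list(y = y, candidate = NULL, dmz = 10), class = "trace_grid")
}

true_profile <- function(C) {
  structure(list(C = C / sum(C), empty = FALSE), class = "elution_profile")
}

# A tiny hand-made two-scan map.
toy_map <- function() {
  lcms_map(rt = c(0, 1),
           peaks = list(cbind(mz = c(400.0, 500.0, 600.0), intensity = c(1, 2, 3)),
                        cbind(mz = c(400.0, 650.0, 700.0), intensity = c(4, 5, 6))))
}
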