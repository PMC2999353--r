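# Theoretical isotope patterns from the averagine model, and m/z geometry.

#' Expected carbon count of a peptide of given mass
#'
#' Scales the averagine carbon content (4.9384 carbons per 111.1254 Da
#' residue) to the neutral monoisotopic mass.
#'
#' @param mass Neutral monoisotopic mass (Da), > 0. Vectorised.
#' @return Expected (real-valued) number of carbon atoms.
#' @export
#' @examples
#' averagine_carbons(111.1254)  # one residue: 4.9384 carbons
averagine_carbons <- function(mass) {
  if (any(!is.finite(mass)) || any(mass <= 0)) icpd_stop("mass must be > 0")
  .icpd$averagine_carbons * mass / .icpd$averagine_mass
}

# Poisson rates of the averagine heavy-isotope model: expected number of
# +1 Da substitutions (C13, H2, N15, O17, S33) and +2 Da substitutions
# (O18, S34) for a peptide of the given mass.
.averagine_rates <- function(mass) {
  units <- mass / .icpd$averagine_mass
  list(lambda1 = units * sum(.icpd$averagine_unit * .icpd$heavy_shift1),
       lambda2 = units * sum(.icpd$averagine_unit * .icpd$heavy_shift2))
}

#' Theoretical isotope pattern of a peptide from its mass
#'
#' The number of +1 Da and +2 Da heavy-isotope substitutions in a peptide of
#' averagine composition are modelled as independent Poisson counts (the
#' Poisson limit of the underlying binomials; C13 dominates the +1 channel,
#' 18O and 34S supply the +2 channel). The envelope over the total nominal
#' shift `iso` is their convolution, truncated to `n_iso` positions and
#' renormalised to sum 1. The pre-truncation ratio `f[1]/f[0]` equals the
#' +1 substitution rate `lambda1`.
#'
#' @param mass Neutral monoisotopic mass (Da), > 0.
#' @param n_iso Number of isotope positions kept (default 5, covering
#'   essentially all of the envelope for tryptic peptides below ~3 kDa).
#' @return Object of class `theoretical_pattern`: list with `f_iso`
#'   (length-`n_iso` fractions summing to 1, `f_iso[1]` is the monoisotopic
#'   fraction), `mass`, `lambda1`, `lambda2`.
#' @export
#' @examples
#' theoretical_pattern(1500)$f_iso
theoretical_pattern <- function(mass, n_iso = 5) {
  if (!is.finite(mass) || mass <= 0) icpd_stop("mass must be > 0")
  if (!is.finite(n_iso) || n_iso < 1 || n_iso != round(n_iso))
    icpd_stop("n_iso must be a positive integer")
  r <- .averagine_rates(mass)
  k <- 0:(n_iso - 1)
  f <- vapply(k, function(kk) {
    j <- 0:(kk %/% 2)
    sum(stats::dpois(kk - 2 * j, r$lambda1) * stats::dpois(j, r$lambda2))
  }, numeric(1))
  structure(list(f_iso = f / sum(f), mass = mass,
                 lambda1 = r$lambda1, lambda2 = r$lambda2),
            class = "theoretical_pattern")
}

#' @export
print.theoretical_pattern <- function(x, ...) {
  cat(sprintf("<theoretical_pattern> mass %.4f Da, lambda1 %.4f, lambda2 %.4f\n",
              x$mass, x$lambda1, x$lambda2))
  cat("  f_iso:", paste(sprintf("%.4f", x$f_iso), collapse = " "), "\n")
  invisible(x)
}

#' m/z of an isotope/charge variant of a peptide
#'
#' `(mass + cs * w_p + iso * w_n) / cs` with `w_p` the proton mass and `w_n`
#' the C13-C12 isotope spacing.
#'
#' @param mass Neutral monoisotopic mass (Da), > 0. Vectorised over all three
#'   arguments with the usual recycling.
#' @param cs Charge state, integer >= 1.
#' @param iso Isotope position (number of heavy shifts), integer >= 0.
#' @return m/z in Thomson.
#' @export
#' @examples
#' mz_of(1000, 2, 1)
mz_of <- function(mass, cs, iso = 0) {
  if (any(!is.finite(mass)) || any(mass <= 0)) icpd_stop("mass must be > 0")
  if (any(!is.finite(cs)) || any(cs < 1)) icpd_stop("cs must be >= 1")
  if (any(!is.finite(iso)) || any(iso < 0)) icpd_stop("iso must be >= 0")
  (mass + cs * .icpd$proton_mass + iso * .icpd$neutron_shift) / cs
}

#' Half-open ppm tolerance window around an m/z value
#'
#' @param mz m/z (Th), > 0. Vectorised.
#' @param dmz Tolerance in ppm, > 0.
#' @return For scalar input, `c(lo, hi)`; for vector input a two-column
#'   matrix. The window is interpreted as half-open, `[lo, hi)`.
#' @export
#' @examples
#' ppm_window(1000, 10)
ppm_window <- function(mz, dmz) {
  if (any(!is.finite(mz)) || any(mz <= 0)) icpd_stop("mz must be > 0")
  if (!is.finite(dmz) || dmz <= 0) icpd_stop("dmz must be > 0")
  lo <- mz * (1 - dmz * 1e-6)
  hi <- mz * (1 + dmz * 1e-6)
  if (length(mz) == 1) c(lo = lo, hi = hi) else cbind(lo = lo, hi = hi)
}
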