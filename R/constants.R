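# Physical constants and the averagine model composition.

.icpd <- new.env(parent = emptyenv())

.icpd$proton_mass   <- 1.007276   # Da, mass of the charge-carrying proton
.icpd$neutron_shift <- 1.003355   # Da, C13-C12 spacing between isotope peaks
.icpd$c13_abundance <- 0.0107
.icpd$averagine_mass    <- 111.1254  # Da, mean residue mass of averagine
.icpd$averagine_carbons <- 4.9384    # carbons per averagine residue

# Averagine elemental composition (atoms per 111.1254 Da residue) and natural
# heavy-isotope abundances grouped by nominal mass shift.  The +2 Da channel
# (18O, 34S) is kept separate: it is small but not negligible for the
# truncated isotope envelope.
.icpd$averagine_unit <- c(C = 4.9384, H = 7.7583, N = 1.3577, O = 1.4773, S = 0.0417)
.icpd$heavy_shift1   <- c(C = 0.0107, H = 0.000115, N = 0.00364, O = 0.00038, S = 0.0075)
.icpd$heavy_shift2   <- c(C = 0, H = 0, N = 0, O = 0.00205, S = 0.0425)

#' Physical constants used throughout the package
#'
#' Returns the proton mass, the isotope spacing (the C13-C12 mass difference,
#' which is what a high-resolution instrument observes between isotope peaks,
#' not the free-neutron mass), the natural C13 abundance, and the averagine
#' residue mass and carbon count.
#'
#' @return Named list of constants (Da, except `c13_abundance`).
#' @export
#' @examples
#' icpd_constants()$proton_mass
icpd_constants <- function() {
  list(
    proton_mass       = .icpd$proton_mass,
    neutron_shift     = .icpd$neutron_shift,
    c13_abundance     = .icpd$c13_abundance,
    averagine_mass    = .icpd$averagine_mass,
    averagine_carbons = .icpd$averagine_carbons
  )
}

# Signal a validation error carrying a dedicated condition class so the CLI
# can map it to exit code 2.
icpd_stop <- function(...) {
  stop(errorCondition(paste0(...), class = c("icpd_validation_error", "error", "condition")))
}
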