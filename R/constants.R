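# Physical constants (monoisotopic, Daltons).
.WATER_MASS  <- 18.010565
.PROTON_MASS <- 1.007276

# Pure numeric deduplication epsilon used inside a single mass set;
# distinct from the measurement tolerance of a ScoringConfig.
.MERGE_EPS <- 1e-9

#' Monoisotopic mass constants
#'
#' @return Named numeric vector with the monoisotopic masses (Da) of water
#'   and a proton, as used for precursor cleaning and m/z conversion.
#' @examples
#' massConstants()
#' @export
massConstants <- function() {
  c(water = .WATER_MASS, proton = .PROTON_MASS)
}
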