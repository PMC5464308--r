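#' Construct a raw spectrum
#'
#' @param id character(1) identifier.
#' @param precursorMz numeric(1) precursor m/z.
#' @param charge integer(1) precursor charge.
#' @param mz numeric fragment m/z values.
#' @param intensity numeric intensities (recycled from 1 if omitted).
#' @return A [RawSpectrum-class].
#' @export
rawSpectrum <- function(id, precursorMz, charge, mz,
                        intensity = rep(1, length(mz))) {
  o <- order(mz)
  new("RawSpectrum", id = as.character(id),
      precursorMz = as.numeric(precursorMz), charge = as.integer(charge),
      mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o]))
}

#' Construct a cleaned spectrum record
#'
#' Cleans a set of prefix-space fragment masses for sequencing: masses are
#' clipped to `[0, M]`, 0 and M are inserted, the set is sorted, and
#' near-identical masses (within a pure numeric epsilon) are merged. The
#' terminal masses 0 and M carry a virtual intensity (default: the median
#' measured intensity, or 1 when no peaks carry intensities).
#'
#' @param masses numeric fragment masses on the residue-sum (prefix) scale.
#' @param totalMass numeric(1) residue-sum peptide mass M (> 0).
#' @param intensity numeric parallel to `masses` (default all 1).
#' @param id character(1) identifier.
#' @param virtualIntensity intensity assigned to inserted terminal masses;
#'   default the median of `intensity`.
#' @param dropAbove drop masses exceeding the upper clip bound instead of
#'   erroring; the number dropped is reported via a message when > 0.
#' @param tol numeric clipping tolerance (Da).
#' @param maxMass upper clip bound (default `totalMass`); offset-space
#'   records keep masses up to `M` plus the largest suffix offset (a y
#'   fragment neutral exceeds M by one water).
#' @return A [SpectrumRecord-class].
#' @examples
#' spectrumRecord(c(2, 3), 5)
#' @export
spectrumRecord <- function(masses, totalMass, intensity = rep(1, length(masses)),
                           id = "spectrum", virtualIntensity = NULL,
                           dropAbove = TRUE, tol = 0, maxMass = totalMass) {
  if (totalMass <= 0) .stopf("total mass must be positive")
  maxMass <- max(maxMass, totalMass)
  keep <- masses >= -tol & masses <= maxMass + tol
  nDropped <- sum(!keep)
  if (nDropped > 0L) {
    if (!dropAbove) .stopf("%d masses outside [0, %g]", nDropped, maxMass)
    message(sprintf("%s: dropped %d peaks outside the mass range", id,
                    nDropped))
  }
  m <- pmin(pmax(masses[keep], 0), maxMass)
  i <- intensity[keep]
  if (is.null(virtualIntensity)) {
    virtualIntensity <- if (length(i)) stats::median(i) else 1
  }
  m <- c(0, m, totalMass)
  i <- c(virtualIntensity, i, virtualIntensity)
  cl <- .clusterWeighted(m, i, eps = .MERGE_EPS)
  new("SpectrumRecord", id = as.character(id), masses = cl$x,
      intensity = cl$w, totalMass = as.numeric(totalMass))
}

#' @rdname peakMasses
#' @export
setGeneric("peakMasses", function(object) standardGeneric("peakMasses"))

#' Accessors for SpectrumRecord
#'
#' `peakMasses()` returns the cleaned mass set X, `peakIntensities()` the
#' parallel intensities, `totalMass()` the residue-sum peptide mass M and
#' `spectrumId()` the identifier.
#'
#' @param object a [SpectrumRecord-class] (or [RawSpectrum-class] for
#'   `spectrumId`).
#' @return numeric vector / numeric(1) / character(1).
#' @aliases peakMasses peakIntensities totalMass spectrumId
#' @export
setMethod("peakMasses", "SpectrumRecord", function(object) object@masses)

#' @rdname peakMasses
#' @export
setGeneric("peakIntensities",
           function(object) standardGeneric("peakIntensities"))

#' @rdname peakMasses
#' @export
setMethod("peakIntensities", "SpectrumRecord",
          function(object) object@intensity)

#' @rdname peakMasses
#' @export
setGeneric("totalMass", function(object) standardGeneric("totalMass"))

#' @rdname peakMasses
#' @export
setMethod("totalMass", "SpectrumRecord", function(object) object@totalMass)

#' @rdname peakMasses
#' @export
setGeneric("spectrumId", function(object) standardGeneric("spectrumId"))

#' @rdname peakMasses
#' @export
setMethod("spectrumId", "SpectrumRecord", function(object) object@id)

#' @rdname peakMasses
#' @export
setMethod("spectrumId", "RawSpectrum", function(object) object@id)

#' Construct a scoring configuration
#'
#' @param variant "symdiff" (default), "scp", "wscp" or "wsymdiff"; see
#'   [ScoringConfig-class].
#' @param tolerance peak-matching tolerance epsilon in Da (default 0.02).
#' @param penalty constant penalty for explained-but-unmatched masses
#'   under "wsymdiff" (default -2500).
#' @return A [ScoringConfig-class].
#' @examples
#' scoringConfig("symdiff", tolerance = 0)
#' @export
scoringConfig <- function(variant = c("symdiff", "scp", "wscp", "wsymdiff"),
                          tolerance = 0.02, penalty = -2500) {
  variant <- match.arg(variant)
  new("ScoringConfig", variant = variant, tolerance = as.numeric(tolerance),
      penalty = as.numeric(penalty))
}
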