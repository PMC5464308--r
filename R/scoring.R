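# Per-mass scoring against the measured mass set X, and whole-string
# scores. The score of a string is the sum over its (deduplicated)
# theoretical spectrum of a per-mass score; under the symmetric-difference
# variant, maximizing this score minimizes |TS(S) delta X|.

#' Tolerant peak matching
#'
#' Finds, for each query mass, the measured mass minimizing the absolute
#' difference, provided it is within `tol`; ties are broken toward the
#' smaller measured mass.
#'
#' @param m numeric query masses.
#' @param rec a [SpectrumRecord-class].
#' @param tol numeric(1) tolerance in Da.
#' @return numeric vector of matched measured masses (NA where unmatched).
#' @examples
#' rec <- spectrumRecord(c(2, 3), 5)
#' matchPeak(c(2.004, 4), rec, tol = 0.01)  # 2, NA
#' @export
matchPeak <- function(m, rec, tol) {
  idx <- .nearestWithin(m, peakMasses(rec), tol)
  peakMasses(rec)[idx]
}

# matched index (internal: scoring needs the intensity of the match)
.matchIndex <- function(m, rec, tol) {
  .nearestWithin(m, peakMasses(rec), tol)
}

#' Per-mass score
#'
#' Scores a single explained mass against the measured set X under the
#' configured variant: `scp` gives 1 if matched else 0; `symdiff` gives
#' +1 if matched else -1; `wscp` gives the matched peak's intensity else
#' 0; `wsymdiff` gives the matched intensity else the constant penalty.
#'
#' @param m numeric masses (vectorized).
#' @param rec a [SpectrumRecord-class].
#' @param config a [ScoringConfig-class].
#' @return numeric vector of scores.
#' @export
massScore <- function(m, rec, config) {
  idx <- .matchIndex(m, rec, config@tolerance)
  matched <- !is.na(idx)
  switch(config@variant,
    scp = as.numeric(matched),
    symdiff = ifelse(matched, 1, -1),
    wscp = ifelse(matched, peakIntensities(rec)[idx], 0),
    wsymdiff = ifelse(matched, peakIntensities(rec)[idx], config@penalty))
}

#' Score of a peptide string against a spectrum
#'
#' Sum of [massScore()] over the deduplicated theoretical spectrum of
#' `seq`. By default the peptide mass must agree with the record's total
#' mass M within the configured tolerance (set `checkMass = FALSE` to
#' score off-mass variants, e.g. in sensitivity analyses).
#'
#' @param seq character(1) peptide string.
#' @param rec a [SpectrumRecord-class].
#' @param config a [ScoringConfig-class].
#' @param alphabet a [MassAlphabet-class].
#' @param checkMass logical, reject mass-mismatched peptides (default
#'   TRUE).
#' @return numeric(1).
#' @examples
#' toy <- toyAlphabet()
#' rec <- spectrumRecord(c(2, 3), 5)
#' scoreString("ab", rec, scoringConfig("symdiff", tolerance = 0), toy) # 4
#' scoreString("c",  rec, scoringConfig("symdiff", tolerance = 0), toy) # 2
#' @export
scoreString <- function(seq, rec, config, alphabet, checkMass = TRUE) {
  ts <- theoreticalSpectrum(seq, alphabet)
  if (checkMass) {
    delta <- abs(peptideMass(seq, alphabet) - totalMass(rec))
    if (delta > max(config@tolerance, 1e-6)) {
      .stopf("peptide mass differs from the spectrum mass M by %g Da", delta)
    }
  }
  sum(massScore(ts, rec, config))
}

#' Score under the extended theoretical spectrum
#'
#' As [scoreString()], but summing over the extended theoretical spectrum
#' induced by prefix/suffix offset sets. This is the objective of the
#' offset-aware (general) sequencing problem.
#'
#' @inheritParams scoreString
#' @param offsets an [IonOffsets-class].
#' @return numeric(1).
#' @export
scoreStringGeneral <- function(seq, rec, config, alphabet, offsets,
                               checkMass = TRUE) {
  tsx <- extendedTheoreticalSpectrum(seq, offsets, alphabet)
  tsx <- .dedup(tsx, eps = max(config@tolerance, .MERGE_EPS))
  if (checkMass) {
    delta <- abs(peptideMass(seq, alphabet) - totalMass(rec))
    if (delta > max(config@tolerance, 1e-6)) {
      .stopf("peptide mass differs from the spectrum mass M by %g Da", delta)
    }
  }
  sum(massScore(tsx, rec, config))
}

#' Size of the symmetric difference between TS(seq) and X
#'
#' Computed by direct tolerant set operations; under exact matching it
#' satisfies `|TS delta X| = |X| - scoreString(seq, ..., "symdiff")`.
#'
#' @inheritParams scoreString
#' @param tol numeric(1) matching tolerance in Da.
#' @return integer(1).
#' @examples
#' rec <- spectrumRecord(c(2, 3), 5)
#' symmetricDifferenceSize("c", rec, toyAlphabet(), tol = 0)  # 2
#' @export
symmetricDifferenceSize <- function(seq, rec, alphabet, tol = 0) {
  ts <- theoreticalSpectrum(seq, alphabet)
  x <- peakMasses(rec)
  sum(!.inSet(ts, x, tol)) + sum(!.inSet(x, ts, tol))
}
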