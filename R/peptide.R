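# Peptide mass algebra: residue sums, prefix-mass ladders, theoretical and
# extended theoretical spectra.

.splitPeptide <- function(seq) {
  if (nchar(seq) == 0L) return(character(0))
  strsplit(seq, "", fixed = TRUE)[[1]]
}

.residueVector <- function(seq, alphabet) {
  ch <- .splitPeptide(seq)
  if (length(ch) == 0L) return(numeric(0))
  m <- residueMasses(alphabet)[ch]
  if (anyNA(m)) {
    .stopf("peptide '%s' contains characters outside the alphabet", seq)
  }
  unname(m)
}

#' Residue-sum mass of a peptide
#'
#' Sum of the residue masses of a peptide string; 0 for the empty string.
#' This is the mass scale of the sequencing problem (the water mass of the
#' intact peptide is removed beforehand, see [cleanPrecursorMass()]).
#'
#' @param seq character(1) peptide string (possibly "").
#' @param alphabet a [MassAlphabet-class].
#' @return numeric(1), Da.
#' @examples
#' peptideMass("ab", toyAlphabet())   # 5
#' @export
peptideMass <- function(seq, alphabet) {
  sum(.residueVector(seq, alphabet))
}

#' Prefix-mass ladder of a peptide
#'
#' Masses of all prefixes including the empty prefix (0) and the full
#' peptide; strictly increasing, length `nchar(seq) + 1`.
#'
#' @inheritParams peptideMass
#' @return numeric vector.
#' @examples
#' prefixMasses("ab", toyAlphabet())  # 0 2 5
#' @export
prefixMasses <- function(seq, alphabet) {
  c(0, cumsum(.residueVector(seq, alphabet)))
}

#' Theoretical spectrum of a peptide
#'
#' The set of masses of all prefixes and suffixes of `seq`, including 0
#' and the full mass, deduplicated on a pure numeric epsilon. Identical
#' for a peptide and its reverse.
#'
#' @inheritParams peptideMass
#' @return sorted numeric vector.
#' @examples
#' theoreticalSpectrum("ab", toyAlphabet())  # 0 2 3 5
#' @export
theoreticalSpectrum <- function(seq, alphabet) {
  p <- prefixMasses(seq, alphabet)
  M <- p[length(p)]
  .dedup(c(p, M - p))
}

#' Masses explained by one prefix mass under offset sets
#'
#' A prefix of mass m of a peptide of total mass M explains every
#' `m + delta` for a prefix offset delta and every `M - m + delta'` for a
#' suffix offset delta'.
#'
#' @param m numeric(1) prefix mass, in `[0, M]`.
#' @param M numeric(1) total residue mass.
#' @param offsets an [IonOffsets-class].
#' @return sorted numeric vector (deduplicated).
#' @examples
#' offsetMasses(2, 5, ionOffsets(0, 0))   # 2 3
#' @export
offsetMasses <- function(m, M, offsets) {
  if (m < -1e-6 || m > M + 1e-6) {
    .stopf("prefix mass %g outside [0, %g]", m, M)
  }
  .om(m, M, offsets)
}

# bounds-unchecked variant for internal use: within the sequencer, label
# masses may overshoot a vertex gap by up to the matching tolerance
.om <- function(m, M, offsets) {
  .dedup(c(m + offsets@prefix, M - m + offsets@suffix))
}

#' Extended theoretical spectrum
#'
#' Union of [offsetMasses()] over every prefix of `seq` (including the
#' empty and the full prefix). Unlike the plain theoretical spectrum it is
#' generally not reversal-symmetric, because prefix and suffix offsets
#' differ.
#'
#' @inheritParams peptideMass
#' @param offsets an [IonOffsets-class].
#' @return sorted numeric vector.
#' @export
extendedTheoreticalSpectrum <- function(seq, offsets, alphabet) {
  p <- prefixMasses(seq, alphabet)
  M <- p[length(p)]
  .dedup(unlist(lapply(p, offsetMasses, M = M, offsets = offsets)))
}

#' Remove the water mass from a neutral peptide mass
#'
#' An intact peptide carries one H2O in addition to its residue masses;
#' the sequencing algorithms work on the residue-sum scale.
#'
#' @param neutralMass numeric neutral (uncharged) peptide mass, Da.
#' @return numeric residue-sum mass M.
#' @examples
#' cleanPrecursorMass(massConstants()["water"] + 5)  # 5
#' @export
cleanPrecursorMass <- function(neutralMass) {
  M <- neutralMass - .WATER_MASS
  if (any(M <= 0)) {
    .stopf("neutral mass below the water mass: no residues left")
  }
  unname(M)
}
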