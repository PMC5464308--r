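#' Construct a mass alphabet
#'
#' @param masses named numeric vector: residue mass (Da) per single-
#'   character symbol.
#' @param collapseIsobaric logical flag recorded on the object (see
#'   [standardAlphabet()]).
#' @return A [MassAlphabet-class].
#' @examples
#' toy <- massAlphabet(c(a = 2, b = 3, c = 5))
#' mu(toy)
#' @export
massAlphabet <- function(masses, collapseIsobaric = FALSE) {
  if (is.null(names(masses)) || any(!nzchar(names(masses)))) {
    .stopf("masses must be a named numeric vector")
  }
  masses <- masses[order(names(masses))]
  new("MassAlphabet", symbols = names(masses), masses = masses,
      mu = min(masses), collapseIsobaric = collapseIsobaric)
}

#' Toy three-letter alphabet
#'
#' Integer-mass alphabet `{a: 2, b: 3, c: 5}` used throughout the examples
#' and tests: `c` is isobaric with `ab`, mirroring the glutamine vs
#' glycine+alanine ambiguity of the standard residues at a desk-checkable
#' scale.
#'
#' @return A [MassAlphabet-class].
#' @export
toyAlphabet <- function() {
  massAlphabet(c(a = 2, b = 3, c = 5))
}

#' Standard amino-acid alphabet
#'
#' The 20 standard amino acids with monoisotopic residue masses. Because
#' mass spectra cannot distinguish isobaric residues, leucine and
#' isoleucine are by default collapsed to a single symbol reported as
#' `L`.
#'
#' @param collapseIsobaric collapse I into L (default TRUE).
#' @return A [MassAlphabet-class].
#' @examples
#' aa <- standardAlphabet()
#' residueMasses(aa)[c("G", "A", "Q")]
#' @export
standardAlphabet <- function(collapseIsobaric = TRUE) {
  path <- system.file("extdata", "monoisotopic_residues.tsv",
                      package = "SymDiffDeNovo", mustWork = TRUE)
  ab <- readAlphabet(path)
  m <- residueMasses(ab)
  if (collapseIsobaric) {
    m <- m[names(m) != "I"]
  }
  massAlphabet(m, collapseIsobaric = collapseIsobaric)
}

#' Read an alphabet from a two-column table
#'
#' Whitespace-separated text with one residue per line: symbol then mass
#' (Da). Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return A [MassAlphabet-class].
#' @export
readAlphabet <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("symbol", "mass"),
                           colClasses = c("character", "numeric"))
  if (nrow(tab) == 0L) .stopf("alphabet table '%s' is empty", path)
  masses <- stats::setNames(tab$mass, tab$symbol)
  massAlphabet(masses)
}

#' @rdname residueMasses
#' @export
setGeneric("residueMasses", function(object) standardGeneric("residueMasses"))

#' Accessors for MassAlphabet
#'
#' `residueMasses()` returns the named residue-mass vector, `mu()` the
#' smallest residue mass, and `alphabetSymbols()` the symbols.
#'
#' @param object a [MassAlphabet-class].
#' @return numeric vector, numeric(1), or character vector respectively.
#' @aliases residueMasses mu alphabetSymbols
#' @export
setMethod("residueMasses", "MassAlphabet", function(object) object@masses)

#' @rdname residueMasses
#' @export
setGeneric("mu", function(object) standardGeneric("mu"))

#' @rdname residueMasses
#' @export
setMethod("mu", "MassAlphabet", function(object) object@mu)

#' @rdname residueMasses
#' @export
setGeneric("alphabetSymbols",
           function(object) standardGeneric("alphabetSymbols"))

#' @rdname residueMasses
#' @export
setMethod("alphabetSymbols", "MassAlphabet", function(object) object@symbols)

#' Collapse isobaric residues in a peptide string
#'
#' Rewrites I as L so that sequences can be compared the way a mass-based
#' method can distinguish them.
#'
#' @param seq character vector of peptide strings.
#' @return character vector.
#' @export
collapseIsobaric <- function(seq) {
  gsub("I", "L", seq, fixed = TRUE)
}

#' Construct prefix/suffix offset sets
#'
#' @param prefix numeric offsets (Da) for prefix fragments.
#' @param suffix numeric offsets (Da) for suffix fragments.
#' @return An [IonOffsets-class].
#' @examples
#' ionOffsets(0, 0)                 # the exact (no-offset) reduction
#' byIonOffsets()                   # b/y fragment-neutral interpretation
#' @export
ionOffsets <- function(prefix = 0, suffix = 0) {
  new("IonOffsets", prefix = as.numeric(prefix), suffix = as.numeric(suffix))
}

#' @rdname ionOffsets
#' @details `byIonOffsets()` encodes the b/y interpretation on the
#'   fragment-neutral scale: a b fragment's neutral mass is the prefix
#'   residue sum (offset 0), a y fragment's neutral mass is the suffix
#'   residue sum plus water.
#' @export
byIonOffsets <- function() {
  ionOffsets(prefix = 0, suffix = .WATER_MASS)
}

#' Maximal offset difference and the alpha-basic condition
#'
#' `gammaMax()` returns gamma, the maximal pairwise difference over the
#' union of prefix and suffix offsets; `isAlphaBasic()` tests
#' `gamma < alpha * mu(alphabet)`, the condition required by the
#' offset-aware sequencer (alpha = 2).
#'
#' @param offsets an [IonOffsets-class].
#' @param alphabet a [MassAlphabet-class].
#' @param alpha numeric(1), default 2.
#' @return numeric(1), respectively logical(1).
#' @export
gammaMax <- function(offsets) {
  all <- c(offsets@prefix, offsets@suffix)
  max(all) - min(all)
}

#' @rdname gammaMax
#' @export
isAlphaBasic <- function(offsets, alphabet, alpha = 2) {
  gammaMax(offsets) < alpha * mu(alphabet)
}
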