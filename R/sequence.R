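#' Sequence one spectrum de novo
#'
#' End-to-end convenience wrapper: builds the spectrum multigraph, runs
#' the symmetric-difference (or shared-peaks-count) dynamic program, and
#' enumerates the k best candidate sequences via the matrix graph. With
#' `offsets` supplied, the offset-aware program is run instead and the
#' co-optimal candidates are reconstructed by traceback (k-best
#' enumeration is defined for the simple program only).
#'
#' @param rec a [SpectrumRecord-class].
#' @param alphabet a [MassAlphabet-class].
#' @param config a [ScoringConfig-class].
#' @param pMax maximal edge-label length (default 2).
#' @param k number of distinct candidates wanted (default 10).
#' @param floorFraction NULL or score-floor fraction, see
#'   [enumerateCandidates()].
#' @param offsets NULL for the simple problem, or an [IonOffsets-class].
#' @return A [SequencingResult-class].
#' @examples
#' toy <- toyAlphabet()
#' rec <- spectrumRecord(c(2, 3), 5)
#' sequenceSpectrum(rec, toy, scoringConfig("symdiff", tolerance = 0))
#' @export
sequenceSpectrum <- function(rec, alphabet, config = scoringConfig(),
                             pMax = 2L, k = 10L, floorFraction = NULL,
                             offsets = NULL) {
  if (is.null(offsets)) {
    g <- suppressWarnings(
      buildSpectrumGraph(rec, alphabet, pMax, config@tolerance))
    mg <- buildMatrixGraph(g, rec, config, alphabet)
    res <- enumerateCandidates(mg, k = k, floorFraction = floorFraction,
                               id = spectrumId(rec))
  } else {
    g <- buildGeneralGraph(rec, alphabet, offsets, pMax, config@tolerance)
    tab <- runDeNovoDeltaG(g, rec, config, alphabet)
    res <- tracebackCandidates(tab)
    res@id <- spectrumId(rec)
  }
  res
}

#' @rdname candidatePeptides
#' @export
setGeneric("candidatePeptides",
           function(object) standardGeneric("candidatePeptides"))

#' Accessors for SequencingResult
#'
#' `candidatePeptides()` returns the ranked candidate strings,
#' `candidateScores()` their scores and `optimumScore()` the best score.
#'
#' @param object a [SequencingResult-class].
#' @return character / numeric vectors, numeric(1).
#' @aliases candidatePeptides candidateScores optimumScore
#' @export
setMethod("candidatePeptides", "SequencingResult",
          function(object) object@peptides)

#' @rdname candidatePeptides
#' @export
setGeneric("candidateScores",
           function(object) standardGeneric("candidateScores"))

#' @rdname candidatePeptides
#' @export
setMethod("candidateScores", "SequencingResult",
          function(object) object@scores)

#' @rdname candidatePeptides
#' @export
setGeneric("optimumScore", function(object) standardGeneric("optimumScore"))

#' @rdname candidatePeptides
#' @export
setMethod("optimumScore", "SequencingResult", function(object) object@optimum)

setMethod("show", "MassAlphabet", function(object) {
  cat(sprintf("MassAlphabet: %d symbols, mu = %.5f Da%s\n",
              length(object@symbols), object@mu,
              if (object@collapseIsobaric) " (I/L collapsed)" else ""))
  print(object@masses)
})

setMethod("show", "IonOffsets", function(object) {
  cat(sprintf("IonOffsets: O_p = {%s}, O_s = {%s}, gamma = %.5f\n",
              paste(format(object@prefix), collapse = ", "),
              paste(format(object@suffix), collapse = ", "),
              gammaMax(object)))
})

setMethod("show", "RawSpectrum", function(object) {
  cat(sprintf("RawSpectrum '%s': precursor %.4f m/z (%d+), %d peaks\n",
              object@id, object@precursorMz, object@charge,
              length(object@mz)))
})

setMethod("show", "SpectrumRecord", function(object) {
  cat(sprintf("SpectrumRecord '%s': M = %.4f Da, |X| = %d\n",
              object@id, object@totalMass, length(object@masses)))
})

setMethod("show", "SpectrumGraph", function(object) {
  cat(sprintf("%s: %d vertices, %d edges (pMax = %d, tol = %g Da), M = %.4f\n",
              class(object), length(object@vertices), nrow(object@edges),
              object@pMax, object@tolerance, object@totalMass))
})

setMethod("show", "DPTable", function(object) {
  cat(sprintf(
    "DPTable: %d x %d states (%d role%s), %d reachable, base = %.4g\n",
    object@nVertices, object@nEdges, object@roles,
    if (object@roles > 1L) "s" else "", sum(is.finite(object@scores)),
    object@baseScore))
})

setMethod("show", "MatrixGraph", function(object) {
  cat(sprintf("MatrixGraph: %d nodes (%d terminal), %d edges\n",
              nrow(object@nodes), sum(object@nodes$terminal),
              length(object@weights)))
})

setMethod("show", "SequencingResult", function(object) {
  cat(sprintf("SequencingResult '%s': %d candidates, optimum = %s\n",
              object@id, length(object@peptides),
              format(object@optimum)))
  n <- min(5L, length(object@peptides))
  if (n > 0L) {
    for (i in seq_len(n)) {
      cat(sprintf("  %2d. %-20s %.4g\n", i, object@peptides[i],
                  object@scores[i]))
    }
    if (length(object@peptides) > n) cat("  ...\n")
  }
})

setMethod("show", "ScoringConfig", function(object) {
  cat(sprintf("ScoringConfig: %s, tolerance = %g Da%s\n", object@variant,
              object@tolerance,
              if (object@variant == "wsymdiff")
                sprintf(", penalty = %g", object@penalty) else ""))
})

setMethod("show", "SimulationParams", function(object) {
  cat(sprintf(paste0("SimulationParams: n = %d, length %d-%d, q = %.2f, ",
                     "noise = %d, sigma = %g Da, mode = %s, seed = %d\n"),
              object@nPeptides, object@lengthRange[1], object@lengthRange[2],
              object@missProb, object@nNoise, object@massSigma,
              object@offsetsMode, object@seed))
})

setMethod("show", "BenchmarkReport", function(object) {
  cat("BenchmarkReport\n")
  print(object@aggregates, row.names = FALSE)
})
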