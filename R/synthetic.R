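# Synthetic ground-truth peptides and corrupted spectra. The simulator
# emulates the noise structure the sequencing problem assumes: some
# prefix/suffix fragment masses are missing (independent dropout of
# internal peaks), other masses are given in addition (uniform spurious
# peaks), and measured masses carry a small Gaussian jitter.

#' Construct simulation parameters
#'
#' Defaults are the simulated study conditions used throughout the
#' package's benchmarks: 200 tryptic peptides of length 7-12, 30% dropout
#' of internal fragment peaks, 10 spurious peaks per spectrum, 0.005 Da
#' mass jitter, and log-normal intensities with median 1000.
#'
#' @param nPeptides number of spectra.
#' @param lengthRange integer pair, min/max peptide length.
#' @param missProb dropout probability q in `[0, 1)` per internal peak.
#' @param nNoise spurious peaks per spectrum.
#' @param massSigma Gaussian m/z jitter standard deviation (Da).
#' @param intensityMeanlog,intensitySdlog log-normal intensity model.
#' @param offsetsMode "none" (peaks at theoretical prefix/suffix masses)
#'   or "by" (b/y ion m/z encoding).
#' @param trypticTerminus force the last residue to K or R (the tryptic
#'   convention the benchmark peptides follow).
#' @param seed RNG seed; fully determines the emitted dataset.
#' @return A [SimulationParams-class].
#' @export
simulationParams <- function(nPeptides = 200L, lengthRange = c(7L, 12L),
                             missProb = 0.3, nNoise = 10L,
                             massSigma = 0.005,
                             intensityMeanlog = log(1000),
                             intensitySdlog = 1,
                             offsetsMode = c("none", "by"),
                             trypticTerminus = TRUE, seed = 1L) {
  offsetsMode <- match.arg(offsetsMode)
  new("SimulationParams", nPeptides = as.integer(nPeptides),
      lengthRange = as.integer(lengthRange), missProb = as.numeric(missProb),
      nNoise = as.integer(nNoise), massSigma = as.numeric(massSigma),
      intensityMeanlog = as.numeric(intensityMeanlog),
      intensitySdlog = as.numeric(intensitySdlog),
      offsetsMode = offsetsMode, trypticTerminus = trypticTerminus,
      seed = as.integer(seed))
}

#' Draw a random ground-truth peptide
#'
#' Uniform random residues within the configured length range; with the
#' tryptic flag the final residue is drawn from {K, R}. Uses the current
#' RNG state.
#'
#' @param params a [SimulationParams-class].
#' @param alphabet a [MassAlphabet-class].
#' @return character(1) peptide string.
#' @export
generatePeptide <- function(params, alphabet) {
  syms <- alphabetSymbols(alphabet)
  lens <- seq.int(params@lengthRange[1], params@lengthRange[2])
  len <- lens[sample.int(length(lens), 1L)]
  res <- syms[sample.int(length(syms), len, replace = TRUE)]
  if (params@trypticTerminus) {
    kr <- intersect(c("K", "R"), syms)
    if (!length(kr)) .stopf("alphabet has neither K nor R for a tryptic terminus")
    res[len] <- sample(kr, 1L)
  }
  paste(res, collapse = "")
}

#' Noise-free spectrum of a peptide
#'
#' Peaks at every theoretical fragment mass (or, in b/y mode, at the b-
#' and y-ion m/z readings of every prefix/suffix), re-encoded as singly
#' charged m/z; intensities drawn from the log-normal intensity model;
#' precursor fields consistent with the peptide's neutral mass.
#'
#' @param peptide character(1).
#' @param params a [SimulationParams-class].
#' @param alphabet a [MassAlphabet-class].
#' @param id spectrum identifier.
#' @return A [RawSpectrum-class].
#' @export
idealSpectrum <- function(peptide, params, alphabet, id = peptide) {
  M <- peptideMass(peptide, alphabet)
  if (params@offsetsMode == "none") {
    frag <- theoreticalSpectrum(peptide, alphabet)
  } else {
    p <- prefixMasses(peptide, alphabet)
    frag <- .dedup(c(p, M - p + .WATER_MASS))   # b and y fragment neutrals
  }
  mz <- frag + .PROTON_MASS
  int <- stats::rlnorm(length(mz), params@intensityMeanlog,
                       params@intensitySdlog)
  rawSpectrum(id, precursorMz = M + .WATER_MASS + .PROTON_MASS,
              charge = 1L, mz = mz, intensity = int)
}

#' Corrupt an ideal spectrum
#'
#' Each non-terminal peak is removed independently with probability
#' `missProb`; `nNoise` spurious peaks are added at uniform m/z within
#' the fragment range with model-drawn intensities; every surviving
#' peak's m/z is jittered by centered Gaussian noise of scale
#' `massSigma`. The precursor fields are untouched. Uses the current RNG
#' state.
#'
#' @param spec a [RawSpectrum-class] (ideal input).
#' @param params a [SimulationParams-class].
#' @return A [RawSpectrum-class].
#' @export
corruptSpectrum <- function(spec, params) {
  mz <- spec@mz
  int <- spec@intensity
  n <- length(mz)
  # terminal-derived peaks (lowest and highest fragment mass) are kept:
  # they encode the 0/M anchors the cleaning step reinserts anyway
  terminal <- mz <= min(mz) + 1e-9 | mz >= max(mz) - 1e-9
  drop <- !terminal & stats::runif(n) < params@missProb
  mz <- mz[!drop]
  int <- int[!drop]
  if (params@nNoise > 0L) {
    lo <- .PROTON_MASS
    hi <- spec@precursorMz * spec@charge - spec@charge * .PROTON_MASS -
      .WATER_MASS + .PROTON_MASS
    noiseMz <- stats::runif(params@nNoise, lo, hi)
    noiseInt <- stats::rlnorm(params@nNoise, params@intensityMeanlog,
                              params@intensitySdlog)
    mz <- c(mz, noiseMz)
    int <- c(int, noiseInt)
  }
  if (params@massSigma > 0) {
    mz <- mz + stats::rnorm(length(mz), 0, params@massSigma)
  }
  rawSpectrum(spec@id, spec@precursorMz, spec@charge, mz, int)
}

#' Emit a reproducible synthetic dataset
#'
#' Generates `nPeptides` ground-truth peptides, their ideal spectra, and
#' corrupted versions; writes the MGF and the truth TSV (or returns the
#' objects when paths are NULL). Fully determined by `params@seed`.
#'
#' @param params a [SimulationParams-class].
#' @param alphabet a [MassAlphabet-class] (default [standardAlphabet()]).
#' @param mgfPath,truthPath output paths, or NULL to skip writing.
#' @return list with `spectra` (list of [RawSpectrum-class]) and `truth`
#'   (data.frame spectrum_id, peptide), invisibly when written.
#' @export
emitDataset <- function(params, alphabet = standardAlphabet(),
                        mgfPath = NULL, truthPath = NULL) {
  runif(1)  # ensure an RNG state exists before saving it
  oldSeed <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(params@seed)
  spectra <- vector("list", params@nPeptides)
  truth <- character(params@nPeptides)
  ids <- sprintf("synthetic_%04d", seq_len(params@nPeptides))
  for (i in seq_len(params@nPeptides)) {
    pep <- generatePeptide(params, alphabet)
    truth[i] <- pep
    ideal <- idealSpectrum(pep, params, alphabet, id = ids[i])
    spectra[[i]] <- corruptSpectrum(ideal, params)
  }
  truthDf <- data.frame(spectrum_id = ids, peptide = truth,
                        stringsAsFactors = FALSE)
  if (!is.null(mgfPath)) writeMGF(spectra, mgfPath)
  if (!is.null(truthPath)) writeTruth(truthDf, truthPath)
  out <- list(spectra = spectra, truth = truthDf)
  if (is.null(mgfPath) && is.null(truthPath)) out else invisible(out)
}
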