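# Shared fixtures: the toy alphabet examples and random toy instance
# generator used across the unit and acceptance tests.

toy <- toyAlphabet()
cfgExact <- scoringConfig("symdiff", tolerance = 0)
cfgScpExact <- scoringConfig("scp", tolerance = 0)

# cleaned toy records: the complete ladder of "ab"/"ba" and the termini-
# only record where "c" and "ab" are isobaric competitors
recFull <- spectrumRecord(c(2, 3), 5)
recBare <- spectrumRecord(numeric(0), 5)

# random toy instance: integer-mass alphabet (3-4 symbols, masses 4..13),
# M in [15, 30], X a random subset of {0..M} containing 0 and M
randomToyInstance <- function() {
  nSym <- sample(3:4, 1)
  masses <- sort(sample(4:13, nSym))
  ab <- massAlphabet(stats::setNames(as.numeric(masses),
                                     letters[seq_len(nSym)]))
  M <- sample(15:30, 1)
  X <- sort(unique(c(0, M, sample(seq_len(M - 1), size = sample(3:9, 1)))))
  list(alphabet = ab, M = M, rec = spectrumRecord(X, M),
       pMax = ceiling(M / mu(ab)))
}

# brute-force oracle: score every string of mass M by direct summation
# over its (extended) theoretical spectrum
bruteForceScores <- function(inst, config, offsets = NULL) {
  allS <- enumerateLabels(inst$M, inst$alphabet, inst$pMax, 0)
  if (!length(allS)) return(numeric(0))
  if (is.null(offsets)) {
    vapply(allS, scoreString, numeric(1), rec = inst$rec, config = config,
           alphabet = inst$alphabet)
  } else {
    vapply(allS, scoreStringGeneral, numeric(1), rec = inst$rec,
           config = config, alphabet = inst$alphabet, offsets = offsets)
  }
}

randomPeptide <- function(alphabet, len) {
  syms <- alphabetSymbols(alphabet)
  paste(syms[sample.int(length(syms), len, replace = TRUE)], collapse = "")
}
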