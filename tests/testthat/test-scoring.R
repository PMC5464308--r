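# Per-mass scores, tolerant matching, whole-string scores and the
# symmetric-difference identity.

test_that("tolerant matching picks the nearest peak, ties to smaller", {
  rec <- spectrumRecord(c(2, 3), 5)
  expect_equal(matchPeak(5, rec, 0.01), 5)
  expect_equal(matchPeak(4.995, rec, 0.01), 5)
  expect_true(is.na(matchPeak(4, rec, 0.01)))
  # equidistant between 2 and 3: the smaller mass wins
  expect_equal(matchPeak(2.5, rec, 1), 2)
})

test_that("per-mass scores implement the four variants", {
  rec <- spectrumRecord(c(2, 3), 5, intensity = c(10, 40))
  sym <- scoringConfig("symdiff", tolerance = 0)
  scp <- scoringConfig("scp", tolerance = 0)
  expect_identical(massScore(c(2, 2.5), rec, sym), c(1, -1))
  expect_identical(massScore(c(2, 2.5), rec, scp), c(1, 0))
  wscp <- scoringConfig("wscp", tolerance = 0)
  wsym <- scoringConfig("wsymdiff", tolerance = 0, penalty = -2500)
  expect_identical(massScore(c(3, 2.5), rec, wscp), c(40, 0))
  expect_identical(massScore(c(3, 2.5), rec, wsym), c(40, -2500))
  # terminal masses carry the median measured intensity
  expect_equal(massScore(0, rec, wscp), 25)
})

test_that("string scores mirror the isobaric-substitution ambiguity", {
  expect_identical(scoreString("ab", recFull, cfgExact, toy), 4)
  expect_identical(scoreString("c", recFull, cfgExact, toy), 2)
  # with only termini measured, the single residue wins under symdiff
  # while the shared peaks count cannot separate the two
  expect_identical(scoreString("c", recBare, cfgExact, toy), 2)
  expect_identical(scoreString("ab", recBare, cfgExact, toy), 0)
  expect_identical(scoreString("c", recBare, cfgScpExact, toy), 2)
  expect_identical(scoreString("ab", recBare, cfgScpExact, toy), 2)
  # ideal input: every explained mass matched
  set.seed(7)
  for (i in 1:20) {
    s <- randomPeptide(toy, sample(2:7, 1))
    ts <- theoreticalSpectrum(s, toy)
    rec <- spectrumRecord(ts, peptideMass(s, toy))
    expect_equal(scoreString(s, rec, cfgExact, toy), length(ts))
  }
  expect_error(scoreString("a", recFull, cfgExact, toy), "mass differs")
})

test_that("symmetric-difference identity |TS delta X| = |X| - score", {
  expect_identical(symmetricDifferenceSize("c", recFull, toy), 2L)
  expect_identical(symmetricDifferenceSize("ab", recBare, toy), 2L)
  set.seed(8)
  for (i in 1:1000) {
    s <- randomPeptide(toy, sample(1:7, 1))
    M <- peptideMass(s, toy)
    X <- sort(unique(c(0, M, sample(0:M, sample(0:min(6, M), 1)))))
    rec <- spectrumRecord(X, M)
    expect_identical(
      symmetricDifferenceSize(s, rec, toy),
      as.integer(length(peakMasses(rec)) -
                   scoreString(s, rec, cfgExact, toy)))
  }
})

test_that("adding or removing a matched mass moves the score by 2", {
  set.seed(9)
  for (i in 1:50) {
    s <- randomPeptide(toy, sample(2:6, 1))
    M <- peptideMass(s, toy)
    ts <- theoreticalSpectrum(s, toy)
    X <- sort(unique(c(0, M, sample(setdiff(0:M, ts), 2))))
    rec <- spectrumRecord(X, M)
    base <- scoreString(s, rec, cfgExact, toy)
    missing <- setdiff(ts, X)
    if (length(missing)) {
      rec2 <- spectrumRecord(c(X, missing[1]), M)
      expect_identical(scoreString(s, rec2, cfgExact, toy), base + 2)
    }
  }
})

test_that("replacing Q by GA never hurts SPC but costs 2 under symdiff", {
  aa <- standardAlphabet()
  cfg <- scoringConfig("symdiff", tolerance = 1e-3)
  scp <- scoringConfig("scp", tolerance = 1e-3)
  set.seed(10)
  for (i in 1:30) {
    s <- randomPeptide(aa, sample(5:9, 1))
    pos <- sample(nchar(s), 1)
    substr(s, pos, pos) <- "Q"
    s2 <- paste0(substr(s, 1, pos - 1), "GA",
                 substr(s, pos + 1, nchar(s)))
    ts <- theoreticalSpectrum(s, aa)
    rec <- spectrumRecord(ts, peptideMass(s, aa), id = s)
    expect_gte(scoreString(s2, rec, scp, aa),
               scoreString(s, rec, scp, aa))
    # the substitution creates one new prefix mass and its complement;
    # when both are novel and unmatched -- no collision with any existing
    # fragment mass, so the spectrum grows by exactly two masses -- the
    # symdiff score drops by 2
    newM <- prefixMasses(s2, aa)[pos + 1L]
    M <- peptideMass(s, aa)
    novel <- !any(abs(ts - newM) <= 1e-3) &&
      !any(abs(ts - (M - newM)) <= 1e-3) &&
      abs(newM - (M - newM)) > 1e-3 &&
      length(theoreticalSpectrum(s2, aa)) == length(ts) + 2L
    if (novel) {
      expect_equal(scoreString(s2, rec, cfg, aa),
                   scoreString(s, rec, cfg, aa) - 2)
    }
  }
})
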