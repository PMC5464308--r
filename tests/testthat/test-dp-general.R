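# Offset-aware sequencing: TSe under offsets, newly explained masses,
# reduction to the simple program, and ladder recovery under b/y offsets.

test_that("offset TSe sets reduce to plain TSe at zero offsets", {
  off0 <- ionOffsets(0, 0)
  set.seed(20)
  for (i in 1:20) {
    lab <- randomPeptide(toy, sample(1:3, 1))
    src <- sample(0:4, 1)
    M <- src + peptideMass(lab, toy) + sample(0:5, 1)
    plain <- tseMasses(src, lab, M, toy)
    expect_identical(
      setdiff(round(tseGeneral(src, lab, M, off0, "prefix", toy), 9),
              round(c(0, M), 9)),
      as.numeric(round(plain, 9)))
  }
  offA <- ionOffsets(0, -1)
  expect_identical(tseGeneral(0, "a", 5, offA, "prefix", toy), 2)
  expect_identical(tseGeneral(0, "a", 5, offA, "suffix", toy), c(1, 3))
})

test_that("newly explained masses remove the anchor readings", {
  off0 <- ionOffsets(0, 0)
  # self-difference is empty at zero offsets (prefix and suffix readings
  # of the same edge coincide)
  expect_length(newMasses(0, "ab", 0, "ab", 5, off0, "prefix", toy), 0L)
  # zero offsets: reduces to the plain TSe difference
  nm <- newMasses(0, "b", 0, "a", 5, off0, "prefix", toy)
  expect_identical(nm, numeric(0))  # TSe sets coincide ({2, 3})
  # asymmetric offsets: the same edge on the other path explains
  # different masses, so the "self"-difference need not be empty:
  # prefix readings of "ab" are {-1, 2, 5}, the suffix-role removal set
  # covers everything except the internal prefix reading 2
  offA <- ionOffsets(0, -1)
  expect_identical(newMasses(0, "ab", 0, "ab", 5, offA, "prefix", toy), 2)
  # readings colliding with the path-end reading are removed: extending
  # from w = 2 with label "a" explains 4 and OM(4) includes 5 - 4 - 1 = 0,
  # while OM(w = 2) = {2} - the mass 4 survives, its mirror reading 0 is
  # the terminus
  nm2 <- newMasses(2, "a", 0, "", 10, offA, "prefix", toy)
  expect_true(all(c(4, 5) %in% nm2))
})

test_that("zero-offset tables equal the simple program exactly", {
  set.seed(21)
  for (i in 1:20) {
    inst <- randomToyInstance()
    g1 <- suppressWarnings(
      buildSpectrumGraph(inst$rec, inst$alphabet, inst$pMax, 0))
    t1 <- runDeNovoDelta(g1, inst$rec, cfgExact, inst$alphabet)
    g0 <- buildGeneralGraph(inst$rec, inst$alphabet, ionOffsets(0, 0),
                            inst$pMax, 0)
    t0 <- runDeNovoDeltaG(g0, inst$rec, cfgExact, inst$alphabet)
    nVE <- t0@nVertices * t0@nEdges
    merged <- pmax(t0@scores[seq_len(nVE)], t0@scores[nVE + seq_len(nVE)])
    expect_identical(merged, t1@scores)
    r1 <- tracebackCandidates(t1)
    r0 <- tracebackCandidates(t0)
    expect_identical(candidatePeptides(r0), candidatePeptides(r1))
    expect_identical(optimumScore(r0), optimumScore(r1))
  }
})

test_that("the offset-aware optimum equals exhaustive extended scoring", {
  set.seed(22)
  done <- 0
  while (done < 20) {
    inst <- randomToyInstance()
    off <- ionOffsets(0, sample(c(-2, -1, 1, 2), 1))
    if (!isAlphaBasic(off, inst$alphabet, 2)) next
    sc <- bruteForceScores(inst, cfgExact, offsets = off)
    if (!length(sc)) next
    done <- done + 1
    gg <- buildGeneralGraph(inst$rec, inst$alphabet, off, inst$pMax, 0)
    tg <- runDeNovoDeltaG(gg, inst$rec, cfgExact, inst$alphabet)
    rg <- tracebackCandidates(tg)
    expect_equal(optimumScore(rg), max(sc))
    co <- sort(names(sc)[sc >= max(sc) - 1e-9])
    expect_true(all(candidatePeptides(rg) %in% co))
  }
})

test_that("complete b/y ladders are recovered at the optimum", {
  aa <- standardAlphabet()
  params <- simulationParams(lengthRange = c(5, 5), missProb = 0,
                             nNoise = 0, massSigma = 0, offsetsMode = "by",
                             seed = 2)
  cfg <- scoringConfig("symdiff", tolerance = 1e-3)
  set.seed(23)
  for (i in 1:8) {
    pep <- generatePeptide(params, aa)
    sp <- idealSpectrum(pep, params, aa)
    conv <- toPrefixSpace(sp, "by-offsets", tol = 1e-3)
    res <- sequenceSpectrum(conv$record, aa, cfg, pMax = 2,
                            offsets = conv$offsets)
    expect_equal(optimumScore(res),
                 scoreStringGeneral(pep, conv$record, cfg, aa,
                                    conv$offsets))
    expect_true(collapseIsobaric(pep) %in%
                  collapseIsobaric(candidatePeptides(res)))
  }
})
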