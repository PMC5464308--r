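# Synthetic dataset generation: determinism, corruption statistics,
# ideal-spectrum contracts.

test_that("peptide generation is deterministic and respects constraints", {
  aa <- standardAlphabet()
  params <- simulationParams(lengthRange = c(7, 12), seed = 5)
  set.seed(31)
  p1 <- generatePeptide(params, aa)
  set.seed(31)
  expect_identical(generatePeptide(params, aa), p1)
  set.seed(32)
  for (i in 1:300) {
    pep <- generatePeptide(params, aa)
    expect_true(nchar(pep) >= 7 && nchar(pep) <= 12)
    expect_true(substr(pep, nchar(pep), nchar(pep)) %in% c("K", "R"))
  }
  paramsFree <- simulationParams(trypticTerminus = FALSE)
  set.seed(33)
  last <- vapply(1:200, function(i) {
    p <- generatePeptide(paramsFree, aa)
    substr(p, nchar(p), nchar(p))
  }, character(1))
  expect_gt(length(unique(last)), 2L)
})

test_that("ideal spectra encode the theoretical ladder", {
  aa <- standardAlphabet()
  params <- simulationParams(seed = 1)
  set.seed(34)
  pep <- generatePeptide(params, aa)
  sp <- idealSpectrum(pep, params, aa)
  expect_identical(length(sp@mz), length(theoreticalSpectrum(pep, aa)))
  expect_equal(sp@mz,
               theoreticalSpectrum(pep, aa) + massConstants()["proton"],
               tolerance = 1e-9, ignore_attr = TRUE)
  # b/y mode shifts the suffix series by one water
  paramsBy <- simulationParams(offsetsMode = "by", seed = 1)
  spBy <- idealSpectrum(pep, paramsBy, aa)
  pm <- prefixMasses(pep, aa)
  w <- unname(massConstants()["water"])
  pr <- unname(massConstants()["proton"])
  expected <- sort(unique(c(pm + pr, peptideMass(pep, aa) - pm + w + pr)))
  expect_equal(spBy@mz, expected, tolerance = 1e-9)
})

test_that("corruption is the identity at zero noise and drops internals", {
  aa <- standardAlphabet()
  clean <- simulationParams(missProb = 0, nNoise = 0, massSigma = 0,
                            seed = 1)
  set.seed(35)
  pep <- generatePeptide(clean, aa)
  sp <- idealSpectrum(pep, clean, aa)
  expect_equal(corruptSpectrum(sp, clean)@mz, sp@mz)
  # q -> 1 leaves only the terminal-derived peaks
  allGone <- simulationParams(missProb = 0.999999, nNoise = 0,
                              massSigma = 0, seed = 1)
  kept <- corruptSpectrum(sp, allGone)
  expect_identical(kept@mz, range(sp@mz))
})

test_that("dropout matches its binomial expectation", {
  aa <- standardAlphabet()
  params <- simulationParams(missProb = 0.3, nNoise = 0, massSigma = 0,
                             seed = 1)
  set.seed(36)
  pep <- generatePeptide(params, aa)
  sp <- idealSpectrum(pep, params, aa)
  nInternal <- length(sp@mz) - 2L
  reps <- 4000
  survived <- vapply(seq_len(reps), function(i) {
    length(corruptSpectrum(sp, params)@mz) - 2L
  }, numeric(1))
  expected <- (1 - 0.3) * nInternal
  se <- sqrt(nInternal * 0.3 * 0.7 / reps)
  expect_lt(abs(mean(survived) - expected), 3 * se)
})

test_that("datasets are reproducible from the seed", {
  aa <- standardAlphabet()
  params <- simulationParams(nPeptides = 5, seed = 99)
  d1m <- tempfile(fileext = ".mgf"); d1t <- tempfile(fileext = ".tsv")
  d2m <- tempfile(fileext = ".mgf"); d2t <- tempfile(fileext = ".tsv")
  emitDataset(params, aa, d1m, d1t)
  emitDataset(params, aa, d2m, d2t)
  expect_identical(readLines(d1m), readLines(d2m))
  expect_identical(readLines(d1t), readLines(d2t))
  truth <- readTruth(d1t)
  expect_identical(nrow(truth), 5L)
  expect_length(readMGF(d1m), 5L)
})

test_that("an uncorrupted dataset is fully identified end to end", {
  aa <- standardAlphabet()
  params <- simulationParams(nPeptides = 4, missProb = 0, nNoise = 0,
                             massSigma = 0, seed = 7)
  out <- emitDataset(params, aa)
  cfg <- scoringConfig("symdiff", tolerance = 1e-4)
  results <- lapply(seq_along(out$spectra), function(i) {
    rec <- toPrefixSpace(out$spectra[[i]], "simple", tol = 1e-4)
    res <- sequenceSpectrum(rec, aa, cfg, pMax = 2, k = 5)
    res
  })
  report <- summarizeBenchmark(list(symdiff = results), out$truth, aa,
                               tol = 1e-4)
  agg <- reportAggregates(report)
  expect_equal(agg$identification_rate, 1)
  expect_equal(agg$top_k_rate, 1)
  expect_equal(agg$recall_rate, 1)
})
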