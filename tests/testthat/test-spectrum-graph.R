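# Spectrum multigraph construction: mirrored vertices, clustering, label
# enumeration, parallel edges and the offset-aware variant.

test_that("vertex sets mirror measured masses and cluster within tol", {
  expect_identical(buildVertexSet(recBare), c(0, 5))
  expect_identical(buildVertexSet(spectrumRecord(2, 5)), c(0, 2, 3, 5))
  rec <- spectrumRecord(c(2.000, 2.004), 5, intensity = c(1, 1))
  v <- buildVertexSet(rec, tol = 0.01)
  expect_length(v, 4L)
  expect_equal(v, c(0, 2.002, 2.998, 5), tolerance = 1e-9)
  expect_error(buildVertexSet(new("SpectrumRecord", id = "x",
                                  masses = numeric(0),
                                  intensity = numeric(0), totalMass = 5),
                              0),
               "empty")
})

test_that("label enumeration is exhaustive under the length bound", {
  expect_identical(enumerateLabels(5, toy, 2), c("ab", "ba", "c"))
  expect_identical(enumerateLabels(5, toy, 1), "c")
  expect_identical(enumerateLabels(1, toy, 5), character(0))
  # cross-check counts against an independent composition recursion
  countCompositions <- function(n, masses) {
    memo <- new.env()
    cnt <- function(m) {
      if (m == 0) return(1)
      if (m < 0) return(0)
      key <- as.character(m)
      if (!is.null(memo[[key]])) return(memo[[key]])
      v <- sum(vapply(masses, function(x) cnt(m - x), numeric(1)))
      memo[[key]] <- v
      v
    }
    cnt(n)
  }
  set.seed(12)
  for (i in 1:20) {
    masses <- sort(sample(2:9, 3))
    ab <- massAlphabet(setNames(as.numeric(masses), c("a", "b", "c")))
    gap <- sample(5:25, 1)
    labs <- enumerateLabels(gap, ab, ceiling(gap / min(masses)))
    expect_identical(length(labs), as.integer(countCompositions(gap, masses)))
    if (length(labs)) {
      expect_true(all(vapply(labs, peptideMass, numeric(1),
                             alphabet = ab) == gap))
    }
  }
})

test_that("graphs carry parallel edges and the loop base edge", {
  g <- buildSpectrumGraph(spectrumRecord(2, 5), toy, pMax = 2)
  e <- graphEdges(g)
  v <- graphVertices(g)
  expect_identical(v, c(0, 2, 3, 5))
  # loop edge first, with the empty label
  expect_identical(e$label[1], "")
  expect_identical(e$from[1], e$to[1])
  # three parallel edges span (0, 5)
  full <- e[v[e$from] == 0 & v[e$to] == 5, ]
  expect_setequal(full$label, c("ab", "ba", "c"))
  expect_setequal(e$label[v[e$from] == 0 & v[e$to] == 2], "a")
  expect_setequal(e$label[v[e$from] == 2 & v[e$to] == 5], "b")
  # mirror closure and label round-trip
  expect_true(all(vapply(v, function(x) any(abs(v - (5 - x)) <= 1e-9),
                         logical(1))))
  gap <- v[e$to] - v[e$from]
  expect_true(all(abs(e$mass - gap) <= 1e-9))
})

test_that("a disconnected graph warns and sequencing returns nothing", {
  # M = 7 cannot be composed from {a:2, b:3, c:5} via vertex 1
  ab <- massAlphabet(c(a = 2, b = 3, c = 5))
  rec <- spectrumRecord(1, 7.5)
  expect_warning(g <- buildSpectrumGraph(rec, ab, pMax = 1),
                 "no 0 -> M connectivity")
  tab <- runDeNovoDelta(g, rec, cfgExact, ab)
  res <- tracebackCandidates(tab)
  expect_length(candidatePeptides(res), 0L)
  expect_true(is.na(optimumScore(res)))
})

test_that("offset-aware graphs reduce at zero offsets and check 2-basic", {
  g0 <- buildGeneralGraph(recFull, toy, ionOffsets(0, 0), 2)
  g1 <- buildSpectrumGraph(recFull, toy, 2)
  expect_identical(graphVertices(g0), graphVertices(g1))
  expect_identical(graphEdges(g0), graphEdges(g1))
  expect_error(buildGeneralGraph(recFull, toy, ionOffsets(0, 4.1), 2),
               "2-basic")
  g2 <- buildGeneralGraph(recFull, toy, ionOffsets(0, 3.9), 2)
  expect_s4_class(g2, "GeneralSpectrumGraph")
  # b/y readings of a single measured mass
  off <- ionOffsets(1.00728, 19.01784)
  aa <- standardAlphabet()
  rec <- spectrumRecord(200, 500)
  gg <- buildGeneralGraph(rec, aa, off, 1)
  v <- graphVertices(gg)
  expect_true(any(abs(v - (200 - 1.00728)) <= 1e-9))
  expect_true(any(abs(v - (500 - 200 + 19.01784)) <= 1e-9))
})

test_that("DOT export lists every vertex and edge", {
  g <- buildSpectrumGraph(recFull, toy, pMax = 2)
  dot <- graphToDot(g)
  expect_identical(sum(grepl("->", dot, fixed = TRUE)),
                   nrow(graphEdges(g)))
  path <- tempfile(fileext = ".dot")
  graphToDot(g, path)
  expect_identical(readLines(path), dot)
})
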