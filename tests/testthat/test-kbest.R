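# Matrix graph and k-best enumeration.

test_that("matrix graphs expose terminal states and consistent weights", {
  g <- buildSpectrumGraph(recFull, toy, pMax = 2)
  mg <- buildMatrixGraph(g, recFull, cfgExact, toy)
  v <- graphVertices(g)
  e <- graphEdges(g)
  # the state (2, (0, 3)) is terminal: 2 = 5 - 3
  term <- mg@nodes[mg@nodes$terminal, ]
  vb <- v[term$v] + v[e$to[term$e]]
  expect_true(all(abs(vb - 5) <= 1e-9))
  expect_true(any(abs(v[term$v] - 2) <= 1e-9 &
                    abs(v[e$from[term$e]] - 0) <= 1e-9 &
                    abs(v[e$to[term$e]] - 3) <= 1e-9))
  # every matrix edge weight equals the gain recomputed independently
  for (i in seq_along(mg@weights)) {
    ge <- mg@gEdge[i]
    se <- mg@nodes$e[match(mg@edgesFrom[i], seq_len(nrow(mg@nodes)))]
    expect_equal(mg@weights[i],
                 edgeGain(v[e$from[ge]], e$label[ge],
                          v[e$from[se]], e$label[se],
                          recFull, cfgExact, toy))
  }
})

test_that("toy k-best returns ab/ba/c with scores 4, 4, 2", {
  g <- buildSpectrumGraph(recFull, toy, pMax = 2)
  mg <- buildMatrixGraph(g, recFull, cfgExact, toy)
  res <- enumerateCandidates(mg, k = 3)
  expect_identical(candidatePeptides(res), c("ab", "ba", "c"))
  expect_identical(candidateScores(res), c(4, 4, 2))
  # k beyond the number of distinct strings returns them all, no error
  resBig <- enumerateCandidates(mg, k = 50)
  expect_identical(candidateScores(resBig), c(4, 4, 2))
  # fraction 1.0 keeps co-optimal candidates only
  resCo <- enumerateCandidates(mg, k = 10, floorFraction = 1.0)
  expect_identical(candidatePeptides(resCo), c("ab", "ba"))
})

test_that("k = 1 agrees with the DP optimum", {
  set.seed(17)
  for (i in 1:15) {
    inst <- randomToyInstance()
    g <- suppressWarnings(
      buildSpectrumGraph(inst$rec, inst$alphabet, inst$pMax, 0))
    tab <- runDeNovoDelta(g, inst$rec, cfgExact, inst$alphabet)
    opt <- optimumScore(tracebackCandidates(tab))
    mg <- buildMatrixGraph(g, inst$rec, cfgExact, inst$alphabet)
    kl <- kLongestPaths(mg, 1)
    if (is.na(opt)) {
      expect_length(kl$weights, 0L)
    } else {
      expect_equal(mg@baseScore + kl$weights[1], opt)
    }
  }
})

test_that("top-k scores equal the brute-force top-k after deduplication", {
  set.seed(18)
  for (i in 1:40) {
    inst <- randomToyInstance()
    g <- suppressWarnings(
      buildSpectrumGraph(inst$rec, inst$alphabet, inst$pMax, 0))
    mg <- buildMatrixGraph(g, inst$rec, cfgExact, inst$alphabet)
    res <- enumerateCandidates(mg, k = 5)
    sc <- sort(bruteForceScores(inst, cfgExact), decreasing = TRUE)
    expect_equal(candidateScores(res), unname(utils::head(sc, 5)))
    # path weights reconstruct the string score exactly
    for (j in seq_along(candidatePeptides(res))) {
      expect_equal(candidateScores(res)[j],
                   scoreString(candidatePeptides(res)[j], inst$rec,
                               cfgExact, inst$alphabet))
    }
  }
})

test_that("enumeration with unbounded k recovers every representable string", {
  set.seed(19)
  done <- 0
  while (done < 10) {
    inst <- randomToyInstance()
    allS <- enumerateLabels(inst$M, inst$alphabet, inst$pMax, 0)
    if (!length(allS) || length(allS) > 200) next
    done <- done + 1
    g <- suppressWarnings(
      buildSpectrumGraph(inst$rec, inst$alphabet, inst$pMax, 0))
    mg <- buildMatrixGraph(g, inst$rec, cfgExact, inst$alphabet)
    res <- enumerateCandidates(mg, k = 100000)
    expect_setequal(candidatePeptides(res), allS)
  }
})

test_that("path enumeration agrees with an independent graph library", {
  skip_if_not_installed("igraph")
  g <- buildSpectrumGraph(recFull, toy, pMax = 2)
  mg <- buildMatrixGraph(g, recFull, cfgExact, toy)
  n <- nrow(mg@nodes)
  ig <- igraph::graph_from_edgelist(cbind(mg@edgesFrom, mg@edgesTo))
  terminals <- which(mg@nodes$terminal)
  weights <- list()
  for (t in terminals) {
    sp <- igraph::all_simple_paths(ig, from = mg@source, to = t,
                                   mode = "out")
    for (p in sp) {
      pv <- as.integer(p)
      w <- 0
      for (j in seq_len(length(pv) - 1L)) {
        cand <- which(mg@edgesFrom == pv[j] & mg@edgesTo == pv[j + 1L])
        w <- w + max(mg@weights[cand])  # parallel edges: best used first
      }
      weights[[length(weights) + 1L]] <- w
    }
  }
  best <- max(unlist(weights)) + mg@baseScore
  kl <- kLongestPaths(mg, 1)
  expect_equal(mg@baseScore + kl$weights[1], best)
})
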