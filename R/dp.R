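# The symmetric-difference sequencing dynamic program.
#
# A DP state (w, (a,b)) holds the best score of two paths from vertex 0:
# one ending at vertex w, the other ending with edge (a,b). One path
# carries the prefix, the other the reversed suffix of a candidate. The
# state is extended by every outgoing edge of w; the masses newly
# explained by an extension are its TSe set minus the other path's last
# edge's TSe set, which is exactly the overlap the extension schedule
# (always extend the smaller-mass path) makes sufficient to track.

.packKey <- function(vIdx, eIdx, nV) (eIdx - 1L) * nV + vIdx
.unpackV <- function(key, nV) ((key - 1L) %% nV) + 1L
.unpackE <- function(key, nV) ((key - 1L) %/% nV) + 1L

# per-edge nonempty-prefix masses of the label (numeric(0) for the loop)
.edgeLabelPrefixes <- function(graph, alphabet) {
  lapply(graph@edges$label, function(l) {
    if (!nzchar(l)) numeric(0) else cumsum(.residueVector(l, alphabet))
  })
}

#' Masses additionally explained by one edge extension
#'
#' For an edge (w, w') with label L, the set
#' `{m(T) + w, M - (m(T) + w)}` over all nonempty label prefixes T. Masses
#' within tolerance of 0 or M are excluded: they are already credited to
#' the base entry (the empty string explains 0 and M), and the literal set
#' would re-count them on edges ending at vertex M. Empty for the loop
#' edge.
#'
#' @param sourceMass numeric(1) source vertex mass w.
#' @param label character(1) edge label.
#' @param M numeric(1) total mass.
#' @param alphabet a [MassAlphabet-class].
#' @param tol numeric(1) tolerance used for the 0/M exclusion and
#'   deduplication.
#' @return sorted numeric vector.
#' @examples
#' tseMasses(0, "ab", 5, toyAlphabet())  # 2 3
#' @export
tseMasses <- function(sourceMass, label, M, alphabet, tol = 0) {
  if (!nzchar(label)) return(numeric(0))
  p <- cumsum(.residueVector(label, alphabet))
  .tseFromPrefixes(sourceMass, p, M, max(tol, .MERGE_EPS))
}

.tseFromPrefixes <- function(sourceMass, prefixes, M, eps) {
  if (length(prefixes) == 0L) return(numeric(0))
  m <- sourceMass + prefixes
  vals <- c(m, M - m)
  vals <- vals[abs(vals) > eps & abs(vals - M) > eps]
  .dedup(vals, eps)
}

#' Additional score of one extension
#'
#' The sum of per-mass scores over the masses explained by `newEdge` but
#' not by the other path's last edge, `tseMasses(new) \ tseMasses(other)`
#' with tolerant set difference.
#'
#' @param newSource,newLabel source mass and label of the appended edge.
#' @param otherSource,otherLabel source mass and label of the other
#'   path's last edge (the loop edge is `otherLabel = ""`).
#' @param rec a [SpectrumRecord-class].
#' @param config a [ScoringConfig-class].
#' @param alphabet a [MassAlphabet-class].
#' @return numeric(1).
#' @examples
#' rec <- spectrumRecord(c(2, 3), 5)
#' cfg <- scoringConfig("symdiff", tolerance = 0)
#' edgeGain(0, "a", 0, "", rec, cfg, toyAlphabet())   # 2
#' edgeGain(0, "b", 0, "a", rec, cfg, toyAlphabet())  # 0
#' @export
edgeGain <- function(newSource, newLabel, otherSource, otherLabel,
                     rec, config, alphabet) {
  M <- totalMass(rec)
  tolD <- max(config@tolerance, .MERGE_EPS)
  tse <- tseMasses(newSource, newLabel, M, alphabet, config@tolerance)
  other <- tseMasses(otherSource, otherLabel, M, alphabet, config@tolerance)
  kept <- tse[!.inSet(tse, other, tolD)]
  if (!length(kept)) return(0)
  sum(massScore(kept, rec, config))
}

# Core relaxation shared by the table computation and the matrix-graph
# construction. Returns the packed score vector, backpointers, and (when
# collectEdges) every extension edge between reachable states.
.dpCore <- function(graph, rec, config, alphabet, collectEdges = FALSE) {
  v <- graph@vertices
  e <- graph@edges
  nV <- length(v)
  nE <- nrow(e)
  M <- graph@totalMass
  eps <- max(graph@tolerance, .MERGE_EPS)
  tolD <- max(config@tolerance, .MERGE_EPS)

  loopIdx <- which(e$from == e$to & !nzchar(e$label))
  if (length(loopIdx) != 1L) .stopf("graph must contain exactly one loop edge")
  loopIdx <- loopIdx[1]

  # per-edge TSe sets and per-mass scores
  labPref <- .edgeLabelPrefixes(graph, alphabet)
  srcMass <- v[e$from]
  toMass <- v[e$to]
  tse <- vector("list", nE)
  tseScore <- vector("list", nE)
  tseTotal <- numeric(nE)
  for (i in seq_len(nE)) {
    ti <- .tseFromPrefixes(srcMass[i], labPref[[i]], M, eps)
    tse[[i]] <- ti
    si <- if (length(ti)) massScore(ti, rec, config) else numeric(0)
    tseScore[[i]] <- si
    tseTotal[i] <- sum(si)
  }
  allTse <- unlist(tse)
  allScore <- unlist(tseScore)
  allEdge <- rep.int(seq_len(nE), lengths(tse))

  gainCache <- vector("list", nE)
  gainCol <- function(j) {
    gc <- gainCache[[j]]
    if (!is.null(gc)) return(gc)
    col <- tseTotal
    tj <- tse[[j]]
    if (length(tj) && length(allTse)) {
      hit <- .inSet(allTse, tj, tolD)
      if (any(hit)) {
        ov <- rowsum(allScore[hit], allEdge[hit])
        col[as.integer(rownames(ov))] <-
          col[as.integer(rownames(ov))] - as.vector(ov)
      }
    }
    gainCache[[j]] <<- col
    col
  }

  # adjacency: outgoing non-loop edges per vertex, in edge order
  outEdges <- rep(list(integer(0)), nV)
  nonLoop <- which(e$from != e$to)
  sp <- split(nonLoop, e$from[nonLoop])
  outEdges[as.integer(names(sp))] <- sp

  scores <- rep(-Inf, nV * nE)
  bpState <- integer(nV * nE)
  bpEdge <- integer(nV * nE)
  bpFamily <- integer(nV * nE)

  idx0 <- which(abs(v) <= eps)[1]
  baseScore <- sum(massScore(.dedup(c(0, M), tolD), rec, config))
  baseKey <- .packKey(idx0, loopIdx, nV)
  scores[baseKey] <- baseScore

  if (collectEdges) {
    mgFrom <- vector("list", 0); mgTo <- vector("list", 0)
    mgW <- vector("list", 0); mgE <- vector("list", 0); mgF <- vector("list", 0)
  }
  expanded <- 0L

  for (vi in seq_len(nV)) {
    out <- outEdges[[vi]]
    if (!length(out)) next
    wIdx <- e$to[out]
    wM <- toMass[out]
    for (ei in seq_len(nE)) {
      key <- .packKey(vi, ei, nV)
      s <- scores[key]
      if (!is.finite(s)) next
      b <- toMass[ei]
      ok <- wM + b <= M + eps
      if (!any(ok)) next
      f1 <- ok & (wM <= b + eps)
      f2 <- ok & !f1
      gains <- gainCol(ei)[out]
      tk <- integer(0); tv <- numeric(0); te <- integer(0); tf <- integer(0)
      if (any(f1)) {
        tk <- .packKey(wIdx[f1], rep.int(ei, sum(f1)), nV)
        tv <- s + gains[f1]
        te <- out[f1]
        tf <- rep.int(1L, sum(f1))
      }
      if (any(f2)) {
        tk <- c(tk, .packKey(rep.int(e$to[ei], sum(f2)), out[f2], nV))
        tv <- c(tv, s + gains[f2])
        te <- c(te, out[f2])
        tf <- c(tf, rep.int(2L, sum(f2)))
      }
      expanded <- expanded + length(tk)
      if (collectEdges) {
        n <- length(mgFrom) + 1L
        mgFrom[[n]] <- rep.int(key, length(tk)); mgTo[[n]] <- tk
        mgW[[n]] <- tv - s; mgE[[n]] <- te; mgF[[n]] <- tf
      }
      # best new value per target key, then strict improvement only
      o <- order(tv, decreasing = TRUE)
      tk <- tk[o]; tv <- tv[o]; te <- te[o]; tf <- tf[o]
      first <- !duplicated(tk)
      tk <- tk[first]; tv <- tv[first]; te <- te[first]; tf <- tf[first]
      imp <- tv > scores[tk]
      if (any(imp)) {
        scores[tk[imp]] <- tv[imp]
        bpState[tk[imp]] <- key
        bpEdge[tk[imp]] <- te[imp]
        bpFamily[tk[imp]] <- tf[imp]
      }
    }
  }

  res <- list(scores = scores, bpState = bpState, bpEdge = bpEdge,
              bpFamily = bpFamily, baseKey = baseKey, baseScore = baseScore,
              nV = nV, nE = nE, expanded = expanded)
  if (collectEdges) {
    res$mgFrom <- unlist(mgFrom); res$mgTo <- unlist(mgTo)
    res$mgWeight <- unlist(mgW); res$mgEdge <- unlist(mgE)
    res$mgFamily <- unlist(mgF)
    if (is.null(res$mgFrom)) {
      res$mgFrom <- integer(0); res$mgTo <- integer(0)
      res$mgWeight <- numeric(0); res$mgEdge <- integer(0)
      res$mgFamily <- integer(0)
    }
  }
  res
}

#' Run the symmetric-difference dynamic program
#'
#' Fills the DP table over a spectrum graph: entry (w, (a,b)) holds the
#' maximum score over all path pairs ending at vertex w and with last
#' edge (a,b). States are processed in ascending vertex order, and within
#' a vertex in ascending edge order, each extended by every outgoing edge
#' of its vertex. The base entry (0, loop) is the score of the empty
#' string, which explains the masses 0 and M.
#'
#' @param graph a [SpectrumGraph-class].
#' @param rec the [SpectrumRecord-class] the graph was built over.
#' @param config a [ScoringConfig-class].
#' @param alphabet the [MassAlphabet-class] of the edge labels.
#' @return A [DPTable-class].
#' @examples
#' toy <- toyAlphabet()
#' rec <- spectrumRecord(c(2, 3), 5)
#' g <- buildSpectrumGraph(rec, toy, pMax = 2)
#' tab <- runDeNovoDelta(g, rec, scoringConfig("symdiff", tolerance = 0), toy)
#' dpEntry(tab, 0, 0, 0)  # base entry: 2
#' dpEntry(tab, 2, 0, 3)  # 4
#' @export
runDeNovoDelta <- function(graph, rec, config, alphabet) {
  core <- .dpCore(graph, rec, config, alphabet, collectEdges = FALSE)
  new("DPTable", scores = core$scores, bpState = core$bpState,
      bpEdge = core$bpEdge, bpFamily = core$bpFamily,
      baseKey = as.integer(core$baseKey), baseScore = core$baseScore,
      nVertices = as.integer(core$nV), nEdges = as.integer(core$nE),
      roles = 1L, graph = graph, config = config)
}

#' Read one DP table entry by masses
#'
#' @param table a [DPTable-class].
#' @param wMass state vertex mass w.
#' @param aMass,bMass source and target mass of the state's edge (a, b);
#'   the base entry is `dpEntry(table, 0, 0, 0)`.
#' @param role for offset-aware tables: 1 if the path ending at w is the
#'   prefix, 2 if it is the suffix; NULL (default) returns the maximum
#'   over roles.
#' @return numeric(1), -Inf for unreachable states.
#' @export
dpEntry <- function(table, wMass, aMass, bMass, role = NULL) {
  g <- table@graph
  v <- g@vertices
  e <- g@edges
  eps <- max(g@tolerance, 1e-6)
  vi <- which(abs(v - wMass) <= eps)[1]
  ei <- which(abs(v[e$from] - aMass) <= eps & abs(v[e$to] - bMass) <= eps)
  if (is.na(vi) || !length(ei)) return(-Inf)
  nVE <- table@nVertices * table@nEdges
  roles <- if (is.null(role)) seq_len(table@roles) else as.integer(role)
  max(vapply(roles, function(r) {
    keys <- (r - 1L) * nVE + .packKey(vi, ei, table@nVertices)
    max(table@scores[keys])
  }, numeric(1)))
}

# terminal state keys (one role layer) and their scores
.terminalKeys <- function(scores, graph, nV, nE, offset = 0L) {
  v <- graph@vertices
  e <- graph@edges
  M <- graph@totalMass
  eps <- max(graph@tolerance, .MERGE_EPS)
  keys <- integer(0)
  for (ei in seq_len(nE)) {
    b <- v[e$to[ei]]
    vis <- which(abs(v + b - M) <= eps)
    if (length(vis)) {
      k <- .packKey(vis, rep.int(ei, length(vis)), nV)
      keys <- c(keys, k[is.finite(scores[offset + k])])
    }
  }
  keys
}

# replay a sequence of (graph edge, family) operations into the two label
# strings; s1 is the path ending at the state vertex
.replayOps <- function(edgesIdx, fams, labels) {
  s1 <- ""
  s2 <- ""
  for (i in seq_along(edgesIdx)) {
    lab <- labels[edgesIdx[i]]
    if (fams[i] == 1L) {
      s1 <- paste0(s1, lab)
    } else {
      tmp <- s2
      s2 <- paste0(s1, lab)
      s1 <- tmp
    }
  }
  c(s1, s2)
}

#' Reconstruct optimal candidates from a DP table
#'
#' Finds all terminal entries (states whose two path ends sum to M within
#' tolerance) achieving the maximum score, follows backpointers to
#' reconstruct the prefix path P and reversed-suffix path Q, and emits
#' `l(P)` concatenated with the reverse of `l(Q)`. Identical peptides are
#' deduplicated; ties are ordered lexicographically.
#'
#' @param table a [DPTable-class].
#' @return A [SequencingResult-class] (empty when no terminal entry is
#'   reachable).
#' @export
tracebackCandidates <- function(table) {
  g <- table@graph
  nV <- table@nVertices
  nE <- table@nEdges
  nVE <- nV * nE
  labels <- g@edges$label
  allKeys <- integer(0)
  allRoles <- integer(0)
  for (r in seq_len(table@roles)) {
    offs <- (r - 1L) * nVE
    tk <- .terminalKeys(table@scores, g, nV, nE, offset = offs)
    allKeys <- c(allKeys, offs + tk)
    allRoles <- c(allRoles, rep.int(r, length(tk)))
  }
  if (!length(allKeys)) {
    return(new("SequencingResult", id = "", peptides = character(0),
               scores = numeric(0), optimum = NA_real_,
               diagnostics = list(tableSize = sum(is.finite(table@scores)))))
  }
  best <- max(table@scores[allKeys])
  sel <- which(table@scores[allKeys] >= best - 1e-9)
  peps <- character(0)
  for (s in sel) {
    key <- allKeys[s]
    edges <- integer(0)
    fams <- integer(0)
    k <- key
    while (table@bpEdge[k] != 0L) {
      edges <- c(table@bpEdge[k], edges)
      fams <- c(table@bpFamily[k], fams)
      k <- table@bpState[k]
    }
    srep <- .replayOps(edges, fams, labels)
    pep <- if (table@roles == 1L || allRoles[s] == 1L) {
      paste0(srep[1], .reverseString(srep[2]))
    } else {
      paste0(srep[2], .reverseString(srep[1]))
    }
    peps <- c(peps, pep)
  }
  peps <- sort(unique(peps))
  new("SequencingResult", id = "", peptides = peps,
      scores = rep(best, length(peps)), optimum = best,
      diagnostics = list(tableSize = sum(is.finite(table@scores))))
}
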