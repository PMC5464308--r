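# Matrix graph over DP states and k-best candidate enumeration. Every
# source-to-terminal path is one extension sequence of the sequencer, its
# weight the summed extension gains; the k best candidate sequences are
# the k longest paths (all terminal nodes feed a dummy sink of weight 0).

#' Build the matrix graph of DP states
#'
#' Nodes are the reachable DP states (w, (a,b)); for every extension step
#' of the sequencer there is a weighted edge between the corresponding
#' states, the weight being the gain of the extension. A node is terminal
#' when its two path ends sum to M within tolerance.
#'
#' @param graph a [SpectrumGraph-class].
#' @param rec the [SpectrumRecord-class] the graph was built over.
#' @param config a [ScoringConfig-class].
#' @param alphabet a [MassAlphabet-class].
#' @return A [MatrixGraph-class].
#' @export
buildMatrixGraph <- function(graph, rec, config, alphabet) {
  core <- .dpCore(graph, rec, config, alphabet, collectEdges = TRUE)
  nV <- core$nV
  v <- graph@vertices
  e <- graph@edges
  M <- graph@totalMass
  eps <- max(graph@tolerance, .MERGE_EPS)

  keys <- sort(unique(c(core$baseKey, core$mgFrom, core$mgTo)))
  vIdx <- .unpackV(keys, nV)
  eIdx <- .unpackE(keys, nV)
  terminal <- abs(v[vIdx] + v[e$to[eIdx]] - M) <= eps
  # topological order: vertex ascending, then edge ascending
  o <- order(vIdx, eIdx)
  keys <- keys[o]; vIdx <- vIdx[o]; eIdx <- eIdx[o]; terminal <- terminal[o]
  nodeOf <- match(c(core$mgFrom, core$mgTo), keys)
  nMG <- length(core$mgFrom)
  nodes <- data.frame(key = keys, v = vIdx, e = eIdx, terminal = terminal)
  new("MatrixGraph", nodes = nodes,
      edgesFrom = nodeOf[seq_len(nMG)],
      edgesTo = nodeOf[nMG + seq_len(nMG)],
      weights = core$mgWeight, gEdge = core$mgEdge, family = core$mgFamily,
      source = match(core$baseKey, keys), baseScore = core$baseScore,
      graph = graph)
}

#' k longest source-to-terminal paths in a matrix graph
#'
#' Computes the k largest-weight paths from the source state to any
#' terminal state (all terminals feed a zero-weight dummy sink) with the
#' standard per-node top-k dynamic program over the topologically ordered
#' DAG. Fewer than k paths are returned iff fewer exist.
#'
#' @param mg a [MatrixGraph-class].
#' @param k integer(1) >= 1.
#' @return list with `weights` (non-increasing numeric), `paths` (list of
#'   matrix-edge index vectors from source to terminal), and `exhausted`
#'   (TRUE when all existing paths are enumerated).
#' @export
kLongestPaths <- function(mg, k) {
  stopifnot(k >= 1)
  nN <- nrow(mg@nodes)
  inc <- rep(list(integer(0)), nN)
  sp <- split(seq_along(mg@edgesTo), mg@edgesTo)
  inc[as.integer(names(sp))] <- sp

  wt <- rep(list(numeric(0)), nN)
  prevSlotEdge <- rep(list(integer(0)), nN)  # matrix-edge index per slot
  prevSlot <- rep(list(integer(0)), nN)      # predecessor slot per slot
  truncated <- FALSE
  wt[[mg@source]] <- 0
  prevSlotEdge[[mg@source]] <- NA_integer_
  prevSlot[[mg@source]] <- NA_integer_

  for (n in seq_len(nN)) {
    ie <- inc[[n]]
    if (!length(ie)) next
    cw <- numeric(0); ce <- integer(0); cs <- integer(0)
    for (me in ie) {
      pw <- wt[[mg@edgesFrom[me]]]
      if (!length(pw)) next
      cw <- c(cw, pw + mg@weights[me])
      ce <- c(ce, rep.int(me, length(pw)))
      cs <- c(cs, seq_along(pw))
    }
    if (n == mg@source) {  # source with incoming edges keeps its seed
      cw <- c(0, cw); ce <- c(NA_integer_, ce); cs <- c(NA_integer_, cs)
    }
    if (!length(cw)) next
    o <- order(cw, decreasing = TRUE)
    if (length(o) > k) {
      truncated <- TRUE
      o <- o[seq_len(k)]
    }
    wt[[n]] <- cw[o]
    prevSlotEdge[[n]] <- ce[o]
    prevSlot[[n]] <- cs[o]
  }

  term <- which(mg@nodes$terminal)
  tw <- numeric(0); tn <- integer(0); ts <- integer(0)
  for (n in term) {
    if (length(wt[[n]])) {
      tw <- c(tw, wt[[n]])
      tn <- c(tn, rep.int(n, length(wt[[n]])))
      ts <- c(ts, seq_along(wt[[n]]))
    }
  }
  o <- order(tw, decreasing = TRUE)
  if (length(o) > k) {
    truncated <- TRUE
    o <- o[seq_len(k)]
  }
  paths <- lapply(o, function(i) {
    n <- tn[i]; s <- ts[i]
    path <- integer(0)
    while (!is.na(prevSlotEdge[[n]][s])) {
      me <- prevSlotEdge[[n]][s]
      path <- c(me, path)
      s <- prevSlot[[n]][s]
      n <- mg@edgesFrom[me]
    }
    path
  })
  list(weights = tw[o], paths = paths, exhausted = !truncated)
}

# matrix-graph path -> peptide string
.pathToPeptide <- function(mg, path) {
  labels <- mg@graph@edges$label
  srep <- .replayOps(mg@gEdge[path], mg@family[path], labels)
  paste0(srep[1], .reverseString(srep[2]))
}

#' Enumerate the k best candidate sequences
#'
#' Converts the longest matrix-graph paths to peptides, deduplicates
#' identical strings (keeping the best score), and continues enumeration
#' until k distinct peptides are found or all paths are exhausted.
#' Optionally filters to candidates scoring at least
#' `max - (1 - floorFraction) * |max|` (with `floorFraction = 0.9`, the
#' at-least-90%-of-the-maximum convention; the absolute value makes the
#' floor well defined for non-positive maxima, degenerating to co-optimal
#' only at max = 0).
#'
#' @param mg a [MatrixGraph-class].
#' @param k integer(1) number of distinct candidate sequences wanted.
#' @param floorFraction NULL (no filter) or a fraction in (0, 1].
#' @param id identifier stored on the result.
#' @return A [SequencingResult-class]: scores non-increasing, ties
#'   lexicographic.
#' @export
enumerateCandidates <- function(mg, k = 10, floorFraction = NULL,
                                id = "spectrum") {
  stopifnot(k >= 1)
  if (!is.null(floorFraction)) {
    stopifnot(floorFraction > 0, floorFraction <= 1)
  }
  K <- max(16L, as.integer(k))
  repeat {
    res <- kLongestPaths(mg, K)
    peps <- vapply(res$paths, function(p) .pathToPeptide(mg, p), character(1))
    scores <- mg@baseScore + res$weights
    keep <- !duplicated(peps)
    peps <- peps[keep]
    scores <- scores[keep]
    if (length(peps) >= k || res$exhausted || K >= 65536L) break
    K <- K * 2L
  }
  if (length(peps) > k) {
    peps <- peps[seq_len(k)]
    scores <- scores[seq_len(k)]
  }
  if (!is.null(floorFraction) && length(scores)) {
    floorVal <- scores[1] - (1 - floorFraction) * abs(scores[1])
    sel <- scores >= floorVal - 1e-9
    peps <- peps[sel]
    scores <- scores[sel]
  }
  o <- order(-scores, peps)
  new("SequencingResult", id = as.character(id), peptides = peps[o],
      scores = scores[o],
      optimum = if (length(scores)) max(scores) else NA_real_,
      diagnostics = list(nodes = nrow(mg@nodes),
                         matrixEdges = length(mg@weights)))
}
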