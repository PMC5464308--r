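# Offset-aware sequencing. Each measured mass may be read under several
# prefix/suffix ion-type offsets, so the extended theoretical spectrum of
# a string is no longer reversal-symmetric and the DP must remember which
# of its two paths carries the prefix. Valid for 2-basic offset sets
# (maximal pairwise offset difference below twice the smallest residue
# mass), which bounds how far an offset can reorder masses.

#' Masses explained by an offset-aware edge extension
#'
#' For an edge with source mass w and label L: in the prefix role, the
#' union of [offsetMasses()] at `w + m(T)` over nonempty label prefixes T;
#' in the suffix role, the union at `M - (w + m(T))` (the path's vertices
#' live on the reversed-suffix scale).
#'
#' @param sourceMass numeric(1) source vertex mass.
#' @param label character(1) edge label.
#' @param M numeric(1) total mass.
#' @param offsets an [IonOffsets-class].
#' @param role "prefix" or "suffix".
#' @param alphabet a [MassAlphabet-class].
#' @param tol numeric(1) deduplication tolerance.
#' @return sorted numeric vector.
#' @examples
#' off <- ionOffsets(0, -1)
#' tseGeneral(0, "a", 5, off, "prefix", toyAlphabet())  # 2
#' tseGeneral(0, "a", 5, off, "suffix", toyAlphabet())  # 1 3
#' @export
tseGeneral <- function(sourceMass, label, M, offsets,
                       role = c("prefix", "suffix"), alphabet, tol = 0) {
  role <- match.arg(role)
  if (!nzchar(label)) return(numeric(0))
  p <- cumsum(.residueVector(label, alphabet))
  pm <- if (role == "prefix") sourceMass + p else M - (sourceMass + p)
  eps <- max(tol, .MERGE_EPS)
  .dedup(unlist(lapply(pm, .om, M = M, offsets = offsets)), eps)
}

#' Newly explained masses of an offset-aware extension
#'
#' The offset-aware TSe set of the appended edge minus everything already
#' explained nearby: the offset readings of the extended path's previous
#' endpoint, the readings of the other path's second-to-last vertex, and
#' the other path's last-edge TSe set. Under 2-basic offsets every
#' earlier vertex of either path is too far away to collide.
#'
#' @inheritParams tseGeneral
#' @param otherSource,otherLabel the other path's last edge (source mass
#'   and label; the empty label denotes the loop edge).
#' @param role role of the path being extended ("prefix" or "suffix").
#' @return sorted numeric vector.
#' @export
newMasses <- function(sourceMass, label, otherSource, otherLabel, M,
                      offsets, role = c("prefix", "suffix"), alphabet,
                      tol = 0) {
  role <- match.arg(role)
  eps <- max(tol, .MERGE_EPS)
  tsex <- tseGeneral(sourceMass, label, M, offsets, role, alphabet, tol)
  if (!length(tsex)) return(numeric(0))
  otherRole <- if (role == "prefix") "suffix" else "prefix"
  otherTse <- tseGeneral(otherSource, otherLabel, M, offsets, otherRole,
                         alphabet, tol)
  if (role == "prefix") {
    removal <- c(.om(sourceMass, M, offsets),
                 .om(M - otherSource, M, offsets), otherTse)
  } else {
    removal <- c(.om(M - sourceMass, M, offsets),
                 .om(otherSource, M, offsets), otherTse)
  }
  tsex[!.inSet(tsex, removal, eps)]
}

#' Run the offset-aware symmetric-difference dynamic program
#'
#' As [runDeNovoDelta()], over an offset-aware graph, with DP states
#' additionally tracking which of the two paths is the prefix and scoring
#' extensions by [newMasses()]. With zero offsets it reduces exactly to
#' the simple program. The optimum equals the maximum of the extended-
#' spectrum score over all strings of mass M.
#'
#' @param graph a [GeneralSpectrumGraph-class].
#' @param rec the [SpectrumRecord-class] the graph was built over.
#' @param config a [ScoringConfig-class].
#' @param alphabet a [MassAlphabet-class].
#' @return A [DPTable-class] with `roles = 2`.
#' @export
runDeNovoDeltaG <- function(graph, rec, config, alphabet) {
  if (!is(graph, "GeneralSpectrumGraph")) {
    .stopf("runDeNovoDeltaG needs a graph built by buildGeneralGraph()")
  }
  offsets <- graph@offsets
  if (!isAlphaBasic(offsets, alphabet, alpha = 2)) {
    .stopf("offset sets violate the 2-basic condition")
  }
  v <- graph@vertices
  e <- graph@edges
  nV <- length(v)
  nE <- nrow(e)
  nVE <- nV * nE
  M <- graph@totalMass
  eps <- max(graph@tolerance, .MERGE_EPS)
  tolD <- max(config@tolerance, .MERGE_EPS)

  loopIdx <- which(e$from == e$to & !nzchar(e$label))
  if (length(loopIdx) != 1L) .stopf("graph must contain exactly one loop edge")

  labPref <- .edgeLabelPrefixes(graph, alphabet)
  srcMass <- v[e$from]
  toMass <- v[e$to]
  omSrc <- lapply(srcMass, .om, M = M, offsets = offsets)
  omMirror <- lapply(M - srcMass, .om, M = M, offsets = offsets)
  tsex <- list(prefix = vector("list", nE), suffix = vector("list", nE))
  for (i in seq_len(nE)) {
    p <- labPref[[i]]
    if (!length(p)) {
      tsex$prefix[[i]] <- numeric(0)
      tsex$suffix[[i]] <- numeric(0)
    } else {
      tsex$prefix[[i]] <- .dedup(unlist(lapply(
        srcMass[i] + p, .om, M = M, offsets = offsets)), tolD)
      tsex$suffix[[i]] <- .dedup(unlist(lapply(
        M - (srcMass[i] + p), .om, M = M, offsets = offsets)), tolD)
    }
  }

  gainMemo <- new.env(hash = TRUE, parent = emptyenv())
  gainG <- function(i, j, newRole) {
    key <- paste0(i, "_", j, "_", newRole)
    got <- gainMemo[[key]]
    if (!is.null(got)) return(got)
    if (newRole == 1L) {
      ts <- tsex$prefix[[i]]
      removal <- c(omSrc[[i]], omMirror[[j]], tsex$suffix[[j]])
    } else {
      ts <- tsex$suffix[[i]]
      removal <- c(omMirror[[i]], omSrc[[j]], tsex$prefix[[j]])
    }
    g <- if (!length(ts)) 0 else {
      kept <- ts[!.inSet(ts, removal, tolD)]
      if (length(kept)) sum(massScore(kept, rec, config)) else 0
    }
    gainMemo[[key]] <- g
    g
  }

  outEdges <- rep(list(integer(0)), nV)
  nonLoop <- which(e$from != e$to)
  sp <- split(nonLoop, e$from[nonLoop])
  outEdges[as.integer(names(sp))] <- sp

  scores <- rep(-Inf, 2L * nVE)
  bpState <- integer(2L * nVE)
  bpEdge <- integer(2L * nVE)
  bpFamily <- integer(2L * nVE)

  idx0 <- which(abs(v) <= eps)[1]
  baseScore <- sum(massScore(
    .dedup(c(offsetMasses(0, M, offsets), offsetMasses(M, M, offsets)), tolD),
    rec, config))
  baseKey <- .packKey(idx0, loopIdx, nV)
  scores[baseKey] <- baseScore          # role 1: empty v-path is prefix
  scores[nVE + baseKey] <- baseScore    # role 2: empty v-path is suffix

  for (vi in seq_len(nV)) {
    out <- outEdges[[vi]]
    if (!length(out)) next
    wIdx <- e$to[out]
    wM <- toMass[out]
    for (ei in seq_len(nE)) {
      for (r in 1:2) {
        key <- (r - 1L) * nVE + .packKey(vi, ei, nV)
        s <- scores[key]
        if (!is.finite(s)) next
        b <- toMass[ei]
        ok <- wM + b <= M + eps
        if (!any(ok)) next
        f1 <- ok & (wM <= b + eps)
        f2 <- ok & !f1
        gains <- vapply(out, gainG, numeric(1), j = ei, newRole = r)
        tk <- integer(0); tv <- numeric(0); te <- integer(0); tf <- integer(0)
        if (any(f1)) {
          tk <- (r - 1L) * nVE + .packKey(wIdx[f1], rep.int(ei, sum(f1)), nV)
          tv <- s + gains[f1]
          te <- out[f1]; tf <- rep.int(1L, sum(f1))
        }
        if (any(f2)) {
          r2 <- 3L - r
          tk <- c(tk, (r2 - 1L) * nVE +
                        .packKey(rep.int(e$to[ei], sum(f2)), out[f2], nV))
          tv <- c(tv, s + gains[f2])
          te <- c(te, out[f2]); tf <- c(tf, rep.int(2L, sum(f2)))
        }
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
  }

  new("DPTable", scores = scores, bpState = bpState, bpEdge = bpEdge,
      bpFamily = bpFamily, baseKey = as.integer(baseKey),
      baseScore = baseScore, nVertices = as.integer(nV),
      nEdges = as.integer(nE), roles = 2L, graph = graph, config = config)
}
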