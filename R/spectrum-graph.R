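# Spectrum multigraph construction: mirrored vertex set, exhaustive label
# enumeration per mass gap, and the offset-aware vertex placement.

#' Mirrored vertex set of a cleaned spectrum
#'
#' Every measured mass m spawns the candidate prefix masses m and M - m.
#' Before mirroring, measured masses closer than `tol` are clustered to a
#' single vertex at their intensity-weighted mean (near-duplicate vertices
#' would otherwise blow up the dynamic program); the mirrored union is
#' clustered the same way.
#'
#' @param rec a [SpectrumRecord-class].
#' @param tol numeric(1) clustering tolerance in Da.
#' @return sorted numeric vector of vertex masses, containing 0 and M.
#' @examples
#' buildVertexSet(spectrumRecord(2, 5))  # 0 2 3 5
#' @export
buildVertexSet <- function(rec, tol = 0) {
  x <- peakMasses(rec)
  if (length(x) == 0L) .stopf("empty mass set")
  M <- totalMass(rec)
  eps <- max(tol, .MERGE_EPS)
  cl <- .clusterWeighted(x, peakIntensities(rec), eps)
  v <- c(cl$x, M - cl$x)
  w <- c(cl$w, cl$w)
  keep <- v >= -eps & v <= M + eps
  cl2 <- .clusterWeighted(pmin(pmax(v[keep], 0), M), w[keep], eps)
  cl2$x
}

#' Enumerate all strings of a given mass
#'
#' All character sequences over the alphabet of length at most `pMax`
#' whose residue-sum mass is within `tol` of `gap`; exhaustive depth-first
#' search with minimum-mass pruning. This is both the edge-label
#' enumeration of the spectrum graph and, with `pMax = ceiling(M / mu)`,
#' an exhaustive enumeration of all peptides of mass M.
#'
#' @param gap numeric(1) target mass (> 0).
#' @param alphabet a [MassAlphabet-class].
#' @param pMax integer(1) maximal length.
#' @param tol numeric(1) mass tolerance.
#' @return character vector of labels (possibly empty), sorted.
#' @examples
#' enumerateLabels(5, toyAlphabet(), pMax = 2)  # "ab" "ba" "c"
#' @export
enumerateLabels <- function(gap, alphabet, pMax, tol = 0) {
  if (gap <= 0) return(character(0))
  masses <- residueMasses(alphabet)
  o <- order(masses)
  masses <- masses[o]
  syms <- names(masses)
  muMin <- masses[1L]
  maxMass <- masses[length(masses)]
  out <- character(0)
  recurse <- function(prefix, mass, depth) {
    if (depth >= pMax) return()
    rem <- gap - mass
    for (i in seq_along(masses)) {
      mi <- masses[[i]]
      if (mi > rem + tol) break
      if (abs(rem - mi) <= tol) {
        out[[length(out) + 1L]] <<- paste0(prefix, syms[[i]])
      }
      # descend only if the residual is still reachable
      if (rem - mi >= muMin - tol &&
          rem - mi <= (pMax - depth - 1L) * maxMass + tol) {
        recurse(paste0(prefix, syms[[i]]), mass + mi, depth + 1L)
      }
    }
  }
  recurse("", 0, 0L)
  sort(unique(out))
}

# Shared edge assembly: all labeled edges between ordered vertex pairs,
# plus the empty-label loop edge at vertex 0 (the DP base case).
.buildEdges <- function(vertices, alphabet, pMax, tol) {
  nV <- length(vertices)
  from <- integer(0); to <- integer(0)
  label <- character(0); mass <- numeric(0)
  # feasible gap range prunes the pair loop; the tolerance is floored at
  # the numeric epsilon so that exact-arithmetic graphs survive last-bit
  # rounding of clustered vertices
  effTol <- max(tol, .MERGE_EPS)
  muMin <- mu(alphabet)
  maxMass <- max(residueMasses(alphabet))
  for (i in seq_len(nV - 1L)) {
    for (j in seq.int(i + 1L, nV)) {
      gap <- vertices[j] - vertices[i]
      if (gap < muMin - effTol) next
      if (gap > pMax * maxMass + effTol) break
      labs <- enumerateLabels(gap, alphabet, pMax, effTol)
      if (length(labs)) {
        from <- c(from, rep(i, length(labs)))
        to <- c(to, rep(j, length(labs)))
        label <- c(label, labs)
        mass <- c(mass, vapply(labs, peptideMass, numeric(1),
                               alphabet = alphabet))
      }
    }
  }
  idx0 <- which(abs(vertices) <= max(tol, .MERGE_EPS))[1]
  df <- data.frame(from = c(idx0, from), to = c(idx0, to),
                   label = c("", label), mass = c(0, mass),
                   stringsAsFactors = FALSE)
  # ascending (source mass, target mass, label): the DP processing order
  df[order(vertices[df$from], vertices[df$to], df$label), , drop = FALSE]
}

#' Build the spectrum multigraph
#'
#' Vertices are the mirrored candidate prefix masses of the cleaned
#' record; for every ordered vertex pair and every string of matching mass
#' (length <= `pMax`) there is one labeled edge. The empty-label loop edge
#' at vertex 0 is materialized as the base case of the dynamic program.
#'
#' @param rec a [SpectrumRecord-class].
#' @param alphabet a [MassAlphabet-class].
#' @param pMax integer maximal label length (default 2: single residues
#'   plus one-peak bridging; use `ceiling(M / mu)` for completeness).
#' @param tol numeric(1) mass tolerance in Da.
#' @return A [SpectrumGraph-class].
#' @examples
#' g <- buildSpectrumGraph(spectrumRecord(2, 5), toyAlphabet(), pMax = 2)
#' graphEdges(g)
#' @export
buildSpectrumGraph <- function(rec, alphabet, pMax = 2L, tol = 0) {
  v <- buildVertexSet(rec, tol)
  edges <- .buildEdges(v, alphabet, as.integer(pMax), tol)
  g <- new("SpectrumGraph", vertices = v, edges = edges,
           totalMass = totalMass(rec), pMax = as.integer(pMax),
           tolerance = as.numeric(tol))
  if (!.hasTerminalPath(g)) {
    .warnf("spectrum graph of '%s' has no 0 -> M connectivity; sequencing will return no candidates",
           spectrumId(rec))
  }
  g
}

# is some prefix/suffix split of M reachable? cheap forward reachability
.hasTerminalPath <- function(graph) {
  v <- graph@vertices
  e <- graph@edges
  M <- graph@totalMass
  tol <- max(graph@tolerance, 1e-9)
  reach <- abs(v) <= tol
  loop <- e$from == e$to
  repeat {
    new <- reach[e$from[!loop]] & !reach[e$to[!loop]]
    if (!any(new)) break
    reach[e$to[!loop][new]] <- TRUE
  }
  # a solution pairs reachable v and w with v + w = M
  any(outer(v[reach], v[reach], function(a, b) abs(a + b - M) <= tol))
}

#' Build the offset-aware spectrum multigraph
#'
#' Every measured mass m is interpreted under every offset delta in
#' `O_p` and `O_s`, placing both the direct reading `m - delta` and its
#' complement `M - (m - delta)` as candidate vertices (the two-sided
#' mirroring that reduces to the plain mirrored vertex set at zero
#' offsets; the complement vertices are what let the prefix path explain
#' suffix-type peaks and vice versa). Vertices are clipped to `[0, M]`
#' and 0 and M are always present. The offset sets must be 2-basic
#' (`gammaMax(offsets) < 2 * mu(alphabet)`), otherwise the extension
#' bookkeeping of the offset-aware sequencer is invalid and construction
#' is refused.
#'
#' @inheritParams buildSpectrumGraph
#' @param offsets an [IonOffsets-class].
#' @return A [GeneralSpectrumGraph-class].
#' @export
buildGeneralGraph <- function(rec, alphabet, offsets, pMax = 2L, tol = 0) {
  if (!isAlphaBasic(offsets, alphabet, alpha = 2)) {
    .stopf("offset sets violate the 2-basic condition: gamma = %g >= 2 * mu = %g",
           gammaMax(offsets), 2 * mu(alphabet))
  }
  x <- peakMasses(rec)
  ints <- peakIntensities(rec)
  M <- totalMass(rec)
  eps <- max(tol, .MERGE_EPS)
  delta <- c(offsets@prefix, offsets@suffix)
  side <- rep(c("prefix", "suffix"),
              c(length(offsets@prefix), length(offsets@suffix)))
  nD <- length(delta)
  direct <- as.vector(outer(x, delta, `-`))
  cand <- data.frame(
    vertex = c(direct, M - direct),
    measured = rep.int(rep(x, nD), 2L),
    offset = rep.int(rep(delta, each = length(x)), 2L),
    role = rep.int(rep(side, each = length(x)), 2L),
    mirrored = rep(c(FALSE, TRUE), each = length(x) * nD),
    weight = rep.int(rep(ints, nD), 2L),
    stringsAsFactors = FALSE)
  keep <- cand$vertex >= -eps & cand$vertex <= M + eps
  cand <- cand[keep, , drop = FALSE]
  cand$vertex <- pmin(pmax(cand$vertex, 0), M)
  cl <- .clusterWeighted(c(cand$vertex, 0, M), c(cand$weight, 1e-12, 1e-12),
                         eps)
  v <- cl$x
  # provenance: map each interpretation to its cluster representative
  repIdx <- .nearestWithin(cand$vertex, v, eps + .MERGE_EPS)
  prov <- data.frame(vertex = v[repIdx], measured = cand$measured,
                     offset = cand$offset, role = cand$role,
                     mirrored = cand$mirrored, stringsAsFactors = FALSE)
  edges <- .buildEdges(v, alphabet, as.integer(pMax), tol)
  new("GeneralSpectrumGraph", vertices = v, edges = edges,
      totalMass = M, pMax = as.integer(pMax), tolerance = as.numeric(tol),
      offsets = offsets, provenance = prov)
}

#' @rdname graphVertices
#' @export
setGeneric("graphVertices", function(object) standardGeneric("graphVertices"))

#' Accessors for SpectrumGraph
#'
#' `graphVertices()` returns the sorted vertex masses and `graphEdges()`
#' the edge table (`from`/`to` vertex indices, `label`, `mass`).
#'
#' @param object a [SpectrumGraph-class].
#' @return numeric vector, respectively data.frame.
#' @aliases graphVertices graphEdges
#' @export
setMethod("graphVertices", "SpectrumGraph", function(object) object@vertices)

#' @rdname graphVertices
#' @export
setGeneric("graphEdges", function(object) standardGeneric("graphEdges"))

#' @rdname graphVertices
#' @export
setMethod("graphEdges", "SpectrumGraph", function(object) object@edges)

#' Export a spectrum graph in DOT format
#'
#' @param graph a [SpectrumGraph-class].
#' @param path file path, or NULL to return the DOT text invisibly.
#' @return character vector of DOT lines, invisibly.
#' @export
graphToDot <- function(graph, path = NULL) {
  v <- graph@vertices
  e <- graph@edges
  lines <- c("digraph spectrum {", "  rankdir=LR;",
    sprintf('  v%d [label="%.4f"];', seq_along(v), v),
    sprintf('  v%d -> v%d [label="%s"];', e$from, e$to,
            ifelse(nzchar(e$label), e$label, "(empty)")),
    "}")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
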