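#' @import methods
NULL

#' Amino-acid mass alphabet
#'
#' A finite set of single-character residue symbols with positive
#' monoisotopic residue masses. `mu` caches the smallest residue mass,
#' the quantity that bounds spectrum-graph edge lengths and the validity
#' of offset sets.
#'
#' @slot symbols character vector of unique single-character symbols.
#' @slot masses named numeric vector, residue mass (Da) per symbol.
#' @slot mu numeric(1), the smallest residue mass.
#' @slot collapseIsobaric logical(1), whether isobaric residues (I/L)
#'   were collapsed to a single symbol when the alphabet was built.
#' @seealso [standardAlphabet()], [toyAlphabet()], [readAlphabet()]
#' @export
setClass("MassAlphabet",
  representation(symbols = "character", masses = "numeric",
                 mu = "numeric", collapseIsobaric = "logical"))

setValidity("MassAlphabet", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@symbols)) {
    msg <- c(msg, "alphabet symbols must be unique")
  }
  if (any(nchar(object@symbols) != 1L)) {
    msg <- c(msg, "alphabet symbols must be single characters")
  }
  if (length(object@masses) != length(object@symbols) ||
      !identical(names(object@masses), object@symbols)) {
    msg <- c(msg, "masses must be named by the symbols")
  }
  if (any(!is.finite(object@masses)) || any(object@masses <= 0)) {
    msg <- c(msg, "all residue masses must be positive and finite")
  }
  if (length(object@mu) != 1L ||
      abs(object@mu - min(object@masses)) > .MERGE_EPS) {
    msg <- c(msg, "mu must equal the minimum residue mass")
  }
  if (length(msg)) msg else TRUE
})

#' Prefix/suffix ion-type mass offsets
#'
#' Sets of mass offsets (Da) applied to prefix fragments and to suffix
#' fragments when interpreting measured peaks. The maximal pairwise
#' difference `gamma` over the union of both sets determines whether the
#' sets are alpha-basic (`gamma < alpha * mu`), the condition under which
#' the offset-aware sequencer's bookkeeping is valid (alpha = 2).
#'
#' @slot prefix numeric, offsets for prefix fragments (O_p).
#' @slot suffix numeric, offsets for suffix fragments (O_s).
#' @seealso [ionOffsets()], [byIonOffsets()], [gammaMax()], [isAlphaBasic()]
#' @export
setClass("IonOffsets",
  representation(prefix = "numeric", suffix = "numeric"))

setValidity("IonOffsets", function(object) {
  msg <- character(0)
  if (length(object@prefix) == 0L || length(object@suffix) == 0L) {
    msg <- c(msg, "prefix and suffix offset sets must be non-empty")
  }
  if (any(!is.finite(c(object@prefix, object@suffix)))) {
    msg <- c(msg, "offsets must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' Raw peak list of one tandem-MS spectrum
#'
#' A measured spectrum as read from an MGF file: precursor m/z and charge
#' plus (m/z, intensity) fragment peaks, before any conversion to the
#' prefix-mass space.
#'
#' @slot id character(1) spectrum identifier (MGF TITLE).
#' @slot precursorMz numeric(1) precursor m/z.
#' @slot charge integer(1) precursor charge (>= 1).
#' @slot mz numeric, fragment m/z values sorted ascending.
#' @slot intensity numeric, non-negative intensities parallel to `mz`.
#' @seealso [rawSpectrum()], [readMGF()], [toPrefixSpace()]
#' @export
setClass("RawSpectrum",
  representation(id = "character", precursorMz = "numeric",
                 charge = "integer", mz = "numeric", intensity = "numeric"))

setValidity("RawSpectrum", function(object) {
  msg <- character(0)
  if (is.unsorted(object@mz)) msg <- c(msg, "peaks must be sorted by m/z")
  if (length(object@mz) != length(object@intensity)) {
    msg <- c(msg, "mz and intensity lengths differ")
  }
  if (any(object@intensity < 0)) msg <- c(msg, "intensities must be >= 0")
  if (object@charge < 1L) msg <- c(msg, "charge must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Cleaned spectrum in prefix-mass space
#'
#' The input of the sequencing algorithms: a sorted set X of fragment
#' masses on the residue-sum scale, guaranteed to contain 0 and the total
#' residue mass M, with an intensity per mass.
#'
#' @slot id character(1) identifier.
#' @slot masses numeric, sorted masses including 0 and M; `[0, M]` for
#'   simple-problem records, extending to M plus the largest suffix
#'   offset for offset-space records.
#' @slot intensity numeric parallel to `masses` (terminal masses carry a
#'   virtual intensity, by default the median measured intensity).
#' @slot totalMass numeric(1), residue-sum peptide mass M (water removed).
#' @seealso [spectrumRecord()], [toPrefixSpace()]
#' @export
setClass("SpectrumRecord",
  representation(id = "character", masses = "numeric",
                 intensity = "numeric", totalMass = "numeric"))

setValidity("SpectrumRecord", function(object) {
  msg <- character(0)
  m <- object@masses
  M <- object@totalMass
  if (length(m) == 0L) msg <- c(msg, "mass set is empty")
  if (is.unsorted(m)) msg <- c(msg, "masses must be sorted")
  if (length(m) && min(m) < -1e-6) {
    msg <- c(msg, "masses must be non-negative")
  }
  if (length(m) && (abs(m[1]) > 1e-6 || !any(abs(m - M) <= 1e-6))) {
    msg <- c(msg, "cleaned mass set must contain 0 and M")
  }
  if (length(object@intensity) != length(m)) {
    msg <- c(msg, "intensity must be parallel to masses")
  }
  if (length(msg)) msg else TRUE
})

#' Scoring configuration
#'
#' Selects the per-mass score applied to every mass a candidate sequence
#' explains: `scp` (shared peaks count), `symdiff` (+1 matched / -1
#' unmatched; maximizing it minimizes the symmetric difference), and their
#' intensity-weighted variants `wscp` and `wsymdiff` (matched masses score
#' their measured intensity; for `wsymdiff` unmatched masses score a
#' constant penalty).
#'
#' @slot variant character(1), one of "scp", "symdiff", "wscp", "wsymdiff".
#' @slot tolerance numeric(1), peak-matching tolerance epsilon (Da), >= 0.
#' @slot penalty numeric(1), constant penalty for unmatched masses under
#'   `wsymdiff` (must be <= 0; default -2500).
#' @seealso [scoringConfig()], [massScore()], [scoreString()]
#' @export
setClass("ScoringConfig",
  representation(variant = "character", tolerance = "numeric",
                 penalty = "numeric"))

setValidity("ScoringConfig", function(object) {
  msg <- character(0)
  if (!object@variant %in% c("scp", "symdiff", "wscp", "wsymdiff")) {
    msg <- c(msg, "unknown scoring variant")
  }
  if (object@tolerance < 0) msg <- c(msg, "tolerance must be >= 0")
  if (object@variant == "wsymdiff" && object@penalty > 0) {
    msg <- c(msg, "penalty must be <= 0 for wsymdiff")
  }
  if (length(msg)) msg else TRUE
})

#' Spectrum multigraph
#'
#' Directed acyclic multigraph on candidate prefix masses: the vertex set
#' mirrors every measured mass m as both m and M-m, and an edge labeled
#' with an amino-acid string connects two vertices whose mass gap equals
#' the label mass (within tolerance). Parallel edges carry the different
#' strings of equal mass. A loop edge at vertex 0 with the empty label is
#' the base case of the dynamic program.
#'
#' @slot vertices numeric, sorted vertex masses (0 and M included).
#' @slot edges data.frame with columns `from`, `to` (vertex indices),
#'   `label` (string), `mass` (label mass); loop edge first.
#' @slot totalMass numeric(1) M.
#' @slot pMax integer(1) maximal label length used for enumeration.
#' @slot tolerance numeric(1) mass tolerance used in construction.
#' @seealso [buildSpectrumGraph()]
#' @export
setClass("SpectrumGraph",
  representation(vertices = "numeric", edges = "data.frame",
                 totalMass = "numeric", pMax = "integer",
                 tolerance = "numeric"))

setValidity("SpectrumGraph", function(object) {
  msg <- character(0)
  e <- object@edges
  need <- c("from", "to", "label", "mass")
  if (!all(need %in% names(e))) {
    return("edges must have columns from, to, label, mass")
  }
  v <- object@vertices
  if (is.unsorted(v)) msg <- c(msg, "vertices must be sorted")
  if (nrow(e)) {
    loop <- e$from == e$to
    if (any(loop & nzchar(e$label))) {
      msg <- c(msg, "only the empty-label loop edge may have from == to")
    }
    if (any(v[e$to[!loop]] <= v[e$from[!loop]])) {
      msg <- c(msg, "edges must be directed from smaller to larger mass")
    }
    gap <- v[e$to] - v[e$from]
    if (any(abs(e$mass - gap) > object@tolerance + 1e-6)) {
      msg <- c(msg, "edge label mass must match the vertex gap")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Offset-aware spectrum multigraph
#'
#' A [SpectrumGraph-class] whose vertices are the prefix-mass readings of
#' each measured mass under every prefix/suffix offset, for the
#' offset-aware (general) sequencer.
#'
#' @slot offsets the [IonOffsets-class] used to place vertices.
#' @slot provenance data.frame mapping each vertex to the measured mass,
#'   interpreting offset and fragment role that produced it.
#' @export
setClass("GeneralSpectrumGraph", contains = "SpectrumGraph",
  representation(offsets = "IonOffsets", provenance = "data.frame"))

#' Dynamic-programming table of the symmetric-difference sequencer
#'
#' Sparse table of states (w, (a,b)): the best score of any two paths from
#' vertex 0 ending at vertex w and with last edge (a,b), one path holding
#' the prefix and the other the reversed suffix of a candidate sequence.
#' The offset-aware variant additionally distinguishes which path is the
#' prefix (`roles = 2`).
#'
#' @slot scores numeric vector indexed by packed state key (-Inf =
#'   unreachable).
#' @slot bpState,bpEdge,bpFamily integer backpointers per state: the
#'   predecessor state key, the appended graph edge, and which extension
#'   family produced the entry.
#' @slot baseKey integer(1) packed key of the base state (0, loop).
#' @slot baseScore numeric(1) value of the base entry.
#' @slot nVertices,nEdges,roles integer(1) table geometry.
#' @slot graph the [SpectrumGraph-class] the table was computed over.
#' @slot config the [ScoringConfig-class] used.
#' @seealso [runDeNovoDelta()], [runDeNovoDeltaG()], [tracebackCandidates()]
#' @export
setClass("DPTable",
  representation(scores = "numeric", bpState = "integer",
                 bpEdge = "integer", bpFamily = "integer",
                 baseKey = "integer", baseScore = "numeric",
                 nVertices = "integer", nEdges = "integer",
                 roles = "integer", graph = "SpectrumGraph",
                 config = "ScoringConfig"))

#' Matrix graph of dynamic-programming states
#'
#' Directed acyclic graph whose nodes are reachable DP states and whose
#' weighted edges are the extension steps of the sequencer; every path
#' from the source state (0, loop) to a terminal state spells a candidate
#' peptide whose score is the base value plus the path weight. The k best
#' candidate sequences are the k longest source-to-terminal paths.
#'
#' @slot nodes data.frame: packed state `key`, vertex index `v`, edge
#'   index `e`, logical `terminal`.
#' @slot edgesFrom,edgesTo integer node indices per matrix edge.
#' @slot weights numeric matrix-edge weights (extension gains).
#' @slot gEdge integer index of the spectrum-graph edge appended.
#' @slot family integer extension family (1 or 2) per matrix edge.
#' @slot source integer(1) node index of the base state.
#' @slot baseScore numeric(1) score of the base state.
#' @slot graph the underlying [SpectrumGraph-class].
#' @seealso [buildMatrixGraph()], [kLongestPaths()], [enumerateCandidates()]
#' @export
setClass("MatrixGraph",
  representation(nodes = "data.frame", edgesFrom = "integer",
                 edgesTo = "integer", weights = "numeric",
                 gEdge = "integer", family = "integer",
                 source = "integer", baseScore = "numeric",
                 graph = "SpectrumGraph"))

#' Ranked candidate sequences for one spectrum
#'
#' @slot id character(1) spectrum identifier.
#' @slot peptides character, candidate sequences, scores non-increasing,
#'   ties in lexicographic order, deduplicated.
#' @slot scores numeric parallel to `peptides`.
#' @slot optimum numeric(1) best achievable score (NA if no candidate).
#' @slot diagnostics list (table size, edges expanded, ...).
#' @seealso [sequenceSpectrum()], [tracebackCandidates()],
#'   [enumerateCandidates()]
#' @export
setClass("SequencingResult",
  representation(id = "character", peptides = "character",
                 scores = "numeric", optimum = "numeric",
                 diagnostics = "list"))

setValidity("SequencingResult", function(object) {
  msg <- character(0)
  if (length(object@peptides) != length(object@scores)) {
    msg <- c(msg, "peptides and scores lengths differ")
  }
  if (length(object@scores) > 1L && any(diff(object@scores) > 1e-9)) {
    msg <- c(msg, "candidate scores must be non-increasing")
  }
  if (anyDuplicated(object@peptides)) {
    msg <- c(msg, "candidates must be deduplicated")
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic-spectrum simulation parameters
#'
#' Defines the study conditions the simulator emulates: a ground-truth
#' tryptic peptide, its fragment-mass ladder, random dropout of internal
#' fragment peaks, spurious uniform noise peaks, mass jitter, and
#' log-normal intensities.
#'
#' @slot nPeptides integer(1) number of spectra.
#' @slot lengthRange integer(2) min/max peptide length.
#' @slot missProb numeric(1) dropout probability q in `[0, 1)` for each
#'   internal fragment peak.
#' @slot nNoise integer(1) spurious peaks per spectrum.
#' @slot massSigma numeric(1) Gaussian m/z jitter scale (Da).
#' @slot intensityMeanlog,intensitySdlog numeric(1) log-normal intensity
#'   model parameters.
#' @slot offsetsMode character(1) "none" (peaks at theoretical prefix/
#'   suffix masses) or "by" (b/y ion m/z encoding).
#' @slot trypticTerminus logical(1) force the last residue to K or R.
#' @slot seed integer(1) RNG seed; fully determines the output.
#' @seealso [simulationParams()], [emitDataset()]
#' @export
setClass("SimulationParams",
  representation(nPeptides = "integer", lengthRange = "integer",
                 missProb = "numeric", nNoise = "integer",
                 massSigma = "numeric", intensityMeanlog = "numeric",
                 intensitySdlog = "numeric", offsetsMode = "character",
                 trypticTerminus = "logical", seed = "integer"))

setValidity("SimulationParams", function(object) {
  msg <- character(0)
  if (object@missProb < 0 || object@missProb >= 1) {
    msg <- c(msg, "missProb must be in [0, 1)")
  }
  if (object@nNoise < 0L) msg <- c(msg, "nNoise must be >= 0")
  if (object@massSigma < 0) msg <- c(msg, "massSigma must be >= 0")
  if (length(object@lengthRange) != 2L ||
      object@lengthRange[1] < 1L ||
      object@lengthRange[2] < object@lengthRange[1]) {
    msg <- c(msg, "lengthRange must be an increasing pair of lengths >= 1")
  }
  if (!object@offsetsMode %in% c("none", "by")) {
    msg <- c(msg, "offsetsMode must be 'none' or 'by'")
  }
  if (length(msg)) msg else TRUE
})

#' Benchmark report comparing scoring variants
#'
#' @slot rows data.frame, one row per (spectrum, variant): id, variant,
#'   truth, rank of the true sequence (NA if absent), recall of the
#'   best-scoring sequence, optimum score, number of candidates.
#' @slot aggregates data.frame per variant: identification rate (truth at
#'   rank 1), fraction with the truth among the top `kWindow`, fraction
#'   with best recall >= `recallFloor`.
#' @seealso [summarizeBenchmark()]
#' @export
setClass("BenchmarkReport",
  representation(rows = "data.frame", aggregates = "data.frame"))
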