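# Evaluation: prefix-mass recall, rank of the true sequence, and the
# paired benchmark summary comparing scoring variants on identical
# spectra.

#' Prefix-mass recall of a reported sequence
#'
#' Number of prefix masses the reported sequence shares with the true
#' sequence (tolerant intersection) divided by the number of prefix
#' masses of the true sequence. By default the trivial masses 0 and the
#' full mass count as shared; `internalOnly = TRUE` restricts to internal
#' prefix masses for sensitivity analyses.
#'
#' @param reported,truth non-empty peptide strings.
#' @param alphabet a [MassAlphabet-class].
#' @param tol numeric(1) matching tolerance (Da).
#' @param internalOnly drop the terminal masses 0 and M from both ladders.
#' @return numeric(1) in `[0, 1]`.
#' @examples
#' peptideRecall("c", "ab", toyAlphabet())   # 2/3: shares 0 and 5
#' @export
peptideRecall <- function(reported, truth, alphabet, tol = 0,
                          internalOnly = FALSE) {
  if (!nzchar(reported) || !nzchar(truth)) {
    .stopf("recall needs non-empty sequences")
  }
  pr <- prefixMasses(reported, alphabet)
  pt <- prefixMasses(truth, alphabet)
  if (internalOnly) {
    pr <- pr[-c(1L, length(pr))]
    pt <- pt[-c(1L, length(pt))]
    if (!length(pt)) return(NA_real_)
  }
  sum(.inSet(pt, pr, max(tol, .MERGE_EPS))) / length(pt)
}

#' Rank of the true sequence in a candidate list
#'
#' 1-based index of the first candidate equal to the truth after isobaric
#' (I/L) collapse; NA when absent. Candidates must already be
#' deduplicated and sorted by (score descending, lexicographic), as
#' [SequencingResult-class] objects are.
#'
#' @param candidates character vector of ranked candidate peptides, or a
#'   [SequencingResult-class].
#' @param truth character(1) true sequence.
#' @return integer(1) or NA.
#' @export
rankOfTrue <- function(candidates, truth) {
  if (is(candidates, "SequencingResult")) {
    candidates <- candidatePeptides(candidates)
  }
  hit <- which(collapseIsobaric(candidates) == collapseIsobaric(truth))
  if (length(hit)) hit[1] else NA_integer_
}

#' Summarize a benchmark over scoring variants
#'
#' For each spectrum and each variant's candidate list: the rank of the
#' true sequence, and the recall of the best-scoring sequence (when
#' several candidates tie for the best score, the one with the highest
#' recall is taken). Aggregates per variant: identification rate, the
#' fraction with the truth among the top `kWindow` candidates, and the
#' fraction whose best-scoring sequence reaches a recall of at least
#' `recallFloor`. A spectrum counts as identified when the truth attains
#' the maximal score: ties among best-scoring sequences favor the truth,
#' consistent with resolving ties by the candidate of highest recall
#' (on an ideal spectrum the truth always ties with its reversal, which
#' explains the same mass set).
#'
#' @param resultsByVariant named list (one element per scoring variant) of
#'   lists of [SequencingResult-class] objects.
#' @param truth data.frame with columns `spectrum_id`, `peptide`.
#' @param alphabet a [MassAlphabet-class].
#' @param kWindow top-rank window (default 10).
#' @param recallFloor recall threshold (default 0.8).
#' @param tol mass tolerance for recall (Da).
#' @return A [BenchmarkReport-class].
#' @export
summarizeBenchmark <- function(resultsByVariant, truth, alphabet,
                               kWindow = 10L, recallFloor = 0.8, tol = 0) {
  stopifnot(is.list(resultsByVariant), !is.null(names(resultsByVariant)))
  rows <- list()
  for (variant in names(resultsByVariant)) {
    for (res in resultsByVariant[[variant]]) {
      ti <- match(res@id, truth$spectrum_id)
      if (is.na(ti)) {
        .warnf("spectrum '%s' missing from the truth table; skipped", res@id)
        next
      }
      tru <- truth$peptide[ti]
      rk <- rankOfTrue(res, tru)
      identified <- !is.na(rk) &&
        res@scores[rk] >= res@scores[1] - 1e-9
      bestRecall <- NA_real_
      if (length(res@peptides)) {
        top <- which(res@scores >= res@scores[1] - 1e-9)
        bestRecall <- max(vapply(res@peptides[top], peptideRecall,
                                 numeric(1), truth = tru,
                                 alphabet = alphabet, tol = tol))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        spectrum_id = res@id, variant = variant, truth = tru,
        rank_of_truth = rk, identified = identified,
        best_recall = bestRecall, optimum = res@optimum,
        n_candidates = length(res@peptides), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(new("BenchmarkReport",
               rows = data.frame(), aggregates = data.frame()))
  }
  rows <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(rows, rows$variant), function(d) {
    data.frame(variant = d$variant[1],
               n = nrow(d),
               identification_rate = mean(d$identified),
               top_k_rate = mean(!is.na(d$rank_of_truth) &
                                   d$rank_of_truth <= kWindow),
               recall_rate = mean(!is.na(d$best_recall) &
                                    d$best_recall >= recallFloor),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  new("BenchmarkReport", rows = rows, aggregates = agg)
}

#' @rdname reportRows
#' @export
setGeneric("reportRows", function(object) standardGeneric("reportRows"))

#' Accessors for BenchmarkReport
#'
#' `reportRows()` returns the per-spectrum rows and `reportAggregates()`
#' the per-variant aggregate rates.
#'
#' @param object a [BenchmarkReport-class].
#' @return data.frame.
#' @aliases reportRows reportAggregates
#' @export
setMethod("reportRows", "BenchmarkReport", function(object) object@rows)

#' @rdname reportRows
#' @export
setGeneric("reportAggregates",
           function(object) standardGeneric("reportAggregates"))

#' @rdname reportRows
#' @export
setMethod("reportAggregates", "BenchmarkReport",
          function(object) object@aggregates)
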