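# MGF peak-list input/output, profile-peak merging, conversion of
# measured peaks into the prefix-mass space, and the candidates /
# ground-truth TSV formats.

#' Read an MGF peak-list file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with TITLE, PEPMASS (first token
#' is the precursor m/z) and CHARGE (e.g. `2+`) headers and two-column
#' whitespace-separated peak lines. Block order is preserved. Blocks
#' without PEPMASS are skipped with a warning; a missing CHARGE defaults
#' to 1+ with a warning.
#'
#' @param path file path.
#' @return list of [RawSpectrum-class] objects.
#' @export
readMGF <- function(path) {
  lines <- readLines(path)
  begins <- grep("^BEGIN IONS\\s*$", lines)
  ends <- grep("^END IONS\\s*$", lines)
  if (length(begins) != length(ends) || any(ends < begins)) {
    .stopf("malformed MGF '%s': unbalanced BEGIN/END IONS", path)
  }
  out <- list()
  for (bi in seq_along(begins)) {
    block <- lines[seq.int(begins[bi] + 1L, ends[bi] - 1L)]
    block <- block[nzchar(trimws(block))]
    headers <- grepl("=", block, fixed = TRUE)
    hv <- block[headers]
    keys <- toupper(sub("=.*$", "", hv))
    vals <- sub("^[^=]*=", "", hv)
    title <- if ("TITLE" %in% keys) vals[match("TITLE", keys)] else
      sprintf("spectrum_%d", bi)
    if (!"PEPMASS" %in% keys) {
      .warnf("MGF block %d has no PEPMASS; skipped", bi)
      next
    }
    pepmass <- as.numeric(strsplit(trimws(vals[match("PEPMASS", keys)]),
                                   "\\s+")[[1]][1])
    if ("CHARGE" %in% keys) {
      charge <- as.integer(gsub("[^0-9]", "", vals[match("CHARGE", keys)]))
    } else {
      .warnf("MGF block %d ('%s') has no CHARGE; assuming 1+", bi, title)
      charge <- 1L
    }
    peakLines <- block[!headers]
    if (length(peakLines)) {
      fields <- strsplit(trimws(peakLines), "\\s+")
      bad <- lengths(fields) < 2L
      if (any(bad)) .stopf("malformed peak line in MGF block %d", bi)
      mz <- as.numeric(vapply(fields, `[`, character(1), 1L))
      int <- as.numeric(vapply(fields, `[`, character(1), 2L))
      if (anyNA(mz) || anyNA(int)) {
        .stopf("non-numeric peak values in MGF block %d", bi)
      }
    } else {
      mz <- numeric(0)
      int <- numeric(0)
    }
    out[[length(out) + 1L]] <- rawSpectrum(title, pepmass, charge, mz, int)
  }
  out
}

#' Write spectra to an MGF file
#'
#' @param spectra list of [RawSpectrum-class] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMGF <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", sp@id),
                 sprintf("PEPMASS=%.6f", sp@precursorMz),
                 sprintf("CHARGE=%d+", sp@charge),
                 sprintf("%.6f %.6f", sp@mz, sp@intensity),
                 "END IONS", ""), con)
  }
  invisible(path)
}

#' Merge profile-mode peak clusters
#'
#' Maximal runs of consecutive peaks whose inter-peak m/z gap is at most
#' `window` are replaced by one centroid peak at the intensity-weighted
#' mean m/z with the summed intensity. Total intensity is conserved and
#' the peak count never increases.
#'
#' @param spectrum a [RawSpectrum-class] (peaks sorted by m/z).
#' @param window numeric(1) maximal intra-cluster gap in Da.
#' @return A [RawSpectrum-class].
#' @examples
#' sp <- rawSpectrum("s", 100, 1, c(100.00, 100.05), c(10, 30))
#' mergeProfilePeaks(sp, window = 0.1)@mz  # 100.0375
#' @export
mergeProfilePeaks <- function(spectrum, window) {
  cl <- .clusterWeighted(spectrum@mz, spectrum@intensity, eps = window)
  rawSpectrum(spectrum@id, spectrum@precursorMz, spectrum@charge,
              cl$x, cl$w)
}

#' Convert a raw spectrum to prefix-mass space
#'
#' The neutral peptide mass is `precursorMz * z - z * proton`; removing
#' one water gives the residue-sum mass M. Fragments are assumed singly
#' charged, so each fragment neutral mass is `mz - proton`. In `simple`
#' mode the fragment neutrals are used directly as the mass set X (peaks
#' above `M + tol` are dropped, with a message); in `by-offsets` mode
#' they are kept unshifted and returned together with the b/y
#' [IonOffsets-class] (`O_p = {0}`, `O_s = {water}`) for the offset-aware
#' sequencer.
#'
#' @param spectrum a [RawSpectrum-class].
#' @param mode "simple" or "by-offsets".
#' @param tol numeric(1) clipping tolerance (Da).
#' @return In simple mode a [SpectrumRecord-class]; in by-offsets mode a
#'   list with elements `record` and `offsets`.
#' @export
toPrefixSpace <- function(spectrum, mode = c("simple", "by-offsets"),
                          tol = 0.02) {
  mode <- match.arg(mode)
  z <- spectrum@charge
  neutral <- spectrum@precursorMz * z - z * .PROTON_MASS
  M <- cleanPrecursorMass(neutral)
  frag <- spectrum@mz - .PROTON_MASS
  if (mode == "simple") {
    spectrumRecord(frag, M, intensity = spectrum@intensity,
                   id = spectrum@id, tol = tol)
  } else {
    offsets <- byIonOffsets()
    rec <- spectrumRecord(frag, M, intensity = spectrum@intensity,
                          id = spectrum@id, tol = tol,
                          maxMass = M + max(offsets@suffix, 0))
    list(record = rec, offsets = offsets)
  }
}

#' Write ranked candidates to a TSV file
#'
#' One row per candidate: `spectrum_id`, `rank`, `peptide`, `score`,
#' `mass`, `n_candidates`; tab-separated with a header line, UTF-8,
#' deterministic order.
#'
#' @param results list of [SequencingResult-class] objects.
#' @param path output path.
#' @param alphabet a [MassAlphabet-class] used to report candidate masses.
#' @param header optional character vector of `#`-prefixed provenance
#'   lines written above the column header (the CLI serializes its
#'   resolved configuration here).
#' @return `path`, invisibly.
#' @export
writeCandidates <- function(results, path, alphabet, header = NULL) {
  rows <- lapply(results, function(res) {
    n <- length(res@peptides)
    if (n == 0L) return(NULL)
    data.frame(spectrum_id = res@id, rank = seq_len(n),
               peptide = res@peptides, score = res@scores,
               mass = vapply(res@peptides, peptideMass, numeric(1),
                             alphabet = alphabet),
               n_candidates = n, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(
    data.frame(spectrum_id = character(0), rank = integer(0),
               peptide = character(0), score = numeric(0),
               mass = numeric(0), n_candidates = integer(0)))))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a candidates TSV written by [writeCandidates()]
#'
#' @param path file path.
#' @return data.frame.
#' @export
readCandidates <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Read / write a ground-truth table
#'
#' Two tab-separated columns with header: `spectrum_id`, `peptide`.
#'
#' @param truth data.frame with columns `spectrum_id`, `peptide`.
#' @param path file path.
#' @return `readTruth` a data.frame; `writeTruth` the path, invisibly.
#' @export
writeTruth <- function(truth, path) {
  utils::write.table(truth[, c("spectrum_id", "peptide")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
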