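# Internal numeric set helpers. All mass sets are plain sorted numeric
# vectors; "membership" is tolerance-aware throughout.

# Index of the nearest element of sorted `table` for each x, with ties
# broken toward the smaller table value. Returns NA where the nearest
# element is farther than `tol`.
.nearestWithin <- function(x, table, tol) {
  n <- length(table)
  if (n == 0L || length(x) == 0L) {
    return(rep(NA_integer_, length(x)))
  }
  lo <- findInterval(x, table)
  lo[lo == 0L] <- 1L
  hi <- pmin(lo + 1L, n)
  dlo <- abs(x - table[lo])
  dhi <- abs(x - table[hi])
  # tie (equal distance) -> smaller mass, i.e. the left candidate
  idx <- ifelse(dhi < dlo, hi, lo)
  d <- pmin(dlo, dhi)
  idx[d > tol] <- NA_integer_
  as.integer(idx)
}

# logical: is each x within tol of some element of `set` (sorted or not)?
.inSet <- function(x, set, tol) {
  if (length(set) == 0L) {
    return(rep(FALSE, length(x)))
  }
  s <- sort(set)
  !is.na(.nearestWithin(x, s, tol))
}

# Deduplicate a numeric vector: sort and keep one representative per run
# of values closer than eps to their predecessor.
.dedup <- function(x, eps = .MERGE_EPS) {
  if (length(x) <= 1L) {
    return(sort(x))
  }
  x <- sort(x)
  keep <- c(TRUE, diff(x) > eps)
  x[keep]
}

# Cluster sorted values whose consecutive gaps are <= eps; representative
# is the weight-weighted mean, returned with summed weights.
.clusterWeighted <- function(x, w, eps) {
  if (length(x) == 0L) {
    return(list(x = numeric(0), w = numeric(0)))
  }
  o <- order(x)
  x <- x[o]
  w <- w[o]
  grp <- cumsum(c(1L, as.integer(diff(x) > eps)))
  sw <- as.vector(rowsum(w, grp))
  sxw <- as.vector(rowsum(x * w, grp))
  # guard all-zero weight clusters: fall back to plain mean
  rep0 <- sw <= 0
  cx <- ifelse(rep0, as.vector(rowsum(x, grp)) / tabulate(grp), sxw / sw)
  # degenerate clusters (all members identical) keep the exact value:
  # the weighted mean would otherwise introduce last-bit rounding noise
  firstIdx <- which(!duplicated(grp))
  lastIdx <- cumsum(tabulate(grp))
  same <- x[firstIdx] == x[lastIdx]
  cx[same] <- x[firstIdx][same]
  list(x = cx, w = sw)
}

.reverseString <- function(s) {
  vapply(strsplit(s, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
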