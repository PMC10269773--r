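# Internal helpers shared across modules. All genomic coordinates inside the
# package are 0-based half-open; I/O converts from 1-based inclusive (GFF,
# printed genome coordinates) or passes BED through unchanged.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Centered moving average with partial windows at the edges
#'
#' The effective span is forced to be odd (`2 * floor(window / 2) + 1`) so the
#' estimator is symmetric around each point and therefore commutes with
#' reversing the input vector. `NA` entries are excluded from the local mean
#' rather than propagated.
#'
#' @param x numeric vector.
#' @param window window size in elements; values `<= 1` return `x` unchanged.
#' @return numeric vector of the same length as `x`.
#' @keywords internal
moving_average <- function(x, window) {
  n <- length(x)
  if (window <= 1 || n == 0) return(x)
  h <- window %/% 2
  ok <- !is.na(x)
  vals <- ifelse(ok, x, 0)
  cs <- cumsum(vals)
  cn <- cumsum(as.numeric(ok))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  tot <- cs[hi] - c(0, cs)[lo]
  cnt <- cn[hi] - c(0, cn)[lo]
  out <- tot / cnt
  out[cnt == 0] <- NA_real_
  out
}

# 0-based positions wrapped onto a replicon of length L (R's %% already
# returns non-negative values for positive L, including negative input).
wrap0 <- function(pos, L) pos %% L

# Extract values of v (length L, 0-based indexing semantics) at possibly
# out-of-range 0-based positions, wrapping for circular replicons. For linear
# replicons out-of-range positions yield NA.
extract_at <- function(v, pos0, circular = TRUE) {
  L <- length(v)
  if (circular) {
    v[wrap0(pos0, L) + 1L]
  } else {
    out <- rep(NA_real_, length(pos0))
    inb <- pos0 >= 0L & pos0 < L
    out[inb] <- v[pos0[inb] + 1L]
    out
  }
}

# 0-based positions of half-open interval [start, end) on a circle of length
# L; end may exceed L (wraps) but the interval must be shorter than L.
interval_pos0 <- function(start, end, L, circular = TRUE) {
  stopifnot(end > start, end - start <= L)
  p <- seq.int(start, end - 1L)
  if (circular) wrap0(p, L) else p[p >= 0 & p < L]
}

# Logical mask vector of length L from a mask tibble restricted to one
# replicon. Intervals are clipped to [0, L).
mask_vector <- function(masks, replicon, L) {
  m <- rep(FALSE, L)
  if (is.null(masks) || nrow(masks) == 0) return(m)
  mk <- masks[masks$replicon == replicon, , drop = FALSE]
  for (i in seq_len(nrow(mk))) {
    s <- max(0L, as.integer(mk$start[i]))
    e <- min(L, as.integer(mk$end[i]))
    if (e > s) m[(s + 1L):e] <- TRUE
  }
  m
}

# Circular rolling sums of x over windows of `window` bp centred at `centers`
# (0-based). Returns one sum per center.
rolling_window_sums <- function(x, centers, window, circular = TRUE) {
  L <- length(x)
  h_lo <- window %/% 2
  h_hi <- window - h_lo - 1L
  if (circular) {
    # pad with one wrap on each side; window assumed < L
    stopifnot(window <= L)
    xp <- c(x, x, x)
    cs <- c(0, cumsum(xp))
    lo <- centers - h_lo + L      # 0-based index into xp
    hi <- centers + h_hi + L
    cs[hi + 2L] - cs[lo + 1L]
  } else {
    cs <- c(0, cumsum(x))
    lo <- pmax(centers - h_lo, 0L)
    hi <- pmin(centers + h_hi, L - 1L)
    cs[hi + 2L] - cs[lo + 1L]
  }
}

is_dna_string <- function(x) {
  length(x) == 1 && is.character(x) && nchar(x) > 0 &&
    !grepl("[^ACGTacgt]", x)
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Deterministic sub-seed derivation, kept below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(offset)) %% 2147483587)
}
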