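# Descriptive read-composition statistics: length distribution, positional
# nucleotide logo, and GC content of guides with their genomic context.

#' Read-length histogram
#'
#' @param reads a `read_set` (or `DNAStringSet`).
#' @return tibble `(length, n, frequency)` with attributes `modal_length`
#'   and `fraction_14_19` (the fraction of reads in the canonical 14-19 nt
#'   guide range).
#' @export
length_histogram <- function(reads) {
  rs <- as_read_set(reads)
  w <- Biostrings::width(rs$reads)
  if (length(w) == 0) {
    out <- tibble::tibble(length = integer(), n = integer(),
                          frequency = numeric())
    attr(out, "modal_length") <- NA_integer_
    attr(out, "fraction_14_19") <- NA_real_
    return(out)
  }
  tb <- table(w)
  out <- tibble::tibble(length = as.integer(names(tb)),
                        n = as.integer(tb),
                        frequency = as.integer(tb) / length(w))
  attr(out, "modal_length") <- out$length[which.max(out$n)]
  attr(out, "fraction_14_19") <- mean(w >= 14 & w <= 19)
  out
}

#' Positional nucleotide frequency matrix (sequence logo input)
#'
#' Built from reads longer than 16 nt; reads longer than 17 nt are truncated
#' to 17 nt from the 3' end, so every contributing read covers positions
#' 1-17 from the guide 5' end.
#'
#' @param reads a `read_set` (or `DNAStringSet`).
#' @return object of class `logo_matrix`: tibble with one row per position
#'   1-17 and columns `A`, `C`, `G`, `T` of per-position base frequencies;
#'   attribute `n_reads` records the number of qualifying reads.
#' @export
logo_matrix <- function(reads) {
  rs <- as_read_set(reads)
  sel <- rs$reads[Biostrings::width(rs$reads) > 16L]
  if (length(sel) == 0) stop("no reads longer than 16 nt")
  sel <- Biostrings::subseq(sel, 1L, 17L)
  cm <- Biostrings::consensusMatrix(sel, baseOnly = TRUE)
  freq <- t(cm[c("A", "C", "G", "T"), , drop = FALSE]) / length(sel)
  out <- tibble::as_tibble(as.data.frame(freq))
  out <- dplyr::mutate(out, position = dplyr::row_number(), .before = 1)
  structure(out, class = c("logo_matrix", class(out)), n_reads = length(sel))
}

#' Write a logo matrix as a plain-text position weight matrix
#'
#' Rows are positions, columns A/C/G/T, tab-separated with a header.
#'
#' @param logo a [logo_matrix()].
#' @param path output file.
#' @export
write_pwm <- function(logo, path) {
  readr::write_tsv(tibble::as_tibble(logo), path)
  invisible(path)
}

#' GC content of guides and their surrounding genomic context
#'
#' For each aligned read, genomic bases are read in guide orientation from
#' `-flank` nt 5' of the guide 5' end to `guide_span + flank - 1` nt 3' of
#' it, and per-offset GC fractions are averaged over reads. GC status is
#' complement-invariant, so minus-strand guides need no sequence flipping,
#' only coordinate reversal. Offset 0 is the guide 5' base; offsets past a
#' short read's 3' end report the downstream genomic context. Within the
#' guide span this equals the GC profile of the read sequences themselves
#' (reads align exactly).
#'
#' @param alignments alignment tibble from [align_exact()].
#' @param bundle the [ref_bundle()] aligned against.
#' @param flank context on each side in nt (default 20).
#' @param guide_span guide offsets reported (default 19, the maximum guide
#'   length).
#' @return tibble `(offset, gc, n, in_guide)` with attribute
#'   `genome_mean_gc`, the chromosome-wide GC fraction.
#' @export
gc_profile <- function(alignments, bundle, flank = 20L, guide_span = 19L) {
  ch <- chromosome_name(bundle)
  aln <- alignments[alignments$replicon == ch, ]
  L <- replicon_length(bundle, ch)
  circ <- replicon_circular(bundle, ch)
  seq_raw <- charToRaw(as.character(bundle$sequences[[match(ch, names(bundle$sequences))]]))
  is_gc <- seq_raw %in% charToRaw("GCgc")
  dir <- ifelse(aln$strand == "-", -1L, 1L)
  offs <- seq.int(-flank, guide_span + flank - 1L)
  gc <- numeric(length(offs))
  n <- integer(length(offs))
  for (j in seq_along(offs)) {
    pos <- aln$position + dir * offs[j]
    if (circ) {
      pos <- wrap0(pos, L)
      v <- is_gc[pos + 1L]
    } else {
      v <- rep(NA, length(pos))
      inb <- pos >= 0L & pos < L
      v[inb] <- is_gc[pos[inb] + 1L]
    }
    gc[j] <- mean(v, na.rm = TRUE)
    n[j] <- sum(!is.na(v))
  }
  out <- tibble::tibble(offset = offs, gc = gc, n = n,
                        in_guide = offs >= 0L & offs < guide_span)
  attr(out, "genome_mean_gc") <- mean(is_gc)
  out
}
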