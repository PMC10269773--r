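# Genome-scale coverage statistics: targeting of the replication-termination
# region, rolling plus/minus strand-ratio profiles for +Cfx vs control
# library pairs, and copy-number-corrected plasmid enrichment.

#' Fraction of the library mapping to each ter window, per strand
#'
#' For each ter site and strand, the number of read 5' ends inside the
#' window divided by the total number of reads mapped to both strands of the
#' chromosome, times 100.
#'
#' @param counts a [strand_counts()].
#' @param ter_sites tibble `(name, replicon, start, end, blocked_strand)`;
#'   windows are 0-based half-open and may extend past the origin of a
#'   circular replicon.
#' @return tibble `(ter, strand, blocked, count, percent)`.
#' @export
ter_fraction <- function(counts, ter_sites) {
  chrom <- counts$replicons$name[1]
  if ("replicon" %in% names(ter_sites) && nrow(ter_sites) > 0) {
    chrom <- ter_sites$replicon[1]
  }
  L <- counts$replicons$length[match(chrom, counts$replicons$name)]
  circ <- counts$replicons$circular[match(chrom, counts$replicons$name)]
  total <- sum(counts$counts[[chrom]]$plus) + sum(counts$counts[[chrom]]$minus)
  if (total == 0) stop("empty library")
  purrr::map_dfr(seq_len(nrow(ter_sites)), function(i) {
    tw <- ter_sites[i, ]
    idx <- interval_pos0(tw$start, tw$end, L, circular = circ) + 1L
    purrr::map_dfr(c("+" = "plus", "-" = "minus"), function(sl) {
      cnt <- sum(counts$counts[[chrom]][[sl]][idx])
      tibble::tibble(ter = tw$name, blocked = sl == c("+" = "plus", "-" = "minus")[[tw$blocked_strand]],
                     count = cnt, percent = 100 * cnt / total)
    }, .id = "strand")
  }) |>
    dplyr::select("ter", "strand", "blocked", "count", "percent")
}

#' Rolling strand-ratio profile, optionally as a +Cfx / control ratio of ratios
#'
#' Computes the plus/minus 5'-end count ratio in rolling windows along the
#' chromosome (pseudocount added to each strand sum) for one library, or,
#' when a control library is supplied, the ratio of the two libraries'
#' strand ratios (+Cfx over control) per window. Windows wrap around
#' circular replicons so the origin and terminus produce no edge artifacts.
#'
#' @param counts_cfx [strand_counts()] of the (+Cfx) library.
#' @param counts_ctrl optional [strand_counts()] of the control library.
#' @param window rolling window in bp (default 50 kb).
#' @param step step between window centers in bp (default 10 kb).
#' @param pseudocount reads added to each strand sum per window (default 1).
#' @param replicon replicon to profile (default the first chromosome).
#' @return tibble with one row per window center: strand sums per library,
#'   per-library ratios and, with a control, the ratio of ratios in `ratio`.
#' @export
strand_ratio_profile <- function(counts_cfx, counts_ctrl = NULL,
                                 window = 50000L, step = 10000L,
                                 pseudocount = 1, replicon = NULL) {
  if (window < step) stop("window must be >= step")
  replicon <- replicon %||% counts_cfx$replicons$name[1]
  L <- counts_cfx$replicons$length[match(replicon, counts_cfx$replicons$name)]
  circ <- counts_cfx$replicons$circular[match(replicon, counts_cfx$replicons$name)]
  centers <- seq.int(0L, L - 1L, by = step)
  sums <- function(counts) {
    list(
      plus = rolling_window_sums(counts$counts[[replicon]]$plus, centers,
                                 window, circular = circ),
      minus = rolling_window_sums(counts$counts[[replicon]]$minus, centers,
                                  window, circular = circ)
    )
  }
  s1 <- sums(counts_cfx)
  out <- tibble::tibble(
    replicon = replicon, center = centers,
    plus_cfx = s1$plus, minus_cfx = s1$minus,
    ratio_cfx = (s1$plus + pseudocount) / (s1$minus + pseudocount)
  )
  if (!is.null(counts_ctrl)) {
    stopifnot(counts_ctrl$replicons$length[
      match(replicon, counts_ctrl$replicons$name)] == L)
    s0 <- sums(counts_ctrl)
    out$plus_ctrl <- s0$plus
    out$minus_ctrl <- s0$minus
    out$ratio_ctrl <- (s0$plus + pseudocount) / (s0$minus + pseudocount)
    out$ratio <- out$ratio_cfx / out$ratio_ctrl
  } else {
    out$ratio <- out$ratio_cfx
  }
  attr(out, "window") <- window
  attr(out, "step") <- step
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Plasmid enrichment corrected for replicon length and copy number
#'
#' `fold = (reads_plasmid / (L_plasmid * copy_number)) /
#'         (reads_chromosome / L_chromosome)`:
#' the per-copy, per-base preference of the Argonaute for plasmid-derived
#' guides over chromosomal ones.
#'
#' @param counts a [strand_counts()].
#' @param bundle the [ref_bundle()] the library was aligned to (must contain
#'   exactly one replicon with role `"plasmid"`).
#' @return one-row tibble `(fold, reads_plasmid, reads_chromosome,
#'   plasmid_length, chromosome_length, copy_number)`.
#' @export
plasmid_enrichment <- function(counts, bundle) {
  pl <- bundle$replicons$name[bundle$replicons$role == "plasmid"]
  if (length(pl) != 1) stop("bundle must contain exactly one plasmid replicon")
  ch <- chromosome_name(bundle)
  reads_p <- sum(counts$counts[[pl]]$plus) + sum(counts$counts[[pl]]$minus)
  reads_c <- sum(counts$counts[[ch]]$plus) + sum(counts$counts[[ch]]$minus)
  if (reads_c == 0) stop("zero chromosome reads")
  Lp <- replicon_length(bundle, pl)
  Lc <- replicon_length(bundle, ch)
  cn <- bundle$replicons$copy_number[match(pl, bundle$replicons$name)]
  tibble::tibble(
    fold = (reads_p / (Lp * cn)) / (reads_c / Lc),
    reads_plasmid = reads_p, reads_chromosome = reads_c,
    plasmid_length = Lp, chromosome_length = Lc, copy_number = cn
  )
}
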