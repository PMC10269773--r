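# Brute-force reference implementations and small fixture builders. These
# are deliberately naive (position-by-position loops) and independent of the
# package's vectorized/dictionary-based code paths.

random_genome <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", sapply(lapply(strsplit(x, ""), rev), paste, collapse = ""))
}

tiny_bundle <- function(seq_chr, topology = "linear", name = "chr",
                        copy_number = 1L, role = "chromosome") {
  s <- Biostrings::DNAStringSet(stats::setNames(seq_chr, name))
  ref_bundle(s, tibble::tibble(name = name, topology = topology,
                               copy_number = as.integer(copy_number),
                               role = role))
}

# O(L * k) scan of motif occurrences on both strands, with optional circular
# wrap, as plain string comparison.
bf_scan <- function(seq_chr, motif, circular = FALSE) {
  L <- nchar(seq_chr)
  k <- nchar(motif)
  s <- if (circular) paste0(seq_chr, substr(seq_chr, 1, k - 1)) else seq_chr
  rc <- revcomp(motif)
  hits <- list()
  for (p in seq_len(L)) {
    win <- substr(s, p, p + k - 1)
    if (nchar(win) < k) next
    if (win == motif) hits[[length(hits) + 1]] <- c(p - 1L, 1L)
    if (win == rc) hits[[length(hits) + 1]] <- c(p - 1L, 2L)
  }
  if (!length(hits)) {
    return(tibble::tibble(position = integer(), strand = character()))
  }
  m <- do.call(rbind, hits)
  out <- tibble::tibble(position = m[, 1], strand = c("+", "-")[m[, 2]])
  dplyr::arrange(out, .data$position, .data$strand)
}

# Enumerate all exact matches of one read on both strands of one replicon.
bf_read_hits <- function(read, seq_chr, circular = FALSE) {
  L <- nchar(seq_chr)
  w <- nchar(read)
  s <- if (circular) paste0(seq_chr, substr(seq_chr, 1, w - 1)) else seq_chr
  rc <- revcomp(read)
  out <- list()
  for (p in seq_len(L)) {
    win <- substr(s, p, p + w - 1)
    if (nchar(win) < w) next
    if (win == read) {
      out[[length(out) + 1]] <- tibble::tibble(start = p - 1L, strand = "+",
                                               position = p - 1L)
    }
    if (win == rc) {
      out[[length(out) + 1]] <- tibble::tibble(start = p - 1L, strand = "-",
                                               position = (p - 1L + w - 1L) %% L)
    }
  }
  dplyr::bind_rows(out)
}

# Loop-based metaplot: mean per-offset 5'-end count over anchors on the
# co-oriented and opposite strands, orientation-flipped, mask-aware, no
# smoothing, in raw counts (not RPKM).
bf_metaplot <- function(plus, minus, anchors, half_width, L, circular = TRUE,
                        mask = rep(FALSE, L)) {
  offs <- -half_width:half_width
  sum_f <- sum_r <- n <- numeric(length(offs))
  for (i in seq_len(nrow(anchors))) {
    w <- if ("width" %in% names(anchors)) anchors$width[i] else 1L
    ref <- if (anchors$strand[i] == "-") anchors$position[i] + w - 1L else anchors$position[i]
    dir <- if (anchors$strand[i] == "-") -1L else 1L
    for (j in seq_along(offs)) {
      p <- ref + dir * offs[j]
      if (circular) p <- ((p %% L) + L) %% L
      if (p < 0 || p >= L || mask[p + 1]) next
      co <- if (anchors$strand[i] == "-") minus else plus
      op <- if (anchors$strand[i] == "-") plus else minus
      sum_f[j] <- sum_f[j] + co[p + 1]
      sum_r[j] <- sum_r[j] + op[p + 1]
      n[j] <- n[j] + 1
    }
  }
  tibble::tibble(offset = offs, F = ifelse(n > 0, sum_f / n, NA_real_),
                 R = ifelse(n > 0, sum_r / n, NA_real_), n = n)
}

# Pairwise-check classifier: a Chi is downstream_gcs iff some GCS lies on
# its 3' side closer than (or tied with) every co-oriented Chi.
bf_classify <- function(chi, gcs, L, circular = TRUE) {
  k <- function(i) {
    w <- if ("width" %in% names(chi)) chi$width[i] else 1L
    if (chi$strand[i] == "-") chi$position[i] + w - 1L else chi$position[i]
  }
  sapply(seq_len(nrow(chi)), function(i) {
    dir <- if (chi$strand[i] == "-") -1 else 1
    dist <- function(x) {
      d <- (x - k(i)) * dir
      if (circular) d <- ((d %% L) + L) %% L
      d[d > 0]
    }
    dg <- dist(gcs$position)
    co_idx <- which(chi$strand == chi$strand[i] & seq_len(nrow(chi)) != i)
    dc <- dist(vapply(co_idx, k, numeric(1)))
    if (length(dg) && (!length(dc) || min(dg) <= min(dc))) "downstream_gcs" else "other"
  })
}

# Build a strand_counts object directly from per-position count vectors.
counts_from_vectors <- function(plus, minus, name = "chr", circular = TRUE,
                                extra = list()) {
  counts <- c(stats::setNames(list(list(plus = plus, minus = minus)), name), extra)
  repl <- tibble::tibble(
    name = names(counts),
    length = vapply(counts, function(x) length(x$plus), integer(1)),
    circular = circular
  )
  tot <- sum(vapply(counts, function(x) sum(as.numeric(x$plus)) +
                      sum(as.numeric(x$minus)), numeric(1)))
  strand_counts(counts, repl, total_aligned = tot, total_input = tot)
}

# Small simulated pair with aligned counts, shared by several test files.
sim_aligned_pair <- function(cfg) {
  pair <- simulate_pair(cfg)
  align1 <- function(smp) {
    tf <- tempfile(fileext = ".fastq")
    smdnaseq:::write_fastq(smp$reads, tf)
    on.exit(unlink(tf))
    align_exact(preprocess_reads(tf, adapter = cfg$adapter), pair$bundle)
  }
  list(pair = pair, ctrl = align1(pair$ctrl), cfx = align1(pair$cfx))
}
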