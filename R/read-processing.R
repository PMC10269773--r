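# Read preprocessing, exact alignment and strand-specific 5'-end counting.
# Density here always means counts of aligned-read 5' ends: guides are
# 14-19 nt and every downstream statistic is strand-polar, so the 5' end is
# the natural single-base attribution point.

#' Trim adapters and length-filter an smDNA FASTQ library
#'
#' For each read the leftmost exact occurrence of the adapter and everything
#' 3' of it is removed; reads shorter than `min_length` after trimming are
#' discarded.
#'
#' @param fastq path to a FASTQ file (Sanger qualities; qualities are not
#'   used).
#' @param adapter adapter sequence (`""` to skip trimming).
#' @param min_length minimum retained read length (default 14 nt, the lower
#'   bound of the Argonaute-bound guide population).
#' @return object of class `read_set`: list with `reads`
#'   ([Biostrings::DNAStringSet]) and a processing `log`.
#' @export
preprocess_reads <- function(fastq, adapter = "", min_length = 14L) {
  lines <- readLines(fastq)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ '", fastq, "': record ", length(lines) %/% 4L + 1L,
         " is truncated", call. = FALSE)
  }
  if (length(lines) > 0) {
    hdr <- seq.int(1L, length(lines), by = 4L)
    bad <- which(substr(lines[hdr], 1L, 1L) != "@" |
                   substr(lines[hdr + 2L], 1L, 1L) != "+")
    if (length(bad)) {
      stop("malformed FASTQ '", fastq, "': record ", bad[1], call. = FALSE)
    }
  }
  if (length(lines) == 0) {
    seq_chr <- character(0); ids <- character(0)
  } else {
    seq_chr <- lines[seq.int(2L, length(lines), by = 4L)]
    ids <- sub("\\s.*$", "",
               substring(lines[seq.int(1L, length(lines), by = 4L)], 2L))
  }
  n_input <- length(seq_chr)
  n_trimmed <- 0L
  if (nzchar(adapter) && n_input > 0) {
    if (!is_dna_string(adapter)) stop("adapter must be a plain A/C/G/T string")
    first <- regexpr(adapter, seq_chr, fixed = TRUE)  # leftmost exact hit
    hit <- first > 0L
    n_trimmed <- sum(hit)
    seq_chr[hit] <- substr(seq_chr[hit], 1L, first[hit] - 1L)
  }
  keep <- nchar(seq_chr) >= min_length
  out <- tryCatch(Biostrings::DNAStringSet(seq_chr[keep]),
                  error = function(e) stop("malformed FASTQ '", fastq, "': ",
                                           conditionMessage(e), call. = FALSE))
  names(out) <- ids[keep]
  structure(
    list(reads = out,
         log = list(n_input = n_input, n_trimmed = n_trimmed,
                    n_discarded = sum(!keep), n_kept = sum(keep),
                    min_length = min_length, adapter = adapter),
         source = fastq),
    class = "read_set"
  )
}

#' @export
print.read_set <- function(x, ...) {
  cat("<read_set> ", length(x$reads), " reads (", x$log$n_input, " input, ",
      x$log$n_trimmed, " adapter-trimmed, ", x$log$n_discarded,
      " discarded < ", x$log$min_length, " nt)\n", sep = "")
  invisible(x)
}

as_read_set <- function(reads) {
  if (inherits(reads, "read_set")) return(reads)
  structure(list(reads = reads,
                 log = list(n_input = length(reads), n_trimmed = 0L,
                            n_discarded = 0L, n_kept = length(reads),
                            min_length = NA_integer_, adapter = ""),
                 source = NA_character_),
            class = "read_set")
}

#' Strand-specific 5'-end count container
#'
#' Per replicon and strand, an integer vector of length `replicon length`
#' counting aligned-read 5' ends at each 0-based position.
#'
#' @param counts named list per replicon of `list(plus =, minus =)` integer
#'   vectors.
#' @param replicons tibble `(name, length, circular)`.
#' @param total_aligned,total_input library totals.
#' @return object of class `strand_counts`.
#' @export
strand_counts <- function(counts, replicons, total_aligned, total_input) {
  stopifnot(setequal(names(counts), replicons$name))
  s <- sum(purrr::map_dbl(counts, ~ sum(as.numeric(.x$plus)) +
                            sum(as.numeric(.x$minus))))
  stopifnot(s == total_aligned, total_aligned <= total_input)
  structure(list(counts = counts, replicons = tibble::as_tibble(replicons),
                 total_aligned = total_aligned, total_input = total_input),
            class = "strand_counts")
}

#' @export
print.strand_counts <- function(x, ...) {
  cat("<strand_counts> ", x$total_aligned, "/", x$total_input,
      " reads aligned over ", nrow(x$replicons), " replicon(s)\n", sep = "")
  invisible(x)
}

#' @rdname strand_counts
#' @param x a `strand_counts` object.
#' @param ... unused.
#' @return `tidy()`: tibble `(replicon, position, strand, count)` of nonzero
#'   positions.
#' @export
tidy.strand_counts <- function(x, ...) {
  purrr::map_dfr(x$replicons$name, function(r) {
    purrr::map_dfr(c("+" = "plus", "-" = "minus"), function(sl) {
      v <- x$counts[[r]][[sl]]
      nz <- which(v > 0L)
      tibble::tibble(replicon = r, position = nz - 1L, count = v[nz])
    }, .id = "strand")
  }) |>
    dplyr::select("replicon", "position", "strand", "count") |>
    dplyr::arrange(.data$replicon, .data$position, .data$strand)
}

#' Align reads to the replicon set with no mismatches
#'
#' Every read is matched exactly against both strands of every replicon
#' (circular origin junctions included) with a Biostrings `PDict` dictionary
#' per read length. The read's 5'-end position (plus strand: match start;
#' minus strand: plus-strand coordinate of the read's 5' base, i.e. match
#' end - 1) increments the strand-specific counts. Reads matching more than
#' one location are resolved by `multimappers`: `"first"` keeps the
#' lexicographically smallest `(replicon, position, strand)` hit
#' (deterministic; repeats are mostly absorbed by downstream masks),
#' `"discard"` drops them (and is exactly equivariant under
#' reverse-complementing the reference). Reads containing non-ACGT letters
#' are unalignable.
#'
#' @param reads a `read_set` (or `DNAStringSet`).
#' @param bundle a [ref_bundle()].
#' @param multimappers `"first"` or `"discard"`.
#' @return list with `counts` (a [strand_counts()]), `alignments` (tibble
#'   `(read_id, replicon, position, strand, length, n_hits)` of assigned
#'   reads; `position` is the 5'-end coordinate) and `log`.
#' @export
align_exact <- function(reads, bundle, multimappers = c("first", "discard")) {
  multimappers <- match.arg(multimappers)
  rs <- as_read_set(reads)
  dss <- rs$reads
  n_input <- length(dss)
  if (is.null(names(dss)) || anyDuplicated(names(dss))) {
    names(dss) <- sprintf("read_%07d", seq_along(dss))
  }
  bf <- Biostrings::alphabetFrequency(dss, baseOnly = TRUE)
  clean <- bf[, "other"] == 0L
  widths <- Biostrings::width(dss)
  rep_names <- bundle$replicons$name
  acc <- list(read = list(), repl = list(), start = list(), pos = list(),
              strand = list())
  for (w in sort(unique(widths[clean & widths > 0]))) {
    idx <- which(clean & widths == w)
    sub <- dss[idx]
    pd_f <- Biostrings::PDict(sub)
    pd_r <- Biostrings::PDict(Biostrings::reverseComplement(sub))
    for (i in seq_len(nrow(bundle$replicons))) {
      L <- bundle$replicons$length[i]
      circ <- bundle$replicons$topology[i] == "circular" && L > w
      subj <- bundle$sequences[[i]]
      if (circ) subj <- Biostrings::xscat(subj, Biostrings::subseq(subj, 1L, w - 1L))
      for (str in 1:2) {
        m <- Biostrings::matchPDict(if (str == 1L) pd_f else pd_r, subj)
        st <- Biostrings::startIndex(m)
        nh <- lengths(st)
        if (sum(nh) == 0) next
        starts <- unlist(st, use.names = FALSE) - 1L
        rid <- rep(idx, nh)
        keep <- starts < L  # appended junction never duplicates a start
        starts <- starts[keep]
        k <- length(acc$read) + 1L
        acc$read[[k]] <- rid[keep]
        acc$repl[[k]] <- rep.int(i, length(starts))
        acc$start[[k]] <- starts
        acc$pos[[k]] <- if (str == 1L) starts else wrap0(starts + w - 1L, L)
        acc$strand[[k]] <- rep.int(str, length(starts))
      }
    }
  }
  read <- unlist(acc$read); repl_i <- unlist(acc$repl)
  start <- unlist(acc$start); pos <- unlist(acc$pos)
  strand_i <- unlist(acc$strand)
  if (length(read) > 0) {
    n_hits_all <- tabulate(read, nbins = length(dss))
    # lexicographically smallest (replicon, match start, strand) per read
    o <- order(read, repl_i, start, strand_i)
    first <- o[!duplicated(read[o])]
    if (multimappers == "discard") first <- first[n_hits_all[read[first]] == 1L]
    rsel <- read[first]
    hits <- tibble::tibble(read = rsel,
                           replicon = rep_names[repl_i[first]],
                           start = start[first], position = pos[first],
                           strand = c("+", "-")[strand_i[first]],
                           length = widths[rsel],
                           n_hits = n_hits_all[rsel])
  } else {
    hits <- tibble::tibble(read = integer(), replicon = character(),
                           start = integer(), position = integer(),
                           strand = character(), length = integer(),
                           n_hits = integer())
  }
  counts <- purrr::map(seq_len(nrow(bundle$replicons)), function(i) {
    L <- bundle$replicons$length[i]
    nm <- bundle$replicons$name[i]
    h <- hits[hits$replicon == nm, ]
    list(
      plus = tabulate(h$position[h$strand == "+"] + 1L, nbins = L),
      minus = tabulate(h$position[h$strand == "-"] + 1L, nbins = L)
    )
  })
  names(counts) <- bundle$replicons$name
  sc <- strand_counts(
    counts,
    tibble::tibble(name = bundle$replicons$name,
                   length = bundle$replicons$length,
                   circular = bundle$replicons$topology == "circular"),
    total_aligned = nrow(hits), total_input = n_input
  )
  alignments <- tibble::tibble(read_id = names(dss)[hits$read],
                               replicon = hits$replicon,
                               position = hits$position, strand = hits$strand,
                               length = hits$length, n_hits = hits$n_hits)
  list(counts = sc, alignments = alignments,
       log = list(n_input = n_input, n_aligned = nrow(hits),
                  n_unaligned = n_input - nrow(hits),
                  multimappers = multimappers))
}

#' Windowed strand-specific coverage in RPKM
#'
#' Sums 5'-end counts in fixed windows per replicon and strand and converts
#' to RPKM (reads per kilobase per million aligned reads):
#' `count * 1e9 / (window_length * total_aligned)`. The final partial window
#' is normalized by its true length.
#'
#' @param counts a [strand_counts()].
#' @param window_size window in bp (default 1000).
#' @return tibble `(replicon, strand, start, end, count, rpkm)`.
#' @export
rpkm_windows <- function(counts, window_size = 1000L) {
  if (counts$total_aligned == 0) stop("empty library")
  purrr::map_dfr(counts$replicons$name, function(r) {
    L <- counts$replicons$length[match(r, counts$replicons$name)]
    starts <- seq.int(0L, L - 1L, by = window_size)
    ends <- pmin(starts + window_size, L)
    purrr::map_dfr(c("+" = "plus", "-" = "minus"), function(sl) {
      v <- counts$counts[[r]][[sl]]
      win <- findInterval(seq_len(L) - 1L, starts)
      cnt <- as.numeric(tapply(v, win, sum))
      tibble::tibble(replicon = r, start = starts, end = ends, count = cnt,
                     rpkm = cnt * 1e9 / ((ends - starts) * counts$total_aligned))
    }, .id = "strand")
  }) |>
    dplyr::select("replicon", "strand", "start", "end", "count", "rpkm")
}

#' Export strand counts as paired bedGraph tracks
#'
#' One bedGraph file per strand with runs of equal counts merged; zero runs
#' are omitted. [read_strand_counts()] restores the object losslessly.
#'
#' @param counts a [strand_counts()].
#' @param prefix output path prefix; writes `<prefix>.plus.bedgraph` and
#'   `<prefix>.minus.bedgraph` plus `<prefix>.totals.json`.
#' @return invisibly, the written paths.
#' @export
write_strand_counts <- function(counts, prefix) {
  paths <- c(plus = paste0(prefix, ".plus.bedgraph"),
             minus = paste0(prefix, ".minus.bedgraph"))
  for (sl in c("plus", "minus")) {
    rows <- purrr::map_dfr(counts$replicons$name, function(r) {
      v <- counts$counts[[r]][[sl]]
      rl <- rle(v)
      e <- cumsum(rl$lengths)
      s <- e - rl$lengths
      keep <- rl$values > 0
      tibble::tibble(chrom = r, start = s[keep], end = e[keep],
                     value = rl$values[keep])
    })
    readr::write_tsv(rows, paths[[sl]], col_names = FALSE)
  }
  meta <- list(total_aligned = counts$total_aligned,
               total_input = counts$total_input,
               replicons = counts$replicons)
  jsonlite::write_json(meta, paste0(prefix, ".totals.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(paths, totals = paste0(prefix, ".totals.json")))
}

#' Restore strand counts written by [write_strand_counts()]
#'
#' @param prefix the prefix given to [write_strand_counts()].
#' @return a [strand_counts()].
#' @export
read_strand_counts <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".totals.json"),
                              simplifyVector = TRUE)
  replicons <- tibble::as_tibble(meta$replicons)
  counts <- purrr::map(seq_len(nrow(replicons)), function(i) {
    L <- replicons$length[i]
    out <- list(plus = integer(L), minus = integer(L))
    for (sl in c("plus", "minus")) {
      p <- paste0(prefix, ".", sl, ".bedgraph")
      df <- tryCatch(
        utils::read.table(p, sep = "\t", col.names = c("chrom", "start", "end", "value")),
        error = function(e) NULL)
      if (is.null(df)) next
      df <- df[df$chrom == replicons$name[i], , drop = FALSE]
      for (j in seq_len(nrow(df))) {
        out[[sl]][(df$start[j] + 1L):df$end[j]] <- df$value[j]
      }
    }
    out
  })
  names(counts) <- replicons$name
  strand_counts(counts, replicons, meta$total_aligned, meta$total_input)
}

#' Write assigned alignments as BED6
#'
#' One record per assigned read covering the full match
#' (0-based half-open), name = read id, score = 0.
#'
#' @param alignments alignment tibble from [align_exact()].
#' @param path output BED file.
#' @export
write_alignments_bed <- function(alignments, path) {
  start <- ifelse(alignments$strand == "+", alignments$position,
                  alignments$position - alignments$length + 1L)
  bed <- tibble::tibble(chrom = alignments$replicon, start = start,
                        end = start + alignments$length,
                        name = alignments$read_id, score = 0L,
                        strand = alignments$strand)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Write oriented sites as BED6
#'
#' The optional `class` column (e.g. from [classify_chi_gcs()]) goes into
#' the BED name field.
#'
#' @param sites site tibble `(replicon, position, strand, width[, class])`.
#' @param path output BED file.
#' @export
write_sites_bed <- function(sites, path) {
  w <- sites$width %||% rep(1L, nrow(sites))
  bed <- tibble::tibble(chrom = sites$replicon, start = sites$position,
                        end = sites$position + w,
                        name = sites$class %||% rep(".", nrow(sites)),
                        score = 0L,
                        strand = ifelse(sites$strand == "*", ".", sites$strand))
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Reverse-complement strand counts (symmetry-check utility)
#'
#' Maps the plus-strand count at position `p` to the minus strand at
#' `L - 1 - p` and vice versa, matching what aligning the same library to
#' the reverse-complemented reference produces.
#'
#' @param counts a [strand_counts()].
#' @return flipped `strand_counts`.
#' @export
flip_strand_counts <- function(counts) {
  out <- counts
  for (r in counts$replicons$name) {
    out$counts[[r]] <- list(plus = rev(counts$counts[[r]]$minus),
                            minus = rev(counts$counts[[r]]$plus))
  }
  out
}
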