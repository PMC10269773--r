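#' Assemble a reference bundle from sequences, annotation and site sets
#'
#' A reference bundle collects everything downstream statistics need: the
#' replicon sequences, per-replicon topology and copy number, gene
#' annotation, masked regions, replication-termination (ter) windows, Chi
#' sites, gyrase cleavage sites (GCSs) and the replication origin/terminus
#' coordinates. All coordinates are 0-based half-open.
#'
#' @param sequences named [Biostrings::DNAStringSet] of replicon sequences.
#' @param replicons tibble with columns `name`, `topology`
#'   (`"circular"`/`"linear"`), `copy_number`, `role`
#'   (`"chromosome"`/`"plasmid"`); defaults to circular chromosomes of copy
#'   number 1 when `NULL`.
#' @param genes optional tibble `(id, replicon, start, end, strand)`.
#' @param masks optional tibble `(replicon, start, end)` of excluded regions.
#' @param ter_sites optional tibble `(name, replicon, start, end,
#'   blocked_strand)`; `blocked_strand` is the strand whose 3' end points
#'   toward the site.
#' @param chi,gcs optional oriented-site tibbles
#'   `(replicon, position, strand, width)`.
#' @param ori,ter_midpoint replication origin / terminus midpoint on the
#'   chromosome (0-based).
#' @return object of class `ref_bundle`.
#' @export
ref_bundle <- function(sequences, replicons = NULL, genes = NULL,
                       masks = NULL, ter_sites = NULL, chi = NULL,
                       gcs = NULL, ori = NULL, ter_midpoint = NULL) {
  stopifnot(methods::is(sequences, "DNAStringSet"))
  if (length(sequences) == 0) stop("empty reference")
  nm <- names(sequences)
  if (is.null(nm) || anyNA(nm) || any(nm == "")) stop("unnamed reference records")
  if (anyDuplicated(nm)) stop("duplicate record names in reference")
  if (any(Biostrings::width(sequences) == 0)) stop("zero-length reference record")
  if (is.null(replicons)) {
    replicons <- tibble::tibble(
      name = nm, topology = "circular", copy_number = 1L,
      role = c("chromosome", rep("plasmid", length(nm) - 1L))
    )
  }
  replicons <- tibble::as_tibble(replicons)
  stopifnot(all(c("name", "topology", "copy_number", "role") %in% names(replicons)))
  if (!setequal(replicons$name, nm)) stop("replicon table does not match sequence names")
  replicons <- replicons[match(nm, replicons$name), ]
  replicons$length <- Biostrings::width(sequences)
  stopifnot(all(replicons$copy_number >= 1))
  if (!is.null(genes)) {
    genes <- tibble::as_tibble(genes)
    if (!all(genes$replicon %in% nm)) {
      stop("annotation refers to unknown replicon: ",
           paste(unique(setdiff(genes$replicon, nm)), collapse = ", "))
    }
    stopifnot(all(genes$start < genes$end), !anyDuplicated(genes$id))
  }
  structure(
    list(sequences = sequences, replicons = replicons, genes = genes,
         masks = if (is.null(masks)) empty_masks() else normalize_masks(masks),
         ter_sites = ter_sites, chi = chi, gcs = gcs,
         ori = ori, ter_midpoint = ter_midpoint),
    class = "ref_bundle"
  )
}

#' @export
print.ref_bundle <- function(x, ...) {
  cat("<ref_bundle> ", nrow(x$replicons), " replicon(s)\n", sep = "")
  print(x$replicons[, c("name", "length", "topology", "copy_number", "role")])
  cat("genes: ", if (is.null(x$genes)) 0L else nrow(x$genes),
      " | masks: ", nrow(x$masks),
      " | ter: ", if (is.null(x$ter_sites)) 0L else nrow(x$ter_sites),
      " | chi: ", if (is.null(x$chi)) 0L else nrow(x$chi),
      " | gcs: ", if (is.null(x$gcs)) 0L else nrow(x$gcs), "\n", sep = "")
  invisible(x)
}

replicon_length <- function(bundle, name) {
  bundle$replicons$length[match(name, bundle$replicons$name)]
}

replicon_circular <- function(bundle, name) {
  bundle$replicons$topology[match(name, bundle$replicons$name)] == "circular"
}

chromosome_name <- function(bundle) {
  nm <- bundle$replicons$name[bundle$replicons$role == "chromosome"]
  if (length(nm) != 1) stop("bundle must contain exactly one chromosome")
  nm
}

#' Read a reference replicon set from FASTA (plus optional GFF annotation)
#'
#' One replicon per FASTA record. Topology, copy number, role and the
#' ori/terminus coordinates come from `config`, a list (typically parsed from
#' YAML) of the form
#' `list(replicons = list(<name> = list(topology=, copy_number=, role=)),
#'  ori =, ter_midpoint =)`. Records absent from the config default to a
#' circular chromosome (first record) or plasmid (rest) of copy number 1.
#'
#' @param fasta_path path to the reference FASTA.
#' @param annotation_path optional GFF3 file of gene models (requires the
#'   `rtracklayer` package).
#' @param config list as described above; may be a path to a YAML file.
#' @return a [ref_bundle()].
#' @export
read_reference <- function(fasta_path, annotation_path = NULL, config = list()) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0) stop("empty reference")
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  nm <- names(seqs)
  cfg_rep <- config$replicons %||% list()
  replicons <- tibble::tibble(
    name = nm,
    topology = purrr::map_chr(nm, ~ cfg_rep[[.x]]$topology %||% "circular"),
    copy_number = purrr::map_int(nm, ~ as.integer(cfg_rep[[.x]]$copy_number %||% 1L)),
    role = purrr::map_chr(
      seq_along(nm),
      ~ cfg_rep[[nm[.x]]]$role %||% if (.x == 1) "chromosome" else "plasmid"
    )
  )
  genes <- if (!is.null(annotation_path)) read_gff_genes(annotation_path) else NULL
  ref_bundle(seqs, replicons, genes = genes,
             ori = config$ori, ter_midpoint = config$ter_midpoint)
}

#' Read gene models from a GFF3 file
#'
#' Uses `rtracklayer` for parsing; keeps `gene` features when present,
#' otherwise all features. GFF 1-based inclusive coordinates are converted to
#' the package's 0-based half-open convention.
#'
#' @param path GFF3 file.
#' @return tibble `(id, replicon, start, end, strand)`.
#' @export
read_gff_genes <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF annotation requires the 'rtracklayer' package")
  }
  df <- as.data.frame(rtracklayer::import(path))
  if ("type" %in% names(df) && any(df$type == "gene")) {
    df <- df[df$type == "gene", , drop = FALSE]
  }
  ids <- df$ID %||% df$gene_id %||% df$Name
  if (is.null(ids)) ids <- paste0("gene_", seq_len(nrow(df)))
  tibble::tibble(
    id = as.character(ids),
    replicon = as.character(df$seqnames),
    start = df$start - 1L,
    end = df$end,
    strand = as.character(df$strand)
  )
}

empty_masks <- function() {
  tibble::tibble(replicon = character(), start = integer(), end = integer())
}

#' Normalize a mask interval set
#'
#' Sorts, clips degenerate intervals and merges overlapping/adjacent ones per
#' replicon. Idempotent.
#'
#' @param masks tibble `(replicon, start, end)`, 0-based half-open.
#' @return normalized tibble of the same shape.
#' @export
normalize_masks <- function(masks) {
  masks <- tibble::as_tibble(masks)
  if (nrow(masks) == 0) return(empty_masks())
  stopifnot(all(masks$end > masks$start))
  masks |>
    dplyr::group_by(.data$replicon) |>
    dplyr::group_modify(function(df, key) {
      ir <- IRanges::reduce(IRanges::IRanges(start = df$start + 1L, end = df$end))
      tibble::tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$replicon, .data$start)
}

#' Read BED intervals (masks, ter windows) as a tidy interval table
#'
#' BED is 0-based half-open, matching the internal convention, so coordinates
#' pass through unchanged.
#'
#' @param path BED file (>= 3 columns; column 4, when present, becomes `name`).
#' @return tibble `(replicon, start, end[, name])`.
#' @export
read_bed_intervals <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  out <- tibble::tibble(replicon = as.character(df[[1]]),
                        start = as.integer(df[[2]]), end = as.integer(df[[3]]))
  if (ncol(df) >= 4) out$name <- as.character(df[[4]])
  if (ncol(df) >= 6) out$strand <- as.character(df[[6]])
  out
}

#' Read oriented point sites (e.g. GCS coordinates) from BED
#'
#' @param path BED file; the interval start is taken as the site position and
#'   column 6, when present, as the strand (`"*"` otherwise).
#' @return tibble `(replicon, position, strand, width)`.
#' @export
read_sites_bed <- function(path) {
  iv <- read_bed_intervals(path)
  tibble::tibble(replicon = iv$replicon, position = iv$start,
                 strand = iv$strand %||% rep("*", nrow(iv)),
                 width = pmax(1L, iv$end - iv$start))
}

#' Scan replicons for a DNA motif on both strands
#'
#' Finds every occurrence of `motif` on the plus strand and of its reverse
#' complement (reported as strand `-`). The reported `position` is always the
#' 0-based start of the matched window on the plus strand, regardless of
#' strand. Circular replicons are scanned across the origin junction. A site
#' is dropped when any base of its window overlaps a mask interval.
#'
#' @param bundle a [ref_bundle()], or a single DNA string for convenience.
#' @param motif DNA motif (`A/C/G/T` only, length >= 4). Defaults to the
#'   E. coli Chi octamer `GCTGGTGG` recognized by RecBCD.
#' @param masks optional mask tibble `(replicon, start, end)`; defaults to no
#'   masking (pass `bundle$masks` to apply the bundle's masks).
#' @return tibble `(replicon, position, strand, width)` sorted by
#'   `(replicon, position)`.
#' @examples
#' scan_motif("TTGCTGGTGGAA", "GCTGGTGG")
#' @export
scan_motif <- function(bundle, motif = "GCTGGTGG", masks = NULL) {
  if (is.character(bundle)) {
    bundle <- ref_bundle(Biostrings::DNAStringSet(c(seq = bundle)),
                         tibble::tibble(name = "seq", topology = "linear",
                                        copy_number = 1L, role = "chromosome"))
  }
  if (!is_dna_string(motif)) stop("motif must be a plain A/C/G/T string")
  k <- nchar(motif)
  if (k < 4) stop("motif length must be >= 4")
  if (!is.null(masks)) masks <- normalize_masks(masks)
  fwd <- Biostrings::DNAString(motif)
  rev <- Biostrings::reverseComplement(fwd)
  res <- purrr::map_dfr(seq_len(nrow(bundle$replicons)), function(i) {
    nm <- bundle$replicons$name[i]
    L <- bundle$replicons$length[i]
    circ <- bundle$replicons$topology[i] == "circular" && L > k
    subj <- bundle$sequences[[i]]
    if (circ) subj <- Biostrings::xscat(subj, Biostrings::subseq(subj, 1L, k - 1L))
    hit1 <- function(pat, strand) {
      st <- BiocGenerics::start(Biostrings::matchPattern(pat, subj, fixed = TRUE)) - 1L
      st <- st[st < L]  # junction window starts < L; no modular duplicates
      tibble::tibble(replicon = nm, position = st, strand = strand, width = k)
    }
    out <- dplyr::bind_rows(hit1(fwd, "+"), hit1(rev, "-"))
    if (!is.null(masks) && nrow(out) > 0) {
      mv <- mask_vector(masks, nm, L)
      keep <- purrr::map_lgl(out$position, function(p) {
        idx <- if (circ) wrap0(p + 0:(k - 1L), L) else (p + 0:(k - 1L))
        idx <- idx[idx < L]
        !any(mv[idx + 1L])
      })
      out <- out[keep, ]
    }
    out
  })
  dplyr::arrange(res, .data$replicon, .data$position, .data$strand)
}

# Anchor reference base: the plus-strand coordinate of the motif's 5'-most
# base in its own orientation. The single convention that makes downstream
# orientation flipping exact.
anchor_ref <- function(sites) {
  w <- sites$width %||% rep(1L, nrow(sites))
  ifelse(sites$strand == "-", sites$position + w - 1L, sites$position)
}

#' Assign genes to replichores and replication co-orientation
#'
#' The rightward replichore is the ori -> ter arc traversed in increasing
#' coordinates (the direction the plus-strand fork travels); the leftward
#' replichore is the complementary arc. A gene is `codirected` when its coding
#' strand matches the direction of fork movement through it, `opposite`
#' otherwise. Midpoints landing exactly on `ori` or `ter_midpoint` go to the
#' rightward replichore.
#'
#' @param genes gene tibble `(id, replicon, start, end, strand)`.
#' @param ori,ter_midpoint chromosome coordinates (0-based).
#' @param chromosome_length replicon length in bp (circular).
#' @return `genes` with added `replichore` and `orientation` columns.
#' @export
assign_replichore <- function(genes, ori, ter_midpoint, chromosome_length) {
  L <- chromosome_length
  mid <- (genes$start + genes$end) %/% 2L
  arc <- wrap0(ter_midpoint - ori, L)
  d <- wrap0(mid - ori, L)
  rightward <- d < arc | mid == wrap0(ori, L) | mid == wrap0(ter_midpoint, L)
  genes |>
    dplyr::mutate(
      replichore = ifelse(rightward, "rightward", "leftward"),
      orientation = ifelse((rightward & .data$strand == "+") |
                             (!rightward & .data$strand == "-"),
                           "codirected", "opposite")
    )
}

#' Classify short intergenic intervals by flanking gene orientation
#'
#' For each pair of adjacent genes separated by a gap shorter than `max_gap`,
#' emits the gap extended by `flank` nt into each flanking gene, labelled by
#' the orientation of the surrounding genes: `divergent` (<- ->), `convergent`
#' (-> <-), `co_forward` (-> ->) or `co_reverse` (<- <-). Overlapping adjacent
#' genes are skipped (with a message).
#'
#' @param genes gene tibble `(id, replicon, start, end, strand)`.
#' @param max_gap gaps of this length or more are not emitted (default 500 nt).
#' @param flank extension into each flanking gene (default 100 nt).
#' @return tibble `(replicon, start, end, class, gap, left_gene, right_gene)`.
#' @export
classify_intergenic <- function(genes, max_gap = 500L, flank = 100L) {
  genes <- dplyr::arrange(tibble::as_tibble(genes), .data$replicon, .data$start)
  by_rep <- split(genes, genes$replicon)
  purrr::map_dfr(by_rep, function(g) {
    if (nrow(g) < 2) return(NULL)
    if (any(g$end[-nrow(g)] >= g$end[-1])) stop("gene containment in annotation")
    l <- g[-nrow(g), ]
    r <- g[-1, ]
    gap <- r$start - l$end
    ok <- gap >= 0 & gap < max_gap
    if (any(!ok & gap < 0)) {
      message(sum(gap < 0), " overlapping adjacent gene pair(s) skipped")
    }
    cls <- dplyr::case_when(
      l$strand == "+" & r$strand == "+" ~ "co_forward",
      l$strand == "-" & r$strand == "-" ~ "co_reverse",
      l$strand == "+" & r$strand == "-" ~ "convergent",
      TRUE ~ "divergent"
    )
    tibble::tibble(replicon = l$replicon, start = l$end - flank,
                   end = r$start + flank, class = cls, gap = gap,
                   left_gene = l$id, right_gene = r$id)[ok, ]
  })
}

#' Reverse-complement a reference bundle (symmetry-check utility)
#'
#' Maps every sequence to its reverse complement and remaps all recorded
#' sites, masks and windows accordingly: an interval `[s, e)` becomes
#' `[L - e, L - s)`, an oriented site at `position` with width `w` moves to
#' `L - position - w` with flipped strand, and `blocked_strand` labels flip.
#' Every statistic in the package is invariant (or maps by a documented rule)
#' under this transformation; the acceptance suite exercises that.
#'
#' @param bundle a [ref_bundle()].
#' @return the flipped bundle.
#' @export
flip_reference <- function(bundle) {
  Ls <- stats::setNames(bundle$replicons$length, bundle$replicons$name)
  flip_iv <- function(df) {
    if (is.null(df) || nrow(df) == 0) return(df)
    L <- Ls[df$replicon]
    new <- df
    new$start <- as.integer(L - df$end)
    new$end <- as.integer(L - df$start)
    new
  }
  out <- bundle
  out$sequences <- Biostrings::reverseComplement(bundle$sequences)
  names(out$sequences) <- names(bundle$sequences)
  out$masks <- flip_iv(bundle$masks)
  if (!is.null(bundle$ter_sites)) {
    out$ter_sites <- flip_iv(bundle$ter_sites)
    out$ter_sites$blocked_strand <- flip_strand(bundle$ter_sites$blocked_strand)
  }
  out$chi <- flip_sites(bundle$chi, Ls)
  out$gcs <- flip_sites(bundle$gcs, Ls)
  if (!is.null(bundle$genes)) {
    g <- flip_iv(bundle$genes)
    g$strand <- flip_strand(bundle$genes$strand)
    out$genes <- g
  }
  if (!is.null(bundle$ori)) out$ori <- wrap0(Ls[[1]] - bundle$ori, Ls[[1]])
  if (!is.null(bundle$ter_midpoint)) {
    out$ter_midpoint <- wrap0(Ls[[1]] - bundle$ter_midpoint, Ls[[1]])
  }
  out
}

flip_strand <- function(s) {
  dplyr::case_when(s == "+" ~ "-", s == "-" ~ "+", TRUE ~ s)
}

#' Remap oriented sites onto the reverse-complemented genome
#'
#' @param sites site tibble `(replicon, position, strand, width)` or `NULL`.
#' @param lengths named vector of replicon lengths.
#' @return remapped site tibble.
#' @export
flip_sites <- function(sites, lengths) {
  if (is.null(sites) || nrow(sites) == 0) return(sites)
  w <- sites$width %||% rep(1L, nrow(sites))
  out <- sites
  out$position <- as.integer(lengths[sites$replicon] - sites$position - w)
  out$strand <- flip_strand(sites$strand)
  dplyr::arrange(out, .data$replicon, .data$position, .data$strand)
}
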