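# Synthetic smDNA library generator. The generator embodies the biogenesis
# model the analysis assumes: RecBCD resects double-strand ends until a
# properly oriented Chi octamer, so smDNA density (i) peaks between each ter
# site and the nearest co-oriented Chi with a 3'-strand bias, (ii) drops
# abruptly on the 5' side of co-oriented Chi sites genome-wide, and (iii) is
# boosted between gyrase cleavage sites and their upstream co-oriented Chi
# when gyrase is poisoned with ciprofloxacin (+Cfx libraries only).

#' Configuration of the synthetic smDNA library generator
#'
#' Defaults are the study conditions used throughout the package's recovery
#' tests: a 1-Mb circular chromosome at 51% GC (the E. coli genome average)
#' with 40 planted Chi octamers, two ter traps arranged like terA/terC around
#' a terminus at 0.5 Mb with the origin at 0, 20 gyrase cleavage sites, a
#' 5-kb plasmid at copy number 12, and 5e5 reads per library.
#'
#' @param seed integer seed; all randomness (genome, site placement, read
#'   sampling) derives from it, so identical configs give byte-identical
#'   FASTQ output.
#' @param n_reads reads per library.
#' @param genome_length,gc_fraction chromosome length (bp) and GC content.
#' @param chi_count number of planted Chi sites (includes the two
#'   ter-adjacent ones).
#' @param ter tibble `(name, position, blocked_strand)`; `blocked_strand` is
#'   the strand whose 3' end points toward the trap.
#' @param ter_chi_distance range (bp) at which a co-oriented Chi is planted
#'   next to each ter site, bounding the ter peak.
#' @param gcs_count number of gyrase cleavage sites (uniformly placed).
#' @param background_rate base intensity per position and strand
#'   (arbitrary units; only ratios matter).
#' @param ter_peak_height multiplicative peak height `h >= 1` on the ter
#'   intervals.
#' @param strand_asymmetry factor `a >= 1`: the 3'-terminated (blocked)
#'   strand gets `h`, the complementary strand `h / a`. The 2-3x bias of
#'   RecBCD processing at ter sites.
#' @param chi_drop proportion `delta` in `[0, 1)` removed at a co-oriented
#'   Chi, recovering linearly to background over `chi_drop_extent` bp on the
#'   5' side.
#' @param chi_drop_extent ramp width `w` (bp).
#' @param gcs_enrichment factor `gamma >= 1` applied (in +Cfx libraries only)
#'   between each GCS and its closest upstream co-oriented Chi on that
#'   Chi's strand.
#' @param plasmid_length,plasmid_copy_number plasmid size and copy number.
#' @param plasmid_preference extra per-copy loading preference of the
#'   Argonaute for plasmid-derived guides (the quantity
#'   [plasmid_enrichment()] recovers); default 12, the order observed for
#'   cyanobacterial Argonautes expressed in E. coli.
#' @param length_probs named numeric vector of read-length probabilities on
#'   14:19 nt.
#' @param adapter 3' sequencing adapter appended to every simulated read
#'   (empty string for none).
#' @param ori,ter_midpoint origin and terminus-midpoint coordinates.
#' @return object of class `generative_config` (a validated list).
#' @export
generative_config <- function(seed = 1L,
                              n_reads = 5e5,
                              genome_length = 1e6,
                              gc_fraction = 0.51,
                              chi_count = 40L,
                              ter = NULL,
                              ter_chi_distance = c(15000L, 25000L),
                              gcs_count = 20L,
                              background_rate = 1,
                              ter_peak_height = 10,
                              strand_asymmetry = 3,
                              chi_drop = 0.25,
                              chi_drop_extent = 5000L,
                              gcs_enrichment = 2,
                              plasmid_length = 5000L,
                              plasmid_copy_number = 12L,
                              plasmid_preference = 12,
                              length_probs = c(`14` = 0.08, `15` = 0.18,
                                               `16` = 0.24, `17` = 0.22,
                                               `18` = 0.18, `19` = 0.10),
                              adapter = "AGATCGGAAGAGC",
                              ori = 0L,
                              ter_midpoint = NULL) {
  L <- as.integer(genome_length)
  if (is.null(ter)) {
    ter <- tibble::tibble(name = c("terA", "terC"),
                          position = as.integer(c(0.42, 0.58) * L),
                          blocked_strand = c("-", "+"))
  }
  if (is.null(ter_midpoint)) ter_midpoint <- as.integer(round(mean(ter$position)))
  cfg <- list(seed = as.integer(seed), n_reads = as.integer(n_reads),
              genome_length = L, gc_fraction = gc_fraction,
              chi_count = as.integer(chi_count), ter = tibble::as_tibble(ter),
              ter_chi_distance = as.integer(ter_chi_distance),
              gcs_count = as.integer(gcs_count),
              background_rate = background_rate,
              ter_peak_height = ter_peak_height,
              strand_asymmetry = strand_asymmetry,
              chi_drop = chi_drop, chi_drop_extent = as.integer(chi_drop_extent),
              gcs_enrichment = gcs_enrichment,
              plasmid_length = as.integer(plasmid_length),
              plasmid_copy_number = as.integer(plasmid_copy_number),
              plasmid_preference = plasmid_preference,
              length_probs = length_probs, adapter = adapter,
              ori = as.integer(ori), ter_midpoint = as.integer(ter_midpoint))
  stopifnot(
    cfg$n_reads >= 0, cfg$genome_length > 0,
    cfg$gc_fraction > 0, cfg$gc_fraction < 1,
    cfg$chi_count >= 0, cfg$gcs_count >= 0,
    cfg$background_rate > 0, cfg$ter_peak_height >= 1,
    cfg$strand_asymmetry >= 1,
    cfg$chi_drop >= 0, cfg$chi_drop < 1, cfg$chi_drop_extent > 0,
    cfg$gcs_enrichment >= 1,
    cfg$plasmid_length > 0, cfg$plasmid_copy_number >= 1,
    cfg$plasmid_preference > 0,
    all(as.integer(names(cfg$length_probs)) >= 14),
    all(as.integer(names(cfg$length_probs)) <= 19),
    all(cfg$length_probs >= 0), sum(cfg$length_probs) > 0,
    all(cfg$ter$position >= 0), all(cfg$ter$position < L),
    adapter == "" || is_dna_string(adapter)
  )
  structure(cfg, class = "generative_config")
}

CHI_MOTIF <- "GCTGGTGG"

random_dna <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# Remove every occurrence of motif (both strands, junction included) from a
# character-vector genome by resampling the offending bases.
scrub_motif <- function(chars, motif, gc, circular = TRUE, max_iter = 50L) {
  k <- nchar(motif)
  L <- length(chars)
  pats <- list(Biostrings::DNAString(motif),
               Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  for (iter in seq_len(max_iter)) {
    s <- paste(chars, collapse = "")
    if (circular && L > k) s <- paste0(s, substr(s, 1L, k - 1L))
    subj <- Biostrings::DNAString(s)
    st <- unlist(lapply(pats, function(p) {
      BiocGenerics::start(Biostrings::matchPattern(p, subj, fixed = TRUE))
    }))
    st <- unique(st[st <= L])
    if (length(st) == 0) return(chars)
    for (p in st) {
      idx <- ((p - 1L + 0:(k - 1L)) %% L) + 1L
      chars[idx] <- random_dna(k, gc)
    }
  }
  stop("could not scrub motif occurrences after ", max_iter, " iterations")
}

#' Build a synthetic reference with planted sites and recorded ground truth
#'
#' Generates a random circular chromosome at the configured GC content with
#' all spurious Chi octamers scrubbed out by rejection, then plants
#' `chi_count` Chi motifs: one co-oriented Chi next to each ter trap (at a
#' distance drawn from `ter_chi_distance`, bounding the ter peak) and the
#' rest at uniform positions and strands outside the ter corridors. Gyrase
#' cleavage sites are placed uniformly. A motif-free plasmid replicon is
#' appended. The realized ter peak windows (trap to nearest co-oriented Chi)
#' and the default analysis mask (the ter region padded by 20 kb, the
#' analogue of masking the chromosome's termination region) are recorded on
#' the bundle; all planted coordinates are returned as ground truth.
#'
#' @param config a [generative_config()].
#' @return list with elements `bundle` (a [ref_bundle()]) and `truth`
#'   (planted site tables and parameters).
#' @export
build_reference <- function(config) {
  stopifnot(inherits(config, "generative_config"))
  withr::with_seed(config$seed, build_reference_impl(config))
}

build_reference_impl <- function(config) {
  L <- config$genome_length
  k <- nchar(CHI_MOTIF)
  gc <- config$gc_fraction
  n_ter <- nrow(config$ter)
  if (config$chi_count < n_ter && config$chi_count > 0) {
    stop("chi_count must be 0 or >= the number of ter sites")
  }
  for (attempt in seq_len(20L)) {
    chars <- scrub_motif(random_dna(L, gc), CHI_MOTIF, gc)
    chi <- tibble::tibble(replicon = character(), position = integer(),
                          strand = character(), width = integer())
    if (config$chi_count > 0) {
      # ter-adjacent co-oriented Chi bound each ter peak
      d <- as.integer(round(stats::runif(n_ter, config$ter_chi_distance[1],
                                         config$ter_chi_distance[2])))
      ter_chi <- tibble::tibble(
        replicon = "chromosome",
        position = ifelse(config$ter$blocked_strand == "-",
                          wrap0(config$ter$position + d - (k - 1L), L),
                          wrap0(config$ter$position - d, L)),
        strand = config$ter$blocked_strand, width = k
      )
      # remaining Chi at uniform positions/strands, kept out of the ter
      # corridors and separated by >= 1 kb
      excl <- rep(FALSE, L)
      pad <- config$ter_chi_distance[2] + 1000L
      for (i in seq_len(n_ter)) {
        tp <- config$ter$position[i]
        excl[wrap0((tp - pad):(tp + pad), L) + 1L] <- TRUE
      }
      n_free <- config$chi_count - n_ter
      pos <- integer(0)
      cand <- which(!excl) - 1L
      while (length(pos) < n_free) {
        p <- sample(cand, 1L)
        if (length(pos) == 0 ||
            min(pmin(wrap0(p - pos, L), wrap0(pos - p, L))) >= 1000L) {
          pos <- c(pos, p)
        }
      }
      free_chi <- tibble::tibble(replicon = "chromosome", position = pos,
                                 strand = sample(c("+", "-"), n_free, TRUE),
                                 width = k)
      chi <- dplyr::bind_rows(ter_chi, free_chi)
      for (i in seq_len(nrow(chi))) {
        m <- if (chi$strand[i] == "+") CHI_MOTIF else revcomp_chr(CHI_MOTIF)
        idx <- wrap0(chi$position[i] + 0:(k - 1L), L) + 1L
        chars[idx] <- strsplit(m, "")[[1]]
      }
      chi <- dplyr::arrange(chi, .data$position)
    }
    chrom <- paste(chars, collapse = "")
    plasmid <- paste(scrub_motif(random_dna(config$plasmid_length, gc),
                                 CHI_MOTIF, gc), collapse = "")
    seqs <- Biostrings::DNAStringSet(c(chromosome = chrom, plasmid = plasmid))
    replicons <- tibble::tibble(
      name = c("chromosome", "plasmid"), topology = "circular",
      copy_number = c(1L, config$plasmid_copy_number),
      role = c("chromosome", "plasmid")
    )
    bundle <- ref_bundle(seqs, replicons, ori = config$ori,
                         ter_midpoint = config$ter_midpoint)
    found <- scan_motif(bundle, CHI_MOTIF)
    planted <- dplyr::arrange(chi, .data$replicon, .data$position, .data$strand)
    if (nrow(found) == nrow(planted) &&
        (nrow(found) == 0 ||
         all(found$position == planted$position & found$strand == planted$strand &
             found$replicon == planted$replicon))) {
      bundle$chi <- planted
      break
    }
    if (attempt == 20L) stop("could not plant Chi motifs cleanly after 20 attempts")
  }
  # gyrase cleavage sites: uniform, unstranded points
  gcs <- tibble::tibble(replicon = character(), position = integer(),
                        strand = character(), width = integer())
  if (config$gcs_count > 0) {
    gp <- sort(sample.int(L, config$gcs_count) - 1L)
    gcs <- tibble::tibble(replicon = "chromosome", position = gp,
                          strand = "*", width = 1L)
  }
  bundle$gcs <- gcs
  bundle$ter_sites <- realized_ter_windows(config, bundle$chi, L)
  if (nrow(bundle$ter_sites) > 0) {
    lo <- min(bundle$ter_sites$start) - 20000L
    hi <- max(bundle$ter_sites$end) + 20000L
    bundle$masks <- normalize_masks(
      tibble::tibble(replicon = "chromosome",
                     start = max(0L, lo), end = min(L, hi))
    )
  }
  truth <- list(chi = bundle$chi, gcs = bundle$gcs, ter = bundle$ter_sites,
                params = config[c("background_rate", "ter_peak_height",
                                  "strand_asymmetry", "chi_drop",
                                  "chi_drop_extent", "gcs_enrichment",
                                  "plasmid_copy_number", "plasmid_preference")],
                config = config)
  list(bundle = bundle, truth = truth)
}

# Realized ter peak windows: from the trap point to the recognition point of
# the nearest co-oriented Chi in the direction RecBCD travels from the trap
# (increasing coordinates for a blocked minus strand, decreasing for plus).
realized_ter_windows <- function(config, chi, L) {
  if (nrow(config$ter) == 0 || is.null(chi) || nrow(chi) == 0) {
    return(tibble::tibble(name = character(), replicon = character(),
                          start = integer(), end = integer(),
                          blocked_strand = character()))
  }
  refs <- anchor_ref(chi)
  purrr::map_dfr(seq_len(nrow(config$ter)), function(i) {
    tp <- config$ter$position[i]
    bs <- config$ter$blocked_strand[i]
    co <- refs[chi$strand == bs]
    if (bs == "-") {
      d <- wrap0(co - tp, L)
      len <- min(d[d > 0])
      tibble::tibble(name = config$ter$name[i], replicon = "chromosome",
                     start = tp, end = tp + len, blocked_strand = bs)
    } else {
      d <- wrap0(tp - co, L)
      len <- min(d[d > 0])
      tibble::tibble(name = config$ter$name[i], replicon = "chromosome",
                     start = tp + 1L - len, end = tp + 1L, blocked_strand = bs)
    }
  })
}

#' Per-position, per-strand read-sampling intensity
#'
#' Composes the generative intensity multiplicatively:
#' `lambda(p, s) = beta * m_ter * m_chi * m_gcs`, where `m_ter` is `h` on the
#' blocked strand and `h / a` on the complementary strand over each ter peak
#' window; `m_chi` is `1 - delta` at each co-oriented Chi, recovering
#' linearly to 1 over `w` bp on the 5' side; and `m_gcs` (only when
#' `cfx = TRUE`) is `gamma` between each GCS and its closest upstream
#' co-oriented Chi on that Chi's strand (union over GCSs, applied once).
#' Plasmid positions get constant `beta * copy_number * preference`.
#'
#' @param bundle bundle from [build_reference()].
#' @param config the [generative_config()].
#' @param cfx logical: +Cfx (gyrase-poisoned) library?
#' @return named list per replicon of `list(plus =, minus =)` intensity
#'   vectors.
#' @export
build_intensity <- function(bundle, config, cfx = FALSE) {
  L <- replicon_length(bundle, "chromosome")
  beta <- config$background_rate
  plus <- rep(beta, L)
  minus <- rep(beta, L)
  h <- config$ter_peak_height
  a <- config$strand_asymmetry
  if (!is.null(bundle$ter_sites) && nrow(bundle$ter_sites) > 0) {
    for (i in seq_len(nrow(bundle$ter_sites))) {
      tw <- bundle$ter_sites[i, ]
      idx <- interval_pos0(tw$start, tw$end, L) + 1L
      if (tw$blocked_strand == "-") {
        minus[idx] <- minus[idx] * h
        plus[idx] <- plus[idx] * (h / a)
      } else {
        plus[idx] <- plus[idx] * h
        minus[idx] <- minus[idx] * (h / a)
      }
    }
  }
  delta <- config$chi_drop
  w <- config$chi_drop_extent
  chi <- bundle$chi
  if (delta > 0 && !is.null(chi) && nrow(chi) > 0) {
    refs <- anchor_ref(chi)
    ramp <- 1 - delta + delta * (w:0) / w  # positions ref - w .. ref
    for (i in seq_len(nrow(chi))) {
      if (chi$strand[i] == "+") {
        idx <- wrap0((refs[i] - w):refs[i], L) + 1L
        plus[idx] <- plus[idx] * ramp
      } else {
        idx <- wrap0(refs[i]:(refs[i] + w), L) + 1L
        minus[idx] <- minus[idx] * rev(ramp)
      }
    }
  }
  gam <- config$gcs_enrichment
  if (cfx && gam > 1 && !is.null(bundle$gcs) && nrow(bundle$gcs) > 0 &&
      !is.null(chi) && nrow(chi) > 0) {
    refs <- anchor_ref(chi)
    boost_p <- rep(FALSE, L)
    boost_m <- rep(FALSE, L)
    plus_refs <- refs[chi$strand == "+"]
    minus_refs <- refs[chi$strand == "-"]
    for (g in bundle$gcs$position) {
      if (length(plus_refs) > 0) {
        len <- min(wrap0(g - plus_refs, L))
        if (len > 0) {  # positions cref+1 .. g on the plus strand
          boost_p[wrap0(g - len + 1L + 0:(len - 1L), L) + 1L] <- TRUE
        }
      }
      if (length(minus_refs) > 0) {
        len <- min(wrap0(minus_refs - g, L))
        if (len > 0) {  # positions g .. aref-1 on the minus strand
          boost_m[wrap0(g + 0:(len - 1L), L) + 1L] <- TRUE
        }
      }
    }
    plus[boost_p] <- plus[boost_p] * gam
    minus[boost_m] <- minus[boost_m] * gam
  }
  # Plasmid rate is defined relative to the chromosome's mean per-base
  # intensity so that `plasmid_preference` is exactly the per-copy,
  # length-corrected fold that plasmid_enrichment() estimates, whatever the
  # chromosomal modifiers do to the average density.
  pl_rate <- mean(c(plus, minus)) * config$plasmid_copy_number *
    config$plasmid_preference
  Lp <- replicon_length(bundle, "plasmid")
  list(chromosome = list(plus = plus, minus = minus),
       plasmid = list(plus = rep(pl_rate, Lp), minus = rep(pl_rate, Lp)))
}

#' Sample reads from an intensity model and write a FASTQ library
#'
#' Draws `n_reads` 5'-end positions proportional to the intensity, read
#' lengths from the configured 14-19 nt distribution, takes the reference
#' strand sequence 5' to 3' from each sampled position (wrapping across the
#' origin of circular replicons), appends the adapter when configured, and
#' optionally writes a Sanger-encoded FASTQ file. Fully reproducible: the
#' generator stream is seeded from `config$seed` and the `cfx` flag.
#'
#' @param bundle bundle from [build_reference()].
#' @param intensity output of [build_intensity()] for the same `cfx` flag.
#' @param config the [generative_config()].
#' @param cfx logical; selects the library-specific random stream.
#' @param out_fastq optional output path.
#' @return list with `reads` ([Biostrings::DNAStringSet], adapter included),
#'   `truth` tibble `(read_id, replicon, position, strand, length)` of true
#'   5'-end coordinates, and `path`.
#' @export
sample_reads <- function(bundle, intensity, config, cfx = FALSE,
                         out_fastq = NULL) {
  seed <- derive_seed(config$seed, 1L + as.integer(cfx))
  res <- withr::with_seed(seed, sample_reads_impl(bundle, intensity, config))
  if (!is.null(out_fastq)) {
    write_fastq(res$reads, out_fastq)
    res$path <- out_fastq
  }
  res
}

sample_reads_impl <- function(bundle, intensity, config) {
  n <- config$n_reads
  reps <- names(intensity)
  lens <- purrr::map_int(reps, ~ length(intensity[[.x]]$plus))
  lam <- unlist(purrr::map(reps, ~ c(intensity[[.x]]$plus, intensity[[.x]]$minus)),
                use.names = FALSE)
  if (n == 0) {
    return(list(reads = Biostrings::DNAStringSet(),
                truth = tibble::tibble(read_id = character(),
                                       replicon = character(),
                                       position = integer(), strand = character(),
                                       length = integer()),
                path = NULL))
  }
  draw <- sample.int(length(lam), n, replace = TRUE, prob = lam)
  # decode (replicon, strand, position)
  offs <- cumsum(c(0, rep(lens, each = 2)))
  block <- findInterval(draw - 1L, offs, rightmost.closed = FALSE)
  repl <- reps[(block + 1L) %/% 2L]
  strand <- ifelse(block %% 2L == 1L, "+", "-")
  pos <- (draw - 1L) - offs[block]
  rl <- as.integer(names(config$length_probs))
  rlen <- rl[sample.int(length(rl), n, replace = TRUE, prob = config$length_probs)]
  seq_chr <- character(n)
  for (r in reps) {
    L <- lens[match(r, reps)]
    s <- as.character(bundle$sequences[[match(r, names(bundle$sequences))]])
    circ <- replicon_circular(bundle, r)
    s2 <- if (circ) paste0(s, substr(s, 1L, 20L)) else s
    ip <- which(repl == r & strand == "+")
    if (length(ip)) {
      if (!circ) {
        over <- ip[pos[ip] + rlen[ip] > L]
        while (length(over)) {  # resample reads running off a linear end
          pos[over] <- sample.int(L, length(over)) - 1L
          over <- over[pos[over] + rlen[over] > L]
        }
      }
      seq_chr[ip] <- substring(s2, pos[ip] + 1L, pos[ip] + rlen[ip])
    }
    im <- which(repl == r & strand == "-")
    if (length(im)) {
      if (!circ) {
        under <- im[pos[im] - rlen[im] + 1L < 0L]
        while (length(under)) {
          pos[under] <- sample.int(L, length(under)) - 1L
          under <- under[pos[under] - rlen[under] + 1L < 0L]
        }
      }
      st0 <- wrap0(pos[im] - rlen[im] + 1L, L)
      fwd <- substring(s2, st0 + 1L, st0 + rlen[im])
      seq_chr[im] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(fwd)))
    }
  }
  if (nzchar(config$adapter)) seq_chr <- paste0(seq_chr, config$adapter)
  reads <- Biostrings::DNAStringSet(seq_chr)
  names(reads) <- sprintf("read_%07d", seq_len(n))
  truth <- tibble::tibble(read_id = names(reads), replicon = repl,
                          position = as.integer(pos), strand = strand,
                          length = rlen)
  list(reads = reads, truth = truth, path = NULL)
}

write_fastq <- function(reads, path) {
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
  names(quals) <- names(reads)
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Simulate a control / +Cfx pair of smDNA libraries
#'
#' Builds the synthetic reference once, then samples a control (`-Cfx`) and a
#' gyrase-poisoned (`+Cfx`) library from their respective intensity models.
#'
#' @param config a [generative_config()].
#' @param out_dir optional directory; when given, writes `ref.fa`,
#'   `ctrl.fastq` and `cfx.fastq` there.
#' @return list with `bundle`, `truth` (ground truth incl. per-library
#'   intensity arrays and per-read source records) and the two read sets.
#' @export
simulate_pair <- function(config, out_dir = NULL) {
  built <- build_reference(config)
  int_ctrl <- build_intensity(built$bundle, config, cfx = FALSE)
  int_cfx <- build_intensity(built$bundle, config, cfx = TRUE)
  p_ctrl <- p_cfx <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(built$bundle$sequences,
                                file.path(out_dir, "ref.fa"))
    p_ctrl <- file.path(out_dir, "ctrl.fastq")
    p_cfx <- file.path(out_dir, "cfx.fastq")
  }
  ctrl <- sample_reads(built$bundle, int_ctrl, config, cfx = FALSE,
                       out_fastq = p_ctrl)
  cfx <- sample_reads(built$bundle, int_cfx, config, cfx = TRUE,
                      out_fastq = p_cfx)
  built$truth$intensity <- list(ctrl = int_ctrl, cfx = int_cfx)
  built$truth$reads <- list(ctrl = ctrl$truth, cfx = cfx$truth)
  list(bundle = built$bundle, truth = built$truth, ctrl = ctrl, cfx = cfx)
}

#' Simulate a single smDNA library
#'
#' @inheritParams simulate_pair
#' @param cfx logical: simulate the gyrase-poisoned library?
#' @param out_fastq optional FASTQ output path.
#' @return list with `bundle`, `truth`, `reads`.
#' @export
simulate_library <- function(config, cfx = FALSE, out_fastq = NULL) {
  built <- build_reference(config)
  intensity <- build_intensity(built$bundle, config, cfx = cfx)
  smp <- sample_reads(built$bundle, intensity, config, cfx = cfx,
                      out_fastq = out_fastq)
  built$truth$intensity <- intensity
  built$truth$reads <- smp$truth
  list(bundle = built$bundle, truth = built$truth, reads = smp$reads,
       path = smp$path)
}
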