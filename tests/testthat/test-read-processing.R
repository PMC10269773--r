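write_tmp_fastq <- function(seqs, quals = NULL) {
  f <- tempfile(fileext = ".fastq")
  lines <- unlist(purrr::map(seq_along(seqs), function(i) {
    c(paste0("@r", i), seqs[i], "+",
      if (is.null(quals)) strrep("I", nchar(seqs[i])) else quals[i])
  }))
  writeLines(lines, f)
  f
}

test_that("adapter trimming and the 14-nt length filter follow the rules", {
  adapter <- "AGATCGGAAGAGC"
  insert16 <- "ACGTACGTACGTACGT"
  insert13 <- "ACGTACGTACGTA"
  plain <- "TTTTACGTACGTACGTTT"
  f <- write_tmp_fastq(c(paste0(insert16, adapter, "TTT"),
                         paste0(insert13, adapter),
                         plain))
  rs <- preprocess_reads(f, adapter = adapter)
  expect_equal(length(rs$reads), 2L)
  expect_equal(as.character(rs$reads[[1]]), insert16)
  expect_equal(as.character(rs$reads[[2]]), plain)  # adapter absent: unchanged
  expect_equal(rs$log$n_trimmed, 2L)
  expect_equal(rs$log$n_discarded, 1L)

  # leftmost occurrence wins when the adapter appears twice
  f2 <- write_tmp_fastq(paste0(insert16, adapter, "AC", adapter))
  rs2 <- preprocess_reads(f2, adapter = adapter)
  expect_equal(as.character(rs2$reads[[1]]), insert16)

  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT"), bad)  # truncated record
  expect_error(preprocess_reads(bad), "malformed FASTQ")
})

test_that("alignment reports 5' ends with the documented strand arithmetic", {
  withr::with_seed(21, g <- random_genome(4000))
  b <- tiny_bundle(g, topology = "linear")
  plus_read <- substr(g, 101, 117)            # 0-based [100, 117)
  minus_read <- revcomp(substr(g, 201, 216))  # 0-based [200, 216)
  f <- write_tmp_fastq(c(plus_read, minus_read))
  al <- align_exact(preprocess_reads(f), b)
  expect_equal(al$alignments$strand, c("+", "-"))
  expect_equal(al$alignments$position, c(100L, 215L))
  expect_equal(al$counts$counts$chr$plus[101], 1L)
  expect_equal(al$counts$counts$chr$minus[216], 1L)
  expect_equal(al$counts$total_aligned, 2L)
})

test_that("non-ACGT reads are unalignable and counted as such", {
  withr::with_seed(22, g <- random_genome(1000))
  f <- write_tmp_fastq(c(substr(g, 1, 20), "ACGTNNACGTACGTACGT"))
  al <- align_exact(preprocess_reads(f), tiny_bundle(g))
  expect_equal(al$log$n_aligned, 1L)
  expect_equal(al$log$n_unaligned, 1L)
})

test_that("multimapper policy is deterministic and matches brute force", {
  withr::with_seed(23, {
    core <- random_genome(15)
    g <- paste0(random_genome(500), core, random_genome(800), core,
                random_genome(300))
    b <- tiny_bundle(g, topology = "linear")
    f <- write_tmp_fastq(core)
    first <- align_exact(preprocess_reads(f), b, multimappers = "first")
    hits <- bf_read_hits(core, g)
    expect_equal(first$alignments$n_hits, nrow(hits))
    best <- hits[order(hits$start, hits$strand), ][1, ]
    expect_equal(first$alignments$position, best$position)
    disc <- align_exact(preprocess_reads(f), b, multimappers = "discard")
    expect_equal(disc$log$n_aligned, 0L)
  })
})

test_that("aligner agrees with brute-force enumeration on random genomes", {
  withr::with_seed(24, {
    for (rep in 1:8) {
      L <- sample(1000:4000, 1)
      circ <- rep %% 2 == 0
      g <- random_genome(L)
      b <- tiny_bundle(g, topology = if (circ) "circular" else "linear")
      # reads sampled from the genome (both strands) plus one random read
      reads <- character(0)
      for (i in 1:20) {
        w <- sample(14:19, 1)
        p <- sample(0:(L - w), 1)
        r <- substr(g, p + 1, p + w)
        if (runif(1) < 0.5) r <- revcomp(r)
        reads <- c(reads, r)
      }
      reads <- c(reads, random_genome(16))
      al <- align_exact(preprocess_reads(write_tmp_fastq(reads)), b)
      for (i in seq_along(reads)) {
        hits <- bf_read_hits(reads[i], g, circular = circ)
        row <- al$alignments[al$alignments$read_id == paste0("r", i), ]
        if (nrow(hits) == 0) {
          expect_equal(nrow(row), 0L)
        } else {
          expect_equal(nrow(row), 1L)
          best <- hits[order(hits$start, hits$strand), ][1, ]
          expect_equal(row$position, best$position)
          expect_equal(row$strand, best$strand)
          expect_equal(row$n_hits, nrow(hits))
        }
      }
    }
  })
})

test_that("simulated reads align back to their recorded source positions", {
  cfg <- generative_config(seed = 25, n_reads = 5000, genome_length = 1e5,
                           chi_count = 8L, gcs_count = 4L,
                           ter = tibble::tibble(name = c("terA", "terC"),
                                                position = c(40000L, 60000L),
                                                blocked_strand = c("-", "+")),
                           ter_chi_distance = c(5000L, 8000L))
  sim <- simulate_library(cfg)
  tf <- tempfile(fileext = ".fastq")
  smdnaseq:::write_fastq(sim$reads, tf)
  al <- align_exact(preprocess_reads(tf, adapter = cfg$adapter), sim$bundle,
                    multimappers = "discard")
  m <- dplyr::inner_join(al$alignments, sim$truth$reads, by = "read_id",
                         suffix = c("", ".true"))
  expect_gt(nrow(m) / cfg$n_reads, 0.98)  # only multimappers drop out
  expect_true(all(m$position == m$position.true))
  expect_true(all(m$strand == m$strand.true))
  expect_true(all(m$replicon == m$replicon.true))
})

test_that("RPKM windows follow the closed form and conserve totals", {
  plus <- integer(10000); minus <- integer(10000)
  plus[5001] <- 100L  # 100 5' ends in window [5000, 6000)
  sc <- counts_from_vectors(plus, minus)
  sc$total_aligned <- 1e6; sc$total_input <- 1e6
  rw <- rpkm_windows(sc, window_size = 1000L)
  expect_equal(rw$rpkm[rw$strand == "+" & rw$start == 5000], 100)
  expect_equal(sum(rw$rpkm[rw$strand == "+" & rw$start != 5000]), 0)

  withr::with_seed(26, {
    plus <- as.integer(rpois(5500, 2)); minus <- as.integer(rpois(5500, 1))
    sc <- counts_from_vectors(plus, minus)
    rw <- rpkm_windows(sc, window_size = 1000L)
    # conservation: window counts reconstructed from RPKM sum to the total
    back <- sum(rw$rpkm * (rw$end - rw$start) * sc$total_aligned / 1e9)
    expect_equal(sum(rw$count), sum(plus) + sum(minus))
    expect_equal(back, sc$total_aligned, tolerance = 1e-9)
    # final partial window (500 bp) normalized by true length
    last <- rw[rw$strand == "+" & rw$start == 5000, ]
    expect_equal(last$rpkm, sum(plus[5001:5500]) * 1e9 /
                   (500 * sc$total_aligned))
    # direct recomputation per window
    for (w in 0:5) {
      idx <- (w * 1000 + 1):min((w + 1) * 1000, 5500)
      expect_equal(rw$count[rw$strand == "-" & rw$start == w * 1000],
                   sum(minus[idx]))
    }
  })
  expect_error(rpkm_windows(counts_from_vectors(integer(10), integer(10))),
               "empty library")
})

test_that("alignments and classified sites export as BED6", {
  withr::with_seed(28, g <- random_genome(2000))
  b <- tiny_bundle(g, topology = "linear")
  f <- write_tmp_fastq(c(substr(g, 101, 116), revcomp(substr(g, 501, 515))))
  al <- align_exact(preprocess_reads(f), b)
  bed <- tempfile(fileext = ".bed")
  write_alignments_bed(al$alignments, bed)
  iv <- read_bed_intervals(bed)
  expect_equal(iv$start, c(100L, 500L))
  expect_equal(iv$end, c(116L, 515L))
  expect_equal(iv$strand, c("+", "-"))

  sites <- tibble::tibble(replicon = "chr", position = c(10L, 50L),
                          strand = c("+", "-"), width = 8L,
                          class = c("downstream_gcs", "other"))
  sb <- tempfile(fileext = ".bed")
  write_sites_bed(sites, sb)
  siv <- read_bed_intervals(sb)
  expect_equal(siv$name, c("downstream_gcs", "other"))
  expect_equal(siv$end - siv$start, c(8L, 8L))
})

test_that("strand counts round-trip through bedGraph export", {
  withr::with_seed(27, {
    plus <- as.integer(rpois(3000, 0.5)); minus <- as.integer(rpois(3000, 0.3))
    sc <- counts_from_vectors(plus, minus)
    pre <- tempfile()
    write_strand_counts(sc, pre)
    back <- read_strand_counts(pre)
    expect_equal(back$counts$chr$plus, sc$counts$chr$plus)
    expect_equal(back$counts$chr$minus, sc$counts$chr$minus)
    expect_equal(back$total_aligned, sc$total_aligned)
  })
})
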