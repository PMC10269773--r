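anchor <- function(position, strand = "+", width = 8L, replicon = "chr") {
  tibble::tibble(replicon = replicon, position = as.integer(position),
                 strand = strand, width = width)
}

test_that("metaplot orientation bookkeeping is exact", {
  L <- 20000L
  plus <- integer(L); minus <- integer(L)
  sc0 <- counts_from_vectors(rep(3L, L), rep(3L, L))
  # uniform counts: flat profile, F equals R
  mp <- anchored_profile(sc0, anchor(10000L), half_width = 2000L,
                         smoothing = 1L)
  expect_true(all(abs(mp$F - mp$F[1]) < 1e-9))
  expect_equal(mp$F, mp$R)

  # counts only at anchor_ref + 10 on the plus strand, plus-strand anchor
  plus[10000 + 10 + 1] <- 7L
  sc <- counts_from_vectors(plus, minus)
  mp <- anchored_profile(sc, anchor(10000L), half_width = 100L, smoothing = 1L)
  expect_equal(mp$F[mp$offset == 10] * sc$total_aligned / 1e9, 7)
  expect_equal(sum(mp$F > 0), 1L)
  expect_true(all(mp$R == 0))

  # mirrored minus-strand configuration gives the identical F profile:
  # minus anchor at position p has reference p + 7, and its +10 offset is
  # reference - 10 on the minus strand
  plus2 <- integer(L); minus2 <- integer(L)
  minus2[(10000 + 7) - 10 + 1] <- 7L
  sc2 <- counts_from_vectors(plus2, minus2)
  mp2 <- anchored_profile(sc2, anchor(10000L, "-"), half_width = 100L,
                          smoothing = 1L)
  expect_equal(mp2$F, mp$F)
  expect_equal(mp2$R, mp$R)
})

test_that("metaplot equals a loop-based recomputation with masks", {
  withr::with_seed(41, {
    for (rep in 1:6) {
      L <- 30000L
      plus <- as.integer(rpois(L, 0.3)); minus <- as.integer(rpois(L, 0.3))
      n_anch <- 30
      anchors <- tibble::tibble(
        replicon = "chr",
        position = sample(0:(L - 9), n_anch),
        strand = sample(c("+", "-"), n_anch, TRUE), width = 8L)
      masks <- tibble::tibble(replicon = "chr",
                              start = c(2000L, 25000L), end = c(4000L, 26000L))
      mask <- rep(FALSE, L); mask[2001:4000] <- TRUE; mask[25001:26000] <- TRUE
      sc <- counts_from_vectors(plus, minus)
      hw <- 1500L
      mp <- anchored_profile(sc, anchors, half_width = hw, smoothing = 1L,
                             masks = masks)
      want <- bf_metaplot(plus, minus, anchors, hw, L, circular = TRUE,
                          mask = mask)
      scale <- 1e9 / sc$total_aligned
      expect_equal(mp$F, want$F * scale, tolerance = 1e-9)
      expect_equal(mp$R, want$R * scale, tolerance = 1e-9)
      expect_equal(mp$n_F, want$n)
    }
  })
})

test_that("background normalization and the drop statistic are arithmetic", {
  # flat profile: background equals the value, drop is 0
  sc <- counts_from_vectors(rep(2L, 120000), rep(2L, 120000))
  mp <- anchored_profile(sc, anchor(60000L), half_width = 50000L,
                         smoothing = 401L)
  nd <- normalize_and_drop(mp)
  expect_equal(nd$drop_percent, 0, tolerance = 1e-9)
  expect_equal(nd$background, mp$F[1], tolerance = 1e-9)

  # a 40% dip at the anchor: normalized minimum 0.60 -> drop 40%
  plus <- rep(10L, 120000)
  plus[60000 + (-100:100) + 1] <- 6L
  sc <- counts_from_vectors(plus, rep(10L, 120000))
  mp <- anchored_profile(sc, anchor(60000L), half_width = 50000L,
                         smoothing = 1L)
  nd <- normalize_and_drop(mp)
  expect_equal(nd$drop_percent, 40, tolerance = 1e-6)

  mp_small <- anchored_profile(sc, anchor(60000L), half_width = 10000L,
                               smoothing = 1L)
  expect_error(normalize_and_drop(mp_small), "half_width")
})

test_that("chi/GCS adjacency classes follow the intervening-site rule", {
  L <- 100000L
  gcs1 <- tibble::tibble(replicon = "chr", position = 12000L, strand = "*",
                         width = 1L)
  # single Chi with a downstream GCS
  c1 <- classify_chi_gcs(anchor(10000L), gcs1, L)
  expect_equal(c1$class, "downstream_gcs")
  expect_equal(c1$gcs_distance, 2000)
  # an intervening co-oriented Chi demotes the upstream site
  two <- dplyr::bind_rows(anchor(10000L), anchor(11000L))
  c2 <- classify_chi_gcs(two, gcs1, L)
  expect_equal(c2$class[c2$position == 10000], "other")
  expect_equal(c2$class[c2$position == 11000], "downstream_gcs")
  # an opposite-strand Chi in between does not
  mixed <- dplyr::bind_rows(anchor(10000L), anchor(11000L, "-"))
  c3 <- classify_chi_gcs(mixed, gcs1, L)
  expect_equal(c3$class[c3$position == 10000], "downstream_gcs")
  # minus-strand Chi looks 3' in decreasing coordinates
  c4 <- classify_chi_gcs(anchor(15000L, "-"), gcs1, L)
  expect_equal(c4$class, "downstream_gcs")
  c5 <- classify_chi_gcs(anchor(15000L, "+"), gcs1, L)
  # circular: the GCS is still downstream, all the way around
  expect_equal(c5$class, "downstream_gcs")
  expect_equal(c5$gcs_distance, L - 15000 + 12000)
  # linear: it is not
  c6 <- classify_chi_gcs(anchor(15000L, "+"), gcs1, L, circular = FALSE)
  expect_equal(c6$class, "other")
  expect_true(c6$upstream_gcs)
})

test_that("classifier matches the brute-force pairwise check", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      L <- 50000L
      n_chi <- sample(3:12, 1); n_gcs <- sample(0:8, 1)
      chi <- tibble::tibble(replicon = "chr",
                            position = sample(0:(L - 9), n_chi),
                            strand = sample(c("+", "-"), n_chi, TRUE),
                            width = 8L)
      gcs <- tibble::tibble(replicon = "chr",
                            position = sample(0:(L - 1), n_gcs),
                            strand = "*", width = 1L)
      got <- classify_chi_gcs(chi, gcs, L)
      expect_equal(got$class, bf_classify(chi, gcs, L))
    }
  })
})

test_that("identical libraries give unit enrichment and a null test", {
  withr::with_seed(43, {
    L <- 60000L
    plus <- as.integer(rpois(L, 1)); minus <- as.integer(rpois(L, 1))
    sc <- counts_from_vectors(plus, minus)
    chi <- tibble::tibble(replicon = "chr",
                          position = seq(2000L, 58000L, by = 7000L),
                          strand = rep(c("+", "-"), length.out = 9), width = 8L)
    gcs <- tibble::tibble(replicon = "chr",
                          position = c(5000L, 20000L, 40000L),
                          strand = "*", width = 1L)
    cls <- classify_chi_gcs(chi, gcs, L)
    enr <- relative_density_enrichment(sc, sc, cls, n_perm = 200)
    expect_true(all(abs(enr$per_site$enrichment - 1) < 1e-12))
    expect_equal(enr$t_statistic, 0)
    expect_equal(enr$p_value, 1)
  })
})

test_that("planted enrichment on downstream intervals is detected", {
  withr::with_seed(44, {
    L <- 200000L
    lambda <- 0.5
    plus_ctrl <- as.integer(rpois(L, lambda))
    minus_ctrl <- as.integer(rpois(L, lambda))
    # 40 co-oriented chi; a GCS 3 kb downstream of alternate sites (the
    # intervening-chi rule then assigns the remaining sites to "other")
    pos <- seq(2000L, by = 5000L, length.out = 40L)
    chi <- tibble::tibble(replicon = "chr", position = pos,
                          strand = "+", width = 8L)
    has_gcs <- rep(c(TRUE, FALSE), length.out = 40)
    gcs <- tibble::tibble(replicon = "chr", position = pos[has_gcs] + 3000L,
                          strand = "*", width = 1L)
    lam_cfx_p <- rep(lambda, L); lam_cfx_m <- rep(lambda, L)
    for (i in which(has_gcs)) {  # gamma = 2 between chi and its GCS
      idx <- (pos[i]):(pos[i] + 3000L) + 1L
      lam_cfx_p[idx] <- 2 * lambda
    }
    sc_ctrl <- counts_from_vectors(plus_ctrl, minus_ctrl)
    sc_cfx <- counts_from_vectors(as.integer(rpois(L, lam_cfx_p)),
                                  as.integer(rpois(L, lam_cfx_m)))
    cls <- classify_chi_gcs(chi, gcs, L)
    expect_gte(sum(cls$class == "downstream_gcs"), 20)
    enr <- relative_density_enrichment(sc_cfx, sc_ctrl, cls, n_perm = 1000,
                                       perm_seed = 7)
    s <- enr$summary
    expect_gt(s$mean[s$class == "downstream_gcs"], s$mean[s$class == "other"])
    expect_lt(enr$p_value, 0.05)
    expect_lt(enr$p_permutation, 0.05)
  })
})

test_that("the reported test equals the closed-form Welch computation", {
  withr::with_seed(47, {
    L <- 80000L
    sc_ctrl <- counts_from_vectors(as.integer(rpois(L, 1)),
                                   as.integer(rpois(L, 1)))
    sc_cfx <- counts_from_vectors(as.integer(rpois(L, 1.2)),
                                  as.integer(rpois(L, 1.2)))
    chi <- tibble::tibble(replicon = "chr",
                          position = seq(3000L, 75000L, by = 6000L),
                          strand = rep(c("+", "-"), length.out = 13),
                          width = 8L)
    gcs <- tibble::tibble(replicon = "chr",
                          position = c(10000L, 30000L, 50000L, 70000L),
                          strand = "*", width = 1L)
    cls <- classify_chi_gcs(chi, gcs, L)
    enr <- relative_density_enrichment(sc_cfx, sc_ctrl, cls, n_perm = 0)
    g1 <- tidy(enr)$enrichment[tidy(enr)$class == "downstream_gcs"]
    g2 <- tidy(enr)$enrichment[tidy(enr)$class == "other"]
    n1 <- length(g1); n2 <- length(g2)
    se <- sqrt(var(g1) / n1 + var(g2) / n2)
    t_hand <- (mean(g1) - mean(g2)) / se
    df_hand <- se^4 / ((var(g1) / n1)^2 / (n1 - 1) +
                         (var(g2) / n2)^2 / (n2 - 1))
    expect_equal(enr$t_statistic, t_hand, tolerance = 1e-12)
    expect_equal(enr$p_value, 2 * stats::pt(-abs(t_hand), df_hand),
                 tolerance = 1e-12)
    g <- glance(enr)
    expect_equal(g$mean_downstream_gcs, mean(g1))
    expect_equal(g$n_other, n2)
  })
})

test_that("drop recovery is monotone in the planted drop depth", {
  drops <- purrr::map_dbl(c(0.1, 0.2, 0.3, 0.4), function(d) {
    cfg <- generative_config(seed = 45, n_reads = 1.5e5, genome_length = 3e5,
                             chi_count = 14L, gcs_count = 6L,
                             chi_drop = d,
                             ter = tibble::tibble(name = c("terA", "terC"),
                                                  position = c(130000L, 170000L),
                                                  blocked_strand = c("-", "+")),
                             ter_chi_distance = c(10000L, 15000L))
    sim <- simulate_library(cfg)
    tr <- sim$truth$reads
    cc <- list(chromosome = list(
      plus = tabulate(tr$position[tr$replicon == "chromosome" & tr$strand == "+"] + 1L, 3e5),
      minus = tabulate(tr$position[tr$replicon == "chromosome" & tr$strand == "-"] + 1L, 3e5)),
      plasmid = list(plus = tabulate(tr$position[tr$replicon == "plasmid" & tr$strand == "+"] + 1L, cfg$plasmid_length),
                     minus = tabulate(tr$position[tr$replicon == "plasmid" & tr$strand == "-"] + 1L, cfg$plasmid_length)))
    sc <- strand_counts(cc, tibble::tibble(name = c("chromosome", "plasmid"),
                                           length = c(3e5L, cfg$plasmid_length),
                                           circular = TRUE), nrow(tr), nrow(tr))
    chi_un <- smdnaseq:::unmasked_sites(sim$bundle$chi, sim$bundle$masks, 3e5)
    mp <- anchored_profile(sc, chi_un, masks = sim$bundle$masks)
    normalize_and_drop(mp)$drop_percent
  })
  expect_true(all(diff(drops) > 0))
})

test_that("GCS-anchored relative profile is flat at 1 without planted enrichment", {
  cfg <- generative_config(seed = 46, n_reads = 1e5, genome_length = 2e5,
                           chi_count = 10L, gcs_count = 6L,
                           gcs_enrichment = 1,
                           ter = tibble::tibble(name = c("terA", "terC"),
                                                position = c(90000L, 110000L),
                                                blocked_strand = c("-", "+")),
                           ter_chi_distance = c(6000L, 9000L))
  res <- sim_aligned_pair(cfg)
  gcs <- res$pair$bundle$gcs
  mp_cfx <- anchored_profile(res$cfx$counts, gcs, half_width = 15000L,
                             smoothing = 2000L, masks = res$pair$bundle$masks)
  mp_ctrl <- anchored_profile(res$ctrl$counts, gcs, half_width = 15000L,
                              smoothing = 2000L, masks = res$pair$bundle$masks)
  rel <- mp_cfx$F / mp_ctrl$F
  expect_lt(max(abs(rel - 1), na.rm = TRUE), 0.25)
  expect_lt(abs(mean(rel, na.rm = TRUE) - 1), 0.05)
})
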