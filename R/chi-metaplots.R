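# Anchor-site machinery: orientation-flipped metaplots around Chi sites (or
# GCSs), background normalization and the drop statistic, Chi/GCS adjacency
# classes, and the +Cfx vs control relative-density enrichment comparison.

# Orientation convention: each anchor's reference base is the 5'-most base of
# its motif in the anchor's own orientation (plus-strand coordinate
# `position` for + anchors, `position + width - 1` for - anchors). Offsets
# are measured along the anchor orientation, so positive offsets are always
# the anchor's 3' side; the co-oriented strand (F) is the strand the anchor
# lies on (plus for unstranded anchors).

#' Orientation-flipped mean density profile around anchor sites
#'
#' For each anchor, per-base 5'-end densities on the co-oriented (F) and
#' opposite (R) strands over `+/- half_width` are extracted in anchor
#' orientation (coordinate-reversed for minus-strand anchors), averaged
#' position-wise over anchors, converted to per-base RPKM, and smoothed with
#' a centered moving average. Offsets falling in masked regions are excluded
#' from that anchor's contribution (per-offset anchor counts are tracked),
#' so anchors near masks do not bias the mean.
#'
#' @param counts a [strand_counts()].
#' @param anchors oriented-site tibble `(replicon, position, strand, width)`
#'   (strand `"*"` is treated as `"+"`; `width` defaults to 1).
#' @param half_width window half-width in bp (default 50 kb).
#' @param smoothing moving-average window in bp (default 400; effective span
#'   is forced odd so the profile commutes with orientation flips).
#' @param masks optional mask tibble `(replicon, start, end)`.
#' @return object of class `metaplot`: tibble
#'   `(offset, F, R, F_raw, R_raw, n_F, n_R)` with RPKM densities (`F`/`R`
#'   smoothed) and attributes recording the parameters.
#' @export
anchored_profile <- function(counts, anchors, half_width = 50000L,
                             smoothing = 400L, masks = NULL) {
  anchors <- tibble::as_tibble(anchors)
  stopifnot(nrow(anchors) > 0)
  offs <- seq.int(-half_width, half_width)
  noff <- length(offs)
  sum_f <- numeric(noff); sum_r <- numeric(noff)
  n_f <- numeric(noff); n_r <- numeric(noff)
  refs <- anchor_ref(anchors)
  used <- 0L
  for (r in unique(anchors$replicon)) {
    L <- counts$replicons$length[match(r, counts$replicons$name)]
    circ <- counts$replicons$circular[match(r, counts$replicons$name)]
    plus <- counts$counts[[r]]$plus
    minus <- counts$counts[[r]]$minus
    mv <- mask_vector(masks, r, L)
    sel <- which(anchors$replicon == r)
    for (i in sel) {
      st <- anchors$strand[i]
      dir <- if (st == "-") -1L else 1L
      pos <- refs[i] + dir * offs
      if (circ) {
        pos <- wrap0(pos, L)
        ok <- !mv[pos + 1L]
      } else {
        inb <- pos >= 0L & pos < L
        ok <- inb & !mv[pmax(pos, 0L) %% L + 1L]
        pos <- wrap0(pos, L)  # safe index; excluded via ok
      }
      co <- if (st == "-") minus else plus
      op <- if (st == "-") plus else minus
      vf <- co[pos + 1L]; vr <- op[pos + 1L]
      sum_f[ok] <- sum_f[ok] + vf[ok]
      sum_r[ok] <- sum_r[ok] + vr[ok]
      n_f[ok] <- n_f[ok] + 1
      n_r[ok] <- n_r[ok] + 1
      used <- used + 1L
    }
  }
  if (used == 0) stop("all anchors masked or outside the counted replicons")
  scale <- 1e9 / counts$total_aligned  # per-base RPKM
  f_raw <- ifelse(n_f > 0, sum_f / n_f, NA_real_) * scale
  r_raw <- ifelse(n_r > 0, sum_r / n_r, NA_real_) * scale
  out <- tibble::tibble(
    offset = offs,
    F = moving_average(f_raw, smoothing),
    R = moving_average(r_raw, smoothing),
    F_raw = f_raw, R_raw = r_raw, n_F = n_f, n_R = n_r
  )
  structure(out, class = c("metaplot", class(out)),
            smoothing = smoothing, half_width = half_width,
            n_anchors = used, total_aligned = counts$total_aligned)
}

#' Background-normalize a Chi metaplot and compute the drop statistic
#'
#' The background is the mean smoothed co-oriented (F) density over the two
#' remote flanks (`-flank[2]` to `-flank[1]` and `+flank[1]` to `+flank[2]`
#' from the anchor). The normalized profile is `F / background`; the drop
#' statistic is `(1 - min(normalized)) * 100` with the minimum taken within
#' `+/- drop_window` of the anchor — the percent decrease of Chi-proximal
#' smDNA density relative to remote background. Negative drops mean density
#' rises at the anchor.
#'
#' @param profile a [anchored_profile()] result.
#' @param flank numeric length-2: inner and outer flank bounds in bp
#'   (default `c(35000, 50000)`).
#' @param drop_window half-width around the anchor searched for the minimum
#'   (default 2000 bp).
#' @return object of class `chi_drop`: list with `profile` (tibble
#'   `offset, relative_density`), `background` (RPKM), `drop_percent`, and
#'   the parameters.
#' @export
normalize_and_drop <- function(profile, flank = c(35000L, 50000L),
                               drop_window = 2000L) {
  stopifnot(inherits(profile, "metaplot"), length(flank) == 2,
            flank[1] < flank[2])
  if (attr(profile, "half_width") < flank[2]) {
    stop("profile half_width is smaller than the outer flank bound")
  }
  ao <- abs(profile$offset)
  in_flank <- ao >= flank[1] & ao <= flank[2]
  background <- mean(profile$F[in_flank], na.rm = TRUE)
  if (!is.finite(background) || background <= 0) stop("background is zero")
  rel <- profile$F / background
  near <- ao <= drop_window
  drop_percent <- (1 - min(rel[near], na.rm = TRUE)) * 100
  structure(
    list(profile = tibble::tibble(offset = profile$offset,
                                  relative_density = rel),
         background = background, drop_percent = drop_percent,
         flank = flank, drop_window = drop_window,
         n_anchors = attr(profile, "n_anchors")),
    class = "chi_drop"
  )
}

#' @export
print.chi_drop <- function(x, ...) {
  cat("<chi_drop> background ", signif(x$background, 4), " RPKM, drop ",
      sprintf("%.1f%%", x$drop_percent), " (", x$n_anchors, " anchors)\n",
      sep = "")
  invisible(x)
}

#' Classify Chi sites by the presence of an adjacent downstream GCS
#'
#' A Chi site is `downstream_gcs` when some GCS lies on its 3' side with no
#' co-oriented Chi site strictly between them (i.e. the Chi is the nearest
#' co-oriented stop signal upstream of that cleavage site); all remaining
#' sites are `other`. The complementary `upstream_gcs` flag (a GCS on the 5'
#' side before the nearest co-oriented Chi — the inactive orientation) is
#' also emitted. A GCS exactly equidistant with a co-oriented Chi resolves
#' toward the GCS.
#'
#' @param chi oriented Chi-site tibble `(replicon, position, strand, width)`.
#' @param gcs GCS tibble `(replicon, position, ...)`; strand is ignored.
#' @param chromosome_length replicon length in bp.
#' @param circular logical (default `TRUE`).
#' @return `chi` with added `class` (`downstream_gcs` / `other`),
#'   `gcs_distance` (bp to the nearest 3'-side GCS, `NA` if none) and
#'   `upstream_gcs` columns.
#' @export
classify_chi_gcs <- function(chi, gcs, chromosome_length, circular = TRUE) {
  L <- chromosome_length
  chi <- tibble::as_tibble(chi)
  refs <- anchor_ref(chi)
  gp <- gcs$position
  res <- purrr::map_dfr(seq_len(nrow(chi)), function(i) {
    dir <- if (chi$strand[i] == "-") -1L else 1L
    co <- refs[chi$strand == chi$strand[i]]
    co <- co[co != refs[i]]
    dist_along <- function(x, sign) {
      d <- ((x - refs[i]) * sign * dir)
      d <- if (circular) wrap0(d, L) else d
      d[d > 0]
    }
    down_gcs <- dist_along(gp, 1L)
    down_chi <- dist_along(co, 1L)
    up_gcs <- dist_along(gp, -1L)
    up_chi <- dist_along(co, -1L)
    nearest <- function(v) if (length(v) == 0) Inf else min(v)
    tibble::tibble(
      class = if (nearest(down_gcs) <= nearest(down_chi) &&
                  is.finite(nearest(down_gcs))) "downstream_gcs" else "other",
      gcs_distance = if (is.finite(nearest(down_gcs))) nearest(down_gcs) else NA_real_,
      upstream_gcs = nearest(up_gcs) <= nearest(up_chi) &&
        is.finite(nearest(up_gcs))
    )
  })
  dplyr::bind_cols(chi, res)
}

#' Per-Chi-site +Cfx / control relative-density enrichment and group test
#'
#' For each Chi site, co-oriented-strand densities in the +Cfx and control
#' libraries are each converted to RPKM, smoothed with a centered moving
#' average, stabilized with a pseudocount equivalent to one read per
#' smoothing window, divided (+Cfx over control) and averaged over offsets
#' `span[1]` to `span[2]` on the 3' side of the Chi sequence. Per-site
#' enrichments are compared between the `downstream_gcs` and `other` classes
#' with a two-sided Welch (unequal-variance) t test, plus a seeded label
#' permutation test for robustness (made order-invariant by canonical
#' sorting, so it is unchanged by coordinate flips).
#'
#' @param counts_cfx,counts_ctrl [strand_counts()] of the two libraries
#'   (aligned to the same reference).
#' @param chi_classes output of [classify_chi_gcs()].
#' @param span offsets quantified, in bp from the Chi sequence (default
#'   `c(0, 5000)`).
#' @param smoothing moving-average window in bp (default 1000).
#' @param masks optional mask tibble; masked offsets are excluded from each
#'   site's mean.
#' @param n_perm permutation count (0 to skip; default 10000).
#' @param perm_seed seed for the permutation stream.
#' @return object of class `enrichment_result`: list with `per_site`
#'   (tibble of per-site enrichments and classes), `summary` (group means,
#'   SD, n), `t_statistic`, `p_value`, `p_permutation` and parameters.
#' @export
relative_density_enrichment <- function(counts_cfx, counts_ctrl, chi_classes,
                                        span = c(0L, 5000L), smoothing = 1000L,
                                        masks = NULL, n_perm = 10000L,
                                        perm_seed = 1L) {
  stopifnot(nrow(chi_classes) > 0)
  refs <- anchor_ref(chi_classes)
  pad <- smoothing  # context so the moving average is clean inside the span
  offs <- seq.int(span[1] - pad, span[2] + pad)
  in_span <- offs >= span[1] & offs <= span[2]
  scale_cfx <- 1e9 / counts_cfx$total_aligned
  scale_ctrl <- 1e9 / counts_ctrl$total_aligned
  ps_cfx <- scale_cfx / smoothing   # 1 read per smoothing window, in RPKM
  ps_ctrl <- scale_ctrl / smoothing
  enr <- purrr::map_dbl(seq_len(nrow(chi_classes)), function(i) {
    r <- chi_classes$replicon[i]
    L <- counts_cfx$replicons$length[match(r, counts_cfx$replicons$name)]
    circ <- counts_cfx$replicons$circular[match(r, counts_cfx$replicons$name)]
    dir <- if (chi_classes$strand[i] == "-") -1L else 1L
    pos <- refs[i] + dir * offs
    if (circ) pos <- wrap0(pos, L)
    sl <- if (chi_classes$strand[i] == "-") "minus" else "plus"
    v_cfx <- extract_at(counts_cfx$counts[[r]][[sl]], pos, circular = circ)
    v_ctrl <- extract_at(counts_ctrl$counts[[r]][[sl]], pos, circular = circ)
    mv <- mask_vector(masks, r, L)
    inb <- circ | (pos >= 0L & pos < L)
    keep <- inb & !mv[wrap0(pos, L) + 1L]
    v_cfx[!keep] <- NA; v_ctrl[!keep] <- NA
    num <- moving_average(v_cfx * scale_cfx, smoothing) + ps_cfx
    den <- moving_average(v_ctrl * scale_ctrl, smoothing) + ps_ctrl
    mean((num / den)[in_span], na.rm = TRUE)
  })
  per_site <- dplyr::mutate(chi_classes, enrichment = enr)
  per_site <- per_site[is.finite(per_site$enrichment), ]
  summary <- per_site |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$enrichment),
                     sd = stats::sd(.data$enrichment), .groups = "drop")
  g1 <- per_site$enrichment[per_site$class == "downstream_gcs"]
  g2 <- per_site$enrichment[per_site$class == "other"]
  t_stat <- NA_real_; p_val <- NA_real_; p_perm <- NA_real_
  if (length(g1) < 2 || length(g2) < 2) {
    warning("a class has fewer than 2 sites; group test skipped")
  } else if (stats::sd(g1) == 0 && stats::sd(g2) == 0) {
    # degenerate but well-defined: identical constant groups are maximally
    # non-significant
    t_stat <- if (mean(g1) == mean(g2)) 0 else Inf
    p_val <- if (mean(g1) == mean(g2)) 1 else 0
    p_perm <- p_val
  } else {
    tt <- stats::t.test(g1, g2, var.equal = FALSE, alternative = "two.sided")
    t_stat <- unname(tt$statistic)
    p_val <- tt$p.value
    if (n_perm > 0) {
      vals <- c(g1, g2)
      labs <- rep(c(TRUE, FALSE), c(length(g1), length(g2)))
      o <- order(vals, labs)  # canonical order: invariant to site ordering
      vals <- vals[o]; labs <- labs[o]
      obs <- abs(mean(vals[labs]) - mean(vals[!labs]))
      p_perm <- withr::with_seed(perm_seed, {
        exceed <- sum(vapply(seq_len(n_perm), function(k) {
          sh <- sample(labs)
          abs(mean(vals[sh]) - mean(vals[!sh])) >= obs
        }, logical(1)))
        (1 + exceed) / (n_perm + 1)
      })
    }
  }
  structure(
    list(per_site = per_site, summary = summary, t_statistic = t_stat,
         p_value = p_val, p_permutation = p_perm, span = span,
         smoothing = smoothing, n_perm = n_perm),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result> Welch t = ", signif(x$t_statistic, 4),
      ", p = ", signif(x$p_value, 3), sep = "")
  if (!is.na(x$p_permutation)) {
    cat(" (permutation p = ", signif(x$p_permutation, 3), ")", sep = "")
  }
  cat("\n")
  print(x$summary)
  invisible(x)
}

#' @rdname relative_density_enrichment
#' @param x an `enrichment_result`.
#' @param ... unused.
#' @return `tidy()`: the per-site enrichment tibble. `glance()`: one-row
#'   tibble with group means, t statistic and p values.
#' @export
tidy.enrichment_result <- function(x, ...) x$per_site

#' @rdname relative_density_enrichment
#' @export
glance.enrichment_result <- function(x, ...) {
  s <- x$summary
  pick <- function(cl, col) {
    v <- s[[col]][s$class == cl]
    if (length(v) == 0) NA_real_ else v
  }
  tibble::tibble(
    mean_downstream_gcs = pick("downstream_gcs", "mean"),
    sd_downstream_gcs = pick("downstream_gcs", "sd"),
    n_downstream_gcs = pick("downstream_gcs", "n"),
    mean_other = pick("other", "mean"),
    sd_other = pick("other", "sd"),
    n_other = pick("other", "n"),
    t_statistic = x$t_statistic, p_value = x$p_value,
    p_permutation = x$p_permutation
  )
}

#' @rdname normalize_and_drop
#' @param x a `chi_drop`.
#' @param ... unused.
#' @return `glance()`: one-row tibble with background, drop percent and
#'   anchor count.
#' @export
glance.chi_drop <- function(x, ...) {
  tibble::tibble(background_rpkm = x$background,
                 drop_percent = x$drop_percent, n_anchors = x$n_anchors)
}
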