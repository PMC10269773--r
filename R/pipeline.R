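# Pipeline orchestration: simulate -> align -> profile -> chi -> compose ->
# report, driven by one YAML (or list) config, with a manifest recording
# parameters, checksums and row counts so identical runs are reproducible
# and stale intermediates are detected. The package's functions are the
# primary interface; a thin command-line wrapper around run_pipeline() ships
# in inst/scripts/smdna-pipeline.R.

PIPELINE_STAGES <- c("simulate", "align", "profile", "chi", "compose", "report")

#' Default pipeline configuration
#'
#' @param seed integer seed forwarded to the simulator.
#' @return nested list with one section per stage; any entry can be
#'   overridden in a user YAML.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    simulate = list(seed = seed, n_reads = 5e4, genome_length = 2e5,
                    gc_fraction = 0.51, chi_count = 12L, gcs_count = 6L,
                    ter_chi_distance = c(8000L, 12000L), ter = NULL),
    align = list(multimappers = "first"),
    profile = list(window = 20000L, step = 5000L, pseudocount = 1),
    chi = list(half_width = 50000L, smoothing = 400L,
               flank = c(35000L, 50000L), drop_window = 2000L,
               enrichment_span = c(0L, 5000L), enrichment_smoothing = 1000L,
               n_perm = 2000L),
    compose = list(flank = 20L)
  )
}

read_pipeline_config <- function(config, seed = 1L) {
  base <- default_pipeline_config(seed)
  user <- if (is.character(config)) yaml::read_yaml(config) else config
  stopifnot(is.list(user))
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) stop("unknown config section(s): ",
                            paste(unknown, collapse = ", "))
  for (sec in names(user)) {
    stopifnot(is.list(user[[sec]]))
    bad <- setdiff(names(user[[sec]]), names(base[[sec]]))
    if (length(bad)) stop("unknown key(s) in '", sec, "': ",
                          paste(bad, collapse = ", "))
    base[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  base
}

config_checksum <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(config, tf)
  unname(tools::md5sum(tf))
}

file_checksums <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Run the smDNA analysis pipeline
#'
#' Executes the requested stages in dependency order on a simulated +Cfx /
#' control library pair: `simulate` writes the reference and both FASTQ
#' libraries, `align` trims/filters/aligns them and exports strand counts as
#' bedGraph, `profile` computes windowed RPKM, ter fractions, the strand
#' ratio-of-ratios profile and plasmid enrichment, `chi` computes the Chi
#' metaplot, normalized drop, Chi/GCS classes and the enrichment test,
#' `compose` the read-composition summaries, and `report` a machine-readable
#' JSON summary of everything. Stages whose outputs exist with matching
#' manifest checksums are reused; requesting a stage whose inputs are absent
#' is an error naming the missing dependency.
#'
#' @param config a YAML file path or nested list (see
#'   [default_pipeline_config()]).
#' @param out_dir output directory (created).
#' @param stages subset of stages to run (dependencies must already exist).
#' @return the run manifest (invisibly a list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config = list(), out_dir,
                         stages = PIPELINE_STAGES) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- read_pipeline_config(config, seed = 1L)
  gcfg <- do.call(generative_config, cfg$simulate[!vapply(cfg$simulate, is.null, TRUE)])
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else list()
  manifest$config_checksum <- config_checksum(cfg)
  manifest$seed <- gcfg$seed
  manifest$package_version <- as.character(utils::packageVersion("smdnaseq"))
  manifest$parameters <- cfg[c("align", "profile", "chi", "compose")]
  state <- new.env(parent = emptyenv())

  need <- function(paths, stage, wanted_by) {
    miss <- paths[!file.exists(paths)]
    if (length(miss)) {
      stop("stage '", wanted_by, "' needs output of stage '", stage,
           "'; missing: ", paste(basename(miss), collapse = ", "),
           "\nrun stages = c(\"", stage, "\", ...) first")
    }
  }
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, paste(..., collapse = " ")))
  }
  sim_paths <- file.path(out_dir, c("ref.fa", "ctrl.fastq", "cfx.fastq"))
  counts_prefix <- function(lib) file.path(out_dir, paste0("counts_", lib))
  counts_paths <- function(lib) paste0(counts_prefix(lib),
                                       c(".plus.bedgraph", ".minus.bedgraph",
                                         ".totals.json"))

  load_bundle <- function() {
    if (is.null(state$sim)) {
      state$sim <- build_reference(gcfg)  # deterministic from config seed
    }
    state$sim$bundle
  }

  if ("simulate" %in% stages) {
    pair <- simulate_pair(gcfg, out_dir = out_dir)
    state$sim <- list(bundle = pair$bundle, truth = pair$truth)
    sites_tsv <- function(df, f) readr::write_tsv(df, file.path(out_dir, f))
    sites_tsv(pair$bundle$chi, "chi_sites.tsv")
    sites_tsv(pair$bundle$gcs, "gcs_sites.tsv")
    sites_tsv(pair$bundle$ter_sites, "ter_sites.tsv")
    sites_tsv(pair$bundle$masks, "masks.tsv")
    manifest$stages$simulate <- list(
      outputs = file_checksums(sim_paths),
      n_reads = gcfg$n_reads, genome_length = gcfg$genome_length)
    log_stage("simulate", gcfg$n_reads, "reads per library,",
              gcfg$genome_length, "bp genome")
  }

  if ("align" %in% stages) {
    need(sim_paths, "simulate", "align")
    bundle <- load_bundle()
    for (lib in c("ctrl", "cfx")) {
      rs <- preprocess_reads(file.path(out_dir, paste0(lib, ".fastq")),
                             adapter = gcfg$adapter)
      al <- align_exact(rs, bundle, multimappers = cfg$align$multimappers)
      write_strand_counts(al$counts, counts_prefix(lib))
      readr::write_tsv(al$alignments,
                       file.path(out_dir, paste0("alignments_", lib, ".tsv")))
      state[[paste0("counts_", lib)]] <- al$counts
      state[[paste0("aln_", lib)]] <- al$alignments
      state[[paste0("reads_", lib)]] <- rs
      manifest$stages$align[[lib]] <- list(
        reads_in = rs$log$n_input, trimmed = rs$log$n_trimmed,
        filtered = rs$log$n_discarded, aligned = al$log$n_aligned,
        unaligned = al$log$n_unaligned,
        outputs = file_checksums(counts_paths(lib)))
      log_stage("align", lib, ":", rs$log$n_input, "in,",
                al$log$n_aligned, "aligned")
    }
  }

  get_counts <- function(lib) {
    key <- paste0("counts_", lib)
    if (is.null(state[[key]])) {
      need(counts_paths(lib), "align", "downstream")
      state[[key]] <- read_strand_counts(counts_prefix(lib))
    }
    state[[key]]
  }

  if ("profile" %in% stages) {
    bundle <- load_bundle()
    ctrl <- get_counts("ctrl"); cfxc <- get_counts("cfx")
    tf <- dplyr::bind_rows(
      ctrl = ter_fraction(ctrl, bundle$ter_sites),
      cfx = ter_fraction(cfxc, bundle$ter_sites), .id = "library")
    readr::write_tsv(tf, file.path(out_dir, "ter_fractions.tsv"))
    rp <- strand_ratio_profile(cfxc, ctrl, window = cfg$profile$window,
                               step = cfg$profile$step,
                               pseudocount = cfg$profile$pseudocount)
    readr::write_tsv(rp, file.path(out_dir, "strand_ratio_profile.tsv"))
    rw <- dplyr::bind_rows(ctrl = rpkm_windows(ctrl),
                           cfx = rpkm_windows(cfxc), .id = "library")
    readr::write_tsv(rw, file.path(out_dir, "rpkm_windows.tsv"))
    pe <- dplyr::bind_rows(ctrl = plasmid_enrichment(ctrl, bundle),
                           cfx = plasmid_enrichment(cfxc, bundle),
                           .id = "library")
    readr::write_tsv(pe, file.path(out_dir, "plasmid_enrichment.tsv"))
    manifest$stages$profile <- list(outputs = file_checksums(file.path(
      out_dir, c("ter_fractions.tsv", "strand_ratio_profile.tsv",
                 "rpkm_windows.tsv", "plasmid_enrichment.tsv"))))
    log_stage("profile", "ter fractions, strand ratios, plasmid enrichment")
  }

  if ("chi" %in% stages) {
    bundle <- load_bundle()
    ctrl <- get_counts("ctrl"); cfxc <- get_counts("cfx")
    L <- replicon_length(bundle, chromosome_name(bundle))
    chi_un <- unmasked_sites(bundle$chi, bundle$masks, L)
    hw <- min(cfg$chi$half_width, (L - 1) %/% 2)
    mp <- purrr::map(list(ctrl = ctrl, cfx = cfxc), anchored_profile,
                     anchors = chi_un, half_width = hw,
                     smoothing = cfg$chi$smoothing, masks = bundle$masks)
    for (lib in names(mp)) {
      readr::write_tsv(tibble::as_tibble(mp[[lib]]),
                       file.path(out_dir, paste0("chi_metaplot_", lib, ".tsv")))
    }
    drops <- purrr::map(mp, normalize_and_drop,
                        flank = pmin(cfg$chi$flank, hw),
                        drop_window = cfg$chi$drop_window)
    readr::write_tsv(
      dplyr::bind_rows(purrr::map(drops, glance), .id = "library"),
      file.path(out_dir, "chi_drop.tsv"))
    cls <- classify_chi_gcs(chi_un, bundle$gcs, L)
    readr::write_tsv(cls, file.path(out_dir, "chi_classes.tsv"))
    write_sites_bed(cls, file.path(out_dir, "chi_classes.bed"))
    enr <- relative_density_enrichment(
      cfxc, ctrl, cls, span = cfg$chi$enrichment_span,
      smoothing = cfg$chi$enrichment_smoothing, masks = bundle$masks,
      n_perm = cfg$chi$n_perm, perm_seed = gcfg$seed)
    readr::write_tsv(tidy(enr), file.path(out_dir, "chi_enrichment_sites.tsv"))
    readr::write_tsv(glance(enr), file.path(out_dir, "chi_enrichment_test.tsv"))
    state$drops <- drops; state$enr <- enr
    manifest$stages$chi <- list(
      n_anchors = nrow(chi_un),
      outputs = file_checksums(file.path(out_dir, c(
        "chi_metaplot_ctrl.tsv", "chi_metaplot_cfx.tsv", "chi_drop.tsv",
        "chi_classes.tsv", "chi_enrichment_sites.tsv",
        "chi_enrichment_test.tsv"))))
    log_stage("chi", nrow(chi_un), "anchors; drop(ctrl) =",
              sprintf("%.1f%%", drops$ctrl$drop_percent))
  }

  if ("compose" %in% stages) {
    need(sim_paths, "simulate", "compose")
    bundle <- load_bundle()
    for (lib in c("ctrl", "cfx")) {
      rs <- state[[paste0("reads_", lib)]]
      if (is.null(rs)) {
        rs <- preprocess_reads(file.path(out_dir, paste0(lib, ".fastq")),
                               adapter = gcfg$adapter)
      }
      aln <- state[[paste0("aln_", lib)]]
      if (is.null(aln)) {
        p <- file.path(out_dir, paste0("alignments_", lib, ".tsv"))
        need(p, "align", "compose")
        aln <- readr::read_tsv(p, show_col_types = FALSE)
      }
      readr::write_tsv(length_histogram(rs),
                       file.path(out_dir, paste0("length_histogram_", lib, ".tsv")))
      write_pwm(logo_matrix(rs), file.path(out_dir, paste0("logo_", lib, ".tsv")))
      gp <- gc_profile(aln, bundle, flank = cfg$compose$flank)
      gp$genome_mean_gc <- attr(gp, "genome_mean_gc")
      readr::write_tsv(gp, file.path(out_dir, paste0("gc_profile_", lib, ".tsv")))
    }
    manifest$stages$compose <- list(outputs = file_checksums(file.path(
      out_dir, paste0(rep(c("length_histogram_", "logo_", "gc_profile_"), 2),
                      rep(c("ctrl", "cfx"), each = 3), ".tsv"))))
    log_stage("compose", "length histograms, logos, GC profiles")
  }

  if ("report" %in% stages) {
    manifest$stages$report <- list(path = "summary.json")
    write_summary(out_dir)
    log_stage("report", "summary.json")
  }

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Drop sites whose footprint overlaps a mask interval
#'
#' A site is masked when any base of its motif window overlaps a mask.
#'
#' @param sites oriented-site tibble `(replicon, position, strand, width)`.
#' @param masks mask tibble `(replicon, start, end)`.
#' @return the unmasked subset of `sites`.
#' @export
filter_masked_sites <- function(sites, masks) {
  if (is.null(masks) || nrow(masks) == 0 || nrow(sites) == 0) return(sites)
  keep <- purrr::map_lgl(seq_len(nrow(sites)), function(i) {
    w <- (sites$width %||% rep(1L, nrow(sites)))[i]
    mv <- masks[masks$replicon == sites$replicon[i], ]
    p <- sites$position[i]
    !any(mv$start < p + w & mv$end > p)
  })
  sites[keep, ]
}

unmasked_sites <- function(sites, masks, L) filter_masked_sites(sites, masks)

#' Collect pipeline outputs into one JSON report
#'
#' Reads the TSV outputs already present in `out_dir` and writes
#' `summary.json` containing ter fractions, plasmid enrichment, drop
#' statistics, Chi/GCS class sizes and the enrichment test results.
#'
#' @param out_dir a directory populated by [run_pipeline()].
#' @return the summary (invisibly).
#' @export
write_summary <- function(out_dir) {
  grab <- function(f) {
    p <- file.path(out_dir, f)
    if (!file.exists(p)) stop("write_summary: missing '", f,
                              "'; run the producing stage first")
    readr::read_tsv(p, show_col_types = FALSE)
  }
  cls <- grab("chi_classes.tsv")
  summary <- list(
    ter_fractions = grab("ter_fractions.tsv"),
    plasmid_enrichment = grab("plasmid_enrichment.tsv"),
    chi_drop = grab("chi_drop.tsv"),
    chi_class_sizes = dplyr::count(cls, .data$class),
    enrichment_test = grab("chi_enrichment_test.tsv")
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
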