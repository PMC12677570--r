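# Seeded synthetic cohorts with planted regional signal.
#
# Window counts are Poisson with a multiplicative class effect on each
# class's planted windows and a lognormal per-sample exposure factor, the
# simplest generative structure that reproduces (i) class-discriminative
# density profiles and (ii) the broad tumor-mutational-burden heterogeneity
# seen across real WGS cohorts.

#' Synthetic cohort configuration
#'
#' Defaults mirror a six-type benchmark cohort at desk scale: 6 classes of
#' 20 samples over 400 windows, baseline 5 expected mutations per window,
#' 30 disjoint planted windows per class boosted 3-fold, and lognormal
#' exposure spread 0.3.
#'
#' @param classes Class labels.
#' @param samples_per_class Samples per class.
#' @param n_windows Number of 1 Mbp windows in the toy genome.
#' @param baseline_rate Expected mutations per window (lambda0).
#' @param planted_per_class Planted windows per class when `planted_map` is
#'   not given.
#' @param planted_map Optional named list class -> 0-based window indices;
#'   overlapping sets are allowed (shared regions) but warned about.
#' @param effect_multiplier Rate multiplier phi (> 1) on a class's planted
#'   windows.
#' @param exposure_sigma Lognormal sd of the per-sample exposure factor.
#' @param seed Generator seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(classes = c("ME", "MM", "RK", "CRC", "GBM",
                                         "ESO"),
                             samples_per_class = 20L, n_windows = 400L,
                             baseline_rate = 5, planted_per_class = 30L,
                             planted_map = NULL, effect_multiplier = 3,
                             exposure_sigma = 0.3, seed = 1L) {
  stopifnot(length(classes) >= 2, is_count(samples_per_class),
            is_count(n_windows), baseline_rate > 0, effect_multiplier >= 1,
            exposure_sigma >= 0)
  if (!is.null(planted_map)) {
    idx <- unlist(planted_map)
    stopifnot(all(idx >= 0), all(idx < n_windows))
    if (anyDuplicated(idx)) warnf("planted sets overlap (shared regions)")
  }
  structure(list(classes = classes,
                 samples_per_class = as.integer(samples_per_class),
                 n_windows = as.integer(n_windows),
                 baseline_rate = baseline_rate,
                 planted_per_class = as.integer(planted_per_class),
                 planted_map = planted_map,
                 effect_multiplier = effect_multiplier,
                 exposure_sigma = exposure_sigma, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Toy window catalogue: n_windows aligned 1 Mbp windows spread over
# chromosomes of 100 windows each, named chr1, chr2, ...
synthetic_window_set <- function(n_windows, window_size = 1e6,
                                 windows_per_chrom = 100L) {
  n_chrom <- ceiling(n_windows / windows_per_chrom)
  chrom <- character(0); start <- numeric(0)
  for (ci in seq_len(n_chrom)) {
    k <- min(windows_per_chrom, n_windows - (ci - 1L) * windows_per_chrom)
    chrom <- c(chrom, rep(paste0("chr", ci), k))
    start <- c(start, (seq_len(k) - 1) * window_size)
  }
  out <- data.frame(chrom = chrom, start = start, end = start + window_size,
                    index = seq_len(n_windows) - 1L, stringsAsFactors = FALSE)
  attr(out, "window_size") <- window_size
  class(out) <- c("window_set", "data.frame")
  out
}

#' Generate a synthetic cohort with planted regional signal
#'
#' `count[i, w] ~ Poisson(e_i * lambda0 * phi^[w planted for class(i)])`
#' with `e_i ~ LogNormal(0, exposure_sigma)`.  When no planted map is given,
#' disjoint planted sets are drawn by a seeded shuffle of the window
#' indices.
#'
#' @param cfg A [synthetic_config()].
#' @return List: `fm` (a `feature_matrix` of raw counts), `truth` (planted
#'   map, exposures, window set, config, seed), both reproducible from
#'   (config, seed).
#' @export
generate_cohort <- function(cfg = synthetic_config()) {
  classes <- cfg$classes
  n_class <- length(classes)
  planted <- cfg$planted_map
  if (is.null(planted)) {
    need <- n_class * cfg$planted_per_class
    if (need > cfg$n_windows) stopf("planted sets exceed window count")
    shuffled <- with_seed(derive_seed(cfg$seed, "planted"),
                          sample.int(cfg$n_windows)) - 1L
    planted <- lapply(seq_len(n_class), function(ci) {
      sort(shuffled[((ci - 1L) * cfg$planted_per_class + 1L):
                      (ci * cfg$planted_per_class)])
    })
    names(planted) <- classes
  }
  n <- n_class * cfg$samples_per_class
  sample_ids <- sprintf("S%03d", seq_len(n))
  labels <- setNames(rep(classes, each = cfg$samples_per_class), sample_ids)
  exposures <- with_seed(derive_seed(cfg$seed, "exposure"),
                         exp(rnorm(n, 0, cfg$exposure_sigma)))
  names(exposures) <- sample_ids
  counts <- matrix(0, n, cfg$n_windows,
                   dimnames = list(sample_ids,
                                   paste0("w", seq_len(cfg$n_windows) - 1L)))
  mult <- matrix(1, n_class, cfg$n_windows, dimnames = list(classes, NULL))
  for (cl in classes) mult[cl, planted[[cl]] + 1L] <- cfg$effect_multiplier
  with_seed(derive_seed(cfg$seed, "counts"), {
    for (i in seq_len(n)) {
      lambda <- exposures[i] * cfg$baseline_rate * mult[labels[i], ]
      counts[i, ] <- rpois(cfg$n_windows, lambda)
    }
  })
  fm <- assemble_feature_matrix(counts, labels)
  truth <- structure(list(planted_map = planted, exposures = exposures,
                          window_set = synthetic_window_set(cfg$n_windows),
                          config = cfg, seed = cfg$seed),
                     class = "truth_set")
  list(fm = fm, truth = truth)
}

#' Materialize a synthetic cohort as variant files on disk
#'
#' Every window count becomes that many variant records at uniformly drawn
#' 1-based positions inside the window, with distinct ref/alt bases.
#' Re-binning the written files through [bin_mutation_density()] reproduces
#' the count matrix exactly.
#'
#' @param cohort Output of [generate_cohort()].
#' @param out_dir Output directory (created if absent).
#' @return Invisible list of written paths: `variants` (per-sample TSVs),
#'   `labels`, `windows`, `truth`.
#' @export
write_cohort_files <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stopf("cannot create directory %s", out_dir)
  fm <- cohort$fm
  truth <- cohort$truth
  ws <- truth$window_set
  bases <- c("A", "C", "G", "T")
  paths <- character(0)
  with_seed(derive_seed(truth$seed, "positions"), {
    for (sid in rownames(fm$x)) {
      counts <- fm$x[sid, seq_len(truth$config$n_windows)]
      rows <- list()
      for (w in which(counts > 0)) {
        k <- counts[w]
        pos <- ws$start[w] + sample.int(ws$end[w] - ws$start[w], k,
                                        replace = TRUE)
        ref <- sample(bases, k, replace = TRUE)
        shift <- sample.int(3, k, replace = TRUE)
        alt <- bases[(match(ref, bases) - 1L + shift) %% 4L + 1L]
        rows[[length(rows) + 1L]] <-
          data.frame(chrom = ws$chrom[w], pos = pos, ref = ref, alt = alt,
                     stringsAsFactors = FALSE)
      }
      df <- if (length(rows)) do.call(rbind, rows) else {
        data.frame(chrom = character(), pos = numeric(), ref = character(),
                   alt = character(), stringsAsFactors = FALSE)
      }
      path <- file.path(out_dir, paste0(sid, ".tsv"))
      write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, path)
    }
  })
  labels_path <- file.path(out_dir, "labels.tsv")
  write.table(data.frame(sample_id = rownames(fm$x),
                         class = as.character(fm$labels)),
              labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  windows_path <- file.path(out_dir, "windows.bed")
  write_window_bed(ws, windows_path)
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(list(planted_map = truth$planted_map,
                            exposures = as.list(truth$exposures),
                            seed = truth$seed),
                       truth_path, digits = NA, auto_unbox = TRUE)
  invisible(list(variants = paths, labels = labels_path,
                 windows = windows_path, truth = truth_path))
}

#' Read a cohort written by [write_cohort_files()]
#'
#' @param dir Directory containing per-sample variant TSVs, `labels.tsv`
#'   and `windows.bed`.
#' @param normalization Density normalization (see
#'   [bin_mutation_density()]).
#' @return A `feature_matrix`.
#' @export
read_cohort_files <- function(dir, normalization = "raw") {
  labels_df <- read.table(file.path(dir, "labels.tsv"), sep = "\t",
                          header = TRUE, colClasses = "character")
  labels <- setNames(labels_df$class, labels_df$sample_id)
  ws <- read_window_bed(file.path(dir, "windows.bed"))
  profiles <- lapply(labels_df$sample_id, function(sid) {
    vs <- read_variants(file.path(dir, paste0(sid, ".tsv")), sid)
    bin_mutation_density(vs, ws, normalization)
  })
  names(profiles) <- labels_df$sample_id
  assemble_feature_matrix(profiles, labels)
}

#' Generate chromatin fixture tracks over the toy genome
#'
#' A configurable number of informative tracks correlate (strength `rho`)
#' with the planted-window indicator of a target class, cycling through the
#' classes; the remainder are pure Gaussian noise.  Track window values are
#' constant within windows, so binning reproduces them exactly.
#'
#' @param truth A `truth_set` from [generate_cohort()].
#' @param n_tracks Total number of tracks.
#' @param n_informative How many tracks carry planted-indicator signal.
#' @param rho Correlation strength in `[0, 1]`.
#' @param seed Seed (default: derived from the cohort seed).
#' @return Named list of `interval_track`s; attribute `info` is a
#'   data.frame with `track_id`, `informative`, `target_class`.
#' @export
generate_chromatin_fixture <- function(truth, n_tracks, n_informative = 0L,
                                       rho = 0.8, seed = NULL) {
  stopifnot(n_tracks >= 1, n_informative <= n_tracks, rho >= 0, rho <= 1)
  ws <- truth$window_set
  W <- nrow(ws)
  classes <- names(truth$planted_map)
  if (is.null(seed)) seed <- derive_seed(truth$seed, "chromatin")
  tracks <- list()
  info <- data.frame(track_id = character(), informative = logical(),
                     target_class = character(), stringsAsFactors = FALSE)
  for (t in seq_len(n_tracks)) {
    id <- sprintf("track%03d", t)
    informative <- t <= n_informative
    target <- if (informative) classes[(t - 1L) %% length(classes) + 1L] else
      NA_character_
    v <- with_seed(derive_seed(seed, "track", t), {
      noise <- rnorm(W)
      if (informative) {
        ind <- as.numeric((seq_len(W) - 1L) %in% truth$planted_map[[target]])
        ind_z <- (ind - mean(ind)) / sd(ind)
        rho * ind_z + sqrt(1 - rho^2) * noise
      } else {
        noise
      }
    })
    tracks[[id]] <- interval_track(ws$chrom, ws$start, ws$end, v)
    info <- rbind(info, data.frame(track_id = id, informative = informative,
                                   target_class = target,
                                   stringsAsFactors = FALSE))
  }
  attr(tracks, "info") <- info
  tracks
}
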