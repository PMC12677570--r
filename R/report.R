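# Report export and the command-line entry point.

#' Export sweep, ranking and occurrence results as TSV/BED
#'
#' Writes `accuracy.tsv` (rows = selection mode x size, columns = cancer
#' types), one `regions_<class>.bed` per class with the significant windows
#' (skipped with a warning when a class has none), and `occurrence.tsv`,
#' the heatmap-ready class-by-window occurrence matrix.
#'
#' @param sweep A `sweep_result` (or rbind of several modes), or `NULL`.
#' @param ranking A `region_ranking`, or `NULL`.
#' @param occurrence Matrix from [region_occurrence_frequency()], or `NULL`.
#' @param out_dir Output directory (created if absent).
#' @param window_set Optional `window_set` mapping ranked window indices to
#'   genomic coordinates for the BED export.
#' @return Invisible character vector of written paths.
#' @export
export_tables <- function(sweep = NULL, ranking = NULL, occurrence = NULL,
                          out_dir = ".", window_set = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  if (!is.null(sweep)) {
    classes <- sort(unique(sweep$class))
    keys <- unique(sweep[, c("mode", "size")])
    wide <- data.frame(selection = keys$mode, regions = keys$size)
    for (cl in classes) {
      wide[[cl]] <- vapply(seq_len(nrow(keys)), function(i) {
        v <- sweep$accuracy[sweep$mode == keys$mode[i] &
                              sweep$size == keys$size[i] &
                              sweep$class == cl]
        if (length(v)) round(v[1], 4) else NA_real_
      }, numeric(1))
    }
    path <- file.path(out_dir, "accuracy.tsv")
    write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, path)
  }
  if (!is.null(ranking)) {
    path <- file.path(out_dir, "ranking.tsv")
    write.table(as.data.frame(ranking), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    written <- c(written, path)
    if (!is.null(window_set)) {
      for (cl in unique(ranking$class)) {
        sub <- ranking[ranking$class == cl & ranking$significant, ,
                       drop = FALSE]
        if (!nrow(sub)) {
          warnf("no significant regions for %s; BED omitted", cl)
          next
        }
        m <- match(sub$window, window_set$index)
        bed <- data.frame(window_set$chrom[m],
                          format(window_set$start[m], scientific = FALSE,
                                 trim = TRUE),
                          format(window_set$end[m], scientific = FALSE,
                                 trim = TRUE),
                          sub$window)
        path <- file.path(out_dir, paste0("regions_", cl, ".bed"))
        write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE)
        written <- c(written, path)
      }
    }
  }
  if (!is.null(occurrence)) {
    path <- file.path(out_dir, "occurrence.tsv")
    write.table(data.frame(class = rownames(occurrence), occurrence,
                           check.names = FALSE),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, path)
  }
  invisible(written)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, seeds, input file digests, package
#' version and timestamp next to every set of artifacts so that runs are
#' auditable and reproducible.
#'
#' @param path Output JSON path.
#' @param config Named list of configuration values.
#' @param seed Integer seed of the run.
#' @param inputs Character vector of input file paths to digest.
#' @return Invisible path.
#' @export
write_run_manifest <- function(path, config, seed, inputs = character(0)) {
  digests <- if (length(inputs)) {
    as.list(tools::md5sum(inputs))
  } else {
    list()
  }
  payload <- list(tool = "regionboost",
                  version = as.character(utils::packageVersion("regionboost")),
                  seed = seed, config = config, input_digests = digests,
                  timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

cli_usage <- function() {
  paste(
    "usage: regionboost <command> [options]",
    "",
    "commands:",
    "  simulate        generate a synthetic cohort (--out DIR, --seed INT)",
    "  windows         build a window catalogue (--chrom-sizes FILE,",
    "                  --mappability FILE, --gc FILE, --out DIR)",
    "  profile         bin variants into a feature matrix (--variants DIR,",
    "                  --labels TSV, --windows BED, --out DIR)",
    "  select-regions  run subset trials + Fisher ranking (--variants DIR,",
    "                  --labels TSV, --windows BED, --sizes CSV,",
    "                  --repeats INT, --q-threshold FLOAT, --out DIR)",
    "  sweep           accuracy vs subset size (--mode MODE, --sizes CSV,",
    "                  --ranking TSV, ... as select-regions)",
    "  report          re-export tables from a select-regions output DIR",
    sep = "\n")
}

cli_parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stopf("unexpected argument: %s", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      flags[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  flags
}

cli_load_matrix <- function(flags, normalization = "raw") {
  if (is.null(flags$variants) || is.null(flags$labels) ||
      is.null(flags$windows)) {
    stopf("need --variants DIR, --labels TSV and --windows BED")
  }
  labels_df <- read.table(flags$labels, sep = "\t", header = TRUE,
                          colClasses = "character")
  labels <- setNames(labels_df$class, labels_df$sample_id)
  ws <- read_window_bed(flags$windows)
  profiles <- lapply(labels_df$sample_id, function(sid) {
    vs <- read_variants(file.path(flags$variants, paste0(sid, ".tsv")), sid)
    bin_mutation_density(vs, ws, normalization)
  })
  names(profiles) <- labels_df$sample_id
  list(fm = assemble_feature_matrix(profiles, labels), ws = ws)
}

#' Command-line pipeline entry point
#'
#' Dispatches the subcommands `simulate`, `windows`, `profile`,
#' `select-regions`, `sweep` and `report`; intended to be called from the
#' shipped `Rscript` wrapper (`system.file("cli", "regionboost",
#' package = "regionboost")`).
#'
#' @param args Character vector of command-line arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly (0 = success, 2 = usage error).
#' @export
run_pipeline <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message(cli_usage())
    return(invisible(2L))
  }
  command <- args[1]
  status <- tryCatch({
    flags <- cli_parse_flags(args[-1])
    seed <- as.integer(if (is.null(flags$seed)) 1L else flags$seed)
    out_dir <- if (is.null(flags$out)) "." else flags$out
    switch(command,
      simulate = {
        cfg <- synthetic_config(seed = seed)
        cohort <- generate_cohort(cfg)
        write_cohort_files(cohort, out_dir)
        write_run_manifest(file.path(out_dir, "manifest.json"),
                           unclass(cfg), seed)
        message(sprintf("wrote synthetic cohort (%d samples, %d windows) to %s",
                        nrow(cohort$fm$x), cfg$n_windows, out_dir))
        0L
      },
      windows = {
        if (is.null(flags[["chrom-sizes"]])) stopf("need --chrom-sizes FILE")
        sizes <- read_chrom_sizes(flags[["chrom-sizes"]])
        ws <- partition_autosomes(sizes)
        if (!is.null(flags$mappability) && !is.null(flags$gc)) {
          ws <- apply_window_filters(ws, read_interval_track(flags$mappability),
                                     read_interval_track(flags$gc))
        }
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        write_window_bed(ws, file.path(out_dir, "windows.bed"))
        message(sprintf("wrote %d windows", nrow(ws)))
        0L
      },
      profile = {
        loaded <- cli_load_matrix(flags)
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        path <- file.path(out_dir, "feature_matrix.tsv")
        write.table(data.frame(sample_id = rownames(loaded$fm$x),
                               class = as.character(loaded$fm$labels),
                               loaded$fm$x, check.names = FALSE),
                    path, sep = "\t", quote = FALSE, row.names = FALSE)
        message(sprintf("wrote %s", path))
        0L
      },
      `select-regions` = {
        loaded <- cli_load_matrix(flags)
        sizes <- if (is.null(flags$sizes)) c(25, 50, 100, 150, 200) else
          as.integer(strsplit(flags$sizes, ",")[[1]])
        repeats <- as.integer(if (is.null(flags$repeats)) 1000L else
          flags$repeats)
        qt <- as.numeric(if (is.null(flags[["q-threshold"]])) 0.05 else
          flags[["q-threshold"]])
        cfg <- selection_config(subset_sizes = sizes, repeats = repeats,
                                q_threshold = qt, seed = seed)
        ledger <- run_random_subset_trials(loaded$fm, cfg)
        ranking <- rank_informative_regions(ledger, cfg)
        occ <- region_occurrence_frequency(ledger)
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        write_trial_ledger(ledger, file.path(out_dir, "trials.tsv"))
        export_tables(ranking = ranking, occurrence = occ, out_dir = out_dir,
                      window_set = loaded$ws)
        write_run_manifest(file.path(out_dir, "manifest.json"),
                           unclass(cfg)[setdiff(names(cfg), "model_cfg")],
                           seed,
                           inputs = c(flags$labels, flags$windows))
        message(sprintf("ranked %d windows over %d trials",
                        length(ledger$window_cols), length(ledger$sizes)))
        0L
      },
      sweep = {
        loaded <- cli_load_matrix(flags)
        mode <- if (is.null(flags$mode)) "informative" else flags$mode
        sizes <- if (is.null(flags$sizes)) c(50, 100, 200, 300, 400, 500, 600)
          else as.integer(strsplit(flags$sizes, ",")[[1]])
        cfg <- selection_config(seed = seed)
        ranking <- NULL
        if (mode == "informative") {
          if (is.null(flags$ranking)) stopf("mode informative needs --ranking TSV")
          ranking <- read.table(flags$ranking, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
          class(ranking) <- c("region_ranking", "data.frame")
        }
        sw <- sweep_subset_sizes(loaded$fm, ranking, sizes, mode, cfg)
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        export_tables(sweep = sw, out_dir = out_dir)
        message(sprintf("swept %d sizes in mode %s", length(sizes), mode))
        0L
      },
      report = {
        if (is.null(flags$`in`)) stopf("need --in DIR from select-regions")
        ranking <- read.table(file.path(flags$`in`, "ranking.tsv"),
                              sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
        class(ranking) <- c("region_ranking", "data.frame")
        export_tables(ranking = ranking, out_dir = out_dir)
        0L
      },
      {
        message(cli_usage())
        stopf("unknown command: %s", command)
      })
  }, error = function(e) {
    message(sprintf("error in stage '%s': %s", command, conditionMessage(e)))
    if (grepl("unknown command|unexpected argument", conditionMessage(e))) 2L
    else 1L
  })
  invisible(status)
}
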