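# Window catalogue: fixed-width 1 Mbp autosomal windows, the feature universe
# of the density profiles.  Coordinates are 0-based half-open throughout;
# 1-based variant positions are converted with pos - 1 on read.

AUTOSOMES <- c(paste0("chr", 1:22), as.character(1:22))

#' Read a chrom.sizes file
#'
#' Parses a two-column whitespace-delimited file of chromosome names and
#' lengths.  Non-autosomal entries are kept but flagged so that windowing can
#' skip them.
#'
#' @param path Path to a two-column text file (name, length in bp).
#' @return A data.frame of class `chrom_sizes` with columns `chrom`,
#'   `length`, `autosome`.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stopf("chrom.sizes file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stopf("no chromosomes in %s", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  chrom <- character(length(fields))
  len <- numeric(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 2L) stopf("parse error at line %d: expected 2 columns", i)
    v <- suppressWarnings(as.numeric(f[2]))
    if (is.na(v) || v <= 0 || v != floor(v)) {
      stopf("parse error at line %d: bad length '%s'", i, f[2])
    }
    chrom[i] <- f[1]
    len[i] <- v
  }
  if (anyDuplicated(chrom)) {
    stopf("duplicate chromosome: %s", chrom[duplicated(chrom)][1])
  }
  out <- data.frame(chrom = chrom, length = len,
                    autosome = chrom %in% AUTOSOMES,
                    stringsAsFactors = FALSE)
  class(out) <- c("chrom_sizes", "data.frame")
  out
}

# Natural autosome order chr1..chr22 so window indices are stable across runs.
autosome_order <- function(chrom) {
  num <- sub("^chr", "", chrom)
  order(as.integer(num))
}

#' Partition autosomes into consecutive fixed-width windows
#'
#' Each autosome of length L yields `floor(L / window_size)` full windows
#' starting at 0; the trailing partial window is dropped so every feature
#' covers the same number of base pairs.  Global 0-based indices are assigned
#' in natural chromosome order (chr1..chr22).
#'
#' @param sizes A `chrom_sizes` object from [read_chrom_sizes()].
#' @param window_size Window width in bp (default 1e6).
#' @return A `window_set`: data.frame with columns `chrom`, `start`, `end`,
#'   `index` and attribute `window_size`.
#' @export
partition_autosomes <- function(sizes, window_size = 1e6) {
  if (!is_count(window_size)) stopf("window_size must be a positive integer")
  auto <- sizes[sizes$autosome, , drop = FALSE]
  auto <- auto[autosome_order(auto$chrom), , drop = FALSE]
  pieces <- lapply(seq_len(nrow(auto)), function(i) {
    n <- floor(auto$length[i] / window_size)
    if (n == 0) return(NULL)
    start <- (seq_len(n) - 1) * window_size
    data.frame(chrom = auto$chrom[i], start = start,
               end = start + window_size, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE)
  }
  out$index <- seq_len(nrow(out)) - 1L
  rownames(out) <- NULL
  attr(out, "window_size") <- window_size
  class(out) <- c("window_set", "data.frame")
  out
}

#' Read a BED3 or bedGraph interval track
#'
#' Three columns give valueless intervals (exclusion tracks); a fourth numeric
#' column gives a signal value (mappability, GC fraction, chromatin signal).
#' Coordinates are 0-based half-open as in BED.
#'
#' @param path Path to a BED3/bedGraph file.
#' @return An `interval_track` data.frame with columns `chrom`, `start`,
#'   `end`, `value` (`NA` when absent).
#' @export
read_interval_track <- function(path) {
  if (!file.exists(path)) stopf("track file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  n <- length(lines)
  chrom <- character(n); s <- numeric(n); e <- numeric(n); v <- rep(NA_real_, n)
  fields <- strsplit(trimws(lines), "[ \t]+")
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < 3L) stopf("parse error at line %d: expected >= 3 columns", i)
    s[i] <- suppressWarnings(as.numeric(f[2]))
    e[i] <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s[i]) || is.na(e[i])) {
      stopf("parse error at line %d: non-numeric coordinate", i)
    }
    if (s[i] >= e[i]) stopf("invalid interval at line %d: start >= end", i)
    if (s[i] < 0) stopf("invalid interval at line %d: negative start", i)
    chrom[i] <- f[1]
    if (length(f) >= 4L) {
      v[i] <- suppressWarnings(as.numeric(f[4]))
      if (!is.finite(v[i])) stopf("parse error at line %d: bad value '%s'", i, f[4])
    }
  }
  interval_track(chrom, s, e, v)
}

#' Construct an interval track in memory
#'
#' @param chrom,start,end,value Parallel vectors; `value` may be `NA`.
#' @return An `interval_track` data.frame.
#' @export
interval_track <- function(chrom, start, end, value = NA_real_) {
  out <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                    end = as.numeric(end),
                    value = rep_len(as.numeric(value), length(chrom)),
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stopf("interval with start >= end")
  class(out) <- c("interval_track", "data.frame")
  out
}

# Length-weighted mean of a track over every window of an aligned window set.
# Uncovered bp contribute value 0, so the mean is (sum of value * overlap) /
# window_size.  Relies on windows being aligned multiples of window_size,
# which partition_autosomes guarantees and filtering preserves.
window_weighted_mean <- function(track, ws) {
  wsz <- attr(ws, "window_size")
  key <- paste0(ws$chrom, ":", ws$start %/% wsz)
  total <- numeric(nrow(ws))
  covered <- numeric(nrow(ws))
  names(total) <- key
  if (nrow(track) > 0) {
    for (i in seq_len(nrow(track))) {
      s <- track$start[i]; e <- track$end[i]
      slots <- (s %/% wsz):((e - 1) %/% wsz)
      for (slot in slots) {
        k <- paste0(track$chrom[i], ":", slot)
        j <- match(k, key)
        if (is.na(j)) next
        ov <- min(e, (slot + 1) * wsz) - max(s, slot * wsz)
        val <- track$value[i]
        if (!is.na(val)) total[j] <- total[j] + val * ov
        covered[j] <- covered[j] + ov
      }
    }
  }
  list(mean = total / wsz, covered_bp = covered)
}

# TRUE for windows overlapped by >= 1 bp of the track.
window_has_overlap <- function(track, ws) {
  window_weighted_mean(track, ws)$covered_bp > 0
}

#' Filter a window catalogue on mappability, GC content and exclusion tracks
#'
#' Retains windows whose length-weighted mean mappability is at least
#' `mappability_min`, whose length-weighted mean GC fraction lies in
#' `[gc_min, gc_max]`, and which overlap none of the exclusion tracks
#' (centromeres, telomeres, assembly gaps).  Uncovered base pairs count as
#' value 0 in the weighted means, so a window with no track coverage fails.
#' Survivors are re-indexed densely in the original order; removals are
#' recorded with their reasons in the `audit` attribute.
#'
#' @param ws A `window_set`.
#' @param mappability,gc `interval_track`s carrying scores / GC fractions.
#' @param cfg A [window_filter_config()].
#' @return The filtered `window_set` with attribute `audit`.
#' @export
apply_window_filters <- function(ws, mappability, gc,
                                 cfg = window_filter_config()) {
  mp <- window_weighted_mean(mappability, ws)$mean
  gcm <- window_weighted_mean(gc, ws)$mean
  excl <- rep(FALSE, nrow(ws))
  for (tr in cfg$exclusion_tracks) {
    excl <- excl | window_has_overlap(tr, ws)
  }
  reasons <- character(nrow(ws))
  add_reason <- function(reasons, hit, label) {
    ifelse(hit, ifelse(nzchar(reasons), paste(reasons, label, sep = ","),
                       label), reasons)
  }
  reasons <- add_reason(reasons, mp < cfg$mappability_min, "mappability")
  reasons <- add_reason(reasons, gcm < cfg$gc_min | gcm > cfg$gc_max, "gc")
  reasons <- add_reason(reasons, excl, "exclusion")
  keep <- !nzchar(reasons)
  audit <- data.frame(chrom = ws$chrom[!keep], start = ws$start[!keep],
                      end = ws$end[!keep], old_index = ws$index[!keep],
                      reason = reasons[!keep], stringsAsFactors = FALSE)
  out <- ws[keep, , drop = FALSE]
  out$index <- seq_len(nrow(out)) - 1L
  rownames(out) <- NULL
  attr(out, "window_size") <- attr(ws, "window_size")
  attr(out, "audit") <- audit
  class(out) <- c("window_set", "data.frame")
  out
}

#' Window filter configuration
#'
#' @param mappability_min Minimum length-weighted mean mappability (default
#'   0.5).
#' @param gc_min,gc_max Allowed range of mean GC fraction (default 0.20-0.80).
#' @param exclusion_tracks List of `interval_track`s; any overlap removes the
#'   window.
#' @return A `window_filter_config` list.
#' @export
window_filter_config <- function(mappability_min = 0.5, gc_min = 0.20,
                                 gc_max = 0.80, exclusion_tracks = list()) {
  stopifnot(mappability_min >= 0, mappability_min <= 1,
            gc_min >= 0, gc_min < gc_max, gc_max <= 1)
  structure(list(mappability_min = mappability_min, gc_min = gc_min,
                 gc_max = gc_max, exclusion_tracks = exclusion_tracks),
            class = "window_filter_config")
}

#' Write a window catalogue as BED4
#'
#' Columns: chrom, start, end, index.  [read_window_bed()] reproduces the
#' `window_set` exactly, so a published catalogue can be pinned verbatim.
#'
#' @param ws A `window_set`.
#' @param path Output path.
#' @export
write_window_bed <- function(ws, path) {
  df <- data.frame(ws$chrom, format(ws$start, scientific = FALSE, trim = TRUE),
                   format(ws$end, scientific = FALSE, trim = TRUE), ws$index)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a window catalogue from BED4
#'
#' @param path Path to a BED4 file written by [write_window_bed()] or any
#'   catalogue with columns chrom, start, end, index.
#' @return A `window_set`.
#' @export
read_window_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "index"),
                   colClasses = c("character", "numeric", "numeric", "integer"))
  widths <- unique(df$end - df$start)
  if (length(widths) != 1L) stopf("window BED has mixed widths")
  if (any(df$index != seq_len(nrow(df)) - 1L)) {
    stopf("window BED indices are not dense 0..n-1")
  }
  attr(df, "window_size") <- widths
  class(df) <- c("window_set", "data.frame")
  df
}
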