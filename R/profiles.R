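# Per-sample mutation density profiles: somatic SNVs aggregated over the
# window catalogue, plus chromatin-signal binning and feature assembly.

#' Read somatic variants from a VCF or minimal TSV
#'
#' VCF input honours CHROM/POS/REF/ALT/FILTER; TSV input needs a header with
#' columns `chrom`, `pos`, `ref`, `alt` (an optional `sample` column is
#' ignored in favour of `sample_id`).  Only single-nucleotide substitutions
#' are kept (somatic point mutations are the unit feature); indels and MNVs
#' are dropped and tallied in the `audit` attribute.
#'
#' @param path Path to a `.vcf` or tab-separated variant file.
#' @param sample_id Sample identifier attached to every record.
#' @return A data.frame of class `variant_table` with columns `chrom`, `pos`
#'   (1-based), `ref`, `alt`, `sample_id`, `filter`, and attribute `audit`
#'   (named counts of dropped records).
#' @export
read_variants <- function(path, sample_id) {
  if (!file.exists(path)) stopf("variant file not found: %s", path)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
    needed <- c("CHROM", "POS", "REF", "ALT")
    if (nrow(fix) > 0 && !all(needed %in% colnames(fix))) {
      stopf("VCF lacks mandatory columns: %s",
            paste(setdiff(needed, colnames(fix)), collapse = ", "))
    }
    df <- data.frame(chrom = as.character(fix[, "CHROM"]),
                     pos = as.numeric(fix[, "POS"]),
                     ref = as.character(fix[, "REF"]),
                     alt = as.character(fix[, "ALT"]),
                     filter = if ("FILTER" %in% colnames(fix)) {
                       as.character(fix[, "FILTER"])
                     } else NA_character_,
                     stringsAsFactors = FALSE)
    df$filter[is.na(df$filter)] <- "."
  } else {
    df <- read.table(path, sep = "\t", header = TRUE,
                     colClasses = "character", check.names = FALSE)
    names(df) <- tolower(names(df))
    needed <- c("chrom", "pos", "ref", "alt")
    if (!all(needed %in% names(df))) {
      stopf("variant TSV lacks columns: %s",
            paste(setdiff(needed, names(df)), collapse = ", "))
    }
    df <- data.frame(chrom = df$chrom, pos = as.numeric(df$pos),
                     ref = df$ref, alt = df$alt, filter = NA_character_,
                     stringsAsFactors = FALSE)
  }
  if (nrow(df) > 0 && any(is.na(df$pos) | df$pos < 1)) {
    stopf("variant with missing or non-positive position in %s", path)
  }
  snv <- nchar(df$ref) == 1L & nchar(df$alt) == 1L & df$ref != df$alt &
    df$ref != "" & df$alt != ""
  audit <- c(dropped_non_snv = sum(!snv))
  df <- df[snv, , drop = FALSE]
  df$sample_id <- rep_len(as.character(sample_id), nrow(df))
  df <- df[, c("chrom", "pos", "ref", "alt", "sample_id", "filter")]
  rownames(df) <- NULL
  attr(df, "audit") <- audit
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Collapse duplicate variant calls and apply a quality predicate
#'
#' Exact duplicates (same sample, chrom, pos, ref, alt) are collapsed to one
#' record.  For VCF-derived tables the default quality rule keeps FILTER
#' `PASS` or `.`; TSV-derived tables carry no FILTER and skip the predicate.
#'
#' @param vs A `variant_table`.
#' @param quality_rule Function mapping the table to a logical keep vector,
#'   or `NULL` for the default FILTER rule.
#' @return The filtered `variant_table`; attribute `audit` counts removals.
#' @export
dedupe_and_filter_variants <- function(vs, quality_rule = NULL) {
  n0 <- nrow(vs)
  if (is.null(quality_rule)) {
    keep <- is.na(vs$filter) | vs$filter %in% c("PASS", ".")
  } else {
    keep <- quality_rule(vs)
  }
  vs2 <- vs[keep, , drop = FALSE]
  n_quality <- n0 - nrow(vs2)
  key <- paste(vs2$sample_id, vs2$chrom, vs2$pos, vs2$ref, vs2$alt, sep = "\r")
  dup <- duplicated(key)
  out <- vs2[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "audit") <- c(removed_quality = n_quality,
                          removed_duplicate = sum(dup))
  class(out) <- c("variant_table", "data.frame")
  out
}

# 0-based window slot lookup for 1-based positions against an aligned
# window set; returns the window index or NA when the position falls in no
# retained window.
window_index_of <- function(chrom, pos, ws) {
  wsz <- attr(ws, "window_size")
  key <- paste0(ws$chrom, ":", ws$start %/% wsz)
  q <- paste0(chrom, ":", (pos - 1) %/% wsz)
  ws$index[match(q, key)]
}

#' Tumor mutational burden over the retained windows
#'
#' Mutations falling inside retained windows divided by the total retained
#' window length in Mb, i.e. mutations per megabase of assessed genome.
#'
#' @param vs A `variant_table`.
#' @param ws A non-empty `window_set`.
#' @return Mutations per Mb (numeric scalar).
#' @export
compute_tmb <- function(vs, ws) {
  if (nrow(ws) == 0L) stopf("empty window set")
  idx <- window_index_of(vs$chrom, vs$pos, ws)
  mb <- sum(ws$end - ws$start) / 1e6
  sum(!is.na(idx)) / mb
}

#' Build a cohort object
#'
#' @param variants Named list of `variant_table`s, one per sample.
#' @param labels Named character vector mapping sample id to cancer-type
#'   label; every sample must be labeled.
#' @return A `cohort` list with `samples`, `labels`, `variants`.
#' @export
cohort <- function(variants, labels) {
  samples <- names(variants)
  if (is.null(samples) || anyDuplicated(samples)) {
    stopf("variants must be a uniquely named list of samples")
  }
  missing <- setdiff(samples, names(labels))
  if (length(missing)) stopf("unlabeled sample: %s", missing[1])
  structure(list(samples = samples,
                 labels = labels[samples],
                 variants = variants),
            class = "cohort")
}

#' Remove hypermutant samples from a cohort
#'
#' The default rule removes samples whose TMB exceeds 10 times the cohort
#' median TMB; a scale-free rule adapts to cohorts whose baseline burden
#' differs by orders of magnitude.  An absolute mutations/Mb cutoff can be
#' supplied instead.
#'
#' @param ch A `cohort`.
#' @param ws A `window_set` used to compute TMB.
#' @param rule Either `"median10"` (default) or a numeric absolute cutoff in
#'   mutations per Mb.
#' @return The filtered `cohort`; attribute `removed` lists removed sample
#'   ids with their TMB.
#' @export
filter_hypermutants <- function(ch, ws, rule = "median10") {
  tmb <- vapply(ch$variants, compute_tmb, numeric(1), ws = ws)
  if (identical(rule, "median10")) {
    cutoff <- 10 * median(tmb)
  } else if (is.numeric(rule) && length(rule) == 1L) {
    cutoff <- rule
  } else {
    stopf("rule must be 'median10' or a numeric cutoff")
  }
  drop <- tmb > cutoff
  if (all(drop)) stopf("empty cohort: all samples removed as hypermutant")
  out <- cohort(ch$variants[!drop], ch$labels[!drop])
  attr(out, "removed") <- data.frame(sample_id = ch$samples[drop],
                                     tmb = unname(tmb[drop]),
                                     stringsAsFactors = FALSE)
  out
}

#' Bin variants into window-level mutation counts
#'
#' `counts[w]` is the number of variants whose 0-based position `pos - 1`
#' falls in `[start, end)` of window `w`.  Normalisations: `raw` counts,
#' `per_mb` (counts divided by window length in Mb), `per_sample_fraction`
#' (counts divided by the sample's total in-window count; an all-zero
#' profile stays all-zero).
#'
#' @param vs A `variant_table` for one sample.
#' @param ws A non-empty `window_set`.
#' @param normalization One of `"raw"`, `"per_mb"`, `"per_sample_fraction"`.
#' @return A `density_profile`: numeric vector of length `nrow(ws)` with
#'   attributes `sample_id`, `normalization`, `out_of_window` (tally of
#'   variants in no retained window).
#' @export
bin_mutation_density <- function(vs, ws,
                                 normalization = c("raw", "per_mb",
                                                   "per_sample_fraction")) {
  normalization <- match.arg(normalization)
  if (nrow(ws) == 0L) stopf("empty window set")
  idx <- window_index_of(vs$chrom, vs$pos, ws)
  counts <- tabulate(idx + 1L, nbins = nrow(ws))
  out_of_window <- sum(is.na(idx))
  values <- switch(normalization,
    raw = as.numeric(counts),
    per_mb = counts / ((ws$end - ws$start) / 1e6),
    per_sample_fraction = if (sum(counts) > 0) counts / sum(counts) else {
      as.numeric(counts)
    })
  structure(values,
            sample_id = if (nrow(vs) > 0) vs$sample_id[1] else NA_character_,
            normalization = normalization, out_of_window = out_of_window,
            class = "density_profile")
}

#' Bin a chromatin signal track into window-level values
#'
#' The raw window value is the length-weighted mean of the track over the
#' window with uncovered base pairs contributing 0.  `zscore` normalisation
#' standardises the values across windows within the track (mean 0, sd 1;
#' a constant track maps to all zeros) so heterogeneous ChIP-seq tracks are
#' comparable.
#'
#' @param track An `interval_track` with values.
#' @param ws A `window_set`.
#' @param normalization `"zscore"` (default) or `"raw"`.
#' @param track_id Identifier stored on the profile.
#' @return A `chromatin_profile` numeric vector of length `nrow(ws)`.
#' @export
bin_chromatin_signal <- function(track, ws, normalization = c("zscore", "raw"),
                                 track_id = "track") {
  normalization <- match.arg(normalization)
  if (all(is.na(track$value))) stopf("track has no values")
  values <- window_weighted_mean(track, ws)$mean
  if (normalization == "zscore") {
    s <- sd(values)
    values <- if (is.na(s) || s == 0) rep(0, length(values)) else {
      (values - mean(values)) / s
    }
  }
  structure(values, track_id = track_id, normalization = normalization,
            class = "chromatin_profile")
}

#' Assemble the labeled sample-by-feature matrix
#'
#' One row per sample; window columns (named `w<index>`, ascending index)
#' come from the density profiles, then chromatin columns in lexicographic
#' track-id order from an optional per-sample chromatin feature matrix such
#' as the one produced by [project_chromatin_features()].  Column order is
#' deterministic and invariant to the input ordering of profiles.
#'
#' @param density Named list of `density_profile`s (names = sample ids), or a
#'   samples-by-windows numeric matrix.
#' @param labels Named vector mapping sample id to class label.
#' @param chromatin Optional numeric matrix (samples x tracks) of per-sample
#'   chromatin features, rownames = sample ids.
#' @return A `feature_matrix` list: `x` (numeric matrix), `labels` (factor),
#'   `window_cols`, `chromatin_cols`.
#' @export
assemble_feature_matrix <- function(density, labels, chromatin = NULL) {
  if (is.matrix(density)) {
    x <- density
    if (is.null(colnames(x))) colnames(x) <- paste0("w", seq_len(ncol(x)) - 1L)
  } else {
    ids <- names(density)
    if (is.null(ids) || anyDuplicated(ids)) stopf("duplicate or missing sample id")
    len <- unique(vapply(density, length, integer(1)))
    if (length(len) != 1L) stopf("density profiles have mismatched lengths")
    x <- do.call(rbind, lapply(density, as.numeric))
    rownames(x) <- ids
    colnames(x) <- paste0("w", seq_len(len) - 1L)
  }
  if (anyDuplicated(rownames(x))) stopf("duplicate sample id")
  missing <- setdiff(rownames(x), names(labels))
  if (length(missing)) stopf("label missing for sample: %s", missing[1])
  window_cols <- colnames(x)
  chromatin_cols <- character(0)
  if (!is.null(chromatin)) {
    if (!all(rownames(x) %in% rownames(chromatin))) {
      stopf("chromatin features missing for some samples")
    }
    chromatin <- chromatin[rownames(x), , drop = FALSE]
    chromatin <- chromatin[, order(colnames(chromatin)), drop = FALSE]
    chromatin_cols <- colnames(chromatin)
    if (any(chromatin_cols %in% window_cols)) stopf("duplicate feature id")
    x <- cbind(x, chromatin)
  }
  if (anyNA(x)) stopf("feature matrix has missing cells")
  lab <- factor(labels[rownames(x)])
  structure(list(x = x, labels = lab, window_cols = window_cols,
                 chromatin_cols = chromatin_cols),
            class = "feature_matrix")
}

#' Project chromatin tracks onto samples as density-weighted context scores
#'
#' Chromatin tracks describe tissues, not tumors, so they cannot enter the
#' sample matrix directly.  Each sample is summarised against each track by
#' the mutation-fraction-weighted mean of the track's z-scored window values:
#' a sample whose mutations concentrate in windows where a track is high
#' scores high on that track.  These per-sample scores are the chromatin
#' columns consumed by [backward_eliminate_chromatin()].
#'
#' @param density Named list of `density_profile`s or samples-by-windows
#'   matrix of counts.
#' @param profiles Named list of `chromatin_profile`s (names = track ids).
#' @return Numeric matrix samples x tracks.
#' @export
project_chromatin_features <- function(density, profiles) {
  if (is.matrix(density)) {
    counts <- density
  } else {
    counts <- do.call(rbind, lapply(density, as.numeric))
    rownames(counts) <- names(density)
  }
  frac <- counts / pmax(rowSums(counts), 1)
  z <- do.call(cbind, lapply(profiles, as.numeric))
  colnames(z) <- names(profiles)
  if (nrow(z) != ncol(counts)) stopf("profiles do not match window count")
  frac %*% z
}

#' Restrict a feature matrix to a subset of columns
#'
#' @param fm A `feature_matrix`.
#' @param cols Character vector of feature ids.
#' @return A `feature_matrix` with the selected columns.
#' @export
subset_features <- function(fm, cols) {
  missing <- setdiff(cols, colnames(fm$x))
  if (length(missing)) stopf("unknown feature id: %s", missing[1])
  structure(list(x = fm$x[, cols, drop = FALSE], labels = fm$labels,
                 window_cols = intersect(cols, fm$window_cols),
                 chromatin_cols = intersect(cols, fm$chromatin_cols)),
            class = "feature_matrix")
}
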