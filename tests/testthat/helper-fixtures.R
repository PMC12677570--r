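# Fixtures built in code at test time.

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Two well-separated Gaussian classes in 2 features.
separable_fm <- function(n_per_class = 30, seed = 42, sep = 6) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * 2), ncol = 2),
             matrix(rnorm(n_per_class * 2, mean = sep), ncol = 2))
  colnames(x) <- c("f1", "f2")
  rownames(x) <- sprintf("s%02d", seq_len(2 * n_per_class))
  labels <- setNames(rep(c("A", "B"), each = n_per_class), rownames(x))
  assemble_feature_matrix(x, labels)
}

# Small synthetic cohort used across module tests (kept tiny for speed).
tiny_cohort <- function(seed = 5) {
  generate_cohort(synthetic_config(samples_per_class = 6, n_windows = 60,
                                   planted_per_class = 6, seed = seed))
}

# Toy aligned window set on one chromosome.
toy_window_set <- function(n = 3, width = 1e6, chrom = "chr1") {
  df <- data.frame(chrom = rep_len(chrom, n),
                   start = (seq_len(n) - 1) * width,
                   end = seq_len(n) * width, index = seq_len(n) - 1L,
                   stringsAsFactors = FALSE)
  attr(df, "window_size") <- width
  class(df) <- c("window_set", "data.frame")
  df
}

variant_df <- function(chrom, pos, ref = "A", alt = "G", sample_id = "s1") {
  df <- data.frame(chrom = rep_len(chrom, length(pos)), pos = pos,
                   ref = rep_len(ref, length(pos)),
                   alt = rep_len(alt, length(pos)),
                   sample_id = rep_len(sample_id, length(pos)),
                   filter = rep_len(NA_character_, length(pos)),
                   stringsAsFactors = FALSE)
  class(df) <- c("variant_table", "data.frame")
  df
}

one_hot_test <- function(class_idx, K) {
  y <- matrix(0, length(class_idx), K)
  y[cbind(seq_along(class_idx), class_idx)] <- 1
  y
}

# Independent Fisher oracle: full hypergeometric enumeration via
# log-factorials, written without reference to the package's code path.
fisher_enum <- function(a, b, cc, d) {
  m <- a + cc; nn <- b + d; k <- a + b
  lo <- max(0, k - nn); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(m, x) + lchoose(nn, k - x) - lchoose(m + nn, k))
  }, numeric(1))
  sum(probs[(lo:hi) >= a])
}

# Independent BH step-up oracle.
bh_enum <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}
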