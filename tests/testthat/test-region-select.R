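# Informative region selection: trials, Fisher enrichment, ranking, sweep,
# backward elimination.

small_trial_setup <- function(seed = 5) {
  co <- tiny_cohort(seed)
  cfg <- selection_config(subset_sizes = c(8, 12), repeats = 6,
                          folds = 3, seed = seed,
                          model_cfg = boosting_config(iterations = 10))
  list(co = co, cfg = cfg,
       ledger = run_random_subset_trials(co$fm, cfg))
}

test_that("subset trials honour the sampling contract and are reproducible", {
  st <- small_trial_setup()
  led <- st$ledger
  expect_length(led$subsets, 12)
  expect_true(all(vapply(led$subsets[1:6], length, integer(1)) == 8))
  expect_true(all(vapply(led$subsets, anyDuplicated, integer(1)) == 0))
  expect_true(all(unlist(led$subsets) >= 0 & unlist(led$subsets) < 60))

  led2 <- run_random_subset_trials(st$co$fm, st$cfg)
  expect_identical(led$subsets, led2$subsets)
  expect_identical(led$correct, led2$correct)

  bad <- selection_config(subset_sizes = 999, repeats = 1)
  expect_error(run_random_subset_trials(st$co$fm, bad), "exceeds")
})

test_that("window inclusion counts stay within binomial bounds", {
  # sampling-only check (no model fitting): each window of W appears in a
  # size-s subset with probability s/W
  co <- tiny_cohort(3)
  W <- length(co$fm$window_cols)
  R <- 400; s <- 10
  counts <- integer(W)
  for (r in seq_len(R)) {
    set.seed(r)
    idx <- sample.int(W, s)
    counts[idx] <- counts[idx] + 1L
  }
  expval <- R * s / W
  sdev <- sqrt(R * (s / W) * (1 - s / W))
  expect_true(all(abs(counts - expval) <= 4 * sdev))
})

test_that("contingency tables count pairs correctly", {
  led <- structure(list(
    subsets = list(c(0L, 1L), c(2L, 3L)),
    sizes = c(2L, 2L),
    correct = matrix(1L, 2, 4,
                     dimnames = list(NULL, paste0("s", 1:4))),
    labels = factor(c("c", "c", "x", "x")),
    window_cols = paste0("w", 0:4), seed = 1L), class = "trial_ledger")
  # window 0 included in trial 1 only; all class-c predictions correct
  tab <- build_contingency(led, 0L, "c")
  expect_equal(unname(unclass(tab)), c(2, 0, 2, 0))
  # margin identity: a+b = (#trials containing w) x (#class-c samples)
  expect_equal(tab[["a"]] + tab[["b"]], 1 * 2)

  expect_error(build_contingency(led, 0L, "nope"), "no samples")
  empty <- led; empty$subsets <- list()
  expect_error(build_contingency(empty, 0L, "c"), "no trials")
})

test_that("one-sided Fisher matches hypergeometric enumeration", {
  expect_equal(fisher_one_sided(c(2, 0, 0, 2)), 1 / 6, tolerance = 1e-12)
  # degenerate margins
  expect_equal(fisher_one_sided(c(0, 0, 3, 4)), 1)
  expect_equal(fisher_one_sided(c(0, 3, 0, 4)), 1)
  # enumeration oracle across random small tables
  set.seed(21)
  for (rep in 1:50) {
    cells <- rmultinom(1, sample(4:20, 1), rep(0.25, 4))[, 1]
    expect_equal(fisher_one_sided(cells),
                 fisher_enum(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-10)
  }
  # agreement with stats::fisher.test on a non-trivial table
  ft <- stats::fisher.test(matrix(c(7, 2, 3, 8), 2, byrow = TRUE),
                           alternative = "greater")
  expect_equal(fisher_one_sided(c(7, 2, 3, 8)), ft$p.value,
               tolerance = 1e-10)
})

test_that("BH adjustment matches the brute-force step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.20)),
               c(0.04, 0.04, 0.04, 0.20))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(31)
  for (rep in 1:20) {
    p <- runif(sample(c(5, 50, 200), 1))
    expect_equal(bh_adjust(p), bh_enum(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("a window present in exactly the correct trials ranks first", {
  # constructed extreme case: window 7 included iff the trial predicted all
  # class-c samples correctly
  set.seed(41)
  n_trials <- 40
  subsets <- list(); correct <- matrix(0L, n_trials, 6)
  colnames(correct) <- paste0("s", 1:6)
  labels <- factor(rep(c("c", "x"), each = 3))
  for (t in seq_len(n_trials)) {
    good <- t %% 2 == 0
    others <- sample(setdiff(0:19, 7), 4)
    subsets[[t]] <- sort(c(if (good) 7L, others)[1:4])
    correct[t, 1:3] <- as.integer(good)
    correct[t, 4:6] <- rbinom(3, 1, 0.5)
  }
  led <- structure(list(subsets = subsets, sizes = rep(4L, n_trials),
                        correct = correct, labels = labels,
                        window_cols = paste0("w", 0:19), seed = 1L),
                   class = "trial_ledger")
  rk <- rank_informative_regions(led, selection_config(seed = 1))
  top_c <- rk[rk$class == "c" & rk$rank == 1, ]
  expect_equal(top_c$window, 7L)
  expect_true(top_c$significant)
})

test_that("ranking output is structurally sound and deterministic", {
  st <- small_trial_setup()
  rk1 <- rank_informative_regions(st$ledger, st$cfg)
  rk2 <- rank_informative_regions(st$ledger, st$cfg)
  expect_identical(rk1, rk2)
  for (cl in unique(rk1$class)) {
    sub <- rk1[rk1$class == cl, ]
    expect_equal(sub$rank, seq_len(nrow(sub)))
    expect_equal(sort(sub$window), 0:59)
    expect_true(all(sub$p >= 0 & sub$p <= 1))
    expect_true(all(sub$q >= 0 & sub$q <= 1))
    # significant block precedes fill block
    expect_true(all(diff(sub$significant) <= 0))
  }
})

test_that("occurrence frequency equals the contingency a-cell", {
  st <- small_trial_setup()
  occ <- region_occurrence_frequency(st$ledger)
  for (cl in rownames(occ)) {
    for (w in c(0L, 7L, 33L)) {
      tab <- build_contingency(st$ledger, w, cl)
      expect_equal(occ[cl, w + 1L], unname(tab[["a"]]))
    }
  }
  # all predictions wrong -> all-zero matrix
  led0 <- st$ledger
  led0$correct[] <- 0L
  expect_true(all(region_occurrence_frequency(led0) == 0))
})

test_that("label permutation keeps the flagged fraction near the FDR level", {
  st <- small_trial_setup()
  led <- st$ledger
  set.seed(17)
  fracs <- replicate(5, {
    perm <- led
    perm$correct <- led$correct[, sample(ncol(led$correct))]
    colnames(perm$correct) <- colnames(led$correct)
    rk <- rank_informative_regions(perm, st$cfg)
    mean(rk$significant)
  })
  sigma <- sqrt(0.05 * 0.95 / (60 * 6))
  expect_lte(mean(fracs), 0.05 + 3 * sigma)
})

test_that("sweep modes behave at their limiting cases", {
  co <- tiny_cohort(7)
  cfg <- selection_config(folds = 3, seed = 2,
                          model_cfg = boosting_config(iterations = 10))
  W <- length(co$fm$window_cols)
  whole <- sweep_subset_sizes(co$fm, NULL, mode = "whole", cfg = cfg)
  expect_equal(nrow(whole), 6)
  expect_true(all(whole$accuracy >= 0 & whole$accuracy <= 1))
  expect_equal(unique(whole$size), W)

  # random draw of all windows equals the whole-genome model
  rnd_all <- sweep_subset_sizes(co$fm, NULL, sizes = W, mode = "random",
                                cfg = cfg, n_random_draws = 1)
  expect_equal(sort(rnd_all$accuracy), sort(whole$accuracy))

  expect_error(sweep_subset_sizes(co$fm, NULL, sizes = W + 1,
                                  mode = "random", cfg = cfg),
               "exceeds")
  expect_error(sweep_subset_sizes(co$fm, NULL, sizes = 5,
                                  mode = "informative", cfg = cfg),
               "ranking")
})

test_that("informative subsets dominate random ones on planted signal", {
  # moderately strong planted signal, small scale; paired seeds
  co <- generate_cohort(synthetic_config(samples_per_class = 10,
                                         n_windows = 80,
                                         planted_per_class = 6,
                                         effect_multiplier = 4, seed = 9))
  cfg <- selection_config(subset_sizes = c(10, 20), repeats = 30, folds = 5,
                          seed = 9,
                          model_cfg = boosting_config(iterations = 15))
  led <- run_random_subset_trials(co$fm, cfg)
  rk <- rank_informative_regions(led, cfg)
  gaps <- vapply(1:3, function(sd) {
    cfg_s <- selection_config(folds = 5, seed = 200 + sd,
                              model_cfg = boosting_config(iterations = 15))
    inf <- sweep_subset_sizes(co$fm, rk, sizes = 10, mode = "informative",
                              cfg = cfg_s)
    rnd <- sweep_subset_sizes(co$fm, NULL, sizes = 10, mode = "random",
                              cfg = cfg_s, n_random_draws = 1)
    mean(inf$accuracy) - mean(rnd$accuracy)
  }, numeric(1))
  expect_gt(mean(gaps), 0)
})

test_that("backward elimination follows the schedule and finds planted tracks", {
  # schedule arithmetic: 25 features, keep 20, 20 rounds -> one per round
  co <- tiny_cohort(11)
  tracks <- generate_chromatin_fixture(co$truth, n_tracks = 25,
                                       n_informative = 3, rho = 0.9)
  profs <- lapply(names(tracks), function(id) {
    bin_chromatin_signal(tracks[[id]], co$truth$window_set, track_id = id)
  })
  names(profs) <- names(tracks)
  proj <- project_chromatin_features(co$fm$x, profs)
  labels <- setNames(as.character(co$fm$labels), rownames(co$fm$x))
  fm <- assemble_feature_matrix(co$fm$x, labels, chromatin = proj)
  out <- backward_eliminate_chromatin(fm, rounds = 20, folds = 3, keep = 20,
                                      cfg = boosting_config(iterations = 10),
                                      seed = 4)
  expect_equal(nrow(out), 20)
  expect_equal(out$rank, 1:20)
  info <- attr(tracks, "info")
  informative <- info$track_id[info$informative]
  expect_true(all(informative %in% out$feature))

  # fewer features than keep: returns all with a warning
  fm_small <- assemble_feature_matrix(co$fm$x, labels,
                                      chromatin = proj[, 1:5])
  expect_warning(all5 <- backward_eliminate_chromatin(
    fm_small, keep = 20, folds = 3,
    cfg = boosting_config(iterations = 5), seed = 1), "returning all")
  expect_equal(nrow(all5), 5)
})

test_that("unused features carry zero importance", {
  fm <- separable_fm(n_per_class = 10)
  # add a constant column that no split can use
  x <- cbind(fm$x, dead = rep(1, nrow(fm$x)))
  labels <- setNames(as.character(fm$labels), rownames(x))
  fm2 <- assemble_feature_matrix(x, labels)
  model <- fit_model(fm2, boosting_config(iterations = 5))
  expect_equal(unname(model$importance["dead"]), 0)
})

test_that("trial ledgers round-trip through TSV", {
  st <- small_trial_setup()
  path <- tempfile(fileext = ".tsv")
  write_trial_ledger(st$ledger, path)
  labels <- setNames(as.character(st$ledger$labels),
                     colnames(st$ledger$correct))
  back <- read_trial_ledger(path, labels, st$ledger$window_cols)
  expect_identical(back$subsets, st$ledger$subsets)
  expect_identical(unname(back$correct), unname(st$ledger$correct))
  expect_equal(back$sizes, st$ledger$sizes)
})
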