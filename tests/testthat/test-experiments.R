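# Small labeled feature frames (fast to train) for experiment machinery.
toy_class_frame <- function(n, shift, seed) {
  set.seed(seed)
  data.frame(f1 = rnorm(n, shift), f2 = rnorm(n, -shift, 2),
             f3 = rnorm(n))
}

test_that("the default sweep grid runs from half the pool to parity", {
  g <- sweep_grid(164, 2826, levels = 30)
  expect_equal(max(g), 1413)
  expect_equal(min(g), 82)
  expect_length(g, 30)
  expect_true(all(diff(g) < 0))
  expect_error(sweep_grid(200, 100), "fewer benign")
})

test_that("the imbalance sweep is reproducible and self-consistent", {
  mr <- toy_class_frame(30, 4, 1)
  benign <- toy_class_frame(60, -4, 2)
  sw1 <- imbalance_sweep(mr, benign, levels = c(25, 15),
                         runs_per_level = 3, seed = 5, min_node = 10)
  sw2 <- imbalance_sweep(mr, benign, levels = c(25, 15),
                         runs_per_level = 3, seed = 5, min_node = 10)
  expect_identical(as.data.frame(sw1), as.data.frame(sw2))
  expect_equal(nrow(sw1), 2L)
  expect_equal(sw1$runs, c(3L, 3L))
  runs <- attr(sw1, "runs")
  expect_equal(sw1$mean_accuracy, rowMeans(runs))
  expect_equal(sw1$sd_accuracy, apply(runs, 1, sd))
  # well-separated toy classes classify perfectly at a balanced level
  expect_equal(sw1$mean_accuracy[2], 1.0)
  expect_error(imbalance_sweep(mr, benign, levels = 100,
                               runs_per_level = 1, seed = 1),
               "more CNVs than available")
})

test_that("training-set selection tracks its accuracy distribution", {
  mr <- toy_class_frame(24, 1, 3)
  benign <- toy_class_frame(24, -1, 4)
  sel <- select_optimal_training_set(mr, benign, n_each = 12,
                                     iterations = 3, seed = 7,
                                     min_node = 5)
  expect_length(sel$accuracy_distribution, 3L)
  expect_equal(max(sel$accuracy_distribution), sel$best_accuracy)
  expect_length(sel$best_mr_idx, 12L)
  expect_s3_class(sel$best_model, "nbtree")

  one <- select_optimal_training_set(mr, benign, n_each = 12,
                                     iterations = 1, seed = 7,
                                     min_node = 5)
  expect_equal(one$best_accuracy, one$accuracy_distribution[1])
  expect_error(select_optimal_training_set(mr, benign, n_each = 12,
                                           iterations = 0, seed = 1),
               "iterations")
  expect_error(select_optimal_training_set(mr, benign, n_each = 50,
                                           iterations = 1, seed = 1),
               "n_each")
})

test_that("removing the only informative feature collapses accuracy", {
  set.seed(9)
  n <- 120
  lab <- rep(c("mr", "benign"), each = n / 2)
  d <- data.frame(
    informative = rnorm(n, ifelse(lab == "mr", 3, -3)),
    constant = rep(1, n),
    noise = rnorm(n),
    class_label = lab
  )
  train <- d[c(1:40, 61:100), ]
  test <- d[c(41:60, 101:120), ]
  fc <- feature_contribution(train, test,
                             feature_groups = list(
                               informative = "informative",
                               constant = "constant"),
                             seed = 2, min_node = 10)
  expect_equal(nrow(fc), 2L)
  decl <- fc$decline_pct_points
  names(decl) <- fc$feature
  # the constant feature carries nothing
  expect_lt(abs(decl[["constant"]]), 3)
  # dropping the informative feature costs at least 30 points
  expect_gt(decl[["informative"]], 30)
  base <- attr(fc, "baseline_accuracy")
  expect_equal(fc$accuracy_without[fc$feature == "informative"],
               base - decl[["informative"]] / 100)
})

test_that("removing length also removes the length-coupled counts", {
  groups <- default_feature_groups(candidate_features())
  expect_setequal(groups$length_bp,
                  c("length_bp", "n_line", "n_sine", "n_segdup", "n_gene"))
  expect_equal(groups$line_density, "line_density")
  expect_error(feature_contribution(
    data.frame(a = 1:10, class_label = rep(c("mr", "benign"), 5)),
    data.frame(a = 1:10, class_label = rep(c("mr", "benign"), 5)),
    feature_groups = list(all = "a"), seed = 1), "no features")
})

test_that("jack-knife retraining guards leakage and orders its summary", {
  pool <- rbind(toy_class_frame(30, 1.2, 11), toy_class_frame(30, -1.2, 12))
  pool$class_label <- rep(c("mr", "benign"), each = 30)
  validation <- rbind(toy_class_frame(10, 1.2, 13),
                      toy_class_frame(10, -1.2, 14))
  validation$class_label <- rep(c("mr", "benign"), each = 10)

  jk <- jackknife_retrain(pool, validation, n_each = 15, iterations = 3,
                          seed = 21, min_node = 5)
  expect_length(jk$accuracies, 3L)
  expect_lte(jk$mean_accuracy, jk$max_accuracy)

  one <- jackknife_retrain(pool, validation, n_each = 15, iterations = 1,
                           seed = 21, min_node = 5)
  expect_equal(one$mean_accuracy, one$max_accuracy)

  expect_error(jackknife_retrain(pool, pool[1:5, ], n_each = 15,
                                 iterations = 1, seed = 1),
               "overlaps")
  expect_error(jackknife_retrain(pool, validation, n_each = 500,
                                 iterations = 1, seed = 1),
               "n_each")
})

test_that("random regions are size-matched and placeable", {
  q <- cnv_records(chrom = c("chr1", "chr1"), start = c(0, 100),
                   end = c(5e4, 2e5), cnv_type = c("gain", "loss"))
  chroms <- c(chr1 = 1e6, chr2 = 3e5)
  sets <- size_matched_random_regions(q, chroms, n_sets = 50, seed = 31)
  expect_length(sets, 50L)
  for (s in sets[c(1, 25, 50)]) {
    expect_equal(s$end - s$start, q$end - q$start)
    expect_equal(as.character(s$cnv_type), as.character(q$cnv_type))
    expect_true(all(s$start >= 0))
    expect_true(all(s$end <= chroms[s$chrom]))
  }
  # a region longer than chr2 can only land on chr1
  big <- cnv_records("chr1", 0, 5e5, "loss")
  sets2 <- size_matched_random_regions(big, chroms, n_sets = 20, seed = 32)
  expect_true(all(vapply(sets2, function(s) s$chrom, "") == "chr1"))
  expect_error(size_matched_random_regions(
    cnv_records("chr1", 0, 2e6, "loss"), chroms, n_sets = 1, seed = 1),
    "longer than every chromosome")
})

test_that("random-region starts are uniform over placeable positions", {
  q <- cnv_records("chr1", 0, 100, "loss")
  chroms <- c(chr1 = 1e5)
  sets <- size_matched_random_regions(q, chroms, n_sets = 10000, seed = 33)
  starts <- vapply(sets, function(s) s$start, numeric(1))
  expect_true(all(starts >= 0 & starts <= 1e5 - 100))
  bins <- table(cut(starts, breaks = seq(-0.5, 1e5 - 99.5, length.out = 11)))
  expect_gt(stats::chisq.test(bins)$p.value, 0.01)
})

test_that("the enrichment p-value behaves at the extremes", {
  fx <- default_fixture()
  g <- fx$genome
  q <- fx$test_cnvs[1:10, ]
  # a single-class benign model classifies nothing as MR: p must be 1
  ben_only <- train_nbtree(fx$train[fx$train$class_label == "benign", ],
                           seed = 1)
  er <- enrichment_test(q, ben_only, g$tracks, g$genes, g$chrom_lengths,
                        n_sets = 20, seed = 41)
  expect_equal(er$observed_mr_count, 0L)
  expect_equal(er$p_value, 1)
  expect_length(er$null_counts, 20L)

  # small-sample correction bounds p away from zero
  er2 <- enrichment_test(q, fx$model, g$tracks, g$genes, g$chrom_lengths,
                         n_sets = 10, seed = 42,
                         small_sample_correction = TRUE)
  expect_gte(er2$p_value, 1 / 11)
  expect_error(enrichment_test(q, fx$model, g$tracks, g$genes,
                               g$chrom_lengths, n_sets = 0, seed = 1),
               "n_sets")

  # with a fixed null, the p-value weakly decreases in the observed count
  p_at <- vapply(0:5, function(obs) mean(er$null_counts >= obs), numeric(1))
  expect_true(all(diff(p_at) <= 0))
})
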