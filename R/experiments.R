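# Training-design experiments: class-imbalance sweep, optimal
# training-set search, leave-one-feature-out contribution, jack-knife
# retraining, and the size-matched permutation enrichment test.
# All operations are reproducible bit-for-bit from (inputs, params, seed).

# Stack two labeled feature frames, attaching explicit class labels.
.stack_classes <- function(mr, benign) {
  x <- rbind(mr, benign)
  x$class_label <- rep(c("mr", "benign"), c(nrow(mr), nrow(benign)))
  x
}

.test_accuracy <- function(model, test) {
  if (nrow(test) == 0L) return(NA_real_)
  pred <- classify(model, test)
  mean(as.character(pred$predicted_class) == test$class_label)
}

# Plain accuracy plus balanced accuracy (mean of sensitivity and
# specificity); the latter is insensitive to the test set's class mix.
.test_rates <- function(model, test) {
  if (nrow(test) == 0L) return(c(accuracy = NA_real_, balanced = NA_real_))
  pred <- as.character(classify(model, test)$predicted_class)
  truth <- as.character(test$class_label)
  acc <- mean(pred == truth)
  sens <- if (any(truth == "mr")) mean(pred[truth == "mr"] == "mr") else NA
  spec <- if (any(truth == "benign"))
    mean(pred[truth == "benign"] == "benign") else NA
  bal <- mean(c(sens, spec), na.rm = TRUE)
  c(accuracy = acc, balanced = if (is.nan(bal)) NA_real_ else bal)
}

#' Default benign-count grid for the imbalance sweep
#'
#' Benign training counts from half of the available benign CNVs
#' (the most imbalanced level) down to parity with the MR training count
#' (half of the available MR CNVs), in `levels` steps.
#'
#' @param n_mr_avail,n_benign_avail Available CNVs per class.
#' @param levels Number of imbalance levels (default 30).
#' @return Integer vector of benign training counts, decreasing.
#' @export
sweep_grid <- function(n_mr_avail, n_benign_avail, levels = 30) {
  n_mr_train <- n_mr_avail %/% 2
  top <- n_benign_avail %/% 2
  if (top < n_mr_train) stop("fewer benign than MR CNVs available")
  unique(round(seq(top, n_mr_train, length.out = levels)))
}

#' Class-imbalance sweep
#'
#' For each imbalance level, repeatedly samples a training set with a
#' fixed number of MR CNVs (half the MR set) and the level's benign
#' count, trains the classifier, and scores accuracy on all remaining
#' CNVs (kept at their natural class frequency). Reports mean and SD of
#' accuracy per level.
#'
#' @param mr,benign Annotated feature `data.frame`s for each class.
#' @param levels Benign training counts per level; default
#'   [sweep_grid()] of the available counts.
#' @param runs_per_level Training/test runs per level (default 1000).
#' @param seed Integer seed.
#' @param n_mr_train MR training count (default half of `nrow(mr)`).
#' @param ... Passed to [train_nbtree()].
#' @return A `data.frame` (class `sweep_result`) with one row per level:
#'   `n_mr_train`, `n_benign_train`, `runs`, mean and SD of plain test
#'   accuracy and of balanced accuracy (mean of sensitivity and
#'   specificity, insensitive to the changing test-set class mix across
#'   levels); per-run matrices are attached as attributes `"runs"` and
#'   `"runs_balanced"`. Levels with no test instances report `NA`.
#' @export
imbalance_sweep <- function(mr, benign, levels = NULL, runs_per_level = 1000,
                            seed = 1, n_mr_train = NULL, ...) {
  if (is.null(n_mr_train)) n_mr_train <- nrow(mr) %/% 2
  if (is.null(levels)) levels <- sweep_grid(nrow(mr), nrow(benign))
  if (n_mr_train > nrow(mr) || any(levels > nrow(benign)))
    stop("a level requests more CNVs than available")
  acc <- bal <- matrix(NA_real_, length(levels), runs_per_level)
  .with_seed(seed, {
    for (li in seq_along(levels)) {
      for (r in seq_len(runs_per_level)) {
        tr_mr <- sample.int(nrow(mr), n_mr_train)
        tr_b <- sample.int(nrow(benign), levels[li])
        train <- .stack_classes(mr[tr_mr, , drop = FALSE],
                                benign[tr_b, , drop = FALSE])
        test <- .stack_classes(mr[-tr_mr, , drop = FALSE],
                               benign[-tr_b, , drop = FALSE])
        if (nrow(test) == 0L) next
        model <- train_nbtree(train, seed = sample.int(2^30, 1), ...)
        rates <- .test_rates(model, test)
        acc[li, r] <- rates[["accuracy"]]
        bal[li, r] <- rates[["balanced"]]
      }
    }
  })
  out <- data.frame(
    n_mr_train = n_mr_train,
    n_benign_train = levels,
    runs = rowSums(!is.na(acc)),
    mean_accuracy = rowMeans(acc, na.rm = TRUE),
    sd_accuracy = apply(acc, 1, stats::sd, na.rm = TRUE),
    mean_balanced_accuracy = rowMeans(bal, na.rm = TRUE),
    sd_balanced_accuracy = apply(bal, 1, stats::sd, na.rm = TRUE)
  )
  out$mean_accuracy[out$runs == 0] <- NA_real_
  out$mean_balanced_accuracy[out$runs == 0] <- NA_real_
  attr(out, "runs") <- acc
  attr(out, "runs_balanced") <- bal
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Optimal training-set search
#'
#' Re-samples balanced training sets (`n_each` CNVs per class, without
#' replacement) over many iterations, training and scoring each on the
#' held-out remainder, and returns the best-scoring set.
#'
#' @param mr,benign Annotated feature `data.frame`s for each class.
#' @param n_each Training CNVs per class (default 82).
#' @param iterations Number of random draws (default 10000).
#' @param seed Integer seed.
#' @param ... Passed to [train_nbtree()].
#' @return A list with `best_mr_idx`/`best_benign_idx` (row indices of
#'   the winning training set), `best_accuracy`, `best_model` and
#'   `accuracy_distribution` (length `iterations`).
#' @export
select_optimal_training_set <- function(mr, benign, n_each = 82,
                                        iterations = 10000, seed = 1, ...) {
  if (iterations < 1) stop("iterations must be >= 1")
  if (n_each > nrow(mr) || n_each > nrow(benign))
    stop("n_each exceeds the available CNVs of a class")
  best <- list(accuracy = -Inf)
  dist <- numeric(iterations)
  .with_seed(seed, {
    for (it in seq_len(iterations)) {
      tr_mr <- sample.int(nrow(mr), n_each)
      tr_b <- sample.int(nrow(benign), n_each)
      train <- .stack_classes(mr[tr_mr, , drop = FALSE],
                              benign[tr_b, , drop = FALSE])
      test <- .stack_classes(mr[-tr_mr, , drop = FALSE],
                             benign[-tr_b, , drop = FALSE])
      model <- train_nbtree(train, seed = sample.int(2^30, 1), ...)
      dist[it] <- .test_accuracy(model, test)
      if (!is.na(dist[it]) && dist[it] > best$accuracy) {
        best <- list(accuracy = dist[it], mr_idx = tr_mr, benign_idx = tr_b,
                     model = model)
      }
    }
  })
  list(best_mr_idx = sort(best$mr_idx), best_benign_idx = sort(best$benign_idx),
       best_accuracy = best$accuracy, best_model = best$model,
       accuracy_distribution = dist)
}

#' Default leave-one-out feature groups
#'
#' One group per feature, except that removing the length feature also
#' removes the length-coupled element and gene counts, so that the
#' contribution of length is not re-expressed through raw counts.
#'
#' @param feature_names Features in the matrix.
#' @return Named list of character vectors (features removed together).
#' @export
default_feature_groups <- function(feature_names = candidate_features()) {
  groups <- lapply(feature_names, function(f) f)
  names(groups) <- feature_names
  coupled <- intersect(c("n_line", "n_sine", "n_segdup", "n_gene"),
                       feature_names)
  if ("length_bp" %in% feature_names)
    groups[["length_bp"]] <- c("length_bp", coupled)
  groups
}

#' Leave-one-feature-out contribution analysis
#'
#' Trains a baseline model on all features, then for each feature (or
#' coupled feature group) retrains without it under identical sampling
#' and reports the decline in test accuracy in percentage points. A
#' zero-or-negative decline marks the feature as droppable.
#'
#' @param train,test Labeled feature `data.frame`s (with `class_label`).
#' @param feature_groups Named list of feature groups to remove; default
#'   [default_feature_groups()] over the training features.
#' @param seed Integer seed (shared by all retrainings).
#' @param ... Passed to [train_nbtree()].
#' @return A `data.frame` with `feature` (group name), `removed`
#'   (features removed, comma-joined), `accuracy_without` and
#'   `decline_pct_points` (baseline minus without, in points); baseline
#'   accuracy attached as attribute `"baseline_accuracy"`.
#' @export
feature_contribution <- function(train, test, feature_groups = NULL,
                                 seed = 1, ...) {
  feats <- setdiff(colnames(train), "class_label")
  if (is.null(feature_groups)) feature_groups <- default_feature_groups(feats)
  baseline_model <- train_nbtree(train, seed = seed, ...)
  baseline <- .test_accuracy(baseline_model, test)
  rows <- lapply(names(feature_groups), function(g) {
    drop <- feature_groups[[g]]
    keep <- setdiff(feats, drop)
    if (!length(keep)) stop("removing group '", g, "' leaves no features")
    m <- train_nbtree(train[, c(keep, "class_label"), drop = FALSE],
                      seed = seed, ...)
    acc <- .test_accuracy(m, test[, c(keep, "class_label"), drop = FALSE])
    data.frame(feature = g, removed = paste(drop, collapse = ","),
               accuracy_without = acc,
               decline_pct_points = 100 * (baseline - acc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline_accuracy") <- baseline
  out
}

#' Jack-knife retraining against a fixed validation set
#'
#' Repeatedly draws balanced training sets (`n_each` per class) from a
#' pooled training+test collection, trains, and scores each model on an
#' independent validation set, reporting the mean and maximum accuracy.
#' Errors if the validation set shares any instance with the pool
#' (leakage guard).
#'
#' @param pool Labeled feature `data.frame` (training + test pooled).
#' @param validation Labeled feature `data.frame`, disjoint from `pool`.
#' @param n_each Per-class training count (default 164).
#' @param iterations Number of draws (default 10000).
#' @param seed Integer seed.
#' @param ... Passed to [train_nbtree()].
#' @return A list with `mean_accuracy`, `max_accuracy` and `accuracies`.
#' @export
jackknife_retrain <- function(pool, validation, n_each = 164,
                              iterations = 10000, seed = 1, ...) {
  key <- function(d) do.call(paste, c(d[setdiff(colnames(d), "class_label")],
                                      sep = "\r"))
  if (any(key(validation) %in% key(pool)))
    stop("validation set overlaps the training pool")
  mr_rows <- which(pool$class_label == "mr")
  b_rows <- which(pool$class_label == "benign")
  if (n_each > length(mr_rows) || n_each > length(b_rows))
    stop("n_each exceeds the pooled CNVs of a class")
  accs <- numeric(iterations)
  .with_seed(seed, {
    for (it in seq_len(iterations)) {
      rows <- c(sample(mr_rows, n_each), sample(b_rows, n_each))
      model <- train_nbtree(pool[rows, , drop = FALSE],
                            seed = sample.int(2^30, 1), ...)
      accs[it] <- .test_accuracy(model, validation)
    }
  })
  list(mean_accuracy = mean(accs), max_accuracy = max(accs),
       accuracies = accs)
}

#' Size-matched random genomic regions
#'
#' For each query CNV, draws one random region of identical length per
#' permutation set, uniformly over placeable positions: the chromosome
#' is chosen with probability proportional to `chrom_len - L + 1` and
#' the start uniformly within it. The query's gain/loss type is carried
#' over (regions are matched for size and type).
#'
#' @param query_cnvs CNV `data.frame`.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param n_sets Number of permutation sets (default 1000).
#' @param seed Integer seed.
#' @return A list of `n_sets` CNV `data.frame`s.
#' @export
size_matched_random_regions <- function(query_cnvs, chrom_lengths,
                                        n_sets = 1000, seed = 1) {
  lens <- query_cnvs$end - query_cnvs$start
  nq <- length(lens)
  chrom_mat <- matrix(NA_character_, nq, n_sets)
  start_mat <- matrix(NA_real_, nq, n_sets)
  .with_seed(seed, {
    for (i in seq_len(nq)) {
      w <- pmax(0, chrom_lengths - lens[i] + 1)
      if (all(w == 0))
        stop("query region ", i, " (", lens[i],
             " bp) is longer than every chromosome")
      ch <- sample(names(chrom_lengths), n_sets, replace = TRUE, prob = w)
      start_mat[i, ] <- floor(stats::runif(n_sets) *
                                (chrom_lengths[ch] - lens[i] + 1))
      chrom_mat[i, ] <- ch
    }
  })
  lapply(seq_len(n_sets), function(s) {
    cnv_records(chrom = chrom_mat[, s], start = start_mat[, s],
                end = start_mat[, s] + lens,
                cnv_type = as.character(query_cnvs$cnv_type))
  })
}

#' Permutation enrichment test for MR-classified CNVs
#'
#' Counts how many query CNVs the model classifies as MR, generates
#' `n_sets` size-matched random region sets, annotates and classifies
#' each, and reports the proportion of null sets with an MR count at
#' least as large as observed.
#'
#' @param query_cnvs CNV `data.frame`.
#' @param model Trained `nbtree`.
#' @param tracks Named list of annotation tracks (LINE/SINE/segdup).
#' @param genes Gene table.
#' @param chrom_lengths Named chromosome-length vector.
#' @param n_sets Number of permutation sets (default 1000).
#' @param seed Integer seed.
#' @param small_sample_correction Use `(b + 1) / (n + 1)` instead of the
#'   plain proportion `b / n` (default `FALSE`).
#' @return A list of class `enrichment_result` with `observed_mr_count`,
#'   `null_counts` and `p_value`.
#' @export
enrichment_test <- function(query_cnvs, model, tracks, genes, chrom_lengths,
                            n_sets = 1000, seed = 1,
                            small_sample_correction = FALSE) {
  if (n_sets < 1) stop("n_sets must be >= 1")
  obs_feat <- annotate_cnvs(query_cnvs, tracks, genes)
  observed <- sum(classify(model, obs_feat)$predicted_class == "mr")
  sets <- size_matched_random_regions(query_cnvs, chrom_lengths, n_sets, seed)
  pooled <- do.call(rbind, sets)
  pooled_feat <- annotate_cnvs(pooled, tracks, genes)
  pred_mr <- classify(model, pooled_feat)$predicted_class == "mr"
  set_id <- rep(seq_len(n_sets), each = nrow(query_cnvs))
  null_counts <- as.integer(rowsum(as.integer(pred_mr), set_id))
  b <- sum(null_counts >= observed)
  p <- if (small_sample_correction) (b + 1) / (n_sets + 1) else b / n_sets
  structure(list(observed_mr_count = observed, null_counts = null_counts,
                 p_value = p),
            class = "enrichment_result")
}
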