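test_that("leaf conditionals follow the Laplace smoothing formula", {
  x <- data.frame(f = factor(rep(c("true", "false"), each = 4),
                             levels = c("false", "true")))
  lab <- rep(c("mr", "benign"), each = 4)
  leaf <- train_nb_leaf(x, lab, laplace = 1)
  cond <- leaf$features$f$cond
  # 4 of 4 mr instances are true: (4 + 1) / (4 + 2)
  expect_equal(unname(cond["mr", 2]), 5 / 6)
  expect_equal(unname(cond["benign", 2]), 1 / 6)
  expect_equal(unname(rowSums(cond)), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(leaf$priors), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("an all-missing feature leaves uniform conditionals", {
  x <- data.frame(f = factor(rep(NA_character_, 6),
                             levels = c("a", "b", "c")),
                  g = c(1, 2, 3, 4, 5, 6))
  leaf <- train_nb_leaf(x, rep(c("mr", "benign"), 3))
  expect_equal(unname(leaf$features$f$cond["mr", ]), rep(1 / 3, 3))
  expect_equal(unname(leaf$features$f$cond["benign", ]), rep(1 / 3, 3))
})

test_that("posteriors match a brute-force Bayes product", {
  set.seed(21)
  for (rep in 1:3) {
    x <- data.frame(
      a = factor(sample(c("u", "v", "w"), 30, replace = TRUE)),
      b = factor(sample(c("y", "n"), 30, replace = TRUE)),
      c = factor(ifelse(runif(30) < 0.2, NA, sample(c("p", "q"), 30,
                                                    replace = TRUE)),
                 levels = c("p", "q"))
    )
    lab <- sample(c("mr", "benign"), 30, replace = TRUE,
                  prob = c(0.4, 0.6))
    if (length(unique(lab)) < 2) next
    leaf <- train_nb_leaf(x, lab)
    for (i in c(1, 7, 13, 25)) {
      expect_equal(nb_posterior(leaf, x[i, ]),
                   brute_nb_posterior_mr(x, lab, x[i, ]),
                   tolerance = 1e-10)
    }
  }
})

test_that("posterior degenerates sensibly without evidence", {
  x <- data.frame(f = factor(c("a", "b", "a", "b")))
  leaf <- train_nb_leaf(x, c("mr", "mr", "benign", "benign"))
  # all features missing: prior only, uniform priors give 0.5
  expect_equal(nb_posterior(leaf, data.frame(f = factor(NA,
                                                        levels = c("a", "b")))),
               0.5, tolerance = 1e-12)

  # hand-built leaf with a 9:1 likelihood ratio and uniform priors
  leaf2 <- structure(list(
    classes = c("benign", "mr"),
    priors = c(benign = 0.5, mr = 0.5),
    laplace = 1, n_train = 2,
    features = list(f = list(
      name = "f", type = "categorical", levels = c("false", "true"),
      cut_points = NULL,
      cond = matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE,
                    dimnames = list(c("benign", "mr"), NULL))
    ))
  ), class = "nb_leaf")
  expect_equal(nb_posterior(leaf2, data.frame(f = "true")), 0.9,
               tolerance = 1e-12)
})

test_that("a depth-0 tree reproduces plain Naive Bayes exactly", {
  for (seed in 1:5) {
    d <- random_labeled_dataset(100, seed)
    x <- d[, setdiff(names(d), "class_label")]
    model <- train_nbtree(d, max_depth = 0, seed = seed)
    leaf <- train_nb_leaf(x, d$class_label)
    expect_equal(classify(model, x)$mr_distance, nb_posterior(leaf, x),
                 tolerance = 1e-10)
  }
})

test_that("linearly separable classes are learned perfectly", {
  set.seed(31)
  n <- 200
  lab <- rep(c("mr", "benign"), each = n / 2)
  d <- data.frame(
    f1 = c(rnorm(n / 2, 10), rnorm(n / 2, -10)),
    f2 = rnorm(n),
    class_label = lab
  )
  model <- train_nbtree(d, seed = 1)
  pred <- classify(model, d)
  expect_equal(mean(as.character(pred$predicted_class) == lab), 1.0)
})

test_that("single-class input yields a degenerate constant classifier", {
  d <- data.frame(f1 = rnorm(40), class_label = rep("mr", 40))
  model <- train_nbtree(d, seed = 1)
  pred <- classify(model, d[, "f1", drop = FALSE])
  expect_true(all(pred$predicted_class == "mr"))
  expect_true(all(pred$mr_distance == 1))
})

test_that("training is deterministic given data, params and seed", {
  d <- random_labeled_dataset(150, 9)
  m1 <- train_nbtree(d, seed = 123)
  m2 <- train_nbtree(d, seed = 123)
  expect_identical(m1, m2)
  x <- d[, setdiff(names(d), "class_label")]
  expect_identical(classify(m1, x), classify(m2, x))
})

test_that("swapping class labels complements the MR distance", {
  d <- random_labeled_dataset(120, 13)
  swapped <- d
  swapped$class_label <- ifelse(d$class_label == "mr", "benign", "mr")
  x <- d[, setdiff(names(d), "class_label")]
  m1 <- train_nbtree(d, seed = 77)
  m2 <- train_nbtree(swapped, seed = 77)
  expect_equal(classify(m1, x)$mr_distance,
               1 - classify(m2, x)$mr_distance, tolerance = 1e-10)
})

test_that("stronger class-conditional evidence never lowers the posterior", {
  dist <- vapply(1:7, function(kk) {
    # kk of 8 mr instances carry the marker; benign counts fixed
    f <- factor(c(rep("true", kk), rep("false", 8 - kk), rep("false", 8)),
                levels = c("false", "true"))
    leaf <- train_nb_leaf(data.frame(f = f),
                          rep(c("mr", "benign"), each = 8))
    nb_posterior(leaf, data.frame(f = "true"))
  }, numeric(1))
  expect_true(all(diff(dist) >= 0))
})

test_that("a missing split value averages the child posteriors", {
  # two regimes along split_f with opposite label-vs-other orientation:
  # a single Naive Bayes model cannot fit both, so the tree must split
  set.seed(41)
  n <- 240
  split_f <- c(rnorm(n / 2, -5), rnorm(n / 2, 5))
  other <- rnorm(n)
  thr <- qnorm(0.3)
  lab <- ifelse(seq_len(n) <= n / 2,
                ifelse(other > thr, "mr", "benign"),
                ifelse(other < thr, "mr", "benign"))
  d <- data.frame(split_f = split_f, other = other, class_label = lab)
  model <- train_nbtree(d, min_node = 10, seed = 2)
  expect_gt(n_leaves(model), 1L)
  node <- model$node
  expect_equal(node$kind, "split")
  x_na <- data.frame(split_f = NA_real_, other = 0.7)
  got <- classify(model, x_na)$mr_distance
  manual <- 0
  for (ci in seq_along(node$children)) {
    child <- node$children[[ci]]
    expect_equal(child$kind, "leaf")
    manual <- manual + node$weights[ci] * nb_posterior(child$leaf, x_na)
  }
  expect_equal(got, manual, tolerance = 1e-12)
})

test_that("classification rejects vectors lacking model features", {
  d <- random_labeled_dataset(60, 3)
  model <- train_nbtree(d, seed = 5)
  expect_error(classify(model, d[, c("f1", "f2")]), "f3")
})

test_that("MR distances are valid probabilities across datasets", {
  for (seed in c(2, 8)) {
    d <- random_labeled_dataset(100, seed)
    model <- train_nbtree(d, min_node = 15, seed = seed)
    p <- classify(model, d[, setdiff(names(d), "class_label")])$mr_distance
    expect_true(all(p >= 0 & p <= 1))
    expect_true(all(is.finite(p)))
  }
})
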