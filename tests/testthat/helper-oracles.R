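# Independent brute-force oracles used to cross-check the implementation.

# O(n) exhaustive overlap scan (0-based half-open).
brute_count_overlaps <- function(cnv, track) {
  n <- 0L
  for (i in seq_len(nrow(track))) {
    if (track$chrom[i] == cnv$chrom[1] &&
        track$start[i] < cnv$end[1] && track$end[i] > cnv$start[1]) {
      n <- n + 1L
    }
  }
  n
}

# O(n^2) pairwise-concordance AUC with half credit for ties.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == "mr"]
  neg <- scores[labels == "benign"]
  s <- 0
  for (p in pos) for (q in neg) {
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

# VIF by explicit normal equations, one feature at a time.
brute_vif <- function(x) {
  x <- as.matrix(x)
  vapply(seq_len(ncol(x)), function(j) {
    y <- x[, j]
    A <- cbind(1, x[, -j, drop = FALSE])
    beta <- solve(t(A) %*% A, t(A) %*% y)
    rss <- sum((y - A %*% beta)^2)
    tss <- sum((y - mean(y))^2)
    1 / (rss / tss)
  }, numeric(1))
}

# Naive recursive MDL discretization: plain loops, same accept rule.
brute_entropy <- function(lab) {
  p <- table(lab) / length(lab)
  p <- p[p > 0]
  -sum(p * log2(p))
}
brute_mdl_cuts <- function(v, lab) {
  ok <- !is.na(v)
  v <- v[ok]
  lab <- as.character(lab)[ok]
  o <- order(v)
  rec <- function(v, lab) {
    n <- length(v)
    if (n < 2 || length(unique(lab)) < 2 || v[1] == v[n]) return(numeric(0))
    best <- NULL
    for (i in seq_len(n - 1)) {
      if (v[i] < v[i + 1]) {
        e <- (i * brute_entropy(lab[1:i]) +
                (n - i) * brute_entropy(lab[(i + 1):n])) / n
        if (is.null(best) || e < best$e) best <- list(i = i, e = e)
      }
    }
    if (is.null(best)) return(numeric(0))
    i <- best$i
    gain <- brute_entropy(lab) - best$e
    k <- length(unique(lab))
    k1 <- length(unique(lab[1:i]))
    k2 <- length(unique(lab[(i + 1):n]))
    delta <- log2(3^k - 2) -
      (k * brute_entropy(lab) - k1 * brute_entropy(lab[1:i]) -
         k2 * brute_entropy(lab[(i + 1):n]))
    if (gain <= (log2(n - 1) + delta) / n) return(numeric(0))
    c(rec(v[1:i], lab[1:i]),
      (v[i] + v[i + 1]) / 2,
      rec(v[(i + 1):n], lab[(i + 1):n]))
  }
  sort(rec(v[o], lab[o]))
}

# Naive Bayes posterior for categorical-only instance tables, computed
# as an explicit Bayes product with Laplace smoothing.
brute_nb_posterior_mr <- function(train, labels, x, laplace = 1) {
  classes <- sort(unique(as.character(labels)))
  logp <- vapply(classes, function(cl) {
    rows <- as.character(labels) == cl
    lp <- log(mean(rows))
    for (f in names(train)) {
      xv <- as.character(x[[f]])
      if (is.na(xv)) next
      col <- train[[f]]
      lv <- if (is.factor(col)) levels(col)
      else sort(unique(as.character(col[!is.na(col)])))
      cnt <- sum(!is.na(col[rows]) & as.character(col[rows]) == xv)
      nm <- sum(!is.na(col[rows]))
      lp <- lp + log((cnt + laplace) / (nm + laplace * length(lv)))
    }
    lp
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  unname(p[classes == "mr"])
}

# Random mixed-type labeled dataset for classifier equivalence checks.
random_labeled_dataset <- function(n, seed) {
  set.seed(seed)
  lab <- rep(c("mr", "benign"), length.out = n)[sample.int(n)]
  shift <- ifelse(lab == "mr", 1, 0)
  data.frame(
    f1 = rnorm(n, mean = shift),
    f2 = rnorm(n, mean = -0.5 * shift, sd = 2),
    f3 = ifelse(runif(n) < 0.1, NA, rnorm(n)),
    f4 = factor(ifelse(runif(n) < 0.3 + 0.3 * shift, "a", "b"),
                levels = c("a", "b")),
    class_label = lab,
    stringsAsFactors = FALSE
  )
}
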