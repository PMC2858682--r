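# Supervised discretization of continuous attributes by recursive
# entropy minimization with the minimum-description-length (MDL)
# stopping rule (Fayyad & Irani 1993). Used inside Naive Bayes leaves.

.entropy <- function(counts) {
  tot <- sum(counts)
  if (tot == 0) return(0)
  p <- counts[counts > 0] / tot
  -sum(p * log2(p))
}

# Row-wise entropy of a count matrix (rows = candidate partitions).
.ent_rows <- function(M) {
  tot <- rowSums(M)
  P <- M / pmax(tot, 1)
  PL <- P * log2(P)
  PL[P == 0] <- 0
  -rowSums(PL)
}

#' Supervised MDL discretization
#'
#' Finds cut points for a continuous attribute by recursive binary
#' splitting on class-information gain; a split is accepted only when the
#' gain exceeds the MDL cost of encoding it. Pure-class or constant
#' inputs yield no cut points. Deterministic.
#'
#' @param values Numeric attribute values (`NA` ignored).
#' @param labels Class labels aligned with `values`.
#' @return An object of class `discretization`: a list with `cut_points`
#'   (strictly increasing thresholds; empty means a single bin) and
#'   `n_bins`.
#' @export
discretize_mdl <- function(values, labels) {
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]
  labels <- as.character(labels)[ok]
  cuts <- numeric(0)
  if (length(values) >= 2L) {
    ord <- order(values, method = "radix")
    classes <- unique(labels)
    cuts <- if (length(classes) == 2L) {
      # compiled fast path for the binary-class case; the recursion
      # emits cut points in ascending order already
      .mdl_split2_cpp(as.numeric(values[ord]),
                      as.integer(labels[ord] == classes[2L]))
    } else {
      sort(.mdl_split(values[ord], labels[ord]))
    }
  }
  structure(list(cut_points = cuts, n_bins = length(cuts) + 1L),
            class = "discretization")
}


# Recursive splitter on a sorted block; returns accepted cut values.
.mdl_split <- function(v, lab) {
  n <- length(v)
  classes <- unique(lab)
  if (n < 2L || length(classes) < 2L || v[1] == v[n]) return(numeric(0))

  lab_i <- match(lab, classes)
  k <- length(classes)
  # cumulative class counts at every prefix
  cum <- vapply(seq_len(k), function(c) cumsum(lab_i == c), numeric(n))
  total <- cum[n, ]
  ent_all <- .entropy(total)

  # candidate boundaries: between adjacent distinct values
  cand <- which(v[-n] < v[-1])
  if (!length(cand)) return(numeric(0))

  left <- cum[cand, , drop = FALSE]
  right <- rep(total, each = length(cand))
  dim(right) <- dim(left)
  right <- right - left
  ent_l <- .ent_rows(left)
  ent_r <- .ent_rows(right)
  gains <- ent_all - (cand * ent_l + (n - cand) * ent_r) / n
  b <- which.max(gains)
  best_gain <- gains[b]
  best_i <- cand[b]

  k1 <- sum(left[b, ] > 0)
  k2 <- sum(right[b, ] > 0)
  delta <- log2(3^k - 2) - (k * ent_all - k1 * ent_l[b] - k2 * ent_r[b])
  threshold <- (log2(n - 1) + delta) / n
  if (best_gain <= threshold) return(numeric(0))

  cut <- (v[best_i] + v[best_i + 1]) / 2
  c(.mdl_split(v[seq_len(best_i)], lab[seq_len(best_i)]),
    cut,
    .mdl_split(v[(best_i + 1):n], lab[(best_i + 1):n]))
}

#' Map continuous values to discretization bins
#'
#' @param disc A `discretization` from [discretize_mdl()].
#' @param values Numeric values (`NA` stays `NA`).
#' @return Integer bin indices in `1..n_bins`.
#' @export
apply_discretization <- function(disc, values) {
  findInterval(values, disc$cut_points) + 1L
}
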