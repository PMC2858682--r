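# Hybrid decision-tree / Naive Bayes classifier (NBTree, after Kohavi
# 1996): a tree with univariate splits is grown only where the
# cross-validated accuracy of a Naive Bayes model improves sufficiently;
# each leaf holds a Naive Bayes model over MDL-discretized attributes.
#
# Internally a node's instances are mapped to integer bin indices
# (categorical level or discretization bin, NA = missing) so Naive Bayes
# fitting and prediction reduce to tabulate() and table lookups.

.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.feature_type <- function(v) {
  if (is.numeric(v)) "continuous" else "categorical"
}

# Bin a node's instances. Discretizations for continuous features are
# learned on the node's own (value, label) pairs.
.node_binning <- function(x, labels, types, levels_list) {
  p <- ncol(x)
  n <- nrow(x)
  bins <- matrix(NA_integer_, n, p)
  nbins <- integer(p)
  disc <- vector("list", p)
  for (j in seq_len(p)) {
    v <- x[[j]]
    if (types[j] == "categorical") {
      bins[, j] <- match(as.character(v), levels_list[[j]])
      nbins[j] <- length(levels_list[[j]])
    } else {
      d <- discretize_mdl(v, labels)
      disc[[j]] <- d
      bins[, j] <- apply_discretization(d, v)
      nbins[j] <- d$n_bins
    }
  }
  list(bins = bins, nbins = nbins, disc = disc)
}

# Class-conditional bin counts and per-class non-missing totals.
.nb_counts <- function(bins, nbins, yidx, k) {
  offs <- cumsum(c(0L, nbins))[seq_along(nbins)]
  tot <- sum(nbins)
  G <- bins + rep(offs, each = nrow(bins))
  counts <- matrix(0, k, tot)
  nm <- matrix(0, k, length(nbins))
  for (c in seq_len(k)) {
    g <- G[yidx == c, , drop = FALSE]
    ok <- !is.na(g)
    counts[c, ] <- tabulate(g[ok], nbins = tot)
    nm[c, ] <- colSums(ok)
  }
  list(counts = counts, nm = nm, offs = offs, tot = tot,
       class_n = tabulate(yidx, nbins = k))
}

# Laplace-smoothed conditional probabilities -> log space fit.
.nb_fit <- function(bins, nbins, yidx, k, laplace) {
  ct <- .nb_counts(bins, nbins, yidx, k)
  cond <- ct$counts
  for (j in seq_along(nbins)) {
    idx <- ct$offs[j] + seq_len(nbins[j])
    cond[, idx] <- (ct$counts[, idx, drop = FALSE] + laplace) /
      (ct$nm[, j] + laplace * nbins[j])
  }
  list(logprior = log(ct$class_n / sum(ct$class_n)),
       logcond = log(cond), offs = ct$offs)
}

# Posterior matrix (n x k) for pre-binned instances.
.nb_scores <- function(fit, bins) {
  n <- nrow(bins)
  k <- length(fit$logprior)
  G <- bins + rep(fit$offs, each = n)
  S <- matrix(fit$logprior, n, k, byrow = TRUE)
  for (c in seq_len(k)) {
    M <- matrix(fit$logcond[c, ][G], n)
    M[is.na(M)] <- 0
    S[, c] <- S[, c] + rowSums(M)
  }
  m <- S[, 1]
  for (c in seq_len(k)[-1]) m <- pmax(m, S[, c])
  P <- exp(S - m)
  P / rowSums(P)
}

# k-fold cross-validated Naive Bayes accuracy on pre-binned instances.
# Fold assignment consumes the caller's RNG stream (the only randomness
# in tree induction). Per-fold training counts are obtained by
# subtracting the fold's counts from the node totals.
.cv_utility <- function(bins, nbins, yidx, k, folds, laplace) {
  n <- nrow(bins)
  folds <- max(2L, min(folds, n))
  offs <- cumsum(c(0L, nbins))[seq_along(nbins)]
  tot <- sum(nbins)
  G <- bins + rep(offs, each = n)
  featidx <- rep.int(seq_along(nbins), nbins)
  lap_exp <- laplace * nbins[featidx]
  fold_id <- sample(rep_len(seq_len(folds), n))

  counts_f <- array(0, c(k, tot, folds))
  nm_f <- array(0, c(k, length(nbins), folds))
  cn_f <- matrix(0, k, folds)
  for (c in seq_len(k)) {
    for (f in seq_len(folds)) {
      rows <- yidx == c & fold_id == f
      cn_f[c, f] <- sum(rows)
      g <- G[rows, , drop = FALSE]
      ok <- !is.na(g)
      counts_f[c, , f] <- tabulate(g[ok], nbins = tot)
      nm_f[c, , f] <- colSums(ok)
    }
  }
  counts_all <- rowSums(counts_f, dims = 2)
  nm_all <- rowSums(nm_f, dims = 2)
  cn_all <- rowSums(cn_f)

  correct <- 0L
  for (f in seq_len(folds)) {
    te <- which(fold_id == f)
    if (!length(te) || length(te) == n) next
    cnts <- counts_all - counts_f[, , f, drop = FALSE][, , 1]
    nm <- nm_all - nm_f[, , f, drop = FALSE][, , 1]
    if (k == 1L) { dim(cnts) <- c(1L, tot); dim(nm) <- c(1L, length(nbins)) }
    denom <- nm[, featidx, drop = FALSE] + rep(lap_exp, each = k)
    logcond <- log((cnts + laplace) / denom)
    cn <- cn_all - cn_f[, f]
    logprior <- log(cn / sum(cn))
    Gt <- G[te, , drop = FALSE]
    S <- matrix(logprior, length(te), k, byrow = TRUE)
    for (c in seq_len(k)) {
      M <- matrix(logcond[c, ][Gt], length(te))
      M[is.na(M)] <- 0
      S[, c] <- S[, c] + rowSums(M)
    }
    pred <- max.col(S, ties.method = "first")
    correct <- correct + sum(pred == yidx[te])
  }
  correct / n
}

# Best binary threshold of a continuous feature by information gain on
# the labels, restricted to the feature's MDL cut points at this node.
.best_threshold <- function(v, yidx, k, cuts) {
  if (!length(cuts)) return(NULL)
  ok <- !is.na(v)
  if (!any(ok)) return(NULL)
  tot <- tabulate(yidx[ok], nbins = k)
  ent_all <- .entropy(tot)
  nT <- sum(tot)
  best <- NULL
  for (th in cuts) {
    le <- ok & v <= th
    left <- tabulate(yidx[le], nbins = k)
    right <- tot - left
    nl <- sum(left)
    gain <- ent_all - (nl * .entropy(left) + (nT - nl) * .entropy(right)) / nT
    if (is.null(best) || gain > best$gain) best <- list(gain = gain, th = th)
  }
  best$th
}

# Assemble the serializable leaf model from node data.
.build_leaf <- function(x, yidx, classes, types, levels_list, laplace,
                        binning = NULL) {
  k <- length(classes)
  labels <- classes[yidx]
  if (is.null(binning)) .node_binning(x, labels, types, levels_list) -> binning
  ct <- .nb_counts(binning$bins, binning$nbins, yidx, k)
  features <- vector("list", ncol(x))
  for (j in seq_len(ncol(x))) {
    idx <- ct$offs[j] + seq_len(binning$nbins[j])
    cond <- (ct$counts[, idx, drop = FALSE] + laplace) /
      (ct$nm[, j] + laplace * binning$nbins[j])
    rownames(cond) <- classes
    features[[j]] <- list(
      name = colnames(x)[j],
      type = types[j],
      levels = if (types[j] == "categorical") levels_list[[j]] else NULL,
      cut_points = if (types[j] == "continuous")
        binning$disc[[j]]$cut_points else NULL,
      cond = cond
    )
  }
  names(features) <- colnames(x)
  structure(list(
    classes = classes,
    priors = stats::setNames(ct$class_n / sum(ct$class_n), classes),
    laplace = laplace,
    n_train = nrow(x),
    features = features
  ), class = "nb_leaf")
}

#' Train a Naive Bayes leaf model
#'
#' Fits a Naive Bayes model with Laplace smoothing. Continuous attributes
#' are discretized by supervised MDL binning ([discretize_mdl()]);
#' categorical attributes use their levels directly. Class priors are the
#' class frequencies; conditionals are `(count + laplace) /
#' (class_non_missing + laplace * n_bins)`. Missing attribute values
#' contribute to no count.
#'
#' @param instances A `data.frame` of attributes (numeric = continuous;
#'   factor/character/logical = categorical).
#' @param labels Class labels aligned with rows.
#' @param laplace Smoothing constant (default 1).
#' @return An object of class `nb_leaf`.
#' @export
train_nb_leaf <- function(instances, labels, laplace = 1) {
  if (nrow(instances) == 0L) stop("cannot train on an empty instance set")
  labels <- as.character(labels)
  if (anyNA(labels)) stop("labels must not be missing")
  classes <- sort(unique(labels))
  types <- vapply(instances, .feature_type, character(1))
  levels_list <- lapply(instances, function(v) {
    if (.feature_type(v) == "categorical") {
      if (is.factor(v)) levels(v) else sort(unique(as.character(v[!is.na(v)])))
    } else NULL
  })
  .build_leaf(instances, match(labels, classes), classes, types, levels_list,
              laplace)
}

# Posterior matrix of a leaf for new raw instances.
.leaf_scores <- function(leaf, x) {
  n <- nrow(x)
  k <- length(leaf$classes)
  S <- matrix(log(leaf$priors), n, k, byrow = TRUE)
  for (f in leaf$features) {
    v <- x[[f$name]]
    if (is.null(v)) stop("instance lacks feature '", f$name, "'")
    b <- if (f$type == "categorical") match(as.character(v), f$levels)
    else findInterval(as.numeric(v), f$cut_points) + 1L
    L <- log(f$cond)
    for (c in seq_len(k)) {
      contrib <- L[c, ][b]
      contrib[is.na(contrib)] <- 0
      S[, c] <- S[, c] + contrib
    }
  }
  m <- S[, 1]
  for (c in seq_len(k)[-1]) m <- pmax(m, S[, c])
  P <- exp(S - m)
  P <- P / rowSums(P)
  colnames(P) <- leaf$classes
  P
}

#' Naive Bayes posterior probability of the pathogenic (MR) class
#'
#' `P(mr | x)` is proportional to `prior(mr)` times the product of the
#' class-conditional probabilities of the non-missing attribute values,
#' normalized over both classes; missing attributes are skipped. With
#' uniform priors and all attributes missing the posterior is 0.5.
#'
#' @param leaf An `nb_leaf` model.
#' @param feature_vector A one-row `data.frame` (or list) with the leaf's
#'   attributes; values may be `NA`.
#' @return The MR-class posterior ("MR distance") in `[0, 1]`.
#' @export
nb_posterior <- function(leaf, feature_vector) {
  x <- as.data.frame(feature_vector, stringsAsFactors = FALSE)
  P <- .leaf_scores(leaf, x)
  if ("mr" %in% colnames(P)) unname(P[, "mr"]) else rep(0, nrow(P))
}

#' Train a hybrid decision-tree / Naive Bayes classifier
#'
#' Grows a decision tree whose leaves are Naive Bayes models. At each
#' node the utility of keeping a single Naive Bayes model is estimated by
#' `utility_folds`-fold cross-validated accuracy; every feature's best
#' univariate split (thresholds from supervised MDL cut points for
#' continuous features; an equality partition for categorical features)
#' is scored by the instance-weighted cross-validated accuracy of its
#' children. The node is split only when the best split reduces the error
#' by at least `min_rel_improvement` relative to the node model and every
#' child holds at least `min_node` instances; otherwise the node becomes
#' a leaf. Fold assignment is the only randomness, so results are fully
#' determined by `seed`.
#'
#' @param x Feature `data.frame` (a `class_label` column, if present, is
#'   dropped from the attributes).
#' @param labels Class labels; defaults to `x$class_label`.
#' @param min_node Minimum instances per child for a split (default 30).
#' @param utility_folds Cross-validation folds for utility (default 5).
#' @param min_rel_improvement Minimum relative error reduction to accept
#'   a split (default 0.05).
#' @param max_depth Maximum tree depth; 0 forces a single Naive Bayes
#'   leaf, reproducing [train_nb_leaf()] exactly.
#' @param laplace Laplace smoothing constant for the leaves (default 1).
#' @param seed Integer seed for fold assignment (default 1).
#' @return An object of class `nbtree`.
#' @export
train_nbtree <- function(x, labels = NULL, min_node = 30, utility_folds = 5,
                         min_rel_improvement = 0.05, max_depth = Inf,
                         laplace = 1, seed = 1) {
  if (is.null(labels)) labels <- x$class_label
  if (is.null(labels)) stop("labels must be supplied (or a class_label column)")
  x <- x[, setdiff(colnames(x), "class_label"), drop = FALSE]
  labels <- as.character(labels)
  if (anyNA(labels)) stop("labels must not be missing")
  if (nrow(x) == 0L) stop("cannot train on an empty feature matrix")
  classes <- sort(unique(labels))
  k <- length(classes)
  yidx <- match(labels, classes)
  types <- vapply(x, .feature_type, character(1))
  levels_list <- lapply(x, function(v) {
    if (.feature_type(v) == "categorical") {
      if (is.factor(v)) levels(v) else sort(unique(as.character(v[!is.na(v)])))
    } else NULL
  })

  build <- function(rows, depth) {
    xs <- x[rows, , drop = FALSE]
    ys <- yidx[rows]
    n <- length(rows)
    binning <- .node_binning(xs, classes[ys], types, levels_list)
    leaf <- function() {
      lf <- .build_leaf(xs, ys, classes, types, levels_list, laplace, binning)
      list(kind = "leaf", leaf = lf, n_train = n)
    }
    if (length(unique(ys)) < 2L || depth >= max_depth || n < 2 * min_node)
      return(leaf())

    u_node <- .cv_utility(binning$bins, binning$nbins, ys, k, utility_folds,
                          laplace)
    err_node <- 1 - u_node
    if (err_node <= 0) return(leaf())

    best <- NULL
    for (j in seq_len(ncol(x))) {
      cands <- if (types[j] == "continuous") {
        th <- .best_threshold(xs[[j]], ys, k, binning$disc[[j]]$cut_points)
        if (is.null(th)) list() else list(list(split_type = "le",
                                               threshold = th))
      } else {
        present <- levels_list[[j]][levels_list[[j]] %in%
                                      as.character(xs[[j]])]
        if (length(present) >= 2L)
          list(list(split_type = "cat", levels = present)) else list()
      }
      for (cand in cands) {
        assign_child <- .split_assign(xs[[j]], cand)
        sizes <- tabulate(assign_child$idx[!assign_child$missing],
                          nbins = assign_child$n_children)
        if (any(sizes < min_node)) next
        # missing values join the largest child for training
        ci <- assign_child$idx
        ci[assign_child$missing] <- which.max(sizes)
        u_split <- 0
        for (c in seq_len(assign_child$n_children)) {
          ch <- which(ci == c)
          # the child Naive Bayes re-discretizes on its own instances;
          # a split is only useful through this local re-binning
          chb <- .node_binning(xs[ch, , drop = FALSE], classes[ys[ch]],
                               types, levels_list)
          u_split <- u_split + length(ch) / n *
            .cv_utility(chb$bins, chb$nbins, ys[ch], k, utility_folds,
                        laplace)
        }
        if (is.null(best) || u_split > best$u) {
          best <- list(u = u_split, feature = colnames(x)[j], cand = cand,
                       child_idx = ci,
                       n_children = assign_child$n_children)
        }
      }
    }
    if (is.null(best)) return(leaf())
    rel_red <- (err_node - (1 - best$u)) / err_node
    if (rel_red < min_rel_improvement) return(leaf())

    children <- vector("list", best$n_children)
    weights <- numeric(best$n_children)
    for (c in seq_len(best$n_children)) {
      ch <- rows[best$child_idx == c]
      weights[c] <- length(ch) / n
      children[[c]] <- build(ch, depth + 1)
    }
    list(kind = "split", feature = best$feature,
         split_type = best$cand$split_type,
         threshold = best$cand$threshold,
         levels = best$cand$levels,
         children = children, weights = weights, n_train = n)
  }

  node <- .with_seed(seed, build(seq_len(nrow(x)), 0))
  structure(list(
    node = node,
    feature_names = colnames(x),
    feature_types = types,
    classes = classes,
    params = list(min_node = min_node, utility_folds = utility_folds,
                  min_rel_improvement = min_rel_improvement,
                  max_depth = max_depth, laplace = laplace, seed = seed),
    version = 1L
  ), class = "nbtree")
}

# Child assignment under a candidate split. Returns 1-based child index
# per instance (NA handled by caller), a missing mask, and arity.
.split_assign <- function(v, cand) {
  if (cand$split_type == "le") {
    idx <- ifelse(as.numeric(v) <= cand$threshold, 1L, 2L)
    list(idx = idx, missing = is.na(idx), n_children = 2L)
  } else {
    idx <- match(as.character(v), cand$levels)
    list(idx = idx, missing = is.na(idx), n_children = length(cand$levels))
  }
}

# Posterior matrix for rows of x routed through a (sub)tree. Instances
# missing a split value take the training-mass-weighted average of the
# child posteriors, keeping posteriors normalized.
.route <- function(node, x, classes) {
  n <- nrow(x)
  if (node$kind == "leaf") {
    Pl <- .leaf_scores(node$leaf, x)
    P <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
    P[, colnames(Pl)] <- Pl
    return(P)
  }
  cand <- list(split_type = node$split_type, threshold = node$threshold,
               levels = node$levels)
  asg <- .split_assign(x[[node$feature]], cand)
  P <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
  for (c in seq_along(node$children)) {
    r <- which(!asg$missing & asg$idx == c)
    if (length(r))
      P[r, ] <- .route(node$children[[c]], x[r, , drop = FALSE], classes)
  }
  miss <- which(asg$missing)
  if (length(miss)) {
    for (c in seq_along(node$children)) {
      P[miss, ] <- P[miss, , drop = FALSE] + node$weights[c] *
        .route(node$children[[c]], x[miss, , drop = FALSE], classes)
    }
  }
  P
}

#' Classify CNVs with a trained model
#'
#' Routes each feature vector through the tree (a missing split value is
#' handled by averaging the child posteriors weighted by child training
#' mass) and returns the leaf Naive Bayes posterior. A CNV is called
#' pathogenic when its MR distance exceeds 0.5; ties go to benign.
#'
#' @param model An `nbtree` from [train_nbtree()].
#' @param newdata Feature `data.frame` with the model's features (values
#'   may be missing).
#' @return A `data.frame` with `predicted_class` (factor mr/benign) and
#'   `mr_distance` (posterior probability of the MR class).
#' @export
classify <- function(model, newdata) {
  stopifnot(inherits(model, "nbtree"))
  missing_feats <- setdiff(model$feature_names, colnames(newdata))
  if (length(missing_feats))
    stop("newdata lacks model feature(s): ",
         paste(missing_feats, collapse = ", "))
  P <- .route(model$node, newdata, model$classes)
  mr <- if ("mr" %in% model$classes) P[, "mr"] else rep(0, nrow(newdata))
  data.frame(
    predicted_class = factor(ifelse(mr > 0.5, "mr", "benign"),
                             levels = c("mr", "benign")),
    mr_distance = as.numeric(mr)
  )
}

#' Count the leaves of a trained tree
#'
#' @param model An `nbtree`.
#' @return Integer number of Naive Bayes leaves.
#' @export
n_leaves <- function(model) {
  count <- function(node) {
    if (node$kind == "leaf") 1L
    else sum(vapply(node$children, count, integer(1)))
  }
  count(model$node)
}

#' @export
print.nbtree <- function(x, ...) {
  cat("Naive Bayes tree classifier\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  features:", length(x$feature_names), "\n")
  cat("  leaves:", n_leaves(x), "\n")
  invisible(x)
}

.MODEL_FORMAT <- "cnvclass-nbtree"
.MODEL_VERSION <- 1L

#' Save or load a trained model
#'
#' The model file is versioned JSON text: a small envelope (format name,
#' version, package version) around the fully serialized model (tree
#' topology, cut points, probability tables, training parameters
#' including the seed and feature order). Probabilities are written at
#' full precision so a save/load round trip reproduces classifications
#' bit for bit.
#'
#' @param model An `nbtree`.
#' @param path File path.
#' @return `save_model`: `path`, invisibly. `load_model`: the `nbtree`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "nbtree"))
  envelope <- list(
    format = .MODEL_FORMAT,
    version = .MODEL_VERSION,
    model_json = as.character(jsonlite::serializeJSON(model, digits = 17))
  )
  writeLines(jsonlite::toJSON(envelope, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  envelope <- tryCatch(jsonlite::fromJSON(readLines(path, warn = FALSE)),
                       error = function(e)
                         stop("corrupt model file: ", path, call. = FALSE))
  if (!identical(envelope$format, .MODEL_FORMAT))
    stop("not a ", .MODEL_FORMAT, " model file: ", path)
  if (!identical(as.integer(envelope$version), .MODEL_VERSION))
    stop("unsupported model file version ", envelope$version,
         " (supported: ", .MODEL_VERSION, ")")
  model <- jsonlite::unserializeJSON(envelope$model_json)
  if (!inherits(model, "nbtree")) stop("corrupt model payload in ", path)
  model
}
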