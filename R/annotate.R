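# Feature annotation: per-CNV structural and functional genomic features.
# Interval arithmetic is delegated to GenomicRanges; everything here is in
# 0-based half-open coordinates and converted at the GRanges boundary.

#' Candidate and final feature sets
#'
#' The 16 candidate per-CNV attributes, in the fixed column order used by
#' the feature matrix, and the 13-feature subset retained in the final
#' classifier (the SINE count, mean dN and mean dN/dS did not contribute
#' to accuracy and are excluded).
#'
#' @return A character vector of feature names.
#' @export
candidate_features <- function() {
  c("cnv_type", "length_bp",
    "n_line", "line_density", "n_sine", "sine_density",
    "n_segdup", "segdup_density", "n_gene", "gene_density",
    "mean_dS", "mean_dN", "mean_dNdS",
    "kegg_flag", "mgi_flag", "mean_expr_sd")
}

#' @rdname candidate_features
#' @export
final_features <- function() {
  setdiff(candidate_features(), c("n_sine", "mean_dN", "mean_dNdS"))
}

.as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end)
  )
}

#' Count track elements overlapping a CNV
#'
#' Counts the intervals of an annotation track that share at least one
#' base pair with the half-open CNV interval (`overlap = "any"`, the
#' default), or that lie entirely within it (`overlap = "within"`). The
#' result is independent of interval order in the track.
#'
#' @param cnv A one-row CNV `data.frame` (or any row of one).
#' @param track An annotation-track `data.frame` (`chrom`, `start`, `end`).
#' @param overlap `"any"` or `"within"`.
#' @return Non-negative integer count. A CNV on a chromosome absent from
#'   the track yields 0 with a warning.
#' @export
count_overlaps_cnv <- function(cnv, track, overlap = c("any", "within")) {
  overlap <- match.arg(overlap)
  if (nrow(track) == 0L) return(0L)
  if (!cnv$chrom[1] %in% track$chrom) {
    warning("chromosome ", cnv$chrom[1], " not present in track; count is 0")
    return(0L)
  }
  .count_overlaps_many(cnv[1, , drop = FALSE], track, overlap)[1]
}

# Vectorized overlap counts: one count per CNV row.
.count_overlaps_many <- function(cnvs, track, overlap = "any") {
  if (nrow(track) == 0L) return(integer(nrow(cnvs)))
  q <- .as_granges(cnvs)
  s <- .as_granges(track)
  if (overlap == "any") {
    as.integer(GenomicRanges::countOverlaps(q, s, type = "any",
                                            ignore.strand = TRUE))
  } else {
    hits <- GenomicRanges::findOverlaps(s, q, type = "within",
                                        ignore.strand = TRUE)
    tabulate(S4Vectors::subjectHits(hits), nbins = nrow(cnvs))
  }
}

#' Element density
#'
#' Number of elements per base pair of CNV length.
#'
#' @param count Non-negative element count.
#' @param length_bp CNV length in bp, at least 1.
#' @return `count / length_bp`, exactly.
#' @export
element_density <- function(count, length_bp) {
  if (any(length_bp < 1)) stop("length_bp must be >= 1")
  count / length_bp
}

# Gene-derived attributes for many CNVs at once. Means are over
# overlapping genes carrying a non-missing value; with no contributing
# gene the mean is NA (missing), never 0. Flags are ORs over genes.
.gene_attributes_many <- function(cnvs, genes) {
  n <- nrow(cnvs)
  out <- data.frame(
    n_gene = integer(n), gene_density = numeric(n),
    mean_dS = rep(NA_real_, n), mean_dN = rep(NA_real_, n),
    mean_dNdS = rep(NA_real_, n), mean_expr_sd = rep(NA_real_, n),
    kegg_flag = logical(n), mgi_flag = logical(n)
  )
  len <- cnvs$end - cnvs$start
  if (nrow(genes) > 0L) {
    hits <- GenomicRanges::findOverlaps(.as_granges(cnvs), .as_granges(genes),
                                        ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hits)
    gi <- S4Vectors::subjectHits(hits)
    out$n_gene <- tabulate(qi, nbins = n)
    mean_by_cnv <- function(v) {
      ok <- !is.na(v[gi])
      if (!any(ok)) return(rep(NA_real_, n))
      s <- rowsum(v[gi][ok], qi[ok])
      m <- rep(NA_real_, n)
      m[as.integer(rownames(s))] <- s[, 1] / tabulate(qi[ok], nbins = n)[as.integer(rownames(s))]
      m
    }
    out$mean_dS <- mean_by_cnv(genes$dS)
    out$mean_dN <- mean_by_cnv(genes$dN)
    out$mean_dNdS <- mean_by_cnv(genes$dNdS)
    out$mean_expr_sd <- mean_by_cnv(genes$expr_sd)
    flag_by_cnv <- function(v) {
      f <- logical(n)
      ok <- !is.na(v[gi]) & v[gi]
      f[unique(qi[ok])] <- TRUE
      f
    }
    out$mgi_flag <- flag_by_cnv(genes$mgi_nervous)
    out$kegg_flag <- flag_by_cnv(genes$kegg_neuro)
  }
  out$gene_density <- element_density(out$n_gene, len)
  out
}

#' Gene-derived attributes of one CNV
#'
#' Counts overlapping genes and aggregates their attributes: means of
#' `dS`, `dN`, `dN/dS` and expression-stability SD over overlapping genes
#' with a non-missing value (missing, not 0, when no gene contributes),
#' and OR-combined MGI nervous-system and KEGG neurodegeneration flags.
#'
#' @param cnv A one-row CNV `data.frame`.
#' @param genes Gene table from [read_gene_table()].
#' @return A one-row `data.frame` with `n_gene`, `gene_density`,
#'   `mean_dS`, `mean_dN`, `mean_dNdS`, `mean_expr_sd`, `kegg_flag`,
#'   `mgi_flag`.
#' @export
gene_attributes <- function(cnv, genes) {
  .gene_attributes_many(cnv[1, , drop = FALSE], genes)
}

#' Annotate CNVs with the candidate feature set
#'
#' Computes all 16 candidate attributes for each CNV: type and length,
#' LINE/SINE/segmental-duplication counts and densities, gene count and
#' density, mean substitution rates, expression stability, and the MGI
#' and KEGG flags. Deterministic and independent of input interval order.
#'
#' @param cnvs CNV `data.frame` (one or more rows).
#' @param tracks Named list of annotation-track `data.frame`s with
#'   elements `LINE`, `SINE` and `segdup`.
#' @param genes Gene table.
#' @param overlap Overlap rule for element counting; `"any"` (default,
#'   at least 1 bp shared) or `"within"` (full containment).
#' @return A feature `data.frame` with the columns of
#'   [candidate_features()] in order, one row per CNV, plus a
#'   `class_label` column carried over from the input. Logical flags are
#'   stored as factors `{false, true}` and `cnv_type` as a factor
#'   `{gain, loss}` so the matrix feeds the classifier directly.
#' @export
annotate_cnvs <- function(cnvs, tracks, genes, overlap = c("any", "within")) {
  overlap <- match.arg(overlap)
  for (tr in c("LINE", "SINE", "segdup"))
    if (is.null(tracks[[tr]])) stop("tracks must include element '", tr, "'")
  len <- cnvs$end - cnvs$start
  n_line <- .count_overlaps_many(cnvs, tracks$LINE, overlap)
  n_sine <- .count_overlaps_many(cnvs, tracks$SINE, overlap)
  n_segdup <- .count_overlaps_many(cnvs, tracks$segdup, overlap)
  ga <- .gene_attributes_many(cnvs, genes)
  out <- data.frame(
    cnv_type = factor(as.character(cnvs$cnv_type), levels = c("gain", "loss")),
    length_bp = len,
    n_line = n_line, line_density = element_density(n_line, len),
    n_sine = n_sine, sine_density = element_density(n_sine, len),
    n_segdup = n_segdup, segdup_density = element_density(n_segdup, len),
    n_gene = ga$n_gene, gene_density = ga$gene_density,
    mean_dS = ga$mean_dS, mean_dN = ga$mean_dN, mean_dNdS = ga$mean_dNdS,
    kegg_flag = factor(ifelse(ga$kegg_flag, "true", "false"),
                       levels = c("false", "true")),
    mgi_flag = factor(ifelse(ga$mgi_flag, "true", "false"),
                      levels = c("false", "true")),
    mean_expr_sd = ga$mean_expr_sd
  )
  out <- out[, candidate_features()]
  if (!is.null(cnvs$class_label)) out$class_label <- cnvs$class_label
  rownames(out) <- NULL
  out
}

#' @rdname annotate_cnvs
#' @param cnv A one-row CNV `data.frame` (single-CNV convenience wrapper).
#' @export
annotate_cnv <- function(cnv, tracks, genes, overlap = c("any", "within")) {
  annotate_cnvs(cnv[1, , drop = FALSE], tracks, genes, match.arg(overlap))
}

#' Prune collinear features by variance inflation factor
#'
#' Iteratively removes the continuous feature with the largest variance
#' inflation factor, `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from
#' the least-squares regression of feature `j` on all other remaining
#' features, until every remaining VIF is at or below `vif_threshold`.
#' A perfectly collinear feature has infinite VIF; ties on the maximum
#' are broken by removing the feature later in column order.
#'
#' @param x Numeric matrix or `data.frame` of continuous features
#'   (complete rows only; at least 2 columns, rows > columns).
#' @param vif_threshold Maximum acceptable VIF (default 10; 5 is the
#'   common stricter alternative).
#' @return A list with `retained` (feature names kept, in input order),
#'   `removed` (a `data.frame` of removal order, feature and its VIF at
#'   removal) and `vif` (named vector of final VIFs).
#' @export
vif_prune <- function(x, vif_threshold = 10) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("vif_prune requires continuous (numeric) features")
  if (ncol(x) < 2L) stop("vif_prune requires at least 2 features")
  if (anyNA(x)) stop("vif_prune requires complete rows (no missing values)")
  if (nrow(x) < ncol(x) + 1L) stop("vif_prune requires rows >= features + 1")
  keep <- colnames(x)
  if (is.null(keep)) keep <- colnames(x) <- paste0("f", seq_len(ncol(x)))
  removed <- data.frame(order = integer(), feature = character(),
                        vif = numeric(), stringsAsFactors = FALSE)
  repeat {
    v <- .vif_values(x[, keep, drop = FALSE])
    if (length(keep) < 2L || max(v) <= vif_threshold) {
      return(list(retained = keep, removed = removed, vif = v))
    }
    worst <- max(which(v == max(v)))  # tie-break: later in feature order
    removed <- rbind(removed, data.frame(
      order = nrow(removed) + 1L, feature = keep[worst], vif = v[worst],
      stringsAsFactors = FALSE))
    keep <- keep[-worst]
  }
}

# VIF per column via QR least squares of each feature on the others.
.vif_values <- function(x) {
  p <- ncol(x)
  v <- numeric(p)
  names(v) <- colnames(x)
  for (j in seq_len(p)) {
    y <- x[, j]
    tss <- sum((y - mean(y))^2)
    if (tss == 0) { v[j] <- 1; next }  # constant feature: no collinearity signal
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), y)
    rss <- sum(fit$residuals^2)
    r2 <- 1 - rss / tss
    v[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  v
}
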