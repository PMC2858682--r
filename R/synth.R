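# Synthetic genomes, annotation tracks, gene tables and class-labeled CNV
# sets with the class-conditional structure seen in clinical cohorts:
# pathogenic (MR) CNVs are roughly an order of magnitude larger, lie in
# SINE-dense regions and frequently contain genes with mouse
# nervous-system knock-out phenotypes, while benign CNVs concentrate in
# LINE- and segmental-duplication-dense regions.
#
# Heterogeneity comes from fixed-width patches tiled along each
# chromosome, each labelled "mr" or "benign": track element intensity is
# multiplied in the patch type that favours the element class, and gene
# flag probabilities depend on the patch. CNV placement is biased toward
# the class's favoured patch type by rejection sampling.

#' Synthetic genome specification
#'
#' Defaults give a 150 Mb three-chromosome genome whose repeat and gene
#' landscape is heterogeneous at the 2 Mb scale. Densities are elements
#' per base pair; element and gene lengths are log-normal.
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param patch_size Width of the heterogeneity patches (bp).
#' @param mr_patch_fraction Fraction of patches favouring the MR class.
#' @param track_density Base intensity per track (elements/bp).
#' @param track_mult Density multiplier inside the patch type favouring
#'   the track (LINE and segdup: benign patches; SINE: mr patches).
#' @param track_mean_length,track_sdlog Log-normal element lengths.
#' @param gene_density Genes per bp (uniform across patches).
#' @param gene_mean_length,gene_sdlog Log-normal gene lengths.
#' @param dS_meanlog,dS_sdlog Per-gene synonymous rate distribution.
#' @param dnds_meanlog,dnds_sdlog Per-gene dN/dS ratio distribution
#'   (dN is derived as dS times the ratio).
#' @param expr_meanlog,expr_sdlog Per-gene expression-stability SD.
#' @param attr_missing_rate Fraction of genes with missing substitution
#'   rates / expression values.
#' @param p_mgi,p_kegg Per-gene flag probabilities, named by patch type.
#' @return A list of class `synth_genome_spec`.
#' @export
synth_genome_spec <- function(
    chrom_lengths = c(chr1 = 60e6, chr2 = 50e6, chr3 = 40e6),
    patch_size = 2e6,
    mr_patch_fraction = 0.5,
    track_density = c(LINE = 1e-4, SINE = 1.5e-4, segdup = 2e-5),
    track_mult = c(LINE = 5, SINE = 5, segdup = 5),
    track_mean_length = c(LINE = 1000, SINE = 300, segdup = 20000),
    track_sdlog = 0.5,
    gene_density = 2e-5,
    gene_mean_length = 3e4, gene_sdlog = 0.8,
    dS_meanlog = log(0.15), dS_sdlog = 0.5,
    dnds_meanlog = log(0.25), dnds_sdlog = 0.5,
    expr_meanlog = log(0.4), expr_sdlog = 0.4,
    attr_missing_rate = 0.1,
    p_mgi = c(mr = 0.09, benign = 0.003),
    p_kegg = c(mr = 0.01, benign = 0.002)) {
  stopifnot(all(chrom_lengths > 0), all(track_density >= 0),
            mr_patch_fraction >= 0, mr_patch_fraction <= 1)
  structure(as.list(environment()), class = "synth_genome_spec")
}

#' Synthetic CNV class specification
#'
#' Defaults encode the reported contrast between clinical CNV classes:
#' MR-associated CNVs average ~6.8 Mb against ~474 kb for benign CNVs
#' (log-normal lengths), MR CNVs are biased into SINE/MGI-rich patches
#' and benign CNVs into LINE/segdup-rich patches, and ~80% of MR CNVs
#' versus ~5% of benign CNVs contain at least one MGI
#' nervous-system-phenotype gene.
#'
#' @param class_label `"mr"` or `"benign"`.
#' @param mean_length Arithmetic mean CNV length (bp).
#' @param sdlog Log-normal shape.
#' @param min_length Lower truncation (bp).
#' @param patch_affinity Placement weight multiplier for the favoured
#'   patch type (1 = uniform placement).
#' @param gain_fraction Probability a CNV is a gain (vs loss).
#' @param mgi_target Nominal fraction of CNVs containing an MGI-flagged
#'   gene (realized through patch placement; used by diagnostics).
#' @return A list of class `synth_class_spec`.
#' @export
synth_class_spec <- function(class_label = c("mr", "benign"),
                             mean_length = NULL, sdlog = NULL,
                             min_length = 1e4, patch_affinity = 8,
                             gain_fraction = NULL, mgi_target = NULL) {
  class_label <- match.arg(class_label)
  defaults <- list(
    # mean 6.8 Mb with sdlog 1.35 puts ~25% of MR CNVs below 1.1 Mb,
    # matching the reported size spectrum of pathogenic CNVs
    mr = list(mean_length = 6.8e6, sdlog = 1.35, gain_fraction = 0.3,
              mgi_target = 0.8, favored_patch = "mr"),
    benign = list(mean_length = 474e3, sdlog = 1.0, gain_fraction = 0.5,
                  mgi_target = 0.05, favored_patch = "benign")
  )[[class_label]]
  if (is.null(mean_length)) mean_length <- defaults$mean_length
  if (is.null(sdlog)) sdlog <- defaults$sdlog
  if (is.null(gain_fraction)) gain_fraction <- defaults$gain_fraction
  if (is.null(mgi_target)) mgi_target <- defaults$mgi_target
  stopifnot(patch_affinity > 0, mean_length > min_length)
  structure(list(
    class_label = class_label,
    meanlog = log(mean_length) - sdlog^2 / 2,
    sdlog = sdlog,
    min_length = min_length,
    favored_patch = defaults$favored_patch,
    patch_affinity = patch_affinity,
    gain_fraction = gain_fraction,
    mgi_target = mgi_target
  ), class = "synth_class_spec")
}

# Patch table for one genome: tiles with a type label.
.make_patches <- function(chrom_lengths, patch_size, mr_fraction) {
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq(0, L - 1, by = patch_size)
    data.frame(chrom = ch, start = starts, end = pmin(starts + patch_size, L),
               type = ifelse(stats::runif(length(starts)) < mr_fraction,
                             "mr", "benign"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Total bp of patches of `type` intersecting [s, e) per interval,
# vectorized over intervals.
.patch_overlap <- function(patches, type, chrom, s, e) {
  sel <- patches[patches$type == type, , drop = FALSE]
  out <- numeric(length(s))
  for (ch in unique(chrom)) {
    pc <- sel[sel$chrom == ch, , drop = FALSE]
    i <- which(chrom == ch)
    if (nrow(pc) == 0L) next
    for (r in seq_len(nrow(pc))) {
      out[i] <- out[i] + pmax(0, pmin(e[i], pc$end[r]) - pmax(s[i], pc$start[r]))
    }
  }
  out
}

# Poisson placement of elements with patch-dependent intensity.
.place_elements <- function(patches, base_density, mult, favored_type,
                            mean_length, sdlog, chrom_lengths) {
  dens <- base_density * ifelse(patches$type == favored_type, mult, 1)
  widths <- patches$end - patches$start
  n_per <- stats::rpois(nrow(patches), dens * widths)
  idx <- rep(seq_len(nrow(patches)), n_per)
  if (!length(idx))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  starts <- floor(patches$start[idx] + stats::runif(length(idx)) * widths[idx])
  lens <- pmax(1, round(stats::rlnorm(length(idx),
                                      log(mean_length) - sdlog^2 / 2, sdlog)))
  chrom <- patches$chrom[idx]
  ends <- pmin(starts + lens, chrom_lengths[chrom])
  ok <- ends > starts
  out <- data.frame(chrom = chrom[ok], start = starts[ok], end = ends[ok],
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Generate a synthetic genome
#'
#' Places LINE, SINE and segmental-duplication elements by a
#' patch-modulated Poisson process, and genes with per-gene attributes
#' (`dS`, `dN`, `dN/dS`, expression-stability SD, MGI and KEGG flags
#' whose probabilities depend on the patch type). Fully reproducible
#' from the seed.
#'
#' @param spec A [synth_genome_spec()].
#' @param seed Integer seed.
#' @return A list of class `synth_genome` with `chrom_lengths`,
#'   `patches`, `tracks` (named list of BED-like `data.frame`s) and
#'   `genes` (a gene table as read by [read_gene_table()]).
#' @export
generate_genome <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "synth_genome_spec"))
  .with_seed(seed, {
    patches <- .make_patches(spec$chrom_lengths, spec$patch_size,
                             spec$mr_patch_fraction)
    favored <- c(LINE = "benign", SINE = "mr", segdup = "benign")
    tracks <- lapply(stats::setNames(nm = names(favored)), function(tr) {
      .place_elements(patches, spec$track_density[[tr]],
                      spec$track_mult[[tr]], favored[[tr]],
                      spec$track_mean_length[[tr]], spec$track_sdlog,
                      spec$chrom_lengths)
    })
    genes <- .place_elements(patches, spec$gene_density, 1, "mr",
                             spec$gene_mean_length, spec$gene_sdlog,
                             spec$chrom_lengths)
    ng <- nrow(genes)
    if (ng > 0L) {
      genes$gene_id <- sprintf("G%05d", seq_len(ng))
      dS <- stats::rlnorm(ng, spec$dS_meanlog, spec$dS_sdlog)
      ratio <- stats::rlnorm(ng, spec$dnds_meanlog, spec$dnds_sdlog)
      miss <- stats::runif(ng) < spec$attr_missing_rate
      genes$dN <- ifelse(miss, NA, dS * ratio)
      genes$dS <- ifelse(miss, NA, dS)
      genes$dNdS <- ifelse(miss, NA, ratio)
      genes$expr_sd <- ifelse(stats::runif(ng) < spec$attr_missing_rate,
                              NA, stats::rlnorm(ng, spec$expr_meanlog,
                                                spec$expr_sdlog))
      # flag probability follows the patch holding the gene start
      pidx <- .patch_index(patches, genes$chrom, genes$start)
      ptype <- patches$type[pidx]
      genes$mgi_nervous <- stats::runif(ng) < spec$p_mgi[ptype]
      genes$kegg_neuro <- stats::runif(ng) < spec$p_kegg[ptype]
      genes <- genes[, c("gene_id", "chrom", "start", "end", "dN", "dS",
                         "dNdS", "expr_sd", "mgi_nervous", "kegg_neuro")]
    }
    structure(list(chrom_lengths = spec$chrom_lengths, patches = patches,
                   tracks = tracks, genes = genes, spec = spec, seed = seed),
              class = "synth_genome")
  })
}

# Index of the patch containing position `pos` on `chrom`.
.patch_index <- function(patches, chrom, pos) {
  # patches are fixed-width tiles except the last per chromosome; use an
  # explicit lookup instead of arithmetic to stay robust to remainders
  idx <- integer(length(chrom))
  for (ch in unique(chrom)) {
    pc <- which(patches$chrom == ch)
    i <- which(chrom == ch)
    idx[i] <- pc[findInterval(pos[i], patches$start[pc])]
  }
  idx
}

#' Generate a class-labeled CNV set
#'
#' Draws CNV lengths from the class's truncated log-normal distribution
#' and places each CNV uniformly over placeable positions (chromosome
#' chosen with probability proportional to `chrom_len - L + 1`), biased
#' toward the class's favoured patch type by rejection sampling: a
#' candidate overlapping its favoured patches over a fraction `f` of its
#' length is accepted with probability `(1 + (affinity-1) f) / affinity`.
#'
#' @param class_label `"mr"` or `"benign"`.
#' @param n Number of CNVs.
#' @param genome A `synth_genome`.
#' @param class_spec A [synth_class_spec()]; defaults to the class's
#'   defaults.
#' @param seed Integer seed.
#' @return A CNV `data.frame` (see [cnv_records()]) with `class_label`
#'   set and probe counts proportional to length.
#' @export
generate_cnv_set <- function(class_label, n, genome, class_spec = NULL,
                             seed = 1) {
  stopifnot(inherits(genome, "synth_genome"))
  if (is.null(class_spec)) class_spec <- synth_class_spec(class_label)
  if (n == 0L)
    return(cnv_records(character(0), numeric(0), numeric(0), character(0)))
  cl <- genome$chrom_lengths
  max_len <- max(cl)
  if (class_spec$min_length > max_len)
    stop("unplaceable CNV lengths: min_length ", class_spec$min_length,
         " exceeds every chromosome")
  .with_seed(seed, {
    # truncated log-normal: draws outside the placeable range are rejected
    lens <- numeric(0)
    while (length(lens) < n) {
      draw <- round(stats::rlnorm(n, class_spec$meanlog, class_spec$sdlog))
      lens <- c(lens, draw[draw >= class_spec$min_length & draw <= max_len])
    }
    lens <- lens[seq_len(n)]
    chrom <- character(n)
    start <- numeric(n)
    for (i in seq_len(n)) {
      L <- lens[i]
      w <- pmax(0, cl - L + 1)
      placed <- FALSE
      for (try in seq_len(1000L)) {
        ch <- sample(names(cl), 1, prob = w)
        s <- floor(stats::runif(1, 0, cl[[ch]] - L + 1))
        f <- .patch_overlap(genome$patches, class_spec$favored_patch,
                            ch, s, s + L) / L
        if (stats::runif(1) <
            (1 + (class_spec$patch_affinity - 1) * f) /
            class_spec$patch_affinity) {
          chrom[i] <- ch
          start[i] <- s
          placed <- TRUE
          break
        }
      }
      if (!placed) { chrom[i] <- ch; start[i] <- s }  # affinity is a bias, not a constraint
    }
    type <- ifelse(stats::runif(n) < class_spec$gain_fraction, "gain", "loss")
    cnv_records(chrom = chrom, start = start, end = start + lens,
                cnv_type = type,
                probe_count = pmax(1L, as.integer(round(lens / 2000))),
                class_label = class_label)
  })
}

#' Generate and write a complete labeled dataset
#'
#' Emits every input the annotation step reads: BED3 tracks, a gene
#' table, a CNV table with truth labels, a chromosome-length table and a
#' key/value manifest recording the specs and seed.
#'
#' @param genome_spec A [synth_genome_spec()].
#' @param n_mr,n_benign CNVs per class.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed controlling genome and both CNV sets.
#' @param mr_spec,benign_spec Optional [synth_class_spec()] overrides.
#' @return A list with `genome`, `cnvs` (the labeled table) and `paths`
#'   (named file paths).
#' @export
generate_labeled_dataset <- function(genome_spec = synth_genome_spec(),
                                     n_mr, n_benign, dir, seed = 1,
                                     mr_spec = NULL, benign_spec = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- generate_genome(genome_spec, seed = seed)
  mr <- generate_cnv_set("mr", n_mr, genome, mr_spec, seed = seed + 1L)
  benign <- generate_cnv_set("benign", n_benign, genome, benign_spec,
                             seed = seed + 2L)
  cnvs <- rbind(mr, benign)
  paths <- c(
    cnvs = file.path(dir, "cnvs.tsv"),
    LINE = file.path(dir, "line.bed"),
    SINE = file.path(dir, "sine.bed"),
    segdup = file.path(dir, "segdup.bed"),
    genes = file.path(dir, "genes.tsv"),
    chroms = file.path(dir, "chroms.tsv"),
    manifest = file.path(dir, "manifest.txt")
  )
  write_tsv_table(cnvs, paths[["cnvs"]])
  for (tr in c("LINE", "SINE", "segdup")) {
    utils::write.table(genome$tracks[[tr]], paths[[tr]], sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  write_tsv_table(genome$genes, paths[["genes"]])
  write_tsv_table(data.frame(chrom = names(genome$chrom_lengths),
                             length = as.numeric(genome$chrom_lengths)),
                  paths[["chroms"]])
  writeLines(c(
    paste0("seed\t", seed),
    paste0("n_mr\t", n_mr),
    paste0("n_benign\t", n_benign),
    paste0("genome_bp\t", sum(genome$chrom_lengths)),
    paste0("patch_size\t", genome_spec$patch_size)
  ), paths[["manifest"]])
  list(genome = genome, cnvs = cnvs, paths = paths)
}
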