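#' Read a CNV table
#'
#' Reads a whitespace/tab-separated CNV table with columns
#' `chrom, start, end, cnv_type[, probe_count, class_label, inheritance]`.
#' A header line is detected automatically (a first line whose second field
#' is not numeric). Coordinates are normalized to the internal convention:
#' 0-based, half-open intervals, so `length = end - start`.
#'
#' @param path Path to the table.
#' @param dialect Coordinate convention of the input: `"bed0"` (0-based,
#'   half-open; the BED/UCSC convention; default) or `"tab1"` (1-based,
#'   inclusive; converted by `start - 1`).
#' @return A `data.frame` with columns `chrom` (character), `start`, `end`
#'   (integer-valued doubles, 0-based half-open), `cnv_type` (factor
#'   gain/loss), `probe_count` (integer or `NA`), `class_label` (factor
#'   mr/benign/unknown), `inheritance` (factor de_novo/inherited/unknown)
#'   and `flagged` (logical; mosaic/complex aberration flag, `FALSE` when
#'   the input has no such column).
#' @export
read_cnv_table <- function(path, dialect = c("bed0", "tab1")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("CNV table not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("CNV table is empty: ", path)
  fields <- strsplit(trimws(lines), "[\t ]+")

  header <- NULL
  first <- fields[[1L]]
  if (length(first) >= 2L && is.na(suppressWarnings(as.numeric(first[2L])))) {
    header <- tolower(first)
    fields <- fields[-1L]
    lineno <- lineno[-1L]
  }
  if (length(fields) == 0L) stop("CNV table has a header but no records: ", path)

  std_cols <- c("chrom", "start", "end", "cnv_type", "probe_count",
                "class_label", "inheritance", "flagged")
  if (is.null(header)) {
    ncol_in <- max(lengths(fields))
    header <- std_cols[seq_len(min(ncol_in, length(std_cols)))]
  } else {
    header[header %in% c("type", "cnv type")] <- "cnv_type"
    header[header %in% c("probes", "probe count")] <- "probe_count"
    header[header %in% c("class", "label")] <- "class_label"
  }
  for (required in c("chrom", "start", "end", "cnv_type")) {
    if (!required %in% header)
      stop("CNV table is missing required column '", required, "': ", path)
  }

  get_col <- function(name) {
    j <- match(name, header)
    if (is.na(j)) return(rep(NA_character_, length(fields)))
    vapply(fields, function(f) if (length(f) >= j) f[j] else NA_character_,
           character(1))
  }
  chrom <- get_col("chrom")
  start <- suppressWarnings(as.numeric(get_col("start")))
  end <- suppressWarnings(as.numeric(get_col("end")))
  bad <- which(is.na(chrom) | is.na(start) | is.na(end))
  if (length(bad))
    stop("Malformed CNV record (non-numeric or missing coordinates) at line ",
         paste(lineno[bad], collapse = ", "), " of ", path)
  if (dialect == "tab1") start <- start - 1
  bad <- which(end <= start)
  if (length(bad))
    stop("CNV record with end <= start at line ",
         paste(lineno[bad], collapse = ", "), " of ", path)

  type <- tolower(get_col("cnv_type"))
  bad <- which(!type %in% c("gain", "loss"))
  if (length(bad))
    stop("cnv_type must be 'gain' or 'loss' at line ",
         paste(lineno[bad], collapse = ", "), " of ", path)

  probes <- suppressWarnings(as.integer(get_col("probe_count")))
  cls <- tolower(get_col("class_label"))
  cls[is.na(cls) | cls == "na"] <- "unknown"
  inh <- tolower(get_col("inheritance"))
  inh[is.na(inh) | inh == "na"] <- "unknown"
  flg <- tolower(get_col("flagged")) %in% c("true", "1", "yes", "mosaic", "complex")

  cnv_records(chrom = chrom, start = start, end = end, cnv_type = type,
              probe_count = probes, class_label = cls, inheritance = inh,
              flagged = flg)
}

#' Construct a CNV record table
#'
#' Validates and assembles CNV records into the canonical `data.frame`
#' used throughout the package (0-based half-open coordinates).
#'
#' @param chrom Chromosome names.
#' @param start,end 0-based half-open interval bounds (`end > start`).
#' @param cnv_type `"gain"` or `"loss"` per record.
#' @param probe_count Optional microarray probe counts (`NA` = unknown).
#' @param class_label Optional truth labels, `"mr"`, `"benign"` or
#'   `"unknown"`.
#' @param inheritance Optional inheritance labels.
#' @param flagged Logical mosaic/complex flag.
#' @return A CNV `data.frame`; see [read_cnv_table()].
#' @export
cnv_records <- function(chrom, start, end, cnv_type,
                        probe_count = NA_integer_, class_label = "unknown",
                        inheritance = "unknown", flagged = FALSE) {
  n <- length(chrom)
  stopifnot(length(start) == n, length(end) == n)
  cnv_type <- rep_len(as.character(cnv_type), n)
  if (any(end <= start)) stop("every CNV must satisfy end > start")
  if (!all(cnv_type %in% c("gain", "loss")))
    stop("cnv_type values must be 'gain' or 'loss'")
  if (!all(class_label %in% c("mr", "benign", "unknown")))
    stop("class_label values must be 'mr', 'benign' or 'unknown'")
  pc <- as.integer(probe_count)
  if (any(!is.na(pc) & pc < 0)) stop("probe_count must be non-negative")
  data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    cnv_type = factor(cnv_type, levels = c("gain", "loss")),
    probe_count = rep_len(pc, n),
    class_label = factor(rep_len(class_label, n),
                         levels = c("mr", "benign", "unknown")),
    inheritance = factor(rep_len(inheritance, n),
                         levels = c("de_novo", "inherited", "unknown")),
    flagged = rep_len(as.logical(flagged), n),
    stringsAsFactors = FALSE
  )
}

#' Quality-control filter for CNV calls
#'
#' Removes CNV calls that are unreliable on diagnostic arrays: fewer than
#' `min_probes` microarray targets, shorter than `min_length_bp`, or
#' flagged as a mosaic/complex aberration. Records without a probe count
#' (e.g. literature CNVs) pass the probe rule; only an explicit count
#' below the threshold excludes.
#'
#' @param cnvs CNV `data.frame` from [read_cnv_table()] or [cnv_records()].
#' @param min_probes Minimum probe count (default 5).
#' @param min_length_bp Minimum CNV length in bp (default 10000).
#' @param drop_flagged_complex Drop records flagged mosaic/complex
#'   (default `TRUE`).
#' @return A list with `retained` (the filtered `data.frame`) and
#'   `exclusions`, a named integer vector of per-rule exclusion counts
#'   (`low_probes`, `short`, `flagged`; a record failing several rules is
#'   counted under each).
#' @export
filter_cnvs <- function(cnvs, min_probes = 5, min_length_bp = 10000,
                        drop_flagged_complex = TRUE) {
  len <- cnvs$end - cnvs$start
  fail_probes <- !is.na(cnvs$probe_count) & cnvs$probe_count < min_probes
  fail_len <- len < min_length_bp
  fail_flag <- if (drop_flagged_complex) cnvs$flagged %in% TRUE else
    rep(FALSE, nrow(cnvs))
  keep <- !(fail_probes | fail_len | fail_flag)
  list(
    retained = cnvs[keep, , drop = FALSE],
    exclusions = c(low_probes = sum(fail_probes), short = sum(fail_len),
                   flagged = sum(fail_flag))
  )
}

#' Read an annotation track (BED3+)
#'
#' Reads a BED file of genomic elements of one class (for example LINE or
#' SINE repeats, or segmental duplications). Only the first three columns
#' are used; coordinates are BED-convention (0-based, half-open).
#'
#' @param path BED file path.
#' @param element_class Label for the track (e.g. `"LINE"`).
#' @return An annotation-track `data.frame` with columns `chrom`, `start`,
#'   `end` and attribute `element_class`.
#' @export
read_track <- function(path, element_class = NA_character_) {
  if (!file.exists(path)) stop("track file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, sep = "", comment.char = "#",
                           fill = TRUE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("track file needs at least 3 BED columns: ", path)
  tab <- tab[, 1:3]
  names(tab) <- c("chrom", "start", "end")
  tab$chrom <- as.character(tab$chrom)
  tab$start <- as.numeric(tab$start)
  tab$end <- as.numeric(tab$end)
  if (any(tab$end <= tab$start)) stop("track interval with end <= start: ", path)
  attr(tab, "element_class") <- element_class
  tab
}

#' Read a gene table
#'
#' Tab-separated with a header:
#' `gene_id chrom start end dN dS dNdS expr_sd mgi_nervous kegg_neuro`,
#' `NA` for missing values, coordinates 0-based half-open. `dN`/`dS` are
#' per-gene non-synonymous/synonymous substitution rates, `expr_sd` the
#' standard deviation of log2 expression intensity across reference cell
#' lines, `mgi_nervous` flags genes whose mouse orthologue knock-out shows
#' a nervous-system phenotype, `kegg_neuro` flags membership of the
#' neurodegenerative-disorder pathway group.
#'
#' @param path File path.
#' @return A gene `data.frame`.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("gene table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  required <- c("gene_id", "chrom", "start", "end", "dN", "dS", "dNdS",
                "expr_sd", "mgi_nervous", "kegg_neuro")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("gene table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  tab$mgi_nervous <- as.logical(tab$mgi_nervous)
  tab$kegg_neuro <- as.logical(tab$kegg_neuro)
  if (any(tab$end <= tab$start)) stop("gene interval with end <= start: ", path)
  tab
}

#' Write a CNV table, track or gene table
#'
#' Tab-separated plain text with a header, `NA` for missing values,
#' readable back by the corresponding `read_*` function.
#'
#' @param x The `data.frame` to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}
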