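#' Read a probe-level methylation matrix with its sample sheet
#'
#' The matrix file is tab-separated with a header row: columns `probe_id`,
#' `chrom`, `pos`, then one beta-value column per sample. The sample sheet
#' is tab-separated with columns `sample` and `group`. Every matrix sample
#' must appear in the sheet and every sheet sample in the matrix; either
#' mismatch is an error. Probes are sorted by (chrom, pos) on load.
#'
#' @param path path to the matrix TSV.
#' @param sample_sheet_path path to the sample sheet TSV.
#' @return A [methylation_dataset()].
#' @export
read_methylation_matrix <- function(path, sample_sheet_path) {
  if (!file.exists(path)) stop_("matrix file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% names(tab)[1:3]))
    stop_("matrix must start with columns probe_id, chrom, pos: ", path)
  groups <- read_sample_sheet(sample_sheet_path)
  samples <- setdiff(names(tab), need)
  extra <- setdiff(names(groups), samples)
  if (length(extra))
    stop_("sample sheet lists samples absent from the matrix: ",
          paste(extra, collapse = ", "))
  beta <- as.matrix(tab[, samples, drop = FALSE])
  if (!is.numeric(beta)) stop_("non-numeric beta values in ", path)
  methylation_dataset(tab$probe_id, tab$chrom, tab$pos, beta, groups)
}

#' Read a tab-separated sample sheet
#' @param path TSV with header columns `sample` and `group`.
#' @return Named character vector, sample -> group.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop_("sample sheet not found: ", path)
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(sheet)))
    stop_("sample sheet needs columns 'sample' and 'group': ", path)
  if (anyDuplicated(sheet$sample))
    stop_("duplicate samples in sheet: ", path)
  stats::setNames(as.character(sheet$group), as.character(sheet$sample))
}

#' Write a methylation matrix and sample sheet
#' @param ds a `MethylationDataset`.
#' @param path output matrix TSV.
#' @param sample_sheet_path optional output sample-sheet TSV.
#' @export
write_methylation_matrix <- function(ds, path, sample_sheet_path = NULL) {
  tab <- cbind(ds$probes, as.data.frame(ds$beta, check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sample_sheet_path)) {
    sheet <- data.frame(sample = ds$samples, group = ds$groups)
    utils::write.table(sheet, sample_sheet_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a detection p-value matrix
#'
#' Same layout as the methylation matrix (probe_id, chrom, pos, one column
#' per sample); reordered to align with `ds` when given.
#'
#' @param path TSV path.
#' @param ds optional `MethylationDataset` to align against.
#' @return Numeric matrix of detection p-values.
#' @export
read_detection_matrix <- function(path, ds = NULL) {
  if (!file.exists(path)) stop_("detection matrix not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, setdiff(names(tab), c("probe_id", "chrom", "pos")), drop = FALSE])
  rownames(m) <- tab$probe_id
  if (any(m < 0 | m > 1)) stop_("detection p-values outside [0, 1]")
  if (!is.null(ds)) {
    if (!all(rownames(ds$beta) %in% rownames(m)) ||
        !all(colnames(ds$beta) %in% colnames(m)))
      stop_("detection matrix does not cover all dataset probes/samples")
    m <- m[rownames(ds$beta), colnames(ds$beta), drop = FALSE]
  }
  m
}

# ---- BED ----

#' Read a BED file as a region set
#'
#' Accepts BED3+: columns chrom, start, end, optionally name (col 4), score
#' (5), strand (6) and gene_name (col 7). Coordinates are 0-based half-open
#' and preserved exactly. `track` and `browser` lines and `#` comments are
#' skipped.
#'
#' @param path BED path.
#' @return Region set data.frame: chrom, start, end, name, gene_name.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (!length(lines))
    return(as_region_set(data.frame(chrom = character(), start = integer(),
                                    end = integer(), name = character())))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) stop_("BED records need at least 3 fields: ", path)
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  if (anyNA(start) || anyNA(end)) stop_("non-numeric BED coordinates: ", path)
  df <- data.frame(chrom = get(1), start = start, end = end,
                   stringsAsFactors = FALSE)
  nm <- get(4)
  df$name <- ifelse(is.na(nm) | nm == ".", sprintf("%s:%d-%d", df$chrom, df$start, df$end), nm)
  gn <- get(7)
  df$gene_name <- ifelse(is.na(gn) | gn == ".", NA_character_, gn)
  as_region_set(df)
}

#' Write a region set as BED
#'
#' Emits BED4 (chrom, start, end, name) or, when any region carries a
#' gene_name, BED6+1 with score 0, strand '.', and gene_name in column 7,
#' so that [read_bed()] round-trips the set exactly. Records are sorted by
#' (chrom, start).
#'
#' @param regions region set data.frame.
#' @param path output path.
#' @param track_name optional BED track header name.
#' @export
write_bed <- function(regions, path, track_name = NULL) {
  regions <- as_region_set(regions)
  regions <- regions[order(regions$chrom, regions$start, regions$end), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(track_name))
    writeLines(sprintf('track name="%s"', track_name), con)
  if (nrow(regions)) {
    if (all(is.na(regions$gene_name))) {
      out <- sprintf("%s\t%d\t%d\t%s", regions$chrom, regions$start,
                     regions$end, regions$name)
    } else {
      out <- sprintf("%s\t%d\t%d\t%s\t0\t.\t%s", regions$chrom, regions$start,
                     regions$end, regions$name,
                     ifelse(is.na(regions$gene_name), ".", regions$gene_name))
    }
    writeLines(out, con)
  }
  invisible(path)
}

# ---- GMT ----

#' Read gene sets from a GMT file
#'
#' Standard MSigDB dialect: per line, set name, description, then one or
#' more member gene symbols, tab-separated. Duplicate members within a set
#' are collapsed; the description is ignored.
#'
#' @param path GMT path.
#' @return Named list of character vectors (set name -> members).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad))
    stop_("malformed GMT line(s) (need name, description, >=1 member): line ",
          paste(bad, collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, "", 1)
  if (anyDuplicated(names(sets))) stop_("duplicate gene set names in ", path)
  sets
}

#' Read a chromosome-sizes file
#' @param path TSV without header: chromosome, length (bp).
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop_("chrom.sizes file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  len <- as.integer(tab[[2]])
  if (anyNA(len) || any(len <= 0)) stop_("chromosome lengths must be positive integers")
  stats::setNames(len, as.character(tab[[1]]))
}
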