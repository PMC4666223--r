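clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

# regions are plain data.frames; normalize to the canonical column set
as_region_set <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (is.null(df$name)) df$name <- sprintf("%s:%d-%d", df$chrom, df$start, df$end)
  if (is.null(df$gene_name)) df$gene_name <- NA_character_
  df <- df[, c("chrom", "start", "end", "name", "gene_name")]
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$name <- as.character(df$name)
  df$gene_name <- as.character(df$gene_name)
  if (any(df$start >= df$end))
    stop_("region start must be < end (0-based half-open intervals)")
  if (anyDuplicated(df$name))
    stop_("region names must be unique within a set")
  rownames(df) <- NULL
  df
}

regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end),
    name = regions$name
  )
}

probes_to_granges <- function(ds) {
  GenomicRanges::GRanges(
    seqnames = ds$probes$chrom,
    ranges = IRanges::IRanges(start = ds$probes$pos + 1L, width = 1L)
  )
}
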