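#' Genome-wide tiling regions
#'
#' Non-overlapping half-open windows `[0,w), [w,2w), ...` per chromosome;
#' the final partial window is kept, so the tiles partition each chromosome
#' exactly. Names are `chrom:start-end`.
#'
#' @param chrom_sizes named vector of chromosome lengths (bp), e.g. from
#'   [read_chrom_sizes()].
#' @param window_bp tile width in bp. Typical analyses use 50 bp up to
#'   100 kb; values outside that range trigger a warning.
#' @return Region set data.frame.
#' @export
make_tiles <- function(chrom_sizes, window_bp) {
  if (window_bp <= 0) stop_("window_bp must be positive")
  if (window_bp < 50 || window_bp > 100000)
    warning("window_bp outside the usual 50 bp - 100 kb range")
  tiles <- GenomicRanges::tileGenome(chrom_sizes, tilewidth = window_bp,
                                     cut.last.tile.in.chrom = TRUE)
  start0 <- GenomicRanges::start(tiles) - 1L
  end0 <- GenomicRanges::end(tiles)
  chrom <- as.character(GenomicRanges::seqnames(tiles))
  as_region_set(data.frame(
    chrom = chrom, start = start0, end = end0,
    name = sprintf("%s:%d-%d", chrom, start0, end0),
    stringsAsFactors = FALSE
  ))
}

read_gtf_features <- function(gtf_path, feature_type) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  gr <- gr[gr$type == feature_type]
  if (!length(gr)) stop_("no '", feature_type, "' features in ", gtf_path)
  gr
}

#' Promoter regions anchored at the TSS
#'
#' One window of `span_bp` per gene, anchored at the transcription start
#' site (plus strand: gene start; minus strand: gene end) and extending
#' downstream (into the gene body, the default) or upstream, strand-aware.
#' Windows are clamped to `[0, chromosome length]`; a window clamped to
#' zero length is dropped with a warning. The `gene_name` attribute is
#' propagated into the region set.
#'
#' @param gtf_path GTF with `gene` features carrying `gene_name` and strand.
#' @param span_bp promoter window size in bp. Default 2000.
#' @param orientation `"downstream"` (default) or `"upstream"` of the TSS.
#' @param chrom_sizes optional named lengths for upper clamping.
#' @return Region set data.frame with gene_name set.
#' @export
promoters_from_gtf <- function(gtf_path, span_bp = 2000,
                               orientation = c("downstream", "upstream"),
                               chrom_sizes = NULL) {
  orientation <- match.arg(orientation)
  genes <- read_gtf_features(gtf_path, "gene")
  strand <- as.character(GenomicRanges::strand(genes))
  if (any(strand == "*")) stop_("gene(s) without strand in ", gtf_path)
  gstart0 <- GenomicRanges::start(genes) - 1L  # 0-based
  gend0 <- GenomicRanges::end(genes)           # half-open end
  tss <- ifelse(strand == "+", gstart0, gend0 - 1L)
  # downstream windows include the TSS base; upstream windows end just
  # before it (strand-mirrored for minus-strand genes)
  start <- if (orientation == "downstream") {
    ifelse(strand == "+", tss, tss + 1L - span_bp)
  } else {
    ifelse(strand == "+", tss - span_bp, tss + 1L)
  }
  end <- start + span_bp
  start <- pmax(start, 0L)
  if (!is.null(chrom_sizes)) {
    len <- chrom_sizes[as.character(GenomicRanges::seqnames(genes))]
    end <- pmin(end, ifelse(is.na(len), end, len))
  }
  gene_name <- genes$gene_name
  if (is.null(gene_name)) stop_("GTF gene features lack a gene_name attribute")
  keep <- start < end
  if (any(!keep)) warning(sum(!keep), " promoter window(s) clamped to zero length; dropped")
  as_region_set(data.frame(
    chrom = as.character(GenomicRanges::seqnames(genes))[keep],
    start = as.integer(start[keep]), end = as.integer(end[keep]),
    name = make.unique(paste0("promoter_", gene_name[keep])),
    gene_name = gene_name[keep],
    stringsAsFactors = FALSE
  ))
}

#' Exon regions from a GTF
#'
#' All `exon` features; identical intervals shared across transcripts of
#' the same gene are collapsed, keeping `gene_name`.
#'
#' @param gtf_path GTF path.
#' @return Region set data.frame with gene_name set.
#' @export
exons_from_gtf <- function(gtf_path) {
  ex <- read_gtf_features(gtf_path, "exon")
  gene_name <- ex$gene_name
  if (is.null(gene_name)) stop_("GTF exon features lack a gene_name attribute")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex),
    gene_name = gene_name,
    stringsAsFactors = FALSE
  )
  df <- unique(df)
  df$name <- make.unique(sprintf("exon_%s_%s:%d-%d", df$gene_name, df$chrom,
                                 df$start, df$end))
  as_region_set(df)
}
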