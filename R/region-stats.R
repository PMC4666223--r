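#' Map probes onto genomic regions
#'
#' A probe at position `p` (0-based point) belongs to region `[s, e)` iff
#' `s <= p < e`. Probes may belong to several overlapping regions; regions
#' without any probe are excluded from testing and reported as skipped.
#'
#' @param ds a `MethylationDataset` (probes sorted by chrom, pos).
#' @param regions region set data.frame (chrom, start, end, name, ...).
#' @return List with `region_probes` (named list, region name -> integer
#'   indices into `ds$probes`) and `skipped` (names of empty regions).
#' @export
map_probes_to_regions <- function(ds, regions) {
  regions <- as_region_set(regions)
  hits <- GenomicRanges::findOverlaps(probes_to_granges(ds), regions_to_granges(regions))
  by_region <- split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
  region_probes <- stats::setNames(
    lapply(by_region, as.integer),
    regions$name[as.integer(names(by_region))]
  )
  list(region_probes = region_probes,
       skipped = setdiff(regions$name, names(region_probes)))
}

#' Estimate autocorrelation of probe z-scores by genomic distance
#'
#' For each distance bin `(breaks[i], breaks[i+1]]`, the Pearson
#' correlation of z-scores over all intra-chromosomal probe pairs whose
#' distance falls in the bin. Bins with fewer than `min_pairs` pairs or
#' zero variance get correlation 0, and negative estimates are truncated
#' at 0 so the combination covariance never drops below independence.
#' Distances beyond the last bin are treated as uncorrelated.
#'
#' @param z finite per-probe z-scores.
#' @param chrom,pos probe chromosome and position (same length as `z`).
#' @param lag_bins upper edges of the distance bins in bp; first bin starts
#'   just above 0. Default `c(1, 51, 101, 201, 501, 1001)`.
#' @param min_pairs minimum pairs for a usable estimate. Default 30.
#' @return `AcfEstimate`: list with `breaks`, per-bin `corr` and `n_pairs`.
#' @export
estimate_acf <- function(z, chrom, pos, lag_bins = c(1, 51, 101, 201, 501, 1001),
                         min_pairs = 30) {
  if (length(z) < 2) stop_("need at least 2 probes to estimate autocorrelation")
  if (length(chrom) != length(z) || length(pos) != length(z))
    stop_("z, chrom and pos must be aligned")
  if (any(!is.finite(z))) stop_("z-scores must be finite")
  breaks <- c(0, sort(lag_bins))
  max_lag <- max(breaks)
  acc <- list()
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    if (length(sel) < 2) next
    o <- order(pos[sel])
    p <- pos[sel][o]; zz <- z[sel][o]
    n <- length(p)
    # pairs by rank offset: with sorted positions, once every pair at offset
    # k exceeds max_lag no larger offset can qualify
    for (k in seq_len(n - 1)) {
      d <- p[(1 + k):n] - p[1:(n - k)]
      keep <- d <= max_lag
      if (!any(keep)) break
      acc[[length(acc) + 1]] <- list(zi = zz[1:(n - k)][keep],
                                     zj = zz[(1 + k):n][keep],
                                     dd = d[keep])
    }
  }
  zi <- unlist(lapply(acc, `[[`, "zi")) %||% numeric(0)
  zj <- unlist(lapply(acc, `[[`, "zj")) %||% numeric(0)
  dd <- unlist(lapply(acc, `[[`, "dd")) %||% numeric(0)
  nb <- length(breaks) - 1
  corr <- numeric(nb)
  n_pairs <- integer(nb)
  bin <- findInterval(dd, breaks, left.open = TRUE)
  bin[bin == 0] <- 1L  # distance-0 pairs (co-located probes) use the first bin
  for (b in seq_len(nb)) {
    s <- which(bin == b)
    n_pairs[b] <- length(s)
    if (length(s) < min_pairs) next
    if (stats::sd(zi[s]) == 0 || stats::sd(zj[s]) == 0) next
    corr[b] <- max(0, stats::cor(zi[s], zj[s]))
  }
  structure(list(breaks = breaks, corr = corr, n_pairs = n_pairs),
            class = "AcfEstimate")
}

#' @export
print.AcfEstimate <- function(x, ...) {
  cat("AcfEstimate over distance bins (bp):\n")
  nb <- length(x$corr)
  lab <- sprintf("(%g,%g]", x$breaks[seq_len(nb)], x$breaks[-1])
  print(data.frame(bin = lab, corr = round(x$corr, 4), n_pairs = x$n_pairs))
  invisible(x)
}

# pairwise correlation matrix for probes at `positions` (same chromosome)
acf_sigma <- function(acf, positions) {
  k <- length(positions)
  d <- abs(outer(positions, positions, "-"))
  idx <- findInterval(d, acf$breaks, left.open = TRUE)
  idx[idx == 0] <- 1L
  corr_ext <- c(acf$corr, 0)  # beyond the last bin: independent
  sigma <- matrix(corr_ext[pmin(idx, length(corr_ext))], k, k)
  diag(sigma) <- 1
  sigma
}

#' Combine p-values with the Stouffer-Liptak method
#'
#' Each p-value is transformed to a z-score `z_i = qnorm(1 - p_i)`; the
#' combined statistic is `C = sum(z) / sqrt(sum(sigma))` where `sigma` is
#' the pairwise correlation matrix (unit diagonal), and the combined
#' p-value is `1 - pnorm(C)`. Under independence `sigma` is the identity;
#' under complete dependence the combination collapses to a single test.
#' If `sum(sigma)` is not positive the independence denominator `k` is
#' used. Inputs and output are clamped to (0, 1) so z-scores stay finite.
#'
#' @param p vector of p-values in (0, 1).
#' @param sigma symmetric correlation matrix with unit diagonal; `NULL`
#'   means independence.
#' @return Combined p-value in (0, 1).
#' @export
stouffer_liptak <- function(p, sigma = NULL) {
  k <- length(p)
  if (!k) stop_("empty p-value list")
  if (is.null(sigma)) sigma <- diag(k)
  if (!all(dim(sigma) == c(k, k))) stop_("sigma must be k x k")
  p <- clamp(p, 1e-16, 1 - 1e-16)
  z <- stats::qnorm(p, lower.tail = FALSE)
  denom <- sum(sigma)
  if (!(denom > 0)) denom <- k
  C <- sum(z) / sqrt(denom)
  clamp(stats::pnorm(C, lower.tail = FALSE), 1e-16, 1 - 1e-16)
}

#' One-step Sidak correction over effective region count
#'
#' The number of effective tests is `m = max(1, floor(total_tested_span_bp /
#' region_span_bp))` — the number of regions of this size that fit in the
#' total tested span — and `q = 1 - (1 - p)^m`, evaluated as
#' `-expm1(m * log1p(-p))` for stability at small p.
#'
#' @param p p-value(s) in (0, 1\].
#' @param region_span_bp span of the region under test (bp, > 0).
#' @param total_tested_span_bp summed span of all tested regions (bp, > 0).
#' @return q-value(s) in \[p, 1\].
#' @export
sidak_correct <- function(p, region_span_bp, total_tested_span_bp) {
  if (any(region_span_bp <= 0) || any(total_tested_span_bp <= 0))
    stop_("spans must be positive")
  if (any(p <= 0 | p > 1)) stop_("p must be in (0, 1]")
  m <- pmax(1, floor(total_tested_span_bp / region_span_bp))
  n <- max(length(p), length(m))
  p <- rep_len(p, n)
  m <- rep_len(m, n)
  q <- pmin(-expm1(m * log1p(-p)), 1)
  q[m == 1] <- p[m == 1]  # exact identity for a single test
  q
}

#' Min/median/max methylation change over a region
#'
#' Per probe, the change is the difference of group median betas,
#' `median(group2) - median(group1)` for the fixed pair order; the region
#' summary is the min, median and max of these per-probe changes.
#'
#' @param ds a `MethylationDataset`.
#' @param pair character vector `c(group1, group2)`.
#' @param probe_ids probe identifiers (or integer indices into `ds$probes`).
#' @return Named numeric vector: change_min, change_median, change_max.
#' @export
region_change_summary <- function(ds, pair, probe_ids) {
  idx <- if (is.numeric(probe_ids)) as.integer(probe_ids)
         else match(probe_ids, ds$probes$probe_id)
  if (anyNA(idx)) stop_("unknown probe IDs in region")
  i1 <- group_columns(ds, pair[1])
  i2 <- group_columns(ds, pair[2])
  if (!length(i1) || !length(i2)) stop_("unknown group in pair")
  med <- function(cols) apply(ds$beta[idx, cols, drop = FALSE], 1, stats::median)
  d <- med(i2) - med(i1)
  c(change_min = min(d), change_median = stats::median(d), change_max = max(d))
}

#' Call differentially methylated regions
#'
#' For every unordered group pair (lexicographic orientation, change =
#' group2 - group1) and both directions: probe p-values inside each region
#' are combined with [stouffer_liptak()] using a correlation matrix looked
#' up from the genome-wide [estimate_acf()] of that direction's z-scores;
#' combined p-values receive the one-step Sidak correction with the total
#' tested span (the summed width of the union of regions containing at
#' least one probe). A region's direction is the group with the smaller
#' q-value; regions pass when `min(q) <= q_cutoff` and
#' `|change_median| >= min_abs_median_change`. Results are sorted by q,
#' ties broken by (chrom, start).
#'
#' @param ds a `MethylationDataset`.
#' @param regions region set data.frame.
#' @param q_cutoff keep regions with q at or below this. Default 0.05.
#' @param min_abs_median_change minimum absolute median beta change.
#'   Default 0 (no change filter).
#' @param probe_tests optional precomputed [all_pairs_probe_tests()] table.
#' @param lag_bins distance bins for [estimate_acf()].
#' @param exact_limit passed to the rank tests.
#' @param sidak_method `"span"` (effective count = total span / region
#'   span) or `"count"` (number of tested regions).
#' @return data.frame with one row per passing region x pair: group1,
#'   group2, chrom, start, end, name, gene_name, n_probes, p_group1,
#'   p_group2, q_group1, q_group2, direction, q, change_min, change_median,
#'   change_max. Attribute `n_regions_skipped` counts probe-free regions.
#' @export
call_dmrs <- function(ds, regions, q_cutoff = 0.05, min_abs_median_change = 0,
                      probe_tests = NULL,
                      lag_bins = c(1, 51, 101, 201, 501, 1001),
                      exact_limit = 16,
                      sidak_method = c("span", "count")) {
  sidak_method <- match.arg(sidak_method)
  regions <- as_region_set(regions)
  if (is.null(probe_tests)) probe_tests <- all_pairs_probe_tests(ds, exact_limit)
  mapping <- map_probes_to_regions(ds, regions)
  tested <- regions[regions$name %in% names(mapping$region_probes), , drop = FALSE]
  if (!nrow(tested)) stop_("no region contains any probe")
  total_span <- sum(IRanges::width(GenomicRanges::reduce(regions_to_granges(tested))))
  n_tested <- nrow(tested)

  pairs <- unique(probe_tests[, c("group1", "group2")])
  out <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    g1 <- pairs$group1[k]; g2 <- pairs$group2[k]
    sub <- probe_tests[probe_tests$group1 == g1 & probe_tests$group2 == g2, ]
    sub <- sub[match(ds$probes$probe_id, sub$probe_id), ]
    p1 <- sub$p_group1_greater
    p2 <- sub$p_group2_greater
    z1 <- stats::qnorm(clamp(p1, 1e-16, 1 - 1e-16), lower.tail = FALSE)
    z2 <- stats::qnorm(clamp(p2, 1e-16, 1 - 1e-16), lower.tail = FALSE)
    acf1 <- estimate_acf(z1, ds$probes$chrom, ds$probes$pos, lag_bins)
    acf2 <- estimate_acf(z2, ds$probes$chrom, ds$probes$pos, lag_bins)

    rows <- lapply(seq_len(nrow(tested)), function(r) {
      idx <- mapping$region_probes[[tested$name[r]]]
      posr <- ds$probes$pos[idx]
      pc1 <- stouffer_liptak(p1[idx], acf_sigma(acf1, posr))
      pc2 <- stouffer_liptak(p2[idx], acf_sigma(acf2, posr))
      span <- tested$end[r] - tested$start[r]
      if (sidak_method == "span") {
        q1 <- sidak_correct(pc1, span, total_span)
        q2 <- sidak_correct(pc2, span, total_span)
      } else {
        q1 <- pmin(-expm1(n_tested * log1p(-pc1)), 1)
        q2 <- pmin(-expm1(n_tested * log1p(-pc2)), 1)
      }
      chg <- region_change_summary(ds, c(g1, g2), idx)
      direction <- if (q1 < q2) g1
                   else if (q2 < q1) g2
                   else if (chg[["change_median"]] >= 0) g2 else g1
      data.frame(group1 = g1, group2 = g2,
                 chrom = tested$chrom[r], start = tested$start[r],
                 end = tested$end[r], name = tested$name[r],
                 gene_name = tested$gene_name[r],
                 n_probes = length(idx),
                 p_group1 = pc1, p_group2 = pc2,
                 q_group1 = q1, q_group2 = q2,
                 direction = direction, q = min(q1, q2),
                 change_min = chg[["change_min"]],
                 change_median = chg[["change_median"]],
                 change_max = chg[["change_max"]],
                 stringsAsFactors = FALSE)
    })
    out[[k]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  res <- res[res$q <= q_cutoff & abs(res$change_median) >= min_abs_median_change, ,
             drop = FALSE]
  res <- res[order(res$q, res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_regions_skipped") <- length(mapping$skipped)
  attr(res, "total_tested_span_bp") <- total_span
  res
}

#' Write per-pair region results as CSV
#' @param results output of [call_dmrs()].
#' @param path output CSV path.
#' @export
write_region_csv <- function(results, path) {
  cols <- c("chrom", "start", "end", "name", "gene_name", "n_probes",
            "p_group1", "p_group2", "q_group1", "q_group2", "direction",
            "q", "change_min", "change_median", "change_max")
  utils::write.csv(results[, c("group1", "group2", cols)], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
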