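#' One-sided two-sample Mann-Whitney U test
#'
#' Tests stochastic dominance of one group over the other: small p-values
#' mean larger values in the group named by `direction`. With tie-free data
#' and `length(a) + length(b) <= exact_limit` the p-value is exact, from the
#' full null distribution of U over all group labelings; otherwise the
#' normal approximation with tie-corrected variance and a 0.5 continuity
#' correction is used. If all pooled values are identical both directions
#' return p = 1 (degenerate contract). P-values are never 0: they are
#' clamped to keep downstream z-transforms finite.
#'
#' @param a,b numeric vectors (each non-empty).
#' @param direction `"a_greater"` or `"b_greater"`: which group is tested
#'   for higher values.
#' @param exact_limit use the exact null when `length(a) + length(b)` is at
#'   most this and there are no ties. Default 16.
#' @return List with `p` (one-sided p-value in (0, 1\]), `U` (the U
#'   statistic of the tested group), `exact` (logical).
#' @export
mwu_one_sided <- function(a, b, direction = c("a_greater", "b_greater"),
                          exact_limit = 16) {
  direction <- match.arg(direction)
  if (!length(a) || !length(b)) stop_("both groups must be non-empty")
  if (direction == "b_greater") {
    tmp <- a; a <- b; b <- tmp
  }
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (!ties && n1 + n2 <= exact_limit) {
    # P(U >= u) under the exact null of all C(n1+n2, n1) labelings
    p <- 1 - stats::pwilcox(U - 1, n1, n2)
    exact <- TRUE
  } else {
    tab <- table(pooled)
    var_u <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(tab^3 - tab) / ((n1 + n2) * (n1 + n2 - 1)))
    if (var_u <= 0) return(list(p = 1, U = U, exact = FALSE))
    z <- (U - n1 * n2 / 2 - 0.5) / sqrt(var_u)
    p <- stats::pnorm(z, lower.tail = FALSE)
    exact <- FALSE
  }
  list(p = clamp(p, .Machine$double.xmin, 1), U = U, exact = exact)
}

#' All-vs-all per-probe directional rank tests
#'
#' For every unordered pair of sample groups (ordered lexicographically)
#' and every probe, computes the two one-sided Mann-Whitney p-values: one
#' for higher methylation in the first group of the pair, one for the
#' second. Keeping both directions allows combining probe p-values over a
#' region separately per direction, so a region can be called as higher
#' methylated in either group.
#'
#' @param ds a `MethylationDataset` with >= 2 groups of >= 2 samples each.
#' @param exact_limit passed to [mwu_one_sided()].
#' @return data.frame with one row per probe x pair: probe_id, chrom, pos,
#'   group1, group2 (group1 < group2 lexicographically), n1, n2, U
#'   (statistic of group1), p_group1_greater, p_group2_greater.
#' @export
all_pairs_probe_tests <- function(ds, exact_limit = 16) {
  check_testable(ds)
  grp <- sample_groups(ds)
  levels <- sort(unique(grp))
  pairs <- utils::combn(levels, 2, simplify = FALSE)
  res <- lapply(pairs, function(pr) {
    i1 <- group_columns(ds, pr[1])
    i2 <- group_columns(ds, pr[2])
    tests <- probe_pair_tests(ds$beta[, i1, drop = FALSE],
                              ds$beta[, i2, drop = FALSE], exact_limit)
    data.frame(
      probe_id = ds$probes$probe_id,
      chrom = ds$probes$chrom,
      pos = ds$probes$pos,
      group1 = pr[1], group2 = pr[2],
      n1 = length(i1), n2 = length(i2),
      U = tests$U,
      p_group1_greater = tests$p1,
      p_group2_greater = tests$p2,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}

# vectorized over probes: both one-sided p-values for one group pair
probe_pair_tests <- function(b1, b2, exact_limit = 16) {
  n1 <- ncol(b1); n2 <- ncol(b2)
  x <- cbind(b1, b2)
  n <- n1 + n2
  out <- vapply(seq_len(nrow(x)), function(i) {
    row <- x[i, ]
    r <- rank(row)
    U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    U2 <- n1 * n2 - U1
    ties <- anyDuplicated(row) > 0
    if (!ties && n <= exact_limit) {
      p1 <- 1 - stats::pwilcox(U1 - 1, n1, n2)
      p2 <- 1 - stats::pwilcox(U2 - 1, n2, n1)
    } else {
      tab <- table(row)
      var_u <- n1 * n2 / 12 * ((n + 1) - sum(tab^3 - tab) / (n * (n - 1)))
      if (var_u <= 0) {
        p1 <- p2 <- 1
      } else {
        sd_u <- sqrt(var_u)
        p1 <- stats::pnorm((U1 - n1 * n2 / 2 - 0.5) / sd_u, lower.tail = FALSE)
        p2 <- stats::pnorm((U2 - n1 * n2 / 2 - 0.5) / sd_u, lower.tail = FALSE)
      }
    }
    c(U1, clamp(p1, .Machine$double.xmin, 1), clamp(p2, .Machine$double.xmin, 1))
  }, numeric(3))
  list(U = out[1, ], p1 = out[2, ], p2 = out[3, ])
}

#' Write the per-probe p-value table as TSV
#' @param probe_tests output of [all_pairs_probe_tests()].
#' @param path output TSV; per-pair p-value columns are spread wide.
#' @export
write_probe_tests <- function(probe_tests, path) {
  pairs <- unique(probe_tests[, c("group1", "group2")])
  base <- unique(probe_tests[, c("probe_id", "chrom", "pos")])
  base <- base[order(base$chrom, base$pos), ]
  for (k in seq_len(nrow(pairs))) {
    sel <- probe_tests$group1 == pairs$group1[k] & probe_tests$group2 == pairs$group2[k]
    sub <- probe_tests[sel, c("probe_id", "p_group1_greater", "p_group2_greater")]
    tag <- paste0(pairs$group1[k], "_vs_", pairs$group2[k])
    names(sub)[2:3] <- c(paste0("p_", tag, ".", pairs$group1[k], "_greater"),
                         paste0("p_", tag, ".", pairs$group2[k], "_greater"))
    base <- merge(base, sub, by = "probe_id", sort = FALSE)
  }
  base <- base[order(base$chrom, base$pos), ]
  utils::write.table(base, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
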