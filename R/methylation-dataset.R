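#' Construct a methylation dataset
#'
#' Bundles a probes-by-samples beta-value matrix with per-probe genomic
#' coordinates and per-sample group labels. Probes are sorted by
#' (chromosome, position); positions are 0-based point coordinates of the
#' interrogated CpG. Beta values must be complete and inside \[0, 1\]:
#' downstream rank tests and region change summaries assume full columns,
#' so missing values are rejected at construction rather than silently
#' propagated.
#'
#' @param probe_id character vector of unique probe identifiers.
#' @param chrom chromosome name per probe.
#' @param pos 0-based genomic position per probe.
#' @param beta numeric matrix, probes x samples, values in \[0, 1\].
#' @param groups named character vector mapping sample name to group label;
#'   names must cover every column of `beta`.
#' @return An object of class `MethylationDataset`: a list with elements
#'   `probes` (data.frame: probe_id, chrom, pos), `beta` (matrix with probe
#'   rownames and sample colnames), `samples`, and `groups`.
#' @export
methylation_dataset <- function(probe_id, chrom, pos, beta, groups) {
  beta <- as.matrix(beta)
  n <- length(probe_id)
  if (anyDuplicated(probe_id))
    stop_("duplicate probe IDs: ", paste(unique(probe_id[duplicated(probe_id)]), collapse = ", "))
  if (length(chrom) != n || length(pos) != n || nrow(beta) != n)
    stop_("probe annotation and beta matrix dimensions disagree")
  if (is.null(colnames(beta)))
    stop_("beta matrix must carry sample names as column names")
  if (anyNA(beta))
    stop_("missing beta values are not supported; impute or filter probes first")
  if (any(beta < 0 | beta > 1))
    stop_("beta values outside [0, 1]")
  missing_grp <- setdiff(colnames(beta), names(groups))
  if (length(missing_grp))
    stop_("samples without a group assignment: ", paste(missing_grp, collapse = ", "))

  ord <- order(chrom, pos)
  probes <- data.frame(
    probe_id = as.character(probe_id)[ord],
    chrom = as.character(chrom)[ord],
    pos = as.integer(pos)[ord],
    stringsAsFactors = FALSE
  )
  beta <- beta[ord, , drop = FALSE]
  rownames(beta) <- probes$probe_id
  groups <- groups[colnames(beta)]

  structure(
    list(probes = probes, beta = beta,
         samples = colnames(beta),
         groups = as.character(stats::setNames(groups, colnames(beta)))),
    class = "MethylationDataset"
  )
}

#' @export
print.MethylationDataset <- function(x, ...) {
  grp <- table(sample_groups(x))
  cat(sprintf("MethylationDataset: %d probes x %d samples on %d chromosome(s)\n",
              nrow(x$beta), ncol(x$beta), length(unique(x$probes$chrom))))
  cat("groups:", paste(sprintf("%s (n=%d)", names(grp), grp), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.MethylationDataset <- function(x) dim(x$beta)

#' Sample-to-group mapping of a dataset
#' @param ds a `MethylationDataset`.
#' @return Named character vector, sample name -> group label.
#' @export
sample_groups <- function(ds) stats::setNames(ds$groups, ds$samples)

# samples (column indices) belonging to one group
group_columns <- function(ds, group) which(sample_groups(ds) == group)

check_testable <- function(ds) {
  tab <- table(sample_groups(ds))
  if (length(tab) < 2)
    stop_("at least 2 sample groups are required for testing")
  small <- names(tab)[tab < 2]
  if (length(small))
    stop_("each group needs >= 2 samples; too small: ", paste(small, collapse = ", "))
  invisible(TRUE)
}

#' Convert beta values to M-values
#'
#' The M-value is the logit2 transform `log2(b / (1 - b))`. Beta values are
#' clamped to `[eps, 1 - eps]` first so that 0 and 1 map to finite values;
#' interior values are unaffected for any reasonable `eps`.
#'
#' @param beta numeric vector or matrix of beta values in \[0, 1\].
#' @param eps clamping bound, in (0, 0.5). Default 1e-6.
#' @return M-values with the shape of `beta`.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  if (!(eps > 0 && eps < 0.5)) stop_("eps must be in (0, 0.5)")
  b <- clamp(beta, eps, 1 - eps)
  log2(b / (1 - b))
}

#' Quality filtering by detection p-values
#'
#' Two-step filter. First, samples whose fraction of probes failing the
#' detection cutoff (`detection_p > probe_p_cutoff`) exceeds
#' `sample_fail_fraction` are dropped. Second, among the surviving samples,
#' any probe that fails in at least one sample is dropped. The "any failing
#' sample" probe rule (rather than a per-probe failure fraction) is this
#' package's contract; complete columns are required downstream.
#'
#' @param ds a `MethylationDataset`.
#' @param detection_p matrix of detection p-values aligned to `ds$beta`
#'   (same probe and sample order).
#' @param probe_p_cutoff a probe measurement with detection p above this is
#'   a failure. Default 0.01 (conventional 450k QC).
#' @param sample_fail_fraction samples failing more than this fraction of
#'   probes are removed. Default 0.1.
#' @return List with `dataset` (the filtered `MethylationDataset`) and
#'   `report` (removed sample names, numbers of probes/samples removed).
#' @export
detection_filter <- function(ds, detection_p, probe_p_cutoff = 0.01,
                             sample_fail_fraction = 0.1) {
  detection_p <- as.matrix(detection_p)
  if (!all(dim(detection_p) == dim(ds$beta)))
    stop_("detection matrix must be aligned to the dataset (same shape)")
  if (!is.null(rownames(detection_p)) &&
      !identical(rownames(detection_p), rownames(ds$beta)))
    stop_("detection matrix probe order differs from the dataset")
  if (!is.null(colnames(detection_p)) &&
      !identical(colnames(detection_p), colnames(ds$beta)))
    stop_("detection matrix sample order differs from the dataset")

  fail <- detection_p > probe_p_cutoff
  sample_fail_frac <- colMeans(fail)
  bad_samples <- which(sample_fail_frac > sample_fail_fraction)
  keep_samples <- setdiff(seq_len(ncol(fail)), bad_samples)
  if (!length(keep_samples)) stop_("all samples removed by detection filter")

  probe_fail <- rowSums(fail[, keep_samples, drop = FALSE]) > 0
  if (all(probe_fail)) stop_("all probes removed by detection filter")

  keep_probes <- which(!probe_fail)
  out <- methylation_dataset(
    probe_id = ds$probes$probe_id[keep_probes],
    chrom = ds$probes$chrom[keep_probes],
    pos = ds$probes$pos[keep_probes],
    beta = ds$beta[keep_probes, keep_samples, drop = FALSE],
    groups = sample_groups(ds)[keep_samples]
  )
  list(
    dataset = out,
    report = list(
      removed_samples = ds$samples[bad_samples],
      n_samples_removed = length(bad_samples),
      n_probes_removed = sum(probe_fail),
      probe_p_cutoff = probe_p_cutoff,
      sample_fail_fraction = sample_fail_fraction
    )
  )
}

#' Cross-sample quantile normalization of beta values
#'
#' Replaces every sample's sorted beta vector by the across-sample mean of
#' sorted vectors; ties within a sample receive the mean of the reference
#' values at their would-be positions. A simple convenience; it is not one
#' of the array-specific normalization methods used upstream of this
#' package.
#'
#' @param ds a `MethylationDataset` without missing values.
#' @return A `MethylationDataset` with normalized beta values in \[0, 1\].
#' @export
quantile_normalize <- function(ds) {
  b <- ds$beta
  ref <- rowMeans(apply(b, 2, sort))
  bq <- apply(b, 2, function(col) {
    r <- rank(col, ties.method = "average")
    # non-integer ranks (ties) interpolate between adjacent reference values
    stats::approx(seq_along(ref), ref, xout = r)$y
  })
  dimnames(bq) <- dimnames(b)
  methylation_dataset(ds$probes$probe_id, ds$probes$chrom, ds$probes$pos,
                      clamp(bq, 0, 1), sample_groups(ds))
}
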