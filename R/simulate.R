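#' Configuration for the synthetic methylation-array generator
#'
#' The generator emulates the statistical structure DMR calling relies on:
#' a bimodal beta-value baseline (hypo- and hypermethylated CpGs), a
#' spatially correlated per-probe random effect shared across samples
#' (exponential decay with distance), spiked differential regions where one
#' group's betas are shifted by a fixed delta, i.i.d. measurement noise,
#' and truncation to \[0, 1\]. Probes inside spiked regions draw their
#' baseline from an intermediate-methylation mode so the spike stays
#' representable on the beta scale (truncation would otherwise attenuate
#' the programmed delta).
#'
#' @param n_probes total probes. Default 2000.
#' @param n_chroms chromosomes, probes split evenly. Default 2.
#' @param mean_spacing_bp mean of the exponential inter-probe spacing.
#'   Default 500.
#' @param groups named integer vector, group -> sample count.
#'   Default `c(case = 8, control = 8)`.
#' @param p_low_mode probability a baseline probe is in the low-methylation
#'   mode (Beta(2,10); high mode is Beta(10,2)). Default 0.6.
#' @param effect_sd sd of the shared spatial probe effect on the beta
#'   scale. Default 0.04.
#' @param corr_length_bp correlation length of the probe effect. Default 300.
#' @param noise_sd sd of i.i.d. per-measurement noise. Default 0.05.
#' @param spike either `NULL` (no spikes), a region set data.frame with
#'   extra columns `group` and `delta`, or a list
#'   `list(n_regions, delta, group, width_bp, min_probes)` asking the
#'   generator to pick grid-aligned windows of `width_bp` (so they coincide
#'   with tiles of that width) containing at least `min_probes` probes.
#' @param detection_fail_rate fraction of measurements given a large
#'   detection p-value. Default 0.
#' @param seed RNG seed (mandatory).
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(n_probes = 2000, n_chroms = 2,
                              mean_spacing_bp = 500,
                              groups = c(case = 8L, control = 8L),
                              p_low_mode = 0.6, effect_sd = 0.04,
                              corr_length_bp = 300, noise_sd = 0.05,
                              spike = NULL, detection_fail_rate = 0,
                              seed = NULL) {
  if (is.null(seed)) stop_("a seed is mandatory for reproducible simulation")
  structure(list(n_probes = n_probes, n_chroms = n_chroms,
                 mean_spacing_bp = mean_spacing_bp, groups = groups,
                 p_low_mode = p_low_mode, effect_sd = effect_sd,
                 corr_length_bp = corr_length_bp, noise_sd = noise_sd,
                 spike = spike, detection_fail_rate = detection_fail_rate,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Simulate a methylation dataset with known spiked DMRs
#'
#' Fully reproducible given the config seed. See [simulation_config()] for
#' the generative model.
#'
#' @param config a `SimulationConfig`.
#' @return List: `dataset` (a `MethylationDataset`), `detection_p` (aligned
#'   matrix), `truth` (region set of spiked regions with columns `group`
#'   and `delta`; zero rows when nothing is spiked), `chrom_sizes`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  with_local_seed(config$seed, {
    per_chrom <- diff(round(seq(0, config$n_probes, length.out = config$n_chroms + 1)))
    chroms <- sprintf("chr%d", seq_len(config$n_chroms))
    chrom <- rep(chroms, per_chrom)
    pos <- unlist(lapply(per_chrom, function(n) {
      1000L + cumsum(pmax(2L, round(stats::rexp(n, 1 / config$mean_spacing_bp))))
    }), use.names = FALSE)
    chrom_sizes <- stats::setNames(
      vapply(chroms, function(ch) max(pos[chrom == ch]) + 1000L, 0),
      chroms
    )

    truth <- resolve_spike(config, chrom, pos, chrom_sizes)
    if (nrow(truth) && any(abs(truth$delta) >= 1))
      stop_("infeasible spike delta (|delta| must be < 1 on the beta scale)")

    n <- length(pos)
    # which probes sit in a spiked region, and with which delta/group
    probe_delta <- numeric(n)
    probe_group <- rep(NA_character_, n)
    if (nrow(truth)) {
      for (r in seq_len(nrow(truth))) {
        sel <- chrom == truth$chrom[r] & pos >= truth$start[r] & pos < truth$end[r]
        probe_delta[sel] <- truth$delta[r]
        probe_group[sel] <- truth$group[r]
      }
    }
    spiked <- probe_delta != 0

    low <- stats::runif(n) < config$p_low_mode
    baseline <- ifelse(low, stats::rbeta(n, 2, 10), stats::rbeta(n, 10, 2))
    baseline[spiked] <- stats::rbeta(sum(spiked), 4, 6)

    effect <- config$effect_sd * ar_effect(chrom, pos, config$corr_length_bp)
    mu <- baseline + effect

    samples <- unlist(lapply(names(config$groups), function(g)
      sprintf("%s_%d", g, seq_len(config$groups[[g]]))), use.names = FALSE)
    grp <- rep(names(config$groups), config$groups)
    m <- length(samples)

    beta <- matrix(mu, n, m) +
      matrix(stats::rnorm(n * m, sd = config$noise_sd), n, m)
    for (j in seq_len(m)) {
      hit <- spiked & probe_group == grp[j]
      beta[hit, j] <- beta[hit, j] + probe_delta[hit]
    }
    beta <- clamp(beta, 0, 1)
    colnames(beta) <- samples

    det <- matrix(stats::runif(n * m, 0, 0.001), n, m, dimnames = list(NULL, samples))
    if (config$detection_fail_rate > 0) {
      failed <- stats::runif(n * m) < config$detection_fail_rate
      det[failed] <- stats::runif(sum(failed), 0.02, 1)
    }

    probe_id <- sprintf("cg%07d", seq_len(n))
    ds <- methylation_dataset(probe_id, chrom, pos, beta,
                              stats::setNames(grp, samples))
    # constructor sorts by (chrom, pos); positions are generated sorted, but
    # chromosome name order may differ from generation order
    ord <- order(chrom, pos)
    rownames(det) <- probe_id
    det <- det[ord, , drop = FALSE]
    list(dataset = ds, detection_p = det, truth = truth,
         chrom_sizes = chrom_sizes)
  })
}

# AR(1)-style standard-normal effect with corr exp(-distance / length)
ar_effect <- function(chrom, pos, corr_length_bp) {
  e <- numeric(length(pos))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    p <- pos[sel]
    x <- numeric(length(sel))
    x[1] <- stats::rnorm(1)
    if (length(sel) > 1) {
      rho <- exp(-diff(p) / corr_length_bp)
      innov <- stats::rnorm(length(sel) - 1)
      for (i in 2:length(sel)) {
        x[i] <- rho[i - 1] * x[i - 1] + sqrt(1 - rho[i - 1]^2) * innov[i - 1]
      }
    }
    e[sel] <- x
  }
  e
}

# turn a spike spec into a truth region table (possibly empty)
resolve_spike <- function(config, chrom, pos, chrom_sizes) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), gene_name = character(),
                      group = character(), delta = numeric(),
                      stringsAsFactors = FALSE)
  sp <- config$spike
  if (is.null(sp)) return(empty)
  if (is.data.frame(sp)) {
    rs <- as_region_set(sp)
    rs$group <- sp$group
    rs$delta <- sp$delta
    return(rs)
  }
  w <- sp$width_bp %||% 10000L
  min_probes <- sp$min_probes %||% 5L
  if (!sp$group %in% names(config$groups)) stop_("spike group not in config groups")
  cand <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    starts <- seq(0L, max(0L, chrom_sizes[[ch]] - w), by = w)
    cnt <- vapply(starts, function(s)
      sum(chrom == ch & pos >= s & pos < s + w), 0L)
    data.frame(chrom = ch, start = starts, end = starts + w, n = cnt,
               stringsAsFactors = FALSE)
  }))
  cand <- cand[cand$n >= min_probes, , drop = FALSE]
  if (nrow(cand) < sp$n_regions)
    stop_("not enough candidate windows with >= ", min_probes, " probes")
  pick <- cand[sort(sample(nrow(cand), sp$n_regions)), , drop = FALSE]
  data.frame(chrom = pick$chrom, start = pick$start, end = pick$end,
             name = sprintf("%s:%d-%d", pick$chrom, pick$start, pick$end),
             gene_name = NA_character_,
             group = sp$group, delta = sp$delta,
             stringsAsFactors = FALSE)
}

#' Write a simulation to disk in the package's input formats
#'
#' Emits matrix.tsv, samples.tsv, detection.tsv, chrom.sizes and, when
#' regions were spiked, truth.bed, all under `dir`.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_methylation_matrix(sim$dataset, file.path(dir, "matrix.tsv"),
                           file.path(dir, "samples.tsv"))
  det <- cbind(sim$dataset$probes,
               as.data.frame(sim$detection_p, check.names = FALSE))
  utils::write.table(det, file.path(dir, "detection.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(chrom = names(sim$chrom_sizes), size = as.integer(sim$chrom_sizes)),
    file.path(dir, "chrom.sizes"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  if (nrow(sim$truth)) write_bed(sim$truth, file.path(dir, "truth.bed"))
  invisible(dir)
}
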