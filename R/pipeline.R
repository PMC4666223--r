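#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis. Regions come from
#' exactly one of: a BED file, a tiling spec (chrom.sizes + window), or a
#' GTF promoter spec.
#'
#' @param matrix_path methylation matrix TSV.
#' @param sample_sheet_path sample sheet TSV.
#' @param out_dir output directory.
#' @param detection_path optional detection p-value matrix TSV.
#' @param regions_bed optional BED of regions of interest.
#' @param chrom_sizes_path,tile_window_bp optional tiling spec.
#' @param gtf_path,promoter_span_bp,promoter_orientation optional promoter
#'   spec.
#' @param normalize apply [quantile_normalize()]. Default FALSE.
#' @param probe_p_cutoff,sample_fail_fraction detection-filter thresholds.
#' @param q_cutoff significance threshold on region q-values. Default 0.05.
#' @param min_abs_median_change minimum absolute median beta change.
#' @param n_top_plots per-region plots for the top regions. Default 0.
#' @param gmt_path optional GMT for enrichment analysis.
#' @param gsea_n_perm,gsea_weight_p,gsea_metric GSEA knobs.
#' @param lag_bins ACF distance bins.
#' @param sidak_method `"span"` or `"count"`, see [call_dmrs()].
#' @param seed RNG seed (GSEA permutations). Default 1.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(matrix_path, sample_sheet_path, out_dir,
                            detection_path = NULL, regions_bed = NULL,
                            chrom_sizes_path = NULL, tile_window_bp = NULL,
                            gtf_path = NULL, promoter_span_bp = 2000,
                            promoter_orientation = "downstream",
                            normalize = FALSE, probe_p_cutoff = 0.01,
                            sample_fail_fraction = 0.1, q_cutoff = 0.05,
                            min_abs_median_change = 0, n_top_plots = 0,
                            gmt_path = NULL, gsea_n_perm = 1000,
                            gsea_weight_p = 1, gsea_metric = "log_q",
                            lag_bins = c(1, 51, 101, 201, 501, 1001),
                            sidak_method = "span", seed = 1) {
  if (!(q_cutoff > 0 && q_cutoff <= 1)) stop_("q_cutoff must be in (0, 1]")
  cfg <- as.list(environment())
  structure(cfg, class = "PipelineConfig")
}

validate_config_paths <- function(config) {
  paths <- c(matrix = config$matrix_path, sample_sheet = config$sample_sheet_path,
             detection = config$detection_path, regions_bed = config$regions_bed,
             chrom_sizes = config$chrom_sizes_path, gtf = config$gtf_path,
             gmt = config$gmt_path)
  for (nm in names(paths)) {
    if (!is.null(paths[[nm]]) && !file.exists(paths[[nm]]))
      stop_(nm, " file missing or unreadable: ", paths[[nm]])
  }
  n_region_sources <- sum(!is.null(config$regions_bed),
                          !is.null(config$tile_window_bp),
                          !is.null(config$gtf_path))
  if (n_region_sources != 1)
    stop_("exactly one region source required (regions_bed, tile_window_bp + chrom_sizes, or gtf_path)")
  if (!is.null(config$tile_window_bp) && is.null(config$chrom_sizes_path))
    stop_("tiling requires chrom_sizes_path")
  invisible(TRUE)
}

#' Run the full DMR-calling pipeline
#'
#' Validates inputs (failing fast with the offending file or sample named),
#' then: detection-p QC filter, optional normalization, all-vs-all probe
#' rank tests, region combination and Sidak correction per group pair,
#' CSV/BED emission, optional per-region plots and GSEA. Per-pair outputs
#' go to `<out_dir>/<group1>_vs_<group2>/`. A run log records every
#' parameter; all result files are deterministic given the inputs and seed.
#'
#' @param config a `PipelineConfig`.
#' @return Invisibly, a list with `results` (all tested regions, all
#'   pairs), `significant`, `out_dir` and the QC `report`.
#' @export
run_pipeline <- function(config) {
  validate_config_paths(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  ds <- read_methylation_matrix(config$matrix_path, config$sample_sheet_path)
  qc_report <- NULL
  if (!is.null(config$detection_path)) {
    det <- read_detection_matrix(config$detection_path, ds)
    flt <- detection_filter(ds, det, config$probe_p_cutoff,
                            config$sample_fail_fraction)
    ds <- flt$dataset
    qc_report <- flt$report
  }
  if (config$normalize) ds <- quantile_normalize(ds)

  regions <- if (!is.null(config$regions_bed)) {
    read_bed(config$regions_bed)
  } else if (!is.null(config$tile_window_bp)) {
    make_tiles(read_chrom_sizes(config$chrom_sizes_path), config$tile_window_bp)
  } else {
    promoters_from_gtf(config$gtf_path, config$promoter_span_bp,
                       config$promoter_orientation)
  }

  probe_tests <- all_pairs_probe_tests(ds)
  all_results <- call_dmrs(ds, regions, q_cutoff = 1, min_abs_median_change = 0,
                           probe_tests = probe_tests, lag_bins = config$lag_bins,
                           sidak_method = config$sidak_method)
  sig <- all_results[all_results$q <= config$q_cutoff &
                       abs(all_results$change_median) >= config$min_abs_median_change, ,
                     drop = FALSE]

  write_run_log(config, ds, all_results, sig, qc_report,
                file.path(config$out_dir, "run.log"))

  pairs <- unique(all_results[, c("group1", "group2")])
  gsea_out <- list()
  for (k in seq_len(nrow(pairs))) {
    g1 <- pairs$group1[k]; g2 <- pairs$group2[k]
    pair_dir <- file.path(config$out_dir, paste0(g1, "_vs_", g2))
    dir.create(pair_dir, showWarnings = FALSE)
    sel_all <- all_results$group1 == g1 & all_results$group2 == g2
    sel_sig <- sig$group1 == g1 & sig$group2 == g2
    pr_sel <- probe_tests$group1 == g1 & probe_tests$group2 == g2
    write_region_csv(all_results[sel_all, ], file.path(pair_dir, "regions.csv"))
    write_region_csv(sig[sel_sig, ], file.path(pair_dir, "significant_regions.csv"))
    write_tracks(sig[sel_sig, ], probe_tests[pr_sel, ], ds, pair_dir)
    write_probe_tests(probe_tests[pr_sel, ], file.path(pair_dir, "probe_tests.tsv"))
    if (config$n_top_plots > 0)
      plot_top_regions(all_results[sel_all, ], ds, config$n_top_plots, pair_dir)
    if (!is.null(config$gmt_path) &&
        any(!is.na(all_results$gene_name[sel_all]))) {
      gsea <- run_gsea(all_results[sel_all, ], read_gmt(config$gmt_path),
                       weight_p = config$gsea_weight_p,
                       n_perm = config$gsea_n_perm, seed = config$seed,
                       metric = config$gsea_metric)
      write_gsea_tsv(gsea, file.path(pair_dir, "gsea.tsv"),
                     file.path(pair_dir, "gsea_leading_edge_overlap.tsv"))
      gsea_out[[paste0(g1, "_vs_", g2)]] <- gsea
    }
  }

  invisible(list(results = all_results, significant = sig,
                 out_dir = config$out_dir, report = qc_report,
                 gsea = gsea_out))
}

write_run_log <- function(config, ds, all_results, sig, qc_report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("run at: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    "parameters:",
    vapply(names(config), function(nm) {
      sprintf("  %s = %s", nm, paste(format(config[[nm]]), collapse = ", "))
    }, ""),
    sprintf("dataset: %d probes x %d samples", nrow(ds$beta), ncol(ds$beta)),
    if (!is.null(qc_report)) sprintf(
      "qc: removed %d sample(s) [%s], %d probe(s)",
      qc_report$n_samples_removed,
      paste(qc_report$removed_samples, collapse = ","),
      qc_report$n_probes_removed) else "qc: detection filter not applied",
    sprintf("regions tested: %d (skipped without probes: %d)",
            nrow(unique(all_results[, c("chrom", "start", "end")])),
            attr(all_results, "n_regions_skipped")),
    sprintf("significant regions (q <= %g, |median change| >= %g): %d",
            config$q_cutoff, config$min_abs_median_change, nrow(sig))
  ), con)
  invisible(path)
}

#' Write genome-browser tracks
#'
#' Emits, per group pair: (a) `significant_regions.bed` — BED6 with score
#' `min(1000, round(-10 log10 q))` and strand `+` when the region is higher
#' methylated in group2 (lexicographically second) else `-`; (b)
#' `probes.bed` — all probes; (c) `probe_q.bed` — BED9 with a per-probe
#' Sidak q (over the probe count, from the smaller one-sided p) and a
#' blue-to-red itemRgb ramp, blue = least significant; (d)
#' `change_median.bedgraph` — per-probe difference of group median betas
#' (group2 - group1). All coordinates 0-based half-open, sorted.
#'
#' @param sig_results significant region results (one group pair).
#' @param probe_tests probe test table for the same pair.
#' @param ds the `MethylationDataset`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_tracks <- function(sig_results, probe_tests, ds, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pt <- probe_tests[order(probe_tests$chrom, probe_tests$pos), ]
  g1 <- pt$group1[1]; g2 <- pt$group2[1]

  # (a) significant regions
  con <- file(file.path(out_dir, "significant_regions.bed"), "w")
  writeLines(sprintf('track name="significant regions %s vs %s"', g1, g2), con)
  if (nrow(sig_results)) {
    sr <- sig_results[order(sig_results$chrom, sig_results$start), ]
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", sr$chrom, sr$start, sr$end,
                       sr$name, pmin(1000, round(-10 * log10(sr$q))),
                       ifelse(sr$direction == g2, "+", "-")), con)
  }
  close(con)

  # (b) all probes
  write_bed(data.frame(chrom = pt$chrom, start = pt$pos, end = pt$pos + 1L,
                       name = pt$probe_id),
            file.path(out_dir, "probes.bed"), track_name = "array probes")

  # (c) per-probe q with color ramp
  p_min <- pmin(pt$p_group1_greater, pt$p_group2_greater)
  q_probe <- pmin(-expm1(nrow(pt) * log1p(-clamp(p_min, 1e-16, 1 - 1e-16))), 1)
  ramp <- grDevices::colorRamp(c("blue", "red"))(clamp(-log10(q_probe) / 4, 0, 1))
  rgb_txt <- apply(round(ramp), 1, paste, collapse = ",")
  con <- file(file.path(out_dir, "probe_q.bed"), "w")
  writeLines(sprintf('track name="probe q %s vs %s" itemRgb="On"', g1, g2), con)
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t.\t%d\t%d\t%s", pt$chrom, pt$pos,
                     pt$pos + 1L, pt$probe_id,
                     pmin(1000, round(-10 * log10(q_probe))),
                     pt$pos, pt$pos + 1L, rgb_txt), con)
  close(con)

  # (d) per-probe median change bar track
  i1 <- group_columns(ds, g1); i2 <- group_columns(ds, g2)
  idx <- match(pt$probe_id, ds$probes$probe_id)
  d <- apply(ds$beta[idx, i2, drop = FALSE], 1, stats::median) -
    apply(ds$beta[idx, i1, drop = FALSE], 1, stats::median)
  con <- file(file.path(out_dir, "change_median.bedgraph"), "w")
  writeLines(sprintf('track type=bedGraph name="median change %s - %s"', g2, g1), con)
  writeLines(sprintf("%s\t%d\t%d\t%.6g", pt$chrom, pt$pos, pt$pos + 1L, d), con)
  close(con)

  invisible(out_dir)
}

#' Plot per-probe betas for the top regions
#'
#' For the `k` most significant regions, a per-probe boxplot of beta values
#' by group, written as PNG.
#'
#' @param region_results region results (one group pair), any order.
#' @param ds the `MethylationDataset`.
#' @param k number of regions to plot (0 writes nothing).
#' @param out_dir output directory.
#' @return Paths of the written files, invisibly.
#' @export
plot_top_regions <- function(region_results, ds, k, out_dir) {
  if (k <= 0 || !nrow(region_results)) return(invisible(character()))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rr <- region_results[order(region_results$q, region_results$chrom,
                             region_results$start), ]
  rr <- rr[seq_len(min(k, nrow(rr))), ]
  grp <- sample_groups(ds)
  files <- character(nrow(rr))
  for (i in seq_len(nrow(rr))) {
    sel <- ds$probes$chrom == rr$chrom[i] &
      ds$probes$pos >= rr$start[i] & ds$probes$pos < rr$end[i]
    b <- ds$beta[sel, , drop = FALSE]
    df <- data.frame(
      pos = rep(ds$probes$pos[sel], ncol(b)),
      beta = as.vector(b),
      group = rep(as.character(grp), each = nrow(b))
    )
    gp <- ggplot2::ggplot(df, ggplot2::aes(x = factor(pos), y = beta,
                                           fill = group)) +
      ggplot2::geom_boxplot(outlier.size = 0.5) +
      ggplot2::labs(title = sprintf("%s (q = %.3g, %s vs %s)", rr$name[i],
                                    rr$q[i], rr$group1[i], rr$group2[i]),
                    x = "probe position", y = "beta value") +
      ggplot2::ylim(0, 1) +
      ggplot2::theme_bw() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 6))
    files[i] <- file.path(out_dir, sprintf("region_%03d_%s.png", i,
                                           gsub("[^A-Za-z0-9._-]", "_", rr$name[i])))
    grDevices::png(files[i], width = 900, height = 500)
    print(gp)
    grDevices::dev.off()
  }
  invisible(files)
}
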