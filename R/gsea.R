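#' Rank genes from region results
#'
#' Builds the pre-ranked gene list for enrichment analysis from
#' gene-linked region results of one group pair. Per gene the region with
#' the smallest q is kept (ties: larger absolute median change, then region
#' name); the ranking score is `sign(change_median) * -log10(q)` (metric
#' `"log_q"`, default) or the signed `change_median` itself (metric
#' `"change"`). Positive scores mean higher methylation in the second
#' group of the pair. Genes are sorted by descending score with a
#' deterministic alphabetical tie-break.
#'
#' @param region_results data.frame from [call_dmrs()] (one group pair).
#' @param metric `"log_q"` or `"change"`.
#' @return data.frame with columns `gene` and `score`, sorted.
#' @export
rank_genes <- function(region_results, metric = c("log_q", "change")) {
  metric <- match.arg(metric)
  rr <- region_results[!is.na(region_results$gene_name), , drop = FALSE]
  if (!nrow(rr)) stop_("no gene-linked regions (gene_name missing everywhere)")
  if (nrow(unique(rr[, c("group1", "group2")])) > 1)
    stop_("rank_genes expects results from a single group pair")
  rr <- rr[order(rr$gene_name, rr$q, -abs(rr$change_median), rr$name), ]
  rr <- rr[!duplicated(rr$gene_name), ]
  score <- if (metric == "log_q") sign(rr$change_median) * -log10(rr$q)
           else rr$change_median
  out <- data.frame(gene = rr$gene_name, score = score, stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list; a gene in the set adds
#' `|score|^weight_p / sum_hits |score|^weight_p`, a miss subtracts
#' `1 / (N - N_hit)`. The enrichment score is the signed maximum deviation
#' of the running sum from zero and `peak_index` the (1-based) position
#' attaining it. `weight_p = 0` gives the classic Kolmogorov-Smirnov form.
#' If every hit has score 0 the hits fall back to equal weights.
#'
#' @param ranked data.frame from [rank_genes()] (columns gene, score).
#' @param gene_set character vector of member genes.
#' @param weight_p score weighting exponent (0, 1 or 2). Default 1.
#' @return List with `ES`, `peak_index`, `n_hits` and the `running` sum.
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  hit <- ranked$gene %in% gene_set
  n_hit <- sum(hit)
  if (n_hit == 0) stop_("gene set has no member in the ranked list (untestable)")
  n <- nrow(ranked)
  w <- abs(ranked$score)^weight_p
  nr <- sum(w[hit])
  if (nr == 0) {
    w[hit] <- 1
    nr <- n_hit
  }
  step <- numeric(n)
  step[hit] <- w[hit] / nr
  if (n > n_hit) step[!hit] <- -1 / (n - n_hit)
  running <- cumsum(step)
  peak <- which.max(abs(running))
  list(ES = running[peak], peak_index = peak, n_hits = n_hit, running = running)
}

# run code under a seed without clobbering the caller's RNG state
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Gene-permutation p-value for an enrichment score
#'
#' Null enrichment scores from `n_perm` random gene subsets of the same
#' size drawn from the ranked list (seeded, reproducible);
#' `p = (1 + #\{|ES_null| >= |ES_obs|\}) / (n_perm + 1)`.
#'
#' @param ranked ranked gene list data.frame.
#' @param gene_set character vector of member genes.
#' @param n_perm number of permutations (>= 100). Default 1000.
#' @param seed RNG seed (required for reproducibility).
#' @param weight_p score weighting exponent.
#' @return List with `p_perm`, `ES`, `peak_index`, `n_hits`.
#' @export
permutation_p <- function(ranked, gene_set, n_perm = 1000, seed = 1,
                          weight_p = 1) {
  if (n_perm < 100) stop_("n_perm must be >= 100")
  obs <- enrichment_score(ranked, gene_set, weight_p)
  size <- obs$n_hits
  if (size > nrow(ranked)) stop_("gene set larger than the ranked list")
  null_es <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      enrichment_score(ranked, sample(ranked$gene, size), weight_p)$ES
    }, 0)
  })
  p <- (1 + sum(abs(null_es) >= abs(obs$ES))) / (n_perm + 1)
  list(p_perm = p, ES = obs$ES, peak_index = obs$peak_index, n_hits = size)
}

#' Leading-edge genes of an enrichment result
#'
#' For a positive enrichment score: the set members at ranks up to and
#' including the running-sum peak; for a negative score: the members
#' ranked after the peak.
#'
#' @param ranked ranked gene list data.frame.
#' @param gene_set character vector of member genes.
#' @param es the enrichment score (its sign selects the side).
#' @param peak_index 1-based peak position.
#' @return Character vector of core genes, in rank order.
#' @export
leading_edge <- function(ranked, gene_set, es, peak_index) {
  hit <- ranked$gene %in% gene_set
  idx <- seq_len(nrow(ranked))
  core <- if (es >= 0) hit & idx <= peak_index else hit & idx > peak_index
  ranked$gene[core]
}

#' Jaccard overlap matrix of leading edges
#' @param edges named list of leading-edge gene vectors.
#' @return Symmetric matrix of Jaccard indices in \[0, 1\], diagonal 1.
#' @export
leading_edge_overlap <- function(edges) {
  k <- length(edges)
  m <- diag(1, k)
  dimnames(m) <- list(names(edges), names(edges))
  if (k < 2) return(m)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      u <- length(union(edges[[i]], edges[[j]]))
      m[i, j] <- m[j, i] <- if (u == 0) 0 else
        length(intersect(edges[[i]], edges[[j]])) / u
    }
  }
  m
}

#' Gene set enrichment analysis on region results
#'
#' Ranks gene-linked regions, scores every gene set with at least one
#' member in the list, computes permutation p-values and the leading-edge
#' overlap matrix across significant sets.
#'
#' @param region_results results of [call_dmrs()] for one group pair.
#' @param gene_sets named list of gene sets (see [read_gmt()]).
#' @param weight_p score weighting exponent. Default 1.
#' @param n_perm permutations per set. Default 1000.
#' @param seed RNG seed.
#' @param metric ranking metric, see [rank_genes()].
#' @param overlap_p_cutoff sets with `p_perm` at or below this enter the
#'   leading-edge overlap matrix. Default 0.05.
#' @param bh also report Benjamini-Hochberg adjusted p-values across sets.
#' @return List: `results` (data.frame set, size, ES, peak_index, p_perm,
#'   optional p_bh, leading_edge), `overlap` (Jaccard matrix),
#'   `untestable` (sets with empty intersection), `ranked`.
#' @export
run_gsea <- function(region_results, gene_sets, weight_p = 1, n_perm = 1000,
                     seed = 1, metric = "log_q", overlap_p_cutoff = 0.05,
                     bh = FALSE) {
  ranked <- rank_genes(region_results, metric)
  testable <- vapply(gene_sets, function(s) any(ranked$gene %in% s), TRUE)
  rows <- vector("list", sum(testable))
  edges <- list()
  names_t <- names(gene_sets)[testable]
  for (i in seq_along(names_t)) {
    nm <- names_t[i]
    pp <- permutation_p(ranked, gene_sets[[nm]], n_perm,
                        seed = seed + i, weight_p = weight_p)
    le <- leading_edge(ranked, gene_sets[[nm]], pp$ES, pp$peak_index)
    edges[[nm]] <- le
    rows[[i]] <- data.frame(set = nm, size = pp$n_hits, ES = pp$ES,
                            peak_index = pp$peak_index, p_perm = pp$p_perm,
                            leading_edge = paste(le, collapse = ","),
                            stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  if (is.null(results))
    results <- data.frame(set = character(), size = integer(), ES = numeric(),
                          peak_index = integer(), p_perm = numeric(),
                          leading_edge = character())
  if (bh && nrow(results)) results$p_bh <- stats::p.adjust(results$p_perm, "BH")
  results <- results[order(results$p_perm, -abs(results$ES), results$set), ]
  rownames(results) <- NULL
  sig <- results$set[results$p_perm <= overlap_p_cutoff]
  list(results = results,
       overlap = leading_edge_overlap(edges[sig]),
       untestable = names(gene_sets)[!testable],
       ranked = ranked)
}

#' Write GSEA outputs as TSV
#' @param gsea output of [run_gsea()].
#' @param results_path per-set table TSV.
#' @param overlap_path optional leading-edge overlap matrix TSV.
#' @export
write_gsea_tsv <- function(gsea, results_path, overlap_path = NULL) {
  utils::write.table(gsea$results, results_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(overlap_path))
    utils::write.table(gsea$overlap, overlap_path, sep = "\t", quote = FALSE,
                       col.names = NA)
  invisible(results_path)
}
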