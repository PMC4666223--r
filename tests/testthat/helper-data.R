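# small dataset with explicit values, built in code
toy_dataset <- function(beta = NULL, groups = c(A = 2, B = 2), n_probes = 4,
                        chrom = NULL, pos = NULL, seed = 1) {
  n_samples <- sum(groups)
  if (is.null(beta)) {
    set.seed(seed)
    beta <- matrix(runif(n_probes * n_samples), n_probes, n_samples)
  }
  n_probes <- nrow(beta)
  samples <- unlist(lapply(names(groups), function(g)
    paste0(g, seq_len(groups[[g]]))))
  colnames(beta) <- samples
  if (is.null(chrom)) chrom <- rep("chr1", n_probes)
  if (is.null(pos)) pos <- seq(100, by = 100, length.out = n_probes)
  methylation_dataset(
    probe_id = sprintf("p%02d", seq_len(n_probes)),
    chrom = chrom, pos = pos, beta = beta,
    groups = setNames(rep(names(groups), groups), samples)
  )
}

write_toy_gtf <- function(path) {
  writeLines(c(
    'chr1\tsrc\tgene\t5001\t9000\t.\t+\t.\tgene_id "g1"; gene_name "GENE1";',
    'chr1\tsrc\tgene\t5001\t9000\t.\t-\t.\tgene_id "g2"; gene_name "GENE2";',
    'chr2\tsrc\tgene\t501\t4000\t.\t+\t.\tgene_id "g3"; gene_name "GENE3";',
    'chr1\tsrc\texon\t5001\t5200\t.\t+\t.\tgene_id "g1"; gene_name "GENE1"; transcript_id "t1";',
    'chr1\tsrc\texon\t5001\t5200\t.\t+\t.\tgene_id "g1"; gene_name "GENE1"; transcript_id "t2";',
    'chr1\tsrc\texon\t6001\t6300\t.\t+\t.\tgene_id "g1"; gene_name "GENE1"; transcript_id "t2";'
  ), path)
  path
}
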