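# Synthetic exon-level coverage with planted 5' enrichment, plus a
# matching GTF gene model.

#' Ground truth for an exon-coverage simulation
#'
#' Defines a gene model (`n_exons` exons per gene on alternating strands),
#' the sample layout (NTC replicates plus one sample per knockout), and
#' planted 5' biases: for a biased (knockout, gene) pair the expected
#' coverage of the First exon is multiplied by `2^bias`.
#'
#' @param n_genes number of genes.
#' @param n_exons exons per gene (recycled; all >= 2 when biases are
#'   planted).
#' @param reads_per_gene expected reads per gene per sample.
#' @param knockouts character vector of knockout sample labels (an AAVS1
#'   entry provides the neutral reference for shift tests).
#' @param n_ntc number of non-targeting control samples.
#' @param bias_true data frame (`knockout`, `gene_id`, `bias`) of planted
#'   log2 first-exon enrichments, or NULL.
#' @param exon_length exon width in bp.
#' @param seed RNG seed.
#' @export
coverage_sim_truth <- function(n_genes = 60, n_exons = 4,
                               reads_per_gene = 1e4,
                               knockouts = c("AAVS1", "CDK12"), n_ntc = 2,
                               bias_true = NULL, exon_length = 200,
                               seed = 1) {
  genes <- sprintf("GENE%03d", seq_len(n_genes))
  n_ex <- rep_len(n_exons, n_genes)
  if (!is.null(bias_true)) {
    stopifnot(all(c("knockout", "gene_id", "bias") %in% names(bias_true)),
              all(bias_true$knockout %in% knockouts),
              all(bias_true$gene_id %in% genes))
    if (any(n_ex[match(bias_true$gene_id, genes)] < 2))
      stop("cannot plant a 5' bias on a single-exon gene")
  }
  structure(list(genes = genes, n_exons = n_ex,
                 reads_per_gene = reads_per_gene, knockouts = knockouts,
                 n_ntc = n_ntc, bias_true = bias_true,
                 exon_length = exon_length, seed = seed),
            class = "coverage_sim_truth")
}

#' Simulate per-exon read counts and the matching gene model
#'
#' NTC samples have uniform expected coverage across a gene's exons;
#' biased (knockout, gene) pairs multiply the First exon's expectation by
#' `2^bias`.  Counts are Poisson.  The gene model places each gene on its
#' own contig with `n_exons` disjoint exons in one transcript
#' (alternating + / - strands, so First is the highest-coordinate exon
#' for half the genes).
#'
#' @param truth a [coverage_sim_truth()].
#' @return list with `counts` (long: sample, gene_id, exon_id, count),
#'   `exons` (classified table), `sample_info` (sample, knockout),
#'   `gtf` (path to the written GTF).
#' @export
simulate_exon_coverage <- function(truth) {
  stopifnot(inherits(truth, "coverage_sim_truth"))
  gtf <- tempfile(fileext = ".gtf")
  write_sim_gtf(truth, gtf)
  exons <- classify_exons(gtf)
  samples <- data.frame(
    sample = c(sprintf("NTC_rep%d", seq_len(truth$n_ntc)), truth$knockouts),
    knockout = c(rep("NTC", truth$n_ntc), truth$knockouts),
    stringsAsFactors = FALSE)
  counts <- with_seed(truth$seed, {
    res <- list()
    for (i in seq_len(nrow(samples))) {
      ex <- exons
      mu <- truth$reads_per_gene /
        truth$n_exons[match(ex$gene_id, truth$genes)]
      if (!is.null(truth$bias_true)) {
        bt <- truth$bias_true[truth$bias_true$knockout ==
                                samples$knockout[i], , drop = FALSE]
        hit <- ex$category == "First" & ex$gene_id %in% bt$gene_id
        mu[hit] <- mu[hit] *
          2^bt$bias[match(ex$gene_id[hit], bt$gene_id)]
      }
      res[[i]] <- data.frame(sample = samples$sample[i],
                             gene_id = ex$gene_id, exon_id = ex$exon_id,
                             count = stats::rpois(nrow(ex), mu),
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, res)
  })
  rownames(counts) <- NULL
  list(counts = counts, exons = exons, sample_info = samples, gtf = gtf)
}

# one transcript per gene, disjoint exons separated by introns
write_sim_gtf <- function(truth, path) {
  lines <- character(0)
  for (i in seq_along(truth$genes)) {
    g <- truth$genes[i]
    strand <- if (i %% 2 == 0) "-" else "+"
    n <- truth$n_exons[i]
    w <- truth$exon_length
    starts <- 1000 + (seq_len(n) - 1) * (w + 300)
    for (j in seq_len(n)) {
      lines <- c(lines, sprintf(
        "chr_%s\tsim\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t1\";",
        g, starts[j], starts[j] + w - 1, strand, g, g))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
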