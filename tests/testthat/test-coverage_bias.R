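# helper: write a small GTF from a transcript structure list
write_test_gtf <- function(tx, strand = "+", gene = "G1") {
  path <- tempfile(fileext = ".gtf")
  lines <- character(0)
  for (t in names(tx)) {
    for (e in tx[[t]]) {
      lines <- c(lines, sprintf(
        "chr1\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
        e[1], e[2], strand, gene, t))
    }
  }
  writeLines(lines, path)
  path
}

e1 <- c(100, 200); e2 <- c(400, 500); e3 <- c(700, 800)

test_that("exon classification follows the positional rules and priority", {
  # single transcript: first / internal / last
  p1 <- write_test_gtf(list(t1 = list(e1, e2, e3)))
  ex1 <- classify_exons(p1)
  expect_equal(ex1$category[order(ex1$start)],
               c("First", "Internal", "Last"))
  # minus strand: the highest-coordinate exon is First
  p2 <- write_test_gtf(list(t1 = list(e1, e2, e3)), strand = "-")
  ex2 <- classify_exons(p2)
  expect_equal(ex2$category[order(ex2$start)],
               c("Last", "Internal", "First"))
  # two transcripts T1=[e1,e2,e3], T2=[e2,e3]: e2 is initial in T2 but not
  # the 5'-most initial exon -> AlternativeFirst; e3 terminal in both -> Last
  p3 <- write_test_gtf(list(t1 = list(e1, e2, e3), t2 = list(e2, e3)))
  ex3 <- classify_exons(p3)
  expect_equal(ex3$category[order(ex3$start)],
               c("First", "AlternativeFirst", "Last"))
  # shared exons are single records
  expect_equal(nrow(ex3), 3)
  # a two-exon single transcript has one First and one Last (priority:
  # the same exon cannot take both roles unless the gene has one exon)
  p4 <- write_test_gtf(list(t1 = list(e1, e2)))
  expect_setequal(classify_exons(p4)$category, c("First", "Last"))
})

test_that("strand flip exchanges First and Last labels", {
  tx <- list(t1 = list(e1, e2, e3), t2 = list(e2, e3))
  plus <- classify_exons(write_test_gtf(tx, "+"))
  minus <- classify_exons(write_test_gtf(tx, "-"))
  plus <- plus[order(plus$start), ]; minus <- minus[order(minus$start), ]
  expect_equal(plus$category[1], "First")
  expect_equal(minus$category[1], "Last")
  expect_equal(plus$category[3], "Last")
  expect_equal(minus$category[3], "First")
})

test_that("read counting by >=1 bp overlap matches a brute-force oracle", {
  set.seed(14)
  exons <- data.frame(gene_id = "G1",
                      exon_id = sprintf("G1:e%d", 1:3),
                      chrom = "chr1", strand = "+",
                      start = c(100, 400, 700), end = c(200, 500, 800),
                      stringsAsFactors = FALSE)
  starts <- sample(1:900, 300, replace = TRUE)
  widths <- sample(20:120, 300, replace = TRUE)
  strands <- sample(c("+", "-"), 300, replace = TRUE)
  reads <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(starts, width = widths),
                                  strand = strands)
  got <- count_exon_reads(reads, exons)
  # brute force: interval intersection test per (read, exon), same strand
  for (i in seq_len(nrow(exons))) {
    manual <- sum(starts <= exons$end[i] &
                    (starts + widths - 1) >= exons$start[i] &
                    strands == "+")
    expect_equal(got$count[i], manual)
  }
  # a read spanning two exons counts for both
  spanner <- GenomicRanges::GRanges("chr1", IRanges::IRanges(150, 450),
                                    strand = "+")
  two <- count_exon_reads(spanner, exons)
  expect_equal(two$count, c(1L, 1L, 0L))
})

test_that("RPM normalization uses the closed form and the 10-read gene floor", {
  counts <- data.frame(
    sample = "s1",
    gene_id = c("A", "A", "B"),
    exon_id = c("A:e1", "A:e2", "B:e1"),
    count = c(100, 999891, 9))
  cov <- exon_coverage(counts)
  # gene B carries 9 < 10 reads -> dropped
  expect_false("B" %in% cov$gene_id)
  # 100 reads in a 10^6-read sample -> RPM 100, log2(101) with c = 1
  expect_equal(cov$rpm[cov$exon_id == "A:e1"], 100)
  expect_equal(cov$rpm_log2[cov$exon_id == "A:e1"], log2(101))
  expect_error(exon_coverage(data.frame(sample = "s", gene_id = "A",
                                        exon_id = "e", count = 0)),
               "zero-read")
})

test_that("NTC-vs-NTC contrast has identically zero bias", {
  tr <- coverage_sim_truth(n_genes = 20, reads_per_gene = 2000,
                           knockouts = "AAVS1", n_ntc = 2, seed = 5)
  sim <- simulate_exon_coverage(tr)
  # relabel the NTC samples as a pseudo-knockout built from the same data
  dup <- sim$counts[sim$counts$sample %in% c("NTC_rep1", "NTC_rep2"), ]
  dup$sample <- paste0(dup$sample, "_as_ko")
  counts <- rbind(sim$counts, dup)
  info <- rbind(sim$sample_info,
                data.frame(sample = unique(dup$sample), knockout = "NTCKO"))
  cov <- exon_coverage(counts)
  fb <- five_prime_bias(cov, sim$exons, info)
  b <- fb$bias5[fb$bias5$knockout == "NTCKO", ]
  expect_true(all(b$bias5 == 0))
})

test_that("the bias convention is the difference of log2 enrichments", {
  # lfc(First) = 1, lfc(Last) = -1  =>  bias5 = 2
  lfc_first <- 1; lfc_last <- -1
  expect_equal(lfc_first - lfc_last, 2)
  # through the pipeline: planted bias 2 on one gene recovered within 0.3
  bt <- data.frame(knockout = "CDK12", gene_id = "GENE001", bias = 2)
  tr <- coverage_sim_truth(n_genes = 30, reads_per_gene = 1e4,
                           bias_true = bt, seed = 6)
  sim <- simulate_exon_coverage(tr)
  cov <- exon_coverage(sim$counts)
  fb <- five_prime_bias(cov, sim$exons, sim$sample_info)
  got <- fb$bias5$bias5[fb$bias5$knockout == "CDK12" &
                          fb$bias5$gene_id == "GENE001"]
  expect_equal(got, 2, tolerance = 0.3)
  # unbiased genes stay near zero
  rest <- fb$bias5$bias5[fb$bias5$knockout == "CDK12" &
                           fb$bias5$gene_id != "GENE001"]
  expect_lt(max(abs(rest)), 0.5)
  # a transcriptome-wide first-exon shift is picked up by the t-test
  # against the AAVS1 reference
  bt_wide <- data.frame(knockout = "CDK12",
                        gene_id = sprintf("GENE%03d", 1:20), bias = 1)
  tr2 <- coverage_sim_truth(n_genes = 30, reads_per_gene = 1e4,
                            bias_true = bt_wide, seed = 7)
  sim2 <- simulate_exon_coverage(tr2)
  fb2 <- five_prime_bias(exon_coverage(sim2$counts), sim2$exons,
                         sim2$sample_info)
  tt <- fb2$first_exon_test
  expect_lt(tt$p[tt$knockout == "CDK12"], 0.01)
  expect_gt(tt$mean_first_lfc[tt$knockout == "CDK12"], 0.2)
  # planting on a single-exon gene is rejected
  expect_error(coverage_sim_truth(n_exons = 1, bias_true = bt),
               "single-exon")
})

test_that("deterministic seeds reproduce the coverage table", {
  tr <- coverage_sim_truth(n_genes = 10, seed = 9)
  expect_identical(simulate_exon_coverage(tr)$counts,
                   simulate_exon_coverage(tr)$counts)
})

test_that("complete-linkage clustering recovers planted bias groups", {
  set.seed(4)
  kos <- paste0("KO", 1:4)
  genes <- sprintf("g%02d", 1:40)
  M <- matrix(rnorm(40 * 4, 0, 0.05), 40, 4,
              dimnames = list(genes, kos))
  M[1:20, ] <- M[1:20, ] + 2  # planted biased group
  cl <- cluster_bias(M, n_clusters = 2)
  grp <- cl$clusters
  expect_equal(length(unique(grp[1:20])), 1)
  expect_equal(length(unique(grp[21:40])), 1)
  expect_false(grp[1] == grp[21])
  # permuting knockout columns leaves memberships unchanged
  cl2 <- cluster_bias(M[, c(3, 1, 4, 2)], n_clusters = 2)
  expect_true(all((cl$clusters == cl$clusters[1]) ==
                    (cl2$clusters == cl2$clusters[1])))
  # identical rows always co-cluster
  M2 <- M; M2[1:30, ] <- rep(M2[1, ], each = 30)
  cl3 <- cluster_bias(M2, n_clusters = 2)
  expect_equal(length(unique(cl3$clusters[1:30])), 1)
  expect_error(cluster_bias(M[1:5, ], n_clusters = 12), "fewer")
})

test_that("GMT round trip and Fisher enrichment flag the planted set", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("SET_A\tdesc\tg1\tg2\tg3\tg4",
               "SET_B\tdesc\tg7\tg8\tg9"), path)
  sets <- read_gmt(path)
  expect_equal(sets$SET_A, c("g1", "g2", "g3", "g4"))
  universe <- sprintf("g%d", 1:100)
  hits <- c("g1", "g2", "g3", "g4", "g20")
  res <- enrich_fisher(hits, sets, universe)
  expect_lt(res$q[res$set == "SET_A"], 0.05)
  expect_gt(res$q[res$set == "SET_B"], 0.5)
  expect_gt(res$odds_ratio[res$set == "SET_A"], 10)
})
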