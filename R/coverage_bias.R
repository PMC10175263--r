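# 5' transcript coverage bias: exon categorization from a gene model,
# per-exon coverage normalization, fold enrichment relative to
# non-targeting controls, the first-vs-last-exon bias statistic, and
# hierarchical clustering of bias patterns.

EXON_CATEGORIES <- c("First", "Last", "AlternativeFirst", "AlternativeLast",
                     "Internal")

#' Classify exons of a gene model into positional categories
#'
#' Per gene (strand-aware): `First` is the single 5'-most
#' transcript-initial exon, `AlternativeFirst` are other transcript-initial
#' exons, `Last` is the 3'-most transcript-terminal exon,
#' `AlternativeLast` other transcript-terminal exons, `Internal` the rest.
#' Exons shared verbatim between transcripts are single records; an exon
#' qualifying for several categories takes the highest-priority one
#' (First > Last > AlternativeFirst > AlternativeLast > Internal).
#'
#' @param gtf path to a GTF file, or a `GRanges` of exon features with
#'   `gene_id` and `transcript_id` metadata.
#' @return data frame with `gene_id`, `exon_id`, `chrom`, `strand`,
#'   `start`, `end` (1-based inclusive, as in the GTF) and `category`.
#' @export
classify_exons <- function(gtf) {
  gr <- if (is.character(gtf)) rtracklayer::import(gtf) else gtf
  md <- S4Vectors::mcols(gr)
  if ("type" %in% names(md)) gr <- gr[md$type == "exon"]
  md <- S4Vectors::mcols(gr)
  stopifnot(all(c("gene_id", "transcript_id") %in% names(md)))
  df <- data.frame(gene_id = md$gene_id,
                   transcript_id = md$transcript_id,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   strand = as.character(GenomicRanges::strand(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  if (any(df$strand == "*")) stop("exon(s) with unknown strand")
  out <- lapply(split(df, df$gene_id), classify_gene_exons)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# category priority resolution for one gene's exon table
classify_gene_exons <- function(g) {
  if (nrow(g) == 0) stop("gene with no exons")
  minus <- g$strand[1] == "-"
  # 5' coordinate of an exon: start on +, end on -
  five_of <- function(d) if (minus) -d$end else d$start
  three_of <- function(d) if (minus) -d$start else d$end
  key <- paste(g$start, g$end)
  # transcript-initial / terminal exon keys
  initial <- vapply(split(g, g$transcript_id), function(tx)
    paste(tx$start, tx$end)[which.min(five_of(tx))], character(1))
  terminal <- vapply(split(g, g$transcript_id), function(tx)
    paste(tx$start, tx$end)[which.max(three_of(tx))], character(1))
  ex <- g[!duplicated(key), , drop = FALSE]
  ekey <- paste(ex$start, ex$end)
  first_key <- ekey[ekey %in% initial][which.min(five_of(
    ex[ekey %in% initial, , drop = FALSE]))]
  last_key <- ekey[ekey %in% terminal][which.max(three_of(
    ex[ekey %in% terminal, , drop = FALSE]))]
  cat <- rep("Internal", nrow(ex))
  cat[ekey %in% initial] <- "AlternativeFirst"
  cat[ekey %in% terminal & cat == "Internal"] <- "AlternativeLast"
  # terminal exons that are also initial keep AlternativeFirst unless they
  # are the First/Last representatives (priority ordering)
  cat[ekey == last_key] <- "Last"
  cat[ekey == first_key] <- "First"
  data.frame(gene_id = ex$gene_id,
             exon_id = sprintf("%s:%d-%d", ex$gene_id, ex$start, ex$end),
             chrom = ex$chrom, strand = ex$strand,
             start = ex$start, end = ex$end, category = cat,
             stringsAsFactors = FALSE)
}

#' Count reads per exon by one-base-pair overlap
#'
#' A read is counted for every exon it overlaps by at least one base
#' (strand-aware); a read spanning two exons counts for both.
#'
#' @param reads `GRanges` of aligned read intervals (strand set).
#' @param exons exon table from [classify_exons()].
#' @param sample sample label attached to the output.
#' @return long data frame (`sample`, `gene_id`, `exon_id`, `count`).
#' @export
count_exon_reads <- function(reads, exons, sample = "sample1") {
  ex_gr <- GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(exons$start, exons$end),
    strand = exons$strand)
  n <- GenomicRanges::countOverlaps(ex_gr, reads, minoverlap = 1,
                                    ignore.strand = FALSE)
  data.frame(sample = sample, gene_id = exons$gene_id,
             exon_id = exons$exon_id, count = as.integer(n),
             stringsAsFactors = FALSE)
}

#' Normalize per-exon counts to log2 reads-per-million
#'
#' Genes with fewer than `min_reads` assigned reads in a sample are
#' dropped from that sample; remaining counts are scaled to reads per
#' million (of all assigned reads in the sample) and log2 transformed
#' with a pseudocount of one RPM unit.
#'
#' @param counts long data frame (`sample`, `gene_id`, `exon_id`,
#'   `count`).
#' @param min_reads per-gene read floor (default 10).
#' @return input filtered, with columns `rpm` and `rpm_log2` added.
#' @export
exon_coverage <- function(counts, min_reads = 10) {
  stopifnot(all(c("sample", "gene_id", "exon_id", "count") %in% names(counts)))
  out <- lapply(split(counts, counts$sample), function(s) {
    tot <- sum(s$count)
    if (tot == 0) stop("zero-read sample: ", s$sample[1])
    gene_tot <- tapply(s$count, s$gene_id, sum)
    keep <- s$gene_id %in% names(gene_tot)[gene_tot >= min_reads]
    s <- s[keep, , drop = FALSE]
    s$rpm <- s$count / tot * 1e6
    s$rpm_log2 <- log2(s$rpm + 1)
    s
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fold enrichment vs non-targeting controls and the 5' coverage bias
#'
#' Per exon, the log2 fold enrichment of a knockout is its mean
#' `rpm_log2` minus the mean over NTC samples.  The 5' coverage bias of a
#' (knockout, gene) is the enrichment of the `First` exon minus that of
#' the `Last` exon (the log2 of the ratio of linear fold enrichments).
#' The first-exon shift test is a t-test of the per-gene First-exon
#' enrichments of the knockout against those of a reference knockout
#' (AAVS1 by default) or against zero.
#'
#' @param cov output of [exon_coverage()].
#' @param exons exon table from [classify_exons()].
#' @param sample_info data frame (`sample`, `knockout`); knockouts named
#'   `ntc_label` form the reference.
#' @param ntc_label label of non-targeting control samples.
#' @param test_vs "baseline" (compare First-exon enrichments against the
#'   `baseline_label` knockout) or "zero".
#' @param baseline_label reference knockout for the t-test.
#' @return list with `lfc` (long per knockout/gene/exon), `bias5` (long
#'   per knockout/gene), and `first_exon_test` (per knockout: t, p).
#' @export
five_prime_bias <- function(cov, exons, sample_info, ntc_label = "NTC",
                            test_vs = c("baseline", "zero"),
                            baseline_label = "AAVS1") {
  test_vs <- match.arg(test_vs)
  stopifnot(all(c("sample", "knockout") %in% names(sample_info)))
  cov$knockout <- sample_info$knockout[match(cov$sample, sample_info$sample)]
  if (!any(cov$knockout == ntc_label)) stop("no NTC samples present")
  cat_of <- stats::setNames(exons$category, exons$exon_id)
  # mean rpm_log2 per (knockout, gene, exon); genes must survive filtering
  # in every sample of both the knockout and the NTC reference
  agg <- stats::aggregate(rpm_log2 ~ knockout + gene_id + exon_id,
                          data = cov, FUN = mean)
  ntc <- agg[agg$knockout == ntc_label, ]
  ref <- stats::setNames(ntc$rpm_log2, ntc$exon_id)
  lfc <- agg[agg$knockout != ntc_label, ]
  lfc <- lfc[lfc$exon_id %in% names(ref), ]
  lfc$lfc <- lfc$rpm_log2 - ref[lfc$exon_id]
  lfc$category <- cat_of[lfc$exon_id]
  # bias per (knockout, gene): First enrichment minus Last enrichment
  fl <- lfc[lfc$category %in% c("First", "Last"), ]
  wide <- stats::reshape(fl[, c("knockout", "gene_id", "category", "lfc")],
                         idvar = c("knockout", "gene_id"),
                         timevar = "category", direction = "wide")
  names(wide) <- sub("^lfc\\.", "", names(wide))
  single_exon <- !("Last" %in% names(wide)) | !("First" %in% names(wide))
  if (single_exon) stop("no gene with both First and Last exon coverage")
  bias5 <- wide[!is.na(wide$First) & !is.na(wide$Last), ]
  excluded <- wide[is.na(wide$First) | is.na(wide$Last), ]
  bias5$bias5 <- bias5$First - bias5$Last
  # first-exon shift test per knockout
  firsts <- lfc[lfc$category == "First", ]
  tests <- lapply(split(firsts, firsts$knockout), function(d) {
    res <- if (test_vs == "zero") {
      stats::t.test(d$lfc)
    } else {
      base <- firsts$lfc[firsts$knockout == baseline_label]
      if (d$knockout[1] == baseline_label || length(base) < 2)
        return(data.frame(knockout = d$knockout[1], t = NA_real_,
                          p = NA_real_, mean_first_lfc = mean(d$lfc)))
      stats::t.test(d$lfc, base)
    }
    data.frame(knockout = d$knockout[1], t = unname(res$statistic),
               p = res$p.value, mean_first_lfc = mean(d$lfc))
  })
  list(lfc = lfc[, c("knockout", "gene_id", "exon_id", "category", "lfc")],
       bias5 = bias5[, c("knockout", "gene_id", "bias5")],
       excluded = excluded[, c("knockout", "gene_id")],
       first_exon_test = do.call(rbind, c(tests, make.row.names = FALSE)))
}

#' Cluster genes by their 5' bias pattern across knockouts
#'
#' Complete-linkage hierarchical clustering of Euclidean distances
#' between gene rows of the bias matrix, cut into `n_clusters` groups.
#' Genes with any missing bias value are dropped.
#'
#' @param bias5 long data frame from [five_prime_bias()], or a genes x
#'   knockouts matrix.
#' @param n_clusters number of trees to cut (default 12).
#' @return list with `clusters` (named integer vector), `gene_lists`
#'   (per cluster), `hclust` (the tree), `matrix` (the clustered matrix).
#' @export
cluster_bias <- function(bias5, n_clusters = 12) {
  M <- if (is.matrix(bias5)) bias5 else {
    wide <- stats::reshape(bias5[, c("knockout", "gene_id", "bias5")],
                           idvar = "gene_id", timevar = "knockout",
                           direction = "wide")
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- wide$gene_id
    colnames(m) <- sub("^bias5\\.", "", colnames(m))
    m
  }
  M <- M[stats::complete.cases(M), , drop = FALSE]
  if (nrow(M) < n_clusters)
    stop("fewer complete genes (", nrow(M), ") than clusters requested")
  hc <- stats::hclust(stats::dist(M), method = "complete")
  cl <- stats::cutree(hc, k = n_clusters)
  list(clusters = cl,
       gene_lists = split(names(cl), cl),
       hclust = hc, matrix = M)
}
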