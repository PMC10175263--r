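# Local gene-set enrichment: GMT reader and Fisher exact tests with BH
# correction, for annotating gene clusters without web services.

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes,
#' tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[[`, character(1), 1))
}

#' Fisher exact enrichment of a gene list against gene sets
#'
#' Two-sided 2x2 Fisher exact test of list membership against set
#' membership over a stated gene universe, Benjamini-Hochberg corrected
#' across sets.
#'
#' @param genes character vector (the query list).
#' @param gene_sets named list of character vectors.
#' @param universe background gene universe (default: union of all set
#'   members and the query).
#' @return data frame per set: overlap, odds ratio, p, q.
#' @export
enrich_fisher <- function(genes, gene_sets, universe = NULL) {
  if (is.null(universe))
    universe <- unique(c(genes, unlist(gene_sets, use.names = FALSE)))
  genes <- intersect(genes, universe)
  res <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    a <- length(intersect(genes, set))
    b <- length(genes) - a
    c0 <- length(set) - a
    d <- length(universe) - a - b - c0
    ft <- stats::fisher.test(matrix(c(a, b, c0, d), 2))
    data.frame(set = nm, overlap = a, set_size = length(set),
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), ]
}
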