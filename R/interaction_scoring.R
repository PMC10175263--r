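# Genetic-interaction scoring: impute single-guide fitness from the
# combinatorial pair-fitness table, score pairwise interactions (pi) at
# guide level, aggregate to gene level and call hits.

#' Impute single-guide fitness from a pair-fitness matrix
#'
#' Under the additive (log-scale multiplicative) null, construct fitness
#' decomposes as `f_{g1g2} = f_g1 + f_g2 + pi_{g1g2}` with interactions rare
#' and centered on zero.  Summing over all constructs containing guide i
#' and dropping the interaction term gives one linear equation per guide;
#' the stacked system is solved exactly.  For a complete one-observation-
#' per-unordered-pair matrix this is `A x = b` with `A = (N-2) I + J`
#' (diagonal N-1, off-diagonal 1) and `b_i` the sum of pair fitness values
#' involving guide i.
#'
#' Both construct orders (i, j) and (j, i) contribute as independent
#' observations when present.  For incomplete matrices each row uses the
#' observed degree of guide i and the observed partner sums, preserving the
#' derivation row by row.
#'
#' @param F square numeric matrix of construct fitness; `F[i, j]` is the
#'   fitness of the construct with guide i in position 1 and guide j in
#'   position 2.  The diagonal must be absent (NA); unobserved pairs NA.
#'   Row/column names identify guides.
#' @return named numeric vector of imputed single-guide fitness.
#' @export
impute_single_fitness <- function(F) {
  stopifnot(is.matrix(F), nrow(F) == ncol(F))
  N <- nrow(F)
  if (N < 3) stop("need at least 3 guides to separate interactions")
  ids <- rownames(F) %||% paste0("g", seq_len(N))
  diag(F) <- NA
  obs <- !is.na(F)
  if (!any(obs)) stop("no observed pairs")
  # n_ij = number of observed constructs joining i and j (0, 1 or 2)
  n_pair <- obs + t(obs)
  deg <- rowSums(n_pair)          # observed constructs containing guide i
  if (any(deg == 0)) stop("guide(s) with no observed pair: ",
                          paste(ids[deg == 0], collapse = ", "))
  A <- n_pair
  diag(A) <- deg
  F0 <- F
  F0[!obs] <- 0
  b <- rowSums(F0) + colSums(F0)  # sum of observed fitness containing i
  x <- solve(A, b)
  stats::setNames(as.numeric(x), ids)
}

#' Guide-level interaction scores
#'
#' `pi_{g1g2} = f_{g1g2} - f_g1 - f_g2` for every observed construct.
#'
#' @param F pair-fitness matrix as in [impute_single_fitness()].
#' @param f_singles named vector of single-guide fitness covering all
#'   guides of F.
#' @return matrix of pi values, NA where F is NA.
#' @export
score_pi <- function(F, f_singles) {
  ids <- rownames(F) %||% paste0("g", seq_len(nrow(F)))
  if (!all(ids %in% names(f_singles)))
    stop("missing single-guide fitness for: ",
         paste(setdiff(ids, names(f_singles)), collapse = ", "))
  fs <- f_singles[ids]
  P <- F - outer(fs, fs, `+`)
  diag(P) <- NA
  dimnames(P) <- list(ids, ids)
  P
}

#' Aggregate guide-level pi to gene-level interaction scores
#'
#' The gene-level score for a pair (a, b) is the mean of pi over all guide
#' combinations and both construct orders; with 4 guides per gene and
#' complete data that is 4 x 4 x 2 = 32 values.  Missing combinations are
#' averaged over what exists, with the number of contributing values
#' recorded.
#'
#' Same-gene constructs (two guides against one gene) are excluded by
#' default: they measure double-cutting burden rather than a genetic
#' interaction between two genes, and they pool only 4 x 3 = 12 ordered
#' combinations, so their scores have markedly higher variance and would
#' distort the z-normalization population downstream.
#'
#' @param pi_guide pi matrix from [score_pi()].
#' @param guide_gene named character vector mapping guide_id to gene.
#' @param include_self also emit (a, a) self-pair scores (default FALSE).
#' @return data frame with `gene_a`, `gene_b` (a < b alphabetically),
#'   `score` (mean pi) and `n_combos`.
#' @export
aggregate_genes <- function(pi_guide, guide_gene, include_self = FALSE) {
  ids <- rownames(pi_guide)
  stopifnot(all(ids %in% names(guide_gene)))
  genes <- unname(guide_gene[ids])
  obs <- which(!is.na(pi_guide), arr.ind = TRUE)
  if (nrow(obs) == 0) stop("no observed pi values")
  ga <- genes[obs[, 1]]; gb <- genes[obs[, 2]]
  if (!include_self) {
    keep <- ga != gb
    obs <- obs[keep, , drop = FALSE]
    ga <- ga[keep]; gb <- gb[keep]
    if (nrow(obs) == 0) stop("no observed between-gene pi values")
  }
  key <- paste(pmin(ga, gb), pmax(ga, gb), sep = "\r")
  vals <- pi_guide[obs]
  sums <- tapply(vals, key, sum)
  ns <- tapply(vals, key, length)
  parts <- do.call(rbind, strsplit(names(sums), "\r", fixed = TRUE))
  data.frame(gene_a = parts[, 1], gene_b = parts[, 2],
             score = as.numeric(sums / ns), n_combos = as.integer(ns),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarize gene-level scores across samples and call interactions
#'
#' Gene-level raw scores are z-normalized within each (timepoint,
#' replicate) sample over all gene pairs; the final score per gene pair is
#' the median z across all samples, itself z-rescaled across gene pairs
#' (the median of several partially correlated z-scores is compressed
#' towards zero, so without the rescale the call threshold would not be
#' on a comparable scale across designs with different sample counts; for
#' a single sample the rescale is the identity).  Pairs with final score
#' at or below `-z_cut` are called synthetic-sick/lethal, at or above
#' `+z_cut` synergistic.
#'
#' @param gene_scores data frame with columns `gene_a`, `gene_b`,
#'   `timepoint`, `replicate`, `score` (stacked [aggregate_genes()] output
#'   over samples).
#' @param z_cut call threshold on the final median z (default 2).
#' @param final_rescale z-rescale the median across gene pairs (default
#'   TRUE; set FALSE to call on the raw median of per-sample z-scores).
#' @return data frame per gene pair with `final_z` and `call` in
#'   {"synthetic_lethal", "synergistic", "none"}; per-sample z-scores are
#'   attached as attribute `"z_by_sample"`.
#' @export
summarize_and_call <- function(gene_scores, z_cut = 2,
                               final_rescale = TRUE) {
  if (z_cut <= 0) stop("z_cut must be positive")
  df <- as.data.frame(gene_scores)
  stopifnot(all(c("gene_a", "gene_b", "timepoint", "replicate", "score")
                %in% names(df)))
  sid <- interaction(df$timepoint, df$replicate, drop = TRUE)
  df$z <- NA_real_
  for (s in levels(sid)) {
    i <- sid == s
    s_pop <- sd_pop(df$score[i])
    if (s_pop == 0) stop("degenerate sample: constant gene scores")
    df$z[i] <- (df$score[i] - mean(df$score[i])) / s_pop
  }
  key <- paste(df$gene_a, df$gene_b, sep = "\r")
  med <- tapply(df$z, key, stats::median)
  if (final_rescale && sd_pop(med) > 0)
    med <- (med - mean(med)) / sd_pop(med)
  parts <- do.call(rbind, strsplit(names(med), "\r", fixed = TRUE))
  out <- data.frame(gene_a = parts[, 1], gene_b = parts[, 2],
                    final_z = as.numeric(med), stringsAsFactors = FALSE,
                    row.names = NULL)
  out$call <- ifelse(out$final_z <= -z_cut, "synthetic_lethal",
                     ifelse(out$final_z >= z_cut, "synergistic", "none"))
  attr(out, "z_by_sample") <- df
  out
}

# assemble the pair-fitness matrix for one (timepoint, replicate) sample
pair_fitness_matrix <- function(fitness_df, guide_ids) {
  F <- matrix(NA_real_, length(guide_ids), length(guide_ids),
              dimnames = list(guide_ids, guide_ids))
  F[cbind(match(fitness_df$g1, guide_ids),
          match(fitness_df$g2, guide_ids))] <- fitness_df$f
  F
}

#' Score a full screen from a construct count table
#'
#' Convenience pipeline: abundance, fold change and standardized fitness
#' per sample ([compute_fitness()]); per-sample single-guide fitness
#' imputation and guide-level pi; gene-level aggregation; z-normalization
#' and median-across-samples calls.  Cell lines can be pooled beforehand by
#' relabeling their replicates ("pan" mode).
#'
#' @param counts a `pair_count_table`.
#' @param z_cut call threshold (see [summarize_and_call()]).
#' @param pseudocount,pool_replicates passed to [compute_fitness()].
#' @return list with `fitness` (per-construct table), `f_singles` (guide x
#'   sample matrix), `pi` (long guide-level table), `gene_scores` (per
#'   sample), `summary` (final calls).
#' @export
score_screen <- function(counts, z_cut = 2, pseudocount = 1,
                         pool_replicates = FALSE, final_rescale = TRUE) {
  lib <- attr(counts, "library")
  if (is.null(lib)) stop("count table lacks its guide library attribute")
  fit <- compute_fitness(counts, pseudocount, pool_replicates)
  guide_gene <- stats::setNames(lib$gene, lib$guide_id)
  t0 <- min(fit$timepoint)
  samples <- unique(fit[fit$timepoint != t0, c("timepoint", "replicate")])
  f_singles <- NULL
  pi_long <- list()
  gene_scores <- list()
  for (k in seq_len(nrow(samples))) {
    t <- samples$timepoint[k]; r <- samples$replicate[k]
    sub <- fit[fit$timepoint == t & fit$replicate == r, ]
    F <- pair_fitness_matrix(sub, lib$guide_id)
    fs <- impute_single_fitness(F)
    P <- score_pi(F, fs)
    f_singles <- cbind(f_singles, fs)
    colnames(f_singles)[ncol(f_singles)] <- sprintf("t%s_r%s", t, r)
    obs <- which(!is.na(P), arr.ind = TRUE)
    pi_long[[k]] <- data.frame(
      g1 = rownames(P)[obs[, 1]], g2 = colnames(P)[obs[, 2]],
      timepoint = t, replicate = r, pi = P[obs], stringsAsFactors = FALSE)
    gs <- aggregate_genes(P, guide_gene)
    gs$timepoint <- t; gs$replicate <- r
    gene_scores[[k]] <- gs
  }
  gene_scores <- do.call(rbind, gene_scores)
  summary <- summarize_and_call(gene_scores, z_cut = z_cut,
                                final_rescale = final_rescale)
  list(fitness = fit, f_singles = f_singles,
       pi = do.call(rbind, pi_long), gene_scores = gene_scores,
       summary = summary)
}

#' Summarize imputed guide fitness at gene level
#'
#' Median of the imputed per-sample single-guide fitness across guides of
#' each gene and across samples; used for fitness-vs-transcriptome
#' comparisons.
#'
#' @param f_singles guide x sample matrix from [score_screen()].
#' @param guide_gene named mapping guide_id -> gene.
#' @return named numeric vector of gene-level fitness.
#' @export
gene_fitness <- function(f_singles, guide_gene) {
  genes <- unname(guide_gene[rownames(f_singles)])
  med <- tapply(seq_len(nrow(f_singles)), genes, function(i)
    stats::median(f_singles[i, , drop = FALSE]))
  stats::setNames(as.numeric(med), names(med))
}
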