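# Synthetic knockout transcriptomes: per-knockout cell populations with
# planted differential-expression programs, mitochondrial reads and guide
# assignments, for QC / profiling / DE recovery tests.

#' Simulate knockout-perturbed single-cell transcriptomes
#'
#' Baseline gene means are log-normal; each knockout population shifts a
#' planted subset of genes by a log2 fold change.  A block of
#' mitochondrial genes (prefix `MT-`) contributes a controllable fraction
#' of reads per cell.  Counts are gamma-Poisson.  Cells carry a detected
#' guide count (all 1 by default) so that "exactly one control guide"
#' baselines can be selected downstream.
#'
#' @param knockouts data frame with columns `gene`, `n_cells`, `n_de`,
#'   `lfc`: each knockout shifts `n_de` randomly chosen genes by `lfc`
#'   (log2) in magnitude, half up- and half down-regulated, so the
#'   planted program is compositionally balanced (real perturbations both
#'   induce and repress, and an unbalanced program would confound
#'   total-count normalization).  Include a row for the baseline
#'   population (e.g. gene "AAVS1", n_de = 0).
#' @param n_genes number of non-mitochondrial genes.
#' @param n_mito number of mitochondrial genes.
#' @param mito_fraction expected fraction of counts from mitochondrial
#'   genes.
#' @param mean_log,sd_log log-normal parameters of baseline gene means.
#' @param depth_scale multiplier on all means (sequencing depth knob).
#' @param dispersion negative binomial size.
#' @param min_de_mean detectability floor: planted DE genes are drawn from
#'   genes whose baseline mean is at least this many counts per cell
#'   (shifts on genes below the detection limit are not recoverable by any
#'   method and would only dilute recovery benchmarks).
#' @param shared_program if TRUE, every knockout's DE genes are the first
#'   `n_de` genes of one common shuffled program list (nested programs:
#'   knockouts engage a shared downstream response with different
#'   breadth), rather than independent random subsets.
#' @param seed RNG seed.
#' @return list with `counts` (cells x genes), `cells` (cell_id, knockout,
#'   n_guides), `de_truth` (named list: planted DE genes per knockout),
#'   `base_mean` (named vector of unperturbed means).
#' @export
simulate_ko_expression <- function(knockouts, n_genes = 2000, n_mito = 10,
                                   mito_fraction = 0.05, mean_log = 0,
                                   sd_log = 1, depth_scale = 1,
                                   dispersion = 5, min_de_mean = 0.5,
                                   shared_program = FALSE, seed = 1) {
  stopifnot(all(c("gene", "n_cells", "n_de", "lfc") %in% names(knockouts)))
  with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    mito <- if (n_mito > 0) sprintf("MT-%02d", seq_len(n_mito)) else character(0)
    mu0 <- stats::rlnorm(n_genes, mean_log, sd_log)
    mu0 <- mu0 / sum(mu0) * (1 - mito_fraction)
    mu_mito <- if (n_mito > 0) rep(mito_fraction / n_mito, n_mito) else numeric(0)
    base <- c(mu0, mu_mito) * 2000 * depth_scale  # ~2000 counts/cell
    names(base) <- c(genes, mito)
    de_truth <- list()
    rows <- list()
    cells <- list()
    program <- sample(genes[base[genes] >= min_de_mean])
    for (i in seq_len(nrow(knockouts))) {
      kk <- knockouts[i, ]
      mu <- base
      if (kk$n_de > 0) {
        if (length(program) < kk$n_de)
          stop("fewer than n_de genes above the detectability floor")
        # up/down signs are mass-balanced so the planted program does not
        # shift null genes through total-count normalization (droplet
        # assays measure composition); in shared-program mode the sign
        # pattern is fixed along the program so knockout profiles are
        # colinear, and the final rescale absorbs the small residual
        if (shared_program) {
          ord <- program[seq_len(kk$n_de)]
          sign <- rep(c(1, -1), length.out = kk$n_de)
        } else {
          de <- sample(program, kk$n_de)
          ord <- de[order(mu[de], decreasing = TRUE)]
          sign <- numeric(length(ord))
          imbalance <- 0
          for (g in seq_along(ord)) {
            d_up <- mu[ord[g]] * (2^kk$lfc - 1)
            d_dn <- mu[ord[g]] * (2^(-kk$lfc) - 1)
            sign[g] <- if (abs(imbalance + d_up) <= abs(imbalance + d_dn)) 1
                       else -1
            imbalance <- imbalance + if (sign[g] > 0) d_up else d_dn
          }
        }
        mu[ord] <- mu[ord] * 2^(sign * kk$lfc)
        mu <- mu * sum(base) / sum(mu)
        de_truth[[kk$gene]] <- stats::setNames(sign * kk$lfc, ord)
      } else {
        de_truth[[kk$gene]] <- stats::setNames(numeric(0), character(0))
      }
      M <- matrix(stats::rnbinom(kk$n_cells * length(mu),
                                 mu = rep(mu, each = kk$n_cells),
                                 size = dispersion),
                  nrow = kk$n_cells)
      rows[[i]] <- M
      cells[[i]] <- data.frame(knockout = rep(kk$gene, kk$n_cells),
                               n_guides = 1L, stringsAsFactors = FALSE)
    }
    counts <- do.call(rbind, rows)
    colnames(counts) <- names(base)
    cells <- do.call(rbind, cells)
    cells$cell_id <- sprintf("cell%05d", seq_len(nrow(cells)))
    rownames(counts) <- cells$cell_id
    list(counts = counts, cells = cells[, c("cell_id", "knockout", "n_guides")],
         de_truth = de_truth, base_mean = base)
  })
}
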