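# Transcriptome-wide knockout phenotyping: QC and normalization, median
# fold-change profiles with bootstrap confidence, MDS embedding of
# knockouts, rank-sum differential expression, and the perturbation
# magnitude vs fitness relation.

#' Quality-control configuration
#'
#' Standard droplet scRNA-seq thresholds: cells keep between
#' `min_genes_per_cell` and `max_genes_per_cell` expressed genes and at
#' most `max_mito_fraction` mitochondrial reads; genes must be expressed
#' in at least `min_cells_per_gene` cells.
#'
#' @param min_genes_per_cell,max_genes_per_cell expressed-gene bounds.
#' @param min_cells_per_gene gene detection floor.
#' @param max_mito_fraction mitochondrial read-fraction ceiling.
#' @param mito_prefix gene-name prefix identifying mitochondrial genes.
#' @export
qc_config <- function(min_genes_per_cell = 200, max_genes_per_cell = 10000,
                      min_cells_per_gene = 3, max_mito_fraction = 0.10,
                      mito_prefix = "MT-") {
  stopifnot(min_genes_per_cell < max_genes_per_cell)
  list(min_genes_per_cell = min_genes_per_cell,
       max_genes_per_cell = max_genes_per_cell,
       min_cells_per_gene = min_cells_per_gene,
       max_mito_fraction = max_mito_fraction,
       mito_prefix = mito_prefix)
}

#' Filter and normalize a raw count matrix
#'
#' Cell filters run first (expressed-gene count within bounds,
#' mitochondrial fraction at or below the ceiling), then the gene filter
#' on the surviving cells; counts are then total-count normalized to the
#' median library size and log(1 + x) transformed.
#'
#' @param counts raw integer count matrix, cells x genes.
#' @param config a [qc_config()].
#' @return list with `norm` (normalized matrix), `cells_kept`,
#'   `genes_kept`, and `stats` (counts of removals by reason).
#' @export
qc_and_normalize <- function(counts, config = qc_config()) {
  stopifnot(is.matrix(counts) || inherits(counts, "Matrix"))
  counts <- as.matrix(counts)
  n_expr <- rowSums(counts > 0)
  mito <- startsWith(colnames(counts), config$mito_prefix)
  mito_frac <- if (any(mito))
    rowSums(counts[, mito, drop = FALSE]) / pmax(rowSums(counts), 1)
  else rep(0, nrow(counts))
  keep_cells <- n_expr >= config$min_genes_per_cell &
    n_expr <= config$max_genes_per_cell &
    mito_frac <= config$max_mito_fraction
  sub <- counts[keep_cells, , drop = FALSE]
  keep_genes <- colSums(sub > 0) >= config$min_cells_per_gene
  sub <- sub[, keep_genes, drop = FALSE]
  if (nrow(sub) == 0 || ncol(sub) == 0)
    stop("no cells or genes left after quality filtering")
  list(norm = normalize_counts(sub),
       cells_kept = rownames(sub) %||% which(keep_cells),
       genes_kept = colnames(sub) %||% which(keep_genes),
       stats = c(cells_in = nrow(counts), cells_kept = nrow(sub),
                 cells_low_genes = sum(n_expr < config$min_genes_per_cell),
                 cells_high_genes = sum(n_expr > config$max_genes_per_cell),
                 cells_high_mito = sum(mito_frac > config$max_mito_fraction),
                 genes_in = ncol(counts), genes_kept = ncol(sub)))
}

#' Median knockout expression profiles with bootstrap confidence
#'
#' The baseline transcriptomic state is the per-gene median over cells
#' that received exactly one guide targeting the baseline locus (AAVS1 by
#' default).  Every cell's expression is expressed as a log fold change
#' from that baseline (difference on the normalized log scale); each
#' knockout's profile is the per-gene median fold change over its cells,
#' with a seeded bootstrap over cells (B resamples) giving the confidence
#' cloud of the median.
#'
#' @param norm normalized matrix, cells x genes.
#' @param cells data frame with `cell_id`, `knockout` and optionally
#'   `n_guides` (cells with `n_guides != 1` are excluded from the
#'   baseline).
#' @param baseline knockout label anchoring the baseline state.
#' @param B bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @param min_baseline_cells required baseline population size.
#' @param boot_baseline also resample the baseline cells within each
#'   bootstrap replicate (default TRUE): the profile is a difference of
#'   medians, and ignoring baseline noise undercovers.
#' @return list of per-knockout entries: `median_lfc` (named vector),
#'   `boot` (B x genes matrix), `n_cells`, `low_confidence` (fewer than 3
#'   cells).
#' @export
knockout_profiles <- function(norm, cells, baseline = "AAVS1", B = 1000,
                              seed = 1, min_baseline_cells = 20,
                              boot_baseline = TRUE) {
  stopifnot(all(c("cell_id", "knockout") %in% names(cells)),
            nrow(norm) == nrow(cells))
  norm <- as.matrix(norm)
  one_guide <- if ("n_guides" %in% names(cells)) cells$n_guides == 1 else TRUE
  base_idx <- which(cells$knockout == baseline & one_guide)
  if (length(base_idx) < min_baseline_cells)
    stop("need at least ", min_baseline_cells, " baseline cells, got ",
         length(base_idx))
  Mb <- norm[base_idx, , drop = FALSE]
  base_med <- apply(Mb, 2, stats::median)
  kos <- unique(cells$knockout)
  out <- with_seed(seed, {
    # baseline bootstrap medians are shared by all knockouts
    base_boot <- if (boot_baseline) {
      t(vapply(seq_len(B), function(b)
        col_medians(Mb[sample.int(nrow(Mb), replace = TRUE), , drop = FALSE]),
        numeric(ncol(Mb))))
    } else {
      matrix(base_med, B, ncol(Mb), byrow = TRUE)
    }
    lapply(stats::setNames(kos, kos), function(k) {
      idx <- which(cells$knockout == k)
      M <- norm[idx, , drop = FALSE]
      med <- apply(M, 2, stats::median) - base_med
      boot <- matrix(NA_real_, B, ncol(M), dimnames = list(NULL, colnames(M)))
      for (b in seq_len(B)) {
        boot[b, ] <- col_medians(M[sample.int(nrow(M), replace = TRUE), ,
                                   drop = FALSE]) - base_boot[b, ]
      }
      list(median_lfc = med, boot = boot, n_cells = length(idx),
           low_confidence = length(idx) < 3)
    })
  })
  structure(out, baseline = baseline, class = "knockout_profiles")
}

# column medians without the per-column apply overhead
col_medians <- function(M) {
  n <- nrow(M)
  S <- apply(M, 2, sort, method = "quick")
  if (n %% 2 == 1) S[(n + 1) / 2, ] else (S[n / 2, ] + S[n / 2 + 1, ]) / 2
}

#' Embed knockout profiles with bootstrap confidence contours
#'
#' Knockout median profiles are embedded in two dimensions by classical
#' multidimensional scaling of their Euclidean distances (equivalently,
#' principal components of the profile matrix), and each knockout's
#' bootstrap replicates are projected onto the same plane.  The embedding
#' is translated so the baseline knockout sits at the origin.  The 95%
#' confidence contour of each knockout is the Gaussian ellipse of its
#' projected bootstrap cloud.
#'
#' @param profiles a [knockout_profiles()] result.
#' @param level contour coverage level.
#' @return list with `coords` (knockout x 2), `boot_coords` (per
#'   knockout), `contours` (per knockout polygon), `covers_origin`
#'   (logical per knockout).
#' @export
embed_knockouts <- function(profiles, level = 0.95) {
  kos <- names(profiles)
  if (length(kos) < 3) stop("need at least 3 knockouts to embed")
  P <- do.call(rbind, lapply(profiles, `[[`, "median_lfc"))
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  sv <- svd(Pc, nu = 2, nv = 2)
  coords <- sv$u %*% diag(sv$d[1:2], 2)
  rownames(coords) <- kos
  rot <- sv$v
  base <- attr(profiles, "baseline")
  shift <- if (base %in% kos) coords[base, ] else c(0, 0)
  coords <- sweep(coords, 2, shift)
  boot_coords <- lapply(profiles, function(pr)
    sweep(sweep(pr$boot, 2, ctr) %*% rot, 2, shift))
  contours <- lapply(boot_coords, boot_ellipse, level = level)
  covers <- vapply(boot_coords, function(bc)
    ellipse_covers(bc, c(0, 0), level = level), logical(1))
  list(coords = coords, boot_coords = boot_coords, contours = contours,
       covers_origin = covers)
}

# Gaussian confidence ellipse of a 2D point cloud as a polygon
boot_ellipse <- function(cloud, level = 0.95, n_points = 100) {
  mu <- colMeans(cloud)
  S <- stats::cov(cloud)
  r <- sqrt(stats::qchisq(level, df = 2))
  e <- eigen(S, symmetric = TRUE)
  ang <- seq(0, 2 * pi, length.out = n_points)
  circ <- rbind(cos(ang), sin(ang)) * r
  pts <- t(e$vectors %*% (sqrt(pmax(e$values, 0)) * circ) + mu)
  colnames(pts) <- c("x", "y")
  pts
}

#' Does a bootstrap confidence ellipse cover a point?
#'
#' Mahalanobis check of `point` against the Gaussian ellipse of `cloud`
#' at the given level.
#'
#' @param cloud n x 2 matrix of bootstrap coordinates.
#' @param point length-2 target.
#' @param level coverage level.
#' @export
ellipse_covers <- function(cloud, point, level = 0.95) {
  mu <- colMeans(cloud)
  S <- stats::cov(cloud)
  d2 <- stats::mahalanobis(matrix(point, 1), mu, S)
  d2 <= stats::qchisq(level, df = 2)
}

#' Rank-sum differential expression between knockout and baseline cells
#'
#' Two-sided Mann-Whitney U test per gene with Benjamini-Hochberg
#' correction across genes; genes constant across both groups get p = 1
#' by convention.  The DE set is q < `fdr`.
#'
#' @param norm normalized matrix, cells x genes.
#' @param idx_ko,idx_base row indices of the two cell groups (>= 3 each).
#' @param fdr FDR threshold for the DE set.
#' @return data frame per gene: `statistic`, `p`, `q`, `de` (logical),
#'   `delta_median`.
#' @export
differential_expression <- function(norm, idx_ko, idx_base, fdr = 0.05) {
  if (length(idx_ko) < 3 || length(idx_base) < 3)
    stop("need at least 3 cells per group")
  A <- as.matrix(norm[idx_ko, , drop = FALSE])
  B <- as.matrix(norm[idx_base, , drop = FALSE])
  n1 <- nrow(A); n2 <- nrow(B)
  G <- ncol(A)
  stat <- numeric(G); p <- numeric(G)
  for (j in seq_len(G)) {
    a <- A[, j]; b <- B[, j]
    if (max(a, b) == min(a, b)) {  # constant in both groups
      stat[j] <- n1 * n2 / 2
      p[j] <- 1
      next
    }
    wt <- stats::wilcox.test(a, b, exact = FALSE)
    stat[j] <- unname(wt$statistic)
    p[j] <- wt$p.value
  }
  q <- stats::p.adjust(p, method = "BH")
  data.frame(gene = colnames(norm), statistic = stat, p = p, q = q,
             de = q < fdr,
             delta_median = apply(A, 2, stats::median) -
                 apply(B, 2, stats::median),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Transcriptional perturbation magnitude versus fitness
#'
#' Per knockout, the magnitude of the transcriptional perturbation is the
#' Euclidean norm of its median fold-change profile (or its radial
#' distance from the control in the 2D embedding); it is correlated
#' (Pearson) with gene-level fitness.
#'
#' @param profiles a [knockout_profiles()] result.
#' @param fitness named numeric vector of gene-level fitness (e.g.
#'   [gene_fitness()]).
#' @param metric "profile_norm" (default) or "embedding" radial distance.
#' @return list with `table` (knockout, magnitude, fitness), `r`, `p`.
#' @export
magnitude_vs_fitness <- function(profiles, fitness,
                                 metric = c("profile_norm", "embedding")) {
  metric <- match.arg(metric)
  base <- attr(profiles, "baseline")
  shared <- setdiff(intersect(names(profiles), names(fitness)), base)
  if (length(shared) < 3) stop("need at least 3 shared knockouts")
  mag <- if (metric == "profile_norm") {
    vapply(profiles[shared], function(p) sqrt(sum(p$median_lfc^2)),
           numeric(1))
  } else {
    emb <- embed_knockouts(profiles)
    sqrt(rowSums(emb$coords[shared, , drop = FALSE]^2))
  }
  if (stats::sd(mag) == 0 || stats::sd(fitness[shared]) == 0)
    stop("zero variance in magnitude or fitness; correlation undefined")
  ct <- stats::cor.test(mag, fitness[shared])
  list(table = data.frame(knockout = shared, magnitude = unname(mag),
                          fitness = unname(fitness[shared]),
                          stringsAsFactors = FALSE),
       r = unname(ct$estimate), p = ct$p.value)
}
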