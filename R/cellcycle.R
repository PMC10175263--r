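# Single-cell cell-cycle analysis: phase marker scoring, polar embedding,
# angular phase ranges, two-sample Kuiper test, and removal of cell-cycle
# signal from expression profiles.

# canonical phase order, also the tie-break order everywhere
PHASES <- c("M", "M/G1", "G1/S", "S", "G2/M")

# default angular extent of each phase as a fraction of the circle.  The
# latent coordinate is transcriptional progression (equal marker turnover
# per radian), not wall-clock time, so with equal-sized marker panels per
# phase the phases occupy equal arcs by construction.
PHASE_FRACTIONS <- c("M" = 0.2, "M/G1" = 0.2, "G1/S" = 0.2,
                     "S" = 0.2, "G2/M" = 0.2)

#' Phase marker gene sets
#'
#' Named list of marker gene sets, one per cell-cycle phase in canonical
#' order M, M/G1, G1/S, S, G2/M.  A gene may belong to at most one phase.
#'
#' @param sets named list of character vectors.
#' @return a `phase_gene_sets` object.
#' @export
phase_gene_sets <- function(sets) {
  stopifnot(is.list(sets), all(names(sets) %in% PHASES))
  sets <- sets[intersect(PHASES, names(sets))]
  if (any(lengths(sets) == 0)) stop("phase sets must be non-empty")
  all_genes <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(all_genes))
    stop("genes may appear in at most one phase set: ",
         paste(unique(all_genes[duplicated(all_genes)]), collapse = ", "))
  structure(sets, class = "phase_gene_sets")
}

#' Per-cell phase scores and pan-phase profile
#'
#' The phase score `E_ik` of cell i for phase k is the mean normalized
#' expression over that phase's marker genes present in the matrix; the
#' pan-phase profile `E_i` is the cell's expression vector over the union
#' of all phase marker genes.
#'
#' @param expr normalized expression matrix, cells x genes.
#' @param sets a [phase_gene_sets()].
#' @return list with `E_phase` (cells x phases), `E_pan` (cells x marker
#'   genes) and `genes_used` (per phase).
#' @export
phase_scores <- function(expr, sets) {
  stopifnot(is.matrix(expr) || inherits(expr, "Matrix"))
  genes <- colnames(expr)
  used <- lapply(sets, intersect, x = genes)
  names(used) <- names(sets)
  missing <- mapply(function(a, b) length(a) - length(b), sets, used)
  if (any(lengths(used) == 0))
    stop("no marker genes present for phase(s): ",
         paste(names(used)[lengths(used) == 0], collapse = ", "))
  if (any(missing > 0))
    warning("dropped ", sum(missing), " marker gene(s) absent from the matrix")
  E_phase <- vapply(used, function(g)
    rowMeans(expr[, g, drop = FALSE]), numeric(nrow(expr)))
  pan_genes <- unlist(used, use.names = FALSE)
  list(E_phase = E_phase, E_pan = as.matrix(expr[, pan_genes, drop = FALSE]),
       genes_used = used)
}

#' Coarse cell-cycle classification
#'
#' Argmax of the per-phase scores; ties break to the earliest phase in the
#' canonical order M, M/G1, G1/S, S, G2/M.
#'
#' @param E_phase cells x phases score matrix from [phase_scores()].
#' @return character vector of phase labels.
#' @export
coarse_classify <- function(E_phase) {
  cols <- colnames(E_phase) %||% PHASES[seq_len(ncol(E_phase))]
  ord <- order(match(cols, PHASES))
  M <- E_phase[, ord, drop = FALSE]
  cols[ord][max.col(M, ties.method = "first")]
}

# circular mean angle of a vector of angles
circ_mean <- function(a) atan2(mean(sin(a)), mean(cos(a))) %% (2 * pi)

#' Embed cells on a circular cell-cycle coordinate
#'
#' Pairwise cell-cell distances are one minus the cosine similarity of the
#' pan-phase profiles; the distance matrix is embedded in two dimensions by
#' classical (metric) multidimensional scaling and each cell converted to
#' polar coordinates `r = sqrt(D1^2 + D2^2)`, `theta = atan2(D2, D1)` in
#' \[0, 2pi).  Because the embedding's orientation is arbitrary, the result
#' is canonicalized: reflected so the coarse phase labels run
#' counter-clockwise in canonical order, then rotated so the circular mean
#' angle of M/G1-labeled cells sits at the midpoint of the default M/G1
#' arc.
#'
#' @param E_pan pan-phase profile matrix, cells x genes.
#' @param coarse coarse phase labels from [coarse_classify()] (used only
#'   for orientation).
#' @return data frame with `D1`, `D2`, `r`, `theta` per cell.
#' @export
embed_cells <- function(E_pan, coarse) {
  n <- nrow(E_pan)
  if (n < 10) stop("need at least 10 cells to embed")
  norms <- sqrt(rowSums(E_pan^2))
  if (any(norms == 0))
    stop("all-zero pan-phase profile(s); drop those cells first")
  U <- E_pan / norms
  D <- 1 - tcrossprod(U)
  D[D < 0] <- 0
  if (all(D < 1e-12)) stop("degenerate distance matrix (all cells identical)")
  xy <- stats::cmdscale(stats::as.dist(D), k = 2)
  theta <- atan2(xy[, 2], xy[, 1]) %% (2 * pi)
  r <- sqrt(rowSums(xy^2))
  # orientation: choose the reflection in which consecutive canonical-phase
  # circular means advance counter-clockwise (their mod-2pi gaps sum to one
  # full turn rather than several)
  present <- PHASES[PHASES %in% unique(coarse)]
  if (length(present) >= 3) {
    winding <- function(th) {
      m <- vapply(present, function(p) circ_mean(th[coarse == p]), numeric(1))
      sum((diff(c(m, m[1])) %% (2 * pi)))
    }
    if (winding((2 * pi - theta) %% (2 * pi)) < winding(theta)) {
      theta <- (2 * pi - theta) %% (2 * pi)
      xy[, 2] <- -xy[, 2]
    }
  }
  # rotation: pin the M/G1 circular mean to its default arc midpoint
  anchor <- "M/G1"
  if (any(coarse == anchor)) {
    cum <- cumsum(c(0, PHASE_FRACTIONS)) * 2 * pi
    target <- (cum[match(anchor, PHASES)] +
                 cum[match(anchor, PHASES) + 1]) / 2
    rot <- target - circ_mean(theta[coarse == anchor])
    theta <- (theta + rot) %% (2 * pi)
    xy <- cbind(r * cos(theta), r * sin(theta))
  }
  data.frame(D1 = xy[, 1], D2 = xy[, 2], r = r, theta = theta)
}

#' Assign consecutive angular ranges to cell-cycle phases
#'
#' The circle is split into `n_bins` equal bins; each bin takes the modal
#' coarse label of its cells (ties to canonical phase order) and empty bins
#' inherit the label of the nearest non-empty bin.  Each cell's assigned
#' phase is its bin's label.
#'
#' @param theta per-cell angle in \[0, 2pi).
#' @param coarse per-cell coarse label.
#' @param n_bins number of angular bins (default 60, i.e. 6 degrees).
#' @return list with `bins` (data frame: `bin`, `lo`, `hi`, `label`),
#'   `phase_assigned` (per cell) and `merged_ranges` (per phase, a data
#'   frame of contiguous arcs).
#' @export
assign_phase_ranges <- function(theta, coarse, n_bins = 60) {
  if (n_bins < length(PHASES)) stop("n_bins must be >= number of phases")
  edges <- seq(0, 2 * pi, length.out = n_bins + 1)
  bin <- pmin(findInterval(theta %% (2 * pi), edges,
                           rightmost.closed = TRUE), n_bins)
  label <- rep(NA_character_, n_bins)
  for (b in unique(bin)) {
    tab <- table(factor(coarse[bin == b], levels = PHASES))
    label[b] <- PHASES[which.max(tab)]  # which.max breaks ties to first
  }
  empty <- which(is.na(label))
  if (length(empty) && length(empty) < n_bins) {
    filled <- which(!is.na(label))
    for (b in empty) {
      d <- pmin(abs(filled - b), n_bins - abs(filled - b))  # circular bins
      label[b] <- label[filled[which.min(d)]]
    }
  }
  bins <- data.frame(bin = seq_len(n_bins), lo = edges[-(n_bins + 1)],
                     hi = edges[-1], label = label)
  merged <- lapply(stats::setNames(PHASES, PHASES), function(p) {
    i <- which(label == p)
    if (!length(i)) return(data.frame(lo = numeric(0), hi = numeric(0)))
    # merge contiguous bins (circularly)
    brk <- c(0, which(diff(i) > 1))
    runs <- split(i, cumsum(seq_along(i) %in% (brk + 1)))
    arcs <- do.call(rbind, lapply(runs, function(r)
      data.frame(lo = edges[min(r)], hi = edges[max(r) + 1])))
    # join a run ending at 2pi with one starting at 0
    if (nrow(arcs) > 1 && arcs$lo[1] == 0 && arcs$hi[nrow(arcs)] == 2 * pi) {
      arcs$lo[1] <- arcs$lo[nrow(arcs)] - 2 * pi
      arcs <- arcs[-nrow(arcs), , drop = FALSE]
    }
    rownames(arcs) <- NULL
    arcs
  })
  list(bins = bins, phase_assigned = label[bin], merged_ranges = merged)
}

#' Two-sample Kuiper test for circular distributions
#'
#' Rotation-invariant analogue of the two-sample Kolmogorov-Smirnov test:
#' `V = max(F1 - F2) + max(F2 - F1)` over the circular empirical CDFs.
#' The p-value uses the asymptotic series with Stephens' small-sample
#' correction of the effective sample size plus a half-lattice continuity
#' correction; below `min(n1, n2) = 20` (or on request) a seeded
#' permutation null is used instead.
#'
#' @param theta1,theta2 angles in radians.
#' @param method "auto" (default), "asymptotic" or "permutation".
#' @param n_perm permutations for the permutation null.
#' @param seed seed for the permutation null.
#' @return list with `V`, `p`, `n1`, `n2`, `method`.
#' @export
kuiper_test <- function(theta1, theta2, method = c("auto", "asymptotic",
                                                   "permutation"),
                        n_perm = 2000, seed = 1) {
  method <- match.arg(method)
  n1 <- length(theta1); n2 <- length(theta2)
  if (n1 < 5 || n2 < 5) stop("both samples need at least 5 observations")
  V <- kuiper_V(theta1 %% (2 * pi), theta2 %% (2 * pi))
  if (method == "auto")
    method <- if (min(n1, n2) < 20) "permutation" else "asymptotic"
  if (method == "asymptotic") {
    ne <- n1 * n2 / (n1 + n2)
    # half-lattice continuity correction: the ECDF difference moves on a
    # lattice with mean step (1/n1 + 1/n2)/2, which otherwise makes the
    # asymptotic series conservative at moderate n
    V_c <- V + 0.25 * (1 / n1 + 1 / n2)
    lambda <- (sqrt(ne) + 0.155 + 0.24 / sqrt(ne)) * V_c
    p <- kuiper_p_asymptotic(lambda)
  } else {
    pool <- c(theta1, theta2)
    p <- with_seed(seed, {
      exceed <- 0L
      for (i in seq_len(n_perm)) {
        idx <- sample.int(n1 + n2, n1)
        if (kuiper_V(pool[idx], pool[-idx]) >= V) exceed <- exceed + 1L
      }
      (exceed + 1) / (n_perm + 1)
    })
  }
  list(V = V, p = min(1, max(0, p)), n1 = n1, n2 = n2, method = method)
}

# Kuiper V statistic on circular ECDFs
kuiper_V <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pool <- c(a, b)
  o <- order(pool)
  who <- c(rep(1 / n1, n1), rep(-1 / n2, n2))[o]
  d <- cumsum(who)  # F1 - F2 evaluated just after each pooled point
  max(d, 0) + max(-d, 0)
}

# asymptotic tail series: P = 2 * sum_j (4 j^2 L^2 - 1) exp(-2 j^2 L^2)
kuiper_p_asymptotic <- function(lambda, j_max = 100) {
  if (lambda < 0.4) return(1)
  j <- seq_len(j_max)
  2 * sum((4 * j^2 * lambda^2 - 1) * exp(-2 * j^2 * lambda^2))
}

#' Remove cell-cycle signal from an expression matrix
#'
#' Each per-phase score is smoothed over the embedding angle with a
#' periodic (cyclic cubic regression spline) smoother, and every gene is
#' residualized on the smoothed phase scores (plus intercept) by linear
#' regression.  The smoother is an unpenalized basis projection, which
#' makes the whole operation a projection: applying it twice changes
#' nothing beyond numerical noise.
#'
#' @param expr normalized expression matrix, cells x genes.
#' @param E_phase per-cell phase scores ([phase_scores()]).
#' @param theta per-cell angle from [embed_cells()].
#' @param k basis dimension of the cyclic smoother.
#' @return residual expression matrix (same shape as `expr`), with the
#'   smoothed phase scores attached as attribute `"smoothed_scores"`.
#' @export
remove_cellcycle_signal <- function(expr, E_phase, theta, k = 10) {
  n <- nrow(expr)
  stopifnot(nrow(E_phase) == n, length(theta) == n)
  if (n <= k + 2) stop("fewer cells than smoother degrees of freedom")
  sm <- apply(E_phase, 2, function(y) {
    fit <- mgcv::gam(y ~ s(theta, bs = "cc", k = k, fx = TRUE),
                     knots = list(theta = seq(0, 2 * pi, length.out = k)))
    stats::fitted(fit)
  })
  # drop smoothed scores with no angular structure left (numerically
  # constant columns would otherwise enter the design as pure noise)
  score_scale <- max(apply(sm, 2, stats::sd), 1)
  keep <- apply(sm, 2, stats::sd) > 1e-10 * score_scale
  X <- cbind(1, sm[, keep, drop = FALSE])
  qr_x <- qr(X)
  resid <- as.matrix(expr) - qr.fitted(qr_x, as.matrix(expr))
  dimnames(resid) <- dimnames(expr)
  attr(resid, "smoothed_scores") <- sm
  resid
}

#' Nominate new phase markers from co-expression with known markers
#'
#' For every gene outside the current marker sets, the phase score for
#' phase k is the mean Pearson correlation with k's markers.  A gene is
#' assigned to its top-scoring phase when (a) its per-marker correlations
#' for that phase significantly exceed those for every other phase
#' (one-sided t-tests), (b) the top score is positive, and (c) the variance
#' of its phase scores exceeds the across-gene mean by `var_sd_cut`
#' standard deviations.
#'
#' @param expr normalized expression matrix, cells x genes (>= 50 cells).
#' @param sets current [phase_gene_sets()].
#' @param var_sd_cut variance threshold in sd units (default 2).
#' @param p_cut t-test significance threshold.
#' @return data frame per candidate gene: phase scores, `score_var`,
#'   `assigned` phase (NA if none).
#' @export
expand_markers <- function(expr, sets, var_sd_cut = 2, p_cut = 0.05) {
  if (nrow(expr) < 50) stop("need expression across at least 50 cells")
  marker_genes <- unlist(sets, use.names = FALSE)
  cand <- setdiff(colnames(expr), marker_genes)
  keep <- cand[apply(expr[, cand, drop = FALSE], 2, stats::sd) > 0]
  mk <- lapply(sets, intersect, x = colnames(expr))
  cors <- stats::cor(as.matrix(expr[, keep, drop = FALSE]),
                     as.matrix(expr[, unlist(mk), drop = FALSE]))
  idx <- split(seq_along(unlist(mk)), rep(names(mk), lengths(mk)))
  scores <- vapply(names(sets), function(k)
    rowMeans(cors[, idx[[k]], drop = FALSE]), numeric(length(keep)))
  scores <- matrix(scores, nrow = length(keep),
                   dimnames = list(NULL, names(sets)))
  v <- apply(scores, 1, stats::var)
  v_cut <- if (length(v) > 1) mean(v) + var_sd_cut * stats::sd(v) else -Inf
  assigned <- rep(NA_character_, length(keep))
  for (i in seq_along(keep)) {
    if (v[i] <= v_cut) next
    best <- which.max(scores[i, ])
    if (scores[i, best] <= 0) next
    rb <- cors[i, idx[[names(sets)[best]]]]
    ok <- TRUE
    for (k2 in setdiff(seq_along(sets), best)) {
      r2 <- cors[i, idx[[names(sets)[k2]]]]
      p <- tryCatch(stats::t.test(rb, r2, alternative = "greater")$p.value,
                    error = function(e) 1)
      if (p >= p_cut) { ok <- FALSE; break }
    }
    if (ok) assigned[i] <- names(sets)[best]
  }
  out <- data.frame(gene = keep, scores, score_var = v, assigned = assigned,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}
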