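# Synthetic single-cell expression with a planted circular cell-cycle
# coordinate, phase-specific marker programs and knockout-specific
# phase-density distortions.

#' Ground truth for a simulated single-cell experiment
#'
#' Cells carry a latent cell-cycle angle theta in \[0, 2pi).  Control cells
#' are asynchronous (uniform on the circle); knockout populations can be
#' concentrated around a target phase by a von Mises density distortion.
#' Each phase owns a set of marker genes whose mean expression is a smooth
#' unimodal circular bump of theta peaking inside the phase's angular
#' range; background genes are phase independent.  Counts are sampled with
#' gamma-Poisson (negative binomial) noise at a depth resembling shallow
#' droplet scRNA-seq (marker means of order 1-5 counts at peak).
#'
#' @param n_cells number of control cells.
#' @param markers_per_phase marker genes per phase.
#' @param n_background phase-independent background genes.
#' @param amplitude peak height of the marker bump (counts above baseline).
#' @param baseline baseline marker mean (counts).
#' @param kappa concentration of the marker bump around its peak angle.
#' @param dispersion negative binomial size parameter (larger = closer to
#'   Poisson).
#' @param phase_fractions angular extent of each phase (fractions of the
#'   circle summing to 1, canonical phase order).
#' @param knockouts NULL, or a data frame with columns `gene`, `n_cells`,
#'   `target_phase`, `kappa_shift`, `weight`: each knockout contributes
#'   `n_cells` cells whose theta is drawn with probability `weight` from a
#'   von Mises centered on the midpoint of `target_phase` (concentration
#'   `kappa_shift`) and otherwise uniformly.
#' @param seed RNG seed.
#' @return a `cell_sim_truth` list with per-cell `theta_true`, `ko`,
#'   `phase_true`, the phase boundaries, marker programs and marker sets.
#' @export
cell_sim_truth <- function(n_cells = 2000, markers_per_phase = 120,
                           n_background = 400, amplitude = 5, baseline = 0.2,
                           kappa = 5, dispersion = 10,
                           phase_fractions = PHASE_FRACTIONS,
                           knockouts = NULL, seed = 1) {
  stopifnot(abs(sum(phase_fractions) - 1) < 1e-8, amplitude >= 0,
            n_cells >= 2 * length(PHASES))
  bounds <- cumsum(c(0, phase_fractions)) * 2 * pi
  names(bounds) <- c(PHASES, "end")
  with_seed(seed, {
    theta <- stats::runif(n_cells, 0, 2 * pi)
    ko <- rep("control", n_cells)
    if (!is.null(knockouts)) {
      stopifnot(all(c("gene", "n_cells", "target_phase", "kappa_shift",
                      "weight") %in% names(knockouts)))
      for (i in seq_len(nrow(knockouts))) {
        kk <- knockouts[i, ]
        p <- match(kk$target_phase, PHASES)
        if (is.na(p)) stop("unknown target phase: ", kk$target_phase)
        mu <- (bounds[p] + bounds[p + 1]) / 2
        shifted <- stats::runif(kk$n_cells) < kk$weight
        th <- ifelse(shifted,
                     rvonmises(kk$n_cells, mu, kk$kappa_shift),
                     stats::runif(kk$n_cells, 0, 2 * pi))
        theta <- c(theta, th)
        ko <- c(ko, rep(kk$gene, kk$n_cells))
      }
    }
    phase_true <- PHASES[pmin(findInterval(theta, bounds), length(PHASES))]
    # marker programs: peak angles spread uniformly through each phase arc
    programs <- do.call(rbind, lapply(seq_along(PHASES), function(p) {
      peaks <- stats::runif(markers_per_phase, bounds[p], bounds[p + 1])
      data.frame(gene = sprintf("%s_mk%02d", gsub("/", "", PHASES[p]),
                                seq_len(markers_per_phase)),
                 phase = PHASES[p], peak = peaks,
                 amplitude = amplitude, baseline = baseline,
                 stringsAsFactors = FALSE)
    }))
    bg_mean <- stats::runif(n_background, 0.2, 2)
    structure(list(theta_true = theta, ko = ko, phase_true = phase_true,
                   phase_boundaries = bounds, programs = programs,
                   bg_mean = stats::setNames(bg_mean,
                                             sprintf("BG%04d",
                                                     seq_len(n_background))),
                   kappa = kappa, dispersion = dispersion, seed = seed),
              class = "cell_sim_truth")
  })
}

# von Mises sampler (Best & Fisher rejection algorithm)
rvonmises <- function(n, mu, kappa) {
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
      i <- i + 1
    }
  }
  out
}

#' Simulate a single-cell count matrix from planted truth
#'
#' Marker gene means follow `baseline + amplitude * exp(kappa *
#' (cos(theta - peak) - 1))`; background genes have constant means.
#' Counts are negative binomial with the truth's dispersion.
#'
#' @param truth a [cell_sim_truth()].
#' @return list with `counts` (cells x genes integer matrix), `cells`
#'   (annotation data frame: `cell_id`, `ko`, `theta_true`, `phase_true`)
#'   and `sets` (the marker [phase_gene_sets()]).
#' @export
simulate_cells <- function(truth) {
  stopifnot(inherits(truth, "cell_sim_truth"))
  n <- length(truth$theta_true)
  pr <- truth$programs
  mu_mark <- truth$theta_true |>
    outer(pr$peak, function(th, pk) exp(truth$kappa * (cos(th - pk) - 1)))
  mu_mark <- sweep(mu_mark, 2, pr$amplitude, `*`)
  mu_mark <- sweep(mu_mark, 2, pr$baseline, `+`)
  mu_bg <- matrix(truth$bg_mean, n, length(truth$bg_mean), byrow = TRUE)
  mu <- cbind(mu_mark, mu_bg)
  colnames(mu) <- c(pr$gene, names(truth$bg_mean))
  counts <- with_seed(truth$seed + 1000, {
    matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                          size = truth$dispersion),
           nrow = n, dimnames = dimnames(mu))
  })
  cells <- data.frame(cell_id = sprintf("cell%05d", seq_len(n)),
                      ko = truth$ko, theta_true = truth$theta_true,
                      phase_true = truth$phase_true,
                      stringsAsFactors = FALSE)
  rownames(counts) <- cells$cell_id
  sets <- phase_gene_sets(split(pr$gene, pr$phase)[PHASES])
  list(counts = counts, cells = cells, sets = sets)
}

#' Total-count normalize and log-transform a count matrix
#'
#' Library sizes are scaled to their median and counts log(1 + x)
#' transformed; the standard normalization used before phase scoring and
#' differential expression.
#'
#' @param counts cells x genes count matrix.
#' @param target size factor target (default median library size).
#' @return normalized matrix of the same shape.
#' @export
normalize_counts <- function(counts, target = NULL) {
  lib <- rowSums(counts)
  if (any(lib == 0)) stop("cell(s) with zero total counts")
  target <- target %||% stats::median(lib)
  log1p(counts / lib * target)
}

#' Full cell-cycle embedding pipeline on a normalized matrix
#'
#' Phase scores, coarse classification, polar embedding and angular phase
#' ranges in one call.
#'
#' @param expr normalized cells x genes matrix.
#' @param sets a [phase_gene_sets()].
#' @param n_bins angular bins for phase ranges.
#' @return list with `scores`, `coarse`, `embedding` (per-cell data
#'   frame incl. `phase_assigned`) and `ranges`.
#' @export
cellcycle_embed <- function(expr, sets, n_bins = 60) {
  sc <- phase_scores(expr, sets)
  coarse <- coarse_classify(sc$E_phase)
  emb <- embed_cells(sc$E_pan, coarse)
  rng <- assign_phase_ranges(emb$theta, coarse, n_bins = n_bins)
  emb$coarse <- coarse
  emb$phase_assigned <- rng$phase_assigned
  list(scores = sc, coarse = coarse, embedding = emb, ranges = rng)
}
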