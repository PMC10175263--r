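# Synthetic dual-guide fitness screen with planted ground truth.

#' Define ground truth for a simulated fitness screen
#'
#' @param library a [guide_library()].
#' @param f_true named numeric vector of per-guide fitness (log2 abundance
#'   change per unit screen time); guides not named default to 0.  Controls
#'   (NTC, AAVS1) default to 0 fitness.
#' @param pi_true data frame with columns `gene_a`, `gene_b`, `pi` of
#'   planted gene-level interactions (symmetric in gene order); may be NULL.
#' @param depth sequencing reads per (timepoint, replicate) sample.
#' @param timepoints numeric vector of timepoints in screen-duration units;
#'   the first is the baseline t0.
#' @param replicates number of biological replicates.
#' @param pair_noise_sd sd of persistent construct-level growth artifacts
#'   (log2 per unit time).  Dual-guide cassettes carry pair-specific
#'   biases -- recombination between spacers and abortive-PCR uncoupling
#'   are why such libraries embed barcodes -- and these artifacts are
#'   properties of the construct pool, hence shared across timepoints and
#'   replicates rather than resampled per library prep.
#' @param seed RNG seed.
#' @return a `screen_truth` list.
#' @export
screen_truth <- function(library, f_true = NULL, pi_true = NULL,
                         depth = 1e6, timepoints = c(0, 1, 2, 3),
                         replicates = 2, pair_noise_sd = 0.3, seed = 1) {
  stopifnot(inherits(library, "guide_library"), depth > 0,
            length(timepoints) >= 2, replicates >= 1)
  f <- stats::setNames(rep(0, nrow(library)), library$guide_id)
  if (!is.null(f_true)) {
    if (!all(names(f_true) %in% library$guide_id))
      stop("f_true names guides missing from the library")
    f[names(f_true)] <- f_true
  }
  if (!is.null(pi_true)) {
    stopifnot(all(c("gene_a", "gene_b", "pi") %in% names(pi_true)))
    bad <- setdiff(c(pi_true$gene_a, pi_true$gene_b), library$gene)
    if (length(bad)) stop("pi_true names genes missing from the library: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(library = library, f_true = f, pi_true = pi_true,
                 depth = depth, timepoints = sort(timepoints),
                 replicates = as.integer(replicates),
                 pair_noise_sd = pair_noise_sd, seed = seed),
            class = "screen_truth")
}

#' Randomized screen truth with planted guide fitness and interactions
#'
#' Convenience generator for recovery tests: per-guide fitness is drawn
#' N(mu_f, sd_f) for targeting guides (0 for controls), and `pi_pairs`
#' specifies planted gene-level interactions.
#'
#' @inheritParams screen_truth
#' @param mu_f,sd_f mean and sd of targeting-guide fitness.
#' @param pi_pairs data frame (`gene_a`, `gene_b`, `pi`) or NULL.
#' @export
random_screen_truth <- function(library, mu_f = -0.5, sd_f = 0.7,
                                pi_pairs = NULL, depth = 1e6,
                                timepoints = c(0, 1, 2, 3), replicates = 2,
                                pair_noise_sd = 0.3, seed = 1) {
  targeting <- !(library$gene %in% c("NTC", "AAVS1"))
  f <- with_seed(seed, {
    # one fitness value per gene, shared across its guides with small
    # guide-level jitter, emulating on-target phenotype plus guide efficacy
    genes <- unique(library$gene[targeting])
    fg <- stats::setNames(stats::rnorm(length(genes), mu_f, sd_f), genes)
    out <- rep(0, nrow(library))
    out[targeting] <- fg[library$gene[targeting]] +
      stats::rnorm(sum(targeting), 0, 0.1)
    stats::setNames(out, library$guide_id)
  })
  screen_truth(library, f_true = f, pi_true = pi_pairs, depth = depth,
               timepoints = timepoints, replicates = replicates,
               pair_noise_sd = pair_noise_sd, seed = seed)
}

#' Simulate a combinatorial fitness screen count table
#'
#' Constructs grow exponentially: the expected relative abundance of
#' construct (g1, g2) at time t is proportional to
#' `p0 * 2^((f_g1 + f_g2 + pi_gene(g1),gene(g2)) * t)`, starting from a
#' uniform plasmid pool.  Reads for each (timepoint, replicate) sample are
#' drawn multinomially at the stated depth, so every sample sums exactly to
#' `depth`.
#'
#' @param truth a [screen_truth()].
#' @return a `pair_count_table` data frame with columns `g1`, `g2`,
#'   `timepoint`, `replicate`, `count`, carrying the library as an
#'   attribute.
#' @export
simulate_screen <- function(truth) {
  stopifnot(inherits(truth, "screen_truth"))
  lib <- truth$library
  pairs <- enumerate_pairs(lib)
  gene <- stats::setNames(lib$gene, lib$guide_id)
  f <- truth$f_true
  growth <- f[pairs$g1] + f[pairs$g2]
  if (!is.null(truth$pi_true)) {
    key <- paste(pmin(gene[pairs$g1], gene[pairs$g2]),
                 pmax(gene[pairs$g1], gene[pairs$g2]))
    pk <- stats::setNames(truth$pi_true$pi,
                          paste(pmin(truth$pi_true$gene_a, truth$pi_true$gene_b),
                                pmax(truth$pi_true$gene_a, truth$pi_true$gene_b)))
    hit <- key %in% names(pk)
    growth[hit] <- growth[hit] + pk[key[hit]]
  }
  out <- with_seed(truth$seed, {
    # construct-level artifacts: drawn once, shared across all samples
    eps <- if ((truth$pair_noise_sd %||% 0) > 0)
      stats::rnorm(nrow(pairs), 0, truth$pair_noise_sd) else 0
    growth <- growth + eps
    res <- list()
    for (r in seq_len(truth$replicates)) {
      for (t in truth$timepoints) {
        p <- 2^(growth * t)
        p <- p / sum(p)
        counts <- stats::rmultinom(1, size = truth$depth, prob = p)[, 1]
        res[[length(res) + 1]] <- data.frame(
          g1 = pairs$g1, g2 = pairs$g2, timepoint = t, replicate = r,
          count = counts, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, res)
  })
  rownames(out) <- NULL
  structure(out, library = lib, class = c("pair_count_table", "data.frame"))
}

#' Simulate paired cassette reads for a construct count table
#'
#' Emits read-1/read-2 pairs in the sequencing cassette layout (constant
#' 5' anchor, spacer, constant 3' context for each position), one pair per
#' counted construct read, with iid per-base substitution errors.
#'
#' @param pair_counts data frame with columns `g1`, `g2`, `count` (a single
#'   sample; subset a [simulate_screen()] table first).
#' @param library a [guide_library()].
#' @param error_rate per-base substitution probability in \[0, 0.25\].
#' @param seed RNG seed.
#' @param r1_path,r2_path output FASTQ paths.
#' @return invisible list with the two paths and the number of pairs.
#' @export
simulate_reads <- function(pair_counts, library, error_rate = 0, seed = 1,
                           r1_path = tempfile(fileext = "_R1.fastq"),
                           r2_path = tempfile(fileext = "_R2.fastq")) {
  stopifnot(error_rate >= 0, error_rate <= 0.25,
            all(c("g1", "g2", "count") %in% names(pair_counts)))
  ref <- build_reference(library)
  keep <- pair_counts$count > 0
  pc <- pair_counts[keep, , drop = FALSE]
  g1 <- rep(pc$g1, pc$count)
  g2 <- rep(pc$g2, pc$count)
  n <- length(g1)
  r1 <- unname(ref$contigs[paste0("pos1|", g1)])
  r2 <- unname(ref$contigs[paste0("pos2|", g2)])
  if (error_rate > 0 && n > 0) {
    r1 <- with_seed(seed, mutate_reads(r1, error_rate))
    r2 <- with_seed(seed + 1, mutate_reads(r2, error_rate))
  }
  ids <- sprintf("read%07d:%s:%s", seq_len(n), g1, g2)
  write_fastq(ids, r1, r1_path)
  write_fastq(ids, r2, r2_path)
  invisible(list(r1 = r1_path, r2 = r2_path, n_pairs = n))
}

# iid substitutions at the given per-base rate; substituted bases are drawn
# uniformly from the three alternatives
mutate_reads <- function(seqs, rate) {
  vapply(seqs, function(s) {
    v <- strsplit(s, "")[[1]]
    hit <- which(stats::runif(length(v)) < rate)
    for (i in hit) {
      v[i] <- sample(setdiff(DNA_ALPHABET, v[i]), 1)
    }
    paste(v, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
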