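# Internal helpers shared across modules.

DNA_ALPHABET <- c("A", "C", "G", "T")

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG seed
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that results are pure functions of (inputs, seed) and the
#' caller's RNG state is left untouched.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

#' Random DNA strings
#' @noRd
random_dna <- function(n, width) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_ALPHABET, width, replace = TRUE), collapse = "")
  }, character(1))
}

#' Hamming distance between two equal-length strings
#' @noRd
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming(): strings must have equal length")
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Levenshtein distance via dynamic programming.
#'
#' Kept as a plain R implementation so it can serve as an independent oracle
#' for the vectorized matching in `match_read()` (which uses utils::adist).
#' @noRd
levenshtein_dp <- function(a, b) {
  x <- utf8ToInt(a); y <- utf8ToInt(b)
  n <- length(x); m <- length(y)
  if (n == 0) return(m)
  if (m == 0) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- integer(m + 1)
    cur[1] <- i
    for (j in seq_len(m)) {
      cost <- if (x[i] == y[j]) 0L else 1L
      cur[j + 1] <- min(prev[j + 1] + 1L, cur[j] + 1L, prev[j] + cost)
    }
    prev <- cur
  }
  prev[m + 1]
}

#' Validate a DNA string vector
#' @noRd
is_dna <- function(x) {
  grepl("^[ACGT]+$", x)
}

#' Population standard deviation (divisor n, not n - 1)
#' @noRd
sd_pop <- function(x) {
  x <- x[is.finite(x)]
  sqrt(mean((x - mean(x))^2))
}

#' Circular (angular) correlation coefficient
#'
#' Fisher-Lee T-linear association in its pairwise form,
#' `sum_{i<j} sin(a_i - a_j) sin(b_i - b_j)` normalized by the analogous
#' sums of squares.  Unlike mean-direction-centered variants this remains
#' well defined when a marginal is uniform on the circle (no mean
#' direction), is invariant to rotations of either variable and changes
#' sign under reflection.
#'
#' @param a,b angles in radians.
#' @return correlation in \[-1, 1\].
#' @export
circular_cor <- function(a, b) {
  stopifnot(length(a) == length(b))
  sa <- sin(a); ca <- cos(a); sb <- sin(b); cb <- cos(b)
  num <- sum(sa * sb) * sum(ca * cb) - sum(sa * cb) * sum(ca * sb)
  den <- sqrt((sum(sa^2) * sum(ca^2) - sum(sa * ca)^2) *
                (sum(sb^2) * sum(cb^2) - sum(sb * cb)^2))
  if (den == 0) return(NA_real_)
  num / den
}

#' Align one set of angles to a reference by rotation/reflection
#'
#' Finds the orientation (identity or reflection) and rotation offset that
#' maximizes the circular correlation with the reference angles, by grid
#' search over rotations.  Used to compare an embedding-derived phase angle,
#' whose absolute orientation is arbitrary, against a planted truth.
#'
#' @param theta angles to align (radians).
#' @param ref reference angles (radians), same length.
#' @param n_grid number of candidate rotations.
#' @return list with `theta` (aligned), `reflected`, `rotation`, `cor`.
#' @export
align_angles <- function(theta, ref, n_grid = 360) {
  grid <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
  best <- list(cor = -Inf)
  for (refl in c(FALSE, TRUE)) {
    th <- if (refl) (2 * pi - theta) %% (2 * pi) else theta
    # circular correlation is rotation invariant; use it to pick orientation,
    # then pick the rotation minimizing mean angular error
    cc <- circular_cor(th, ref)
    if (is.na(cc)) next
    if (cc > best$cor) {
      err <- vapply(grid, function(g) {
        d <- ((th + g - ref + pi) %% (2 * pi)) - pi
        mean(abs(d))
      }, numeric(1))
      g <- grid[which.min(err)]
      best <- list(theta = (th + g) %% (2 * pi), reflected = refl,
                   rotation = g, cor = cc)
    }
  }
  if (is.infinite(best$cor)) stop("align_angles(): degenerate input")
  best
}

#' Write a simple four-line FASTQ file
#' @noRd
write_fastq <- function(ids, seqs, path, qual_char = "I") {
  stopifnot(length(ids) == length(seqs))
  qual <- vapply(nchar(seqs), function(n) strrep(qual_char, n), character(1))
  lines <- as.vector(rbind(paste0("@", ids), seqs, "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a four-line FASTQ file into id/sequence vectors
#' @noRd
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) return(list(id = character(0), seq = character(0)))
  if (length(lines) %% 4 != 0) stop("malformed FASTQ: ", path)
  idx <- seq(1, length(lines), by = 4)
  list(id = sub("^@", "", sub("\\s.*$", "", lines[idx])),
       seq = toupper(lines[idx + 1]))
}
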