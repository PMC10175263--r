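# Assign paired cassette reads to guide pairs and derive construct
# abundance, fold change and standardized fitness.

#' Match one read to its expected-position guide by windowed edit distance
#'
#' The spacer window of the read (everything after the constant 5' anchor of
#' its position) is compared against every spacer in the library by
#' Levenshtein distance, taking for each guide the minimum distance over
#' window lengths spacer_length +/- max_dist (so that up to `max_dist`
#' insertions or deletions inside the spacer are scored correctly).  The
#' read is assigned to the guide minimizing this distance when the minimum
#' is at most `max_dist`; if two guides tie at the minimal distance the
#' read is ambiguous and rejected.
#'
#' @param read_seq read sequence (uppercase DNA).
#' @param position 1 or 2 (which cassette position the read covers).
#' @param reference a [build_reference()] result.
#' @param max_dist maximum accepted edit distance (default 2: reads at
#'   distance less than 3 pass the validity filter).
#' @return list with `guide_id` (or NA), `distance`, and `reason` (one of
#'   "ok", "too_distant", "ambiguous", "too_short").
#' @export
match_read <- function(read_seq, position, reference, max_dist = 2) {
  stopifnot(inherits(reference, "position_reference"), position %in% c(1, 2))
  anchor <- if (position == 1) READ1_5P else READ2_5P
  a <- nchar(anchor)
  if (nchar(read_seq) < a + SPACER_LENGTH - max_dist) {
    return(list(guide_id = NA_character_, distance = NA_integer_,
                reason = "too_short"))
  }
  spacers <- reference$library$spacer
  ids <- reference$library$guide_id
  lens <- (SPACER_LENGTH - max_dist):(SPACER_LENGTH + max_dist)
  windows <- vapply(lens, function(L)
    substr(read_seq, a + 1, min(a + L, nchar(read_seq))), character(1))
  d <- apply(utils::adist(unique(windows), spacers), 2, min)
  dmin <- min(d)
  if (dmin > max_dist) {
    return(list(guide_id = NA_character_, distance = as.integer(dmin),
                reason = "too_distant"))
  }
  hits <- which(d == dmin)
  if (length(hits) > 1) {
    return(list(guide_id = NA_character_, distance = as.integer(dmin),
                reason = "ambiguous"))
  }
  list(guide_id = ids[hits], distance = as.integer(dmin), reason = "ok")
}

# vectorized matcher over many reads for one position; returns a data frame
match_reads_vec <- function(seqs, position, reference, max_dist = 2) {
  anchor <- if (position == 1) READ1_5P else READ2_5P
  a <- nchar(anchor)
  spacers <- reference$library$spacer
  ids <- reference$library$guide_id
  n <- length(seqs)
  guide <- rep(NA_character_, n)
  dist <- rep(NA_integer_, n)
  reason <- rep("too_short", n)
  ok_len <- nchar(seqs) >= a + SPACER_LENGTH - max_dist
  if (any(ok_len)) {
    lens <- (SPACER_LENGTH - max_dist):(SPACER_LENGTH + max_dist)
    dmat <- NULL
    for (L in lens) {
      w <- substr(seqs[ok_len], a + 1, a + L)
      dd <- utils::adist(w, spacers)
      dmat <- if (is.null(dmat)) dd else pmin(dmat, dd)
    }
    dmin <- apply(dmat, 1, min)
    nmin <- rowSums(dmat == dmin)
    best <- max.col(-dmat, ties.method = "first")
    idx <- which(ok_len)
    dist[idx] <- as.integer(dmin)
    reason[idx] <- ifelse(dmin > max_dist, "too_distant",
                          ifelse(nmin > 1, "ambiguous", "ok"))
    assigned <- reason[idx] == "ok"
    guide[idx[assigned]] <- ids[best[assigned]]
  }
  data.frame(guide_id = guide, distance = dist, reason = reason,
             stringsAsFactors = FALSE)
}

#' Count guide pairs from paired FASTQ files
#'
#' Each mate is matched to its expected-position guide with [match_read()]
#' semantics; a mate pair is valid only if both mates are assigned (edit
#' distance < 3, unambiguous) and the resulting ordered (g1, g2) pair is
#' expected from the library construction (g1 != g2).  Invalid pairs are
#' tallied by rejection reason, and assigned + rejected always equals the
#' number of input pairs.
#'
#' @param r1_path,r2_path FASTQ paths for read 1 (position 1) and read 2
#'   (position 2).
#' @param library a [guide_library()].
#' @param reference optional prebuilt [build_reference()].
#' @param max_dist maximum edit distance per mate.
#' @param timepoint,replicate labels attached to the resulting counts.
#' @return list with `counts` (a `pair_count_table` over all n(n-1)
#'   library pairs, zero-filled) and `report` (totals and rejection
#'   reasons).
#' @export
count_pairs <- function(r1_path, r2_path, library, reference = NULL,
                        max_dist = 2, timepoint = 0, replicate = 1) {
  if (is.null(reference)) reference <- build_reference(library)
  fq1 <- read_fastq(r1_path)
  fq2 <- read_fastq(r2_path)
  n1 <- length(fq1$seq); n2 <- length(fq2$seq)
  n <- min(n1, n2)
  orphans <- abs(n1 - n2)
  m1 <- if (n > 0) match_reads_vec(fq1$seq[seq_len(n)], 1, reference, max_dist)
        else data.frame()
  m2 <- if (n > 0) match_reads_vec(fq2$seq[seq_len(n)], 2, reference, max_dist)
        else data.frame()
  pairs <- enumerate_pairs(library)
  key_all <- paste(pairs$g1, pairs$g2, sep = "\r")
  counts <- stats::setNames(integer(nrow(pairs)), key_all)
  report <- c(input_pairs = n + orphans, assigned = 0L, orphan = orphans,
              r1_too_distant = 0L, r1_ambiguous = 0L, r1_too_short = 0L,
              r2_too_distant = 0L, r2_ambiguous = 0L, r2_too_short = 0L,
              unexpected_pair = 0L)
  if (n > 0) {
    bad1 <- m1$reason != "ok"
    bad2 <- m2$reason != "ok"
    for (rr in c("too_distant", "ambiguous", "too_short")) {
      report[paste0("r1_", rr)] <- sum(m1$reason == rr)
      report[paste0("r2_", rr)] <- sum(m2$reason == rr & !bad1)
    }
    cand <- !bad1 & !bad2
    key <- paste(m1$guide_id[cand], m2$guide_id[cand], sep = "\r")
    expected <- key %in% key_all
    report["unexpected_pair"] <- sum(!expected)
    tab <- table(key[expected])
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
    report["assigned"] <- sum(expected)
  }
  out <- data.frame(g1 = pairs$g1, g2 = pairs$g2, timepoint = timepoint,
                    replicate = replicate, count = unname(counts),
                    stringsAsFactors = FALSE)
  list(counts = structure(out, library = library,
                          class = c("pair_count_table", "data.frame")),
       report = as.list(report))
}

#' Log2 relative construct abundance within one sample
#'
#' `x = log2((M + c) / sum(M + c))` with pseudocount `c` (default 1, so
#' zero counts stay finite); within a sample `sum(2^x) == 1`.
#'
#' @param counts integer vector of construct read counts for one
#'   (timepoint, replicate) sample.
#' @param pseudocount added to every count before normalization.
#' @return numeric vector of log2 relative abundances.
#' @export
compute_abundance <- function(counts, pseudocount = 1) {
  stopifnot(all(counts >= 0))
  m <- counts + pseudocount
  tot <- sum(m)
  if (tot <= 0) stop("all-zero sample with zero pseudocount")
  log2(m / tot)
}

#' Construct fold change and standardized fitness across timepoints
#'
#' Per construct, fold change at time t is the abundance difference from
#' baseline, `m_t = x_t - x_t0`; fitness is the z-standardization of `m_t`
#' over all constructs within the same (timepoint, replicate) sample using
#' the population standard deviation, so `f` has mean 0 and sd 1 within
#' each standardization population.
#'
#' @param counts a `pair_count_table` (long data frame with `g1`, `g2`,
#'   `timepoint`, `replicate`, `count`).
#' @param pseudocount for [compute_abundance()].
#' @param pool_replicates if TRUE, mu/sigma are estimated pooling
#'   replicates at each timepoint; default standardizes per replicate.
#' @return the input with columns `x`, `m`, `f` added (m and f are NA at
#'   the baseline timepoint).
#' @export
compute_fitness <- function(counts, pseudocount = 1, pool_replicates = FALSE) {
  df <- as.data.frame(counts)
  stopifnot(all(c("g1", "g2", "timepoint", "replicate", "count") %in% names(df)))
  t0 <- min(df$timepoint)
  df$x <- NA_real_
  for (r in unique(df$replicate)) {
    for (t in unique(df$timepoint)) {
      i <- df$replicate == r & df$timepoint == t
      df$x[i] <- compute_abundance(df$count[i], pseudocount)
    }
  }
  # baseline lookup per replicate
  df$m <- NA_real_
  for (r in unique(df$replicate)) {
    base <- df[df$replicate == r & df$timepoint == t0, ]
    if (nrow(base) == 0) stop("baseline timepoint missing for replicate ", r)
    key0 <- paste(base$g1, base$g2, sep = "\r")
    x0 <- stats::setNames(base$x, key0)
    i <- df$replicate == r & df$timepoint != t0
    df$m[i] <- df$x[i] - unname(x0[paste(df$g1[i], df$g2[i], sep = "\r")])
  }
  df$f <- NA_real_
  groups <- if (pool_replicates) list(df$timepoint) else
    list(df$timepoint, df$replicate)
  gid <- interaction(groups, drop = TRUE)
  for (g in levels(gid)) {
    i <- gid == g & df$timepoint != t0
    if (!any(i)) next
    s <- sd_pop(df$m[i])
    if (s == 0) stop("degenerate sample: zero variance in fold changes")
    df$f[i] <- (df$m[i] - mean(df$m[i])) / s
  }
  structure(df, library = attr(counts, "library"),
            class = c("pair_count_table", "data.frame"))
}
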