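# Small fixtures shared across test files; everything is generated in code.

tiny_library <- function(n_genes = 3, guides_per_gene = 2, seed = 42) {
  simulate_guide_library(n_genes = n_genes, guides_per_gene = guides_per_gene,
                         seed = seed)
}

# Independent brute-force oracle for read matching: plain DP Levenshtein of
# the read's spacer window against every spacer, min over window lengths.
oracle_match <- function(read_seq, position, library, max_dist = 2) {
  anchor_len <- if (position == 1) nchar(cdkperturb:::READ1_5P) else
    nchar(cdkperturb:::READ2_5P)
  lens <- (20 - max_dist):(20 + max_dist)
  d <- vapply(library$spacer, function(sp) {
    min(vapply(lens, function(L) {
      w <- substr(read_seq, anchor_len + 1, min(anchor_len + L, nchar(read_seq)))
      cdkperturb:::levenshtein_dp(w, sp)
    }, numeric(1)))
  }, numeric(1))
  dmin <- min(d)
  hits <- which(d == dmin)
  if (dmin > max_dist || length(hits) > 1) {
    list(guide_id = NA_character_, distance = dmin)
  } else {
    list(guide_id = library$guide_id[hits], distance = dmin)
  }
}

# introduce k random substitutions into a string at distinct positions
substitute_bases <- function(s, k, positions = NULL) {
  v <- strsplit(s, "")[[1]]
  if (is.null(positions)) positions <- sample(seq_along(v), k)
  for (i in positions) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}
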