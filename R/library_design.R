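# Dual-guide library combinatorics: pair enumeration, barcode design,
# oligo scaffold assembly and two-position alignment references.

# Fixed scaffold segments of the synthesized oligo pool:
# 5' constant | spacer 1 | linker 1 | 15-nt barcode | linker 2 | spacer 2 | 3' constant
OLIGO_5P <- "TCTTGTGGAAAGGACGAAACACCG"
OLIGO_LINKER1 <- "GTTTTGAGACG"
OLIGO_LINKER2 <- "CGTCTCGTTTG"
OLIGO_3P <- "GTTTTAGAGCTAGAAATAGCAAGTTAAAA"

# Constant context of the sequencing cassette around each spacer position.
# Read 1 carries the position-1 spacer, read 2 the position-2 spacer.
READ1_5P <- "TATATATCTTGTGGAAAGGACGAAACACCG"
READ1_3P <- "GTTTCAGAGCTATGCTGGAAACTGCATAGCAAGTTGAAATAAGGCTAGTCC"
READ2_5P <- "CCTTATTTTAACTTGCTATTTCTAGCTCTAAAAC"
READ2_3P <- "GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGG"

SPACER_LENGTH <- 20L
BARCODE_LENGTH <- 15L

# Non-targeting and AAVS1 safe-harbor control spacers used in the screen.
NTC_SPACERS <- c("AAAAAGCTTCCGCCTGATGG", "AACTAGCCCGAGCAGCTTCG",
                 "AAGTGACGGTGTCATGCGGG", "AATATTTGGCTCGGCTGCGC")
AAVS1_SPACERS <- c("CCTGCAACAGATCTTTGATG", "GGTCCAAACTTAGGGATGTG",
                   "AGTACAGTTGGGAAACAACT", "GGCCATTCCCGGCCTCCCTG")

#' Construct a validated guide library
#'
#' A guide library is a data frame of single guides: an identifier, the gene
#' symbol it targets (the reserved labels `"NTC"` and `"AAVS1"` mark
#' non-targeting and safe-harbor cutting controls) and its 20-nt spacer
#' sequence.  Downstream modules treat AAVS1 guides as the neutral-fitness
#' anchor.
#'
#' @param guides data frame with columns `guide_id`, `gene`, `spacer`.
#' @param n_guides_per_gene design constant recorded as an attribute
#'   (default 4, the number of distinct spacers per targeted gene).
#' @return a `guide_library` object (data frame subclass).
#' @export
guide_library <- function(guides, n_guides_per_gene = 4L) {
  stopifnot(is.data.frame(guides),
            all(c("guide_id", "gene", "spacer") %in% names(guides)))
  guides <- as.data.frame(guides)[, c("guide_id", "gene", "spacer")]
  guides$guide_id <- as.character(guides$guide_id)
  guides$gene <- as.character(guides$gene)
  guides$spacer <- toupper(as.character(guides$spacer))
  if (nrow(guides) == 0) stop("guide library is empty")
  if (anyDuplicated(guides$guide_id))
    stop("duplicate guide_id in library")
  if (anyDuplicated(guides$spacer))
    stop("duplicate spacer sequences in library (ambiguous reference)")
  if (!all(nchar(guides$spacer) == SPACER_LENGTH))
    stop("all spacers must be exactly ", SPACER_LENGTH, " nt")
  if (!all(is_dna(guides$spacer)))
    stop("spacers must be uppercase DNA over {A,C,G,T}")
  structure(guides,
            n_guides_per_gene = as.integer(n_guides_per_gene),
            class = c("guide_library", "data.frame"))
}

#' Simulate a guide library in the dual-guide screen design
#'
#' Generates `n_genes` gene symbols with `guides_per_gene` random spacers
#' each, augmented with the four non-targeting and four AAVS1 safe-harbor
#' control spacers used in the screen design.  With the defaults
#' (26 genes x 4 guides + 8 controls) the library has 112 guides.
#'
#' @param n_genes number of targeted genes.
#' @param guides_per_gene spacers per targeted gene.
#' @param seed RNG seed.
#' @param gene_names optional character vector of gene symbols.
#' @return a [guide_library()].
#' @export
simulate_guide_library <- function(n_genes = 26, guides_per_gene = 4,
                                   seed = 1, gene_names = NULL) {
  if (is.null(gene_names)) gene_names <- sprintf("GENE%02d", seq_len(n_genes))
  stopifnot(length(gene_names) == n_genes)
  controls <- c(NTC_SPACERS, AAVS1_SPACERS)
  spacers <- with_seed(seed, {
    out <- character(0)
    while (length(out) < n_genes * guides_per_gene) {
      cand <- random_dna(n_genes * guides_per_gene, SPACER_LENGTH)
      out <- unique(c(out, setdiff(cand, controls)))
    }
    out[seq_len(n_genes * guides_per_gene)]
  })
  df <- data.frame(
    guide_id = c(paste0(rep(gene_names, each = guides_per_gene), "_g",
                        seq_len(guides_per_gene)),
                 paste0("NTC_g", 1:4), paste0("AAVS1_g", 1:4)),
    gene = c(rep(gene_names, each = guides_per_gene),
             rep("NTC", 4), rep("AAVS1", 4)),
    spacer = c(spacers, NTC_SPACERS, AAVS1_SPACERS),
    stringsAsFactors = FALSE)
  guide_library(df, n_guides_per_gene = guides_per_gene)
}

#' Read / write a guide library as TSV
#' @param path file path.
#' @rdname guide_library_io
#' @export
read_guide_library <- function(path) {
  guide_library(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @param library a [guide_library()].
#' @rdname guide_library_io
#' @export
write_guide_library <- function(library, path) {
  utils::write.table(as.data.frame(library), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Enumerate all ordered guide pairs
#'
#' Every ordered pair of distinct guides is a separate construct: (a, b) and
#' (b, a) are synthesized and counted independently, so a library of n guides
#' yields n(n-1) constructs (12,432 for the 112-guide design).
#'
#' @param library a [guide_library()].
#' @return data frame with columns `g1`, `g2` in lexicographic order of
#'   (position-1 index, position-2 index).
#' @export
enumerate_pairs <- function(library) {
  stopifnot(inherits(library, "guide_library"))
  ids <- library$guide_id
  n <- length(ids)
  if (n < 1) stop("invalid design: empty library")
  idx <- expand.grid(j = seq_len(n), i = seq_len(n))  # i varies slowest
  idx <- idx[idx$i != idx$j, c("i", "j")]
  data.frame(g1 = ids[idx$i], g2 = ids[idx$j],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Generate DNA barcodes with a minimum pairwise Hamming distance
#'
#' Seeded random sampling with greedy rejection: a candidate barcode is
#' accepted iff its Hamming distance to every previously accepted barcode is
#' at least `min_hamming`.  For small sequence spaces (<= 4^8) candidates
#' are a seeded permutation of the full enumeration, so the search is
#' exhaustive; for longer barcodes candidates are sampled.  If `count`
#' barcodes cannot be found the result carries a shortfall flag rather than
#' failing.
#'
#' Requests beyond the Singleton bound 4^(length - min_hamming + 1) are
#' impossible for any code and are flagged immediately.
#'
#' @param length_nt barcode length in nucleotides.
#' @param min_hamming minimum pairwise Hamming distance.
#' @param count number of barcodes requested.
#' @param seed RNG seed.
#' @param max_attempts sampling attempts for large spaces.
#' @return list with `barcodes`, `shortfall` (logical), `requested`,
#'   `found`, and `message`.
#' @export
generate_barcodes <- function(length_nt, min_hamming, count, seed = 1,
                              max_attempts = 200 * count) {
  stopifnot(min_hamming >= 1, min_hamming <= length_nt, count >= 1)
  singleton <- 4^(length_nt - min_hamming + 1)
  if (count > singleton) {
    res <- generate_barcodes(length_nt, min_hamming,
                             count = floor(singleton), seed = seed)
    res$requested <- as.integer(count)
    res$shortfall <- TRUE
    res$message <- sprintf(
      "requested %d barcodes exceeds the Singleton bound 4^(%d - %d + 1) = %g",
      count, length_nt, min_hamming, singleton)
    return(res)
  }
  accepted <- character(0)
  acc_mat <- NULL  # accepted barcodes as an integer matrix for fast distance
  add <- function(cand) {
    v <- utf8ToInt(cand)
    if (!is.null(acc_mat)) {
      d <- rowSums(acc_mat != matrix(v, nrow = nrow(acc_mat),
                                     ncol = length(v), byrow = TRUE))
      if (any(d < min_hamming)) return(FALSE)
    }
    acc_mat <<- rbind(acc_mat, v)
    accepted <<- c(accepted, cand)
    TRUE
  }
  with_seed(seed, {
    if (4^length_nt <= 65536) {
      # exhaustive: greedy pass in lexicographic order.  For Hamming-metric
      # codes the lexicographic greedy (lexicode) construction reaches far
      # larger codes than random-order greedy -- e.g. the perfect 64-word
      # [5,3]-code at distance 3, where random orders stall near 30.  The
      # seed only shuffles which of the accepted words are returned.
      grid <- expand.grid(rep(list(DNA_ALPHABET), length_nt),
                          stringsAsFactors = FALSE)[, length_nt:1, drop = FALSE]
      full <- sort(do.call(paste0, grid))
      for (cand in full) {
        add(cand)
        if (length(accepted) >= count) break
      }
      accepted <- sample(accepted)
    } else {
      attempts <- 0
      while (length(accepted) < count && attempts < max_attempts) {
        attempts <- attempts + 1
        add(random_dna(1, length_nt))
      }
    }
  })
  shortfall <- length(accepted) < count
  list(barcodes = accepted,
       shortfall = shortfall,
       requested = as.integer(count),
       found = length(accepted),
       message = if (shortfall)
         sprintf("found %d of %d requested barcodes", length(accepted), count)
       else "ok")
}

#' Audit a barcode set against a minimum pairwise Hamming distance
#'
#' Exhaustive pairwise check, usable as an independent oracle on any
#' barcode-generation output.
#'
#' @param barcodes character vector of equal-length DNA strings.
#' @param min_hamming required minimum distance.
#' @return TRUE if every pair is at distance >= `min_hamming`.
#' @export
audit_barcodes <- function(barcodes, min_hamming) {
  n <- length(barcodes)
  if (n < 2) return(TRUE)
  if (length(unique(nchar(barcodes))) != 1)
    stop("barcodes must have equal length")
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (hamming(barcodes[i], barcodes[j]) < min_hamming) return(FALSE)
    }
  }
  TRUE
}

#' Generate 15-nt cassette barcodes
#'
#' Each 15-mer is a unique permutation of three words from a 5-mer code with
#' minimum pairwise Hamming distance 3; uniqueness is enforced at the
#' 15-mer level.
#'
#' @param n number of 15-mers required.
#' @param seed RNG seed.
#' @return character vector of `n` distinct 15-nt barcodes.
#' @export
generate_pair_barcodes <- function(n, seed = 1) {
  words <- generate_barcodes(5, 3, count = 48, seed = seed)$barcodes
  k <- length(words)
  if (k^3 < n) stop("5-mer code too small for ", n, " triples")
  with_seed(seed + 1, {
    out <- character(0)
    while (length(out) < n) {
      need <- n - length(out)
      cand <- paste0(sample(words, 2 * need + 10, replace = TRUE),
                     sample(words, 2 * need + 10, replace = TRUE),
                     sample(words, 2 * need + 10, replace = TRUE))
      out <- unique(c(out, cand))
    }
    out[seq_len(n)]
  })
}

#' Assemble a dual-guide oligo from two guides and a 15-nt barcode
#'
#' The synthesized oligo places the position-1 spacer, the cassette barcode
#' and the position-2 spacer between fixed scaffold segments; total length
#' is 130 nt.
#'
#' @param g1,g2 rows of a guide library (lists/data frames with `guide_id`
#'   and `spacer`) or plain spacer strings with names.
#' @param barcode15 15-nt DNA barcode, unique per oligo.
#' @return list with `g1`, `g2`, `barcode15`, `oligo`.
#' @export
assemble_oligo <- function(g1, g2, barcode15) {
  s1 <- if (is.list(g1)) g1$spacer else g1
  s2 <- if (is.list(g2)) g2$spacer else g2
  id1 <- if (is.list(g1)) g1$guide_id else names(g1) %||% s1
  id2 <- if (is.list(g2)) g2$guide_id else names(g2) %||% s2
  if (identical(id1, id2) || identical(s1, s2))
    stop("identical guides in a pair are excluded from the design")
  if (nchar(barcode15) != BARCODE_LENGTH || !is_dna(barcode15))
    stop("barcode must be ", BARCODE_LENGTH, " nt of uppercase DNA")
  stopifnot(nchar(s1) == SPACER_LENGTH, nchar(s2) == SPACER_LENGTH)
  list(g1 = id1, g2 = id2, barcode15 = barcode15,
       oligo = paste0(OLIGO_5P, s1, OLIGO_LINKER1, barcode15,
                      OLIGO_LINKER2, s2, OLIGO_3P))
}

#' Parse an assembled oligo back into (spacer1, barcode, spacer2)
#'
#' Inverse of [assemble_oligo()] under the scaffold grammar.
#' @param oligo assembled oligo string.
#' @return list with `spacer1`, `barcode15`, `spacer2`.
#' @export
parse_oligo <- function(oligo) {
  pat <- paste0("^", OLIGO_5P, "([ACGT]{20})", OLIGO_LINKER1,
                "([ACGT]{15})", OLIGO_LINKER2, "([ACGT]{20})", OLIGO_3P, "$")
  m <- regmatches(oligo, regexec(pat, oligo))[[1]]
  if (length(m) != 4) stop("oligo does not match the scaffold grammar")
  list(spacer1 = m[2], barcode15 = m[3], spacer2 = m[4])
}

#' Build the full oligo pool for a library
#'
#' @param library a [guide_library()].
#' @param seed RNG seed for barcode generation.
#' @return data frame with columns `g1`, `g2`, `barcode`, `oligo`.
#' @export
build_oligo_pool <- function(library, seed = 1) {
  pairs <- enumerate_pairs(library)
  bc <- generate_pair_barcodes(nrow(pairs), seed = seed)
  spacer <- stats::setNames(library$spacer, library$guide_id)
  oligo <- paste0(OLIGO_5P, spacer[pairs$g1], OLIGO_LINKER1, bc,
                  OLIGO_LINKER2, spacer[pairs$g2], OLIGO_3P)
  data.frame(g1 = pairs$g1, g2 = pairs$g2, barcode = bc, oligo = oligo,
             stringsAsFactors = FALSE)
}

#' Build the two-position alignment reference
#'
#' One contig per (spacer position, guide): the spacer flanked by the
#' constant cassette context seen by read 1 (position 1) or read 2
#' (position 2).  A 112-guide library yields 224 contigs.
#'
#' @param library a [guide_library()].
#' @return a `position_reference`: list with `contigs` (named character
#'   vector, names `"pos{1|2}|{guide_id}"`) and `library`.
#' @export
build_reference <- function(library) {
  stopifnot(inherits(library, "guide_library"))
  pos1 <- paste0(READ1_5P, library$spacer, READ1_3P)
  pos2 <- paste0(READ2_5P, library$spacer, READ2_3P)
  contigs <- c(stats::setNames(pos1, paste0("pos1|", library$guide_id)),
               stats::setNames(pos2, paste0("pos2|", library$guide_id)))
  structure(list(contigs = contigs, library = library),
            class = "position_reference")
}

#' Write a position reference as FASTA
#' @param reference a [build_reference()] result.
#' @param path output path.
#' @export
write_reference_fasta <- function(reference, path) {
  stopifnot(inherits(reference, "position_reference"))
  x <- Biostrings::DNAStringSet(reference$contigs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
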