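---
title: "Methods: combinatorial CRISPR interaction scoring and single-cell cell-cycle phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combinatorial CRISPR interaction scoring and single-cell cell-cycle phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the models behind `cdkperturb`, the parameter
choices that matter, what the bundled simulators do and do not emulate,
and the numerical decisions taken where the design was genuinely open.
It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

# Dual-guide library combinatorics

A dual-guide library over *n* single guides synthesizes every ordered
pair of distinct guides: both (a, b) and (b, a) are separate constructs,
so the pool has *n(n−1)* members (12,432 for the 112-guide design of 26
target genes × 4 guides plus 4 non-targeting and 4 AAVS1 safe-harbor
controls). Each oligo places the position-1 spacer, a 15-nt cassette
barcode and the position-2 spacer between fixed scaffold segments
(130 nt total); `parse_oligo()` inverts `assemble_oligo()` exactly, and
that round trip is a tested invariant.

Cassette barcodes guard against uncoupling of the two spacers by
abortive PCR. They are built as permutations of three words from a 5-mer
code with minimum pairwise Hamming distance 3. `generate_barcodes()`
constructs such codes greedily: for spaces that can be enumerated
(≤ 4^8) the greedy pass runs in *lexicographic* order — the classic
lexicode construction — because random-order greedy acceptance stalls
far below the attainable code size at these parameters, while the
lexicographic pass attains the maximum 64-word code for length 5,
distance 3 (the sequence space is 4^5 = 1024; the Singleton bound is
4^(5−3+1) = 64). For longer barcodes, seeded random sampling with greedy
rejection is used. Requests beyond the Singleton bound
4^(length − d + 1) are flagged as shortfalls immediately; in all cases
the returned set can be audited independently with `audit_barcodes()`,
an exhaustive pairwise check. A request for more barcodes than any code
of the stated distance can contain is reported as a shortfall rather
than an error, so callers can decide how to degrade.

# Guide-pair counting

Reads follow the sequencing cassette layout: a constant 5′ anchor, the
20-nt spacer, and constant 3′ context, different for the two positions.
`match_read()` compares the read's spacer window against every library
spacer by Levenshtein distance, taking for each spacer the minimum over
window lengths 18–22 so that up to two insertions or deletions inside
the spacer are scored at their true edit distance. A read is assigned to
the unique closest guide at distance ≤ 2 ("less than 3"); ties at the
minimal distance are rejected as ambiguous rather than broken
arbitrarily, because near-homologous spacers against the same gene
family make silent misassignment the worse failure mode. A mate pair
contributes a count only if both mates are assigned and the ordered
(g1, g2) pair exists in the library; rejection reasons (too distant,
ambiguous, too short, unexpected pair, orphan mate) are tallied so that
assigned + rejected always equals the input count.

# Interaction scoring

Within a sample, relative abundance is
`x = log2((M + c) / Σ(M + c))` with pseudocount `c = 1` (zero counts
stay finite; `Σ 2^x = 1` holds by construction). Fold change is
`m_t = x_t − x_t0` against the baseline of the same replicate, and
fitness is the z-standardization of `m_t` over all constructs in the
same (timepoint, replicate), using the population (divisor *n*)
standard deviation. Standardization is per replicate by default;
`pool_replicates = TRUE` pools them.

Under the additive (log-scale multiplicative) null,
`f_{g1g2} = f_{g1} + f_{g2} + π_{g1g2}` with interactions rare and
centered on zero. Summing over the constructs containing a guide and
dropping the interaction sum yields one linear equation per guide; the
stacked system is solved exactly. Both construct orders enter as
independent observations; for incomplete tables each row uses the
observed degree and partner sums, which preserves the derivation row by
row. For a complete symmetric table this is the textbook system
`((N−2)I + J)·x = rowsums`, and the implementation is tested against a
generic dense solve of that system to 1e−10, plus the exact closed-form
case `F_ij = a_i + a_j → x = a, π ≡ 0`.

Gene-level scores average π over all guide combinations and both orders
(32 values at 4 guides/gene). Same-gene aggregates — two guides against
one gene — are excluded by default: they measure double-cutting burden
rather than an interaction between two genes, and because they pool
only 4 × 3 = 12 ordered combinations their variance is ~2.7× that of a
proper gene pair, which would inflate the z-normalization denominator
for everything else. Scores are z-normalized per (timepoint, replicate)
over gene pairs, median-combined across samples, and the median is
itself z-rescaled across gene pairs before calling: the median of
several partially correlated z-scores is compressed toward zero by an
amount that depends on the sample count and noise structure, so without
the rescale a fixed threshold would mean different stringencies for
different designs. For a single sample the rescale is the identity. The
default call threshold is |z| ≥ 2 (negative = synthetic-sick/lethal,
positive = synergistic); the threshold is a tunable, not an estimate,
because the underlying screen literature does not fix one. Cell lines
can be pooled as replicates before scoring ("pan" mode) by relabeling.

# Cell-cycle phenotyping

Per-cell phase scores `E_ik` are means of normalized expression over the
five phase marker sets; the pan-phase profile `E_i` is the expression
vector over the union of all marker genes. Coarse classification is the
argmax over phases with ties broken in the canonical order M → M/G1 →
G1/S → S → G2/M. Cells are embedded by classical multidimensional
scaling (`stats::cmdscale`) of `1 − cosine similarity` between pan-phase
profiles; classical MDS is used rather than iterative stress
majorization because it is deterministic, exact for this purpose, and
standard in the R ecosystem. Cartesian coordinates become polar
(r, Θ ∈ [0, 2π)).

The embedding's orientation is arbitrary, so it is canonicalized:
reflected so that the circular means of the coarse phase labels advance
counter-clockwise in canonical order (chosen as the reflection whose
consecutive phase-mean gaps sum to one full turn), then rotated so the
circular mean of M/G1-labeled cells sits at the midpoint of the default
M/G1 arc. Angular bins (default 60, i.e. 6°) take the modal coarse
label, with empty bins inheriting the nearest non-empty bin's label
circularly; a cell's assigned phase is its bin's label.

Association between an inferred angle and a reference uses the
Fisher–Lee T-linear circular correlation in its pairwise form
(`Σ_{i<j} sin(a_i − a_j) sin(b_i − b_j)`, normalized). The
mean-direction-centered variant is unusable here: an asynchronous
population has angles nearly uniform on the circle, its mean direction
is undefined, and that estimator then returns arbitrary values.

**Kuiper test.** Knockout-vs-control shifts in phase density are tested
with the two-sample Kuiper statistic `V = max(F1 − F2) + max(F2 − F1)`
on circular ECDFs, which is invariant to common rotations. The p-value
uses the asymptotic series `P = 2 Σ_j (4j²λ² − 1) e^{−2j²λ²}` with
Stephens' effective-sample-size factor
`λ = (√n_e + 0.155 + 0.24/√n_e)·V'`, `n_e = n1·n2/(n1+n2)`, where `V'`
adds half of the mean ECDF lattice step `(1/n1 + 1/n2)/4`. The
continuity term was calibrated against a large simulated exact null of
the statistic itself (not against any external target): without it the
series is visibly conservative at n ≈ 200. Below min(n1, n2) = 20 the
test switches to a seeded permutation null.

**Signal removal.** Each phase score is smoothed over Θ with an
*unpenalized* cyclic cubic regression spline (`mgcv`, `bs = "cc"`,
`fx = TRUE`, k = 10 with knots spanning the circle), and every gene is
residualized on the smoothed scores plus intercept. The unpenalized
basis makes the smoother a projection, and therefore the whole
operation idempotent up to numerical noise — a property penalized or
local smoothers do not have. Smoothed-score columns that come back
numerically constant are dropped from the design; they would otherwise
enter the regression as pure noise directions. Removal is *with respect
to the five smoothed phase-score curves*: residual angular structure
orthogonal to that 5-dimensional function space (for example the exact
peak position of an individual marker within its phase) is deliberately
retained, which matches how the residualization is defined.

**Marker expansion.** For a gene outside the marker sets, the phase
score is its mean Pearson correlation with each set's markers; it is
assigned to its top phase only if (a) its per-marker correlations for
that phase exceed every other phase's by one-sided t-tests, (b) the top
score is positive, and (c) the variance of its five phase scores
exceeds the across-gene mean by 2 standard deviations (the reference
distribution for that threshold is the across-gene distribution of the
per-gene variance of the five scores). Constant genes are excluded
(undefined correlation). Note that on a circle, "anti-correlated with
phase k" usually means "correlated with the antipodal phase", which is
a legitimate assignment; a gene is left unassigned only when no phase
exceeds the others positively.

# Knockout transcriptome effects

QC keeps cells with 200–10,000 expressed genes and ≤ 10% mitochondrial
reads (gene-name prefix `MT-`, configurable), then drops genes seen in
fewer than 3 of the surviving cells — cell filters first, gene filter
second, so the gene filter is evaluated on the post-cell-filter matrix.
Normalization is total-count scaling to the median library size
followed by log(1 + x).

The baseline state is the per-gene median over cells carrying exactly
one AAVS1 guide. Profiles are per-gene median fold changes (differences
on the normalized log scale); their uncertainty comes from a seeded
bootstrap (default B = 1000) that resamples the knockout's cells *and*
the baseline cells within each replicate — the profile is a difference
of two medians, and a bootstrap that ignores baseline noise understates
the spread. Knockout medians are embedded by principal components of
the profile matrix (equivalent to classical MDS of Euclidean
distances), bootstrap replicates are projected onto the same plane, and
the embedding is translated so the baseline sits at the origin. The 95%
confidence contour of a knockout is the Gaussian ellipse of its
projected bootstrap cloud (Mahalanobis radius √χ²₂(0.95)); an ellipse
was chosen over a kernel-density level set because its coverage is
controlled by the cloud's covariance alone, with no bandwidth to pick.

Differential expression is a two-sided Mann–Whitney U test per gene
(normal approximation with tie correction, as in `wilcox.test`) with
Benjamini–Hochberg correction; genes constant across both groups get
p = 1 by convention, and the DE set is q < 0.05. The
perturbation-magnitude-vs-fitness relation correlates (Pearson) each
knockout's profile norm — or its embedding distance from the control,
both offered because the choice is not determined by the problem — with
gene-level fitness from the screen.

# What the simulators emulate

`simulate_screen()` grows constructs exponentially at rate
`f_g1 + f_g2 + π(gene pair)` (log2 per unit screen time; the growth
timescale is fixed at 1 so planted fitness is in the scorer's natural
units), plus a persistent construct-level artifact term
(`pair_noise_sd`, default 0.3): dual-guide cassettes have
construct-specific biases — spacer recombination and abortive-PCR
uncoupling are why such libraries carry barcodes at all — and these are
properties of the pool, shared across timepoints and replicates.
Sampling is multinomial at exactly `depth` reads per sample, so reads
are conserved by construction. `simulate_reads()` emits the paired
cassette layout with iid substitution errors only, keeping edit-distance
expectations analytic. Not emulated: PCR amplification bias, UMI
collisions, chimeric reads, indel sequencing errors (available but off
by default).

`simulate_cells()` draws each cell's latent angle uniformly (controls)
or from a von Mises mixture (knockout-specific arrest), and gives each
of 5 × 120 marker genes a smooth unimodal circular bump
`baseline + amplitude·exp(κ(cos(θ − peak) − 1))` with peaks uniform in
the phase's arc, plus 400 phase-independent background genes; counts
are gamma-Poisson at shallow-droplet depth (marker means of order 1–5).
The marker panel size mirrors the ~600-gene panels used for
transcriptome-based cell-cycle staging. Phase arcs are equal fifths of
the circle: the latent coordinate is transcriptional progression, not
wall-clock time, and with equal-sized marker panels per phase, equal
arcs are the only self-consistent choice — unequal arcs with equal
panels would make marker density per radian uneven and warp the
embedding's angular speed. Consequently, passing recovery tests show
that the pipeline recovers transcriptional phase structure; they say
nothing about mapping angle to clock time, doublets, ambient RNA, or
partially cycling populations.

`simulate_ko_expression()` plants per-knockout DE programs that are
half up- and half down-regulated and mass-balanced (greedily, by
expected library mass), with the mean vector rescaled to constant total:
droplet assays measure composition, and an unbalanced program shifts
every null gene through total-count normalization — a real biological
phenomenon (global transcription shutdown) that is deliberately out of
scope here because it would make "null gene" ill-defined. DE genes are
drawn from genes above a 0.5 counts/cell detectability floor, since
shifts below the detection limit are unrecoverable by any method and
only dilute benchmarks. The optional shared-program mode makes knockout
profiles colinear (nested response with scaling magnitude), the regime
in which a 2-D embedding can represent the profiles faithfully.

`simulate_exon_coverage()` gives NTC samples uniform expected coverage
across each gene's exons and multiplies the First exon's expectation by
`2^bias` for biased (knockout, gene) pairs, with Poisson sampling and a
matching single-transcript-per-gene GTF on alternating strands. It does
not emulate length-dependent coverage, 3′ capture bias of droplet
protocols, or multi-isoform mixtures beyond the classification test
cases.

# 5′ coverage bias

Exon categories are assigned per gene, strand-aware: First is the
single 5′-most transcript-initial exon, AlternativeFirst the other
transcript-initial exons, Last the 3′-most transcript-terminal exon,
AlternativeLast the remaining terminal exons, Internal the rest; exons
shared verbatim between transcripts are single records, and conflicts
resolve by the priority First > Last > AlternativeFirst >
AlternativeLast > Internal. Coordinates are kept 1-based inclusive as
read from the GTF; overlap counting (`≥ 1 bp`, strand-aware, a read
spanning two exons counts for both) is delegated to
`GenomicRanges::countOverlaps` and tested against a brute-force
interval oracle.

Genes with fewer than 10 assigned reads in a sample are dropped from
that sample; counts are normalized to reads per million of all assigned
reads and log2-transformed with a pseudocount of 1 RPM unit (the
pseudocount choice is not dictated by the problem; 1 keeps the zero
point finite and the top of the scale unchanged). Enrichment of a
knockout over NTC is the difference of mean log2 RPM values; the 5′
bias is enrichment(First) − enrichment(Last) — the log2 of the ratio of
linear fold enrichments, kept as a difference so the statistic is
symmetric and finite. An NTC-labeled contrast is therefore identically
zero, a tested invariant. The transcriptome-wide first-exon shift test
is a t-test of per-gene First-exon enrichments against the AAVS1
reference knockout by default (against zero on request; the reference
population is genuinely ambiguous, so both are offered). Bias patterns
across knockouts are clustered by complete-linkage hierarchical
clustering of Euclidean distances, cut into 12 groups by default, and
cluster gene lists feed a local Fisher-exact enrichment against
GMT-format gene sets with BH correction.

# Numerical choices and degenerate inputs

- Population (divisor *n*) standard deviations are used for every
  z-standardization, matching the definition of a z-score over the
  whole standardization population.
- Zero-variance situations raise errors rather than silently producing
  NaN: all-zero count samples, constant fold changes, constant gene
  scores, identical perturbation magnitudes.
- Argmax ties (coarse phase, bin mode) break to the canonical phase
  order; read-assignment ties are rejected as ambiguous.
- The imputation system requires N ≥ 3 guides (interaction separation
  is underdetermined below that) and every guide to appear in at least
  one observed pair.
- `ellipse_covers()` and the contours use the χ²₂ quantile of the
  Mahalanobis distance; bootstrap clouds of medians are close enough to
  Gaussian at the cell numbers involved for this to be calibrated, and
  the calibration is itself measured by a 500-run coverage experiment
  in the acceptance suite.
- Problem sizes in the test and acceptance suites (2,000-cell
  embeddings, depth-10⁶ screens over 20 genes, 1,000-trial Kuiper
  nulls, 500-run coverage experiments, 10⁴-read coverage genes) were
  chosen as the smallest scales at which the statistical claims under
  test are identifiable with comfortable Monte Carlo margins.

# Known limitations

- The interaction call threshold (|z| ≥ 2) is a convention, not an
  error-controlled decision rule; hit counts therefore depend on it and
  are not comparable across thresholds.
- Strongly depleted constructs saturate at zero reads; with the
  pseudocount this censors their fitness and biases their π upward.
  The effect is visible in extreme-fitness simulations and is inherent
  to count-based fitness estimation, not specific to this
  implementation.
- The cell-cycle embedding recovers angular order and phase arcs, not
  absolute time; its orientation canonicalization depends on M/G1 cells
  being present and reasonably classified.
- Cell-cycle removal eliminates the component of expression explained
  by the five smoothed phase scores; sharper angular structure escapes
  the projection by construction.
- The Gaussian-ellipse contours assume approximately elliptical
  bootstrap clouds; for very small cell numbers (< ~30) the median
  bootstrap becomes lumpy and coverage degrades.
- The marker-expansion t-test treats per-marker correlations as
  independent observations, which overstates confidence when markers
  are strongly co-expressed; the variance gate is the primary guard.
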