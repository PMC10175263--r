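test_that("phase scores are marker means and the pan profile their union", {
  sets <- phase_gene_sets(list(M = c("g1", "g2"), "M/G1" = "g3",
                               "G1/S" = "g4", S = "g5", "G2/M" = "g6"))
  expr <- matrix(c(2, 4, 1, 0, 0, 0), nrow = 1,
                 dimnames = list("c1", paste0("g", 1:6)))
  expr <- expr[rep(1, 3), ]
  sc <- phase_scores(expr, sets)
  expect_equal(unname(sc$E_phase[1, "M"]), 3)  # mean of (2, 4)
  expect_equal(ncol(sc$E_pan), 6)
  # permutation invariance of the mean
  sc2 <- phase_scores(expr[, 6:1], sets)
  expect_equal(sc2$E_phase[, colnames(sc$E_phase)], sc$E_phase)
  # all-zero cell scores zero
  expr0 <- expr; expr0[2, ] <- 0
  expect_true(all(phase_scores(expr0, sets)$E_phase[2, ] == 0))
  # absent phase errors
  expect_error(phase_scores(expr[, 1:5], sets), "G2/M")
})

test_that("coarse classification is an argmax with canonical tie-break", {
  E <- rbind(c(M = 1, "M/G1" = 0, "G1/S" = 0, S = 3, "G2/M" = 2),
             c(M = 1, "M/G1" = 1, "G1/S" = 1, S = 1, "G2/M" = 1))
  expect_equal(coarse_classify(E), c("S", "M"))
})

test_that("guide-free phase sets reject duplicated or empty sets", {
  expect_error(phase_gene_sets(list(M = "a", "M/G1" = "a")), "at most one")
  expect_error(phase_gene_sets(list(M = character(0))), "non-empty")
})

test_that("cosine distances and polar conversion behave at the extremes", {
  # identical, orthogonal and anti-parallel profiles
  E <- rbind(c(1, 0), c(2, 0), c(0, 1), c(-1, 0))
  U <- E / sqrt(rowSums(E^2))
  D <- 1 - tcrossprod(U)
  expect_equal(D[1, 2], 0)
  expect_equal(D[1, 3], 1)
  expect_equal(D[1, 4], 2)
  # polar identity: Cartesian (0, 1) -> (r, theta) = (1, pi/2)
  expect_equal(atan2(1, 0) %% (2 * pi), pi / 2)
  expect_equal(sqrt(0^2 + 1^2), 1)
  # embed_cells guards
  expect_error(embed_cells(matrix(1, 5, 3), rep("M", 5)), "at least 10")
  Ez <- matrix(1, 12, 3); Ez[1, ] <- 0
  expect_error(embed_cells(Ez, rep("M", 12)), "all-zero")
  expect_error(embed_cells(matrix(1, 12, 3), rep("M", 12)), "degenerate")
})

test_that("embedding recovers the planted circular coordinate and phase arcs", {
  tr <- cell_sim_truth(n_cells = 800, seed = 11)
  sim <- simulate_cells(tr)
  expr <- normalize_counts(sim$counts)
  cc <- cellcycle_embed(expr, sim$sets)
  al <- align_angles(cc$embedding$theta, sim$cells$theta_true)
  expect_gt(al$cor, 0.9)
  # low-noise cells classify to their true phase most of the time
  expect_gt(mean(cc$coarse == sim$cells$phase_true), 0.8)
  # each phase occupies one contiguous arc on a clean simulation
  n_arcs <- vapply(cc$ranges$merged_ranges, nrow, integer(1))
  expect_true(all(n_arcs == 1))
  # canonical orientation: phases advance counter-clockwise in order
  mids <- vapply(cdkperturb:::PHASES, function(p)
    cdkperturb:::circ_mean(cc$embedding$theta[cc$coarse == p]), numeric(1))
  gaps <- diff(c(mids, mids[1])) %% (2 * pi)
  expect_equal(sum(gaps), 2 * pi, tolerance = 1e-6)
})

test_that("angular range assignment takes bin modes and fills empty bins", {
  theta <- c(0.1, 0.15, 0.2, 3.2, 3.25)
  coarse <- c("S", "S", "M", "G1/S", "G1/S")
  rng <- assign_phase_ranges(theta, coarse, n_bins = 8)
  # first bin holds {S, S, M} -> S
  expect_equal(rng$bins$label[1], "S")
  expect_equal(rng$phase_assigned[1:3], rep("S", 3))
  # all bins labeled (empty ones inherit nearest neighbor)
  expect_false(any(is.na(rng$bins$label)))
  # all cells labeled S -> every bin S
  rngS <- assign_phase_ranges(theta, rep("S", 5), n_bins = 8)
  expect_true(all(rngS$bins$label == "S"))
  expect_error(assign_phase_ranges(theta, coarse, n_bins = 3), "n_bins")
})

test_that("Kuiper V is rotation invariant and p is calibrated", {
  set.seed(31)
  a <- runif(150, 0, 2 * pi); b <- runif(150, 0, 2 * pi)
  v0 <- kuiper_test(a, b)$V
  for (rot in c(0.7, 2.9, 5.1)) {
    expect_equal(kuiper_test((a + rot) %% (2 * pi),
                             (b + rot) %% (2 * pi))$V, v0)
  }
  # identical samples: V at its minimum, p ~ 1
  same <- kuiper_test(a, a)
  expect_lt(same$V, 2 / 150 + 1e-12)
  expect_gt(same$p, 0.95)
  expect_error(kuiper_test(a[1:3], b), "at least 5")
})

test_that("Kuiper asymptotic p matches a permutation oracle on separated samples", {
  set.seed(17)
  x <- runif(400, 0, 2 * pi)
  y <- cdkperturb:::rvonmises(400, pi, 1.5)
  asym <- kuiper_test(x, y, method = "asymptotic")
  perm <- kuiper_test(x, y, method = "permutation", n_perm = 2000, seed = 5)
  expect_lt(asym$p, 0.001)
  expect_lt(perm$p, 0.001)
  # and on a null pair the two methods agree within Monte Carlo error
  z1 <- runif(100, 0, 2 * pi); z2 <- runif(100, 0, 2 * pi)
  pa <- kuiper_test(z1, z2, method = "asymptotic")$p
  pp <- kuiper_test(z1, z2, method = "permutation", n_perm = 4000, seed = 6)$p
  expect_lt(abs(pa - pp), 0.08)
})

test_that("small samples fall back to a seeded permutation null", {
  set.seed(8)
  a <- runif(12, 0, 2 * pi); b <- runif(12, 0, 2 * pi)
  k1 <- kuiper_test(a, b, seed = 3)
  expect_equal(k1$method, "permutation")
  expect_identical(k1$p, kuiper_test(a, b, seed = 3)$p)
})

test_that("knockout phase-density distortions are detected against controls", {
  ko <- data.frame(gene = "CDK2", n_cells = 500, target_phase = "G1/S",
                   kappa_shift = 2, weight = 0.6)
  tr <- cell_sim_truth(n_cells = 1000, knockouts = ko, seed = 21)
  sim <- simulate_cells(tr)
  cc <- cellcycle_embed(normalize_counts(sim$counts), sim$sets)
  ctrl <- sim$cells$ko == "control"
  kt <- kuiper_test(cc$embedding$theta[!ctrl], cc$embedding$theta[ctrl])
  expect_lt(kt$p, 0.001)
  # the enriched arc is the planted one: the knockout's modal assigned
  # phase matches the target
  mode_phase <- names(which.max(table(cc$embedding$phase_assigned[!ctrl])))
  expect_equal(mode_phase, "G1/S")
})

test_that("cell-cycle removal strips marker structure, keeps background, and is idempotent", {
  tr <- cell_sim_truth(n_cells = 800, seed = 12)
  sim <- simulate_cells(tr)
  expr <- normalize_counts(sim$counts)
  cc <- cellcycle_embed(expr, sim$sets)
  res <- remove_cellcycle_signal(expr, cc$scores$E_phase, cc$embedding$theta)
  sm <- attr(res, "smoothed_scores")
  set.seed(2)
  mk <- sample(unlist(sim$sets), 25)
  bg <- sample(grep("^BG", colnames(expr), value = TRUE), 25)
  # residuals carry no variance explainable by the smoothed phase scores
  ve_sm <- vapply(mk, function(g)
    summary(stats::lm(res[, g] ~ sm))$r.squared, numeric(1))
  expect_lt(max(ve_sm), 0.05)
  # and markers lose most of their free-angle structure
  ve_theta <- function(M, g) {
    th <- cc$embedding$theta
    f <- mgcv::gam(M[, g] ~ s(th, bs = "cc", k = 10, fx = TRUE),
                   knots = list(th = seq(0, 2 * pi, length.out = 10)))
    1 - stats::var(stats::residuals(f)) / stats::var(M[, g])
  }
  pre <- vapply(mk, function(g) ve_theta(expr, g), numeric(1))
  post <- vapply(mk, function(g) ve_theta(res, g), numeric(1))
  expect_lt(mean(post), mean(pre) / 3)
  # background genes pass through nearly unchanged
  cors <- vapply(bg, function(g) stats::cor(res[, g], expr[, g]), numeric(1))
  expect_gt(min(cors), 0.95)
  # idempotency
  sc2 <- phase_scores(res, sim$sets)
  res2 <- remove_cellcycle_signal(res, sc2$E_phase, cc$embedding$theta)
  expect_lt(norm(res2 - res, "F") / norm(res, "F"), 1e-6)
  # constant gene -> zero-centered constant residual
  e2 <- cbind(expr, CONST = 3)
  r2 <- remove_cellcycle_signal(e2, cc$scores$E_phase, cc$embedding$theta)
  expect_equal(unname(range(r2[, "CONST"])), c(0, 0), tolerance = 1e-10)
})

test_that("marker expansion assigns correlated genes and rejects noise", {
  tr <- cell_sim_truth(n_cells = 800, seed = 4)
  sim <- simulate_cells(tr)
  expr <- normalize_counts(sim$counts)
  set.seed(2)
  clone <- expr[, sim$sets$S[1]] + rnorm(nrow(expr), 0, 0.3)
  e2 <- cbind(expr, SCLONE = clone)
  em <- expand_markers(e2, sim$sets)
  expect_equal(em$assigned[em$gene == "SCLONE"], "S")
  # independent background genes: false-assignment rate under 5%
  bg <- grepl("^BG", em$gene)
  expect_lt(mean(!is.na(em$assigned[bg])), 0.05)
  # constant genes are excluded
  e3 <- cbind(expr, CONST = 1)
  em3 <- expand_markers(e3, sim$sets)
  expect_false("CONST" %in% em3$gene)
})

test_that("genes negatively correlated with every phase are never assigned", {
  # discrete-group construction where all five phase scores go negative:
  # markers peak in groups 1..5, the candidate peaks in group 6 only
  set.seed(9)
  n_per <- 30
  grp <- rep(1:6, each = n_per)
  mk_names <- paste0("mk", 1:10)
  expr <- sapply(rep(1:5, each = 2), function(k)
    as.numeric(grp == k) + rnorm(length(grp), 0, 0.1))
  colnames(expr) <- mk_names
  cand <- as.numeric(grp == 6) + rnorm(length(grp), 0, 0.1)
  expr <- cbind(expr, ANTI = cand)
  sets <- phase_gene_sets(list(M = mk_names[1:2], "M/G1" = mk_names[3:4],
                               "G1/S" = mk_names[5:6], S = mk_names[7:8],
                               "G2/M" = mk_names[9:10]))
  em <- expand_markers(expr, sets, var_sd_cut = -10)  # variance gate open
  expect_true(is.na(em$assigned[em$gene == "ANTI"]))
})

test_that("zero marker amplitude leaves coarse classes near uniform", {
  tr <- cell_sim_truth(n_cells = 1000, amplitude = 0, seed = 5)
  sim <- simulate_cells(tr)
  sc <- phase_scores(normalize_counts(sim$counts), sim$sets)
  tab <- table(factor(coarse_classify(sc$E_phase),
                      levels = cdkperturb:::PHASES)) / 1000
  expect_true(all(tab > 0.1 & tab < 0.35))
})

test_that("cell simulator is deterministic and marker bumps peak in phase arcs", {
  tr <- cell_sim_truth(n_cells = 60, seed = 33)
  expect_identical(simulate_cells(tr)$counts, simulate_cells(tr)$counts)
  # planted marker peaks lie inside their phase's angular range
  b <- tr$phase_boundaries
  pr <- tr$programs
  for (p in cdkperturb:::PHASES) {
    i <- match(p, cdkperturb:::PHASES)
    pk <- pr$peak[pr$phase == p]
    expect_true(all(pk >= b[i] & pk <= b[i + 1]))
  }
  expect_error(cell_sim_truth(n_cells = 5), "n_cells")
})
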