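# Cross-dataset comparison: similarity, RBH graph, clusters, regression.

test_that("component similarity is |Pearson r| with sign and identity invariances", {
  set.seed(14)
  u <- setNames(rnorm(100), sprintf("g%03d", 1:100))
  expect_equal(component_similarity(u, u), 1)
  expect_equal(component_similarity(u, -u), 1)
  # orthogonalized pair is near zero
  u2 <- setNames(rnorm(1000), sprintf("g%04d", 1:1000))
  v2 <- setNames(resid(lm(rnorm(1000) ~ u2)), names(u2))
  expect_lt(component_similarity(u2, v2), 0.1)
  expect_equal(component_similarity(u2, v2), abs(cor(u2, v2)),
               tolerance = 1e-12)
  expect_error(component_similarity(u[1:2], u[1:2]), "3 shared genes")
  expect_error(component_similarity(setNames(rep(1, 10), names(u)[1:10]),
                                    u[1:10]), "zero-variance")
})

test_that("identical decompositions produce a perfect RBH matching", {
  gt <- tiny_truth(n_components = 3, n_genes = 200, gpc = c(8, 15))
  d <- centered_dataset(gt, noise_sd = 0, seed = 5)
  dec <- run_robust_ica(d$x, n_runs = 5, n_repetitions = 2,
                        min_members = 3, seed = 7)
  g <- build_rbh_graph(list(A = dec, B = dec))
  expect_identical(nrow(g$edges), 3L)
  expect_equal(g$edges$similarity, rep(1, 3), tolerance = 1e-12)
  expect_identical(g$edges$comp_a, g$edges$comp_b)
})

test_that("twin datasets sharing true_S recover the planted correspondence; dataset-specific components stay unlinked", {
  gt <- make_ground_truth(600, 5, c(10, 25), n_conditions = 10,
                          replicates = 3, seed = 21)
  dA <- centered_dataset(gt, "A", noise_sd = 0.05, seed = 31,
                         gene_subset_fraction = 0.8)
  dB <- centered_dataset(dA$gt, "B", noise_sd = 0.05, seed = 32,
                         gene_subset_fraction = 0.8)
  decA <- run_robust_ica(dA$x, n_runs = 10, n_repetitions = 3,
                         min_members = 5, seed = 41)
  decB <- run_robust_ica(dB$x, n_runs = 10, n_repetitions = 3,
                         min_members = 5, seed = 42)
  g <- build_rbh_graph(list(A = decA, B = decB), prune_threshold = 0.3)
  # ground-truth matching oracle: each estimated component's planted identity
  idA <- match_to_truth(gt$true_S[rownames(decA$S), ], decA$S)
  idB <- match_to_truth(gt$true_S[rownames(decB$S), ], decB$S)
  lookupA <- setNames(idA$truth, idA$est)
  lookupB <- setNames(idB$truth, idB$est)
  agree <- lookupA[g$edges$comp_a] == lookupB[g$edges$comp_b]
  expect_gte(mean(agree), 0.9)
  expect_gte(nrow(g$edges), ceiling(0.9 * 5))

  # RBH symmetry: each node carries at most one edge to the other dataset
  expect_lte(max(table(g$edges$comp_a)), 1L)
  expect_lte(max(table(g$edges$comp_b)), 1L)

  # appending an unrelated component to A only must not create an edge:
  # give A an extra orthogonal weighting absent from B's structure
  extra <- withr::with_seed(77, rnorm(nrow(decA$S), sd = 1))
  extra <- extra - decA$S %*% (t(decA$S) %*% extra)  # orthogonal to A's S
  extra <- extra / sqrt(sum(extra^2))
  decA2 <- decA
  decA2$S <- cbind(decA$S, ICxx = extra)
  g2 <- build_rbh_graph(list(A = decA2, B = decB), prune_threshold = 0.3)
  expect_false("ICxx" %in% g2$edges$comp_a)
})

test_that("sub-threshold mutual best hits are pruned", {
  set.seed(15)
  genes <- sprintf("g%03d", 1:200)
  mk_dec <- function(S) {
    structure(list(S = S, A = NULL), class = "Decomposition")
  }
  a <- scale(rnorm(200))[, 1]
  b0 <- scale(resid(lm(rnorm(200) ~ a)))[, 1]
  b <- 0.2 * a + sqrt(1 - 0.04) * b0   # |rho| = 0.2 with a
  SA <- matrix(a, dimnames = list(genes, "c1"))
  SB <- matrix(b, dimnames = list(genes, "c1"))
  g <- build_rbh_graph(list(A = mk_dec(SA), B = mk_dec(SB)),
                       prune_threshold = 0.3)
  expect_identical(nrow(g$edges), 0L)
})

test_that("cluster tiers follow the dataset-span rules", {
  nodes <- data.frame(
    dataset_id = c("d1", "d2", "d3", "d4", "d5",   # clique, all 5
                   "d1", "d2", "d3",               # chain, 3 of 5
                   "d1", "d1", "d2",               # two nodes from d1
                   "d4"),                          # singleton
    component_id = c(rep("k1", 5), rep("k2", 3), c("k3", "k3b", "k3"), "k4"))
  edges <- data.frame(
    dataset_a = c("d1", "d2", "d3", "d4", "d1", "d2", "d1", "d1"),
    comp_a = c("k1", "k1", "k1", "k1", "k2", "k2", "k3", "k3b"),
    dataset_b = c("d2", "d3", "d4", "d5", "d2", "d3", "d2", "d2"),
    comp_b = c("k1", "k1", "k1", "k1", "k2", "k2", "k3", "k3"),
    similarity = 0.9)
  g <- structure(list(nodes = nodes, edges = edges, prune_threshold = 0.3),
                 class = "RBHGraph")
  cl <- find_clusters(g, n_datasets = 5)
  tier_of <- function(pat) cl$tier[grepl(pat, cl$members)]
  expect_identical(tier_of("d1/k1"), "highly-reproducible")
  expect_identical(tier_of("d1/k2"), "moderately-reproducible")
  expect_identical(tier_of("d1/k3"), "complex")
  expect_identical(tier_of("d4/k4"), "dataset-specific")
})

test_that("overlap coefficient handles identity, disjoint and partial overlap", {
  expect_equal(overlap_coefficient(letters[1:5], letters[1:5]), 1)
  expect_equal(overlap_coefficient(letters[1:5], letters[10:12]), 0)
  expect_equal(overlap_coefficient(letters[1:10], c(letters[1:5], LETTERS[1:10])), 0.5)
  expect_error(overlap_coefficient(character(0), "a"), "empty")
})

test_that("linear-combination fit recovers exact mixtures and rejects unrelated targets", {
  set.seed(16)
  genes <- sprintf("g%04d", 1:1000)
  cand <- matrix(rnorm(1000 * 12), 1000, 12,
                 dimnames = list(genes, sprintf("c%02d", 1:12)))
  target <- setNames(0.6 * cand[, 1] + 0.4 * cand[, 2], genes)
  fit <- fit_linear_combination(target, cand, n_select = 10)
  expect_gt(fit$r_squared, 1 - 1e-10)
  expect_equal(unname(fit$coefficients["c01"]), 0.6, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["c02"]), 0.4, tolerance = 1e-8)
  others <- setdiff(names(fit$coefficients), c("c01", "c02"))
  expect_lt(max(abs(fit$coefficients[others])), 1e-8)
  # cross-check against a direct OLS oracle on the selected design
  Xs <- cbind(1, cand[, fit$selected])
  beta <- oracle_lstsq(Xs, target)
  expect_equal(unname(fit$coefficients), unname(beta[-1]), tolerance = 1e-8)

  # target orthogonalized against every candidate: R^2 ~ 0
  y <- rnorm(1000)
  y_perp <- setNames(resid(lm(y ~ cand)), genes)
  fit0 <- fit_linear_combination(y_perp, cand, n_select = 10)
  expect_lt(fit0$r_squared, 0.05)

  # collinear candidates fall back to a least-norm solution with a warning
  cand2 <- cbind(cand[, 1:3], dup = cand[, 3])
  expect_warning(fit_linear_combination(target, cand2, n_select = 4),
                 "collinear")
})

test_that("merged-activity datasets resolve as a linear combination across datasets", {
  # one dataset renders two components with nearly identical activities so
  # ICA fuses them; the twin dataset keeps them independent
  gt <- make_ground_truth(600, 5, c(15, 25), n_conditions = 10,
                          replicates = 3, seed = 51)
  dM <- render_dataset(gt, "M", noise_sd = 0.05, seed = 61,
                       correlate_pair = c(1, 2))
  xM <- center_to_reference(dM$x, dM$meta)
  dI <- render_dataset(dM$ground_truth, "I", noise_sd = 0.05, seed = 62)
  xI <- center_to_reference(dI$x, dI$meta)

  # the planted activity correlation is >= 0.95 in M, < 0.3 in I
  AM <- dM$ground_truth$true_A_by_dataset[["M"]]
  AI <- dI$ground_truth$true_A_by_dataset[["I"]]
  expect_gte(abs(cor(AM[1, ], AM[2, ])), 0.95)
  expect_lt(abs(cor(AI[1, ], AI[2, ])), 0.3)

  decM <- run_robust_ica(xM, n_runs = 10, n_repetitions = 3,
                         min_members = 5, seed = 71)
  decI <- run_robust_ica(xI, n_runs = 10, n_repetitions = 3,
                         min_members = 5, seed = 72)
  # the merged dataset yields fewer components than planted
  expect_lt(ncol(decM$S), 5L)
  expect_identical(ncol(decI$S), 5L)

  # the fused component of M is a linear combination of two of I's
  fused_truth <- gt$true_S[, 1] + gt$true_S[, 2]
  sim <- abs(cor(fused_truth[rownames(decM$S)], decM$S))
  fused <- colnames(decM$S)[which.max(sim)]
  fit <- fit_linear_combination(setNames(decM$S[, fused], rownames(decM$S)),
                                decI$S, n_select = min(10, ncol(decI$S)))
  expect_gte(fit$r_squared, 0.9)
  dom <- sort(abs(fit$coefficients), decreasing = TRUE)
  expect_gt(dom[2], 3 * max(dom[-(1:2)], 0))
})

test_that("RBH graph export writes edge-list TSV and DOT", {
  gt <- tiny_truth(n_components = 3, n_genes = 200, gpc = c(8, 15))
  d <- centered_dataset(gt, noise_sd = 0, seed = 5)
  dec <- run_robust_ica(d$x, n_runs = 5, n_repetitions = 2,
                        min_members = 3, seed = 7)
  g <- build_rbh_graph(list(A = dec, B = dec))
  dir <- withr::local_tempdir()
  paths <- write_rbh_graph(g, dir)
  expect_true(all(file.exists(paths)))
  edges <- read.delim(paths[1])
  expect_identical(nrow(edges), nrow(g$edges))
  dot <- readLines(paths[2])
  expect_identical(dot[1], "graph rbh {")
})
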