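# Dimension selection, FastICA ensembles, component clustering, consensus.

test_that("dimension selection finds the rank of noiseless data and matches an SVD oracle", {
  gt <- tiny_truth(n_components = 5, n_genes = 400, gpc = c(10, 20))
  d <- centered_dataset(gt, noise_sd = 0, seed = 2)
  expect_identical(select_dimension(d$x), 5L)

  # synthetic singular spectrum: cumulative ratios checked by hand
  u <- qr.Q(qr(matrix(rnorm(100 * 3), 100, 3)))
  v <- qr.Q(qr(matrix(rnorm(12 * 3), 12, 3)))
  sv <- c(10, 1, 0.01)
  x <- em(u %*% diag(sv) %*% t(v), centered = TRUE)
  cum <- cumsum(sv^2) / sum(sv^2)        # 0.99007..., 0.999999...
  expect_identical(select_dimension(x, 0.99), 1L)
  expect_true(cum[1] >= 0.99)
  expect_identical(select_dimension(x, 0.995), 2L)
  expect_identical(select_dimension(x, 1.0), 3L)
  expect_error(select_dimension(em(matrix(0, 5, 4), centered = TRUE)),
               "zero-variance")
})

test_that("ensemble candidates recover planted components and are seed-deterministic", {
  gt <- tiny_truth(n_components = 3, n_genes = 200, gpc = c(10, 20),
                   n_conditions = 6)
  d <- centered_dataset(gt, noise_sd = 0, seed = 5)
  cand <- run_ica_ensemble(d$x, n_dims = 3, n_runs = 10, seed = 17)
  expect_identical(ncol(cand), 30L)
  expect_equal(unname(colSums(cand^2)), rep(1, 30), tolerance = 1e-9)
  # candidates match planted components almost perfectly in the noiseless case
  cc <- abs(cor(gt$true_S, cand))
  matched <- apply(cc, 2, max)
  expect_true(all(matched > 0.99))
  cand2 <- run_ica_ensemble(d$x, n_dims = 3, n_runs = 10, seed = 17)
  expect_identical(cand, cand2)
  expect_error(run_ica_ensemble(d$x, n_dims = 100, n_runs = 2, seed = 1),
               "n_dims")
})

test_that("clustering collapses sign-flipped copies and respects eps / min_members", {
  set.seed(8)
  base <- unit_norm_columns(matrix(rnorm(300 * 3), 300, 3))
  base <- qr.Q(qr(base))                  # orthogonal, so well separated
  copies <- base[, rep(1:3, each = 100)]
  flips <- sample(c(-1, 1), 300, replace = TRUE)
  cand <- sweep(copies, 2, flips, "*") |> unit_norm_columns()
  cl <- cluster_components(cand, eps = 0.1, min_members = 50)
  expect_identical(ncol(cl$centroids), 3L)
  expect_identical(sort(cl$sizes), rep(100L, 3))
  cc <- abs(cor(base, cl$centroids))
  expect_true(all(apply(cc, 1, max) > 0.999))

  # a component present in only 49 of 100 runs is noise at min_members = 50
  rare <- cbind(base[, rep(1, 100)], base[, rep(2, 49)])
  rare <- sweep(rare, 2, sample(c(-1, 1), 149, TRUE), "*")
  cl2 <- cluster_components(rare, eps = 0.1, min_members = 50)
  expect_identical(ncol(cl2$centroids), 1L)
  expect_gt(abs(cor(base[, 1], cl2$centroids[, 1])), 0.999)
})

test_that("two components at |rho| = 0.85 stay separate clusters at eps = 0.1", {
  # construct a pair with exact correlation 0.85: d = 0.15 > eps
  set.seed(11)
  a <- scale(rnorm(500))[, 1]
  b0 <- scale(resid(lm(rnorm(500) ~ a)))[, 1]
  rho <- 0.85
  b <- rho * a + sqrt(1 - rho^2) * b0
  expect_equal(abs(cor(a, b)), 0.85, tolerance = 1e-12)
  cand <- cbind(matrix(a, 500, 60), matrix(b, 500, 60)) |> unit_norm_columns()
  cl <- cluster_components(cand, eps = 0.1, min_members = 50)
  expect_identical(ncol(cl$centroids), 2L)
})

test_that("consensus keeps only components recurring in every repetition", {
  gt <- tiny_truth(n_components = 4, n_genes = 300, gpc = c(10, 20))
  d <- centered_dataset(gt, noise_sd = 0, seed = 3)
  dec <- run_robust_ica(d$x, n_runs = 10, n_repetitions = 3,
                        min_members = 5, seed = 19)
  expect_s3_class(dec, "Decomposition")
  expect_identical(ncol(dec$S), 4L)
  m <- match_to_truth(gt$true_S, dec$S)
  expect_true(all(m$rho >= 0.95))
  # reconstruction on noiseless rank-k data
  err <- norm(d$x$values - dec$S %*% dec$A, "F") / norm(d$x$values, "F")
  expect_lt(err, 1e-6)
  # sign convention: dominant weight of each column is positive
  expect_true(all(apply(dec$S, 2, function(s) s[which.max(abs(s))] > 0)))
  # determinism: the whole consensus is a pure function of (X, config, seed)
  dec2 <- run_robust_ica(d$x, n_runs = 10, n_repetitions = 3,
                         min_members = 5, seed = 19)
  expect_identical(dec$S, dec2$S)
  expect_identical(dec$A, dec2$A)
})

test_that("activity recovery matches least-squares and projection identities", {
  set.seed(23)
  # orthonormal-column S: pinv recovers the planted activities exactly
  S <- qr.Q(qr(matrix(rnorm(100 * 5), 100, 5)))
  A0 <- matrix(rnorm(5 * 12), 5, 12)
  A <- compute_activities(S, S %*% A0)
  expect_lt(max(abs(A - A0)), 1e-10)
  # X orthogonal to the column space of S projects to zero
  x_perp <- resid(lm(rnorm(100) ~ S - 1))
  expect_lt(max(abs(compute_activities(S, matrix(x_perp)))), 1e-10)
  # random full-rank S against an independent least-squares oracle
  S2 <- matrix(rnorm(100 * 5), 100, 5)
  A02 <- matrix(rnorm(5 * 7), 5, 7)
  X2 <- S2 %*% A02
  expect_lt(max(abs(compute_activities(S2, X2) - A02)), 1e-8)
  expect_equal(unname(compute_activities(S2, X2)),
               unname(oracle_lstsq(S2, X2)), tolerance = 1e-8)
  # rank-deficient S proceeds with a warning
  S3 <- cbind(S2, S2[, 1])
  expect_warning(compute_activities(S3, X2), "rank-deficient")
})

test_that("consensus survives appended pure-noise samples", {
  gt <- tiny_truth(n_components = 4, n_genes = 300, gpc = c(10, 20))
  d <- centered_dataset(gt, noise_sd = 0.05, seed = 31)
  v <- d$x$values
  n_noise <- ceiling(0.1 * ncol(v))
  noise <- withr::with_seed(99, matrix(rnorm(nrow(v) * n_noise, sd = 0.5),
                                       nrow(v), n_noise))
  colnames(noise) <- paste0("noise", seq_len(n_noise))
  rownames(noise) <- rownames(v)
  xg <- em(cbind(v, noise), centered = TRUE)
  dec <- run_robust_ica(xg, n_dims = 4, n_runs = 10, n_repetitions = 3,
                        min_members = 5, seed = 19)
  m <- match_to_truth(gt$true_S, dec$S)
  expect_true(all(m$rho >= 0.9))
})

test_that("consensus on a two-dataset compendium is robust to per-gene batch offsets", {
  gt <- tiny_truth(n_components = 4, n_genes = 300, gpc = c(10, 20))
  dA <- centered_dataset(gt, "A", noise_sd = 0.05, seed = 51,
                         batch_shift_sd = 2)
  dB <- centered_dataset(dA$gt, "B", noise_sd = 0.05, seed = 52,
                         batch_shift_sd = 2)
  comb <- concatenate_datasets(list(dA$x, dB$x), list(dA$meta, dB$meta))
  dec <- run_robust_ica(comb$x, n_runs = 10, n_repetitions = 3,
                        min_members = 5, seed = 53)
  m <- match_to_truth(gt$true_S, dec$S)
  expect_gte(median(m$rho), 0.9)
  # reference centering removes constant per-gene offsets exactly, so no
  # component's activities should be dominated by the dataset label:
  # between-dataset variance stays well below within-dataset variance
  lab <- comb$meta$dataset_id
  ratio <- apply(dec$A, 1, function(a) {
    mu <- tapply(a, lab, mean)
    stats::var(mu[lab]) / stats::var(a - mu[lab])
  })
  expect_lt(min(ratio), 0.5)
})

test_that("decompositions round-trip through TSV + JSON", {
  gt <- tiny_truth(n_components = 3, n_genes = 200, gpc = c(8, 15))
  d <- centered_dataset(gt, noise_sd = 0, seed = 5)
  dec <- run_robust_ica(d$x, n_runs = 5, n_repetitions = 2,
                        min_members = 3, seed = 7)
  dir <- withr::local_tempdir()
  write_decomposition(dec, dir)
  back <- read_decomposition(dir)
  expect_equal(back$S, dec$S, tolerance = 1e-9)
  expect_equal(back$A, dec$A, tolerance = 1e-9)
})
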