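# QC filters, gene harmonization, centering and concatenation.

test_that("profile filter drops only profiles with more than max_missing holes", {
  set.seed(1)
  v <- matrix(rnorm(400 * 10), 400, 10)
  v[1:301, 1] <- NA          # 301 missing -> dropped
  v[1:300, 2] <- NA          # exactly 300 -> kept (strict >)
  x <- em(v)
  f <- filter_profiles_missing(x, max_missing = 300)
  expect_identical(ncol(f$values), 9L)
  expect_identical(colnames(f$values), colnames(x$values)[-1])
  # identity when nothing is missing
  dense <- em(matrix(rnorm(50), 10, 5))
  expect_identical(filter_profiles_missing(dense)$values, dense$values)
  # everything removed is an error
  allna <- em(matrix(NA_real_, 301, 2))
  expect_error(filter_profiles_missing(allna), "all profiles")
})

test_that("gene filter removes exactly the genes with any missing value", {
  v <- matrix(rnorm(24), 6, 4)
  v[2, 1] <- NA
  v[5, 3] <- NA
  f <- filter_genes_missing(em(v))
  expect_identical(nrow(f$values), 4L)
  expect_identical(rownames(f$values), rownames(em(v)$values)[-c(2, 5)])
  dense <- em(matrix(rnorm(24), 6, 4))
  expect_identical(filter_genes_missing(dense)$values, dense$values)
})

test_that("replicate filter keeps agreeing mates and discards noise profiles", {
  set.seed(42)
  base <- rnorm(200)
  v <- cbind(a1 = base + rnorm(200, sd = 0.1),
             a2 = base + rnorm(200, sd = 0.1),
             a3 = rnorm(200),               # independent noise
             b1 = rnorm(200))               # singleton group
  x <- em(v, genes = sprintf("g%03d", 1:200))
  meta <- sample_table(colnames(v), "T", c("a", "a", "a", "b"),
                       c("grpA", "grpA", "grpA", "grpB"),
                       c(TRUE, TRUE, TRUE, FALSE))
  # oracle: pairwise Pearson on the fixture
  cc <- cor(v[, 1:3])
  expect_true(max(cc["a3", c("a1", "a2")]) < 0.2)
  expect_true(cc["a1", "a2"] > 0.2)
  f <- filter_replicate_correlation(x, meta, min_r = 0.2)
  expect_identical(colnames(f$x$values), c("a1", "a2", "b1"))
  expect_identical(sort(f$meta$sample_id), c("a1", "a2", "b1"))
  # duplicate columns always survive (r = 1)
  dup <- em(cbind(c1 = base, c2 = base))
  meta2 <- sample_table(c("c1", "c2"), "T", "c", "grpC", c(TRUE, TRUE))
  expect_identical(ncol(filter_replicate_correlation(dup, meta2)$x$values), 2L)
})

test_that("gene intersection matches brute-force set computation, sorted", {
  m1 <- em(matrix(1:6, 3, 2), genes = c("c", "a", "b"))
  m2 <- em(matrix(1:6, 3, 2), genes = c("b", "d", "c"))
  out <- intersect_genes(list(m1, m2))
  expect_identical(rownames(out[[1]]$values), c("b", "c"))
  expect_identical(rownames(out[[2]]$values), c("b", "c"))
  expect_identical(out[[1]]$values["b", ], m1$values["b", ])

  set.seed(9)
  gs <- sprintf("g%04d", 1:1000)
  picks <- lapply(1:3, function(i) sort(sample(gs, 800)))
  xs <- lapply(picks, function(p) em(matrix(rnorm(length(p) * 4),
                                            length(p), 4), genes = p))
  out <- intersect_genes(xs)
  expect_identical(rownames(out[[1]]$values),
                   sort(Reduce(intersect, picks)))
  expect_error(intersect_genes(list(em(matrix(1:4, 2), genes = c("x", "y")),
                                    em(matrix(1:4, 2), genes = c("p", "q")))),
               "empty")
})

test_that("reference centering subtracts the reference-mean profile", {
  v <- matrix(c(2, 4, 6, 8), 1, 4,
              dimnames = list("g1", paste0("s", 1:4)))
  meta <- sample_table(paste0("s", 1:4), "T", c("ref", "ref", "c1", "c1"),
                       c("r", "r", "c", "c"), c(TRUE, TRUE, FALSE, FALSE))
  cx <- center_to_reference(em(v), meta)
  expect_equal(unname(cx$values[1, ]), c(-1, 1, 3, 5))
  expect_true(cx$centered)

  # replicated reference profiles center to exactly zero
  v0 <- matrix(5, 3, 4, dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  meta0 <- sample_table(paste0("s", 1:4), "T", "ref", "r", rep(TRUE, 4))
  expect_true(all(center_to_reference(em(v0), meta0)$values == 0))

  # post-hoc invariant on a random fixture: reference-column means are 0
  set.seed(4)
  v2 <- matrix(rnorm(50 * 12, mean = 7), 50, 12)
  x2 <- em(v2)
  meta2 <- sample_table(colnames(x2$values), "T",
                        rep(c("ref", "a", "b"), each = 4),
                        rep(c("ref", "a", "b"), each = 4),
                        rep(c(TRUE, FALSE, FALSE), each = 4))
  c2 <- center_to_reference(x2, meta2)
  expect_equal(unname(rowMeans(c2$values[, 1:4])), rep(0, 50),
               tolerance = 1e-9)
  # idempotence: re-centering changes nothing
  c2$centered <- FALSE
  expect_equal(center_to_reference(c2, meta2)$values, c2$values,
               tolerance = 1e-12)
  expect_error(center_to_reference(em(v2, dataset_id = "other"), meta2),
               "other")
})

test_that("concatenation binds centered datasets without touching values", {
  set.seed(5)
  mk <- function(id, n) {
    v <- matrix(rnorm(100 * n), 100, n,
                dimnames = list(sprintf("g%03d", 1:100),
                                sprintf("s%02d", 1:n)))
    meta <- sample_table(colnames(v), id,
                         rep(c("ref", "x"), length.out = n),
                         rep(c("ref", "x"), length.out = n),
                         rep(c(TRUE, FALSE), length.out = n))
    list(x = center_to_reference(em(v, dataset_id = id), meta), meta = meta)
  }
  d1 <- mk("A", 10); d2 <- mk("B", 10)
  comb <- concatenate_datasets(list(d1$x, d2$x), list(d1$meta, d2$meta))
  expect_identical(dim(comb$x$values), c(100L, 20L))
  expect_identical(unname(comb$x$values[, 1:10]), unname(d1$x$values))
  expect_identical(unname(comb$x$values[, 11:20]), unname(d2$x$values))
  expect_identical(comb$meta$sample_id, colnames(comb$x$values))
  expect_true(all(startsWith(comb$x$values |> colnames() |> head(10), "A:")))
  # restriction to one dataset's columns equals the centered single dataset
  expect_identical(unname(comb$x$values[, comb$meta$dataset_id == "B"]),
                   unname(d2$x$values))
  # single dataset: identity up to prefixing
  c1 <- concatenate_datasets(list(d1$x), list(d1$meta))
  expect_identical(unname(c1$x$values), unname(d1$x$values))
  # uncentered input refused
  expect_error(concatenate_datasets(list(em(matrix(rnorm(4), 2))), list(d1$meta)),
               "centered")
})

test_that("five rendered datasets concatenate to the summed column count", {
  gt <- tiny_truth(n_conditions = 5, replicates = 2)
  xs <- list(); metas <- list()
  for (i in 1:5) {
    d <- centered_dataset(gt, paste0("D", i), seed = 100 + i,
                          gene_subset_fraction = 0.9)
    gt <- d$gt
    xs[[i]] <- d$x
    metas[[i]] <- d$meta
  }
  xs <- intersect_genes(xs)
  comb <- concatenate_datasets(xs, metas)
  expect_identical(ncol(comb$x$values), sum(vapply(metas, nrow, integer(1))))
})
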