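mk_rm <- function(mat, samples = paste0("S", seq_len(ncol(mat)))) {
  n <- nrow(mat)
  region_methylation_matrix(
    genomic_intervals(rep("chr1", n), seq(0L, by = 100L, length.out = n),
                      seq(0L, by = 100L, length.out = n) + 50L),
    mat, samples)
}

test_that("missingness filter applies a strict threshold and preserves order", {
  mat <- matrix(0.5, 5, 10)
  n_miss <- c(0L, 5L, 7L, 8L, 9L)   # fractions 0, .5, .7 kept; .8, .9 dropped
  for (i in 1:5) if (n_miss[i] > 0) mat[i, seq_len(n_miss[i])] <- NA
  rm_ <- mk_rm(mat)
  out <- filter_missingness(rm_, max_missing = 0.8)
  expect_equal(nrow(out$density), 3L)
  expect_equal(out$regions$start, rm_$regions$start[c(1, 2, 3)])

  complete <- mk_rm(matrix(runif(20), 4, 5))
  expect_equal(filter_missingness(complete)$density, complete$density)

  allmiss <- mk_rm(matrix(NA_real_, 2, 3))
  expect_warning(out2 <- filter_missingness(allmiss), "threshold")
  expect_equal(nrow(out2$density), 0L)
})

test_that("kNN imputation fills from neighbours and is idempotent on complete data", {
  # twin rows, k = 1: the missing cell copies the twin
  mat <- rbind(c(0.2, 0.4, 0.6), c(0.2, 0.4, NA), c(0.9, 0.9, 0.9))
  out <- knn_impute(mk_rm(mat), k = 1L)
  expect_equal(out$density[2, 3], 0.6, ignore_attr = TRUE)
  expect_equal(out$density[1, ], mat[1, ], ignore_attr = TRUE)

  complete <- mk_rm(matrix(runif(12), 3, 4))
  expect_identical(knn_impute(complete, k = 2L)$density, complete$density)

  expect_error(knn_impute(mk_rm(rbind(c(NA, NA), c(0.1, 0.2)))),
               "zero observed")
})

test_that("kNN imputation matches a brute-force nearest-neighbour oracle", {
  mat <- rbind(c(0.10, 0.20, 0.30, 0.40),
               c(0.12, 0.22, NA,   0.42),
               c(0.90, 0.80, 0.70, 0.60),
               c(0.50, 0.55, 0.60, 0.65))
  out <- knn_impute(mk_rm(mat), k = 2L)
  # oracle: scaled Euclidean distance from row 2 over shared columns
  d <- apply(mat[-2, c(1, 2, 4)], 1, function(r)
    sqrt(sum((r - mat[2, c(1, 2, 4)])^2) * 4 / 3))
  nearest2 <- order(d)[1:2]
  expect_equal(out$density[2, 3], mean(mat[-2, ][nearest2, 3]),
               ignore_attr = TRUE)
})

test_that("SVD features capture exact low-rank structure", {
  # rank-1 matrix: first component explains everything
  fd <- svd_features(mk_rm(outer(c(1, 2, 3), c(1, -1, 2, -2)) / 20 + 0.5),
                     k = 1L)
  expect_equal(fd$variance_explained[1], 1, tolerance = 1e-10)

  # completeness: all components explain everything
  m2 <- matrix(runif(30), 5, 6)
  fd2 <- svd_features(mk_rm(m2), k = 6L)
  expect_equal(sum(fd2$variance_explained), 1, tolerance = 1e-10)
  expect_true(all(diff(fd2$variance_explained) <= 1e-12))
})

test_that("component-1 scores separate an orthogonal two-group block design", {
  g <- rep(c(0, 1), each = 5)
  mat <- matrix(0.3, 20, 10)
  mat[1:10, g == 1] <- 0.7
  mat <- mat + matrix(rnorm(200, 0, 0.01), 20, 10)
  fd <- svd_features(mk_rm(pmin(pmax(mat, 0), 1)), k = 2L)
  s1 <- fd$scores[, 1]
  expect_true(max(s1[g == 0]) < min(s1[g == 1]) ||
                min(s1[g == 0]) > max(s1[g == 1]))
})

test_that("SVD scores are sample-permutation equivariant up to sign", {
  set.seed(9)
  mat <- matrix(runif(60), 6, 10)
  fd <- svd_features(mk_rm(mat), k = 3L)
  perm <- sample(10)
  fd2 <- svd_features(mk_rm(mat[, perm]), k = 3L)
  for (j in 1:3)
    expect_equal(abs(cor(fd$scores[perm, j], fd2$scores[, j])), 1,
                 tolerance = 1e-8)
})

test_that("enrichment reproduces the exact hypergeometric answer on a fixed table", {
  # 10/20 query hits vs 5/100 random hits
  ft <- fisher.test(matrix(c(10, 10, 5, 95), 2))
  or_sample <- (10 * 95) / (10 * 5)
  expect_equal(or_sample, 19)
  # exact two-sided hypergeometric p computed independently
  dens <- dhyper(0:15, 15, 105, 20)
  p_oracle <- sum(dens[dens <= dhyper(10, 15, 105, 20) * (1 + 1e-7)])
  expect_equal(ft$p.value, p_oracle, tolerance = 1e-10)
})

test_that("a fully enriched query region set is detected", {
  set.seed(2)
  layout <- data.frame(chrom = "chr1", length = 100000L)
  # annotation: TSS covers 10% of the chromosome in 10 blocks
  tss <- genomic_intervals(rep("chr1", 10), seq(0, 90000, 10000),
                           seq(0, 90000, 10000) + 1000L)
  tss$name <- "TSS"
  quies <- genomic_intervals("chr1", 0L, 100000L); quies$name <- "Quies"
  ann <- rbind(tss, quies)
  # 50 query regions all inside TSS blocks
  qs <- rep(seq(0, 90000, 10000), length.out = 50) + 100L
  query <- genomic_intervals(rep("chr1", 50), qs, qs + 200L)
  res <- enrichment(query, ann, layout, n_draws = 20L, seed = 3L)
  tssrow <- res[res$state == "TSS", ]
  expect_gt(tssrow$odds_ratio, 5)
  expect_lt(tssrow$p, 0.01)
  expect_equal(tssrow$direction, "enriched")
})

test_that("enrichment is calibrated when the query is itself random", {
  set.seed(4)
  layout <- data.frame(chrom = "chr1", length = 100000L)
  states <- genomic_intervals(rep("chr1", 20), seq(0, 95000, 5000),
                              seq(0, 95000, 5000) + 2500L)
  states$name <- rep(c("A", "B"), 10)
  qs <- replicate(10, {
    q <- matched_random_intervals(
      genomic_intervals(rep("chr1", 30), 0L, 300L), layout, 1L)
    res <- enrichment(q, states, layout, n_draws = 10L, seed = NULL)
    c(min(res$q), max(abs(log(pmax(res$odds_ratio, 1e-3)))))
  })
  expect_lte(mean(qs[1, ] < 0.05), 0.2)
})
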