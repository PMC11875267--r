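test_that("identical groups give a null site test", {
  y <- rep(c(3L, 5L, 4L, 2L, 6L), 2); n <- rep(10L, 10)
  res <- fit_site_test(y, n, two_group_labels())
  expect_equal(res$lrt, 0, tolerance = 1e-4)
  expect_gt(res$p_raw, 0.95)
  expect_equal(res$delta, 0)
})

test_that("fully separated groups are strongly significant and match an independent maximizer", {
  y <- c(rep(10L, 5), rep(0L, 5)); n <- rep(10L, 10)
  g <- rev(two_group_labels())
  res <- fit_site_test(y, n, g)
  # the small-sample F reference keeps this 10-sample fixture above the
  # asymptotic chi-square tail, but it remains decisively significant
  expect_lt(res$p_raw, 5e-3)
  expect_equal(res$delta, 1)  # group 1 carries the fully methylated counts

  # oracle: recompute the likelihood-ratio statistic with an independent
  # maximizer (nlminb on the helper likelihood) at the dispersion the
  # implementation selected; the statistics must agree
  set.seed(1)
  y2 <- rbetabinom(10, 12, plogis(-0.5 + 2 * g), 0.1)
  n2 <- rep(12L, 10)
  imp <- fit_site_test(y2, n2, g)
  Xf <- cbind(1, g); Xr <- cbind(rep(1, 10))
  negll <- function(b, X) -oracle_bb_loglik(c(b, qlogis(imp$rho)), y2, n2, X)
  lrt_oracle <- 2 * (nlminb(0, negll, X = Xr)$objective -
                       nlminb(c(0, 0), negll, X = Xf)$objective)
  expect_equal(imp$lrt, lrt_oracle, tolerance = 1e-4)
})

test_that("site test refuses low-coverage groups and records them untested", {
  y <- c(1L, 0L, 2L, 3L, 1L, 0L, 0L, 0L, 0L, 0L)
  n <- c(5L, 5L, 5L, 5L, 5L, 0L, 0L, 0L, 0L, 1L)
  res <- fit_site_test(y, n, two_group_labels())
  expect_false(res$tested)
})

test_that("window = 1 neighbour combination is the identity", {
  p <- c(0.2, 0.01, 0.8, 0.4)
  out <- combine_neighbors(p, window = 1L)
  expect_identical(out$p_combined, p)
})

test_that("Stouffer combination matches its closed form without autocorrelation", {
  p <- rep(0.04, 10)
  out <- combine_neighbors(p, window = 10L, correct_autocorr = FALSE)
  closed <- pnorm(sqrt(10) * qnorm(0.96), lower.tail = FALSE)
  expect_equal(out$p_combined[5], closed, tolerance = 1e-12)
  expect_lt(out$p_combined[5], 0.04)
})

test_that("window selection collapses to 1 for independent uniform p-values", {
  set.seed(31)
  p <- runif(3000)
  out <- combine_neighbors(p)
  expect_equal(out$window, 1L)
  expect_gt(ks.test(out$p_combined, "punif")$p.value, 0.01)
})

test_that("DMR calling merges consistent runs and respects gaps and direction", {
  base <- data.frame(chrom = "chr1", pos = c(100L, 120L, 140L),
                     tested = TRUE, delta = 0.3, p_combined = 0.01,
                     q = 0.01)
  out <- call_dmrs(base)
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 100L)
  expect_equal(out$end, 141L)
  expect_equal(out$n_cpgs, 3L)
  expect_equal(out$direction, "hyper")

  # alternating directions never merge
  alt <- base
  alt$delta <- c(0.3, -0.3, 0.3)
  alt$q <- 0.01
  out2 <- call_dmrs(alt, delta_threshold = 0.1)
  expect_true(all(out2$n_cpgs == 1L))

  # an untested site breaks the run
  brk <- rbind(base[1:2, ], data.frame(chrom = "chr1", pos = 130L,
                                       tested = FALSE, delta = NA,
                                       p_combined = NA, q = NA), base[3, ])
  brk <- brk[order(brk$pos), ]
  out3 <- call_dmrs(brk)
  expect_true(all(out3$n_cpgs < 3L))

  # a gap beyond max_gap_bp splits regions
  far <- base; far$pos <- c(100L, 120L, 5000L)
  out4 <- call_dmrs(far)
  expect_equal(sort(out4$n_cpgs), c(1L, 2L))
})

test_that("BH q-values preserve p-value ordering in the pipeline output", {
  set.seed(5)
  cfg <- sim_config(n_cpgs = 120L, coverage_mean = 10, n_dmrs = 2L,
                    dmr_size_cpgs = 3L, seed = 13L)
  sim <- simulate_counts(cfg)
  res <- dm_pipeline(sim$counts, sim$samples$group != "Control",
                     max_window = 10L)
  tested <- res$sites[res$sites$tested, ]
  o <- order(tested$p_combined)
  expect_true(all(diff(tested$q[o]) >= -1e-12))
})

test_that("median raw p decreases with planted effect size", {
  meds <- sapply(c(0, 0.8, 1.6), function(eff) {
    cfg <- sim_config(n_cpgs = 300L, coverage_mean = 10, n_dmrs = 30L,
                      dmr_size_cpgs = 3L, dmr_effect = eff, seed = 17L)
    sim <- simulate_counts(cfg)
    tr <- sim$truth$dmr_regions
    idx <- unlist(lapply(seq_len(nrow(tr)),
                         function(k) seq(tr$first_site[k], length.out = 3L)))
    sub <- cpg_count_matrix(sim$counts$sites$chrom[idx],
                            sim$counts$sites$pos[idx],
                            sim$counts$meth[idx, ], sim$counts$total[idx, ],
                            sim$counts$samples)
    sc <- dm_scan(sub, sim$samples$group != "Control")
    median(sc$p_raw[sc$tested])
  })
  expect_true(all(diff(meds) <= 0))
})

test_that("a sex effect without a group effect does not inflate group significance", {
  set.seed(23)
  ns <- 40L
  sex <- rep(c("F", "M"), 20)
  group <- rep(c(0L, 1L), each = 20L)
  n_cpg <- 300L
  mu <- matrix(plogis(qlogis(0.4) + 1.0 * (sex == "M")), n_cpg, ns,
               byrow = TRUE)
  total <- matrix(rpois(n_cpg * ns, 10), n_cpg, ns)
  meth <- matrix(rbetabinom(n_cpg * ns, as.vector(total), as.vector(mu),
                            0.1), n_cpg, ns)
  counts <- cpg_count_matrix(rep("chr1", n_cpg),
                             seq(0L, by = 100L, length.out = n_cpg),
                             meth, total, sprintf("S%02d", 1:ns))
  sc <- dm_scan(counts, group, covariate = factor(sex))
  expect_lt(mean(sc$p_raw[sc$tested] < 0.05), 0.1)
})
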