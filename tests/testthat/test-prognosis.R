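test_that("PDDS interpolation is linear, clamped to the observed span", {
  obs <- data.frame(patient_id = "P1", day = c(0L, 100L), pdds = c(2L, 4L))
  g <- interpolate_pdds(obs)
  expect_equal(g$day, c(0, 50, 100))
  expect_equal(g$pdds, c(2, 3, 4))

  const <- data.frame(patient_id = "P1", day = c(0L, 50L, 2000L),
                      pdds = c(5L, 5L, 5L))
  expect_true(all(interpolate_pdds(const)$pdds == 5))

  late <- data.frame(patient_id = "P1", day = c(120L, 400L), pdds = c(1L, 3L))
  gl <- interpolate_pdds(late)
  expect_equal(min(gl$day), 150)      # first multiple of 50 inside the span
  expect_true(all(gl$pdds >= 1 & gl$pdds <= 3))

  single <- data.frame(patient_id = c("P1", "P2"), day = c(0L, 0L),
                       pdds = c(1L, 2L))
  single <- rbind(single[1, ], data.frame(patient_id = "P2", day = 300L,
                                          pdds = 4L))
  expect_message(g2 <- interpolate_pdds(validate_outcomes(single)),
                 "excluded")
  expect_true(all(g2$patient_id == "P2"))
})

test_that("candidate regions merge fully observed runs across small gaps", {
  # loci fully observed at [0,100] every 50 bp and at 350..400; gap 250
  pos <- c(seq(0L, 100L, 50L), 350L, 400L)
  n <- length(pos)
  counts <- cpg_count_matrix(rep("chr1", n), pos,
                             matrix(1L, n, 3), matrix(2L, n, 3),
                             paste0("S", 1:3))
  out <- build_candidate_regions(counts, merge_gap = 300L)
  expect_equal(nrow(out$regions), 1L)
  expect_equal(out$regions$start, 0L)
  expect_equal(out$regions$end, 401L)

  out2 <- build_candidate_regions(counts, merge_gap = 249L)
  expect_equal(nrow(out2$regions), 2L)

  # a largely uncovered sample outside the region-defining set is excluded
  tot <- matrix(2L, n, 3); tot[, 3] <- 0L
  counts2 <- cpg_count_matrix(rep("chr1", n), pos, matrix(0L, n, 3), tot,
                              paste0("S", 1:3))
  expect_message(out3 <- build_candidate_regions(
    counts2, merge_gap = 10L, sample_missing_max = 0.5,
    region_samples = c("S1", "S2")), "excluded")
  expect_false("S3" %in% out3$samples)
  expect_true(all(c("S1", "S2") %in% out3$samples))
})

test_that("the fast REML solver reproduces lmerTest (estimate, SE, df, p)", {
  skip_if_not_installed("lmerTest")
  set.seed(7)
  m <- 25L; v <- 5L
  pid <- rep(sprintf("P%02d", 1:m), each = v)
  day <- rep(seq(0, 1000, length.out = v), m)
  g <- rep(rbinom(m, 1, 0.5), each = v)
  u <- rep(rnorm(m, 0, 0.5), each = v)
  y <- 2 + 3e-4 * day + 1e-3 * day * g + u + rnorm(m * v, 0, 0.4)
  X <- cbind(1, time = day, group = g, tg = day * g)
  fit <- lmm_ranint(y, X, pid)
  lf <- lmerTest::lmer(y ~ day + g + day:g + (1 | pid),
                       data = data.frame(y, day, g, pid), REML = TRUE)
  s <- summary(lf)$coefficients["day:g", ]
  expect_equal(fit$beta, unname(s["Estimate"]), tolerance = 1e-6)
  expect_equal(fit$se, unname(s["Std. Error"]), tolerance = 1e-6)
  expect_equal(fit$df, unname(s["df"]), tolerance = 1e-3)
  expect_equal(fit$p, unname(s["Pr(>|t|)"]), tolerance = 1e-6)
})

test_that("a zero-noise fixture returns the exact slope difference", {
  m <- 10L; v <- 4L
  pid <- rep(sprintf("P%02d", 1:m), each = v)
  day <- rep(c(0, 100, 200, 300), m)
  g <- rep(rep(c(0, 1), each = 5L), each = v)
  y <- 1 + 0.004 * day + 0.003 * day * g
  X <- cbind(1, time = day, group = g, tg = day * g)
  fit <- lmm_ranint(y, X, pid)
  expect_equal(fit$beta, 0.003, tolerance = 1e-8)
})

test_that("rank scores and selection follow the informativeness rule", {
  res <- data.frame(chrom = "chr1", start = c(0L, 100L, 200L),
                    end = c(50L, 150L, 250L),
                    beta3 = c(2.0, 0.5, 1.0), se3 = 0.1, df3 = 10,
                    p3 = c(1e-4, 0.002, 0.0005), tested = TRUE,
                    satterthwaite = TRUE)
  res$p3_adjusted <- pmin(res$p3 * 3, 1)
  res$rank_score <- abs(res$beta3) * -log10(res$p3_adjusted)
  expect_equal(res$rank_score[1], 2 * -log10(3e-4))
  r1 <- data.frame(res[1, ]); r1$p3_adjusted <- 0.01;
  expect_equal(abs(r1$beta3) * -log10(r1$p3_adjusted), 4)

  sel <- rank_and_select(res, k = 2L, alpha = 0.05)
  expect_equal(sel$start, c(0L, 200L))   # ranked by score
  expect_warning(rank_and_select(res, k = 10L, alpha = 0.05), "only 3")
  bot <- rank_and_select(res, k = 1L, direction = "bottom")
  expect_equal(bot$start, 100L)
})

test_that("MBPRS is the weighted sum with a deterministic median split", {
  rm_ <- region_methylation_matrix(
    genomic_intervals(rep("chr1", 3), c(0L, 100L, 200L), c(50L, 150L, 250L)),
    cbind(A = c(0.8, 0.5, 0.1), B = c(0.1, 0.5, 0.8), C = c(0.5, 0.5, 0.5)),
    c("A", "B", "C"))
  w <- c(0.5, -0.2, 1.0)
  mb <- compute_mbprs(rm_, w)
  expect_equal(mb$score[mb$sample_id == "A"], 0.4, tolerance = 1e-12)
  # doubling weights preserves the partition
  mb2 <- compute_mbprs(rm_, 2 * w)
  expect_equal(mb$group, mb2$group)
  expect_error(compute_mbprs(rm_, c(0, 0, 0)), "zero")
  # ties at the median go Low
  expect_equal(sum(mb$group == "High"), 1L)
})

test_that("survival records implement first-visit-at-PDDS>=4 with censoring", {
  out <- validate_outcomes(data.frame(
    patient_id = rep(c("P1", "P2", "P3"), each = 3),
    day = rep(c(0L, 100L, 200L), 3),
    pdds = c(1, 2, 5,  2, 3, 3,  6, 7, 8)))
  expect_message(rec <- survival_records(out), "excluded")
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$time[rec$patient_id == "P1"], 200)
  expect_equal(rec$event[rec$patient_id == "P1"], 1L)
  expect_equal(rec$event[rec$patient_id == "P2"], 0L)
  rec2 <- survival_records(out, baseline_policy = "event_at_0")
  expect_equal(rec2$time[rec2$patient_id == "P3"], 0)
})

test_that("log-rank agrees with a hand-computed 6-patient fixture and nulls out", {
  time <- c(6, 13, 21, 30, 37, 38)
  event <- c(1, 1, 1, 1, 0, 1)
  group <- rep(c("High", "Low"), each = 3)
  rec <- data.frame(patient_id = paste0("P", 1:6), time = time,
                    event = event)
  lr <- pfs_logrank(group, rec)
  expect_equal(lr$chisq, oracle_logrank(time, event, group),
               tolerance = 1e-10)

  # identical event structure in both groups: statistic 0, p = 1
  rec2 <- data.frame(patient_id = paste0("P", 1:6),
                     time = rep(c(5, 10, 20), 2), event = 1L)
  lr2 <- pfs_logrank(rep(c("High", "Low"), 3), rec2)
  expect_lt(lr2$chisq, 1e-10)
  expect_equal(lr2$p, 1, tolerance = 1e-8)
})

test_that("permutation control returns the boundary p and validates n_perm", {
  set.seed(1)
  coh <- simulate_prognosis_cohort(n_patients = 20L, n_regions = 60L,
                                   n_prognostic = 6L, seed = 14L)
  scr <- suppressWarnings(lmm_screen(coh$region_matrix, coh$samples,
                                     coh$outcomes,
                                     use_covariates = "age"))
  sel <- suppressWarnings(rank_and_select(scr, k = 10L, alpha = 0.5))
  recs <- suppressMessages(survival_records(coh$outcomes))
  s2p <- setNames(coh$samples$patient_id, coh$samples$sample_id)
  pc <- permutation_control(sel$weight,
                            genomic_intervals(sel$chrom, sel$start, sel$end),
                            coh$layout, coh$counts, recs, s2p,
                            observed_p = 0, n_perm = 19L, seed = 3L)
  expect_equal(pc$empirical_p, 1 / 20)
  expect_error(permutation_control(sel$weight, sel, coh$layout, coh$counts,
                                   recs, s2p, 0.5, n_perm = 0L),
               "n_perm")
})

test_that("the screen recovers a planted interaction and flags selections consistently", {
  coh <- simulate_prognosis_cohort(n_patients = 40L, n_regions = 80L,
                                   n_prognostic = 8L, seed = 31L)
  scr <- suppressWarnings(lmm_screen(coh$region_matrix, coh$samples,
                                     coh$outcomes))
  expect_gt(attr(scr, "n_tested"), 0)
  planted <- coh$truth$prognostic_idx
  expect_lt(abs(mean(scr$beta3[planted]) - 0.002) / 0.002, 0.35)
  sel <- suppressWarnings(rank_and_select(scr, k = 100L))
  expect_true(all(sel$p3_adjusted < 0.01))   # top set is Bonferroni-significant
})
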