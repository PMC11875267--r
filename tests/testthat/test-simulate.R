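test_that("identical config and seed give identical cohorts", {
  cfg <- sim_config(n_cpgs = 200L, n_dmrs = 5L, dmr_size_cpgs = 3L,
                    seed = 99L)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts$meth, b$counts$meth)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth$dmr_regions, b$truth$dmr_regions)
})

test_that("simulated coverage matches the Poisson mean and counts are valid", {
  cfg <- sim_config(n_cpgs = 10000L, coverage_mean = 1.5, n_dmrs = 0L,
                    seed = 4L)
  sim <- simulate_counts(cfg)
  expect_lt(abs(mean(sim$counts$total) - 1.5) / 1.5, 0.05)
  expect_true(all(sim$counts$meth <= sim$counts$total))
})

test_that("null planted effect leaves group means equal", {
  cfg <- sim_config(n_cpgs = 2000L, coverage_mean = 10, n_dmrs = 20L,
                    dmr_effect = 0, seed = 12L)
  sim <- simulate_counts(cfg)
  g <- sim$samples$group != "Control"
  tr <- sim$truth$dmr_regions
  idx <- unlist(lapply(seq_len(nrow(tr)),
                       function(k) seq(tr$first_site[k],
                                       length.out = tr$n_cpgs[k])))
  d1 <- sum(sim$counts$meth[idx, g]) / sum(sim$counts$total[idx, g])
  d0 <- sum(sim$counts$meth[idx, !g]) / sum(sim$counts$total[idx, !g])
  n_reads <- sum(sim$counts$total[idx, ])
  expect_lt(abs(d1 - d0), 3 * sqrt(0.5 / n_reads) * sqrt(2) * 2)
})

test_that("beta-binomial variance approaches binomial as rho -> 0", {
  set.seed(8)
  n <- 20L
  draws <- rbetabinom(10000, n, 0.3, 1e-8) / n
  expect_lt(abs(var(draws) - 0.3 * 0.7 / n) / (0.3 * 0.7 / n), 0.1)
  # and exceeds it markedly at rho = 0.3
  draws2 <- rbetabinom(10000, n, 0.3, 0.3) / n
  expect_gt(var(draws2), 2 * 0.3 * 0.7 / n)
})

test_that("fragment mixtures reproduce their generative proportions", {
  atlas <- make_marker_atlas(n_celltypes = 2L, markers_per_type = 5L)
  fr <- simulate_fragments(atlas, c(0.5, 0.5), 10000L, seed = 3L)
  frac <- mean(attr(fr, "truth") == 1L)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
  expect_error(simulate_fragments(atlas, c(0.6, 0.2), 10L),
               "sum to 1")
})

test_that("a pure unmethylated cell type yields all-zero calls at its markers", {
  atlas <- make_marker_atlas(n_celltypes = 2L, markers_per_type = 3L,
                             m_low = 0, m_high = 1)
  fr <- simulate_fragments(atlas, c(1, 0), 500L, seed = 5L)
  at_own <- fr$start < max(atlas$markers$end[atlas$markers$target == "CT1"])
  own_markers <- atlas$markers[atlas$markers$target == "CT1", ]
  in_own <- fr$chrom %in% own_markers$chrom &
    sapply(seq_len(nrow(fr)), function(i)
      any(fr$start[i] >= own_markers$start & fr$start[i] < own_markers$end))
  expect_true(all(fr$nmeth[in_own] == 0L))
})

test_that("marginal fragment methylation matches the mixture-weighted atlas", {
  atlas <- make_marker_atlas(n_celltypes = 3L, markers_per_type = 4L)
  props <- c(0.5, 0.3, 0.2)
  fr <- simulate_fragments(atlas, props, 10000L, seed = 6L)
  # at CT1 markers the expected per-CpG methylation mixes m_low and m_high
  ct1 <- atlas$markers[atlas$markers$target == "CT1", ]
  in1 <- sapply(seq_len(nrow(fr)), function(i)
    any(fr$start[i] >= ct1$start & fr$start[i] < ct1$end))
  obs <- sum(fr$nmeth[in1]) / sum(fr$ncpg[in1])
  expected <- props[1] * 0.05 + (1 - props[1]) * 0.92
  expect_lt(abs(obs - expected), 0.02)
})

test_that("trajectories follow the latent linear model exactly when noiseless", {
  st <- data.frame(sample_id = c("S1", "S2"), patient_id = c("P1", "P2"),
                   group = "S-RRMS", age = c(40, 50), sex = c("F", "M"),
                   race = "White", stringsAsFactors = FALSE)
  tr <- list(beta0 = 3, beta1 = 0, beta3 = 0, sigma_u = 0, sigma_eps = 0,
             visit_spacing_days = 100, n_visits = 4)
  res <- simulate_trajectories(st, c(0, 1), tr, seed = 1L)
  expect_true(all(res$outcomes$pdds == 3L))

  # deterministic interaction: high group exceeds low by beta3 * t
  tr2 <- list(beta0 = 1, beta1 = 0, beta3 = 0.002, sigma_u = 0,
              sigma_eps = 0, visit_spacing_days = 1000, n_visits = 3)
  res2 <- simulate_trajectories(st, c(0, 1), tr2, seed = 1L)
  p2 <- res2$outcomes
  last_high <- p2$pdds[p2$patient_id == "P2"][3]
  last_day <- p2$day[p2$patient_id == "P2"][3]
  expect_equal(last_high, min(round(1 + 0.002 * last_day), 8L))

  # clamping to the ordinal scale
  tr3 <- list(beta0 = 9.3, beta1 = 0, beta3 = 0, sigma_u = 0,
              sigma_eps = 0, visit_spacing_days = 100, n_visits = 2)
  res3 <- simulate_trajectories(st, c(0, 0), tr3, seed = 1L)
  expect_true(all(res3$outcomes$pdds == 8L))
})

test_that("prognosis cohort generator satisfies container invariants", {
  coh <- simulate_prognosis_cohort(n_patients = 10L, n_regions = 40L,
                                   n_prognostic = 4L, seed = 21L)
  expect_s3_class(coh$counts, "CpGCountMatrix")
  expect_equal(nrow(coh$region_matrix$density), 40L)
  d <- coh$region_matrix$density
  expect_true(all(is.na(d) | (d >= 0 & d <= 1)))
  expect_equal(length(coh$truth$h), 10L)
  expect_true(all(table(coh$outcomes$patient_id) >= 2))
})
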