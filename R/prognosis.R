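## PDDS interpolation, candidate regions, the per-region linear
## mixed-effects screen, MBPRS, progression-free survival and the
## matched-interval permutation control.

#' Interpolate PDDS trajectories onto a fixed-day grid
#'
#' Linear interpolation of each patient's observed scores at multiples of
#' `step` days within the overlap of `span` and the patient's observed day
#' range; no extrapolation. Patients with fewer than two observations are
#' excluded (with a message).
#'
#' @param outcomes data.frame `patient_id`, `day`, `pdds`.
#' @param step grid spacing in days (default 50).
#' @param span evaluation window, default day 0 to day 2000.
#' @return data.frame `patient_id`, `day`, `pdds` (interpolated).
#' @export
interpolate_pdds <- function(outcomes, step = 50L, span = c(0L, 2000L)) {
  outcomes <- validate_outcomes(outcomes)
  out <- lapply(split(outcomes, outcomes$patient_id), function(o) {
    if (nrow(o) < 2L) return(NULL)
    lo <- max(span[1], min(o$day)); hi <- min(span[2], max(o$day))
    grid <- seq(ceiling(lo / step) * step, hi, by = step)
    if (!length(grid)) return(NULL)
    data.frame(patient_id = o$patient_id[1], day = grid,
               pdds = approx(o$day, o$pdds, xout = grid)$y)
  })
  dropped <- sum(vapply(out, is.null, logical(1)))
  if (dropped > 0)
    message(dropped, " patient(s) excluded from interpolation (",
            "insufficient observations or empty grid)")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build candidate regions from fully observed CpG runs
#'
#' Candidate regions are maximal runs of CpGs covered (`total > 0`) in
#' every sample; runs separated by at most `merge_gap` base pairs are
#' merged. Samples whose missing fraction across the final regions exceeds
#' `sample_missing_max` are excluded (with a message).
#'
#' @param counts a `CpGCountMatrix`.
#' @param merge_gap merge distance in bp (default 300).
#' @param sample_missing_max per-sample missingness tolerance (default 0.9).
#' @param region_samples sample ids used to define the fully observed runs
#'   (e.g. the two disability groups being contrasted); defaults to all
#'   samples. Missingness is then assessed across all samples of `counts`.
#' @return list: `regions` (intervals), `samples` (retained ids).
#' @export
build_candidate_regions <- function(counts, merge_gap = 300L,
                                    sample_missing_max = 0.9,
                                    region_samples = NULL) {
  use <- if (is.null(region_samples)) seq_along(counts$samples) else
    match(region_samples, counts$samples)
  if (anyNA(use)) stop("region_samples not found in counts")
  complete <- rowSums(counts$total[, use, drop = FALSE] == 0L) == 0L
  regs <- list()
  for (ch in unique(counts$sites$chrom)) {
    i <- which(counts$sites$chrom == ch & complete)
    if (!length(i)) next
    pos <- counts$sites$pos[i]
    brk <- c(TRUE, diff(pos) > merge_gap)
    id <- cumsum(brk)
    regs[[ch]] <- data.frame(
      chrom = ch,
      start = tapply(pos, id, min),
      end = tapply(pos, id, max) + 1L)
  }
  regions <- do.call(rbind, regs)
  if (is.null(regions)) stop("no fully observed CpG runs found")
  regions <- genomic_intervals(regions$chrom, regions$start, regions$end)
  dens <- aggregate_to_regions(counts, regions)
  miss <- colMeans(is.na(dens$density))
  drop <- miss > sample_missing_max
  if (any(drop))
    message(sum(drop), " sample(s) excluded (> ",
            100 * sample_missing_max, "% missing across candidate regions)")
  list(regions = regions, samples = counts$samples[!drop])
}

## ---- fast random-intercept REML ------------------------------------------

# Precompute the pieces of the profiled REML criterion that do not depend
# on the tested region. `pid` must be a factor; rows are observations.
make_lmm_context <- function(y, pid) {
  pid <- factor(pid)
  list(y = y, pid = pid, idx = as.integer(pid),
       m = nlevels(pid), n = length(y),
       n_i = tabulate(as.integer(pid), nlevels(pid)))
}

# Profiled REML criterion and GLS quantities at variance ratio theta for
# design X. Uses the closed-form inverse of I + theta * J per patient
# block, so the cost is O(n p + m p^2) per evaluation.
reml_pieces <- function(theta, X, ctx, XtX, Xty, yty, SX, Sy) {
  ci <- theta / (1 + ctx$n_i * theta)
  XtVX <- XtX - crossprod(SX * ci, SX)
  XtVy <- Xty - crossprod(SX * ci, Sy)
  ytVy <- yty - sum(ci * Sy^2)
  ch <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  beta <- backsolve(ch, forwardsolve(t(ch), XtVy))
  rss <- max(ytVy - sum(beta * XtVy), 1e-12)
  logdetV <- sum(log1p(ctx$n_i * theta))
  logdetXtVX <- 2 * sum(log(diag(ch)))
  list(beta = beta, rss = rss, chol = ch,
       logdetV = logdetV, logdetXtVX = logdetXtVX)
}

# -2 * restricted log-likelihood as a function of (sigma_u^2, sigma_e^2),
# used for the numerical information matrix behind Satterthwaite.
reml_m2ll <- function(s2u, s2e, X, ctx, XtX, Xty, yty, SX, Sy) {
  th <- s2u / s2e
  pc <- reml_pieces(th, X, ctx, XtX, Xty, yty, SX, Sy)
  if (is.null(pc)) return(Inf)
  p <- ncol(X)
  (ctx$n - p) * log(s2e) + pc$logdetV + pc$logdetXtVX + pc$rss / s2e
}

#' Random-intercept linear mixed model with a Satterthwaite test
#'
#' REML fit of `y ~ X + (1 | patient)` using the closed-form per-patient
#' block inverse, profiled over the variance ratio. The p-value for one
#' coefficient uses Satterthwaite's degrees-of-freedom approximation
#' computed from the numerical REML information matrix; when the random
#' intercept variance collapses to the boundary the normal approximation
#' is used and flagged.
#'
#' @param y response vector.
#' @param X fixed-effects design matrix (full column rank).
#' @param pid patient identifier per observation.
#' @param test_col column of `X` to test (default the last).
#' @param ctx optionally a precomputed [make_lmm_context()] result.
#' @return list: `beta`, `se`, `t`, `df`, `p`, `sigma_u`, `sigma_e`,
#'   `converged`, `satterthwaite` (FALSE when the normal fallback fired).
#' @export
lmm_ranint <- function(y, X, pid, test_col = ncol(X), ctx = NULL) {
  if (is.null(ctx)) ctx <- make_lmm_context(y, pid)
  X <- as.matrix(X)
  XtX <- crossprod(X); Xty <- crossprod(X, ctx$y)
  yty <- sum(ctx$y^2)
  SX <- rowsum(X, ctx$idx, reorder = TRUE)
  Sy <- drop(rowsum(matrix(ctx$y), ctx$idx, reorder = TRUE))
  p <- ncol(X)
  crit <- function(th) {
    pc <- reml_pieces(th, X, ctx, XtX, Xty, yty, SX, Sy)
    if (is.null(pc)) return(1e12)
    pc$logdetV + pc$logdetXtVX + (ctx$n - p) * log(pc$rss)
  }
  opt <- optimize(crit, interval = c(0, 1e4), tol = 1e-9)
  th <- opt$minimum
  pc <- reml_pieces(th, X, ctx, XtX, Xty, yty, SX, Sy)
  if (is.null(pc))
    return(list(converged = FALSE, beta = NA_real_, se = NA_real_,
                t = NA_real_, df = NA_real_, p = NA_real_,
                sigma_u = NA_real_, sigma_e = NA_real_,
                satterthwaite = FALSE))
  s2e <- pc$rss / (ctx$n - p)
  s2u <- th * s2e
  Cfull <- chol2inv(pc$chol) * s2e
  beta <- pc$beta[test_col]
  se <- sqrt(Cfull[test_col, test_col])
  tstat <- beta / se

  satt <- FALSE; df <- ctx$n - p
  if (s2u > 1e-8 * s2e) {
    fvar <- function(su, se2) {
      pp <- reml_pieces(su / se2, X, ctx, XtX, Xty, yty, SX, Sy)
      if (is.null(pp)) return(NA_real_)
      (chol2inv(pp$chol) * se2)[test_col, test_col]
    }
    h_u <- 1e-4 * s2u; h_e <- 1e-4 * s2e
    g <- c((fvar(s2u + h_u, s2e) - fvar(s2u - h_u, s2e)) / (2 * h_u),
           (fvar(s2u, s2e + h_e) - fvar(s2u, s2e - h_e)) / (2 * h_e))
    f0 <- function(a, b) reml_m2ll(a, b, X, ctx, XtX, Xty, yty, SX, Sy)
    hu <- 1e-3 * s2u; he <- 1e-3 * s2e
    H <- matrix(NA_real_, 2, 2)
    H[1, 1] <- (f0(s2u + hu, s2e) - 2 * f0(s2u, s2e) +
                  f0(s2u - hu, s2e)) / hu^2
    H[2, 2] <- (f0(s2u, s2e + he) - 2 * f0(s2u, s2e) +
                  f0(s2u, s2e - he)) / he^2
    H[1, 2] <- H[2, 1] <-
      (f0(s2u + hu, s2e + he) - f0(s2u + hu, s2e - he) -
         f0(s2u - hu, s2e + he) + f0(s2u - hu, s2e - he)) / (4 * hu * he)
    covv <- tryCatch(solve(H / 2), error = function(e) NULL)
    if (!is.null(covv) && all(is.finite(g))) {
      denom <- drop(t(g) %*% covv %*% g)
      if (is.finite(denom) && denom > 0) {
        df_s <- 2 * (se^2)^2 / denom
        if (is.finite(df_s) && df_s > 1) { df <- df_s; satt <- TRUE }
      }
    }
  }
  pval <- 2 * stats::pt(-abs(tstat), df)
  list(converged = TRUE, beta = beta, se = se, t = tstat, df = df,
       p = pval, sigma_u = sqrt(s2u), sigma_e = sqrt(s2e),
       satterthwaite = satt)
}

## ---- the per-region screen -----------------------------------------------

# Fixed-effect covariate design from the cohort table: age, sex, race,
# disease duration, DMT type/effectiveness, follow-up duration. Categorical
# covariates with < 2 observed levels, and covariates with missing values,
# are dropped with a warning.
covariate_design <- function(samples,
                             covariates = c("age", "sex", "race",
                                            "disease_duration", "dmt_type",
                                            "dmt_effectiveness",
                                            "followup_duration")) {
  cols <- list()
  for (cv in covariates) {
    v <- samples[[cv]]
    if (is.null(v)) next
    if (anyNA(v)) { warning("covariate '", cv, "' has missing values; dropped"); next }
    if (is.character(v) || is.factor(v)) {
      f <- factor(v)
      if (nlevels(droplevels(f)) < 2L) {
        warning("covariate '", cv, "' has < 2 levels; dropped"); next
      }
      mm <- model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(cv, seq_len(ncol(mm)))
      cols[[cv]] <- mm
    } else {
      if (var(v) == 0) { warning("covariate '", cv, "' is constant; dropped"); next }
      cols[[cv]] <- matrix(v, ncol = 1, dimnames = list(NULL, cv))
    }
  }
  if (!length(cols)) return(NULL)
  do.call(cbind, cols)
}

#' Linear mixed-model screen for prognostic regions
#'
#' For each region, patients are dichotomized High/Low at the cohort median
#' of baseline region methylation (ties to Low), and the model
#' `PDDS ~ time + group + time:group + covariates + (1 | patient)` is fit
#' by REML on the raw visit data; the reported test is the
#' Satterthwaite-approximated p-value of the time-by-group interaction.
#' Bonferroni adjustment runs across converged regions only.
#'
#' @param region_matrix a `RegionMethylationMatrix` (columns = samples,
#'   one per patient).
#' @param samples cohort table mapping `sample_id` to `patient_id` and
#'   covariates.
#' @param outcomes longitudinal PDDS table.
#' @param alpha significance level on the Bonferroni-adjusted p (recorded,
#'   used downstream by [rank_and_select()]).
#' @param use_covariates covariate names to adjust for; `NULL` for none.
#' @return data.frame of class `PrognosticRegionResult`: region
#'   coordinates, `beta3` (PDDS/day), `se3`, `df3`, `p3`, `p3_adjusted`,
#'   `rank_score`, `tested`, `n_tested` attribute.
#' @export
lmm_screen <- function(region_matrix, samples, outcomes, alpha = 0.01,
                       use_covariates = c("age", "sex", "race",
                                          "disease_duration", "dmt_type",
                                          "dmt_effectiveness",
                                          "followup_duration")) {
  outcomes <- validate_outcomes(outcomes)
  nobs <- table(outcomes$patient_id)
  keep_pat <- names(nobs)[nobs >= 2L]
  samples <- samples[samples$patient_id %in% keep_pat, , drop = FALSE]
  si <- match(samples$sample_id, region_matrix$samples)
  if (anyNA(si)) stop("sample table and region matrix disagree on samples")
  outcomes <- outcomes[outcomes$patient_id %in% samples$patient_id, ]

  pid <- factor(outcomes$patient_id, levels = samples$patient_id)
  y <- outcomes$pdds
  tday <- outcomes$day
  ctx <- make_lmm_context(y, pid)
  covX <- if (is.null(use_covariates)) NULL else
    covariate_design(samples, use_covariates)
  base <- cbind(`(Intercept)` = 1, time = tday,
                if (!is.null(covX)) covX[as.integer(pid), , drop = FALSE])

  dens <- region_matrix$density[, si, drop = FALSE]
  nr <- nrow(dens)
  res <- data.frame(region_matrix$regions,
                    beta3 = NA_real_, se3 = NA_real_, df3 = NA_real_,
                    p3 = NA_real_, tested = FALSE,
                    satterthwaite = FALSE)
  for (r in seq_len(nr)) {
    d <- dens[r, ]
    if (anyNA(d)) next                      # candidate regions are complete
    g_pat <- as.numeric(d > median(d))      # ties -> Low
    if (all(g_pat == g_pat[1])) next
    g <- g_pat[as.integer(pid)]
    X <- cbind(base, group = g, time_group = tday * g)
    fit <- lmm_ranint(y, X, pid, test_col = ncol(X), ctx = ctx)
    if (!fit$converged || !is.finite(fit$p)) next
    res$beta3[r] <- fit$beta; res$se3[r] <- fit$se; res$df3[r] <- fit$df
    res$p3[r] <- fit$p; res$tested[r] <- TRUE
    res$satterthwaite[r] <- fit$satterthwaite
  }
  n_tested <- sum(res$tested)
  res$p3_adjusted <- NA_real_
  res$p3_adjusted[res$tested] <- pmin(res$p3[res$tested] * n_tested, 1)
  res$rank_score <- abs(res$beta3) *
    -log10(pmax(res$p3_adjusted, 1e-300))
  attr(res, "n_tested") <- n_tested
  attr(res, "alpha") <- alpha
  class(res) <- c("PrognosticRegionResult", "data.frame")
  res
}

#' Rank prognostic regions and select the scoring set
#'
#' Informativeness is `rank_score = |beta3| * -log10(p3_adjusted)`. With
#' `direction = "top"`, regions are first restricted to
#' `p3_adjusted < alpha` and the `k` highest scores are kept (ties broken
#' by smaller adjusted p, then genomic order); fewer than `k` significant
#' regions returns them all with a warning. With `direction = "bottom"`,
#' the `k` least informative tested regions are returned (no significance
#' filter: the control set is deliberately drawn from the uninformative
#' end of the ranking).
#'
#' Ties in `rank_score` are broken by smaller adjusted p, then smaller
#' absolute effect for the bottom set (so the control is genuinely the
#' least informative end), then genomic order.
#'
#' @param results a [lmm_screen()] table.
#' @param k number of regions (default 100).
#' @param alpha threshold on `p3_adjusted` for the top set.
#' @param direction "top" or "bottom".
#' @return subset of `results` with a `weight` column (= `beta3`).
#' @export
rank_and_select <- function(results, k = 100L, alpha = 0.01,
                            direction = c("top", "bottom")) {
  direction <- match.arg(direction)
  cand <- results[results$tested, , drop = FALSE]
  if (!nrow(cand)) stop("no tested regions to rank")
  if (direction == "top") {
    cand <- cand[cand$p3_adjusted < alpha, , drop = FALSE]
    if (!nrow(cand)) stop("no regions pass the adjusted-p threshold")
    if (nrow(cand) < k)
      warning("only ", nrow(cand), " significant regions (< k = ", k, ")")
    o <- order(-cand$rank_score, cand$p3_adjusted, cand$chrom, cand$start)
  } else {
    o <- order(cand$rank_score, -cand$p3_adjusted, abs(cand$beta3),
               cand$chrom, cand$start)
  }
  sel <- cand[head(o, k), , drop = FALSE]
  sel$weight <- sel$beta3
  rownames(sel) <- NULL
  sel
}

#' Methylation-based progression risk score (MBPRS)
#'
#' Weighted sum of baseline methylation at the selected regions, the
#' weights being the interaction effect sizes from the mixed-model screen.
#' Missing baselines are kNN-imputed first. Patients are split High/Low at
#' the cohort median score (ties to Low).
#'
#' @param region_matrix `RegionMethylationMatrix` restricted to the
#'   selected regions (rows aligned with `weights`).
#' @param weights per-region weights.
#' @param k_impute neighbours for [knn_impute()].
#' @return data.frame: `sample_id`, `score`, `group` ("High"/"Low").
#' @export
compute_mbprs <- function(region_matrix, weights, k_impute = 10L) {
  if (length(weights) != nrow(region_matrix$density))
    stop("one weight per region required")
  if (all(weights == 0))
    stop("all weights are zero; check the selection step")
  dens <- knn_impute(region_matrix, k = k_impute)$density
  score <- drop(crossprod(dens, weights))
  grp <- ifelse(score > median(score), "High", "Low")
  data.frame(sample_id = region_matrix$samples, score = score,
             group = grp, stringsAsFactors = FALSE)
}

#' Derive progression-free survival records from outcome series
#'
#' The event is the first visit with PDDS >= 4 (needing ambulatory
#' assistance); patients without one are censored at their last visit.
#' Patients already at PDDS >= 4 at baseline cannot progress under this
#' definition and are excluded by default (`baseline_policy = "exclude"`);
#' `"event_at_0"` records an immediate event instead.
#'
#' @param outcomes longitudinal PDDS table.
#' @param baseline_policy see above.
#' @return data.frame: `patient_id`, `time` (days), `event` (0/1).
#' @export
survival_records <- function(outcomes,
                             baseline_policy = c("exclude", "event_at_0")) {
  baseline_policy <- match.arg(baseline_policy)
  outcomes <- validate_outcomes(outcomes)
  recs <- lapply(split(outcomes, outcomes$patient_id), function(o) {
    if (o$pdds[1] >= 4L) {
      if (baseline_policy == "exclude") return(NULL)
      return(data.frame(patient_id = o$patient_id[1], time = 0, event = 1L))
    }
    hit <- which(o$pdds >= 4L)
    if (length(hit))
      data.frame(patient_id = o$patient_id[1], time = o$day[hit[1]],
                 event = 1L)
    else
      data.frame(patient_id = o$patient_id[1], time = o$day[nrow(o)],
                 event = 0L)
  })
  excluded <- sum(vapply(recs, is.null, logical(1)))
  if (excluded > 0)
    message(excluded, " patient(s) at PDDS >= 4 at baseline excluded from PFS")
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Two-group log-rank test on progression-free survival
#'
#' @param group named ("High"/"Low") or two-level grouping per record.
#' @param records a [survival_records()] table aligned with `group`.
#' @return list: `chisq`, `p`, `fit` (Kaplan-Meier `survfit`), `n_events`.
#' @export
pfs_logrank <- function(group, records) {
  g <- factor(group)
  if (nlevels(g) != 2L) stop("log-rank needs exactly two groups")
  sd_ <- survival::survdiff(
    survival::Surv(records$time, records$event) ~ g)
  p <- pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  fit <- survival::survfit(
    survival::Surv(records$time, records$event) ~ g)
  list(chisq = unname(sd_$chisq), p = p, fit = fit,
       n_events = sum(records$event))
}

#' Matched-random-interval permutation control for the MBPRS
#'
#' Repeats the MBPRS construction with the original weights but
#' methylation measured at random intervals matched to the selected
#' regions in chromosome and length, re-splitting at the median and
#' re-running the log-rank test each time. The empirical p-value is
#' `(1 + #{perm p <= observed p}) / (n_perm + 1)`.
#'
#' @param weights selected-region weights.
#' @param selected_regions the intervals the weights belong to.
#' @param layout data.frame `chrom`, `length`.
#' @param counts the `CpGCountMatrix` methylation is measured from.
#' @param records survival records for the scored patients (aligned with
#'   `counts$samples` via `sample_to_patient`).
#' @param sample_to_patient named map sample_id -> patient_id.
#' @param observed_p the log-rank p of the real MBPRS split.
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @return list: `empirical_p`, `perm_p` (vector), `observed_p`.
#' @export
permutation_control <- function(weights, selected_regions, layout, counts,
                                records, sample_to_patient, observed_p,
                                n_perm = 1000L, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  perm_p <- rep(NA_real_, n_perm)
  pat <- sample_to_patient[counts$samples]
  ri <- match(records$patient_id, pat)
  if (anyNA(ri)) stop("records contain patients without a scored sample")
  ctx <- region_sums_ctx(counts)
  for (b in seq_len(n_perm)) {
    rint <- matched_random_intervals(selected_regions, layout, 1L)
    s <- region_sums(counts, rint, ctx)
    dens <- s$meth / s$total
    dens[s$total == 0] <- NA_real_
    ok_rows <- rowSums(!is.na(dens)) > 0L
    if (!any(ok_rows) || all(weights[ok_rows] == 0)) next
    sc <- compute_mbprs(
      region_methylation_matrix(rint[ok_rows, , drop = FALSE],
                                dens[ok_rows, , drop = FALSE],
                                counts$samples),
      weights[ok_rows])
    grp <- sc$group[ri]
    if (length(unique(grp)) < 2L) next
    perm_p[b] <- pfs_logrank(grp, records)$p
  }
  # degenerate permutations (no covered region, or a one-sided split)
  # count as non-extreme, keeping the estimate conservative
  emp <- (1 + sum(perm_p <= observed_p, na.rm = TRUE)) / (n_perm + 1)
  list(empirical_p = emp, perm_p = perm_p, observed_p = observed_p)
}

#' MBPRS stratification and validation in one call
#'
#' Convenience wrapper running the full risk-score stage on a screened
#' cohort: region selection, MBPRS computation, median split, log-rank
#' test on progression-free survival, the matched-interval permutation
#' control, and the bottom-of-ranking control split.
#'
#' @param screen a [lmm_screen()] result.
#' @param region_matrix,counts,samples,outcomes,layout cohort objects as
#'   produced by [simulate_prognosis_cohort()] or built from real data.
#' @param k regions per set (default 100).
#' @param n_perm permutations for the matched-interval control.
#' @param seed integer seed for the permutation draws.
#' @return list: `selected`, `mbprs`, `logrank_p`, `empirical_p`,
#'   `bottom_logrank_p`, `records`.
#' @export
mbprs_analysis <- function(screen, region_matrix, counts, samples,
                           outcomes, layout, k = 100L, n_perm = 1000L,
                           seed = 1L) {
  key <- function(df) paste(df$chrom, df$start)
  s2p <- setNames(samples$patient_id, samples$sample_id)
  records <- survival_records(outcomes)

  score_set <- function(sel) {
    idx <- match(key(sel), key(region_matrix$regions))
    rm_ <- region_methylation_matrix(
      region_matrix$regions[idx, , drop = FALSE],
      region_matrix$density[idx, , drop = FALSE], region_matrix$samples)
    mb <- compute_mbprs(rm_, sel$weight)
    grp <- mb$group[match(records$patient_id, s2p[mb$sample_id])]
    list(mbprs = mb, lr = pfs_logrank(grp, records))
  }

  sel <- rank_and_select(screen, k = k)
  top <- score_set(sel)
  perm <- permutation_control(
    sel$weight, genomic_intervals(sel$chrom, sel$start, sel$end),
    layout, counts, records, s2p, top$lr$p, n_perm = n_perm, seed = seed)
  bottom <- score_set(rank_and_select(screen, k = k, direction = "bottom"))
  list(selected = sel, mbprs = top$mbprs, logrank_p = top$lr$p,
       empirical_p = perm$empirical_p, bottom_logrank_p = bottom$lr$p,
       records = records)
}
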