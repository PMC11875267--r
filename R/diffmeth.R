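## Per-CpG beta-binomial regression, neighbour p-value combination and DMR
## calling for low-coverage WGBS count data.

# Negative beta-binomial log-likelihood with logit-linear mean and
# site-level dispersion rho = plogis(par[last]). Binomial-coefficient
# constants are dropped (they cancel in likelihood ratios).
bb_negll <- function(par, y, n, X) {
  eta <- drop(X %*% par[-length(par)])
  mu <- plogis(eta)
  rho <- plogis(par[length(par)])
  t <- (1 - rho) / rho
  a <- mu * t; b <- (1 - mu) * t
  ll <- lbeta(y + a, n - y + b) - lbeta(a, b)
  if (any(!is.finite(ll))) return(1e10)
  -sum(ll)
}

# Same likelihood with the dispersion held fixed.
bb_negll_fixrho <- function(beta, y, n, X, rho) {
  bb_negll(c(beta, qlogis(rho)), y, n, X)
}

# Analytic gradient of bb_negll_fixrho with respect to the mean
# coefficients (logit link).
bb_grad_fixrho <- function(beta, y, n, X, rho) {
  mu <- plogis(drop(X %*% beta))
  t <- (1 - rho) / rho
  a <- mu * t; b <- (1 - mu) * t
  w <- mu * (1 - mu) * t *
    (digamma(y + a) - digamma(a) - digamma(n - y + b) + digamma(b))
  -drop(crossprod(X, w))
}

# Numerical log-determinant of the observed information for the mean
# parameters at their optimum (Cox-Reid adjustment term).
bb_beta_info_logdet <- function(beta, y, n, X, rho) {
  p <- length(beta)
  f <- function(b) bb_negll_fixrho(b, y, n, X, rho)
  h <- pmax(abs(beta), 1) * 1e-4
  H <- matrix(0, p, p)
  f0 <- f(beta)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h[i])
    H[i, i] <- (f(beta + ei) - 2 * f0 + f(beta - ei)) / h[i]^2
    if (i < p) for (j in seq((i + 1), p)) {
      ej <- replace(numeric(p), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(beta + ei + ej) - f(beta + ei - ej) -
           f(beta - ei + ej) + f(beta - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  d <- determinant(H, logarithm = TRUE)
  if (d$sign <= 0) return(NA_real_)
  as.numeric(d$modulus)
}

#' Beta-binomial likelihood-ratio test at one CpG
#'
#' Fits a beta-binomial model with logit-linear mean (intercept + group +
#' optional covariate) and a site-level dispersion. The dispersion is
#' estimated under the full model by maximizing the Cox-Reid adjusted
#' profile likelihood (the adjustment compensates the downward bias of the
#' plain profile estimate, which would make the likelihood-ratio test
#' anticonservative at cohort-scale sample sizes), then held fixed while
#' the full and reduced (no group) mean models are maximized. The p-value
#' refers the likelihood-ratio statistic to an F(1, n - p) distribution
#' (n covered samples, p mean parameters), the quasi-likelihood-style
#' small-sample reference; it converges to the chi-square(1) test as n
#' grows. The dispersion search is floored at 1e-6, where the likelihood
#' coincides with the binomial.
#'
#' @param y,n methylated and total counts per sample.
#' @param group factor or 0/1 indicator (reference level first).
#' @param covariate optional factor (e.g. sex) adjusted in both models.
#' @param min_per_group minimum covered samples required per group.
#' @return list: `tested`, `mean_ref`, `mean_alt`, `delta`
#'   (alt - ref pooled densities), `lrt`, `p_raw`, `rho`.
#' @export
fit_site_test <- function(y, n, group, covariate = NULL,
                          min_per_group = 2L) {
  g <- if (is.factor(group)) as.integer(group) - 1L else as.integer(group)
  keep <- n > 0
  untested <- list(tested = FALSE, mean_ref = NA_real_, mean_alt = NA_real_,
                   delta = NA_real_, lrt = NA_real_, p_raw = NA_real_,
                   rho = NA_real_)
  if (sum(keep & g == 0L) < min_per_group ||
      sum(keep & g == 1L) < min_per_group) return(untested)
  y <- y[keep]; n <- n[keep]; g <- g[keep]
  mean_ref <- sum(y[g == 0L]) / sum(n[g == 0L])
  mean_alt <- sum(y[g == 1L]) / sum(n[g == 1L])
  delta <- mean_alt - mean_ref
  if (sum(y) == 0L || sum(y) == sum(n))   # no variation: full == reduced
    return(list(tested = TRUE, mean_ref = mean_ref, mean_alt = mean_alt,
                delta = delta, lrt = 0, p_raw = 1, rho = 0))
  Xr <- cbind(intercept = rep(1, length(y)))
  if (!is.null(covariate))
    Xr <- cbind(Xr, model.matrix(~ covariate)[keep, -1, drop = FALSE])
  Xf <- cbind(Xr[, 1, drop = FALSE], group = g, Xr[, -1, drop = FALSE])
  p0 <- min(max(sum(y) / sum(n), 1e-3), 1 - 1e-3)
  pa <- min(max(mean_alt, 1e-3), 1 - 1e-3)
  pr <- min(max(mean_ref, 1e-3), 1 - 1e-3)
  sf <- c(qlogis(pr), qlogis(pa) - qlogis(pr), rep(0, ncol(Xf) - 2L))
  sr <- c(qlogis(p0), rep(0, ncol(Xr) - 1L))
  fit_beta <- function(rho, X, start) {
    ft <- optim(start, bb_negll_fixrho, gr = bb_grad_fixrho,
                y = y, n = n, X = X, rho = rho, method = "BFGS",
                control = list(maxit = 100, reltol = 1e-10))
    ft
  }
  warm <- sf                  # warm start shared across the profile search
  apl <- function(rho) {      # negative Cox-Reid adjusted profile loglik
    ft <- fit_beta(rho, Xf, warm)
    warm <<- ft$par
    ld <- bb_beta_info_logdet(ft$par, y, n, Xf, rho)
    if (!is.finite(ld)) return(1e10)
    ft$value + 0.5 * ld
  }
  ropt <- optimize(apl, interval = c(1e-6, 0.9), tol = 2e-3)
  rho <- ropt$minimum
  ff <- fit_beta(rho, Xf, sf)
  fr <- fit_beta(rho, Xr, sr)
  lrt <- max(0, 2 * (fr$value - ff$value))
  df2 <- max(length(y) - ncol(Xf), 1L)
  list(tested = TRUE, mean_ref = mean_ref, mean_alt = mean_alt,
       delta = delta, lrt = lrt,
       p_raw = stats::pf(lrt, 1, df2, lower.tail = FALSE),
       rho = rho)
}

#' Genome-wide beta-binomial differential methylation scan
#'
#' Applies [fit_site_test()] at every CpG of a count matrix. Sites without
#' at least `min_per_group` covered samples in each group are recorded as
#' untested.
#'
#' @param counts a `CpGCountMatrix`.
#' @param group per-sample group factor/indicator (reference first).
#' @param covariate optional per-sample covariate (e.g. sex).
#' @param min_per_group coverage requirement per group.
#' @return data.frame with site coordinates, group means, `delta`, `lrt`,
#'   `p_raw`, `tested`.
#' @export
dm_scan <- function(counts, group, covariate = NULL, min_per_group = 2L) {
  ns <- nrow(counts$meth)
  res <- vector("list", ns)
  for (i in seq_len(ns)) {
    res[[i]] <- fit_site_test(counts$meth[i, ], counts$total[i, ], group,
                              covariate, min_per_group)
  }
  out <- data.frame(chrom = counts$sites$chrom, pos = counts$sites$pos,
                    tested = vapply(res, `[[`, logical(1), "tested"),
                    mean_ref = vapply(res, `[[`, numeric(1), "mean_ref"),
                    mean_alt = vapply(res, `[[`, numeric(1), "mean_alt"),
                    delta = vapply(res, `[[`, numeric(1), "delta"),
                    lrt = vapply(res, `[[`, numeric(1), "lrt"),
                    p_raw = vapply(res, `[[`, numeric(1), "p_raw"))
  out
}

#' Combine neighbouring p-values by an autocorrelation-corrected Stouffer sum
#'
#' Raw p-values are converted to upper-tail z-scores and summed over a
#' centred window of adjacent tested CpGs; the sum's variance is inflated by
#' the empirical lag-autocorrelation of the z series, and the combined
#' p-value is the upper-tail normal probability. A single window size is
#' applied to all sites. With `window = NULL` the size is chosen from the
#' data: 1 plus the run of consecutive positive significant lags of the z
#' autocorrelation (capped at `max_window`), so that under a global null
#' the window collapses to 1 and combined p-values equal the raw ones.
#'
#' @param p raw p-values of tested sites, in genomic order.
#' @param window fixed window size in CpGs, or `NULL` to select from the
#'   autocorrelation structure.
#' @param max_window largest window considered during selection.
#' @param correct_autocorr apply the empirical autocorrelation variance
#'   correction (disable only for closed-form checks).
#' @return list: `p_combined`, `window`, `acf` (lag correlations used).
#' @export
combine_neighbors <- function(p, window = NULL, max_window = 100L,
                              correct_autocorr = TRUE) {
  m <- length(p)
  z <- qnorm(pmin(pmax(p, 1e-15), 1 - 1e-15), lower.tail = FALSE)
  max_window <- min(max_window, m)
  r <- rep(0, max(max_window - 1L, 1L))
  if (m > 3L && sd(z) > 0) {
    zc <- z - mean(z)
    denom <- sum(zc^2)
    for (l in seq_len(min(max_window - 1L, m - 2L)))
      r[l] <- sum(zc[seq_len(m - l)] * zc[seq_len(m - l) + l]) / denom
  }
  if (is.null(window)) {
    thr <- qnorm(0.975) / sqrt(m)
    sig <- r > thr
    run <- if (length(sig) && sig[1]) which(!sig)[1] - 1L else 0L
    if (is.na(run)) run <- length(sig)
    window <- min(1L + run, max_window)
  }
  if (!correct_autocorr) r[] <- 0
  w <- as.integer(window)
  if (w <= 1L) return(list(p_combined = p, window = 1L, acf = r))
  lo <- pmax(seq_len(m) - ((w - 1L) %/% 2L), 1L)
  hi <- pmin(lo + w - 1L, m)
  lo <- pmax(hi - w + 1L, 1L)
  cz <- c(0, cumsum(z))
  sums <- cz[hi + 1L] - cz[lo]
  wi <- hi - lo + 1L
  lags <- seq_len(w - 1L)
  varw <- vapply(unique(wi), function(k)
    k + 2 * sum((k - lags[lags < k]) * r[lags[lags < k]]), numeric(1))
  names(varw) <- unique(wi)
  v <- pmax(varw[as.character(wi)], wi * 0.05)
  pc <- pnorm(sums / sqrt(v), lower.tail = FALSE)
  list(p_combined = as.numeric(pc), window = w, acf = r)
}

#' Call differentially methylated regions from site-level results
#'
#' Merges maximal runs of consecutive tested CpGs that pass the combined
#' p-value threshold with a consistent direction (sign of delta) and
#' inter-CpG gaps at most `max_gap_bp`. Untested CpGs break runs. Candidate
#' regions are retained when the minimum site q-value (Benjamini-Hochberg
#' over combined p-values of tested sites) is below `q_threshold` and the
#' absolute mean delta exceeds `delta_threshold`.
#'
#' @param sites data.frame from [dm_scan()] with a `p_combined` column
#'   (added by [combine_neighbors()]); a `q` column is computed when
#'   absent.
#' @param p_threshold run-membership threshold on combined p.
#' @param q_threshold,delta_threshold retention filters.
#' @param max_gap_bp largest within-run gap in base pairs.
#' @return data.frame of DMR calls: `chrom`, `start`, `end`, `n_cpgs`,
#'   `mean_delta`, `min_q`, `direction`.
#' @export
call_dmrs <- function(sites, p_threshold = 0.1, q_threshold = 0.1,
                      delta_threshold = 0.1, max_gap_bp = 500L) {
  if (is.null(sites$q)) {
    sites$q <- NA_real_
    sites$q[sites$tested] <- p.adjust(sites$p_combined[sites$tested], "BH")
  }
  sig <- sites$tested & !is.na(sites$p_combined) &
    sites$p_combined < p_threshold & sites$delta != 0
  dir <- sign(sites$delta)
  n <- nrow(sites)
  # run breaks: non-significant site, chrom change, direction flip, long gap
  new_run <- rep(TRUE, n)
  if (n > 1) {
    same <- sig[-1] & sig[-n] &
      sites$chrom[-1] == sites$chrom[-n] &
      dir[-1] == dir[-n] &
      (sites$pos[-1] - sites$pos[-n]) <= max_gap_bp
    new_run[-1] <- !same
  }
  run_id <- cumsum(new_run)
  keep <- which(sig)
  if (!length(keep))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpgs = integer(),
                      mean_delta = numeric(), min_q = numeric(),
                      direction = character()))
  spl <- split(keep, run_id[keep])
  out <- do.call(rbind, lapply(spl, function(i) {
    data.frame(chrom = sites$chrom[i[1]],
               start = sites$pos[i[1]],
               end = sites$pos[i[length(i)]] + 1L,
               n_cpgs = length(i),
               mean_delta = mean(sites$delta[i]),
               min_q = min(sites$q[i]),
               direction = if (sign(sites$delta[i[1]]) > 0) "hyper" else "hypo")
  }))
  out <- out[out$min_q < q_threshold &
               abs(out$mean_delta) > delta_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full differential methylation pipeline
#'
#' Scan, neighbour combination, BH adjustment and DMR calling in one call.
#'
#' @inheritParams dm_scan
#' @inheritParams call_dmrs
#' @param max_window see [combine_neighbors()].
#' @return list: `sites` (per-CpG table with `p_combined` and `q`),
#'   `dmrs`, `window` (combination window used).
#' @export
dm_pipeline <- function(counts, group, covariate = NULL,
                        min_per_group = 2L, max_window = 100L,
                        p_threshold = 0.1, q_threshold = 0.1,
                        delta_threshold = 0.1, max_gap_bp = 500L) {
  sites <- dm_scan(counts, group, covariate, min_per_group)
  sites$p_combined <- NA_real_
  comb <- combine_neighbors(sites$p_raw[sites$tested],
                            max_window = max_window)
  sites$p_combined[sites$tested] <- comb$p_combined
  sites$q <- NA_real_
  sites$q[sites$tested] <- p.adjust(sites$p_combined[sites$tested], "BH")
  dmrs <- call_dmrs(sites, p_threshold, q_threshold, delta_threshold,
                    max_gap_bp)
  list(sites = sites, dmrs = dmrs, window = comb$window)
}
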