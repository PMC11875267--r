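## DMR feature-matrix construction (missingness filter, kNN imputation,
## SVD with elbow selection) and chromatin-state enrichment against
## matched random intervals.

#' Filter regions by missing-data fraction
#'
#' Regions whose missing fraction across samples is `>= max_missing` are
#' removed (strict: a region at exactly the threshold is dropped); order is
#' preserved.
#'
#' @param x a `RegionMethylationMatrix`.
#' @param max_missing maximum tolerated missing fraction (default 0.8:
#'   regions with less than 80 percent missing data are retained).
#' @export
filter_missingness <- function(x, max_missing = 0.8) {
  frac <- rowMeans(is.na(x$density))
  keep <- frac < max_missing
  if (!any(keep)) warning("all regions exceed the missingness threshold")
  region_methylation_matrix(x$regions[keep, , drop = FALSE],
                            x$density[keep, , drop = FALSE], x$samples)
}

#' k-nearest-neighbour imputation of missing region methylation
#'
#' A missing cell is replaced by the mean over the `k` nearest regions
#' (Euclidean distance computed on the samples observed in both regions,
#' scaled to the full sample count), using only neighbours observed for the
#' target sample. Observed cells are unchanged; imputed values are clipped
#' to `[0, 1]`. Rows with no observed value are an error (they should have
#' been filtered upstream).
#'
#' @param x a `RegionMethylationMatrix` (or plain matrix).
#' @param k number of neighbouring regions.
#' @return object of the same type, complete.
#' @export
knn_impute <- function(x, k = 10L) {
  mat <- if (inherits(x, "RegionMethylationMatrix")) x$density else as.matrix(x)
  if (!anyNA(mat)) return(x)
  nobs <- rowSums(!is.na(mat))
  if (any(nobs == 0L))
    stop("region(s) with zero observed values; filter before imputing")
  nr <- nrow(mat)
  miss_rows <- which(rowSums(is.na(mat)) > 0L)
  filled <- mat
  for (i in miss_rows) {
    d <- row_distances(mat, i)
    ord <- order(d)
    for (j in which(is.na(mat[i, ]))) {
      donors <- ord[!is.na(mat[ord, j]) & ord != i]
      use <- head(donors, k)
      v <- if (length(use)) mean(mat[use, j]) else
        mean(mat[i, ], na.rm = TRUE)      # isolated row: fall back to row mean
      filled[i, j] <- min(max(v, 0), 1)
    }
  }
  if (inherits(x, "RegionMethylationMatrix")) {
    x$density <- filled
    x
  } else filled
}

# Euclidean distances from row i to all rows over shared observed samples,
# rescaled by the fraction observed (as impute.knn-style imputers do).
row_distances <- function(mat, i) {
  diffs <- sweep(mat, 2, mat[i, ])
  shared <- !is.na(diffs)
  d2 <- rowSums(diffs^2, na.rm = TRUE) * ncol(mat) / pmax(rowSums(shared), 1)
  d2[rowSums(shared) == 0L] <- Inf
  d2[i] <- Inf
  sqrt(d2)
}

#' SVD feature decomposition of a region methylation matrix
#'
#' Regions (rows) are standardized to zero mean, unit variance
#' (zero-variance regions dropped with a warning), then a singular value
#' decomposition of the region x sample matrix is taken. Sample scores for
#' the top `k` components are returned; each component is oriented so its
#' largest-magnitude sample score is positive, making outputs reproducible
#' under sign indeterminacy.
#'
#' With `k = "elbow"` the number of retained components is the elbow of the
#' variance-explained curve over the first 50 components: the point with
#' the largest second difference.
#'
#' @param x complete `RegionMethylationMatrix` or matrix (regions x samples).
#' @param k integer number of components, or `"elbow"`.
#' @return list of class `FeatureDecomposition`: `scores` (sample x k),
#'   `d` (singular values), `variance_explained`, `retained_k`.
#' @export
svd_features <- function(x, k = "elbow") {
  mat <- if (inherits(x, "RegionMethylationMatrix")) x$density else as.matrix(x)
  if (anyNA(mat)) stop("matrix must be complete; impute first")
  v <- apply(mat, 1, var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance region(s) dropped")
    mat <- mat[v > 0, , drop = FALSE]
  }
  z <- t(scale(t(mat)))
  sv <- svd(z)
  ve <- sv$d^2 / sum(sv$d^2)
  retained <- if (identical(k, "elbow")) elbow_point(ve) else
    min(as.integer(k), length(sv$d))
  scores <- sv$v[, seq_len(retained), drop = FALSE] %*%
    diag(sv$d[seq_len(retained)], retained)
  for (j in seq_len(retained)) {
    if (scores[which.max(abs(scores[, j])), j] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- colnames(mat)
  structure(list(scores = scores, d = sv$d, variance_explained = ve,
                 retained_k = retained),
            class = "FeatureDecomposition")
}

elbow_point <- function(ve, max_k = 50L) {
  ve <- ve[seq_len(min(max_k, length(ve)))]
  if (length(ve) < 3L) return(length(ve))
  second <- ve[-c(length(ve) - 1L, length(ve))] - 2 * ve[-c(1L, length(ve))] +
    ve[-c(1L, 2L)]
  which.max(second) + 1L
}

#' Chromatin-state enrichment of a region set vs matched random intervals
#'
#' For each annotation state, builds the 2x2 table of query vs
#' matched-random intervals crossed with overlapping vs not overlapping the
#' state, and applies the two-sided Fisher exact test; q-values are
#' Benjamini-Hochberg across states. Matched randoms are drawn per query
#' region on the same chromosome with identical length and uniform start.
#' Overlap means >= 1 bp intersection by default; set `min_frac` to require
#' a fraction of the region instead.
#'
#' @param regions query intervals.
#' @param annotation intervals with a `name` column holding state labels.
#' @param layout data.frame `chrom`, `length` giving placeable extents.
#' @param n_draws matched random intervals per query region.
#' @param seed integer seed for the draws.
#' @param min_frac minimum overlapping fraction of the region (0 = any bp).
#' @return data.frame: `state`, `odds_ratio` (sample OR of the 2x2 table),
#'   `p`, `q`, `direction` (enriched/depleted), counts.
#' @export
enrichment <- function(regions, annotation, layout, n_draws = 10L,
                       seed = 1L, min_frac = 0) {
  if (!is.null(seed)) set.seed(seed)
  rand <- matched_random_intervals(regions, layout, n_draws)
  states <- sort(unique(annotation$name))
  q_n <- nrow(regions); r_n <- nrow(rand)
  out <- lapply(states, function(st) {
    ann <- annotation[annotation$name == st, , drop = FALSE]
    a <- sum(overlaps_any(regions, ann, min_frac))
    c_ <- sum(overlaps_any(rand, ann, min_frac))
    b <- q_n - a; d_ <- r_n - c_
    ft <- fisher.test(matrix(c(a, b, c_, d_), 2), alternative = "two.sided")
    or_sample <- (a * d_) / max(b * c_, .Machine$double.eps)
    data.frame(state = st, odds_ratio = or_sample, p = ft$p.value,
               query_hits = a, random_hits = c_,
               direction = if (a / q_n >= c_ / r_n) "enriched" else "depleted")
  })
  out <- do.call(rbind, out)
  out$q <- p.adjust(out$p, "BH")
  out[c("state", "odds_ratio", "p", "q", "direction",
        "query_hits", "random_hits")]
}

#' Draw random intervals matched on chromosome and length
#'
#' @param regions template intervals.
#' @param layout data.frame `chrom`, `length`.
#' @param n_draws draws per template region.
#' @export
matched_random_intervals <- function(regions, layout, n_draws = 1L) {
  idx <- rep(seq_len(nrow(regions)), each = n_draws)
  len <- regions$end[idx] - regions$start[idx]
  chrom <- regions$chrom[idx]
  maxlen <- layout$length[match(chrom, layout$chrom)]
  if (anyNA(maxlen)) stop("layout missing chromosome(s): ",
                          paste(unique(chrom[is.na(maxlen)]), collapse = ", "))
  room <- pmax(maxlen - len, 0L)
  start <- floor(runif(length(idx)) * (room + 1L))
  genomic_intervals(chrom, start, start + len)
}

# For each interval in a, TRUE if it overlaps any interval in b (same
# chromosome, half-open) with at least min_frac of its own length.
overlaps_any <- function(a, b, min_frac = 0) {
  res <- logical(nrow(a))
  for (ch in unique(a$chrom)) {
    ai <- which(a$chrom == ch)
    bi <- which(b$chrom == ch)
    if (!length(bi)) next
    bs <- b$start[bi]; be <- b$end[bi]
    o <- order(bs); bs <- bs[o]; be <- be[o]
    for (i in ai) {
      ov <- pmin(a$end[i], be) - pmax(a$start[i], bs)
      need <- if (min_frac > 0) min_frac * (a$end[i] - a$start[i]) else 0
      res[i] <- any(ov > need | (min_frac == 0 & ov > 0))
    }
  }
  res
}
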