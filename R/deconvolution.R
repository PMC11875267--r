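## Fragment-level U/X/M tissue-of-origin deconvolution against a marker
## atlas, group comparison of cell-type proportions, and the
## coverage-downsampling power simulation.

#' Classify fragments as U / X / M
#'
#' A fragment with fewer than `min_cpgs` CpG calls is ineligible. Otherwise
#' its methylated fraction f = methylated calls / calls puts it in U
#' (mostly unmethylated, `f <= low`), M (mostly methylated, `f >= high`) or
#' X (mixed). Boundaries are inclusive toward U and M.
#'
#' @param frags a `fragments` table.
#' @param low,high classification thresholds, `0 <= low < high <= 1`.
#' @param min_cpgs minimum CpG calls for eligibility.
#' @return character vector in `{"U","X","M","ineligible"}`.
#' @export
classify_uxm <- function(frags, low = 0.25, high = 0.75, min_cpgs = 3L) {
  stopifnot(low >= 0, low < high, high <= 1)
  f <- frags$nmeth / frags$ncpg
  out <- ifelse(frags$ncpg < min_cpgs, "ineligible",
                ifelse(f <= low, "U", ifelse(f >= high, "M", "X")))
  out
}

#' Per-marker U-fractions of a fragment set
#'
#' Fragments are assigned to markers by interval overlap (a fragment's CpG
#' run intersecting the marker); per marker, the U-fraction is the
#' multiplicity-weighted count of U fragments over all eligible (U+X+M)
#' fragments. Markers with no eligible fragment are `NA`.
#'
#' @param frags a `fragments` table.
#' @param atlas a `MarkerAtlas`.
#' @param low,high,min_cpgs see [classify_uxm()].
#' @return list: `u_fraction` (per marker), `n_eligible` (per marker).
#' @export
marker_u_fractions <- function(frags, atlas, low = 0.25, high = 0.75,
                               min_cpgs = 3L) {
  cls <- classify_uxm(frags, low, high, min_cpgs)
  frag_end <- frags$start + (frags$ncpg - 1L) * atlas$cpg_spacing + 1L
  nm <- nrow(atlas$markers)
  u <- rep(NA_real_, nm); n_el <- integer(nm)
  for (ch in unique(atlas$markers$chrom)) {
    mi <- which(atlas$markers$chrom == ch)
    fi <- which(frags$chrom == ch & cls != "ineligible")
    if (!length(fi)) next
    for (k in mi) {
      hit <- fi[frags$start[fi] < atlas$markers$end[k] &
                  frag_end[fi] > atlas$markers$start[k]]
      if (!length(hit)) next
      w <- frags$mult[hit]
      n_el[k] <- sum(w)
      u[k] <- sum(w[cls[hit] == "U"]) / sum(w)
    }
  }
  list(u_fraction = u, n_eligible = n_el)
}

#' Deconvolve cell-type proportions from marker U-fractions
#'
#' Non-negative least squares fit of the observed per-marker U-fractions to
#' the atlas reference columns over non-missing markers; the solution is
#' normalized to sum to 1.
#'
#' @param u_fractions per-marker U-fraction vector (NA = missing marker).
#' @param atlas a `MarkerAtlas`.
#' @return list of class `DeconvolutionResult`: `proportions` (named, sums
#'   to 1), `n_markers_used`.
#' @export
deconvolve <- function(u_fractions, atlas) {
  ok <- !is.na(u_fractions)
  k <- length(atlas$celltypes)
  if (sum(ok) < k)
    stop("only ", sum(ok), " informative markers for ", k,
         " cell types; need at least as many markers as cell types")
  A <- atlas$reference[ok, , drop = FALSE]
  b <- u_fractions[ok]
  fit <- pracma::lsqnonneg(A, b)
  x <- fit$x
  if (sum(x) <= 0) stop("degenerate NNLS solution (all-zero proportions)")
  props <- x / sum(x)
  names(props) <- atlas$celltypes
  structure(list(proportions = props, n_markers_used = sum(ok)),
            class = "DeconvolutionResult")
}

#' Fragment set to cell-type proportions in one step
#'
#' @param frags fragments of one sample.
#' @param atlas a `MarkerAtlas`.
#' @param ... passed to [marker_u_fractions()].
#' @export
deconvolve_fragments <- function(frags, atlas, ...) {
  uf <- marker_u_fractions(frags, atlas, ...)
  deconvolve(uf$u_fraction, atlas)
}

#' Coverage-downsampling simulation for deconvolution stability
#'
#' Mirrors the sequencing-depth power analysis: a pooled fragment set at
#' known effective coverage is thinned to each target coverage by binomial
#' thinning of multiplicities (keep-probability coverage / total coverage),
#' deconvolved, and the per-cell-type mean and SD of the estimated
#' proportions across repetitions are reported.
#'
#' @param frags pooled fragments.
#' @param atlas a `MarkerAtlas`.
#' @param total_coverage effective coverage of the pool (x).
#' @param coverages target coverage grid (default 0.01x to 12x).
#' @param reps repetitions per coverage (default 100).
#' @param seed integer seed.
#' @return data.frame: `coverage`, `celltype`, `mean`, `sd`, `n_failed`.
#' @export
coverage_simulation <- function(frags, atlas, total_coverage,
                                coverages = c(0.01, 0.05, 0.1, 0.5, 1, 2,
                                              4, 8, 12),
                                reps = 100L, seed = 1L) {
  if (!is.null(seed)) set.seed(seed)
  if (max(coverages) > total_coverage)
    stop("target coverages must not exceed the pool coverage")
  k <- length(atlas$celltypes)
  out <- list()
  for (cv in coverages) {
    keep_p <- cv / total_coverage
    est <- matrix(NA_real_, reps, k)
    failed <- 0L
    for (r in seq_len(reps)) {
      kept <- if (keep_p >= 1) frags$mult else
        rbinom(nrow(frags), frags$mult, keep_p)
      sub <- frags[kept > 0L, , drop = FALSE]
      sub$mult <- kept[kept > 0L]
      res <- tryCatch(deconvolve_fragments(sub, atlas),
                      error = function(e) NULL)
      if (is.null(res)) failed <- failed + 1L else est[r, ] <- res$proportions
    }
    out[[length(out) + 1L]] <- data.frame(
      coverage = cv, celltype = atlas$celltypes,
      mean = colMeans(est, na.rm = TRUE),
      sd = apply(est, 2, sd, na.rm = TRUE),
      n_failed = failed)
  }
  do.call(rbind, out)
}

#' Compare cell-type proportions between groups (Mann-Whitney)
#'
#' One-sided Mann-Whitney U test per cell type (exact when sample sizes
#' permit, normal approximation with tie correction otherwise).
#'
#' @param props matrix or data.frame of per-sample proportions
#'   (samples x cell types).
#' @param group two-level factor/indicator; the alternative is stated for
#'   the second level relative to the first.
#' @param alternative "greater", "less" or "two.sided".
#' @return data.frame: `celltype`, `p`, `alternative`.
#' @export
compare_proportions <- function(props, group, alternative = "greater") {
  props <- as.matrix(props)
  g <- factor(group)
  if (nlevels(g) != 2L) stop("exactly two groups required")
  if (any(table(g) < 2L)) stop("need >= 2 samples per group")
  p <- vapply(seq_len(ncol(props)), function(j) {
    wilcox.test(props[g == levels(g)[2], j], props[g == levels(g)[1], j],
                alternative = alternative)$p.value
  }, numeric(1))
  data.frame(celltype = colnames(props), p = p, alternative = alternative)
}
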