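#' @importFrom stats approx aggregate median optimize optim pnorm qnorm quantile
#'   rbinom rpois rbeta rnorm runif sd var fisher.test wilcox.test p.adjust
#'   ks.test pchisq plogis qlogis setNames predict complete.cases dbinom
#'   model.matrix cor binomial coef glm pt
#' @importFrom utils read.delim write.table head tail
NULL

AUTOSOMES <- paste0("chr", 1:22)

#' Construct a genomic interval table
#'
#' Intervals are 0-based half-open `[start, end)` throughout the package; a
#' CpG at `position == end` is outside the interval.
#'
#' @param chrom character chromosome names.
#' @param start,end integer 0-based half-open bounds, `0 <= start < end`.
#' @return data.frame with class `genomic_intervals`.
#' @export
genomic_intervals <- function(chrom, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0L)) stop("interval start must be >= 0")
  if (any(start >= end)) stop("interval start must be < end (0-based half-open)")
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    stringsAsFactors = FALSE)
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' Construct a per-CpG methylation count matrix
#'
#' Holds methylated and total read counts at each CpG site for each sample.
#' A cell with `total == 0` encodes missing (no coverage); there are no
#' sentinel densities. Sites are stored sorted by `(chrom, pos)` without
#' duplicates.
#'
#' @param chrom,pos site coordinates (0-based CpG positions).
#' @param meth,total integer matrices, sites x samples, `0 <= meth <= total`.
#' @param samples character sample identifiers (column names).
#' @return object of class `CpGCountMatrix` with elements `sites` (data.frame
#'   `chrom`, `pos`), `meth`, `total`, `samples`.
#' @export
cpg_count_matrix <- function(chrom, pos, meth, total, samples) {
  meth <- as.matrix(meth); total <- as.matrix(total)
  chrom <- as.character(chrom); pos <- as.integer(pos)
  if (nrow(meth) != length(pos) || !all(dim(meth) == dim(total)))
    stop("meth/total dimensions must match the site list")
  if (ncol(meth) != length(samples)) stop("sample ids must match columns")
  if (any(meth < 0) || any(total < 0)) stop("counts must be non-negative")
  if (any(meth > total)) stop("validation error: meth > total at some cell")
  o <- order(chrom, pos)
  chrom <- chrom[o]; pos <- pos[o]
  meth <- meth[o, , drop = FALSE]; total <- total[o, , drop = FALSE]
  if (anyDuplicated(paste(chrom, pos))) stop("duplicate CpG sites")
  colnames(meth) <- colnames(total) <- samples
  structure(list(sites = data.frame(chrom = chrom, pos = pos,
                                    stringsAsFactors = FALSE),
                 meth = meth, total = total, samples = as.character(samples)),
            class = "CpGCountMatrix")
}

#' @export
print.CpGCountMatrix <- function(x, ...) {
  cat(sprintf("CpGCountMatrix: %d CpGs x %d samples (%.1f%% cells covered)\n",
              nrow(x$meth), ncol(x$meth), 100 * mean(x$total > 0)))
  invisible(x)
}

#' Methylation densities of a count matrix
#'
#' @param x a `CpGCountMatrix`.
#' @return site x sample matrix of meth/total, `NA` where `total == 0`.
#' @export
cpg_density <- function(x) {
  d <- x$meth / x$total
  d[x$total == 0] <- NA_real_
  d
}

#' Restrict a count matrix to autosomes
#'
#' Non-autosomal records (chrX, chrY, chrM, scaffolds) are dropped; only
#' autosomal CpGs enter any analysis.
#'
#' @param x a `CpGCountMatrix`.
#' @param quiet suppress the dropped-site message.
#' @export
filter_autosomes <- function(x, quiet = FALSE) {
  keep <- x$sites$chrom %in% AUTOSOMES
  if (!quiet && any(!keep))
    message(sum(!keep), " non-autosomal CpG(s) dropped")
  subset_sites(x, keep)
}

subset_sites <- function(x, keep) {
  cpg_count_matrix(x$sites$chrom[keep], x$sites$pos[keep],
                   x$meth[keep, , drop = FALSE], x$total[keep, , drop = FALSE],
                   x$samples)
}

#' Construct a region x sample methylation matrix
#'
#' @param regions a `genomic_intervals` table (or data.frame with
#'   `chrom`, `start`, `end`).
#' @param density regions x samples matrix of methylation densities in
#'   `[0, 1]`, `NA` for missing.
#' @param samples sample identifiers.
#' @return object of class `RegionMethylationMatrix`.
#' @export
region_methylation_matrix <- function(regions, density, samples) {
  density <- as.matrix(density)
  if (nrow(density) != nrow(regions)) stop("density rows must match regions")
  if (ncol(density) != length(samples)) stop("density cols must match samples")
  ok <- is.na(density) | (density >= 0 & density <= 1)
  if (!all(ok)) stop("densities must lie in [0, 1] or be NA")
  colnames(density) <- samples
  structure(list(regions = as.data.frame(regions)[c("chrom", "start", "end")],
                 density = density, samples = as.character(samples)),
            class = "RegionMethylationMatrix")
}

#' @export
print.RegionMethylationMatrix <- function(x, ...) {
  cat(sprintf("RegionMethylationMatrix: %d regions x %d samples (%.1f%% missing)\n",
              nrow(x$density), ncol(x$density), 100 * mean(is.na(x$density))))
  invisible(x)
}

#' Aggregate CpG counts to region methylation densities
#'
#' Region density is the read-weighted mean: sum of methylated counts over
#' the CpGs falling in the half-open interval divided by the sum of totals.
#' Regions with zero total coverage in a sample are missing (`NA`).
#'
#' @param counts a `CpGCountMatrix`.
#' @param regions interval table.
#' @return a `RegionMethylationMatrix`.
#' @export
aggregate_to_regions <- function(counts, regions) {
  s <- region_sums(counts, regions)
  dens <- s$meth / s$total
  dens[s$total == 0] <- NA_real_
  region_methylation_matrix(regions, dens, counts$samples)
}

# Fast interval sums over the sorted site list via per-chromosome cumulative
# sums; shared by aggregation, candidate-region checks and the permutation
# loop, where it is the hot path. The cumulative-sum context can be
# precomputed once and reused across many region sets.
region_sums_ctx <- function(counts) {
  ns <- length(counts$samples)
  out <- list()
  for (ch in unique(counts$sites$chrom)) {
    sidx <- which(counts$sites$chrom == ch)
    cm <- apply(counts$meth[sidx, , drop = FALSE], 2, cumsum)
    ct <- apply(counts$total[sidx, , drop = FALSE], 2, cumsum)
    out[[ch]] <- list(pos = counts$sites$pos[sidx],
                      cm = rbind(0, matrix(cm, ncol = ns)),
                      ct = rbind(0, matrix(ct, ncol = ns)))
  }
  out
}

region_sums <- function(counts, regions, ctx = NULL) {
  if (is.null(ctx)) ctx <- region_sums_ctx(counts)
  nr <- nrow(regions); ns <- length(counts$samples)
  meth_s <- matrix(0, nr, ns); total_s <- matrix(0, nr, ns)
  for (ch in unique(regions$chrom)) {
    cc <- ctx[[ch]]
    ridx <- which(regions$chrom == ch)
    if (is.null(cc)) next
    # half-open: sites with start <= pos < end
    lo <- findInterval(regions$start[ridx] - 0.5, cc$pos) + 1L
    hi <- findInterval(regions$end[ridx] - 0.5, cc$pos)
    nonempty <- hi >= lo
    if (any(nonempty)) {
      i <- ridx[nonempty]
      meth_s[i, ] <- cc$cm[hi[nonempty] + 1L, , drop = FALSE] -
        cc$cm[lo[nonempty], , drop = FALSE]
      total_s[i, ] <- cc$ct[hi[nonempty] + 1L, , drop = FALSE] -
        cc$ct[lo[nonempty], , drop = FALSE]
    }
  }
  list(meth = meth_s, total = total_s)
}
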