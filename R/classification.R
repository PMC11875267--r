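## Leakage-safe cross-validated classification: stratified folds, in-fold
## feature discovery, a configurable model zoo, rank-statistic AUC.

#' Stratified cross-validation fold assignments
#'
#' Each class is shuffled and dealt round-robin across folds, so per-fold
#' class counts differ from the global ratio by at most one sample; every
#' sample appears in exactly one test fold per repeat.
#'
#' @param labels two-level class labels.
#' @param n_folds folds per repeat (default 10).
#' @param repeats number of repeats (default 1; e.g. 100 with 5 folds for
#'   the prognosis setting).
#' @param seed integer seed.
#' @return integer matrix, samples x repeats, entries in `1..n_folds`.
#' @export
make_folds <- function(labels, n_folds = 10L, repeats = 1L, seed = 1L) {
  f <- factor(labels)
  if (nlevels(f) < 2L) stop("labels must contain at least two classes")
  if (min(table(f)) < n_folds && min(table(f)) < 2L)
    stop("too few samples in the smallest class")
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(NA_integer_, length(labels), repeats)
  for (r in seq_len(repeats)) {
    for (lv in levels(f)) {
      i <- sample(which(f == lv))
      out[i, r] <- rep_len(seq_len(n_folds), length(i))
    }
  }
  out
}

#' Area under the ROC curve by the rank statistic
#'
#' Mann-Whitney identity with mid-ranks for ties.
#'
#' @param score predicted scores.
#' @param label 0/1 (or two-level) truth.
#' @export
rank_auc <- function(score, label) {
  y <- as.integer(factor(label)) - 1L
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' In-fold feature discovery
#'
#' Builds a feature definition from training samples only. Two modes:
#' `"dmr"` runs the beta-binomial DMR pipeline on the training fold and
#' defines features as methylation densities at the discovered DMRs;
#' `"tissue"` selects cell types whose deconvolved proportions differ
#' between training classes by a one-sided Mann-Whitney test at `cutoff`.
#' Applying a definition to new samples never touches their labels;
#' missing feature values become zero after the missing-value handling.
#'
#' @param mode "dmr" or "tissue".
#' @param counts training-fold `CpGCountMatrix` (dmr mode).
#' @param labels training labels.
#' @param proportions samples x celltype matrix (tissue mode).
#' @param cutoff Mann-Whitney p cutoff (tissue mode; 1.0 keeps all).
#' @param covariate optional covariate for the DMR scan.
#' @param ... passed to [dm_pipeline()].
#' @return list of class `feature_definition` with an `apply` closure.
#' @export
infold_features <- function(mode = c("dmr", "tissue"), counts = NULL,
                            labels = NULL, proportions = NULL,
                            cutoff = 0.05, covariate = NULL, ...) {
  mode <- match.arg(mode)
  if (mode == "dmr") {
    pipe <- dm_pipeline(counts, labels, covariate = covariate, ...)
    regs <- if (nrow(pipe$dmrs)) genomic_intervals(pipe$dmrs$chrom,
                                                   pipe$dmrs$start,
                                                   pipe$dmrs$end) else NULL
    def <- list(mode = "dmr", regions = regs, dmrs = pipe$dmrs)
    def$apply <- function(new_counts) {
      if (is.null(regs)) return(matrix(0, length(new_counts$samples), 0))
      dens <- t(aggregate_to_regions(new_counts, regs)$density)
      dens[is.na(dens)] <- 0      # missing-at-apply-time becomes zero
      dens
    }
  } else {
    both <- levels(factor(labels))
    ps <- vapply(seq_len(ncol(proportions)), function(j) {
      suppressWarnings(wilcox.test(proportions[labels == both[2], j],
                                   proportions[labels == both[1], j],
                                   alternative = "greater")$p.value)
    }, numeric(1))
    ps2 <- vapply(seq_len(ncol(proportions)), function(j) {
      suppressWarnings(wilcox.test(proportions[labels == both[2], j],
                                   proportions[labels == both[1], j],
                                   alternative = "less")$p.value)
    }, numeric(1))
    keep <- pmin(ps, ps2) < cutoff | cutoff >= 1
    sel <- colnames(proportions)[keep]
    def <- list(mode = "tissue", celltypes = sel)
    def$apply <- function(new_proportions) {
      out <- matrix(0, nrow(new_proportions), length(sel),
                    dimnames = list(NULL, sel))
      hit <- intersect(sel, colnames(new_proportions))
      out[, hit] <- as.matrix(new_proportions[, hit, drop = FALSE])
      out[is.na(out)] <- 0
      out
    }
  }
  class(def) <- "feature_definition"
  def
}

#' Classifier specification
#'
#' @param family "logistic" (L2/elastic-net via glmnet), "svm" (linear or
#'   radial kernel via e1071) or "gbt" (gradient-boosted trees via
#'   xgboost).
#' @param params named hyperparameter list, validated against the family.
#' @param feature_pipeline "raw" or "svd" (top-k training-fold SVD
#'   components; test samples are projected onto the training loadings).
#' @param svd_k components when `feature_pipeline = "svd"`.
#' @export
classifier_spec <- function(family = c("logistic", "svm", "gbt"),
                            params = list(), feature_pipeline = "raw",
                            svd_k = 2L) {
  family <- match.arg(family)
  allowed <- switch(family,
    logistic = c("alpha", "lambda"),
    svm = c("kernel", "cost", "gamma"),
    gbt = c("nrounds", "eta", "max_depth", "subsample"))
  bad <- setdiff(names(params), allowed)
  if (length(bad))
    stop("invalid hyperparameter(s) for ", family, ": ",
         paste(bad, collapse = ", "))
  structure(list(family = family, params = params,
                 feature_pipeline = feature_pipeline, svd_k = svd_k),
            class = "ClassifierSpec")
}

#' Named presets mirroring the published per-comparison model settings
#'
#' These are experiment settings, not algorithms: each maps a comparison to
#' a default model family and hyperparameters.
#'
#' @param name one of "ms_vs_control", "pms_vs_rrms", "arrms_vs_srrms",
#'   "severity", "prognosis".
#' @export
classifier_preset <- function(name) {
  presets <- list(
    ms_vs_control = classifier_spec("logistic",
                                    list(alpha = 0, lambda = 1 / 120),
                                    feature_pipeline = "svd", svd_k = 2L),
    pms_vs_rrms = classifier_spec("svm", list(kernel = "radial", cost = 8)),
    arrms_vs_srrms = classifier_spec("svm",
                                     list(kernel = "radial", cost = 0.1),
                                     feature_pipeline = "svd", svd_k = 3L),
    severity = classifier_spec("gbt", list(nrounds = 200, eta = 0.4,
                                           max_depth = 3,
                                           subsample = 0.667)),
    prognosis = classifier_spec("gbt", list(nrounds = 100, eta = 0.1,
                                            max_depth = 5,
                                            subsample = 0.8)))
  if (!name %in% names(presets))
    stop("unknown preset; available: ", paste(names(presets), collapse = ", "))
  presets[[name]]
}

train_model <- function(x, y, spec) {
  fam <- spec$family
  if (fam == "logistic") {
    alpha <- spec$params$alpha %||% 0
    lambda <- spec$params$lambda %||% 0.01
    fit <- glmnet::glmnet(x, factor(y), family = "binomial", alpha = alpha,
                          lambda = lambda)
    list(predict = function(newx)
      as.numeric(predict(fit, newx = newx, type = "response")))
  } else if (fam == "svm") {
    fit <- e1071::svm(x, factor(y),
                      kernel = spec$params$kernel %||% "radial",
                      cost = spec$params$cost %||% 1,
                      probability = TRUE, scale = apply(x, 2, sd) > 0)
    lv <- levels(factor(y))
    list(predict = function(newx) {
      pr <- attr(predict(fit, newx, probability = TRUE), "probabilities")
      as.numeric(pr[, lv[2]])
    })
  } else {
    y01 <- as.integer(factor(y)) - 1L
    dtrain <- xgboost::xgb.DMatrix(data = x, label = y01)
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    eta = spec$params$eta %||% 0.1,
                    max_depth = spec$params$max_depth %||% 3,
                    subsample = spec$params$subsample %||% 1,
                    nthread = 1),
      data = dtrain, nrounds = spec$params$nrounds %||% 100, verbose = 0)
    list(predict = function(newx)
      as.numeric(predict(fit, xgboost::xgb.DMatrix(newx))))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

transform_features <- function(train_x, test_x, spec) {
  if (spec$feature_pipeline != "svd") return(list(train = train_x,
                                                  test = test_x))
  mu <- colMeans(train_x)
  sdv <- apply(train_x, 2, sd); sdv[sdv == 0] <- 1
  zc <- sweep(sweep(train_x, 2, mu), 2, sdv, "/")
  k <- min(spec$svd_k, dim(zc) - 1L, na.rm = TRUE)
  k <- max(k, 1L)
  sv <- svd(zc, nu = 0, nv = k)
  proj <- function(m) sweep(sweep(m, 2, mu), 2, sdv, "/") %*%
    sv$v[, seq_len(k), drop = FALSE]
  list(train = proj(train_x), test = proj(test_x))
}

#' Cross-validated fit and evaluation
#'
#' For every fold of every repeat: derive features on the training side
#' (either a fixed feature matrix or an in-fold discovery function),
#' transform both sides, fit the classifier, and score the held-out fold.
#' AUC uses the rank statistic; folds whose test side contains a single
#' class are recorded as skipped.
#'
#' @param features samples x features numeric matrix, or a function
#'   `(train_idx)` returning a `feature_definition`-like list with an
#'   `apply(idx)` closure (for in-fold discovery).
#' @param labels two-level labels.
#' @param spec a [classifier_spec()].
#' @param n_folds,repeats,seed fold plan, see [make_folds()].
#' @return list of class `CVResult`: `fold_auc` (matrix folds x repeats),
#'   `mean_auc`, `sd_auc`, `roc` (pooled score/label points),
#'   `n_skipped`.
#' @export
fit_and_eval <- function(features, labels, spec, n_folds = 10L,
                         repeats = 1L, seed = 1L) {
  y <- factor(labels)
  folds <- make_folds(y, n_folds, repeats, seed)
  aucs <- matrix(NA_real_, n_folds, repeats)
  pooled_score <- numeric(0); pooled_lab <- character(0)
  skipped <- 0L
  for (r in seq_len(repeats)) {
    for (k in seq_len(n_folds)) {
      te <- which(folds[, r] == k); tr <- which(folds[, r] != k)
      if (length(unique(y[te])) < 2L) { skipped <- skipped + 1L; next }
      if (is.function(features)) {
        def <- features(tr)
        fx_tr <- def$apply(tr); fx_te <- def$apply(te)
      } else {
        fx_tr <- features[tr, , drop = FALSE]
        fx_te <- features[te, , drop = FALSE]
      }
      if (ncol(fx_tr) == 0L) { skipped <- skipped + 1L; next }
      tf <- transform_features(fx_tr, fx_te, spec)
      mdl <- train_model(tf$train, y[tr], spec)
      sc <- mdl$predict(tf$test)
      aucs[k, r] <- rank_auc(sc, y[te])
      pooled_score <- c(pooled_score, sc)
      pooled_lab <- c(pooled_lab, as.character(y[te]))
    }
  }
  ok <- !is.na(aucs)
  structure(list(fold_auc = aucs, mean_auc = mean(aucs[ok]),
                 sd_auc = sd(aucs[ok]),
                 roc = data.frame(score = pooled_score, label = pooled_lab),
                 n_skipped = skipped),
            class = "CVResult")
}

#' Binary outcome at a fixed post-baseline horizon
#'
#' From interpolated trajectories, label 1 when the PDDS value at the grid
#' point nearest `horizon_day` (within `tolerance` days) is at least the
#' severe cutoff, 0 when at most the mild cutoff; patients in between, or
#' without a grid point near the horizon, are excluded.
#'
#' @param grid interpolated trajectories from [interpolate_pdds()].
#' @param horizon_day evaluation day (default 1000).
#' @param extremes `c(mild_max, severe_min)` PDDS cutoffs (default 1 and 6).
#' @param tolerance largest |grid day - horizon| accepted (default 100).
#' @return data.frame `patient_id`, `label` (0/1) for labelable patients.
#' @export
fixed_horizon_outcome <- function(grid, horizon_day = 1000L,
                                  extremes = c(1, 6), tolerance = 100L) {
  out <- lapply(split(grid, grid$patient_id), function(g) {
    d <- abs(g$day - horizon_day)
    if (min(d) > tolerance) return(NULL)
    v <- g$pdds[which.min(d)]
    if (v >= extremes[2])
      data.frame(patient_id = g$patient_id[1], label = 1L)
    else if (v <= extremes[1])
      data.frame(patient_id = g$patient_id[1], label = 0L)
    else NULL
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(patient_id = character(), label = integer()))
  rownames(res) <- NULL
  res
}
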