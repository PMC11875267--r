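#' Beta-binomial random draws
#'
#' Parameterized by mean `mu` and intra-class correlation `rho` (the
#' overdispersion): counts are Binomial(size, p) with
#' p ~ Beta(mu (1 - rho) / rho, (1 - mu)(1 - rho) / rho). `rho = 0` reduces
#' to the binomial.
#'
#' @param n number of draws.
#' @param size total counts (recycled).
#' @param mu mean methylation in (0, 1).
#' @param rho overdispersion in `[0, 1)`.
#' @export
rbetabinom <- function(n, size, mu, rho) {
  if (any(rho < 0 | rho >= 1)) stop("rho must lie in [0, 1)")
  size <- rep_len(size, n); mu <- rep_len(mu, n); rho <- rep_len(rho, n)
  p <- ifelse(rho == 0, mu,
              rbeta(n, mu * (1 - rho) / rho, (1 - mu) * (1 - rho) / rho))
  rbinom(n, size, p)
}

#' Simulation configuration for the synthetic cohort generator
#'
#' Defaults emulate the study conditions of a low-coverage plasma cfDNA
#' WGBS cohort: ~1.5 reads per CpG, beta-binomial overdispersion, a bimodal
#' baseline methylation landscape, and DMRs planted as logit-scale shifts in
#' the affected group.
#'
#' @param n_per_group named integer vector of samples per group.
#' @param n_cpgs number of CpGs to simulate.
#' @param cpg_spacing base pairs between adjacent CpGs.
#' @param coverage_mean mean reads per CpG (Poisson).
#' @param dispersion beta-binomial intra-class correlation rho in (0,1).
#' @param n_dmrs,dmr_size_cpgs planted DMR count and width in CpGs.
#' @param dmr_effect logit-scale mean shift in the affected group.
#' @param dmr_groups group label(s) receiving the shift.
#' @param mu_shapes Beta shape pairs for the bimodal baseline mixture.
#' @param dmr_mu_shape Beta shape pair for baselines at planted DMR CpGs
#'   (mid-range, so logit shifts translate into sizeable density
#'   differences, as regulatory-region DMRs do).
#' @param trajectory list of longitudinal-model parameters: `beta0`
#'   (latent baseline PDDS), `beta1` (PDDS/day drift), `beta3`
#'   (PDDS/day time-by-biomarker-group interaction), `sigma_u` (SD of the
#'   per-patient random intercept), `sigma_eps` (residual SD),
#'   `visit_spacing_days`, `n_visits`.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @export
sim_config <- function(n_per_group = c(Control = 20, `S-RRMS` = 20),
                       n_cpgs = 10000L, cpg_spacing = 100L,
                       coverage_mean = 1.5, dispersion = 0.1,
                       n_dmrs = 50L, dmr_size_cpgs = 5L,
                       dmr_effect = 1.4,
                       dmr_groups = names(n_per_group)[-1],
                       mu_shapes = list(c(2, 8), c(8, 2)),
                       dmr_mu_shape = c(5, 5),
                       trajectory = list(beta0 = 1.5, beta1 = 3e-4,
                                         beta3 = 2e-3, sigma_u = 0.5,
                                         sigma_eps = 0.5,
                                         visit_spacing_days = 250,
                                         n_visits = 8),
                       seed = NULL) {
  stopifnot(all(n_per_group > 0), n_cpgs > 0, coverage_mean > 0,
            dispersion > 0, dispersion < 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a CpG count matrix with planted DMRs
#'
#' Per CpG i and sample s, `total ~ Poisson(coverage_mean)` and
#' `meth ~ BetaBinomial(total, mu_is, rho)` with
#' `logit(mu_is) = logit(mu_i) + effect * [s in affected group, i in DMR]`.
#' Baseline `mu_i` is drawn from a bimodal Beta mixture; planted DMR CpGs
#' draw from a mid-range Beta.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (a `CpGCountMatrix`), `samples` (cohort
#'   table), and `truth` (planted DMR intervals with per-site effects).
#' @export
simulate_counts <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  groups <- rep(names(config$n_per_group), config$n_per_group)
  ns <- length(groups)
  ids <- sprintf("S%03d", seq_len(ns))
  pos <- seq(0L, by = config$cpg_spacing, length.out = config$n_cpgs)
  chrom <- rep("chr1", config$n_cpgs)

  comp <- sample(seq_along(config$mu_shapes), config$n_cpgs, replace = TRUE)
  mu <- vapply(seq_len(config$n_cpgs), function(i) {
    sh <- config$mu_shapes[[comp[i]]]
    rbeta(1, sh[1], sh[2])
  }, numeric(1))

  dmr_sites <- integer(0); truth_regions <- NULL
  if (config$n_dmrs > 0) {
    blocks <- plant_blocks(config$n_cpgs, config$n_dmrs, config$dmr_size_cpgs)
    signs <- rep(c(1, -1), length.out = config$n_dmrs)
    site_list <- lapply(seq_len(config$n_dmrs), function(k)
      seq(blocks[k], length.out = config$dmr_size_cpgs))
    dmr_sites <- unlist(site_list)
    mu[dmr_sites] <- rbeta(length(dmr_sites), config$dmr_mu_shape[1],
                           config$dmr_mu_shape[2])
    truth_regions <- data.frame(
      chrom = "chr1",
      start = pos[blocks],
      end = pos[blocks + config$dmr_size_cpgs - 1L] + 1L,
      effect = signs * config$dmr_effect,
      first_site = blocks, n_cpgs = config$dmr_size_cpgs)
  }

  shifted <- groups %in% config$dmr_groups
  total <- matrix(rpois(config$n_cpgs * ns, config$coverage_mean),
                  config$n_cpgs, ns)
  eff <- numeric(config$n_cpgs)
  if (config$n_dmrs > 0) {
    eff[dmr_sites] <- rep(truth_regions$effect,
                          each = config$dmr_size_cpgs)
  }
  mu_mat <- matrix(mu, config$n_cpgs, ns)
  mu_mat[, shifted] <- plogis(qlogis(mu_mat[, shifted, drop = FALSE]) + eff)
  meth <- matrix(rbetabinom(length(total), as.vector(total),
                            as.vector(mu_mat), config$dispersion),
                 config$n_cpgs, ns)
  counts <- cpg_count_matrix(chrom, pos, meth, total, ids)
  samples <- simulate_sample_table(ids, groups)
  list(counts = counts, samples = samples,
       truth = list(dmr_regions = truth_regions, mu = mu,
                    delta_planted = if (config$n_dmrs > 0)
                      plogis(qlogis(mu[dmr_sites]) + eff[dmr_sites]) -
                        mu[dmr_sites] else numeric(0)))
}

plant_blocks <- function(n_cpgs, n_blocks, block_size) {
  # non-adjacent block starts with >= 2 buffer CpGs between blocks
  slots <- floor(n_cpgs / (block_size + 4L))
  if (slots < n_blocks) stop("not enough CpGs to plant the requested blocks")
  picked <- sort(sample(slots, n_blocks))
  (picked - 1L) * (block_size + 4L) + 2L
}

simulate_sample_table <- function(ids, groups) {
  n <- length(ids)
  data.frame(
    sample_id = ids,
    patient_id = paste0("P", sub("^S", "", ids)),
    group = groups,
    age = round(runif(n, 25, 68), 1),
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.7, 0.3)),
    race = sample(c("White", "Black", "Asian"), n, replace = TRUE,
                  prob = c(0.85, 0.12, 0.03)),
    disease_duration = ifelse(groups == "Control", NA,
                              round(runif(n, 1, 30), 1)),
    dmt_type = ifelse(groups == "Control", "none",
                      sample(c("injectable", "oral", "infusion"), n,
                             replace = TRUE)),
    dmt_effectiveness = ifelse(groups == "Control", "none",
                               sample(c("standard", "high"), n,
                                      replace = TRUE)),
    followup_duration = NA_real_,
    baseline_pdds = NA_integer_,
    stringsAsFactors = FALSE)
}

#' Build a synthetic cell-type methylation marker atlas
#'
#' Mirrors the structure of fragment-level deconvolution atlases: each
#' marker is unmethylated in its target cell type and methylated elsewhere.
#' The reference U-fraction per marker and cell type is the exact expected
#' fraction of eligible fragments classified U under the generative model
#' (binomial CpG calls at the marker methylation level, fragment lengths
#' uniform over `len_range`).
#'
#' @param n_celltypes,markers_per_type atlas dimensions.
#' @param marker_cpgs CpGs per marker; `cpg_spacing` base pairs apart.
#' @param cpg_spacing spacing of marker CpGs in bp.
#' @param m_low,m_high methylation level in the target / background type.
#' @param len_range inclusive range of fragment CpG counts.
#' @param low,min_cpgs U/X/M classification parameters used for the
#'   reference calculation (must match [classify_uxm()] at deconvolution).
#' @return list of class `MarkerAtlas`: `markers` (intervals with `target`),
#'   `meth` (marker x celltype generative methylation), `reference`
#'   (marker x celltype expected U-fraction), `celltypes`, `len_range`.
#' @export
make_marker_atlas <- function(n_celltypes = 5L, markers_per_type = 10L,
                              marker_cpgs = 25L, cpg_spacing = 50L,
                              m_low = 0.05, m_high = 0.92,
                              len_range = c(4L, 8L),
                              low = 0.25, min_cpgs = 3L) {
  celltypes <- paste0("CT", seq_len(n_celltypes))
  n_mark <- n_celltypes * markers_per_type
  width <- marker_cpgs * cpg_spacing
  markers <- genomic_intervals(
    chrom = rep("chr1", n_mark),
    start = seq(0L, by = width + 1000L, length.out = n_mark),
    end = seq(0L, by = width + 1000L, length.out = n_mark) + width)
  markers$target <- rep(celltypes, each = markers_per_type)
  meth <- matrix(m_high, n_mark, n_celltypes,
                 dimnames = list(NULL, celltypes))
  meth[cbind(seq_len(n_mark), match(markers$target, celltypes))] <- m_low
  reference <- apply(meth, 2, expected_u_fraction, len_range = len_range,
                     low = low, min_cpgs = min_cpgs)
  structure(list(markers = markers, meth = meth, reference = reference,
                 celltypes = celltypes, len_range = len_range,
                 cpg_spacing = cpg_spacing),
            class = "MarkerAtlas")
}

#' Expected U-fraction of fragments at a marker
#'
#' For methylation level `m`, fragment CpG counts uniform over `len_range`
#' and eligibility `len >= min_cpgs`, returns
#' `E[ P(Binomial(L, m) <= floor(low * L)) ]` over eligible lengths.
#'
#' @param m per-CpG methylation probability (vectorized).
#' @param len_range,low,min_cpgs see [make_marker_atlas()].
#' @export
expected_u_fraction <- function(m, len_range, low = 0.25, min_cpgs = 3L) {
  lens <- seq(len_range[1], len_range[2])
  lens <- lens[lens >= min_cpgs]
  sapply(m, function(mm)
    mean(vapply(lens, function(L)
      sum(dbinom(0:floor(low * L), L, mm)), numeric(1))))
}

#' Simulate cfDNA fragments from a cell-type mixture
#'
#' Each fragment draws a cell type from `proportions`, a marker uniformly,
#' a CpG count uniform over the atlas length range, a start position inside
#' the marker, and per-CpG Bernoulli calls at the cell type's methylation
#' level for that marker.
#'
#' @param atlas a `MarkerAtlas`.
#' @param proportions named (or atlas-ordered) mixture over cell types,
#'   summing to 1 within 1e-8.
#' @param n_fragments number of fragments to draw.
#' @param seed optional seed.
#' @return `fragments` table; attribute `truth` holds per-fragment
#'   cell-type indices.
#' @export
simulate_fragments <- function(atlas, proportions, n_fragments,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("validation error: proportions must sum to 1")
  k <- length(atlas$celltypes)
  stopifnot(length(proportions) == k)
  ct <- sample.int(k, n_fragments, replace = TRUE, prob = proportions)
  mk <- sample.int(nrow(atlas$markers), n_fragments, replace = TRUE)
  L <- sample(seq(atlas$len_range[1], atlas$len_range[2]), n_fragments,
              replace = TRUE)
  # start so the fragment's CpG run stays inside the marker
  n_slots <- (atlas$markers$end[mk] - atlas$markers$start[mk]) %/%
    atlas$cpg_spacing - L + 1L
  offs <- floor(runif(n_fragments) * pmax(n_slots, 1L))
  start <- atlas$markers$start[mk] + offs * atlas$cpg_spacing
  m <- atlas$meth[cbind(mk, ct)]
  calls <- vapply(seq_len(n_fragments), function(i)
    paste(rbinom(L[i], 1L, m[i]), collapse = ""), character(1))
  out <- fragments(atlas$markers$chrom[mk], start, calls, 1L)
  attr(out, "truth") <- ct
  out
}

#' Fragment count equivalent to a target effective coverage
#'
#' Effective coverage c means each marker CpG is covered on average c times,
#' so the expected fragment count is `c * total marker CpGs / mean fragment
#' CpG count`.
#'
#' @param atlas a `MarkerAtlas`.
#' @param coverage target effective coverage (x).
#' @export
fragments_for_coverage <- function(atlas, coverage) {
  total_cpgs <- sum((atlas$markers$end - atlas$markers$start) %/%
                      atlas$cpg_spacing)
  round(coverage * total_cpgs / mean(seq(atlas$len_range[1],
                                         atlas$len_range[2])))
}

#' Simulate longitudinal PDDS trajectories
#'
#' Latent severity follows a linear mixed model with a per-patient random
#' intercept and a time-by-biomarker-group interaction:
#' `beta0 + beta1 t + beta3 t h_i + covariates + u_i + eps_ij`; recorded
#' PDDS is the latent value rounded and clamped to the 0-8 ordinal scale.
#' Visit days are jittered around the nominal spacing (baseline fixed at
#' day 0) so downstream interpolation is exercised honestly.
#'
#' @param sample_table cohort table (one row per patient).
#' @param high 0/1 latent biomarker-group indicator per patient.
#' @param trajectory parameter list, see [sim_config()].
#' @param covariate_effects optional named list (`age`, `sexM`) of fixed
#'   covariate coefficients; defaults to zero so null calibration is exact.
#' @param seed optional seed.
#' @return list with `outcomes` (patient_id, day, pdds), `u` (random
#'   intercepts), `high`.
#' @export
simulate_trajectories <- function(sample_table, high, trajectory,
                                  covariate_effects = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- trajectory
  n <- nrow(sample_table)
  u <- rnorm(n, 0, tr$sigma_u)
  cov_term <- numeric(n)
  if (!is.null(covariate_effects)) {
    if (!is.null(covariate_effects$age))
      cov_term <- cov_term +
        covariate_effects$age * (sample_table$age - mean(sample_table$age))
    if (!is.null(covariate_effects$sexM))
      cov_term <- cov_term + covariate_effects$sexM *
        (sample_table$sex == "M")
  }
  rows <- lapply(seq_len(n), function(i) {
    j <- seq_len(tr$n_visits) - 1L
    jit <- c(0, runif(tr$n_visits - 1L, -0.2, 0.2)) * tr$visit_spacing_days
    day <- round(j * tr$visit_spacing_days + jit)
    day <- sort(unique(pmax(day, 0L)))
    latent <- tr$beta0 + tr$beta1 * day + tr$beta3 * day * high[i] +
      cov_term[i] + u[i] + rnorm(length(day), 0, tr$sigma_eps)
    data.frame(patient_id = sample_table$patient_id[i], day = day,
               pdds = pmin(pmax(round(latent), 0L), 8L))
  })
  out <- validate_outcomes(do.call(rbind, rows))
  list(outcomes = out, u = u, high = high)
}

#' Simulate a full prognostic cohort: regions, counts, trajectories
#'
#' Generates a baseline cfDNA cohort of `n_patients` with `n_regions`
#' candidate regions (each `region_size_cpgs` CpGs), of which
#' `n_prognostic` carry a latent progression factor: patients with
#' `h_i = 1` have their planted-region methylation shifted by
#' `prog_effect` logit units, and their disability trajectory rises by
#' `beta3` PDDS per day faster. Regions are spread across autosomes so
#' matched random intervals can be drawn per chromosome.
#'
#' @param n_patients,n_regions,n_prognostic cohort dimensions.
#' @param region_size_cpgs,cpg_spacing region geometry.
#' @param coverage_mean reads per CpG at retained candidate regions (the
#'   candidate-region procedure keeps fully observed loci, so depth there
#'   exceeds the genome-wide average).
#' @param dispersion beta-binomial rho.
#' @param prog_effect logit-scale methylation gap between latent groups.
#' @param trajectory see [sim_config()].
#' @param seed integer seed.
#' @return list: `counts`, `regions`, `region_matrix`, `samples`,
#'   `outcomes`, `truth` (prognostic indices, `h`, `u`), `layout`
#'   (chromosome extents for interval matching).
#' @export
simulate_prognosis_cohort <- function(n_patients = 60L, n_regions = 2000L,
                                      n_prognostic = 20L,
                                      region_size_cpgs = 5L,
                                      cpg_spacing = 50L,
                                      coverage_mean = 10, dispersion = 0.1,
                                      prog_effect = 2.0,
                                      trajectory = list(beta0 = 1.5,
                                                        beta1 = 3e-4,
                                                        beta3 = 2e-3,
                                                        sigma_u = 0.5,
                                                        sigma_eps = 0.5,
                                                        visit_spacing_days = 250,
                                                        n_visits = 8),
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("S%03d", seq_len(n_patients))
  groups <- sample(c("A-RRMS", "S-RRMS", "PMS"), n_patients, replace = TRUE)
  samples <- simulate_sample_table(ids, groups)
  h <- rep(c(0L, 1L), length.out = n_patients)[sample.int(n_patients)]

  chroms <- rep(AUTOSOMES, length.out = n_regions)
  chroms <- chroms[order(match(chroms, AUTOSOMES))]
  idx_in_chrom <- unlist(lapply(table(factor(chroms, AUTOSOMES)), seq_len))
  region_bp <- region_size_cpgs * cpg_spacing
  start <- (idx_in_chrom - 1L) * (region_bp + 1500L)
  regions <- genomic_intervals(chroms, start, start + region_bp)
  prog_idx <- sort(sample.int(n_regions, n_prognostic))

  mu_r <- rbeta(n_regions, 5, 5)           # mid-range region baselines
  n_cpg_tot <- n_regions * region_size_cpgs
  site_region <- rep(seq_len(n_regions), each = region_size_cpgs)
  site_pos <- regions$start[site_region] +
    (seq_len(region_size_cpgs) - 1L) * cpg_spacing
  mu_site <- plogis(qlogis(mu_r[site_region]) +
                      rnorm(n_cpg_tot, 0, 0.15))
  shift <- matrix(0, n_cpg_tot, n_patients)
  prog_sites <- site_region %in% prog_idx
  if (any(prog_sites))
    shift[prog_sites, ] <- prog_effect *
      matrix(h - 0.5, sum(prog_sites), n_patients, byrow = TRUE)
  mu_mat <- plogis(qlogis(matrix(mu_site, n_cpg_tot, n_patients)) + shift)
  total <- matrix(rpois(n_cpg_tot * n_patients, coverage_mean),
                  n_cpg_tot, n_patients)
  meth <- matrix(rbetabinom(length(total), as.vector(total),
                            as.vector(mu_mat), dispersion),
                 n_cpg_tot, n_patients)
  counts <- cpg_count_matrix(regions$chrom[site_region], site_pos,
                             meth, total, ids)

  traj <- simulate_trajectories(samples, h, trajectory)
  samples$followup_duration <-
    tapply(traj$outcomes$day, traj$outcomes$patient_id, max)[samples$patient_id]
  first <- traj$outcomes[!duplicated(traj$outcomes$patient_id), ]
  samples$baseline_pdds <- first$pdds[match(samples$patient_id,
                                            first$patient_id)]
  layout <- aggregate(end ~ chrom, data = as.data.frame(regions), FUN = max)
  names(layout) <- c("chrom", "length")
  list(counts = counts, regions = regions,
       region_matrix = aggregate_to_regions(counts, regions),
       samples = samples, outcomes = traj$outcomes,
       truth = list(prognostic_idx = prog_idx, h = h, u = traj$u,
                    beta3 = trajectory$beta3),
       layout = layout)
}
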