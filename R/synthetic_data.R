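#' Specification for a synthetic AP-MS proximity-labeling experiment
#'
#' Describes a two-group label-free quantification (LFQ) pulldown experiment:
#' bait (split-TurboID fusion) versus mock samples, with a subset of proteins
#' truly enriched in the bait group and intensity-dependent (MNAR,
#' left-censored) missingness. Defaults mirror a 10-bait vs 6-mock design
#' with planted bait log2 fold changes spanning 1 to 8.
#'
#' Missingness is applied to each stored value with probability
#' `plogis((value - mnar_midpoint) * mnar_slope)`; a negative slope makes
#' low-intensity values preferentially missing (left-censoring). A slope of
#' exactly 0 disables MNAR missingness entirely. An optional `mcar_rate` adds
#' completely-at-random missingness on top for sensitivity analyses.
#'
#' @param n_bait_samples,n_mock_samples group sizes.
#' @param n_proteins total simulated proteins.
#' @param n_enriched number of proteins with a planted bait effect.
#' @param effect_log2fc planted bait-minus-mock log2 fold changes; scalar or
#'   length-`n_enriched` vector. Default spans 1 to 8 evenly.
#' @param baseline_mean,baseline_sd mean and SD of the per-protein baseline
#'   log2 intensity (abundance spread across proteins).
#' @param noise_sd replicate-to-replicate SD of log2 intensity within a
#'   protein (default 0.5, typical for LFQ).
#' @param mnar_midpoint,mnar_slope logistic missingness parameters (log2
#'   intensity units; slope per log2 unit).
#' @param mcar_rate additional missing-completely-at-random probability.
#' @param seed RNG seed; identical seed gives an identical dataset.
#' @return a list of class `ApmsSimSpec`.
#' @export
apms_sim_spec <- function(n_bait_samples = 10, n_mock_samples = 6,
                          n_proteins = 2000, n_enriched = 50,
                          effect_log2fc = NULL,
                          baseline_mean = 30, baseline_sd = 2,
                          noise_sd = 0.5,
                          mnar_midpoint = 26.5, mnar_slope = -1,
                          mcar_rate = 0, seed = 1) {
  if (n_enriched > n_proteins) stop("n_enriched must not exceed n_proteins")
  if (is.null(effect_log2fc)) {
    effect_log2fc <- if (n_enriched > 0) {
      if (n_enriched == 1) 8 else seq(1, 8, length.out = n_enriched)
    } else numeric(0)
  }
  effect_log2fc <- rep_len(as.numeric(effect_log2fc), n_enriched)
  if (mcar_rate < 0 || mcar_rate > 1)
    stop("mcar_rate gives a missingness probability outside [0, 1]")
  structure(list(n_bait_samples = n_bait_samples,
                 n_mock_samples = n_mock_samples,
                 n_proteins = n_proteins, n_enriched = n_enriched,
                 effect_log2fc = effect_log2fc,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 noise_sd = noise_sd,
                 mnar_midpoint = mnar_midpoint, mnar_slope = mnar_slope,
                 mcar_rate = mcar_rate, seed = as.integer(seed)),
            class = "ApmsSimSpec")
}

#' Generate a synthetic AP-MS dataset
#'
#' Each protein receives a baseline log2 intensity drawn from
#' `Normal(baseline_mean, baseline_sd)`; individual values add replicate
#' noise `Normal(0, noise_sd)`, and the planted effect is added to
#' bait-group values of the enriched proteins; each value is then censored
#' (set missing) with the logistic MNAR probability of its own (true) value,
#' so missingness acts on the value before storage, as left-censoring does.
#'
#' @param spec an [apms_sim_spec()].
#' @return list with `matrix` (an [abundance_matrix()], log2 scale, `NA` =
#'   missing), `design` (sample design data.frame), and `truth` (per-protein
#'   planted effects).
#' @export
generate_apms <- function(spec) {
  stopifnot(inherits(spec, "ApmsSimSpec"))
  set.seed(spec$seed)
  n_s <- spec$n_bait_samples + spec$n_mock_samples
  proteins <- sprintf("P%04d", seq_len(spec$n_proteins))
  samples <- c(sprintf("sTurbo_%02d", seq_len(spec$n_bait_samples)),
               sprintf("Mock_%02d", seq_len(spec$n_mock_samples)))
  group <- rep(c("sTurbo", "Mock"),
               c(spec$n_bait_samples, spec$n_mock_samples))

  baseline <- stats::rnorm(spec$n_proteins, spec$baseline_mean,
                           spec$baseline_sd)
  vals <- baseline +
    matrix(stats::rnorm(spec$n_proteins * n_s, 0, spec$noise_sd),
           nrow = spec$n_proteins, ncol = n_s,
           dimnames = list(proteins, samples))
  enriched_idx <- seq_len(spec$n_enriched)
  if (spec$n_enriched > 0) {
    bait_cols <- which(group == "sTurbo")
    vals[enriched_idx, bait_cols] <-
      vals[enriched_idx, bait_cols] + spec$effect_log2fc
  }

  p_miss <- if (spec$mnar_slope == 0) {
    matrix(0, nrow(vals), ncol(vals))
  } else {
    stats::plogis((vals - spec$mnar_midpoint) * spec$mnar_slope)
  }
  p_miss <- p_miss + spec$mcar_rate * (1 - p_miss)
  if (any(p_miss < 0 | p_miss > 1))
    stop("missingness probability outside [0, 1] after parameterization")
  miss <- matrix(stats::runif(length(vals)) < p_miss, nrow(vals))
  vals[miss] <- NA_real_

  design <- data.frame(sample_id = samples, group = group,
                       stringsAsFactors = FALSE)
  truth <- data.frame(
    protein_id = proteins,
    enriched = seq_len(spec$n_proteins) %in% enriched_idx,
    effect_log2fc = 0,
    baseline = baseline,
    stringsAsFactors = FALSE)
  truth$effect_log2fc[enriched_idx] <- spec$effect_log2fc
  list(matrix = abundance_matrix(vals, "log2"),
       design = validate_design(design), truth = truth)
}

#' Specification for a synthetic multi-batch cohort proteome
#'
#' Emulates a TMT-style human brain cohort: three diagnosis groups
#' (CTL/AD/PSP), planted co-expression modules driven by shared latent
#' factors, additive batch offsets, pooled global-internal-standard (GIS)
#' reference samples per batch, linear covariate effects (age/sex/PMI),
#' diagnosis-linked module shifts, and neuropathology-like traits generated
#' with target correlations to designated module factors.
#'
#' Signal model: protein i of module m in sample j is
#' `baseline_i + l_i * (f_m(j) + delta_ij)` with factor `f_m ~ N(dx shift, 1)`,
#' loadings `l_i ~ |N(1, 0.2)|` and per-protein noise `delta ~ N(0, tau)` with
#' `tau^2 = (1 - r_w)/r_w`, which yields within-module Pearson correlation
#' `r_w` irrespective of the loading. Module factors share a global factor so
#' that between-module protein correlation is `r_b`. Background (grey)
#' proteins are factor-free noise of matching total variance.
#'
#' @param group_sizes named integer vector of real (non-GIS) samples per
#'   diagnosis group.
#' @param n_proteins total proteins; those beyond `sum(module_sizes)` are
#'   unstructured background.
#' @param module_sizes sizes of the planted modules.
#' @param r_w,r_b target within-/between-module Pearson correlations,
#'   `0 <= r_b < r_w <= 1`.
#' @param batch_offsets named numeric vector of additive log2 batch offsets;
#'   samples are assigned to batches by a seeded shuffle so batch is not
#'   confounded with diagnosis.
#' @param gis_per_batch number of pooled GIS reference samples per batch.
#' @param gis_noise_sd SD of the noise added to GIS pooled means.
#' @param covariate_effects named numeric vector of log2-per-unit covariate
#'   coefficients for `age`, `sex`, `pmi`.
#' @param covariate_modules named integer vector: module each covariate acts
#'   on (0 = all proteins).
#' @param dx_effects named list: module index (as character) -> named vector
#'   of per-group latent-factor mean shifts.
#' @param trait_loadings named list: trait -> c(module, loading) target
#'   correlation of the trait with that module's latent factor.
#' @param protein_baseline_sd SD of per-protein baseline (row) offsets.
#' @param seed RNG seed.
#' @return a list of class `CohortSimSpec`.
#' @export
cohort_sim_spec <- function(group_sizes = c(CTL = 46, AD = 49, PSP = 26),
                            n_proteins = 2000,
                            module_sizes = c(120, 100, 80, 60, 40),
                            r_w = 0.8, r_b = 0.1,
                            batch_offsets = c(b1 = 0, b2 = 1.5, b3 = -0.7),
                            gis_per_batch = 2, gis_noise_sd = 0.02,
                            covariate_effects = c(age = 0.05, sex = 0, pmi = 0),
                            covariate_modules = c(age = 1, sex = 1, pmi = 1),
                            dx_effects = list(`1` = c(CTL = 0, AD = 1, PSP = 0.5)),
                            trait_loadings = list(
                              Braak = c(module = 1, loading = 0.6),
                              CERAD = c(module = 2, loading = 0.5),
                              MFTau = c(module = 1, loading = 0.55)),
                            protein_baseline_sd = 1, seed = 1) {
  if (sum(module_sizes) > n_proteins)
    stop("sum(module_sizes) must not exceed n_proteins")
  if (!(r_b >= 0 && r_b < r_w && r_w <= 1))
    stop("need 0 <= r_b < r_w <= 1")
  if (r_w > 0 && r_b / r_w > 1)
    stop("infeasible correlation structure: r_b/r_w > 1 is not positive definite")
  if (is.null(names(group_sizes))) stop("group_sizes must be named")
  if (is.null(names(batch_offsets))) stop("batch_offsets must be named")
  structure(list(group_sizes = group_sizes, n_proteins = n_proteins,
                 module_sizes = module_sizes, r_w = r_w, r_b = r_b,
                 batch_offsets = batch_offsets,
                 gis_per_batch = gis_per_batch, gis_noise_sd = gis_noise_sd,
                 covariate_effects = covariate_effects,
                 covariate_modules = covariate_modules,
                 dx_effects = dx_effects, trait_loadings = trait_loadings,
                 protein_baseline_sd = protein_baseline_sd,
                 seed = as.integer(seed)),
            class = "CohortSimSpec")
}

#' Generate a synthetic cohort proteome
#'
#' @param spec a [cohort_sim_spec()].
#' @return list with `matrix` (log2 [abundance_matrix()], GIS columns
#'   included), `design` (covariates/traits; GIS rows carry `NA` traits), and
#'   `truth` (per-protein module labels and loadings plus the planted batch
#'   offsets, covariate coefficients, diagnosis shifts and trait loadings).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSimSpec"))
  set.seed(spec$seed)
  n_real <- sum(spec$group_sizes)
  groups <- rep(names(spec$group_sizes), spec$group_sizes)
  sample_ids <- sprintf("S%03d", seq_len(n_real))
  batches <- names(spec$batch_offsets)
  # seeded shuffle -> round-robin so batch is balanced across groups
  batch <- rep_len(batches, n_real)[order(sample(n_real))]

  n_mod <- length(spec$module_sizes)
  labels <- rep(0L, spec$n_proteins)
  labels[seq_len(sum(spec$module_sizes))] <-
    rep(seq_len(n_mod), spec$module_sizes)
  proteins <- sprintf("G%04d", seq_len(spec$n_proteins))

  tau2 <- if (spec$r_w > 0) (1 - spec$r_w) / spec$r_w else Inf
  rho_f <- if (spec$r_w > 0) spec$r_b / spec$r_w else 0

  # correlated module factors: f_m = sqrt(rho_f) g + sqrt(1-rho_f) h_m
  g <- stats::rnorm(n_real)
  fac <- sapply(seq_len(n_mod), function(m)
    sqrt(rho_f) * g + sqrt(1 - rho_f) * stats::rnorm(n_real))
  fac <- matrix(fac, nrow = n_real)
  # diagnosis-linked latent shifts
  for (m in names(spec$dx_effects)) {
    mi <- as.integer(m)
    if (mi >= 1 && mi <= n_mod) {
      shifts <- spec$dx_effects[[m]]
      fac[, mi] <- fac[, mi] + unname(shifts[groups])
    }
  }

  loadings <- abs(stats::rnorm(spec$n_proteins, 1, 0.2))
  baseline <- stats::rnorm(spec$n_proteins, 0, spec$protein_baseline_sd)

  vals <- matrix(0, spec$n_proteins, n_real,
                 dimnames = list(proteins, sample_ids))
  bg_sd <- sqrt(1 + ifelse(is.finite(tau2), tau2, 0))
  for (i in seq_len(spec$n_proteins)) {
    if (labels[i] > 0 && is.finite(tau2)) {
      vals[i, ] <- loadings[i] *
        (fac[, labels[i]] + stats::rnorm(n_real, 0, sqrt(tau2)))
    } else if (labels[i] > 0) {
      vals[i, ] <- stats::rnorm(n_real, 0, bg_sd)
    } else {
      vals[i, ] <- stats::rnorm(n_real, 0, bg_sd)
    }
  }
  vals <- vals + baseline

  # covariates
  age <- stats::rnorm(n_real, 70, 10)
  sex <- stats::rbinom(n_real, 1, 0.5)
  pmi <- pmax(stats::rnorm(n_real, 12, 4), 1)
  covs <- cbind(age = age, sex = sex, pmi = pmi)
  cov_coef <- matrix(0, spec$n_proteins, 3,
                     dimnames = list(proteins, c("age", "sex", "pmi")))
  for (cv in intersect(names(spec$covariate_effects), colnames(covs))) {
    coef <- spec$covariate_effects[[cv]]
    if (coef == 0) next
    target <- spec$covariate_modules[[cv]]
    idx <- if (is.na(target) || target == 0) seq_len(spec$n_proteins)
           else which(labels == target)
    cov_coef[idx, cv] <- coef
    centered <- covs[, cv] - mean(covs[, cv])
    vals[idx, ] <- vals[idx, ] + coef * matrix(centered, length(idx),
                                               n_real, byrow = TRUE)
  }

  # batch offsets
  vals <- vals + matrix(spec$batch_offsets[batch], spec$n_proteins,
                        n_real, byrow = TRUE)

  # traits correlated with designated module factors
  traits <- list()
  for (tr in names(spec$trait_loadings)) {
    tl <- spec$trait_loadings[[tr]]
    mi <- as.integer(tl[["module"]]); lam <- tl[["loading"]]
    f_std <- as.numeric(scale(fac[, mi]))
    traits[[tr]] <- lam * f_std + sqrt(1 - lam^2) * stats::rnorm(n_real)
  }

  # GIS pooled reference samples: within-batch mean plus small noise
  gis_vals <- NULL; gis_ids <- character(0); gis_batch <- character(0)
  if (spec$gis_per_batch > 0) {
    for (b in batches) {
      bm <- rowMeans(vals[, batch == b, drop = FALSE])
      for (k in seq_len(spec$gis_per_batch)) {
        gis_vals <- cbind(gis_vals,
                          bm + stats::rnorm(spec$n_proteins, 0,
                                            spec$gis_noise_sd))
        gis_ids <- c(gis_ids, sprintf("GIS_%s_%d", b, k))
        gis_batch <- c(gis_batch, b)
      }
    }
    colnames(gis_vals) <- gis_ids
  }

  all_vals <- cbind(vals, gis_vals)
  design <- data.frame(
    sample_id = c(sample_ids, gis_ids),
    group = c(groups, rep("GIS", length(gis_ids))),
    batch = c(batch, gis_batch),
    is_gis = c(rep(FALSE, n_real), rep(TRUE, length(gis_ids))),
    age = c(age, rep(NA_real_, length(gis_ids))),
    sex = c(sex, rep(NA_real_, length(gis_ids))),
    pmi = c(pmi, rep(NA_real_, length(gis_ids))),
    stringsAsFactors = FALSE)
  for (tr in names(traits))
    design[[tr]] <- c(traits[[tr]], rep(NA_real_, length(gis_ids)))

  truth_proteins <- data.frame(protein_id = proteins, module = labels,
                               loading = ifelse(labels > 0, loadings, 0),
                               baseline = baseline, cov_coef,
                               stringsAsFactors = FALSE)
  list(matrix = abundance_matrix(all_vals, "log2"),
       design = validate_design(design),
       truth = list(proteins = truth_proteins,
                    batch_offsets = spec$batch_offsets,
                    covariate_effects = spec$covariate_effects,
                    covariate_modules = spec$covariate_modules,
                    dx_effects = spec$dx_effects,
                    trait_loadings = spec$trait_loadings,
                    factors = fac))
}
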