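#' Parameters for left-censored down-shifted Gaussian imputation
#'
#' Missing LFQ values are assumed left-censored: a protein is unquantified
#' because its true abundance sits near or below the detection noise level.
#' The Perseus-style convention replaces each missing value with a draw from a
#' Gaussian centred at the sample's noise level, taken to be `shift` standard
#' deviations below the sample mean, with width `width` standard deviations.
#'
#' @param shift multiples of the sample SD below the sample mean at which the
#'   noise level sits (default 1.8).
#' @param width imputation SD as a fraction of the sample SD (default 0.3).
#' @param per_sample compute mean/SD per sample (default) or globally.
#' @param truncate truncate draws to +/- one imputation SD around the noise
#'   level (a literal reading of "between +/- 0.3 SD from the noise level");
#'   default is the untruncated Gaussian convention.
#' @param seed RNG seed; identical seed gives an identical imputed matrix.
#' @export
imputation_params <- function(shift = 1.8, width = 0.3, per_sample = TRUE,
                              truncate = FALSE, seed = 1) {
  if (shift <= 0 || width <= 0) stop("shift and width must be positive")
  structure(list(shift = shift, width = width, per_sample = per_sample,
                 truncate = truncate, seed = as.integer(seed)),
            class = "ImputationParams")
}

#' Parameters for differential enrichment analysis
#'
#' @param max_missing_frac proteins missing in at least this fraction of
#'   samples are removed (default 0.5, i.e. "absent in 50% or more").
#' @param lfc_threshold absolute log2 fold-change cutoff for volcano
#'   classification (default 1, a two-fold change).
#' @param p_threshold p-value cutoff for volcano classification (default
#'   0.05).
#' @param tukey_floor below this value Tukey pairwise p estimates are
#'   replaced by Bonferroni-corrected pairwise t-test p-values, avoiding the
#'   ceiling effect of imprecise tiny Tukey estimates (default 10^-8.5).
#' @param fdr_method multiple-testing method across proteins (default BH).
#' @param welch use Welch instead of pooled-variance (Student) t.
#' @param use_fdr_for_class classify the volcano on FDR-adjusted rather than
#'   raw p-values.
#' @export
dea_params <- function(max_missing_frac = 0.5, lfc_threshold = 1,
                       p_threshold = 0.05, tukey_floor = 10^-8.5,
                       fdr_method = "BH", welch = FALSE,
                       use_fdr_for_class = FALSE) {
  if (max_missing_frac <= 0 || lfc_threshold <= 0 || p_threshold <= 0)
    stop("thresholds must be positive")
  if (tukey_floor <= 0 || tukey_floor >= 1)
    stop("tukey_floor must lie in (0, 1)")
  structure(list(max_missing_frac = max_missing_frac,
                 lfc_threshold = lfc_threshold, p_threshold = p_threshold,
                 tukey_floor = tukey_floor, fdr_method = fdr_method,
                 welch = welch, use_fdr_for_class = use_fdr_for_class),
            class = "DEAParams")
}

#' Filter proteins by missingness
#'
#' Retains exactly the proteins whose missing fraction across all samples is
#' strictly below `max_missing_frac`; a protein absent in exactly 50% of
#' samples is removed under the default. Row order is preserved.
#'
#' @param x an [abundance_matrix()] (log2 scale).
#' @param params a [dea_params()].
#' @return the filtered [abundance_matrix()].
#' @export
filter_missingness <- function(x, params = dea_params()) {
  x <- as_abundance(x)
  frac <- rowMeans(is.na(unclass(x)))
  keep <- frac < params$max_missing_frac
  if (!any(keep)) warning("missingness filter removed every protein")
  abundance_matrix(unclass(x)[keep, , drop = FALSE], amat_scale(x))
}

#' Impute missing values by down-shifted Gaussian draws
#'
#' For each sample, the mean `m` and SD `s` of its observed log2 values are
#' computed; every missing cell in that sample is replaced by a draw from
#' `Normal(m - shift*s, width*s)` (optionally truncated to one imputation SD
#' around the centre). Observed cells are never altered.
#'
#' @param x a filtered log2 [abundance_matrix()].
#' @param params an [imputation_params()].
#' @return a complete [abundance_matrix()].
#' @export
impute_missing <- function(x, params = imputation_params()) {
  x <- as_abundance(x)
  v <- unclass(x)
  if (!anyNA(v)) return(x)
  set.seed(params$seed)
  if (params$per_sample) {
    for (j in seq_len(ncol(v))) {
      obs <- v[, j][!is.na(v[, j])]
      miss <- which(is.na(v[, j]))
      if (!length(miss)) next
      if (length(obs) < 3)
        stop("sample ", colnames(v)[j],
             " has fewer than 3 observed values; cannot impute")
      v[miss, j] <- rnorm_downshift(length(miss), mean(obs), stats::sd(obs),
                                    params)
    }
  } else {
    obs <- v[!is.na(v)]
    if (length(obs) < 3) stop("fewer than 3 observed values; cannot impute")
    miss <- which(is.na(v))
    v[miss] <- rnorm_downshift(length(miss), mean(obs), stats::sd(obs),
                               params)
  }
  abundance_matrix(v, amat_scale(x))
}

rnorm_downshift <- function(n, m, s, params) {
  centre <- m - params$shift * s
  sdev <- params$width * s
  if (!params$truncate) return(stats::rnorm(n, centre, sdev))
  # truncated to centre +/- sdev via inverse-CDF sampling
  u <- stats::runif(n, stats::pnorm(-1), stats::pnorm(1))
  centre + sdev * stats::qnorm(u)
}

#' Differential enrichment analysis
#'
#' Two groups: a pooled-variance (Student's) two-tailed t-test per protein,
#' with a Welch option. More than two groups: one-way ANOVA with Tukey
#' studentized-range pairwise p-values, each replaced by a
#' Bonferroni-corrected pairwise t-test p when the Tukey estimate falls below
#' `tukey_floor`. BH FDR is applied across proteins. The reported log2 fold
#' change is `mean(contrast[1]) - mean(contrast[2])`.
#'
#' Degenerate proteins with zero within-group variance use a machine-epsilon
#' variance floor; a protein identical in both groups gets `log2fc = 0`,
#' `p = 1`.
#'
#' @param x complete (imputed) log2 [abundance_matrix()].
#' @param design sample design with a `group` column.
#' @param params a [dea_params()].
#' @param contrast length-2 character: (bait, control) group labels; defaults
#'   to the first two groups in design order of appearance.
#' @return a `data.frame` (class `DEAResult`) with per-group means, `log2fc`,
#'   `t_statistic`, `raw_p`, `fdr_p` and a `class` column (filled by
#'   [classify_volcano()]); for >2 groups also the ANOVA F/p and every
#'   pairwise p column.
#' @export
run_dea <- function(x, design, params = dea_params(), contrast = NULL) {
  x <- as_abundance(x)
  v <- unclass(x)
  if (anyNA(v)) stop("run_dea requires a complete (imputed) matrix")
  design <- check_matrix_design(x, validate_design(design))
  grp <- design$group
  lev <- unique(grp)
  if (length(lev) < 2) stop("need at least 2 groups")
  n_g <- table(factor(grp, levels = lev))
  if (any(n_g < 2))
    stop("group(s) with fewer than 2 samples: ",
         paste(names(n_g)[n_g < 2], collapse = ", "))
  if (is.null(contrast)) contrast <- lev[1:2]
  if (!all(contrast %in% lev))
    stop("unknown group label(s) in contrast: ",
         paste(setdiff(contrast, lev), collapse = ", "))

  means <- sapply(lev, function(g) rowMeans(v[, grp == g, drop = FALSE]))
  means <- matrix(means, nrow = nrow(v), dimnames = list(rownames(v), lev))
  log2fc <- means[, contrast[1]] - means[, contrast[2]]

  res <- data.frame(protein_id = rownames(v), stringsAsFactors = FALSE)
  for (g in lev) res[[paste0("mean_", g)]] <- means[, g]
  res$log2fc <- unname(log2fc)

  if (length(lev) == 2) {
    tt <- row_t_test(v, grp == contrast[1], grp == contrast[2],
                     welch = params$welch)
    res$t_statistic <- tt$t
    res$raw_p <- tt$p
  } else {
    an <- row_anova_tukey(v, factor(grp, levels = lev), params$tukey_floor)
    res$f_statistic <- an$f
    res$anova_p <- an$p
    for (pair in colnames(an$pairwise))
      res[[paste0("p_", pair)]] <- an$pairwise[, pair]
    key <- paste0(contrast[1], "_vs_", contrast[2])
    key2 <- paste0(contrast[2], "_vs_", contrast[1])
    pcol <- if (key %in% colnames(an$pairwise)) key else key2
    res$t_statistic <- NA_real_
    res$raw_p <- an$pairwise[, pcol]
  }
  res$fdr_p <- stats::p.adjust(res$raw_p, method = params$fdr_method)
  res$class <- "not_significant"
  attr(res, "contrast") <- contrast
  class(res) <- c("DEAResult", class(res))
  res
}

# Vectorized two-sample t across matrix rows.
row_t_test <- function(v, i1, i2, welch = FALSE) {
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- rowMeans(v[, i1, drop = FALSE]); m2 <- rowMeans(v[, i2, drop = FALSE])
  s1 <- apply(v[, i1, drop = FALSE], 1, stats::var)
  s2 <- apply(v[, i2, drop = FALSE], 1, stats::var)
  d <- m1 - m2
  if (welch) {
    se2 <- s1 / n1 + s2 / n2
    se2 <- pmax(se2, .Machine$double.eps)
    df <- se2^2 / ((s1 / n1)^2 / (n1 - 1) + (s2 / n2)^2 / (n2 - 1))
    df[!is.finite(df)] <- n1 + n2 - 2
    t <- d / sqrt(se2)
  } else {
    sp2 <- ((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2)
    sp2 <- pmax(sp2, .Machine$double.eps)
    t <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(t))
  }
  t[d == 0] <- 0
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, p = pmin(p, 1))
}

# One-way ANOVA + Tukey pairwise p (studentized range), Bonferroni fallback.
row_anova_tukey <- function(v, grp, tukey_floor) {
  lev <- levels(grp)
  k <- length(lev)
  n <- ncol(v)
  n_g <- as.numeric(table(grp))
  idx <- lapply(lev, function(g) grp == g)
  means <- sapply(idx, function(i) rowMeans(v[, i, drop = FALSE]))
  ssw <- rowSums(sapply(seq_along(lev), function(j) {
    sub <- v[, idx[[j]], drop = FALSE]
    rowSums((sub - means[, j])^2)
  }))
  gm <- rowMeans(v)
  ssb <- rowSums(sweep(means^2, 2, n_g, `*`)) - n * gm^2
  df1 <- k - 1; df2 <- n - k
  mse <- pmax(ssw / df2, .Machine$double.eps)
  f <- (ssb / df1) / mse
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)

  pairs <- utils::combn(lev, 2)
  pw <- matrix(NA_real_, nrow(v), ncol(pairs))
  colnames(pw) <- apply(pairs, 2, paste, collapse = "_vs_")
  n_pairs <- ncol(pairs)
  for (j in seq_len(ncol(pairs))) {
    i1 <- match(pairs[1, j], lev); i2 <- match(pairs[2, j], lev)
    d <- means[, i1] - means[, i2]
    se <- sqrt(mse / 2 * (1 / n_g[i1] + 1 / n_g[i2]))
    q <- abs(d) / se
    p_tuk <- stats::ptukey(q, nmeans = k, df = df2, lower.tail = FALSE)
    # Bonferroni-corrected pairwise t where Tukey underflows
    floor_hit <- p_tuk < tukey_floor
    if (any(floor_hit)) {
      t <- d / sqrt(mse * (1 / n_g[i1] + 1 / n_g[i2]))
      p_bon <- pmin(2 * stats::pt(-abs(t), df2) * n_pairs, 1)
      p_tuk[floor_hit] <- p_bon[floor_hit]
    }
    p_tuk[d == 0] <- 1
    pw[, j] <- p_tuk
  }
  list(f = f, p = p, pairwise = pw)
}

#' Classify proteins on the volcano plane
#'
#' Labels each protein `bait_enriched` when `log2fc >= lfc_threshold` and
#' `p < p_threshold`, `control_enriched` for the mirrored condition, and
#' `not_significant` otherwise. By convention raw (unadjusted) p-values drive
#' the classification, matching volcano-plot practice; set
#' `use_fdr_for_class = TRUE` in [dea_params()] to classify on BH-adjusted p.
#'
#' @param dea a [run_dea()] result.
#' @param params a [dea_params()].
#' @return the `DEAResult` with its `class` column filled and a `counts`
#'   attribute summarizing the three classes.
#' @export
classify_volcano <- function(dea, params = dea_params()) {
  p <- if (params$use_fdr_for_class) dea$fdr_p else dea$raw_p
  cls <- rep("not_significant", nrow(dea))
  cls[dea$log2fc >= params$lfc_threshold & p < params$p_threshold] <-
    "bait_enriched"
  cls[dea$log2fc <= -params$lfc_threshold & p < params$p_threshold] <-
    "control_enriched"
  dea$class <- cls
  attr(dea, "counts") <- table(factor(
    cls, levels = c("bait_enriched", "control_enriched", "not_significant")))
  dea
}
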