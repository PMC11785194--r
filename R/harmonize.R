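#' Parameters for TAMPOR batch harmonization
#'
#' Tunable Approach for Median Polish of Ratio: abundances are expressed as
#' ratios to a per-batch central tendency (pooled global internal standard,
#' GIS, samples by default), then a two-way median polish over samples and
#' proteins is iterated until the log2 central tendencies converge to 0.
#'
#' @param gis_mode `"gis_samples"` to use only flagged GIS samples as the
#'   central tendency of each batch, `"all_samples"` to use every sample.
#' @param batch_key design column naming the batch.
#' @param max_iterations iteration cap (default 250).
#' @param convergence_tol maximum absolute change in the log2 central
#'   tendencies at which iteration stops (default 1e-6).
#' @export
tampor_params <- function(gis_mode = c("gis_samples", "all_samples"),
                          batch_key = "batch", max_iterations = 250,
                          convergence_tol = 1e-6) {
  gis_mode <- match.arg(gis_mode)
  if (convergence_tol <= 0) stop("convergence_tol must be positive")
  structure(list(gis_mode = gis_mode, batch_key = batch_key,
                 max_iterations = max_iterations,
                 convergence_tol = convergence_tol),
            class = "TamporParams")
}

#' TAMPOR median-polish-of-ratios batch harmonization
#'
#' Per protein within each batch, abundances are divided by the median
#' abundance of that protein over the batch's central-tendency samples; log2
#' of the ratios is taken; then the polish alternates (a) subtracting each
#' sample's median log2 ratio and (b) subtracting each protein's median log2
#' ratio over central-tendency samples, until the maximum absolute adjustment
#' falls below `convergence_tol` or `max_iterations` is reached (with a
#' warning reporting the final delta). The output is the converged log2
#' relative abundance matrix with central tendency 0.
#'
#' Proteins whose central-tendency samples are all missing in some batch
#' cannot be ratio-normalized there; they are dropped with a message.
#'
#' @param x an [abundance_matrix()] on linear or log2 scale.
#' @param design sample design with batch and `is_gis` columns.
#' @param params a [tampor_params()].
#' @return log2 relative [abundance_matrix()].
#' @export
tampor <- function(x, design, params = tampor_params()) {
  x <- as_abundance(x)
  design <- check_matrix_design(x, validate_design(design))
  bk <- params$batch_key
  if (!bk %in% colnames(design))
    stop("design lacks batch column ", dQuote(bk))
  batch <- as.character(design[[bk]])
  central <- if (params$gis_mode == "gis_samples") design$is_gis
             else rep(TRUE, nrow(design))
  linear <- unclass(amat_to_linear(x))

  ratio <- linear
  drop <- logical(nrow(linear))
  for (b in unique(batch)) {
    cols <- which(batch == b)
    ct_cols <- cols[central[cols]]
    if (!length(ct_cols))
      stop("batch ", dQuote(b), " has no central-tendency samples under ",
           "gis_mode = ", dQuote(params$gis_mode))
    med <- apply(linear[, ct_cols, drop = FALSE], 1, stats::median,
                 na.rm = TRUE)
    bad <- !is.finite(med) | med <= 0
    drop <- drop | bad
    med[bad] <- 1
    ratio[, cols] <- linear[, cols, drop = FALSE] / med
  }
  if (any(drop)) {
    message("tampor: dropping ", sum(drop),
            " protein(s) with no usable central-tendency values: ",
            paste(utils::head(rownames(linear)[drop], 5), collapse = ", "),
            if (sum(drop) > 5) ", ...")
    ratio <- ratio[!drop, , drop = FALSE]
  }
  r <- log2(ratio)

  delta <- Inf
  for (it in seq_len(params$max_iterations)) {
    col_med <- apply(r, 2, stats::median, na.rm = TRUE)
    r <- sweep(r, 2, col_med)
    row_med <- apply(r[, central, drop = FALSE], 1, stats::median,
                     na.rm = TRUE)
    row_med[!is.finite(row_med)] <- 0
    r <- r - row_med
    delta <- max(abs(col_med), abs(row_med))
    if (delta < params$convergence_tol) break
  }
  if (delta >= params$convergence_tol)
    warning("tampor did not converge in ", params$max_iterations,
            " iterations (final delta ", signif(delta, 3), ")")
  abundance_matrix(r, "log2")
}

#' Parameters for bootstrap covariate regression
#'
#' @param covariates design columns whose linear effects are removed
#'   (default age, sex, PMI).
#' @param protected design columns whose effects must be modelled but never
#'   removed (default the diagnosis `group`).
#' @param n_boot number of non-parametric bootstrap resamples whose median
#'   coefficient is used (default 1000).
#' @param seed RNG seed.
#' @export
regress_params <- function(covariates = c("age", "sex", "pmi"),
                           protected = "group", n_boot = 1000, seed = 1) {
  if (length(intersect(covariates, protected)))
    stop("covariates and protected variables must be disjoint")
  if (n_boot < 1) stop("n_boot must be >= 1")
  structure(list(covariates = covariates, protected = protected,
                 n_boot = n_boot, seed = as.integer(seed)),
            class = "RegressParams")
}

#' Remove covariate effects by non-parametric bootstrap regression
#'
#' Per protein, log2 abundance is modelled by ordinary least squares on the
#' centred covariates plus the protected variables (diagnosis group dummies).
#' For each bootstrap resample of samples the OLS fit is recomputed; the final
#' per-protein coefficient of each covariate is the median over bootstraps.
#' The returned matrix is the input minus `sum(coef * centred covariate)`;
#' protected-variable effects are left untouched. Resamples in which a
#' protected group level is absent are redrawn (and counted in a message).
#'
#' @param x complete log2 [abundance_matrix()] (no GIS samples).
#' @param design design rows for the matrix samples; covariate columns must
#'   be complete.
#' @param params a [regress_params()].
#' @return list with `matrix` (regressed [abundance_matrix()]) and
#'   `coefficients` (protein x covariate data.frame of median bootstrap
#'   coefficients).
#' @export
bootstrap_regress <- function(x, design, params = regress_params()) {
  x <- as_abundance(x)
  v <- unclass(x)
  if (anyNA(v)) stop("bootstrap_regress requires a complete matrix")
  design <- check_matrix_design(x, validate_design(design))
  miss_cov <- setdiff(c(params$covariates, params$protected),
                      colnames(design))
  if (length(miss_cov))
    stop("design lacks column(s): ", paste(miss_cov, collapse = ", "))

  covs <- design[params$covariates]
  for (cv in params$covariates) {
    col <- covs[[cv]]
    if (!is.numeric(col)) {
      lv <- sort(unique(as.character(col)))
      if (length(lv) != 2)
        stop("non-numeric covariate ", dQuote(cv), " must be binary")
      covs[[cv]] <- as.numeric(as.character(col) == lv[2])
      message("covariate ", cv, ": encoded ", lv[2], " = 1, ", lv[1], " = 0")
    }
    if (anyNA(covs[[cv]]))
      stop("covariate ", dQuote(cv), " has missing values; subset samples first")
  }
  covs <- as.matrix(covs)
  covs_c <- scale(covs, center = TRUE, scale = FALSE)

  prot_f <- interaction(design[params$protected], drop = TRUE)
  xmat <- cbind(`(Intercept)` = 1, covs_c,
                stats::model.matrix(~ prot_f)[, -1, drop = FALSE])
  qr_x <- qr(xmat)
  if (qr_x$rank < ncol(xmat)) {
    aliased <- colnames(xmat)[qr_x$pivot[(qr_x$rank + 1):ncol(xmat)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }

  y <- t(v)  # samples x proteins
  n <- nrow(y)
  set.seed(params$seed)
  boot_coef <- array(NA_real_,
                     dim = c(params$n_boot, length(params$covariates),
                             ncol(y)))
  n_redrawn <- 0L
  for (b in seq_len(params$n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (nlevels(droplevels(prot_f[idx])) == nlevels(prot_f)) break
      n_redrawn <- n_redrawn + 1L
    }
    fit <- stats::lm.fit(xmat[idx, , drop = FALSE], y[idx, , drop = FALSE])
    boot_coef[b, , ] <- fit$coefficients[params$covariates, , drop = FALSE]
  }
  if (n_redrawn > 0)
    message("bootstrap_regress: redrew ", n_redrawn,
            " resample(s) missing a protected group level")

  coef_med <- apply(boot_coef, c(2, 3), stats::median)  # covariate x protein
  rownames(coef_med) <- params$covariates
  adj <- t(covs_c %*% coef_med)  # protein x sample
  out <- v - adj
  coefficients <- data.frame(protein_id = rownames(v), t(coef_med),
                             stringsAsFactors = FALSE, check.names = FALSE)
  list(matrix = abundance_matrix(out, "log2"), coefficients = coefficients)
}
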