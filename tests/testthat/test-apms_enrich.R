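test_that("missingness filter keeps <50% and drops >=50% missing proteins", {
  v <- matrix(rnorm(3 * 16, 28, 1), 3, 16,
              dimnames = list(c("full", "half", "seven16"),
                              sprintf("s%02d", 1:16)))
  v["half", 1:8] <- NA        # exactly 50% -> removed
  v["seven16", 1:7] <- NA     # 43.75% -> retained
  f <- filter_missingness(abundance_matrix(v, "log2"))
  expect_identical(rownames(f), c("full", "seven16"))
})

test_that("filter matches a brute-force per-row count oracle on random data", {
  set.seed(11)
  v <- matrix(rnorm(200 * 16, 28, 2), 200, 16,
              dimnames = list(sprintf("P%03d", 1:200), sprintf("s%02d", 1:16)))
  v[sample(length(v), 900)] <- NA
  f <- filter_missingness(abundance_matrix(v, "log2"))
  oracle <- rownames(v)[apply(v, 1, function(r) sum(is.na(r)) < 8)]
  expect_identical(rownames(f), oracle)
  expect_warning(
    filter_missingness(abundance_matrix(
      matrix(NA_real_, 1, 16, dimnames = list("P1", sprintf("s%02d", 1:16))),
      "log2")),
    "removed every protein")
})

test_that("imputation is a no-op on complete matrices and deterministic", {
  m <- random_amat(10, 4, n_missing = 0, seed = 2)
  expect_identical(unclass(impute_missing(m)), unclass(m))
  m2 <- random_amat(30, 6, n_missing = 25, seed = 3)
  i1 <- impute_missing(m2, imputation_params(seed = 5))
  i2 <- impute_missing(m2, imputation_params(seed = 5))
  expect_identical(unclass(i1), unclass(i2))
  i3 <- impute_missing(m2, imputation_params(seed = 6))
  expect_false(identical(unclass(i1), unclass(i3)))
})

test_that("imputation alters exactly the missing cells", {
  m <- random_amat(40, 8, n_missing = 60, seed = 4)
  mask <- is.na(unclass(m))
  imp <- unclass(impute_missing(m, imputation_params(seed = 1)))
  expect_false(anyNA(imp))
  expect_identical(imp[!mask], unclass(m)[!mask])
  expect_true(all(imp[mask] != 0))
})

test_that("imputed draws follow Normal(mean - 1.8 SD, 0.3 SD) per sample", {
  # one sample: observed values with mean 30, SD 2, plus many missing cells
  n_miss <- 1e5
  obs <- as.numeric(scale(rnorm(500))) * 2 + 30
  v <- matrix(c(obs, rep(NA_real_, n_miss)), ncol = 1,
              dimnames = list(sprintf("P%06d", seq_len(500 + n_miss)), "s1"))
  imp <- unclass(impute_missing(abundance_matrix(v, "log2"),
                                imputation_params(seed = 8)))
  draws <- imp[is.na(v)]
  expect_lt(abs(mean(draws) - 26.4), 0.01)
  expect_lt(abs(sd(draws) - 0.6), 0.01)
})

test_that("truncated imputation stays within one width of the noise level", {
  obs <- as.numeric(scale(rnorm(100))) * 2 + 30
  v <- matrix(c(obs, rep(NA_real_, 5000)), ncol = 1,
              dimnames = list(sprintf("P%05d", 1:5100), "s1"))
  imp <- unclass(impute_missing(abundance_matrix(v, "log2"),
                                imputation_params(truncate = TRUE, seed = 1)))
  draws <- imp[is.na(v)]
  expect_true(all(draws >= 26.4 - 0.6 & draws <= 26.4 + 0.6))
})

test_that("samples with too few observations cannot be imputed", {
  v <- matrix(c(1, 2, NA, NA, 5, 6, 7, 8), 4, 2,
              dimnames = list(sprintf("P%d", 1:4), c("bad", "good")))
  expect_error(impute_missing(abundance_matrix(v, "log2")), "bad")
})

test_that("two-group DEA matches hand-computed pooled-variance t", {
  v <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6,
              dimnames = list("P1", sprintf("s%d", 1:6)))
  des <- data.frame(sample_id = sprintf("s%d", 1:6),
                    group = rep(c("A", "B"), each = 3))
  dea <- run_dea(abundance_matrix(v, "log2"), des, contrast = c("A", "B"))
  expect_equal(dea$log2fc, -3)
  expect_equal(dea$t_statistic, -3.674, tolerance = 1e-3)
  oracle <- t.test(v[1, 1:3], v[1, 4:6], var.equal = TRUE)
  expect_equal(dea$raw_p, oracle$p.value, tolerance = 1e-12)
})

test_that("DEA matches t.test across random proteins, pooled and Welch", {
  set.seed(21)
  v <- matrix(rnorm(50 * 16, 28, 1.5), 50, 16,
              dimnames = list(sprintf("P%02d", 1:50), sprintf("s%02d", 1:16)))
  des <- two_group_design(colnames(v), n_bait = 10)
  for (welch in c(FALSE, TRUE)) {
    dea <- run_dea(abundance_matrix(v, "log2"), des,
                   dea_params(welch = welch),
                   contrast = c("sTurbo", "Mock"))
    for (i in c(1, 17, 50)) {
      o <- t.test(v[i, 1:10], v[i, 11:16], var.equal = !welch)
      expect_equal(dea$raw_p[i], o$p.value, tolerance = 1e-10)
      expect_equal(dea$t_statistic[i], unname(o$statistic),
                   tolerance = 1e-10)
    }
  }
})

test_that("a protein identical across groups is a perfect null", {
  v <- matrix(rep(5, 8), 1, 8,
              dimnames = list("P1", sprintf("s%d", 1:8)))
  des <- two_group_design(colnames(v), n_bait = 4)
  dea <- run_dea(abundance_matrix(v, "log2"), des)
  expect_equal(dea$log2fc, 0)
  expect_equal(dea$raw_p, 1)
})

test_that("three-group DEA reproduces aov + TukeyHSD", {
  set.seed(31)
  v <- matrix(rnorm(20 * 121, 0, 1), 20, 121,
              dimnames = list(sprintf("P%02d", 1:20),
                              sprintf("s%03d", 1:121)))
  grp <- rep(c("CTL", "AD", "PSP"), c(46, 49, 26))
  des <- data.frame(sample_id = colnames(v), group = grp)
  dea <- run_dea(abundance_matrix(v, "log2"), des,
                 contrast = c("AD", "CTL"))
  for (i in c(1, 10, 20)) {
    fit <- aov(v[i, ] ~ factor(grp))
    tk <- TukeyHSD(fit)[[1]]
    expect_equal(dea$anova_p[i],
                 summary(fit)[[1]][["Pr(>F)"]][1], tolerance = 1e-8)
    expect_equal(dea$raw_p[i], tk["CTL-AD", "p adj"], tolerance = 1e-6)
    expect_equal(dea$log2fc[i], -tk["CTL-AD", "diff"], tolerance = 1e-10)
  }
})

test_that("tiny Tukey estimates fall back to Bonferroni pairwise t", {
  set.seed(5)
  v <- matrix(rnorm(2 * 30, 0, 0.1), 2, 30,
              dimnames = list(c("big", "null"), sprintf("s%02d", 1:30)))
  grp <- rep(c("A", "B", "C"), each = 10)
  v["big", grp == "A"] <- v["big", grp == "A"] + 10  # astronomically sig.
  des <- data.frame(sample_id = colnames(v), group = grp)
  dea <- run_dea(abundance_matrix(v, "log2"), des, contrast = c("A", "B"))
  t_or <- t.test(v["big", grp == "A"], v["big", grp == "B"],
                 var.equal = TRUE)
  d <- unname(t_or$estimate[1] - t_or$estimate[2])
  mse <- sum(tapply(v["big", ], grp, function(x) sum((x - mean(x))^2))) / 27
  t_pool <- d / sqrt(mse * (1 / 10 + 1 / 10))
  p_bonf <- min(1, 2 * pt(-abs(t_pool), 27) * 3)
  expect_equal(dea$raw_p[1], p_bonf, tolerance = 1e-10)
  # the null protein keeps its ordinary (above-floor) Tukey p
  expect_gt(dea$raw_p[2], 10^-8.5)
  tk <- TukeyHSD(aov(v["null", ] ~ factor(grp)))[[1]]
  expect_equal(dea$raw_p[2], tk["B-A", "p adj"], tolerance = 1e-6)
})

test_that("group and contrast validation errors are informative", {
  v <- matrix(rnorm(4 * 5), 4, 5,
              dimnames = list(sprintf("P%d", 1:4), sprintf("s%d", 1:5)))
  des <- data.frame(sample_id = colnames(v),
                    group = c("A", "A", "B", "B", "C"))
  expect_error(run_dea(abundance_matrix(v, "log2"), des), "fewer than 2")
  des$group <- rep(c("A", "B"), c(3, 2))
  expect_error(run_dea(abundance_matrix(v, "log2"), des,
                       contrast = c("A", "X")), "unknown group")
})

test_that("BH FDR column is monotone-consistent and never below raw p", {
  sim <- generate_apms(apms_sim_spec(n_proteins = 300, seed = 2))
  imp <- impute_missing(filter_missingness(sim$matrix),
                        imputation_params(seed = 1))
  dea <- run_dea(imp, sim$design, contrast = c("sTurbo", "Mock"))
  expect_true(all(dea$fdr_p >= dea$raw_p))
  expect_equal(dea$fdr_p, p.adjust(dea$raw_p, "BH"))
})

test_that("volcano classification honours both thresholds strictly", {
  dea <- data.frame(protein_id = c("a", "b", "c", "d"),
                    log2fc = c(0.99, 8.3, -1.5, 1.2),
                    raw_p = c(0.001, 1e-7, 0.01, 0.2),
                    fdr_p = c(0.002, 1e-6, 0.02, 0.3))
  out <- classify_volcano(dea, dea_params())
  expect_identical(out$class, c("not_significant", "bait_enriched",
                                "control_enriched", "not_significant"))
  cnt <- attr(out, "counts")
  expect_identical(as.vector(cnt), c(1L, 1L, 2L))
})

test_that("planted effects are recovered exactly on complete data", {
  sim <- generate_apms(apms_sim_spec(n_enriched = 5, effect_log2fc = 4,
                                     mnar_slope = 0, seed = 1))
  dea <- classify_volcano(run_dea(sim$matrix, sim$design,
                                  contrast = c("sTurbo", "Mock")))
  hits <- dea$protein_id[dea$class == "bait_enriched"]
  expect_setequal(hits, sim$truth$protein_id[sim$truth$enriched])
})

test_that("with MNAR missingness all planted effects are still detected", {
  sim <- generate_apms(apms_sim_spec(n_enriched = 5, effect_log2fc = 4,
                                     seed = 11))
  imp <- impute_missing(filter_missingness(sim$matrix),
                        imputation_params(seed = 2))
  dea <- classify_volcano(run_dea(imp, sim$design,
                                  contrast = c("sTurbo", "Mock")))
  hits <- dea$protein_id[dea$class == "bait_enriched"]
  expect_true(all(sim$truth$protein_id[sim$truth$enriched] %in% hits))
})

test_that("null DEA p-values are uniform (pooled Kolmogorov-Smirnov)", {
  ps <- unlist(lapply(1:20, function(s) {
    sim <- generate_apms(apms_sim_spec(n_proteins = 500, n_enriched = 0,
                                       mnar_slope = 0, seed = s))
    run_dea(sim$matrix, sim$design, contrast = c("sTurbo", "Mock"))$raw_p
  }))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
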