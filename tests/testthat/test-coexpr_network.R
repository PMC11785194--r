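test_that("bicor satisfies identity, antisymmetry and bounds", {
  set.seed(1)
  x <- rnorm(50)
  expect_equal(bicor(x, x), 1)
  expect_equal(bicor(x, -x), -1)
  y <- rnorm(50)
  expect_true(abs(bicor(x, y)) <= 1)
})

test_that("bicor tracks Pearson on bivariate Gaussian data", {
  set.seed(2)
  diffs <- replicate(1000, {
    z <- rnorm(100)
    x <- z + rnorm(100, 0, sqrt(1 / 0.6^2 - 1))
    y <- z + rnorm(100, 0, sqrt(1 / 0.6^2 - 1))
    abs(bicor(x, y) - cor(x, y))
  })
  expect_lt(mean(diffs), 0.02)
})

test_that("bicor degenerate inputs error or fall back as documented", {
  expect_error(bicor(1:3, 1:3), "length >= 4")
  expect_error(bicor(rep(1, 10), rnorm(10)), "constant")
  # MAD = 0 but SD > 0: Pearson fallback with a message
  x <- c(rep(0, 8), 5, -5)
  y <- rnorm(10)
  expect_message(r <- bicor(x, y), "fallback")
  expect_equal(r, suppressMessages(bicor(x, y)))
})

test_that("signed adjacency maps correlation endpoints exactly", {
  r <- matrix(c(1, 1, -1, 0, 0.8,
                1, 1, 0, 0, 0,
                -1, 0, 1, 0, 0,
                0, 0, 0, 1, 0,
                0.8, 0, 0, 0, 1), 5, 5)
  r <- (r + t(r)) / 2; diag(r) <- 1
  a <- signed_adjacency(r, network_params(beta = 9))
  expect_equal(a[1, 2], 1)
  expect_equal(a[1, 3], 0)
  expect_equal(a[1, 4], 0.5^9)
  expect_equal(a[1, 5], 0.9^9)
  expect_error(signed_adjacency(matrix(c(1, 2, 2, 1), 2), network_params()),
               "outside")
})

test_that("TOM reproduces the hand-evaluated 3-node case", {
  a <- matrix(0.5, 3, 3); diag(a) <- 1
  tom <- tom_similarity(a)
  expect_equal(tom[1, 2], (0.25 + 0.5) / (0.5 * (1 + 1) + 1 - 0.5))
  expect_equal(tom[1, 2], 0.5)
})

test_that("an edgeless adjacency has zero topological overlap", {
  tom <- tom_similarity(diag(4))
  expect_true(all(tom[upper.tri(tom)] == 0))
  expect_true(all(diag(tom) == 1))
})

test_that("TOM equals the brute-force double loop on random matrices", {
  for (s in 1:50) {
    set.seed(s)
    p <- sample(5:15, 1)
    a <- matrix(runif(p * p), p, p)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    tom <- tom_similarity(a)
    expect_equal(unname(tom), brute_force_tom(a), tolerance = 1e-12)
    expect_true(all(tom >= 0 & tom <= 1))
    expect_true(isSymmetric(tom))
  }
  expect_error(tom_similarity(matrix(runif(9), 3, 3)), "symmetric")
})

test_that("average-linkage dendrogram handles forced topologies", {
  d <- matrix(1, 6, 6)
  d[1:3, 1:3] <- 0; d[4:6, 4:6] <- 0; diag(d) <- 0
  dimnames(d) <- list(letters[1:6], letters[1:6])
  dend <- cluster_dendrogram(d)
  expect_equal(max(dend$height), 1)
  expect_equal(sort(cutree(dend, k = 2)[1:3]), cutree(dend, k = 2)[1:3])
  # 4-point fixture against hand agglomeration: merge (a,b)@0.1,
  # (c,d)@0.2, then average of the 4 cross distances @ mean(.5,.6,.7,.8)
  d4 <- matrix(c(0, .1, .5, .6,
                 .1, 0, .7, .8,
                 .5, .7, 0, .2,
                 .6, .8, .2, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  h <- cluster_dendrogram(d4)$height
  expect_equal(h, c(0.1, 0.2, mean(c(.5, .6, .7, .8))))
  dn <- d4; dn[1, 2] <- NaN; dn[2, 1] <- NaN
  expect_error(cluster_dendrogram(dn), "finite")
})

test_that("dendrograms are isomorphic under input permutation", {
  bm <- block_matrix(c(10, 10), n_samp = 60, r_w = 0.9, seed = 3)
  d <- 1 - tom_similarity(signed_adjacency(
    bicor_mat <- suppressMessages(cor(t(unclass(bm$matrix)))),
    network_params()))
  diag(d) <- 0
  dend1 <- cluster_dendrogram(d)
  perm <- sample(nrow(d))
  dend2 <- cluster_dendrogram(d[perm, perm])
  expect_equal(sort(dend1$height), sort(dend2$height), tolerance = 1e-12)
})

test_that("two planted blocks are cut into exactly two modules", {
  skip_if_not_installed("mclust")
  bm <- block_matrix(c(60, 60), n_samp = 100, r_w = 0.9, seed = 7)
  net <- build_network(bm$matrix, network_params(), keep_tom = FALSE)
  rec <- net$modules$labels[names(bm$labels)]
  expect_equal(max(rec), 2)
  expect_equal(mclust::adjustedRandIndex(rec, bm$labels), 1.0)
})

test_that("blocks below the minimum module size dissolve to grey", {
  bm <- block_matrix(10, n_samp = 80, r_w = 0.9, n_noise = 90, seed = 4)
  v <- unclass(bm$matrix)
  corr <- suppressMessages(cor(t(v)))
  diss <- 1 - tom_similarity(signed_adjacency(corr, network_params()))
  diag(diss) <- 0
  dend <- cluster_dendrogram(diss)
  expect_warning(
    labels <- dynamic_hybrid_cut(dend, diss, network_params()),
    "unassigned")
  expect_true(all(labels == 0))
})

test_that("the tree cut and PAM stage are deterministic", {
  bm <- block_matrix(c(40, 30), n_samp = 80, r_w = 0.8, n_noise = 30,
                     seed = 9)
  v <- unclass(bm$matrix)
  diss <- 1 - tom_similarity(signed_adjacency(cor(t(v)), network_params()))
  diag(diss) <- 0
  dend <- cluster_dendrogram(diss)
  l1 <- dynamic_hybrid_cut(dend, diss, network_params())
  l2 <- dynamic_hybrid_cut(dend, diss, network_params())
  expect_identical(l1, l2)
  expect_gte(max(l1), 2)
})

test_that("a degenerate module of identical profiles has eigengene = profile", {
  set.seed(5)
  prof <- rnorm(30)
  v <- matrix(rep(prof, each = 4), 4, 30, byrow = FALSE,
              dimnames = list(sprintf("P%d", 1:4), sprintf("s%02d", 1:30)))
  v <- v * c(1, 2, 3, 4) + c(0, 1, 2, 3)   # same shape, different scale
  eg <- module_eigengenes(abundance_matrix(v, "log2"),
                          setNames(rep(1L, 4), rownames(v)))
  expect_equal(abs(cor(eg$eigengenes[, "M1"], prof)), 1, tolerance = 1e-10)
  expect_equal(unname(eg$variance_explained["M1"]), 1, tolerance = 1e-10)
})

test_that("eigengene sign follows the mean module profile", {
  for (s in 1:100) {
    set.seed(s)
    v <- matrix(rnorm(6 * 20), 6, 20,
                dimnames = list(sprintf("P%d", 1:6), sprintf("s%02d", 1:20)))
    eg <- module_eigengenes(abundance_matrix(v, "log2"),
                            setNames(rep(1L, 6), rownames(v)))
    z <- (v - rowMeans(v)) / apply(v, 1, sd)
    expect_gte(cor(eg$eigengenes[, 1], colMeans(z)), 0)
  }
})

test_that("variance explained reflects the planted within-module correlation", {
  bm <- block_matrix(60, n_samp = 121, r_w = 0.9, seed = 12)
  eg <- module_eigengenes(bm$matrix, bm$labels)
  expect_gte(eg$variance_explained[["M1"]], 0.75)
  expect_lte(eg$variance_explained[["M1"]], 0.95)
})

test_that("modules driven by one latent factor merge; distinct ones do not", {
  set.seed(20)
  f <- rnorm(100); g <- rnorm(100)
  mk <- function(fac, n, tag) {
    v <- t(sapply(seq_len(n), function(i) fac + rnorm(100, 0, 0.15)))
    rownames(v) <- sprintf("%s%02d", tag, seq_len(n)); v
  }
  v <- rbind(mk(f, 30, "A"), mk(f, 30, "B"), mk(g, 30, "C"))
  colnames(v) <- sprintf("s%03d", 1:100)
  labels <- setNames(rep(1:3, each = 30), rownames(v))
  ms <- merge_and_reassign(abundance_matrix(v, "log2"), labels,
                           network_params(merge_cut_height = 0.07))
  lab <- ms$labels
  expect_length(unique(lab[1:60]), 1)            # A and B merged
  expect_false(unique(lab[61:90]) %in% lab[1:60])  # C stays apart
  expect_equal(ncol(ms$eigengenes), 2)
})

test_that("eigengene dissimilarity above the cut height blocks merging", {
  # two factors correlated at r = 0.5: dissimilarity 0.5 >> 0.07
  set.seed(21)
  f <- rnorm(80)
  g <- 0.5 * f + sqrt(1 - 0.25) * rnorm(80)
  v <- rbind(t(replicate(25, f + rnorm(80, 0, 0.2))),
             t(replicate(25, g + rnorm(80, 0, 0.2))))
  dimnames(v) <- list(sprintf("P%02d", 1:50), sprintf("s%02d", 1:80))
  ms <- merge_and_reassign(abundance_matrix(v, "log2"),
                           setNames(rep(1:2, each = 25), rownames(v)),
                           network_params())
  expect_equal(ncol(ms$eigengenes), 2)
})

test_that("a protein planted in the wrong module is reassigned by kME", {
  # module sizes of 50 keep the mislabelled protein from inflating its
  # own-module eigengene correlation past the significance gate
  set.seed(22)
  n <- 60
  f <- rnorm(n); g <- rnorm(n)
  v <- rbind(t(replicate(50, f + rnorm(n, 0, 0.3))),
             t(replicate(50, g + rnorm(n, 0, 0.3))))
  dimnames(v) <- list(sprintf("P%03d", 1:100), sprintf("s%02d", 1:n))
  labels <- setNames(rep(1:2, each = 50), rownames(v))
  labels["P100"] <- 1L   # P100 is driven by g but labelled module 1
  ms <- merge_and_reassign(abundance_matrix(v, "log2"), labels,
                           network_params())
  expect_equal(ms$labels[["P100"]], ms$labels[["P099"]])
})

test_that("kME is 1 for a protein equal to its module eigengene", {
  bm <- block_matrix(20, n_samp = 50, r_w = 0.85, seed = 30)
  eg <- module_eigengenes(bm$matrix, bm$labels)
  v2 <- rbind(unclass(bm$matrix), ME_copy = eg$eigengenes[, "M1"])
  km <- signed_kme(abundance_matrix(v2, "log2"), eg$eigengenes)
  expect_equal(unname(km$r["ME_copy", "M1"]), 1, tolerance = 1e-10)
  expect_identical(dim(km$r), c(21L, 1L))
  expect_identical(dim(km$p), dim(km$r))
})

test_that("module proteins dominate background proteins in own-module kME", {
  bm <- block_matrix(50, n_samp = 100, r_w = 0.8, n_noise = 50, seed = 31)
  eg <- module_eigengenes(bm$matrix, bm$labels)
  km <- signed_kme(bm$matrix, eg$eigengenes)
  own <- km$r[bm$labels == 1, "M1"]
  bg <- km$r[bm$labels == 0, "M1"]
  frac <- mean(outer(own, bg, `>`))
  expect_gte(frac, 0.99)
})

test_that("module-trait correlation recovers identities and planted loadings", {
  bm <- block_matrix(40, n_samp = 121, r_w = 0.8, seed = 40)
  eg <- module_eigengenes(bm$matrix, bm$labels)
  des <- data.frame(sample_id = colnames(bm$matrix), group = "x",
                    self = eg$eigengenes[, "M1"],
                    flat = 1)
  tc <- module_trait_correlation(eg$eigengenes, des,
                                 traits = c("self", "flat"))
  expect_equal(unname(tc$r["M1", "self"]), 1, tolerance = 1e-10)
  expect_identical(unname(tc$stars["M1", "self"]), "***")
  expect_true(is.na(tc$r["M1", "flat"]))
})

test_that("planted trait loadings are recovered within the expected band", {
  rs <- sapply(1:2, function(s) {
    sim <- generate_cohort(cohort_sim_spec(
      n_proteins = 150, module_sizes = c(60, 40),
      batch_offsets = c(b = 0), gis_per_batch = 0,
      covariate_effects = c(age = 0, sex = 0, pmi = 0), dx_effects = list(),
      trait_loadings = list(Braak = c(module = 1, loading = 0.6)),
      seed = s))
    eg <- module_eigengenes(sim$matrix,
                            setNames(sim$truth$proteins$module,
                                     sim$truth$proteins$protein_id))
    tc <- module_trait_correlation(eg$eigengenes, sim$design,
                                   traits = "Braak")
    abs(tc$r["M1", "Braak"])
  })
  expect_true(all(rs >= 0.45 & rs <= 0.75))
})

test_that("permuted traits are significant at the nominal 5% rate", {
  bm <- block_matrix(40, n_samp = 121, r_w = 0.8, seed = 41)
  eg <- module_eigengenes(bm$matrix, bm$labels)
  me <- eg$eigengenes[, 1]
  set.seed(42)
  trait <- rnorm(121)
  hits <- replicate(1000, {
    tp <- sample(trait)
    r <- bicor(me, tp)
    t <- abs(r) * sqrt(119 / (1 - r^2))
    2 * pt(-t, 119) < 0.05
  })
  expect_gt(mean(hits), 0.03)
  expect_lt(mean(hits), 0.07)
})

test_that("top TOM edge export honours count, ordering and oracle", {
  bm <- block_matrix(50, n_samp = 80, r_w = 0.8, seed = 50)
  tom <- tom_similarity(signed_adjacency(cor(t(unclass(bm$matrix))),
                                         network_params()))
  # 5-protein module, 10 pairs, frac 0.05 -> exactly the single best pair
  lab5 <- setNames(c(rep(1L, 5), rep(0L, 45)), rownames(tom))
  e1 <- top_tom_edges(tom, lab5, 1, network_params(top_edge_frac = 0.05))
  expect_identical(nrow(e1), 1L)
  sub <- tom[1:5, 1:5]
  expect_equal(e1$weight, max(sub[upper.tri(sub)]))
  # frac = 1 returns every pair
  eall <- top_tom_edges(tom, lab5, 1, network_params(top_edge_frac = 1))
  expect_identical(nrow(eall), 10L)
  # 50-protein module against a brute-force sort-and-slice oracle
  lab50 <- setNames(rep(1L, 50), rownames(tom))
  e5 <- top_tom_edges(tom, lab50, 1, network_params(top_edge_frac = 0.05))
  pairs <- t(combn(sort(rownames(tom)), 2))
  w <- tom[pairs]
  oracle <- order(-w)[seq_len(ceiling(0.05 * nrow(pairs)))]
  expect_setequal(paste(e5$node_a, e5$node_b),
                  paste(pairs[oracle, 1], pairs[oracle, 2]))
  expect_true(all(diff(e5$weight) <= 0))
  expect_warning(top_tom_edges(tom, setNames(rep(0L, 50), rownames(tom)),
                               1, network_params()),
                 "fewer than 2")
})

test_that("the full network path is deterministic", {
  bm <- block_matrix(c(30, 30), n_samp = 60, r_w = 0.85, n_noise = 20,
                     seed = 60)
  n1 <- build_network(bm$matrix, network_params(), keep_tom = FALSE)
  n2 <- build_network(bm$matrix, network_params(), keep_tom = FALSE)
  expect_identical(n1$modules$labels, n2$modules$labels)
  expect_identical(n1$modules$eigengenes, n2$modules$eigengenes)
})
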