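#' Parameters for signed weighted co-expression network construction
#'
#' Defaults follow common practice for deeply-fractionated brain proteome
#' networks: soft power 9 on a signed adjacency, mean-denominator topological
#' overlap, dynamic hybrid tree cut at deepSplit 2 with minimum module size
#' 25 and a dendrogram-respecting PAM stage, eigengene merge cut height 0.07,
#' and module reassignment at p < 0.05.
#'
#' @param beta soft-thresholding power (>= 1).
#' @param deep_split dendrogram split sensitivity, integer 0..4.
#' @param min_module_size smallest module created by the tree cut.
#' @param merge_cut_height eigengene dissimilarity (1 - correlation) below
#'   which modules are merged, in (0, 1).
#' @param pam_stage run the dendrogram-respecting partitioning-around-medoids
#'   assignment of leftover proteins.
#' @param reassign_p significance threshold for kME-based module
#'   reassignment.
#' @param top_edge_frac fraction of intra-module pairs exported as top-TOM
#'   edges, in (0, 1].
#' @param cor_method `"bicor"` (biweight midcorrelation, default) or
#'   `"pearson"` for the network correlation.
#' @export
network_params <- function(beta = 9, deep_split = 2, min_module_size = 25,
                           merge_cut_height = 0.07, pam_stage = TRUE,
                           reassign_p = 0.05, top_edge_frac = 0.05,
                           cor_method = c("bicor", "pearson")) {
  cor_method <- match.arg(cor_method)
  if (beta < 1) stop("beta must be >= 1")
  if (!deep_split %in% 0:4) stop("deep_split must be an integer in 0..4")
  if (merge_cut_height <= 0 || merge_cut_height >= 1)
    stop("merge_cut_height must lie in (0, 1)")
  if (top_edge_frac <= 0 || top_edge_frac > 1)
    stop("top_edge_frac must lie in (0, 1]")
  structure(list(beta = beta, network_sign = "signed",
                 tom_denominator = "mean", deep_split = deep_split,
                 min_module_size = min_module_size,
                 merge_cut_height = merge_cut_height, pam_stage = pam_stage,
                 reassign_p = reassign_p, top_edge_frac = top_edge_frac,
                 cor_method = cor_method),
            class = "NetworkParams")
}

# Standardize one vector for biweight midcorrelation: median/MAD-based
# weights w = (1 - u^2)^2 on |u| < 1 with u = (x - med) / (9 * MAD).
# Falls back to Pearson standardization when MAD = 0 but SD > 0.
bicor_standardize <- function(x, label = "vector") {
  med <- stats::median(x)
  madv <- stats::mad(x, constant = 1)
  if (madv == 0) {
    if (stats::sd(x) == 0)
      stop("undefined correlation: ", label, " is constant")
    w <- x - mean(x)
    attr_fallback <- TRUE
  } else {
    u <- (x - med) / (9 * madv)
    wt <- (1 - u^2)^2 * (abs(u) < 1)
    w <- (x - med) * wt
    attr_fallback <- FALSE
  }
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) stop("undefined correlation: ", label,
                     " has zero weighted variance")
  structure(w / nrm, fallback = attr_fallback)
}

#' Biweight midcorrelation
#'
#' A robust correlation: deviations from the median are weighted by
#' `(1 - u^2)^2` with `u = (x - median) / (9 * MAD)`, observations beyond
#' `|u| >= 1` receiving zero weight. When a vector's MAD is zero but its SD
#' is not, the computation falls back to Pearson for that vector (with a
#' message).
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return correlation in `[-1, 1]`.
#' @export
bicor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4) stop("bicor requires length >= 4")
  wx <- bicor_standardize(x, "x")
  wy <- bicor_standardize(y, "y")
  if (attr(wx, "fallback") || attr(wy, "fallback"))
    message("bicor: MAD = 0, Pearson fallback used")
  min(1, max(-1, sum(wx * wy)))
}

# Column-wise bicor of a samples x variables matrix (cor()-like orientation).
bicor_matrix <- function(m) {
  w <- bicor_standardize_cols(m)
  r <- crossprod(w)
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  r
}

# Cross-correlation bicor between columns of two samples x variables matrices.
bicor_cross <- function(mx, my) {
  r <- crossprod(bicor_standardize_cols(mx), bicor_standardize_cols(my))
  r[r > 1] <- 1; r[r < -1] <- -1
  r
}

bicor_standardize_cols <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 4) stop("bicor requires >= 4 observations")
  n_fallback <- 0L
  w <- m
  for (j in seq_len(ncol(m))) {
    s <- bicor_standardize(m[, j],
                           label = colnames(m)[j] %||% paste("column", j))
    if (attr(s, "fallback")) n_fallback <- n_fallback + 1L
    w[, j] <- s
  }
  if (n_fallback > 0)
    message("bicor: Pearson fallback for ", n_fallback,
            " column(s) with MAD = 0")
  w
}

`%||%` <- function(a, b) {
  if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
}

#' Signed soft-thresholded adjacency
#'
#' `a_ij = ((1 + r_ij) / 2) ^ beta`: perfectly anti-correlated pairs get
#' adjacency 0, perfectly correlated pairs 1, so the sign of the correlation
#' is preserved in the network topology.
#'
#' @param corr symmetric correlation matrix with unit diagonal.
#' @param params a [network_params()] (uses `beta`).
#' @return adjacency matrix in `[0, 1]` with unit diagonal.
#' @export
signed_adjacency <- function(corr, params = network_params()) {
  corr <- as.matrix(corr)
  if (any(corr < -1 - 1e-8 | corr > 1 + 1e-8))
    stop("correlations outside [-1, 1]")
  a <- ((1 + pmin(pmax(corr, -1), 1)) / 2)^params$beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix (mean denominator)
#'
#' With shared-neighbour weight `l_ij = sum_u a_iu a_uj` (u != i, j) and
#' connectivity `k_i = sum_u a_iu` (u != i):
#' `TOM_ij = (l_ij + a_ij) / (0.5 * (k_i + k_j) + 1 - a_ij)`, diagonal 1.
#' The corresponding dissimilarity is `1 - TOM`.
#'
#' @param adj symmetric adjacency with unit diagonal.
#' @return TOM similarity matrix in `[0, 1]`.
#' @export
tom_similarity <- function(adj) {
  adj <- as.matrix(adj)
  if (!isSymmetric(unname(adj), tol = 1e-10)) stop("adjacency must be symmetric")
  a0 <- adj
  diag(a0) <- 0
  l <- a0 %*% a0
  k <- rowSums(a0)
  denom <- 0.5 * outer(k, k, `+`) + 1 - a0
  tom <- (l + a0) / denom
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Average-linkage dendrogram of a dissimilarity matrix
#'
#' @param diss symmetric dissimilarity with zero diagonal and no NaN.
#' @return an `hclust` object.
#' @export
cluster_dendrogram <- function(diss) {
  diss <- as.matrix(diss)
  if (any(!is.finite(diss))) stop("dissimilarities must be finite")
  if (!isSymmetric(unname(diss), tol = 1e-10))
    stop("dissimilarity must be symmetric")
  if (any(abs(diag(diss)) > 1e-12)) stop("dissimilarity diagonal must be 0")
  stats::hclust(stats::as.dist(diss), method = "average")
}

# deep_split -> (maxCoreScatter, minGap) mapping, dynamic-tree-cut convention.
deep_split_criteria <- function(deep_split) {
  mcs <- c(0.64, 0.73, 0.82, 0.91, 0.95)[deep_split + 1]
  list(max_core_scatter = mcs, min_gap = 0.75 * (1 - mcs))
}

#' Dynamic hybrid tree cut
#'
#' Identifies module branches of an average-linkage dendrogram. Merge heights
#' are rescaled to `[0, 1]`; a branch becomes a module when (i) it has at
#' least `min_module_size` leaves, (ii) its core scatter (mean rescaled merge
#' height inside the branch) is at most the deepSplit-dependent
#' `maxCoreScatter`, and (iii) the gap between the height at which it joins
#' the rest of the tree and its own top merge is at least
#' `minGap = 0.75 * (1 - maxCoreScatter)`. The tree is walked from the root;
#' the outermost qualifying branch wins, and branches too small to qualify
#' are left unassigned (label 0). The optional PAM stage then assigns each
#' unassigned protein to the module with smallest average dissimilarity,
#' restricted to modules on the protein's own dendrogram branch (ties broken
#' by lowest module label). Labels are renumbered by decreasing module size.
#'
#' @param dend an `hclust` from [cluster_dendrogram()] on `diss`.
#' @param diss the dissimilarity matrix the dendrogram was built on.
#' @param params a [network_params()].
#' @return integer labels named by protein; 0 = unassigned (grey).
#' @export
dynamic_hybrid_cut <- function(dend, diss, params = network_params()) {
  n <- length(dend$order)
  diss <- as.matrix(diss)
  crit <- deep_split_criteria(params$deep_split)
  h <- dend$height
  rng <- max(h) - min(h)
  hr <- if (rng > 0) (h - min(h)) / rng else rep(0, length(h))

  n_nodes <- nrow(dend$merge)
  members <- vector("list", n_nodes)
  top <- numeric(n_nodes)
  cs_sum <- numeric(n_nodes)   # sum of rescaled internal merge heights
  cs_n <- integer(n_nodes)
  for (k in seq_len(n_nodes)) {
    ch <- dend$merge[k, ]
    mem <- integer(0); s <- hr[k]; cnt <- 1L
    for (c in ch) {
      if (c < 0) mem <- c(mem, -c)
      else {
        mem <- c(mem, members[[c]])
        s <- s + cs_sum[c]; cnt <- cnt + cs_n[c]
      }
    }
    members[[k]] <- mem; top[k] <- hr[k]; cs_sum[k] <- s; cs_n[k] <- cnt
  }

  labels <- integer(n)
  next_label <- 0L
  # walk from the root; join height of the root is its own top (gap 0), so
  # the root itself always splits at least once
  stack <- list(list(node = n_nodes, join = top[n_nodes]))
  while (length(stack)) {
    fr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    k <- fr$node
    if (k < 0) next                      # leaf: stays unassigned
    size <- length(members[[k]])
    if (size < params$min_module_size) next
    gap <- fr$join - top[k]
    core_scatter <- cs_sum[k] / cs_n[k]
    if (gap >= crit$min_gap && core_scatter <= crit$max_core_scatter) {
      next_label <- next_label + 1L
      labels[members[[k]]] <- next_label
    } else {
      for (c in dend$merge[k, ])
        stack[[length(stack) + 1L]] <- list(node = c, join = top[k])
    }
  }

  if (params$pam_stage && next_label > 0 && any(labels == 0)) {
    labels <- pam_assign(labels, dend, diss, members)
  }
  if (all(labels == 0)) warning("dynamic_hybrid_cut: no module found; all proteins unassigned")

  labels <- renumber_by_size(labels)
  names(labels) <- dend$labels %||% as.character(seq_len(n))
  labels
}

# Dendrogram-respecting PAM: each unassigned leaf is assigned to the module
# with smallest average dissimilarity among modules under the nearest
# ancestor branch that contains any assigned leaf.
pam_assign <- function(labels, dend, diss, members) {
  n <- length(labels)
  n_nodes <- nrow(dend$merge)
  parent_leaf <- integer(n); parent_node <- integer(n_nodes)
  for (k in seq_len(n_nodes)) {
    for (c in dend$merge[k, ]) {
      if (c < 0) parent_leaf[-c] <- k else parent_node[c] <- k
    }
  }
  mod_members <- split(seq_len(n)[labels > 0], labels[labels > 0])
  has_assigned <- vapply(seq_len(n_nodes),
                         function(k) any(labels[members[[k]]] > 0),
                         logical(1))
  out <- labels
  for (i in which(labels == 0)) {
    k <- parent_leaf[i]
    while (k != 0 && !has_assigned[k]) k <- parent_node[k]
    cand <- if (k == 0) sort(unique(labels[labels > 0]))
            else sort(unique(labels[members[[k]]][labels[members[[k]]] > 0]))
    avg <- vapply(as.character(cand),
                  function(m) mean(diss[i, mod_members[[m]]]), numeric(1))
    out[i] <- cand[which.min(avg)]   # which.min: first (lowest label) on tie
  }
  out
}

renumber_by_size <- function(labels) {
  pos <- labels[labels > 0]
  if (!length(pos)) return(labels)
  sizes <- table(pos)
  ord <- names(sizes)[order(-as.numeric(sizes), as.numeric(names(sizes)))]
  map <- stats::setNames(seq_along(ord), ord)
  out <- labels
  out[labels > 0] <- map[as.character(pos)]
  as.integer(out) -> out2
  names(out2) <- names(labels)
  out2
}

#' Module eigengenes
#'
#' Each module's proteins are standardized (z-score across samples); the
#' eigengene is the first principal component over samples, sign-oriented so
#' it correlates positively with the module's mean standardized profile.
#'
#' @param x complete log2 [abundance_matrix()] (proteins x samples).
#' @param labels integer module labels named by protein (0 = grey, excluded).
#' @return list with `eigengenes` (samples x modules matrix, columns
#'   `M1, M2, ...`) and `variance_explained` (named numeric).
#' @export
module_eigengenes <- function(x, labels) {
  x <- as_abundance(x)
  v <- unclass(x)
  if (anyNA(v)) stop("module_eigengenes requires a complete matrix")
  labels <- labels[rownames(v)]
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) stop("no assigned modules")
  me <- matrix(NA_real_, ncol(v), length(mods),
               dimnames = list(colnames(v), paste0("M", mods)))
  ve <- stats::setNames(numeric(length(mods)), paste0("M", mods))
  for (j in seq_along(mods)) {
    sub <- v[labels == mods[j], , drop = FALSE]
    z <- row_zscore(sub)
    if (nrow(z) == 1) {
      message("module M", mods[j], " has a single protein; eigengene equals ",
              "its z-profile")
      me[, j] <- z[1, ]; ve[j] <- 1
      next
    }
    sv <- svd(z, nu = 0, nv = 1)
    pc <- sv$v[, 1]
    if (stats::cor(pc, colMeans(z)) < 0) pc <- -pc
    me[, j] <- pc
    ve[j] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = me, variance_explained = ve)
}

row_zscore <- function(m) {
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  if (any(sdv == 0))
    stop("zero-variance protein(s): ",
         paste(utils::head(rownames(m)[sdv == 0], 5), collapse = ", "))
  (m - mu) / sdv
}

#' Merge close modules and reassign misplaced proteins
#'
#' Modules whose eigengenes are closer than `merge_cut_height` on the
#' `1 - correlation` scale are merged (average-linkage clustering of
#' eigengene dissimilarity cut at that height) and eigengenes recomputed.
#' Then one reassignment pass moves every protein whose kME (biweight
#' midcorrelation with an eigengene) to a foreign module exceeds its
#' own-module kME, with the foreign correlation significant at `reassign_p`
#' while the own-module correlation is not. Labels are renumbered by
#' decreasing size and the final eigengene/kME tables recomputed.
#'
#' @param x complete log2 [abundance_matrix()].
#' @param labels integer labels from [dynamic_hybrid_cut()].
#' @param params a [network_params()].
#' @return a `ModuleSet`: list with `labels`, `eigengenes`,
#'   `variance_explained`, `kme` (list of `r` and `p` matrices).
#' @export
merge_and_reassign <- function(x, labels, params = network_params()) {
  x <- as_abundance(x)
  labels <- labels[rownames(unclass(x))]
  eg <- module_eigengenes(x, labels)
  if (ncol(eg$eigengenes) > 1) {
    d <- 1 - stats::cor(eg$eigengenes)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    grp <- stats::cutree(hc, h = params$merge_cut_height)
    mod_ids <- as.integer(sub("^M", "", colnames(eg$eigengenes)))
    remap <- stats::setNames(
      vapply(grp, function(g) min(mod_ids[grp == g]), integer(1)), NULL)
    map <- stats::setNames(remap, mod_ids)
    labels[labels > 0] <- map[as.character(labels[labels > 0])]
    eg <- module_eigengenes(x, labels)
  }
  km <- signed_kme(x, eg$eigengenes)
  labels <- reassign_by_kme(labels, km, params$reassign_p)
  labels <- renumber_by_size(labels)
  eg <- module_eigengenes(x, labels)
  km <- signed_kme(x, eg$eigengenes)
  structure(list(labels = labels, eigengenes = eg$eigengenes,
                 variance_explained = eg$variance_explained, kme = km),
            class = "ModuleSet")
}

reassign_by_kme <- function(labels, km, reassign_p) {
  mod_ids <- as.integer(sub("^M", "", colnames(km$r)))
  for (i in which(labels > 0)) {
    own <- match(labels[i], mod_ids)
    best <- which.max(km$r[i, ])
    if (best != own &&
        km$r[i, best] > km$r[i, own] &&
        km$p[i, best] < reassign_p &&
        km$p[i, own] >= reassign_p) {
      labels[i] <- mod_ids[best]
    }
  }
  labels
}

#' Signed module membership (kME)
#'
#' `kME(protein, module)` is the biweight midcorrelation of the protein's
#' profile with the module eigengene; two-tailed p-values come from the
#' correlation t-transform `t = r * sqrt((n - 2) / (1 - r^2))`. Proteins with
#' the highest own-module kME are the module hubs.
#'
#' @param x complete log2 [abundance_matrix()].
#' @param eigengenes samples x modules eigengene matrix.
#' @return list with matrices `r` and `p` (proteins x modules).
#' @export
signed_kme <- function(x, eigengenes) {
  x <- as_abundance(x)
  v <- unclass(x)
  r <- bicor_cross(t(v), eigengenes)
  n <- ncol(v)
  r_t <- pmin(abs(r), 1 - 1e-15)
  tstat <- r_t * sqrt((n - 2) / (1 - r_t^2))
  p <- 2 * stats::pt(-tstat, n - 2)
  dimnames(p) <- dimnames(r)
  list(r = r, p = p)
}

#' Module hub proteins
#'
#' @param module_set a `ModuleSet` from [merge_and_reassign()].
#' @param n_hubs hubs per module.
#' @return named list: module -> character vector of hub proteins ordered by
#'   decreasing own-module kME.
#' @export
module_hubs <- function(module_set, n_hubs = 10) {
  labels <- module_set$labels
  out <- list()
  for (m in sort(unique(labels[labels > 0]))) {
    prot <- names(labels)[labels == m]
    k <- module_set$kme$r[prot, paste0("M", m)]
    out[[paste0("M", m)]] <- prot[order(-k)][seq_len(min(n_hubs, length(prot)))]
  }
  out
}

#' Module-trait correlation table
#'
#' Biweight midcorrelation of each module eigengene with each numeric trait
#' (neuropathology scores, 0/1-encoded diagnosis indicators, ...), with
#' t-transform p-values and significance stars at 0.05 / 0.01 / 0.001.
#' Samples with a missing trait value are dropped pairwise; constant traits
#' yield `NA`.
#'
#' @param eigengenes samples x modules eigengene matrix.
#' @param design design rows for those samples.
#' @param traits design columns to correlate; defaults to every numeric
#'   column.
#' @return list of class `TraitCorTable` with matrices `r`, `p`, `stars`
#'   (modules x traits) and a long-format `table` data.frame.
#' @export
module_trait_correlation <- function(eigengenes, design, traits = NULL) {
  design <- validate_design(design)
  design <- design[match(rownames(eigengenes), design$sample_id), ,
                   drop = FALSE]
  if (is.null(traits)) {
    num <- vapply(design, is.numeric, logical(1))
    traits <- setdiff(colnames(design)[num], c("is_gis"))
  }
  mods <- colnames(eigengenes)
  r <- p <- matrix(NA_real_, length(mods), length(traits),
                   dimnames = list(mods, traits))
  for (tr in traits) {
    tv <- design[[tr]]
    ok <- !is.na(tv)
    if (sum(ok) < 4 || stats::sd(tv[ok]) == 0) {
      message("trait ", tr, " is constant or too sparse; reported as NA")
      next
    }
    for (m in mods) {
      r[m, tr] <- bicor(eigengenes[ok, m], tv[ok])
    }
    n <- sum(ok)
    r_t <- pmin(abs(r[, tr]), 1 - 1e-15)
    tstat <- r_t * sqrt((n - 2) / (1 - r_t^2))
    p[, tr] <- 2 * stats::pt(-tstat, n - 2)
  }
  stars <- matrix("", length(mods), length(traits),
                  dimnames = dimnames(r))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  stars[!is.na(p) & p < 0.001] <- "***"
  long <- data.frame(module = rep(mods, times = length(traits)),
                     trait = rep(traits, each = length(mods)),
                     r = as.vector(r), p = as.vector(p),
                     stars = as.vector(stars), stringsAsFactors = FALSE)
  structure(list(r = r, p = p, stars = stars, table = long),
            class = "TraitCorTable")
}

#' Top intra-module TOM edges
#'
#' Among all within-module protein pairs, returns the `top_edge_frac`
#' fraction (count rounded up) with the highest topological overlap, sorted
#' by decreasing weight with lexicographic tie-break on the (sorted) pair.
#'
#' @param tom TOM similarity matrix with protein dimnames.
#' @param labels module labels named by protein.
#' @param module_id module to export.
#' @param params a [network_params()].
#' @return data.frame with `node_a`, `node_b`, `weight`.
#' @export
top_tom_edges <- function(tom, labels, module_id,
                          params = network_params()) {
  prot <- names(labels)[labels == module_id]
  if (length(prot) < 2) {
    warning("module ", module_id, " has fewer than 2 proteins; no edges")
    return(data.frame(node_a = character(0), node_b = character(0),
                      weight = numeric(0)))
  }
  pr <- utils::combn(sort(prot), 2)
  w <- tom[cbind(pr[1, ], pr[2, ])]
  n_top <- ceiling(params$top_edge_frac * ncol(pr))
  ord <- order(-w, pr[1, ], pr[2, ])
  keep <- ord[seq_len(n_top)]
  data.frame(node_a = pr[1, keep], node_b = pr[2, keep], weight = w[keep],
             stringsAsFactors = FALSE)
}

#' End-to-end signed co-expression network
#'
#' Correlation (bicor by default), signed soft-power adjacency,
#' mean-denominator TOM, average-linkage dendrogram, dynamic hybrid cut with
#' PAM, eigengene merge and kME reassignment — the full module-detection
#' path in one call.
#'
#' @param x complete log2 [abundance_matrix()] (proteins x samples).
#' @param params a [network_params()].
#' @param keep_tom retain the TOM matrix in the result (needed for
#'   [top_tom_edges()]).
#' @return list with `modules` (a `ModuleSet`), `dendrogram`, `pre_merge_labels`
#'   and optionally `tom`.
#' @export
build_network <- function(x, params = network_params(), keep_tom = TRUE) {
  x <- as_abundance(x)
  v <- unclass(x)
  corr <- if (params$cor_method == "bicor") bicor_matrix(t(v))
          else stats::cor(t(v))
  adj <- signed_adjacency(corr, params)
  tom <- tom_similarity(adj)
  diss <- 1 - tom
  diag(diss) <- 0
  dend <- cluster_dendrogram(diss)
  labels <- dynamic_hybrid_cut(dend, diss, params)
  modules <- merge_and_reassign(x, labels, params)
  out <- list(modules = modules, dendrogram = dend,
              pre_merge_labels = labels)
  if (keep_tom) out$tom <- tom
  out
}
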