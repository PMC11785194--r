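# Independent oracles used across the suite. Each is a deliberately naive
# implementation (enumeration, brute-force loops, per-element arithmetic)
# kept separate from the package's computation paths.

# Exact hypergeometric upper-tail by direct enumeration of binomial products.
enum_hyper_p <- function(overlap, K, n, N) {
  kmax <- min(n, K)
  if (overlap > kmax) return(0)
  ks <- seq(overlap, kmax)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

# Brute-force mean-denominator TOM by explicit double loop.
brute_force_tom <- function(adj) {
  p <- nrow(adj)
  tom <- diag(p)
  k <- numeric(p)
  for (i in seq_len(p)) k[i] <- sum(adj[i, -i])
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(p)) if (u != i && u != j) l <- l + adj[i, u] * adj[u, j]
    tom[i, j] <- (l + adj[i, j]) / (0.5 * (k[i] + k[j]) + 1 - adj[i, j])
  }
  tom
}

# Hand step-up Benjamini-Hochberg (independent of p.adjust).
step_up_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Strip class/scale attributes for plain-matrix comparisons.
amat_values <- function(x) {
  v <- unclass(x)
  attr(v, "scale_tag") <- NULL
  v
}

# Random small abundance matrix fixture with a given missing count.
random_amat <- function(n_prot = 5, n_samp = 4, n_missing = 3, seed = 1,
                        scale_tag = "log2") {
  set.seed(seed)
  v <- matrix(round(rnorm(n_prot * n_samp, 25, 3), 4), n_prot, n_samp,
              dimnames = list(sprintf("P%03d", seq_len(n_prot)),
                              sprintf("S%02d", seq_len(n_samp))))
  n_missing <- min(n_missing, length(v))
  if (n_missing > 0) v[sample(length(v), n_missing)] <- NA
  abundance_matrix(v, scale_tag)
}

# Two-group design for an AP-MS style matrix.
two_group_design <- function(sample_ids, n_bait) {
  data.frame(sample_id = sample_ids,
             group = rep(c("sTurbo", "Mock"),
                         c(n_bait, length(sample_ids) - n_bait)),
             stringsAsFactors = FALSE)
}

# Blocked correlation data: `sizes` blocks of proteins sharing a latent
# factor (within-correlation ~ r_w), plus optional pure-noise proteins.
block_matrix <- function(sizes, n_samp = 100, r_w = 0.9, n_noise = 0,
                         seed = 1) {
  set.seed(seed)
  tau <- sqrt((1 - r_w) / r_w)
  rows <- list()
  labels <- integer(0)
  for (b in seq_along(sizes)) {
    f <- rnorm(n_samp)
    for (i in seq_len(sizes[b])) {
      rows[[length(rows) + 1L]] <- f + rnorm(n_samp, 0, tau)
      labels <- c(labels, b)
    }
  }
  for (i in seq_len(n_noise)) {
    rows[[length(rows) + 1L]] <- rnorm(n_samp, 0, sqrt(1 + tau^2))
    labels <- c(labels, 0L)
  }
  v <- do.call(rbind, rows)
  dimnames(v) <- list(sprintf("P%04d", seq_len(nrow(v))),
                      sprintf("S%03d", seq_len(n_samp)))
  list(matrix = abundance_matrix(v, "log2"),
       labels = stats::setNames(labels, rownames(v)))
}
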