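#' One-tailed hypergeometric enrichment p from 2x2 counts
#'
#' The tail probability behind [fisher_enrich()]:
#' `p = sum_{k >= overlap} C(K, k) C(N - K, n - k) / C(N, n)`. Vectorized
#' over its arguments.
#'
#' @param overlap observed overlap count.
#' @param K target-set size, `n` list size, `N` background size.
#' @param n,N see above.
#' @export
hypergeom_enrich_p <- function(overlap, K, n, N) {
  pmin(stats::phyper(overlap - 1, K, N - K, n, lower.tail = FALSE), 1)
}

#' One-tailed hypergeometric enrichment (Fisher's exact test)
#'
#' Tests whether `list` overlaps `target_set` more than expected by chance
#' within `background`: `p = sum_{k >= overlap} C(K, k) C(N - K, n - k) /
#' C(N, n)` with `N = |background|`, `K = |target_set|`, `n = |list|`.
#' Identifiers outside the background are dropped (with a message). The odds
#' ratio comes from the 2x2 table, with a 0.5 Haldane correction when any
#' cell is zero.
#'
#' @param list character vector of query identifiers.
#' @param target_set character vector, the gene set tested for enrichment.
#' @param background character vector, the identifier universe.
#' @param normalize apply uppercase gene-symbol normalization to all three
#'   inputs before intersecting.
#' @return one-row data.frame of class `FETResult`: contingency counts,
#'   `odds_ratio`, one-tailed `p`, and the background size.
#' @export
fisher_enrich <- function(list, target_set, background, normalize = FALSE) {
  if (normalize) {
    list <- normalize_symbols(list)
    target_set <- normalize_symbols(target_set)
    background <- normalize_symbols(background)
  }
  background <- unique(background)
  if (!length(background)) stop("empty background")
  list <- unique(list); target_set <- unique(target_set)
  out_l <- setdiff(list, background)
  out_s <- setdiff(target_set, background)
  if (length(out_l) || length(out_s))
    message("fisher_enrich: dropping ", length(out_l), " list / ",
            length(out_s), " set identifier(s) outside the background")
  list <- intersect(list, background)
  target_set <- intersect(target_set, background)

  N <- length(background); K <- length(target_set); n <- length(list)
  overlap <- length(intersect(list, target_set))
  list_only <- n - overlap
  set_only <- K - overlap
  neither <- N - K - list_only
  p <- hypergeom_enrich_p(overlap, K, n, N)
  cells <- c(overlap, list_only, set_only, neither)
  hc <- if (any(cells == 0)) 0.5 else 0
  odds_ratio <- ((overlap + hc) * (neither + hc)) /
    ((list_only + hc) * (set_only + hc))
  structure(data.frame(overlap = overlap, list_only = list_only,
                       set_only = set_only, neither = neither,
                       odds_ratio = odds_ratio, p = p,
                       background_size = N),
            class = c("FETResult", "data.frame"))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH with monotonicity enforcement; input order is preserved and
#' `q >= p` elementwise.
#'
#' @param pvalues numeric vector of p-values in `(0, 1]`.
#' @return the BH-adjusted q-values.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Gene-set (GMT) enrichment of an identifier list
#'
#' Runs [fisher_enrich()] for every set in the collection whose size (after
#' intersection with the background) lies within `[min_set, max_set]`,
#' BH-adjusts across the retained sets and sorts by p.
#'
#' @param list character vector of query identifiers (non-empty).
#' @param gmt a [gene_set_collection()].
#' @param background identifier universe (e.g. all quantified proteins).
#' @param min_set,max_set retained set-size range after background
#'   intersection.
#' @param normalize uppercase-normalize identifiers before joining.
#' @return data.frame with one row per retained set: counts, odds ratio,
#'   one-tailed `p` and BH `q`, ordered by increasing `p`.
#' @export
gmt_enrichment <- function(list, gmt, background, min_set = 1,
                           max_set = Inf, normalize = FALSE) {
  if (!length(list)) stop("empty query list")
  if (normalize) {
    list <- normalize_symbols(list)
    background <- normalize_symbols(background)
  }
  background <- unique(background)
  rows <- list()
  for (nm in names(gmt)) {
    members <- if (normalize) normalize_symbols(gmt[[nm]]) else gmt[[nm]]
    members <- intersect(unique(members), background)
    if (length(members) < min_set || length(members) > max_set) next
    fr <- suppressMessages(fisher_enrich(list, members, background))
    fr$set_name <- nm
    fr$set_size <- length(members)
    rows[[nm]] <- fr
  }
  if (!length(rows)) {
    warning("no gene set within the size bounds")
    return(data.frame(set_name = character(0), set_size = integer(0),
                      overlap = integer(0), odds_ratio = numeric(0),
                      p = numeric(0), q = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out <- out[order(out$p, out$set_name),
             c("set_name", "set_size", "overlap", "list_only", "set_only",
               "neither", "odds_ratio", "p", "q", "background_size")]
  rownames(out) <- NULL
  out
}

#' Fisher enrichment of identifier lists against network modules
#'
#' For every (list, module) pair, tests enrichment of the list in the
#' module's membership by one-tailed hypergeometric FET; BH correction is
#' applied within each list across modules. Also returns the `-log10(q)`
#' matrix used for heatmap panels.
#'
#' @param lists named list of character vectors (e.g. tau interactome hits).
#' @param labels module labels named by protein (0 = grey, excluded as a
#'   target but part of the background).
#' @param background identifier universe; defaults to all labelled proteins
#'   (the network).
#' @param normalize uppercase-normalize identifiers before joining.
#' @return list with `table` (long data.frame) and `neg_log10_q`
#'   (lists x modules matrix).
#' @export
lists_vs_modules <- function(lists, labels, background = NULL,
                             normalize = TRUE) {
  if (is.null(names(lists)) || any(names(lists) == ""))
    stop("lists must be named")
  prot <- names(labels)
  if (is.null(background)) background <- prot
  if (normalize) {
    background <- normalize_symbols(background)
    prot <- normalize_symbols(prot)
  }
  mods <- sort(unique(labels[labels > 0]))
  rows <- list()
  for (ln in names(lists)) {
    lst <- if (normalize) normalize_symbols(lists[[ln]]) else lists[[ln]]
    if (!length(intersect(lst, background)))
      warning("list ", dQuote(ln), " has zero overlap with the background")
    for (m in mods) {
      members <- prot[labels == m]
      fr <- suppressMessages(fisher_enrich(lst, members, background))
      fr$list_name <- ln
      fr$module <- paste0("M", m)
      rows[[paste(ln, m)]] <- fr
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$q <- NA_real_
  for (ln in names(lists)) {
    i <- tab$list_name == ln
    tab$q[i] <- bh_fdr(tab$p[i])
  }
  mat <- matrix(-log10(tab$q), nrow = length(lists), byrow = TRUE,
                dimnames = list(names(lists), paste0("M", mods)))
  list(table = tab[, c("list_name", "module", "overlap", "list_only",
                       "set_only", "neither", "odds_ratio", "p", "q",
                       "background_size")],
       neg_log10_q = mat)
}

#' Venn/UpSet region counts for named identifier lists
#'
#' Counts every non-empty membership pattern (all `2^k - 1` regions of the
#' Venn partition) over the union of the lists.
#'
#' @param lists named list (length >= 2) of character vectors.
#' @return data.frame with one row per pattern: a logical column per list,
#'   a `pattern` label and the exclusive `count`.
#' @export
overlap_sets <- function(lists) {
  if (length(lists) < 2) stop("need at least 2 lists")
  if (is.null(names(lists))) stop("lists must be named")
  lists <- lapply(lists, unique)
  universe <- unique(unlist(lists))
  member <- sapply(lists, function(l) universe %in% l)
  member <- matrix(member, ncol = length(lists),
                   dimnames = list(NULL, names(lists)))
  key <- apply(member, 1, paste, collapse = "")
  pats <- expand.grid(rep(list(c(FALSE, TRUE)), length(lists)))[-1, ,
                                                                drop = FALSE]
  colnames(pats) <- names(lists)
  pat_key <- apply(as.matrix(pats), 1, paste, collapse = "")
  counts <- as.integer(table(factor(key, levels = pat_key)))
  out <- cbind(pats,
               pattern = apply(as.matrix(pats), 1, function(r)
                 paste(names(lists)[r], collapse = "&")),
               count = counts)
  rownames(out) <- NULL
  out
}

#' Row z-score with clipping for heatmap display
#'
#' Each protein row is centred and scaled by its sample SD, then clamped to
#' `[-clip, +clip]`; constant rows map to 0. Already-clipped z-scored rows
#' pass through unchanged (idempotence).
#'
#' @param x complete [abundance_matrix()] or matrix.
#' @param clip clamp bound (default 4).
#' @return matrix of clipped z-scores with the input dimnames.
#' @export
zscale_clip <- function(x, clip = 4) {
  v <- unclass(as_abundance(x))
  mu <- rowMeans(v)
  sdv <- apply(v, 1, stats::sd)
  z <- (v - mu) / ifelse(sdv == 0, 1, sdv)
  z[sdv == 0, ] <- 0
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  z
}

#' Left-join annotation tables onto a protein table
#'
#' Joins RBP class, subcellular compartment, insolubility flags, interactome
#' membership and similar annotations onto a protein list by a shared key
#' column; unmatched proteins get `NA` in the annotation columns and the
#' match counts are reported in a message.
#'
#' @param proteins character vector of identifiers or a data.frame with a
#'   key column.
#' @param annotation_tables named list of data.frames, each carrying the key
#'   column.
#' @param key key column name (default `"protein_id"`).
#' @param normalize uppercase-normalize keys before joining.
#' @return the annotated data.frame (one row per input protein, order
#'   preserved).
#' @export
annotate_proteins <- function(proteins, annotation_tables,
                              key = "protein_id", normalize = TRUE) {
  if (is.character(proteins)) {
    out <- data.frame(proteins, stringsAsFactors = FALSE)
    colnames(out) <- key
  } else {
    out <- as.data.frame(proteins)
  }
  if (!key %in% colnames(out)) stop("protein table lacks key column ", key)
  join_key <- if (normalize) normalize_symbols(out[[key]]) else out[[key]]
  for (nm in names(annotation_tables)) {
    tab <- as.data.frame(annotation_tables[[nm]])
    if (!key %in% colnames(tab))
      stop("annotation table ", dQuote(nm), " lacks key column ", key)
    tk <- if (normalize) normalize_symbols(tab[[key]]) else tab[[key]]
    idx <- match(join_key, tk)
    message("annotate_proteins: ", sum(!is.na(idx)), "/", length(idx),
            " proteins matched in ", nm)
    add <- tab[idx, setdiff(colnames(tab), key), drop = FALSE]
    rownames(add) <- NULL
    out <- cbind(out, add)
  }
  out
}
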