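#' Construct an abundance matrix
#'
#' The central data container of the pipeline: a numeric protein x sample
#' matrix of abundances with `NA` marking missing (unquantified) values and a
#' scale tag recording whether values are log2-transformed or linear
#' intensities. Conversions between the two scales are always explicit
#' ([amat_to_log2()], [amat_to_linear()]); no function silently re-interprets
#' the scale.
#'
#' @param values numeric matrix, proteins as rows and samples as columns, with
#'   unique non-empty dimnames. `NA` encodes a missing value.
#' @param scale_tag `"log2"` or `"linear"`.
#' @return a matrix of class `"AbundanceMatrix"` with a `scale_tag` attribute.
#' @export
abundance_matrix <- function(values, scale_tag = c("log2", "linear")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values))) {
    if (nrow(values) > 0)
      stop("`values` must have protein row names")
    rownames(values) <- character(0)
  }
  if (is.null(colnames(values))) {
    if (ncol(values) > 0)
      stop("`values` must have sample column names")
    colnames(values) <- character(0)
  }
  dup_p <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_p))
    stop("duplicate protein identifier(s): ", paste(unique(dup_p), collapse = ", "))
  dup_s <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_s))
    stop("duplicate sample identifier(s): ", paste(unique(dup_s), collapse = ", "))
  if (any(is.infinite(values)))
    stop("abundance values must be finite or NA")
  structure(values, scale_tag = scale_tag,
            class = c("AbundanceMatrix", class(matrix())))
}

#' @rdname abundance_matrix
#' @param x object to test or coerce.
#' @export
is_abundance_matrix <- function(x) inherits(x, "AbundanceMatrix")

#' @rdname abundance_matrix
#' @export
amat_scale <- function(x) {
  tag <- attr(x, "scale_tag")
  if (is.null(tag)) "log2" else tag
}

#' Explicit scale conversions for abundance matrices
#'
#' @param x an [abundance_matrix()] (or plain matrix, assumed log2).
#' @return an `AbundanceMatrix` on the requested scale.
#' @export
amat_to_log2 <- function(x) {
  if (amat_scale(x) == "log2") return(as_abundance(x, "log2"))
  v <- unclass(x)
  if (any(v <= 0, na.rm = TRUE))
    stop("cannot log2-transform non-positive linear abundances")
  abundance_matrix(log2(v), "log2")
}

#' @rdname amat_to_log2
#' @export
amat_to_linear <- function(x) {
  if (amat_scale(x) == "linear") return(as_abundance(x, "linear"))
  abundance_matrix(2^unclass(x), "linear")
}

# Coerce plain matrices coming from user code; scale defaults to log2.
as_abundance <- function(x, scale_tag = NULL) {
  if (is.null(scale_tag)) scale_tag <- amat_scale(x)
  abundance_matrix(unclass(as.matrix(x)), scale_tag)
}

#' Read an abundance matrix from a tab-delimited file
#'
#' Reads a TSV with one header row; the first column carries row identifiers.
#' Orientation is always declared by the caller, never inferred. Cells whose
#' literal text is in `missing_tokens` become `NA`; any other non-numeric cell
#' is a parse error reported with its (row, column) coordinates within the
#' numeric block. Literal zeros are preserved as zeros unless
#' `zero_as_missing = TRUE` (some LFQ exports encode absent proteins as 0).
#'
#' @param path file path.
#' @param orientation `"proteins"` if proteins are rows in the file,
#'   `"samples"` if samples are rows (the matrix is transposed after reading so
#'   the returned object is always proteins x samples).
#' @param missing_tokens character vector of cell values mapped to missing.
#' @param zero_as_missing treat numeric 0 as missing.
#' @param scale_tag scale of the stored values.
#' @return an [abundance_matrix()].
#' @export
read_abundance_tsv <- function(path,
                               orientation = c("proteins", "samples"),
                               missing_tokens = c("", "NA", "NaN", "nan"),
                               zero_as_missing = FALSE,
                               scale_tag = c("log2", "linear")) {
  orientation <- match.arg(orientation)
  scale_tag <- match.arg(scale_tag)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "",
                           na.strings = character(0))
  if (ncol(raw) < 2) stop("abundance TSV needs an identifier column plus data")
  ids <- raw[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate identifier(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  is_missing_tok <- array(cells %in% missing_tokens, dim = dim(cells))
  bad <- which(is.na(num) & !is_missing_tok, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell %s at row %d, column %d of %s",
                 dQuote(cells[bad[1, 1], bad[1, 2]]),
                 bad[1, 1], bad[1, 2], path))
  }
  num[is_missing_tok] <- NA_real_
  if (zero_as_missing) num[!is.na(num) & num == 0] <- NA_real_
  dimnames(num) <- list(ids, colnames(raw)[-1L])
  if (orientation == "samples") num <- t(num)
  abundance_matrix(num, scale_tag)
}

#' Write an abundance matrix to TSV
#'
#' Missing values are written as the literal string `NA`, which
#' [read_abundance_tsv()] maps back to missing: write -> read is the identity.
#'
#' @param x an [abundance_matrix()] or plain matrix.
#' @param path output path.
#' @param id_col header name of the identifier column.
#' @export
write_abundance_tsv <- function(x, path, id_col = "protein_id") {
  x <- as_abundance(x)
  df <- data.frame(rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Construct a gene-set collection
#'
#' A named list of character vectors (set members) with a parallel
#' `descriptions` attribute, as parsed from Broad-dialect GMT files.
#'
#' @param sets named list of character vectors.
#' @param descriptions character vector, one per set (recycled from "" if
#'   omitted).
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("every gene set must be named")
  dup <- names(sets)[duplicated(names(sets))]
  if (length(dup))
    stop("duplicate gene-set name(s): ", paste(unique(dup), collapse = ", "))
  if (any(!lengths(sets)))
    stop("gene sets must be non-empty: ",
         paste(names(sets)[!lengths(sets)], collapse = ", "))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  if (length(descriptions) != length(sets))
    stop("one description per set required")
  structure(lapply(sets, as.character), descriptions = descriptions,
            class = "GeneSetCollection")
}

#' Read a GMT gene-set file
#'
#' Broad dialect: each line is `name<TAB>description<TAB>member1<TAB>...`.
#' Empty member fields are dropped; duplicate set names and lines with fewer
#' than three fields are errors (reported with their line number).
#'
#' @param path GMT file path.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 fields in ", path)
  nm <- vapply(fields, `[[`, character(1), 1L)
  dup <- which(duplicated(nm))
  if (length(dup))
    stop("duplicate gene-set name ", dQuote(nm[dup[1L]]),
         " at GMT line ", dup[1L])
  desc <- vapply(fields, `[[`, character(1), 2L)
  members <- lapply(fields, function(f) {
    m <- f[-(1:2)]
    m[nzchar(m)]
  })
  names(members) <- nm
  gene_set_collection(members, desc)
}

#' @rdname read_gmt
#' @param gsc a [gene_set_collection()].
#' @export
write_gmt <- function(gsc, path) {
  desc <- attr(gsc, "descriptions")
  if (is.null(desc)) desc <- rep("", length(gsc))
  lines <- mapply(function(nm, d, members) {
    paste(c(nm, d, members), collapse = "\t")
  }, names(gsc), desc, gsc)
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample design table
#'
#' Tab-delimited, one header row, one row per sample. Requires at minimum
#' `sample_id` and `group` columns; `batch` and the boolean `is_gis` flag
#' (pooled global internal standard samples) are optional, with `is_gis`
#' defaulting to `FALSE`. Any further columns (covariates such as age, sex,
#' PMI; traits such as Braak, CERAD) are auto-typed numeric where parseable.
#'
#' @param path TSV path.
#' @return a `data.frame` with one row per sample.
#' @export
read_design_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  validate_design(df)
}

#' @rdname read_design_tsv
#' @param design a design `data.frame`.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Validate (and normalize) a sample design table
#'
#' @param design a data.frame with at least `sample_id` and `group`.
#' @return the validated design with `sample_id`/`group` as character and
#'   `is_gis` as logical (added as all-`FALSE` when absent).
#' @export
validate_design <- function(design) {
  if (!is.data.frame(design)) stop("design must be a data.frame")
  if (!"sample_id" %in% colnames(design))
    stop("design lacks required column `sample_id`")
  if (!"group" %in% colnames(design))
    stop("design lacks required column `group`")
  design$sample_id <- as.character(design$sample_id)
  design$group <- as.character(design$group)
  dup <- design$sample_id[duplicated(design$sample_id)]
  if (length(dup))
    stop("duplicate sample_id(s): ", paste(unique(dup), collapse = ", "))
  if (!length(design$sample_id)) stop("design has no samples")
  if ("is_gis" %in% colnames(design)) {
    design$is_gis <- parse_logical(design$is_gis)
  } else {
    design$is_gis <- FALSE
  }
  if ("batch" %in% colnames(design)) design$batch <- as.character(design$batch)
  design
}

parse_logical <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  out <- tolower(as.character(x)) %in% c("true", "t", "1", "yes")
  out
}

# Every sample column of the matrix must have a design row.
check_matrix_design <- function(x, design) {
  missing <- setdiff(colnames(x), design$sample_id)
  if (length(missing))
    stop("samples absent from design: ", paste(missing, collapse = ", "))
  design[match(colnames(x), design$sample_id), , drop = FALSE]
}

#' Read / write plain one-identifier-per-line lists
#'
#' Used for interactome hit lists, cell-type markers and similar inputs.
#' Blank lines are dropped; order and case are preserved.
#'
#' @param path file path.
#' @export
read_id_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' @rdname read_id_list
#' @param ids character vector of identifiers.
#' @export
write_id_list <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}

#' Uppercase gene-symbol normalization
#'
#' Gene symbols differ in case across datasets (e.g. mouse vs human
#' conventions); all cross-dataset joins in this package optionally pass
#' identifiers through this normalization first.
#'
#' @param x character vector of identifiers.
#' @export
normalize_symbols <- function(x) toupper(trimws(as.character(x)))

#' Write a network edge list as TSV
#'
#' @param edges data.frame with columns `node_a`, `node_b`, `weight`.
#' @param path output path.
#' @export
write_edge_list <- function(edges, path) {
  stopifnot(all(c("node_a", "node_b", "weight") %in% colnames(edges)))
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
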