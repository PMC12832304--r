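#' Read a genes-by-samples expression matrix
#'
#' Reads a delimited text file with gene symbols in the first column and
#' sample identifiers in the header row, returning a numeric matrix
#' (genes in rows, samples in columns). Values are expected on the log2
#' scale. Rows sharing a gene symbol are collapsed to a single row by the
#' element-wise median, the standard rule when several microarray probes
#' map to the same symbol. For an even number of duplicate rows the median
#' is the mean of the two central values.
#'
#' The delimiter is inferred from the file extension (`.csv` comma,
#' anything else tab). Symbol matching everywhere in the package is
#' case-sensitive and no alias resolution is attempted.
#'
#' @param path Path to a TSV/CSV file.
#' @param collapse Duplicate-symbol collapsing rule; only `"median"` is
#'   supported.
#' @return Numeric matrix with unique gene symbols as rownames and sample
#'   ids as colnames.
#' @export
read_expression <- function(path, collapse = c("median")) {
  collapse <- match.arg(collapse)
  tab <- read_matrix_table(path)
  collapse_genes(tab$values, tab$ids)
}

#' Read a genes-by-latent-variables loading matrix
#'
#' Same file dialect as [read_expression()]: gene symbols in the first
#' column, latent-variable identifiers in the header. The loading matrix
#' is a fixed prior learned elsewhere; it is never modified or fine-tuned
#' by this package. Duplicate gene symbols are an error here (a prior
#' should already be symbol-level).
#'
#' @param path Path to a TSV/CSV file.
#' @return Numeric matrix, genes in rows, latent variables in columns.
#' @export
read_loadings <- function(path) {
  tab <- read_matrix_table(path)
  if (anyDuplicated(tab$ids))
    stop("duplicate gene identifiers in loading matrix: ",
         paste(unique(tab$ids[duplicated(tab$ids)]), collapse = ", "))
  if (anyDuplicated(colnames(tab$values)))
    stop("duplicate latent-variable identifiers in loading matrix")
  tab$values
}

#' Write a matrix as TSV with row identifiers in the first column
#'
#' Inverse of [read_expression()]/[read_loadings()]; full `%.17g`
#' precision so a write/read round trip is exact.
#'
#' @param x Numeric matrix with dimnames.
#' @param path Output path; delimiter inferred from extension as in
#'   [read_expression()].
#' @param id_name Header label for the identifier column.
#' @export
write_matrix_tsv <- function(x, path, id_name = "gene_id") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(id_name, colnames(x)), collapse = sep), con)
  body <- apply(x, 2, function(col) sprintf("%.17g", col))
  if (is.null(dim(body))) body <- matrix(body, nrow = nrow(x))
  lines <- apply(cbind(rownames(x), body), 1, paste, collapse = sep)
  writeLines(lines, con)
  invisible(path)
}

# Parse a delimited numeric table; first column = row ids (header of that
# column is ignored), remaining columns numeric. Errors name the offending
# cell so malformed exports are diagnosable.
read_matrix_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("empty or malformed matrix file: ", path)
  ids <- raw[[1L]]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(NULL, colnames(vals))))
  bad <- which(is.na(num) & !(vals %in% c("NA", "NaN")), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s' in %s",
                 vals[bad[1L, 1L], bad[1L, 2L]], ids[bad[1L, 1L]],
                 colnames(vals)[bad[1L, 2L]], path))
  if (any(!is.finite(num)))
    stop("non-finite values in ", path)
  rownames(num) <- ids
  list(ids = ids, values = num)
}

#' Collapse duplicate gene rows by the element-wise median
#'
#' @param values Numeric matrix, one row per (possibly duplicated) gene.
#' @param genes Character vector of gene symbols, one per row.
#' @return Matrix with one row per unique symbol, in first-appearance
#'   order. Idempotent: collapsing an already-unique matrix is the
#'   identity.
#' @export
collapse_genes <- function(values, genes = rownames(values)) {
  stopifnot(is.matrix(values), length(genes) == nrow(values))
  if (!anyDuplicated(genes)) {
    rownames(values) <- genes
    return(values)
  }
  keep <- unique(genes)
  out <- matrix(NA_real_, nrow = length(keep), ncol = ncol(values),
                dimnames = list(keep, colnames(values)))
  idx <- split(seq_along(genes), factor(genes, levels = keep))
  for (g in seq_along(keep)) {
    rows <- idx[[g]]
    out[g, ] <- if (length(rows) == 1L) values[rows, ]
                else apply(values[rows, , drop = FALSE], 2, stats::median)
  }
  out
}

#' Read a sample label table
#'
#' Two-column delimited file `sample_id`, `label`, with labels coded
#' either `{0,1}` or `{control,case}` (0 = control, 1 = case). A header
#' row is detected and skipped if its second field is not a valid label.
#'
#' @param path Path to TSV/CSV.
#' @return Named integer vector of 0/1 labels, names = sample ids.
#' @export
read_labels <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("label table needs two columns: sample_id, label")
  valid <- c("0", "1", "control", "case")
  if (nrow(raw) > 1L && !(tolower(raw[1L, 2L]) %in% valid))
    raw <- raw[-1L, , drop = FALSE]   # header row
  lab <- tolower(raw[[2L]])
  if (!all(lab %in% valid))
    stop("labels must be 0/1 or control/case; saw: ",
         paste(unique(setdiff(lab, valid)), collapse = ", "))
  y <- ifelse(lab %in% c("1", "case"), 1L, 0L)
  names(y) <- raw[[1L]]
  if (anyDuplicated(names(y)))
    stop("duplicate sample ids in label table")
  y
}

#' Read a gene list (one symbol per line, `#` comments allowed)
#'
#' @param path Path to a plain-text file.
#' @return Character vector of unique symbols in file order.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}

#' Restrict expression and loading matrices to their common gene space
#'
#' The ridge projection requires the expression matrix and the prior to
#' live on the same genes in the same order. Genes present on only one
#' side are dropped, and the counts of dropped genes are reported via
#' [message()].
#'
#' @param expression Genes-by-samples matrix (rownames = symbols).
#' @param loadings Genes-by-LVs matrix (rownames = symbols).
#' @return List with elements `expression`, `loadings` (identical
#'   rowname order), `dropped_expression`, `dropped_loadings`.
#' @export
align_to_prior <- function(expression, loadings) {
  gx <- rownames(expression)
  gz <- rownames(loadings)
  common <- intersect(gx, gz)
  if (length(common) == 0L)
    stop("no genes shared between expression matrix and loading matrix")
  message(sprintf(
    "align_to_prior: %d shared genes; dropped %d expression-only, %d prior-only",
    length(common), length(gx) - length(common), length(gz) - length(common)))
  list(expression = expression[common, , drop = FALSE],
       loadings   = loadings[common, , drop = FALSE],
       dropped_expression = setdiff(gx, common),
       dropped_loadings   = setdiff(gz, common))
}

#' Per-gene z-scoring with training-derived parameters
#'
#' Centers and scales each gene row to mean 0, SD 1 before projection
#' onto the latent prior. The population SD convention (divide by n, not
#' n-1) is used. In fit mode (`params = NULL`) means and SDs are
#' estimated from the supplied samples and returned for later reuse; in
#' apply mode the stored training parameters are applied unchanged, so
#' no information leaks from new query samples. Genes with zero variance
#' in fit mode are dropped with a warning and recorded in the returned
#' parameters.
#'
#' @param expression Genes-by-samples matrix.
#' @param params `NULL` (fit mode) or a `"standardization"` object from a
#'   previous fit (apply mode).
#' @return List with `values` (standardized matrix) and `params`.
#' @export
standardize_genes <- function(expression, params = NULL) {
  if (is.null(params)) {
    mu <- rowMeans(expression)
    n <- ncol(expression)
    sdev <- sqrt(rowMeans((expression - mu)^2))  # population (1/n) SD
    zero <- sdev <= .Machine$double.eps * 10
    if (any(zero)) {
      warning("dropping ", sum(zero), " zero-variance gene(s): ",
              paste(utils::head(rownames(expression)[zero], 5), collapse = ", "))
    }
    params <- structure(list(mean = mu[!zero], sd = sdev[!zero],
                             dropped = rownames(expression)[zero]),
                        class = "standardization")
    expression <- expression[!zero, , drop = FALSE]
  } else {
    stopifnot(inherits(params, "standardization"))
    missing <- setdiff(rownames(expression), names(params$mean))
    missing <- setdiff(missing, params$dropped)
    if (length(missing) > 0L)
      stop("standardization params do not cover genes: ",
           paste(utils::head(missing, 5), collapse = ", "))
    keep <- intersect(rownames(expression), names(params$mean))
    expression <- expression[keep, , drop = FALSE]
  }
  g <- rownames(expression)
  values <- (expression - params$mean[g]) / params$sd[g]
  list(values = values, params = params)
}
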