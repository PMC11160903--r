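#' Expression matrix with an explicit missing-value mask
#'
#' `expr_mat()` builds the container used throughout the package: a numeric
#' genes x samples matrix together with a logical mask of missing cells and a
#' flag recording whether values are on the linear (intensity) or log scale.
#' Missing cells hold `NA` in `values` *and* `TRUE` in `missing`; the two are
#' kept consistent by the constructor so downstream code can rely on either
#' view.
#'
#' @param values Numeric matrix, genes as rows, samples as columns. Row and
#'   column names are the gene and sample identifiers.
#' @param missing Logical matrix of the same dimension; `TRUE` marks a missing
#'   cell. Defaults to `is.na(values)`.
#' @param space `"linear"` (non-negative intensities) or `"log"`.
#' @param log_base Base of the log transform when `space = "log"`.
#' @param pseudocount Pseudocount used by the log transform (recorded so the
#'   inverse transform can undo it).
#' @param meta Named list of free-form metadata (e.g. normalization factors).
#'
#' @return An object of class `expr_mat`.
#' @export
expr_mat <- function(values, missing = NULL, space = c("linear", "log"),
                     log_base = 2, pseudocount = 0, meta = list()) {
  space <- match.arg(space)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("gene_", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("sample_", seq_len(ncol(values)))
  }
  if (is.null(missing)) missing <- is.na(values)
  if (!is.matrix(missing) || !is.logical(missing) ||
      !identical(dim(missing), dim(values))) {
    stop("`missing` must be a logical matrix with the dimensions of `values`",
         call. = FALSE)
  }
  values[missing] <- NA_real_
  dimnames(missing) <- dimnames(values)
  x <- structure(
    list(values = values, missing = missing, space = space,
         log_base = log_base, pseudocount = pseudocount, meta = meta),
    class = "expr_mat"
  )
  validate_expr_mat(x)
}

#' @rdname expr_mat
#' @param x An `expr_mat`.
#' @export
validate_expr_mat <- function(x) {
  stopifnot(inherits(x, "expr_mat"))
  v <- x$values
  m <- x$missing
  if (anyDuplicated(rownames(v))) {
    stop("duplicate gene ids: ",
         paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(v))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", "),
         call. = FALSE)
  }
  obs <- v[!m]
  if (any(!is.finite(obs))) {
    stop("observed cells must hold finite values", call. = FALSE)
  }
  if (x$space == "linear" && any(obs < 0)) {
    bad <- which(!m & v < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at gene '%s', sample '%s' in linear space",
                 rownames(v)[bad[1]], colnames(v)[bad[2]]), call. = FALSE)
  }
  if (x$space == "log" && (!is.numeric(x$log_base) || x$log_base <= 1)) {
    stop("`log_base` must be > 1", call. = FALSE)
  }
  x
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' @export
dimnames.expr_mat <- function(x) dimnames(x$values)

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> %d genes x %d samples, %s space, %d missing (%.1f%%)\n",
              nrow(x$values), ncol(x$values), x$space, sum(x$missing),
              100 * mean(x$missing)))
  invisible(x)
}

#' Gene and sample identifiers of an expression matrix
#' @param x An `expr_mat`.
#' @return Character vector of ids.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Long tidy view of an expression matrix
#'
#' @param x An `expr_mat`.
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `sample_id`, `value`, `missing`.
#' @exportS3Method tibble::as_tibble
as_tibble.expr_mat <- function(x, ...) {
  tibble::tibble(
    gene_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values),
    missing = as.vector(x$missing)
  )
}

#' Read a delimited expression table
#'
#' Expects a header row of sample ids, a first column of gene ids and one gene
#' per row. Cells equal to one of `na_tokens` (or empty) become missing.
#'
#' @param path Path to a TSV/CSV file; the delimiter is taken from the
#'   extension (`.csv` means comma, anything else tab) unless `delim` is given.
#' @param na_tokens Strings treated as missing.
#' @param space,log_base Scale of the stored values, see [expr_mat()].
#' @param delim Optional explicit field delimiter.
#' @return An `expr_mat`.
#' @export
read_expression <- function(path, na_tokens = c("NA", "NaN", ""),
                            space = c("linear", "log"), log_base = 2,
                            delim = NULL) {
  space <- match.arg(space)
  if (is.null(delim)) delim <- if (grepl("\\.csv$", path)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), na = character(), progress = FALSE)
  if (ncol(raw) < 2) stop("expression table needs gene ids plus >= 1 sample",
                          call. = FALSE)
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate gene ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  cells <- as.matrix(raw[, -1, drop = FALSE])
  miss <- is.na(cells) | cells %in% na_tokens
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(!miss & is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric cell '%s' at row %d (gene '%s'), column '%s'",
                 cells[bad[1, 1], bad[1, 2]], bad[1, 1], ids[bad[1, 1]],
                 colnames(cells)[bad[1, 2]]), call. = FALSE)
  }
  num[miss] <- NA_real_
  rownames(num) <- ids
  colnames(num) <- colnames(cells)
  expr_mat(num, miss, space = space, log_base = log_base)
}

#' Write an expression matrix back to disk
#'
#' Values are printed with `%.17g` so a read/write/read round trip reproduces
#' every double bit-exactly; missing cells are written as `NA`.
#'
#' @param x An `expr_mat`.
#' @param path Output path; `.csv` selects comma, otherwise tab.
#' @param delim Optional explicit delimiter.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, delim = NULL) {
  if (is.null(delim)) delim <- if (grepl("\\.csv$", path)) "," else "\t"
  v <- x$values
  chr <- array(sprintf("%.17g", v), dim = dim(v))
  chr[x$missing] <- "NA"
  header <- paste(c("gene_id", colnames(v)), collapse = delim)
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(rownames(v)[i], chr[i, ]), collapse = delim)
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Group design: ordered sample-to-group assignment
#'
#' @param sample_id Character vector of sample ids.
#' @param group Character (or factor) group label per sample. Group order is
#'   the order of first appearance.
#' @return A tibble of class `group_design` with columns `sample_id` and
#'   `group` (factor with the design's group order as levels).
#' @export
group_design <- function(sample_id, group) {
  sample_id <- as.character(sample_id)
  group <- as.character(group)
  if (length(sample_id) != length(group)) {
    stop("`sample_id` and `group` must have the same length", call. = FALSE)
  }
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample rows in design: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  d <- tibble::tibble(sample_id = sample_id,
                      group = factor(group, levels = unique(group)))
  class(d) <- c("group_design", class(d))
  d
}

#' @rdname group_design
#' @param path Two-column delimited file `sample_id<TAB>group` with header.
#' @export
read_design <- function(path) {
  delim <- if (grepl("\\.csv$", path)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = "cc",
                           progress = FALSE)
  if (ncol(raw) < 2) stop("design file needs two columns", call. = FALSE)
  group_design(raw[[1]], raw[[2]])
}

#' @rdname group_design
#' @param design A `group_design` tibble.
#' @export
write_design <- function(design, path) {
  delim <- if (grepl("\\.csv$", path)) "," else "\t"
  writeLines(c(paste("sample_id", "group", sep = delim),
               paste(design$sample_id, as.character(design$group),
                     sep = delim)),
             path)
  invisible(path)
}

# Align a design with a matrix: every sample must be assigned to one group.
# Returns integer group index per column plus the ordered labels.
design_index <- function(x, design) {
  if (!all(c("sample_id", "group") %in% names(design))) {
    stop("design must have columns `sample_id` and `group`", call. = FALSE)
  }
  sid <- colnames(x$values)
  pos <- match(sid, design$sample_id)
  if (anyNA(pos)) {
    stop("samples absent from design: ",
         paste(sid[is.na(pos)], collapse = ", "), call. = FALSE)
  }
  grp <- design$group[pos]
  if (!is.factor(grp)) grp <- factor(grp, levels = unique(grp))
  grp <- droplevels(grp)
  if (nlevels(grp) < 1 || anyNA(grp)) {
    stop("every sample must map to exactly one group", call. = FALSE)
  }
  list(k = as.integer(grp), labels = levels(grp), K = nlevels(grp))
}

#' Move an expression matrix to log space and back
#'
#' Observed cells are mapped `v -> log(v + pseudocount, base)`; the missing
#' mask is untouched. `from_log_space()` inverts the transform using the
#' base and pseudocount recorded on the object.
#'
#' @param x An `expr_mat` in linear space (`to_log_space`) or log space
#'   (`from_log_space`).
#' @param base Log base, must be > 1.
#' @param pseudocount Added before taking logs; 0 is fine for strictly
#'   positive intensities.
#' @return An `expr_mat` on the other scale.
#' @export
to_log_space <- function(x, base = 2, pseudocount = 1) {
  stopifnot(inherits(x, "expr_mat"))
  if (x$space != "linear") stop("`x` is already in log space", call. = FALSE)
  if (base <= 1) stop("`base` must be > 1", call. = FALSE)
  v <- log(x$values + pseudocount, base = base)
  expr_mat(v, x$missing, space = "log", log_base = base,
           pseudocount = pseudocount, meta = x$meta)
}

#' @rdname to_log_space
#' @export
from_log_space <- function(x) {
  stopifnot(inherits(x, "expr_mat"))
  if (x$space != "log") stop("`x` is not in log space", call. = FALSE)
  v <- x$log_base^x$values - x$pseudocount
  v[!x$missing & v < 0 & v > -1e-12] <- 0  # guard tiny negative round-off
  expr_mat(v, x$missing, space = "linear", meta = x$meta)
}
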