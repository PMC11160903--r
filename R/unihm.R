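#' Simplex (perspective) normalization of an expression matrix
#'
#' Divides every cell of gene i by the sum of that gene's K group means, so
#' that each gene's vector of group means sums to exactly one — the
#' perspective projection of the cross-group pattern onto the scatter
#' simplex. Zero cells stay zero, and cosine statistics are unchanged
#' because the map rescales each gene by a positive constant.
#'
#' @param x A complete `expr_mat` in linear space.
#' @param design A [group_design()].
#' @return A normalized `expr_mat`; genes whose group-mean sum is zero are
#'   dropped with a warning (ids in `meta$dropped_genes`).
#' @export
simplex_normalize <- function(x, design) {
  stopifnot(inherits(x, "expr_mat"))
  if (x$space != "linear") stop("simplex normalization acts on linear space",
                                call. = FALSE)
  if (any(x$missing)) stop("matrix must be complete; impute first",
                           call. = FALSE)
  di <- design_index(x, design)
  m <- .group_means_matrix(x, di)
  denom <- rowSums(m)
  drop <- denom <= 0
  if (any(drop)) {
    warning(sum(drop), " gene(s) with zero group-mean sum dropped")
  }
  v <- x$values[!drop, , drop = FALSE] / denom[!drop]
  meta <- x$meta
  meta$dropped_genes <- rownames(x$values)[drop]
  expr_mat(v, space = "linear", meta = meta)
}

#' Origin-preserving display standardization
#'
#' Maps each simplex-normalized value to
#' `d = (log(v + delta) - log(delta)) / scale(i)` where `scale(i)` is the
#' pooled log-space within-group SD of gene i. Zero expression maps to
#' display value 0 for every gene (the common origin), while the per-gene
#' scale makes contrast comparable across genes. The `"classic"` style is
#' the conventional per-gene log-space z-score, which centres each gene and
#' therefore moves the origin.
#'
#' @param xn Output of [simplex_normalize()].
#' @param design A [group_design()].
#' @param pseudocount Positive delta of the log transform (default `1e-4`,
#'   on the normalized scale).
#' @param style `"unified"` (scale only, origin preserved) or `"classic"`
#'   (centred z-score).
#' @return A numeric display matrix with attribute `"flagged"` listing genes
#'   whose scale was zero (constant genes; scale set to 1).
#' @export
display_standardize <- function(xn, design, pseudocount = 1e-4,
                                style = c("unified", "classic")) {
  style <- match.arg(style)
  stopifnot(inherits(xn, "expr_mat"), pseudocount > 0)
  di <- design_index(xn, design)
  l <- log(xn$values + pseudocount)
  xl <- expr_mat(l, space = "log", log_base = exp(1),
                 pseudocount = pseudocount)
  st <- .group_stats(xl, di)
  w <- pmax(st$n_obs - 1L, 0L)
  ss <- st$sd^2 * w
  ss[is.na(ss)] <- 0
  scale <- sqrt(rowSums(ss) / pmax(rowSums(w), 1))
  flagged <- rownames(l)[scale == 0 | !is.finite(scale)]
  scale[scale == 0 | !is.finite(scale)] <- 1
  d <- if (style == "unified") {
    (l - log(pseudocount)) / scale
  } else {
    (l - rowMeans(l)) / scale
  }
  attr(d, "flagged") <- flagged
  attr(d, "style") <- style
  d
}

#' Build a unified heatmap specification ordered by cosine score
#'
#' Selects the top signature genes per (kind, group) block, orders genes
#' within each block by descending cosine statistic (ties by gene id), keeps
#' samples contiguous by group and orders them within each group by their
#' cosine agreement with the expected signature pattern of that group.
#'
#' @param scores A `sig_score_table` from [score_signatures()].
#' @param x The complete linear-space `expr_mat` the scores were computed on.
#' @param design A [group_design()].
#' @param top_n Genes kept per (kind, group) block.
#' @param pseudocount,style Passed to [display_standardize()].
#' @return A `heatmap_spec`: list with `display` (genes x samples display
#'   matrix, rows and columns already ordered), `gene_order`,
#'   `sample_order`, `group_boundaries` and `color_limits`.
#' @export
order_by_cosine <- function(scores, x, design, top_n = 20,
                            pseudocount = 1e-4,
                            style = c("unified", "classic")) {
  stopifnot(inherits(scores, "sig_score_table"))
  style <- match.arg(style)
  di <- design_index(x, design)
  sel <- scores |>
    dplyr::group_by(.data$kind, .data$best_group) |>
    dplyr::arrange(dplyr::desc(.data$statistic), .data$gene_id,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = top_n) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      kind = factor(.data$kind, levels = c("sg", "dsg")),
      best_group = factor(.data$best_group, levels = di$labels)
    ) |>
    dplyr::arrange(.data$kind, .data$best_group)
  if (nrow(sel) == 0) stop("no genes selected for the heatmap", call. = FALSE)

  xn <- simplex_normalize(x, design)
  keep <- intersect(sel$gene_id, rownames(xn$values))
  sel <- sel[sel$gene_id %in% keep, ]
  d <- display_standardize(xn, design, pseudocount, style)

  # sample order: contiguous groups, within-group by cosine to the expected
  # block pattern of the sample's own group
  ord_samples <- integer(0)
  boundaries <- integer(0)
  vals <- xn$values[sel$gene_id, , drop = FALSE]
  for (k in seq_len(di$K)) {
    ref <- ifelse(sel$kind == "sg",
                  as.numeric(sel$best_group == di$labels[k]),
                  ifelse(sel$best_group == di$labels[k], 0, 1 / (di$K - 1)))
    cols <- which(di$k == k)
    cosv <- vapply(cols, function(s) {
      v <- vals[, s]
      nv <- sqrt(sum(v^2)) * sqrt(sum(ref^2))
      if (nv == 0) 0 else sum(v * ref) / nv
    }, numeric(1))
    ord <- cols[order(-cosv, colnames(vals)[cols])]
    ord_samples <- c(ord_samples, ord)
    boundaries <- c(boundaries, length(ord_samples))
  }
  boundaries <- boundaries[-length(boundaries)]

  disp <- d[sel$gene_id, ord_samples, drop = FALSE]
  lims <- stats::quantile(disp, c(0.01, 0.99), names = FALSE)
  structure(
    list(display = disp,
         gene_order = sel,
         sample_order = colnames(xn$values)[ord_samples],
         sample_group = di$labels[di$k[ord_samples]],
         group_boundaries = boundaries,
         color_limits = lims,
         style = style),
    class = "heatmap_spec"
  )
}

#' @export
print.heatmap_spec <- function(x, ...) {
  cat(sprintf("<heatmap_spec> %d genes x %d samples (%s style)\n",
              nrow(x$display), ncol(x$display), x$style))
  invisible(x)
}

#' Plot a heatmap specification
#'
#' @param object A `heatmap_spec` from [order_by_cosine()].
#' @param ... Unused.
#' @return A ggplot: tiles filled from the common origin, with vertical
#'   separators at group boundaries.
#' @exportS3Method ggplot2::autoplot
autoplot.heatmap_spec <- function(object, ...) {
  df <- tibble::tibble(
    gene_id = factor(rep(rownames(object$display),
                         times = ncol(object$display)),
                     levels = rev(rownames(object$display))),
    sample_id = factor(rep(colnames(object$display),
                           each = nrow(object$display)),
                       levels = colnames(object$display)),
    display = as.vector(object$display)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$gene_id,
                                   fill = .data$display)) +
    ggplot2::geom_tile() +
    ggplot2::geom_vline(xintercept = object$group_boundaries + 0.5,
                        colour = "white", linewidth = 0.8) +
    ggplot2::scale_fill_viridis_c(limits = object$color_limits,
                                  oob = scales_squish) +
    ggplot2::labs(x = NULL, y = NULL, fill = "display") +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

# minimal squish to avoid a hard dependency on the scales package namespace
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1]), range[2])
}

#' Render a heatmap to image and sidecar table
#'
#' Writes the figure and, alongside it, the ordered display matrix as a
#' tab-separated table (printed with `%.17g`, so re-reading reproduces the
#' displayed values bit-exactly).
#'
#' @param spec A `heatmap_spec`.
#' @param path Image output path (`.png`/`.svg`/`.pdf`); `NULL` skips the
#'   image.
#' @param table_path Sidecar TSV path; `NULL` skips the table.
#' @param width,height Image size in inches.
#' @return `spec`, invisibly.
#' @export
render_heatmap <- function(spec, path = NULL, table_path = NULL,
                           width = 7, height = 5) {
  stopifnot(inherits(spec, "heatmap_spec"))
  if (!is.null(table_path)) {
    d <- spec$display
    chr <- array(sprintf("%.17g", d), dim = dim(d))
    writeLines(c(paste(c("gene_id", colnames(d)), collapse = "\t"),
                 vapply(seq_len(nrow(d)), function(i) {
                   paste(c(rownames(d)[i], chr[i, ]), collapse = "\t")
                 }, character(1))),
               table_path)
  }
  if (!is.null(path)) {
    p <- autoplot.heatmap_spec(spec)
    ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
  }
  invisible(spec)
}
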