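#' Cross-group mean expression vectors
#'
#' Averages each gene over the samples of every group, giving the K-vector
#' scored by the cosine tests. Genes whose vector is all zero carry no
#' directional information and are dropped with a warning.
#'
#' @param x An `expr_mat` in linear space. By default the matrix must be
#'   complete (impute first); with `use = "observed"` means are taken over
#'   observed cells only.
#' @param design A [group_design()].
#' @param use `"complete"` or `"observed"`.
#' @return A tibble with `gene_id` and one numeric column per group, carrying
#'   the group labels as attribute `"groups"`.
#' @export
group_mean_vectors <- function(x, design, use = c("complete", "observed")) {
  use <- match.arg(use)
  stopifnot(inherits(x, "expr_mat"))
  if (x$space != "linear") {
    stop("cosine statistics are defined on linear-space expression",
         call. = FALSE)
  }
  di <- design_index(x, design)
  if (di$K < 2) stop("need at least two groups", call. = FALSE)
  if (use == "complete" && any(x$missing)) {
    stop("matrix has missing cells; impute first or set use = \"observed\"",
         call. = FALSE)
  }
  m <- .group_means_matrix(x, di)
  zero <- rowSums(m, na.rm = TRUE) == 0 | !stats::complete.cases(m)
  if (any(zero)) {
    warning(sum(zero), " gene(s) with all-zero or undefined group means dropped")
    m <- m[!zero, , drop = FALSE]
  }
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  names(out) <- di$labels
  out <- tibble::add_column(out, gene_id = rownames(m), .before = 1)
  attr(out, "groups") <- di$labels
  out
}

.group_means_matrix <- function(x, di) {
  v <- x$values
  obs <- !x$missing
  vz <- v
  vz[!obs] <- 0
  m <- matrix(NA_real_, nrow(v), di$K,
              dimnames = list(rownames(v), di$labels))
  for (k in seq_len(di$K)) {
    cols <- di$k == k
    n <- rowSums(obs[, cols, drop = FALSE])
    m[, k] <- ifelse(n > 0, rowSums(vz[, cols, drop = FALSE]) / n, NA_real_)
  }
  m
}

#' Cosine one-sample statistics for signature references
#'
#' `cot_statistic()` scores a gene's cross-group mean vector against the
#' ideal upregulated signature of group `k` (the Cartesian unit vector: high
#' in group k, zero elsewhere). `ecot_statistic()` scores it against the
#' ideal downregulated signature (zero in group k, equal in all others —
#' the centre of the opposite simplex facet). Both are cosines of the angle
#' between the vector and the reference, lie in `[0, 1]` for non-negative
#' input, and are invariant to rescaling the vector.
#'
#' @param v Non-negative, non-zero numeric vector of K group means.
#' @param k Group index in `1..K`.
#' @return A number in `[0, 1]`.
#' @export
cot_statistic <- function(v, k) {
  .check_sig_vector(v, k)
  v[k] / sqrt(sum(v^2))
}

#' @rdname cot_statistic
#' @export
ecot_statistic <- function(v, k) {
  .check_sig_vector(v, k)
  if (length(v) < 2) stop("need K >= 2 groups", call. = FALSE)
  (sum(v) - v[k]) / (sqrt(sum(v^2)) * sqrt(length(v) - 1))
}

.check_sig_vector <- function(v, k) {
  if (any(v < 0)) stop("group-mean vector must be non-negative", call. = FALSE)
  if (all(v == 0)) stop("group-mean vector must not be all zero", call. = FALSE)
  if (k < 1 || k > length(v)) stop("`k` out of range", call. = FALSE)
}

#' Score every gene against all signature references
#'
#' For each gene the cosine statistic is maximized over the K candidate
#' groups; ties are broken toward the lowest group index and flagged.
#'
#' @param means Output of [group_mean_vectors()] (or an `expr_mat` plus
#'   `design`, which is averaged internally).
#' @param design Required when `means` is an `expr_mat`.
#' @param kind `"dsg"` (downregulated, eCOT), `"sg"` (upregulated, COT) or
#'   `"both"`.
#' @return A `sig_score_table` tibble: `gene_id`, `kind`, `best_group`,
#'   `statistic`, `tie`.
#' @export
score_signatures <- function(means, design = NULL,
                             kind = c("dsg", "sg", "both")) {
  kind <- match.arg(kind)
  if (inherits(means, "expr_mat")) {
    if (is.null(design)) stop("`design` required with an expression matrix",
                              call. = FALSE)
    means <- group_mean_vectors(means, design)
  }
  groups <- attr(means, "groups")
  m <- as.matrix(means[, groups, drop = FALSE])
  if (nrow(m) < 2) stop("need at least two genes to score", call. = FALSE)
  kinds <- if (kind == "both") c("sg", "dsg") else kind
  out <- purrr::map_dfr(kinds, function(kd) {
    stat <- .cosine_matrix(m, kd)
    best <- max.col(stat, ties.method = "first")
    best_stat <- stat[cbind(seq_len(nrow(stat)), best)]
    tie <- rowSums(abs(stat - best_stat) <= 1e-12 * pmax(best_stat, 1)) > 1
    tibble::tibble(gene_id = means$gene_id, kind = kd,
                   best_group = groups[best], statistic = best_stat,
                   tie = tie)
  })
  class(out) <- c("sig_score_table", class(out))
  attr(out, "groups") <- groups
  out
}

# G x K matrix of cosine statistics against every reference of one kind.
.cosine_matrix <- function(m, kind) {
  norm <- sqrt(rowSums(m^2))
  if (kind == "sg") {
    m / norm
  } else {
    (rowSums(m) - m) / (norm * sqrt(ncol(m) - 1))
  }
}

#' Empirical-null p-values for signature scores
#'
#' When the large majority of genes satisfies the null hypothesis, the
#' empirical distribution of the statistic over all genes approximates the
#' null. The right-tail p-value of gene i is the add-one tail proportion
#' `(1 + #\{j : t_j >= t_i\}) / (1 + N)`, computed within each `kind`;
#' Benjamini-Hochberg q-values are appended.
#'
#' @param scores A `sig_score_table` from [score_signatures()].
#' @return The table with `p_value` and `q_value` columns.
#' @export
empirical_null_pvalues <- function(scores) {
  stopifnot(inherits(scores, "sig_score_table"))
  out <- scores |>
    dplyr::group_by(.data$kind) |>
    dplyr::mutate(
      p_value = .empirical_p(.data$statistic),
      q_value = stats::p.adjust(.data$p_value, method = "BH")
    ) |>
    dplyr::ungroup()
  if (any(table(scores$kind) < 100)) {
    warning("fewer than 100 genes: the empirical null is unreliable")
  }
  class(out) <- c("sig_score_table", class(out))
  attr(out, "groups") <- attr(scores, "groups")
  out
}

.empirical_p <- function(t) {
  n <- length(t)
  # #{j : t_j >= t_i} via ranks; ties counted fully on both sides
  ge <- n - rank(t, ties.method = "min") + 1
  (1 + ge) / (1 + n)
}

#' One-versus-rest Welch t-test per gene
#'
#' Compares the samples of one group against all remaining samples merged,
#' with unequal variances (Welch). `direction = "down"` ranks negative t
#' (under-expression in the group) as downregulated-signature evidence.
#'
#' @param x An `expr_mat` (typically log space for t-statistics).
#' @param design A [group_design()].
#' @param group Group label or index to test.
#' @param direction `"up"` or `"down"`; only flips the ranking score.
#' @return A tibble: `gene_id`, `statistic` (Welch t), `df`, `p_value`
#'   (two-sided), `score` (direction-adjusted ranking score). Genes with
#'   fewer than two observed samples on either side get `NA` statistics.
#' @export
ovr_t_test <- function(x, design, group, direction = c("up", "down")) {
  direction <- match.arg(direction)
  di <- design_index(x, design)
  k <- if (is.character(group)) match(group, di$labels) else as.integer(group)
  if (is.na(k) || k < 1 || k > di$K) stop("unknown group", call. = FALSE)
  in_k <- di$k == k
  if (sum(in_k) < 2 || sum(!in_k) < 2) {
    stop("need >= 2 samples in the group and in the rest", call. = FALSE)
  }
  w <- .welch_rows(x$values[, in_k, drop = FALSE],
                   x$values[, !in_k, drop = FALSE])
  score <- if (direction == "up") w$t else -w$t
  tibble::tibble(gene_id = rownames(x$values), statistic = unname(w$t),
                 df = unname(w$df), p_value = unname(w$p),
                 score = unname(score))
}

# Row-wise Welch t over observed cells; cross-checked against stats::t.test
# in the test suite.
.welch_rows <- function(a, b) {
  na <- rowSums(!is.na(a)); nb <- rowSums(!is.na(b))
  ma <- rowMeans(a, na.rm = TRUE); mb <- rowMeans(b, na.rm = TRUE)
  va <- apply(a, 1, stats::var, na.rm = TRUE)
  vb <- apply(b, 1, stats::var, na.rm = TRUE)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  bad <- na < 2 | nb < 2
  t[bad] <- NA_real_; df[bad] <- NA_real_
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

#' One-versus-rest fold change per gene
#'
#' Ratio of a gene's mean expression in one group to its mean over all other
#' samples merged (linear space). Downregulated-signature ranking uses
#' ascending fold change.
#'
#' @param x An `expr_mat` in linear space.
#' @param design A [group_design()].
#' @param group Group label or index.
#' @param pseudocount Added to both means when the rest mean is zero (or
#'   always, if positive); with both means zero and no pseudocount the fold
#'   change is undefined (`NA`, flagged).
#' @return A tibble: `gene_id`, `mean_group`, `mean_rest`, `fold_change`,
#'   `undefined`.
#' @export
ovr_fold_change <- function(x, design, group, pseudocount = 0) {
  di <- design_index(x, design)
  k <- if (is.character(group)) match(group, di$labels) else as.integer(group)
  if (is.na(k) || k < 1 || k > di$K) stop("unknown group", call. = FALSE)
  in_k <- di$k == k
  mk <- rowMeans(x$values[, in_k, drop = FALSE], na.rm = TRUE)
  mr <- rowMeans(x$values[, !in_k, drop = FALSE], na.rm = TRUE)
  num <- mk + pseudocount
  den <- mr + pseudocount
  fc <- num / den
  undefined <- den == 0
  fc[undefined] <- NA_real_
  tibble::tibble(gene_id = rownames(x$values), mean_group = unname(mk),
                 mean_rest = unname(mr), fold_change = unname(fc),
                 undefined = unname(undefined))
}

# Downregulated-signature ranking scores for the three detectors (higher =
# stronger DSG evidence). Used by the detection benchmark and the CLI.
dsg_detector_scores <- function(x, design, detector = c("ecot", "ovr_t", "ovr_fc"),
                                pseudocount = 1e-8) {
  detector <- match.arg(detector)
  di <- design_index(x, design)
  if (detector == "ecot") {
    tab <- score_signatures(x, design, kind = "dsg")
    return(tibble::tibble(gene_id = tab$gene_id, score = tab$statistic))
  }
  if (detector == "ovr_t") {
    xl <- if (x$space == "linear") to_log_space(x) else x
    per_k <- vapply(di$labels, function(g) {
      ovr_t_test(xl, design, g, direction = "down")$score
    }, numeric(nrow(x$values)))
    return(tibble::tibble(gene_id = rownames(x$values),
                          score = apply(per_k, 1, max)))
  }
  per_k <- vapply(di$labels, function(g) {
    ovr_fold_change(x, design, g, pseudocount = pseudocount)$fold_change
  }, numeric(nrow(x$values)))
  tibble::tibble(gene_id = rownames(x$values),
                 score = -apply(per_k, 1, min))
}
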