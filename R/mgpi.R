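#' Per-sample normalization over fully observed genes
#'
#' Equalizes the per-sample medians computed from the subset of genes with no
#' missing cell, so that samples are comparable before imputation. In linear
#' space each sample is multiplied by `target / median_s`; in log space the
#' equivalent additive shift `target - median_s` is applied. The target is the
#' median of the per-sample medians. Scale factors (or shifts) are stored in
#' `meta$norm_factors`.
#'
#' @param x An `expr_mat`.
#' @return The normalized `expr_mat`.
#' @export
normalize_complete <- function(x) {
  stopifnot(inherits(x, "expr_mat"))
  complete <- rowSums(x$missing) == 0
  if (!any(complete)) {
    stop("no gene is fully observed; relax the requirement or skip ",
         "normalization (`normalize = FALSE`)", call. = FALSE)
  }
  sub <- x$values[complete, , drop = FALSE]
  med <- apply(sub, 2, stats::median)
  target <- stats::median(med)
  v <- x$values
  if (x$space == "linear") {
    fac <- target / med
    v <- sweep(v, 2, fac, `*`)
  } else {
    fac <- target - med
    v <- sweep(v, 2, fac, `+`)
  }
  meta <- x$meta
  meta$norm_factors <- stats::setNames(fac, colnames(v))
  expr_mat(v, x$missing, space = x$space, log_base = x$log_base,
           pseudocount = x$pseudocount, meta = meta)
}

#' Overall minimum observed value (LLOD anchor)
#'
#' The lower-limit-of-detection anchor epsilon is the minimum observed value
#' of the whole matrix in the working log space.
#'
#' @param x An `expr_mat` in log space.
#' @return A single number.
#' @export
estimate_epsilon <- function(x) {
  stopifnot(inherits(x, "expr_mat"))
  if (x$space != "log") stop("epsilon is defined in log space; transform first",
                             call. = FALSE)
  obs <- x$values[!x$missing]
  if (length(obs) == 0) stop("matrix has no observed cell", call. = FALSE)
  min(obs)
}

# Matrix-form per-gene per-group statistics over observed cells only.
.group_stats <- function(x, di) {
  v <- x$values
  m <- !x$missing
  G <- nrow(v); K <- di$K
  mean_mat <- sd_mat <- matrix(NA_real_, G, K,
                               dimnames = list(rownames(v), di$labels))
  n_mat <- matrix(0L, G, K, dimnames = dimnames(mean_mat))
  vz <- v
  vz[!m] <- 0
  for (k in seq_len(K)) {
    cols <- di$k == k
    n <- rowSums(m[, cols, drop = FALSE])
    s1 <- rowSums(vz[, cols, drop = FALSE])
    s2 <- rowSums(vz[, cols, drop = FALSE]^2)
    mu <- ifelse(n > 0, s1 / n, NA_real_)
    var <- ifelse(n > 1, pmax(0, (s2 - n * mu^2) / (n - 1)), NA_real_)
    mean_mat[, k] <- mu
    sd_mat[, k] <- sqrt(var)
    n_mat[, k] <- as.integer(n)
  }
  list(mean = mean_mat, sd = sd_mat, n_obs = n_mat)
}

#' Per-gene per-group means and standard deviations
#'
#' Statistics are computed from observed cells only; missing cells never enter
#' the estimates. The SD uses the n - 1 denominator and is `NA` when fewer
#' than two observed cells are available.
#'
#' @param x An `expr_mat` (log space for the imputation model).
#' @param design A [group_design()].
#' @return A tibble with columns `gene_id`, `group`, `mean`, `sd`, `n_obs`.
#' @export
group_stats <- function(x, design) {
  di <- design_index(x, design)
  st <- .group_stats(x, di)
  tibble::tibble(
    gene_id = rep(rownames(x$values), times = di$K),
    group = rep(di$labels, each = nrow(x$values)),
    mean = as.vector(st$mean),
    sd = as.vector(st$sd),
    n_obs = as.vector(st$n_obs)
  )
}

#' Probability that a missing cell is LLOD-censored
#'
#' Given the fitted per-group normal model (mean, sd) of a gene's observed
#' values and the global minimum observed value `epsilon`, the probability
#' that a value falls below the detection limit is the normal left-tail mass
#' `pnorm((epsilon - mean) / sd)`. A degenerate group (`sd = 0`) is a point
#' mass: alpha is 1 when its mean is at or below `epsilon`, else 0.
#'
#' @param mean,sd Numeric vectors (recycled) of group means and SDs.
#' @param epsilon The LLOD anchor, see [estimate_epsilon()].
#' @return Numeric vector of probabilities in `[0, 1]`; `NA` where `mean` is
#'   `NA`.
#' @export
llod_probability <- function(mean, sd, epsilon) {
  n <- max(length(mean), length(sd))
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  alpha <- stats::pnorm((epsilon - mean) / sd)
  deg <- !is.na(sd) & sd == 0
  alpha[deg] <- as.numeric(mean[deg] <= epsilon)
  alpha
}

# SD fallback for (gene, group) cells with n_obs < 2: the gene's pooled
# cross-group SD, else the matrix-wide median of defined SDs.
.sd_with_fallback <- function(st) {
  sd <- st$sd
  need <- is.na(sd)
  if (!any(need)) return(list(sd = sd, n_pooled = 0L, n_global = 0L))
  w <- pmax(st$n_obs - 1L, 0L)
  ss <- st$sd^2 * w
  ss[is.na(ss)] <- 0
  pooled <- sqrt(rowSums(ss) / pmax(rowSums(w), 1))
  pooled[rowSums(w) == 0] <- NA_real_
  global <- stats::median(sd[!is.na(sd)])
  if (is.na(global)) global <- 0
  fill <- matrix(pooled, nrow(sd), ncol(sd))
  n_pooled <- sum(need & !is.na(fill))
  fill[is.na(fill)] <- global
  sd[need] <- fill[need]
  list(sd = sd, n_pooled = n_pooled, n_global = sum(need) - n_pooled)
}

#' Mechanism-integrated group-wise pre-imputation
#'
#' Each missing cell of gene i in group k is imputed by a convex blend of two
#' classical imputands: the LLOD value `epsilon / 2` (weight `alpha_k(i)`, the
#' estimated probability that the cell is left-censored) and the group mean
#' `mean_k(i)` (weight `1 - alpha_k(i)`, the random-missingness imputand).
#' `alpha_k(i)` is the left-tail mass below `epsilon` of the normal
#' distribution fitted to the group's observed values, see
#' [llod_probability()].
#'
#' The model is estimated and applied in log space; a linear-space input is
#' transformed with `log(v + pseudocount, log_base)` and the completed matrix
#' is returned on the original scale. When a (gene, group) has no observed
#' cell at all, the group is treated as fully censored (`alpha = 1`) and the
#' cell imputes to the LLOD imputand. Observed cells are returned bit-
#' identical.
#'
#' @param x An `expr_mat` (linear or log space).
#' @param design A [group_design()].
#' @param normalize Run [normalize_complete()] internally before estimating
#'   the model (parameters only; returned values stay on the input scale).
#'   Off by default because heavily masked matrices rarely contain a fully
#'   observed gene.
#' @param log_base,pseudocount Log transform applied to linear-space input.
#' @param mnar_imputand `"half_epsilon"` applies `epsilon / 2` literally in
#'   log space; `"epsilon_minus_log2"` halves the intensity instead
#'   (`epsilon - log(2) / log(log_base)`).
#' @param refine_with Optional name of a peer imputer (e.g. `"ppca"`) re-run
#'   on the original mask afterwards, using the pre-imputed matrix as
#'   initialization; `NULL` (default) disables refinement.
#' @return An `imputation_result`: list with `completed` (an `expr_mat` with
#'   an empty mask), `method`, `params` (epsilon, alpha matrix, group stats,
#'   fallback counts) and `input_missing`.
#' @export
impute_mgpi <- function(x, design, normalize = FALSE, log_base = 2,
                        pseudocount = 1,
                        mnar_imputand = c("half_epsilon", "epsilon_minus_log2"),
                        refine_with = NULL) {
  stopifnot(inherits(x, "expr_mat"))
  mnar_imputand <- match.arg(mnar_imputand)
  di <- design_index(x, design)

  was_linear <- x$space == "linear"
  xl <- if (was_linear) to_log_space(x, base = log_base, pseudocount) else x

  shifts <- rep(0, ncol(xl$values))
  xw <- xl
  if (normalize) {
    xw <- normalize_complete(xl)
    shifts <- xw$meta$norm_factors
  }

  eps <- estimate_epsilon(xw)
  st <- .group_stats(xw, di)
  sdfix <- .sd_with_fallback(st)
  alpha <- matrix(
    llod_probability(as.vector(st$mean), as.vector(sdfix$sd), eps),
    nrow(st$mean), ncol(st$mean), dimnames = dimnames(st$mean)
  )
  silent <- st$n_obs == 0
  alpha[silent] <- 1

  mnar_val <- switch(mnar_imputand,
    half_epsilon = eps / 2,
    epsilon_minus_log2 = eps - log(2) / log(xw$log_base)
  )
  mu <- st$mean
  mu[silent] <- 0  # weight is 0 there; value irrelevant
  imputand <- alpha * mnar_val + (1 - alpha) * mu  # G x K, normalized space

  filled <- xl$values
  miss <- xl$missing
  for (k in seq_len(di$K)) {
    cols <- which(di$k == k)
    for (s in cols) {
      rows <- miss[, s]
      if (any(rows)) filled[rows, s] <- imputand[rows, k] - shifts[s]
    }
  }

  completed_log <- expr_mat(filled, matrix(FALSE, nrow(filled), ncol(filled)),
                            space = "log", log_base = xl$log_base,
                            pseudocount = xl$pseudocount, meta = x$meta)
  completed <- if (was_linear) {
    out <- from_log_space(completed_log)
    out$values[x$missing & out$values < 0] <- 0
    out$values[!x$missing] <- x$values[!x$missing]  # exact observed bits
    out
  } else {
    completed_log$values[!x$missing] <- x$values[!x$missing]
    completed_log
  }

  res <- new_imputation_result(
    completed = completed, input_missing = x$missing, method = "mgpi",
    params = list(epsilon = eps, alpha = alpha, mean = st$mean,
                  sd = sdfix$sd, n_obs = st$n_obs,
                  mnar_imputand = mnar_imputand, mnar_value = mnar_val,
                  normalize = normalize, norm_factors = shifts,
                  n_silent_cells = sum(silent),
                  n_sd_pooled = sdfix$n_pooled,
                  n_sd_global = sdfix$n_global)
  )
  if (!is.null(refine_with)) {
    res <- refine_imputation(res, x, method = refine_with)
  }
  res
}

new_imputation_result <- function(completed, input_missing, method, params) {
  structure(list(completed = completed, input_missing = input_missing,
                 method = method, params = params),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("<imputation_result> method '%s': %d cells imputed in a %d x %d matrix\n",
              x$method, sum(x$input_missing), nrow(x$completed$values),
              ncol(x$completed$values)))
  invisible(x)
}

#' Tidy the imputed cells of an imputation result
#'
#' @param x An `imputation_result`.
#' @param ... Unused.
#' @return A tibble with one row per originally missing cell: `gene_id`,
#'   `sample_id`, `imputed`.
#' @exportS3Method generics::tidy
tidy.imputation_result <- function(x, ...) {
  idx <- which(x$input_missing, arr.ind = TRUE)
  tibble::tibble(
    gene_id = rownames(x$input_missing)[idx[, 1]],
    sample_id = colnames(x$input_missing)[idx[, 2]],
    imputed = x$completed$values[idx]
  )
}

#' One-row summary of an imputation result
#'
#' @param x An `imputation_result`.
#' @param ... Unused.
#' @return A one-row tibble: method, matrix size, number of imputed cells and
#'   (for MGpI) epsilon plus fallback counts.
#' @exportS3Method generics::glance
glance.imputation_result <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_genes = nrow(x$completed$values),
    n_samples = ncol(x$completed$values),
    n_imputed = sum(x$input_missing),
    epsilon = if (!is.null(x$params$epsilon)) x$params$epsilon else NA_real_
  )
}
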