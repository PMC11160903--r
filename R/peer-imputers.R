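#' Classical peer imputers
#'
#' Seven widely used single-mechanism imputation methods, provided so that
#' the group-wise pre-imputation can be benchmarked like-for-like. All of
#' them operate in the working space of the input matrix (the benchmark
#' harness runs everything in log space), never modify observed cells, and
#' return an [`imputation_result`][impute_mgpi] with an empty missing mask.
#'
#' * `impute_half_min()`: gene-wise `min(observed) / 2`, the classical
#'   left-censoring (LLOD/MNAR) imputand.
#' * `impute_mean()`: gene-wise observed mean, the classical MAR/MCAR
#'   imputand.
#' * `impute_swknn()`: sample-wise k-nearest-neighbour average, weighted by
#'   proximity.
#'
#' @param x An `expr_mat`.
#' @return An `imputation_result`.
#' @name peer_imputers
NULL

.check_genes_observed <- function(x) {
  dead <- rowSums(!x$missing) == 0 & rowSums(x$missing) > 0
  if (any(dead)) {
    stop("genes with missing cells but no observed value: ",
         paste(rownames(x$values)[dead], collapse = ", "), call. = FALSE)
  }
}

.finish_peer <- function(x, filled, method, params = list()) {
  if (x$space == "linear") {
    # factorization-based fills can dip below zero; intensities cannot
    filled[x$missing & filled < 0] <- 0
  }
  filled[!x$missing] <- x$values[!x$missing]
  completed <- expr_mat(filled, matrix(FALSE, nrow(filled), ncol(filled)),
                        space = x$space, log_base = x$log_base,
                        pseudocount = x$pseudocount, meta = x$meta)
  new_imputation_result(completed, x$missing, method, params)
}

#' @rdname peer_imputers
#' @export
impute_half_min <- function(x) {
  stopifnot(inherits(x, "expr_mat"))
  .check_genes_observed(x)
  v <- x$values
  halfmin <- apply(v, 1, function(r) min(r, na.rm = TRUE)) / 2
  filled <- v
  filled[x$missing] <- halfmin[row(v)[x$missing]]
  .finish_peer(x, filled, "halfmin")
}

#' @rdname peer_imputers
#' @export
impute_mean <- function(x) {
  stopifnot(inherits(x, "expr_mat"))
  .check_genes_observed(x)
  v <- x$values
  mu <- rowMeans(v, na.rm = TRUE)
  filled <- v
  filled[x$missing] <- mu[row(v)[x$missing]]
  .finish_peer(x, filled, "mean")
}

# Pairwise sample distances: root-mean-square difference over co-observed
# genes; NA when two samples share no observed gene.
.sample_distances <- function(v, obs) {
  S <- ncol(v)
  vz <- v
  vz[!obs] <- 0
  o <- obs * 1
  cross <- crossprod(vz)           # sum over co-observed of x*y (zeros elsewhere)
  sq <- crossprod(vz^2, o)         # sum x^2 over co-observed
  co <- crossprod(o)               # co-observed counts
  ss <- sq + t(sq) - 2 * cross
  d <- sqrt(pmax(ss, 0) / co)
  d[co == 0] <- NA_real_
  d
}

#' @rdname peer_imputers
#' @param k Number of nearest neighbouring samples.
#' @export
impute_swknn <- function(x, k = 10) {
  stopifnot(inherits(x, "expr_mat"), k >= 1)
  .check_genes_observed(x)
  v <- x$values
  obs <- !x$missing
  d <- .sample_distances(v, obs)
  mu <- rowMeans(v, na.rm = TRUE)
  filled <- v
  n_fallback <- 0L
  for (i in which(rowSums(x$missing) > 0)) {
    observers <- which(obs[i, ])
    for (s in which(x$missing[i, ])) {
      ds <- d[s, observers]
      ok <- !is.na(ds)
      if (!any(ok)) {
        filled[i, s] <- mu[i]
        n_fallback <- n_fallback + 1L
        next
      }
      cand <- observers[ok]
      dv <- ds[ok]
      ord <- order(dv)[seq_len(min(k, length(cand)))]
      dv <- dv[ord]; cand <- cand[ord]
      if (any(dv == 0)) {
        w <- as.numeric(dv == 0)   # exact duplicates take full weight
      } else {
        w <- 1 / (dv + 1e-12)
      }
      filled[i, s] <- sum(w * v[i, cand]) / sum(w)
    }
  }
  .finish_peer(x, filled, "swknn",
               params = list(k = k, n_fallback = n_fallback))
}
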