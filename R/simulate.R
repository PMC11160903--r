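#' Simulate a ground-truth-embedded scatter-simplex benchmark
#'
#' Generates a genes x samples matrix in which every gene has a known class:
#' two null populations drawn from symmetric Dirichlet distributions on the
#' K-simplex (a flat one with concentration `alpha = 1` and a centre-peaked
#' one with `alpha = 4`), upregulated signature genes (SGs) placed at the
#' simplex vertices, and downregulated signature genes (DSGs) placed at the
#' centres of the opposite facets. Signature positions are jittered with a
#' truncated/non-negative Gaussian perturbation (folded on boundary
#' coordinates, clipped at zero elsewhere) and renormalized onto the
#' simplex. Sample-level intensities are
#' `A(i) * m_k(i) * (1 + eta)` with a log-normal per-gene amplitude `A(i)`
#' and multiplicative Gaussian noise `eta` truncated at -1.
#'
#' @param K Number of groups (2 or more; the benchmark uses 3-5).
#' @param n_null_flat,n_null_peaked Null gene counts for the alpha = 1 and
#'   alpha = 4 Dirichlet components.
#' @param n_sg_per_group,n_dsg_per_group Signature gene counts per group.
#' @param sg_sigma,dsg_sigma SD of the truncated-Gaussian jitter around the
#'   vertex / facet-centre positions.
#' @param samples_per_group Samples drawn per group.
#' @param amplitude_log_sd SD of `log(A)`; amplitudes are
#'   `exp(rnorm(log(100), amplitude_log_sd))`.
#' @param noise_cv SD of the multiplicative noise.
#' @param seed Mandatory RNG seed; identical seeds give bit-identical output.
#' @return A list of class `simplex_sim`: `x` (linear-space `expr_mat`),
#'   `design` (a [group_design()]), `truth` (list with tibble
#'   `feature_class` and the proportion matrix `proportions`; `omega` is
#'   filled in by [simulate_missingness()]).
#' @export
simulate_simplex <- function(K = 3, n_null_flat = 1200, n_null_peaked = 1200,
                             n_sg_per_group = 20, n_dsg_per_group = 50,
                             sg_sigma = 0.45, dsg_sigma = 0.03,
                             samples_per_group = 10, amplitude_log_sd = 1,
                             noise_cv = 0.2, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(K >= 2, n_null_flat >= 0, n_null_peaked >= 0,
            n_sg_per_group >= 0, n_dsg_per_group >= 0, samples_per_group >= 1)
  set.seed(seed)

  rdirichlet <- function(n, alpha) {
    g <- matrix(stats::rgamma(n * K, shape = alpha), n, K)
    g / rowSums(g)
  }
  # Truncated/non-negative Gaussian jitter: coordinates sitting on the
  # boundary (centre = 0) receive folded half-normal noise, interior
  # coordinates are clipped at zero; the result is renormalized onto the
  # simplex.
  jitter_on_simplex <- function(centres, sigma) {
    noise <- matrix(stats::rnorm(length(centres), 0, sigma),
                    nrow(centres), K)
    out <- ifelse(centres == 0, abs(noise), pmax(centres + noise, 0))
    bad <- rowSums(out) <= 0
    out[bad, ] <- centres[bad, ]
    out / rowSums(out)
  }

  cls <- c(rep("null_flat", n_null_flat), rep("null_peaked", n_null_peaked),
           rep("sg", K * n_sg_per_group), rep("dsg", K * n_dsg_per_group))
  grp_of <- c(rep(NA_integer_, n_null_flat + n_null_peaked),
              rep(seq_len(K), each = n_sg_per_group),
              rep(seq_len(K), each = n_dsg_per_group))
  G <- length(cls)
  if (G < 2) stop("need at least two features", call. = FALSE)

  m <- matrix(0, G, K)
  if (n_null_flat > 0) m[cls == "null_flat", ] <- rdirichlet(n_null_flat, 1)
  if (n_null_peaked > 0) {
    m[cls == "null_peaked", ] <- rdirichlet(n_null_peaked, 4)
  }
  if (n_sg_per_group > 0) {
    idx <- which(cls == "sg")
    m[idx, ] <- jitter_on_simplex(diag(K)[grp_of[idx], , drop = FALSE],
                                  sg_sigma)
  }
  if (n_dsg_per_group > 0) {
    idx <- which(cls == "dsg")
    centres <- (1 - diag(K)[grp_of[idx], , drop = FALSE]) / (K - 1)
    m[idx, ] <- jitter_on_simplex(centres, dsg_sigma)
  }

  amp <- exp(stats::rnorm(G, log(100), amplitude_log_sd))
  S <- K * samples_per_group
  grp_s <- rep(seq_len(K), each = samples_per_group)
  eta <- matrix(stats::rnorm(G * S, 0, noise_cv), G, S)
  eta[eta < -1] <- -1
  v <- (amp * m[, grp_s]) * (1 + eta)
  rownames(v) <- sprintf("gene_%04d", seq_len(G))
  colnames(v) <- sprintf("s%03d", seq_len(S))
  labels <- paste0("G", seq_len(K))

  truth <- list(
    feature_class = tibble::tibble(
      gene_id = rownames(v), class = cls,
      group = ifelse(is.na(grp_of), NA_character_, labels[grp_of])
    ),
    proportions = m,
    omega = NULL
  )
  structure(
    list(x = expr_mat(v, space = "linear"),
         design = group_design(colnames(v), labels[grp_s]),
         truth = truth),
    class = "simplex_sim"
  )
}

#' @export
print.simplex_sim <- function(x, ...) {
  cat(sprintf("<simplex_sim> %d genes x %d samples, %d groups\n",
              nrow(x$x$values), ncol(x$x$values), nlevels(x$design$group)))
  invisible(x)
}

#' Introduce mixed-mechanism missingness with recorded ground truth
#'
#' Masks a fixed fraction of the eligible cells. A `mar_proportion` share of
#' the masked cells is drawn uniformly at random (MAR); the remainder is
#' drawn with probability proportional to the left-censoring weight
#' `pnorm((c - l) / s)` on the log-intensity scale, where `c` is the
#' `llod_quantile` of the eligible log-intensities — a soft LLOD that
#' concentrates MNAR missingness in low-intensity cells while still allowing
#' occasional mid-range losses. True values and mechanism labels of every
#' masked cell are stored in `omega`.
#'
#' @param x An `expr_mat` (linear or log space); only currently observed
#'   cells are eligible.
#' @param truth Optional truth list from [simulate_simplex()]; its `omega`
#'   slot is filled.
#' @param overall_rate Fraction of eligible cells to mask, in (0, 1).
#' @param mar_proportion Fraction of the masked cells that is MAR, in (0, 1).
#' @param llod_quantile Quantile of the eligible intensity distribution used
#'   as the soft censoring threshold.
#' @param nonzero_only Restrict masking to non-zero cells.
#' @param min_observed Number of observed cells each gene is guaranteed to
#'   keep (default 1): gene-wise imputands are undefined on fully masked
#'   genes, so the benchmark protocol always leaves at least one anchor.
#'   The protected cells are drawn at random per gene and simply removed
#'   from the eligible pool.
#' @param seed Mandatory RNG seed.
#' @return A list: `masked` (the `expr_mat` with new missing cells), `omega`
#'   (tibble `gene_id`, `sample_id`, `true_value`, `mechanism`), and `truth`
#'   (input truth with `omega` attached, if supplied).
#' @export
simulate_missingness <- function(x, truth = NULL, overall_rate,
                                 mar_proportion, llod_quantile = 0.25,
                                 nonzero_only = TRUE, min_observed = 1,
                                 seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(inherits(x, "expr_mat"),
            overall_rate > 0, overall_rate < 1,
            mar_proportion > 0, mar_proportion < 1, min_observed >= 0)
  set.seed(seed)
  v <- x$values
  eligible <- which(!x$missing & (!nonzero_only | v != 0))
  if (min_observed > 0 && length(eligible) > 0) {
    byg <- split(eligible, row(v)[eligible])
    protected <- unlist(lapply(byg, function(idx) {
      if (length(idx) <= min_observed) idx
      else idx[sample.int(length(idx), min_observed)]
    }), use.names = FALSE)
    eligible <- setdiff(eligible, protected)
  }
  n_total <- round(overall_rate * length(eligible))
  if (n_total < 1) stop("overall_rate too small: no cell would be masked",
                        call. = FALSE)
  n_mar <- round(mar_proportion * n_total)
  n_mnar <- n_total - n_mar

  mar_idx <- sample(eligible, n_mar)
  rest <- setdiff(eligible, mar_idx)
  lv <- if (x$space == "linear") log2(v[rest] + 1) else v[rest]
  cen <- stats::quantile(lv, llod_quantile, names = FALSE)
  sc <- stats::sd(lv)
  if (!is.finite(sc) || sc == 0) sc <- 1
  w <- stats::pnorm((cen - lv) / sc)
  mnar_idx <- rest[sample.int(length(rest), n_mnar, prob = pmax(w, 1e-12))]

  masked_idx <- c(mar_idx, mnar_idx)
  mech <- rep(c("MAR", "MNAR"), c(n_mar, n_mnar))
  ord <- order(masked_idx)
  masked_idx <- masked_idx[ord]
  mech <- mech[ord]

  ij <- arrayInd(masked_idx, dim(v))
  omega <- tibble::tibble(
    gene_id = rownames(v)[ij[, 1]],
    sample_id = colnames(v)[ij[, 2]],
    true_value = v[masked_idx],
    mechanism = mech
  )
  miss <- x$missing
  miss[masked_idx] <- TRUE
  masked <- expr_mat(replace(v, masked_idx, NA_real_), miss, space = x$space,
                     log_base = x$log_base, pseudocount = x$pseudocount,
                     meta = x$meta)
  if (!is.null(truth)) truth$omega <- omega
  list(masked = masked, omega = omega, truth = truth)
}
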