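#' Imputation error over the masked ground-truth cells
#'
#' Root-mean-square error between imputed and true values, measured over the
#' masked cells only. `nrmse()` divides by the standard deviation (population
#' normalization, `1/|omega|`) of the true masked values, making the score
#' scale-free.
#'
#' @param imputed An `imputation_result` or completed `expr_mat`.
#' @param omega Tibble of masked cells (`gene_id`, `sample_id`,
#'   `true_value`), as produced by [simulate_missingness()].
#' @param genes Optional gene-id subset (e.g. signature genes only).
#' @return A single non-negative number.
#' @export
rmse <- function(imputed, omega, genes = NULL) {
  e <- .omega_errors(imputed, omega, genes)
  sqrt(mean(e$err^2))
}

#' @rdname rmse
#' @export
nrmse <- function(imputed, omega, genes = NULL) {
  e <- .omega_errors(imputed, omega, genes)
  if (length(e$true) < 2) stop("need >= 2 masked cells for NRMSE",
                               call. = FALSE)
  v <- mean((e$true - mean(e$true))^2)
  if (v == 0) stop("true masked values have zero variance", call. = FALSE)
  sqrt(mean(e$err^2)) / sqrt(v)
}

.omega_errors <- function(imputed, omega, genes) {
  x <- if (inherits(imputed, "imputation_result")) imputed$completed else imputed
  stopifnot(inherits(x, "expr_mat"))
  if (!is.null(genes)) omega <- omega[omega$gene_id %in% genes, , drop = FALSE]
  if (nrow(omega) == 0) stop("no masked cells in the requested subset",
                             call. = FALSE)
  i <- match(omega$gene_id, rownames(x$values))
  j <- match(omega$sample_id, colnames(x$values))
  if (anyNA(i) || anyNA(j)) stop("omega refers to unknown genes or samples",
                                 call. = FALSE)
  est <- x$values[cbind(i, j)]
  list(err = est - omega$true_value, true = omega$true_value)
}

#' Partial ROC curve and partial AUC at an FPR cutoff
#'
#' Ranks genes by descending score, builds the ROC curve with simultaneous
#' steps for tied scores, and integrates the area under it (trapezoidal)
#' over `FPR` in `[0, fpr_cutoff]`, interpolating at the cutoff. The raw
#' pAUC is at most `fpr_cutoff`; the normalized variant divides by the
#' cutoff, so a perfect ranker scores 1 while a random one scores about
#' `fpr_cutoff / 2` (the chance diagonal restricted to the cutoff).
#'
#' @param scores Numeric vector of detector scores (higher = more positive),
#'   or a tibble with columns `gene_id` and `score`.
#' @param labels Logical vector (`TRUE` = positive) aligned with `scores`.
#' @param fpr_cutoff Upper FPR bound of the partial area.
#' @return A `proc_curve` object: `points` (tibble `fpr`, `tpr`),
#'   `pauc_raw`, `pauc_normalized`, `auc` (full), `sensitivity_at_cutoff`
#'   (TPR at `FPR = fpr_cutoff`, interpolated), `fpr_cutoff`.
#' @export
proc_curve <- function(scores, labels, fpr_cutoff = 0.05) {
  if (is.data.frame(scores)) scores <- scores$score
  stopifnot(length(scores) == length(labels),
            fpr_cutoff > 0, fpr_cutoff <= 1)
  labels <- as.logical(labels)
  np <- sum(labels)
  nn <- sum(!labels)
  if (np == 0 || nn == 0) stop("need both positive and negative genes",
                               call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  last <- !duplicated(s, fromLast = TRUE)  # simultaneous step on ties
  tp <- cumsum(l)[last]
  fp <- cumsum(!l)[last]
  fpr <- c(0, fp / nn)
  tpr <- c(0, tp / np)

  interp_tpr <- function(at) {
    if (at >= fpr[length(fpr)]) return(tpr[length(tpr)])
    j <- findInterval(at, fpr, rightmost.closed = TRUE)
    if (fpr[j + 1] == fpr[j]) return(max(tpr[j], tpr[j + 1]))
    tpr[j] + (tpr[j + 1] - tpr[j]) * (at - fpr[j]) / (fpr[j + 1] - fpr[j])
  }
  pauc_at <- function(cut) {
    keep <- fpr <= cut
    xs <- c(fpr[keep], cut)
    ys <- c(tpr[keep], interp_tpr(cut))
    sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  }
  structure(
    list(points = tibble::tibble(fpr = fpr, tpr = tpr),
         pauc_raw = pauc_at(fpr_cutoff),
         pauc_normalized = pauc_at(fpr_cutoff) / fpr_cutoff,
         auc = pauc_at(1),
         sensitivity_at_cutoff = interp_tpr(fpr_cutoff),
         fpr_cutoff = fpr_cutoff,
         n_positive = np, n_negative = nn),
    class = "proc_curve"
  )
}

#' @export
print.proc_curve <- function(x, ...) {
  cat(sprintf("<proc_curve> pAUC(FPR<=%.3g) raw %.4f, normalized %.4f; AUC %.4f\n",
              x$fpr_cutoff, x$pauc_raw, x$pauc_normalized, x$auc))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.proc_curve <- function(x, ...) {
  tibble::tibble(pauc_raw = x$pauc_raw,
                 pauc_normalized = x$pauc_normalized,
                 auc = x$auc,
                 sensitivity_at_cutoff = x$sensitivity_at_cutoff,
                 fpr_cutoff = x$fpr_cutoff,
                 n_positive = x$n_positive, n_negative = x$n_negative)
}

#' @exportS3Method generics::tidy
tidy.proc_curve <- function(x, ...) x$points

#' Plot a partial ROC curve
#' @param object A `proc_curve`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.proc_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = object$fpr_cutoff, linetype = 2) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate") +
    ggplot2::theme_minimal()
}

#' Imputation benchmark over a missingness grid
#'
#' For every replicate, simulates a simplex benchmark matrix, log-transforms
#' it, masks it at each (overall rate, MAR proportion) grid cell with
#' recorded ground truth, runs every requested imputer, and scores RMSE and
#' NRMSE over the masked cells — overall and restricted to the upregulated
#' signature genes, whose missingness is the most mechanism-mixed.
#'
#' @param K,samples_per_group Simulation shape, see [simulate_simplex()].
#' @param overall_rates,mar_proportions Grid of masking conditions.
#' @param methods Imputer names among `mgpi`, `halfmin`, `mean`, `swknn`,
#'   `ppca`, `nipals`, `svd`, `svt`.
#' @param replicates Number of independent replicates.
#' @param seed Master seed; every replicate and grid cell derives a fixed
#'   sub-seed from it.
#' @param sim_args Extra arguments forwarded to [simulate_simplex()].
#' @param method_args Named list of per-method argument lists.
#' @return An `imputation_benchmark`: `results` (per replicate x cell x
#'   method tibble) and `summary` (means and SDs across replicates).
#' @export
run_imputation_benchmark <- function(K = 4, samples_per_group = 15,
                                     overall_rates = c(0.4, 0.5, 0.6),
                                     mar_proportions = c(0.3, 0.4, 0.5),
                                     methods = c("mgpi", "mean", "halfmin"),
                                     replicates = 5, seed,
                                     sim_args = list(),
                                     method_args = list()) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  reg <- imputer_registry()
  bad <- setdiff(methods, names(reg))
  if (length(bad)) stop("unknown methods: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  grid <- tidyr::expand_grid(overall_rate = overall_rates,
                             mar_proportion = mar_proportions)
  rows <- list()
  for (r in seq_len(replicates)) {
    sim <- do.call(simulate_simplex, c(
      list(K = K, samples_per_group = samples_per_group,
           seed = (seed + 7919L * r) %% 2147483647L),
      sim_args))
    xl <- to_log_space(sim$x)
    sg_genes <- sim$truth$feature_class$gene_id[
      sim$truth$feature_class$class == "sg"]
    for (g in seq_len(nrow(grid))) {
      msk <- simulate_missingness(
        xl, overall_rate = grid$overall_rate[g],
        mar_proportion = grid$mar_proportion[g],
        seed = (seed + 7919L * r + 131L * g) %% 2147483647L)
      for (m in methods) {
        res <- tryCatch(
          do.call(reg[[m]], c(list(msk$masked, design = sim$design),
                              method_args[[m]])),
          error = function(e) e)
        if (inherits(res, "error")) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            replicate = r, overall_rate = grid$overall_rate[g],
            mar_proportion = grid$mar_proportion[g], method = m,
            rmse = NA_real_, nrmse = NA_real_, rmse_sg = NA_real_,
            nrmse_sg = NA_real_, error = conditionMessage(res))
          next
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          replicate = r, overall_rate = grid$overall_rate[g],
          mar_proportion = grid$mar_proportion[g], method = m,
          rmse = rmse(res, msk$omega),
          nrmse = nrmse(res, msk$omega),
          rmse_sg = rmse(res, msk$omega, genes = sg_genes),
          nrmse_sg = nrmse(res, msk$omega, genes = sg_genes),
          error = NA_character_)
      }
    }
  }
  results <- dplyr::bind_rows(rows)
  summary <- results |>
    dplyr::group_by(.data$method, .data$overall_rate, .data$mar_proportion) |>
    dplyr::summarise(dplyr::across(c("rmse", "nrmse", "rmse_sg", "nrmse_sg"),
                                   list(mean = mean, sd = stats::sd)),
                     .groups = "drop")
  structure(list(results = results, summary = summary,
                 replicates = replicates, seed = seed),
            class = "imputation_benchmark")
}

#' @export
print.imputation_benchmark <- function(x, ...) {
  cat(sprintf("<imputation_benchmark> %d methods x %d grid cells x %d replicates\n",
              length(unique(x$results$method)),
              nrow(unique(x$results[c("overall_rate", "mar_proportion")])),
              x$replicates))
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.imputation_benchmark <- function(x, ...) x$summary

#' @exportS3Method ggplot2::autoplot
autoplot.imputation_benchmark <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$overall_rate, y = .data$rmse_mean,
                               colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~mar_proportion,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Overall missing rate", y = "RMSE (masked cells)") +
    ggplot2::theme_minimal()
}

#' Downregulated-signature detection benchmark
#'
#' For every replicate and group count, simulates the simplex benchmark
#' (no masking), ranks all genes by each detector's downregulated-signature
#' evidence, and scores the ranking against the ground truth (positives =
#' true DSGs, negatives = everything else) with a partial ROC at the given
#' FPR cutoff.
#'
#' @param K Integer vector of group counts to test.
#' @param detectors Among `"ecot"`, `"ovr_t"`, `"ovr_fc"`.
#' @param fpr_cutoff FPR bound of the partial AUC.
#' @param replicates,seed As in [run_imputation_benchmark()].
#' @param samples_per_group,sim_args Simulation shape.
#' @return A `detection_benchmark`: per-replicate `results` and a `summary`
#'   of mean pAUC and sensitivity per (K, detector).
#' @export
run_detection_benchmark <- function(K = c(3, 4, 5),
                                    detectors = c("ecot", "ovr_t", "ovr_fc"),
                                    fpr_cutoff = 0.05, replicates = 5, seed,
                                    samples_per_group = 10, sim_args = list()) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  detectors <- match.arg(detectors, several.ok = TRUE)
  rows <- list()
  for (k in K) {
    for (r in seq_len(replicates)) {
      sim <- do.call(simulate_simplex, c(
        list(K = k, samples_per_group = samples_per_group,
             seed = (seed + 104729L * k + 7919L * r) %% 2147483647L),
        sim_args))
      pos <- sim$truth$feature_class$class == "dsg"
      for (d in detectors) {
        sc <- dsg_detector_scores(sim$x, sim$design, detector = d)
        pr <- proc_curve(sc$score, pos, fpr_cutoff = fpr_cutoff)
        rows[[length(rows) + 1]] <- tibble::tibble(
          K = k, replicate = r, detector = d,
          pauc_raw = pr$pauc_raw, pauc_normalized = pr$pauc_normalized,
          auc = pr$auc, sensitivity = pr$sensitivity_at_cutoff)
      }
    }
  }
  results <- dplyr::bind_rows(rows)
  summary <- results |>
    dplyr::group_by(.data$K, .data$detector) |>
    dplyr::summarise(dplyr::across(c("pauc_raw", "pauc_normalized", "auc",
                                     "sensitivity"),
                                   list(mean = mean, sd = stats::sd)),
                     .groups = "drop")
  structure(list(results = results, summary = summary,
                 fpr_cutoff = fpr_cutoff, replicates = replicates,
                 seed = seed),
            class = "detection_benchmark")
}

#' @export
print.detection_benchmark <- function(x, ...) {
  cat(sprintf("<detection_benchmark> pAUC at FPR <= %.3g, %d replicates\n",
              x$fpr_cutoff, x$replicates))
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.detection_benchmark <- function(x, ...) x$summary

#' @exportS3Method ggplot2::autoplot
autoplot.detection_benchmark <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = factor(.data$K),
                               y = .data$pauc_normalized,
                               colour = .data$detector)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "Number of groups",
                  y = sprintf("Normalized pAUC (FPR <= %.3g)",
                              object$fpr_cutoff)) +
    ggplot2::theme_minimal()
}
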