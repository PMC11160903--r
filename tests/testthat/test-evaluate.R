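make_eval_case <- function() {
  v <- matrix(as.numeric(1:12), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  omega <- tibble::tibble(
    gene_id = c("g1", "g2"), sample_id = c("s2", "s3"),
    true_value = c(v["g1", "s2"], v["g2", "s3"]))
  list(x = expr_mat(v, space = "log"), omega = omega)
}

test_that("RMSE and NRMSE follow their formulas on hand-built cases", {
  ec <- make_eval_case()
  expect_equal(rmse(ec$x, ec$omega), 0)
  expect_equal(nrmse(ec$x, ec$omega), 0)

  xh <- ec$x
  xh$values["g1", "s2"] <- xh$values["g1", "s2"] + 1
  xh$values["g2", "s3"] <- xh$values["g2", "s3"] + 3
  expect_equal(rmse(xh, ec$omega), sqrt((1 + 9) / 2))

  single <- ec$omega[1, ]
  expect_equal(rmse(xh, single, genes = "g1"), 1)

  # errors of +-1 SD of the truth give NRMSE close to 1 (population variance)
  true <- c(2, 4, 6, 8)
  sd_pop <- sqrt(mean((true - mean(true))^2))
  v <- matrix(true + sd_pop * c(1, -1, 1, -1), 4, 1,
              dimnames = list(paste0("g", 1:4), "s1"))
  om <- tibble::tibble(gene_id = paste0("g", 1:4), sample_id = "s1",
                       true_value = true)
  expect_equal(nrmse(expr_mat(v, space = "log"), om), 1)

  # scaling truth and estimates together leaves NRMSE unchanged
  v10 <- expr_mat(10 * v, space = "log")
  om10 <- om; om10$true_value <- 10 * om10$true_value
  expect_equal(nrmse(v10, om10), nrmse(expr_mat(v, space = "log"), om))

  expect_error(rmse(xh, ec$omega, genes = "none"), "no masked cells")
  const <- om; const$true_value <- rep(5, 4)
  expect_error(nrmse(expr_mat(v, space = "log"), const), "zero variance")
})

test_that("partial ROC handles perfect, inverted and random rankings", {
  labels <- rep(c(TRUE, FALSE), c(50, 950))
  perfect <- proc_curve(c(seq(2, 3, length.out = 50),
                          seq(0, 1, length.out = 950)), labels,
                        fpr_cutoff = 0.05)
  expect_equal(perfect$pauc_raw, 0.05)
  expect_equal(perfect$pauc_normalized, 1)
  expect_equal(perfect$sensitivity_at_cutoff, 1)

  inverted <- proc_curve(-c(seq(2, 3, length.out = 50),
                            seq(0, 1, length.out = 950)), labels,
                         fpr_cutoff = 0.05)
  expect_lt(inverted$pauc_raw, 1e-6)

  set.seed(10)
  rnd <- proc_curve(runif(20000), rep(c(TRUE, FALSE), 10000),
                    fpr_cutoff = 0.05)
  expect_equal(rnd$pauc_raw, 0.05^2 / 2, tolerance = 0.25)
  expect_equal(rnd$pauc_normalized, 0.025, tolerance = 0.25)

  expect_error(proc_curve(1:5, rep(TRUE, 5)), "positive and negative")
})

test_that("full AUC equals the Mann-Whitney statistic on tie-free data", {
  set.seed(4)
  scores <- rnorm(60)
  labels <- rep(c(TRUE, FALSE), c(25, 35))
  pc <- proc_curve(scores, labels, fpr_cutoff = 1)
  u <- wilcox.test(scores[labels], scores[!labels])$statistic
  expect_equal(pc$auc, unname(u) / (25 * 35), tolerance = 1e-12)
  expect_equal(pc$pauc_raw, pc$auc)
})

test_that("partial AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  scores <- c(rnorm(40, 1), rnorm(160))
  labels <- rep(c(1, 0), c(40, 160))
  for (cut in c(0.05, 0.2, 0.5)) {
    ours <- proc_curve(scores, labels == 1, fpr_cutoff = cut)
    ref <- pROC::roc(labels, scores, direction = "<", quiet = TRUE)
    ref_pauc <- as.numeric(pROC::auc(ref, partial.auc = c(1, 1 - cut),
                                     partial.auc.focus = "specificity"))
    expect_equal(ours$pauc_raw, ref_pauc, tolerance = 1e-9)
  }
})

test_that("ROC points are monotone and bounded", {
  set.seed(2)
  pc <- proc_curve(rnorm(300), runif(300) < 0.3, fpr_cutoff = 0.1)
  expect_true(all(diff(pc$points$fpr) >= 0))
  expect_true(all(diff(pc$points$tpr) >= 0))
  expect_true(all(pc$points$fpr >= 0 & pc$points$fpr <= 1))
  expect_lte(pc$pauc_raw, pc$fpr_cutoff)
  expect_s3_class(autoplot(pc), "ggplot")
  expect_equal(nrow(glance(pc)), 1)
})

test_that("mean imputation error on group-flat noiseless data is analytic", {
  # two groups with constant levels a and b; one masked cell per gene in
  # group A: gene mean over the remaining cells is analytic
  a <- 2; b <- 6
  v <- rbind(g1 = c(a, a, a, b, b, b), g2 = c(2 * a, 2 * a, 2 * a,
                                              2 * b, 2 * b, 2 * b))
  colnames(v) <- paste0("s", 1:6)
  masked <- v
  masked[, "s1"] <- NA
  x <- expr_mat(masked, space = "log")
  om <- tibble::tibble(gene_id = c("g1", "g2"), sample_id = "s1",
                       true_value = v[, "s1"])
  res <- impute_mean(x)
  exp_err <- function(aa, bb) (2 * aa + 3 * bb) / 5 - aa
  expect_equal(rmse(res, om),
               sqrt(mean(c(exp_err(a, b)^2, exp_err(2 * a, 2 * b)^2))))
})

test_that("benchmarks are bit-reproducible under a master seed", {
  args <- list(K = 3, samples_per_group = 4, overall_rates = 0.4,
               mar_proportions = 0.4, methods = c("mgpi", "mean"),
               replicates = 2, seed = 77,
               sim_args = list(n_null_flat = 80, n_null_peaked = 80,
                               n_sg_per_group = 5, n_dsg_per_group = 5))
  b1 <- do.call(run_imputation_benchmark, args)
  b2 <- do.call(run_imputation_benchmark, args)
  expect_identical(b1$results, b2$results)
  expect_s3_class(tidy(b1), "tbl_df")
  expect_s3_class(autoplot(b1), "ggplot")

  d1 <- run_detection_benchmark(K = 3, replicates = 2, seed = 88,
                                samples_per_group = 4,
                                sim_args = list(n_null_flat = 80,
                                                n_null_peaked = 80,
                                                n_sg_per_group = 5,
                                                n_dsg_per_group = 5))
  d2 <- run_detection_benchmark(K = 3, replicates = 2, seed = 88,
                                samples_per_group = 4,
                                sim_args = list(n_null_flat = 80,
                                                n_null_peaked = 80,
                                                n_sg_per_group = 5,
                                                n_dsg_per_group = 5))
  expect_identical(d1$results, d2$results)
  expect_true(all(d1$results$pauc_raw <= 0.05 + 1e-12))
  expect_s3_class(autoplot(d1), "ggplot")
})

test_that("an oracle detector reaches normalized pAUC 1 and shuffled truth sits near chance", {
  sim <- simulate_simplex(K = 3, n_null_flat = 300, n_null_peaked = 300,
                          n_sg_per_group = 10, n_dsg_per_group = 20,
                          samples_per_group = 5, seed = 14)
  pos <- sim$truth$feature_class$class == "dsg"
  oracle <- proc_curve(as.numeric(pos), pos, fpr_cutoff = 0.05)
  expect_equal(oracle$pauc_normalized, 1)

  set.seed(15)
  shuffled <- sample(pos)
  sc <- dsg_detector_scores(sim$x, sim$design, "ecot")
  chance <- proc_curve(sc$score, shuffled, fpr_cutoff = 0.05)
  expect_lt(chance$pauc_normalized, 0.15)
})
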