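test_that("group mean vectors average samples within groups", {
  v <- rbind(g1 = c(1, 3, 2, 2, 2),
             g2 = c(0, 0, 0, 0, 0),
             g3 = c(1, 2, 4, 5, 6))
  colnames(v) <- paste0("s", 1:5)
  x <- expr_mat(v, space = "linear")
  d <- group_design(colnames(v), c("A", "A", "B", "B", "B"))
  expect_warning(mv <- group_mean_vectors(x, d), "dropped")
  expect_equal(nrow(mv), 2)  # all-zero g2 dropped
  expect_equal(unlist(mv[mv$gene_id == "g1", c("A", "B")]),
               c(A = 2, B = 2))
  expect_error(group_mean_vectors(rand_expr(miss_frac = 0.2, seed = 1),
                                  halves_design(rand_expr(seed = 1))),
               "missing cells")
})

test_that("cosine statistics match their closed forms", {
  expect_equal(cot_statistic(c(1, 0, 0), 1), 1)
  expect_equal(cot_statistic(c(0, 1, 1), 1), 0)
  expect_equal(cot_statistic(c(1, 1, 1), 1), 1 / sqrt(3))
  expect_equal(ecot_statistic(c(0, 1, 1), 1), 1)
  expect_equal(ecot_statistic(c(1, 0, 0), 1), 0)
  expect_equal(ecot_statistic(c(1, 1, 1), 1), 2 / sqrt(6))
  expect_error(cot_statistic(c(0, 0), 1), "zero")
  expect_error(ecot_statistic(c(-1, 2), 1), "non-negative")
})

test_that("statistics are scale-invariant and bounded in [0, 1]", {
  set.seed(77)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    v <- runif(k, 0, 10)
    j <- sample(k, 1)
    for (f in list(cot_statistic, ecot_statistic)) {
      t1 <- f(v, j)
      expect_gte(t1, 0); expect_lte(t1, 1)
      expect_equal(f(10 * v, j), t1, tolerance = 1e-12)
      expect_equal(f(0.037 * v, j), t1, tolerance = 1e-12)
    }
  }
  # statistic is 1 iff the vector is proportional to the reference
  expect_equal(ecot_statistic(3 * c(0, 1, 1, 1), 1), 1)
  expect_lt(ecot_statistic(c(0.05, 1, 1, 1), 1), 1)
})

test_that("on two groups the DSG statistic equals the opposite SG statistic", {
  set.seed(12)
  for (i in 1:20) {
    v <- runif(2, 0, 5)
    expect_equal(ecot_statistic(v, 1), cot_statistic(v, 2), tolerance = 1e-12)
    expect_equal(ecot_statistic(v, 2), cot_statistic(v, 1), tolerance = 1e-12)
  }
})

test_that("scoring maximizes over groups with deterministic tie-breaks", {
  v <- rbind(ideal_dsg2 = c(4, 0, 4),   # silent in group 2
             flat = c(1, 1, 1),
             sg1 = c(9, 0.1, 0.2))
  colnames(v) <- paste0("s", 1:3)
  x <- expr_mat(v, space = "linear")
  d <- group_design(colnames(v), c("A", "B", "C"))
  tab <- score_signatures(x, d, kind = "dsg")
  r <- tab[tab$gene_id == "ideal_dsg2", ]
  expect_equal(r$best_group, "B")
  expect_equal(r$statistic, 1)
  flat <- tab[tab$gene_id == "flat", ]
  expect_equal(flat$best_group, "A")  # tie broken toward the first group
  expect_true(flat$tie)

  # global rescaling leaves every statistic unchanged
  tab10 <- score_signatures(expr_mat(10 * v, space = "linear"), d,
                            kind = "dsg")
  expect_equal(tab10$statistic, tab$statistic, tolerance = 1e-12)

  both <- score_signatures(x, d, kind = "both")
  expect_setequal(unique(both$kind), c("sg", "dsg"))
})

test_that("empirical-null p-values match brute-force tail counts", {
  stats_vec <- c(0.95, 0.2, 0.4, 0.6, 0.8, 0.1, 0.3, 0.5, 0.7, 0.9)
  tab <- tibble::tibble(gene_id = paste0("g", 1:10), kind = "dsg",
                        best_group = "A", statistic = stats_vec, tie = FALSE)
  class(tab) <- c("sig_score_table", class(tab))
  out <- suppressWarnings(empirical_null_pvalues(tab))
  brute <- vapply(stats_vec,
                  function(t) (1 + sum(stats_vec >= t)) / (1 + 10),
                  numeric(1))
  expect_equal(out$p_value, brute)
  expect_equal(out$p_value[1], 2 / 11)  # unique maximum
  expect_equal(out$q_value, p.adjust(out$p_value, "BH"))
  # p is monotone non-increasing in t
  expect_true(all(diff(out$p_value[order(out$statistic)]) <= 0))

  tied <- tab
  tied$statistic <- rep(0.5, 10)
  out2 <- suppressWarnings(empirical_null_pvalues(tied))
  expect_true(all(out2$p_value == 1))
})

test_that("the one-versus-rest Welch test agrees with stats::t.test", {
  v <- rbind(gA = c(1, 2, 3, 4, 5, 6),
             gB = c(10, 11, 12, 1.1, 0.9, 1.0))
  colnames(v) <- paste0("s", 1:6)
  x <- expr_mat(v, space = "log")
  d <- group_design(colnames(v), rep(c("k", "rest"), each = 3))
  res <- ovr_t_test(x, d, "k")
  for (g in rownames(v)) {
    tt <- t.test(v[g, 1:3], v[g, 4:6])
    row <- res[res$gene_id == g, ]
    expect_equal(row$statistic, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(row$df, unname(tt$parameter), tolerance = 1e-12)
    expect_equal(row$p_value, tt$p.value, tolerance = 1e-12)
  }
  # identical distributions give t near 0; separated constants a huge |t|
  set.seed(3)
  v2 <- rbind(null = rnorm(40, 5, 1),
              sep = c(rep(10, 20), rep(1, 20)) + rnorm(40, 0, 1e-3))
  colnames(v2) <- paste0("s", 1:40)
  x2 <- expr_mat(v2, space = "log")
  d2 <- group_design(colnames(v2), rep(c("k", "rest"), each = 20))
  res2 <- ovr_t_test(x2, d2, "k")
  expect_lt(abs(res2$statistic[res2$gene_id == "null"]), 2)
  expect_gt(res2$statistic[res2$gene_id == "sep"], 100)
  expect_equal(ovr_t_test(x2, d2, "k", direction = "down")$score,
               -res2$statistic)
  expect_error(ovr_t_test(x2, d2, "nope"), "unknown group")
})

test_that("one-versus-rest fold change follows the stated pseudocount policy", {
  v <- rbind(g1 = c(2, 2, 8, 8, 8, 8),
             g2 = c(3, 3, 3, 3, 3, 3),
             g3 = c(0, 0, 4, 4, 4, 4))
  colnames(v) <- paste0("s", 1:6)
  x <- expr_mat(v, space = "linear")
  d <- group_design(colnames(v), rep(c("k", "rest"), c(2, 4)))
  fc <- ovr_fold_change(x, d, "k")
  expect_equal(fc$fold_change[fc$gene_id == "g1"], 0.25)
  expect_equal(fc$fold_change[fc$gene_id == "g2"], 1)
  expect_equal(fc$fold_change[fc$gene_id == "g3"], 0)
  delta <- 0.5
  fcd <- ovr_fold_change(x, d, "k", pseudocount = delta)
  expect_equal(fcd$fold_change[fcd$gene_id == "g3"], delta / (4 + delta))

  z <- expr_mat(rbind(g1 = rep(0, 6), g2 = 1:6), space = "linear")
  dz <- group_design(colnames(z$values), rep(c("k", "rest"), each = 3))
  fz <- ovr_fold_change(z, dz, "k")
  expect_true(fz$undefined[fz$gene_id == "g1"])
  expect_true(is.na(fz$fold_change[fz$gene_id == "g1"]))
})
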