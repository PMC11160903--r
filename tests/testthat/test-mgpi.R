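test_that("normalization equalizes per-sample medians over complete genes", {
  set.seed(5)
  v <- matrix(rlnorm(40, 2, 0.5), 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  x <- expr_mat(v, space = "linear")
  xn <- normalize_complete(x)
  med <- apply(xn$values, 2, median)
  expect_equal(max(med) - min(med), 0, tolerance = 1e-12)

  # already balanced: factors all 1
  v2 <- v
  v2[] <- rep(apply(v, 1, median), 4)
  xb <- normalize_complete(expr_mat(v2, space = "linear"))
  expect_equal(unname(xb$meta$norm_factors), rep(1, 4))
  expect_equal(xb$values, v2)

  # doubling one sample of a balanced matrix is undone up to a common scale
  v3 <- v2
  v3[, 2] <- v3[, 2] * 2
  xn3 <- normalize_complete(expr_mat(v3, space = "linear"))
  expect_equal(apply(xn3$values, 2, median),
               apply(xn3$values, 2, median)[c(1, 1, 1, 1)],
               ignore_attr = TRUE)
  fac <- xn3$meta$norm_factors
  expect_equal(unname(fac[2] / fac[1]), 0.5, tolerance = 1e-12)

  v4 <- v
  v4[cbind(1:10, rep_len(1:4, 10))] <- NA
  expect_error(normalize_complete(expr_mat(v4, space = "linear")),
               "no gene is fully observed")
})

test_that("epsilon is the minimum observed log-space value", {
  v <- matrix(c(3, 5, 7, NA), 2, 2)
  x <- expr_mat(v, space = "log")
  expect_equal(estimate_epsilon(x), 3)
  expect_equal(estimate_epsilon(expr_mat(matrix(4.2, 1, 1), space = "log")),
               4.2)
  v2 <- rbind(v, c(10, 11))
  expect_equal(estimate_epsilon(expr_mat(v2, space = "log")), 3)
  allna <- expr_mat(matrix(NA_real_, 2, 2), space = "log")
  expect_error(estimate_epsilon(allna), "no observed cell")
  expect_error(estimate_epsilon(rand_expr(space = "linear")), "log space")
})

test_that("group statistics use observed cells and the n-1 denominator", {
  v <- rbind(g1 = c(2, 4, NA, 5, 5, 5),
             g2 = c(NA, NA, NA, 1, 2, 3))
  colnames(v) <- paste0("s", 1:6)
  x <- expr_mat(v, space = "log")
  d <- group_design(colnames(v), rep(c("A", "B"), each = 3))
  st <- group_stats(x, d)
  a1 <- st[st$gene_id == "g1" & st$group == "A", ]
  expect_equal(a1$mean, 3)
  expect_equal(a1$sd, sqrt(2))
  expect_equal(a1$n_obs, 2L)
  b1 <- st[st$gene_id == "g1" & st$group == "B", ]
  expect_equal(b1$sd, 0)
  a2 <- st[st$gene_id == "g2" & st$group == "A", ]
  expect_equal(a2$n_obs, 0L)
  expect_true(is.na(a2$mean) && is.na(a2$sd))
})

test_that("LLOD probability matches the normal left tail and its limits", {
  expect_equal(llod_probability(1, 2, epsilon = 1), 0.5)
  expect_equal(llod_probability(3, 1, epsilon = 1), pnorm(-2))
  expect_equal(llod_probability(-2, 1, epsilon = 1), pnorm(3))
  # degenerate point mass
  expect_equal(llod_probability(c(1, 2), c(0, 0), epsilon = 1.5), c(1, 0))
  # monotone non-increasing in the mean at fixed sd
  mu <- seq(-3, 3, length.out = 41)
  a <- llod_probability(mu, 0.7, epsilon = 0)
  expect_true(all(diff(a) < 0))
  expect_true(all(a >= 0 & a <= 1))
})

test_that("the imputation blend hits its exact limits", {
  fx <- blend_limit_fixture()
  res <- impute_mgpi(fx$x, fx$design)
  expect_identical(res$params$epsilon, 1)
  v <- res$completed$values
  expect_identical(v["g_alpha0", "s3"], 5)        # alpha = 0 -> group mean
  expect_identical(v["g_alpha1", "s3"], 0.5)      # alpha = 1 -> eps / 2
  expect_identical(v["g_half", "s2"], 0.75)       # alpha = 1/2 -> 0.75 eps
  # observed cells bit-identical
  obs <- !fx$x$missing
  expect_identical(v[obs], fx$x$values[obs])
})

test_that("imputed values are convex blends, monotone in the group mean", {
  x <- rand_expr(G = 30, S = 12, miss_frac = 0.25, seed = 11, space = "log")
  d <- halves_design(x)
  res <- impute_mgpi(x, d)
  eps <- res$params$epsilon
  di <- sigsimplex:::design_index(x, d)
  idx <- which(x$missing, arr.ind = TRUE)
  mu <- res$params$mean[cbind(idx[, 1], di$k[idx[, 2]])]
  mu[is.na(mu)] <- eps / 2   # silent groups impute to the LLOD value
  imp <- res$completed$values[idx]
  lo <- pmin(eps / 2, mu) - 1e-12
  hi <- pmax(eps / 2, mu) + 1e-12
  expect_true(all(imp >= lo & imp <= hi))

  # raising the group mean at fixed sd never lowers the imputand
  a <- llod_probability(c(2, 3, 4), 1, epsilon = 2)
  blend <- a * 1 + (1 - a) * c(2, 3, 4)
  expect_true(all(diff(blend) > 0))
})

test_that("imputation is group-local", {
  x <- rand_expr(G = 15, S = 10, miss_frac = 0.2, seed = 21, space = "log")
  # pin the global minimum (epsilon) to an observed cell of group A so that
  # edits confined to group B cannot move it
  x$values[1, 1] <- min(x$values, na.rm = TRUE) - 1
  x$missing[1, 1] <- FALSE
  d <- halves_design(x)
  res <- impute_mgpi(x, d)

  # permuting samples inside a group leaves all imputed values unchanged
  perm <- c(3, 1, 2, 5, 4, 6:10)
  xp <- expr_mat(x$values[, perm], space = "log")
  dp <- group_design(colnames(xp$values), d$group[perm])
  resp <- impute_mgpi(xp, dp)
  expect_equal(resp$completed$values[, colnames(x$values)],
               res$completed$values)

  # editing only group B's observed data leaves group A's imputands alone
  v2 <- x$values
  bcols <- 6:10
  bobs <- !x$missing[, bcols]
  v2[, bcols][bobs] <- v2[, bcols][bobs] + 0.37
  res2 <- impute_mgpi(expr_mat(v2, space = "log"), d)
  acols <- 1:5
  amiss <- x$missing[, acols]
  expect_identical(res2$completed$values[, acols][amiss],
                   res$completed$values[, acols][amiss])
})

test_that("linear-space input is transformed, imputed, and returned in linear space", {
  x <- rand_expr(G = 12, S = 8, miss_frac = 0.2, seed = 31, space = "linear")
  d <- halves_design(x)
  res <- impute_mgpi(x, d)
  expect_equal(res$completed$space, "linear")
  obs <- !x$missing
  expect_identical(res$completed$values[obs], x$values[obs])
  expect_true(all(res$completed$values >= 0))
  expect_false(anyNA(res$completed$values))
})

test_that("tidy and glance summarize an imputation result", {
  x <- rand_expr(G = 10, S = 6, miss_frac = 0.3, seed = 41, space = "log")
  res <- impute_mgpi(x, halves_design(x))
  td <- tidy(res)
  expect_equal(nrow(td), sum(x$missing))
  expect_false(anyNA(td$imputed))
  gl <- glance(res)
  expect_equal(gl$n_imputed, sum(x$missing))
  expect_equal(gl$method, "mgpi")
})
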