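# Shared fixture builders: everything is generated in code at test time.

# Random expression matrix with a given missing fraction (no gene fully
# missing), in the requested space.
rand_expr <- function(G = 20, S = 12, miss_frac = 0.15, seed = 1,
                      space = "linear") {
  set.seed(seed)
  v <- matrix(stats::rlnorm(G * S, 3, 1), G, S,
              dimnames = list(sprintf("g%02d", 1:G), sprintf("s%02d", 1:S)))
  if (space == "log") v <- log2(v + 1)
  mask <- matrix(stats::runif(G * S) < miss_frac, G, S)
  for (i in which(rowSums(!mask) == 0)) mask[i, 1] <- FALSE
  v[mask] <- NA
  expr_mat(v, space = space)
}

# Two-group design over the columns of an expr_mat (first half / second half).
halves_design <- function(x) {
  s <- colnames(x$values)
  group_design(s, rep(c("A", "B"), c(ceiling(length(s) / 2),
                                     floor(length(s) / 2))))
}

# Noiseless low-rank matrix with MCAR masking; returns truth for recovery
# checks.
lowrank_case <- function(G = 40, S = 25, rank = 1, miss_frac = 0.1,
                         seed = 42) {
  set.seed(seed)
  u <- matrix(stats::runif(G * rank, 0.5, 2), G, rank)
  w <- matrix(stats::runif(S * rank, 0.5, 2), rank, S)
  x0 <- u %*% w
  mask <- matrix(stats::runif(G * S) < miss_frac, G, S)
  for (i in which(rowSums(!mask) == 0)) mask[i, 1] <- FALSE
  xm <- x0
  xm[mask] <- NA
  list(x = expr_mat(xm, space = "linear"), truth = x0, mask = mask)
}

max_rel_err <- function(res, truth, mask) {
  max(abs(res$completed$values[mask] - truth[mask])) / max(abs(truth))
}

# The log-space fixture used for the exact blend-limit checks: epsilon = 1,
# one gene per limit case (see test-mgpi.R for the arithmetic).
blend_limit_fixture <- function() {
  v <- rbind(
    g_alpha0 = c(5, 5, NA, 6, 7),   # sd 0, mean > eps  -> alpha = 0
    g_alpha1 = c(1, 1, NA, 6, 7),   # sd 0, mean = eps  -> alpha = 1
    g_half = c(1, NA, NA, 2, 4)     # n = 1 at eps, pooled sd > 0 -> 0.5
  )
  colnames(v) <- paste0("s", 1:5)
  x <- expr_mat(v, space = "log")
  list(x = x, design = group_design(colnames(v),
                                    c("A", "A", "A", "B", "B")))
}

# Run the installed command-line script in a fresh R process.
run_cli <- function(args, dir = ".") {
  script <- system.file("cli", "sigsimplex-cli.R", package = "sigsimplex")
  stopifnot(nzchar(script))
  withr::with_dir(dir, {
    out <- suppressWarnings(system2(
      file.path(R.home("bin"), "Rscript"), c(shQuote(script), args),
      stdout = TRUE, stderr = TRUE,
      env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
    ))
    list(status = attr(out, "status") %||% 0L, output = out)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
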