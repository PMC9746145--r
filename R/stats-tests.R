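#' Statistical test result record
#'
#' Common container for every test in the battery. `p_adjusted` is filled by
#' [run_family()] (Holm) or directly by the family-wise procedures
#' ([dunnett_test()], [tukey_hsd()]).
#'
#' @param method One of `"t_one_sample"`, `"t_welch"`, `"dunnett"`,
#'   `"tukey_hsd"`, `"sign_exact"`.
#' @param comparison Human-readable label of what is being compared.
#' @param alternative `"two_sided"`, `"greater"` or `"less"`.
#' @param statistic Test statistic.
#' @param df Degrees of freedom (`NA` for exact tests).
#' @param p_raw Unadjusted p-value.
#' @param p_adjusted Family-adjusted p-value (`NA` until adjusted).
#' @param family_id Identifier of the multiple-testing family, if any.
#' @param n Total number of observations used.
#' @param seed RNG seed for Monte Carlo procedures (`NA` otherwise).
#' @param notes Free-text notes (degeneracies, draw counts, ...).
#' @return Object of class `test_result`.
#' @export
test_result <- function(method, comparison, alternative, statistic, df = NA_real_,
                        p_raw, p_adjusted = NA_real_, family_id = NA_character_,
                        n = NA_integer_, seed = NA_integer_, notes = "") {
  if (is.finite(p_raw) && (p_raw < 0 || p_raw > 1))
    stop("p_raw outside [0, 1]")
  structure(
    list(method = method, comparison = comparison, alternative = alternative,
         statistic = as.numeric(statistic), df = as.numeric(df),
         p_raw = as.numeric(p_raw), p_adjusted = as.numeric(p_adjusted),
         family_id = as.character(family_id), n = as.integer(n),
         seed = as.integer(seed), notes = as.character(notes)),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s [%s] %s: stat=%.4g df=%.3g p=%.4g adj=%.4g\n",
              x$method, x$alternative, x$comparison, x$statistic, x$df,
              x$p_raw, x$p_adjusted))
  invisible(x)
}

#' Bind test results into a data frame
#'
#' @param tests A list of [test_result()] objects.
#' @return One data frame row per test, in input order.
#' @export
results_table <- function(tests) {
  stopifnot(all(vapply(tests, inherits, logical(1), "test_result")))
  out <- do.call(rbind, lapply(tests, function(t)
    data.frame(family_id = t$family_id, method = t$method,
               comparison = t$comparison, alternative = t$alternative,
               statistic = t$statistic, df = t$df, p_raw = t$p_raw,
               p_adjusted = t$p_adjusted, n = t$n, seed = t$seed,
               notes = t$notes, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

.p_from_t <- function(t, df, alternative) {
  switch(alternative,
         two_sided = 2 * pt(abs(t), df, lower.tail = FALSE),
         greater   = pt(t, df, lower.tail = FALSE),
         less      = pt(t, df),
         stop("unknown alternative: ", alternative))
}

#' One-sample Student t test
#'
#' @param values Numeric sample (n >= 2, positive variance).
#' @param mu0 Null value (default 0).
#' @param alternative `"two_sided"` (default), `"greater"` or `"less"`.
#' @param comparison Label stored on the result.
#' @return A [test_result()].
#' @export
t_one_sample <- function(values, mu0 = 0,
                         alternative = c("two_sided", "greater", "less"),
                         comparison = "one-sample t") {
  alternative <- match.arg(alternative)
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 2L) stop("one-sample t requires n >= 2")
  s <- sd(x)
  if (s == 0) stop("degenerate sample: zero variance")
  stat <- (mean(x) - mu0) / (s / sqrt(n))
  test_result("t_one_sample", comparison, alternative, stat, df = n - 1,
              p_raw = .p_from_t(stat, n - 1, alternative), n = n)
}

#' Welch two-sample t test
#'
#' Unequal-variance two-sample t with Welch-Satterthwaite degrees of freedom.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @param alternative `"two_sided"` (default), `"greater"` or `"less"`;
#'   one-sided alternatives refer to `mean(x) - mean(y)`.
#' @param comparison Label stored on the result.
#' @return A [test_result()].
#' @export
t_welch <- function(x, y, alternative = c("two_sided", "greater", "less"),
                    comparison = "Welch t") {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("Welch t requires n >= 2 per sample")
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) stop("degenerate samples: zero variance in both groups")
  df <- se2^2 / (vx^2 / (nx^2 * (nx - 1)) + vy^2 / (ny^2 * (ny - 1)))
  stat <- (mean(x) - mean(y)) / sqrt(se2)
  test_result("t_welch", comparison, alternative, stat, df = df,
              p_raw = .p_from_t(stat, df, alternative), n = nx + ny)
}

#' Holm step-down multiple-testing adjustment
#'
#' Sorts the m raw p-values ascending, multiplies the k-th smallest by
#' `m - k + 1`, enforces monotonicity with a cumulative maximum, caps at 1,
#' and maps the adjusted values back to the input order. `NA` entries are
#' left `NA` and do not count towards m.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
holm_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) return(numeric(0))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  m <- sum(ok)
  if (m > 0L) {
    pv <- p[ok]
    o <- order(pv)
    adj <- pmin(1, (m - seq_len(m) + 1) * pv[o])
    adj <- cummax(adj)
    back <- numeric(m)
    back[o] <- adj
    out[ok] <- back
  }
  out
}

#' Exact binomial sign test
#'
#' Tail probability of `k` successes in `n` fair-coin trials. One-tailed
#' `"greater"` sums the upper tail at and beyond `k`; `"less"` the lower
#' tail; `"two_sided"` doubles the smaller tail and caps at 1 (no continuity
#' correction).
#'
#' @param successes Number of successes `k` (0 <= k <= n).
#' @param trials Number of trials `n` (>= 1).
#' @param alternative `"greater"` (default), `"less"` or `"two_sided"`.
#' @param comparison Label stored on the result.
#' @return A [test_result()] with `statistic = k`.
#' @export
sign_test_exact <- function(successes, trials,
                            alternative = c("greater", "less", "two_sided"),
                            comparison = "exact sign test") {
  alternative <- match.arg(alternative)
  k <- successes; n <- trials
  stopifnot(n >= 1, k >= 0, k <= n, k == floor(k), n == floor(n))
  p_greater <- sum(dbinom(k:n, n, 0.5))
  p_less <- sum(dbinom(0:k, n, 0.5))
  p <- switch(alternative,
              greater = p_greater,
              less = p_less,
              two_sided = min(1, 2 * min(p_greater, p_less)))
  test_result("sign_exact", comparison, alternative, statistic = k,
              p_raw = min(1, p), n = as.integer(n),
              notes = sprintf("k=%d of n=%d under p=1/2", k, n))
}

#' Dunnett many-to-one comparisons
#'
#' Compares each treatment group against a shared control using pooled-
#' variance t statistics, with family-wise adjusted p-values taken from the
#' joint null distribution of the maximum (absolute) statistic over the
#' correlated t variates. The correlation has the one-factor structure
#' `rho_ij = lambda_i * lambda_j`, `lambda_i = sqrt(n_i / (n_i + n_0))`
#' (1/2 under balance), which is exploited to sample the multivariate t by
#' seeded Monte Carlo.
#'
#' @param groups Named list of numeric treatment samples (each n >= 2).
#' @param control Numeric control sample (n >= 2).
#' @param alternative `"two_sided"` (default), `"greater"` or `"less"`.
#' @param mc_draws Monte Carlo draws for the max-statistic null
#'   (default 1e5).
#' @param seed RNG seed for the draws.
#' @return List of [test_result()], one per treatment group, with `p_raw`
#'   the unadjusted pooled-t p and `p_adjusted` the family-wise value
#'   (clamped to be no smaller than `p_raw`).
#' @export
dunnett_test <- function(groups, control,
                         alternative = c("two_sided", "greater", "less"),
                         mc_draws = 1e5, seed = 1L) {
  alternative <- match.arg(alternative)
  stopifnot(is.list(groups), length(groups) >= 1L)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  sizes <- vapply(groups, length, integer(1))
  n0 <- length(control)
  if (any(sizes < 2L) || n0 < 2L)
    stop("every group (and the control) needs >= 2 observations")
  k <- length(groups)
  means <- vapply(groups, mean, numeric(1))
  m0 <- mean(control)
  ss <- sum(vapply(groups, function(g) (length(g) - 1) * var(g), numeric(1))) +
    (n0 - 1) * var(control)
  df <- sum(sizes) + n0 - (k + 1)
  s2 <- ss / df
  if (!is.finite(s2) || s2 <= 0) stop("zero pooled variance")
  stat <- (means - m0) / sqrt(s2 * (1 / sizes + 1 / n0))
  p_raw <- .p_from_t(stat, df, alternative)

  lam <- sqrt(sizes / (sizes + n0))
  extreme <- with_seed(seed, {
    z0 <- rnorm(mc_draws)
    z <- matrix(rnorm(mc_draws * k), mc_draws, k)
    z <- sweep(z, 2, sqrt(1 - lam^2), `*`) + outer(z0, lam)
    s <- sqrt(rchisq(mc_draws, df) / df)
    tt <- z / s
    cols <- lapply(seq_len(k), function(j)
      if (alternative == "two_sided") abs(tt[, j]) else tt[, j])
    if (alternative == "less") do.call(pmin, cols) else do.call(pmax, cols)
  })
  p_adj <- vapply(seq_len(k), function(i) {
    switch(alternative,
           two_sided = mean(extreme >= abs(stat[i])),
           greater   = mean(extreme >= stat[i]),
           less      = mean(extreme <= stat[i]))
  }, numeric(1))
  p_adj <- pmax(p_adj, p_raw)

  lapply(seq_len(k), function(i)
    test_result("dunnett", paste(names(groups)[i], "- control"), alternative,
                stat[i], df = df, p_raw = p_raw[i], p_adjusted = p_adj[i],
                family_id = "dunnett", n = sizes[i] + n0, seed = seed,
                notes = sprintf("mc_draws=%g, control n=%d", mc_draws, n0)))
}

#' Tukey HSD all-pairs comparisons
#'
#' Studentized-range statistic `q = |mean_a - mean_b| /
#' sqrt((s2p/2) (1/n_a + 1/n_b))` (Tukey-Kramer under imbalance) on the
#' variance pooled across all groups; the family-wise p-value comes from the
#' studentized range distribution with k groups and the pooled degrees of
#' freedom. `p_raw` is the unadjusted pooled two-sample t p-value.
#'
#' @param groups Named list of >= 2 numeric samples (each n >= 2).
#' @return List of [test_result()], one per unordered pair.
#' @export
tukey_hsd <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2L)) stop("every group needs >= 2 observations")
  k <- length(groups)
  means <- vapply(groups, mean, numeric(1))
  df <- sum(sizes) - k
  s2 <- sum(vapply(groups, function(g) (length(g) - 1) * var(g),
                   numeric(1))) / df
  if (!is.finite(s2) || s2 <= 0) stop("zero pooled variance")
  pairs <- utils::combn(k, 2)
  lapply(seq_len(ncol(pairs)), function(c) {
    a <- pairs[1, c]; b <- pairs[2, c]
    diff <- means[a] - means[b]
    tstat <- diff / sqrt(s2 * (1 / sizes[a] + 1 / sizes[b]))
    q <- abs(diff) / sqrt((s2 / 2) * (1 / sizes[a] + 1 / sizes[b]))
    p_raw <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
    p_adj <- max(ptukey(q, k, df, lower.tail = FALSE), p_raw)
    test_result("tukey_hsd",
                paste(names(groups)[a], "-", names(groups)[b]),
                "two_sided", tstat, df = df, p_raw = p_raw,
                p_adjusted = p_adj, family_id = "tukey",
                n = sizes[a] + sizes[b],
                notes = sprintf("q=%.6g, k=%d", q, k))
  })
}

#' Run a declared family of tests with Holm adjustment
#'
#' Applies [holm_adjust()] across the raw p-values of an explicit family of
#' already-computed tests and stamps each member with the family id.
#'
#' @param tests List of [test_result()] objects.
#' @param family_id Family identifier attached to every member.
#' @return The list with `p_adjusted` and `family_id` filled in.
#' @export
run_family <- function(tests, family_id) {
  stopifnot(all(vapply(tests, inherits, logical(1), "test_result")))
  if (length(tests) == 0L) return(tests)
  p <- vapply(tests, function(t) t$p_raw, numeric(1))
  adj <- holm_adjust(p)
  for (i in seq_along(tests)) {
    tests[[i]]$p_adjusted <- adj[i]
    tests[[i]]$family_id <- family_id
  }
  tests
}
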