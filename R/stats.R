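#' Normality gate over experimental groups
#'
#' Routes the downstream group comparison: every group is assessed with the
#' Shapiro-Wilk test, and the family is treated as normal only when all
#' groups have `p >= alpha`. Groups with fewer than 3 observations (or
#' constant values, where the test is undefined) force the non-normal route
#' with a warning.
#'
#' @param groups Named list of numeric vectors, one per group.
#' @param alpha Shapiro-Wilk significance cut (default 0.05).
#' @return A list: `normal` (logical), `shapiro_p` (named numeric, `NA`
#'   where the test is undefined).
#' @export
normality_gate <- function(groups, alpha = 0.05) {
  p <- vapply(groups, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 3L || length(unique(v)) == 1L) return(NA_real_)
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  if (anyNA(p)) {
    warning("group(s) with n < 3 or constant values: ",
            "treated as non-normal", call. = FALSE)
  }
  list(normal = !anyNA(p) && all(p >= alpha), shapiro_p = p)
}

#' Conover-Iman pairwise rank test
#'
#' Pairwise multiple comparisons on joint ranks: observations of all groups
#' are ranked together (midranks for ties); the statistic for a pair (i, j)
#' is `t = (Rbar_i - Rbar_j) / sqrt(S2 * (N - 1 - H) / (N - k) *
#' (1/n_i + 1/n_j))`, where `S2 = (sum(R^2) - N (N+1)^2 / 4) / (N - 1)` and
#' `H` is the tie-corrected Kruskal-Wallis statistic `(sum_i n_i Rbar_i^2 -
#' N (N+1)^2 / 4) / S2`; `t` is referred to a Student t distribution with
#' `N - k` degrees of freedom, two-sided. Being rank-based, p-values are
#' invariant under strictly monotone transforms of the data.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return Data.frame with one row per unordered pair: `group_a`, `group_b`,
#'   `statistic`, `df`, `p_value`.
#' @export
conover_test <- function(groups) {
  groups <- lapply(groups, function(v) v[!is.na(v)])
  k <- length(groups)
  if (k < 2L) stop("need at least two groups", call. = FALSE)
  n_i <- lengths(groups)
  if (any(n_i < 2L)) stop("each group needs at least two values", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), n_i)
  N <- length(x)
  r <- rank(x)                                     # midranks for ties
  rbar <- tapply(r, g, mean)[names(groups)]
  s2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  if (s2 <= 0) stop("all values identical: rank test degenerate", call. = FALSE)
  h <- (sum(n_i * rbar^2) - N * (N + 1)^2 / 4) / s2 # tie-corrected KW
  dfree <- N - k
  pair_idx <- utils::combn(k, 2)
  scale2 <- s2 * (N - 1 - h) / (N - k)
  scale2 <- max(scale2, .Machine$double.eps)       # guard: H near its maximum
  out <- data.frame(
    group_a = names(groups)[pair_idx[1, ]],
    group_b = names(groups)[pair_idx[2, ]],
    statistic = NA_real_, df = dfree, p_value = NA_real_,
    stringsAsFactors = FALSE)
  for (m in seq_len(ncol(pair_idx))) {
    i <- pair_idx[1, m]; j <- pair_idx[2, m]
    tt <- (rbar[i] - rbar[j]) / sqrt(scale2 * (1 / n_i[i] + 1 / n_i[j]))
    out$statistic[m] <- tt
    out$p_value[m] <- 2 * stats::pt(-abs(tt), dfree)
  }
  out
}

#' Normality-gated pairwise group comparison with Bonferroni correction
#'
#' For one metric at one timepoint: applies [normality_gate()] to all
#' groups, then tests every unordered pair with Welch's unequal-variance
#' t-test (normal route) or the Conover-Iman rank test (non-normal route).
#' Raw p-values are Bonferroni-adjusted over the family of all
#' `choose(k, 2)` pairs: `p_adj = min(1, m * p_raw)`.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each with >= 2
#'   observations).
#' @param alpha Significance level used by the normality gate (and reported
#'   downstream); default 0.05.
#' @return Data.frame with one row per pair: `group_a`, `group_b`,
#'   `test_used` (`"welch"` or `"conover"`), `statistic`, `p_raw`,
#'   `p_adjusted`, `n_a`, `n_b`, `normality_p_a`, `normality_p_b`.
#' @examples
#' g <- list(CTRL = rnorm(6), PBS = rnorm(6), DCZ = rnorm(6, 2))
#' pairwise_compare(g)
#' @export
pairwise_compare <- function(groups, alpha = 0.05) {
  groups <- lapply(groups, function(v) v[!is.na(v)])
  k <- length(groups)
  if (k < 2L) stop("need at least two groups", call. = FALSE)
  if (any(lengths(groups) < 2L)) {
    stop("each group needs at least two observations", call. = FALSE)
  }
  gate <- suppressWarnings(normality_gate(groups, alpha = alpha))
  m_family <- choose(k, 2)
  if (gate$normal) {
    pair_idx <- utils::combn(k, 2)
    rows <- lapply(seq_len(ncol(pair_idx)), function(m) {
      i <- pair_idx[1, m]; j <- pair_idx[2, m]
      a <- groups[[i]]; b <- groups[[j]]
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        # Welch statistic undefined for two constant samples
        return(data.frame(group_a = names(groups)[i],
                          group_b = names(groups)[j], test_used = "welch",
                          statistic = NA_real_, p_raw = NA_real_,
                          stringsAsFactors = FALSE))
      }
      tt <- stats::t.test(a, b, var.equal = FALSE)
      data.frame(group_a = names(groups)[i], group_b = names(groups)[j],
                 test_used = "welch", statistic = unname(tt$statistic),
                 p_raw = tt$p.value, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  } else {
    co <- conover_test(groups)
    out <- data.frame(group_a = co$group_a, group_b = co$group_b,
                      test_used = "conover", statistic = co$statistic,
                      p_raw = co$p_value, stringsAsFactors = FALSE)
  }
  out$p_adjusted <- pmin(1, out$p_raw * m_family)
  out$n_a <- lengths(groups)[out$group_a]
  out$n_b <- lengths(groups)[out$group_b]
  out$normality_p_a <- gate$shapiro_p[out$group_a]
  out$normality_p_b <- gate$shapiro_p[out$group_b]
  rownames(out) <- NULL
  out
}

#' Family-wise type-I error of the gated comparison under the null
#'
#' Simulates `reps` families of identically distributed groups, runs
#' [pairwise_compare()] on each, and returns the fraction of families with
#' at least one Bonferroni-adjusted rejection — the empirical family-wise
#' error rate of the full gate-plus-test-plus-correction procedure.
#'
#' @param n_groups Number of groups per family (default 3).
#' @param n_per_group Observations per group (default 6 networks).
#' @param reps Number of simulated families (>= 100).
#' @param alpha Nominal level (default 0.05).
#' @param rdist Null sampler, `function(n)` (default standard normal).
#' @param seed Integer seed.
#' @return A list: `fwer`, `reps`, `alpha`.
#' @export
type_i_calibration <- function(n_groups = 3, n_per_group = 6, reps = 2000,
                               alpha = 0.05, rdist = stats::rnorm, seed = 1L) {
  stopifnot(reps >= 100)
  nm <- paste0("G", seq_len(n_groups))
  rejected <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      groups <- stats::setNames(
        lapply(seq_len(n_groups), function(i) rdist(n_per_group)), nm)
      res <- pairwise_compare(groups, alpha = alpha)
      any(res$p_adjusted < alpha, na.rm = TRUE)
    }, logical(1))
  })
  list(fwer = mean(rejected), reps = reps, alpha = alpha)
}
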