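# Group comparison statistics: Lilliefors normality screening with a
# Monte-Carlo null, t / Mann-Whitney testing with effect sizes, Pearson /
# Spearman correlation, and the Dubey-Armitage-Parmar (DAP) multiplicity
# adjustment for correlated muscle-specific endpoints.

# cached Monte-Carlo null distributions of the Lilliefors statistic, per
# (sample size, n_sim, seed)
.lilliefors_cache <- new.env(parent = emptyenv())

lilliefors_statistic <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  p <- pnorm(z)
  i <- seq_len(n)
  max(pmax(i / n - p, p - (i - 1) / n))
}

#' Lilliefors test of normality with a simulated null
#'
#' Kolmogorov-Smirnov statistic against the normal distribution with
#' sample-estimated mean and SD; the p-value comes from a seeded Monte-Carlo
#' simulation of the null (standard-normal samples of the same size), not
#' from table interpolation. Null distributions are cached per sample size.
#'
#' @param x numeric sample, n >= 4.
#' @param n_sim Monte-Carlo replicates (>= 1e4 by default).
#' @param seed seed for the null simulation; fixed by default so the test
#'   is deterministic.
#' @return List with `statistic`, `p_value`, `n`, `degenerate` (constant
#'   sample, reported as `p_value = 0`).
#' @export
lilliefors_test <- function(x, n_sim = 10000, seed = 190523) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) abort("Lilliefors test needs n >= 4")
  if (sd(x) == 0) {
    return(list(statistic = NA_real_, p_value = 0, n = n, degenerate = TRUE))
  }
  d <- lilliefors_statistic(x)
  key <- sprintf("n%d_s%d_seed%d", n, n_sim, seed)
  null <- .lilliefors_cache[[key]]
  if (is.null(null)) {
    null <- with_local_seed(seed, {
      vapply(seq_len(n_sim), function(i) lilliefors_statistic(rnorm(n)), numeric(1))
    })
    .lilliefors_cache[[key]] <- null
  }
  p <- (sum(null >= d) + 1) / (n_sim + 1)
  list(statistic = d, p_value = p, n = n, degenerate = FALSE)
}

# tie-corrected normal approximation of the Mann-Whitney U statistic
mann_whitney_z <- function(x, y, continuity = TRUE) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  nt <- n1 + n2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 * ((nt + 1) - sum(ties^3 - ties) / (nt * (nt - 1)))
  if (sig2 <= 0) return(list(u = u, z = 0))
  cc <- if (continuity) sign(u - mu) * 0.5 else 0
  list(u = u, z = (u - mu - cc) / sqrt(sig2))
}

#' Compare one endpoint between two groups
#'
#' Both samples are screened with the Lilliefors test at `alpha`; if both
#' look normal an unpaired two-sample t-test (pooled variance) is used,
#' otherwise a Mann-Whitney U test. Effect size: `r_eff = sqrt(t^2 /
#' (t^2 + df))` for the t branch, `|z| / sqrt(N)` (tie-corrected normal
#' approximation) for the U branch. For the U branch the p-value is exact
#' (enumeration) when both groups have n <= 8 and there are no ties, and
#' the normal approximation otherwise.
#'
#' @param x,y numeric samples for the two groups (>= 2 each after removing
#'   non-finite values; >= 4 each for the normality screen, below which the
#'   U branch is used).
#' @param alpha significance level of the normality screen.
#' @return One-row tibble: `test_used`, `p_raw`, `r_eff`, `n_x`, `n_y`,
#'   `normal_x`, `normal_y`.
#' @export
compare_groups <- function(x, y, alpha = 0.05) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) {
    return(tibble::tibble(test_used = NA_character_, p_raw = NA_real_,
                          r_eff = NA_real_, n_x = length(x), n_y = length(y),
                          normal_x = NA, normal_y = NA))
  }
  can_screen <- length(x) >= 4 && length(y) >= 4 && sd(x) > 0 && sd(y) > 0
  norm_x <- if (can_screen) lilliefors_test(x)$p_value > alpha else FALSE
  norm_y <- if (can_screen) lilliefors_test(y)$p_value > alpha else FALSE
  if (norm_x && norm_y) {
    tt <- t.test(x, y, var.equal = TRUE)
    tval <- unname(tt$statistic)
    df <- unname(tt$parameter)
    tibble::tibble(test_used = "t", p_raw = tt$p.value,
                   r_eff = sqrt(tval^2 / (tval^2 + df)),
                   n_x = length(x), n_y = length(y),
                   normal_x = norm_x, normal_y = norm_y)
  } else {
    mw <- mann_whitney_z(x, y)
    has_ties <- anyDuplicated(c(x, y)) > 0
    p <- if (max(length(x), length(y)) <= 8 && !has_ties) {
      wilcox.test(x, y, exact = TRUE)$p.value
    } else {
      2 * pnorm(-abs(mw$z))
    }
    tibble::tibble(test_used = "mann_whitney", p_raw = min(p, 1),
                   r_eff = min(abs(mw$z) / sqrt(length(x) + length(y)), 1),
                   n_x = length(x), n_y = length(y),
                   normal_x = norm_x, normal_y = norm_y)
  }
}

#' Dubey-Armitage-Parmar multiplicity adjustment
#'
#' Adjusts per-endpoint p-values for `m` correlated endpoints: for endpoint
#' `j`, with mean correlation `rbar_j` of that endpoint with the other
#' `m - 1`, the effective number of tests is `g_j = m^(1 - rbar_j)` and
#' `p_adj = 1 - (1 - p_j)^g_j`. With `rbar = 1` the p-values are unchanged;
#' with `rbar = 0` the adjustment equals the Sidak-style bound
#' `1 - (1 - p)^m` (the conservative independent-endpoint limit). Negative
#' mean correlations are clamped to 0.
#'
#' @param p raw p-values, one per endpoint.
#' @param values optional wide matrix/data frame (subjects x endpoints, in
#'   the same endpoint order) from which `rbar` is computed as the mean
#'   pairwise-complete Pearson correlation of each endpoint with the others.
#' @param rbar mean correlations, one per endpoint (or scalar); overrides
#'   `values`.
#' @return Adjusted p-values (never below the raw ones).
#' @export
dap_adjust <- function(p, values = NULL, rbar = NULL) {
  m <- length(p)
  if (m <= 1) return(p)
  if (is.null(rbar)) {
    if (is.null(values)) abort("supply either endpoint values or rbar")
    values <- as.matrix(values)
    if (ncol(values) != m) abort("values must have one column per endpoint")
    cm <- suppressWarnings(cor(values, use = "pairwise.complete.obs"))
    diag(cm) <- NA
    rbar <- rowMeans(cm, na.rm = TRUE)
    rbar[is.nan(rbar)] <- 0
  }
  rbar <- rep_len(rbar, m)
  rbar <- pmin(pmax(rbar, 0), 1)
  g <- m^(1 - rbar)
  pmin(1, 1 - (1 - p)^g)
}

#' Compare all endpoints of one parameter between two groups
#'
#' Tidy interface to [compare_groups()] plus [dap_adjust()]: takes a long
#' table of per-subject per-region values, tests each region between the
#' two group labels, and adjusts the p-values for the intermuscular
#' correlation structure computed on the pooled subjects-by-regions matrix.
#'
#' @param data long tibble with subject, region, value and group columns.
#' @param value,region,subject,group the respective columns.
#' @param alpha normality-screen level passed to [compare_groups()].
#' @return Tibble with one row per region: `region`, `test_used`, `p_raw`,
#'   `p_adjusted`, `r_eff`, `rbar`, `n_x`, `n_y`.
#' @export
compare_endpoints <- function(data, value, region, subject, group,
                              alpha = 0.05) {
  df <- dplyr::select(data, subject = {{ subject }}, region = {{ region }},
                      value = {{ value }}, group = {{ group }})
  groups <- sort(unique(df$group))
  if (length(groups) != 2) abort("compare_endpoints needs exactly 2 groups")
  regions <- unique(df$region)
  res <- purrr::map_dfr(regions, function(rg) {
    d <- df[df$region == rg, ]
    x <- d$value[d$group == groups[1]]
    y <- d$value[d$group == groups[2]]
    dplyr::mutate(compare_groups(x, y, alpha = alpha), region = rg,
                  .before = 1)
  })
  wide <- tidyr::pivot_wider(df, id_cols = "subject", names_from = "region",
                             values_from = "value")
  mat <- as.matrix(wide[, regions, drop = FALSE])
  keep <- !is.na(res$p_raw)
  res$p_adjusted <- NA_real_
  res$rbar <- NA_real_
  if (any(keep)) {
    cm <- suppressWarnings(cor(mat[, keep, drop = FALSE],
                               use = "pairwise.complete.obs"))
    diag(cm) <- NA
    rbar <- rowMeans(cm, na.rm = TRUE)
    rbar[is.nan(rbar)] <- 0
    res$rbar[keep] <- pmin(pmax(rbar, 0), 1)
    res$p_adjusted[keep] <- dap_adjust(res$p_raw[keep], rbar = res$rbar[keep])
  }
  res
}

#' Correlation with automatic method selection
#'
#' Pearson correlation if both variables pass the Lilliefors screen at
#' `alpha`, Spearman otherwise; pairs with missing values are removed
#' pairwise (>= 4 pairs required).
#'
#' @param x,y numeric vectors.
#' @param alpha normality-screen level.
#' @return One-row tibble: `r`, `p_value`, `method`, `n`.
#' @export
correlate <- function(x, y, alpha = 0.05) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) abort("correlation needs >= 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble::tibble(r = NA_real_, p_value = NA_real_,
                          method = "undefined_zero_variance", n = length(x)))
  }
  use_pearson <- lilliefors_test(x)$p_value > alpha &&
    lilliefors_test(y)$p_value > alpha
  method <- if (use_pearson) "pearson" else "spearman"
  ct <- suppressWarnings(cor.test(x, y, method = method))
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 method = method, n = length(x))
}
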