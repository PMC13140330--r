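test_that("Lilliefors Monte-Carlo test behaves under null and alternative", {
  set.seed(61)
  x <- rnorm(200)
  lt <- lilliefors_test(x)
  expect_gt(lt$p_value, 0.05)

  # power against an exponential alternative
  set.seed(62)
  rej <- mean(vapply(1:500, function(i) {
    lilliefors_test(stats::rexp(50), n_sim = 2000)$p_value < 0.05
  }, logical(1)))
  expect_gt(rej, 0.9)

  # Monte-Carlo alpha = 0.05 critical value at n = 20, stable across seeds
  crit <- vapply(c(1, 2, 3), function(sd) {
    null <- xmuscle:::with_local_seed(sd, vapply(1:10000, function(i)
      xmuscle:::lilliefors_statistic(rnorm(20)), numeric(1)))
    unname(stats::quantile(null, 0.95))
  }, numeric(1))
  expect_lt(diff(range(crit)) / mean(crit), 0.02)

  # cross-check against the reference implementation on a fixed sample
  skip_if_not_installed("nortest")
  set.seed(63)
  y <- rnorm(40) + c(rep(0, 30), rep(2.5, 10))
  expect_equal(lilliefors_test(y, n_sim = 40000)$p_value,
               nortest::lillie.test(y)$p.value, tolerance = 0.1)

  expect_equal(lilliefors_test(rep(3, 10))$p_value, 0)
  expect_error(lilliefors_test(c(1, 2, 3)), "n >= 4")
})

test_that("group comparison selects the right branch and matches a hand t oracle", {
  set.seed(71)
  x <- rnorm(20, 5, 1)
  same <- compare_groups(x, x)
  expect_gt(same$p_raw, 0.99)
  expect_lt(same$r_eff, 0.05)

  # textbook pooled two-sample t on a fixed 5+5 input
  a <- c(4.1, 5.2, 3.8, 4.9, 5.5)
  b <- c(6.3, 7.1, 6.8, 5.9, 7.4)
  sp2 <- (4 * var(a) + 4 * var(b)) / 8
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = 8)
  res <- compare_groups(a, b)
  expect_equal(res$test_used, "t")
  expect_equal(res$p_raw, p_hand, tolerance = 1e-12)
  expect_equal(res$r_eff, sqrt(t_hand^2 / (t_hand^2 + 8)), tolerance = 1e-12)

  # clearly non-normal data routes to Mann-Whitney
  set.seed(72)
  e1 <- stats::rexp(30); e2 <- stats::rexp(30) + 2
  resmw <- compare_groups(e1, e2)
  expect_equal(resmw$test_used, "mann_whitney")
  expect_lt(resmw$p_raw, 0.001)

  # degenerate group sizes are reported as excluded endpoints
  expect_true(is.na(compare_groups(c(1, 2), numeric(0))$p_raw))
})

test_that("group comparison has power at the study's sample sizes", {
  set.seed(73)
  res <- purrr::map_dfr(1:200, function(i) {
    x <- rnorm(9, 0, 1)
    y <- rnorm(10, 3, 1)  # 3 SD shift
    compare_groups(x, y)
  })
  expect_gte(mean(res$p_raw < 0.001), 0.95)
  expect_gt(median(res$r_eff), 0.8)
})

test_that("DAP adjustment limits, hand value, and monotonicity", {
  p <- c(0.01, 0.04, 0.2)
  # complete correlation: unchanged
  expect_equal(dap_adjust(p, rbar = 1), p, tolerance = 1e-12)
  # zero correlation: the conservative independent-endpoint bound
  p7 <- rep(0.01, 7)
  expect_equal(dap_adjust(p7, rbar = 0), rep(1 - (1 - 0.01)^7, 7), tolerance = 1e-12)
  # hand evaluation at p = 0.01, m = 7, rbar = 0.5
  g <- 7^0.5
  expect_equal(g, 2.6458, tolerance = 1e-4)
  expect_equal(dap_adjust(rep(0.01, 7), rbar = 0.5)[1], 1 - 0.99^g, tolerance = 1e-12)
  expect_equal(dap_adjust(rep(0.01, 7), rbar = 0.5)[1], 0.0262, tolerance = 5e-3)

  # single endpoint passes through
  expect_equal(dap_adjust(0.03), 0.03)
  # adjusted never below raw; monotone in p and in (1 - rbar)
  set.seed(81)
  for (i in 1:20) {
    pr <- sort(runif(5))
    rb <- runif(1)
    adj <- dap_adjust(pr, rbar = rb)
    expect_true(all(adj >= pr - 1e-12))
    expect_true(all(diff(adj) >= -1e-12))
    expect_true(all(dap_adjust(pr, rbar = rb * 0.5) >= adj - 1e-12))
  }
  # negative mean correlations are clamped to zero
  expect_equal(dap_adjust(p, rbar = -0.4), dap_adjust(p, rbar = 0))
  # rbar computed from perfectly correlated columns reproduces the r=1 limit
  v <- matrix(rnorm(30), 10, 3)
  v <- v[, c(1, 1, 1)] # identical endpoints
  expect_equal(dap_adjust(p, values = v), p, tolerance = 1e-12)
})

test_that("family-wise error after DAP stays controlled under the global null", {
  m <- 7
  sim_fwer <- function(w, n_sim) {
    vapply(seq_len(n_sim), function(i) {
      mk <- function(n) {
        shared <- rnorm(n)
        sapply(seq_len(m), function(j) w * shared + sqrt(1 - w^2) * rnorm(n))
      }
      x <- mk(10); y <- mk(9)
      praw <- vapply(seq_len(m), function(j) compare_groups(x[, j], y[, j])$p_raw,
                     numeric(1))
      padj <- dap_adjust(praw, values = rbind(x, y))
      any(padj < 0.05)
    }, logical(1))
  }
  # weakly correlated endpoints: the adjustment approaches the independent
  # 1-(1-p)^m bound and controls the family-wise rate
  set.seed(91)
  expect_lte(mean(sim_fwer(0.3, 1000)), 0.07)
  # at intermediate correlation the procedure is known to be mildly
  # anti-conservative; the inflation stays bounded
  set.seed(92)
  expect_lte(mean(sim_fwer(0.7, 400)), 0.12)
})

test_that("correlation picks Pearson/Spearman and is monotone-invariant", {
  set.seed(101)
  x <- rnorm(40)
  expect_equal(correlate(x, x)$r, 1)
  expect_equal(correlate(x, -x)$r, -1)
  expect_equal(correlate(x, x)$method, "pearson")

  y <- stats::rexp(40)
  r0 <- correlate(x, y)
  expect_equal(r0$method, "spearman")
  for (f in list(function(z) z^3, function(z) exp(z), function(z) z + z^5)) {
    rf <- correlate(x, f(y))
    expect_equal(rf$method, "spearman")
    expect_equal(rf$r, r0$r, tolerance = 1e-12)
  }
  z <- rep(1, 10)
  expect_equal(correlate(x[1:10], z)$method, "undefined_zero_variance")
  expect_error(correlate(c(1, 2), c(3, 4)), ">= 4")
})

test_that("endpoint-level comparison wires groups, adjustment and exclusions together", {
  set.seed(111)
  subj <- c(sprintf("C%02d", 1:10), sprintf("P%02d", 1:9))
  grp <- rep(c("control", "mfm"), c(10, 9))
  d <- tidyr::expand_grid(subject_id = subj, region = MUSCLE_NAMES)
  d$group <- grp[match(d$subject_id, subj)]
  shift <- ifelse(d$group == "mfm" & d$region != "GL", 3, 0)
  d$value <- rnorm(nrow(d)) + shift
  d$value[d$subject_id == "P01" & d$region == "SOL"] <- NA  # an exclusion
  res <- compare_endpoints(d, value, region, subject_id, group)
  expect_equal(nrow(res), 7)
  expect_true(all(res$p_adjusted >= res$p_raw - 1e-12, na.rm = TRUE))
  expect_lt(max(res$p_adjusted[res$region != "GL"]), 0.05)
  expect_gt(res$p_raw[res$region == "GL"], 0.05)
  expect_equal(res$n_x[res$region == "SOL"], 10)
  expect_equal(res$n_y[res$region == "SOL"], 8)
})
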