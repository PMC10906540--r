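test_that("batch-means MCSE of an i.i.d. chain is close to sd/sqrt(N)", {
  set.seed(1)
  x <- matrix(rnorm(10000), ncol = 1, dimnames = list(NULL, "z"))
  rep <- mc_error_check(x)
  expect_true(attr(rep, "passed"))
  # analytic MCSE of an i.i.d. mean: 1/sqrt(10000) = 0.01
  expect_lt(abs(rep$ratio - 0.01), 0.005)
  # property over repeated seeds: within 20% of sd/sqrt(N)
  ratios <- vapply(2:6, function(s) {
    set.seed(s)
    mc_error_check(matrix(rnorm(4000), ncol = 1))$ratio
  }, numeric(1))
  expect_true(all(abs(ratios * sqrt(4000) - 1) < 0.2))
})

test_that("degenerate and short chains are handled explicitly", {
  const <- matrix(1, 500, 1)
  rep <- mc_error_check(const)
  expect_equal(rep$ratio, 0)
  expect_true(attr(rep, "passed"))
  expect_error(mc_error_check(matrix(rnorm(50), ncol = 1)),
               "at least 100")
})

test_that("a correlated chain inflates the MCSE ratio above the i.i.d. rate", {
  set.seed(4)
  n <- 10000
  x <- as.numeric(stats::arima.sim(list(ar = 0.95), n))
  r <- mc_error_check(matrix(x, ncol = 1))$ratio
  expect_gt(r, 3 / sqrt(n))   # far above the 1/sqrt(N) i.i.d. benchmark
})

test_that("arm deviance is zero when the fit is saturated", {
  net <- toy_network()   # arms: 30/100, 45/100, 40/120, 70/120
  qlog <- stats::qlogis
  # constant draws that reproduce every arm proportion exactly
  d <- cbind(B = rep(qlog(0.45) - qlog(0.30), 20),
             C = rep(qlog(70 / 120) - qlog(40 / 120), 20))
  mu <- cbind(s1 = rep(qlog(0.30), 20), s2 = rep(qlog(40 / 120), 20))
  fit <- fake_draws(net, d, mu)
  dev <- arm_deviance(net, fit)
  expect_equal(dev$deviance, rep(0, 4), tolerance = 1e-10)
  expect_equal(attr(dev, "total"), 0, tolerance = 1e-10)
})

test_that("arm deviance matches a brute-force recomputation", {
  net <- toy_network()
  fit <- sample_posterior(net, quick_cfg(seed = 31))
  dev <- arm_deviance(net, fit)
  # independent recomputation straight from the draws
  for (a in seq_len(nrow(net$arms))) {
    arm <- net$arms[a, ]
    s <- match(arm$study, net$studies$study)
    base <- net$studies$baseline_index[s]
    dcol <- function(tr_idx) {
      if (tr_idx == 0) rep(0, nrow(fit$d_draws))
      else fit$d_draws[, net$treatments$label[tr_idx + 1L]]
    }
    eta <- fit$mu_draws[, s] + dcol(arm$treatment_index) - dcol(base)
    p <- 1 / (1 + exp(-eta))
    r <- arm$events; n <- arm$n
    want <- mean(2 * ((if (r > 0) r * log(r / (n * p)) else 0) +
                        (if (r < n) (n - r) * log((n - r) / (n - n * p))
                         else 0)))
    expect_equal(dev$deviance[a], want, tolerance = 1e-9)
  }
  expect_true(all(dev$deviance >= 0))
  expect_error(arm_deviance(jak_network("remission"), fit), "not fit")
})

test_that("total residual deviance is calibrated on a well-specified fit", {
  sim <- simulate_network(synthetic_scenario("star4", seed = 5))
  fit <- sample_posterior(sim$network, quick_cfg(seed = 5))
  dev <- arm_deviance(sim$network, fit)
  n_arms <- nrow(sim$network$arms)
  # chi-square-like calibration: mean ~ 1 per datapoint, generous band
  expect_gt(attr(dev, "total"), 0.1 * n_arms)
  expect_lt(attr(dev, "total"), 3 * n_arms)
  expect_gt(attr(dev, "dic"), attr(dev, "total"))  # pD > 0
})

test_that("consistency and UME fits coincide on a loop-free network", {
  net <- jak_network("remission")
  cmp <- inconsistency_comparison(net, quick_cfg(seed = 41))
  expect_identical(attr(cmp, "n_loops"), 0L)
  # structurally identical models: per-arm deviances equal up to MC noise
  expect_lt(max(abs(cmp$dev_consistency - cmp$dev_inconsistency)), 0.5)
  # and the UME effect estimates match the basic parameters
  fit_con <- sample_posterior(net, quick_cfg(seed = 41))
  fit_ume <- sample_posterior(net, quick_cfg(seed = 43),
                              parametrization = "ume")
  for (tr in setdiff(net$treatments$label, "MTX")) {
    con <- median(exp(fit_con$d_draws[, tr]))
    ume <- median(exp(fit_ume$d_draws[, paste("MTX vs", tr)]))
    expect_lt(abs(con / ume - 1), 0.1, label = tr)
  }
})

test_that("injected direct/indirect conflict surfaces in the deviance pairs", {
  # A-B-C loop where the direct A-C effect contradicts the indirect path:
  # direct B vs A = +1.5, direct C vs B = +1.5, but direct C vs A = -1.5
  mk <- function(study, trts, logits) {
    n <- 600L
    data.frame(study = study, treatment = trts, n = n,
               events = round(n * stats::plogis(logits)),
               stringsAsFactors = FALSE)
  }
  rows <- rbind(
    mk("ab", c("A", "B"), c(-1, 0.5)),
    mk("bc", c("B", "C"), c(-1, 0.5)),
    mk("ac", c("A", "C"), c(-0.5, -2)))
  net <- load_network(rows, "conflict", "A")
  expect_identical(jaknet:::count_loops(net), 1L)
  cmp <- inconsistency_comparison(net, quick_cfg(seed = 47))
  expect_identical(attr(cmp, "n_loops"), 1L)
  # the UME model can fit each study exactly; consistency cannot
  worst <- max(cmp$dev_consistency - cmp$dev_inconsistency)
  expect_gt(worst, 2)
  expect_gt(attr(cmp, "total_consistency"),
            attr(cmp, "total_inconsistency") + 5)
})

test_that("sensitivity comparison flags identical fits as perfect agreement", {
  net <- toy_network()
  fit <- sample_posterior(net, quick_cfg(seed = 51))
  cmp <- sensitivity_compare(fit, fit)
  expect_equal(cmp$median_ratio, rep(1, nrow(cmp)))
  expect_true(all(cmp$agree))
  expect_true(attr(cmp, "all_agree"))
  other <- sample_posterior(jak_network("remission"), quick_cfg(seed = 51))
  expect_error(sensitivity_compare(fit, other), "same network")
})

test_that("under heterogeneity the RE intervals are wider than FE", {
  sim <- simulate_network(synthetic_scenario("hetero", seed = 3))
  fe <- sample_posterior(sim$network, quick_cfg(seed = 3))
  re <- sample_posterior(sim$network, quick_cfg(model = "random",
                                                seed = 3))
  cmp <- sensitivity_compare(fe, re)
  width_fe <- log(cmp$fe_high) - log(cmp$fe_low)
  width_re <- log(cmp$re_high) - log(cmp$re_low)
  expect_true(all(width_re > width_fe))
  # medians still in the same ballpark for the directly informed contrasts
  expect_true(all(abs(log(cmp$median_ratio)) < log(2)))
})

test_that("FE and RE medians agree on the fixture (sensitivity analysis)", {
  net <- jak_network("remission")
  fe <- sample_posterior(net, quick_cfg(seed = 61))
  re <- sample_posterior(net, quick_cfg(model = "random", seed = 62))
  cmp <- sensitivity_compare(fe, re)
  vs_mtx <- grepl("MTX", cmp$comparison)
  expect_true(all(abs(log(cmp$median_ratio[vs_mtx])) < log(1.25)))
})
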