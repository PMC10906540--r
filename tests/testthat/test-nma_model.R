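# Brute-force reference density, written independently of the package:
# explicit binomial terms and normal priors, no shared code paths.
brute_force_logpost_fe <- function(d_by_label, mu_by_study, net, sd_d,
                                   sd_mu) {
  lp <- 0
  for (a in seq_len(nrow(net$arms))) {
    arm <- net$arms[a, ]
    b <- net$studies$baseline[net$studies$study == arm$study]
    eta <- mu_by_study[[arm$study]] +
      d_by_label[[arm$treatment]] - d_by_label[[b]]
    p <- 1 / (1 + exp(-eta))
    lp <- lp + lchoose(arm$n, arm$events) + arm$events * log(p) +
      (arm$n - arm$events) * log(1 - p)
  }
  for (lab in names(d_by_label))
    if (d_by_label[[lab]] != 0 || lab != net$reference)
      lp <- lp + (-0.5 * (d_by_label[[lab]] / sd_d)^2 -
                    log(sd_d) - 0.5 * log(2 * pi))
  for (s in names(mu_by_study))
    lp <- lp + (-0.5 * (mu_by_study[[s]] / sd_mu)^2 -
                  log(sd_mu) - 0.5 * log(2 * pi))
  lp
}

test_that("log_posterior matches a brute-force density on a toy network", {
  net <- toy_network()
  cfg <- nma_config(seed = 1)
  for (i in 1:5) {
    set.seed(i)
    d <- c(0, rnorm(2, 0, 1))
    mu <- rnorm(2, -0.5, 1)
    got <- log_posterior(list(d = d, mu = mu), net, cfg)
    want <- brute_force_logpost_fe(
      stats::setNames(as.list(d), net$treatments$label),
      stats::setNames(as.list(mu), net$studies$study),
      net, cfg$prior_sd_d, cfg$prior_sd_mu)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("all-zero parameters give each arm probability one half", {
  net <- jak_network("remission")
  cfg <- nma_config(seed = 1)
  K <- nrow(net$treatments); S <- nrow(net$studies)
  got <- log_posterior(list(d = rep(0, K), mu = rep(0, S)), net, cfg)
  want <- sum(lchoose(net$arms$n, net$arms$events)) +
    sum(net$arms$n) * log(0.5) +
    (K - 1 + S) * stats::dnorm(0, 0, 100, log = TRUE)
  expect_equal(got, want, tolerance = 1e-12)
  expect_true(is.finite(got))
})

test_that("log_posterior increases as d moves toward the sample log-OR", {
  net <- jak_network("remission")
  cfg <- nma_config(seed = 1)
  # hold baselines at their sample logits, other d at sample log-ORs
  arms <- net$arms
  logit <- function(r, n) log((r) / (n - r))
  mu <- vapply(net$studies$study, function(s) {
    a <- arms[arms$study == s & arms$treatment == "MTX", ]
    logit(a$events, a$n)
  }, numeric(1))
  d_hat <- vapply(net$treatments$label[-1], function(tr) {
    a <- arms[arms$treatment == tr, ]
    s <- a$study
    m <- arms[arms$study == s & arms$treatment == "MTX", ]
    logit(a$events, a$n) - logit(m$events, m$n)
  }, numeric(1))
  upad <- match("upadacitinib 15 mg", net$treatments$label) - 1L
  grid <- seq(0, d_hat[upad], length.out = 6)
  vals <- vapply(grid, function(g) {
    d <- c(0, d_hat); d[upad + 1L] <- g
    log_posterior(list(d = d, mu = mu), net, cfg)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("log_posterior validates dimensions and the reference constraint", {
  net <- toy_network()
  cfg <- nma_config(seed = 1)
  expect_error(log_posterior(list(d = c(0, 1), mu = c(0, 0)), net, cfg),
               "one entry per treatment")
  expect_error(log_posterior(list(d = c(0, 1, 2), mu = 0), net, cfg),
               "one entry per study")
  expect_error(log_posterior(list(d = c(1, 1, 2), mu = c(0, 0)), net, cfg),
               "reference")
})

test_that("the sampler's compiled density agrees with log_posterior", {
  # compare differences between parameter points: the two implementations
  # may differ by an additive constant only
  net <- toy_network()
  for (model in c("fixed", "random")) {
    cfg <- nma_config(model = model, seed = 1)
    X <- jaknet:::effect_design(net, "consistency")
    study_idx <- match(net$arms$study, net$studies$study) - 1L
    pts <- lapply(1:4, function(i) {
      set.seed(100 + i)
      list(d = c(0, rnorm(2)), mu = rnorm(2),
           delta = rnorm(2, 0, 0.3), tau = runif(1, 0.1, 1.5))
    })
    vals_r <- vapply(pts, function(p)
      log_posterior(p, net, cfg), numeric(1))
    vals_cpp <- vapply(pts, function(p)
      jaknet:::nma_logpost_cpp(p$d[-1], p$mu, p$delta, p$tau,
                               study_idx, net$arms$n, net$arms$events, X,
                               nrow(net$studies), model == "random",
                               cfg$prior_sd_d, cfg$prior_sd_mu,
                               cfg$tau_prior_upper), numeric(1))
    expect_equal(diff(vals_r), diff(vals_cpp), tolerance = 1e-8,
                 info = model)
  }
})

test_that("sampling is bit-reproducible for a fixed seed", {
  net <- toy_network()
  f1 <- sample_posterior(net, quick_cfg(seed = 7))
  f2 <- sample_posterior(net, quick_cfg(seed = 7))
  expect_identical(f1$d_draws, f2$d_draws)
  f3 <- sample_posterior(net, quick_cfg(seed = 8))
  expect_false(identical(f1$d_draws, f3$d_draws))
})

test_that("retained draws have the contracted shape and finite ORs", {
  net <- toy_network()
  cfg <- quick_cfg(seed = 3)
  fit <- sample_posterior(net, cfg)
  expect_identical(nrow(fit$d_draws),
                   cfg$n_chains * cfg$iterations)
  expect_identical(sort(unique(fit$chain_ids)), seq_len(cfg$n_chains))
  expect_true(all(is.finite(exp(fit$d_draws))))
  expect_true(all(exp(fit$d_draws) > 0))
  expect_true(all(fit$rhat < 1.05))
})

test_that("pairwise_or: self-comparison, reciprocity, and errors", {
  net <- toy_network()
  fit <- sample_posterior(net, quick_cfg(seed = 11))
  self <- pairwise_or(fit, "B", "B")
  expect_equal(self$median, 1); expect_equal(self$cri_low, 1)
  expect_equal(self$cri_high, 1); expect_false(self$significant)
  ab <- pairwise_or(fit, "B", "C"); ba <- pairwise_or(fit, "C", "B")
  expect_equal(ab$median * ba$median, 1, tolerance = 1e-12)
  expect_true(ab$cri_low <= ab$median && ab$median <= ab$cri_high)
  expect_identical(ab$significant, ab$cri_low > 1 || ab$cri_high < 1)
  expect_error(pairwise_or(fit, "B", "Z"), "unknown treatment")
})

test_that("direct odds-ratio oracle reproduces 2x2 arithmetic", {
  net <- jak_network("remission")
  expect_equal(direct_or_oracle(net, "filgotinib 200 mg", "MTX"),
               (89 * 295) / (121 * 121), tolerance = 1e-10)
  expect_equal(direct_or_oracle(net, "upadacitinib 15 mg", "MTX"),
               (153 * 256) / (164 * 58), tolerance = 1e-10)
  expect_equal(direct_or_oracle(identical_arms_network(), "B", "A"), 1,
               tolerance = 1e-12)
  expect_error(direct_or_oracle(net, "filgotinib 200 mg",
                                "tofacitinib 5 mg"), "share no study")
})

test_that("Mantel-Haenszel pooling matches the hand formula over studies", {
  rows <- data.frame(
    study = rep(c("s1", "s2"), each = 2),
    treatment = rep(c("A", "B"), 2),
    n = c(100L, 100L, 200L, 200L),
    events = c(30L, 45L, 50L, 80L), stringsAsFactors = FALSE)
  net <- load_network(rows, "toy", "A")
  # MH weights: sum(b_t * a_c / N_t) / sum(b_c * a_t / N_t), B vs A
  num <- 45 * 70 / 200 + 80 * 150 / 400
  den <- 55 * 30 / 200 + 120 * 50 / 400
  expect_equal(direct_or_oracle(net, "B", "A"), num / den,
               tolerance = 1e-10)
})

test_that("posterior medians track the direct oracle on the star fixture", {
  net <- jak_network("remission")
  fit <- sample_posterior(net, quick_cfg(seed = 5))
  for (tr in setdiff(net$treatments$label, "MTX")) {
    post <- pairwise_or(fit, tr, "MTX")$median
    direct <- direct_or_oracle(net, tr, "MTX")
    expect_lt(abs(post / direct - 1), 0.10, label = tr)
  }
})

test_that("posterior is insensitive to the vague-prior scale", {
  net <- jak_network("remission")
  wide <- sample_posterior(net, quick_cfg(seed = 5))
  tight <- sample_posterior(net, quick_cfg(prior_sd_d = 15,
                                           prior_sd_mu = 15, seed = 5))
  for (tr in setdiff(net$treatments$label, "MTX")) {
    r <- pairwise_or(wide, tr, "MTX")$median /
      pairwise_or(tight, tr, "MTX")$median
    expect_lt(abs(r - 1), 0.05, label = tr)
  }
})

test_that("random effects collapse to fixed effects as tau_prior_upper -> 0", {
  net <- jak_network("remission")
  fe <- sample_posterior(net, quick_cfg(seed = 9))
  re0 <- sample_posterior(net, quick_cfg(model = "random",
                                         tau_prior_upper = 0.01, seed = 9))
  for (tr in setdiff(net$treatments$label, "MTX")) {
    r <- pairwise_or(re0, tr, "MTX")$median /
      pairwise_or(fe, tr, "MTX")$median
    expect_lt(abs(r - 1), 0.06, label = tr)
  }
})

test_that("zero-event networks: exchangeable arms stay symmetric under the prior", {
  # With no events anywhere the likelihood is monotone decreasing in every
  # logit, so effects versus the reference are left-shifted in proportion
  # to the prior scale (the data cannot centre them); but two structurally
  # identical zero-event treatments are exchangeable, and the prior keeps
  # their mutual OR centred at 1.
  rows <- data.frame(
    study = rep(c("s1", "s2"), each = 2),
    treatment = c("A", "B", "A", "C"),
    n = 50L, events = 0L, stringsAsFactors = FALSE)
  net <- load_network(rows, "toy", "A")
  fit <- sample_posterior(net, nma_config(prior_sd_d = 15,
                                          prior_sd_mu = 15,
                                          n_chains = 2, burn_in = 4000,
                                          iterations = 8000, seed = 13))
  bc <- pairwise_or(fit, "B", "C")$median
  expect_lt(abs(log(bc)), 0.4)
  expect_false(pairwise_or(fit, "B", "C")$significant)
  # the documented monotone-likelihood shift: both vs-reference medians
  # are pulled the same way, below 1
  expect_lt(pairwise_or(fit, "B", "A")$median, 1)
  expect_lt(pairwise_or(fit, "C", "A")$median, 1)
})

test_that("a hopelessly short run fails the convergence gate with diagnostics", {
  net <- jak_network("remission")
  cfg <- nma_config(n_chains = 4, burn_in = 1, iterations = 60, seed = 2)
  err <- tryCatch(sample_posterior(net, cfg), error = identity)
  expect_s3_class(err, "nma_convergence_error")
  expect_true(any(err$rhat > 1.05))
  expect_s3_class(err$draws, "nma_draws")
})
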