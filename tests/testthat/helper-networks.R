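# Shared fixtures built in code.

# two-study toy network: A (reference) vs B, A vs C
toy_network <- function() {
  load_network(data.frame(
    study = c("s1", "s1", "s2", "s2"),
    treatment = c("A", "B", "A", "C"),
    n = c(100L, 100L, 120L, 120L),
    events = c(30L, 45L, 40L, 70L),
    stringsAsFactors = FALSE
  ), endpoint = "toy", reference = "A")
}

# single 2-arm study with identical arms
identical_arms_network <- function() {
  load_network(data.frame(
    study = c("s1", "s1"), treatment = c("A", "B"),
    n = c(50L, 50L), events = c(20L, 20L), stringsAsFactors = FALSE
  ), endpoint = "toy", reference = "A")
}

# short MCMC settings for tests that only need a correct, converged chain,
# not full-run Monte-Carlo precision
quick_cfg <- function(..., seed = 1) {
  nma_config(n_chains = 2, burn_in = 2000, iterations = 2000,
             seed = seed, ...)
}

# hand-built draws object (bypasses MCMC) for ranking/diagnostic unit tests;
# d_draws columns must be the non-reference treatment labels in index order
fake_draws <- function(net, d_draws, mu_draws = NULL,
                       model = "fixed", chains = 1L) {
  n <- nrow(d_draws)
  if (is.null(mu_draws))
    mu_draws <- matrix(0, n, nrow(net$studies),
                       dimnames = list(NULL, net$studies$study))
  cfg <- nma_config(model = model, seed = 1)
  structure(
    list(d_draws = d_draws, mu_draws = mu_draws, delta_draws = NULL,
         nonbase_arms = integer(0), tau_draws = NULL,
         chain_ids = rep(seq_len(chains), each = n / chains),
         accept = numeric(0), X = effect_design_for_tests(net),
         config = cfg, parametrization = "consistency", network = net,
         rhat = setNames(rep(1, ncol(d_draws)), colnames(d_draws))),
    class = "nma_draws")
}

# the package's design-matrix builder is internal; recreate the consistency
# design here so fake draws stay structurally valid
effect_design_for_tests <- function(net) {
  arms <- net$arms
  base <- net$studies$baseline_index[match(arms$study, net$studies$study)]
  K <- nrow(net$treatments)
  X <- matrix(0, nrow(arms), K - 1L)
  colnames(X) <- net$treatments$label[net$treatments$index > 0]
  for (a in seq_len(nrow(arms))) {
    t <- arms$treatment_index[a]
    if (t > 0L) X[a, t] <- X[a, t] + 1
    if (base[a] > 0L) X[a, base[a]] <- X[a, base[a]] - 1
  }
  X
}
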