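#' Configuration for the Bayesian NMA sampler
#'
#' Bundles model choice, priors, and MCMC run lengths. Defaults follow the
#' analysis the package reproduces: vague normal priors on the basic
#' parameters and study baselines, a uniform prior on the between-study SD,
#' and 10,000 burn-in plus 10,000 monitoring iterations per chain.
#'
#' @param model \code{"fixed"} or \code{"random"} effects.
#' @param prior_sd_d SD of the zero-mean normal prior on the basic
#'   parameters d_k (log-OR vs reference). Default 100 (vague on the
#'   log-odds scale).
#' @param prior_sd_mu SD of the zero-mean normal prior on study baseline
#'   logits. Default 100.
#' @param tau_prior_upper Upper bound of the uniform prior on the
#'   between-study SD tau (random effects only). Default 2 on the log-odds
#'   scale.
#' @param n_chains Number of MCMC chains (>= 2). Default 4.
#' @param burn_in Burn-in iterations per chain. Default 10000.
#' @param iterations Retained (monitoring) iterations per chain, thin 1.
#'   Default 10000.
#' @param seed Integer seed; chain c uses stream seed + c, so results are
#'   bit-reproducible for fixed inputs.
#' @return An object of class \code{nma_config}.
#' @export
nma_config <- function(model = c("fixed", "random"),
                       prior_sd_d = 100, prior_sd_mu = 100,
                       tau_prior_upper = 2,
                       n_chains = 4, burn_in = 10000, iterations = 10000,
                       seed = 1) {
  model <- match.arg(model)
  stopifnot(prior_sd_d > 0, prior_sd_mu > 0, tau_prior_upper > 0,
            n_chains >= 2, burn_in > 0, iterations > 0)
  structure(list(model = model, prior_sd_d = prior_sd_d,
                 prior_sd_mu = prior_sd_mu,
                 tau_prior_upper = tau_prior_upper,
                 n_chains = as.integer(n_chains),
                 burn_in = as.integer(burn_in),
                 iterations = as.integer(iterations),
                 seed = as.integer(seed)),
            class = "nma_config")
}

# Effect design matrix: one row per arm, one column per effect parameter.
# consistency: columns are basic parameters d_1..d_{K-1}; arm with treatment
#   t and study baseline b gets +1 on t and -1 on b (reference column d_0
#   does not exist, its coefficient is identically 0).
# ume: one free effect per observed (baseline, treatment) design pair.
effect_design <- function(net, parametrization = c("consistency", "ume")) {
  parametrization <- match.arg(parametrization)
  arms <- net$arms
  base <- net$studies$baseline_index[match(arms$study, net$studies$study)]
  A <- nrow(arms)
  if (parametrization == "consistency") {
    K <- nrow(net$treatments)
    X <- matrix(0, A, K - 1L)
    colnames(X) <- net$treatments$label[net$treatments$index > 0]
    for (a in seq_len(A)) {
      t <- arms$treatment_index[a]
      if (t > 0L) X[a, t] <- X[a, t] + 1
      if (base[a] > 0L) X[a, base[a]] <- X[a, base[a]] - 1
    }
  } else {
    nonbase <- arms$treatment_index != base
    pair <- paste(net$treatments$label[base + 1L], arms$treatment,
                  sep = " vs ")[nonbase]
    levels <- unique(pair)
    X <- matrix(0, A, length(levels))
    colnames(X) <- levels
    X[cbind(which(nonbase), match(pair, levels))] <- 1
  }
  X
}

#' Joint log posterior density of the arm-based NMA model
#'
#' Reference (R-level) evaluation of the model the sampler targets:
#' binomial likelihood with logit link, \code{logit(p_ik) = mu_i + d_t - d_b}
#' for fixed effects, or \code{mu_i + delta_ik} with
#' \code{delta_i ~ MVN(d_t - d_b, tau^2 (0.5 I + 0.5 J))} for random
#' effects, plus normal priors on \code{d} and \code{mu} and a uniform
#' prior on \code{tau}. Normalising constants that do not depend on the
#' parameters (binomial coefficients, prior normalisers) are included, so
#' the value is a proper joint log density up to the uniform-prior constant.
#'
#' @param params List with elements \code{d} (length n_treatments, first
#'   element must be 0 for the reference), \code{mu} (length n_studies), and
#'   for random effects \code{delta} (one per non-baseline arm, in arm
#'   order) and \code{tau}.
#' @param net An \code{evidence_network}.
#' @param cfg An \code{nma_config}.
#' @return The joint log density (finite real, or -Inf outside the prior
#'   support).
#' @export
log_posterior <- function(params, net, cfg) {
  stopifnot(inherits(net, "evidence_network"), inherits(cfg, "nma_config"))
  arms <- net$arms
  K <- nrow(net$treatments); S <- nrow(net$studies)
  d <- params$d; mu <- params$mu
  if (length(d) != K)
    stop("params$d must have one entry per treatment (reference first)",
         call. = FALSE)
  if (abs(d[1L]) > 1e-12)
    stop("d for the reference treatment must be 0", call. = FALSE)
  if (length(mu) != S)
    stop("params$mu must have one entry per study", call. = FALSE)

  base <- net$studies$baseline_index[match(arms$study, net$studies$study)]
  random <- cfg$model == "random"
  nonbase <- which(arms$treatment_index != base)
  mean_eff <- d[arms$treatment_index + 1L] - d[base + 1L]

  if (random) {
    delta_arm <- numeric(nrow(arms))
    if (length(params$delta) != length(nonbase))
      stop("params$delta must have one entry per non-baseline arm",
           call. = FALSE)
    delta_arm[nonbase] <- params$delta
    tau <- params$tau
    if (!is.finite(tau) || tau <= 0 || tau > cfg$tau_prior_upper)
      return(-Inf)
    eta <- mu[match(arms$study, net$studies$study)] + delta_arm
  } else {
    eta <- mu[match(arms$study, net$studies$study)] + mean_eff
  }

  lp <- sum(stats::dbinom(arms$events, arms$n, stats::plogis(eta),
                          log = TRUE))
  lp <- lp + sum(stats::dnorm(d[-1L], 0, cfg$prior_sd_d, log = TRUE))
  lp <- lp + sum(stats::dnorm(mu, 0, cfg$prior_sd_mu, log = TRUE))

  if (random) {
    # per-study MVN with variance tau^2 and pairwise correlation 0.5
    for (s in seq_len(S)) {
      idx <- nonbase[arms$study[nonbase] == net$studies$study[s]]
      m <- length(idx)
      if (m == 0L) next
      e <- delta_arm[idx] - mean_eff[idx]
      quad <- (2 * sum(e^2) - 2 / (m + 1) * sum(e)^2) / tau^2
      logdet <- 2 * m * log(tau) + (m - 1) * log(0.5) + log(0.5 * (m + 1))
      lp <- lp - 0.5 * (quad + logdet + m * log(2 * pi))
    }
  }
  lp
}

#' Draw from the posterior of the arm-based NMA model
#'
#' Runs the compiled adaptive random-walk Metropolis-within-Gibbs sampler:
#' \code{n_chains} independent chains, each with \code{burn_in} adaptation
#' iterations discarded and \code{iterations} monitoring iterations retained
#' (thin 1). Convergence is gated on the split-Rhat of every basic
#' parameter: values above 1.05 raise an error carrying the diagnostics.
#'
#' @param net An \code{evidence_network}.
#' @param cfg An \code{nma_config}.
#' @param parametrization \code{"consistency"} (basic parameters, the
#'   default) or \code{"ume"} (unrelated mean effects — one free effect per
#'   observed design pair, used by the inconsistency assessment).
#' @return An object of class \code{nma_draws}: list with \code{d_draws}
#'   (draws x effect-parameters matrix, columns named by treatment or design
#'   pair), \code{mu_draws}, \code{tau_draws} (random effects only),
#'   \code{chain_ids}, \code{rhat}, \code{accept}, \code{config},
#'   \code{parametrization}, and the \code{network} the fit was run on.
#' @examples
#' \donttest{
#' net <- jak_network("remission")
#' fit <- sample_posterior(net, nma_config(seed = 42))
#' pairwise_or(fit, "upadacitinib 15 mg", "MTX")
#' }
#' @export
sample_posterior <- function(net, cfg,
                             parametrization = c("consistency", "ume")) {
  stopifnot(inherits(net, "evidence_network"), inherits(cfg, "nma_config"))
  parametrization <- match.arg(parametrization)
  X <- effect_design(net, parametrization)
  arms <- net$arms
  study_idx <- match(arms$study, net$studies$study) - 1L
  # empirical baseline logits centre the chain starts
  base_arm <- arms$treatment_index ==
    net$studies$baseline_index[match(arms$study, net$studies$study)]
  mu_init <- vapply(seq_len(nrow(net$studies)), function(s) {
    a <- which(study_idx == s - 1L & base_arm)[1L]
    stats::qlogis((arms$events[a] + 0.5) / (arms$n[a] + 1))
  }, numeric(1))

  random <- cfg$model == "random"
  res <- nma_mcmc(study_idx, arms$n, arms$events, X,
                  nrow(net$studies), random,
                  cfg$prior_sd_d, cfg$prior_sd_mu, cfg$tau_prior_upper,
                  cfg$n_chains, cfg$burn_in, cfg$iterations, cfg$seed,
                  mu_init)
  d_draws <- res$theta
  colnames(d_draws) <- colnames(X)
  mu_draws <- res$mu
  colnames(mu_draws) <- net$studies$study

  nonbase_arms <- which(rowSums(X != 0) > 0)
  delta_draws <- NULL
  if (random) {
    delta_draws <- res$delta
    colnames(delta_draws) <- paste(arms$study[nonbase_arms],
                                   arms$treatment[nonbase_arms],
                                   sep = ": ")
  }
  draws <- structure(
    list(d_draws = d_draws, mu_draws = mu_draws,
         delta_draws = delta_draws, nonbase_arms = nonbase_arms,
         tau_draws = if (random) as.numeric(res$tau) else NULL,
         chain_ids = as.integer(res$chain),
         accept = as.numeric(res$accept), X = X,
         config = cfg, parametrization = parametrization, network = net),
    class = "nma_draws")
  draws$rhat <- split_rhat(draws)
  # the gate covers the effect parameters; tau's Rhat is reported but not
  # gated (on sparse networks tau is prior-dominated and slow-mixing
  # without being wrong)
  gate <- draws$rhat[seq_len(ncol(d_draws))]
  if (any(gate > 1.05)) {
    msg <- paste0("MCMC did not converge: split-Rhat > 1.05 for ",
                  paste(names(gate)[gate > 1.05], collapse = ", "))
    cond <- structure(class = c("nma_convergence_error", "error",
                                "condition"),
                      list(message = msg, call = sys.call(-1),
                           rhat = draws$rhat, draws = draws))
    stop(cond)
  }
  draws
}

# split-Rhat (each chain halved) for every effect parameter and tau
split_rhat <- function(draws) {
  one <- function(x) {
    halves <- list()
    for (c in unique(draws$chain_ids)) {
      xc <- x[draws$chain_ids == c]
      h <- length(xc) %/% 2L
      halves <- c(halves, list(xc[seq_len(h)]), list(xc[h + seq_len(h)]))
    }
    m <- length(halves[[1L]])
    means <- vapply(halves, mean, numeric(1))
    vars <- vapply(halves, stats::var, numeric(1))
    W <- mean(vars); B <- m * stats::var(means)
    if (W <= 0) return(1)
    sqrt(((m - 1) / m * W + B / m) / W)
  }
  r <- apply(draws$d_draws, 2L, one)
  if (!is.null(draws$tau_draws)) r <- c(r, tau = one(draws$tau_draws))
  r
}

#' @export
print.nma_draws <- function(x, ...) {
  cat("NMA posterior draws (", x$config$model, " effects, ",
      x$parametrization, " parametrisation)\n", sep = "")
  cat(nrow(x$d_draws), "draws from", max(x$chain_ids), "chains;",
      "max split-Rhat", format(max(x$rhat), digits = 4), "\n")
  for (lab in colnames(x$d_draws)) {
    s <- pairwise_or_draws(x, lab)
    cat(sprintf("  OR %s vs %s: %.2f (%.2f-%.2f)\n", lab,
                if (x$parametrization == "consistency") x$network$reference
                else "baseline",
                s$median, s$cri_low, s$cri_high))
  }
  invisible(x)
}

# quantile summary of log-OR draws; quantiles are taken on the log scale
# (where they are exactly antisymmetric under negation) and exponentiated,
# so reciprocal comparisons multiply to 1 exactly
or_summary_from_draws <- function(log_or, comparison) {
  q <- exp(unname(stats::quantile(log_or, c(0.025, 0.5, 0.975),
                                  type = 7)))
  structure(list(comparison = comparison, median = q[2L],
                 cri_low = q[1L], cri_high = q[3L],
                 significant = q[1L] > 1 || q[3L] < 1),
            class = "or_summary")
}

#' @export
print.or_summary <- function(x, ...) {
  cat(sprintf("OR %s: %.2f (95%% CrI %.2f-%.2f)%s\n", x$comparison,
              x$median, x$cri_low, x$cri_high,
              if (x$significant) " *" else ""))
  invisible(x)
}

pairwise_or_draws <- function(draws, label) {
  or_summary_from_draws(draws$d_draws[, label],
                        paste(label, "vs", draws$network$reference))
}

# per-draw log-OR of treatment a vs reference (0 for the reference itself)
d_column <- function(draws, label) {
  if (draws$parametrization != "consistency")
    stop("pairwise comparisons require the consistency parametrisation",
         call. = FALSE)
  if (!label %in% draws$network$treatments$label)
    stop("unknown treatment: ", label, call. = FALSE)
  if (label == draws$network$reference)
    return(rep(0, nrow(draws$d_draws)))
  draws$d_draws[, label]
}

#' Posterior odds-ratio summary for a treatment pair
#'
#' The OR of a vs b is computed per draw as \code{exp(d_a - d_b)} (the
#' reference treatment has d identically 0), then summarised by the
#' posterior median and central 95\% credible interval. A comparison is
#' flagged significant when the 95\% CrI excludes 1.
#'
#' @param draws An \code{nma_draws} object (consistency parametrisation).
#' @param a,b Treatment labels; the OR is for a vs b (OR > 1 favours a when
#'   the outcome is beneficial).
#' @return An \code{or_summary}: \code{comparison}, \code{median},
#'   \code{cri_low}, \code{cri_high}, \code{significant}.
#' @export
pairwise_or <- function(draws, a, b) {
  stopifnot(inherits(draws, "nma_draws"))
  or_summary_from_draws(d_column(draws, a) - d_column(draws, b),
                        paste(a, "vs", b))
}

#' Mantel-Haenszel direct odds ratio (frequentist cross-check)
#'
#' Pools the sample odds ratio of a vs b over the studies containing both
#' treatments with the Mantel-Haenszel method (via
#' \code{\link[metafor]{rma.mh}}, no continuity correction). With a single
#' common study this is the plain 2x2 sample OR. Used as an independent
#' check on the Bayesian posterior medians in star-shaped networks, where
#' every comparison against the reference is directly observed.
#'
#' @param net An \code{evidence_network}.
#' @param a,b Treatment labels with at least one common study.
#' @return The pooled sample odds ratio of a vs b (numeric scalar).
#' @export
direct_or_oracle <- function(net, a, b) {
  stopifnot(inherits(net, "evidence_network"))
  arms <- net$arms
  common <- intersect(arms$study[arms$treatment == a],
                      arms$study[arms$treatment == b])
  if (length(common) == 0L)
    stop("treatments ", sQuote(a), " and ", sQuote(b),
         " share no study; no direct comparison exists", call. = FALSE)
  ai <- bi <- ci <- di <- numeric(length(common))
  for (i in seq_along(common)) {
    ra <- arms[arms$study == common[i] & arms$treatment == a, ]
    rb <- arms[arms$study == common[i] & arms$treatment == b, ]
    ai[i] <- ra$events; bi[i] <- ra$n - ra$events
    ci[i] <- rb$events; di[i] <- rb$n - rb$events
  }
  fit <- metafor::rma.mh(ai = ai, bi = bi, ci = ci, di = di,
                         measure = "OR", add = 0, to = "none",
                         correct = FALSE)
  unname(exp(as.numeric(fit$beta)))
}
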