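#' Monte-Carlo-error gate for posterior summaries
#'
#' For each effect parameter (and the heterogeneity SD when present) the
#' Monte-Carlo standard error of the posterior mean is estimated by batch
#' means within each chain (batch size about the square root of the chain
#' length) and compared to the posterior SD. The run passes when every
#' MCSE/SD ratio is below the threshold — the usual rule that simulation
#' error should be under 5\% of the posterior uncertainty.
#'
#' @param draws An \code{nma_draws} fit, or a plain numeric matrix of draws
#'   (columns = parameters, treated as one chain).
#' @param threshold Maximum acceptable MCSE/SD ratio. Default 0.05.
#' @return An \code{mc_error_report}: data frame with \code{parameter},
#'   \code{sd}, \code{mcse}, \code{ratio}; attribute \code{passed}.
#'   A parameter with zero posterior SD (a degenerate, constant chain) is
#'   reported with ratio 0.
#' @export
mc_error_check <- function(draws, threshold = 0.05) {
  if (inherits(draws, "nma_draws")) {
    mat <- draws$d_draws
    if (!is.null(draws$tau_draws)) mat <- cbind(mat, tau = draws$tau_draws)
    chains <- draws$chain_ids
  } else {
    mat <- as.matrix(draws)
    if (is.null(colnames(mat)))
      colnames(mat) <- paste0("par", seq_len(ncol(mat)))
    chains <- rep(1L, nrow(mat))
  }
  if (nrow(mat) < 100L)
    stop("need at least 100 retained draws for the batch-means MCSE",
         call. = FALSE)
  one <- function(x) {
    per_chain <- vapply(unique(chains), function(c) {
      xc <- x[chains == c]
      m <- max(2L, floor(sqrt(length(xc))))       # batch size
      nb <- length(xc) %/% m                      # number of batches
      bm <- vapply(seq_len(nb), function(b)
        mean(xc[((b - 1L) * m + 1L):(b * m)]), numeric(1))
      stats::var(bm) * m / (nb * m)               # var of the chain mean
    }, numeric(1))
    sqrt(sum(per_chain)) / length(per_chain)      # MCSE of the pooled mean
  }
  sds <- apply(mat, 2L, stats::sd)
  mcse <- apply(mat, 2L, one)
  ratio <- ifelse(sds > 0, mcse / sds, 0)
  rep <- data.frame(parameter = colnames(mat), sd = sds, mcse = mcse,
                    ratio = ratio, row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(rep, passed = all(ratio < threshold), threshold = threshold,
            class = c("mc_error_report", "data.frame"))
}

#' @export
print.mc_error_report <- function(x, ...) {
  thr <- attr(x, "threshold"); if (is.null(thr)) thr <- 0.05
  cat("Monte-Carlo error check (MCSE/SD < ", thr, "): ",
      if (all(x$ratio < thr)) "PASSED" else "FAILED", "\n", sep = "")
  print(data.frame(parameter = x$parameter,
                   sd = signif(x$sd, 4), mcse = signif(x$mcse, 4),
                   ratio = signif(x$ratio, 3)), row.names = FALSE)
  invisible(x)
}

# per-draw fitted probabilities for every arm of the network the fit ran on
fitted_probs <- function(draws) {
  net <- draws$network
  arms <- net$arms
  study_col <- match(arms$study, net$studies$study)
  eta <- draws$mu_draws[, study_col, drop = FALSE]
  if (draws$config$model == "random") {
    for (k in seq_along(draws$nonbase_arms))
      eta[, draws$nonbase_arms[k]] <- eta[, draws$nonbase_arms[k]] +
        draws$delta_draws[, k]
  } else {
    eta <- eta + draws$d_draws %*% t(draws$X)
  }
  stats::plogis(eta)   # draws x arms
}

#' Posterior mean deviance of each data point
#'
#' For every study arm the binomial deviance against the saturated model,
#' \deqn{dev = 2 [ r \log(r / (n \hat p)) + (n-r) \log((n-r)/(n - n \hat p)) ],}
#' (with 0 log 0 = 0) is averaged over the posterior draws of the fitted
#' probability. A well-fitting model gives a posterior mean deviance near 1
#' per arm, so the total residual deviance is compared to the number of
#' arms.
#'
#' @param net The \code{evidence_network} the fit was run on.
#' @param draws The \code{nma_draws} fit.
#' @return A \code{deviance_report}: data frame with one row per arm
#'   (\code{study}, \code{treatment}, \code{n}, \code{events},
#'   \code{deviance}); attributes \code{total} (residual deviance),
#'   \code{dic} and \code{pD} (deviance information criterion and effective
#'   parameters, computed from the deviance at the posterior mean fit).
#' @export
arm_deviance <- function(net, draws) {
  stopifnot(inherits(net, "evidence_network"),
            inherits(draws, "nma_draws"))
  if (!identical(net$arms, draws$network$arms))
    stop("draws were not fit on this network", call. = FALSE)
  arms <- net$arms
  p <- fitted_probs(draws)
  dev_at <- function(pvec) {
    # pvec: one probability per arm (recycled against r, n)
    r <- arms$events; n <- arms$n
    t1 <- ifelse(r > 0, r * log(r / (n * pvec)), 0)
    t2 <- ifelse(r < n, (n - r) * log((n - r) / (n - n * pvec)), 0)
    2 * (t1 + t2)
  }
  dev_mean <- vapply(seq_len(nrow(arms)), function(a) {
    r <- arms$events[a]; n <- arms$n[a]; pa <- p[, a]
    t1 <- if (r > 0) r * log(r / (n * pa)) else 0
    t2 <- if (r < n) (n - r) * log((n - r) / (n - n * pa)) else 0
    mean(2 * (t1 + t2))
  }, numeric(1))
  dbar <- sum(dev_mean)
  dhat <- sum(dev_at(colMeans(p)))         # deviance at posterior mean fit
  pD <- dbar - dhat
  rep <- data.frame(study = arms$study, treatment = arms$treatment,
                    n = arms$n, events = arms$events, deviance = dev_mean,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(rep, total = dbar, pD = pD, dic = dbar + pD,
            class = c("deviance_report", "data.frame"))
}

#' @export
print.deviance_report <- function(x, ...) {
  cat("Posterior mean deviance per data point (total ",
      sprintf("%.2f", attr(x, "total")), " over ", nrow(x),
      " arms; pD ", sprintf("%.2f", attr(x, "pD")),
      ", DIC ", sprintf("%.2f", attr(x, "dic")), ")\n", sep = "")
  print(data.frame(study = x$study, treatment = x$treatment,
                   deviance = signif(x$deviance, 4)), row.names = FALSE)
  invisible(x)
}

# number of independent closed loops in the treatment graph
# (cycle rank of the comparison graph; 0 for a star of two-arm trials)
count_loops <- function(net) {
  arms <- net$arms
  edges <- unique(do.call(rbind, lapply(split(arms$treatment_index,
                                              arms$study), function(tr) {
    tr <- sort(unique(tr))
    if (length(tr) < 2L) return(NULL)
    pairs <- utils::combn(tr, 2L)
    data.frame(a = pairs[1L, ], b = pairs[2L, ])
  })))
  n_edges <- nrow(unique(edges))
  n_nodes <- nrow(net$treatments)
  n_edges - (n_nodes - 1L)
}

#' Consistency vs inconsistency (unrelated mean effects) comparison
#'
#' Fits the network twice — once under the consistency model, where every
#' comparison is a difference of basic parameters, and once under the
#' unrelated-mean-effects (UME) model, where each observed design pair gets
#' its own free effect — and pairs the per-datapoint posterior mean
#' deviances. Points far off the diagonal flag disagreement between direct
#' and indirect evidence. On a loop-free (star) network the two models are
#' structurally identical, so the pairs coincide up to Monte-Carlo noise and
#' the report notes that no closed loops exist.
#'
#' @param net An \code{evidence_network}.
#' @param cfg An \code{nma_config}; the UME fit derives its seed from
#'   \code{cfg$seed} so the comparison is reproducible.
#' @return An \code{inconsistency_report}: data frame with one row per arm
#'   (\code{study}, \code{treatment}, \code{dev_consistency},
#'   \code{dev_inconsistency}); attributes \code{n_loops},
#'   \code{total_consistency}, \code{total_inconsistency}.
#' @export
inconsistency_comparison <- function(net, cfg) {
  stopifnot(inherits(net, "evidence_network"), inherits(cfg, "nma_config"))
  fit_con <- sample_posterior(net, cfg, parametrization = "consistency")
  cfg_ume <- cfg
  cfg_ume$seed <- cfg$seed + 104729L   # independent stream for the UME fit
  fit_ume <- sample_posterior(net, cfg_ume, parametrization = "ume")
  dev_con <- arm_deviance(net, fit_con)
  dev_ume <- arm_deviance(net, fit_ume)
  rep <- data.frame(study = dev_con$study, treatment = dev_con$treatment,
                    dev_consistency = dev_con$deviance,
                    dev_inconsistency = dev_ume$deviance,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(rep, n_loops = count_loops(net),
            total_consistency = attr(dev_con, "total"),
            total_inconsistency = attr(dev_ume, "total"),
            class = c("inconsistency_report", "data.frame"))
}

#' @export
print.inconsistency_report <- function(x, ...) {
  cat("Consistency vs inconsistency (UME) per-datapoint deviance\n")
  if (attr(x, "n_loops") == 0L)
    cat("Network has no closed loops: direct and indirect evidence never",
        "conflict by construction;\nthe two models are structurally",
        "identical and deviations are Monte-Carlo noise.\n")
  else
    cat("Network has", attr(x, "n_loops"), "independent closed loop(s).\n")
  print(data.frame(study = x$study, treatment = x$treatment,
                   consistency = signif(x$dev_consistency, 4),
                   inconsistency = signif(x$dev_inconsistency, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Fixed- vs random-effects sensitivity comparison
#'
#' Places the posterior OR summaries of two fits of the same network side
#' by side for every unordered treatment pair and flags agreement: same
#' significance classification (95\% CrI on the same side of 1) and median
#' ratio within the stated tolerance.
#'
#' @param fe,re Two \code{nma_draws} fits on the same network and endpoint
#'   (canonically fixed- and random-effects).
#' @param tolerance Maximum relative difference between medians that still
#'   counts as agreement. Default 0.25 (medians within 25\%).
#' @return A \code{sensitivity_report}: data frame with one row per pair,
#'   columns for both models' medians and CrIs, \code{median_ratio}
#'   (fe/re), \code{same_significance}, \code{agree}; attribute
#'   \code{all_agree}.
#' @export
sensitivity_compare <- function(fe, re, tolerance = 0.25) {
  stopifnot(inherits(fe, "nma_draws"), inherits(re, "nma_draws"))
  if (!identical(fe$network$arms, re$network$arms) ||
      !identical(fe$network$endpoint, re$network$endpoint))
    stop("the two fits are not on the same network/endpoint", call. = FALSE)
  trts <- fe$network$treatments$label
  pairs <- utils::combn(trts, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    sf <- pairwise_or(fe, a, b); sr <- pairwise_or(re, a, b)
    ratio <- sf$median / sr$median
    same_sig <- identical(sf$significant, sr$significant)
    data.frame(comparison = paste(a, "vs", b),
               fe_median = sf$median, fe_low = sf$cri_low,
               fe_high = sf$cri_high, fe_significant = sf$significant,
               re_median = sr$median, re_low = sr$cri_low,
               re_high = sr$cri_high, re_significant = sr$significant,
               median_ratio = ratio, same_significance = same_sig,
               agree = same_sig && abs(log(ratio)) <= log1p(tolerance),
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  structure(rep, all_agree = all(rep$agree), tolerance = tolerance,
            class = c("sensitivity_report", "data.frame"))
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Fixed- vs random-effects sensitivity: ",
      if (all(x$agree)) "models agree" else "models disagree",
      if (!is.null(attr(x, "tolerance")))
        paste0(" (median tolerance ", attr(x, "tolerance") * 100, "%)"),
      "\n", sep = "")
  print(data.frame(comparison = x$comparison,
                   fe = sprintf("%.2f (%.2f-%.2f)", x$fe_median, x$fe_low,
                                x$fe_high),
                   re = sprintf("%.2f (%.2f-%.2f)", x$re_median, x$re_low,
                                x$re_high),
                   agree = x$agree), row.names = FALSE)
  invisible(x)
}
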