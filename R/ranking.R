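#' Posterior rank probabilities of the treatments
#'
#' For every retained draw the treatments (including the reference, whose
#' log-OR is identically 0) are ranked by their effect, rank 1 being the
#' best. For a beneficial outcome such as remission, a larger log-OR vs
#' reference means better. Tied draws are resolved by spreading the tied
#' treatments' mass uniformly over the tied rank positions (equivalent to
#' averaging over all tie-break orders), which keeps the matrix doubly
#' stochastic; ties have probability zero for continuous samplers but occur
#' with constructed integer draws.
#'
#' @param draws An \code{nma_draws} fit (consistency parametrisation).
#' @param direction \code{"higher_is_better"} (efficacy, default) or
#'   \code{"lower_is_better"} (harm outcomes).
#' @return A \code{rank_prob_matrix}: list with \code{P} (n_treatments x
#'   n_treatments matrix, \code{P[j, r]} = posterior probability that
#'   treatment j has rank r), \code{direction}, \code{n_draws}.
#' @export
rank_probabilities <- function(draws,
                               direction = c("higher_is_better",
                                             "lower_is_better")) {
  stopifnot(inherits(draws, "nma_draws"))
  direction <- match.arg(direction)
  if (nrow(draws$d_draws) < 1L) stop("no retained draws", call. = FALSE)
  labels <- draws$network$treatments$label
  eff <- cbind(0, draws$d_draws[, setdiff(labels,
                                          draws$network$reference),
                                drop = FALSE])
  colnames(eff) <- c(draws$network$reference,
                     setdiff(labels, draws$network$reference))
  eff <- eff[, labels, drop = FALSE]  # treatment-index order
  if (direction == "lower_is_better") eff <- -eff

  K <- ncol(eff); N <- nrow(eff)
  # per treatment: number of strictly better treatments and tie-group size
  G <- matrix(0L, N, K)
  M <- matrix(1L, N, K)
  for (j in seq_len(K)) for (k in seq_len(K)) {
    if (j == k) next
    G[, j] <- G[, j] + (eff[, k] > eff[, j])
    M[, j] <- M[, j] + (eff[, k] == eff[, j])
  }
  P <- matrix(0, K, K, dimnames = list(labels, NULL))
  for (j in seq_len(K)) {
    simple <- M[, j] == 1L
    if (any(simple))
      P[j, ] <- P[j, ] + tabulate(G[simple, j] + 1L, nbins = K)
    for (i in which(!simple)) {
      span <- G[i, j] + seq_len(M[i, j])
      P[j, span] <- P[j, span] + 1 / M[i, j]
    }
  }
  structure(list(P = P / N, direction = direction, n_draws = N),
            class = "rank_prob_matrix")
}

#' @export
print.rank_prob_matrix <- function(x, digits = 3, ...) {
  cat("Rank probabilities (", x$n_draws, " draws, ", x$direction, ")\n",
      sep = "")
  m <- round(x$P, digits)
  colnames(m) <- paste0("rank", seq_len(ncol(m)))
  print(m)
  invisible(x)
}

#' SUCRA scores from a rank-probability matrix
#'
#' The surface under the cumulative ranking curve for treatment j is
#' \deqn{SUCRA_j = \sum_{r=1}^{a-1} F_{j,r} / (a-1),}
#' where \eqn{F_{j,r}} is the cumulative probability that treatment j ranks
#' r-th or better and a is the number of treatments. SUCRA is 1 for a
#' treatment that is certainly the best and 0 for one that is certainly the
#' worst; the scores always sum to a/2.
#'
#' @param P A \code{rank_prob_matrix} (or a bare rank-probability matrix
#'   with treatments as rows).
#' @return A \code{sucra_table}: data frame with \code{treatment} and
#'   \code{sucra}, ordered by descending SUCRA; the unordered scores are
#'   kept in attribute \code{"scores"}.
#' @export
sucra <- function(P) {
  mat <- if (inherits(P, "rank_prob_matrix")) P$P else as.matrix(P)
  a <- ncol(mat)
  if (a < 2L) stop("SUCRA needs at least two treatments", call. = FALSE)
  scores <- apply(mat, 1L, function(p)
    sum(cumsum(p)[seq_len(a - 1L)]) / (a - 1L))
  out <- data.frame(treatment = rownames(mat), sucra = scores,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$sucra), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, scores = scores, class = c("sucra_table", "data.frame"))
}

#' @export
print.sucra_table <- function(x, ...) {
  cat("SUCRA (descending)\n")
  df <- data.frame(treatment = x$treatment, sucra = sprintf("%.3f", x$sucra))
  print(df, row.names = FALSE)
  invisible(x)
}

#' League table of all pairwise odds ratios, ordered by SUCRA
#'
#' Treatments are listed in descending SUCRA order, so the best-ranked
#' treatment sits at the top left. Each off-diagonal cell summarises the
#' posterior OR of the row treatment vs the column treatment; above the
#' diagonal OR > 1 therefore favours the higher-ranked (top-left) treatment.
#' Cells across the diagonal are exact reciprocals because the OR draws are
#' reciprocal draw by draw and the median is a monotone summary.
#'
#' @param draws An \code{nma_draws} fit (consistency parametrisation).
#' @param sucra_tab The \code{\link{sucra}} table from the same fit.
#' @return A \code{league_table}: list with \code{treatments} (SUCRA order),
#'   \code{median}, \code{cri_low}, \code{cri_high}, \code{significant}
#'   (all n x n matrices, diagonal NA).
#' @export
league_table <- function(draws, sucra_tab) {
  stopifnot(inherits(draws, "nma_draws"),
            inherits(sucra_tab, "sucra_table"))
  trts <- sucra_tab$treatment
  K <- length(trts)
  med <- lo <- hi <- matrix(NA_real_, K, K, dimnames = list(trts, trts))
  sig <- matrix(NA, K, K, dimnames = list(trts, trts))
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i == j) next
    s <- pairwise_or(draws, trts[i], trts[j])
    med[i, j] <- s$median; lo[i, j] <- s$cri_low; hi[i, j] <- s$cri_high
    sig[i, j] <- s$significant
  }
  structure(list(treatments = trts, median = med, cri_low = lo,
                 cri_high = hi, significant = sig),
            class = "league_table")
}

#' @export
print.league_table <- function(x, digits = 2, ...) {
  K <- length(x$treatments)
  m <- matrix("", K, K, dimnames = list(x$treatments, x$treatments))
  for (i in seq_len(K)) for (j in seq_len(K)) {
    m[i, j] <- if (i == j) x$treatments[i] else
      sprintf("%.*f (%.*f-%.*f)", digits, x$median[i, j],
              digits, x$cri_low[i, j], digits, x$cri_high[i, j])
  }
  cat("League table (OR > 1 favours the row = higher-SUCRA treatment)\n")
  print(m, quote = FALSE)
  invisible(x)
}

#' Render a league table as a markdown grid
#'
#' @param lt A \code{league_table}.
#' @param digits Decimal places for ORs (default 2, matching common
#'   reporting precision).
#' @return Character vector of markdown lines.
#' @export
league_markdown <- function(lt, digits = 2) {
  K <- length(lt$treatments)
  cell <- function(i, j) {
    if (i == j) return(paste0("**", lt$treatments[i], "**"))
    sprintf("%.*f (%.*f-%.*f)", digits, lt$median[i, j],
            digits, lt$cri_low[i, j], digits, lt$cri_high[i, j])
  }
  header <- paste0("| ", paste(c("", lt$treatments), collapse = " | "),
                   " |")
  sep <- paste0("|", paste(rep("---", K + 1L), collapse = "|"), "|")
  rows <- vapply(seq_len(K), function(i)
    paste0("| ", paste(c(lt$treatments[i],
                         vapply(seq_len(K), function(j) cell(i, j),
                                character(1))), collapse = " | "), " |"),
    character(1))
  c(header, sep, rows)
}

#' Flatten a league table to long-format data
#'
#' @param x A \code{league_table}.
#' @param ... Unused.
#' @return Data frame with one row per ordered treatment pair.
#' @export
as.data.frame.league_table <- function(x, ...) {
  K <- length(x$treatments)
  idx <- which(upper.tri(x$median) | lower.tri(x$median), arr.ind = TRUE)
  data.frame(
    treatment = x$treatments[idx[, 1L]],
    comparator = x$treatments[idx[, 2L]],
    or_median = x$median[idx],
    cri_low = x$cri_low[idx],
    cri_high = x$cri_high[idx],
    significant = x$significant[idx],
    stringsAsFactors = FALSE
  )
}
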