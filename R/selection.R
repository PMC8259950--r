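# Exact binomial machinery for the neutral-drift criterion and the
# direction-equivalence test on marker tallies.

#' Exact binomial upper tail at p = 1/2
#'
#' `P(X >= k | n, 1/2)`, computed exactly (log-safe for large n).
#'
#' @param k,n Integers, `0 <= k <= n`, `n >= 1`.
#' @return The upper-tail probability.
#' @examples
#' binom_upper_tail(10, 11)  # 12/2048
#' @export
binom_upper_tail <- function(k, n) {
  k <- as.integer(k); n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (k < 0L || k > n) stop("k must satisfy 0 <= k <= n", call. = FALSE)
  if (k == 0L) return(1)
  stats::pbinom(k - 1L, n, 0.5, lower.tail = FALSE)
}

#' Exact two-sided binomial test at p = 1/2
#'
#' Doubled smaller tail, capped at 1:
#' `min(1, 2 * min(P(X <= k), P(X >= k)))`.
#'
#' @param k,n Integers, `0 <= k <= n`, `n >= 1`.
#' @return Two-sided p-value.
#' @export
binom_two_sided <- function(k, n) {
  k <- as.integer(k); n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (k < 0L || k > n) stop("k must satisfy 0 <= k <= n", call. = FALSE)
  lower <- stats::pbinom(k, n, 0.5)
  upper <- binom_upper_tail(k, n)
  min(1, 2 * min(lower, upper))
}

#' Neutral-drift test on improving vs damaging markers
#'
#' Under neutral evolution, variants damaging protein-binding sites are
#' expected to outnumber those improving them. The directional null
#' "improving markers do not outnumber damaging ones" is tested with the
#' one-sided exact binomial `P(X >= n_improve | n, 1/2)`: a large p keeps
#' the tally consistent with drift, a small p signals selection favouring
#' site improvement.
#'
#' @param n_improve,n_damage Counts of significant markers improving /
#'   damaging the TBP-site.
#' @param alpha Level for the drift-consistency verdict.
#' @return Object of class `binomial_result`: `k`, `n`, `p_one_sided`,
#'   `p_two_sided`, `drift_consistent`.
#' @examples
#' neutral_drift_test(14, 37)   # drift-consistent
#' neutral_drift_test(46, 23)   # selection against damage
#' @export
neutral_drift_test <- function(n_improve, n_damage, alpha = 0.05) {
  n <- n_improve + n_damage
  if (n < 1L) stop("need at least one marker", call. = FALSE)
  p1 <- binom_upper_tail(n_improve, n)
  p2 <- binom_two_sided(n_improve, n)
  structure(
    list(k = as.integer(n_improve), n = as.integer(n),
         p_one_sided = p1, p_two_sided = p2,
         drift_consistent = p1 > alpha, alpha = alpha),
    class = "binomial_result"
  )
}

#' @export
print.binomial_result <- function(x, ...) {
  cat(sprintf("exact binomial: k = %d of n = %d (p = 1/2)\n", x$k, x$n))
  cat(sprintf("  one-sided P(X >= k) = %.4g; two-sided = %.4g\n",
              x$p_one_sided, x$p_two_sided))
  if (!is.null(x$drift_consistent)) {
    cat("  verdict:", if (x$drift_consistent) "consistent with neutral drift"
        else "drift rejected (selection)", sprintf("at alpha = %g\n", x$alpha))
  }
  invisible(x)
}

#' Selection-mode summary over marker tallies
#'
#' For each tally row, reports the one-sided drift test on
#' `n_improve` vs `n_damage` and the two-sided direction-equivalence test
#' on `n_aggravate` vs `n_relieve`, with verdicts at `alpha`.
#'
#' @param tallies A [tally_markers()] data frame (or any data frame with
#'   columns `category, n_genes, n_snps, n_sig, n_improve, n_damage,
#'   n_aggravate, n_relieve`).
#' @param alpha Significance level for verdicts.
#' @return `data.frame` of class `selection_summary` with the tally counts,
#'   `p_drift`, `drift_verdict`, `p_equivalence`, `equivalence_verdict`.
#' @export
summarize_selection <- function(tallies, alpha = 0.05) {
  rows <- lapply(seq_len(nrow(tallies)), function(i) {
    t <- tallies[i, ]
    if (t$n_sig == 0L) {
      return(cbind(t, data.frame(
        p_drift = NA_real_, drift_verdict = "no markers",
        p_equivalence = NA_real_, equivalence_verdict = "no markers",
        stringsAsFactors = FALSE)))
    }
    drift <- neutral_drift_test(t$n_improve, t$n_damage, alpha)
    p_eq <- binom_two_sided(t$n_aggravate, t$n_aggravate + t$n_relieve)
    cbind(t, data.frame(
      p_drift = drift$p_one_sided,
      drift_verdict = if (drift$drift_consistent) "neutral drift"
                      else "selection",
      p_equivalence = p_eq,
      equivalence_verdict = if (p_eq < alpha) "directional" else "equivalent",
      stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("selection_summary", "data.frame")
  out
}
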