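# Independent oracles, deliberately written against the exported data
# structures with plain string/loop code, not the package's scan internals.

default_model <- tbp_model()

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1L]]]), collapse = "")
}

oracle_window_score <- function(win, model) {
  p <- model$params
  chars <- strsplit(win, "")[[1L]]
  pwm <- 0
  for (i in seq_along(chars)) pwm <- pwm + model$pwm$weights[i, chars[i]]
  din <- paste0(chars[-length(chars)], chars[-1L])
  p$w0 + p$w_pwm * pwm +
    p$w_ta * mean(model$scales$ta_richness[din]) +
    p$w_mg * mean(model$scales$minor_groove_width[din]) +
    p$w_melt * mean(model$scales$melting[din])
}

# brute-force enumeration of every window on both strands with the tie rule
# (highest score; sense before antisense; smallest offset)
oracle_affinity <- function(seq_str, model, tss_offset = -1L) {
  p <- model$params
  n <- nchar(seq_str)
  recs <- list()
  for (s in seq_len(n - p$L + 1L)) {
    win <- substr(seq_str, s, s + p$L - 1L)
    off <- tss_offset - n + s
    recs[[length(recs) + 1L]] <-
      list(score = oracle_window_score(win, model), off = off, strand = "+")
    if (p$scan_both_strands) {
      recs[[length(recs) + 1L]] <-
        list(score = oracle_window_score(oracle_revcomp(win), model),
             off = off, strand = "-")
    }
  }
  scores <- vapply(recs, `[[`, 0, "score")
  offs <- vapply(recs, `[[`, 0L, "off")
  strands <- vapply(recs, `[[`, "", "strand")
  ord <- order(-scores, strands != "+", offs)
  k <- min(p$top_k_for_se, length(scores))
  top <- sort(scores, decreasing = TRUE)[seq_len(k)]
  list(value = scores[ord[1L]], best_offset = offs[ord[1L]],
       best_strand = strands[ord[1L]],
       stderr = stats::sd(top) / sqrt(k))
}

random_promoter <- function(n = 70L, gc = 0.5) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

# marker-record builder for tally tests (bypasses the affinity model)
make_records <- function(genes, categories, decisions, directions,
                         ra_directions) {
  data.frame(snp_id = sprintf("s%03d", seq_along(genes)), gene = genes,
             category = categories, decision = decisions,
             site_direction = directions, ra_direction = ra_directions,
             stringsAsFactors = FALSE)
}

# Genome-scale marker tallies as printed: counts only, used as reference
# constants for the selection-mode statistics.
table2_counts <- function() {
  data.frame(
    row = c(1L, 2L, 3L, 4L, 5L, 6L, 7L),
    n_improve = c(200L, 14L, 12L, 84L, 46L, 71L, 104L),
    n_damage = c(800L, 37L, 30L, 70L, 23L, 43L, 75L),
    n_aggravate = c(NA, NA, 32L, 96L, 42L, 71L, 70L),
    n_relieve = c(NA, NA, 10L, 58L, 27L, 43L, 109L)
  )
}
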