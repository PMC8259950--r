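# Cross-validation of disease-direction markers against domestic-vs-wild
# differential-expression (DEG) tables: filter, pair orthologs, call the
# divergence direction of each lineage from the nearest common ancestor,
# map both lineages to disease directions through the human annotation,
# and test the resulting 2x2 lineage-by-effect table.

#' Filter DEG records by adjusted significance
#'
#' Keeps records with `p_adj <= threshold` (inclusive, so records printed
#' at exactly the threshold survive); input order is preserved.
#'
#' @param degs DEG `data.frame` with at least `gene` and `p_adj` columns.
#' @param threshold Adjusted-p cutoff, default 0.05.
#' @return The filtered data frame.
#' @export
filter_degs <- function(degs, threshold = 0.05) {
  degs[!is.na(degs$p_adj) & degs$p_adj <= threshold, , drop = FALSE]
}

#' Default species-symbol alias table
#'
#' Animal symbols that map to a differently named human ortholog
#' (beyond case normalization), e.g. the hemoglobin paralog symbol
#' `Hbbl` -> `HBB`.
#'
#' @return Named character vector (animal symbol -> human symbol), keys
#'   uppercased.
#' @export
default_ortholog_aliases <- function() {
  c(HBBL = "HBB")
}

#' Pair animal DEGs with annotated human genes
#'
#' Case-insensitive symbol matching after applying the alias table.
#' Unmatched DEGs are reported, not fatal.
#'
#' @param degs DEG `data.frame` (column `gene`).
#' @param catalog A [gene_catalog()] of human annotations.
#' @param aliases Named character vector of symbol aliases
#'   ([default_ortholog_aliases()] by default).
#' @return List with `pairs` (the DEG rows that matched, plus a
#'   `human_gene` column) and `unmatched` (character vector of symbols).
#' @export
map_orthologs <- function(degs, catalog, aliases = default_ortholog_aliases()) {
  key <- toupper(degs$gene)
  ali <- aliases[key]
  key[!is.na(ali)] <- ali[!is.na(ali)]
  hit <- key %in% rownames(catalog)
  pairs <- degs[hit, , drop = FALSE]
  pairs$human_gene <- key[hit]
  list(pairs = pairs, unmatched = unique(degs$gene[!hit]))
}

#' Call the divergence direction of a DEG
#'
#' Interprets a domestic-vs-wild log2 fold change as expression divergence
#' from the nearest common ancestor: a positive log2fc means the domestic
#' lineage is in excess and the wild lineage in deficit, and vice versa.
#' A zero log2fc is ambiguous and rejected.
#'
#' @param log2fc Numeric vector of log2 fold changes (domestic over wild).
#' @return `data.frame` with `domestic_state` and `wild_state`
#'   (`"excess"` / `"deficit"`, always complementary).
#' @export
call_divergence <- function(log2fc) {
  if (any(!is.finite(log2fc))) stop("log2fc must be finite", call. = FALSE)
  if (any(log2fc == 0)) {
    stop("log2fc = 0 is direction-ambiguous; exclude the record",
         call. = FALSE)
  }
  data.frame(
    domestic_state = ifelse(log2fc > 0, "excess", "deficit"),
    wild_state = ifelse(log2fc > 0, "deficit", "excess"),
    stringsAsFactors = FALSE
  )
}

#' Map a divergence call to disease directions for both lineages
#'
#' Each lineage's expression state (deficit or excess) is translated into
#' a disease direction through the human gene's annotation.
#'
#' @param call One-row result of [call_divergence()] (or a list with
#'   `domestic_state`, `wild_state`).
#' @param ann One catalog row (from [gene_catalog()]).
#' @return List with `domestic_effect` and `wild_effect`, each
#'   `"aggravate"` or `"relieve"`.
#' @export
map_ra_effect <- function(call, ann) {
  pick <- function(state) {
    if (state == "deficit") ann$deficit_effect else ann$excess_effect
  }
  list(domestic_effect = pick(call$domestic_state),
       wild_effect = pick(call$wild_state))
}

#' Build the lineage-by-effect contingency table
#'
#' @param effects `data.frame` with columns `domestic_effect` and
#'   `wild_effect` (one row per ortholog pair).
#' @return 2x2 integer matrix, rows `domestic`/`wild`, columns
#'   `aggravate`/`relieve`; each pair contributes one count per row.
#' @export
build_contingency <- function(effects) {
  if (!nrow(effects)) stop("need at least one ortholog pair", call. = FALSE)
  lev <- c("aggravate", "relieve")
  tab <- rbind(
    domestic = table(factor(effects$domestic_effect, levels = lev)),
    wild = table(factor(effects$wild_effect, levels = lev))
  )
  matrix(as.integer(tab), nrow = 2L,
         dimnames = list(c("domestic", "wild"), lev))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Standard Pearson statistic with optional Yates continuity correction
#' (|O - E| reduced by 0.5 before squaring), p-value from the chi-square
#' distribution with 1 degree of freedom.
#'
#' @param table 2x2 matrix of non-negative counts with positive margins.
#' @param yates Apply the continuity correction (default `FALSE`).
#' @return List with `statistic` and `p_value`.
#' @export
pearson_chi2 <- function(table, yates = FALSE) {
  check_2x2(table)
  res <- suppressWarnings(stats::chisq.test(table, correct = yates))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

check_2x2 <- function(table) {
  if (!is.matrix(table) || any(dim(table) != 2L)) {
    stop("expected a 2x2 matrix", call. = FALSE)
  }
  if (any(table < 0) || any(table != round(table))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate table: zero margin", call. = FALSE)
  }
  invisible(table)
}

#' Fisher's exact test on a 2x2 table (two-sided)
#'
#' Enumerates every table compatible with the observed margins under the
#' hypergeometric null and sums the point probabilities not exceeding the
#' observed one (with the conventional relative tolerance of 1e-7 for
#' floating-point ties).
#'
#' @param table 2x2 matrix of non-negative counts with positive margins.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(10, 1, 3, 8), 2, 2, byrow = TRUE))
#' @export
fisher_exact <- function(table) {
  check_2x2(table)
  m <- sum(table[1, ])          # row 1 total
  n2 <- sum(table[2, ])         # row 2 total
  k <- sum(table[, 1])          # column 1 total
  a <- table[1, 1]
  support <- max(0L, k - n2):min(m, k)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Cross-validation report: DEGs vs disease-direction annotations
#'
#' Runs the full six-step chain: filter DEGs at `p_threshold`, pair
#' orthologs with the human catalog, call per-lineage divergence
#' directions, map both lineages to disease directions, build the 2x2
#' lineage-by-effect table, and test it (Pearson chi-square with and
#' without Yates correction, two-sided Fisher exact, and a one-sided
#' exact binomial per lineage row on its larger cell).
#'
#' @param degs DEG `data.frame` with columns `gene, log2fc, p_adj` (and
#'   optionally `dataset_id, domestic_label, wild_label, tissue`).
#' @param catalog A [gene_catalog()].
#' @param alpha Significance level reported with the verdicts.
#' @param p_threshold DEG adjusted-p cutoff (inclusive), default 0.05.
#' @param aliases Ortholog symbol aliases.
#' @return Object of class `crossval_result`: the contingency `table`,
#'   `chi2_stat`, `chi2_p`, `chi2_yates_stat`, `chi2_yates_p`,
#'   `fisher_p_two_sided`, `binom_p_domestic`, `binom_p_wild`, the paired
#'   records (`pairs`), and `unmatched` symbols. Single-pair inputs are
#'   flagged `degenerate` and skip the chi-square/Fisher tests.
#' @export
crossval_report <- function(degs, catalog, alpha = 0.05, p_threshold = 0.05,
                            aliases = default_ortholog_aliases()) {
  kept <- filter_degs(degs, p_threshold)
  kept <- kept[kept$log2fc != 0, , drop = FALSE]
  mapped <- map_orthologs(kept, catalog, aliases)
  pairs <- mapped$pairs
  if (!nrow(pairs)) stop("no ortholog pairs after filtering", call. = FALSE)
  div <- call_divergence(pairs$log2fc)
  eff <- lapply(seq_len(nrow(pairs)), function(i) {
    ann <- catalog_lookup(catalog, pairs$human_gene[i])
    map_ra_effect(div[i, ], ann)
  })
  effects <- data.frame(
    gene = pairs$human_gene,
    domestic_state = div$domestic_state, wild_state = div$wild_state,
    domestic_effect = vapply(eff, `[[`, "", "domestic_effect"),
    wild_effect = vapply(eff, `[[`, "", "wild_effect"),
    stringsAsFactors = FALSE
  )
  tab <- build_contingency(effects)
  degenerate <- nrow(pairs) < 2L || any(colSums(tab) == 0)
  if (!degenerate) {
    chi <- pearson_chi2(tab, yates = FALSE)
    chi_y <- pearson_chi2(tab, yates = TRUE)
    fish <- fisher_exact(tab)
  } else {
    chi <- chi_y <- list(statistic = NA_real_, p_value = NA_real_)
    fish <- NA_real_
  }
  structure(
    list(table = tab,
         chi2_stat = chi$statistic, chi2_p = chi$p_value,
         chi2_yates_stat = chi_y$statistic, chi2_yates_p = chi_y$p_value,
         fisher_p_two_sided = fish,
         binom_p_domestic = binom_upper_tail(max(tab[1, ]), sum(tab[1, ])),
         binom_p_wild = binom_upper_tail(max(tab[2, ]), sum(tab[2, ])),
         n_pairs = nrow(pairs), pairs = effects,
         unmatched = mapped$unmatched, alpha = alpha,
         degenerate = degenerate),
    class = "crossval_result"
  )
}

#' @export
print.crossval_result <- function(x, ...) {
  cat("Lineage x disease-effect cross-validation (", x$n_pairs,
      " ortholog pairs)\n", sep = "")
  print(x$table)
  if (x$degenerate) {
    cat("  degenerate table: chi-square / Fisher tests skipped\n")
  } else {
    cat(sprintf("  Pearson chi2 = %.3f (p = %.3g); Yates chi2 = %.3f\n",
                x$chi2_stat, x$chi2_p, x$chi2_yates_stat))
    cat(sprintf("  Fisher exact (two-sided) p = %.3g\n", x$fisher_p_two_sided))
  }
  cat(sprintf("  row binomials: domestic p = %.3g, wild p = %.3g\n",
              x$binom_p_domestic, x$binom_p_wild))
  if (length(x$unmatched)) {
    cat("  unmatched DEG symbols:", paste(x$unmatched, collapse = ", "), "\n")
  }
  invisible(x)
}
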