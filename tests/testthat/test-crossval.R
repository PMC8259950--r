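fx <- fixture_table3()

test_that("DEG filtering is inclusive at the threshold", {
  df <- data.frame(gene = c("a", "b", "c"), log2fc = c(1, -1, 2),
                   p_adj = c(0.05, 0.06, 0.01))
  kept <- filter_degs(df)
  expect_equal(kept$gene, c("a", "c"))
  expect_equal(nrow(filter_degs(df[0, ])), 0L)
  expect_equal(nrow(filter_degs(fx$degs)), 11L)
})

test_that("ortholog pairing is case-insensitive with alias support", {
  mapped <- map_orthologs(fx$degs, fx$catalog)
  expect_equal(nrow(mapped$pairs), 11L)
  expect_equal(mapped$pairs$human_gene[mapped$pairs$gene == "Npy"], "NPY")
  expect_equal(mapped$pairs$human_gene[mapped$pairs$gene == "Hbbl"], "HBB")
  stranger <- rbind(fx$degs,
                    data.frame(dataset_id = "x", domestic_label = "d",
                               wild_label = "w", tissue = "t",
                               gene = "Nosuch", log2fc = 1, p_adj = 0.01))
  mapped2 <- map_orthologs(stranger, fx$catalog)
  expect_equal(mapped2$unmatched, "Nosuch")
})

test_that("divergence calls follow the fold-change sign", {
  div <- call_divergence(c(0.4, -5.9))
  expect_equal(div$domestic_state, c("excess", "deficit"))
  expect_equal(div$wild_state, c("deficit", "excess"))
  expect_error(call_divergence(0), "ambiguous")
})

test_that("lineage states map to disease effects through the annotation", {
  cat <- fx$catalog
  esr2 <- map_ra_effect(list(domestic_state = "deficit",
                             wild_state = "excess"), cat["ESR2", ])
  expect_equal(esr2, list(domestic_effect = "aggravate",
                          wild_effect = "relieve"))
  pdyn <- map_ra_effect(list(domestic_state = "excess",
                             wild_state = "deficit"), cat["PDYN", ])
  expect_equal(pdyn, list(domestic_effect = "relieve",
                          wild_effect = "aggravate"))
  cetp <- map_ra_effect(list(domestic_state = "excess",
                             wild_state = "deficit"), cat["CETP", ])
  expect_equal(cetp$domestic_effect, "aggravate")
  expect_equal(cetp$wild_effect, "aggravate")
})

test_that("the ortholog fixture builds the published 2x2 table exactly", {
  cv <- crossval_report(fx$degs, fx$catalog)
  expect_equal(unname(cv$table),
               matrix(c(10L, 3L, 1L, 8L), 2L, 2L))
  expect_equal(rowSums(cv$table), c(domestic = 11, wild = 11))
})

test_that("chi-square statistics match hand computation", {
  tab <- matrix(c(10, 1, 3, 8), 2, 2, byrow = TRUE)
  flat <- matrix(c(5, 5, 5, 5), 2, 2)
  expect_equal(pearson_chi2(flat)$statistic, 0)
  expect_equal(pearson_chi2(flat)$p_value, 1)
  chi <- pearson_chi2(tab, yates = FALSE)
  expect_equal(chi$statistic, 9.2137, tolerance = 1e-4)
  expect_equal(round(chi$statistic), 9)
  chi_y <- pearson_chi2(tab, yates = TRUE)
  expect_equal(chi_y$statistic, 6.769, tolerance = 1e-3)
  expect_error(pearson_chi2(matrix(c(0, 0, 3, 8), 2, 2, byrow = TRUE)),
               "margin")
})

test_that("fisher_exact enumerates the hypergeometric two-sided p", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2, 2)), 1)
  expect_equal(fisher_exact(matrix(c(10, 1, 3, 8), 2, 2, byrow = TRUE)),
               0.007519, tolerance = 1e-4)
})

test_that("fisher_exact and pearson_chi2 agree with stats oracles on random tables", {
  set.seed(99)
  n_checked <- 0L
  while (n_checked < 200L) {
    tab <- matrix(rpois(4, 3), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    n_checked <- n_checked + 1L
    expect_equal(fisher_exact(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-10)
    ours <- pearson_chi2(tab, yates = FALSE)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, unname(ref$p.value))
  }
})

test_that("transposing lineages swaps row binomials, leaves chi2/Fisher", {
  flipped <- fx$degs
  flipped$log2fc <- -flipped$log2fc   # relabel which side is domestic
  cv <- crossval_report(fx$degs, fx$catalog)
  cvf <- crossval_report(flipped, fx$catalog)
  expect_equal(cvf$table["domestic", ], cv$table["wild", ])
  expect_equal(cvf$binom_p_domestic, cv$binom_p_wild)
  expect_equal(cvf$binom_p_wild, cv$binom_p_domestic)
  expect_equal(cvf$chi2_stat, cv$chi2_stat)
  expect_equal(cvf$fisher_p_two_sided, cv$fisher_p_two_sided)
})

test_that("row binomials match the exact one-sided tails", {
  cv <- crossval_report(fx$degs, fx$catalog)
  expect_equal(cv$binom_p_domestic, 12 / 2048)
  expect_equal(cv$binom_p_wild, 0.1133, tolerance = 1e-3)
})

test_that("randomly relabelling lineages gives null-like Fisher p-values", {
  cv <- crossval_report(fx$degs, fx$catalog)
  eff <- cv$pairs
  set.seed(123)
  rejections <- 0L
  n_shuffles <- 400L
  for (b in seq_len(n_shuffles)) {
    swap <- runif(nrow(eff)) < 0.5
    dom <- ifelse(swap, eff$wild_effect, eff$domestic_effect)
    wld <- ifelse(swap, eff$domestic_effect, eff$wild_effect)
    tab <- build_contingency(data.frame(domestic_effect = dom,
                                        wild_effect = wld))
    if (any(colSums(tab) == 0)) next
    if (fisher_exact(tab) < 0.05) rejections <- rejections + 1L
  }
  expect_lt(rejections / n_shuffles, 0.075)
})

test_that("single-pair input is flagged degenerate without crashing", {
  one <- fx$degs[fx$degs$gene == "Npy", ]
  cv <- crossval_report(one, fx$catalog)
  expect_true(cv$degenerate)
  expect_true(is.na(cv$chi2_stat))
  expect_equal(unname(rowSums(cv$table)), c(1, 1))
})

test_that("an effect-inverted catalog swaps the contingency columns", {
  cv <- crossval_report(fx$degs, fx$catalog)
  cvi <- crossval_report(fx$degs, invert_catalog(fx$catalog))
  expect_equal(cvi$table[, "aggravate"], cv$table[, "relieve"])
  expect_equal(cvi$table[, "relieve"], cv$table[, "aggravate"])
})
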