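planted_promoter <- function(seed = 1) {
  spec <- synthetic_spec(seed = seed, n_promoters = 1)
  gen_promoters(spec)[[1L]]
}

test_that("point substitutions edit exactly one base", {
  pr <- planted_promoter()
  ref <- substr(pr$sequence, 41, 41)   # offset -30 of a 70-bp promoter
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1L]
  edited <- apply_variant(pr, snp_spec("s1", -30L, ref, alt))
  expect_equal(nchar(edited$sequence), 70L)
  expect_equal(substr(edited$sequence, 41, 41), alt)
  expect_equal(substr(edited$sequence, 1, 40), substr(pr$sequence, 1, 40))
  expect_equal(substr(edited$sequence, 42, 70), substr(pr$sequence, 42, 70))
})

test_that("reference mismatches are rejected with offset and bases named", {
  pr <- planted_promoter()
  ref <- substr(pr$sequence, 41, 41)
  wrong <- setdiff(c("A", "C", "G", "T"), ref)[1L]
  expect_error(apply_variant(pr, snp_spec("s1", -30L, wrong, "A")),
               "mismatch.*-30", ignore.case = TRUE)
})

test_that("an 18-bp deletion spanning the box shortens and weakens the promoter", {
  pr <- planted_promoter()
  ref <- substr(pr$sequence, 36, 53)   # offsets -35..-18, covers the box
  edited <- apply_variant(pr, snp_spec("del18", -35L, ref, ""))
  expect_equal(nchar(edited$sequence), 52L)
  expect_lt(estimate_affinity(edited, default_model)$value,
            estimate_affinity(pr, default_model)$value)
})

test_that("insertions lengthen the sequence; over-short edits are rejected", {
  pr <- planted_promoter()
  ins <- apply_variant(pr, snp_spec("ins", -10L, "", "ACGT"))
  expect_equal(nchar(ins$sequence), 74L)
  short <- promoter_sequence("S", strrep("ACGT", 4))   # 16 bp
  expect_error(apply_variant(short, snp_spec("d", -10L,
                             substr(short$sequence, 7, 10), "")),
               "shorter")
  expect_error(snp_spec("x", -5L, "", ""), "both be empty")
})

test_that("fisher_z_compare matches the closed-form normal tail", {
  eq <- fisher_z_compare(list(value = 5, stderr = 0.2),
                         list(value = 5, stderr = 0.2))
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)
  fz <- fisher_z_compare(list(value = 6, stderr = 0.1),
                         list(value = 5, stderr = 0.1))
  expect_equal(fz$z, 7.0711, tolerance = 1e-4)
  expect_equal(fz$p_value, 1.537e-12, tolerance = 1e-3)
  sw <- fisher_z_compare(list(value = 5, stderr = 0.1),
                         list(value = 6, stderr = 0.1))
  expect_equal(sw$z, fz$z)
  expect_equal(sw$p_value, fz$p_value)
})

test_that("zero-stderr disagreement is flagged degenerate with p = 0", {
  expect_warning(
    res <- fisher_z_compare(list(value = 6, stderr = 0),
                            list(value = 5, stderr = 0)),
    "infinite Z")
  expect_true(res$degenerate)
  expect_equal(res$p_value, 0)
})

test_that("an identity variant is insignificant with z = 0", {
  pr <- planted_promoter()
  ref <- substr(pr$sequence, 41, 41)
  cmp <- compare_alleles(pr, snp_spec("id", -30L, ref, ref), default_model)
  expect_equal(cmp$z, 0)
  expect_equal(cmp$decision, "insignificant")
  expect_equal(cmp$site_direction, "unchanged")
})

test_that("damaging the planted consensus core yields a deficiency call", {
  pr <- planted_promoter(seed = 3)
  # offset -30 holds the first T of TATAAAAG; C is its worst base
  cmp <- compare_alleles(pr, snp_spec("dmg", -30L, "T", "C"), default_model)
  expect_equal(cmp$decision, "deficiency")
  expect_equal(cmp$site_direction, "damaged")
  expect_lt(cmp$min$value, cmp$wt$value)
})

test_that("swapping which allele is ancestral flips the decision, not z or p", {
  pr <- planted_promoter(seed = 3)
  fwd <- compare_alleles(pr, snp_spec("dmg", -30L, "T", "C"), default_model)
  min_pr <- apply_variant(pr, snp_spec("dmg", -30L, "T", "C"))
  rev <- compare_alleles(min_pr, snp_spec("dmg", -30L, "C", "T"),
                         default_model)
  expect_equal(rev$z, fwd$z)
  expect_equal(rev$p_value, fwd$p_value)
  expect_equal(fwd$decision, "deficiency")
  expect_equal(rev$decision, "excess")
})

test_that("substitutions far from every scoring site are insignificant", {
  spec <- synthetic_spec(seed = 8, n_promoters = 30, n_neutral = 10)
  prom <- gen_promoters(spec)
  snps <- gen_snps(spec, prom, default_model)
  res <- compare_snp_table(prom, snps, default_model)
  expect_true(all(abs(res$wt_value - res$min_value) < 1e-9 |
                  res$decision == "insignificant"))
})

test_that("p decreases monotonically in the affinity difference", {
  deltas <- seq(0.2, 3, by = 0.4)
  ps <- vapply(deltas, function(d) {
    fisher_z_compare(list(value = 10 + d, stderr = 0.3),
                     list(value = 10, stderr = 0.3))$p_value
  }, 0)
  expect_true(all(diff(ps) < 0))
})
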