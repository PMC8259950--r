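test_that("with all sequence weights zero every window scores w0", {
  params <- affinity_params(w0 = 7.5, w_pwm = 0, w_ta = 0, w_mg = 0,
                            w_melt = 0)
  m <- tbp_model(params = params)
  set.seed(11)
  for (i in 1:5) {
    expect_equal(window_score(random_promoter(15), m), 7.5)
  }
})

test_that("the consensus window outscores its shuffle", {
  expect_gt(window_score("TATAAAAGGCGGGGC", default_model),
            window_score("GGTGAGAACGATGCA", default_model))
})

test_that("explain mode decomposes the score additively", {
  s <- window_score("TATAAAAGGCGGGGC", default_model, explain = TRUE)
  expect_equal(sum(attr(s, "terms")), as.numeric(s))
})

test_that("a homopolymer promoter scans flat: zero stderr, 5'-most best site", {
  est <- estimate_affinity(promoter_sequence("POLYA", strrep("A", 70)),
                           default_model)
  expect_equal(est$stderr, 0)
  expect_equal(est$best_offset, -70L)
})

test_that("estimate_affinity matches the brute-force window oracle", {
  set.seed(101)
  for (i in 1:100) {
    s <- random_promoter(70L, gc = runif(1, 0.25, 0.7))
    est <- estimate_affinity(promoter_sequence("R", s), default_model)
    orc <- oracle_affinity(s, default_model)
    expect_equal(est$value, orc$value)
    expect_equal(est$best_offset, orc$best_offset)
    expect_equal(est$best_strand, orc$best_strand)
    expect_equal(est$stderr, orc$stderr)
  }
})

test_that("affinity is strand-symmetric when both strands are scanned", {
  set.seed(202)
  for (i in 1:25) {
    s <- random_promoter(70L)
    expect_equal(estimate_affinity(s, default_model)$value,
                 estimate_affinity(reverse_complement(s), default_model)$value)
  }
})

test_that("planting the TATA consensus raises the affinity of any background", {
  set.seed(303)
  for (i in 1:50) {
    bg <- random_promoter(70L)
    planted <- paste0(substr(bg, 1, 40), "TATAAAAG", substr(bg, 49, 70))
    expect_gt(estimate_affinity(planted, default_model)$value,
              estimate_affinity(bg, default_model)$value)
  }
})

test_that("substituting the PWM-argmax base in the best window never lowers value", {
  cons <- pwm_consensus(default_model$pwm)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  set.seed(404)
  for (i in 1:20) {
    s <- random_promoter(70L)
    pr <- promoter_sequence("R", s)
    est <- estimate_affinity(pr, default_model)
    start <- est$best_offset + 71L   # string index of the window's 5' base
    for (row in seq_len(default_model$params$L)) {
      # map the PWM row to the sense-strand base it constrains
      if (est$best_strand == "+") {
        idx <- start + row - 1L
        base <- cons[row]
      } else {
        idx <- start + default_model$params$L - row
        base <- comp[[cons[row]]]
      }
      edited <- s
      substr(edited, idx, idx) <- base
      expect_gte(estimate_affinity(edited, default_model)$value, est$value)
    }
  }
})

test_that("ties go to the smallest offset", {
  # two identical planted boxes in an otherwise constant background
  bg <- strrep("C", 70)
  two <- bg
  substr(two, 6, 13) <- "TATAAAAG"
  substr(two, 41, 48) <- "TATAAAAG"
  est <- estimate_affinity(promoter_sequence("TIE", two), default_model)
  expect_equal(est$best_offset, 6L - 71L)
  expect_equal(est$best_strand, "+")
})

test_that("scoring is deterministic and rejects short input", {
  s <- random_promoter(70L)
  e1 <- estimate_affinity(s, default_model)
  e2 <- estimate_affinity(s, default_model)
  expect_identical(e1, e2)
  expect_error(estimate_affinity(strrep("A", 10), default_model), "shorter")
  expect_error(window_score("ACGT", default_model), "length L")
})

test_that("predict() scores a promoter list rowwise", {
  spec <- synthetic_spec(seed = 5, n_promoters = 4)
  prom <- gen_promoters(spec)
  df <- predict(default_model, prom)
  expect_equal(nrow(df), 4L)
  expect_equal(df$value[1], estimate_affinity(prom[[1]], default_model)$value)
})
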