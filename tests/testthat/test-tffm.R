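test_that("model constructors validate their probability structure", {
  bad_row <- toy_tffm()$motif_conditional
  bad_row[[1]][1, ] <- c(0.5, 0.2, 0.1, 0.1)  # sums to 0.9
  expect_error(tffm_first_order(bad_row), "row-stochastic")
  expect_error(tffm_first_order(toy_tffm()$motif_conditional,
                                bg_emission = c(.5, .5, .2, .2)),
               "sum")
  expect_error(tffm_first_order(toy_tffm()$motif_conditional,
                                self_transition = 0.9, motif_entry = 0.2),
               "sum")
  d <- build_detailed_from_first_order(toy_tffm())
  bad <- d$transition
  bad[5, ] <- bad[5, ] * 0.9
  expect_error(tffm_detailed(bad), "sum to 1")
})

test_that("whole-sequence posteriors match brute-force path enumeration", {
  set.seed(11)
  for (r in 1:12) {
    L <- sample(1:3, 1)
    m <- make_tffm(r * 37L, L, dependency_strength = stats::runif(1),
                   self_transition = stats::runif(1, 0.6, 0.95),
                   motif_entry = stats::runif(1, 0.01, 0.05))
    s <- paste(sample(c("A", "C", "G", "T"), sample(4:7, 1), replace = TRUE),
               collapse = "")
    expect_equal(tffm_posterior_scores(m, s), oracle_fo_posterior(m, s),
                 tolerance = 1e-9)
  }
  # detailed flavour against its own enumeration oracle
  for (r in 1:4) {
    m <- make_tffm(r * 101L, 1L, dependency_strength = stats::runif(1))
    d <- build_detailed_from_first_order(m)
    s <- paste(sample(c("A", "C", "G", "T"), 5, replace = TRUE), collapse = "")
    expect_equal(tffm_posterior_scores(d, s), oracle_detailed_posterior(d, s),
                 tolerance = 1e-9)
  }
})

test_that("posterior edge cases behave as documented", {
  m <- toy_tffm()
  # unreachable motif: zero entry probability
  m0 <- tffm_first_order(m$motif_conditional, m$bg_emission,
                         m$bg_conditional, self_transition = 0.95,
                         motif_entry = 0)
  expect_equal(tffm_posterior_scores(m0, "ACGTACGT"), rep(0, 8))
  # all-N input: uniform substitution keeps posteriors in [0, 1]
  pN <- tffm_posterior_scores(m, "NNNNNN")
  expect_true(all(pN >= 0 & pN <= 1))
  # shorter than the motif: empty result with a warning
  expect_warning(out <- tffm_posterior_scores(m, "A"), "shorter")
  expect_identical(out, numeric(0))
  # posteriors are probabilities
  p <- tffm_posterior_scores(m, "CACGTGCA")
  expect_true(all(p >= 0 & p <= 1))
})

test_that("detailed decomposition preserves sequence likelihoods", {
  m <- toy_tffm()
  d <- build_detailed_from_first_order(m)
  expect_s3_class(d, "tffm_detailed")

  # L = 1 model: 8 states, likelihood equal on all 64 3-mers
  m1 <- make_tffm(5L, 1L, dependency_strength = 0.7)
  d1 <- build_detailed_from_first_order(m1)
  expect_identical(nrow(d1$transition), 8L)
  for (w in all_kmers(3)) {
    expect_equal(tffm_sequence_loglik(m1, w), tffm_sequence_loglik(d1, w),
                 tolerance = 1e-9)
  }

  # uniform first-order model: motif transition blocks are flat 0.25
  flat <- matrix(0.25, 4, 4)
  mu <- tffm_first_order(list(flat, flat),
                         bg_emission = c(A = .25, C = .25, G = .25, T = .25),
                         self_transition = 0.9, motif_entry = 0.1)
  du <- build_detailed_from_first_order(mu)
  expect_equal(unname(du$transition[5:8, 9:12]), flat)
  expect_equal(unname(du$transition[9:12, 1:4]),
               matrix(0.25, 4, 4))

  # likelihood equality on random sequences of mixed length
  set.seed(23)
  for (r in 1:100) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(2:6, 1), replace = TRUE),
               collapse = "")
    expect_equal(tffm_sequence_loglik(m, s), tffm_sequence_loglik(d, s),
                 tolerance = 1e-9)
  }
})

test_that("local window scores match their two-hypothesis definition", {
  m <- toy_tffm()
  seq <- "TTGACGTACCA"
  sc <- window_scores(m, seq)
  expect_length(sc, nchar(seq) - m$L + 1L)
  manual <- vapply(seq_along(sc), function(p) {
    ctx <- if (p == 1L) NULL else substr(seq, p - 1L, p - 1L)
    oracle_window_score(m, substr(seq, p, p + m$L - 1L), ctx)
  }, numeric(1))
  expect_equal(sc, manual, tolerance = 1e-12)
  expect_true(all(sc >= 0 & sc <= 1))

  # detailed decomposition scores windows identically
  d <- build_detailed_from_first_order(m)
  expect_equal(window_scores(d, seq), sc, tolerance = 1e-12)

  # a window's score depends only on its content and context base
  seq2 <- paste0("GGGG", substr(seq, 1, 6), "TTTTT")
  expect_equal(window_scores(m, seq2)[6], sc[2])
})
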