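plant_in <- function(background, word, at) {
  # at = 0-based offset of the word start
  stopifnot(at + nchar(word) <= nchar(background))
  substr(background, at + 1L, at + nchar(word)) <- word
  background
}

test_that("the scan finds a planted consensus at and around the variant", {
  word <- "ACGTAGCA"
  p <- word_pwm(word)
  cfg <- scan_config()
  set.seed(401)
  n <- 80L
  vo <- 40L                                  # variant offset, 0-based
  bg <- random_dna(n)
  while (max(window_scores(p, bg)) == 1) bg <- random_dna(n)

  hit <- best_window_score(p, plant_in(bg, word, vo), vo, cfg)
  expect_identical(hit$score, 1)
  expect_identical(hit$offset, 0L)
  expect_identical(hit$strand, "+")

  # reverse-complement planting is found via the minus strand
  hit_rc <- best_window_score(p, plant_in(bg, rc(word), vo), vo, cfg)
  expect_identical(hit_rc$score, 1)
  expect_identical(hit_rc$offset, 0L)
  expect_identical(hit_rc$strand, "-")

  # the window range boundary: offsets -15 and +15 in, -16 and +16 out
  for (k in c(-15L, 15L)) {
    h <- best_window_score(p, plant_in(bg, word, vo + k), vo, cfg)
    expect_identical(h$score, 1)
    expect_identical(h$offset, k)
  }
  for (k in c(-16L, 16L)) {
    h <- best_window_score(p, plant_in(bg, word, vo + k), vo, cfg)
    expect_lt(h$score, 1)
  }
})

test_that("window ties break towards the smallest |offset|, then forward strand", {
  word <- "ACGTAGCA"
  p <- word_pwm(word)
  cfg <- scan_config()
  bg <- strrep("C", 80)                       # no chance consensus in C-runs
  vo <- 40L
  two <- plant_in(plant_in(bg, word, vo - 10L), word, vo + 4L)
  h <- best_window_score(p, two, vo, cfg)
  expect_identical(h$offset, 4L)              # |4| < |-10|
  both_signs <- plant_in(plant_in(bg, word, vo - 6L), word, vo + 6L)
  h2 <- best_window_score(p, both_signs, vo, cfg)
  expect_identical(h2$offset, -6L)            # tie on |offset|: negative first
  palin <- plant_in(bg, paste0(word, rc(word)), vo)  # fwd and rc hit at once
  h3 <- best_window_score(p, palin, vo, cfg)
  expect_identical(h3$strand, "+")
})

test_that("no scorable window yields score 0 with a warning", {
  p <- word_pwm("ACGTAGCA")
  expect_warning(h <- best_window_score(p, "ACG", 1L), "no scorable window")
  expect_identical(h$score, 0)
  expect_true(is.na(h$offset))
})

test_that("scan_variant scores reference and variant sequence per model", {
  word <- "ACGTAGCA"
  p <- word_pwm(word)
  t1 <- make_tffm(77L, 8L, 0, motif_probs = {
    idx <- match(strsplit(word, "")[[1]], c("A", "C", "G", "T"))
    vapply(idx, function(b) { v <- rep(0.02, 4); v[b] <- 0.94; v }, numeric(4))
  }, tf_name = "PLANT", model_id = "PLANT.t1")
  set.seed(402)
  bg <- random_dna(90)
  while (max(window_scores(p, bg)) == 1) bg <- random_dna(90)
  vo <- 45L

  # loss: consensus in WT destroyed at a maximally informative column
  wt <- plant_in(bg, word, vo)
  mt <- wt
  substr(mt, vo + 1L, vo + 1L) <- "T"         # consensus A -> anti-consensus
  out <- scan_variant(sequence_pair(wt, mt, vo, "A", "T"), list(p, t1))
  expect_identical(nrow(out), 2L)
  expect_true(all(out$S < 0))
  expect_identical(out$WT[out$model_id == "PLANT.pwm"], 1)

  # gain: the mirrored fixture
  out_gain <- scan_variant(sequence_pair(mt, wt, vo, "T", "A"), list(p, t1))
  expect_true(all(out_gain$S > 0))
  expect_equal(out_gain$S, -out$S, tolerance = 1e-12)

  # a difference outside every scorable window forces S = 0 exactly
  far <- nchar(wt) - 1L                       # last base, > vo + 15 + L - 1
  mt_far <- wt
  substr(mt_far, far + 1L, far + 1L) <- setdiff(c("A", "C", "G", "T"),
                                                substr(wt, far + 1L, far + 1L))[1]
  pair_far <- sequence_pair(wt, mt_far, vo,
                            substr(wt, vo + 1L, far + 1L),
                            substr(mt_far, vo + 1L, far + 1L))
  out_far <- scan_variant(pair_far, list(p, t1))
  expect_identical(out_far$S, c(0, 0))
})

test_that("scanning is invariant under reverse-complementing both sequences", {
  word <- "ACGTAGCA"
  models <- list(word_pwm(word), toy_tffm())
  set.seed(403)
  for (r in 1:5) {
    bg <- random_dna(70)
    vo <- 35L
    wt <- plant_in(bg, word, vo - sample(0:10, 1))
    mt <- wt
    substr(mt, vo + 1L, vo + 1L) <- setdiff(c("A", "C", "G", "T"),
                                            substr(wt, vo + 1L, vo + 1L))[1]
    fwd <- scan_variant(sequence_pair(wt, mt, vo), models)
    vo_rc <- nchar(wt) - vo - 1L
    rev <- scan_variant(sequence_pair(rc(wt), rc(mt), vo_rc), models)
    expect_equal(fwd$WT, rev$WT, tolerance = 1e-12)
    expect_equal(fwd$MT, rev$MT, tolerance = 1e-12)
    expect_equal(fwd$S, rev$S, tolerance = 1e-12)
  }
})

test_that("long deletions are rejected as not analysable", {
  p <- word_pwm("ACGTAGCA")
  wt <- strrep("ACGT", 30)
  ref <- substr(wt, 41, 41 + 31)              # 32-nt deletion > 2 * 15
  pair <- sequence_pair(wt, paste0(substr(wt, 1, 40), substr(wt, 73, 120)),
                        40L, ref, substr(ref, 1, 1))
  expect_error(scan_variant(pair, list(p)), "not analysable")
})

test_that("combined per-TF predictions average the selected joint scores", {
  mk <- function(id, kind, S) {
    tibble::tibble(model_id = id, tf_name = "TFX", model_kind = kind,
                   WT = 0.5, MT = 0.5, S = S,
                   best_wt_offset = 0L, best_wt_strand = "+",
                   best_mt_offset = 0L, best_mt_strand = "+")
  }
  two_tffm <- dplyr::bind_rows(mk("a", "TFFM_first", 0.5),
                               mk("b", "TFFM_detailed", -0.5))
  res <- combine_per_tf(two_tffm, tffm_only = TRUE)
  expect_identical(res$combined_S, 0)
  expect_identical(res$n_models_used, 2L)

  mixed <- dplyr::bind_rows(mk("t", "TFFM_first", 0.8), mk("p", "PWM", -0.8))
  res_t <- combine_per_tf(mixed, tffm_only = TRUE)
  expect_identical(res_t$combined_S, 0.8)
  expect_identical(res_t$n_models_used, 1L)
  expect_true(res_t$tffm_only_used)
  res_all <- combine_per_tf(mixed, tffm_only = FALSE)
  expect_identical(res_all$combined_S, 0)
  expect_identical(res_all$n_models_used, 2L)
  expect_false(res_all$tffm_only_used)

  # a TF with only PWMs falls back to averaging them even under tffm_only
  pwm_only <- mk("p2", "PWM", 0.4)
  res_p <- combine_per_tf(pwm_only, tffm_only = TRUE)
  expect_identical(res_p$combined_S, 0.4)
  expect_false(res_p$tffm_only_used)
})

test_that("variant notation parses and round-trips", {
  v <- parse_variant("1:160001799G>C")
  expect_identical(v$chrom, "1")
  expect_identical(v$pos, 160001799L)
  expect_identical(v$ref, "G")
  expect_identical(v$alt, "C")
  indel <- parse_variant("chrX:100AT>A")
  expect_identical(indel$ref, "AT")
  expect_error(parse_variant("1:100G>G"), "differ")
  expect_error(parse_variant("not-a-variant"), "parse")
})

test_that("sequence extraction around a variant spans every scorable window", {
  set.seed(404)
  chrom_seq <- random_dna(400)
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom_seq))
  pos <- 200L
  ref <- substr(chrom_seq, pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  v <- tibble::tibble(chrom = "chr1", pos = pos, ref = ref, alt = alt)
  pair <- variant_to_sequence_pair(v, genome, scan_config(), motif_length = 10L)
  expect_identical(nchar(pair$wt_seq), 49L)
  expect_identical(pair$variant_offset, 24L)
  expect_identical(substr(pair$mt_seq, 25, 25), alt)

  # chromosome-name normalisation: "1" finds "chr1"
  v2 <- dplyr::mutate(v, chrom = "1")
  expect_identical(variant_to_sequence_pair(v2, genome, scan_config(), 10L)$wt_seq,
                   pair$wt_seq)

  # reference mismatch is an error
  v_bad <- dplyr::mutate(v, ref = setdiff(c("A", "C", "G", "T"), c(ref, alt))[1])
  expect_error(variant_to_sequence_pair(v_bad, genome, scan_config(), 10L),
               "reference allele does not match")

  # variants near the chromosome start are left-clipped, not an error
  v_edge <- tibble::tibble(chrom = "chr1", pos = 3L,
                           ref = substr(chrom_seq, 3, 3),
                           alt = setdiff(c("A", "C", "G", "T"),
                                         substr(chrom_seq, 3, 3))[1])
  pair_edge <- variant_to_sequence_pair(v_edge, genome, scan_config(), 10L)
  expect_identical(pair_edge$variant_offset, 2L)
  expect_lt(nchar(pair_edge$wt_seq), 49L)

  expect_error(variant_to_sequence_pair(dplyr::mutate(v, chrom = "chr9"),
                                        genome, scan_config(), 10L),
               "unknown chromosome")
})

test_that("the batch scanner caps the number of variants", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 100)))
  p <- word_pwm("ACGTAGCA")
  many <- tibble::tibble(chrom = "chr1", pos = 100 + seq_len(5),
                         ref = substr(strrep("ACGT", 100), 101, 101),
                         alt = "T")
  cfg <- scan_config(max_variants = 3L)
  expect_error(scan_variants(many, genome, list(p), cfg), "limited to 3")
})
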