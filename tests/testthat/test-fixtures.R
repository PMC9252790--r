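test_that("generated count matrices are deterministic with tunable IC", {
  a <- make_pcm(7L, 8L, concentration = 20)
  b <- make_pcm(7L, 8L, concentration = 20)
  expect_identical(a$counts, b$counts)
  expect_false(identical(a$counts, make_pcm(8L, 8L, concentration = 20)$counts))

  hot <- make_pcm(7L, 6L, concentration = Inf)
  expect_equal(information_content(hot), rep(2, 6))
  expect_true(all(colSums(hot$counts > 0) == 1))

  cold <- make_pcm(7L, 6L, concentration = 0)
  expect_equal(information_content(cold), rep(0, 6))
})

test_that("generated TFFMs are valid stochastic models for many seeds", {
  for (s in seq_len(100)) {
    m <- make_tffm(s, 5L, dependency_strength = (s %% 11) / 10)
    for (cond in m$motif_conditional) {
      expect_true(all(abs(rowSums(cond) - 1) < 1e-9))
      expect_true(all(cond >= 0))
    }
  }
  expect_identical(make_tffm(3L, 6L, 0.4)$motif_conditional,
                   make_tffm(3L, 6L, 0.4)$motif_conditional)
})

test_that("dependency strength 0 reproduces the equivalent PWM's ranking", {
  L <- 5L
  m <- make_tffm(21L, L, dependency_strength = 0)
  kmers <- all_kmers(L)
  tffm_scores <- vapply(kmers, function(w) {
    window_scores(m, paste0("A", w))[2L]   # fixed context base
  }, numeric(1))
  # positional probability product of the shared emission distribution
  probs <- vapply(m$motif_conditional, function(cond) cond[1, ], numeric(4))
  pwm_scores <- vapply(kmers, function(w) {
    idx <- match(strsplit(w, "")[[1]], c("A", "C", "G", "T"))
    prod(probs[cbind(idx, seq_len(L))])
  }, numeric(1))
  expect_identical(cor(tffm_scores, pwm_scores, method = "spearman"), 1)
})

test_that("dependency strength 1 can invert the marginal PWM's ranking", {
  L <- 4L
  m <- make_tffm(22L, L, dependency_strength = 1)
  kmers <- all_kmers(L)
  tffm_scores <- vapply(kmers, function(w) {
    window_scores(m, paste0("A", w))[2L]
  }, numeric(1))
  # marginalise the chain into positional base frequencies
  marg <- matrix(0, 4, L)
  prev <- m$bg_emission
  for (i in seq_len(L)) {
    marg[, i] <- as.numeric(prev %*% m$motif_conditional[[i]])
    prev <- marg[, i]
  }
  pwm_scores <- vapply(kmers, function(w) {
    idx <- match(strsplit(w, "")[[1]], c("A", "C", "G", "T"))
    prod(marg[cbind(idx, seq_len(L))])
  }, numeric(1))
  o <- order(tffm_scores)
  expect_lt(cor(tffm_scores, pwm_scores, method = "spearman"), 1)
  # an explicitly opposite-ranked pair exists
  inverted <- FALSE
  for (i in seq_len(200)) {
    a <- sample(length(kmers), 1)
    b <- sample(length(kmers), 1)
    if ((tffm_scores[a] - tffm_scores[b]) *
        (pwm_scores[a] - pwm_scores[b]) < 0) { inverted <- TRUE; break }
  }
  expect_true(inverted)
})

test_that("planted genomes match their truth table and never overlap", {
  spec <- fixture_spec(seed = 3L)
  fx <- make_genome_with_sites(spec)
  expect_identical(nrow(fx$sites), 2L * spec$n_planted_sites)
  expect_identical(sum(fx$sites$kind == "consensus"), spec$n_planted_sites)
  seqs <- as.character(fx$genome[[1]])
  # every planted word is present at its recorded location
  for (i in seq_len(nrow(fx$sites))) {
    s <- fx$sites[i, ]
    found <- substr(seqs, s$start + 1L, s$end)
    expected <- if (s$kind == "consensus") fx$consensus else {
      w <- fx$consensus
      substr(w, fx$hot_col, fx$hot_col) <- fx$anti_base
      w
    }
    if (s$strand == "-") expected <- rc(expected)
    expect_identical(found, expected)
  }
  # sites do not overlap each other
  o <- order(fx$sites$start)
  expect_true(all(fx$sites$start[o][-1] >= fx$sites$end[o][-length(o)]))
  # determinism
  fx2 <- make_genome_with_sites(fixture_spec(seed = 3L))
  expect_identical(as.character(fx$genome), as.character(fx2$genome))
  expect_identical(fx$sites, fx2$sites)
})

test_that("derived variants map one-to-one onto truth rows at safe distances", {
  spec <- fixture_spec(seed = 9L)
  fx <- make_genome_with_sites(spec)
  vcf <- make_disrupting_vcf(fx)
  expect_identical(nrow(vcf$variants), spec$n_variants)
  expect_identical(nrow(vcf$truth), nrow(vcf$variants))
  expect_identical(sum(vcf$truth$expected_sign == -1), spec$n_planted_sites)
  expect_identical(sum(vcf$truth$expected_sign == 1), spec$n_planted_sites)

  genome_seq <- as.character(fx$genome[[1]])
  l_max <- max(vapply(fx$models, motif_length, integer(1)))
  for (i in seq_len(nrow(vcf$variants))) {
    v <- vcf$variants[i, ]
    # the stated reference allele matches the genome
    expect_identical(substr(genome_seq, v$pos, v$pos + nchar(v$ref) - 1L),
                     v$ref)
    if (vcf$truth$expected_sign[i] == 0) {
      # neutral changed base lies beyond every scorable window and far from
      # all planted sites
      delta <- which(strsplit(v$ref, "")[[1]] != strsplit(v$alt, "")[[1]])
      expect_identical(length(delta), 1L)
      expect_gt(delta - 1L, 15L + nchar(fx$consensus) - 1L)
      changed <- v$pos + delta - 1L
      dist <- min(abs(changed - fx$sites$start), abs(changed - fx$sites$end))
      expect_gte(dist, 15L + l_max)
    }
  }
  # determinism
  vcf2 <- make_disrupting_vcf(make_genome_with_sites(fixture_spec(seed = 9L)))
  expect_identical(vcf$truth, vcf2$truth)
})

test_that("demo fixture files round-trip through the standard readers", {
  dir <- withr::local_tempdir()
  spec <- fixture_spec(seed = 2L, n_tfs = 3L)
  write_demo_fixtures(spec, dir)
  expect_true(all(file.exists(file.path(dir, c("genome.fa", "sites.bed",
                                               "variants.vcf", "truth.tsv")))))
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_identical(names(genome), spec$chrom)
  models <- read_models(file.path(dir, "models"))
  expect_gte(length(models), 2L * spec$n_tfs)
  v <- read_vcf(file.path(dir, "variants.vcf"))
  expect_identical(nrow(v), spec$n_variants)
  ks <- read_known_sites(c(synthetic = file.path(dir, "sites.bed")))
  expect_identical(nrow(ks$sites), 2L * spec$n_planted_sites)
})
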