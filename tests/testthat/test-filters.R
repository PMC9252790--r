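filters_variants <- function() {
  tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    pos = c(4500L, 9000L, 20000L, 500L, 800L),
    ref = "A", alt = "C",
    depth = c(30L, 9L, 30L, 10L, NA),
    homozygous = c(TRUE, FALSE, TRUE, FALSE, TRUE),
    af = c(0.001, 0.02, NA, 0.01, 0.5))
}

filters_genes <- function() {
  tibble::tibble(chrom = "chr1", start = 4999L, end = 8000L,
                 name = "GENE1", strand = "+")
}

test_that("candidate-gene vicinity is strand-aware with asymmetric flanks", {
  cfg <- filter_config(candidate_genes = "GENE1", flank_up = 1000L,
                       flank_down = 100L)
  v <- filters_variants()
  kept <- apply_variant_filters(v, cfg, filters_genes())
  # pos 4500 is 500 bp upstream of the + strand gene span: inside the
  # 1000-nt upstream flank; pos 9000 is 1000 bp downstream: outside the
  # 100-nt downstream flank
  expect_identical(kept$pos, 4500L)
  # on the minus strand the flanks flip: 9000 is now upstream and kept
  genes_minus <- dplyr::mutate(filters_genes(), strand = "-")
  kept_m <- apply_variant_filters(v, cfg, genes_minus)
  expect_identical(kept_m$pos, 9000L)
  # unknown candidate genes are reported by name
  expect_error(
    apply_variant_filters(v, filter_config(candidate_genes = c("GENE1", "NOPE")),
                          filters_genes()),
    "NOPE")
  # the gene table is mandatory when the filter is active
  expect_error(apply_variant_filters(v, cfg, NULL), "gene_table")
})

test_that("region, depth, zygosity and rarity filters use documented bounds", {
  v <- filters_variants()
  regions <- tibble::tibble(chrom = "chr2", start = 400L, end = 800L)
  kept_r <- apply_variant_filters(v, filter_config(regions = regions))
  expect_identical(kept_r$pos, c(500L, 800L))   # half-open: 401..800 in

  kept_d <- apply_variant_filters(v, filter_config(min_depth = 10L))
  expect_identical(kept_d$pos, c(4500L, 20000L, 500L))  # 9 < 10 out, NA out

  kept_h <- apply_variant_filters(v, filter_config(homozygous_only = TRUE))
  expect_identical(kept_h$pos, c(4500L, 20000L, 800L))

  kept_a <- apply_variant_filters(v, filter_config(max_allele_freq = 0.01))
  # AF 0.02 and 0.5 dropped; boundary 0.01 kept; missing AF kept but flagged
  expect_identical(kept_a$pos, c(4500L, 20000L, 500L))
  expect_identical(kept_a$af_missing, c(FALSE, TRUE, FALSE))
})

test_that("filter composition is order-independent", {
  v <- filters_variants()
  genes <- filters_genes()
  single_filters <- list(
    function(x) apply_variant_filters(x, filter_config(min_depth = 10L)),
    function(x) apply_variant_filters(x, filter_config(max_allele_freq = 0.1)),
    function(x) apply_variant_filters(x, filter_config(homozygous_only = TRUE)),
    function(x) apply_variant_filters(
      x, filter_config(candidate_genes = "GENE1"), genes))
  joint <- apply_variant_filters(
    v, filter_config(min_depth = 10L, max_allele_freq = 0.1,
                     homozygous_only = TRUE, candidate_genes = "GENE1"),
    genes)
  for (perm in list(c(1, 2, 3, 4), c(4, 3, 2, 1), c(2, 4, 1, 3), c(3, 1, 4, 2))) {
    out <- v
    for (i in perm) out <- single_filters[[i]](out)
    expect_identical(out$pos, joint$pos)
  }
})

test_that("model filters intersect kind, source, TF list and known sites", {
  models <- list(
    word_pwm("ACGTACGT", tf_name = "TFA", model_id = "TFA.pwm"),
    make_tffm(1L, 6L, 0, tf_name = "TFA", model_id = "TFA.t1"),
    make_tffm(2L, 6L, 0, tf_name = "TFB", model_id = "TFB.t1"))
  ids <- function(x) vapply(x, `[[`, character(1), "model_id")

  sel <- apply_model_filters(models, cfg = filter_config(model_kinds = "TFFM_first"))
  expect_identical(ids(sel), c("TFA.t1", "TFB.t1"))

  sel2 <- apply_model_filters(models, cfg = filter_config(tf_names = "TFA"))
  expect_identical(ids(sel2), c("TFA.pwm", "TFA.t1"))

  models[[3]]$source <- "JASPAR"
  sel3 <- apply_model_filters(models, cfg = filter_config(sources = "JASPAR"))
  expect_identical(ids(sel3), "TFB.t1")

  ks <- known_sites(tibble::tibble(chrom = "chr1", start = 90L, end = 120L,
                                   tf_name = "TFA", source = "ENCODE"))
  v <- tibble::tibble(chrom = "chr1", pos = 100L)
  sel4 <- apply_model_filters(models, ks, v,
                              filter_config(known_tfbs_only = TRUE))
  expect_identical(ids(sel4), c("TFA.pwm", "TFA.t1"))
  v_far <- tibble::tibble(chrom = "chr1", pos = 500L)
  expect_warning(
    sel5 <- apply_model_filters(models, ks, v_far,
                                filter_config(known_tfbs_only = TRUE)),
    "no models")
  expect_length(sel5, 0L)
})
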