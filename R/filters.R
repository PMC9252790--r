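#' Filter configuration
#'
#' Mirrors the search-interface semantics: variants can be restricted to
#' custom genomic regions or the vicinity of candidate genes, by sequencing
#' depth, zygosity and allele frequency; models can be restricted by kind,
#' source, explicit TF list, or to TFs with a known binding site at the
#' variant position.
#'
#' @param regions Tibble of intervals (`chrom`, `start`, `end`, 0-based
#'   half-open) or `NULL`.
#' @param candidate_genes Character vector of gene names or `NULL`.
#' @param flank_up,flank_down Candidate-gene vicinity in nucleotides upstream
#'   / downstream of the annotated gene span (defaults 5000 / 1000,
#'   strand-aware).
#' @param min_depth Minimum INFO/DP depth, or `NULL`.
#' @param homozygous_only Keep only variants homozygous for the ALT allele.
#' @param max_allele_freq Keep variants with allele frequency at or below
#'   this bound (boundary inclusive); records without an AF annotation are
#'   kept and flagged. `NULL` disables the filter.
#' @param known_tfbs_only Restrict models to TFs with a known site
#'   overlapping the variant.
#' @param model_kinds Subset of `c("PWM", "TFFM_first", "TFFM_detailed")` or
#'   `NULL`.
#' @param sources Subset of model source labels or `NULL`.
#' @param tf_names Explicit TF selection or `NULL`.
#' @return A list of class `"filter_config"`.
#' @export
filter_config <- function(regions = NULL, candidate_genes = NULL,
                          flank_up = 5000L, flank_down = 1000L,
                          min_depth = NULL, homozygous_only = FALSE,
                          max_allele_freq = NULL, known_tfbs_only = FALSE,
                          model_kinds = NULL, sources = NULL,
                          tf_names = NULL) {
  stopifnot(flank_up >= 0, flank_down >= 0)
  if (!is.null(max_allele_freq)) {
    stopifnot(max_allele_freq >= 0, max_allele_freq <= 1)
  }
  if (!is.null(model_kinds)) {
    stopifnot(all(model_kinds %in% c("PWM", "TFFM_first", "TFFM_detailed")))
  }
  structure(
    list(regions = regions, candidate_genes = candidate_genes,
         flank_up = as.integer(flank_up), flank_down = as.integer(flank_down),
         min_depth = min_depth, homozygous_only = isTRUE(homozygous_only),
         max_allele_freq = max_allele_freq,
         known_tfbs_only = isTRUE(known_tfbs_only),
         model_kinds = model_kinds, sources = sources, tf_names = tf_names),
    class = "filter_config"
  )
}

# 1-based position inside a 0-based half-open interval table?
pos_in_intervals <- function(chrom, pos, intervals) {
  same <- norm_chrom(intervals$chrom) == norm_chrom(chrom)
  any(same & intervals$start < pos & pos <= intervals$end)
}

#' Apply variant-level filters
#'
#' A variant is kept iff it passes every *active* filter: located inside a
#' custom region OR within the flanked span of a candidate gene (when either
#' is set); depth at least `min_depth`; homozygous if required; allele
#' frequency at or below `max_allele_freq` (a variant with no AF annotation
#' is kept and flagged in `af_missing`). The filters commute: any order of
#' application yields the same surviving set.
#'
#' @param variants Tibble with `chrom`, `pos` and optional `depth`,
#'   `homozygous`, `af` columns (see [read_vcf()]).
#' @param cfg A [filter_config()].
#' @param gene_table Gene coordinates from [read_gene_table()]; required iff
#'   `candidate_genes` is set.
#' @param verbose Log the number of variants surviving each filter.
#' @return The filtered tibble, with an added logical `af_missing` column
#'   when the rarity filter is active.
#' @export
apply_variant_filters <- function(variants, cfg, gene_table = NULL,
                                  verbose = FALSE) {
  stopifnot(inherits(cfg, "filter_config"))
  log_step <- function(what, kept) {
    if (verbose) message(sprintf("filter %-12s: %d variant(s) kept", what, sum(kept)))
  }
  keep <- rep(TRUE, nrow(variants))
  if (!is.null(cfg$regions) || !is.null(cfg$candidate_genes)) {
    in_region <- rep(FALSE, nrow(variants))
    if (!is.null(cfg$regions)) {
      in_region <- vapply(seq_len(nrow(variants)), function(i) {
        pos_in_intervals(variants$chrom[i], variants$pos[i], cfg$regions)
      }, logical(1))
    }
    near_gene <- rep(FALSE, nrow(variants))
    if (!is.null(cfg$candidate_genes)) {
      if (is.null(gene_table)) {
        stop("candidate_genes filter needs a gene_table", call. = FALSE)
      }
      missing <- setdiff(cfg$candidate_genes, gene_table$name)
      if (length(missing) > 0L) {
        stop(sprintf("candidate gene(s) absent from gene table: %s",
                     paste(missing, collapse = ", ")), call. = FALSE)
      }
      genes <- gene_table[gene_table$name %in% cfg$candidate_genes, ]
      spans <- tibble::tibble(
        chrom = genes$chrom,
        start = ifelse(genes$strand == "-", genes$start - cfg$flank_down,
                       genes$start - cfg$flank_up),
        end = ifelse(genes$strand == "-", genes$end + cfg$flank_up,
                     genes$end + cfg$flank_down))
      near_gene <- vapply(seq_len(nrow(variants)), function(i) {
        pos_in_intervals(variants$chrom[i], variants$pos[i], spans)
      }, logical(1))
    }
    keep <- keep & (in_region | near_gene)
    log_step("location", keep)
  }
  if (!is.null(cfg$min_depth)) {
    depth <- if ("depth" %in% names(variants)) variants$depth else NA_integer_
    keep <- keep & !is.na(depth) & depth >= cfg$min_depth
    log_step("depth", keep)
  }
  if (cfg$homozygous_only) {
    hom <- if ("homozygous" %in% names(variants)) variants$homozygous else NA
    keep <- keep & hom %in% TRUE
    log_step("zygosity", keep)
  }
  af_missing <- rep(NA, nrow(variants))
  if (!is.null(cfg$max_allele_freq)) {
    af <- if ("af" %in% names(variants)) variants$af else NA_real_
    af_missing <- is.na(af)
    keep <- keep & (af_missing | af <= cfg$max_allele_freq)
    log_step("rarity", keep)
  }
  out <- variants[keep, , drop = FALSE]
  if (!is.null(cfg$max_allele_freq)) out$af_missing <- af_missing[keep]
  out
}

#' Select the models applicable to one variant
#'
#' Intersects the model collection with the configured kind, source and TF
#' restrictions; with `known_tfbs_only`, additionally keeps only TFs that
#' have a known binding site overlapping the variant position.
#'
#' @param models List of motif models.
#' @param known_sites A `"known_sites"` object (required iff
#'   `known_tfbs_only` is set).
#' @param variant One-row tibble/list with `chrom` and `pos`.
#' @param cfg A [filter_config()].
#' @return The selected sub-list of models (possibly empty, with a warning).
#' @export
apply_model_filters <- function(models, known_sites = NULL, variant = NULL,
                                cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  keep <- rep(TRUE, length(models))
  kinds <- vapply(models, model_kind, character(1))
  if (!is.null(cfg$model_kinds)) keep <- keep & kinds %in% cfg$model_kinds
  if (!is.null(cfg$sources)) {
    keep <- keep & vapply(models, `[[`, character(1), "source") %in% cfg$sources
  }
  tfs <- vapply(models, `[[`, character(1), "tf_name")
  if (!is.null(cfg$tf_names)) keep <- keep & tfs %in% cfg$tf_names
  if (cfg$known_tfbs_only) {
    if (is.null(known_sites) || is.null(variant)) {
      stop("known_tfbs_only needs known_sites and a variant", call. = FALSE)
    }
    hits <- query_known_sites(known_sites, variant$chrom, variant$pos)
    keep <- keep & tfs %in% hits$tf_name
  }
  sel <- models[keep]
  if (length(sel) == 0L) warning("no models left after model filters")
  sel
}
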