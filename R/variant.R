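#' Parse variants in chromosomal notation
#'
#' Accepts strings such as `"1:160001799G>C"` or `"chr7:100AT>A"` (1-based
#' position, explicit reference and alternate alleles).
#'
#' @param x Character vector of variant strings.
#' @return A tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`.
#' @examples
#' parse_variant("1:160001799G>C")
#' @export
parse_variant <- function(x) {
  m <- regmatches(x, regexec("^([^:[:space:]]+):([0-9]+)([ACGTacgt]+)>([ACGTacgt]+)$", x))
  bad <- vapply(m, length, integer(1)) != 5L
  if (any(bad)) {
    stop(sprintf("cannot parse variant notation: %s",
                 paste(x[bad], collapse = ", ")), call. = FALSE)
  }
  out <- tibble::tibble(
    chrom = vapply(m, `[[`, character(1), 2L),
    pos = as.integer(vapply(m, `[[`, character(1), 3L)),
    ref = toupper(vapply(m, `[[`, character(1), 4L)),
    alt = toupper(vapply(m, `[[`, character(1), 5L))
  )
  if (any(out$ref == out$alt)) {
    stop("reference and alternate allele must differ", call. = FALSE)
  }
  out
}

# Resolve a chromosome name against the genome, tolerating chr prefixes.
genome_chrom <- function(genome, chrom) {
  nm <- names(genome)
  hit <- which(norm_chrom(nm) == norm_chrom(chrom))
  if (length(hit) == 0L) {
    stop(sprintf("unknown chromosome: %s", chrom), call. = FALSE)
  }
  nm[hit[1L]]
}

#' Extract the reference/variant sequence pair for a variant
#'
#' Pulls enough flanking sequence from the genome that every window within
#' `window_halfwidth` of the variant is fully scorable by a model of length
#' `motif_length`: the span is
#' `[pos - halfwidth - (L - 1), pos + nchar(ref) - 1 + halfwidth + (L - 1)]`,
#' clipped at the chromosome ends. The extracted reference subsequence is
#' checked against the stated reference allele.
#'
#' @param variant One-row data frame (or list) with `chrom`, `pos` (1-based),
#'   `ref`, `alt`.
#' @param genome A named [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param cfg A [scan_config()].
#' @param motif_length Length of the longest model to be scanned.
#' @return A [sequence_pair()].
#' @export
variant_to_sequence_pair <- function(variant, genome, cfg = scan_config(),
                                     motif_length = 10L) {
  if (is.character(genome) && length(genome) == 1L) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  v <- as.list(variant)
  chrom <- genome_chrom(genome, v$chrom)
  chr_seq <- genome[[chrom]]
  chr_len <- length(chr_seq)
  pos <- as.integer(v$pos)
  ref <- toupper(v$ref)
  alt <- toupper(v$alt)
  if (pos < 1L || pos + nchar(ref) - 1L > chr_len) {
    stop(sprintf("variant %s:%d lies outside the chromosome", v$chrom, pos),
         call. = FALSE)
  }
  pad <- cfg$window_halfwidth + motif_length - 1L
  start <- max(1L, pos - pad)
  end <- min(chr_len, pos + nchar(ref) - 1L + pad)
  wt_seq <- as.character(Biostrings::subseq(chr_seq, start, end))
  variant_offset <- pos - start
  found <- substr(wt_seq, variant_offset + 1L, variant_offset + nchar(ref))
  if (found != ref) {
    stop(sprintf("reference allele does not match genome at %s:%d (genome has %s, stated %s)",
                 v$chrom, pos, found, ref), call. = FALSE)
  }
  mt_seq <- paste0(substr(wt_seq, 1L, variant_offset),
                   alt,
                   substr(wt_seq, variant_offset + nchar(ref) + 1L, nchar(wt_seq)))
  sequence_pair(wt_seq, mt_seq, variant_offset, ref, alt)
}

#' Scan a table of variants against a model collection
#'
#' The end-to-end engine: for every variant the flanking sequence is
#' extracted, every selected model is evaluated on the reference and mutated
#' sequence in the sliding window around the variant, per-model joint scores
#' are computed, and the per-TF combined prediction is formed. Variants whose
#' reference allele does not match the genome, or deletions longer than twice
#' the window halfwidth, are skipped with a warning and listed in the
#' `skipped` component.
#'
#' @param variants Tibble with columns `chrom`, `pos`, `ref`, `alt`
#'   (additional columns are carried through).
#' @param genome Named [Biostrings::DNAStringSet] or FASTA path.
#' @param models List of motif models (see [read_models()]).
#' @param cfg A [scan_config()].
#' @param known_sites Optional known-TFBS index from [read_known_sites()];
#'   adds overlap annotation to the predictions.
#' @param filter_cfg Optional [filter_config()] applied per variant to the
#'   model selection (kind/source/TF restriction, known-TFBS-only).
#' @return An object of class `"tf_scan"`: a list with tibbles `predictions`
#'   (one row per variant x TF), `outcomes` (one row per variant x model),
#'   `variants`, `skipped`, and the `config` used. Use [tidy()] /
#'   [glance()] / [ggplot2::autoplot()] on it.
#' @export
scan_variants <- function(variants, genome, models, cfg = scan_config(),
                          known_sites = NULL, filter_cfg = NULL) {
  stopifnot(is.data.frame(variants), length(models) >= 1L)
  if (nrow(variants) > cfg$max_variants) {
    stop(sprintf("analysis limited to %s variants (got %d)",
                 format(cfg$max_variants, big.mark = " "), nrow(variants)),
         call. = FALSE)
  }
  if (is.character(genome) && length(genome) == 1L) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  l_max <- max(vapply(models, motif_length, integer(1)))
  variants <- dplyr::mutate(variants,
                            variant_id = sprintf("%s:%d%s>%s", .data$chrom,
                                                 .data$pos, .data$ref, .data$alt))
  outcome_list <- list()
  pred_list <- list()
  skipped <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    sel <- models
    if (!is.null(filter_cfg)) {
      sel <- apply_model_filters(models, known_sites, v, filter_cfg)
      if (length(sel) == 0L) {
        warning(sprintf("no models selected for %s; variant skipped", v$variant_id))
        skipped[[length(skipped) + 1L]] <-
          dplyr::mutate(v, reason = "no models selected")
        next
      }
    }
    res <- tryCatch({
      pair <- variant_to_sequence_pair(v, genome, cfg, motif_length = l_max)
      scan_variant(pair, sel, cfg)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("variant %s skipped: %s", v$variant_id, conditionMessage(res)))
      skipped[[length(skipped) + 1L]] <-
        dplyr::mutate(v, reason = conditionMessage(res))
      next
    }
    res <- dplyr::mutate(res, variant_id = v$variant_id, .before = 1L)
    outcome_list[[length(outcome_list) + 1L]] <- res
    pred <- combine_per_tf(res, tffm_only = cfg$tffm_only)
    pred <- dplyr::mutate(pred, variant_id = v$variant_id, .before = 1L)
    if (!is.null(known_sites)) {
      hits <- query_known_sites(known_sites, v$chrom, v$pos)
      pred <- dplyr::mutate(
        pred,
        known_tfbs = .data$tf_name %in% hits$tf_name,
        known_sources = vapply(.data$tf_name, function(tf) {
          paste(sort(unique(hits$source[hits$tf_name == tf])), collapse = ",")
        }, character(1), USE.NAMES = FALSE)
      )
    } else {
      pred <- dplyr::mutate(pred, known_tfbs = NA, known_sources = "")
    }
    pred_list[[length(pred_list) + 1L]] <- pred
  }
  predictions <- dplyr::bind_rows(pred_list)
  if (nrow(predictions) > 0L) {
    predictions <- dplyr::mutate(predictions,
                                 category = score_category(.data$combined_S),
                                 .after = "combined_S")
  }
  structure(
    list(predictions = predictions,
         outcomes = dplyr::bind_rows(outcome_list),
         variants = variants,
         skipped = dplyr::bind_rows(skipped),
         config = cfg),
    class = "tf_scan"
  )
}

#' @export
print.tf_scan <- function(x, ...) {
  cat(sprintf("<tf_scan> %d variant(s) x %d transcription factor(s); %d model outcomes\n",
              nrow(x$variants), length(unique(x$predictions$tf_name)),
              nrow(x$outcomes)))
  if (nrow(x$skipped) > 0L) {
    cat(sprintf("  %d variant(s) skipped\n", nrow(x$skipped)))
  }
  top <- dplyr::arrange(x$predictions, dplyr::desc(abs(.data$combined_S)))
  print(utils::head(top, 10L))
  invisible(x)
}
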