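#' Specification for a synthetic fixture set
#'
#' Describes the deterministic synthetic inputs (models, genome, planted
#' sites, variants) used by the tests, the demo and the quickstart. The same
#' seed always yields byte-identical outputs.
#'
#' @param seed Integer seed; every generator below is a pure function of its
#'   seed.
#' @param n_tfs Number of transcription factors (the first is the "truth" TF
#'   whose sites are planted and perturbed; the rest act as decoys).
#' @param motif_length Length range (min, max) for generated motifs.
#' @param dependency_strength In `[0, 1]`: 0 makes TFFM emissions independent
#'   of the previous base (PWM-equivalent), 1 makes the conditional rows
#'   maximally different.
#' @param genome_length Length of the synthetic chromosome in nucleotides.
#' @param n_planted_sites Number of perfect consensus sites planted for the
#'   truth TF; the same number of near-consensus (one base off) sites is
#'   planted for gain variants.
#' @param n_variants Total variants emitted by [make_disrupting_vcf()]:
#'   one loss per consensus site, one gain per near-consensus site, and the
#'   remainder neutral.
#' @param concentration Dirichlet concentration of generated count-matrix
#'   columns around their consensus base (`Inf` = invariant columns, `0` =
#'   uniform).
#' @param chrom Name of the synthetic chromosome.
#' @return A list of class `"fixture_spec"`.
#' @export
fixture_spec <- function(seed = 1L, n_tfs = 21L, motif_length = c(8L, 8L),
                         dependency_strength = 0, genome_length = 4000L,
                         n_planted_sites = 2L, n_variants = 6L,
                         concentration = 50, chrom = "chrS") {
  stopifnot(n_tfs >= 1, genome_length >= 1, n_planted_sites >= 1,
            n_variants >= 2 * n_planted_sites,
            dependency_strength >= 0, dependency_strength <= 1)
  motif_length <- rep_len(as.integer(motif_length), 2L)
  structure(
    list(seed = as.integer(seed), n_tfs = as.integer(n_tfs),
         motif_length = motif_length,
         dependency_strength = dependency_strength,
         genome_length = as.integer(genome_length),
         n_planted_sites = as.integer(n_planted_sites),
         n_variants = as.integer(n_variants),
         concentration = concentration, chrom = chrom),
    class = "fixture_spec"
  )
}

# One Dirichlet column around a consensus base.
dirichlet_column <- function(consensus, concentration) {
  if (is.infinite(concentration)) {
    p <- rep(0, 4); p[consensus] <- 1
  } else if (concentration == 0) {
    p <- rep(0.25, 4)
  } else {
    a <- 1 + concentration * (seq_len(4) == consensus)
    g <- rgamma(4, shape = a)
    p <- g / sum(g)
  }
  p
}

#' Generate a random position count matrix
#'
#' Columns are drawn Dirichlet-style around a random consensus;
#' `concentration` controls the information content (`Inf` gives one-hot
#' columns of 2 bits, `0` gives exactly uniform columns of 0 bits). Counts
#' are scaled to `n_sites` observations per column (non-integer counts are
#' allowed).
#'
#' @param seed Integer seed.
#' @param length Motif length.
#' @param concentration Dirichlet concentration (default 50).
#' @param n_sites Nominal number of aligned sites (column total).
#' @param tf_name,model_id,source Model metadata.
#' @return A [pcm()].
#' @export
make_pcm <- function(seed, length, concentration = 50, n_sites = 100,
                     tf_name = "TF", model_id = paste0(tf_name, ".pcm"),
                     source = "synthetic") {
  stopifnot(length >= 1)
  with_seed(seed, {
    consensus <- sample.int(4L, length, replace = TRUE)
    counts <- vapply(seq_len(length), function(i) {
      n_sites * dirichlet_column(consensus[i], concentration)
    }, numeric(4))
    pcm(matrix(counts, nrow = 4L), tf_name = tf_name, model_id = model_id,
        source = source)
  })
}

#' Generate a random first-order TFFM
#'
#' Builds a motif whose emissions at each position depend on the previous
#' base with tunable strength. At `dependency_strength = 0` all four
#' conditional rows of a position are identical, so the model ranks windows
#' exactly like the PWM of its positional base distributions; at 1 the rows
#' are maximally different (near-one-hot rows rotated per previous base), so
#' window rankings can invert relative to any positional marginal. The
#' background emissions are uniform.
#'
#' @param seed Integer seed.
#' @param length Motif length.
#' @param dependency_strength In `[0, 1]`.
#' @param motif_probs Optional 4 x L matrix of positional base
#'   distributions; drawn Dirichlet-style when `NULL`.
#' @param concentration Dirichlet concentration for drawn positions.
#' @param self_transition,motif_entry Background self-transition and motif
#'   entry probabilities. The default entry of 0.001 corresponds to an
#'   expected binding-site density of roughly one per kilobase, which keeps
#'   site posteriors in their discriminative range instead of saturating
#'   near 1.
#' @param tf_name,model_id,source Model metadata.
#' @return A `"tffm_first"` model.
#' @export
make_tffm <- function(seed, length, dependency_strength = 0,
                      motif_probs = NULL, concentration = 50,
                      self_transition = 0.999, motif_entry = 0.001,
                      tf_name = "TF", model_id = paste0(tf_name, ".t1"),
                      source = "synthetic") {
  stopifnot(dependency_strength >= 0, dependency_strength <= 1, length >= 1)
  with_seed(seed, {
    if (is.null(motif_probs)) {
      consensus <- sample.int(4L, length, replace = TRUE)
      motif_probs <- vapply(seq_len(length), function(i) {
        dirichlet_column(consensus[i], concentration)
      }, numeric(4))
    }
    motif_probs <- as.matrix(motif_probs)
    stopifnot(nrow(motif_probs) == 4L, ncol(motif_probs) == length)
    d <- dependency_strength
    conds <- lapply(seq_len(length), function(i) {
      q <- motif_probs[, i] / sum(motif_probs[, i])
      top <- which.max(q)
      rows <- vapply(1:4, function(p) {
        # per-previous-base target: a near-one-hot row rotated by p, with a
        # per-row peak mass so the positional marginal stays non-uniform
        peak <- 0.97 - 0.03 * (p - 1)
        target <- rep((1 - peak) / 3, 4)
        target[((top + p - 2L) %% 4L) + 1L] <- peak
        (1 - d) * q + d * target
      }, numeric(4))
      t(rows)
    })
    tffm_first_order(conds,
                     bg_emission = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                     self_transition = self_transition,
                     motif_entry = motif_entry,
                     tf_name = tf_name, model_id = model_id, source = source)
  })
}

# The full model panel for a fixture spec: per TF a PWM and a first-order
# TFFM sharing the same positional base frequencies; the truth TF (TF01)
# additionally gets the detailed decomposition of its TFFM.
make_fixture_models <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  len_range <- seq(spec$motif_length[1L], spec$motif_length[2L])
  lens <- if (length(len_range) == 1L) {
    rep(len_range, spec$n_tfs)
  } else {
    with_seed(spec$seed, sample(len_range, spec$n_tfs, replace = TRUE))
  }
  models <- list()
  pcms <- list()
  for (j in seq_len(spec$n_tfs)) {
    tf <- sprintf("TF%02d", j)
    sub_seed <- (spec$seed * 1009L + j) %% .Machine$integer.max
    p <- make_pcm(sub_seed, lens[j], spec$concentration,
                  tf_name = tf, model_id = paste0(tf, ".pcm"))
    freq <- sweep(p$counts, 2, colSums(p$counts), "/")
    t1 <- make_tffm(sub_seed, lens[j], spec$dependency_strength,
                    motif_probs = freq, tf_name = tf,
                    model_id = paste0(tf, ".t1"))
    pcms[[tf]] <- p
    models <- c(models, list(pcm_to_pwm(p, pseudocount = 1)), list(t1))
    if (j == 1L) {
      td <- build_detailed_from_first_order(t1)
      td$model_id <- paste0(tf, ".t1d")
      models <- c(models, list(td))
    }
  }
  list(models = models, pcms = pcms)
}

#' Generate a synthetic genome with planted binding sites
#'
#' Samples a background chromosome from the configured base composition and
#' plants, for the truth TF, perfect consensus occurrences (loss targets)
#' and near-consensus occurrences in which the most informative motif column
#' carries the anti-consensus base (gain targets), on randomly chosen
#' strands, at positions spaced far enough apart that no scan window ever
#' sees two planted sites or a site and a neutral region simultaneously.
#'
#' The generator certifies its own truth table: the local background around
#' each planted site is resampled until no decoy model shows a material
#' joint score (`|S| < 0.5`) for the variant that will later perturb the
#' site. Without this, a chance decoy match overlapping the planted locus
#' could legitimately be disrupted more strongly than the planted site
#' itself, making the recorded "affected TF" wrong.
#'
#' @param spec A [fixture_spec()].
#' @return A list of class `"tf_fixture"`: `genome` (named
#'   [Biostrings::DNAStringSet]), `sites` (tibble, BED-style 0-based
#'   half-open, with `tf_name`, `strand`, `kind`), `models`, `pcms`,
#'   `neutral_pos` (1-based anchor positions reserved for neutral variants)
#'   and the `spec`.
#' @export
make_genome_with_sites <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  mm <- make_fixture_models(spec)
  truth_pwm <- mm$models[[1L]]
  truth_pcm <- mm$pcms[[1L]]
  L <- truth_pwm$L
  ic <- information_content(truth_pcm)
  hot_col <- which.max(ic)
  consensus <- pwm_consensus(truth_pwm)
  anti_base <- substr(pwm_anticonsensus(truth_pwm), hot_col, hot_col)
  near <- consensus
  substr(near, hot_col, hot_col) <- anti_base
  hw <- 15L
  l_max <- max(vapply(mm$models, motif_length, integer(1)))
  pad <- hw + l_max
  n_slots <- 2L * spec$n_planted_sites +
    max(0L, spec$n_variants - 2L * spec$n_planted_sites)
  margin <- 2L * (hw + l_max) + 40L
  need <- n_slots * margin + 2L * margin
  if (spec$genome_length < need) {
    stop(sprintf("genome_length must be at least %d for this layout", need),
         call. = FALSE)
  }
  decoys <- mm$models[vapply(mm$models, `[[`, character(1), "tf_name") !=
                        truth_pwm$tf_name]
  cfg <- scan_config(window_halfwidth = hw)
  with_seed(spec$seed + 7L, {
    genome_seq <- random_dna(spec$genome_length)
    slot_at <- function(k) {
      round(margin + (k - 1L) * (spec$genome_length - 2L * margin) /
              max(1L, n_slots - 1L))
    }
    kinds <- c(rep("consensus", spec$n_planted_sites),
               rep("near", spec$n_planted_sites),
               rep("neutral", n_slots - 2L * spec$n_planted_sites))
    sites <- list()
    neutral_pos <- integer(0)
    for (k in seq_len(n_slots)) {
      start0 <- slot_at(k)          # 0-based start of the planted element
      if (kinds[k] == "neutral") {
        neutral_pos <- c(neutral_pos, start0 + 1L)
        next
      }
      strand <- sample(c("+", "-"), 1L)
      word <- if (kinds[k] == "consensus") consensus else near
      if (strand == "-") word <- revcomp(word)
      # the base swap that make_disrupting_vcf() will apply at this site,
      # in local coordinates of the resampled region
      if (strand == "+") {
        v_local <- pad + hot_col                 # 1-based within region
        ref_b <- if (kinds[k] == "consensus") substr(consensus, hot_col, hot_col) else anti_base
        alt_b <- if (kinds[k] == "consensus") anti_base else substr(consensus, hot_col, hot_col)
      } else {
        v_local <- pad + (L - hot_col) + 1L
        ref_b <- revcomp(if (kinds[k] == "consensus") substr(consensus, hot_col, hot_col) else anti_base)
        alt_b <- revcomp(if (kinds[k] == "consensus") anti_base else substr(consensus, hot_col, hot_col))
      }
      region_len <- L + 2L * pad
      best_region <- NULL
      best_conf <- Inf
      for (try in seq_len(60L)) {
        region <- random_dna(region_len)
        substr(region, pad + 1L, pad + L) <- word
        mt_region <- region
        substr(mt_region, v_local, v_local) <- alt_b
        stopifnot(substr(region, v_local, v_local) == ref_b)
        conf <- max(vapply(decoys, function(m) {
          wt <- best_window_score(m, region, v_local - 1L, cfg)$score
          mt <- best_window_score(m, mt_region, v_local - 1L, cfg)$score
          abs(joint_score(wt, mt, cfg$alpha))
        }, numeric(1)), 0)
        if (conf < best_conf) {
          best_conf <- conf
          best_region <- region
        }
        if (conf < 0.5) break
      }
      # best-effort: if a decoy motif intrinsically resembles the planted
      # word, no background resampling can push its effect to zero; keep the
      # least-confounded placement seen
      substr(genome_seq, start0 - pad + 1L, start0 - pad + region_len) <- best_region
      sites[[length(sites) + 1L]] <- tibble::tibble(
        chrom = spec$chrom, start = start0, end = start0 + L,
        tf_name = truth_pwm$tf_name, strand = strand, kind = kinds[k])
    }
    genome <- Biostrings::DNAStringSet(setNames(genome_seq, spec$chrom))
    structure(
      list(genome = genome, sites = dplyr::bind_rows(sites),
           models = mm$models, pcms = mm$pcms,
           neutral_pos = neutral_pos, hot_col = hot_col,
           consensus = consensus, anti_base = anti_base, spec = spec),
      class = "tf_fixture"
    )
  })
}

#' Derive loss / gain / neutral variants from planted sites
#'
#' For each planted consensus site, emits an SNV at the most informative
#' motif column replacing the consensus base by the anti-consensus base
#' (expected binding loss, `S < 0`); for each near-consensus site, the
#' reverse SNV completing the consensus (expected gain, `S > 0`); plus
#' neutral variants placed far from every planted site. A neutral variant is
#' an equal-length substitution whose single changed base lies beyond the
#' last scorable window (more than `halfwidth + L - 1` nucleotides from the
#' variant start), which forces `S = 0` exactly for every model.
#'
#' @param fixture A `"tf_fixture"` from [make_genome_with_sites()].
#' @return A list with `variants` (tibble `chrom`, `pos`, `ref`, `alt`) and
#'   `truth` (the same rows plus `tf_name` and `expected_sign` in
#'   `c(-1, 0, 1)`).
#' @export
make_disrupting_vcf <- function(fixture) {
  stopifnot(inherits(fixture, "tf_fixture"))
  spec <- fixture$spec
  genome_seq <- as.character(fixture$genome[[1L]])
  truth_pwm <- fixture$models[[1L]]
  L <- truth_pwm$L
  col <- fixture$hot_col
  cons_base <- substr(fixture$consensus, col, col)
  anti_base <- fixture$anti_base
  rows <- list()
  for (i in seq_len(nrow(fixture$sites))) {
    s <- fixture$sites[i, ]
    if (s$strand == "+") {
      pos <- s$start + col                      # 1-based genomic position
      from <- cons_base; to <- anti_base
    } else {
      pos <- s$start + (L - col) + 1L
      from <- revcomp(cons_base); to <- revcomp(anti_base)
    }
    if (s$kind == "consensus") {
      ref <- from; alt <- to; sign <- -1
    } else {
      ref <- to; alt <- from; sign <- 1
    }
    stopifnot(substr(genome_seq, pos, pos) == ref)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      chrom = s$chrom, pos = pos, ref = ref, alt = alt,
      tf_name = s$tf_name, expected_sign = sign)
  }
  n_neutral <- spec$n_variants - 2L * spec$n_planted_sites
  hw <- 15L
  block <- hw + L + 2L   # changed base at offset block - 1 > hw + L - 1
  for (k in seq_len(n_neutral)) {
    pos <- fixture$neutral_pos[k]
    ref <- substr(genome_seq, pos, pos + block - 1L)
    last <- substr(ref, block, block)
    alt <- ref
    substr(alt, block, block) <- setdiff(DNA_BASES, last)[1L]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      chrom = spec$chrom, pos = pos, ref = ref, alt = alt,
      tf_name = truth_pwm$tf_name, expected_sign = 0)
  }
  truth <- dplyr::bind_rows(rows)
  list(variants = dplyr::select(truth, "chrom", "pos", "ref", "alt"),
       truth = truth)
}

#' Write a complete demo fixture set to disk
#'
#' Emits standard files generated from a [fixture_spec()]: `genome.fa`,
#' `sites.bed` (planted sites as a known-TFBS track), `models/` (per-TF
#' count matrices as JASPAR PFM text and TFFMs as JSON), `variants.vcf` and
#' `truth.tsv`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly, with the fixture as attribute
#'   `"fixture"`.
#' @export
write_demo_fixtures <- function(spec, dir) {
  fixture <- make_genome_with_sites(spec)
  vcf <- make_disrupting_vcf(fixture)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model_dir <- file.path(dir, "models")
  dir.create(model_dir, showWarnings = FALSE)
  Biostrings::writeXStringSet(fixture$genome, file.path(dir, "genome.fa"))
  write_bed(fixture$sites, file.path(dir, "sites.bed"))
  for (p in fixture$pcms) {
    write_pfm(p, file.path(model_dir, paste0(p$model_id, ".pfm")))
  }
  for (m in fixture$models) {
    if (is_tffm(m)) {
      write_model_json(m, file.path(model_dir, paste0(m$model_id, ".json")))
    }
  }
  write_vcf(vcf$variants, file.path(dir, "variants.vcf"))
  readr::write_tsv(vcf$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  attr(dir, "fixture") <- fixture
  invisible(dir)
}

#' Write a PCM as JASPAR PFM text
#'
#' @param x A [pcm()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(x, path) {
  stopifnot(inherits(x, "pcm"))
  lines <- c(sprintf(">%s %s", x$model_id, x$tf_name),
             vapply(1:4, function(b) {
               sprintf("%s [ %s ]", DNA_BASES[b],
                       paste(format(x$counts[b, ], trim = TRUE), collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
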