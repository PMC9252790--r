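#' Scan configuration
#'
#' Tunable parameters of the variant scan.
#'
#' @param window_halfwidth Maximum window-start offset, in nucleotides, on
#'   either side of the variant start (default 15, i.e. windows from -15 to
#'   +15).
#' @param alpha Pseudocount of the joint score (default 0.1); keeps the score
#'   denominators away from zero.
#' @param tffm_only If `TRUE` (default) the per-TF combined score averages
#'   TFFM results only whenever at least one TFFM is available for the TF.
#' @param both_strands Scan the reverse-complement strand as well (default
#'   `TRUE`).
#' @param max_variants Maximum number of VCF records accepted per analysis
#'   (default 10 000).
#' @return A list of class `"scan_config"`.
#' @export
scan_config <- function(window_halfwidth = 15L, alpha = 0.1,
                        tffm_only = TRUE, both_strands = TRUE,
                        max_variants = 10000L) {
  stopifnot(window_halfwidth >= 1, alpha > 0, max_variants >= 1)
  structure(
    list(window_halfwidth = as.integer(window_halfwidth), alpha = alpha,
         tffm_only = isTRUE(tffm_only), both_strands = isTRUE(both_strands),
         max_variants = as.integer(max_variants)),
    class = "scan_config"
  )
}

#' Joint score of a wild-type / mutated score pair
#'
#' Combines the maximal window scores on the reference (`WT`) and variant
#' (`MT`) sequence into a single signed score
#' `S = 2 / (1 + 2^(-2F)) - 1`, where
#' `F = -(1 - MT + alpha)/(1 - WT + alpha) + 1` when `WT > MT` and
#' `F = (1 - WT + alpha)/(1 - MT + alpha) - 1` otherwise. `S` lies strictly
#' between -1 (likely binding-site loss) and +1 (likely gain), is 0 exactly
#' when `WT == MT`, and is antisymmetric in its arguments.
#'
#' @param WT,MT Numeric vectors of scores in `[0, 1]` (recycled).
#' @param alpha Pseudocount, must be positive (default 0.1).
#' @return Numeric vector of joint scores in `(-1, 1)`.
#' @examples
#' joint_score(0.9, 0.2)   # strong predicted loss
#' joint_score(0.2, 0.9)   # equal-magnitude predicted gain
#' @export
joint_score <- function(WT, MT, alpha = 0.1) {
  if (!is.numeric(WT) || !is.numeric(MT)) {
    stop("WT and MT must be numeric", call. = FALSE)
  }
  if (any(WT < 0 | WT > 1, na.rm = TRUE) || any(MT < 0 | MT > 1, na.rm = TRUE)) {
    stop("WT and MT must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("alpha must be a single positive number", call. = FALSE)
  }
  n <- max(length(WT), length(MT))
  WT <- rep_len(WT, n)
  MT <- rep_len(MT, n)
  F <- ifelse(WT > MT,
              -(1 - MT + alpha) / (1 - WT + alpha) + 1,
              (1 - WT + alpha) / (1 - MT + alpha) - 1)
  2 / (1 + 2^(-2 * F)) - 1
}

#' Map a joint score to a qualitative loss/gain category
#'
#' Thresholds on `|S|` of 0.2 / 0.5 / 0.8 bound the weak / moderate / strong
#' bins; the raw score is always reported alongside, so the binning is purely
#' descriptive.
#'
#' @param S Numeric vector of joint scores.
#' @return Character vector such as `"strong_loss"`, `"weak_gain"`, `"none"`.
#' @export
score_category <- function(S) {
  strength <- cut(abs(S), c(-Inf, 0.2, 0.5, 0.8, Inf),
                  labels = c("none", "weak", "moderate", "strong"))
  out <- ifelse(strength == "none", "none",
                paste0(strength, ifelse(S < 0, "_loss", "_gain")))
  as.character(out)
}

# ---- batched window scoring --------------------------------------------------

#' Model score for every window of a sequence
#'
#' Returns the normalised model score of the length-L window starting at each
#' position of `sequence` (forward strand reading). For PWMs this is the
#' min-max-normalised log-odds score. For TFFMs it is the posterior
#' probability that the window is a binding site rather than background:
#' `w_site / (w_site + w_background)`, where `w_site` is the weight of the
#' hidden-state path that enters the motif at the window start and traverses
#' it (motif entry times the first-order motif emissions) and `w_background`
#' is the weight of staying in the background state throughout. Both weights
#' are computed on the window plus one base of left context (marginalised
#' over the background distribution at the sequence start or at an `N`), so
#' a window's score depends only on its local sequence content; `N` bases
#' inside the window contribute a uniform 0.25 to both hypotheses.
#'
#' @param x A motif model.
#' @param sequence DNA string (A/C/G/T/N).
#' @return Numeric vector of length `nchar(sequence) - L + 1` (empty if the
#'   sequence is shorter than the motif).
#' @export
window_scores <- function(x, sequence) {
  UseMethod("window_scores")
}

#' @export
window_scores.pwm <- function(x, sequence) {
  idx <- encode_dna(sequence)
  L <- x$L
  n <- length(idx)
  if (n < L) return(numeric(0))
  starts <- seq_len(n - L + 1L)
  w <- x$weights
  expected <- as.numeric(x$background %*% w)
  raw <- numeric(length(starts))
  for (i in seq_len(L)) {
    o <- idx[starts + i - 1L]
    v <- w[cbind(o, i)]
    v[is.na(o)] <- expected[i]
    raw <- raw + v
  }
  normalise_pwm_score(raw, x)
}

# Per-step factor matrices for the local two-hypothesis window score.
# Each is 5 x 4: rows = previous base A,C,G,T plus a background-marginalised
# row used when the previous base is unknown (sequence start or N).
tffm_step_matrices <- function(x) {
  marg <- function(m, w) rbind(m, as.numeric(w %*% m))
  if (inherits(x, "tffm_first")) {
    list(bg = marg(x$self_transition * x$bg_conditional, x$bg_emission),
         entry = marg(x$motif_entry * x$motif_conditional[[1L]], x$bg_emission),
         motif = lapply(x$motif_conditional[-1L], marg, w = x$bg_emission))
  } else {
    b_idx <- 1:4
    m_idx <- function(i) 4L + 4L * (i - 1L) + 1:4
    motif <- if (x$L > 1L) {
      lapply(2:x$L, function(i) {
        marg(x$transition[m_idx(i - 1L), m_idx(i), drop = FALSE], x$bg_emission)
      })
    } else list()
    list(bg = marg(x$transition[b_idx, b_idx, drop = FALSE], x$bg_emission),
         entry = marg(x$transition[b_idx, m_idx(1L), drop = FALSE], x$bg_emission),
         motif = motif)
  }
}

tffm_window_scores <- function(x, sequence) {
  idx <- encode_dna(sequence)
  L <- x$L
  n <- length(idx)
  if (n < L) return(numeric(0))
  starts <- seq_len(n - L + 1L)
  W <- length(starts)
  mats <- tffm_step_matrices(x)
  w_site <- rep(1, W)
  w_bg <- rep(1, W)
  for (t in seq_len(L)) {
    o <- idx[starts + t - 1L]
    prev <- if (t == 1L) c(NA_integer_, idx)[starts]
            else idx[starts + t - 2L]
    prev_row <- ifelse(is.na(prev), 5L, prev)
    step <- if (t == 1L) mats$entry else mats$motif[[t - 1L]]
    fs <- step[cbind(prev_row, o)]
    fb <- mats$bg[cbind(prev_row, o)]
    fs[is.na(o)] <- 0.25
    fb[is.na(o)] <- 0.25
    w_site <- w_site * fs
    w_bg <- w_bg * fb
  }
  tot <- w_site + w_bg
  out <- ifelse(tot > 0, w_site / tot, 0)
  unname(out)
}

#' @export
window_scores.tffm_first <- function(x, sequence) {
  tffm_window_scores(x, sequence)
}

#' @export
window_scores.tffm_detailed <- function(x, sequence) {
  tffm_window_scores(x, sequence)
}

# ---- best window around a variant --------------------------------------------

#' Best window score around a variant position
#'
#' Evaluates the model in every window whose start offset relative to the
#' variant start lies within `[-window_halfwidth, +window_halfwidth]`, on the
#' forward and (optionally) reverse-complement strand, and returns the
#' maximum normalised score. Windows extending past either sequence end are
#' skipped. Ties are broken deterministically: smallest `|offset|` first,
#' then the negative offset, then the forward strand.
#'
#' @param x A motif model.
#' @param sequence DNA string.
#' @param variant_offset 0-based index of the variant start within `sequence`.
#' @param cfg A [scan_config()].
#' @return A list with elements `score` (in `[0, 1]`), `offset` (window start
#'   relative to the variant start) and `strand` (`"+"` or `"-"`). If no
#'   window fits, `score` is 0 with a warning and `offset`/`strand` are `NA`.
#' @export
best_window_score <- function(x, sequence, variant_offset, cfg = scan_config()) {
  L <- motif_length(x)
  n <- nchar(sequence)
  hw <- cfg$window_halfwidth
  starts0 <- (variant_offset - hw):(variant_offset + hw)   # 0-based starts
  starts0 <- starts0[starts0 >= 0 & starts0 + L <= n]
  if (length(starts0) == 0L) {
    warning("no scorable window around the variant")
    return(list(score = 0, offset = NA_integer_, strand = NA_character_))
  }
  fwd_all <- window_scores(x, sequence)
  cand <- data.frame(offset = starts0 - variant_offset,
                     strand = "+",
                     score = fwd_all[starts0 + 1L])
  if (cfg$both_strands) {
    rc_all <- window_scores(x, revcomp(sequence))
    # window with 0-based start p on the forward strand appears in the
    # reverse complement at 0-based start n - L - p
    cand_rc <- data.frame(offset = starts0 - variant_offset,
                          strand = "-",
                          score = rc_all[n - L - starts0 + 1L])
    cand <- rbind(cand, cand_rc)
  }
  ord <- order(-cand$score, abs(cand$offset), cand$offset,
               match(cand$strand, c("+", "-")))
  best <- cand[ord[1L], ]
  list(score = best$score, offset = as.integer(best$offset),
       strand = best$strand)
}

# ---- sequence pairs ----------------------------------------------------------

#' Reference/variant sequence pair
#'
#' Holds the extracted wild-type sequence, the mutated sequence obtained by
#' substituting the alternate allele, and the 0-based offset of the variant
#' start shared by both (windows are anchored at the variant start in each
#' sequence's own coordinate frame).
#'
#' @param wt_seq,mt_seq DNA strings.
#' @param variant_offset 0-based index of the variant start.
#' @param ref,alt Reference and alternate alleles. If omitted they are
#'   inferred from the first and last positions at which the two sequences
#'   differ (sequences of equal length only).
#' @return A list of class `"sequence_pair"`.
#' @export
sequence_pair <- function(wt_seq, mt_seq, variant_offset = NULL,
                          ref = NULL, alt = NULL) {
  wt_seq <- toupper(wt_seq)
  mt_seq <- toupper(mt_seq)
  if (!is_dna_string(wt_seq) || !is_dna_string(mt_seq)) {
    stop("sequences must be non-empty A/C/G/T/N strings", call. = FALSE)
  }
  if (is.null(ref) || is.null(alt) || is.null(variant_offset)) {
    if (nchar(wt_seq) != nchar(mt_seq)) {
      stop("ref/alt can only be inferred for equal-length sequences",
           call. = FALSE)
    }
    a <- strsplit(wt_seq, "")[[1L]]
    b <- strsplit(mt_seq, "")[[1L]]
    diffs <- which(a != b)
    if (length(diffs) == 0L) {
      stop("sequences are identical; nothing to score", call. = FALSE)
    }
    variant_offset <- diffs[1L] - 1L
    ref <- substr(wt_seq, diffs[1L], diffs[length(diffs)])
    alt <- substr(mt_seq, diffs[1L], diffs[length(diffs)])
  }
  stopifnot(variant_offset >= 0)
  if (substr(wt_seq, variant_offset + 1L, variant_offset + nchar(ref)) != ref) {
    stop("wt_seq does not carry the reference allele at variant_offset",
         call. = FALSE)
  }
  structure(
    list(wt_seq = wt_seq, mt_seq = mt_seq,
         variant_offset = as.integer(variant_offset), ref = ref, alt = alt),
    class = "sequence_pair"
  )
}

#' Score one variant against a set of models
#'
#' For each model, the maximal window score is computed independently on the
#' wild-type and the mutated sequence (both anchored at the variant start)
#' and combined into the signed joint score `S`.
#'
#' @param pair A [sequence_pair()].
#' @param models A list of motif models.
#' @param cfg A [scan_config()].
#' @return A tibble with one row per model: `model_id`, `tf_name`,
#'   `model_kind`, `WT`, `MT`, `S`, and the best window offset/strand on each
#'   sequence.
#' @export
scan_variant <- function(pair, models, cfg = scan_config()) {
  stopifnot(inherits(pair, "sequence_pair"), length(models) >= 1L)
  del_len <- nchar(pair$ref) - nchar(pair$alt)
  if (del_len > 2L * cfg$window_halfwidth) {
    stop("deletion abolishes complete TFBS; not analysable", call. = FALSE)
  }
  rows <- purrr::map(models, function(m) {
    wt <- best_window_score(m, pair$wt_seq, pair$variant_offset, cfg)
    mt <- best_window_score(m, pair$mt_seq, pair$variant_offset, cfg)
    tibble::tibble(
      model_id = m$model_id, tf_name = m$tf_name, model_kind = model_kind(m),
      WT = wt$score, MT = mt$score,
      S = joint_score(wt$score, mt$score, cfg$alpha),
      best_wt_offset = wt$offset, best_wt_strand = wt$strand,
      best_mt_offset = mt$offset, best_mt_strand = mt$strand
    )
  })
  dplyr::bind_rows(rows)
}

#' Combine per-model joint scores into per-TF predictions
#'
#' Averages the joint score `S` over the models of each transcription
#' factor. With `tffm_only = TRUE` (the default) only TFFM results enter the
#' average whenever at least one TFFM outcome exists for the TF; TFs with
#' only PWM models fall back to averaging over all of their models.
#'
#' @param outcomes Tibble of per-model outcomes as returned by
#'   [scan_variant()].
#' @param tffm_only Restrict the combined score to TFFMs where available.
#' @return Tibble with one row per TF: `tf_name`, `combined_S`,
#'   `n_models_used`, `tffm_only_used`, and the contributing outcomes as a
#'   nested list-column `outcomes`.
#' @export
combine_per_tf <- function(outcomes, tffm_only = TRUE) {
  stopifnot(is.data.frame(outcomes))
  if (nrow(outcomes) == 0L) {
    return(tibble::tibble(tf_name = character(), combined_S = numeric(),
                          n_models_used = integer(),
                          tffm_only_used = logical(), outcomes = list()))
  }
  outcomes |>
    dplyr::group_by(.data$tf_name) |>
    dplyr::group_modify(function(g, key) {
      is_t <- g$model_kind %in% c("TFFM_first", "TFFM_detailed")
      use_tffm <- tffm_only && any(is_t)
      sel <- if (use_tffm) g[is_t, ] else g
      tibble::tibble(combined_S = mean(sel$S),
                     n_models_used = nrow(sel),
                     tffm_only_used = use_tffm,
                     outcomes = list(g))
    }) |>
    dplyr::ungroup()
}
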