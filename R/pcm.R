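#' Position count matrix
#'
#' Container for the raw base counts observed at each position of an aligned
#' set of transcription-factor binding sites. Counts may be non-integer
#' (weighted alignments are common); they must be non-negative and at least
#' one column must have a positive total.
#'
#' @param counts 4 x L numeric matrix, rows A, C, G, T.
#' @param tf_name Transcription-factor name.
#' @param model_id Unique model identifier.
#' @param source Data source label.
#' @return An object of class `"pcm"`.
#' @examples
#' pcm(matrix(c(8, 0, 0, 0, 2, 2, 2, 2), nrow = 4), "TFX", "TFX.1")
#' @export
pcm <- function(counts, tf_name, model_id, source = "custom") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) {
    stop("a position count matrix needs 4 rows (A, C, G, T)", call. = FALSE)
  }
  if (ncol(counts) < 1L) {
    stop("a position count matrix needs at least one column", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  if (all(colSums(counts) == 0)) {
    stop("at least one column must have a positive total", call. = FALSE)
  }
  dimnames(counts) <- list(DNA_BASES, NULL)
  structure(
    list(counts = counts, tf_name = tf_name, model_id = model_id,
         source = source),
    class = "pcm"
  )
}

#' @export
print.pcm <- function(x, ...) {
  cat(sprintf("<pcm> %s (%s, source: %s), %d positions\n",
              x$model_id, x$tf_name, x$source, ncol(x$counts)))
  print(round(x$counts, 2))
  invisible(x)
}

#' Convert a position count matrix to a position weight matrix
#'
#' Log2-odds conversion against a background distribution with a
#' background-weighted pseudocount:
#' `w[b,i] = log2( ((counts[b,i] + k*bg[b]) / (N_i + k)) / bg[b] )`
#' where `N_i` is the column total. By default the pseudocount `k` is the
#' square root of the column total; a non-negative constant can be supplied
#' instead. Column-wise minimum and maximum attainable sums are cached for
#' score normalisation.
#'
#' @param x A [pcm()].
#' @param bg Background distribution, see [dna_background()].
#' @param pseudocount `NULL` (default, `k = sqrt(N_i)` per column) or a single
#'   non-negative number used for every column.
#' @return An object of class `"pwm"`.
#' @examples
#' m <- pcm(matrix(c(8, 0, 0, 0, 2, 2, 2, 2), nrow = 4), "TFX", "TFX.1")
#' pcm_to_pwm(m, dna_background(.25, .25, .25, .25), pseudocount = 1)
#' @export
pcm_to_pwm <- function(x, bg = dna_background(), pseudocount = NULL) {
  stopifnot(inherits(x, "pcm"))
  if (any(bg <= 0)) stop("background must be strictly positive", call. = FALSE)
  counts <- x$counts
  n_i <- colSums(counts)
  if (any(n_i == 0)) stop("degenerate motif column", call. = FALSE)
  if (is.null(pseudocount)) {
    k <- sqrt(n_i)
  } else {
    if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0) {
      stop("pseudocount must be a single non-negative number", call. = FALSE)
    }
    k <- rep(pseudocount, length(n_i))
  }
  freq <- sweep(counts + outer(bg, k), 2, n_i + k, "/")
  if (any(freq <= 0)) {
    stop("zero frequency with zero pseudocount; supply pseudocount > 0",
         call. = FALSE)
  }
  weights <- log2(freq / bg)
  dimnames(weights) <- list(DNA_BASES, NULL)
  structure(
    list(weights = weights, background = bg,
         min_score = sum(apply(weights, 2, min)),
         max_score = sum(apply(weights, 2, max)),
         L = ncol(weights),
         tf_name = x$tf_name, model_id = x$model_id, source = x$source),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (%s, source: %s), %d positions, raw score range [%.3f, %.3f]\n",
              x$model_id, x$tf_name, x$source, x$L, x$min_score, x$max_score))
  print(round(x$weights, 3))
  invisible(x)
}

#' Per-position information content of a motif
#'
#' `IC_i = 2 + sum_b p[b,i] * log2 p[b,i]` in bits, with frequencies
#' `p[b,i] = (counts[b,i] + k/4) / (N_i + k)`. Lies in `[0, 2]`: 0 for a
#' uniform column, 2 for an invariant base. An all-zero column with `k = 0`
#' is treated as uniform (0 bits).
#'
#' @param x A [pcm()].
#' @param pseudocount Single non-negative number `k` (default 0).
#' @return Numeric vector, one value per motif position.
#' @export
information_content <- function(x, pseudocount = 0) {
  stopifnot(inherits(x, "pcm"), pseudocount >= 0)
  counts <- x$counts + pseudocount / 4
  n_i <- colSums(counts)
  ic <- vapply(seq_len(ncol(counts)), function(i) {
    if (n_i[i] == 0) return(0)
    p <- counts[, i] / n_i[i]
    p <- p[p > 0]
    2 + sum(p * log2(p))
  }, numeric(1))
  pmin(pmax(ic, 0), 2)
}

#' Normalised PWM score of a single window
#'
#' The raw log-odds sum is rescaled to `[0, 1]` as
#' `(raw - min_score) / (max_score - min_score)`, so the consensus sequence
#' (per-column argmax) scores exactly 1 and the anti-consensus exactly 0.
#' `N` bases contribute their background-expected column value. A constant
#' PWM (`max_score == min_score`) returns 0.5 for every window.
#'
#' @param x A `"pwm"` object.
#' @param window DNA string of exactly the motif length (A/C/G/T/N).
#' @return A number in `[0, 1]`.
#' @export
pwm_window_score <- function(x, window) {
  stopifnot(inherits(x, "pwm"))
  if (!is.character(window) || nchar(window) != x$L) {
    stop(sprintf("window must be a string of length %d", x$L), call. = FALSE)
  }
  idx <- encode_dna(window)
  w <- x$weights
  expected <- as.numeric(x$background %*% w)  # per-column E[w | background]
  per_pos <- ifelse(is.na(idx), expected, w[cbind(idx, seq_len(x$L))])
  normalise_pwm_score(sum(per_pos), x)
}

normalise_pwm_score <- function(raw, pwm) {
  rng <- pwm$max_score - pwm$min_score
  if (rng <= 0) return(rep(0.5, length(raw)))
  pmin(pmax((raw - pwm$min_score) / rng, 0), 1)
}

#' Consensus and anti-consensus sequences of a PWM
#'
#' @param x A `"pwm"` object.
#' @return A DNA string (ties broken towards the first of A, C, G, T).
#' @export
pwm_consensus <- function(x) {
  stopifnot(inherits(x, "pwm"))
  decode_dna(apply(x$weights, 2, which.max))
}

#' @rdname pwm_consensus
#' @export
pwm_anticonsensus <- function(x) {
  stopifnot(inherits(x, "pwm"))
  decode_dna(apply(x$weights, 2, which.min))
}
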