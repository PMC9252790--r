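#' First-order transcription factor flexible model
#'
#' A TFFM is a hidden Markov model of a binding site. In the first-order
#' flavour each motif position is one state whose emission probabilities
#' depend on the nucleotide observed at the previous position; a single
#' background state emits flanking sequence. The state chain is
#' `B -> M1 -> M2 -> ... -> ML -> B`, with `P(B -> B) = self_transition` and
#' `P(B -> M1) = motif_entry` (their sum may be below 1, in which case the
#' remaining mass is unassigned and the background row is sub-stochastic;
#' posteriors are normalised so this only down-weights background paths).
#'
#' @param motif_conditional List of L row-stochastic 4x4 matrices;
#'   `[[i]][p, b]` is the probability of base `b` at motif position `i` given
#'   previous base `p` (position 1 conditions on the last background base).
#' @param bg_emission Marginal background base distribution (first base of a
#'   sequence and context marginalisation).
#' @param bg_conditional Row-stochastic 4x4 matrix of background emissions
#'   given the previous base. Defaults to rows equal to `bg_emission`.
#' @param self_transition,motif_entry Background self-transition and motif
#'   entry probabilities, both in (0, 1) with sum at most 1.
#' @param tf_name,model_id,source Model metadata.
#' @return An object of class `"tffm_first"`.
#' @export
tffm_first_order <- function(motif_conditional,
                             bg_emission = dna_background(),
                             bg_conditional = NULL,
                             self_transition = 0.95,
                             motif_entry = 1 - self_transition,
                             tf_name = "TF", model_id = "TFFM",
                             source = "custom") {
  stopifnot(is.list(motif_conditional), length(motif_conditional) >= 1L)
  motif_conditional <- lapply(motif_conditional, as.matrix)
  if (abs(sum(bg_emission) - 1) > 1e-9 || any(bg_emission <= 0)) {
    stop("bg_emission must be a positive distribution summing to 1", call. = FALSE)
  }
  if (is.null(bg_conditional)) {
    bg_conditional <- matrix(rep(bg_emission, each = 4), 4, 4,
                             dimnames = list(DNA_BASES, DNA_BASES))
  }
  check_stochastic <- function(m, what) {
    if (!all(dim(m) == c(4L, 4L)) || any(m < 0) ||
        any(abs(rowSums(m) - 1) > 1e-9)) {
      stop(sprintf("%s must be a row-stochastic 4x4 matrix", what),
           call. = FALSE)
    }
  }
  check_stochastic(bg_conditional, "bg_conditional")
  for (i in seq_along(motif_conditional)) {
    check_stochastic(motif_conditional[[i]], sprintf("motif_conditional[[%d]]", i))
  }
  if (self_transition <= 0 || self_transition >= 1 ||
      motif_entry < 0 || motif_entry >= 1 ||
      self_transition + motif_entry > 1 + 1e-12) {
    stop("need 0 < self_transition < 1, 0 <= motif_entry < 1, sum <= 1",
         call. = FALSE)
  }
  structure(
    list(L = length(motif_conditional),
         bg_emission = bg_emission,
         bg_conditional = bg_conditional,
         motif_conditional = motif_conditional,
         self_transition = self_transition,
         motif_entry = motif_entry,
         tf_name = tf_name, model_id = model_id, source = source),
    class = "tffm_first"
  )
}

#' @export
print.tffm_first <- function(x, ...) {
  cat(sprintf("<tffm_first> %s (%s, source: %s), %d motif positions, entry %.3g\n",
              x$model_id, x$tf_name, x$source, x$L, x$motif_entry))
  invisible(x)
}

#' @export
print.tffm_detailed <- function(x, ...) {
  cat(sprintf("<tffm_detailed> %s (%s, source: %s), %d motif positions, %d states\n",
              x$model_id, x$tf_name, x$source, x$L, nrow(x$transition)))
  invisible(x)
}

#' Decompose a first-order TFFM into its detailed form
#'
#' Each first-order state is split into four per-nucleotide states; the
#' first-order emission probabilities become transition probabilities between
#' these states, and every state deterministically emits its own nucleotide.
#' The detailed model assigns exactly the same likelihood to every sequence
#' as the source model.
#'
#' @param x A `"tffm_first"` model.
#' @return An object of class `"tffm_detailed"` with `4 + 4L` states
#'   (4 background states followed by 4 states per motif position).
#' @export
build_detailed_from_first_order <- function(x) {
  stopifnot(inherits(x, "tffm_first"))
  L <- x$L
  n <- 4L + 4L * L
  A <- matrix(0, n, n)
  b_idx <- 1:4
  m_idx <- function(i) 4L + 4L * (i - 1L) + 1:4
  A[b_idx, b_idx] <- x$self_transition * x$bg_conditional
  A[b_idx, m_idx(1)] <- x$motif_entry * x$motif_conditional[[1]]
  if (L > 1) {
    for (i in seq_len(L - 1)) {
      A[m_idx(i), m_idx(i + 1)] <- x$motif_conditional[[i + 1]]
    }
  }
  A[m_idx(L), b_idx] <- x$bg_conditional
  state_base <- rep(1:4, L + 1)       # emitted nucleotide per state
  state_pos <- rep(0:L, each = 4)     # 0 = background
  structure(
    list(L = L, transition = A, initial = as.numeric(x$bg_emission),
         state_base = state_base, state_pos = state_pos,
         bg_emission = x$bg_emission,
         tf_name = x$tf_name, model_id = x$model_id, source = x$source),
    class = "tffm_detailed"
  )
}

#' Construct a detailed TFFM directly
#'
#' For models read from files rather than decomposed from a first-order
#' model. States are ordered as 4 background states (A, C, G, T) followed by
#' 4 states per motif position; the state for nucleotide `b` deterministically
#' emits `b`.
#'
#' @param transition `(4 + 4L) x (4 + 4L)` transition matrix; motif rows must
#'   be stochastic, background rows may be sub-stochastic.
#' @param initial Initial distribution over the 4 background states.
#' @param tf_name,model_id,source Model metadata.
#' @return An object of class `"tffm_detailed"`.
#' @export
tffm_detailed <- function(transition, initial = dna_background(),
                          tf_name = "TF", model_id = "TFFM.d",
                          source = "custom") {
  transition <- as.matrix(transition)
  n <- nrow(transition)
  if (n != ncol(transition) || n %% 4L != 0L || n < 8L) {
    stop("transition must be square with 4 + 4L rows (L >= 1)", call. = FALSE)
  }
  L <- n %/% 4L - 1L
  if (any(transition < 0) || any(rowSums(transition) > 1 + 1e-9)) {
    stop("transition rows must be non-negative with sums at most 1", call. = FALSE)
  }
  if (any(abs(rowSums(transition[-(1:4), , drop = FALSE]) - 1) > 1e-9)) {
    stop("motif-state transition rows must sum to 1", call. = FALSE)
  }
  if (abs(sum(initial) - 1) > 1e-9) {
    stop("initial distribution must sum to 1", call. = FALSE)
  }
  structure(
    list(L = L, transition = transition, initial = as.numeric(initial),
         state_base = rep(1:4, L + 1), state_pos = rep(0:L, each = 4),
         bg_emission = as.numeric(initial),
         tf_name = tf_name, model_id = model_id, source = source),
    class = "tffm_detailed"
  )
}

# ---- generic model accessors -------------------------------------------------

#' Motif model properties
#'
#' @param x A `"pwm"`, `"tffm_first"` or `"tffm_detailed"` model.
#' @return `motif_length()`: integer motif length; `model_kind()`: one of
#'   `"PWM"`, `"TFFM_first"`, `"TFFM_detailed"`.
#' @export
motif_length <- function(x) {
  if (inherits(x, "pwm")) x$L
  else if (inherits(x, c("tffm_first", "tffm_detailed"))) x$L
  else if (inherits(x, "pcm")) ncol(x$counts)
  else stop("not a motif model", call. = FALSE)
}

#' @rdname motif_length
#' @export
model_kind <- function(x) {
  if (inherits(x, "pwm")) "PWM"
  else if (inherits(x, "tffm_first")) "TFFM_first"
  else if (inherits(x, "tffm_detailed")) "TFFM_detailed"
  else if (inherits(x, "pcm")) "PCM"
  else stop("not a motif model", call. = FALSE)
}

is_tffm <- function(x) inherits(x, c("tffm_first", "tffm_detailed"))

# ---- forward-backward --------------------------------------------------------

# Scaled forward-backward. A: transition (possibly sub-stochastic rows),
# pi: initial distribution, E: T x S emission matrix. Returns posteriors
# gamma (T x S) and the log-likelihood. Per-position scaling factors keep the
# recursion in range; posteriors are identical to unscaled arithmetic.
forward_backward <- function(A, pi, E) {
  TT <- nrow(E)
  S <- ncol(E)
  alpha <- matrix(0, TT, S)
  scale <- numeric(TT)
  a <- pi * E[1, ]
  scale[1] <- sum(a)
  if (scale[1] <= 0) stop("sequence has zero likelihood under model", call. = FALSE)
  alpha[1, ] <- a / scale[1]
  if (TT > 1) {
    for (t in 2:TT) {
      a <- as.numeric(alpha[t - 1, ] %*% A) * E[t, ]
      scale[t] <- sum(a)
      if (scale[t] <= 0) stop("sequence has zero likelihood under model", call. = FALSE)
      alpha[t, ] <- a / scale[t]
    }
  }
  beta <- matrix(0, TT, S)
  beta[TT, ] <- 1
  if (TT > 1) {
    for (t in (TT - 1):1) {
      beta[t, ] <- as.numeric(A %*% (E[t + 1, ] * beta[t + 1, ])) / scale[t + 1]
    }
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(gamma = gamma, loglik = sum(log(scale)))
}

# Augmented conditional emission lookup for first-order models: a 5 x 4
# matrix per state where row 5 is the background-marginalised row used when
# the previous base is unknown (sequence start or N).
fo_augmented <- function(x) {
  aug <- function(m) rbind(m, as.numeric(x$bg_emission %*% m))
  list(
    bg = aug(x$bg_conditional),
    motif = lapply(x$motif_conditional, aug)
  )
}

# Emission matrix for a first-order model over an encoded sequence (NA = N).
# State order: B, M1..ML. The first base is emitted from the marginal
# bg_emission in state B and from the marginalised conditional in motif
# states (only reachable if the initial distribution allows it).
fo_emission_matrix <- function(x, idx) {
  TT <- length(idx)
  L <- x$L
  augs <- fo_augmented(x)
  E <- matrix(0, TT, L + 1L)
  prev <- c(NA_integer_, idx[-TT])
  prev_row <- ifelse(is.na(prev), 5L, prev)
  for (t in seq_len(TT)) {
    o <- idx[t]
    if (t == 1L) {
      E[t, 1L] <- if (is.na(o)) 0.25 else x$bg_emission[o]
      E[t, -1L] <- if (is.na(o)) 0.25 else
        vapply(augs$motif, function(m) m[5L, o], numeric(1))
    } else if (is.na(o)) {
      E[t, ] <- 0.25
    } else {
      E[t, 1L] <- augs$bg[prev_row[t], o]
      E[t, -1L] <- vapply(augs$motif, function(m) m[prev_row[t], o], numeric(1))
    }
  }
  E
}

fo_transition <- function(x) {
  L <- x$L
  A <- matrix(0, L + 1L, L + 1L)
  A[1L, 1L] <- x$self_transition
  A[1L, 2L] <- x$motif_entry
  if (L > 1) for (i in seq_len(L - 1)) A[i + 1L, i + 2L] <- 1
  A[L + 1L, 1L] <- 1
  A
}

#' Posterior motif-end probabilities along a sequence
#'
#' Runs the forward-backward algorithm and returns, for every sequence
#' position, the posterior probability (given the whole sequence) that a
#' motif occurrence ends at that position, i.e. that the hidden state is the
#' final motif state (summed over its per-nucleotide sub-states for detailed
#' models). `N` bases are scored with a uniform emission substitution.
#'
#' @param x A `"tffm_first"` or `"tffm_detailed"` model.
#' @param sequence DNA string (A/C/G/T/N), at least as long as the motif.
#' @return Numeric vector in `[0, 1]`, one element per sequence position.
#'   A sequence shorter than the motif returns `numeric(0)` with a warning.
#' @export
tffm_posterior_scores <- function(x, sequence) {
  stopifnot(is_tffm(x))
  idx <- encode_dna(sequence)
  if (length(idx) < x$L) {
    warning("sequence shorter than motif; no positions scorable")
    return(numeric(0))
  }
  if (inherits(x, "tffm_first")) {
    E <- fo_emission_matrix(x, idx)
    pi <- c(1, rep(0, x$L))
    fb <- forward_backward(fo_transition(x), pi, E)
    unname(fb$gamma[, x$L + 1L])
  } else {
    E <- detailed_emission_matrix(x, idx)
    pi <- c(x$initial, rep(0, 4L * x$L))
    fb <- forward_backward(x$transition, pi, E)
    unname(rowSums(fb$gamma[, x$state_pos == x$L, drop = FALSE]))
  }
}

detailed_emission_matrix <- function(x, idx) {
  TT <- length(idx)
  E <- matrix(0.25, TT, length(x$state_base))
  known <- !is.na(idx)
  for (t in which(known)) {
    E[t, ] <- as.numeric(x$state_base == idx[t])
  }
  E
}

#' Log-likelihood of a sequence under a TFFM
#'
#' @param x A `"tffm_first"` or `"tffm_detailed"` model.
#' @param sequence DNA string.
#' @return Log-likelihood (natural log).
#' @export
tffm_sequence_loglik <- function(x, sequence) {
  stopifnot(is_tffm(x))
  idx <- encode_dna(sequence)
  if (inherits(x, "tffm_first")) {
    E <- fo_emission_matrix(x, idx)
    pi <- c(1, rep(0, x$L))
    forward_backward(fo_transition(x), pi, E)$loglik
  } else {
    E <- detailed_emission_matrix(x, idx)
    pi <- c(x$initial, rep(0, 4L * x$L))
    forward_backward(x$transition, pi, E)$loglik
  }
}
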