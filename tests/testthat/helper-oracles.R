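# Independent oracles and tiny model builders used across the tests.

# Exhaustive hidden-path posterior: enumerates every state path of an HMM
# with transition A, initial pi and emission matrix E (T x S), and returns
# for each time point the posterior mass of `target_states`. Independent of
# the package's forward-backward implementation.
enum_posterior <- function(A, pi, E, target_states) {
  TT <- nrow(E)
  S <- ncol(E)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), TT)))
  w <- pi[paths[, 1L]] * E[cbind(1L, paths[, 1L])]
  if (TT > 1L) {
    for (t in 2:TT) {
      w <- w * A[cbind(paths[, t - 1L], paths[, t])] * E[cbind(t, paths[, t])]
    }
  }
  tot <- sum(w)
  vapply(seq_len(TT), function(t) {
    sum(w[paths[, t] %in% target_states]) / tot
  }, numeric(1))
}

# Emission matrix of a first-order TFFM over an encoded sequence, written
# directly from the model definition (state order B, M1..ML; first base from
# the marginal distributions).
oracle_fo_emissions <- function(m, seq_chars) {
  idx <- match(seq_chars, c("A", "C", "G", "T"))
  TT <- length(idx)
  E <- matrix(0, TT, m$L + 1L)
  for (t in seq_len(TT)) {
    o <- idx[t]
    if (is.na(o)) { E[t, ] <- 0.25; next }
    if (t == 1L) {
      E[t, 1L] <- m$bg_emission[o]
      for (i in seq_len(m$L)) {
        E[t, i + 1L] <- sum(m$bg_emission * m$motif_conditional[[i]][, o])
      }
    } else {
      p <- idx[t - 1L]
      prow <- function(mat) if (is.na(p)) sum(m$bg_emission * mat[, o]) else mat[p, o]
      E[t, 1L] <- prow(m$bg_conditional)
      for (i in seq_len(m$L)) E[t, i + 1L] <- prow(m$motif_conditional[[i]])
    }
  }
  E
}

oracle_fo_transition <- function(m) {
  A <- matrix(0, m$L + 1L, m$L + 1L)
  A[1L, 1L] <- m$self_transition
  A[1L, 2L] <- m$motif_entry
  if (m$L > 1L) for (i in seq_len(m$L - 1L)) A[i + 1L, i + 2L] <- 1
  A[m$L + 1L, 1L] <- 1
  A
}

# Posterior of a first-order TFFM by brute force.
oracle_fo_posterior <- function(m, sequence) {
  ch <- strsplit(sequence, "")[[1L]]
  enum_posterior(oracle_fo_transition(m), c(1, rep(0, m$L)),
                 oracle_fo_emissions(m, ch), m$L + 1L)
}

# Posterior of a detailed TFFM by brute force.
oracle_detailed_posterior <- function(d, sequence) {
  idx <- match(strsplit(sequence, "")[[1L]], c("A", "C", "G", "T"))
  TT <- length(idx)
  S <- length(d$state_base)
  E <- matrix(0.25, TT, S)
  for (t in seq_len(TT)) {
    if (!is.na(idx[t])) E[t, ] <- as.numeric(d$state_base == idx[t])
  }
  enum_posterior(d$transition, c(d$initial, rep(0, S - 4L)), E,
                 which(d$state_pos == d$L))
}

# Direct two-hypothesis window score of a first-order TFFM for one window,
# spelled out from its definition (site path weight vs background path
# weight over window plus context base).
oracle_window_score <- function(m, window, context = NULL) {
  idx <- match(strsplit(window, "")[[1L]], c("A", "C", "G", "T"))
  bg <- m$bg_emission
  cond_row <- function(mat, prev) {
    if (is.null(prev) || is.na(prev)) as.numeric(bg %*% mat) else mat[prev, ]
  }
  prev <- if (is.null(context)) NULL else match(context, c("A", "C", "G", "T"))
  w_site <- m$motif_entry
  w_bg <- 1
  for (i in seq_along(idx)) {
    w_site <- w_site * cond_row(m$motif_conditional[[i]], prev)[idx[i]]
    w_bg <- w_bg * m$self_transition * cond_row(m$bg_conditional, prev)[idx[i]]
    prev <- idx[i]
  }
  w_site / (w_site + w_bg)
}

# All DNA words of a given length.
all_kmers <- function(k) {
  apply(as.matrix(expand.grid(rep(list(c("A", "C", "G", "T")), k))), 1L,
        paste, collapse = "")
}

rc <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1L]]), collapse = "")
}

# A small fixed PCM used in several tests: strong consensus ACGT with one
# degenerate column appended.
toy_pcm <- function() {
  counts <- cbind(c(90, 4, 3, 3), c(2, 90, 4, 4), c(5, 3, 90, 2),
                  c(1, 2, 2, 95), c(25, 25, 25, 25))
  pcm(counts, tf_name = "TOY", model_id = "TOY.1", source = "test")
}

# A tiny hand-specified first-order TFFM (L = 2) with visible dependency.
toy_tffm <- function(entry = 0.1, self = 0.85) {
  c1 <- rbind(c(0.70, 0.10, 0.10, 0.10),
              c(0.10, 0.70, 0.10, 0.10),
              c(0.10, 0.10, 0.70, 0.10),
              c(0.10, 0.10, 0.10, 0.70))
  c2 <- rbind(c(0.05, 0.85, 0.05, 0.05),
              c(0.85, 0.05, 0.05, 0.05),
              c(0.05, 0.05, 0.85, 0.05),
              c(0.25, 0.25, 0.25, 0.25))
  tffm_first_order(list(c1, c2),
                   bg_emission = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                   self_transition = self, motif_entry = entry,
                   tf_name = "TOY", model_id = "TOY.t1", source = "test")
}

# A PWM whose consensus is a fixed word, for planting tests.
word_pwm <- function(word, tf_name = "PLANT", model_id = paste0(tf_name, ".pwm")) {
  idx <- match(strsplit(word, "")[[1L]], c("A", "C", "G", "T"))
  counts <- vapply(idx, function(b) {
    col <- rep(2, 4)
    col[b] <- 94
    col
  }, numeric(4))
  pcm_to_pwm(pcm(matrix(counts, nrow = 4), tf_name, model_id, "test"),
             dna_background(.25, .25, .25, .25), pseudocount = 1)
}
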