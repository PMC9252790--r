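DNA_BASES <- c("A", "C", "G", "T")

#' Background nucleotide distribution
#'
#' Genome-wide base composition used for PCM-to-PWM conversion, for the
#' background states of TFFMs and for sampling synthetic sequence. The default
#' reflects the approximately 41% GC content of the human genome
#' (A = T = 0.295, C = G = 0.205).
#'
#' @param A,C,G,T Base probabilities; must be positive and sum to 1.
#' @return A named numeric vector of length 4 (A, C, G, T).
#' @examples
#' dna_background()            # human-genome default
#' dna_background(.25, .25, .25, .25)  # uniform
#' @export
dna_background <- function(A = 0.295, C = 0.205, G = 0.205, T = 0.295) {
  probs <- c(A = A, C = C, G = G, T = T)
  if (any(probs <= 0)) {
    stop("background probabilities must all be positive", call. = FALSE)
  }
  if (abs(sum(probs) - 1) > 1e-9) {
    stop("background probabilities must sum to 1", call. = FALSE)
  }
  probs
}

# Encode a DNA string as integers 1..4 (A,C,G,T); anything else (N and other
# ambiguity codes) becomes NA.
encode_dna <- function(x) {
  stopifnot(length(x) == 1L)
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  match(chars, DNA_BASES)
}

decode_dna <- function(idx) {
  paste(ifelse(is.na(idx), "N", DNA_BASES[idx]), collapse = "")
}

# Reverse complement preserving N.
revcomp <- function(x) {
  stopifnot(length(x) == 1L)
  chars <- rev(strsplit(chartr("ACGTNacgtn", "TGCANTGCAN", x), "", fixed = TRUE)[[1L]])
  paste(chars, collapse = "")
}

is_dna_string <- function(x, allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  is.character(x) && length(x) == 1L && !is.na(x) && grepl(pat, toupper(x))
}

# Random DNA of length n drawn from a background distribution. Uses the
# current RNG stream; callers are responsible for seeding.
random_dna <- function(n, bg = dna_background()) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = bg), collapse = "")
}

# Save/restore the global RNG state around seeded fixture generation so that
# generators are deterministic without clobbering the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Unify "chr1" and "1" style chromosome names (comparison key).
norm_chrom <- function(x) {
  sub("^chr", "", as.character(x), ignore.case = TRUE)
}
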