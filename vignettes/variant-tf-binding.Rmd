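---
title: "Scoring the effect of DNA variants on transcription factor binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the effect of DNA variants on transcription factor binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfshift)
```

## The problem

Most disease-associated variants fall outside coding sequence, and a large
class of them acts by changing whether a transcription factor (TF) can bind
a promoter or enhancer. A single base substitution inside a binding site can
abolish binding (a *loss*, typically reducing expression of the downstream
gene) or create a new site (a *gain*). `tfshift` scores this effect: given a
variant, a reference genome, and a collection of binding models, it reports
for every TF a signed score between −1 (likely binding-site loss) and +1
(likely gain).

Two families of binding models are supported:

* **Position weight matrices (PWMs)**, derived from position count matrices
  (PCMs) of aligned, experimentally confirmed binding sites. PWMs treat
  motif positions as independent.
* **Transcription factor flexible models (TFFMs)**, hidden Markov models in
  which the emission probabilities of each motif position depend on the
  nucleotide at the previous position, capturing adjacent-position
  dependencies that PWMs ignore. Both common flavours are implemented: the
  *first-order* parameterisation (one state per motif position with
  previous-base-conditional emissions) and the *detailed* parameterisation,
  in which every first-order state is decomposed into four per-nucleotide
  states and the emissions become transition probabilities.
  `build_detailed_from_first_order()` performs this decomposition and the
  two forms assign identical likelihoods to every sequence — a property the
  test suite verifies exhaustively for short sequences.

## From counts to scores

**PCM → PWM.** Counts are converted to log2 odds against a genomic
background distribution `b`:

`w[b,i] = log2( ((n[b,i] + k·bg[b]) / (N_i + k)) / bg[b] )`,

with `N_i` the column total and pseudocount `k = sqrt(N_i)` by default (a
constant can be supplied). The default background is A = T = 0.295,
C = G = 0.205, i.e. the ~41% GC content of the human genome; it is
configurable because no single composition suits every locus or organism.

**PWM window score.** A window of motif length `L` gets the raw log-odds
sum rescaled to `[0, 1]` by the attainable extrema
(`(raw − min)/(max − min)`), so the consensus scores exactly 1 and the
anti-consensus exactly 0. A degenerate constant-score matrix (max = min)
returns 0.5 for every window rather than dividing by zero. `N` bases
contribute their background-expected column value, so windows containing
ambiguity codes are scored rather than discarded.

**TFFM whole-sequence posteriors.** `tffm_posterior_scores()` runs the
scaled forward–backward algorithm and returns, per position, the posterior
probability that a motif occurrence ends there given the entire sequence.
Scaling factors are applied per position; the results equal unscaled
arithmetic to within 1e-9, and the test suite checks them against
brute-force enumeration over all hidden-state paths on toy models.

**TFFM window score.** For scanning, each window is scored with the local
two-hypothesis posterior: the weight of the hidden-state path that enters
the motif at the window start and traverses it, against the weight of
staying in background, both computed on the window plus one base of left
context (the first-order dependency needs it; where no context exists it is
marginalised over the background distribution). This choice — rather than
taking whole-sequence posteriors — was deliberate: it makes a window's
score a function of its local content only, which yields exact strand
symmetry, forces the joint score to 0 exactly when a change falls outside
every scorable window, and makes a dependency-free TFFM rank windows
exactly like the PWM of its positional emissions. With the background rows
uniform, the two definitions order windows identically in the common case;
the local score is simply the cleaner primitive for differential scoring.
A consequence worth knowing: the score depends on the motif-entry
probability, which acts as the prior odds of a site per position.

## Scanning a variant

For a variant at 1-based position `p`, the engine extracts
`[p − 15 − (L_max − 1), p + |ref| − 1 + 15 + (L_max − 1)]` from the genome
(clipped at chromosome ends), substitutes the alternate allele to form the
mutated sequence, and evaluates every model in all windows whose start
offset relative to the variant start lies in `[−15, +15]`, on both strands.
Offsets are interpreted as *window starts* — symmetric, well defined for
indels, and covering every placement that overlaps an SNV for motifs up to
16 nt. The maxima on the reference (`WT`) and mutated (`MT`) sequence are
combined into the joint score

`S = 2 / (1 + 2^(−2F)) − 1`, with
`F = −(1 − MT + α)/(1 − WT + α) + 1` if `WT > MT`, else
`F = (1 − WT + α)/(1 − MT + α) − 1`,

using pseudocount `α = 0.1`. `S` is antisymmetric, strictly inside
`(−1, 1)`, zero exactly when `WT = MT`, and monotone in `MT` at fixed `WT`;
the inverted scores (`1 − WT`) make the ratio most sensitive where scores
are high, i.e. where binding is actually plausible. Per TF, the combined
prediction is the arithmetic mean of `S` over that TF's models; when both
TFFMs and PWMs exist for a TF, only the TFFMs enter the average by default
(set `tffm_only = FALSE` to include all models). `|S|` thresholds of
0.2 / 0.5 / 0.8 label weak / moderate / strong loss or gain — the binning
is purely cosmetic and the raw score is always emitted.

Numerical and tie-break conventions: equal window scores resolve to the
smallest `|offset|`, then the negative offset, then the forward strand, so
outputs are bit-reproducible. Deletions longer than twice the window
halfwidth (30 nt at the default) are rejected per variant as not
analysable — the scan is designed for variants *within* a binding site, and
a deletion spanning the whole site leaves nothing to anchor on.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `window_halfwidth` | 15 nt | maximal window-start offset around the variant |
| `alpha` | 0.1 | joint-score pseudocount |
| `tffm_only` | `TRUE` | combined score uses TFFMs where available |
| `both_strands` | `TRUE` | scan the reverse complement too |
| `max_variants` | 10 000 | VCF record cap per analysis |
| background | A=T 0.295, C=G 0.205 | genomic base composition |

The variant filters mirror a typical search interface: custom regions,
candidate-gene vicinity (5 kb upstream / 1 kb downstream by default,
strand-aware — chosen as an ordinary promoter-plus-terminator envelope,
configurable because the field has no standard), minimum depth, homozygous
genotypes only, and a maximal allele frequency read from a user-supplied
VCF INFO field (boundary inclusive; records without the annotation are kept
and flagged rather than silently dropped). Known-TFBS tracks (BED with a TF
name column) can restrict scoring to factors with experimental evidence at
the variant; note that ChIP-seq intervals span hundreds of bases, so an
overlap locates the variant inside a peak, not inside the site itself.

## The synthetic-fixture generator

Everything the tool consumes can be generated deterministically
(`fixture_spec()`, `make_pcm()`, `make_tffm()`, `make_genome_with_sites()`,
`make_disrupting_vcf()`, `write_demo_fixtures()`), so the test suite and
the demo run with zero downloads. The generator emulates:

* **Motifs**: Dirichlet-concentrated count columns around a random
  consensus (concentration 50 by default — sharply informative columns, as
  for a well-characterised TF; `Inf` gives invariant columns, 0 exactly
  uniform ones). Each TF gets a PWM and a first-order TFFM sharing the same
  positional frequencies; the truth TF also carries the detailed
  decomposition.
* **Site prior**: TFFMs default to a motif-entry probability of 0.001
  (background self-transition 0.999), i.e. roughly one binding site per
  kilobase. This matters: an implausibly dense prior saturates the site
  posterior near 1 for any decent match and compresses reference/variant
  differences.
* **Genome**: one background chromosome (4 kb default) with planted perfect
  consensus sites (loss targets) and near-consensus sites carrying the
  anti-consensus base at the most informative column (gain targets), on
  random strands, spaced so no scan window ever sees two planted elements.
  The panel holds 21 TFs — one truth TF plus 20 decoys.
* **Ground-truth certification**: the local background of each planted site
  is resampled until no decoy model shows `|S| ≥ 0.5` for the variant that
  will perturb the site. The truth table asserts *which* TF the variant
  affects; without this step a chance decoy match overlapping the locus can
  legitimately be disrupted more strongly than the planted site, making the
  assertion false. If a decoy motif intrinsically resembles the planted
  word, the least-confounded placement is kept.
* **Variants**: one loss SNV per consensus site (consensus →
  anti-consensus at the most informative column), one gain SNV per
  near-consensus site (the reverse swap), and neutral variants placed far
  from every site. A neutral variant is an equal-length substitution whose
  single changed base lies beyond the last scorable window
  (> halfwidth + L − 1 nt from the variant start), the only construction
  that guarantees `S = 0` exactly — an SNV still sits inside its own scan
  window and generically shifts some window score.

What the fixtures do *not* emulate: realistic chromatin (accessibility,
nucleosomes), motif families with correlated specificities, sequencing
error, population allele-frequency structure, or realistic ChIP-seq
peak-length distributions. Passing the recovery suite therefore shows the
engine recovers planted signals under idealised conditions; it does not
validate biological accuracy on real genomes.

## Problem sizes used by the checks

The joint-score algebra is verified on a 1001 × 1001 grid; forward–backward
is compared with exhaustive path enumeration on 50 toy models (motifs up to
3 positions, sequences up to 8 nt); first-order/detailed equivalence on all
sequences up to 6 nt for toy models; PWM normalisation on all `4^L` windows
up to `L = 8`; end-to-end recovery on 100 seeded fixture replicates (21 TFs,
6 variants each). These sizes keep every property exhaustively or
statistically meaningful while the whole suite stays desk-scale.

## Known limitations

* Sequence-level only: chromatin context and expression consequences are
  out of scope by design.
* Deletions longer than 30 nt are rejected rather than scored.
* The TFFM window score depends on the model's entry probability; models
  imported from files should carry a sensible site prior.
* The XML model reader accepts a strict dialect
  (states/transitions/emissions with explicit conditional rows); anything
  unrecognised is a hard error rather than a silent default.
* Scores for windows flush against a sequence end marginalise the missing
  context base over the background; at chromosome edges fewer windows are
  scorable and the maxima are accordingly conservative.

## A worked example

```{r example, eval = FALSE}
library(tfshift)

dir <- tempfile("demo")
write_demo_fixtures(fixture_spec(seed = 1), dir)

genome <- file.path(dir, "genome.fa")
models <- read_models(file.path(dir, "models"))
variants <- read_vcf(file.path(dir, "variants.vcf"))

scan <- scan_variants(variants, genome, models,
                      known_sites = read_known_sites(
                        c(synthetic = file.path(dir, "sites.bed"))))
tidy(scan)      # per variant x TF: combined_S, category, models used
glance(scan)    # one-row summary
autoplot(scan)  # loss/gain heatmap
write_report(scan, file.path(dir, "results"))
```
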