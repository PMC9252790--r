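# tfshift

`tfshift` predicts whether — and how strongly — a DNA variant weakens or
strengthens transcription factor (TF) binding. It is aimed at regulatory
genomics: prioritising non-coding variants (promoter/enhancer SNVs and
short indels) by their predicted effect on TF binding sites.

Binding is modelled two ways: **position weight matrices** (PWMs, log2-odds
matrices derived from position count matrices against a genomic background)
and **transcription factor flexible models** (TFFMs) — hidden Markov models
whose emissions at each motif position depend on the previous base, in both
the *first-order* and the *detailed* (per-nucleotide state) parameterisation.
TFFM posteriors are computed with a scaled forward–backward algorithm.

For a variant, every selected model is evaluated in a sliding window from
−15 to +15 nt around the variant, on both strands, on the reference and the
mutated sequence. The two maximal normalised window scores
(0 ≤ *WT*, *MT* ≤ 1) are combined per model into a signed joint score

```
S = 2 / (1 + 2^(−2F)) − 1
F = −(1 − MT + α)/(1 − WT + α) + 1   if WT > MT
F =  (1 − WT + α)/(1 − MT + α) − 1   otherwise        (α = 0.1)
```

so S ∈ (−1, 1), with negative values meaning likely binding-site **loss**
and positive values likely **gain**. Per TF, the combined prediction is the
mean of S over that TF's models; by default only TFFMs contribute when a TF
has both model types. Inputs: variants in `chrom:posREF>ALT` notation, raw
reference/mutated sequence pairs, or VCF (up to 10 000 records, with
region/gene/depth/zygosity/allele-frequency filters); genomes as FASTA;
models as JASPAR PFM text, a strict TFFM XML dialect, or a documented JSON
format; known-TFBS tracks as BED.

## Worked example

The package ships a deterministic fixture generator that emulates a small
study: a 4 kb chromosome, a panel of 21 TFs (PWM + TFFM each), planted
binding sites for the first TF, and a VCF with site-destroying,
site-creating and neutral variants.

```r
library(tfshift)
dir <- tempfile("demo")
write_demo_fixtures(fixture_spec(seed = 1), dir)

models   <- read_models(file.path(dir, "models"))
variants <- read_vcf(file.path(dir, "variants.vcf"))
scan <- scan_variants(variants, file.path(dir, "genome.fa"), models,
                      known_sites = read_known_sites(
                        c(synthetic = file.path(dir, "sites.bed"))))
subset(tidy(scan), tf_name == "TF01")
```

```
                   variant_id combined_S    category n_models_used known_tfbs
1                  chrS:94C>A    -1.0000 strong_loss             2       TRUE
2                 chrS:853G>T    -1.0000 strong_loss             2       TRUE
3                chrS:1625A>C     1.0000 strong_gain             2       TRUE
4                chrS:2391A>C     1.0000 strong_gain             2       TRUE
5 chrS:3149CGGTAAATTAGCCTT...     0.0000        none             2      FALSE
6 chrS:3915GCCATGTTAGTATGA...     0.0000        none             2      FALSE
```

The two variants that strike a planted consensus site score a strong loss
(S ≈ −1) for the planted TF, the two that complete a near-consensus site a
strong gain, and the neutral variants score exactly 0; `known_tfbs` flags
variants falling inside a known-site interval. Decoy TFs stay near zero —
for the first variant the strongest decoy reaches |S| ≈ 0.002:

```
  variant_id tf_name combined_S    category
1 chrS:94C>A    TF01    -1.0000 strong_loss
2 chrS:94C>A    TF03     0.0022        none
3 chrS:94C>A    TF09    -0.0019        none
```

`glance(scan)` summarises the run, `autoplot(scan)` draws the variant × TF
loss/gain heatmap, `plot_model_scores(scan, variant, tf)` shows the
per-model WT/MT detail, and `write_report(scan, prefix)` writes three TSV
files: the full per-(variant, TF) table (columns `variant_id chrom pos ref
alt tf_name combined_S category n_models_used tffm_only_used known_tfbs
known_sources model_scores`, the last packing per-model
`model_id|kind|WT|MT|S` triplets), a filtered summary, and a per-model
detail table.

A command-line wrapper is installed at `inst/cli/tfshift`:

```sh
Rscript inst/cli/tfshift demo out_dir --seed 1
Rscript inst/cli/tfshift single 1:160001799G>C --genome g.fa --models models/
Rscript inst/cli/tfshift vcf input.vcf --genome g.fa --models models/ \
    --genes GATA1 --gene-table genes.tsv --max-af 0.01 --out results
```

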