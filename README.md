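# promtss

Genome-wide transcription start site (TSS) annotation and promoter
characterization for draft plant genomes.

Draft assemblies — conifer mega-genomes being the extreme case — usually
ship with gene models but no experimentally determined TSSs. Computational
TSS predictors emit several candidate positions per gene, some of which
even fall inside the coding sequence. `promtss` turns such candidate lists
into a one-TSS-per-gene annotation and then asks whether the resulting
promoters look like promoters.

## What the package does

**TSS selection.** For a gene with candidate TSS positions, each upstream
candidate implies a 5′UTR length ℓ (the distance from the candidate to the
start of translation). 5′UTR lengths across plant genes are well described
by a gamma distribution; fitting by the method of moments from a pool of
annotated lengths with sample mean *m* and unbiased variance *v* gives

```
theta = v / m        (scale, bp)
k     = m / theta    (shape)
```

The package ships *k* = 0.62, *theta* = 238.99 bp (fitted from pooled
5′UTR lengths of four model plants) and can refit from any user-supplied
pool. Candidates inside the CDS are excluded; among the remainder the
selected TSS is the candidate maximizing the gamma density
ℓ^(k−1) e^(−ℓ/θ) / (Γ(k) θ^k), with the predictor score as tie-breaker
(`--rank-by` exposes score-primary and hybrid rankings).

**Promoter characterization** on TSS-centered windows (−1000, +200):

* TATA-box (`TATAWAW`) and initiator CA sliding-window frequency profiles
  (width 20, step 10);
* CG-skew (C−G)/(C+G) profiles (width 50, step 10);
* DNA duplex free-energy profiles from a bundled nearest-neighbor
  dinucleotide ΔG°₃₇ table (15 bp windows);
* MATCH-style PWM scanning — information-weighted, min–max-normalized
  similarity scores in [0, 1] — with per-PWM and per-family positional
  hit-density tracks;
* core-promoter classification: TATA start in [−40, −20], initiator CA
  with the A in [−2, +2].

**Coding-sequence GC3 analytics**: per-gene third-codon-position GC, the
5′→3′ positional gradient and its regression slope over the first
1000 nt, 10%/90% quantile GC3-poor/-rich classes, and Mann–Whitney
comparisons of CDS length and exon count between classes.

**Synthetic data.** A generator emits a genome + GFF3 + candidate set with
planted ground truth (gamma 5′UTRs, TATA/CA plants, a CG-skew bump, a GC3
gradient, in-CDS decoy candidates), so the whole pipeline is testable
without any external download.

## Worked example

```r
library(promtss)

sim   <- generate_genome(sim_config(n_genes = 500, seed = 42))
paths <- sim_write(sim, "demo")
cand  <- generate_candidates(sim, candidate_noise(), seed = 43)
write_candidates(cand, "demo/candidates.tsv")

manifest <- run_pipeline(pipeline_config(
  genome = paths[["genome"]], gff3 = paths[["annotation"]],
  candidates = "demo/candidates.tsv", evidence = paths[["evidence"]],
  out_dir = "demo/out", seed = 1))
str(manifest$counts)
```

```
$ genes_in                 : int 500
$ genes_supported          : int 500
$ candidates               : int 1500
$ excluded_in_cds_fraction : num 0.135
$ selected_tss             : int 497
$ core_promoter: fraction_tata 0.0765, fraction_ca 0.501, ratio_tata_to_both 2.24
$ gc3_mean                 : num 0.376
$ gc3_gradient_slope       : num -0.000283
$ cds_length_comparison    : U 2500, p 7.04e-18, medians poor 981 vs rich 414
```

1500 candidates arrive, 13.5% are excluded as in-CDS, and 497 of 500
genes receive a TSS. The selected table carries each gene's implied 5′UTR
length and its prior density:

```
    gene_id genomic_pos strand     score utr_length          pdf
1 g00001.t1        1677      - 0.7095902        245 1.029026e-03
2 g00002.t1        4079      + 0.6201950        882 4.400175e-05
3 g00003.t1        8465      - 0.8582796         83 3.058069e-03
```

99% of the selected TSSs land within ±5 bp of the planted truth, and the
TATA-frequency track peaks at window center −30.5 — the generator planted
the motif 30 bp upstream of the TSS. The class comparison recovers the
built-in association (GC3-poor genes longer, more exons; p ≈ 7e-18).

A thin command-line front end wraps the same functions:

```sh
Rscript inst/scripts/promtss.R simulate --n-genes 500 --seed 42 --out demo
Rscript inst/scripts/promtss.R select --gff3 demo/annotation.gff3 \
    --candidates demo/candidates.tsv --out demo/selected.tsv
```

Subcommands: `simulate`, `filter`, `select`, `profile`, `pwmscan`, `gc3`,
`run`.

## Documentation

The methods vignette (`vignettes/promoter-tss-annotation.Rmd`) describes
the model, its assumptions, all tunable parameters, the synthetic-data
design, and known limitations.
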