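---
title: "Selecting TSSs with a gamma 5'UTR prior and characterizing the resulting promoters"
author: "promtss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting TSSs with a gamma 5'UTR prior and characterizing the resulting promoters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promtss)
```

## The problem

A TSS predictor run over the upstream regions of annotated genes returns
several scored candidate positions per gene. Two kinds of error dominate:
candidates that fall *inside* the coding sequence (plainly wrong for a
transcription start), and candidates that imply wildly implausible 5'UTR
lengths. `promtss` removes the first class outright and resolves the rest
with an explicit prior on 5'UTR length.

## The model

Let $\ell$ be the 5'UTR length implied by a candidate: the distance, in
transcription orientation, from the candidate position to the first base
of the start codon. Across plant genes $\ell$ is well approximated by a
gamma distribution

$$ f(\ell) = \frac{\ell^{k-1} e^{-\ell/\theta}}{\Gamma(k)\,\theta^{k}}, $$

with shape $k$ and scale $\theta$ fitted by the method of moments from a
pool of annotated 5'UTR lengths with sample mean $m$ and unbiased
($n-1$ denominator) variance $v$:

$$ \theta = v/m, \qquad k = m/\theta = m^2/v. $$

This fit reproduces the sample moments exactly ($k\theta = m$,
$k\theta^2 = v$), which the test suite asserts as an algebraic identity.
The shipped default, $k = 0.62$, $\theta = 238.99$ bp (mean
$k\theta \approx 148$ bp), derives from pooled model-plant annotations
(*A. thaliana*, *O. sativa*, *S. bicolor*, *P. trichocarpa*);
`fit_gamma_moments()` refits from any user pool, and whether such a pool
should be weighted per species or pooled raw is the user's choice — we
pool raw.

Selection maximizes $f(\ell)$ over the CDS-filtered upstream candidates
of each gene. Two points deserve note:

* **Score versus prior.** Predictor scores and prior fit are two
  different rankings; we make the prior density the primary key and the
  predictor score the tie-breaker, because the density is the instrument
  that makes the procedure portable across predictors. `rank_by =
  "score"` and `"pdf_times_score"` expose the alternatives, and an
  optional `min_pdf_quantile` imposes a hard "better fit" cut before
  ranking.
* **$k < 1$.** The default shape makes $f$ unbounded at $0$ and strictly
  decreasing, so a candidate *at* the start codon would dominate.
  Lengths of 0 bp are evaluated at 1 bp; any monotone cap preserves the
  order among positive lengths, and only upstream candidates
  ($\ell \ge 1$) are eligible anyway.

Remaining ties (equal density and score) break by smaller $\ell$, then
genomic position, making selection fully deterministic and invariant to
candidate order.

## Coordinates and windows

Internally all coordinates are 0-based half-open; GFF3 (1-based closed)
and BED convert at the boundary, and a round-trip preserves coordinates
exactly. The "start codon" is the first CDS base in transcription
orientation, taken from CDS features rather than annotated 5'UTR
features, which draft annotations usually lack. Each mRNA is an
independent gene model — the "one TSS per gene" guarantee is per mRNA id,
since draft annotations count gene models rather than collapsed loci.
Promoter windows are addressed relative to an anchor (TSS or start
codon); position 0 *is* the anchor base, negative offsets are upstream,
and minus-strand windows are reverse-complemented. Windows may overrun a
contig; the overhang is filled with `N` and flagged, and `N` positions
never match a pattern and are dropped from denominators.

## Promoter statistics

All profiles are sliding-window statistics over TSS-centered windows
(default $[-1000, +200)$); the x-axis reports window centers and a motif
contributes through its match start. Defaults: motif frequency width
20 / step 10 with the TATA-box consensus `TATAWAW` and the initiator
dinucleotide `CA`; CG-skew $(C-G)/(C+G)$ width 50 / step 10, with
zero-$C{+}G$ windows excluded from the average; duplex free energy as the
mean nearest-neighbor dinucleotide-step $\Delta G^{\circ}_{37}$ over
15 bp windows. The bundled step table
(`inst/extdata/dinucleotide_dg37.tsv`, kcal/mol) is the unified
nearest-neighbor parameter set used throughout the free-energy
promoter-prediction literature and is user-replaceable; AT-rich
(promoter-like, less stable) windows score less negative than GC-rich
ones.

Core-promoter classification calls a promoter TATA-containing when a
`TATAWAW` match *starts* in the closed interval $[-40, -20]$ —
containment by start position is the convention of PWM-era scanners — and
initiator-containing when a `CA` occurs with its A in $[-2, +2]$. Both
region and pattern are arguments.

PWM scanning follows the MATCH convention: per-position information
weights $I(i) = \sum_b f_{ib}\ln(4 f_{ib})$ (natural log), score
$(\mathrm{Current}-\mathrm{Min})/(\mathrm{Max}-\mathrm{Min}) \in [0,1]$,
so the consensus scores exactly 1 and the anti-consensus 0. Both strands
are scanned (the reverse strand through the reverse-complement matrix)
and hits are reported at their leftmost promoter coordinate, making the
tracks strand-agnostic. No database matrices are bundled — curated PWM
collections are licensed — so matrices are user-supplied in a
TRANSFAC-like flat format; the shipped toys exist for tests and examples
only. The default similarity threshold of 0.85 is a conventional
moderate-stringency cut, not a calibrated constant; per-matrix cut-off
profiles are out of scope.

## GC3 analytics

GC3 is the G+C fraction at codon third positions of the spliced CDS
(frame from the first base; `N` thirds dropped from both numerator and
denominator; non-multiple-of-3 CDSs are excluded and counted). The
positional gradient is the per-codon mean GC3 across genes long enough to
contribute, and its slope is a single OLS regression of those means on
nucleotide position over the first 1000 nt — one slope per data set, not
an average of per-gene slopes. Classes use empirical 10%/90% quantiles
(median-unbiased type-8 convention; boundary ties go to the extreme
class, so class sizes differ only by ties). Class comparisons use the
two-sided Mann–Whitney U test: exact enumeration when the smaller class
has at most 8 observations and no ties, otherwise the normal
approximation with tie and continuity corrections. The exact branch is
validated against full enumeration and the approximate branch is
calibrated: under a null simulation its type-I error at $\alpha = 0.05$
is within $0.05 \pm 0.01$.

## The synthetic-data generator

`generate_genome()` emulates exactly the structure the analysis assumes,
with defaults chosen once as the package's study conditions:

* 5'UTR lengths: integer-rounded Gamma(0.62, 238.99) draws clamped to
  $[1, 5000]$ bp;
* TATA-box planted verbatim at 30 bp upstream of the TSS in 7% of
  promoters (inside the canonical 20–40 bp band, between the two
  peak locations reported for plant data), initiator CA at $[0, +1]$ in
  50%;
* a CG-skew bump of $\pm 50$ bp around the TSS (G/C draws become C with
  probability 0.65, local skew $\approx +0.3$);
* background i.i.d. sequence at GC 0.38 (conifer-like); no repeat or
  transposon structure, deliberately — repeats are irrelevant to these
  statistics at desk scale;
* CDS built codon-wise: class base levels 0.25/0.45/0.70 (poor/mid/rich,
  10% in each extreme class) plus a $-2\times10^{-4}$ per-nt positional
  decline; GC3-rich genes drawn short with 1–2 exons and GC3-poor genes
  long with 4–8 exons, so the class comparisons have signal of the
  expected sign;
* candidates: per gene, each of 3 candidates is an in-CDS decoy with
  probability 0.14 (uniform over CDS positions), otherwise the true TSS
  with rounded Gaussian jitter (sd 2 bp) clamped to stay upstream of the
  start codon — a predictor searching an upstream window cannot emit
  downstream calls, and the clamp keeps the in-CDS fraction exactly
  binomial in the decoy rate. Optional far-upstream decoys beyond the
  99.9th prior percentile exercise the prior-vs-score comparison. True
  candidates score Normal(0.8, 0.1), decoys Normal(0.6, 0.15), clamped
  to $[0,1]$.

One enforcement rule matters for interpretation: within the scored core
regions (TATA starts in $[-40, -20]$, CA with A in $[-2, +2]$) the
generator makes motif presence *equal* the drawn flag — planted motifs
are written verbatim and chance background occurrences in motif-free
promoters are disrupted (resampled from the local base distribution).
Observed classification fractions are therefore exactly binomial in the
configured rates, which is what makes rate-recovery tests sharp. Real
promoters carry background motif occurrences, so on real data the
classifier reports the *observed* motif fraction, not an underlying plant
rate.

What passing tests show, and what they do not: planted-truth recovery
(≥ 95% of TSSs within ±5 bp, TATA-track argmax at the planted offset,
in-CDS exclusion at the decoy rate) demonstrates that the machinery is
correct under the generative model. It does not certify predictor
accuracy on real genomes, where candidate error is not Gaussian, 5'UTR
lengths need not follow the model-plant prior, and annotations carry
their own biases.

## Numerical choices and degenerate inputs

Unbiased ($n-1$) variance throughout; at realistic pool sizes the choice
is numerically irrelevant but it must be fixed. Degenerate gamma fits
(constant samples, negative lengths) error out rather than returning
infinities. Empty window sets, header-only tracks, empty GFF3 files and
zero-gene configurations all produce well-formed empty outputs. Windows
are emitted only where complete (a length-$L$ sequence yields
$\lfloor (L - w)/s \rfloor + 1$ windows). PWMs with zero information at
every position have undefined similarity and score `NA`.

## Problem sizes

The shipped validation runs at sizes chosen to make sampling error small
relative to the asserted tolerances while staying desk-scale: $10^5$
draws for moment-recovery (±3%), 2000 genes (≈ 5 Mb, 6000 candidates)
for planted-truth recovery, 5000 promoters for motif-rate recovery, 2000
replicates for test calibration, and randomized instances ≤ 2 kb for the
brute-force oracle equivalences.

## Known limitations

* The TSS predictor itself is out of scope: `promtss` consumes candidate
  tables, it does not generate them.
* Single-TSS semantics: broad transcription start regions (TSRs) are not
  modeled; one position is returned per mRNA.
* Evidence support is interval coverage of the spliced CDS; running
  aligners, and protein-level homology, are external. When both RNA and
  protein evidence exist, the combination rule (AND/OR) is left to the
  user — supply a combined BED or intersect the verdicts.
* The free-energy profile uses a generic nearest-neighbor table; it
  ranks windows by stability but is not a calibrated melting model.
* PWM scanning inherits the futility-theorem caveat of all matrix
  matching: hit densities are positional summaries, not binding-site
  calls.
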