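---
title: "Methods: gene-level probe design, QC and two-color analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-level probe design, QC and two-color analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carpoligo)
```

# The problem

Expression microarrays for species with duplicated, isoform-rich genomes
face two coupled risks: probes that target one isoform miss others of the
same locus, and probes that target any member of a high-identity paralog
family (globin-like clusters are the canonical case in teleost fish) report
a mixture of its relatives. carpoligo implements the standard mitigation —
collapse transcripts to genes, probe the longest isoform near its 3' end,
and screen every probe for cross-hybridization — together with the
downstream measurement pipeline (spot QC, dye normalization, moderated-t
contrasts) needed to show that a finished array measures what it claims to.

# Gene models and probe placement

Transcripts are spliced from exon intervals (1-based inclusive annotation
coordinates; 0-based half-open offsets internally) and reverse-complemented
on the minus strand. Per gene the *longest* isoform is the probe target;
ties break to the lexicographically smallest transcript id so the choice is
reproducible. Orphan transcripts without a gene parent become single-isoform
genes — discarding them would silently shrink the design space.

Probes are 60-mers confined to the 3'-terminal window (default 1,000 nt)
because oligo(dT)-primed labeling chemistry reads transcripts from the
poly(A) tail; coverage decays with distance from the 3' end, so probe and
signal must share that end. Candidates may not overlap any masked base.

## Masking

Three mask sources, merged into disjoint intervals:

* **vector**: maximal exact matches (>= 15 nt) to a vector library, either
  strand. Exact matching is appropriate because cloning-vector contamination
  is verbatim sequence, not homology.
* **low_complexity**: a DUST-style triplet score per 64-nt sliding window
  (step 8), `sum(c_t(c_t-1)/2)/(k-1)` over triplet counts; windows scoring
  above 2.0 are masked. A random window scores ~0.5, a homopolymer ~k/2, so
  the threshold separates the two regimes by an order of magnitude.
* **ambiguous**: every N. Ns are retained in sequence (coordinates must stay
  stable) but are never probed.

## Scoring

Commercial base-composition scoring is proprietary, so the ranking here is a
declared surrogate with the same observable behavior — prefer balanced
composition, avoid homopolymers, prefer 3'-proximal placement:

$$\mathrm{score} = -w_{gc}\,|GC - 0.45| \;-\; w_{hp}\max(0, \mathrm{run} - 6)
\;-\; w_{pos}\,\frac{d_{3'}}{1000}$$

Defaults $w_{gc}=1$, $w_{hp}=0.1$, $w_{pos}=0.25$, floor $-1$. The weights
were fixed once, by construction rather than tuning: a typical random 60-mer
(GC deviation ~0.05, no long run, mid-window placement) scores about $-0.2$,
comfortably above the floor, while degenerate candidates (a 60-nt
homopolymer scores below $-5$) fail it. The floor exists so that the
`design_fail` ledger class is reachable — a gene whose whole 3' window is
compositionally pathological should be reported, not probed badly. Ties on
score resolve to the smallest start, again for reproducibility.

Statuses are assigned in a fixed order — `too_short` (< 60 nt), `masked`
(no candidate survives), `design_fail` (no candidate meets the floor), then
selection; `duplicate` is assigned afterwards in gene-id order when two
genes select identical 60-mers. The accounting identity
`submitted = designed + exclusions` is asserted on every run.

## Cross-hybridization screen

A probe is flagged iff, against a transcript of a *different* gene, it shows
(a) an exact contiguous match >= 25 nt, or (b) >= 45/60 matching positions
in an ungapped alignment reachable from an exact 15-mer seed. Same-gene
isoforms never flag — they are the very redundancy gene-level collapsing
embraced. The thresholds are conventional specificity heuristics for
60-mers and are configuration, not claims about any vendor's unpublished
values. Because any alignment with >= 45 matches and a >= 15-nt run is
necessarily found from its seed, the seed-and-extend implementation is
*exactly* equivalent to an exhaustive ungapped screen under this definition;
the test suite asserts that equivalence against an independently coded
brute-force oracle on fixtures of up to 20 transcripts.

# Layout

Each subarray holds a control manifest, replicate probes, and biological
probes placed by a seeded permutation. At full scale: 62,976 features,
1,319 controls, 20 replicate probes x 10 copies. The manifest's internal
split (1,000 spike-ins as 10 levels x 100, 303 stringency probes, 16 corner
markers) is declared configuration: commercial control grids publish their
totals, not their composition. Residual biological capacity is filled by
round-robin duplication of designed probes, recorded in the design table —
an explicit policy in place of the unspecified vendor fill rule.

# Spot QC

SNR = (median signal − background median) / background pixel SD; the
statistic is invariant under scanner gain, which the tests assert. Detection
is `robust` iff the well-above-background flag is set AND SNR >= 3,
`cautionary` for SNR in [1.5, 3) or when the flag gate fails, else
`low_confidence`. Both boundaries are closed from below ("SNR >= 3" read
literally). Replicate spots collapse by the median SNR (resistant) and mean
signal/background (the metrics are already medians per spot); an array is
excluded from a probe's robustness summary if any of its spots is a
non-uniformity outlier, population outlier, or saturated, but it still
counts in `flagged_array_count`. The present-call rate is the robust
fraction among unflagged arrays.

DLRSpread is computed as IQR(adjacent log-ratio differences)/1.349/sqrt(2).
The scanner vendor's exact recipe is unpublished; this estimator is the
conventional robust-SD reading and is calibrated in the tests: for i.i.d.
Gaussian log ratios of SD sigma it recovers sigma within 5% at n = 10,000.

# Normalization and inference

Two pipelines mirror the two experiment types:

* **two-color (self-self dye balance)**: LOWESS fit of M on A per array
  (span 0.3, 3 robustness iterations — conventional MA-normalization
  defaults), corrected M = residual. The per-feature test is a one-sample
  moderated t of mean corrected M against 0.
* **single-channel (isolation reproducibility, landscape summaries)**: log2
  (non-positive values floored at half the array's smallest positive value,
  recorded in provenance), 75th-percentile scaling (linear-interpolation
  quantile — the declared interpolation rule, since it changes exact
  values), then baseline-to-median centering; multi-probe genes collapse by
  median. Provenance is append-only and re-running a step errors, so a
  matrix cannot be silently double-normalized.

The moderated t-test uses the standard empirical-Bayes closed forms: with
per-feature residual variance $s_g^2$ on $d_g$ df, set
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$; the prior df $d_0$ solves
$\psi'(d_0/2) = \mathrm{var}(e) - \psi'(d_g/2)$ (Newton inversion of the
trigamma function) and $s_0^2 = \exp(\bar e + \psi(d_0/2) - \log(d_0/2))$.
Posterior variance $(d_0 s_0^2 + d_g s_g^2)/(d_0+d_g)$, moderated t on
$d_0 + d_g$ df. When the moment estimate leaves no excess variability
(e.g. identical $s_g^2$), $d_0 = \infty$ and every posterior variance is
$s_0^2 = \exp(\bar e)$. Tests verify agreement with an independently coded
oracle to 1e-10 and with limma to 1e-6 on finite-$d_0$ fixtures. BH
adjustment is delegated to `stats::p.adjust` and checked against a hand
step-up computation.

Significance uses two gates: |FC| >= 2 and a statistical criterion. Both a
raw-p and a BH-q variant exist because the platform-validation contrasts
were historically run at p < 0.05 while the general pipeline default is
q <= 0.05; the `criterion` switch records which was used rather than
guessing a single intent. logFC exactly 0 counts as "unchanged" in
direction summaries — an explicit third bucket instead of a silent tie-break.

# The synthetic fixture layer

`generate_transcriptome` emulates the design-relevant hazards: 2–14
isoforms per gene sharing the 3'-terminal exon (so the probe window is
common), paralog families mutated from a seed to a target identity (0.92 by
default — globin-family territory, squarely inside the flagging range),
poly(A) tails, and vector/low-complexity insertions at 5% per gene. All
gene models are plus-strand; strand handling is exercised by dedicated
loader tests instead. It does *not* emulate codon structure, GC
heterogeneity, expression-correlated composition, or real repeat families —
passing tests show the pipeline's logic is correct under controlled hazards,
not that design yields on a real genome are reproduced.

`simulate_scan` draws foreground as gain·2^(x+e) with log2-normal noise e
(default SD 0.25), truncated-Gaussian background (mean 100, SD 15), and
flag injection at configurable rates; spike-in features follow declared
expected log ratios (10 levels spanning ±2, since the real panel's ratios
are not published). It does not model scanner physics, spatial gradients,
or saturation nonlinearity.

The two presets package the platform-validation designs at synthetic scale:
`preset_selfself` (3 arrays, identical channel truths) and
`preset_two_isolations` (8 + 8 arrays, exactly 12 probes shifted +1.23
log2 — the published design's regime). Presets use 5,000 fabricated
biological probes by default: the simulation layer tests measurement and
inference, so sequence-level design is exercised separately in a ~40-gene
full-chain test (design → layout → simulate → QC → normalize → contrast),
sizes chosen to keep the whole suite fast while leaving every code path
covered. With noise SD 0.25 and n = 8 vs 8, the injected +1.23 shift gives
per-probe recovery probability ~0.97 at the |FC| >= 2, p < 0.05 criterion,
so >= 10/12 recovery is the expected outcome, and the FC gate keeps null
false positives near zero — both asserted in the acceptance tests.

# Numerical choices and degenerate inputs

* Quantiles: linear interpolation (R type 7) everywhere, declared because it
  changes exact percentile-normalization values.
* Zero-variance features: t = 0 (p = 1) when logFC is also 0, ±Inf (p = 0)
  otherwise, so zero-noise fixtures behave sensibly.
* `bg_pix_sd = 0` is a hard error (degenerate background), not an Inf SNR.
* Standard curves with slope >= 0 (within 1e-12) are rejected as
  non-physical rather than yielding complex efficiencies.
* All layout/generator randomness flows through explicit integer seeds;
  identical seeds give byte-identical outputs.

# Known limitations

* No thermodynamic (nearest-neighbor ΔG) probe modeling; composition
  scoring is a surrogate with declared weights, not a vendor reimplementation.
* One probe per gene; multi-probe designs are out of scope.
* The cross-hybridization screen is ungapped; indel-containing paralogy is
  only caught via its local exact runs.
* Enrichment scoring takes cluster membership and term p-values as input;
  no ontology querying or ortholog mapping is performed.
* Genome-scale design yields (probe counts, flag fractions on a real
  assembly) depend on the real transcriptome and are not claims this
  package can verify; its guarantees are the ledger identities, oracle
  equivalences, and parameter-recovery results above.
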