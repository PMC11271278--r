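---
title: "HAPI scoring and enhancer-hijacking detection: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HAPI scoring and enhancer-hijacking detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapir)
library(data.table)
```

## The model

`hapir` operates on called HiChIP loops — pairs of genomic anchors with a
PET (paired-end tag) count — not on reads. The underlying assumption is
that H3K27ac HiChIP loop calls enumerate contacts between active
regulatory elements, so the set of loops touching a gene's promoter is a
direct readout of that gene's enhancer usage, *including* contacts created
by structural variants and ecDNA that reference-genome distance cannot
explain.

Three ingredients define the method:

1. **Loop classes.** Intra-chromosomal loops spanning strictly between
   5 kb and 2 Mb (anchor midpoint to midpoint) are *normal*; spans of at
   least 2 Mb are *abnormal cis* (beyond the upper bound of typical TADs,
   so unlikely without a structural alteration); inter-chromosomal loops
   are *trans*. Spans of at most 5 kb are dropped as self-ligation-scale
   artifacts and never enter any class.
2. **Two per-gene scores.** Over a gene's enhancer–promoter loops (all
   three classes combined, at its primary promoter), the *enhancer contact
   value* C counts distinct enhancer anchors and the *interaction
   intensity* I sums PETs. Both matter: C alone rewards promiscuous weak
   contact, I alone rewards one strong loop.
3. **Inflection cutoffs.** Each score's ranked curve is thresholded at the
   point where a line of slope (max − min)/N is tangent to the curve —
   the hockey-stick construction familiar from super-enhancer calling.
   HAPI genes meet or exceed both cutoffs.

Enhancer *origin* is quantified by the contribution formula: per class,
activity is `log10(summed PETs) x distinct anchors`, normalized across
the three classes. A HAPI gene with over 25% of activity in trans or in
abnormal cis is a hijacking candidate. The log10 damping means a class
needs either many anchors or disproportionate PET mass, not just one
strong loop, to dominate.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `min_pets` | 3 | PETs | loop-support floor; also guarantees `log10(pets_c) > 0` whenever a class is non-empty, so the contribution formula needs no pseudocount |
| `promoter_halfwidth` | 2500 | bp | promoter = TSS ± 2.5 kb, symmetric (strand ignored) |
| `min_span` | 5000 | bp | spans ≤ 5 kb dropped (strict "more than 5 kb") |
| `max_normal_span` | 2e6 | bp | spans ≥ 2 Mb are abnormal cis (closed bound, "at least 2 Mb"); TAD-scale ceiling |
| `hijack_threshold` | 0.25 | fraction | strict inequality ("over 25%") |
| v4c `window` | 2000 | bp | anchor window centered on the TSS |
| v4c `bin_width` | 10 | bp | track resolution |
| `top_k` | 50 | regions | averaged virtual-4C profile |

All are surfaced as function arguments and CLI flags; defaults are the
published operating point.

## Numerical choices

- **Inflection cutoff.** The tangency is computed on the discrete sorted
  curve `v_1..v_N` as `v_k`, `k = argmin_i (v_i − s·i)` with
  `s = (max − min)/N` — translating the slope-`s` line up until it touches
  the curve from below. Ties break to the **largest** index (the more
  stringent cutoff); when all values are equal, `s = 0` and the cutoff is
  the common value. The construction is scale-equivariant: multiplying all
  values by a positive constant scales `s` with them, so the called set is
  unchanged (tested).
- **Span metric.** Distance between anchor midpoints. Anchor widths vary
  between loop callers; midpoints are symmetric and insensitive to width.
- **Primary promoter.** For multi-promoter genes, the promoter anchor with
  the largest summed PETs over E-P loops (after promoter–promoter
  exclusion); ties break to the smallest coordinate. Genes with no E-P
  loop are absent from the output rather than scored zero.
- **Anchor roles are global.** An anchor inside any promoter window is a
  promoter, full stop; it cannot serve as another gene's enhancer. This is
  what makes promoter–promoter exclusion well defined. Multi-gene promoter
  anchors fan out to one E-P record per gene.
- **Anchor deduplication is per class.** An enhancer anchor looped to the
  same gene in both a normal and a trans context counts once in each
  class. Cross-class deduplication would change C for a handful of genes;
  the per-class convention keeps C equal to the sum of the per-class
  anchor counts used by the contribution formula.
- **Own-vs-donor precedence.** In the locus partition, an enhancer within
  2 Mb of both the gene's own promoter and the reference (donor) promoter
  counts as *own* — conservative against inflating hijack fractions.
- **Copy number.** A gene's log2(CN) is the segment mean of the single
  segment containing its primary TSS (half-open containment), not an
  overlap-weighted gene-body average; genes in coverage gaps stay `NA`
  and are never flagged high-copy.
- **Ties in Spearman clustering** are mid-ranked; the correlation is
  Pearson on ranks. Constant columns have undefined correlations: they are
  reported `NA` and ordered last rather than imputed.
- **Virtual 4C.** Bins are aligned to multiples of the bin width (floor
  division). Pairs with *both* ends in the anchor window are counted once
  toward the bin of the end farther from the TSS; a config flag drops them
  instead (the published choice is unstated; such pairs are rare at 2 kb).
  Scaling is counts per million total valid pairs — the library-size
  normalization realized as CPM, which fixes only the track's unit.

## Design decisions where the design was open

- **Cutoff universe.** Cutoffs are computed on all enhancer-connected
  genes with the three loop classes combined, not per class.
- **Filter order.** PET filtering is applied before blacklist filtering;
  this affects only how removals are attributed in the report, never the
  kept set (tested by accounting identities).
- **Score-matrix zero fill.** A gene that is not HAPI in some sample gets
  0 in that sample's column, not its sub-threshold score: the matrix is a
  statement about HAPI status, and zero-fill keeps it complete. Average
  linkage on `1 − rho` orders samples; only the correlation method itself
  is prescribed.
- **PET column dialect.** Hichipper-style BEDPE varies in column layout;
  files with ≥ 8 columns default to PETs in column 8 (name column before
  it), 7-column files to column 7, both overridable.
- **CLI scope.** Subcommands + flags + a JSON manifest per run; no config
  file parser or structured log file. The manifest plus seeded generator
  already make every output reproducible byte for byte.

## What the synthetic generator emulates — and what it does not

`generate_fixture()` states a world: 4 chromosomes of 60 Mb; several
hundred background genes each with 1–4 local E-P loops (spans drawn inside
the open (5 kb, 2 Mb) band) and PETs from `3 + NB(size 2, mu 3)`; 30
"boosted" genes with 15–25 distinct enhancer anchors and PETs from
`3 + NB(mu 25)` forming the hockey-stick tail; and 3 boosted genes that
additionally receive 12 trans anchors clustered in a 2 Mb donor window
with PETs from `3 + NB(mu 30)`, giving analytic trans fractions of
~0.3–0.45 — comfortably over the 0.25 threshold by construction, not by
tuning. Decoy loops with PETs < 3 and loops anchored in blacklist
intervals are injected separately so both filter branches are exercised.
Promoter windows are kept disjoint and enhancer anchors are
rejection-sampled away from all promoter windows, so the emitted truth
table is *exactly* recoverable: every anchor/PET count in the pipeline
output must match the generator's ledger, not just approximately.

It does **not** emulate: read-level noise or ligation artifacts (input is
loop calls, as for the real method); anchor-width variability; promoter
anchors shared between genes (truth recovery requires disjoint windows —
the shared-promoter fan-out path is tested separately on hand-built
cases); copy-number-driven loop inflation (CN is painted on top,
independent of loop counts); or cohort-scale biological variability. A
green end-to-end test therefore establishes that the pipeline's
*bookkeeping and decision rules* are exact on data obeying the stated
model — it does not validate sensitivity or specificity on real HiChIP,
which depends on the upstream loop caller.

## Degenerate inputs and edge behavior

Empty loop tables flow through filtering/classification and yield empty
E-P sets; HAPI calling refuses cohorts of fewer than two profiles (a
cutoff over one value is meaningless). A contribution over zero total
activity returns all-zero fractions rather than NaN. Scaling a track with
zero total pairs is an error, as is re-scaling. SEG overlap within one
sample is an input error, reported with the offending sample/chromosome.

## Known limitations

- Hijacking calls name the *pattern* (origin fraction), not the causal
  structural variant; distinguishing translocation vs insertion vs ecDNA
  needs WGS/amplicon reconstruction, out of scope here.
- Copy number is annotated, never used to normalize loop counts —
  deliberate, since focal amplification genuinely drives E-P contact, but
  it means high-copy loci can reach HAPI status partly through copy
  number.
- The inflection cutoff is cohort-relative: adding or removing genes moves
  the cutoffs, so HAPI sets are comparable across samples only through the
  score matrix, not by membership alone.
- Virtual-4C reading loads the validPairs file into memory; files beyond
  a few tens of millions of pairs should be pre-filtered by chromosome.

All empirical statements in this vignette are computed by the test suite
(`tests/testthat/`, in particular `test-acceptance.R`) or by
`scripts/acceptance.R`; none rely on external data.
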