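---
title: "Methods: fragment-level TaDa Pol II occupancy analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fragment-level TaDa Pol II occupancy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadascope)
```

## The measurement and its resolution

Targeted DamID reads out protein–DNA proximity through adenine methylation
of GATC motifs: Dam fused to RNA Pol II methylates GA(me)TC near
transcribed loci, DpnI cuts only methylated GATC, and the amplified
fragments are sequenced. Because every informative molecule begins and ends
at a GATC motif, the natural unit of analysis is the *GATC fragment*, the
interval between consecutive motif start coordinates. All coordinates in
this package are 0-based half-open internally; BED output is 0-based
half-open and GTF input/output 1-based closed, the standard dialects.

Two conventions deserve explicit statement because the field leaves them
loose:

* **GATC fragment distance** is defined here as the distance between
  consecutive motif *start* coordinates, equivalently the width of the
  fragment between them. The genome-wide summary is the *lower median*
  (no averaging at even counts), pooled across contigs. On the
  D. melanogaster r6.21 reference this convention gives 350 bp, the value
  used as the default peak-merge gap; other plausible conventions
  (midpoints, DpnI cut positions GA^TC) shift every distance by a constant
  and would change the median by at most 4 bp.
* **Terminal sub-fragments** (before the first and after the last motif of
  a contig) are not DpnI-digestible units; they are kept in the fragment
  map flagged `terminal` but excluded from the median-distance statistic.

## Edge counting

DamID reads should start at a DpnI cut. `count_reads_to_fragments()`
therefore assigns each primary mapped read to the fragment whose boundary
GATC lies within `edge_tolerance` (default 5 bp) of the read's 5'-most
aligned base — the leftmost base for forward reads, the rightmost for
reverse reads, with forward reads attached to the fragment *starting* at
the boundary and reverse reads to the fragment *ending* there. Reads with
no boundary within tolerance fall back to the fragment containing their 5'
base and are tallied separately; `strict_edge = TRUE` rejects them instead.
The counting invariant `assigned + rejected + skipped = records` is
asserted on every call. Whether the original helper scripts required one or
both read ends on a boundary is not documented anywhere we could verify;
the single-end-5' rule is this package's documented choice, and the
simulator's SAM emission is constructed so that recounting reproduces the
simulated matrix exactly, which pins the rule down operationally.

## The moderated per-fragment test

Counts are CPM-normalized per sample and transformed as
`log2(cpm + pseudocount)` (pseudocount 1). The expression scale fed to the
moderated model is not fixed by the original analyses; log2 CPM is the
common choice for count data entering a normal-theory test and is
configurable.

For fragment *g* with fusion samples `n1` and Dam-only samples `n2`:

* `logFC_g = mean(fusion) − mean(Dam)`,
* pooled variance `s²_g` with `d = n1 + n2 − 2` degrees of freedom,
* prior `(d₀, s₀²)` fit by method of moments on `z = log s²_g`:
  `trigamma(d₀/2) = max(0, var(e) − trigamma(d/2))` with
  `e = z − digamma(d/2) + log(d/2)`, and
  `s₀² = exp(mean(e) + digamma(d₀/2) − log(d₀/2))`; a non-positive
  right-hand side means the spread of log variances is within its sampling
  noise and the prior degenerates to `d₀ = ∞` (complete shrinkage),
* posterior variance `s̃²_g = (d₀ s₀² + d s²_g)/(d₀ + d)`,
* `t_g = logFC_g / (s̃_g √(1/n1 + 1/n2))`, two-sided p on `d + d₀` df
  (standard normal at `d₀ = ∞`).

The limits anchor the implementation: `d₀ = 0` reproduces the classical
pooled two-sample t exactly, and `d₀ → ∞` the normal z form; both are
asserted numerically in the test suite, and the whole fit is cross-checked
against an independent reference implementation of the same empirical-Bayes
model on simulated data. Exactly equal variances (zero empirical spread)
are special-cased to `d₀ = ∞` with `s₀²` equal to the common value, since
the bias-correction formula assumes a non-degenerate spread.

Fragments with zero counts in every sample are dropped before fitting (and
reported); no other pre-filtering is applied. The per-fragment significance
gate is `p < 1e−5`. Whether that gate was historically applied to moderated
or ordinary p-values is ambiguous; moderated is the default here. Contrasts
of low-quality conditions (the ligand-overexpression arm) can be flagged
`qualitative_only`, in which case they are meant for visual confirmation
and not for FDR-bearing claims.

## Peaks, combined significance, gene calls

Fragments passing the gate are merged single-linkage along each contig
whenever the gap to the previous fragment is at most the merge tolerance —
by default the genome's median GATC fragment distance. A `merge_all` mode
merges every fragment instead (relying on the combined test alone); it is
exposed because the published description is ambiguous about whether the
gate precedes merging, but gating first is the default reading. Note that
with `merge_all` a fragment map that tiles the contig merges into one peak
per contig, which is rarely what is wanted; the mode is useful only with
pre-filtered fragment sets.

Each peak reports the mean logFC over member GATCs (mixed-sign membership
is allowed but flagged), a Simes-combined p-value
`min_i (m · p₍ᵢ₎ / i)` — valid under the positive dependence expected of
neighbouring fragments — and a Benjamini–Hochberg q across peaks. Genes
take the minimum-q overlapping peak (gene span, 0 bp upstream margin by
default; ties break to larger |mean logFC|, then leftmost) and are called
at `q < 0.01`. On synthetic data the calls are insensitive to small margins,
which is why 0 is the default.

Peak feature annotation uses priority classification (promoter ≤ 1 kb
upstream of a TSS > 5'UTR > 3'UTR > exon > intron > downstream ≤ 1 kb >
distal intergenic); UTR categories activate only when the gene models carry
UTR intervals.

## Coverage tracks

`log_ratio_track()` reproduces the browser-track recipe: each sample is
scaled to 1× genome coverage (scale factor = effective genome size / total
aligned bases; the *Drosophila* effective genome size 142,573,017 bp is the
default), the per-bin value is `log2((t + pc)/(r + pc))` with a pseudocount
of 1 normalized unit (the recipe's own pseudocount is undocumented), bins
default to 1 bp, and a centered 5-bin running mean is applied with the
window clamped at contig edges so values stay finite. Tracks are
antisymmetric under swapping treatment and reference. Replicates are kept
separate for statistics; tracks may be built from pooled replicate reads,
mirroring the practice of merging replicate alignments before
visualization.

## The synthetic-data generator

The generator defines the study conditions the tests certify:

| parameter | default | rationale |
|---|---|---|
| conditions | Dam vs. DN | dominant-negative fusion contrast; the final published contrast |
| replicates | 3 per condition | the study's design |
| depth | 1e6 reads/sample | desk-scale stand-in for >15M-read libraries, ~500 reads per fragment |
| dispersion | 0.1 | typical overdispersion of DamID fragment counts; single genome-wide value |
| fraction DE | 0.2 at \|log2FC\| = 2 | planted effect size for recovery tests |
| contig | 700 kb, ~2000 fragments | smallest size at which peak/gene structure is non-trivial |
| genes | 100 × 2 kb | ~6 fragments per gene body |
| background | 0.1 relative occupancy | uniform Dam accessibility; no published background model exists |
| expression | lognormal, sdlog 0.5 | mild realistic spread of per-gene signal |

GATC motifs are injected at right-skewed gamma-Poisson spacings whose
*median* sits at the configured value (350 bp default): the median is the
statistic the pipeline consumes, and a pure geometric with the right mean
would place the median near 245 bp. Accidental motifs arising in the random
filler are mutated away, so the motif set equals the injected set and
spacing statements are exact. Planted treatment effects multiply the whole
occupancy of a differential gene's fragments by `2^(±log2FC)`, so the
planted fragment-level occupancy ratio is exact by construction; the
realized log2 CPM fold change is slightly smaller because normalization
redistributes library mass.

What the generator does *not* emulate: sequencing error, PCR duplicates,
mappability and GC bias (a hook exists for GC-linked background),
fragment-length variation, and between-replicate library-quality
differences. Passing tests therefore certify the statistical machinery on
an idealized library, not robustness to real-data artifacts.

### Problem sizes used by the checks

Recovery runs at the default conditions above (~2000 fragments, 3v3, fixed
seed) and asks for sensitivity ≥ 0.8 at empirical FDR ≤ 0.10 under the
gene-level `FDR < 0.01` call. Null calibration runs a no-effect simulation
at ~10⁴ fragments with depth scaled to 5e6 so per-fragment coverage matches
the default conditions — at five-fold lower coverage the log-CPM moderated
t becomes visibly miscalibrated through count discreteness, which is a
property of extreme low coverage rather than of the statistic. The
Kolmogorov–Smirnov uniformity check runs at α = 0.01 and the `p < 1e−5`
exceedance rate is required to stay at its nominal level; note that with
10⁴ fragments the nominal expectation is ~0.1 exceedances, so the check
effectively requires zero hits and can fail by chance (~9%) under an
arbitrary seed even for a perfectly calibrated statistic.

## Numerical choices and degenerate inputs

* Lower median for spacing (deterministic under ties), `trigamma⁻¹` by
  Newton iteration with the standard large/small-argument fallbacks.
* `t = 0/0` (zero logFC with zero posterior variance) is defined as 0,
  p = 1.
* Empty fragment sets merge to empty peak sets; genes without overlapping
  peaks carry `NA` and are never significant; a zero-width leading fragment
  (motif at position 0) is dropped from the map.
* Overlap percentages truncate to whole percent after rounding to one
  decimal — the convention that reproduces the published worked-example
  values (339/1094 → 31%, 510/1094 → 46%, 157/510 → 30%), which no plain
  floor or round rule does.
* Fisher's exact test uses the two-sided point-probability rule; the
  reported odds ratio is the sample `(ad)/(bc)` with Haldane 0.5 correction
  at zero cells, not the conditional MLE.

## Known limitations

Single-factor designs only (no covariates, batch terms or voom-style
mean-variance weighting); no irreproducibility analysis across replicates;
no peak-shape statistics; paired-end reads are counted once via the
leftmost mate's 5' end rather than modeled as fragments; the "methylated
GATC" site class for TSS meta-profiles is a configurable coverage-quantile
operationalization (default: above the median of non-zero fragment means)
because no published threshold exists, and it is validated only on
synthetic constructions.
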