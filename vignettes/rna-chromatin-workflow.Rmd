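---
title: "Methods: calling RNA-chromatin interactions from chimeric proximity-ligation reads"
author: "radipr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling RNA-chromatin interactions from chimeric proximity-ligation reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radipr)
library(data.table)
```

## The data and the problem

RADICL-seq and its immunoprecipitation extension RADIP capture RNA-chromatin
contacts by ligating, inside crosslinked nuclei, an RNA fragment and a
nearby genomic DNA fragment to the two ends of an internal bridge adaptor.
After EcoP15I digestion each sequencing read is a chimera

```
  [RNA tag, 25-27 nt] - [bridge adaptor] - [DNA tag, 25-27 nt]
```

Processing such a library means (i) splitting each read at the adaptor,
(ii) annotating the aligned RNA tag to a gene and the DNA tag to a
fixed-width genomic bin, (iii) deciding which (RNA, bin) pairs occur more
often than a background of incidental contacts, and (iv), when an
immunoprecipitated (IP) library is paired with an un-selected Input
library, deciding which RNAs the IP enriched. `radipr` implements this
workflow end to end together with a synthetic-data generator, so that every
stage can be exercised and verified against known truth without external
data.

## Read deconvolution

The adaptor is located by exact or Hamming-tolerant string matching
(`locate_adaptor()`); indels are not considered because the library design
sequences the entire adaptor at a fixed length. When several offsets are
acceptable the leftmost is chosen and the read flagged `multi_hit`, which
keeps the operation deterministic and auditable. Both tags are trimmed to
`max_tag_len` (default 27 nt) from the adaptor-proximal end, and a pair
passes QC when both tags fall in the 25-27 nt window left by EcoP15I.
Quality metrics (per-position Phred, base composition, length histograms)
are reported but not enforced by default; enforcement thresholds are
arguments, not policy. `trim_tags()` reproduces in-silico tag-shortening
experiments (e.g. 27 to 20 nt) used to quantify how tag length drives
unique-mapping rates.

## Annotation

All internal coordinates are 0-based half-open; GTF and SAM are converted
at the boundary. Each tag is reduced to the single nucleotide at its floor
midpoint (`center_coord()`), which prevents one fragment from touching two
genes or two bins; the floor convention for even lengths is an arbitrary
but fixed tie-break. RNA tags are assigned strand-aware to the unique gene
containing the center (two same-strand candidates make the tag ambiguous
and it is dropped; strand disambiguates antisense overlaps). DNA tags are
assigned to `floor(center / width)` bins (default 25 kb), strand discarded.
Only tag pairs where both sides are uniquely mapped are used; with BWA this
is `MAPQ == 37`, and `mapq_mode = "min"` supports aligners with other
conventions. Records whose DNA tag interval overlaps a blacklist interval
by at least 1 bp are removed. Unassigned-gene records stay in
coordinate-level outputs (they still inform genome-wide contact maps) but
are excluded from gene-level statistics.

## The background model

Observed (RNA, bin) counts mix genuine association with incidental
crosslinking, which is why raw libraries are dominated by low-frequency
pairs. Because a pairs file only contains bins that were hit at least once,
the natural background for an observed count $x \ge 1$ is a
zero-truncated negative binomial,

$$ P(X = k \mid X \ge 1) = \frac{\mathrm{NB}(k;\mu,r)}{1 - \mathrm{NB}(0;\mu,r)}, \qquad
   \mathrm{Var}(X) = \mu + \mu^2/r, $$

fitted per RNA over that RNA's observed bins. A pair's p-value is the
conditional upper tail $P(X \ge x \mid X \ge 1)$, which is exactly 1 at
$x = 1$: single-read pairs can never be significant on their own, matching
the intuition that they are uninformative. One genome-wide
Benjamini-Hochberg correction is applied across all tested pairs, and
pairs with $q \le 0.1$ are retained, the cutoff used throughout this
assay family.

Two identifiability facts shaped the estimator:

* On a typical RNA the observed counts are overwhelmingly 1-3. A joint
  per-RNA ML fit of $(\mu, r)$ on such a support is unstable - the
  likelihood drifts to a heavy-tailed boundary (the log-series limit
  $\mu \to 0$, $r \to 0$) whenever a few large counts are present, and a
  heavy-tailed background masks exactly the pairs one wants to find. The
  dispersion is therefore shared across RNAs, and each RNA contributes
  only its mean (`fit_ztnb_mu()`, a one-dimensional fit, well-posed on
  small supports). The joint fit remains available as `fit_ztnb()` and is
  verified against a likelihood-grid oracle in the tests.
* Genuine signal must not inflate the background it is tested against.
  All background fits are estimated from the low-count bulk: only counts
  $\le$ `bulk_max` enter, with the likelihood conditioned on
  $1 \le X \le$ `bulk_max` so that the exclusion is modeled, not ignored.
  The default `bulk_max` is the larger of 3 and the median count; a
  tenfold-enriched pair has negligible mass in that range, so the
  estimator's breakdown point against enrichment is high while remaining
  consistent under the null.

RNAs with fewer than `min_bins` (default 10) observed bins cannot support
even a one-parameter fit and fall back to a pooled background shared by
genes in the same quartile of per-gene total count, flagged
`pooled_fallback` in the output. An optional `strata` argument (cis
distance deciles plus a trans stratum, `distance_strata()`) refits the
background per stratum as a sensitivity analysis for the constant-mean
assumption; the default background carries no distance covariate.

## Differential interaction analysis

Per-RNA interaction counts per replicate are compared between IP and Input
with the standard count-data core: TMM scaling factors (doubly trimmed
weighted mean of M-values, 30%/5% trims, factors normalised to geometric
mean 1), one common NB dispersion maximising the offset-based profile
likelihood over genes, and a per-gene exact NB test on pseudo-counts
rescaled to a common effective library size, summing all outcomes no more
probable than the observation. The implementation is self-contained and is
cross-checked in the test suite against edgeR's `calcNormFactors` and
`exactTest` on shared settings. Fold changes use a prior count of 0.5 so
that RNAs narrowly missing the "unique to one condition" rule do not get
infinite estimates. An RNA is called enriched when adjusted
$P \le 0.1$ and $|\log_2 \mathrm{FC}| \ge 0.5$, and each condition's
"Special" set is the union of its enriched RNAs and the RNAs captured only
in that condition. By default capture and counting use background-filtered
pairs; `counts = "raw"` switches to raw pairs (the pipeline also falls
back to raw counts, with a warning, if a replicate retains no significant
pair at toy depth).

## Summary analytics

Distance classes split contacts at 100 kb and 1 Mb (lower-inclusive,
consistent with "greater than 100 kb" long-range cis) plus trans;
distances are center-to-center, the only reference points that survive the
center-point reduction. The genome-wide contact map is a sparse RNA-bin by
DNA-bin matrix over a global bin index; its total equals the record count,
and re-binning at a coarser width is verified against a direct recount.
Meta-profiles average tag density in 50-bp sub-bins over +/-3 kb windows
around peak centers, normalising each offset by the number of windows that
actually cover it (windows are clipped at chromosome edges). Saturation
curves subsample records without replacement and report distinct DNA bins
and RNA species, using one permutation per seed so depths are nested and
the curves monotone by construction. The Monte-Carlo chi-square compares
two per-category count profiles: the Pearson statistic on the 2 x K table
against null tables drawn with fixed margins (`stats::r2dtable`), with
$p = (1 + \#\{\mathrm{sim} \ge \mathrm{obs}\})/(B+1)$, whose floor at the
default $B = 2000$ is $1/2001 \approx 4.9975 \times 10^{-4}$.

## The synthetic-data generator

The generator emulates the statistical structure the pipeline assumes, not
sequence realism. Candidate (gene, bin) pairs receive counts
$\mathrm{NB}(\mu, r_0)$ with $\mu = \mu_0 e^{-d/\mathrm{decay}}$ for cis
pairs at planned tag distance $d$ and $\mu = \mu_0\,\varepsilon_{trans}$
for trans pairs; bins overlapping designated peaks have their mean
multiplied by `enrichment_fold` in the IP condition only, and those pairs
form the planted truth. Reads are then emitted per unit of count as
RNA tag + adaptor + DNA tag with uniform 25-27 nt tag lengths, optional
per-base substitution errors, and truth SAM/TSV files with MAPQ 37.

Defaults were fixed once as the study conditions: `trans_fraction = 0.7`
(raw libraries of this type are about 69-73% trans), `eps_trans = 0.05`
(trans pairs individually rare, which is why background removal eliminates
most of them), `decay_scale = 50` kb (cis contacts concentrate below
100 kb), `mu0 = 2`, and `r0 = 10`. The dispersion default comes from a
design-stage power calculation: with a mean-1 background, a tenfold
enrichment must push most planted counts past the count (about 5) at which
the conditional NB tail crosses the BH threshold at $10^4$ pairs, which
holds for mild overdispersion ($r \approx 10$) but not for heavy
($r \le 2$), and mild overdispersion is also what count data dominated by
low-multiplicity pairs looks like. Gene models are intron-dominated (short
100-400 bp exons, a small single-exon fraction), and RNA tag anchors fall
in exons with probability `exonic_fraction = 0.15`, mirroring the
intron-dominated tag origin of real libraries.

What the generator does *not* model: realistic sequence composition, PCR
duplicates, rRNA contamination (only a blocklist filter hook), spliced
alignment, mappability structure, or alignment errors - the truth SAM
stands in for an external aligner. Passing tests therefore demonstrate the
correctness of the statistical machinery and the bookkeeping, not
robustness to alignment artefacts.

## Numerical choices and degenerate inputs

* Even-length intervals take the floor midpoint; ties in adaptor matching
  take the leftmost offset.
* Dispersion is optimised on the log scale within $[10^{-3}, 10^6]$; the
  upper cap behaves as the Poisson limit.
* `fit_ztnb()` flags fewer than `min_bins` counts, all-equal counts
  (dispersion unidentifiable) and non-convergence for pooled fallback
  rather than guessing.
* Empty inputs return empty, typed results with a warning (QC report,
  distance summary), not errors; invalid domains (k = 0 in a
  zero-truncated pmf, p-values outside (0, 1]) are errors.
* All generators and the pipeline are pure functions of (inputs, seed);
  per-stage seeds are derived from one root seed via a fixed affine map
  below $2^{31}$.

## Problem sizes

The shipped tests and the acceptance script run, per invocation: a
round-trip simulation of roughly $10^5$ reads; twenty null and five
planted background-removal simulations of $10^4$ candidate pairs each;
five planted and five null 200-gene, 4-vs-4 differential simulations; and
a 200-replicate validity check of the Monte-Carlo chi-square at $B = 99$.
These sizes give binomial standard errors comfortably inside the asserted
bands while keeping a full run in the minutes range on one CPU.

## Known limitations

* The background carries no distance covariate by default; strong
  distance-dependence within an RNA's contact profile inflates the
  background mean for its proximal bins and is only addressed by the
  optional distance-strata mode.
* The shared dispersion assumes exchangeability of RNAs' background shape;
  RNA-specific overdispersion beyond the shared value is absorbed into
  higher means or, for strong cases, into false negatives rather than
  false positives.
* The differential core implements the two-group common-dispersion exact
  test only - no tagwise shrinkage, no GLM designs.
* Significance is assessed per (RNA, bin) pair independently; spatial
  correlation between neighbouring bins is not modelled.
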