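---
title: "Methods behind apexdge: models, thresholds and design choices"
author: "apexdge authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind apexdge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apexdge)
```

## The problem

Many crops — sugar beet among them — have no reference genome and no
commercial expression arrays. Digital gene expression (DGE) profiling
sidesteps both: short sequencing tags are counted per locus of a de novo
assembled reference transcriptome, and all downstream analysis operates on
the resulting locus × sample count matrix. `apexdge` implements that
downstream analysis for the canonical six-library shoot-apex design: two
genotypes (an experimental line, C600, and a commercial cultivar,
Roberta), with and without vernalization (prolonged cold that licenses
bolting and flowering in biennial beet), and with and without applied
gibberellin (GA), laid out as samples A–F (`beet_design()`).

A deliberate property of that design is that there are **no biological
replicates**: each library is a single pooled-apex RNA sample. Every
statistical choice below is made with that constraint in mind.

## Normalization and filtering

Tag counts are made comparable across libraries by scaling to **tags per
10 million uniquely mappable reads**:

$$x_{ls} = \frac{c_{ls}}{N_s} \times 10^7,$$

where $c_{ls}$ is the tag count of locus $l$ in sample $s$ and $N_s$ the
sample's total of uniquely mappable reads. When $N_s$ is not supplied it
defaults to the column sum, in which case every normalized column sums to
exactly $10^7$ (a conservation property the tests assert). The
denominators are supplied separately from the matrix because mappable-read
totals (71–77% of raw reads in typical short-tag libraries) are not
recoverable from the matrix itself.

Loci are retained when they reach a **normalized count of at least 10 in
at least one sample** (`filter_min_tag()`, inclusive at the threshold).
The filter is applied after normalization; a raw-count mode exists for
sensitivity analysis, because with single-digit-million libraries the two
orders can disagree near the floor.

## Global structure

`sample_correlation()` computes all pairwise Pearson coefficients and
clusters samples by **average linkage on the distance $1 - r$** — the
conventional choice for expression heatmaps; the merge heights are then
monotone, giving a well-formed dendrogram (exported as Newick via `ape`).
`dge_pca()` performs PCA by singular value decomposition of the
locus-centered matrix with samples as observations.

Both operate by default on $\log_2(x + 1)$-transformed values: tag counts
span four orders of magnitude, and without the log the handful of most
abundant loci dominate both statistics. The pseudocount of 1 maps zeros to
zeros. A raw-scale mode is provided for comparison. PCA component signs
are fixed so that each component's largest-magnitude loading is positive,
which makes scores reproducible across platforms and locus orderings.

## Genotype differential expression

The genotype contrast opposes the four C600 samples to the two Roberta
samples; treatment heterogeneity inside the C600 group (untreated, GA,
vernalized, vernalized + GA) is deliberately treated as replicate noise,
which biases the test toward conservatism for treatment-responsive loci
but lets genotype-driven differences that are *stable across treatments*
reach significance. Effects are summarized as MA statistics,

$$M = \log_2(R + c) - \log_2(G + c), \qquad
  A = \tfrac12\left(\log_2(R + c) + \log_2(G + c)\right),$$

with $R$ and $G$ the per-group mean normalized counts and pseudocount
$c = 1$ by default ($c = 0$ is available for strictly positive input).

The per-locus test is a **pooled-variance two-sample Student t** on
$\log_2(x + 1)$, chosen over Welch because the Roberta group has only two
members and a Satterthwaite df estimate from $n = 2$ is unstable. The
pooled variance is floored at $10^{-8}$ (log2 scale) so that an
all-identical locus yields statistic 0 and $p = 1$ rather than 0/0. The DE
call uses the **raw** $p < 0.01$; no multiple-testing correction is part
of the call (a Benjamini–Hochberg column is emitted for information).
This mirrors the classical analysis of such designs; with ~23,000 loci
a raw 1% threshold implies on the order of a couple hundred false
positives, which is why the package reports the FDR column alongside.

## The locus screens

All screens share a `screen_config()`: expression floor 10 (the matrix
retention floor), correlation threshold 0.95, induction fold 2, untreated
similarity bound 1.5, pseudocount 1 in every ratio.

**Vernalization ranking** (`rank_vernalization_response()`) restricts to
loci expressed in *both* the vernalized and non-vernalized sample and
ranks by pseudocounted fold change, descending — up-regulation, not
absolute abundance, is the question being asked; ties break by vernalized
expression and then locus id so the order is total and reproducible.

**Seed-locus correlation** (`correlation_screen()`) computes the Pearson
correlation between each locus profile and a chosen seed locus over a
stated sample list, admitting loci with $r \ge 0.95$ (positive set) or
$r \le -0.95$ (negative set). The threshold is a *correlation
coefficient*, not a p-value: with only four samples, a significance
reading is not testable, and co-varying profile plots are exactly what an
$r$ threshold expresses. Constant candidate profiles have undefined $r$
and are excluded (tallied in `n_skipped`); the seed is excluded from both
sets.

A statistical caveat worth stating plainly: for $n$ independent points
the null density of the sample correlation is proportional to
$(1 - r^2)^{(n-4)/2}$, which at $n = 4$ is **uniform** on $[-1, 1]$ — a
cut at $|r| \ge 0.95$ then admits about 2.5% of completely unrelated
loci into each tail's screen (≈2.5% positive, ≈2.5% negative). Over the
four C600 samples this is the screen the classical analysis ran, and it is
the package default; but when the seed's profile varies across the whole
design, correlating over all six samples drops the null admission rate to
about 0.2% at the same threshold. The package's own recovery benchmarks
therefore exercise the six-sample variant, and users screening a
four-sample profile should expect the larger false-positive floor.

**GA induction** (`ga_induction_screen()`) formalizes "similar expression
in all untreated samples, and at least 2-fold induction in every
treated/untreated pair": (i) max/min pseudocounted spread across the
untreated samples at most 1.5 — the classical criterion gives no number
for "similar", and 1.5 sits between technical noise (±20% at moderate
counts) and the 2-fold induction it must not swallow; (ii) every pair's
induction ratio at least 2; (iii) expression at or above the floor in at
least one treated sample, so that ratios of near-zero values cannot pass.
All three are pure predicates over the reported evidence table, so the
passing set is exactly re-derivable from the output.

## Assembly and homology statistics

`n50()` uses the **length-weighted median** convention: the length at
which the cumulative sum, taken in descending order, first reaches half
the total — equivalently the largest $L$ such that sequences of length
$\ge L$ cover half the assembly. `assembly_summary()` reports a
transcript-level N50 and a locus-level N50 over each locus's *longest*
transcript: a locus needs one representative length, and the longest
transcript is the least arbitrary choice (total locus span and
all-transcript pooling are both defensible; only this one is computed, and
the transcript-level value is always reported next to it).

Large transcripts are those **strictly longer than 500 bp**; with 100 bp
reads such an assembly already implies at least six independent supporting
reads, so read support is treated as derived from length unless an
explicit `read_support` column is present. A locus is large when at least
one of its transcripts is.

Homology hits are consumed as 12-column BLAST `outfmt 6` tables — the
package never runs an aligner. `stringency_filter()` applies inclusive
thresholds (alignment length ≥ 100 bp, identity ≥ 98%, optional E-value
≤ cutoff); alignment length is BLAST column 4, i.e. including gap
columns, the conventional reading of "overlap". `overlap_accounting()`
counts matched ids on a configurable side, because the same comparison is
legitimately summarized from either end (matched subjects for a
locus-side Venn, matched queries for an EST-side coverage figure), and
reports queries matching more than one subject as the redundancy tally.
`best_hit_annotation()` keeps, per query, the smallest-E-value hit at or
below $10^{-10}$, breaking ties by bit score then subject id.

## The synthetic-data generator

`simulate_counts()` exists so that every stage can be validated against a
known truth. Counts for locus $l$ in sample $s$ are negative binomial
with mean

$$\mu_{ls} = \frac{N_s}{10^7} \cdot \beta_l \cdot f_{ls},$$

where $\beta_l$ is a baseline on the normalized scale and $f_{ls}$ the
product of the planted fold effects, and variance
$\mu + \phi\mu^2$ ($\phi = 0$ is the Poisson limit). Defaults, chosen
once as the study conditions:

* **Library sizes** uniform on [13,786,000, 20,360,000] — the mappable-read
  range of the six real libraries, so normalization is exercised exactly
  where it operated.
* **Baseline** $\log_2\beta \sim \mathcal N(6, 2^2)$: a median of 64 tags
  per 10M with a realistic multi-order-of-magnitude spread.
* **Dispersion** $\phi = 0.01$ (BCV 0.1): the six libraries are single
  libraries from pooled, genetically near-identical material, so
  locus-level variation between them is technical-replicate-like; 0.01 is
  the conventional dispersion for that regime. The study provides no
  replicate information from which to *estimate* dispersion, so this is a
  convention, not an estimate.
* **Planted folds** of 4 for genotype (half up in each genotype, mirroring
  the bidirectional MA cloud), vernalization and GA effects; **planted set
  sizes** of 50 each plus one seed locus with 50 positive and 10 negative
  partners, within 5,000 loci.
* **Planted baselines** are truncated at ≥ 32 tags per 10M: an effect
  planted below the detection floor of 10 is unobservable by construction
  and would only measure the filter, not the screens.
* **Seed partners** multiply the seed's relative profile (positive
  partners) or its exact negative-affine image (negative partners, $r = -1$
  before noise) by $e^{\mathcal N(0,\,0.05^2)}$ per sample, making screen
  recovery tunable via the noise sd.

What the generator does *not* emulate: read-level sequencing (no FASTQ),
mis-assembly or chimeric loci, genotype-specific mappability, correlated
null loci, or compositional effects of a few very abundant genes on the
library totals. Passing recovery benchmarks on this generator therefore
demonstrates correctness of the statistics and predicates, not robustness
to assembly artefacts or biological confounding in real data.

## Problem sizes and numerical choices

The packaged benchmarks use 5,000-locus simulations (the null calibration
uses 10,000 loci), sizes at which every stage is exact and fast; all
results are reproducible from fixed seeds recorded in the tests and in
`scripts/acceptance.R`. Numerical conventions collected in one place:
pseudocount 1 in every log and ratio (0 available); variance floor
$10^{-8}$; inclusive comparisons at every printed threshold (≥ 10 tags,
≥ 98% identity, ≥ 100 bp, E ≤ $10^{-10}$, $p < 0.01$ strict as printed);
PCA signs fixed by largest loading; screen ties broken by evidence value
then locus id.

## Limitations

* With two genotype groups of 4 and 2 samples confounded with treatment,
  the genotype test's power is asymmetric and a mild bias toward the
  larger group is expected; no correction is attempted.
* The four-sample correlation screen has the ~2.5%-per-tail null
  admission floor derived above.
* The locus-level N50 convention (longest transcript) is one of several
  defensible choices; comparisons across tools should use the
  transcript-level N50.
* No enrichment, network or ortholog-function analysis is included;
  homology joins are limited to user-supplied tabular hits.

## An end-to-end run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(out_dir = "apexdge-demo",
                       simulation = simulation_config(seed = 20120319))
manifest <- run_pipeline(cfg)
str(manifest$counts_in_out)
```

The manifest records the configuration, the per-stage locus counts and an
MD5 checksum of every written table; re-running the same configuration
reproduces the checksums bit for bit.
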