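---
title: "Reciprocal aneuploidy analysis of egg/polar-body pairs and morphokinetics of meiotic maturation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reciprocal aneuploidy analysis of egg/polar-body pairs and morphokinetics of meiotic maturation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aneukin)
```

## The biological model

At meiosis I an oocyte resolves each bivalent — two homologous chromosomes of
two sister chromatids each — by extruding one homolog into the first polar
body (PB1). For every chromosome, the four chromatids of the bivalent are
therefore partitioned between the egg and PB1, and the partition is
conserved: **egg + PB = 4 chromatids**, whatever goes wrong. The two
canonical meiosis-I errors leave distinct reciprocal signatures:

* **NDJ** (non-disjunction): both homologs segregate to one cell — 4/0 or 0/4;
* **PSSC** (premature separation of sister chromatids): sister cohesion fails
  early and a lone chromatid ends up on the wrong side — 3/1 or 1/3.

`aneukin` reimplements a clinical PGT-A style shallow-sequencing workflow
reverse-translated to mouse gametes: binned read counts per sample are
compared against a euploid male (40,XY) normal panel, per-chromosome
fractional copy numbers are observed, and integer chromatid copies are
*designated* jointly for each matched egg/PB pair under the conservation
constraint. A ground-truthed synthetic-data generator stands in for the raw
sequencing and time-lapse imaging data, which are not publicly deposited.

## Copy-number calling

The genome is tiled into fixed 10 Mb windows (0-based, half-open; the last
window of each chromosome may be shorter). GRCm39 chromosome lengths are
bundled as constants and can be overridden with a two-column TSV. The
calling chain per sample is:

1. **Sample QC** — a sample whose fraction of reads mapped to the mouse
   genome is below 0.90 is excluded from all downstream analysis; a missing
   mapped fraction yields an explicit indeterminate status.
2. **Bin filtering** — raw bin counts strictly above 1000 are considered
   overrepresented and masked (counts exactly at 1000 are retained). The
   rule operates on raw counts, before normalization, so it is deliberately
   not scale invariant.
3. **Normalization** — unmasked bins are scaled so the unmasked *autosomal*
   total is 1 million counts (relative tolerance 1e-9 in tests). The sample
   and the panel are normalized over the same set of unmasked bins so their
   denominators are comparable.
4. **Fold change** — ratio of normalized sample to normalized panel per bin;
   bins with a zero panel value are masked with reason `zero-panel` rather
   than erroring.
5. **Observed copy number** — the per-chromosome median of unmasked bin fold
   changes, times 2 for autosomes and 1 for sex chromosomes (the male panel
   carries one X and one Y). The median is used because the aggregation of
   windows into a chromosome call is not otherwise constrained, and the
   median is robust to residual outlier bins.

Two situations receive special handling, both arising from whole-complement
segregation failures where one cell inherits (almost) the entire chromosome
complement and its partner (almost) nothing:

* a chromosome with **more than half of its bins masked as
  overrepresented** has no reliable fold change — the surviving bins are a
  downward-truncated draw — so its observation is dropped (NA) and the call
  is made from the partner;
* a sample whose unmasked autosomal counts are **all zero** cannot be
  normalized; it yields an all-NA profile flagged `normalization_failed`
  instead of an error, again deferring to the partner.

## Reciprocal designation

Because each sample is normalized to a fixed autosomal total, its observed
copy numbers are the true chromatid counts times an unknown sample-specific
scale factor: an egg that retains extra chromosomes has *all* its observed
values deflated, and its polar body inflated. For mild aneuploidy the
distortion is a few percent; for whole-complement failures it reaches an
order of magnitude, and the observed profile of the nearly-empty cell is
degenerate. The designation step therefore interprets the two profiles
*jointly* under the conservation constraint:

1. Each side's scale is estimated by alternating (i) provisional integer
   designation of every chromosome with (ii) a per-side least-squares refit
   of that side's scale against its own designated integers, to a fixed
   point. Fitting each side against its own integers keeps the problem well
   conditioned for euploid pairs, where a joint two-scale regression would
   be collinear.
2. Two starting points are tried: a common scale fitted to the
   per-chromosome sums, and the joint least-squares solution of
   $a\,\mathrm{obs}_e + b\,\mathrm{obs}_p = 4$, which locates the extreme
   per-side factors of whole-complement failures.
3. The calibration is only weakly identified in one direction: a euploid
   pair and a uniform whole-complement mis-segregation produce identical
   data up to scale. Parsimony breaks such near-ties — the solution calling
   fewer euploid chromosomes is accepted only when its residual is
   decisively smaller (less than half the parsimonious one's). This encodes
   the biological prior that aneuploidy is the exception; a spectrum of
   intermediate evidence ratios would leave the call genuinely ambiguous on
   real data too.
4. When one profile is entirely missing, the partner's scale is anchored on
   the whole complement (4 copies), since a collapsed profile is itself
   evidence that its sample was nearly empty.

After calibration, each chromosome's integer pair $(e, p)$ with $e + p = 4$
is chosen to minimize the squared distance to the rescaled observations.
Ties are broken toward the euploid call (2, 2). If the winning residual
exceeds **0.5** — the half-copy rounding radius — the chromosome is marked
*discordant* rather than forced to a call; discordant chromosomes are
counted separately and never as errors. When one side of a single
chromosome is unobserved, the call is made from the partner alone via
$e = 4 - p$.

X participates in conservation exactly like the autosomes (egg X + PB X = 4
chromatids); Y is excluded for oocyte-derived pairs and is used only for
blastomere sex-concordance checks.

## Karyotype nomenclature

Designated copies are rendered in a shallow-NGS style string grammar:

```
sseq cht(<chrom list>)x<copies>, cht(<chrom list>)x<copies>, ...
```

one clause per abnormal copy value. Within a clause X precedes the
autosomes, which are listed ascending with runs of **three or more**
consecutive autosomes collapsed to `a-b` (printed reference karyotypes
leave two-chromosome runs uncollapsed, e.g. `12,13`, and this writer
follows that style). Clauses are ordered by their lowest chromosome, with X
sorting lowest. A fully euploid sample is rendered as the fixed token
`sseq euploid`, since reference reports print no euploid string; the
round-trip contract (`parse(write(x)) == x`) is what tests enforce. The
parser is whitespace-tolerant — printed strings contain irregular spacing
such as `cht(X , 1-6,8-19)x4` — and rejects malformed clauses, duplicate
chromosomes, and copies outside 0..4.

```{r}
calls <- pair_calls_from_karyotypes("sseq cht(14)x4, cht(18)x0",
                                    "sseq cht(14)x0, cht(18)x4",
                                    pair_id = "demo")
classify_sample(calls)
```

Per-pair classification: the aneuploidy type is NDJ, PSSC or NDJ+PSSC
(when both classes occur), and severity is bucketed as euploid, 1–3 errors
or ≥4 errors.

## The synthetic-data generator

The generator's defaults are the study conditions of the Nocodazole
dose-response experiment the package models, fixed once:

* **Cohort**: three groups — vehicle control, 25 nM and 50 nM Nocodazole —
  with 11, 13 and 23 matched egg/PB pairs.
* **Segregation model**: per chromosome, an independent mis-segregation
  probability `p_err`; errors are NDJ with probability `q_ndj = 0.9`, else
  PSSC, with the retaining side fair (both directions are observed in
  practice). With probability `p_cat` a pair suffers a *catastrophic*
  whole-complement event: every chromosome segregates to one cell except
  1–4 exception chromosomes carrying the opposite 4/0 or a 3/1 pattern
  (PSSC-like with probability 0.7). The dose parameters
  (`p_err` = 0, 0.004, 0.067; `p_cat` = 0, 0, 0.30) were calibrated once
  from the observed incidences — 0/11, 1/13 and 19/23 aneuploid with 7/23
  whole-complement events at the high dose — via
  $1-(1-p)^{20} = \text{incidence}$, and are not claims about mechanism.
* **Read counts**: the expected count of a bin is proportional to a shared
  lognormal bin bias (log-SD 0.1, drawn from a dedicated `bias_seed` so
  panel and samples see identical biases), the bin width, and the
  chromatid count of its chromosome divided by two. Counts are
  negative-binomial (Poisson–gamma) with size 50 at an expected depth of
  50,000 reads per sample — a per-bin overdispersion floor of ~14% CV,
  typical of WGA shallow sequencing. `dispersion = Inf` gives Poisson
  counts and `0` the noiseless limit. A configured fraction of bins
  (default 0.5%) is forced overrepresented (counts > 1000), and designated
  QC failures (default probability 1%) draw a mapped fraction below 0.90.
* **Normal panel**: the 40,XY copy map with the same biases and noise
  model; by default 10 replicate draws are averaged after normalization,
  emulating a reference animal characterized much more deeply than single
  gametes.
* **Morphokinetics**: tGVBD and tPB1 are drawn per severity class from
  normal distributions with means 0.92/1.00/0.95 h and 9.19/11.23/13.80 h
  for euploid, 1–3 and ≥4 errors; SDs are the printed SEMs times
  $\sqrt{n}$ with group sizes 27/9/11. Draws are rejection-resampled so
  tPB1 > tGVBD and dMI is the exact difference. Per-group counts of
  immature oocytes (GV-arrested or GVBD without extrusion) are appended to
  emulate dose-dependent maturation failure; their defaults (1/1, 1/2 and
  2/6) are illustrative, as exact stage counts are not printed.

What the generator does *not* emulate: read-level artifacts (no FASTQ), GC
or mappability structure derived from sequence, the WGA amplification
mechanism, segmental aneuploidy, or mosaicism. Passing tests on synthetic
data therefore demonstrate that the calling and designation logic is
correct under the stated noise model, not that the noise model captures
every failure mode of real libraries.

## Morphokinetic statistics

Event times are hours from imaging start (t0 = 0). dMI = tPB1 − tGVBD
exactly; records lacking tPB1 are GV or GVBD-only and are retained for
maturation-rate reporting but excluded from timing summaries; tPB1 ≤ tGVBD
is flagged `invalid-annotation`. Group comparisons follow a fixed gate:
Shapiro–Wilk normality per group at α = 0.05 (groups too small to test, or
with zero spread, are treated as compatible with normality); all normal
with two groups → Student's t-test (equal variances); all normal with more
→ one-way ANOVA with Tukey's HSD; any non-normal → Kruskal–Wallis with
Dunn's multiple comparisons. Dunn's rank-based z statistics with tie
correction are implemented in the package (Bonferroni adjustment, as in
common graphing software) and are cross-checked in tests against the
two-group equivalence $z^2 = \chi^2_{KW}$. Outlier screening uses the
iterated two-sided Grubbs test at α = 0.05, removing at most one point per
iteration; other exclusion reasons (vacuoles, lost PB) are ingested as
flags, not computed. Maturation-stage compositions are tested with
Fisher's exact test when any expected cell is below 5, else chi-square.

```{r}
derive_variables(data.frame(tGVBD = 0.95, tPB1 = 13.80))[, c("dMI", "status")]
```

## End-to-end pipeline and problem sizes

`run_pipeline(sim_config(), seed)` chains simulation, QC, calling,
designation, classification and statistics, and every aggregate is
recomputable from the per-pair rows. A mandatory seed drives all
randomness; identical (config, seed) gives byte-identical artifacts.

```{r}
report <- run_pipeline(sim_config(), seed = 7)
report$aggregates$incidence
head(summarize_error_spectrum(report))
```

The test suite exercises the noiseless limit (exact recovery of every
simulated configuration), recovery at the default noise level over a
200-pair cohort (≥99% of chromosome calls), designation against brute-force
enumeration on 10,000 random observation pairs, grammar round-trips over
the bundled reference karyotypes plus 1,000 random configurations, and a
2,000-replicate null calibration of the Grubbs exclusion rate. These sizes
keep the full suite in the minutes range on a single core while holding
Monte-Carlo error well below the tested margins.

## Known limitations

* Whole-chromosome chromatid counts only: no segmental events, no
  mosaicism, no mitotic-error logic.
* The euploid-versus-uniform-complement ambiguity is resolved by parsimony;
  a real sample genuinely consisting of a uniform all-PSSC complement in
  one direction would be called euploid, as it would be by eye.
* The designated copy range is capped at 0..4; patterns outside the
  four-chromatid model surface as discordant chromosomes rather than calls.
* Morphokinetic class distributions are normal by construction; heavy tails
  in real annotation data are only partly absorbed by the Grubbs screen.
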