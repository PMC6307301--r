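---
title: "Models and methods behind encult"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind encult}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(encult)
```

`encult` analyses enrichment-culture time courses of sediment microbial
communities: why do cultured "novel" species so often come out of flasks
they never dominated? The package combines five statistics — isolate
recruitment, a degree-of-enrichment ratio, an RNA:DNA activity ratio,
alpha diversity with rarefaction, and co-occurrence networks — with a
cofactor prototrophy screen, and validates all of them against a
synthetic community with planted ground truth. This vignette documents
the models, the defaults and the design decisions; it states no result
that the test suite and `scripts/acceptance.R` do not themselves compute.

## The two ratio statistics

Both headline classifiers are pseudocounted read ratios with a strict
boundary.

**Degree of enrichment.** For a cultured species with rarefied recruited
reads $a_t$ at its isolation stage and $a_0$ at day 0 (same source,
common rarefaction depth),

$$R_E = \frac{a_t + 1}{a_0 + 1},$$

and the species is *enriched* iff $R_E > 1$. The +1 reflects that an
isolated species must have been present in both samples even when
sequencing missed it; it also pins $R_E = 1$ exactly when $a_t = a_0$,
and the boundary case is classified **not** enriched. The community
summary is the fraction of species isolated *after* enrichment
(isolation day > 0) that were not enriched; day-0 direct-plating isolates
are excluded from that denominator, since "was culturing explained by
enrichment?" is not a meaningful question for them.

**Activity.** For a taxon with $r$ reads in the 16S rRNA (RNA) library
and $d$ reads in the 16S rRNA gene (DNA) library of the same
(source, day),

$$R_A = \frac{r + 1}{d + 1},$$

active iff $R_A > 1$, dormant otherwise (again strict, so $r = d$ is
dormant). Ribosome content per cell tracks growth activity, so an
RNA:DNA ratio above parity marks taxa transcribing rRNA out of
proportion to their gene abundance. Aggregation to a taxonomic rank is
**sum-then-ratio**: reads are summed within the rank in each library
before the ratio, which is the only version consistent across ranks
(the rank-level ratio equals the ratio of rank-level marginal counts
exactly, a property the tests assert). `proportion_active()` reports,
per (source, day), the fraction of *present* taxa ($r + d > 0$) that are
active; taxon-weighted is the primary statistic and a read-weighted
variant is emitted alongside, since "percent of the community" can mean
either.

## Recruitment by percent identity

Isolates are near-full-length 16S sequences; amplicon features are
shorter fragments. `pairwise_identity()` therefore uses a semi-global
(end-gap-free) alignment: terminal overhangs are free and excluded from
the identity denominator, internal gap columns are counted, and columns
involving N never count as matches. Scoring is match +1, mismatch −1,
with affine gaps costing 2 for the first column of a run and 1 for each
further column.

Score ties are resolved by a lexicographic objective — maximize score,
then matches, then minimize aligned columns. Because identity and
overlap are read off this optimal *value* rather than off one traceback
path, the result is deterministic and exactly symmetric in its two
arguments (the objective is invariant under swapping the sequences). A
path-based tie-break such as "prefer fewer gaps, leftmost traceback"
cannot guarantee that symmetry, which is why the value-based rule was
chosen; a brute-force dynamic-programming oracle in the test suite
implements the same objective independently.

A feature is recruited when identity ≥ 0.99 over ≥ 200 aligned columns.
The overlap floor is the reproducible stand-in for an E-value gate:
E-values depend on the search tool's statistics and database size,
whereas identity + overlap is a pure function of the two sequences. All
features over the gate are treated as the same species, so their reads
are **summed**, not max-taken. A shared 12-mer prefilter skips pairs
that provably cannot reach the gate (a ≥ 99% match over ≥ 200 columns
must contain an exact run of at least 66 nt); the prefilter disables
itself automatically whenever the user relaxes the gate past the point
where the pigeonhole guarantee holds, so it can never change a profile.

## Rarefaction and diversity

All ratios and richness comparisons are computed on libraries rarefied
(subsampled without replacement) to a common depth, by default the
smallest library. Normalization uses a single recorded draw under a
stated seed; rarefaction *curves* average ≥ 10 draws per depth, and the
tests check the curve against the analytic hypergeometric expectation
$E[S] = \sum_i \left(1 - \binom{N - n_i}{d} / \binom{N}{d}\right)$.
Subsampling itself is delegated to `vegan::rrarefy()`.

Chao1 is the bias-corrected form $S_{obs} + F_1(F_1 - 1)/(2(F_2 + 1))$,
which never divides by zero and floors at $S_{obs}$. ACE follows Chao &
Lee with rare/abundant cutoff 10; when every rare species is a singleton
the coverage estimate is zero and ACE falls back to Chao1 (the standard
convention). These two are computed in-package because the report
exposes their components (F1, F2, S_rare, S_abund, C_ace, gamma), and
are cross-checked against `vegan::estimateR()` in the tests; Shannon
(natural log) and Simpson go through `vegan::diversity()`. Simpson is
reported as Gini–Simpson $1 - \sum p_i^2$ with the raw concentration
$\sum p_i^2$ emitted alongside, as conventions differ.

**Novel-OTU gain** is the number of features detected after enrichment
but absent from all day-0 libraries, divided by day-0 richness. Because
"x% more OTUs" may also mean the net richness change, both statistics
are returned and neither is asserted as the canonical definition.

## Co-occurrence networks

Features are first filtered to at most 2 zero occurrences across the
(typically 15) samples and total reads strictly above 1 — the
"majority" abundance floor, interpreted as a total-count threshold
following its parenthetical description in the source pipeline's
parameters. Counts are log10-transformed with zeros kept blank
(missing), Pearson correlations are computed on pairwise-complete
samples, and an edge is kept iff $|r| \ge 0.7$ with at least
`min_pairs = 9` complete pairs. The pair floor guards degenerate
correlations; on tables that passed the zero filter over 15 samples
every pair already has ≥ 11 complete pairs, so it is inert there. No
multiple-testing correction or random-matrix thresholding is applied —
the fixed cutoff *is* the method — but the tests include a
permutation-null diagnostic showing the false-edge rate on independent
noise matches the permuted-data rate.

One mathematical caution the tests encode: Pearson on log counts is
invariant to scaling any *feature* (or the whole table) by a power of
10, since that shifts a whole vector; it is **not** invariant to scaling
one *sample*, which perturbs a single coordinate of every pair.
Library-size differences should therefore be removed by rarefaction
before network construction, not assumed away by the log transform.

Family-level association tables count positive and negative edges per
family pair and report the majority sign, with ties reported as
`"mixed"` and edge-less families listed with zero counts.

## Cofactor screen and syntrophy candidates

`completeness()` scores a genome as the fraction of a pathway's core
genes present in its gene-presence table (absent-from-table = absent).
With the default `prototroph_min = 1`, a genome is a *prototroph* iff no
core gene is missing — a strict reading of "can synthesize de novo";
the threshold is relaxable because real annotation pipelines miss genes.
Non-prototrophs with a salvage transporter (BioY/BioM for biotin,
BtuBFCD for cobalamin) are `auxotroph_salvage`, the rest `auxotroph`.
The biotin core is the six-gene late pathway (bioC, bioH, bioF, bioA,
bioD, bioB; both pimeloyl-entry genes are required unless the user
supplies an alternative-entry definition), with BirA recorded as the
ligase but not scored. The shipped cobalamin list is an editorial
~20-symbol corrinoid set — no curated reference list was adopted — and
should be replaced for real screens.

`syntrophy_candidates()` joins group-aggregated trophy classes (majority
vote per group; ties skipped) with the network's association table and
emits a donor→recipient pair for every *positive* net-sign association
from a prototroph group to an auxotroph group. By construction the
output is a subset of positive associations × (prototroph, auxotroph)
pairs; negative and mixed associations never nominate candidates.

## The synthetic community generator

The generator emulates the study design the statistics were built for:
3 sediment sources × days 0/5/12/21/30, paired DNA/RNA libraries, and a
community of 200 taxa in four behavioural classes.

- **r-strategists** (20%) start from a rare dormant seed bank (log10
  relative abundance uniform in [−5, −3]) and bloom log-linearly by 3.5
  decades to a peak at an interior day, then decay over 15 days — the
  "respond fast to a nutrient flush, then collapse" phenotype.
- **k-strategists** (20%) grow steadily at 0.08 decades/day from a
  moderate baseline.
- **inert** taxa (60%) keep constant expected absolute abundance; their
  *relative* abundance falls as blooms take over, which is what makes
  them recoverable negatives for the enrichment classifier.
- **planted-pair** taxa (6 by default, in dedicated single-member
  families) carry designed trajectories in relative-abundance space:
  each partner's log relative abundance is an exact ±1-slope function of
  its leader's realized trajectory. Designing in relative space matters:
  community log-totals grow during blooms, and that common-mode term
  cancels for positively tied pairs but destroys anticorrelations
  planted in absolute abundance (measured attenuation from −1 to about
  −0.4), so the generator adds the log-total back explicitly. Planted
  baselines (10^−2.8 to 10^−2.0) keep the pairs above the zero-filter
  at 10^4-read depth while swinging ±0.8 decades.

Lognormal noise (sd 0.15 log10 units) is applied per (taxon, source,
day); abundances are then renormalized per sample and counts drawn
multinomially at the library depth, so column sums are exact. RNA
libraries scale each taxon's DNA proportion by an activity factor (4 for
active, 0.2 for dormant — chosen so the ratio classifier has signal
without being trivial at 1% abundance) and renormalize; this
one-parameter stand-in for ribosome content is sufficient because the
analysis consumes only the ratio's position relative to 1. The fraction
of active taxa declines linearly from 0.27 at day 0 to 0.13 at day 30 —
the community-level figures reported for real sediment enrichments —
with a nested (per-taxon) deactivation schedule.

**Ground truth.** `true_enriched` is defined per (taxon, source, day) on
the realized (post-noise, pre-multinomial) relative abundances the
counts are actually drawn from: "did this taxon's relative abundance in
this flask exceed its own day-0 value". Source-level noise is thus real
biological variation, not classifier error, and recovery accuracy
measures only what sequencing depth can resolve. `true_active` is the
assigned activity state per (taxon, day). Default depth is 50,443 reads
(the rarefaction floor of the motivating study design); recovery checks
run at 10,000 reads and 200 taxa, scoring only taxa at ≥ 1% relative
abundance, where a 10^4-read library resolves the ratios.

Reference sequences are i.i.d. A/C/G/T strings (1400 nt), resampled
until mutually below 97% identity; at these lengths a ≥ 97% pair must
share at least 21 distinct 12-mers (pigeonhole on ≤ 42 edits), so pairs
sharing fewer than 10 are accepted without alignment. Isolates differ
from their source reference by Binomial(length, divergence)
substitutions at uniform sites, divergence 0.005 by default — about 7
substitutions, comfortably inside the 99% recruitment gate, while 0.03+
falls reliably outside it. What the generator does **not** emulate:
sequencing error and chimeras, compositional count overdispersion beyond
multinomial, phylogenetic signal in the sequences, taxon interactions
beyond the planted pairs, and continuous (rather than two-state)
activity. Passing recovery tests therefore demonstrate correctness of
the statistics under the stated model, not performance on real reads.

## Pipeline, seeds and numerics

`run_pipeline()` chains simulate → recruit → diversity → enrichment →
activity → network → trophy, writing plain-text outputs per stage and a
manifest with parameter provenance (default vs override), per-stage
seeds and MD5 checksums; identical config + seed give byte-identical
outputs, and no stage rewrites another stage's files. Each stage derives
its seed from the global one by a stable string hash of the stage name,
so inserting or removing a stage never reshuffles the randomness of the
others.

Numerical conventions worth stating: ratios are exact rational
arithmetic in doubles (no logs taken before classification; log10 ratios
are emitted for plotting only); all-zero columns are errors for
diversity (undefined) rather than silently zero; an empty feature set
after network filtering is a warning, not an error; pairs with fewer
complete samples than `min_pairs` are recorded as skipped; and boundary
classifications are strict (`> 1`) everywhere, so equality never counts
as enriched or active.

Problem sizes in the shipped checks — 200 taxa, 10^4 reads, 20
simulation replicates for association recovery — were chosen as the
smallest sizes at which the ≥ 1%-abundance taxa are well resolved and
the planted effects are unambiguous; the generator accepts larger values
unchanged.
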