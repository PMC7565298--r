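---
title: "Models and methods behind smoltmiR"
author: "smoltmiR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smoltmiR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smoltmiR)
```

# Overview

smoltmiR re-implements, as a single tested pipeline, an integrative
miRNA-mRNA expression analysis of Atlantic salmon smoltification: head
kidney was profiled at six timepoints (T1, one day before the photoperiod
treatment; T2-T4 during smoltification; T5 and T6 one week and one month
after seawater transfer), small-RNA libraries were sequenced for eight
fish per timepoint, and mRNA expression was measured on one-color
microarrays.  The pipeline chains seven stages:

1. small-RNA quantification (adapter trimming, 18-25 nt size selection,
   unique mapping to mature miRNAs);
2. miRNA differential expression, each of T2-T6 against T1, with a
   negative binomial Wald test;
3. mRNA differential expression with per-gene Welch tests;
4. clustering of the DE miRNA log2 fold-change trajectories;
5. annotation of DE genes anti-correlated to the cluster mean profiles;
6. seed-constrained miRNA:3'UTR duplex minimum-free-energy target
   prediction;
7. overrepresentation analysis and aggregation of the final
   miRNA-target pair table.

A synthetic-data generator produces every input with the statistical
structure this analysis assumes, so the full pipeline runs, and its
operating characteristics can be measured, without any external data.

# The miRNA count model and differential expression

Counts for miRNA $i$ in sample $j$ are modeled as negative binomial with
mean $s_j \mu_{i,t(j)}$ and shared dispersion $\alpha$, where $s_j$ is a
sample size factor and $t(j)$ the sample's timepoint.  Size factors use
the median-of-ratios estimator over features with all-positive counts,
rescaled to geometric mean one.

The Wald test for a contrast (a timepoint against T1) estimates, per
feature, a moment-based dispersion
$\hat\alpha = \max\{0, (s^2 - \bar m)/\bar m^2\}$ from the pooled
within-group variance of normalized counts, and shrinks it halfway (on the
log scale) toward a mean-dispersion trend $\alpha(m) = a_0 + a_1/m$ fitted
across features.  The log2 fold change uses normalized group means with
pseudocount 0.5, its standard error is
$\mathrm{SE}^2 = \frac{1}{\ln^2 2}\left[\frac{1}{n_A}\left(\frac{1}{\bar
m_A + 0.5} + \alpha\right) + \frac{1}{n_B}\left(\frac{1}{\bar m_B + 0.5} +
\alpha\right)\right]$, and $z = \mathrm{lfc}/\mathrm{SE}$ is referred to a
standard normal.  This is deliberately a documented, simplified NB test:
the published analysis used an external package whose shrinkage estimators
are not specified in the text, so bit-equality is not a goal; the
threshold semantics are preserved exactly (BH-adjusted $p \le 0.05$,
$|\mathrm{lfc}| \ge 1$, baseMean $\ge 10$, all bounds inclusive, per
contrast).  On a seeded null simulation (2000 features, 8 vs 8,
dispersion 0.05) the empirical type-I error at nominal 0.05 is computed by
the test suite and required to lie in [0.03, 0.07].

The microarray branch uses per-gene Welch t-tests on log2 intensities
with the platform's reporting convention: raw $p \le 0.05$ and
$|\mathrm{lfc}| \ge 0.8$.  BH adjustment is applied within each contrast;
adjusting across all five contrasts jointly is not done by default (the
source analysis describes per-contrast comparisons).

# Fold-change clustering and the number of clusters

DE miRNAs are represented by their five log2 fold changes (T2-T6, each
vs T1).  The dendrogram uses Spearman correlation distance
$d = 1 - \rho_s$ with complete linkage; the number of clusters is chosen
by the gap statistic on k-means (within-cluster sum of *squared*
distances, best of 25 restarts; B reference data sets drawn uniformly over
the per-dimension range of the data), selecting the smallest $k$ with
$\mathrm{Gap}(k) \ge \mathrm{Gap}(k+1) - s_{k+1}$.  The tree is cut at the
chosen $k$ for the final labels; the k-means labels are written alongside
for comparison.  Both procedures appear in the source analysis; coupling
them this way reproduces both and their point of contact.

A practical note measured on synthetic data: when profiles are estimated
with low noise, the gap curve rises steeply to $k = 3$ and is nearly flat
beyond it, so the one-standard-error rule resolves three clusters in about
half the runs and occasionally splits one archetype into two adjacent
sub-clusters ($k = 4$).  The three planted shapes are recovered either
way; the end-to-end checks therefore require $k \ge 3$, a one-to-one map
of three clusters onto the three archetypes, and the three qualitative
shapes (all means $\le 0$ with the minimum at T6; minimum at T5; all means
$\ge 0$).  On idealized three-blob data at five-SD separation the rule
selects $k = 3$ in at least 95 of 100 seeded runs.

# Correlation integration

Gene trajectories (per-timepoint mean log2FC vs T1, matching the miRNA
profile construction) are correlated with each cluster's mean profile.
With only five points per profile the coefficient type matters little but
is configurable; the default is Pearson ("r" conventionally denotes
Pearson), Spearman is available by flag.  A gene is annotated negative
(positive) to a cluster iff $r < -0.67$ ($r > 0.67$), strictly.  Genes
negative to several clusters are reported once, under the negative cluster
with the largest $|r|$; the overall $\arg\max |r|$ is reported separately.
Before clustering, miRNAs must pass the expressed filter: raw counts
strictly above 10 in at least $\lceil 2n/3 \rceil$ samples.

# Duplex target prediction

Candidate sites require a perfect Watson-Crick match of the miRNA seed
(positions 2-8 from the 5' end); G:U is explicitly not a seed match.  Each
site is extended by a dynamic program over intermolecular pairings only
(neither strand folds on itself): the seed must remain contiguously
paired, position 1 and positions 9 onward pair freely, G:U is allowed
outside the seed, and loops obey the published constraints (bulges at
most 9 nt; internal loops at most 9 nt per side).  Hits are reported iff
MFE $\le -18$ kcal/mol, inclusive; overlapping sites of one (miRNA, UTR)
pair collapse to the lowest-energy one.

The free energy is
$\Delta G = \Delta G_\mathrm{init} + \sum \Delta G_\mathrm{stack} +
\sum \Delta G_\mathrm{loop} + \Delta G_\mathrm{ends}$ under a
nearest-neighbor RNA/RNA parameter set at 37 degrees C (Turner 2004
values), shipped as versioned constants: the 6x6 stack table over
{CG, GC, GU, UG, AU, UA}, bulge and internal-loop initiation penalties by
size, a Ninio asymmetry term (0.6 kcal/mol per unpaired-length difference,
capped at 3.0), duplex initiation +4.10, and +0.50 per AU/GU pair closing
either duplex end.  Three standard simplifications are documented:
single-nucleotide bulges keep their flanking stack; internal loops use
size-plus-asymmetry initiation without terminal-mismatch bonuses; and the
terminal penalty applies at the two outermost pairs only.  Because the
published screen names a tool but no parameter set, energies are
comparable in rank, not bit-identical; only the threshold behavior is a
reproduction target.  The scan window around a seed site extends
miRNA-length + 9 nt to each side, which any loop-legal structure fits.

The dynamic program is validated two ways: exhaustive enumeration of all
loop-legal structures on windows up to 12 nt (1000 seeded instances), and
an independent structure-scoring pass that re-scores every reported
optimal structure to its reported MFE.  Appending complementary bases can
never raise the MFE (every added Watson-Crick stack is at least
0.9 kcal/mol stabilizing, exceeding the worst 0.5 terminal-penalty
change), and the suite asserts this monotonicity.

# Enrichment

Overrepresentation of a study set against a background uses the
hypergeometric upper tail $P(X \ge k)$, identical to the one-sided
Fisher's exact test; terms are significant at BH FDR < 0.05, strictly.
Annotation is a user-supplied gene-to-term table: the published analysis
used an external web service and database snapshot, so term counts from
the publication are snapshot-dependent and are not reproduction targets.
Significant terms can be rolled up under their most general significant
ancestors along user-supplied parent links; a term below a diamond may
appear in two groups, and a gene may appear in several groups.

# The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions at desk scale.

* **Design**: 6 timepoints x 8 replicates (48 small-RNA samples); 5
  arrays per timepoint for the mRNA branch (the study analyzed 29 of the
  48 fish, 4-5 per timepoint).
* **miRNAs**: 120 matures grouped into gene families of 1-4 members
  (salmonid genome duplication makes large families common), with random
  20-24 nt sequences; 71 DE miRNAs split 34/14/23 across three archetypes,
  matching the published cluster sizes; the rest are nulls.
* **Archetypes** (log2FC at T2-T6 vs T1): I, sustained decrease
  (-0.8, -1.4, -1.8, -1.8, -2.2); II, flat with a dip at one week post
  transfer (-0.4, -0.2, 0.1, -2.2, 0.4); III, sustained increase
  (0.4, 0.7, 1.0, 1.3, 1.5).  These are stylizations of the published
  cluster tables at typical magnitudes.  The configuration validator
  enforces: I monotone non-increasing and at least -1 by T6; II minimum at
  T5 and $|\mathrm{lfc}| \ge 1$ at T5 only; III reaching +1.  The
  published Cluster I shows a small T5 rebound that the monotonicity
  constraint deliberately smooths away.
* **Counts**: NB with shared dispersion 0.05 (per-feature dispersion in
  real data is simplified to one value for testability); T1 baselines
  log-uniform in [100, 1000] — the floor keeps archetype-I miRNAs above
  the expressed filter at T6 ($100 \cdot 2^{-2.2} \approx 22 > 10$);
  per-sample size factors log-uniform in [0.5, 2] so normalization
  genuinely matters (real library sizes vary more than 3-fold).
* **mRNA branch**: 600 genes; 11 and 70 genes anti-correlated to
  archetypes I and III (the published group A/B sizes); a planted gene's
  log2 intensity is baseline $- 0.8 \cdot$ (archetype mean profile) plus
  Gaussian noise, SD 0.25 on the log2 scale (no noise model is published;
  0.25 is a typical one-color array residual SD).  The generator refuses
  noise levels at which the expected planted correlation
  $g\,\mathrm{sd}(\mu) / \sqrt{g^2 \mathrm{var}(\mu) + 2\sigma^2/m}$ drops
  below 0.67, since the planted truth would be unrecoverable by
  construction.
* **3'UTRs**: 200-400 nt; each of 42 planted (miRNA, gene) pairs (6 to
  archetype-I genes, 36 to archetype-III genes, one site per gene) embeds
  the full reverse complement of the miRNA, and the construction verifies
  the duplex scores at least 4 kcal/mol below the -18 threshold.  All
  other UTRs are decoys, rejection-sampled to contain no seed complement
  of any planted miRNA.
* **Reads**: mature sequence + the library's 3' adapter + random bases,
  75 nt, constant Q40; 5% contaminants with post-trim lengths outside
  18-25 nt.  With zero contaminants, quantification reproduces the
  simulated count matrix exactly (a round-trip identity the suite
  asserts).

What the generator does *not* emulate — hence what passing tests do not
show about real data: sequencing errors and quality degradation, isomiR
heterogeneity, per-feature dispersion, probe-level microarray artifacts
and their normalization, paralogous multi-mapping structure beyond
identical-sequence collisions, genuinely correlated null genes, and real
salmon sequence composition.  Recovery rates on synthetic data are
construction-validity checks, not field performance estimates.

# Numerical and engineering choices

* Determinism: every generator function reseeds locally from the
  configuration seed (offsets +1 to +5 per stage), so identical
  configurations give bit-identical outputs and `run_pipeline()` writes
  byte-identical summaries.
* Adapter matching is exact (leftmost full occurrence, or an adapter
  prefix of at least 3 nt running to the read end); synthetic reads are
  error-free, and real-data users should pre-trim with an error-tolerant
  tool if needed.
* Mapping is bounded-mismatch (default 0) end-to-end comparison against
  the mature reference — appropriate because references are short
  (16-30 nt) and reads are size-matched; multimappers are discarded, so no
  tie-breaking exists.  A spliced genomic aligner is out of scope.
* Degenerate inputs: all-zero count features get $p = 1$ and zero fold
  change, flagged; zero-variance expression rows get $p \in \{0, 1\}$ by
  mean equality; constant fold-change profiles are an error in the
  distance stage (rank correlation undefined) and `NA` with a warning in
  the gene-correlation stage; families with zero counts get no
  major-expressed flag, with a warning.
* Problem sizes in the shipped tests: the full default configuration
  (about 2.8 million reads) runs end-to-end in about a minute; oracle
  comparisons use windows up to 12 nt (duplex), n up to 8 (linkage), and
  N up to 12 (hypergeometric enumeration), where exhaustive enumeration
  is exact and fast.

# Known limitations

The NB test is a simplified Wald test, slightly anticonservative at n = 8
(empirical size about 0.055 at nominal 0.05); no independent filtering,
covariates, or outlier handling.  Duplex energies ignore target-site
accessibility (no intramolecular folding) and 3'-supplementary scoring.
The gap statistic's one-SE rule is unstable between k = 3 and k = 4 on
tightly estimated profiles (see above).  Cross-species ortholog mapping
for enrichment is user-supplied, not implemented.
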