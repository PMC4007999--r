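---
title: "Single-dose marker mapping and chromosome pairing in autopolyploids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-dose marker mapping and chromosome pairing in autopolyploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdmap)
```

## The problem

Highly polyploid crops such as sugarcane (modern cultivars carry roughly
100--120 chromosomes in 8 homology groups, with unequal homologue counts per
group) cannot be mapped with the codominant machinery built for diploids.
The workable strategy is the pseudo-testcross with **single-dose (SD)
markers**: dominant presence/absence markers carried on exactly one
homologue of the informative parent and absent from the other parent. An SD
marker segregates 1:1 in the F1 regardless of ploidy, so two-point linkage
between SD markers in coupling behaves exactly like a diploid testcross.
Each resulting linkage group (LG) represents (part of) one homologue, not
one basic chromosome; LGs are then stitched into **homology groups (HGs)**
using multi-allelic anchor loci (SSR/SNP/RFLP sources whose distinct
alleles map to different homologous LGs). Finally, repulsion-phase linkage
between LGs of one HG is a signature of **preferential pairing**
(partial disomy) among the underlying homologues, because under fully
polysomic inheritance repulsion between single-dose markers is almost
undetectable at realistic population sizes.

`sdmap` implements this whole chain, plus a forward simulator of polysomic
meiosis so that every stage can be validated against known truth.

## Dosage classification

For even ploidy $m$, random chromosomal segregation transmits $m/2$ of the
$m$ homologues to a gamete, so a marker present on $k$ homologues is absent
from a progeny individual with probability
$\binom{m-k}{m/2} / \binom{m}{m/2}$. At $m = 8$ the expected
present:absent ratios are 1:1 (single dose), 55:15 (double dose, DD) and
65:5 (triple dose, TD). `classify_dosage()` tests the observed counts
against each ratio with 1-df chi-square statistics:

* `SD` when the 1:1 test is non-significant at `alpha` (default 0.05);
* `SD_skewed` when 1:1 is rejected but the 1:1 statistic is still strictly
  smaller than the statistic against the DD ratio --- this keeps markers
  with moderate segregation distortion (common in plants, and pervasive in
  wide crosses) while excluding likely double-dose markers;
* `DD`/`TD` when the corresponding statistic is minimal and
  non-significant;
* `unclassified` otherwise.

The classical 3:1 ratio of markers segregating from both parents is
reported (`chi2_3to1`) but competes only for markers flagged bi-parental:
at $n \approx 227$ progeny the 3:1 and octoploid DD (3.67:1) expectations
differ by less than one standard error, so letting 3:1 compete would
arbitrarily relabel true DD markers. Bi-parental markers are excluded from
SD mapping either way.

Note one consequence of the chi-square gate: by construction about
$\alpha$ of true SD markers are pushed out of the plain `SD` class (almost
all into `SD_skewed`), and about $\alpha$ of true DD markers land in
`unclassified`. What matters for mapping is the SD-vs-rest discrimination
--- whether a marker enters the SD set --- and that is the quantity our
validation measures (it exceeds 99% at $n = 227$, ploidy 8).

## Two-point linkage and map construction

With $R$ discordant calls among $n$ progeny informative for both markers,

$$\hat r = \min(R/n,\ 0.5), \qquad
\mathrm{LOD} = R\log_{10}\hat r + (n-R)\log_{10}(1-\hat r) +
n\log_{10} 2,$$

with the $\hat r = 0$ limit handled exactly ($\mathrm{LOD} = n\log_{10}2$).
Markers join a group when $\mathrm{LOD} \ge 10$ and $\hat r \le 0.35$
(both inclusive; single-linkage transitive closure). Distances are Haldane
($d = -50\ln(1-2r)$ cM), consistent with the simulator's no-interference
crossover model.

Ordering within a group minimises the **sum of adjacent recombination
fractions (SARF)**: greedy path construction seeded at the closest pair,
refined by 2-opt segment reversals, with deterministic lexicographic
tie-breaks and a canonical orientation (lexicographically smaller terminal
marker first). On groups small enough for exhaustive search the greedy +
2-opt order attains the exhaustive SARF optimum in well over 95% of
simulated replicates, and the implementation is fully reproducible, which
is why it was chosen over stochastic or proprietary ordering methods.

`two_stage_build()` mirrors the two-stage practice for panels scored at
different depths: markers scored on at least `framework_min_scored`
progeny (default 188 of 227) build the framework; remaining markers (for
instance those scored on a reduced 94-progeny panel) are inserted one at a
time at the LG and slot minimising the SARF increase. Insertion is
sequential into the evolving order --- the framework order itself is never
revisited --- so two partial markers falling into the same framework slot
get a well-defined relative position. Markers with no framework linkage at
the grouping thresholds stay unplaced.

## Homology-group assembly

`anchor_families()` collects locus families with at least two mapped
alleles on distinct LGs; `assemble_hgs()` joins two LGs when they share at
least `min_shared = 2` **distinct families** and takes connected
components. Two distinct families (rather than two alleles of one family)
are required because multi-locus families --- a fifth to a quarter of SSR
sources in published sugarcane panels map to more than one HG --- would
otherwise bridge unrelated groups. Component semantics (a chain of
pairwise-supported links) is used rather than requiring pairwise support
between every member pair; components held together by a single
articulation LG are flagged with a message so the user can inspect them.
Sequence-similarity evidence and repulsion evidence are reported alongside
but never merge components automatically.

## Repulsion and the difference ratio

`invert_matrix()` swaps present/absent (missing preserved); a two-point
scan of original against inverted markers turns repulsion into coupling,
so the same estimator applies. A supporting marker pair needs
$\mathrm{LOD} \ge 5$ (inclusive); an LG pair is accepted as being in
repulsion only when at least 3 supporting pairs span at least 30% of each
LG's length, because artefactual repulsion tends to involve isolated
marker pairs. Both knobs are exposed (`repulsion_min_pairs`,
`repulsion_min_span`); the 3-pair/30% quantification is this package's
operationalisation of "large parts of the LG involved".

The **difference ratio** compares interval structure between homologous
LGs. With $LG_{max,k}$ the length of the $k$-th shared marker interval on
the most densely mapped LG of the HG and $LG_{ik}$ the matching interval
on a compared LG,

$$\mathrm{ratio} = \frac{\sum_k |LG_{max,k} - LG_{ik}|}
{LG_{max} + LG_i},$$

where the denominator is the summed shared-interval length on both LGs.
It is 0 for identical interval structure and at most 1. Shared markers are
alleles of the same locus family (homologous LGs never share an SD
marker), taken in reference order; because LG orientation is arbitrary,
the compared LG is flipped when its shared markers run predominantly
opposite to the reference (Spearman correlation < 0; for a single pair of
shared markers, a negative interval). Residual order conflicts are skipped
with a message. Values are kept at full precision internally and rounded
to one decimal only in written reports.

`pairing_summary()` reports, per HG, the percentage of member LGs in
accepted repulsion and the mean difference ratio, and the least-squares
$R^2$ between the two across HGs (requires at least 3 HGs with both
statistics).

## The simulator

`generate_population()` is a forward simulator of the cross the package
targets: an aneu-polyploid informative parent (default 8 HGs, 13--23
homologues each, drawn once per parent) crossed to a parent contributing
no segregating alleles, default 227 progeny. Markers are placed uniformly
on homologues (or at user-fixed positions for controlled designs) with a
configurable SD/DD/TD mix; defaults (0.79/0.155/0.055) follow the dosage
composition reported for a large sugarcane mapping panel. Anchor families
place SD alleles at a homologous position on several homologues of one HG
and occasionally (rate 0.2, matching the observed multi-locus SSR
fraction) one allele in a second HG.

Meiosis per HG: homologues are paired into bivalents uniformly at random,
or within `partner_sets` with probability `pairing_preference` (0 = fully
polysomic, 1 with pair-sized sets = strict disomy). An odd homologue count
under random pairing leaves one homologue unpaired (dropped) at random,
mimicking aneuploid meiosis; partner sets must have even sizes. Each
bivalent transmits one chromatid whose crossover switch points follow a
Poisson process at 1 per 100 cM, uniformly placed, no interference --- so
recombination fractions obey the Haldane map function by construction, and
random pairing plus random chromatid choice makes the transmitted
homologue subset uniform over all $\binom{m}{m/2}$ subsets, reproducing
the combinatorial dosage ratios above.

The observation model masks a configurable fraction of markers outside a
reduced progeny panel (default panel 94, fraction 0.14 --- the approximate
share of markers scored only on the reduced panel in the emulated study)
and adds 2% random missingness. Random streams are per stage (parent:
`seed`; meiosis: `seed + 1`; missingness: `seed + 2`), so each stage is
independently reproducible and a fixed seed reproduces the matrix bit for
bit.

What the simulator does **not** model: sequence-level variation or
hybridisation intensities, interspecific mosaic (translocated/fused)
chromosomes, crossover interference, genotyping error beyond missingness,
and selfed 3:1 designs. Passing recovery tests on simulated data therefore
demonstrates correctness of the estimators under polysomic/preferential
pairing with dominant markers --- not robustness to structural
rearrangement or scoring error in real panels.

## Validation conditions and problem sizes

The test-suite and the acceptance script `scripts/acceptance.R` use these
study-condition checks (sizes chosen to keep each suite comfortably inside
a few minutes on one CPU while retaining statistical power):

* dosage discrimination: 1000 SD + 1000 DD markers, $n = 227$, ploidy 8;
  SD-vs-DD discrimination must reach 95% (observed: >99%);
* recombination fraction: 300 replicates of a disomic two-marker design at
  true $r = 0.2$, $n = 227$; the mean estimate must sit within 3 standard
  errors of 0.2;
* LG recovery: 100 replicates of an 8-HG genome (2 homologues per HG, 10
  markers per homologue at 10 cM spacing); the grouped LG count must equal
  the simulated homologue count in at least 95% of replicates;
* HG assembly: 8 HGs x 4 homologues with 6 anchor families per HG on all
  homologues; at least 95% of LGs assigned, at least 95% correctly;
* pairing: strict-disomic octoploid (partner sets of two) must yield
  accepted repulsion links exactly between true partners; the fully
  polysomic octoploid control must yield (on average over replicates)
  essentially none --- at $n = 227$ the polysomic repulsion LOD
  concentrates around 1, far below the threshold of 5.

## Numerical choices and edge cases

* Thresholds are inclusive throughout (LOD >= 10, rf <= 0.35, repulsion
  LOD >= 5); quality filtering is strict in Q (> 80) and inclusive in call
  rate (>= 0.8).
* Missing data: all chi-square counts and pairwise estimates use complete
  cases; pairs below `min_informative = 30` shared progeny are excluded
  rather than down-weighted; duplicate markers additionally need >= 50
  shared non-missing progeny before being merged, to avoid spurious
  merges between disjoint reduced panels.
* $\hat r \ge 0.5$ has no Haldane distance; in ordering, missing pairwise
  estimates enter the SARF objective as 0.49999 so they are maximally
  discouraged without becoming infinite.
* Zero segregation counts raise errors in classification but yield an
  infinite, significant skew in `skew_statistic()` (a scoring report must
  not die on a monomorphic row).
* Ties everywhere (ordering seeds, insertion slots, representatives of
  duplicate clusters, HG numbering) are broken lexicographically so that
  every result is reproducible to the byte.

## Known limitations

Multipoint likelihood ordering and integrated bi-parental maps are out of
scope; ordering quality on sparse or short LGs is limited by two-point
information. HG assembly uses anchor families only --- sequence-based
placement is not automated. The difference ratio compares each LG only to
its HG reference, following the published convention; it is not a metric
between arbitrary LG pairs. Repulsion acceptance (3 pairs / 30% span) is a
pragmatic rule, not an inference procedure with controlled error rates;
treat per-HG repulsion percentages as descriptive.
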