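---
title: "Classifying modes of evolution from paired polyp and cancer somatic profiles"
author: "moeinfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying modes of evolution from paired polyp and cancer somatic profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moeinfer)
```

## The problem

A colorectal cancer resected together with its contiguous residual polyp
of origin provides a rare snapshot of the pre-cancer time course: the
polyp stands in for the cancer's ancestral population. Comparing the
somatic SNVs and copy-number aberrations (CNAs) of the two compartments
lets one ask *how* the cancer evolved out of the polyp. Four archetypal
modes of evolution (MOE) are distinguished:

* **Stepwise (S)** — gradual accumulation with selection: most SNVs are
  shared, each compartment also carries a sizable private set, and the
  selected cancer-private lineage is swept almost to clonality.
* **Parallel (P)** — early branching: polyp and cancer evolve
  independently, so the majority of SNVs are private, and each private
  set is clonal *within its own compartment*.
* **Neutral (N)** — no selection: essentially everything is shared, and
  subclonal mutations form a 1/f tail rather than discrete clusters.
* **Eruptive (E)** — an early burst ("Big Bang") followed by stasis:
  a very large shared fraction including early subclonal families in
  both compartments, a sizable polyp-private set, almost no
  cancer-private SNVs, and aneuploidies already present in the polyp.

`moeinfer` turns the published qualitative rule set for these modes into
a tested, reusable pipeline, and ships a seeded clonal-evolution
simulator so that the full classifier can be exercised end to end with
no access to patient data.

## The five rules and the majority vote

Each rule maps a feature of the case to the subset of modes compatible
with it; the final call is the set of modes with the maximum tally over
the applicable rules (`majority_vote()`). Ties are reported as sets
(e.g. `S,P`), mirroring how genuinely ambiguous cases are reported.

| rule | feature | S | P | N | E |
|------|---------|---|---|---|---|
| 1 | private/shared fractions | cancer ≥ 10%, polyp ≥ 10%, shared ≥ 40% | either private side ≥ 50% | both private sides < 5% | cancer < 5%, polyp ≥ 10%, shared ≥ 80% |
| 2 | AF gap in polyp / in cancer | yes/yes | yes/yes | no/no | no/yes |
| 3 | private cluster position vs shared | polyp lower | both equal | no privates | both lower |
| 4 | early vs late shared distinguishable | yes | yes | no | no |
| 5 | numerous aneuploidies start in | cancer | cancer | any (drift) | polyp |

Notes on the encoding:

* Rule 1's stepwise condition is read as cancer-specific **and**
  polyp-specific ≥ 10% (the published table repeats "cancer specific"
  twice, an apparent typo).
* Rule 2's eruptive direction follows the published table (`no/yes`:
  no polyp gap, cancer gap). The accompanying narrative text describes
  the opposite direction; both are available via
  `moe_config(rule2_convention = "narrative")`. A polyp-only gap matches
  no mode under the default convention — exactly the pattern of the two
  cohort cases suspected of independent polyp/cancer origins.
* Rule 5 calls a sample aneuploid when more than 10% of its autosomal
  genome is altered. Because drift can fix aneuploidies at any time
  under neutrality, every aneuploid configuration keeps the neutral
  vote. A polyp fraction within ±0.02 of the threshold is treated as
  ambiguous timing and the rule abstains — this reproduces the one
  published cell that reads "n,e or s,p,n".
* Removing a rule can only remove tally mass, never add a mode
  (monotonicity; tested).

```{r table2, eval = FALSE}
classify_table2()   # re-derives all 13 published conclusions
moe_frequencies()   # 70% S/P(+tie), 1 eruptive, 3 neutral
```

## From allele fractions to rule inputs

**Partition.** An SNV is *detected* in a sample when its allele fraction
(AF) is at or above the detection limit (default 0.05, the approximate
limit of a standard calling pipeline at this depth). SNVs detected in
both compartments are shared; all fractions are over the union
(`partition_snvs()`). SNVs detected in one compartment are routinely
re-quantified below the limit in the other; they count as shared only
when they reach the limit in both — a documented convention.

**Clustering and gaps.** The rules speak of visually evident clusters
and gaps, which `cluster_afs()` operationalizes as: a Gaussian kernel
density (bandwidth 0.03 on the AF scale), clusters = maximal regions
where the density reaches at least 10% of its global maximum, regions
closer than the minimum gap width (0.08) merged, clusters holding less
than 5% of the SNVs discarded. `has_gap` is then simply "two or more
clusters", and every reported gap is at least 0.08 wide — merging before
weighing keeps the flag and the gap list consistent. With fewer than 20
values the distribution is *not assessable* (`has_gap = NA`) and
downstream rules abstain rather than guess.

**Which AFs feed rule 2.** The gap patterns of the four modes are
defined on the joint 2-D distribution of *all* somatic SNVs of a case:
on the polyp axis, cancer-private SNVs contribute mass near zero, and it
is the interval between that mass and the detected clusters that forms
the characteristic gaps (a stepwise cancer axis shows two gaps: absent
polyp-private SNVs near 0, the swept cancer-private cluster, the clonal
cluster). `classify_case()` therefore evaluates rule 2 on the union AF
vector per axis with the density support starting at 0, while rules 3
and 4 and the purity estimate use detected-only AFs on
[detection limit, 1]. Without the near-zero mass, a parallel case —
whose private clusters sit *at* the shared AF within their own
compartment — could never show the gap/gap pattern the rules assign it.

**Relative position and purity.** Rule 3 compares the weight-dominant
private modal AF against the weight-dominant shared modal AF with a
tolerance `delta = 0.10` (the scale of a bandwidth-broadened cluster).
Sample purity rescales all AFs of a compartment together, so the
relative position is purity invariant (tested). Purity itself is
estimated as twice the modal AF of the highest-AF shared cluster,
capped at 1 — on a neutral case with a heavy subclonal tail the single
merged cluster can place its mode below the clonal peak, so the
estimate is meaningful mainly where a discrete clonal cluster exists.
A private side with fewer than 20 detected SNVs has no assessable
cluster and counts as "no private mutations" for rule 3; large cohorts
with thousands of SNVs still get a position for a 3% private fraction.

**Independent origin.** If the cancer grew from the sampled polyp,
drivers clonal in the polyp should persist. A driver with polyp AF
≥ 0.25 whose cancer AF falls below half its polyp AF (or that is
undetected in cancer) raises the independent-origin flag; flagged cases
are classified from rules 1 and 5 only, at low confidence, because the
AF-shape rules presuppose a common clonal origin. Confidence is also
low whenever fewer than three rules were applicable.

## The synthetic-data generator

`build_scenario()` fixes the study conditions; `simulate_case()` draws a
case deterministically from a scenario (including its seed). The
defaults are the package's chosen study conditions:

| parameter | default | rationale |
|-----------|---------|-----------|
| depth | 60× (Poisson per site, ≥ 1 read) | whole-genome runs targeting at least 30× typically land at 30–60×; 60 is a representative mean |
| purity polyp / cancer | 0.70 / 0.80 | macrodissected compartments; pathology reviews in such cohorts report 60–80% tumor density |
| detection limit | 0.05 AF | the approximate pipeline detection limit |
| SNVs per case | ~2000 | enough for stable kernel densities while keeping 200-case suites fast |
| CNA events | 4 whole-chromosome or arm-scale | "numerous aneuploidies" at the scale visible in genome-wide profiles |
| S fractions (shared/polyp/cancer) | 0.55 / 0.20 / 0.25 | rule-1 stepwise condition with margin |
| P fractions | 0.20 / 0.275 / 0.525 | private majority |
| N fractions | 0.985 / 0.0075 / 0.0075 | both private sides well under 5% |
| E fractions | 0.85 / 0.12 / 0.03 | the eruptive rule-1 condition exactly |

The observation model is: expected AF = purity × CCF / 2 (heterozygous
diploid), site depth Poisson, variant reads binomial, undetected when
the observed AF falls below the limit. Raw sub-limit AFs are kept,
mirroring re-quantification of known sites.

Archetype cell-fraction layouts (cancer-cell fractions, CCF):

* **S** — clonal trunk (CCF 1/1, 70% of shared) plus a sweep lineage
  (0.25 in polyp, 1 in cancer, 30% of shared); polyp-private at 0.25;
  cancer-private at 0.25 + `selection_shift`. The default shift 0.6
  places the selected cluster at CCF 0.85 so its AF essentially
  coincides with the clonal cluster — the defining stepwise signature
  of strong selection; rule 3 then reads the cancer side as *equal*.
* **P** — clonal trunk; both private sets clonal (CCF 1) within their
  own compartment and absent (0) from the other.
* **N** — 30% of shared clonal, 70% in a 1/f² tail on [0.15, 0.5]
  (half scale; CCF = 2f). The support and weight are chosen so the tail
  stays above the detection limit at the default purities and blends
  into the clonal cluster, producing the characteristic gap-free
  distribution; a lower bound near the detection limit would instead
  manufacture spurious private SNVs from borderline detections.
* **E** — 40% of shared clonal plus three early subclonal families at
  CCF 0.75/0.55/0.40 in the polyp that drift upward to 0.90/0.80/0.70
  in the cancer, giving a gap-free polyp continuum and a compact
  near-clonal cancer cluster; privates at CCF 0.25.

Aneuploidy timing defaults follow the modes (S, P: cancer; E: polyp;
N: random), and every simulated SNV carries a trinucleotide context
drawn from a mixture of three built-in toy spectra (flat;
C>T-at-NpCpG-enriched "deamination-like"; C>T/C>A-mixed "MMR-like").
These are invented stand-ins so the package ships no third-party
signature data; real signature matrices can be supplied to
`match_signatures()` as a 96-row matrix.

What the generator deliberately does **not** emulate: read-level errors
(no FASTQ/BAM), AF adjustment of SNVs overlapping CNAs (large aberrations
are argued not to change the distribution's shape, and most of the
genome is balanced), genome doubling, mutation-rate differences between
cases, and multi-region sampling. Passing the recovery suite therefore
shows that the rules separate the archetypes under purity scaling,
finite-depth binomial noise and a detection limit — not that they are
robust to every artifact of real tumor data.

```{r recovery, eval = FALSE}
call <- classify_case(simulate_case(build_scenario("E", seed = 1)))
call$final   # "E"
```

At the default conditions, stepwise cases occasionally return the tie
`S,E`: with no polyp gap resolvable at 60× depth and 0.7 purity, rule 2
reads the case as eruptive under the table convention — the same
ambiguity the published narrative concedes for stepwise adenomas, whose
gap may be faint or absent at realistic depth. At noiseless settings
(purity 1, depth 10⁶) every archetype maps to its exact single label
(tested).

## CNA similarity, recurrence, clustering

Raw segment tables are genotype-filtered (`genotype_filter()`): matched
normal copy number strictly within (1.75, 2.25), tumor–normal
difference > 0.2, chromosomes X and Y excluded; coordinates are 0-based
half-open with 1-based input converted at the reader.

The per-chromosome similarity of two profiles is the Jaccard-style
score: common duplications plus common deletions over the union of all
aberrant regions (cross-state overlap counts only toward the
denominator), 0 when neither sample has events. The genome-wide metric
M sums the 22 autosomal scores, so M ∈ [0, 22]. The implementation uses
IRanges interval arithmetic and is tested to 1e-12 against an
independent per-bin bitmap oracle.

`recurrence_test()` asks which chromosomes carry significantly
recurrent aberrations: for each autosome, the paired observation is the
per-chromosome score minus the mean score over the other autosomes, and
a one-sided Wilcoxon signed-rank test is applied. The published method
does not state the paired unit; the default pairs are sample pairs
(the unit on which the similarity score is defined), with a per-sample
altered-fraction variant behind `unit = "sample"`. Raw p-values are
primary, Benjamini–Hochberg values advisory. All-zero differences give
p = 1 with a note rather than an error.

UPGMA clustering (`upgma_cluster()`) delegates to
`stats::hclust(method = "average")`; similarities are converted to
distances by `d = max(s) − s` (monotone, parameter-free). Equal-distance
ties follow hclust's stable lowest-index order; merge heights are tested
against a hand-rolled average-linkage oracle.

## Mutation spectra

The 96 channels are ordered lexicographically by substitution class
(C>A, C>G, C>T, T>A, T>C, T>G; pyrimidine reference) × 5′ base × 3′
base, so channel 1 is `A[C>A]A`. Purine-reference variants are
reverse-complemented before lookup; the mapping is exhaustively tested
over all 192 raw combinations. Cancer spectra subtract polyp-detected
SNVs to obtain compartment-specific mutations; with fewer than 50 of
those, the spectrum falls back to all SNVs of the sample and is flagged
(the asterisk convention of the original figure). Spectra are compared
by Pearson correlation — scale invariant, so proportions are canonical
even though counts give identical values — and clustered by UPGMA on
d = 1 − r. Signature matching uses cosine similarity, the field
convention, since the original matching criterion is unstated.

## Numerical and degenerate-input conventions

* All seeded helpers restore the caller's RNG state, so
  `simulate_case()` is reproducible regardless of surrounding code.
* `cluster_afs()` clamps AFs to [0, 1] and evaluates the density on a
  512-point grid; modes are grid arguments of the density maximum.
* Zero-variance spectra yield `NA` correlations with a warning;
  empty driver sets yield `flag = FALSE` with empty evidence; an SNV
  table in which nothing is detected is an error, not a silent call.
* `majority_vote()` returns `"unclassifiable"` when no rule is
  applicable or every applicable rule matches no mode.
* Malformed CNA segment rows are dropped row-wise with a message;
  a malformed file is an error.

## Problem sizes used by the test suite

The shipped suite simulates 50 cases per mode (seeds 1–200) for the
recovery check, 8 noiseless cases per mode, 10,000 draws for the 1/f
law, 200 random profile pairs for the metric oracle, and the full
13-case published vote fixture; these sizes were chosen to give stable
statistics while keeping a complete run around a minute on one core.

## Known limitations

* The rules are qualitative by design; no probabilistic MOE model is
  provided (the original work names that as future work).
* Purity estimation assumes a discrete clonal cluster and no
  mutation-copy-number deconvolution is attempted; CNA-overlapping SNVs
  are not AF-adjusted.
* Rule 2's eruptive direction is genuinely ambiguous in the source
  material; both conventions are implemented, and the table reading is
  the default.
* For multi-stage cases (tubular + villous + cancer) the rules operate
  on the most advanced polyp stage by default; which stage fed the
  original 2-D plots is not stated in the source material.
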