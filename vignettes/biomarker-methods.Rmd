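---
title: "Methods: multi-omic PARPi-response biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omic PARPi-response biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoparp)
```

## The problem

Germline *BRCA1/2* carriers with breast cancer can respond dramatically
to single-agent PARP inhibition, but a substantial fraction of tumors
are intrinsically resistant. In an all-carrier neoadjuvant cohort the
classical homologous-recombination-deficiency (HRD) readouts — scar
scores, signature-3 exposure, mutation burden — are expected to be high
across the board and therefore uninformative for response. The package
implements that full readout stack anyway (it is the necessary negative
control) and the expression-level biomarkers that do separate
responders: shieldin (SHLD2) loss, hypoxia, and an EMT/stem-cell
program, combined disjunctively into a resistance call. Response is the
residual cancer burden (RCB) after therapy, dichotomized as
sensitive = pCR or RCB-I versus resistant = RCB-II or RCB-III (an
alternative pCR-versus-rest mode is provided).

## Scar scores

All three scores consume ordered allele-specific segments
(1-based inclusive; total = major + minor) and a genome build carrying
chromosome lengths, centromere intervals, and the set of acrocentric
p-arms. Sex chromosomes are retained in profiles but excluded from all
three scores: the wGII definition is explicitly restricted to
chromosomes 1–22, and LST/TAI follow the same restriction for symmetry
since capture designs and allele-specific calls on X are unreliable in
a mixed-sex cohort. Scores are integer counts (LST, TAI) or a fraction
(wGII) and are deterministic and invariant to segment input order.

**Median copy number.** The reference state is the length-weighted
median of total copy number over autosomal segments, taking the *lower*
median when the weight splits exactly in half. This keeps the reference
at an observed copy-number state and makes the flat-profile score
exactly zero.

**wGII.** Per autosome, the fraction of *segmented* length (not full
chromosome length — capture segmentation leaves gaps that carry no
evidence) at a copy number different from the sample median; the score
is the unweighted mean over autosomes present, so long chromosomes do
not dominate.

**LST** (defaults: `min_segment` 10 Mb, `max_gap` 3 Mb, `min_keep`
3 Mb). Processing order per chromosome: merge adjacent segments with
identical (major, minor) (absorbing any gap between them), drop
segments shorter than `min_keep` entirely, and re-merge. Dropping
short segments outright — rather than smoothing them into a neighbor —
is the deliberate simplification adopted here; with `drop_before_merge`
the drop can instead precede the first merge. Counting: every segment
≥ 10 Mb with another ≥ 10 Mb segment of different allele profile within
3 Mb counts once, so an isolated transition contributes 2 and a segment
flanked by two qualifying neighbors still contributes 1. The score is
computed per chromosome; a per-arm mode (`per_arm = TRUE`, splitting at
the centromere as the original array-era protocol did) is available
behind a flag.

**TAI.** For each autosome end, the maximal run of consecutive
imbalanced segments (major ≠ minor) anchored at the terminal segment
scores 1 if non-empty and strictly short of the centromere; a run
touching or crossing the centromere scores 0 at both ends. Acrocentric
p-arms (13, 14, 15, 22 on the human builds) are skipped because exome
capture cannot estimate copy number there. Two conventions matter on
capture data and are fixed here: the outermost *segment* is treated as
reaching the telomere (exome segmentation never reaches the literal
chromosome end, so a literal-telomere rule would zero the score), and
no minimum run length is imposed.

Each score has a deliberately naive counterpart (`wgii_naive` expands
the profile position by position; `lst_naive` enumerates all segment
pairs with loop-based merging; `tai_naive` walks inward from each end)
sharing no code with the fast path; the test suite asserts equality on
hundreds of random profiles, and the simulators recompute their planted
truths through the naive path on every call.

## Consensus filtering, TMB and catalogs

The variant filter keeps records with support from at least 2 of the
six-caller panel (MuSE, MuTect, MuTect2, SomaticSniper, Strelka2,
VarScan2 — configurable), depth ≥ 20 reads and VAF ≥ 5%;
nonsynonymous-only by default, with the consequence class taken as an
input annotation (re-deriving it from transcripts is out of scope).
VAF is recomputed as `alt_reads/depth` — callers disagree on VAF
definitions, so the stored column is only sanity-checked (tolerance
0.01) at read time. TMB divides the surviving nonsynonymous count by
the unique capture territory in Mb, computed as the merged-interval
union of the BED (0-based half-open, converted internally to the
1-based inclusive convention used everywhere else).

Mutation catalogs tally SNVs into 96 pyrimidine-centered trinucleotide
channels; purine-reference variants are reverse-complemented into the
pyrimidine frame. The catalog input uses the same filter *without* the
nonsynonymous requirement, since mutational processes act genome-wide.
Channel order is fixed (byte-wise lexicographic of `A[C>A]A`-style
labels) and file output is bit-exact in that order.

## Signature refitting

Exposures are estimated by constrained forward selection on the
96-simplex: normalize the (optionally channel-rescaled) catalog, then
repeatedly add, for the signature whose optimal step most reduces the
squared channel error, that step. The optimal step has a closed form —
the least-squares projection of the residual on the signature profile,
clipped to the remaining weight budget — so the procedure is fully
deterministic, needs no starting point, and its residual is
non-increasing by construction. Iteration stops when the best
achievable improvement falls below 1e-3 (on the squared-error scale of
a normalized catalog); final weights below 0.06 are zeroed and the
survivors rescaled to the pre-discard total, mirroring the discard
convention of widely used refitting tools. Ties in the improvement are
broken by signature name so the fit is invariant to column order. The
exome-to-genome context correction is injected as a user-supplied
96-vector (default all-ones); computing it from reference trinucleotide
frequencies is out of scope.

The bundled reference (`synthetic_signature_reference()`) is a
*synthetic* stand-in: four signatures, each concentrated on six
disjoint channels. Published reference profiles cannot be
redistributed here; the synthetic reference keeps the recovery problem
well-posed (near-orthogonal profiles) while exercising exactly the
same code paths. Recovery tolerances in the tests — ±0.03 on
noise-free mixtures, mean L1 < 0.10 on 2000-mutation multinomial
draws — are calibrated to sampling noise at those catalog sizes, not to
the optimizer.

## Expression: ranking, GSEA, scores

Counts are converted to log2(TPM + 1) (per sample: length-normalized
rates scaled to a million). Between-group ranking uses a per-gene
Welch t statistic on log2 TPM, oriented sensitive-minus-resistant,
with ties broken by gene id. This replaces a count-model Wald
statistic deliberately: dispersion modelling of counts is outside the
package's scope, the downstream preranked test needs only a ranking,
and on the synthetic cohorts the two orderings agree in direction. A
gene with zero variance in both groups gets statistic 0 rather than an
error.

Preranked GSEA uses the classic weighted Kolmogorov–Smirnov running
sum (hits weighted by |statistic|^p with p = 1 by default, misses by
1/(N−|S|)); the enrichment score is the extremum of maximal absolute
deviation, with a tie between the positive and negative extremum
resolved to the positive side. Because the running sum is piecewise
linear and decreasing between hits, the extrema are evaluated only at
hit positions and immediately before them, making each permutation
O(|S| log |S|). The null is `n_perm` seeded gene-label permutations —
the natural null for a preranked list, where sample-level permutation
is not available; NES divides ES by the mean |null ES| of matching
sign, and the nominal p-value is the matching-sign tail with +1
smoothing (so p is never exactly 0 and is conservative at small
`n_perm`). BH adjustment is applied across scored sets; sets smaller
than `min_size` (default 5) in the ranking are skipped. The leading
edge is the in-set genes at or before the peak (positive ES) or at or
after the trough (negative ES). A degenerate set covering the whole
ranking has ES fixed at 1 with an uninformative p of 1, since its
permutation null is a point mass.

Per-sample signature scores are the mean of row-wise z-scored
expression over the set's genes (zero-variance genes contribute 0).
The published analyses do not state their scoring method; the mean
z-score was chosen for transparency — it is monotone in expression,
centered so that "above the cohort average" is exactly score > 0, and
averages away single-gene noise roughly with the square root of the
set size.

## The composite classifier

Per sample, three flags: shieldin loss = copy-number loss over the
SHLD2 locus (segment total CN below the sample's median CN) **and**
SHLD2 expression z-score < −1; hypoxia-high and EMT/stem-high =
signature score above 0 (the cohort mean). The prediction is resistant
iff any flag is true. The score cutoffs are configuration knobs
(`score_cutoff`, `z_cutoff`): the original per-sample "+" calls carry
no numeric thresholds, so the defaults mark "above the cohort
average", and the planted effects in the acceptance cohorts are large
enough to be robust to the exact cutoff. A sample whose SHLD2 locus is
not covered by any segment gets an NA call and is excluded with a
message rather than silently classified.

## What the generators emulate — and what they do not

`simulate_profile` plants LST pairs (two abutting 10–13 Mb segments
with distinct profiles, isolated by > 3 Mb unsegmented gaps so the
neighboring baseline cannot also qualify; 2 LST counts each) and TAI
runs (5 Mb imbalanced terminal segments, below the LST length
threshold so the event types cannot interact; 1 TAI count each) on a
toy build of three 200 Mb chromosomes with centromeres at 90–100 Mb,
one acrocentric — small enough for the brute-force oracles, with all
boundaries on whole megabases so the per-unit expansion is exact.
`simulate_catalog` draws multinomially from a known signature mixture.
`simulate_expression_cohort` adds planted log2 shifts and Gaussian
noise to per-gene baselines; `simulate_variant_table` draws caller
support binomially, depth Poisson, VAF Beta.

`simulate_cohort` composes all of these under the disjunctive truth
model at the study's shape (n = 13, 7 sensitive : 6 resistant): every
resistant sample gets at least one mechanism (each drawn with
probability 0.5, forced to ≥ 1), shieldin loss capped at 3 per cohort
(the recurrence observed for copy-number loss), sensitive samples get
none. Chosen effect sizes: hypoxia/EMT shifts of 2 log2 units on
30-gene sets with noise SD 0.5 — a strong but realistic pathway
activation, detectable through a 30-gene average with large margin —
and a 5 log2-unit SHLD2 drop in loss samples, i.e. ~32-fold, the deep
loss expected when deletion and transcriptional silencing coincide.
The SHLD2 call rests on a *single* gene's cohort z-score, where
outlier samples inflate the row SD; the 5-unit drop keeps the loss
samples below the z < −1 cutoff with comfortable margin even in the
worst allowed configuration (3 loss samples of 13).

What the generators do **not** emulate: purity/ploidy admixture and
subclonality in copy number; count-level (negative-binomial)
dispersion, library-size and GC effects in expression; inter-gene
correlation within pathways; caller-specific error profiles; indels
and structural variants. Passing tests therefore demonstrate that the
implementations compute their definitions correctly and recover
planted structure at realistic effect sizes — not that the biomarkers
would survive the noise structure of real tumors, which is exactly why
the original cohort's controlled-access data cannot be replaced by
simulation for scientific claims.

## Numerical conventions and degenerate inputs

- Coordinates 1-based inclusive internally; BED parsed as 0-based
  half-open and converted on read.
- Lower length-weighted median for the copy-number reference.
- LST order of operations: merge, drop, re-merge (the alternative
  drop-first order is exposed as `drop_before_merge`).
- ER status: any nonzero ER staining counts as ER-positive, including
  weak partial positivity ("ER 5% weak") — required for the cohort's
  2/10 ER-positive rate among g*BRCA1* carriers to reproduce.
- GSEA: ES sign ties resolve positive; +1-smoothed permutation
  p-values; gene-id tie-breaks everywhere a sort occurs.
- Refit: improvement tolerance 1e-3, discard cutoff 0.06, iteration
  cap 500 (never reached in practice).
- Degenerate cases: empty catalogs, empty autosomal profiles,
  zero-variance genes, uncovered loci, and groups of fewer than two
  samples all raise informative errors or documented neutral values
  (statistic 0, score 0, NA call) rather than propagating NaNs.
- All stochastic entry points take an explicit integer seed and reset
  the generator kind, so results are byte-identical across sessions.

## Problem sizes

The shipped tests and the reproduction script use: 200 random profiles
per oracle-equivalence sweep (plus 200 small-genome profiles for the
per-base wGII oracle), 50 multinomial catalogs of 2000 mutations for
refit recovery, 20 simulated cohorts of 13 samples for the classifier
and for GSEA power (1000 genes, 1000 permutations), 50 random sets for
p-value calibration, and 5000 variants for the analytic filter check.
These sizes give the property checks comfortable statistical margins
while keeping a full run in the tens of seconds on one core.

## Known limitations

- The scar scores operate on called segments; purity/ploidy correction
  and segmentation quality are upstream concerns the package does not
  revisit.
- Consequence annotation is trusted input; two annotation stacks can
  legitimately disagree on the nonsynonymous set and hence on TMB.
- The refit reference bundled here is synthetic; analyses of real
  catalogs must supply a published reference via `read_signatures()`.
- The permutation GSEA reports p-values no smaller than
  1/(n_perm + 1); very small advertised p-values require raising
  `n_perm` accordingly.
- The composite classifier is a fixed disjunction with cohort-relative
  thresholds; it is a descriptive rule for biomarker exploration, not
  a validated clinical test.
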