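# neoparp

Pre-treatment multi-omic biomarker analysis for germline *BRCA*-mutant
(g*BRCA*+) breast tumors treated with neoadjuvant PARP inhibition.

About half of g*BRCA*+ breast cancer patients treated with single-agent
talazoparib do not reach a pathologic complete response, and classical
homologous-recombination-deficiency (HRD) readouts do not separate
responders from non-responders in an all-carrier cohort. This package
implements the analysis layer for that problem, for bioinformaticians
working with exome-derived allele-specific copy number, somatic variant
calls and bulk RNA-seq:

- **Genomic scar scores** from allele-specific copy-number segments:
  - *wGII*, the weighted genome instability index — per autosome *c*,
    the fraction of segmented length with total copy number differing
    from the sample's length-weighted median copy number, averaged
    without length weighting over chromosomes 1–22;
  - *LST*, large-scale state transitions — after merging identical
    neighbors, dropping segments < 3 Mb outright and re-merging, the
    number of segments ≥ 10 Mb lying within 3 Mb of another ≥ 10 Mb
    segment with a different (major, minor) allele profile;
  - *TAI*, telomeric allelic imbalance — the number of chromosome ends
    whose terminal run of segments has major ≠ minor copy number
    without that run reaching the centromere, skipping the p-arms of
    the acrocentric chromosomes 13, 14, 15 and 22.
- **Consensus variant filtering and TMB**: keep nonsynonymous variants
  supported by ≥ 2 of six callers, ≥ 20 reads and ≥ 5% VAF; TMB is the
  surviving count per megabase of the merged capture target.
- **Mutational-signature refitting**: deterministic constrained forward
  selection of per-sample exposures over a 96-channel reference
  (weights ≥ 0, sum ≤ 1, sub-6% weights discarded), with an optional
  channel-wise exome-to-genome correction vector.
- **Preranked GSEA** with the classic weighted Kolmogorov–Smirnov
  enrichment score, a seeded gene-label permutation null,
  Benjamini–Hochberg adjustment and leading-edge extraction, plus a
  hypergeometric over-representation test.
- **The composite resistance classifier**: a tumor is predicted
  resistant iff it shows shieldin loss (copy-number loss over the
  SHLD2 locus *and* SHLD2 expression z < −1), a high hypoxia
  signature score, or a high EMT/stem-cell signature score.
- **Seeded synthetic generators** for every input — scarred
  allele-specific profiles with known event counts, multinomial
  96-channel catalogs, log-normal expression cohorts with planted
  pathways, multi-caller variant tables, and whole cohorts under the
  disjunctive resistance model — so the entire pipeline is testable
  without the controlled-access study data.

## Worked example

```r
library(neoparp)

# scar scores on a simulated profile with 2 planted LST pairs and
# 1 telomeric imbalance run
build <- load_genome_build("toy")
sim <- simulate_profile(build, n_lst_pairs = 2, n_tai_runs = 1, seed = 7)
scar_scores(sim$profile, build)
#>   sample       wgii lst tai median_total_cn
#> 1    SIM 0.09576427   4   1               2

# signature refitting on a 2000-mutation catalog drawn from a
# 70/30 mixture
sigs <- synthetic_signature_reference()
cat96 <- simulate_catalog(sigs, c(Signature3 = 0.7, Signature5 = 0.3),
                          2000, seed = 7)
refit_exposures(cat96$catalog, sigs)
#> signature_exposure: Signature3=0.715, Signature5=0.285 (residual 0.0280)

# cohort summary of the bundled clinical table (13 analyzed tumors)
rec <- read_cohort(system.file("extdata", "cohort_clinical.tsv",
                               package = "neoparp"))
cohort_summary(rec[rec$analyzed, ])
```

The planted profile scores LST = 4 (2 per planted pair) and TAI = 1,
exactly the planted counts; the refit recovers the mixture within the
multinomial sampling noise; and the cohort summary reports n = 13 with
10 g*BRCA1* carriers, 69% triple-negative, 77% *TP53*-mutant, a median
mutation burden of 2.44/Mb and an RCB mix of pCR 38%, RCB-I 15%,
RCB-II 31%, RCB-III 15%.

A thin command-line wrapper over the same functions is in
`inst/scripts/neoparp-cli.R` (`scars`, `consensus`, `tmb`,
`signatures`, `gsea`, `summarize`, `classify`, `simulate`).

## Package layout

- `R/` — genome builds and file formats (`genome-build.R`, `io.R`),
  scar scores and their naive oracles (`scar-scores.R`, `oracles.R`),
  variant statistics (`variant-stats.R`), signature refitting
  (`signature-refit.R`), expression/GSEA (`expression-enrichment.R`),
  the biomarker model (`biomarker-model.R`), the cohort pipeline
  (`pipeline.R`) and the generators (`synthetic-data.R`).
- `inst/extdata/` — the clinical cohort table and a synthetic
  96-channel signature reference.
- `vignettes/biomarker-methods.Rmd` — the methods vignette: models,
  parameter choices, numerical conventions and limitations.
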