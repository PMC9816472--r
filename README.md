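# dtmr — drug-target Mendelian randomization from GWAS summary statistics

`dtmr` implements a drug-target Mendelian randomization (MR) study as a
reusable, fully tested R pipeline. The scientific question it is built for:
given genetic variants in and around the gene encoding a drug's protein
target, does genetically proxied *inhibition* of that target change the risk
of a disease outcome? The motivating application is TNFR1 (encoded by
*TNFRSF1A* on chromosome 12), whose inhibition is proxied by cis-variants
that lower circulating TNFR1, CRP and white blood cell counts, with
colorectal-cancer risk on the absolute scale as the primary outcome and
inflammatory-bowel-disease / multiple-sclerosis GWAS as positive controls.
It is aimed at genetic epidemiologists who have summary statistics, not
individual-level data.

## What it computes

- **Instrument selection** (`extract_cis_window`, `concordance_filter`,
  `ld_clump`): candidate SNPs within a flanked gene window (e.g. ±15 kb of
  chr12:6,328,757–6,342,114), kept only if they lower *all* configured
  biomarkers at p < 0.05, then greedily pruned to pairwise LD r² ≤ 0.001.
- **Harmonization** (`harmonize_dataset`, `orient_to_inhibition`): exposure
  and outcome effects aligned to one effect allele; strand complements
  resolved for non-palindromic SNPs; palindromic SNPs with effect-allele
  frequency in (0.42, 0.58) — or missing — excluded; everything re-oriented
  so the effect allele is the biomarker-lowering allele.
- **Causal estimation** (`wald_ratio`, `ivw_fixed`, `weighted_median`,
  `mr_egger`, `cochran_q`): per-SNP Wald ratios θ_j = β_yj/β_xj with
  first-order SEs se_yj/|β_xj|; the fixed-effects inverse-variance-weighted
  (IVW) combination θ̂ = Σw_jθ_j/Σw_j, w_j = 1/se_j²; Cochran's Q for
  heterogeneity; a weighted-median sensitivity estimator with a seeded
  parametric-bootstrap SE; and MR-Egger regression whose intercept estimates
  average directional pleiotropy.
- **Colocalization** (`log_abf`, `coloc_posteriors`): Wakefield
  approximate Bayes factors per SNP, enumerated into posterior probabilities
  of the five standard hypotheses (H0 none, H1/H2 one trait, H3 two distinct
  causal variants, H4 one shared variant), all in log space.
- **Simulation** (`simulate_instrument_panel`, `simulate_coloc_region`):
  summary-level generators with known ground truth for every pipeline stage.
- **Orchestration** (`run_drug_target_mr`): one YAML configuration runs the
  whole study and writes `report.json`, `estimates.tsv`,
  `selection_report.tsv`, `exclusions.tsv` and `coloc.json`.

## Worked example

The package ships a fixture generator that writes a complete synthetic
study — a 28-SNP candidate catalog arranged like the motivating analysis —
plus its `study.yaml`:

```r
library(dtmr)
dir <- tempfile("study")
cfg <- write_study_fixture(dir, seed = 1)
report <- run_drug_target_mr(cfg, out_dir = file.path(dir, "out"))
print(report)
```

```
[extract_cis_window] n_in=28 n_out=28 elapsed=0.013s
[concordance_filter] n_in=28 n_out=8 elapsed=0.027s
[ld_clump] n_in=8 n_out=8 elapsed=0.031s
[primary_mr] n_in=8 n_out=7 elapsed=0.111s
[positive_controls] n_in=3 n_out=3 elapsed=0.118s
[coloc] n_in=15 n_out=15 elapsed=0.120s
<study_report> candidates=28 concordant=8 clumped=8 combined=7
primary IVW: theta=0.017957 [0.011414, 0.024499] p=7.49e-08 (n_snps=7)
coloc: PP3=0.0108 PP4=0.041
```

Reading the cascade: of 28 candidate SNPs in the cis window, 15 have
association estimates in the biomarker GWAS, 8 lower all three biomarkers at
p < 0.05, all 8 survive LD clumping, and one (rs4149569, an A/T SNP at
frequency 0.50) is excluded as palindromic with intermediate allele
frequency, leaving 7 combined instruments. The primary IVW estimate 0.0180
(true simulated value 0.021) is the absolute-risk increase per 1-unit
biomarker increase, i.e. a ~1.8% absolute risk reduction per unit of
biomarker lowering; the weighted median agrees (0.0167, p = 8e-4) while
MR-Egger is uninformative (SE 0.61) because the instruments' exposure
effects are nearly constant — the same behaviour reported for small
cis-instrument sets. Both coloc posteriors are small: no evidence that the
exposure and outcome signals share (PP4) or split (PP3) causal variants.

Extrapolation of an absolute risk reduction over a drug-induced biomarker
change is a plain product:

```r
extrapolate_arr(2.1, 16)   # 33.6  (% ARR over a 16 mg/L decrease)
extrapolate_arr(2.1, 13.9) # 29.19
```

A command-line wrapper is installed at
`system.file("cli", "dtmr", package = "dtmr")`:
`dtmr run --config study.yaml --out OUT`, `dtmr fixture --out DIR`,
`dtmr coloc --trait1 a.tsv --trait2 b.tsv`.

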