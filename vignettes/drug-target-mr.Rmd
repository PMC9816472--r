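---
title: "Methods: drug-target MR with dtmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drug-target MR with dtmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtmr)
```

# The model

Drug-target Mendelian randomization treats cis-variants near the gene
encoding a drug's protein target as randomized proxies for pharmacological
modulation of that target. For each instrument SNP $j$ we observe a summary
association with the exposure biomarker, $(\hat\beta_{xj}, se_{xj})$, and
with the outcome, $(\hat\beta_{yj}, se_{yj})$. Under the instrumental-variable
assumptions (relevance, no confounding of the variant–outcome path, no
direct effect on the outcome other than through the exposure) each SNP
identifies the same causal effect $\theta$ through its Wald ratio
$\hat\theta_j = \hat\beta_{yj} / \hat\beta_{xj}$, and the fixed-effects
inverse-variance-weighted (IVW) combination

$$\hat\theta = \frac{\sum_j w_j \hat\theta_j}{\sum_j w_j},
\qquad w_j = se_j^{-2},
\qquad se(\hat\theta) = \Big(\sum_j w_j\Big)^{-1/2}$$

is the efficient pooled estimate when all instruments are valid. Cochran's
$Q = \sum_j w_j(\hat\theta_j - \hat\theta)^2$, referred to
$\chi^2_{J-1}$, flags heterogeneity (a symptom of pleiotropy); the package
treats a significant Q as a logged warning, not a gate. Two sensitivity
estimators relax the validity assumption: the weighted median (consistent
when at least half the instrument weight is valid) and MR-Egger regression
of $\hat\beta_{yj}$ on $\hat\beta_{xj}$ with a free intercept, whose
intercept estimates average directional pleiotropy and whose slope remains
consistent under the InSIDE assumption.

# Instrument selection

Candidates are SNPs inside a flanked gene window (`gene_region`; the
motivating target occupies chr12:6,328,757–6,342,114, GRCh38, with a ±15 kb
flank). Selection then requires tri-biomarker concordance: the SNP must be
present in the protein GWAS and in both downstream-biomarker GWAS, lower
all three (after orienting every table's effect to the candidate's effect
allele), and reach p < 0.05 in all three. The source text is ambiguous
about whether p < 0.05 must hold in all biomarkers or any one; the package
defaults to the strict all-three reading, with `require_all = FALSE` as the
lenient switch. Finally greedy LD clumping (`ld_clump`) sorts by p-value —
ties broken by position then rsid, for determinism — and discards any
remaining SNP with $r^2 > 0.001$ against a kept SNP. The clump ranking uses
the protein GWAS p-values; the LD matrix is supplied (or simulated), never
computed from genotypes.

A deliberate plumbing choice: the candidate list may come from a separate
catalog table (`tables.candidates`), because a realistic cascade includes
SNPs that are absent from *every* biomarker GWAS — those are counted in
`n_with_any_association` (present in ≥ 1 biomarker table) and excluded with
reason `missing`. Without a catalog the exposure table itself is the
candidate source, in which case nothing can be `missing` from it.

# Harmonization and orientation

Exposure and outcome tables are matched on rsid. Outcome alleles equal to
the exposure's are `aligned`; swapped ea/nea flips the sign of
$\hat\beta_y$ and replaces $eaf_y$ by $1-eaf_y$; non-palindromic SNPs
reported on opposite strands are complemented first. A/T and C/G SNPs are
strand-ambiguous: they are excluded whenever either trait's effect-allele
frequency lies in the intermediate band or is missing. The band default
(0.42, 0.58) is the established two-sample MR convention — the source
analysis states the concept but not the band — and is configurable.
Palindromic SNPs *outside* the band are retained at their nominal
orientation; no frequency-based re-stranding is attempted, the simplest
defensible rule. `orient_to_inhibition` then flips each pair so the effect
allele is the biomarker-lowering allele ($\hat\beta_x < 0$); Wald ratios are
invariant under this joint negation, so it only fixes the reporting frame.

# Numerical choices

* **Wald SE order.** The default SE is first-order, $se_{yj}/|\hat\beta_{xj}|$,
  with the second-order delta formula behind `second_order = TRUE`. The
  source does not state which it used; first-order makes the
  Egger-through-origin ≡ IVW identity exact (asserted to 1e-10 in tests),
  at the price of a small weak-instrument attenuation (measured ≈ 4% of
  $\theta$ in the simulator's stated world; see the decisions notes).
* **CI multiplier** 1.959964 (normal) everywhere except Egger, which uses
  $t_{J-2}$.
* **Weighted median.** Ratios sorted ascending, cumulative standardized
  weights $s_j = (\sum_{k\le j} w_k - w_j/2)/\sum w$, linear interpolation
  at $s = 0.5$. The SE is a parametric bootstrap (redraw both betas from
  their reported normals, default 1000 replicates, mandatory seed); the
  source does not describe its SE method at all. `se_method = "none"`
  returns only the point estimate for simulation loops.
* **Egger residual scaling** is multiplicative and floored at 1 — no
  under-dispersion credit — and the design is declared singular when all
  $\hat\beta_x$ are identical.
* **Colocalization** uses Wakefield log-ABFs
  $\tfrac12\log(1-r) + z^2r/2$, $r = W/(V+W)$, with prior effect SD 0.15
  for continuous traits and 0.2 for log-odds traits, priors
  $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ (the cited framework's
  defaults; the source states none). All hypothesis sums run in log space
  via log-sum-exp; the H3 cross-term uses
  $\log(1 - e^{d})$ with $d = \log\sum_j A_{1j}A_{2j} - \log\sum_j A_{1j}
  - \log\sum_k A_{2k}$, clamped when $d \ge 0$. Posteriors renormalize to
  sum to 1 within 1e-12. A single-SNP region forces PP3 = 0 with a warning.
  The two-hypothesis labelling used in some reports maps to PP3 (two
  distinct variants) and PP4 (one shared variant); exports carry both.
* **MR exposure scale.** The spec-level "exposure" is the protein GWAS, but
  effect sizes in the motivating analysis are expressed per unit of the
  CRP-like biomarker; `mr_exposure` in the config selects which biomarker
  table supplies $\hat\beta_x$, and the fixture defaults to the CRP-like
  table. Candidate ranking for clumping still uses the protein table.

# The simulator: what it emulates and what it does not

`simulate_instrument_panel` generates summary statistics only — no
individual genotypes — for four GWAS sharing one SNP panel. Its defaults
are the stated world of the motivating study: sample sizes 21,758
(protein), 204,402 and 172,435 (biomarkers), 377,673 (outcome,
absolute-risk scale); per-SNP true protein effects
$b_j = -|N(0.05, 0.02)|$ (inhibition-signed); biomarker effects
$c_2 b_j, c_3 b_j$ with $c_2 = 0.5, c_3 = 0.3$ (chosen once as a realistic
downstream attenuation; the source gives no values); outcome effects
$\theta b_j + \alpha_j$ with $\alpha_j$ = `pleiotropy_mean` on a seeded
`pleiotropy_frac` subset; sampling SEs $1/\sqrt{2n\,maf(1-maf)}$, the
standardized-continuous-trait form reused for binary outcomes under an
effective-n reading — only relative calibration matters here. Sampling
noise can be AR(1)-correlated across SNPs (`ld_rho`), and a configurable
fraction of SNPs (default 10%) gets palindromic alleles. The robustness
experiments set `pleiotropy_mean = 0.01`, about ten times the median direct
effect $|\theta b_j|$, a deliberately strong contamination.

What the simulator does **not** model: realistic human LD maps, sample
overlap between the GWAS, winner's curse in instrument discovery, and
allele-frequency differences between studies. A green calibration test
therefore establishes correctness of the estimators under the stated noise
model, not robustness to those artefacts.

`simulate_coloc_region` draws marginal z-scores
$z = R\lambda + \mathrm{MVN}(0, R)$ with AR(1) LD $R$ and a single causal
spike $\lambda$, at a nominal $n = 50{,}000$ ($se = n^{-1/2}$); hypothesis
H3 places the two causal variants at the region quartiles so their LD is
negligible at the default $\rho = 0.9$.

# The packaged fixture

`write_study_fixture` arranges a 28-SNP cascade whose pathway is forced by
the selection rules: 13 candidates absent from every biomarker GWAS, 4 with
a wrong-direction biomarker effect, 3 null in the protein GWAS, and 8
concordant — one of them (named rs4149569 after the motivating analysis's
palindromic instrument) an A/T SNP at frequency 0.50, excluded at
harmonization, leaving 7 combined. Effects are deterministic up to a small
seeded jitter whose 4-standard-deviation range cannot cross any selection
boundary, so the cascade is identical for every seed while outputs stay
seed-reproducible; the true outcome effect is 0.021 per biomarker unit.
The fixture's instruments have nearly constant exposure effects, so its
MR-Egger estimate is very imprecise — usefully mirroring the instability of
Egger on small cis-instrument sets.

# Degenerate inputs and tie-breaks

Zero-`beta_x` pairs are excluded (`null-exposure`) before ratio estimation;
`beta_x = 0` in a lone Wald ratio is an error. Clumping ties on p-value
break by position then rsid. `is_intermediate_af(NA)` is `TRUE`
(conservative). Empty stage outputs abort the pipeline with the stage name.
Simulated p-values are floored at 1e-300 so extreme z-scores survive
validation.

# Known limitations

Random-effects IVW, MR-PRESSO (explicitly not performed in the motivating
analysis), mode-based estimators, Steiger filtering, reference-panel LD,
proxy-SNP lookup and multi-causal-variant colocalization are out of scope.
The weak-instrument attenuation of the first-order Wald ratio (~4% of
$\theta$ at the default protein GWAS size) is documented rather than
corrected; the second-order SE switch does not de-bias the point estimate.
Unit interpretation of "per 1 mg/L" effects when the exposure GWAS is
log-transformed is left to the caller — the pipeline reports per-unit
effects on the configured exposure's native scale.
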