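# Synthetic GWAS summary statistics with known ground truth, standing in for
# the external protein / CRP-like / WBC-like / outcome GWAS datasets.

#' Simulation configuration for an instrument panel
#'
#' Defaults emulate the study's stated world: a 21,758-sample protein GWAS,
#' downstream biomarker GWAS of 204,402 (CRP-like) and 172,435 (WBC-like),
#' and a 377,673-sample absolute-risk outcome GWAS.
#'
#' @param n_snps Number of instruments (default 20).
#' @param theta_true Causal effect of the exposure on the outcome per 1-unit
#'   exposure increase (default 0.02, of the order of the reported 2.1%
#'   absolute-risk change per biomarker unit).
#' @param n_exposure,n_biomarker2,n_biomarker3,n_outcome GWAS sample sizes.
#' @param maf_range Uniform sampling range for minor-allele frequency,
#'   within (0, 0.5].
#' @param pleiotropy_frac Fraction of SNPs given a direct (invalid) path to
#'   the outcome.
#' @param pleiotropy_mean Directional pleiotropy effect added to each invalid
#'   SNP's true outcome effect.
#' @param ld_rho AR(1) correlation in [0, 1) shared by the sampling noise of
#'   all traits (0 = independent instruments, the post-clumping situation).
#' @param palindromic_frac Fraction of SNPs drawn with A/T or C/G alleles.
#' @param b_mean,b_sd The per-SNP true exposure effect is
#'   `-|Normal(b_mean, b_sd)|` (inhibition-signed).
#' @param c2,c3 Positive scalings of the exposure effect shared by the second
#'   and third biomarker.
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 20L, theta_true = 0.02,
                       n_exposure = 21758, n_biomarker2 = 204402,
                       n_biomarker3 = 172435, n_outcome = 377673,
                       maf_range = c(0.05, 0.5),
                       pleiotropy_frac = 0, pleiotropy_mean = 0,
                       ld_rho = 0, palindromic_frac = 0.1,
                       b_mean = 0.05, b_sd = 0.02,
                       c2 = 0.5, c3 = 0.3, seed = 1L) {
  stopifnot(n_snps >= 1, pleiotropy_frac >= 0, pleiotropy_frac <= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5, maf_range[1] <= maf_range[2],
            ld_rho >= 0, ld_rho < 1, c2 > 0, c3 > 0,
            palindromic_frac >= 0, palindromic_frac <= 1)
  structure(list(n_snps = as.integer(n_snps), theta_true = theta_true,
                 n_exposure = n_exposure, n_biomarker2 = n_biomarker2,
                 n_biomarker3 = n_biomarker3, n_outcome = n_outcome,
                 maf_range = maf_range, pleiotropy_frac = pleiotropy_frac,
                 pleiotropy_mean = pleiotropy_mean, ld_rho = ld_rho,
                 palindromic_frac = palindromic_frac,
                 b_mean = b_mean, b_sd = b_sd, c2 = c2, c3 = c3,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' GWAS standard error for a standardized continuous trait
#'
#' `se = 1 / sqrt(2 n maf (1 - maf))`. Binary outcomes reuse the same form
#' under an effective-n interpretation; only relative calibration matters for
#' the simulator.
#'
#' @param n Sample size.
#' @param maf Minor-allele frequency.
#' @return Standard error(s).
#' @export
gwas_se <- function(n, maf) 1 / sqrt(2 * n * maf * (1 - maf))

#' Simulate an AR(1) LD matrix
#'
#' Correlation `r_ij = rho^|i-j|`; r2 is the elementwise square. The
#' correlation matrix is positive-definite by construction for `rho` in
#' [0, 1).
#'
#' @param n_snps Number of SNPs (rsids `rs1..rsN`).
#' @param rho AR(1) parameter in [0, 1).
#' @param rsids Optional rsid labels.
#' @return An [ld_matrix()].
#' @export
simulate_ld_matrix <- function(n_snps, rho, rsids = paste0("rs", seq_len(n_snps))) {
  if (!(rho >= 0 && rho < 1)) stop("simulate_ld_matrix: rho must be in [0,1)",
                                   call. = FALSE)
  idx <- seq_len(n_snps)
  r <- rho^abs(outer(idx, idx, "-"))
  ld_matrix(rsids, r^2)
}

#' @noRd
ar1_chol <- function(n, rho) {
  idx <- seq_len(n)
  chol(rho^abs(outer(idx, idx, "-")))
}

# Draw allele pairs; a palindromic_frac subset gets A/T or C/G.
#' @noRd
draw_alleles <- function(n, palindromic_frac) {
  pal <- stats::runif(n) < palindromic_frac
  pal_pairs <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"), ncol = 2, byrow = TRUE)
  npal_pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                      c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
  ea <- nea <- character(n)
  k <- sample.int(4, n, replace = TRUE)
  m <- sample.int(8, n, replace = TRUE)
  ea[pal] <- pal_pairs[k[pal], 1]; nea[pal] <- pal_pairs[k[pal], 2]
  ea[!pal] <- npal_pairs[m[!pal], 1]; nea[!pal] <- npal_pairs[m[!pal], 2]
  list(ea = ea, nea = nea)
}

#' Simulate a four-GWAS instrument panel with known truth
#'
#' Generates one exposure (protein-like), two downstream biomarker and one
#' outcome GWAS over the same SNPs. Per SNP `j`: true exposure effect
#' `b_j = -|Normal(b_mean, b_sd)|`; biomarker 2/3 true effects `c2 b_j`,
#' `c3 b_j`; true outcome effect `theta_true b_j + alpha_j`, where `alpha_j`
#' equals `pleiotropy_mean` on a seeded random `pleiotropy_frac` subset and 0
#' elsewhere. Observed effects add trait-specific sampling noise with
#' `se = 1/sqrt(2 n maf (1-maf))`, correlated across SNPs by the AR(1)
#' structure when `ld_rho > 0`; p-values come from the normal z-score.
#'
#' @param config A [sim_config()].
#' @return A list with `exposure`, `biomarker2`, `biomarker3`, `outcome`
#'   (all `gwas_table`s sharing rsids, positions and alleles) and `truth`
#'   (`theta_true`, per-SNP `b`, `alpha`, `maf`, and the `invalid` rsid set).
#' @export
simulate_instrument_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_snps
    rsids <- paste0("rs", 1000 + seq_len(n))
    pos <- round(seq(6313757, 6357114, length.out = max(n, 2)))[seq_len(n)]
    maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
    al <- draw_alleles(n, config$palindromic_frac)
    b <- -abs(stats::rnorm(n, config$b_mean, config$b_sd))
    n_invalid <- round(config$pleiotropy_frac * n)
    invalid <- sort(sample.int(n, n_invalid))
    alpha <- numeric(n)
    alpha[invalid] <- config$pleiotropy_mean

    L <- if (config$ld_rho > 0) ar1_chol(n, config$ld_rho) else NULL
    noise <- function() {
      z <- stats::rnorm(n)
      if (is.null(L)) z else drop(crossprod(L, z))
    }
    mk <- function(true_beta, n_gwas, trait, scale) {
      se <- gwas_se(n_gwas, maf)
      beta <- true_beta + se * noise()
      gwas_table(data.frame(rsid = rsids, chrom = "12", pos = pos,
                            ea = al$ea, nea = al$nea, eaf = maf,
                            beta = beta, se = se,
                            pval = pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300),
                            n = n_gwas),
                 trait_name = trait, trait_scale = scale)
    }
    list(exposure = mk(b, config$n_exposure, "protein", "continuous"),
         biomarker2 = mk(config$c2 * b, config$n_biomarker2, "crp_like",
                         "log_continuous"),
         biomarker3 = mk(config$c3 * b, config$n_biomarker3, "wbc_like",
                         "continuous"),
         outcome = mk(config$theta_true * b + alpha, config$n_outcome,
                      "outcome", "absolute_risk"),
         truth = list(theta_true = config$theta_true, b = b, alpha = alpha,
                      maf = maf, invalid = rsids[invalid]))
  })
}

#' Colocalization scenario
#'
#' @param hypothesis One of `"H0".."H4"`: no association, trait-1 only,
#'   trait-2 only, two distinct causal variants, one shared variant.
#' @param n_snps Region size (default 200).
#' @param causal_index_1,causal_index_2 Causal SNP positions for each trait;
#'   defaults place shared causality mid-region (H4) or at the quartiles
#'   (H3). H4 requires equal indices, H3 distinct.
#' @param causal_z Marginal z-score at the causal SNP (default 8).
#' @param ld_rho AR(1) LD correlation (default 0.9).
#' @param n Nominal GWAS sample size setting the constant per-SNP
#'   `se = 1/sqrt(n)` (default 50,000).
#' @param seed Integer seed.
#' @return A list of class `coloc_scenario`.
#' @export
coloc_scenario <- function(hypothesis = c("H4", "H3", "H0", "H1", "H2"),
                           n_snps = 200L, causal_index_1 = NULL,
                           causal_index_2 = NULL, causal_z = 8,
                           ld_rho = 0.9, n = 50000, seed = 1L) {
  hypothesis <- match.arg(hypothesis)
  n_snps <- as.integer(n_snps)
  causal_index_1 <- causal_index_1 %||% switch(hypothesis,
    H0 = NA_integer_, H2 = NA_integer_,
    H3 = max(1L, n_snps %/% 4L),
    as.integer(ceiling(n_snps / 2)))
  causal_index_2 <- causal_index_2 %||% switch(hypothesis,
    H0 = NA_integer_, H1 = NA_integer_,
    H3 = min(n_snps, 3L * n_snps %/% 4L),
    H4 = causal_index_1,
    as.integer(ceiling(n_snps / 2)))
  if (hypothesis == "H4" && !identical(causal_index_1, causal_index_2)) {
    stop("coloc_scenario: H4 requires causal_index_1 == causal_index_2",
         call. = FALSE)
  }
  if (hypothesis == "H3" && identical(causal_index_1, causal_index_2)) {
    stop("coloc_scenario: H3 requires distinct causal indices", call. = FALSE)
  }
  stopifnot(ld_rho >= 0, ld_rho < 1)
  structure(list(hypothesis = hypothesis, n_snps = n_snps,
                 causal_index_1 = causal_index_1,
                 causal_index_2 = causal_index_2,
                 causal_z = causal_z, ld_rho = ld_rho, n = n,
                 seed = as.integer(seed)),
            class = "coloc_scenario")
}

#' Simulate regional summary statistics for a colocalization scenario
#'
#' Marginal z-scores for each trait are drawn as `z = R lambda + MVN(0, R)`
#' with `R` the AR(1) correlation matrix and `lambda` zero except `causal_z`
#' at that trait's causal index (absent for null traits). Betas are `z * se`
#' with constant `se = 1/sqrt(n)`.
#'
#' @param scenario A [coloc_scenario()].
#' @return A list of two `gwas_table`s (`trait1`, `trait2`) over shared SNPs.
#' @export
simulate_coloc_region <- function(scenario) {
  stopifnot(inherits(scenario, "coloc_scenario"))
  with_seed(scenario$seed, {
    m <- scenario$n_snps
    idx <- seq_len(m)
    R <- scenario$ld_rho^abs(outer(idx, idx, "-"))
    L <- chol(R)
    se <- 1 / sqrt(scenario$n)
    rsids <- paste0("rs", 2000 + idx)
    pos <- 6313757 + 150 * (idx - 1)
    draw <- function(causal_index) {
      lam <- numeric(m)
      if (!is.na(causal_index)) lam[causal_index] <- scenario$causal_z
      z <- drop(R %*% lam) + drop(crossprod(L, stats::rnorm(m)))
      gwas_table(data.frame(rsid = rsids, chrom = "12", pos = pos,
                            ea = "A", nea = "G", eaf = 0.3,
                            beta = z * se, se = se,
                            pval = pmax(2 * stats::pnorm(-abs(z)), 1e-300),
                            n = scenario$n),
                 trait_name = "region_trait", trait_scale = "continuous")
    }
    list(trait1 = draw(scenario$causal_index_1),
         trait2 = draw(scenario$causal_index_2))
  })
}
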