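# Packaged end-to-end study fixture: a 28-SNP candidate cascade arranged so
# the selection pathway is forced by the stated rules (13 candidates absent
# from every biomarker GWAS, 7 failing concordance, 8 concordant of which one
# palindromic SNP with intermediate frequencies falls at harmonization,
# leaving 7 combined instruments).

#' Write a complete synthetic study fixture
#'
#' Generates, under `dir`: a 28-SNP candidate catalog in the cis window, a
#' protein (exposure), CRP-like and WBC-like biomarker GWAS covering 15 of
#' the candidates, an absolute-risk outcome GWAS covering all 28, three
#' positive-control GWAS (two protective, one detrimental), an LD matrix and
#' a ready-to-run `study.yaml`. All effect sizes are deterministic up to a
#' small seeded jitter that cannot move any SNP across a selection boundary,
#' so the selection cascade is identical for every seed while outputs remain
#' seed-reproducible. The true causal effect on the outcome is 0.021 in
#' absolute risk per biomarker unit.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed for the jitter and sampling noise.
#' @return The path to the written `study.yaml`, invisibly.
#' @export
write_study_fixture <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- 28L
  rsids <- paste0("rs", 3000 + seq_len(n))
  rsids[24] <- "rs4149569"  # the palindromic instrument lost at harmonization
  pos <- round(seq(6314000, 6357000, length.out = n))
  ea <- rep("A", n); nea <- rep("G", n)
  ea[24] <- "A"; nea[24] <- "T"
  eaf <- rep(0.25, n); eaf[24] <- 0.5

  miss <- 1:13          # absent from every biomarker GWAS
  dirfail <- 14:17      # wrong direction in the WBC-like GWAS
  pfail <- 18:20        # null in the protein GWAS (p >= 0.05)
  kept <- 21:28         # concordant instruments
  present <- c(dirfail, pfail, kept)

  true_b <- list(protein = numeric(n), crp = numeric(n), wbc = numeric(n))
  true_b$protein[kept] <- -0.2
  true_b$crp[kept] <- -0.3
  true_b$wbc[kept] <- -0.1
  true_b$protein[dirfail] <- -0.2
  true_b$crp[dirfail] <- -0.3
  true_b$wbc[dirfail] <- 0.1            # direction violation
  true_b$protein[pfail] <- -0.008       # |z| ~ 1 in the protein GWAS
  true_b$crp[pfail] <- -0.3
  true_b$wbc[pfail] <- -0.1

  theta_true <- 0.021                   # absolute risk per biomarker unit
  theta_uc <- 0.15; theta_cd <- 0.18; theta_ms <- -0.3

  with_seed(seed, {
    jit <- function(k, sd) stats::rnorm(k, 0, sd)
    mk <- function(idx, beta_true, n_gwas, trait, scale, noise_sd = NULL) {
      se <- gwas_se(n_gwas, pmin(eaf[idx], 1 - eaf[idx]))
      beta <- beta_true[idx] + jit(length(idx), noise_sd %||% 0.002)
      gwas_table(data.frame(rsid = rsids[idx], chrom = "12", pos = pos[idx],
                            ea = ea[idx], nea = nea[idx], eaf = eaf[idx],
                            beta = beta, se = se,
                            pval = pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300),
                            n = n_gwas),
                 trait_name = trait, trait_scale = scale)
    }
    protein <- mk(present, true_b$protein, 21758, "protein", "continuous")
    crp <- mk(present, true_b$crp, 204402, "crp_like", "log_continuous")
    wbc <- mk(present, true_b$wbc, 172435, "wbc_like", "continuous")

    # outcome covers all 28 candidates; sampling noise at the outcome scale
    se_out <- gwas_se(377673, pmin(eaf, 1 - eaf))
    beta_out <- theta_true * true_b$crp + se_out * stats::rnorm(n)
    outcome <- gwas_table(data.frame(rsid = rsids, chrom = "12", pos = pos,
                                     ea = ea, nea = nea, eaf = eaf,
                                     beta = beta_out, se = se_out,
                                     pval = pmax(2 * stats::pnorm(-abs(beta_out / se_out)),
                                                 1e-300),
                                     n = 377673),
                          trait_name = "crc_like", trait_scale = "absolute_risk")
    # candidate catalog: the outcome GWAS restricted to the window stands in
    # for a region variant catalog
    candidates <- outcome
    attr(candidates, "trait_name") <- "candidate_catalog"

    ctrl <- function(theta_c, n_gwas, trait) {
      se_c <- gwas_se(n_gwas, pmin(eaf[present], 1 - eaf[present]))
      beta <- theta_c * true_b$crp[present] + se_c * stats::rnorm(length(present))
      gwas_table(data.frame(rsid = rsids[present], chrom = "12", pos = pos[present],
                            ea = ea[present], nea = nea[present], eaf = eaf[present],
                            beta = beta, se = se_c,
                            pval = pmax(2 * stats::pnorm(-abs(beta / se_c)), 1e-300),
                            n = n_gwas),
                 trait_name = trait, trait_scale = "log_odds")
    }
    uc <- ctrl(theta_uc, 45975, "uc_like")
    cd <- ctrl(theta_cd, 40266, "cd_like")
    ms <- ctrl(theta_ms, 115803, "ms_like")

    ld <- simulate_ld_matrix(n, rho = 0.01, rsids = rsids)

    paths <- list(candidates = "candidates.tsv", exposure = "protein.tsv",
                  crp = "crp.tsv", wbc = "wbc.tsv", outcome = "outcome.tsv",
                  uc = "uc.tsv", cd = "cd.tsv", ms = "ms.tsv", ld = "ld.tsv")
    write_gwas_table(candidates, file.path(dir, paths$candidates))
    write_gwas_table(protein, file.path(dir, paths$exposure))
    write_gwas_table(crp, file.path(dir, paths$crp))
    write_gwas_table(wbc, file.path(dir, paths$wbc))
    write_gwas_table(outcome, file.path(dir, paths$outcome))
    write_gwas_table(uc, file.path(dir, paths$uc))
    write_gwas_table(cd, file.path(dir, paths$cd))
    write_gwas_table(ms, file.path(dir, paths$ms))
    write_ld_matrix(ld, file.path(dir, paths$ld))

    cfg <- list(
      seed = as.integer(seed),
      region = list(chrom = "12", start = 6328757L, end = 6342114L, flank = 15000L),
      thresholds = list(p_threshold = 0.05, r2_threshold = 0.001,
                        af_band = c(0.42, 0.58)),
      estimators = list(n_boot = 1000L, second_order = FALSE),
      coloc = list(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5),
      mr_exposure = "crp_like",
      arr = list(deltas = c(16, 13.9)),
      tables = list(
        candidates = list(path = paths$candidates, trait_name = "candidate_catalog",
                          trait_scale = "absolute_risk"),
        exposure = list(path = paths$exposure, trait_name = "protein",
                        trait_scale = "continuous"),
        biomarkers = list(
          list(path = paths$crp, trait_name = "crp_like",
               trait_scale = "log_continuous"),
          list(path = paths$wbc, trait_name = "wbc_like",
               trait_scale = "continuous")),
        outcome = list(path = paths$outcome, trait_name = "crc_like",
                       trait_scale = "absolute_risk"),
        controls = list(
          list(path = paths$uc, trait_name = "uc_like", trait_scale = "log_odds",
               expected_direction = "protective"),
          list(path = paths$cd, trait_name = "cd_like", trait_scale = "log_odds",
               expected_direction = "protective"),
          list(path = paths$ms, trait_name = "ms_like", trait_scale = "log_odds",
               expected_direction = "detrimental"))),
      ld_matrix = paths$ld)
    cfg_path <- file.path(dir, "study.yaml")
    yaml::write_yaml(cfg, cfg_path)
    invisible(cfg_path)
  })
}
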