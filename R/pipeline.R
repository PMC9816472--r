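# Study orchestration: one YAML configuration drives instrument selection,
# positive controls, primary MR, sensitivity analyses, colocalization and
# absolute-risk extrapolation.

#' Read and validate a study configuration
#'
#' Loads a YAML study configuration, applies defaults, checks required
#' fields with field-level messages, and resolves table paths relative to
#' the configuration file's directory.
#'
#' @param path Path to a `study.yaml` (see [write_study_fixture()] for a
#'   complete example).
#' @return A validated list of class `study_config`.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("read_study_config: no such file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  validate_study_config(cfg, base_dir = base)
}

#' @rdname read_study_config
#' @param cfg A configuration list (as parsed from YAML).
#' @param base_dir Directory against which relative paths resolve.
#' @export
validate_study_config <- function(cfg, base_dir = ".") {
  fail <- function(field, msg) {
    stop(sprintf("study config: field '%s' %s", field, msg), call. = FALSE)
  }
  if (is.null(cfg$seed)) fail("seed", "is required")
  cfg$seed <- as.integer(cfg$seed)
  r <- cfg$region
  for (f in c("chrom", "start", "end")) {
    if (is.null(r[[f]])) fail(paste0("region.", f), "is required")
  }
  cfg$region <- gene_region(r$chrom, r$start, r$end, r$flank %||% 0)
  th <- cfg$thresholds %||% list()
  cfg$thresholds <- list(p_threshold = th$p_threshold %||% 0.05,
                         r2_threshold = th$r2_threshold %||% 0.001,
                         af_band = as.numeric(th$af_band %||% c(0.42, 0.58)))
  if (length(cfg$thresholds$af_band) != 2L) fail("thresholds.af_band", "needs two values")
  est <- cfg$estimators %||% list()
  cfg$estimators <- list(n_boot = as.integer(est$n_boot %||% 1000L),
                         second_order = isTRUE(est$second_order))
  co <- cfg$coloc %||% list()
  cfg$coloc <- list(priors = coloc_priors(co$p1 %||% 1e-4, co$p2 %||% 1e-4,
                                          co$p12 %||% 1e-5),
                    prior_sd_exposure = co$prior_sd_exposure,
                    prior_sd_outcome = co$prior_sd_outcome)
  tab <- cfg$tables
  if (is.null(tab)) fail("tables", "is required")
  check_tab <- function(t, field, need_dir = FALSE) {
    if (is.null(t$path)) fail(paste0(field, ".path"), "is required")
    p <- if (file.exists(t$path)) t$path else file.path(base_dir, t$path)
    if (!file.exists(p)) fail(paste0(field, ".path"), paste("does not exist:", t$path))
    t$path <- p
    t$trait_scale <- t$trait_scale %||% "continuous"
    t$trait_name <- t$trait_name %||% basename(p)
    if (need_dir && is.null(t$expected_direction)) {
      fail(paste0(field, ".expected_direction"), "is required for controls")
    }
    if (!is.null(t$expected_direction) &&
        !t$expected_direction %in% c("protective", "detrimental")) {
      fail(paste0(field, ".expected_direction"), "must be protective or detrimental")
    }
    t
  }
  if (is.null(tab$exposure)) fail("tables.exposure", "is required")
  tab$exposure <- check_tab(tab$exposure, "tables.exposure")
  if (is.null(tab$biomarkers) || length(tab$biomarkers) == 0L) {
    fail("tables.biomarkers", "needs at least one entry")
  }
  tab$biomarkers <- lapply(seq_along(tab$biomarkers), function(i) {
    check_tab(tab$biomarkers[[i]], sprintf("tables.biomarkers[%d]", i))
  })
  if (is.null(tab$outcome)) fail("tables.outcome", "is required")
  tab$outcome <- check_tab(tab$outcome, "tables.outcome")
  tab$controls <- lapply(seq_along(tab$controls %||% list()), function(i) {
    check_tab(tab$controls[[i]], sprintf("tables.controls[%d]", i), need_dir = TRUE)
  })
  if (!is.null(tab$candidates)) tab$candidates <- check_tab(tab$candidates, "tables.candidates")
  cfg$tables <- tab
  if (is.null(cfg$ld_matrix)) fail("ld_matrix", "is required")
  if (!file.exists(cfg$ld_matrix)) cfg$ld_matrix <- file.path(base_dir, cfg$ld_matrix)
  if (!file.exists(cfg$ld_matrix)) fail("ld_matrix", "does not exist")
  cfg$mr_exposure <- cfg$mr_exposure %||% NULL
  cfg$arr <- list(deltas = as.numeric((cfg$arr %||% list())$deltas %||% numeric(0)))
  structure(cfg, class = "study_config")
}

#' @noRd
load_cfg_table <- function(t) {
  map <- if (is.null(t$columns)) column_map() else do.call(column_map, t$columns)
  read_gwas_table(t$path, map, trait_name = t$trait_name, trait_scale = t$trait_scale)
}

#' @noRd
estimate_to_report <- function(e) {
  if (is.null(e)) return(NULL)
  list(method = e$method, theta = e$theta, se = e$se, ci_low = e$ci_low,
       ci_high = e$ci_high, pval = e$pval, n_snps = e$n_snps)
}

# Harmonize instruments against one outcome table, orient to inhibition and
# run the estimator battery.
#' @noRd
analyze_outcome <- function(instr_table, outcome_table, cfg, seed_offset) {
  h <- harmonize_dataset(instr_table, outcome_table, band = cfg$thresholds$af_band)
  if (nrow(h) == 0L) stop("pipeline: harmonization left no pairs for outcome '",
                          attr(outcome_table, "trait_name"), "'", call. = FALSE)
  h <- orient_to_inhibition(h)
  res <- mr_all(h, n_boot = cfg$estimators$n_boot,
                seed = cfg$seed + seed_offset,
                second_order = cfg$estimators$second_order)
  if (!is.null(res$q) && res$q$pval < 0.05) {
    warning(sprintf("pipeline: Cochran's Q detects heterogeneity for '%s' (p=%.3g)",
                    attr(outcome_table, "trait_name"), res$q$pval), call. = FALSE)
  }
  list(set = h, res = res)
}

#' Positive-control analyses
#'
#' For each control outcome, harmonizes the instruments, orients them to
#' inhibition, computes the fixed-effects IVW estimate, and compares its
#' sign against the configured expectation. After orientation the effect
#' allele lowers the biomarker, so a `protective` drug effect corresponds to
#' a positive causal estimate (outcome risk rises with the biomarker, hence
#' falls under inhibition) and a `detrimental` one to a negative estimate.
#'
#' @param instruments A `gwas_table` of the selected instruments on the
#'   effect-scale (exposure) trait.
#' @param controls A list; each element has `table` (a `gwas_table`),
#'   `expected_direction` (`"protective"`/`"detrimental"`), and optionally
#'   `name`.
#' @param band Intermediate-frequency band for harmonization.
#' @return A named list per control: `ivw` estimate fields,
#'   `expected_direction`, and `verdict` (`"pass"`/`"fail"`).
#' @export
run_positive_controls <- function(instruments, controls, band = c(0.42, 0.58)) {
  if (length(controls) == 0L) return(list())
  out <- lapply(controls, function(ctl) {
    if (is.null(ctl$expected_direction)) {
      stop("run_positive_controls: control without expected_direction", call. = FALSE)
    }
    h <- orient_to_inhibition(harmonize_dataset(instruments, ctl$table, band = band))
    ivw <- ivw_fixed(wald_ratios(h))
    pass <- if (ctl$expected_direction == "protective") ivw$theta > 0 else ivw$theta < 0
    list(ivw = estimate_to_report(ivw),
         n_snps = nrow(h),
         expected_direction = ctl$expected_direction,
         verdict = if (pass) "pass" else "fail")
  })
  names(out) <- vapply(seq_along(controls), function(i) {
    controls[[i]]$name %||% attr(controls[[i]]$table, "trait_name") %||% paste0("control", i)
  }, character(1))
  out
}

#' Run the full drug-target MR study
#'
#' Executes, in order: table reading and validation; cis-window extraction of
#' the candidate catalog; tri-biomarker concordance filtering; LD clumping
#' (ranked by the protein-exposure p-values); harmonization of the
#' effect-scale exposure against the primary outcome and every control,
#' orientation to inhibition; per-SNP Wald ratios; IVW, Cochran's Q, weighted
#' median and MR-Egger per outcome; colocalization of the exposure and
#' primary outcome over the gene region; and absolute-risk extrapolations.
#' Each stage logs input/output counts; any stage with empty output aborts
#' with the stage name; a significant Q is a logged warning, not a gate.
#'
#' @param config A `study_config` (from [read_study_config()]) or a path to
#'   a YAML configuration.
#' @param out_dir Optional output directory; when given, writes
#'   `report.json`, `estimates.tsv`, `selection_report.tsv`,
#'   `exclusions.tsv` and `coloc.json`.
#' @return The study report, a nested list of class `study_report`.
#' @export
run_drug_target_mr <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "study_config"))
  cfg <- config
  t0 <- proc.time()[["elapsed"]]

  exposure <- load_cfg_table(cfg$tables$exposure)
  biomarkers <- c(list(exposure), lapply(cfg$tables$biomarkers, load_cfg_table))
  outcome <- load_cfg_table(cfg$tables$outcome)
  controls <- lapply(cfg$tables$controls, function(t) {
    list(table = load_cfg_table(t), expected_direction = t$expected_direction,
         name = t$trait_name)
  })
  candidates <- if (!is.null(cfg$tables$candidates)) {
    load_cfg_table(cfg$tables$candidates)
  } else exposure
  ld <- read_ld_matrix(cfg$ld_matrix)

  # which biomarker table carries the effect scale for MR (the paper uses the
  # CRP-like trait); default: the protein exposure table
  mr_exp <- exposure
  if (!is.null(cfg$mr_exposure)) {
    names_b <- vapply(biomarkers, attr, character(1), "trait_name")
    hit <- which(names_b == cfg$mr_exposure)
    if (length(hit) == 0L) {
      stop("pipeline: mr_exposure '", cfg$mr_exposure,
           "' matches no biomarker table", call. = FALSE)
    }
    mr_exp <- biomarkers[[hit[1]]]
  }

  cand_window <- extract_cis_window(candidates, cfg$region)
  stage_log("extract_cis_window", nrow(candidates), nrow(cand_window), t0)
  if (nrow(cand_window) == 0L) stop("pipeline: extract_cis_window produced no candidates",
                                    call. = FALSE)

  cf <- concordance_filter(cand_window, biomarkers,
                           p_threshold = cfg$thresholds$p_threshold,
                           required_direction = -1)
  stage_log("concordance_filter", nrow(cand_window), nrow(cf$kept), t0)
  if (nrow(cf$kept) == 0L) stop("pipeline: concordance_filter kept no SNPs", call. = FALSE)

  exp_kept <- exposure[match(cf$kept$rsid, exposure$rsid), ]
  clumped <- ld_clump(exp_kept, ld, r2_threshold = cfg$thresholds$r2_threshold)
  stage_log("ld_clump", nrow(exp_kept), nrow(clumped), t0)
  if (nrow(clumped) == 0L) stop("pipeline: ld_clump kept no SNPs", call. = FALSE)
  report_sel <- cf$report
  report_sel$n_after_clump <- nrow(clumped)
  for (d in names(attr(clumped, "clump_dropped"))) report_sel$excluded[d] <- "ld_clump"

  instr <- mr_exp[match(clumped$rsid, mr_exp$rsid), ]
  instr <- instr[!is.na(instr$rsid), , drop = FALSE]

  primary <- analyze_outcome(instr, outcome, cfg, seed_offset = 1L)
  stage_log("primary_mr", nrow(instr), nrow(primary$set), t0)

  control_section <- run_positive_controls(instr, controls,
                                           band = cfg$thresholds$af_band)
  if (length(controls) > 0L) stage_log("positive_controls", length(controls),
                                       length(control_section), t0)

  region1 <- extract_cis_window(mr_exp, cfg$region)
  region2 <- extract_cis_window(outcome, cfg$region)
  coloc <- coloc_posteriors(region1, region2, priors = cfg$coloc$priors,
                            prior_sd1 = cfg$coloc$prior_sd_exposure,
                            prior_sd2 = cfg$coloc$prior_sd_outcome)
  stage_log("coloc", nrow(region1), coloc$n_snps, t0)

  # theta is the risk change per 1-unit biomarker increase; the absolute risk
  # reduction under inhibition is theta per 1-unit decrease (positive = risk
  # falls when the biomarker falls)
  theta <- primary$res$ivw_fe$theta
  arr <- list(
    risk_change_per_unit_increase = theta,
    risk_change_per_unit_decrease = -theta,
    arr_per_unit_decrease = theta,
    extrapolations = lapply(cfg$arr$deltas, function(d) {
      list(delta_biomarker = d, arr = extrapolate_arr(theta, d))
    }))

  res <- primary$res
  report <- structure(list(
    selection = list(n_candidates = report_sel$n_candidates,
                     n_with_any_association = report_sel$n_with_any_association,
                     n_concordant = report_sel$n_concordant,
                     n_after_clump = report_sel$n_after_clump,
                     excluded = as.list(report_sel$excluded)),
    instruments = clumped$rsid,
    harmonization = list(
      n_pairs = nrow(primary$set),
      exclusions = as.list(stats::setNames(attr(primary$set, "exclusions")$reason,
                                           attr(primary$set, "exclusions")$rsid))),
    primary = list(
      outcome = attr(outcome, "trait_name"),
      wald = primary$res$wald,
      ivw_fe = estimate_to_report(res$ivw_fe),
      weighted_median = estimate_to_report(res$weighted_median),
      egger_slope = estimate_to_report(res$egger_slope),
      egger_intercept = estimate_to_report(res$egger_intercept),
      q = if (is.null(res$q)) NULL else list(q = res$q$q, df = res$q$df,
                                             pval = res$q$pval)),
    positive_controls = control_section,
    coloc = list(pp = as.list(coloc$pp), paper_pp1 = coloc$pp[["PP3"]],
                 paper_pp2 = coloc$pp[["PP4"]], n_snps = coloc$n_snps),
    arr = arr,
    seed = cfg$seed), class = "study_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass_report(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    write_mr_estimates(Filter(Negate(is.null),
                              list(res$ivw_fe, res$weighted_median,
                                   res$egger_slope, res$egger_intercept)),
                       file.path(out_dir, "estimates.tsv"))
    utils::write.table(data.frame(stage = c("candidates", "with_any_association",
                                            "concordant", "after_clump", "combined"),
                                  n = c(report_sel$n_candidates,
                                        report_sel$n_with_any_association,
                                        report_sel$n_concordant,
                                        report_sel$n_after_clump,
                                        nrow(primary$set))),
                       file.path(out_dir, "selection_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_exclusion_log(primary$set, file.path(out_dir, "exclusions.tsv"))
    write_coloc_json(coloc, file.path(out_dir, "coloc.json"))
  }
  report
}

#' @noRd
unclass_report <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), unclass_report))
  x
}

#' @export
print.study_report <- function(x, ...) {
  s <- x$selection
  cat(sprintf("<study_report> candidates=%d concordant=%d clumped=%d combined=%d\n",
              s$n_candidates, s$n_concordant, s$n_after_clump, x$harmonization$n_pairs))
  ivw <- x$primary$ivw_fe
  cat(sprintf("primary IVW: theta=%.5g [%.5g, %.5g] p=%.3g (n_snps=%d)\n",
              ivw$theta, ivw$ci_low, ivw$ci_high, ivw$pval, ivw$n_snps))
  cat(sprintf("coloc: PP3=%.3g PP4=%.3g\n", x$coloc$paper_pp1, x$coloc$paper_pp2))
  invisible(x)
}

#' Extrapolate an absolute risk change over a biomarker shift
#'
#' Multiplies a per-unit absolute risk change by a biomarker change in the
#' same units: e.g. a 2.1% absolute risk reduction per 1 mg/L over a 16 mg/L
#' drug-induced decrease extrapolates to 33.6%.
#'
#' @param arr_per_unit Risk change per 1-unit biomarker change.
#' @param delta_biomarker Biomarker change, same units.
#' @return `arr_per_unit * delta_biomarker`.
#' @examples
#' extrapolate_arr(2.1, 16)   # 33.6
#' extrapolate_arr(2.1, 13.9) # 29.19
#' @export
extrapolate_arr <- function(arr_per_unit, delta_biomarker) {
  stopifnot(is.finite(arr_per_unit), is.finite(delta_biomarker))
  arr_per_unit * delta_biomarker
}
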