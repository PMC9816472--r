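# Bayesian colocalization: per-SNP approximate Bayes factors and posterior
# enumeration over the five standard hypotheses (H0..H4).

#' Colocalization priors
#'
#' Per-SNP prior probabilities: `p1` causal for trait 1 only, `p2` for trait 2
#' only, `p12` for both. Defaults are the standard single-causal-variant
#' convention.
#'
#' @param p1,p2,p12 Priors with `0 < p12 <= min(p1, p2) < 1`.
#' @return A list of class `coloc_priors`.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  if (!(p12 > 0 && p12 <= min(p1, p2) && max(p1, p2) < 1)) {
    stop("coloc_priors: need 0 < p12 <= min(p1, p2) < 1", call. = FALSE)
  }
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

#' Log approximate Bayes factor for one association
#'
#' Wakefield's approximation: with `V = se^2`, `W = prior_sd^2`,
#' `r = W/(V+W)` and `z = beta/se`, the log ABF against the null is
#' `0.5 log(1 - r) + z^2 r / 2`.
#'
#' @param beta Effect estimate.
#' @param se Standard error (> 0).
#' @param prior_sd Prior standard deviation of the true effect (`sqrt(W)`,
#'   > 0); 0.15 is conventional for continuous traits, 0.2 for binary.
#' @return Log Bayes factor (vectorized over `beta`/`se`).
#' @export
log_abf <- function(beta, se, prior_sd = 0.15) {
  if (any(!se > 0)) stop("log_abf: se must be > 0", call. = FALSE)
  if (!prior_sd > 0) stop("log_abf: prior_sd must be > 0", call. = FALSE)
  v <- se^2
  r <- prior_sd^2 / (v + prior_sd^2)
  z <- beta / se
  0.5 * log1p(-r) + z^2 * r / 2
}

#' @noRd
default_prior_sd <- function(table) {
  if (identical(attr(table, "trait_scale"), "log_odds")) 0.2 else 0.15
}

#' Colocalization posteriors for two traits over one region
#'
#' Computes per-SNP log ABFs for each trait and enumerates the five
#' hypotheses: H0 no association; H1/H2 one trait associated; H3 both traits
#' associated through two distinct causal variants; H4 both through one
#' shared variant. All sums run in log space via log-sum-exp. With a single
#' shared SNP, PP3 is exactly 0 (H3 needs two distinct variants) and a
#' warning is emitted.
#'
#' @param region1,region2 `gwas_table`s over the same region; posteriors use
#'   the SNPs shared by both (a message reports any asymmetry; at least one
#'   shared SNP is required).
#' @param priors A [coloc_priors()].
#' @param prior_sd1,prior_sd2 Effect-scale prior SDs; default 0.15, or 0.2
#'   for a `log_odds` trait.
#' @return A list of class `coloc_result`: `log_abf1`, `log_abf2` (named
#'   per-SNP vectors), `pp` (named `PP0..PP4`, summing to 1), `n_snps`,
#'   `priors`.
#' @export
coloc_posteriors <- function(region1, region2, priors = coloc_priors(),
                             prior_sd1 = NULL, prior_sd2 = NULL) {
  stopifnot(inherits(region1, "gwas_table"), inherits(region2, "gwas_table"),
            inherits(priors, "coloc_priors"))
  prior_sd1 <- prior_sd1 %||% default_prior_sd(region1)
  prior_sd2 <- prior_sd2 %||% default_prior_sd(region2)
  shared <- intersect(region1$rsid, region2$rsid)
  if (length(shared) == 0L) {
    stop("coloc_posteriors: no shared SNPs between the two regions", call. = FALSE)
  }
  if (length(shared) < nrow(region1) || length(shared) < nrow(region2)) {
    message(sprintf("coloc_posteriors: restricting to %d shared SNPs", length(shared)))
  }
  r1 <- region1[match(shared, region1$rsid), ]
  r2 <- region2[match(shared, region2$rsid), ]
  l1 <- stats::setNames(log_abf(r1$beta, r1$se, prior_sd1), shared)
  l2 <- stats::setNames(log_abf(r2$beta, r2$se, prior_sd2), shared)

  ls1 <- logsumexp(l1)            # log sum_j ABF1_j
  ls2 <- logsumexp(l2)            # log sum_j ABF2_j
  ls12 <- logsumexp(l1 + l2)      # log sum_j ABF1_j ABF2_j
  log_s <- c(
    H0 = 0,
    H1 = log(priors$p1) + ls1,
    H2 = log(priors$p2) + ls2,
    # sum over j != k pairs = (sum1)(sum2) - sum_j prod_j, kept in log space
    H3 = if (length(shared) == 1L) -Inf else {
      diff <- ls12 - (ls1 + ls2)
      log(priors$p1) + log(priors$p2) + ls1 + ls2 +
        if (diff >= 0) -Inf else log1p(-exp(diff))
    },
    H4 = log(priors$p12) + ls12
  )
  if (length(shared) == 1L) {
    warning("coloc_posteriors: single-SNP region, PP3 forced to 0", call. = FALSE)
  }
  denom <- logsumexp(log_s)
  pp <- exp(log_s - denom)
  pp <- pp / sum(pp)
  names(pp) <- paste0("PP", 0:4)
  structure(list(log_abf1 = l1, log_abf2 = l2, pp = pp,
                 n_snps = length(shared), priors = priors),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> n_snps=%d\n", x$n_snps))
  print(signif(x$pp, 4))
  invisible(x)
}

#' Export a colocalization result as JSON
#'
#' The five posteriors are written as `pp0..pp4`; `paper_pp1`/`paper_pp2`
#' duplicate PP3 (two distinct causal variants) and PP4 (one shared variant)
#' for reports that use the two-hypothesis labelling.
#'
#' @param result A `coloc_result`.
#' @param path Output JSON path.
#' @export
write_coloc_json <- function(result, path) {
  stopifnot(inherits(result, "coloc_result"))
  obj <- list(pp0 = result$pp[["PP0"]], pp1 = result$pp[["PP1"]],
              pp2 = result$pp[["PP2"]], pp3 = result$pp[["PP3"]],
              pp4 = result$pp[["PP4"]],
              paper_pp1 = result$pp[["PP3"]], paper_pp2 = result$pp[["PP4"]],
              n_snps = result$n_snps,
              priors = list(p1 = result$priors$p1, p2 = result$priors$p2,
                            p12 = result$priors$p12))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
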