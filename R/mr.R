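# Two-sample MR estimators: Wald ratio, fixed-effects IVW, Cochran's Q,
# weighted median, MR-Egger.

#' @noRd
new_mr_estimate <- function(method, theta, se, n_snps, df = NULL) {
  if (is.null(df)) {
    crit <- Z95
    pval <- if (is.na(se)) NA_real_ else 2 * stats::pnorm(-abs(theta / se))
  } else {
    crit <- stats::qt(0.975, df)
    pval <- if (is.na(se)) NA_real_ else 2 * stats::pt(-abs(theta / se), df)
  }
  structure(list(method = method, theta = theta, se = se,
                 ci_low = theta - crit * se, ci_high = theta + crit * se,
                 pval = pval, n_snps = as.integer(n_snps)),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate %s> theta=%.6g se=%.6g 95%%CI [%.6g, %.6g] p=%.3g n_snps=%d\n",
              x$method, x$theta, x$se, x$ci_low, x$ci_high, x$pval, x$n_snps))
  invisible(x)
}

#' One row per estimate, for export
#' @param x An `mr_estimate` or list of them.
#' @return data.frame with columns method, theta, se, ci_low, ci_high, pval, n_snps.
#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, theta = x$theta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high,
             pval = x$pval, n_snps = x$n_snps)
}

# Accept a list of mr_estimate, a single mr_estimate, or a data.frame with
# theta/se columns, and return list(theta=, se=).
#' @noRd
as_theta_se <- function(estimates) {
  if (inherits(estimates, "mr_estimate")) estimates <- list(estimates)
  if (is.data.frame(estimates)) {
    return(list(theta = estimates$theta, se = estimates$se))
  }
  stopifnot(is.list(estimates))
  list(theta = vapply(estimates, function(e) e$theta, numeric(1)),
       se = vapply(estimates, function(e) e$se, numeric(1)))
}

#' Wald ratio causal estimate for one SNP
#'
#' `theta = beta_y / beta_x`. The default standard error is first-order
#' (`se_y / |beta_x|`), ignoring exposure uncertainty; the second-order delta
#' approximation adds the `beta_y^2 se_x^2 / beta_x^4` term.
#'
#' @param beta_x,se_x Exposure effect and its SE (`beta_x != 0`).
#' @param beta_y,se_y Outcome effect and its SE (`se_y > 0`).
#' @param second_order Use the second-order delta SE (default `FALSE`).
#' @return An `mr_estimate` with method `"wald"`.
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y, second_order = FALSE) {
  if (beta_x == 0) stop("wald_ratio: beta_x = 0, ratio undefined", call. = FALSE)
  if (!se_y > 0) stop("wald_ratio: se_y must be > 0", call. = FALSE)
  theta <- beta_y / beta_x
  se <- if (second_order) {
    sqrt(se_y^2 / beta_x^2 + beta_y^2 * se_x^2 / beta_x^4)
  } else {
    se_y / abs(beta_x)
  }
  new_mr_estimate("wald", theta, se, 1L)
}

#' Per-SNP Wald ratios for a harmonized set
#'
#' @param set A `harmonized_set` (all `beta_x != 0`).
#' @inheritParams wald_ratio
#' @return A data frame with one row per SNP: `rsid, method, theta, se,
#'   ci_low, ci_high, pval, n_snps`.
#' @export
wald_ratios <- function(set, second_order = FALSE) {
  stopifnot(inherits(set, "harmonized_set"), nrow(set) > 0L)
  if (any(set$beta_x == 0)) stop("wald_ratios: beta_x = 0, ratio undefined", call. = FALSE)
  theta <- set$beta_y / set$beta_x
  se <- if (second_order) {
    sqrt(set$se_y^2 / set$beta_x^2 + set$beta_y^2 * set$se_x^2 / set$beta_x^4)
  } else {
    set$se_y / abs(set$beta_x)
  }
  data.frame(rsid = set$rsid, method = "wald", theta = theta, se = se,
             ci_low = theta - Z95 * se, ci_high = theta + Z95 * se,
             pval = 2 * stats::pnorm(-abs(theta / se)), n_snps = 1L,
             stringsAsFactors = FALSE)
}

#' Fixed-effects inverse-variance-weighted meta-analysis
#'
#' Combines per-SNP estimates with weights `1/se^2`:
#' `theta = sum(w theta_j) / sum(w)`, `se = sqrt(1 / sum(w))`. On a single
#' estimate this reproduces the Wald ratio exactly.
#'
#' @param estimates A list of `mr_estimate`s or a data frame with `theta` and
#'   `se` columns, all `se > 0`.
#' @return An `mr_estimate` with method `"ivw_fe"`.
#' @export
ivw_fixed <- function(estimates) {
  ts <- as_theta_se(estimates)
  j <- length(ts$theta)
  if (j == 0L) stop("ivw_fixed: no estimates", call. = FALSE)
  if (any(!ts$se > 0)) stop("ivw_fixed: all se must be > 0", call. = FALSE)
  if (j == 1L) return(new_mr_estimate("ivw_fe", ts$theta, ts$se, 1L))
  w <- 1 / ts$se^2
  theta <- sum(w * ts$theta) / sum(w)
  new_mr_estimate("ivw_fe", theta, sqrt(1 / sum(w)), j)
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum(w_j (theta_j - theta_ivw)^2)` with `w_j = 1/se_j^2`, referred to a
#' chi-square with `J - 1` degrees of freedom (upper tail).
#'
#' @inheritParams ivw_fixed
#' @return A list of class `q_result` with `q`, `df`, `pval`.
#' @export
cochran_q <- function(estimates) {
  ts <- as_theta_se(estimates)
  j <- length(ts$theta)
  if (j < 2L) stop("cochran_q: need at least 2 estimates", call. = FALSE)
  w <- 1 / ts$se^2
  theta_ivw <- sum(w * ts$theta) / sum(w)
  q <- sum(w * (ts$theta - theta_ivw)^2)
  structure(list(q = q, df = j - 1L,
                 pval = stats::pchisq(q, df = j - 1L, lower.tail = FALSE)),
            class = "q_result")
}

#' @export
print.q_result <- function(x, ...) {
  cat(sprintf("<q_result> Q=%.4g df=%d p=%.3g\n", x$q, x$df, x$pval))
  invisible(x)
}

# Weighted-median interpolation of ratio estimates theta with weights w.
#' @noRd
weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]; w <- w[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  stats::approx(s, theta, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' Per-SNP Wald ratios are weighted by their inverse variance; the estimate
#' linearly interpolates the ratio at cumulative standardized weight 0.5.
#' Consistent when at least half the total weight comes from valid
#' instruments. The SE comes from a seeded parametric bootstrap that redraws
#' each `beta_x` and `beta_y` from normal distributions centred on the
#' observed values with their reported SEs.
#'
#' @param set A `harmonized_set` with at least 3 pairs.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap (mandatory when bootstrapping).
#' @param se_method `"bootstrap"` (default) or `"none"` (point estimate only;
#'   se/ci/p are NA — for simulation loops that only need the point).
#' @inheritParams wald_ratio
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
weighted_median <- function(set, n_boot = 1000L, seed = NULL,
                            se_method = c("bootstrap", "none"),
                            second_order = FALSE) {
  stopifnot(inherits(set, "harmonized_set"))
  se_method <- match.arg(se_method)
  j <- nrow(set)
  if (j < 3L) stop("weighted_median: need at least 3 pairs", call. = FALSE)
  theta <- set$beta_y / set$beta_x
  se_w <- if (second_order) {
    sqrt(set$se_y^2 / set$beta_x^2 + set$beta_y^2 * set$se_x^2 / set$beta_x^4)
  } else {
    set$se_y / abs(set$beta_x)
  }
  w <- 1 / se_w^2
  point <- weighted_median_point(theta, w)
  if (se_method == "none") {
    return(new_mr_estimate("weighted_median", point, NA_real_, j))
  }
  if (n_boot < 1L) stop("weighted_median: n_boot must be >= 1", call. = FALSE)
  if (is.null(seed)) stop("weighted_median: seed is required for the bootstrap",
                          call. = FALSE)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(j, set$beta_x, set$se_x)
      by <- stats::rnorm(j, set$beta_y, set$se_y)
      ok <- bx != 0
      th <- by[ok] / bx[ok]
      sw <- if (second_order) {
        sqrt(set$se_y[ok]^2 / bx[ok]^2 + by[ok]^2 * set$se_x[ok]^2 / bx[ok]^4)
      } else {
        set$se_y[ok] / abs(bx[ok])
      }
      weighted_median_point(th, 1 / sw^2)
    }, numeric(1))
  })
  new_mr_estimate("weighted_median", point, stats::sd(boots), j)
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of outcome effects on exposure effects
#' with a free intercept, weights `1/se_y^2`. The slope is the causal
#' estimate; the intercept estimates average directional pleiotropy. SEs use
#' a multiplicative residual scaling floored at 1 (no under-dispersion
#' credit); p-values and CIs use a t distribution with `J - 2` df.
#'
#' @param set A `harmonized_set` with at least 3 pairs and non-constant
#'   `beta_x`.
#' @return A list with `slope` and `intercept`, both `mr_estimate`s
#'   (methods `"egger_slope"`, `"egger_intercept"`).
#' @export
mr_egger <- function(set) {
  stopifnot(inherits(set, "harmonized_set"))
  j <- nrow(set)
  if (j < 3L) stop("mr_egger: need at least 3 pairs", call. = FALSE)
  x <- set$beta_x; y <- set$beta_y
  if (max(x) == min(x)) stop("mr_egger: all beta_x identical, design singular",
                             call. = FALSE)
  w <- 1 / set$se_y^2
  X <- cbind(1, x)
  xtwx <- crossprod(X, w * X)
  coef <- solve(xtwx, crossprod(X, w * y))
  resid <- y - X %*% coef
  sigma2 <- max(1, sum(w * resid^2) / (j - 2))
  covm <- sigma2 * solve(xtwx)
  list(slope = new_mr_estimate("egger_slope", coef[2], sqrt(covm[2, 2]), j, df = j - 2),
       intercept = new_mr_estimate("egger_intercept", coef[1], sqrt(covm[1, 1]), j,
                                   df = j - 2))
}

#' Run the full estimator battery on a harmonized set
#'
#' @param set A `harmonized_set`.
#' @param n_boot,seed Passed to [weighted_median()].
#' @inheritParams wald_ratio
#' @return A list: `wald` (per-SNP data frame), `ivw_fe`, `q`,
#'   `weighted_median`, `egger_slope`, `egger_intercept` (the latter three
#'   `NULL` when fewer than 3 pairs are available).
#' @export
mr_all <- function(set, n_boot = 1000L, seed = NULL, second_order = FALSE) {
  wald <- wald_ratios(set, second_order = second_order)
  ivw <- ivw_fixed(wald)
  q <- if (nrow(set) >= 2L) cochran_q(wald) else NULL
  wm <- eg <- NULL
  if (nrow(set) >= 3L) {
    wm <- weighted_median(set, n_boot = n_boot, seed = seed,
                          second_order = second_order)
    eg <- mr_egger(set)
  }
  list(wald = wald, ivw_fe = ivw, q = q, weighted_median = wm,
       egger_slope = eg$slope, egger_intercept = eg$intercept)
}

#' Export MR estimates as TSV
#'
#' Writes one row per estimate with columns
#' `method, theta, se, ci_low, ci_high, pval, n_snps`.
#'
#' @param estimates A list of `mr_estimate`s (NULLs are skipped).
#' @param path Output path.
#' @export
write_mr_estimates <- function(estimates, path) {
  estimates <- Filter(Negate(is.null), estimates)
  df <- do.call(rbind, lapply(estimates, as.data.frame))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
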