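test_that("Wald ratio arithmetic, null case, sign symmetry and errors", {
  e <- wald_ratio(0.1, 0.01, 0.02, 0.005)
  expect_equal(e$theta, 0.2)
  expect_equal(e$se, 0.05)
  expect_equal(e$ci_low, 0.2 - 1.959964 * 0.05)

  e0 <- wald_ratio(0.1, 0.01, 0, 0.005)
  expect_equal(e0$theta, 0)
  expect_equal(e0$pval, 1)

  en <- wald_ratio(-0.1, 0.01, 0.02, 0.005)
  expect_equal(en$theta, -0.2)
  expect_equal(en$se, 0.05)

  # second-order SE adds the exposure-uncertainty term
  e2 <- wald_ratio(0.1, 0.01, 0.02, 0.005, second_order = TRUE)
  expect_equal(e2$se, sqrt(0.005^2 / 0.01 + 0.02^2 * 0.01^2 / 1e-4))

  expect_error(wald_ratio(0, 0.01, 0.02, 0.005), "beta_x")
})

test_that("fixed-effects IVW is the precision-weighted mean", {
  est <- data.frame(theta = c(0.2, 0.4), se = c(0.05, 0.1))
  ivw <- ivw_fixed(est)
  expect_equal(ivw$theta, 0.24)
  expect_equal(ivw$se, sqrt(1 / 500))
  expect_equal(ivw$n_snps, 2L)

  # single estimate: identical to the Wald ratio (exact), relabeled
  w <- wald_ratio(0.1, 0.01, 0.02, 0.005)
  one <- ivw_fixed(list(w))
  expect_identical(one$theta, w$theta)
  expect_identical(one$se, w$se)
  expect_equal(one$method, "ivw_fe")

  # weighted-mean invariance when all estimates agree
  expect_equal(ivw_fixed(data.frame(theta = rep(0.3, 4),
                                    se = c(0.1, 0.2, 0.5, 1)))$theta, 0.3)
  expect_error(ivw_fixed(list()), "no estimates")
})

test_that("Cochran's Q matches the chi-square oracle and its scale property", {
  est <- data.frame(theta = c(0.2, 0.4), se = c(0.05, 0.1))
  q <- cochran_q(est)
  expect_equal(q$q, 3.2)
  expect_equal(q$df, 1L)
  expect_equal(q$pval, stats::pchisq(3.2, 1, lower.tail = FALSE))
  expect_equal(q$pval, 0.0736383, tolerance = 1e-6)

  expect_equal(cochran_q(data.frame(theta = rep(0.3, 3), se = 0.1))$q, 0)
  expect_equal(cochran_q(data.frame(theta = rep(0.3, 3), se = 0.1))$pval, 1)

  # doubling every se quarters Q
  est2 <- data.frame(theta = est$theta, se = 2 * est$se)
  expect_equal(cochran_q(est2)$q, q$q / 4)
  expect_error(cochran_q(est[1, ]), "at least 2")
})

test_that("weighted median interpolates at cumulative weight 0.5", {
  # equal weights reduce to the plain median
  s <- make_set(beta_x = c(1, 1, 1), beta_y = c(1, 2, 3), se_y = 0.01)
  wm <- weighted_median(s, se_method = "none")
  expect_equal(wm$theta, 2)

  # weights {1,1,4}: s = {1/12, 1/4, 2/3}; interpolation gives 2.6
  s2 <- make_set(beta_x = c(1, 1, 1), beta_y = c(1, 2, 3),
                 se_y = c(1, 1, 0.5))
  expect_equal(weighted_median(s2, se_method = "none")$theta, 2.6)

  # same seed -> bit-identical bootstrap se
  s3 <- make_set(beta_x = c(0.1, 0.12, 0.08, 0.11), beta_y = c(0.02, 0.03, 0.01, 0.02),
                 se_x = 0.01, se_y = 0.005)
  a <- weighted_median(s3, n_boot = 200, seed = 99)
  b <- weighted_median(s3, n_boot = 200, seed = 99)
  expect_identical(a$se, b$se)
  expect_error(weighted_median(s3[1:2, ], seed = 1), "at least 3")
  expect_error(weighted_median(s3, n_boot = 10), "seed")
})

test_that("MR-Egger solves the weighted normal equations", {
  # perfect line: slope 2, intercept 0.1
  s <- make_set(beta_x = c(1, 2, 3), beta_y = c(2.1, 4.1, 6.1), se_y = 0.1)
  eg <- mr_egger(s)
  expect_equal(eg$slope$theta, 2, tolerance = 1e-12)
  expect_equal(eg$intercept$theta, 0.1, tolerance = 1e-12)

  # proportional effects: intercept 0, slope c
  s2 <- make_set(beta_x = c(0.5, 1, 1.5, 2), beta_y = 3 * c(0.5, 1, 1.5, 2),
                 se_y = c(0.1, 0.2, 0.1, 0.3))
  eg2 <- mr_egger(s2)
  expect_equal(eg2$slope$theta, 3, tolerance = 1e-12)
  expect_equal(eg2$intercept$theta, 0, tolerance = 1e-12)

  # random 10-SNP set vs explicit 2x2 normal-equations oracle
  set.seed(5)
  bx <- stats::rnorm(10, 0.1, 0.05); by <- stats::rnorm(10, 0.02, 0.01)
  sey <- stats::runif(10, 0.005, 0.02)
  s3 <- make_set(beta_x = bx, beta_y = by, se_y = sey)
  w <- 1 / sey^2
  sw <- sum(w); sx <- sum(w * bx); sxx <- sum(w * bx^2)
  sy <- sum(w * by); sxy <- sum(w * bx * by)
  det <- sw * sxx - sx^2
  slope_o <- (sw * sxy - sx * sy) / det
  int_o <- (sxx * sy - sx * sxy) / det
  eg3 <- mr_egger(s3)
  expect_equal(eg3$slope$theta, slope_o, tolerance = 1e-10)
  expect_equal(eg3$intercept$theta, int_o, tolerance = 1e-10)

  expect_error(mr_egger(make_set(beta_x = c(1, 1, 1), beta_y = c(1, 2, 3))),
               "singular")
  expect_error(mr_egger(s3[1:2, ]), "at least 3")
})

test_that("estimators are equivariant under a joint sign flip", {
  set.seed(8)
  bx <- stats::rnorm(8, 0.1, 0.03); by <- stats::rnorm(8, 0.02, 0.01)
  sey <- stats::runif(8, 0.005, 0.02)
  s <- make_set(beta_x = bx, beta_y = by, se_y = sey)
  sf <- make_set(beta_x = -bx, beta_y = -by, se_y = sey)

  expect_equal(ivw_fixed(wald_ratios(sf))$theta, ivw_fixed(wald_ratios(s))$theta)
  expect_equal(weighted_median(sf, se_method = "none")$theta,
               weighted_median(s, se_method = "none")$theta)
  eg <- mr_egger(s); egf <- mr_egger(sf)
  expect_equal(egf$slope$theta, eg$slope$theta, tolerance = 1e-12)
  expect_equal(egf$intercept$theta, -eg$intercept$theta, tolerance = 1e-12)
})

test_that("Egger constrained through the origin reproduces IVW exactly", {
  set.seed(13)
  for (rep in 1:25) {
    j <- sample(3:12, 1)
    bx <- stats::rnorm(j, 0.1, 0.05); by <- stats::rnorm(j, 0.02, 0.02)
    sey <- stats::runif(j, 0.005, 0.02)
    s <- make_set(beta_x = bx, beta_y = by, se_y = sey)
    # no-intercept WLS slope with weights 1/se_y^2 (algebraic identity with
    # first-order Wald-ratio IVW)
    w <- 1 / sey^2
    slope0 <- sum(w * bx * by) / sum(w * bx^2)
    expect_equal(ivw_fixed(wald_ratios(s))$theta, slope0, tolerance = 1e-10)
  }
})

test_that("mr_all bundles the battery consistently", {
  set.seed(21)
  s <- make_set(beta_x = stats::rnorm(6, -0.1, 0.02),
                beta_y = stats::rnorm(6, -0.002, 0.001), se_y = 0.002)
  res <- mr_all(s, n_boot = 50, seed = 4)
  expect_equal(res$ivw_fe$theta, ivw_fixed(res$wald)$theta)
  expect_equal(res$ivw_fe$n_snps, nrow(s))
  expect_s3_class(res$weighted_median, "mr_estimate")
  expect_equal(res$egger_slope$method, "egger_slope")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_mr_estimates(list(res$ivw_fe, res$weighted_median, res$egger_slope,
                          res$egger_intercept), path)
  tab <- utils::read.delim(path)
  expect_equal(tab$method,
               c("ivw_fe", "weighted_median", "egger_slope", "egger_intercept"))
})
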