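test_that("palindromic and intermediate-frequency predicates follow the definitions", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("C", "G"))
  expect_false(is_palindromic("G", "A"))

  expect_true(is_intermediate_af(0.50, c(0.42, 0.58)))
  expect_false(is_intermediate_af(0.10, c(0.42, 0.58)))
  expect_true(is_intermediate_af(NA_real_, c(0.42, 0.58)))  # conservative rule
  expect_error(is_intermediate_af(0.5, c(0.6, 0.4)))
})

test_that("harmonization aligns, flips, complements and excludes correctly", {
  ex <- gwas_table(data.frame(
    rsid = c("s_flip", "s_comp", "s_pal", "s_mm", "s_ok"),
    chrom = "12", pos = 1:5, eaf = c(0.3, 0.3, 0.5, 0.3, 0.2),
    ea = c("G", "G", "A", "A", "A"), nea = c("A", "A", "T", "G", "G"),
    beta = c(-0.05, -0.05, -0.05, -0.05, -0.05), se = 0.01, pval = 1e-4, n = 10),
    "exposure")
  oc <- gwas_table(data.frame(
    rsid = c("s_flip", "s_comp", "s_pal", "s_mm", "s_ok"),
    chrom = "12", pos = 1:5, eaf = c(0.7, 0.3, 0.5, 0.3, 0.2),
    ea = c("A", "C", "A", "C", "A"), nea = c("G", "T", "T", "G", "G"),
    beta = c(0.002, 0.003, 0.004, 0.005, 0.006), se = 0.002, pval = 1e-3, n = 10),
    "outcome")
  h <- harmonize_dataset(ex, oc)

  flip <- h[h$rsid == "s_flip", ]
  expect_equal(flip$status, "flipped")
  expect_equal(flip$beta_y, -0.002)   # sign flip under allele swap
  expect_equal(flip$eaf_y, 0.3)       # 1 - 0.7

  # opposite-strand report (exposure G/A vs outcome C/T): complemented, aligned,
  # betas unchanged — the oracle is complement-then-rematch, which gives "same"
  comp <- h[h$rsid == "s_comp", ]
  expect_equal(comp$status, "aligned")
  expect_equal(comp$beta_y, 0.003)

  ok <- h[h$rsid == "s_ok", ]
  expect_equal(ok$beta_y, 0.006)

  excl <- attr(h, "exclusions")
  expect_equal(excl$reason[excl$rsid == "s_pal"], "palindromic")
  expect_equal(excl$reason[excl$rsid == "s_mm"], "mismatch")
  expect_equal(nrow(h), 3L)

  expect_error(harmonize_dataset(ex, make_table(2, rsid = c("x1", "x2"))),
               "no shared")
})

test_that("palindromic SNPs outside the band are kept; missing eaf excludes", {
  ex <- make_table(2, ea = c("A", "C"), nea = c("T", "G"), eaf = c(0.1, NA))
  oc <- make_table(2, ea = c("A", "C"), nea = c("T", "G"), eaf = c(0.1, 0.2),
                   beta = 0.01)
  h <- harmonize_dataset(ex, oc)
  expect_equal(h$rsid, "rs1")  # outside band retained at nominal orientation
  expect_equal(attr(h, "exclusions")$reason, "palindromic")  # missing eaf
})

test_that("a single palindromic-intermediate SNP among eight leaves seven pairs", {
  eaf <- c(rep(0.25, 7), 0.5)
  ea <- c(rep("A", 7), "A"); nea <- c(rep("G", 7), "T")
  ex <- make_table(8, ea = ea, nea = nea, eaf = eaf)
  oc <- make_table(8, ea = ea, nea = nea, eaf = eaf, beta = 0.001)
  h <- harmonize_dataset(ex, oc)
  expect_equal(nrow(h), 7L)
  expect_equal(attr(h, "exclusions")$rsid, "rs8")
})

test_that("double harmonization is idempotent", {
  ex <- make_table(5, ea = c("G", "A", "A", "C", "T"),
                   nea = c("A", "C", "G", "T", "C"),
                   beta = c(-0.05, 0.04, -0.03, 0.02, -0.01))
  oc <- make_table(5, ea = c("A", "A", "G", "C", "C"),
                   nea = c("G", "C", "A", "T", "T"),
                   beta = c(0.002, -0.001, 0.003, 0.004, -0.002))
  h1 <- harmonize_dataset(ex, oc)
  # rebuild the outcome from the harmonized pairs: a second pass must be identity
  oc2 <- gwas_table(data.frame(rsid = h1$rsid, chrom = "12",
                               pos = seq_len(nrow(h1)), ea = h1$ea, nea = h1$nea,
                               eaf = h1$eaf_y, beta = h1$beta_y, se = h1$se_y,
                               pval = 0.5, n = 10), "outcome2")
  h2 <- harmonize_dataset(ex, oc2)
  expect_equal(h2$beta_y, h1$beta_y)
  expect_equal(h2$beta_x, h1$beta_x)
  expect_true(all(h2$status == "aligned"))
})

test_that("flipping the whole outcome table leaves harmonized effects unchanged", {
  set.seed(11)
  n <- 12
  ea <- sample(c("A", "C"), n, TRUE); nea <- ifelse(ea == "A", "G", "T")
  ex <- make_table(n, ea = ea, nea = nea, beta = stats::rnorm(n, 0, 0.05),
                   eaf = stats::runif(n, 0.05, 0.4))
  oc <- make_table(n, ea = ea, nea = nea, beta = stats::rnorm(n, 0, 0.01),
                   eaf = stats::runif(n, 0.05, 0.4))
  oc_fl <- gwas_table(data.frame(rsid = oc$rsid, chrom = oc$chrom, pos = oc$pos,
                                 ea = oc$nea, nea = oc$ea, eaf = 1 - oc$eaf,
                                 beta = -oc$beta, se = oc$se, pval = oc$pval,
                                 n = oc$n), "flipped_outcome")
  h1 <- harmonize_dataset(ex, oc)
  h2 <- harmonize_dataset(ex, oc_fl)
  expect_equal(h2$beta_x, h1$beta_x)
  expect_equal(h2$beta_y, h1$beta_y)
})

test_that("orientation to inhibition negates pairs jointly and drops null exposures", {
  s <- make_set(beta_x = c(0.04, -0.03, 0), beta_y = c(0.001, 0.002, 0.003))
  o <- orient_to_inhibition(s)
  expect_equal(nrow(o), 2L)
  expect_equal(o$beta_x, c(-0.04, -0.03))
  expect_equal(o$beta_y, c(-0.001, 0.002))
  expect_equal(o$ea[1], "G")  # alleles swapped on the re-oriented pair
  excl <- attr(o, "exclusions")
  expect_equal(excl$reason[excl$rsid == "rs3"], "null-exposure")

  # Wald ratios are invariant under the re-orientation
  s2 <- make_set(beta_x = c(0.04, -0.03, 0.05), beta_y = c(0.001, 0.002, -0.004))
  expect_equal(wald_ratios(orient_to_inhibition(s2))$theta, wald_ratios(s2)$theta)
})
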