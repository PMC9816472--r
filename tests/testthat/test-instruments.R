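test_that("cis-window extraction applies the flanked bounds inclusively", {
  region <- gene_region("12", 6328757, 6342114, flank = 15000)
  pos <- c(6313756, 6313757, 6330000, 6357114, 6357115)
  t <- make_table(5, pos = pos)
  out <- extract_cis_window(t, region)
  expect_equal(out$pos, c(6313757, 6330000, 6357114))

  # flank = 0 keeps a SNP exactly at start; other chromosome never matches
  r0 <- gene_region("12", 6328757, 6342114, flank = 0)
  expect_equal(extract_cis_window(make_table(1, pos = 6328757), r0)$pos, 6328757)
  expect_equal(nrow(extract_cis_window(make_table(1, pos = 6330000, chrom = "11"), r0)), 0L)

  # idempotent
  expect_equal(as.data.frame(extract_cis_window(out, region)), as.data.frame(out))
})

test_that("concordance filter enforces membership, direction and p-value", {
  cand <- make_table(4, beta = c(-0.05, -0.05, -0.05, -0.05))
  b1 <- make_table(4, beta = c(-0.03, -0.03, 0.03, -0.03),
                   pval = c(0.01, 0.2, 0.01, 0.01))
  b2 <- make_table(3, beta = -0.02, pval = 0.01)  # rs4 absent
  res <- concordance_filter(cand, list(b1, b2), p_threshold = 0.05,
                            required_direction = -1)
  expect_equal(res$kept$rsid, "rs1")
  expect_equal(res$report$excluded[["rs3"]], "direction")
  expect_equal(res$report$excluded[["rs4"]], "missing")
  expect_equal(res$report$excluded[["rs2"]], "pvalue")
  expect_equal(res$report$n_candidates, 4L)
  expect_equal(res$report$n_with_any_association, 4L)
  # counts reconcile: kept + excluded = candidates
  expect_equal(nrow(res$kept) + length(res$report$excluded), 4L)

  # invariant to biomarker ordering
  res2 <- concordance_filter(cand, list(b2, b1))
  expect_equal(res2$kept$rsid, res$kept$rsid)
  expect_mapequal(as.list(res2$report$excluded), as.list(res$report$excluded))

  # biomarker betas are oriented to the candidate's effect allele
  b_sw <- make_table(4, ea = "G", nea = "A", beta = 0.03, pval = 0.01)
  res3 <- concordance_filter(cand, list(b_sw))
  expect_equal(res3$kept$rsid, paste0("rs", 1:4))

  expect_error(concordance_filter(cand, list()), "non-empty")
})

test_that("greedy LD clumping matches the stated rule", {
  # independent SNPs survive untouched
  t3 <- make_table(3, pval = c(1e-8, 1e-6, 1e-4))
  ld0 <- simulate_ld_matrix(3, 0, rsids = t3$rsid)
  expect_equal(ld_clump(t3, ld0, 0.001)$rsid, t3$rsid)

  # pairwise: the more significant SNP wins
  t2 <- make_table(2, pval = c(1e-8, 1e-4))
  r2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  ld2 <- ld_matrix(t2$rsid, r2)
  kept <- ld_clump(t2, ld2, 0.001)
  expect_equal(kept$rsid, "rs1")
  expect_equal(attr(kept, "clump_dropped"), c(rs2 = "rs1"))

  # chain LD: output equals brute-force re-execution of the greedy rule
  t5 <- make_table(5, pval = c(1e-4, 1e-8, 1e-6, 1e-3, 1e-7))
  r <- diag(5)
  for (i in 1:4) r[i, i + 1] <- r[i + 1, i] <- 0.9
  ld5 <- ld_matrix(t5$rsid, r)
  expect_equal(ld_clump(t5, ld5, 0.001)$rsid,
               clump_oracle(t5$rsid, t5$pval, t5$pos, ld5$r2, 0.001))

  expect_error(ld_clump(make_table(2, rsid = c("rsX", "rsY")), ld5), "absent")
})

test_that("clumped sets are mutually independent and match the oracle on random LD", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    rho <- stats::runif(1, 0, 0.95)
    t <- make_table(n, pval = stats::runif(n, 1e-10, 1))
    perm <- sample(n)  # LD structure decoupled from p-value order
    ld <- ld_matrix(t$rsid, simulate_ld_matrix(n, rho)$r2[perm, perm])
    thr <- sample(c(0.001, 0.1, 0.5), 1)
    kept <- ld_clump(t, ld, thr)
    expect_equal(kept$rsid, clump_oracle(t$rsid, t$pval, t$pos, ld$r2, thr))
    if (nrow(kept) > 1) {
      sub <- ld$r2[kept$rsid, kept$rsid]
      expect_lte(max(sub[upper.tri(sub)]), thr)
    }
  }
})

test_that("LD matrices round-trip through TSV and reject bad input", {
  ld <- simulate_ld_matrix(4, 0.6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ld_matrix(ld, path)
  ld2 <- read_ld_matrix(path)
  expect_equal(ld2$rsids, ld$rsids)
  expect_equal(ld2$r2, ld$r2, tolerance = 1e-12)

  expect_error(ld_matrix(c("a", "b"), matrix(c(1, 2, 2, 1), 2)), "\\[0,1\\]")
  expect_error(ld_matrix(c("a", "b"), matrix(c(1, 0.1, 0.3, 1), 2)), "symmetric")
  expect_error(ld_matrix(c("a", "b"), matrix(c(0.9, 0.1, 0.1, 1), 2)), "diagonal")
})
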