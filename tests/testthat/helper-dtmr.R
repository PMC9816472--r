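# Shared fixture builders. All tables are built in code; no stored data.

# Minimal well-formed table; override any field via ...
make_table <- function(snps = 3, trait = "t", scale = "continuous", ...) {
  df <- data.frame(rsid = paste0("rs", seq_len(snps)), chrom = "12",
                   pos = 6320000 + seq_len(snps) * 100,
                   ea = "A", nea = "G", eaf = 0.25,
                   beta = -0.05, se = 0.01, pval = 1e-4, n = 1000,
                   stringsAsFactors = FALSE)
  over <- list(...)
  for (f in names(over)) df[[f]] <- over[[f]]
  gwas_table(df, trait_name = trait, trait_scale = scale)
}

# Harmonized set straight from beta/se vectors (already aligned).
make_set <- function(beta_x, beta_y, se_x = 0.01, se_y = 0.01) {
  j <- length(beta_x)
  ex <- make_table(j, beta = beta_x, se = rep_len(se_x, j))
  oc <- make_table(j, beta = beta_y, se = rep_len(se_y, j))
  harmonize_dataset(ex, oc)
}

# Independent greedy-clump oracle: literal re-execution of the stated rule.
clump_oracle <- function(rsids, pval, pos, r2, threshold) {
  ord <- order(pval, pos, rsids)
  remaining <- rsids[ord]
  kept <- character(0)
  while (length(remaining) > 0) {
    best <- remaining[1]
    kept <- c(kept, best)
    remaining <- remaining[-1]
    remaining <- remaining[r2[best, remaining] <= threshold]
  }
  kept
}

# Independent weighted-median oracle: bracket search + manual interpolation.
wm_oracle <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]; w <- w[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= s[1]) return(theta[1])
  if (0.5 >= s[length(s)]) return(theta[length(s)])
  k <- max(which(s <= 0.5))
  if (s[k] == 0.5) return(theta[k])
  theta[k] + (theta[k + 1] - theta[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}
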