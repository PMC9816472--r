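# Harmonization of exposure and outcome summary statistics to one shared
# effect-allele orientation, with palindromic-SNP exclusion.

#' Is an allele pair palindromic?
#'
#' A/T and C/G pairs read the same on both strands, so their orientation
#' cannot be resolved from alleles alone.
#'
#' @param ea,nea Single-nucleotide alleles.
#' @return Logical.
#' @export
is_palindromic <- function(ea, nea) {
  (ea == "A" & nea == "T") | (ea == "T" & nea == "A") |
    (ea == "C" & nea == "G") | (ea == "G" & nea == "C")
}

#' Is an effect-allele frequency in the intermediate band?
#'
#' Palindromic SNPs with frequency near 0.5 cannot be strand-resolved even
#' with frequency information; a missing frequency is conservatively treated
#' as intermediate.
#'
#' @param eaf Effect-allele frequency in [0, 1], or `NA`.
#' @param band Length-2 numeric `(low, high)` with `0 <= low < high <= 1`;
#'   default `c(0.42, 0.58)`, the two-sample MR convention.
#' @return Logical: `TRUE` iff `low <= eaf <= high` or `eaf` is missing.
#' @export
is_intermediate_af <- function(eaf, band = c(0.42, 0.58)) {
  stopifnot(length(band) == 2L, band[1] >= 0, band[1] < band[2], band[2] <= 1)
  is.na(eaf) | (eaf >= band[1] & eaf <= band[2])
}

#' @noRd
new_harmonized_set <- function(pairs, exclusions) {
  rownames(pairs) <- NULL
  structure(pairs, exclusions = exclusions,
            class = c("harmonized_set", "data.frame"))
}

#' @export
`[.harmonized_set` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("beta_x", "beta_y") %in% names(out))) {
    attr(out, "exclusions") <- attr(x, "exclusions")
    class(out) <- c("harmonized_set", "data.frame")
  }
  out
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> pairs=%d excluded=%d\n",
              nrow(x), nrow(attr(x, "exclusions"))))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  invisible(x)
}

#' Harmonize exposure and outcome tables to one effect-allele orientation
#'
#' For each rsid shared by the two tables: outcome alleles matching the
#' exposure's are kept as `aligned`; a swapped ea/nea pair flips the outcome
#' (`beta_y` negated, `eaf_y` replaced by `1 - eaf_y`); non-palindromic SNPs
#' reported on opposite strands are complemented and then matched; palindromic
#' SNPs whose exposure or outcome frequency is in the intermediate band (or
#' missing) are excluded (`palindromic`); irreconcilable allele pairs are
#' excluded (`mismatch`). Palindromic SNPs outside the band are kept at their
#' nominal orientation — no frequency-based re-stranding is attempted.
#'
#' @param exposure,outcome `gwas_table`s.
#' @param band Intermediate-frequency band, see [is_intermediate_af()].
#' @return A `harmonized_set`: a data frame of aligned/flipped pairs with
#'   columns `rsid, ea, nea, beta_x, se_x, beta_y, se_y, eaf_x, eaf_y, status`
#'   and an `exclusions` attribute (data frame `rsid`, `reason`).
#' @export
harmonize_dataset <- function(exposure, outcome, band = c(0.42, 0.58)) {
  stopifnot(inherits(exposure, "gwas_table"), inherits(outcome, "gwas_table"))
  shared <- intersect(exposure$rsid, outcome$rsid)
  if (length(shared) == 0L) {
    stop("harmonize_dataset: no shared rsids between exposure and outcome",
         call. = FALSE)
  }
  ex <- as.data.frame(exposure[match(shared, exposure$rsid), ])
  oc <- as.data.frame(outcome[match(shared, outcome$rsid), ])

  pal <- is_palindromic(ex$ea, ex$nea)
  same <- oc$ea == ex$ea & oc$nea == ex$nea
  swap <- oc$ea == ex$nea & oc$nea == ex$ea
  # strand complement resolves only non-palindromic pairs
  can_comp <- !pal & !is_palindromic(oc$ea, oc$nea)
  cea <- complement_allele(oc$ea); cnea <- complement_allele(oc$nea)
  comp_same <- can_comp & cea == ex$ea & cnea == ex$nea
  comp_swap <- can_comp & cea == ex$nea & cnea == ex$ea

  status <- rep(NA_character_, length(shared))
  status[comp_swap] <- "flipped"
  status[comp_same] <- "aligned"
  status[swap] <- "flipped"
  status[same] <- "aligned"
  mismatch <- is.na(status)
  pal_excl <- !mismatch & pal &
    (is_intermediate_af(ex$eaf, band) | is_intermediate_af(oc$eaf, band))

  keep <- !mismatch & !pal_excl
  flip <- keep & status == "flipped"
  beta_y <- ifelse(flip, -oc$beta, oc$beta)
  eaf_y <- ifelse(flip, 1 - oc$eaf, oc$eaf)
  pairs <- data.frame(rsid = ex$rsid, ea = ex$ea, nea = ex$nea,
                      beta_x = ex$beta, se_x = ex$se,
                      beta_y = beta_y, se_y = oc$se,
                      eaf_x = ex$eaf, eaf_y = eaf_y,
                      status = status, stringsAsFactors = FALSE)[keep, , drop = FALSE]
  exclusions <- data.frame(
    rsid = ex$rsid[!keep],
    reason = ifelse(mismatch[!keep], "mismatch", "palindromic"),
    stringsAsFactors = FALSE)
  rownames(exclusions) <- NULL
  new_harmonized_set(pairs, exclusions)
}

#' Re-orient a harmonized set so the effect allele lowers the exposure
#'
#' Pairs with `beta_x > 0` are re-oriented — ea/nea swapped, both betas
#' negated, both frequencies complemented — so that every effect allele is
#' the biomarker-lowering (inhibition-proxying) allele. Pairs with
#' `beta_x == 0` are excluded with reason `null-exposure`. Wald ratios are
#' invariant under this operation since both betas negate together.
#'
#' @param set A `harmonized_set`.
#' @return A `harmonized_set` with every `beta_x < 0`.
#' @export
orient_to_inhibition <- function(set) {
  stopifnot(inherits(set, "harmonized_set"))
  if (nrow(set) == 0L) stop("orient_to_inhibition: empty set", call. = FALSE)
  exclusions <- attr(set, "exclusions")
  null_x <- set$beta_x == 0
  if (any(null_x)) {
    exclusions <- rbind(exclusions,
                        data.frame(rsid = set$rsid[null_x], reason = "null-exposure"))
    set <- set[!null_x, , drop = FALSE]
  }
  flip <- set$beta_x > 0
  if (any(flip)) {
    ea <- set$ea[flip]
    set$ea[flip] <- set$nea[flip]
    set$nea[flip] <- ea
    set$beta_x[flip] <- -set$beta_x[flip]
    set$beta_y[flip] <- -set$beta_y[flip]
    set$eaf_x[flip] <- 1 - set$eaf_x[flip]
    set$eaf_y[flip] <- 1 - set$eaf_y[flip]
  }
  new_harmonized_set(as.data.frame(set), exclusions)
}

#' Write a harmonization exclusion log
#'
#' @param set A `harmonized_set`.
#' @param path Output TSV path (columns `rsid`, `reason`).
#' @export
write_exclusion_log <- function(set, path) {
  stopifnot(inherits(set, "harmonized_set"))
  utils::write.table(attr(set, "exclusions"), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
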