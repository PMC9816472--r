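# cis-instrument selection: gene-window extraction, tri-biomarker concordance
# filtering, greedy LD clumping.

#' Gene region with flanking window
#'
#' @param chrom Chromosome label.
#' @param start,end 1-based inclusive base-pair bounds of the gene body
#'   (`start <= end`).
#' @param flank Non-negative flanking window in base pairs added on both sides.
#' @return A list of class `gene_region`.
#' @examples
#' # TNFRSF1A gene body (GRCh38) with the conventional +/- 15 kb cis window
#' gene_region("12", 6328757, 6342114, flank = 15000)
#' @export
gene_region <- function(chrom, start, end, flank = 0) {
  stopifnot(length(chrom) == 1L, length(start) == 1L, length(end) == 1L)
  start <- as.numeric(start); end <- as.numeric(end); flank <- as.numeric(flank)
  if (!is.finite(start) || !is.finite(end) || start > end) {
    stop("gene_region: need finite start <= end", call. = FALSE)
  }
  if (!is.finite(flank) || flank < 0) stop("gene_region: flank must be >= 0", call. = FALSE)
  structure(list(chrom = as.character(chrom), start = start, end = end, flank = flank),
            class = "gene_region")
}

#' Extract SNPs inside a cis window
#'
#' Keeps records on the region's chromosome with
#' `start - flank <= pos <= end + flank`; input order is preserved. Records
#' with missing chromosome or position never match.
#'
#' @param table A `gwas_table`.
#' @param region A [gene_region()].
#' @return A `gwas_table` restricted to the window (possibly empty).
#' @export
extract_cis_window <- function(table, region) {
  stopifnot(inherits(table, "gwas_table"), inherits(region, "gene_region"))
  lo <- region$start - region$flank
  hi <- region$end + region$flank
  keep <- !is.na(table$chrom) & table$chrom == region$chrom &
    !is.na(table$pos) & table$pos >= lo & table$pos <= hi
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
`[.gwas_table` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && identical(names(out), GWAS_FIELDS)) {
    attr(out, "trait_name") <- attr(x, "trait_name")
    attr(out, "trait_scale") <- attr(x, "trait_scale")
    class(out) <- c("gwas_table", "data.frame")
  }
  out
}

# Orient a biomarker row's beta to a candidate's effect allele. Returns the
# signed beta, or NA when the allele pairs are irreconcilable. Strand
# complement is tried for non-palindromic pairs only.
#' @noRd
orient_beta_to <- function(cand_ea, cand_nea, ea, nea, beta) {
  if (ea == cand_ea && nea == cand_nea) return(beta)
  if (ea == cand_nea && nea == cand_ea) return(-beta)
  if (!is_palindromic(ea, nea) && !is_palindromic(cand_ea, cand_nea)) {
    cea <- complement_allele(ea); cnea <- complement_allele(nea)
    if (cea == cand_ea && cnea == cand_nea) return(beta)
    if (cea == cand_nea && cnea == cand_ea) return(-beta)
  }
  NA_real_
}

#' Tri-biomarker concordance filter
#'
#' Keeps candidate SNPs that (a) appear in every biomarker table, (b) show the
#' required direction of effect in all (or, optionally, any) biomarker tables
#' after orienting each biomarker's beta to the candidate's effect allele, and
#' (c) reach `pval < p_threshold` in the same tables. Exclusion reasons are
#' `"missing"`, `"allele_mismatch"`, `"direction"` and `"pvalue"`, assigned in
#' that order of precedence.
#'
#' @param candidates A `gwas_table` of candidate SNPs.
#' @param biomarkers A non-empty list of `gwas_table`s (e.g. the protein, a
#'   CRP-like and a WBC-like GWAS).
#' @param p_threshold Associations require `pval < p_threshold` (default 0.05).
#' @param required_direction `-1` to keep biomarker-lowering alleles (the
#'   proxied-inhibition convention), `+1` for raising.
#' @param require_all If `TRUE` (default, the strict reading) direction and
#'   p-value must pass in every biomarker table; if `FALSE`, in at least one
#'   (membership in every table is still required).
#' @return A list with `kept` (a `gwas_table`) and `report` (a
#'   `selection_report`: counts `n_candidates`, `n_with_any_association`,
#'   `n_concordant`, `n_after_clump` (NA here), and `excluded`, a named
#'   character vector of rsid -> reason).
#' @export
concordance_filter <- function(candidates, biomarkers, p_threshold = 0.05,
                               required_direction = -1, require_all = TRUE) {
  stopifnot(inherits(candidates, "gwas_table"))
  if (!is.list(biomarkers) || length(biomarkers) == 0L) {
    stop("concordance_filter: biomarkers must be a non-empty list of gwas_table",
         call. = FALSE)
  }
  if (nrow(candidates) == 0L) stop("concordance_filter: no candidates", call. = FALSE)
  if (!p_threshold > 0 || !p_threshold < 1) {
    stop("concordance_filter: p_threshold must lie in (0,1)", call. = FALSE)
  }
  required_direction <- sign(required_direction)
  stopifnot(required_direction %in% c(-1, 1))

  excluded <- character(0)
  n_any <- 0L
  keep <- logical(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    hits <- lapply(biomarkers, function(b) b[b$rsid == cand$rsid, , drop = FALSE])
    present <- vapply(hits, nrow, integer(1)) > 0L
    if (any(present)) n_any <- n_any + 1L
    if (!all(present)) {
      excluded[cand$rsid] <- "missing"
      next
    }
    oriented <- vapply(hits, function(h) {
      orient_beta_to(cand$ea, cand$nea, h$ea[1], h$nea[1], h$beta[1])
    }, numeric(1))
    if (anyNA(oriented)) {
      excluded[cand$rsid] <- "allele_mismatch"
      next
    }
    dir_ok <- sign(oriented) == required_direction
    p_ok <- vapply(hits, function(h) h$pval[1] < p_threshold, logical(1))
    pass <- if (require_all) all(dir_ok) && all(p_ok) else any(dir_ok & p_ok)
    if (!pass) {
      excluded[cand$rsid] <- if ((require_all && !all(dir_ok)) ||
                                 (!require_all && !any(dir_ok))) "direction" else "pvalue"
      next
    }
    keep[i] <- TRUE
  }
  kept <- candidates[keep, , drop = FALSE]
  rownames(kept) <- NULL
  report <- structure(list(n_candidates = nrow(candidates),
                           n_with_any_association = n_any,
                           n_concordant = nrow(kept),
                           n_after_clump = NA_integer_,
                           excluded = excluded),
                      class = "selection_report")
  list(kept = kept, report = report)
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf(paste0("<selection_report> candidates=%d with_any_association=%d ",
                     "concordant=%d after_clump=%s excluded=%d\n"),
              x$n_candidates, x$n_with_any_association, x$n_concordant,
              ifelse(is.na(x$n_after_clump), "NA", x$n_after_clump),
              length(x$excluded)))
  invisible(x)
}

#' LD matrix of squared correlations
#'
#' @param rsids Character vector of SNP identifiers.
#' @param r2 Square symmetric matrix of squared correlations in [0, 1] with a
#'   unit diagonal, one row/column per rsid.
#' @return A list of class `ld_matrix`.
#' @export
ld_matrix <- function(rsids, r2) {
  rsids <- as.character(rsids)
  r2 <- as.matrix(r2)
  stopifnot(length(rsids) == nrow(r2), nrow(r2) == ncol(r2))
  if (anyDuplicated(rsids)) stop("ld_matrix: duplicate rsids", call. = FALSE)
  if (any(r2 < -1e-12 | r2 > 1 + 1e-12, na.rm = TRUE)) {
    stop("ld_matrix: r2 entries must lie in [0,1]", call. = FALSE)
  }
  if (max(abs(r2 - t(r2))) > 1e-8) stop("ld_matrix: r2 must be symmetric", call. = FALSE)
  if (max(abs(diag(r2) - 1)) > 1e-8) stop("ld_matrix: unit diagonal required", call. = FALSE)
  dimnames(r2) <- list(rsids, rsids)
  structure(list(rsids = rsids, r2 = r2), class = "ld_matrix")
}

#' Read / write an LD matrix TSV
#'
#' File format: tab-separated; header row of rsids preceded by a `rsid`
#' corner label; first column the rsid, remaining columns the square r2
#' matrix.
#'
#' @param path File path.
#' @return `read_ld_matrix` returns an [ld_matrix()].
#' @export
read_ld_matrix <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  rsids <- as.character(raw[[1]])
  ld_matrix(rsids, as.matrix(raw[, -1, drop = FALSE]))
}

#' @param ld An [ld_matrix()].
#' @rdname read_ld_matrix
#' @export
write_ld_matrix <- function(ld, path) {
  stopifnot(inherits(ld, "ld_matrix"))
  df <- data.frame(rsid = ld$rsids, ld$r2, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Greedy LD clumping
#'
#' Sorts SNPs by p-value (ties broken by position, then rsid), repeatedly
#' keeps the best remaining SNP and discards every remaining SNP with
#' `r2 > r2_threshold` against it. The output is mutually independent at the
#' threshold, and every discarded SNP is in LD above the threshold with a kept
#' SNP of smaller or equal p-value.
#'
#' @param table A `gwas_table`; every rsid must be present in `ld`.
#' @param ld An [ld_matrix()].
#' @param r2_threshold Retention requires pairwise `r2 <= r2_threshold`
#'   (default 0.001, the stringent drug-target convention).
#' @return The clumped `gwas_table`, with attribute `clump_dropped`, a named
#'   character vector mapping each discarded rsid to the kept rsid that
#'   removed it.
#' @export
ld_clump <- function(table, ld, r2_threshold = 0.001) {
  stopifnot(inherits(table, "gwas_table"), inherits(ld, "ld_matrix"))
  missing <- setdiff(table$rsid, ld$rsids)
  if (length(missing) > 0L) {
    stop("ld_clump: rsid(s) absent from LD matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(table) == 0L) return(table)
  ord <- order(table$pval, table$pos, table$rsid)
  queue <- table$rsid[ord]
  kept <- character(0)
  dropped <- character(0)
  while (length(queue) > 0L) {
    best <- queue[1]
    kept <- c(kept, best)
    queue <- queue[-1]
    if (length(queue) > 0L) {
      in_ld <- ld$r2[best, queue] > r2_threshold
      if (any(in_ld)) {
        newly <- stats::setNames(rep(best, sum(in_ld)), queue[in_ld])
        dropped <- c(dropped, newly)
        queue <- queue[!in_ld]
      }
    }
  }
  out <- table[match(kept, table$rsid), , drop = FALSE]
  rownames(out) <- NULL
  # invariant: the kept set is mutually independent at the threshold
  if (nrow(out) > 1L) {
    sub <- ld$r2[out$rsid, out$rsid]
    stopifnot(max(sub[upper.tri(sub)]) <= r2_threshold)
  }
  attr(out, "clump_dropped") <- dropped
  out
}
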