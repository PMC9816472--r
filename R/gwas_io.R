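# GWAS summary-statistics tables: construction, validation, TSV input/output.

GWAS_FIELDS <- c("rsid", "chrom", "pos", "ea", "nea", "eaf", "beta", "se", "pval", "n")
GWAS_MANDATORY <- c("rsid", "ea", "nea", "beta", "se", "pval")

#' Column mapping for GWAS summary-statistics files
#'
#' Maps the canonical per-SNP field names onto the column headers of a source
#' file. `rsid`, `ea`, `nea`, `beta`, `se` and `pval` are mandatory; the
#' remaining fields (`chrom`, `pos`, `eaf`, `n`) may be set to `NA` when the
#' source file lacks them, in which case the corresponding column is filled
#' with missing values.
#'
#' @param rsid,chrom,pos,ea,nea,eaf,beta,se,pval,n Source-file column header
#'   for each field, or `NA` for an absent optional column.
#' @return A named character vector of class `column_map`.
#' @examples
#' column_map(rsid = "SNP", beta = "Effect", se = "StdErr")
#' @export
column_map <- function(rsid = "rsid", chrom = "chrom", pos = "pos",
                       ea = "ea", nea = "nea", eaf = "eaf",
                       beta = "beta", se = "se", pval = "pval", n = "n") {
  m <- c(rsid = rsid, chrom = chrom, pos = pos, ea = ea, nea = nea,
         eaf = eaf, beta = beta, se = se, pval = pval, n = n)
  missing_mand <- GWAS_MANDATORY[is.na(m[GWAS_MANDATORY])]
  if (length(missing_mand) > 0L) {
    stop("column_map: mandatory fields cannot be NA: ",
         paste(missing_mand, collapse = ", "), call. = FALSE)
  }
  structure(m, class = "column_map")
}

#' Construct a validated GWAS summary-statistics table
#'
#' Builds a `gwas_table` from a data frame holding one row per SNP. Alleles
#' are normalized to uppercase; rows violating the per-SNP invariants
#' (single-nucleotide alleles with `ea != nea`, finite `beta`, `se > 0`,
#' `pval` in (0, 1], `eaf` in [0, 1] when present) are dropped with a message,
#' as are duplicated rsids beyond the first occurrence. `eaf`, `n`, `chrom`
#' and `pos` may be missing (`NA`).
#'
#' @param x Data frame with (a superset of) the canonical columns
#'   `rsid, chrom, pos, ea, nea, eaf, beta, se, pval, n`.
#' @param trait_name Label for the trait the table describes.
#' @param trait_scale One of `"continuous"`, `"log_continuous"`, `"log_odds"`,
#'   `"absolute_risk"` — the scale `beta` is measured on.
#' @return A data frame of class `gwas_table` with attributes `trait_name`,
#'   `trait_scale` and `n_dropped` (count of rows removed by validation).
#' @export
gwas_table <- function(x, trait_name, trait_scale = "continuous") {
  trait_scale <- match.arg(trait_scale, TRAIT_SCALES)
  stopifnot(is.data.frame(x))
  for (f in setdiff(GWAS_FIELDS, names(x))) x[[f]] <- NA
  x <- x[GWAS_FIELDS]
  x$rsid <- as.character(x$rsid)
  x$chrom <- as.character(x$chrom)
  x$pos <- as.numeric(x$pos)
  x$ea <- toupper(as.character(x$ea))
  x$nea <- toupper(as.character(x$nea))
  for (f in c("eaf", "beta", "se", "pval", "n")) x[[f]] <- as.numeric(x[[f]])

  ok <- !is.na(x$rsid) & nzchar(x$rsid) &
    x$ea %in% NUCLEOTIDES & x$nea %in% NUCLEOTIDES & x$ea != x$nea &
    is.finite(x$beta) &
    is.finite(x$se) & x$se > 0 &
    is.finite(x$pval) & x$pval > 0 & x$pval <= 1 &
    (is.na(x$eaf) | (x$eaf >= 0 & x$eaf <= 1)) &
    (is.na(x$pos) | (is.finite(x$pos) & x$pos >= 1))
  ok[is.na(ok)] <- FALSE
  ok <- ok & !duplicated(x$rsid)
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    message(sprintf("gwas_table(%s): dropped %d of %d rows failing validation",
                    trait_name, n_dropped, nrow(x)))
  }
  out <- x[ok, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            trait_name = trait_name,
            trait_scale = trait_scale,
            n_dropped = n_dropped,
            class = c("gwas_table", "data.frame"))
}

#' @export
print.gwas_table <- function(x, ...) {
  cat(sprintf("<gwas_table> trait=%s scale=%s snps=%d\n",
              attr(x, "trait_name"), attr(x, "trait_scale"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Read a GWAS summary-statistics table from TSV
#'
#' Reads a tab-separated file with one header row, remaps columns through
#' `column_map`, and validates the result via [gwas_table()]. Missing values
#' may be encoded as `NA` or empty fields.
#'
#' @param path Path to the TSV file.
#' @param map A [column_map()].
#' @param trait_name,trait_scale Passed to [gwas_table()].
#' @return A `gwas_table`.
#' @export
read_gwas_table <- function(path, map = column_map(), trait_name = basename(path),
                            trait_scale = "continuous") {
  if (!file.exists(path)) stop("read_gwas_table: no such file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           na.strings = c("NA", ""), check.names = FALSE,
                           colClasses = "character")
  map <- unclass(map)
  present <- map[!is.na(map)]
  absent_mand <- intersect(names(present)[!present %in% names(raw)], GWAS_MANDATORY)
  if (length(absent_mand) > 0L) {
    stop("read_gwas_table: mapped column(s) not in header: ",
         paste(map[absent_mand], collapse = ", "), call. = FALSE)
  }
  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (f in GWAS_FIELDS) {
    col <- map[[f]]
    df[[f]] <- if (!is.na(col) && col %in% names(raw)) raw[[col]] else NA
  }
  out <- gwas_table(df, trait_name = trait_name, trait_scale = trait_scale)
  if (nrow(out) == 0L) {
    stop("read_gwas_table: no valid rows in ", path, call. = FALSE)
  }
  out
}

#' Write a GWAS summary-statistics table to TSV
#'
#' Writes the canonical column order
#' `rsid, chrom, pos, ea, nea, eaf, beta, se, pval, n`, tab-separated with one
#' header row and `NA` for missing values, so that
#' `read_gwas_table(write_gwas_table(t))` reproduces `t` field for field.
#'
#' @param table A `gwas_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gwas_table <- function(table, path) {
  stopifnot(inherits(table, "gwas_table"))
  df <- as.data.frame(table)[GWAS_FIELDS]
  # full precision so the round trip is exact
  for (f in c("eaf", "beta", "se", "pval", "n", "pos")) {
    df[[f]] <- vapply(df[[f]], function(v) {
      if (is.na(v)) NA_character_ else format(v, digits = 17, scientific = NA, trim = TRUE)
    }, character(1))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}
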