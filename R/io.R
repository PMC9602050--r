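# Readers and writers for the tab-delimited exchange formats: GWAS summary
# statistics, labeled correlation matrices and heritability vectors.

# Synonym map for summary-statistic headers; the practical hazard with
# these files is dialect drift, not structure.
.col_synonyms <- c(
  snp = "rsid", rs = "rsid", variant_id = "rsid", markername = "rsid",
  chrom = "chr", chromosome = "chr",
  bp = "pos", position = "pos", base_pair_location = "pos",
  a1 = "ea", effect_allele = "ea", allele1 = "ea",
  a2 = "oa", other_allele = "oa", allele2 = "oa", a0 = "oa",
  frq = "eaf", freq = "eaf", af = "eaf", effect_allele_frequency = "eaf",
  effect = "beta", b = "beta",
  stderr = "se", standard_error = "se",
  zscore = "z", z_score = "z", stat = "z",
  pval = "p", p_value = "p", pvalue = "p",
  nmiss = "n", samplesize = "n", n_samples = "n"
)

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-delimited file with a header, normalizes column names
#' through a synonym map (disable with `strict = TRUE`), derives `z` from
#' `beta`/`se` and `p` from `z` where absent, and applies the standard
#' quality filters: minor allele frequency at least `maf_filter`, p-values
#' exactly zero removed, duplicate variant ids reduced to their first
#' occurrence. Dropped-row counts are recorded in the `drop_counts`
#' attribute.
#'
#' @param path File path.
#' @param maf_filter Minimum minor allele frequency (default 0.01).
#' @param strict If `TRUE`, only canonical column names are accepted.
#' @return Summary-statistics tibble ordered by (chr, pos).
#' @export
read_sumstats <- function(path, maf_filter = 0.01, strict = FALSE) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  nm <- tolower(names(d))
  if (!strict) {
    hit <- nm %in% names(.col_synonyms)
    nm[hit] <- .col_synonyms[nm[hit]]
  }
  names(d) <- nm
  required <- c("rsid", "chr", "pos", "ea", "oa", "eaf")
  missing <- setdiff(required, nm)
  if (length(missing) > 0) {
    stop("missing required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  has_z <- all(c("z", "n") %in% nm)
  has_beta <- all(c("beta", "se", "n") %in% nm)
  if (!has_z && !has_beta) {
    stop("need either (z, n) or (beta, se, n) columns", call. = FALSE)
  }
  if (!"z" %in% nm) d$z <- d$beta / d$se
  if (!"p" %in% nm) d$p <- 2 * stats::pnorm(-abs(d$z))

  n0 <- nrow(d)
  maf <- pmin(d$eaf, 1 - d$eaf)
  keep_maf <- !is.na(maf) & maf >= maf_filter
  d <- d[keep_maf, , drop = FALSE]
  n_maf <- n0 - nrow(d)

  p_zero <- !is.na(d$p) & d$p == 0
  n_p0 <- sum(p_zero)
  d <- d[!p_zero, , drop = FALSE]

  dup <- duplicated(d$rsid)
  n_dup <- sum(dup)
  d <- d[!dup, , drop = FALSE]

  d <- dplyr::arrange(d, .data$chr, .data$pos)
  keep_cols <- intersect(sumstat_cols, names(d))
  d <- tibble::as_tibble(d[, keep_cols, drop = FALSE])
  attr(d, "drop_counts") <- c(maf = n_maf, p_zero = n_p0, duplicate = n_dup)
  d
}

#' Write a GWAS summary-statistics table
#'
#' Canonical column order `rsid chr pos ea oa eaf beta se z p n`, full float
#' precision (round-trips through [read_sumstats()] without loss); a
#' `neg_log10_p` column is added so extreme associations survive p-value
#' underflow.
#'
#' @param stats Summary-statistics tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(stats, path) {
  cols <- intersect(sumstat_cols, names(stats))
  d <- stats[, cols, drop = FALSE]
  if ("z" %in% cols) {
    d$neg_log10_p <- -(stats::pnorm(-abs(stats$z), log.p = TRUE) +
                         log(2)) / log(10)
  }
  readr::write_tsv(d, path, progress = FALSE)
  invisible(path)
}

#' Read a labeled square correlation matrix from tab-delimited text
#'
#' Expects a header row of trait names and a leading label column with the
#' same names in the same order.
#'
#' @param path File path.
#' @param pd_tol Positive-definiteness tolerance passed to [corr_matrix()].
#' @return Validated correlation matrix with dimnames.
#' @export
read_corr_matrix <- function(path, pd_tol = 1e-8) {
  d <- utils::read.delim(path, check.names = FALSE)
  labels <- as.character(d[[1]])
  m <- as.matrix(d[, -1, drop = FALSE])
  if (!identical(labels, colnames(m))) {
    stop("matrix row labels do not match column header in ", path,
         call. = FALSE)
  }
  dimnames(m) <- list(labels, labels)
  corr_matrix(m, pd_tol, what = paste0("matrix in ", path))
}

#' Write a labeled matrix to tab-delimited text
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corr_matrix <- function(m, path) {
  d <- data.frame(trait = rownames(m), m, check.names = FALSE)
  readr::write_tsv(tibble::as_tibble(d), path, progress = FALSE)
  invisible(path)
}

#' Read a heritability vector from tab-delimited text
#'
#' Two columns: trait name and h2.
#'
#' @param path File path.
#' @return Named numeric vector.
#' @export
read_h2 <- function(path) {
  d <- utils::read.delim(path)
  out <- as.numeric(d[[2]])
  names(out) <- as.character(d[[1]])
  out
}

#' Assemble a trait panel from matrix and heritability files
#'
#' @param ugen_path,uphen_path Paths to the genetic and phenotypic
#'   correlation matrix files.
#' @param h2_path Path to the heritability table.
#' @return A [trait_panel()]; trait order follows the genetic matrix.
#' @export
read_trait_panel <- function(ugen_path, uphen_path, h2_path) {
  ugen <- read_corr_matrix(ugen_path)
  uphen <- read_corr_matrix(uphen_path)
  h2 <- read_h2(h2_path)
  nms <- rownames(ugen)
  if (!setequal(nms, rownames(uphen)) || !setequal(nms, names(h2))) {
    stop("trait names disagree between input files", call. = FALSE)
  }
  trait_panel(nms, h2[nms], ugen, uphen[nms, nms])
}
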