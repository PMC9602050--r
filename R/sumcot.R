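# Summary-statistic combination: align per-trait GWAS tables, combine
# Z-scores into a linear-combination trait with overlap-aware standard
# errors, estimate effective sample sizes, phenotypic correlations from
# null Z-scores, and apply genomic-control correction.

sumstat_cols <- c("rsid", "chr", "pos", "ea", "oa", "eaf",
                  "beta", "se", "z", "p", "n")

is_ambiguous_pair <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Align a list of GWAS summary-statistic tables on shared variants
#'
#' Inner-joins all tables on variant id; flips the Z-score, beta sign and
#' effect-allele frequency of any trait whose effect/other alleles are
#' swapped relative to the first table; drops variants with inconsistent
#' allele pairs or strand-ambiguous pairs (A/T, C/G). Output rows are
#' ordered by (chromosome, position) of the first table.
#'
#' @param stats_list List of >= 2 summary-statistic tibbles (columns
#'   `rsid, chr, pos, ea, oa, eaf, z, n` at minimum; `beta`, `se`, `p`
#'   carried when present).
#' @return List of aligned tibbles (same variants, same order), with
#'   attributes `n_dropped_ambiguous` and `n_dropped_mismatch`.
#' @export
harmonize_sumstats <- function(stats_list) {
  if (length(stats_list) < 2) {
    stop("need at least two summary-statistic tables", call. = FALSE)
  }
  ids <- Reduce(intersect, lapply(stats_list, function(d) d$rsid))
  if (length(ids) == 0) {
    stop("no variants shared by all tables", call. = FALSE)
  }
  ref <- dplyr::arrange(
    dplyr::filter(stats_list[[1]], .data$rsid %in% ids),
    .data$chr, .data$pos
  )
  amb <- is_ambiguous_pair(ref$ea, ref$oa)
  n_amb <- sum(amb)
  ref <- ref[!amb, , drop = FALSE]

  aligned <- vector("list", length(stats_list))
  mismatch <- rep(FALSE, nrow(ref))
  aligned[[1]] <- ref
  for (j in seq_along(stats_list)[-1]) {
    d <- stats_list[[j]]
    d <- d[match(ref$rsid, d$rsid), , drop = FALSE]
    same <- d$ea == ref$ea & d$oa == ref$oa
    swap <- d$ea == ref$oa & d$oa == ref$ea
    mismatch <- mismatch | !(same | swap)
    d$z[swap] <- -d$z[swap]
    if ("beta" %in% names(d)) d$beta[swap] <- -d$beta[swap]
    d$eaf[swap] <- 1 - d$eaf[swap]
    d$ea <- ref$ea
    d$oa <- ref$oa
    aligned[[j]] <- d
  }
  n_mis <- sum(mismatch)
  aligned <- lapply(aligned, function(d) {
    tibble::as_tibble(d[!mismatch, , drop = FALSE])
  })
  if (nrow(aligned[[1]]) == 0) {
    stop("no variants left after allele harmonization", call. = FALSE)
  }
  attr(aligned, "n_dropped_ambiguous") <- n_amb
  attr(aligned, "n_dropped_mismatch") <- n_mis
  aligned
}

#' GWAS summary statistics of a linear combination of traits
#'
#' Combines per-trait Z-scores into the summary statistics of the trait
#' `t = k' y / sqrt(k' U_phen k)` (normalized to unit phenotypic variance).
#' On the doubly standardized scale (standardized trait, standardized
#' genotype) each trait's per-SNP effect is `b_i = z_i / sqrt(n_i)` with
#' standard error `1 / sqrt(n_i)`; the combined effect sums these with the
#' coefficients, and the combined squared standard error applies
#' variance-covariance arithmetic with the phenotypic correlation matrix,
#' which absorbs sample overlap between the input GWASs:
#' \deqn{se_t^2 = \sum_{i,l} k_i k_l\, U_{phen,il}\, se_i se_l \; / \; k^T U_{phen} k.}
#' Output betas/SEs are re-expressed on the conventional dosage scale using
#' the effect-allele frequency; the Z-score is scale-free.
#'
#' @param stats_list Harmonized list from [harmonize_sumstats()] (or a
#'   single-trait list for the identity combination).
#' @param coeffs Numeric K-vector of combination coefficients.
#' @param uphen K x K phenotypic correlation matrix of the input traits.
#' @return Summary-statistics tibble (`rsid chr pos ea oa eaf beta se z p n`,
#'   `n` the per-SNP minimum across inputs) with attribute `effective_n`.
#' @export
combine_sumstats <- function(stats_list, coeffs, uphen) {
  k <- length(stats_list)
  coeffs <- as.numeric(coeffs)
  if (length(coeffs) != k) {
    stop("one coefficient per input table required", call. = FALSE)
  }
  if (!is.matrix(uphen) || any(dim(uphen) != k)) {
    stop("uphen must be ", k, " x ", k, call. = FALSE)
  }
  varc <- drop(crossprod(coeffs, uphen %*% coeffs))
  if (varc < 1e-10) {
    stop("degenerate combination: phenotypic variance of the combined ",
         "trait is (near) zero", call. = FALSE)
  }
  m <- nrow(stats_list[[1]])
  zmat <- vapply(stats_list, function(d) d$z, numeric(m))
  nmat <- vapply(stats_list, function(d) as.numeric(d$n), numeric(m))
  semat <- 1 / sqrt(nmat)                       # standardized-scale SEs
  bmat <- zmat * semat

  bt <- drop(bmat %*% coeffs) / sqrt(varc)
  # se_t^2 = sum_il k_i k_l U_il se_i se_l / varc, rowwise over SNPs
  se2 <- numeric(m)
  for (i in seq_len(k)) for (l in seq_len(k)) {
    se2 <- se2 + coeffs[i] * coeffs[l] * uphen[i, l] * semat[, i] * semat[, l]
  }
  se2 <- se2 / varc
  set <- sqrt(se2)
  zt <- bt / set
  pt <- 2 * stats::pnorm(-abs(zt))

  ref <- stats_list[[1]]
  eaf <- ref$eaf
  dose_sd <- sqrt(pmax(2 * eaf * (1 - eaf), 1e-12))
  out <- tibble::tibble(
    rsid = ref$rsid, chr = ref$chr, pos = ref$pos,
    ea = ref$ea, oa = ref$oa, eaf = eaf,
    beta = bt / dose_sd, se = set / dose_sd,
    z = zt, p = pt,
    n = apply(nmat, 1, min)
  )
  attr(out, "effective_n") <- effective_n(out)
  out
}

#' Effective sample size of a (combined) GWAS
#'
#' Inverts the standard relation between the standard error of a per-SNP
#' effect on the dosage scale and the sample size,
#' `n_j = 1 / (2 p_j (1 - p_j) se_j^2)`, and returns the median over SNPs.
#'
#' @param stats Summary-statistics tibble with `eaf` and `se` columns.
#' @return Scalar effective sample size.
#' @export
effective_n <- function(stats) {
  if (!all(c("eaf", "se") %in% names(stats))) {
    stop("effective N needs eaf and se columns", call. = FALSE)
  }
  if (anyNA(stats$eaf)) stop("missing effect-allele frequencies", call. = FALSE)
  stats::median(1 / (2 * stats$eaf * (1 - stats$eaf) * stats$se^2))
}

#' Phenotypic correlation between two traits from null Z-scores
#'
#' Estimates the phenotypic correlation (as seen by the GWAS errors, i.e.
#' attenuated by partial sample overlap) as the Pearson correlation between
#' the two traits' Z-scores over approximately independent,
#' non-significant SNPs: SNPs are greedily pruned to one per
#' `prune_window_bp` along each chromosome, then restricted to
#' `|z| < z_max` in both traits.
#'
#' @param stats_a,stats_b Harmonized summary-statistic tibbles (same
#'   variants, same order).
#' @param z_max Null-Z cutoff (default 2).
#' @param prune_window_bp Distance-pruning window (default 500 kb).
#' @return Scalar correlation.
#' @export
estimate_pheno_corr <- function(stats_a, stats_b, z_max = 2,
                                prune_window_bp = 500000) {
  if (!identical(stats_a$rsid, stats_b$rsid)) {
    stop("tables must be harmonized (same variants, same order)",
         call. = FALSE)
  }
  ord <- order(stats_a$chr, stats_a$pos)
  a <- stats_a[ord, ]
  b <- stats_b[ord, ]
  keep <- logical(nrow(a))
  last_chr <- NA
  last_pos <- -Inf
  for (i in seq_len(nrow(a))) {
    if (!identical(a$chr[i], last_chr) ||
        a$pos[i] - last_pos >= prune_window_bp) {
      keep[i] <- TRUE
      last_chr <- a$chr[i]
      last_pos <- a$pos[i]
    }
  }
  null_snps <- keep & abs(a$z) < z_max & abs(b$z) < z_max
  if (sum(null_snps) < 100) {
    stop("fewer than 100 independent null SNPs survive pruning; the ",
         "phenotypic-correlation estimate would be unstable", call. = FALSE)
  }
  stats::cor(a$z[null_snps], b$z[null_snps])
}

#' Pairwise phenotypic correlation matrix from a list of GWAS tables
#'
#' @param stats_list List of summary-statistic tibbles (harmonized
#'   internally).
#' @param ... Passed to [estimate_pheno_corr()].
#' @return K x K correlation matrix with unit diagonal.
#' @export
pheno_corr_matrix <- function(stats_list, ...) {
  k <- length(stats_list)
  aligned <- harmonize_sumstats(stats_list)
  out <- diag(k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    out[i, j] <- out[j, i] <-
      estimate_pheno_corr(aligned[[i]], aligned[[j]], ...)
  }
  nm <- names(stats_list)
  if (!is.null(nm)) dimnames(out) <- list(nm, nm)
  out
}

#' Genomic-control correction by the LD-score-regression intercept
#'
#' When the intercept exceeds one, standard errors are multiplied by its
#' square root, Z-scores divided by it, and p-values recomputed; an
#' intercept at or below one leaves the statistics untouched.
#'
#' @param stats Summary-statistics tibble.
#' @param intercept Positive scalar intercept.
#' @return Corrected tibble.
#' @export
gc_correct <- function(stats, intercept) {
  if (!is.numeric(intercept) || length(intercept) != 1 || intercept <= 0) {
    stop("intercept must be a positive scalar", call. = FALSE)
  }
  if (intercept <= 1) return(stats)
  lambda <- sqrt(intercept)
  dplyr::mutate(stats,
                se = .data$se * lambda,
                z = .data$z / lambda,
                p = 2 * stats::pnorm(-abs(.data$z)))
}

#' Full pipeline: decomposition plus SGIT/UGIT summary statistics
#'
#' Runs the SGI screen and the shared-heritability decomposition on the
#' panel, then combines the per-trait GWAS tables into summary statistics
#' for the shared-impact trait (coefficients alpha) and each per-trait
#' unshared-impact trait (columns of Gamma), assigning each output an
#' effective sample size and optionally a genomic-control correction.
#'
#' @param panel A [trait_panel()] (trait order must match `stats_list`).
#' @param stats_list Named list of K summary-statistic tibbles.
#' @param threshold SGI screen threshold.
#' @param gc_intercepts Optional named/numeric vector of LDSC intercepts for
#'   the outputs: entry `"sgit"` plus one per trait name (or unnamed length
#'   K + 1, SGIT first).
#' @return List with `fit` (the `maxsh_fit`), `sgit` (tibble), `ugits`
#'   (named list of tibbles) and `report` (one-row glance tibble with
#'   effective sample sizes).
#' @export
run_shaher <- function(panel, stats_list, threshold = 0.2,
                       gc_intercepts = NULL) {
  stopifnot(inherits(panel, "trait_panel"))
  if (length(stats_list) != panel$k) {
    stop("need one summary-statistic table per trait", call. = FALSE)
  }
  fit <- run_maxsh(panel, threshold = threshold)
  aligned <- harmonize_sumstats(stats_list)

  sgit <- combine_sumstats(aligned, fit$alpha, panel$uphen)
  ugits <- lapply(seq_len(panel$k), function(i) {
    combine_sumstats(aligned, fit$gamma[, i], panel$uphen)
  })
  names(ugits) <- panel$names
  n_eff_sgit <- attr(sgit, "effective_n")

  if (!is.null(gc_intercepts)) {
    if (is.null(names(gc_intercepts))) {
      names(gc_intercepts) <- c("sgit", panel$names)
    }
    if (!is.na(gc_intercepts["sgit"])) {
      sgit <- gc_correct(sgit, gc_intercepts[["sgit"]])
    }
    for (nm in panel$names) {
      if (!is.na(gc_intercepts[nm])) {
        ugits[[nm]] <- gc_correct(ugits[[nm]], gc_intercepts[[nm]])
      }
    }
  }

  report <- dplyr::mutate(
    glance(fit),
    n_variants = nrow(sgit),
    n_eff_sgit = n_eff_sgit
  )
  list(fit = fit, sgit = sgit, ugits = ugits, report = report)
}
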