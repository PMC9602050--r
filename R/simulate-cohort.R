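# Individual-level cohort generator for end-to-end validation of the
# summary-statistic combiner: genotypes, traits built from a shared genetic
# factor plus per-trait unshared factors and correlated noise, and a fast
# vectorized per-SNP linear GWAS.

# Draw n rows from N(0, sigma) via Cholesky (sigma must be PD).
rmvn <- function(n, sigma) {
  k <- nrow(sigma)
  z <- matrix(stats::rnorm(n * k), n, k)
  z %*% chol(sigma)
}

#' Simulate an individual-level cohort under the shared-heredity model
#'
#' Genotypes are independent biallelic SNPs: `m0` SNPs form the shared
#' genetic factor and `m1` SNPs the unshared factors; dosages are drawn
#' Binomial(2, maf) and column-standardized. Trait i is assembled as
#' \deqn{y_i = G_0 \beta_0\, w_i h_i / \sqrt{M_0}
#'       + G_1 \beta_{1i} \sqrt{1 - w_i^2}\, h_i / \sqrt{M_1}
#'       + \varepsilon_i \sqrt{1 - h_i^2}}
#' with \eqn{h_i = \sqrt{h^2_i}}: a shared effect vector `beta0` common to
#' all traits and scaled per trait by the signed loading w_i; per-SNP
#' unshared effect vectors drawn jointly across traits with correlation
#' `uunsh`; and noise drawn jointly with correlation `uenv`. The 1/sqrt(M)
#' scalings make the expected variance contributions w_i^2 h_i^2,
#' (1-w_i^2) h_i^2 and 1-h_i^2 at finite SNP counts; traits are
#' re-standardized empirically after assembly.
#'
#' @param n Individuals.
#' @param m0 Shared-factor SNPs.
#' @param m1 Unshared SNPs.
#' @param w Numeric K-vector of signed shared loadings.
#' @param h2 Numeric K-vector of heritabilities.
#' @param uunsh K x K correlation of unshared effects across traits
#'   (default identity).
#' @param uenv K x K correlation of environmental noise (default identity).
#' @param maf_low,maf_high Allele-frequency range for simulated SNPs.
#' @return An object of class `simulated_cohort`: list with `genotypes`
#'   (n x (m0+m1) standardized), `dosages` (raw 0/1/2), `traits` (n x K,
#'   standardized), `maf`, and the truth (`beta0`, `beta1`, `w`, `h2`,
#'   `m0`, `m1`, genetic values `gshared`, `gtotal`).
#' @export
simulate_cohort <- function(n, m0, m1, w, h2,
                            uunsh = NULL, uenv = NULL,
                            maf_low = 0.05, maf_high = 0.5) {
  k <- length(w)
  if (length(h2) != k) stop("w and h2 must have equal length", call. = FALSE)
  if (any(abs(w) > 1)) stop("|w_i| must not exceed 1", call. = FALSE)
  if (any(h2 < 0) || any(h2 > 1)) stop("h2 must lie in [0, 1]", call. = FALSE)
  if (maf_low <= 0 || maf_high > 0.5 || maf_low > maf_high) {
    stop("MAF bounds must satisfy 0 < maf_low <= maf_high <= 0.5",
         call. = FALSE)
  }
  if (is.null(uunsh)) uunsh <- diag(k)
  if (is.null(uenv)) uenv <- diag(k)
  stopifnot(all(dim(uunsh) == k), all(dim(uenv) == k))

  m <- m0 + m1
  maf <- stats::runif(m, maf_low, maf_high)
  dos <- matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), n, m)
  g <- scale(dos)
  # monomorphic columns (sd 0) standardize to NaN; replace with zeros
  bad <- !is.finite(colSums(g))
  if (any(bad)) g[, bad] <- 0

  beta0 <- stats::rnorm(m0)
  beta1 <- rmvn(m1, uunsh)                      # m1 x K
  eps <- rmvn(n, uenv)                          # n x K

  h <- sqrt(h2)
  gshared <- drop(g[, seq_len(m0), drop = FALSE] %*% beta0) / sqrt(m0)
  gunsh <- g[, m0 + seq_len(m1), drop = FALSE] %*% beta1 / sqrt(m1)
  traits <- matrix(0, n, k)
  for (i in seq_len(k)) {
    traits[, i] <- gshared * w[i] * h[i] +
      gunsh[, i] * sqrt(1 - w[i]^2) * h[i] +
      eps[, i] * sqrt(1 - h2[i])
  }
  gtotal <- sweep(matrix(gshared, n, k), 2, w * h, `*`) +
    sweep(gunsh, 2, sqrt(1 - w^2) * h, `*`)
  traits <- scale(traits)

  structure(
    list(genotypes = g, dosages = dos, traits = traits, maf = maf,
         beta0 = beta0, beta1 = beta1, w = w, h2 = h2, m0 = m0, m1 = m1,
         gshared = gshared, gtotal = gtotal),
    class = "simulated_cohort"
  )
}

#' Per-SNP linear GWAS of one simulated trait
#'
#' Simple linear regression of the trait on the unstandardized dosage of
#' each SNP, vectorized across SNPs. Betas and standard errors are on the
#' dosage scale; monomorphic SNPs are dropped (count recorded in the
#' `n_dropped` attribute). Variant ids and positions are synthetic and
#' deterministic: a single chromosome with 10 kb spacing, so distance-based
#' locus procedures behave sensibly on the output.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param trait Trait index (column of `cohort$traits`).
#' @return Summary-statistics tibble with columns
#'   `rsid, chr, pos, ea, oa, eaf, beta, se, z, p, n`.
#' @export
gwas_linear <- function(cohort, trait = 1) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  y <- cohort$traits[, trait]
  x <- cohort$dosages
  n <- length(y)
  m <- ncol(x)

  xbar <- colMeans(x)
  sxx <- colSums(x^2) - n * xbar^2
  keep <- sxx > 1e-12
  n_dropped <- sum(!keep)

  xc <- x[, keep, drop = FALSE]
  sxy <- drop(crossprod(xc, y)) - n * xbar[keep] * mean(y)
  beta <- sxy / sxx[keep]
  syy <- sum(y^2) - n * mean(y)^2
  sse <- pmax(syy - beta * sxy, 0)
  se <- sqrt(sse / (n - 2) / sxx[keep])
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))

  idx <- which(keep)
  out <- tibble::tibble(
    rsid = paste0("rs", idx),
    chr = 1L,
    pos = idx * 10000L,
    ea = "A",
    oa = "G",
    eaf = xbar[keep] / 2,
    beta = beta,
    se = se,
    z = z,
    p = p,
    n = as.integer(n)
  )
  attr(out, "n_dropped") <- n_dropped
  out
}
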