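#' Validate a trait-trait correlation matrix
#'
#' Checks that `m` is a square symmetric matrix with unit diagonal and all
#' entries in \[-1, 1\], and records whether its smallest eigenvalue exceeds
#' `pd_tol` (i.e. whether it is usable as a positive-definite correlation
#' matrix). Symmetry and unit diagonal are required to within 1e-10.
#'
#' @param m A numeric K x K matrix of correlations.
#' @param pd_tol Positive-definiteness tolerance on the smallest eigenvalue
#'   (default `1e-8`).
#' @param what Label used in error messages.
#' @return `m` (dimnames preserved) with attributes `min_eigen` (smallest
#'   eigenvalue) and `pd_ok` (logical).
#' @export
corr_matrix <- function(m, pd_tol = 1e-8, what = "correlation matrix") {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(what, " must be a numeric matrix", call. = FALSE)
  }
  if (nrow(m) != ncol(m)) {
    stop(what, " must be square, got ", nrow(m), " x ", ncol(m), call. = FALSE)
  }
  if (anyNA(m)) stop(what, " contains missing values", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-10) {
    stop(what, " is not symmetric (tolerance 1e-10)", call. = FALSE)
  }
  if (max(abs(diag(m) - 1)) > 1e-10) {
    stop(what, " must have unit diagonal (tolerance 1e-10)", call. = FALSE)
  }
  if (any(m < -1 - 1e-12) || any(m > 1 + 1e-12)) {
    stop(what, " has entries outside [-1, 1]", call. = FALSE)
  }
  ev <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  attr(m, "min_eigen") <- ev
  attr(m, "pd_ok") <- ev > pd_tol
  m
}

#' Is a correlation matrix positive definite?
#'
#' @param m Numeric symmetric matrix.
#' @param pd_tol Tolerance on the smallest eigenvalue.
#' @return Logical scalar.
#' @export
is_pd_corr <- function(m, pd_tol = 1e-8) {
  min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) > pd_tol
}

#' Bundle a trait panel: names, heritabilities and correlation matrices
#'
#' A trait panel is the complete input of the heritability-decomposition
#' stage: K trait identifiers, their SNP heritabilities, and the K x K
#' genetic and phenotypic correlation matrices. All traits are treated as
#' standardized to unit variance. The decomposition is only identifiable
#' with at least three traits.
#'
#' @param names Character vector of K trait identifiers (K >= 3).
#' @param h2 Numeric K-vector of heritabilities, each in (0, 1].
#' @param ugen K x K genetic correlation matrix.
#' @param uphen K x K phenotypic correlation matrix.
#' @param pd_tol Positive-definiteness tolerance passed to [corr_matrix()].
#' @return An object of class `trait_panel`: a list with elements `names`,
#'   `h2`, `ugen`, `uphen` and `k`.
#' @export
trait_panel <- function(names, h2, ugen, uphen, pd_tol = 1e-8) {
  k <- length(names)
  if (k < 3) {
    stop("a trait panel needs at least three traits, got ", k, call. = FALSE)
  }
  if (length(h2) != k) {
    stop("h2 must have one entry per trait", call. = FALSE)
  }
  if (any(h2 <= 0) || any(h2 > 1)) {
    stop("heritabilities must lie in (0, 1]", call. = FALSE)
  }
  ugen <- corr_matrix(ugen, pd_tol, what = "genetic correlation matrix")
  uphen <- corr_matrix(uphen, pd_tol, what = "phenotypic correlation matrix")
  if (nrow(ugen) != k || nrow(uphen) != k) {
    stop("matrix dimensions do not match the number of traits", call. = FALSE)
  }
  dimnames(ugen) <- dimnames(uphen) <- list(names, names)
  structure(
    list(names = as.character(names), h2 = as.numeric(h2),
         ugen = ugen, uphen = uphen, k = k),
    class = "trait_panel"
  )
}

#' @export
print.trait_panel <- function(x, ...) {
  cat("Trait panel:", x$k, "traits\n")
  cat("  traits:", paste(x$names, collapse = ", "), "\n")
  cat("  h2:    ", paste(formatC(x$h2, digits = 3, format = "fg"),
                         collapse = ", "), "\n")
  cat("  min eigenvalue U_gen: ",
      formatC(attr(x$ugen, "min_eigen"), digits = 3, format = "g"),
      " | U_phen: ",
      formatC(attr(x$uphen, "min_eigen"), digits = 3, format = "g"), "\n",
      sep = "")
  invisible(x)
}

#' Genetic correlation matrix implied by shared loadings and unshared part
#'
#' Assembles the genetic correlation matrix of the shared-heredity model:
#' a rank-one component `w w'` contributed by the shared genetic factor,
#' plus the unshared genetic correlations scaled so each trait keeps unit
#' genetic variance:
#' \deqn{U_{gen} = w w^T + D\, U_{unsh}\, D,\quad D = diag(\sqrt{1 - w_i^2}).}
#' The unit diagonal holds algebraically (w_i^2 + (1 - w_i^2) = 1).
#'
#' @param w Numeric K-vector of signed shared-heritability loadings,
#'   each in \[-1, 1\]; `w_i^2` is the proportion of trait i's heritability
#'   explained by the shared genetic factor.
#' @param uunsh K x K correlation matrix of the unshared genetic components.
#' @return K x K genetic correlation matrix.
#' @export
compose_ugen <- function(w, uunsh) {
  w <- as.numeric(w)
  k <- length(w)
  if (!is.matrix(uunsh) || nrow(uunsh) != k || ncol(uunsh) != k) {
    stop("uunsh must be a ", k, " x ", k, " matrix", call. = FALSE)
  }
  if (any(abs(w) > 1 + 1e-12)) {
    stop("entries of w must lie in [-1, 1]", call. = FALSE)
  }
  d <- sqrt(pmax(1 - w^2, 0))
  out <- tcrossprod(w) + (d %o% d) * uunsh
  diag(out) <- 1
  out
}

#' Phenotypic correlation matrix from genetic and environmental parts
#'
#' Mixes genetic and environmental correlations by heritability:
#' \deqn{U_{phen} = H U_{gen} H + E U_{env} E}
#' with \eqn{H = diag(\sqrt{h_i^2})} and \eqn{E = diag(\sqrt{1 - h_i^2})},
#' keeping every trait at unit phenotypic variance.
#'
#' @param ugen K x K genetic correlation matrix.
#' @param uenv K x K environmental correlation matrix.
#' @param h2 Numeric K-vector of heritabilities in \[0, 1\].
#' @return K x K phenotypic correlation matrix.
#' @export
compose_uphen <- function(ugen, uenv, h2) {
  h2 <- as.numeric(h2)
  k <- length(h2)
  if (!is.matrix(ugen) || any(dim(ugen) != k) ||
      !is.matrix(uenv) || any(dim(uenv) != k)) {
    stop("ugen and uenv must be ", k, " x ", k, " matrices", call. = FALSE)
  }
  if (any(h2 < 0) || any(h2 > 1)) {
    stop("heritabilities must lie in [0, 1]", call. = FALSE)
  }
  h <- sqrt(h2)
  e <- sqrt(1 - h2)
  out <- (h %o% h) * ugen + (e %o% e) * uenv
  diag(out) <- 1
  out
}

#' Phenotypic and genetic moments of a linear combination of traits
#'
#' For a combination `t = k' y` of the standardized original traits, returns
#' its phenotypic variance, total heritability, the heritability explained by
#' the shared genetic factor, and their ratio Q (the specificity of the
#' combination for shared genetics):
#' \deqn{var = k^T U_{phen} k,\quad
#'       h^2_{tot} = k^T H U_{gen} H k / var,\quad
#'       h^2_{sh}  = (k^T H w)^2 / var}
#' with \eqn{H = diag(\sqrt{h_i^2})}.
#'
#' @param k Numeric K-vector of combination coefficients (not all zero).
#' @param panel A [trait_panel()].
#' @param w Numeric K-vector of shared loadings used to define the shared
#'   component.
#' @return One-row tibble with columns `var_phen`, `h2_total`, `h2_shared`,
#'   `q`.
#' @export
combo_moments <- function(k, panel, w) {
  stopifnot(inherits(panel, "trait_panel"))
  k <- as.numeric(k)
  w <- as.numeric(w)
  if (length(k) != panel$k || length(w) != panel$k) {
    stop("k and w must have one entry per trait", call. = FALSE)
  }
  h <- sqrt(panel$h2)
  var_phen <- drop(crossprod(k, panel$uphen %*% k))
  if (var_phen < 1e-12) {
    stop("degenerate combination: phenotypic variance is (near) zero",
         call. = FALSE)
  }
  cgen <- (h %o% h) * panel$ugen
  h2_total <- drop(crossprod(k, cgen %*% k)) / var_phen
  h2_shared <- drop(crossprod(k, h * w))^2 / var_phen
  tibble::tibble(
    var_phen = var_phen,
    h2_total = h2_total,
    h2_shared = h2_shared,
    q = h2_shared / h2_total
  )
}

# Genetic covariance matrix H %*% Ugen %*% H of a panel (internal shorthand).
panel_cgen <- function(panel) {
  h <- sqrt(panel$h2)
  (h %o% h) * panel$ugen
}
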