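#' First genetically independent phenotype (GIP1) coefficients
#'
#' The baseline alternative to the optimized SGIT: principal component
#' analysis on the genetic covariance matrix \eqn{C_{gen} = H U_{gen} H}.
#' The leading eigenvector v is rescaled to unit phenotypic variance,
#' \eqn{\beta = v / \sqrt{v^T U_{phen} v}}, so its heritability is directly
#' comparable with the SGIT's, and sign-fixed so `sum(beta) >= 0`.
#'
#' @param panel A [trait_panel()].
#' @param tol Eigenvalue-gap tolerance; a leading eigenvalue tied within
#'   `tol` makes the first component ill-defined.
#' @return Numeric K-vector of GIP1 combination coefficients.
#' @export
gip1_weights <- function(panel, tol = 1e-10) {
  stopifnot(inherits(panel, "trait_panel"))
  cgen <- panel_cgen(panel)
  eig <- eigen(cgen, symmetric = TRUE)
  if (eig$values[1] - eig$values[2] <= tol) {
    stop("degenerate spectrum: leading eigenvalue of the genetic covariance ",
         "matrix is not unique (gap ",
         format(eig$values[1] - eig$values[2]), ")", call. = FALSE)
  }
  v <- eig$vectors[, 1]
  beta <- v / sqrt(drop(crossprod(v, panel$uphen %*% v)))
  if (sum(beta) < 0) beta <- -beta
  names(beta) <- panel$names
  beta
}
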