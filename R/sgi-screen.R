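#' Screen a genetic correlation matrix for a shared genetic impact
#'
#' Before any decomposition is attempted, the genetic correlation matrix must
#' look like it carries a single shared factor. Three conditions are checked:
#'
#' 1. positive definiteness (smallest eigenvalue above `pd_tol`);
#' 2. every off-diagonal correlation exceeds `threshold` in absolute value
#'    (exact zeros therefore always fail);
#' 3. the sign pattern of the off-diagonals is rank-one consistent: there is
#'    a sign vector s in \{-1, +1\}^K with sign(r_ij) = s_i s_j for every
#'    pair — equivalently, rounding all correlations to -1/+1 gives a
#'    rank-one matrix.
#'
#' The sign vector is constructed as s_1 = +1, s_i = sign(r_1i), then
#' verified on every pair. The threshold applies to absolute values; the
#' sign test separately handles direction.
#'
#' @param ugen K x K genetic correlation matrix (K >= 3).
#' @param threshold Minimum absolute off-diagonal correlation required
#'   (default 0.2).
#' @param pd_tol Positive-definiteness tolerance on the smallest eigenvalue.
#' @return An object of class `sgi_verdict`: list with `passed`, `pd_ok`,
#'   `min_abs_offdiag`, `threshold`, `sign_rank1_ok` and `sign_vector`
#'   (the +/-1 vector when the pattern is consistent, otherwise `NULL`).
#' @examples
#' u <- matrix(0.9, 3, 3); diag(u) <- 1
#' check_sgi(u)$passed
#' @export
check_sgi <- function(ugen, threshold = 0.2, pd_tol = 1e-8) {
  ugen <- corr_matrix(ugen, pd_tol, what = "genetic correlation matrix")
  k <- nrow(ugen)
  if (k < 3) stop("SGI screening needs at least three traits", call. = FALSE)

  pd_ok <- attr(ugen, "pd_ok")
  off <- ugen[upper.tri(ugen)]
  min_abs <- min(abs(off))

  s <- c(1, sign(ugen[1, -1]))
  sign_ok <- all(s != 0)
  if (sign_ok) {
    pattern <- tcrossprod(s)
    offd <- upper.tri(ugen)
    sign_ok <- all(sign(ugen[offd]) == pattern[offd])
  }

  structure(
    list(
      passed = pd_ok && (min_abs > threshold) && sign_ok,
      pd_ok = pd_ok,
      min_abs_offdiag = min_abs,
      threshold = threshold,
      sign_rank1_ok = sign_ok,
      sign_vector = if (sign_ok) s else NULL
    ),
    class = "sgi_verdict"
  )
}

#' @export
print.sgi_verdict <- function(x, ...) {
  cat("SGI screen:", if (x$passed) "PASS" else "FAIL", "\n")
  cat("  positive definite:       ", x$pd_ok, "\n")
  cat("  min |off-diagonal r|:    ",
      formatC(x$min_abs_offdiag, digits = 4, format = "f"),
      " (threshold ", x$threshold, ")\n", sep = "")
  cat("  rank-one sign pattern:   ", x$sign_rank1_ok, "\n")
  if (!is.null(x$sign_vector)) {
    cat("  sign vector:             ",
        paste(ifelse(x$sign_vector > 0, "+", "-"), collapse = " "), "\n")
  }
  invisible(x)
}
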