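#' Loss of a candidate shared-loading vector against a genetic correlation
#' matrix
#'
#' The shared-loading vector w is estimated by comparing the observed genetic
#' correlation matrix with the auxiliary matrix
#' \eqn{V = w w^T + (I - diag(w_i^2))}, i.e. the model matrix with identity
#' unshared correlations. Diagonals agree identically, so the loss is the sum
#' of squared off-diagonal deviations:
#' \deqn{Loss(w) = \sum_{i<j} (r_{ij} - w_i w_j)^2.}
#'
#' @param w Numeric K-vector, entries in \[-1, 1\].
#' @param ugen K x K genetic correlation matrix.
#' @return Nonnegative scalar.
#' @export
loss_value <- function(w, ugen) {
  w <- as.numeric(w)
  k <- length(w)
  if (!is.matrix(ugen) || any(dim(ugen) != k)) {
    stop("ugen must be a ", k, " x ", k, " matrix", call. = FALSE)
  }
  if (any(abs(w) > 1 + 1e-12)) {
    stop("entries of w must lie in [-1, 1]", call. = FALSE)
  }
  r <- ugen - tcrossprod(w)
  sum(r[upper.tri(r)]^2)
}

# Analytic gradient of loss_value: dLoss/dw_i = -2 sum_{j != i} (r_ij - w_i w_j) w_j
loss_grad <- function(w, ugen) {
  res <- ugen - tcrossprod(w)
  diag(res) <- 0
  -2 * drop(res %*% w)
}

#' Estimate shared-heritability loadings from a genetic correlation matrix
#'
#' Finds the w minimizing [loss_value()] over the box \[-1+eps, 1-eps\]^K by
#' bounded quasi-Newton (`L-BFGS-B`) with an analytic gradient, run from a
#' small multi-start grid: the all-equal vector at magnitudes
#' `c(0.3, 0.5, 0.7, 0.9)`, crossed with the sign patterns suggested by the
#' SGI screen's sign vector and their negations. The best solution is
#' sign-canonicalized so that `sum(w) >= 0`; among starts whose losses tie
#' within 1e-12, the one with the largest `sum(w^2)` is kept.
#'
#' The unshared genetic correlation matrix is recovered as
#' \eqn{U_{unsh} = D^{-1} (U_{gen} - w w^T) D^{-1}} with
#' \eqn{D = diag(\sqrt{1 - w_i^2})}; its diagonal is forced to exactly one
#' and off-diagonals are clipped to \[-1, 1\].
#'
#' @param ugen K x K genetic correlation matrix.
#' @param eps Box margin keeping |w_i| away from 1 (default 1e-6).
#' @param starts Optional matrix of additional start vectors (rows).
#' @param pd_tol Tolerance used when validating `ugen`.
#' @return An object of class `shared_decomposition`: list with `w` (signed
#'   loadings), `w2` (= w^2, proportions of heritability explained by the
#'   shared factor), `uunsh`, `loss`, `boundary` (TRUE if any |w_i| reached
#'   the box edge) and `convergence` diagnostics.
#' @export
estimate_w <- function(ugen, eps = 1e-6, starts = NULL, pd_tol = 1e-8) {
  ugen <- corr_matrix(ugen, pd_tol, what = "genetic correlation matrix")
  k <- nrow(ugen)

  # sign pattern from the screen when consistent, else all-positive
  s1 <- c(1, sign(ugen[1, -1]))
  s1[s1 == 0] <- 1
  signs <- unique(list(rep(1, k), s1, rep(-1, k), -s1))
  mags <- c(0.3, 0.5, 0.7, 0.9)
  start_list <- list()
  for (s in signs) for (m in mags) start_list <- c(start_list, list(m * s))
  if (!is.null(starts)) {
    start_list <- c(start_list, lapply(seq_len(nrow(starts)), function(i) starts[i, ]))
  }

  lower <- rep(-1 + eps, k)
  upper <- rep(1 - eps, k)
  best <- NULL
  n_conv <- 0L
  for (w0 in start_list) {
    fit <- tryCatch(
      stats::optim(pmin(pmax(w0, lower), upper), fn = loss_value,
                   gr = loss_grad, ugen = ugen, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e-3, maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    # L-BFGS-B reports code 52 when the line search stalls at machine
    # precision; treat the solution as converged if the projected gradient
    # is numerically zero
    g <- loss_grad(fit$par, ugen)
    at_lo <- fit$par <= lower + 1e-12
    at_hi <- fit$par >= upper - 1e-12
    g[at_lo & g > 0] <- 0
    g[at_hi & g < 0] <- 0
    if (fit$convergence == 0 || max(abs(g)) < 1e-6) n_conv <- n_conv + 1L
    if (is.null(best) ||
        fit$value < best$value - 1e-12 ||
        (abs(fit$value - best$value) <= 1e-12 &&
         sum(fit$par^2) > sum(best$par^2))) {
      best <- fit
    }
  }
  if (is.null(best) || n_conv == 0L) {
    stop("w estimation failed to converge from any start (K = ", k,
         ", loss at best candidate = ",
         if (is.null(best)) "none" else format(best$value), ")",
         call. = FALSE)
  }

  w <- best$par
  if (sum(w) < 0) w <- -w
  boundary <- any(abs(w) >= 1 - eps - 1e-12)
  if (boundary) {
    warning("some |w_i| reached the box boundary: heritability fully shared ",
            "for those traits", call. = FALSE)
  }

  d <- sqrt(pmax(1 - w^2, eps^2))
  uunsh <- (ugen - tcrossprod(w)) / (d %o% d)
  uunsh[] <- pmin(pmax(uunsh, -1), 1)
  diag(uunsh) <- 1
  dimnames(uunsh) <- dimnames(ugen)

  structure(
    list(w = w, w2 = w^2, uunsh = uunsh, loss = best$value,
         boundary = boundary, n_starts = length(start_list),
         n_converged = n_conv),
    class = "shared_decomposition"
  )
}

#' @export
print.shared_decomposition <- function(x, ...) {
  cat("Shared-heritability decomposition\n")
  cat("  w:   ", paste(formatC(x$w, digits = 4, format = "f"),
                       collapse = " "), "\n")
  cat("  w^2: ", paste(formatC(x$w2, digits = 4, format = "f"),
                       collapse = " "), "\n")
  cat("  loss:", formatC(x$loss, digits = 4, format = "g"), "\n")
  if (x$boundary) cat("  note: boundary solution (fully shared trait)\n")
  invisible(x)
}

#' Combination coefficients of the shared genetic impact trait
#'
#' Solves for the coefficients alpha of the linear combination of original
#' traits maximizing the heritability explained by the shared genetic
#' factor, i.e. maximizing \eqn{(k^T H w)^2 / (k^T U_{phen} k)} over k.
#' The closed form is
#' \deqn{\alpha = \frac{U_{phen}^{-1} H w}{\sqrt{w^T H U_{phen}^{-1} H w}},}
#' normalized so the combination has unit phenotypic variance
#' (\eqn{\alpha^T U_{phen} \alpha = 1}).
#'
#' @param panel A [trait_panel()].
#' @param w Numeric K-vector of shared loadings (not all zero).
#' @return Numeric K-vector alpha.
#' @export
solve_alpha <- function(panel, w) {
  stopifnot(inherits(panel, "trait_panel"))
  w <- as.numeric(w)
  if (length(w) != panel$k) stop("w must have one entry per trait", call. = FALSE)
  hw <- sqrt(panel$h2) * w
  if (sum(hw^2) < 1e-16) {
    stop("w has no shared component (H w is the zero vector)", call. = FALSE)
  }
  uinv_hw <- tryCatch(solve(panel$uphen, hw), error = function(e) {
    stop("phenotypic correlation matrix is singular", call. = FALSE)
  })
  alpha <- uinv_hw / sqrt(drop(crossprod(hw, uinv_hw)))
  names(alpha) <- panel$names
  alpha
}

#' SGIT impact coefficients and UGIT combination matrix
#'
#' Given the SGIT coefficients alpha, computes the genetic impact of SGIT on
#' each original trait,
#' \deqn{c_i = cov_{gen}(y_i, SGIT) / h^2_{SGIT} = (C_{gen}\alpha)_i / (\alpha^T C_{gen} \alpha)}
#' with \eqn{C_{gen} = H U_{gen} H}, and the matrix
#' \eqn{\Gamma = I - \alpha c^T} whose i-th column holds the coefficients of
#' the i-th unshared impact trait \eqn{UGIT_i = y_i - c_i\, SGIT}. Genetic
#' (not phenotypic) covariances are used: only the genetic component of each
#' trait is adjusted, so every UGIT is genetically uncorrelated with SGIT
#' (\eqn{\Gamma^T C_{gen} \alpha = 0}).
#'
#' @param panel A [trait_panel()].
#' @param alpha Numeric K-vector, normalized so `alpha' U_phen alpha = 1`.
#' @param tol Minimum SGIT heritability below which the adjustment is
#'   undefined.
#' @return List with `c` (K-vector) and `gamma` (K x K matrix, UGITs in
#'   columns).
#' @export
solve_ugit_weights <- function(panel, alpha, tol = 1e-10) {
  stopifnot(inherits(panel, "trait_panel"))
  alpha <- as.numeric(alpha)
  if (length(alpha) != panel$k) {
    stop("alpha must have one entry per trait", call. = FALSE)
  }
  nrm <- drop(crossprod(alpha, panel$uphen %*% alpha))
  if (abs(nrm - 1) > 1e-8) {
    stop("alpha must be normalized to unit phenotypic variance", call. = FALSE)
  }
  cgen <- panel_cgen(panel)
  cov_gen <- drop(cgen %*% alpha)
  h2_sgit <- drop(crossprod(alpha, cov_gen))
  if (h2_sgit <= tol) {
    stop("SGIT has (near) zero genetic variance; cannot build UGITs",
         call. = FALSE)
  }
  cvec <- cov_gen / h2_sgit
  gamma <- diag(panel$k) - tcrossprod(alpha, cvec)
  names(cvec) <- panel$names
  dimnames(gamma) <- list(panel$names, panel$names)
  list(c = cvec, gamma = gamma)
}

#' Run the full shared-heritability decomposition on a trait panel
#'
#' Pipeline: SGI screen on the genetic correlation matrix; estimation of the
#' shared loadings w; closed-form SGIT coefficients alpha; SGIT impact
#' coefficients c and UGIT matrix Gamma; per-trait and per-combination
#' heritability summaries; and a final check that no shared impact remains
#' among the UGITs (the SGI screen re-run on the UGIT genetic correlation
#' matrix is expected to fail).
#'
#' @param panel A [trait_panel()].
#' @param threshold SGI screen threshold on |genetic correlation|
#'   (default 0.2).
#' @param w Optional known loadings; when supplied, estimation is skipped
#'   (used by the simulation study to evaluate the oracle-w combination).
#' @return An object of class `maxsh_fit` with elements `panel`, `screen`,
#'   `decomposition`, `alpha`, `c`, `gamma`, `trait_summary` (tibble),
#'   `sgit_summary`, `ugit_summary` (tibble), `ugit_ugen`, `final_screen`.
#' @export
run_maxsh <- function(panel, threshold = 0.2, w = NULL) {
  stopifnot(inherits(panel, "trait_panel"))
  screen <- check_sgi(panel$ugen, threshold = threshold)
  if (!screen$passed) {
    stop("SGI screen failed: min |off-diagonal r| = ",
         formatC(screen$min_abs_offdiag, digits = 4, format = "f"),
         " (threshold ", threshold, "), positive definite = ", screen$pd_ok,
         ", rank-one signs = ", screen$sign_rank1_ok, call. = FALSE)
  }

  if (is.null(w)) {
    dec <- estimate_w(panel$ugen)
  } else {
    dec <- structure(
      list(w = as.numeric(w), w2 = as.numeric(w)^2,
           uunsh = NULL, loss = loss_value(w, panel$ugen),
           boundary = FALSE, n_starts = 0L, n_converged = NA_integer_),
      class = "shared_decomposition"
    )
  }

  alpha <- solve_alpha(panel, dec$w)
  ug <- solve_ugit_weights(panel, alpha)

  trait_summary <- tibble::tibble(
    trait = panel$names,
    h2 = panel$h2,
    w = dec$w,
    w2 = dec$w2,
    h2_shared = dec$w2 * panel$h2,
    h2_unshared = (1 - dec$w2) * panel$h2,
    c = ug$c
  )

  sgit_summary <- combo_moments(alpha, panel, dec$w)
  ugit_summary <- purrr::map_dfr(seq_len(panel$k), function(i) {
    combo_moments(ug$gamma[, i], panel, dec$w)
  })
  ugit_summary <- dplyr::mutate(ugit_summary,
                                trait = panel$names, .before = 1)

  # genetic correlations among UGITs; zero-heritability UGITs get zero rows
  cgen <- panel_cgen(panel)
  cov_ugit <- crossprod(ug$gamma, cgen %*% ug$gamma)
  v <- diag(cov_ugit)
  scale <- ifelse(v > 1e-8, 1 / sqrt(pmax(v, 1e-300)), 0)
  if (any(v <= 1e-8)) {
    warning("some UGITs have heritability below 1e-8; their genetic ",
            "correlations are reported as 0", call. = FALSE)
  }
  ugit_ugen <- (scale %o% scale) * cov_ugit
  ugit_ugen[] <- pmin(pmax(ugit_ugen, -1), 1)
  diag(ugit_ugen) <- 1
  dimnames(ugit_ugen) <- list(panel$names, panel$names)

  final_screen <- tryCatch(check_sgi(ugit_ugen, threshold = threshold),
                           error = function(e) {
                             structure(list(passed = FALSE, pd_ok = FALSE,
                                            min_abs_offdiag = NA_real_,
                                            threshold = threshold,
                                            sign_rank1_ok = FALSE,
                                            sign_vector = NULL),
                                       class = "sgi_verdict")
                           })

  structure(
    list(panel = panel, screen = screen, decomposition = dec,
         alpha = alpha, c = ug$c, gamma = ug$gamma,
         trait_summary = trait_summary,
         sgit_summary = sgit_summary, ugit_summary = ugit_summary,
         ugit_ugen = ugit_ugen, final_screen = final_screen),
    class = "maxsh_fit"
  )
}

#' @export
print.maxsh_fit <- function(x, ...) {
  cat("Shared-heritability fit on", x$panel$k, "traits\n\n")
  print(x$trait_summary)
  cat("\nSGIT: h2_total = ",
      formatC(x$sgit_summary$h2_total, digits = 4, format = "f"),
      ", h2_shared = ",
      formatC(x$sgit_summary$h2_shared, digits = 4, format = "f"),
      ", Q = ", formatC(x$sgit_summary$q, digits = 4, format = "f"),
      "\n", sep = "")
  cat("Residual SGI among UGITs: ",
      if (x$final_screen$passed) "detected (unexpected)" else "none",
      "\n", sep = "")
  invisible(x)
}

#' Tidy per-trait coefficients of a shared-heritability fit
#'
#' @param x A `maxsh_fit`.
#' @param ... Unused.
#' @return Tibble with one row per trait: heritability, shared loading `w`,
#'   shared/unshared heritability split, SGIT coefficient `alpha`, impact
#'   coefficient `c`, and the UGIT heritability.
#' @method tidy maxsh_fit
#' @export
tidy.maxsh_fit <- function(x, ...) {
  dplyr::mutate(x$trait_summary,
                alpha = as.numeric(x$alpha),
                h2_ugit = x$ugit_summary$h2_total)
}

#' One-row summary of a shared-heritability fit
#'
#' @param x A `maxsh_fit`.
#' @param ... Unused.
#' @return Tibble with `k`, `loss`, SGIT total/shared heritability, `q`, and
#'   whether any residual shared impact was detected among UGITs.
#' @method glance maxsh_fit
#' @export
glance.maxsh_fit <- function(x, ...) {
  tibble::tibble(
    k = x$panel$k,
    loss = x$decomposition$loss,
    h2_sgit = x$sgit_summary$h2_total,
    h2_sgit_shared = x$sgit_summary$h2_shared,
    q = x$sgit_summary$q,
    residual_sgi = x$final_screen$passed
  )
}

#' Plot the per-trait heritability split of a fit
#'
#' Stacked bars of shared vs unshared heritability per trait.
#'
#' @param object A `maxsh_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot maxsh_fit
#' @export
autoplot.maxsh_fit <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object$trait_summary[, c("trait", "h2_shared", "h2_unshared")],
    cols = c("h2_shared", "h2_unshared"),
    names_to = "component", values_to = "h2",
    names_prefix = "h2_"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$trait, y = .data$h2,
                                  fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = expression(h^2),
                  fill = NULL,
                  title = "Heritability split by shared genetic factor") +
    ggplot2::theme_minimal()
}
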