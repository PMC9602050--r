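# Simulation engine for validating the shared-heritability estimators:
# random unshared/environmental correlation matrices, full panels drawn from
# the generative model, and the accuracy metrics (delta-W, Q) aggregated
# over replicates. All randomness flows through R's global RNG; the scenario
# runners seed it deterministically per replicate.

# Shrink a symmetric unit-diagonal matrix toward the identity until its
# smallest eigenvalue clears `target`; lam is the identity weight, searched
# on a coarse grid from below.
pd_repair <- function(u, target = 1e-6) {
  if (is_pd_corr(u, target)) return(u)
  for (lam in seq(0.05, 1, by = 0.05)) {
    v <- (1 - lam) * u + lam * diag(nrow(u))
    if (is_pd_corr(v, target)) return(v)
  }
  diag(nrow(u))
}

#' Random unshared genetic correlation matrix
#'
#' Each off-diagonal entry is independently zero with probability `s`, and
#' otherwise Uniform(-d1, d1); the matrix is symmetrized with unit diagonal.
#' Draws failing positive definiteness are redrawn (up to 50 times), then
#' shrunk toward the identity by the smallest amount restoring a smallest
#' eigenvalue above 1e-6.
#'
#' @param k Number of traits.
#' @param s Proportion of zero entries, in \[0, 1\].
#' @param d1 Amplitude of the uniform distribution for non-zero entries.
#' @return K x K correlation matrix.
#' @export
gen_unsh <- function(k, s, d1) {
  stopifnot(s >= 0, s <= 1, d1 >= 0)
  for (try in 1:50) {
    u <- diag(k)
    idx <- upper.tri(u)
    n_off <- sum(idx)
    vals <- ifelse(stats::runif(n_off) < s, 0,
                   stats::runif(n_off, -d1, d1))
    u[idx] <- vals
    u <- u + t(u) - diag(diag(u))
    diag(u) <- 1
    if (is_pd_corr(u, 1e-6)) return(u)
  }
  pd_repair(u)
}

#' Random environmental correlation matrix
#'
#' Off-diagonals Uniform(-d2, d2); same positive-definiteness repair as
#' [gen_unsh()].
#'
#' @param k Number of traits.
#' @param d2 Amplitude of the uniform distribution.
#' @return K x K correlation matrix.
#' @export
gen_env <- function(k, d2) {
  gen_unsh(k, s = 0, d1 = d2)
}

#' Parameters of one simulation scenario
#'
#' @param k Number of traits (>= 3).
#' @param w2 Nominal proportion of heritability explained by the shared
#'   genetic factor, in (0, 1).
#' @param h2 Heritability applied to every trait, in (0, 1).
#' @param s Proportion of zeros in the unshared genetic correlation matrix.
#' @param d1 Amplitude for non-zero unshared genetic correlations.
#' @param d2 Amplitude for environmental correlations.
#' @param same_w If `TRUE` all traits get the nominal `w2`; otherwise
#'   per-trait `w2` values are spread evenly across `w2 + [-0.1, 0.1]`,
#'   clipped to \[0.05, 0.95\].
#' @param reps Number of replicates.
#' @param seed RNG seed for the scenario.
#' @return A list of class `scenario_params`.
#' @export
scenario_params <- function(k, w2, h2, s = 0.3, d1 = 0.5, d2 = 0.5,
                            same_w = TRUE, reps = 1000, seed = 1) {
  stopifnot(k >= 3, w2 > 0, w2 < 1, h2 > 0, h2 < 1,
            s >= 0, s <= 1, d1 >= 0, d2 >= 0, reps >= 1)
  structure(list(k = k, w2 = w2, h2 = h2, s = s, d1 = d1, d2 = d2,
                 same_w = same_w, reps = as.integer(reps),
                 seed = as.integer(seed)),
            class = "scenario_params")
}

# Per-trait true loadings implied by the nominal w2.
scenario_w0 <- function(params) {
  k <- params$k
  if (params$same_w) {
    w2 <- rep(params$w2, k)
  } else {
    w2 <- params$w2 + seq(-0.1, 0.1, length.out = k)
    w2 <- pmin(pmax(w2, 0.05), 0.95)
  }
  sqrt(w2)
}

#' Draw one trait panel from the generative shared-heredity model
#'
#' Builds the true loadings w0 from the scenario, draws unshared and
#' environmental correlation matrices, assembles
#' `ugen = compose_ugen(w0, uunsh)` and
#' `uphen = compose_uphen(ugen, uenv, h2)`, and verifies all matrices are
#' positive definite (a handful of redraws; failure marks the replicate).
#'
#' @param params A [scenario_params()].
#' @return List with `panel` (a [trait_panel()]), `w0`, `uunsh`, `uenv`;
#'   or `NULL` if no positive-definite draw was found.
#' @export
simulate_panel <- function(params) {
  stopifnot(inherits(params, "scenario_params"))
  k <- params$k
  w0 <- scenario_w0(params)
  for (try in 1:10) {
    uunsh <- gen_unsh(k, params$s, params$d1)
    uenv <- gen_env(k, params$d2)
    ugen <- compose_ugen(w0, uunsh)
    uphen <- compose_uphen(ugen, uenv, rep(params$h2, k))
    if (is_pd_corr(ugen, 1e-8) && is_pd_corr(uphen, 1e-8)) {
      panel <- trait_panel(paste0("trait", seq_len(k)), rep(params$h2, k),
                           ugen, uphen)
      return(list(panel = panel, w0 = w0, uunsh = uunsh, uenv = uenv))
    }
  }
  NULL
}

#' Mean squared relative error between true and estimated loadings
#'
#' \deqn{\Delta W = \frac{1}{K}\sum_i ((w_{0i} - \hat w_i) / w_{0i})^2,}
#' evaluated after resolving the global sign of the estimate (the whole
#' vector is flipped if that reduces the metric; the loss is invariant
#' under a global flip).
#'
#' @param w0 True loadings (all nonzero).
#' @param west Estimated loadings.
#' @return Nonnegative scalar.
#' @export
delta_w <- function(w0, west) {
  w0 <- as.numeric(w0)
  west <- as.numeric(west)
  if (length(w0) != length(west)) stop("length mismatch", call. = FALSE)
  if (any(w0 == 0)) stop("delta_w undefined for zero true loadings",
                         call. = FALSE)
  dplus <- mean(((w0 - west) / w0)^2)
  dminus <- mean(((w0 + west) / w0)^2)
  min(dplus, dminus)
}

#' Run one simulation scenario
#'
#' For each replicate: draw a panel; estimate the shared loadings from the
#' simulated genetic correlation matrix; build the combination three ways
#' (closed-form alpha from the true w0, alpha from the estimated w, and the
#' GIP1 eigenvector baseline); and evaluate each combination's total and
#' shared heritability analytically against the true panel and true w0.
#' Replicates are seeded deterministically from `params$seed` so the whole
#' scenario is reproducible bit-for-bit; generation or optimization failures
#' are counted and skipped, never aborting the scenario.
#'
#' @param params A [scenario_params()].
#' @param keep_replicates If `TRUE`, attach the per-replicate tibble.
#' @return One-row tibble with the scenario parameters and the replicate
#'   means: `delta_w_mean`, `loss_mean`, `q_mean_w0`, `q_mean_west`,
#'   `q_mean_gip`, `h2_total_*` and `h2_shared_*` for the three combination
#'   variants, plus `failures` and `n_ok`.
#' @export
run_scenario <- function(params, keep_replicates = FALSE) {
  stopifnot(inherits(params, "scenario_params"))
  rows <- vector("list", params$reps)
  failures <- 0L
  for (r in seq_len(params$reps)) {
    set.seed((params$seed + 1789L * r) %% .Machine$integer.max)
    sim <- simulate_panel(params)
    if (is.null(sim)) { failures <- failures + 1L; next }
    res <- tryCatch({
      dec <- estimate_w(sim$panel$ugen)
      a0 <- solve_alpha(sim$panel, sim$w0)
      ae <- solve_alpha(sim$panel, dec$w)
      ag <- gip1_weights(sim$panel)
      m0 <- combo_moments(a0, sim$panel, sim$w0)
      me <- combo_moments(ae, sim$panel, sim$w0)
      mg <- combo_moments(ag, sim$panel, sim$w0)
      tibble::tibble(
        rep = r,
        delta_w = delta_w(sim$w0, dec$w),
        loss = dec$loss,
        q_w0 = m0$q, q_west = me$q, q_gip = mg$q,
        h2_total_w0 = m0$h2_total, h2_shared_w0 = m0$h2_shared,
        h2_total_west = me$h2_total, h2_shared_west = me$h2_shared,
        h2_total_gip = mg$h2_total, h2_shared_gip = mg$h2_shared
      )
    }, error = function(e) NULL)
    if (is.null(res)) { failures <- failures + 1L; next }
    rows[[r]] <- res
  }
  repdat <- dplyr::bind_rows(rows)
  out <- tibble::tibble(
    k = params$k, w2 = params$w2, h2 = params$h2, s = params$s,
    d1 = params$d1, d2 = params$d2, same_w = params$same_w,
    reps = params$reps, seed = params$seed,
    n_ok = nrow(repdat), failures = failures,
    delta_w_mean = mean(repdat$delta_w),
    loss_mean = mean(repdat$loss),
    q_mean_w0 = mean(repdat$q_w0),
    q_mean_west = mean(repdat$q_west),
    q_mean_gip = mean(repdat$q_gip),
    h2_total_w0 = mean(repdat$h2_total_w0),
    h2_shared_w0 = mean(repdat$h2_shared_w0),
    h2_total_west = mean(repdat$h2_total_west),
    h2_shared_west = mean(repdat$h2_shared_west),
    h2_total_gip = mean(repdat$h2_total_gip),
    h2_shared_gip = mean(repdat$h2_shared_gip),
    gip_not_above_sgit = mean(repdat$h2_shared_gip <=
                                repdat$h2_shared_west + 1e-12)
  )
  if (keep_replicates) attr(out, "replicates") <- repdat
  out
}

#' Run a grid of simulation scenarios
#'
#' Cartesian-product runner: one scenario per combination of the supplied
#' parameter values, each with a seed derived deterministically from
#' `master_seed`, returning a tidy table with one row per scenario.
#'
#' @param k,w2,h2,s,same_w Vectors of grid values.
#' @param d1,d2 Amplitudes (scalars, default 0.5).
#' @param reps Replicates per scenario.
#' @param master_seed Master seed from which per-scenario seeds are derived.
#' @return Tibble with one row per scenario (see [run_scenario()]).
#' @export
scenario_grid <- function(k = 3:5,
                          w2 = seq(0.2, 0.9, by = 0.1),
                          h2 = c(0.2, 0.5, 0.8),
                          s = c(0.3, 0.8),
                          same_w = c(TRUE, FALSE),
                          d1 = 0.5, d2 = 0.5,
                          reps = 1000, master_seed = 1) {
  grid <- tidyr::expand_grid(k = k, w2 = w2, h2 = h2, s = s, same_w = same_w)
  if (nrow(grid) == 0) return(tibble::tibble())
  purrr::pmap_dfr(
    c(grid, list(i = seq_len(nrow(grid)))),
    function(k, w2, h2, s, same_w, i) {
      run_scenario(scenario_params(
        k = k, w2 = w2, h2 = h2, s = s, d1 = d1, d2 = d2,
        same_w = same_w, reps = reps,
        seed = (master_seed + 104729L * i) %% .Machine$integer.max
      ))
    }
  )
}

#' Plot shared heritability of the optimized combination against GIP1
#'
#' One point per scenario; points above the diagonal are scenarios where the
#' optimized combination captures more shared heritability than the leading
#' genetic principal component.
#'
#' @param results A scenario table from [scenario_grid()].
#' @return A ggplot object.
#' @export
plot_sgit_vs_gip <- function(results) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$h2_shared_gip,
                               y = .data$h2_shared_west,
                               colour = factor(.data$k))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "shared heritability, GIP1",
                  y = "shared heritability, SGIT (estimated w)",
                  colour = "traits") +
    ggplot2::theme_minimal()
}
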