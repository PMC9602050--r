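test_that("loss is zero at the generating loadings and sums squared residuals", {
  w <- c(0.6, 0.8, 0.9)
  u <- compose_ugen(w, diag(3))
  expect_equal(loss_value(w, u), 0)
  expect_equal(loss_value(rep(0, 3), u), sum(u[upper.tri(u)]^2))
  # hand arithmetic: (0.48-0.25)^2 + (0.54-0.25)^2 + (0.72-0.25)^2
  expect_equal(loss_value(rep(0.5, 3), u), 0.3579)
})

test_that("loss is invariant under a global sign flip", {
  set.seed(3)
  for (i in 1:20) {
    k <- sample(3:6, 1)
    u <- compose_ugen(runif(k, 0.3, 0.9), gen_unsh(k, 0.3, 0.5))
    w <- runif(k, -1, 1)
    expect_equal(loss_value(w, u), loss_value(-w, u))
  }
})

test_that("exact model loadings are recovered to high precision", {
  dec <- estimate_w(compose_ugen(c(0.6, 0.8, 0.9), diag(3)))
  expect_lt(max(abs(dec$w - c(0.6, 0.8, 0.9))), 1e-6)
  expect_lt(dec$loss, 1e-10)
  expect_true(is.matrix(dec$uunsh))
  expect_lt(max(abs(dec$uunsh - diag(3))), 1e-5)

  set.seed(41)
  for (i in 1:25) {
    k <- sample(3:6, 1)
    w <- runif(k, 0.3, 0.95)
    dec <- estimate_w(compose_ugen(w, diag(k)))
    expect_lt(max(abs(dec$w - w)), 1e-6)
    expect_lt(dec$loss, 1e-10)
  }
})

test_that("the K=3 closed form is reproduced", {
  # three consistent correlations determine w exactly:
  # w1 = sqrt(r12 r13 / r23), etc.
  r12 <- 0.48; r13 <- 0.54; r23 <- 0.72
  u <- diag(3)
  u[1, 2] <- u[2, 1] <- r12
  u[1, 3] <- u[3, 1] <- r13
  u[2, 3] <- u[3, 2] <- r23
  closed <- c(sqrt(r12 * r13 / r23), sqrt(r12 * r23 / r13),
              sqrt(r13 * r23 / r12))
  expect_equal(closed, c(0.6, 0.8, 0.9))
  expect_equal(estimate_w(u)$w, closed, tolerance = 1e-6)
})

test_that("sign-flipped matrices give sign-flipped loadings, canonicalized", {
  w <- c(0.6, 0.8, 0.9)
  s <- c(1, -1, 1)
  u <- (s %o% s) * compose_ugen(w, diag(3))
  dec <- estimate_w(u)
  expect_gte(sum(dec$w), 0)
  expect_equal(abs(dec$w), w, tolerance = 1e-6)
  expect_equal(sign(dec$w) * sign(dec$w[1]), s * s[1])
})

test_that("alpha is normalized and symmetric panels give equal weights", {
  # exchangeable panel: equal h2, equal w, equicorrelated everything
  w <- rep(0.8, 4)
  panel <- model_panel(w = w, h2 = rep(0.5, 4),
                       uunsh = diag(4), uenv = diag(4))
  a <- solve_alpha(panel, w)
  expect_equal(max(a) - min(a), 0, tolerance = 1e-12)
  expect_equal(drop(crossprod(a, panel$uphen %*% a)), 1, tolerance = 1e-10)

  set.seed(53)
  for (i in 1:20) {
    rp <- random_panel(sample(3:5, 1))
    if (is.null(rp)) next
    a <- solve_alpha(rp$panel, rp$w)
    expect_equal(drop(crossprod(a, rp$panel$uphen %*% a)), 1,
                 tolerance = 1e-8)
  }
})

test_that("alpha maximizes shared heritability over random unit directions", {
  set.seed(61)
  panel <- model_panel(w = c(0.6, 0.8, 0.9))
  a <- solve_alpha(panel, c(0.6, 0.8, 0.9))
  best <- combo_moments(a, panel, c(0.6, 0.8, 0.9))$h2_shared
  # independent numeric search over the unit phenotypic-variance ellipsoid
  for (i in 1:2000) {
    k <- rnorm(3)
    k <- k / sqrt(drop(crossprod(k, panel$uphen %*% k)))
    h <- combo_moments(k, panel, c(0.6, 0.8, 0.9))$h2_shared
    expect_lte(h, best + 1e-9)
  }
  # and a direct optimizer started away from alpha lands on the same value
  obj <- function(k) -combo_moments(k, panel, c(0.6, 0.8, 0.9))$h2_shared
  opt <- optim(c(1, 0, 0), obj, control = list(reltol = 1e-14))
  expect_equal(-opt$value, best, tolerance = 1e-6)
})

test_that("UGITs are genetically uncorrelated with the SGIT", {
  set.seed(67)
  for (i in 1:20) {
    rp <- random_panel(sample(3:5, 1))
    if (is.null(rp)) next
    panel <- rp$panel
    a <- solve_alpha(panel, rp$w)
    ug <- solve_ugit_weights(panel, a)
    h <- sqrt(panel$h2)
    cgen <- (h %o% h) * panel$ugen
    expect_lt(max(abs(crossprod(ug$gamma, cgen %*% a))), 1e-10)
    expect_equal(unname(ug$gamma),
                 diag(panel$k) - tcrossprod(unname(a), unname(ug$c)))
  }
})

test_that("fully shared panels give zero-heritability UGITs", {
  w <- rep(1, 3)
  ugen <- compose_ugen(w, diag(3))
  h2 <- c(0.3, 0.5, 0.7)
  uphen <- compose_uphen(ugen, diag(3), h2)
  panel <- trait_panel(paste0("t", 1:3), h2, ugen, uphen, pd_tol = -1)
  a <- solve_alpha(panel, w)
  ug <- solve_ugit_weights(panel, a)
  h <- sqrt(h2)
  cgen <- (h %o% h) * ugen
  for (i in 1:3) {
    expect_equal(drop(crossprod(ug$gamma[, i], cgen %*% ug$gamma[, i])), 0,
                 tolerance = 1e-12)
  }
  # the SGIT absorbs each trait's full genetic standard deviation
  expect_equal(unname(ug$c) * drop(crossprod(a, h)), h, tolerance = 1e-10)
})

test_that("c and UGIT heritabilities match a brute-force covariance assembly", {
  panel <- model_panel(w = c(0.6, 0.8, 0.9))
  w <- c(0.6, 0.8, 0.9)
  a <- solve_alpha(panel, w)
  ug <- solve_ugit_weights(panel, a)
  h <- sqrt(panel$h2)
  # brute force: explicit sums over pairs
  cov_gen <- numeric(3)
  h2_sgit <- 0
  for (i in 1:3) for (j in 1:3) {
    h2_sgit <- h2_sgit + a[i] * a[j] * h[i] * h[j] * panel$ugen[i, j]
  }
  for (i in 1:3) for (j in 1:3) {
    cov_gen[i] <- cov_gen[i] + a[j] * h[i] * h[j] * panel$ugen[i, j]
  }
  expect_equal(unname(ug$c), cov_gen / h2_sgit, tolerance = 1e-12)
  for (i in 1:3) {
    got <- combo_moments(ug$gamma[, i], panel, w)
    want <- brute_moments(unname(ug$gamma[, i]), panel, w)
    expect_equal(got$h2_total, want$h2_total, tolerance = 1e-12)
  }
})

test_that("the full pipeline reports no residual shared impact", {
  panel <- model_panel(w = c(0.75, 0.8, 0.85, 0.9), h2 = rep(0.5, 4))
  fit <- run_maxsh(panel)
  expect_false(fit$final_screen$passed)
  expect_equal(fit$decomposition$w, c(0.75, 0.8, 0.85, 0.9),
               tolerance = 1e-6)
  g <- glance(fit)
  expect_equal(g$q, fit$sgit_summary$q)
  td <- tidy(fit)
  expect_equal(nrow(td), 4)
  expect_equal(td$alpha, unname(fit$alpha))
})

test_that("the pipeline aborts when the screen fails", {
  u <- diag(3)
  u[1, 2] <- u[2, 1] <- 0.05
  u[1, 3] <- u[3, 1] <- 0.5
  u[2, 3] <- u[3, 2] <- 0.5
  panel <- trait_panel(paste0("t", 1:3), rep(0.5, 3), u,
                       compose_uphen(u, diag(3), rep(0.5, 3)))
  expect_error(run_maxsh(panel), "SGI screen failed")
})

test_that("exchangeable panels propagate symmetry through the pipeline", {
  panel <- model_panel(w = rep(0.8, 4))
  fit <- run_maxsh(panel)
  expect_equal(max(fit$alpha) - min(fit$alpha), 0, tolerance = 1e-6)
  expect_equal(max(fit$c) - min(fit$c), 0, tolerance = 1e-6)
  expect_equal(max(fit$ugit_summary$h2_total) -
                 min(fit$ugit_summary$h2_total), 0, tolerance = 1e-6)
})
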