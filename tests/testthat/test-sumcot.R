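test_that("harmonization is the identity on identical tables", {
  a <- toy_sumstats()
  out <- harmonize_sumstats(list(a, a))
  expect_equal(out[[1]], out[[2]])
  expect_equal(nrow(out[[1]]), 3)
  expect_equal(attr(out, "n_dropped_ambiguous"), 0)
  expect_equal(attr(out, "n_dropped_mismatch"), 0)
})

test_that("swapped alleles are flipped back", {
  a <- toy_sumstats()
  b <- a
  b$ea <- a$oa
  b$oa <- a$ea
  b$z <- -a$z
  b$beta <- -a$beta
  b$eaf <- 1 - a$eaf
  out <- harmonize_sumstats(list(a, b))
  expect_equal(out[[1]]$z, out[[2]]$z)
  expect_equal(out[[1]]$eaf, out[[2]]$eaf)
})

test_that("strand-ambiguous and mismatched variants are dropped and counted", {
  a <- toy_sumstats(ea = c("A", "C", "G"), oa = c("T", "T", "C"))
  b <- a
  out <- harmonize_sumstats(list(a, b))
  # rs1 is A/T (ambiguous), rs3 is C/G (ambiguous) -> only rs2 left
  expect_equal(out[[1]]$rsid, "rs2")
  expect_equal(attr(out, "n_dropped_ambiguous"), 2)

  b2 <- toy_sumstats()
  b2$ea[2] <- "A"; b2$oa[2] <- "C"     # inconsistent allele pair
  out2 <- harmonize_sumstats(list(toy_sumstats(), b2))
  expect_false("rs2" %in% out2[[1]]$rsid)
  expect_equal(attr(out2, "n_dropped_mismatch"), 1)
})

test_that("a unit-vector combination returns the input Z-scores exactly", {
  a <- toy_sumstats(z = c(3, -1, 2))
  b <- toy_sumstats(z = c(0.5, 1.5, -2.5))
  up <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  out <- combine_sumstats(list(a, b), c(1, 0), up)
  expect_equal(out$z, a$z)
  expect_equal(out$p, a$p)
  out2 <- combine_sumstats(list(a, b), c(0, 1), up)
  expect_equal(out2$z, b$z)
})

test_that("independent equal-N traits combine as z / sqrt(k)", {
  a <- toy_sumstats(z = c(3, 1, -1))
  b <- toy_sumstats(z = c(4, 0, 2))
  out <- combine_sumstats(list(a, b), c(1, 1), diag(2))
  expect_equal(out$z, (a$z + b$z) / sqrt(2))
  expect_equal(out$z[1], 7 / sqrt(2))
})

test_that("a zero-variance contrast is rejected", {
  a <- toy_sumstats()
  up <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_error(combine_sumstats(list(a, a), c(1, -1), up), "degenerate")
})

test_that("overlap inflates the combined standard error", {
  a <- toy_sumstats(z = c(3, 1, -1))
  b <- toy_sumstats(z = c(4, 0, 2))
  indep <- combine_sumstats(list(a, b), c(1, 1), diag(2))
  over <- combine_sumstats(list(a, b), c(1, 1),
                           matrix(c(1, 0.8, 0.8, 1), 2, 2))
  # with positive error correlation the sum's z shrinks relative to
  # independent sampling
  expect_lt(abs(over$z[1]), abs(indep$z[1]))
  expect_equal(over$z, (a$z + b$z) / sqrt(2 * 1.8))
})

test_that("effective N inverts the SE-frequency relation", {
  s <- tibble::tibble(eaf = rep(0.5, 10), se = rep(0.02, 10))
  expect_equal(effective_n(s), 5000)
  # identity combination of a simulated GWAS recovers the cohort size
  set.seed(137)
  coh <- simulate_cohort(n = 1200, m0 = 300, m1 = 900,
                         w = c(0.7, 0.8, 0.9), h2 = rep(0.4, 3))
  stats <- gwas_linear(coh, 1)
  expect_equal(effective_n(stats), 1200, tolerance = 0.01)
  out <- combine_sumstats(list(stats, gwas_linear(coh, 2),
                               gwas_linear(coh, 3)),
                          c(1, 0, 0), diag(3))
  expect_equal(attr(out, "effective_n"), 1200, tolerance = 0.01)
})

test_that("disjoint-cohort combination has the per-cohort effective size", {
  set.seed(139)
  w <- rep(0, 3); h2 <- rep(0.4, 3)   # mutually uncorrelated traits
  coh_a <- simulate_cohort(n = 1000, m0 = 200, m1 = 600, w = w, h2 = h2)
  coh_b <- simulate_cohort(n = 1000, m0 = 200, m1 = 600, w = w, h2 = h2)
  sa <- gwas_linear(coh_a, 1)
  sb <- gwas_linear(coh_b, 2)
  sb$eaf <- sa$eaf          # same variants measured in a second cohort
  # two uncorrelated traits on non-overlapping cohorts of n each: the
  # combined statistic carries the information of a direct GWAS of the
  # sum trait on n individuals with both traits measured
  comb <- combine_sumstats(list(sa, sb), c(1, 1), diag(2))
  expect_equal(attr(comb, "effective_n"), 1000, tolerance = 0.1)
  # oracle: direct GWAS of (y1 + y2)/sqrt(2) on one cohort of n
  ydir <- (coh_a$traits[, 1] + coh_a$traits[, 2]) / sqrt(2)
  c2 <- coh_a
  c2$traits <- cbind(ydir)
  expect_equal(attr(comb, "effective_n"),
               effective_n(gwas_linear(c2, 1)), tolerance = 0.1)
})

test_that("phenotypic correlation is recovered from null Z-scores", {
  a <- toy_sumstats()
  expect_error(estimate_pheno_corr(a, a), "fewer than 100")

  set.seed(149)
  # pure-noise traits with known phenotypic correlation 0.5, full overlap
  uenv <- matrix(c(1, 0.5, 0.2, 0.5, 1, 0.2, 0.2, 0.2, 1), 3, 3)
  coh <- simulate_cohort(n = 500, m0 = 100, m1 = 4900,
                         w = rep(0.5, 3), h2 = rep(0, 3), uenv = uenv)
  sa <- gwas_linear(coh, 1)
  sb <- gwas_linear(coh, 2)
  est <- estimate_pheno_corr(sa, sb, z_max = 2, prune_window_bp = 10000)
  expect_lt(abs(est - 0.5), 0.1)

  # disjoint cohorts: no overlap, expect zero
  coh2 <- simulate_cohort(n = 500, m0 = 100, m1 = 4900,
                          w = rep(0.5, 3), h2 = rep(0, 3), uenv = uenv)
  sc <- gwas_linear(coh2, 2)
  sc$eaf <- sa$eaf
  est0 <- estimate_pheno_corr(sa, sc, z_max = 2, prune_window_bp = 10000)
  expect_lt(abs(est0), 0.05)

  m <- pheno_corr_matrix(list(t1 = sa, t2 = sb), z_max = 2,
                         prune_window_bp = 10000)
  expect_equal(diag(m), c(t1 = 1, t2 = 1))
  expect_equal(m[1, 2], est)
})

test_that("genomic control rescales only inflated statistics", {
  a <- toy_sumstats(z = c(2.2, -1.1, 3.3))
  expect_identical(gc_correct(a, 1), a)
  expect_identical(gc_correct(a, 0.95), a)
  out <- gc_correct(a, 1.21)
  expect_equal(out$z, a$z / 1.1)
  expect_equal(out$z[1], 2.0)
  expect_equal(out$se, a$se * 1.1)
  expect_equal(out$z, out$beta / out$se)
  expect_equal(out$p, 2 * pnorm(-abs(out$z)))
  expect_error(gc_correct(a, -1), "positive")
})

test_that("the full pipeline matches a direct GWAS of the combined traits", {
  set.seed(151)
  w <- c(0.7, 0.8, 0.9)
  h2 <- rep(0.5, 3)
  ug <- compose_ugen(w, diag(3))
  up <- compose_uphen(ug, diag(3), h2)
  panel <- trait_panel(paste0("t", 1:3), h2, ug, up)
  coh <- simulate_cohort(n = 1500, m0 = 150, m1 = 850, w = w, h2 = h2)
  stats <- lapply(1:3, function(i) gwas_linear(coh, i))
  res <- run_shaher(panel, stats)

  direct_combo <- function(k) {
    y <- drop(coh$traits %*% k) / sqrt(drop(crossprod(k, up %*% k)))
    c2 <- coh
    c2$traits <- cbind(y)
    gwas_linear(c2, 1)
  }
  d <- direct_combo(res$fit$alpha)
  expect_gt(cor(res$sgit$z, d$z), 0.99)
  for (i in 1:3) {
    du <- direct_combo(res$fit$gamma[, i])
    expect_gt(cor(res$ugits[[i]]$z, du$z), 0.99)
  }
  expect_equal(res$report$n_variants, nrow(stats[[1]]))

  # genomic-control hooks apply per output
  res2 <- run_shaher(panel, stats,
                     gc_intercepts = c(sgit = 1.21, t1 = 1, t2 = 1, t3 = 1))
  expect_equal(res2$sgit$z, res$sgit$z / 1.1)
  expect_equal(res2$ugits[[1]]$z, res$ugits[[1]]$z)
})

test_that("the pipeline refuses panels without a shared impact", {
  u <- diag(3)
  u[1, 2] <- u[2, 1] <- 0.05
  u[1, 3] <- u[3, 1] <- 0.4
  u[2, 3] <- u[3, 2] <- 0.4
  panel <- trait_panel(paste0("t", 1:3), rep(0.5, 3), u,
                       compose_uphen(u, diag(3), rep(0.5, 3)))
  stats <- list(toy_sumstats(), toy_sumstats(), toy_sumstats())
  expect_error(run_shaher(panel, stats), "SGI screen failed")
  expect_error(run_shaher(panel, stats[1:2]), "one summary-statistic table")
})
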