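# Small panel constructors shared across test files. All fixtures are built
# in code; nothing is read from disk unless a test writes it first.

# Panel generated exactly from the correlation-component model.
model_panel <- function(w = c(0.6, 0.8, 0.9), h2 = rep(0.5, length(w)),
                        uunsh = diag(length(w)), uenv = diag(length(w))) {
  ugen <- compose_ugen(w, uunsh)
  uphen <- compose_uphen(ugen, uenv, h2)
  trait_panel(paste0("t", seq_along(w)), h2, ugen, uphen)
}

# Random valid panel: positive loadings, random unshared/environmental parts.
random_panel <- function(k = 4, wmin = 0.3, wmax = 0.95) {
  w <- runif(k, wmin, wmax)
  h2 <- runif(k, 0.2, 0.8)
  uunsh <- gen_unsh(k, s = 0.3, d1 = 0.5)
  uenv <- gen_env(k, d2 = 0.5)
  ugen <- compose_ugen(w, uunsh)
  uphen <- compose_uphen(ugen, uenv, h2)
  if (!is_pd_corr(ugen) || !is_pd_corr(uphen)) return(NULL)
  list(panel = trait_panel(paste0("t", seq_len(k)), h2, ugen, uphen), w = w)
}

# Independent brute-force combination moments: explicit double loops over
# trait pairs, no matrix products (oracle for combo_moments).
brute_moments <- function(k, panel, w) {
  K <- panel$k
  h <- sqrt(panel$h2)
  var_phen <- 0
  gen <- 0
  for (i in seq_len(K)) for (j in seq_len(K)) {
    var_phen <- var_phen + k[i] * k[j] * panel$uphen[i, j]
    gen <- gen + k[i] * k[j] * h[i] * h[j] * panel$ugen[i, j]
  }
  shared_sd <- 0
  for (i in seq_len(K)) shared_sd <- shared_sd + k[i] * h[i] * w[i]
  list(var_phen = as.numeric(var_phen),
       h2_total = as.numeric(gen / var_phen),
       h2_shared = as.numeric(shared_sd^2 / var_phen))
}

# Tiny summary-statistics table for harmonization / IO tests.
toy_sumstats <- function(z = c(3, -1, 2), n = 1000,
                         ea = c("A", "C", "G"), oa = c("G", "T", "A"),
                         eaf = c(0.3, 0.4, 0.2),
                         pos = c(1e6, 2e6, 3e6), chr = 1L) {
  m <- length(z)
  tibble::tibble(
    rsid = paste0("rs", seq_len(m)), chr = chr, pos = as.integer(pos),
    ea = ea, oa = oa, eaf = eaf,
    beta = z / sqrt(n), se = 1 / sqrt(n), z = z,
    p = 2 * pnorm(-abs(z)), n = as.integer(n)
  )
}
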