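---
title: "Decomposing shared and unshared heritability from GWAS summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing shared and unshared heritability from GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shaher)
```

## The model

Consider K standardized traits measured (possibly in different, partially
overlapping cohorts) with per-trait GWAS summary statistics available. The
package assumes the causal SNPs split into two sets: a *shared genetic
factor* (SGF) whose effects on all K traits are collinear — one effect
vector, scaled per trait — and *unshared* factors without such joint
collinear influence. Writing $w_i$ for the signed loading of trait $i$ on
the shared factor ($w_i^2$ is the proportion of $h_i^2$ explained by it),
the trait-trait correlation matrices decompose as

$$
U_{gen} = w w^\top + D\,U_{unsh}\,D, \qquad D = \mathrm{diag}\sqrt{1-w_i^2},
$$
$$
U_{phen} = H\,U_{gen}\,H + E\,U_{env}\,E, \qquad
H = \mathrm{diag}\sqrt{h_i^2},\; E = \mathrm{diag}\sqrt{1-h_i^2}.
$$

Both compositions preserve unit diagonals algebraically, so all four
matrices are genuine correlation matrices. `compose_ugen()` and
`compose_uphen()` implement these identities and are the generative core of
every simulation in the package.

A note on the phenotypic composition: we read the heritability weighting as
$H U_{gen} H$ with $H$ the elementwise *square root* of the heritabilities.
This is the only reading under which $U_{phen}$ keeps a unit diagonal
(each trait's variance splits as $h_i^2 + (1 - h_i^2) = 1$), and it makes
every downstream covariance formula internally consistent.

## The pipeline

**Screening.** A single shared factor leaves a strong signature on
$U_{gen}$: it must be positive definite, all off-diagonal correlations must
clear a threshold in absolute value (default 0.2), and the matrix obtained
by rounding every correlation to $\pm 1$ must have rank one — equivalently,
there must exist a sign vector $s$ with $\mathrm{sign}(r_{ij}) = s_i s_j$.
`check_sgi()` verifies all three. The threshold comparison uses the point
estimates of the correlations; we treat "significantly above the threshold"
as a plain comparison because the screen is a coarse gate, not a test, and
the rank-one sign check separately handles effect direction. Exact zero
correlations always fail.

**Loading estimation.** `estimate_w()` minimizes
$\mathrm{Loss}(w) = \sum_{i<j} (r_{ij} - w_i w_j)^2$, the squared deviation
between $U_{gen}$ and the auxiliary matrix $V = ww^\top + (I -
\mathrm{diag}\,w_i^2)$ (the model matrix with identity unshared
correlations; diagonals match identically and contribute nothing). The sum
is unweighted — no pair-count normalization — which changes the reported
loss magnitude but not the minimizer. Optimization is bounded quasi-Newton
(`L-BFGS-B`) on $[-1+\varepsilon, 1-\varepsilon]^K$
($\varepsilon = 10^{-6}$) with the analytic gradient
$\partial\mathrm{Loss}/\partial w_i = -2\sum_{j\neq i}(r_{ij}-w_iw_j)w_j$,
started from the all-equal vector at magnitudes 0.3, 0.5, 0.7, 0.9 crossed
with the screen's sign pattern and its negation (16 starts, deduplicated).
The line search can stall at machine precision near the optimum (L-BFGS-B
code 52); a solution whose projected gradient is below $10^{-6}$ is
accepted as converged. Two conventions resolve the symmetries of the loss:
the global sign flip is canonicalized to $\sum_i w_i \ge 0$, and among
starts tying within $10^{-12}$ the solution with the larger $\sum w_i^2$ is
kept. A loading at the box edge is flagged — it means a trait's
heritability is estimated as fully shared. The unshared correlation matrix
is recovered as $D^{-1}(U_{gen} - ww^\top)D^{-1}$ with its diagonal forced
to one and off-diagonals clipped to $[-1, 1]$.

**The optimized combination.** The shared-impact trait (SGIT) is the linear
combination $t = \alpha^\top y$ maximizing the heritability explained by
the shared factor, $(k^\top H w)^2 / (k^\top U_{phen} k)$. The closed-form
maximizer is

$$
\alpha = \frac{U_{phen}^{-1} H w}{\sqrt{w^\top H U_{phen}^{-1} H w}},
$$

normalized so $\alpha^\top U_{phen}\,\alpha = 1$ (unit phenotypic
variance). The normalization matters downstream: the impact coefficients
$c_i = (C_{gen}\alpha)_i / (\alpha^\top C_{gen}\alpha)$ with $C_{gen} = H
U_{gen} H$ presuppose an SGIT on the same variance scale as the original
traits. Each unshared-impact trait is the *genetic* residual
$\mathrm{UGIT}_i = y_i - c_i\,t$; genetic rather than phenotypic
covariances are used because only the genetic component of each trait
should be adjusted. Collecting coefficients columnwise,
$\Gamma = I - \alpha c^\top$, and $\Gamma^\top C_{gen}\,\alpha = 0$ holds
as an algebraic identity — every UGIT is genetically uncorrelated with the
SGIT. `run_maxsh()` chains all stages and finishes with a correctness
check: the SGI screen re-run on the UGIT genetic correlation matrix, which
is expected to fail (no residual shared impact). UGITs with heritability
below $10^{-8}$ get zero correlation entries rather than 0/0.

**Baseline.** `gip1_weights()` implements the comparison method: the
leading eigenvector of $C_{gen}$ (principal component analysis on the
genetic covariances), rescaled to unit phenotypic variance so its
heritability is directly comparable to the SGIT's. A leading eigenvalue
tied within $10^{-10}$ (e.g. $w = 0$ with identity unshared correlations)
is reported as a degenerate spectrum rather than silently picking a
direction.

**Summary-statistic combination.** `combine_sumstats()` produces the GWAS
of any linear combination from the per-trait GWASs alone. On the doubly
standardized scale (standardized trait, standardized genotype) each
per-SNP effect is $b_i = z_i/\sqrt{n_i}$ with standard error
$1/\sqrt{n_i}$; we use this rather than $z/\sqrt{n - 2 + z^2}$ — at GWAS
sample sizes the difference is negligible, and it keeps the method a pure
function of the declared inputs (Z-scores and sample sizes). The combined
effect is $\sum_i k_i b_i$ and its squared standard error
$\sum_{i,l} k_i k_l\, U_{phen,il}\, se_i\, se_l$, both divided by the
normalizer $k^\top U_{phen} k$ (which cancels in the Z-score). The
phenotypic correlation matrix here plays the role of the correlation of
per-SNP estimation errors across traits: when estimated from insignificant
Z-scores of the same GWASs (`estimate_pheno_corr()`), it automatically
absorbs partial sample overlap; with full overlap it coincides with the
true phenotypic correlation. Output betas and SEs are re-expressed on the
conventional dosage scale via the effect-allele frequency.

The effective sample size of a combined GWAS inverts the standard
SE-frequency relation, $n_j = 1/(2p_j(1-p_j)\,se_j^2)$, and reports the
median over SNPs; it is exact for the identity combination and behaves as
an information-equivalent sample size otherwise. A single trait-level
median is reported rather than a per-SNP column.

**Harmonization and quality control.** Input tables are inner-joined on
variant id; alleles are aligned to the first table with Z and frequency
flips for swapped pairs; strand-ambiguous pairs (A/T, C/G) and
inconsistent pairs are dropped with counts. `read_sumstats()` applies the
standard filters — minor allele frequency at least 0.01 by default, rows
with a p-value of exactly zero removed (such rows carry no usable
information and break downstream log-scale work; the writer emits
$-\log_{10} p$ alongside p to avoid producing them), duplicate ids reduced
to first occurrence. Genomic-control correction multiplies SEs by
$\sqrt{\text{intercept}}$ and divides Z accordingly, only when the
intercept exceeds one.

**Locus post-processing.** `clump_loci()` is greedy distance clumping:
repeatedly take the most significant uncovered SNP below $5\times10^{-8}$
and claim ±500 kb around it. Overlap and novelty calls use the
lead-within-span predicate on closed intervals with 1-based positions; a
lead exactly one base outside a span is outside it. The locus-overlap
matrix is not symmetric by construction (a's lead inside b's span is not
the same relation as b's lead inside a's span); the scaled matrix divides
by the smaller locus count of the pair, and pairs involving an empty locus
list scale to zero.

## The simulation study

`run_scenario()` validates the estimator under a six-parameter generative
model: K traits; nominal shared proportion $w^2$ (either equal across
traits or spread evenly over $w^2 \pm 0.1$, clipped to $[0.05, 0.95]$);
common heritability $h^2$; sparsity $s$ of the unshared correlation matrix;
and amplitudes $d_1$, $d_2$ of the uniform distributions for unshared and
environmental correlations. Default amplitudes are $d_1 = d_2 = 0.5$ —
moderate correlation noise, large enough that the rank-one structure is
genuinely obscured at small $w$. Random matrices failing positive
definiteness are redrawn up to 50 times, then shrunk toward the identity by
the smallest grid step $\lambda \in \{0.05, 0.10, \dots\}$ restoring a
smallest eigenvalue above $10^{-6}$.

Per replicate, the panel is drawn, the loadings re-estimated from the
simulated $U_{gen}$, and three combinations evaluated *analytically against
the true matrices*: the optimized combination built from the true loadings,
the one built from the estimated loadings, and the eigenvector baseline.
Accuracy is $\Delta W$, the mean over traits of the squared relative error
$((w_{0i} - \hat w_i)/w_{0i})^2$ after resolving the global sign;
specificity is $Q$, the ratio of the combination's shared to total
heritability. Every replicate is seeded deterministically from the scenario
seed, so whole scenario tables reproduce bit-for-bit. Replicate failures
are counted, never propagated.

The suite and the acceptance script run these scenarios at 1,000
replicates each — large enough that the Monte-Carlo standard error of a
scenario mean is a few percent of its value, small enough that the whole
grid completes in minutes on one core. The full factorial grid
(K ∈ {3,4,5} × eight $w^2$ values × three $h^2$ × two sparsities × equal/
spread loadings = 288 scenarios) is exposed through `scenario_grid()` for
users who want the complete map.

Two empirical behaviours are worth stating plainly, since the test suite
checks them. First, estimation accuracy collapses for three traits at
small shared proportions ($w^2 \le 0.3$): with three traits the loss has
exactly as many informative equations as unknowns, so correlation noise
propagates directly into $\hat w$. Second, at moderate shared proportions
the per-replicate contest between the optimized combination (built from
*estimated* loadings) and the eigenvector baseline is close to a coin
toss weighted by estimation noise — the two differ by well under a
percentage point of heritability there — and the optimized combination
only dominates replicate-by-replicate once the shared factor is strong.
With the *true* loadings, its dominance is a theorem (it is the exact
maximizer) and the suite asserts it against ten thousand random
unit-variance combinations.

## The cohort generator

`simulate_cohort()` builds individual-level data matching the model:
independent biallelic SNPs (dosages Binomial(2, MAF), column-standardized),
a shared effect vector scaled per trait by $w_i h_i/\sqrt{M_0}$, per-SNP
unshared effects drawn jointly across traits with correlation $U_{unsh}$
and scaled by $\sqrt{1-w_i^2}\,h_i/\sqrt{M_1}$, plus jointly drawn noise.
The $1/\sqrt{M}$ scalings make the expected variance contributions equal
$w_i^2h_i^2$, $(1-w_i^2)h_i^2$ and $1-h_i^2$ at finite SNP counts; traits
are re-standardized empirically afterwards because the decomposition is
exact only in expectation. Variants sit on one synthetic chromosome at
10 kb spacing so distance-based locus procedures are meaningful on the
output of `gwas_linear()`.

What the generator deliberately lacks: linkage disequilibrium between
SNPs, case-control ascertainment and liability-scale effects, population
structure, and relatedness. Tests passing on these cohorts therefore
demonstrate the *algebra* of the pipeline — that combined summary
statistics match a direct GWAS of the combined trait to correlation
above 0.99, that effective sample sizes invert correctly, that genetic
residualization removes shared signal — not robustness to LD-induced
correlation between test statistics or to confounding. For real data
those concerns are delegated to the inputs: heritabilities and
correlation matrices from LD-score regression, and the genomic-control
intercept hook.

## Degenerate inputs and numerical edges

* Positive definiteness is judged by the smallest eigenvalue against a
  $10^{-8}$ tolerance, recorded on every validated matrix.
* Combinations with phenotypic variance below $10^{-12}$ (e.g. the
  difference of two perfectly correlated traits) raise an explicit
  degenerate-combination error rather than returning infinities.
* `solve_alpha()` refuses a zero shared component ($Hw = 0$) and a
  singular phenotypic matrix.
* `delta_w()` is undefined when a true loading is zero (relative error),
  and says so.
* Monomorphic SNPs are dropped by the GWAS with a count, and standardized
  genotype columns with zero variance are zeroed in the generator.

## Limitations

The framework needs at least three traits, and three is the identifiable
minimum, not a comfortable operating point — both the estimation-accuracy
collapse at small $w^2$ and the recommended practice of four or more
traits reflect that. Weakly genetically correlated traits contribute
little shared heritability and their loadings are easily overestimated.
The summary-statistic combination assumes the supplied phenotypic
correlation matrix correctly describes error correlations across input
GWASs; misspecified overlap propagates directly into combined standard
errors. Confidence intervals for the combination coefficients are not
provided.
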