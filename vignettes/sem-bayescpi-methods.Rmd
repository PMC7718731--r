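---
title: "SEM-BayesC-pi: models, priors and design choices"
author: "sembayes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SEM-BayesC-pi: models, priors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Multi-trait genome-wide association studies usually treat traits as jointly
distributed outcomes and ignore that one phenotype may causally drive
another. When trait 1 affects trait 2, a marker with a direct effect only
on trait 1 still shows an association with trait 2 — a real signal, but a
mediated one. This package implements a multi-trait Bayesian
variable-selection regression that embeds a recursive structural equation
model (SEM) among phenotypes, so that marker effects can be decomposed into
**direct**, **indirect** (transmitted through intermediate traits) and
**overall** components, each with its own window-level association test.

# Models

## Multi-trait BayesC-pi

For individual $i$ with $t$ traits and $p$ markers coded $m_{ij} \in
\{0,1,2\}$:

$$
y_i = \mu + \sum_{j=1}^{p} m_{ij}\,\alpha_j + e_i,
\qquad \alpha_j = D_j \beta_j, \qquad e_i \sim N(0, R),
$$

where $D_j = \mathrm{diag}(\delta_{j1},\dots,\delta_{jt})$ holds per-trait
inclusion indicators and $\beta_j \sim N(0, G)$. Each locus can affect any
combination of traits; the $2^t$ possible indicator vectors are labelled
(all-zero first) and carry mixture probabilities $\Pi$ with a uniform
Dirichlet prior. $G$ and $R$ have inverse-Wishart priors, the overall mean
is flat. Genotypes are deliberately **not centered or scaled** — the model
is fitted exactly as written, with $\mu$ absorbing the genotype means.

## SEM-BayesC-pi

A recursive causal structure $\Lambda$ ($\Lambda_{kl} \ne 0$ meaning trait
$l \to$ trait $k$; acyclic support, zero diagonal) enters as

$$
(I - \Lambda)\, y_i = \mu + \sum_j m_{ij} D_j \beta_j + e_i ,
$$

with **diagonal** residual covariance — the standard identifiability
condition for structural coefficients. Because a recursive system has
$\det(I-\Lambda) = 1$, the Jacobian of the transformation drops out and the
nonzero coefficients $\lambda$ (prior $N(\mathbf{1}\lambda_0, I\tau^2)$,
defaults $\lambda_0 = 0$, $\tau^2 = 1$) have an exact multivariate-normal
full conditional

$$
V_\lambda = \Big(\sum_i Y_i' R^{-1} Y_i + \tau^{-2} I\Big)^{-1},
\qquad
\hat\lambda = V_\lambda \Big(\sum_i Y_i' R^{-1} w_i +
  \tau^{-2}\mathbf{1}\lambda_0\Big),
$$

where $w_i = y_i - \mu - \sum_j m_{ij}\alpha_j$ and $Y_i$ is the sparse
design with $y_i[l]$ at row $k$ for each coefficient $(k, l)$, so that
$(I-\Lambda) y_i = y_i - Y_i \lambda$ identically. $\lambda$ is sampled
**jointly** as one normal block, and the working response $(I-\Lambda)y$
is refreshed immediately afterwards so every other update conditions on
the current $\lambda$. $\tau^2$ is a fixed tuning parameter, not sampled.

## Marker-effect updates

$(\delta_{jk}, \beta_{jk})$ are updated single-site (per locus, per trait)
with $\beta_{jk}$ integrated out of the inclusion draw under its
conditional prior $\beta_{jk} \mid \beta_{j,-k} \sim N(\cdot,\cdot)$
implied by $G$. The inclusion odds multiply the prior odds implied by
$\Pi$ (conditional on the locus's other indicators) by the marginal
likelihood ratio. This is $O(t)$ per locus instead of $O(2^t)$ and leaves
the stationary distribution unchanged; the test suite validates it against
exact enumeration of all four labels on a tiny instance with $G$, $R$,
$\Pi$ fixed. When $\delta_{jk} = 0$ the effect is drawn from its
conditional prior, so $G$ conditioning stays coherent.

The $G$ update accumulates $\beta_j \beta_j'$ over loci with at least one
nonzero indicator (degrees of freedom grow by the number of such loci),
following the model family's convention; with no active loci it is a
prior draw.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| $\nu_e$, $\nu_\beta$ | $t + 2$ | IW degrees of freedom (weakly informative; smallest integer with a finite prior mean) |
| $S_e$, $S_\beta$ | from data | scales chosen so the prior means of $R$ and of the total genetic covariance each equal half the sample phenotypic covariance; the genetic part is divided by $\sum_j 2f_j(1-f_j)$ and by the prior inclusion expectation (0.5) |
| $\lambda_0$, $\tau^2$ | 0, 1 | structural-coefficient prior mean and variance |
| window size | 100 SNPs | non-overlapping, never spanning a chromosome boundary |
| $T$ | $1/N$ | variance-proportion threshold for WPPA ($N$ = window count) |
| WPPA threshold | 0.8 | declaration cutoff; restricts the proportion of false positives below 0.2 |
| HPD mass | 0.9 | decision rule for conditional independence |
| chain | 20,000 / 5,000 / 10 | iterations / burn-in / thinning defaults (config-exposed, not claims about any dataset) |

The conjugate updates use effective inverse-Wishart scale matrices
$S\,\nu$ (posterior scale $S_e\nu_e + \sum_i e_ie_i'$ with degrees of
freedom $\nu_e + n$), matching the update rules the samplers implement.

# Causal-structure discovery

Because the phenotypic covariance is confounded by genetic effects,
conditional independence among traits is judged on the **residual**
covariance of the multi-trait (full-$R$) fit: for every trait pair
$(i,j)$ and every subset $h$ of the remaining traits, the residual partial
correlation $-\omega_{ij}/\sqrt{\omega_{ii}\omega_{jj}}$ (from the inverse
of the $(i,j,h)$ submatrix) is computed per posterior sample of $R$; the
pair is declared conditionally independent given $h$ when the 0.9 HPD
interval of those draws contains zero.

The Pearl–Verma IC algorithm turns these decisions into a CPDAG:
skeleton (edge iff *no* conditioning set separates), v-structures
($i \to k \leftarrow j$ iff $k$ is in *no* separating set of a
nonadjacent pair), then closure under the Meek orientation rules R1–R3
(R4 only matters with background knowledge, which this pipeline does not
inject). Orientation conflicts are warned about and the edge left
undirected rather than aborting — equivalence-class ambiguity is expected.
All conditioning subsets are tested since $t$ is small in practice; a
`maxCond` knob bounds the subset size for larger $t$. HPD intervals are
empirical shortest intervals on sorted samples with ties broken toward the
lower start — deterministic and assumption-free.

`enumerateOrientations()` lists all acyclic, v-structure-preserving
orientations of the undirected edges; the user picks the member to carry
into the SEM fit (the class is statistically indistinguishable, so the
choice encodes biological knowledge). A chain skeleton over three traits,
for instance, yields exactly three members.

# Effect decomposition and window inference

Per retained sample, using the **joint** draws of $\Lambda$ and $\alpha$
(not posterior means — the two are dependent):

- direct $= \alpha_j$; indirect $= \sum_{\rho=1}^{t-1}\Lambda^\rho
  \alpha_j$; overall $= (I-\Lambda)^{-1}\alpha_j$ = direct + indirect.

For each window $w$, effect type and trait: $a_w = M_w \alpha_w$,
$\sigma^2_{a_w}$ is the **population** variance of $a_w$ (divide by $n$,
no Bessel correction — exactly as defined), and $q_w =
\sigma^2_{a_w}/\sigma^2_a$ where $\sigma^2_a$ always uses the overall
effects of all markers. $q_w$ is not clamped: it can exceed 1 when a
window's genetic values anti-correlate with the rest. WPPA is the
proportion of samples with $q_w$ **strictly** greater than $T$. A zero
total genetic variance yields $q = 0$ with a warning.

Pleiotropy proportions come in two flavours: for direct effects, the
posterior mean of $\Pi$ per combination label; for overall effects, a
locus counts as affecting trait $k$ in a sample when it has a nonzero
direct effect on $k$ or on any causal ancestor of $k$ in that sample's
$\Lambda$.

# The simulator

`simulateDataset()` emulates a two-trait causal architecture: marker
allele frequencies uniform on a configurable range (default 0.05–0.5),
genotypes binomial(2, f), an optional first-order gamete-copying parameter
for LD; QTL positions uniform without replacement among the $p$ genotyped
markers; effect magnitudes gamma(shape, scale = 1) with shape in
$\{0.18, 1.48, 3.0\}$ spanning few-large to many-moderate architectures;
half the QTL affect both traits directly (scenario 1), half only trait 1
(scenario 2), so trait 2 receives part of its signal purely through the
causal path $y_2 = \lambda y_1 + u_2 + e_2$ with $\lambda = 1$ by default
and per-trait heritability 0.5.

Choices the underlying design leaves open, fixed once here:

- **Effect signs** are random $\pm 1$: a gamma distribution is
  nonnegative, and signless effects would make genetic values
  systematically directional.
- **Heritability** is defined per trait on the structural-equation scale
  (variance of the trait's own direct genetic values over the variance of
  that equation's total), since heritability of a downstream trait under
  causal propagation is otherwise ambiguous. The residual variance is set
  from the realized genetic variance, so the target is met per replicate
  up to residual-sampling noise.
- **QTL are genotyped**: causal variants are not masked from the fitted
  panel.

What the generator does *not* emulate: realistic LD beyond first-order
adjacency, allele-frequency spectra of real panels, population structure
and relatedness, dominance or epistasis. Passing tests therefore
demonstrate correctness of the samplers and inference machinery under the
generating model, not robustness to confounding found in real data; real
genotypes can be supplied through the CSV/PLINK loaders.

# Numerical choices

- Residual matrices are maintained incrementally and recomputed from
  scratch every 1000 sweeps to cap floating-point drift; the working
  response identity $y - Y\lambda = (I-\Lambda)y$ is asserted to
  $10^{-10}$ in tests.
- One seeded RNG stream per chain; identical seeds give bit-identical
  chains. No draws are parallelised within a sweep.
- The update order is fixed: $\mu$ → marker effects → $G$ → $R$ → $\Pi$
  (→ $\lambda$ in the SEM sampler).
- Non-finite state aborts with the iteration index.
- Degenerate inputs: monomorphic all-zero markers contribute no
  likelihood and fall back to prior inclusion odds; empty structure
  supports reduce the SEM sampler exactly (bit-for-bit) to the
  diagonal-$R$ multi-trait sampler.

# Evaluation harness

`pauc5()` computes the area under the empirical trapezoidal ROC for
false-positive rates in $[0, 0.05]$, with tie-grouped thresholds and
vertical interpolation at the bound — numerically identical to pROC's
partial AUC, which a test asserts. `rescalePauc5()` divides by the
diagonal's strip area $0.05^2/2 = 0.00125$ so an ideal random classifier
scores 1 and a perfect one 40.

One property worth knowing: with a *finite* number of windows the
empirical staircase of randomly ordered scores carries a half-step
discreteness bias, $E[\text{rescaled pAUC5}] \approx
\frac{f+1}{f}\cdot\frac{n^-}{n^-+1}$ with $f = 0.05\,n^-$ negatives inside
the strip — about 1.19 at 100 negatives, 1.005 at 4000. The tests pin the
quantified finite-sample value and the asymptotic limit separately.
Benchmark comparisons between methods are unaffected (both scores carry
the same geometry).

# Problem sizes used by the test and acceptance runs

The shipped validation uses desk-scale study conditions chosen once: the
parameter-recovery experiment simulates $n = 500$, $p = 1000$, 30 QTL,
gamma shape 0.18, $\lambda = 1$, $h^2 = 0.5$ and runs 20,000-iteration
chains (5,000 burn-in, thinning 10) over 20 replicates; at $p = 1000$ the
100-SNP window default would leave almost no truly null windows (30 QTL
scattered over 10 windows), so the window-level scoring in that experiment
uses 20-SNP windows (50 windows, roughly half truly null) — a property of
the scaled-down design, not a recommendation for genome-scale data, where
the 100-SNP default stands. Sampler-correctness oracles run on
deliberately tiny instances ($n \le 12$, $p \le 1$) where exact
enumeration and conjugate closed forms are available.

# Known limitations

- Only recursive (acyclic) structures: simultaneous systems are out of
  scope, as are latent confounders (IC conflicts are surfaced, not
  modelled).
- A single overall mean is the only fixed effect; additional covariates
  are not supported.
- BayesC-pi is the only mixture prior implemented; the SEM machinery is
  agnostic to that choice but other members of the whole-genome
  regression family are not provided.
- $\tau^2$ is fixed, not sampled.
- The IC step tests all subsets; beyond a dozen traits this needs the
  `maxCond` bound and the discovered class may be large.
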