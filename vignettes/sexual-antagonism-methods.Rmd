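---
title: "Models and methods: sexually antagonistic selection on continuous traits"
author: "antagsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: sexually antagonistic selection on continuous traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antagsim)
```

## The scientific question

When a continuous trait $z$ is expressed in both sexes from a shared genetic
basis but males and females have different optima, selection is sexually
antagonistic over the intervening trait range. A long-standing expectation is
that such conflict maintains genetic polymorphism. `antagsim` implements the
machinery needed to interrogate that expectation quantitatively: the nature
of selection induced by arbitrary sex-specific fitness landscapes, the
response of single-locus (continuum-of-alleles) and polygenic architectures,
and the genomic signatures a segregating antagonistic trait would leave.

## Life cycle and fitness landscapes

All models share one two-sex life cycle: a constant population with equal
adult numbers per sex; adults produce gametes in proportion to sex-specific
fecundity; gametes fuse at random; juveniles compete within each sex to fill
the next generation. Fecundity landscapes place the male optimum at $-\theta$
and the female optimum at $+\theta$, and the models are analyzed on
$z \in [-\theta, \theta]$, the region of conflict. Calls outside this
interval are hard errors, and the simulators keep state inside it (the
continuum-of-alleles mutation kernel clamps allelic values to
$[-\theta/2, \theta/2]$; a rejection-sampling alternative would distort the
kernel near the boundary in a different way and is not implemented).

The power family is

$$w_m(z) = K_m\left(1 - c_m\left[1 - \left(\tfrac{\theta - z}{2\theta}\right)^{b_m}\right]\right),
\qquad
w_f(z) = K_f\left(1 - c_f\left[1 - \left(\tfrac{\theta + z}{2\theta}\right)^{b_f}\right]\right),$$

with costs $c_u \in [0, 1]$ setting how much fecundity is lost at the
disfavored optimum and exponents $b_u > 0$ setting the shape: accelerating
(convex) for $b_u > 1$, linear at $b_u = 1$, diminishing (concave) for
$b_u < 1$. A Gaussian family
$w_u(z) = K_u \exp(-(z - o_u)^2 / 2\sigma_u^2)$ with optima $o_m = -\theta$,
$o_f = +\theta$ is provided as the standard alternative parameterization of
smooth single-optimum landscapes; $\sigma_u$ plays the role of an inverse
selection strength. All downstream code consumes only $w_u$, $w_u'/w_u$, and
$w_u''/w_u$, so both families (and, in principle, user-supplied ones) are
interchangeable.

## Invasion analysis

At a single additive autosomal locus with fully sex-concordant allelic
effects, a rare mutant of effect $x_\bullet$ in a resident population of
effect $x$ has growth rate

$$W(x_\bullet, x) = \tfrac12 \frac{w_m(x_\bullet + x)}{w_m(2x)}
 + \tfrac12 \frac{w_f(x_\bullet + x)}{w_f(2x)},$$

giving the selection gradient
$s(x) = \tfrac12[w_m'(2x)/w_m(2x) + w_f'(2x)/w_f(2x)]$ and the
disruptiveness $h(x) = \tfrac12[w_m''(2x)/w_m(2x) + w_f''(2x)/w_f(2x)]$.
An interior singular value $x^*$ (trait value $z^* = 2x^*$) satisfies
$s(x^*) = 0$; it is convergence stable when $s'(x^*) < 0$ and disruptive
when $h(x^*) > 0$. The package classifies the attracting dynamics as

* **diversifying** — attracting and disruptive: the sex-averaged fitness
  curvature at $z^*$ is positive but smaller than the summed squared
  directional-selection strengths, so branching into male- and
  female-adapted lineages follows;
* **stabilizing** — attracting, not disruptive;
* **directional** — $z^*$ is a repellor or absent, and the population is
  driven to one sex's optimum.

Derivatives are analytic per family and validated against central finite
differences (step $10^{-6}\theta$, relative tolerance $10^{-6}$); finite
differences remain the fallback strategy for landscapes without closed
forms. Root finding brackets sign changes of $s$ on a 512-point grid over
$(-\theta/2, \theta/2)$ and polishes each with `uniroot`. Diagnostics within
$10^{-10}$ (on $\theta$-normalized scale) of zero are reported as
`"boundary"` rather than silently classified, since the regime boundaries
in the $(c, b)$ plane are measure-zero.

One structural finding from implementation: for symmetric power landscapes
with strong costs (e.g. $c \gtrsim 0.6$ at $b = 1.5$) the gradient has
*three* interior roots — the central attractor flanked by two repellors near
the boundaries, where the disfavored sex's fecundity approaches $K(1-c)$
and its logarithmic slope is inflated. `find_singular()` therefore returns
all roots; classification and reporting use the attracting one. The basin
of attraction of $z^*$ is bounded by the flanking repellors, which matters
for initial conditions far from the midpoint.

For symmetric landscapes ($c_m = c_f = c$, $b_m = b_f = b$), $z^* = 0$ and
the directional-to-diversifying boundary has the closed form

$$c^* = \frac{b - 1}{b\,2^{-b} + (b - 1)(1 - 2^{-b})},$$

derived by evaluating the two classification inequalities at $z^* = 0$
(`critical_cost()`); it is cross-checked in the tests against brute-force
bisection on the classifier. No boundary exists for $b \le 1$: on
diminishing or linear landscapes selection is never diversifying, which is
why the diversifying region's infimum in $b$ is exactly 1.

## Continuum-of-alleles simulator

`run_coa()` follows one additive locus in $2n$ diploids. Each transmitted
allele mutates with probability $\mu$ by a zero-mean Gaussian step. Defaults
($n$ = 500 per sex, $\mu = 10^{-3}$ per copy, kernel s.d. $0.02\theta$)
encode small-effect mutations, the regime the invasion analysis assumes;
the mutational details beyond "small and symmetric" do not change which
qualitative outcome (branching / unimodal / directional fixation) a
landscape produces, only its timescale. Parent sampling is multinomial with
replacement, the large-gamete-number limit of the life cycle. With the
diversifying preset ($c = 0.9$, $b = 1.5$, $\theta = 2$, initial allele
$x = 0.3$) branching completes within a few times $10^4$ generations at
these defaults; directional selection with $c = 0.05$ is nearly neutral per
mutation step ($2Ns \lesssim 0.1$), so fixation at an optimum needs several
$10^5$ generations — run lengths in the tests and acceptance runs are chosen
accordingly, and cluster counts rather than timings are asserted.

Branching is detected operationally: `detect_clusters()` splits sorted
values at gaps exceeding $\theta/4$; a branched population shows two allelic
clusters near $\pm\theta/2$ and three phenotypic clusters (two optima plus
heterozygotes).

## Polygenic diallelic simulator

`run_polygenic()` is a forward two-sex Wright–Fisher simulation of $L$
diallelic loci with additive effects $\pm\delta_k$, phenotype
$z = \sum_k (x_{k,1} + x_{k,2})$, and $\theta = 2\sum_k \delta_k$ so the
genotypic extremes coincide with the sex optima. Per-allele mutation flips
$A_k \leftrightarrow a_k$ at rate $\mu$; recombination is free between
adjacent loci by default ($r = 0.5$) with arbitrary $r$ supported. The
engine is written in C++ (one generation at $N = 2000$, $L = 10$ costs well
under a millisecond, so $10^5$-generation runs are desk-scale) and consumes
R's seeded RNG in a fixed documented order, which a pure-R mirror
reproduces draw-for-draw in the tests. We use R's single seeded stream with
this documented order rather than named per-component substreams: the
replay contract delivers the same step-level testability without inventing
RNG plumbing.

Inheritance modes:

* **autosome** — ordinary diploid transmission, offspring sex assigned to
  fill $N/2$ per sex;
* **x_hemizygous** — loci on the non-recombining X; males carry a single,
  maternally inherited copy whose alleles each count twice in the
  phenotype. This dosage convention keeps both sexes on the same
  $[-\theta, \theta]$ scale; conventions without dosage doubling would
  introduce a systematic sex difference in trait range, which the model's
  fully sex-concordant assumption is designed to exclude;
* **par** — loci in the pseudoautosomal region, linked to the
  sex-determining region (SDR) at recombination fraction `r_sdr`; the
  paternal gamete's SDR allele (X or Y) determines zygote sex, and zygotes
  are drawn until each sex's quota is filled.

Populations initialize at allele frequency 0.5 per locus (maximal standing
variation) unless configured otherwise. Default $N = 2000$ balances drift
against the strong-selection presets; runs probing drift-sensitive
quantities (the balanced "remainder" locus, between-sex FST) state larger
$N$ explicitly. Burn-in defaults to half the run; stationary summaries use
post-burn-in records only.

## Summary statistics

* **Heterozygosity** $2p(1-p)$ per locus, against the neutral
  mutation–drift closed form $E[H] = 4N\mu/(8N\mu + 1)$ (stationary
  symmetric two-allele diffusion), which the simulator reproduces within
  Monte-Carlo error.
* **Between-sex FST among successful parents**: allele frequencies among
  one generation's fathers and mothers, each parent weighted by its number
  of recruited offspring (the one-generation footprint of fecundity
  selection); Nei's $(H_T - H_S)/H_T$ with equal sex weights; loci with
  $H_T = 0$ are missing, not zero. The unweighted set-of-parents variant is
  available via `weighted = FALSE` and runs roughly fivefold smaller under
  the diversifying presets; both are calibrated against the package's own
  permuted-sex control, which absorbs the estimator's finite-sample bias.
* **Sex-specific fitness associations**: per-locus OLS slopes
  $\beta_{m,k}, \beta_{f,k}$ of offspring number on within-individual
  allele frequency (dose/2), with $|\beta_{m,k} - \beta_{f,k}|$ as the
  antagonism screen and `permute_sex()` building the null.
* **Sex load** $1 - \tfrac12(\bar w_m/K_m + \bar w_f/K_f)$. The
  $K_u$-relative normalization (each sex's own maximum) is stated in all
  outputs.
* **Balanced-locus count**: loci holding $H \ge 0.25$ through the trailing
  25% of sampled records. The 0.25 threshold is half the diallelic maximum
  — far above anything mutation–drift can sustain at the preset $\mu$, and
  comfortably below the $\approx 0.5$ of a balanced locus.
* **Fecundity variance** $\mathrm{Var}[w_m]/2 + \mathrm{Var}[w_f]/2$ and
  the **MAF spectrum** (proportion of loci with minor allele frequency
  above 0.05).

The neutral-comparison rule for heterozygosity grids is a 95% CI criterion:
a parameter combination is called elevated/depressed only outside the CI of
matched neutral replicates.

## What the generator emulates — and what it does not

The simulators generate the study's own data; no external data enter. They
emulate: two separate sexes with fecundity selection, Mendelian diploid
inheritance with recombination and recurrent mutation, finite-population
drift, and sex-chromosome transmission asymmetries. They deliberately omit:
environmental variance on $z$ (heritability is 1, the best case for
detecting signatures), sex-specific allelic effects (which would let
dimorphism evolve and dissolve the conflict), dominance at the allele level
(dominance on *fitness* still emerges from landscape curvature), age
structure, and linkage to loci outside the focal block. Passing tests
therefore demonstrate the model's internal claims, not that real
populations behave this way; in real data, environmental noise and partial
intersexual correlations can only weaken the already-weak signatures.

## Numerical choices and known limitations

* Problem sizes: analytic checks run in seconds; simulation-based checks
  use $N$ between 500 and $10^4$ and $10^4$–$5\times10^5$ generations,
  stated inline where used. Near-critical parameter combinations (costs
  within a few percent of $c^*$) are drift-sensitive at these sizes: the
  polymorphism a very large population would hold at $c$ slightly above
  $c^*$ can collapse at $N = 2000$, which is visible as a sharp rather than
  gradual heterozygosity transition in cost sweeps.
* The balanced "remainder" locus under asymmetric stabilizing selection
  carries a selective advantage of order half a percent at the presets; it
  is stably held at $N = 10^4$ but drift-dominated at $N \lesssim 10^3$,
  where only transient polymorphism with identity turnover is visible.
* Mutation counts enter per allele copy per generation; at the preset
  $\mu = 5\times10^{-6}$, turnover statistics need runs long relative to
  $1/(2N\mu)$.
* `detect_clusters()` is a deliberate gap heuristic, not model-based
  clustering; it is appropriate because branched populations are separated
  by empty trait regions of width $\gg \theta/4$.
* The PAR quota-rejection scheme discards opposite-sex zygotes once a sex
  is full; this conditions on the realized sex ratio exactly as the
  within-sex competition step intends, but it means offspring counts in
  `par` mode include only recruited zygotes.
* Analytic invasion conditions are implemented for autosomes only;
  X-linked and PAR questions are answered by simulation (the sex-linkage
  heterozygosity ordering PAR $\ge$ autosome $\ge$ X at marginally
  diversifying costs is a tested property).

## A worked example

```{r example, eval = FALSE}
lp <- symmetric_power(c = 0.9, b = 1.5, theta = 2)
classify_regime(lp)
#> [1] "diversifying"

cfg <- coa_config(lp, n_per_sex = 500, generations = 50000, init_x = 0.3)
res <- run_coa(cfg, seed = 42)
detect_clusters(res$final$x1 + res$final$x2, gap = 0.5)$means
#> [1] -2.00 0.00 2.00  (approximately: male optimum, heterozygotes, female optimum)
```

The same workflow drives the polygenic model through `architecture()`,
`run_polygenic()`, and `summarize_run()`; `scripts/acceptance.R` at the
repository root re-derives the package's headline numbers end to end.
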