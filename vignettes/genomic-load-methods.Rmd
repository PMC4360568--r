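---
title: "Methods: the genomic-load models in mutload"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the genomic-load models in mutload}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutload)
```

`mutload` models the balance between the deleterious mutations humans
carry and the selection that removes them. This vignette documents the
models, their assumptions, the free parameters and their defaults, the
numerical choices, and what the synthetic-data generators do and do not
emulate.

## Notation and global parameters

All loads are diploid-genome counts. `model_params()` holds:

| field | default | meaning |
|---|---|---|
| `M` | 7 | mean heterozygous deleterious mutations per adult diploid germ line |
| `N` | 1 | mean new deleterious mutations per zygote per generation |
| `L_haploid` | 20,000 | conserved functioning genes per haploid set |
| `genome_bp_diploid` | 6e9 | base pairs in the diploid genome |
| `mu_per_bp_div` | 5e-10 | mutation rate per bp per mitotic division |
| `x_fraction_haploid` | 0.05 | genome fraction on the X chromosome |
| `generation_years` | 25 | years per generation |

The defaults are the round figures of the underlying model: `M = 7` sits
at the top of the "single figures, below 7" range the consanguinity
arguments support, and `N = 1` is the midpoint of the 0.5–1.5 range for
the deleterious mutational input. Statements about the diploid gene
complement ("about 40,000 genes") are `2 * L_haploid`.

## The Poisson load and the truncation equilibrium

Meiosis distributes parental mutations into gametes at random, and new
mutations arrive independently, so zygote loads are Poisson with mean
`M + N`. At mutation–selection balance the adult mean must return to
`M`; selection therefore removes mass from the upper tail of the zygote
distribution.

`solve_truncation_equilibrium()` computes the *minimal* such scheme —
hard truncation with fractional acceptance at the boundary count. The
survivor set is `{k < k_star}` plus a fraction `a` of `{k = k_star}`,
and `(k_star, a)` solve "survivor mean = M" exactly. Because the
conditional mean of the truncated distribution is strictly increasing
in the threshold, the smallest threshold whose fully-truncated mean
reaches `M` admits a unique `a` in `[0, 1]`; the solver scans
thresholds with cumulative sums and solves the linear equation for `a`.

```{r}
sol <- solve_truncation_equilibrium(model_params(M = 7, N = 1))
unlist(sol[c("k_star", "accept_at_k_star", "loss_fraction")])
```

Hard truncation is a lower bound on the zygote loss: any selection
scheme spread over more load classes must discard more zygotes to
achieve the same mean shift. Richer multi-system synergy models put the
total loss near 30%; the hard-truncation answer at the defaults is
about 19%. The package keeps both: the analytic solver returns the
truncation bound, and the forward simulator (below) measures the loss
of the graded model. They are not expected to agree, and no tuning
forces them to.

Numerical choices: the Poisson support is auto-extended until the
excluded tail mass is below 1e-14 and then renormalised, so every
returned mass function sums to one within 1e-12 and the mean is exact
to well within the solver tolerance (default 1e-9 on the
post-selection mean). `N = 0` returns an identity solution rather than
degenerate truncation.

## The synergistic-selection simulator

The forward model groups the `L_haploid` conserved genes into essential
genetic systems. The default architecture is ten equal systems of
2,000 genes; the underlying statement is only that systems comprise
"hundreds or thousands" of genes, so the partition is configurable and
ten equal systems is the neutral choice.

Viability depends on the worst essential-system count through
`selection_rule()`:

* ≥ 4 in any essential system: lethal at (or shortly after) conception;
* 3: postnatal death with probability `q3` (default 0.3);
* 2: postnatal death with probability `q2` (default 0.05);
* ≤ 1: survives.

`q3` and `q2` quantify ordinal statements ("might die in infancy…",
"could also die…"); the defaults are documented free parameters chosen
once — a substantial but not certain risk at three hits, a small one at
two — and `sweep_loss_fraction()` exposes their effect on the
equilibrium loss rather than pretending a point value is known.

Each generation: parents are paired uniformly at random with
replacement (sex is tracked for bookkeeping but does not constrain
pairing); each parent's per-system counts are thinned binomially with
probability 1/2 (meiosis); Poisson(`N`) new mutations are added, each
landing in a system with probability proportional to its size
(implemented as independent Poisson(`N * share`) draws per system,
which is the exact multinomial split of a Poisson total); the viability
rule is applied; survivors are sampled back to the fixed population
size. New and inherited mutations are exchangeable — only counts per
system are tracked, not gene identities — which loses
homozygosity bookkeeping (delegated to the consanguinity module) but
makes population-scale runs cheap. An X-linked side-count is maintained
by binomial thinning at rate `x_fraction_haploid / 2`.

Conception-stage loss and postnatal deaths are reported **separately**
per generation: the model itself does not say how much of the total
loss is pre- versus postnatal, so the simulator does not collapse the
two into one number.

Problem sizes: the package's own checks run the simulator at 5,000
adults for 200 generations for the stationarity analysis (the final
50 generations show no trend in the mean adult load) and 1,000 adults
for the shorter property checks; both settle well before the analysis
window. Extinction (no survivors in a generation) raises a structured
error carrying the partial series.

## First-cousin autozygosity and the estimation of M

A heterozygous allele in one shared grandparent appears homozygous in a
first-cousin child only if it traverses six meioses: down both branches
to the two cousins and from each cousin to the child. The probability
is (1/2)^6 = 1/64, which `per_allele_autozygosity()` obtains by
exhaustive gene-dropping enumeration over every Mendelian transmission
outcome of the pedigree (the sibling-mating pedigree gives (1/2)^4, an
unrelated pairing 0). The enumeration, not the closed form, is the
implementation; the closed form is the test oracle.

With two shared grandparents each carrying Poisson(`M`) independent
rare alleles, the autozygous count in the child is Poisson with mean
`M/32` (consistent with the inbreeding coefficient `F = 1/16` via
`F * M/2`), so

* disease fraction: `D = 1 - exp(-M/32)`,
* inversion: `M = -32 * log(1 - D)`.

```{r}
estimate_M(0.10)
```

Assumptions stated explicitly: "recessive disease" means at least one
autozygous deleterious locus, with penetrance 1 by default
(configurable); new mutations in the cousins' own gametes are ignored
because they cannot be identical by descent; no inbreeding elsewhere in
the pedigree. The small-`M` linear form `D ≈ M/32` is exposed via
`linear = TRUE`. Note the richer published estimation machinery that
yielded `M = 4–8` used a larger assumed gene count and a fuller model;
this package's simpler inversion gives a smaller estimate at `D = 0.10`
(about 3.4) and both statements are kept side by side rather than
reconciled.

## X-linked risk algebra

The X chromosome carries 5% of the haploid genome, so among `M`
diploid-load mutations the expected X-linked count is `M/40`
(`x_linked_expected_load()`; a male-viability factor below 1 excludes
male-lethal X alleles from male cohorts). The carrier-risk algebra
attributes the entire male death excess (ratio `rho`, default 1.5) to
males carrying a deleterious X-linked mutation with relative risk `rr`,
with **non-carrier males at the female baseline risk** — the model
assumption behind the whole table, stated here prominently. Then

* prevalence: `p = (rho - 1) / (rr - 1)`,
* carrier fraction among male deaths: `rr * p / rho`.

`rr` is read as a risk ratio; under the attribution model the carrier
odds among cases are exactly `rr` times the control odds, so the odds
ratio of a case/control carrier table is the consistent estimator
(`estimate_rr()`, Wald CI on the log odds ratio). Display rounding is
to the nearest whole percent (36.67 prints as 37); raw values are
always retained.

```{r}
build_table(c(3, 6, 11), sex_ratio = 1.5)
```

## Neutral-mutation kinetics

A new neutral allele in a stable population is a critical
Galton–Watson process. The default offspring model is Poisson with
mean 1; the two-child family model (each copy transmitted to each of
two children with probability 1/2, i.e. 25% lost / 50% one copy / 25%
both) is available as `offspring = "binomial"`. For offspring variance
`sigma^2`, survival to generation `n` behaves as `2 / (sigma^2 * n)` —
`2/n` for Poisson (`sigma^2 = 1`) — and the copy number conditional on
survival as `sigma^2 * n / 2`, so the unconditional mean stays at one
copy. The simulators exploit additivity (`sum of Poisson = Poisson`,
`sum of Binomial(2, 1/2) = Binomial(2k, 1/2)`) to step whole lineages
at once; estimates carry Monte-Carlo standard errors, and checks use
1e5 lineages.

The clock arithmetic is exact rational arithmetic at the defaults:
`5e-10 * 6e9 = 3` miscopies per division; `3 * (40 + 60) / 2 = 150`
new base changes per zygote (the 1/2 is the package's stated
convention: each gamete transmits one strand of the lineage's diploid
miscopies — the interpretation that makes the default consistent with
"over 100"); `(1/300 * 3e9) / 100 = 100,000` generations, times 25
years = 2.5 million years. The divergence comparison is haploid (two
homologous strands, 3e9 aligned bases), which is what reproduces the
printed generation count; the divergence density is treated as
SNV-only.

## Synthetic cohorts: what they emulate and what they do not

`simulate_population()`, `simulate_cousin_cohort()` and
`simulate_case_control()` generate exactly the stochastic structure the
estimators assume: Poisson loads, per-meiosis Mendelian gene dropping,
and carrier flags at the attribution-model rates (the case rate is
obtained by calling the risk-algebra functions, not re-derived). Every
generator is deterministic under its seed and echoes its full
parameters in the cohort header, so any file can be regenerated
bit-identically.

They do **not** emulate: base-level sequence or VCF structure, linkage
and recombination, locus identity (hence allelic heterogeneity),
variable penetrance or ascertainment bias in disease scoring, family
structure beyond the single pedigree analysed, or demographic change.
Passing parameter-recovery tests on these cohorts therefore shows the
estimators are correct *under the model's own assumptions* — it says
nothing about robustness to the violations real cohorts exhibit.

## Known limitations

* The truncation solver and the synergy simulator are two deliberately
  different selection models; their loss fractions differ and should.
* The mean adult load of the synergy simulator equilibrates at a value
  set by the viability rule, not at the founding `M`; the rule's `q`
  defaults are order-of-magnitude choices, which is why the sweep
  exists.
* The consanguinity inversion is a point-model inverse, not a
  likelihood; its confidence statements come from the binomial error of
  the observed fraction only.
* The X-linked table is an attribution bound: it assumes the whole male
  excess is X-linked recessive, and says nothing about the competing
  heterozygous-advantage explanation.
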