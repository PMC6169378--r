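---
title: "Estimating pairwise relatedness in admixed populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating pairwise relatedness in admixed populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inrelate)
```

## The problem

The relatedness $r_{XY}$ between two diploid individuals is twice their
coancestry $\theta_{XY}$, the probability that a random allele drawn from
each is identical by descent (IBD). Estimators that compare observed allele
sharing against *population* allele frequencies implicitly assume one
panmictic population. When the sample actually spans several partially
differentiated subpopulations — or individuals with mixed ancestry —
alleles are shared through population structure as well as through recent
pedigree, and panmictic estimators are biased.

`inrelate` addresses this by a two-step design:

1. **Structure first.** An admixture model is fit to the panel: individual
   $i$ has ancestry proportions $\eta_{ik}$ over $K$ subpopulations, each
   with its own allele frequencies $p_{kla}$ (locus $l$, allele $a$). Every
   allele copy is an independent draw from the mixture.
2. **Relatedness second.** For a pair of individuals, the probabilities of
   the nine condensed (Jacquard) IBD states $\Delta_1,\dots,\Delta_9$ are
   estimated by maximum likelihood, with the *per-individual* allele
   probabilities $Z_i(l,a) = \sum_k \eta_{ik}\, p_{kla}$ standing in for
   population frequencies in the IBS-given-IBD conditional probabilities.

The coancestry is then the fixed affine map
$\theta_{XY} = \Delta_1 + \tfrac12(\Delta_3+\Delta_5+\Delta_7) +
\tfrac14\Delta_8$ and $r_{XY} = 2\theta_{XY}$. Because the first six
(inbred) states contribute, $r_{XY}$ can exceed 1 in inbred pairs; no
clamping is applied.

The package targets multi-allelic codominant markers
(microsatellites/STRs). It deliberately does not ingest SNP-oriented binary
formats (VCF/PLINK): the method's comparative advantage is multi-allelic
data, and the di-allelic tool chain is a different ecosystem.

## The admixture fit

`fit_admixture()` maximizes
$\sum_{i,l,a} n_{ila}\,\log \sum_k \eta_{ik} p_{kla}$
(with $n_{ila}$ the per-individual allele counts) by EM:
the E-step computes the responsibility of each subpopulation for each
observed allele copy; the M-step renormalizes $\eta$ by each individual's
observed allele copies and $p$ by responsibility-weighted tallies. Choices
that matter:

* **Convergence**: stop when the log-likelihood gain drops below `tol`
  (default $10^{-6}$, dimensionless log-likelihood units); the trace is
  monotone by construction and checked in tests.
* **Starts**: 5 random restarts by default ($\eta$ from a symmetric
  Dirichlet(1), $p$ perturbed around pooled frequencies); the best
  log-likelihood is kept. The likelihood surface is multimodal for $K>1$.
* **Frequency floor**: $10^{-9}$, renormalized, after every M-step, so that
  downstream logarithms stay finite. At $K=1$ the closed-form MLE (pooled
  sample frequencies) is returned directly.
* **$K$ is user-supplied.** Model choice for $K$ is out of scope; labels
  are only identified up to permutation (label switching), which is
  irrelevant downstream because only the mixture $Z$ enters the likelihood.
* Degenerate clusters (a $K$ larger than the data support) converge with
  near-zero total ancestry and are flagged, not fatal.

Missing genotypes contribute nothing to the fit, and loci missing in either
member of a dyad are dropped for that dyad only.

## IBS modes and conditional probabilities

At one locus the ordered genotype pair falls in one of nine
identity-by-state modes (S1 = (aa, aa) through S9 = (ab, cd));
`classify_ibs()` implements that partition. The dyad likelihood needs
$P(\text{observed configuration} \mid D_q)$ for each condensed IBD state
$D_q$, parametrized by the two members' $Z$ rows. `ibs_condprob()`
evaluates a 9-column registry built from one generative convention:

* a *detailed* (per-gene-copy) realization of the condensed state is chosen
  uniformly (e.g. $D_8$ has four: either allele of $X$ IBD with either
  allele of $Y$);
* a global swap of the two members' $Z$ rows is applied with probability
  $\tfrac12$, which makes every cell symmetric in the dyad;
* each IBD lineage private to one member draws its allele from that
  member's (possibly swapped) $Z$ row; a cross-individual lineage whose two
  row "slots" are already taken by private lineages ($D_1$, $D_8$) draws
  from the even mixture $\tfrac12(Z_X + Z_Y)$.

This convention was chosen because it is the unique coherent probability
model we found that reproduces the published cell formulas for this
parametrization; being a proper model, each column sums to one over the
exhaustive space of ordered configurations, which the tests verify exactly
on a 3-allele alphabet. An independent Monte-Carlo sampler
(`sample_ibs_given_ibd()`) implements the same recipe by simulation and is
compared against the closed forms at $10^6$ draws.

Two structural facts worth knowing:

* **Order equivariance, not invariance.** States $D_3/D_5$ and $D_4/D_6$
  encode *which* member is inbred, so swapping the dyad order permutes those
  columns rather than fixing them. The maximized likelihood, $\theta$ and
  $r$ are order-invariant; the per-state vector is order-equivariant.
* Structural zeros are exact zeros, so the likelihood never walks through
  `log(0)` paths it does not need.

## Maximizing over the IBD simplex

For a dyad the log-likelihood
$\ell(\Delta) = \sum_l \log \sum_q P(S_{x_l} \mid D_q)\,\Delta_q$
is concave on the unit simplex (a sum of logs of linear functions). The
package therefore uses the multiplicative EM update for mixture weights,
which converges to the *global* constrained maximum; convergence is
certified by the KKT conditions (equal gradient on the support, no ascent
direction off it; residual tolerance $10^{-8}$, cap 20000 iterations).
Multistart (uniform + Dirichlet(1) draws, 5 by default) is retained as a
safeguard and the best kept; a grid-search oracle over the 3-state simplex
backs this up in the tests. Components below $10^{-9}$ — the optimizer's
working precision — are snapped to zero and the vector renormalized, so
vertex solutions (e.g. $\Delta_8 = 1$ for parent-offspring) are exact.

Two variants are exposed: the full nine-state estimator, and a three-state
variant restricted to $\Delta_7,\Delta_8,\Delta_9$ for outbred populations
(states 1-6 pinned to zero). The nine-state maximum can never be below the
three-state maximum (nested models); tests assert this dyad by dyad.

## Fst-parametrized baselines

For comparison, the same likelihood machinery runs with conditionals built
from a single reference frequency vector per locus plus a differentiation
parameter $\theta$ (the Fst sense, not coancestry): correlated draws within
a subpopulation follow the Pólya-urn / Dirichlet kernel
$P(\text{next} = a \mid m_a \text{ of } m \text{ prior copies}) =
\frac{(1-\theta)p_a + m_a\theta}{(1-\theta) + m\theta}$,
so $P(\text{second}=a \mid \text{first}=a) = \theta + (1-\theta)p_a$, and
four-gene joint draws extend the urn sequentially. At $\theta = 0$ the urn
collapses to independent draws and the baseline likelihood coincides
exactly with the admixture likelihood at $K = 1$ — a limit the tests
exploit.

* `Wang2011`-style: all nine states.
* `AW2007`-style: three states with the additional no-inbreeding condition
  $4\Delta_7\Delta_9 < \Delta_8^2$. When the unconstrained optimum violates
  it, the constrained optimum lies on the boundary
  $4\Delta_7\Delta_9 = \Delta_8^2$, which is one-dimensional
  ($\Delta_8 = s \le \tfrac12$, $(\Delta_7,\Delta_9)$ the two roots of
  $t^2 - (1-s)t + s^2/4$); both branches and the two simplex edges are
  optimized by golden-section search and the best feasible point returned.
  This is exact for a concave objective. Note the constraint genuinely
  binds for many full-sib-like optima (the pedigree value
  $4\cdot\tfrac14\cdot\tfrac14 = \tfrac14 = \Delta_8^2$ sits exactly on the
  boundary), so AW2007 and the unconstrained three-state estimator agree
  only where it is inactive.

The reference $\theta$ usually comes from `weir_cockerham_theta()`, a
multi-allelic Weir-Cockerham (1984) variance-components estimator,
aggregated as the ratio of summed numerators to summed denominators across
loci and alleles ("normalized multi-locus"). It is written in-house because
no installed dependency provides the multi-allelic version; it is tested
against limit cases (fixed alternate alleles $\to$ 1, duplicated
population $\to$ 0) and invariances (allele relabeling, locus order).

`shuffle_labels()` emulates mis-assignment of individuals to a-priori
subpopulations: a chosen fraction of individuals each receive a uniformly
chosen *different* label. One non-obvious consequence: with $K$ labels, a
*full* shuffle does not destroy differentiation completely — each relabeled
group becomes an even mixture of the other $K-1$ subpopulations, leaving
about $1/(K-1)^2$ of the among-group variance (about a quarter at $K=3$),
and with $K=2$ a full shuffle merely swaps the groups. The tests assert the
strong reduction, not zero. The admixture-based estimators ignore labels
entirely, which is the point of the comparison.

## Bootstrap and pedigree classification

`bootstrap_theta()` resamples the dyad's informative loci with replacement
(loci are unlinked, hence independent), re-maximizes $\Delta$ per
replicate, and reports the sample standard deviation of the replicate
$\hat\theta$ values (denominator $B-1$) plus a 2.5/97.5 percentile
interval. The structure fit is *not* re-estimated per replicate: only the
loci entering the dyad likelihood are resampled. Replicates whose
optimization fails are dropped and counted; more than 10% dropped is an
error.

`wald_assign()` tests $\hat\theta$ against reference coancestries
$\theta_0$ for MZ (0.5), FS/PO (0.25), HS/AC (0.125), FC (0.0625),
SC (1/64) and UR (0) with two-sided normal Wald statistics
$(\hat\theta - \theta_0)/\mathrm{SE}$, Bonferroni-corrected
($\alpha/8$ per test at the default eight categories). The dyad is assigned
to the surviving category with the largest p-value; categories sharing the
winning $\theta_0$ are reported jointly, because a test on $\theta$ alone
cannot separate FS from PO or HS from avuncular. If everything is rejected
the dyad is "unassigned". With $\mathrm{SE}=0$ (degenerate resampling) the
assignment falls back to exact matching and is flagged.

## The synthetic-data generator

`population_model()` + `make_frequencies()` generate subpopulation allele
frequencies either as independent Dirichlet($\alpha$) draws per
subpopulation and locus, or — emulating an island model at migration-drift
equilibrium — as Balding-Nichols draws around an ancestral vector with
concentration $p_{\text{anc}}(1-F_{ST})/F_{ST}$, targeting
$F_{ST} = 1/(1+4Nm)$. The equilibrium frequencies are all the downstream
machinery consumes, so a forward-time simulation is not reproduced; the
$F_{ST}$ target is the summary being matched. Defaults: 10 alleles per
locus (a realistic observed STR allele count; the generator accepts up to
any number), $\alpha = 1$.

`make_dyad()` builds FS, HS, FC, PO, UR and MZ pairs by Mendelian
gene-dropping from founders sampled in a designated subpopulation (or with
an explicit admixed ancestry vector): transmission is independent per locus
(unlinked loci — no IBD-tract length model), founder alleles carry globally
unique labels, and the true condensed IBD state at every locus is read off
the label partition of the four allele copies. First cousins are built as
two full sibs each mated to an unrelated same-subpopulation individual.
Enumerating the 16 equally likely full-sib transmission patterns gives the
exact $(\Delta_7,\Delta_8,\Delta_9) = (\tfrac14,\tfrac12,\tfrac14)$;
parent-offspring pairs are $D_8$ at every locus and unrelated pairs $D_9$,
all of which the tests check both by enumeration and by simulation.

`run_scenario()` wires everything together: frequencies, background
individuals, replicate dyads, a structure fit at the true $K$, relatedness
estimates per variant, and per-category MSE
($\frac1R\sum(\hat r_i - r_{\text{true}})^2$) and bias
($r_{\text{true}} - \bar{\hat r}$, truth minus estimate).

What the generator does *not* emulate: linkage and IBD-tract structure,
mutation, genotyping error, hierarchically nested subpopulations, and
temporal change in structure. Passing tests therefore demonstrate correct
behavior under the admixture model's own assumptions — unlinked, neutrally
evolving, codominant loci with structure fully captured by $(\eta, p)$ —
not robustness to their violation on real data.

## Problem sizes used by the checks

The automated checks run at desk scale, chosen to keep the full suite in a
few minutes while leaving the statistical conclusions unambiguous:
gene-dropping distributions at 5000-10000 loci; conditional-table
normalization exhaustively on a 3-allele alphabet and Monte-Carlo agreement
at $10^6$ draws; Weir-Cockerham recovery of the $F_{ST}=0.2$ island target
on 500-locus, 198-individual panels; full-sib recovery with 100 dyads at
$K=3$, $L=50$, $F_{ST}\approx0.1$ (mean bias within $\pm 0.1$);
consistency of $\hat\Delta$ at 2000 loci (within 0.05 per component); and
bootstrap classification of five parent-offspring dyads at 300 loci with
$B=200$ replicates, all of which land in the $r=0.5$ tier.

## Known limitations

* FS vs PO (and HS vs avuncular) cannot be separated by $\theta$ alone;
  the Wald machinery reports such ties jointly rather than inventing a
  $\Delta$-pattern tie-break.
* Distant relationships (FC, SC, UR) are intrinsically hard for all
  likelihood estimators at realistic locus counts; expect wide intervals.
* Structure and relatedness are estimated in two steps; uncertainty in
  $(\eta, p)$ is not propagated into the bootstrap, which resamples loci
  with the structure fit held fixed.
* The admixture fit assumes the panel is mostly unrelated; panels saturated
  with relatives bias $(\eta, p)$ toward the relatives' own alleles and
  deflate relatedness. Include unrelated background individuals when
  possible.
* The estimator is only as good as the supplied $K$; the package does not
  choose $K$.

## A note on naming

The three-state outbred restriction is sometimes labelled "WI" ("with
inbreeding") in comparative tables even though it is the variant that
*assumes no* inbreeding; both variants are exposed here under the
unambiguous names `nine_state` and `three_state`.
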