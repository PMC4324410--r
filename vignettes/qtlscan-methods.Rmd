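---
title: "Models and methods in qtlscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in qtlscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlscan)
```

qtlscan implements three whole-genome QTL mapping strategies used in
livestock genetics — a haplotype-cluster variance-component scan (LDLA),
single-SNP mixed-model association with a genomic relationship matrix
(EMMA), and Bayesian variable-selection regression (BayesC) — together with
the simulation, thresholding and scoring machinery needed to compare them
on populations with strong family structure.  This vignette documents the
models, the tunable parameters, and the design decisions taken where the
methodology leaves genuine choices open.

## The three scans

### LDLA: haplotype-cluster variance components

At every window of four consecutive polymorphic SNPs the model

$$\mathbf{y} = \mathbf{1}\mu + \mathbf{Z u} + \mathbf{T h} + \mathbf{e},
\qquad \mathrm{Var}(\mathbf{u}) = \mathbf{A}\sigma_u^2,\quad
\mathrm{Var}(\mathbf{h}) = \mathbf{H}\sigma_h^2$$

is fitted by REML, where $\mathbf{u}$ is a pedigree polygenic effect
($\mathbf{A}$ the numerator relationship matrix) and $\mathbf{h}$ holds
one effect per haplotype cluster at the window.  Clusters are built in two
steps.  First, transmissions are traced down the pedigree: an offspring
gamete identical in state to the transmitting parent's gamete over the
four SNPs is taken as identical by descent with it; recombinant gametes
found new founder-level haplotypes.  Second, founder-level haplotypes —
whose identity by descent cannot be ascertained — are clustered by
alikeness in state, and $\mathbf{H}$ carries the between-cluster mean
alikeness (unit diagonal, floored to positive semi-definiteness).  Each
window is tested against the no-haplotype null with a likelihood ratio
test; because $\sigma_h^2$ sits on the boundary under the null, P values
use the standard 50:50 mixture of $\chi^2_0$ and $\chi^2_1$.  The exact
null reference for this LRT is a genuinely open choice; the mixture is the
standard boundary correction and is isolated in one place should a
different reference be preferred.

**Cluster granularity.** The similarity cut for merging founder
haplotypes defaults to 1: only haplotypes identical in state over the four
SNPs are merged, and all softer resemblance (3/4, 2/4, ... alleles shared)
is expressed through the off-diagonal entries of $\mathbf{H}$.  We
deliberately do not merge at the softer 3/4-identity cut: with four
biallelic SNPs most of the 16 possible states segregate in any sizeable
panel, and under single linkage the Hamming-distance-1 chains connect the
entire state hypercube, collapsing every window to a single cluster and
making $\sigma_h^2$ unidentifiable.  The `similarity_threshold` argument
of `cluster_founders()` exposes the cut for users who want to explore
coarser clusterings.

**Phasing.** When the panel carries the simulator's true phase it is used
as-is.  Otherwise a family-and-LD heuristic phases the panel: Mendelian
rules from parent genotypes, a reverse family rule that recovers a
founder's transmitted gamete from one offspring and its mate, and a greedy
left-to-right orientation of the remaining heterozygous sites anchored at
the individual's most recent heterozygous phased site (through a
homozygous run the previous marker carries no orientation information).
On simulated half-sib panels with adjacent-marker LD of 0.8 this keeps the
switch-error rate under 5%; gametes with unresolved sites fall into
singleton clusters at affected windows rather than being spread across
clusters.

### EMMA: mixed-model association

Per SNP, $\mathbf{y} = \mathbf{1}\mu + \mathbf{Z u} + \mathbf{w}s +
\mathbf{e}$ with $\mathrm{Var}(\mathbf{u}) = \mathbf{G}\sigma_u^2$, where
$\mathbf{G}$ is the VanRaden method-1 genomic relationship matrix computed
from observed allele frequencies (a 1e-6 ridge keeps it invertible;
centering by observed rather than base-population frequencies is a
documented choice).  The test statistic is $t = \hat s / \mathrm{s.e.}
(\hat s)$ with a two-sided P value from the standard normal — at the
sample sizes involved (hundreds of individuals) the difference from a t
reference is negligible.

By default the variance components are estimated once under the no-SNP
null and reused at every marker (the standard two-stage approximation,
roughly two orders of magnitude faster); `refit = TRUE` re-estimates the
variance ratio per SNP exactly on the shared eigenbasis of $\mathbf{G}$.
The approximation is conservative exactly where it matters least for
localization: near a strong causal flank the null model absorbs some QTL
variance into $\sigma_u^2$.  The GLS step re-profiles the overall scale on
the augmented design, so with an identity covariance the statistic reduces
exactly to the OLS t.

### BayesC: variable-selection regression

All SNPs enter jointly: $\mathbf{y} = \mathbf{1}\mu + \sum_i \mathbf{w}_i
d_i s_i + \mathbf{e}$, with indicator $d_i \sim \mathrm{Bernoulli}(\pi)$,
$\pi = 1/1000$ by default, a common effect variance $\sigma_s^2$, and
scaled-inverse-$\chi^2$ hyperpriors.  The Gibbs sampler (compiled code)
draws each indicator from its conditional odds with the effect integrated
out, then the effect from its conditional normal; chains default to
100 000 iterations with a 20% burn-in and thinning of 10.  The per-SNP
evidence is the Bayes factor

$$\mathrm{BF}_i = \frac{\hat d_i / (1 - \hat d_i)}{\pi / (1 - \pi)},$$

the prior-to-posterior odds ratio of the SNP being in the model (999
$\times$ odds at $\pi = 1/1000$).  A posterior inclusion probability of
exactly 1 yields an infinite Bayes factor, which the detection machinery
treats as a valid extreme.  Hyperprior scales follow the usual heuristic —
effect-variance scale matched to an expected genetic variance (half the
phenotypic variance by default) spread over the $\pi m$ markers expected
in the model, residual scale at half the phenotypic variance, both with
$\nu = 4$ — and are configurable; they are declared defaults, not
estimates.  Sensitivity runs at $\pi = 1/100$ and $1/10000$ leave the top
signal in place on strong-QTL panels (this is exercised in the test
suite).

## The synthetic-data generator

The generator emulates the population structures of dense-SNP livestock
panels so that every stage is testable without any external data:

* **Pedigrees** — five designs: a few very large paternal half-sib
  families; many smaller half-sib families; a three-generation F1 /
  backcross / backcross-x-backcross cross between two divergent lines;
  very many small sire families; and several diverged subpopulations.
  Dams are always fresh founders, so the designs are non-inbred by
  construction (the polygenic gene-flow simulator relies on this and
  documents it).
* **Founder haplotypes** — a first-order Markov copying process along the
  map whose adjacent-marker allelic correlation is
  `ld_strength^(d / mean(d))` for an interval of d cM: LD decays
  geometrically with map distance and equals `ld_strength` exactly at the
  mean spacing.  Allele-frequency profiles follow a block pattern whose
  block means include the scenario-relevant frequencies (0.1, 0.3), so
  causal-marker candidates at those MAFs always exist with
  similar-frequency neighbours (high LD pairs are attainable there;
  correlated binary variables with very different frequencies cannot reach
  high correlations).
* **Gene dropping** — founders receive pool haplotypes; each non-founder
  inherits one recombined gamete per parent with independent per-interval
  crossovers at the Haldane probability $(1 - e^{-2d/100})/2$.  Phase is
  retained exactly.
* **QTL scenarios** — one or two causal SNPs, additive (-a, 0, a) or
  completely dominant (-a, a, a; "dominant" is interpreted as complete
  dominance, d = a) action, target MAF and target LD with the strongest
  neighbouring marker.  Candidates must match both targets within 0.05;
  the causal marker is fixed per scenario (one seed) and masked from the
  scanned panel, with its true cM position retained for scoring.  With two
  QTL the 5% variance share is carried by the two loci jointly, with equal
  allele effects.
* **Phenotypes** — `y = mu + qtl + polygenic + residual`, exactly, per
  individual.  The polygenic term is simulated by gene flow down the
  pedigree (covariance $\mathbf{A}\sigma_u^2$ without forming
  $\mathbf{A}$); the allele effect a is solved against the realized
  genotype frequencies so the QTL explains 5% of the total genetic
  variance, and the residual scale is solved so the realized broad-sense
  heritability is 0.30.  "Total genetic variance" is Var(qtl genotypic
  value) + Var(polygenic), which is what broad-sense heritability divides
  by.  All non-QTL genetic variance is additive polygenic — the split of
  the remainder is not pinned down by the headline targets and this is the
  declared default.

What the generator does **not** emulate: coalescent or demographic
realism, sequence-level mutation, interference in recombination,
selection, genotyping error, multi-chromosome LD (one chromosome per run),
epistasis or pleiotropy.  Passing tests therefore show that the methods
behave as designed under clean additive/dominant architectures with
calibrated LD and family structure — not that they are robust to the full
range of gene action in real data.

## Thresholds, detection and scoring

All thresholds operate on a per-method `score` ("larger = stronger
evidence": $-\log_{10} P$ for LDLA/EMMA, the Bayes factor for BayesC), so
detection is method-agnostic:

* **Chromosome-wise Bonferroni** at level 0.05 over the scanned positions
  (frequentist scans), and the fixed "very strong evidence" Bayes factor
  150 for BayesC — the real-data-style rules.
* **Pseudo-null thresholds** for simulations: the distribution of scores
  at non-QTL positions (beyond ±2 cM of every true QTL — the most
  conservative of the scored windows) of simulations that do contain a
  QTL elsewhere.  The 5% empirical threshold is the 95th percentile of
  the pooled per-position scores; two more stringent thresholds are the
  quantiles of per-replicate best non-QTL scores crossed by only 10% and
  20% of replicates.  All quantiles use the type-7 linear-interpolation
  definition, isolated behind one function.
* **Detection** — at most one QTL per replicate and method: the most
  extreme score, declared only if it strictly beats the threshold, ties
  broken by the smallest cM position.
* **Scoring** over ±0.5, ±1 and ±2 cM windows: power is the fraction of
  replicates declaring inside a window; FDR the fraction declaring outside
  every window (per-replicate denominator, which makes cells comparable
  across the factorial); localization MSE (cM²) averages the squared
  distance to the nearest true QTL over in-window declarations only — an
  out-of-window declaration is a false discovery, not a localization
  error; including it would conflate the two indicators.
* **Redundancy** — the effective number of independent tests of a score
  series: $N / (1 + 2\sum_k \rho_k)$ with the autocorrelation sum
  truncated by the initial-positive/monotone sequence rule.  Family-driven,
  haplotype-based scans (LDLA) are expected to be the most redundant.

A full factorial (5 fixtures × 5 scenarios × 3 methods × 3 thresholds × 3
windows) yields 675 averaged cells per indicator; the grid is balanced, so
marginal method means are plain averages.

## Numerical choices

* REML: with one random term the restricted likelihood is profiled
  exactly on the eigenbasis of its covariance (1-D optimization of the
  variance ratio).  With several terms an expectation-style fixed-point
  iteration is used (components floored at zero, relative logL tolerance
  1e-6, at most 200 iterations; non-convergence flags the fit rather than
  raising).  The per-window LDLA alternative runs on the eigenbasis of
  $\mathbf{A}$ with Woodbury identities on the low-rank cluster term, so
  each iteration is O(n·c²).  A window whose alternative fit cannot beat
  the shared null is reported at LRT 0, P 1, flagged.
* Window position is the cM midpoint of its four markers (any monotone
  convention works for ±cM scoring).
* Ambiguous transmission (parent identical in state on both gametes)
  follows the sire-side gamete, deterministically.
* Degenerate windows (a single cluster among phenotyped individuals) are
  flagged, not dropped silently.
* Monomorphic markers are excluded from G, from the BayesC model, and
  flagged in EMMA scans; "polymorphic" is decided by realized variance,
  not allele frequency alone.

## Problem sizes in the shipped tests

The test suite exercises the full pipeline at desk scale, chosen once as
the smallest sizes at which the statistical checks are sharp: simulator
calibration at n = 2000 individuals × 50 replicates (realized heritability
within 0.02 of 0.30, QTL share within 1 point of 5%); type-I error of all
three scans under a global null at 400 individuals × 500 markers, with the
5% pseudo-null threshold built from 20 replicates and the rejection rate
measured on 10 fresh ones; and the directional LDLA-vs-EMMA comparison
(power, localization MSE, redundancy) at 600 individuals × 500 markers ×
20 replicates of scenario 1.  In that comparison G is built from the
scanned chromosome plus four unlinked background chromosomes: with a
single-chromosome G the polygenic term absorbs the QTL ("proximal
contamination") and handicaps the mixed-model scan in a way a
whole-genome kinship does not.  BayesC chains in these loops run 10 000
iterations — scan-profile checks stabilize well before the 100 000-iteration
default used for single analyses.

## Known limitations

* The LDLA clustering is an identity-by-state surrogate for
  coalescence-based identity-by-descent probabilities; windows are fixed
  at four SNPs.
* The EMMA default reuses null variance components (exact refit available
  per SNP); P values use the normal reference.
* BayesC hyperprior scales are declared defaults, not estimated; a single
  common effect variance is used (no BayesA/B/R variants).
* FDR uses a per-replicate denominator; with at most one declaration per
  replicate it is a rate of false declarations, not a proportion of
  discoveries.
* `G` is built from all simulated markers including the scanned
  chromosome (no leave-one-chromosome-out correction), which slightly
  absorbs the QTL signal into the polygenic term.
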