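---
title: "Two-locus haplotype probabilities in advanced intercross populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-locus haplotype probabilities in advanced intercross populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpphap)
```

## The problem

Genotype reconstruction in multiparent mouse populations -- advanced
intercross lines (AIL), heterogeneous stock (HS) and the diversity
outcross (DO) -- is done with hidden Markov models whose transition
probabilities between adjacent markers are conditional founder-allele
probabilities.  When the population is maintained with a large number of
mating pairs, the two haplotypes within an individual are independent, so
the HMM only needs *two-locus haplotype probabilities*: the chance that a
random chromosome carries founder allele $i$ at one locus and founder
allele $j$ at the other, as a function of the meiotic recombination
fraction $r$ between the loci.  `mpphap` computes these probabilities
exactly, for autosomes and the X chromosome, together with the map
expansion (the density of recombination breakpoints accumulated by the
design) and the row-stochastic transition matrices an HMM consumes.

Throughout, the model assumes an effectively infinite set of mating pairs
per generation, no sex difference in recombination, no interference
beyond what $r$ encodes, and no selection or mutation.

## Two-way AIL

Let $p_s$ be the frequency of the intact $AA$ haplotype at generation
$F_s$ (founders $A$ and $B$; $p_1 = 1/2$).  A haplotype sampled at
$F_{s+1}$ is an unrecombined copy from $F_s$ (probability $1-r$) or a
recombinant joining two independent alleles, each $A$ with frequency
$1/2$:
$$p_{s+1} = (1-r)\,p_s + r/4, \qquad s \ge 2 .$$

The recurrence starts at $s = 2$, not $s = 1$: every F1 individual
carries the perfectly anticorrelated pair $(AA, BB)$, so an F1
recombinant gamete is never $AA$ and the exact first step is
$p_2 = (1-r)/2$.  This makes the F2 recombinant frequency
$1 - 2p_2 = r$ exactly, as it must be (an F2 gamete is one meiosis
beyond the F1).  Naively applying the recurrence from $s = 1$ would
inflate $p_2$ by $r/4$; the same care recurs in every design below, and
the package's independent full-table propagator
(`propagate_exact()`) and forward simulator (`simulate_freqs()`) were
used to pin these boundary cases down.  The closed form, valid for
$s \ge 2$ and consistent with the exact $p_2$, is
$$p_s = \tfrac14\left[1 + (1-2r)(1-r)^{s-2}\right].$$

### Balanced X chromosome

With equal numbers of reciprocal F1 crosses, the $A$ frequency is $1/2$
in both sexes at every generation.  Writing $m_s$, $f_s$ for the $AA$
frequency in males and females (a male X is his dam's gamete; a female X
is equally likely her sire's intact X or her dam's gamete),
$$m_{s+1} = (1-r) f_s + r/4, \qquad
  f_{s+1} = \tfrac12 m_s + \tfrac{1-r}{2} f_s + r/8, \qquad s \ge 2,$$
with the exact anchor $m_2 = (1-r)/2$, $f_2 = (2-r)/4$ (the F1 female is
again $(AA, BB)$, and the F1 male's X is intact).  The homogeneous part
has matrix $\bigl[\begin{smallmatrix}0 & 1-r\\ 1/2 &
(1-r)/2\end{smallmatrix}\bigr]$ with eigenvalues
$w = (1-r+z)/4$ and $y = (1-r-z)/4$, $z = \sqrt{(1-r)(9-r)}$
(`x_eigen_coefficients()`).  Diagonalizing and anchoring at the exact
generation-2 values gives, for $s \ge 2$,
$$m_s = \tfrac18\left[2 + (1-2r)(w^{s-2}+y^{s-2})
        + \tfrac{3-5r+2r^2}{z}(w^{s-2}-y^{s-2})\right],$$
$$f_s = \tfrac18\left[2 + (1-r)(w^{s-2}+y^{s-2})
        + \tfrac{3-6r+r^2}{z}(w^{s-2}-y^{s-2})\right].$$
These were recovered by solving the recurrence symbolically rather than
transcribed; the recurrence remains the reference path and the closed
form is tested against it to $10^{-12}$ over a dense $(s, r)$ grid.
Versions of the $f_s$ line circulate with $(1-2r)$ in place of $(1-r)$
on the $(w^{s-2}+y^{s-2})$ term; that variant does not solve the
recurrence.

Overall X-chromosome quantities weight females by $2/3$, since
two-thirds of X chromosomes reside in females.

### Unbalanced X chromosome

In practice AILs are often started from a single cross direction
(dam line $A$, sire line $B$), so all F1 males are hemizygous $A$ and
allele frequencies differ between sexes and across generations.  The
female $A$ frequency $q_s$ obeys $q_{s+1} = (q_s + q_{s-1})/2$ with
$q_0 = 1$, $q_1 = 1/2$, solved by $q_s = 2/3 + (1/3)(-1/2)^s$; males at
$F_s$ carry $q_{s-1}$.  The haplotype recurrence is as in the balanced
case except that a recombinant female gamete joins alleles with the
sex-specific frequencies one generation back:
$$m'_{s+1} = (1-r) f'_s + r\, q_{s-1} q_{s-2}, \qquad
  f'_{s+1} = \tfrac12 m'_s + \tfrac{1-r}{2} f'_s +
  \tfrac{r}{2}\, q_{s-1} q_{s-2},$$
with $m'_1 = 1$, $f'_1 = 1/2$.  The boundary value $q_{-1} = 0$ encodes
that the F1 female's paternal X carries no $A$ allele; it reproduces the
exact hand value $m'_2 = (1-r)/2$ and makes the first step exact without
a special case.  No closed form is available; the recurrence is the
implementation, and for $r > 0$ both sexes converge to $4/9$ (the
stationary allele frequencies are $2/3$ in females and the two loci
decouple).  Labels are *not* exchangeable here, so the full $2\times 2$
table is completed from the allele frequencies:
$AB = BA = q - AA$, $BB = 1 - 2q + AA$.

## Pre-CC progenitors: the sib-mating chains

HS and DO generation-1 haplotypes are gametes from eight-way funnel
animals (HS) or from partially inbred Collaborative Cross intermediates
("pre-CC", at sib-mating generation $G_2{:}F_k$ with user-supplied
weights $\alpha_k$; DO).  The package derives the required quantities
from first principles by propagating an exact Markov chain over a
sib-mating pair, rather than transcribing published tables:

* meiosis is the standard two-locus gamete law (each non-recombinant
  haplotype with probability $(1-r)/2$, each recombinant with $r/2$);
* states are lumped by tracking, for one founder of interest, the
  indicator pattern of "is this allele from the tracked founder" across
  the pair's haplotypes.  Lumping is exact because copying alleles maps
  indicator patterns autonomously; exactness is verified in the test
  suite against an independently coded finer two-founder chain and
  against labeled-founder simulation;
* the two siblings that found the chain share their funnel parents, so
  their gametes are conditionally independent given the shared parental
  diplotype, not marginally independent.  The initial pair distribution
  therefore mixes over the shared two-way gamete realization.  (Getting
  this wrong leaves every marginal quantity -- including all HS values --
  intact but corrupts $k \ge 2$ joints; the package's exact enumeration
  oracle guards it.)

On the autosome this yields $q_k$, the intact-founder-haplotype
frequency at $G_2{:}F_k$; a progenitor at $G_2{:}F_k$ transmits such a
haplotype with frequency $q_{k+1}$, e.g. $q_2 = (1-r)^3/8$ (three
independent meioses separate a transmitted gamete from the founders).

On the X, the funnel structure makes founders inequivalent: per funnel,
two founders enter through the dam-side recombining pair, one
contributes an intact X, two enter through the sire-side pair, and three
contribute no X; random funnel orders restore balance on average.  The
chain tracks female and male X states per founder class and returns the
probabilities that a pre-CC dam's X gamete, a pre-CC sire's X, and a
random female X haplotype are intact founder haplotypes.  The DO
initial values are then
$$m_1 = \sum_k \alpha_k\, \mathrm{Tg}(k)/8, \qquad
  f_1 = \sum_k \alpha_k\, [\mathrm{Tg}(k) + \mathrm{Mh}(k)]/16,$$
where $\mathrm{Tg}$ and $\mathrm{Mh}$ are the dam-gamete and sire-X
parental probabilities.  For HS ($\alpha_1 = 1$) these reduce to
$$m_1 = (1-r)^2(4-r)/32, \qquad f_1 = (1-r)(8-7r+r^2)/64 .$$
Note these are *transmitted-gamete* (generation-1) quantities.  The
progenitors' own X haplotype frequencies, $(1-r)(2-r)/16$ for males and
$(1-r)(4-r)/32$ for females, are one generation earlier; seeding the
recurrence with them is a subtle off-by-one error that the forward
simulator detects immediately (it also breaks the exact $2/3$
map-expansion ratio below).

An equivalent decomposition expresses $f_1$ through four-way sib-mating
RIL ingredients, the female-X frequencies $h^{AA}_k$ and $h^{CC}_k$ of
`precc_x_freqs()`:
$f_1 = \sum_k \alpha_k \tfrac18[(2-r)h^{AA}_{k+1} + (1-r)h^{CC}_{k+1}]$.
The test suite verifies that this reproduces the direct eight-way
computation at machine precision for every $k$, which pins down the
bracket weights $(2-r)$ and $(1-r)$.

## DO and HS outcross generations

With complete balance over the eight founders, the autosomal recurrence
is $p_{s+1} = (1-r) p_s + r/64$ from
$p_1 = \sum_k \alpha_k q_{k+1}$, with closed form
$p_s = 1/64 + (1-r)^{s-1}(p_1 - 1/64)$; recombinant haplotypes are
uniform over the 56 ordered founder pairs, each with probability
$(1-8p_s)/56$.  Here no generation-1 special case is needed: a
generation-1 individual's two haplotypes come from different progenitor
lines and are already independent.  The X recurrence mirrors the
balanced AIL with stationary value $1/64$:
$$m_{s+1} = (1-r) f_s + r/64, \qquad
  f_{s+1} = \tfrac12 m_s + \tfrac{1-r}{2} f_s + r/128,$$
and its closed form is obtained by the same diagonalization (same $w$,
$y$, $z$) anchored at $(m_1, f_1)$.  HS is DO with $\alpha_1 = 1$, an
identity the test suite asserts at machine precision across the API.

## Map expansion

The map expansion $M = \mathrm{d}R/\mathrm{d}r|_{r=0}$, with $R(r)$ the
recombinant haplotype frequency, is the breakpoint density per Morgan.
Differentiating the recurrences at $r = 0$ gives constant per-generation
gains, so every closed form is affine in $s$:

| design | autosome | X |
|---|---|---|
| AIL | $s/2$ ($s\ge2$; $0$ at $s=1$) | $s/3$ ($s\ge2$; $0$ at $s=1$) |
| HS  | $(7s+17)/8$ | $(2/3)(7s+17)/8$ |
| DO  | $(7/8)(s-1) + M_1(\alpha)$ | $(7/12)(s-1) + M^X_1(\alpha)$ |

The HS autosomal value decomposes as three fully visible breakpoint
units from the three all-heterozygous funnel generations plus $7/8$ per
outcross generation (a haplotype is an unrecombined survivor with
probability $1/8$ at stationarity).  Earlier HMM software for HS (the
HAPPY package) assumed $(7/8)(s+2)$ instead; the difference is exactly
$3/8$ at every $s$, and `hs_map_expansion_legacy()` reproduces the old
value so the correction is testable.  At $s = 10$, $r = 0.01$ the
corrected recombinant frequency is $0.103$ versus $0.099$ under the old
assumption.

On the X the per-generation gain is exactly $7/12 = (2/3)(7/8)$
regardless of the initial values.  The full $2/3$ autosome-to-X ratio is
exact at every $s$ for AIL ($s \ge 2$) and HS, because their
generation-1 X values already sit in the $2/3$ ratio.  For DO with
progenitors beyond $k = 1$ it is only approximate: the X and autosome
sib-mating chains do not accumulate breakpoints in a fixed $2/3$ ratio,
so $M^X_1(\alpha)$ is computed from the X chain itself (numerically, as
is $M_1(\alpha)$ on the autosome) rather than scaled from the autosomal
value.  For the unbalanced AIL X, differentiating the haplotype
recurrence gives
$$M'_{s+1} = M'_s + \tfrac43\,(q_s - q_{s-1} q_{s-2}),
  \qquad M'_1 = 0,\; M'_2 = 2/3,$$
an *overall* (2/3-female-weighted) quantity: the package checks it
against numerical derivatives of the per-sex and overall recombinant
frequencies, and only the overall interpretation matches.

Numerical derivatives use forward differences from $r = 0$ with
two-point Richardson extrapolation at steps $10^{-6}$ and
$5\times10^{-7}$ (forward, because $R(r)$ exists only for $r \ge 0$);
closed forms and derivatives agree to $10^{-4}$ across the test grid.

## Transition matrices

`transition_matrix()` divides each haplotype-table row by its locus-1
marginal, yielding $P(\text{founder } j \text{ at locus } 2 \mid
\text{founder } i \text{ at locus } 1)$.  For balanced designs the
matrix is symmetric and doubly stochastic with diagonal $n p_s$; at
$r = 0$ it is the identity.  The unbalanced AIL X is the one case with
non-uniform allele frequencies, so the matrix is emitted together with
its locus-1 distribution (the `init` attribute) and both are
sex-specific; an HMM must consume them as a pair.  `read_genetic_map()`
converts marker positions (cM) to per-interval $r$ via the Haldane map
function (Kosambi optionally), and `transition_matrices()` maps a vector
of interval $r$ values to the per-interval matrices.  The core API works
in $r$, not genetic distance, so no map-function assumption leaks into
the probabilities themselves.

## The simulation oracle and what it does (not) show

Two independent verification paths back every analytic result:

* `propagate_exact()` iterates the full $n \times n$ haplotype table
  under the infinite-population mating rules (handling the F1
  correlation exactly), sharing no code with the scalar recurrences;
  agreement is required to $10^{-12}$.
* `simulate_freqs()` simulates the designs forward with labeled
  founders: randomized funnel orders, shared sib-pair parents, pre-CC
  sib mating, then finite random-mating populations with balanced sexes.
  Gametes are split over 16 independent replicate populations; because
  haplotypes within one finite population share ancestors, frequencies
  fluctuate more than binomially (drift), so standard errors are
  estimated empirically from the replicate spread (with a binomial
  floor).  Analytic values must fall within 3 SE at 200,000 gametes for
  a battery spanning all designs and chromosomes.  A single seed set at
  entry makes the vectorized pipeline fully reproducible.

The simulator emulates exactly the idealized breeding design the
analytic theory assumes: no crossover interference beyond the two-locus
$r$, no sex difference in recombination, no selection, mutation,
overlapping generations, or the actual finite DO pedigree structure.
Passing tests therefore certify the mathematics under those assumptions,
not the fit of the model to any particular real colony; in small real
populations inbreeding reduces observable recombination below these
values.

## Parameters, defaults and degenerate inputs

* $r$ is accepted on the closed interval $[0, 0.5]$; both endpoints are
  exercised in tests and no normalization divides by zero there.
* Generations are integers $\ge 1$ ($q_s$ additionally supports the
  boundary indices $0$ and $-1$).
* The DO progenitor distribution $\alpha_k$ is a required user input.
  `example_alpha()` ships a documented illustrative choice -- uniform on
  $k = 4..8$, mean 6, a realistic center and spread for DO founder
  stock -- and is *not* the generation distribution of any actual
  colony.  Weights are validated to sum to 1 within $10^{-6}$ and then
  renormalized.
* Recurrences are always the reference implementation; closed forms are
  a fast path cross-checked to $10^{-12}$.  Convergence-to-limit tests
  iterate to $s = 1000$ with tolerance $10^{-8}$ or tighter (limits
  require $r > 0$).
* Test problem sizes: closed-form grids use $s$ up to 50 and 21 values
  of $r$; the simulation battery uses 200,000 gametes per condition;
  the exact-enumeration oracle covers the X pedigree to $k = 2$ and the
  finer lumping chain to $k = 3$.  All run in well under a minute.

## Known limitations

Only two-locus (not multilocus) probabilities are provided, with no
interference model within a meiosis; diplotype-level transition
matrices are unnecessary under the many-mating-pairs assumption and are
not emitted.  Sex-specific recombination fractions and mixtures of
balanced/unbalanced founder crosses beyond the two supported cases are
out of scope, as are finite-population inbreeding corrections and
sibling relationships in the final generation.
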