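# mpphap

Exact two-locus founder-haplotype probabilities, recombinant-haplotype
frequencies, founder-allele transition matrices, and map expansion for
advanced intercross populations: two-way advanced intercross lines (AIL,
with balanced or unbalanced X chromosome), eight-way heterogeneous stock
(HS), and the diversity outcross (DO) founded from partially inbred
Collaborative Cross intermediates (pre-CC).

These are the quantities needed to build hidden Markov models for
genotype reconstruction in multiparent mouse (and other) populations:
under the standard assumption of many mating pairs per generation, the
two haplotypes within an individual are independent, so the HMM
transition matrix for a marker interval with meiotic recombination
fraction `r` is just the conditional founder-allele probability derived
from the two-locus haplotype table. `mpphap` computes those tables
exactly from recurrence relations, seeds them with first-principles
breeding-chain calculations (funnel crosses plus sibling mating for
HS/DO), and verifies everything against an independent infinite-population
table propagator and a labeled-founder forward simulator.

## The model in brief

For a two-way AIL autosome, with `p_s` the frequency of an intact `AA`
haplotype at generation `F_s`:

    p_{s+1} = (1 - r) p_s + r/4          (s >= 2)
    p_2     = (1 - r)/2                  (exact F1 meiosis)
    p_s     = 1/4 [1 + (1-2r)(1-r)^{s-2}]

and the recombinant-haplotype frequency is `1 - 2 p_s`. Analogous
recurrences, with closed forms obtained by diagonalizing the two-sex
system (eigenvalues `w, y` with `z = sqrt((1-r)(9-r))`), cover the X
chromosome, the unbalanced-cross X (where allele frequencies differ by
sex and generation), and the eight-founder HS/DO with stationary value
1/64. HS/DO generation-1 values come from exact sib-mating Markov chains
over the pre-CC pedigree; for HS the transmitted-gamete results reduce to

    p_1 = q_2 = (1-r)^3 / 8
    m_1 = (1-r)^2 (4-r) / 32     (X, males)
    f_1 = (1-r)(8 - 7r + r^2) / 64   (X, females)

The map expansion (breakpoint density, `dR/dr` at `r = 0`) is `s/2` for
the AIL autosome, `(7s+17)/8` for HS, `(7/8)(s-1) + M_1(alpha)` for the
DO, and exactly 2/3 of those on the X for AIL/HS. The methods vignette
(`vignettes/haplotype-probabilities.Rmd`) derives all of this and
documents the numerical choices.

## Worked example

```r
library(mpphap)

# HS recombinant-haplotype frequency after ten outcross generations,
# for a marker interval with r = 0.01:
round(do_recombinant(10, 0.01, hs_alpha()), 6)
#> [1] 0.102805
```

About 10.3% of HS chromosomes are recombinant across a 1 cM interval
after ten generations -- roughly ten times the single-meiosis rate,
which is why these populations map QTL so finely. The corresponding HMM
transition matrix:

```r
transition_matrix("DO8", "autosome", s = 10, r = 0.01, alpha = hs_alpha())
#> Founder-allele transition matrix (DO8 autosome, s = 10, r = 0.01)
#>       locus2
#> locus1         A         B         C      ...          H
#>      A 0.8971952 0.0146864 0.0146864      ...  0.0146864
#>      B 0.0146864 0.8971952 0.0146864      ...  0.0146864
#>      ...
#> locus-1 allele frequencies: 0.125 0.125 0.125 0.125 0.125 0.125 0.125 0.125
```

A founder mosaic stays on the same founder with probability 0.897 and
switches to each of the seven others with probability 0.0147. The map
expansion, and the legacy value older HS software assumed (always
exactly 3/8 too small):

```r
map_expansion("HS8", "autosome", 10)   #> [1] 10.875
hs_map_expansion_legacy(10)            #> [1] 10.5
```

The unbalanced AIL X needs sex-specific tables because the founder
allele frequencies are unequal (female frequency tends to 2/3):

```r
ail_unbalancedX_table(2, 0.2, "male")
#> Two-locus haplotype frequency table (2 founders, male; AIL2 X unbalanced, s = 2, r = 0.2)
#>       locus2
#> locus1   A   B
#>      A 0.4 0.1
#>      B 0.1 0.4
```

And the forward simulator, the package's brute-force oracle:

```r
sim <- simulate_freqs("HS8", "autosome", s = 10, r = 0.01,
                      n_gametes = 200000, seed = 1)
#> simulated parental frequency: 0.90065 (SE 0.00186); analytic: 0.89720
```

## Command line

A thin CLI over the same functions is installed as `exec/mpphap`:

```sh
Rscript exec/mpphap haplofreq --design hs --chrom A --s 10 --r 0.01
Rscript exec/mpphap mapexp --design hs --chrom A --s-grid 1:10:1 --legacy-hs
Rscript exec/mpphap haplofreq --design do --chrom X --s 5 \
    --alpha alpha.json --map map.csv --sex overall --format json
```

`--map` accepts a genetic-map CSV (`marker,chromosome,position_cM`) and
converts interval lengths to `r` with the Haldane map function
(`--map-function kosambi` optional); `--alpha` is a JSON object mapping
pre-CC generation `k` to weight.

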