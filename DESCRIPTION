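Package: mpphap
Title: Two-Locus Haplotype Probabilities in Advanced Intercross Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Exact two-locus founder-haplotype probabilities, recombinant
    haplotype frequencies, founder-allele transition matrices, and map
    expansion for advanced intercross populations: two-way advanced
    intercross lines (AIL, with balanced and unbalanced X chromosome),
    eight-way heterogeneous stock (HS), and the diversity outcross (DO)
    seeded from partially inbred Collaborative Cross (pre-CC) progenitors.
    Quantities are computed on autosomes and the X chromosome from exact
    recurrence relations and first-principles breeding-chain calculations,
    with closed forms obtained by diagonalizing the recurrences.  An
    independent infinite-population table propagator and a forward
    Monte-Carlo simulator of the breeding designs serve as cross-checks.
    The transition matrices are the ingredients needed to build hidden
    Markov models for genotype reconstruction in these populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: jsonlite, optparse, stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
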