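#' AA haplotype frequency on a DO/HS autosome
#'
#' The first diversity-outcross generation receives gametes from pre-CC
#' progenitors: a progenitor at G2:F_k transmits the AA haplotype with
#' frequency q_{k+1}, so \eqn{p_1 = \sum_k \alpha_k q_{k+1}}.  Subsequent
#' random-mating generations follow
#' \deqn{p_{s+1} = (1-r) p_s + r/64,}
#' with closed form \eqn{p_s = 1/64 + (1-r)^{s-1}(p_1 - 1/64)}.
#' Heterogeneous stock is the special case alpha = \{1: 1\}, for which
#' p_1 = q_2 = (1-r)^3/8.
#'
#' @param s Outcross generation (integer >= 1).
#' @param r A single recombination fraction in `[0, 0.5]`.
#' @param alpha An [alpha_distribution()]; use [hs_alpha()] for HS.
#' @param method `"recurrence"` (reference) or `"closed_form"`.
#' @return The probability p_s.
#' @examples
#' do_autosome_AA(10, 0.01, hs_alpha())   # 0.11213...
#' @export
do_autosome_AA <- function(s, r, alpha,
                           method = c("recurrence", "closed_form")) {
  method <- match.arg(method)
  s <- check_generation(s)
  stopifnot(length(r) == 1L)
  check_recfrac(r)
  alpha <- as_alpha_distribution(alpha)
  ks <- as.integer(names(alpha))
  p1 <- sum(alpha * precc_autosome_q(ks + 1L, r))
  if (method == "closed_form")
    return(1 / 64 + (1 - r)^(s - 1L) * (p1 - 1 / 64))
  p <- p1
  if (s > 1L) for (i in seq_len(s - 1L)) p <- (1 - r) * p + r / 64
  p
}

#' Two-locus haplotype table for a DO/HS autosome
#'
#' The random order of the funnel crosses gives complete balance across the
#' eight founder alleles, so the 8 diagonal entries are each p_s and the 56
#' recombinant entries are each (1 - 8 p_s)/56.
#'
#' @inheritParams do_autosome_AA
#' @return A [hap_freq_table()] (8 x 8).
#' @export
do_autosome_table <- function(s, r, alpha,
                              method = c("recurrence", "closed_form")) {
  p <- do_autosome_AA(s, r, alpha, method = match.arg(method))
  hap_freq_table(symmetric_table(p, 8L), sex = "not_applicable",
                 design = "DO8 autosome", s = s, r = r)
}

#' Recombinant haplotype frequency on a DO/HS autosome
#'
#' The total recombinant mass 1 - 8 p_s; it is non-decreasing in s and r
#' and approaches 7/8 as s grows (all 64 ordered haplotypes equally likely).
#'
#' @inheritParams do_autosome_AA
#' @examples
#' round(do_recombinant(10, 0.01, hs_alpha()), 3)   # 0.103
#' @export
do_recombinant <- function(s, r, alpha,
                           method = c("recurrence", "closed_form")) {
  1 - 8 * do_autosome_AA(s, r, alpha, method = match.arg(method))
}

#' X-chromosome initial haplotype frequencies for the DO/HS
#'
#' Frequencies (m_1, f_1) of the AA haplotype on the X at the first
#' outcross generation.  A generation-1 male's X is a gamete from a pre-CC
#' dam; a generation-1 female adds her pre-CC sire's X transmitted intact.
#' Writing Tg(k) for the probability that a G2:F_k dam's X gamete is an
#' intact founder haplotype and Mh(k) for the same for a G2:F_k male's own
#' X, complete balance over the eight founders gives
#' \deqn{m_1 = \sum_k \alpha_k Tg(k) / 8, \qquad
#'       f_1 = \sum_k \alpha_k (Tg(k) + Mh(k)) / 16.}
#' Both are computed exactly from the eight-way pre-CC X chain.  For HS
#' (alpha = \{1: 1\}) they reduce to
#' m_1 = (1-r)^2 (4-r)/32 and f_1 = (1-r)(8 - 7r + r^2)/64.
#'
#' @inheritParams do_autosome_AA
#' @return Named numeric vector `c(m1 = , f1 = )`.
#' @examples
#' do_x_init(hs_alpha(), 0.1)
#' @export
do_x_init <- function(alpha, r) {
  stopifnot(length(r) == 1L)
  check_recfrac(r)
  alpha <- as_alpha_distribution(alpha)
  ks <- as.integer(names(alpha))
  st <- precc_x8_stats(ks, r)
  c(m1 = sum(unclass(alpha) * st$damgam / 8),
    f1 = sum(unclass(alpha) * (st$damgam + st$malehap) / 16))
}

#' AA haplotype frequency on the DO/HS X chromosome
#'
#' From the initial values of [do_x_init()], the random-mating generations
#' follow
#' \deqn{m_{s+1} = (1-r) f_s + r/64}
#' \deqn{f_{s+1} = m_s/2 + ((1-r)/2) f_s + r/128,}
#' where a recombinant female gamete joins two independent alleles of
#' frequency 1/8 each.  The closed form diagonalizes the same 2x2 matrix as
#' the balanced AIL X recurrence (eigenvalues w, y of
#' [x_eigen_coefficients()]); both converge to 1/64 for r > 0.
#'
#' @inheritParams do_autosome_AA
#' @param sex `"male"` or `"female"`.
#' @examples
#' do_x_AA(5, 0.1, hs_alpha(), "female")
#' @export
do_x_AA <- function(s, r, alpha, sex = c("male", "female"),
                    method = c("recurrence", "closed_form")) {
  sex <- match.arg(sex)
  method <- match.arg(method)
  s <- check_generation(s)
  init <- do_x_init(alpha, r)
  res <- if (method == "recurrence")
    x_recur(s, r, init["m1"], init["f1"], 1 / 64)
  else
    x_closed(s, r, init["m1"], init["f1"], 1 / 64)
  unname(if (sex == "male") res$m else res$f)
}

#' Two-locus haplotype table for the DO/HS X chromosome
#'
#' @inheritParams do_x_AA
#' @return A [hap_freq_table()] (8 x 8) for the requested sex.
#' @export
do_x_table <- function(s, r, alpha, sex = c("male", "female"),
                       method = c("recurrence", "closed_form")) {
  sex <- match.arg(sex)
  aa <- do_x_AA(s, r, alpha, sex, method = match.arg(method))
  hap_freq_table(symmetric_table(aa, 8L), sex = sex,
                 design = "DO8 X", s = s, r = r)
}

#' Recombinant haplotype frequency on the DO/HS X chromosome
#'
#' By the eight-fold allele symmetry the per-sex recombinant frequency is
#' 1 - 8 m_s (males) or 1 - 8 f_s (females); the overall frequency weights
#' females 2/3 (two-thirds of X chromosomes are in females).
#'
#' @inheritParams do_x_AA
#' @param sex `"male"`, `"female"`, or `"overall"`.
#' @export
do_x_recombinant <- function(s, r, alpha,
                             sex = c("male", "female", "overall"),
                             method = c("recurrence", "closed_form")) {
  sex <- match.arg(sex)
  method <- match.arg(method)
  m <- do_x_AA(s, r, alpha, "male", method)
  f <- do_x_AA(s, r, alpha, "female", method)
  switch(sex,
         male = 1 - 8 * m,
         female = 1 - 8 * f,
         overall = (1 - 8 * m) / 3 + 2 * (1 - 8 * f) / 3)
}
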