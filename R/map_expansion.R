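#' Map expansion (recombination-breakpoint density)
#'
#' The map expansion is the derivative, at r = 0, of the recombinant
#' haplotype frequency R(r) with respect to the meiotic recombination
#' fraction: the expected density of recombination breakpoints on a random
#' chromosome, per unit of r (equivalently per Morgan in the r -> 0 limit).
#'
#' Closed forms, per design (autosome / X):
#' \itemize{
#'   \item AIL2 autosome: s/2 for s >= 2 (the F1, s = 1, carries intact
#'     haplotypes, so its map expansion is 0).
#'   \item AIL2 balanced X: s/3 for s >= 2 (0 at s = 1) -- exactly
#'     two-thirds of the autosomal value, because only the two X
#'     chromosomes in females (out of three) pass through a recombining
#'     meiosis.
#'   \item HS8 autosome: M_1 = 3 and M_s = (7s + 17)/8: in the first three
#'     generations with recombination every breakpoint falls on a
#'     heterozygous background and is visible; thereafter a haplotype
#'     escapes recombination-free with chance 1/8 per generation, so only
#'     7/8 of events accumulate.
#'   \item HS8 X: exactly 2/3 of the autosomal value, (2/3)(7s + 17)/8.
#'   \item DO8 autosome: M_s = (7/8)(s - 1) + M_1, where M_1 is the
#'     alpha-weighted map expansion of the pre-CC transmitted gamete,
#'     computed numerically from the pre-CC chain (for alpha = \{1: 1\},
#'     M_1 = 3, recovering HS).
#'   \item DO8 X: M_s = M_1^X + (7/12)(s - 1).  Differentiating the X
#'     recurrence at r = 0 shows the overall X map expansion gains exactly
#'     7/12 per outcross generation (2/3 of the autosomal 7/8) regardless
#'     of the initial values, but the generation-1 value M_1^X must be
#'     computed from the pre-CC X chain; it equals 2/3 of the autosomal
#'     M_1 exactly only for HS (progenitors at k = 1) and only
#'     approximately for later pre-CC generations.
#' }
#'
#' @param design `"AIL2"`, `"HS8"` or `"DO8"`.
#' @param chromosome `"autosome"` or `"X"`.
#' @param s Generation (integer >= 1).
#' @param alpha Progenitor distribution, required for `"DO8"`.
#' @param balance For the AIL2 X only; `"unbalanced"` is handled by
#'   [map_expansion_unbalancedX()] and is rejected here.
#' @return The map expansion (breakpoints per Morgan at r -> 0).
#' @examples
#' map_expansion("AIL2", "autosome", 12)  # 6
#' map_expansion("HS8", "autosome", 1)    # 3
#' map_expansion("HS8", "autosome", 10)   # 10.875
#' @export
map_expansion <- function(design, chromosome = "autosome", s,
                          alpha = NULL, balance = "balanced") {
  pars <- validate_params(design, chromosome, balance, s, r = 0,
                          alpha = alpha)
  if (pars$balance == "unbalanced")
    stop("use map_expansion_unbalancedX() for the unbalanced AIL X")
  s <- pars$s
  if (pars$design == "AIL2") {
    if (s == 1L) return(0)
    return(if (pars$chromosome == "autosome") s / 2 else s / 3)
  }
  # HS8 / DO8: generation-1 value, then a constant gain per generation
  # (7/8 autosome, 7/12 X).  For HS the generation-1 values are exact:
  # M_1 = 3 (from q_2 = (1-r)^3/8) and M_1^X = 2; for general alpha they
  # are computed numerically from the pre-CC chains.
  if (pars$chromosome == "autosome") {
    m1 <- if (pars$design == "HS8") 3 else precc_map_expansion(pars$alpha)
    return(7 / 8 * (s - 1) + m1)
  }
  m1x <- if (pars$design == "HS8") 2 else precc_x_map_expansion(pars$alpha)
  7 / 12 * (s - 1) + m1x
}

# generation-1 X map expansion for DO: derivative at r = 0 of the overall
# X recombinant frequency (1/3 male, 2/3 female) built from do_x_init()
precc_x_map_expansion <- function(alpha, h = 1e-6) {
  alpha <- as_alpha_distribution(alpha)
  map_expansion_numeric(function(r) {
    ini <- do_x_init(alpha, r)
    (1 - 8 * ini[["m1"]]) / 3 + 2 * (1 - 8 * ini[["f1"]]) / 3
  }, h = h)
}

# map expansion of the gamete transmitted by pre-CC progenitors, i.e. the
# DO generation-1 value M_1 = -8 d/dr sum_k alpha_k q_{k+1}(r) at r = 0,
# by forward differences with Richardson extrapolation (the chain is exact,
# so truncation dominates; q is smooth in r)
precc_map_expansion <- function(alpha, h = 1e-6) {
  alpha <- as_alpha_distribution(alpha)
  ks <- as.integer(names(alpha))
  p1 <- function(r) sum(alpha * vapply(ks, function(k)
    precc_autosome_q(k + 1L, r), numeric(1)))
  map_expansion_numeric(function(r) 1 - 8 * p1(r), h = h)
}

#' Legacy HS map expansion
#'
#' The formula (7/8)(s + 2) historically assumed for heterogeneous stock in
#' earlier HMM software.  The exact value is (7/8)(s - 1) + 3, which
#' exceeds the legacy value by exactly 3/8 for every s: the first three
#' fully heterozygous generations contribute 3 breakpoint units, not
#' (7/8) x 3 = 21/8.
#'
#' @param s Generation (integer >= 1).
#' @examples
#' map_expansion("HS8", "autosome", 10) - hs_map_expansion_legacy(10)  # 3/8
#' @export
hs_map_expansion_legacy <- function(s) {
  s <- check_generation(s)
  7 / 8 * (s + 2)
}

#' Map expansion of the unbalanced AIL X chromosome
#'
#' The overall (2/3 female, 1/3 male weighted) X map expansion M'_s when
#' all F1 males are hemizygous A.  No closed form is available; it follows
#' the recurrence
#' \deqn{M'_{s+1} = M'_s + (4/3)(q_s - q_{s-1} q_{s-2})}
#' obtained by differentiating the haplotype recurrences at r = 0, with
#' initial conditions M'_1 = 0 and M'_2 = 2/3 and q_s the female A-allele
#' frequency of [unbalanced_allele_freq()].
#'
#' @param s Generation (integer >= 1).
#' @examples
#' map_expansion_unbalancedX(1)  # 0
#' map_expansion_unbalancedX(2)  # 2/3
#' @export
map_expansion_unbalancedX <- function(s) {
  s <- check_generation(s)
  if (s == 1L) return(0)
  m <- 2 / 3
  if (s > 2L) for (t in 2:(s - 1L)) {
    m <- m + 4 / 3 * (unbalanced_allele_freq(t) -
                        unbalanced_allele_freq(t - 1L) *
                        unbalanced_allele_freq(t - 2L))
  }
  m
}

#' Numerical map expansion
#'
#' Forward-difference estimate of dR/dr at r = 0 with two-point Richardson
#' extrapolation (steps h and h/2); forward differences are used because
#' R(r) is defined only for r >= 0.
#'
#' @param recombinant_fn Function of r returning the recombinant haplotype
#'   frequency; must be finite on `[0, 4h]`.
#' @param h Base step (default 1e-6).
#' @return The derivative estimate.
#' @examples
#' map_expansion_numeric(function(r) ail_autosome_recombinant(12, r))  # ~6
#' @export
map_expansion_numeric <- function(recombinant_fn, h = 1e-6) {
  f0 <- recombinant_fn(0)
  d1 <- (recombinant_fn(h) - f0) / h
  d2 <- (recombinant_fn(h / 2) - f0) / (h / 2)
  out <- 2 * d2 - d1
  if (!is.finite(out))
    stop("recombinant_fn returned non-finite values near r = 0")
  out
}
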