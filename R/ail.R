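#' AA haplotype frequency on an AIL autosome
#'
#' Frequency p_s of the intact AA two-locus haplotype at generation F_s of
#' two-way advanced intercross lines.  From generation 2 onward a haplotype
#' is transmitted intact with probability 1 - r or is a recombinant joining
#' two independent A alleles (frequency 1/2 at each locus):
#' \deqn{p_{s+1} = (1 - r) p_s + r/4, \quad s \ge 2.}
#' The F1 -> F2 step is exact rather than following the recurrence: an F1
#' individual carries the anticorrelated pair (AA, BB), so its recombinant
#' gametes are never AA and p_2 = (1 - r)/2 (hence the F2 recombinant
#' frequency is exactly r).  The closed form, valid for s >= 2, is
#' \deqn{p_s = (1/4)[1 + (1 - 2r)(1 - r)^{s-2}],}
#' and satisfies both the recurrence and the exact p_2.
#'
#' @param s Generation number (integer >= 1).
#' @param r Recombination fraction(s) in `[0, 0.5]`; vectorized.
#' @param method `"recurrence"` (reference) or `"closed_form"`.
#' @return Numeric vector of p_s, same length as `r`.
#' @examples
#' ail_autosome_AA(2, 0.1)          # 0.45
#' ail_autosome_AA(12, 0.01)        # 0.4715735...
#' @export
ail_autosome_AA <- function(s, r, method = c("recurrence", "closed_form")) {
  method <- match.arg(method)
  s <- check_generation(s)
  check_recfrac(r)
  if (s == 1L) return(rep(0.5, length(r)))
  if (method == "closed_form")
    return(0.25 * (1 + (1 - 2 * r) * (1 - r)^(s - 2)))
  p <- (1 - r) / 2                      # exact F1 -> F2 step
  if (s > 2L) for (i in seq_len(s - 2L)) p <- (1 - r) * p + r / 4
  rep_len(p, length(r))
}

#' Recombinant haplotype frequency on an AIL autosome
#'
#' Equals 1 - 2 p_s.  At s = 2 (one meiosis beyond the F1) this is exactly
#' r; it increases with both s and r towards the stationary value 1/2.
#'
#' @inheritParams ail_autosome_AA
#' @return Numeric vector.
#' @examples
#' ail_autosome_recombinant(2, 0.1)   # exactly 0.1
#' @export
ail_autosome_recombinant <- function(s, r,
                                     method = c("recurrence", "closed_form")) {
  1 - 2 * ail_autosome_AA(s, r, method = match.arg(method))
}

#' Two-locus haplotype table for the AIL autosome
#'
#' By the exchange symmetry of the two founder labels, the table has equal
#' diagonal entries p_s and equal off-diagonal entries (1 - 2 p_s)/2.
#'
#' @inheritParams ail_autosome_AA
#' @param r A single recombination fraction.
#' @return A [hap_freq_table()] (2 x 2).
#' @export
ail_autosome_table <- function(s, r, method = c("recurrence", "closed_form")) {
  stopifnot(length(r) == 1L)
  p <- ail_autosome_AA(s, r, method = match.arg(method))
  hap_freq_table(symmetric_table(p, 2L), sex = "not_applicable",
                 design = "AIL2 autosome", s = s, r = r)
}

# shared 2x2 recurrence for X-linked AA-haplotype frequencies:
#   m_{s+1} = (1-r) f_s + r * cst
#   f_{s+1} = (1/2) m_s + ((1-r)/2) f_s + (r/2) * cst
# with cst the probability that a recombinant female gamete joins two A
# alleles (1/4 for balanced AIL, 1/64 for HS/DO), valid whenever the
# female's two haplotypes are independent draws.  Iterated from the
# anchoring generation `anchor` with values (m_a, f_a).
x_recur <- function(s, r, m_a, f_a, cst, anchor = 1L) {
  m <- rep_len(m_a, length(r)); f <- rep_len(f_a, length(r))
  if (s > anchor) for (i in seq_len(s - anchor)) {
    m_new <- (1 - r) * f + r * cst
    f_new <- 0.5 * m + 0.5 * (1 - r) * f + 0.5 * r * cst
    m <- m_new; f <- f_new
  }
  list(m = m, f = f)
}

# closed form for the same recurrence, by diagonalizing the homogeneous part
#   T = [[0, 1-r], [1/2, (1-r)/2]]
# whose eigenvalues are w = (1-r+z)/4 and y = (1-r-z)/4 with
# z = sqrt((1-r)(9-r)); the stationary point is m = f = cst/2... the fixed
# point solves m* = (1-r) f* + r cst, f* = m*/2 + (1-r) f*/2 + r cst / 2,
# giving m* = f* = cst (both sexes).  Deviations v_s = (m_s, f_s) - cst
# satisfy v_{s+1} = T v_s, and T's eigenvector for eigenvalue L is
# (1 - r, L).
x_closed <- function(s, r, m_a, f_a, cst, anchor = 1L) {
  z <- sqrt((1 - r) * (9 - r))
  w <- (1 - r + z) / 4
  y <- (1 - r - z) / 4
  vm <- m_a - cst
  vf <- f_a - cst
  # solve (vm, vf) = c1 (1-r, w) + c2 (1-r, y)
  det <- (1 - r) * (y - w)
  c1 <- (vm * y - (1 - r) * vf) / det
  c2 <- ((1 - r) * vf - vm * w) / det
  pw <- w^(s - anchor); py <- y^(s - anchor)
  list(m = cst + (1 - r) * (c1 * pw + c2 * py),
       f = cst + c1 * pw * w + c2 * py * y,
       z = z, w = w, y = y)
}

#' Eigen-quantities of the X-chromosome recurrence
#'
#' The homogeneous part of the X-linked recurrence has matrix
#' `[[0, 1-r], [1/2, (1-r)/2]]`, with eigenvalues w and y satisfying
#' w + y = (1-r)/2 and w y = -(1-r)/2.  Here z = sqrt((1-r)(9-r)),
#' w = (1-r+z)/4, y = (1-r-z)/4.
#'
#' @param r Recombination fraction(s).
#' @return List with components `z`, `w`, `y` (vectors).
#' @export
x_eigen_coefficients <- function(r) {
  check_recfrac(r)
  z <- sqrt((1 - r) * (9 - r))
  list(z = z, w = (1 - r + z) / 4, y = (1 - r - z) / 4)
}

#' AA haplotype frequency on the balanced AIL X chromosome
#'
#' Balanced AIL starts from equal numbers of reciprocal F1s, so F1 males are
#' equally likely hemizygous A or B and the A allele has frequency 1/2 in
#' both sexes at every generation.  For s >= 2,
#' \deqn{m_{s+1} = (1-r) f_s + r/4}
#' \deqn{f_{s+1} = m_s/2 + ((1-r)/2) f_s + r/8}
#' (a male X is his dam's gamete; a female X is equally likely her sire's
#' intact X or her dam's gamete; a recombinant gamete joins independent
#' alleles of frequency 1/2).  The F1 -> F2 step is exact: every F1 female
#' carries the anticorrelated pair (AA, BB), so her recombinant gametes are
#' never AA and m_2 = (1-r)/2, f_2 = (2-r)/4 (with m_1 = f_1 = 1/2).  The
#' closed form diagonalizes the 2x2 recurrence anchored at these exact
#' generation-2 values (see [x_eigen_coefficients()]).
#'
#' @inheritParams ail_autosome_AA
#' @param sex `"male"` or `"female"`.
#' @return Numeric vector of m_s or f_s.
#' @examples
#' ail_balancedX_AA(2, 0.1, "male")    # 0.45
#' ail_balancedX_AA(2, 0.1, "female")  # 0.475
#' @export
ail_balancedX_AA <- function(s, r, sex = c("male", "female"),
                             method = c("recurrence", "closed_form")) {
  sex <- match.arg(sex)
  method <- match.arg(method)
  s <- check_generation(s)
  check_recfrac(r)
  if (s == 1L) return(rep(0.5, length(r)))
  m2 <- (1 - r) / 2
  f2 <- (2 - r) / 4
  res <- if (method == "recurrence") x_recur(s, r, m2, f2, 0.25, anchor = 2L)
         else x_closed(s, r, m2, f2, 0.25, anchor = 2L)
  if (sex == "male") res$m else res$f
}

#' Recombinant haplotype frequency on the balanced AIL X
#'
#' 1 - 2 m_s in males, 1 - 2 f_s in females; the overall frequency weights
#' females by 2/3 because two-thirds of X chromosomes reside in females:
#' 1 - (2 m_s + 4 f_s)/3.
#'
#' @inheritParams ail_balancedX_AA
#' @param sex `"male"`, `"female"`, or `"overall"`.
#' @export
ail_balancedX_recombinant <- function(s, r,
                                      sex = c("male", "female", "overall"),
                                      method = c("recurrence", "closed_form")) {
  sex <- match.arg(sex)
  method <- match.arg(method)
  m <- ail_balancedX_AA(s, r, "male", method)
  f <- ail_balancedX_AA(s, r, "female", method)
  switch(sex,
         male = 1 - 2 * m,
         female = 1 - 2 * f,
         overall = 1 - (2 * m + 4 * f) / 3)
}

#' A-allele frequency in the unbalanced AIL X chromosome
#'
#' In unbalanced AIL all F1s come from the single cross dam A x sire B, so
#' all F1 males are hemizygous A.  Let q_s be the A-allele frequency in
#' females at F_s (males at F_s carry q_{s-1}).  With q_0 = 1, q_1 = 1/2,
#' \deqn{q_{s+1} = q_s/2 + q_{s-1}/2,}
#' solved by q_s = 2/3 + (1/3)(-1/2)^s for s >= 0.  The pre-cross boundary
#' value q_{-1} = 0 (the F1 female's paternal X carries no A allele) is also
#' supported.
#'
#' @param s Integer generation, >= -1.
#' @param method `"closed_form"` (default) or `"recurrence"`.
#' @return The allele frequency q_s.
#' @examples
#' unbalanced_allele_freq(0)  # 1
#' unbalanced_allele_freq(2)  # 0.75
#' @export
unbalanced_allele_freq <- function(s, method = c("closed_form", "recurrence")) {
  method <- match.arg(method)
  s <- check_generation(s, least = -1L)
  if (s == -1L) return(0)
  if (method == "closed_form") return(2 / 3 + (1 / 3) * (-0.5)^s)
  q_prev <- 1; q <- 0.5           # q_0, q_1
  if (s == 0L) return(1)
  if (s >= 2L) for (i in 2:s) {
    q_new <- 0.5 * q + 0.5 * q_prev
    q_prev <- q; q <- q_new
  }
  q
}

#' AA haplotype frequency on the unbalanced AIL X chromosome
#'
#' Frequencies m'_s (males) and f'_s (females) of the AA haplotype when all
#' F1 males are hemizygous A.  With m'_1 = 1, f'_1 = 1/2,
#' \deqn{m'_{s+1} = (1-r) f'_s + r q_{s-1} q_{s-2}}
#' \deqn{f'_{s+1} = m'_s/2 + ((1-r)/2) f'_s + (r/2) q_{s-1} q_{s-2},}
#' where a recombinant female gamete joins independent alleles whose
#' frequencies are those of females (q_{s-1}) and males (q_{s-2}) one
#' generation back; q_{-1} = 0.  No closed form is available; the recurrence
#' is the reference implementation.  For r > 0 both sexes converge to 4/9.
#'
#' @inheritParams ail_balancedX_AA
#' @return Numeric vector of m'_s or f'_s.
#' @examples
#' ail_unbalancedX_AA(1, 0.3, "male")   # 1: all F1 males hemizygous A
#' ail_unbalancedX_AA(2, 0.2, "male")   # 0.4 = (1 - r)/2
#' @export
ail_unbalancedX_AA <- function(s, r, sex = c("male", "female")) {
  sex <- match.arg(sex)
  s <- check_generation(s)
  check_recfrac(r)
  m <- rep(1, length(r)); f <- rep(0.5, length(r))
  if (s > 1L) for (t in seq_len(s - 1L)) {
    # step from generation t to t+1
    qq <- unbalanced_allele_freq(t - 1L) * unbalanced_allele_freq(t - 2L)
    m_new <- (1 - r) * f + r * qq
    f_new <- 0.5 * m + 0.5 * (1 - r) * f + 0.5 * r * qq
    m <- m_new; f <- f_new
  }
  if (sex == "male") m else f
}

#' Two-locus haplotype table for the unbalanced AIL X
#'
#' Completes the 2 x 2 joint distribution from the AA entry and the allele
#' frequencies: both loci have A-allele frequency q_s in females and
#' q_{s-1} in males, so AB = BA = q - AA and BB = 1 - 2q + AA.
#'
#' @inheritParams ail_unbalancedX_AA
#' @param r A single recombination fraction.
#' @return A [hap_freq_table()] (2 x 2).
#' @examples
#' ail_unbalancedX_table(2, 0.2, "male")  # entries 0.4, 0.1, 0.1, 0.4
#' @export
ail_unbalancedX_table <- function(s, r, sex = c("male", "female")) {
  sex <- match.arg(sex)
  stopifnot(length(r) == 1L)
  aa <- ail_unbalancedX_AA(s, r, sex)
  q <- unbalanced_allele_freq(if (sex == "male") s - 1L else s)
  m <- matrix(c(aa, q - aa, q - aa, 1 - 2 * q + aa), 2, 2,
              dimnames = list(locus1 = .founders2, locus2 = .founders2))
  hap_freq_table(m, sex = sex, design = "AIL2 X unbalanced", s = s, r = r)
}

#' Recombinant haplotype frequency on the unbalanced AIL X
#'
#' The recombinant (non-parental) frequency is 1 - AA - BB, which equals
#' 2(q_{s-1} - m'_s) in males and 2(q_s - f'_s) in females; overall weights
#' females by 2/3.
#'
#' @inheritParams ail_unbalancedX_AA
#' @param sex `"male"`, `"female"`, or `"overall"`.
#' @export
ail_unbalancedX_recombinant <- function(s, r,
                                        sex = c("male", "female", "overall")) {
  sex <- match.arg(sex)
  rm_ <- 2 * (unbalanced_allele_freq(s - 1L) - ail_unbalancedX_AA(s, r, "male"))
  rf <- 2 * (unbalanced_allele_freq(s) - ail_unbalancedX_AA(s, r, "female"))
  switch(sex, male = rm_, female = rf, overall = rm_ / 3 + 2 * rf / 3)
}
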