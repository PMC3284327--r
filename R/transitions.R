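#' Founder-allele transition matrix between two loci
#'
#' Converts the two-locus haplotype table into the row-stochastic matrix of
#' conditional probabilities P(founder allele at locus 2 = j | founder
#' allele at locus 1 = i) = table[i, j] / (locus-1 marginal of i) -- the
#' quantity a hidden Markov model for genotype reconstruction consumes as
#' its transition matrix for one marker interval.  At r = 0 the matrix is
#' the identity; for balanced designs it is symmetric and doubly
#' stochastic.  For the unbalanced AIL X the locus-1 allele frequencies are
#' not uniform, so the matrix carries its initial (locus-1) distribution in
#' the `"init"` attribute; downstream HMMs must use the pair together.
#'
#' @param design `"AIL2"`, `"HS8"` or `"DO8"`.
#' @param chromosome `"autosome"` or `"X"`.
#' @param s Generation (integer >= 1).
#' @param r A single recombination fraction.
#' @param sex `"male"` or `"female"`; required for the X chromosome.
#' @param alpha Progenitor distribution (DO8 only).
#' @param balance `"balanced"` or `"unbalanced"` (AIL2 X only).
#' @return A matrix of class `"transition_matrix"` with attributes `init`
#'   (locus-1 allele frequencies), `design`, `s`, `r`, `sex`.
#' @examples
#' transition_matrix("DO8", "autosome", s = 10, r = 0.01, alpha = hs_alpha())
#' transition_matrix("AIL2", "X", s = 2, r = 0.2, sex = "male",
#'                   balance = "unbalanced")
#' @export
transition_matrix <- function(design, chromosome = "autosome", s, r,
                              sex = NULL, alpha = NULL,
                              balance = "balanced") {
  pars <- validate_params(design, chromosome, balance, s, r, alpha)
  stopifnot(length(r) == 1L)
  if (pars$chromosome == "X") {
    if (is.null(sex)) stop("sex is required for X-chromosome matrices")
    sex <- match.arg(sex, .sexes)
  }
  tab <- hap_table_for(pars, sex)
  marg <- locus_marginals(tab, 1L)
  if (any(marg <= 0))
    stop("zero allele frequency at locus 1")  # cannot occur for s >= 1
  P <- unclass(tab) / marg
  structure(P, class = c("transition_matrix", "matrix"),
            init = marg, design = pars$design, chromosome = pars$chromosome,
            balance = pars$balance, s = pars$s, r = r, sex = sex)
}

# dispatch to the appropriate table construction
hap_table_for <- function(pars, sex = NULL) {
  with(pars, {
    if (design == "AIL2") {
      if (chromosome == "autosome") return(ail_autosome_table(s, r))
      if (balance == "unbalanced") return(ail_unbalancedX_table(s, r, sex))
      aa <- ail_balancedX_AA(s, r, sex)
      return(hap_freq_table(symmetric_table(aa, 2L), sex = sex,
                            design = "AIL2 X balanced", s = s, r = r))
    }
    if (chromosome == "autosome") do_autosome_table(s, r, alpha)
    else do_x_table(s, r, alpha, sex)
  })
}

#' Transition matrices for a vector of marker intervals
#'
#' Applies [transition_matrix()] to each interval recombination fraction,
#' as needed to assemble an HMM along a chromosome.
#'
#' @inheritParams transition_matrix
#' @param r Numeric vector of interval recombination fractions.
#' @return List of `"transition_matrix"` objects, one per interval.
#' @export
transition_matrices <- function(design, chromosome = "autosome", s, r,
                                sex = NULL, alpha = NULL,
                                balance = "balanced") {
  lapply(r, function(ri)
    transition_matrix(design, chromosome, s, ri, sex, alpha, balance))
}

#' @export
print.transition_matrix <- function(x, digits = 7, ...) {
  cat(sprintf("Founder-allele transition matrix (%s %s, s = %d, r = %s",
              attr(x, "design"), attr(x, "chromosome"), attr(x, "s"),
              format(attr(x, "r"))))
  if (!is.null(attr(x, "sex"))) cat(", ", attr(x, "sex"), sep = "")
  cat(")\n")
  m <- x
  attributes(m) <- attributes(m)["dim"]
  dimnames(m) <- dimnames(x)
  print(signif(m, digits), ...)
  cat("locus-1 allele frequencies:",
      paste(signif(attr(x, "init"), digits), collapse = " "), "\n")
  invisible(x)
}
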