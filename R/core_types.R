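#' mpphap: two-locus haplotype probabilities in advanced intercross populations
#'
#' Exact two-locus founder-haplotype probabilities, recombinant-haplotype
#' frequencies, founder-allele transition matrices and map expansion for
#' two-way advanced intercross lines (AIL), eight-way heterogeneous stock
#' (HS) and the diversity outcross (DO), on autosomes and the X chromosome.
#'
#' The population designs are identified by the strings `"AIL2"` (two
#' founders), `"HS8"` (eight founders, all progenitors at pre-CC generation
#' k = 1) and `"DO8"` (eight founders, progenitors drawn from pre-CC
#' generations according to a weight distribution alpha).  HS8 is exactly
#' DO8 with alpha concentrated at k = 1.
#'
#' @keywords internal
"_PACKAGE"

# design/chromosome/sex enumerations used throughout
.designs <- c("AIL2", "HS8", "DO8")
.chromosomes <- c("autosome", "X")
.sexes <- c("male", "female")

#' Validate design parameters
#'
#' Checks a parameter bundle (design, chromosome, balance, generation,
#' recombination fraction, alpha) against the domain invariants and returns
#' it, normalized, as a list.  All user-facing functions funnel their inputs
#' through this check.
#'
#' @param design One of `"AIL2"`, `"HS8"`, `"DO8"`.
#' @param chromosome `"autosome"` or `"X"`.
#' @param balance `"balanced"` or `"unbalanced"`; only meaningful for the
#'   AIL2 X chromosome (unbalanced = all F1 from a single cross direction,
#'   so all F1 males are hemizygous for the dam-line allele).
#' @param s Generation number, integer >= 1.
#' @param r Meiotic recombination fraction(s) in `[0, 0.5]`.
#' @param alpha An [alpha_distribution()] (required for DO8, ignored
#'   otherwise).
#' @return A list with the validated components (invisibly usable by
#'   callers); `alpha` is replaced by `hs_alpha()` for HS8.
#' @examples
#' validate_params("AIL2", "autosome", s = 2, r = 0.1)
#' @export
validate_params <- function(design, chromosome = "autosome",
                            balance = "balanced", s = 1L, r = 0,
                            alpha = NULL) {
  design <- match.arg(design, .designs)
  chromosome <- match.arg(chromosome, .chromosomes)
  balance <- match.arg(balance, c("balanced", "unbalanced"))
  check_generation(s)
  check_recfrac(r)
  if (balance == "unbalanced" && !(design == "AIL2" && chromosome == "X"))
    stop("balance = \"unbalanced\" is only defined for the AIL2 X chromosome")
  if (design == "HS8") {
    alpha <- hs_alpha()
  } else if (design == "DO8") {
    if (is.null(alpha))
      stop("design \"DO8\" requires an alpha distribution over pre-CC generations")
    alpha <- as_alpha_distribution(alpha)
  }
  list(design = design, chromosome = chromosome, balance = balance,
       s = as.integer(s), r = r, alpha = alpha)
}

# invariant: 0 <= r <= 0.5 (both endpoints legal)
check_recfrac <- function(r) {
  if (!is.numeric(r) || length(r) < 1L || anyNA(r))
    stop("r must be numeric and non-missing")
  if (any(r < 0 | r > 0.5))
    stop("r out of range: the recombination fraction must lie in [0, 0.5]")
  invisible(r)
}

# invariant: s integer-valued and >= `least` (1 for generations; q_s allows -1)
check_generation <- function(s, least = 1L, what = "s") {
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s != round(s))
    stop(what, " must be a single integer")
  if (s < least)
    stop(what, " must be >= ", least)
  invisible(as.integer(s))
}

#' Progenitor-generation weight distribution for the DO
#'
#' Constructs the distribution alpha_k giving the proportion of diversity
#' outcross progenitors that were pre-CC mice at sib-mating generation
#' G2:F_k.  Weights must be non-negative and sum to 1 (within `tol`); they
#' are renormalized to sum to exactly 1.
#'
#' @param k Integer vector of pre-CC generations (each >= 1), no duplicates.
#' @param weights Numeric vector of the same length.
#' @param tol Tolerance for the sum-to-one check before renormalization.
#' @return A named numeric vector of class `"alpha_distribution"` (names are
#'   the generations k).
#' @examples
#' alpha_distribution(4:8, rep(1 / 5, 5))
#' hs_alpha()  # all mass at k = 1
#' @export
alpha_distribution <- function(k, weights, tol = 1e-6) {
  if (length(k) != length(weights) || length(k) < 1L)
    stop("k and weights must be non-empty vectors of equal length")
  if (any(k != round(k)) || any(k < 1L))
    stop("pre-CC generations k must be integers >= 1")
  if (anyDuplicated(k))
    stop("duplicated pre-CC generation in alpha distribution")
  if (!is.numeric(weights) || anyNA(weights) || any(weights < 0))
    stop("alpha weights must be non-negative and non-missing")
  if (abs(sum(weights) - 1) > tol)
    stop("alpha weights must sum to 1 (within ", format(tol), ")")
  a <- weights / sum(weights)
  names(a) <- as.character(as.integer(k))
  class(a) <- "alpha_distribution"
  a
}

#' @rdname alpha_distribution
#' @param x Object to coerce: an `alpha_distribution`, or a named numeric
#'   vector / single-level list mapping k to weight.
#' @export
as_alpha_distribution <- function(x, tol = 1e-6) {
  if (inherits(x, "alpha_distribution")) return(x)
  if (is.list(x)) x <- unlist(x)
  if (is.null(names(x)))
    stop("alpha must be named by pre-CC generation k")
  alpha_distribution(as.integer(names(x)), as.numeric(x), tol = tol)
}

#' @rdname alpha_distribution
#' @export
hs_alpha <- function() alpha_distribution(1L, 1)

#' Illustrative DO progenitor distribution
#'
#' A documented example alpha distribution, uniform over pre-CC generations
#' k = 4..8 (mean 6).  The generation distribution of the actual DO founder
#' stock is not reproduced here; this synthetic example merely has a
#' realistic mean and spread, and any analysis of a real DO population
#' should supply its own weights.
#'
#' @return An [alpha_distribution()].
#' @examples
#' example_alpha()
#' @export
example_alpha <- function() alpha_distribution(4:8, rep(1 / 5, 5))

#' Two-locus haplotype frequency table
#'
#' Wraps an `n x n` matrix of joint probabilities, indexed by founder allele
#' at locus 1 (rows) and locus 2 (columns), as a validated table.  Entries
#' must be non-negative and sum to 1 (within 1e-12).
#'
#' @param entries Square numeric matrix of joint probabilities.
#' @param sex `"male"`, `"female"`, `"pooled"`, or `"not_applicable"`.
#' @param design,s,r Optional metadata stored as attributes.
#' @return The matrix with class `"hap_freq_table"`.
#' @export
hap_freq_table <- function(entries, sex = "not_applicable",
                           design = NULL, s = NULL, r = NULL) {
  if (!is.matrix(entries) || nrow(entries) != ncol(entries))
    stop("entries must be a square matrix")
  if (!nrow(entries) %in% c(2L, 8L))
    stop("haplotype tables have 2 or 8 founders")
  if (any(entries < -1e-12))
    stop("haplotype probabilities must be non-negative")
  if (abs(sum(entries) - 1) > 1e-12)
    stop("haplotype probabilities must sum to 1")
  sex <- match.arg(sex, c("male", "female", "pooled", "not_applicable"))
  entries[entries < 0] <- 0
  structure(entries, class = c("hap_freq_table", "matrix"),
            sex = sex, design = design, s = s, r = r)
}

#' @export
print.hap_freq_table <- function(x, digits = 7, ...) {
  cat(sprintf("Two-locus haplotype frequency table (%d founders", nrow(x)))
  if (!identical(attr(x, "sex"), "not_applicable"))
    cat(", ", attr(x, "sex"), sep = "")
  if (!is.null(attr(x, "design")))
    cat(sprintf("; %s, s = %s, r = %s", attr(x, "design"),
                attr(x, "s"), format(attr(x, "r"))))
  cat(")\n")
  m <- x
  attributes(m) <- attributes(m)["dim"]
  dimnames(m) <- dimnames(x)
  print(signif(m, digits), ...)
  invisible(x)
}

#' Marginal allele frequencies of a haplotype table
#'
#' @param x A [hap_freq_table()].
#' @param locus 1 (rows) or 2 (columns).
#' @return Numeric vector of founder-allele frequencies at the locus.
#' @export
locus_marginals <- function(x, locus = 1L) {
  if (locus == 1L) rowSums(unclass(x)) else colSums(unclass(x))
}

# total non-parental (recombinant) probability mass of a table
recombinant_mass <- function(x) {
  m <- unclass(x)
  1 - sum(diag(m))
}

# founder labels used for 8-founder tables
.founders8 <- LETTERS[1:8]
.founders2 <- c("A", "B")

# helper: exchangeable n x n table with given diagonal entry
symmetric_table <- function(p_diag, n) {
  off <- (1 - n * p_diag) / (n * (n - 1))
  m <- matrix(off, n, n)
  diag(m) <- p_diag
  labs <- if (n == 2L) .founders2 else .founders8
  dimnames(m) <- list(locus1 = labs, locus2 = labs)
  m
}
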