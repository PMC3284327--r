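# Exact two-locus chains for pre-CC progenitors, built from first
# principles: the founder funnel (two-way, four-way, eight-way crosses)
# followed by sibling mating, with meiosis modeled as the standard
# two-locus gamete distribution (non-recombinant haplotypes at (1-r)/2
# each, recombinants at r/2 each).
#
# States are lumped by tracking, for one founder allele of interest, the
# indicator pattern of "is this allele the tracked founder's" across the
# haplotypes of a sib-mating pair.  The lumping is exact because gamete
# formation copies alleles, so indicator patterns evolve autonomously.
#
# Encodings:
#   haplotype h in 0..3:  h = 1(locus1 tracked) + 2 * 1(locus2 tracked)
#   individual i in 0..15: i = h_maternal + 4 * h_paternal
#   autosome sib pair in 0..255: i_dam + 16 * i_sire
#   X-chromosome state in 0..63: h_female_maternal + 4 * h_female_paternal
#                                 + 16 * h_male

# gamete distribution from each of the 16 individual states: 16 x 4 matrix.
# Row i+1 gives P(gamete = g) for an individual with haplotypes (h1, h2):
# start haplotype uniform, locus-2 allele from the same haplotype with
# probability 1-r, from the other with probability r.
gamete_dist16 <- function(r) {
  G <- matrix(0, 16, 4)
  for (h1 in 0:3) for (h2 in 0:3) {
    i <- h1 + 4 * h2
    gd <- numeric(4)
    rec12 <- (h1 %% 2) + 2 * (h2 %/% 2)   # locus1 from h1, locus2 from h2
    rec21 <- (h2 %% 2) + 2 * (h1 %/% 2)
    gd[h1 + 1] <- gd[h1 + 1] + 0.5 * (1 - r)
    gd[h2 + 1] <- gd[h2 + 1] + 0.5 * (1 - r)
    gd[rec12 + 1] <- gd[rec12 + 1] + 0.5 * r
    gd[rec21 + 1] <- gd[rec21 + 1] + 0.5 * r
    G[i + 1, ] <- gd
  }
  G
}

# Conditional indicator law of a gamete from a four-way (G2) parent, given
# the realized two-way gamete h carried by the arm that contains the
# tracked founder (the other arm never carries it).  h takes the values
# AA, BB, AB, BA with probabilities (1-r)/2, (1-r)/2, r/2, r/2.  The two
# siblings of a G2:F1 pair share their parents, so their funnel gametes
# are conditionally independent given h but not marginally independent;
# the initial pair distribution must mix over h jointly.
funnel4_cond_dists <- function(r) {
  list(AA = c((1 - r) / 2, r / 2, r / 2, (1 - r) / 2),
       BB = c(1, 0, 0, 0),
       AB = c(0.5, 0.5, 0, 0),
       BA = c(0.5, 0, 0.5, 0))
}

funnel4_h_probs <- function(r) {
  c(AA = (1 - r) / 2, BB = (1 - r) / 2, AB = r / 2, BA = r / 2)
}

# marginal law of a four-way funnel gamete: P(1,1) = (1-r)^2/4,
# P(1,0) = P(0,1) = r(2-r)/4
funnel4_gamete_dist <- function(r) {
  g <- funnel4_cond_dists(r)
  p <- funnel4_h_probs(r)
  p["AA"] * g$AA + p["BB"] * g$BB + p["AB"] * g$AB + p["BA"] * g$BA
}

# 256 x 256 sib-mating transition matrix for the autosomal chain.
sib_transition_auto <- function(r) {
  G <- gamete_dist16(r)
  T <- matrix(0, 256, 256)
  for (i1 in 0:15) for (i2 in 0:15) {
    s <- i1 + 16 * i2
    gd <- G[i1 + 1, ]   # gamete from dam
    gs <- G[i2 + 1, ]   # gamete from sire
    child16 <- as.vector(outer(gd, gs))      # index h_m + 4 h_p
    T[s + 1, ] <- as.vector(outer(child16, child16))
  }
  T
}

# distribution over pair states at G2:F1 (k = 1): the two siblings share
# their G2 parents, so their maternal haplotypes are gametes from the SAME
# four-way dam -- conditionally independent given her realized two-way
# gamete h, mixed over h jointly.  Their paternal haplotypes come from the
# other four-way arm and never carry the tracked allele (state 0); by
# symmetry every founder yields this same law on the autosome.
precc_auto_init <- function(r) {
  g <- funnel4_cond_dists(r)
  p <- funnel4_h_probs(r)
  d <- numeric(256)
  for (h in names(g)) {
    ind16 <- numeric(16)
    ind16[0:3 + 1] <- g[[h]]    # paternal haplotype = state 0
    d <- d + p[[h]] * as.vector(outer(ind16, ind16))
  }
  d
}

# number of tracked-parental (state 3) haplotypes in each pair state
pair_par_count <- local({
  cnt <- NULL
  function() {
    if (is.null(cnt)) {
      cnt <<- vapply(0:255, function(s) {
        i1 <- s %% 16; i2 <- s %/% 16
        sum(c(i1 %% 4, i1 %/% 4, i2 %% 4, i2 %/% 4) == 3)
      }, numeric(1))
    }
    cnt
  }
})

#' AA haplotype frequency in pre-CC progenitors (autosome)
#'
#' Exact frequency q_k of an intact AA founder haplotype at two loci with
#' recombination fraction r, at sib-mating generation G2:F_k of
#' Collaborative Cross line construction (k = 1 is the eight-way cross
#' offspring).  Computed from the lumped sib-pair indicator chain; at r = 0
#' the answer is 1/8 for every k, and q_2 = (1-r)^3/8 (three independent
#' meioses separate a G2:F2 haplotype from the founders).
#'
#' @param k Pre-CC generation(s), integer(s) >= 1; may be a vector if `r`
#'   is scalar (one chain run serves all generations).
#' @param r Recombination fraction(s) in `[0, 0.5]`; may be a vector if
#'   `k` is scalar.
#' @return Numeric vector of q_k (same length as the vector argument).
#' @examples
#' precc_autosome_q(2, 0.01)   # (1 - 0.01)^3 / 8 = 0.1212874
#' @export
precc_autosome_q <- function(k, r) {
  if (length(k) > 1L && length(r) > 1L)
    stop("only one of k and r may be a vector")
  for (ki in k) check_generation(ki, what = "k")
  k <- as.integer(k)
  check_recfrac(r)
  out <- vapply(r, function(ri) {
    d <- precc_auto_init(ri)
    kmax <- max(k)
    qs <- numeric(kmax)
    qs[1] <- sum(d * pair_par_count()) / 4
    if (kmax > 1L) {
      T <- sib_transition_auto(ri)
      for (i in 2:kmax) {
        d <- as.vector(d %*% T)
        qs[i] <- sum(d * pair_par_count()) / 4
      }
    }
    qs[k]
  }, numeric(length(k)))
  as.vector(out)
}

# --- X chromosome chains -------------------------------------------------

# 64 x 64 sib-mating transition for the X: the next female's maternal
# haplotype is a gamete from the current female, her paternal haplotype is
# the current male's X transmitted intact, and the next male's X is an
# independent gamete from the current female.
sib_transition_x <- function(r) {
  G <- gamete_dist16(r)
  T <- matrix(0, 64, 64)
  for (fm in 0:3) for (fp in 0:3) for (mh in 0:3) {
    s <- fm + 4 * fp + 16 * mh
    gf <- G[fm + 4 * fp + 1, ]
    # next state: fm' ~ gf, fp' = mh, mh' ~ gf
    idx <- outer(0:3, 0:3, function(a, b) a + 4 * mh + 16 * b)
    T[s + 1, as.vector(idx) + 1] <- as.vector(outer(gf, gf))
  }
  T
}

# initial X-state distributions at G2:F1 of the eight-way funnel, for the
# three founder position classes that carry X material:
#   "A": a founder in the recombining pair of the dam-side two-way cross
#        (two such founders),
#   "C": the founder whose X enters the dam-side four-way intact (one),
#   "E": a founder in the recombining pair of the sire-side two-way cross
#        (two); the remaining three founders contribute no X.
# The G2:F1 female carries (V1, V2) and her brother V1', where V1, V1' are
# independent gametes from the dam-side four-way female (haplotypes
# {gamete(A,B), intact C}) and V2 is the sire-side male X (a two-way
# gamete of E and F).
precc_x8_init <- function(r, class = c("A", "C", "E")) {
  class <- match.arg(class)
  # V1 and V1' are two gametes from the same four-way dam (X diplotype
  # {gam(A,B), intact C}); for a founder of the recombining pair they are
  # conditionally independent given her realized two-way gamete h, so the
  # joint law mixes over h.  For the intact-C founder the conditional
  # gamete law does not depend on h, and for the sire-side pair only V2
  # (a single two-way gamete) carries the founder, so no mixing is needed.
  dV1_C <- c((1 - r) / 2, r / 2, r / 2, (1 - r) / 2)
  d2way <- c((1 - r) / 2, r / 2, r / 2, (1 - r) / 2)
  delta <- function(h) { d <- numeric(4); d[h + 1] <- 1; d }
  prod3 <- function(dfm, dfp, dmh) {
    d <- numeric(64)
    for (fm in 0:3) for (fp in 0:3) for (mh in 0:3)
      d[fm + 4 * fp + 16 * mh + 1] <-
        dfm[fm + 1] * dfp[fp + 1] * dmh[mh + 1]
    d
  }
  if (class == "A") {
    g <- funnel4_cond_dists(r)
    p <- funnel4_h_probs(r)
    d <- numeric(64)
    for (h in names(g))
      d <- d + p[[h]] * prod3(g[[h]], delta(0), g[[h]])
    return(d)
  }
  if (class == "C") return(prod3(dV1_C, delta(0), dV1_C))
  prod3(delta(0), d2way, delta(0))
}

# run the X chain for one class to every generation in `ks` and report the
# three parental probabilities needed downstream (one row per statistic)
precc_x8_class_stats <- function(ks, r, class) {
  d <- precc_x8_init(r, class)
  G <- gamete_dist16(r)
  st <- 0:63
  fm <- st %% 4; fp <- (st %/% 4) %% 4; mh <- st %/% 16
  gf_par <- G[fm + 4 * fp + 1, 4]
  grab <- function(d) c(damgam = sum(d * gf_par),
                        malehap = sum(d * (mh == 3)),
                        femhap = sum(d * ((fm == 3) + (fp == 3)) / 2))
  kmax <- max(ks)
  out <- matrix(0, 3, kmax, dimnames = list(names(grab(d)), NULL))
  out[, 1] <- grab(d)
  if (kmax > 1L) {
    T <- sib_transition_x(r)
    for (i in 2:kmax) {
      d <- as.vector(d %*% T)
      out[, i] <- grab(d)
    }
  }
  out[, ks, drop = FALSE]
}

# total (over all eight founders) parental-haplotype probabilities for the
# pre-CC X at G2:F_k, for each k in `ks`: class multiplicities 2 (A-like),
# 1 (C-like), 2 (E-like)
precc_x8_stats <- function(ks, r) {
  for (ki in ks) check_generation(ki, what = "k")
  ks <- as.integer(ks)
  stopifnot(length(r) == 1L)
  check_recfrac(r)
  tot <- 2 * precc_x8_class_stats(ks, r, "A") +
    precc_x8_class_stats(ks, r, "C") +
    2 * precc_x8_class_stats(ks, r, "E")
  list(damgam = unname(tot["damgam", ]),
       malehap = unname(tot["malehap", ]),
       femhap = unname(tot["femhap", ]))
}

#' X-linked haplotype frequencies in four-way RIL by sib mating
#'
#' Frequencies h^AA_k and h^CC_k of the AA and CC haplotypes on the X
#' chromosome in females at generation G1:F_k of four-way recombinant
#' inbred line construction by sibling mating (cross (A x B) dam by
#' (C x D) sire, so the G1:F1 female carries a recombined A/B maternal X
#' and an intact C paternal X; founder D contributes no X).  These are the
#' four-way ingredients from which DO/HS X-chromosome initial values are
#' assembled.
#'
#' @param k Generation (integer >= 1).
#' @param r A single recombination fraction.
#' @return Named numeric vector `c(hAA = , hCC = )`.
#' @examples
#' precc_x_freqs(1, 0.1)   # hAA = (1-r)/4, hCC = 1/2
#' @export
precc_x_freqs <- function(k, r) {
  k <- check_generation(k, what = "k")
  stopifnot(length(r) == 1L)
  check_recfrac(r)
  d2way <- c((1 - r) / 2, r / 2, r / 2, (1 - r) / 2)
  delta <- function(h) { d <- numeric(4); d[h + 1] <- 1; d }
  mk_init <- function(dists) {
    d <- numeric(64)
    for (fm in 0:3) for (fp in 0:3) for (mh in 0:3)
      d[fm + 4 * fp + 16 * mh + 1] <-
        dists$fm[fm + 1] * dists$fp[fp + 1] * dists$mh[mh + 1]
    d
  }
  run <- function(dists) {
    d <- mk_init(dists)
    if (k > 1L) {
      T <- sib_transition_x(r)
      for (i in seq_len(k - 1L)) d <- as.vector(d %*% T)
    }
    st <- 0:63
    fm <- st %% 4; fp <- (st %/% 4) %% 4
    sum(d * ((fm == 3) + (fp == 3)) / 2)
  }
  hAA <- run(list(fm = d2way, fp = delta(0), mh = d2way))
  hCC <- run(list(fm = delta(0), fp = delta(3), mh = delta(0)))
  c(hAA = hAA, hCC = hCC)
}
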