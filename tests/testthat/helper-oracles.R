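# Independent oracles used by the test suite.  These re-derive pre-CC
# quantities by different routes than the package implementation: a
# finer-partition two-founder chain (checks the exactness of the
# single-founder indicator lumping) and an exact labeled-haplotype
# enumeration of the small X pedigree.

# ---- finer lumping: track TWO founders jointly on the autosome ---------
# Alleles carry one of three classes per locus: 1 = founder A (dam-side
# recombining pair), 2 = founder E (sire-side recombining pair), 0 =
# anything else.  Haplotype code h = v1 + 3 v2 (9 values); individual
# i = h_m + 9 h_p (81); sib pair = i1 + 81 i2 (6561).  If the coarse
# single-founder lumping is exact, the A-marginal of this finer chain must
# reproduce precc_autosome_q().
dual_gamete_dist <- function(r) {
  G <- matrix(0, 81, 9)
  for (h1 in 0:8) for (h2 in 0:8) {
    gd <- numeric(9)
    rec12 <- (h1 %% 3) + 3 * (h2 %/% 3)
    rec21 <- (h2 %% 3) + 3 * (h1 %/% 3)
    gd[h1 + 1] <- gd[h1 + 1] + 0.5 * (1 - r)
    gd[h2 + 1] <- gd[h2 + 1] + 0.5 * (1 - r)
    gd[rec12 + 1] <- gd[rec12 + 1] + 0.5 * r
    gd[rec21 + 1] <- gd[rec21 + 1] + 0.5 * r
    G[h1 + 9 * h2 + 1, ] <- gd
  }
  G
}

# conditional class-coded gamete law of a four-way gamete given the
# realized two-way gamete h of the arm carrying the tracked founder;
# `cls` is the class label (1 for A, 2 for E)
dual_cond <- function(r, cls) {
  enc <- function(v1, v2) v1 * cls + 3 * v2 * cls
  base <- list(AA = c((1 - r) / 2, r / 2, r / 2, (1 - r) / 2),
               BB = c(1, 0, 0, 0),
               AB = c(0.5, 0.5, 0, 0),
               BA = c(0.5, 0, 0.5, 0))
  lapply(base, function(p4) {
    d <- numeric(9)
    d[enc(0, 0) + 1] <- d[enc(0, 0) + 1] + p4[1]
    d[enc(1, 0) + 1] <- d[enc(1, 0) + 1] + p4[2]
    d[enc(0, 1) + 1] <- d[enc(0, 1) + 1] + p4[3]
    d[enc(1, 1) + 1] <- d[enc(1, 1) + 1] + p4[4]
    d
  })
}

dual_h_probs <- function(r) c(AA = (1 - r) / 2, BB = (1 - r) / 2,
                              AB = r / 2, BA = r / 2)

# initial 6561-state pair distribution: both siblings share the dam-side
# two-way gamete hA (A material, maternal haplotype) and the sire-side
# two-way gamete hE (E material, paternal haplotype)
dual_init <- function(r) {
  gA <- dual_cond(r, 1L)
  gE <- dual_cond(r, 2L)
  p <- dual_h_probs(r)
  d <- numeric(6561)
  for (hA in names(gA)) for (hE in names(gE)) {
    ind <- as.vector(outer(gA[[hA]], gE[[hE]]))   # i = h_m + 9 h_p
    d <- d + p[[hA]] * p[[hE]] * as.vector(outer(ind, ind))
  }
  d
}

# one sib-mating step of the finer chain (sparse accumulation)
dual_step <- function(d, r) {
  G <- dual_gamete_dist(r)
  out <- numeric(6561)
  nz <- which(d > 0)
  for (sidx in nz) {
    s <- sidx - 1L
    i1 <- s %% 81; i2 <- s %/% 81
    child <- as.vector(outer(G[i1 + 1, ], G[i2 + 1, ]))
    out <- out + d[sidx] * as.vector(outer(child, child))
  }
  out
}

# frequency of the intact founder-A (class 1) haplotype at G2:F_k
dual_qA <- function(k, r) {
  d <- dual_init(r)
  if (k > 1L) for (i in seq_len(k - 1L)) d <- dual_step(d, r)
  st <- 0:6560
  i1 <- st %% 81; i2 <- st %/% 81
  haps <- cbind(i1 %% 9, i1 %/% 9, i2 %% 9, i2 %/% 9)
  cntA <- rowSums(haps == 4)   # code 1 + 3*1 = AA for class 1
  cntE <- rowSums(haps == 8)   # code 2 + 3*2 = EE for class 2
  c(A = sum(d * cntA) / 4, E = sum(d * cntE) / 4)
}

# ---- exact labeled enumeration of the eight-way X pedigree, k <= 2 -----
# Haplotypes carry founder labels; gout() enumerates the four gamete
# outcomes of one meiosis with their probabilities.
enum_gout <- function(h1, h2, r) list(
  list(h = h1, p = (1 - r) / 2), list(h = h2, p = (1 - r) / 2),
  list(h = c(h1[1], h2[2]), p = r / 2), list(h = c(h2[1], h1[2]), p = r / 2))

enum_x8_stats <- function(k, r) {
  stopifnot(k %in% 1:2)
  par_ <- function(h) as.numeric(h[1] == h[2])
  damgam <- malehap <- femhap <- 0
  for (g12 in enum_gout(c(1, 1), c(2, 2), r))
    for (v1 in enum_gout(g12$h, c(3, 3), r))
      for (v1p in enum_gout(g12$h, c(3, 3), r))
        for (v2 in enum_gout(c(5, 5), c(6, 6), r)) {
          p0 <- g12$p * v1$p * v1p$p * v2$p
          if (k == 1L) {
            fh <- (par_(v1$h) + par_(v2$h)) / 2
            femhap <- femhap + p0 * fh
            malehap <- malehap + p0 * par_(v1p$h)
            for (g in enum_gout(v1$h, v2$h, r))
              damgam <- damgam + p0 * g$p * par_(g$h)
          } else {
            for (ga in enum_gout(v1$h, v2$h, r)) {
              # G2:F2 female = (ga, v1p); male = an independent gamete
              # with the same conditional law as ga
              p1 <- p0 * ga$p
              malehap <- malehap + p1 * par_(ga$h)
              femhap <- femhap + p1 * (par_(ga$h) + par_(v1p$h)) / 2
              for (fin in enum_gout(ga$h, v1p$h, r))
                damgam <- damgam + p1 * fin$p * par_(fin$h)
            }
          }
        }
  list(damgam = damgam, malehap = malehap, femhap = femhap)
}

# tolerance used for "machine precision" comparisons
tol12 <- 1e-12
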