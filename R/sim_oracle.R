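# Independent verification paths for the analytic results:
#  * propagate_exact(): deterministic infinite-population recursion over
#    full haplotype tables, written independently of the scalar
#    recurrences (the core defense against transcription errors in the
#    recurrence algebra);
#  * simulate_freqs(): forward Monte-Carlo of the actual breeding designs
#    with labeled founders (also exercises the funnel structure and the
#    lumped pre-CC chains, which the table propagator shares).

# one random-mating gamete-table update (autosome): a gamete from an
# individual whose two haplotypes are independent draws from table T
random_mating_step <- function(T, r) {
  (1 - r) * T + r * outer(rowSums(T), colSums(T))
}

# gamete table from females whose maternal haplotype ~ matT and paternal
# haplotype ~ patT (independent)
x_gamete_step <- function(matT, patT, r) {
  (1 - r) * (matT + patT) / 2 +
    r * (outer(rowSums(matT), colSums(patT)) +
         outer(rowSums(patT), colSums(matT))) / 2
}

diag_table <- function(p_diag, n) symmetric_table(p_diag, n)

#' Exact infinite-population haplotype-table propagation
#'
#' Propagates the full two-locus haplotype-frequency table (2 x 2 or 8 x 8)
#' generation by generation under the infinite-population random-mating
#' assumptions, as an independent code path from the scalar AA-frequency
#' recurrences.  The F1 generation of an AIL is handled exactly (its two
#' haplotypes are perfectly anticorrelated); from generation 2 on, the two
#' haplotypes of an individual are independent draws.
#'
#' @inheritParams transition_matrix
#' @return For the autosome, a [hap_freq_table()]; for the X, a list with
#'   components `female` and `male`.
#' @examples
#' propagate_exact("AIL2", "autosome", s = 12, r = 0.01)
#' @export
propagate_exact <- function(design, chromosome = "autosome",
                            balance = "balanced", s, r, alpha = NULL) {
  pars <- validate_params(design, chromosome, balance, s, r, alpha)
  stopifnot(length(r) == 1L)
  s <- pars$s
  n <- if (pars$design == "AIL2") 2L else 8L

  if (pars$chromosome == "autosome") {
    if (pars$design == "AIL2") {
      if (s == 1L) return(hap_freq_table(diag_table(0.5, 2L),
                                         design = "AIL2", s = s, r = r))
      T <- diag_table((1 - r) / 2, 2L)     # exact F1-female/male gamete
      if (s > 2L) for (i in 3:s) T <- random_mating_step(T, r)
    } else {
      alpha <- pars$alpha
      ks <- as.integer(names(alpha))
      p1 <- sum(alpha * precc_autosome_q(ks + 1L, r))
      T <- diag_table(p1, 8L)              # gen-1 haplotypes independent
      if (s > 1L) for (i in 2:s) T <- random_mating_step(T, r)
    }
    return(hap_freq_table(T, design = pars$design, s = s, r = r))
  }

  # X chromosome: track the female's maternal- and paternal-haplotype
  # tables separately plus the male haplotype table
  if (pars$design == "AIL2") {
    male1 <- if (pars$balance == "balanced") diag_table(0.5, 2L)
             else matrix(c(1, 0, 0, 0), 2, 2,
                         dimnames = list(locus1 = .founders2,
                                         locus2 = .founders2))
    if (s == 1L) {
      fem <- diag_table(0.5, 2L)           # F1 female carries AA and BB
      return(list(female = hap_freq_table(fem, sex = "female",
                                          design = pars$design, s = s, r = r),
                  male = hap_freq_table(male1, sex = "male",
                                        design = pars$design, s = s, r = r)))
    }
    gam <- diag_table((1 - r) / 2, 2L)     # exact F1-female gamete
    fem_mat <- gam; fem_pat <- male1; male <- gam
    gens_left <- s - 2L
  } else {
    init <- do_x_init(pars$alpha, r)
    fem_mat <- diag_table(init[["m1"]], 8L)              # pre-CC dam gamete
    fem_pat <- diag_table(2 * init[["f1"]] - init[["m1"]], 8L)  # sire's X
    male <- fem_mat
    gens_left <- s - 1L
  }
  if (gens_left > 0L) for (i in seq_len(gens_left)) {
    gam <- x_gamete_step(fem_mat, fem_pat, r)
    fem_pat <- male
    fem_mat <- gam
    male <- gam
  }
  list(female = hap_freq_table((fem_mat + fem_pat) / 2, sex = "female",
                               design = pars$design, s = s, r = r),
       male = hap_freq_table(male, sex = "male",
                             design = pars$design, s = s, r = r))
}

# --- Monte-Carlo forward simulation --------------------------------------

# vectorized two-locus meiosis: h1, h2 are lists with integer vectors l1,
# l2 (founder labels); returns one gamete per element
gamv <- function(h1, h2, r) {
  n <- length(h1$l1)
  u <- stats::runif(n) < 0.5
  sw <- stats::runif(n) < r
  l1 <- h2$l1; l1[u] <- h1$l1[u]
  keep <- xor(u, sw)
  l2 <- h2$l2; l2[keep] <- h1$l2[keep]
  list(l1 = l1, l2 = l2)
}

hap_const <- function(f, n) list(l1 = rep.int(f, n), l2 = rep.int(f, n))
hap_pick <- function(h, idx) list(l1 = h$l1[idx], l2 = h$l2[idx])

# sample pre-CC generations for n lines (safe for length-1 k sets)
sample_k <- function(ks, n, prob) ks[sample.int(length(ks), n,
                                                replace = TRUE, prob = prob)]

# all permutations of 1:8, cached (used to randomize funnel orders)
perm8 <- local({
  tab <- NULL
  gen <- function(n) {
    if (n == 1L) return(matrix(1L))
    p <- gen(n - 1L)
    do.call(rbind, lapply(1:n, function(i) {
      q <- p; q[q >= i] <- q[q >= i] + 1L
      cbind(rep.int(i, nrow(p)), q)
    }))
  }
  function() {
    if (is.null(tab)) tab <<- gen(8L)
    tab
  }
})

# simulate n_lines independent pre-CC lines to generation G2:F_k (k may
# vary by line) and return the material needed to found HS/DO generation 1
sim_precc_lines <- function(n_lines, k_by_line, r, chromosome) {
  P <- perm8()[sample.int(nrow(perm8()), n_lines, replace = TRUE), ,
               drop = FALSE]
  lab <- function(pos) list(l1 = P[, pos], l2 = P[, pos])
  kmax <- max(k_by_line)
  if (chromosome == "autosome") {
    # funnel: two-way, four-way, eight-way.  The G2:F1 sib pair shares one
    # four-way dam and one four-way sire, so both siblings' haplotypes are
    # independent meioses from the same two G2 diplotypes.
    g2dam <- list(h1 = gamv(lab(1), lab(2), r), h2 = gamv(lab(3), lab(4), r))
    g2sire <- list(h1 = gamv(lab(5), lab(6), r), h2 = gamv(lab(7), lab(8), r))
    dam <- list(h1 = gamv(g2dam$h1, g2dam$h2, r),
                h2 = gamv(g2sire$h1, g2sire$h2, r))
    sire <- list(h1 = gamv(g2dam$h1, g2dam$h2, r),
                 h2 = gamv(g2sire$h1, g2sire$h2, r))
    out_dam <- dam
    snapshot <- function(cur, out, sel) {
      out$h1$l1[sel] <- cur$h1$l1[sel]; out$h1$l2[sel] <- cur$h1$l2[sel]
      out$h2$l1[sel] <- cur$h2$l1[sel]; out$h2$l2[sel] <- cur$h2$l2[sel]
      out
    }
    if (kmax > 1L) for (t in 2:kmax) {
      dam_new <- list(h1 = gamv(dam$h1, dam$h2, r),
                      h2 = gamv(sire$h1, sire$h2, r))
      sire_new <- list(h1 = gamv(dam$h1, dam$h2, r),
                       h2 = gamv(sire$h1, sire$h2, r))
      dam <- dam_new; sire <- sire_new
      sel <- k_by_line == t
      out_dam <- snapshot(dam, out_dam, sel)
    }
    # transmitted gamete from the progenitor (the dam of the final pair)
    return(gamv(out_dam$h1, out_dam$h2, r))
  }
  # X chromosome: female carries (V1, V2); male carries V1'
  g2fem <- list(h1 = gamv(lab(1), lab(2), r), h2 = lab(3))  # four-way dam
  V1 <- gamv(g2fem$h1, g2fem$h2, r)
  V1p <- gamv(g2fem$h1, g2fem$h2, r)
  V2 <- gamv(lab(5), lab(6), r)                             # sire-side X
  fem <- list(h1 = V1, h2 = V2)
  malex <- V1p
  out_fem <- fem; out_male <- malex
  snap_hap <- function(cur, out, sel) {
    out$l1[sel] <- cur$l1[sel]; out$l2[sel] <- cur$l2[sel]; out
  }
  if (kmax > 1L) for (t in 2:kmax) {
    fem_new <- list(h1 = gamv(fem$h1, fem$h2, r), h2 = malex)
    male_new <- gamv(fem$h1, fem$h2, r)
    fem <- fem_new; malex <- male_new
    sel <- k_by_line == t
    out_fem$h1 <- snap_hap(fem$h1, out_fem$h1, sel)
    out_fem$h2 <- snap_hap(fem$h2, out_fem$h2, sel)
    out_male <- snap_hap(malex, out_male, sel)
  }
  list(female = out_fem, male = out_male)
}

# tabulate haplotype frequencies into an n x n matrix
tab_freq <- function(hap, n_founders) {
  labs <- if (n_founders == 2L) .founders2 else .founders8
  counts <- matrix(0, n_founders, n_founders,
                   dimnames = list(locus1 = labs, locus2 = labs))
  t0 <- table(factor(hap$l1, levels = 1:n_founders),
              factor(hap$l2, levels = 1:n_founders))
  counts[] <- as.numeric(t0)
  counts / length(hap$l1)
}

#' Forward Monte-Carlo simulation of the breeding designs
#'
#' Simulates the full breeding design with labeled founders -- founder
#' funnels with randomized cross orders, pre-CC sibling mating, and the
#' random-mating outcross generations -- and tabulates the two-locus
#' haplotype frequencies at generation s.  Per gamete, the two-locus
#' meiosis picks the locus-1 haplotype uniformly and keeps the same
#' haplotype at locus 2 with probability 1 - r.  Serves as the brute-force
#' oracle for every analytic result in the package.
#'
#' The gametes are split across `n_replicates` independent populations.
#' Within one finite population the final haplotypes share ancestors, so
#' their frequencies fluctuate more than binomially (genetic drift);
#' averaging independent replicates both restores independence between
#' replicate means and allows the standard error to be estimated
#' empirically from their spread.  The reported `se_parental` is the
#' larger of that empirical standard error and the binomial one.
#'
#' @inheritParams transition_matrix
#' @param n_gametes Total number of haplotypes tabulated at generation s
#'   (>= 1000).
#' @param seed Integer random seed (results are reproducible given the
#'   seed).
#' @param n_replicates Number of independent populations simulated.
#' @return A list with components `freq` (for the autosome a single
#'   frequency matrix; for the X a list `female`/`male`), `n` (haplotypes
#'   per table), `parental` (total intact-founder-haplotype frequency per
#'   table), and `se_parental` (standard error of `parental`).
#' @examples
#' sim <- simulate_freqs("AIL2", "autosome", s = 5, r = 0.1,
#'                       n_gametes = 2000, seed = 1)
#' sim$parental
#' @export
simulate_freqs <- function(design, chromosome = "autosome",
                           balance = "balanced", s, r, alpha = NULL,
                           n_gametes = 200000L, seed = 1L,
                           n_replicates = 16L) {
  pars <- validate_params(design, chromosome, balance, s, r, alpha)
  stopifnot(length(r) == 1L, n_replicates >= 2L)
  if (n_gametes < 1000L) stop("n_gametes must be >= 1000")
  set.seed(as.integer(seed))
  nf <- if (pars$design == "AIL2") 2L else 8L
  n_rep <- ceiling(n_gametes / n_replicates)

  se_est <- function(reps, pooled, n_tot) {
    emp <- stats::sd(reps) / sqrt(length(reps))
    max(emp, sqrt(pooled * (1 - pooled) / n_tot))
  }

  if (pars$chromosome == "autosome") {
    acc <- matrix(0, nf, nf)
    reps <- numeric(n_replicates)
    n_tot <- 0L
    for (b in seq_len(n_replicates)) {
      hap <- sim_population_autosome(pars, r, n_rep)
      fr <- tab_freq(hap, nf)
      acc <- acc + fr * length(hap$l1)
      reps[b] <- sum(diag(fr))
      n_tot <- n_tot + length(hap$l1)
    }
    fr <- acc / n_tot
    dimnames(fr) <- dimnames(tab_freq(list(l1 = 1L, l2 = 1L), nf))
    par_ <- sum(diag(fr))
    return(list(freq = fr, n = n_tot, parental = par_,
                se_parental = se_est(reps, par_, n_tot)))
  }

  acc_f <- acc_m <- matrix(0, nf, nf)
  reps_f <- reps_m <- numeric(n_replicates)
  n_ftot <- n_mtot <- 0L
  for (b in seq_len(n_replicates)) {
    popx <- sim_population_x(pars, r, n_rep)
    fr_f <- tab_freq(popx$female, nf)
    fr_m <- tab_freq(popx$male, nf)
    acc_f <- acc_f + fr_f * length(popx$female$l1)
    acc_m <- acc_m + fr_m * length(popx$male$l1)
    reps_f[b] <- sum(diag(fr_f)); reps_m[b] <- sum(diag(fr_m))
    n_ftot <- n_ftot + length(popx$female$l1)
    n_mtot <- n_mtot + length(popx$male$l1)
  }
  fr_f <- acc_f / n_ftot; fr_m <- acc_m / n_mtot
  dn <- dimnames(tab_freq(list(l1 = 1L, l2 = 1L), nf))
  dimnames(fr_f) <- dimnames(fr_m) <- dn
  pf <- sum(diag(fr_f)); pm <- sum(diag(fr_m))
  list(freq = list(female = fr_f, male = fr_m),
       n = c(female = n_ftot, male = n_mtot),
       parental = c(female = pf, male = pm),
       se_parental = c(female = se_est(reps_f, pf, n_ftot),
                       male = se_est(reps_m, pm, n_mtot)))
}

# one finite random-mating population on the autosome; returns the final
# generation's haplotypes (labels)
sim_population_autosome <- function(pars, r, n_gametes) {
  s <- pars$s
  n_ind <- ceiling(n_gametes / 2)
  if (pars$design == "AIL2") {
    pop <- list(h1 = hap_const(1L, n_ind), h2 = hap_const(2L, n_ind))
  } else {
    ks <- as.integer(names(pars$alpha))
    pop <- list(h1 = sim_precc_lines(n_ind, sample_k(ks, n_ind, pars$alpha),
                                     r, "autosome"),
                h2 = sim_precc_lines(n_ind, sample_k(ks, n_ind, pars$alpha),
                                     r, "autosome"))
  }
  if (s > 1L) for (g in 2:s) {
    i1 <- sample.int(n_ind, n_ind, replace = TRUE)
    i2 <- sample.int(n_ind, n_ind, replace = TRUE)
    pop <- list(h1 = gamv(hap_pick(pop$h1, i1), hap_pick(pop$h2, i1), r),
                h2 = gamv(hap_pick(pop$h1, i2), hap_pick(pop$h2, i2), r))
  }
  list(l1 = c(pop$h1$l1, pop$h2$l1), l2 = c(pop$h1$l2, pop$h2$l2))
}

# one finite random-mating population on the X (balanced sexes); returns
# the final female haplotypes and male haplotypes
sim_population_x <- function(pars, r, n_gametes) {
  s <- pars$s
  n_f <- max(2L, ceiling(n_gametes / 3))
  n_m <- n_f
  if (pars$design == "AIL2") {
    femp <- list(h1 = hap_const(1L, n_f), h2 = hap_const(2L, n_f))
    malep <- if (pars$balance == "unbalanced") hap_const(1L, n_m)
             else list(l1 = rep(1:2, length.out = n_m),
                       l2 = rep(1:2, length.out = n_m))
  } else {
    ks <- as.integer(names(pars$alpha))
    dams1 <- sim_precc_lines(n_f, sample_k(ks, n_f, pars$alpha), r, "X")
    sires <- sim_precc_lines(n_f, sample_k(ks, n_f, pars$alpha), r, "X")
    damsm <- sim_precc_lines(n_m, sample_k(ks, n_m, pars$alpha), r, "X")
    femp <- list(h1 = gamv(dams1$female$h1, dams1$female$h2, r),
                 h2 = sires$male)
    malep <- gamv(damsm$female$h1, damsm$female$h2, r)
  }
  if (s > 1L) for (g in 2:s) {
    im <- sample.int(n_f, n_f, replace = TRUE)   # dams of new females
    ip <- sample.int(n_m, n_f, replace = TRUE)   # sires of new females
    ib <- sample.int(n_f, n_m, replace = TRUE)   # dams of new males
    femp_new <- list(h1 = gamv(hap_pick(femp$h1, im),
                               hap_pick(femp$h2, im), r),
                     h2 = hap_pick(malep, ip))
    malep <- gamv(hap_pick(femp$h1, ib), hap_pick(femp$h2, ib), r)
    femp <- femp_new
  }
  list(female = list(l1 = c(femp$h1$l1, femp$h2$l1),
                     l2 = c(femp$h1$l2, femp$h2$l2)),
       male = malep)
}
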