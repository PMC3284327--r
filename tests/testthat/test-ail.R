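test_that("AIL autosome AA frequency matches exact small-s derivations", {
  # F1 haplotypes intact at r = 0
  expect_equal(ail_autosome_AA(5, 0), 0.5)
  # one exact meiosis beyond the F1: p_2 = (1-r)/2
  expect_equal(ail_autosome_AA(2, 0.1), 0.45)
  expect_equal(ail_autosome_AA(2, 0.3), 0.35)
  # iterate the recurrence by hand from the exact p_2 (independent loop)
  p <- (1 - 0.01) / 2
  for (i in 1:10) p <- (1 - 0.01) * p + 0.01 / 4
  expect_equal(ail_autosome_AA(12, 0.01), p, tolerance = 1e-15)
  expect_equal(p, 0.4715736, tolerance = 1e-7)
})

test_that("AIL autosome recombinant frequency behaves as 1 - 2 p_s", {
  expect_equal(ail_autosome_recombinant(12, 0), 0)
  r_grid <- seq(0, 0.5, by = 0.01)
  # at s = 2 the recombinant frequency is exactly r (one meiosis from F1)
  expect_equal(ail_autosome_recombinant(2, r_grid), r_grid,
               tolerance = 1e-15)
  # monotone non-decreasing in s and r; stationary limit 1/2
  for (s in c(2, 5, 9)) {
    expect_true(all(diff(ail_autosome_recombinant(s, r_grid)) >= 0))
    expect_true(all(ail_autosome_recombinant(s + 1, r_grid) >=
                      ail_autosome_recombinant(s, r_grid)))
  }
  expect_equal(ail_autosome_recombinant(2000, 0.25), 0.5, tolerance = 1e-10)
})

test_that("closed forms solve the recurrences on a dense (s, r) grid", {
  r_grid <- seq(0, 0.5, by = 0.025)
  for (s in 2:50) {
    expect_equal(ail_autosome_AA(s, r_grid),
                 ail_autosome_AA(s, r_grid, method = "closed_form"),
                 tolerance = 1e-12)
    for (sex in c("male", "female"))
      expect_equal(ail_balancedX_AA(s, r_grid, sex),
                   ail_balancedX_AA(s, r_grid, sex, "closed_form"),
                   tolerance = 1e-12)
  }
})

test_that("eigen-quantities reproduce the X recurrence matrix spectrum", {
  r <- seq(0, 0.5, by = 0.05)
  e <- x_eigen_coefficients(r)
  expect_equal(e$w + e$y, (1 - r) / 2, tolerance = 1e-14)
  expect_equal(e$w * e$y, -(1 - r) / 2, tolerance = 1e-14)
  expect_true(all(e$z >= 0))
  # against an explicit eigendecomposition of [[0, 1-r], [1/2, (1-r)/2]]
  for (ri in c(0.07, 0.33)) {
    ev <- eigen(matrix(c(0, 0.5, 1 - ri, (1 - ri) / 2), 2, 2))$values
    ec <- x_eigen_coefficients(ri)
    expect_equal(sort(ev), sort(c(ec$w, ec$y)), tolerance = 1e-12)
  }
})

test_that("balanced X AA frequencies match exact small-s derivations", {
  expect_equal(ail_balancedX_AA(3, 0, "female"), 0.5)
  # exact F1 -> F2: the F1 female carries (AA, BB), so her recombinant
  # gametes are never AA: m_2 = (1-r)/2, f_2 = (m_1 + (1-r)/2)/2
  expect_equal(ail_balancedX_AA(2, 0.1, "male"), 0.45)
  expect_equal(ail_balancedX_AA(2, 0.1, "female"), 0.475)
  # one recurrence step beyond the exact anchor, by hand
  r <- 0.2
  m3 <- (1 - r) * (2 - r) / 4 + r / 4
  f3 <- 0.5 * (1 - r) / 2 + 0.5 * (1 - r) * (2 - r) / 4 + r / 8
  expect_equal(ail_balancedX_AA(3, r, "male"), m3, tolerance = 1e-14)
  expect_equal(ail_balancedX_AA(3, r, "female"), f3, tolerance = 1e-14)
  # convergence to 1/4 for r > 0
  expect_equal(ail_balancedX_AA(1000, 0.1, "male"), 0.25,
               tolerance = 1e-10)
  expect_equal(ail_balancedX_AA(1000, 0.1, "female"), 0.25,
               tolerance = 1e-10)
})

test_that("balanced X recombinant frequencies use the 2/3 female weight", {
  for (r in c(0.05, 0.2)) for (s in c(2, 6)) {
    m <- ail_balancedX_recombinant(s, r, "male")
    f <- ail_balancedX_recombinant(s, r, "female")
    expect_equal(ail_balancedX_recombinant(s, r, "overall"),
                 m / 3 + 2 * f / 3, tolerance = 1e-14)
  }
  expect_equal(ail_balancedX_recombinant(7, 0, "overall"), 0)
  # a male X at s = 2 is one female meiosis from the F1: recombinant = r
  expect_equal(ail_balancedX_recombinant(2, 0.1, "male"), 0.1,
               tolerance = 1e-14)
})

test_that("unbalanced X allele frequency follows its recurrence and limit", {
  expect_equal(unbalanced_allele_freq(-1), 0)
  expect_equal(unbalanced_allele_freq(0), 1)
  expect_equal(unbalanced_allele_freq(1), 0.5)
  expect_equal(unbalanced_allele_freq(2), 0.75)
  for (s in 0:30)
    expect_equal(unbalanced_allele_freq(s),
                 unbalanced_allele_freq(s, method = "recurrence"),
                 tolerance = 1e-14)
  expect_equal(unbalanced_allele_freq(40), 2 / 3, tolerance = 1e-12)
})

test_that("unbalanced X haplotype frequencies match exact derivations", {
  # all F1 males hemizygous A
  expect_equal(ail_unbalancedX_AA(1, 0.3, "male"), 1)
  expect_equal(ail_unbalancedX_AA(1, 0.3, "female"), 0.5)
  # F1 female is (AA, BB): her non-recombinant AA gamete has prob (1-r)/2
  expect_equal(ail_unbalancedX_AA(2, 0.2, "male"), 0.4)
  # female tables at s = 1 and male tables at s = 2
  t1f <- ail_unbalancedX_table(1, 0.3, "female")
  expect_equal(unclass(t1f)[], matrix(c(0.5, 0, 0, 0.5), 2, 2),
               ignore_attr = TRUE)
  t1m <- ail_unbalancedX_table(1, 0.3, "male")
  expect_equal(unname(t1m[1, 1]), 1)
  t2m <- ail_unbalancedX_table(2, 0.2, "male")
  expect_equal(as.vector(unclass(t2m)), c(0.4, 0.1, 0.1, 0.4))
  # tables remain proper distributions with the right marginals
  for (s in c(1, 3, 8)) for (r in c(0, 0.25, 0.5))
    for (sex in c("male", "female")) {
      tab <- ail_unbalancedX_table(s, r, sex)
      expect_true(all(tab >= 0))
      expect_equal(sum(tab), 1, tolerance = 1e-12)
      q <- unbalanced_allele_freq(if (sex == "male") s - 1 else s)
      expect_equal(unname(locus_marginals(tab, 1)), c(q, 1 - q),
                   tolerance = 1e-12)
    }
})

test_that("unbalanced X frequencies converge to 4/9 in both sexes", {
  expect_equal(ail_unbalancedX_AA(1000, 0.1, "female"), 4 / 9,
               tolerance = 1e-10)
  expect_equal(ail_unbalancedX_AA(1000, 0.1, "male"), 4 / 9,
               tolerance = 1e-10)
  # and the overall recombinant weighting is 1/3 male + 2/3 female
  for (s in c(2, 5)) {
    m <- ail_unbalancedX_recombinant(s, 0.2, "male")
    f <- ail_unbalancedX_recombinant(s, 0.2, "female")
    expect_equal(ail_unbalancedX_recombinant(s, 0.2, "overall"),
                 m / 3 + 2 * f / 3, tolerance = 1e-14)
  }
})
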