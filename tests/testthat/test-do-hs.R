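test_that("DO/HS autosomal AA frequency follows the alpha-weighted chain", {
  expect_equal(do_autosome_AA(1, 0, example_alpha()), 0.125)
  expect_equal(do_autosome_AA(1, 0, hs_alpha()), 0.125)
  # HS: p_1 = q_2 = (1-r)^3/8, then nine recurrence steps (independent loop)
  r <- 0.01
  p <- (1 - r)^3 / 8
  for (i in 1:9) p <- (1 - r) * p + r / 64
  expect_equal(do_autosome_AA(10, r, hs_alpha()), p, tolerance = 1e-15)
  expect_equal(p, 0.1121495, tolerance = 1e-5)
  # stationary limit 1/64
  expect_equal(do_autosome_AA(2000, 0.25, example_alpha()), 1 / 64,
               tolerance = 1e-12)
})

test_that("DO closed form (geometric decay to 1/64) equals the recurrence", {
  for (al in list(hs_alpha(), example_alpha()))
    for (r in seq(0, 0.5, by = 0.05)) for (s in c(1, 2, 5, 10, 25))
      expect_equal(do_autosome_AA(s, r, al),
                   do_autosome_AA(s, r, al, method = "closed_form"),
                   tolerance = 1e-14)
})

test_that("DO autosomal table spreads recombinants uniformly over 56 cells", {
  t0 <- do_autosome_table(1, 0, hs_alpha())
  expect_equal(diag(unclass(t0)), rep(1 / 8, 8), ignore_attr = TRUE)
  expect_equal(sum(unclass(t0)) - sum(diag(unclass(t0))), 0)
  tt <- do_autosome_table(10, 0.01, hs_alpha())
  off <- unclass(tt)[row(tt) != col(tt)]
  expect_equal(length(unique(round(off, 15))), 1L)
  expect_equal(off[1], do_recombinant(10, 0.01, hs_alpha()) / 56,
               tolerance = 1e-14)
  tinf <- do_autosome_table(2000, 0.3, example_alpha())
  expect_equal(as.vector(unclass(tinf)), rep(1 / 64, 64), tolerance = 1e-12)
})

test_that("HS recombinant frequency reproduces 0.103 at s = 10, r = 0.01", {
  expect_equal(round(do_recombinant(10, 0.01, hs_alpha()), 3), 0.103)
  expect_equal(do_recombinant(3, 0, hs_alpha()), 0)
  expect_equal(do_recombinant(5000, 0.2, hs_alpha()), 7 / 8,
               tolerance = 1e-12)
  # non-decreasing in s and r
  rg <- seq(0, 0.5, by = 0.05)
  rec5 <- vapply(rg, function(r) do_recombinant(5, r, hs_alpha()),
                 numeric(1))
  rec6 <- vapply(rg, function(r) do_recombinant(6, r, hs_alpha()),
                 numeric(1))
  expect_true(all(diff(rec5) >= 0))
  expect_true(all(rec6 >= rec5))
})

test_that("HS X initial values match the first-principles closed forms", {
  # transmitted-gamete derivation: m1 = (1-r)^2(4-r)/32,
  # f1 = (1-r)(8-7r+r^2)/64; cross-validated by forward simulation and by
  # the exact 2/3 map-expansion ratio
  for (r in c(0, 0.1, 0.3, 0.5)) {
    ini <- do_x_init(hs_alpha(), r)
    expect_equal(ini[["m1"]], (1 - r)^2 * (4 - r) / 32, tolerance = tol12)
    expect_equal(ini[["f1"]], (1 - r) * (8 - 7 * r + r^2) / 64,
                 tolerance = tol12)
  }
  expect_equal(unname(do_x_init(hs_alpha(), 0)), c(0.125, 0.125))
})

test_that("the four-way decomposition of the X initial values is exact", {
  # f_1 = sum_k alpha_k (1/8)[(2-r) h^AA_{k+1} + (1-r) h^CC_{k+1}]:
  # the (2-r)/(1-r) bracket over four-way RIL ingredients reproduces the
  # direct eight-way computation for every progenitor generation
  for (r in c(0.1, 0.3)) for (k in 1:5) {
    f1 <- do_x_init(alpha_distribution(k, 1), r)[["f1"]]
    h <- precc_x_freqs(k + 1, r)
    expect_equal(f1, ((2 - r) * h[["hAA"]] + (1 - r) * h[["hCC"]]) / 8,
                 tolerance = tol12)
  }
})

test_that("DO X recurrence, closed form and fixed point are consistent", {
  # closed form (eigendecomposition) vs recurrence across alphas
  for (al in list(hs_alpha(), example_alpha()))
    for (r in seq(0, 0.5, by = 0.1)) for (s in c(1, 2, 7, 20))
      for (sex in c("male", "female"))
        expect_equal(do_x_AA(s, r, al, sex),
                     do_x_AA(s, r, al, sex, method = "closed_form"),
                     tolerance = 1e-12)
  # s = 1 returns the initial values; one hand recurrence step
  r <- 0.1
  ini <- do_x_init(hs_alpha(), r)
  expect_equal(do_x_AA(1, r, hs_alpha(), "female"), ini[["f1"]])
  expect_equal(do_x_AA(2, r, hs_alpha(), "male"),
               (1 - r) * ini[["f1"]] + r / 64, tolerance = 1e-14)
  # fixed point of the recurrence is 1/64 for r > 0
  expect_equal(do_x_AA(500, 0.2, example_alpha(), "female"), 1 / 64,
               tolerance = 1e-12)
  expect_equal(do_x_AA(500, 0.2, hs_alpha(), "male"), 1 / 64,
               tolerance = 1e-12)
})

test_that("HS is identical to DO with alpha concentrated at k = 1", {
  al <- alpha_distribution(1, 1)
  for (r in c(0.05, 0.4)) for (s in c(1, 4, 9)) {
    expect_identical(do_autosome_AA(s, r, hs_alpha()),
                     do_autosome_AA(s, r, al))
    expect_identical(do_x_AA(s, r, hs_alpha(), "female"),
                     do_x_AA(s, r, al, "female"))
    expect_identical(do_recombinant(s, r, hs_alpha()),
                     do_recombinant(s, r, al))
  }
})

test_that("DO X recombinant frequencies respect the eight-fold symmetry", {
  r <- 0.1
  m2 <- do_x_AA(2, r, hs_alpha(), "male")
  expect_equal(do_x_recombinant(2, r, hs_alpha(), "male"), 1 - 8 * m2,
               tolerance = 1e-14)
  for (s in c(1, 5)) {
    m <- do_x_recombinant(s, r, example_alpha(), "male")
    f <- do_x_recombinant(s, r, example_alpha(), "female")
    expect_equal(do_x_recombinant(s, r, example_alpha(), "overall"),
                 m / 3 + 2 * f / 3, tolerance = 1e-14)
  }
  expect_equal(do_x_recombinant(1, 0, hs_alpha(), "overall"), 0)
  # table route gives the same recombinant mass
  tt <- do_x_table(5, r, example_alpha(), "female")
  expect_equal(1 - sum(diag(unclass(tt))),
               do_x_recombinant(5, r, example_alpha(), "female"),
               tolerance = 1e-12)
})
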