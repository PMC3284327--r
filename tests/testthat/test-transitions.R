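test_that("transition matrices are row-stochastic and non-negative", {
  cases <- list(
    list("AIL2", "autosome", NULL, "balanced"),
    list("AIL2", "X", "male", "balanced"),
    list("AIL2", "X", "female", "unbalanced"),
    list("HS8", "autosome", NULL, "balanced"),
    list("DO8", "X", "female", "balanced"))
  for (cs in cases) for (r in c(0, 0.2, 0.5)) for (s in c(1, 3, 10)) {
    P <- transition_matrix(cs[[1]], cs[[2]], s = s, r = r, sex = cs[[3]],
                           alpha = if (cs[[1]] == "DO8") example_alpha(),
                           balance = cs[[4]])
    expect_true(all(P >= 0))
    expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-12)
  }
})

test_that("zero recombination gives the identity matrix", {
  expect_equal(unclass(transition_matrix("AIL2", "autosome", s = 7, r = 0)),
               diag(2), ignore_attr = TRUE)
  expect_equal(unclass(transition_matrix("DO8", "autosome", s = 4, r = 0,
                                         alpha = example_alpha())),
               diag(8), ignore_attr = TRUE)
  expect_equal(unclass(transition_matrix("AIL2", "X", s = 5, r = 0,
                                         sex = "female",
                                         balance = "unbalanced")),
               diag(2), ignore_attr = TRUE)
})

test_that("DO transition matrix entries are the haplotype-table quotients", {
  P <- transition_matrix("DO8", "autosome", s = 10, r = 0.01,
                         alpha = hs_alpha())
  p10 <- do_autosome_AA(10, 0.01, hs_alpha())
  expect_equal(unname(diag(unclass(P))), rep(8 * p10, 8), tolerance = 1e-12)
  expect_equal(unname(P[1, 2]), (1 - 8 * p10) / 7, tolerance = 1e-12)
  expect_equal(unname(diag(unclass(P))[1]), 0.897, tolerance = 1e-3)
  # balanced matrices are symmetric and doubly stochastic
  expect_equal(unclass(P), t(unclass(P)), ignore_attr = TRUE)
  expect_equal(unname(colSums(P)), rep(1, 8), tolerance = 1e-12)
})

test_that("unbalanced X matrices carry sex-specific initial distributions", {
  P <- transition_matrix("AIL2", "X", s = 2, r = 0.2, sex = "male",
                         balance = "unbalanced")
  expect_equal(unclass(P), matrix(c(0.8, 0.2, 0.2, 0.8), 2, 2),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unname(attr(P, "init")), c(0.5, 0.5), tolerance = 1e-12)
  Pf <- transition_matrix("AIL2", "X", s = 2, r = 0.2, sex = "female",
                          balance = "unbalanced")
  expect_equal(unname(attr(Pf, "init")),
               c(unbalanced_allele_freq(2), 1 - unbalanced_allele_freq(2)),
               tolerance = 1e-12)
  expect_error(transition_matrix("AIL2", "X", s = 2, r = 0.2,
                                 balance = "unbalanced"), "sex")
})

test_that("matrix times locus-1 marginals reconstructs the joint table", {
  for (r in c(0.1, 0.4)) {
    tab <- ail_unbalancedX_table(4, r, "female")
    P <- transition_matrix("AIL2", "X", s = 4, r = r, sex = "female",
                           balance = "unbalanced")
    expect_equal(unclass(P) * attr(P, "init"), unclass(tab),
                 ignore_attr = TRUE, tolerance = 1e-12)
    tab8 <- do_autosome_table(6, r, example_alpha())
    P8 <- transition_matrix("DO8", "autosome", s = 6, r = r,
                            alpha = example_alpha())
    expect_equal(unclass(P8) * attr(P8, "init"), unclass(tab8),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("rows converge to the stationary allele-frequency vector", {
  P <- transition_matrix("HS8", "autosome", s = 3000, r = 0.3)
  for (i in 1:8)
    expect_equal(unname(P[i, ]), rep(1 / 8, 8), tolerance = 1e-10)
  Pu <- transition_matrix("AIL2", "X", s = 2000, r = 0.3, sex = "female",
                          balance = "unbalanced")
  for (i in 1:2)
    expect_equal(unname(Pu[i, ]), c(2 / 3, 1 / 3), tolerance = 1e-8)
})

test_that("diagonal entries decrease with r and interval lists work", {
  rs <- seq(0, 0.5, by = 0.1)
  diags <- vapply(rs, function(r)
    transition_matrix("HS8", "autosome", s = 8, r = r)[1, 1], numeric(1))
  expect_true(all(diff(diags) < 0))
  Ps <- transition_matrices("AIL2", "autosome", s = 5, r = c(0, 0.1, 0.2))
  expect_length(Ps, 3L)
  expect_equal(unname(Ps[[1]][1, 1]), 1)
  expect_equal(attr(Ps[[3]], "r"), 0.2)
})
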