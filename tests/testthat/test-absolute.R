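test_that("banded death rate matches arithmetic and the summation oracle", {
  # two-age toy band: dx = (10, 10), Lx = (1000, 1000) over ages 30-31
  ages <- 0:110
  dx <- numeric(111)
  dx[c(31, 32)] <- 10
  dx[81] <- 100000 - 20
  lx <- 100000 - cumsum(c(0, dx[-111]))
  tab <- lifetable("T", 2000, ages, dx, lx, lx - dx / 2, rep(0, 111))
  tab$Lx[c(31, 32)] <- 1000
  expect_equal(banded_death_rate(tab, 30, 31), 0.01)

  # no deaths in band
  expect_equal(banded_death_rate(tab, 40, 64), 0)

  # brute-force per-age summation oracle on a synthetic table
  syn <- synthetic_lifetable(sn_cp(80, 10, -0.4),
                             premature = sn_cp(55, 10, 0.3), alpha = 0.25)
  num <- 0
  den <- 0
  for (a in 30:64) {
    num <- num + syn$dx[syn$ages == a]
    den <- den + syn$Lx[syn$ages == a]
  }
  expect_equal(banded_death_rate(syn, 30, 64), num / den,
               tolerance = 1e-12)
  expect_error(banded_death_rate(syn, 30, 120), "range")
})

test_that("threshold fraction is monotone with point-mass edge cases", {
  w <- numeric(106)
  w[66] <- 1  # point mass at age 70
  d <- death_density(5:110, w, effective_n = 1)
  expect_equal(premature_fraction_below(d, 75), 1)
  expect_equal(premature_fraction_below(d, 65), 0)
  expect_equal(premature_fraction_below(d, 5), 0)    # below grid
  expect_equal(premature_fraction_below(d, 200), 1)  # above grid

  syn <- to_death_density(synthetic_lifetable(sn_cp(80, 10, -0.4),
                                              premature = sn_cp(55, 10, 0.3),
                                              alpha = 0.25))
  fr <- vapply(seq(10, 110, 5), function(th) {
    premature_fraction_below(syn, th)
  }, 0)
  expect_true(all(diff(fr) >= 0))
})

test_that("pyll matches closed forms and the loop oracle", {
  # single death at exact age 80.5 with SLE 86.01 -> 5.51 years
  ages <- 0:110
  dx <- numeric(111)
  dx[81] <- 1
  dx[111] <- 100000 - 1
  lx <- 100000 - cumsum(c(0, dx[-111]))
  tab <- lifetable("T", 2000, ages, dx, lx, lx - dx / 2, rep(0, 111))
  expect_equal(pyll(tab, sle = 86.01), 5.51, tolerance = 1e-9)

  # all deaths at ages >= sle contribute nothing
  dx2 <- numeric(111)
  dx2[96] <- 100000  # age 95
  lx2 <- 100000 - cumsum(c(0, dx2[-111]))
  tab2 <- lifetable("T", 2000, ages, dx2, lx2, lx2 - dx2 / 2,
                    rep(0, 111))
  expect_equal(pyll(tab2, sle = 86.01), 0)

  # loop oracle on a synthetic table
  syn <- synthetic_lifetable(sn_cp(80, 10, -0.4),
                             premature = sn_cp(55, 10, 0.3), alpha = 0.25)
  oracle <- 0
  for (i in seq_along(syn$ages)) {
    rem <- 86.01 - (syn$ages[i] + 0.5)
    if (rem > 0) oracle <- oracle + syn$dx[i] * rem
  }
  expect_equal(pyll(syn, 86.01), oracle, tolerance = 1e-9)

  # monotone in sle
  expect_lt(pyll(syn, 86.01), pyll(syn, 91.93))
})

test_that("threshold choice can reverse a two-population ranking", {
  # A: more deaths below 65 than B, but fewer below 75
  wA <- numeric(106)
  wA[5:110 == 60] <- 0.10
  wA[5:110 == 72] <- 0.05
  wA[5:110 == 85] <- 0.85
  wB <- numeric(106)
  wB[5:110 == 60] <- 0.06
  wB[5:110 == 72] <- 0.14
  wB[5:110 == 85] <- 0.80
  dA <- death_density(5:110, wA, effective_n = 1e5)
  dB <- death_density(5:110, wB, effective_n = 1e5)

  below65 <- c(premature_fraction_below(dA, 65),
               premature_fraction_below(dB, 65))
  below75 <- c(premature_fraction_below(dA, 75),
               premature_fraction_below(dB, 75))
  expect_gt(below65[1], below65[2])  # A looks worse at threshold 65
  expect_lt(below75[1], below75[2])  # B looks worse at threshold 75
})

test_that("absolute_measures assembles a tidy per-table summary", {
  syn <- synthetic_lifetable(sn_cp(80, 10, -0.4),
                             premature = sn_cp(55, 10, 0.3), alpha = 0.25)
  out <- absolute_measures(syn)
  expect_s3_class(out, "data.frame")
  expect_equal(nrow(out), 1L)
  expect_true(all(c("m_band", "pyll", "frac_below_65", "frac_below_75")
                  %in% names(out)))
  expect_true(out$frac_below_65 <= out$frac_below_70)
})
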