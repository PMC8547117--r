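test_that("HMD reader returns the requested year and parses 110+", {
  path <- write_hmd_fixture(years = c(2010L, 2011L))
  tab <- read_hmd_lifetable(path, 2011)
  expect_s3_class(tab, "lifetable")
  expect_identical(tab$year, 2011L)
  expect_identical(tab$ages, 0:110)
  expect_identical(tab$open_age, 110L)
  expect_lt(abs(sum(tab$dx) - 100000), 0.5)
  expect_equal(tab$population_id, "FIX")
})

test_that("missing year and malformed rows raise informative errors", {
  path <- write_hmd_fixture(years = 2010L)
  expect_error(read_hmd_lifetable(path, 1800), "year not found")

  lines <- readLines(path)
  lines[10] <- "  2010  6  0.1 0.1"  # truncated row
  bad <- tempfile(fileext = ".txt")
  writeLines(lines, bad)
  expect_error(read_hmd_lifetable(bad, 2010), "line 10")

  expect_error(read_hmd_lifetable(tempfile(), 2010), "not found")
})

test_that("write-then-read round-trips dx within rounding", {
  tab <- synthetic_lifetable(sn_cp(82, 9, -0.45),
                             premature = sn_cp(58, 11, 0.2), alpha = 0.2,
                             eta = 0.01, year = 1999L)
  path <- tempfile(fileext = ".txt")
  write_hmd_lifetable(tab, path)
  back <- read_hmd_lifetable(path, 1999)
  expect_true(all(abs(back$dx - tab$dx) <= 0.5))
  expect_true(all(diff(back$lx) <= 0))
  expect_lt(abs(sum(back$dx) - back$radix), 0.5)
})

test_that("to_death_density normalizes dx above min_age", {
  # uniform dx over all ages
  ages <- 0:110
  dx <- rep(100000 / 111, 111)
  lx <- 100000 - cumsum(c(0, dx[-111]))
  tab <- lifetable("U", 2000, ages, dx, lx, lx - dx / 2,
                   dx / (lx - dx / 2))
  d <- to_death_density(tab, min_age = 5)
  expect_identical(d$ages, 5:110)
  expect_equal(d$weights, rep(1 / 106, 106), tolerance = 1e-12)
  expect_equal(d$effective_n, sum(dx[ages >= 5]))

  # point mass at age 80
  dx2 <- numeric(111)
  dx2[81] <- 100000
  lx2 <- 100000 - cumsum(c(0, dx2[-111]))
  tab2 <- lifetable("P", 2000, ages, dx2, lx2, lx2 - dx2 / 2,
                    rep(0, 111))
  d2 <- to_death_density(tab2)
  expect_equal(d2$weights[d2$ages == 80], 1)
  expect_equal(sum(d2$weights), 1, tolerance = 1e-12)

  # all-zero above min_age
  dx3 <- numeric(111)
  dx3[1] <- 100000
  lx3 <- 100000 - cumsum(c(0, dx3[-111]))
  tab3 <- lifetable("Z", 2000, ages, dx3, lx3, pmax(lx3 - dx3 / 2, 0),
                    rep(0, 111))
  expect_error(to_death_density(tab3), "zero")
})

test_that("density invariants hold for read tables", {
  path <- write_hmd_fixture()
  tab <- read_hmd_lifetable(path, 2010)
  d <- to_death_density(tab)
  expect_equal(sum(d$weights), 1, tolerance = 1e-9)
  expect_true(all(d$weights >= 0))
  expect_identical(d$ages[1], d$min_age)
})

test_that("pool_group averages per age and is permutation-invariant", {
  w1 <- numeric(106); w1[66] <- 1  # point mass at 70
  w2 <- numeric(106); w2[86] <- 1  # point mass at 90
  d1 <- death_density(5:110, w1, effective_n = 100)
  d2 <- death_density(5:110, w2, effective_n = 300)
  pooled <- pool_group(list(d1, d2))
  expect_equal(pooled$weights[pooled$ages == 70], 0.5)
  expect_equal(pooled$weights[pooled$ages == 90], 0.5)
  expect_equal(pooled$effective_n, 400)

  # idempotence on identical members
  same <- pool_group(list(d1, d1))
  expect_equal(same$weights, d1$weights)

  # brute-force per-age averaging oracle on three fixtures
  set.seed(1)
  ds <- lapply(1:3, function(i) {
    w <- runif(106)
    death_density(5:110, w / sum(w), effective_n = 10)
  })
  pooled3 <- pool_group(ds)
  oracle <- sapply(seq_len(106), function(a) {
    mean(c(ds[[1]]$weights[a], ds[[2]]$weights[a], ds[[3]]$weights[a]))
  })
  expect_equal(pooled3$weights, oracle / sum(oracle), tolerance = 1e-12)

  # permutation invariance
  perm <- pool_group(ds[c(3, 1, 2)])
  expect_equal(pooled3$weights, perm$weights, tolerance = 1e-15)

  # mismatched grids
  d_short <- death_density(5:100, rep(1 / 96, 96), effective_n = 10)
  expect_error(pool_group(list(d1, d_short)), "grid")
})

test_that("death_density CSV export round-trips", {
  d <- death_density(5:110, rep(1 / 106, 106), effective_n = 10)
  f <- tempfile(fileext = ".csv")
  write_density_csv(d, f)
  back <- read.csv(f)
  expect_equal(names(back), c("age", "weight"))
  expect_equal(back$weight, d$weights, tolerance = 1e-12)
})
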