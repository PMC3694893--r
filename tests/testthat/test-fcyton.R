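test_that("moment-matched lognormal has the requested mean and SD", {
  d <- lognormal_from_moments(30, 10)
  expect_equal(integrate(d$pdf, 0, Inf)$value, 1, tolerance = 1e-6)
  set.seed(9)
  x <- rlnorm(1e6, d$meanlog, d$sdlog)
  expect_equal(mean(x), 30, tolerance = 0.005 * 30)
  expect_equal(sd(x), 10, tolerance = 0.01 * 10)
  # SD -> 0: mass concentrates at the mean
  d0 <- lognormal_from_moments(30, 0.1)
  expect_gt(d0$cdf(30.3) - d0$cdf(29.7), 0.95)
})

test_that("progressor fractions are survivor-function ratios of the destiny Gaussian", {
  expect_equal(unname(progressor_fractions(100, 0.1, 8L)), rep(1, 7))
  expect_equal(unname(progressor_fractions(-50, 1, 8L)), rep(0, 7))
  Dmu <- 3; Ds <- 1
  S <- function(g) 1 - pnorm(g, Dmu, Ds)  # independent survivor oracle
  expect_equal(unname(progressor_fractions(Dmu, Ds, 8L)),
               S(1:7) / S(0:6), tolerance = 1e-12)
  f <- progressor_fractions(3, 1, 8L)
  expect_true(all(f >= 0 & f <= 1))
})

test_that("simulation starts with all founders undivided and conserves cells", {
  p <- bcell_truth()
  sim <- simulate_fcyton(p, times = c(0, 24, 48, 96, 144))
  expect_equal(unname(sim$counts[, 1]), c(1e4, rep(0, 7)))
  # every division removes one mother and adds two daughters
  resid <- colSums(sim$counts) + sim$cum_deaths - sim$cum_divisions - 1e4
  expect_lt(max(abs(resid)), 1e-6 * 1e4)
  # cumulative dividers never decrease
  expect_true(all(diff(sim$cum_divisions) >= -1e-9))
})

test_that("non-responders never divide and eventually die", {
  p <- as_fcyton_params(c(N = 5000, F0 = 0, Dmu = 3, Dsigma = 1,
                          Ediv0 = 40, SDdiv0 = 10, Ediv1 = 10, SDdiv1 = 4,
                          Edie0 = 30, SDdie0 = 10, Edie1 = 80, SDdie1 = 30))
  sim <- simulate_fcyton(p, times = c(0, 48, 300))
  expect_equal(sum(sim$counts[-1, ]), 0)
  expect_lt(sim$counts[1, 3], 5)  # gen 0 emptied by death
})

test_that("with no destiny limit and full response the population doubles g_max-1 times", {
  p <- as_fcyton_params(c(N = 1000, F0 = 1, Dmu = 100, Dsigma = 0.1,
                          Ediv0 = 20, SDdiv0 = 5, Ediv1 = 10, SDdiv1 = 5,
                          Edie0 = 60, SDdie0 = 20, Edie1 = 80, SDdie1 = 30))
  sim <- simulate_fcyton(p, times = 600)
  expect_equal(sum(sim$counts), 1000 * 2^7, tolerance = 1)
  expect_equal(unname(sim$counts[8, 1]), 1000 * 2^7, tolerance = 1)
})

test_that("conservation and non-negativity hold across random parameter draws", {
  cfg <- generator_config()
  for (k in 1:40) {
    p <- draw_params(cfg, seed = 5000 + k)$fcyton
    sim <- simulate_fcyton(p, times = c(12, 36, 72, 120, 192), dt = 1)
    expect_true(all(sim$counts >= 0))
    resid <- colSums(sim$counts) + sim$cum_deaths - sim$cum_divisions -
      p[["N"]]
    expect_lt(max(abs(resid)) / p[["N"]], 1e-6)
  }
})

test_that("halving the integration step changes counts by less than 0.5%", {
  p <- bcell_truth()
  t_chk <- c(24, 48, 96, 144)
  a <- simulate_fcyton(p, t_chk, dt = 0.5)
  b <- simulate_fcyton(p, t_chk, dt = 0.25)
  denom <- max(a$counts)
  expect_lt(max(abs(a$counts - b$counts)) / denom, 0.005)
})

test_that("cyton reduces to fcyton when death is far slower than division", {
  p <- as_fcyton_params(c(N = 1e4, F0 = 0.8, Dmu = 3, Dsigma = 1,
                          Ediv0 = 30, SDdiv0 = 8, Ediv1 = 10, SDdiv1 = 4,
                          Edie0 = 149, SDdie0 = 5, Edie1 = 149, SDdie1 = 5))
  a <- simulate_fcyton(p, times = c(24, 48, 72))
  b <- simulate_cyton(p, times = c(24, 48, 72))
  expect_lt(max(abs(a$counts - b$counts)) / max(a$counts), 0.01)
})

test_that("cyton with division far beyond death drives extinction", {
  p <- as_fcyton_params(c(N = 1e4, F0 = 0.9, Dmu = 3, Dsigma = 1,
                          Ediv0 = 149, SDdiv0 = 5, Ediv1 = 149, SDdiv1 = 5,
                          Edie0 = 10, SDdie0 = 3, Edie1 = 10, SDdie1 = 3))
  sim <- simulate_cyton(p, times = 400)
  expect_lt(sum(sim$counts), 0.01 * 1e4)
})

test_that("identical competing clocks split generation 0 exactly in half", {
  # F0 = 1, phi = psi: each founder's division and death race is a coin flip
  p <- as_fcyton_params(c(N = 1e4, F0 = 1, Dmu = 0.5, Dsigma = 0.1,
                          Ediv0 = 30, SDdiv0 = 10, Ediv1 = 30, SDdiv1 = 10,
                          Edie0 = 30, SDdie0 = 10, Edie1 = 30, SDdie1 = 10))
  sim <- simulate_cyton(p, times = 500, g_max = 2L)
  # Dmu ~ 0: generation-1 cells never divide again -> all divisions are gen 0
  expect_equal(sim$cum_divisions[1], 5000, tolerance = 5)
})
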