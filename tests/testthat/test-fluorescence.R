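test_that("generation means follow background-additive geometric dilution", {
  p <- fluor_params(cv = 0.2, r = 0.5, b = 150, s = 0, i0 = 2e4)
  gg <- generation_gaussian(p, 0:7)
  M <- 10^gg$mu
  # r = 0.5 halves the background-subtracted fluorescence each generation
  expect_equal(M[-1] - p$b, (M[-8] - p$b) / 2, tolerance = 1e-12)
  expect_true(all(diff(gg$mu) < 0))

  # no background, no shift: mu_0 is just log10(i0)
  p0 <- fluor_params(cv = 0.2, r = 0.5, b = 0, s = 0, i0 = 1000)
  expect_equal(generation_gaussian(p0, 0)$mu, 3)
  # peak spacing tends to log10(1/r) as b -> 0
  expect_equal(diff(generation_gaussian(p0, 0:7)$mu),
               rep(-log10(2), 7), tolerance = 1e-12)
})

test_that("log10 peak SD comes from the lognormal cv identity, all generations", {
  p <- fluor_params(cv = 0.18, r = 0.5, b = 100, s = 0, i0 = 5e4)
  sig_oracle <- sqrt(log(1 + 0.18^2)) / log(10)  # closed form
  for (g in 0:7) expect_equal(generation_gaussian(p, g)$sigma, sig_oracle)
  expect_error(fluor_params(cv = 0.2, r = 0.5, b = 200, s = -900, i0 = 1000),
               "exceed")
})

test_that("mixture rendering conserves component masses on a wide grid", {
  p <- low_cv_fluor(g_max = 2L)
  edges <- seq(2, 5.2, length.out = 257)
  m1 <- mixture_density(p, c(100, 0), edges)
  expect_equal(sum(m1), 100, tolerance = 0.005 * 100)
  m2 <- mixture_density(p, c(100, 50), edges)
  gg <- generation_gaussian(p, 0:1)
  cut <- mean(gg$mu)  # peaks are ~15 sigma apart; split at the midpoint
  lowbin <- edges[-length(edges)] < cut
  expect_equal(sum(m2[!lowbin]), 100, tolerance = 0.5)
  expect_equal(sum(m2[lowbin]), 50, tolerance = 0.5)
})

test_that("analytic mixture matches Monte-Carlo sampling of the same model", {
  p <- low_cv_fluor()
  set.seed(3)
  w <- runif(8, 10, 100)
  edges <- seq(2, 5.2, length.out = 65)
  model <- mixture_density(p, w, edges)
  n_mc <- 2e5
  gg <- generation_gaussian(p, 0:7)
  gen <- sample.int(8, n_mc, replace = TRUE, prob = w / sum(w))
  lx <- rnorm(n_mc, gg$mu[gen], gg$sigma)
  mc <- tabulate(pmin(pmax(findInterval(lx, edges), 1L), 64L), 64L) *
    sum(w) / n_mc
  expect_lt(max(abs(model - mc)), 4 * sqrt(max(model)) * sqrt(sum(w) / n_mc) +
              0.05 * max(model))
  expect_gt(stats::cor(model, mc), 0.999)
})

test_that("NNLS peak weights recover exact mixtures and scale linearly", {
  p <- low_cv_fluor()
  edges <- seq(2, 5.2, length.out = 257)
  w <- c(120, 0, 340, 55, 0, 10, 80, 5)
  h <- new_histogram(edges, mixture_density(p, w, edges), time_h = 48)
  w_hat <- fit_peak_weights(p, h)
  expect_lt(max(abs(w_hat - w) / pmax(w, 1)), 1e-6)

  # scaling the histogram scales the weights
  h10 <- new_histogram(edges, 10 * h$counts, time_h = 48)
  expect_equal(unname(fit_peak_weights(p, h10)), unname(10 * w_hat),
               tolerance = 1e-9)

  # zero histogram, zero weights
  h0 <- new_histogram(edges, rep(0, 256), time_h = 0)
  expect_equal(unname(fit_peak_weights(p, h0)), rep(0, 8))

  # single undivided peak: all mass in generation 0
  h1 <- new_histogram(edges, mixture_density(p, c(500, rep(0, 7)), edges),
                      time_h = 0)
  w1 <- fit_peak_weights(p, h1)
  expect_equal(unname(w1[1]), 500, tolerance = 0.5)
  expect_lt(sum(w1[-1]), 0.5)
})

test_that("fluorescence fitting recovers cv on a single peak with others pinned", {
  p_true <- low_cv_fluor()
  edges <- seq(2, 5.2, length.out = 257)
  h <- new_histogram(edges, mixture_density(p_true, c(1e4, rep(0, 7)), edges),
                     time_h = 0)
  pinned <- rbind(cv = c(0.10, 0.35), r = c(0.5, 0.5), b = c(100, 100),
                  s = c(0, 0))
  fit <- fit_fluorescence_histogram(h, i0 = 5e4, bounds = pinned)
  expect_lt(abs(fit$params$cv - 0.18) / 0.18, 0.05)
})

test_that("time-course fitting is deterministic and recovers a noise-free course", {
  truth <- list(fcyton = bcell_truth(), fluor = low_cv_fluor())
  cfg <- generator_config(schedule = c(24, 48, 72, 96), n_bins = 128L)
  course <- generate_course(truth, cfg)
  fit1 <- fit_fluorescence_timecourse(course$timecourse, seed = 5)
  fit2 <- fit_fluorescence_timecourse(course$timecourse, seed = 5)
  expect_identical(fit1$counts, fit2$counts)
  # multi-peak time points pin down cv and r to within 2%
  p_late <- fit1$fits[[4]]$params
  expect_lt(abs(p_late$cv - 0.18) / 0.18, 0.02)
  expect_lt(abs(p_late$r - 0.5) / 0.5, 0.02)
  # recovered counts close to generated ones
  expect_lt(max(count_error_profile(course$counts, fit1$counts)), 2)
})
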