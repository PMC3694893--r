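test_that("NPAE spans 0 to 100 with constructed overlap cases", {
  edges <- seq(0, 4, length.out = 5)
  H <- matrix(c(10, 10, 0, 0), ncol = 1)
  expect_equal(npae(H, H), 0)
  M_disjoint <- matrix(c(0, 0, 5, 5), ncol = 1)
  expect_equal(npae(M_disjoint, H), 100)
  M_half <- matrix(c(10, 0, 10, 0), ncol = 1)  # shares exactly half the area
  expect_equal(npae(M_half, H), 50)
})

test_that("NPAE is symmetric, scale-invariant, and cell-count weighted", {
  set.seed(2)
  H <- matrix(runif(40), ncol = 2)
  M <- matrix(runif(40), ncol = 2)
  tot <- c(100, 300)
  expect_equal(npae(M, H, totals = tot), npae(H, M, totals = tot),
               tolerance = 1e-12)
  expect_equal(npae(M, H, totals = tot), npae(10 * M, 7 * H, totals = tot),
               tolerance = 1e-12)
  # weighting: a time point with more cells dominates
  a1 <- npae(cbind(H[, 1], H[, 2]), cbind(H[, 1], M[, 2]),
             totals = c(1000, 1))
  a2 <- npae(cbind(H[, 1], H[, 2]), cbind(H[, 1], M[, 2]),
             totals = c(1, 1000))
  expect_lt(a1, a2)
  expect_error(npae(matrix(1, 3, 1), matrix(1, 4, 1)), "grid")
})

test_that("objectives vanish iff model equals data, and MAD adds single-bin deviations", {
  set.seed(4)
  H <- matrix(rexp(60), ncol = 3)
  for (kind in c("mad", "mrsd", "mrsd+", "sd_counts"))
    expect_equal(objective_score(kind, H, H), 0)
  M <- H; M[5, 2] <- M[5, 2] + 1.5
  expect_equal(objective_score("mad", M, H), 1.5 / 3)
  expect_gt(objective_score("mrsd+", M, H), 0)
})

test_that("the correlation term makes MRSD+ prefer shape-matched models", {
  h <- dnorm(seq(-3, 3, length.out = 50))
  H <- matrix(h, ncol = 1)
  M_scaled <- matrix(0.8 * h, ncol = 1)          # right shape, wrong scale
  d <- sqrt(sum((M_scaled - H)^2))
  set.seed(8)
  repeat {  # construct a shape-mismatched model with the same MRSD
    noise <- rnorm(50)
    M_mis <- H + noise / sqrt(sum(noise^2)) * d
    if (all(M_mis >= 0) && cor(M_mis, H) < 0.99) break
  }
  expect_equal(objective_score("mrsd", M_scaled, H),
               objective_score("mrsd", M_mis, H), tolerance = 1e-9)
  expect_lt(objective_score("mrsd+", M_scaled, H),
            objective_score("mrsd+", M_mis, H))
})

test_that("annealing finds a quadratic bowl minimum and is reproducible", {
  bowl <- function(x) sum((x - c(0.3, -0.2))^2)
  for (s in 1:10) {
    fit <- anneal(bowl, c(-1, -1), c(1, 1), seed = s,
                  schedule = anneal_schedule(cooling = 0.9,
                                             steps_per_temp = 60L,
                                             t_min_ratio = 1e-4))
    expect_lt(sqrt(bowl(fit$par)), 1e-2)
  }
  f1 <- anneal(bowl, c(-1, -1), c(1, 1), seed = 3, schedule = quick_schedule())
  f2 <- anneal(bowl, c(-1, -1), c(1, 1), seed = 3, schedule = quick_schedule())
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$par, f2$par)
})

test_that("degenerate schedules: no stages returns the start, zero temperature is greedy", {
  bowl <- function(x) sum(x^2)
  none <- anneal(bowl, -1, 1, seed = 1,
                 schedule = anneal_schedule(t0 = 5, t_min_ratio = 1),
                 init = 0.4)
  expect_equal(none$par, 0.4)
  expect_equal(none$n_eval, 1L)
  greedy <- anneal(bowl, -1, 1, seed = 1,
                   schedule = anneal_schedule(t0 = 0, cooling = 0.5,
                                              steps_per_temp = 50L,
                                              t_min_ratio = 1e-3),
                   init = 0.9)
  expect_true(all(diff(greedy$trace) <= 0))  # only improvements accepted
  expect_lt(greedy$value, bowl(0.9))
})

test_that("sequential fitting flags an under-determined single time point", {
  p <- bcell_truth()
  sim <- simulate_fcyton(p, times = 48)
  fit <- sequential_fit(sim$counts, times = 48, n_restarts = 1L, seed = 1,
                        schedule = quick_schedule(), polish_top = 0L)
  expect_false(fit$converged)
})

test_that("best-of-8 restarts never beats best-of-1 on the same seeds, integrated", {
  truth <- list(fcyton = bcell_truth(), fluor = low_cv_fluor())
  cfg <- generator_config(schedule = c(24, 48, 96), n_bins = 64L)
  course <- generate_course(truth, cfg)
  fl <- fit_fluorescence_timecourse(course$timecourse, seed = 2)
  c8 <- integrated_fit(course$timecourse, fl, n_restarts = 8L, seed = 40,
                       schedule = quick_schedule())
  c1 <- integrated_fit(course$timecourse, fl, n_restarts = 1L, seed = 40,
                       schedule = quick_schedule())
  expect_lte(c8[[1]]$npae, c1[[1]]$npae)
  # candidates come back sorted by NPAE
  np <- vapply(c8, `[[`, numeric(1), "npae")
  expect_true(!is.unsorted(np))
})
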