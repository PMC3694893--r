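test_that("parameter draws respect ranges, the SD<=E constraint, and determinism", {
  cfg <- generator_config()
  d1 <- draw_params(cfg, seed = 1)
  d2 <- draw_params(cfg, seed = 1)
  expect_identical(unclass(d1$fcyton), unclass(d2$fcyton))
  rg <- cfg$fcyton_ranges
  for (k in 1:200) {
    p <- unclass(draw_params(cfg, seed = k)$fcyton)
    expect_true(all(p >= rg[, 1] & p <= rg[, 2]))
    expect_true(p[["SDdiv0"]] <= p[["Ediv0"]])
    expect_true(p[["SDdiv1"]] <= p[["Ediv1"]])
    expect_true(p[["SDdie0"]] <= p[["Edie0"]])
    expect_true(p[["SDdie1"]] <= p[["Edie1"]])
  }
})

test_that("degenerate draw ranges echo the range value exactly", {
  cfg <- generator_config()
  cfg$fcyton_ranges[, 1] <- cfg$fcyton_ranges[, 2] <-
    unclass(bcell_truth())
  cfg$fluor_ranges[, 1] <- cfg$fluor_ranges[, 2] <- c(0.18, 0.5, 100, 0)
  d <- draw_params(cfg, seed = 99)
  expect_equal(unclass(d$fcyton), unclass(bcell_truth()))
  expect_equal(d$fluor$cv, 0.18)
})

test_that("noise-free rendering round-trips counts through NNLS to 1e-6", {
  truth <- list(fcyton = bcell_truth(), fluor = low_cv_fluor())
  cfg <- generator_config(schedule = c(24, 72, 120))
  course <- generate_course(truth, cfg)
  for (i in seq_along(cfg$schedule)) {
    w <- fit_peak_weights(truth$fluor, course$timecourse$histograms[[i]])
    expect_lt(max(abs(w - course$counts[, i])) / max(course$counts), 1e-6)
  }
})

test_that("a time-zero schedule gives a single undivided peak at the anchor", {
  truth <- list(fcyton = bcell_truth(), fluor = low_cv_fluor())
  course <- generate_course(truth, generator_config(schedule = 0))
  expect_length(course$timecourse$histograms, 1L)
  h <- course$timecourse$histograms[[1]]
  mid <- (head(h$bin_edges, -1) + tail(h$bin_edges, -1)) / 2
  peak <- mid[which.max(h$counts)]
  expect_equal(peak, log10(5e4), tolerance = 0.02)
  w <- fit_peak_weights(truth$fluor, h)
  expect_equal(unname(w[1]) / sum(w), 1, tolerance = 1e-6)
})

test_that("count noise scales each generation independently with the stated SD", {
  truth <- list(fcyton = bcell_truth(), fluor = low_cv_fluor())
  cfg <- generator_config(schedule = c(48, 96))
  course <- generate_course(truth, cfg)
  expect_equal(add_count_noise(course, sigma = 0, seed = 1)$counts,
               course$counts)
  set.seed(11)
  ratios <- replicate(400, {
    nz <- add_count_noise(course, sigma = 0.1,
                          seed = sample.int(1e6, 1))$counts
    (nz / pmax(course$counts, 1e-9))[course$counts > 1]
  })
  # finite-sample check; zero-clamping also trims the SD slightly
  expect_equal(sd(unlist(ratios)), 0.1, tolerance = 0.025)
  expect_true(all(unlist(ratios) >= 0))  # negative draws clamp to zero
})

test_that("scale noise multiplies whole time points", {
  truth <- list(fcyton = bcell_truth(), fluor = low_cv_fluor())
  course <- generate_course(truth, generator_config(schedule = c(48, 96)))
  nz <- add_scale_noise(course, sigma = 0.1, seed = 4)
  r <- nz$counts / pmax(course$counts, 1e-12)
  # within a time point every generation is scaled by the same factor
  for (i in 1:2) {
    col <- r[course$counts[, i] > 1, i]
    expect_lt(diff(range(col)), 1e-9)
  }
})

test_that("count error profile matches its formula and a brute-force oracle", {
  tr <- matrix(c(100, 0, 50, 25), nrow = 2)
  expect_equal(count_error_profile(tr, tr), c(0, 0))
  ft <- tr; ft[1, 2] <- ft[1, 2] + 100  # one generation off by the max count
  expect_equal(count_error_profile(tr, ft), c(0, 100 / 2))
  set.seed(12)
  tl <- lapply(1:5, function(i) matrix(runif(24, 0, 100), nrow = 4))
  fl <- lapply(tl, function(m) m * (1 + matrix(rnorm(24, 0, 0.1), nrow = 4)))
  oracle <- rowMeans(sapply(seq_along(tl), function(ci) {
    sapply(seq_len(6), function(t)
      mean(100 * abs(tl[[ci]][, t] - fl[[ci]][, t]) / max(tl[[ci]])))
  }))
  expect_equal(count_error_profile(tl, fl), oracle, tolerance = 1e-12)
  expect_error(count_error_profile(matrix(0, 2, 2), matrix(0, 2, 2)),
               "zero")
})

test_that("parameter errors use percent or absolute scales as appropriate", {
  tr <- bcell_truth()
  expect_true(all(param_error(tr, tr) == 0))
  ft <- unclass(tr)
  ft["N"] <- 1.01 * ft["N"]; ft["F0"] <- ft["F0"] - 0.05
  ft["Dmu"] <- ft["Dmu"] + 2; ft["Edie1"] <- 1.18 * ft["Edie1"]
  pe <- param_error(tr, as_fcyton_params(ft))
  expect_equal(unname(pe["N_pct"]), 1, tolerance = 1e-9)
  expect_equal(unname(pe["F0_abs"]), 0.05)
  expect_equal(unname(pe["Dmu_gen"]), 2)
  expect_equal(unname(pe["Edie1_pct"]), 18, tolerance = 1e-9)
})

test_that("the full generator pipeline is reproducible from its seed", {
  cfg <- generator_config(schedule = c(24, 72), n_bins = 64L)
  mk <- function() {
    truth <- draw_params(cfg, seed = 77)
    generate_course(truth, cfg)
  }
  a <- mk(); b <- mk()
  expect_identical(a$counts, b$counts)
  for (i in 1:2)
    expect_identical(a$timecourse$histograms[[i]]$counts,
                     b$timecourse$histograms[[i]]$counts)
})
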