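#' Named time-point schedules for generated time courses
#'
#' Reconstructed presets spanning a 192-hour stimulation window: ten-, five-
#' and three-point schedules for schedule-density experiments, a four-point
#' distributed (24-144 h) and a four-point early (12-48 h) schedule, and an
#' eight-point schedule for data-quality experiments.
#'
#' @param name one of `"ten-point"`, `"eight-point"`, `"five-point"`,
#'   `"four-distributed"`, `"four-early"`, `"three-point"`.
#' @return Numeric vector of hours post stimulation.
#' @export
schedule_preset <- function(name = c("ten-point", "eight-point",
                                     "five-point", "four-distributed",
                                     "four-early", "three-point")) {
  switch(match.arg(name),
         "ten-point" = c(0, 12, 24, 36, 48, 72, 96, 120, 144, 192),
         "eight-point" = c(12, 24, 36, 48, 72, 96, 120, 144),
         "five-point" = c(0, 24, 48, 96, 192),
         "four-distributed" = c(24, 64, 104, 144),
         "four-early" = c(12, 24, 36, 48),
         "three-point" = c(24, 96, 192))
}

#' Configuration for the synthetic CFSE time-course generator
#'
#' The generator emulates benchmark panels of realistic CFSE time courses:
#' population parameters drawn uniformly within realistic ranges (the
#' log-normal SDs constrained not to exceed their means), histograms
#' rendered as weighted Gaussian mixtures on a shared grid, and optional
#' Gaussian noise on per-generation counts or per-time-point totals.
#'
#' @param fcyton_ranges 12 x 2 matrix of draw ranges
#'   ([default_fcyton_bounds()]).
#' @param fluor_ranges 4 x 2 matrix of `(cv, r, b, s)` draw ranges
#'   ([default_fluor_bounds()]).
#' @param i0 undivided-population mean fluorescence (linear a.u.).
#' @param schedule time points in hours ([schedule_preset()]).
#' @param g_max generations modelled.
#' @param n_bins histogram bins.
#' @param events_per_timepoint `NULL` for deterministic analytic rendering
#'   (the default), or an event count for sampled-event rendering.
#' @param count_sigma,scale_sigma SDs of the multiplicative `1 + N(0,
#'   sigma)` noise on per-generation counts and per-time-point totals
#'   (0 = noise-free).
#' @param dt simulation step in hours.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(fcyton_ranges = default_fcyton_bounds(),
                             fluor_ranges = default_fluor_bounds(i0),
                             i0 = 5e4,
                             schedule = schedule_preset("ten-point"),
                             g_max = 8L, n_bins = 256L,
                             events_per_timepoint = NULL,
                             count_sigma = 0, scale_sigma = 0, dt = 0.5) {
  structure(list(fcyton_ranges = fcyton_ranges, fluor_ranges = fluor_ranges,
                 i0 = i0, schedule = schedule, g_max = as.integer(g_max),
                 n_bins = as.integer(n_bins),
                 events_per_timepoint = events_per_timepoint,
                 count_sigma = count_sigma, scale_sigma = scale_sigma,
                 dt = dt),
            class = "generator_config")
}

#' Draw ground-truth parameters for one synthetic course
#'
#' Uniform independent draws within the configured ranges; each log-normal
#' (E, SD) timing pair is redrawn until `SD <= E`. Deterministic for a
#' fixed seed.
#'
#' @param cfg a [generator_config()].
#' @param seed integer seed.
#' @return List with `fcyton` ([fcyton_params()]) and `fluor`
#'   ([fluor_params()]).
#' @export
draw_params <- function(cfg, seed = 1L) {
  set.seed(seed)
  rg <- cfg$fcyton_ranges
  if (any(rg[, 2] < rg[, 1])) stop("infeasible fcyton ranges")
  draw1 <- function(nm) runif(1, rg[nm, 1], rg[nm, 2])
  p <- setNames(numeric(12), fcyton_param_names())
  for (nm in c("N", "F0", "Dmu", "Dsigma")) p[nm] <- draw1(nm)
  for (pair in list(c("Ediv0", "SDdiv0"), c("Ediv1", "SDdiv1"),
                    c("Edie0", "SDdie0"), c("Edie1", "SDdie1"))) {
    repeat {
      e <- draw1(pair[1]); s <- draw1(pair[2])
      if (s <= e) break
    }
    p[pair[1]] <- e; p[pair[2]] <- s
  }
  fr <- cfg$fluor_ranges
  if (any(fr[, 2] < fr[, 1])) stop("infeasible fluorescence ranges")
  fl <- setNames(runif(4, fr[, 1], fr[, 2]), c("cv", "r", "b", "s"))
  list(fcyton = as_fcyton_params(p),
       fluor = fluor_params(fl[["cv"]], fl[["r"]], fl[["b"]], fl[["s"]],
                            i0 = cfg$i0, g_max = cfg$g_max))
}

course_bin_grid <- function(fluor, n_bins) {
  gg <- generation_gaussian(fluor, seq_len(fluor$g_max) - 1L)
  lo <- min(gg$mu) - 4.5 * gg$sigma
  hi <- max(gg$mu) + 4.5 * gg$sigma
  seq(lo, hi, length.out = n_bins + 1L)
}

render_course <- function(course, seed = NULL) {
  cfg <- course$cfg
  edges <- course$bin_edges
  A <- adaptor_matrix(course$truth$fluor, edges)
  n_ev <- cfg$events_per_timepoint
  if (!is.null(n_ev) && !is.null(seed)) set.seed(seed)
  hs <- lapply(seq_along(cfg$schedule), function(i) {
    w <- course$counts[, i]
    if (is.null(n_ev)) {
      cnts <- drop(A %*% w)
    } else {
      gg <- generation_gaussian(course$truth$fluor,
                                seq_len(cfg$g_max) - 1L)
      gen <- sample.int(cfg$g_max, n_ev, replace = TRUE,
                        prob = w + 1e-12)
      lx <- rnorm(n_ev, gg$mu[gen], gg$sigma)
      idx <- pmin(pmax(findInterval(lx, edges), 1L), cfg$n_bins)
      cnts <- tabulate(idx, nbins = cfg$n_bins) *
        (sum(w) / max(n_ev, 1))
    }
    new_histogram(edges, cnts, cfg$schedule[i])
  })
  course$timecourse <- build_timecourse(hs, rep(course$truth$fluor$i0,
                                                length(hs)))
  course
}

#' Generate a synthetic CFSE time course with known ground truth
#'
#' Simulates generational counts with the fcyton model at the scheduled
#' times and renders them as log-fluorescence histograms through the
#' ground-truth fluorescence model — analytically (deterministic, the
#' default) or by sampling individual events.
#'
#' @param truth list with `fcyton` and `fluor` parameters (as returned by
#'   [draw_params()]).
#' @param cfg a [generator_config()]; its `schedule` is used.
#' @param seed seed for event sampling (unused in analytic mode).
#' @return List of class `generated_course`: `truth`, `counts`
#'   (ground-truth generational counts), `timecourse`
#'   (`cfse_timecourse`), `bin_edges`, `cfg`.
#' @export
generate_course <- function(truth, cfg = generator_config(), seed = NULL) {
  stopifnot(length(cfg$schedule) >= 1)
  sim <- simulate_fcyton(truth$fcyton, cfg$schedule, g_max = cfg$g_max,
                         dt = cfg$dt)
  course <- structure(list(truth = truth, counts = sim$counts,
                           bin_edges = course_bin_grid(truth$fluor,
                                                       cfg$n_bins),
                           cfg = cfg, timecourse = NULL),
                      class = "generated_course")
  render_course(course, seed = seed)
}

#' Multiplicative Gaussian noise on generational counts
#'
#' Each generation's count at each time point is scaled by an independent
#' `1 + N(0, sigma)` draw (clamped at zero), emulating mixed populations;
#' histograms are re-rendered from the perturbed counts.
#'
#' @param course a `generated_course`.
#' @param sigma noise SD (default 0.1).
#' @param seed integer seed.
#' @return The perturbed `generated_course`.
#' @export
add_count_noise <- function(course, sigma = 0.1, seed = 1L) {
  set.seed(seed)
  fac <- pmax(1 + rnorm(length(course$counts), 0, sigma), 0)
  course$counts <- course$counts * matrix(fac, nrow = nrow(course$counts))
  render_course(course)
}

#' Multiplicative Gaussian noise on per-time-point totals
#'
#' The total cell count of each time point is scaled by an independent
#' `1 + N(0, sigma)` draw (clamped at zero), emulating mixing/preparation
#' noise.
#'
#' @inheritParams add_count_noise
#' @export
add_scale_noise <- function(course, sigma = 0.1, seed = 1L) {
  set.seed(seed)
  fac <- pmax(1 + rnorm(ncol(course$counts), 0, sigma), 0)
  course$counts <- sweep(course$counts, 2, fac, `*`)
  render_course(course)
}

#' Per-time-point average normalized count error
#'
#' For each course, the per-generation percent errors are normalized to the
#' course's maximum generational count (so late sparse generations do not
#' dominate), averaged over generations per time point, then averaged over
#' courses.
#'
#' @param true_counts,fitted_counts a matrix (generations x time points) or
#'   a list of such matrices (one per course) with identical dimensions.
#' @return Numeric vector: average normalized percent error per time point.
#' @export
count_error_profile <- function(true_counts, fitted_counts) {
  if (is.matrix(true_counts)) true_counts <- list(true_counts)
  if (is.matrix(fitted_counts)) fitted_counts <- list(fitted_counts)
  stopifnot(length(true_counts) == length(fitted_counts))
  per_course <- vapply(seq_along(true_counts), function(ci) {
    tr <- true_counts[[ci]]; ft <- fitted_counts[[ci]]
    stopifnot(all(dim(tr) == dim(ft)))
    denom <- max(tr)
    if (denom <= 0) stop("all-zero true counts")
    colMeans(100 * abs(tr - ft) / denom)
  }, numeric(ncol(true_counts[[1]])))
  rowMeans(matrix(per_course, ncol = length(true_counts)))
}

#' Per-parameter fit error
#'
#' Percent error `100 |fit - true| / true` for the founder count and the
#' log-normal timing parameters; absolute error for the fraction `F0` and
#' for the destiny parameters `Dmu`/`Dsigma` (generations).
#'
#' @param truth,fitted [fcyton_params()] vectors.
#' @return Named numeric vector (`N_pct`, `F0_abs`, `Dmu_gen`,
#'   `Dsigma_gen`, `<timing>_pct` ...).
#' @export
param_error <- function(truth, fitted) {
  tr <- unclass(as_fcyton_params(truth))
  ft <- unclass(as_fcyton_params(fitted))
  timing <- c("Ediv0", "SDdiv0", "Ediv1", "SDdiv1",
              "Edie0", "SDdie0", "Edie1", "SDdie1")
  out <- c(N_pct = 100 * abs(ft[["N"]] - tr[["N"]]) / tr[["N"]],
           F0_abs = abs(ft[["F0"]] - tr[["F0"]]),
           Dmu_gen = abs(ft[["Dmu"]] - tr[["Dmu"]]),
           Dsigma_gen = abs(ft[["Dsigma"]] - tr[["Dsigma"]]))
  for (nm in timing)
    out[paste0(nm, "_pct")] <- 100 * abs(ft[[nm]] - tr[[nm]]) / tr[[nm]]
  out
}
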