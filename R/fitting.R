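#' Normalized percent area error between model and data histograms
#'
#' Per time point the histograms are normalized to densities and compared by
#' total variation distance, `a = 0.5 * sum(|H - M|)`, which lies in
#' `[0, 1]` (0 for identical shapes, 1 for disjoint supports). The reported
#' score is the cell-count-weighted mean across time points (and runs),
#' scaled to percent: 0 is a perfect shape match, 100 total mismatch.
#'
#' @param model,data histograms on a shared bin grid: either lists of
#'   `cfse_histogram` objects or numeric matrices (bins x time points).
#' @param totals cell-count weights per time point; defaults to the data
#'   histogram totals.
#' @param weighted weight time points by their cell counts (default) or use
#'   an unweighted mean.
#' @return NPAE in percent, in `[0, 100]`.
#' @export
npae <- function(model, data, totals = NULL, weighted = TRUE) {
  M <- as_hist_matrix(model)
  H <- as_hist_matrix(data)
  if (!all(dim(M) == dim(H)))
    stop("model and data histograms must share one bin grid")
  if (is.null(totals)) totals <- colSums(H)
  a <- vapply(seq_len(ncol(H)), function(i) {
    h <- H[, i]; m <- M[, i]
    th <- sum(h); tm <- sum(m)
    if (th > 0) h <- h / th
    if (tm > 0) m <- m / tm
    0.5 * sum(abs(h - m))
  }, numeric(1))
  w <- if (weighted) totals else rep(1, length(a))
  if (sum(w) == 0) return(0)
  100 * sum(w * a) / sum(w)
}

as_hist_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (inherits(x, "cfse_timecourse")) x <- x$histograms
  if (is.list(x)) return(vapply(x, `[[`, numeric(length(x[[1]]$counts)),
                                "counts"))
  stop("expected a matrix, list of histograms, or cfse_timecourse")
}

#' Histogram / count objective functions
#'
#' All objectives are non-negative and vanish iff model equals data on the
#' grid; lower is better.
#' * `MAD`: mean over time points of the summed absolute per-bin count
#'   deviation.
#' * `MRSD`: mean over time points of the root summed squared count
#'   deviation.
#' * `MRSD+`: each time point's MRSD term is multiplied by
#'   `2 - cor(H, M)` (Pearson over bins) before averaging, rewarding shape
#'   agreement; an undefined correlation (zero variance) contributes 0.
#' * `SD_counts`: summed squared deviation of generational cell counts, for
#'   sequential fitting to extracted counts.
#'
#' @param kind one of `"mad"`, `"mrsd"`, `"mrsd+"`, `"sd_counts"`.
#' @param model,data matrices on matching grids: per-bin counts
#'   (bins x time points) for the histogram objectives, generational counts
#'   (generations x time points) for `sd_counts`.
#' @return Scalar score.
#' @export
objective_score <- function(kind, model, data) {
  kind <- tolower(kind)
  M <- as_hist_matrix(model); H <- as_hist_matrix(data)
  if (!all(dim(M) == dim(H))) stop("model/data dimension mismatch")
  switch(kind,
    mad = mean(colSums(abs(H - M))),
    mrsd = mean(sqrt(colSums((H - M)^2))),
    "mrsd+" = {
      terms <- vapply(seq_len(ncol(H)), function(i) {
        rho <- if (sd(H[, i]) == 0 || sd(M[, i]) == 0) 0
               else cor(H[, i], M[, i])
        sqrt(sum((H[, i] - M[, i])^2)) * (2 - rho)
      }, numeric(1))
      mean(terms)
    },
    sd_counts = sum((H - M)^2),
    stop("unknown objective kind: ", kind))
}

#' Annealing schedule settings
#'
#' The initial temperature defaults to the standard deviation of the score
#' over `n_t0_draws` uniform random parameter draws; cooling is geometric
#' and stops at `t0 * t_min_ratio`. Proposals are full-vector Gaussian
#' steps with per-parameter SD `width * max(step_scale * T/T0,
#' min_step_frac)`, reflected at the bounds.
#'
#' @param t0 initial temperature (`NULL`: estimated from random draws; `0`
#'   gives pure greedy descent).
#' @param cooling geometric cooling factor per temperature stage.
#' @param steps_per_temp proposals per temperature stage.
#' @param t_min_ratio stop when `T < t0 * t_min_ratio`.
#' @param step_scale proposal SD at `T = T0`, as a fraction of bound width.
#' @param min_step_frac floor on the proposal SD fraction.
#' @param n_t0_draws random draws used to estimate `t0`.
#' @return List of class `anneal_schedule`.
#' @export
anneal_schedule <- function(t0 = NULL, cooling = 0.95, steps_per_temp = 100L,
                            t_min_ratio = 1e-3, step_scale = 0.5,
                            min_step_frac = 0.02, n_t0_draws = 50L) {
  structure(list(t0 = t0, cooling = cooling,
                 steps_per_temp = as.integer(steps_per_temp),
                 t_min_ratio = t_min_ratio, step_scale = step_scale,
                 min_step_frac = min_step_frac,
                 n_t0_draws = as.integer(n_t0_draws)),
            class = "anneal_schedule")
}

reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  for (i in seq_along(x)) {
    if (w[i] <= 0) { x[i] <- lo[i]; next }
    while (x[i] < lo[i] || x[i] > hi[i]) {
      if (x[i] < lo[i]) x[i] <- 2 * lo[i] - x[i]
      if (x[i] > hi[i]) x[i] <- 2 * hi[i] - x[i]
    }
  }
  x
}

#' Simulated annealing over a box
#'
#' Metropolis acceptance with geometric cooling; deterministic for a fixed
#' seed. Always returns the best parameter vector encountered.
#'
#' @param score_fn function from parameter vector to scalar score (lower is
#'   better).
#' @param lower,upper finite per-parameter bounds.
#' @param seed integer RNG seed.
#' @param schedule an [anneal_schedule()].
#' @param init optional starting vector; default a uniform random draw.
#' @return List with `par` (best vector), `value`, `trace` (best score per
#'   temperature stage), `n_eval`.
#' @export
anneal <- function(score_fn, lower, upper, seed = 1L,
                   schedule = anneal_schedule(), init = NULL) {
  stopifnot(all(is.finite(lower)), all(is.finite(upper)),
            all(upper >= lower))
  set.seed(seed)
  d <- length(lower)
  width <- upper - lower
  if (is.null(init)) init <- lower + runif(d) * width
  x <- pmin(pmax(init, lower), upper)
  fx <- score_fn(x)
  n_eval <- 1L
  t0 <- schedule$t0
  if (is.null(t0)) {
    draws <- vapply(seq_len(schedule$n_t0_draws),
                    function(k) score_fn(lower + runif(d) * width),
                    numeric(1))
    n_eval <- n_eval + length(draws)
    t0 <- sd(draws)
    if (!is.finite(t0) || t0 == 0) t0 <- 1
  }
  best <- x; fbest <- fx
  n_temps <- if (t0 <= 0) ceiling(log(schedule$t_min_ratio) /
                                  log(schedule$cooling))
             else ceiling(log(schedule$t_min_ratio) / log(schedule$cooling))
  trace <- numeric(0)
  temp <- t0
  for (stage in seq_len(max(n_temps, 0))) {
    frac <- if (t0 > 0) temp / t0 else 0
    step_sd <- width * max(schedule$step_scale * frac,
                           schedule$min_step_frac)
    for (k in seq_len(schedule$steps_per_temp)) {
      prop <- reflect_into(x + rnorm(d) * step_sd, lower, upper)
      fp <- score_fn(prop)
      n_eval <- n_eval + 1L
      if (fp <= fx || (temp > 0 && runif(1) < exp(-(fp - fx) / temp))) {
        x <- prop; fx <- fp
        if (fx < fbest) { best <- x; fbest <- fx }
      }
    }
    trace <- c(trace, fbest)
    temp <- temp * schedule$cooling
  }
  list(par = best, value = fbest, trace = trace, n_eval = n_eval)
}

# fast closure: fcyton parameter vector -> generational counts at `times`
make_count_fn <- function(times, g_max, dt) {
  force(times); force(g_max); force(dt)
  t_max <- max(times)
  n <- max(2L, as.integer(ceiling(t_max / dt - 1e-9)) + 1L)
  grid <- seq(0, by = dt, length.out = n)
  if (grid[n] < t_max - 1e-9) {
    n <- n + 1L
    grid <- seq(0, by = dt, length.out = n)
  }
  on_grid <- all(abs(times / dt - round(times / dt)) < 1e-9)
  idx <- round(times / dt) + 1L
  zeros <- numeric(n)  # CDF slots; only read by the competing-fates variant
  function(p) {
    s_div0 <- sqrt(log(1 + (p[6] / p[5])^2))
    s_div1 <- sqrt(log(1 + (p[8] / p[7])^2))
    s_die0 <- sqrt(log(1 + (p[10] / p[9])^2))
    s_die1 <- sqrt(log(1 + (p[12] / p[11])^2))
    m_div0 <- log(p[5]) - s_div0^2 / 2
    m_div1 <- log(p[7]) - s_div1^2 / 2
    m_die0 <- log(p[9]) - s_die0^2 / 2
    m_die1 <- log(p[11]) - s_die1^2 / 2
    Fg <- progressor_fractions(p[3], p[4], g_max)
    res <- .sim_grid_cpp(p[1], p[2], Fg,
                         dlnorm(grid, m_div0, s_div0),
                         dlnorm(grid, m_div1, s_div1),
                         dlnorm(grid, m_die0, s_die0),
                         dlnorm(grid, m_die1, s_die1),
                         zeros, zeros, zeros, zeros,
                         dt, g_max, FALSE)
    cg <- res$counts
    cg[cg < 0] <- 0
    if (on_grid) cg[, idx, drop = FALSE]
    else t(vapply(seq_len(g_max),
                  function(g) approx(grid, cg[g, ], xout = times,
                                     rule = 2)$y,
                  numeric(length(times))))
  }
}

#' Build an NPAE evaluator for population-model parameter vectors
#'
#' Renders the generational counts implied by a parameter vector through the
#' fitted per-time-point fluorescence model (the adaptor matrices) and
#' returns the [npae()] against the data time course. Used for candidate
#' scoring, sensitivity ranges and cluster filtering.
#'
#' @param tc a `cfse_timecourse`.
#' @param fluor a `fluor_fit` for the same time course.
#' @param g_max generations modelled.
#' @param dt integration step for the population model (hours).
#' @return Function: numeric parameter vector (order
#'   [fcyton_param_names()]) -> NPAE percent.
#' @export
make_npae_function <- function(tc, fluor, g_max = 8L, dt = 1) {
  D <- as_hist_matrix(tc)
  totals <- colSums(D)
  A <- lapply(fluor$fits, function(f) adaptor_matrix(f$params, tc$bin_edges))
  count_fn <- make_count_fn(tc$times, g_max, dt)
  function(par) {
    cg <- count_fn(par)
    M <- vapply(seq_along(A), function(i) drop(A[[i]] %*% cg[, i]),
                numeric(nrow(D)))
    npae(M, D, totals = totals)
  }
}

#' Integrated fit: train the population model on fluorescence histograms
#'
#' For each restart, fcyton parameters are annealed; every proposal is
#' simulated to generational counts, rendered to model histograms through
#' the fixed fitted fluorescence parameters (the adaptor), and scored
#' against the data histograms with the chosen objective. Candidates are
#' returned sorted by their final NPAE.
#'
#' @param tc a `cfse_timecourse`.
#' @param fluor a `fluor_fit` for the same time course (fixed during
#'   population fitting).
#' @param bounds 12 x 2 fcyton bounds ([default_fcyton_bounds()]).
#' @param n_restarts independent annealing restarts (default 100, as used
#'   for solution-quality estimation; full production runs use more).
#' @param objective_kind histogram objective (default `"mrsd+"`).
#' @param seed base seed; restart k uses `seed + k`.
#' @param schedule an [anneal_schedule()].
#' @param g_max,dt population-model settings.
#' @param polish polish every annealed restart with bounded quasi-Newton
#'   descent before scoring. Off by default: the downstream redundancy
#'   estimation treats the candidate ensemble as samples of the solution
#'   landscape, and deterministic descent concentrates them artificially.
#' @return List of `solution_candidate` objects (fields `params`, `score`,
#'   `npae`, `seed`, `converged`), sorted by `npae`.
#' @export
integrated_fit <- function(tc, fluor, bounds = default_fcyton_bounds(),
                           n_restarts = 100L, objective_kind = "mrsd+",
                           seed = 1L, schedule = anneal_schedule(),
                           g_max = 8L, dt = 1, polish = FALSE) {
  D <- as_hist_matrix(tc)
  A <- lapply(fluor$fits, function(f) adaptor_matrix(f$params, tc$bin_edges))
  count_fn <- make_count_fn(tc$times, g_max, dt)
  render <- function(par) {
    cg <- count_fn(par)
    vapply(seq_along(A), function(i) drop(A[[i]] %*% cg[, i]),
           numeric(nrow(D)))
  }
  score_fn <- function(par) objective_score(objective_kind, render(par), D)
  npae_fn <- make_npae_function(tc, fluor, g_max = g_max, dt = dt)
  cands <- lapply(seq_len(n_restarts), function(k) {
    fit <- anneal(score_fn, bounds[, 1], bounds[, 2], seed = seed + k,
                  schedule = schedule)
    if (polish) {
      pol <- tryCatch(
        optim(fit$par, score_fn, method = "L-BFGS-B",
              lower = bounds[, 1], upper = bounds[, 2],
              control = list(maxit = 60,
                             parscale = pmax(bounds[, 2] - bounds[, 1],
                                             1e-8))),
        error = function(e) NULL)
      if (!is.null(pol) && pol$value < fit$value) {
        fit$par <- pol$par
        fit$value <- pol$value
      }
    }
    structure(list(params = as_fcyton_params(setNames(fit$par,
                                                      fcyton_param_names())),
                   score = fit$value, npae = npae_fn(fit$par),
                   seed = seed + k, converged = TRUE),
              class = "solution_candidate")
  })
  cands[order(vapply(cands, `[[`, numeric(1), "npae"))]
}

#' Sequential fit: train the population model on generational counts
#'
#' Anneals fcyton parameters directly against a matrix of generational cell
#' counts (extracted by fluorescence fitting, or known ground truth),
#' scored by summed squared count deviation. The best restarts are polished
#' with bounded quasi-Newton descent.
#'
#' @param counts generations x time-points matrix of target cell counts.
#' @param times hours corresponding to the columns of `counts`.
#' @param bounds 12 x 2 fcyton bounds.
#' @param n_restarts annealing restarts (default 8).
#' @param objective_kind objective (default `"sd_counts"`).
#' @param seed base seed.
#' @param schedule an [anneal_schedule()].
#' @param g_max,dt population-model settings (`g_max` defaults to
#'   `nrow(counts)`).
#' @param polish_top number of best restarts refined by `optim(method =
#'   "L-BFGS-B")`.
#' @param polish_control `control` entries for the polishing `optim()`
#'   call (merged with the parameter scaling).
#' @return A `solution_candidate` (the overall best), with `converged =
#'   FALSE` when the fit is under-determined (fewer than two time points).
#' @export
sequential_fit <- function(counts, times, bounds = default_fcyton_bounds(),
                           n_restarts = 8L, objective_kind = "sd_counts",
                           seed = 1L, schedule = anneal_schedule(),
                           g_max = nrow(counts), dt = 1, polish_top = 2L,
                           polish_control = list(maxit = 100)) {
  stopifnot(is.matrix(counts), length(times) == ncol(counts))
  count_fn <- make_count_fn(times, g_max, dt)
  score_fn <- function(par) objective_score(objective_kind, count_fn(par),
                                            counts)
  fits <- lapply(seq_len(n_restarts), function(k) {
    anneal(score_fn, bounds[, 1], bounds[, 2], seed = seed + k,
           schedule = schedule)
  })
  ord <- order(vapply(fits, `[[`, numeric(1), "value"))
  fits <- fits[ord]
  for (k in seq_len(min(polish_top, length(fits)))) {
    ctrl <- utils::modifyList(
      list(maxit = 100,
           parscale = pmax(bounds[, 2] - bounds[, 1], 1e-8)),
      polish_control)
    pol <- tryCatch(
      optim(fits[[k]]$par, score_fn, method = "L-BFGS-B",
            lower = bounds[, 1], upper = bounds[, 2], control = ctrl),
      error = function(e) NULL)
    if (!is.null(pol) && pol$value < fits[[k]]$value) {
      fits[[k]]$par <- pol$par
      fits[[k]]$value <- pol$value
    }
  }
  ord <- order(vapply(fits, `[[`, numeric(1), "value"))
  best <- fits[[ord[1]]]
  structure(list(params = as_fcyton_params(setNames(best$par,
                                                    fcyton_param_names())),
                 score = best$value, npae = NA_real_, seed = seed,
                 converged = ncol(counts) >= 2),
            class = "solution_candidate")
}

#' @export
print.solution_candidate <- function(x, ...) {
  cat(sprintf("solution candidate: score = %.4g, NPAE = %s%%\n", x$score,
              if (is.na(x$npae)) "NA" else sprintf("%.2f", x$npae)))
  print(x$params)
  invisible(x)
}

#' Serialize solution candidates as JSON lines
#'
#' @param cands list of `solution_candidate`s.
#' @param path output path (one JSON object per line).
#' @export
write_candidates_jsonl <- function(cands, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cd in cands) {
    writeLines(jsonlite::toJSON(list(params = as.list(unclass(cd$params)),
                                     score = cd$score, npae = cd$npae,
                                     seed = cd$seed,
                                     converged = cd$converged),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
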