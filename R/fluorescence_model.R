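#' Gaussian parameters of one generation's fluorescence peak
#'
#' The linear-scale mean fluorescence of generation g is
#' `M_g = (i0 + s - b) * r^g + b`: the dye-derived signal halves (ratio `r`)
#' with each division on top of a constant autofluorescence background `b`,
#' with `s` a small shift correction to the anchored undivided mean `i0`.
#' On the log10 scale the peak is Gaussian with mean `log10(M_g)` and a
#' generation-invariant SD obtained from the coefficient of variation via
#' the log-normal identity `sigma = sqrt(log(1 + cv^2)) / log(10)`.
#'
#' @param p a [fluor_params()] object.
#' @param g generation index (0-based; vectorized), `0 <= g < g_max`.
#' @return List with `mu` (log10 units, strictly decreasing in g) and
#'   `sigma` (log10 units, shared across generations).
#' @export
generation_gaussian <- function(p, g) {
  stopifnot(inherits(p, "fluor_params"), all(g >= 0), all(g < p$g_max))
  M <- (p$i0 + p$s - p$b) * p$r^g + p$b
  if (any(M <= 0)) stop("non-positive generation mean fluorescence")
  list(mu = log10(M), sigma = sqrt(log(1 + p$cv^2)) / log(10))
}

#' Per-bin Gaussian mass of each generation (the adaptor matrix)
#'
#' Column g + 1 holds the probability mass of generation g's Gaussian in
#' each bin of the grid. Multiplying by a vector of generational cell
#' counts renders a model histogram; this is the linear map that lets the
#' population model be scored directly against fluorescence data.
#'
#' @param p a [fluor_params()] object.
#' @param bin_edges shared log10 bin grid.
#' @return `length(bin_edges) - 1` x `g_max` matrix.
#' @export
adaptor_matrix <- function(p, bin_edges) {
  gg <- generation_gaussian(p, seq_len(p$g_max) - 1L)
  vapply(seq_len(p$g_max),
         function(j) diff(pnorm(bin_edges, gg$mu[j], gg$sigma)),
         numeric(length(bin_edges) - 1L))
}

#' Render a weighted Gaussian-mixture model histogram
#'
#' @param p a [fluor_params()] object.
#' @param w non-negative cell count per generation (length `g_max`).
#' @param bin_edges shared log10 bin grid.
#' @return Per-bin model counts; their sum is `sum(w)` minus the (small)
#'   mixture mass falling outside the grid.
#' @export
mixture_density <- function(p, w, bin_edges) {
  stopifnot(length(w) == p$g_max, all(is.finite(w)), all(w >= 0))
  drop(adaptor_matrix(p, bin_edges) %*% w)
}

#' Analytic peak weights by non-negative least squares
#'
#' With the fluorescence parameters fixed, the model histogram is linear in
#' the generational cell counts, so the optimal weights under squared error
#' with a non-negativity constraint are found exactly (Lawson-Hanson NNLS)
#' rather than by stochastic search.
#'
#' @param p a [fluor_params()] object.
#' @param h a `cfse_histogram`.
#' @return Named non-negative weight vector (`gen0` ...), one per
#'   generation; all zero for an all-zero histogram.
#' @export
fit_peak_weights <- function(p, h) {
  stopifnot(inherits(h, "cfse_histogram"))
  nm <- paste0("gen", seq_len(p$g_max) - 1L)
  if (sum(h$counts) == 0) return(setNames(numeric(p$g_max), nm))
  A <- adaptor_matrix(p, h$bin_edges)
  w <- pracma::lsqnonneg(A, h$counts)$x
  setNames(pmax(w, 0), nm)
}

# squared-deviation objective on the free fluorescence parameters, with the
# weights profiled out analytically at every proposal
fluor_objective <- function(theta, i0, g_max, h, norm) {
  p <- tryCatch(fluor_params(theta[1], theta[2], theta[3], theta[4],
                             i0 = i0, g_max = g_max),
                error = function(e) NULL)
  if (is.null(p)) return(1e6)
  A <- adaptor_matrix(p, h$bin_edges)
  w <- pracma::lsqnonneg(A, h$counts)$x
  sum((drop(A %*% w) - h$counts)^2) / norm
}

#' Fit the fluorescence model to a single histogram
#'
#' Optimizes `(cv, r, b, s)` within bounds by quasi-Newton minimization of
#' the squared histogram deviation, profiling the peak weights out by
#' [fit_peak_weights()] at every proposal; `i0` stays anchored. Several
#' deterministic multi-starts guard against local minima.
#'
#' @param h a `cfse_histogram`.
#' @param i0 anchored undivided-population mean fluorescence (linear a.u.).
#' @param bounds 4 x 2 matrix as [default_fluor_bounds()].
#' @param g_max generations (peaks) modelled.
#' @param init optional starting vector `(cv, r, b, s)`.
#' @param n_starts additional seeded random starts beyond the bound
#'   midpoint (and `init` when given).
#' @param seed integer seed controlling the random starts.
#' @return List with `params` ([fluor_params()]), `weights`, `objective`
#'   (normalized squared deviation), `converged`.
#' @export
fit_fluorescence_histogram <- function(h, i0, bounds = default_fluor_bounds(i0),
                                       g_max = 8L, init = NULL, n_starts = 2L,
                                       seed = 1L) {
  lo <- bounds[, 1]; hi <- bounds[, 2]
  norm <- max(sum(h$counts^2), 1)
  starts <- list((lo + hi) / 2)
  if (!is.null(init)) starts <- c(list(pmin(pmax(init, lo), hi)), starts)
  if (n_starts > 0) {
    set.seed(seed)
    for (k in seq_len(n_starts))
      starts <- c(starts, list(lo + runif(4) * (hi - lo)))
  }
  obj <- function(theta) fluor_objective(theta, i0, g_max, h, norm)
  best <- NULL
  for (x0 in starts) {
    fit <- tryCatch(
      nlminb(x0, obj, lower = lo, upper = hi,
             control = list(iter.max = 150, eval.max = 250)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective))
      best <- fit
  }
  if (is.null(best)) stop("fluorescence fitting failed for all starts")
  p <- fluor_params(best$par[1], best$par[2], best$par[3], best$par[4],
                    i0 = i0, g_max = g_max)
  list(params = p, weights = fit_peak_weights(p, h),
       objective = best$objective, converged = best$convergence == 0)
}

#' Fit the fluorescence model across a time course
#'
#' Time points are fitted in order; the accepted fit at one time point
#' initializes the next and narrows its `(cv, r)` bounds to +/-10% around
#' the previous estimate (intersected with the global bounds), reflecting
#' that staining variability and the dilution ratio drift only slowly
#' between consecutive samples. Bounds are narrowed only once some previous
#' fit resolved at least two peaks: a single-peak histogram leaves `r`
#' unidentified, and propagating tight bounds around such arbitrary values
#' would corrupt every later time point. The background `b` is never
#' narrowed: it is constrained only by peaks approaching the
#' autofluorescence floor, so early estimates of it are arbitrary — and
#' where it is unidentified it is also harmless to the fit. The shift `s`
#' keeps its global bounds, and the undivided-peak anchor `i0` is fixed per
#' time point from `tc$undivided_mean`.
#'
#' @param tc a `cfse_timecourse` with `undivided_mean` set per time point.
#' @param bounds optional global 4 x 2 bounds; default
#'   [default_fluor_bounds()] evaluated at each time point's anchor.
#' @param g_max generations modelled (default 8).
#' @param narrow relative half-width of the propagated bounds (default 0.1).
#' @param seed integer seed for the multi-start initialization.
#' @return A list of class `fluor_fit`: per time point `params`, `weights`,
#'   `objective`, `converged`; plus `counts` (`g_max` x time-points matrix
#'   of fitted generational cell counts).
#' @export
fit_fluorescence_timecourse <- function(tc, bounds = NULL, g_max = 8L,
                                        narrow = 0.1, seed = 1L) {
  stopifnot(inherits(tc, "cfse_timecourse"))
  n_t <- length(tc$histograms)
  fits <- vector("list", n_t)
  prev <- NULL
  prev_multi <- FALSE
  for (t in seq_len(n_t)) {
    i0 <- tc$undivided_mean[t]
    if (!is.finite(i0)) stop("undivided_mean must be anchored per time point")
    gb <- if (is.null(bounds)) default_fluor_bounds(i0) else bounds
    b_t <- gb
    init <- NULL
    if (!is.null(prev)) {
      est <- c(prev$cv, prev$r, prev$b, prev$s)
      if (prev_multi) {
        for (i in 1:2) {  # cv and r propagate; b and s stay free
          w <- abs(est[i]) * narrow
          b_t[i, 1] <- max(gb[i, 1], est[i] - w)
          b_t[i, 2] <- min(gb[i, 2], est[i] + w)
        }
      }
      init <- est
    }
    fits[[t]] <- fit_fluorescence_histogram(tc$histograms[[t]], i0 = i0,
                                            bounds = b_t, g_max = g_max,
                                            init = init,
                                            n_starts = if (t == 1L) 2L else 1L,
                                            seed = seed + t - 1L)
    prev <- fits[[t]]$params
    w_t <- fits[[t]]$weights
    prev_multi <- prev_multi || sum(w_t > 0.01 * sum(w_t)) >= 2
  }
  counts <- vapply(fits, `[[`, numeric(g_max), "weights")
  rownames(counts) <- paste0("gen", seq_len(g_max) - 1L)
  colnames(counts) <- format(tc$times, trim = TRUE)
  structure(list(fits = fits, counts = counts, times = tc$times,
                 g_max = as.integer(g_max),
                 converged = all(vapply(fits, `[[`, logical(1), "converged"))),
            class = "fluor_fit")
}

#' @export
print.fluor_fit <- function(x, ...) {
  cat(sprintf("fluorescence fit: %d time points, g_max = %d\n",
              length(x$fits), x$g_max))
  for (i in seq_along(x$fits)) {
    p <- x$fits[[i]]$params
    cat(sprintf("  t = %6g h: cv=%.3f r=%.3f b=%.1f s=%+.1f obj=%.3g\n",
                x$times[i], p$cv, p$r, p$b, p$s, x$fits[[i]]$objective))
  }
  invisible(x)
}

#' Serialize fitted fluorescence parameters as JSON
#'
#' One record per time point: `time_h`, `cv`, `r`, `b`, `s`, `i0`,
#' `weights`.
#'
#' @param fit a `fluor_fit`.
#' @param path output path.
#' @export
write_fluor_json <- function(fit, path) {
  recs <- lapply(seq_along(fit$fits), function(i) {
    p <- fit$fits[[i]]$params
    list(time_h = fit$times[i], cv = p$cv, r = p$r, b = p$b, s = p$s,
         i0 = p$i0, weights = unname(fit$fits[[i]]$weights))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
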