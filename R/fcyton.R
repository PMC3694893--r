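#' Log-normal distribution parameterized by its mean and SD
#'
#' Lymphocyte times to divide and to die are well approximated by log-normal
#' distributions; experimental reports quote their mean and SD in hours, so
#' the underlying normal parameters are recovered by moment matching:
#' `sdlog^2 = log(1 + SD^2/E^2)`, `meanlog = log(E) - sdlog^2/2`.
#'
#' @param E distribution mean (hours, > 0).
#' @param SD distribution standard deviation (hours, > 0).
#' @return A list of class `lognormal_moments` with `meanlog`, `sdlog`,
#'   `mean`, `sd` and vectorized `pdf`/`cdf` functions over age in hours.
#' @examples
#' d <- lognormal_from_moments(30, 10)
#' integrate(d$pdf, 0, Inf)$value  # 1
#' @export
lognormal_from_moments <- function(E, SD) {
  stopifnot(E > 0, SD > 0)
  s2 <- log(1 + SD^2 / E^2)
  meanlog <- log(E) - s2 / 2
  sdlog <- sqrt(s2)
  structure(list(meanlog = meanlog, sdlog = sdlog, mean = E, sd = SD,
                 pdf = function(x) dlnorm(x, meanlog, sdlog),
                 cdf = function(x) plnorm(x, meanlog, sdlog)),
            class = "lognormal_moments")
}

#' Progressor fractions from the division-destiny distribution
#'
#' The fraction of cells in generation g committed to a further division is
#' the ratio of consecutive survivor values of the Gaussian division-destiny
#' distribution: `F_g = S(g) / S(g - 1)` with
#' `S(g) = 1 - pnorm(g, Dmu, Dsigma)`, clamped to `[0, 1]`. `F_g = 0` when
#' `S(g - 1)` vanishes.
#'
#' @param Dmu,Dsigma destiny mean and SD in generations (`Dsigma > 0`).
#' @param g_max number of modelled generations; fractions are returned for
#'   generations `1 .. g_max - 1` (the undivided fraction `F0` is an
#'   independent model parameter).
#' @return Numeric vector of length `g_max - 1` named `F1`, `F2`, ...
#' @export
progressor_fractions <- function(Dmu, Dsigma, g_max = 8L) {
  stopifnot(Dsigma > 0, g_max >= 1)
  if (g_max == 1L) return(numeric(0))
  g <- seq_len(g_max - 1L)
  S <- 1 - pnorm(c(0, g), mean = Dmu, sd = Dsigma)
  f <- ifelse(S[-length(S)] <= 0, 0, S[-1] / S[-length(S)])
  setNames(pmin(pmax(f, 0), 1), paste0("F", g))
}

#' Simulate the fcyton (or cyton) cell-population model
#'
#' Forward-simulates generational cell counts over time. In the fcyton model
#' the division and death fates are decoupled: a fraction `F0` of founders
#' responds and divides after a log-normal delay, protected from death, while
#' non-responders die; in each later generation the progressor fraction
#' `F_g` of incoming cells divides again and the remainder (cells that have
#' reached their division destiny) dies after a log-normal delay. The cyton
#' variant (`model = "cyton"`) instead races per-cell division and death
#' clocks, scaling the division flux by the survival of the death clock and
#' vice versa. Cells in the last modelled generation do not divide further
#' but their destiny-reached fraction remains exposed to death.
#'
#' @param params an [fcyton_params()] vector.
#' @param times hours at which counts are reported (within `[0, max]`).
#' @param g_max generations modelled (default 8).
#' @param dt uniform integration step in hours (default 0.5).
#' @param model `"fcyton"` (decoupled fates) or `"cyton"` (competing fates).
#' @return A list of class `count_matrix` with `counts` (`g_max` x
#'   `length(times)` matrix), `times`, `cum_divisions`, `cum_deaths`, and the
#'   call settings. At `t = 0` all `N` cells are in generation 0.
#' @examples
#' p <- fcyton_params(1e4, 0.8, 3, 1, 40, 10, 10, 4, 60, 20, 80, 30)
#' sim <- simulate_fcyton(p, times = seq(0, 144, by = 24))
#' colSums(sim$counts)  # total population over time
#' @export
simulate_fcyton <- function(params, times, g_max = 8L, dt = 0.5,
                            model = c("fcyton", "cyton")) {
  model <- match.arg(model)
  params <- as_fcyton_params(params)
  stopifnot(length(times) >= 1, all(times >= 0), dt > 0)
  t_max <- max(times)
  n <- max(2L, as.integer(ceiling(t_max / dt - 1e-9)) + 1L)
  grid <- seq(0, by = dt, length.out = n)
  if (grid[n] < t_max - 1e-9) {
    n <- n + 1L
    grid <- seq(0, by = dt, length.out = n)
  }

  d_div0 <- lognormal_from_moments(params[["Ediv0"]], params[["SDdiv0"]])
  d_div1 <- lognormal_from_moments(params[["Ediv1"]], params[["SDdiv1"]])
  d_die0 <- lognormal_from_moments(params[["Edie0"]], params[["SDdie0"]])
  d_die1 <- lognormal_from_moments(params[["Edie1"]], params[["SDdie1"]])

  Fg <- progressor_fractions(params[["Dmu"]], params[["Dsigma"]], g_max)

  res <- .sim_grid_cpp(params[["N"]], params[["F0"]], Fg,
                       d_div0$pdf(grid), d_div1$pdf(grid),
                       d_die0$pdf(grid), d_die1$pdf(grid),
                       d_div1$cdf(grid), d_die0$cdf(grid),
                       d_die1$cdf(grid), d_div0$cdf(grid),
                       dt, as.integer(g_max), model == "cyton")

  cg <- res$counts
  neg <- min(cg)
  if (neg < -1e-6 * params[["N"]])
    stop(sprintf("negative cell count (%.3g) beyond numerical tolerance", neg))
  cg[cg < 0] <- 0

  counts <- matrix(0, nrow = g_max, ncol = length(times),
                   dimnames = list(paste0("gen", seq_len(g_max) - 1L),
                                   format(times, trim = TRUE)))
  for (g in seq_len(g_max))
    counts[g, ] <- approx(grid, cg[g, ], xout = times, rule = 2)$y
  structure(list(counts = counts, times = times, g_max = as.integer(g_max),
                 dt = dt, model = model,
                 cum_divisions = approx(grid, res$cum_divisions,
                                        xout = times, rule = 2)$y,
                 cum_deaths = approx(grid, res$cum_deaths,
                                     xout = times, rule = 2)$y),
            class = "count_matrix")
}

#' @rdname simulate_fcyton
#' @export
simulate_cyton <- function(params, times, g_max = 8L, dt = 0.5) {
  simulate_fcyton(params, times, g_max = g_max, dt = dt, model = "cyton")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("%s simulation: %d generations, %d time points (dt = %g h)\n",
              x$model, x$g_max, length(x$times), x$dt))
  print(round(x$counts, 1))
  invisible(x)
}

#' Serialize a count matrix as TSV
#'
#' Columns `time_h`, `gen0` ... `genG`, `total`.
#'
#' @param sim a `count_matrix` from [simulate_fcyton()].
#' @param path output file path.
#' @export
write_counts_tsv <- function(sim, path) {
  df <- data.frame(time_h = sim$times, t(sim$counts),
                   total = colSums(sim$counts), check.names = FALSE)
  names(df) <- c("time_h", rownames(sim$counts), "total")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
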