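#' Canonical order of the cell-population model parameters
#'
#' The twelve parameters of the fcyton model: founder cell count `N`, initial
#' responding fraction `F0`, division-destiny mean and standard deviation
#' `Dmu`/`Dsigma` (generations), and mean/SD pairs (hours) of the log-normal
#' times to divide and to die for undivided (`...0`) and divided (`...1`)
#' cells.
#'
#' @return Character vector of length 12.
#' @export
fcyton_param_names <- function() {
  c("N", "F0", "Dmu", "Dsigma",
    "Ediv0", "SDdiv0", "Ediv1", "SDdiv1",
    "Edie0", "SDdie0", "Edie1", "SDdie1")
}

#' Construct a validated fcyton parameter set
#'
#' @param N founder cell count (> 0).
#' @param F0 fraction of undivided cells that respond to the stimulus, in
#'   `[0, 1]`. Responders are committed to division and protected from death.
#' @param Dmu,Dsigma mean and SD, in generations, of the Gaussian
#'   division-destiny distribution limiting how many times a lineage divides.
#' @param Ediv0,SDdiv0 mean and SD (hours) of the log-normal time to first
#'   division of undivided cells.
#' @param Ediv1,SDdiv1 mean and SD (hours) of the log-normal time to divide
#'   of cells that have divided at least once.
#' @param Edie0,SDdie0 mean and SD (hours) of the log-normal time to die of
#'   undivided non-responding cells.
#' @param Edie1,SDdie1 mean and SD (hours) of the log-normal time to die of
#'   divided cells that have reached their division destiny.
#'
#' @return A named numeric vector of class `fcyton_params`.
#' @examples
#' p <- fcyton_params(N = 1e4, F0 = 0.9, Dmu = 3.5, Dsigma = 1,
#'                    Ediv0 = 40, SDdiv0 = 10, Ediv1 = 10, SDdiv1 = 4,
#'                    Edie0 = 60, SDdie0 = 20, Edie1 = 80, SDdie1 = 30)
#' @export
fcyton_params <- function(N, F0, Dmu, Dsigma, Ediv0, SDdiv0, Ediv1, SDdiv1,
                          Edie0, SDdie0, Edie1, SDdie1) {
  p <- c(N = N, F0 = F0, Dmu = Dmu, Dsigma = Dsigma,
         Ediv0 = Ediv0, SDdiv0 = SDdiv0, Ediv1 = Ediv1, SDdiv1 = SDdiv1,
         Edie0 = Edie0, SDdie0 = SDdie0, Edie1 = Edie1, SDdie1 = SDdie1)
  validate_fcyton_params(p)
  structure(p, class = "fcyton_params")
}

#' @rdname fcyton_params
#' @param x a named numeric vector with the twelve entries of
#'   [fcyton_param_names()].
#' @export
as_fcyton_params <- function(x) {
  x <- unclass(x)[fcyton_param_names()]
  if (anyNA(x)) stop("missing fcyton parameter(s): ",
                     paste(fcyton_param_names()[is.na(x)], collapse = ", "))
  names(x) <- fcyton_param_names()
  validate_fcyton_params(x)
  structure(x, class = "fcyton_params")
}

validate_fcyton_params <- function(p) {
  if (p[["N"]] <= 0) stop("N must be positive")
  if (p[["F0"]] < 0 || p[["F0"]] > 1) stop("F0 must lie in [0, 1]")
  timing <- p[c("Ediv0", "SDdiv0", "Ediv1", "SDdiv1",
                "Edie0", "SDdie0", "Edie1", "SDdie1")]
  if (any(timing <= 0)) stop("timing means and SDs must be positive")
  if (p[["Dsigma"]] <= 0) stop("Dsigma must be positive")
  invisible(p)
}

#' Construct a fluorescence model parameter set
#'
#' Time-independent model of log10 CFSE fluorescence: generation g is a
#' Gaussian with linear-scale mean `(i0 + s - b) * r^g + b` and a
#' generation-invariant coefficient of variation `cv`.
#'
#' @param cv coefficient of variation of fluorescence within a generation
#'   (dimensionless, > 0).
#' @param r dye halving ratio per division, around 0.5; in (0, 1).
#' @param b background autofluorescence on the linear scale (a.u., >= 0).
#' @param s additive shift correction (a.u.) applied to the anchored
#'   undivided-population fluorescence; may be negative.
#' @param i0 anchored linear-scale mean fluorescence of the undivided
#'   population (a.u.), typically set manually per time point.
#' @param g_max number of modelled generations (peaks), default 8.
#'
#' @return A list of class `fluor_params`.
#' @export
fluor_params <- function(cv, r, b, s = 0, i0, g_max = 8L) {
  if (cv <= 0) stop("cv must be positive")
  if (r <= 0 || r >= 1) stop("r must lie in (0, 1)")
  if (b < 0) stop("b must be non-negative")
  if (i0 + s <= b)
    stop("i0 + s must exceed b so every generation mean is positive")
  if (g_max < 1) stop("g_max must be at least 1")
  structure(list(cv = cv, r = r, b = b, s = s, i0 = i0,
                 g_max = as.integer(g_max)),
            class = "fluor_params")
}

#' Default box constraints for fcyton model fitting
#'
#' The same ranges are used to draw ground-truth parameters in the synthetic
#' generator and to constrain fitting, so that benchmark fits are restricted
#' to the regime the data were generated from.
#'
#' @return A 12 x 2 matrix (columns `lower`, `upper`) in the order of
#'   [fcyton_param_names()].
#' @export
default_fcyton_bounds <- function() {
  b <- rbind(N      = c(1e3, 1e5),
             F0     = c(0, 1),
             Dmu    = c(1, 10),
             Dsigma = c(0.1, 3),
             Ediv0  = c(5, 150), SDdiv0 = c(5, 150),
             Ediv1  = c(5, 150), SDdiv1 = c(5, 150),
             Edie0  = c(5, 150), SDdie0 = c(5, 150),
             Edie1  = c(5, 150), SDdie1 = c(5, 150))
  colnames(b) <- c("lower", "upper")
  b
}

#' Default box constraints for the free fluorescence parameters
#'
#' @param i0 anchored undivided-population fluorescence; the shift bound
#'   scales with it.
#' @return A 4 x 2 matrix with rows `cv`, `r`, `b`, `s`.
#' @export
default_fluor_bounds <- function(i0) {
  b <- rbind(cv = c(0.10, 0.35),
             r  = c(0.45, 0.55),
             b  = c(50, 500),
             s  = c(-0.1, 0.1) * i0)
  colnames(b) <- c("lower", "upper")
  b
}

#' @export
print.fcyton_params <- function(x, ...) {
  cat("fcyton parameters:\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' @export
print.fluor_params <- function(x, ...) {
  cat(sprintf(
    "fluorescence model: cv=%.3f r=%.3f b=%.1f s=%.1f i0=%.1f g_max=%d\n",
    x$cv, x$r, x$b, x$s, x$i0, x$g_max))
  invisible(x)
}
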