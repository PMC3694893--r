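#' End-to-end phenotyping of a CFSE time course
#'
#' Runs the full three-step workflow on a histogram time course: (1) fit the
#' fluorescence model per time point, (2) repeatedly train the population
#' model on the histograms via the fitted fluorescence adaptor, (3) filter
#' candidates by NPAE, estimate per-parameter sensitivity ranges, cluster
#' into non-redundant maximum-likelihood ranges, and apply the final
#' resampling filter. All stage outputs (and the seeds that produced them)
#' are returned, and optionally persisted to `output_dir`.
#'
#' @param tc a `cfse_timecourse` (e.g. from [read_histogram_csv()] or the
#'   synthetic generator).
#' @param bounds 12 x 2 fcyton bounds.
#' @param n_restarts population-model fit repetitions (default 100).
#' @param objective_kind histogram objective for integrated fitting.
#' @param g_max generations modelled.
#' @param dt population-model integration step (hours).
#' @param seed base seed recorded in the report.
#' @param schedule an [anneal_schedule()].
#' @param sensitivity_tol NPAE increase defining sensitivity ranges.
#' @param filter_window candidate NPAE filter window (points).
#' @param final_samples draws per cluster in the final filter.
#' @param final_window final-filter NPAE window (points).
#' @param output_dir optional directory for persisted intermediates
#'   (`fluor.json`, `cands.jsonl`, `clusters.json`, `manifest.json`).
#' @param verbose print stage progress.
#' @return A list of class `phenotype_report`: `fluor`, `candidates`,
#'   `kept`, `ranges`, `clusters` (after the final filter), `best`
#'   (best cluster), `seed`, `config`.
#' @export
run_phenotyping <- function(tc, bounds = default_fcyton_bounds(),
                            n_restarts = 100L, objective_kind = "mrsd+",
                            g_max = 8L, dt = 1, seed = 1L,
                            schedule = anneal_schedule(),
                            sensitivity_tol = 1.0, filter_window = 0.1,
                            final_samples = 1000L, final_window = 1.0,
                            output_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(tc, "cfse_timecourse"))
  say <- function(...) if (verbose) message(sprintf(...))

  say("step 1: fluorescence model (%d time points)", length(tc$times))
  fluor <- fit_fluorescence_timecourse(tc, g_max = g_max, seed = seed)

  say("step 2: population model, %d restarts", n_restarts)
  cands <- integrated_fit(tc, fluor, bounds = bounds,
                          n_restarts = n_restarts,
                          objective_kind = objective_kind, seed = seed,
                          schedule = schedule, g_max = g_max, dt = dt)

  say("step 3: filtering, sensitivity, clustering")
  kept <- filter_candidates(cands, window = filter_window)
  npae_fn <- make_npae_function(tc, fluor, g_max = g_max, dt = dt)
  ranges <- lapply(kept, function(cd) {
    sensitivity_range(unclass(cd$params), npae_fn, bounds,
                      base_npae = cd$npae, tol = sensitivity_tol)
  })
  clusters <- cluster_candidates(kept, ranges)
  clusters <- final_filter(clusters, npae_fn, n_samples = final_samples,
                           seed = seed, window = final_window)

  report <- structure(
    list(fluor = fluor, candidates = cands, kept = kept, ranges = ranges,
         clusters = clusters, best = clusters[[1]], seed = seed,
         config = list(n_restarts = n_restarts,
                       objective_kind = objective_kind, g_max = g_max,
                       dt = dt, sensitivity_tol = sensitivity_tol,
                       filter_window = filter_window,
                       final_samples = final_samples,
                       final_window = final_window, bounds = bounds)),
    class = "phenotype_report")

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_fluor_json(fluor, file.path(output_dir, "fluor.json"))
    write_candidates_jsonl(cands, file.path(output_dir, "cands.jsonl"))
    write_cluster_json(clusters, file.path(output_dir, "clusters.json"))
    jsonlite::write_json(list(seed = seed, n_restarts = n_restarts,
                              objective = objective_kind, g_max = g_max,
                              dt = dt,
                              bounds = apply(bounds, 1, unname,
                                             simplify = FALSE)),
                         file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.phenotype_report <- function(x, ...) {
  cat(sprintf(
    "phenotype report: %d candidate(s), %d kept, %d cluster(s); seed %d\n",
    length(x$candidates), length(x$kept), length(x$clusters), x$seed))
  cat(sprintf("best cluster (NPAE %.2f%%, median %.2f%%):\n", x$best$npae,
              x$best$median_npae))
  print(round(cbind(lower = x$best$ranges[, 1], average = x$best$average,
                    upper = x$best$ranges[, 2]), 4))
  invisible(x)
}

chimera_groups <- list(
  F0 = "F0",
  F1plus = c("Dmu", "Dsigma"),
  Tdivs = c("Ediv0", "SDdiv0", "Ediv1", "SDdiv1"),
  Tdies = c("Edie0", "SDdie0", "Edie1", "SDdie1"))

#' Simulate a chimeric parameter set
#'
#' Copies named parameter groups from phenotype `b` into a copy of
#' phenotype `a` and simulates the population model, to dissect which
#' cellular processes drive a phenotype difference. Groups: `F0` (initial
#' responding fraction), `F1plus` (division destiny `Dmu`, `Dsigma`),
#' `Tdivs` (all division timing parameters), `Tdies` (all death timing
#' parameters).
#'
#' @param a,b [fcyton_params()] vectors (recipient and donor).
#' @param groups non-empty subset of `c("F0", "F1plus", "Tdivs", "Tdies")`.
#' @param times hours at which to report counts.
#' @param g_max,dt simulation settings.
#' @return A `count_matrix` for the chimera (see [simulate_fcyton()]);
#'   the chimeric parameters are attached as attribute `params`.
#' @export
chimeric_simulate <- function(a, b, groups, times, g_max = 8L, dt = 0.5) {
  if (length(groups) == 0) stop("groups must be a non-empty subset")
  unknown <- setdiff(groups, names(chimera_groups))
  if (length(unknown) > 0)
    stop("unknown chimera group(s): ", paste(unknown, collapse = ", "))
  pa <- unclass(as_fcyton_params(a))
  pb <- unclass(as_fcyton_params(b))
  for (g in groups) pa[chimera_groups[[g]]] <- pb[chimera_groups[[g]]]
  sim <- simulate_fcyton(as_fcyton_params(pa), times, g_max = g_max,
                         dt = dt)
  attr(sim, "params") <- as_fcyton_params(pa)
  sim
}

#' Export plotting-ready tables for a solution cluster
#'
#' Samples parameter sets from the cluster ranges and tabulates (i) the
#' progressor fraction per generation, (ii) the four log-normal timing
#' densities on an hourly grid (each normalized to its own maximum), and
#' (iii) generational and total count trajectories — the data behind
#' standard solution-cluster visualizations, with no plotting dependency.
#'
#' @param cluster a `solution_cluster`.
#' @param n number of sampled parameter sets (default 250).
#' @param seed integer seed.
#' @param times trajectory time points (hours).
#' @param g_max,dt simulation settings.
#' @param hours age grid for the timing densities.
#' @param output_dir optional directory; writes `fs.tsv`,
#'   `timing_pdfs.tsv`, `trajectories.tsv`.
#' @return List of data frames `fs`, `timing_pdfs`, `trajectories` (empty
#'   data frames when `n = 0`).
#' @export
export_visual_data <- function(cluster, n = 250L, seed = 1L,
                               times = seq(0, 144, by = 12), g_max = 8L,
                               dt = 0.5, hours = seq(0, 150, by = 2),
                               output_dir = NULL) {
  if (n == 0L) {
    out <- list(fs = data.frame(), timing_pdfs = data.frame(),
                trajectories = data.frame())
  } else {
    draws <- sample_cluster(cluster, n, seed = seed)
    fs <- do.call(rbind, lapply(seq_len(n), function(k) {
      p <- draws[k, ]
      data.frame(sample = k, generation = seq_len(g_max) - 1L,
                 F = c(p[["F0"]],
                       progressor_fractions(p[["Dmu"]], p[["Dsigma"]],
                                            g_max)))
    }))
    dists <- c(div0 = "Ediv0", div1 = "Ediv1", die0 = "Edie0",
               die1 = "Edie1")
    timing <- do.call(rbind, lapply(seq_len(n), function(k) {
      p <- draws[k, ]
      do.call(rbind, lapply(names(dists), function(dn) {
        e <- p[[dists[[dn]]]]
        s <- p[[sub("^E", "SD", dists[[dn]])]]
        d <- lognormal_from_moments(e, s)$pdf(hours)
        data.frame(sample = k, distribution = dn, hours = hours,
                   density = d / max(d, 1e-300))
      }))
    }))
    traj <- do.call(rbind, lapply(seq_len(n), function(k) {
      sim <- simulate_fcyton(as_fcyton_params(draws[k, ]), times,
                             g_max = g_max, dt = dt)
      data.frame(sample = k, time_h = times, t(sim$counts),
                 total = colSums(sim$counts), check.names = FALSE)
    }))
    out <- list(fs = fs, timing_pdfs = timing, trajectories = traj)
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out))
      write.table(out[[nm]], file.path(output_dir, paste0(nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
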