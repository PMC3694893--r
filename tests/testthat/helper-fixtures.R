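# shared fixtures: a realistic B-cell-like ground truth and fast settings

bcell_truth <- function() {
  fcyton_params(N = 1e4, F0 = 0.9, Dmu = 3.5, Dsigma = 1,
                Ediv0 = 40, SDdiv0 = 10, Ediv1 = 10, SDdiv1 = 6,
                Edie0 = 60, SDdie0 = 20, Edie1 = 80, SDdie1 = 30)
}

low_cv_fluor <- function(i0 = 5e4, g_max = 8L) {
  fluor_params(cv = 0.18, r = 0.5, b = 100, s = 0, i0 = i0, g_max = g_max)
}

# annealing schedule small enough for unit tests
quick_schedule <- function() {
  anneal_schedule(cooling = 0.85, steps_per_temp = 25L, t_min_ratio = 1e-2,
                  n_t0_draws = 20L)
}

# reduced-budget schedule used for fitting experiments
reduced_schedule <- function() {
  anneal_schedule(cooling = 0.9, steps_per_temp = 40L, t_min_ratio = 1 / 500)
}

# a synthetic candidate with explicit ranges, for clustering tests
make_candidate <- function(params, npae) {
  structure(list(params = params, score = npae, npae = npae, seed = 0L,
                 converged = TRUE),
            class = "solution_candidate")
}

# a bare cluster object for filter/sampling tests
new_cluster_for_test <- function(ranges, npae) {
  structure(list(members = 1L, ranges = ranges,
                 average = rowMeans(ranges), npae = npae,
                 median_npae = NA_real_),
            class = "solution_cluster")
}
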