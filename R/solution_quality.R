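#' Filter solution candidates by NPAE score
#'
#' Keeps candidates whose NPAE is within `window` percentage points of the
#' best candidate's NPAE.
#'
#' @param cands non-empty list of `solution_candidate`s with `npae` set.
#' @param window score window in NPAE points (default 0.1), or as a
#'   fraction of the best NPAE when `relative = TRUE`.
#' @param relative interpret `window` relative to the best score instead
#'   of as absolute percentage points.
#' @return The kept candidates (at least the best one).
#' @export
filter_candidates <- function(cands, window = 0.1, relative = FALSE) {
  stopifnot(length(cands) >= 1)
  scores <- vapply(cands, `[[`, numeric(1), "npae")
  cut <- if (relative) min(scores) * (1 + window) else min(scores) + window
  cands[scores <= cut]
}

#' One-dimensional parameter sensitivity ranges
#'
#' For each parameter independently, bisects outward from the point
#' estimate (within the global bounds) for the value at which the NPAE
#' rises by `tol` percentage points above the candidate's own score, all
#' other parameters held fixed. If the global bound is reached without
#' crossing, the range endpoint is the bound: the parameter is insensitive
#' in that direction. Along a non-monotone NPAE ray the bisection returns
#' the first bracketed crossing.
#'
#' @param par candidate parameter vector (order [fcyton_param_names()], or
#'   any vector matching `bounds`).
#' @param npae_fn scalar NPAE function of the full parameter vector, e.g.
#'   from [make_npae_function()].
#' @param bounds p x 2 matrix of global bounds.
#' @param base_npae candidate NPAE; computed from `npae_fn(par)` if `NULL`.
#' @param tol NPAE increase defining the range (default 1 point); `tol = 0`
#'   collapses the range onto the point estimate.
#' @param rel_tol relative bisection bracket tolerance (default 1e-3 of the
#'   bound width).
#' @return p x 2 matrix (`lower`, `upper`) with
#'   `lower <= par <= upper` elementwise.
#' @export
sensitivity_range <- function(par, npae_fn, bounds, base_npae = NULL,
                              tol = 1.0, rel_tol = 1e-3) {
  p <- length(par)
  stopifnot(nrow(bounds) == p)
  if (is.null(base_npae)) base_npae <- npae_fn(par)
  target <- base_npae + tol
  out <- matrix(NA_real_, p, 2,
                dimnames = list(rownames(bounds), c("lower", "upper")))
  for (i in seq_len(p)) {
    for (side in 1:2) {
      bound <- bounds[i, side]
      if (tol <= 0) { out[i, side] <- par[i]; next }
      at <- function(v) { x <- par; x[i] <- v; npae_fn(x) }
      if (at(bound) <= target) {  # insensitive out to the bound
        out[i, side] <- bound
        next
      }
      a <- par[i]; b <- bound  # f(a) <= target < f(b): bisect the crossing
      eps <- rel_tol * (bounds[i, 2] - bounds[i, 1])
      while (abs(b - a) > eps) {
        mid <- (a + b) / 2
        if (at(mid) <= target) a <- mid else b <- mid
      }
      out[i, side] <- a
    }
  }
  out
}

new_cluster <- function(members, ranges, average, npae) {
  structure(list(members = members, ranges = ranges, average = average,
                 npae = npae, median_npae = NA_real_),
            class = "solution_cluster")
}

#' @export
print.solution_cluster <- function(x, ...) {
  cat(sprintf("solution cluster: %d member(s), best NPAE %.2f%%%s\n",
              length(x$members), x$npae,
              if (is.na(x$median_npae)) ""
              else sprintf(", median NPAE %.2f%%", x$median_npae)))
  print(round(cbind(x$ranges[, 1, drop = FALSE], average = x$average,
                    x$ranges[, 2, drop = FALSE]), 4))
  invisible(x)
}

# total normalized overlap between two range sets; NA when any parameter
# fails to overlap
range_overlap <- function(ra, rb) {
  lo <- pmax(ra[, 1], rb[, 1])
  hi <- pmin(ra[, 2], rb[, 2])
  if (any(hi < lo)) return(NA_real_)
  union_lo <- pmin(ra[, 1], rb[, 1])
  union_hi <- pmax(ra[, 2], rb[, 2])
  len_u <- union_hi - union_lo
  frac <- ifelse(len_u <= 0, 1, (hi - lo) / len_u)  # both degenerate: full
  sum(frac)
}

# merged average: per parameter, the two cluster averages are combined with
# weight proportional to each one's distance from the overlap midpoint (the
# farther average pulls harder), then clamped into the overlap
merge_average <- function(avg_a, avg_b, ov_lo, ov_hi) {
  mid <- (ov_lo + ov_hi) / 2
  da <- abs(avg_a - mid); db <- abs(avg_b - mid)
  w <- ifelse(da + db <= 0, 0.5, da / (da + db))
  pmin(pmax(w * avg_a + (1 - w) * avg_b, ov_lo), ov_hi)
}

#' Agglomerative clustering of candidate sensitivity ranges
#'
#' Candidates whose sensitivity ranges overlap in every parameter describe
#' the same solution region; the pair of clusters with the highest total
#' normalized overlap (summed per-parameter overlap/union length) is merged
#' repeatedly until no all-parameter-overlapping pair remains. Merged
#' ranges are the per-parameter intersections, so they tighten as members
#' accumulate; the cluster average stays inside the overlap, weighted
#' toward the farther of the two merged averages. Ties are broken by lowest
#' member NPAE, then input order, so the result is deterministic.
#'
#' @param cands list of `solution_candidate`s.
#' @param ranges list of sensitivity-range matrices (one per candidate,
#'   from [sensitivity_range()]).
#' @return List of `solution_cluster`s (fields `members` — input indices,
#'   `ranges`, `average`, `npae` — best member NPAE).
#' @export
cluster_candidates <- function(cands, ranges) {
  stopifnot(length(cands) == length(ranges), length(cands) >= 1)
  cl <- lapply(seq_along(cands), function(i) {
    new_cluster(i, ranges[[i]], unclass(cands[[i]]$params), cands[[i]]$npae)
  })
  repeat {
    n <- length(cl)
    if (n < 2) break
    best <- NULL
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        ov <- range_overlap(cl[[i]]$ranges, cl[[j]]$ranges)
        if (is.na(ov)) next
        key <- c(ov, -min(cl[[i]]$npae, cl[[j]]$npae))
        if (is.null(best) || key[1] > best$key[1] + 1e-12 ||
            (abs(key[1] - best$key[1]) <= 1e-12 && key[2] > best$key[2]))
          best <- list(i = i, j = j, key = key)
      }
    }
    if (is.null(best)) break
    a <- cl[[best$i]]; b <- cl[[best$j]]
    ov_lo <- pmax(a$ranges[, 1], b$ranges[, 1])
    ov_hi <- pmin(a$ranges[, 2], b$ranges[, 2])
    merged <- new_cluster(c(a$members, b$members),
                          cbind(lower = ov_lo, upper = ov_hi),
                          merge_average(a$average, b$average, ov_lo, ov_hi),
                          min(a$npae, b$npae))
    cl[[best$i]] <- merged
    cl[[best$j]] <- NULL
  }
  cl[order(vapply(cl, `[[`, numeric(1), "npae"))]
}

#' Resampling-based final cluster filter
#'
#' Draws parameter vectors uniformly and independently per parameter within
#' each cluster's ranges, scores their NPAE, and keeps clusters whose
#' median sampled NPAE is within `window` points of the best cluster's
#' median. Removes clusters whose ranges admit unrealistic parameter
#' combinations despite good point fits.
#'
#' @param clusters list of `solution_cluster`s.
#' @param npae_fn NPAE evaluator from [make_npae_function()].
#' @param n_samples draws per cluster (default 1000).
#' @param seed integer seed (deterministic medians).
#' @param window NPAE window in points (default 1.0).
#' @return The kept clusters, each with `median_npae` filled in.
#' @export
final_filter <- function(clusters, npae_fn, n_samples = 1000L, seed = 1L,
                         window = 1.0) {
  stopifnot(length(clusters) >= 1)
  meds <- numeric(length(clusters))
  for (ci in seq_along(clusters)) {
    draws <- sample_cluster(clusters[[ci]], n_samples, seed = seed + ci)
    meds[ci] <- median(apply(draws, 1, npae_fn))
    clusters[[ci]]$median_npae <- meds[ci]
  }
  clusters[meds <= min(meds) + window]
}

#' Sample parameter vectors uniformly from a cluster's ranges
#'
#' @param cluster a `solution_cluster`.
#' @param n number of draws.
#' @param seed integer seed.
#' @return n x p matrix; every row lies inside the cluster ranges
#'   (degenerate ranges yield the point estimate).
#' @export
sample_cluster <- function(cluster, n, seed = 1L) {
  set.seed(seed)
  lo <- cluster$ranges[, 1]; hi <- cluster$ranges[, 2]
  p <- length(lo)
  m <- matrix(runif(n * p), nrow = n)
  out <- sweep(sweep(m, 2, hi - lo, `*`), 2, lo, `+`)
  colnames(out) <- rownames(cluster$ranges)
  out
}

#' Serialize clusters as a JSON report
#'
#' @param clusters list of `solution_cluster`s.
#' @param path output path.
#' @export
write_cluster_json <- function(clusters, path) {
  recs <- lapply(clusters, function(cl) {
    list(members = cl$members,
         ranges = setNames(lapply(seq_len(nrow(cl$ranges)),
                                  function(i) unname(cl$ranges[i, ])),
                           rownames(cl$ranges)),
         average = as.list(cl$average), npae = cl$npae,
         median_npae = cl$median_npae)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
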