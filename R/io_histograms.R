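#' Read flow-cytometry events from an FCS or CSV file
#'
#' Supports FCS 3.0/3.1 list-mode files (float, double or integer data) via a
#' lightweight built-in parser, and two-column CSV files
#' (`fluorescence[, viability]`). Only the named channels are retained.
#'
#' @param path file path. FCS files are recognized by their `FCS3.` magic
#'   bytes; anything else is parsed as CSV.
#' @param fl_channel fluorescence channel name (e.g. `"FL1-A"`). For CSV
#'   input the default is the first column.
#' @param viability_channel optional viability channel name (e.g. PI on
#'   `"FL3-A"`); for CSV input, the second column when present.
#' @param time_h collection time in hours to attach to the events.
#' @return A list of class `event_table` with numeric `fluorescence`,
#'   optional `viability`, and `time_h`.
#' @export
read_events <- function(path, fl_channel = NULL, viability_channel = NULL,
                        time_h = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  magic <- readBin(path, "raw", n = 6L)
  if (length(magic) == 0L) stop("empty file: ", path)
  if (identical(rawToChar(magic[1:4]), "FCS3")) {
    fcs <- read_fcs(path)
    chans <- colnames(fcs)
    pick <- function(ch) {
      if (!ch %in% chans)
        stop(sprintf("unknown channel '%s'; available channels: %s",
                     ch, paste(chans, collapse = ", ")))
      fcs[, ch]
    }
    if (is.null(fl_channel))
      stop("fl_channel is required for FCS input; available channels: ",
           paste(chans, collapse = ", "))
    fl <- pick(fl_channel)
    vi <- if (is.null(viability_channel)) NULL else pick(viability_channel)
  } else {
    df <- read.csv(path, header = looks_like_header(path))
    if (nrow(df) == 0L) stop("no events in ", path)
    fl <- as.numeric(df[[1]])
    vi <- if (ncol(df) >= 2) as.numeric(df[[2]]) else NULL
    if (!is.null(viability_channel) && ncol(df) < 2)
      stop("viability channel requested but CSV has a single column")
  }
  event_table(fl, vi, time_h)
}

looks_like_header <- function(path) {
  first <- readLines(path, n = 1L)
  is.na(suppressWarnings(as.numeric(strsplit(first, ",")[[1]][1])))
}

#' @rdname read_events
#' @param fluorescence,viability numeric event vectors (viability may be
#'   `NULL`).
#' @export
event_table <- function(fluorescence, viability = NULL, time_h = NA_real_) {
  if (length(fluorescence) < 1L) stop("at least one event is required")
  if (!is.null(viability) && length(viability) != length(fluorescence))
    stop("viability must match fluorescence length")
  structure(list(fluorescence = as.numeric(fluorescence),
                 viability = if (is.null(viability)) NULL
                             else as.numeric(viability),
                 time_h = time_h),
            class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("event table: %d events%s%s\n", length(x$fluorescence),
              if (is.null(x$viability)) "" else " (+viability)",
              if (is.na(x$time_h)) "" else sprintf(", t = %g h", x$time_h)))
  invisible(x)
}

# --- minimal FCS 3.0/3.1 list-mode parser -------------------------------

read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", n = 58L))
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("unsupported FCS version: ", version)
  off <- function(i) as.integer(trimws(substr(header, 11 + 8 * i, 18 + 8 * i)))
  text_beg <- off(0); text_end <- off(1)
  data_beg <- off(2); data_end <- off(3)

  seek(con, text_beg)
  txt <- rawToChar(readBin(con, "raw", n = text_end - text_beg + 1L))
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substr(txt, 2, nchar(txt)), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- toupper(trimws(parts[seq(1, length(parts), by = 2)]))
  vals <- parts[seq(2, length(parts), by = 2)]
  kw <- setNames(vals, keys)

  if (data_beg == 0L) data_beg <- as.integer(kw[["$BEGINDATA"]])
  if (data_end == 0L) data_end <- as.integer(kw[["$ENDDATA"]])
  n_par <- as.integer(kw[["$PAR"]])
  n_tot <- as.integer(kw[["$TOT"]])
  dtype <- toupper(kw[["$DATATYPE"]])
  endian <- if (startsWith(kw[["$BYTEORD"]], "1")) "little" else "big"
  if (!identical(toupper(kw[["$MODE"]]), "L"))
    stop("only list-mode ($MODE L) FCS data is supported")

  seek(con, data_beg)
  n_values <- n_par * n_tot
  data <- switch(dtype,
    F = readBin(con, "numeric", n = n_values, size = 4L, endian = endian),
    D = readBin(con, "numeric", n = n_values, size = 8L, endian = endian),
    I = {
      bits <- as.integer(kw[[sprintf("$P%dB", 1L)]])
      readBin(con, "integer", n = n_values, size = bits / 8L,
              signed = bits > 16L, endian = endian)
    },
    stop("unsupported $DATATYPE: ", dtype))
  if (length(data) < n_values)
    stop("truncated FCS data segment in ", path)
  chan_names <- vapply(seq_len(n_par), function(i) {
    nm <- kw[sprintf("$P%dN", i)]
    if (is.na(nm)) sprintf("P%d", i) else unname(nm)
  }, character(1))
  matrix(data, ncol = n_par, byrow = TRUE,
         dimnames = list(NULL, chan_names))
}

#' Write a minimal FCS 3.0 file
#'
#' List-mode, 32-bit float, little-endian. Primarily intended for writing
#' synthetic event data in tests and examples.
#'
#' @param data numeric matrix (events x channels) with channel names as
#'   column names.
#' @param path output path.
#' @export
write_fcs <- function(data, path) {
  data <- as.matrix(data)
  if (is.null(colnames(data)))
    colnames(data) <- sprintf("P%d", seq_len(ncol(data)))
  n_par <- ncol(data); n_tot <- nrow(data)
  kv <- c("$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
          "$PAR", n_par, "$TOT", n_tot, "$NEXTDATA", "0")
  for (i in seq_len(n_par)) {
    kv <- c(kv, sprintf("$P%dN", i), colnames(data)[i],
            sprintf("$P%dB", i), "32", sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), format(ceiling(max(data[, i], 1)),
                                        scientific = FALSE))
  }
  # reserve room for $BEGINDATA/$ENDDATA, then fix up offsets
  build_text <- function(beg, end) {
    paste0("/", paste(c(kv, "$BEGINDATA", sprintf("%10d", beg),
                        "$ENDDATA", sprintf("%10d", end)),
                      collapse = "/"), "/")
  }
  text0 <- build_text(0L, 0L)
  text_beg <- 58L
  text_end <- text_beg + nchar(text0) - 1L
  data_beg <- text_end + 1L
  data_end <- data_beg + 4L * n_par * n_tot - 1L
  txt <- build_text(data_beg, data_end)
  stopifnot(nchar(txt) == nchar(text0))
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_beg, text_end, data_beg, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(txt), con)
  writeBin(as.numeric(t(data)), con, size = 4L, endian = "little")
  invisible(path)
}

# --- gating and binning --------------------------------------------------

#' Gate viable events on a viability channel
#'
#' Keeps events whose viability-channel intensity is below the threshold
#' (PI-negative convention: dead cells take up propidium iodide and
#' fluoresce brightly).
#'
#' @param events an [event_table()].
#' @param threshold linear-scale intensity; events with
#'   `viability < threshold` are kept.
#' @return A gated `event_table` (viability channel retained).
#' @export
gate_viable <- function(events, threshold) {
  stopifnot(inherits(events, "event_table"))
  if (is.null(events$viability))
    stop("no viability channel present; skip gating for this sample")
  keep <- events$viability < threshold
  if (!any(keep)) {
    warning("viability gate removed all events")
    return(structure(list(fluorescence = numeric(0), viability = numeric(0),
                          time_h = events$time_h), class = "event_table"))
  }
  event_table(events$fluorescence[keep], events$viability[keep],
              events$time_h)
}

#' Bin events into a log10-fluorescence histogram
#'
#' Non-positive intensities are clamped to a tiny positive value before the
#' log transform (rather than dropped) so binning conserves the instrument
#' event count; events falling outside `log_range` accumulate into the
#' terminal bins.
#'
#' @param events an [event_table()].
#' @param n_bins number of uniform bins (>= 16; default 256).
#' @param log_range `c(lo, hi)` in log10 fluorescence units. Bins are
#'   half-open `[edge_i, edge_{i+1})`.
#' @param run_id replicate label.
#' @return A list of class `cfse_histogram` with `bin_edges`, `counts`,
#'   `time_h`, `run_id`.
#' @export
build_histogram <- function(events, n_bins = 256L, log_range, run_id = 1L) {
  stopifnot(inherits(events, "event_table"), n_bins >= 16L,
            log_range[1] < log_range[2])
  fl <- pmax(events$fluorescence, 1e-12)
  lx <- log10(fl)
  edges <- seq(log_range[1], log_range[2], length.out = n_bins + 1L)
  idx <- findInterval(lx, edges, rightmost.closed = FALSE, left.open = FALSE)
  idx <- pmin(pmax(idx, 1L), n_bins)  # terminal-bin accumulation
  counts <- tabulate(idx, nbins = n_bins)
  new_histogram(edges, counts, events$time_h, run_id)
}

#' @rdname build_histogram
#' @param bin_edges strictly increasing, uniform-width log10 bin edges.
#' @param counts non-negative per-bin counts (`length(bin_edges) - 1`).
#' @param time_h hours post stimulation.
#' @export
new_histogram <- function(bin_edges, counts, time_h, run_id = 1L) {
  stopifnot(length(counts) == length(bin_edges) - 1L, all(counts >= 0),
            all(diff(bin_edges) > 0))
  structure(list(bin_edges = as.numeric(bin_edges),
                 counts = as.numeric(counts),
                 time_h = as.numeric(time_h), run_id = run_id),
            class = "cfse_histogram")
}

#' @rdname build_histogram
#' @param h a `cfse_histogram`.
#' @return `hist_density()`: per-bin probability mass summing to 1 (zero
#'   histogram stays zero).
#' @export
hist_density <- function(h) {
  tot <- sum(h$counts)
  if (tot == 0) h$counts else h$counts / tot
}

#' @export
print.cfse_histogram <- function(x, ...) {
  cat(sprintf(
    "CFSE histogram: %d bins on [%.2f, %.2f] log10 a.u., %g cells, t = %g h\n",
    length(x$counts), min(x$bin_edges), max(x$bin_edges), sum(x$counts),
    x$time_h))
  invisible(x)
}

#' Assemble histograms into a time course
#'
#' All histograms must share one bin grid; times must be non-decreasing.
#'
#' @param histograms list of `cfse_histogram`, ordered by time.
#' @param undivided_mean per-time-point linear-scale mean fluorescence of the
#'   undivided population (the manual anchor for the fluorescence model).
#' @param runs replicate count annotation.
#' @return A list of class `cfse_timecourse`.
#' @export
build_timecourse <- function(histograms, undivided_mean, runs = 1L) {
  stopifnot(length(histograms) >= 1,
            length(undivided_mean) == length(histograms))
  edges <- histograms[[1]]$bin_edges
  for (h in histograms) {
    stopifnot(inherits(h, "cfse_histogram"))
    if (!isTRUE(all.equal(h$bin_edges, edges)))
      stop("all histograms in a time course must share one bin grid")
  }
  times <- vapply(histograms, `[[`, numeric(1), "time_h")
  if (is.unsorted(times)) stop("histograms must be ordered by time")
  structure(list(histograms = histograms, undivided_mean = undivided_mean,
                 times = times, runs = runs, bin_edges = edges),
            class = "cfse_timecourse")
}

#' @export
print.cfse_timecourse <- function(x, ...) {
  cat(sprintf("CFSE time course: %d time points (%s h), %d bins\n",
              length(x$times), paste(x$times, collapse = ", "),
              length(x$bin_edges) - 1L))
  invisible(x)
}

#' Choose a shared log10 bin grid that encompasses all events
#'
#' @param event_tables list of [event_table()]s across time points and runs.
#' @param n_bins number of bins.
#' @param pad padding in log10 units added on both sides.
#' @return `c(lo, hi)` log10 range.
#' @export
shared_log_range <- function(event_tables, n_bins = 256L, pad = 0.05) {
  fl <- unlist(lapply(event_tables, function(e) pmax(e$fluorescence, 1e-12)))
  range(log10(fl)) + c(-pad, pad)
}

# --- histogram CSV dialect ----------------------------------------------
# header: time_h,run_id,bin_lo_log10,bin_hi_log10,count

#' Read and write the histogram CSV interchange format
#'
#' One row per bin per time point: columns `time_h`, `run_id`,
#' `bin_lo_log10`, `bin_hi_log10`, `count`. Writing uses full double
#' precision so a write/read round trip reproduces counts exactly.
#'
#' @param tc a `cfse_timecourse`.
#' @param path file path.
#' @export
write_histogram_csv <- function(tc, path) {
  rows <- lapply(tc$histograms, function(h) {
    data.frame(time_h = h$time_h, run_id = h$run_id,
               bin_lo_log10 = head(h$bin_edges, -1L),
               bin_hi_log10 = tail(h$bin_edges, -1L),
               count = h$counts)
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_h,run_id,bin_lo_log10,bin_hi_log10,count", con)
  writeLines(sprintf("%.17g,%s,%.17g,%.17g,%.17g", df$time_h,
                     as.character(df$run_id), df$bin_lo_log10,
                     df$bin_hi_log10, df$count), con)
  invisible(path)
}

#' @rdname write_histogram_csv
#' @param undivided_mean per-time-point undivided-peak anchor to attach to
#'   the reconstructed time course (recycled if length 1).
#' @export
read_histogram_csv <- function(path, undivided_mean = NA_real_) {
  df <- read.csv(path)
  need <- c("time_h", "run_id", "bin_lo_log10", "bin_hi_log10", "count")
  if (!all(need %in% names(df)))
    stop("histogram CSV must have columns: ", paste(need, collapse = ", "))
  key <- paste(df$time_h, df$run_id, sep = "\r")
  groups <- split(df, factor(key, levels = unique(key)))
  hs <- lapply(groups, function(g) {
    new_histogram(c(g$bin_lo_log10, tail(g$bin_hi_log10, 1L)), g$count,
                  g$time_h[1], g$run_id[1])
  })
  ord <- order(vapply(hs, `[[`, numeric(1), "time_h"))
  hs <- hs[ord]
  um <- rep_len(undivided_mean, length(hs))
  build_timecourse(unname(hs), um)
}
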