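#' Beam-break event stream
#'
#' Timestamped photocell interruptions in an activity chamber with five
#' infrared beams spaced 5 cm apart.
#'
#' @param events data.frame with columns `time_s` (non-decreasing) and
#'   `beam` (integer in 1..n_beams).
#' @param n_beams Number of beams.
#' @param beam_spacing_cm Distance between adjacent beams, cm.
#' @param session_min Session length, minutes.
#' @return Object of class `beambreak_stream`.
#' @export
beambreak_stream <- function(events, n_beams = 5L, beam_spacing_cm = 5,
                             session_min = 60) {
  stopifnot(is.data.frame(events),
            all(c("time_s", "beam") %in% names(events)))
  if (nrow(events)) {
    if (is.unsorted(events$time_s)) stop("event times must be non-decreasing")
    if (any(events$beam < 1 | events$beam > n_beams)) {
      stop("beam index out of range")
    }
    if (any(events$time_s < 0)) stop("negative event time")
  }
  structure(
    list(events = events, n_beams = as.integer(n_beams),
         beam_spacing_cm = beam_spacing_cm, session_min = session_min),
    class = "beambreak_stream"
  )
}

#' Read / write beam events CSV
#'
#' Plain CSV with columns `time_s,beam`.
#'
#' @param path File path.
#' @param stream A [beambreak_stream()] (for writing).
#' @param ... Passed to [beambreak_stream()] when reading.
#' @return For reading, a [beambreak_stream()]; writing returns `path`
#'   invisibly.
#' @export
read_beambreak_csv <- function(path, ...) {
  ev <- utils::read.csv(path)
  beambreak_stream(ev[, c("time_s", "beam")], ...)
}

#' @rdname read_beambreak_csv
#' @export
write_beambreak_csv <- function(stream, path) {
  utils::write.csv(stream$events, path, row.names = FALSE)
  invisible(path)
}

#' Classify beam-break transitions
#'
#' Each consecutive pair of events is one transition: a move between
#' adjacent beams (|delta beam| = 1) counts as ambulation, a repeat of
#' the same beam as fine motor activity (grooming-like), and a jump of
#' two or more beams as neither (retained for audit).
#'
#' @param stream A [beambreak_stream()].
#' @return data.frame with one row per transition: `time_s` (time of
#'   the second event), `from`, `to`, `class` in
#'   {ambulation, fine, other}.
#' @export
classify_events <- function(stream) {
  ev <- stream$events
  n <- nrow(ev)
  if (n < 2) {
    return(data.frame(time_s = numeric(), from = integer(),
                      to = integer(), class = character()))
  }
  from <- ev$beam[-n]
  to <- ev$beam[-1]
  d <- abs(to - from)
  cls <- ifelse(d == 1, "ambulation", ifelse(d == 0, "fine", "other"))
  data.frame(time_s = ev$time_s[-1], from = from, to = to, class = cls,
             stringsAsFactors = FALSE)
}

#' Bin activity into an activity summary
#'
#' Counts ambulation, fine, and other transitions per time bin
#' (transition assigned to the bin of its second event) and converts
#' ambulation counts to distance at `beam_spacing_cm` per count
#' (0.05 m per count for the 5-cm chamber).
#'
#' @param stream A [beambreak_stream()].
#' @param bin_min Bin width, minutes.
#' @return Object of class `activity_summary`: data.frame `bins` with
#'   columns bin_start, bin_end (min), ambulation, fine, other,
#'   distance_m, cumulative_m; plus chamber metadata.
#' @export
activity_summary <- function(stream, bin_min = 5) {
  stopifnot(bin_min > 0)
  cls <- classify_events(stream)
  edges <- seq(0, stream$session_min, by = bin_min)
  if (edges[length(edges)] < stream$session_min) {
    edges <- c(edges, stream$session_min)
  }
  nb <- length(edges) - 1
  counts <- matrix(0L, nrow = nb, ncol = 3,
                   dimnames = list(NULL, c("ambulation", "fine", "other")))
  if (nrow(cls)) {
    bin_idx <- findInterval(cls$time_s / 60, edges,
                            rightmost.closed = TRUE, left.open = TRUE)
    bin_idx[cls$time_s == 0] <- 1L
    bin_idx <- pmin(pmax(bin_idx, 1L), nb)
    for (ci in c("ambulation", "fine", "other")) {
      tab <- tabulate(bin_idx[cls$class == ci], nbins = nb)
      counts[, ci] <- tab
    }
  }
  dist_m <- counts[, "ambulation"] * stream$beam_spacing_cm / 100
  bins <- data.frame(bin_start = edges[-length(edges)],
                     bin_end = edges[-1],
                     ambulation = counts[, "ambulation"],
                     fine = counts[, "fine"],
                     other = counts[, "other"],
                     distance_m = dist_m,
                     cumulative_m = cumsum(dist_m))
  structure(list(bins = bins, bin_min = bin_min,
                 session_min = stream$session_min,
                 beam_spacing_cm = stream$beam_spacing_cm),
            class = "activity_summary")
}

#' Distance traveled in a time window
#'
#' Beam-spacing (5 cm) times the number of ambulation counts whose
#' transitions fall in the window.
#'
#' @param summary An [activity_summary()].
#' @param window Length-2 numeric, start and end minutes (must lie
#'   within the session, start < end, and align with bin edges).
#' @return Distance in meters.
#' @export
distance_traveled <- function(summary, window = c(0, summary$session_min)) {
  stopifnot(inherits(summary, "activity_summary"), length(window) == 2)
  if (window[2] <= window[1]) stop("window end must exceed start")
  if (window[1] < 0 || window[2] > summary$session_min) {
    stop("window outside session")
  }
  b <- summary$bins
  sel <- b$bin_start >= window[1] & b$bin_end <= window[2]
  sum(b$distance_m[sel])
}

#' Locomotor onset delay
#'
#' First bin start at which the ambulation rate reaches
#' `factor * baseline_rate` and stays there for at least two
#' consecutive bins; sessions that never reach it return the session
#' length (no onset).
#'
#' @param summary An [activity_summary()].
#' @param baseline_rate Reference ambulation rate, counts per minute.
#' @param factor Onset threshold multiple of the baseline rate
#'   (positive).
#' @param sustain_bins Consecutive bins required at or above threshold.
#' @return Onset time in minutes.
#' @export
onset_delay <- function(summary, baseline_rate, factor = 2,
                        sustain_bins = 2) {
  if (factor <= 0) stop("factor must be positive")
  b <- summary$bins
  if (nrow(b) < 2) stop("need at least two bins")
  rate <- b$ambulation / (b$bin_end - b$bin_start)
  hot <- rate >= factor * baseline_rate
  run <- rle(hot)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1
  ok <- which(run$values & run$lengths >= sustain_bins)
  if (!length(ok)) return(summary$session_min)
  b$bin_start[starts[ok[1]]]
}
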