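#' Detect release events in an open-channel trace
#'
#' A release event begins with the transition from 0 to 1 open channel and
#' ends when the last channel closes -- unless a channel re-opens within
#' \code{gap_window} (500 ms by default), in which case the quiet stretch
#' is absorbed and the event continues.  Formally: maximal unions of active
#' periods (n_open >= 1) separated by quiet gaps shorter than
#' \code{gap_window} form single events, and the event lifetime is the full
#' span from first opening to last closing, internal sub-window gaps
#' included.  An active period truncated by either end of the trace is
#' discarded, because its onset or termination cannot be certified.
#'
#' @param trace a [Trace-class] object, or a data.frame with columns
#'   \code{time_s} and \code{n_open}.  The sampling must resolve the
#'   0/1 transitions: \code{record_dt <= gap_window / 10} is enforced.
#' @param gap_window gap-closure window, s.
#' @return data.frame with one row per event: \code{t_start}, \code{t_end},
#'   \code{lifetime} (s) and \code{amplitude} (peak n_open).
#' @examples
#' detectEvents(makeFixtureTrace("two-puffs"))
#' @export
detectEvents <- function(trace, gap_window = 0.5) {
  if (is(trace, "Trace")) {
    time <- trace@time
    n_open <- trace@n_open
    if (trace@config@record_dt > gap_window / 10)
      stop("record_dt must be <= gap_window / 10 to resolve event boundaries")
  } else {
    time <- trace$time_s
    n_open <- trace$n_open
    if (is.null(time) || is.null(n_open))
      stop("trace must be a Trace or a data.frame with time_s and n_open")
    n_open <- as.integer(n_open)
  }
  if (length(time) == 0L) return(.emptyEvents())
  if (any(time < 0) || is.unsorted(time, strictly = TRUE))
    stop("trace times must be non-negative and strictly increasing")
  if (gap_window <= 0) stop("gap_window must be > 0")

  active <- n_open >= 1L
  if (!any(active)) return(.emptyEvents())
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- which(r$values)
  seg_start <- time[starts[seg]]
  seg_end <- time[ends[seg]]

  ## merge consecutive active segments separated by gaps < gap_window
  n_seg <- length(seg)
  merged_start <- seg_start[1L]
  merged_end <- seg_end[1L]
  out_start <- out_end <- numeric(0)
  if (n_seg > 1L) {
    for (j in 2:n_seg) {
      if (seg_start[j] - merged_end < gap_window) {
        merged_end <- seg_end[j]
      } else {
        out_start <- c(out_start, merged_start)
        out_end <- c(out_end, merged_end)
        merged_start <- seg_start[j]
        merged_end <- seg_end[j]
      }
    }
  }
  out_start <- c(out_start, merged_start)
  out_end <- c(out_end, merged_end)

  ## truncated events: onset not observed (active at first sample) or
  ## termination not certifiable (no full quiet window before trace end)
  keep <- rep(TRUE, length(out_start))
  if (active[1L]) keep[1L] <- FALSE
  if (out_end[length(out_end)] > time[length(time)] - gap_window)
    keep[length(keep)] <- FALSE
  out_start <- out_start[keep]
  out_end <- out_end[keep]
  if (length(out_start) == 0L) return(.emptyEvents())

  amplitude <- vapply(seq_along(out_start), function(j)
    max(n_open[time >= out_start[j] & time <= out_end[j]]), integer(1L))
  data.frame(t_start = out_start, t_end = out_end,
             lifetime = out_end - out_start, amplitude = amplitude)
}

.emptyEvents <- function() {
  data.frame(t_start = numeric(0), t_end = numeric(0),
             lifetime = numeric(0), amplitude = integer(0))
}

#' Summarize a detected event train
#'
#' Computes the lifetime, interpuff-interval (IPI) and dormancy statistics
#' of a detected event train.  The IPI is the onset-to-onset interval of
#' consecutive events; the dormancy is the complementary end-to-next-onset
#' interval during which no channel is open, so every IPI equals the
#' preceding event's lifetime plus the following dormancy and
#' mean IPI >= mean dormancy.  With fewer than two events the IPI and
#' dormancy are undefined and reported as NA, never zero.
#'
#' @param events event table from [detectEvents()].
#' @param trace_duration duration of the analyzed trace, s.
#' @return an [EventStatistics-class] object.
#' @export
eventStatistics <- function(events, trace_duration = NA_real_) {
  stopifnot(is.data.frame(events),
            all(c("t_start", "t_end", "lifetime", "amplitude") %in%
                names(events)))
  n <- nrow(events)
  if (n >= 2L) {
    ipis <- diff(events$t_start)
    dorms <- events$t_start[-1L] - events$t_end[-n]
  } else {
    ipis <- dorms <- numeric(0)
  }
  new("EventStatistics", lifetimes = as.numeric(events$lifetime),
      amplitudes = as.numeric(events$amplitude), ipis = ipis,
      dormancies = dorms, trace_duration = trace_duration)
}

#' @rdname eventStatistics
#' @param stats an [EventStatistics-class] object.
#' @export
nEvents <- function(stats) length(stats@lifetimes)

#' Mean event-train statistics
#'
#' Accessors for [EventStatistics-class]: mean event lifetime, mean
#' onset-to-onset interpuff interval, and mean dormancy (quiet interval).
#' Undefined quantities (fewer than two events for IPI/dormancy, no events
#' for lifetime) are NA.
#'
#' @param stats an [EventStatistics-class] object.
#' @return numeric scalar, s.
#' @export
meanLifetime <- function(stats) {
  if (nEvents(stats) == 0L) NA_real_ else mean(stats@lifetimes)
}

#' @rdname meanLifetime
#' @export
meanIpi <- function(stats) {
  if (length(stats@ipis) == 0L) NA_real_ else mean(stats@ipis)
}

#' @rdname meanLifetime
#' @export
meanDormancy <- function(stats) {
  if (length(stats@dormancies) == 0L) NA_real_ else mean(stats@dormancies)
}

#' @rdname meanLifetime
#' @export
medianLifetime <- function(stats) {
  if (nEvents(stats) == 0L) NA_real_ else median(stats@lifetimes)
}

#' @rdname meanLifetime
#' @export
medianAmplitude <- function(stats) {
  if (nEvents(stats) == 0L) NA_real_ else median(stats@amplitudes)
}

#' Histogram of an event-train quantity
#'
#' Fixed-bin histograms matching the conventions used for event trains:
#' 100 ms bins for lifetimes, 0.5 s bins for IPI and dormancy, unit bins
#' for amplitudes.
#'
#' @param stats an [EventStatistics-class] object.
#' @param what one of "lifetime", "ipi", "dormancy", "amplitude".
#' @param bin_width optional override of the bin width.
#' @return data.frame with columns \code{mid}, \code{count}.
#' @export
eventHistogram <- function(stats,
                           what = c("lifetime", "ipi", "dormancy",
                                    "amplitude"),
                           bin_width = NULL) {
  what <- match.arg(what)
  x <- switch(what, lifetime = stats@lifetimes, ipi = stats@ipis,
              dormancy = stats@dormancies, amplitude = stats@amplitudes)
  if (is.null(bin_width))
    bin_width <- switch(what, lifetime = 0.1, ipi = 0.5, dormancy = 0.5,
                        amplitude = 1)
  if (length(x) == 0L)
    return(data.frame(mid = numeric(0), count = integer(0)))
  breaks <- seq(0, (max(x) %/% bin_width + 1) * bin_width, by = bin_width)
  count <- as.integer(table(cut(x, breaks, right = FALSE,
                                include.lowest = TRUE)))
  data.frame(mid = breaks[-length(breaks)] + bin_width / 2, count = count)
}

setMethod("show", "EventStatistics", function(object) {
  cat(sprintf("EventStatistics: %d events over %.6g s\n", nEvents(object),
              object@trace_duration))
  cat(sprintf("  mean lifetime %.4g s (median %.4g s), median amplitude %g\n",
              meanLifetime(object), medianLifetime(object),
              medianAmplitude(object)))
  cat(sprintf("  mean IPI %.4g s (onset-to-onset), mean dormancy %.4g s\n",
              meanIpi(object), meanDormancy(object)))
})

#' Gating-state counters of a cluster state
#'
#' The three refractory/availability counters tracked alongside traces:
#' the number of subunits in the fully bound state (1,1,1) (inhibited with
#' IP3 still bound), the number in state (0,1,1) (inhibited subunits that
#' have lost IP3), and the number of channels with at least three
#' IP3-bound subunits, i.e. channels still available for opening.
#'
#' @param state a [ClusterState-class] object.
#' @return named integer vector \code{n111}, \code{n011}, \code{n_avail}.
#' @examples
#' cfg <- simulationConfig(n_channels = 2L)
#' stateCounters(clusterState(cfg))
#' @export
stateCounters <- function(state) {
  stopifnot(is(state, "ClusterState"))
  s <- state@subunits
  c(n111 = sum(s == 7L),
    n011 = sum(s == 3L),
    n_avail = sum(rowSums(s >= 4L) >= 3L))
}
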