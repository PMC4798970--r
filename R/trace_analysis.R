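# Single-cell NCI trace analysis: significant peaks, phase, periods,
# phase differences to the forcing, and entropy-based synchrony.

#' Single-cell trace set
#'
#' Container for per-cell NCI time series at uniform sampling.
#'
#' @param cells named list; each element a list/data.frame with numeric
#'   \code{times} (min) and \code{nci} of equal length.
#' @param sampling_interval sampling step in minutes (default 6).
#' @param metadata free-form condition metadata (e.g. the forcing).
#' @return an object of class \code{trace_set}.
#' @export
trace_set <- function(cells, sampling_interval = 6, metadata = list()) {
  if (!length(cells) || is.null(names(cells))) stop("cells must be a named list")
  for (id in names(cells)) {
    cl <- cells[[id]]
    tt <- cl$times
    if (length(tt) != length(cl$nci)) stop("times/nci length mismatch for cell ", id)
    if (length(tt) > 1) {
      dt <- diff(tt)
      if (any(dt <= 0) || max(abs(dt - sampling_interval)) > 1e-6)
        stop("cell ", id, ": times must be uniform at the sampling interval")
    }
    if (any(cl$nci < 0)) stop("cell ", id, ": nci must be non-negative")
  }
  structure(list(cells = cells, sampling_interval = sampling_interval,
                 metadata = metadata), class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  len <- vapply(x$cells, function(c) length(c$times), numeric(1))
  cat(sprintf("<trace_set> %d cells, %g min sampling, track length %g-%g min\n",
              length(x$cells), x$sampling_interval,
              min(len - 1) * x$sampling_interval, max(len - 1) * x$sampling_interval))
  invisible(x)
}

# Collapse plateaus to their midpoint sample and find strict interior
# extrema. Returns indices into the original series.
local_extrema <- function(v) {
  n <- length(v)
  r <- rle(v)
  reps <- cumsum(r$lengths) - (r$lengths - 1L) %/% 2L - (r$lengths %% 2L == 0L)
  w <- r$values
  m <- length(w)
  if (m < 3) return(list(max = integer(0), min = integer(0)))
  core <- 2:(m - 1)
  is_max <- w[core] > w[core - 1] & w[core] > w[core + 1]
  is_min <- w[core] < w[core - 1] & w[core] < w[core + 1]
  list(max = reps[core][is_max], min = reps[core][is_min])
}

#' Detect significant oscillatory peaks
#'
#' A peak is a local-minimum / local-maximum / local-minimum sequence of the
#' trace: maxima are strict local maxima (plateaus collapsed to their
#' midpoint sample, trace endpoints never eligible) and each maximum's
#' flanking minima are the lowest samples between it and the neighbouring
#' maxima (or the trace boundary), taking the tied sample nearest the
#' maximum. The peak height theta is measured from the highest of the two
#' flanking minima to the maximum. Peaks spanning only three consecutive
#' samples are noise peaks; a peak is \emph{significant} when it is not
#' noise and its height exceeds \code{threshold}. Tracks shorter than
#' \code{min_track} are flagged (\code{short_track}) so cohort statistics
#' can exclude them.
#'
#' @param times sample times (min), uniform.
#' @param values NCI (or nuclear-fraction) values.
#' @param threshold significance threshold on peak height (default 0.15).
#' @param min_track minimum track length for cohort statistics (min,
#'   default 7 h).
#' @return an object of class \code{peak_list} with per-peak vectors:
#'   \code{maxima_times}, \code{maxima_values}, \code{left_min_times},
#'   \code{right_min_times}, \code{heights}, \code{noise},
#'   \code{significant}; plus \code{short_track} and the inputs' span.
#' @export
detect_peaks <- function(times, values, threshold = 0.15, min_track = 420) {
  if (length(times) < 3) stop("need at least 3 samples")
  if (length(times) != length(values)) stop("times/values length mismatch")
  n <- length(values)
  maxima <- sort(local_extrema(values)$max)
  keep <- logical(length(maxima))
  left <- right <- integer(length(maxima))
  for (j in seq_along(maxima)) {
    lo <- if (j > 1) maxima[j - 1] + 1L else 1L
    hi <- if (j < length(maxima)) maxima[j + 1] - 1L else n
    lseg <- lo:(maxima[j] - 1L)
    rseg <- (maxima[j] + 1L):hi
    if (!length(lseg) || !length(rseg)) next
    keep[j] <- TRUE
    lv <- values[lseg]; rv <- values[rseg]
    left[j] <- lseg[max(which(lv == min(lv)))]    # tied: nearest the maximum
    right[j] <- rseg[min(which(rv == min(rv)))]
  }
  maxima <- maxima[keep]; left <- left[keep]; right <- right[keep]
  heights <- values[maxima] - pmax(values[left], values[right])
  noise <- (right - left) == 2L
  structure(list(
    maxima_times = times[maxima], maxima_values = values[maxima],
    left_min_times = times[left], left_min_values = values[left],
    right_min_times = times[right], right_min_values = values[right],
    heights = heights, noise = noise,
    significant = !noise & heights > threshold,
    threshold = threshold,
    short_track = (times[length(times)] - times[1]) < min_track,
    t_span = range(times)), class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> %d peaks (%d significant, %d noise)%s\n",
              length(x$maxima_times), sum(x$significant), sum(x$noise),
              if (x$short_track) " [short track]" else ""))
  invisible(x)
}

#' Phase assignment from significant peaks
#'
#' Significant peak maxima carry phase 2*pi (equivalently 0) and the minima
#' between consecutive significant maxima carry phase pi; the phase is
#' linearly interpolated in time between those anchors and is undefined
#' (NA) before the first and after the last anchor.
#'
#' @param peaks a [detect_peaks()] result.
#' @param times sample times (min) at which to evaluate the phase.
#' @return numeric vector of phases in \code{[0, 2*pi]} with NA outside the
#'   anchored range; maxima evaluate to \code{2*pi}.
#' @export
assign_phase <- function(peaks, times) {
  tp <- peaks$maxima_times[peaks$significant]
  phi <- rep(NA_real_, length(times))
  if (length(tp) == 0) return(phi)
  anchors_t <- tp[1]; anchors_v <- 2 * pi
  if (length(tp) > 1) {
    for (j in 1:(length(tp) - 1)) {
      # the minimum between two consecutive significant maxima: right minimum
      # of peak j (== left minimum of peak j+1 when extrema alternate)
      k <- which(peaks$maxima_times == tp[j])
      tmin <- peaks$right_min_times[k]
      anchors_t <- c(anchors_t, tmin, tp[j + 1])
      anchors_v <- c(anchors_v, pi, 2 * pi)
    }
  }
  inside <- times >= anchors_t[1] & times <= anchors_t[length(anchors_t)]
  if (length(anchors_t) == 1) {
    phi[times == anchors_t] <- 2 * pi
    return(phi)
  }
  # piecewise-linear rising phase: 0 -> pi -> 2*pi within each full cycle
  seg_start <- c(0, pi)
  for (s in 1:(length(anchors_t) - 1)) {
    t0 <- anchors_t[s]; t1 <- anchors_t[s + 1]
    v0 <- if (anchors_v[s] == 2 * pi) 0 else pi
    v1 <- anchors_v[s + 1]
    sel <- inside & times >= t0 & times <= t1
    phi[sel] <- v0 + (v1 - v0) * (times[sel] - t0) / (t1 - t0)
  }
  phi[times %in% tp] <- 2 * pi
  phi
}

#' Inter-peak periods
#'
#' Successive time differences between consecutive significant peak maxima.
#'
#' @param peaks a single [detect_peaks()] result or a list of them
#'   (a cohort); cells with fewer than two significant peaks contribute
#'   nothing.
#' @param drop_short drop peak lists flagged \code{short_track}
#'   (default TRUE, matching the 7 h tracking requirement).
#' @return numeric vector of periods T_exp (min), pooled over cells.
#' @export
experimental_periods <- function(peaks, drop_short = TRUE) {
  if (inherits(peaks, "peak_list")) peaks <- list(peaks)
  out <- lapply(peaks, function(p) {
    if (drop_short && p$short_track) return(numeric(0))
    diff(p$maxima_times[p$significant])
  })
  unlist(out, use.names = FALSE)
}

#' Mean peak height per forcing interval
#'
#' Buckets significant-peak heights by the interval index
#' \code{n = floor(t_peak / T_ref) + 1} and reports mean and sd per bucket
#' (peaks right after a stimulation fall in even or odd buckets depending
#' on the convention \code{T_ref = T_f/2}).
#'
#' @param peaks a [detect_peaks()] result or list of them.
#' @param T_ref reference interval (min).
#' @return data frame with \code{interval}, \code{n_peaks},
#'   \code{mean_height}, \code{sd_height}; empty buckets up to the last
#'   occupied interval are reported with \code{n_peaks = 0}.
#' @export
peak_heights_per_cycle <- function(peaks, T_ref) {
  if (T_ref <= 0) stop("T_ref must be positive")
  if (inherits(peaks, "peak_list")) peaks <- list(peaks)
  tp <- unlist(lapply(peaks, function(p) p$maxima_times[p$significant]))
  ht <- unlist(lapply(peaks, function(p) p$heights[p$significant]))
  if (!length(tp))
    return(data.frame(interval = integer(0), n_peaks = integer(0),
                      mean_height = numeric(0), sd_height = numeric(0)))
  idx <- floor(tp / T_ref) + 1L
  ivals <- seq_len(max(idx))
  data.frame(
    interval = ivals,
    n_peaks = vapply(ivals, function(n) sum(idx == n), integer(1)),
    mean_height = vapply(ivals, function(n)
      if (any(idx == n)) mean(ht[idx == n]) else NA_real_, numeric(1)),
    sd_height = vapply(ivals, function(n)
      if (sum(idx == n) > 1) stats::sd(ht[idx == n]) else NA_real_, numeric(1)))
}

# Cycle start times of a periodic forcing covering [t0, t1].
forcing_cycle_starts <- function(forcing, t0, t1) {
  Tf <- forcing_period(forcing)
  if (is.na(Tf)) stop("phase differences need a periodic (square/sawtooth) forcing")
  ks <- ceiling((t0 - forcing$t_start) / Tf):floor((t1 - forcing$t_start) / Tf)
  st <- forcing$t_start + ks * Tf
  st[st >= t0 & st <= t1]
}

#' Phase difference between forcing cycles and peaks
#'
#' For every forcing-cycle start inside the trace span, the timing
#' \code{DT} to the closest significant peak (searching both directions,
#' ties broken toward the earlier peak) is converted to a phase difference
#' \code{dphi = 2*pi*DT/T_f}, reduced to \code{[0, 2*pi)}.
#'
#' @param peaks a [detect_peaks()] result.
#' @param forcing a periodic [forcing_signal()].
#' @param forward_only if TRUE, search only peaks at or after each cycle
#'   start.
#' @return numeric vector of phase differences (possibly empty).
#' @export
phase_difference <- function(peaks, forcing, forward_only = FALSE) {
  tp <- peaks$maxima_times[peaks$significant]
  if (!length(tp)) return(numeric(0))
  Tf <- forcing_period(forcing)
  starts <- forcing_cycle_starts(forcing, peaks$t_span[1], peaks$t_span[2])
  dphi <- vapply(starts, function(s) {
    cand <- if (forward_only) tp[tp >= s] else tp
    if (!length(cand)) return(NA_real_)
    dt <- cand - s
    best <- which(abs(dt) == min(abs(dt)))
    DT <- dt[best[1]]  # ties: earlier peak (smaller time) first in order
    (2 * pi * DT / Tf) %% (2 * pi)
  }, numeric(1))
  dphi[!is.na(dphi)]
}

#' Entropy-based synchrony intensity
#'
#' Bins the phase differences into \code{n_bins} uniform bins on
#' \code{[0, 2*pi)}, computes the Shannon entropy
#' \code{S = -sum(p_k log p_k)} (empty bins contribute zero) and the
#' synchrony intensity \code{eta = 1 - S/S_max} with
#' \code{S_max = log(n_bins)} (the flat-distribution entropy): 0 for a flat
#' distribution, 1 for a delta-like one.
#'
#' @param delta_phi phase differences (any reals; reduced mod 2*pi).
#' @param n_bins number of bins (default 8).
#' @return list with \code{p} (bin probabilities), \code{entropy},
#'   \code{eta}.
#' @export
synchrony_intensity <- function(delta_phi, n_bins = 8) {
  if (!length(delta_phi)) stop("eta is undefined for an empty sample")
  x <- delta_phi %% (2 * pi)
  bins <- findInterval(x, seq(0, 2 * pi, length.out = n_bins + 1),
                       rightmost.closed = TRUE)
  bins[bins > n_bins] <- n_bins
  p <- tabulate(bins, nbins = n_bins) / length(x)
  S <- -sum(ifelse(p > 0, p * log(p), 0))
  list(p = p, entropy = S, eta = 1 - S / log(n_bins))
}

#' Per-cycle synchrony intensity
#'
#' Computes the synchrony intensity restricted to significant peaks falling
#' in each forcing cycle window \code{[(n-1)*T_f, n*T_f)}, with each peak's
#' phase difference taken relative to its own cycle start. A constant
#' \code{eta_n} across cycles indicates synchronization without a
#' cumulative training effect.
#'
#' @param peaks a [detect_peaks()] result or list of them (cohort).
#' @param forcing a periodic [forcing_signal()].
#' @param n_cycles number of cycles to evaluate.
#' @param n_bins bins for the entropy (default 8).
#' @return data frame with \code{cycle}, \code{n_peaks}, \code{eta}
#'   (NA for cycles without peaks).
#' @export
synchrony_per_cycle <- function(peaks, forcing, n_cycles, n_bins = 8) {
  if (inherits(peaks, "peak_list")) peaks <- list(peaks)
  Tf <- forcing_period(forcing)
  tp <- unlist(lapply(peaks, function(p) p$maxima_times[p$significant]))
  tp <- tp - forcing$t_start
  out <- data.frame(cycle = seq_len(n_cycles), n_peaks = 0L, eta = NA_real_)
  for (n in seq_len(n_cycles)) {
    sel <- tp >= (n - 1) * Tf & tp < n * Tf
    out$n_peaks[n] <- sum(sel)
    if (any(sel)) {
      dphi <- (2 * pi * (tp[sel] - (n - 1) * Tf) / Tf) %% (2 * pi)
      out$eta[n] <- synchrony_intensity(dphi, n_bins)$eta
    }
  }
  out
}

#' Cohort synchrony analysis
#'
#' Runs peak detection on every cell of a trace set, pools the phase
#' differences to the forcing and computes the cohort synchrony intensity.
#' Cells flagged as short tracks are excluded from the pooled statistics.
#'
#' @param traces a [trace_set()].
#' @param forcing a periodic [forcing_signal()] (or NULL to skip synchrony).
#' @param threshold significant-peak threshold.
#' @param n_bins entropy bins.
#' @param min_track minimum track length (min).
#' @return list with \code{peaks} (per-cell peak lists), \code{periods}
#'   (pooled T_exp), \code{delta_phi}, \code{synchrony} (NULL without
#'   forcing), \code{n_cells_used}.
#' @export
analyze_traces <- function(traces, forcing = NULL, threshold = 0.15,
                           n_bins = 8, min_track = 420) {
  pk <- lapply(traces$cells, function(cl)
    detect_peaks(cl$times, cl$nci, threshold = threshold, min_track = min_track))
  used <- !vapply(pk, function(p) p$short_track, logical(1))
  res <- list(peaks = pk,
              periods = experimental_periods(pk),
              n_cells_used = sum(used))
  if (!is.null(forcing)) {
    dphi <- unlist(lapply(pk[used], phase_difference, forcing = forcing))
    res$delta_phi <- dphi
    res$synchrony <- if (length(dphi)) synchrony_intensity(dphi, n_bins) else NULL
  }
  res
}
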