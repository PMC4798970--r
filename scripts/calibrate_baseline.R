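#!/usr/bin/env Rscript
# Calibration of the default baseline parameter set (default_parameters()).
#
# The baseline is required to put the model, under constant stimulation
# S = 2 h^-1, in a damped oscillatory regime with
#   - a responding trajectory (N > 0.4 within 3 h, tail mean <= 0.4),
#   - a first nuclear peak within ~30 min of stimulus onset,
#   - an inter-peak interval of ~90 min (the natural period T0),
#   - at least two significant NCI peaks (theta = 0.15) when a pre-stimulus
#     baseline segment is present,
#   - a stable fixed point (damped classification) with enough margin that
#     randomization under the default uncertainty degrees keeps the
#     sustained fraction clearly below 10%.
#
# Stage 1 draws parameter sets log-uniformly from broad physiological
# ranges and keeps those with a damped ~90 min response; stage 2 is a
# greedy coordinate refinement of the best candidate under the combined
# score (period error, first-peak lateness, significant-peak count,
# sustained fraction of a 400-draw scan). The result was rounded to three
# significant digits and frozen into R/parameters.R; rerunning this script
# reproduces the search (several minutes).
#
# Usage: Rscript scripts/calibrate_baseline.R [n_stage1] [seed]

library(nfkbsync)

args <- commandArgs(TRUE)
n_stage1 <- if (length(args) >= 1) as.integer(args[1]) else 400
seed <- if (length(args) >= 2) as.integer(args[2]) else 42

ranges <- list(
  lo = c(d_K = 0.5, n = 1, d = 0.01, gamma = 0.1, d_I = 0.1, p = 5, a = 10,
         kappa = 0.2, k_I = 5, d_RI = 1, k_on_I = 1, k_on0_I = 0.01,
         k_off_I = 1, k_off0_I = 0.1, k_on_A = 1, k_on0_A = 0.01,
         k_off_A = 1, k_off0_A = 0.1, d_RA = 0.3, k_A = 0.5, d_A = 0.2),
  hi = c(d_K = 10, n = 4, d = 0.2, gamma = 0.6, d_I = 1, p = 40, a = 200,
         kappa = 3, k_I = 60, d_RI = 4, k_on_I = 20, k_on0_I = 0.1,
         k_off_I = 20, k_off0_I = 1, k_on_A = 20, k_on0_A = 0.1,
         k_off_A = 20, k_off0_A = 1, d_RA = 20, k_A = 4, d_A = 1.5))

trace_shape <- function(p, horizon = 1260) {
  fc <- forcing_signal("constant", S_high = 2, t_start = 60)
  tr <- try(simulate_nfkb(p, fc, t_grid = seq(0, horizon, by = 3)),
            silent = TRUE)
  if (inherits(tr, "try-error")) return(NULL)
  N <- tr$states[, "N"]; tt <- tr$times - 60
  i <- which(diff(sign(diff(N))) == -2) + 1
  i <- i[N[i] > 0.02]
  pk <- tt[i]
  sig <- detect_peaks(tr$times, tr$nci, threshold = 0.15)
  nsig <- sum(sig$significant)
  list(first = if (length(pk)) pk[1] else NA,
       per = if (length(pk) > 1) mean(diff(pk[1:min(6, length(pk))])) else NA,
       n_peaks = length(pk), nsig = nsig,
       sigper = if (nsig > 1)
         mean(diff(sig$maxima_times[sig$significant])) else NA,
       maxN3h = max(N[tt >= 0 & tt <= 180]),
       tail = mean(N[tt >= horizon - 180]))
}

admissible <- function(s) {
  !is.null(s) && !is.na(s$first) && s$n_peaks >= 4 &&
    s$maxN3h > 0.45 && s$tail <= 0.35
}

score <- function(p, with_scan = FALSE) {
  s <- trace_shape(p)
  if (!admissible(s)) return(-Inf)
  st <- try(classify_stability(p, 2), silent = TRUE)
  if (inherits(st, "try-error") || st$classification != "damped") return(-Inf)
  sc <- -abs(s$per - 90) / 5 - max(0, s$first - 33) / 5 +
    0.4 * min(s$nsig, 4) -
    (if (is.na(s$sigper)) 6 else abs(s$sigper - 90) / 15)
  if (with_scan) {
    if (s$nsig < 2) return(-Inf)
    pr <- parameter_prior(p, default_degrees())
    fr <- try(stability_scan(pr, 400, S_const = 2,
                             seed = 101)$fraction_sustained, silent = TRUE)
    if (inherits(fr, "try-error")) return(-Inf)
    sc <- sc - 80 * max(0, fr - 0.035)
  }
  sc
}

message("stage 1: random search (", n_stage1, " draws)")
set.seed(seed)
best <- list(sc = -Inf, v = NULL)
for (it in seq_len(n_stage1)) {
  u <- runif(length(ranges$lo))
  v <- exp(log(ranges$lo) + u * (log(ranges$hi) - log(ranges$lo)))
  p <- try(do.call(kinetic_params, as.list(v)), silent = TRUE)
  if (inherits(p, "try-error")) next
  sc <- score(p)
  if (is.finite(sc) && sc > best$sc) {
    best <- list(sc = sc, v = v)
    message(sprintf("  it %d: score %.2f", it, sc))
  }
}
stopifnot(is.finite(best$sc))

message("stage 2: greedy coordinate refinement (with scan penalty)")
v <- best$v
cur <- score(do.call(kinetic_params, as.list(v)), with_scan = TRUE)
repeat {
  improved <- FALSE
  for (nm in names(v)) {
    for (f in c(0.7, 0.85, 1.18, 1.43)) {
      v2 <- v; v2[nm] <- v[nm] * f
      if (nm == "n") v2[nm] <- max(1, min(4, v2[nm]))
      p2 <- try(do.call(kinetic_params, as.list(v2)), silent = TRUE)
      if (inherits(p2, "try-error")) next
      sc2 <- score(p2, with_scan = TRUE)
      if (is.finite(sc2) && sc2 > cur + 1e-9) {
        v <- v2; cur <- sc2; improved <- TRUE
        message(sprintf("  %s x%.2f -> %.3f", nm, f, cur))
      }
    }
  }
  if (!improved) break
}

v <- signif(v, 3)
message("calibrated baseline (3 significant digits):")
print(v)
s <- trace_shape(do.call(kinetic_params, as.list(v)))
message(sprintf("period %.1f min, first peak %.0f min, %d significant peaks",
                s$per, s$first, s$nsig))
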