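# TNF-alpha forcing protocols.
#
# All user-facing times are in minutes; the evaluated rate S(t) is in h^-1,
# matching the normalized model equations (10 ng/ml constant TNF ~ S = 2 h^-1).

#' TNF-alpha forcing signal
#'
#' Construct a stimulation protocol: a constant flow, a square wave of
#' alternating doses (high phase of duration \code{T1}, low phase of duration
#' \code{T2}, forcing period \code{T_f = T1 + T2}), or a sawtooth profile in
#' which a short medium pulse is followed by exponential clearance of the
#' ligand (emulating pulse-then-stop microfluidic delivery).
#'
#' @param kind one of \code{"constant"}, \code{"square"}, \code{"sawtooth"}.
#' @param S_high activation rate during the high phase (h^-1).
#' @param S_low activation rate during the low phase (h^-1, default 0).
#' @param T1 high-phase duration (min; square only).
#' @param T2 low-phase duration (min; square only).
#' @param period full sawtooth period (min; sawtooth only).
#' @param pulse_len sawtooth pulse duration (min, default 15).
#' @param decay_halflife sawtooth clearance half-life (min, default 30).
#' @param t_start,t_end active window (min); outside it S = S_low.
#' @return an object of class \code{forcing_signal}.
#' @seealso [evaluate_forcing()], [dose_to_rate()]
#' @export
forcing_signal <- function(kind = c("constant", "square", "sawtooth"),
                           S_high, S_low = 0,
                           T1 = NULL, T2 = NULL,
                           period = NULL, pulse_len = 15, decay_halflife = 30,
                           t_start = 0, t_end = Inf) {
  kind <- match.arg(kind)
  if (!is.finite(S_high) || S_high < 0) stop("S_high must be a finite non-negative rate")
  if (!is.finite(S_low) || S_low < 0) stop("S_low must be a finite non-negative rate")
  if (S_high < S_low) stop("S_high must be >= S_low")
  if (kind == "square") {
    if (is.null(T1) || is.null(T2)) stop("square forcing needs T1 and T2")
    if (T1 < 0 || T2 < 0) stop("durations T1, T2 must be non-negative")
    if (T1 + T2 <= 0) stop("square forcing needs T1 + T2 > 0")
  }
  if (kind == "sawtooth") {
    if (is.null(period)) stop("sawtooth forcing needs a period")
    if (period <= 0) stop("sawtooth period must be positive")
    if (pulse_len < 0 || pulse_len > period) stop("pulse_len must lie in [0, period]")
    if (decay_halflife <= 0) stop("decay_halflife must be positive")
  }
  structure(list(kind = kind, S_high = S_high, S_low = S_low,
                 T1 = T1, T2 = T2, period = period,
                 pulse_len = pulse_len, decay_halflife = decay_halflife,
                 t_start = t_start, t_end = t_end),
            class = "forcing_signal")
}

#' @export
print.forcing_signal <- function(x, ...) {
  desc <- switch(x$kind,
    constant = sprintf("constant S = %g h^-1", x$S_high),
    square   = sprintf("square S = %g/%g h^-1, T1 = %g min, T2 = %g min (T_f = %g min)",
                       x$S_high, x$S_low, x$T1, x$T2, x$T1 + x$T2),
    sawtooth = sprintf("sawtooth S = %g h^-1, pulse %g min, half-life %g min, period %g min",
                       x$S_high, x$pulse_len, x$decay_halflife, x$period))
  cat("<forcing_signal> ", desc, "\n", sep = "")
  invisible(x)
}

#' Forcing period in minutes
#'
#' \code{T_f = T1 + T2} for square signals, the pulse period for sawtooth,
#' \code{NA} for constant stimulation.
#' @param signal a \code{forcing_signal}.
#' @return period in minutes, or NA.
#' @export
forcing_period <- function(signal) {
  switch(signal$kind,
         constant = NA_real_,
         square = signal$T1 + signal$T2,
         sawtooth = signal$period)
}

#' Evaluate a forcing signal
#'
#' @param signal a \code{forcing_signal}.
#' @param t time(s) in minutes (vectorized).
#' @return IKK-activation rate(s) S(t) in h^-1 (non-negative).
#' @examples
#' sq <- forcing_signal("square", S_high = 2, T1 = 45, T2 = 45)
#' evaluate_forcing(sq, c(10, 50))  # 2 during the pulse, 0 after
#' @export
evaluate_forcing <- function(signal, t) {
  if (any(!is.finite(t))) stop("t must be finite")
  out <- rep(signal$S_low, length(t))
  active <- t >= signal$t_start & t < signal$t_end
  tt <- t[active] - signal$t_start
  out[active] <- switch(signal$kind,
    constant = signal$S_high,
    square = {
      Tf <- signal$T1 + signal$T2
      phase <- tt %% Tf
      ifelse(phase < signal$T1, signal$S_high, signal$S_low)
    },
    sawtooth = {
      phase <- tt %% signal$period
      k <- log(2) / signal$decay_halflife
      ifelse(phase < signal$pulse_len, signal$S_high,
             signal$S_low + (signal$S_high - signal$S_low) *
               exp(-k * (phase - signal$pulse_len)))
    })
  out
}

#' Map a TNF-alpha dose to the normalized activation rate
#'
#' Linear map anchored so that a constant 10 ng/ml dose corresponds to
#' S = 2 h^-1; lower doses map proportionally lower.
#'
#' @param dose TNF-alpha concentration (ng/ml), vectorized.
#' @param rate_per_ngml slope of the map (default 0.2 h^-1 per ng/ml).
#' @return activation rate (h^-1).
#' @export
dose_to_rate <- function(dose, rate_per_ngml = 0.2) {
  if (any(dose < 0)) stop("dose must be non-negative")
  rate_per_ngml * dose
}

# Switch times (min) of a forcing signal inside [t0, t1], used to integrate
# piecewise so discontinuities are never smeared by the adaptive solver.
forcing_switch_times <- function(signal, t0, t1) {
  sw <- numeric(0)
  if (signal$kind == "square") {
    Tf <- signal$T1 + signal$T2
    k <- floor((t0 - signal$t_start) / Tf):ceiling((t1 - signal$t_start) / Tf)
    sw <- c(signal$t_start + k * Tf, signal$t_start + k * Tf + signal$T1)
  } else if (signal$kind == "sawtooth") {
    k <- floor((t0 - signal$t_start) / signal$period):
         ceiling((t1 - signal$t_start) / signal$period)
    sw <- c(signal$t_start + k * signal$period,
            signal$t_start + k * signal$period + signal$pulse_len)
  }
  if (is.finite(signal$t_start)) sw <- c(sw, signal$t_start)
  if (is.finite(signal$t_end)) sw <- c(sw, signal$t_end)
  sort(unique(sw[sw > t0 & sw < t1]))
}
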