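# Fixed points, Jacobian eigenvalues and regime classification.
#
# Damped regime: the fixed point under constant stimulation is stable (all
# eigenvalue real parts negative) and trajectories ring down towards it.
# Sustained regime: the fixed point is unstable (some Re(lambda) > 0) and
# trajectories converge to a limit cycle around it.

#' Locate the fixed point under constant stimulation
#'
#' Damped Newton iteration on the analytic vector field/Jacobian, seeded
#' from a long transient of the ODE, until \code{max |dy/dt| < tol}.
#'
#' @param params a [kinetic_params()] set.
#' @param S_const constant activation rate (h^-1).
#' @param genes named list of [gene_params()].
#' @param tol residual tolerance (h^-1).
#' @param seed_state optional state to seed the Newton iteration (e.g. the
#'   end of an already-computed long trajectory); when NULL a 100 h
#'   transient is integrated first.
#' @return named fixed-point state.
#' @export
find_fixed_point <- function(params, S_const, genes = list(), tol = 1e-10,
                             seed_state = NULL) {
  if (S_const < 0) stop("S_const must be >= 0")
  if (is.null(seed_state)) {
    fc <- forcing_signal("constant", S_high = S_const)
    tr <- simulate_nfkb(params, fc, genes = genes,
                        t_grid = c(0, 6000), initial = "resting")
    y <- as.numeric(tr$states[nrow(tr$states), ])
  } else {
    y <- as.numeric(seed_state)
  }
  nm <- state_names(genes)
  fl <- flatten_params(params, genes)
  for (it in 1:200) {
    f <- rhs_core(y, S_const, fl$pv, fl$gv)
    if (max(abs(f)) < tol) break
    J <- jac_core(y, S_const, fl$pv, fl$gv)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) stop("singular Jacobian during Newton iteration")
    lambda <- 1
    f0 <- sum(f^2)
    repeat {
      y_new <- y + lambda * step
      f_new <- rhs_core(y_new, S_const, fl$pv, fl$gv)
      if (all(is.finite(f_new)) && sum(f_new^2) < f0) break
      lambda <- lambda / 2
      if (lambda < 1e-8) { y_new <- y + 1e-8 * step; break }
    }
    y <- y_new
  }
  f <- rhs_core(y, S_const, fl$pv, fl$gv)
  if (max(abs(f)) >= tol)
    stop(sprintf("fixed point not found (residual %.3e h^-1)", max(abs(f))))
  names(y) <- nm
  y
}

#' Analytic Jacobian of the model
#'
#' @param params a [kinetic_params()] set.
#' @param state named state vector (typically a fixed point).
#' @param S_const constant activation rate (h^-1) at which to evaluate.
#' @param genes named list of [gene_params()].
#' @return the (8 + 2 per gene) square Jacobian matrix (units h^-1).
#' @export
model_jacobian <- function(params, state, S_const, genes = list()) {
  y <- as.numeric(state)
  if (any(!is.finite(y))) stop("non-finite state")
  fl <- flatten_params(params, genes)
  J <- jac_core(y, S_const, fl$pv, fl$gv)
  dimnames(J) <- list(state_names(genes), state_names(genes))
  J
}

#' Classify the dynamical regime at constant stimulation
#'
#' Finds the fixed point, computes the eigenvalues of the analytic Jacobian
#' and classifies the regime: \emph{sustained} oscillations if at least one
#' eigenvalue has positive real part (unstable fixed point, stable limit
#' cycle around it), \emph{damped} otherwise. Real parts within
#' \code{dead_band} of zero are classified damped and flagged marginal.
#'
#' @param params a [kinetic_params()] set.
#' @param S_const constant activation rate (h^-1).
#' @param dead_band tolerance around zero for marginal eigenvalues.
#' @param seed_state optional Newton seed passed to [find_fixed_point()].
#' @return an object of class \code{stability_report}: fixed point,
#'   eigenvalues, \code{classification} ("damped"/"sustained"),
#'   \code{n_complex_pairs}, \code{marginal} flag.
#' @export
classify_stability <- function(params, S_const, dead_band = 1e-9,
                               seed_state = NULL) {
  fp <- if (is.null(seed_state)) find_fixed_point(params, S_const) else
    tryCatch(find_fixed_point(params, S_const, seed_state = seed_state),
             error = function(e) find_fixed_point(params, S_const))
  J <- model_jacobian(params, fp, S_const)
  ev <- eigen(J, only.values = TRUE)$values
  re <- Re(ev)
  sustained <- any(re > dead_band)
  marginal <- !sustained && any(abs(re) <= dead_band)
  structure(list(fixed_point = fp, eigenvalues = ev,
                 classification = if (sustained) "sustained" else "damped",
                 n_complex_pairs = sum(abs(Im(ev)) > 1e-12) %/% 2L,
                 marginal = marginal, S_const = S_const),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %s (max Re lambda = %.4g, %d complex pair%s%s)\n",
              x$classification, max(Re(x$eigenvalues)), x$n_complex_pairs,
              if (x$n_complex_pairs == 1) "" else "s",
              if (x$marginal) ", marginal" else ""))
  invisible(x)
}

#' Responding-trajectory filter
#'
#' A trajectory under constant stimulation counts as a \emph{response} when
#' the nuclear fraction exceeds 0.4 within the first 3 h and its mean over
#' the final window has relaxed back to at most 0.4.
#'
#' @param traj an \code{nfkb_trajectory}.
#' @param threshold nuclear-fraction threshold (default 0.4).
#' @param early_window initial window that must contain the excursion (min).
#' @param tail_window length of the final averaging window (min).
#' @return logical flag.
#' @export
is_responding <- function(traj, threshold = 0.4,
                          early_window = 180, tail_window = 120) {
  tt <- traj$times
  if (max(tt) < early_window + tail_window)
    stop("trajectory too short for the responding filter")
  N <- traj$states[, "N"]
  peak_ok <- max(N[tt <= early_window]) > threshold
  tail_ok <- mean(N[tt >= max(tt) - tail_window]) <= threshold
  peak_ok && tail_ok
}

#' Randomized-parameter stability scan
#'
#' Draws parameter sets from a log-uniform prior, keeps the ones whose
#' simulated response passes the [is_responding()] filter, classifies each
#' by Jacobian eigenvalues, and reports the fraction of responding draws in
#' the sustained regime, together with per-draw records and a per-parameter
#' summary of oscillating versus damped draws.
#'
#' @param prior a [parameter_prior()].
#' @param n_samples number of draws.
#' @param S_const constant activation rate (h^-1).
#' @param seed integer seed (required for reproducibility).
#' @param horizon simulation horizon for the responding filter (min).
#' @param sampling sampling step (min).
#' @return an object of class \code{stability_scan}: \code{draws} data frame
#'   (one row per draw: parameters, responding flag, classification, max real
#'   part, complex pairs), \code{fraction_sustained} among responding draws,
#'   \code{n_responding}, and \code{parameter_summary} (mean/sd of each
#'   parameter by classification).
#' @export
stability_scan <- function(prior, n_samples, S_const = 2, seed,
                           horizon = 1200, sampling = 6) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (missing(seed)) stop("stability_scan requires an explicit seed")
  set.seed(seed)
  fc <- forcing_signal("constant", S_high = S_const)
  grid <- seq(0, horizon, by = sampling)
  rows <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    pars <- randomize_parameters(prior)
    rec <- as.list(unlist(pars[.kinetic_names]))
    rec$responding <- FALSE
    rec$classification <- NA_character_
    rec$max_re <- NA_real_
    rec$n_complex_pairs <- NA_integer_
    ok <- try({
      traj <- simulate_nfkb(pars, fc, t_grid = grid)
      rec$responding <- is_responding(traj)
      if (rec$responding) {
        rep_ <- classify_stability(pars, S_const,
                                   seed_state = traj$states[nrow(traj$states), ])
        rec$classification <- rep_$classification
        rec$max_re <- max(Re(rep_$eigenvalues))
        rec$n_complex_pairs <- rep_$n_complex_pairs
      }
    }, silent = TRUE)
    if (inherits(ok, "try-error")) rec$classification <- "error"
    rows[[i]] <- rec
  }
  draws <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  resp <- draws[which(draws$responding & draws$classification %in% c("damped", "sustained")), ]
  if (nrow(resp) == 0) stop("no responding draws in the scan")
  frac <- mean(resp$classification == "sustained")
  summ <- do.call(rbind, lapply(.kinetic_names, function(nm) {
    data.frame(parameter = nm,
               mean_damped = mean(resp[[nm]][resp$classification == "damped"]),
               sd_damped = stats::sd(resp[[nm]][resp$classification == "damped"]),
               mean_sustained = mean(resp[[nm]][resp$classification == "sustained"]),
               sd_sustained = stats::sd(resp[[nm]][resp$classification == "sustained"]))
  }))
  structure(list(draws = draws, n_sampled = n_samples,
                 n_responding = nrow(resp), fraction_sustained = frac,
                 parameter_summary = summ, seed = seed, S_const = S_const),
            class = "stability_scan")
}

#' @export
print.stability_scan <- function(x, ...) {
  cat(sprintf(paste0("<stability_scan> %d draws, %d responding, ",
                     "fraction sustained = %.3f (seed %d)\n"),
              x$n_sampled, x$n_responding, x$fraction_sustained, x$seed))
  invisible(x)
}

#' Forcing-period locking scan
#'
#' For each forcing period \code{T_f} and high-phase amplitude, simulates a
#' symmetric square forcing (\code{T1 = T2 = T_f/2}), detects significant
#' NCI peaks, and reports the ratio of the mean inter-peak interval
#' \code{T_numerical} to \code{T_f}. Ratios near one indicate the damped
#' oscillator follows the forcing period; ratios near 0.5 are flagged as
#' small-inter-pulse-peak regimes.
#'
#' @param params a [kinetic_params()] set (damped regime assumed).
#' @param T_f_grid forcing periods (min).
#' @param amplitudes high-phase activation rates (h^-1).
#' @param horizon simulation span (min, default 15 h).
#' @param sampling sampling interval (min).
#' @param theta significant-peak height threshold on NCI.
#' @param skip_first drop significant peaks earlier than this (min) before
#'   measuring intervals, so the entrainment transient (which can ring at
#'   the natural rather than the forcing period for a few cycles) does not
#'   contaminate the asymptotic period estimate.
#' @return data frame with columns \code{T_f}, \code{amplitude},
#'   \code{n_peaks}, \code{T_numerical}, \code{ratio},
#'   \code{small_peak_regime}; \code{ratio} is \code{NA} when fewer than two
#'   significant peaks are found.
#' @export
forcing_period_scan <- function(params, T_f_grid, amplitudes = 2,
                                horizon = 900, sampling = 6, theta = 0.15,
                                skip_first = 360) {
  grid <- seq(0, horizon, by = sampling)
  out <- expand.grid(T_f = T_f_grid, amplitude = amplitudes,
                     KEEP.OUT.ATTRS = FALSE)
  out$n_peaks <- NA_integer_; out$T_numerical <- NA_real_
  out$ratio <- NA_real_; out$small_peak_regime <- FALSE
  for (i in seq_len(nrow(out))) {
    Tf <- out$T_f[i]
    fc <- forcing_signal("square", S_high = out$amplitude[i], S_low = 0,
                         T1 = Tf / 2, T2 = Tf / 2)
    traj <- simulate_nfkb(params, fc, t_grid = grid)
    pk <- detect_peaks(traj$times, traj$nci, threshold = theta)
    tp <- pk$maxima_times[pk$significant & pk$maxima_times >= skip_first]
    out$n_peaks[i] <- length(tp)
    if (length(tp) >= 2) {
      Tn <- mean(diff(tp))
      out$T_numerical[i] <- Tn
      out$ratio[i] <- Tn / Tf
      out$small_peak_regime[i] <- Tn / Tf < 0.75
    }
  }
  out
}
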