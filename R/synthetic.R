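# Seed-reproducible synthetic data: heterogeneous single-cell NCI cohorts,
# gene-expression panels with known ground truth, and phase-difference
# samples. These generators define the study conditions every downstream
# analysis is exercised on.

#' Cohort specification
#'
#' Conditions for a synthetic single-cell imaging cohort: cell-to-cell
#' heterogeneity is parameter variation (a small per-cell uncertainty
#' degree), measurement noise is multiplicative log-normal on NCI, and
#' tracking loss is a per-frame dropout.
#'
#' @param n_cells number of cells.
#' @param forcing a [forcing_signal()]; give it \code{t_start} > 0 to
#'   include a pre-stimulus baseline segment in every trace.
#' @param base baseline [kinetic_params()].
#' @param cell_degree per-cell uncertainty degree applied to every
#'   parameter (default 0.15; a factor within [10^-0.15, 10^0.15]).
#' @param sampling_interval imaging interval (min, default 6).
#' @param duration track duration (min, default 12 h).
#' @param noise_sd log-normal measurement noise sd on NCI (default 0.05).
#' @param track_loss per-frame dropout probability (default 0.002).
#' @param theta significance threshold used for the ground-truth peaks.
#' @param seed integer seed.
#' @return an object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_cells, forcing, base = kinetic_params(),
                        cell_degree = 0.15, sampling_interval = 6,
                        duration = 720, noise_sd = 0.05, track_loss = 0.002,
                        theta = 0.15, seed = 1) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (track_loss < 0 || track_loss >= 1) stop("track_loss must be in [0, 1)")
  structure(list(n_cells = n_cells, forcing = forcing, base = base,
                 cell_degree = cell_degree,
                 sampling_interval = sampling_interval, duration = duration,
                 noise_sd = noise_sd, track_loss = track_loss,
                 theta = theta, seed = seed), class = "cohort_spec")
}

#' Generate a synthetic single-cell cohort
#'
#' Per cell: draws a parameter set from the cell-heterogeneity prior,
#' simulates the model under the configured forcing, samples NCI on the
#' imaging grid, applies multiplicative log-normal noise (unit mean) and
#' truncates the track at the first dropout frame. The significant peaks
#' of each noiseless trace are returned as ground truth for detector
#' benchmarking.
#'
#' @param spec a [cohort_spec()].
#' @return list with \code{traces} (a [trace_set()]) and \code{truth}
#'   (per-cell list: \code{peak_times} of the noiseless trace,
#'   \code{params}, \code{track_frames}).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  grid <- seq(0, spec$duration, by = spec$sampling_interval)
  degrees <- rep(spec$cell_degree, length(.kinetic_names))
  names(degrees) <- .kinetic_names
  prior <- parameter_prior(spec$base, degrees)
  cells <- list(); truth <- list()
  for (i in seq_len(spec$n_cells)) {
    id <- sprintf("cell_%03d", i)
    pars <- randomize_parameters(prior)
    traj <- simulate_nfkb(pars, spec$forcing, t_grid = grid)
    nci_clean <- traj$nci
    pk <- detect_peaks(grid, nci_clean, threshold = spec$theta)
    noise <- if (spec$noise_sd > 0)
      stats::rlnorm(length(grid), -spec$noise_sd^2 / 2, spec$noise_sd)
    else rep(1, length(grid))
    nci_noisy <- nci_clean * noise
    n_keep <- length(grid)
    if (spec$track_loss > 0) {
      # geometric tracking loss; never truncate below 3 frames
      drop_at <- stats::rgeom(1, spec$track_loss) + 1L
      n_keep <- max(3L, min(n_keep, drop_at))
    }
    cells[[id]] <- list(times = grid[seq_len(n_keep)],
                        nci = nci_noisy[seq_len(n_keep)])
    truth[[id]] <- list(
      peak_times = pk$maxima_times[pk$significant &
                                     pk$maxima_times <= grid[n_keep]],
      params = pars, track_frames = n_keep)
  }
  list(traces = trace_set(cells, spec$sampling_interval,
                          metadata = list(forcing = spec$forcing)),
       truth = truth)
}

#' Default gene archetypes for expression panels
#'
#' Six dynamical archetypes spanning the observed expression patterns.
#' Up-regulated, NF-kB-driven: \code{oscillating} (fast mRNA turnover,
#' expression pulses resetting with each stimulation), \code{fast_up}
#' (persistently activated promoter, smooth saturating rise) and
#' \code{slow_up} (accumulating; mRNA turnover two orders of magnitude
#' below the oscillating archetype's). Down-regulated, NF-kB-independent
#' pure mRNA decay: immediate (\code{decay_early}), delayed onset
#' (\code{decay_late}) and gradual (\code{decay_slow}). The shapes differ
#' in normalized temporal form, not only in rate or scale: profile
#' standardization removes scale, under which e.g. pure exponentials of
#' different rates would be indistinguishable.
#'
#' @return named list; model-driven archetypes hold a [gene_params()],
#'   decay archetypes \code{rate} (h^-1), \code{delay} (min), \code{floor}
#'   (plateau fold change).
#' @export
default_archetypes <- function() {
  list(
    oscillating = list(kind = "model",
                       gene = gene_params(k_on_G = 4.68, k_on0_G = 0.0908,
                                          k_off_G = 11.8, k_off0_G = 0.189,
                                          d_R_G = 2.4)),
    fast_up = list(kind = "model",
                   gene = gene_params(k_on_G = 4.68, k_on0_G = 0.001,
                                      k_off_G = 0, k_off0_G = 0.4,
                                      d_R_G = 2)),
    slow_up = list(kind = "model",
                   gene = gene_params(k_on_G = 1, k_on0_G = 0,
                                      k_off_G = 11.8, k_off0_G = 3,
                                      d_R_G = 0.06)),
    decay_early = list(kind = "decay", rate = 3, delay = 0, floor = 0.08),
    decay_late = list(kind = "decay", rate = 1.2, delay = 240, floor = 0.05),
    decay_slow = list(kind = "decay", rate = 0.22, delay = 0, floor = 0))
}

#' Microarray-style sampling schedule
#'
#' Timepoints at 0 and 20, 40, 60 min after each of \code{n_pulses}
#' periodic stimulation pulses.
#'
#' @param T_f forcing period (min, default 180).
#' @param n_pulses number of pulses sampled (default 3).
#' @return numeric timepoints (min).
#' @export
panel_timepoints <- function(T_f = 180, n_pulses = 3) {
  sort(unique(c(0, as.vector(outer(c(20, 40, 60),
                                   T_f * (seq_len(n_pulses) - 1), "+")))))
}

#' Panel specification
#'
#' @param archetypes archetype list as in [default_archetypes()].
#' @param genes_per_archetype number of genes per archetype (default 20).
#' @param timepoints sampling times (min), default [panel_timepoints()].
#' @param noise_sd sd of the multiplicative log-normal noise on fold
#'   changes, quoted on the log2 scale as is conventional for array
#'   replicate noise (default 0.1; the underlying normal has
#'   sd = noise_sd * log 2).
#' @param seed integer seed.
#' @return an object of class \code{panel_spec}.
#' @export
panel_spec <- function(archetypes = default_archetypes(),
                       genes_per_archetype = 20,
                       timepoints = panel_timepoints(), noise_sd = 0.1,
                       seed = 1) {
  structure(list(archetypes = archetypes,
                 genes_per_archetype = genes_per_archetype,
                 timepoints = timepoints, noise_sd = noise_sd, seed = seed),
            class = "panel_spec")
}

#' Generate a synthetic expression panel
#'
#' Model-driven archetypes produce mature-mRNA fold changes through the
#' telegraph transcription module under the given dynamics and forcing;
#' decay archetypes produce pure exponential decays (emulating
#' down-regulated genes whose profile is simple RNA degradation).
#' Log-normal noise multiplies every entry. Archetype labels are returned
#' as ground truth.
#'
#' @param spec a [panel_spec()].
#' @param params shared [kinetic_params()].
#' @param forcing a [forcing_signal()].
#' @return list with \code{em} (an [expression_matrix()] of fold changes),
#'   \code{labels} (named archetype per gene), \code{clean} (noiseless
#'   matrix).
#' @export
generate_expression_panel <- function(spec, params = kinetic_params(),
                                      forcing = forcing_signal(
                                        "square", S_high = 2, S_low = 0,
                                        T1 = 30, T2 = 150)) {
  stopifnot(inherits(spec, "panel_spec"))
  set.seed(spec$seed)
  tp <- spec$timepoints
  arche_fc <- lapply(spec$archetypes, function(a) {
    if (a$kind == "model")
      fold_change_series(params, a$gene, forcing, tp)
    else
      a$floor + (1 - a$floor) * exp(-a$rate * pmax(0, min2h(tp - a$delay)))
  })
  sdlog <- spec$noise_sd * log(2)  # log2-scale sd -> natural-log sd
  values <- NULL; labels <- character(0); clean <- NULL
  for (nm in names(arche_fc)) {
    for (j in seq_len(spec$genes_per_archetype)) {
      gid <- sprintf("%s_%02d", nm, j)
      base <- arche_fc[[nm]]
      noise <- if (spec$noise_sd > 0)
        stats::rlnorm(length(tp), -sdlog^2 / 2, sdlog)
      else rep(1, length(tp))
      values <- rbind(values, base * noise)
      clean <- rbind(clean, base)
      rownames(values)[nrow(values)] <- gid
      rownames(clean)[nrow(clean)] <- gid
      labels[gid] <- nm
    }
  }
  list(em = expression_matrix(values, tp), labels = labels, clean = clean)
}

#' Generate phase-difference samples
#'
#' Reference distributions for the synchrony statistic: \code{flat}
#' (uniform on [0, 2*pi)), \code{delta} (a single repeated value) and
#' \code{concentrated} (wrapped normal around pi with circular sd
#' \code{1/sqrt(kappa)}).
#'
#' @param kind one of "flat", "delta", "concentrated".
#' @param n sample size.
#' @param seed integer seed.
#' @param kappa concentration for the wrapped distribution.
#' @param center location for delta/concentrated samples (default pi).
#' @return numeric vector of phase differences in [0, 2*pi).
#' @export
generate_phase_samples <- function(kind = c("flat", "delta", "concentrated"),
                                   n, seed = 1, kappa = 4, center = pi) {
  kind <- match.arg(kind)
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  x <- switch(kind,
    flat = stats::runif(n, 0, 2 * pi),
    delta = rep(center, n),
    concentrated = stats::rnorm(n, center, 1 / sqrt(kappa)))
  x %% (2 * pi)
}
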