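# Normalized NF-kB ODE system with IkBa and A20 negative feedbacks.
#
# State ordering: K, N, G_I, R_I, I, G_A, R_A, A [, gene_<id>_G, gene_<id>_R].
# Internal time unit is hours (all rates are h^-1); every public interface
# takes and returns minutes. Conversion happens only in this file.

.core_state_names <- c("K", "N", "G_I", "R_I", "I", "G_A", "R_A", "A")

min2h <- function(t) t / 60
h2min <- function(t) t * 60

state_names <- function(genes = list()) {
  nm <- .core_state_names
  if (length(genes)) {
    ids <- names(genes)
    if (is.null(ids)) ids <- paste0("g", seq_along(genes))
    nm <- c(nm, as.vector(rbind(paste0("gene_", ids, "_G"),
                                paste0("gene_", ids, "_R"))))
  }
  nm
}

# Flatten a kinetic_params (+ genes) into the numeric vectors used by the
# inner loops: pv follows .kinetic_names; each gene contributes 5 rates with
# its k_off_G already zeroed when the repressor arm is off.
flatten_params <- function(params, genes = list()) {
  pv <- unlist(params[.kinetic_names], use.names = FALSE)
  if (!params$repressor_active) pv[c(13L, 17L)] <- 0  # k_off_I, k_off_A
  gv <- lapply(genes, function(g) {
    v <- c(g$k_on_G, g$k_on0_G, g$k_off_G, g$k_off0_G, g$d_R_G)
    if (!params$repressor_active) v[3L] <- 0
    v
  })
  list(pv = pv, gv = gv)
}

# Core vector field in internal units (t in hours, returns d/dt in h^-1).
# S is the instantaneous activation rate (h^-1); pv/gv from flatten_params.
rhs_core <- function(y, S, pv, gv = list()) {
  K <- y[1L]; N <- y[2L]; G_I <- y[3L]; R_I <- y[4L]
  I <- y[5L]; G_A <- y[6L]; R_A <- y[7L]; A <- y[8L]
  dy <- numeric(length(y))
  dy[1L] <- -pv[1L] * K + S / (1 + A^pv[2L])
  dy[2L] <- pv[3L] * (1 - N) + pv[4L] * pv[5L] * (1 - N) +
            pv[6L] * K * (1 - N) - pv[7L] * I * N
  dy[3L] <- (pv[11L] * N + pv[12L]) * (1 - G_I) - (pv[13L] * I + pv[14L]) * G_I
  dy[4L] <- pv[10L] * (G_I - R_I)
  dy[5L] <- pv[3L] * (1 - N) - pv[8L] * pv[6L] * K * I - pv[7L] * I * N +
            pv[9L] * R_I - pv[5L] * I
  dy[6L] <- (pv[15L] * N + pv[16L]) * (1 - G_A) - (pv[17L] * I + pv[18L]) * G_A
  dy[7L] <- pv[19L] * (G_A - R_A)
  dy[8L] <- pv[20L] * R_A - pv[21L] * A
  if (length(gv)) {
    for (j in seq_along(gv)) {
      g <- gv[[j]]
      iG <- 7L + 2L * j; iR <- iG + 1L
      G <- y[iG]; R <- y[iR]
      dy[iG] <- (g[1L] * N + g[2L]) * (1 - G) - (g[3L] * I + g[4L]) * G
      dy[iR] <- g[5L] * (G - R)
    }
  }
  dy
}

# Analytic Jacobian of the full system at state y (internal units).
jac_core <- function(y, S, pv, gv = list()) {
  K <- y[1L]; N <- y[2L]; G_I <- y[3L]
  I <- y[5L]; G_A <- y[6L]; A <- y[8L]
  m <- length(y)
  J <- matrix(0, m, m)
  n <- pv[2L]
  An <- A^n
  J[1L, 1L] <- -pv[1L]
  J[1L, 8L] <- -S * n * A^(n - 1) / (1 + An)^2
  J[2L, 1L] <- pv[6L] * (1 - N)
  J[2L, 2L] <- -pv[3L] - pv[4L] * pv[5L] - pv[6L] * K - pv[7L] * I
  J[2L, 5L] <- -pv[7L] * N
  J[3L, 2L] <- pv[11L] * (1 - G_I)
  J[3L, 3L] <- -(pv[11L] * N + pv[12L]) - (pv[13L] * I + pv[14L])
  J[3L, 5L] <- -pv[13L] * G_I
  J[4L, 3L] <- pv[10L]
  J[4L, 4L] <- -pv[10L]
  J[5L, 1L] <- -pv[8L] * pv[6L] * I
  J[5L, 2L] <- -pv[3L] - pv[7L] * I
  J[5L, 4L] <- pv[9L]
  J[5L, 5L] <- -pv[8L] * pv[6L] * K - pv[7L] * N - pv[5L]
  J[6L, 2L] <- pv[15L] * (1 - G_A)
  J[6L, 6L] <- -(pv[15L] * N + pv[16L]) - (pv[17L] * I + pv[18L])
  J[6L, 5L] <- -pv[17L] * G_A
  J[7L, 6L] <- pv[19L]
  J[7L, 7L] <- -pv[19L]
  J[8L, 7L] <- pv[20L]
  J[8L, 8L] <- -pv[21L]
  if (length(gv)) {
    for (j in seq_along(gv)) {
      g <- gv[[j]]
      iG <- 7L + 2L * j; iR <- iG + 1L
      G <- y[iG]
      J[iG, 2L] <- g[1L] * (1 - G)
      J[iG, iG] <- -(g[1L] * N + g[2L]) - (g[3L] * I + g[4L])
      J[iG, 5L] <- -g[3L] * G
      J[iR, iG] <- g[5L]
      J[iR, iR] <- -g[5L]
    }
  }
  J
}

#' Model vector field
#'
#' Time derivative of the normalized state at time \code{t_min} under the
#' given forcing. Exposed mainly for inspection and testing; simulations use
#' the stiff integrator in [simulate_nfkb()].
#'
#' @param state named numeric state (K, N, G_I, R_I, I, G_A, R_A, A, plus a
#'   \code{gene_<id>_G}/\code{gene_<id>_R} pair per regulated gene).
#' @param t_min time in minutes.
#' @param params a [kinetic_params()] set.
#' @param forcing a [forcing_signal()].
#' @param genes named list of [gene_params()] for regulated genes.
#' @return named derivative vector in units of h^-1.
#' @export
nfkb_rhs <- function(state, t_min, params, forcing, genes = list()) {
  if (any(!is.finite(state))) stop("non-finite state")
  S <- evaluate_forcing(forcing, t_min)
  fl <- flatten_params(params, genes)
  dy <- rhs_core(as.numeric(state), S, fl$pv, fl$gv)
  names(dy) <- state_names(genes)
  dy
}

#' Nuclear-to-cytoplasmic intensity observable
#'
#' The NCI readout of a nuclear NF-kB fraction \code{N}:
#' \code{NCI = area_ratio * N / (1 - N)}, where \code{area_ratio} is the
#' nuclear-to-total area ratio of the imaged cells (about 1/3). Strictly
#' increasing in \code{N}, so NCI peaks coincide with nuclear-fraction peaks.
#'
#' @param N nuclear fraction(s) in [0, 1).
#' @param area_ratio nuclear-to-total area ratio (default 1/3).
#' @return NCI value(s).
#' @export
nci_of <- function(N, area_ratio = 1 / 3) {
  if (any(!is.finite(N)) || any(N < 0)) stop("N must be finite and >= 0")
  if (any(N >= 1)) stop("N must be < 1 (NCI diverges as the free fraction -> 1)")
  area_ratio * N / (1 - N)
}

#' Pre-stimulus resting state
#'
#' Integrates the unstimulated core system (S = 0) from a neutral interior
#' state until the vector field vanishes (max |dy/dt| < tol), giving the
#' initial condition used for all simulations. Regulated genes do not feed
#' back on the core, so their resting gene-activation fraction and mature
#' mRNA follow in closed form from the core rest point:
#' \code{G* = on/(on + off)}, \code{R* = G*} with
#' \code{on = k_on_G N* + k_on0_G}, \code{off = k_off_G I* + k_off0_G}.
#'
#' @param params a [kinetic_params()] set.
#' @param genes named list of [gene_params()].
#' @param tol convergence tolerance on the residual (h^-1).
#' @param max_hours give up after this much model time.
#' @return named resting state vector.
#' @export
resting_state <- function(params, genes = list(), tol = 1e-8, max_hours = 1000) {
  y <- rep(0.5, 8L); names(y) <- .core_state_names
  y["K"] <- 0
  null_forcing <- forcing_signal("constant", S_high = 0)
  fl <- flatten_params(params)
  t_chunk <- 50
  elapsed <- 0
  repeat {
    traj <- integrate_piecewise(y, c(0, t_chunk), params, null_forcing)
    y <- traj[nrow(traj), -1L]
    res <- max(abs(rhs_core(as.numeric(y), 0, fl$pv)))
    if (res < tol) break
    # Newton polish: the integrator's accuracy floor can sit above tol for
    # very stiff parameter draws
    yn <- newton_root(as.numeric(y), 0, fl$pv)
    if (!is.null(yn) && max(abs(rhs_core(yn, 0, fl$pv))) < tol &&
        all(yn > -1e-9)) {
      y <- yn
      break
    }
    elapsed <- elapsed + t_chunk
    if (elapsed >= max_hours)
      stop(sprintf("resting state not converged within %g h (residual %.3e h^-1)",
                   max_hours, res))
  }
  y <- pmin(pmax(as.numeric(y), 0), 1)
  names(y) <- .core_state_names
  if (length(genes)) {
    flg <- flatten_params(params, genes)
    gst <- unlist(lapply(flg$gv, function(g) {
      on <- g[1L] * y[["N"]] + g[2L]
      off <- g[3L] * y[["I"]] + g[4L]
      Gs <- if (on + off > 0) on / (on + off) else 0
      c(Gs, Gs)
    }))
    y <- c(y, gst)
    names(y) <- state_names(genes)
  }
  y
}

compiled_available <- function() {
  is.loaded("nfkb_derivs", PACKAGE = "nfkbsync")
}

# Damped Newton iteration on the core vector field at constant S.
# Returns the root or NULL.
newton_root <- function(y, S, pv, gv = list(), tol = 1e-12, max_iter = 100) {
  for (it in seq_len(max_iter)) {
    f <- rhs_core(y, S, pv, gv)
    if (max(abs(f)) < tol) return(y)
    J <- jac_core(y, S, pv, gv)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lambda <- 1
    f0 <- sum(f^2)
    repeat {
      y_new <- y + lambda * step
      f_new <- rhs_core(y_new, S, pv, gv)
      if (all(is.finite(f_new)) && sum(f_new^2) < f0) break
      lambda <- lambda / 2
      if (lambda < 1e-10) return(y)
    }
    y <- y_new
  }
  y
}

# Integrate over an internal-hours window [t0, t1] given in `times` (hours),
# splitting at forcing switch times. Returns a deSolve-style matrix.
# Uses the compiled vector field when the package DLL is loaded; the pure-R
# closures (rhs_core/jac_core) are the reference path and drop-in fallback.
integrate_piecewise <- function(y0, times_h, params, forcing, genes = list(),
                                rtol = 1e-8, atol = 1e-10) {
  sw_min <- forcing_switch_times(forcing, h2min(times_h[1]),
                                 h2min(times_h[length(times_h)]))
  knots <- sort(unique(c(times_h, min2h(sw_min))))
  seg_ends <- c(min2h(sw_min), times_h[length(times_h)])
  seg_ends <- sort(unique(seg_ends[seg_ends > times_h[1]]))
  fl <- flatten_params(params, genes)
  out <- matrix(c(times_h[1], y0), nrow = 1)
  y <- y0
  t0 <- times_h[1]
  use_c <- compiled_available()
  for (t1 in seg_ends) {
    # constant S within the open segment; evaluate just inside it
    S <- evaluate_forcing(forcing, h2min(t0) + 1e-9)
    tt <- unique(c(t0, times_h[times_h > t0 & times_h < t1], t1))
    sol <- if (use_c) {
      deSolve::lsoda(
        y = y, times = tt, func = "nfkb_derivs",
        parms = {
          pp <- c(S, fl$pv, length(fl$gv), unlist(fl$gv))
          length(pp) <- 543L  # fixed DLL parameter block, zero-padded
          pp[is.na(pp)] <- 0
          pp
        },
        jacfunc = "nfkb_jac", dllname = "nfkbsync", initfunc = "nfkb_init",
        jactype = "fullusr", rtol = rtol, atol = atol, maxsteps = 50000)
    } else {
      deSolve::lsoda(
        y = y, times = tt,
        func = function(t, y, p) list(rhs_core(y, S, fl$pv, fl$gv)),
        parms = NULL,
        jacfunc = function(t, y, p) jac_core(y, S, fl$pv, fl$gv),
        jactype = "fullusr", rtol = rtol, atol = atol, maxsteps = 50000)
    }
    if (attr(sol, "istate")[1L] < 0)
      stop("stiff integrator failed (istate = ", attr(sol, "istate")[1L], ")")
    out <- rbind(out, sol[-1L, , drop = FALSE])
    y <- sol[nrow(sol), -1L]
    t0 <- t1
  }
  out[out[, 1] %in% times_h, , drop = FALSE]
}

#' Simulate the NF-kB model
#'
#' Stiff adaptive integration (lsoda with the analytic Jacobian) of the
#' normalized system, sampled on a user grid in minutes. The forcing signal
#' is integrated piecewise between its switch times so square and sawtooth
#' discontinuities are resolved exactly. Bound violations within 1e-6
#' (solver slop) are clipped; anything larger raises an error.
#'
#' @param params a [kinetic_params()] set.
#' @param forcing a [forcing_signal()].
#' @param genes named list of [gene_params()] for regulated genes.
#' @param t_grid strictly increasing sampling times (minutes).
#' @param initial \code{"resting"} (default) or a full named state vector.
#' @param area_ratio nuclear-to-total area ratio for the NCI observable.
#' @return an object of class \code{nfkb_trajectory}: list with \code{times}
#'   (min), \code{states} (matrix, one row per time), \code{nci}, and the
#'   provenance fields \code{params}, \code{forcing}, \code{genes}.
#' @examples
#' tr <- simulate_nfkb(kinetic_params(),
#'                     forcing_signal("constant", S_high = 2),
#'                     t_grid = seq(0, 360, by = 6))
#' @export
simulate_nfkb <- function(params, forcing, genes = list(),
                          t_grid = seq(0, 720, by = 6),
                          initial = "resting", area_ratio = 1 / 3) {
  if (is.unsorted(t_grid, strictly = TRUE)) stop("t_grid must be strictly increasing")
  nm <- state_names(genes)
  if (identical(initial, "resting")) {
    y0 <- resting_state(params, genes)
  } else {
    if (length(initial) != length(nm)) stop("initial state has wrong length")
    y0 <- as.numeric(initial); names(y0) <- nm
  }
  times_h <- min2h(t_grid)
  pad <- FALSE
  if (times_h[1] > 0) { times_h <- c(0, times_h); pad <- TRUE }
  sol <- integrate_piecewise(y0, times_h, params, forcing, genes)
  if (pad) sol <- sol[-1L, , drop = FALSE]
  states <- sol[, -1L, drop = FALSE]
  colnames(states) <- nm
  states <- repair_bounds(states, nm)
  traj <- structure(list(times = t_grid, states = states,
                         nci = nci_of(states[, "N"], area_ratio),
                         params = params, forcing = forcing, genes = genes),
                    class = "nfkb_trajectory")
  traj
}

# Clip tiny invariant violations, raise on real ones.
repair_bounds <- function(states, nm) {
  tol <- 1e-6
  unit <- grepl("^(N|G_I|G_A|R_I|R_A)$|_G$|_R$", nm)
  low <- min(states)
  high <- max(states[, unit, drop = FALSE])
  if (low < -tol || high > 1 + tol)
    stop(sprintf("state invariant violated beyond tolerance (min %.3e, max %.3e)",
                 low, high))
  states[states < 0] <- 0
  states[, unit][states[, unit] > 1] <- 1
  states
}

#' @export
print.nfkb_trajectory <- function(x, ...) {
  cat(sprintf("<nfkb_trajectory> %d samples over [%g, %g] min, %d state variables\n",
              length(x$times), min(x$times), max(x$times), ncol(x$states)))
  invisible(x)
}

#' Trajectory as a data frame
#'
#' @param x an \code{nfkb_trajectory}.
#' @param ... unused.
#' @return data frame with \code{time_min}, one column per state variable,
#'   and \code{nci} — the trajectory export format.
#' @export
as.data.frame.nfkb_trajectory <- function(x, ...) {
  data.frame(time_min = x$times, x$states, nci = x$nci, check.names = FALSE)
}
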