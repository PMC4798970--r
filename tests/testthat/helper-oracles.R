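# Independent oracles and small fixture builders shared across tests.

# Fixed-step classical RK4 integration of the model at constant S,
# independent of the adaptive solver path (uses the pure-R vector field).
rk4_integrate <- function(params, S, y0, t_end_h, dt_h = 0.001,
                          genes = list()) {
  fl <- nfkbsync:::flatten_params(params, genes)
  f <- function(y) nfkbsync:::rhs_core(y, S, fl$pv, fl$gv)
  n <- ceiling(t_end_h / dt_h)
  y <- y0
  out <- matrix(NA_real_, n + 1, length(y0))
  out[1, ] <- y
  for (i in seq_len(n)) {
    k1 <- f(y)
    k2 <- f(y + dt_h / 2 * k1)
    k3 <- f(y + dt_h / 2 * k2)
    k4 <- f(y + dt_h * k3)
    y <- y + dt_h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1, ] <- y
  }
  list(times_h = seq(0, n) * dt_h, states = out)
}

# Central finite-difference Jacobian of the vector field.
fd_jacobian <- function(params, state, S, h = 1e-6, genes = list()) {
  fl <- nfkbsync:::flatten_params(params, genes)
  y <- as.numeric(state)
  m <- length(y)
  J <- matrix(0, m, m)
  for (j in seq_len(m)) {
    yp <- y; ym <- y
    yp[j] <- yp[j] + h; ym[j] <- ym[j] - h
    J[, j] <- (nfkbsync:::rhs_core(yp, S, fl$pv, fl$gv) -
                 nfkbsync:::rhs_core(ym, S, fl$pv, fl$gv)) / (2 * h)
  }
  J
}

# One-sided hypergeometric tail P(X >= a) by direct enumeration over the
# 2x2 tables with the given margins (binomial-coefficient arithmetic).
hypergeom_tail <- function(a, b, c, d) {
  n_cluster <- a + b
  n_target <- a + c
  n_total <- a + b + c + d
  kmax <- min(n_cluster, n_target)
  sum(vapply(a:kmax, function(k)
    exp(lchoose(n_target, k) + lchoose(n_total - n_target, n_cluster - k) -
          lchoose(n_total, n_cluster)), numeric(1)))
}

# Synthetic trace with Gaussian bumps planted at known times.
planted_trace <- function(times, peak_times, height = 0.4, width = 25,
                          baseline = 0.05) {
  v <- rep(baseline, length(times))
  for (tp in peak_times)
    v <- v + height * exp(-(times - tp)^2 / (2 * width^2))
  v
}

# Match detected peak times against planted truth within a tolerance.
match_peaks <- function(detected, truth, tol = 15) {
  hits <- vapply(truth, function(tt) any(abs(detected - tt) <= tol), logical(1))
  fp <- vapply(detected, function(td) !any(abs(truth - td) <= tol), logical(1))
  c(recall = if (length(truth)) mean(hits) else NA_real_,
    precision = if (length(detected)) 1 - mean(fp) else NA_real_)
}

# Small cached baseline objects (built once per test run).
baseline_params <- kinetic_params()
constant_forcing <- function(S = 2, t_start = 0)
  forcing_signal("constant", S_high = S, t_start = t_start)
square_forcing <- function(S = 2, T1 = 45, T2 = 45, t_start = 0)
  forcing_signal("square", S_high = S, S_low = 0, T1 = T1, T2 = T2,
                 t_start = t_start)
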