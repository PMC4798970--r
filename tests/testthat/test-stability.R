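test_that("analytic Jacobian entries match calculus and finite differences", {
  p <- baseline_params
  st <- c(K = 0.3, N = 0.2, G_I = 0.4, R_I = 0.35, I = 0.25, G_A = 0.3,
          R_A = 0.3, A = 0.6)
  S <- 2
  J <- model_jacobian(p, st, S)
  expect_equal(J["K", "K"], -p$d_K)
  expect_equal(J["K", "A"],
               -S * p$n * st[["A"]]^(p$n - 1) / (1 + st[["A"]]^p$n)^2)
  expect_equal(J["R_I", "G_I"], p$d_RI)
  expect_equal(J["A", "A"], -p$d_A)
  # against central differences on random interior states
  set.seed(4)
  for (i in 1:5) {
    y <- runif(8, 0.05, 0.8)
    Jfd <- fd_jacobian(p, y, S)
    Jan <- model_jacobian(p, y, S)
    scale <- pmax(abs(Jfd), 1e-6)
    expect_lt(max(abs(Jan - Jfd) / scale), 1e-5)
  }
})

test_that("fixed point solves the stationarity condition and attracts", {
  p <- baseline_params
  fp <- find_fixed_point(p, 2)
  expect_lt(max(abs(nfkb_rhs(fp, 0, p, constant_forcing(2)))), 1e-10)
  # long integration lands on it
  tr <- simulate_nfkb(p, constant_forcing(2), t_grid = c(0, 12000))
  expect_lt(max(abs(tr$states[2, ] - fp)), 1e-4)
  # S = 0 with no basal activation has K = 0
  p0 <- kinetic_params(k_on0_I = 0, k_on0_A = 0)
  fp0 <- find_fixed_point(p0, 0)
  expect_equal(unname(fp0["K"]), 0)
})

test_that("baseline is damped with conjugate eigenvalue pairs", {
  rep_ <- classify_stability(baseline_params, 2)
  expect_identical(rep_$classification, "damped")
  expect_true(all(Re(rep_$eigenvalues) < 0))
  ev <- rep_$eigenvalues
  cplx <- ev[abs(Im(ev)) > 1e-12]
  expect_true(length(cplx) %% 2 == 0)
  for (lam in cplx) expect_true(any(abs(Conj(lam) - cplx) < 1e-8))
  # dominant complex pair rings close to the 90-min natural period
  dom <- cplx[which.max(Re(cplx))]
  expect_lt(abs(2 * pi / abs(Im(dom)) * 60 - 90), 10)
})

test_that("parameter randomization follows the log-uniform degree law", {
  pr <- parameter_prior(baseline_params, default_degrees())
  # D = 0 returns the baseline untouched
  pr0 <- parameter_prior(baseline_params,
                         setNames(rep(0, 21), nfkbsync:::.kinetic_names))
  d0 <- randomize_parameters(pr0, seed = 1)
  expect_equal(unlist(d0[nfkbsync:::.kinetic_names]),
               unlist(baseline_params[nfkbsync:::.kinetic_names]))
  # D = 1 keeps the multiplicative factor within one decade either way
  pr1 <- parameter_prior(baseline_params,
                         setNames(rep(1, 21), nfkbsync:::.kinetic_names))
  set.seed(10)
  base_v <- unlist(baseline_params[nfkbsync:::.kinetic_names])
  for (i in 1:200) {
    f <- unlist(randomize_parameters(pr1)[nfkbsync:::.kinetic_names]) / base_v
    expect_true(all(f >= 0.1 - 1e-12 & f <= 10 + 1e-12))
  }
  # a seed reproduces the draw exactly
  expect_identical(randomize_parameters(pr, seed = 33),
                   randomize_parameters(pr, seed = 33))
})

test_that("responding filter demands an early excursion and late relaxation", {
  grid <- seq(0, 1200, by = 6)
  mk <- function(N) {
    states <- matrix(0.1, length(grid), 8,
                     dimnames = list(NULL, nfkbsync:::state_names()))
    states[, "N"] <- N
    structure(list(times = grid, states = states, nci = nci_of(N)),
              class = "nfkb_trajectory")
  }
  expect_false(is_responding(mk(rep(0.1, length(grid)))))   # never exceeds 0.4
  expect_false(is_responding(mk(rep(0.9, length(grid)))))   # tail stays high
  pulse <- 0.1 + 0.7 * exp(-(grid - 60)^2 / (2 * 30^2))
  expect_true(is_responding(mk(pulse)))
  short_grid <- seq(0, 200, by = 6)
  short_traj <- structure(
    list(times = short_grid,
         states = matrix(0.1, length(short_grid), 8,
                         dimnames = list(NULL, nfkbsync:::state_names())),
         nci = rep(0.03, length(short_grid))),
    class = "nfkb_trajectory")
  expect_error(is_responding(short_traj), "short")
  # the calibrated baseline responds
  tr <- simulate_nfkb(baseline_params, constant_forcing(2), t_grid = grid)
  expect_true(is_responding(tr))
})

test_that("stability scan is seed-reproducible and internally consistent", {
  pr <- parameter_prior(baseline_params, default_degrees())
  sc1 <- stability_scan(pr, 40, S_const = 2, seed = 7)
  sc2 <- stability_scan(pr, 40, S_const = 2, seed = 7)
  expect_identical(sc1$draws, sc2$draws)
  expect_equal(sc1$n_sampled, 40)
  expect_true(sc1$fraction_sustained >= 0 && sc1$fraction_sustained <= 1)
  resp <- sc1$draws[sc1$draws$responding &
                      sc1$draws$classification %in% c("damped", "sustained"), ]
  expect_equal(sc1$n_responding, nrow(resp))
  expect_equal(sc1$fraction_sustained,
               mean(resp$classification == "sustained"))
  # degenerate prior (all D = 0) on the damped baseline: zero sustained
  pr0 <- parameter_prior(baseline_params,
                         setNames(rep(0, 21), nfkbsync:::.kinetic_names))
  sc0 <- stability_scan(pr0, 3, S_const = 2, seed = 1)
  expect_equal(sc0$fraction_sustained, 0)
})

test_that("forcing-period scan locks at the baseline and goes missing without drive", {
  sc <- forcing_period_scan(baseline_params, T_f_grid = 90)
  expect_equal(sc$ratio, 1, tolerance = 0.05)
  # zero amplitude: no significant peaks, ratio reported missing
  sc0 <- forcing_period_scan(baseline_params, T_f_grid = 90, amplitudes = 0)
  expect_true(is.na(sc0$ratio))
  expect_identical(sc0$n_peaks, 0L)
})

test_that("stronger forcing never yields fewer post-stimulation peaks", {
  amps <- c(0.5, 1, 2)
  sc <- forcing_period_scan(baseline_params, T_f_grid = 90, amplitudes = amps,
                            skip_first = 0)
  npk <- sc$n_peaks[order(sc$amplitude)]
  expect_true(all(diff(npk) >= 0))
})
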