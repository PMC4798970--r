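test_that("relative distance follows the printed per-timepoint formula", {
  expect_equal(fit_distance(c(1), c(2)), 0.5)
  expect_equal(fit_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(fit_distance(c(0, 1), c(0, 1)), 0)      # 0/0 term counts as 0
  expect_equal(fit_distance(c(0, 2), c(1, 2)), 0.5)    # |0-1|/1 averaged over 2
  expect_error(fit_distance(c(-1), c(1)), "non-negative")
  expect_error(fit_distance(1:3, 1:2), "equal length")
})

test_that("distance is a premetric on non-negative series", {
  set.seed(14)
  for (i in 1:30) {
    X <- rexp(10); x <- rexp(10)
    d <- fit_distance(X, x)
    expect_gte(d, 0)
    expect_equal(d, fit_distance(x, X))
  }
  X <- rexp(10)
  expect_equal(fit_distance(X, X), 0)
  expect_gt(fit_distance(X, X + 0.1), 0)
})

test_that("model NCI series starts at the resting observable and peaks with N", {
  p <- baseline_params
  fc <- square_forcing(T1 = 30, T2 = 150)
  times <- seq(0, 540, by = 6)
  nci <- model_nci_series(p, fc, times)
  rest <- resting_state(p)
  expect_equal(nci[1], nci_of(rest[["N"]]), tolerance = 1e-6)
  tr <- simulate_nfkb(p, fc, t_grid = times)
  loc_max <- function(v) which(diff(sign(diff(v))) == -2) + 1
  expect_identical(loc_max(nci), loc_max(tr$states[, "N"]))
})

test_that("fold change is flat without stimulation and shaped by mRNA turnover", {
  p <- baseline_params
  times <- seq(0, 540, by = 20)
  flat <- fold_change_series(p, gene_params(), constant_forcing(0), times)
  expect_equal(flat, rep(1, length(times)), tolerance = 1e-5)
  fc <- square_forcing(T1 = 30, T2 = 150)
  fast <- fold_change_series(p, gene_params(d_R_G = 2.4), fc, times)
  slow_gene <- gene_params(k_on_G = 1, k_on0_G = 0.005, k_off_G = 11.8,
                           k_off0_G = 3, d_R_G = 0.024)
  slow <- fold_change_series(p, slow_gene, fc, times)
  # fast turnover: expression falls back between pulses (oscillating)
  between <- times > 60 & times < 180
  expect_lt(min(fast[between]) / max(fast[times <= 60]), 0.6)
  # 100x slower turnover: net accumulation with only shallow inter-pulse sags
  expect_gt(which.max(slow), 0.7 * length(slow))
  expect_gt(slow[length(slow)], 1.8 * slow[1])
  expect_true(all(diff(slow) > -0.05 * diff(range(slow))))
  # a gene with no basal activation at all has an undefined baseline
  p_noN <- kinetic_params(k_on0_I = 0, k_on0_A = 0, a = 500, d = 0, gamma = 0)
  expect_error(fold_change_series(p_noN, gene_params(k_on_G = 1, k_on0_G = 0),
                                  fc, times), "basal")
})

test_that("noiseless self-fit stays at the optimum", {
  p <- baseline_params
  fc <- square_forcing(T1 = 30, T2 = 150)
  times <- seq(0, 360, by = 12)
  obs <- model_nci_series(p, fc, times)
  pb <- fit_problem(datasets = list(list(kind = "nci", times = times,
                                         values = obs)),
                    params = p, free_nfkb = c("p", "a", "k_I"))
  res <- fit_model(pb, fc, mcmc = list(n_steps = 40), seed = 2)
  expect_lt(res$distance, 1e-6)
  expect_equal(res$params$p, p$p, tolerance = 1e-8)
})

test_that("fit respects the uncertainty box and the refinement never hurts", {
  p <- baseline_params
  fc <- square_forcing(T1 = 30, T2 = 150)
  times <- seq(0, 360, by = 12)
  truth <- kinetic_params(p = p$p * 1.6, k_I = p$k_I * 0.7)
  obs <- model_nci_series(truth, fc, times)
  pb <- fit_problem(datasets = list(list(kind = "nci", times = times,
                                         values = obs)),
                    params = p, free_nfkb = c("p", "k_I"))
  res <- fit_model(pb, fc, mcmc = list(n_steps = 150), seed = 5)
  for (i in seq_len(nrow(res$free))) {
    lo <- log10(res$free$init[i]) - res$free$degree[i]
    hi <- log10(res$free$init[i]) + res$free$degree[i]
    expect_gte(res$theta[i], lo - 1e-12)
    expect_lte(res$theta[i], hi + 1e-12)
  }
  # final distance never exceeds the best explored state
  expect_lte(res$distance, min(res$trace) + 1e-12)
  expect_lt(res$distance, 0.05)
})

test_that("degenerate problems are rejected up front", {
  times <- seq(0, 60, by = 12)
  expect_error(fit_problem(datasets = list(), params = baseline_params),
               "at least one")
  expect_error(fit_problem(
    datasets = list(list(kind = "nci", times = times,
                         values = rep(0.2, length(times)))),
    params = baseline_params, free_nfkb = "p"), "zero-variance")
  expect_error(fit_problem(
    datasets = list(list(kind = "nci", times = times, values = seq_along(times))),
    params = baseline_params, free_nfkb = "not_a_rate"), "unknown")
})

test_that("gene-panel fitting recovers the degradation-rate ordering", {
  p <- baseline_params
  fc <- square_forcing(T1 = 30, T2 = 150)
  times <- panel_timepoints()
  g_fast <- gene_params(d_R_G = 2.4)
  g_slow <- gene_params(k_on_G = 1, k_on0_G = 0, k_off_G = 11.8,
                        k_off0_G = 3, d_R_G = 0.06)
  fcs <- rbind(osc = fold_change_series(p, g_fast, fc, times),
               acc = fold_change_series(p, g_slow, fc, times))
  pf <- fit_gene_panel(fcs, times, p, fc, mcmc = list(n_steps = 250), seed = 9)
  expect_true(all(pf$table$ok))
  expect_lt(max(pf$table$distance), 0.05)
  expect_gt(pf$table$d_R_G[pf$table$gene == "osc"],
            pf$table$d_R_G[pf$table$gene == "acc"])
})
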