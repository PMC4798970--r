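test_that("peak detection applies the min-max-min rule with the height threshold", {
  tt <- seq(0, 600, by = 6)
  # an isolated 3-sample bump is a noise peak, never significant
  v <- rep(0.05, length(tt)); v[20] <- 0.30; v[19] <- 0.05; v[21] <- 0.05
  pk <- detect_peaks(tt, v)
  expect_equal(length(pk$maxima_times), 1L)
  expect_true(pk$noise[1])
  expect_false(pk$significant[1])
  # broad peak: height measured from the highest flanking minimum
  v2 <- planted_trace(tt, 300, height = 0.25, width = 30, baseline = 0.05)
  v2[tt < 150] <- 0.10   # left minimum higher than right one
  pk2 <- detect_peaks(tt, v2)
  sig <- which(pk2$significant)
  expect_length(sig, 1L)
  expect_equal(pk2$maxima_times[sig], 300)
  expect_equal(pk2$heights[sig],
               pk2$maxima_values[sig] - max(pk2$left_min_values[sig],
                                            pk2$right_min_values[sig]))
  # monotone trace has no peaks; sub-threshold peaks detected but flagged
  expect_length(detect_peaks(tt, seq(0, 1, length.out = length(tt)))$maxima_times, 0L)
  v3 <- planted_trace(tt, 300, height = 0.12, width = 30, baseline = 0.05)
  pk3 <- detect_peaks(tt, v3)
  expect_length(pk3$maxima_times, 1L)
  expect_false(any(pk3$significant))
  expect_error(detect_peaks(c(0, 6), c(1, 2)), "3 samples")
})

test_that("raising the threshold never increases the significant-peak count", {
  set.seed(11)
  tt <- seq(0, 720, by = 6)
  v <- planted_trace(tt, c(120, 300, 480), height = 0.3, width = 25) *
    rlnorm(length(tt), 0, 0.05)
  counts <- vapply(c(0.05, 0.1, 0.15, 0.25, 0.4),
                   function(th) sum(detect_peaks(tt, v, threshold = th)$significant),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_lte(sum(detect_peaks(tt, v)$significant), length(detect_peaks(tt, v)$maxima_times))
})

test_that("plateaus collapse to their midpoint and endpoints are never extrema", {
  tt <- seq(0, 120, by = 6)
  v <- c(0.1, 0.1, 0.3, 0.5, 0.5, 0.5, 0.3, 0.1, 0.05, 0.2, 0.4,
         0.6, 0.8, 0.9, 1.0, 1.1, 1.2, 1.3, 1.4, 1.5, 1.6)
  pk <- detect_peaks(tt, v)
  expect_equal(pk$maxima_times, 24)  # middle of the 3-sample plateau
  # rising tail endpoint is not counted as a maximum
  expect_length(pk$maxima_times, 1L)
})

test_that("phase anchors at 2*pi on maxima, pi on minima, interpolates between", {
  tt <- seq(0, 600, by = 6)
  v <- planted_trace(tt, c(150, 390), height = 0.4, width = 35)
  pk <- detect_peaks(tt, v)
  expect_equal(sum(pk$significant), 2L)
  phi <- assign_phase(pk, tt)
  expect_equal(phi[tt == 150], 2 * pi)
  expect_equal(phi[tt == 390], 2 * pi)
  tmin <- pk$right_min_times[which(pk$maxima_times == 150)]
  expect_equal(phi[tt == tmin], pi)
  # linear interpolation: midpoint of max -> min leg sits at pi/2
  mid <- (150 + tmin) / 2
  if (mid %in% tt) expect_equal(phi[tt == mid], pi / 2)
  expect_true(all(is.na(phi[tt < 150])))
  expect_true(all(is.na(phi[tt > 390])))
  # single significant peak: only that sample is anchored
  v1 <- planted_trace(tt, 300, height = 0.4, width = 35)
  pk1 <- detect_peaks(tt, v1)
  phi1 <- assign_phase(pk1, tt)
  expect_equal(phi1[tt == 300], 2 * pi)
  expect_true(all(is.na(phi1[tt != 300])))
})

test_that("inter-peak periods pool significant maxima differences", {
  tt <- seq(0, 600, by = 6)
  v <- planted_trace(tt, c(30, 120, 210), height = 0.4, width = 20)
  pk <- detect_peaks(tt, v)
  expect_equal(experimental_periods(pk), c(90, 90))
  v1 <- planted_trace(tt, 300, height = 0.4, width = 20)
  expect_length(experimental_periods(detect_peaks(tt, v1)), 0L)
  # short tracks are dropped from cohort pooling by default
  ts <- seq(0, 300, by = 6)   # 5 h < 7 h minimum
  pk_short <- detect_peaks(ts, planted_trace(ts, c(60, 150, 240),
                                             height = 0.4, width = 20))
  expect_length(experimental_periods(pk_short), 0L)
  expect_equal(experimental_periods(pk_short, drop_short = FALSE), c(90, 90))
})

test_that("peak heights bucket by forcing interval", {
  tt <- seq(0, 600, by = 6)
  v <- planted_trace(tt, c(100, 280), height = 0.4, width = 20)
  ph <- peak_heights_per_cycle(detect_peaks(tt, v), T_ref = 90)
  expect_equal(ph$interval, 1:4)
  expect_equal(ph$n_peaks, c(0L, 1L, 0L, 1L))   # floor(100/90)+1 = 2
  expect_true(is.na(ph$mean_height[1]))
  expect_error(peak_heights_per_cycle(detect_peaks(tt, v), T_ref = 0), "positive")
})

test_that("phase differences convert peak lags into forcing phase", {
  tt <- seq(0, 720, by = 6)
  fc <- square_forcing()   # T_f = 90
  # peaks exactly at cycle starts
  v <- planted_trace(tt, c(90, 180, 270, 360), height = 0.4, width = 15)
  dphi <- phase_difference(detect_peaks(tt, v), fc)
  expect_true(all(abs(dphi) < 1e-9 | abs(dphi - 2 * pi) < 1e-9))
  # constant 24-min lag (on the 6-min grid) after every cycle start
  v2 <- planted_trace(tt, c(90, 180, 270, 360) + 24, height = 0.4, width = 15)
  dphi2 <- phase_difference(detect_peaks(tt, v2), fc)
  expect_true(all(abs(dphi2 - 2 * pi * 24 / 90) < 1e-9))
  # half-period lag maps to pi (T_f = 96 keeps the lagged peaks on the grid)
  fc96 <- forcing_signal("square", S_high = 2, S_low = 0, T1 = 48, T2 = 48)
  v3 <- planted_trace(tt, c(96, 192, 288) + 48, height = 0.4, width = 15)
  dphi3 <- phase_difference(detect_peaks(tt, v3), fc96)
  expect_true(any(abs(dphi3 - pi) < 1e-9))
  # no significant peaks: empty result
  expect_length(phase_difference(detect_peaks(tt, rep(0.05, length(tt)) +
                                                0.001 * sin(tt)), fc), 0L)
})

test_that("synchrony intensity spans its closed-form limits", {
  centers <- (seq_len(8) - 0.5) * 2 * pi / 8
  flat <- rep(centers, each = 25)
  s_flat <- synchrony_intensity(flat)
  expect_equal(s_flat$eta, 0)
  expect_equal(s_flat$p, rep(1 / 8, 8))
  s_delta <- synchrony_intensity(rep(1.1, 300))
  expect_equal(s_delta$eta, 1)
  # two equally-loaded bins out of eight
  two <- rep(centers[c(2, 6)], each = 50)
  expect_equal(synchrony_intensity(two)$eta, 1 - log(2) / log(8))
  expect_error(synchrony_intensity(numeric(0)), "empty")
})

test_that("eta is bounded, 2*pi-invariant and monotone in concentration", {
  set.seed(2)
  for (i in 1:20) {
    x <- runif(sample(5:200, 1), 0, 2 * pi)
    eta <- synchrony_intensity(x)$eta
    expect_gte(eta, 0); expect_lte(eta, 1)
    expect_equal(synchrony_intensity(x + 2 * pi * sample(-3:3, length(x),
                                                         TRUE))$eta, eta)
  }
  etas <- vapply(c(0.5, 1, 2, 4, 8), function(k)
    synchrony_intensity(generate_phase_samples("concentrated", 4000, seed = 5,
                                               kappa = k))$eta, numeric(1))
  expect_true(all(diff(etas) > 0))
})

test_that("per-cycle synchrony is 1 for an identical lag and low for random peaks", {
  fc <- square_forcing()
  tt <- seq(0, 720, by = 6)
  pk <- detect_peaks(tt, planted_trace(tt, c(90, 180, 270, 360, 450) + 18,
                                       height = 0.4, width = 12))
  sc <- synchrony_per_cycle(pk, fc, n_cycles = 6)
  expect_true(all(sc$eta[sc$n_peaks > 0] == 1))
  # asynchronous cohort: random peak times across 200 cells
  set.seed(8)
  pks <- lapply(1:200, function(i) {
    tp <- sort(runif(4, 30, 690))
    detect_peaks(tt, planted_trace(tt, tp, height = 0.4, width = 10))
  })
  sc2 <- synchrony_per_cycle(pks, fc, n_cycles = 7)
  # interior cycles only: the first window is truncated by the fixture's
  # 30-min margin, which restricts the phase support
  interior <- 2:7
  expect_true(all(sc2$eta[interior][sc2$n_peaks[interior] > 50] < 0.15))
})
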