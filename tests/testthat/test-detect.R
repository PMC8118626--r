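test_that("surround correction zeroes matched traces and rejects bad input", {
  n <- 400
  surround <- matrix(10 + sin(seq_len(n) / 15), n, 1)
  out <- preprocess_traces(surround, surround)
  expect_true(all(abs(out) < 1e-12))
  roi <- surround + 0.5
  expect_error(preprocess_traces(roi[1:10, , drop = FALSE], surround),
               "dimensions")
  roi_bad <- roi; roi_bad[5] <- NA
  expect_error(preprocess_traces(roi_bad, surround), "non-finite")
})

test_that("low-pass filter attenuates the stopband by at least 25 dB", {
  set.seed(8)
  x <- rnorm(4096)
  h <- coactr:::design_lowpass()
  y <- coactr:::apply_fir(x, h)
  px <- Mod(fft(x))^2
  py <- Mod(fft(y))^2
  freqs <- seq(0, 2, length.out = 4097)[1:4096]  # units of Nyquist
  stop_band <- freqs > 0.7 & freqs < 1
  atten_db <- 10 * log10(mean(px[stop_band]) / mean(py[stop_band]))
  expect_gte(atten_db, 25)
  # passband roughly unity
  pass_band <- freqs > 0.05 & freqs < 0.4
  ripple_db <- abs(10 * log10(mean(px[pass_band]) / mean(py[pass_band])))
  expect_lt(ripple_db, 2)
})

test_that("sigma estimation matches a brute-force oracle and resists transients", {
  set.seed(4)
  x <- rnorm(2000, sd = 0.02)
  params <- detection_params()
  s <- estimate_sigma(x, params)
  # oracle: same definition, computed independently
  w <- 20
  sm <- stats::filter(abs(x), rep(1 / w, w), sides = 2)
  sm[is.na(sm)] <- abs(x)[is.na(sm)]
  oracle <- sd(x[sm <= quantile(sm, 0.5)])
  expect_equal(s, oracle)
  expect_lt(abs(s - 0.02) / 0.02, 0.15)
  # constant trace flagged
  s0 <- estimate_sigma(rep(1, 500), params)
  expect_identical(as.numeric(s0), 0)
  expect_true(isTRUE(attr(s0, "degenerate")))
  # large transients occupying ~10% of frames do not inflate sigma
  xt <- x
  for (s0 in c(200, 900, 1600)) xt[s0:(s0 + 65)] <- xt[s0:(s0 + 65)] + 0.5
  expect_lt(estimate_sigma(xt, params), 0.04)
})

test_that("a single synthetic transient yields one event with the documented active period", {
  sigma <- 0.01
  n <- 600
  x <- numeric(n)
  onset <- 100
  # rise over 2 frames to 20 sigma, tau = 30 frames (AUC ~ 600 sigma-frames)
  amp <- 20 * sigma
  kernel <- c(amp / 2, amp, amp * exp(-(1:200) / 30))
  x[onset:(onset + length(kernel) - 1)] <- kernel
  row <- detect_events(x, sigma, detection_params())
  ev <- attr(row, "events")
  expect_identical(nrow(ev), 1L)
  # hand-computed end: first frame after the peak at <= 70% of peak, capped
  peak_frame <- which.max(x)
  peak <- max(x)
  drop_frame <- which(x <= 0.7 * peak & seq_len(n) > peak_frame)[1]
  expected_end <- min(drop_frame, ev$onset + 1 + 40)  # 1-based, exclusive
  expect_identical(ev$active_end[1] + 1L, as.integer(expected_end))
  expect_identical(sum(row), as.integer(expected_end - (ev$onset + 1)))
  # all-zero trace -> nothing
  expect_identical(sum(detect_events(numeric(n), sigma, detection_params())), 0L)
})

test_that("detection is invariant to joint positive rescaling of trace and sigma", {
  set.seed(12)
  tpl <- transient_template(amplitude = 25, rise_frames = 2, decay_tau = 25,
                            noise_sd = 0.02)
  blocks <- tibble::tibble(neuron = 1L, start = c(100L, 700L), duration = 4L)
  g <- gen_traces(blocks, tpl, n_frames = 1200, n_neurons = 1, seed = 5)
  x <- g$traces[, 1]
  s <- estimate_sigma(x, detection_params())
  r1 <- detect_events(x, s, detection_params())
  r2 <- detect_events(10 * x, 10 * s, detection_params())
  expect_identical(as.integer(r1), as.integer(r2))
})

test_that("raising thresholds never increases the number of detected events", {
  set.seed(31)
  tpl <- transient_template(amplitude = 18, rise_frames = 2, decay_tau = 25,
                            noise_sd = 0.02)
  blocks <- tibble::tibble(neuron = rep(1:10, each = 2),
                           start = rep(c(150L, 900L), 10) +
                             sample(0:80, 20, TRUE),
                           duration = 4L)
  g <- gen_traces(blocks, tpl, n_frames = 1500, n_neurons = 10, seed = 6)
  count_events <- function(params) {
    sum(vapply(1:10, function(j) {
      s <- estimate_sigma(g$traces[, j], params)
      nrow(attr(detect_events(g$traces[, j], s, params), "events"))
    }, numeric(1)))
  }
  base <- count_events(detection_params())
  expect_lte(count_events(detection_params(rise_sigma_2 = 25)), base)
  expect_lte(count_events(detection_params(rise_sigma_1 = 6)), base)
  expect_lte(count_events(detection_params(auc_sigma = 400)), base)
  expect_lte(count_events(detection_params(abs_peak_min = 0.2)), base)
})

test_that("detector recovers known transients on a small labeled batch", {
  tpl <- transient_template(amplitude = 25, rise_frames = 2, decay_tau = 25,
                            noise_sd = 0.02)
  set.seed(44)
  blocks <- tibble::tibble(neuron = rep(1:20, each = 3),
                           start = rep(c(200L, 1000L, 1800L), 20) +
                             sample(0:150, 60, TRUE),
                           duration = 4L)
  g <- gen_traces(blocks, tpl, n_frames = 2500, n_neurons = 20, seed = 45)
  params <- detection_params()
  hits <- 0; n_true <- 0; matched <- 0; n_det <- 0
  for (j in 1:20) {
    s <- estimate_sigma(g$traces[, j], params)
    ev <- attr(detect_events(g$traces[, j], s, params), "events")
    tb <- blocks[blocks$neuron == j, ]
    n_true <- n_true + nrow(tb)
    n_det <- n_det + nrow(ev)
    for (i in seq_len(nrow(tb))) {
      win <- c(tb$start[i] - 60, tb$start[i] + 100)
      hits <- hits + any(ev$onset >= win[1] & ev$onset <= win[2])
    }
    for (k in seq_len(nrow(ev)))
      matched <- matched +
        any(tb$start - 60 <= ev$onset[k] & tb$start + 100 >= ev$onset[k])
  }
  expect_gte(hits / n_true, 0.9)
  expect_gte(matched / n_det, 0.9)
})
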