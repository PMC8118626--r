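test_that("swap shuffle conserves per-frame counts and per-neuron block counts exactly", {
  for (seed in 1:5) {
    r <- random_raster(30, 2000, p = 0.04, seed = seed)
    s <- swap_shuffle(r, seed = seed + 100)
    expect_identical(colSums(s), colSums(r))
    expect_identical(count_blocks_per_neuron(s), count_blocks_per_neuron(r))
  }
})

test_that("per-epoch swap shuffling conserves marginals within each epoch (no leakage)", {
  r <- random_raster(20, 600, p = 0.06, seed = 9)
  ep <- epoch_annotation(tibble::tibble(condition = c("HC", "SOC", "HC"),
                                        start = c(0L, 200L, 400L),
                                        end = c(200L, 400L, 600L)))
  s <- swap_shuffle(r, scope = "epoch", epochs = ep, seed = 10)
  for (i in 1:3) {
    f <- interval_frames(ep$epochs$start[i], ep$epochs$end[i])
    expect_identical(colSums(s[, f]), colSums(r[, f]))
    expect_identical(count_blocks_per_neuron(s[, f, drop = FALSE]),
                     count_blocks_per_neuron(r[, f, drop = FALSE]))
  }
})

test_that("swap shuffle keeps per-neuron activity levels similar but erases correlations", {
  sc <- synth_config(n_neurons = 50, n_frames = 4000, mean_activity = 0.06,
                     n_assemblies = 3, assembly_size = 8, seed = 13)
  b <- insert_assemblies(gen_state_a(sc), sc)
  s <- swap_shuffle(b, seed = 14)
  expect_gt(activity_similarity(b, s), 0.9)
  expect_lt(abs(correlation_similarity(correlation_matrix(b),
                                       correlation_matrix(s))), 0.15)
})

test_that("SHARC respects the activity budget and tracks the target correlations", {
  sc <- synth_config(n_neurons = 50, n_frames = 3000, mean_activity = 0.06,
                     n_assemblies = 3, assembly_size = 8, seed = 23)
  b <- insert_assemblies(gen_state_a(sc), sc)
  sh <- sharc_shuffle(b, seed = 24)
  expect_identical(colSums(sh), colSums(b))
  delta <- count_blocks_per_neuron(sh) - count_blocks_per_neuron(b)
  expect_true(all(delta >= -3 & delta <= 4))
  d <- attr(sh, "diagnostics")
  expect_identical(as.integer(d$net_gain), as.integer(delta))
  # SHARC beats swap at preserving the correlation pattern
  sw <- swap_shuffle(b, seed = 25)
  tgt <- correlation_matrix(b)
  expect_gt(correlation_similarity(tgt, correlation_matrix(sh)),
            correlation_similarity(tgt, correlation_matrix(sw)))
})

test_that("SHARC rearranges the raster rather than copying it", {
  r <- random_raster(40, 3000, p = 0.05, seed = 31)
  tgt <- correlation_matrix(r)
  sh <- sharc_shuffle(r, seed = 32)
  sw <- swap_shuffle(r, seed = 33)
  # swap destroys the (noise) correlation pattern; SHARC tracks its target
  # even when the target is pure sampling noise
  expect_lt(abs(correlation_similarity(tgt, correlation_matrix(sw))), 0.15)
  expect_gt(correlation_similarity(tgt, correlation_matrix(sh)),
            correlation_similarity(tgt, correlation_matrix(sw)))
  # the surrogate is a genuine rearrangement, not the original raster:
  # cell-level overlap stays near the chance rate
  overlap <- sum(sh & r) / sum(r)
  expect_lt(overlap, 3 * mean(r))
})

test_that("similarity measures satisfy identities and nulls", {
  r1 <- random_raster(30, 2000, p = 0.05, seed = 41)
  r2 <- random_raster(30, 2000, p = 0.05, seed = 42)
  m1 <- correlation_matrix(r1)
  expect_equal(correlation_similarity(m1, m1), 1)
  expect_lt(abs(correlation_similarity(m1, correlation_matrix(r2))), 0.1)
  expect_equal(activity_similarity(r1, r1), 1)
  expect_error(correlation_similarity(matrix(NA_real_, 3, 3),
                                      matrix(NA_real_, 3, 3)), "valid")
})

test_that("circular rotation counts match a brute-force oracle", {
  set.seed(51)
  row <- as.integer(runif(200) < 0.1)
  condf <- sort(sample(200, 60))
  brute <- sapply(0:199, function(o)
    sum(row[((condf - 1 + o) %% 200) + 1]))
  fr <- fft(as.numeric(row))
  ind <- numeric(200); ind[condf] <- 1
  cc <- round(Re(fft(fr * Conj(fft(ind)), inverse = TRUE)) / 200)
  expect_identical(sort(as.integer(cc)), sort(as.integer(brute)))
  expect_identical(as.integer(cc[1]), as.integer(sum(row[condf])))
})

test_that("circular null percentiles flag condition-locked and silent neurons", {
  row <- integer(1000)
  # irregular pattern spanning the full condition window, so no nonzero
  # rotation can keep all events inside it (no ties at the maximum)
  on <- c(1, 17, 24, 41, 58, 66, 79, 100)
  row[on] <- 1L
  res <- circular_null_percentile(row, list(social = 1:100, hc = 501:600),
                                  n_shuffles = 3000, seed = 2)
  expect_equal(res$percentile[res$condition == "social"], 100)
  expect_identical(res$label[res$condition == "social"], "positive")
  silent <- circular_null_percentile(integer(1000), list(social = 1:100),
                                     n_shuffles = 100, seed = 3)
  expect_true(is.na(silent$percentile))
  expect_identical(silent$label, "unmodulated")
})
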