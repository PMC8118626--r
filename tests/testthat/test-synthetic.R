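test_that("state A per-frame active counts follow the oscillation formula", {
  sc <- synth_config(n_neurons = 60, n_frames = 900, mean_activity = 0.05,
                     oscillation_period = 150, seed = 11)
  r <- gen_state_a(sc)
  # independent recomputation of the prescribed counts
  f <- 0:899
  expected <- pmax(round(60 * 0.05 * (1 + sin(2 * pi * f / 150))), 0)
  expect_identical(as.integer(colSums(r)), as.integer(expected))
  # mean activity equals the configured level within 1/n_neurons
  expect_lt(abs(mean(colSums(r)) / 60 - 0.05), 1 / 60)
})

test_that("state A handles zero activity and rejects impossible rates", {
  sc0 <- synth_config(n_neurons = 20, n_frames = 100, mean_activity = 0,
                      seed = 1)
  expect_true(all(gen_state_a(sc0) == 0L))
  sc_bad <- synth_config(n_neurons = 20, n_frames = 100, mean_activity = 0.9,
                         seed = 1)
  expect_error(gen_state_a(sc_bad), "exceeds")
})

test_that("generators are bit-reproducible under a fixed seed", {
  sc <- synth_config(n_neurons = 30, n_frames = 400, n_assemblies = 2,
                     assembly_size = 8, seed = 99)
  expect_identical(gen_state_a(sc), gen_state_a(sc))
  a <- gen_state_a(sc)
  expect_identical(insert_assemblies(a, sc), insert_assemblies(a, sc))
  scm <- synth_config(n_neurons = 30, n_frames = 400,
                      modulation_bound = 0.4, seed = 99)
  m1 <- modulate_activity(a, scm)
  m2 <- modulate_activity(a, scm)
  attributes(m1) <- attributes(m2) <- NULL
  expect_identical(m1, m2)
})

test_that("assembly insertion conserves both marginals and raises within-assembly correlations", {
  sc <- synth_config(n_neurons = 100, n_frames = 3000, mean_activity = 0.05,
                     n_assemblies = 5, assembly_size = 8, seed = 7)
  a <- gen_state_a(sc)
  b <- insert_assemblies(a, sc)
  expect_identical(colSums(b), colSums(a))
  expect_identical(rowSums(b), rowSums(a))
  for (k in 1:5) {
    members <- ((k - 1) * 8 + 1):(k * 8)
    ca <- correlation_matrix(a)[members, members]
    cb <- correlation_matrix(b)[members, members]
    expect_gt(mean(cb[upper.tri(cb)]), mean(ca[upper.tri(ca)]))
  }
  # no assemblies requested -> identity
  sc0 <- synth_config(n_neurons = 100, n_frames = 3000, n_assemblies = 0,
                      seed = 7)
  expect_identical(insert_assemblies(a, sc0), a)
})

test_that("rate modulation conserves column sums and shifts activity between halves", {
  sc <- synth_config(n_neurons = 40, n_frames = 2000, mean_activity = 0.08,
                     modulation_bound = 0.5, seed = 21)
  a <- gen_state_a(sc)
  b <- modulate_activity(a, sc)
  expect_identical(colSums(b), colSums(a))
  expect_lt(sum(b[1:20, ]), sum(a[1:20, ]))
  expect_gt(sum(b[21:40, ]), sum(a[21:40, ]))
  expect_true(all(rowSums(b[1:20, ]) <= rowSums(a[1:20, ])))
  expect_true(all(rowSums(b[21:40, ]) >= rowSums(a[21:40, ])))
  # zero bound -> identity
  sc0 <- synth_config(n_neurons = 40, n_frames = 2000, modulation_bound = 0,
                      seed = 21)
  expect_identical(modulate_activity(a, sc0), a)
})

test_that("epoch label generator lays out the plan and reproduces bouts under a seed", {
  plan <- tibble::tibble(condition = c("HC", "SOC"), length = c(100L, 100L))
  ann <- gen_epoch_labels(200, plan, seed = 5)
  expect_identical(ann$frame_condition[1:100], rep("HC", 100))
  expect_identical(ann$frame_condition[101:200], rep("SOC", 100))
  expect_true(all(ann$bouts$condition == "SOC"))
  expect_true(all(ann$bouts$start >= 100 & ann$bouts$end <= 200))
  ann2 <- gen_epoch_labels(200, plan, seed = 5)
  expect_equal(ann$bouts, ann2$bouts)
  expect_error(gen_epoch_labels(150, plan), "sum")
})

test_that("trace rendering matches the template and reproduces under a seed", {
  tpl0 <- transient_template(amplitude = 20, rise_frames = 2, decay_tau = 10,
                             noise_sd = 0)
  empty <- gen_traces(tibble::tibble(neuron = integer(), start = integer(),
                                     duration = integer()),
                      tpl0, n_frames = 100, n_neurons = 2)
  expect_true(all(empty$traces == 0))
  tpl <- transient_template(amplitude = 20, rise_frames = 2, decay_tau = 10,
                            noise_sd = 0.01)
  blocks <- tibble::tibble(neuron = 1L, start = 50L, duration = 4L)
  g <- gen_traces(blocks, tpl, n_frames = 300, n_neurons = 1, seed = 2)
  peak <- max(g$traces[45:80, 1])
  expect_lt(abs(peak - 20 * 0.01), 5 * 0.01)  # peak ~ 20 noise SDs
  expect_identical(g$raster[1, 51:54], rep(1L, 4))
  g2 <- gen_traces(blocks, tpl, n_frames = 300, n_neurons = 1, seed = 2)
  expect_identical(g$traces, g2$traces)
})
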