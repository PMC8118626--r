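fake_trained <- function(w, connections) {
  clf <- build_network(ncol(connections), p_connect = 0.5,
                       n_hidden = nrow(connections), seed = 1)
  clf$connections <- connections
  clf$w <- w
  clf$trained <- TRUE
  clf
}

test_that("unit groups come from the weight order with index tie-breaks", {
  set.seed(2)
  conn <- matrix(rbinom(90 * 10, 1, 0.5), 90, 10)
  clf <- fake_trained(seq(-1, 1, length.out = 90), conn)
  g <- extract_unit_groups(clf, n_group = 25)
  expect_identical(g$social, 1:25)
  expect_identical(g$homecage, 66:90)
  expect_identical(length(intersect(g$neutral, c(g$social, g$homecage))), 0L)
  expect_identical(length(g$neutral), 25L)
  # all-zero weights are flagged as degenerate
  clf0 <- fake_trained(numeric(90), conn)
  expect_warning(g0 <- extract_unit_groups(clf0, 25), "zero")
  expect_true(g0$degenerate)
  expect_error(extract_unit_groups(clf, n_group = 40), "at least")
})

test_that("input similarity is a correlation with unit diagonal and symmetric structure", {
  conn <- rbind(c(1, 0, 1, 0, 1), c(1, 0, 1, 0, 1), c(0, 1, 0, 1, 0),
                matrix(rbinom(90 * 5, 1, 0.5), 90, 5))
  clf <- fake_trained(seq(-1, 1, length.out = 93), conn)
  g <- extract_unit_groups(clf, n_group = 3)
  sim <- input_similarity(clf, g)
  expect_equal(sim$matrix[1, 2], 1)          # identical input vectors
  expect_equal(sim$matrix, t(sim$matrix))
  expect_equal(unname(diag(sim$matrix)[1]), 1)
  expect_identical(nrow(sim$by_unit), 93L)
})

test_that("independent random input vectors have near-zero expected similarity", {
  set.seed(5)
  conn <- matrix(rbinom(400 * 60, 1, 0.3), 400, 60)
  clf <- fake_trained(rnorm(400), conn)
  g <- extract_unit_groups(clf, n_group = 25)
  sim <- input_similarity(clf, g)
  off <- sim$matrix[upper.tri(sim$matrix)]
  expect_lt(abs(mean(off, na.rm = TRUE)), 0.02)
})

test_that("ensembles take the top fifth of neurons by group connection count", {
  set.seed(7)
  conn <- matrix(rbinom(100 * 20, 1, 0.3), 100, 20)
  conn[1:25, 1] <- 1L   # neuron 1 feeds every social unit
  w <- seq(-1, 1, length.out = 100)
  clf <- fake_trained(w, conn)
  g <- extract_unit_groups(clf, n_group = 25)
  ens <- define_ensembles(clf, g, top_frac = 0.2)
  expect_identical(ens$size, as.integer(ceiling(0.2 * 20)))
  expect_identical(length(ens$social), ens$size)
  expect_identical(ens$social[1], 1L)
  expect_identical(nrow(ens$counts), 20L)
})

test_that("condition statistics separate planted coactivity from rate changes", {
  # assembly of 4 neurons coactive only in "social" frames
  set.seed(9)
  n <- 20; Fr <- 2000
  r <- random_raster(n, Fr, p = 0.05, seed = 9)
  soc <- 1:1000; hc <- 1001:2000
  co_frames <- sample(soc, 60)
  r[1:4, ] <- 0L
  for (f in co_frames) r[1:4, f] <- 1L
  for (j in 1:4) r[j, sample(hc, 60)] <- 1L   # same rate, uncorrelated, in HC
  st <- ensemble_condition_stats(r, list(social = soc, homecage = hc),
                                 list(assembly = 1:4, rest = 5:20))
  a_soc <- st[st$ensemble == "assembly" & st$condition == "social", ]
  a_hc <- st[st$ensemble == "assembly" & st$condition == "homecage", ]
  expect_gt(a_soc$mean_correlation, a_hc$mean_correlation)
  expect_equal(a_soc$mean_activity, a_hc$mean_activity, tolerance = 0.1)
  expect_error(ensemble_condition_stats(r, list(social = soc),
                                        list(tiny = 1L)), "fewer than 2")

  # rate-only change: activity up, correlation unchanged
  r2 <- random_raster(n, Fr, p = 0.04, seed = 10)
  r2[1:4, soc] <- matrix(as.integer(runif(4 * 1000) < 0.12), 4, 1000)
  st2 <- ensemble_condition_stats(r2, list(social = soc, homecage = hc),
                                  list(up = 1:4))
  u_soc <- st2[st2$condition == "social", ]
  u_hc <- st2[st2$condition == "homecage", ]
  expect_gt(u_soc$mean_activity, u_hc$mean_activity)
  expect_lt(abs(u_soc$mean_correlation - u_hc$mean_correlation), 0.05)
})

test_that("group extraction is a pure function of the weights", {
  set.seed(11)
  conn <- matrix(rbinom(200 * 30, 1, 0.3), 200, 30)
  w <- rnorm(200)
  g1 <- extract_unit_groups(fake_trained(w, conn), 25)
  g2 <- extract_unit_groups(fake_trained(w, conn), 25)
  expect_identical(g1$social, g2$social)
  expect_identical(g1$homecage, g2$homecage)
  expect_identical(g1$neutral, g2$neutral)
})
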