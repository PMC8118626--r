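test_that("network construction follows the connection probability", {
  clf1 <- build_network(10, p_connect = 1, n_hidden = 50, seed = 1)
  expect_true(all(clf1$connections == 1L))
  expect_identical(clf1$w, numeric(50))
  clf <- build_network(100, p_connect = 0.3, seed = 2)
  expect_identical(clf$n_hidden, 1000L)   # default hidden-layer size
  dens <- mean(clf$connections)
  ci <- 2.576 * sqrt(0.3 * 0.7 / (1000 * 100))
  expect_lt(abs(dens - 0.3), ci)
})

# a perfectly separable toy: one neuron active exactly on label-1 frames,
# an anti-correlated partner active on label-0 frames (a no-bias logistic
# read-out needs opposite-signed directions to separate the classes)
separable_toy <- function(n_frames = 400, seed = 3) {
  set.seed(seed)
  z <- rep(c(0, 1), n_frames / 2)
  raster <- matrix(0L, 4, n_frames)
  raster[1, ] <- as.integer(z)
  raster[2, ] <- 1L - as.integer(z)
  list(raster = raster, labels = z)
}

test_that("a separable toy is learned perfectly and the loss decreases", {
  toy <- separable_toy()
  clf <- build_network(4, p_connect = 0.5, n_hidden = 40, seed = 4)
  clf <- train_classifier(clf, toy$raster, toy$labels, min_active = 0,
                          passes = 200)
  expect_lt(clf$loss[length(clf$loss)], clf$loss[1])
  expect_equal(evaluate_classifier(clf, toy$raster, toy$labels,
                                   min_active = 0), 1.0)
  # linear baselines solve it too
  part <- frame_partition(400, 50)
  expect_equal(linear_baseline(toy$raster, toy$labels, part, "logistic",
                               min_active = 0), 1.0)
  expect_equal(linear_baseline(toy$raster, toy$labels, part, "svm",
                               min_active = 0), 1.0)
})

test_that("evaluation equals an independent closed-form sigmoid oracle", {
  set.seed(6)
  r <- random_raster(25, 1000, p = 0.15, seed = 6)
  z <- rep(c(0, 1), 500)
  clf <- build_network(25, p_connect = 0.3, n_hidden = 120, seed = 7)
  clf$w <- rnorm(120, sd = 0.3)
  clf$trained <- TRUE
  # oracle computed from scratch: explicit per-frame loop over units
  k <- pmax(1, rowSums(clf$connections))
  preds <- numeric(1000)
  for (f in 1:1000) {
    x <- as.numeric(clf$connections %*% r[, f]) / sqrt(k) * clf$gain
    y <- 1 / (1 + exp(-sum(clf$w * x)))
    preds[f] <- as.numeric(y > 0.5)
  }
  elig <- which(colSums(r) >= 3)
  expect_true(all(output_activity(clf, r, elig) != 0.5))
  expect_equal(evaluate_classifier(clf, r, z),
               mean(preds[elig] == z[elig]))
})

test_that("frames below the population-activity floor are excluded", {
  r <- matrix(0L, 5, 6)
  r[1:2, 1] <- 1L          # 2 active: ineligible at min_active = 3
  r[1:3, 2] <- 1L
  r[1:4, 3] <- 1L
  z <- c(0, 1, 1, 0, 0, 0)
  clf <- build_network(5, p_connect = 1, n_hidden = 10, seed = 8)
  expect_identical(coactr:::eligible_frames(r, z, min_active = 3), 2:3)
  clf <- train_classifier(clf, r, z, passes = 5)
  expect_error(train_classifier(clf, r * 0L, z), "eligible")
})

test_that("an unconnected network performs at chance through tie-breaking", {
  set.seed(9)
  r <- random_raster(30, 800, p = 0.2, seed = 9)
  z <- rep(c(0, 1), 400)
  clf <- build_network(30, p_connect = 0, n_hidden = 100, seed = 10)
  clf <- train_classifier(clf, r, z, passes = 10)
  acc <- evaluate_classifier(clf, r, z)
  expect_lt(abs(acc - 0.5), 0.1)
})

test_that("connection-probability sweeps are reproducible and tidy", {
  toy <- small_two_state("rate", seed = 12, n_neurons = 20, n_frames = 600)
  part <- frame_partition(1200, 100)
  s1 <- sweep_connection_probability(toy$raster, toy$labels, part,
                                     p_values = c(0.1, 0.3), runs = 2,
                                     n_hidden = 80, passes = 30, seed = 13)
  s2 <- sweep_connection_probability(toy$raster, toy$labels, part,
                                     p_values = c(0.1, 0.3), runs = 2,
                                     n_hidden = 80, passes = 30, seed = 13)
  expect_equal(tibble::as_tibble(s1), tibble::as_tibble(s2))
  sm <- summary(s1)
  expect_identical(names(sm), c("p_connect", "mean_accuracy", "sem", "n"))
  expect_identical(nrow(sm), 2L)
})

test_that("tidy and glance expose weights and hyperparameters", {
  toy <- separable_toy()
  clf <- build_network(4, p_connect = 0.5, n_hidden = 20, seed = 4)
  clf <- train_classifier(clf, toy$raster, toy$labels, min_active = 0,
                          passes = 20)
  td <- tidy(clf)
  expect_identical(nrow(td), 20L)
  expect_identical(td$weight, clf$w)
  gl <- glance(clf)
  expect_identical(gl$passes, 20L)
  expect_true(gl$trained)
})

test_that("label permutation yields chance accuracy", {
  toy <- small_two_state("rate", seed = 15, n_neurons = 30, n_frames = 1000)
  set.seed(16)
  z <- sample(toy$labels)
  part <- frame_partition(2000, 200)
  clf <- build_network(30, 0.3, n_hidden = 200, seed = 17)
  clf <- train_classifier(clf, toy$raster, z, part, passes = 100)
  acc <- evaluate_classifier(clf, toy$raster, z, part$test)
  expect_lt(abs(acc - 0.5), 0.08)
})
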