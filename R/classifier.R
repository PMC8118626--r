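#' Build a single-hidden-layer random-projection classifier
#'
#' Each of the `n_hidden` hidden units pools the activity of a fixed random
#' subset of neurons: the binary input-connection matrix has independent
#' Bernoulli(`p_connect`) entries and never changes after construction. A
#' unit's activity in a frame is its summed input normalized by the square
#' root of its connection count and scaled by `gain` — the normalization
#' keeps the drive's scale independent of the connection count, and the gain
#' keeps delta-rule weight updates in the logistic output's dynamic range
#' (an unnormalized sum over 1000 units saturates the output after a single
#' update and learning halts). A single logistic output unit with one
#' trainable weight per hidden unit classifies frames; output below 0.5
#' decodes the condition labeled 0 (e.g. social), above 0.5 the condition
#' labeled 1 (e.g. home cage). Output weights start at zero.
#'
#' @param n_neurons Number of input neurons.
#' @param p_connect Connection probability (default 0.3, the operating point
#'   at which classification accuracy peaks).
#' @param n_hidden Hidden units (default 1000).
#' @param gain Hidden-unit gain (default 1.5).
#' @param seed Optional RNG seed for the connection draw.
#' @return An object of class `coact_nn`.
#' @export
build_network <- function(n_neurons, p_connect = 0.3, n_hidden = 1000,
                          gain = 1.5, seed = NULL) {
  stopifnot(p_connect >= 0, p_connect <= 1, n_hidden >= 1, n_neurons >= 1,
            gain > 0)
  if (!is.null(seed)) set.seed(seed)
  connections <- matrix(rbinom(n_hidden * n_neurons, 1, p_connect),
                        n_hidden, n_neurons)
  structure(list(connections = connections,
                 w = numeric(n_hidden),
                 n_hidden = as.integer(n_hidden),
                 n_neurons = as.integer(n_neurons),
                 p_connect = p_connect, gain = gain,
                 lr = NA_real_, passes = NA_integer_,
                 min_active = NA_integer_,
                 loss = NULL, trained = FALSE),
            class = "coact_nn")
}

# hidden-layer projection: per-unit normalized, gain-scaled connections
projection_matrix <- function(clf) {
  k <- pmax(1, rowSums(clf$connections))
  clf$gain * clf$connections / sqrt(k)
}

#' @export
print.coact_nn <- function(x, ...) {
  cat("<coact_nn> ", x$n_hidden, " hidden units over ", x$n_neurons,
      " neurons, p_connect = ", x$p_connect,
      if (x$trained) sprintf(", trained (%d passes, lr %.3g)",
                             x$passes, x$lr) else ", untrained",
      "\n", sep = "")
  invisible(x)
}

#' Alternating-block train/test frame partition
#'
#' Divides the session timeline into consecutive blocks of `block_size`
#' frames and assigns alternating blocks to training and testing (the first
#' block trains). Blocks are laid out on the unfiltered timeline; frame
#' filters are applied afterwards.
#'
#' @param n_frames Session length in frames.
#' @param block_size Frames per block (default 500).
#' @return List with integer vectors `train` and `test` (1-based, disjoint).
#' @export
frame_partition <- function(n_frames, block_size = 500) {
  stopifnot(n_frames >= 1, block_size >= 1)
  block <- ((seq_len(n_frames) - 1) %/% block_size) %% 2
  list(train = which(block == 0L), test = which(block == 1L))
}

# frames usable for training/testing: labeled, and population activity at
# least min_active neurons
eligible_frames <- function(raster, labels, frames = NULL, min_active = 3) {
  if (is.null(frames)) frames <- seq_len(ncol(raster))
  keep <- !is.na(labels[frames]) & colSums(raster[, frames, drop = FALSE]) >=
    min_active
  frames[keep]
}

#' Train the output weights with the delta rule
#'
#' Hidden activity in a frame is the normalized projection (see
#' [build_network()]) of the raster column; the output is
#' `y = 1 / (1 + exp(-sum(w_i x_i)))`; each visited
#' frame updates every weight by `dw_i = lr * y (1 - y) (z - y) x_i`. Training
#' makes `passes` passes over the eligible training frames, visiting them in
#' a fresh random order each pass. Only frames with a label and at least
#' `min_active` active neurons are used.
#'
#' @param clf A `coact_nn` from [build_network()].
#' @param raster Binary event raster (neurons x frames).
#' @param labels Numeric vector, one per frame: 0 or 1 (e.g. 0 = social,
#'   1 = home cage), `NA` for unusable frames.
#' @param partition Optional [frame_partition()]; training uses
#'   `partition$train`. `NULL` trains on all eligible frames.
#' @param lr Learning rate (default 0.05).
#' @param passes Training passes (default 500).
#' @param min_active Minimum active neurons per eligible frame (default 3;
#'   0 disables the filter).
#' @return The trained classifier, with the per-pass training log-loss in
#'   `$loss`.
#' @export
train_classifier <- function(clf, raster, labels, partition = NULL,
                             lr = 0.05, passes = 500, min_active = 3) {
  stopifnot(inherits(clf, "coact_nn"))
  raster <- as_event_raster(raster)
  stopifnot(nrow(raster) == clf$n_neurons, length(labels) == ncol(raster))
  frames <- eligible_frames(raster, labels,
                            if (is.null(partition)) NULL else partition$train,
                            min_active)
  if (length(frames) == 0) stop("no eligible training frames")
  z <- labels[frames]
  if (!all(z %in% c(0, 1))) stop("labels must be 0/1 (or NA)")
  X <- projection_matrix(clf) %*% raster[, frames, drop = FALSE]
  fit <- cpp_train_delta(X, as.numeric(z), clf$w, lr, as.integer(passes))
  clf$w <- fit$w
  clf$loss <- fit$loss
  clf$lr <- lr
  clf$passes <- as.integer(passes)
  clf$min_active <- as.integer(min_active)
  clf$trained <- TRUE
  clf
}

#' Output-unit activity per frame
#'
#' The closed-form logistic output computed from the fixed connections and
#' the current weights.
#'
#' @param clf A `coact_nn`.
#' @param raster Binary event raster.
#' @param frames 1-based frame indices (default all).
#' @return Numeric vector of `y` values in (0, 1).
#' @export
output_activity <- function(clf, raster, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(ncol(raster))
  X <- projection_matrix(clf) %*% raster[, frames, drop = FALSE]
  as.numeric(plogis(drop(clf$w %*% X)))
}

#' Classification accuracy on eligible frames
#'
#' Fraction of eligible frames on which the thresholded output (`y > 0.5`)
#' matches the label; a `y` of exactly 0.5 is resolved by a seeded coin flip.
#'
#' @inheritParams train_classifier
#' @param frames 1-based frame indices to evaluate on (default all); the
#'   label and `min_active` filters are applied on top.
#' @return Accuracy in `[0, 1]`.
#' @export
evaluate_classifier <- function(clf, raster, labels, frames = NULL,
                                min_active = 3) {
  stopifnot(inherits(clf, "coact_nn"))
  raster <- as_event_raster(raster)
  frames <- eligible_frames(raster, labels, frames, min_active)
  if (length(frames) == 0) stop("no eligible frames to evaluate")
  y <- output_activity(clf, raster, frames)
  pred <- as.numeric(y > 0.5)
  ties <- y == 0.5
  if (any(ties)) pred[ties] <- as.numeric(runif(sum(ties)) > 0.5)
  mean(pred == labels[frames])
}

#' Sweep the input connection probability
#'
#' Rebuilds, trains and tests the network at each connection probability,
#' with a fresh connection draw per run. The sweep locates the operating
#' point (typically around 0.3) at which accuracy peaks.
#'
#' @inheritParams train_classifier
#' @param p_values Connection probabilities to test.
#' @param runs Runs per probability.
#' @param n_hidden,lr,passes,min_active Network and training settings.
#' @param seed Optional master seed; run seeds are derived from it.
#' @return Tibble of class `coact_sweep` with columns `p_connect`, `run`,
#'   `accuracy`; `summary()`/[autoplot()] give mean and SEM per probability.
#' @export
sweep_connection_probability <- function(raster, labels, partition,
                                         p_values = c(0.05, 0.1, 0.2, 0.3,
                                                      0.4, 0.5),
                                         runs = 5, n_hidden = 1000, lr = 0.05,
                                         passes = 500, min_active = 3,
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- tidyr::expand_grid(p_connect = p_values, run = seq_len(runs))
  acc <- purrr::pmap_dbl(grid, function(p_connect, run) {
    clf <- build_network(nrow(raster), p_connect, n_hidden)
    clf <- train_classifier(clf, raster, labels, partition, lr, passes,
                            min_active)
    evaluate_classifier(clf, raster, labels, partition$test, min_active)
  })
  out <- dplyr::mutate(grid, accuracy = acc)
  class(out) <- c("coact_sweep", class(out))
  out
}

#' @export
summary.coact_sweep <- function(object, ...) {
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(object), .data$p_connect),
                   mean_accuracy = mean(.data$accuracy),
                   sem = sd(.data$accuracy) / sqrt(dplyr::n()),
                   n = dplyr::n(), .groups = "drop")
}

#' Optimal linear classifier baselines
#'
#' Ridge-regularized logistic regression (penalty chosen by k-fold
#' cross-validation on the training frames) or a linear support vector
#' machine, trained on raw per-frame neuron activity under the same partition
#' and frame filters as the network. A linear read-out of activity levels
#' cannot exploit state-specific coactivity, so these baselines isolate the
#' rate-coded component of the information; when no linear signal
#' generalizes, the cross-validated penalty collapses the model to chance
#' rather than letting it overfit.
#'
#' @inheritParams train_classifier
#' @param method `"logistic"` or `"svm"` (linear kernel).
#' @param nfolds Cross-validation folds for the logistic ridge penalty.
#' @return Test-set accuracy in `[0, 1]`.
#' @export
linear_baseline <- function(raster, labels, partition,
                            method = c("logistic", "svm"), min_active = 3,
                            nfolds = 5) {
  method <- match.arg(method)
  raster <- as_event_raster(raster)
  trf <- eligible_frames(raster, labels, partition$train, min_active)
  tef <- eligible_frames(raster, labels, partition$test, min_active)
  if (length(trf) == 0 || length(tef) == 0) stop("no eligible frames")
  ztr <- labels[trf]
  if (length(unique(ztr)) < 2)
    stop("degenerate single-class training set")
  xtr <- t(raster[, trf, drop = FALSE])
  xte <- t(raster[, tef, drop = FALSE])
  if (method == "logistic") {
    fit <- glmnet::cv.glmnet(xtr, factor(ztr), family = "binomial",
                             alpha = 0, nfolds = nfolds,
                             standardize = FALSE)
    pred <- as.numeric(predict(fit, xte, s = "lambda.min", type = "class"))
  } else {
    fit <- e1071::svm(x = xtr, y = factor(ztr), kernel = "linear",
                      scale = FALSE)
    pred <- as.numeric(as.character(predict(fit, xte)))
  }
  mean(pred == labels[tef])
}

#' @export
tidy.coact_nn <- function(x, ...) {
  tibble::tibble(unit = seq_len(x$n_hidden), weight = x$w,
                 n_inputs = as.integer(rowSums(x$connections)))
}

#' @export
glance.coact_nn <- function(x, ...) {
  tibble::tibble(n_hidden = x$n_hidden, n_neurons = x$n_neurons,
                 p_connect = x$p_connect, trained = x$trained,
                 passes = x$passes, lr = x$lr,
                 final_loss = if (is.null(x$loss)) NA_real_
                              else x$loss[length(x$loss)])
}

#' Serialize a classifier to JSON and back
#'
#' Connections are stored as sparse per-unit neuron index lists; weights at
#' full precision, so a reloaded model reproduces [output_activity()] and
#' [evaluate_classifier()] bit for bit.
#'
#' @param clf A `coact_nn`.
#' @param path File path.
#' @export
write_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "coact_nn"))
  payload <- list(
    n_hidden = clf$n_hidden, n_neurons = clf$n_neurons,
    p_connect = clf$p_connect, gain = clf$gain, lr = clf$lr,
    passes = clf$passes,
    min_active = clf$min_active, trained = clf$trained,
    # 17 significant digits guarantee a bit-exact numeric round trip
    weights = sprintf("%.17g", clf$w),
    loss = clf$loss,
    inputs = lapply(seq_len(clf$n_hidden), function(i)
      which(clf$connections[i, ] == 1L)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$n_hidden) || is.null(p$weights))
    stop("malformed classifier file")
  conn <- matrix(0L, p$n_hidden, p$n_neurons)
  inputs <- p$inputs
  if (is.matrix(inputs)) inputs <- split(inputs, row(inputs))
  for (i in seq_len(p$n_hidden)) {
    idx <- inputs[[i]]
    if (length(idx)) conn[i, idx] <- 1L
  }
  structure(list(connections = conn,
                 w = as.numeric(p$weights),
                 n_hidden = as.integer(p$n_hidden),
                 n_neurons = as.integer(p$n_neurons),
                 p_connect = p$p_connect,
                 gain = p$gain %||% 1.5,
                 lr = p$lr %||% NA_real_,
                 passes = as.integer(p$passes %||% NA_integer_),
                 min_active = as.integer(p$min_active %||% NA_integer_),
                 loss = if (!is.null(p$loss)) as.numeric(p$loss) else NULL,
                 trained = isTRUE(p$trained)),
            class = "coact_nn")
}
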