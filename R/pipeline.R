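#' Experiment configuration
#'
#' A fully serializable description of one end-to-end experiment on a
#' synthetic two-state dataset: generation, classifier, surrogate testing and
#' repetition settings. A config plus the package version determines all
#' outputs.
#'
#' @param coding `"correlation"` (assemblies planted in State B) or `"rate"`
#'   (activity transferred between neuron halves).
#' @param n_neurons,n_frames,mean_activity,oscillation_period,n_assemblies,assembly_size,modulation_bound
#'   Passed to [synth_config()]; `n_frames` is the length of each state's
#'   raster.
#' @param p_connect,n_hidden,lr,passes,min_active Classifier settings.
#' @param block_size Train/test partition block length (frames).
#' @param runs Number of training/testing repetitions.
#' @param sharc A [sharc_params()].
#' @param seed Master seed; all per-run seeds are derived from it.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(coding = c("correlation", "rate"),
                              n_neurons = 100, n_frames = 6000,
                              mean_activity = 0.05, oscillation_period = 100,
                              n_assemblies = 5, assembly_size = 8,
                              modulation_bound = 0.5,
                              p_connect = 0.3, n_hidden = 1000, lr = 0.05,
                              passes = 500, min_active = 3, block_size = 500,
                              runs = 10, sharc = sharc_params(), seed = 1) {
  coding <- match.arg(coding)
  structure(list(coding = coding, n_neurons = n_neurons, n_frames = n_frames,
                 mean_activity = mean_activity,
                 oscillation_period = oscillation_period,
                 n_assemblies = n_assemblies, assembly_size = assembly_size,
                 modulation_bound = modulation_bound, p_connect = p_connect,
                 n_hidden = n_hidden, lr = lr, passes = passes,
                 min_active = min_active, block_size = block_size,
                 runs = runs, sharc = unclass(sharc), seed = seed),
            class = "experiment_config")
}

#' Build a labeled two-state dataset from a config
#'
#' Generates a State A raster, derives the State B raster by the configured
#' coding mechanism, concatenates them on one timeline (A first) and labels
#' frames 1 (State A) / 0 (State B), mirroring the home-cage = 1 /
#' social = 0 labeling convention.
#'
#' @param config An [experiment_config()].
#' @param seed Seed for this dataset (defaults to `config$seed`).
#' @return List with `raster`, `labels`, `state_a`, `state_b`, and
#'   `state_frames` (list of 1-based frame indices per state on the combined
#'   timeline).
#' @export
make_two_state_dataset <- function(config, seed = config$seed) {
  sc <- synth_config(n_neurons = config$n_neurons, n_frames = config$n_frames,
                     mean_activity = config$mean_activity,
                     oscillation_period = config$oscillation_period,
                     assembly_size = config$assembly_size,
                     n_assemblies = config$n_assemblies,
                     modulation_bound = config$modulation_bound,
                     seed = seed)
  state_a <- gen_state_a(sc)
  state_b <- if (config$coding == "correlation")
    insert_assemblies(state_a, sc) else modulate_activity(state_a, sc)
  raster <- cbind(state_a, state_b)
  Fr <- config$n_frames
  labels <- c(rep(1, Fr), rep(0, Fr))
  list(raster = raster, labels = labels, state_a = state_a, state_b = state_b,
       state_frames = list(a = seq_len(Fr), b = Fr + seq_len(Fr)),
       config = sc)
}

# shuffle each state's half of the combined raster independently
# (within-state scope), preserving state-specific activity levels
shuffle_within_states <- function(dataset, method = c("swap", "sharc"),
                                  sharc = sharc_params()) {
  method <- match.arg(method)
  parts <- lapply(dataset$state_frames, function(f) {
    sub <- dataset$raster[, f, drop = FALSE]
    if (method == "swap") swap_shuffle(sub)
    else sharc_shuffle(sub, params = sharc)
  })
  do.call(cbind, parts)
}

#' Run one end-to-end experiment
#'
#' The central comparison: train the classifier on the real (synthetic
#' two-state) data, test it on the held-out real frames and on within-state
#' swap- and SHARC-shuffled versions of the dataset, and report the relative
#' improvement `(acc_sharc - acc_swap) / (acc_swap - 0.5)` that quantifies
#' how much information the preserved correlations add beyond activity
#' levels. Linear baselines run on the same partition.
#'
#' @param config An [experiment_config()].
#' @return A list of class `results_bundle` with `config`, `runs` (tibble:
#'   per-run accuracies), and `summary` (tibble of means, SEMs and the
#'   relative improvement).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  partition <- frame_partition(2 * config$n_frames, config$block_size)
  rows <- list()
  for (r in seq_len(config$runs)) {
    run_seed <- config$seed + 1000L * r
    dataset <- make_two_state_dataset(config, seed = run_seed)
    set.seed(run_seed + 1L)
    clf <- build_network(config$n_neurons, config$p_connect, config$n_hidden)
    clf <- train_classifier(clf, dataset$raster, dataset$labels, partition,
                            lr = config$lr, passes = config$passes,
                            min_active = config$min_active)
    acc_real <- evaluate_classifier(clf, dataset$raster, dataset$labels,
                                    partition$test, config$min_active)
    swap_r <- shuffle_within_states(dataset, "swap")
    acc_swap <- evaluate_classifier(clf, swap_r, dataset$labels,
                                    partition$test, config$min_active)
    sharc_r <- shuffle_within_states(dataset, "sharc",
                                     do.call(sharc_params, config$sharc))
    acc_sharc <- evaluate_classifier(clf, sharc_r, dataset$labels,
                                     partition$test, config$min_active)
    acc_logistic <- linear_baseline(dataset$raster, dataset$labels, partition,
                                    "logistic", config$min_active)
    acc_svm <- linear_baseline(dataset$raster, dataset$labels, partition,
                               "svm", config$min_active)
    rows[[r]] <- tibble::tibble(
      run = r, seed = run_seed, accuracy_real = acc_real,
      accuracy_swap = acc_swap, accuracy_sharc = acc_sharc,
      accuracy_logistic = acc_logistic, accuracy_svm = acc_svm,
      relative_improvement = (acc_sharc - acc_swap) /
        (acc_swap - 0.5))
  }
  runs <- dplyr::bind_rows(rows)
  summ <- tidyr::pivot_longer(runs, -c("run", "seed"),
                              names_to = "metric", values_to = "value")
  summ <- dplyr::summarise(dplyr::group_by(summ, .data$metric),
                           mean = mean(.data$value),
                           sem = sd(.data$value) / sqrt(dplyr::n()),
                           .groups = "drop")
  structure(list(config = config, runs = runs, summary = summ),
            class = "results_bundle")
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("<results_bundle> coding =", x$config$coding, "over", x$config$runs,
      "runs\n")
  print(x$summary)
  invisible(x)
}

#' Serialize a results bundle (or config) to JSON and back
#'
#' @param bundle A `results_bundle`.
#' @param path File path.
#' @export
write_results_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "results_bundle"))
  payload <- list(config = unclass(bundle$config),
                  runs = bundle$runs, summary = bundle$summary)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_results_bundle
#' @export
read_results_bundle <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(config = structure(p$config, class = "experiment_config"),
                 runs = tibble::as_tibble(p$runs),
                 summary = tibble::as_tibble(p$summary)),
            class = "results_bundle")
}

#' @rdname write_results_bundle
#' @param config An `experiment_config`.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_results_bundle
#' @export
read_experiment_config <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(p, class = "experiment_config")
}

#' Matched condition frame sets from an epoch annotation
#'
#' Training and testing are restricted to interaction bouts and temporally
#' matched home-cage frames: for each interaction bout, the matched frames
#' sit at the same offsets within the preceding home-cage epoch (offsets
#' taken modulo that epoch's length, so the sets are always equal in size).
#'
#' @param epochs An [epoch_annotation()] whose bouts mark interaction.
#' @param social,homecage Condition labels used in the annotation.
#' @return Named list with 1-based frame-index vectors `social` and
#'   `homecage`, equal in length.
#' @export
matched_condition_frames <- function(epochs, social = "SOC",
                                     homecage = "HC") {
  ep <- epochs$epochs
  bouts <- epochs$bouts[epochs$bouts$interacting, , drop = FALSE]
  if (nrow(bouts) == 0) stop("annotation contains no interaction bouts")
  soc_frames <- integer(0)
  hc_frames <- integer(0)
  for (i in seq_len(nrow(bouts))) {
    b <- bouts[i, ]
    host <- which(ep$condition == social & ep$start <= b$start &
                    ep$end >= b$end)
    if (length(host) == 0) next
    host <- host[1]
    prev_hc <- which(ep$condition == homecage &
                       ep$end <= ep$start[host])
    if (length(prev_hc) == 0)
      stop("no preceding home-cage epoch for a bout")
    prev_hc <- prev_hc[length(prev_hc)]
    hc_len <- ep$end[prev_hc] - ep$start[prev_hc]
    offs <- (seq.int(b$start, b$end - 1) - ep$start[host]) %% hc_len
    soc_frames <- c(soc_frames, interval_frames(b$start, b$end))
    hc_frames <- c(hc_frames, ep$start[prev_hc] + offs + 1L)
  }
  list(social = soc_frames, homecage = hc_frames)
}

#' Per-frame 0/1 labels from matched condition frames
#'
#' @param n_frames Session length.
#' @param condition_frames Result of [matched_condition_frames()].
#' @return Numeric vector: 0 on social frames, 1 on matched home-cage frames,
#'   `NA` elsewhere.
#' @export
condition_labels <- function(n_frames, condition_frames) {
  z <- rep(NA_real_, n_frames)
  z[condition_frames$social] <- 0
  z[condition_frames$homecage] <- 1
  z
}
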