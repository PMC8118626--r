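#' Configuration for synthetic two-state rasters
#'
#' Defines the simulated study conditions: a population whose total activity
#' oscillates around a mean level, with state identity encoded either by
#' planted cell assemblies (correlation coding) or by transferring activity
#' between neuron halves (rate coding).
#'
#' @param n_neurons Number of neurons (default 100).
#' @param n_frames Number of frames per state raster (default 6000, i.e.
#'   5 minutes at 20 Hz).
#' @param mean_activity Mean fraction of neurons active per frame (default
#'   0.05).
#' @param oscillation_period Frames per cycle of the population-rate
#'   oscillation (default 100, i.e. a 5 s fluctuation at 20 Hz — short
#'   relative to the 500-frame train/test blocks so every block samples all
#'   phases).
#' @param assembly_size Neurons per planted assembly (default 8).
#' @param n_assemblies Number of disjoint assemblies planted by
#'   [insert_assemblies()] (0-5).
#' @param modulation_bound Upper bound on the per-pair fraction of activity
#'   transferred by [modulate_activity()] (0 to 0.5).
#' @param seed Optional RNG seed; when given, generation is bit-reproducible.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_neurons = 100, n_frames = 6000,
                         mean_activity = 0.05, oscillation_period = 100,
                         assembly_size = 8, n_assemblies = 0,
                         modulation_bound = 0, seed = NULL) {
  stopifnot(n_neurons >= 1, n_frames >= 1, oscillation_period > 0,
            assembly_size >= 1)
  if (mean_activity < 0 || mean_activity > 1)
    stop("mean_activity must be in [0, 1]")
  if (n_assemblies * assembly_size > n_neurons)
    stop("n_assemblies * assembly_size must not exceed n_neurons")
  if (modulation_bound < 0 || modulation_bound > 1)
    stop("modulation_bound must be in [0, 1]")
  structure(list(n_neurons = as.integer(n_neurons),
                 n_frames = as.integer(n_frames),
                 mean_activity = mean_activity,
                 oscillation_period = oscillation_period,
                 assembly_size = as.integer(assembly_size),
                 n_assemblies = as.integer(n_assemblies),
                 modulation_bound = modulation_bound,
                 seed = seed),
            class = "synth_config")
}

#' Per-frame active-neuron counts implied by a synthetic configuration
#'
#' The population rate oscillates sinusoidally around the mean activity
#' level: in (0-based) frame f, `round(N * A * (1 + sin(2*pi*f/period)))`
#' neurons are active, floored at 0.
#'
#' @param config A [synth_config()].
#' @return Integer vector of length `n_frames`.
#' @export
state_a_counts <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  f <- seq_len(config$n_frames) - 1
  n <- round(config$n_neurons * config$mean_activity *
               (1 + sin(2 * pi * f / config$oscillation_period)))
  if (any(n > config$n_neurons))
    stop("per-frame active count exceeds n_neurons; lower mean_activity")
  as.integer(pmax(n, 0))
}

#' Generate a State A raster (random activity, oscillating population rate)
#'
#' In each frame the prescribed number of distinct neurons is drawn uniformly
#' at random.
#'
#' @param config A [synth_config()].
#' @return Binary event raster (`n_neurons` x `n_frames`).
#' @export
gen_state_a <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  counts <- state_a_counts(config)
  raster <- matrix(0L, config$n_neurons, config$n_frames)
  for (f in seq_len(config$n_frames)) {
    k <- counts[f]
    if (k > 0) raster[sample.int(config$n_neurons, k), f] <- 1L
  }
  raster
}

#' Plant coactive assemblies into a raster (correlation-coded State B)
#'
#' Returns a raster in which, whenever the first neuron of an assembly is
#' active in a frame, the other assembly members are made coactive in that
#' frame via reciprocal swaps: a non-assembly neuron active in the frame
#' donates its activity to the assembly member, and the member repays it from
#' another frame where the member is active and the donor is not. Per-frame
#' column sums and per-neuron row sums are exactly those of the input, so
#' State B differs from State A only in its correlation structure. In frames
#' with fewer active neurons than the assembly size, a random subset of the
#' assembly is coactivated.
#'
#' @param state_a Raster from [gen_state_a()].
#' @param config A [synth_config()] with `n_assemblies >= 1`. Assemblies are
#'   the first `n_assemblies` consecutive groups of `assembly_size` neurons.
#' @param max_retries Donor/frame resampling attempts before failing.
#' @return Binary event raster with identical marginals to `state_a`.
#' @export
insert_assemblies <- function(state_a, config, max_retries = 50) {
  raster <- as_event_raster(state_a)
  stopifnot(inherits(config, "synth_config"))
  if (config$n_assemblies == 0) return(raster)
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  N <- nrow(raster)
  assemblies <- lapply(seq_len(config$n_assemblies), function(a)
    ((a - 1) * config$assembly_size + 1):(a * config$assembly_size))
  in_any_assembly <- rep(FALSE, N)
  in_any_assembly[unlist(assemblies)] <- TRUE

  for (a in seq_along(assemblies)) {
    members <- assemblies[[a]]
    leader <- members[1]
    lead_frames <- which(raster[leader, ] == 1L)
    for (f in lead_frames) {
      active <- which(raster[, f] == 1L)
      k <- length(active)
      target_size <- min(config$assembly_size, k)
      active_members <- intersect(members, active)
      n_more <- target_size - length(active_members)
      if (n_more <= 0) next
      pool <- setdiff(members, active_members)
      to_add <- if (length(pool) == 1) pool else
        sample(pool, n_more)
      for (m in to_add) {
        # prefer donors outside every assembly so earlier patterns survive
        cand <- setdiff(active, members)
        free <- cand[!in_any_assembly[cand]]
        donors <- if (length(free) > 0) free else cand
        swapped <- FALSE
        for (try in seq_len(max_retries)) {
          if (length(donors) == 0) break
          q <- if (length(donors) == 1) donors else sample(donors, 1)
          repay <- which(raster[m, ] == 1L & raster[q, ] == 0L)
          repay <- setdiff(repay, f)
          if (length(repay) > 0) {
            f2 <- if (length(repay) == 1) repay else sample(repay, 1)
            raster[m, f] <- 1L; raster[q, f] <- 0L
            raster[m, f2] <- 0L; raster[q, f2] <- 1L
            active <- c(setdiff(active, q), m)
            swapped <- TRUE
            break
          }
          donors <- setdiff(donors, q)
        }
        if (!swapped)
          stop(sprintf(
            "no reciprocal swap found for assembly %d, frame %d, neuron %d",
            a, f - 1, m))
      }
    }
  }
  raster
}

#' Transfer activity between neuron halves (rate-coded State B)
#'
#' Each donor neuron i in the first half is paired with recipient i + N/2. A
#' proportion drawn uniformly from `[0, modulation_bound]` of the donor's
#' blocks of activity is reassigned to the recipient at the same frames, so
#' per-frame column sums are preserved while first-half row sums fall and
#' second-half row sums rise. Transfers whose target frames are already
#' occupied in the recipient are skipped (counted in the `skipped` attribute).
#'
#' @param state_a Raster from [gen_state_a()]; `n_neurons` must be even.
#' @param config A [synth_config()] with `modulation_bound` in `[0, 0.5]`.
#' @return Binary event raster; attribute `skipped` counts skipped transfers.
#' @export
modulate_activity <- function(state_a, config) {
  raster <- as_event_raster(state_a)
  stopifnot(inherits(config, "synth_config"))
  N <- nrow(raster)
  if (N %% 2 != 0) stop("n_neurons must be even for rate modulation")
  if (config$modulation_bound == 0) return(raster)
  if (config$modulation_bound > 0.5)
    stop("modulation_bound must be in (0, 0.5] for rate modulation")
  if (!is.null(config$seed)) set.seed(config$seed + 2L)
  half <- N / 2
  skipped <- 0L
  for (i in seq_len(half)) {
    recipient <- i + half
    prop <- runif(1, 0, config$modulation_bound)
    r <- rle(raster[i, ] > 0L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    bs <- starts[r$values]; be <- ends[r$values]
    nb <- length(bs)
    n_move <- round(prop * nb)
    if (n_move == 0) next
    pick <- sample.int(nb, n_move)
    for (b in pick) {
      f <- bs[b]:be[b]
      if (all(raster[recipient, f] == 0L)) {
        raster[recipient, f] <- 1L
        raster[i, f] <- 0L
      } else {
        skipped <- skipped + 1L
      }
    }
  }
  attr(raster, "skipped") <- skipped
  raster
}

#' Generate epoch-structured condition labels with interaction bouts
#'
#' Builds a per-frame condition track from a plan of consecutive epochs, and
#' draws alternating interaction / non-interaction runs inside the chosen
#' epochs (geometric run lengths with configurable means), emulating scored
#' behavior bouts.
#'
#' @param n_frames Total frames; the plan lengths must sum to this.
#' @param epoch_plan Data frame with columns `condition` and `length`
#'   (frames), in temporal order.
#' @param bout_conditions Conditions whose epochs contain interaction bouts.
#' @param bout_mean,gap_mean Mean lengths (frames) of interaction and
#'   non-interaction runs.
#' @param seed Optional RNG seed.
#' @return An [epoch_annotation()].
#' @export
gen_epoch_labels <- function(n_frames, epoch_plan, bout_conditions = "SOC",
                             bout_mean = 60, gap_mean = 40, seed = NULL) {
  epoch_plan <- tibble::as_tibble(epoch_plan)
  stopifnot(all(c("condition", "length") %in% names(epoch_plan)))
  if (sum(epoch_plan$length) != n_frames)
    stop("epoch plan lengths must sum to n_frames")
  if (!is.null(seed)) set.seed(seed)
  ends <- cumsum(epoch_plan$length)
  starts <- ends - epoch_plan$length
  epochs <- tibble::tibble(condition = epoch_plan$condition,
                           start = starts, end = ends)
  bouts <- list()
  for (i in seq_len(nrow(epochs))) {
    if (!(epochs$condition[i] %in% bout_conditions)) next
    pos <- epochs$start[i]
    interacting <- FALSE   # epochs open with a non-interaction run
    while (pos < epochs$end[i]) {
      mu <- if (interacting) bout_mean else gap_mean
      len <- min(1L + stats::rgeom(1, 1 / mu), epochs$end[i] - pos)
      bouts[[length(bouts) + 1]] <- tibble::tibble(
        condition = epochs$condition[i], start = pos, end = pos + len,
        interacting = interacting)
      pos <- pos + len
      interacting <- !interacting
    }
  }
  bouts <- if (length(bouts)) dplyr::bind_rows(bouts) else NULL
  epoch_annotation(epochs, bouts, n_frames = n_frames)
}

#' Calcium transient template
#'
#' Shape parameters used by [gen_traces()] to render ground-truth events as
#' fluorescence transients.
#'
#' @param amplitude Peak height in multiples of the noise SD.
#' @param rise_frames Frames over which the transient rises linearly.
#' @param decay_tau Exponential decay time constant (frames).
#' @param noise_sd Additive white-noise SD in dF/F0 units.
#' @return A list of class `transient_template`.
#' @export
transient_template <- function(amplitude = 20, rise_frames = 2,
                               decay_tau = 10, noise_sd = 0.01) {
  stopifnot(amplitude > 0, decay_tau > 0, rise_frames >= 1, noise_sd >= 0)
  structure(list(amplitude = amplitude, rise_frames = rise_frames,
                 decay_tau = decay_tau, noise_sd = noise_sd),
            class = "transient_template")
}

#' Render ground-truth events as synthetic dF/F0 traces
#'
#' Each block of activity becomes a transient: a linear rise to the template
#' amplitude followed by exponential decay, plus additive white noise. Used
#' as the ground-truth fixture generator for event-detection validation.
#'
#' @param blocks Tibble as from [raster_to_blocks()] (columns `neuron`,
#'   `start`, `duration`).
#' @param template A [transient_template()].
#' @param n_frames Trace length.
#' @param n_neurons Number of traces; defaults to `max(blocks$neuron)`.
#' @param seed Optional RNG seed for the noise.
#' @return List with `traces` (frames x neurons matrix) and `raster` (the
#'   ground-truth binary raster).
#' @export
gen_traces <- function(blocks, template, n_frames,
                       n_neurons = if (nrow(blocks)) max(blocks$neuron) else 1,
                       seed = NULL) {
  stopifnot(inherits(template, "transient_template"))
  if (!is.null(seed)) set.seed(seed)
  amp <- template$amplitude * template$noise_sd
  if (template$noise_sd == 0) amp <- template$amplitude  # absolute units
  kernel_len <- template$rise_frames + ceiling(8 * template$decay_tau)
  kernel <- c(seq_len(template$rise_frames) / template$rise_frames,
              exp(-(seq_len(kernel_len - template$rise_frames)) /
                    template$decay_tau)) * amp
  traces <- matrix(0, n_frames, n_neurons)
  for (i in seq_len(nrow(blocks))) {
    s <- blocks$start[i] + 1           # blocks use 0-based starts
    idx <- s:min(s + kernel_len - 1, n_frames)
    traces[idx, blocks$neuron[i]] <-
      traces[idx, blocks$neuron[i]] + kernel[seq_along(idx)]
  }
  if (template$noise_sd > 0)
    traces <- traces + matrix(rnorm(length(traces), 0, template$noise_sd),
                              nrow(traces), ncol(traces))
  raster <- blocks_to_raster(blocks, n_neurons, n_frames)
  list(traces = traces, raster = raster)
}
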