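#' Swap-shuffle an event raster
#'
#' Randomly exchanges the neuron identities of blocks of activity while
#' leaving every block's start time and duration untouched. Per-frame active
#' counts and per-neuron block counts are preserved exactly; per-neuron
#' activity levels are preserved approximately (block durations vary). With
#' `scope = "epoch"`, each epoch's sub-raster is shuffled independently and
#' the results concatenated, which preserves condition-specific activity
#' levels while destroying correlations.
#'
#' @param raster Binary event raster (neurons x frames).
#' @param scope `"whole"` (default) or `"epoch"`.
#' @param epochs An [epoch_annotation()]; required for `scope = "epoch"`.
#' @param max_retries Resampling attempts when a proposed swap would make a
#'   neuron active in overlapping frames.
#' @param seed Optional RNG seed.
#' @return Shuffled raster; attribute `skipped` counts blocks for which no
#'   conflict-free partner was found.
#' @export
swap_shuffle <- function(raster, scope = c("whole", "epoch"), epochs = NULL,
                         max_retries = 100, seed = NULL) {
  raster <- as_event_raster(raster)
  scope <- match.arg(scope)
  if (!is.null(seed)) set.seed(seed)
  if (scope == "whole") return(swap_shuffle_segment(raster, max_retries))
  if (is.null(epochs)) stop("epoch scope requires an epoch annotation")
  out <- matrix(0L, nrow(raster), ncol(raster))
  skipped <- 0L
  for (i in seq_len(nrow(epochs$epochs))) {
    f <- interval_frames(epochs$epochs$start[i], epochs$epochs$end[i])
    seg <- swap_shuffle_segment(raster[, f, drop = FALSE], max_retries)
    out[, f] <- seg
    skipped <- skipped + attr(seg, "skipped")
  }
  attr(out, "skipped") <- skipped
  out
}

swap_shuffle_segment <- function(raster, max_retries) {
  blocks <- raster_to_blocks(raster)
  if (nrow(blocks) == 0) {
    attr(raster, "skipped") <- 0L
    return(raster)
  }
  res <- cpp_swap_shuffle(blocks$start, blocks$duration, blocks$neuron - 1L,
                          nrow(raster), ncol(raster), max_retries)
  blocks$neuron <- res$neuron + 1L
  out <- blocks_to_raster(blocks, nrow(raster), ncol(raster))
  attr(out, "skipped") <- res$skipped
  out
}

#' SHARC parameters
#'
#' Activity-budget and iteration settings for [sharc_shuffle()]: a neuron may
#' gain at most `max_net_gain` blocks and lose at most `max_net_loss` blocks
#' relative to the source raster; every block is reassigned
#' `reassignment_passes` times after the initial swap shuffle.
#'
#' @param max_net_gain Maximum net blocks a neuron may receive (default +4).
#' @param max_net_loss Maximum net blocks a neuron may donate (default 3).
#' @param reassignment_passes Reassignment passes over all blocks (default 5).
#' @param temperature Softness of the fallback receiver weighting.
#' @param max_retries Retries for the initial swap shuffle.
#' @return A list of class `sharc_params`.
#' @export
sharc_params <- function(max_net_gain = 4, max_net_loss = 3,
                         reassignment_passes = 5, temperature = 1,
                         max_retries = 100) {
  stopifnot(reassignment_passes >= 1, max_net_gain >= 0, max_net_loss >= 0,
            temperature > 0)
  structure(list(max_net_gain = max_net_gain, max_net_loss = max_net_loss,
                 reassignment_passes = reassignment_passes,
                 temperature = temperature, max_retries = max_retries),
            class = "sharc_params")
}

#' SHARC: shuffle activity to rearrange correlations
#'
#' Generates a surrogate raster whose pairwise correlation matrix approaches
#' a target (by default the source raster's own matrix) while conserving
#' per-frame active counts exactly and per-neuron block counts within the
#' activity budget. After an initial swap shuffle, blocks are repeatedly
#' reassigned: for block i, every already-assigned overlapping block j
#' "votes" for candidate neurons with weight `r_j / (L_i L_j)` times the gap
#' between the target and current correlations of j's neuron, and block i
#' goes to the neuron with the largest total vote (ties broken at random).
#' Neurons owning an overlapping block are excluded; neurons at the net-gain
#' bound cannot receive and blocks of neurons at the net-loss bound cannot
#' donate. When no votes are available the receiver is drawn with probability
#' weighted toward net donors, pulling activity budgets back toward balance.
#'
#' @inheritParams swap_shuffle
#' @param target Target correlation matrix (neurons x neurons); default is
#'   the correlation matrix of `raster` (per epoch under epoch scope).
#' @param params A [sharc_params()].
#' @return Shuffled raster with attribute `diagnostics`: a list with
#'   `net_gain` (per-neuron block-count change), `unassignable` and
#'   `fallback_used` counts.
#' @export
sharc_shuffle <- function(raster, target = NULL, scope = c("whole", "epoch"),
                          epochs = NULL, params = sharc_params(),
                          seed = NULL) {
  raster <- as_event_raster(raster)
  scope <- match.arg(scope)
  if (!is.null(seed)) set.seed(seed)
  if (scope == "whole") return(sharc_segment(raster, target, params))
  if (is.null(epochs)) stop("epoch scope requires an epoch annotation")
  out <- matrix(0L, nrow(raster), ncol(raster))
  diags <- list()
  for (i in seq_len(nrow(epochs$epochs))) {
    f <- interval_frames(epochs$epochs$start[i], epochs$epochs$end[i])
    seg <- sharc_segment(raster[, f, drop = FALSE], target, params)
    out[, f] <- seg
    diags[[i]] <- attr(seg, "diagnostics")
  }
  attr(out, "diagnostics") <- list(
    net_gain = Reduce(`+`, lapply(diags, `[[`, "net_gain")),
    unassignable = sum(vapply(diags, `[[`, numeric(1), "unassignable")),
    fallback_used = sum(vapply(diags, `[[`, numeric(1), "fallback_used")))
  out
}

sharc_segment <- function(raster, target, params) {
  N <- nrow(raster); F <- ncol(raster)
  if (is.null(target)) target <- correlation_matrix(raster)
  stopifnot(nrow(target) == N, ncol(target) == N)
  tgt <- target
  tgt[!is.finite(tgt)] <- 0            # zero-variance rows carry no votes
  blocks <- raster_to_blocks(raster)
  if (nrow(blocks) == 0) {
    attr(raster, "diagnostics") <- list(net_gain = integer(N),
                                        unassignable = 0L, fallback_used = 0L)
    return(raster)
  }
  sw <- cpp_swap_shuffle(blocks$start, blocks$duration, blocks$neuron - 1L,
                         N, F, params$max_retries)
  res <- cpp_sharc(blocks$start, blocks$duration, sw$neuron, N, F, tgt,
                   params$reassignment_passes, params$max_net_gain,
                   params$max_net_loss, params$temperature)
  # the budget ledger is kept relative to the source raster, so fold in the
  # block-count changes made by the initial swap shuffle
  orig_counts <- tabulate(blocks$neuron, N)
  blocks$neuron <- res$neuron + 1L
  new_counts <- tabulate(blocks$neuron, N)
  out <- blocks_to_raster(blocks, N, F)
  attr(out, "diagnostics") <- list(net_gain = new_counts - orig_counts,
                                   unassignable = res$unassignable,
                                   fallback_used = res$fallback_used)
  out
}

#' Pairwise correlation matrix of neuron rows
#'
#' Pearson correlations between the binary activity rows of a raster,
#' optionally restricted to a frame set. Zero-variance rows give `NA`.
#'
#' @param raster Binary event raster.
#' @param frames Optional 1-based frame indices.
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
correlation_matrix <- function(raster, frames = NULL) {
  m <- if (is.null(frames)) raster else raster[, frames, drop = FALSE]
  suppressWarnings(cor(t(m)))
}

#' Similarity between two correlation matrices or two rasters
#'
#' `correlation_similarity()` is the Pearson correlation of the vectorized
#' off-diagonal upper triangles of two correlation matrices; entries that are
#' undefined in either matrix (zero-variance rows) are excluded from both
#' vectors. `activity_similarity()` is the Pearson correlation of the
#' per-neuron activity-level vectors of two rasters.
#'
#' @param m1,m2 Correlation matrices of matching dimension.
#' @return A scalar in `[-1, 1]`.
#' @export
correlation_similarity <- function(m1, m2) {
  stopifnot(all(dim(m1) == dim(m2)))
  ut <- upper.tri(m1)
  v1 <- m1[ut]; v2 <- m2[ut]
  ok <- is.finite(v1) & is.finite(v2)
  if (sum(ok) < 3) stop("fewer than 3 valid correlation pairs")
  cor(v1[ok], v2[ok])
}

#' @rdname correlation_similarity
#' @param r1,r2 Event rasters of matching dimension.
#' @param frames Optional 1-based frame indices over which activity levels
#'   are computed.
#' @export
activity_similarity <- function(r1, r2, frames = NULL) {
  stopifnot(all(dim(r1) == dim(r2)))
  if (!is.null(frames)) {
    r1 <- r1[, frames, drop = FALSE]
    r2 <- r2[, frames, drop = FALSE]
  }
  a1 <- rowMeans(r1); a2 <- rowMeans(r2)
  if (length(a1) < 3) stop("fewer than 3 neurons")
  if (sd(a1) == 0 || sd(a2) == 0) stop("degenerate activity-level vector")
  cor(a1, a2)
}

#' Circular-shuffle null percentile of condition-specific activity
#'
#' Builds a per-neuron null distribution of percent time active by circularly
#' rotating the neuron's full-session activity row and re-extracting each
#' condition's frames, then scores the observed activity as a mid-rank
#' percentile of that null. Percentiles above 90 (below 10) label the neuron
#' positively (negatively) modulated in that condition.
#'
#' @param row Binary activity vector for one neuron (full session).
#' @param condition_frames Named list of 1-based frame-index vectors, one per
#'   condition (conditions are typically matched in size).
#' @param n_shuffles Number of circular rotations drawn (default 10000).
#' @param upper,lower Percentile thresholds for the modulation labels.
#' @param seed Optional RNG seed.
#' @return Tibble with one row per condition: `condition`, `observed`
#'   (fraction of condition frames active), `percentile`, `label`
#'   (`"positive"`, `"negative"` or `"none"`; `NA` percentile and
#'   `"unmodulated"` for an all-zero row).
#' @export
circular_null_percentile <- function(row, condition_frames, n_shuffles = 10000,
                                     upper = 90, lower = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  F <- length(row)
  row <- as.numeric(row)
  conds <- names(condition_frames)
  if (is.null(conds)) conds <- paste0("condition_", seq_along(condition_frames))
  if (all(row == 0)) {
    return(tibble::tibble(condition = conds,
                          observed = 0, percentile = NA_real_,
                          label = "unmodulated"))
  }
  fr <- fft(row)
  offsets <- sample.int(F - 1L, n_shuffles, replace = TRUE)
  out <- lapply(seq_along(condition_frames), function(ci) {
    idx <- condition_frames[[ci]]
    ind <- numeric(F); ind[idx] <- 1
    # counts for every rotation via circular cross-correlation
    cc <- Re(fft(fr * Conj(fft(ind)), inverse = TRUE)) / F
    counts <- round(cc)                 # integer counts, fp noise removed
    # counts[o + 1] = sum over f of ind[f] * row[(f + o - 1) mod F + 1]
    null <- counts[offsets + 1L]
    obs <- sum(row[idx])
    pct <- 100 * (sum(null < obs) + 0.5 * sum(null == obs)) / n_shuffles
    tibble::tibble(condition = conds[ci], observed = obs / length(idx),
                   percentile = pct,
                   label = if (pct > upper) "positive"
                           else if (pct < lower) "negative" else "none")
  })
  dplyr::bind_rows(out)
}

#' Behaviorally modulated neurons across a raster
#'
#' Applies [circular_null_percentile()] to every neuron.
#'
#' @param raster Binary event raster.
#' @param condition_frames Named list of 1-based frame-index vectors.
#' @param n_shuffles,upper,lower,seed Passed through.
#' @return Tibble with columns `neuron`, `condition`, `observed`,
#'   `percentile`, `label`.
#' @export
modulated_neurons <- function(raster, condition_frames, n_shuffles = 10000,
                              upper = 90, lower = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(seq_len(nrow(raster)), function(n)
    dplyr::mutate(circular_null_percentile(raster[n, ], condition_frames,
                                           n_shuffles, upper, lower),
                  neuron = n, .before = 1))
  dplyr::bind_rows(res)
}
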