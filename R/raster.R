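#' Validate an event raster
#'
#' An event raster is a binary integer matrix, neurons as rows and frames as
#' columns. `as_event_raster()` checks the shape and 0/1 content and returns
#' the matrix in integer storage mode.
#'
#' @param x A matrix of 0s and 1s (neurons x frames).
#' @return The validated integer matrix.
#' @export
as_event_raster <- function(x) {
  if (!is.matrix(x)) stop("event raster must be a matrix (neurons x frames)")
  if (anyNA(x)) stop("event raster contains missing values")
  if (!all(x == 0L | x == 1L)) stop("event raster must be binary (0/1)")
  storage.mode(x) <- "integer"
  x
}

#' Decompose a raster into blocks of activity
#'
#' A block is one maximal run of consecutive active frames for one neuron:
#' the unit moved by the shuffling procedures. `blocks_to_raster()` inverts
#' the decomposition exactly.
#'
#' @param raster Binary event raster (neurons x frames).
#' @return A tibble with columns `neuron` (1-based row index), `start`
#'   (0-based first frame of the block) and `duration` (frames).
#' @export
raster_to_blocks <- function(raster) {
  raster <- as_event_raster(raster)
  out <- lapply(seq_len(nrow(raster)), function(n) {
    r <- rle(raster[n, ] > 0L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths          # 0-based starts
    keep <- r$values
    if (!any(keep)) return(NULL)
    tibble::tibble(neuron = n, start = starts[keep], duration = r$lengths[keep])
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0)
    res <- tibble::tibble(neuron = integer(), start = integer(),
                          duration = integer())
  res
}

#' @rdname raster_to_blocks
#' @param blocks Tibble as returned by [raster_to_blocks()].
#' @param n_neurons,n_frames Dimensions of the reconstructed raster.
#' @export
blocks_to_raster <- function(blocks, n_neurons, n_frames) {
  raster <- matrix(0L, n_neurons, n_frames)
  for (i in seq_len(nrow(blocks))) {
    f <- (blocks$start[i] + 1):(blocks$start[i] + blocks$duration[i])
    if (any(raster[blocks$neuron[i], f] == 1L))
      stop("blocks of one neuron overlap")
    raster[blocks$neuron[i], f] <- 1L
  }
  raster
}

#' Read and write event rasters as delimited text
#'
#' Neurons are rows and frames are columns; values are 0/1 and the delimiter
#' is a tab. No header or row names are written.
#'
#' @param raster Binary event raster.
#' @param path File path.
#' @return `read_raster()` returns the integer raster matrix.
#' @export
write_raster <- function(raster, path) {
  raster <- as_event_raster(raster)
  utils::write.table(raster, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  as_event_raster(m)
}

#' Epoch annotations
#'
#' An epoch annotation carries the per-frame condition track, the epoch
#' intervals, and the interaction-bout intervals inside behavioral epochs.
#' All intervals are 0-based half-open `[start, end)`.
#'
#' @param epochs Tibble with columns `condition`, `start`, `end`.
#' @param bouts Tibble with columns `condition`, `start`, `end`,
#'   `interacting` (logical). May have zero rows.
#' @param n_frames Total frame count.
#' @return An object of class `epoch_annotation`: a list with elements
#'   `n_frames`, `epochs`, `bouts` and `frame_condition` (character vector,
#'   one label per frame).
#' @export
epoch_annotation <- function(epochs, bouts = NULL, n_frames = max(epochs$end)) {
  epochs <- tibble::as_tibble(epochs)
  stopifnot(all(c("condition", "start", "end") %in% names(epochs)))
  epochs <- dplyr::arrange(epochs, .data$start)
  if (any(epochs$start < 0) || any(epochs$end > n_frames) ||
      any(epochs$end <= epochs$start))
    stop("malformed epoch intervals")
  if (nrow(epochs) > 1 && any(epochs$start[-1] < epochs$end[-nrow(epochs)]))
    stop("overlapping epochs rejected")
  if (is.null(bouts))
    bouts <- tibble::tibble(condition = character(), start = integer(),
                            end = integer(), interacting = logical())
  frame_condition <- rep(NA_character_, n_frames)
  for (i in seq_len(nrow(epochs)))
    frame_condition[(epochs$start[i] + 1):epochs$end[i]] <- epochs$condition[i]
  structure(list(n_frames = n_frames, epochs = epochs,
                 bouts = tibble::as_tibble(bouts),
                 frame_condition = frame_condition),
            class = "epoch_annotation")
}

#' @export
print.epoch_annotation <- function(x, ...) {
  cat("<epoch_annotation> ", x$n_frames, " frames, ", nrow(x$epochs),
      " epochs, ", sum(x$bouts$interacting %||% logical(0)),
      " interaction bouts\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a 0-based half-open interval to 1-based frame indices
#'
#' @param start,end Interval bounds, 0-based half-open.
#' @return Integer vector of 1-based frame (column) indices.
#' @export
interval_frames <- function(start, end) {
  if (end <= start) return(integer(0))
  seq.int(start + 1L, end)
}

#' Read and write epoch annotations as JSON
#'
#' @param ann An `epoch_annotation`.
#' @param path File path.
#' @export
write_epochs <- function(ann, path) {
  stopifnot(inherits(ann, "epoch_annotation"))
  payload <- list(
    n_frames = ann$n_frames,
    epochs = lapply(seq_len(nrow(ann$epochs)), function(i) list(
      condition = ann$epochs$condition[i],
      start_frame = ann$epochs$start[i],
      end_frame_exclusive = ann$epochs$end[i])),
    bouts = lapply(seq_len(nrow(ann$bouts)), function(i) list(
      condition = ann$bouts$condition[i],
      start_frame = ann$bouts$start[i],
      end_frame_exclusive = ann$bouts$end[i],
      interacting = ann$bouts$interacting[i]))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(p$n_frames) || is.null(p$epochs))
    stop("malformed epochs file: missing n_frames or epochs")
  grab <- function(items, interacting = FALSE) {
    if (length(items) == 0) {
      t <- tibble::tibble(condition = character(), start = integer(),
                          end = integer())
      if (interacting) t$interacting <- logical(0)
      return(t)
    }
    t <- tibble::tibble(
      condition = vapply(items, function(e) e$condition, character(1)),
      start = vapply(items, function(e) as.integer(e$start_frame), integer(1)),
      end = vapply(items, function(e) as.integer(e$end_frame_exclusive),
                   integer(1)))
    if (interacting)
      t$interacting <- vapply(items, function(e) isTRUE(e$interacting),
                              logical(1))
    t
  }
  epoch_annotation(grab(p$epochs), grab(p$bouts %||% list(), interacting = TRUE),
                   n_frames = as.integer(p$n_frames))
}
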