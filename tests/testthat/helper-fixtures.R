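# shared fixture builders (everything generated in code; no stored data)

random_raster <- function(n_neurons, n_frames, p = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(as.integer(runif(n_neurons * n_frames) < p), n_neurons, n_frames)
}

# independent oracle for per-neuron block counts: count 0->1 transitions
count_blocks_per_neuron <- function(raster) {
  apply(raster, 1, function(r) sum(diff(c(0L, r)) == 1L))
}

# independent R oracle for triplet counting (frame-by-frame enumeration)
brute_triplets <- function(raster, frames = seq_len(ncol(raster))) {
  env <- new.env()
  for (f in frames) {
    act <- which(raster[, f] == 1L)
    if (length(act) < 3) next
    cmb <- utils::combn(act, 3)
    for (i in seq_len(ncol(cmb))) {
      key <- paste(cmb[, i], collapse = "-")
      env[[key]] <- (env[[key]] %||% 0L) + 1L
    }
  }
  keys <- ls(env)
  if (length(keys) == 0)
    return(tibble::tibble(n1 = integer(), n2 = integer(), n3 = integer(),
                          count = integer()))
  parts <- do.call(rbind, lapply(strsplit(keys, "-"), as.integer))
  out <- tibble::tibble(n1 = parts[, 1], n2 = parts[, 2], n3 = parts[, 3],
                        count = vapply(keys, function(k) env[[k]],
                                       integer(1), USE.NAMES = FALSE))
  dplyr::arrange(out, n1, n2, n3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a tiny labeled two-state dataset for classifier tests
small_two_state <- function(coding = "correlation", seed = 1,
                            n_neurons = 40, n_frames = 1500,
                            n_assemblies = 2, bound = 0.5) {
  sc <- synth_config(n_neurons = n_neurons, n_frames = n_frames,
                     mean_activity = 0.08, oscillation_period = 100,
                     assembly_size = 8,
                     n_assemblies = if (coding == "correlation") n_assemblies else 0,
                     modulation_bound = if (coding == "rate") bound else 0,
                     seed = seed)
  a <- gen_state_a(sc)
  b <- if (coding == "correlation") insert_assemblies(a, sc)
       else modulate_activity(a, sc)
  list(raster = cbind(a, b),
       labels = c(rep(1, n_frames), rep(0, n_frames)),
       state_a = a, state_b = b, config = sc)
}
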