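#' Count three-neuron coactivity combinations
#'
#' For every frame in which at least 3 neurons are active, each of the
#' `choose(k, 3)` unordered triplets of active neurons is incremented once.
#' The catalog is stored sparsely; its total mass equals
#' `sum(choose(colSums(raster)[frames], 3))`.
#'
#' @param raster Binary event raster.
#' @param frames Optional 1-based frame indices (a condition restriction).
#' @return Tibble with columns `n1 < n2 < n3` (1-based neuron indices) and
#'   `count`, sorted by triplet.
#' @export
count_triplets <- function(raster, frames = NULL) {
  raster <- as_event_raster(raster)
  if (is.null(frames)) frames <- seq_len(ncol(raster))
  res <- cpp_count_triplets(raster, as.integer(frames) - 1L)
  out <- tibble::tibble(n1 = res$n1 + 1L, n2 = res$n2 + 1L, n3 = res$n3 + 1L,
                        count = res$count)
  dplyr::arrange(out, .data$n1, .data$n2, .data$n3)
}

#' Triplet enrichment against swap-shuffled surrogates
#'
#' Compares how often each observed triplet occurs in the real raster versus
#' in `n_surrogates` swap-shuffled surrogates of the whole session (which
#' preserve per-frame active counts and per-neuron block counts, hence the
#' total triplet mass per frame). Enrichment is the mid-rank percentile of
#' the real count within the surrogate count distribution, computed within
#' each condition's frame set; triplets never observed in a condition are
#' excluded for that condition.
#'
#' @param raster Binary event raster.
#' @param condition_frames Named list of 1-based frame-index vectors; use
#'   `list(all = seq_len(ncol(raster)))` for a whole-session analysis.
#' @param n_surrogates Number of swap-shuffled surrogates (default 1000).
#' @param threshold Enrichment percentile threshold (default 95; 99.9 is the
#'   strong criterion).
#' @param max_retries Swap-shuffle conflict retries.
#' @param seed Optional RNG seed.
#' @return Tibble with columns `condition`, `n1`, `n2`, `n3`, `count`,
#'   `percentile`, `enriched`.
#' @export
triplet_enrichment <- function(raster, condition_frames, n_surrogates = 1000,
                               threshold = 95, max_retries = 100,
                               seed = NULL) {
  raster <- as_event_raster(raster)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(condition_frames)))
    stop("condition_frames must be a named list")
  blocks <- raster_to_blocks(raster)
  real <- lapply(condition_frames, function(f) count_triplets(raster, f))
  keys <- lapply(real, function(r)
    list(triplets = cbind(r$n1, r$n2, r$n3) - 1L, count = r$count))
  res <- cpp_triplet_enrichment(
    blocks$start, blocks$duration, blocks$neuron - 1L,
    nrow(raster), ncol(raster),
    lapply(condition_frames, function(f) as.integer(f) - 1L),
    keys, as.integer(n_surrogates), max_retries)
  out <- lapply(seq_along(real), function(ci) {
    r <- real[[ci]]
    pct <- 100 * (res[[ci]]$n_less + 0.5 * res[[ci]]$n_equal) / n_surrogates
    dplyr::mutate(r, condition = names(condition_frames)[ci], .before = 1,
                  percentile = pct, enriched = pct > threshold)
  })
  dplyr::bind_rows(out)
}

# number of distinct intervals (0-based half-open) in which all three
# neurons of a triplet are coactive in at least one frame
triplet_bout_support <- function(raster, triplet, intervals) {
  if (nrow(intervals) == 0) return(0L)
  sup <- 0L
  for (i in seq_len(nrow(intervals))) {
    f <- interval_frames(intervals$start[i], intervals$end[i])
    if (length(f) == 0) next
    co <- colSums(raster[triplet, f, drop = FALSE]) == 3L
    if (any(co)) sup <- sup + 1L
  }
  sup
}

#' Behavioral specificity and overlap structure of enriched triplets
#'
#' A triplet is condition-specific when its enrichment percentile exceeds
#' `enrich_pct` in one condition and falls below `other_pct` in the other. A
#' repetition filter keeps only triplets coactive in at least `min_bouts`
#' distinct bouts (or matched interval sets) of their enriched condition. The
#' overlap report examines every pair of opposite-condition specific triplets
#' sharing exactly two neurons and asks whether the "left-out" neuron (the
#' one present in a triplet of one condition but missing from the overlapping
#' triplet of the other) itself participates in some enriched triplet of the
#' opposite condition.
#'
#' @param enrichment Tibble from [triplet_enrichment()] computed over exactly
#'   two conditions.
#' @param raster Binary event raster (for bout support).
#' @param bout_intervals Named list (same names as the conditions) of tibbles
#'   with 0-based half-open `start`, `end` columns: interaction bouts for one
#'   condition, matched interval sets for the other. `NULL` disables the
#'   repetition filter.
#' @param enrich_pct,other_pct Specificity thresholds (default 95 and 50).
#' @param min_bouts Minimum distinct bouts (default 2).
#' @return List with `labels` (tibble: triplet, per-condition percentile,
#'   `specificity` in social-specific/homecage-specific/both/neither,
#'   `bout_support`, `kept`) and `overlap` (tibble of 2-shared-neuron pairs
#'   with the left-out neuron's opposite-condition participation).
#' @export
specificity_and_overlap <- function(enrichment, raster, bout_intervals = NULL,
                                    enrich_pct = 95, other_pct = 50,
                                    min_bouts = 2) {
  conds <- unique(enrichment$condition)
  if (length(conds) != 2)
    stop("specificity requires exactly two conditions")
  key <- function(d) paste(d$n1, d$n2, d$n3, sep = "-")
  wide <- tidyr::pivot_wider(
    dplyr::select(enrichment, dplyr::all_of(
      c("condition", "n1", "n2", "n3", "count", "percentile"))),
    names_from = "condition", values_from = c("count", "percentile"))
  p1 <- wide[[paste0("percentile_", conds[1])]]
  p2 <- wide[[paste0("percentile_", conds[2])]]
  # a triplet absent from a condition occurred less often there than in any
  # surrogate that contains it; treat its percentile as 0 for specificity
  p1[is.na(p1)] <- 0
  p2[is.na(p2)] <- 0
  spec <- dplyr::case_when(
    p1 > enrich_pct & p2 < other_pct ~ paste0(conds[1], "-specific"),
    p2 > enrich_pct & p1 < other_pct ~ paste0(conds[2], "-specific"),
    p1 > enrich_pct & p2 > enrich_pct ~ "both",
    TRUE ~ "neither")
  labels <- dplyr::mutate(wide, specificity = spec)

  support <- rep(NA_integer_, nrow(labels))
  if (!is.null(bout_intervals)) {
    for (i in seq_len(nrow(labels))) {
      cond_i <- dplyr::case_when(
        spec[i] == paste0(conds[1], "-specific") ~ conds[1],
        spec[i] == paste0(conds[2], "-specific") ~ conds[2],
        TRUE ~ NA_character_)
      if (is.na(cond_i)) next
      support[i] <- triplet_bout_support(
        raster, c(labels$n1[i], labels$n2[i], labels$n3[i]),
        bout_intervals[[cond_i]])
    }
  }
  labels$bout_support <- support
  labels$kept <- is.na(support) | support >= min_bouts
  labels$kept[spec == "neither"] <- FALSE

  spec1 <- labels[labels$specificity == paste0(conds[1], "-specific") &
                    labels$kept, ]
  spec2 <- labels[labels$specificity == paste0(conds[2], "-specific") &
                    labels$kept, ]
  enriched_members <- function(d) unique(c(d$n1, d$n2, d$n3))
  enr1 <- enrichment[enrichment$condition == conds[1] &
                       enrichment$percentile > enrich_pct, ]
  enr2 <- enrichment[enrichment$condition == conds[2] &
                       enrichment$percentile > enrich_pct, ]
  mem1 <- enriched_members(enr1)
  mem2 <- enriched_members(enr2)

  overlap <- list()
  if (nrow(spec1) > 0 && nrow(spec2) > 0) {
    t1 <- lapply(seq_len(nrow(spec1)), function(i)
      c(spec1$n1[i], spec1$n2[i], spec1$n3[i]))
    t2 <- lapply(seq_len(nrow(spec2)), function(i)
      c(spec2$n1[i], spec2$n2[i], spec2$n3[i]))
    for (i in seq_along(t1)) for (j in seq_along(t2)) {
      shared <- intersect(t1[[i]], t2[[j]])
      if (length(shared) != 2) next
      left_out_1 <- setdiff(t1[[i]], shared)   # in cond1 triplet, not cond2
      left_out_2 <- setdiff(t2[[j]], shared)
      overlap[[length(overlap) + 1]] <- tibble::tibble(
        triplet_1 = key(spec1[i, ]), triplet_2 = key(spec2[j, ]),
        left_out_1 = left_out_1, left_out_2 = left_out_2,
        left_out_1_in_opposite = left_out_1 %in% mem2,
        left_out_2_in_opposite = left_out_2 %in% mem1)
    }
  }
  overlap <- if (length(overlap)) dplyr::bind_rows(overlap) else
    tibble::tibble(triplet_1 = character(), triplet_2 = character(),
                   left_out_1 = integer(), left_out_2 = integer(),
                   left_out_1_in_opposite = logical(),
                   left_out_2_in_opposite = logical())
  list(labels = labels, overlap = overlap)
}
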