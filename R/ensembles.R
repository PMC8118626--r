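#' Extract social / home-cage / neutral hidden-unit groups
#'
#' Hidden units are ranked by trained output weight (ties broken by unit
#' index): the `n_group` most negative weights form the social units (they
#' bias the output toward the condition labeled 0), the `n_group` most
#' positive the home-cage units, and the `n_group` remaining units with
#' weights nearest zero the neutral units. Groups are disjoint.
#'
#' @param clf A trained `coact_nn`.
#' @param n_group Units per group (default 25).
#' @return A list of class `unit_groups` with integer vectors `social`,
#'   `homecage`, `neutral` and a `degenerate` flag (all-zero weights).
#' @export
extract_unit_groups <- function(clf, n_group = 25) {
  stopifnot(inherits(clf, "coact_nn"))
  if (!clf$trained) stop("classifier has not been trained")
  H <- clf$n_hidden
  if (H < 3 * n_group)
    stop(sprintf("need at least %d hidden units for groups of %d",
                 3 * n_group, n_group))
  ord <- order(clf$w, seq_len(H))
  social <- ord[seq_len(n_group)]
  homecage <- ord[seq.int(H - n_group + 1, H)]
  rest <- setdiff(order(abs(clf$w), seq_len(H)), c(social, homecage))
  neutral <- rest[seq_len(n_group)]
  degenerate <- all(clf$w == 0)
  if (degenerate)
    warning("all output weights are zero; unit groups are arbitrary")
  structure(list(social = social, homecage = homecage, neutral = neutral,
                 n_group = n_group, degenerate = degenerate),
            class = "unit_groups")
}

#' Input similarity between hidden units
#'
#' Pairwise Pearson correlation between the binary input-connection vectors
#' of hidden units, and each unit's mean similarity to the social, home-cage
#' and neutral groups (self-pairs excluded). Units with constant input
#' vectors are excluded (NA similarities).
#'
#' @param clf A trained `coact_nn`.
#' @param groups A [extract_unit_groups()] result.
#' @return List with `matrix` (unit x unit similarity) and `by_unit` (tibble
#'   with `unit`, `weight`, `sim_social`, `sim_homecage`, `sim_neutral`).
#' @export
input_similarity <- function(clf, groups) {
  stopifnot(inherits(clf, "coact_nn"), inherits(groups, "unit_groups"))
  S <- suppressWarnings(cor(t(clf$connections)))
  group_mean <- function(u, members) {
    m <- setdiff(members, u)
    v <- S[u, m]
    mean(v[is.finite(v)])
  }
  H <- clf$n_hidden
  by_unit <- tibble::tibble(
    unit = seq_len(H),
    weight = clf$w,
    sim_social = vapply(seq_len(H), group_mean, numeric(1),
                        members = groups$social),
    sim_homecage = vapply(seq_len(H), group_mean, numeric(1),
                          members = groups$homecage),
    sim_neutral = vapply(seq_len(H), group_mean, numeric(1),
                         members = groups$neutral))
  list(matrix = S, by_unit = by_unit)
}

#' Classifier-derived neuronal ensembles
#'
#' For each unit group, each neuron is scored by its number of input
#' connections into the group; the top `top_frac` of neurons (ties broken by
#' neuron index) form the group's ensemble.
#'
#' @param clf A trained `coact_nn`.
#' @param groups A [extract_unit_groups()] result.
#' @param top_frac Fraction of neurons per ensemble (default 0.2).
#' @return A list of class `neuron_ensembles` with integer vectors `social`,
#'   `homecage`, `neutral` (each of size `ceiling(top_frac * n_neurons)`) and
#'   the per-neuron connection-count tibble in `$counts`.
#' @export
define_ensembles <- function(clf, groups, top_frac = 0.2) {
  stopifnot(inherits(clf, "coact_nn"), inherits(groups, "unit_groups"))
  N <- clf$n_neurons
  size <- as.integer(ceiling(top_frac * N))
  pick <- function(members) {
    cnt <- colSums(clf$connections[members, , drop = FALSE])
    order(-cnt, seq_len(N))[seq_len(size)]
  }
  counts <- tibble::tibble(
    neuron = seq_len(N),
    social = colSums(clf$connections[groups$social, , drop = FALSE]),
    homecage = colSums(clf$connections[groups$homecage, , drop = FALSE]),
    neutral = colSums(clf$connections[groups$neutral, , drop = FALSE]))
  structure(list(social = pick(groups$social),
                 homecage = pick(groups$homecage),
                 neutral = pick(groups$neutral),
                 size = size, counts = counts),
            class = "neuron_ensembles")
}

#' Per-ensemble, per-condition activity and correlation statistics
#'
#' For each ensemble and condition frame set: the mean fraction of ensemble
#' neurons active per frame, and the mean off-diagonal pairwise Pearson
#' correlation between ensemble neurons over those frames. The condition
#' frame sets should be matched in size so correlations are comparable.
#'
#' @param raster Binary event raster.
#' @param condition_frames Named list of 1-based frame-index vectors.
#' @param ensembles A [define_ensembles()] result, or a named list of integer
#'   neuron-index vectors.
#' @return Tibble with columns `ensemble`, `condition`, `mean_activity`,
#'   `mean_correlation`, `n_neurons`, `n_frames`.
#' @export
ensemble_condition_stats <- function(raster, condition_frames, ensembles) {
  if (inherits(ensembles, "neuron_ensembles"))
    ensembles <- ensembles[c("social", "homecage", "neutral")]
  out <- list()
  for (e in names(ensembles)) {
    members <- ensembles[[e]]
    if (length(members) < 2)
      stop(sprintf("ensemble '%s' has fewer than 2 neurons", e))
    for (cn in names(condition_frames)) {
      f <- condition_frames[[cn]]
      sub <- raster[members, f, drop = FALSE]
      cm <- suppressWarnings(cor(t(sub)))
      offdiag <- cm[upper.tri(cm)]
      out[[length(out) + 1]] <- tibble::tibble(
        ensemble = e, condition = cn,
        mean_activity = mean(sub),
        mean_correlation = mean(offdiag[is.finite(offdiag)]),
        n_neurons = length(members), n_frames = length(f))
    }
  }
  dplyr::bind_rows(out)
}
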