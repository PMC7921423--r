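#' Label connected components of protein units
#'
#' 4-connected component labelling over the squares occupied by protein
#' units; obstacles and empty squares never join components. Connectivity
#' matches the von Neumann move/contact neighbourhood of the simulator.
#'
#' @param state A `lattice_state`, or a plain occupancy matrix (0 empty,
#'   1 unit, 2 obstacle).
#' @return Integer matrix of the same dimensions; background 0, components
#'   labelled 1..n.
#' @export
label_components <- function(state) {
  occ <- if (inherits(state, "lattice_state")) state$occ else state
  storage.mode(occ) <- "integer"
  label_components_cpp(occ)
}

#' Sizes of labelled components
#'
#' @param labels Label matrix from [label_components()].
#' @return Integer vector of component sizes (possibly empty).
#' @export
component_sizes <- function(labels) {
  labels <- labels[labels > 0L]
  if (length(labels) == 0L) return(integer(0))
  tabulate(labels)
}

#' Summarize clusters above the detection threshold
#'
#' A cluster is a connected component of at least `min_size` units
#' (default 6), mimicking the smallest assembly visible as a condensate
#' under confocal microscopy; smaller components contribute to neither the
#' count nor the mean size. When no component qualifies, `mean_size` is
#' reported as 0 so that time series stay defined.
#'
#' @param sizes Integer vector of component sizes (see
#'   [component_sizes()]).
#' @param min_size Minimum qualifying component size.
#' @param step,time_unit Iteration step of the snapshot and steps per time
#'   unit; reported time is `t = step / time_unit`.
#' @return One-row data.frame: `step`, `t`, `n_clusters`, `mean_size`,
#'   plus the qualifying sizes as a list column `sizes`.
#' @export
summarize_clusters <- function(sizes, min_size = 6L, step = NA_real_,
                               time_unit = 1e5) {
  keep <- sizes[sizes >= min_size]
  data.frame(step = step, t = step / time_unit,
             n_clusters = length(keep),
             mean_size = if (length(keep)) mean(keep) else 0,
             sizes = I(list(as.integer(keep))))
}

#' Cluster statistics of a lattice snapshot
#'
#' Convenience wrapper: [label_components()] then [summarize_clusters()].
#'
#' @param state A `lattice_state`.
#' @inheritParams summarize_clusters
#' @return One-row data.frame as in [summarize_clusters()].
#' @export
cluster_summary <- function(state, min_size = 6L, time_unit = 1e5) {
  sizes <- component_sizes(label_components(state))
  summarize_clusters(sizes, min_size = min_size, step = state$step,
                     time_unit = time_unit)
}

#' Mean and standard error across simulation replicates
#'
#' @param x Numeric vector of per-replicate values (length >= 1).
#' @return Named numeric vector `c(mean, sem, n)`; `sem` is
#'   `sd(x)/sqrt(n)`, reported as 0 (with a warning) for a single
#'   replicate.
#' @export
replicate_stats <- function(x) {
  if (length(x) == 0L) stop("no replicate values supplied")
  n <- length(x)
  if (n == 1L) {
    warning("single replicate: SEM reported as 0")
    return(c(mean = x, sem = 0, n = 1))
  }
  c(mean = mean(x), sem = sd(x) / sqrt(n), n = n)
}
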