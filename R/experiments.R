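#' Protocol for the grid-shrinkage sweep
#'
#' The shrink sweep emulates osmotic cell shrinkage by holding the molecule
#' numbers fixed while reducing the grid, so that both protein and crowder
#' densities rise together. Two presets are provided. `"full"` is the
#' full-scale protocol: 500 units with 1500 obstacles on grids from
#' 50 x 50 to 120 x 120, 5e6 steps, 18 replicates (long-running; hours of
#' CPU). `"desk"` is a density-preserving reduction: 125 units and 375
#' obstacles (the same occupancy fractions at the largest grid, 60 x 60,
#' as at full scale on 120 x 120) on grids from 24 x 24 (near-full
#' occupancy) to 60 x 60, 1.25e6 steps (the same 2500 attempted moves
#' per molecule), 8 replicates; it runs in seconds and reproduces the
#' same qualitative phase behaviour. The desk grid list samples the
#' crowded end finely because the cluster-size turnover is confined to
#' high occupancy (above roughly two-thirds of the lattice filled).
#'
#' @param scale `"desk"` or `"full"`.
#' @param grid_sizes Integer vector of square grid edge lengths.
#' @param n_units,n_obstacles Molecule counts (fixed across grid sizes).
#' @param n_steps Iterations per run.
#' @param n_replicates Independent replicates per grid size.
#' @param base_seed Replicate `i` of every condition is seeded with
#'   `base_seed + i - 1`.
#' @param min_size Cluster detection threshold (see
#'   [summarize_clusters()]).
#' @param k1,k5,A,dE_over_theta Rate parameters, see [lattice_config()].
#' @return A `shrink_protocol` list.
#' @export
shrink_protocol <- function(scale = c("desk", "full"),
                            grid_sizes = NULL, n_units = NULL,
                            n_obstacles = NULL, n_steps = NULL,
                            n_replicates = NULL, base_seed = 20201,
                            min_size = 6L,
                            k1 = 1, k5 = 0.01, A = 1, dE_over_theta = 1) {
  scale <- match.arg(scale)
  defaults <- if (scale == "desk") {
    list(grid_sizes = c(24L, 25L, 26L, 27L, 28L, 30L, 35L, 60L),
         n_units = 125L, n_obstacles = 375L,
         n_steps = 1.25e6, n_replicates = 8L)
  } else {
    list(grid_sizes = seq(50L, 120L, by = 10L),
         n_units = 500L, n_obstacles = 1500L,
         n_steps = 5e6, n_replicates = 18L)
  }
  p <- list(kind = "shrink_sweep", scale = scale,
            grid_sizes = grid_sizes %||% defaults$grid_sizes,
            n_units = n_units %||% defaults$n_units,
            n_obstacles = n_obstacles %||% defaults$n_obstacles,
            n_steps = n_steps %||% defaults$n_steps,
            n_replicates = n_replicates %||% defaults$n_replicates,
            base_seed = base_seed, min_size = min_size,
            k1 = k1, k5 = k5, A = A, dE_over_theta = dE_over_theta)
  stopifnot(p$n_replicates >= 1L, p$n_steps >= 0)
  structure(p, class = "shrink_protocol")
}

#' Protocol for the grid-expansion reversal experiment
#'
#' Clusters are first grown on a small (shrunken) grid, then the grid is
#' expanded and the dissolution of clusters is followed over time,
#' emulating the return to isoosmotic conditions. `"full"`: 55 x 55 for
#' 5e6 steps then 120 x 120 for 35e6 steps, recording every 1e5 steps,
#' 12 replicates. `"desk"`: the density-preserving half-scale analogue,
#' 28 x 28 then 60 x 60 with 125 units / 375 obstacles, 1.25e6 then
#' 8.75e6 steps, recording every 2.5e4 steps, 6 replicates.
#'
#' @inheritParams shrink_protocol
#' @param phase1_grid,phase2_grid Square grid edge lengths before and
#'   after expansion (`phase2_grid >= phase1_grid`).
#' @param n_steps_phase1,n_steps_phase2 Iterations in each phase.
#' @param record_every Steps between recorded cluster summaries in
#'   phase 2; also used as the unit of reported time `t`.
#' @return An `expansion_protocol` list.
#' @export
expansion_protocol <- function(scale = c("desk", "full"),
                               phase1_grid = NULL, phase2_grid = NULL,
                               n_steps_phase1 = NULL, n_steps_phase2 = NULL,
                               record_every = NULL,
                               n_units = NULL, n_obstacles = NULL,
                               n_replicates = NULL, base_seed = 20301,
                               min_size = 6L,
                               k1 = 1, k5 = 0.01, A = 1,
                               dE_over_theta = 1) {
  scale <- match.arg(scale)
  defaults <- if (scale == "desk") {
    list(phase1_grid = 28L, phase2_grid = 60L,
         n_steps_phase1 = 1.25e6, n_steps_phase2 = 8.75e6,
         record_every = 2.5e4, n_units = 125L, n_obstacles = 375L,
         n_replicates = 6L)
  } else {
    list(phase1_grid = 55L, phase2_grid = 120L,
         n_steps_phase1 = 5e6, n_steps_phase2 = 35e6,
         record_every = 1e5, n_units = 500L, n_obstacles = 1500L,
         n_replicates = 12L)
  }
  p <- list(kind = "expansion", scale = scale,
            phase1_grid = phase1_grid %||% defaults$phase1_grid,
            phase2_grid = phase2_grid %||% defaults$phase2_grid,
            n_steps_phase1 = n_steps_phase1 %||% defaults$n_steps_phase1,
            n_steps_phase2 = n_steps_phase2 %||% defaults$n_steps_phase2,
            record_every = record_every %||% defaults$record_every,
            n_units = n_units %||% defaults$n_units,
            n_obstacles = n_obstacles %||% defaults$n_obstacles,
            n_replicates = n_replicates %||% defaults$n_replicates,
            base_seed = base_seed, min_size = min_size,
            k1 = k1, k5 = k5, A = A, dE_over_theta = dE_over_theta)
  stopifnot(p$phase2_grid >= p$phase1_grid, p$n_replicates >= 1L,
            p$n_steps_phase1 >= 0, p$n_steps_phase2 >= 0)
  structure(p, class = "expansion_protocol")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

protocol_config <- function(p, grid) {
  lattice_config(grid, grid, n_units = p$n_units,
                 n_obstacles = p$n_obstacles,
                 k1 = p$k1, k5 = p$k5, A = p$A,
                 dE_over_theta = p$dE_over_theta)
}

#' Run the grid-shrinkage sweep
#'
#' For every grid size and replicate, initializes a fresh random state
#' (seeded as `base_seed + replicate - 1`), runs `n_steps` iterations and
#' records the final-step cluster count and mean cluster size, then
#' aggregates mean +/- SEM across replicates per grid size.
#'
#' @param protocol A [shrink_protocol()] (or one with `n_obstacles = 0`
#'   for the obstacle-free control, see [run_no_obstacle_control()]).
#' @return List with `replicates` (one row per grid size x replicate) and
#'   `summary` (per grid size: `count_mean`, `count_sem`, `size_mean`,
#'   `size_sem`, `n`).
#' @export
run_shrink_sweep <- function(protocol) {
  stopifnot(inherits(protocol, "shrink_protocol"))
  model <- rate_model(protocol$k1, protocol$k5, protocol$A,
                      protocol$dE_over_theta)
  rows <- list()
  for (grid in protocol$grid_sizes) {
    cfg <- protocol_config(protocol, grid)
    for (rep in seq_len(protocol$n_replicates)) {
      seed <- protocol$base_seed + rep - 1L
      set.seed(seed)
      st <- lattice_init(cfg)
      res <- lattice_run(st, model, protocol$n_steps, record = "none")
      cs <- cluster_summary(res$state, min_size = protocol$min_size)
      rows[[length(rows) + 1L]] <-
        data.frame(grid = grid, replicate = rep, seed = seed,
                   n_clusters = cs$n_clusters, mean_size = cs$mean_size)
    }
  }
  replicates <- do.call(rbind, rows)
  list(replicates = replicates,
       summary = summarize_sweep(replicates, "grid"))
}

summarize_sweep <- function(replicates, by) {
  agg <- function(v) {
    m <- aggregate(replicates[[v]], by = replicates[by], FUN = mean)
    s <- aggregate(replicates[[v]], by = replicates[by],
                   FUN = function(x) sd(x) / sqrt(length(x)))
    n <- aggregate(replicates[[v]], by = replicates[by], FUN = length)
    list(mean = m$x, sem = s$x, n = n$x, key = m[[by]])
  }
  cnt <- agg("n_clusters"); siz <- agg("mean_size")
  out <- data.frame(key = cnt$key,
                    count_mean = cnt$mean, count_sem = cnt$sem,
                    size_mean = siz$mean, size_sem = siz$sem,
                    n = cnt$n)
  names(out)[1] <- by
  out
}

#' Run the shrink sweep without obstacles
#'
#' The obstacle-free control isolates the pure excluded-volume effect of
#' shrinking the space available to the condensate-forming units: cluster
#' size then increases monotonically as the grid shrinks, without the
#' crowding-induced turnover seen with obstacles.
#'
#' @param protocol A [shrink_protocol()]; its `n_obstacles` is forced
#'   to 0.
#' @return As [run_shrink_sweep()].
#' @export
run_no_obstacle_control <- function(protocol) {
  protocol$n_obstacles <- 0L
  run_shrink_sweep(protocol)
}

#' Run the grid-expansion reversal experiment
#'
#' Each replicate is initialized on the phase-1 grid (seeded as
#' `base_seed + replicate - 1`), aged for `n_steps_phase1` iterations,
#' expanded to the phase-2 grid, and followed for `n_steps_phase2`
#' iterations with a cluster summary recorded every `record_every` steps
#' (the first record is the expansion instant). Reported time `t` is in
#' units of `record_every` steps, 0 at the expansion instant.
#'
#' @param protocol An [expansion_protocol()].
#' @return List with `replicates` (per replicate x time point:
#'   `replicate`, `step`, `t`, `n_clusters`, `mean_size`) and `summary`
#'   (per time point mean +/- SEM).
#' @export
run_expansion <- function(protocol) {
  stopifnot(inherits(protocol, "expansion_protocol"))
  model <- rate_model(protocol$k1, protocol$k5, protocol$A,
                      protocol$dE_over_theta)
  cfg <- protocol_config(protocol, protocol$phase1_grid)
  rows <- list()
  for (rep in seq_len(protocol$n_replicates)) {
    seed <- protocol$base_seed + rep - 1L
    set.seed(seed)
    st <- lattice_init(cfg)
    st <- lattice_run(st, model, protocol$n_steps_phase1,
                      record = "none")$state
    st <- expand_lattice(st, protocol$phase2_grid, protocol$phase2_grid)
    st$step <- 0  # time axis restarts at the expansion instant
    res <- lattice_run(st, model, protocol$n_steps_phase2,
                       record_every = protocol$record_every,
                       record = "summary", min_size = protocol$min_size,
                       time_unit = protocol$record_every)
    sm <- res$summary
    rows[[length(rows) + 1L]] <-
      data.frame(replicate = rep, seed = seed, step = sm$step, t = sm$t,
                 n_clusters = sm$n_clusters, mean_size = sm$mean_size)
  }
  replicates <- do.call(rbind, rows)
  list(replicates = replicates,
       summary = summarize_sweep(replicates, "t"))
}

#' Plot a shrink-sweep or expansion summary
#'
#' Base-graphics mean +/- SEM curves for the cluster count and mean size.
#'
#' @param result Output of [run_shrink_sweep()] or [run_expansion()].
#' @param which `"count"` or `"size"`.
#' @param ... Passed to [plot()].
#' @export
plot_summary <- function(result, which = c("count", "size"), ...) {
  which <- match.arg(which)
  sm <- result$summary
  xv <- sm[[1]]
  m <- sm[[paste0(which, "_mean")]]
  s <- sm[[paste0(which, "_sem")]]
  ylab <- if (which == "count") "clusters (n)" else "mean cluster size (units)"
  plot(xv, m, type = "b", pch = 16, xlab = names(sm)[1], ylab = ylab,
       ylim = range(c(m - s, m + s)), ...)
  graphics::arrows(xv, m - s, xv, m + s, angle = 90, code = 3,
                   length = 0.03, col = "grey40")
  invisible(result)
}
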