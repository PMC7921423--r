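#' Configuration for the crowded-lattice simulator
#'
#' Defines a bounded 2D square lattice populated by diffusing protein units
#' (the condensate-forming species) and inert obstacle squares representing
#' averaged macromolecular crowders. Defaults correspond to the reference
#' crowded condition: 500 protein units and 1500 obstacles, free-unit
#' diffusion rate `k1 = 1`, obstacle diffusion rate `k5 = 0.01`, and a
#' contact-loss penalty `A * exp(-n_lost * dE_over_theta)` with `A = 1` and
#' `dE_over_theta = 1`, so that a move losing no unit-unit contacts is as
#' fast as free diffusion.
#'
#' @param width,height Grid dimensions in squares.
#' @param n_units Number of protein units.
#' @param n_obstacles Number of obstacle squares.
#' @param k1 Acceptance rate for a unit move into an empty square that loses
#'   no contacts, in `[0, 1]`.
#' @param k5 Acceptance rate for an obstacle move into an empty square, in
#'   `[0, 1]`.
#' @param A Penalty prefactor (> 0); the penalized rate at `n_lost = 0`.
#' @param dE_over_theta Dimensionless energy cost per lost unit-unit
#'   contact (>= 0).
#' @param seed Optional integer seed applied by [lattice_init()].
#' @param record_every Steps between recorded snapshots in [lattice_run()].
#' @return A `lattice_config` list.
#' @seealso [lattice_init()], [lattice_run()], [rate_model()]
#' @export
#' @examples
#' cfg <- lattice_config(20, 20, n_units = 30, n_obstacles = 90, seed = 1)
lattice_config <- function(width, height,
                           n_units = 500, n_obstacles = 1500,
                           k1 = 1, k5 = 0.01,
                           A = 1, dE_over_theta = 1,
                           seed = NULL, record_every = 1e5) {
  width <- as.integer(width); height <- as.integer(height)
  n_units <- as.integer(n_units); n_obstacles <- as.integer(n_obstacles)
  stopifnot(width >= 1L, height >= 1L, n_units >= 0L, n_obstacles >= 0L)
  if (n_units + n_obstacles > width * height)
    stop("capacity exceeded: n_units + n_obstacles > width * height")
  stopifnot(k1 >= 0, k1 <= 1, k5 >= 0, k5 <= 1, A > 0, dE_over_theta >= 0)
  structure(list(width = width, height = height,
                 n_units = n_units, n_obstacles = n_obstacles,
                 k1 = k1, k5 = k5, A = A, dE_over_theta = dE_over_theta,
                 seed = seed, record_every = record_every),
            class = "lattice_config")
}

#' Rate model mapping classified moves to acceptance rates
#'
#' A proposed move is accepted when its rate `k` exceeds a uniform draw
#' `r` in `[0, 1)`. Free unit moves carry `k1`, obstacle moves `k5`, and
#' unit moves that lose `n_lost > 0` unit-unit contacts carry the penalty
#' rate `k3(n_lost) = A * exp(-n_lost * dE_over_theta)`. Exchange and
#' reflection classes deterministically leave the molecule in place and
#' consume no acceptance draw.
#'
#' @param k1,k5,A,dE_over_theta See [lattice_config()].
#' @return A `rate_model` list with a `k3` function component.
#' @export
#' @examples
#' m <- rate_model()
#' m$k3(0)  # 1: no contact lost, moving inside a cluster is as fast as free
#' m$k3(2)  # exp(-2)
rate_model <- function(k1 = 1, k5 = 0.01, A = 1, dE_over_theta = 1) {
  stopifnot(k1 >= 0, k1 <= 1, k5 >= 0, k5 <= 1, A > 0, dE_over_theta >= 0)
  force(A); force(dE_over_theta)
  structure(list(k1 = k1, k5 = k5, A = A, dE_over_theta = dE_over_theta,
                 k3 = function(n_lost) {
                   stopifnot(all(n_lost >= 0))
                   A * exp(-n_lost * dE_over_theta)
                 }),
            class = "rate_model")
}

#' @rdname rate_model
#' @param config A [lattice_config()].
#' @export
rate_model_from_config <- function(config) {
  rate_model(config$k1, config$k5, config$A, config$dE_over_theta)
}

move_classes <- c("unit_free", "unit_penalized", "unit_exchange",
                  "obstacle_free", "reflect_out_of_bounds",
                  "reflect_occupied")

#' Acceptance rate for a classified move proposal
#'
#' @param model A [rate_model()].
#' @param proposal A move proposal as returned by [classify_move()], or a
#'   list with at least `move_class` and (for penalized moves) `n_lost`.
#' @return Rate in `[0, 1]`; exchange and reflection classes return 0
#'   (the molecule stays put without an acceptance draw).
#' @export
rate_for <- function(model, proposal) {
  switch(proposal$move_class,
         unit_free = model$k1,
         unit_penalized = model$k3(proposal$n_lost),
         obstacle_free = model$k5,
         unit_exchange = 0,
         reflect_out_of_bounds = 0,
         reflect_occupied = 0,
         stop("unknown move class: ", proposal$move_class))
}

new_lattice_state <- function(width, height, occ, x, y, kind, step = 0L) {
  structure(list(width = as.integer(width), height = as.integer(height),
                 occ = occ, x = as.integer(x), y = as.integer(y),
                 kind = as.integer(kind), step = as.numeric(step)),
            class = "lattice_state")
}

#' Randomly initialize a lattice state
#'
#' Places all units and obstacles on distinct squares sampled uniformly
#' without replacement. If `config$seed` is set, the R RNG is seeded first,
#' making the whole subsequent trajectory reproducible.
#'
#' @param config A [lattice_config()].
#' @return A `lattice_state`: occupancy matrix `occ` (`width x height`,
#'   0 empty / 1 unit / 2 obstacle, indexed `occ[x + 1, y + 1]` with
#'   0-based coordinates), per-molecule vectors `x`, `y`, `kind`, and the
#'   `step` counter (0).
#' @export
lattice_init <- function(config) {
  stopifnot(inherits(config, "lattice_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  w <- config$width; h <- config$height
  n <- config$n_units + config$n_obstacles
  idx <- sample.int(w * h, n) - 1L
  x <- idx %% w
  y <- idx %/% w
  kind <- rep(c(1L, 2L), c(config$n_units, config$n_obstacles))
  occ <- matrix(0L, nrow = w, ncol = h)
  occ[cbind(x + 1L, y + 1L)] <- kind
  new_lattice_state(w, h, occ, x, y, kind)
}

#' @export
print.lattice_state <- function(x, ...) {
  cat(sprintf("<lattice_state> %d x %d grid, %d units, %d obstacles, step %g\n",
              x$width, x$height, sum(x$kind == 1L), sum(x$kind == 2L), x$step))
  invisible(x)
}

#' @export
as.data.frame.lattice_state <- function(x, ...) {
  data.frame(step = x$step, id = seq_along(x$x),
             kind = c("unit", "obstacle")[x$kind],
             x = x$x, y = x$y)
}

#' Display a lattice state
#'
#' Units are drawn red, obstacles black, matching the usual rendering of
#' these simulations.
#'
#' @param x A `lattice_state`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.lattice_state <- function(x, ...) {
  image(seq_len(x$width) - 1L, seq_len(x$height) - 1L, x$occ,
        col = c("white", "red", "black"), breaks = c(-0.5, 0.5, 1.5, 2.5),
        xlab = "x", ylab = "y", useRaster = TRUE, asp = 1, ...)
  invisible(x)
}

#' Count unit-unit contacts around a lattice position
#'
#' Number of protein units among the (up to 4) von Neumann neighbours of
#' `(x, y)`; 0-based coordinates. The occupant of `(x, y)` itself is not
#' counted.
#'
#' @param state A `lattice_state`.
#' @param x,y 0-based position.
#' @param exclude Optional 0-based `c(x, y)` cell to ignore (used to
#'   exclude a mover's own origin when counting destination contacts).
#' @return Integer in 0..4.
#' @export
count_contacts <- function(state, x, y, exclude = NULL) {
  if (x < 0 || x >= state$width || y < 0 || y >= state$height)
    stop("position out of bounds")
  nx <- x + c(1L, -1L, 0L, 0L)
  ny <- y + c(0L, 0L, 1L, -1L)
  ok <- nx >= 0L & nx < state$width & ny >= 0L & ny < state$height
  if (!is.null(exclude))
    ok <- ok & !(nx == exclude[1] & ny == exclude[2])
  sum(state$occ[cbind(nx[ok] + 1L, ny[ok] + 1L)] == 1L)
}

#' Classify a proposed move
#'
#' Assigns the move class that determines its acceptance rate:
#' \describe{
#'   \item{`reflect_out_of_bounds`}{destination off the grid;}
#'   \item{`reflect_occupied`}{destination holds an obstacle, or holds a
#'     unit while the mover is an obstacle;}
#'   \item{`unit_exchange`}{unit moving onto a unit (exchange/vibration,
#'     treated as staying put);}
#'   \item{`obstacle_free`}{obstacle moving onto an empty square;}
#'   \item{`unit_free`}{unit moving onto an empty square losing no
#'     contacts;}
#'   \item{`unit_penalized`}{unit moving onto an empty square losing
#'     `n_lost > 0` contacts.}
#' }
#' `n_lost = max(0, contacts(origin) - contacts(destination excluding the
#' mover))`: moves that gain contacts are free.
#'
#' @param state A `lattice_state`.
#' @param origin,destination 0-based `c(x, y)`; destination must be a von
#'   Neumann neighbour of origin.
#' @return List with `origin`, `destination`, `move_class`, `n_lost`.
#' @export
classify_move <- function(state, origin, destination) {
  ox <- origin[1]; oy <- origin[2]
  dx <- destination[1]; dy <- destination[2]
  if (abs(dx - ox) + abs(dy - oy) != 1L)
    stop("destination must be a von Neumann neighbour of origin")
  mover <- state$occ[ox + 1L, oy + 1L]
  if (mover == 0L) stop("origin square is empty")
  out <- list(origin = c(ox, oy), destination = c(dx, dy), n_lost = 0L)
  if (dx < 0 || dx >= state$width || dy < 0 || dy >= state$height) {
    out$move_class <- "reflect_out_of_bounds"
    return(out)
  }
  dest <- state$occ[dx + 1L, dy + 1L]
  if (dest == 0L) {
    if (mover == 2L) {
      out$move_class <- "obstacle_free"
    } else {
      c_orig <- count_contacts(state, ox, oy)
      c_dest <- count_contacts(state, dx, dy, exclude = c(ox, oy))
      out$n_lost <- max(0L, c_orig - c_dest)
      out$move_class <- if (out$n_lost == 0L) "unit_free" else "unit_penalized"
    }
  } else if (mover == 1L && dest == 1L) {
    out$move_class <- "unit_exchange"
  } else {
    out$move_class <- "reflect_occupied"
  }
  out
}

# Direction table shared by the R step and the C++ kernel: index d in 0..3
# maps to (+x, -x, +y, -y).
.step_dx <- c(1L, -1L, 0L, 0L)
.step_dy <- c(0L, 0L, 1L, -1L)

#' Advance the simulation by one rejection-KMC step
#'
#' One iteration: pick a molecule uniformly from the whole population, pick
#' one of its 4 neighbour squares uniformly, classify the move, and (for
#' classes that carry a rate) accept it when `k > r` with `r` uniform on
#' `[0, 1)`. Exchange and reflection proposals leave the molecule in place
#' and consume no acceptance draw. This reference implementation in R is
#' draw-for-draw identical to the compiled loop used by [lattice_run()].
#'
#' @param state A `lattice_state`.
#' @param model A [rate_model()].
#' @return The updated `lattice_state` (step counter incremented).
#' @export
lattice_step <- function(state, model) {
  n <- length(state$x)
  i <- min(floor(runif(1) * n) + 1, n)
  d <- min(floor(runif(1) * 4) + 1, 4)
  origin <- c(state$x[i], state$y[i])
  destination <- origin + c(.step_dx[d], .step_dy[d])
  prop <- classify_move(state, origin, destination)
  if (prop$move_class %in% c("unit_free", "unit_penalized", "obstacle_free")) {
    k <- rate_for(model, prop)
    r <- runif(1)
    if (k > r) {
      state$occ[destination[1] + 1L, destination[2] + 1L] <- state$kind[i]
      state$occ[origin[1] + 1L, origin[2] + 1L] <- 0L
      state$x[i] <- destination[1]
      state$y[i] <- destination[2]
    }
  }
  state$step <- state$step + 1
  state
}

#' Run the simulator for many steps
#'
#' Executes `n_steps` rejection-KMC iterations in compiled code, optionally
#' recording cluster summaries (see [cluster_summary()]) or full position
#' snapshots every `record_every` steps and at the final step. Molecule
#' counts are conserved across the whole trajectory.
#'
#' @param state A `lattice_state`.
#' @param model A [rate_model()].
#' @param n_steps Number of iterations (>= 0).
#' @param record_every Steps between recorded frames; `NULL` records only
#'   the initial and final frames.
#' @param record `"summary"` (cluster statistics per frame, the default),
#'   `"snapshot"` (full position tables), or `"none"`.
#' @param min_size Minimum cluster size for summaries (see
#'   [summarize_clusters()]).
#' @param time_unit Steps per unit of reported time `t` (default `1e5`).
#' @return List with `state` (final), `summary` (data.frame of per-frame
#'   cluster statistics, if recorded), `snapshots` (list of data.frames, if
#'   recorded), and `counters` (proposed/accepted counts by move class,
#'   accumulated over the run).
#' @export
lattice_run <- function(state, model, n_steps,
                        record_every = NULL, record = "summary",
                        min_size = 6L, time_unit = 1e5) {
  stopifnot(inherits(state, "lattice_state"), n_steps >= 0)
  record <- match.arg(record, c("summary", "snapshot", "none"))
  n_steps <- as.numeric(n_steps)
  if (is.null(record_every) || record_every <= 0) record_every <- Inf

  counters <- matrix(0, nrow = 2, ncol = 6,
                     dimnames = list(c("proposed", "accepted"), move_classes))
  summaries <- list()
  snapshots <- list()
  record_frame <- function(st) {
    if (record == "summary") {
      summaries[[length(summaries) + 1L]] <<-
        cluster_summary(st, min_size = min_size, time_unit = time_unit)
    } else if (record == "snapshot") {
      snapshots[[length(snapshots) + 1L]] <<- as.data.frame(st)
    }
  }

  record_frame(state)
  done <- 0
  while (done < n_steps) {
    chunk <- min(record_every, n_steps - done)
    res <- kmc_run_cpp(state$occ, state$x, state$y, state$kind,
                       model$k1, model$k5, model$A, model$dE_over_theta,
                       chunk)
    state$occ <- res$occ
    state$x <- res$x
    state$y <- res$y
    state$step <- state$step + chunk
    counters["proposed", ] <- counters["proposed", ] + res$proposed
    counters["accepted", ] <- counters["accepted", ] + res$accepted
    done <- done + chunk
    record_frame(state)
  }

  out <- list(state = state, counters = counters)
  if (record == "summary")
    out$summary <- do.call(rbind, summaries)
  if (record == "snapshot")
    out$snapshots <- snapshots
  out
}

#' Expand the grid while keeping molecules in place
#'
#' Grows the lattice to `new_width x new_height`; molecules keep their
#' coordinates, the original block stays anchored at the origin corner and
#' the added rows/columns start empty. Shrinking is rejected because there
#' is no defined relocation rule for molecules outside the smaller grid.
#'
#' @param state A `lattice_state`.
#' @param new_width,new_height New dimensions (each >= current).
#' @return The expanded `lattice_state` (step counter unchanged).
#' @export
expand_lattice <- function(state, new_width, new_height) {
  new_width <- as.integer(new_width); new_height <- as.integer(new_height)
  if (new_width < state$width || new_height < state$height)
    stop("expand_lattice() cannot shrink the grid")
  occ <- matrix(0L, nrow = new_width, ncol = new_height)
  occ[seq_len(state$width), seq_len(state$height)] <- state$occ
  new_lattice_state(new_width, new_height, occ,
                    state$x, state$y, state$kind, state$step)
}

#' Read a simulator configuration from a YAML or JSON file
#'
#' The file holds any subset of [lattice_config()]'s fields by name;
#' unspecified fields take the defaults. `overrides` (e.g. parsed command
#' line values) take precedence over the file.
#'
#' @param file Path to a `.yaml`/`.yml` or `.json` file.
#' @param overrides Named list of field values overriding the file.
#' @return A `lattice_config`.
#' @export
read_lattice_config <- function(file, overrides = list()) {
  ext <- tolower(tools::file_ext(file))
  vals <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(file)
  } else if (ext == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("reading JSON configs requires the 'jsonlite' package")
    jsonlite::read_json(file, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: ", ext)
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(lattice_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(lattice_config, vals)
}

#' Write a position snapshot to CSV
#'
#' Long format, one row per molecule: `step, id, kind, x, y` with 0-based
#' coordinates (`x` = column, `y` = row).
#'
#' @param state A `lattice_state`.
#' @param file Output path.
#' @export
write_snapshot <- function(state, file) {
  write.csv(as.data.frame(state), file, row.names = FALSE)
  invisible(file)
}
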