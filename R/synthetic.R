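#' Ground truth for synthetic FRAP track tables
#'
#' Describes a simulated FRAP acquisition: a cohort of tracked condensates
#' inside and outside the bleach rectangle, a bleach of depth `d`, single
#' exponential recovery of the mobile fraction `m` with time constant
#' `tau`, a global acquisition quench `exp(-quench_rate * t)` affecting
#' every track, and multiplicative Gaussian intensity noise. Defaults
#' mirror a typical acquisition for fast-moving condensates: 5 Before
#' frames, 100 After frames at ~2.1 s interval, more than ten bleached
#' condensates, and an 80% bleach depth.
#'
#' The expected relative intensity of a bleached track at time `t` after
#' the bleach is `((1 - d) + m * d * (1 - exp(-t / tau)))`, all multiplied
#' by the quench factor; with recovery sampled for several time constants
#' the plateau of the FRAP-rate curve is `100 * m`.
#'
#' @param n_bleached,n_nonbleached Tracks inside / outside the bleach
#'   rectangle.
#' @param bleach_depth `d` in (0, 1): fractional intensity lost at the
#'   bleach.
#' @param mobile_fraction `m` in `[0, 1]`: fraction of the lost intensity
#'   that recovers.
#' @param tau Recovery time constant, seconds.
#' @param quench_rate Global photobleach rate `lambda`, 1/s.
#' @param noise_sd Relative intensity noise sd (0 for noiseless tables).
#' @param frame_interval Seconds between frames.
#' @param n_before_frames,n_after_frames Frames before/after the bleach.
#' @param bleach_rect `c(x_min, x_max, y_min, y_max)` px.
#' @param field `c(width, height)` px of the imaged field.
#' @param jitter_sd Per-frame Brownian position jitter sd, px.
#' @return A `frap_truth` list.
#' @export
frap_truth <- function(n_bleached = 12L, n_nonbleached = 20L,
                       bleach_depth = 0.8, mobile_fraction = 0.6,
                       tau = 30, quench_rate = 0.002, noise_sd = 0.05,
                       frame_interval = 2.1, n_before_frames = 5L,
                       n_after_frames = 100L,
                       bleach_rect = c(100, 200, 100, 200),
                       field = c(512, 512), jitter_sd = 0.5) {
  stopifnot(n_bleached >= 1L, n_nonbleached >= 1L,
            bleach_depth > 0, bleach_depth < 1,
            mobile_fraction >= 0, mobile_fraction <= 1,
            tau > 0, quench_rate >= 0, noise_sd >= 0,
            frame_interval > 0, n_before_frames >= 1L,
            n_after_frames >= 1L)
  structure(as.list(environment()), class = "frap_truth")
}

#' Generate a synthetic particle-tracking table
#'
#' Emits one row per track-point (`track_id, frame, time, x, y,
#' intensity`) following the model in [frap_truth()]: bleached tracks
#' start inside the bleach rectangle and non-bleached tracks outside, all
#' with Brownian positional jitter; recovery is measured from the first
#' After frame, whose expected relative intensity is exactly `1 - d`.
#' Track lengths always satisfy the pipeline's retention rules, so a
#' generated table passes [filter_tracks()] without exclusions.
#'
#' @param truth A [frap_truth()].
#' @param seed Optional integer seed.
#' @return List with `tracks` (data.frame) and `truth`.
#' @export
make_frap_tracks <- function(truth = frap_truth(), seed = NULL) {
  stopifnot(inherits(truth, "frap_truth"))
  if (!is.null(seed)) set.seed(seed)
  nf <- truth$n_before_frames + truth$n_after_frames
  frames <- seq_len(nf) - 1L
  times <- frames * truth$frame_interval
  t_bleach <- times[truth$n_before_frames + 1L]
  after <- frames >= truth$n_before_frames
  quench <- exp(-truth$quench_rate * times)
  r <- truth$bleach_rect

  start_inside <- function() {
    mx <- 0.1 * (r[2] - r[1]); my <- 0.1 * (r[4] - r[3])
    c(runif(1, r[1] + mx, r[2] - mx), runif(1, r[3] + my, r[4] - my))
  }
  start_outside <- function() {
    repeat {
      p <- c(runif(1, 0, truth$field[1]), runif(1, 0, truth$field[2]))
      pad <- 5 * truth$jitter_sd
      if (p[1] < r[1] - pad || p[1] > r[2] + pad ||
          p[2] < r[3] - pad || p[2] > r[4] + pad) return(p)
    }
  }

  one_track <- function(id, bleached) {
    p0 <- if (bleached) start_inside() else start_outside()
    x <- p0[1] + cumsum(c(0, rnorm(nf - 1L, sd = truth$jitter_sd)))
    y <- p0[2] + cumsum(c(0, rnorm(nf - 1L, sd = truth$jitter_sd)))
    rel <- rep(1, nf)
    if (bleached) {
      d <- truth$bleach_depth; m <- truth$mobile_fraction
      rel[after] <- (1 - d) +
        m * d * (1 - exp(-(times[after] - t_bleach) / truth$tau))
    }
    f0 <- runif(1, 100, 300)
    intensity <- f0 * (quench * rel + truth$noise_sd * rnorm(nf))
    data.frame(track_id = id, frame = frames, time = times,
               x = x, y = y, intensity = pmax(intensity, 0))
  }

  n_b <- truth$n_bleached; n_n <- truth$n_nonbleached
  tracks <- do.call(rbind, c(
    lapply(seq_len(n_b), function(i) one_track(i, TRUE)),
    lapply(seq_len(n_n), function(i) one_track(n_b + i, FALSE))))
  list(tracks = tracks, truth = truth)
}

#' Pipeline parameters matching a synthetic FRAP truth
#'
#' @param truth A [frap_truth()].
#' @return A [frap_params()] with the generator's bleach rectangle and
#'   Before-phase length.
#' @export
frap_params_for <- function(truth) {
  frap_params(bleach_rect = truth$bleach_rect,
              n_before_frames = truth$n_before_frames)
}

#' Generate a synthetic spot image with known ground truth
#'
#' Gaussian spots of known centers, width and amplitude on a noisy
#' constant background; the ground truth (spot table and count) is
#' returned alongside the image for test assertions. Spot centers are
#' rejection-sampled to honour a minimum separation; if that fails the
#' remaining spots are placed unconstrained with a warning, since
#' overlapping spots are no longer guaranteed to be separable by the
#' detector.
#'
#' @param n_spots Number of planted spots.
#' @param dim Image dimensions `c(nx, ny)` px.
#' @param amplitude Peak spot amplitude above background (scalar or per
#'   spot).
#' @param spot_sigma Gaussian spot sigma, px.
#' @param background Constant background level.
#' @param noise_sd Additive Gaussian noise sd.
#' @param min_sep Minimum center-to-center separation, px.
#' @param margin Margin to the image border, px.
#' @param mask Optional logical matrix (default: whole frame).
#' @param seed Optional integer seed.
#' @return List with `image`, `mask`, `truth` (list: `spots` data.frame
#'   with `x`, `y`, `sigma`, `amplitude`; `n_spots`, `background`,
#'   `noise_sd`).
#' @export
make_spot_image <- function(n_spots = 7L, dim = c(128L, 128L),
                            amplitude = 1, spot_sigma = 2,
                            background = 0.1, noise_sd = 0.01,
                            min_sep = 6 * spot_sigma,
                            margin = 4 * spot_sigma,
                            mask = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_spots >= 0L, all(dim >= 8L), noise_sd >= 0)
  amplitude <- rep_len(amplitude, max(n_spots, 1L))
  cx <- cy <- numeric(0)
  tries <- 0L
  while (length(cx) < n_spots && tries < 2000L) {
    tries <- tries + 1L
    px <- runif(1, margin, dim[1] - margin)
    py <- runif(1, margin, dim[2] - margin)
    if (!length(cx) || all((cx - px)^2 + (cy - py)^2 >= min_sep^2)) {
      cx <- c(cx, px); cy <- c(cy, py)
    }
  }
  if (length(cx) < n_spots) {
    warning("could not honour minimum spot separation; ",
            "placing remaining spots unconstrained")
    extra <- n_spots - length(cx)
    cx <- c(cx, runif(extra, margin, dim[1] - margin))
    cy <- c(cy, runif(extra, margin, dim[2] - margin))
  }
  xg <- matrix(seq_len(dim[1]), dim[1], dim[2])
  yg <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  img <- matrix(background, dim[1], dim[2])
  for (i in seq_len(n_spots)) {
    img <- img + amplitude[i] *
      exp(-((xg - cx[i])^2 + (yg - cy[i])^2) / (2 * spot_sigma^2))
  }
  if (noise_sd > 0)
    img <- img + matrix(rnorm(prod(dim), sd = noise_sd), dim[1], dim[2])
  if (is.null(mask)) mask <- matrix(TRUE, dim[1], dim[2])
  truth <- list(spots = data.frame(x = cx, y = cy,
                                   sigma = rep(spot_sigma, n_spots),
                                   amplitude = amplitude[seq_len(n_spots)]),
                n_spots = as.integer(n_spots), background = background,
                noise_sd = noise_sd)
  list(image = img, mask = mask, truth = truth)
}

#' Build a hand-specified lattice state
#'
#' Deterministic fixture builder for unit tests of cluster detection and
#' move classification: place protein units and obstacles at explicit
#' 0-based coordinates.
#'
#' @param width,height Grid dimensions.
#' @param units,obstacles Two-column matrices (or data.frames) of 0-based
#'   `(x, y)` coordinates; overlapping or out-of-bounds placements are an
#'   error.
#' @return A `lattice_state` at step 0.
#' @export
make_lattice_fixture <- function(width, height, units = NULL,
                                 obstacles = NULL) {
  coords <- function(m) {
    if (is.null(m)) return(matrix(integer(0), ncol = 2))
    m <- as.matrix(m); storage.mode(m) <- "integer"
    stopifnot(ncol(m) == 2)
    m
  }
  u <- coords(units); o <- coords(obstacles)
  all_xy <- rbind(u, o)
  if (nrow(all_xy)) {
    if (any(all_xy[, 1] < 0 | all_xy[, 1] >= width |
            all_xy[, 2] < 0 | all_xy[, 2] >= height))
      stop("placement out of bounds")
    if (anyDuplicated(all_xy)) stop("overlapping placements")
  }
  occ <- matrix(0L, width, height)
  if (nrow(u)) occ[u + 1L] <- 1L
  if (nrow(o)) occ[o + 1L] <- 2L
  kind <- rep(c(1L, 2L), c(nrow(u), nrow(o)))
  new_lattice_state(width, height, occ, all_xy[, 1], all_xy[, 2], kind)
}
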