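#' Parameters of the FRAP quantification pipeline
#'
#' The assay design: a cell is imaged for `n_before_frames` frames
#' ("Before"), a rectangular region containing many condensates is
#' photobleached, and imaging continues ("After"). Condensates are tracked
#' by an external spot tracker and handed to this pipeline as a long-format
#' table; the pipeline classifies tracks by the bleach rectangle, filters
#' unusable tracks, corrects the acquisition photobleach (quench) against
#' the non-bleached group, and converts the pooled bleached-group signal to
#' a FRAP-rate curve in percent.
#'
#' @param bleach_rect Numeric `c(x_min, x_max, y_min, y_max)` in pixels;
#'   closed bounds.
#' @param n_before_frames Number of pre-bleach frames (frame indices
#'   `0 .. n_before_frames - 1` are "Before").
#' @param min_track_frames Minimum total frames for a track to be kept.
#' @param fp_drop_threshold Minimum fractional intensity decrease between
#'   Before and After for a bleached-group track to be considered truly
#'   photobleached (default 0.15: tracks dropping less than 15% are
#'   discarded as false positives).
#' @return A `frap_params` list.
#' @export
frap_params <- function(bleach_rect, n_before_frames = 5L,
                        min_track_frames = 25L, fp_drop_threshold = 0.15) {
  stopifnot(length(bleach_rect) == 4L,
            bleach_rect[2] > bleach_rect[1], bleach_rect[4] > bleach_rect[3],
            n_before_frames >= 1L, min_track_frames >= 1L,
            fp_drop_threshold >= 0, fp_drop_threshold < 1)
  structure(list(bleach_rect = as.numeric(bleach_rect),
                 n_before_frames = as.integer(n_before_frames),
                 min_track_frames = as.integer(min_track_frames),
                 fp_drop_threshold = fp_drop_threshold),
            class = "frap_params")
}

#' Read a particle-tracking table
#'
#' Reads a delimiter-separated spot-tracker export (e.g. a TrackMate spot
#' table) into the long format the pipeline expects: one row per
#' track-point with columns `track_id`, `frame`, `time`, `x`, `y`,
#' `intensity`.
#'
#' @param file Path to a CSV/TSV file.
#' @param col_map Named character vector mapping the six canonical names
#'   to the file's column names.
#' @param sep Field separator.
#' @return A data.frame with the canonical columns.
#' @export
read_tracks <- function(file,
                        col_map = c(track_id = "TRACK_ID", frame = "FRAME",
                                    time = "POSITION_T", x = "POSITION_X",
                                    y = "POSITION_Y",
                                    intensity = "MEAN_INTENSITY"),
                        sep = ",") {
  raw <- read.csv(file, sep = sep, check.names = FALSE)
  missing <- setdiff(unname(col_map), names(raw))
  if (length(missing))
    stop("columns not found in track file: ", paste(missing, collapse = ", "))
  out <- raw[, unname(col_map)]
  names(out) <- names(col_map)
  validate_tracks(out)
}

validate_tracks <- function(tracks) {
  needed <- c("track_id", "frame", "time", "x", "y", "intensity")
  stopifnot(all(needed %in% names(tracks)))
  if (nrow(tracks) == 0L) stop("empty track table")
  if (any(tracks$frame < 0)) stop("negative frame indices")
  if (any(tracks$intensity < 0)) stop("negative intensities")
  ord <- order(tracks$track_id, tracks$frame)
  tracks <- tracks[ord, , drop = FALSE]
  dup <- ave(tracks$frame, tracks$track_id,
             FUN = function(f) c(1, diff(f)))
  if (any(dup <= 0)) stop("frames must be strictly increasing within a track")
  rownames(tracks) <- NULL
  tracks
}

is_before <- function(tracks, params) tracks$frame < params$n_before_frames

#' Filter tracks usable for FRAP quantification
#'
#' A track is retained iff it has at least one Before frame, at least one
#' After frame (i.e. it was successfully tracked across the bleach), and
#' at least `min_track_frames` frames in total.
#'
#' @param tracks Long-format track table (see [read_tracks()]).
#' @param params A [frap_params()].
#' @return List with `tracks` (retained rows) and `log` (data.frame
#'   `track_id`, `reason` for each excluded track).
#' @export
filter_tracks <- function(tracks, params) {
  tracks <- validate_tracks(tracks)
  before <- is_before(tracks, params)
  per <- split(seq_len(nrow(tracks)), tracks$track_id)
  reasons <- vapply(per, function(i) {
    nb <- sum(before[i]); na <- length(i) - nb
    if (nb == 0L) "no_before"
    else if (na == 0L) "no_after"
    else if (length(i) < params$min_track_frames) "short"
    else ""
  }, character(1))
  bad <- reasons[reasons != ""]
  log <- data.frame(track_id = names(bad), reason = unname(bad))
  keep_ids <- names(reasons)[reasons == ""]
  list(tracks = tracks[tracks$track_id %in% keep_ids, , drop = FALSE],
       log = log)
}

#' Classify tracks as photobleached or not
#'
#' A track belongs to the bleached group iff its mean position over the
#' Before frames lies inside the bleach rectangle (closed bounds; a mean
#' position exactly on the boundary counts as bleached). The Before-phase
#' mean is used rather than a single frame for robustness to localization
#' jitter.
#'
#' @inheritParams filter_tracks
#' @return `tracks` with an added `group` column
#'   (`"bleached"`/`"nonbleached"`).
#' @export
classify_bleached <- function(tracks, params) {
  r <- params$bleach_rect
  before <- is_before(tracks, params)
  if (!any(before)) stop("no Before frames in table")
  mx <- tapply(tracks$x[before], tracks$track_id[before], mean)
  my <- tapply(tracks$y[before], tracks$track_id[before], mean)
  inside <- mx >= r[1] & mx <= r[2] & my >= r[3] & my <= r[4]
  grp <- ifelse(inside, "bleached", "nonbleached")
  tracks$group <- as.character(grp[as.character(tracks$track_id)])
  tracks
}

#' Relative fluorescence change per track
#'
#' Divides every intensity of a track by that track's mean intensity over
#' its Before frames, yielding the relative change `F_i(t) / F_i,Before`.
#'
#' @inheritParams filter_tracks
#' @return `tracks` with an added `rel` column.
#' @export
relative_change <- function(tracks, params) {
  before <- is_before(tracks, params)
  fb <- tapply(tracks$intensity[before], tracks$track_id[before], mean)
  if (any(is.na(fb)) || any(fb <= 0))
    stop("every track needs a positive Before-phase mean intensity")
  tracks$rel <- tracks$intensity /
    as.numeric(fb[as.character(tracks$track_id)])
  tracks
}

#' Drop false-positive bleached tracks
#'
#' A track assigned to the bleached group by geometry but whose relative
#' intensity did not drop by at least `fp_drop_threshold` (mean over its
#' first three After frames above `1 - fp_drop_threshold`) is discarded:
#' it was most likely mis-tracked or shielded from the bleach. A drop of
#' exactly the threshold is retained.
#'
#' @param tracks Track table with `group` and `rel` columns (see
#'   [classify_bleached()], [relative_change()]).
#' @param params A [frap_params()].
#' @return List with `tracks` and `log` (dropped track ids with reason
#'   `"false_positive"`).
#' @export
drop_false_positives <- function(tracks, params) {
  after <- !is_before(tracks, params) & tracks$group == "bleached"
  sub <- tracks[after, , drop = FALSE]
  sub <- sub[order(sub$track_id, sub$frame), , drop = FALSE]
  early <- do.call(rbind, lapply(split(sub, sub$track_id),
                                 function(d) head(d, 3L)))
  m <- tapply(early$rel, early$track_id, mean)
  fp <- names(m)[m > 1 - params$fp_drop_threshold]
  log <- data.frame(track_id = fp,
                    reason = rep("false_positive", length(fp)))
  list(tracks = tracks[!(tracks$track_id %in% fp), , drop = FALSE],
       log = log)
}

#' Quench correction against the non-bleached group
#'
#' Divides each bleached track's relative change at time `t` by the mean
#' relative change of the non-bleached group at the same time point,
#' removing the global acquisition photobleach (quench):
#' `G_i(t) = (F_i(t)/F_i,Before) / mean_j(F_j(t)/F_j,Before)`. Time points
#' with no non-bleached coverage are dropped and logged.
#'
#' @inheritParams drop_false_positives
#' @return List with `tracks` (bleached rows with an added `G` column)
#'   and `dropped_times` (times lacking non-bleached coverage).
#' @export
quench_correct <- function(tracks, params) {
  nb <- tracks[tracks$group == "nonbleached", , drop = FALSE]
  bl <- tracks[tracks$group == "bleached", , drop = FALSE]
  if (nrow(nb) == 0L) stop("no nonbleached tracks: cannot quench-correct")
  if (nrow(bl) == 0L) stop("no bleached tracks retained")
  # group by the numeric time values themselves (no character round-trip)
  nb_times <- sort(unique(nb$time))
  nb_mean <- vapply(split(nb$rel, match(nb$time, nb_times)), mean,
                    numeric(1))
  denom <- nb_mean[match(bl$time, nb_times)]
  dropped <- sort(unique(bl$time[is.na(denom)]))
  bl$G <- bl$rel / denom
  bl <- bl[!is.na(bl$G), , drop = FALSE]
  list(tracks = bl, dropped_times = dropped)
}

#' FRAP-rate curve from quench-corrected tracks
#'
#' Pools the bleached group into one virtual condensate:
#' `G(t)` is the mean of `G_i(t)` over bleached tracks available at `t`,
#' `G_Min` the minimum of `G(t)` over the first three After time points,
#' and `FRAP rate [%] (t) = (G(t) - G_Min) / (1 - G_Min) * 100`, so the
#' curve is 0 at the bleach floor and 100 at full recovery.
#'
#' @param corrected Bleached-track table with a `G` column (see
#'   [quench_correct()]).
#' @param params A [frap_params()].
#' @return List with `curve` (data.frame `time`, `frame`, `n_tracks`,
#'   `G`, `frap_rate`; After time points only for `frap_rate`) and
#'   `g_min`.
#' @export
frap_rate_curve <- function(corrected, params) {
  after <- corrected[!is_before(corrected, params), , drop = FALSE]
  if (nrow(after) == 0L) stop("no After time points in bleached group")
  times <- sort(unique(after$time))
  grp <- match(after$time, times)
  G <- vapply(split(after$G, grp), mean, numeric(1))
  n_tr <- vapply(split(after$G, grp), length, integer(1))
  frame <- vapply(split(after$frame, grp), min, numeric(1))
  g_min <- min(G[seq_len(min(3L, length(G)))])
  if (1 - g_min <= 0) {
    warning("G_Min >= 1: no detectable bleach depth, FRAP rate undefined")
    rate <- rep(NA_real_, length(G))
  } else {
    rate <- (G - g_min) / (1 - g_min) * 100
  }
  list(curve = data.frame(time = times, frame = frame, n_tracks = n_tr,
                          G = G, frap_rate = rate),
       g_min = g_min)
}

#' Full FRAP quantification of one cell
#'
#' Runs the whole pipeline on a raw track table: validity filtering,
#' bleached/non-bleached classification, per-track relative change,
#' false-positive removal, quench correction and FRAP-rate conversion.
#'
#' @param tracks Long-format track table (see [read_tracks()]).
#' @param params A [frap_params()].
#' @return A `frap_result` list: `curve` (time, G, frap_rate), `g_min`,
#'   `n_bleached`, `n_nonbleached`, `exclusions` (combined log),
#'   `dropped_times`, and the annotated `tracks`.
#' @export
frap_quantify <- function(tracks, params) {
  flt <- filter_tracks(tracks, params)
  tr <- classify_bleached(flt$tracks, params)
  tr <- relative_change(tr, params)
  fp <- drop_false_positives(tr, params)
  qc <- quench_correct(fp$tracks, params)
  rc <- frap_rate_curve(qc$tracks, params)
  keep <- fp$tracks
  structure(list(curve = rc$curve, g_min = rc$g_min,
                 n_bleached = length(unique(keep$track_id[keep$group == "bleached"])),
                 n_nonbleached = length(unique(keep$track_id[keep$group == "nonbleached"])),
                 exclusions = rbind(flt$log, fp$log),
                 dropped_times = qc$dropped_times,
                 tracks = keep),
            class = "frap_result")
}

#' @export
print.frap_result <- function(x, ...) {
  cat(sprintf(
    "<frap_result> %d bleached / %d nonbleached tracks, G_min = %.3f, final FRAP rate = %.1f%%\n",
    x$n_bleached, x$n_nonbleached, x$g_min,
    tail(x$curve$frap_rate, 1)))
  invisible(x)
}

#' Plateau FRAP rate of a quantified cell
#'
#' Mean FRAP rate over the last `n_points` time points; with
#' single-exponential recovery sampled well past its time constant this
#' estimates 100 x the mobile fraction.
#'
#' @param result A [frap_quantify()] result.
#' @param n_points Number of trailing time points to average.
#' @return Plateau FRAP rate in percent.
#' @export
frap_plateau <- function(result, n_points = 10L) {
  mean(tail(result$curve$frap_rate, n_points))
}

#' Remove outlier cells from a cohort of FRAP curves
#'
#' Applies the extreme-outlier rule ([trim_extreme()]) to the cells'
#' final-time FRAP rates and retains the surviving cells.
#'
#' @param results List of [frap_quantify()] results (>= 4 for the trim to
#'   be applied).
#' @param k IQR multiplier.
#' @return List with `results` (retained), `keep`, `final_rates`,
#'   `bounds`.
#' @export
trim_outlier_cells <- function(results, k = 5) {
  finals <- vapply(results, function(r) tail(r$curve$frap_rate, 1),
                   numeric(1))
  tr <- trim_extreme(finals, k = k)
  list(results = results[tr$keep], keep = tr$keep,
       final_rates = finals, bounds = tr$bounds)
}
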