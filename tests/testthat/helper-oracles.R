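# Independent oracles used by the tests. These are deliberately written
# with different algorithms from the package implementation.

# Recursive flood fill over unit squares (occ == 1), 4-connectivity.
flood_fill_labels <- function(occ) {
  w <- nrow(occ); h <- ncol(occ)
  lab <- matrix(0L, w, h)
  cur <- 0L
  fill <- function(i, j) {
    if (i < 1L || i > w || j < 1L || j > h) return(invisible())
    if (occ[i, j] != 1L || lab[i, j] != 0L) return(invisible())
    lab[i, j] <<- cur
    fill(i + 1L, j); fill(i - 1L, j); fill(i, j + 1L); fill(i, j - 1L)
    invisible()
  }
  for (j in seq_len(h)) for (i in seq_len(w)) {
    if (occ[i, j] == 1L && lab[i, j] == 0L) {
      cur <- cur + 1L
      fill(i, j)
    }
  }
  lab
}

# Component size multiset from a label matrix, sorted.
sizes_of <- function(lab) sort(tabulate(lab[lab > 0L]))

# Random occupancy matrix with given molecule densities.
random_occ <- function(w, h, p_unit = 0.25, p_obstacle = 0.1) {
  occ <- matrix(sample(c(0L, 1L, 2L), w * h, replace = TRUE,
                       prob = c(1 - p_unit - p_obstacle, p_unit, p_obstacle)),
                w, h)
  occ
}

# Closed-form FRAP-rate of a single-exponential recovery measured from the
# first post-bleach time point.
closed_form_frap <- function(times, t_bleach, mobile_fraction, tau) {
  100 * mobile_fraction * (1 - exp(-(times - t_bleach) / tau))
}

# Minimal synthetic track row builder.
track_rows <- function(id, frames, intensity, x = 0, y = 0,
                       interval = 1) {
  data.frame(track_id = id, frame = frames, time = frames * interval,
             x = x, y = y, intensity = intensity)
}
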