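# Replace index windows [a, b] of x by the straight line joining x[a]
# and x[b]. Windows are merged if they overlap.
interp_windows <- function(x, starts, ends) {
  if (length(starts) == 0) return(x)
  o <- order(starts)
  starts <- pmax(starts[o], 1L)
  ends <- pmin(ends[o], length(x))
  # merge overlapping windows
  ms <- starts[1]
  me <- ends[1]
  merged_s <- integer(0)
  merged_e <- integer(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me) {
      me <- max(me, ends[i])
    } else {
      merged_s <- c(merged_s, ms)
      merged_e <- c(merged_e, me)
      ms <- starts[i]
      me <- ends[i]
    }
  }
  merged_s <- c(merged_s, ms)
  merged_e <- c(merged_e, me)
  for (i in seq_along(merged_s)) {
    a <- merged_s[i]
    b <- merged_e[i]
    x[a:b] <- seq(x[a], x[b], length.out = b - a + 1)
  }
  x
}

#' Pseudo-generator potential: excise action potentials
#'
#' Replaces a window around every detected spike (default 1 ms before to
#' 5 ms after the threshold crossing, i.e. a 6 ms footprint covering the
#' maximum action-potential width) with a straight line joining the
#' voltages at the window edges. Overlapping windows are merged. The
#' result approximates the generator potential that drove the spikes.
#'
#' @param v voltage samples (mV) or a `simulation_result`
#' @param dt sample interval (s); taken from the result if one is given
#' @param spikes spike times (s); detected with defaults when `NULL`
#' @param width total window width (ms)
#' @param pre portion of the window ahead of the crossing (ms)
#' @return numeric voltage vector with spikes excised
#' @export
pseudo_generator <- function(v, dt = NULL, spikes = NULL, width = 6,
                             pre = 1) {
  if (inherits(v, "simulation_result")) {
    dt <- v$dt
    v <- v$v
  }
  stopifnot(!is.null(dt), width > 0, pre >= 0, pre <= width)
  if (is.null(spikes)) spikes <- detect_spikes(v, dt)
  if (length(spikes) == 0) return(v)
  starts <- round((spikes - pre / 1000) / dt) + 1L
  ends <- starts + round(width / 1000 / dt)
  interp_windows(v, starts, ends)
}

#' Footprint insertion plan
#'
#' Describes how artificial action-potential footprints (6 ms linear
#' interpolations) are placed into graded responses: `deterministic`
#' (identical positions in every trial), `jittered` (shared base
#' positions plus per-trial, per-window uniform jitter), or `random`
#' (independent admissible positions per trial). Base positions always
#' have pairwise start gaps of at least `min_gap` ms; after jitter the
#' windows are re-checked for overlap and violating jitters resampled.
#'
#' @param scheme `"deterministic"`, `"jittered"` or `"random"`
#' @param n_per_second number of footprints per second (10-80)
#' @param width footprint width (ms)
#' @param min_gap minimum start-to-start gap for base positions (ms)
#' @param jitter_max maximum absolute jitter (ms)
#' @param seed RNG seed
#' @return a `footprint_plan` list
#' @export
footprint_plan <- function(scheme = c("deterministic", "jittered", "random"),
                           n_per_second = 10, width = 6, min_gap = 10,
                           jitter_max = 4, seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(n_per_second >= 1, width > 0, min_gap >= width, jitter_max >= 0)
  structure(
    list(scheme = scheme, n_per_second = as.integer(n_per_second),
         width = width, min_gap = min_gap, jitter_max = jitter_max,
         seed = as.integer(seed)),
    class = "footprint_plan"
  )
}

# Uniform sample of n ordered starts in [0, t_max] with pairwise gaps
# >= gap: shift a sorted uniform sample of the free space.
sample_admissible_starts <- function(n, t_max, gap) {
  free <- t_max - (n - 1) * gap
  if (free < 0) stop("infeasible footprint packing", call. = FALSE)
  sort(stats::runif(n, 0, free)) + (seq_len(n) - 1) * gap
}

jitter_starts <- function(base, jitter_max, width, t_max, max_iter = 200) {
  n <- length(base)
  jit <- stats::runif(n, -jitter_max, jitter_max)
  for (i in seq_len(max_iter)) {
    s <- pmin(pmax(base + jit, 0), t_max)
    ok <- c(diff(sort(s)) >= width, TRUE)
    if (all(ok)) return(sort(s))
    bad <- which(!ok[order(order(s))])
    jit[bad] <- stats::runif(length(bad), -jitter_max, jitter_max)
    jitter_max <- jitter_max * 0.95  # shrink to guarantee termination
  }
  base
}

#' Insert action-potential footprints into traces
#'
#' Replaces `width`-ms windows of each trace by edge-to-edge linear
#' interpolations, placed according to the plan's scheme. Returns the
#' modified traces together with the per-trial window start times so the
#' identical windows can be applied to the stimulus.
#'
#' @param traces list of numeric vectors or a samples x trials matrix
#' @param plan a [footprint_plan()]
#' @param dt sample interval (s)
#' @return list: `traces` (matrix, samples x trials), `positions` (list of
#'   per-trial start times, ms), `plan`
#' @export
insert_footprints <- function(traces, plan, dt) {
  m <- as_trial_matrix(traces)
  n <- nrow(m)
  duration_ms <- n * dt * 1000
  n_windows <- round(plan$n_per_second * n * dt)
  t_max <- duration_ms - plan$width
  if (n_windows * plan$min_gap >= duration_ms) {
    stop("infeasible footprint packing", call. = FALSE)
  }
  width_idx <- round(plan$width / 1000 / dt)

  positions <- with_seed(plan$seed, {
    switch(plan$scheme,
      deterministic = {
        base <- sample_admissible_starts(n_windows, t_max, plan$min_gap)
        replicate(ncol(m), base, simplify = FALSE)
      },
      jittered = {
        # one jitter draw shared by all trials: windows land at irregular
        # but trial-identical positions (reliable, low-noise spiking);
        # per-trial jitter would add trial-to-trial noise that the
        # signal/noise decomposition counts against the SNR
        base <- sample_admissible_starts(n_windows, t_max, plan$min_gap)
        jit <- jitter_starts(base, plan$jitter_max, plan$width, t_max)
        replicate(ncol(m), jit, simplify = FALSE)
      },
      random = lapply(seq_len(ncol(m)), function(i) {
        sample_admissible_starts(n_windows, t_max, plan$min_gap)
      })
    )
  })

  for (j in seq_len(ncol(m))) {
    starts <- round(positions[[j]] / 1000 / dt) + 1L
    m[, j] <- interp_windows(m[, j], starts, starts + width_idx)
  }
  list(traces = m, positions = positions, plan = plan)
}

#' Apply footprint windows to a stimulus
#'
#' Linearly interpolates the same windows (per-trial positions from
#' [insert_footprints()]) in the stimulus traces, for matched
#' stimulus/response interpolation experiments.
#'
#' @param stimuli list of [current_trace()] / numeric vectors or a matrix
#' @param positions list of per-trial window start times (ms)
#' @param width window width (ms)
#' @param dt sample interval (s)
#' @return matrix (samples x trials) of interpolated stimuli
#' @export
interpolate_stimulus <- function(stimuli, positions, width = 6, dt = 1e-5) {
  m <- as_trial_matrix(stimuli)
  stopifnot(length(positions) == ncol(m))
  width_idx <- round(width / 1000 / dt)
  for (j in seq_len(ncol(m))) {
    starts <- round(positions[[j]] / 1000 / dt) + 1L
    m[, j] <- interp_windows(m[, j], starts, starts + width_idx)
  }
  m
}
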