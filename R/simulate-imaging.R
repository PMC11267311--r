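#' Validate and class an SWC-style skeleton table
#'
#' @param df data frame with columns `id, type, x, y, z, radius, parent`
#'   (parent `-1` marks the root soma node).
#' @return the validated data frame with class `skeleton`.
#' @export
as_skeleton <- function(df) {
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  stopifnot(is.data.frame(df), all(need %in% names(df)))
  df <- df[, need]
  if (anyDuplicated(df$id)) stop("duplicate node ids")
  roots <- which(df$parent == -1)
  if (length(roots) != 1) stop("skeleton must have exactly one root soma node")
  if (!all(is.finite(as.matrix(df[, c("x", "y", "z")]))))
    stop("coordinates must be finite")
  pidx <- match(df$parent, df$id)
  if (anyNA(pidx[-roots])) stop("orphan node: parent id not found")
  # walk to root from every node; a cycle never reaches the root
  for (i in seq_len(nrow(df))) {
    j <- i; steps <- 0
    while (df$parent[j] != -1) {
      j <- pidx[j]; steps <- steps + 1
      if (steps > nrow(df)) stop("cycle detected in skeleton")
    }
  }
  class(df) <- c("skeleton", "data.frame")
  df
}

#' Configuration for the synthetic astrocyte skeleton generator
#'
#' Trees grow outward from a soma: `n_primary` primary branches leave the
#' soma, and each tip bifurcates at every subsequent depth level up to
#' `branching_depth`, so a cell has `n_primary * 2^(branching_depth - 1)`
#' terminal branches.
#'
#' @param n_primary primary branches (>= 1).
#' @param branching_depth levels of growth (1 = unbranched primaries).
#' @param segment_length nominal segment length, um.
#' @param jitter s.d. of Gaussian positional jitter per coordinate, um.
#' @param soma_radius soma node radius, um.
#' @param seed RNG seed.
#' @return a `skeleton_config` list.
#' @export
skeleton_config <- function(n_primary = 5, branching_depth = 3,
                            segment_length = 20, jitter = 2,
                            soma_radius = 5, seed = 1L) {
  stopifnot(n_primary >= 1, branching_depth >= 1, segment_length > 0,
            jitter >= 0, soma_radius > 0)
  structure(list(n_primary = n_primary, branching_depth = branching_depth,
                 segment_length = segment_length, jitter = jitter,
                 soma_radius = soma_radius, seed = as.integer(seed)),
            class = "skeleton_config")
}

# unit vector, optionally biased toward `toward`
runit <- function(toward = NULL, spread = 1) {
  v <- stats::rnorm(3)
  if (!is.null(toward)) v <- toward / sqrt(sum(toward^2)) + spread * v
  v / sqrt(sum(v^2))
}

#' Simulate an astrocyte skeleton with known branch statistics
#'
#' @param config a [skeleton_config()].
#' @return list with `skeleton` (an [as_skeleton()] data frame) and `truth`
#'   (list: `total_length` um, `n_primary`, `n_terminal`, `soma_area` um^2).
#'   Total length is recorded by an edge walk over the generated
#'   coordinates, so it accounts for jitter.
#' @export
simulate_skeleton <- function(config) {
  stopifnot(inherits(config, "skeleton_config"))
  with_seed(config$seed, {
    nodes <- data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                        radius = config$soma_radius, parent = -1L)
    nid <- 1L
    add_node <- function(parent_id, pos) {
      nid <<- nid + 1L
      nodes[nrow(nodes) + 1L, ] <<- list(nid, 3L, pos[1], pos[2], pos[3],
                                         1, parent_id)
      nid
    }
    # tips: list of (id, position, direction)
    tips <- lapply(seq_len(config$n_primary), function(k) {
      d <- runit()
      pos <- d * config$segment_length + stats::rnorm(3, 0, config$jitter)
      list(id = add_node(1L, pos), pos = pos, dir = d)
    })
    depth <- 1L
    while (depth < config$branching_depth) {
      tips <- do.call(c, lapply(tips, function(tp) {
        lapply(1:2, function(.) {
          d <- runit(toward = tp$dir, spread = 0.4)
          pos <- tp$pos + d * config$segment_length +
            stats::rnorm(3, 0, config$jitter)
          list(id = add_node(tp$id, pos), pos = pos, dir = d)
        })
      }))
      depth <- depth + 1L
    }
    sk <- as_skeleton(nodes)
    pidx <- match(sk$parent, sk$id)
    seg <- which(sk$parent != -1)
    elen <- sqrt((sk$x[seg] - sk$x[pidx[seg]])^2 +
                 (sk$y[seg] - sk$y[pidx[seg]])^2 +
                 (sk$z[seg] - sk$z[pidx[seg]])^2)
    list(skeleton = sk,
         truth = list(total_length = sum(elen),
                      n_primary = config$n_primary,
                      n_terminal = config$n_primary *
                        2^(config$branching_depth - 1L),
                      soma_area = pi * config$soma_radius^2))
  })
}

#' Simulate neurite evidence points along a skeleton
#'
#' Discretizes the skeleton into sub-segments, selects a random subset
#' covering (as nearly as the discretization allows) `coverage_fraction` of
#' the total length, and drops one point near each selected midpoint, at
#' most `offset` um away. The realized covered fraction is returned as
#' ground truth for colocalization scoring.
#'
#' @param skeleton an [as_skeleton()] data frame.
#' @param coverage_fraction target fraction of skeleton length covered,
#'   in `[0, 1]`.
#' @param offset maximum displacement of each point from the fiber, um.
#' @param seed RNG seed.
#' @param step discretization step, um.
#' @return list with `points` (data frame x, y, z; zero rows when coverage
#'   is 0) and `truth_fraction` (realized covered length fraction).
#' @export
simulate_neurite_points <- function(skeleton, coverage_fraction, offset = 0,
                                    seed = 1L, step = 0.5) {
  stopifnot(inherits(skeleton, "skeleton"),
            coverage_fraction >= 0, coverage_fraction <= 1, offset >= 0)
  segs <- discretize_skeleton(skeleton, step = step)
  with_seed(as.integer(seed), {
    total <- sum(segs$len)
    if (coverage_fraction == 0 || nrow(segs) == 0)
      return(list(points = data.frame(x = numeric(), y = numeric(),
                                      z = numeric()),
                  truth_fraction = 0))
    ord <- sample.int(nrow(segs))
    cum <- cumsum(segs$len[ord])
    take <- ord[seq_len(which(cum >= coverage_fraction * total - 1e-9)[1])]
    pts <- segs[take, c("mx", "my", "mz")]
    if (offset > 0) {
      d <- t(vapply(seq_len(nrow(pts)), function(i) runit(), numeric(3)))
      pts <- pts + d * stats::runif(nrow(pts), 0, offset)
    }
    names(pts) <- c("x", "y", "z")
    rownames(pts) <- NULL
    list(points = pts, truth_fraction = sum(segs$len[take]) / total)
  })
}

#' Configuration for the stimulus-locked calcium trace simulator
#'
#' Fluorescence sits at `baseline_f` before the stimulus, then ramps
#' linearly to `baseline_f * (1 + amplitude_fraction)` over `rise_time`
#' seconds, with Gaussian noise throughout.
#'
#' @param dt sampling interval, s.
#' @param duration recording length, s.
#' @param stimulus_time stimulus onset, s (0 < stimulus_time < duration).
#' @param baseline_f baseline fluorescence, a.u. (> 0).
#' @param amplitude_fraction planted peak dF/F0 (dimensionless).
#' @param rise_time ramp duration, s (0 = instantaneous step).
#' @param noise_sd Gaussian noise s.d., a.u.
#' @param seed RNG seed.
#' @return a `trace_config` list.
#' @export
trace_config <- function(dt = 0.1, duration = 60, stimulus_time = 10,
                         baseline_f = 100, amplitude_fraction = 0.5,
                         rise_time = 2, noise_sd = 0, seed = 1L) {
  stopifnot(dt > 0, duration > 0, stimulus_time > 0,
            stimulus_time < duration, baseline_f > 0, rise_time >= 0,
            noise_sd >= 0)
  structure(list(dt = dt, duration = duration, stimulus_time = stimulus_time,
                 baseline_f = baseline_f,
                 amplitude_fraction = amplitude_fraction,
                 rise_time = rise_time, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "trace_config")
}

#' Bundle fluorescence traces into a trace set
#'
#' @param times sample times, strictly increasing and uniformly spaced, s.
#' @param f matrix of fluorescence values, one column per cell.
#' @param stimulus_time stimulus onset, s.
#' @param groups optional per-cell treatment labels (e.g. CONT, DA, ACh).
#' @return a `trace_set` list.
#' @export
trace_set <- function(times, f, stimulus_time, groups = NULL) {
  f <- as.matrix(f)
  stopifnot(length(times) == nrow(f), all(is.finite(f)))
  d <- diff(times)
  if (any(d <= 0) || diff(range(d)) > 1e-8 * mean(d))
    stop("times must be strictly increasing and uniformly spaced")
  if (stimulus_time <= times[1] || stimulus_time > times[length(times)])
    stop("stimulus_time must lie within the record")
  if (is.null(colnames(f))) colnames(f) <- sprintf("cell%03d", seq_len(ncol(f)))
  if (!is.null(groups)) {
    groups <- as.character(groups)
    stopifnot(length(groups) == ncol(f))
  }
  structure(list(times = times, f = f, stimulus_time = stimulus_time,
                 groups = groups),
            class = "trace_set")
}

#' Simulate stimulus-locked calcium traces
#'
#' @param config a [trace_config()]; its amplitude/rise values are defaults.
#' @param n_cells number of traces.
#' @param amplitude_fraction optional per-cell planted amplitudes (recycled).
#' @param rise_time optional per-cell rise times (recycled).
#' @param groups optional per-cell group labels (recycled).
#' @return a `trace_set` with attribute `truth`: data frame of the planted
#'   per-cell amplitude and rise time.
#' @export
simulate_traces <- function(config, n_cells = 1, amplitude_fraction = NULL,
                            rise_time = NULL, groups = NULL) {
  stopifnot(inherits(config, "trace_config"), n_cells >= 1)
  amp <- rep_len(if (is.null(amplitude_fraction)) config$amplitude_fraction
                 else amplitude_fraction, n_cells)
  rt <- rep_len(if (is.null(rise_time)) config$rise_time else rise_time,
                n_cells)
  if (!is.null(groups)) groups <- rep_len(groups, n_cells)
  with_seed(config$seed, {
    times <- seq(0, config$duration, by = config$dt)
    f <- vapply(seq_len(n_cells), function(i) {
      el <- pmax(0, times - config$stimulus_time)  # elapsed since stimulus
      frac <- if (rt[i] > 0) pmin(1, el / rt[i]) else as.numeric(el > 0)
      config$baseline_f * (1 + amp[i] * frac) +
        stats::rnorm(length(times), 0, config$noise_sd)
    }, numeric(length(times)))
    ts <- trace_set(times, f, config$stimulus_time, groups = groups)
    attr(ts, "truth") <- data.frame(cell = colnames(ts$f), amplitude = amp,
                                    rise_time = rt,
                                    stringsAsFactors = FALSE)
    ts
  })
}
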