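#' Resample a trajectory to a uniform time grid
#'
#' Positions are linearly interpolated between the bracketing raw samples on
#' the grid `t_first, t_first + interval_s, ...`; the grid never extends
#' beyond the recorded time span. Tag dropouts longer than `max_gap_s` are
#' not interpolated across: grid points falling strictly inside such a gap
#' are dropped rather than filled with fabricated movement.
#'
#' All phase-level analytics in this package operate on a 1 Hz grid
#' (`interval_s = 1`), at which the distance between consecutive points is a
#' speed in mm/s.
#'
#' @param traj An [trajectory()].
#' @param interval_s Positive sampling interval in seconds (default 1).
#' @param max_gap_s Gaps between raw samples longer than this many seconds
#'   are not interpolated across (default 5; `Inf` disables gap handling).
#' @return A resampled `or_trajectory`.
#' @export
#' @examples
#' tr <- trajectory("c1", "surgeon", t = c(0, 2), x = c(0, 200), y = 0)
#' resample(tr)$points$x  # 0 100 200
resample <- function(traj, interval_s = 1, max_gap_s = 5) {
  stopifnot(inherits(traj, "or_trajectory"))
  if (interval_s <= 0) stop("interval_s must be positive", call. = FALSE)
  p <- traj$points
  if (nrow(p) < 2) {
    stop("cannot resample a trajectory with fewer than 2 points", call. = FALSE)
  }
  grid <- seq(p$t[1], p$t[nrow(p)], by = interval_s)
  if (is.finite(max_gap_s)) {
    gaps <- which(diff(p$t) > max_gap_s)
    if (length(gaps) > 0) {
      keep <- rep(TRUE, length(grid))
      for (g in gaps) {
        keep <- keep & !(grid > p$t[g] & grid < p$t[g + 1])
      }
      grid <- grid[keep]
    }
  }
  xi <- approx(p$t, p$x, xout = grid)$y
  yi <- approx(p$t, p$y, xout = grid)$y
  zi <- approx(p$t, p$z, xout = grid)$y
  trajectory(traj$case_id, traj$role, t = grid, x = xi, y = yi, z = zi,
             tag_id = traj$tag_id)
}

#' Slice a trajectory into phase segments
#'
#' Each phase interval is half-open: a segment contains exactly the points
#' with `t_start <= t < t_end`, so a point lying exactly on a boundary
#' belongs to the following interval and the segments partition the points.
#' A role absent during a phase yields an empty segment, which is preserved
#' (absence itself is informative).
#'
#' @param traj An [trajectory()].
#' @param intervals An [phase_intervals()] table for `traj`'s case.
#' @return A named list of `or_trajectory` segments, one per interval row,
#'   named `"<phase>"` or `"<phase>.<occurrence>"` for repeated phases. Each
#'   segment carries `phase` and `occurrence` attributes.
#' @export
slice_by_phase <- function(traj, intervals) {
  stopifnot(inherits(traj, "or_trajectory"))
  ints <- intervals[intervals$case_id == traj$case_id, , drop = FALSE]
  p <- traj$points
  out <- vector("list", nrow(ints))
  nm <- character(nrow(ints))
  for (i in seq_len(nrow(ints))) {
    sel <- p$t >= ints$t_start[i] & p$t < ints$t_end[i]
    seg <- trajectory(traj$case_id, traj$role, t = p$t[sel], x = p$x[sel],
                      y = p$y[sel], z = p$z[sel], tag_id = traj$tag_id)
    attr(seg, "phase") <- ints$phase[i]
    attr(seg, "occurrence") <- ints$occurrence[i]
    out[[i]] <- seg
    nm[i] <- if (ints$occurrence[i] > 1) {
      paste0(ints$phase[i], ".", ints$occurrence[i])
    } else {
      ints$phase[i]
    }
  }
  names(out) <- nm
  out
}

#' Planar step distances of a trajectory
#'
#' Distance in the x-y plane between each pair of consecutive points. On a
#' uniformly resampled 1 Hz trajectory each step distance is a speed in
#' mm/s.
#'
#' @param traj An [trajectory()].
#' @return Numeric vector of length `n_points(traj) - 1` (empty for fewer
#'   than 2 points).
#' @export
#' @examples
#' tr <- trajectory("c1", "surgeon", t = 0:1, x = c(0, 3000), y = c(0, 4000))
#' step_distances(tr)  # 5000
step_distances <- function(traj) {
  stopifnot(inherits(traj, "or_trajectory"))
  p <- traj$points
  if (nrow(p) < 2) return(numeric(0))
  sqrt(diff(p$x)^2 + diff(p$y)^2)
}

#' Step-distance (speed) distributions by phase and/or role
#'
#' Builds normalized step-distance histograms over phase segments, grouped
#' by phase, by role, or by phase x role, with a per-group mode (the bin
#' midpoint of highest density) and mean. With 1 Hz segments these are the
#' speed distributions of the staff.
#'
#' @param segments A list of phase segments as returned by
#'   [slice_by_phase()] (each carrying a `phase` attribute), possibly pooled
#'   over several trajectories and cases.
#' @param grouping One of `"by_phase"`, `"by_role"`, `"by_phase_role"`.
#' @param binwidth Histogram bin width in millimetres (default 20).
#' @return An object of class `or_speed_distribution`: a list with `grouping`,
#'   `breaks`, and `groups` -- a named list each holding `density`
#'   (summing to 1 over bins), `mode`, `mean`, and `n_steps`. Groups with no
#'   steps are omitted with a warning.
#' @export
speed_distribution <- function(segments,
                               grouping = c("by_phase", "by_role", "by_phase_role"),
                               binwidth = 20) {
  grouping <- match.arg(grouping)
  key_of <- function(seg) {
    switch(grouping,
           by_phase = attr(seg, "phase"),
           by_role = seg$role,
           by_phase_role = paste(attr(seg, "phase"), seg$role, sep = ":"))
  }
  steps <- list()
  for (seg in segments) {
    k <- key_of(seg)
    d <- step_distances(seg)
    steps[[k]] <- c(steps[[k]], d)
  }
  empty <- names(steps)[vapply(steps, length, 1L) == 0]
  if (length(empty) > 0) {
    warning("omitting group(s) with no steps: ", paste(empty, collapse = ", "),
            call. = FALSE)
    steps <- steps[setdiff(names(steps), empty)]
  }
  if (length(steps) == 0) stop("no steps in any group", call. = FALSE)
  top <- max(unlist(steps))
  breaks <- seq(0, top + binwidth, by = binwidth)
  groups <- lapply(steps, function(d) {
    h <- graphics::hist(d, breaks = breaks, plot = FALSE)
    dens <- h$counts / sum(h$counts)
    list(density = dens,
         mode = h$mids[which.max(dens)],
         mean = mean(d),
         n_steps = length(d))
  })
  structure(list(grouping = grouping, breaks = breaks, groups = groups),
            class = "or_speed_distribution")
}

#' @export
print.or_speed_distribution <- function(x, ...) {
  cat(sprintf("<or_speed_distribution> grouping %s, %d group(s)\n",
              x$grouping, length(x$groups)))
  for (nm in names(x$groups)) {
    g <- x$groups[[nm]]
    cat(sprintf("  %-28s mode %6.1f mm  mean %6.1f mm  (n = %d)\n",
                nm, g$mode, g$mean, g$n_steps))
  }
  invisible(x)
}
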