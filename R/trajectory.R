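#' Construct a staff trajectory
#'
#' A trajectory is the time-ordered track of one staff member (one ultrasonic
#' tag) within one case. Timestamps are seconds since case start; coordinates
#' are millimetres in the room frame. `z` is carried through all operations
#' but ignored by the planar analytics (step distances, LCSS), matching the
#' two-dimensional treatment of activity space.
#'
#' @param case_id Case identifier (scalar, coerced to character).
#' @param role One of [or_roles()].
#' @param t Numeric vector of timestamps in seconds, strictly increasing.
#' @param x,y,z Numeric coordinate vectors in millimetres (`z` defaults to 0).
#' @param tag_id Tag identifier; defaults to the role name.
#' @return An object of class `or_trajectory`: a list with elements
#'   `case_id`, `role`, `tag_id` and `points` (a data.frame with columns
#'   `t`, `x`, `y`, `z`).
#' @export
#' @examples
#' tr <- trajectory("c1", "surgeon", t = 0:3, x = c(0, 100, 200, 300), y = 0)
#' n_points(tr)
trajectory <- function(case_id, role, t, x, y, z = 0, tag_id = role) {
  role <- as.character(role)
  if (!role %in% or_roles()) {
    stop("unknown role '", role, "'; must be one of: ",
         paste(or_roles(), collapse = ", "), call. = FALSE)
  }
  n <- length(t)
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  z <- rep_len(as.numeric(z), n)
  t <- as.numeric(t)
  if (n > 0) {
    if (any(!is.finite(t)) || any(!is.finite(x)) || any(!is.finite(y)) ||
        any(!is.finite(z))) {
      stop("trajectory coordinates and timestamps must be finite", call. = FALSE)
    }
    if (any(t < 0)) stop("timestamps must be >= 0", call. = FALSE)
    if (n > 1 && any(diff(t) <= 0)) {
      stop("timestamps must be strictly increasing", call. = FALSE)
    }
  }
  structure(
    list(case_id = as.character(case_id), role = role,
         tag_id = as.character(tag_id),
         points = data.frame(t = t, x = x, y = y, z = z)),
    class = "or_trajectory"
  )
}

#' Number of points in a trajectory
#' @param traj An `or_trajectory`.
#' @return Integer point count.
#' @export
n_points <- function(traj) nrow(traj$points)

#' @export
print.or_trajectory <- function(x, ...) {
  n <- n_points(x)
  span <- if (n > 0) sprintf("%.1f-%.1f s", x$points$t[1], x$points$t[n]) else "empty"
  cat(sprintf("<or_trajectory> case %s, %s (tag %s): %d points [%s]\n",
              x$case_id, x$role, x$tag_id, n, span))
  invisible(x)
}

#' Read staff track files
#'
#' Reads a delimited track file with header columns
#' `case_id,role,tag_id,t,x,y,z` (seconds and millimetres) and returns one
#' trajectory per (case, role, tag), each sorted by time.
#'
#' @param path Path to a CSV track file.
#' @return List of [trajectory()] objects, one per (case, role, tag) group.
#' @export
read_tracks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("case_id", "role", "tag_id", "t", "x", "y", "z")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("track file '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(df$role), or_roles())
  if (length(bad) > 0) {
    stop("track file contains unknown role(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df$.row <- seq_len(nrow(df))
  keys <- interaction(df$case_id, df$role, df$tag_id, drop = TRUE, lex.order = TRUE)
  groups <- split(df, keys)
  out <- lapply(groups, function(g) {
    g <- g[order(g$t), , drop = FALSE]
    if (nrow(g) > 1 && any(diff(g$t) <= 0)) {
      i <- which(diff(g$t) <= 0)[1]
      stop(sprintf(
        "duplicate or non-increasing timestamp for case %s tag %s at input row %d (t = %g)",
        g$case_id[1], g$tag_id[1], g$.row[i + 1], g$t[i + 1]), call. = FALSE)
    }
    trajectory(g$case_id[1], g$role[1], t = g$t, x = g$x, y = g$y, z = g$z,
               tag_id = g$tag_id[1])
  })
  names(out) <- NULL
  out
}

#' Write staff track files
#'
#' Writes trajectories to the CSV track format read by [read_tracks()].
#' Reading the written file back yields the same points (bit-identical
#' round-trip at full double precision).
#'
#' @param trajs A list of [trajectory()] objects (or a single one).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(trajs, path) {
  if (inherits(trajs, "or_trajectory")) trajs <- list(trajs)
  rows <- lapply(trajs, function(tr) {
    if (n_points(tr) == 0) return(NULL)
    data.frame(case_id = tr$case_id, role = tr$role, tag_id = tr$tag_id,
               t = tr$points$t, x = tr$points$x, y = tr$points$y,
               z = tr$points$z)
  })
  df <- do.call(rbind, rows)
  # format() at 17 significant digits keeps the CSV round-trip exact
  for (col in c("t", "x", "y", "z")) {
    df[[col]] <- format(df[[col]], digits = 17, trim = TRUE, scientific = FALSE)
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Phase-interval table constructor
#'
#' @param case_id Character vector of case identifiers.
#' @param phase Character vector of phase labels from [or_phases()].
#' @param t_start,t_end Numeric vectors of interval bounds in seconds since
#'   case start; intervals are half-open `[t_start, t_end)` and must not
#'   overlap within a case.
#' @return A data.frame of class `or_phase_intervals` with one row per
#'   interval, ordered by case and start time, with an `occurrence` column
#'   numbering repeats of the same phase within a case.
#' @export
#' @examples
#' phase_intervals("c1", c("Preparation", "Craniotomy"), c(0, 60), c(60, 180))
phase_intervals <- function(case_id, phase, t_start, t_end) {
  df <- data.frame(case_id = as.character(case_id), phase = as.character(phase),
                   t_start = as.numeric(t_start), t_end = as.numeric(t_end),
                   stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$phase), or_phases())
  if (length(bad) > 0) {
    stop("unknown phase label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(df$t_start >= df$t_end)) {
    stop("phase intervals must satisfy t_start < t_end", call. = FALSE)
  }
  df <- df[order(df$case_id, df$t_start), , drop = FALSE]
  for (cid in unique(df$case_id)) {
    sub <- df[df$case_id == cid, , drop = FALSE]
    if (nrow(sub) > 1 && any(sub$t_start[-1] < sub$t_end[-nrow(sub)])) {
      stop("overlapping phase intervals in case ", cid, call. = FALSE)
    }
  }
  occ <- stats::ave(seq_len(nrow(df)), df$case_id, df$phase, FUN = seq_along)
  df$occurrence <- as.integer(occ)
  rownames(df) <- NULL
  class(df) <- c("or_phase_intervals", "data.frame")
  df
}

#' Read a phase-interval file
#'
#' CSV with header `case_id,phase,t_start,t_end` (seconds since case start).
#'
#' @param path Path to the CSV file.
#' @return An [phase_intervals()] table.
#' @export
read_phase_intervals <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("case_id", "phase", "t_start", "t_end")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("phase file '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  phase_intervals(df$case_id, df$phase, df$t_start, df$t_end)
}

#' Write a phase-interval file
#'
#' @param intervals An [phase_intervals()] table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_phase_intervals <- function(intervals, path) {
  df <- as.data.frame(intervals)[, c("case_id", "phase", "t_start", "t_end")]
  for (col in c("t_start", "t_end")) {
    df[[col]] <- format(df[[col]], digits = 17, trim = TRUE, scientific = FALSE)
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
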