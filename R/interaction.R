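#' LCSS matching parameters
#'
#' @param eps Spatial matching threshold in mm (default 500, roughly
#'   within-reach distance and well above the 80 mm tracking noise floor).
#' @param delta Temporal matching window in samples (default 5 at 1 Hz);
#'   points can only match when their sample indices differ by at most
#'   `delta`. Use `Inf` for an unconstrained window.
#' @return A list of class `lcss_params`.
#' @export
lcss_params <- function(eps = 500, delta = 5) {
  if (eps <= 0) stop("eps must be positive", call. = FALSE)
  if (is.finite(delta) && (delta < 0 || delta != round(delta))) {
    stop("delta must be a non-negative integer (or Inf)", call. = FALSE)
  }
  structure(list(eps = eps, delta = delta), class = "lcss_params")
}

#' LCSS length of two trajectories
#'
#' Length of the longest order-preserving matching between the two point
#' sequences in which matched points lie within `eps` mm in the x-y plane
#' and within `delta` samples in time. Both trajectories should share the
#' common 1 Hz analysis grid so that index offsets are time offsets.
#'
#' @param a,b [trajectory()] objects (or empty trajectories).
#' @param params An [lcss_params()].
#' @return Non-negative integer; 0 if either trajectory is empty.
#' @export
#' @examples
#' a <- trajectory("c", "surgeon", t = 0:4, x = 0:4 * 100, y = 0)
#' lcss_length(a, a, lcss_params(eps = 50, delta = 2))  # 5
lcss_length <- function(a, b, params = lcss_params()) {
  stopifnot(inherits(a, "or_trajectory"), inherits(b, "or_trajectory"))
  delta <- if (is.finite(params$delta)) params$delta else -1
  .lcss_length_cpp(a$points$x, a$points$y, b$points$x, b$points$y,
                   params$eps, delta)
}

#' LCSS similarity of two trajectories
#'
#' `lcss_length(a, b) / min(n_points(a), n_points(b))`, a value in
#' `[0, 1]`; 1 for identical tracks, 0 for tracks that never come within
#' `eps` of each other. Defined as 0 when either trajectory is empty (an
#' absent staff member interacts with no one). Symmetric in its arguments.
#'
#' @inheritParams lcss_length
#' @return Similarity in `[0, 1]`.
#' @export
lcss_similarity <- function(a, b, params = lcss_params()) {
  na <- n_points(a); nb <- n_points(b)
  if (na == 0 || nb == 0) return(0)
  lcss_length(a, b, params) / min(na, nb)
}

#' All pairwise interactions for one case
#'
#' For every phase segment of a case and every ordered pair of the four
#' staff roles (4 x 4 = 16 pairs including self-pairs) computes the LCSS
#' similarity between the two roles' segment trajectories. Self-pairs have
#' similarity 1 by convention and are excluded from modelling; a pair with
#' an absent member gets similarity 0 and `missing = TRUE`.
#'
#' @param case An `or_case` (or any list with `case_id`, `trajectories`
#'   named by role, and `intervals`).
#' @param params An [lcss_params()].
#' @param resample_first If `TRUE` (default), trajectories are resampled to
#'   the 1 Hz analysis grid before slicing. Set to `FALSE` for data already
#'   on the grid.
#' @return Data frame with one row per (segment, ordered pair):
#'   `case_id`, `phase`, `occurrence`, `role_a`, `role_b`, `similarity`,
#'   `missing`.
#' @export
pairwise_interactions <- function(case, params = lcss_params(),
                                  resample_first = TRUE) {
  roles <- or_roles()
  segs <- list()
  for (r in roles) {
    tr <- case$trajectories[[r]]
    if (!is.null(tr) && n_points(tr) >= 2 && resample_first) {
      tr <- resample(tr, interval_s = 1)
    }
    if (!is.null(tr)) segs[[r]] <- slice_by_phase(tr, case$intervals)
  }
  ints <- case$intervals
  rows <- vector("list", nrow(ints) * length(roles)^2)
  k <- 0
  for (s in seq_len(nrow(ints))) {
    for (ra in roles) {
      for (rb in roles) {
        seg_a <- if (!is.null(segs[[ra]])) segs[[ra]][[s]] else NULL
        seg_b <- if (!is.null(segs[[rb]])) segs[[rb]][[s]] else NULL
        na <- if (is.null(seg_a)) 0L else n_points(seg_a)
        nb <- if (is.null(seg_b)) 0L else n_points(seg_b)
        absent <- na == 0 || nb == 0
        sim <- if (absent) {
          0
        } else if (ra == rb) {
          1
        } else {
          lcss_similarity(seg_a, seg_b, params)
        }
        k <- k + 1
        rows[[k]] <- data.frame(
          case_id = case$case_id, phase = ints$phase[s],
          occurrence = ints$occurrence[s], role_a = ra, role_b = rb,
          similarity = sim, missing = absent, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Fit tertile discretization boundaries
#'
#' Computes per-column quantile boundaries (tertiles by default) on
#' training values only, for later application to held-out values with
#' [discretize_apply()]. Boundary ties go to the lower level. A column with
#' fewer distinct values than levels yields degenerate boundaries and a
#' warning; rows are still assigned by value against those boundaries.
#'
#' @param values Numeric vector (one feature column); `NA`s (absent roles)
#'   are ignored when fitting.
#' @param n_levels Number of levels (default 3: Low, Medium, High).
#' @return List of class `or_discretizer` with `boundaries` (length
#'   `n_levels - 1`) and `levels`.
#' @export
#' @examples
#' d <- discretize_fit(1:9)
#' discretize_apply(d, c(2, 5, 8))  # Low Medium High
discretize_fit <- function(values, n_levels = 3) {
  v <- values[!is.na(values)]
  lev <- if (n_levels == 3) c("Low", "Medium", "High") else
    paste0("L", seq_len(n_levels))
  if (length(unique(v)) < n_levels) {
    warning("fewer than ", n_levels,
            " distinct values; discretization boundaries are degenerate",
            call. = FALSE)
  }
  probs <- seq_len(n_levels - 1) / n_levels
  b <- if (length(v) > 0) unname(quantile(v, probs, type = 7)) else
    rep(NA_real_, n_levels - 1)
  structure(list(boundaries = b, levels = lev), class = "or_discretizer")
}

#' Apply fitted discretization boundaries
#'
#' A value equal to a boundary is assigned to the lower level. `NA` input
#' (absent role) maps to the lowest level -- an absent staff member's
#' interaction is minimal -- while the missingness itself should be tracked
#' separately so inference can drop the attribute from the evidence.
#'
#' @param disc An [discretize_fit()] result.
#' @param values Numeric vector.
#' @return Factor with the discretizer's levels.
#' @export
discretize_apply <- function(disc, values) {
  b <- disc$boundaries
  idx <- rep(1L, length(values))
  for (k in seq_along(b)) {
    if (!is.na(b[k])) idx <- idx + (values > b[k])
  }
  idx[is.na(values)] <- 1L
  factor(disc$levels[idx], levels = disc$levels)
}

#' Build the interaction feature table for a dataset
#'
#' One row per (case, phase-occurrence) segment; one continuous similarity
#' column per selected role pair (`<pair>_sim`, `NA` when a member is
#' absent) plus the `phase` label. With `discretize = TRUE`, adds
#' `<pair>_level` factors from tertile boundaries fitted on the whole
#' table (for a single full-data model; holdout evaluation instead refits
#' boundaries on each training split).
#'
#' @param dataset An `or_dataset`, or a list of `or_case` objects.
#' @param params An [lcss_params()].
#' @param selected_pairs Named list of role pairs (default
#'   [default_pairs()], the four pairs used to learn the phase model).
#' @param discretize Add level columns fitted on all rows (default FALSE).
#' @param resample_first Passed to segment preparation; see
#'   [pairwise_interactions()].
#' @return Data frame of class `or_feature_table` with columns `case_id`,
#'   `occurrence`, `phase` (factor over [or_phases()]) and the feature
#'   columns. The LCSS parameters and pair definitions are attached as
#'   attributes.
#' @export
build_feature_table <- function(dataset, params = lcss_params(),
                                selected_pairs = default_pairs(),
                                discretize = FALSE, resample_first = TRUE) {
  roles <- or_roles()
  for (pn in names(selected_pairs)) {
    pr <- selected_pairs[[pn]]
    if (length(pr) != 2 || !all(pr %in% roles)) {
      stop("selected pair '", pn, "' must name two of: ",
           paste(roles, collapse = ", "), call. = FALSE)
    }
  }
  rows <- list()
  for (cs in dataset) {
    segs <- list()
    for (r in roles) {
      tr <- cs$trajectories[[r]]
      if (!is.null(tr) && n_points(tr) >= 2 && resample_first) {
        tr <- resample(tr, interval_s = 1)
      }
      if (!is.null(tr)) segs[[r]] <- slice_by_phase(tr, cs$intervals)
    }
    ints <- cs$intervals
    for (s in seq_len(nrow(ints))) {
      row <- data.frame(case_id = cs$case_id, occurrence = ints$occurrence[s],
                        phase = ints$phase[s], stringsAsFactors = FALSE)
      for (pn in names(selected_pairs)) {
        pr <- selected_pairs[[pn]]
        seg_a <- if (!is.null(segs[[pr[1]]])) segs[[pr[1]]][[s]] else NULL
        seg_b <- if (!is.null(segs[[pr[2]]])) segs[[pr[2]]][[s]] else NULL
        sim <- if (is.null(seg_a) || is.null(seg_b) ||
                   n_points(seg_a) == 0 || n_points(seg_b) == 0) {
          NA_real_
        } else {
          lcss_similarity(seg_a, seg_b, params)
        }
        row[[paste0(pn, "_sim")]] <- sim
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  tab <- do.call(rbind, rows)
  tab$phase <- factor(tab$phase, levels = or_phases())
  if (discretize) {
    for (pn in names(selected_pairs)) {
      disc <- discretize_fit(tab[[paste0(pn, "_sim")]])
      tab[[paste0(pn, "_level")]] <- discretize_apply(disc, tab[[paste0(pn, "_sim")]])
    }
  }
  attr(tab, "lcss_params") <- params
  attr(tab, "pairs") <- selected_pairs
  class(tab) <- c("or_feature_table", "data.frame")
  tab
}

#' Write / read a feature table
#'
#' CSV with header `case_id,occurrence,phase,<pair>_sim,...` (and
#' `<pair>_level` columns if present).
#'
#' @param table An `or_feature_table`.
#' @param path CSV path.
#' @return `path` (writer, invisibly) or the table (reader).
#' @export
write_feature_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("case_id", "phase")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("feature table '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab$phase <- factor(tab$phase, levels = or_phases())
  for (col in grep("_level$", names(tab), value = TRUE)) {
    tab[[col]] <- factor(tab[[col]], levels = c("Low", "Medium", "High"))
  }
  class(tab) <- c("or_feature_table", "data.frame")
  tab
}
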