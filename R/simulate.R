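#' Simulation configuration for synthetic operating-room movement
#'
#' Encodes the study conditions the simulator emulates: a 5.8 x 4.8 m room,
#' four staff roles with role-specific activity zones, six ordered phases,
#' 80 mm positional tracking noise, 1 Hz analysis sampling, and
#' phase-dependent pairwise cooperation (high surgeon--scrub-nurse
#' cooperation in Craniotomy and TR, low in Preparation and End).
#'
#' Movement is a mean-reverting (Ornstein-Uhlenbeck-style) walk around each
#' role's zone anchor. Cooperation is realized as rendezvous events: with
#' rate proportional to the configured cooperation intensity, both members
#' of a pair are steered to a shared waypoint for a sampled dwell time,
#' which is what makes LCSS trajectory similarity phase-dependent.
#'
#' @param room_mm Width (x) and depth (y) of the room in mm.
#' @param landmarks Named list of x-y points in mm; defaults place the
#'   entrance at (4000, 0) and the tool table at (1000, 3000).
#' @param role_zones Named list per role: `anchor` (x, y in mm), `sd`
#'   (dispersion of the stationary activity space, mm), and `base_step`
#'   (per-second innovation scale, mm).
#' @param phase_speed Named multiplier per phase applied to `base_step`;
#'   defaults make Preparation the slowest phase and MRI the fastest.
#' @param phase_duration_mean Named mean segment duration per phase, seconds.
#' @param duration_cv Lognormal coefficient of variation of durations.
#' @param cooperation Data frame with columns `pair`, `phase`, `intensity`
#'   in `[0, 1]`; see [default_cooperation()]. Pairs absent from the table
#'   do not cooperate.
#' @param presence Data frame with columns `role`, `phase`, `prob`; roles
#'   default to always present except the scrub nurse, who is usually
#'   absent during Preparation and often during End, and the anesthetist,
#'   who may leave before End.
#' @param noise_sd Positional measurement noise sd in mm (default 80, the
#'   tracking accuracy of the ultrasonic zone position system).
#' @param sample_hz Output sampling rate; the default 1 Hz is the analysis
#'   rate at which step distances are speeds.
#' @param rendezvous_rate Baseline rendezvous event rate (events/s) at
#'   cooperation intensity 1 (default 1/40).
#' @param dwell_mean Mean rendezvous dwell time in seconds (default 20).
#' @param ou_phi Mean-reversion factor per second of the zone walk (0-1).
#' @param extra_cycle_prob Probability that a case includes a second
#'   TR--MRI cycle (see [generate_dataset()] for exact segment-count
#'   control).
#' @return A validated list of class `or_sim_config`.
#' @export
or_sim_config <- function(room_mm = c(width = 5800, depth = 4800),
                          landmarks = list(entrance = c(4000, 0),
                                           tool_table = c(1000, 3000)),
                          role_zones = default_role_zones(),
                          phase_speed = c(Preparation = 0.6, Craniotomy = 1.2,
                                          Close = 1.0, MRI = 1.4, TR = 1.0,
                                          End = 0.8),
                          phase_duration_mean = c(Preparation = 300,
                                                  Craniotomy = 420, Close = 300,
                                                  MRI = 300, TR = 480, End = 180),
                          duration_cv = 0.25,
                          cooperation = default_cooperation(),
                          presence = default_presence(),
                          noise_sd = 80,
                          sample_hz = 1,
                          rendezvous_rate = 1 / 40,
                          dwell_mean = 20,
                          ou_phi = 0.85,
                          extra_cycle_prob = 0.65) {
  cfg <- list(room_mm = room_mm, landmarks = landmarks, role_zones = role_zones,
              phase_speed = phase_speed,
              phase_duration_mean = phase_duration_mean,
              duration_cv = duration_cv, cooperation = cooperation,
              presence = presence, noise_sd = noise_sd, sample_hz = sample_hz,
              rendezvous_rate = rendezvous_rate, dwell_mean = dwell_mean,
              ou_phi = ou_phi, extra_cycle_prob = extra_cycle_prob)
  validate_sim_config(cfg)
  structure(cfg, class = "or_sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$room_mm) == 2, all(cfg$room_mm > 0))
  for (r in or_roles()) {
    z <- cfg$role_zones[[r]]
    if (is.null(z)) stop("role_zones must cover role ", r, call. = FALSE)
    a <- z$anchor
    if (a[1] < 0 || a[1] > cfg$room_mm[[1]] || a[2] < 0 || a[2] > cfg$room_mm[[2]]) {
      stop("zone anchor for ", r, " lies outside the room", call. = FALSE)
    }
  }
  if (any(cfg$cooperation$intensity < 0 | cfg$cooperation$intensity > 1)) {
    stop("cooperation intensities must lie in [0, 1]", call. = FALSE)
  }
  if (any(cfg$presence$prob < 0 | cfg$presence$prob > 1)) {
    stop("presence probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(cfg$phase_duration_mean <= 0)) {
    stop("phase durations must be positive", call. = FALSE)
  }
  if (cfg$noise_sd < 0 || cfg$sample_hz <= 0) {
    stop("noise_sd must be >= 0 and sample_hz > 0", call. = FALSE)
  }
  invisible(cfg)
}

#' Default role activity zones
#'
#' Anchors and dispersions reproduce the observed spatial pattern: surgeons
#' and assistant nurses have the largest activity spaces (room centre and
#' bottom/tool area respectively), anesthetists occupy the upper-right
#' corner, and scrub nurses hold a small central zone at the surgical field.
#'
#' @return Named list per role with `anchor` (mm), `sd` (mm), `base_step`
#'   (mm per second).
#' @export
default_role_zones <- function() {
  list(
    surgeon         = list(anchor = c(2900, 2200), sd = 700, base_step = 150),
    assistant_nurse = list(anchor = c(2600, 1000), sd = 800, base_step = 180),
    scrub_nurse     = list(anchor = c(2400, 3200), sd = 250, base_step = 80),
    anesthetist     = list(anchor = c(5100, 4100), sd = 350, base_step = 100)
  )
}

#' Default phase-dependent cooperation intensities
#'
#' Encodes the qualitative cooperation structure of an intraoperative-MRI
#' neurosurgery: surgeon--scrub-nurse cooperation is high during Craniotomy
#' and TR and near-absent during Preparation and End; the assistant nurse
#' supports the sterile pair during the operative phases; the
#' anesthetist--assistant-nurse channel dominates Preparation and MRI.
#'
#' @return Data frame with columns `pair` (a name of [default_pairs()]),
#'   `phase`, `intensity`.
#' @export
default_cooperation <- function() {
  phases <- or_phases()  # Preparation, Craniotomy, Close, MRI, TR, End
  tab <- rbind(
    surg_scrub = c(0.05, 0.90, 0.45, 0.15, 0.85, 0.05),
    asst_surg  = c(0.30, 0.55, 0.60, 0.10, 0.50, 0.15),
    anes_asst  = c(0.60, 0.15, 0.25, 0.70, 0.15, 0.45),
    asst_scrub = c(0.10, 0.70, 0.45, 0.15, 0.75, 0.30)
  )
  colnames(tab) <- phases
  data.frame(pair = rep(rownames(tab), times = length(phases)),
             phase = rep(phases, each = nrow(tab)),
             intensity = as.vector(tab),
             stringsAsFactors = FALSE)
}

#' Default per-role, per-phase presence probabilities
#'
#' All roles are present throughout except the scrub nurse, who seldom
#' appears during Preparation and often leaves before End, and the
#' anesthetist, who may be absent at End.
#'
#' @return Data frame with columns `role`, `phase`, `prob`.
#' @export
default_presence <- function() {
  df <- expand.grid(role = or_roles(), phase = or_phases(),
                    stringsAsFactors = FALSE)
  df$prob <- 1
  df$prob[df$role == "scrub_nurse" & df$phase == "Preparation"] <- 0.15
  df$prob[df$role == "scrub_nurse" & df$phase == "End"] <- 0.6
  df$prob[df$role == "anesthetist" & df$phase == "End"] <- 0.7
  df
}

# Counter-based per-case seed derivation: stable under case reordering and
# kept below 2^31 - 1 so set.seed() accepts it.
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) + 9973 * as.numeric(index)) %% 2147483647)
}

# Sample the per-case phase schedule. The base cycle is
# Preparation -> Craniotomy -> TR -> MRI -> TR -> Close -> End (7 segments;
# intraoperative MRI interleaves imaging with resection). `extra_cycles`
# inserts further MRI -> TR pairs before Close; `extra_segments` appends
# single alternating MRI/TR segments to hit an exact dataset-wide count.
case_schedule <- function(cfg, extra_cycles = 0, extra_segments = 0) {
  phases <- c("Preparation", "Craniotomy", "TR", "MRI", "TR")
  if (extra_cycles > 0) {
    phases <- c(phases, rep(c("MRI", "TR"), extra_cycles))
  }
  if (extra_segments > 0) {
    add <- rep(c("MRI", "TR"), length.out = extra_segments)
    phases <- c(phases, add)
  }
  c(phases, "Close", "End")
}

sample_durations <- function(cfg, phases) {
  mu <- cfg$phase_duration_mean[phases]
  cv <- cfg$duration_cv
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mu) - sdlog^2 / 2
  pmax(30, round(rlnorm(length(phases), meanlog, sdlog)))
}

cooperation_lookup <- function(cfg) {
  coop <- cfg$cooperation
  key <- paste(coop$pair, coop$phase, sep = "|")
  setNames(coop$intensity, key)
}

presence_lookup <- function(cfg) {
  pres <- cfg$presence
  setNames(pres$prob, paste(pres$role, pres$phase, sep = "|"))
}

#' Generate one synthetic surgical case
#'
#' Simulates 1 Hz staff movement for one case. Per phase, each present role
#' performs a mean-reverting walk around its zone anchor; cooperating pairs
#' are repeatedly steered to shared rendezvous waypoints with rate
#' proportional to the configured cooperation intensity; Gaussian
#' positional noise of sd `noise_sd` is added to every sample; positions
#' are clipped to the room.
#'
#' @param config An [or_sim_config()].
#' @param seed Integer seed; the case is a pure function of
#'   `(config, seed)`.
#' @param case_id Case identifier (default derived from the seed).
#' @param extra_cycles,extra_segments Extra TR/MRI segments appended to the
#'   base 7-segment schedule (see [generate_dataset()]).
#' @return A list of class `or_case`: `case_id`, `trajectories` (named by
#'   role; absent roles appear with the phases they missed removed),
#'   `intervals` ([phase_intervals()]), `cooperation` (the intensity table
#'   used, ground truth for tests), `presence_drawn` (logical role x segment
#'   presence actually drawn), and `seed`.
#' @export
generate_case <- function(config, seed, case_id = paste0("case", seed),
                          extra_cycles = 0, extra_segments = 0) {
  validate_sim_config(config)
  set.seed(seed)
  phases <- case_schedule(config, extra_cycles, extra_segments)
  durations <- sample_durations(config, phases)
  t_end <- cumsum(durations)
  t_start <- c(0, head(t_end, -1))
  intervals <- phase_intervals(rep(case_id, length(phases)), phases,
                               t_start, t_end)
  dt <- 1 / config$sample_hz
  total_n <- sum(durations) * config$sample_hz
  tgrid <- seq(0, by = dt, length.out = total_n)
  seg_of <- findInterval(tgrid, t_start)  # segment index per sample

  pres <- presence_lookup(config)
  coop <- cooperation_lookup(config)
  pairs <- default_pairs()

  # presence draw per (role, segment)
  present <- matrix(TRUE, nrow = length(or_roles()), ncol = length(phases),
                    dimnames = list(or_roles(), NULL))
  for (r in or_roles()) {
    for (s in seq_along(phases)) {
      p <- pres[[paste(r, phases[s], sep = "|")]]
      if (is.null(p)) p <- 1
      present[r, s] <- runif(1) < p
    }
  }

  # per-sample target anchor, pull and step scale, per role
  anchors_x <- matrix(NA_real_, total_n, length(or_roles()),
                      dimnames = list(NULL, or_roles()))
  anchors_y <- anchors_x
  pull <- matrix(config$ou_phi, total_n, length(or_roles()),
                 dimnames = list(NULL, or_roles()))
  stepscale <- matrix(1, total_n, length(or_roles()),
                      dimnames = list(NULL, or_roles()))
  for (r in or_roles()) {
    anchors_x[, r] <- config$role_zones[[r]]$anchor[1]
    anchors_y[, r] <- config$role_zones[[r]]$anchor[2]
  }

  # rendezvous events: shared waypoints override both members' anchors
  for (s in seq_along(phases)) {
    idx <- which(seg_of == s)
    if (length(idx) == 0) next
    for (pn in names(pairs)) {
      kappa <- coop[[paste(pn, phases[s], sep = "|")]]
      if (is.null(kappa) || kappa <= 0) next
      ra <- pairs[[pn]][1]; rb <- pairs[[pn]][2]
      if (!present[ra, s] || !present[rb, s]) next
      n_ev <- rpois(1, kappa * config$rendezvous_rate * length(idx) * dt)
      if (n_ev == 0) next
      ev_start <- sort(sample(idx, n_ev, replace = TRUE))
      mid <- (config$role_zones[[ra]]$anchor + config$role_zones[[rb]]$anchor) / 2
      for (e in seq_len(n_ev)) {
        dwell <- max(4, round(rgamma(1, shape = 4,
                                     scale = config$dwell_mean / 4)))
        span <- ev_start[e]:min(ev_start[e] + dwell * config$sample_hz,
                                max(idx))
        wp <- mid + rnorm(2, 0, 200)
        wp[1] <- min(max(wp[1], 0), config$room_mm[[1]])
        wp[2] <- min(max(wp[2], 0), config$room_mm[[2]])
        for (r in c(ra, rb)) {
          anchors_x[span, r] <- wp[1]
          anchors_y[span, r] <- wp[2]
          pull[span, r] <- 0.5       # stronger pull: converge within seconds
          stepscale[span, r] <- 0.4  # hover near the waypoint
        }
      }
    }
  }

  trajectories <- list()
  for (r in or_roles()) {
    zone <- config$role_zones[[r]]
    keep <- present[r, seg_of]
    if (!any(keep)) next
    sp_mult <- config$phase_speed[phases[seg_of]]
    sigma <- zone$base_step * sp_mult * stepscale[, r]
    x <- numeric(total_n); y <- numeric(total_n)
    x[1] <- zone$anchor[1] + rnorm(1, 0, zone$sd / 2)
    y[1] <- zone$anchor[2] + rnorm(1, 0, zone$sd / 2)
    ex <- rnorm(total_n, 0, sigma)
    ey <- rnorm(total_n, 0, sigma)
    for (i in 2:total_n) {
      ph <- pull[i, r]
      x[i] <- anchors_x[i, r] + ph * (x[i - 1] - anchors_x[i, r]) + ex[i]
      y[i] <- anchors_y[i, r] + ph * (y[i - 1] - anchors_y[i, r]) + ey[i]
    }
    if (config$noise_sd > 0) {
      x <- x + rnorm(total_n, 0, config$noise_sd)
      y <- y + rnorm(total_n, 0, config$noise_sd)
    }
    x <- pmin(pmax(x, 0), config$room_mm[[1]])
    y <- pmin(pmax(y, 0), config$room_mm[[2]])
    trajectories[[r]] <- trajectory(case_id, r, t = tgrid[keep],
                                    x = x[keep], y = y[keep],
                                    z = 1200, tag_id = r)
  }

  structure(list(case_id = case_id, trajectories = trajectories,
                 intervals = intervals, cooperation = config$cooperation,
                 presence_drawn = present, seed = seed),
            class = "or_case")
}

#' @export
print.or_case <- function(x, ...) {
  cat(sprintf("<or_case> %s: %d role(s), %d phase segment(s), seed %d\n",
              x$case_id, length(x$trajectories), nrow(x$intervals), x$seed))
  invisible(x)
}

#' Generate a synthetic multi-case dataset
#'
#' Generates `n_cases` independent cases with per-case seeds derived from
#' the master seed by a fixed counter scheme. Phase durations and staffing
#' vary across cases. The total number of phase segments is controlled by
#' `target_segments`: the base schedule contributes 7 segments per case and
#' extra alternating MRI/TR segments are distributed round-robin across
#' cases until the target is met (the default, 83 segments from 10 cases,
#' matches a ten-case intraoperative-MRI caseload in which imaging and
#' resection interleave a varying number of times).
#'
#' @param config An [or_sim_config()].
#' @param n_cases Number of cases (default 10).
#' @param seed Master integer seed.
#' @param target_segments Total (case, phase-occurrence) segment count for
#'   the dataset, or `NULL` to draw extra TR--MRI cycles at random with
#'   probability `config$extra_cycle_prob` per case (default 83).
#' @return A list of class `or_dataset` of [generate_case()] results.
#' @export
generate_dataset <- function(config, n_cases = 10, seed = 1,
                             target_segments = 83) {
  stopifnot(n_cases >= 1)
  validate_sim_config(config)
  extra <- integer(n_cases)
  if (is.null(target_segments)) {
    set.seed(derive_seed(seed, 0))
    extra <- 2L * as.integer(runif(n_cases) < config$extra_cycle_prob)
  } else {
    base <- 7L * n_cases
    if (target_segments < base) {
      stop("target_segments must be >= 7 * n_cases = ", base, call. = FALSE)
    }
    surplus <- target_segments - base
    extra <- rep(surplus %/% n_cases, n_cases)
    r <- surplus %% n_cases
    if (r > 0) extra[seq_len(r)] <- extra[seq_len(r)] + 1L
  }
  cases <- lapply(seq_len(n_cases), function(i) {
    generate_case(config, seed = derive_seed(seed, i),
                  case_id = sprintf("case%02d", i),
                  extra_segments = extra[i])
  })
  structure(cases, class = "or_dataset")
}

#' Write a synthetic dataset to disk
#'
#' Writes the track CSV, the phase-interval CSV, and a ground-truth JSON
#' (cooperation table, presence draws, per-case seeds) into a directory.
#'
#' @param dataset An `or_dataset` from [generate_dataset()].
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  all_trajs <- unlist(lapply(dataset, function(cs) cs$trajectories),
                      recursive = FALSE)
  write_tracks(all_trajs, file.path(dir, "tracks.csv"))
  ints <- do.call(rbind, lapply(dataset, function(cs) as.data.frame(cs$intervals)))
  write_phase_intervals(phase_intervals(ints$case_id, ints$phase,
                                        ints$t_start, ints$t_end),
                        file.path(dir, "phases.csv"))
  truth <- list(
    cooperation = dataset[[1]]$cooperation,
    cases = lapply(dataset, function(cs) {
      list(case_id = cs$case_id, seed = cs$seed,
           presence = as.data.frame(which(!cs$presence_drawn, arr.ind = TRUE)))
    })
  )
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
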