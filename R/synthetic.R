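#' Synthetic-scene configuration
#'
#' Describes the synthetic test-cage scene the generator renders: a bright
#' blob subject over a static noisy background, alternating between freezing
#' (no displacement), ambiguous slow movement (sub-pixel jitter, emulating
#' slow head movements), and motion (a pixel-scale random walk). Defaults are
#' calibrated so the similarity trace is trimodal with state-conditional
#' means near 0.95 / 0.975 / 0.995 — the regime fixed-camera primate cage
#' video occupies, where even locomotion keeps consecutive-frame similarity
#' high because the subject is small relative to the scene.
#'
#' @param frame_size Square frame side in pixels (default 80).
#' @param fps Frames per second (default 30).
#' @param bg_mean Background mean intensity, 0-255 scale (default 60).
#' @param bg_texture_sd SD of the static background texture (default 20).
#' @param sensor_noise_sd SD of i.i.d. per-frame sensor noise (default 0.8);
#'   this is what keeps freezing-state similarity just below 1.
#' @param blob_intensity Peak blob intensity above background (default 150).
#' @param blob_radius Gaussian blob radius in pixels (default 4).
#' @param motion_step_sd Per-frame displacement scale, pixels, in the motion
#'   state (default 2). Displacements have random direction and magnitude
#'   `|N(scale, 0.15 * scale)|`: real locomotion has a characteristic speed,
#'   and a near-constant step keeps each state's score distribution compact
#'   (isotropic Gaussian steps would smear it into a Rayleigh-wide band).
#' @param ambiguous_step_sd Jitter scale in the ambiguous state
#'   (default 0.9), same step model; freezing displacement is exactly 0.
#' @param freezing_dwell,ambiguous_dwell,motion_dwell Integer ranges
#'   (frames) for uniformly drawn state dwell times; freezing dwells start at
#'   120 frames so every true freezing interval exceeds the 90-frame bout
#'   floor.
#' @param seed Integer seed fixed per dataset.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(frame_size = 80, fps = 30, bg_mean = 60,
                         bg_texture_sd = 20, sensor_noise_sd = 0.8,
                         blob_intensity = 150, blob_radius = 4,
                         motion_step_sd = 2, ambiguous_step_sd = 0.9,
                         freezing_dwell = c(120, 420),
                         ambiguous_dwell = c(30, 120),
                         motion_dwell = c(60, 300), seed = 1) {
  if (motion_step_sd <= ambiguous_step_sd || ambiguous_step_sd < 0) {
    abort("Require motion_step_sd > ambiguous_step_sd >= 0.",
          class = "stillframe_config_error")
  }
  structure(list(frame_size = as.integer(frame_size), fps = fps,
                 bg_mean = bg_mean, bg_texture_sd = bg_texture_sd,
                 sensor_noise_sd = sensor_noise_sd,
                 blob_intensity = blob_intensity, blob_radius = blob_radius,
                 motion_step_sd = motion_step_sd,
                 ambiguous_step_sd = ambiguous_step_sd,
                 freezing_dwell = as.integer(freezing_dwell),
                 ambiguous_dwell = as.integer(ambiguous_dwell),
                 motion_dwell = as.integer(motion_dwell),
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Sample a ground-truth behavioral schedule
#'
#' Draws an alternating-state schedule (freezing / ambiguous / motion) with
#' uniformly distributed dwell times from a [scene_config()]. Successive
#' states always differ; a trailing truncated freezing interval shorter than
#' 90 frames is merged into its predecessor so every freezing interval stays
#' detectable under the 3-second rule. Reproducible per seed.
#'
#' @param cfg A [scene_config()].
#' @param duration_s Session duration in seconds.
#' @param total_frames Optional exact frame count overriding `duration_s`.
#' @return A tibble of class `ground_truth_schedule` with columns `state`,
#'   `start_frame`, `end_frame` (1-based, inclusive) partitioning the session.
#' @export
sample_schedule <- function(cfg = scene_config(), duration_s = 60,
                            total_frames = NULL) {
  if (is.null(total_frames)) {
    if (duration_s <= 0) {
      abort("`duration_s` must be positive.", class = "stillframe_input_error")
    }
    total_frames <- as.integer(round(duration_s * cfg$fps))
  }
  dwell_range <- list(freezing = cfg$freezing_dwell,
                      ambiguous = cfg$ambiguous_dwell,
                      motion = cfg$motion_dwell)
  with_local_seed(cfg$seed, {
    states <- character(0)
    dwells <- integer(0)
    current <- sample(c("freezing", "ambiguous", "motion"), 1)
    total <- 0L
    while (total < total_frames) {
      r <- dwell_range[[current]]
      d <- sample(r[1]:r[2], 1)
      states <- c(states, current)
      dwells <- c(dwells, d)
      total <- total + d
      current <- sample(setdiff(c("freezing", "ambiguous", "motion"), current), 1)
    }
    dwells[length(dwells)] <- dwells[length(dwells)] - (total - total_frames)
    if (dwells[length(dwells)] == 0L) {
      states <- states[-length(states)]
      dwells <- dwells[-length(dwells)]
    }
    if (length(states) > 1 && states[length(states)] == "freezing" &&
        dwells[length(dwells)] < 90L) {
      # merge an undersized trailing freezing stub into its predecessor
      dwells[length(dwells) - 1L] <- dwells[length(dwells) - 1L] +
        dwells[length(dwells)]
      states <- states[-length(states)]
      dwells <- dwells[-length(dwells)]
    }
    ends <- cumsum(dwells)
    out <- tibble(state = states, start_frame = ends - dwells + 1L,
                  end_frame = ends)
    attr(out, "fps") <- cfg$fps
    attr(out, "total_frames") <- total_frames
    class(out) <- c("ground_truth_schedule", class(out))
    out
  })
}

#' Per-frame and per-score ground-truth states
#'
#' `schedule_states()` expands a schedule to one state per frame;
#' `schedule_score_states()` aligns it with a similarity trace, assigning
#' score `i` (spanning frames `i` and `i + 1`) the state of frame `i`.
#'
#' @param schedule A [sample_schedule()] result.
#' @return Character vector of states.
#' @export
schedule_states <- function(schedule) {
  rep(schedule$state, schedule$end_frame - schedule$start_frame + 1L)
}

#' @rdname schedule_states
#' @export
schedule_score_states <- function(schedule) {
  s <- schedule_states(schedule)
  s[-length(s)]
}

#' Render a synthetic session to frames
#'
#' Draws the scene described by a [scene_config()]: a static noisy background
#' (fixed texture plus per-frame sensor noise) and a Gaussian blob whose
#' center displacement per frame follows the schedule's state (0 when
#' freezing, sub-pixel jitter when ambiguous, a larger random walk in
#' motion). The blob reflects off frame boundaries. Intensities are clipped
#' to `[0, 255]`.
#'
#' @param schedule A [sample_schedule()] result.
#' @param cfg The [scene_config()] used to draw it.
#' @param source_id Identifier for the rendered sequence.
#' @return A [frame_sequence()].
#' @export
render_session <- function(schedule, cfg = scene_config(),
                           source_id = "synthetic") {
  n <- attr(schedule, "total_frames")
  sz <- cfg$frame_size
  states <- schedule_states(schedule)
  step_sd <- c(freezing = 0, ambiguous = cfg$ambiguous_step_sd,
               motion = cfg$motion_step_sd)
  with_local_seed(cfg$seed + 1L, {
    background <- matrix(cfg$bg_mean + rnorm(sz * sz, sd = cfg$bg_texture_sd),
                         sz, sz)
    margin <- cfg$blob_radius
    lo <- 1 + margin
    hi <- sz - margin
    pos <- c(sz / 2, sz / 2)
    xs <- matrix(rep(seq_len(sz), sz), sz, sz)
    ys <- t(xs)
    frames <- vector("list", n)
    for (i in seq_len(n)) {
      sdv <- step_sd[[states[i]]]
      if (i > 1 && sdv > 0) {
        ang <- runif(1, 0, 2 * pi)
        mag <- abs(rnorm(1, mean = sdv, sd = 0.15 * sdv))
        pos <- pos + mag * c(cos(ang), sin(ang))
        # reflect at the margins so the blob never leaves the frame
        for (d in 1:2) {
          if (pos[d] < lo) pos[d] <- lo + (lo - pos[d])
          if (pos[d] > hi) pos[d] <- hi - (pos[d] - hi)
        }
      }
      blob <- cfg$blob_intensity *
        exp(-((ys - pos[1])^2 + (xs - pos[2])^2) / (2 * cfg$blob_radius^2))
      f <- background + blob + rnorm(sz * sz, sd = cfg$sensor_noise_sd)
      frames[[i]] <- pmin(pmax(f, 0), 255)
    }
    frame_sequence(frames, fps = cfg$fps, source_id = source_id)
  })
}

#' Simulate a similarity trace directly from state Gaussians
#'
#' The fast generation path: instead of rendering frames, draws each score
#' from the Gaussian its behavioral state is assumed to induce, truncated to
#' `[0, 1]` (truncation rather than clipping keeps the mixture identifiable —
#' no probability mass piles up at the bounds). Defaults match the regime the
#' mixture model assumes: motion 0.955, ambiguous 0.975, freezing 0.995, with
#' SDs 0.004 / 0.004 / 0.002.
#'
#' @param schedule A [sample_schedule()] result.
#' @param means,sds Named numeric vectors (`motion`, `ambiguous`, `freezing`)
#'   of state score means (strictly increasing in that order, in `(0, 1)`)
#'   and SDs.
#' @param seed Integer seed.
#' @param source_id Identifier for the trace.
#' @return A [similarity_trace()] with `total_frames - 1` scores.
#' @export
simulate_trace <- function(schedule,
                           means = c(motion = 0.955, ambiguous = 0.975,
                                     freezing = 0.995),
                           sds = c(motion = 0.004, ambiguous = 0.004,
                                   freezing = 0.002),
                           seed = 1, source_id = "synthetic") {
  if (!(means[["motion"]] < means[["ambiguous"]] &&
        means[["ambiguous"]] < means[["freezing"]])) {
    abort("State means must be ordered motion < ambiguous < freezing.",
          class = "stillframe_input_error")
  }
  if (any(means <= 0 | means >= 1)) {
    abort("State means must lie in (0, 1).", class = "stillframe_input_error")
  }
  st <- schedule_score_states(schedule)
  m <- means[st]
  s <- sds[st]
  scores <- with_local_seed(seed, {
    if (all(s == 0)) {
      as.numeric(m)
    } else {
      # inverse-CDF truncated-normal draw on [0, 1]
      lo <- stats::pnorm((0 - m) / pmax(s, 1e-300))
      hi <- stats::pnorm((1 - m) / pmax(s, 1e-300))
      u <- runif(length(m))
      x <- m + s * qnorm(lo + u * (hi - lo))
      ifelse(s == 0, m, pmin(pmax(x, 0), 1))
    }
  })
  similarity_trace(scores, fps = attr(schedule, "fps") %||% 30,
                   source_id = source_id)
}
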