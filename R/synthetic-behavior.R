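#' Default VR T-maze task parameters
#'
#' Geometry and timing of the two-alternative choice task: a 219 cm stem, a
#' 37 cm arm, memory-trial cue positions sampled uniformly between 8.5 and
#' 153.8 cm from the junction, a 5.7 cm/s movement threshold to initiate the
#' trial, a 120 s response timeout, a 1-1.5 s random inter-trial delay with
#' 8 extra seconds after errors and timeouts, and cue-side probabilities
#' adjusted over the trailing 40 trials to counteract side bias.
#'
#' @param stem_cm,arm_cm Maze dimensions (cm).
#' @param cue_range_cm Memory-trial cue position range (cm from junction).
#' @param init_speed_cm_s Minimum speed to initiate a trial (cm/s).
#' @param timeout_s Response timeout (s).
#' @param iti_range_s Random inter-trial delay range (s).
#' @param error_timeout_s Extra timeout after an error or timeout (s).
#' @param visual_frac Fraction of trials presented as visual (cue in the
#'   arm) rather than memory trials.
#' @param bias_k Gain of the side-bias correction rule.
#' @param bias_window Trailing window (trials) over which per-side accuracy
#'   is measured.
#' @param bias_clip Bounds on the adjusted cue-side probability.
#' @return A list of task parameters.
#' @export
task_params <- function(stem_cm = 219, arm_cm = 37,
                        cue_range_cm = c(8.5, 153.8),
                        init_speed_cm_s = 5.7,
                        timeout_s = 120,
                        iti_range_s = c(1, 1.5),
                        error_timeout_s = 8,
                        visual_frac = 0.15,
                        bias_k = 0.75,
                        bias_window = 40L,
                        bias_clip = c(0.2, 0.8)) {
  as.list(environment())
}

#' Simulate a VR T-maze behavior session
#'
#' A parameterized agent runs trials of the two-alternative choice task. On
#' each trial the cue side is drawn with a probability adjusted by the
#' side-bias rule (see below), the agent runs at a per-trial speed drawn
#' from a truncated normal distribution, chooses the cued side with
#' probability `accuracy` and otherwise guesses with a configurable side
#' preference, and receives reward, punishment, or a timeout. Trials in
#' which the agent's speed is below the initiation threshold, or in which
#' the run would exceed the response timeout, end as timeouts (no choice).
#'
#' The bias rule is a stand-in for performance-dependent cue scheduling:
#' `P(right cue) = clip(0.5 + k * (acc_left - acc_right), clip_lo, clip_hi)`
#' with per-side accuracies measured over the trailing `bias_window` trials,
#' so the side the agent fails more often is cued more often.
#'
#' @param n_trials Number of trials (>= 1).
#' @param agent List: `speed_cm_s` (mean run speed), `speed_sd` (between-trial
#'   SD), `accuracy` (probability of choosing the cued side), `guess_right`
#'   (probability a non-cue-driven guess goes right).
#' @param task Task parameters from [task_params()].
#' @param frame_rate_hz Rate of the per-frame velocity trace (volumes/s).
#' @param seed Integer seed.
#' @return Object of class `behavior_log`: list with `trials` (one row per
#'   trial: type, cue side/position, event times, outcome, chosen side,
#'   speed) and `velocity` (data frame `t_s`, `v_cm_s` at the frame rate).
#' @export
simulate_behavior <- function(n_trials,
                              agent = list(speed_cm_s = 20, speed_sd = 4,
                                           accuracy = 0.8, guess_right = 0.5),
                              task = task_params(),
                              frame_rate_hz = 10.4,
                              seed = 1L) {
  stopifnot(n_trials >= 1)
  if (is.null(agent$speed_sd)) agent$speed_sd <- 0
  if (is.null(agent$guess_right)) agent$guess_right <- 0.5
  if (agent$speed_cm_s <= 0) stop("agent speed must be positive")
  with_seed(seed, {
    trials <- vector("list", n_trials)
    outcome_hist <- character(0)  # "L_correct", "L_wrong", "R_correct", ...
    clock <- 0
    speed_trace <- list()
    for (k in seq_len(n_trials)) {
      p_right <- side_bias_probability(outcome_hist, task)
      cue_side <- if (runif(1) < p_right) "R" else "L"
      trial_type <- if (runif(1) < task$visual_frac) "visual" else "memory"
      cue_pos <- if (trial_type == "memory")
        runif(1, task$cue_range_cm[1], task$cue_range_cm[2]) else NA_real_
      speed <- max(0.1, rnorm(1, agent$speed_cm_s, agent$speed_sd))
      t_start <- clock
      run_time <- (task$stem_cm + task$arm_cm) / speed
      if (speed < task$init_speed_cm_s ||
          task$stem_cm / speed > task$timeout_s) {
        outcome <- "timeout"
        chosen <- NA_character_
        t_choice <- NA_real_
        t_outcome <- t_start + task$timeout_s
        moved <- speed >= task$init_speed_cm_s
        run_dur <- if (moved) task$timeout_s else 0
      } else {
        chose_cue <- runif(1) < agent$accuracy
        chosen <- if (chose_cue) cue_side
                  else if (runif(1) < agent$guess_right) "R" else "L"
        t_choice <- t_start + task$stem_cm / speed
        t_outcome <- t_start + run_time
        outcome <- if (chosen == cue_side) "correct" else "incorrect"
        run_dur <- run_time
      }
      iti <- runif(1, task$iti_range_s[1], task$iti_range_s[2])
      if (outcome != "correct") iti <- iti + task$error_timeout_s
      trials[[k]] <- data.frame(
        trial = k, trial_type = trial_type, cue_side = cue_side,
        cue_pos_cm = cue_pos, t_start = t_start, t_choice = t_choice,
        t_outcome = t_outcome, outcome = outcome, chosen_side = chosen,
        speed_cm_s = speed, p_right_cue = p_right,
        stringsAsFactors = FALSE)
      speed_trace[[k]] <- c(run_dur = run_dur,
                            still_dur = (t_outcome - t_start - run_dur) + iti,
                            speed = speed)
      side <- cue_side
      outcome_hist <- c(outcome_hist, paste0(
        side, "_", if (outcome == "correct") "correct" else "wrong"))
      clock <- t_outcome + iti
    }
    trials <- do.call(rbind, trials)
    total_s <- clock
    nf <- ceiling(total_s * frame_rate_hz)
    t_s <- (seq_len(nf) - 0.5) / frame_rate_hz
    v <- numeric(nf)
    for (k in seq_len(n_trials)) {
      tr <- trials[k, ]
      st <- speed_trace[[k]]
      run <- t_s >= tr$t_start & t_s < tr$t_start + st["run_dur"]
      v[run] <- st["speed"]
    }
    structure(list(
      trials = trials,
      velocity = data.frame(t_s = t_s, v_cm_s = v),
      frame_rate_hz = frame_rate_hz,
      task = task,
      seed = as.integer(seed)
    ), class = "behavior_log")
  })
}

# P(right cue) from trailing per-side accuracy; counteracts side bias by
# cueing the side the subject fails more often.
side_bias_probability <- function(outcome_hist, task) {
  h <- utils::tail(outcome_hist, task$bias_window)
  nL <- sum(startsWith(h, "L")); nR <- sum(startsWith(h, "R"))
  accL <- if (nL > 0) sum(h == "L_correct") / nL else 0.5
  accR <- if (nR > 0) sum(h == "R_correct") / nR else 0.5
  min(max(0.5 + task$bias_k * (accL - accR), task$bias_clip[1]),
      task$bias_clip[2])
}

#' @export
print.behavior_log <- function(x, ...) {
  tab <- table(x$trials$outcome)
  cat(sprintf("<behavior_log> %d trials (%s), %.0f s\n", nrow(x$trials),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              max(x$trials$t_outcome)))
  invisible(x)
}
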