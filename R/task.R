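#' Timing of the sequential paired-association trial
#'
#' A trial lasts 2,400 ms and is discretised in steps of `dt` ms.  The
#' eight task periods are, in order: initial fixation (600 ms), first
#' (sample) stimulus (400 ms), first delay (500 ms), second stimulus
#' (200 ms), first decision window (100 ms), mid-trial fixation (300 ms),
#' third stimulus (200 ms) and second decision window (100 ms).  With the
#' default `dt = 20` ms this yields 121 time points (steps 0..120, the
#' last being the terminal trial-end step).
#'
#' @param dt Step duration in ms.
#' @param durations Named numeric vector of period durations in ms, in
#'   trial order.  Every duration must be divisible by `dt`.
#' @return An object of class `task_timing`.
#' @export
task_timing <- function(dt = 20,
                        durations = c(initial_fixation = 600,
                                      first_stimulus   = 400,
                                      first_delay      = 500,
                                      second_stimulus  = 200,
                                      first_decision   = 100,
                                      mid_fixation     = 300,
                                      third_stimulus   = 200,
                                      second_decision  = 100)) {
  stopifnot(is.numeric(dt), length(dt) == 1, dt > 0)
  if (any(durations %% dt != 0)) {
    stop("every period duration must be divisible by dt", call. = FALSE)
  }
  structure(list(dt = dt, durations = durations), class = "task_timing")
}

#' Build the per-step event schedule of a trial
#'
#' Converts period durations into contiguous half-open step ranges
#' `[start, end)`.  Step 0 is the first observation step; the terminal
#' step (`2400/dt`) lies beyond the last period and only ends the trial.
#'
#' @param timing A [task_timing()] object.
#' @return An object of class `event_schedule` with elements `dt`,
#'   `periods` (data frame: name, start, end in steps), `n_steps`
#'   (number of action steps, terminal step included) and `period_of`
#'   (integer vector mapping step index 0..n_steps-1 to a period id;
#'   the terminal step has id 0).
#' @export
build_schedule <- function(timing = task_timing()) {
  stopifnot(inherits(timing, "task_timing"))
  steps <- timing$durations / timing$dt
  end <- cumsum(steps)
  start <- c(0, end[-length(end)])
  periods <- data.frame(name = names(timing$durations),
                        start = as.integer(start),
                        end = as.integer(end),
                        stringsAsFactors = FALSE)
  total <- as.integer(end[length(end)])
  period_of <- integer(total + 1L)          # steps 0 .. total
  for (i in seq_len(nrow(periods))) {
    period_of[(periods$start[i] + 1L):periods$end[i]] <- i
  }
  period_of[total + 1L] <- 0L               # terminal trial-end step
  structure(list(dt = timing$dt,
                 periods = periods,
                 n_steps = total + 1L,      # action steps incl. terminal
                 period_of = period_of),
            class = "event_schedule")
}

# period ids by name (fixed order above)
.PERIOD <- c(initial_fixation = 1L, first_stimulus = 2L, first_delay = 3L,
             second_stimulus = 4L, first_decision = 5L, mid_fixation = 6L,
             third_stimulus = 7L, second_decision = 8L)

.ORDERS <- c("ABC", "BCA", "CAB")
# cyclic rotations of the three-item chain
.ORDER_LETTERS <- list(ABC = c("A", "B", "C"),
                       BCA = c("B", "C", "A"),
                       CAB = c("C", "A", "B"))
.LETTER_VALUE <- c(A = 2, B = 3, C = 4)

#' All 24 trial conditions
#'
#' The condition space is sequence order (ABC, BCA, CAB) x associative
#' group (1 = A1-group, 2 = A2-group) x target side of the first choice
#' pair x target side of the second choice pair.
#'
#' @return A data frame with 24 rows and columns `order`, `group`,
#'   `pos1`, `pos2` (`"L"` or `"R"` = side on which the trial's own
#'   group's stimulus, i.e. the correct choice, appears).
#' @export
trial_conditions <- function() {
  g <- expand.grid(pos2 = c("L", "R"), pos1 = c("L", "R"),
                   group = 1:2, order = .ORDERS,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g[, c("order", "group", "pos1", "pos2")]
}

#' Sample trial conditions in shuffled balanced blocks
#'
#' Trials are drawn in blocks of 24 within which every condition occurs
#' exactly once, in shuffled order.  This keeps each 24-trial parameter
#' update balanced across conditions while the sequences still appear in
#' random order.
#'
#' @param n Number of trials.
#' @return A data frame of `n` trial specifications (see
#'   [trial_conditions()]).
#' @export
sample_trials <- function(n) {
  conds <- trial_conditions()
  blocks <- ceiling(n / 24L)
  idx <- unlist(lapply(seq_len(blocks), function(b) sample.int(24L)))
  out <- conds[idx[seq_len(n)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Observation channel names
#'
#' Eleven input channels: the fixation spot, one sample channel per
#' group, and sided channels for the two choice pairs of each group.  In
#' an ABC trial these are exactly (fixation, A1, A2, B1-left, B1-right,
#' B2-left, B2-right, C1-left, C1-right, C2-left, C2-right); in BCA/CAB
#' trials the same role channels carry the stimulus actually presented
#' there, with values coding stimulus identity (A = 2, B = 3, C = 4;
#' fixation = 1).
#'
#' @return Character vector of length 11.
#' @export
observation_channels <- function() {
  c("fixation", "sample_g1", "sample_g2",
    "pair1_g1_L", "pair1_g1_R", "pair1_g2_L", "pair1_g2_R",
    "pair2_g1_L", "pair2_g1_R", "pair2_g2_L", "pair2_g2_R")
}

#' Full observation matrix of one trial
#'
#' Observations do not depend on the agent's actions while the trial is
#' alive, so the whole 11 x n_steps input matrix can be precomputed.
#' The fixation channel is 1 at every step; the sample stimulus drives
#' its group's sample channel during the first stimulus period; each
#' choice pair drives one left and one right channel (target on the
#' trial's `pos` side, distractor opposite) during its stimulus period.
#'
#' @param spec One-row data frame (or list) with `order`, `group`,
#'   `pos1`, `pos2`.
#' @param schedule An [build_schedule()] result.
#' @return Numeric matrix 11 x `schedule$n_steps`.
#' @export
trial_observation_matrix <- function(spec, schedule = build_schedule()) {
  u <- matrix(0, 11L, schedule$n_steps,
              dimnames = list(observation_channels(), NULL))
  u["fixation", ] <- 1
  letters3 <- .ORDER_LETTERS[[spec$order]]
  vals <- .LETTER_VALUE[letters3]
  p <- schedule$periods
  rng <- function(name) (p$start[p$name == name] + 1L):p$end[p$name == name]
  g <- spec$group
  other <- 3L - g
  # sample
  u[1L + g, rng("first_stimulus")] <- vals[1]
  # first choice pair: target = group's own stimulus on side pos1
  tgt1 <- paste0("pair1_g", g, "_", spec$pos1)
  dis1 <- paste0("pair1_g", other, "_", if (spec$pos1 == "L") "R" else "L")
  u[tgt1, rng("second_stimulus")] <- vals[2]
  u[dis1, rng("second_stimulus")] <- vals[2]
  # second choice pair
  tgt2 <- paste0("pair2_g", g, "_", spec$pos2)
  dis2 <- paste0("pair2_g", other, "_", if (spec$pos2 == "L") "R" else "L")
  u[tgt2, rng("third_stimulus")] <- vals[3]
  u[dis2, rng("third_stimulus")] <- vals[3]
  u
}

#' Single-step observation
#'
#' @param spec Trial specification row.
#' @param schedule Event schedule.
#' @param state A `trial_state` (see [trial_state()]); only used for the
#'   step index and alive flag.
#' @return Numeric vector of 11 channel values (zeros once the trial has
#'   terminated).
#' @export
observe <- function(spec, schedule, state) {
  if (!state$alive) return(stats::setNames(numeric(11L), observation_channels()))
  trial_observation_matrix(spec, schedule)[, state$t + 1L]
}

#' Fresh per-trial state
#'
#' @param schedule Event schedule (used only for labelling).
#' @return A `trial_state` list: step index `t` (0-based), period label,
#'   `alive`, `first_choice`/`second_choice` in none/L/R, and the
#'   realised reward history.
#' @export
trial_state <- function(schedule = build_schedule()) {
  structure(list(t = 0L, period = "initial_fixation", alive = TRUE,
                 first_choice = "none", second_choice = "none",
                 rewards = numeric(0)),
            class = "trial_state")
}

#' Advance the task environment by one step
#'
#' Implements the full reward schedule: left/right outside a decision
#' window breaks fixation (reward -1, trial terminated); fixation
#' elsewhere is reward 0; the first left/right inside a decision window
#' is the choice (+1 if it matches the target side; a wrong first choice
#' gives -1 and terminates, a wrong second choice gives 0 and the trial
#' runs on to its end); letting either decision window expire without a
#' choice gives -1 and terminates (for the first window this is the
#' configurable `timeout1_reward`); the terminal step ends the trial
#' with reward 0.  After the first choice the agent has committed:
#' left/right actions are ignored until the second decision window
#' (the policy cannot observe its own past action, so a per-step
#' re-fixation requirement after the choice saccade would be
#' unsatisfiable by the stated architecture).  Rewards are credited at
#' the following time index.
#'
#' @param spec Trial specification row.
#' @param schedule Event schedule.
#' @param state Current `trial_state` (must be alive).
#' @param action One of `"F"`, `"L"`, `"R"`.
#' @param timeout1_reward Reward when the first decision window expires
#'   with no choice.
#' @return List with the updated `state` and an `outcome` list
#'   (`reward`, `done`, `event`).
#' @export
task_step <- function(spec, schedule, state, action, timeout1_reward = -1) {
  if (!state$alive) stop("task_step on a terminated trial", call. = FALSE)
  if (!action %in% c("F", "L", "R")) stop("unknown action", call. = FALSE)
  t <- state$t
  pid <- schedule$period_of[t + 1L]
  reward <- 0
  done <- FALSE
  event <- "ok-fixation"

  if (pid == 0L) {                       # terminal step
    done <- TRUE
    event <- "trial-end"
  } else if (pid == .PERIOD["first_decision"]) {
    last <- schedule$periods$end[.PERIOD["first_decision"]] - 1L
    if (state$first_choice == "none" && action != "F") {
      state$first_choice <- action
      if (action == spec$pos1) {
        reward <- 1; event <- "correct-choice-1"
      } else {
        reward <- -1; done <- TRUE; event <- "wrong-choice-1"
      }
    } else if (state$first_choice == "none" && t == last) {
      reward <- timeout1_reward; done <- TRUE; event <- "no-choice-1"
    }
  } else if (pid == .PERIOD["second_decision"]) {
    last <- schedule$periods$end[.PERIOD["second_decision"]] - 1L
    if (state$second_choice == "none" && action != "F") {
      state$second_choice <- action
      if (action == spec$pos2) {
        reward <- 1; event <- "correct-choice-2"
      } else {
        reward <- 0; event <- "wrong-choice-2"
      }
    } else if (state$second_choice == "none" && t == last) {
      reward <- -1; done <- TRUE; event <- "no-choice-2"
    }
  } else if (action != "F" && state$first_choice == "none") {
    # left/right before the first choice breaks fixation; after the
    # first choice the agent has committed (its gaze rests on the
    # chosen target, and the policy cannot observe its own past
    # action), so left/right is ignored until the second window
    reward <- -1; done <- TRUE; event <- "break-fixation"
  }

  state$rewards <- c(state$rewards, reward)
  state$t <- t + 1L
  state$alive <- !done
  nxt <- schedule$period_of[min(state$t, schedule$n_steps - 1L) + 1L]
  state$period <- if (nxt == 0L) "trial-end" else schedule$periods$name[nxt]
  list(state = state, outcome = list(reward = reward, done = done,
                                     event = event))
}

#' Run one trial under a scripted or functional policy
#'
#' Convenience driver for tests and oracles: steps the environment with
#' actions supplied either as a character vector (recycled as needed) or
#' a function `f(state, observation)` returning an action.
#'
#' @inheritParams task_step
#' @param policy Character vector of actions or a function.
#' @return List with `return` (summed reward), `length` (number of
#'   action steps taken), `events` and the final `state`.
#' @export
run_scripted_trial <- function(spec, policy, schedule = build_schedule(),
                               timeout1_reward = -1) {
  state <- trial_state(schedule)
  events <- character(0)
  k <- 0L
  while (state$alive) {
    k <- k + 1L
    a <- if (is.function(policy)) {
      policy(state, observe(spec, schedule, state))
    } else {
      policy[(k - 1L) %% length(policy) + 1L]
    }
    res <- task_step(spec, schedule, state, a, timeout1_reward)
    state <- res$state
    events <- c(events, res$outcome$event)
  }
  list(return = sum(state$rewards), length = state$t,
       events = events, state = state)
}
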