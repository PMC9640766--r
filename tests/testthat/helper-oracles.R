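# Independent oracles used across the test files.  These are written
# as explicit loops over pairs / conditions, deliberately unrelated to
# the package's vectorised implementations.

# brute-force category index: explicit loops over all stimulus pairs
brute_ci <- function(means) {
  g1 <- means[1:3]; g2 <- means[4:6]
  within <- c()
  for (g in list(g1, g2)) {
    for (i in 1:2) for (j in (i + 1):3) {
      within <- c(within, abs(g[i] - g[j]))
    }
  }
  between <- c()
  for (i in 1:3) for (j in 1:3) between <- c(between, abs(g1[i] - g2[j]))
  wcd <- mean(within); bcd <- mean(between)
  if (bcd + wcd == 0) return(NA_real_)
  (bcd - wcd) / (bcd + wcd)
}

# brute-force stimulus index
brute_si <- function(means) {
  comp <- function(g) {
    if (max(g) + min(g) == 0) return(NA_real_)
    (max(g) - min(g)) / (max(g) + min(g))
  }
  (comp(means[1:3]) + comp(means[4:6])) / 2
}

# scripted policies for the environment oracle
script_always_f <- function(state, obs) "F"

script_optimal <- function(spec) {
  force(spec)
  function(state, obs) {
    if (state$period == "first_decision" && state$first_choice == "none") {
      return(spec$pos1)
    }
    if (state$period == "second_decision" && state$second_choice == "none") {
      return(spec$pos2)
    }
    "F"
  }
}

script_wrong_first <- function(spec) {
  force(spec)
  function(state, obs) {
    if (state$period == "first_decision" && state$first_choice == "none") {
      return(if (spec$pos1 == "L") "R" else "L")
    }
    "F"
  }
}

script_wrong_second <- function(spec) {
  force(spec)
  function(state, obs) {
    if (state$period == "first_decision" && state$first_choice == "none") {
      return(spec$pos1)
    }
    if (state$period == "second_decision" && state$second_choice == "none") {
      return(if (spec$pos2 == "L") "R" else "L")
    }
    "F"
  }
}

script_break_at <- function(step) {
  force(step)
  function(state, obs) if (state$t == step) "L" else "F"
}

# hand-written lookup for the scripted families, built from the period
# arithmetic (dt = 20): decision-1 window is steps 85..89, decision-2
# window 115..119, terminal step 120.
oracle_expectations <- function(timeout1_reward = -1) {
  list(
    always_f = list(ret = timeout1_reward, len = 90),
    optimal = list(ret = 2, len = 121),
    wrong_first = list(ret = -1, len = 86),
    wrong_second = list(ret = 1, len = 121),
    break_initial = list(ret = -1, len = 6),      # break at step 5
    break_delay = list(ret = -1, len = 61),       # break at step 60
    press_midfix = list(ret = 2, len = 121),      # post-choice press ignored
    press_stim3 = list(ret = 2, len = 121),       # post-choice press ignored
    break_stim2 = list(ret = -1, len = 81)        # anticipatory press
  )
}

# small agent + schedule used in several gradient tests
tiny_setup <- function(seed = 42, n_policy = 5, n_value = 4, B = 3) {
  set.seed(seed)
  cfg <- agent_config(n_policy = n_policy, n_value = n_value,
                      fixation_bias = 0)
  tim <- task_timing(durations = c(initial_fixation = 40,
                                   first_stimulus = 40, first_delay = 40,
                                   second_stimulus = 20, first_decision = 60,
                                   mid_fixation = 40, third_stimulus = 20,
                                   second_decision = 60))
  sch <- build_schedule(tim)
  agent <- init_agent(cfg)
  specs <- sample_trials(B)
  list(agent = agent, schedule = sch, specs = specs, config = cfg)
}

# finite-difference check helper: compares analytic gradients with
# central differences of `loss(agent)` over a sample of parameters.
# h = 1e-4 balances truncation (~h^2) against round-off (~eps/h) for
# losses of order one, keeping both well below the 1e-5 tolerance.
fd_max_rel_err <- function(agent, loss, grads, n_each = 3, h = 1e-4) {
  worst <- 0
  for (nm in names(grads)) {
    flat <- agent_trainable(agent)
    g <- grads[[nm]]
    idx <- sample(seq_along(flat[[nm]]), min(n_each, length(flat[[nm]])))
    for (i in idx) {
      if (grepl("^(p|v)\\.(W_rec|W_in)", nm)) {
        mk <- if (grepl("W_rec", nm)) "M_rec" else "M_in"
        net <- if (grepl("^p\\.", nm)) agent$policy else agent$value
        if (net[[mk]][i] == 0) next
      }
      f1 <- agent_trainable(agent); f1[[nm]][i] <- f1[[nm]][i] + h
      f2 <- agent_trainable(agent); f2[[nm]][i] <- f2[[nm]][i] - h
      num <- (loss(agent_set_trainable(agent, f1)) -
                loss(agent_set_trainable(agent, f2))) / (2 * h)
      an <- g[i]
      rel <- abs(num - an) / max(1e-6, abs(num), abs(an))
      worst <- max(worst, rel)
    }
  }
  worst
}
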