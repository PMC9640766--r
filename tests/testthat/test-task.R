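test_that("schedule arithmetic: periods tile the 2,400 ms trial", {
  tim <- task_timing()
  expect_equal(sum(tim$durations), 2400)
  sch <- build_schedule(tim)
  # 121 time points: steps 0..119 carry the eight periods, step 120 ends
  expect_equal(sch$n_steps, 121L)
  expect_equal(sch$periods$start, c(0L, cumsum(tim$durations / 20)[-8]),
               ignore_attr = TRUE)
  expect_equal(sch$periods$end[8], 120L)
  # contiguity / no overlap
  expect_equal(sch$periods$start[-1], sch$periods$end[-8])
  # initial fixation [0,30), first stimulus [30,50)
  expect_equal(unlist(sch$periods[sch$periods$name == "initial_fixation",
                                  c("start", "end")]),
               c(start = 0L, end = 30L))
  expect_equal(unlist(sch$periods[sch$periods$name == "first_stimulus",
                                  c("start", "end")]),
               c(start = 30L, end = 50L))
  # both decision windows are 5 steps
  dec <- sch$periods[grepl("decision", sch$periods$name), ]
  expect_equal(dec$end - dec$start, c(5L, 5L))
  # non-divisible durations rejected
  expect_error(task_timing(dt = 2400), "divisible")
  expect_error(task_timing(dt = 7), "divisible")
})

test_that("condition space has 24 balanced conditions and seeded sampling", {
  conds <- trial_conditions()
  expect_equal(nrow(conds), 24L)
  expect_equal(nrow(unique(conds)), 24L)
  set.seed(7)
  one_block <- sample_trials(24)
  key <- function(df) paste(df$order, df$group, df$pos1, df$pos2)
  expect_setequal(key(one_block), key(conds))
  # block balance over 240 trials: each order appears 80 times
  set.seed(8)
  many <- sample_trials(240)
  expect_equal(as.vector(table(many$order)), c(80, 80, 80))
  # determinism under seed
  set.seed(99); a <- sample_trials(48)
  set.seed(99); b <- sample_trials(48)
  expect_identical(a, b)
})

test_that("observations carry the stimulus code on the right channels", {
  sch <- build_schedule()
  spec <- list(order = "ABC", group = 1, pos1 = "L", pos2 = "R")
  u <- trial_observation_matrix(spec, sch)
  expect_true(all(u["fixation", ] == 1))
  # first stimulus period: A1 sample channel = 2, others silent
  expect_equal(unname(u["sample_g1", 35]), 2)
  expect_equal(sum(u[-1, 35] != 0), 1)
  # first delay: fixation only
  expect_equal(sum(u[, 60] != 0), 1)
  # second stimulus, target left: B1 left and B2 right, value 3
  expect_equal(unname(u["pair1_g1_L", 80]), 3)
  expect_equal(unname(u["pair1_g2_R", 80]), 3)
  expect_equal(sum(u[, 80] != 0), 3)
  # third stimulus, target right: C1 right and C2 left, value 4
  expect_equal(unname(u["pair2_g1_R", 110]), 4)
  expect_equal(unname(u["pair2_g2_L", 110]), 4)
  # channel magnitudes never exceed their stimulus code
  expect_true(all(u %in% c(0, 1, 2, 3, 4)))
})

test_that("non-ABC orders present identity codes in role channels", {
  sch <- build_schedule()
  spec <- list(order = "BCA", group = 2, pos1 = "R", pos2 = "L")
  u <- trial_observation_matrix(spec, sch)
  # sample is B2 -> value 3 on the group-2 sample channel
  expect_equal(unname(u["sample_g2", 35]), 3)
  # first pair is C1/C2 -> value 4; C2 (own group) on the right
  expect_equal(unname(u["pair1_g2_R", 80]), 4)
  expect_equal(unname(u["pair1_g1_L", 80]), 4)
  # second pair is A1/A2 -> value 2; A2 on the left
  expect_equal(unname(u["pair2_g2_L", 110]), 2)
  expect_equal(unname(u["pair2_g1_R", 110]), 2)
})

test_that("observation stream identifies the trial uniquely", {
  sch <- build_schedule()
  conds <- trial_conditions()
  sigs <- apply(conds, 1, function(row) {
    spec <- list(order = row[["order"]], group = as.integer(row[["group"]]),
                 pos1 = row[["pos1"]], pos2 = row[["pos2"]])
    paste(trial_observation_matrix(spec, sch), collapse = ",")
  })
  expect_equal(length(unique(sigs)), 24L)
})

test_that("reward schedule follows the task rules step by step", {
  sch <- build_schedule()
  spec <- list(order = "ABC", group = 1, pos1 = "L", pos2 = "R")
  st <- trial_state(sch)
  # fixation during a stimulus period: reward 0, trial continues
  for (i in 1:40) {
    res <- task_step(spec, sch, st, "F")
    st <- res$state
    expect_equal(res$outcome$reward, 0)
    expect_false(res$outcome$done)
  }
  # left during first delay: -1 and terminated
  res <- task_step(spec, sch, st, "L")
  expect_equal(res$outcome$reward, -1)
  expect_true(res$outcome$done)
  expect_equal(res$outcome$event, "break-fixation")
  expect_error(task_step(spec, sch, res$state, "F"), "terminated")
  expect_error(task_step(spec, sch, trial_state(sch), "X"), "unknown")
})

test_that("environment oracle: all 24 conditions x scripted families", {
  sch <- build_schedule()
  conds <- trial_conditions()
  exp <- oracle_expectations(timeout1_reward = -1)
  for (r in seq_len(nrow(conds))) {
    spec <- conds[r, ]
    runs <- list(
      always_f = run_scripted_trial(spec, script_always_f, sch),
      optimal = run_scripted_trial(spec, script_optimal(spec), sch),
      wrong_first = run_scripted_trial(spec, script_wrong_first(spec), sch),
      wrong_second = run_scripted_trial(spec, script_wrong_second(spec), sch),
      break_initial = run_scripted_trial(spec, script_break_at(5), sch),
      break_delay = run_scripted_trial(spec, script_break_at(60), sch),
      press_midfix = run_scripted_trial(spec, {
        pol <- script_optimal(spec)
        function(state, obs) if (state$t == 95) "L" else pol(state, obs)
      }, sch),
      press_stim3 = run_scripted_trial(spec, {
        pol <- script_optimal(spec)
        function(state, obs) if (state$t == 108) "L" else pol(state, obs)
      }, sch),
      break_stim2 = run_scripted_trial(spec, script_break_at(80), sch))
    for (nm in names(runs)) {
      expect_equal(runs[[nm]]$return, exp[[nm]]$ret,
                   label = paste(nm, "return, condition", r))
      expect_equal(runs[[nm]]$length, exp[[nm]]$len,
                   label = paste(nm, "length, condition", r))
    }
  }
})

test_that("returns are bounded by +2 and -1 per episode", {
  sch <- build_schedule()
  conds <- trial_conditions()
  set.seed(3)
  for (i in 1:30) {
    spec <- conds[sample.int(24, 1), ]
    pol <- function(state, obs) sample(c("F", "F", "F", "F", "L", "R"), 1)
    run <- run_scripted_trial(spec, pol, sch)
    expect_true(run$return %in% c(-1, 0, 1, 2))
    expect_lte(run$return, 2)
    if (run$return == -1) expect_lt(run$length, 121)
  }
})
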