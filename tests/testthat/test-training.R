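test_that("advantages follow their definitions", {
  setup <- tiny_setup(seed = 1, B = 3)
  set.seed(2)
  ro <- rollout_batch(setup$agent, setup$specs, setup$schedule, cache = TRUE)
  # whole-episode mode: return 2 with zero predictions -> 2 everywhere
  ro0 <- ro
  ro0$values[] <- 0
  adv <- compute_advantage(ro0, "episode")
  for (b in seq_len(3)) {
    expect_equal(unique(adv[b, ro0$taken[b, ]]), ro0$returns[b])
  }
  # prediction equal to the return -> zero advantage
  rop <- ro
  rop$values <- matrix(ro$returns, ro$n_trials, ro$n_steps)
  expect_true(all(compute_advantage(rop, "episode") == 0))
  # hand case: return -1, v = (0.5, -0.5) -> (-1.5, -0.5)
  ro2 <- ro
  ro2$taken[] <- FALSE; ro2$taken[1, 1:2] <- TRUE
  ro2$rewards[] <- 0; ro2$rewards[1, 2] <- -1
  ro2$returns <- rowSums(ro2$rewards)
  ro2$values[] <- 0; ro2$values[1, 1:2] <- c(0.5, -0.5)
  adv <- compute_advantage(ro2, "episode")
  expect_equal(adv[1, 1:2], c(-1.5, -0.5))
  # return-to-go: reverse cumulative sums of the rewards
  adv3 <- compute_advantage(ro2, "return_to_go")
  expect_equal(adv3[1, 1:2], c(-1 - 0.5, -1 + 0.5))
})

test_that("value objective matches the per-trial mean squared error", {
  setup <- tiny_setup(seed = 3, B = 2)
  set.seed(4)
  ro <- rollout_batch(setup$agent, setup$specs, setup$schedule, cache = TRUE)
  # perfect predictions -> objective 0
  rop <- ro
  rop$values <- categru:::return_targets(ro, "return_to_go")
  vo <- value_objective(setup$agent, rop)
  expect_equal(vo$objective, 0)
  # hand case (immediate-reward target): full-length trial, v = 0,
  # one +1 at the last step -> M_n = 1/(T+1)
  TT <- ro$n_steps
  roh <- ro
  roh$taken[] <- TRUE
  roh$lengths <- rep(TT, 2)
  roh$values[] <- 0
  roh$rewards[] <- 0; roh$rewards[, TT] <- 1
  voh <- value_objective(setup$agent, roh, target = "reward")
  expect_equal(voh$per_trial, rep(1 / TT, 2))
  # the objective is nonnegative, zero only at exact fit
  expect_gte(value_objective(setup$agent, ro)$objective, 0)
})

test_that("policy surrogate gradient scales linearly in the advantage", {
  setup <- tiny_setup(seed = 5, B = 3)
  set.seed(6)
  ro <- rollout_batch(setup$agent, setup$specs, setup$schedule, cache = TRUE)
  adv <- compute_advantage(ro, "return_to_go")
  g1 <- policy_objective(setup$agent, ro, adv)$grads
  g2 <- policy_objective(setup$agent, ro, 2 * adv)$grads
  for (nm in names(g1)) expect_equal(g2[[nm]], 2 * g1[[nm]])
  g0 <- policy_objective(setup$agent, ro, adv * 0)$grads
  expect_true(all(vapply(g0, function(g) all(g == 0), logical(1))))
})

test_that("analytic gradients match central finite differences", {
  setup <- tiny_setup(seed = 42, B = 3)
  agent <- setup$agent
  specs <- setup$specs
  sch <- setup$schedule
  run <- function(ag, scripted = NULL) {
    set.seed(7)
    rollout_batch(ag, specs, sch, noise_on = TRUE, cache = TRUE,
                  scripted = scripted)
  }
  ro <- run(agent)
  adv <- compute_advantage(ro, "return_to_go")
  po <- policy_objective(agent, ro, adv)
  vo <- value_objective(agent, ro)
  A <- ro$actions
  w <- adv * ro$taken / ro$n_trials
  loss_pi <- function(ag) {
    r <- run(ag, scripted = A)
    -sum(r$logp * w)
  }
  loss_v <- function(ag) {
    r <- run(ag, scripted = A)
    tgt <- categru:::return_targets(r, "return_to_go")
    err <- (r$values - tgt) * r$taken
    mean(rowSums(err^2) / r$lengths)
  }
  set.seed(99)
  expect_lt(fd_max_rel_err(agent, loss_pi, po$grads, n_each = 3), 1e-5)
  expect_lt(fd_max_rel_err(agent, loss_v, vo$grads, n_each = 3), 1e-5)
})

test_that("compiled and reference engines agree to machine precision", {
  setup <- tiny_setup(seed = 13, B = 4)
  set.seed(17); ro_c <- rollout_batch(setup$agent, setup$specs,
                                      setup$schedule, cache = TRUE,
                                      engine = "cpp")
  set.seed(17); ro_r <- rollout_batch(setup$agent, setup$specs,
                                      setup$schedule, cache = TRUE,
                                      engine = "r")
  expect_equal(ro_c$rates, ro_r$rates, tolerance = 1e-14)
  expect_equal(ro_c$values, ro_r$values, tolerance = 1e-14)
  expect_identical(ro_c$actions, ro_r$actions)
  expect_equal(ro_c$rewards, ro_r$rewards)
  expect_identical(ro_c$lengths, ro_r$lengths)
  adv <- compute_advantage(ro_c)
  pc <- policy_objective(setup$agent, ro_c, adv, engine = "cpp")$grads
  pr <- policy_objective(setup$agent, ro_r, adv, engine = "r")$grads
  for (nm in names(pc)) expect_equal(pc[[nm]], pr[[nm]], tolerance = 1e-12,
                                     ignore_attr = TRUE)
  vc <- value_objective(setup$agent, ro_c, engine = "cpp")$grads
  vr <- value_objective(setup$agent, ro_r, engine = "r")$grads
  for (nm in names(vc)) expect_equal(vc[[nm]], vr[[nm]], tolerance = 1e-12,
                                     ignore_attr = TRUE)
})

test_that("optimiser honours degenerate settings and rejects bad gradients", {
  set.seed(8)
  flat <- list(w = matrix(stats::rnorm(4), 2, 2), b = stats::rnorm(2))
  grads <- list(w = matrix(1, 2, 2), b = c(1, 1))
  # zero learning rate leaves parameters unchanged
  st <- optim_init(flat, "adam")
  res <- optim_step(flat, grads, st, lr = 0)
  expect_equal(res$flat, flat)
  # zero gradient leaves parameters unchanged in plain-descent mode
  st <- optim_init(flat, "sgd")
  res <- optim_step(flat, list(w = matrix(0, 2, 2), b = c(0, 0)), st)
  expect_equal(res$flat, flat)
  # non-finite gradients abort with a diagnostic
  expect_error(optim_step(flat, list(w = matrix(NaN, 2, 2), b = c(0, 0)),
                          optim_init(flat)), "non-finite")
  # clipping: norms above the bound are rescaled onto it
  big <- list(a = matrix(10, 3, 3))
  clipped <- clip_global_norm(big, 1)
  expect_equal(sqrt(sum(clipped$a^2)), 1)
  small <- list(a = matrix(0.01, 2, 2))
  expect_equal(clip_global_norm(small, 1), small)
})

test_that("scripted rollouts reproduce the task oracle inside the loop", {
  set.seed(10)
  agent <- init_agent(agent_config(n_policy = 8, n_value = 6))
  sch <- build_schedule()
  specs <- sample_trials(4)
  TT <- sch$n_steps
  # always-F script: -1 at the first decision timeout, length 90
  ro <- rollout_batch(agent, specs, sch, cache = FALSE,
                      scripted = matrix(1L, 4, TT))
  expect_equal(ro$returns, rep(-1, 4))
  expect_equal(ro$lengths, rep(90L, 4))
  # optimal script: return 2, full length
  opt <- matrix(1L, 4, TT)
  opt[, 86] <- ifelse(specs$pos1 == "L", 2L, 3L)
  opt[, 116] <- ifelse(specs$pos2 == "L", 2L, 3L)
  ro <- rollout_batch(agent, specs, sch, cache = FALSE, scripted = opt)
  expect_equal(ro$returns, rep(2, 4))
  expect_equal(ro$lengths, rep(121L, 4))
  expect_true(all(ro$correct_trial))
  # same seeds give identical trajectories
  set.seed(12); a <- rollout_batch(agent, specs, sch)
  set.seed(12); b <- rollout_batch(agent, specs, sch)
  expect_equal(a$rates, b$rates)
  expect_identical(a$actions, b$actions)
})

test_that("learning sanity: one-decision bandit converges to the target", {
  # degenerate bandit: a short trial whose target side is always left,
  # so the first decision is a two-armed bandit with reward +1 for L
  # and -1 for R; the policy should converge onto the rewarded action
  tim <- task_timing(durations = c(initial_fixation = 40,
                                   first_stimulus = 40, first_delay = 20,
                                   second_stimulus = 20, first_decision = 100,
                                   mid_fixation = 20, third_stimulus = 20,
                                   second_decision = 100))
  sch <- build_schedule(tim)
  set.seed(4)
  cfg <- agent_config(n_policy = 16, n_value = 8, fixation_bias = 2)
  agent <- init_agent(cfg)
  specs <- trial_conditions()
  specs$pos1 <- "L"; specs$pos2 <- "L"
  opts <- train_schedule()
  flat <- agent_trainable(agent)
  pn <- grep("^p\\.", names(flat), value = TRUE)
  vn <- grep("^v\\.", names(flat), value = TRUE)
  sp <- optim_init(flat[pn]); sv <- optim_init(flat[vn])
  for (i in 1:250) {
    ro <- rollout_batch(agent, specs, sch, cache = TRUE)
    adv <- compute_advantage(ro, "return_to_go")
    po <- policy_objective(agent, ro, adv)
    vo <- value_objective(agent, ro)
    rp <- optim_step(flat[pn], clip_global_norm(po$grads), sp, lr = 0.003)
    rv <- optim_step(flat[vn], clip_global_norm(vo$grads), sv, lr = 0.01)
    flat[pn] <- rp$flat; sp <- rp$state
    flat[vn] <- rv$flat; sv <- rv$state
    agent <- agent_set_trainable(agent, flat)
  }
  ro <- rollout_batch(agent, specs[rep(1:24, 4), ], sch, cache = FALSE)
  expect_gt(mean(ro$first_correct), 0.8)
  expect_gt(mean(ro$first_correct), mean(ro$correct_trial) - 1e-9)
})
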