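# Training: alternating learn blocks (parameter updates every 24-trial
# batch) and frozen-parameter test blocks, with a correct-rate
# convergence criterion.

#' Training schedule and learning options
#'
#' @param lr Actor (policy network) learning rate.
#' @param lr_value Critic (value network) learning rate.  The critic
#'   is trained an order of magnitude faster than the actor by
#'   default, so newly discovered rewards are priced into the baseline
#'   before the actor can commit to blind side habits.
#' @param n_trials Trials per parameter update (one iteration).
#' @param learn_block Iterations per learning block.
#' @param test_trials Trials per frozen-parameter test block.
#' @param criterion Correct-trial rate (both choices correct) that ends
#'   training.
#' @param max_iter Iteration cap.
#' @param optimizer `"adam"` (default, for stable convergence) or
#'   `"sgd"` (plain gradient descent).
#' @param adam_eps Adam denominator constant.
#' @param clip Global gradient-norm clip, applied per network.
#' @param advantage_mode `"return_to_go"` (default) or `"episode"`
#'   (whole-trial return); see [compute_advantage()].
#' @param value_target `"return_to_go"` (default) or `"reward"`
#'   (immediate reward); see [value_objective()].
#' @param fixed_T_norm Normalise the value error by the full trial
#'   length rather than the realised length.
#' @param timeout1_reward Reward when the first decision window expires
#'   unanswered.
#' @param critic_action Action one-hot the critic sees: `"current"`
#'   (default, the literal same-step form) or `"previous"` (a strictly
#'   action-independent baseline).  See [rollout_batch()].
#' @param eval_chunk Batch size used inside test blocks.
#' @return A `train_schedule` list.
#' @export
train_schedule <- function(lr = 0.001, lr_value = 0.01, n_trials = 24,
                           learn_block = 50,
                           test_trials = 800, criterion = 0.98,
                           max_iter = 2000, optimizer = c("adam", "sgd"),
                           adam_eps = 1e-8, clip = 1,
                           advantage_mode = c("return_to_go", "episode"),
                           value_target = c("return_to_go", "reward"),
                           fixed_T_norm = FALSE,
                           timeout1_reward = -1,
                           critic_action = c("current", "previous"),
                           eval_chunk = 200) {
  structure(list(lr = lr, lr_value = lr_value,
                 n_trials = as.integer(n_trials),
                 learn_block = as.integer(learn_block),
                 test_trials = as.integer(test_trials),
                 criterion = criterion, max_iter = as.integer(max_iter),
                 optimizer = match.arg(optimizer), adam_eps = adam_eps,
                 clip = clip,
                 advantage_mode = match.arg(advantage_mode),
                 value_target = match.arg(value_target),
                 fixed_T_norm = fixed_T_norm,
                 timeout1_reward = timeout1_reward,
                 critic_action = match.arg(critic_action),
                 eval_chunk = as.integer(eval_chunk)),
            class = "train_schedule")
}

# deterministic sub-seeds for the named rng streams
derive_seed <- function(master, k) {
  (as.numeric(master) * 7919 + k * 104729) %% 2147483646 + 1
}

# evaluate `expr` under the rng state of stream `name`, saving it back
with_stream <- function(streams, name, expr) {
  saved <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", streams[[name]], globalenv())
  on.exit({
    streams[[name]] <- get(".Random.seed", globalenv())
    if (!is.null(saved)) assign(".Random.seed", saved, globalenv())
  })
  expr
}

make_streams <- function(master, names) {
  streams <- new.env(parent = emptyenv())
  for (i in seq_along(names)) {
    set.seed(derive_seed(master, i))
    streams[[names[i]]] <- get(".Random.seed", globalenv())
  }
  streams
}

#' Evaluate an agent over frozen-parameter test trials
#'
#' Runs `n_trials` trials (balanced blocks of the 24 conditions) with
#' frozen parameters, stochastic action sampling and process noise, in
#' batched chunks.  Optionally records the per-trial window-averaged
#' firing rates of every policy-layer neuron for the analysis suite.
#'
#' @param agent An agent.
#' @param n_trials Number of test trials.
#' @param schedule Event schedule.
#' @param opts A [train_schedule()] (for chunking and task options).
#' @param record Keep per-trial neuron rates and trial metadata?
#' @return A list with `behaviour` (first-choice rate, correct-trial
#'   rate, mean reward, value MSE at the second choice) and, when
#'   `record = TRUE`, `trials` (per-trial metadata), `win_rates`
#'   (trial x neuron x window array), `trace_first` (neuron x step mean
#'   rates over the first stimulus period, correct trials),
#'   `max_rate` (per-neuron maximum over all steps and trials).
#' @export
evaluate_agent <- function(agent, n_trials = 800,
                           schedule = build_schedule(),
                           opts = train_schedule(), record = FALSE) {
  wins <- analysis_windows(schedule)
  np <- agent$config$n_policy
  n_first <- length(wins$steps$first_stimulus)
  tot <- list(first = 0, both = 0, reward = 0, mse2_num = 0, mse2_den = 0)
  trials <- list(); win_rates <- list()
  trace_sum <- matrix(0, np, n_first); trace_n <- 0
  max_rate <- numeric(np)
  done <- 0L
  while (done < n_trials) {
    B <- min(opts$eval_chunk, n_trials - done)
    specs <- sample_trials(B)
    ro <- rollout_batch(agent, specs, schedule, noise_on = TRUE,
                        cache = FALSE, timeout1_reward = opts$timeout1_reward,
                        critic_action = opts$critic_action)
    tot$first <- tot$first + sum(ro$first_correct)
    tot$both <- tot$both + sum(ro$correct_trial)
    tot$reward <- tot$reward + sum(ro$returns)
    has2 <- !is.na(ro$choice2_step)
    if (any(has2)) {
      idx <- cbind(which(has2), ro$choice2_step[has2])
      err2 <- ro$rewards[idx] - ro$values[idx]
      tot$mse2_num <- tot$mse2_num + sum(err2^2)
      tot$mse2_den <- tot$mse2_den + sum(has2)
    }
    if (record) {
      wr <- array(0, c(B, np, length(wins$names)),
                  dimnames = list(NULL, NULL, wins$names))
      for (w in seq_along(wins$names)) {
        st <- wins$steps[[w]]
        wr[, , w] <- t(apply(ro$rates[, , st, drop = FALSE], c(1, 2), mean))
      }
      win_rates[[length(win_rates) + 1L]] <- wr
      df <- ro$specs
      df$first_letter <- vapply(df$order, function(o) .ORDER_LETTERS[[o]][1],
                                character(1))
      df$first_correct <- ro$first_correct
      df$correct <- ro$correct_trial
      df$first_choice_side <- c("none", "L", "R")[
        1L + pmax(ro$first_choice - 1L, 0L)]
      df$return <- ro$returns
      df$length <- ro$lengths
      trials[[length(trials) + 1L]] <- df
      ok <- ro$correct_trial
      if (any(ok)) {
        fs <- ro$rates[, ok, wins$steps$first_stimulus, drop = FALSE]
        trace_sum <- trace_sum + apply(fs, c(1, 3), sum)
        trace_n <- trace_n + sum(ok)
      }
      max_rate <- pmax(max_rate, apply(ro$rates, 1, max))
    }
    done <- done + B
  }
  out <- list(behaviour = list(
    n_trials = n_trials,
    first_rate = tot$first / n_trials,
    correct_rate = tot$both / n_trials,
    mean_reward = tot$reward / n_trials,
    value_mse2 = if (tot$mse2_den > 0) tot$mse2_num / tot$mse2_den else NA_real_))
  if (record) {
    out$trials <- do.call(rbind, trials)
    out$win_rates <- do.call(function(...) abind_first(list(...)), win_rates)
    out$trace_first <- trace_sum / max(trace_n, 1)
    out$max_rate <- max_rate
  }
  out
}

# rbind 3-d arrays along the first dimension (no external deps)
abind_first <- function(lst) {
  if (length(lst) == 1L) return(lst[[1L]])
  d <- dim(lst[[1L]])
  n <- sum(vapply(lst, function(a) dim(a)[1], numeric(1)))
  out <- array(0, c(n, d[2], d[3]), dimnames = c(list(NULL), dimnames(lst[[1]])[2:3]))
  at <- 0L
  for (a in lst) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Train the agent on the sequential paired-association task
#'
#' Alternates learning blocks (`learn_block` iterations of one
#' 24-trial batched policy-gradient update each) with frozen-parameter
#' test blocks, and stops once the test-block correct-trial rate
#' reaches the criterion or the iteration cap is hit.  All randomness
#' is derived from `seed` through named sub-streams (initialisation,
#' task condition sampling, simulation noise/action sampling, and
#' evaluation).
#'
#' @param seed Master seed.
#' @param config An [agent_config()].
#' @param opts A [train_schedule()].
#' @param schedule Event schedule.
#' @param verbose Print a line per test block?
#' @return A `categru_fit` list: final `agent`, `init_params`, the
#'   per-test-block `history` data frame, `checkpoints` (per-block
#'   condition-mean rate summaries for time-course analyses),
#'   `final_record` (detailed last test-block recording), `converged`,
#'   `n_iterations`, plus the configuration objects.
#' @export
train_agent <- function(seed = 1, config = agent_config(),
                        opts = train_schedule(),
                        schedule = build_schedule(), verbose = FALSE) {
  streams <- make_streams(seed, c("init", "task", "sim", "eval"))
  agent <- with_stream(streams, "init", init_agent(config))
  init_params <- agent_trainable(agent)
  flat <- init_params
  pn <- grep("^p\\.", names(flat), value = TRUE)
  vn <- grep("^v\\.", names(flat), value = TRUE)
  ostate_p <- optim_init(flat[pn], opts$optimizer)
  ostate_v <- optim_init(flat[vn], opts$optimizer)
  history <- list(); checkpoints <- list()
  converged <- FALSE
  iter <- 0L
  final_record <- NULL
  best <- list(correct_rate = -1, iteration = NA_integer_, params = NULL)

  evaluate_block <- function() {
    rec <- with_stream(streams, "eval",
                       evaluate_agent(agent, opts$test_trials, schedule,
                                      opts, record = TRUE))
    rec
  }

  repeat {
    # --- learning block ---
    for (i in seq_len(opts$learn_block)) {
      iter <- iter + 1L
      specs <- with_stream(streams, "task", sample_trials(opts$n_trials))
      ro <- with_stream(streams, "sim",
                        rollout_batch(agent, specs, schedule,
                                      noise_on = TRUE, cache = TRUE,
                                      timeout1_reward = opts$timeout1_reward,
                                      critic_action = opts$critic_action))
      adv <- compute_advantage(ro, opts$advantage_mode)
      po <- policy_objective(agent, ro, adv)
      vo <- value_objective(agent, ro, target = opts$value_target,
                            fixed_T = opts$fixed_T_norm)
      res_p <- optim_step(flat[pn], clip_global_norm(po$grads, opts$clip),
                          ostate_p, lr = opts$lr, eps = opts$adam_eps)
      res_v <- optim_step(flat[vn], clip_global_norm(vo$grads, opts$clip),
                          ostate_v, lr = opts$lr_value, eps = opts$adam_eps)
      flat[pn] <- res_p$flat; ostate_p <- res_p$state
      flat[vn] <- res_v$flat; ostate_v <- res_v$state
      agent <- agent_set_trainable(agent, flat)
      if (iter >= opts$max_iter) break
    }
    # --- test block (frozen parameters) ---
    rec <- evaluate_block()
    beh <- rec$behaviour
    history[[length(history) + 1L]] <-
      data.frame(iteration = iter, first_rate = beh$first_rate,
                 correct_rate = beh$correct_rate,
                 mean_reward = beh$mean_reward,
                 value_mse2 = beh$value_mse2)
    checkpoints[[length(checkpoints) + 1L]] <-
      list(iteration = iter,
           cond_means = condition_period_means(rec, schedule),
           behaviour = beh)
    final_record <- rec
    if (beh$correct_rate > best$correct_rate) {
      best <- list(correct_rate = beh$correct_rate, iteration = iter,
                   params = flat)
    }
    if (verbose) {
      message(sprintf("iter %4d  first %.3f  both %.3f  reward %.3f",
                      iter, beh$first_rate, beh$correct_rate,
                      beh$mean_reward))
    }
    if (beh$correct_rate >= opts$criterion) { converged <- TRUE; break }
    if (iter >= opts$max_iter) break
  }

  structure(list(agent = agent, init_params = init_params,
                 history = do.call(rbind, history),
                 checkpoints = checkpoints,
                 final_record = final_record,
                 best = best,
                 converged = converged, n_iterations = iter,
                 seed = seed, config = config, opts = opts,
                 schedule = schedule),
            class = "categru_fit")
}

#' Agent at the best test-block checkpoint of a fit
#'
#' Returns the agent whose parameters scored the highest correct-trial
#' rate across the fit's frozen test blocks (early-stopping model
#' selection).  For a converged fit this is the final agent.  The
#' returned checkpoint should be re-evaluated on fresh trials for an
#' unbiased performance estimate.
#'
#' @param fit A [train_agent()] fit.
#' @return An agent.
#' @export
best_agent <- function(fit) {
  if (is.null(fit$best$params)) return(fit$agent)
  agent_set_trainable(fit$agent, fit$best$params)
}

#' @export
print.categru_fit <- function(x, ...) {
  cat("categru fit: ", x$n_iterations, " iterations, ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("final test block: first-choice %.1f%%, correct-trial %.1f%%\n",
                100 * last$first_rate, 100 * last$correct_rate))
  }
  invisible(x)
}
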