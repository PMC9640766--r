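# Plain-text configuration and log export.

#' Write a run configuration file
#'
#' Serialises the task timing, network sizes and training options to a
#' YAML key-value file using the conventional hyperparameter names
#' (alpha, dt, tau, N_p, N_v, p_0, p_1, p_2, delta_rec2, N_trials).
#'
#' @param path Output file.
#' @param config An [agent_config()].
#' @param opts A [train_schedule()].
#' @param timing A [task_timing()].
#' @return `path`, invisibly.
#' @export
write_run_config <- function(path, config = agent_config(),
                             opts = train_schedule(),
                             timing = task_timing()) {
  cfg <- list(
    alpha = opts$lr, dt = timing$dt, tau = config$policy$tau,
    N_p_in = config$n_inputs, N_v_in = config$n_value_in,
    N_p = config$n_policy, N_v = config$n_value,
    N_p_out = config$n_actions, N_v_out = 1L,
    p_0 = config$p0, p_1 = config$p1, p_2 = config$p2,
    delta_rec2 = config$policy$noise_var,
    N_trials = opts$n_trials,
    durations = as.list(timing$durations),
    learn_block = opts$learn_block, test_trials = opts$test_trials,
    criterion = opts$criterion, max_iter = opts$max_iter,
    optimizer = opts$optimizer, clip = opts$clip,
    advantage_mode = opts$advantage_mode,
    value_target = opts$value_target,
    timeout1_reward = opts$timeout1_reward,
    fixation_bias = config$fixation_bias)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a run configuration file
#'
#' @param path A file written by [write_run_config()].
#' @return List with `config`, `opts` and `timing` objects.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  timing <- task_timing(dt = y$dt, durations = unlist(y$durations))
  config <- agent_config(n_policy = y$N_p, n_value = y$N_v,
                         n_inputs = y$N_p_in, n_actions = y$N_p_out,
                         p0 = y$p_0, p1 = y$p_1, p2 = y$p_2,
                         dt = y$dt, tau = y$tau, noise_var = y$delta_rec2,
                         fixation_bias = y$fixation_bias)
  opts <- train_schedule(lr = y$alpha, n_trials = y$N_trials,
                         learn_block = y$learn_block,
                         test_trials = y$test_trials,
                         criterion = y$criterion, max_iter = y$max_iter,
                         optimizer = y$optimizer, clip = y$clip,
                         advantage_mode = y$advantage_mode,
                         value_target = y$value_target,
                         timeout1_reward = y$timeout1_reward)
  list(config = config, opts = opts, timing = timing)
}

#' Export the per-test-block behaviour history as CSV
#'
#' @param fit A [train_agent()] fit.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_history <- function(fit, path) {
  utils::write.csv(fit$history, path, row.names = FALSE)
  invisible(path)
}

#' Export the per-trial log of a recording as CSV
#'
#' @param record An [evaluate_agent()] recording (`record = TRUE`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_trial_log <- function(record, path) {
  utils::write.csv(record$trials, path, row.names = FALSE)
  invisible(path)
}

#' Export the per-neuron index table as CSV
#'
#' @param analysis An [analyse_fit()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_neuron_table <- function(analysis, path) {
  tab <- analysis$classes
  tab$direct <- analysis$connectivity$direct
  tab$action_class <- analysis$action_coding$action_class
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Save / load an agent checkpoint
#'
#' Checkpoints hold the flat trainable parameters, the connectivity
#' masks, the configuration and an iteration tag, serialised with R's
#' native format.
#'
#' @param agent An agent.
#' @param path Checkpoint file.
#' @param iteration Iteration tag stored alongside.
#' @return `path` (save) or the restored agent (load).
#' @export
save_agent <- function(agent, path, iteration = NA_integer_) {
  saveRDS(list(trainable = agent_trainable(agent),
               masks = list(p.M_in = agent$policy$M_in,
                            p.M_rec = agent$policy$M_rec,
                            v.M_in = agent$value$M_in,
                            v.M_rec = agent$value$M_rec),
               config = agent$config, iteration = iteration), path)
  invisible(path)
}

#' @rdname save_agent
#' @export
load_agent <- function(path) {
  x <- readRDS(path)
  agent <- init_agent(x$config)
  agent$policy$M_in <- x$masks$p.M_in
  agent$policy$M_rec <- x$masks$p.M_rec
  agent$value$M_in <- x$masks$v.M_in
  agent$value$M_rec <- x$masks$v.M_rec
  agent <- agent_set_trainable(agent, x$trainable)
  attr(agent, "iteration") <- x$iteration
  agent
}
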