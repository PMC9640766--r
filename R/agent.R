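#' Agent configuration
#'
#' The actor (policy network) is an 11-channel input layer, a sparsely
#' connected 150-unit gated recurrent layer (input connection
#' probability `p0 = 0.2`, recurrent probability `p1 = 0.1`) and a fully
#' connected 3-way softmax action head (fixate / left / right).  The
#' critic (value network) is a dense 100-unit gated recurrent layer
#' whose 153-dimensional input is the concatenation of the policy
#' layer's firing rates and the one-hot action, with a scalar linear
#' value head.
#'
#' @param n_policy,n_value Recurrent layer sizes.
#' @param n_inputs Observation channels.
#' @param n_actions Number of actions.
#' @param p0,p1,p2 Input, recurrent and output connection probabilities
#'   of the policy network.
#' @param dt,tau,noise_var Shared continuous-time dynamics parameters
#'   (see [gru_config()]).
#' @param fixation_bias Initial bias of the fixation output unit.  A
#'   positive value starts the untrained agent with a fixation-prone
#'   action prior, standing in for the pre-training that animals receive
#'   before the task proper; without it the chance of surviving the 1.7 s
#'   of enforced fixation is (1/3)^85 and no reward is ever seen.
#' @return An `agent_config` list holding the two [gru_config()]s.
#' @export
agent_config <- function(n_policy = 150, n_value = 100, n_inputs = 11,
                         n_actions = 3, p0 = 0.2, p1 = 0.1, p2 = 1,
                         dt = 20, tau = 100, noise_var = 0.01,
                         fixation_bias = 4) {
  stopifnot(p2 == 1)  # output head is fully connected
  structure(list(
    n_policy = as.integer(n_policy), n_value = as.integer(n_value),
    n_inputs = as.integer(n_inputs), n_actions = as.integer(n_actions),
    n_value_in = as.integer(n_policy + n_actions),
    p0 = p0, p1 = p1, p2 = p2,
    fixation_bias = fixation_bias,
    policy = gru_config(n_policy, n_inputs, dt = dt, tau = tau,
                        noise_var = noise_var, p_in = p0, p_rec = p1),
    value = gru_config(n_value, n_policy + n_actions, dt = dt, tau = tau,
                       noise_var = noise_var, p_in = 1, p_rec = 1)),
    class = "agent_config")
}

#' Initialise both networks of the agent
#'
#' @param config An [agent_config()].
#' @param gain Weight-scale multiplier passed to [init_gru_params()].
#' @param policy_head_zero Start the policy output weights at zero
#'   (default).  The untrained policy is then exactly the fixation
#'   prior, uncommitted between left and right; the actor only commits
#'   as gradients accumulate, after the critic has begun tracking
#'   state values.  A randomly initialised head lets sampling noise
#'   break the left/right symmetry before the critic can price it,
#'   which locks policies into side habits.
#' @return An `agent` list: `config`, `policy` / `value` recurrent
#'   parameters, policy head `W_out_pi` (3 x n_policy), `b_out_pi`
#'   (with the fixation bias applied to action F), value head
#'   `W_out_v` (1 x n_value), `b_out_v`.
#' @export
init_agent <- function(config = agent_config(), gain = 1,
                       policy_head_zero = TRUE) {
  pol <- init_gru_params(config$policy, gain = gain)
  val <- init_gru_params(config$value, gain = gain)
  np <- config$n_policy
  nv <- config$n_value
  na <- config$n_actions
  W_pi <- if (policy_head_zero) matrix(0, na, np) else
    matrix(stats::rnorm(na * np, 0, 1 / sqrt(np)), na, np)
  agent <- list(
    config = config,
    policy = pol,
    value = val,
    W_out_pi = W_pi,
    b_out_pi = c(config$fixation_bias, rep(0, na - 1L)),
    W_out_v = matrix(stats::rnorm(nv, 0, 1 / sqrt(nv)), 1, nv),
    b_out_v = 0)
  class(agent) <- "categru_agent"
  agent
}

.ACTIONS <- c("F", "L", "R")

#' Softmax over the rows of a logit matrix
#'
#' Numerically stabilised column-wise softmax.
#'
#' @param z Logit matrix (actions x batch) or vector.
#' @return Matrix of probabilities with columns summing to 1.
#' @export
softmax <- function(z) {
  if (is.vector(z)) z <- matrix(z, ncol = 1)
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

#' One policy-network step
#'
#' Advances the policy recurrent layer on an observation, forms action
#' logits from the rectified rates, and samples an action from the
#' softmax distribution (or takes the argmax when `sample = FALSE`).
#'
#' @param agent An [init_agent()] result.
#' @param h_prev Policy hidden state (n_policy vector/1-col matrix).
#' @param u Observation (11-vector).
#' @param noise_on Process noise on?
#' @param sample Sample the action (default) or take the argmax.
#' @return List: `action` ("F"/"L"/"R"), `action_id`, `log_prob`,
#'   `probs`, `rates` (x^pi), `h` (new hidden state).
#' @export
policy_step <- function(agent, h_prev, u, noise_on = TRUE, sample = TRUE) {
  cfg <- agent$config$policy
  eps <- if (noise_on) matrix(stats::rnorm(cfg$n_units), ncol = 1) else NULL
  st <- gru_step(cfg, agent$policy, h_prev, u, eps)
  z <- agent$W_out_pi %*% st$x + agent$b_out_pi
  p <- softmax(z)
  aid <- if (sample) sample.int(length(p), 1L, prob = p) else which.max(p)
  list(action = .ACTIONS[aid], action_id = aid, log_prob = log(p[aid]),
       probs = as.vector(p), rates = as.vector(st$x), h = st$h)
}

#' One value-network step
#'
#' Advances the value recurrent layer on the concatenation of the
#' policy rates and the one-hot action taken at this step, and returns
#' the scalar reward prediction.
#'
#' @param agent An [init_agent()] result.
#' @param h_prev Value hidden state (n_value vector/1-col matrix).
#' @param policy_rates Firing rates x^pi of the policy layer (n_policy).
#' @param action_id Integer action index (1 = F, 2 = L, 3 = R).
#' @param noise_on Process noise on?
#' @return List: `value` (scalar v_phi), `h` (new hidden state).
#' @export
value_step <- function(agent, h_prev, policy_rates, action_id,
                       noise_on = TRUE) {
  cfg <- agent$config$value
  a <- numeric(agent$config$n_actions)
  a[action_id] <- 1
  u <- c(policy_rates, a)
  if (length(u) != cfg$n_inputs) stop("shape mismatch in value_step",
                                      call. = FALSE)
  eps <- if (noise_on) matrix(stats::rnorm(cfg$n_units), ncol = 1) else NULL
  st <- gru_step(cfg, agent$value, h_prev, u, eps)
  list(value = as.numeric(agent$W_out_v %*% st$x + agent$b_out_v),
       h = st$h)
}

#' Flatten agent parameters to a named list of numeric arrays
#'
#' Used by the optimiser and by checkpoint (de)serialisation.  Masks
#' are not trainable and are excluded.
#'
#' @param agent An agent.
#' @return Named list of matrices/vectors.
#' @export
agent_trainable <- function(agent) {
  list(p.W_rec = agent$policy$W_rec, p.W_rec_phi = agent$policy$W_rec_phi,
       p.W_rec_psi = agent$policy$W_rec_psi, p.W_in = agent$policy$W_in,
       p.W_in_phi = agent$policy$W_in_phi, p.W_in_psi = agent$policy$W_in_psi,
       p.b = agent$policy$b, p.b_phi = agent$policy$b_phi,
       p.b_psi = agent$policy$b_psi,
       p.W_out = agent$W_out_pi, p.b_out = agent$b_out_pi,
       v.W_rec = agent$value$W_rec, v.W_rec_phi = agent$value$W_rec_phi,
       v.W_rec_psi = agent$value$W_rec_psi, v.W_in = agent$value$W_in,
       v.W_in_phi = agent$value$W_in_phi, v.W_in_psi = agent$value$W_in_psi,
       v.b = agent$value$b, v.b_phi = agent$value$b_phi,
       v.b_psi = agent$value$b_psi,
       v.W_out = agent$W_out_v, v.b_out = agent$b_out_v)
}

#' Write a flat parameter list back into an agent
#'
#' @param agent An agent.
#' @param flat A named list as produced by [agent_trainable()].
#' @return The updated agent, with connectivity masks re-applied.
#' @export
agent_set_trainable <- function(agent, flat) {
  agent$policy$W_rec <- flat$p.W_rec; agent$policy$W_rec_phi <- flat$p.W_rec_phi
  agent$policy$W_rec_psi <- flat$p.W_rec_psi; agent$policy$W_in <- flat$p.W_in
  agent$policy$W_in_phi <- flat$p.W_in_phi
  agent$policy$W_in_psi <- flat$p.W_in_psi
  agent$policy$b <- flat$p.b; agent$policy$b_phi <- flat$p.b_phi
  agent$policy$b_psi <- flat$p.b_psi
  agent$W_out_pi <- flat$p.W_out; agent$b_out_pi <- flat$p.b_out
  agent$value$W_rec <- flat$v.W_rec; agent$value$W_rec_phi <- flat$v.W_rec_phi
  agent$value$W_rec_psi <- flat$v.W_rec_psi; agent$value$W_in <- flat$v.W_in
  agent$value$W_in_phi <- flat$v.W_in_phi
  agent$value$W_in_psi <- flat$v.W_in_psi
  agent$value$b <- flat$v.b; agent$value$b_phi <- flat$v.b_phi
  agent$value$b_psi <- flat$v.b_psi
  agent$W_out_v <- flat$v.W_out; agent$b_out_v <- flat$v.b_out
  agent$policy <- apply_masks(agent$policy)
  agent$value <- apply_masks(agent$value)
  agent
}
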