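# Backpropagation through time for the batched gated recurrent layers.
# The forward caches produced by rollout_batch() hold, per step, the
# hidden state h, gate activations phi/psi and the realised candidate
# drive (noise included); the backward pass treats the noise draw and
# all reinforcement weights (advantages) as constants.

# Shared BPTT over one gated recurrent layer.
# h, phi, psi, cand: n x B x T arrays; U: k x B x T; dX_head: n x B x T
# gradient of the loss w.r.t. the rectified rates x_t coming from the
# readout head.  Returns masked parameter gradients.  Input-projection
# and bias gradients are accumulated in deferred matrix products over
# the whole trial; the gradient w.r.t. the inputs themselves is never
# formed (policy inputs are external stimuli, and the critic's view of
# the policy rates is treated as a constant).
gru_backward <- function(params, eta, h, phi, psi, cand, U, dX_head) {
  n <- dim(h)[1]; B <- dim(h)[2]; TT <- dim(h)[3]
  k <- dim(U)[1]
  gW_rec <- matrix(0, n, n)
  gW_gates <- matrix(0, 2L * n, n)            # [dphi; dpsi] recurrent grads
  dcand_all <- matrix(0, n, B * TT)
  dgate_all <- matrix(0, 2L * n, B * TT)      # [dpphi; dppsi]
  dXrec <- matrix(0, n, B)
  dHdir <- matrix(0, n, B)
  tW_rec <- t(params$W_rec)
  tW_gates <- cbind(t(params$W_rec_phi), t(params$W_rec_psi))  # n x 2n
  seqB <- seq_len(B)
  # plain a[, , t] would drop dims when n or B is 1
  sl <- if (n > 1L && B > 1L) {
    function(a, t) a[, , t]
  } else {
    function(a, t) matrix(a[, , t], n, B)
  }
  for (t in TT:1) {
    h_t <- sl(h, t)
    h_prev <- if (t > 1L) sl(h, t - 1L) else matrix(0, n, B)
    x_prev <- pmax(h_prev, 0)
    phi_t <- sl(phi, t)
    psi_t <- sl(psi, t)

    dX <- sl(dX_head, t) + dXrec
    dH <- dHdir + dX * (h_t > 0)
    ef <- eta * phi_t
    dcand <- dH * ef
    dphi <- dH * eta * (sl(cand, t) - h_prev)
    dHdir <- dH * (1 - ef)
    dpphi <- dphi * phi_t * (1 - phi_t)
    g <- tW_rec %*% dcand
    dppsi <- (g * x_prev) * psi_t * (1 - psi_t)
    dgates <- rbind(dpphi, dppsi)
    dXrec <- g * psi_t + tW_gates %*% dgates

    txp <- t(x_prev)
    gW_rec <- gW_rec + dcand %*% (t(psi_t) * txp)
    gW_gates <- gW_gates + dgates %*% txp
    cols <- (t - 1L) * B + seqB
    dcand_all[, cols] <- dcand
    dgate_all[, cols] <- dgates
  }
  tU <- t(matrix(U, k, B * TT))
  gW_in <- dcand_all %*% tU
  gW_in_gates <- dgate_all %*% tU
  i1 <- seq_len(n); i2 <- n + i1
  list(W_rec = gW_rec * params$M_rec,
       W_rec_phi = gW_gates[i1, , drop = FALSE] * params$M_rec,
       W_rec_psi = gW_gates[i2, , drop = FALSE] * params$M_rec,
       W_in = gW_in * params$M_in,
       W_in_phi = gW_in_gates[i1, , drop = FALSE] * params$M_in,
       W_in_psi = gW_in_gates[i2, , drop = FALSE] * params$M_in,
       b = rowSums(dcand_all),
       b_phi = rowSums(dgate_all[i1, , drop = FALSE]),
       b_psi = rowSums(dgate_all[i2, , drop = FALSE]))
}

# engine dispatch for the BPTT kernel
gru_backward_dispatch <- function(params, eta, h, phi, psi, cand, U, dX,
                                  engine = categru_engine()) {
  if (identical(engine, "cpp")) {
    .cpp_gru_backward(params$W_rec, params$W_rec_phi, params$W_rec_psi,
                      params$M_rec, params$M_in,
                      h, phi, psi, cand, U, dX, eta)
  } else {
    gru_backward(params, eta, h, phi, psi, cand, U, dX)
  }
}

#' Policy objective and its gradient
#'
#' The reported objective is the negative mean episode return.  Its
#' policy-gradient surrogate weights each step's log-probability by the
#' advantage (treated as a constant), and the gradient is obtained by
#' backpropagation through time across the policy network only; no
#' gradient flows through the critic or the sampled actions.
#'
#' @param agent The agent the rollout was produced with.
#' @param ro A cached [rollout_batch()] result (`cache = TRUE`).
#' @param adv Advantage matrix from [compute_advantage()].
#' @param engine Kernel engine, see [categru_engine()].
#' @return List: `objective` (scalar, -mean return), `surrogate` (the
#'   differentiated scalar), `grads` (named list over policy
#'   parameters, prefix `p.`).
#' @export
policy_objective <- function(agent, ro, adv, engine = categru_engine()) {
  if (ro$n_trials < 1L) stop("empty batch", call. = FALSE)
  cc <- ro$cache
  if (is.null(cc)) stop("rollout must be run with cache = TRUE", call. = FALSE)
  B <- ro$n_trials; TT <- ro$n_steps
  na <- agent$config$n_actions; np <- agent$config$n_policy
  w <- adv * ro$taken / B                       # (B x T) constant weights
  # dL/dz = w * (pi - onehot(a)) at each taken step
  dZ <- matrix(cc$probs, na, B * TT)
  ia <- cbind(as.vector(ro$actions), seq_len(B * TT))
  dZ[ia] <- dZ[ia] - 1
  dZ <- dZ * rep(as.vector(w), each = na)
  X <- matrix(ro$rates, np, B * TT)
  gW_out <- dZ %*% t(X)
  gb_out <- rowSums(dZ)
  dX <- array(t(agent$W_out_pi) %*% dZ, c(np, B, TT))
  g <- gru_backward_dispatch(agent$policy, agent$config$policy$eta,
                             cc$p.h, cc$p.phi, cc$p.psi, cc$p.cand,
                             ro$U, dX, engine)
  grads <- list(p.W_rec = g$W_rec, p.W_rec_phi = g$W_rec_phi,
                p.W_rec_psi = g$W_rec_psi, p.W_in = g$W_in,
                p.W_in_phi = g$W_in_phi, p.W_in_psi = g$W_in_psi,
                p.b = g$b, p.b_phi = g$b_phi, p.b_psi = g$b_psi,
                p.W_out = gW_out, p.b_out = gb_out)
  list(objective = -mean(ro$returns), grads = grads,
       surrogate = -sum(ro$logp * w))
}

#' Value objective and its gradient
#'
#' Mean squared error between the critic's per-step predictions and
#' their targets, averaged within each trial over its realised length
#' and then across trials.  The default target is the return-to-go (the
#' quantity the prediction is subtracted from in the advantage); the
#' `"reward"` target trains on the immediate reward instead, the
#' literal per-step form.  Policy rates entering the value network are
#' treated as constants.
#'
#' @param agent The agent.
#' @param ro A cached rollout.
#' @param target `"return_to_go"` or `"reward"`.
#' @param fixed_T Normalise every trial by the full trial length
#'   instead of its realised length.
#' @param engine Kernel engine, see [categru_engine()].
#' @return List: `objective` (Gamma_v), `per_trial` (M_n vector),
#'   `grads` (named list over value parameters, prefix `v.`).
#' @export
value_objective <- function(agent, ro, target = c("return_to_go", "reward"),
                            fixed_T = FALSE, engine = categru_engine()) {
  if (ro$n_trials < 1L) stop("empty batch", call. = FALSE)
  target <- match.arg(target)
  cc <- ro$cache
  if (is.null(cc)) stop("rollout must be run with cache = TRUE", call. = FALSE)
  B <- ro$n_trials; TT <- ro$n_steps
  nv <- agent$config$n_value
  tgt <- if (target == "reward") ro$rewards else return_targets(ro, "return_to_go")
  err <- (ro$values - tgt) * ro$taken
  norm <- if (fixed_T) rep(TT, B) else ro$lengths
  per_trial <- rowSums(err^2) / norm
  dv <- as.vector(2 * err / (norm * B))          # length B*T
  xv <- matrix(pmax(cc$v.h, 0), nv, B * TT)
  gW_out <- matrix(xv %*% dv, 1, nv)
  gb_out <- sum(dv)
  dX <- array(outer(as.vector(agent$W_out_v), dv), c(nv, B, TT))
  # value-network input across time: [x^pi ; one-hot action], the
  # action lagged by one step when the rollout used the default
  # "previous" critic-action convention
  na <- agent$config$n_actions
  np <- agent$config$n_policy
  acts <- ro$actions
  if (identical(ro$critic_action, "previous")) {
    acts <- cbind(rep(0L, B), acts[, -TT, drop = FALSE])
  }
  Uv <- array(0, c(np + na, B, TT))
  Uv[seq_len(np), , ] <- ro$rates
  onehot <- matrix(0, na, B * TT)
  av <- as.vector(acts)
  has <- av > 0L
  onehot[cbind(av[has], which(has))] <- 1
  Uv[np + seq_len(na), , ] <- onehot
  g <- gru_backward_dispatch(agent$value, agent$config$value$eta,
                             cc$v.h, cc$v.phi, cc$v.psi, cc$v.cand,
                             Uv, dX, engine)
  grads <- list(v.W_rec = g$W_rec, v.W_rec_phi = g$W_rec_phi,
                v.W_rec_psi = g$W_rec_psi, v.W_in = g$W_in,
                v.W_in_phi = g$W_in_phi, v.W_in_psi = g$W_in_psi,
                v.b = g$b, v.b_phi = g$b_phi, v.b_psi = g$b_psi,
                v.W_out = gW_out, v.b_out = gb_out)
  list(objective = mean(per_trial), per_trial = per_trial, grads = grads)
}

# ---- optimiser -----------------------------------------------------------

#' Clip a gradient list to a global norm
#'
#' @param grads Named list of numeric arrays.
#' @param max_norm Maximum Euclidean norm over all entries jointly.
#' @return The (possibly rescaled) gradient list.
#' @export
clip_global_norm <- function(grads, max_norm = 1) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(total) && total > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / total))
  }
  grads
}

#' Initialise optimiser state
#'
#' @param flat Named parameter list ([agent_trainable()]).
#' @param method `"adam"` or `"sgd"`.
#' @return An `optim_state` list.
#' @export
optim_init <- function(flat, method = c("adam", "sgd")) {
  method <- match.arg(method)
  zeros <- lapply(flat, function(p) p * 0)
  structure(list(method = method, t = 0L, m = zeros, v = zeros),
            class = "optim_state")
}

#' One optimiser step
#'
#' Applies Adam (default) or plain gradient descent to the named
#' parameter list.  Gradients must already be masked; masks are
#' re-applied downstream by [agent_set_trainable()].
#'
#' @param flat Named parameter list.
#' @param grads Matching named gradient list.
#' @param state An [optim_init()] state.
#' @param lr Learning rate.
#' @param beta1,beta2,eps Adam moment parameters.
#' @return List with updated `flat` and `state`.
#' @export
optim_step <- function(flat, grads, state, lr = 0.01,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bad <- vapply(grads, function(g) any(!is.finite(g)), logical(1))
  if (any(bad)) {
    stop("non-finite gradient in: ", paste(names(grads)[bad], collapse = ", "),
         call. = FALSE)
  }
  if (state$method == "sgd") {
    for (nm in names(grads)) flat[[nm]] <- flat[[nm]] - lr * grads[[nm]]
    return(list(flat = flat, state = state))
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    flat[[nm]] <- flat[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(flat = flat, state = state)
}
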