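#' Configuration of a continuous-time gated recurrent layer
#'
#' The layer follows leaky gated-recurrent-unit dynamics discretised
#' with Euler step `dt` and membrane time constant `tau` (leak factor
#' `eta = dt/tau`).  Additive Gaussian process noise with variance
#' `noise_var` enters the candidate drive with standard deviation
#' `sqrt(2 * noise_var / eta)`, the standard discretisation of
#' continuous-time rate-network noise.  Input and recurrent connections
#' are present independently with probabilities `p_in` and `p_rec`; one
#' anatomical mask per projection is shared by the candidate, update and
#' reset matrices.
#'
#' @param n_units Number of recurrent units.
#' @param n_inputs Number of input channels.
#' @param dt Time step (ms).
#' @param tau Time constant (ms).
#' @param noise_var Process-noise variance (delta_rec^2).
#' @param p_in,p_rec Connection probabilities in \[0, 1\].
#' @return A `gru_config` list with the derived `eta`.
#' @export
gru_config <- function(n_units, n_inputs, dt = 20, tau = 100,
                       noise_var = 0.01, p_in = 1, p_rec = 1) {
  eta <- dt / tau
  stopifnot(eta > 0, eta <= 1, noise_var >= 0,
            p_in >= 0, p_in <= 1, p_rec >= 0, p_rec <= 1)
  structure(list(n_units = as.integer(n_units),
                 n_inputs = as.integer(n_inputs),
                 dt = dt, tau = tau, eta = eta, noise_var = noise_var,
                 p_in = p_in, p_rec = p_rec),
            class = "gru_config")
}

#' Initialise parameters of a gated recurrent layer
#'
#' Connectivity masks are drawn once (Bernoulli `p_in` / `p_rec`) and
#' shared across the candidate, update-gate and reset-gate matrices of
#' the same projection.  Weights are zero-mean Gaussian with standard
#' deviation `gain / sqrt(expected fan-in)` and are masked; biases start
#' at zero.  Matrices are stored in "to x from" orientation, so the
#' recurrent drive of unit i is `W_rec[i, ] %*% x`.
#'
#' @param config A [gru_config()].
#' @param gain Multiplier on the fan-in-scaled weight s.d.
#' @return A `gru_params` list: `W_rec`, `W_rec_phi`, `W_rec_psi`
#'   (n_units x n_units), `W_in`, `W_in_phi`, `W_in_psi`
#'   (n_units x n_inputs), biases `b`, `b_phi`, `b_psi`, and binary
#'   masks `M_rec`, `M_in` of matching shapes.
#' @export
init_gru_params <- function(config, gain = 1) {
  n <- config$n_units
  k <- config$n_inputs
  M_rec <- matrix(stats::rbinom(n * n, 1L, config$p_rec), n, n)
  M_in <- matrix(stats::rbinom(n * k, 1L, config$p_in), n, k)
  sd_rec <- gain / sqrt(max(1, config$p_rec * n))
  sd_in <- gain / sqrt(max(1, config$p_in * k))
  rmat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
  params <- list(
    W_rec = rmat(n, n, sd_rec) * M_rec,
    W_rec_phi = rmat(n, n, sd_rec) * M_rec,
    W_rec_psi = rmat(n, n, sd_rec) * M_rec,
    W_in = rmat(n, k, sd_in) * M_in,
    W_in_phi = rmat(n, k, sd_in) * M_in,
    W_in_psi = rmat(n, k, sd_in) * M_in,
    b = numeric(n), b_phi = numeric(n), b_psi = numeric(n),
    M_rec = M_rec, M_in = M_in)
  class(params) <- "gru_params"
  params
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' One batched step of the gated recurrent dynamics
#'
#' Computes, for a batch of hidden-state columns,
#' \deqn{\phi = \sigma(W^{\phi}_{rec} x_{t-1} + W^{\phi}_{in} u_t + b^{\phi})}
#' \deqn{\psi = \sigma(W^{\psi}_{rec} x_{t-1} + W^{\psi}_{in} u_t + b^{\psi})}
#' \deqn{c = W_{rec}(\psi \odot x_{t-1}) + W_{in} u_t + b +
#'       \sqrt{2\delta^2/\eta}\,\varepsilon}
#' \deqn{h_t = (1-\eta\phi)\odot h_{t-1} + \eta\phi\odot c, \quad
#'       x_t = [h_t]_+}
#' The recurrent drive uses the rectified rates `x_{t-1}`, not the raw
#' hidden state.
#'
#' @param config A [gru_config()].
#' @param params A [init_gru_params()] result.
#' @param h_prev Hidden state, n_units x batch matrix (or vector).
#' @param u Input, n_inputs x batch matrix (or vector).
#' @param eps Standard-normal noise draw of the same shape as `h_prev`,
#'   or `NULL` for noiseless dynamics.
#' @return List with `h`, `x`, `phi`, `psi` and the candidate drive
#'   `cand` (all n_units x batch).
#' @export
gru_step <- function(config, params, h_prev, u, eps = NULL) {
  if (is.vector(h_prev)) h_prev <- matrix(h_prev, ncol = 1)
  if (is.vector(u)) u <- matrix(u, ncol = 1)
  if (nrow(h_prev) != config$n_units || nrow(u) != config$n_inputs ||
      ncol(h_prev) != ncol(u)) {
    stop("shape mismatch in gru_step", call. = FALSE)
  }
  x_prev <- pmax(h_prev, 0)
  phi <- .sigmoid(params$W_rec_phi %*% x_prev + params$W_in_phi %*% u +
                    params$b_phi)
  psi <- .sigmoid(params$W_rec_psi %*% x_prev + params$W_in_psi %*% u +
                    params$b_psi)
  cand <- params$W_rec %*% (psi * x_prev) + params$W_in %*% u + params$b
  if (!is.null(eps)) {
    cand <- cand + sqrt(2 * config$noise_var / config$eta) * eps
  }
  ef <- config$eta * phi
  h <- (1 - ef) * h_prev + ef * cand
  list(h = h, x = pmax(h, 0), phi = phi, psi = psi, cand = cand)
}

#' Run a gated recurrent layer over an input sequence
#'
#' Iterates [gru_step()] from a zero initial hidden state and records
#' every state, for analysis or backpropagation through time.
#'
#' @param config,params As in [gru_step()].
#' @param u_seq Input sequence, n_inputs x n_steps matrix.
#' @param noise_on Draw fresh standard-normal process noise each step?
#' @param h0 Initial hidden state (default zeros).
#' @return List of matrices (n_units x n_steps): `h`, `x`, `phi`,
#'   `psi`, `cand`, `eps`.
#' @export
gru_run <- function(config, params, u_seq, noise_on = TRUE, h0 = NULL) {
  n <- config$n_units
  n_steps <- ncol(u_seq)
  out <- list(h = matrix(0, n, n_steps), x = matrix(0, n, n_steps),
              phi = matrix(0, n, n_steps), psi = matrix(0, n, n_steps),
              cand = matrix(0, n, n_steps), eps = matrix(0, n, n_steps))
  h <- if (is.null(h0)) matrix(0, n, 1) else matrix(h0, n, 1)
  for (t in seq_len(n_steps)) {
    eps <- if (noise_on) matrix(stats::rnorm(n), n, 1) else NULL
    st <- gru_step(config, params, h, u_seq[, t, drop = FALSE], eps)
    out$h[, t] <- st$h; out$x[, t] <- st$x
    out$phi[, t] <- st$phi; out$psi[, t] <- st$psi
    out$cand[, t] <- st$cand
    if (noise_on) out$eps[, t] <- eps
    h <- st$h
  }
  out
}

#' Re-apply connectivity masks to a parameter set
#'
#' @param params A `gru_params` list.
#' @return The parameter list with masked entries forced to exactly zero.
#' @export
apply_masks <- function(params) {
  params$W_rec <- params$W_rec * params$M_rec
  params$W_rec_phi <- params$W_rec_phi * params$M_rec
  params$W_rec_psi <- params$W_rec_psi * params$M_rec
  params$W_in <- params$W_in * params$M_in
  params$W_in_phi <- params$W_in_phi * params$M_in
  params$W_in_psi <- params$W_in_psi * params$M_in
  params
}
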