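# Synthetic trial x neuron x time firing-rate tensors with prescribed
# within-category (WCD) and between-category (BCD) response structure,
# for testing the analysis stages in isolation.

#' Synthetic firing-rate tensor with known category structure
#'
#' Builds per-neuron condition means with exactly the requested
#' within-category and between-category mean absolute differences, then
#' adds i.i.d. Gaussian noise per trial and time step.  Group means are
#' placed at `baseline +/- bcd/2` and the three within-group means are
#' spread by `(-1, 0, 1) * 3/4 * wcd` (which yields a within-group mean
#' absolute pairwise difference of exactly `wcd`; the construction is
#' exact when `bcd >= 1.5 * wcd`, so cross-group differences do not
#' change sign).  The noiseless CI is therefore
#' `(bcd - wcd) / (bcd + wcd)`.  Which group is elevated and the order
#' of the within-group offsets are randomised per neuron.
#'
#' @param n_neurons Number of neurons.
#' @param trials_per_condition Trials per each of the 6 conditions.
#' @param wcd,bcd Target within- and between-category mean absolute
#'   differences (scalars or per-neuron vectors).
#' @param noise_sd Trial/step noise standard deviation.
#' @param baseline Additive offset keeping rates positive.
#' @param n_steps Time steps per trial.
#' @param rectify Clip rates at zero (real rates are nonnegative).
#' @return List: `rates` (trial x neuron x time array), `labels`
#'   (per-trial condition factor), `window_rates` (trial x neuron
#'   time-averaged matrix), `true_means` (neuron x 6), `true_ci`,
#'   `true_si` (noiseless index values).
#' @export
synthetic_rate_tensor <- function(n_neurons = 50, trials_per_condition = 10,
                                  wcd = 0.5, bcd = 2, noise_sd = 0.2,
                                  baseline = 5, n_steps = 20,
                                  rectify = TRUE) {
  wcd <- rep_len(wcd, n_neurons)
  bcd <- rep_len(bcd, n_neurons)
  if (any(bcd < 1.5 * wcd - 1e-12)) {
    warning("bcd < 1.5 * wcd: construction is no longer exact")
  }
  labels <- factor(rep(.COND6, each = trials_per_condition),
                   levels = .COND6)
  n_trials <- length(labels)
  true_means <- matrix(0, n_neurons, 6, dimnames = list(NULL, .COND6))
  for (i in seq_len(n_neurons)) {
    gamma <- 0.75 * wcd[i]
    m <- bcd[i] / 2
    hi <- sample(c(1, -1), 1)                      # which group is elevated
    g1 <- baseline + hi * m + gamma * sample(c(-1, 0, 1))
    g2 <- baseline - hi * m + gamma * sample(c(-1, 0, 1))
    true_means[i, ] <- c(g1, g2)
  }
  rates <- array(stats::rnorm(n_trials * n_neurons * n_steps, 0, noise_sd),
                 c(n_trials, n_neurons, n_steps))
  for (k in seq_len(6)) {
    idx <- which(labels == .COND6[k])
    rates[idx, , ] <- rates[idx, , , drop = FALSE] +
      rep(true_means[, k], each = length(idx))
  }
  if (rectify) rates <- pmax(rates, 0)
  list(rates = rates, labels = labels,
       window_rates = apply(rates, c(1, 2), mean),
       true_means = true_means,
       true_ci = .ci_matrix(true_means),
       true_si = .si_matrix(true_means))
}

#' Wrap a synthetic tensor as an analysis-ready recording
#'
#' Produces the same structure as an [evaluate_agent()] recording so
#' the analysis pipeline can run on synthetic data: every synthetic
#' trial is marked correct and the tensor's time average fills the
#' first-stimulus window.
#'
#' @param syn A [synthetic_rate_tensor()] result.
#' @return A record list with `trials`, `win_rates`, `max_rate`,
#'   `trace_first`.
#' @export
synthetic_record <- function(syn) {
  n_trials <- dim(syn$rates)[1]
  lab <- as.character(syn$labels)
  letter <- substr(lab, 1, 1)
  group <- as.integer(substr(lab, 2, 2))
  order <- c(A = "ABC", B = "BCA", C = "CAB")[letter]
  trials <- data.frame(order = unname(order), group = group,
                       pos1 = "L", pos2 = "L",
                       first_letter = letter,
                       first_correct = TRUE, correct = TRUE,
                       first_choice_side = "L",
                       return = 2, length = dim(syn$rates)[3],
                       stringsAsFactors = FALSE)
  wr <- array(syn$window_rates,
              c(n_trials, dim(syn$rates)[2], 1),
              dimnames = list(NULL, NULL, "first_stimulus"))
  list(trials = trials, win_rates = wr,
       max_rate = apply(syn$rates, 2, max),
       trace_first = t(apply(syn$rates, c(2, 3), mean)))
}
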