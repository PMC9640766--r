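#!/usr/bin/env Rscript
# Evaluate a trained checkpoint over frozen-parameter trials.
#
#   Rscript scripts/evaluate.R --checkpoint <file> [--trials 800]
#                              [--seed 1] [--out <csv>]

suppressMessages(library(categru))

args <- commandArgs(trailingOnly = TRUE)
arg_val <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
ckpt <- arg_val("--checkpoint", NA)
if (is.na(ckpt)) stop("--checkpoint is required")
n_trials <- as.integer(arg_val("--trials", "800"))
seed <- as.integer(arg_val("--seed", "1"))
out <- arg_val("--out", NA)

agent <- load_agent(ckpt)
set.seed(seed)
rec <- evaluate_agent(agent, n_trials = n_trials, record = !is.na(out))
b <- rec$behaviour
message(sprintf(
  "%d trials: first-choice %.2f%%, correct-trial %.2f%%, mean reward %.3f",
  b$n_trials, 100 * b$first_rate, 100 * b$correct_rate, b$mean_reward))
if (!is.na(out)) export_trial_log(rec, out)
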