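#!/usr/bin/env Rscript
# Generate a synthetic trial x neuron x time firing-rate fixture with
# prescribed within/between-category structure.
#
#   Rscript scripts/make_fixtures.R --neurons 50 --trials-per-condition 10 \
#       --wcd 0.5 --bcd 2 --noise-sd 0.2 --seed 1 --out fixture.rds

suppressMessages(library(categru))

args <- commandArgs(trailingOnly = TRUE)
arg_val <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
set.seed(as.integer(arg_val("--seed", "1")))
syn <- synthetic_rate_tensor(
  n_neurons = as.integer(arg_val("--neurons", "50")),
  trials_per_condition = as.integer(arg_val("--trials-per-condition", "10")),
  wcd = as.numeric(arg_val("--wcd", "0.5")),
  bcd = as.numeric(arg_val("--bcd", "2")),
  noise_sd = as.numeric(arg_val("--noise-sd", "0.2")))
out <- arg_val("--out", "fixture.rds")
saveRDS(syn, out)
message(sprintf("wrote %s: %d trials x %d neurons x %d steps (true CI %.3f)",
                out, dim(syn$rates)[1], dim(syn$rates)[2],
                dim(syn$rates)[3], mean(syn$true_ci)))
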