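#!/usr/bin/env Rscript
# Train the model on the sequential paired-association task.
#
#   Rscript scripts/train.R --seed <int> --out <dir> [--config <yaml>]
#
# Writes: <out>/history.csv (per-test-block behaviour curves),
# <out>/checkpoint.rds (final agent), <out>/best_checkpoint.rds (best
# test-block agent), <out>/trials.csv (final test-block trial log),
# <out>/config.yaml (the configuration actually used).

suppressMessages(library(categru))

args <- commandArgs(trailingOnly = TRUE)
arg_val <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
seed <- as.integer(arg_val("--seed", "1"))
out_dir <- arg_val("--out", "run")
config_path <- arg_val("--config", NA)

if (!is.na(config_path)) {
  cfgs <- read_run_config(config_path)
  config <- cfgs$config; opts <- cfgs$opts
  schedule <- build_schedule(cfgs$timing)
} else {
  config <- agent_config(); opts <- train_schedule()
  schedule <- build_schedule()
}

dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
fit <- train_agent(seed = seed, config = config, opts = opts,
                   schedule = schedule, verbose = TRUE)
print(fit)

export_history(fit, file.path(out_dir, "history.csv"))
export_trial_log(fit$final_record, file.path(out_dir, "trials.csv"))
save_agent(fit$agent, file.path(out_dir, "checkpoint.rds"),
           iteration = fit$n_iterations)
save_agent(best_agent(fit), file.path(out_dir, "best_checkpoint.rds"),
           iteration = fit$best$iteration)
write_run_config(file.path(out_dir, "config.yaml"), config, opts)
saveRDS(fit, file.path(out_dir, "fit.rds"))
message("wrote ", out_dir)
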