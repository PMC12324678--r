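#!/usr/bin/env Rscript
# Desk-scale meta-training of the recurrent agent and its behavioural
# comparison against the uniform-random-valid baseline.
#
# Trains with masked PPO on the open-field 'both' condition (the desk-scale
# geometry: 16 environments x 128 steps x 240 updates, 10 epochs per
# update), then evaluates 1,000 greedy trials against 1,000 random-baseline
# trials and summarises strategy use. The full-scale geometry of the study
# (128 x 8,192 x 8,000) is available via ppo_config(scale = "full") but is
# cluster-class work, not a workstation run.

library(metanav)

out_dir <- "results/agent"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

task <- task_config(env_kinds = "open", conditions = "both")
cfg <- ppo_config(n_envs = 16L, n_steps = 128L, n_updates = 240L,
                  n_epochs = 10L)

cat("training desk-scale agent (", cfg$n_envs, "x", cfg$n_steps, "x",
    cfg$n_updates, ")...\n")
res <- train(task, network_config(), cfg, seed = 20260101L, verbose = 40L)
write.csv(res$curve, file.path(out_dir, "training_curve.csv"),
          row.names = FALSE)
saveRDS(res$params, file.path(out_dir, "params.rds"))

agent <- evaluate(res$params, 1000, task, policy = "greedy", seed = 9)
baseline <- evaluate(NULL, 1000, task, policy = "random", seed = 9)
write.csv(agent$trials, file.path(out_dir, "agent_trials.csv"),
          row.names = FALSE)
write.csv(baseline$trials, file.path(out_dir, "baseline_trials.csv"),
          row.names = FALSE)

cat(sprintf("agent:    median %d steps, mean %.1f, success %.2f\n",
            median(agent$trials$steps_to_goal),
            mean(agent$trials$steps_to_goal), mean(agent$trials$success)))
cat(sprintf("baseline: median %d steps, mean %.1f, success %.2f\n",
            median(baseline$trials$steps_to_goal),
            mean(baseline$trials$steps_to_goal),
            mean(baseline$trials$success)))

sp <- strategy_proportions(agent$log)
cat(sprintf("agent direction-use proportion (both condition): %.3f\n",
            sp$overall))
write.csv(sp$by_cell, file.path(out_dir, "agent_strategy.csv"),
          row.names = FALSE)
cat("wrote", out_dir, "\n")
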