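#!/usr/bin/env Rscript
# Unit-level analyses of the trained agent: spatial/landmark/conjunctive
# classification over the four fixed two-landmark environments, functional
# module identification, lesion comparison, decoding, and representational
# geometry. Requires the checkpoint written by 02_train_agent.R.

library(metanav)

ckpt <- "results/agent/params.rds"
if (!file.exists(ckpt))
  stop("run analysis/02_train_agent.R first (missing ", ckpt, ")")
params <- readRDS(ckpt)

out_dir <- "results/units"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cat("recording activations over the four classification environments...\n")
ds <- record_activations(params, n_trials_per_env = 250L, seed = 21L)
cat("  ", nrow(ds$activations), "timesteps recorded\n")

cls <- classify_units(ds)
write.csv(cls, file.path(out_dir, "unit_labels.csv"), row.names = FALSE)
cat("unit-type counts:\n")
print(table(cls$label))

mods <- identify_functional_modules(ds, k = 10)
write.csv(mods$r2, file.path(out_dir, "module_r2.csv"), row.names = FALSE)
writeLines(jsonlite::toJSON(mods[c("vector", "transition", "unspecialized")]),
           file.path(out_dir, "modules.json"))

cat("lesion analysis (paired seeds)...\n")
les <- evaluate_lesioned(params,
                         mods[c("vector", "transition", "unspecialized")],
                         n_trials = 200L, seed = 22L, env_kinds = "open")
write.csv(les, file.path(out_dir, "lesion_effects.csv"), row.names = FALSE)
print(as.data.frame(les[, c("lesion", "condition", "mean_steps",
                            "excess_steps", "p_direction_both")]))

dec <- tibble::tibble()
for (mod in c("vector", "transition", "unspecialized")) {
  units <- mods[[mod]]
  dec <- rbind(dec, tibble::tibble(
    module = mod,
    current_error = decode_continuous(ds, units, "current", seed = 23L)$error,
    goal_error = decode_continuous(ds, units, "goal", seed = 23L)$error,
    landmark_adj_error = decode_binary(ds, units, "landmark", seed = 23L)$error,
    goal_adj_error = decode_binary(ds, units, "goal", seed = 23L)$error))
}
write.csv(dec, file.path(out_dir, "decoding.csv"), row.names = FALSE)
cat("decoding errors by module:\n")
print(as.data.frame(dec))

geom <- representational_pca(ds, sort(c(mods$vector, mods$transition)),
                             condition_split = "post_landmark")
write.csv(geom$centroids, file.path(out_dir, "geometry_centroids.csv"),
          row.names = FALSE)
cat("variance explained by first 3 PCs:",
    round(geom$variance_explained[1:3], 3), "\n")
cat("wrote", out_dir, "\n")
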