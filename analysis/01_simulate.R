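#!/usr/bin/env Rscript

# Step 1 — simulate the study.
#
# Builds the hierarchical stimulus design (2 coarse x 4 fine categories x
# 4 entities + 8 category nouns), a 24-run session schedule with balanced
# question types, hierarchical entity vectors, and a cohort of synthetic
# subjects whose evoked responses contain category signals in fixed time
# windows and an entity component that is a linear image of each
# stimulus's vector. Writes everything under results/.
#
# The cohort uses a reduced geometry (32 channels, 128 Hz, 10 subjects)
# so the whole workflow runs in minutes on one CPU; the package defaults
# reproduce the full 128-channel, 256 Hz recording setup.

library(entityeeg)

dir.create("results/cohort", showWarnings = FALSE, recursive = TRUE)
seed <- 2026L

design <- build_design(seed = seed)
print(design)
write_design_tsv(design, "results/design.tsv")

sched <- generate_schedule(design, n_runs = 24L, seed = seed + 1L)
print(sched)
tab <- schedule_table(sched)
cat(sprintf("per-run questions: %d coarse / %d fine (%d expecting 'correct')\n",
            sum(tab$question_kind == "coarse" & tab$run == 1),
            sum(tab$question_kind == "fine" & tab$run == 1),
            sum(tab$expected_answer == "correct" & tab$run == 1, na.rm = TRUE)))
write_schedule_tsv(sched, "results/schedule.tsv")

vectors <- generate_entity_vectors(design, dim = 50L, seed = seed + 2L)
write_vector_set_tsv(vectors, "results/entity_vectors.tsv")
cat(sprintf("entity vectors: %d x %d\n", length(vectors$names), vectors$dim))

config <- generator_config(n_channels = 32L, rate = 128, noise_sd = 5,
                           n_repetitions = 24L, seed = seed + 3L)
n_subjects <- 10L
cat(sprintf("simulating %d subjects...\n", n_subjects))
cohort <- generate_cohort(design, vectors, config, n_subjects = n_subjects)

for (subject in cohort) {
  evoked <- preprocess_subject(subject, design)
  write_epoch_container(evoked, file.path("results/cohort", evoked$subject_id))
  cat(sprintf("  %s: %d trials -> %d evoked responses\n", subject$subject_id,
              dim(subject$trials)[1], dim(evoked$evoked)[1]))
}
cat("wrote results/design.tsv, results/schedule.tsv, results/entity_vectors.tsv,",
    "results/cohort/<subject>/\n")
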