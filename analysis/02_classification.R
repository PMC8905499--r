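#!/usr/bin/env Rscript

# Step 2 — time-resolved category classification.
#
# For every subject of the simulated cohort, trains a linear SVM
# separately at each (decimated) timepoint under the confound-controlled
# split plans: people-vs-places (chance 0.5), eight fine-grained
# categories (chance 0.125), four categories within each coarse branch
# (chance 0.25), and the entity-to-noun transfer task. Group-level
# significance of above-chance decoding uses TFCE with sign-flip
# permutations (10 ms temporal adjacency, max-statistic correction).
#
# Reads results/cohort/ from step 1; writes accuracy time courses and
# TFCE significance tables under results/.

library(entityeeg)

design <- read_design_tsv("results/design.tsv")
subject_dirs <- list.dirs("results/cohort", recursive = FALSE)
cohort <- lapply(subject_dirs, read_epoch_container)
cat(sprintf("loaded %d subjects\n", length(cohort)))

times <- cohort[[1]]$times
timepoints <- seq(1L, length(times), by = 8L)  # ~60 ms grid for speed
cat(sprintf("evaluating %d of %d timepoints\n", length(timepoints), length(times)))

# each task's splits are selected against its own label encoding (coarse
# labels for people-vs-places, fine labels for the 8-way task)
cands4 <- enumerate_balanced_test_sets(design)
plan_coarse <- select_confound_controlled(cands4, design, n_select = 50L,
                                          label = "coarse")
plan_fine <- select_confound_controlled(cands4, design, n_select = 50L,
                                        label = "fine")
for (p in list(coarse = plan_coarse, fine = plan_fine)) {
  rhos <- vapply(p$splits, `[[`, numeric(1), "rho")
  cat(sprintf("leave-4-out plan: %d/%d candidates kept, max |rho| = %.3f\n",
              length(p$splits), length(cands4), max(abs(rhos))))
}
write_split_plan_json(plan_fine, "results/split_plan_leave4.json")

report <- function(tc, label) {
  sig <- permutation_significance(tc$accuracies - tc$chance, tc$times,
                                  n_perm = 1024L, seed = 99L)
  n_sig <- sum(sig$significant_mask)
  win <- if (n_sig > 0)
    sprintf("%d significant timepoints, %.0f-%.0f ms",
            n_sig, min(tc$times[sig$significant_mask]),
            max(tc$times[sig$significant_mask]))
  else "no significant timepoints"
  cat(sprintf("%-22s peak %.3f at %.0f ms (chance %.3f); %s\n", label,
              max(colMeans(tc$accuracies)),
              tc$times[which.max(colMeans(tc$accuracies))], tc$chance, win))
  write_timecourse_csv(tc, sprintf("results/accuracy_%s.csv", label))
  write_significance_csv(sig, sprintf("results/tfce_%s.csv", label))
}

report(time_resolved_classification(cohort, design, "coarse", plan_coarse,
                                    timepoints = timepoints), "coarse")
report(time_resolved_classification(cohort, design, "fine", plan_fine,
                                    timepoints = timepoints), "fine")

for (co in c("person", "place")) {
  task <- if (co == "person") "within_people" else "within_places"
  plan2 <- select_confound_controlled(
    enumerate_within_coarse_test_sets(design, co), design, n_select = 96L)
  report(time_resolved_classification(cohort, design, task, plan2,
                                      timepoints = timepoints), task)
}

# entity -> category-noun transfer (whole dataset, no split plan); with the
# generator's default shared noun templates the category code transfers
report(transfer_classification(cohort, design, "coarse",
                               timepoints = timepoints), "transfer_coarse")
report(transfer_classification(cohort, design, "fine",
                               timepoints = timepoints), "transfer_fine")
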